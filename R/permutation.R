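# Shuffle null and polarization classification.
#
# The null hypothesis is "no spatial structure in expression": shuffling the
# measured intensities across the fixed nucleus positions preserves the
# geometry (centroid, radius of gyration) and the intensity multiset while
# destroying any spatial domain. A structure is called polarized when its
# observed normalized polarization magnitude exceeds the magnitude in at
# least `percentile_threshold` of the shuffled draws, ties counting against
# the call.

#' Null distribution of the polarization magnitude by intensity shuffling
#'
#' Each draw permutes the weight vector uniformly at random (without
#' replacement) over the fixed positions and records the normalized
#' polarization magnitude. Positions, radius of gyration and the weight
#' multiset are identical across draws.
#'
#' @inheritParams polarization_vector
#' @param n_perm number of random permutations (>= 1).
#' @param seed integer RNG seed; the same seed reproduces the same null.
#' @param return_vectors if `TRUE`, also return the normalized null vector
#'   components (needed by the `mean_vector` slice-combination rule).
#' @return numeric vector of `n_perm` null magnitudes; with
#'   `return_vectors = TRUE`, a list with `magnitudes` and an
#'   `n_perm x 2` matrix `vectors`.
#' @export
permutation_null <- function(positions, weights, n_perm = 100, seed = 1,
                             norm_exponent = 1, return_vectors = FALSE) {
  positions <- as_position_matrix(positions)
  stopifnot(n_perm >= 1, length(weights) == nrow(positions))
  if (nrow(positions) < 2) stop("need at least 2 positions")
  if (any(weights < 0)) stop("weights must be non-negative")
  if (sum(weights) == 0) stop("all weights are zero: null undefined")
  centered <- sweep(positions, 2, colMeans(positions))
  r_norm <- radius_of_gyration(positions)^norm_exponent
  w_sum <- sum(weights)
  local_seed(seed, {
    vecs <- matrix(NA_real_, n_perm, 2)
    for (k in seq_len(n_perm)) {
      w <- sample(weights)
      vecs[k, ] <- colSums(centered * w) / w_sum / r_norm
    }
    mags <- sqrt(rowSums(vecs^2))
    if (return_vectors) list(magnitudes = mags, vectors = vecs) else mags
  })
}

#' Classify a structure as polarized against its shuffle null
#'
#' `exceed_fraction` is the fraction of null draws strictly below the
#' observed magnitude; the structure is polarized when that fraction reaches
#' `percentile_threshold`. Ties count against the polarized call, so a
#' degenerate observed statistic of zero (e.g. uniform weights) is never
#' flagged. The null mean magnitude is reported alongside the percentile
#' verdict.
#'
#' @param observed_p observed normalized polarization magnitude, or a
#'   [polarization_vector()] result.
#' @param null_p numeric vector of null magnitudes from [permutation_null()].
#' @param percentile_threshold fraction of the null the observation must
#'   exceed (default 0.95).
#' @param seed the seed used for the null, recorded in the result.
#' @return a `permutation_result` list: `observed_p`, `n_perm`,
#'   `exceed_fraction`, `polarized`, `null_mean`, `null_q`, `threshold`,
#'   `seed`, `defined`.
#' @export
classify_polarized <- function(observed_p, null_p,
                               percentile_threshold = 0.95, seed = NA) {
  if (inherits(observed_p, "polarization_result")) {
    if (!observed_p$defined) {
      res <- list(observed_p = NA_real_, n_perm = length(null_p),
                  exceed_fraction = NA_real_, polarized = NA,
                  null_mean = mean(null_p),
                  null_q = stats::quantile(null_p, percentile_threshold,
                                           names = FALSE),
                  threshold = percentile_threshold, seed = seed,
                  defined = FALSE)
      class(res) <- "permutation_result"
      return(res)
    }
    observed_p <- observed_p$p
  }
  stopifnot(length(null_p) >= 1, is.finite(observed_p))
  exceed <- mean(null_p < observed_p)
  res <- list(observed_p = observed_p, n_perm = length(null_p),
              exceed_fraction = exceed,
              polarized = exceed >= percentile_threshold,
              null_mean = mean(null_p),
              null_q = stats::quantile(null_p, percentile_threshold,
                                       names = FALSE),
              threshold = percentile_threshold, seed = seed, defined = TRUE)
  class(res) <- "permutation_result"
  res
}

#' One-call permutation test of an expression domain
#'
#' Convenience wrapper: computes the observed [polarization_vector()], its
#' [permutation_null()], and the [classify_polarized()] verdict.
#'
#' @inheritParams permutation_null
#' @inheritParams classify_polarized
#' @return a `permutation_result` with the null magnitudes attached as
#'   `null_p` (and normalized observed/null vectors as `observed_vec` /
#'   `null_vectors` when `return_vectors = TRUE`).
#' @export
permutation_test <- function(positions, weights, n_perm = 100, seed = 1,
                             norm_exponent = 1, percentile_threshold = 0.95,
                             return_vectors = FALSE) {
  obs <- suppressWarnings(
    polarization_vector(positions, weights, norm_exponent))
  if (!obs$defined) {
    stop("all weights are zero: permutation test undefined")
  }
  null <- permutation_null(positions, weights, n_perm, seed, norm_exponent,
                           return_vectors = return_vectors)
  mags <- if (return_vectors) null$magnitudes else null
  res <- classify_polarized(obs, mags, percentile_threshold, seed)
  res$null_p <- mags
  res$observed_result <- obs
  if (return_vectors) {
    res$observed_vec <- obs$raw_vector / obs$r_gyr^norm_exponent
    res$null_vectors <- null$vectors
  }
  res
}

#' Combine per-slice polarization calls into one aggregate-level call
#'
#' The study design measures two independent Z-slices per aggregate; the rule
#' combining them into one per-aggregate call is configurable:
#' `"any"` (default) flags the aggregate if any slice is polarized, `"all"`
#' requires every slice, and `"mean_vector"` re-tests the magnitude of the
#' slice-averaged normalized vector against the per-draw average of the
#' slices' null vectors (requires results from
#' `permutation_test(..., return_vectors = TRUE)` with equal `n_perm`).
#'
#' @param slice_results list of `permutation_result`s for one aggregate and
#'   one channel.
#' @param rule `"any"`, `"all"` or `"mean_vector"`.
#' @param percentile_threshold threshold for the `mean_vector` re-test
#'   (default: the threshold stored in the first slice result).
#' @return a list with `polarized`, `rule`, `n_slices`, and for
#'   `mean_vector` the combined `observed_p` and `exceed_fraction`.
#' @export
combine_slices <- function(slice_results, rule = c("any", "all",
                                                   "mean_vector"),
                           percentile_threshold = NULL) {
  rule <- match.arg(rule)
  stopifnot(length(slice_results) >= 1)
  flags <- vapply(slice_results, function(r) isTRUE(r$polarized), TRUE)
  out <- list(rule = rule, n_slices = length(slice_results))
  if (rule == "any") {
    out$polarized <- any(flags)
  } else if (rule == "all") {
    out$polarized <- all(flags)
  } else {
    have_vecs <- vapply(slice_results,
                        function(r) !is.null(r$null_vectors), TRUE)
    if (!all(have_vecs)) {
      stop("mean_vector rule needs results with return_vectors = TRUE")
    }
    n_perms <- vapply(slice_results, function(r) r$n_perm, 0)
    if (length(unique(n_perms)) != 1) {
      stop("mean_vector rule needs equal n_perm across slices")
    }
    obs_vec <- Reduce(`+`, lapply(slice_results, `[[`, "observed_vec")) /
      length(slice_results)
    null_vecs <- Reduce(`+`, lapply(slice_results, `[[`, "null_vectors")) /
      length(slice_results)
    obs_mag <- sqrt(sum(obs_vec^2))
    null_mags <- sqrt(rowSums(null_vecs^2))
    thr <- percentile_threshold %||% slice_results[[1]]$threshold
    cl <- classify_polarized(obs_mag, null_mags, thr)
    out$polarized <- cl$polarized
    out$observed_p <- cl$observed_p
    out$exceed_fraction <- cl$exceed_fraction
  }
  out
}

#' Permutation tests for every slice and channel of a nucleus table
#'
#' Runs [permutation_test()] per (aggregate, slice, channel) with a sub-seed
#' derived deterministically from the master seed and the identifiers, then
#' combines slices per aggregate with [combine_slices()].
#'
#' @inheritParams compute_polarization
#' @param n_perm,percentile_threshold,norm_exponent test parameters.
#' @param master_seed master RNG seed; per-test seeds come from
#'   [derive_seed()].
#' @param combine_rule slice-combination rule (see [combine_slices()]).
#' @return list with `slices` (per-slice data frame: observed p, exceed
#'   fraction, polarized flag, null mean/quantile, seed) and `aggregates`
#'   (per-aggregate, per-channel combined flags).
#' @export
run_permutation_tests <- function(table, channels, n_perm = 100,
                                  percentile_threshold = 0.95,
                                  norm_exponent = 1, master_seed = 1,
                                  combine_rule = "any") {
  need_vecs <- combine_rule == "mean_vector"
  slice_rows <- list()
  agg_rows <- list()
  for (agg in unique(table$aggregate_id)) {
    at <- table[table$aggregate_id == agg, ]
    for (ch in names(channels)) {
      comp <- channels[[ch]]
      per_slice <- list()
      for (sl in unique(at$slice_id)) {
        sub <- at[at$slice_id == sl & at$compartment == comp, ]
        seed <- derive_seed(master_seed, agg, sl, ch)
        row <- data.frame(aggregate_id = agg, slice_id = sl, channel = ch,
                          compartment = comp, n_nuclei = nrow(sub),
                          observed_p = NA_real_,
                          exceed_fraction = NA_real_, polarized = NA,
                          null_mean = NA_real_, null_q = NA_real_,
                          n_perm = n_perm,
                          threshold = percentile_threshold,
                          seed = seed, stringsAsFactors = FALSE)
        wcol <- rescaled_col(ch)
        if (nrow(sub) >= 2 && !is.null(sub[[wcol]]) &&
            sum(sub[[wcol]]) > 0) {
          pt <- permutation_test(cbind(sub$x_um, sub$y_um), sub[[wcol]],
                                 n_perm = n_perm, seed = seed,
                                 norm_exponent = norm_exponent,
                                 percentile_threshold = percentile_threshold,
                                 return_vectors = need_vecs)
          row$observed_p <- pt$observed_p
          row$exceed_fraction <- pt$exceed_fraction
          row$polarized <- pt$polarized
          row$null_mean <- pt$null_mean
          row$null_q <- pt$null_q
          per_slice[[length(per_slice) + 1]] <- pt
        }
        slice_rows[[length(slice_rows) + 1]] <- row
      }
      if (length(per_slice) > 0) {
        comb <- combine_slices(per_slice, combine_rule)
        agg_rows[[length(agg_rows) + 1]] <-
          data.frame(aggregate_id = agg, channel = ch, rule = combine_rule,
                     n_slices = comb$n_slices, polarized = comb$polarized,
                     stringsAsFactors = FALSE)
      }
    }
  }
  list(slices = do.call(rbind, slice_rows),
       aggregates = if (length(agg_rows)) do.call(rbind, agg_rows) else NULL)
}
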