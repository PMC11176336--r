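# Relative orientation of two expression domains.

#' Unsigned angle between two 2D vectors
#'
#' `acos` of the normalized dot product, reported in degrees on `[0, 180]`.
#' Symmetric in its arguments and invariant to positive rescaling of either
#' vector; signed angles are not meaningful without a fixed anatomical frame.
#'
#' @param vec_a,vec_b numeric length-2 vectors; both must be nonzero.
#' @return angle in degrees.
#' @export
#' @examples
#' angle_between(c(1, 0), c(0, 1))  # 90
angle_between <- function(vec_a, vec_b) {
  stopifnot(length(vec_a) == 2, length(vec_b) == 2,
            all(is.finite(vec_a)), all(is.finite(vec_b)))
  na <- sqrt(sum(vec_a^2))
  nb <- sqrt(sum(vec_b^2))
  if (na == 0 || nb == 0) {
    stop("angle between vectors undefined: zero vector")
  }
  cosang <- sum(vec_a * vec_b) / (na * nb)
  acos(pmin(pmax(cosang, -1), 1)) * 180 / pi
}

#' Angles between two channels' polarization vectors, per slice
#'
#' Joins the polarization table on (aggregate, slice) and computes
#' [angle_between()] for the two channels' raw vectors. Slices where either
#' vector is undefined or zero get `defined = FALSE` instead of an angle.
#' When a per-slice classification table is supplied, each row also carries
#' the two channels' polarized flags so angles from non-polarized structures
#' can be reported separately rather than dropped.
#'
#' @param polarization result of [compute_polarization()].
#' @param channel_a,channel_b the two channel names.
#' @param classification optional `slices` table from
#'   [run_permutation_tests()].
#' @return data frame: aggregate_id, slice_id, angle_deg in `[0, 180]`,
#'   defined, polarized_a, polarized_b.
#' @export
compute_angles <- function(polarization, channel_a, channel_b,
                           classification = NULL) {
  a <- polarization[polarization$channel == channel_a, ]
  b <- polarization[polarization$channel == channel_b, ]
  key_a <- paste(a$aggregate_id, a$slice_id, sep = "\r")
  key_b <- paste(b$aggregate_id, b$slice_id, sep = "\r")
  keys <- intersect(key_a, key_b)
  out <- list()
  for (key in keys) {
    ra <- a[key_a == key, ][1, ]
    rb <- b[key_b == key, ][1, ]
    ok <- isTRUE(ra$defined) && isTRUE(rb$defined) &&
      (ra$px_um^2 + ra$py_um^2) > 0 && (rb$px_um^2 + rb$py_um^2) > 0
    ang <- if (ok) {
      angle_between(c(ra$px_um, ra$py_um), c(rb$px_um, rb$py_um))
    } else {
      NA_real_
    }
    pol_a <- pol_b <- NA
    if (!is.null(classification)) {
      ca <- classification[classification$aggregate_id == ra$aggregate_id &
                             classification$slice_id == ra$slice_id &
                             classification$channel == channel_a, ]
      cb <- classification[classification$aggregate_id == ra$aggregate_id &
                             classification$slice_id == ra$slice_id &
                             classification$channel == channel_b, ]
      if (nrow(ca)) pol_a <- ca$polarized[1]
      if (nrow(cb)) pol_b <- cb$polarized[1]
    }
    out[[length(out) + 1]] <-
      data.frame(aggregate_id = ra$aggregate_id, slice_id = ra$slice_id,
                 channel_a = channel_a, channel_b = channel_b,
                 angle_deg = ang, defined = ok,
                 polarized_a = pol_a, polarized_b = pol_b,
                 stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Summarize inter-domain angles per group, with a uniformity check
#'
#' For each group (typically polarized vs non-polarized structures) reports
#' the count, median angle, and a histogram over `n_bins` equal bins of
#' `[0, 180]`. Uniformity is assessed by Monte Carlo: the angle between two
#' independent uniformly oriented vectors is uniform on `[0, 180]`, so the
#' observed Kolmogorov-Smirnov distance from that uniform law is compared
#' with `n_mc` simulated samples of the same size; the empirical p-value is
#' the fraction of simulations at least as extreme.
#'
#' @param angles data frame from [compute_angles()] (or any frame with an
#'   `angle_deg` column).
#' @param group optional factor/character grouping vector (one per row);
#'   default: a single group `"all"`.
#' @param n_bins number of histogram bins over `[0, 180]`.
#' @param n_mc Monte Carlo replicates for the uniformity check.
#' @param seed RNG seed for the Monte Carlo draw.
#' @return data frame with one row per group: n, median_angle_deg,
#'   uniformity_p, and bin counts `bin_<lo>_<hi>`.
#' @export
orientation_summary <- function(angles, group = NULL, n_bins = 6,
                                n_mc = 1000, seed = 1) {
  stopifnot(n_bins >= 1)
  ang <- angles$angle_deg
  group <- group %||% rep("all", length(ang))
  stopifnot(length(group) == length(ang))
  keep <- is.finite(ang)
  ang <- ang[keep]
  group <- group[keep]
  if (length(ang) == 0) stop("no defined angles to summarize")
  breaks <- seq(0, 180, length.out = n_bins + 1)
  rows <- list()
  for (g in unique(group)) {
    x <- ang[group == g]
    counts <- as.integer(table(cut(x, breaks, include.lowest = TRUE)))
    ks_obs <- ks_stat_uniform(x)
    p_mc <- local_seed(derive_seed(seed, g), {
      sims <- replicate(n_mc,
                        ks_stat_uniform(stats::runif(length(x), 0, 180)))
      (1 + sum(sims >= ks_obs)) / (n_mc + 1)
    })
    row <- data.frame(group = g, n = length(x),
                      median_angle_deg = stats::median(x),
                      uniformity_p = p_mc, stringsAsFactors = FALSE)
    for (i in seq_len(n_bins)) {
      row[[sprintf("bin_%d_%d", round(breaks[i]), round(breaks[i + 1]))]] <-
        counts[i]
    }
    rows[[length(rows) + 1]] <- row
  }
  do.call(rbind, rows)
}

# Kolmogorov-Smirnov distance of a sample from Uniform(0, 180).
ks_stat_uniform <- function(x) {
  n <- length(x)
  u <- sort(x) / 180
  max(pmax(seq_len(n) / n - u, u - (seq_len(n) - 1) / n))
}

#' Circular-aware median of angles on \[0, 180\]
#'
#' Used to aggregate the per-slice angles of one aggregate: the plain median
#' is adequate away from the wrap point, but angles are first doubled onto
#' the circle, averaged as unit vectors, and the member angle closest to the
#' resulting direction is returned, so near-0/near-180 mixtures do not
#' average to 90.
#'
#' @param angles_deg numeric angles in `[0, 180]`.
#' @return one angle in `[0, 180]`.
#' @export
circular_median_axial <- function(angles_deg) {
  angles_deg <- angles_deg[is.finite(angles_deg)]
  stopifnot(length(angles_deg) >= 1)
  if (length(angles_deg) == 1) return(angles_deg)
  doubled <- angles_deg * 2 * pi / 180
  mean_dir <- atan2(mean(sin(doubled)), mean(cos(doubled))) / 2 * 180 / pi
  mean_dir <- mean_dir %% 180
  d <- abs(angles_deg - mean_dir)
  d <- pmin(d, 180 - d)
  angles_deg[which.min(d)]
}
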