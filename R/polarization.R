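# The polarization statistic: intensity-weighted mean displacement of nuclei
# from the unweighted compartment centroid, normalized by the compartment's
# radius of gyration.

#' Radius of gyration of a set of positions
#'
#' `R_gyr = sqrt(mean(|r_i - c|^2))` with `c` the unweighted centroid — the
#' root-mean-square distance of the compartment's nuclei from their centroid,
#' used as the structure-size scale.
#'
#' @param positions n x 2 matrix (or data frame with `x_um`/`y_um`) in um.
#' @return radius of gyration in um.
#' @export
#' @examples
#' radius_of_gyration(rbind(c(0, 0), c(1, 0), c(0, 1), c(1, 1)))  # sqrt(0.5)
radius_of_gyration <- function(positions) {
  positions <- as_position_matrix(positions)
  if (nrow(positions) < 2) {
    stop("radius of gyration needs at least 2 positions")
  }
  centered <- sweep(positions, 2, colMeans(positions))
  sqrt(mean(rowSums(centered^2)))
}

#' Intensity-weighted polarization vector of an expression domain
#'
#' The raw vector is the weighted mean displacement from the unweighted
#' centroid, `P = sum(w_i * (r_i - c)) / sum(w_i)`; uniform weights therefore
#' give exactly `(0, 0)`. The normalized magnitude is
#' `p = |P| / R_gyr^norm_exponent`: dimensionless and scale-invariant with
#' exponent 1 (the default), in 1/um with exponent 2. Weights are the
#' rescaled per-nucleus median intensities of the channel, restricted to the
#' channel's own compartment.
#'
#' @param positions n x 2 matrix (um), n >= 2.
#' @param weights non-negative weights, one per position.
#' @param norm_exponent 1 or 2: the power of `R_gyr` used for normalization.
#' @return a `polarization_result` list with `raw_vector`, `magnitude`
#'   (`|P|`, um), `r_gyr`, `p` (normalized magnitude), `domain_angle_deg`
#'   (in `[0, 360)`; `NA` for a zero vector), `n_nuclei`, `norm_exponent`,
#'   and `defined` (`FALSE` when all weights are zero).
#' @export
#' @examples
#' pos <- rbind(c(0, 0), c(2, 0), c(0, 2), c(2, 2))
#' polarization_vector(pos, c(1, 1, 1, 3))$p  # 1/3
polarization_vector <- function(positions, weights, norm_exponent = 1) {
  positions <- as_position_matrix(positions)
  stopifnot(length(weights) == nrow(positions),
            all(is.finite(weights)), norm_exponent %in% c(1, 2))
  if (nrow(positions) < 2) stop("need at least 2 positions")
  if (any(weights < 0)) stop("weights must be non-negative")
  r_gyr <- radius_of_gyration(positions)
  res <- list(raw_vector = c(NA_real_, NA_real_), magnitude = NA_real_,
              r_gyr = r_gyr, p = NA_real_, domain_angle_deg = NA_real_,
              n_nuclei = nrow(positions),
              norm_exponent = norm_exponent, defined = FALSE)
  class(res) <- "polarization_result"
  if (sum(weights) == 0) {
    warning("all weights are zero: polarization undefined")
    return(res)
  }
  centered <- sweep(positions, 2, colMeans(positions))
  raw <- colSums(centered * weights) / sum(weights)
  mag <- sqrt(sum(raw^2))
  res$raw_vector <- raw
  res$magnitude <- mag
  res$p <- mag / r_gyr^norm_exponent
  res$domain_angle_deg <- if (mag > 0) {
    (atan2(raw[2], raw[1]) * 180 / pi) %% 360
  } else {
    NA_real_
  }
  res$defined <- TRUE
  res
}

#' Domain angle of a polarization result
#'
#' Angle of the raw polarization vector from the +x axis, in degrees in
#' `[0, 360)`, in the stored (image) coordinate frame.
#'
#' @param result a [polarization_vector()] result.
#' @return angle in degrees.
#' @export
domain_angle <- function(result) {
  stopifnot(inherits(result, "polarization_result"))
  if (!result$defined || !is.finite(result$magnitude) ||
      result$magnitude == 0) {
    stop("domain angle undefined for a zero or undefined polarization vector")
  }
  result$domain_angle_deg
}

#' Per-slice, per-channel polarization table
#'
#' Computes [polarization_vector()] for every (aggregate, slice, channel)
#' combination, using each channel's rescaled intensities as weights over the
#' nuclei of the channel's own compartment.
#'
#' @param table a rescaled nucleus table.
#' @param channels named character vector mapping channel name ->
#'   compartment (`"Epi"` or `"VE"`).
#' @param norm_exponent passed to [polarization_vector()].
#' @return data frame with one row per (aggregate_id, slice_id, channel):
#'   compartment, raw vector components, `r_gyr`, `p`, domain angle, number
#'   of nuclei, and a `defined` flag.
#' @export
compute_polarization <- function(table, channels, norm_exponent = 1) {
  stopifnot(length(channels) >= 1, !is.null(names(channels)))
  out <- list()
  for (key in unique(paste(table$aggregate_id, table$slice_id, sep = "\r"))) {
    sl <- table[paste(table$aggregate_id, table$slice_id, sep = "\r") == key, ]
    for (ch in names(channels)) {
      comp <- channels[[ch]]
      sub <- sl[sl$compartment == comp, ]
      wcol <- rescaled_col(ch)
      if (is.null(sub[[wcol]])) {
        stop("channel '", ch, "' has no rescaled intensities; ",
             "run rescale_intensities() first")
      }
      row <- data.frame(aggregate_id = sl$aggregate_id[1],
                        slice_id = sl$slice_id[1],
                        channel = ch, compartment = comp,
                        n_nuclei = nrow(sub),
                        px_um = NA_real_, py_um = NA_real_,
                        r_gyr_um = NA_real_, p = NA_real_,
                        domain_angle_deg = NA_real_,
                        norm_exponent = norm_exponent,
                        defined = FALSE,
                        stringsAsFactors = FALSE)
      if (nrow(sub) >= 2 && sum(sub[[wcol]]) > 0) {
        pv <- polarization_vector(cbind(sub$x_um, sub$y_um), sub[[wcol]],
                                  norm_exponent)
        row$px_um <- pv$raw_vector[1]
        row$py_um <- pv$raw_vector[2]
        row$r_gyr_um <- pv$r_gyr
        row$p <- pv$p
        row$domain_angle_deg <- pv$domain_angle_deg
        row$defined <- pv$defined
      }
      out[[length(out) + 1]] <- row
    }
  }
  do.call(rbind, out)
}
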