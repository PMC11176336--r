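# Synthetic aggregate slices and clonal cultures with known ground truth.
#
# The generator emulates a single optical section through a bilayered
# aggregate: an inner epiblast-like (Epi) disk and an outer visceral-endoderm
# (VE) annulus separated at the basement-membrane ("Laminin-ring") radius.
# Expression domains are angular: each channel's mean intensity follows a von
# Mises density around a domain angle, rescaled so its peak equals the channel
# amplitude, with concentration kappa = 0 recovering the angularly uniform
# (null) case exactly.

#' Specify one synthetic intensity channel
#'
#' The per-nucleus mean intensity in the channel's own compartment is
#' `baseline + amplitude * g(theta)`, where
#' `g(theta) = exp(kappa * (cos(theta - theta0) - 1))` is the von Mises
#' density rescaled to peak 1 at the domain angle `theta0`. Nuclei in the
#' other compartment receive only the baseline. Independent Gaussian noise
#' (`noise_sd` of the slice configuration) is added and the result clipped
#' at zero.
#'
#' @param name channel name (becomes column `intensity_<name>`).
#' @param compartment `"Epi"` or `"VE"`: the compartment carrying the domain.
#' @param baseline non-negative baseline intensity (a.u.).
#' @param amplitude non-negative domain amplitude (a.u.).
#' @param theta0 domain angle in degrees.
#' @param kappa von Mises concentration; `0` means angularly uniform (null).
#' @return a `channel_spec` list.
#' @export
#' @examples
#' channel_spec("cer1", "VE", theta0 = 90, kappa = 4)
channel_spec <- function(name, compartment = c("VE", "Epi"),
                         baseline = 0.1, amplitude = 0.5,
                         theta0 = 0, kappa = 0) {
  compartment <- match.arg(compartment)
  stopifnot(is.character(name), nchar(name) > 0,
            baseline >= 0, amplitude >= 0, kappa >= 0,
            is.finite(theta0))
  structure(list(name = name, compartment = compartment,
                 baseline = baseline, amplitude = amplitude,
                 theta0 = theta0, kappa = kappa),
            class = "channel_spec")
}

#' Default channel pair: an AVE-like reporter in the VE and a mesoderm-like
#' marker in the Epi, on opposite sides of the aggregate.
#' @export
default_channels <- function() {
  list(channel_spec("cer1", "VE", theta0 = 90, kappa = 4),
       channel_spec("bra", "Epi", theta0 = 270, kappa = 4))
}

#' Configuration for a synthetic aggregate slice
#'
#' Geometry defaults describe a mid-plane section of a roughly 200 um
#' aggregate with a basement-membrane ring at 45 um; nucleus centers keep a
#' minimum pairwise distance of one nucleus diameter (rejection sampling).
#'
#' @param n_epi,n_ve number of Epi / VE nuclei (>= 0).
#' @param r_ring Laminin-ring radius in um (Epi/VE boundary).
#' @param r_out outer aggregate radius in um; must exceed `r_ring`.
#' @param channels list of [channel_spec()] objects.
#' @param noise_sd additive Gaussian intensity noise SD (a.u.).
#' @param nucleus_diameter nominal nucleus diameter in um; sets the minimum
#'   center spacing and the rendered disc size.
#' @param seed integer RNG seed; identical configurations reproduce
#'   identical slices.
#' @param pixel_size um per pixel, used only by [render_slice()].
#' @return a `synthetic_config` list.
#' @export
synthetic_config <- function(n_epi = 40, n_ve = 150,
                             r_ring = 45, r_out = 100,
                             channels = default_channels(),
                             noise_sd = 0.1, nucleus_diameter = 8,
                             seed = 1, pixel_size = 0.5) {
  stopifnot(n_epi >= 0, n_ve >= 0,
            r_ring > 0, r_out > r_ring,
            noise_sd >= 0, nucleus_diameter > 0, pixel_size > 0,
            length(channels) >= 1)
  if (!all(vapply(channels, inherits, TRUE, "channel_spec"))) {
    stop("`channels` must be a list of channel_spec objects")
  }
  nm <- vapply(channels, `[[`, "", "name")
  if (anyDuplicated(nm)) stop("channel names must be unique")
  structure(list(n_epi = n_epi, n_ve = n_ve, r_ring = r_ring, r_out = r_out,
                 channels = channels, noise_sd = noise_sd,
                 nucleus_diameter = nucleus_diameter,
                 seed = as.integer(seed), pixel_size = pixel_size),
            class = "synthetic_config")
}

# Rejection-sample n points uniformly in the annulus [r_min, r_max] keeping a
# minimum center distance to every already-accepted point. Errors out after
# max_reject consecutive rejections (infeasible packing).
place_points <- function(n, r_min, r_max, min_dist, existing = NULL,
                         max_reject = 1e4) {
  if (n == 0) return(matrix(numeric(0), 0, 2))
  pts <- matrix(NA_real_, n, 2)
  n_placed <- 0L
  consecutive <- 0L
  while (n_placed < n) {
    r <- sqrt(stats::runif(1, r_min^2, r_max^2))
    phi <- stats::runif(1, 0, 2 * pi)
    cand <- c(r * cos(phi), r * sin(phi))
    ok <- TRUE
    if (n_placed > 0) {
      d2 <- (pts[seq_len(n_placed), 1] - cand[1])^2 +
        (pts[seq_len(n_placed), 2] - cand[2])^2
      ok <- all(d2 >= min_dist^2)
    }
    if (ok && !is.null(existing) && nrow(existing) > 0) {
      d2 <- (existing[, 1] - cand[1])^2 + (existing[, 2] - cand[2])^2
      ok <- all(d2 >= min_dist^2)
    }
    if (ok) {
      n_placed <- n_placed + 1L
      pts[n_placed, ] <- cand
      consecutive <- 0L
    } else {
      consecutive <- consecutive + 1L
      if (consecutive >= max_reject) {
        stop("infeasible packing: ", consecutive,
             " consecutive rejections while placing point ", n_placed + 1L,
             " of ", n)
      }
    }
  }
  pts
}

# von Mises density rescaled to peak 1; exactly 1 everywhere at kappa = 0.
von_mises_profile <- function(theta, theta0_deg, kappa) {
  exp(kappa * (cos(theta - theta0_deg * pi / 180) - 1))
}

#' Generate one synthetic aggregate slice with ground truth
#'
#' Epi nucleus centers are uniform in the disk of radius
#' `r_ring - nucleus_diameter / 2`; VE centers are uniform in the annulus
#' between `r_ring + nucleus_diameter / 2` and `r_out - nucleus_diameter / 2`,
#' so all centroids respect their compartment boundaries. A minimum pairwise
#' center distance of one nucleus diameter is enforced by rejection sampling.
#' Channel intensities follow the [channel_spec()] model. The aggregate
#' center is at the origin.
#'
#' @param config a [synthetic_config()].
#' @param aggregate_id,slice_id identifiers written into the table.
#' @return a list with elements
#'   * `nuclei`: nucleus table (one row per nucleus: position, area,
#'     circularity, compartment, one `intensity_<channel>` column per channel);
#'   * `truth`: ground truth (per-channel domain angle, concentration and
#'     polarized flag, plus the seed and config).
#' @export
#' @examples
#' sl <- generate_slice(synthetic_config(seed = 7))
#' table(sl$nuclei$compartment)
generate_slice <- function(config, aggregate_id = "synthetic",
                           slice_id = "z1") {
  stopifnot(inherits(config, "synthetic_config"))
  d <- config$nucleus_diameter
  local_seed(config$seed, {
    epi <- place_points(config$n_epi, 0, max(config$r_ring - d / 2, 0), d)
    ve <- place_points(config$n_ve, config$r_ring + d / 2,
                       config$r_out - d / 2, d, existing = epi)
    pos <- rbind(epi, ve)
    n <- nrow(pos)
    compartment <- rep(c("Epi", "VE"), c(config$n_epi, config$n_ve))
    theta <- atan2(pos[, 2], pos[, 1])
    mean_area <- pi * (d / 2)^2
    area <- pmax(stats::rnorm(n, mean_area, 0.08 * mean_area), 0.5 * mean_area)
    circ <- stats::runif(n, 0.88, 0.98)
    tab <- data.frame(aggregate_id = aggregate_id, slice_id = slice_id,
                      nucleus_id = seq_len(n),
                      x_um = pos[, 1], y_um = pos[, 2],
                      area_um2 = area, circularity = circ,
                      compartment = compartment,
                      clonal_label = NA_character_,
                      stringsAsFactors = FALSE)
    for (ch in config$channels) {
      g <- von_mises_profile(theta, ch$theta0, ch$kappa)
      mu <- ch$baseline + ch$amplitude * g * (compartment == ch$compartment)
      tab[[intensity_col(ch$name)]] <-
        pmax(mu + stats::rnorm(n, 0, config$noise_sd), 0)
    }
    truth <- list(
      channels = data.frame(
        name = vapply(config$channels, `[[`, "", "name"),
        compartment = vapply(config$channels, `[[`, "", "compartment"),
        theta0_deg = vapply(config$channels, `[[`, 0, "theta0") %% 360,
        kappa = vapply(config$channels, `[[`, 0, "kappa"),
        amplitude = vapply(config$channels, `[[`, 0, "amplitude"),
        stringsAsFactors = FALSE),
      seed = config$seed, config = config)
    truth$channels$polarized <-
      truth$channels$kappa > 0 & truth$channels$amplitude > 0
    list(nuclei = tab, truth = truth)
  })
}

#' Render a synthetic slice as a label mask and intensity images
#'
#' Nuclei become filled discs (area-matched radius) in a 16-bit-style integer
#' label mask; each channel image carries the nucleus's intensity value on
#' its disc, so per-nucleus median intensities round-trip exactly through
#' [extract_nucleus_table()]. The image origin (pixel `(0, 0)` center) sits at
#' `origin_um` in slice coordinates.
#'
#' @param slice result of [generate_slice()].
#' @param config the [synthetic_config()] used to generate it (`pixel_size`
#'   is taken from here).
#' @param fov_um optional square field-of-view side length in um; must cover
#'   the whole aggregate (`2 * r_out` plus one nucleus diameter).
#' @return list with `label_mask` (integer matrix, rows = y), `channels`
#'   (named list of numeric matrices), `pixel_size`, and `origin_um`
#'   (um coordinates of the first pixel center).
#' @export
render_slice <- function(slice, config, fov_um = NULL) {
  stopifnot(inherits(config, "synthetic_config"))
  ps <- config$pixel_size
  need <- 2 * (config$r_out + config$nucleus_diameter)
  fov_um <- fov_um %||% need
  if (fov_um < 2 * config$r_out) {
    stop("field of view (", fov_um, " um) too small to contain the aggregate",
         " (outer diameter ", 2 * config$r_out, " um)")
  }
  n_px <- ceiling(fov_um / ps)
  origin <- -fov_um / 2
  tab <- slice$nuclei
  labels <- matrix(0L, n_px, n_px)   # rows = y, cols = x
  chans <- lapply(table_channels(tab), function(ch) matrix(0, n_px, n_px))
  names(chans) <- table_channels(tab)
  px_centers <- origin + (seq_len(n_px) - 1) * ps
  for (i in seq_len(nrow(tab))) {
    r_um <- sqrt(tab$area_um2[i] / pi)
    cols <- which(abs(px_centers - tab$x_um[i]) <= r_um)
    rows <- which(abs(px_centers - tab$y_um[i]) <= r_um)
    if (!length(cols) || !length(rows)) next
    dx2 <- (px_centers[cols] - tab$x_um[i])^2
    dy2 <- (px_centers[rows] - tab$y_um[i])^2
    inside <- outer(dy2, dx2, `+`) <= r_um^2
    sub <- labels[rows, cols, drop = FALSE]
    sub[inside] <- tab$nucleus_id[i]
    labels[rows, cols] <- sub
    for (ch in names(chans)) {
      sub <- chans[[ch]][rows, cols, drop = FALSE]
      sub[inside] <- tab[[intensity_col(ch)]][i]
      chans[[ch]][rows, cols] <- sub
    }
  }
  list(label_mask = labels, channels = chans, pixel_size = ps,
       origin_um = c(origin, origin))
}

#' Write a rendered slice to single-plane TIFF files
#'
#' The label mask is written as 16-bit integer TIFF; intensity channels are
#' written as 32-bit float TIFFs (values in arbitrary units).
#'
#' @param rendered result of [render_slice()].
#' @param dir output directory (created if missing).
#' @param prefix file-name prefix.
#' @return named character vector of file paths, invisibly.
#' @export
write_rendered_slice <- function(rendered, dir, prefix = "slice") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (max(rendered$label_mask) > 65535) stop("more than 65535 labels")
  paths <- c(label_mask = file.path(dir, paste0(prefix, "_labels.tif")))
  tiff::writeTIFF(rendered$label_mask / 65535, paths[["label_mask"]],
                  bits.per.sample = 16)
  for (ch in names(rendered$channels)) {
    p <- file.path(dir, paste0(prefix, "_", ch, ".tif"))
    tiff::writeTIFF(rendered$channels[[ch]] / max(rendered$channels[[ch]], 1),
                    p, bits.per.sample = 32)
    paths[[ch]] <- p
  }
  invisible(paths)
}

#' Generate a synthetic 2D clonal-mosaic culture
#'
#' Emulates the mixed-label experiment used to distinguish two origins of
#' marker-positive cell nests in a homogeneous 2D layer: under the `clonal`
#' regime every nest is the progeny of one founder and all members inherit the
#' founder's label; under the `signaling` regime nests are purely spatial
#' neighborhoods and member labels are drawn independently from the label
#' frequencies. Nest members receive high marker intensity
#' (`baseline + amplitude`), all other cells only the baseline; Gaussian noise
#' is added and clipped at zero.
#'
#' Cells are placed with a minimum center spacing of `cell_diameter` um in a
#' square field. Nest founders keep at least `founder_separation` um between
#' them and members lie within `nest_radius` um of their founder, so distinct
#' nests are spatially resolvable.
#'
#' @param n_cells total number of cells.
#' @param labels character vector of clonal label names (>= 1).
#' @param regime `"clonal"` or `"signaling"`.
#' @param nest_params list with `n_nests`, `nest_size`, and optionally
#'   `nest_radius` (um, default 15) and `founder_separation` (um, default 60).
#' @param seed integer RNG seed.
#' @param label_probs label frequencies (default equiprobable).
#' @param field_size square field side in um (default scales with `n_cells`).
#' @param cell_diameter minimum center spacing in um.
#' @param baseline,amplitude,noise_sd marker intensity model (a.u.).
#' @return list with `nuclei` (nucleus table with `clonal_label` and
#'   `intensity_marker` columns) and `truth` (`nests`: data frame of
#'   `nest_id`/`nucleus_id`; `labels`: nucleus id -> label; `regime`).
#' @export
#' @examples
#' cc <- generate_clonal_culture(150, c("A", "B", "C"), "clonal",
#'                               list(n_nests = 5, nest_size = 4), seed = 3)
#' head(cc$truth$nests)
generate_clonal_culture <- function(n_cells, labels,
                                    regime = c("clonal", "signaling"),
                                    nest_params = list(n_nests = 10,
                                                       nest_size = 5),
                                    seed = 1, label_probs = NULL,
                                    field_size = NULL, cell_diameter = 8,
                                    baseline = 0.05, amplitude = 0.6,
                                    noise_sd = 0.05) {
  regime <- match.arg(regime)
  stopifnot(length(labels) >= 1, n_cells >= 1)
  n_nests <- nest_params$n_nests
  nest_size <- nest_params$nest_size
  nest_radius <- nest_params$nest_radius %||% 15
  founder_sep <- nest_params$founder_separation %||% 60
  stopifnot(n_nests >= 0, nest_size >= 1)
  if (n_nests * nest_size > n_cells) {
    stop("nest cells (", n_nests * nest_size, ") exceed n_cells (", n_cells, ")")
  }
  label_probs <- label_probs %||% rep(1 / length(labels), length(labels))
  stopifnot(length(label_probs) == length(labels),
            all(label_probs >= 0), sum(label_probs) > 0)
  label_probs <- label_probs / sum(label_probs)
  field_size <- field_size %||%
    max(sqrt(n_cells * 600), n_nests * 1.2 * founder_sep / 2, 4 * nest_radius)
  half <- field_size / 2

  local_seed(seed, {
    # founders on a wide-spaced point process so nests cannot touch
    founders <- place_points_square(n_nests, half - nest_radius, founder_sep)
    pos <- matrix(numeric(0), 0, 2)
    nest_of <- integer(0)
    for (k in seq_len(n_nests)) {
      members <- place_points(nest_size - 1, 0, nest_radius, cell_diameter,
                              existing = matrix(0, 1, 2))
      members <- sweep(rbind(c(0, 0), members), 2, founders[k, ], `+`)
      pos <- rbind(pos, members)
      nest_of <- c(nest_of, rep(k, nest_size))
    }
    n_free <- n_cells - n_nests * nest_size
    free <- place_points_square(n_free, half, cell_diameter, existing = pos)
    pos <- rbind(pos, free)
    nest_of <- c(nest_of, rep(0L, n_free))
    n <- nrow(pos)

    lab <- sample(labels, n, replace = TRUE, prob = label_probs)
    if (regime == "clonal" && n_nests > 0) {
      founder_label <- sample(labels, n_nests, replace = TRUE,
                              prob = label_probs)
      in_nest <- nest_of > 0
      lab[in_nest] <- founder_label[nest_of[in_nest]]
    }
    marker <- baseline + amplitude * (nest_of > 0)
    marker <- pmax(marker + stats::rnorm(n, 0, noise_sd), 0)
    mean_area <- pi * (cell_diameter / 2)^2
    tab <- data.frame(aggregate_id = "culture", slice_id = "s1",
                      nucleus_id = seq_len(n),
                      x_um = pos[, 1], y_um = pos[, 2],
                      area_um2 = pmax(stats::rnorm(n, mean_area,
                                                   0.08 * mean_area),
                                      0.5 * mean_area),
                      circularity = stats::runif(n, 0.88, 0.98),
                      compartment = "VE",
                      clonal_label = lab,
                      intensity_marker = marker,
                      stringsAsFactors = FALSE)
    truth <- list(
      nests = data.frame(nest_id = nest_of[nest_of > 0],
                         nucleus_id = which(nest_of > 0)),
      labels = stats::setNames(lab, seq_len(n)),
      marker_positive = nest_of > 0,
      regime = regime, seed = seed,
      nest_params = list(n_nests = n_nests, nest_size = nest_size,
                         nest_radius = nest_radius,
                         founder_separation = founder_sep))
    list(nuclei = tab, truth = truth)
  })
}

# Uniform points in the square [-half, half]^2 with a minimum spacing.
place_points_square <- function(n, half, min_dist, existing = NULL,
                                max_reject = 1e4) {
  if (n == 0) return(matrix(numeric(0), 0, 2))
  pts <- matrix(NA_real_, n, 2)
  n_placed <- 0L
  consecutive <- 0L
  while (n_placed < n) {
    cand <- stats::runif(2, -half, half)
    ok <- TRUE
    if (n_placed > 0) {
      d2 <- (pts[seq_len(n_placed), 1] - cand[1])^2 +
        (pts[seq_len(n_placed), 2] - cand[2])^2
      ok <- all(d2 >= min_dist^2)
    }
    if (ok && !is.null(existing) && nrow(existing) > 0) {
      d2 <- (existing[, 1] - cand[1])^2 + (existing[, 2] - cand[2])^2
      ok <- all(d2 >= min_dist^2)
    }
    if (ok) {
      n_placed <- n_placed + 1L
      pts[n_placed, ] <- cand
      consecutive <- 0L
    } else {
      consecutive <- consecutive + 1L
      if (consecutive >= max_reject) {
        stop("infeasible packing in square field after ", consecutive,
             " consecutive rejections")
      }
    }
  }
  pts
}
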