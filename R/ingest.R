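# From segmentation output to a filtered, compartment-annotated,
# intensity-rescaled nucleus table.
#
# Coordinate convention throughout: image axes, x to the right and y down,
# units um, origin at the center of pixel (0, 0), 0-based pixel indexing.
# A centroid is the unweighted mean of member pixel centers.

#' Extract a nucleus table from a label mask and intensity images
#'
#' Consumes the label-mask output of an external nucleus segmentation (e.g.
#' StarDist) together with the matching intensity channels and produces one
#' record per labelled nucleus: centroid position in um, area, circularity
#' (`4 * pi * A / P^2`, with the perimeter measured as the marching-squares
#' contour length of the label's 3x3-smoothed indicator at level 0.5), and
#' the median intensity over
#' the label's pixels in each channel.
#'
#' @param label_mask integer matrix (rows = y, cols = x); background 0,
#'   nuclei labelled with positive integers.
#' @param channel_images named list of numeric matrices with the same
#'   dimensions as `label_mask`.
#' @param pixel_size um per pixel.
#' @param aggregate_id,slice_id identifiers written into the table.
#' @return a nucleus table (data frame), one row per distinct label, sorted
#'   by label.
#' @export
extract_nucleus_table <- function(label_mask, channel_images, pixel_size,
                                  aggregate_id = "img", slice_id = "s1") {
  stopifnot(is.matrix(label_mask), pixel_size > 0)
  if (length(channel_images) > 0 && is.null(names(channel_images))) {
    stop("channel_images must be a named list")
  }
  for (ch in names(channel_images)) {
    if (!identical(dim(channel_images[[ch]]), dim(label_mask))) {
      stop("channel '", ch, "' dimensions do not match the label mask")
    }
  }
  labs <- sort(unique(label_mask[label_mask > 0]))
  if (length(labs) == 0) stop("label mask contains no labels")
  idx_by_label <- split(seq_along(label_mask), match(label_mask, labs,
                                                     nomatch = 0L))
  idx_by_label[["0"]] <- NULL
  nr <- nrow(label_mask)
  out <- data.frame(aggregate_id = aggregate_id, slice_id = slice_id,
                    nucleus_id = as.integer(labs),
                    x_um = NA_real_, y_um = NA_real_,
                    area_um2 = NA_real_, circularity = NA_real_,
                    compartment = NA_character_,
                    clonal_label = NA_character_,
                    stringsAsFactors = FALSE)
  for (ch in names(channel_images)) out[[intensity_col(ch)]] <- NA_real_
  for (k in seq_along(labs)) {
    idx <- idx_by_label[[as.character(k)]]
    row0 <- (idx - 1L) %% nr          # 0-based row (y)
    col0 <- (idx - 1L) %/% nr         # 0-based col (x)
    out$x_um[k] <- mean(col0) * pixel_size
    out$y_um[k] <- mean(row0) * pixel_size
    out$area_um2[k] <- length(idx) * pixel_size^2
    per <- label_perimeter_px(row0, col0) * pixel_size
    out$circularity[k] <- 4 * pi * out$area_um2[k] / per^2
    for (ch in names(channel_images)) {
      out[[intensity_col(ch)]][k] <- stats::median(channel_images[[ch]][idx])
    }
  }
  out
}

# Marching-squares contour length (in pixels) of one label, given the 0-based
# row/col indices of its pixels. The binary indicator is averaged over a 3x3
# neighborhood before contouring at level 0.5: the level set of the smoothed
# coverage interpolates the boundary sub-pixel, removing the staircase bias
# that makes the raw binary contour overestimate perimeters by ~8%.
label_perimeter_px <- function(row0, col0) {
  rmin <- min(row0); cmin <- min(col0)
  nr <- max(row0) - rmin + 5L   # 2-pixel zero pad on each side
  nc <- max(col0) - cmin + 5L
  ind <- matrix(0, nr, nc)
  ind[cbind(row0 - rmin + 3L, col0 - cmin + 3L)] <- 1
  sm <- matrix(0, nr, nc)
  padded <- matrix(0, nr + 2L, nc + 2L)
  padded[2:(nr + 1L), 2:(nc + 1L)] <- ind
  for (di in 0:2) {
    for (dj in 0:2) {
      sm <- sm + padded[(1L + di):(nr + di), (1L + dj):(nc + dj)] / 9
    }
  }
  ind <- sm
  # contourLines expects z[i, j] at (x[i], y[j]); transpose so x runs over
  # image columns. Units: pixels.
  cl <- grDevices::contourLines(x = seq_len(nc), y = seq_len(nr),
                                z = t(ind), levels = 0.5)
  sum(vapply(cl, function(seg) {
    sum(sqrt(diff(seg$x)^2 + diff(seg$y)^2))
  }, 0))
}

#' Filter nuclei by area and circularity
#'
#' Removes under-/over-segmented objects, debris and boundary artefacts by
#' size and circularity thresholds. The thresholds are not universal; the
#' defaults suit mouse embryonic stem cell nuclei at ~7-10 um diameter and
#' every report should state the values used. Counts removed per criterion
#' are attached as the `"removed"` attribute and messaged.
#'
#' @param table a nucleus table.
#' @param area_min,area_max area bounds in um^2 (`area_min < area_max`).
#' @param circ_min minimum circularity in `[0, 1]`.
#' @return the filtered table, with attribute `removed` = list of counts
#'   per criterion.
#' @export
filter_nuclei <- function(table, area_min = 40, area_max = 400,
                          circ_min = 0.5) {
  stopifnot(is.finite(area_min), is.finite(area_max), area_min < area_max,
            circ_min >= 0, circ_min <= 1)
  too_small <- table$area_um2 < area_min
  too_big <- table$area_um2 > area_max
  not_round <- table$circularity < circ_min
  keep <- !(too_small | too_big | not_round)
  out <- table[keep, , drop = FALSE]
  rownames(out) <- NULL
  removed <- list(area_low = sum(too_small), area_high = sum(too_big),
                  circularity = sum(not_round))
  attr(out, "removed") <- removed
  attr(out, "filter_params") <- list(area_min = area_min, area_max = area_max,
                                     circ_min = circ_min)
  if (nrow(out) == 0) message("filter_nuclei: no nuclei survived the filters")
  out
}

#' Build compartment masks from ring and outer contours
#'
#' The ring contour traces the basement-membrane (Laminin) ring separating
#' the Epi core from the VE layer; the outer contour traces the aggregate
#' boundary. Both must be simple (non-self-intersecting) closed polygons in
#' um, with the ring strictly inside the outer contour.
#'
#' @param ring_contour,outer_contour two-column matrices (x, y) of polygon
#'   vertices; closure is implicit.
#' @return a `compartment_masks` object.
#' @export
compartment_masks <- function(ring_contour, outer_contour) {
  ring_contour <- as_position_matrix(ring_contour)
  outer_contour <- as_position_matrix(outer_contour)
  stopifnot(nrow(ring_contour) >= 3, nrow(outer_contour) >= 3)
  if (!polygon_is_simple(ring_contour)) {
    stop("ring_contour is self-intersecting")
  }
  if (!polygon_is_simple(outer_contour)) {
    stop("outer_contour is self-intersecting")
  }
  if (!all(points_in_polygon(ring_contour, outer_contour))) {
    stop("ring_contour must lie strictly inside outer_contour")
  }
  structure(list(ring_contour = ring_contour, outer_contour = outer_contour),
            class = "compartment_masks")
}

#' Regular polygon approximating a circle, for circular compartment masks
#' @param radius circle radius (um).
#' @param center circle center (um).
#' @param n number of vertices.
#' @export
circle_polygon <- function(radius, center = c(0, 0), n = 180) {
  phi <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  cbind(center[1] + radius * cos(phi), center[2] + radius * sin(phi))
}

# Point-in-polygon via mgcv's boundary test; polygon closed explicitly.
points_in_polygon <- function(points, polygon) {
  points <- as_position_matrix(points)
  polygon <- as_position_matrix(polygon)
  bnd <- rbind(polygon, polygon[1, ])
  mgcv::in.out(bnd, points)
}

# O(n^2) check that no two non-adjacent edges intersect.
polygon_is_simple <- function(polygon) {
  n <- nrow(polygon)
  p <- rbind(polygon, polygon[1, ])
  seg_intersect <- function(a1, a2, b1, b2) {
    d <- function(u, v, w) (v[1] - u[1]) * (w[2] - u[2]) -
      (v[2] - u[2]) * (w[1] - u[1])
    d1 <- d(b1, b2, a1); d2 <- d(b1, b2, a2)
    d3 <- d(a1, a2, b1); d4 <- d(a1, a2, b2)
    (d1 * d2 < 0) && (d3 * d4 < 0)
  }
  for (i in seq_len(n - 2)) {
    for (j in seq(i + 2, n)) {
      if (i == 1 && j == n) next   # closing edge is adjacent to the first
      if (seg_intersect(p[i, ], p[i + 1, ], p[j, ], p[j + 1, ])) return(FALSE)
    }
  }
  TRUE
}

#' Assign nuclei to compartments by centroid containment
#'
#' A centroid inside the ring contour is Epi; between ring and outer contour,
#' VE; outside the outer contour, excluded. Nuclei straddling the ring are
#' assigned by centroid only (boundary artefacts are expected to be removed
#' by [filter_nuclei()] beforehand).
#'
#' @param table a nucleus table.
#' @param masks a [compartment_masks()] object.
#' @return the table with its `compartment` column set to
#'   `"Epi"`, `"VE"` or `"excluded"`.
#' @export
assign_compartments <- function(table, masks) {
  stopifnot(inherits(masks, "compartment_masks"))
  if (nrow(table) == 0) return(table)
  pts <- cbind(table$x_um, table$y_um)
  in_ring <- points_in_polygon(pts, masks$ring_contour)
  in_outer <- points_in_polygon(pts, masks$outer_contour)
  table$compartment <- ifelse(in_ring, "Epi",
                              ifelse(in_outer, "VE", "excluded"))
  table
}

#' Rescale per-nucleus median intensities to the per-slice channel maximum
#'
#' For each channel, divides every nucleus's median intensity by the maximum
#' per-nucleus median within the same scope, so the brightest nucleus maps to
#' exactly 1.0. The default scope is per slice (each slice is an independent
#' acquisition); `scope = "aggregate"` pools slices of one aggregate.
#' A channel whose maximum is zero yields all-zero rescaled values with a
#' warning.
#'
#' @param table a nucleus table with `intensity_<channel>` columns.
#' @param channels channel names to rescale (default: all present).
#' @param scope `"slice"` or `"aggregate"`.
#' @return the table with one `rescaled_<channel>` column per channel,
#'   values in `[0, 1]`.
#' @export
rescale_intensities <- function(table, channels = NULL,
                                scope = c("slice", "aggregate")) {
  scope <- match.arg(scope)
  stopifnot(nrow(table) > 0)
  channels <- channels %||% table_channels(table)
  key <- if (scope == "slice") {
    paste(table$aggregate_id, table$slice_id, sep = "\r")
  } else {
    as.character(table$aggregate_id)
  }
  for (ch in channels) {
    med <- table[[intensity_col(ch)]]
    if (is.null(med)) stop("unknown channel: ", ch)
    mx <- stats::ave(med, key, FUN = max)
    resc <- ifelse(mx > 0, med / mx, 0)
    if (any(tapply(med, key, max) <= 0)) {
      warning("channel '", ch, "': zero maximum in at least one slice; ",
              "rescaled intensities set to 0 there")
    }
    table[[rescaled_col(ch)]] <- resc
  }
  table
}

#' Read / write the delimited-text nucleus table
#'
#' Tab-separated text with one row per nucleus and the columns
#' `aggregate_id, slice_id, nucleus_id, x_um, y_um, area_um2, circularity,
#' compartment, clonal_label`, plus one `intensity_<channel>` column per
#' channel (and `rescaled_<channel>` after rescaling).
#'
#' @param path file path.
#' @return `read_nucleus_table` returns the table; `write_nucleus_table`
#'   returns `path` invisibly.
#' @export
read_nucleus_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  required <- c("aggregate_id", "slice_id", "nucleus_id", "x_um", "y_um")
  missing <- setdiff(required, names(tab))
  if (length(missing)) {
    stop("nucleus table lacks columns: ", paste(missing, collapse = ", "))
  }
  tab
}

#' @rdname read_nucleus_table
#' @param table a nucleus table.
#' @export
write_nucleus_table <- function(table, path) {
  write_stage_table(table, path)
}

#' Read a single-plane TIFF as a numeric or label matrix
#'
#' 16-bit label masks written by [write_rendered_slice()] are recovered as
#' integer matrices; intensity channels come back as numeric matrices on
#' whatever scale they were written.
#'
#' @param path TIFF file path.
#' @param as_labels if `TRUE`, undo the 16-bit `[0, 1]` scaling and round to
#'   integer labels.
#' @export
read_image <- function(path, as_labels = FALSE) {
  img <- tiff::readTIFF(path)
  if (length(dim(img)) == 3) img <- img[, , 1]
  if (as_labels) img <- matrix(as.integer(round(img * 65535)),
                               nrow(img), ncol(img))
  img
}
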