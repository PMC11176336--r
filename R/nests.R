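# Marker-positive nests and their clonal composition.

#' Flag marker-positive nuclei by a rescaled-intensity threshold
#'
#' Positivity is `rescaled intensity >= threshold` (boundary inclusive). The
#' threshold operationalizes what is otherwise a by-eye call; it is recorded
#' as an attribute and should be varied (see [clonality_sweep()]) when
#' reporting.
#'
#' @param table a rescaled nucleus table.
#' @param channel channel name.
#' @param threshold positivity threshold on the rescaled intensity.
#' @return the table with a logical `positive_<channel>` column; the
#'   threshold is attached as attribute `positive_threshold`.
#' @export
flag_positive <- function(table, channel, threshold = 0.3) {
  col <- rescaled_col(channel)
  if (is.null(table[[col]])) {
    stop("unknown or unrescaled channel: ", channel)
  }
  table[[paste0("positive_", channel)]] <- table[[col]] >= threshold
  attr(table, "positive_threshold") <- threshold
  table
}

#' Detect nests as fixed-radius connected components
#'
#' Builds the graph joining marker-positive nuclei whose centers lie within
#' `link_distance` of each other and keeps connected components of at least
#' `min_size` members. Nest ids are deterministic: components are numbered by
#' their smallest member `nucleus_id`.
#'
#' @param table a nucleus table restricted to (or flagged for) the positive
#'   nuclei; if a `positive_<channel>` column is present pass `channel` to
#'   use it, otherwise all rows are treated as positive.
#' @param link_distance linking radius in um (> 0); roughly two cell
#'   diameters.
#' @param min_size minimum nest size (>= 1).
#' @param channel optional channel whose `positive_<channel>` flags select
#'   the nuclei.
#' @return data frame with one row per nest member: nest_id, nucleus_id,
#'   nest_size. Zero rows when no nest qualifies. Parameters are attached as
#'   attribute `nest_params`.
#' @export
detect_nests <- function(table, link_distance = 25, min_size = 3,
                         channel = NULL) {
  stopifnot(link_distance > 0, min_size >= 1)
  if (!is.null(channel)) {
    flag_col <- paste0("positive_", channel)
    if (is.null(table[[flag_col]])) {
      stop("no ", flag_col, " column; run flag_positive() first")
    }
    table <- table[table[[flag_col]], , drop = FALSE]
  }
  empty <- data.frame(nest_id = integer(0), nucleus_id = integer(0),
                      nest_size = integer(0))
  attr(empty, "nest_params") <- list(link_distance = link_distance,
                                     min_size = min_size)
  if (nrow(table) == 0) return(empty)
  pos <- cbind(table$x_um, table$y_um)
  adj <- as.matrix(stats::dist(pos)) <= link_distance
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                           diag = FALSE)
  comp <- igraph::components(g)$membership
  out <- data.frame(component = comp, nucleus_id = table$nucleus_id)
  sizes <- table(out$component)
  out <- out[sizes[as.character(out$component)] >= min_size, , drop = FALSE]
  if (nrow(out) == 0) return(empty)
  # renumber by ascending minimum member id
  min_id <- tapply(out$nucleus_id, out$component, min)
  rank_of <- stats::setNames(rank(min_id, ties.method = "first"),
                             names(min_id))
  out$nest_id <- as.integer(rank_of[as.character(out$component)])
  out$nest_size <- as.integer(table(out$nest_id)[as.character(out$nest_id)])
  out <- out[order(out$nest_id, out$nucleus_id),
             c("nest_id", "nucleus_id", "nest_size")]
  rownames(out) <- NULL
  attr(out, "nest_params") <- list(link_distance = link_distance,
                                   min_size = min_size)
  out
}

#' Score the clonal composition of nests
#'
#' A nest is monoclonal when all its members carry the same clonal label and
#' mixed otherwise. Nests containing any unlabeled member are excluded from
#' the fraction and counted separately as unscored, so missing labels cannot
#' bias the monoclonal fraction.
#'
#' @param nests data frame from [detect_nests()] (`nest_id`, `nucleus_id`).
#' @param table the nucleus table carrying `clonal_label` (or a named
#'   character vector nucleus_id -> label).
#' @return list with `summary` (one-row data frame: n_nests, monoclonal,
#'   mixed, unscored, monoclonal_fraction) and `per_nest` (nest_id, size,
#'   n_labels, labels, status).
#' @export
clonality_score <- function(nests, table) {
  labels <- if (is.data.frame(table)) {
    stats::setNames(as.character(table$clonal_label),
                    as.character(table$nucleus_id))
  } else {
    stats::setNames(as.character(table), names(table))
  }
  per <- list()
  for (nid in unique(nests$nest_id)) {
    members <- nests$nucleus_id[nests$nest_id == nid]
    labs <- labels[as.character(members)]
    status <- if (anyNA(labs)) {
      "unscored"
    } else if (length(unique(labs)) == 1) {
      "monoclonal"
    } else {
      "mixed"
    }
    per[[length(per) + 1]] <-
      data.frame(nest_id = nid, size = length(members),
                 n_labels = length(unique(labs[!is.na(labs)])),
                 labels = paste(sort(unique(labs[!is.na(labs)])),
                                collapse = "+"),
                 status = status, stringsAsFactors = FALSE)
  }
  per <- if (length(per)) do.call(rbind, per) else {
    data.frame(nest_id = integer(0), size = integer(0),
               n_labels = integer(0), labels = character(0),
               status = character(0))
  }
  mono <- sum(per$status == "monoclonal")
  mixed <- sum(per$status == "mixed")
  unsc <- sum(per$status == "unscored")
  list(summary = data.frame(
         n_nests = nrow(per), monoclonal = mono, mixed = mixed,
         unscored = unsc,
         monoclonal_fraction = if (mono + mixed > 0) {
           mono / (mono + mixed)
         } else {
           NA_real_
         }),
       per_nest = per)
}

#' Sensitivity of the monoclonal fraction to the positivity threshold
#'
#' Re-runs [flag_positive()], [detect_nests()] and [clonality_score()] over a
#' grid of positivity thresholds; because no threshold is canonical, the
#' sweep belongs in every clonality report.
#'
#' @inheritParams flag_positive
#' @inheritParams detect_nests
#' @param thresholds numeric vector of thresholds to sweep.
#' @return data frame with one row per threshold: threshold, n_positive,
#'   n_nests, monoclonal, mixed, unscored, monoclonal_fraction.
#' @export
clonality_sweep <- function(table, channel,
                            thresholds = seq(0.1, 0.9, by = 0.1),
                            link_distance = 25, min_size = 3) {
  rows <- lapply(thresholds, function(thr) {
    tb <- flag_positive(table, channel, thr)
    nests <- detect_nests(tb, link_distance, min_size, channel = channel)
    sc <- clonality_score(nests, tb)
    cbind(data.frame(threshold = thr,
                     n_positive = sum(tb[[paste0("positive_", channel)]])),
          sc$summary)
  })
  do.call(rbind, rows)
}
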