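# Internal helpers shared across modules.

#' Evaluate an expression under a fixed RNG seed, restoring the caller's RNG
#' state afterwards.
#' @noRd
local_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old_seed <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old_seed, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  code
}

#' Derive a reproducible sub-seed from a master seed and a key path
#'
#' Hashes the master seed together with an arbitrary sequence of string/number
#' keys (e.g. aggregate id, slice id, channel name) into an integer seed in
#' `[1, 2^31)`. The same master seed and keys always yield the same sub-seed,
#' so every randomized stage of a run can be replayed in isolation.
#'
#' @param master integer master seed.
#' @param ... additional keys (coerced to character) identifying the stream.
#' @return a single integer seed.
#' @export
#' @examples
#' derive_seed(1, "agg01", "z1", "cer1")
derive_seed <- function(master, ...) {
  key <- paste(c(as.character(master), vapply(list(...), as.character, "")),
               collapse = "/")
  h <- 0
  for (b in utf8ToInt(key)) h <- (h * 31 + b) %% 2147483629
  as.integer(h + 1)
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

#' @noRd
as_position_matrix <- function(positions) {
  if (is.data.frame(positions)) {
    stopifnot(all(c("x_um", "y_um") %in% names(positions)))
    positions <- cbind(positions$x_um, positions$y_um)
  }
  positions <- as.matrix(positions)
  stopifnot(ncol(positions) == 2L, is.numeric(positions),
            all(is.finite(positions)))
  unname(positions)
}

#' @noRd
intensity_col <- function(channel) paste0("intensity_", channel)

#' @noRd
rescaled_col <- function(channel) paste0("rescaled_", channel)

#' Channel names present in a nucleus table
#' @noRd
table_channels <- function(table) {
  sub("^intensity_", "", grep("^intensity_", names(table), value = TRUE))
}

#' Write a stage table as tab-separated text
#' @noRd
write_stage_table <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
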