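## Internal helpers shared across modules.

#' Clip a numeric vector to an interval
#' @noRd
clip <- function(x, lo = 0, hi = 1) pmin(pmax(x, lo), hi)

#' Population-weighted mean
#' @noRd
wmean <- function(x, w) sum(x * w) / sum(w)

#' Deterministic sub-seed for a pipeline stage
#'
#' A single master seed spawns per-stage seeds so stages can be rerun in
#' isolation without sharing a stream. Kept below 2^31 - 1.
#' @noRd
substream <- function(master_seed, stage) {
  stage_id <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(master_seed) * 7919 + stage_id) %% 2147483629)
}

#' Run code under a local RNG seed, restoring the global state afterwards
#' @noRd
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Assert that required columns are present
#' @noRd
check_columns <- function(data, cols, what = "data") {
  missing <- setdiff(cols, names(data))
  if (length(missing) > 0) {
    abort(sprintf(
      "%s is missing required column%s: %s",
      what, if (length(missing) > 1) "s" else "", paste(missing, collapse = ", ")
    ))
  }
  invisible(data)
}

#' Weighted fractional rank (ordered by a ranking variable, ascending)
#'
#' Ranks run from the most disadvantaged group (largest `rank_var` when
#' `poorest_first = TRUE`) at rank near 0 to the least at rank near 1.
#' Midpoint convention: rank_i = (cumulative weight before i + w_i / 2) / W.
#' Ties broken by stable id order.
#' @noRd
fractional_rank <- function(rank_var, weights, poorest_first = TRUE) {
  ord <- order(if (poorest_first) -rank_var else rank_var)
  w <- weights[ord] / sum(weights)
  r <- cumsum(w) - w / 2
  out <- numeric(length(rank_var))
  out[ord] <- r
  out
}
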