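# Internal helpers: named random substreams and attrition bookkeeping.

# Derive a deterministic 32-bit seed for a named substream of a master seed.
# Per-operation substreams keep outputs stable when unrelated operations are
# added to a pipeline run.
substream_seed <- function(seed, name) {
  stopifnot(is.numeric(seed), length(seed) == 1L, !is.na(seed))
  chars <- utf8ToInt(name)
  h <- 0
  for (ch in chars) h <- (h * 131 + ch) %% 2147483647
  as.integer((abs(as.numeric(seed)) %% 65521) * 32749 + h) %% 2147483647L
}

# Evaluate `code` under a seed derived from (seed, name), restoring the
# caller's RNG state afterwards.
with_substream <- function(seed, name, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(substream_seed(seed, name))
  code
}

new_attrition <- function(step, input, kept) {
  data.frame(step = step, input = as.integer(input),
             removed = as.integer(input - kept), kept = as.integer(kept),
             stringsAsFactors = FALSE)
}

append_attrition <- function(out, input_obj, step, n_in, n_kept) {
  prev <- attr(input_obj, "attrition")
  attr(out, "attrition") <- rbind(prev, new_attrition(step, n_in, n_kept))
  out
}

#' Attrition ledger of a filtered object
#'
#' Every site filter in panelforge records, for each step applied so far, the
#' input, removed and kept counts. The ledger always satisfies
#' `input == removed + kept` row-wise, so pipeline accounting can be audited.
#'
#' @param x a filtered `CallSet` or candidate table.
#' @return a data.frame with columns `step`, `input`, `removed`, `kept`
#'   (NULL if `x` has never been filtered).
#' @export
attrition <- function(x) attr(x, "attrition")

`%||%` <- function(a, b) if (is.null(a)) b else a
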