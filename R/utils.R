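#' Evaluate an expression under a temporary RNG seed
#'
#' Runs `code` with the global random number generator seeded at `seed`, then
#' restores the previous RNG state, so seeded operations are pure functions of
#' their inputs and do not disturb the caller's random stream.
#'
#' @param seed Integer seed (kept below 2^31 by callers).
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @export
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# data.table is used via :: only; mark the namespace as aware so grouped
# `[` calls keep data.table semantics.
.datatable.aware <- TRUE

# Two-sided normal p-value from a z-score, computed on the log scale so very
# large |z| do not underflow prematurely.
two_sided_p <- function(z) {
  p <- 2 * pnorm(abs(z), lower.tail = FALSE)
  p[!is.na(p) & p > 1] <- 1
  p
}

# log10 of the two-sided normal p-value; stable for large |z|.
log10_two_sided_p <- function(z) {
  (pnorm(abs(z), lower.tail = FALSE, log.p = TRUE) + log(2)) / log(10)
}

is_missing_num <- function(x) is.na(x)

stop_input <- function(...) stop(..., call. = FALSE)
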