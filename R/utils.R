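## Internal helpers shared across modules.

# Deterministic fan-out of one user seed into named substreams, so that e.g.
# the meiosis and read-depth draws of a simulation can be reproduced
# independently. Kept below 2^31 - 1 to stay a valid R integer seed.
substream_seed <- function(seed, name) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(name))
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name)) * 131L)
  as.integer((abs(seed) * 48271 + h) %% 2147483629)
}

# Run `expr` under a named substream of `seed`, restoring the caller's RNG
# state afterwards.
with_substream <- function(seed, name, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
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
  set.seed(substream_seed(seed, name))
  force(expr)
}

#' Format a percentage the way study reports print them
#'
#' Rounds `100 * fraction` to a fixed number of decimal places, returning a
#' number (not a string) on the percent scale, e.g. `format_pct(103/419, 1)`
#' is `24.6` and `format_pct(29/32)` is `91`.
#'
#' @param fraction Numeric vector of fractions in `[0, 1]`.
#' @param digits Decimal places on the percent scale (default 0).
#' @return Numeric vector of percentages.
#' @export
#' @examples
#' format_pct(103 / 419, 1)
#' format_pct(29 / 32)
format_pct <- function(fraction, digits = 0) {
  round(100 * fraction, digits)
}

# Number formatter used when writing text outputs, so that write -> read ->
# write round trips are byte-identical.
format_num <- function(x) {
  ifelse(is.na(x), ".", format(x, trim = TRUE, scientific = FALSE))
}

`%,%` <- function(a, b) paste0(a, b)
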