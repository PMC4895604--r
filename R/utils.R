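# Internal helpers shared across modules.

#' Evaluate code with a temporary RNG state
#'
#' Runs `code` under `set.seed(seed)` and restores the caller's RNG state
#' afterwards, so library functions stay pure with respect to the global
#' random stream.
#' @noRd
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("seed must be a single finite number")
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed) %% .Machine$integer.max)
  force(code)
}

# deterministic sub-seed derivation; stays below 2^31
derive_seed <- function(seed, offset) {
  (as.integer(seed) %% 1000000L) * 1000L + as.integer(offset) %% 1000L
}

#' Round half away from zero
#'
#' The rounding convention of every reported percentage and fold.
#' @param x Numeric vector.
#' @param digits Decimal places (default 2).
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 2L) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

DNA_BASES <- c("A", "C", "G", "T")

complement_base <- function(b) {
  c(A = "T", C = "G", G = "C", T = "A", N = "N")[b]
}

# format a numeric column at full (round-trip exact) precision
format_full <- function(x) {
  ifelse(is.na(x), "NA", sprintf("%.17g", x))
}

stop_rddkit <- function(...) stop(..., call. = FALSE)
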