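# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a child RNG seed from a macro seed and a stream index
#'
#' Counter-based splitting: a small multiplicative mix of the macro seed and
#' one or more integer stream components, reduced modulo 2^31 - 1 so the
#' result is always a valid R seed. Distinct component tuples give distinct
#' streams in practice; the mapping is deterministic.
#'
#' @param macro_seed integer macro seed.
#' @param ... integer stream components (e.g. condition index, replicate).
#' @return a single integer seed in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(macro_seed, ...) {
  parts <- c(macro_seed, ...)
  s <- 1234567
  for (x in parts) {
    # 69069 * (2^31) < 2^53, so the double-precision products stay exact
    s <- (s * 69069 + (as.numeric(x) %% 2147483647)) %% 2147483647
    s <- (s * 18329 + 1) %% 2147483647
  }
  as.integer(s %% 2147483645 + 1)
}

#' Round half away from zero
#'
#' Display rounding used for tabulated percentages; internal computation is
#' never rounded.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# run `expr` under a temporary RNG seed, restoring the caller's RNG state;
# seed = NULL runs in the current stream
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

stop_config <- function(...) {
  stop(structure(class = c("schoolnet_config_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

check_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < 0 || x > 1)
    stop_config(name, " must be a probability in [0, 1], got ", format(x))
  invisible(x)
}
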