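#' @keywords internal
"_PACKAGE"

# shared internal helpers: argument checks, smoothing, seed derivation

stop_if_not <- function(cond, msg) {
  if (!isTRUE(cond)) stop(msg, call. = FALSE)
}

#' Derive a child random seed from a master seed
#'
#' One master seed drives a whole simulated study; per-subject streams are
#' derived by a fixed integer offset so that subjects are independent but the
#' dataset is reproducible from the single seed.
#'
#' @param seed master seed (integer).
#' @param index child index (1-based).
#' @return an integer seed below 2^31.
#' @export
child_seed <- function(seed, index) {
  as.integer((as.numeric(seed) + 104729 * as.numeric(index)) %% 2147483647)
}

# centred moving average with edge padding; width in samples (>=1)
moving_average <- function(x, width) {
  if (width <= 1L) return(x)
  k <- rep(1 / width, width)
  pad <- width %/% 2
  xp <- c(rep(x[1L], pad), x, rep(x[length(x)], width - pad - 1L))
  out <- stats::filter(xp, k, sides = 1)
  as.numeric(out[(width):(length(xp))])
}

# population variance (divides by n, not n - 1)
pop_var <- function(x) mean((x - mean(x))^2)
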