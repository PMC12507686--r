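#' @keywords internal
"_PACKAGE"

# Internal validation helpers -------------------------------------------------

stop_validation <- function(...) {
  stop(structure(
    class = c("sensint_validation_error", "error", "condition"),
    list(message = paste0(...), call = sys.call(-1))
  ))
}

stop_structural <- function(...) {
  stop(structure(
    class = c("sensint_structural_error", "error", "condition"),
    list(message = paste0(...), call = sys.call(-1))
  ))
}

check_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_validation(name, " must be a single finite number")
  if (x < lower || x > upper)
    stop_validation(name, " must be in [", lower, ", ", upper, "], got ", x)
  invisible(x)
}

#' Derive a reproducible per-unit random seed from a session seed
#'
#' A counter-based fan-out: each `(seed, counter)` pair maps to an independent
#' 31-bit seed through a splitmix-style integer hash, so adding units to a
#' session never perturbs the random stream of existing units.
#'
#' @param seed Integer session seed.
#' @param counter Non-negative integer counter (e.g. unit index).
#' @return An integer in `[1, 2^31 - 2]` suitable for [set.seed()].
#' @export
substream_seed <- function(seed, counter) {
  check_scalar_number(seed, "seed")
  check_scalar_number(counter, "counter", lower = 0)
  # 64-bit-free mixing in double precision: all intermediates < 2^52
  x <- (abs(seed) %% 2147483647) + 1
  y <- (counter %% 2147483647) + 1
  h <- (x * 2654435.0 + y * 40503.0 + (x * y) %% 1048573) %% 2147483646
  h <- (h * 48271) %% 2147483647
  as.integer(h %% 2147483645 + 1)
}

# Gaussian smoothing with reflective edges ------------------------------------

#' Smooth a rate trace with a Gaussian kernel
#'
#' Reflective (mirror) edge padding preserves total mass and keeps the output
#' mean equal to the input mean up to numerical tolerance. `kernel_sd = 0`
#' returns the input unchanged.
#'
#' @param trace Numeric vector, a rate time series on a uniform grid.
#' @param kernel_sd Kernel standard deviation in seconds.
#' @param dt Sample spacing of `trace` in seconds.
#' @return Numeric vector of the same length.
#' @export
smooth_rate <- function(trace, kernel_sd, dt) {
  if (!is.numeric(trace)) stop_validation("trace must be numeric")
  check_scalar_number(kernel_sd, "kernel_sd", lower = 0)
  check_scalar_number(dt, "dt", lower = 1e-12)
  if (kernel_sd == 0 || length(trace) < 2L) return(trace)
  half <- max(1L, ceiling(4 * kernel_sd / dt))
  k <- stats::dnorm(seq(-half, half) * dt, sd = kernel_sd)
  k <- k / sum(k)
  n <- length(trace)
  # mirror pad; replicate edges if the trace is shorter than the kernel arm
  pre <- trace[pmin(n, pmax(1L, seq(half + 1, 2)))]
  post <- trace[pmin(n, pmax(1L, seq(n - 1, n - half)))]
  padded <- c(pre, trace, post)
  out <- stats::filter(padded, k, sides = 2)
  as.numeric(out[(half + 1):(half + n)])
}
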