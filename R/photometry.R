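# Isosbestic-referenced photometry normalization and event-aligned
# quantification.
#
# The calcium-dependent channel (470-nm excitation) and the
# calcium-independent isosbestic channel (405 nm) share motion and bleaching
# artefacts. A whole-session linear fit of the isosbestic channel onto the
# signal channel predicts the artefactual component, and
#   F_n(t) = 100 * (F470(t) - F405fit(t)) / F405fit(t)
# expresses the residual signal in percent of the fitted reference.

#' Fit the isosbestic channel to the signal channel
#'
#' Ordinary least squares of `f470 ~ f405` over the whole session:
#' `F405fit = a * F405 + b`. A constant isosbestic channel degenerates to an
#' intercept-only fit with a warning.
#'
#' @param session A `photometry_session` (fields `time`, `f470`, `f405`).
#' @return List of class `isosbestic_fit`: `a`, `b`, `fitted` (F405fit).
#' @export
fit_isosbestic <- function(session) {
  f470 <- session$f470; f405 <- session$f405
  if (length(f470) != length(f405))
    stop_structural("channel lengths differ")
  if (length(f470) < 2L) stop_validation("session too short to fit")
  if (stats::sd(f405) < 1e-12) {
    warning("isosbestic channel is constant; intercept-only fit",
            call. = FALSE)
    a <- 0; b <- mean(f470)
  } else {
    fit <- stats::lm.fit(cbind(1, f405), f470)
    b <- fit$coefficients[1]; a <- fit$coefficients[2]
  }
  structure(list(a = unname(a), b = unname(b),
                 fitted = unname(a * f405 + b)),
            class = "isosbestic_fit")
}

#' Normalize the signal channel against the fitted isosbestic reference
#'
#' @param session A `photometry_session`.
#' @param fit An `isosbestic_fit` (computed from `session` if `NULL`).
#' @param fit_floor Samples where `F405fit` falls at or below this value are
#'   masked (`NA`) rather than divided by a vanishing reference.
#' @return List of class `normalized_trace`: `time`, `f_n` (percent),
#'   `f405fit`, `n_masked`.
#' @export
normalize_photometry <- function(session, fit = NULL, fit_floor = 1e-6) {
  if (is.null(fit)) fit <- fit_isosbestic(session)
  f405fit <- fit$fitted
  f_n <- 100 * (session$f470 - f405fit) / f405fit
  bad <- f405fit <= fit_floor
  f_n[bad] <- NA_real_
  structure(list(time = session$time, f_n = f_n, f405fit = f405fit,
                 n_masked = sum(bad)),
            class = "normalized_trace")
}

#' z-score a trace over the session
#'
#' @param x Numeric trace (or a `normalized_trace`, whose `f_n` is used).
#' @return Numeric trace with mean 0 and standard deviation 1.
#' @export
zscore_trace <- function(x) {
  if (inherits(x, "normalized_trace")) x <- x$f_n
  v <- x[is.finite(x)]
  if (length(v) < 2L) stop_validation("trace needs >= 2 finite samples")
  s <- stats::sd(v)
  if (s < 1e-12) stop_validation("trace has zero variance")
  (x - mean(v)) / s
}

#' Event-aligned photometry responses
#'
#' Segments the trace around each event onset; the per-event scalar response
#' is the mean over the post window minus the mean over the pre window.
#' Events without full window coverage are dropped with a warning.
#'
#' @param time Time grid (s), strictly increasing and uniform.
#' @param trace Numeric trace on `time` (e.g. `f_n` or its z-score).
#' @param event_times Event onsets (s).
#' @param window `c(pre_s, post_s)` (defaults 2 and 5).
#' @return List: `time_rel`, `aligned` (events x samples), `mean`, `sem`,
#'   `responses` (per-event scalars), `event_times` (those used).
#' @export
event_aligned_response <- function(time, trace, event_times,
                                   window = c(2, 5)) {
  if (length(time) != length(trace)) stop_structural("time/trace mismatch")
  if (length(event_times) < 1L) stop_validation("at least one event required")
  dt <- stats::median(diff(time))
  n_pre <- as.integer(round(window[1] / dt))
  n_post <- as.integer(round(window[2] / dt))
  rel <- seq(-n_pre, n_post - 1L) * dt
  rows <- list(); used <- numeric(0)
  for (ev in event_times) {
    i0 <- which.min(abs(time - ev))
    idx <- seq(i0 - n_pre, i0 + n_post - 1L)
    if (idx[1] < 1L || idx[length(idx)] > length(trace)) next
    rows[[length(rows) + 1L]] <- trace[idx]
    used <- c(used, ev)
  }
  if (length(rows) == 0L)
    stop_validation("no event has full window coverage")
  if (length(used) < length(event_times))
    warning(length(event_times) - length(used),
            " event(s) without full window coverage dropped", call. = FALSE)
  aligned <- do.call(rbind, rows)
  pre_idx <- rel < 0
  responses <- rowMeans(aligned[, !pre_idx, drop = FALSE]) -
    rowMeans(aligned[, pre_idx, drop = FALSE])
  list(time_rel = rel, aligned = aligned,
       mean = colMeans(aligned),
       sem = apply(aligned, 2, stats::sd) / sqrt(nrow(aligned)),
       responses = responses, event_times = used)
}

#' Compare per-event responses between two groups of events
#'
#' Group means, their difference, and a seeded bootstrap confidence interval
#' for the difference (resampling events within groups).
#'
#' @param responses Per-event scalar responses.
#' @param groups Factor/character of the same length (exactly two levels
#'   present, e.g. `pre_milestone` / `post_milestone`).
#' @param n_boot Bootstrap resamples (default 1000).
#' @param seed Integer seed.
#' @param conf Confidence level (default 0.95).
#' @return List: `levels`, `means`, `difference` (level1 - level2),
#'   `ci` (bootstrap percentile interval), `n` per group.
#' @export
state_split_comparison <- function(responses, groups, n_boot = 1000,
                                   seed = 1L, conf = 0.95) {
  groups <- as.character(groups)
  if (length(groups) != length(responses))
    stop_structural("responses/groups mismatch")
  lev <- unique(groups)
  if (length(lev) != 2L)
    stop_validation("exactly two groups required, got: ",
                    paste(lev, collapse = ", "))
  x <- responses[groups == lev[1]]
  y <- responses[groups == lev[2]]
  if (length(x) < 1L || length(y) < 1L)
    stop_validation("both groups need at least one event")
  set.seed(substream_seed(seed, 424242))
  boot <- replicate(n_boot,
                    mean(sample(x, replace = TRUE)) -
                      mean(sample(y, replace = TRUE)))
  alpha <- (1 - conf) / 2
  list(levels = lev, means = c(mean(x), mean(y)),
       difference = mean(x) - mean(y),
       ci = unname(stats::quantile(boot, c(alpha, 1 - alpha))),
       n = c(length(x), length(y)))
}
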