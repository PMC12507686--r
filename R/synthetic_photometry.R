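# Synthetic two-channel photometry generator
#
# The signal channel carries a slow double-exponential bleaching drift
# multiplied by (1 + planted contact transients), plus a motion artefact
# shared with the isosbestic channel and independent sensor noise. The
# isosbestic channel is an affine image of the same drift and motion
# artefact, so a whole-session linear fit can cancel both.

#' Build a planted photometry event design
#'
#' Bouts of three types are interleaved on a regular schedule: `object`
#' (inanimate object contact), `cup` (no-contact presentation, amplitude 0)
#' and `free` (free social contact, the high-amplitude condition; default
#' eightfold the object amplitude). Optional factorial splits tag body site
#' (face vs back, back responses planted at zero) and state epoch
#' (pre- vs post-milestone, post scaled by `post_factor`).
#'
#' @param n_per_type Bouts per type.
#' @param bout_s Contact bout duration (s).
#' @param gap_s Gap between bout onsets (s).
#' @param amplitudes Named fractional response amplitudes per bout type.
#' @param site_split Alternate face/back within each type.
#' @param epoch_split Label the first half of bouts `pre_milestone` and the
#'   second half `post_milestone`.
#' @param post_factor Amplitude factor applied post-milestone (default 0.25,
#'   a 4:1 pre:post contrast).
#' @param back_factor Amplitude factor for back contact (default 0).
#' @return data.frame with columns `event_id`, `t_on`, `t_off`, `bout_type`,
#'   `body_site`, `epoch`, `amplitude`.
#' @export
photometry_events <- function(n_per_type = 15, bout_s = 3, gap_s = 30,
                              amplitudes = c(object = 0.02, cup = 0,
                                             free = 0.16),
                              site_split = FALSE, epoch_split = FALSE,
                              post_factor = 0.25, back_factor = 0) {
  check_scalar_number(n_per_type, "n_per_type", lower = 1)
  types <- rep(names(amplitudes), times = n_per_type)
  n <- length(types)
  t_on <- 30 + (seq_len(n) - 1) * gap_s
  site <- if (site_split) rep_len(c("face", "back"), n) else rep("face", n)
  epoch <- if (epoch_split)
    ifelse(seq_len(n) <= n / 2, "pre_milestone", "post_milestone")
  else rep("pre_milestone", n)
  amp <- unname(amplitudes[types]) *
    ifelse(site == "back", back_factor, 1) *
    ifelse(epoch == "post_milestone", post_factor, 1)
  data.frame(event_id = sprintf("ev%03d", seq_len(n)),
             t_on = t_on, t_off = t_on + bout_s,
             bout_type = types, body_site = site, epoch = epoch,
             amplitude = amp, stringsAsFactors = FALSE)
}

# contact-locked transient: alpha-like rise/decay, unit peak
event_kernel <- function(t_rel, rise = 0.3, decay = 2.0) {
  k <- (1 - exp(-pmax(0, t_rel) / rise)) * exp(-pmax(0, t_rel) / decay)
  k[t_rel < 0] <- 0
  peak <- max((1 - exp(-seq(0, 10, by = 0.01) / rise)) *
                exp(-seq(0, 10, by = 0.01) / decay))
  k / peak
}

#' Simulate a two-channel photometry session with planted ground truth
#'
#' @param spec A [session_spec()] (supplies the sampling rate and seed).
#' @param seed Integer seed; defaults to `spec$seed`.
#' @param events Planted event design from [photometry_events()]; default
#'   design if `NULL`.
#' @param duration_s Session length (s); defaults to 30 s past the last bout.
#' @param motion_sd Standard deviation of the shared motion artefact (a.u.);
#'   the artefact dominates the independent sensor noise, as it does in
#'   freely moving recordings.
#' @param noise_sd Independent per-channel sensor noise s.d. (a.u.).
#' @return List of class `photometry_sim` with `session` (class
#'   `photometry_session`: `time`, `f470`, `f405`, `events`, `fs`) and
#'   `truth` (the event design with planted amplitudes).
#' @export
simulate_photometry <- function(spec, seed = spec$seed, events = NULL,
                                duration_s = NULL, motion_sd = 2,
                                noise_sd = 0.2) {
  stopifnot(inherits(spec, "session_spec"))
  fs <- spec$photo_rate
  check_scalar_number(fs, "photo_rate", lower = 1e-6)
  if (is.null(events)) events <- photometry_events()
  if (nrow(events) == 0L) stop_validation("no photometry events planted")
  if (is.null(duration_s)) duration_s <- max(events$t_off) + 30
  n <- as.integer(round(duration_s * fs))
  t <- (seq_len(n) - 1) / fs

  set.seed(substream_seed(seed, 900001))
  bleach <- 100 * (0.55 + 0.35 * exp(-t / 600) + 0.10 * exp(-t / 120))
  motion <- smooth_rate(stats::rnorm(n), 0.3, 1 / fs)
  motion <- motion / stats::sd(motion) * motion_sd

  signal <- numeric(n)
  for (j in seq_len(nrow(events))) {
    if (events$amplitude[j] == 0) next
    signal <- signal + events$amplitude[j] * event_kernel(t - events$t_on[j])
  }

  f470 <- bleach * (1 + signal) + motion + stats::rnorm(n, 0, noise_sd)
  f405 <- 0.7 * (bleach + motion) + 2 + stats::rnorm(n, 0, noise_sd)

  session <- structure(
    list(time = t, f470 = f470, f405 = f405, events = events, fs = fs),
    class = "photometry_session"
  )
  structure(list(session = session, truth = events),
            class = "photometry_sim")
}
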