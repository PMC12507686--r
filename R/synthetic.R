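# Synthetic session generator
#
# Emulates a head-fixed multimodal stimulation experiment: three interleaved
# trial conditions (state stimulation alone, object contact alone, or both),
# 10 trials per condition, 10-s stimulation epochs, 5-s contact epochs. Units
# are planted into known response classes driven by the rectified-linear
# disinhibition circuit, and spikes are emitted as inhomogeneous Poisson
# processes by thinning on a 1-ms grid.

PLANTED_CLASSES <- c("integration", "interneuron", "cue_only", "state_only",
                     "action_only", "unresponsive")

#' Specify a synthetic recording session
#'
#' @param regions Named list; each element is a named integer vector of unit
#'   counts per planted class (names among `integration`, `interneuron`,
#'   `cue_only`, `state_only`, `action_only`, `unresponsive`). The default
#'   plants 40% integration cells in the focal region (`SPFp`) versus 10%
#'   in a control region, and roughly 15% interneurons in the focal region.
#' @param n_trials_per_condition Trials per condition (default 10).
#' @param stim_s Duration of the state-stimulation epoch (s; default 10, a
#'   10-s 20-Hz pulse train).
#' @param contact_s Duration of the object-contact epoch (s; default 5).
#' @param delay_s Delay between the first and second input in multimodal
#'   trials (s; default 2).
#' @param pre_s Pre-onset coverage per trial (s; default 5, so a 4-s baseline
#'   window always fits).
#' @param gap_s Inter-trial gap after the stimulation epoch (s; default 5).
#' @param orders Presentation orders for multimodal trials: `"state_first"`,
#'   `"contact_first"`, or both.
#' @param lateralized If `TRUE`, contact epochs alternate between the
#'   contralateral and ipsilateral face, and contact-driven units are planted
#'   contra-selective (ipsilateral contact gain drawn uniformly in [0, 0.3]).
#' @param bin_width Analysis bin width (s; default 0.1).
#' @param photo_rate Photometry sampling rate (Hz; default 20).
#' @param seed Integer seed.
#' @return An object of class `session_spec`.
#' @export
session_spec <- function(regions = NULL,
                         n_trials_per_condition = 10,
                         stim_s = 10, contact_s = 5, delay_s = 2,
                         pre_s = 5, gap_s = 5,
                         orders = "state_first",
                         lateralized = FALSE,
                         bin_width = 0.1,
                         photo_rate = 20,
                         seed = 1L) {
  if (is.null(regions)) {
    regions <- list(
      SPFp = c(integration = 20, interneuron = 8, cue_only = 6,
               state_only = 6, action_only = 2, unresponsive = 8),
      vPAG = c(integration = 5, interneuron = 2, cue_only = 10,
               state_only = 10, action_only = 3, unresponsive = 20)
    )
  }
  if (!is.list(regions) || is.null(names(regions)) || any(names(regions) == ""))
    stop_validation("regions must be a named list of class-count vectors")
  for (rg in names(regions)) {
    cnt <- regions[[rg]]
    if (is.null(names(cnt)) || !all(names(cnt) %in% PLANTED_CLASSES))
      stop_validation("region ", rg, ": class names must be among ",
                      paste(PLANTED_CLASSES, collapse = ", "))
    if (any(cnt < 0)) stop_validation("region ", rg, ": unit counts must be >= 0")
  }
  check_scalar_number(n_trials_per_condition, "n_trials_per_condition", lower = 1)
  for (nm in c("stim_s", "contact_s", "pre_s", "gap_s", "bin_width",
               "photo_rate"))
    check_scalar_number(get(nm), nm, lower = 1e-9)
  check_scalar_number(delay_s, "delay_s", lower = 0)
  orders <- match.arg(orders, c("state_first", "contact_first"),
                      several.ok = TRUE)
  structure(
    list(regions = regions,
         n_trials_per_condition = as.integer(n_trials_per_condition),
         stim_s = stim_s, contact_s = contact_s, delay_s = delay_s,
         pre_s = pre_s, gap_s = gap_s, orders = orders,
         lateralized = isTRUE(lateralized),
         bin_width = bin_width, photo_rate = photo_rate,
         seed = as.integer(seed)),
    class = "session_spec"
  )
}

# Trial slot length: pre-onset coverage + longest epoch footprint + gap.
slot_length <- function(spec) {
  span <- max(spec$stim_s, spec$contact_s,
              spec$delay_s + max(spec$stim_s, spec$contact_s))
  spec$pre_s + span + spec$gap_s
}

#' Build the trial table for a session specification
#'
#' Conditions are interleaved (seeded permutation of a round-robin layout) and
#' laid out in fixed-length slots. `t_ref_on` is the first input onset of the
#' trial; baselines are taken in the 4 s preceding it.
#'
#' @param spec A [session_spec()].
#' @return A `data.frame` of class `trial_table` with columns `trial_id`,
#'   `condition`, `order`, `side`, `t_start`, `t_ref_on`, `t_stim_on`,
#'   `t_stim_off`, `t_contact_on`, `t_contact_off`, `t_reach_on`.
#' @export
build_trial_table <- function(spec) {
  stopifnot(inherits(spec, "session_spec"))
  n <- spec$n_trials_per_condition
  if (n < 1L) stop_validation("at least one trial per condition required")
  conditions <- c("state_only", "contact_only", "multimodal")
  cond <- rep(conditions, each = n)
  ord <- ifelse(cond == "multimodal",
                rep_len(spec$orders, length(cond)), "n/a")
  has_contact <- cond != "state_only"
  side <- ifelse(has_contact,
                 if (spec$lateralized) rep_len(c("contra", "ipsi"), length(cond))
                 else "contra",
                 "n/a")
  set.seed(substream_seed(spec$seed, 0))
  perm <- sample.int(length(cond))
  cond <- cond[perm]; ord <- ord[perm]; side <- side[perm]

  slot <- slot_length(spec)
  t_start <- (seq_along(cond) - 1) * slot
  t_ref <- t_start + spec$pre_s

  stim_on <- contact_on <- rep(NA_real_, length(cond))
  stim_on[cond == "state_only"] <- t_ref[cond == "state_only"]
  contact_on[cond == "contact_only"] <- t_ref[cond == "contact_only"]
  mm <- cond == "multimodal"
  sf <- mm & ord == "state_first"
  cf <- mm & ord == "contact_first"
  stim_on[sf] <- t_ref[sf]
  contact_on[sf] <- t_ref[sf] + spec$delay_s
  contact_on[cf] <- t_ref[cf]
  stim_on[cf] <- t_ref[cf] + spec$delay_s

  reach_on <- rep(NA_real_, length(cond))
  reach_on[mm] <- contact_on[mm] + 1.0

  out <- data.frame(
    trial_id = sprintf("tr%03d", seq_along(cond)),
    condition = cond, order = ord, side = side,
    t_start = t_start, t_ref_on = t_ref,
    t_stim_on = stim_on, t_stim_off = stim_on + spec$stim_s,
    t_contact_on = contact_on, t_contact_off = contact_on + spec$contact_s,
    t_reach_on = reach_on,
    stringsAsFactors = FALSE
  )
  class(out) <- c("trial_table", "data.frame")
  out
}

# Deterministic rate trace (spikes/s) for one unit over one trial slot.
# Times in the trial row are absolute; the trace covers [t_start, t_start+slot).
unit_trial_trace <- function(class, params, trial, spec, contact_gain,
                             unit_gain, dt = 0.001) {
  slot <- slot_length(spec)
  L <- as.integer(round(slot / dt))
  tt <- trial$t_start + (seq_len(L) - 1) * dt
  s_M <- as.numeric(!is.na(trial$t_stim_on) &
                      tt >= trial$t_stim_on & tt < trial$t_stim_off)
  c_in <- as.numeric(!is.na(trial$t_contact_on) &
                       tt >= trial$t_contact_on & tt < trial$t_contact_off)
  c_in <- c_in * contact_gain
  tr <- switch(
    class,
    integration = rate_traces(params, s_M, c_in, dt)$r_P,
    interneuron = rate_traces(params, s_M, c_in, dt)$r_I,
    cue_only = pmax(0, 5 + 10 * c_in),
    state_only = pmax(0, 3 + 8 * shift_series(s_M, params$tau_P, dt)),
    action_only = {
      b <- rep(2, L)
      if (!is.na(trial$t_reach_on)) {
        on <- tt >= trial$t_reach_on - 0.3 & tt < trial$t_reach_on + 0.5
        b <- b + 8 * as.numeric(on)
      }
      b
    },
    unresponsive = rep(4, L),
    stop_validation("unknown planted class: ", class)
  )
  unit_gain * tr
}

#' Sample spikes from a rate trace by Poisson thinning
#'
#' Candidate events are drawn from a homogeneous Poisson process at the trace
#' maximum and retained with probability `rate(t) / max(rate)`, yielding an
#' inhomogeneous Poisson process with the given piecewise-constant intensity.
#'
#' @param rate Non-negative numeric intensity trace (spikes/s) on a uniform
#'   grid of spacing `dt` starting at `t0`.
#' @param dt Grid spacing (s).
#' @param t0 Absolute time of the first grid point (s).
#' @return Sorted numeric vector of spike times (s).
#' @export
sample_poisson_spikes <- function(rate, dt = 0.001, t0 = 0) {
  if (any(rate < 0)) stop_validation("rate must be non-negative")
  lam_max <- max(rate)
  span <- length(rate) * dt
  if (lam_max <= 0 || span <= 0) return(numeric(0))
  n_cand <- stats::rpois(1, lam_max * span)
  if (n_cand == 0) return(numeric(0))
  u <- stats::runif(n_cand, 0, span)
  idx <- pmin(length(rate), floor(u / dt) + 1)
  keep <- stats::runif(n_cand) < rate[idx] / lam_max
  sort(t0 + u[keep])
}

#' Simulate an extracellular spiking session with planted ground truth
#'
#' Each planted unit receives its own random substream derived from the
#' session seed, so enlarging a session leaves existing units' spike trains
#' untouched. Trial-to-trial variability is an additive rectified rate offset
#' with standard deviation `params$noise_sd`.
#'
#' @param spec A [session_spec()].
#' @param params A [circuit_params()] driving the integration and interneuron
#'   classes.
#' @param seed Integer seed; defaults to `spec$seed`.
#' @param dt Thinning grid (s; default 1 ms).
#' @return A list of class `spike_session` with elements `spikes` (class
#'   `spike_data`: `units` data.frame and named list `times`), `trials`
#'   (a `trial_table`), and `truth` (data.frame of planted class, laterality
#'   and true per-condition window-mean rates).
#' @export
simulate_spike_session <- function(spec, params = circuit_params(),
                                   seed = spec$seed, dt = 0.001) {
  stopifnot(inherits(spec, "session_spec"), inherits(params, "circuit_params"))
  trials <- build_trial_table(spec)
  if (nrow(trials) == 0L) stop_validation("session has zero trials")

  units <- do.call(rbind, lapply(names(spec$regions), function(rg) {
    cnt <- spec$regions[[rg]]
    cnt <- cnt[cnt > 0]
    if (length(cnt) == 0L) return(NULL)
    data.frame(region = rg, class = rep(names(cnt), cnt),
               stringsAsFactors = FALSE)
  }))
  if (is.null(units) || nrow(units) == 0L)
    stop_validation("session has zero units")
  units$unit_id <- sprintf("u%04d", seq_len(nrow(units)))
  units <- units[, c("unit_id", "region", "class")]

  contact_classes <- c("integration", "cue_only")
  resp_win <- 5  # condition response window (s) for planted true means

  times <- vector("list", nrow(units))
  names(times) <- units$unit_id
  truth_rows <- vector("list", nrow(units))

  for (i in seq_len(nrow(units))) {
    cls <- units$class[i]
    set.seed(substream_seed(seed, i))
    unit_gain <- stats::runif(1, 0.85, 1.15)
    lateral <- spec$lateralized && cls %in% contact_classes
    ipsi_gain <- if (lateral) stats::runif(1, 0, 0.3) else 1
    laterality <- if (lateral) "contra" else "none"

    # deterministic trace per distinct trial type, reused across trials
    type_key <- paste(trials$condition, trials$order, trials$side)
    type_trace <- list()
    spk <- vector("list", nrow(trials))
    win_mean <- numeric(nrow(trials))
    for (j in seq_len(nrow(trials))) {
      key <- type_key[j]
      if (is.null(type_trace[[key]])) {
        cg <- if (identical(trials$side[j], "ipsi")) ipsi_gain else 1
        type_trace[[key]] <- unit_trial_trace(cls, params, trials[j, ], spec,
                                              contact_gain = cg,
                                              unit_gain = unit_gain, dt = dt)
      }
      base <- type_trace[[key]]
      # planted true mean over the response window (noise-free expectation)
      on <- if (!is.na(trials$t_contact_on[j])) trials$t_contact_on[j]
            else trials$t_stim_on[j]
      rel0 <- as.integer(round((on - trials$t_start[j]) / dt))
      widx <- seq(rel0 + 1, min(length(base), rel0 + round(resp_win / dt)))
      win_mean[j] <- mean(base[widx])
      lam <- pmax(0, base + stats::rnorm(1, 0, params$noise_sd))
      spk[[j]] <- sample_poisson_spikes(lam, dt, t0 = trials$t_start[j])
    }
    times[[i]] <- sort(unlist(spk, use.names = FALSE))
    tm <- tapply(win_mean, trials$condition, mean)
    truth_rows[[i]] <- data.frame(
      unit_id = units$unit_id[i], region = units$region[i], class = cls,
      laterality = laterality, ipsi_gain = ipsi_gain, unit_gain = unit_gain,
      true_rate_state_only = unname(tm["state_only"]),
      true_rate_contact_only = unname(tm["contact_only"]),
      true_rate_multimodal = unname(tm["multimodal"]),
      stringsAsFactors = FALSE
    )
  }

  spikes <- structure(list(units = units[, c("unit_id", "region")],
                           times = times),
                      class = "spike_data")
  truth <- do.call(rbind, truth_rows)
  structure(list(spikes = spikes, trials = trials, truth = truth,
                 spec = spec, params = params),
            class = "spike_session")
}

#' @export
print.spike_session <- function(x, ...) {
  cat("<spike_session>", nrow(x$spikes$units), "units,",
      nrow(x$trials), "trials,",
      length(unique(x$spikes$units$region)), "regions\n")
  invisible(x)
}
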