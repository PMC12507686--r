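# Responsiveness classification at the 2-sigma criterion, the cross-region
# multimodal-enhancement screen, and putative-interneuron identification.

# Reference onset of a trial's response window: contact onset when the trial
# has one (the epoch in which both inputs overlap under the default layout),
# otherwise stimulation onset.
response_onset <- function(trials) {
  ifelse(is.finite(trials$t_contact_on), trials$t_contact_on, trials$t_stim_on)
}

#' Per-unit mean response rate for one condition
#'
#' Mean firing rate over a fixed window from the condition's response onset
#' (contact onset if present, else stimulation onset), averaged over all
#' trials of the condition.
#'
#' @param spikes A `spike_data` object.
#' @param trials A `trial_table`.
#' @param condition One of the values in `trials$condition`.
#' @param window_s Response window length (s; default 5).
#' @param bin_width Bin width (s; default 0.1).
#' @return data.frame `unit_id`, `condition`, `response` (spikes/s),
#'   `n_trials`.
#' @export
condition_response <- function(spikes, trials, condition, window_s = 5,
                               bin_width = 0.1) {
  check_scalar_number(window_s, "window_s", lower = 1e-9)
  sel <- trials$condition == condition
  if (!any(sel)) stop_validation("no trials of condition '", condition, "'")
  tr <- trials[sel, , drop = FALSE]
  tr$t_resp_on <- response_onset(tr)
  br <- align_trials(spikes, tr, "t_resp_on", window = c(0, window_s),
                     bin_width = bin_width)
  resp <- apply(br$rates, 1, mean)
  data.frame(unit_id = br$unit_ids, condition = condition,
             response = as.numeric(resp), n_trials = length(br$trial_ids),
             stringsAsFactors = FALSE)
}

#' Mean responses for all three conditions, one row per unit
#'
#' @inheritParams condition_response
#' @param conditions Conditions to tabulate.
#' @return data.frame `unit_id`, then one `response_<condition>` column each.
#' @export
condition_response_table <- function(spikes, trials,
                                     conditions = c("state_only",
                                                    "contact_only",
                                                    "multimodal"),
                                     window_s = 5, bin_width = 0.1) {
  out <- data.frame(unit_id = spikes$units$unit_id,
                    region = spikes$units$region, stringsAsFactors = FALSE)
  for (cond in conditions) {
    r <- condition_response(spikes, trials, cond, window_s, bin_width)
    out[[paste0("response_", cond)]] <-
      r$response[match(out$unit_id, r$unit_id)]
  }
  out
}

#' Classify responsiveness at the 2-sigma criterion
#'
#' `z = (response - mu) / sigma`; units are `activated` when `z > threshold`,
#' `inhibited` when `z < -threshold`, otherwise `nonresponsive`.
#'
#' @param responses data.frame with `unit_id` and `response` (spikes/s),
#'   e.g. from [condition_response()].
#' @param baseline A `baseline_stats` data.frame.
#' @param threshold z threshold (default 2).
#' @return `responses` with added `z` and `label` columns.
#' @export
classify_responsive <- function(responses, baseline, threshold = 2) {
  check_scalar_number(threshold, "threshold", lower = 0)
  idx <- match(responses$unit_id, baseline$unit_id)
  if (anyNA(idx)) stop_validation("baseline missing for some units")
  z <- (responses$response - baseline$mu[idx]) / baseline$sigma[idx]
  label <- ifelse(z > threshold, "activated",
                  ifelse(z < -threshold, "inhibited", "nonresponsive"))
  out <- responses
  out$z <- z
  out$label <- label
  out
}

#' Multimodal-enhancement screen
#'
#' For each unit, the enhancement z compares the multimodal response to a
#' unimodal reference (default: the larger of the two unimodal responses,
#' the conservative choice; `reference = "mean"` uses their average), in
#' units of the unit's baseline sigma:
#' `z_enh = (response_multimodal - reference) / sigma`.
#' Units with `z_enh > threshold` are multimodal-enhanced; `z_enh <
#' -threshold`, multimodal-suppressed.
#'
#' @param responses data.frame from [condition_response_table()] with columns
#'   `response_state_only`, `response_contact_only`, `response_multimodal`.
#' @param baseline A `baseline_stats` data.frame.
#' @param reference `"max"` (default) or `"mean"` of the unimodal responses.
#' @param threshold z threshold (default 2).
#' @return `responses` with added `z_enhancement` and `enhancement_label`
#'   (`enhanced` / `suppressed` / `neither`).
#' @export
multimodal_screen <- function(responses, baseline,
                              reference = c("max", "mean"), threshold = 2) {
  reference <- match.arg(reference)
  need <- c("response_state_only", "response_contact_only",
            "response_multimodal")
  if (!all(need %in% names(responses)))
    stop_validation("responses needs columns: ", paste(need, collapse = ", "))
  idx <- match(responses$unit_id, baseline$unit_id)
  if (anyNA(idx)) stop_validation("baseline missing for some units")
  uni <- if (reference == "max")
    pmax(responses$response_state_only, responses$response_contact_only)
  else (responses$response_state_only + responses$response_contact_only) / 2
  z <- (responses$response_multimodal - uni) / baseline$sigma[idx]
  out <- responses
  out$z_enhancement <- z
  out$enhancement_label <- ifelse(z > threshold, "enhanced",
                                  ifelse(z < -threshold, "suppressed",
                                         "neither"))
  out
}

#' Per-region fractions of multimodal-enhanced and -suppressed units
#'
#' @param screen Output of [multimodal_screen()] (needs a `region` column).
#' @return data.frame `region`, `n_units`, `frac_enhanced`, `frac_suppressed`.
#' @export
screen_fractions <- function(screen) {
  if (!"region" %in% names(screen))
    stop_validation("screen table needs a region column")
  regions <- unique(screen$region)
  do.call(rbind, lapply(regions, function(rg) {
    s <- screen[screen$region == rg, ]
    data.frame(region = rg, n_units = nrow(s),
               frac_enhanced = mean(s$enhancement_label == "enhanced"),
               frac_suppressed = mean(s$enhancement_label == "suppressed"),
               stringsAsFactors = FALSE)
  }))
}

#' Flag putative inhibitory interneurons
#'
#' Units inhibited under state stimulation (`z < -threshold`) whose baseline
#' rate exceeds `baseline_min` — the high-tonic-rate signature of inhibitory
#' interneurons (population mean around 20 spikes/s).
#'
#' @param classified Output of [classify_responsive()] for the state-only
#'   condition.
#' @param baseline A `baseline_stats` data.frame.
#' @param baseline_min High-baseline threshold (spikes/s; default 10).
#' @param threshold z threshold (default 2).
#' @return `classified` with an added logical `putative_interneuron` column.
#' @export
identify_interneurons <- function(classified, baseline, baseline_min = 10,
                                  threshold = 2) {
  idx <- match(classified$unit_id, baseline$unit_id)
  if (anyNA(idx)) stop_validation("baseline missing for some units")
  out <- classified
  out$putative_interneuron <- classified$z < -threshold &
    baseline$mu[idx] > baseline_min
  out
}
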