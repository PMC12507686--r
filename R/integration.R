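# Superadditive integration index.
#
# index = 100 * (response_multi - (response_state + response_contact)) /
#               (response_state + response_contact)
# on 5-s-window condition-mean rates. An index of 100 means the multimodal
# response is double the additive prediction; units with index > 0 (strict)
# are superadditive integration cells.

#' Superadditive integration index
#'
#' Responses below `floor_rate` in the additive denominator make the index
#' undefined; such units return `NA` and are reported by the caller rather
#' than silently dropped.
#'
#' @param response_state Unimodal state-stimulation response (spikes/s).
#' @param response_contact Unimodal contact response (spikes/s).
#' @param response_multi Multimodal response (spikes/s).
#' @param floor_rate Denominator floor (spikes/s; default 0.5).
#' @return Numeric index in percent of the additive response (vectorised);
#'   `NA` where the additive response is below the floor.
#' @export
integration_index <- function(response_state, response_contact,
                              response_multi, floor_rate = 0.5) {
  if (any(c(response_state, response_contact, response_multi) < 0,
          na.rm = TRUE))
    stop_validation("responses must be non-negative rates")
  additive <- response_state + response_contact
  idx <- 100 * (response_multi - additive) / additive
  idx[additive < floor_rate] <- NA_real_
  idx
}

#' Classify indices as superadditive
#'
#' @param index Integration index (percent).
#' @return Logical: `TRUE` where `index > 0` strictly, `NA` where undefined.
#' @export
classify_superadditive <- function(index) {
  ifelse(is.na(index), NA, index > 0)
}

#' Fractions of units above integration-index thresholds
#'
#' @param index Numeric vector of indices (NA = excluded units).
#' @param thresholds Index thresholds (default above additive, double, triple:
#'   0, 100, 200).
#' @return data.frame `threshold`, `fraction` over the defined indices; the
#'   fractions are monotone non-increasing in the threshold.
#' @export
summarize_integration <- function(index, thresholds = c(0, 100, 200)) {
  ok <- index[!is.na(index)]
  if (length(ok) == 0L)
    stop_validation("no defined integration indices to summarize")
  data.frame(threshold = thresholds,
             fraction = vapply(thresholds, function(th) mean(ok > th),
                               numeric(1)))
}

#' Integration results for every unit of a session
#'
#' Computes the three condition responses (5-s windows), optionally
#' baseline-subtracted (the evoked-response variant appropriate for
#' additivity analyses of circuits with nonzero baseline), and the index.
#'
#' @param spikes A `spike_data` object.
#' @param trials A `trial_table`.
#' @param baseline A `baseline_stats` data.frame; required when
#'   `baseline_subtract = TRUE`.
#' @param baseline_subtract Subtract each unit's baseline mean from the
#'   responses before forming the index (evoked rates clipped at 0).
#' @param window_s Response window (s; default 5).
#' @param bin_width Bin width (s; default 0.1).
#' @param floor_rate Denominator floor (spikes/s).
#' @return data.frame with per-unit responses, `response_additive`,
#'   `integration_index` and `superadditive`.
#' @export
integration_table <- function(spikes, trials, baseline = NULL,
                              baseline_subtract = FALSE, window_s = 5,
                              bin_width = 0.1, floor_rate = 0.5) {
  resp <- condition_response_table(spikes, trials, window_s = window_s,
                                   bin_width = bin_width)
  s <- resp$response_state_only
  o <- resp$response_contact_only
  m <- resp$response_multimodal
  if (baseline_subtract) {
    if (is.null(baseline))
      stop_validation("baseline required for baseline_subtract = TRUE")
    mu <- baseline$mu[match(resp$unit_id, baseline$unit_id)]
    s <- pmax(0, s - mu); o <- pmax(0, o - mu); m <- pmax(0, m - mu)
  }
  resp$response_additive <- s + o
  resp$integration_index <- integration_index(s, o, m, floor_rate)
  resp$superadditive <- classify_superadditive(resp$integration_index)
  n_excl <- sum(is.na(resp$integration_index))
  if (n_excl > 0)
    message(n_excl, " unit(s) excluded: additive response below ",
            floor_rate, " spikes/s")
  resp
}
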