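# Laterality metrics: selectivity index and ROC choice probability for a
# pair of conditions (canonically contralateral vs ipsilateral contact).

#' Selectivity index between two condition responses
#'
#' `SI = (C - I) / (C + I)` on non-negative mean rates; bounded in [-1, 1].
#' Pairs whose summed response falls below `floor_rate` are undefined (`NA`).
#'
#' @param response_contra Contralateral mean response (spikes/s).
#' @param response_ipsi Ipsilateral mean response (spikes/s).
#' @param floor_rate Denominator floor (spikes/s; default 0.5).
#' @return Numeric SI (vectorised), `NA` where undefined.
#' @export
selectivity_index <- function(response_contra, response_ipsi,
                              floor_rate = 0.5) {
  if (any(c(response_contra, response_ipsi) < 0, na.rm = TRUE))
    stop_validation("responses must be non-negative rates")
  tot <- response_contra + response_ipsi
  si <- (response_contra - response_ipsi) / tot
  si[tot < floor_rate] <- NA_real_
  si
}

#' ROC choice probability for two sets of per-trial responses
#'
#' The area under the ROC curve built from the two per-trial activity
#' distributions. `method = "rank"` (default) uses the exact Mann-Whitney
#' identity — the probability that a random trial of the first condition
#' exceeds a random trial of the second, ties counted 1/2 — which equals the
#' integrated ROC area without any binning artefact. `method = "histogram"`
#' constructs the ROC curve explicitly from the empirical distributions over
#' shared value bins and integrates it by trapezoids; with one bin per
#' distinct value the two methods agree exactly.
#'
#' @param responses_a Per-trial responses for the first condition (e.g.
#'   contralateral).
#' @param responses_b Per-trial responses for the second condition.
#' @param method `"rank"` or `"histogram"`.
#' @return Choice probability in [0, 1]; 0.5 means the two conditions are
#'   indistinguishable from this unit's activity.
#' @export
choice_probability <- function(responses_a, responses_b,
                               method = c("rank", "histogram")) {
  method <- match.arg(method)
  na <- length(responses_a); nb <- length(responses_b)
  if (na < 1L || nb < 1L)
    stop_validation("both conditions need at least one trial")
  if (any(!is.finite(c(responses_a, responses_b))))
    stop_validation("per-trial responses must be finite")
  if (method == "rank") {
    r <- rank(c(responses_a, responses_b), ties.method = "average")
    u <- sum(r[seq_len(na)]) - na * (na + 1) / 2
    u / (na * nb)
  } else {
    # explicit ROC: threshold sweep over shared bins (one per distinct value)
    breaks <- sort(unique(c(responses_a, responses_b)))
    # hit/false-alarm rates P(x >= threshold) as the threshold drops
    tpr <- c(0, vapply(rev(breaks), function(th) mean(responses_a >= th),
                       numeric(1)), 1)
    fpr <- c(0, vapply(rev(breaks), function(th) mean(responses_b >= th),
                       numeric(1)), 1)
    sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  }
}

#' Per-trial window-mean responses for a set of trials
#'
#' The per-trial summary entering the ROC analysis: mean rate in the
#' `window_s` seconds from the trial's response onset.
#'
#' @param spikes A `spike_data` object.
#' @param trials A `trial_table` subset (e.g. one side's contact trials).
#' @param window_s Window length (s; default 5).
#' @param bin_width Bin width (s).
#' @return Matrix units x trials of mean rates (spikes/s).
#' @export
per_trial_responses <- function(spikes, trials, window_s = 5,
                                bin_width = 0.1) {
  tr <- trials
  tr$t_resp_on <- response_onset(tr)
  br <- align_trials(spikes, tr, "t_resp_on", window = c(0, window_s),
                     bin_width = bin_width)
  out <- apply(br$rates, c(1, 2), mean)
  dimnames(out) <- list(br$unit_ids, br$trial_ids)
  out
}

#' Laterality analysis for every unit of a session
#'
#' Contrasts contralateral vs ipsilateral contact trials (any condition with
#' a contact epoch): selectivity index on the mean responses and choice
#' probability on the per-trial responses.
#'
#' @param spikes A `spike_data` object.
#' @param trials A `trial_table` with a `side` column.
#' @param window_s Response window (s).
#' @param bin_width Bin width (s).
#' @param si_threshold SI threshold for selectivity labels (default 0.3).
#' @param cp_thresholds `c(low, high)` CP thresholds (default 0.3, 0.7).
#' @param floor_rate SI denominator floor (spikes/s).
#' @return data.frame of class labels per unit: `selectivity_index`,
#'   `choice_probability`, `si_label`, `cp_informative`.
#' @export
laterality_table <- function(spikes, trials, window_s = 5, bin_width = 0.1,
                             si_threshold = 0.3, cp_thresholds = c(0.3, 0.7),
                             floor_rate = 0.5) {
  contra <- trials[trials$side == "contra", , drop = FALSE]
  ipsi <- trials[trials$side == "ipsi", , drop = FALSE]
  if (nrow(contra) < 2L || nrow(ipsi) < 2L)
    stop_validation("need >= 2 contra and >= 2 ipsi contact trials")
  rc <- per_trial_responses(spikes, contra, window_s, bin_width)
  ri <- per_trial_responses(spikes, ipsi, window_s, bin_width)
  si <- selectivity_index(rowMeans(rc), rowMeans(ri), floor_rate)
  cp <- vapply(seq_len(nrow(rc)),
               function(ui) choice_probability(rc[ui, ], ri[ui, ]),
               numeric(1))
  out <- data.frame(unit_id = rownames(rc),
                    region = spikes$units$region[
                      match(rownames(rc), spikes$units$unit_id)],
                    selectivity_index = as.numeric(si),
                    choice_probability = cp,
                    stringsAsFactors = FALSE)
  out <- cbind(out, classify_laterality(out$selectivity_index,
                                        out$choice_probability,
                                        si_threshold, cp_thresholds))
  out
}

#' Apply the selectivity and choice-probability thresholds
#'
#' Strict inequalities: contra-selective when `SI > si_threshold`,
#' ipsi-selective when `SI < -si_threshold`; CP-informative when
#' `CP > cp_thresholds[2]` or `CP < cp_thresholds[1]`.
#'
#' @param si Selectivity indices.
#' @param cp Choice probabilities.
#' @param si_threshold Default 0.3.
#' @param cp_thresholds Default `c(0.3, 0.7)`.
#' @return data.frame `si_label` (`contra_selective` / `ipsi_selective` /
#'   `nonselective` / `NA`), logical `cp_informative`.
#' @export
classify_laterality <- function(si, cp, si_threshold = 0.3,
                                cp_thresholds = c(0.3, 0.7)) {
  lab <- ifelse(si > si_threshold, "contra_selective",
                ifelse(si < -si_threshold, "ipsi_selective", "nonselective"))
  data.frame(si_label = lab,
             cp_informative = cp > cp_thresholds[2] | cp < cp_thresholds[1],
             stringsAsFactors = FALSE)
}
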