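# Session container I/O and the end-to-end pipeline.
#
# Sessions live in a directory of TSV tables plus a JSON manifest:
#   units.tsv              unit_id, region
#   spikes.tsv             unit_id, time_s
#   trials.tsv             the trial table
#   ground_truth.tsv       planted labels and true rates (simulated sessions)
#   photometry.tsv         time_s, f470, f405            (optional)
#   photometry_events.tsv  the photometry event table    (optional)
#   manifest.json          format version and table inventory

SESSION_FORMAT <- "sensint-session/1"

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

read_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}

#' Write a session to a directory of TSV tables
#'
#' @param session A `spike_session` (optionally carrying `$photometry`, a
#'   `photometry_session`).
#' @param dir Target directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_session <- function(session, dir) {
  stopifnot(inherits(session, "spike_session"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_tsv(session$spikes$units, file.path(dir, "units.tsv"))
  sp <- do.call(rbind, lapply(session$spikes$units$unit_id, function(u) {
    tt <- session$spikes$times[[u]]
    if (length(tt) == 0L) return(NULL)
    data.frame(unit_id = u, time_s = tt, stringsAsFactors = FALSE)
  }))
  if (is.null(sp)) sp <- data.frame(unit_id = character(0),
                                    time_s = numeric(0))
  write_tsv(sp, file.path(dir, "spikes.tsv"))
  write_tsv(as.data.frame(session$trials), file.path(dir, "trials.tsv"))
  tables <- c("units", "spikes", "trials")
  if (!is.null(session$truth)) {
    write_tsv(session$truth, file.path(dir, "ground_truth.tsv"))
    tables <- c(tables, "ground_truth")
  }
  if (!is.null(session$photometry)) {
    ph <- session$photometry
    write_tsv(data.frame(time_s = ph$time, f470 = ph$f470, f405 = ph$f405),
              file.path(dir, "photometry.tsv"))
    write_tsv(ph$events, file.path(dir, "photometry_events.tsv"))
    tables <- c(tables, "photometry", "photometry_events")
  }
  jsonlite::write_json(
    list(format = SESSION_FORMAT, tables = tables,
         n_units = nrow(session$spikes$units),
         n_trials = nrow(session$trials)),
    file.path(dir, "manifest.json"), auto_unbox = TRUE)
  invisible(dir)
}

validate_trials <- function(trials) {
  problems <- character(0)
  need <- c("trial_id", "condition", "t_ref_on")
  miss <- setdiff(need, names(trials))
  if (length(miss))
    return(paste("missing mandatory trial columns:",
                 paste(miss, collapse = ", ")))
  for (i in seq_len(nrow(trials))) {
    id <- trials$trial_id[i]
    for (pair in list(c("t_stim_on", "t_stim_off"),
                      c("t_contact_on", "t_contact_off"))) {
      if (all(pair %in% names(trials))) {
        on <- trials[[pair[1]]][i]; off <- trials[[pair[2]]][i]
        if (is.finite(on) != is.finite(off))
          problems <- c(problems, paste0(id, ": ", pair[1], "/", pair[2],
                                         " must be both present or both absent"))
        else if (is.finite(on) && off < on)
          problems <- c(problems, paste0(id, ": ", pair[2], " precedes ",
                                         pair[1]))
      }
    }
    cond <- trials$condition[i]
    has_c <- "t_contact_on" %in% names(trials) &&
      is.finite(trials$t_contact_on[i])
    has_s <- "t_stim_on" %in% names(trials) && is.finite(trials$t_stim_on[i])
    if (identical(cond, "state_only") && has_c)
      problems <- c(problems, paste0(id, ": state_only trial has contact times"))
    if (identical(cond, "contact_only") && has_s)
      problems <- c(problems, paste0(id, ": contact_only trial has stim times"))
    if (identical(cond, "multimodal") && !(has_c && has_s))
      problems <- c(problems, paste0(id, ": multimodal trial lacks an epoch"))
  }
  problems
}

#' Read a session directory written by [write_session()]
#'
#' All schema violations found are collected and reported together in a
#' single structured error.
#'
#' @param dir Session directory.
#' @return A `spike_session` (with `$truth` / `$photometry` when present).
#' @export
read_session <- function(dir) {
  if (!dir.exists(dir)) stop_validation("no session directory at ", dir)
  man_path <- file.path(dir, "manifest.json")
  if (!file.exists(man_path)) stop_validation("manifest.json missing")
  manifest <- jsonlite::read_json(man_path, simplifyVector = TRUE)
  if (!identical(manifest$format, SESSION_FORMAT))
    stop_validation("unknown session format: ", manifest$format)

  units <- read_tsv(file.path(dir, "units.tsv"))
  sp <- read_tsv(file.path(dir, "spikes.tsv"))
  trials <- read_tsv(file.path(dir, "trials.tsv"))

  problems <- character(0)
  if (anyDuplicated(units$unit_id))
    problems <- c(problems, "duplicate unit_ids in units.tsv")
  if (nrow(sp) && !all(sp$unit_id %in% units$unit_id))
    problems <- c(problems, "spikes.tsv references unknown unit_ids")
  problems <- c(problems, validate_trials(trials))
  times <- lapply(units$unit_id, function(u)
    sort(sp$time_s[sp$unit_id == u]))
  names(times) <- units$unit_id
  for (u in units$unit_id) {
    if (length(times[[u]]) && (any(!is.finite(times[[u]])) ||
                               any(times[[u]] < 0)))
      problems <- c(problems, paste0("unit ", u,
                                     ": non-finite or negative spike times"))
  }
  if (length(problems))
    stop_validation("session validation failed:\n  - ",
                    paste(problems, collapse = "\n  - "))

  class(trials) <- c("trial_table", "data.frame")
  out <- list(spikes = spike_data(units, times), trials = trials)
  gt_path <- file.path(dir, "ground_truth.tsv")
  if (file.exists(gt_path)) out$truth <- read_tsv(gt_path)
  ph_path <- file.path(dir, "photometry.tsv")
  if (file.exists(ph_path)) {
    ph <- read_tsv(ph_path)
    if (is.unsorted(ph$time_s, strictly = TRUE))
      stop_validation("photometry time grid must be strictly increasing")
    ev_path <- file.path(dir, "photometry_events.tsv")
    events <- if (file.exists(ev_path)) read_tsv(ev_path) else NULL
    out$photometry <- structure(
      list(time = ph$time_s, f470 = ph$f470, f405 = ph$f405,
           events = events,
           fs = 1 / stats::median(diff(ph$time_s))),
      class = "photometry_session")
  }
  structure(out, class = "spike_session")
}

#' Pipeline configuration with the study's default thresholds
#'
#' @param bin_width Analysis bin width (s; 0.1).
#' @param baseline_s Baseline window before trial onset (s; 4).
#' @param response_window_s Condition response window (s; 5).
#' @param z_threshold Responsiveness threshold in baseline sigmas (2).
#' @param index_thresholds Integration-index summary thresholds (0, 100, 200).
#' @param si_threshold Selectivity-index threshold (0.3).
#' @param cp_thresholds Choice-probability thresholds (0.3, 0.7).
#' @param k Clusters for profile k-means (6).
#' @param latency_bin_width Latency analysis bin width (s; 0.01).
#' @param latency_kernel_sd Latency smoothing kernel s.d. (s; 0.05).
#' @param photometry_window Photometry event window `c(pre, post)` (s; 2, 5).
#' @param seed Seed for stochastic stages.
#' @param strict Abort on recoverable data issues instead of warning.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(bin_width = 0.1, baseline_s = 4,
                            response_window_s = 5, z_threshold = 2,
                            index_thresholds = c(0, 100, 200),
                            si_threshold = 0.3, cp_thresholds = c(0.3, 0.7),
                            k = 6, latency_bin_width = 0.01,
                            latency_kernel_sd = 0.05,
                            photometry_window = c(2, 5),
                            seed = 1L, strict = FALSE) {
  cfg <- list(bin_width = bin_width, baseline_s = baseline_s,
              response_window_s = response_window_s,
              z_threshold = z_threshold,
              index_thresholds = index_thresholds,
              si_threshold = si_threshold, cp_thresholds = cp_thresholds,
              k = k, latency_bin_width = latency_bin_width,
              latency_kernel_sd = latency_kernel_sd,
              photometry_window = photometry_window,
              seed = as.integer(seed), strict = isTRUE(strict))
  for (nm in setdiff(names(cfg), "strict"))
    if (any(!is.finite(unlist(cfg[[nm]]))))
      stop_validation("config field ", nm, " must be finite")
  structure(cfg, class = "pipeline_config")
}

#' Run the full analysis pipeline on a session
#'
#' Stages: baseline statistics, per-condition responses, 2-sigma
#' classification and multimodal screen, interneuron flags, integration
#' indices, laterality (when both contact sides are present), latency and
#' profile clustering, and photometry normalization/event alignment (when a
#' photometry session is attached). Deterministic given the session, config
#' and seed.
#'
#' @param session A `spike_session` (from [simulate_spike_session()] or
#'   [read_session()]).
#' @param config A [pipeline_config()].
#' @param out_dir Optional directory for TSV/JSON outputs.
#' @return List of result tables plus a `manifest` describing the run.
#' @export
run_pipeline <- function(session, config = pipeline_config(),
                         out_dir = NULL) {
  stopifnot(inherits(session, "spike_session"),
            inherits(config, "pipeline_config"))
  spikes <- session$spikes; trials <- session$trials

  base <- baseline_stats(spikes, trials, baseline_s = config$baseline_s,
                         bin_width = config$bin_width)
  resp <- condition_response_table(spikes, trials,
                                   window_s = config$response_window_s,
                                   bin_width = config$bin_width)
  screen <- multimodal_screen(resp, base, threshold = config$z_threshold)
  fractions <- screen_fractions(screen)

  state_resp <- data.frame(unit_id = resp$unit_id,
                           response = resp$response_state_only)
  state_class <- classify_responsive(state_resp, base,
                                     threshold = config$z_threshold)
  state_class <- identify_interneurons(state_class, base,
                                       threshold = config$z_threshold)

  integ <- suppressMessages(
    integration_table(spikes, trials, base,
                      window_s = config$response_window_s,
                      bin_width = config$bin_width))
  integ_summary <- summarize_integration(integ$integration_index,
                                         config$index_thresholds)

  lat_tbl <- NULL
  if (all(c("contra", "ipsi") %in% trials$side) &&
      sum(trials$side == "contra") >= 2 && sum(trials$side == "ipsi") >= 2) {
    lat_tbl <- laterality_table(spikes, trials,
                                window_s = config$response_window_s,
                                bin_width = config$bin_width,
                                si_threshold = config$si_threshold,
                                cp_thresholds = config$cp_thresholds)
  }

  # peak latency for most units, trough latency for putative interneurons
  state_trials <- trials[trials$condition == "state_only", , drop = FALSE]
  latency <- latency_table(spikes, state_trials, event = "t_stim_on",
                           direction = "peak",
                           bin_width = config$latency_bin_width,
                           kernel_sd = config$latency_kernel_sd)
  inh_ids <- state_class$unit_id[state_class$putative_interneuron]
  if (length(inh_ids)) {
    inh_units <- spikes$units[spikes$units$unit_id %in% inh_ids, ,
                              drop = FALSE]
    inh_spikes <- spike_data(inh_units, spikes$times[inh_units$unit_id])
    tr_lat <- latency_table(inh_spikes, state_trials, event = "t_stim_on",
                            direction = "trough",
                            bin_width = config$latency_bin_width,
                            kernel_sd = config$latency_kernel_sd)
    idx <- match(tr_lat$unit_id, latency$unit_id)
    latency$direction[idx] <- "trough"
    latency$latency_s[idx] <- tr_lat$latency_s
  }

  profiles <- profile_matrix(spikes, trials, base,
                             bin_width = config$bin_width)
  clusters <- kmeans_profiles(profiles, k = min(config$k, nrow(profiles)),
                              seed = config$seed)

  photometry <- NULL
  if (!is.null(session$photometry)) {
    ph <- session$photometry
    norm <- normalize_photometry(ph)
    if (!is.null(ph$events) && nrow(ph$events) > 0) {
      ear <- event_aligned_response(ph$time, norm$f_n, ph$events$t_on,
                                    window = config$photometry_window)
      photometry <- list(normalized = norm, event_aligned = ear)
    } else {
      photometry <- list(normalized = norm)
    }
  }

  excluded <- sum(is.na(integ$integration_index))
  manifest <- list(
    package_version = as.character(utils::packageVersion("sensint")),
    config = unclass(config),
    n_units = nrow(spikes$units), n_trials = nrow(trials),
    n_excluded_integration = excluded,
    has_photometry = !is.null(photometry),
    has_laterality = !is.null(lat_tbl)
  )

  result <- list(baseline = base, responses = resp, screen = screen,
                 screen_fractions = fractions, state_classification = state_class,
                 integration = integ, integration_summary = integ_summary,
                 laterality = lat_tbl, latency = latency,
                 clusters = clusters, photometry = photometry,
                 manifest = manifest)

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_tsv(screen, file.path(out_dir, "classification.tsv"))
    write_tsv(integ, file.path(out_dir, "integration.tsv"))
    write_tsv(latency, file.path(out_dir, "latency.tsv"))
    if (!is.null(lat_tbl))
      write_tsv(lat_tbl, file.path(out_dir, "laterality.tsv"))
    write_tsv(data.frame(unit_id = rownames(profiles),
                         cluster = clusters$labels),
              file.path(out_dir, "clusters.tsv"))
    jsonlite::write_json(
      list(fractions = fractions,
           integration_summary = integ_summary,
           manifest = manifest),
      file.path(out_dir, "summary.json"), auto_unbox = TRUE, digits = NA)
  }
  result
}
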