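# Temporal dynamics: latency to extremum, k-means response-profile
# clustering, behaviour-triggered averages, and motion-energy correlation.

#' Latency to peak or trough of a trial-averaged trace
#'
#' The trace (typically a 10-ms-binned, Gaussian-smoothed trial average) is
#' searched within `window` for its maximum (`direction = "peak"`) or minimum
#' (`"trough"`); the latency is the time of the first bin attaining the
#' extremum, relative to time zero of the trace. A flat trace has no
#' extremum and returns `NA`.
#'
#' @param trace Numeric trace on a uniform grid starting at `t0`.
#' @param dt Bin width (s).
#' @param direction `"peak"` or `"trough"`.
#' @param window `c(from, to)` in seconds relative to the trace's time zero.
#' @param t0 Time of the first bin's left edge (s; default 0).
#' @param kernel_sd Gaussian smoothing applied before the search (s; 0 =
#'   none).
#' @return Latency in seconds, or `NA` if the windowed trace is flat.
#' @export
latency_to_extremum <- function(trace, dt, direction = c("peak", "trough"),
                                window = c(0, Inf), t0 = 0, kernel_sd = 0) {
  direction <- match.arg(direction)
  check_scalar_number(dt, "dt", lower = 1e-12)
  sm <- smooth_rate(trace, kernel_sd, dt)
  tt <- t0 + (seq_along(sm) - 1) * dt
  sel <- tt >= window[1] & tt <= window[2]
  if (!any(sel)) stop_validation("window contains no bins")
  v <- sm[sel]
  if (max(v) - min(v) < 1e-12) return(NA_real_)
  i <- if (direction == "peak") which.max(v) else which.min(v)
  tt[sel][i]
}

#' Latency table for a set of units
#'
#' Aligns spikes at 10-ms resolution to `event`, averages over trials,
#' smooths, and extracts the per-unit latency in the given direction.
#'
#' @param spikes A `spike_data` object.
#' @param trials A `trial_table` (typically one condition).
#' @param event Alignment event column (default `"t_stim_on"`).
#' @param direction `"peak"` or `"trough"` (per the unit's classification).
#' @param window `c(pre_s, post_s)` alignment window (default 0 to 10 s).
#' @param bin_width Bin width (s; default 0.01).
#' @param kernel_sd Smoothing kernel s.d. (s; default 0.05).
#' @return data.frame `unit_id`, `direction`, `latency_s` (`NA` = flat,
#'   excluded).
#' @export
latency_table <- function(spikes, trials, event = "t_stim_on",
                          direction = "peak", window = c(0, 10),
                          bin_width = 0.01, kernel_sd = 0.05) {
  br <- align_trials(spikes, trials, event, window = window,
                     bin_width = bin_width)
  lat <- vapply(seq_along(br$unit_ids), function(ui) {
    avg <- apply(br$rates[ui, , , drop = FALSE], 3, mean)
    latency_to_extremum(avg, bin_width, direction,
                        window = c(0, Inf), t0 = -window[1],
                        kernel_sd = kernel_sd)
  }, numeric(1))
  data.frame(unit_id = br$unit_ids, direction = direction, latency_s = lat,
             stringsAsFactors = FALSE)
}

# squared distances from rows of x to a center
row_sq_dist <- function(x, center) {
  colSums((t(x) - center)^2)
}

kmeanspp_init <- function(x, k) {
  n <- nrow(x)
  centers <- matrix(NA_real_, k, ncol(x))
  centers[1, ] <- x[sample.int(n, 1), ]
  if (k > 1) for (j in 2:k) {
    d2 <- do.call(pmin, lapply(seq_len(j - 1), function(i)
      row_sq_dist(x, centers[i, ])))
    if (sum(d2) == 0) {
      centers[j, ] <- x[sample.int(n, 1), ]
    } else {
      centers[j, ] <- x[sample.int(n, 1, prob = d2), ]
    }
  }
  centers
}

#' k-means clustering of z-scored response profiles
#'
#' Lloyd iterations from k-means++ seeds, repeated `n_restarts` times, best
#' run by within-cluster sum of squares (inertia). Deterministic given
#' `seed`. The inertia path of every run is checked to be non-increasing.
#'
#' @param profiles Numeric matrix, units x features (e.g. concatenated
#'   z-scored trial-average traces of the three conditions).
#' @param k Number of clusters (default 6).
#' @param seed Integer seed.
#' @param n_restarts Restarts (default 10).
#' @param max_iter Maximum Lloyd iterations per run.
#' @return List of class `cluster_result`: `labels` (1..k per unit),
#'   `centers`, `inertia`, `inertia_path`, `k`, `seed`.
#' @export
kmeans_profiles <- function(profiles, k = 6, seed = 1L, n_restarts = 10,
                            max_iter = 100) {
  if (!is.matrix(profiles)) profiles <- as.matrix(profiles)
  if (any(!is.finite(profiles)))
    stop_validation("profiles must be finite")
  n <- nrow(profiles)
  check_scalar_number(k, "k", lower = 1)
  if (k > n) stop_validation("k (", k, ") exceeds the number of units (", n, ")")
  set.seed(substream_seed(seed, 777))
  best <- NULL
  for (r in seq_len(n_restarts)) {
    centers <- kmeanspp_init(profiles, k)
    labels <- rep(1L, n)
    path <- numeric(0)
    for (it in seq_len(max_iter)) {
      d2 <- vapply(seq_len(k), function(j) row_sq_dist(profiles, centers[j, ]),
                   numeric(n))
      d2 <- matrix(d2, nrow = n)
      new_labels <- max.col(-d2, ties.method = "first")
      inertia <- sum(d2[cbind(seq_len(n), new_labels)])
      if (length(path) && inertia > path[length(path)] + 1e-8)
        stop("internal error: k-means inertia increased")
      path <- c(path, inertia)
      for (j in seq_len(k)) {
        members <- new_labels == j
        if (any(members))
          centers[j, ] <- colMeans(profiles[members, , drop = FALSE])
      }
      if (identical(new_labels, labels) && it > 1) break
      labels <- new_labels
    }
    if (is.null(best) || path[length(path)] < best$inertia) {
      best <- list(labels = labels, centers = centers,
                   inertia = path[length(path)], inertia_path = path)
    }
  }
  structure(c(best, list(k = k, seed = seed)), class = "cluster_result")
}

#' Concatenated z-scored trial-average profiles per unit
#'
#' Builds the feature matrix for [kmeans_profiles()]: for each condition, the
#' trial-average z-scored rate trace over a 20-s window (200 bins at 100 ms)
#' aligned to the trial onset, concatenated across conditions by unit.
#'
#' @param spikes A `spike_data` object.
#' @param trials A `trial_table`.
#' @param baseline A `baseline_stats` data.frame.
#' @param conditions Conditions to concatenate (default all three).
#' @param window `c(pre_s, post_s)` around the trial onset (default 5 and 15,
#'   a 20-s trial window).
#' @param bin_width Bin width (s; default 0.1).
#' @return Matrix units x (bins * conditions), rownames = unit ids.
#' @export
profile_matrix <- function(spikes, trials, baseline,
                           conditions = c("state_only", "contact_only",
                                          "multimodal"),
                           window = c(5, 15), bin_width = 0.1) {
  blocks <- lapply(conditions, function(cond) {
    tr <- trials[trials$condition == cond, , drop = FALSE]
    if (nrow(tr) == 0L) stop_validation("no trials of condition '", cond, "'")
    br <- align_trials(spikes, tr, "t_ref_on", window = window,
                       bin_width = bin_width)
    z <- zscore_rates(br, baseline)
    t(apply(z, 1, function(m) colMeans(matrix(m, nrow = dim(z)[2]))))
  })
  out <- do.call(cbind, blocks)
  rownames(out) <- spikes$units$unit_id
  out
}

#' Behaviour-event-triggered average
#'
#' Aligns spikes to a behaviour event (e.g. reach onset) and returns per-unit
#' mean traces plus the population mean with its standard error across
#' events.
#'
#' @param spikes A `spike_data` object.
#' @param trials A `trial_table`; rows lacking the event are skipped.
#' @param event Behaviour event column (e.g. `"t_reach_on"`).
#' @param window `c(pre_s, post_s)`.
#' @param bin_width Bin width (s).
#' @return List: `time` (bin centres, s), `per_unit` (units x bins),
#'   `population_mean`, `population_sem`, `n_events`.
#' @export
event_triggered_average <- function(spikes, trials, event, window = c(2, 2),
                                    bin_width = 0.1) {
  ev <- trials[[event]]
  if (is.null(ev) || !any(is.finite(ev)))
    stop_validation("no trials carry event '", event, "'")
  br <- suppressWarnings(
    align_trials(spikes, trials, event, window = window,
                 bin_width = bin_width))
  per_unit <- t(apply(br$rates, 1, function(m)
    colMeans(matrix(m, nrow = length(br$trial_ids)))))
  pop_by_event <- apply(br$rates, c(2, 3), mean)  # events x bins
  pop_by_event <- matrix(pop_by_event, nrow = length(br$trial_ids))
  n_ev <- length(br$trial_ids)
  list(time = (br$edges_rel[-1] + utils::head(br$edges_rel, -1)) / 2,
       per_unit = per_unit,
       population_mean = colMeans(pop_by_event),
       population_sem = apply(pop_by_event, 2, stats::sd) / sqrt(n_ev),
       n_events = n_ev)
}

#' Correlate the leading motion-energy component with a rate trace
#'
#' Motion energy is the absolute frame-to-frame pixel difference within the
#' ROI; its principal components come from a singular value decomposition of
#' the centred motion matrix (capped at 500 components, of which only the
#' first is consumed). The first component's sign is oriented so that it
#' correlates positively with total motion energy, and its Pearson r against
#' the (smoothed) rate trace is returned.
#'
#' @param frames 3-D array, time x rows x cols of pixel intensities.
#' @param roi Logical matrix (rows x cols) selecting the region of interest;
#'   `NULL` uses the full frame.
#' @param rate_trace Numeric trace with one sample per motion sample
#'   (i.e. `dim(frames)[1] - 1` samples) or per frame (first sample dropped).
#' @return List: `r` (Pearson correlation), `pc1` (motion PC scores),
#'   `motion_energy` (total per frame pair).
#' @export
motion_pc_correlation <- function(frames, roi = NULL, rate_trace) {
  if (length(dim(frames)) != 3L || dim(frames)[1] < 2L)
    stop_validation("frames must be a time x rows x cols array with >= 2 frames")
  n_t <- dim(frames)[1]
  flat <- matrix(frames, nrow = n_t)
  if (!is.null(roi)) {
    if (!is.logical(roi) || length(roi) != prod(dim(frames)[2:3]))
      stop_validation("roi must be a logical mask matching the frame shape")
    flat <- flat[, as.vector(roi), drop = FALSE]
  }
  me <- abs(diff(flat))                      # (n_t - 1) x pixels
  total <- rowSums(me)
  centred <- sweep(me, 2, colMeans(me))
  n_comp <- min(500L, dim(centred))
  sv <- svd(centred, nu = n_comp, nv = 0)
  pc1 <- sv$u[, 1] * sv$d[1]
  if (stats::cor(pc1, total) < 0) pc1 <- -pc1
  if (length(rate_trace) == n_t) rate_trace <- rate_trace[-1]
  if (length(rate_trace) != length(pc1))
    stop_validation("rate_trace length must match the motion samples")
  list(r = stats::cor(pc1, rate_trace), pc1 = pc1, motion_energy = total)
}
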