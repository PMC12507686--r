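test_that("latency finds constructed extrema and excludes flat traces", {
  dt <- 0.01
  tri <- c(seq(0, 1, length.out = 51), seq(1, 0, length.out = 51)[-1])
  trace <- c(rep(0, 50), tri, rep(0, 50))  # peak at bin 101 -> 1.00 s
  lat <- latency_to_extremum(trace, dt, "peak")
  expect_equal(lat, 1.00, tolerance = dt + 1e-9)
  lat_tr <- latency_to_extremum(-trace, dt, "trough")
  expect_equal(lat_tr, 1.00, tolerance = dt + 1e-9)
  expect_true(is.na(latency_to_extremum(rep(2, 100), dt, "peak")))
  # earliest bin wins ties: a plateau reports its first sample
  plat <- c(rep(0, 10), rep(5, 20), rep(0, 10))
  expect_equal(latency_to_extremum(plat, dt, "peak"), 10 * dt)
})

test_that("latency is invariant to positive affine transforms of the trace", {
  set.seed(9)
  trace <- smooth_rate(rnorm(300), 0.05, 0.01)
  l1 <- latency_to_extremum(trace, 0.01, "peak")
  l2 <- latency_to_extremum(3.7 * trace + 11, 0.01, "peak")
  expect_equal(l1, l2)
})

test_that("interneuron troughs precede integration-cell peaks in simulation", {
  ses <- simulate_spike_session(session_spec(
    regions = list(A = c(integration = 10, interneuron = 8)), seed = 71))
  st <- ses$trials[ses$trials$condition == "state_only", ]
  inh <- ses$truth$unit_id[ses$truth$class == "interneuron"]
  exc <- ses$truth$unit_id[ses$truth$class == "integration"]
  keep <- function(ids) {
    u <- ses$spikes$units[ses$spikes$units$unit_id %in% ids, ]
    spike_data(u, ses$spikes$times[u$unit_id])
  }
  lt_inh <- latency_table(keep(inh), st, direction = "trough")
  lt_exc <- latency_table(keep(exc), st, direction = "peak")
  expect_lt(median(lt_inh$latency_s, na.rm = TRUE),
            median(lt_exc$latency_s, na.rm = TRUE))
})

test_that("k-means recovers planted partitions and behaves at k = 1", {
  set.seed(15)
  t1 <- c(rep(0, 20), rep(4, 20))
  t2 <- c(rep(4, 20), rep(0, 20))
  noise_sd <- max(abs(t1 - t2)) / 10  # 5x separation margin
  X <- rbind(
    t(replicate(15, t1 + rnorm(40, 0, noise_sd))),
    t(replicate(15, t2 + rnorm(40, 0, noise_sd)))
  )
  res <- kmeans_profiles(X, k = 2, seed = 5)
  truth <- rep(1:2, each = 15)
  agree <- max(mean(res$labels == truth), mean(res$labels == 3 - truth))
  expect_equal(agree, 1)
  # inertia path non-increasing, and the best run beats a random labelling
  expect_true(all(diff(res$inertia_path) <= 1e-8))

  one <- kmeans_profiles(X, k = 1, seed = 5)
  expect_true(all(one$labels == 1))
  expect_equal(as.vector(one$centers), colMeans(X))

  # duplicated units always share a label
  Xd <- rbind(X, X[1, , drop = FALSE])
  resd <- kmeans_profiles(Xd, k = 2, seed = 5)
  expect_equal(resd$labels[1], resd$labels[31])

  expect_error(kmeans_profiles(X, k = 31), class = "sensint_validation_error")
})

test_that("hand-rolled k-means matches the stats::kmeans optimum on planted data", {
  set.seed(16)
  X <- rbind(matrix(rnorm(200, 0), 10), matrix(rnorm(200, 6), 10))
  ours <- kmeans_profiles(X, k = 2, seed = 3, n_restarts = 5)
  ref <- stats::kmeans(X, centers = 2, nstart = 5, algorithm = "Lloyd")
  expect_equal(ours$inertia, ref$tot.withinss, tolerance = 1e-6)
})

test_that("clustering separates planted response classes end to end", {
  ses <- simulate_spike_session(session_spec(
    regions = list(A = c(integration = 8, interneuron = 8)), seed = 23))
  base <- baseline_stats(ses$spikes, ses$trials)
  X <- profile_matrix(ses$spikes, ses$trials, base)
  expect_equal(ncol(X), 3 * 200)  # three 20-s condition blocks at 100 ms
  res <- kmeans_profiles(X, k = 2, seed = 1)
  cls <- ses$truth$class[match(rownames(X), ses$truth$unit_id)]
  tab <- table(res$labels, cls)
  expect_equal(max(tab[1, ]) + max(tab[2, ]), 16)  # pure clusters
})

test_that("event-triggered averages localize planted pre-event steps", {
  # rate steps up 200 ms before each event
  events <- c(20, 40, 60, 80)
  spk <- sort(unlist(lapply(events, function(e)
    seq(e - 0.2, e + 0.3, by = 0.01))))
  spikes <- manual_spikes(list(u1 = spk))
  trials <- data.frame(trial_id = sprintf("t%d", 1:4), t_beh = events)
  eta <- event_triggered_average(spikes, trials, "t_beh", window = c(1, 1),
                                 bin_width = 0.1)
  expect_equal(eta$n_events, 4)
  peak_t <- eta$time[which.max(eta$population_mean)]
  expect_lt(peak_t, 0.31)
  expect_gt(max(eta$population_mean[eta$time < 0]), 0)  # precedes the event

  # single event: average equals that segment
  tr1 <- trials[1, , drop = FALSE]
  eta1 <- event_triggered_average(spikes, tr1, "t_beh", window = c(1, 1),
                                  bin_width = 0.1)
  br1 <- align_trials(spikes, tr1, "t_beh", window = c(1, 1), bin_width = 0.1)
  expect_equal(eta1$population_mean, as.vector(br1$rates[1, 1, ]))
  expect_error(event_triggered_average(spikes, transform(trials, t_beh = NA),
                                       "t_beh"),
               class = "sensint_validation_error")
})

test_that("event-triggered averaging is linear in the rate tensor", {
  set.seed(77)
  spikes <- manual_spikes(list(a = sort(runif(200, 0, 100)),
                               b = sort(runif(150, 0, 100))))
  trials <- data.frame(trial_id = c("t1", "t2"), t_beh = c(30, 70))
  eta <- event_triggered_average(spikes, trials, "t_beh", window = c(1, 1))
  expect_equal(colMeans(eta$per_unit) * 2,
               colSums(eta$per_unit))
  expect_equal(eta$population_mean, colMeans(eta$per_unit))
})

test_that("motion PC correlation behaves on injected and null signals", {
  set.seed(31)
  n_t <- 400
  frames <- array(rnorm(n_t * 8 * 8), dim = c(n_t, 8, 8))
  # inject a strong common motion component in half the pixels
  drive <- abs(rnorm(n_t - 1)) * 5
  for (i in 2:n_t) frames[i, 1:4, ] <- frames[i - 1, 1:4, ] +
      drive[i - 1] * 0.5
  res <- motion_pc_correlation(frames, roi = NULL,
                               rate_trace = rnorm(n_t - 1))
  # sign convention: PC1 oriented with total motion energy
  expect_gt(cor(res$pc1, res$motion_energy), 0)
  # injecting the PC itself as the rate trace gives r = 1
  res2 <- motion_pc_correlation(frames, roi = NULL, rate_trace = res$pc1)
  expect_equal(res2$r, 1, tolerance = 1e-9)
  # independent noise: negligible correlation
  res3 <- motion_pc_correlation(frames, roi = NULL,
                                rate_trace = rnorm(n_t - 1))
  expect_lt(abs(res3$r), 0.2)
  expect_error(motion_pc_correlation(array(0, c(1, 4, 4)), NULL, 1),
               class = "sensint_validation_error")
})
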