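test_that("binning follows the half-open convention and conserves counts", {
  b <- bin_spikes(c(0.05, 0.15, 0.151), c(0, 0.1, 0.2))
  expect_identical(b$counts, c(1L, 2L))
  expect_equal(b$rates, c(10, 20))

  # 20-s trial at 100-ms bins = 200 bins
  edges <- seq(0, 20, by = 0.1)
  expect_length(bin_spikes(numeric(0), edges)$counts, 200)
  expect_true(all(bin_spikes(numeric(0), edges)$counts == 0))

  # right edge excluded, left edge included
  b2 <- bin_spikes(c(0, 0.2), c(0, 0.1, 0.2))
  expect_identical(b2$counts, c(1L, 0L))

  set.seed(1)
  spk <- sort(runif(500, 0, 20))
  expect_equal(sum(bin_spikes(spk, edges)$counts),
               sum(spk >= 0 & spk < 20))
  expect_error(bin_spikes(1, c(0.2, 0.1)), class = "sensint_validation_error")
})

test_that("trial alignment matches a naive double loop and is order/translation invariant", {
  set.seed(42)
  times <- list(uA = sort(runif(300, 0, 100)), uB = sort(runif(80, 0, 100)))
  spikes <- manual_spikes(times)
  trials <- data.frame(trial_id = c("t1", "t2", "t3"),
                       t_ev = c(20, 50, 80))
  br <- align_trials(spikes, trials, "t_ev", window = c(1, 2),
                     bin_width = 0.5)
  # naive oracle: loop spikes per trial window
  for (u in c("uA", "uB")) for (k in 1:3) {
    ev <- trials$t_ev[k]
    for (bin in 1:6) {
      lo <- ev - 1 + (bin - 1) * 0.5
      expected <- sum(times[[u]] >= lo & times[[u]] < lo + 0.5)
      expect_equal(br$counts[u, trials$trial_id[k], bin], expected)
    }
  }
  # row order of the trial table must not matter
  br2 <- align_trials(spikes, trials[c(3, 1, 2), ], "t_ev",
                      window = c(1, 2), bin_width = 0.5)
  expect_identical(br$counts, br2$counts)
  # global time translation
  spikes_sh <- manual_spikes(lapply(times, function(x) x + 5))
  trials_sh <- transform(trials, t_ev = t_ev + 5)
  br3 <- align_trials(spikes_sh, trials_sh, "t_ev", window = c(1, 2),
                      bin_width = 0.5)
  expect_identical(br$counts, br3$counts)
  # spike exactly at the event lands in the first post-event bin
  sp1 <- manual_spikes(list(u1 = 10))
  b1 <- align_trials(sp1, data.frame(trial_id = "t", t_ev = 10), "t_ev",
                     window = c(1, 1), bin_width = 0.5)
  expect_equal(as.vector(b1$counts), c(0, 0, 1, 0))
})

test_that("missing events drop trials leniently and abort under strict mode", {
  spikes <- manual_spikes(list(u1 = c(1, 2, 3)))
  trials <- data.frame(trial_id = c("t1", "t2"), t_ev = c(2, NA))
  expect_warning(br <- align_trials(spikes, trials, "t_ev",
                                    window = c(1, 1)), "excluded")
  expect_identical(br$trial_ids, "t1")
  expect_error(align_trials(spikes, trials, "t_ev", window = c(1, 1),
                            strict = TRUE),
               class = "sensint_validation_error")
})

test_that("baseline statistics match Poisson expectations and floor silent units", {
  set.seed(5)
  lam <- 8
  spikes <- manual_spikes(list(hp = sort(runif(rpois(1, lam * 200), 0, 200)),
                               silent = numeric(0)))
  trials <- data.frame(trial_id = sprintf("t%02d", 1:10),
                       condition = "state_only",
                       t_ref_on = seq(10, 190, by = 20))
  base <- baseline_stats(spikes, trials)
  se <- sqrt(lam / (4 * 10))
  expect_lt(abs(base$mu[base$unit_id == "hp"] - lam), 3 * se)
  expect_equal(base$mu[base$unit_id == "silent"], 0)
  expect_equal(base$sigma_raw[base$unit_id == "silent"], 0)
  expect_equal(base$sigma[base$unit_id == "silent"], 0.1)
  expect_error(baseline_stats(spikes,
                              data.frame(trial_id = "t1", condition = "x",
                                         t_ref_on = 2)),
               class = "sensint_validation_error")
})

test_that("identical trials contribute zero between-trial baseline variance", {
  # same spike pattern before both onsets -> per-trial means identical
  pat <- c(0.5, 1.2, 2.2, 3.1)
  spikes <- manual_spikes(list(u1 = sort(c(6 + pat, 26 + pat))))
  trials <- data.frame(trial_id = c("t1", "t2"), condition = "state_only",
                       t_ref_on = c(10.5, 30.5))
  base <- baseline_stats(spikes, trials)
  expect_equal(base$sigma_raw, 0)
  expect_equal(base$sigma, 0.1)  # floored
  # bin-pooled mode still sees within-trial bin variance
  basep <- baseline_stats(spikes, trials, sigma_mode = "bin_pooled")
  expect_gt(basep$sigma_raw, 0)
})

test_that("z-scoring matches an elementwise oracle and is affine-equivariant", {
  ses <- small_session()
  base <- baseline_stats(ses$spikes, ses$trials)
  br <- align_trials(ses$spikes, ses$trials, "t_ref_on", window = c(2, 4))
  z <- zscore_rates(br, base)
  ui <- 3; ti <- 2; bi <- 5
  mu <- base$mu[base$unit_id == br$unit_ids[ui]]
  sg <- base$sigma[base$unit_id == br$unit_ids[ui]]
  expect_equal(z[ui, ti, bi], (br$rates[ui, ti, bi] - mu) / sg)

  # scaling rates and baseline stats together leaves z unchanged
  br2 <- br; br2$rates <- br$rates * 3
  base2 <- base; base2$mu <- base$mu * 3; base2$sigma <- base$sigma * 3
  expect_equal(zscore_rates(br2, base2), z)

  # a unit sitting exactly at baseline + 2 sigma scores z = 2
  fake <- br
  fake$rates[1, , ] <- base$mu[1] + 2 * base$sigma[1]
  expect_true(all(abs(zscore_rates(fake, base)[1, , ] - 2) < 1e-12))
})

test_that("Gaussian smoothing conserves mass, is identity at sd 0, and matches the CDF on a step", {
  x <- c(rep(0, 50), rep(0, 0)); x[25] <- 1
  sm <- smooth_rate(x, 0.05, 0.01)
  expect_equal(sum(sm), sum(x), tolerance = 1e-9)
  expect_identical(smooth_rate(x, 0, 0.01), x)

  step <- c(rep(0, 200), rep(1, 200))
  sms <- smooth_rate(step, 0.05, 0.01)
  tt <- (seq_along(step) - 200.5) * 0.01
  expect_lt(max(abs(sms[50:350] - pnorm(tt[50:350], sd = 0.05))), 0.02)
})
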