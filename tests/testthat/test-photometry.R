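toy_session <- function(f470, f405, fs = 20) {
  structure(list(time = (seq_along(f470) - 1) / fs,
                 f470 = f470, f405 = f405, events = NULL, fs = fs),
            class = "photometry_session")
}

test_that("isosbestic fit recovers exact affine relations", {
  x <- seq(50, 100, length.out = 500)
  fit <- fit_isosbestic(toy_session(3 * x + 2, x))
  expect_equal(fit$a, 3, tolerance = 1e-10)
  expect_equal(fit$b, 2, tolerance = 1e-9)
  # identical channels: slope 1, intercept 0, fitted equals the signal
  fit2 <- fit_isosbestic(toy_session(x, x))
  expect_equal(fit2$fitted, x, tolerance = 1e-9)
  expect_warning(fit_isosbestic(toy_session(x, rep(1, 500))), "constant")
})

test_that("normalization satisfies the printed identities and scale invariance", {
  x <- 80 + 10 * sin(seq(0, 6, length.out = 400))
  s <- toy_session(x, x)
  norm <- normalize_photometry(s)
  expect_true(all(abs(norm$f_n) < 1e-8))  # F470 == F405fit -> 0

  # F470 = 2 * F405fit -> F_n = 100 everywhere
  fit <- fit_isosbestic(s)
  s2 <- s; s2$f470 <- 2 * fit$fitted
  norm2 <- normalize_photometry(s2, fit)
  expect_equal(unique(round(norm2$f_n, 9)), 100)

  # common rescaling of both channels leaves F_n unchanged
  set.seed(6)
  y <- x + rnorm(400, 0, 2)
  n1 <- normalize_photometry(toy_session(y, x))
  n3 <- normalize_photometry(toy_session(7 * y, 7 * x))
  expect_equal(n1$f_n, n3$f_n, tolerance = 1e-9)
})

test_that("isosbestic referencing suppresses the shared motion artefact", {
  sim <- simulate_photometry(small_spec(), seed = 41,
                             events = photometry_events(n_per_type = 4))
  s <- sim$session
  norm <- normalize_photometry(s)
  naive <- 100 * (s$f470 - mean(s$f470)) / mean(s$f470)
  # high-pass both to isolate the fast (motion) band from bleach and signal
  hp <- function(x) x - smooth_rate(x, 2, 1 / s$fs)
  quiet <- s$time < min(sim$truth$t_on)  # pre-event segment: artefact only
  expect_gt(stats::var(hp(naive)[quiet]) / stats::var(hp(norm$f_n)[quiet]), 10)
})

test_that("trace z-scoring has unit scale and is affine invariant", {
  set.seed(8)
  x <- rnorm(200, 50, 4)
  z <- zscore_trace(x)
  expect_equal(mean(z), 0, tolerance = 1e-12)
  expect_equal(stats::sd(z), 1, tolerance = 1e-12)
  expect_equal(zscore_trace(5 * x - 3), z, tolerance = 1e-10)
  v <- c(1, 2, 3, 4, 10)
  expect_equal(zscore_trace(v), (v - mean(v)) / stats::sd(v))
  expect_error(zscore_trace(rep(1, 10)), class = "sensint_validation_error")
})

test_that("event alignment recovers planted amplitudes and handles edge cases", {
  spec <- small_spec()
  ev <- photometry_events(n_per_type = 20,
                          amplitudes = c(object = 0.02, free = 0.16))
  sim <- simulate_photometry(spec, seed = 51, events = ev)
  norm <- normalize_photometry(sim$session)
  resp_by <- function(type) {
    t_on <- sim$truth$t_on[sim$truth$bout_type == type]
    mean(event_aligned_response(sim$session$time, norm$f_n, t_on)$responses)
  }
  ratio <- resp_by("free") / resp_by("object")
  expect_lt(abs(ratio - 8), 0.2 * 8)

  # single event: aligned mean equals that segment
  one <- event_aligned_response(sim$session$time, norm$f_n,
                                sim$truth$t_on[1])
  expect_equal(one$mean, as.vector(one$aligned[1, ]))
  # events without coverage are dropped with a warning
  expect_warning(event_aligned_response(sim$session$time, norm$f_n,
                                        c(sim$truth$t_on[1], -50)),
                 "dropped")
  expect_error(event_aligned_response(sim$session$time, norm$f_n,
                                      numeric(0)),
               class = "sensint_validation_error")
})

test_that("state-split comparison recovers planted contrasts", {
  spec <- small_spec()
  ev <- photometry_events(n_per_type = 40,
                          amplitudes = c(free = 0.16),
                          epoch_split = TRUE, post_factor = 0.25)
  sim <- simulate_photometry(spec, seed = 61, events = ev)
  norm <- normalize_photometry(sim$session)
  ear <- event_aligned_response(sim$session$time, norm$f_n, sim$truth$t_on)
  groups <- sim$truth$epoch[match(ear$event_times, sim$truth$t_on)]
  cmp <- state_split_comparison(ear$responses, groups, seed = 2)
  pre <- cmp$means[cmp$levels == "pre_milestone"]
  post <- cmp$means[cmp$levels == "post_milestone"]
  expect_lt(abs(pre / post - 4), 0.25 * 4)
  expect_true(cmp$ci[1] < cmp$difference & cmp$difference < cmp$ci[2])

  # identical groups: difference exactly zero
  same <- state_split_comparison(rep(c(1, 2), 10),
                                 rep(c("a", "b"), each = 10), seed = 3)
  expect_equal(same$difference, 0)
  expect_error(state_split_comparison(1:4, rep("a", 4)),
               class = "sensint_validation_error")

  # face-vs-back: planted back amplitude 0 stays within noise of 0
  ev2 <- photometry_events(n_per_type = 20, amplitudes = c(free = 0.16),
                           site_split = TRUE, back_factor = 0)
  sim2 <- simulate_photometry(spec, seed = 71, events = ev2)
  norm2 <- normalize_photometry(sim2$session)
  ear2 <- event_aligned_response(sim2$session$time, norm2$f_n,
                                 sim2$truth$t_on)
  site <- sim2$truth$body_site[match(ear2$event_times, sim2$truth$t_on)]
  back_mean <- mean(ear2$responses[site == "back"])
  back_se <- stats::sd(ear2$responses[site == "back"]) /
    sqrt(sum(site == "back"))
  expect_lt(abs(back_mean), 4 * back_se + 0.05)
})
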