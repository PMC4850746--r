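test_that("pulse extraction handles toy traces exactly", {
  # all below threshold: one censored interval, no pulses
  ps <- extract_pulses(fx_trace(rep(0, 10)), threshold = 1)
  expect_equal(sum(ps$type == "pulse"), 0)
  expect_equal(sum(ps$type == "interval"), 1)
  expect_true(all(ps$censored))
  # alternating frames: all pulses one frame long
  ps2 <- extract_pulses(fx_trace(rep(c(0, 5), 10)), threshold = 1)
  pd <- ps2[ps2$type == "pulse", ]
  expect_true(all(pd$n_frames == 1))
  expect_equal(nrow(pd), 10)
  # values exactly at the threshold count as below
  ps3 <- extract_pulses(fx_trace(c(0, 2, 2, 0)), threshold = 2)
  expect_equal(sum(ps3$type == "pulse"), 0)
  # alternation bookkeeping per track
  set.seed(60)
  tr <- dplyr::bind_rows(fx_trace(runif(50), cell = 1),
                         fx_trace(runif(35), cell = 2))
  ps4 <- extract_pulses(tr, 0.5)
  counts <- ps4 |>
    dplyr::count(.data$cell, .data$type) |>
    tidyr::pivot_wider(names_from = "type", values_from = "n",
                       values_fill = 0)
  expect_true(all(abs(counts$pulse - counts$interval) <= 1))
  expect_error(extract_pulses(fx_trace(numeric(0)), 1), "empty")
})

test_that("censored exponential MLE recovers a known rate", {
  set.seed(61)
  dt <- 10
  lam <- 1 / 80
  dur <- rexp(1e4, lam) + 2 * dt
  ps <- fx_trace(rep(0, 2))  # container for attrs
  pulses <- tibble::tibble(cell = 1, type = "pulse", start_time_s = 0,
                           n_frames = dur / dt, duration_s = dur,
                           censored = FALSE)
  attr(pulses, "frame_interval_s") <- dt
  class(pulses) <- c("pulse_set", class(pulses))
  fit <- fit_exponential_durations(pulses, "pulse", min_duration_s = 2 * dt)
  expect_lt(abs(fit$rate - lam) / lam, 0.03)
  expect_true(fit$ci[1] < lam && lam < fit$ci[2])
  # identical durations: degenerate fit flagged
  pulses2 <- pulses[1:50, ]
  pulses2$duration_s <- 40
  fit2 <- fit_exponential_durations(pulses2, "pulse", min_duration_s = 40)
  expect_true(fit2$degenerate)
  expect_error(fit_exponential_durations(pulses[1:5, ], "pulse"),
               ">= 20")
})

test_that("one-state pulse durations are exponential in the tail", {
  tr <- simulate_trace(fx_construct(), fx_poisson_kinetics(0.1),
                       fx_frames(10, noise = 5), duration_s = 8e4,
                       seed = 62)
  mom <- campbell_moments(fx_construct(), fx_poisson_kinetics(0.1),
                          fx_frames(10, noise = 5))
  ps <- extract_pulses(tr, mom$mean)
  # short pulses deviate from the exponential (frame quantization and the
  # finite polymerase residence); the tail beyond 3 frames is exponential
  set.seed(63)
  fit <- fit_exponential_durations(ps, "pulse", min_duration_s = 30)
  expect_gt(fit$ks_p_value, 0.01)
  expect_gt(fit$n_uncensored, 100)
})

test_that("fluctuation ACF has the expected structure", {
  # white noise: G(0) = sigma^2/mu^2, G(tau > 0) ~ 0
  set.seed(64)
  tr <- dplyr::bind_rows(lapply(1:20, function(i)
    fx_trace(100 + rnorm(200, 0, 10), cell = i)))
  G <- autocorrelate(tr, max_lag_s = 100)
  expect_lt(abs(G$G[1] - 100 / 1e4) / (100 / 1e4), 0.15)
  expect_true(all(abs(G$G[-1]) < 3.5 * G$se[-1] + 1e-5))
  # one-state simulation matches the Campbell covariance at positive lags
  trs <- simulate_traces(fx_construct(), fx_poisson_kinetics(0.13),
                         fx_frames(10), duration_s = 8000, n_cells = 12,
                         seed = 65)
  G2 <- autocorrelate(trs, max_lag_s = 150)
  kern <- fx_kernel()
  mu <- 0.13 * kern$loop_integral
  for (k in c(2, 6, 11)) {
    pred <- 0.13 * kernel_cross_integral(kern, G2$lag_s[k]) / mu^2
    expect_lt(abs(G2$G[k] - pred), 4 * G2$se[k])
  }
  expect_error(autocorrelate(fx_trace(rep(0, 30)), 50), "zero")
})

test_that("ACF decomposition separates dwell and slow components", {
  kern <- fx_kernel()
  # one-state gene: no slow component; dwell estimate near the release time
  trs <- simulate_traces(fx_construct(), fx_poisson_kinetics(0.13),
                         fx_frames(10, noise = 10), duration_s = 4000,
                         n_cells = 15, seed = 66)
  G <- autocorrelate(trs, max_lag_s = 2.2 * kern$release_time_s + 30)
  d <- decompose_acf(G, kern)
  expect_lt(abs(d$dwell_s - kern$release_time_s), 4 * 10)
  expect_lt(abs(d$slow_line[[2]]), 5e-5)  # flat long-lag line
  # continuum gene: slow component present, dwell still recovered
  trc <- simulate_traces(fx_construct(),
                         kinetic_params(initiation_continuum(), 22, 65),
                         fx_frames(10, noise = 15), duration_s = 3000,
                         n_cells = 12, seed = 67, diploid = TRUE)
  Gc <- autocorrelate(trc, max_lag_s = 2.2 * kern$release_time_s + 30)
  dc <- decompose_acf(Gc, kern)
  expect_gt(dc$acf$slow_line[1], 0)       # nonzero slow component at lag 0
  expect_gt(dc$dwell_s, 120)
  expect_lt(dc$dwell_s, 260)
  # continuum ACF stays positive beyond the dwell (slow decay persists)
  tail_G <- Gc$G[Gc$lag_s > kern$release_time_s]
  expect_gt(mean(tail_G), 0)
  expect_gt(mean(tail_G > 0), 0.8)
})

test_that("quantile calibration recovers monotone transforms", {
  set.seed(68)
  live <- rgamma(5000, 4, 0.02)
  # exact factor-two scaling recovered to machine-ish precision
  cal <- quantile_calibrate(live, 2 * live)
  xs <- unname(quantile(live, c(0.1, 0.4, 0.8)))
  expect_equal(cal$map(xs), 2 * xs, tolerance = 1e-6)
  # smooth monotone cubic transform recovered within 2% centrally
  g <- function(x) 0.5 * x + 1e-5 * x^2 + 30
  fish <- g(rgamma(10000, 4, 0.02))
  cal2 <- quantile_calibrate(rgamma(10000, 4, 0.02), fish)
  xs2 <- quantile(live, seq(0.05, 0.95, by = 0.05))
  expect_lt(max(abs(cal2$map(xs2) - g(xs2)) / g(xs2)), 0.02)
  # distributional round trip: mapped live sample looks like the fish one
  mapped <- cal2$map(rgamma(10000, 4, 0.02))
  expect_lt(suppressWarnings(ks.test(mapped, fish)$statistic), 0.05)
  # re-binning the percentile grid barely moves the map
  cal3 <- quantile_calibrate(live, 2 * live,
                             probs = seq(0.02, 0.98, by = 0.02))
  expect_lt(max(abs(cal3$map(xs) - cal$map(xs)) / cal$map(xs)), 0.01)
  expect_error(quantile_calibrate(live[1:50], 2 * live), ">= 100")
})

test_that("calibration application is a per-frame monotone map", {
  set.seed(69)
  live <- rgamma(2000, 4, 0.02)
  tr <- fx_trace(live[1:100])
  id <- quantile_calibrate(live, live)
  expect_equal(apply_calibration(tr, id)$intensity, tr$intensity,
               tolerance = 1e-8)
  x2 <- quantile_calibrate(live, 2 * live)
  tr2 <- apply_calibration(tr, x2)
  expect_equal(tr2$intensity, 2 * tr$intensity, tolerance = 1e-6)
  expect_equal(attr(tr2, "units"), "loops")
  # round trip through the inverse curve
  inv <- quantile_calibrate(2 * live, live)
  back <- apply_calibration(tr2, inv)
  expect_lt(max(abs(back$intensity - tr$intensity) /
                  pmax(tr$intensity, 1)), 0.02)
})
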