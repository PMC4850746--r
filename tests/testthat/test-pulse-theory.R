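test_that("Campbell moments have the filtered-Poisson structure", {
  gc5 <- fx_construct()
  fr <- fx_frames(10, noise = 4)
  # zero rate: pure noise
  m0 <- campbell_moments(gc5, fx_poisson_kinetics(0), fr)
  expect_equal(m0$mean, 0)
  expect_equal(m0$var, 16)
  expect_equal(m0$cov, 0)
  # no shared polymerases at lags beyond the residence time
  fr_long <- fx_frames(200)
  m_long <- campbell_moments(gc5, fx_poisson_kinetics(0.13), fr_long)
  expect_equal(m_long$cov, 0)
  # moments against direct quadrature of the kernel
  kern <- fx_kernel()
  m <- campbell_moments(gc5, fx_poisson_kinetics(0.13), fr)
  expect_equal(m$mean, 0.13 * kern$loop_integral)
  expect_equal(m$var, 0.13 * kern$loop_sq_integral + 16)
  # diploid doubles signal moments, not the noise
  md <- campbell_moments(gc5, fx_poisson_kinetics(0.13), fr, diploid = TRUE)
  expect_equal(md$mean, 2 * m$mean)
  expect_equal(md$var - 16, 2 * (m$var - 16))
  # non-constant kinetics are rejected with a pointer to simulation
  kin2 <- kinetic_params(initiation_discrete(c(0, 0.1), 100))
  expect_error(campbell_moments(gc5, kin2, fr), "simulation")
})

test_that("orthant probabilities match Monte Carlo sampling", {
  set.seed(31)
  for (rho in c(-0.6, 0, 0.45, 0.9)) {
    a <- -0.3; b <- 0.5
    n <- 4e5
    z1 <- rnorm(n)
    z2 <- rho * z1 + sqrt(1 - rho^2) * rnorm(n)
    p_mc <- mean(z1 > a & z2 > b)
    p <- msburst:::.bvn_upper(a, b, rho)
    expect_lt(abs(p - p_mc), 3 * sqrt(p_mc * (1 - p_mc) / n))
  }
  # independence factorizes exactly
  expect_equal(msburst:::.bvn_upper(0.2, -0.7, 0),
               pnorm(0.2, lower.tail = FALSE) * pnorm(-0.7,
                                                      lower.tail = FALSE),
               tolerance = 1e-8)
})

test_that("pulse statistics follow the two-frame disappearance logic", {
  mom <- frame_joint_moments(mean = 100, var = 400, cov = 0,
                             frame_interval_s = 10)
  ps <- pulse_statistics(mom, threshold = 100)
  # independent frames at the median threshold: p_off = 1/2, pulse = 2 dt
  expect_equal(ps$p_off, 0.5, tolerance = 1e-7)
  expect_equal(ps$mean_pulse_s, 20, tolerance = 1e-6)
  expect_equal(ps$spot_frequency, 0.5, tolerance = 1e-8)
  # raising the threshold shortens pulses monotonically
  mom2 <- frame_joint_moments(100, 400, 250, 10)
  pulses <- vapply(seq(60, 160, by = 10), function(th)
    pulse_statistics(mom2, th)$mean_pulse_s, numeric(1))
  expect_true(all(diff(pulses) <= 1e-9))
  # p_off and spot frequency are probabilities; pulses at least one frame
  sweep <- purrr::map_dfr(seq(40, 180, by = 20),
                          function(th) pulse_statistics(mom2, th))
  expect_true(all(sweep$p_off >= 0 & sweep$p_off <= 1))
  expect_true(all(sweep$spot_frequency >= 0 & sweep$spot_frequency <= 1))
  expect_true(all(sweep$mean_pulse_s >= 10))
  expect_error(pulse_statistics(frame_joint_moments(1, 0, 0, 10), 1),
               "degenerate")
  # near-zero mean triggers the Gaussian-validity warning
  expect_warning(pulse_statistics(frame_joint_moments(10, 400, 0, 10), 5),
                 "Gaussian")
})

test_that("theory predicts simulated pulse durations and spot fractions", {
  gc5 <- fx_construct()
  fr <- fx_frames(10, noise = 5)
  for (r in c(0.05, 0.13)) {
    tr <- simulate_trace(gc5, fx_poisson_kinetics(r), fr,
                         duration_s = 6e4, seed = 40 + round(100 * r))
    mom <- campbell_moments(gc5, fx_poisson_kinetics(r), fr)
    mu <- mom$mean
    for (th in c(mu - 0.5 * sqrt(mom$var), mu, mu + sqrt(mom$var))) {
      ps <- extract_pulses(tr, th)
      # low-rate sweeps sit near the flagged Gaussian-validity boundary
      th_stats <- suppressWarnings(pulse_statistics(mom, th))
      # spot frequency: binomial-ish s.e. with correlation-time inflation
      f_obs <- mean(tr$intensity > th)
      neff <- nrow(tr) / (fx_kernel()$release_time_s / 10)
      se_f <- sqrt(f_obs * (1 - f_obs) / neff)
      expect_lt(abs(f_obs - th_stats$spot_frequency), 3.5 * se_f)
      # mean pulse duration of uncensored pulses
      pd <- ps$duration_s[ps$type == "pulse" & !ps$censored]
      if (length(pd) > 30) {
        expect_lt(abs(mean(pd) - th_stats$mean_pulse_s),
                  3.5 * sd(pd) / sqrt(length(pd)))
      }
    }
  }
})

test_that("one-state contours are monotone in rate and never cross", {
  gc5 <- fx_construct()
  fr <- fx_frames(10, noise = 5)
  ct <- one_state_contours(gc5, rates = c(0.05, 0.1, 0.15), frames = fr,
                           thresholds = seq(50, 500, by = 50))
  wide_f <- tidyr::pivot_wider(ct[, c("rate", "threshold",
                                      "spot_frequency")],
                               names_from = "rate",
                               values_from = "spot_frequency")
  # at every threshold the faster gene has the higher spot frequency
  expect_true(all(wide_f[[2]] <= wide_f[[3]] & wide_f[[3]] <= wide_f[[4]]))
  # noise-only limit of the spot frequency at r -> 0
  ct0 <- one_state_contours(gc5, rates = 1e-12, frames = fr,
                            thresholds = 10)
  expect_equal(ct0$spot_frequency, pnorm(-10 / 5), tolerance = 1e-4)
})

test_that("two-state contours match at low threshold and deviate above", {
  gc5 <- fx_construct()
  fr <- fx_frames(10, noise = 5)
  set.seed(50)
  ths <- c(150, 300)
  ct2 <- two_state_contours(gc5, r_active = 0.13, frames = fr,
                            thresholds = ths,
                            target_spot_frequency = 0.93,
                            cycle_timescale_s = 2000,
                            n_cells = 8, duration_s = 4000, seed = 51)
  ct1 <- one_state_contours(gc5, rates = 0.13, frames = fr,
                            thresholds = ths)
  # a high target frequency forces a high duty cycle
  expect_gt(ct2$duty[1], 0.8)
  # matched at the lowest threshold by construction
  expect_lt(abs(ct2$spot_frequency[1] - 0.93), 0.03)
  # off periods depress the two-state frequency below the always-on gene:
  # the threshold sweep separates the models (the rejection logic)
  expect_lt(ct2$spot_frequency[1], ct1$spot_frequency[1])
  expect_lt(ct2$spot_frequency[2], ct1$spot_frequency[2])
  expect_error(
    two_state_contours(gc5, 0.13, fr, ths, target_spot_frequency = 1.2),
    "target_spot_frequency")
})
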