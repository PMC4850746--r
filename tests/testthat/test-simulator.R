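test_that("zero initiation rate gives an all-zero trace", {
  tr <- simulate_trace(fx_construct(), fx_poisson_kinetics(0), fx_frames(),
                       duration_s = 500, seed = 1)
  expect_true(all(tr$true_signal == 0))
  expect_true(all(tr$initiations == 0))
})

test_that("initiations are conserved: arrivals = releases + residents", {
  tr <- simulate_trace(fx_construct(),
                       kinetic_params(initiation_constant(0.1), 22, 65),
                       fx_frames(), duration_s = 3000, seed = 2,
                       burn_in_s = 0)
  ev <- attr(tr, "events")
  expect_true(all(ev$cum_initiations == ev$cum_releases + tr$resident))
})

test_that("identical seeds give bit-identical traces", {
  kin <- kinetic_params(initiation_discrete(c(0, 0.1), 300), 22, 65)
  a <- simulate_trace(fx_construct(), kin, fx_frames(noise = 5), 1000,
                      seed = 7)
  b <- simulate_trace(fx_construct(), kin, fx_frames(noise = 5), 1000,
                      seed = 7)
  expect_identical(a$intensity, b$intensity)
  expect_identical(attr(a, "events")$release_times,
                   attr(b, "events")$release_times)
})

test_that("steric exclusion caps the polymerase load", {
  # saturating initiation on a slow gene: occupancy bounded by G/footprint
  kin <- kinetic_params(initiation_constant(5), 5, 0, footprint_nt = 40)
  tr <- simulate_trace(fx_construct(), kin, fx_frames(), 500, seed = 3)
  expect_true(all(tr$resident <= 2500 / 40 + 1))
  # a footprint covering the whole gene admits one polymerase at a time
  kin1 <- kinetic_params(initiation_constant(5), 50, 0, footprint_nt = 2500)
  tr1 <- simulate_trace(fx_construct(), kin1, fx_frames(), 500, seed = 4)
  expect_true(all(tr1$resident <= 1))
})

test_that("one-state moments match Campbell's theorem (Poisson regime)", {
  r <- 0.13
  kern <- fx_kernel()
  tr <- simulate_trace(fx_construct(), fx_poisson_kinetics(r), fx_frames(),
                       duration_s = 1e5, seed = 5)
  n <- nrow(tr)
  m_obs <- mean(tr$true_signal)
  v_obs <- var(tr$true_signal)
  c_obs <- cov(tr$true_signal[-n], tr$true_signal[-1])
  # s.e. scaled by the intensity correlation time (~release / dt frames)
  neff <- n / (kern$release_time_s / 10)
  se_m <- sd(tr$true_signal) / sqrt(neff)
  expect_lt(abs(m_obs - r * kern$loop_integral), 3 * se_m)
  expect_lt(abs(v_obs - r * kern$loop_sq_integral),
            3 * v_obs * sqrt(2 / neff) * 2)
  expect_lt(abs(c_obs - r * kernel_cross_integral(kern, 10)),
            3 * v_obs * sqrt(2 / neff) * 2)
  expect_lt(abs(mean(tr$resident) - r * kern$release_time_s),
            3 * sd(tr$resident) / sqrt(neff))
})

test_that("discrete-state switching has the configured dwell structure", {
  # symmetric two-state gene spends half its time active
  tr <- simulate_trace(fx_construct(),
                       kinetic_params(initiation_discrete(c(0, 0.1), 100)),
                       fx_frames(), duration_s = 4e4, seed = 6)
  # ~400 dwells: binomial-ish s.e. of the active fraction ~0.025
  expect_lt(abs(mean(tr$gene_state == 2) - 0.5), 0.08)
  # state dwells are exponential with the preset 1176 s mean
  tr2 <- simulate_trace(fx_construct(),
                        kinetic_params(
                          initiation_discrete(c(0, 0.05, 0.1), 1176)),
                        fx_frames(30), duration_s = 3e5, seed = 7)
  runs <- rle(tr2$gene_state)
  dwell <- runs$lengths[-c(1, length(runs$lengths))] * 30
  expect_gt(length(dwell), 100)
  expect_lt(abs(mean(dwell) - 1176) / 1176, 0.15)
})

test_that("infinitely slow switching freezes the gene state", {
  tr <- simulate_discrete_state_trace(fx_construct(), c(0, 0.1),
                                      switching_timescale_s = 1e12,
                                      frames = fx_frames(),
                                      duration_s = 2000, seed = 8)
  expect_equal(length(unique(tr$gene_state)), 1L)
})

test_that("elongation fluctuation limits behave correctly", {
  # sparse gene, fast switching: bulk transit speed -> mean of the two speeds
  tr <- simulate_elongation_fluctuations(
    fx_construct(), "independent", 10, 30, switch_timescale_s = 5,
    initiation = initiation_constant(0.002), termination_s = 0,
    frames = fx_frames(), duration_s = 2e5, seed = 9)
  ev <- attr(tr, "events")
  expect_gt(length(ev$transit_times), 200)
  bulk <- 2500 / mean(ev$transit_times)
  expect_lt(abs(bulk - 20), 1.0)
  # global mode with near-instant switching matches a constant 20 nt/s gene
  tr_g <- simulate_elongation_fluctuations(
    fx_construct(), "global", 10, 30, switch_timescale_s = 1,
    initiation = initiation_constant(0.05), termination_s = 65,
    frames = fx_frames(), duration_s = 4e4, seed = 10, footprint_nt = 0)
  kern20 <- signal_kernel(fx_construct(), 20, 65)
  m <- mean(tr_g$true_signal)
  neff <- nrow(tr_g) / (kern20$release_time_s / 10)
  expect_lt(abs(m - 0.05 * kern20$loop_integral),
            3 * sd(tr_g$true_signal) / sqrt(neff) +
              0.02 * 0.05 * kern20$loop_integral)
})

test_that("continuum limits reduce to simpler models", {
  # drift frozen: the active rate is constant within a trace
  init <- initiation_continuum(k_on = 1, k_off = 0,
                               step_timescale_s = 1e12)
  tr <- simulate_continuum_trace(fx_construct(), init, fx_frames(), 2000,
                                 seed = 11, diploid = FALSE)
  expect_equal(length(unique(tr$rate)), 1L)
  # single ladder level, always on: matches the constant-rate model
  init2 <- initiation_continuum(k_on = 1, k_off = 0,
                                rate_levels = 0.1,
                                step_timescale_s = 1e6)
  tr2 <- simulate_trace(fx_construct(),
                        kinetic_params(init2, 22, 65, footprint_nt = 0),
                        fx_frames(), 4e4, seed = 12)
  kern <- fx_kernel()
  neff <- nrow(tr2) / (kern$release_time_s / 10)
  expect_lt(abs(mean(tr2$true_signal) - 0.1 * kern$loop_integral),
            3 * sd(tr2$true_signal) / sqrt(neff))
})

test_that("FRAP bleaching darkens existing loops only", {
  kin <- kinetic_params(initiation_constant(0.13), 22, 65)
  fe <- simulate_frap(fx_construct(), kin, fx_frames(), n_cells = 5,
                      recovery_s = 300, seed = 13)
  first <- fe[fe$time_s == min(fe$time_s), ]
  # just after the bleach only one frame of new synthesis is visible:
  # every resident polymerase can have added at most 10 s x 22 nt/s of
  # ramp, far below the ~460-loop stationary signal
  expect_lt(mean(first$fluorescence), 30)
  expect_true(all(first$fluorescence < 100))
  # no initiation after bleach: recovery stays at zero
  kin0 <- kinetic_params(initiation_constant(0), 22, 65)
  tr0 <- simulate_trace(fx_construct(), kin0, fx_frames(), 300, seed = 14,
                        bleach_time_s = 0, burn_in_s = 0)
  expect_true(all(tr0$intensity == 0))
})

test_that("cytoplasmic pools have the right stationary statistics", {
  # constant production: Poisson counts with mean rho * lifetime
  set.seed(15)
  rel <- lapply(1:400, function(i) sort(runif(rpois(1, 0.05 * 12000),
                                              0, 12000)))
  pool <- simulate_cytoplasmic_pool(rel, mrna_lifetime_s = 600,
                                    sample_time_s = 12000, seed = 16)
  expect_lt(abs(mean(pool$count) - 30), 3 * sqrt(30 / 400))
  expect_lt(abs(var(pool$count) / mean(pool$count) - 1), 0.25)
  # zero production
  pool0 <- simulate_cytoplasmic_pool(list(numeric(0), numeric(0)), 600,
                                     1000)
  expect_true(all(pool0$count == 0))
  # telegraph production is over-dispersed relative to Poisson
  kin_tel <- kinetic_params(initiation_discrete(c(0, 0.1), 1200), 22, 65)
  rel_t <- simulate_release_times(fx_construct(), kin_tel, n_cells = 300,
                                  duration_s = 12000, seed = 17,
                                  diploid = FALSE)
  pool_t <- simulate_cytoplasmic_pool(rel_t, 600, 12000, seed = 18)
  expect_gt(var(pool_t$count) / mean(pool_t$count), 1.5)
})
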