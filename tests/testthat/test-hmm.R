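test_that("joint state space enumerates and stays row-stochastic", {
  m <- hmm_model(0.05, diag(1), x = 5, sigma = 1, frame_interval_s = 10,
                 m_max = 2)
  ss <- build_state_space(m)
  expect_equal(ss$n_states, 3L)
  expect_true(all(ss$row_mass <= 1 + 1e-12))
  # transition rows are sub-stochastic only by the truncated Poisson tail
  expect_true(all(ss$row_mass >= ppois(2, 0.05 * 10) - 1e-12))
  # K = 3, D = 4, m_max = 8: 3 * 9^4 joint states
  A3 <- matrix(1 / 3, 3, 3)
  m3 <- hmm_model(c(0, 0.02, 0.05), A3, x = c(3, 7, 7, 5), sigma = 1,
                  frame_interval_s = 10, m_max = 8)
  ss3 <- build_state_space(m3)
  expect_equal(ss3$n_states, 3L * 9^4)
  expect_equal(nrow(ss3$states), 3L * 9^4)
  expect_error(build_state_space(m3, max_states = 100), "reduce")
  # ladder and free are identical topologies at K = 2
  expect_equal(topology_mask(2, "ladder"), topology_mask(2, "free"))
})

test_that("AIC parameter counts match hand counts per topology", {
  # K rates + free transition entries (row sums fixed) + 1 noise term
  hand <- list(
    ladder = c(`1` = 2, `2` = 5, `3` = 8, `4` = 11),
    jump1 = c(`1` = 2, `2` = 5, `3` = 10, `4` = 15),
    free = c(`1` = 2, `2` = 5, `3` = 10, `4` = 17))
  for (top in names(hand)) {
    for (K in 1:4) {
      expect_equal(msburst:::.n_free_params(K, top), hand[[top]][[K]],
                   info = paste(top, K))
    }
  }
})

test_that("forward likelihood equals brute-force path enumeration", {
  set.seed(80)
  for (rep in 1:5) {
    K <- sample(1:2, 1)
    D <- sample(1:2, 1)
    m_max <- sample(1:2, 1)
    rates <- sort(runif(K, 0, 0.08))
    A <- matrix(runif(K * K, 0.05, 1), K, K)
    A <- A / rowSums(A)
    x <- runif(D, 2, 8)
    model <- hmm_model(rates, A, x = x, sigma = runif(1, 1, 3),
                       frame_interval_s = 20, m_max = m_max,
                       topology = "free")
    I <- runif(3, 0, 10)
    ll_fb <- hmm_loglik(model, fx_trace(I, dt = 20))
    ll_bf <- fx_brute_loglik(I, model)
    expect_equal(ll_fb, ll_bf, tolerance = 1e-10)
  }
})

test_that("uninformative emissions make the likelihood rate-independent", {
  A <- matrix(c(0.9, 0.1, 0.2, 0.8), 2, 2, byrow = TRUE)
  tr <- fx_trace(c(1, 4, 2, 7, 3), dt = 20)
  # m_max far in the Poisson tail so truncation mass cannot differ
  m1 <- hmm_model(c(0.01, 0.04), A, x = 5, sigma = 1e5,
                  frame_interval_s = 20, m_max = 12, topology = "free")
  m2 <- hmm_model(c(0.02, 0.03), A, x = 5, sigma = 1e5,
                  frame_interval_s = 20, m_max = 12, topology = "free")
  expect_equal(hmm_loglik(m1, tr), hmm_loglik(m2, tr), tolerance = 1e-4)
})

test_that("true parameters dominate perturbed rates in likelihood", {
  gc5 <- fx_construct()
  dt <- 60
  fr <- frame_settings(dt, noise_sd = 15)
  x <- emission_weights(gc5, 22, 65, fr)
  wins <- 0
  for (s in 1:8) {
    tr <- simulate_traces(gc5, fx_poisson_kinetics(0.08), fr, 3600,
                          n_cells = 2, seed = 90 + s)
    mk <- function(r) hmm_model(r, diag(1), x, sigma = 30,
                                frame_interval_s = dt, m_max = 12)
    ll_true <- hmm_loglik(mk(0.08), tr)
    ll_hi <- hmm_loglik(mk(0.12), tr)
    ll_lo <- hmm_loglik(mk(0.04), tr)
    wins <- wins + (ll_true > ll_hi && ll_true > ll_lo)
  }
  expect_gte(wins, 7)
})

test_that("Baum-Welch is monotone and recovers a one-state rate", {
  gc5 <- fx_construct()
  dt <- 60
  fr <- frame_settings(dt, noise_sd = 15)
  x <- emission_weights(gc5, 22, 65, fr)
  tr <- simulate_traces(gc5, fx_poisson_kinetics(0.08), fr, 3600,
                        n_cells = 40, seed = 100)
  fit <- fit_hmm(tr, K = 1, x = x, frame_interval_s = dt,
                 topology = "free", m_max = 12, n_restarts = 2,
                 max_iter = 30, seed = 101)
  expect_true(all(diff(fit$ll_trace) > -1e-9 * (abs(fit$ll_trace[-1]) + 1)))
  expect_lt(abs(fit$model$rates - 0.08) / 0.08, 0.03)
  # restarts from different random points reach the same optimum
  fit2 <- fit_hmm(tr, K = 1, x = x, frame_interval_s = dt,
                  topology = "free", m_max = 12, n_restarts = 2,
                  max_iter = 30, seed = 999)
  expect_lt(abs(fit$loglik - fit2$loglik), 1e-3 * abs(fit$loglik))
})

test_that("likelihood is robust to doubling the count cap", {
  gc5 <- fx_construct()
  dt <- 60
  fr <- frame_settings(dt, noise_sd = 15)
  x <- emission_weights(gc5, 22, 65, fr)
  tr <- simulate_traces(gc5, fx_poisson_kinetics(0.05), fr, 1800,
                        n_cells = 3, seed = 102)
  # m_max at the 1e-6 tail criterion for rate 0.05/s, dt 60 s
  m_tail <- qpois(1 - 1e-6, 0.05 * dt)
  mk <- function(mm) hmm_model(0.05, diag(1), x, sigma = 25,
                               frame_interval_s = dt, m_max = mm)
  ll1 <- hmm_loglik(mk(m_tail), tr)
  ll2 <- hmm_loglik(mk(2 * m_tail), tr)
  expect_lt(abs(ll1 - ll2) / nrow(tr), 1e-6)
})

test_that("Gibbs marginals match exact smoothing marginals", {
  A <- matrix(c(0.8, 0.2, 0.3, 0.7), 2, 2, byrow = TRUE)
  model <- hmm_model(c(0.01, 0.05), A, x = 5, sigma = 2,
                     frame_interval_s = 20, m_max = 2, topology = "free")
  fit <- structure(list(model = model, loglik = 0), class = "burst_hmm")
  trc <- fx_trace(c(4.2, 9.1, 1.0), dt = 20)
  gs <- gibbs_sample(fit, trc, n_samples = 8000, burn_in = 500, thin = 1,
                     seed = 103)
  for (t in 1:3) {
    p_g <- mean(gs$gene_state[, t] == 2)
    p_ex <- fx_brute_marginal(trc$intensity, model, t, 2)
    # MC s.e. inflated for autocorrelation between sweeps
    expect_lt(abs(p_g - p_ex), 4 * sqrt(p_ex * (1 - p_ex) / 8000) * 3)
  }
  expect_true(all(gs$cumulative[, 3] >= gs$cumulative[, 1]))
})

test_that("noise-free identifiable counts are sampled exactly", {
  model <- hmm_model(0.05, diag(1), x = 10, sigma = 1e-3,
                     frame_interval_s = 20, m_max = 3)
  fit <- structure(list(model = model, loglik = 0), class = "burst_hmm")
  true_counts <- c(1, 0, 2, 1, 3)
  trc <- fx_trace(10 * true_counts, dt = 20)
  gs <- gibbs_sample(fit, trc, n_samples = 50, burn_in = 20, thin = 1,
                     seed = 104)
  expect_true(all(t(gs$counts) == true_counts))
})

test_that("rate-path estimation finds change points and plateaus", {
  # noiseless piecewise-constant counts: exact recovery of the two levels
  counts <- c(rep(2, 30), rep(8, 30))
  rp <- estimate_rate_path(counts, frame_interval_s = 10)
  expect_lte(nrow(rp$segments), 3)
  expect_equal(rp$segments$rate[1], 0.2, tolerance = 0.05)
  expect_equal(rp$segments$rate[nrow(rp$segments)], 0.8, tolerance = 0.05)
  jump <- which(abs(diff(rp$path$rate)) > 0.1)
  expect_equal(length(jump), 1L)
  expect_equal(jump, 30L, tolerance = 1)
  # constant-rate counts collapse to a single segment
  set.seed(105)
  rp2 <- estimate_rate_path(rpois(60, 3), frame_interval_s = 10)
  expect_lte(nrow(rp2$segments), 3)
  expect_lt(abs(mean(rp2$path$rate) - 0.3) / 0.3, 0.25)
})

test_that("rate ACF recovers a known telegraph timescale", {
  set.seed(106)
  # telegraph between two positive rates, dwell 200 s, dt 10 s
  sim_tel <- function(n) {
    st <- integer(n); st[1] <- 1
    for (i in 2:n) st[i] <- if (runif(1) < 1 / 20) 3 - st[i - 1] else
      st[i - 1]
    c(0.05, 0.25)[st]
  }
  rp <- dplyr::bind_rows(lapply(1:10, function(i)
    tibble::tibble(cell = i, time_s = (1:1000) * 10, rate = sim_tel(1000))))
  ra <- rate_autocorrelation(rp, max_lag_s = 600)
  # symmetric telegraph ACF decays as exp(-2 k t): 1/e at ~100 s
  expect_lt(abs(ra$timescale_s - 100) / 100, 0.3)
  expect_equal(ra$acf$rho[1], 1)
})

test_that("bursting statistics recover telegraph switching rates", {
  set.seed(107)
  k <- 1 / 300
  sim_onoff <- function(n, dt) {
    st <- logical(n); st[1] <- TRUE
    p <- 1 - exp(-k * dt)
    for (i in 2:n) st[i] <- if (runif(1) < p) !st[i - 1] else st[i - 1]
    ifelse(st, 0.2, 0)
  }
  rp <- dplyr::bind_rows(lapply(1:20, function(i)
    tibble::tibble(cell = i, time_s = (1:500) * 10,
                   rate = sim_onoff(500, 10))))
  bs <- bursting_statistics(rp, off_threshold = 0.01)
  expect_lt(abs(bs$k_on - k) / k, 0.15)
  expect_lt(abs(bs$k_off - k) / k, 0.15)
  # all-on path flags the undefined k_on
  rp_on <- tibble::tibble(cell = 1, time_s = (1:100) * 10, rate = 0.2)
  expect_warning(bursting_statistics(rp_on), "k_on undefined")
})
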