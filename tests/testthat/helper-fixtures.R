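# Shared fixtures: small constructs, kinetics and deterministic toy traces.

fx_construct <- function() construct_preset("five_prime")

fx_kernel <- function() signal_kernel(fx_construct(), 22, 65)

fx_frames <- function(dt = 10, noise = 0, thr = 0) {
  frame_settings(dt, noise_sd = noise, detection_threshold = thr)
}

# one-state kinetics without promoter exclusion (pure Poisson initiation,
# the regime in which the filtered-Poisson theory is exact)
fx_poisson_kinetics <- function(rate = 0.13) {
  kinetic_params(initiation_constant(rate), 22, 65, footprint_nt = 0)
}

# hand-built trace tibble from an intensity vector
fx_trace <- function(intensity, dt = 10, cell = 1) {
  out <- tibble::tibble(cell = cell,
                        frame = seq_along(intensity),
                        time_s = seq_along(intensity) * dt,
                        intensity = intensity)
  attr(out, "frame_interval_s") <- dt
  out
}

# brute-force joint likelihood of the two-layer HMM by path enumeration
# (independent of the forward implementation; tiny instances only)
fx_brute_loglik <- function(I, model) {
  K <- model$K
  B <- model$m_max + 1L
  D <- model$D
  Tn <- length(I)
  pois <- t(vapply(model$rates,
                   function(r) dpois(0:model$m_max,
                                     r * model$frame_interval_s),
                   numeric(B)))
  dim(pois) <- c(K, B)
  ncnt <- Tn + D - 1
  grid_g <- as.matrix(expand.grid(rep(list(seq_len(K)), Tn)))
  grid_n <- as.matrix(expand.grid(rep(list(0:(B - 1)), ncnt)))
  tot <- 0
  for (a in seq_len(nrow(grid_g))) {
    g <- grid_g[a, ]
    pg <- 1 / K
    if (Tn > 1) for (t in 2:Tn) pg <- pg * model$A[g[t - 1], g[t]]
    for (b in seq_len(nrow(grid_n))) {
      n <- grid_n[b, ]             # n[1..D-1] prefix (state g1), then frames
      pn <- pois[g[1], n[D] + 1]
      if (D > 1) for (j in 1:(D - 1)) pn <- pn * pois[g[1], n[j] + 1]
      if (Tn > 1) for (t in 2:Tn) pn <- pn * pois[g[t], n[D - 1 + t] + 1]
      pe <- 1
      for (t in seq_len(Tn)) {
        reg <- n[(D - 1 + t):t]    # m_1..m_D
        pe <- pe * dnorm(I[t], sum(model$x * reg), model$sigma)
      }
      tot <- tot + pg * pn * pe
    }
  }
  log(tot)
}

# exact posterior P(g_t = k) by the same enumeration
fx_brute_marginal <- function(I, model, t_q, k_q) {
  K <- model$K
  B <- model$m_max + 1L
  D <- model$D
  Tn <- length(I)
  pois <- t(vapply(model$rates,
                   function(r) dpois(0:model$m_max,
                                     r * model$frame_interval_s),
                   numeric(B)))
  dim(pois) <- c(K, B)
  grid_g <- as.matrix(expand.grid(rep(list(seq_len(K)), Tn)))
  grid_n <- as.matrix(expand.grid(rep(list(0:(B - 1)), Tn + D - 1)))
  tot <- 0; num <- 0
  for (a in seq_len(nrow(grid_g))) {
    g <- grid_g[a, ]
    pg <- 1 / K
    if (Tn > 1) for (t in 2:Tn) pg <- pg * model$A[g[t - 1], g[t]]
    for (b in seq_len(nrow(grid_n))) {
      n <- grid_n[b, ]
      pn <- pois[g[1], n[D] + 1]
      if (D > 1) for (j in 1:(D - 1)) pn <- pn * pois[g[1], n[j] + 1]
      if (Tn > 1) for (t in 2:Tn) pn <- pn * pois[g[t], n[D - 1 + t] + 1]
      pe <- 1
      for (t in seq_len(Tn)) {
        pe <- pe * dnorm(I[t], sum(model$x * n[(D - 1 + t):t]), model$sigma)
      }
      p <- pg * pn * pe
      tot <- tot + p
      if (g[t_q] == k_q) num <- num + p
    }
  }
  num / tot
}
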