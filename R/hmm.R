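#' Switching-topology masks for gene-state transitions
#'
#' `"ladder"` permits moves of at most one state per frame, `"jump1"` at
#' most two states, `"free"` is unconstrained.
#'
#' @param K Number of gene states.
#' @param topology `"ladder"`, `"jump1"` or `"free"`.
#' @return K x K logical matrix of allowed transitions.
#' @export
topology_mask <- function(K, topology = c("ladder", "jump1", "free")) {
  topology <- match.arg(topology)
  d <- abs(outer(seq_len(K), seq_len(K), "-"))
  switch(topology, ladder = d <= 1, jump1 = d <= 2, free = d >= 0)
}

.n_free_params <- function(K, topology) {
  if (K == 1) return(2L)  # one rate + noise
  mask <- topology_mask(K, topology)
  K + sum(rowSums(mask) - 1L) + 1L
}

# truncated (unnormalized) Poisson emission table, K x (m_max + 1)
.pois_table <- function(rates, dt, m_max) {
  tab <- t(vapply(rates, function(r) stats::dpois(0:m_max, r * dt),
                  numeric(m_max + 1)))
  dim(tab) <- c(length(rates), m_max + 1L)
  tab
}

# expected-intensity vector over register states, index i = m_1 + B m_2 + ...
.register_mu <- function(x, m_max) {
  B <- m_max + 1L
  mu <- 0
  for (j in seq_along(x)) {
    mj <- (0:(B^length(x) - 1)) %/% B^(j - 1) %% B
    mu <- mu + x[j] * mj
  }
  mu
}

#' Construct a two-layer HMM model
#'
#' @param rates Non-decreasing gene-state initiation rates (events/s);
#'   `rates[1]` may be 0 (off state).
#' @param A Row-stochastic K x K gene-state transition matrix (per frame);
#'   entries outside the topology must be 0.
#' @param x Emission weights: expected loops per polymerase by frame of
#'   initiation, from [emission_weights()].
#' @param sigma Measurement noise s.d. (loop units).
#' @param frame_interval_s Frame interval (s).
#' @param m_max Per-frame initiation count cap; defaults so the Poisson
#'   tail mass at the largest rate is below 1e-6.
#' @param topology Switching topology (see [topology_mask()]).
#' @return Object of class `hmm_model`.
#' @export
hmm_model <- function(rates, A = NULL, x, sigma, frame_interval_s,
                      m_max = NULL, topology = "free") {
  K <- length(rates)
  if (is.unsorted(rates)) stop("rates must be sorted non-decreasing")
  if (any(rates < 0)) stop("rates must be >= 0")
  if (is.null(A)) A <- diag(K)
  A <- as.matrix(A)
  if (!all(dim(A) == K)) stop("A must be K x K")
  if (max(abs(rowSums(A) - 1)) > 1e-8) stop("rows of A must sum to 1")
  if (any(A[!topology_mask(K, topology)] > 0)) {
    stop("A has transitions forbidden by the '", topology, "' topology")
  }
  if (sigma <= 0) stop("sigma must be > 0")
  if (is.null(m_max)) {
    m_max <- max(2L, stats::qpois(1 - 1e-6, max(rates) * frame_interval_s))
  }
  structure(list(K = K, rates = rates, A = A, x = x, sigma = sigma,
                 frame_interval_s = frame_interval_s,
                 m_max = as.integer(m_max), D = length(x),
                 topology = topology),
            class = "hmm_model")
}

#' Enumerate the joint state space of a two-layer HMM
#'
#' Expands the joint hidden states `(g, m_1..m_D)` and verifies the
#' factorized transition structure (gene state by `A`, register shift,
#' new count truncated-Poisson). Intended for inspection and for exact
#' small-instance computations; errors if the joint space exceeds
#' `max_states`.
#'
#' @param model An [hmm_model()].
#' @param max_states Size budget for `K * (m_max+1)^D`.
#' @return List: `states` tibble (`g`, `m_1`..`m_D`, `mu`), `n_states`,
#'   `B`, `D`, `pois` (emission-count table), `row_mass` (transition row
#'   sums; below 1 only by the truncated Poisson tail).
#' @export
build_state_space <- function(model, max_states = 4e6) {
  stopifnot(inherits(model, "hmm_model"))
  B <- model$m_max + 1L
  S <- B^model$D * model$K
  if (S > max_states) {
    stop("joint state space has ", S, " states (> ", max_states,
         "); reduce m_max or the horizon D")
  }
  reg <- as.matrix(expand.grid(rep(list(0:model$m_max), model$D)))
  colnames(reg) <- paste0("m_", seq_len(model$D))
  states <- tibble::as_tibble(reg[rep(seq_len(nrow(reg)), model$K), ,
                                  drop = FALSE])
  states$g <- rep(seq_len(model$K), each = nrow(reg))
  states$mu <- rep(as.vector(reg %*% model$x), model$K)
  pois <- .pois_table(model$rates, model$frame_interval_s, model$m_max)
  row_mass <- as.vector(model$A %*% rowSums(pois))
  list(states = states[, c("g", paste0("m_", seq_len(model$D)), "mu")],
       n_states = S, B = B, D = model$D, pois = pois, row_mass = row_mass)
}

.check_traces <- function(traces) {
  if (!all(c("cell", "intensity") %in% names(traces))) {
    stop("traces need 'cell' and 'intensity' columns")
  }
  if (any(!is.finite(traces$intensity))) stop("non-finite intensities")
  split(traces$intensity, traces$cell)
}

.fb_trace <- function(I, model, stats = FALSE) {
  B <- model$m_max + 1L
  pois <- .pois_table(model$rates, model$frame_interval_s, model$m_max)
  mu <- .register_mu(model$x, model$m_max)
  .hmm_fb(I, model$K, B, model$D, model$A, pois, mu, model$sigma,
          rep(1 / model$K, model$K), stats)
}

#' Log-likelihood of calibrated traces under a two-layer HMM
#'
#' Scaled forward algorithm over the joint (gene state, count register)
#' space, summed over cells (pooled fitting with shared parameters).
#'
#' @param model An [hmm_model()].
#' @param traces Tibble with `cell` and `intensity` (loop units).
#' @return Scalar log-likelihood.
#' @export
hmm_loglik <- function(model, traces) {
  sum(vapply(.check_traces(traces),
             function(I) .fb_trace(I, model, FALSE)$loglik, numeric(1)))
}

.random_init <- function(K, topology, x, dt, I, m_max) {
  r_top <- max(stats::quantile(I, 0.98), 1e-3) / (dt * sum(x))
  rates <- sort(stats::runif(K, 0, 1.3 * r_top))
  if (K > 1 && stats::runif(1) < 0.5) rates[1] <- 0
  mask <- topology_mask(K, topology)
  A <- matrix(0, K, K)
  for (i in seq_len(K)) {
    w <- stats::runif(K, 0.05, 1) * mask[i, ]
    w[i] <- w[i] + 3            # sticky diagonal
    A[i, ] <- w / sum(w)
  }
  sigma <- max(0.25 * stats::sd(I), 1e-3)
  hmm_model(rates, A, x, sigma, dt, m_max = m_max, topology = topology)
}

.em_once <- function(tracks, model, max_iter, tol) {
  ll_trace <- numeric(0)
  ll_old <- -Inf
  warn <- TRUE
  for (it in seq_len(max_iter)) {
    st <- lapply(tracks, function(I) .fb_trace(I, model, TRUE))
    ll <- sum(vapply(st, `[[`, numeric(1), "loglik"))
    ll_trace <- c(ll_trace, ll)
    occ <- Reduce(`+`, lapply(st, `[[`, "occ"))
    initsum <- Reduce(`+`, lapply(st, `[[`, "initsum"))
    trans <- Reduce(`+`, lapply(st, `[[`, "trans"))
    res2 <- sum(vapply(st, `[[`, numeric(1), "res2"))
    n_frames <- sum(lengths(tracks))
    new_rates <- ifelse(occ > 0, initsum / (occ * model$frame_interval_s),
                        model$rates)
    if (model$K > 1) {
      rs <- rowSums(trans)
      A <- model$A
      ok <- rs > 0
      A[ok, ] <- trans[ok, , drop = FALSE] / rs[ok]
      model$A <- A
    }
    model$rates <- pmax(new_rates, 0)
    model$sigma <- max(sqrt(res2 / n_frames), 1e-4)
    if (is.finite(ll_old) && abs(ll - ll_old) < tol * (abs(ll_old) + 1)) {
      warn <- FALSE
      break
    }
    ll_old <- ll
  }
  # final likelihood at the updated parameters
  ll_final <- sum(vapply(tracks, function(I)
    .fb_trace(I, model, FALSE)$loglik, numeric(1)))
  list(model = model, loglik = ll_final, ll_trace = c(ll_trace, ll_final),
       not_converged = warn, iterations = length(ll_trace))
}

.sort_states <- function(model) {
  o <- order(model$rates)
  model$rates <- model$rates[o]
  model$A <- model$A[o, o, drop = FALSE]
  model
}

#' Baum-Welch training of the two-layer HMM
#'
#' EM on the joint (gene state, count register) space: state initiation
#' rates from expected initiations per expected time in state, the
#' transition matrix from expected transition counts (masked by the
#' topology), the noise s.d. from expected squared residuals. The
#' likelihood is non-decreasing across iterations. Random restarts guard
#' against label swaps and local optima: each restart is run for
#' `restart_iter` iterations and only the best is then polished to
#' convergence; states are sorted by rate afterwards.
#'
#' @param traces Tibble with `cell`, `intensity` (loop units, calibrated).
#' @param K Number of gene states.
#' @param x Emission weights ([emission_weights()]).
#' @param frame_interval_s Frame interval (s).
#' @param topology Switching topology.
#' @param m_max Count cap (default from the data-scale rate guess).
#' @param n_restarts Seeded random restarts (default 5).
#' @param restart_iter Short-run iterations per restart before the best
#'   is polished.
#' @param max_iter,tol EM stopping rule (relative log-likelihood change).
#' @param seed Integer seed.
#' @return Object of class `burst_hmm`: the trained `hmm_model` plus
#'   `loglik`, `n_params`, `aic`, `ll_trace`, `not_converged`.
#' @export
fit_hmm <- function(traces, K, x, frame_interval_s,
                    topology = c("ladder", "jump1", "free"), m_max = NULL,
                    n_restarts = 5, restart_iter = 8, max_iter = 50,
                    tol = 1e-6, seed = 1L) {
  topology <- match.arg(topology)
  tracks <- .check_traces(traces)
  I_all <- unlist(tracks)
  if (is.null(m_max)) {
    r_top <- max(stats::quantile(I_all, 0.98), 1e-3) /
      (frame_interval_s * sum(x))
    m_max <- max(3L, stats::qpois(1 - 1e-6, 1.3 * r_top * frame_interval_s))
  }
  best <- NULL
  for (i in seq_len(n_restarts)) {
    set.seed(seed + 1000L * i)
    m0 <- .random_init(K, topology, x, frame_interval_s, I_all, m_max)
    fit <- .em_once(tracks, m0, min(restart_iter, max_iter), tol)
    if (is.null(best) || fit$loglik > best$loglik) best <- fit
  }
  # polish the winning restart to convergence
  if (max_iter > restart_iter) {
    polished <- .em_once(tracks, best$model,
                         max_iter - restart_iter, tol)
    polished$ll_trace <- c(best$ll_trace, polished$ll_trace)
    best <- polished
  }
  model <- .sort_states(best$model)
  structure(list(model = model, loglik = best$loglik,
                 n_params = .n_free_params(K, topology),
                 aic = 2 * .n_free_params(K, topology) - 2 * best$loglik,
                 ll_trace = best$ll_trace,
                 not_converged = best$not_converged,
                 n_frames = length(I_all), n_cells = length(tracks)),
            class = "burst_hmm")
}

#' @export
print.burst_hmm <- function(x, ...) {
  cat("<burst_hmm> K =", x$model$K, "(", x$model$topology, ")\n")
  cat("  rates (/s):", signif(x$model$rates, 3), "\n")
  cat("  sigma:", signif(x$model$sigma, 3), " logL:", round(x$loglik, 2),
      " AIC:", round(x$aic, 2), "\n")
  invisible(x)
}

#' Scan the number of gene states by AIC
#'
#' Trains models for K = 1..`K_max` and reports the AIC curve
#' (`2 p - 2 logL`), the selected K (argmin), and the AIC excess of the
#' 3-state model over the minimum (`delta_aic_3`), the complexity beyond
#' three states.
#'
#' @inheritParams fit_hmm
#' @param K_max Largest number of states tried.
#' @return Object of class `hmm_scan`: `table` tibble (`K`, `loglik`,
#'   `n_params`, `aic`), `models` list, `selected_K`, `delta_aic_3`.
#' @export
model_scan <- function(traces, K_max = 8, x, frame_interval_s,
                       topology = "ladder", m_max = NULL, n_restarts = 5,
                       restart_iter = 8, max_iter = 50, tol = 1e-6,
                       seed = 1L) {
  fits <- lapply(seq_len(K_max), function(K) {
    fit_hmm(traces, K, x, frame_interval_s, topology, m_max,
            n_restarts, restart_iter, max_iter, tol, seed + K)
  })
  tab <- tibble::tibble(
    K = seq_len(K_max),
    loglik = vapply(fits, `[[`, numeric(1), "loglik"),
    n_params = vapply(fits, `[[`, numeric(1), "n_params"),
    aic = vapply(fits, `[[`, numeric(1), "aic"))
  sel <- tab$K[which.min(tab$aic)]
  d3 <- if (K_max >= 3) tab$aic[3] - min(tab$aic) else NA_real_
  structure(list(table = tab, models = fits, selected_K = sel,
                 delta_aic_3 = d3), class = "hmm_scan")
}

#' Posterior distribution of initiations per frame, by gene state
#'
#' The forward-backward smoother yields the joint posterior of the gene
#' state and the current-frame initiation count; aggregating over frames
#' and cells gives the per-state count distribution, which for a faithful
#' discrete-state model should be (close to) Poisson. A chi-square
#' goodness-of-fit against the best Poisson is reported per state, along
#' with the variance/mean ratio (super-Poisson dispersion indicates rate
#' variation hidden within a state).
#'
#' @param fit A `burst_hmm` from [fit_hmm()].
#' @param traces Calibrated traces.
#' @return List of class `state_posteriors`: `distribution` tibble
#'   (`state`, `m`, `probability`), `gof` tibble (`state`, `mean`,
#'   `var_mean_ratio`, `chisq`, `dof`, `p_value`).
#' @export
state_polymerase_posteriors <- function(fit, traces) {
  stopifnot(inherits(fit, "burst_hmm"))
  tracks <- .check_traces(traces)
  st <- lapply(tracks, function(I) .fb_trace(I, fit$model, TRUE))
  cnt <- Reduce(`+`, lapply(st, `[[`, "cnt"))
  K <- fit$model$K
  if (any(rowSums(cnt) <= 0)) stop("a gene state has no posterior occupancy")
  dist <- purrr::map_dfr(seq_len(K), function(k) {
    tibble::tibble(state = k, m = 0:(ncol(cnt) - 1),
                   probability = cnt[k, ] / sum(cnt[k, ]))
  })
  gof <- purrr::map_dfr(seq_len(K), function(k) {
    w <- cnt[k, ]
    n_eff <- sum(w)
    m <- 0:(length(w) - 1)
    mean_k <- sum(w * m) / n_eff
    var_k <- sum(w * (m - mean_k)^2) / n_eff
    expd <- n_eff * stats::dpois(m, mean_k)
    expd[length(expd)] <- n_eff - sum(expd[-length(expd)])  # tail pooled
    # pool adjacent bins left to right until each has expected >= 5
    grp <- integer(length(expd))
    gid <- 1L; acc <- 0
    for (i in seq_along(expd)) {
      grp[i] <- gid
      acc <- acc + expd[i]
      if (acc >= 5 && i < length(expd)) { gid <- gid + 1L; acc <- 0 }
    }
    if (acc < 5 && gid > 1) grp[grp == gid] <- gid - 1L  # merge short tail
    obs_p <- tapply(w, grp, sum)
    exp_p <- tapply(expd, grp, sum)
    keep <- exp_p > 0
    chisq <- sum((obs_p[keep] - exp_p[keep])^2 / exp_p[keep])
    dof <- max(sum(keep) - 2L, 0L)
    tibble::tibble(state = k, mean = mean_k,
                   var_mean_ratio = if (mean_k > 0) var_k / mean_k else NA,
                   chisq = chisq, dof = dof,
                   p_value = if (dof > 0)
                     stats::pchisq(chisq, dof, lower.tail = FALSE) else NA)
  })
  structure(list(distribution = dist, gof = gof),
            class = "state_posteriors")
}

# forward-filter backward-sample of the gene path given counts
.ffbs_gene <- function(model, counts, prefix_counts) {
  K <- model$K
  T_ <- length(counts)
  pois <- .pois_table(model$rates, model$frame_interval_s, model$m_max)
  lem <- matrix(0, T_, K)
  for (g in seq_len(K)) {
    lem[, g] <- log(pmax(pois[g, counts + 1L], 1e-300))
    if (length(prefix_counts)) {
      lem[1, g] <- lem[1, g] +
        sum(log(pmax(pois[g, prefix_counts + 1L], 1e-300)))
    }
  }
  alpha <- matrix(0, T_, K)
  a <- rep(1 / K, K) * exp(lem[1, ] - max(lem[1, ]))
  alpha[1, ] <- a / sum(a)
  for (t in seq_len(T_)[-1]) {
    a <- (alpha[t - 1, ] %*% model$A)[1, ] * exp(lem[t, ] - max(lem[t, ]))
    alpha[t, ] <- a / sum(a)
  }
  g <- integer(T_)
  g[T_] <- sample.int(K, 1, prob = alpha[T_, ])
  for (t in rev(seq_len(T_ - 1))) {
    w <- alpha[t, ] * model$A[, g[t + 1]]
    g[t] <- sample.int(K, 1, prob = w)
  }
  g
}

#' Gibbs sampling of gene-state paths and initiation counts
#'
#' Alternates two exact block updates: (i) the per-frame initiation-count
#' register given the gene path, by forward-filter backward-sampling over
#' the count shift register with Gaussian emissions; (ii) the gene path
#' given the counts, by forward-filter backward-sampling over the K gene
#' states with truncated-Poisson count observations. A split-chain
#' potential-scale-reduction diagnostic on the total initiation count is
#' reported and a warning flag raised above 1.1.
#'
#' @param fit A `burst_hmm`.
#' @param trace Single-cell tibble with `intensity`.
#' @param n_samples Retained samples.
#' @param burn_in Discarded initial sweeps.
#' @param thin Keep every `thin`-th sweep.
#' @param seed Integer seed.
#' @return List of class `gibbs_samples`: `counts` (n_samples x T matrix),
#'   `gene_state` (matrix), `cumulative` (matrix), `rhat`,
#'   `not_converged`.
#' @export
gibbs_sample <- function(fit, trace, n_samples = 200, burn_in = 100,
                         thin = 2, seed = 1L) {
  stopifnot(inherits(fit, "burst_hmm"))
  model <- fit$model
  I <- trace$intensity
  if (any(!is.finite(I))) stop("non-finite intensities")
  set.seed(seed)
  T_ <- length(I)
  B <- model$m_max + 1L
  pois <- .pois_table(model$rates, model$frame_interval_s, model$m_max)
  mu <- .register_mu(model$x, model$m_max)
  g <- sample.int(model$K, T_, replace = TRUE)
  counts <- matrix(0L, n_samples, T_)
  genes <- matrix(0L, n_samples, T_)
  kept <- 0L
  sweeps <- burn_in + n_samples * thin
  for (s in seq_len(sweeps)) {
    reg <- .ffbs_counts(I, g - 1L, B, model$D, pois, mu, model$sigma)
    n_t <- reg %% B
    prefix <- if (model$D > 1) {
      (reg[1] %/% B^(seq_len(model$D - 1))) %% B
    } else integer(0)
    g <- .ffbs_gene(model, n_t, prefix)
    if (s > burn_in && (s - burn_in) %% thin == 0) {
      kept <- kept + 1L
      counts[kept, ] <- n_t
      genes[kept, ] <- g
    }
  }
  totals <- rowSums(counts)
  half <- floor(n_samples / 2)
  rhat <- if (half >= 10) {
    ch <- list(totals[seq_len(half)], totals[(half + 1):(2 * half)])
    W <- mean(vapply(ch, stats::var, numeric(1)))
    Bv <- half * stats::var(vapply(ch, mean, numeric(1)))
    if (W > 0) sqrt(((half - 1) / half * W + Bv / half) / W) else 1
  } else NA_real_
  out <- structure(list(
    counts = counts, gene_state = genes,
    cumulative = t(apply(counts, 1, cumsum)),
    rhat = rhat,
    not_converged = is.finite(rhat) && rhat > 1.1,
    frame_interval_s = model$frame_interval_s),
    class = "gibbs_samples")
  if (isTRUE(out$not_converged)) {
    warning("split-chain Rhat = ", round(rhat, 3),
            " > 1.1: Gibbs chain may not have converged", call. = FALSE)
  }
  out
}

#' Piecewise-constant initiation-rate path from posterior samples
#'
#' The initiation rate is the gradient of the cumulative initiation curve.
#' The posterior-mean per-frame initiation counts are converted to rates
#' and smoothed with an edge-preserving total-variation filter (piecewise-
#' constant output with sharp change points); the smoothing strength is
#' chosen per trace by a BIC-style criterion over a grid unless given.
#'
#' @param samples A `gibbs_samples` object, or a numeric vector of
#'   per-frame initiation counts.
#' @param frame_interval_s Frame interval (s) (taken from `samples` when
#'   available).
#' @param lambda Optional fixed smoothing strength (rate units).
#' @return List of class `rate_path`: `path` tibble (`frame`, `time_s`,
#'   `rate`), `segments` tibble (`start_s`, `end_s`, `duration_s`,
#'   `rate`), `lambda`.
#' @export
estimate_rate_path <- function(samples, frame_interval_s = NULL,
                               lambda = NULL) {
  if (inherits(samples, "gibbs_samples")) {
    y <- colMeans(samples$counts) / samples$frame_interval_s
    dt <- samples$frame_interval_s
  } else {
    if (is.null(frame_interval_s)) stop("frame_interval_s required")
    dt <- frame_interval_s
    y <- as.numeric(samples) / dt
  }
  T_ <- length(y)
  if (is.null(lambda)) {
    lams <- stats::sd(y) * c(0.25, 0.5, 1, 2, 4, 8) * sqrt(log(T_) / T_) * 4
    bic <- vapply(lams, function(l) {
      f <- .tv_denoise(y, l)
      k <- sum(abs(diff(f)) > 1e-9) + 1
      T_ * log(mean((y - f)^2) + 1e-12) + k * log(T_)
    }, numeric(1))
    lambda <- lams[which.min(bic)]
  }
  f <- .tv_denoise(y, lambda)
  r <- rle(cumsum(c(TRUE, abs(diff(f)) > 1e-9)))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  segs <- tibble::tibble(
    start_s = (starts - 1) * dt, end_s = ends * dt,
    duration_s = r$lengths * dt, rate = f[starts])
  structure(list(path = tibble::tibble(frame = seq_len(T_),
                                       time_s = seq_len(T_) * dt,
                                       rate = f),
                 segments = segs, lambda = lambda,
                 frame_interval_s = dt),
            class = "rate_path")
}

#' Autocorrelation of non-zero initiation rates
#'
#' Pools inferred rate paths across cells, restricts to frames with rate
#' above `active_floor`, and reports the normalized fluctuation ACF and
#' its 1/e decay timescale (linearly interpolated).
#'
#' @param rate_paths Tibble with `cell`, `time_s`, `rate` (stack
#'   `rate_path$path` results with a `cell` column).
#' @param max_lag_s Largest lag (s).
#' @param active_floor Rates at or below this count as inactive.
#' @return List of class `rate_acf`: `acf` tibble (`lag_s`, `rho`),
#'   `timescale_s`.
#' @export
rate_autocorrelation <- function(rate_paths, max_lag_s, active_floor = 0) {
  dt <- .frame_dt(rate_paths |>
                    dplyr::mutate(intensity = .data$rate))
  max_k <- floor(max_lag_s / dt)
  tracks <- split(rate_paths$rate, rate_paths$cell)
  act_mean <- mean(rate_paths$rate[rate_paths$rate > active_floor])
  if (!is.finite(act_mean)) stop("no active frames")
  num <- den <- numeric(max_k + 1)
  for (x in tracks) {
    pres <- x > active_floor
    xm <- x - act_mean
    for (k in 0:max_k) {
      i <- seq_len(length(x) - k)
      ok <- pres[i] & pres[i + k]
      num[k + 1] <- num[k + 1] + sum(xm[i][ok] * xm[i + k][ok])
      den[k + 1] <- den[k + 1] + sum(ok)
    }
  }
  if (den[1] == 0) stop("no active frames")
  C <- num / pmax(den, 1)
  rho <- C / C[1]
  below <- which(rho < exp(-1))[1]
  ts <- if (is.na(below)) NA_real_ else if (below == 1) 0 else {
    l1 <- (below - 2) * dt; l2 <- (below - 1) * dt
    r1 <- rho[below - 1]; r2 <- rho[below]
    l1 + (r1 - exp(-1)) / (r1 - r2) * (l2 - l1)
  }
  structure(list(acf = tibble::tibble(lag_s = (0:max_k) * dt, rho = rho),
                 timescale_s = ts),
            class = "rate_acf")
}

#' Bursting statistics from piecewise-constant rate paths
#'
#' Treats frames with rate below `off_threshold` as the closed (off)
#' state. Reports the switching rates `k_on` (off -> active transitions
#' per unit off time) and `k_off` (active -> off per unit active time),
#' the mean lifetime of constant-rate segments binned by rate, the
#' probability that the next segment has a higher vs lower rate as a
#' function of the current rate, and the crossover rate where those
#' probabilities are equal (linear interpolation between bins).
#'
#' @param rate_paths Tibble with `cell`, `time_s`, `rate`.
#' @param off_threshold Rates below this are "off" (events/s).
#' @param rate_breaks Bin edges for the active-rate axis (events/s).
#' @return List of class `bursting_stats`: `k_on`, `k_off`,
#'   `lifetimes` tibble, `switching` tibble (`rate_bin`, `p_up`,
#'   `p_down`), `crossover_rate`, `occupancy` tibble.
#' @export
bursting_statistics <- function(rate_paths, off_threshold = 0.01,
                                rate_breaks = seq(0, 0.5, by = 0.05)) {
  dt <- .frame_dt(rate_paths |> dplyr::mutate(intensity = .data$rate))
  cells <- split(rate_paths$rate, rate_paths$cell)
  on_off <- lapply(cells, function(x) x >= off_threshold)
  t_active <- sum(vapply(on_off, sum, numeric(1))) * dt
  t_off <- sum(vapply(on_off, function(a) sum(!a), numeric(1))) * dt
  n_to_off <- sum(vapply(on_off, function(a)
    sum(a[-length(a)] & !a[-1]), numeric(1)))
  n_to_on <- sum(vapply(on_off, function(a)
    sum(!a[-length(a)] & a[-1]), numeric(1)))
  k_off <- if (t_active > 0) n_to_off / t_active else NA_real_
  k_on <- if (t_off > 0) n_to_on / t_off else NA_real_
  if (t_off == 0) {
    warning("no off periods observed: k_on undefined", call. = FALSE)
  }
  segs <- purrr::map_dfr(names(cells), function(cl) {
    x <- cells[[cl]]
    r <- rle(x)
    tibble::tibble(cell = cl, rate = r$values,
                   duration_s = r$lengths * dt,
                   next_rate = c(r$values[-1], NA))
  })
  act <- segs[segs$rate >= off_threshold, ]
  act$bin <- cut(act$rate, rate_breaks, include.lowest = TRUE)
  lifetimes <- act |>
    dplyr::group_by(.data$bin) |>
    dplyr::summarise(rate_mid = mean(.data$rate),
                     mean_lifetime_s = mean(.data$duration_s),
                     n = dplyr::n(), .groups = "drop")
  sw <- act[!is.na(act$next_rate), ]
  switching <- sw |>
    dplyr::group_by(.data$bin) |>
    dplyr::summarise(rate_mid = mean(.data$rate),
                     p_up = mean(.data$next_rate > .data$rate),
                     p_down = mean(.data$next_rate < .data$rate),
                     n = dplyr::n(), .groups = "drop")
  cross <- NA_real_
  d <- switching$p_up - switching$p_down
  ok <- which(!is.na(d))
  if (length(ok) >= 2) {
    s <- d[ok]; rm_ <- switching$rate_mid[ok]
    flip <- which(s[-length(s)] > 0 & s[-1] <= 0)[1]
    if (!is.na(flip)) {
      i1 <- ok[flip]; i2 <- ok[flip + 1]
      cross <- rm_[flip] + d[i1] / (d[i1] - d[i2]) *
        (rm_[flip + 1] - rm_[flip])
    }
  }
  occupancy <- tibble::tibble(
    bin = levels(cut(act$rate, rate_breaks, include.lowest = TRUE)),
    time_frac = as.numeric(
      tapply(act$duration_s,
             cut(act$rate, rate_breaks, include.lowest = TRUE), sum,
             default = 0)) / max(t_active, 1e-12))
  occupancy$time_frac[is.na(occupancy$time_frac)] <- 0
  structure(list(k_on = k_on, k_off = k_off, lifetimes = lifetimes,
                 switching = switching, crossover_rate = cross,
                 occupancy = occupancy,
                 t_active_s = t_active, t_off_s = t_off),
            class = "bursting_stats")
}
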