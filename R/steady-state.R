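#' Negative-binomial fit to cytoplasmic mRNA counts
#'
#' Maximum-likelihood fit of the standard two-state bursting (negative
#' binomial) model to per-cell mRNA counts. Parameterization, recorded
#' explicitly to avoid convention drift: `P(X = k) ~ NB(size, prob)` with
#' mean `size (1 - prob) / prob`; `size` scales with the burst frequency
#' (bursts per mRNA lifetime) and the mean burst size is
#' `(1 - prob) / prob`. The mean MLE equals the sample mean, so only the
#' dispersion is optimized. Under-dispersed samples (variance < mean)
#' cannot be negative binomial: a Poisson fit is returned with
#' `poisson_fallback = TRUE`. A chi-square goodness-of-fit with bins
#' pooled to expected counts >= 5 is reported.
#'
#' @param counts Non-negative integer counts, `>= 200` values.
#' @return List of class `nb_fit`: `size`, `prob`, `mean`,
#'   `burst_size`, `loglik`, `chisq`, `dof`, `p_value`,
#'   `poisson_fallback`.
#' @export
fit_negative_binomial <- function(counts) {
  if (length(counts) < 200) stop("need >= 200 counts")
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be non-negative integers")
  }
  m <- mean(counts)
  v <- stats::var(counts)
  fallback <- v <= m
  if (!fallback) {
    nll <- function(ls) -sum(stats::dnbinom(counts, size = exp(ls),
                                            mu = m, log = TRUE))
    opt <- stats::optimize(nll, c(log(1e-3), log(1e4)))
    size <- exp(opt$minimum)
    # sizes at the upper search bound mean NB degenerates toward Poisson
    if (size > 0.99e4) fallback <- TRUE
  }
  if (fallback) {
    size <- Inf
    prob <- NA_real_
    ll <- sum(stats::dpois(counts, m, log = TRUE))
    dens <- function(k) stats::dpois(k, m)
    n_par <- 1L
  } else {
    prob <- size / (size + m)
    ll <- -nll(log(size))
    dens <- function(k) stats::dnbinom(k, size = size, mu = m)
    n_par <- 2L
  }
  kmax <- max(counts)
  expd <- length(counts) * dens(0:kmax)
  expd <- c(expd, length(counts) - sum(expd))   # upper tail
  obs <- c(tabulate(counts + 1L, nbins = kmax + 1L), 0)
  grp <- integer(length(expd)); gid <- 1L; acc <- 0
  for (i in seq_along(expd)) {
    grp[i] <- gid; acc <- acc + expd[i]
    if (acc >= 5 && i < length(expd)) { gid <- gid + 1L; acc <- 0 }
  }
  if (acc < 5 && gid > 1) grp[grp == gid] <- gid - 1L
  obs_p <- tapply(obs, grp, sum); exp_p <- tapply(expd, grp, sum)
  chisq <- sum((obs_p - exp_p)^2 / exp_p)
  dof <- max(length(obs_p) - 1L - n_par, 0L)
  structure(list(size = size, prob = prob, mean = m,
                 burst_size = if (fallback) NA_real_ else (1 - prob) / prob,
                 loglik = ll, chisq = chisq, dof = dof,
                 p_value = if (dof > 0)
                   stats::pchisq(chisq, dof, lower.tail = FALSE) else NA_real_,
                 poisson_fallback = fallback, n = length(counts)),
            class = "nb_fit")
}

#' @export
print.nb_fit <- function(x, ...) {
  if (x$poisson_fallback) {
    cat("<nb_fit> Poisson fallback (no over-dispersion), mean =",
        signif(x$mean, 4), "\n")
  } else {
    cat("<nb_fit> size =", signif(x$size, 4), " prob =", signif(x$prob, 4),
        " mean =", signif(x$mean, 4), " burst size =",
        signif(x$burst_size, 4), "\n")
  }
  cat("  GOF: chisq =", round(x$chisq, 2), "on", x$dof,
      "df, p =", signif(x$p_value, 3), "\n")
  invisible(x)
}

#' Contrast snapshot (smFISH-like) and live readouts of one gene model
#'
#' Runs the same generative model through both measurement channels:
#' (a) steady-state cytoplasmic counts (production events decayed with an
#' exponential mRNA lifetime), fit with the negative-binomial bursting
#' model; (b) live nascent-transcription traces, scanned for the number of
#' gene states by AIC. A continuum gene yields an adequate NB snapshot fit
#' while the live scan keeps improving beyond three states: the long
#' cytoplasmic lifetime averages out initiation-rate fluctuations that the
#' short nascent-RNA integration time resolves.
#'
#' @param construct A [gene_construct()].
#' @param kinetics A [kinetic_params()].
#' @param frames A [frame_settings()].
#' @param n_cells_snapshot Cells for the cytoplasmic count distribution.
#' @param n_cells_live,live_duration_s Live-trace ensemble size.
#' @param mrna_lifetime_s Cytoplasmic mRNA lifetime (default 40 min).
#' @param K_max,m_max,n_restarts Model-scan settings.
#' @param diploid Two gene copies per spot/cell.
#' @param seed Integer seed.
#' @param ... Passed to [simulate_traces()] for the live arm (e.g.
#'   `termination_deterministic`).
#' @return List of class `snapshot_contrast`: `nb` (an `nb_fit`), `scan`
#'   (an `hmm_scan`), `counts`, `selected_K`, `nb_adequate`
#'   (GOF not rejected at the 1% level).
#' @export
snapshot_vs_live_contrast <- function(construct, kinetics, frames,
                                      n_cells_snapshot = 2000,
                                      n_cells_live = 40,
                                      live_duration_s = 3600,
                                      mrna_lifetime_s = 2400,
                                      K_max = 5, m_max = 12, n_restarts = 3,
                                      diploid = TRUE, seed = 1L, ...) {
  sample_time <- 8 * mrna_lifetime_s
  rel <- simulate_release_times(construct, kinetics,
                                n_cells = n_cells_snapshot,
                                duration_s = sample_time, seed = seed,
                                diploid = diploid)
  pool <- simulate_cytoplasmic_pool(rel, mrna_lifetime_s, sample_time,
                                    seed = seed + 1L)
  nb <- fit_negative_binomial(pool$count)
  tr <- simulate_traces(construct, kinetics, frames, live_duration_s,
                        n_cells_live, seed = seed + 2L, diploid = diploid,
                        ...)
  x <- emission_weights(construct,
                        elongation_nt_per_s =
                          .mean_speed(kinetics$elongation),
                        termination_s = kinetics$termination_s, frames)
  sc <- model_scan(tr, K_max = K_max, x = x,
                   frame_interval_s = frames$frame_interval_s,
                   topology = "ladder", m_max = m_max,
                   n_restarts = n_restarts, seed = seed + 3L)
  structure(list(nb = nb, scan = sc, counts = pool,
                 selected_K = sc$selected_K,
                 nb_adequate = is.na(nb$p_value) || nb$p_value > 0.01),
            class = "snapshot_contrast")
}
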