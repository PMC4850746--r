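#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a trained two-layer HMM
#'
#' One row per gene state: initiation rate, stationary occupancy (from
#' the transition matrix) and self-transition probability.
#'
#' @param x A `burst_hmm`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.burst_hmm <- function(x, ...) {
  K <- x$model$K
  statd <- if (K == 1) 1 else {
    e <- eigen(t(x$model$A))
    v <- abs(Re(e$vectors[, which.max(Re(e$values))]))
    v / sum(v)
  }
  tibble::tibble(state = seq_len(K), rate = x$model$rates,
                 occupancy = statd, self_transition = diag(x$model$A))
}

#' @exportS3Method generics::glance
glance.burst_hmm <- function(x, ...) {
  tibble::tibble(K = x$model$K, topology = x$model$topology,
                 loglik = x$loglik, n_params = x$n_params, aic = x$aic,
                 sigma = x$model$sigma, n_frames = x$n_frames,
                 n_cells = x$n_cells, converged = !x$not_converged)
}

#' @exportS3Method generics::tidy
tidy.hmm_scan <- function(x, ...) x$table

#' @exportS3Method generics::glance
glance.hmm_scan <- function(x, ...) {
  tibble::tibble(selected_K = x$selected_K, delta_aic_3 = x$delta_aic_3,
                 K_max = max(x$table$K))
}

#' @exportS3Method generics::tidy
tidy.frap_fit <- function(x, ...) {
  tibble::tibble(term = c("elongation_nt_per_s", "termination_s"),
                 estimate = c(x$elongation_nt_per_s, x$termination_s))
}

#' @exportS3Method generics::glance
glance.frap_fit <- function(x, ...) {
  tibble::tibble(elongation_nt_per_s = x$elongation_nt_per_s,
                 termination_s = x$termination_s, rss = x$rss,
                 converged = x$convergence == 0)
}

#' @exportS3Method generics::tidy
tidy.nb_fit <- function(x, ...) {
  tibble::tibble(term = c("size", "prob", "mean", "burst_size"),
                 estimate = c(x$size, x$prob, x$mean, x$burst_size))
}

#' @exportS3Method generics::glance
glance.nb_fit <- function(x, ...) {
  tibble::tibble(mean = x$mean, size = x$size, loglik = x$loglik,
                 chisq = x$chisq, dof = x$dof, p_value = x$p_value,
                 poisson_fallback = x$poisson_fallback, n = x$n)
}

#' @exportS3Method generics::tidy
tidy.acf_decomposition <- function(x, ...) x$acf

#' @exportS3Method generics::glance
glance.acf_decomposition <- function(x, ...) {
  tibble::tibble(dwell_s = x$dwell_s, polymerase_load = x$polymerase_load,
                 noise_amplitude = x$noise_amplitude,
                 slow_intercept = x$slow_line[[1]],
                 slow_slope = x$slow_line[[2]])
}

#' @exportS3Method generics::tidy
tidy.exp_fit <- function(x, ...) {
  tibble::tibble(term = "rate", estimate = x$rate,
                 conf.low = x$ci[1], conf.high = x$ci[2])
}

#' @exportS3Method generics::glance
glance.exp_fit <- function(x, ...) {
  tibble::tibble(rate = x$rate, mean_s = x$mean_s,
                 n_uncensored = x$n_uncensored, n_censored = x$n_censored,
                 ks_p_value = x$ks_p_value, degenerate = x$degenerate)
}

#' @exportS3Method generics::tidy
tidy.bursting_stats <- function(x, ...) x$switching

#' @exportS3Method generics::glance
glance.bursting_stats <- function(x, ...) {
  tibble::tibble(k_on = x$k_on, k_off = x$k_off,
                 crossover_rate = x$crossover_rate,
                 t_active_s = x$t_active_s, t_off_s = x$t_off_s)
}
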