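.frame_dt <- function(trace) {
  dt <- attr(trace, "frame_interval_s")
  if (!is.null(dt)) return(dt)
  tm <- trace$time_s[trace$cell == trace$cell[1]]
  if (length(tm) < 2) stop("cannot infer frame interval from a 1-frame trace")
  stats::median(diff(tm))
}

#' Extract pulses and intervals from intensity traces
#'
#' A pulse is a maximal run of successive frames with intensity above the
#' detection threshold; intervals are the complementary runs. Intensities
#' exactly at the threshold count as below (deterministic tie-break). Runs
#' touching either end of a track are flagged censored: their true duration
#' is only known to be at least the observed one.
#'
#' @param trace Tibble with columns `cell`, `time_s`, `intensity` (e.g.
#'   from [simulate_trace()] or read from a delimited export).
#' @param threshold Detection threshold in trace units.
#' @return Tibble of class `pulse_set`: `cell`, `type` (`"pulse"` or
#'   `"interval"`), `start_time_s`, `duration_s`, `n_frames`, `censored`.
#' @export
extract_pulses <- function(trace, threshold) {
  if (!nrow(trace)) stop("empty trace")
  dt <- .frame_dt(trace)
  out <- trace |>
    dplyr::group_by(.data$cell) |>
    dplyr::group_modify(function(d, key) {
      r <- rle(d$intensity > threshold)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      tibble::tibble(
        type = ifelse(r$values, "pulse", "interval"),
        start_time_s = d$time_s[starts],
        n_frames = r$lengths,
        duration_s = r$lengths * dt,
        censored = seq_along(r$lengths) %in% c(1L, length(r$lengths)))
    }) |>
    dplyr::ungroup()
  attr(out, "threshold") <- threshold
  attr(out, "frame_interval_s") <- dt
  class(out) <- c("pulse_set", class(out))
  out
}

#' Censored maximum-likelihood exponential fit to duration tails
#'
#' Fits an exponential to durations at or above `min_duration_s` (default
#' two frames, below which frame discretization distorts the distribution).
#' Right-censored runs contribute survival terms. The closed-form MLE for
#' the left-truncated exponential is `rate = n_events / sum(t - L)`; the
#' confidence interval is the usual log-scale normal interval. A
#' goodness-of-fit p-value is computed by a Kolmogorov-Smirnov test on the
#' uncensored exceedances, with uniform within-frame jitter undoing the
#' frame quantization of the underlying continuous crossing times.
#'
#' @param pulses A `pulse_set` from [extract_pulses()].
#' @param type `"pulse"` or `"interval"` durations.
#' @param min_duration_s Tail cutoff L (s); defaults to 2 frames.
#' @param conf_level Confidence level for the rate CI.
#' @return List of class `exp_fit`: `rate` (1/s), `mean_s`, `ci`,
#'   `n_uncensored`, `n_censored`, `ks_p_value`, `degenerate`.
#' @export
fit_exponential_durations <- function(pulses, type = c("pulse", "interval"),
                                      min_duration_s = NULL,
                                      conf_level = 0.95) {
  type <- match.arg(type)
  dt <- attr(pulses, "frame_interval_s")
  if (is.null(min_duration_s)) min_duration_s <- 2 * dt
  d <- pulses[pulses$type == type & pulses$duration_s >= min_duration_s, ]
  unc <- d$duration_s[!d$censored] - min_duration_s
  cen <- d$duration_s[d$censored] - min_duration_s
  if (length(unc) < 20) {
    stop("need >= 20 uncensored durations above min_duration_s (have ",
         length(unc), ")")
  }
  tot <- sum(unc) + sum(cen)
  degenerate <- tot <= 0 || stats::sd(unc) == 0
  rate <- if (tot > 0) length(unc) / tot else Inf
  zq <- stats::qnorm(1 - (1 - conf_level) / 2)
  ci <- rate * exp(c(-1, 1) * zq / sqrt(length(unc)))
  ks_p <- if (degenerate) NA_real_ else {
    jit <- unc + stats::runif(length(unc), 0, dt)
    suppressWarnings(stats::ks.test(jit, "pexp", rate)$p.value)
  }
  structure(list(rate = rate, mean_s = 1 / rate, ci = ci,
                 n_uncensored = length(unc), n_censored = length(cen),
                 min_duration_s = min_duration_s,
                 ks_p_value = ks_p, degenerate = degenerate),
            class = "exp_fit")
}

#' Fluctuation autocorrelation of intensity traces
#'
#' Computes the normalized fluctuation autocorrelation
#' `G(tau) = <dI(t) dI(t+tau)> / <I>^2`, with per-track mean subtraction,
#' averaged over tracks and normalized by the squared pooled mean. With
#' `spot_present_only = TRUE` only frame pairs in which both frames exceed
#' the threshold enter, and the mean is taken over present frames (used to
#' show that slow decay persists within visibly active periods).
#'
#' @param trace Tibble with `cell`, `time_s`, `intensity`.
#' @param max_lag_s Largest lag (s) evaluated.
#' @param spot_present_only Restrict to above-threshold frame pairs.
#' @param threshold Detection threshold for `spot_present_only`.
#' @return Tibble of class `trace_acf`: `lag_s`, `G`, `se`, `n_pairs`.
#' @export
autocorrelate <- function(trace, max_lag_s, spot_present_only = FALSE,
                          threshold = 0) {
  dt <- .frame_dt(trace)
  max_k <- floor(max_lag_s / dt)
  tracks <- split(trace$intensity, trace$cell)
  if (any(vapply(tracks, length, 1L) < 20)) {
    stop("all tracks must have >= 20 frames")
  }
  mu <- if (spot_present_only) {
    mean(trace$intensity[trace$intensity > threshold])
  } else mean(trace$intensity)
  if (!is.finite(mu) || abs(mu) < .Machine$double.eps^0.5) {
    stop("trace mean is zero; fluctuation ACF undefined")
  }
  per_track <- lapply(tracks, function(x) {
    pres <- if (spot_present_only) x > threshold else rep(TRUE, length(x))
    xm <- x - mean(x[pres])
    vapply(0:max_k, function(k) {
      i <- seq_len(length(x) - k)
      ok <- pres[i] & pres[i + k]
      if (sum(ok) < 3) return(c(NA_real_, 0))
      c(mean(xm[i][ok] * xm[i + k][ok]), sum(ok))
    }, numeric(2))
  })
  cmat <- do.call(rbind, lapply(per_track, function(m) m[1, ]))
  nmat <- do.call(rbind, lapply(per_track, function(m) m[2, ]))
  w <- nmat / pmax(colSums(nmat), 1)[col(nmat)]
  G <- colSums(cmat * w, na.rm = TRUE) / mu^2
  se <- apply(cmat / mu^2, 2, function(x) {
    x <- x[is.finite(x)]
    if (length(x) > 1) stats::sd(x) / sqrt(length(x)) else NA_real_
  })
  out <- tibble::tibble(lag_s = (0:max_k) * dt, G = G, se = se,
                        n_pairs = colSums(nmat))
  attr(out, "mean_intensity") <- mu
  attr(out, "frame_interval_s") <- dt
  attr(out, "n_tracks") <- length(tracks)
  class(out) <- c("trace_acf", class(out))
  out
}

#' Decompose an intensity autocorrelation into noise, polymerase and slow parts
#'
#' Fits a line to `G(tau)` over a long-lag window (default
#' `[release + 2 dt, 2.2 release]`: beyond any single-RNA correlation, yet
#' short enough that a minutes-scale drift component is locally linear;
#' the default was fixed by recovery of the known polymerase load on
#' simulated ground truth), capturing slow initiation-rate fluctuations. Scanning downward from the
#' window start, the deviation point is the largest lag at which `G`
#' exceeds the extrapolated line by more than `criterion_se` standard
#' errors of the fit: this is the dwell-time estimate, since a single
#' nascent RNA correlates the signal out to its residence time. The
#' polymerase load is estimated from the zero-lag excess above the line
#' after removing the measurement-noise spike (confined to lag 0):
#' `load = shape_factor / G_dev(0)` with
#' `shape_factor = dwell * integral(L^2) / integral(L)^2` from the signal
#' kernel.
#'
#' @param acf_tbl A `trace_acf` from [autocorrelate()].
#' @param kernel_guess A [signal_kernel()] giving the expected kernel shape
#'   (window placement and shape factor only; the dwell itself is
#'   estimated from the data).
#' @param criterion_se Deviation criterion in units of the line-fit
#'   residual standard error (default 2).
#' @param window_s Optional explicit `c(lo, hi)` long-lag window (s).
#' @return List of class `acf_decomposition`: `dwell_s`, `polymerase_load`,
#'   `noise_amplitude`, `slow_line` (intercept, slope), `window_s`, and the
#'   annotated ACF table.
#' @export
decompose_acf <- function(acf_tbl, kernel_guess, criterion_se = 2,
                          window_s = NULL) {
  stopifnot(inherits(acf_tbl, "trace_acf"),
            inherits(kernel_guess, "signal_kernel"))
  dt <- attr(acf_tbl, "frame_interval_s")
  rel <- kernel_guess$release_time_s
  if (is.null(window_s)) window_s <- c(rel + 2 * dt, 2.2 * rel)
  if (max(acf_tbl$lag_s) < window_s[2]) {
    stop("ACF lag range must reach ", window_s[2],
         " s; recompute with a larger max_lag_s")
  }
  inw <- acf_tbl$lag_s >= window_s[1] & acf_tbl$lag_s <= window_s[2]
  fit <- stats::lm(G ~ lag_s, data = acf_tbl[inw, ])
  sigma_fit <- summary(fit)$sigma
  pred <- stats::predict(fit, newdata = acf_tbl)
  excess <- acf_tbl$G - pred
  below <- which(acf_tbl$lag_s < window_s[1] & acf_tbl$lag_s > 0)
  dev_idx <- rev(below)[which(excess[rev(below)] > criterion_se * sigma_fit)[1]]
  if (is.na(dev_idx) || !length(dev_idx)) {
    stop("no deviation from the long-timescale line detected: fast and ",
         "slow components are not separable in this ACF")
  }
  dwell <- acf_tbl$lag_s[dev_idx]
  # noise spike is confined to lag 0: extrapolate lags dt..3dt back to 0
  i13 <- which(acf_tbl$lag_s >= dt & acf_tbl$lag_s <= 3 * dt)
  ext0 <- stats::predict(stats::lm(ex ~ lag_s,
                                   data = data.frame(ex = excess[i13],
                                                     lag_s = acf_tbl$lag_s[i13])),
                         newdata = data.frame(lag_s = 0))
  noise_amp <- max(excess[acf_tbl$lag_s == 0] - ext0, 0)
  g_dev0 <- as.numeric(ext0)
  shape <- dwell * kernel_guess$loop_sq_integral / kernel_guess$loop_integral^2
  load <- if (g_dev0 > 0) as.numeric(shape / g_dev0) else NA_real_
  structure(list(dwell_s = dwell, polymerase_load = load,
                 noise_amplitude = as.numeric(noise_amp),
                 slow_line = stats::coef(fit), window_s = window_s,
                 sigma_fit = sigma_fit,
                 acf = dplyr::mutate(acf_tbl, slow_line = pred,
                                     excess = excess)),
            class = "acf_decomposition")
}

#' Quantile calibration of live intensities against smFISH loop counts
#'
#' Aligns the distribution of live transcription-spot intensities (a.u.)
#' with the distribution of smFISH nascent loop counts by matching
#' percentiles: the paired percentile values are calibration points and
#' isotonic regression enforces a monotone non-decreasing map. Outside the
#' central 5th-95th percentile range the map is extrapolated linearly from
#' a fit to the central segment, since the extreme percentiles of the two
#' measurement modalities deviate from a stable relationship.
#'
#' @param live_values Live spot intensities (a.u.), `>= 100` values.
#' @param fish_loop_counts smFISH loop counts, `>= 100` values.
#' @param probs Percentile grid (default 1st-99th).
#' @return List of class `calibration_curve`: `points` tibble
#'   (`percentile`, `live`, `loops`), `map` (vectorized function a.u. ->
#'   loops), `central_fit` (slope, intercept).
#' @export
quantile_calibrate <- function(live_values, fish_loop_counts,
                               probs = seq(0.01, 0.99, by = 0.01)) {
  if (length(live_values) < 100 || length(fish_loop_counts) < 100) {
    stop("both samples must have >= 100 values")
  }
  ql <- stats::quantile(live_values, probs, names = FALSE, type = 7)
  qf <- stats::quantile(fish_loop_counts, probs, names = FALSE, type = 7)
  iso <- stats::isoreg(ql, qf)
  loops <- iso$yf[order(order(ql))]
  keep <- !duplicated(ql)
  if (sum(keep) < 2) stop("live sample support too narrow to calibrate")
  central <- probs >= 0.05 & probs <= 0.95
  cfit <- stats::lm(loops ~ live,
                    data = data.frame(live = ql, loops = loops)[central, ])
  slope <- stats::coef(cfit)[["live"]]
  icept <- stats::coef(cfit)[["(Intercept)"]]
  lo <- min(ql); hi <- max(ql)
  core <- stats::approxfun(ql[keep], loops[keep], ties = mean, rule = 2)
  map <- function(x) {
    y <- core(pmin(pmax(x, lo), hi))
    y[x < lo] <- core(lo) + slope * (x[x < lo] - lo)
    y[x > hi] <- core(hi) + slope * (x[x > hi] - hi)
    y
  }
  structure(list(points = tibble::tibble(percentile = probs, live = ql,
                                         loops = loops),
                 map = map,
                 central_fit = c(slope = slope, intercept = icept),
                 range_live = c(lo, hi)),
            class = "calibration_curve")
}

#' Apply a calibration curve to a trace
#'
#' Maps per-frame intensities through the monotone calibration curve,
#' converting arbitrary units to loop units; frames outside the calibrated
#' range use linear extrapolation and are flagged.
#'
#' @param trace Tibble with an `intensity` column.
#' @param curve A [quantile_calibrate()] curve.
#' @return The trace with `intensity` in loop units, an `extrapolated`
#'   flag column, and the `units` attribute updated.
#' @export
apply_calibration <- function(trace, curve) {
  stopifnot(inherits(curve, "calibration_curve"))
  out <- dplyr::mutate(trace,
                       extrapolated = .data$intensity < curve$range_live[1] |
                         .data$intensity > curve$range_live[2],
                       intensity = curve$map(.data$intensity))
  attr(out, "units") <- "loops"
  attr(out, "frame_interval_s") <- attr(trace, "frame_interval_s")
  out
}
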