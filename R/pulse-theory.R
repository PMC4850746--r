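#' @importFrom stats pnorm dnorm integrate var cov acf
NULL

# Upper orthant probability P(X > a, Y > b) of a standard bivariate normal
# with correlation rho, by 1-D quadrature of phi(x) * Phi-bar((b - rho x) /
# sqrt(1 - rho^2)). Absolute tolerance 1e-8.
.bvn_upper <- function(a, b, rho) {
  if (abs(rho) >= 1 - 1e-12) {
    if (rho > 0) return(pnorm(max(a, b), lower.tail = FALSE))
    return(max(0, pnorm(a, lower.tail = FALSE) - pnorm(-b)))
  }
  s <- sqrt(1 - rho^2)
  integrate(function(x) dnorm(x) * pnorm((b - rho * x) / s, lower.tail = FALSE),
            a, Inf, rel.tol = 1e-10, abs.tol = 1e-10,
            subdivisions = 500L)$value
}

#' Frame-to-frame joint moments of a one-state gene (Campbell's theorem)
#'
#' For a constant (Poisson) initiation rate r, the spot intensity is a
#' filtered Poisson process with kernel `L`: its stationary moments follow
#' Campbell's theorem. The mean is `r * integral(L)`, the variance
#' `r * integral(L^2)` plus the measurement-noise variance, and the lag-dt
#' covariance `r * integral(L(t) L(t+dt))`. With `diploid = TRUE` the
#' signal contributions double (two independent gene copies in one spot);
#' the noise enters once. These moments neglect promoter-footprint
#' exclusion, which slightly thins initiation at high rates.
#'
#' @param construct A [gene_construct()].
#' @param kinetics A [kinetic_params()] with constant-rate initiation and
#'   constant elongation speed.
#' @param frames A [frame_settings()] (supplies the lag and noise s.d.).
#' @param diploid Sum two independent copies into one spot.
#' @return A list of class `frame_joint_moments` with `mean`, `var`,
#'   `cov` (lag one frame) and the pieces they were built from.
#' @export
campbell_moments <- function(construct, kinetics, frames, diploid = FALSE) {
  stopifnot(inherits(kinetics, "kinetic_params"),
            inherits(frames, "frame_settings"))
  if (kinetics$initiation$model != "constant") {
    stop("campbell_moments() applies to the one-state (constant-rate) ",
         "model only; use the simulation backend for multi-state or ",
         "continuum kinetics")
  }
  if (kinetics$elongation$mode != "constant") {
    stop("campbell_moments() requires a constant elongation speed")
  }
  r <- kinetics$initiation$rate
  kern <- signal_kernel(construct, kinetics$elongation$v,
                        kinetics$termination_s)
  copies <- if (diploid) 2 else 1
  structure(list(
    mean = copies * r * kern$loop_integral,
    var = copies * r * kern$loop_sq_integral + frames$noise_sd^2,
    cov = copies * r * kernel_cross_integral(kern, frames$frame_interval_s),
    noise_sd = frames$noise_sd, rate = r, copies = copies,
    frame_interval_s = frames$frame_interval_s, kernel = kern),
    class = "frame_joint_moments")
}

#' Build joint moments directly
#'
#' @param mean,var,cov Stationary mean, variance (noise included) and
#'   lag-one-frame covariance of the intensity.
#' @param frame_interval_s Frame interval (s).
#' @param noise_sd Measurement noise s.d. included in `var`.
#' @export
frame_joint_moments <- function(mean, var, cov, frame_interval_s,
                                noise_sd = 0) {
  if (var < abs(cov)) stop("variance must be >= |covariance|")
  if (var < noise_sd^2) stop("variance must include the noise variance")
  structure(list(mean = mean, var = var, cov = cov, noise_sd = noise_sd,
                 frame_interval_s = frame_interval_s),
            class = "frame_joint_moments")
}

#' Pulse statistics from the bivariate Gaussian pulsing theory
#'
#' Treats successive frame intensities as bivariate Gaussian with the given
#' moments. A spot is present when the intensity exceeds the detection
#' threshold. The probability that a visible spot disappears between one
#' frame and the next is `p_off = P(above then below) / P(above)`, giving a
#' geometric pulse-length distribution with mean pulse duration
#' `dt / p_off`; the mean interval is the analogous below-threshold
#' quantity. The Gaussian approximation degrades when the mean is within
#' ~3 s.d. of zero (intensity positivity skews the true law); a warning is
#' issued there.
#'
#' @param moments A `frame_joint_moments` object.
#' @param threshold Detection threshold, same units as the intensity.
#' @return One-row tibble: `threshold`, `spot_frequency`, `p_off`,
#'   `mean_pulse_s`, `mean_interval_s`.
#' @export
pulse_statistics <- function(moments, threshold) {
  stopifnot(inherits(moments, "frame_joint_moments"))
  s2 <- moments$var
  if (s2 <= 0) stop("degenerate (zero-variance) moments")
  s <- sqrt(s2)
  if (moments$mean < 3 * s && moments$mean > 0) {
    warning("mean intensity within 3 s.d. of zero: the Gaussian pulsing ",
            "theory is a poor approximation here", call. = FALSE)
  }
  rho <- moments$cov / s2
  z <- (threshold - moments$mean) / s
  p_above <- pnorm(z, lower.tail = FALSE)
  p_green <- .bvn_upper(z, z, rho)
  p_red <- max(p_above - p_green, 0)
  dt <- moments$frame_interval_s
  p_off <- if (p_above > 0) p_red / p_above else NA_real_
  p_on <- if (p_above < 1) p_red / (1 - p_above) else NA_real_
  tibble::tibble(
    threshold = threshold,
    spot_frequency = p_above,
    p_off = p_off,
    mean_pulse_s = dt / p_off,
    mean_interval_s = dt / p_on)
}

#' One-state theoretical contours of pulse duration and spot frequency
#'
#' For each initiation rate, sweeps the detection threshold and evaluates
#' the pulsing theory, producing the contour table against which
#' experimental or simulated threshold sweeps are overlaid.
#'
#' @param construct A [gene_construct()].
#' @param rates Vector of constant initiation rates (events/s).
#' @param frames A [frame_settings()].
#' @param thresholds Vector of detection thresholds (intensity units).
#' @param elongation_nt_per_s,termination_s Kinetic constants.
#' @param diploid Two gene copies per spot.
#' @return Tibble with columns `rate`, `threshold`, `spot_frequency`,
#'   `p_off`, `mean_pulse_s`, `mean_interval_s`.
#' @export
one_state_contours <- function(construct, rates, frames, thresholds,
                               elongation_nt_per_s = 22, termination_s = 65,
                               diploid = FALSE) {
  if (!length(rates) || !length(thresholds)) stop("grids must be non-empty")
  purrr::map_dfr(rates, function(r) {
    kin <- kinetic_params(initiation_constant(r), elongation_nt_per_s,
                          termination_s)
    mom <- campbell_moments(construct, kin, frames, diploid = diploid)
    out <- suppressWarnings(
      purrr::map_dfr(thresholds, function(th) pulse_statistics(mom, th)))
    dplyr::mutate(out, rate = r, .before = 1)
  })
}

#' Two-state contours with switching matched to a target spot frequency
#'
#' For each active-state rate, the telegraph on/off switching is chosen so
#' that the model's spot frequency at the lowest threshold matches
#' `target_spot_frequency` (matching at low threshold, as when comparing
#' against experimental sweeps); pulse statistics across thresholds are
#' then measured from simulated traces, since the Gaussian theory is not
#' conditional-state exact for a switching gene.
#'
#' @param construct A [gene_construct()].
#' @param r_active Vector of active-state initiation rates (events/s).
#' @param frames A [frame_settings()].
#' @param thresholds Threshold sweep; the lowest is the matching point.
#' @param target_spot_frequency Spot frequency to match at the lowest
#'   threshold, in (0, 1).
#' @param cycle_timescale_s Mean on + off cycle duration (s); the duty
#'   ratio is the optimized quantity.
#' @param n_cells,duration_s Simulation effort per evaluated parameter set.
#' @param seed Integer seed.
#' @param elongation_nt_per_s,termination_s Kinetic constants.
#' @return Tibble with `rate`, `duty`, `threshold`, `spot_frequency`,
#'   `mean_pulse_s`.
#' @export
two_state_contours <- function(construct, r_active, frames, thresholds,
                               target_spot_frequency, cycle_timescale_s = 600,
                               n_cells = 10, duration_s = 4000, seed = 1L,
                               elongation_nt_per_s = 22, termination_s = 65) {
  if (target_spot_frequency <= 0 || target_spot_frequency >= 1) {
    stop("target_spot_frequency must be in (0, 1)")
  }
  th0 <- min(thresholds)
  sim_sweep <- function(r, duty) {
    k_off <- 1 / (duty * cycle_timescale_s)
    k_on <- 1 / ((1 - duty) * cycle_timescale_s)
    Q <- matrix(c(-k_on, k_on, k_off, -k_off), 2, 2, byrow = TRUE)
    kin <- kinetic_params(initiation_discrete(c(0, r), Q = Q),
                          elongation_nt_per_s, termination_s)
    simulate_traces(construct, kin, frames, duration_s, n_cells, seed = seed)
  }
  purrr::map_dfr(r_active, function(r) {
    duties <- seq(0.1, 0.95, length.out = 8)
    freqs <- vapply(duties, function(d) {
      mean(sim_sweep(r, d)$intensity > th0)
    }, numeric(1))
    if (target_spot_frequency < min(freqs) ||
        target_spot_frequency > max(freqs)) {
      stop("target spot frequency infeasible for active rate ", r)
    }
    duty <- stats::approx(freqs, duties, xout = target_spot_frequency,
                          ties = mean)$y
    tr <- sim_sweep(r, duty)
    purrr::map_dfr(thresholds, function(th) {
      ps <- extract_pulses(tr, th)
      tibble::tibble(rate = r, duty = duty, threshold = th,
                     spot_frequency = mean(tr$intensity > th),
                     mean_pulse_s = mean(ps$duration_s[ps$type == "pulse" &
                                                         !ps$censored]))
    })
  })
}
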