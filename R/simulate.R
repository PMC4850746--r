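#' @useDynLib msburst, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import tibble
#' @importFrom rlang .data
#' @importFrom dplyr bind_rows mutate group_by summarise ungroup filter arrange n
#' @importFrom stats rnorm
NULL

.elong_mode_code <- function(elong) {
  switch(elong$mode, constant = 0L, two_speed_global = 1L,
         two_speed_independent = 2L,
         stop("unknown elongation mode: ", elong$mode))
}

.init_args <- function(init) {
  out <- list(init_type = 0L, init_rate = 0,
              state_rates = numeric(0), Q = matrix(0, 1, 1),
              k_on = 0, k_off = 0, levels = numeric(0),
              ladder_step_ts = 1, p_up = 0.5)
  if (init$model == "constant") {
    out$init_rate <- init$rate
  } else if (init$model == "discrete") {
    out$init_type <- 1L
    out$state_rates <- init$rates
    out$Q <- init$Q
  } else if (init$model == "continuum") {
    out$init_type <- 2L
    out$k_on <- init$k_on; out$k_off <- init$k_off
    out$levels <- init$rate_levels
    out$ladder_step_ts <- init$step_timescale_s
    out$p_up <- init$p_up
  } else stop("unknown initiation model: ", init$model)
  out
}

.mean_speed <- function(elong) {
  if (elong$mode == "constant") elong$v else (elong$v_low + elong$v_high) / 2
}

.sim_one_copy <- function(construct, kinetics, frames, n_frames, burn_in_s,
                          bleach_time_s, step_deterministic, record_events,
                          termination_deterministic) {
  ia <- .init_args(kinetics$initiation)
  el <- kinetics$elongation
  .sim_core(
    transcript_nt = as.integer(construct$transcript_length_nt),
    array_offset_nt = construct$array_offset_nt,
    array_length_nt = construct$array_length_nt,
    n_loops = construct$n_loops,
    footprint_nt = kinetics$footprint_nt,
    term_mean_s = kinetics$termination_s,
    elong_mode = .elong_mode_code(el),
    v_const = if (el$mode == "constant") el$v else 0,
    v_low = if (el$mode == "constant") el$v else el$v_low,
    v_high = if (el$mode == "constant") el$v else el$v_high,
    elong_switch_ts = if (el$mode == "constant") 1 else el$switch_timescale_s,
    step_deterministic = step_deterministic,
    init_type = ia$init_type, init_rate = ia$init_rate,
    state_rates = ia$state_rates, Q = ia$Q,
    k_on = ia$k_on, k_off = ia$k_off, levels = ia$levels,
    ladder_step_ts = ia$ladder_step_ts, p_up = ia$p_up,
    frame_interval_s = frames$frame_interval_s,
    n_frames = as.integer(n_frames), burn_in_s = burn_in_s,
    bleach_time_s = if (is.null(bleach_time_s)) Inf else bleach_time_s,
    record_events = record_events,
    term_deterministic = termination_deterministic)
}

#' Simulate one transcription-spot intensity trace
#'
#' Exact event-driven Monte Carlo of the MS2 system: polymerases initiate
#' with the current initiation rate (blocked while the promoter-proximal
#' footprint is occupied), elongate one nucleotide at a time with steric
#' exclusion, pause at the transcript end for an exponential termination
#' delay of the given mean, and then release. The true signal is the summed
#' loop signal of resident polymerases; the recorded intensity adds
#' Gaussian measurement noise.
#'
#' @param construct A [gene_construct()].
#' @param kinetics A [kinetic_params()].
#' @param frames A [frame_settings()].
#' @param duration_s Observed duration (s); the trace has
#'   `floor(duration_s / frame_interval_s)` frames.
#' @param seed Integer seed; identical seeds give identical traces.
#' @param cell Cell identifier stored in the output.
#' @param burn_in_s Unrecorded run-in (s) before the first frame, to reach
#'   polymerase-occupancy stationarity. Defaults to three RNA residence
#'   times at the mean elongation speed.
#' @param bleach_time_s Optional photobleach time (s, on the output time
#'   axis): all loops present go dark (the coat protein stays bound) and
#'   subsequent signal counts only loops synthesized later.
#' @param diploid If `TRUE`, two independent gene copies are summed into
#'   one spot (replicated sister loci resolved as a single spot); the
#'   reported gene state/rate is the sum of per-copy initiation rates.
#' @param step_deterministic If `TRUE`, per-nucleotide steps take exactly
#'   `1/v` instead of exponential waits with that mean.
#' @param termination_deterministic If `TRUE`, the post-elongation
#'   retention lasts exactly `termination_s` instead of an exponential
#'   delay with that mean; use this when benchmarking inference models
#'   that assume a hard release time.
#' @param record_events Keep per-event release/transit/initiation times in
#'   the `events` attribute.
#'
#' @return A tibble of class `sim_trace` with columns `cell`, `frame`,
#'   `time_s`, `intensity`, `true_signal`, `gene_state`, `rate`,
#'   `initiations`, `resident`, plus attributes `events` (release, transit
#'   and initiation times) and `units` (`"loops"`).
#' @export
simulate_trace <- function(construct, kinetics, frames, duration_s,
                           seed = NULL, cell = 1L, burn_in_s = NULL,
                           bleach_time_s = NULL, diploid = FALSE,
                           step_deterministic = FALSE,
                           termination_deterministic = FALSE,
                           record_events = TRUE) {
  if (duration_s <= 0) stop("duration_s must be > 0")
  stopifnot(inherits(construct, "gene_construct"),
            inherits(kinetics, "kinetic_params"),
            inherits(frames, "frame_settings"))
  if (!is.null(seed)) set.seed(seed)
  n_frames <- floor(duration_s / frames$frame_interval_s)
  if (n_frames < 1) stop("duration_s shorter than one frame interval")
  if (is.null(burn_in_s)) {
    burn_in_s <- 3 * (construct$transcript_length_nt /
                        .mean_speed(kinetics$elongation) +
                        kinetics$termination_s)
  }
  ncopies <- if (diploid) 2L else 1L
  sims <- lapply(seq_len(ncopies), function(i) {
    .sim_one_copy(construct, kinetics, frames, n_frames, burn_in_s,
                  bleach_time_s, step_deterministic, record_events,
                  termination_deterministic)
  })
  true_signal <- Reduce(`+`, lapply(sims, `[[`, "signal"))
  rate <- Reduce(`+`, lapply(sims, `[[`, "rate"))
  inits <- Reduce(`+`, lapply(sims, `[[`, "initiations"))
  noise <- if (frames$noise_sd > 0) rnorm(n_frames, 0, frames$noise_sd) else 0
  out <- tibble::tibble(
    cell = cell,
    frame = seq_len(n_frames),
    time_s = seq_len(n_frames) * frames$frame_interval_s,
    intensity = true_signal + noise,
    true_signal = true_signal,
    gene_state = sims[[1]]$state,
    rate = rate,
    initiations = inits,
    resident = Reduce(`+`, lapply(sims, `[[`, "resident")))
  attr(out, "events") <- list(
    release_times = sort(unlist(lapply(sims, `[[`, "release_times"))),
    transit_times = unlist(lapply(sims, `[[`, "transit_times")),
    init_times = sort(unlist(lapply(sims, `[[`, "init_times"))),
    cum_initiations = Reduce(`+`, lapply(sims, `[[`, "cum_initiations")),
    cum_releases = Reduce(`+`, lapply(sims, `[[`, "cum_releases")))
  attr(out, "units") <- "loops"
  attr(out, "frame_interval_s") <- frames$frame_interval_s
  class(out) <- c("sim_trace", class(out))
  out
}

#' Simulate an ensemble of traces
#'
#' Runs [simulate_trace()] for `n_cells` cells with per-cell seeds derived
#' deterministically from `seed`.
#'
#' @inheritParams simulate_trace
#' @param n_cells Number of independent cells.
#' @param ... Passed to [simulate_trace()].
#' @return A tibble with one row per cell and frame.
#' @export
simulate_traces <- function(construct, kinetics, frames, duration_s,
                            n_cells, seed = 1L, ...) {
  stopifnot(n_cells >= 1)
  res <- lapply(seq_len(n_cells), function(i) {
    simulate_trace(construct, kinetics, frames, duration_s,
                   seed = seed + 7919L * i, cell = i, ...)
  })
  out <- dplyr::bind_rows(res)
  attr(out, "units") <- "loops"
  attr(out, "frame_interval_s") <- frames$frame_interval_s
  attr(out, "events") <- lapply(res, attr, "events")
  out
}

#' Simulate a discrete multi-state trace
#'
#' Gene-state path is a continuous-time Markov chain over `rates`;
#' initiation is Poisson at the current state's rate.
#'
#' @inheritParams simulate_trace
#' @param rates Non-decreasing initiation rates of the K >= 2 states
#'   (events/s); the first may be 0 (off state).
#' @param switching_timescale_s Mean state dwell time (s); the preset used
#'   for slow well-separated switching is 1176 s.
#' @param ... Passed to [simulate_trace()].
#' @export
simulate_discrete_state_trace <- function(construct, rates,
                                          switching_timescale_s = 1176,
                                          frames, duration_s, seed = NULL,
                                          elongation_nt_per_s = 22,
                                          termination_s = 65, ...) {
  kin <- kinetic_params(
    initiation = initiation_discrete(rates, switching_timescale_s),
    elongation_nt_per_s = elongation_nt_per_s,
    termination_s = termination_s)
  simulate_trace(construct, kin, frames, duration_s, seed = seed, ...)
}

#' Simulate traces under fluctuating elongation speed
#'
#' The elongation speed telegraph-switches between `v_low` and `v_high`,
#' either globally (one shared speed) or independently per polymerase.
#' With independent fluctuations and steric exclusion, trailing polymerases
#' pile up behind slow leaders ("traffic jams") and the bulk transit speed
#' approaches `v_low` at experimental initiation densities.
#'
#' @inheritParams simulate_trace
#' @param mode `"global"` or `"independent"`.
#' @param v_low,v_high Telegraph speeds (nt/s).
#' @param switch_timescale_s Mean dwell (s) in each speed state.
#' @param initiation Initiation process (default: constant 0.13/s).
#' @param footprint_nt Polymerase exclusion length (nt).
#' @param ... Passed to [simulate_trace()].
#' @export
simulate_elongation_fluctuations <- function(construct,
                                             mode = c("global", "independent"),
                                             v_low = 10, v_high = 30,
                                             switch_timescale_s = 130,
                                             initiation = initiation_constant(0.13),
                                             termination_s = 65,
                                             footprint_nt = 40,
                                             frames, duration_s, seed = NULL,
                                             ...) {
  mode <- match.arg(mode)
  kin <- kinetic_params(
    initiation = initiation,
    elongation_nt_per_s = elongation_two_speed(v_low, v_high,
                                               switch_timescale_s, mode),
    termination_s = termination_s, footprint_nt = footprint_nt)
  simulate_trace(construct, kin, frames, duration_s, seed = seed, ...)
}

#' Simulate a continuum-model trace
#'
#' Off/on telegraph switching on a ~10 minute timescale; while on, the
#' initiation rate performs a reflecting random walk on a geometric ladder
#' of levels, producing a slowly drifting spectrum of initiation rates.
#' Defaults give a true-rate autocorrelation decay timescale of ~5-6 min
#' and a mean polymerase load in the 20s for a diploid spot.
#'
#' @inheritParams simulate_trace
#' @param initiation An [initiation_continuum()] process.
#' @param ... Passed to [simulate_trace()].
#' @export
simulate_continuum_trace <- function(construct,
                                     initiation = initiation_continuum(),
                                     frames, duration_s, seed = NULL,
                                     elongation_nt_per_s = 22,
                                     termination_s = 65, diploid = TRUE,
                                     ...) {
  stopifnot(inherits(initiation, "initiation_continuum"))
  kin <- kinetic_params(initiation = initiation,
                        elongation_nt_per_s = elongation_nt_per_s,
                        termination_s = termination_s)
  simulate_trace(construct, kin, frames, duration_s, seed = seed,
                 diploid = diploid, ...)
}

#' Simulate a FRAP experiment
#'
#' Each cell is simulated to stationarity, photobleached at time 0 of the
#' output axis (all loop fluorescence present goes dark; the coat protein
#' stays bound), and followed as fluorescence recovers through synthesis of
#' new loops. Recovery curves are returned unnormalized.
#'
#' @inheritParams simulate_trace
#' @param n_cells Number of bleached cells.
#' @param recovery_s Post-bleach observation time (s).
#' @param ... Passed to [simulate_trace()].
#' @return A tibble of class `frap_ensemble` with columns `cell`, `time_s`
#'   (since bleach) and `fluorescence`.
#' @export
simulate_frap <- function(construct, kinetics, frames, n_cells,
                          recovery_s = 400, seed = 1L, ...) {
  if (n_cells < 1) stop("n_cells must be >= 1")
  res <- lapply(seq_len(n_cells), function(i) {
    tr <- simulate_trace(construct, kinetics, frames, duration_s = recovery_s,
                         seed = seed + 104729L * i, cell = i,
                         bleach_time_s = 0, record_events = FALSE, ...)
    tibble::tibble(cell = i, time_s = tr$time_s, fluorescence = tr$intensity)
  })
  out <- dplyr::bind_rows(res)
  attr(out, "frame_interval_s") <- frames$frame_interval_s
  class(out) <- c("frap_ensemble", class(out))
  out
}

#' Release-time sequences from the initiation process alone
#'
#' For steady-state cytoplasmic pools only production times matter, so the
#' full elongation bookkeeping can be skipped: initiation events are drawn
#' from the (possibly fluctuating) initiation process and each transcript
#' is released one mean transit time later.
#'
#' @inheritParams simulate_trace
#' @param n_cells Number of independent cells.
#' @param duration_s Production window per cell (s).
#' @return List of per-cell release-time vectors.
#' @export
simulate_release_times <- function(construct, kinetics, n_cells, duration_s,
                                   seed = 1L, diploid = TRUE) {
  if (!is.null(seed)) set.seed(seed)
  ia <- .init_args(kinetics$initiation)
  transit <- construct$transcript_length_nt /
    .mean_speed(kinetics$elongation) + kinetics$termination_s
  ncopies <- if (diploid) 2L else 1L
  lapply(seq_len(n_cells), function(i) {
    ev <- unlist(lapply(seq_len(ncopies), function(k) {
      .sim_init_events(ia$init_type, ia$init_rate, ia$state_rates, ia$Q,
                       ia$k_on, ia$k_off, ia$levels, ia$ladder_step_ts,
                       ia$p_up, duration_s, burn_in_s = 0)
    }))
    sort(ev) + transit
  })
}

#' Sample steady-state cytoplasmic mRNA counts
#'
#' Each released transcript survives an independent exponential lifetime;
#' counts are taken per cell at `sample_time_s`. Sample at least ~5
#' lifetimes after the start of production so the pool is stationary.
#'
#' @param release_times List of per-cell release-time vectors (s), e.g.
#'   from [simulate_release_times()] or the `events` attribute of
#'   simulated traces.
#' @param mrna_lifetime_s Mean cytoplasmic lifetime (s); default 40 min.
#' @param sample_time_s Sampling time (s).
#' @param seed Integer seed.
#' @return A tibble with columns `cell` and `count`.
#' @export
simulate_cytoplasmic_pool <- function(release_times, mrna_lifetime_s = 2400,
                                      sample_time_s, seed = NULL) {
  if (mrna_lifetime_s <= 0) stop("mrna_lifetime_s must be > 0")
  if (!is.null(seed)) set.seed(seed)
  counts <- vapply(release_times, function(rt) {
    rt <- rt[rt <= sample_time_s]
    if (!length(rt)) return(0L)
    p_survive <- exp(-(sample_time_s - rt) / mrna_lifetime_s)
    sum(stats::rbinom(length(rt), 1L, p_survive))
  }, integer(1))
  tibble::tibble(cell = seq_along(release_times), count = counts)
}
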