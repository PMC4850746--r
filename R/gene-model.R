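#' Define the geometry of an MS2-tagged gene construct
#'
#' A construct records where the stem-loop array sits along the transcribed
#' region. Coordinates are 0-based distances (nt) from the transcription
#' start along the transcript; the model is strandless and sequence-free.
#'
#' @param name Label for the construct.
#' @param array_offset_nt Distance (nt) from the transcription start to the
#'   first loop of the array. Must be `>= 0`.
#' @param array_length_nt Length (nt) of the loop array. Must be `> 0`.
#' @param n_loops Number of stem loops in the array (`>= 1`).
#' @param transcript_length_nt Total transcribed length (nt); the array must
#'   fit inside it.
#'
#' @return An object of class `gene_construct`.
#' @seealso [construct_preset()] for the built-in constructs.
#' @export
#' @examples
#' gc <- gene_construct("five_prime", 21, 1300, 24, 2500)
#' loop_signal(gc, c(21, 671, 1321))
gene_construct <- function(name, array_offset_nt, array_length_nt, n_loops,
                           transcript_length_nt) {
  stopifnot(is.numeric(array_offset_nt), is.numeric(array_length_nt),
            is.numeric(n_loops), is.numeric(transcript_length_nt))
  if (array_offset_nt < 0) stop("array_offset_nt must be >= 0")
  if (array_length_nt <= 0) stop("array_length_nt must be > 0")
  if (n_loops < 1) stop("n_loops must be >= 1")
  if (array_offset_nt + array_length_nt > transcript_length_nt) {
    stop("loop array extends beyond the transcript ",
         "(array_offset_nt + array_length_nt > transcript_length_nt)")
  }
  structure(
    list(name = as.character(name),
         array_offset_nt = array_offset_nt,
         array_length_nt = array_length_nt,
         n_loops = n_loops,
         transcript_length_nt = transcript_length_nt),
    class = "gene_construct"
  )
}

#' @export
print.gene_construct <- function(x, ...) {
  cat("<gene_construct> ", x$name, "\n",
      "  loop array: ", x$n_loops, " loops over ",
      x$array_length_nt, " nt starting at +", x$array_offset_nt, "\n",
      "  transcript: ", x$transcript_length_nt, " nt\n", sep = "")
  invisible(x)
}

#' Built-in gene constructs
#'
#' Three insertion geometries of a 24-loop, 1.3 kb MS2 array into a strongly
#' expressed ~2.5 kb actin gene: at the 5' end of the coding region
#' (`"five_prime"`), replacing the coding region (`"gene_replacement"`), and
#' at the 3' end (`"three_prime"`). Coordinates follow the cloning
#' boundaries of the corresponding targeting vectors; the terminator length
#' is absorbed into a default 2.5 kb transcript for the 5' insertion.
#'
#' @param name One of `"five_prime"`, `"gene_replacement"`, `"three_prime"`.
#' @return A [gene_construct()].
#' @export
construct_preset <- function(name = c("five_prime", "gene_replacement",
                                      "three_prime")) {
  name <- match.arg(name)
  switch(name,
    five_prime = gene_construct("five_prime", 21, 1300, 24, 2500),
    # promoter fragment to +21, array, then the +1092..+1899 3' fragment
    gene_replacement = gene_construct("gene_replacement", 21, 1300, 24, 2130),
    # 5' coding fragment +259..+1113 (855 nt), array, then the 3' fragment
    three_prime = gene_construct("three_prime", 855, 1300, 24, 2960)
  )
}

#' Kinetic parameters of transcription
#'
#' Bundles the initiation-rate process, elongation speed(s), termination
#' delay and polymerase footprint used by the simulator, the pulsing theory
#' and the HMM emission model.
#'
#' @param initiation Initiation-rate process; one of [initiation_constant()],
#'   [initiation_discrete()], [initiation_continuum()].
#' @param elongation_nt_per_s Either a single speed v (nt/s), or a two-speed
#'   specification from [elongation_two_speed()].
#' @param termination_s Mean post-elongation retention delay (s) before the
#'   RNA is released from the gene.
#' @param footprint_nt Steric exclusion length of a polymerase (nt). A
#'   trailing polymerase can never approach a leader closer than this, and
#'   initiation is blocked while the promoter-proximal footprint is occupied.
#'   Default 40 nt, a typical Pol II footprint.
#'
#' @return An object of class `kinetic_params`.
#' @export
kinetic_params <- function(initiation = initiation_constant(0.13),
                           elongation_nt_per_s = 22,
                           termination_s = 65,
                           footprint_nt = 40) {
  if (termination_s < 0) stop("termination_s must be >= 0")
  if (footprint_nt < 0) stop("footprint_nt must be >= 0")
  if (!inherits(initiation, "initiation_process")) {
    stop("initiation must be built with initiation_constant(), ",
         "initiation_discrete() or initiation_continuum()")
  }
  if (is.numeric(elongation_nt_per_s)) {
    if (length(elongation_nt_per_s) != 1L || elongation_nt_per_s <= 0) {
      stop("elongation_nt_per_s must be a single positive speed or an ",
           "elongation_two_speed() specification")
    }
    elong <- list(mode = "constant", v = elongation_nt_per_s)
  } else if (inherits(elongation_nt_per_s, "elongation_two_speed")) {
    elong <- unclass(elongation_nt_per_s)
  } else {
    stop("invalid elongation specification")
  }
  structure(list(initiation = initiation, elongation = elong,
                 termination_s = termination_s, footprint_nt = footprint_nt),
            class = "kinetic_params")
}

#' Two-speed (telegraph) elongation specification
#'
#' The elongation speed switches between `v_low` and `v_high` with
#' exponential dwell of mean `switch_timescale_s` in each speed. In
#' `"global"` mode one shared speed state affects every polymerase on the
#' gene; in `"independent"` mode each polymerase carries its own telegraph
#' state (with steric exclusion a trailing polymerase still never passes a
#' leader, producing polymerase traffic jams behind slow leaders).
#'
#' @param v_low,v_high Low and high speeds (nt/s), `v_low <= v_high`.
#' @param switch_timescale_s Mean dwell time (s) in each speed state.
#' @param mode `"global"` or `"independent"`.
#' @export
elongation_two_speed <- function(v_low = 10, v_high = 30,
                                 switch_timescale_s = 130,
                                 mode = c("global", "independent")) {
  mode <- match.arg(mode)
  if (v_low <= 0 || v_high <= 0) stop("speeds must be positive")
  if (v_low > v_high) stop("v_low must be <= v_high")
  if (switch_timescale_s <= 0) stop("switch_timescale_s must be > 0")
  structure(list(mode = paste0("two_speed_", mode), v_low = v_low,
                 v_high = v_high, switch_timescale_s = switch_timescale_s),
            class = "elongation_two_speed")
}

#' Initiation-rate processes
#'
#' `initiation_constant()` is the one-state (Poisson) model: polymerases
#' initiate with constant probability per unit time. `initiation_discrete()`
#' is a K-state continuous-time Markov chain over initiation rates
#' `rates[1..K]` (rate 0 allowed as an off state); the gene dwells in a
#' state for an exponential time of mean `switch_timescale_s` and then jumps
#' to one of the other states uniformly, unless an explicit generator matrix
#' `Q` is supplied. `initiation_continuum()` is an off/on telegraph
#' (`k_on`, `k_off` per second) where, while on, the rate performs a
#' reflecting random walk on a geometric ladder of levels with steps at rate
#' `1/step_timescale_s` (upward with probability `p_up`).
#'
#' @param rate Constant initiation rate (events/s).
#' @param rates Non-decreasing vector of state initiation rates (events/s).
#' @param switch_timescale_s Mean state dwell time (s).
#' @param Q Optional K x K generator matrix (rows sum to 0) overriding the
#'   uniform-jump parameterization.
#' @param k_on,k_off Telegraph rates (per s) from off to on and back.
#' @param rate_levels Ladder of active-state initiation rates (events/s),
#'   strictly increasing.
#' @param step_timescale_s Mean time (s) between ladder steps while active.
#' @param p_up Probability that a ladder step is upward (0.5 = unbiased).
#' @name initiation
NULL

#' @rdname initiation
#' @export
initiation_constant <- function(rate) {
  if (rate < 0) stop("rate must be >= 0")
  structure(list(model = "constant", rate = rate),
            class = c("initiation_constant", "initiation_process"))
}

#' @rdname initiation
#' @export
initiation_discrete <- function(rates, switch_timescale_s = 1176, Q = NULL) {
  if (is.unsorted(rates)) stop("rates must be sorted non-decreasing")
  if (any(rates < 0)) stop("rates must be >= 0")
  K <- length(rates)
  if (K < 2) stop("discrete model needs K >= 2 states")
  if (is.null(Q)) {
    if (switch_timescale_s <= 0) stop("switch_timescale_s must be > 0")
    Q <- matrix(1 / (switch_timescale_s * (K - 1)), K, K)
    diag(Q) <- -1 / switch_timescale_s
  } else {
    Q <- as.matrix(Q)
    if (!all(dim(Q) == K)) stop("Q must be K x K")
    if (max(abs(rowSums(Q))) > 1e-8) stop("rows of Q must sum to 0")
    if (any(Q - diag(diag(Q)) < 0)) stop("off-diagonal of Q must be >= 0")
  }
  structure(list(model = "discrete", rates = rates, Q = Q),
            class = c("initiation_discrete", "initiation_process"))
}

#' @rdname initiation
#' @export
initiation_continuum <- function(k_on = 1 / 600, k_off = 1 / 600,
                                 rate_levels = continuum_rate_ladder(),
                                 step_timescale_s = 60, p_up = 0.5) {
  if (k_on < 0 || k_off < 0) stop("telegraph rates must be >= 0")
  if (any(diff(rate_levels) <= 0)) stop("rate_levels must be increasing")
  if (any(rate_levels < 0)) stop("rate_levels must be >= 0")
  if (step_timescale_s <= 0) stop("step_timescale_s must be > 0")
  if (p_up < 0 || p_up > 1) stop("p_up must be in [0, 1]")
  structure(list(model = "continuum", k_on = k_on, k_off = k_off,
                 rate_levels = rate_levels,
                 step_timescale_s = step_timescale_s, p_up = p_up),
            class = c("initiation_continuum", "initiation_process"))
}

#' Default geometric ladder of active-state initiation rates
#'
#' Twelve geometrically spaced levels whose stationary mean (the reflecting
#' unbiased walk is uniform over levels) is ~0.13 initiations/s, matching
#' the polymerase load of ~20-27 RNAs per spot implied by the
#' autocorrelation analysis at a ~180 s dwell time.
#'
#' @param n_levels Number of ladder levels.
#' @param r_min,r_max Lowest and highest active rates (events/s).
#' @export
continuum_rate_ladder <- function(n_levels = 12, r_min = 0.06, r_max = 0.22) {
  exp(seq(log(r_min), log(r_max), length.out = n_levels))
}

#' Imaging frame settings
#'
#' @param frame_interval_s Frame interval (s). There is no meaningful
#'   default: the interval is an imaging choice and must be supplied.
#' @param noise_sd Additive Gaussian measurement noise s.d., in the same
#'   units as the intensity (loop units once calibrated).
#' @param detection_threshold Spot-detection threshold, same units.
#' @export
frame_settings <- function(frame_interval_s, noise_sd = 0,
                           detection_threshold = 0) {
  if (frame_interval_s <= 0) stop("frame_interval_s must be > 0")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  structure(list(frame_interval_s = frame_interval_s, noise_sd = noise_sd,
                 detection_threshold = detection_threshold),
            class = "frame_settings")
}

#' Nascent loop signal of a polymerase at a given position
#'
#' The expected fluorescent signal (in loop units) contributed by a single
#' polymerase whose active site is at `position_nt`. The signal is a
#' continuous linear ramp: 0 before the array, rising linearly to `n_loops`
#' across the array, and `n_loops` afterwards. A continuous ramp (rather
#' than a staircase per completed loop) matches the continuous-intensity
#' Gaussian pulsing theory and differs from the staircase by under one loop.
#'
#' @param construct A [gene_construct()].
#' @param position_nt Position(s) along the transcript (nt); must lie in
#'   `[0, transcript_length_nt]`.
#' @return Signal in loop units, clamped to `[0, n_loops]`.
#' @export
loop_signal <- function(construct, position_nt) {
  stopifnot(inherits(construct, "gene_construct"))
  if (any(position_nt < 0 | position_nt > construct$transcript_length_nt)) {
    stop("position_nt outside [0, transcript_length_nt]: caller bug")
  }
  frac <- (position_nt - construct$array_offset_nt) / construct$array_length_nt
  construct$n_loops * pmin(pmax(frac, 0), 1)
}

#' Deterministic signal kernel of one polymerase over its residence
#'
#' For constant elongation speed `v` and mean termination delay
#' `termination_s`, returns the expected loop signal `L(age)` of a single
#' polymerase as a function of its age since initiation, together with
#' closed-form integrals of the kernel. `L` ramps up as the array is
#' transcribed, stays at `n_loops` while the polymerase transcribes the rest
#' of the gene and during termination, and is 0 at and after
#' `release_time_s = transcript_length/v + termination_s` (the termination
#' delay enters the kernel at its mean; the simulator draws it
#' exponentially).
#'
#' @param construct A [gene_construct()].
#' @param elongation_nt_per_s Constant elongation speed v (nt/s).
#' @param termination_s Termination delay (s).
#' @return A list of class `signal_kernel` with elements `L` (vectorized
#'   function of age in s), `L_int` (closed-form running integral of `L`),
#'   `release_time_s`, `synthesis_time_s`, `loop_integral` (= integral of L
#'   dt, loop.s), `loop_sq_integral` (= integral of L^2 dt), and the
#'   construct and kinetic constants used.
#' @export
signal_kernel <- function(construct, elongation_nt_per_s = 22,
                          termination_s = 65) {
  stopifnot(inherits(construct, "gene_construct"))
  v <- elongation_nt_per_s
  if (v <= 0) stop("elongation speed must be > 0")
  n <- construct$n_loops
  ta <- construct$array_offset_nt / v                      # ramp start (s)
  tb <- (construct$array_offset_nt + construct$array_length_nt) / v
  ts <- construct$transcript_length_nt / v                 # synthesis end
  tr <- ts + termination_s                                 # release
  L <- function(age_s) {
    out <- n * pmin(pmax((age_s - ta) / (tb - ta), 0), 1)
    out[age_s >= tr | age_s < 0] <- 0
    out
  }
  # running integral of L (valid on [0, release_time]; constant after)
  L_int <- function(age_s) {
    t0 <- pmin(age_s, tr)
    ramp <- pmin(pmax(t0, ta), tb)
    n * (ramp - ta)^2 / (2 * (tb - ta)) + n * pmax(t0 - tb, 0)
  }
  loop_integral <- n * (tb - ta) / 2 + n * (tr - tb)
  loop_sq_integral <- n^2 * (tb - ta) / 3 + n^2 * (tr - tb)
  structure(list(L = L, L_int = L_int,
                 release_time_s = tr, synthesis_time_s = ts,
                 ramp_start_s = ta, ramp_end_s = tb,
                 loop_integral = loop_integral,
                 loop_sq_integral = loop_sq_integral,
                 n_loops = n, construct = construct,
                 elongation_nt_per_s = v, termination_s = termination_s),
            class = "signal_kernel")
}

#' Lagged self-overlap integral of the signal kernel
#'
#' Computes `integral of L(t) L(t + lag) dt`, the kernel cross-product that
#' sets the frame-to-frame covariance of a one-state gene (Campbell's
#' theorem). Evaluated by adaptive quadrature on the piecewise-linear
#' kernel.
#'
#' @param kernel A [signal_kernel()].
#' @param lag_s Non-negative lag (s); vectorized.
#' @export
kernel_cross_integral <- function(kernel, lag_s) {
  stopifnot(inherits(kernel, "signal_kernel"))
  vapply(lag_s, function(d) {
    if (d >= kernel$release_time_s) return(0)
    stats::integrate(function(t) kernel$L(t) * kernel$L(t + d),
                     0, kernel$release_time_s - d,
                     subdivisions = 400L, rel.tol = 1e-9)$value
  }, numeric(1))
}

#' Expected loops per polymerase by frame of initiation
#'
#' The emission weights of the two-layer HMM: `x[j]` is the expected loop
#' signal, at the moment of observation, of a polymerase initiated during
#' the j-th previous frame, averaging over a uniform initiation time within
#' that frame. `x` rises with age up to saturation at `n_loops` and takes a
#' partial value in the frame spanning release.
#'
#' @param construct A [gene_construct()].
#' @param elongation_nt_per_s,termination_s Constant-speed kinetics.
#' @param frames A [frame_settings()].
#' @param horizon_frames Number of frames D a polymerase can contribute;
#'   defaults to `ceiling(release_time / frame_interval)`.
#' @return Numeric vector `x[1..D]` (loop units per polymerase).
#' @export
emission_weights <- function(construct, elongation_nt_per_s = 22,
                             termination_s = 65, frames,
                             horizon_frames = NULL) {
  stopifnot(inherits(frames, "frame_settings"))
  kern <- signal_kernel(construct, elongation_nt_per_s, termination_s)
  dt <- frames$frame_interval_s
  D <- if (is.null(horizon_frames)) ceiling(kern$release_time_s / dt) else
    as.integer(horizon_frames)
  if (D < 1) stop("horizon_frames must be >= 1")
  j <- seq_len(D)
  (kern$L_int(j * dt) - kern$L_int((j - 1) * dt)) / dt
}

#' Convert loop units to complete-RNA equivalents
#'
#' Expresses an intensity in units of complete MS2 RNA molecules, each
#' carrying the full loop array.
#'
#' @param loop_units Intensity in loop units.
#' @param construct A [gene_construct()] (supplies `n_loops`).
#' @export
loops_to_rna_equivalents <- function(loop_units, construct) {
  loop_units / construct$n_loops
}
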