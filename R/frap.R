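#' Processive-polymerase FRAP recovery model
#'
#' After a photobleach, spot fluorescence recovers only through loops
#' synthesized post-bleach. For a stationary constant-rate gene the
#' ensemble-average normalized recovery has the closed form
#' `F(t) = 1 - D(t) / D(0)` with
#' `D(t) = integral over ages a of Q(a + t) Lsyn(a) da`, where `Lsyn(a)`
#' is the loop count synthesized by age `a` and `Q(u)` the probability a
#' polymerase is still resident at age `u`. The initiation rate cancels in
#' the normalization, so FRAP constrains only the elongation speed and
#' termination time. With `termination_model = "deterministic"` every RNA
#' is released exactly at `transcript_length/v + termination_s` and the
#' recovery reaches exactly 1 there; with `"exponential"` (matching a
#' single rate-limiting termination step) release is exponentially
#' distributed and the recovery approaches 1 asymptotically.
#'
#' @param construct A [gene_construct()].
#' @param elongation_nt_per_s Elongation speed v (nt/s).
#' @param termination_s Mean termination time (s).
#' @param t Time(s) since bleach (s, `>= 0`).
#' @param termination_model `"exponential"` or `"deterministic"`.
#' @return Normalized recovery fraction(s) in `[0, 1]`.
#' @export
recovery_model <- function(construct, elongation_nt_per_s, termination_s, t,
                           termination_model = c("exponential",
                                                 "deterministic")) {
  termination_model <- match.arg(termination_model)
  if (any(t < 0)) stop("t must be >= 0")
  kern <- signal_kernel(construct, elongation_nt_per_s, termination_s)
  S <- kern$synthesis_time_s
  R <- kern$release_time_s
  if (termination_model == "deterministic") {
    # D(t) = L_int(R - t); plateau D(0) = L_int(R)
    out <- 1 - kern$L_int(pmax(R - t, 0)) / kern$L_int(R)
    out[t >= R] <- 1
    return(out)
  }
  Tm <- termination_s
  if (Tm < 1e-9) {
    out <- 1 - kern$L_int(pmax(S - t, 0)) / kern$L_int(S)
    out[t >= S] <- 1
    return(out)
  }
  # D(t) = int_0^inf Q(a + t) Lsyn(a) da in closed form, with
  # Lsyn the synthesis ramp (ta..tb) then plateau n, and
  # Q(u) = 1 for u <= S, exp(-(u - S)/T) after (exponential release).
  n <- construct$n_loops
  ta <- kern$ramp_start_s
  tb <- kern$ramp_end_s
  lt <- tb - ta
  D <- function(tt) {
    sstar <- S - tt                       # Q switches at a = sstar
    # plateau piece, a in [tb, inf)
    d3 <- if (sstar >= tb) n * ((sstar - tb) + Tm) else
      n * Tm * exp(-(tb - sstar) / Tm)
    # ramp piece, a in [ta, tb], split at c = clamp(sstar)
    cc <- min(max(sstar, ta), tb)
    d2a <- n * (cc - ta)^2 / (2 * lt)
    e_c <- exp(-(cc - sstar) / Tm)
    e_b <- exp(-(tb - sstar) / Tm)
    d2b <- n / lt * (Tm * ((cc - ta) * e_c - lt * e_b) +
                       Tm^2 * (e_c - e_b))
    d3 + d2a + d2b
  }
  D0 <- D(0)
  vapply(t, function(tt) 1 - D(tt) / D0, numeric(1))
}

#' Normalize and average FRAP recovery curves
#'
#' A bleached spot is not expected to recover to its pre-bleach intensity,
#' so each cell's curve is normalized by its own recovered intensity,
#' defined as the mean of the final `plateau_frac` of frames. Cells whose
#' plateau is below `reject_sd` times the residual scatter of the early
#' post-bleach frames are rejected as showing no recovery. Accepted
#' normalized curves are averaged frame-by-frame with standard errors.
#'
#' @param ensemble A `frap_ensemble` tibble (`cell`, `time_s`,
#'   `fluorescence`), e.g. from [simulate_frap()].
#' @param plateau_frac Fraction of final frames defining the recovered
#'   intensity (default 0.2).
#' @param reject_sd No-recovery rejection floor, in units of the s.d. of
#'   the first 10% of frames about their mean.
#' @param min_cells Minimum accepted cells required.
#' @return List of class `frap_average`: `curve` tibble (`time_s`,
#'   `recovery`, `se`, `n`), `cells` tibble (`cell`, `plateau`,
#'   `accepted`).
#' @export
normalize_and_average <- function(ensemble, plateau_frac = 0.2,
                                  reject_sd = 2, min_cells = 10) {
  cells <- split(ensemble, ensemble$cell)
  info <- purrr::map_dfr(cells, function(d) {
    nf <- nrow(d)
    tail_i <- seq.int(ceiling((1 - plateau_frac) * nf) + 1L, nf)
    head_i <- seq_len(max(3L, floor(0.1 * nf)))
    plateau <- mean(d$fluorescence[tail_i])
    early_sd <- stats::sd(d$fluorescence[head_i])
    tibble::tibble(cell = d$cell[1], plateau = plateau,
                   early_sd = early_sd,
                   accepted = is.finite(plateau) &
                     plateau > reject_sd * max(early_sd, 1e-12))
  })
  acc <- info$cell[info$accepted]
  if (length(acc) < min_cells) {
    stop("only ", length(acc), " cells show recovery (need >= ", min_cells,
         "); cannot average")
  }
  norm <- ensemble |>
    dplyr::filter(.data$cell %in% acc) |>
    dplyr::left_join(info[, c("cell", "plateau")], by = "cell") |>
    dplyr::mutate(norm = .data$fluorescence / .data$plateau)
  curve <- norm |>
    dplyr::group_by(.data$time_s) |>
    dplyr::summarise(recovery = mean(.data$norm),
                     se = stats::sd(.data$norm) / sqrt(dplyr::n()),
                     n = dplyr::n(), .groups = "drop")
  structure(list(curve = curve, cells = info), class = "frap_average")
}

#' Fit elongation rate and termination time to multi-construct FRAP curves
#'
#' Jointly least-squares fits the processive-polymerase [recovery_model()]
#' to averaged recovery curves from constructs of different downstream
#' length. The constructs must differ (e.g. a 5' insertion vs a gene
#' replacement), otherwise v and the termination time are confounded: the
#' dwell-time difference between constructs isolates
#' `delta(downstream length) / v`.
#'
#' @param curves Named list: construct name -> list(construct =
#'   [gene_construct()], average = [normalize_and_average()] result or its
#'   `curve` tibble).
#' @param termination_model Passed to [recovery_model()].
#' @param v_init,term_init Optimizer start values.
#' @return List of class `frap_fit`: `elongation_nt_per_s`,
#'   `termination_s`, `dwell_s` (per construct), `rss`, `convergence`,
#'   `fitted` (tibble of observed and fitted curves).
#' @export
fit_kinetics <- function(curves, termination_model = "exponential",
                         v_init = 20, term_init = 50) {
  if (length(curves) < 2) stop("need averaged curves for >= 2 constructs")
  lens <- vapply(curves, function(x) x$construct$transcript_length_nt,
                 numeric(1))
  if (length(unique(lens)) < 2) {
    stop("constructs have identical transcript lengths: ",
         "singular design, elongation rate unidentifiable")
  }
  get_curve <- function(x) if (inherits(x$average, "frap_average"))
    x$average$curve else x$average
  obj <- function(par) {
    v <- par[1]; Tm <- par[2]
    sum(vapply(curves, function(x) {
      cv <- get_curve(x)
      sum((cv$recovery - recovery_model(x$construct, v, Tm, cv$time_s,
                                        termination_model))^2)
    }, numeric(1)))
  }
  opt <- stats::optim(c(v_init, term_init), obj, method = "L-BFGS-B",
                      lower = c(0.5, 0), upper = c(200, 500))
  v <- opt$par[1]; Tm <- opt$par[2]
  fitted <- purrr::map_dfr(names(curves), function(nm) {
    cv <- get_curve(curves[[nm]])
    tibble::tibble(construct = nm, time_s = cv$time_s,
                   recovery = cv$recovery,
                   fitted = recovery_model(curves[[nm]]$construct, v, Tm,
                                           cv$time_s, termination_model))
  })
  structure(list(
    elongation_nt_per_s = v, termination_s = Tm,
    dwell_s = vapply(curves, function(x)
      x$construct$transcript_length_nt / v + Tm, numeric(1)),
    rss = opt$value, convergence = opt$convergence, fitted = fitted),
    class = "frap_fit")
}

#' Compare FRAP recovery between spot-intensity groups
#'
#' Splits accepted cells into `n_groups` equal-size bins of recovered
#' intensity, averages the normalized recovery per group, and reports a
#' difference statistic: the maximum over time of
#' `|high - low| / pooled s.e.`. Systematic dwell-time differences between
#' bright and dim spots (as produced by slow global elongation-rate
#' fluctuations, but not by per-polymerase ones) show up as a large
#' statistic. By default the maximum is taken over every frame; passing
#' `n_bins` evaluates it on coarse per-cell time bins instead, which
#' tightens the null distribution of the max statistic at some cost in
#' sensitivity.
#'
#' @param ensemble A `frap_ensemble` tibble.
#' @param n_groups Number of intensity groups (default 3).
#' @param min_cells Minimum accepted cells.
#' @param n_bins Optional number of coarse time bins for the difference
#'   statistic (default: every frame).
#' @inheritParams normalize_and_average
#' @return List of class `frap_groups`: `curves` tibble (`group`,
#'   `time_s`, `recovery`, `se`, `n`), `difference_statistic`,
#'   `cells`.
#' @export
group_by_intensity <- function(ensemble, n_groups = 3, min_cells = 15,
                               plateau_frac = 0.2, reject_sd = 2,
                               n_bins = NULL) {
  avg <- normalize_and_average(ensemble, plateau_frac, reject_sd,
                               min_cells = min_cells)
  cells <- avg$cells[avg$cells$accepted, ]
  grp <- dplyr::mutate(
    dplyr::arrange(cells, .data$plateau),
    group = factor(ceiling(seq_along(.data$plateau) * n_groups /
                             length(.data$plateau)),
                   levels = seq_len(n_groups),
                   labels = if (n_groups == 3)
                     c("low", "medium", "high") else
                       paste0("g", seq_len(n_groups))))
  norm <- ensemble |>
    dplyr::inner_join(grp[, c("cell", "plateau", "group")], by = "cell") |>
    dplyr::mutate(norm = .data$fluorescence / .data$plateau)
  curves <- norm |>
    dplyr::group_by(.data$group, .data$time_s) |>
    dplyr::summarise(recovery = mean(.data$norm),
                     se = stats::sd(.data$norm) / sqrt(dplyr::n()),
                     n = dplyr::n(), .groups = "drop")
  binned <- norm |>
    dplyr::mutate(bin = if (is.null(n_bins)) .data$time_s else
      cut(.data$time_s, n_bins, labels = FALSE)) |>
    dplyr::group_by(.data$group, .data$cell, .data$bin) |>
    dplyr::summarise(cellm = mean(.data$norm), .groups = "drop") |>
    dplyr::group_by(.data$group, .data$bin) |>
    dplyr::summarise(m = mean(.data$cellm),
                     se = stats::sd(.data$cellm) / sqrt(dplyr::n()),
                     .groups = "drop")
  lo_b <- binned[binned$group == levels(grp$group)[1], ]
  hi_b <- binned[binned$group == levels(grp$group)[n_groups], ]
  pooled <- sqrt(lo_b$se^2 + hi_b$se^2)
  stat <- max(abs(hi_b$m - lo_b$m) / pmax(pooled, 1e-12))
  structure(list(curves = curves, difference_statistic = stat,
                 cells = grp), class = "frap_groups")
}
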