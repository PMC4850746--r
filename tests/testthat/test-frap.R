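test_that("recovery model boundary and scaling behaviour", {
  gc5 <- fx_construct()
  tt <- seq(0, 250, by = 5)
  f <- recovery_model(gc5, 22, 65, tt, "deterministic")
  expect_equal(f[1], 0)
  expect_true(all(diff(f) >= -1e-12))
  rel <- 2500 / 22 + 65
  expect_equal(recovery_model(gc5, 22, 65, rel, "deterministic"), 1)
  expect_lt(recovery_model(gc5, 22, 65, rel - 10, "deterministic"), 1)
  expect_equal(recovery_model(gc5, 22, 65, c(rel, rel + 50),
                              "deterministic"), c(1, 1))
  # time-speed rescaling: v -> 2v, T -> T/2, t -> t/2 leaves F unchanged
  f2 <- recovery_model(gc5, 44, 32.5, tt / 2, "deterministic")
  expect_equal(f2, f, tolerance = 1e-10)
  fe <- recovery_model(gc5, 22, 65, tt, "exponential")
  expect_true(all(diff(fe) >= -1e-9))
  expect_lt(fe[length(fe)], 1)  # exponential release: asymptotic approach
  expect_error(recovery_model(gc5, 22, 65, -1), ">= 0")
})

test_that("ensemble-average simulated recovery matches the closed form", {
  gc5 <- fx_construct()
  kin <- kinetic_params(initiation_constant(0.13), 22, 65)
  fe <- simulate_frap(gc5, kin, fx_frames(10), n_cells = 300,
                      recovery_s = 400, seed = 70)
  em <- fe |>
    dplyr::group_by(.data$time_s) |>
    dplyr::summarise(m = mean(.data$fluorescence))
  mod <- recovery_model(gc5, 22, 65, em$time_s, "exponential")
  late <- em$time_s > 300
  emn <- em$m / mean(em$m[late])
  modn <- mod / mean(mod[late])
  expect_lt(sqrt(mean((emn - modn)^2)), 0.02)
})

test_that("normalization and rejection behave on constructed ensembles", {
  tt <- seq(10, 200, by = 10)
  curve <- recovery_model(fx_construct(), 22, 65, tt, "deterministic")
  mk <- function(cell, scale) tibble::tibble(cell = cell, time_s = tt,
                                             fluorescence = scale * curve)
  ens <- dplyr::bind_rows(lapply(1:12, function(i) mk(i, 50)))
  class(ens) <- c("frap_ensemble", class(ens))
  avg <- normalize_and_average(ens, min_cells = 10)
  # identical noiseless curves: the average is the curve itself
  expect_equal(avg$curve$recovery, curve / mean(curve[17:20]),
               tolerance = 1e-10)
  expect_true(all(avg$curve$se < 1e-12))
  # a zero-plateau cell is rejected, not averaged
  ens2 <- dplyr::bind_rows(ens, tibble::tibble(cell = 99, time_s = tt,
                                               fluorescence = 0 * tt))
  avg2 <- normalize_and_average(ens2, min_cells = 10)
  expect_false(avg2$cells$accepted[avg2$cells$cell == 99])
  expect_equal(sum(avg2$cells$accepted), 12)
  expect_error(normalize_and_average(ens[ens$cell == 1, ]), "cells")
})

test_that("kinetics are recovered from multi-construct recovery curves", {
  gc5 <- construct_preset("five_prime")
  gcr <- construct_preset("gene_replacement")
  tt <- seq(5, 300, by = 5)
  curves <- list(
    five_prime = list(construct = gc5,
                      average = tibble::tibble(
                        time_s = tt,
                        recovery = recovery_model(gc5, 22, 65, tt))),
    replacement = list(construct = gcr,
                       average = tibble::tibble(
                         time_s = tt,
                         recovery = recovery_model(gcr, 22, 65, tt))))
  fit <- fit_kinetics(curves)
  # noiseless self-consistency: exact recovery to optimizer tolerance
  expect_lt(abs(fit$elongation_nt_per_s - 22), 0.2)
  expect_lt(abs(fit$termination_s - 65), 1.5)
  # dwell difference equals the downstream-length difference over v
  expect_equal(fit$dwell_s[["five_prime"]] - fit$dwell_s[["replacement"]],
               (2500 - 2130) / fit$elongation_nt_per_s, tolerance = 1e-6)
  expect_error(fit_kinetics(curves["five_prime"]), ">= 2")
  curves_same <- curves
  curves_same$replacement$construct <- gc5
  expect_error(fit_kinetics(curves_same), "singular")
})

test_that("simulated FRAP ensembles give usable kinetic estimates", {
  fr <- fx_frames(10, noise = 3)
  mk <- function(cons, seed) {
    fe <- simulate_frap(cons, kinetic_params(initiation_constant(0.13),
                                             22, 65), fr,
                        n_cells = 30, recovery_s = 400, seed = seed)
    list(construct = cons, average = normalize_and_average(fe))
  }
  fit <- fit_kinetics(list(five_prime = mk(construct_preset("five_prime"), 71),
                           repl = mk(construct_preset("gene_replacement"), 72)))
  expect_lt(abs(fit$elongation_nt_per_s - 22) / 22, 0.2)
  expect_lt(abs(fit$termination_s - 65), 25)
})

test_that("intensity grouping partitions cells and is order-invariant", {
  set.seed(73)
  tt <- seq(10, 300, by = 10)
  base <- recovery_model(fx_construct(), 22, 65, tt, "exponential")
  ens <- dplyr::bind_rows(lapply(1:18, function(i)
    tibble::tibble(cell = i, time_s = tt,
                   fluorescence = (20 + 4 * i) * base +
                     rnorm(length(tt), 0, 2))))
  class(ens) <- c("frap_ensemble", class(ens))
  g <- group_by_intensity(ens, n_bins = 8)
  expect_equal(as.vector(table(g$cells$group)), c(6, 6, 6))
  # permuting cell ids leaves group curves unchanged
  perm <- sample(18)
  ens2 <- dplyr::mutate(ens, cell = perm[.data$cell])
  g2 <- group_by_intensity(ens2, n_bins = 8)
  expect_equal(dplyr::arrange(g$curves, .data$group, .data$time_s)$recovery,
               dplyr::arrange(g2$curves, .data$group, .data$time_s)$recovery,
               tolerance = 1e-12)
  # statistically identical cells show no group separation
  expect_lt(g$difference_statistic, 3)
})
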