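---
title: "Models and methods behind msburst"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind msburst}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(msburst)
```

msburst analyses transcriptional bursting as seen through live-cell imaging
of MS2/MCP-tagged nascent RNA: a nuclear spot whose intensity tracks the
instantaneous load of fluorescent stem loops at the gene. The package
couples an exact stochastic simulator of that measurement process to the
inference tools needed to ask how many states of gene activity the data
support — one constant initiation rate, a few discrete rates, or a slowly
drifting continuum.

## The measurement model

A gene construct is described by where the loop array sits
(`gene_construct()`): for the built-in 5' insertion, 24 loops over 1.3 kb
starting 21 nt into a 2.5 kb transcript. A single polymerase at position
p contributes a *loop signal* `L(p)`: zero before the array, rising
linearly to 24 across it, then flat. We use the continuous ramp rather
than a staircase of completed loops; the two differ by less than one loop
and the ramp matches the continuous-intensity Gaussian theory. As a
function of the polymerase's age at constant speed v with termination
delay T, `signal_kernel()` gives `L(t)` together with closed forms for
its integrals; the residence (dwell) time is `transcript_length / v + T`,
178.6 s for the 5' construct at v = 22 nt/s, T = 65 s.

All intensities are carried internally in loop units; dividing by the
loop count (`loops_to_rna_equivalents()`) expresses them as complete-RNA
equivalents.

## The simulator

`simulate_trace()` is an exact event-driven Monte Carlo: initiation,
gene-state switching and termination are single rate-limiting
(exponential) events, and elongation advances one nucleotide at a time
with exponential waits of mean 1/v (a config switch makes steps
deterministic). Transit times over 2500 steps are therefore Erlang —
nearly deterministic — as intended. Two physical constraints are always
enforced: a 40 nt steric footprint (a typical polymerase footprint; the
value is not construct-specific) that a trailing polymerase cannot
violate, and initiation blocking while the promoter-proximal footprint is
occupied. Exponential clocks are redrawn whenever their rate changes and
blocked arrivals are discarded, which is exact thinning. Terminating
polymerases hold their full loop complement until an exponential release
delay elapses and are treated as clear of the template.

Initiation-rate processes:

* constant (the one-state, Poisson gene);
* discrete K-state continuous-time Markov chains (uniform jumps with a
  mean dwell, or an explicit generator);
* the continuum model: an off/on telegraph with `k_on = k_off = 1/600`
  s^-1 (closed-state switching on the ten-minute scale), and, while on, a
  reflecting random walk over a geometric ladder of initiation rates.

The continuum defaults were fixed once, from observable anchors: ladder
levels 0.06–0.22 /s per gene copy, so that two-copy total rates span
~0.1–0.45 /s (the range over which inferred initiation rates are
displayed) with a stationary mean total of ~0.125 /s — which at a
~180 s dwell reproduces the 20–27 resident polymerases estimated for a
two-allele spot; and a ladder step timescale of 60 s, tuned so the
rate-path autocorrelation decays (1/e) in roughly five minutes. Because
cells carrying a replicated locus image two gene copies as one spot, the
experiment-matched presets sum two independent copies (`diploid = TRUE`);
unit tests use single copies.

What the generator does *not* emulate: microscope photophysics beyond
additive Gaussian noise and a bleach flag, nuclear movement, cell
division, and any feedback between polymerase density and the promoter.
Passing tests therefore validate the analysis chain against the stated
stochastic model, not against everything real imaging data can do.

Measurement noise defaults to a constant s.d. in loop units (15 loops in
the presets, a few percent of a typical spot) — small relative to the
signal but large enough that spot detection near zero is thresholded, as
in experiments.

## Pulsing theory

For the one-state gene the spot intensity is a filtered Poisson process,
so Campbell's theorem gives the stationary mean `r∫L dt`, variance
`r∫L² dt + σ²` and lag-Δt covariance `r∫L(t)L(t+Δt) dt`
(`campbell_moments()`; contributions double for two copies, noise enters
once). Treating successive frames as bivariate Gaussian with those
moments, a spot "pulse" ends when the intensity drops below the
detection threshold between frames: `p_off = P(above then below) /
P(above)` from bivariate-normal orthant probabilities (evaluated by 1-D
quadrature to 1e-8; no closed-form bivariate CDF is assumed), giving a
geometric pulse-length law with mean `Δt / p_off`. This is why pulse
durations are exponential without any off state, and why they shorten as
the threshold rises or the frame interval changes. The Gaussian
approximation is flagged (a warning) when the mean is within three s.d.
of zero, where positivity skews the true law. The theory deliberately
neglects promoter-footprint exclusion; theory-vs-simulation tests
therefore run the simulator with the footprint disabled, the regime in
which the filtered-Poisson description is exact.

`one_state_contours()` sweeps rate and threshold; `two_state_contours()`
optimizes the telegraph duty cycle so the model matches a target spot
frequency at the lowest threshold and then measures the sweep by
simulation, since the Gaussian theory is not conditional-state exact for
a switching gene.

## Trace analytics

`extract_pulses()` segments traces at a threshold (ties count as below;
runs touching track ends are censored). `fit_exponential_durations()`
fits the left-truncated, right-censored exponential in closed form;
durations below two frames are excluded by default because frame
quantization and the finite RNA residence distort the short end — the
goodness-of-fit KS test undoes quantization with uniform within-frame
jitter.

`autocorrelate()` computes the fluctuation autocorrelation
`G(τ) = ⟨δI δI⟩/⟨I⟩²` with per-track mean subtraction, optionally
restricted to frames where a spot is present. `decompose_acf()` splits
G into the lag-0 noise spike, the polymerase (single-RNA) component and
a slow initiation-rate component: a line is fitted over the window
`[release + 2Δt, 2.2 × release]` and the dwell estimate is the largest
lag at which G exceeds the extrapolated line by twice the fit's residual
s.e. The window's upper bound matters: with minutes-scale drift the slow
component is convex, and extrapolating a line fitted too far out
under-subtracts it at lag 0, biasing the polymerase-load estimate
(`load = dwell · ∫L²/(∫L)² / G_dev(0)`) low. The default 2.2× bound was
set by recovering the known load on simulated ground truth and then
frozen; both window and criterion are exposed as arguments. On the
continuum preset the median estimates across seeded runs are a dwell of
~190 s and a load of ~22 polymerases.

`quantile_calibrate()` aligns live spot intensities (a.u.) with smFISH
loop counts by matched percentiles (1st–99th), isotonic regression for
monotonicity, and linear extrapolation beyond the central 5th–95th
segment, where the two modalities' extremes are unreliable.

## FRAP

After a photobleach only newly synthesized loops fluoresce. For a
stationary constant-rate gene the normalized recovery has the closed form
`F(t) = 1 − D(t)/D(0)` with `D(t) = ∫ Q(a+t) Lsyn(a) da`, where `Lsyn`
is the synthesis ramp and Q the residence survival. Both a deterministic
release (recovery reaches exactly 1 at the residence time) and an
exponential termination step (matching the simulator; asymptotic
approach) are provided; the initiation rate cancels, so FRAP constrains
only v and T. `fit_kinetics()` needs constructs of different downstream
length — the dwell-time difference isolates Δlength/v — and recovers
v = 22 nt/s, T = 65 s from simulated ensembles to within ~10%.
`group_by_intensity()` bins cells into three equal recovered-intensity
groups and reports the maximum over time of the high-low group
difference in pooled-s.e. units (optionally on coarse time bins, which
tightens the null of a max statistic). At ensembles of some tens of
cells — the scale of real FRAP experiments — global speed fluctuations
separate the groups while per-polymerase fluctuations do not, because
exclusion pins the bulk flux to the slow leaders; the separation fades
as the switching timescale drops toward tens of seconds, which is what
bounds elongation-fluctuation lifetimes from FRAP data. At much larger
ensembles a genuine density effect (brighter spots are denser and so
transit slightly slower) becomes detectable in either mode and blurs
the contrast; the comparison is a statement about experimental-scale
power, and the tests run it at that scale.

## The two-layer HMM

The hidden state at frame t is `(g, m_1..m_D)`: the gene state g and the
number of polymerases initiated in each of the last D frames (a shift
register, D = ceiling(residence/Δt)). Gene states carry initiation rates
r_g and switch by a row-stochastic matrix A constrained by a topology
(ladder/jump-1/free); the new register entry is Poisson(r_g·Δt) in the
state being entered (the destination convention; a source-state variant
differs only at switch frames), truncated at `m_max`. The truncated
Poisson is left unnormalized: the discarded tail must be negligible
(`build_state_space()` reports the row mass), and keeping it
unnormalized makes the EM M-step exact, so the likelihood is provably
non-decreasing — a property the tests assert to 1e-9. Emission is
`I_t ~ Normal(Σ_j x_j m_j, σ²)` with weights `x_j` from
`emission_weights()`; σ is fitted and absorbs, besides camera noise, the
within-frame initiation-timing variability the register cannot resolve.

Forward-backward and the EM sufficient statistics run in compiled code
over the factorized joint space (collapse over the oldest register slot,
mix gene states, expand with the new-count Poisson), so likelihoods are
exact up to truncation, and are verified against brute-force path
enumeration on small instances. Training uses five seeded random
restarts by default, each run for a few iterations before the best is
polished to convergence (the usual short-run restart strategy); states
are sorted by rate afterwards. Model order
is chosen by AIC with the parameter count K rates + free transition
entries + 1 noise term. `gibbs_sample()` alternates two exact block
updates — the count register given the gene path (forward-filter
backward-sample with Gaussian emissions) and the gene path given counts
(K-state FFBS with truncated-Poisson observations) — and its marginals
match exact smoothing marginals on enumerable instances.
`estimate_rate_path()` converts posterior-mean counts to a
piecewise-constant rate by 1-D total-variation denoising (the
edge-preserving smoother), with the penalty chosen per trace by a
BIC-style criterion over a grid; `bursting_statistics()` then reads off
k_on, k_off, constant-rate segment lifetimes by rate, up/down switching
probabilities and their crossover.

A related discretization effect: frames that straddle an off/on switch
carry intermediate effective initiation rates, so on discretely sampled
telegraph traces the AIC can reward a small extra "switch-frame" state
that the continuous-time generator does not contain. Strict model-order
self-consistency holds for data drawn from the discrete-time model
itself, and the tests check it there.

Desk-scale caveat: at a 60 s frame interval individual per-frame counts
are only partially identified, so the per-state count posteriors are
shrunk toward their Poisson priors. The super-Poisson dispersion that a
3-state fit shows on continuum data is therefore directional but modest
here (variance/mean ≈ 1.1 versus ≤ 1.0 on true 3-state data), whereas
sharply sampled experimental data shows it dramatically. The tests
assert the direction and the contrast, not the magnitude.

## Steady-state contrast

`simulate_release_times()` draws production events from the initiation
process alone (elongation adds only a fixed transit delay, which is all
a steady-state pool can see), and `simulate_cytoplasmic_pool()` decays
each transcript with an exponential lifetime (default 40 min).
`fit_negative_binomial()` is a direct MLE (the mean profile is exact, a
1-D search sets the dispersion) with a pooled chi-square GOF;
under-dispersed samples fall back to Poisson with a flag, and the NB
parameterization (`size`, `prob`, burst size `(1−prob)/prob`) is
recorded explicitly. `snapshot_vs_live_contrast()` packages the central
comparison: the same continuum gene yields cytoplasmic counts that a
standard two-state (negative binomial) model fits acceptably — the long
lifetime averages the rate drift away — while its live traces keep
rewarding additional HMM states beyond three.

## Sizes, seeds and reproducibility

Every stochastic function takes an explicit seed, and ensembles derive
per-cell seeds from it; identical seeds give bit-identical traces.
`run_pipeline()` executes preset analyses with per-stage derived seeds
and writes a manifest of outputs and checksums. Default problem sizes
throughout the tests and the acceptance script (tens of cells, 60-frame
traces, 20-seed medians, K scans to 5) are chosen as the smallest
ensembles at which each qualitative result is stable; they are the
package's desk-scale working points, and all of them can be scaled up
through ordinary arguments.

Open choices resolved here, for the record: the frame interval is a
required imaging parameter with no default; per-nucleotide steps default
to exponential (deterministic available); the two-state contour matching
fixes the switching cycle time and optimizes the duty ratio; the
deviation-point criterion is two residual s.e. above the long-lag line;
the ΔAIC significance calibration for experimental replicates is not
reimplemented (no procedure is defined for it here), and `model_scan()`
reports ΔAIC without a p-value.
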