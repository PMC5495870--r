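---
title: "Methods: time-variant directed connectivity during balance control"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: time-variant directed connectivity during balance control}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6,
                      fig.height = 4)
library(balancenet)
```

`balancenet` estimates how directed interactions between cortical areas
reorganize in the seconds around a balance perturbation. This vignette
documents the statistical model, the main numerical choices, what the
synthetic-data generator does and does not emulate, and the known limitations
of the estimators. The function reference documents individual arguments; here
the focus is on *why* things are the way they are.

## The experiment the generator emulates

The target experiment is a cohort of subjects standing on a platform that
switches from a stable to an unstable (free-swinging) state at a trigger. Each
subject contributes repeated trials; each trial is an epoch of multichannel
EEG spanning a few seconds before and after the transition. The scientific
questions are:

1. how band-limited amplitude (theta, alpha) evolves around the transition,
2. which directed cortico-cortical interactions carry the adjustment, and
3. whether interaction strength differs between the stable and unstable
   balance conditions.

The generator (`sim_config()` + `simulate_dataset()`) produces data with a
known ground truth for all three. Its defaults describe one fixed synthetic
"study": 37 subjects, 10 trials each, 8-second epochs sampled at 1000 Hz with
the platform release at 3 s, an 11-electrode midline/parietal montage plus one
EOG channel. Signals are built from:

- a per-channel time-variant vector autoregressive (VAR) core with a planted
  directed coupling (by default CPz → Cz at lag 2) that switches on at the
  release — the coupling is realized **inside** the autoregression, not as an
  additive mixed signal, so it is a genuine directed, lagged interaction;
- stochastic narrowband rhythms (theta over central, alpha over posterior
  electrodes), generated as noise-driven damped AR(2) resonances
  (`oscillator()`); the pole radius is `exp(-pi * bandwidth / fs)`, giving a
  Lorentzian-like line of controllable width rather than a deterministic
  sinusoid. Alpha amplitude drops after the release; rhythms are independent
  across channels and trials;
- a phase-locked platform-sway interference (`sway_spec()`): a sawtooth-like
  harmonic series that is *identical across trials* (it is mechanically locked
  to the platform), with an anterior–posterior gain gradient so that posterior
  channels (Oz strongest) carry more of it — a spatially uniform artifact
  would be annihilated exactly by the common average reference and would be
  undetectable downstream;
- ocular artifacts: blinks and slow eye movements on a dedicated EOG channel,
  linearly leaked into EEG channels with distance-dependent coefficients;
- white measurement noise.

### What the generator deliberately does not emulate

Volume conduction (instantaneous mixing of cortical sources), electrode
impedance drift, line noise, and non-stationary noise floors are out of scope.
The generator exists to give the estimators a known answer, not to fool a
human reviewer; every component is there because some stage of the pipeline
must be able to detect, remove, or recover it.

## Preprocessing

`detect_onset()` finds the release trigger from the platform channel,
`epoch()` aligns trials to it, `rereference_common_average()` applies a common
average reference over EEG channels (the EOG channel is excluded),
`correct_ocular()` removes the EOG leakage by per-channel regression, and
`decimate_recording()` low-pass filters (FIR, cutoff below the output Nyquist)
and downsamples to 100 Hz. After decimation the Nyquist frequency is 50 Hz —
about 8.3 times the theta rhythm and 5 times the alpha rhythm, so both bands
of interest are far from the filter edge.

## Time-variant MVAR by multi-trial Kalman filtering

The core model for a `D`-channel epoch is a time-variant VAR of order `p`:

$$ y_t = \sum_{k=1}^{p} A_k(t)\, y_{t-k} + e_t, \qquad e_t \sim (0, \Sigma_t), $$

with the coefficients evolving as a random walk. `fit_kalman()` estimates
$A_k(t)$ with a linear Kalman filter in which **all trials update the same
state at each time step** before time advances; this multi-trial scheme is
what makes single-epoch time resolution possible at realistic noise levels.

Two scalars control the filter (`kalman_config()`):

- `c1 = 0.02` adapts the measurement-noise variance by exponentially smoothing
  squared innovations;
- `c2 = 0.005` is the **step width** of the coefficient random walk. We read
  the published value as a standard deviation, so the process-noise covariance
  is $Q = c_2^2 I$. The alternative reading $Q = c_2 I$ is available via
  `c2_is_variance = TRUE`; it yields visibly wigglier trajectories. The choice
  trades tracking speed against variance and the default is the conservative
  reading.

The filter needs roughly the first second of each epoch to converge from its
zero initialization; that burn-in is carried on the model object and excluded
by downstream condition averages. Convergence speed scales with the number of
trials — with many fewer than 10 trials the pre-transition coefficient
estimates are still settling when the transition arrives, which biases
pre/post contrasts.

`select_order()` chooses `p` by multivariate AIC on a pooled stationary fit;
the study operating point is `p = 20` at 100 Hz, which gives the parametric
spectrum enough poles to resolve theta and alpha simultaneously.

## Generalized partial directed coherence

From the fitted $A_k(t)$, `gpdc()` computes the generalized PDC

$$ \pi_{i \leftarrow j}(t, f) \;=\;
   \frac{ |\bar A_{ij}(t,f)| / \sigma_i(t) }
        { \sqrt{ \sum_m |\bar A_{mj}(t,f)|^2 / \sigma_m^2(t) } }, $$

with $\bar A(t,f) = I - \sum_k A_k(t) e^{-\mathrm i 2 \pi f k / f_s}$. Each
column (source) is normalized to unit energy, so gPDC measures the *relative*
outflow from channel $j$ toward each target. The raw object keeps the
diagonal; network-facing accessors (`roi_mean()`, `condition_ans()`,
`discretize()`) zero it, because self-terms are not interactions.

### The resonance floor — an important estimator property

gPDC has a structural null floor that users must be aware of. At a frequency
where a channel carries a strong narrowband rhythm, the diagonal entry
$|\bar A_{jj}(f)|$ collapses (the AR polynomial nearly vanishes at its own
resonance). The column normalization then redistributes energy onto the noisy
off-diagonal entries, so *absent* couplings in the rhythm band show gPDC
values around 0.2 rather than near zero. Even without rhythms the finite-order
Kalman estimate has an in-band floor around 0.10–0.12 for small montages.

Consequently, fixed absolute thresholds are not portable across datasets. The
package's recommended procedure is **calibration against the stable-condition
(pre-transition) segment**: take the maximum pre-transition ROI-mean gPDC as
the noise ceiling and set the discretization thresholds relative to it. The
bundled defaults in `discretize()` (0.08 / 0.10 / 0.12) reproduce a published
operating point and are appropriate after such a calibration, not as
universal constants.

A second property interacts with the generator design: because the planted
coupling lives inside the VAR core, strong *additive* rhythms on the coupled
channels act as errors-in-variables and attenuate the estimable
cross-coefficient. Recovery benchmarks in the package therefore use
rhythm-free planted simulations; with rhythms on, the same coupling is
detected but with a reduced margin over the resonance floor.

## Time-frequency analysis and phase-locking

`mgt()` computes a multi-window Gabor transform (Gaussian windows, bandwidth
matched to the analysis band) returning amplitude and phase maps.
Single-trial phases at each (time, frequency) bin are combined across trials
into the phase-locking index

$$ \mathrm{PLI}(t,f) = \Bigl| \tfrac{1}{n} \sum_{r=1}^{n}
      e^{\mathrm i \varphi_r(t,f)} \Bigr| \in [0, 1]. $$

Under the null of uniform phases, $n\,\mathrm{PLI}^2$ is asymptotically
exponential (Rayleigh test), giving the closed-form trigger threshold
`rayleigh_threshold(n, alpha) = sqrt(-log(alpha)/n)` — at `n = 37` and
$\alpha = 0.05$ this is `r round(sqrt(-log(0.05)/37), 4)`. The package
verifies the type-I error of this threshold by Monte Carlo as part of its
acceptance checks.

Because the platform sway is phase-locked to the trigger, it produces PLI
peaks at its fundamental and harmonics. `screen_harmonics()` flags frequencies
where the fraction of post-transition bins exceeding the Rayleigh threshold is
high, and renders a verdict per analysis band: a band is *contaminated* when a
flagged harmonic falls inside the band (a guard margin widens the band), in
which case phase-locked interference could masquerade as induced activity and
the band's amplitude results should be interpreted with care. Screening is
performed at a posterior channel (default `Oz`) where the sway gradient is
strongest.

## Cohort statistics

`confidence_tube()` builds pointwise percentile-bootstrap confidence bands
(default 95%, 1000 replicates) for the cohort-mean time course of band
amplitude, resampling subjects with replacement. Coverage of the percentile
interval at `n = 37` subjects is verified by Monte Carlo (1000 cohorts) in the
acceptance checks. `paired_ttest_ans()` compares stable vs unstable average
node strength per frequency bin with Bonferroni correction across bins.

## PARAFAC of the connectivity tensor

`build_pdc_tensor()` stacks gPDC into a 4-mode array
(channel-pair × time × frequency × subject); self-pairs are excluded.
`parafac()` decomposes it with nonnegative hierarchical ALS (HALS), multiple
random restarts, factors matched across restarts by Tucker congruence, and a
core-consistency diagnostic. Nonnegativity matches the data (gPDC is
nonnegative) and makes components directly readable as co-varying
"subnetworks × time course × spectrum × subject weight".

For pipeline use the tensor is reduced before decomposition — a time
decimation factor (default 10) and a frequency crop (default 3–13 Hz,
covering theta and alpha) — because the PDC time axis is far oversampled
relative to how fast the Kalman trajectory can actually move. These are
tractability choices of this package, not properties of the method.

## Problem sizes

The default generator sizes (37 subjects, 10 trials, 11 + 1 channels, 8 s at
1000 Hz) define the synthetic study and are used as-is by
`run_pipeline(pipeline_config())`. They are deliberately *not* tuned for
speed: a full default run takes a few minutes per subject-block on one core,
dominated by the Kalman filter and PARAFAC. Examples and tests use smaller
montages and cohorts; every size reduction is visible in the corresponding
configuration object.

## A small end-to-end run

```{r pipeline, eval = FALSE}
cfg <- pipeline_config(
  sim = sim_config(n_subjects = 3, n_trials = 10,
                   channel_names = c("C1", "Cz", "C2",
                                     "CP1", "CPz", "CP2", "Oz")),
  freqs = seq(1, 15, 0.5),
  parafac_M = 2, parafac_restarts = 2,
  tensor_subset = c("Cz", "CPz", "C1", "C2", "Oz"),
  seed = 1
)
report <- run_pipeline(cfg)
report$log
report$networks
```

## Limitations

- gPDC quantifies *relative* directed outflow under a linear VAR model; it is
  blind to nonlinear coupling and distorted by unmodelled instantaneous mixing
  (e.g. volume conduction, or the common average reference itself, which
  leaks every channel into every other with weight $-1/D$).
- The resonance floor described above means absolute gPDC values are not
  comparable across montages, model orders, or rhythm regimes — always
  calibrate thresholds against a within-dataset null segment.
- The Kalman random-walk prior smooths coefficient trajectories; transitions
  appear with a time constant set by `c2` and the trial count, not
  instantaneously.
- Bootstrap tubes are pointwise, not simultaneous: the family-wise coverage
  over a whole time course is below the nominal pointwise level.
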