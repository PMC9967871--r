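---
title: "cardioflux: models, defaults and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{cardioflux: models, defaults and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cardioflux)
```

cardioflux quantifies four kinds of cardiomyocyte measurements: paced
calcium transients (cytosolic Fura-2 ratio and mitochondrial Rhod-2
dF/F0), the caffeine-bolus assay of sarcoplasmic-reticulum (SR) store
content, high-resolution respirometry with safranine-O membrane-potential
readout, and cluster statistics from STED/confocal immunolabel images. This
vignette documents the models behind each stage, the tunable parameters and
their defaults, what the synthetic generators do and do not emulate, and the
design choices made where reasonable alternatives existed.

## Calcium-transient kinetics

A paced recording is segmented into one half-open window `[stim, stim + 1/f)`
per stimulus (`segmentBeats()`); explicit stimulus times override the pacing
frequency, and a partial final window is dropped. Within each window
(`analyzeTransient()`) the per-beat quintet is:

* **diastolic** — mean over the first `baseline_ms` (default 50 ms) of the
  window, before the upstroke;
* **peak / amplitude** — see the estimator note below; amplitude is always
  peak minus diastolic;
* **maximum rate of rise** — the largest central-difference derivative of the
  smoothed signal between the stimulus and the peak, reported in signal
  units per millisecond (the convention for a.u. ms^-1 readouts);
* **time to peak** — stimulus to the (earliest) smoothed maximum; an
  onset-referenced variant (`ttp_reference = "onset"`) measures from the
  first sample exceeding diastolic + `noise_k` baseline SDs instead, for
  users who prefer excluding the excitation latency;
* **decay tau** — least-squares fit of `A exp(-(t - t_p)/tau) + C` from the
  peak sample to the end of the window, offset `C` free. A free offset makes
  the fit robust to residual drift and to inter-beat summation (overlapping
  tails of earlier beats share the same tau, so they fold into `A` and `C`
  without biasing the estimate). `fit_r2`/`fit_rmse` are reported so callers
  can filter poor fits.

Smoothing before peak and derivative extraction is a centred moving average
of `smooth_width = 5` samples (12.5 ms at the 400 Hz acquisition rate):
enough to suppress single-sample PMT noise without materially biasing the
time-to-peak. Ties at the maximum break to the earliest sample, making
time-to-peak deterministic.

**Peak estimator.** The raw (or smoothed) maximum of a noisy trace is biased
upward: the expectation of a maximum over many near-peak samples grows like
the noise SD times `sqrt(2 log n)`. At cytosolic signal-to-noise this is
negligible, but for mitochondrial transients (amplitude ~0.03 dF/F0 against
noise ~0.005) it approaches 8% — outside the 5% recovery band the package
aims for. The default (`peak_estimate = "fit"`) therefore reads the peak
value from the fitted decay extrapolated to the peak time (`A + C` at the
fit start): exact on clean data, unbiased under noise, and it degrades
gracefully to the smoothed maximum when the fit fails. The observed-maximum
convention remains available as `peak_estimate = "smoothed_max"`.

Beats whose amplitude does not exceed `noise_k = 3` baseline SDs are
rejected ("amplitude below noise floor"); `steadyStateSummary()` then
averages the last `n_last` accepted beats (mean ± SEM per field), emulating
the experimental practice of reading out once pacing has reached steady
state.

## Caffeine-bolus assay

A 20 mM caffeine bolus applied without field stimulation empties the SR: the
transient amplitude (peak minus the diastolic level over the 2 s before the
bolus) measures total SR calcium content, and the decay time constant in the
continued presence of caffeine measures trans-sarcolemmal efflux (dominated
by the sodium–calcium exchanger, since SERCA re-uptake is defeated while the
SR is held leaky). The peak is sought within `peak_search_s = 10` s of the
event; the efflux fit runs from the peak to the first return within
`recovery_frac = 5%` of the amplitude above diastolic, or the end of the
record — the original work does not state a fit window, so this one is
pinned in configuration rather than claimed. The bolus time comes from the
event annotation by default; an onset-detection fallback (first sample
exceeding diastolic + 5 SD) handles unannotated traces. The same
fit-extrapolated peak estimator is used as for the paced transients.

## Respirometry and membrane potential

Event-marked oxygraph recordings are segmented into respiratory states:
complex-I substrates (Leak), ADP with hexokinase/glucose (OXPHOS), calcium
titrations, and FCCP. Each state window opens `settle = 60` s after its
addition (mixing and stabilisation) and closes at the next event. Per-state
readouts are taken over the **last third** of the window, after the signal
has stabilised; a state is flagged steady when the flux drift there is below
`steady_tol` (0.05 pmol s^-1 mg^-1 per s, from the quadratic term of a fit
to the O2 trace).

Mass-specific oxygen flux is the negative least-squares O2 slope scaled by
chamber volume and tissue mass:
`flux [pmol s^-1 mg^-1] = -slope [uM/s] x V [mL] x 1000 / mass [mg]`.

Membrane potential comes from safranine-O partitioning. With `C_RB` the
concentration remaining in the buffer, `C_out = C_RB` and the matrix
concentration follows by mass balance,

`C_in = (C_FCCP - C_RB) x V_RB / V_mito`,

where `C_FCCP` is the buffer concentration after full uncoupling — using
`C_FCCP` rather than the total added (`C_total`, 2 uM) subtracts
non-mitochondrial uptake, which does not release on FCCP in homogenates.
The typeset source formula is ambiguous about this parenthesisation; the
form above is the only dimensionally and narratively consistent reading, and
it is what the package implements. Then

`psi = (RT / zF) ln(C_out / C_in)` (mV),

with `T = 310.15 K` (37 °C assay), `z = +1`, and the mitochondrial volume
taken as 3.1 uL per mg of tissue. At 310.15 K a tenfold ratio change moves
psi by 61.54 mV. The closed-form inverse (`inversePsi()`) gives the buffer
concentration for a target potential; the synthetic generator uses it so
ground-truth potentials are exact. The FCCP state is depolarised by
definition (psi = 0) and supplies the `C_FCCP` estimate when the calibration
leaves it open. The instrument's fluorescence-to-concentration mapping is
assumed linear; a two-point helper (`safranineCalibrate()`) is provided, and
free-calcium values for titration states come from a user-supplied ladder
(chelator-equilibrium speciation is out of scope). Irreversible
depolarisation during calcium titration (permeability-transition-pore
opening) is detected, not modelled: a sustained safranine rise reaching 80%
of the FCCP level.

## Cluster quantification

`segmentClusters()` applies optional grey-morphology background subtraction,
a global threshold (Otsu by default — the thresholding used in the original
ImageJ analysis is unstated, so the method is recorded in every result for
provenance), 8-connected component labelling, and a minimum size of 4 px
(at 15 nm pixels that is ~0.0009 um^2, two orders of magnitude below the
smallest reported clusters, so it removes only shot noise). Areas are pixel
counts times the pixel area; centroids are pixel-centre means with the
origin at the top-left frame corner, x along columns. Edge-touching clusters
are retained but flagged. Cluster density tiles the frame from the origin
into 1 um^2 tiles and assigns each cluster to the tile containing its
centroid (tiling origin and straddling rules are unstated in the source;
centroid assignment is the pinned choice). Fractional labelled area is the
percentage of ROI pixels above the same threshold, against a supplied
polygon ROI or the full frame. Colocalisation is expressed only as
nearest-neighbour distances between cluster centroids (with self-exclusion
within one set); intensity-correlation coefficients are deliberately not
implemented.

## Synthetic data: what it emulates, and what it does not

Every generator is a deterministic function of its mandatory seed, and every
generator/analyzer pair closes a round trip: noiseless recovery is exact to
solver tolerance, noisy recovery unbiased within Monte-Carlo error.

**Transient kernel.** Beats are built from a normalised kernel that is
quiescent for a short latency after the stimulus (default 50 ms, standing in
for the excitation-to-release delay so the analyzer's pre-upstroke baseline
segment is genuinely baseline), rises as a half-cosine to exactly 1 at the
configured time-to-peak, and then decays as an exact monoexponential. This
shape was chosen over the superficially natural product of exponentials
`(1 - e^(-t/tau_r)) e^(-t/tau_d)` because the product's decay phase is a
two-exponential mixture until the rise factor saturates: a monoexponential
fitter applied from the peak can never recover `tau_d` from it exactly, so
that kernel cannot serve as ground truth for exact parameter recovery. The
product kernel remains available (`kernel = "expprod"`, with `solveTauRise()`
giving the rise constant from the closed peak-time relation
`t* = tau_r log(1 + tau_d/tau_r)`, reachable only for `ttp < tau_d`) for
studying exactly this fitting bias. In ratiometric mode the target ratio
`r(t)` is split anti-correlated into `F340 = B r^s`, `F380 = B r^(s-1)`
(default `s = 0.5`), so the computed ratio reproduces the target exactly at
zero noise for any split; channel noise is scaled to land approximately at
the requested ratio-scale SD at the diastolic level. Noise is additive
Gaussian white noise and photobleaching is a linear drift; heavier-tailed
noise, dye saturation, motion artefacts and de-interleaving of raw PMT
streams are not modelled, so passing recovery tests bounds estimator error
under these idealised conditions, not under every pathology of real data.

**Caffeine trace.** Flat diastolic, a fixed 0.5 s linear ramp to
diastolic + store amplitude at the event, then exponential decay back to
diastolic. A post-event record shorter than 3 tau triggers a truncation
warning because it visibly biases the fit.

**Oxygraph.** O2 is piecewise linear and continuous across states (so
per-state mass balance is exact by construction); safranine is constant per
state at `inversePsi(psi_state)`, with the FCCP state at `C_FCCP`.

**Cluster images.** Spot count is Poisson in the frame area at the requested
density (or fixed), sizes are lognormal around the requested mean area, and
placement is hard core (spots do not touch). At the mitochondrial-marker
operating points studied here (~11–15 clusters/um^2 with mean areas of
0.027–0.034 um^2) the labelled area fraction is ~0.4, which is at or beyond
the jamming density of random sequential placement — uniform
reject-and-resample placement is infeasible there, and overlapping Gaussian
tails would merge neighbouring spots at any half-max threshold. The
generator therefore (a) renders spots as uniform-intensity disks of the
target area with a ~1 px logistic edge roll-off (a Gaussian profile remains
available for sparse scenes), and (b) uses `placement = "auto"`: uniform
rejection sampling below a packing fraction of 0.35, and a jittered square
lattice above it, with size draws clamped to the lattice cell and the
distribution rescaled so the realized mean area still matches the request
(at the studied settings this clamps a small minority of draws and changes
the realized mean by under 2%; the manifest records realized values). The
lattice is more regular than biological mitochondria; density and area
recovery are insensitive to this, but second-order spatial statistics on
synthetic images should not be over-interpreted. The stripe-mask generator
(`genFillMask()`) produces myofibril-like banding with an exactly
accountable fill fraction for fractional-area checks.

**Group study.** `genGroupStudy()` draws per-cell parameters from Gaussians
around the two groups' reported means. Only summary statistics are
published, so per-cell SDs are reconstructed as SEM x sqrt(n) with the
reported cell counts; for image sections a 10% between-section coefficient
of variation is used (the published image-level dispersions are heart-level
summaries that do not translate to a per-section spread). Non-positive
draws are redrawn (truncation). The default study size (24 cells and 6
image sections per group) was set by a power calculation so that each
configured effect direction reproduces in a single seeded run with ~99%
probability under these spreads. The manifest lists the checked directions;
they are the statistically established effects of the source study
(beta-adrenergic amplitude, rate-of-rise and decay-tau responses in
controls; larger mitochondrial transients, larger caffeine store and faster
caffeine decay in the hypertrophic group; smaller/denser mitochondrial
clusters). A control-vs-disease baseline cytosolic-amplitude contrast is
deliberately not checked: the published summaries for it are internally
inconsistent between figure and text, and under the figure's numbers the
contrast is not statistically reproducible. Cells whose response falls below
the acceptance noise floor are skipped as non-responders during analysis,
as in experimental practice.

## Numerical choices

* Monoexponential fits use Levenberg–Marquardt (`minpack.lm::nlsLM`) with
  starting values from the decay tail (offset) and the 1/e crossing of the
  lightly smoothed, offset-corrected signal (robust to noise-dominated
  tails, where a log-linear slope estimate can explode); two fallback
  starts at span/5 and span/20 are tried before declaring non-convergence.
  A non-convergent per-beat fit keeps the beat but marks tau invalid with a
  reason.
* Time grids must be uniform to 1 part in 10^6 of the median step;
  non-finite samples are rejected at read time rather than imputed, because
  silent interpolation corrupts kinetics. Time is 0-based; all windows are
  half-open `[start, end)`.
* An optional per-channel constant background (`computeDff(background=)`)
  covers the unstated possibility of dark-count subtraction; the default is
  0.
* Connected components: EBImage's 4-connected labelling plus a union-find
  merge across diagonal adjacencies yields 8-connectivity.
* Rate-of-rise and time-to-peak of sampled waveforms carry O(dt^2)
  discretisation error; at 400 Hz this is <0.1% for the kinetics studied
  but grows toward ~2% for rise times under ~50 ms. The property tests
  assert recovery at these sampling bounds, which are bounds of the data,
  not of the estimators.

## Problem sizes used in the shipped checks

The recovery suite uses 100 seeded replicates of 20-beat 1 Hz traces for
the decay-tau check, a single 20-beat 0.1 Hz trace for the dF/F0 amplitude
check, 50 seeded caffeine transients per group parameterisation, 40
replicate two-group caffeine studies at the reported cell counts (21 vs 16),
a four-state noiseless oxygraph protocol, 15 x 15 um images at 15 nm pixels
for the cluster checks, and a full two-group study of 24 cells and 6 image
sections per group. These sizes make every check reproducible on a single
CPU in a few minutes while keeping Monte-Carlo error well inside the stated
tolerances.

## Known limitations

* Ratio traces are reported in arbitrary ratio units; conversion to absolute
  calcium via indicator Kd calibration is out of scope.
* The caffeine decay measures total trans-sarcolemmal efflux; decomposition
  into exchanger/pump/uniporter components is not computable from a single
  trace.
* Safranine-O inhibits respiration slightly at higher concentrations; the
  package treats the supplied signal as calibrated and makes no correction.
* Images are single 2-D frames: no deconvolution, no 3-D clusters, no
  time-lapse, and myocyte ROIs must be supplied, not auto-segmented.
* Vendor binary formats (respirometer and photometry acquisition files) are
  not parsed; inputs are delimited text and TIFF with JSON sidecars.
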