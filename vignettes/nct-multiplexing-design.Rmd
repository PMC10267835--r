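---
title: "Designing single-color multiplexed NCT experiments in silico"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing single-color multiplexed NCT experiments in silico}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The problem

Nascent chain tracking (NCT) images translation of single mRNA molecules in
live cells: tandem epitope repeats in the coding sequence are bound by
fluorescent antibody fragments as the nascent peptide emerges, so each
translating mRNA appears as a fluctuating diffraction-limited spot. Because
only a few spectrally resolvable fluorophores exist, classical NCT watches
one or two mRNA species per cell. `nctmux` implements a simulation-based
design loop for *temporal multiplexing*: discriminating identically tagged
species by the statistics of their intensity fluctuations — their brightness
distribution and their fluctuation frequency content — rather than by color.

The package covers the full loop: mechanistic simulation of translation,
realistic video synthesis and re-quantification, feature extraction, a
dual-input 1D convolutional classifier, and analytic calculators that locate
the degenerate parameter manifolds where no classifier can succeed.

# The translation model

Translation is modeled as a codon-dependent totally asymmetric simple
exclusion process (TASEP). A construct of `n` codons carries per-codon
stepping rates `lambda_j`; ribosomes occupy a 9-codon footprint, so two
ribosomes never come closer than 9 codons. Initiation attempts arrive at
rate `k_i` (1/s) and succeed only when the first 9 codons are clear; blocked
attempts are discarded. A ribosome at codon `j` steps to `j + 1` at rate
`lambda_j` unless the ribosome ahead is within the footprint, and
terminates from the last codon at that codon's rate. The simulation is
event-driven and exact (direct-method stochastic simulation); we chose an
exact sampler over fixed-step approximations because the second moments and
autocorrelation times that drive classification are sensitive to
discretization error.

Spot intensity is reported in *units of mature protein* (UMP): the epitope
profile `f(j)` counts the fraction of intact epitopes fully translated when
a ribosome sits at codon `j`, and intensity is the sum of `f` over ribosome
positions. Two ribosomes past a 10-epitope tag plus one halfway through it
give 2.5 UMP.

Rate assignment has three modes. `construct_normalized` (default) makes
per-codon rates proportional to the codon's usage weight, scaled so the
construct's collision-free transit time is exactly `n / k_e`; this pins the
dwell times of the two reference constructs (354 s and 517 s at
`k_e = 5.33` aa/s) regardless of the synthetic codon composition.
`uniform` sets every rate to `k_e` (used by the analytic oracles), and
`genome_normalized` fixes the usage-weighted genome-mean stepping rate at
`k_e`, letting per-construct transit depend on composition.

## Sparse-loading calculators

Neglecting collisions, ribosome arrivals are Poisson and the spot is a
filtered Poisson process. For an N-terminally tagged construct of total
length `L` NT with tag length `L_tag` NT and transit time `tau`:

* mean intensity: `(1 - L_tag / (2 L)) * tau * k_i` (the tag ramp
  contributes half its length on average);
* variance (Campbell's theorem): `k_i * tau * mean_j f(j)^2`;
* the *critical initiation-rate ratio* at which two constructs' mean
  intensities coincide, `[(1 - L_tag/(2 L_B)) tau_B] / [(1 - L_tag/(2 L_A))
  tau_A]` (0.662 for the reference pair at the printed transit times); and
* the *critical elongation-rate ratio* at which both the means and dwell
  times coincide — the codon-count ratio, 1.46129 for the reference pair.
  On that manifold the pair is unclassifiable by any amount of video, and
  the remedy is tag redesign (`make_tag_variant()`).

(The companion figure annotation in the source work quotes 0.648 for the
initiation-rate manifold while its displayed equation evaluates to 0.662;
we expose the equation's value.)

# What the synthetic data emulate

`generate_synthetic_gene()` draws sense codons i.i.d. from a bundled human
codon-usage table at the exact published gene lengths (1200-7257 NT
ladder), so no sequence download is required; real coding sequences can be
supplied as FASTA. The default tag is a representative 10x FLAG design:
ten `DYKDDDDK` epitopes, each preceded by a 25-aa glycine-serine linker,
padded to exactly 1011 NT (337 codons); all downstream statistics depend
only on the tag length and the epitope completion positions, not the exact
linker chemistry. An epitope becomes countable at the codon where its last
residue is translated (probe-binding kinetics are not modeled). Epitopes
spaced evenly through the tag make the profile's mean `1 - L_tag/(2L)`,
matching the sparse-loading closed forms.

The imaging layer emulates the statistical role of real calibration videos
without shipping them: a parametric background with an elliptical cell
mask, a brighter nuclear region, smooth random lumpiness and a
diffraction-like blur; every frame draws each pixel independently from a
Normal with that mean field and an sd field `2 + 0.5 sqrt(M)`. Spots
follow Brownian motion (default `D = 0.21` pixel^2/s, the value used in
the published sweep tables; the source work also quotes 0.925 um^2/s and
0.55 pixel^2/s in other sections — the coefficient is configurable and no
reconciliation is attempted) with mirrored steps at the mask edge. Each
spot adds an isotropic Gaussian PSF (sigma 1 pixel at 130 nm/pixel)
integrated over a 3x3 pixel patch at its sub-pixel position. Videos are
re-quantified with the disk-and-doughnut readout: mean of the 3x3 disk at
the rounded spot position minus the mean of the surrounding 9x9 annulus.
Perfect tracking (the simulated coordinates) is the default analysis path;
spot detection and track linking are out of scope.

Because the readout only ever uses the 9x9 neighborhood,
`simulate_nct_traces()` draws exactly that neighborhood per spot and frame
instead of materializing full 512x512 frames; it is identical in
distribution to `render_video()` followed by `extract_intensity()` (a test
asserts this) and makes large sweeps tractable.

**SNR definition.** The source work never defines its SNR numerically. We
define it as the mean disk-and-doughnut readout of a spot held at the
reference species' mean intensity divided by the standard deviation of the
same readout on spot-free probes moving through the background. The
rendering gain is solved from this definition per video; species sharing a
video share the gain, so their SNRs scale with their mean intensities —
with the reference species at SNR 6.2 the brighter partner lands near 8.9,
reproducing the published coupling. Including motion in the noise
measurement matters: the dominant non-photon noise source is the readout
fluctuation as a spot crosses background structure.

What the generator does *not* emulate: z-stacks and maximum-intensity
projection, camera EM-gain statistics, photobleaching by default (an
exponential hook `apply_photobleach()` exists but is unstudied here),
tracking errors, and non-stationary perturbations. Classifiers that pass
on these simulations therefore demonstrate the information content of the
modeled fluctuations, not robustness to every laboratory artifact.

# Features and classifier

Each video is min-max normalized with extrema over *all spots and all
frames of that video*, preserving relative brightness between spots. The
second input is the normalized empirical autocorrelation
`G(tau) = 1/(T-1-tau) sum_t z_t z_{t+tau}` with `z` the per-trace z-score
under the population (divide-by-T) standard deviation. We keep the printed
estimator verbatim rather than renormalizing, so `G(0) = T/(T-1)`, and we
feed the full lag range `0..T-2` to the classifier (the truncation policy
of the original is unstated). Constant traces (no signal, e.g. failed
spots) are flagged and routed to the noise-class pathway.

Test videos are normalized with the *same min-max procedure* as the
training videos: each video by its own global extrema. The alternative
reading — re-applying the raw pooled training extrema to test videos — is
also supported (`generate_test_features(extrema = ...)`) but is not the
default: the pooled training range always exceeds a single video's range,
so it compresses every test feature and systematically shifts spots toward
their dimmer length-neighbor class, which measurably destroys multiclass
accuracy. Per-video normalization keeps training and test features on one
distributional scale; the pooled extrema are still stored on the trained
classifier for provenance.

The classifier is a dual-branch 1D CNN: each input feeds its own conv1d
(shared kernel size and filter count across branches) with ReLU and
max-pooling (window 2), the flattened branches are concatenated into a
200-unit dense layer, and a softmax output is trained end-to-end with
cross-entropy and elastic-net weight regularization. No deep-learning
framework ships with this package's target environment, and the network is
tiny (inputs of ~64 points), so the package implements the forward/backward
pass directly on BLAS-backed matrix algebra with Adam (lr 1e-3, default
`l1 = l2 = 1e-5`; the original reports the architecture and search grid but
not the optimizer, so we default to a standard adaptive first-order
optimizer). Training follows the published protocol: an 80:20 train/test
split, hyperparameters drawn by random search from the 54-cell grid
(kernel 3/5/7, filters 16/32/64, batch 16/32/64, epochs 50/100) maximizing
3-fold cross-validated accuracy, then one final fit and a single withheld
evaluation. The search budget is unstated in the original; the package
default is 15 draws without replacement, and desk-scale studies in the
tests and acceptance script use 3 draws with a CV epoch cap as their
reduced-replication setting. Single-branch ablations (`branches =
"intensity"` / `"frequency"`) reproduce the intensity-only and
frequency-only variants.

# Study conditions and problem sizes

The baseline condition (`baseline_experiment()`) is the published
reference: KDM5B (4647 NT) vs P300 (7257 NT), both 10x-tagged, `k_i =
0.06`/s, `k_e = 5.33` aa/s, 64 frames at 5 s, D = 0.21 pixel^2/s, SNR 6.2
for KDM5B. Its analytic summary reproduces dwell times 354/517 s and
sparse moments 19.3/29.1 UMP and 18.6/28.4 UMP^2. Under the 9-codon entry
exclusion the simulated steady state sits a few percent below the sparse
values (initiation attempts are discarded whenever the entry footprint is
occupied, about 7% of the time at baseline); the simulated variance is
further reduced (~14%) because exclusion anti-correlates arrivals. This is
an honest property of the stated exclusion convention, discussed again
under Limitations.

The full published protocol (100 cells with 25+25 spots at 3000 s and 1 s
resolution, 2500 spots per species per condition) is available through the
configuration arguments, but package defaults and the test suite run
desk-scale reductions chosen once: 20 training cells (1000 spots, giving
an 800-spot training split) and 10 fresh test cells (500 spots) for the
baseline accuracy study; 8 training cells per length pair; and for the
multiplexing demonstration 12 training cells with 25 spots per species
(the published training pool is drawn from such length-sweep cells, not
from the sparse multiplex cells) with 10 fresh 10-spot test cells; moment
estimation uses 200 spots x 2000 s. Long-video
studies slice full-resolution 1-s traces to the requested frame interval
and count (`slice_traces()`), exactly as the published pipeline reimages
its 3000-frame masters.

# The multiplexing demonstration

`multiplex_demo()` simulates seven identically tagged species in one cell
across two channels (green: RRAGC, LONRF2, MAP3K6, DOCK8; blue: ORC2,
TRIM33, PHIP; tag included, all at the shared baseline rates), adds a
non-translating class extracted from the spot-free channel at the same
Brownian motion, trains one multiclass model per channel, and evaluates on
fresh cells: confusion matrices, accuracy excluding the noise class, and
accuracy as a function of the fraction of least-confident non-noise spots
discarded. The per-channel SNR anchors (3.7 for the dimmest green species,
5.2 for the dimmest blue species) place the channel SNR ranges at the
published values. Softmax calibration is out of scope, as in the original.

# Numerical choices and degenerate inputs

* Seeds: every stochastic stage takes a master seed and derives
  independent child streams per cell/spot with an integer hash, so any
  sweep cell is reproducible in isolation.
* Spot centers are rounded to the nearest pixel for patch placement; a
  patch clipped by the frame edge yields a missing frame value.
* A video whose intensities are all equal cannot be min-max normalized and
  raises a degenerate-video error; constant traces are flagged instead of
  producing NaN autocorrelations.
* `k_i = 0` is legal and yields dark spots; diffusion 0 yields static
  spots; bleach rate 0 is the identity.
* Whether the published gene-ladder lengths include the stop codon is
  unstated; synthetic genes use the printed NT lengths verbatim. Both
  length conventions (with and without tag) are accepted by the
  fold-change helper; published fold thresholds include the tag.

# Known limitations

At the desk-scale multiplexing replication the channel accuracies land a
few points below the full-scale published figures (the blue channel's
length-neighbor pair is the binding constraint): over a 320-s video a
long construct completes roughly one ribosome transit, so the trace mean
carries about one independent sample of the dwell-time information, and
an independent reference classifier (a random forest on engineered
mean/sd/autocorrelation features) reaches the same ceiling as the CNN on
the same generated data. Confidence filtering behaves as published:
discarding the lower half of spots by softmax confidence raises both
channels' accuracies by roughly ten points.

* The exclusion convention (leading-edge footprint, entry requires codons
  1..9 free, blocked attempts discarded) is one self-consistent reading of
  a 9-codon footprint. It depresses the steady-state variance ~14% below
  the collision-free Campbell value at baseline occupancy, whereas the
  published moment table sits at the Campbell value, implying a weaker
  entry interference in the original implementation whose exact rule is
  not documented. Means agree within ~1 UMP; the variance discrepancy is
  visible in the moment comparisons.
* The parametric background is statistically heterogeneous but not a real
  cell; absolute SNR values are calibration targets, not predictions.
* The classifier is intentionally small and uncalibrated; reported
  confidences are raw softmax outputs.
* Accuracy at desk-scale replication carries binomial noise of a few
  percentage points; full-scale settings reduce it but take hours per
  condition.
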