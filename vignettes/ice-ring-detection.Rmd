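---
title: "Detecting ice-ring artefacts in merged reflection data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting ice-ring artefacts in merged reflection data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Macromolecular crystals are usually cryocooled before X-ray data collection.
Cryocooling can deposit small hexagonal ice crystallites on or around the
sample, whose powder diffraction adds sharp rings at characteristic
d-spacings. After integration, scaling and merging, these rings survive as
narrow resolution shells in which observed intensities are systematically
inflated (or, when the shells were excluded during processing, entirely
missing). Archived structure-factor depositions rarely come with raw images,
so contamination must be diagnosed from the merged reflection data alone.
Classical statistical indicators catch strong rings but miss subtle ones
that a human recognizes instantly in an intensity-versus-resolution scatter
plot. `icering` follows the machine-learning route: render what the human
looks at as a small image, and let a convolutional network do the looking.

## Featurization: windowed 2D histograms

Hexagonal ice diffracts at approximately 3.90, 3.67, 3.44, 2.67, 2.25, 2.07,
1.95/1.92 and 1.88 Å. The package ships a table of eight lettered windows
(A-H) around these positions, computed from the ice-Ih unit cell
(a = 4.4975 Å, c = 7.3224 Å); it can be replaced by any CSV with columns
`label,d_high,d_low`. For every window fully contained in the data's
resolution span, the reflections are binned into an 80 x 80 histogram:

* **x axis** — resolution, binned uniformly in 1/d². Reflections are
  approximately uniformly dense in reciprocal volume, so this choice gives
  even column occupancy. The plotted extent is the ice-ring window plus one
  window-width of context on each side, placing the candidate ring in the
  central third of the columns with clean background around it — the
  spike-in-the-middle geometry the classifier relies on.
* **y axis** — the observed value (I~obs~ preferred, F~obs~ otherwise),
  clipped to the 0.5th-95th percentile of the in-plot values
  (linear-interpolation percentile convention). Values outside the clip
  interval are excluded rather than clamped: the purpose of the clip is to
  remove extreme outliers, and clamping would pile them onto the border
  rows. Negative merged intensities are legitimate and retained.
* **normalization** — each count grid is divided by its own maximum, making
  the network input scale-free per plot. An all-zero grid stays zero.

Orientation is fixed and documented: row 1 is the lowest value bin (the
"bottom"), column 1 the low-resolution edge, so sensitivity maps are
directly comparable across plots.

Plots are flagged *nonpredictable* when the blank discriminator fires (see
below) or when fewer than `min_reflections = 30` reflections fall in the
plotted extent; very sparse histograms are a known source of
misclassification, and a warning is more honest than a guess.

## The classifier

The network has a convolutional part — four blocks, each two 3 x 3
same-padding convolutions with batch normalization and ReLU, closed by 2 x 2
max pooling — and a fully connected part: flatten, two hidden dense layers
separated by dropout (rate 0.3), and a single sigmoid output neuron. The
score is therefore in [0, 1]; a plot is called contaminated when the score
is at least 0.5, with the tie at exactly 0.5 resolved toward flagging (the
conservative direction for artefact screening).

Default sizes are filters (6, 12, 24, 48) and dense units (48, 24). These
were chosen so that a full training run on a ~1600-plot corpus completes in
a few minutes on one CPU core while validating above 0.95 on synthetic
corpora; every size is overridable through `architecture_config()`. The
engine behind it is a purpose-built RcppArmadillo implementation
(im2col + GEMM convolutions, Adam, inverted dropout, batch-norm running
statistics) whose stochastic steps all draw from one explicitly seeded
generator, so training is bit-reproducible for a given seed.

Training (`train_network()`) splits the plots 80/20 into training and
validation at the configured seed, optimizes weighted binary cross-entropy
(inverse-frequency class weights by default — contaminated plots are
typically well under 10% of an annotated corpus), and keeps the weights of
the epoch with the lowest validation loss. `transfer_network()` continues
optimization from a trained base at the deliberately moderate rate 0.0005,
the standard recipe for adapting an amplitude-trained network to intensity
plots (or vice versa) without destroying its learned features.

A data set is judged by OR-aggregation (`predict_dataset()`): it is
contaminated when *any* predictable window is contaminated, clean when all
predictable windows are clean, and nonpredictable when no window is
predictable.

## Blank-window discrimination

Depositions sometimes omit entire resolution shells. The discriminator
(`is_blank()`) cuts each candidate window into 4 equal sub-bins (in the x
binning coordinate) and flags the window when any sub-bin is empty or has a
mean observed value below 1% of the set-wide mean. This catches both fully
and partially blank windows; such plots bypass the network entirely, since a
blank region is indistinguishable from an ice-ring exclusion zone and any
score would be misleading.

## Sensitivity maps

`smoothgrad()` averages the absolute input gradient of the sigmoid score
over noise-perturbed copies of a plot (Gaussian noise, scale expressed as a
fraction of the input range; default 25 samples at 0.1). On networks trained
on synthetic corpora the averaged maps concentrate in the upper-middle rows
of the central columns — exactly where spiked (high) values land in this
orientation — and are weakest at the left edge, top band and right band.
A secondary band of sensitivity appears at mid-height on the right: under
per-plot percentile clipping, a spike stretches the y axis and compresses
the clean background toward the bottom *everywhere*, so background height
is itself a (synthetic-data) contamination cue. Real merged data is
messier, which is one reason synthetically trained networks should not be
shipped for archival screening.

## The synthetic-data generator

The simulator exists so that every stage — featurization, training,
aggregation, evaluation — is exercisable at desk scale without any
downloads. It models exactly the two coordinates the classifier sees:

* All Friedel-unique lattice points with d >= `d_min` are enumerated for the
  chosen cell (optionally subsampled to `n_target`); intensities follow
  acentric Wilson statistics, exponential draws with mean
  A·exp(−B/(2d²)), plus Gaussian noise of scale `sigma_fraction` times the
  local mean. Amplitude sets use F = sqrt(max(I, 0)) — a crude stand-in for
  a proper Bayesian intensity-to-amplitude conversion, which is deliberately
  out of scope.
* Ice spikes multiply the intensities of a fraction *f* of the reflections
  inside a contaminated window by the spike factor *s* >= 1. "Accumulating"
  contamination (ice growing during data collection, so contaminated and
  clean observations coexist at every resolution in the window) takes a
  contiguous block of the enumeration order rather than the whole window.
* Blank shells drop all reflections of a window.

Ground-truth window labels are assigned by a computable analogue of the
plot-overlay annotation rule: a window is labelled contaminated when a spike
with s > 1 was injected **and** at least 1% of the histogram cells change
occupancy between the contaminated rendering and the clean rendering of the
same plot under the same clip limits. Borderline injections (tiny fractions,
very sparse plots) are thus labelled clean, exactly as a human annotator
ignores invisible contamination; as a consequence the realized positive
fraction of a corpus sits slightly below the injection probability. The two
non-computable annotation criteria (naked-eye visibility, visibility in the
full-resolution scatter plot) are represented by the spike-factor threshold
of the generator.

`make_corpus()` randomizes cells (32-48 Å edges), resolution limits
(1.62-1.80 Å, so all eight windows are present), Wilson B (15-40 Å²),
scales and noise, and assigns each set a difficulty regime — strong spikes
(s in 4-8), weak spikes (2.2-3.5), accumulating (f in 0.3-0.7), or low
reflection counts (600-1500) — with a small fraction of sets given a blank
window. The default injection probability is 0.075 per window, mirroring
the strong class imbalance of annotated archives.

**What the simulator does not model:** spot shape, profile fitting and
integration artefacts, space-group symmetry beyond Friedel pairing,
anisotropy, twinning, the French-Wilson posterior for weak intensities, and
the detailed texture of real ice rings (icing is often anisotropic and
multi-ring). Passing synthetic tests therefore demonstrates that the
pipeline and the learning machinery are sound — not that a synthetically
trained network transfers to archival depositions. For real use the network
should be trained on annotated real plots; the package's I/O accepts them
in MTZ or text form.

## Numerical choices and degenerate inputs

* Percentiles use the linear-interpolation convention, stated explicitly so
  tests can be exact.
* Histogram bins are left-closed with a closed final edge on both axes;
  clip-interval membership is inclusive on both ends.
* A constant-valued window (clip_lo = clip_hi) puts all reflections in the
  bottom row rather than failing.
* Batch normalization uses eps = 1e-5 and running-statistic momentum 0.9;
  Adam uses (0.9, 0.999, 1e-8).
* Reflections with non-finite values or negative sigmas are dropped with a
  message at construction; (0,0,0) is rejected.
* The MTZ reader handles both byte orders, treats the missing-number flag
  (NaN by default) as absent data, and refuses unmerged (batch-carrying)
  files.

## Problem sizes used in the shipped tests

The test suite trains on a 250-set corpus (~2000 plots, 1600 for training)
for 8 epochs per seed, three seeds; the transfer experiment uses two
80-set corpora; oracle comparisons run on 100 random small instances.
These sizes were chosen as the smallest at which the statistical checks are
stable; they complete in minutes on a single core.

## Known limitations

* The default window table is derived from ideal ice-Ih lattice constants;
  beamline-specific calibration or exotic ice polymorphs need a custom
  table.
* The severity of a detected ring is not graded — detection only.
* CIF to MTZ conversion and space-group-aware merging are out of scope; the
  reader expects merged data.
* OR-aggregation is deliberately alarm-prone: one false-positive window
  flags the whole data set, which matches screening use but inflates
  dataset-level false positives when many windows are evaluated.

## A worked example

```{r, eval = FALSE}
library(icering)

# simulate a contaminated data set (spike in window E, factor 6)
sim <- simulate_reflections(simulation_params(
  unit_cell(41, 43, 39), d_min = 1.7,
  contaminated_ranges = data.frame(label = "E", spike_factor = 6,
                                   affected_fraction = 1),
  n_target = 8000, seed = 1))

# train a classifier on a labelled synthetic corpus
corpus <- make_corpus(100, fraction_contaminated = 0.15,
                      spike_range = c(3, 8), seed = 2)
td <- corpus_training_data(corpus)
model <- train_network(td$x, td$y, tc = training_config(seed = 3),
                       kind = td$kind)

# per-window report and dataset verdict
predict_dataset(model, sim$set)
```
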