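---
title: "Dual-stream modelling of EEG differential-entropy features: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dual-stream modelling of EEG differential-entropy features}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(eegfusion)
```

This vignette is the package's own account of what it computes, which
choices were genuinely open, and what the synthetic experiments do and do
not demonstrate.

## The feature model

EEG emotion decoding rests on band-power contrasts that differ across the
scalp and evolve over seconds. The package's feature pipeline encodes a
trial as a sequence of topographic log-power maps:

1. **Band-pass filtering.** 4th-order Butterworth filters (designed by
   `signal::butter`), applied forward and backward for zero phase, with
   one second of odd-reflection padding at each edge to suppress start-up
   transients. The two passes square the magnitude response, which is why
   a tone at a band centre passes essentially unattenuated while tones in
   non-adjacent bands are suppressed below 1% power. Band edges (theta
   4–8, alpha 8–13, beta 13–30, gamma 30–45 Hz) are the conventional
   split in this literature and are configurable per band.

2. **Differential entropy.** For a band-limited Gaussian signal the
   differential entropy has the closed form DE = ½·ln(2πe·σ²). The
   package computes exactly this, with σ² the sample variance of a
   filtered window. A discrete Shannon-sum reading of entropy is not
   well defined on continuous-valued samples without a binning rule, so
   the closed form *is* the estimator; a histogram plug-in estimator
   exists in the test suite purely as an independent oracle (they agree
   within 0.05 nats at n = 10⁵). Windows with variance below 1e−12 are an
   error in the scalar API; inside the bulk pipeline they are clamped to
   that floor so a fully attenuated channel degrades gracefully instead
   of aborting a whole dataset.

3. **Spatial mapping.** Channels are placed injectively on an 8×9 grid
   (row 0 frontal, column 0 left). The shipped 62-channel cap fills 62 of
   the 72 cells; cells without an electrode are *structurally zero* and
   stay zero through every later stage, including normalisation. The
   62-electrode-to-cell assignment is a documented package default (no
   canonical table exists); any injective mapping can be supplied.

4. **4D stacking.** Six consecutive 1-s windows form one sample of shape
   (6, 8, 9, 4). The stride between samples is configurable: 1 window
   (maximal overlap) by default in `assemble_4d`/`extract_features`, 6
   windows (non-overlapping samples) in the reference experiment profile,
   where sample count, not overlap, drives compute.

   One interpretive point: the three per-step axes are read as 8 grid
   rows × 9 grid columns × 4 frequency bands (a topographic map per
   band). An alternative reading — electrode groups × bands × other
   features — circulates in prose descriptions of this tensor shape; the
   topographic reading is the one that makes the CNN's spatial weight
   sharing meaningful, and is the one implemented.

5. **Per-subject normalisation** z-scores all of a subject's feature
   values (electrode-bearing cells only) by that subject's own mean and
   standard deviation. This removes global gain and offset differences
   between subjects. It deliberately does *not* remove per-band or
   per-channel subject idiosyncrasies — doing so would also remove real
   class signal — which is why leave-one-subject-out evaluation stays
   strictly harder than subject-dependent folds.

## The dual-stream classifier

Each time-step map is encoded by a small CNN (3×3 "same" convolutions,
ReLU, ceil-mode 2×2 max-pooling; two blocks by default) whose weights are
shared across the six steps — the test suite certifies this by
reconstructing the full forward pass from the public per-component
operations. A bidirectional LSTM (standard forget/input/output gate
recursion, verified against a scalar oracle) consumes the six step
features; its forward and backward final states merge by concatenation by
default (sum and average are selectable; average ≡ sum/2 exactly).

The probabilistic stream is a convolutional VAE in the DC-IGN family: the
(8, 9, 4) × 6 sample is reshaped to an 8×9×24 volume, encoded by stride-2
3×3 convolutions (channel ladder 32–64–128 by default) into a diagonal
Gaussian q(z|x) = N(μ, diag(σ²)) with a 64-dimensional latent by default.
The described full-scale ladder for this architecture family (five 5×5
stride-2 layers, channels 64→1024, a 7×7×1024 map, 256 latents) implies
~224×224 image input and cannot act on an 8×9 map; the package keeps the
family but scales the ladder to the actual input, and the full-scale
ladder remains expressible through `model_config` for image-sized inputs.
The decoder mirrors the encoder with nearest-neighbour-upsample +
convolution blocks ("resize-convolution") rather than transposed
convolutions: gradients are simpler, checkerboard artifacts are avoided,
and the "gradually upsample and reconstruct" structure is preserved.

Two places were genuinely underdetermined and are package decisions:

* **What the VAE stream sees.** The raw stacked features, not the CNN
  output — keeping the two streams independent until fusion maximises the
  diversity the fusion layer can exploit.
* **What fusion consumes.** The latent *mean* μ, not a sample z, so that
  evaluation is deterministic; sampling only affects the reconstruction
  path during training.

The loss is CE + λ·MSE + β·KL with λ = β = 1 by default (the unweighted
ELBO next to the classifier term); both weights are exposed, and λ = β = 0
reduces the model to a pure CNN-BiLSTM classifier.

All forward/backward passes are hand-implemented on BLAS matrix
primitives. Correctness is guarded by a central-difference gradient check
(relative error below 1e−4 required; observed ~1e−10). One numerical
subtlety: biases initialise to zero while upsampled ReLU-sparse maps can
make a whole receptive field zero, so pre-activations sit exactly on the
ReLU kink where finite differences are invalid — the gradient check
therefore evaluates at a generic point (small random offset on all
parameters), which is a property of the *check*, not of training.

## Training and schedules

Adam (β₁ = 0.9, β₂ = 0.999), batch 64, 80 epochs by default; the epoch's
learning rate comes from one of five closed-form schedules. The
piecewise-exponential policy applies a per-epoch decay factor per segment
and is kept continuous at segment boundaries; defaults (boundaries 30/60,
factors 1, 0.95, 0.9, lr₀ = 1e−3) are package choices — no canonical
values exist — and every schedule's parameters are exposed. Schedules are
epoch-granular: the simplest reading of adjusting the rate "in different
periods of training".

Training is exactly reproducible: initialisation, batch order and the
reparameterization noise all derive from one seed, and each
cross-validation fold gets an independent derived seed so fold accuracies
are independent draws for the Std estimate.

## The synthetic study and what it shows

The generator's reference conditions are 8 subjects × 3 classes × 20
trials × 60 s at 200 Hz on the 62-channel cap (seed 42). Classes are
band-power signature matrices over frontal/central/posterior row-blocks
(e.g. the negative class is frontal-theta dominant, the positive class
beta/gamma dominant); a multiplier of 1 corresponds to 25 µV² of band
power. Subjects draw per-channel log-normal gains (sd 0.3), per-band
log-power offsets (sd 0.4) and 2–4 µV baseline noise; trials draw
log-normal band-power jitter (sd 0.3). These values were chosen once as
plausible magnitudes for between-subject and between-trial variability in
band-power space: offsets of sd 0.4 shift a band's DE by ±0.2 nats,
commensurate with the ½·ln(multiplier) class contrasts of 0.35–0.55
nats, so subject identity genuinely competes with class identity —
without that, the two evaluation protocols would not separate.

Band components are synthesised in the frequency domain on disjoint bins
and rescaled so realised band power equals its target exactly; a 4×
multiplier therefore yields a 4× periodogram power ratio up to
measurement leakage. Filtered Gaussian noise (not sinusoids) keeps the
Gaussian assumption behind the DE closed form approximately true.

The reference experiment profile (stride-6 sampling → 4800 samples; CNN
channels 6–12; H = 24; VAE ladder 6–12–24 with 12 latents; 6 epochs of
Adam at lr₀ = 2e−3 under piecewise-exponential decay, batch 128) is sized
so that the full study — featurisation plus thirteen model fits (5-fold +
LOSO) — completes in minutes on one CPU; accuracy saturates within 2–3
epochs at these signal strengths, so the small profile costs nothing
measurable. The acceptance script runs the same pipeline at 6 subjects
(11 fits) for the same reason. With these conditions the package's own
tests compute: subject-dependent 5-fold accuracy ≈ 99.7%, LOSO ≈ 86%,
LOSO strictly below the subject-dependent figure.

What this does and does not show: the synthetic study validates the
*mechanics* — feature organisation, normalisation, both network streams,
schedules, both CV protocols, and the direction and rough size of the
subject-dependent/LOSO gap. It does not emulate ocular or muscle
artifacts, 1/f background spectra, electrode drift, volume-conduction
correlations between channels, or label noise, so absolute accuracies
here say nothing about accuracies on real recordings; published results
on the access-controlled film-clip and music-video datasets are not
reproducible from this package and are not claimed.

## Degenerate inputs and numerical conventions

* Constant windows: scalar DE errors; the bulk pipeline clamps variance
  at 1e−12.
* Max-pooling ties resolve to the first element (deterministic).
* Softmax subtracts the column maximum; cross-entropy uses
  log-sum-exp, so saturated logits are exact.
* `logvar → −∞` in `reparameterize` collapses to z = μ.
* Subjects with fewer than two samples, or zero feature variance, are
  errors in normalisation; classes absent from a test fold give NA
  per-class accuracy, flagged rather than thrown.
* Container and checkpoint round trips are bit-exact (R serialisation of
  double arrays), which the determinism tests rely on.

## Known limitations

* The spectral realism gaps listed above.
* The schedule-comparison harness demonstrates a *directional* property
  (decay rescues an over-large initial rate, measured on seed-averaged
  final loss); individual seeds can fluctuate, which matches the
  stochastic nature of the quantity.
* Adapters for real recording formats are out of scope; the dataset
  container is this package's own serialised format.
* Training is single-threaded CPU R; it is sized for the study above,
  not for large-scale hyperparameter sweeps.
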