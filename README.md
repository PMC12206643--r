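# eegfusion

Emotion-state decoding from multi-channel EEG with 4D differential-entropy
features and a dual-stream neural classifier, plus a fully synthetic EEG
generator so the entire pipeline can be exercised and tested without access
to restricted recordings.

## The method

EEG emotion decoders face two structural problems: the discriminative
signal lives jointly in frequency, scalp location and time, and raw
amplitudes differ wildly between subjects. The pipeline implemented here
addresses both:

1. **4D feature organisation.** Each trial is band-pass filtered into the
   four classical bands (theta 4–8, alpha 8–13, beta 13–30, gamma 30–45 Hz)
   and cut into 1-s windows. For each (window, channel, band) cell the
   *differential entropy* is computed under the Gaussian closed form

   DE = ½ · ln(2πe·σ²)  [nats],

   where σ² is the sample variance of the band-filtered window — a
   log-power feature with well-behaved scale (DE(a·x) = DE(x) + ln a).
   Per-band DE values are arranged on an 8×9 scalp grid (62- and
   32-channel montages ship with the package), the four band maps are
   stacked, and six consecutive windows form one sample of shape
   (6, 8, 9, 4): time × rows × columns × bands.

2. **Per-subject standardisation.** Every subject's feature values are
   z-scored with that subject's own mean and standard deviation, removing
   between-subject gain and baseline offsets before any training.

3. **Dual-stream network.** A CNN (3×3 kernels, ReLU, 2×2 max-pooling,
   weights shared across the six steps) encodes each time-step map; a
   bidirectional LSTM over the six step features captures temporal
   dynamics (merge modes: concatenation, sum, average). In parallel, a
   convolutional variational autoencoder (DC-IGN-style strided-conv
   encoder, diagonal-Gaussian latent, upsample-conv decoder) models the
   stacked tensor probabilistically. A fully connected head fuses the
   BiLSTM feature with the latent mean μ and classifies through softmax.
   Training minimises CE + λ·MSE(reconstruction) + β·KL(q(z|x) ‖ N(0, I))
   with Adam under one of five learning-rate schedules (constant,
   piecewise-exponential, cosine annealing, stepped, linear); the
   piecewise-exponential policy is the default.

4. **Evaluation.** Accuracy Acc = trace(confusion)/total (equal to
   (TP+TN)/(TP+TN+FP+FN) in the binary case) with the fold standard
   deviation Std = sqrt(Σ(xᵢ−x̄)²/(N−1)) across N cross-validation folds,
   under two protocols: subject-dependent 5-fold CV and
   leave-one-subject-out (LOSO).

The synthetic generator produces class-conditioned band-limited Gaussian
noise: each emotion class is a matrix of band-power multipliers over scalp
regions, each subject has per-channel gains, per-band log-power offsets and
baseline noise, and trials carry multiplicative band-power jitter. Band
components are synthesised in the frequency domain with exact power
calibration, so class contrasts in DE space are known by construction.

The forward and backward passes of the network are implemented in R on top
of BLAS (im2col convolutions, backpropagation through time, the
reparameterization trick) and verified against central finite differences
to ~1e-10 relative error.

## Worked example

```r
library(eegfusion)

cfg <- experiment_config()          # 8 subjects x 3 classes x 20 trials,
                                    # 60 s at 200 Hz, seed 42
feats <- extract_features(cfg$dataset, stride = 6L)
feats
#> <eeg_features: 4800 samples of shape (6, 8, 9, 4) [t, row, col, band],
#>  8 subjects, 3 classes, normalized>

rep5 <- run_experiment(cfg, features = feats)
rep5
#> <experiment_report [subject_dependent_kfold], schedule piecewise_exponential>
#>   fold accuracies (%): 100.00, 99.69, 99.90, 99.27, 99.79
#>   Acc 99.73%  Std 0.28
#>   per-class (%): negative 99.50, neutral 99.81, positive 99.88

loso <- run_experiment(cfg, protocol = "leave_one_subject_out",
                       features = feats)
loso
#> <experiment_report [leave_one_subject_out], schedule piecewise_exponential>
#>   fold accuracies (%): 78.33, 98.17, 89.33, 78.17, 83.50, 86.00, 92.17, 82.00
#>   Acc 85.96%  Std 6.96
#>   per-class (%): negative 91.88, neutral 83.81, positive 82.19
```

Read: with subject-dependent folds the classifier recovers the synthetic
class structure almost perfectly (99.7% mean accuracy over 5 folds, fold
std 0.28 points). Under LOSO the same model generalises to unseen subjects
at 86.0% — lower, as it must be, because the generator gives every subject
idiosyncratic band offsets that per-subject normalisation only partially
removes; the per-fold spread (78–98%) mirrors the per-subject variability
the generator injects.

A shell front end with `simulate` / `featurize` / `train` / `evaluate` /
`compare-schedules` subcommands is installed at
`system.file("cli", "eegfusion", package = "eegfusion")`; configs are YAML
(see `?read_experiment_config`).

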