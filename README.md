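# emofuse

Four-class emotion recognition (happy, sad, fear, neutral) from paired
EEG and eye-tracking recordings, for researchers in affective computing
and multimodal neurophysiology who want a fully scripted, testable
version of the attentive feature-fusion approach.

## The method

Each ~2-minute trial provides a 62-channel EEG series (nominal 200 Hz)
and a 4-channel eye series (pupil size X/Y, gaze X/Y). Preprocessing
band-pass filters the EEG to 1–75 Hz (zero-phase Butterworth), removes
per-channel baselines, strips the pupillary light reflex, and cuts both
modalities into non-overlapping 4-s windows downsampled to 60 Hz, so
every sample is a 240 × 62 EEG window aligned with a 240 × 4 eye window.

The light reflex — pupil size driven by screen luminance rather than
emotion — is removed by principal component analysis across
participants: for the panel *M* (time × participants) of one pupil
channel's z-scored responses to the same film clip, the projection onto
the first principal component estimates the shared reflex *A*, and the
retained emotional component is *B* with *M = A + B*.

Two parallel convolutional branches extract features. The EEG branch
treats a window as a time × electrode image and applies four blocks of
3 × 1 temporal and 1 × 5 spatial convolutions (ReLU, batch norm, 2 × 1
temporal max-pooling in the first three blocks); the eye branch applies
5-tap temporal convolutions with the four eye series as input channels.
Adaptive pooling maps both branches to identical H × W × C feature maps
V<sub>eeg</sub>, V<sub>eye</sub>.

Fusion selects per channel how much each modality contributes:

- V = V<sub>eeg</sub> + V<sub>eye</sub>, pooled to a channel summary
  x ∈ R<sup>C</sup> (global average pooling),
- compact descriptor y = ReLU(BN(W x)) with
  d = max(⌈C / r⌉, L), L = 32,
- two-way channel softmax
  a<sub>c</sub> = e^{A_c y} / (e^{A_c y} + e^{B_c y}),
  b<sub>c</sub> = 1 − a<sub>c</sub>,
- fused map F<sub>c</sub> = a<sub>c</sub> V<sub>eeg,c</sub> +
  b<sub>c</sub> V<sub>eye,c</sub>.

A dense head (256 units, dropout 0.2) and a 4-way softmax classify each
window; the network trains by cross-entropy with Adam (learning rate
0.001, batch 256, 100 epochs by default). Evaluation uses stratified
5-fold cross-validation grouped by trial, reporting accuracy, macro
precision/recall/F1 and Cohen's kappa.

Because the licensed recordings the method was designed for cannot be
redistributed, the package ships a synthetic generator that emulates
their structure (15 subjects × 3 sessions × 24 balanced trials) with an
analytically controlled twist: classes 0/1 differ only through EEG
signatures, classes 2/3 only through pupil/gaze dynamics, and a smooth
illumination waveform shared across subjects contaminates the pupil
channels. Every claim the test-suite checks is stated relative to this
controlled design.

## Worked example

```r
library(emofuse)

cfg <- synthetic_config(n_subjects = 6, n_sessions = 1,
                        trials_per_session = 4, trial_seconds = 120,
                        seed = 20260928)
ws  <- preprocess_trialset(generate_trialset(cfg))   # 720 windows
ws
#> Windowed multimodal dataset: 720 windows, 240 rows, 62 EEG + 4 eye channels
#>   labels: happy=180, sad=180, fear=180, neutral=180

rw  <- c(4, 8, 16, 16)  # narrow desk-scale branches
res <- ablation_run(ws, train = train_config(epochs = 30, batch_size = 64,
                                             seed = 42),
                    max_folds = 1,
                    branch_eeg = branch_config("eeg", channel_widths = rw),
                    branch_eye = branch_config("eye", channel_widths = rw))
sapply(res, function(r) r$reports[[1]]$accuracy)
#> eeg_only eye_only    fused
#>    0.820    0.653    0.947
```

The ordering is the method's central claim at desk scale: each modality
alone recognises only the contrasts it encodes (EEG separates happy vs
sad perfectly here but fear vs neutral at chance; the eye branch the
reverse), while the fused model exploits both and beats either alone.
`attention_weights(res$fused$fits[[1]], ws)` exposes the learned
per-channel weights; on windows whose classes are EEG-coded the mean EEG
weight rises (0.524 vs 0.451 in this run).

A thin command-line interface wraps the same pipeline
(`inst/cli/emofuse`; subcommands `simulate`, `preprocess`, `evaluate`,
`ablate`, `inspect-attention`, one YAML config, JSON/CSV reports and a
reproducibility manifest).

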