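# gazephysio

Joint analysis of gaze behavior and autonomic physiology during prolonged
scene viewing, for researchers in eye-tracking psychophysiology. The
package implements the full measurement-to-inference pipeline for
synchronized recordings — gaze samples in scene-camera pixels (60 Hz), ECG
(2048 Hz) and GSR (256 Hz) — together with a synthetic-data generator with
known ground truth, so every stage is validated by parameter-recovery and
calibration tests rather than by eye.

## The model at the core

Scanpaths are modeled as a two-state hidden Markov chain — a compact
**central** state and a dispersed **peripheral** state — with
Gaussian-mixture emissions per state:

p(g | s = i) = Σₘ c₍ᵢₘ₎ N(g; μ₍ᵢₘ₎, Σ₍ᵢₘ₎),  a₍ᵢⱼ₎ = p(sₜ = j | sₜ₋₁ = i).

The summary statistic is the **gaze transition entropy**

H = −Σᵢ πᵢ Σⱼ a₍ᵢⱼ₎ log₂ a₍ᵢⱼ₎   (bits, 0·log 0 ≡ 0),

where π is the stationary distribution (π A = π). H ∈ [0, 1] for two
states: 1 bit for uniform transitions, 0 for a frozen gaze; lower H means
more deliberative scanning. A subject-independent HMM is trained by
Baum–Welch on pooled fixation centroids; inside each 3-minute window only
the transition matrix is re-estimated (emissions frozen, bit-exact), and
that window's H is joined against baseline-relative physiology —
ΔHR and ΔRMSSD from Pan-Tompkins beat detection on the ECG, ΔSCL from the
GSR — for pooled Pearson correlations and 2×2 factorial ANOVA with partial
η². Spatial descriptors (σ = 10 px heatmaps, spatial entropy,
fixation/saccade statistics from a velocity-HMM segmenter, BIC-selected
region-of-interest mixtures with group reweighting) round out the gaze
side.

## Worked example

```r
library(gazephysio)

# a 15-minute session from a known chain, 20% blink dropout
A <- matrix(c(0.9, 0.3, 0.1, 0.7), 2)        # a12 = 0.1, a21 = 0.3
hmm <- default_gaze_hmm(A)
ses <- simulate_gaze(hmm, session_config(), seed = 7, duration = 900)

fs   <- segment_fixations(ses$traj)
obs  <- fixation_obs(fs)
fit  <- train_hmm(obs, init_gaze_hmm(obs, 2, 6, seed = 1007))
round(fit$A, 3)
#>       [,1]  [,2]
#> [1,] 0.902 0.098
#> [2,] 0.319 0.681
transition_entropy(fit$A)
#> [1] 0.5664899
transition_entropy(A)      # generating value
#> [1] 0.5720694
```

The recovered transition matrix sits within ±0.02 of the generating one
and the entropy within ±0.02 bits: the pipeline's estimate of "how often
gaze switches between center and periphery" is faithful at session scale.
On the physiology side:

```r
e <- simulate_ecg(mean_rr = 1000, rmssd_target = 30, duration = 300, seed = 6)
beats <- detect_r_peaks(e$record)
c(hr = heart_rate(beats, c(0, 300)), rmssd = rmssd(beats, c(0, 300)))
#>       hr    rmssd
#> 60.07338 30.14081
```

i.e. the detector recovers 60 bpm and the designed 30 ms RMSSD from the
raw waveform. The `analysis/` directory chains the stages as numbered
drivers (simulate → gaze metrics → HMM/entropy → physiology → stats),
writing tables under `results/`.

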