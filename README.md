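# rppgmamba

Multi-task remote photoplethysmography (rPPG) in R: simultaneous estimation
of heart rate (HR), blood-oxygen saturation (SpO2), respiration rate (RR)
and the blood-volume-pulse (BVP) waveform from **spatial-temporal maps**
(STMaps) of facial video.

## Who this is for

Researchers in camera-based physiological measurement who want a fully
inspectable, desk-scale implementation of a hybrid
convolution + selective state-space (Mamba-style) + attention estimator —
trainable and verifiable on one CPU with no dataset download, no GPU and
no deep-learning framework. Every forward and backward pass is implemented
in the package and checked against finite differences and independent
oracles.

## The model

An STMap stacks per-frame means of facial ROI blocks as image rows, so an
H×W×3 array carries H colour time series. The network is:

* **Stem + residual conv blocks** — two stride-2 3×3 convolutions, then
  residual layers `α̂ = GELU(BN(Conv(α)))`, `α ← BN(Conv(α̂)) + α` with
  stride-2 downsamplers (widths C, 2C, 4C, 8C at strides 4, 8, 16, 32).
* **Hybrid stages** — tokens scanned along the temporal axis through
  pre-norm residual *integrator* layers built on the zero-order-hold
  discretized state space

      ψ' = Aψ + Bρ,  φ = Cψ;   Ā = exp(ΔA),  B̄ = (ΔA)⁻¹(exp(ΔA) − I)·ΔB,  C̄ = C

  with input-dependent (selective) Δₜ, Bₜ, Cₜ and a scan-free "vice" path,
  followed by multi-head attention layers; two stages separated by a
  stride-2 sampler.
* **Gated multi-task heads** — a pooled task-shared representation `r` is
  filtered per task by a sigmoid gate `σ = Sigmoid(LN(Linear(ReLU(LN(Linear(r))))))`,
  `r' = σ ⊙ r`, feeding one linear head per scalar vital; the BVP head
  reads the pre-pooling token sequence.
* **Loss** — `L = θ(w₁·L_SpO2 + w₂·L_RR + w₃·L_BVP) + L_HR` with L1 scalar
  losses, negative-Pearson waveform loss `1 − ρ`, and a linear warm-up
  ramp θ.

A synthetic STMap generator with known ground truth (harmonic pulse,
respiratory AM/FM, ratio-of-ratios SpO2 encoding `SpO2 = 110 − 25R`,
configurable noise) plus an independent Welch-spectrum HR oracle make the
whole method testable end to end.

## Worked example

```r
library(rppgmamba)

# 40 synthetic samples at moderate noise, 30 Hz, 64x256 STMaps
cfg  <- synthConfig(nSamples = 40, noiseSd = 0.25, seed = 1)
data <- makeSyntheticDataset(cfg)
sp   <- trainTestSplit(data$samples, 0.8)

model <- rppgModel(modelConfig(cEmbed = 8, n1 = 1, n2 = 1, nMp = 2,
                               nHeads = 2, sState = 8, dR = 64), seed = 1)
res <- trainModel(model, sp$train,
                  trainConfig(batchSize = 8, nIters = 150, seed = 1))
rep <- evaluateModel(model, sp$test)
cat(sprintf("HR MAE %.1f bpm | SpO2 MAE %.1f %% | RR MAE %.1f /min | BVP 1-rho %.2f\n",
            rep$hr$mae, rep$spo2$mae, rep$rr$mae, rep$bvpNegPearson))
```

```
HR MAE 8.6 bpm | SpO2 MAE 2.3 % | RR MAE 5.3 /min | BVP 1-rho 0.64
```

After 150 steps on 32 samples the model is already tracking the waveform
(negative-Pearson 0.64 means correlation ≈ 0.36) and has pulled HR MAE to
8.6 beats/min against 15.9 for the constant-mean baseline on the same
split (`constantBaselineMetrics`). Longer training at the shipped
experiment sizes (200 train / 300 steps) reaches HR MAE ≈ 2–3 beats/min
and BVP correlation ≈ 0.9. An untrained check of the generator labels:

```r
s <- makeStmapSample(synthConfig(noiseSd = 0, seed = 5), 1)
c(truth = s@truth@hr, oracle = spectralOracleHR(s@stmap, refine = TRUE))
#>    truth   oracle
#> 110.6268 110.5210
```

A thin CLI mirrors the package functions
(`inst/cli/rppgmamba synth|train|eval|sweep-layers|ssm-check`).

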