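# eegfuse

Noise-robust analysis of multichannel EEG in R: MIMO subspace denoising,
band-wise differential-entropy features, and a band-attention graph
classifier, with a seeded synthetic-data module so the whole chain is
testable against known ground truth.

## Who this is for

EEG/BCI researchers who need (a) a principled multichannel noise-reduction
front end whose behavior can be verified on simulated scenes, and (b) a
reference implementation of the band-attention graph classification
pipeline used in subject-independent emotion recognition, runnable on a
single CPU without any deep-learning framework.

## The method

**Denoising.** All processing happens in the STFT domain (64 ms windows,
50% overlap). Per frequency bin *k* and frame *l*, a multichannel
minima-controlled recursive averaging (M-MCRA) tracker maintains the noise
covariance

    R_nn(k,l) = a_d(k,l) R_nn(k,l-1) + [1 - a_d(k,l)] Y(k,l) Y(k,l)^H ,

where the smoothing coefficient `a_d` rises with the signal-presence
probability so genuine activity never contaminates the noise estimate.
The pencil (R_yy, R_nn) is jointly diagonalized, `R_yy V = R_nn V Λ`; each
generalized eigenvalue λᵢ is the (signal+noise)/noise ratio of its
component, and each retained component receives the parameterized Wiener
gain

    g_i = (λ_i − 1) / (λ_i − 1 + μ) ,

with μ scheduled from 1 (SNR ≥ 20 dB) to 1201 (SNR < −5 dB) by linear
interpolation. The filtered spectrum `X̂ = V^{-H} G V^H Y` (noise-subspace
gains zeroed) is returned to the time domain by inverse FFT and
overlap-add.

**Features.** The denoised signal is decomposed into δ, θ, α, β, γ bands;
each 1 s window yields the differential entropy `0.5 ln(2πe σ²)`, smoothed
per channel/band by a linear dynamical system, producing a
`(trials, 62, T, 5)` tensor.

**Classification.** Per band: a hierarchical 1×5 convolution stack
(64→128→256 filters), a self-adaptive channel adjacency
`E = softmax(A + S)` with top-k sparsification, and spectral graph
convolution `H' = σ(D̂^{-1/2} Ê D̂^{-1/2} X Θ)`. The five band vectors are
fused by single-head attention `A = softmax(QKᵀ/√d_k)` into
`Z = [flatten(X′); mean(X′)] ∈ R^{372}` and classified; evaluation is
leave-one-subject-out with accuracy, multiclass MCC, macro-F1 and a paired
t-test. All forward/backward passes are hand-derived matrix computations
(Adam optimizer included), fully seeded.

## Worked example

```r
library(eegfuse)

# a 62-channel, 60 s scene at 0 dB input SNR with spikes, 1/f and line noise
rec <- generate_recording(scene_config(seed = 1))
dn  <- denoise_recording(rec$noisy, 200, reference = rec$clean)
round(c(snr_in = dn$snr_in_db, snr_out = dn$snr_out_db,
        gain = dn$snr_out_db - dn$snr_in_db), 2)
#>  snr_in snr_out    gain
#>    0.00    3.21    3.21
```

The input mixture sits at exactly 0 dB SNR by construction; blind subspace
filtering recovers about 3.2 dB. (An oracle given the true noise
covariance gains ~6.3 dB with the same filter — the rest is the price of
blind noise tracking.)

```r
lf <- generate_labeled_features(labeled_feature_spec(seed = 5))
ev <- loso_evaluate(lf$features, lf$labels, lf$subjects,
                    config = train_config(lr = 0.003, epochs = 8,
                                          batch_size = 32, seed = 1))
round(100 * ev$mean, 1)
#> accuracy      mcc       f1
#>     98.9     98.5     98.7
```

Nine simulated subjects, three classes with distinct band-power patterns:
the full backbone + attention classifier recovers the class structure on
held-out subjects almost perfectly, confirming the training machinery
(the features are separable by construction — this is a correctness check,
not a claim about real EEG).

A thin CLI wrapping the same functions lives at `inst/cli/eegfuse`
(subcommands `validate`, `simulate`, `denoise`, `run`), driven by a YAML
config validated against the package schema; see `?validate_config`.

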