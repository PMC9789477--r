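# FrontalGait

Video-based scoring of Parkinson's disease gait severity from a single
front-facing RGB camera. The package is aimed at movement-disorder
researchers and biomedical engineers who want an inexpensive,
marker-free estimate of the UPDRS-gait item (0 = healthy, 1 = mild
shuffling, 2 = short-shuffling steps with festination) from ordinary
walk-toward-the-camera recordings.

## Method

A walking subject's silhouette is detected frame by frame; the
bounding-box height `Sh_i` grows as the subject approaches the camera
and shrinks as they walk away, and it rises in spurts — constant while
the legs pass each other, stepping up when the legs are maximally apart.
This height signal is the only measurement the method needs.

Per recording the pipeline is:

1. **Face-height adjustment** — divide `Sh_i` by the detected face
   height `fh` (anthropometrically proportional to stature), removing
   inter-subject height differences.
2. **Normalization** — min-max rescale to [0, 1], removing camera
   placement: `Sh_i <- (Sh_i' - min) / (max - min)`.
3. **Smoothing and quantization** — 5-frame moving average, then
   5-frame partitions replaced by their mean, producing the
   plateau-and-rise staircase that exposes gait events.
4. **Forward/backward split** at the first global maximum (closest
   approach / turn).
5. **Five features**:
   * `S_avg` — mean stride time from the event timestamps `Ts`:
     stance `ST(i) = Ts(i+1) - Ts(i)`, swing `SW(i) = Ts(i+2) - Ts(i+1)`,
     stride = stance + swing over non-overlapping pairs. Short shuffling
     steps lower it.
   * `alpha` — detrended fluctuation analysis exponent of the signal
     (box sizes 5, 10, …, n/4; log–log slope of the RMS detrended
     fluctuation). Self-similar smooth progress gives `alpha ≈ 1`.
   * `E` — amplitude entropy `E = -Σ Sh_i log2 Sh_i` (with
     `0·log 0 := 0`), capturing irregular progression.
   * `A_delta_C` — mean difference of consecutive 5-sample spectral
     centroids `C = Σ f_i x_i / Σ x_i` (Hz), weak and unstable under
     festination.
   * `T` — valley-to-peak time, the duration of the forward approach;
     grows with impairment.
6. **Classification** — features are screened with the Kruskal–Wallis
   rank test and classified by a one-vs-all soft-margin SVM over the
   Pearson VII universal (PUK) kernel

   `k(Vi, Vj) = 1 / [1 + (2 ||Vi - Vj|| sqrt(2^(1/ω) - 1) / σ)²]^ω`

   with ω = 0.2, σ = 1.0, under stratified 10-fold cross-validation
   (per-fold feature standardization, pooled confusion matrix,
   per-class ROC/AUC).

Because clinical recordings cannot be redistributed, the package ships
a seeded simulator (`simulateWalk`, `simulateGaitDataset`) that
generates labeled staircase height signals with class-dependent
cadence, step amplitude, irregularity, festination bursts and turn
dwell, plus a silhouette renderer (`renderWalkVideo`) producing TIFF
frame stacks that the tracker (`trackVideo`) can consume, so the whole
pipeline is testable end to end against known ground truth.

## Worked example

```r
library(FrontalGait)

w <- simulateWalk(gaitProfile(1), seed = 42)   # one mildly impaired walk
w
#> SyntheticWalk: sim_L1_s42 (label 1, seed 42)
#>   540 frames, 15 ground-truth events, turn at frame 244

computeGaitFeatures(w@series, label = 1)
#>   recording_id S_avg alpha   E A_delta_C     T label flags
#> 1   sim_L1_s42 1.286 1.648 197 -0.007149 11.16     1
```

`S_avg` = 1.29 s matches the profile's 0.8 strides/s cadence, and `T` =
11.2 s is the forward-walk duration. On a balanced set of 30 simulated
recordings:

```r
feats <- do.call(rbind, lapply(0:2, function(lab)
    do.call(rbind, lapply(1:10, function(s)
        computeGaitFeatures(simulateWalk(gaitProfile(lab), seed = s)@series,
                            label = lab)))))
rankFeatures(feats)
#>     feature      H        p meanRank_0 meanRank_1 meanRank_2
#> 1     S_avg 22.294 1.44e-05        5.5       17.2       23.8
#> 2     alpha 25.806 2.49e-06       25.5       15.5        5.5
#> ...
crossValidate(feats, folds = 10, seed = 1)
#> GaitEvalReport
#>   10 folds, averaged accuracy 0.9667
#>   per-class TPR: 1.000 0.900 1.000
#>   per-class AUC: 1.000 1.000 1.000 (macro 1.0000)
```

Stride time rises and the fluctuation exponent falls with severity
(mean ranks above), and the cross-validated model separates the three
simulated levels almost perfectly — simulated classes are cleaner than
clinical ones by construction.

A command-line front end for batch use
(`track | features | analyze | train | evaluate | simulate`) is
installed at `system.file("scripts", "frontalgait.R", package = "FrontalGait")`.

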