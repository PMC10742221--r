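# eegskill

Classifying surgical-skill level — expert versus novice performers of a
bimanual laparoscopic-style suturing task — from multichannel scalp EEG
recorded around the task-start trigger. Motor expertise leaves a topographic
trace: the balance of quasi-stable scalp potential maps ("microstates")
during the first seconds of a complex visuomotor task differs between people
who already hold a perceptual model of the task and people still building
one. `eegskill` implements two complementary ways of reading that trace, for
researchers in motor-skill neuroscience, surgical-simulation training, and
EEG-based brain-computer interfaces.

**Branch 1 — microstate-conditioned regularized CSP + LDA.** Task-onset EEG
(10 s at 250 Hz, 32 channels) is segmented into polarity-invariant
microstates by modified K-means on GFP-peak maps, with the number of states
K chosen by the cross-validation criterion (minimum = best). Given class
scatter matrices C₁ (expert) and C₂ (novice), the spatial filters are the
leading eigenvectors of the Tikhonov-regularized problems

    M₁ = (C₂ + αK)⁻¹ C₁,   M₂ = (C₁ + αK)⁻¹ C₂,   K = I,

computed on microstate-conditioned samples; log-variance features feed a
Fisher discriminant under stratified 10-fold cross-validation.

**Branch 2 — topography-preserving 3-D CNN with temporal attentive
pooling.** EEG is projected to a 16×16 scalp grid (azimuthal equidistant
projection, biharmonic spline interpolation) and cut into 3 s / 120 Hz
windows, giving 16×16×360 tensors (180 per trial; 11,340 for a full
21-subject × 3-trial cohort). A three-layer 3-D CNN with batch norm and a
temporal attentive pooling (TAP) layer — a learned softmax over time —
classifies each window; Grad-CAM localizes the discriminative scalp regions.

Both branches share a standard preprocessing chain (polyphase resampling,
zero-phase 1 Hz FIR high-pass, line-noise regression, bad-channel detection
with spherical-spline interpolation, average reference, artifact subspace
reconstruction, surface Laplacian), BrainVision/EDF+ readers and writers,
and a synthetic-data generator that plants group-specific scalp topographies
so the whole pipeline can be validated end to end without any recordings.

## Worked example

Simulate a small high-SNR two-group cohort, preprocess it, and run the CSP
branch:

```r
library(eegskill)

mon  <- standard_montage_32()
spec <- simulation_spec(n_experts = 4, n_novices = 4, trials_per_subject = 2,
                        task_s = 15, rest_s = 5, pre_trigger_s = 31,
                        snr_db = 10,
                        expert_weights = c(1, 0, 0, 0, 0, 0),
                        novice_weights = c(0, 1, 0, 0, 0, 0), seed = 511)

sets <- list()
for (g in c("expert", "novice")) for (s in 1:4) for (tr in 1:2) {
  rec <- simulate_subject(spec, g, subject_id = s + (g == "novice") * 100, trial_id = tr)
  sets[[length(sets) + 1]] <- preprocess_recording(rec, mon, preprocess_config(),
                                                   subject = paste0(g, s),
                                                   trial = tr, group = g)
}

res <- csp_branch_pipeline(sets, K = 6, n_init = 5, folds = 4, seed = 1)
res$model
#> <microstate_model> K = 6, GEV = 0.971, CV = 1.439e+06
res$report
#> <classifier_report> n = 16
#>   accuracy 1.0000 | F1 1.0000 | MCC 1.0000 | kappa 1.0000
#>   sensitivity 1.0000 | specificity 1.0000 | precision 1.0000
```

The fitted model reports six microstates explaining ~97% of the GFP-weighted
variance (the CV criterion is in the squared units of the Laplacian-filtered
signal, µV²/m⁴); with fully disjoint group prototypes at 10 dB SNR, every held-out
epoch is classified correctly (accuracy, F1, MCC, and kappa all 1), which is
the expected behaviour in this easy regime — chance level for the same
pipeline under label permutation is ~0.5 (kappa ~0).

For the CNN branch on planted tensors:

```r
ds   <- simulate_tensor_dataset(n_per_class = 80, effect = 2, seed = 21)
plan <- make_splits(160, holdout = 0.25, folds = 2, seed = 1, labels = ds$info$label)
m    <- cnn_train(ds, cnn_config(epochs = 12, seed = 101),
                  train_idx = sort(unlist(plan$folds)))
mean(cnn_predict(m, ds, plan$holdout) == ds$info$label[plan$holdout])
#> [1] 1
round(saliency_quadrants(gradcam(m, ds, "expert", "tap",
                                 idx = which(ds$info$label == "expert")[1])), 3)
#>  upper-left upper-right  lower-left lower-right
#>       0.446       0.329       0.811       0.552
```

Grad-CAM's strongest quadrant (lower-left, the left parieto-occipital corner
of the grid) is exactly where the generator planted the expert signature.

Plotting helpers: `autoplot()` on microstate models, CSP models, trained
CNNs and saliency maps; `tidy()`/`glance()` on all fitted objects.

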