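# rehabsense

Tools for monitoring rehabilitation patients at home with low-cost
wearables, in two parts:

1. **Indoor localization from Bluetooth RSS.** A log-distance +
   log-normal-shadowing channel simulator; neural *proximity reporting*
   (a binary per-anchor vicinity vector that confines the patient to a
   region of interest without coordinates), with a plain feed-forward
   classifier and an LSTM that exploits trajectory continuity; and
   fingerprint k-nearest-neighbour positioning from a reference-point
   codebook.
2. **Upper-body kinematics from three sparse IMUs** (pelvis and both
   forearms). Quaternion rotation algebra, pelvis-frame normalization and
   forward kinematics of a 15-segment skeleton, sensor-to-segment
   calibration of standalone IMUs onto a motion-capture convention, four
   sequence models (recurrent encoder–decoder with and without attention,
   transformer encoder, full transformer) trained with a mean-absolute-error
   loss on quaternion components, and orientation / joint-angle evaluation.

A seeded synthetic-data module emulates both the RSS traces and the
240 Hz / 60 Hz motion streams, so the whole pipeline runs and is tested
without any hardware or downloads.

The models in brief: RSS from anchor *u* at distance *d* is
`ν_u = P_t − PL_u(d0) − 10 ξ_u log10(d/d0) + N(0, σ_u²)` (dBm), clipped to
[−100, −50] dBm and scaled to [0, 1]. Proximity classifiers minimize
per-anchor binary cross entropy by SGD (lr 0.01, 400 epochs, batch 500).
The k-NN localizer returns the centroid of the W = 3 codebook entries
minimizing ‖F − G‖. Orientation error is the relative-rotation angle
θ = (360/π)·arccos(|⟨q̂, q⟩|); motion models are trained on
MAE = (1/mn)ΣΣ|q̂ − q| over 5-frame, 40 Hz windows of pelvis-normalized
quaternions. Calibration maps a raw IMU stream onto the motion-capture
convention with a per-session rotation pair computed at one frame,
`R_ori = R_mvn[n]·R_imu[n]⁻¹`, and averages sessions into a fixed map by
the eigenvector quaternion mean. See `vignettes/methods.Rmd` for
assumptions, parameters and numerical choices.

## Worked example

Simulate a patient walk, train the LSTM proximity reporter, and score it
on an independent noisier walk:

```r
library(rehabsense)

scene <- default_anchor_scene()              # 50 m x 50 m, 10 anchors
res <- proximity_experiment("lstm", seed = 1, test_shadowing_var = 15)
round(unlist(res$metrics[c("proximity", "distance", "overall")]), 3)
#> proximity  distance   overall
#>     0.841     0.955     0.926
```

`proximity = 0.841` means 84.1% of the moments the patient was within
15 m of an anchor were reported as such on the test walk (whose shadowing
variance, 15 dB², is twice the training condition); `distance` is the
same rate for out-of-vicinity moments, and `overall` is their
label-weighted combination.

The kinematics half, end to end on synthetic data:

```r
skel <- upper_body_skeleton()
truth <- generate_pose_sequence(skel, motion_config(duration_s = 6.25, seed = 5))
windows <- build_windows(normalize_orientations(truth), model_config())
model <- train_model(windows, model_config("seq2seq", epochs = 200),
                     seed = 1, early_stop_loss = 0.015)
pred <- predict_upper_body(model, windows)
round(mean_angular_error(pred, window_targets(windows))$overall, 2)
#> [1] 2.74
```

2.74 is the mean angular error in degrees over all 15 segments and
frames after the recurrent model fits the 50-window corpus. Standalone-IMU
calibration closes exactly when the mounting offset is a fixed rotation:

```r
dot  <- emulate_dot_stream(truth, dot_config(mounting = quat_from_axis_angle(c(1, 2, 3), 37)))
sync <- synchronize_streams(truth, dot, rate_out = 20)
map  <- compute_variable_mapping(sync$mvn, sync$dot, "RightForearm")
cal  <- apply_mapping(map, sync$dot)
max(angle_between(cal$orientation[, "RightForearm", ],
                  sync$mvn$orientation[, "RightForearm", ]))
#> [1] 0
```

## Command line

A thin dispatcher over the same functions is installed at
`inst/cli/rehabsense`:

```sh
Rscript inst/cli/rehabsense simulate-rss --config cfg.yaml --seed 1 --out run/
```

Subcommands: `simulate-rss`, `train-proximity`, `eval-proximity`,
`classify-roi`, `build-codebook`, `locate`, `generate-motion`,
`calibrate`, `train-motion`, `infer-motion`, `evaluate-motion`. Every run
writes its outputs plus a log (seed, config checksum, package version)
into the `--out` directory.

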