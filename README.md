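# ccdnet — chest-compression depth quality from accelerometer waveforms

During CPR each chest compression should reach a depth of 5–6 cm at
100–120 compressions per minute. Portable feedback devices traditionally
estimate depth by **double integration** of a chest-mounted accelerometer
signal — a route plagued by drift and error accumulation. `ccdnet`
implements the alternative: cut each compression's acceleration waveform out
of the stream and classify it directly as *correct-depth* (label 1, depth in
[5 cm, 6 cm]) or *abnormal* (label 0) with a small one-dimensional
convolutional neural network

    Y = F(X | Θ),

where `X` is the max-aligned, zero-padded pulse waveform and `Θ` the learned
convolution kernels and weights, trained by minimizing the binary
cross-entropy `−1/N Σ [ŷ log y + (1−ŷ) log(1−y)]` of the class-1 softmax
probability. The package is aimed at people building or studying CPR
training devices and, more generally, at anyone classifying short
reciprocating sensor pulses.

It provides, end to end:

* a **synthetic accelerometry generator** (`simulate_trace()`,
  `make_dataset()`) with per-pulse ground truth — the study-grade manikin
  recordings this emulates are not publicly deposited;
* **filtering**: amplitude-controlled (clipping) low-pass plus sliding
  median (`apply_filters()`);
* **segmentation**: dual-sliding-window threshold detection at α% of the
  static gravity value, with duration / amplitude / unimodality
  restrictions, and max-value alignment to a fixed-length input
  (`detect_pulses()`, `align_and_pad()`, `segment_trace()`);
* **models**: `lenet5_1d`, `cpcnn4`, `cpcnn5`, `alexnet_1d` — pure-R 1D-CNNs
  (im2col convolutions, batch norm, dropout, Adam) with exact parameter
  counting (`build_architecture()`, `count_parameters()`, `train_model()`);
* **evaluation**: confusion counts, accuracy, F-score, ROC/AUC, and the
  calibrated double-integration baseline (`evaluate_model()`,
  `integrate_depth()`);
* an **end-to-end pipeline** (`run_pipeline()`) and a CLI
  (`inst/cli/ccdnet.R`) with `simulate` / `filter` / `segment` / `train` /
  `evaluate` / `run` / `count-params` subcommands.

## Worked example

```r
library(ccdnet)

cfg <- simulator_config(seed = 42)      # 5 ms sampling, 100-120/min, noise + spikes
trace <- simulate_trace(cfg, 60)        # one minute of compressions
trace
#> <accel_trace> 12000 samples @ 0.005 s (60.0 s), 108 annotated pulses

pulses <- segment_trace(trace)          # filter -> detect -> max-align
pulses
#> <pulse_set> 108 pulses x 70 points (47 correct / 61 abnormal)

report <- run_pipeline(pipeline_config(
  train = train_config(iterations = 150),
  split = c(train = 200, test = 60, validation = 40),
  correct_fraction = 0.5, seed = 42))
report
#> <ccdnet_report> cpcnn4 on 300 pulses (split 200/60/40)
#>   CNN:         ACC 0.9833  F-score 0.9831  AUC 0.9978
#>   Integration: ACC 0.6333  F-score 0.5417
#>   final training loss 0.0738, 30.0 s elapsed
```

The 60 s trace at ~108 compressions/min yields 108 detected and aligned
pulses, matching the annotated ground truth. In the pipeline run, the
trained `cpcnn4` classifies 98.3% of held-out test pulses correctly
(F-score 0.983, AUC 0.998), while the calibrated double-integration
baseline — handicapped by pulse-duration variability and noise drift —
reaches only 63.3%: the gap is the point of the classification approach.

Parameter counts are architecture-determined and exact:

```r
count_parameters(build_architecture("lenet5_1d"))                      # 158274
count_parameters(build_architecture("cpcnn4", batch_norm = FALSE))     # 191234
```

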