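# swallowphase

Frame-level temporal localization of swallowing phases in
videofluoroscopic swallowing studies (VFSS), with the downstream calculus
that turns detected phases into the seven clinical timing parameters.

## The problem

A VFSS is a continuous lateral-view X-ray video of a patient swallowing a
contrast bolus, recorded here at 15 frames per second. Clinicians score it
by labeling seven events — oral phase start, bolus passing the ramus of the
mandible, the hyoid bone's anterosuperior burst, laryngeal vestibule closure
(LVC) onset and offset, and upper esophageal sphincter (UES) opening and
closure — and reading off seven durations:

| Parameter | Definition (frames) |
|---|---|
| OPD, oral phase duration | bolus_past_mandible − oral_start |
| PDT, pharyngeal delay time | hyoid_burst − bolus_past_mandible (signed) |
| PRT, pharyngeal response time | ues_closure − hyoid_burst |
| PTT, pharyngeal transit time | ues_closure − bolus_past_mandible = PDT + PRT |
| LVCRT, LVC reaction time | lvc_onset − hyoid_burst (signed) |
| LVCD, LVC duration | lvc_offset − lvc_onset |
| UESOD, UES opening duration | ues_closure − ues_opening |

each converted to milliseconds via 1000/fps. Manual labeling is slow and
rater-dependent, which motivates automating it: a binary classifier per
phase decides, frame by frame, whether the frame belongs to the phase, and
the detected frame span yields the duration.

## The models

Three variants of an 18-layer 3D-convolutional residual network
(ResNet3D-18, stages F = [64, 128, 256, 512], scalable) are implemented
with a self-contained training engine (im2col-based conv3d kernels in
C++, backpropagation, Adam, class-weighted cross-entropy):

- **DEFAULT** — an L-frame window (L = 7 or 13) is classified by the phase
  membership of its center frame.
- **BIDIRECTIONAL** — two separate backbones read the first and last L
  frames of a 2L−1-frame span (forward and backward context of the shared
  center frame); their pooled features are concatenated into one
  fully connected head.
- **CONV-SA** — all temporal strides are fixed to 1 so a W-frame segment
  (W = 50) yields W frame features; sinusoidal positional encoding plus a
  4-head self-attention layer and a shared per-frame head label every frame
  of the segment at once.

Evaluation is frame-pooled accuracy, precision, recall, F1
(= TP/(TP + (FP+FN)/2)) and non-interpolated average precision, with
mean ± SD aggregation over repeated training runs.

Because clinical VFSS recordings are not redistributable, the package ships
a synthetic fluoroscopy-like clip generator: a schematic lateral scene with
a moving bolus, hyoid marker, vestibule and UES gate, whose event schedule
is drawn from moment-matched truncated distributions calibrated to
published per-phase frame statistics, plus the irregularities of real
recordings (patient drift, occluders, a hand entering the frame, contrast
jitter). Every generated clip carries exact ground-truth annotations, and
read-back oracles verify the rendering against them.

## Worked example

```r
library(swallowphase)

# events at frames (0, 10, 13, 15, 16, 22, 24) at 15 FPS
ev <- event_set("clip1", 0, 10, 13, 15, 16, 22, 24)
compute_parameters(ev, fps = 15)
#> <temporal_parameters> clip1 @ 15 fps
#>   OPD          666.67 ms
#>   PDT          200.00 ms
#>   PRT          600.00 ms
#>   PTT          800.00 ms
#>   LVCRT        133.33 ms
#>   LVCD         600.00 ms
#>   UESOD        400.00 ms
```

The PTT of 800 ms is the 12 frames from bolus-past-mandible (frame 10) to
UES closure (frame 22); PDT (3 frames) plus PRT (9 frames) sums to it
exactly.

End to end on synthetic data:

```r
generate_dataset(120, scene_config(), "data", seed = 1)
man  <- read_manifest("data")
tcfg <- train_config("PTT",
                     model_config("DEFAULT", stage_widths = c(4, 8, 16, 32),
                                  input_size = c(32, 32)),
                     epochs = 3, windows_per_clip = 40, seed = 1)
det <- train_phase_detector(load_split(man, "train"), load_split(man, "val"), tcfg)
ev  <- evaluate_detector(det, load_split(man, "test"))
unlist(ev$metrics[c("accuracy", "f1", "ap")])
#>  accuracy        f1        ap
#> 0.9988914 0.9990934 0.9999967
```

On this clean desk-scale fixture the tiny-width detector localizes the
pharyngeal transit phase almost perfectly, and the predicted interval
recovers the true duration within 2 frames on every test clip but one
(12/13 exact, 13/13 within one frame).

A thin CLI wraps the same functions
(`inst/exec/swallowphase generate|run|measure|report`), and
`run_experiment()` orchestrates all seven phases — including the
`paper_best` per-phase variant mapping — into a seeded, fully reproducible
experiment directory.

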