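# neurochair

A desk-scale, fully simulated implementation of a hybrid brain–computer
interface (BCI) control stack for a smart wheelchair. The physical system
it emulates lets a severely motor-impaired user drive an omnidirectional
wheelchair with a mounted robotic arm by doing three things only:
confirming a control mode, selecting a target through a P300 speller, and
validating with a jaw clench. Everything else — recognizing and localizing
targets, planning what to do with them, and executing the motion — is
autonomous. This package rebuilds that entire loop in software so its
decision logic can be tested, measured and extended without hardware,
subjects, or a robot.

## What is in the box

* **Synthetic signal generators** — seeded oddball EEG with a P300 bump
  (Gaussian template, 300 ms latency, centro-parietal gains) and
  single-channel jaw-clench EMG (55–77 Hz band-limited noise with
  rest/clench envelopes calibrated to the detector's 100/1500 variance
  bounds).
* **P300 decoder** — causal 2–25 Hz Butterworth filtering, 800 ms epochs,
  block-mean features, stepwise linear discriminant analysis (SWLDA), and
  candidate-restricted trial classification. For epoch score
  `s = w·x + b`, per-stimulus scores are summed across sequences and the
  output is `argmax` over the displayed candidates only.
* **EMG validation detector** — contiguous 200 ms windows, per-window
  band-pass, variance threshold 1500, and a length-4 FIFO that fires on
  the cessation pattern `[1,1,0,0]`, i.e. exactly 0.4 s after the clench
  ends.
* **Simulated perception** — a pinhole depth camera (57° field of view),
  loose detection boxes, point clouds with pixel provenance; localization
  by 60% bbox shrink + floor filter + centroid; orientation by the
  v/vn/f PCA rule with a face-the-user fallback for isotropic clouds.
* **Planner and shared control** — the ten object classes partition into
  four solution groups (stop at 80 cm / stop at 20 cm / pass through /
  arm press-or-pick inside a calibrated workspace box), priority ranking
  with at most six displayed targets, and the mode-selection /
  validation state machine with collision-and-deadloop reset.
* **2D simulator** — holonomic chassis (0.1–0.4 m/s), 5 cm grid path
  planning for the 0.70 m footprint, closed-loop session runner with a
  simulated user and a walking "guest", and the evaluation metrics
  (TrP3, TiP3, VT, FV, SR, EP/NV deductions).

## Worked example

A jaw clench from 1.0 s to 2.0 s fires the validation command exactly
0.4 s after it ends:

```r
library(neurochair)

trace <- synth_emg_trace(4, clench_intervals = list(c(1.0, 2.0)), seed = 1)
detect_validations(trace)
#> # A tibble: 1 × 1
#>   time_s
#>    <dbl>
#> 1    2.4
```

A full closed-loop session replays the nine-step sickroom scenario
(drive to the desk, pick up the bottle, drink, reverse, turn, pass the
80 cm door, turn, approach the walking person, converse) with the
ideal-user stub:

```r
log <- run_session(scenario_a(), user = ideal_user(),
                   decoder = "ideal", seed = 1)
log
#> <session_log A> 92 events, 77.5 s simulated, completed

compute_metrics(log)
#>   TrP3 TiP3 VT FV SR EP NV n_selections
#> 1    1  3.6  0  0  1  0  0            7
```

`TrP3 = 1` means every selection was correct on the first 3.6 s trial
(`TiP3 = TrP3 × 3.6 s`); `VT = 0` because the stub validates instantly;
`SR = 1` with no false validations and no deductions. Swapping in a
trained decoder and a realistic user (`simulated_user()`, which clenches
a synthetic jaw-EMG burst and waits for the detector) yields validation
times in the few-second range, like a human in the loop:

```r
cal <- calibrate_decoder(tempfile("cal"), seed = 11)  # 60 synthetic trials
log <- run_session(scenario_a(), user = simulated_user(),
                   decoder = cal$model, seed = 42)
```

`run_evaluation("A", n_sessions = 10, ...)` repeats sessions and writes
per-session and aggregate metric tables (CSV), per-session event logs
(JSON lines) and a reproducibility manifest. A thin command-line wrapper
with `calibrate`, `validate-emg`, `run-scenario` and `plan-demo`
subcommands lives in `inst/cli/neurochair.R`.

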