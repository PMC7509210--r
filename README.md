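# steerlimb

Analysis of upper-limb neuromuscular dynamics during steering, for
researchers in kinesiology, human factors and driver–vehicle
interaction who record multichannel surface EMG together with
steering-wheel torque and angle.

A steering trial couples 10 EMG channels (muscle codes `MS1…MS10` for a
single-arm montage, `MB1…MB10` for both arms) with the steering torque
`T(t)` (N·m, positive = clockwise) and angle, under an *active*
(target-following) or *passive* (disturbance-rejection) task and a hand
position (`0300`, `1010`/`0130`, `1200`). The package answers four
questions per muscle *i* and steering direction *d* ∈ {cw, ccw}:

- **Coupling** — the correlation
  `r_id = max_τ ρ(e_i, |T|; τ)` over lags |τ| ≤ 1 s, where `e_i` is the
  normalized activation envelope restricted to direction-*d* episodes;
  `r > 0.75` (strict) classifies the muscle as strongly coupled.
- **Effort** — the amplitude `a_id = mean(e_i)` over direction-*d*
  episodes, and the contribution ratio
  `c_id = r_id·a_id / Σ_j r_jd·a_jd`, which sums to 1 across the 10
  muscles of a direction and ranks muscle importance.
- **Responsiveness** — the delay `τ_i` at the maximum absolute
  normalized cross-correlation between the envelope and `|T|`;
  `τ < 0` means the muscle activity *leads* the torque, `τ > 0` means
  it lags (co-contraction).
- **Smoothness** — approximate entropy
  `ApEn(m=2, r=0.2·SD)` of the torque (decimated to 100 Hz) and the
  sliding standard deviation (mean windowed SD, 0.5-s window); lower is
  smoother.

Envelopes are extracted with zero-phase (real-masked FFT) 20–450 Hz
band-pass → rectification → 6-Hz low-pass, so preprocessing adds no lag
that would bias the delay estimates. Direction episodes come from a
dead-band segmentation of the torque (±5 % of the trial maximum,
minimum 0.5 s). Because no public recordings exist for this paradigm,
the package includes a synthetic-cohort generator whose ground truth
(per-muscle direction gains and lead times) drives the test suite's
recovery checks.

## Worked example

```r
library(steerlimb)

# a 20-subject synthetic cohort: right-arm ccw agonists on channels 1-2,
# left-arm cw agonists on channels 6-7, lead times 330-400 ms
cfg <- sim_config(n_subjects = 20, duration_s = 60, task = "active",
                  arm_mode = "both", hand_position = "0300", seed = 1)
write_cohort(generate_cohort(cfg), "cohort")

res <- run_pipeline("cohort", "report", run_params(seed = 1))
subset(res$summary, statistic == "r.MB1" | statistic == "tau_ms.MB2",
       select = c(direction, statistic, mean, sd, n_subjects))
```

```
   direction  statistic         mean           sd n_subjects
1         cw      r.MB1    0.8769571  0.040009077         20
31       ccw      r.MB1    0.9547614  0.002925874         20
63       all tau_ms.MB2 -396.5000000 12.258187382         20
```

Reading: channel MB1 (right pectoralis major, a counterclockwise
agonist in the default specification: gain 0.80 ccw vs 0.25 cw)
correlates strongly with the torque magnitude in both directions
(r > 0.75), more tightly for ccw; MB2's activity leads the torque by
≈ 400 ms on average (negative delay), recovering that channel's
injected 400 ms lead. Per-subject
tables (`muscle_direction_results.csv`, `delays.csv`,
`smoothness.csv`), per-muscle cw-vs-ccw permutation tests
(`direction_tests.csv`) and the cohort summary
(mean ± SD + quartiles, `cohort_summary.csv`) are written to
`report/`.

A command-line driver with `simulate | preprocess | analyze | report`
subcommands is installed at `inst/cli/steerlimb.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/steerlimb.R", package="steerlimb"))')" \
  report --in cohort --out report --seed 1
```

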