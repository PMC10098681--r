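# handfusion

Dual-sensor hand-tracking fusion and telerehabilitation kinematics.

Touchless skeletal hand trackers report the 3D positions of the hand
joints without worn equipment, which makes them attractive for at-home
hand rehabilitation after stroke or surgery: the therapist gets
quantitative, per-joint mobility data instead of a subjective
impression. A single tracker, however, fails whenever the palm turns
perpendicular to its viewing axis. `handfusion` implements the
computational core of a rig that mounts **two sensors orthogonally** and
fuses their views, together with everything around it — entirely
hardware-free, with a synthetic two-sensor simulator standing in for the
physical devices:

- **Data model** — the 25-landmark skeletal hand (4 thumb joints,
  5 per remaining finger, 1 palm center), per-instant records carrying
  the *vertical*, *horizontal* and *fused* hand models, and a bit-exact
  JSON-Lines stream format (`.vgs.jsonl`).
- **Calibration** — Kabsch/Umeyama SVD registration of corresponded
  stick-tip point clouds, s·R·aᵢ + t ≈ bᵢ with the reflection case
  corrected (det R = +1), plus a second-step per-axis bias refinement.
- **Fusion** — the *binary switch*: the palm-normal projection angle θ
  (from the horizontal sensor's X-axis, in its X–Y plane) selects the
  horizontal sensor iff θ ∈ [45°, 135°] ∪ [225°, 315°] (palm up or
  down), the vertical sensor otherwise; and the *joint-wise switch*: a
  joint moves to the other sensor when its active-sensor speed
  ‖pₛ(t) − pₛ(t−1)‖/Δt exceeds κ times the other's (slower tracking is
  taken as more robust). Both are switches, never blends.
- **Kinematics** — per-joint speed and acceleration by central
  differences on actual timestamps, path length, per-axis range of
  motion, session summaries, cross-session comparison, and JSON/CSV/PNG
  report export.
- **Session store** — a file-backed, role-checked document store with
  one collection per session named
  `Session_<patient>_<therapist>_<params>_<YYYYMMDD>`, staging-based
  insertion and therapist query criteria.
- **Simulator** — parametric hand motion with analytic speed oracles,
  sensor noise and palm-orientation-dependent occlusion (inflated
  jitter + hold-last-value dropout), calibration-cloud synthesis, a toy
  rehabilitation task scorer and a wall-clock-free session state
  machine (ten-second pre-task countdown, repetitions, rests).

See `vignettes/handfusion-methods.Rmd` for the full account of the
models, parameters and numerical choices.

## Worked example

Simulate a 5 s session in which the palm sweeps a full circle (so each
sensor is occluded in its own angular window), calibrate from a noisy
50-pair cloud, fuse, and summarize:

```r
library(handfusion)

pose  <- hand_pose_model(
  flexion     = list(index = list(amplitude_deg = 40, frequency_hz = 1, phase = 0)),
  orientation = list(type = "sweep", from_deg = 0, to_deg = 360))
truth <- generate_ground_truth(pose, duration_s = 5, fps = 40)
rig   <- default_sensor_rig(sigma_mm = 0.5, p_drop = 0)
v     <- observe(truth, rig$vertical,   seed = 1)
h     <- observe(truth, rig$horizontal, seed = 2)

cloud <- make_calibration_cloud(rig$calibration, n = 50, sigma_mm = 0.5, seed = 3)
tf    <- estimate_rigid_transform(cloud)
tf
#> <rigid_transform> euler ZYX [89.973, 0.0079429, -0.075738] deg, t = [-259.96, -39.97, -15.007] mm, s = 1
registration_residual(tf, cloud)   # ~ sigma * sqrt(3)
#> 0.890 mm

fused <- fuse_streams(v, h, tf)    # binary switch by default
fused
#> <session_stream> patient sim-patient, task simulated: 200 records
#>   0 .. 4975 ms; models per record: vertical, horizontal, fused
table(vapply(fusion_decisions(fused), `[[`, "", "active"))
#> horizontal   vertical
#>        102         98

summ <- joint_statistics(fused, "fused")
summ
#> <session_summary> sim-patient_sim-therapist_20230325 (fused model): 200 frames @ 40.0 fps
#>   task score: NA
#>   mean speed 107.8 mm/s (max 669.7), mean path 587.1 mm over 25 joints
subset(summ$joints, joint %in% c("INDEX_TIP", "INDEX_PIP", "PALM_CENTER"))
#>          joint mean_speed max_speed path_length range_x range_y range_z
#>      INDEX_PIP     218.85    462.41      1121.9 170.873 170.397   3.063
#>      INDEX_TIP     332.39    669.75      1682.7 248.702 249.990   2.189
#>    PALM_CENTER      22.19     54.32       224.8   2.672   3.013   2.986
```

Reading the numbers: the true vertical→horizontal transform is a 90°
rotation about Z with translation (−260, −40, −15) mm, recovered here to
a few hundredths of a degree and of a millimetre from 50 noisy pairs;
the residual 0.890 mm matches the expected σ√3 ≈ 0.87 mm for 0.5 mm
per-axis noise. The full palm sweep splits the 200 frames between the
sensors (102 horizontal / 98 vertical — the two closed windows cover
182 of 360 integer degrees). The flexing index fingertip dominates the
motion (its analytic peak speed for this profile is
2π · 1 Hz · 40° · 115 mm = 504 mm/s; the finite-difference maximum lands
within sampling error), while the static palm center shows only noise.

`export_report(summ, "report/")` writes `summary.json`, the 25-row
`joints.csv` and a per-joint plot; `compare_sessions()` differences two
or more summaries for progress monitoring.

A thin command-line wrapper over these functions is installed at
`inst/cli/handfusion.R` (`calibrate`, `simulate`, `fuse`, `analyze`,
`compare`, `report`, and an end-to-end `pipeline` that also stores and
queries the session).

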