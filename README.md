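# gridwave

Spiking continuous-attractor network of grid cells that produces theta
phase precession, theta sequences, and replay — together with the analysis
pipeline that measures them.

## The science

Grid cells in the medial entorhinal cortex fire on a triangular lattice of
spatial locations. A continuous attractor network explains this: neurons on
a 2D sheet with local excitation, surround inhibition, and
direction-shifted output synapses develop a lattice of activity bumps that
translates with the animal's velocity, so each neuron inherits grid-like
spatial tuning. `gridwave` implements this architecture with fully spiking
leaky integrate-and-fire dynamics — five overlapping populations (N, S, W,
E excitatory and one inhibitory) on an `n x n` sheet, membrane equation

    tau_m dphi/dt = -phi + sum_syn w * s(t - tau_s) + a(r, t) + noise,

threshold 1, reset 0, hyperpolarization floor -1 — and shows that two
hippocampal sequence phenomena emerge purely from changes in external
drive, with fixed connectivity:

* **Runs** (theta-oscillating inhibitory drive at 8 Hz): attractor bumps
  oscillate in *size*, which yields single-neuron theta phase precession,
  and in *speed*, which makes the decoded position sweep ahead of the
  animal within each cycle — theta sequences at roughly twice the running
  speed.
* **Quiescence** (reduced, non-oscillating drive): bumps near the sheet
  edge give way to traveling wavefronts of excitatory activity, which are
  decoded as replays an order of magnitude faster than the animal.

The package also contains the full measurement chain used to quantify
these phenomena: tetrode-style recording emulation (rings of recording
regions, lap-stability selection of up to 150 cells), occupancy-normalized
rate maps and firing fields, circular-linear phase regression and
subgroup classification (phase-independent / locking / precessing),
memoryless Bayesian population decoding, theta-quadruplet averaging with
sequence-speed fitting, consensus-line replay detection, attractor-bump
segmentation and fixed-drive sweeps, and the two simplified single-neuron
models (threshold pass and Poisson pass through the average bump).

## Worked example

```r
library(gridwave)

cfg  <- grid_config(n = 144, seed = 21)        # scaled-down sheet
traj <- generate_track_trajectory(cfg, n_laps = 8, seed = 21)
ses  <- run_session(cfg, traj, seed = 21)      # includes allocentric setup
an   <- analyze_session(ses, set = "A")
an
#> <session_analysis> set A: 150 neurons, 160 phase fits, 10 replays, theta-seq 1.08 m/s

an$run_speed                    # 0.512  (m/s, fBm trajectory around 0.5)
an$sequence_speed$speed_mps     # 1.08   (theta-sequence speed, m/s)
mean(an$replays$speed_mps)      # 8.29   (replay speed, m/s)
table(an$phase_stats$subgroup)
#> independent     locking  precessing
#>          87          20          53
```

The theta-sequence speed is about twice the running speed and the replay
speed more than an order of magnitude faster, while the recorded cells
split into phase-independent, phase-locking (near 360 degrees, the
inhibitory-drive trough) and phase-precessing subgroups — the three
signatures the model is built to explain. `render_figures(ses, an, "figs")`
draws the sheet activity, rasters, phase scatters, averaged theta
quadruplets and replay fits; `run_experiment()` orchestrates replicate
simulations and variants (`low-gain`, `periodic-uniform`,
`no-allocentric`). A thin command-line wrapper lives at
`inst/cli/gridwave.R`.

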