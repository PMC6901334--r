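---
title: "Methods: a spiking continuous-attractor grid-cell network with theta sequences and replay"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a spiking continuous-attractor grid-cell network}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(gridwave)
```

## The model

`gridwave` simulates a single grid-cell module as a continuous attractor
network of fully spiking neurons. Five populations overlap on an `n x n`
neural sheet: four excitatory populations (N, S, W, E) and one inhibitory
population. Each neuron is a leaky integrate-and-fire unit in arbitrary
potential units: the membrane potential relaxes toward its net input with
time constant `tau_m` (40 ms excitatory, 20 ms inhibitory); crossing the
threshold of 1 emits a spike and resets the potential to 0; a floor at -1
limits hyperpolarization. The discrete update is the explicit Euler form

    phi(t + dt) = phi(t) + (dt / tau_m) * (-phi(t) + I_syn + I_drive + noise)

with `dt = 1` ms and i.i.d. Gaussian noise of variance `0.002^2` per neuron
and step. Synaptic events enter the right-hand side of this equation (each
presynaptic spike contributes its weight to the input for one step), which is
the literal reading of the leaky-integrator dynamics; at `dt = 1` ms this
differs from an instantaneous potential jump only by the fixed factor
`dt / tau_m`.

Connectivity is distance-dependent and fixed. Excitatory neurons excite all
populations through a raised-cosine kernel of radius 6 neurons and peak 0.2,
with the outgoing synapses of each population displaced by `xi_shift = 3`
neurons along its preferred sheet direction (up, down, left, right).
Inhibitory neurons inhibit only excitatory neurons through a surround kernel
that vanishes at the origin and beyond twice its radius and reaches -2.8 at
12 neurons; there are no inhibitory-to-inhibitory connections. Synaptic
delays are 5 ms (exc-to-exc), 2 ms (exc-to-inh) and 2 ms (inh-to-exc).

Drive terms represent input from outside the module. Excitatory neurons
receive a radial raised-cosine profile, maximal (2.0 during runs) at the
sheet centre and decaying to 0.8 toward the edges; the scaled radius is
`rho = dist(centre) / (n / 2)`, so `rho` is about 1 at the midpoint of a
sheet edge (this normalization is chosen precisely so that the stated
property holds). The drive is modulated per population by the animal's
velocity, `1 + alpha * (E_P . V)` with `alpha = 0.25` s/m. Inhibitory
neurons share a spatially uniform drive `a_mag - a_theta * cos(2 pi f t +
psi0)` with `f = 8` Hz during runs; theta phase 0 is defined at the troughs
of this drive, where excitatory cells are most disinhibited. During idle
periods the excitatory drive falls (max 1.6, narrower profile) and the
inhibitory drive drops to 0 without oscillation; during brief allocentric
pulses the excitatory drive is replaced by a learned map (below) with
constant inhibition 0.72.

With random initial potentials the sheet self-organizes bumps of activity
into a triangular lattice. Because each excitatory population's output is
shifted along its preferred direction and its drive grows when the animal
moves along the corresponding spatial direction, the lattice translates with
the animal's velocity (path integration) and each neuron fires on a spatial
grid.

### Behavioural protocol and allocentric correction

Sessions alternate end-to-end runs along a linear track (default 100 cm)
with idle periods (default 3 s) at the ends; between an idle period and the
next run the network receives a 100 ms allocentric pulse. Before the
session, a setup phase runs the settled network once in each direction and
then tallies excitatory spikes for 1 s while the animal rests at each track
end; the tallies, linearly rescaled to the drive range [0.8, 2.0], become
the allocentric maps that reset bump locations and cancel path-integration
drift. The theta phase offset `psi0` is redrawn uniformly at the start of
each lap. The network state (potentials and synaptic delay queues) is
carried continuously from setup through the session.

### Numerical implementation

The four excitatory populations share one kernel shape, so their spike
fields are shifted at the source, summed, and convolved once per step; the
excitatory and inhibitory convolutions are fused into a single complex FFT
pair (real and imaginary channels) on a zero-padded grid for nonperiodic
boundaries, or the bare sheet for periodic ones. Noise is generated from a
counter-based stream keyed on (seed, absolute step, population), so a
session split across calls reproduces an uninterrupted run exactly; this is
verified in the test suite. Simulation output records spike events at the
recorded sheet locations, full-sheet spike tallies, and optional activity
snapshots at a 10 ms cadence.

## Trajectories

Running speed fluctuates around the 0.5 m/s target as `v (1 + 0.1 g_H(t))`,
where `g_H` is unit-variance fractional Gaussian noise with Hurst exponent
0.8 generated by circulant embedding; instantaneous speed is clipped below
at 0.05 m/s. The 10% relative amplitude reproduces a run-speed dispersion of
about 0.05 m/s. The Hurst exponent and amplitude are conventional choices
for smooth, persistent speed variation and are exposed in the
configuration. Idle duration (3 s) and allocentric pulse duration (100 ms)
are likewise configuration values. Open-field paths use an
Ornstein-Uhlenbeck velocity with reflective walls, with the stationary mean
speed matched to the run-speed target.

## Recording emulation and analyses

Two recording sets of four circular regions (radius 12 neurons) are placed
on a ring around the sheet centre at equally spaced but randomly rotated
angles, the second set offset 45 degrees; the ring radius is 95 neurons on
the default 232-wide sheet and is scaled proportionally (`round(95/232 n)`)
for other sheet sizes. Up to 150 excitatory neurons per set with lap-stable
fields are kept (per-lap field-peak s.d. below 10 cm on laps with at least
3 spikes, at least half of the laps active, peak rate above 1 spike/s);
each set is analyzed independently as one recording. Rate maps use 2 cm
bins, occupancy normalization and 4 cm Gaussian smoothing; fields are
contiguous regions above 20% of a neuron's peak rate. With the default
velocity gain the bump lattice travels about two grid periods per track
traversal, so recorded neurons commonly express two (sometimes three)
fields; field progress is computed within the field that contains each
spike, with entry and exit defined by the lap direction.

Phase statistics follow the circular-linear framework: the regression slope
maximizes the mean resultant length of `phase - slope * progress`, the fit
score is that maximized resultant length, and the correlation is the
circular-circular correlation between the phase and the circularized linear
predictor. The slope search is bounded to two theta cycles per field
(720 degrees per field of progress). A wider bound (four cycles) was found
to lock onto aliased optima at realistic in-field spike counts — phase
recurs every theta cycle within a single pass, so with a handful of passes
a slope of about one cycle per crossing fits spuriously well — which
inflates fit scores and scrambles slope signs; two cycles still covers the
largest precession ranges reported for entorhinal neurons. Neurons with a
fit score below 0.4 are classified phase-independent; above it, a
precession range (|slope| x field span) of at least 60 degrees separates
precessing from locking cells. Note that genuine precession gives negative
slopes against field progress in both running directions, which corresponds
to negative slopes against track position on rightward laps and positive on
leftward laps; the stats table carries both conventions.

Decoding uses the standard Poisson population decoder with a uniform prior
over 2 cm track bins, 10 ms windows stepped by 5 ms, in log space with a
0.01 spikes/s rate floor. Theta sequences are exposed by averaging decoded
densities over quadruplets of consecutive cycles: quadruplets are discarded
when more than a quarter of their bins decode within 10 cm of a track end
(a fraction rather than an any-bin rule, because multi-field aliasing
produces isolated hops to the alias position), right-to-left quadruplets
are position-reversed, each is shifted by the actual position at its
midpoint, and the densities are averaged. Position traces of the average
are computed within 30 cm of the animal so that alias lines a lattice
period away do not dilute them. The sequence speed is the steepest slope of
the averaged position over a sliding 62.5 ms window contained in one cycle.

Replay detection works on idle-period decoding with the run-derived fields.
The recorded multiunit rate is smoothed (20 ms s.d.) and z-scored against
the idle baseline; windows above z = 1 are extended down to z = 0.3 —
which merges the sub-bursts produced as one wavefront crosses the four
recording regions in sequence — and kept when they last 80-300 ms. The
typical merged event lasts about 100 ms, the timescale on which replays
traverse the track. The 80 ms floor exists because a shorter window holds
only a handful of independent decode bins: line fits on such windows were
dominated by alias-jump artifacts (below). Within each window a single
line is fit to the maximum-likelihood positions by a deterministic
consensus search (all point pairs, inliers within 8 cm, least-squares
refit on the inlier set): with multi-field cells the decoded distribution
can split between parallel alias lines, and the consensus fit recovers the
dominant one, which is the single-line detection method applied robustly.
Events are kept when at least half the bins are inliers, the inlier span
covers at least half the track and the inlier fit has R^2 >= 0.5; the
absolute slope is the replay speed. All thresholds sit in the
configuration.

Bump geometry is measured from 10 ms activity snapshots of one excitatory
population smoothed with a 1.5-neuron Gaussian: bumps are connected
components above 30% of the maximum, with equivalent-circle diameters.
Bump motion is tracked by cross-correlating successive frames with
subpixel (parabolic) refinement and a search window centred on the
previous shift; frame lengths should be chosen so the expected shift per
frame is a few neurons, since much smaller shifts suffer peak-locking bias
and much larger ones risk lattice-period ambiguity. Fixed-drive sweeps hold
the inhibitory drive at five levels spanning the theta range [0.52, 0.92]
at constant 0.5 m/s velocity. Every level continues from a single lattice
settled at the run-mean drive, mirroring how the oscillating drive visits
these levels with the lattice intact; cold starts at the sweep extremes
can land in qualitatively different activity states. The per-level
diameter statistic is the median over segmented bumps, which is robust to
occasionally merged neighbours. Across the sweep, diameters fall and
speeds rise approximately linearly.

## Design notes and limitations

* **Problem sizes.** Replicate sessions for the headline numbers use a
  144-neuron-per-side sheet (recording ring scaled accordingly), 8 laps per
  session and three sessions with two recording sets each; the bump sweeps
  use a 128-wide sheet; lattice-geometry checks use the full 232-wide
  sheet. These sizes preserve the kernel, drive and delay parameters
  exactly and leave several grid periods across the sheet. The sheet-size
  reduction mainly reduces the number of simultaneously visible bumps; the
  in m/s quantities (sequence and replay speeds) are set by the dynamics of
  individual bumps and wavefronts together with the learned sheet-to-track
  correspondence, and were found to be stable across sheet sizes.
* **Ring packing on small sheets.** The radial drive envelope packs bumps
  into concentric rings when the sheet holds only a few grid periods;
  triangular-lattice statistics (six-peak autocorrelation) are therefore
  evaluated on the central patch of the full-size sheet, after removing the
  local mean at half a lattice period to strip the envelope.
* **Path-integration linearity.** Displacement is proportional to speed to
  within about 10% over 0.25-0.5 m/s; at much lower speeds the lattice
  creeps with slow fluctuations (transient pinning against the drive
  envelope), and at higher speeds the gain compresses mildly. The
  linearity property is therefore tested at 0, 0.25 and 0.5 m/s on the
  full-size sheet with displacements pooled over seeds.
* **Allocentric rescale bounds** default to the drive range
  `[a_min_exc, a_max_exc(allo)]`; no spatial smoothing is applied to the
  learned maps. Both are configuration choices.
* **Variants.** `variant_config()` exposes the lower-velocity-gain network
  (gain halved to 0.125 s/m, giving a one-to-one sheet-track
  correspondence and directionally biased replays), periodic boundaries
  with uniform drive (bumps and wavefronts across the whole sheet; the
  radial profile exists only to tame sheet edges), and a no-allocentric
  mode in which correction pulses are replaced by idle drive. The exact
  reduced gain is not pinned down by the phenomenology; halving is the
  package default and the value is a parameter.
* **Correlation magnitudes are floor-limited at short sessions.** With
  8 laps, recorded cells contribute roughly 5-40 in-field spikes per
  direction, and the circular-linear correlation has a small-sample noise
  floor: the same pipeline applied to phase-shuffled spikes at matched
  counts returns a mean magnitude near 0.3. Population means of |corr|
  from short sessions therefore sit near that floor regardless of the
  underlying phase structure; slope signs, subgroup classification and the
  pooled density ridges remain informative at this scale.
* **Multi-field decoding aliases.** Because the lattice travels about two
  grid periods per traversal, decoded idle activity can split between
  parallel position lines one lattice period apart. The single-line replay
  detector recovers the dominant line; a multi-line fit is deliberately out
  of scope, and replay-speed summaries from multi-field recordings run
  somewhat above those of single-field configurations.
* **What the synthetic data does not show.** All analyses run on the
  simulator's own spike output; there is no LFP model (theta phase is
  defined from the known inhibitory drive), no measurement noise or spike
  sorting, no multiple grid modules, no spike-frequency adaptation and no
  hippocampal coupling. Passing tests demonstrate the internal consistency
  of the mechanism — bump size and speed oscillations producing phase
  precession and theta sequences, and wavefronts producing replay — not
  agreement with any particular animal's recordings.

## Reproducibility

Every stochastic component — network noise, initial potentials, theta
offsets, trajectories, region placement — derives from explicit integer
seeds. The network noise stream is counter-based, keyed on the absolute
timestep, so runs are reproducible and restartable; identical seeds and
configurations give bit-identical spike records.
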