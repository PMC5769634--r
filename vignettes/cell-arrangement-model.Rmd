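---
title: "Mechanics of four-cell arrangement in nematode eggshells"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mechanics of four-cell arrangement in nematode eggshells}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

At the four-cell stage a *C. elegans* embryo normally shows a "diamond"
arrangement of its blastomeres ABa, ABp, EMS and P2, and other nematode
species show pyramid, T-shaped or linear arrangements that correlate with
how elongated their eggshells are. `embryomech` implements a minimal
mechanical account of this: blastomeres are soft spheres whose centres move
by overdamped Langevin dynamics inside a rigid ellipsoidal eggshell,

r_i(t + dt) = r_i(t) + F_i dt + xi,

where the mobility has been set to 1 so that forces are expressed directly
as velocities (um/s), and xi is an isotropic Gaussian displacement applied
once per step. The net force F_i on a cell is the sum of pairwise
cell--cell forces and a repulsion from the eggshell.

**Pairwise force law.** The signed magnitude along the line of centres, for
cells of radii R_i, R_j at centre distance d:

* constant repulsion `F0` for `0 < d <= min(Ri, Rj)` -- a stand-in for
  cytokinetic elongation, which proceeds at roughly constant velocity;
* decreasing linearly through zero at `d = alpha (Ri + Rj)` until
  `d = (1 + alpha)(Ri + Rj)/2`;
* increasing linearly back to zero at contact loss `d = Ri + Rj`;
* zero beyond.

The parameter `alpha` is the *stable repulsion ratio*: the centre distance
of two attached cells at force balance, divided by the sum of their radii.
`alpha = 1` gives a repulsion-only (RO) law, the limit in which cells push
but never pull. `alpha < 1` adds an adhesion well between
`alpha (Ri + Rj)` and `Ri + Rj`. The asymmetric-attraction (AA) model uses
`alpha = 0.90` for the EMS--P2 pair and `alpha = 0.75` for every other
pair, i.e. the EMS--P2 contact is the least adhesive one. Only the
boundary values (F0 at `min(Ri, Rj)`, zero at `alpha (Ri + Rj)`, zero at
and beyond `Ri + Rj`) and continuity are constrained by the underlying
biology; the piecewise-linear interpolant is the simplest law satisfying
all of them and is the one implemented.

**Eggshell.** A rigid ellipsoid of revolution about the
anterior--posterior (x) axis, semi-axes `lx >= ly = lz`, aspect ratio
`AR = lx/ly`. Sweeps reshape the shell at constant volume,
`ly = (3V / 4 pi AR)^(1/3)`. A cell touching the shell (centre-to-surface
distance `a <= R`) is pushed along the inward surface normal with
magnitude `shell_gain (R - a)/R`; the exact profile is not constrained
beyond being continuous, vanishing at `a = R` and growing with overlap,
and this linear ramp is the simplest such choice. The distance `a` solves
the perpendicular-foot condition; by axial symmetry that is a 1-D root
problem in the foot-point parameter, solved by a guarded Newton iteration
(tolerance 1e-12, verified against dense surface sampling to 1e-6 um in
the test suite).

**Divisions.** A run starts at the two-cell stage, AB and P1 placed 2.0 um
apart on the x-axis at the shell centre. AB divides along z into ABa and
ABp; P1 divides along x into EMS and P2 120 s later (wild type, "T-div").
The perturbed orientation classes seen in par-depleted embryos are
expressible in the same machinery: I-div (both along x), H-div (both along
z), C-div (one z, one y), optionally with simultaneous timing and equal
volumes. A division replaces the mother by two daughters offset
symmetrically along the division axis; volumes split exactly by the
configured fraction and radii follow `R = (3V / 4 pi)^(1/3)`.

**Classification.** After a settling interval the final state's contact
graph is computed -- an edge whenever `d < Ri + Rj`, strictly, so grazing
contact counts as separation -- and matched, up to swapping the two AB
daughters, against the named templates: pyramid (all 6 edges), diamond
(missing exactly one ABd--P2 edge), T-shaped (missing both ABd--P2 edges),
linear (the chain ABd--ABd--EMS--P2), T-reverse (one ABd holding EMS and
P2 while its sister holds only it), H-shaped (any 4-cycle), and "other"
for everything else. Nothing is coerced to a nearest named pattern.

## Parameters

| parameter | default | units | role |
|---|---|---|---|
| `shell_volume` | 23 562 | um^3 | egg volume (25 x 15 x 15 um semi-axes), held fixed in sweeps |
| `cell_volume_fraction` | 0.92 | -- | total blastomere volume / shell volume |
| `F0` | 0.45 | um/s | pairwise force amplitude at deep overlap |
| `shell_gain` | 0.8 | um/s | scale of the eggshell response |
| `noise_variance` | 0.027 | um^2 | per-component displacement variance per step |
| `dt` | 5 | s | Euler--Maruyama step |
| `alpha` | 0.90 EMS--P2, 0.75 others | -- | stable repulsion ratios (AA); all 1 in RO |
| `t_first`, `interval` | 300, 120 | s | AB division time; P1 delay |
| `settle` | 600 | s | post-division interval before classification |
| `ab_fraction` | 0.60 | -- | AB share of embryo volume |
| `aba_fraction`, `ems_fraction` | 0.55, 0.60 | -- | ABa share of AB; EMS share of P1 |
| `offset` | 2.0 | um | daughter centre separation at division |

`alpha`, the noise variance, dt, the initial 2.0-um separation and the
constant-volume AR sweep (1.0--4.0, step 0.1, 30 replicates) are taken
directly from the experimental characterisation of the system. The
remaining mechanical and timing constants are not published; they were
calibrated once, against two criteria, and then frozen in
`default_config()` (also shipped as `inst/extdata/default_config.json`):

1. a free pair of cells must relax to its stable separation well within
   one inter-division interval (`two_cell_relaxation()` reports
   convergence to `alpha (R1 + R2)` within 1e-3 um in under 420 s);
2. the repulsion-only model must reproduce its reference phase behaviour
   -- pyramid at AR near 1, diamond on the 1.4--2.0 plateau, linear above
   2.0 -- which is the behaviour the unpublished parameter set was
   reported to produce, making it the natural calibration target.

The volume fractions are within the physiological range (AB is the larger
two-cell blastomere; EMS is the larger P1 daughter; the AB daughters are
nearly equal). No acceptance threshold, tolerance or seed was adjusted
after this calibration was frozen.

## What the generator emulates, and what it does not

A replicate is a synthetic embryo: the stated initial configuration, the
programmed divisions, thermal positional noise, and nothing else. Cells
remain perfect spheres -- there is no shape deformation, no surface
tension, no cortical flow and no adhesion-molecule kinetics; the shell is
a perfect rigid ellipsoid, whereas strongly elongated real eggshells
bulge near the poles; spindle reorientation in elongated cells
(Hertwig's rule) is absent, divisions occur exactly on schedule along
fixed axes. A green arrangement-frequency test therefore establishes that
*this force law in this geometry* reproduces the reference pattern
statistics; it says nothing about molecular mechanism, and deviations at
extreme AR (where real embryos show T-reverse arrangements the spherical
model cannot favour) are expected rather than alarming.

## Numerical choices

* Explicit Euler--Maruyama at the stated dt = 5 s; no adaptive stepping.
  With the frozen force scales the per-step contraction factors are well
  inside the stable region.
* The noise variance is interpreted as the per-component, per-step
  displacement variance, in um^2; the description of the noise vector
  attaches no units, and this is the weakest (most conservative) reading.
* If a step would carry a centre onto or beyond the shell, the centre is
  rescaled radially to ellipsoidal radius 0.99. A radial rescale rather
  than a normal projection keeps the operation well defined for any
  exterior point and coincides with it for spheres; shell repulsion makes
  the clamp a rare event in practice.
* A point at the exact centre of a spherical shell has no defined surface
  normal; the foot is taken at (-lx, 0, 0) by convention and noise breaks
  the symmetry at the next step. On the major axis of a prolate shell the
  nearest surface points form a ring below the evolute cusp; the +y
  azimuth is chosen deterministically.
* Contact uses strict inequality; a pair at exactly `d = Ri + Rj`
  (measure zero) is not in contact.
* Replicate seeds derive from (master seed, orientation class,
  round(100 AR), replicate index) by congruential mixing mod 2^31 - 1,
  exact in double arithmetic, so a condition's replicates are invariant
  to which other conditions are swept. The force model is deliberately
  not hashed: an RO sweep is bit-identical to an AA sweep whose alpha
  table is overridden to all 1.
* Classification reads the single final state; no temporal smoothing. A
  consequence worth knowing: in the RO model an uncompressed attached
  pair equilibrates at exactly `d = Ri + Rj`, the classification
  boundary, so a pattern whose definition hinges on such a pair can
  flicker with the noise. The frozen configuration keeps the embryo
  compressed enough that this is rare on the reported conditions.

## Known limitations

Runs stop at the four-cell stage. The eggshell cannot deform or thicken.
The RO/AA dichotomy compresses all adhesion biology into one ratio per
pair. Arrangement frequencies within a few percentage points of a plateau
(100% or 0%) remain binomial estimates from 30 replicates. The T-reverse
pattern is classified but not favoured by the spherical-cell mechanics,
matching its absence from the simulated reference outcomes.
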