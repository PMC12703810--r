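---
title: "Methods and design notes for mrfmap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design notes for mrfmap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`mrfmap` implements a complete magnetic resonance fingerprinting (MRF)
T1/T2 quantification chain for an inversion-prepared, gradient-spoiled
FISP echo train, together with the phantom/in-vivo style quality-assurance
statistics used to validate quantitative MRI systems, and a synthetic
digital-phantom generator so the whole pipeline runs and is tested without
any scanner data. This vignette records the model, its assumptions, the
parameters that matter, and the design decisions that were genuinely open.

## Signal model

The acquisition is a single adiabatic inversion followed by a train of
small-to-moderate flip-angle excitations (0-74 degrees) with constant RF
phase, 2 ms echo time and repetition times varying within 12.1-15.0 ms.
Each voxel's complex signal evolution over the 1500 excitations is the
fingerprint to be matched.

`simulate_signal()` evaluates this model with the extended phase graph
(EPG) formalism for unbalanced sequences: configuration states
$(F_k, F_{-k}, Z_k)$ evolve under per-pulse RF mixing, $T_1$/$T_2$
relaxation split at the echo time, and a unit gradient-dephasing shift per
TR. The detected sample is $F_0$ at TE. The recursion is validated against
an independent isochromat Bloch simulator (1000 spins uniformly dephased
over $2\pi$ per TR, identical event sequence) to below 1% relative RMS —
in practice the agreement is ~1e-7.

Assumptions and deliberate omissions:

* ideal inversion (efficiency 1.0; an `inv_eff` knob exists),
* instantaneous RF pulses, no slice-profile averaging,
* no magnetization transfer, diffusion, flow, or off-resonance effects,
* noise entering in image space as i.i.d. complex Gaussian per time point
  (the spiral/NUFFT/coil-combination chain of a real reconstruction is out
  of scope).

**EPG truncation.** The default retains 30 configuration orders. On the
default schedule at a white-matter-like probe (T1 = 1000 ms, T2 = 100 ms),
doubling to 60 states changes the signal by < 1e-6 relative RMS (tested).
Convergence degrades for very long T2: a CSF-like (T2 ≈ 3000 ms)
evolution at 30 states is accurate to ~5e-4. Because probes and dictionary
atoms are simulated with the same truncation, matching is self-consistent;
users studying long-T2 species specifically can raise `n_epg_states`.

**The flip/TR pattern is data, not algorithm.** The clinical sequence's
exact temporal pattern is not public. `default_schedule()` provides a
documented deterministic stand-in — half-sinusoid flip lobes (peaks 44-74
degrees, one zero between lobes, 250 pulses per lobe) and a smooth TR
series from a fixed mixture of incommensurate harmonics (periods 17, 61
and 193 pulses; constants in the source). No RNG state is consumed, so
the schedule is byte-stable. Any real pattern can be loaded with
`read_schedule_csv()`; everything downstream is pattern-agnostic.

## Dictionary

`grid_spec()` reproduces the multi-resolution clinical grid: T1 from 10
to 4500 ms with steps 10/20/40/100 ms, T2 from 2 to 3000 ms with steps
2/5/10/50/100/200 ms, and relative B1 from 0.6 to 1.4 in steps of 0.01.
Segment boundaries shared by two segments appear once. Combinations with
T2 > T1 are *included* by default (fluid-like entries need T2 of the same
order as T1; a flag excludes them).

Atoms are unit-L2-norm complex signal evolutions. `compress_dictionary()`
projects them onto the top-`rank` right singular vectors of the atom
matrix (default rank 50). The basis is obtained from the Hermitian
eigendecomposition of the time-domain Gram matrix $A^H A$ — much cheaper
than a direct SVD when entries far outnumber time points, and exact for
the leading components. Conventions: with atoms as rows of $A$ and basis
$V$, stored coordinates are $C = A\,\overline{V}$ so the matching product
$\langle a, s\rangle = \sum \overline{a}\,s$ is computed in compressed
space as $\overline{C}\,(V^H s)$, identical to the full-space product up
to truncation.

At desk scale the full 81-value B1 axis is supported but rarely built;
tests and examples use thinned subsets (e.g. {0.9, 1.0, 1.1}), which is a
runtime choice only — matching snaps each voxel's measured B1 to whatever
planes exist.

## Matching

`match_pixel()`/`match_image()` implement B1-informed exhaustive
inner-product matching: the measured per-voxel B1 fixes the dictionary
plane (nearest grid value; exact midpoints resolve to the *lower* plane;
values outside [0.6, 1.4] are clamped with a warning), then the entry
maximizing $|\langle \text{atom}, \text{signal}\rangle|$ wins. The
magnitude is used because the acquisition phase convention is arbitrary.
Ties break deterministically to the lowest T1, then lowest T2. Since
atoms are unit norm, $M_0 = \langle \text{atom}, s_{\text{raw}}\rangle$;
the map reports its magnitude. Zero-norm voxels are masked rather than
matched. Approximate-nearest-neighbor acceleration is deliberately out of
scope; exhaustive search is the reference semantics.

`apply_t1_mask()` removes voxels with matched T1 below 400 ms from the
reporting mask: the B1 mapping feeding the matcher is unreliable below
that, which in practice masks fat-like species. Masking is monotone in
the threshold and never mutates its input.

## Synthetic data generator

The generator states a world and keeps it fixed:

* **Vial phantom** — 16 mm cylindrical vials in a fibroglandular-mimic
  background at 1 x 1 x 5 mm voxels over 7 slices: one 0% PVP vial, two
  each of 10/25/40% PVP, four fat mimics. PVP and FBG T1/T2 are the NMR
  reference values (e.g. 40% PVP: 656/472 ms; FBG: 1321/41 ms). The fat
  mimic values (300/60 ms) are *invented* — the real fat vials are masked
  and unreported — and exist only to exercise the masking path; they are
  configurable and documented as non-reference.
* **Brain-like volumes** — compact non-overlapping blobs grown to exact
  voxel counts (5 mm^3 granularity) at CSF/GM/WM population means
  (3383/453, 1516/68, 1046/46 ms). Default target volumes are desk-scale
  stand-ins, not anatomical volumes.
* **B1 fields** — seeded quadratic polynomial centered at 1.0, scaled to
  a stated amplitude, clipped to [0.6, 1.4].
* **Noise** — i.i.d. complex Gaussian per voxel and time point, SD stated
  as a fraction of peak proton density; default 2%. Test-retest pairs
  share truth and B1 and differ only in noise seeds.

Voxel membership is by voxel center — no partial-volume mixing. A green
test therefore establishes correctness of the algorithmic chain under the
stated noise model; it does not establish robustness to partial volume,
CSF pulsation, B0 blurring, motion, or reconstruction artifacts, none of
which are modeled.

## Reference relaxometry

The gold-standard fits mirror an NMR metrology protocol: T1 by
inversion recovery at 20 log-spaced TIs, model
$S(\mathrm{TI}) = a + b\,e^{-\mathrm{TI}/T_1}$ on signed data (three
parameters — the protocol's standard IR model; a four-parameter
inversion-efficiency variant was considered and left out, with a
magnitude-mode knob restoring signs at the zero crossing instead); T2 by
single-echo spin echo at 51 log-spaced TEs from 2.026 to 2502 ms, model
$S(\mathrm{TE}) = A\,e^{-\mathrm{TE}/T_2}$ (no offset unless requested).
The IR TI range is not part of the protocol statement; the default
50-15000 ms spans recovery of the slowest phantom material (T1 2872 ms).
Fits are unweighted nonlinear least squares initialized from log-linear
regressions; `nls` runs with `scaleOffset` so noiseless (zero-residual)
data converges cleanly. Failures return a flagged result, never an error.

## QA statistics

* Test-retest variation:
  $\mathrm{Var} = \frac{1}{N}\sum_i \frac{|t_i - r_i|}{(t_i + r_i)/2}\times 100$.
  The absolute value is a deliberate reading: the quantity is a
  *variation* and all its reported values are positive; without the bars
  positive and negative differences would cancel.
* Longitudinal CV: sample SD over mean, in percent. Sessions contribute
  the mean of their test and retest ROI means by default
  (`cv_pool_repeats` pools every repeat instead) — the longitudinal
  protocol defines the study-level value only loosely, so the choice is a
  flag, not a constant.
* Percent deviation from reference: signed.
* Bland-Altman: per-pair signed percent differences relative to the pair
  mean; limits at mean ± 1.96 x sample SD *of the percent differences*
  (the agreement plots are drawn in percent).
* ROI means: 8 mm circles, center-in-circle pixel membership (unambiguous
  on the 1 mm grid), masked voxels excluded, fully masked ROIs raise.
* Region summaries: mean, sample SD, and volume = unmasked voxel count x
  0.005 cm^3.
* Age trends: OLS with $R^2$ and the two-sided slope p-value from the t
  statistic; no multiple-testing correction (raw p per region).

Sample (n-1) standard deviations are used everywhere.

## File formats

The deliverable environment has no NIfTI or HDF5 R bindings, so the
package persists volumes and dictionaries as plain-text containers: a
directory with `meta.json` (shape, geometry, format version) plus one CSV
per volume, and the dictionary as `meta.json` + `entries.csv` + real/imag
CSV pairs. Plain text is diff-able and byte-deterministic (identical
config and seeds reproduce identical files, which the tests assert);
volumes round-trip at float32-equivalent precision (8 significant
digits) while statistics run in float64. Masked voxels are written as
NaN with the mask stored as its own volume. Pipeline configuration is
JSON.

## Desk-scale choices in the test suite

Unit tests run on short schedules (150-400 points) and coarse grids;
physics fidelity is asserted where it belongs (oracle agreement,
convergence, recovery within one grid step). The acceptance suite builds
the full default T1/T2 grid on the 1500-point schedule with a thinned
B1 subset {0.9, 1.0, 1.1}; the volume-dependence experiment (three
gray-matter-like regions of 0.125/1/8 cm^3, 2% noise, 100 seed-pairs,
200 matched maps) matches against the default-step sub-grid covering
T1 1000-2000 ms / T2 40-150 ms so it stays inside its runtime budget.
These are runtime reductions, not physics changes, and none of them were
chosen by looking at test outcomes.

## Known limitations

* The stand-in schedule is not the clinical pattern; absolute
  timing-dependent numbers (e.g. exact score margins) will differ from
  any specific scanner implementation.
* Long-T2 atoms carry ~5e-4 truncation error at the default 30 EPG
  states.
* The matcher is exhaustive; very large dictionaries (full 81-plane B1
  axis) are compute-bound.
* The generator's crisp-edged, noise-only world makes repeatability
  statistics optimistic relative to real scanners, where segmentation,
  registration and physiological effects dominate small-region variance.
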