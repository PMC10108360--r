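---
title: "Orientation-based membrane screening: models, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Orientation-based membrane screening: models, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(membscreen)
```

## The screening problem

Protein kinase C (PKC) is activated when its C1 domain engages
diacylglycerol (DAG) or a DAG-mimetic agonist at the membrane surface.
For a small-molecule DAG mimetic to be available for that interaction, it
must partition into the bilayer in a particular pose: its hydroxymethyl
group pointing out of the hydrocarbon core toward the lipid–water
interface, the molecule sitting shallow enough that the hydroxy and
carbonyl groups can reach the half-inserted C1 domain. A candidate that
flips over and buries its hydroxy group deep in the core — for example
because an intramolecular hydrogen bond sequesters it — presents nothing
to the protein and is predicted to be a poor agonist, whatever its gas-phase
pharmacophore looks like.

Molecular-dynamics simulations of candidates embedded in an anionic
bilayer can discriminate these behaviors, but the discrimination lives in
the *post-processing*: orientation–depth population maps, density
profiles, hydrogen-bond counts, solvent-accessible surface areas and
cluster statistics. `membscreen` implements that post-processing layer,
with a synthetic trajectory generator providing ground truth so the whole
pipeline is testable without running any MD.

## Observables and conventions

**Tilt angle and depth.** Each ligand copy carries a central axis vector
from the mass-weighted centroid of its heteroaromatic core ring to its
hydroxy oxygen (both endpoints configurable per ligand in `ligand_spec()`).
The tilt angle $\theta$ is the angle between that axis and the membrane
normal; the depth is the distance of the hydroxy-group center of mass from
the bilayer center of mass along the normal. The membrane normal is fixed
to the box $z$ axis: the systems this targets are flat bilayer patches, and
an instantaneous fitted normal would add noise without information. Axis
endpoints were chosen so that the axis points the hydroxymethyl toward
water exactly when $\theta$ is small — that makes "correct" a small-angle
statement in both leaflets.

Two conventions remove sign ambiguity. First, $\theta$ is measured against
the per-leaflet *outward* normal ($+z$ for the upper leaflet, $-z$ for the
lower), so a correctly oriented ligand reads $\theta \lesssim 50^\circ$
whichever leaflet it occupies, and a flipped one reads
$\theta \gtrsim 130^\circ$. Second, depth is folded to a nonnegative
distance from the bilayer center (leaflet folding), so both leaflets
contribute to one population map. A consequence worth testing (and tested):
mirroring every $z$ coordinate through the bilayer midplane leaves every
$(\theta, \mathrm{depth})$ sample unchanged.

**The population heat map and verdict.** Samples accumulate into a 2D
histogram with half-open bins (last bin closed), by default
$5^\circ \times 0.05$ nm — the apparent resolution of published maps of
this kind; both are configurable and echoed into reports. Counts are kept
raw internally (conservation is exact and testable); normalization happens
at plotting time. Classification reasons about the *mode* cell, because
the field reasons about "the main population": the verdict is `correct`
when the mode has $\theta \le 60^\circ$ and depth $\ge 1.4$ nm, `incorrect`
when $\theta \ge 120^\circ$ and depth $\le 1.2$ nm, `ambiguous` otherwise.
These defaults are calibrated to separate the reference populations
(correct at $\sim 1.6$ nm, $\theta \lesssim 50^\circ$; incorrect at
$\sim 1$ nm, $\theta \gtrsim 130^\circ$) with a wide margin on both sides;
they are thresholds of convenience, not published constants, which is why
they are configuration keys and appear in every report. The minority
population on the far side of $\theta = 90^\circ$ is reported as a
fraction, never penalized — transient flips are real and expected.

**Density profiles.** Partial mass densities (kg m$^{-3}$) are accumulated
along $z$ after recentering each frame on the lipid center of mass, which
removes the slow bilayer drift that would otherwise smear microsecond-scale
profiles. Mass units were chosen over number densities because the natural
overlay — whole molecule and hydroxy group, very different atom counts —
only reads sensibly on a common mass scale. The bin grid always covers the
full box height, so the profile integral times the lateral area returns
the group's total mass exactly; this is the module's conservation
invariant. The lipid–water interface is the outermost sign change of
(water − lipid) density in each half-space, linearly interpolated between
bin centers. Signed-$z$ profiles are kept; folding is a plotting option.

**Hydrogen bonds.** The criterion is the conventional geometric one:
donor–acceptor distance $\le 0.35$ nm and H–D–A angle $\le 30^\circ$ —
the source analyses printed no cutoffs, so both are configuration keys
echoed into every report, and the H–D–A (vertex at donor) convention is
documented here precisely because unstated conventions are the main
obstacle to reproducing this kind of analysis. The hydroxy group acts as
both donor and acceptor; ester/amide carbonyl oxygens and amide nitrogens
are acceptors only. "Per molecule" means summed over the ligand copies and
divided by the copy count. Detection offers a periodic cell-list path and
an exhaustive path; they must return identical triples, and the test suite
enforces exactly that.

**SASA.** Shrake–Rupley dot surfaces: each atom's sphere (vdW radius +
0.14 nm probe) is sampled with a deterministic Fibonacci spiral lattice of
960 dots, so areas are seed-free and bit-reproducible; the single-dot
resolution is $4\pi(r+p)^2/960 \approx 10^{-3}$ nm$^2$, and the practical
error for partially occluded spheres is governed by boundary dots,
$\mathcal{O}(4\pi(r+p)^2/\sqrt{n_\mathrm{dots}})$. Radii come from a
Bondi-type table keyed on the element inferred from the atom name, with
per-name overrides. Occluders default to *every* other atom in the system
— lipids, water, ions, the other ligand copies, the rest of the molecule —
because the quantity of interest is the group's availability in the
membrane context; a config switch restricts the occluder set (e.g. to
study clustering effects on exposure).

**Block statistics.** Every tabulated observable is a time-block average:
the analyzed span divided into 5 contiguous equal blocks (remainder frames
dropped from the end and logged), the error bar being the standard
deviation over block means — deliberately the SD, not the SEM. At the
reference span of 1500 ns this gives the canonical 5 × 300 ns layout.

**Clusters.** Copies are adjacent when their minimum-image minimum
inter-atomic distance is ≤ 0.4 nm; clusters are single-linkage connected
components. No published criterion exists for these transient aggregates,
so the cutoff is a config key; single linkage matches the qualitative
"clusters formed and disassembled" description of the phenomenon.

## The synthetic generator

`generate_scenario()` emulates the assay-mimicking simulation system — an
anionic-lipid bilayer (128 lipids at full scale), 6400 waters, 128 K$^+$,
four ligand copies placed with lateral separation — at a reduced default
scale of 16 three-bead pseudo-lipids, 400 three-site waters, 16 ions and 4
copies in a 4 × 4 × 10 nm box, 200 frames of 7.5 ns (the 1500 ns analyzed
span). Head beads sit on the ±2.0 nm phosphate planes; the default tilt
(30° ± 8°) and depth (1.65 ± 0.08 nm) distributions reproduce the
correct-orientation reference population, and `reference_scenarios()`
provides the flipped (150°, 1.0 nm), ambiguous and hydroxy-less variants.

Design points a user should know:

* **Frames are i.i.d. draws, not dynamics.** Every statistic in the
  pipeline is a time-average of configurational observables, so an
  emulator with known marginal distributions is exactly what the tests
  need; no force field, integrator or correlation structure is pretended.
* **Solvent excluded volume.** Waters landing within 0.45 nm of any ligand
  atom are displaced to the outer water shell. Physically no water sits
  inside a ligand; operationally this guarantees that injected
  ideal-geometry H-bond events (donor–acceptor 0.30 nm, angle 0°) are the
  *only* ligand–water bonds, so a configured Bernoulli event rate is the
  exact expected count — the ground-truth contract the H-bond tests rely
  on.
* **Ground truth is recorded, not re-derived**: every drawn angle, depth,
  leaflet, flip, H-bond event and cluster episode is stored alongside the
  trajectory (and serialized to JSON by `write_scenario()`).
* **What the emulator does not reproduce:** realistic lipid packing
  density (the reduced-scale core is sparse), correlated dynamics and
  H-bond lifetimes, electrostatics, and any force-field physics. Passing
  tests therefore demonstrate that the *analysis* is correct, determinate
  and self-consistent — not that any particular chemistry is right.

## Numerical choices and degenerate inputs

* Molecule unwrapping is a breadth-first minimum-image walk over the bond
  graph from a root atom; a disconnected graph is an error listing
  component sizes, not a silent partial unwrap.
* The bilayer center is computed with minimum-image displacements relative
  to the first lipid atom, so a bilayer drifting through the periodic
  boundary is handled.
* Heat-map mode ties break deterministically toward smaller $\theta$, then
  smaller depth.
* A zero-length ligand axis raises a degenerate-geometry error; an empty
  sample stream yields an empty heat map (not an error) but asking for its
  mode raises.
* Interface localization requires a genuine sign change; flat zero
  stretches (e.g. a waterless profile) are not interfaces and raise a
  no-interface error.
* Only orthorhombic boxes are accepted; triclinic GRO boxes are rejected
  outright rather than silently skewing every minimum-image distance.
* GRO coordinates are fixed-point with 3 decimals; the write→read round
  trip is exact at that precision and the writer refuses coordinates that
  would overflow the fixed columns.

## Problem sizes used in the shipped tests

Unit tests run scenarios of 15–150 frames at the reduced scale;
distribution-recovery tests use 1500 frames × 4 copies (6000 draws), and
mode-recovery tests 5000 frames × 4 copies (20 000 samples) with the
water/ion count set to zero, since solvent plays no role in the
orientation observable. The acceptance script classifies ten independent
seeds per reference scenario at the default 200-frame span. These sizes
were chosen so the statistical assertions (3-standard-error bands,
one-bin mode recovery) are meaningful while the whole suite stays quick on
a laptop.

## Known limitations

* The pipeline analyzes; it does not simulate. Real trajectories must come
  from an MD engine, via GRO (or through any reader that can populate the
  `trajectory()` container — XTC/TRR/DCD readers are deliberately out of
  scope).
* One global z-axis normal: curved or undulating membranes are out of
  scope.
* The classifier is a mode-based decision rule with configurable
  thresholds; it is intended for ranking and flagging, not as a calibrated
  probability of biological activity.
* H-bond analysis is geometric only — no energetic or orbital definitions,
  and no lifetime/autocorrelation analysis.
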