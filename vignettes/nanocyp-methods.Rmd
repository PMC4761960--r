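---
title: "nanocyp: models, criteria and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{nanocyp: models, criteria and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nanocyp)
```

`nanocyp` analyses trajectories of a carbon nanotube interacting with a
protein — canonically a carboxylated single-walled carbon nanotube
(c-SWCNT) against CYP3A4, whose buried active site exchanges substrates
and products with the solvent through named access channels (2a, 2b, 2c,
2e, 3, S). The scientific question the statistics address is whether the
tube occludes those channels, and which interaction modes (π-π stacking,
salt bridges, hydrogen bonds, nonspecific contacts) hold it in place.
This vignette records the models, the tunable parameters, and the design
decisions taken where the problem statement was genuinely open.

## Units and containers

All in-memory quantities use MD-community units: nm, ps, kJ/mol, and the
elementary charge e. PDB I/O converts Å↔nm at the boundary; GRO is
already nm. kcal/mol exports (÷ 4.184) accompany all energies because the
literature mixes both.

A `md_structure` is an ordered atom table plus named atom groups
(`cnt`, `carboxyl`, `protein`, ...); a `md_trajectory` couples one
topology to a list of coordinate frames with strictly increasing ps
timestamps. Atom indices are 1-based, the native R convention; residue
numbers are preserved exactly as read. Multi-model PDB is the on-disk
trajectory format; it has no time field, so frame times are synthesized
as 0, 1, 2, … ps and flagged (`times_synthesized`), and the pipeline
config can override the spacing (`frame_spacing_ps`). XTC/DCD are binary
formats that would need an external reader and are rejected with an
informative error rather than half-supported.

## The armchair tube builder

An armchair (n,n) tube is a graphene sheet wrapped by arc length: the
chiral vector has length 3·n·a_cc (a_cc = 0.142 nm), giving radius
R = 3·n·a_cc/2π and the closed-form diameter

d = (√3·a_cc/π)·√(3n²),

which is 1.627 nm for n = 12 — the nominal "1.6 nm" tube. Atoms lie in
circumferential rings of 2n, spaced √3/2·a_cc apart; one translational
period T = √3·a_cc holds 4n atoms.

**Length realization.** The canonical "7.0 nm, 1340 atoms" figure is not
a whole multiple of any armchair ring: 1340/24 is not an integer, so no
ring-complete (12,12) tube has exactly 1340 atoms. The builder therefore
realizes the *whole number of translational periods nearest the request*
and reports the achieved length: for 7.0 nm that is 28 periods = 56 rings
= 1344 atoms at 6.887 nm. This choice — periods, not rings — is forced by
consistency: a tube of exactly k axial periods must contain 4n·k atoms
(the builder's own invariant, testable by brute-force lattice
enumeration), and it lands within 0.3% of the published atom count where
ring-nearest rounding would miss by 3.9%.

**Wrapping distortion.** Mapping the flat sheet onto the cylinder by arc
length turns in-plane bonds into chords; for n = 12 the shortening is
< 0.7%, every interior atom keeps exactly 3 neighbours and rim atoms 2.
This is the standard builder convention; bond-length fidelity is not used
downstream, so it is documented rather than corrected.

**Carboxylation.** `carboxylate_edges()` attaches deprotonated carboxyl
groups (C + 2 O) to rim carbons, split as evenly as possible between the
two open ends ("mostly located at the two edges"); site choice within a
rim is a seeded draw. Published information fixes only the total charge
(−1 e per group); the internal geometry (C–C 0.142 nm axial, C–O
0.125 nm, O–C–O 124°) and the charge split (−0.5 e per oxygen, 0 on the
carbon) are idealized choices that conserve the group charge, which is
all any downstream statistic consumes.

**Nonbonded parameters.** Tube sp² carbons carry the uncharged pair
ε_cc = 0.36 kJ/mol, σ_cc = 0.34 nm. Protein atoms fall back to a bundled
element-keyed table that is deliberately *not* a biomolecular force
field: reproducing CHARMM27 is out of scope, so energies computed with
the fallback are comparable to published simulation energies in trend
only. Every value is in `default_parameter_table()` and can be replaced
wholesale.

## Fingerprint criteria

None of the interaction definitions used in the source analyses are
published with numbers, so `nanocyp` adopts widely used
trajectory-analysis defaults and exposes all of them:

| criterion | default | note |
|---|---|---|
| heavy-atom contact | pair distance ≤ 0.5 nm | common in the nano-bio MD literature |
| hydrogen bond | D–A ≤ 0.35 nm and D–H···A ≥ 150° | classic geometric H-bond |
| salt bridge | N⁺–O⁻ ≤ 0.4 nm | reported once per residue pair, min distance |
| π-π parallel | centroid ≤ 0.45 nm, angle ≤ 30°, offset ≤ 0.20 nm | face-to-face |
| π-π T-shape | centroid ≤ 0.55 nm, angle 60–90° | edge-to-face |

Because the tube wall is curved, stacking is evaluated *locally*: the
reference point is the nearest lattice hexagon centroid (the builder
enumerates hexagon membership) and the surface normal is the radial unit
vector at the nearest tube atom, with the tube axis refit per frame by
principal components so the classification survives rigid motion. A ring
produces at most one event per frame; if both class gates pass, parallel
wins — the thresholds were chosen to make the two classes crisp and
mutually exclusive. Histidine counts as cationic only if its formal
charge is explicitly set, since protonation is input-dependent.

Salt-bridge detection requires explicit charge annotations
(`formal_charge` column): the builders set them (+1 on the toy lysine
NZ, −0.5 on carboxylate oxygens), raw PDB input has none, and silently
treating unannotated atoms as neutral would hide errors, so it is an
error instead.

## Channel occlusion

A channel is specified by its lining residues (a selection expression —
lining sets are shipped as editable configuration examples, not
hard-coded truth, since the canonical definitions belong to the tunnel
literature). The mouth centroid is the mean lining Cα position; the
outward vector points from the protein center of geometry through the
centroid. A frame is *blocked* when any tube heavy atom is within
`block_distance` (default 0.7 nm) of the centroid. This minimum-distance
operationalization is the simplest criterion that reproduces the pooled
arithmetic exactly, because the pooled statistic depends only on onsets;
a probe-disc occupancy criterion remains a config stub (`mouth_radius`).

The per-run onset is the earliest time t such that the blocked fraction
over [t, end] is at least `persistence` (default 1.0, mirroring blocking
that "remains unchanged until the end"; lower it for noisy data). The
pooled statistic is Σ blocked time / Σ duration — for three 120 ns runs
with onsets 40, 10 and 28 ns this is (360 − 78)/360 = 78.33%.

## Energetics and RMSD

Interaction energies are pairwise sums over cross pairs within a cutoff
(default 1.0 nm, mirroring the usual 10 Å vdW truncation):
4ε[(σ/r)¹² − (σ/r)⁶] with Lorentz–Berthelot combination, plus
f·q_iq_j/r with f = 138.935458 kJ·mol⁻¹·nm·e⁻². There is deliberately no
Ewald/mesh summation or reaction field: this is post-hoc analysis in
vacuum, so absolute Coulomb values differ from engine output computed
with PME; trends are preserved. RMSD uses Kabsch superposition with the
reflection guard (smallest singular vector sign-flipped when the
determinant is negative), so pure rigid motion yields RMSD ≤ 1e-6 nm and
the result matches an independent quaternion-based superposition.

## The synthetic generator: what a green test establishes

`generate_scenario()` does not simulate anything. A toy host (a compact
body, three mouth-lining residues, and one each of an aromatic PHE-like,
cationic LYS-like, amide GLN-like and backbone GLY-like site, numbered
228/35/78/31 so reports read analogously to the real system) sits fixed;
a small (5,5) tube and the event residues are *placed* frame by frame.
During an event's frame range the geometry satisfies the corresponding
detector's criteria with a margin of at least 20% of each threshold
(blocking pose at 0.6× the block distance; stacking at 0.35 nm/0° and
0.40 nm/80°; H-bond and salt bridge at 0.8× their cutoffs); outside it,
pieces are parked ≥ 2.5 nm away. Seeded Gaussian jitter is applied last;
one seed controls everything, and margins were fixed before any test was
run so that the default 0.02 nm jitter cannot flip classifications.

Ground truth (event frame sets, implied onset, implied ratios) is
therefore exact, and the validation suite demands exact recovery at zero
jitter and ≤ 2 frames of onset error at 0.02 nm jitter across 20 seeds.
What a green run establishes is that the *detectors implement their
geometric definitions correctly and degrade gracefully under coordinate
noise* — not that the defaults are the right chemistry for any particular
real system, and not anything about magnitudes that depend on long
equilibrium trajectories (contact plateaus near ~2000, RMSD near
~0.2 nm, vdW near −120 kcal/mol): those require the original 100+ ns
simulations and are out of reach of desk-scale synthetic data, which is
why the acceptance battery substitutes property-based checks
(brute-force oracle equality, exact recovery, monotonicity, rigid-motion
invariance, byte-identical reports).

## Numerical and degenerate-input choices

* Selections: empty resolution is a valid result, distinguishable from
  syntax errors (reported with a character position) and unknown groups.
* Rings with fewer than 5 atoms, or collinear rings, are errors — a plane
  fit on them is meaningless.
* Fixed-width writers refuse over-long names rather than truncating;
  PDB serials beyond 99999 switch to hexadecimal.
* `pool_blocked_fraction` works from `blocked_fraction × duration`, so it
  is identical to per-frame flag counting for any uniform frame spacing
  (property-tested), and run summaries with known onsets can be pooled
  without frames.
* Determinism: builders take explicit seeds; the pipeline report omits
  wall-clock data (a sidecar carries it) so identical inputs give
  byte-identical JSON.

## Known limitations

* No MD engine, no solvent, no bonded terms, no free energies.
* Energies are trend-only (simplified parameters, truncated vacuum sums).
* Stacking detection assumes a reasonably intact tube lattice (hexagon
  membership is computed at build time).
* The toy host is a scaffold, not a protein: detector validation there
  does not validate residue-level conclusions about any real enzyme.
* Tunnel *finding* (CAVER-style) and allosteric closure detection are out
  of scope; channels must be specified by their lining residues.
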