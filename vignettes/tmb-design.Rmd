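---
title: "Designing and analyzing transmembrane beta-barrel nanopores"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing and analyzing transmembrane beta-barrel nanopores}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tmbarrel)
```

Transmembrane beta-barrels (TMBs) are membrane proteins whose single
beta-sheet closes into a cylinder spanning the lipid bilayer.  Built
from scratch, they make attractive nanopores: the channel width and
shape follow directly from two integers — the number of strands and the
shear number — rather than from whatever evolution happened to provide.
This vignette explains the models behind each of the package's
components, the parameters that matter, and the choices made where the
design was genuinely open.

## Barrel geometry

A closed barrel of `n` antiparallel strands with shear number `S`
(the register offset accumulated over one full circuit of
strand-to-strand hydrogen bonding) built from a beta-sheet with rise
`a` per residue along the strand and interstrand spacing `b` lies on a
cylinder of circumference

$$C = \sqrt{(Sa)^2 + (nb)^2}, \qquad R = C / 2\pi,$$

with the strands tilted by $\alpha = \mathrm{atan2}(Sa,\, nb)$ relative
to the barrel axis.  `barrel_radius()` implements the closed form;
`build_calpha_lattice()` realizes it as coordinates.  The defaults
`a = 3.32` Å and `b = 4.6` Å sit inside the canonical beta-sheet ranges
and reproduce the diameter series of the design family:

```{r radius}
sapply(c(10, 12, 14), function(n) 2 * barrel_radius(n, n + 2))
```

Two non-obvious constructions make the lattice physical:

* **Distributed shear.**  Residue $(j, k)$ of the lattice sits at
  circumferential coordinate $u = jb\cos\alpha - ka\sin\alpha$ and
  height $z = jb\sin\alpha + ka\cos\alpha$, which is exactly periodic:
  strand $n$ coincides with strand 0 shifted by $S$ registers.  Each
  strand covers registers starting at $k_{0,j} = -\mathrm{round}(jS/n)$,
  so all strands span the same membrane z-range and the shear is
  distributed in steps of 1–2 registers per strand pair, as in native
  barrels, rather than dumped at the closure seam.
* **Beta-pleat.**  Calpha atoms alternate by
  $\pm\sqrt{3.8^2 - a^2}/2 \approx 0.92$ Å along the local wall normal,
  which restores the canonical 3.8 Å consecutive Calpha distance and
  gives side chains their alternating lumen/lipid orientation.

The family rule `S = n + 2` is the default.  The printed shears of the
10- and 12-stranded designs (12 and 14) fix two points of the series;
the 14-stranded shear is not printed anywhere we know of, and `S = 16`
is this package's operational extrapolation — it also reproduces the
14-strand diameter.  Both choices are overridable per spec.  Likewise
the "constant transmembrane span" of the family is interpreted here as
a constant number of TM residues per strand (default 10, configurable),
not a constant height in Å; the two differ only through the weak
dependence of $\cos\alpha$ on `n`.

`compute_shear()` recovers `S` from coordinates alone: register
partners are identified by nearest-Calpha pairing on pleat-smoothed
coordinates (each position averaged with its strand neighbors, so the
pleat cannot flip a pairing decision to a diagonal neighbor), and the
rank offsets of mid-strand references are accumulated around the
barrel, taking the median over references per interface.  The
independent check in the test suite walks an explicitly built partner
graph with modal offsets instead.

## Glycine kinks and cross-section sculpting

Cylindrical beta-barrel walls are strained: the side chains packing the
lumen converge and repel.  Glycine kinks — glycines in the extended
positive-phi conformation — bend a strand locally and let the
cross-section flatten into faces, relieving the lumen packing.
`place_glycine_kinks()` realizes a target cross-section as *kink
columns* parallel to the barrel axis: corners of the square and
rectangle (interior angles ≥ 90°) use a single kink per strand
crossing; the tighter triangle corners and the high-curvature oval ends
use two stacked kinks.  Because each tilted strand covers only part of
the circumference, a corner column contains the 3–5 strands that
actually cross it.  Single kinks snap to outward-pleating
(even-register) residues, where the corner bend and the pleat
cooperate; at inward-pleating positions the rigid-geometry builder
cannot reach positive phi.

`sculpt_cross_section()` maps the cylindrical wall onto a rounded
polygon of the *same perimeter* by arc-length reparameterization: the
circumference is preserved exactly, faces between corners are flat
planes, and all bending concentrates in the rounded corners at the kink
columns.  Corner rounding radii (1.8 Å for 90° corners, 2.0 Å for the
triangle, `C/(4 + 2π)` for the stadium-shaped oval) spread the bend
over roughly one to two residues so that corner-crossing Calpha
distances stay within 3.8 ± 0.3 Å.

## Full-backbone completion and kink dihedrals

`build_full_backbone()` places N, C, O and Cbeta on the Calpha trace as
rigid planar trans-peptide units spanning consecutive Calphas, solved
once per Calpha–Calpha distance from ideal bond lengths and angles.
Planarity makes every omega exactly 180°.  The one free parameter per
unit is its orientation about the Calpha–Calpha axis: beta-strand
units alternate the carbonyl along the intra-wall hydrogen-bond
direction following the register parity, which lands interior strand
residues at phi ≈ −127/−134°, psi ≈ +112/+121°.  Around each kink run
the flanking unit orientations are refined by multi-start Nelder–Mead
against the kink targets (phi = +75°, psi = −150°, configurable) while
anchoring the bordering residues at their beta values; the refinement
is deterministic (fixed start set, no randomness).

Two kinds of *transition residues* are excluded from the beta-region
expectation, and the tests reflect this: the single residue preceding
a kink (a positive-phi kink cannot be inserted without perturbing one
flanking psi — real kinked strands show the same), and the two
turn-flanking termini of each strand, whose frames are taken from the
loops.  Cbeta atoms use ideal L-amino-acid tetrahedral geometry and are
virtual on glycine.

Hairpin closure (`close_hairpins()`) places 2- or 3-residue turns
analytically on a circular arc through the two strand termini, bulging
axially outward, with equal segments targeting 3.6 Å and never
exceeding the 4.1 Å connectivity bound; distant termini fall back to a
minor arc or linear interpolation.  Template-free analytic placement
was chosen over fragment insertion to keep the builder deterministic
and dependency-free.

## Strain proxy

`strain_proxy()` scores lumen packing with a soft truncated repulsion,
$(r_0/r)^{12} - 1$ below $r_0 = 5.5$ Å between lumen-facing Cbeta
atoms.  Glycine kinks (no side chain) and their immediate register
neighbors are excluded: the corner columns are small-residue territory
under the patterning rules, and their virtual Cbeta contacts otherwise
swamp the score with geometry that no real side chain would adopt.
Only the ordering between cross-section variants is meaningful — the
cylinder scores highest, every sculpted shape lower — and the proxy
makes no claim to force-field energetics.

## Sequence patterning

`assign_pattern()` emits per-position allowed amino-acid sets, not
sequences; `sample_sequence()` draws uniform fixtures from them.  The
rules: kinks are glycine; one Tyr-Gly-Asp/Glu folding motif is sited
per strand interface where the triad verifies geometrically (all Calpha
pairs < 8 Å — on sculpted flat faces the closest arrangement is 8.07 Å,
so mid-face interfaces are skipped with a warning while corner-adjacent
and cylinder interfaces all carry motifs); remaining lumen positions
alternate polar-network sets with 1–2-position frustration patches of
G/A/S placed greedily so that no strand retains a beta-optimal run
longer than 6 residues, plus a seeded hydrophobic-in-lumen fraction
(default ≤ 15 % — the quantitative fraction and patch lengths are not
published, so these are operational defaults); the lipid face is
hydrophobic, with Ser/Thr admitted within one register of a kink
(where the hydroxyl can hydrogen-bond the bent backbone) and charged
residues only within 3 Å of the membrane interface (the standard
aromatic-girdle band convention).  `frustration_audit()` checks the
resulting run structure per strand: an all-polar "optimal" lumen flags
every strand, the default assignment flags none.

## Pore profiling

`profile_pore()` measures the water-accessible channel as the largest
inscribed sphere per axial slice: at each z the full 3D distance to
every atom's Bondi van der Waals surface (C 1.70, N 1.55, O 1.52,
S 1.80 Å; hydrogens ignored) is maximized over the in-slice center.
Each slice runs a Nelder–Mead simplex seeded at the previous center
*and* at a coarse-grid optimum, keeping the better result, with a finer
grid pass when the center jumps more than 2 Å — pore slices of
noncylindrical shapes can be multi-modal, and the exhaustive 0.05 Å
grid oracle in the tests holds the optimizer to 0.05 Å.  Summaries
average over the transmembrane z-range only, since the quantities of
interest describe the membrane-spanning channel, and report the
per-slice standard deviation alongside the mean.  The probe is
unbounded (geometric inscribed radius, not a rolled solvent probe).
Generated poly-alanine backbones necessarily profile wider than
full-side-chain design models; profile numbers on generated models are
for ordering comparisons, not absolute diameters.

## Conductance model

A cylindrical channel of diameter $d$ and length $L$ in electrolyte of
conductivity $\sigma$, with a hemispherical access (convergence)
resistance at each mouth, conducts

$$G = \sigma \left[ \frac{4L}{\pi d^2} + \frac{1}{d} \right]^{-1}.$$

`diameter_from_conductance()` inverts this by bracketed root finding
(the forward map is strictly increasing; round trips are exact to
1e-9 relative).  Neither $\sigma$ nor $L$ is printed for the reported
diameter estimates, so the package's defaults are calibrated choices,
flagged in CLI output: $L = 3.5$ nm (DPhPC bilayer hydrophobic span
plus headgroup region) and $\sigma$ from `electrolyte_conductivity()`,
a Kohlrausch-type model $\Lambda = \Lambda_0 - K\sqrt{c}$ with
$\Lambda_0 = 126.45$ S cm²/mol and $K = 47.31$ calibrated to the
standard-table value 4.65 S/m at the 0.5 M / 25 °C recording buffer
(accuracy a few percent over 0.05–1 M; 2 %/°C linear temperature
scaling).  With these defaults the measured 108 / 220 / 427 pS
conductances invert to 3.3 / 4.8 / 6.9 Å — within the uncertainty the
"~" of the published ~3.5 / ~5 / 7 Å estimates carries, and sensitive
to the unpublished $\sigma$ and $L$ at the ±10 % level.

## Electrophysiology simulation and analysis

`simulate_trace()` produces the idealized staircase of sequential pore
insertions — level $k G V$ after the $k$-th insertion — plus white
Gaussian noise, deterministic per seed.  The generator emulates the
step structure, amplitudes and noise floor of planar-bilayer
recordings; it deliberately omits baseline drift, 1/f and capacitive
transients, gating/blockade kinetics and hardware filtering, so
passing tests demonstrate correct recovery on clean staircases, not
robustness to every hardware artifact.

`detect_jumps()` is a two-sided sliding-window mean-difference
change-point detector with a robust threshold
$\max(\texttt{min\_step},\, k\,\hat\sigma)$, $\hat\sigma$ from the MAD
of first differences and $k = 5$; events closer than the window merge.
CUSUM-type detectors would serve equally for staircase signals; the
window detector was chosen for transparency and determinism.  With the
default 20 ms window the mean-difference noise is
$\hat\sigma\sqrt{2/w} \approx 0.14\,\hat\sigma$, so the $5\hat\sigma$
threshold makes false positives on pure noise essentially impossible
(< 0.1/s is enforced by test) while steps 1.5× the threshold are found
reliably.

`fit_single_channel()` histograms insertion amplitudes up to 50 pA and
fits one Gaussian to the smallest-amplitude cluster, isolated by an
iterated ±40 % window around the running cluster center so that
double-insertion jumps at integral multiples are excluded;
`conductance_from_fit()` converts the fitted mean to pS with a standard
error.  `iv_analysis()` reports mean steady currents per voltage and
per-branch monotonicity of |I| against |V|, with rectification as the
ratio of branch conductances.

## Problem sizes and determinism

The test suite builds barrels of 8–16 strands with 10-residue strands
(100–160 TM residues), profiles pores on ≤ 200-atom synthetic cavities
against a 0.05 Å exhaustive grid, and runs the
simulate–detect–fit pipeline over 20 seeds of 6 s recordings at 5 kHz
with noise at 15 % of the step amplitude — sizes chosen to exercise
every code path at interactive speeds.  Every stochastic step in the
package takes an explicit seed and restores the caller's RNG state;
the backbone builder and all analyses are fully deterministic.

## Known limitations

* Backbones are idealized: no side chains beyond Cbeta, no membrane,
  no energetics beyond the strain ordering proxy.  Sequence patterning
  emits constraint sets, not optimized sequences.
* The conductance model is macroscopic; it ignores ion selectivity,
  electroosmosis and voltage-dependent effects, and its absolute
  diameters inherit the uncertainty of $\sigma$ and $L$.
* The pore profiler tracks a straight principal axis; strongly bent
  channels would need a curved-axis search.
* Loop conformations are single analytic turns, not ensembles.
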