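# tmbarrel

Computational design and analysis of transmembrane β-barrel (TMB)
nanopores, for protein designers and single-channel
electrophysiologists.  The package builds idealized TMB backbones from
blueprint parameters, patterns their sequences by rule, profiles the
resulting channels, links pore geometry to single-channel conductance,
and simulates and analyzes insertion recordings.

## The models at the core

**Barrel geometry.** A closed barrel of *n* antiparallel β-strands with
shear number *S* (the register offset accumulated over one circuit of
strand-to-strand H-bonding), built from a β-sheet with rise *a* per
residue and interstrand spacing *b*, lies on a cylinder of radius

    R = sqrt((S·a)² + (n·b)²) / 2π

with strand tilt α = atan2(S·a, n·b).  With canonical spacings
(a = 3.32 Å, b = 4.6 Å) and the family rule S = n + 2, the 10-, 12- and
14-stranded barrels have mean diameters of 19.4, 23.0 and 26.6 Å.
Cross-sections are sculpted into squares, rectangles, triangles or
ovals by *glycine kinks* — glycines in the extended positive-φ
conformation placed in columns along the barrel axis at the corners
(one kink per strand crossing at ≥ 90° corners, stacked kinks at
tighter ones) — and the strands are connected by 2–3-residue
β-hairpins.

**Pore → conductance.** A channel of diameter *d* and length *L* in
electrolyte of conductivity σ, with hemispherical access resistance at
both mouths, conducts

    G = σ · [ 4L/(π d²) + 1/d ]⁻¹

which the package inverts by root finding to estimate pore diameters
from measured single-channel conductances.

**Recordings.** Insertion staircases are simulated as level jumps of
G·V plus Gaussian noise; detection uses a robust sliding-window
change-point statistic, and single-channel conductance is estimated by
a Gaussian fit to the smallest-amplitude jump cluster.

## Worked example

```r
library(tmbarrel)

spec <- barrel_spec(12, cross_section = "square")
spec
#> TMB blueprint: 12 strands, shear 14, square cross-section
#>   spacings a = 3.32 A (rise), b = 4.60 A (interstrand)
#>   strand length 10 TM residues; mean barrel diameter 23.0 A

model <- design_backbone(spec)   # lattice -> kinks -> sculpt -> loops -> atoms
model
#> TMB backbone (full): 142 residues, 12 strands, square cross-section
#>   22 loop residues, 16 glycine kinks, TM z-range -12.7..12.7 A

compute_shear(model)             # register traversal around the barrel
#> [1] 14

summary(profile_pore(model))     # inscribed-sphere channel profile
#> Pore profile: average diameter 11.41 +/- 0.34 A, min 11.06 A (26 slices)

p <- conductance_params()        # 0.5 M NaCl, 25 C, L = 3.5 nm
diameter_from_conductance(108e-12, p) * 1e10   # measured 108 pS -> pore size
#> [1] 3.34

tr <- simulate_trace(108, 100, c(1, 2.2, 3.1), noise_sd = 1,
                     duration = 5, seed = 42)
detect_jumps(tr)
#>   time  delta_I    pre_mean post_mean      sign
#> 1  1.0 10.61677  0.09564893  10.71242 insertion
#> 2  2.2 10.88128 10.80859294  21.68987 insertion
#> 3  3.1 10.88549 21.64972685  32.53522 insertion
```

The blueprint diameter (23.0 Å) is the backbone wall; the profiled pore
(~11 Å here) is the water-accessible lumen of the poly-alanine model,
which narrows further once full side chains are designed in.  The
3.34 Å estimate is what the access-resistance model assigns to a
108 pS channel in the recording buffer.

A command-line interface wraps the same functions
(`inst/cli/tmbarrel design-backbone --strands 12 --shape square
--out model.pdb`); see `tmbarrel --help` for the subcommands.

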