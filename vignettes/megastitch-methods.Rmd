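---
title: "Methods: fragment assembly and tunnel profiling of megaprotein models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: fragment assembly and tunnel profiling of megaprotein models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(megastitch)
```

## The problem

Machine-learning structure predictors are capped at roughly 2500 residues
per run. A single-chain megaprotein — the motivating case is a
4018-residue, 452 kDa bridge-like lipid transfer protein (BLTP) spanning
the gap between the endoplasmic reticulum and the plasma membrane — must
therefore be predicted as overlapping fragments and rejoined into one
model before any whole-molecule geometry (rod length, internal tunnel) can
be measured. megastitch is the reproducible version of that workflow, plus
the downstream measurements that characterize a BLTP rod: a continuous
hydrophobic tunnel wide enough for lipid monomers, a tunnel-blocking
missense substitution, an N-terminal transmembrane anchor and a C-terminal
amphipathic/polybasic membrane-binding patch.

## Fragment planning

For sequence length $L$, fragment length $t$ and minimum overlap $v$, the
number of fragments is the smallest $n$ with $n t - (n-1) v \ge L$, i.e.
$n = \lceil (L-v)/(t-v) \rceil$, and starts are evenly spaced,
$\mathrm{start}_i = 1 + \mathrm{round}\!\big((i-1)(L-t)/(n-1)\big)$ with
round-half-up (banker's rounding would make boundaries depend on parity).
All intervals are 1-based inclusive, matching the field's "a.a. 1–72" /
"G200E" conventions. Because $n$ is minimal, realized overlaps typically
exceed $v$; $v$ is a floor, not a target. With the defaults
($t = 1500$, $v = 500$, predictor cap 2500) a 4018-residue chain yields 4
fragments with overlaps of 660–661 residues. The published description of
this scheme gives counts ("four fragments", "~1500 residues", "~500
overlapping"), not exact boundaries; the even-spacing rule is our
deterministic instantiation, and `validate_plan()` audits any externally
chosen set of windows.

## Superposition and splicing

Fragments are aligned the way an interactive align-on-overlap workflow
does it, but deterministically: paired Cα atoms of the shared overlap
residues are fitted by the closed-form least-squares rotation (Kabsch,
SVD form) with the determinant correction that excludes reflections.
Cα-only fitting is deliberate — independently predicted fragments agree on
backbone but not side-chain conformations. Sequence identity on the
shared residues is *checked*, not assumed; a mismatch (numbering drift)
is an error naming the first offending residue.

Fragment 1 anchors the global frame and transforms propagate left to
right; any other anchor differs only by a global rigid motion, which is
why benchmark RMSDs are computed after optimal superposition onto truth
(`rmsd_to_reference()`). Each overlap is spliced at a single crossover
residue $c$: residues $\le c$ from the left source, $> c$ from the right.
The default takes the overlap midpoint $c = \lfloor (s+e)/2 \rfloor$; the
`max_confidence` rule instead maximizes
$\min(\bar{p}_L(\le c), \bar{p}_R(> c))$ over candidate crossovers (first
argmax on ties), exploiting the pLDDT decay toward artificial fragment
termini — the same decay that motivates overlapping windows at all. A
`trim_overlap` option drops residues at overlap ends before fitting;
the default (0, full overlap) uses all shared information. An interactive
merge resolved duplicated overlap residues by hand; the crossover rule is
our declared, reproducible convention, not a reconstruction of any manual
choice. Junction quality is reported as overlap Cα-RMSD (warning above
5 Å, assembly continues) and a *junction clash count*: atom pairs closer
than 2 Å, at least 3 residues apart in sequence, whose members come from
two different source fragments. Clash search uses a uniform grid with
cell size equal to the cutoff, so it stays near-linear in atom count.

## Axis and radius profile

The central axis is the smoothed polyline of sliding-window Cα centroids
(default window 50 residues, moving-average width 5, resampled every 2 Å
of arclength). Sequence-order centroids follow a curved rod, which a
straight PCA axis cannot; windows covering whole helical turns cancel the
winding. Rod length is deliberately the *straight* extent — max minus min
Cα projection on the first principal axis — an end-to-end measure; the
curved centerline length is reported alongside (axis arclength), since a
"~30 nm rod" could be read either way. A degenerate centerline (atoms not
in spatial sequence order) is detected by the mean cosine of consecutive
turning angles of the raw centroid polyline (< 0.5 flags) or by arclength
collapse below half the principal extent.

The radius profile is HOLE-style with fixed centers: at each axis station
the radius of the largest ball touching no atom's van der Waals surface,
$r(s) = \min_a (\lVert x_s - x_a \rVert - \mathrm{vdW}_a)$. Keeping
centers on the axis (no Monte-Carlo ball wiggling) makes the profile
deterministic and a conservative lower bound on the true pore radius —
adequate for a wide lipid conduit, not a branched-channel finder.
Negative radii (axis inside an atom) clamp to 0 with a warning. vdW radii
come from a bundled element table (C 1.70, N 1.55, O 1.52, S 1.80 Å,
default 1.70); the source models never state radii, so the table is part
of the package's contract. Lining residues at a station own an atom
within radius + shell (default shell 3 Å) of the station point; their
mean Kyte–Doolittle hydropathy summarizes the wall chemistry.

"Hydrophobic tunnel" has no quantitative definition in the motivating
literature, so the package declares one: *continuous* — radius at least
the probe (default 1.4 Å, a water) at every interior station, the first
and last 5% of arclength excluded because mouth stations have no
enclosing wall — *and* mean lining hydropathy above 0. Probe, shell and
mouth fraction are all configurable.

## Mutation blockage

A substitution at residue $k$ is modelled as a single sphere at
$\mathrm{C}\alpha + 2.4\,\hat{u}$ Å, where $\hat{u}$ is the Cα→Cβ unit
vector (for glycine, an ideal tetrahedral Cβ direction constructed from
backbone N, Cα, C), with the volume-equivalent radius of the target side
chain from a bundled table (Gly 1.0, Glu 3.1 Å, ...). Radii are
recomputed at stations within 15 Å arclength of the residue, with *both*
the original and the substituted residue modelled as spheres, so the
identity substitution is exactly a no-op and the reported
$\Delta r = r_\mathrm{after} - r_\mathrm{before} \le 0$ isolates the
side-chain size change. One sphere per side chain is coarse by intent:
the question answered is "does the larger side chain protrude into the
lumen here", not a rotamer-resolved remodelling.

## Sequence features

Hydropathy profiles are Kyte–Doolittle window means (default window 19,
ends undefined rather than padded; `X` contributes 0 and is flagged).
Transmembrane-like segments are maximal runs of window means ≥ 1.6 of
length ≥ 15 — the classical criterion; the motivating description
("putatively hydrophobic transmembrane helix") gives none, so this is the
package's operationalization, and in the LPD-3 preset the scan is
confined to the reporter-defined N-terminal region (a.a. 1–72). The
Eisenberg hydrophobic moment of a window is
$\lvert \sum_i h_i(\cos i\delta, \sin i\delta) \rvert / n$ at
$\delta = 100^\circ$ per residue; the preset reports the top-moment
window within the C-terminal reporter region (a.a. 3945–4018). The
polybasic motif is interpreted as exactly four residues, K-x-K-K with x
any amino acid, overlapping matches all reported. Molecular weight is the
sum of IUPAC average residue masses plus one water (18.0153 Da).

## The synthetic benchmark

`make_tube()` builds a residue chain wound helically about a straight
axis: Cα at `inner_wall_radius + 2.4` Å from the axis, backbone N and C
offset ±1.2 Å along the local tangent, and one pseudo-side-chain CB
sphere 2.4 Å from Cα pointing at the axis (odd residues, identities from
a hydrophobic alphabet, default I/L/V) or away from it (even residues,
default D/E/K/R). The innermost atoms are thus the lumen-facing CB
carbons at `inner_wall_radius`, so the true open lumen radius is
`inner_wall_radius − 1.70`. The default winding is the smallest turn
count giving consecutive Cα spacing ≥ 3.9 Å (spacing below 3.8 Å is
rejected as infeasible), confidence is 90 everywhere, and one seed fixes
the residue identities. The defaults (900 residues, 300 Å, wall 7.7 Å →
lumen 6.0 Å) are sized like the motivating rod: ~30 nm long with a lumen
comfortably passing a lipid headgroup.

`fragment_and_perturb()` inverts the stitcher's job: each plan window is
cut out, given an independent uniformly random proper rotation
(quaternion sampling) and a translation uniform in ±100 Å per axis, plus
iid Gaussian coordinate noise σ, with pLDDT-style confidence decaying
linearly 90 → 50 over the terminal 50 residues of each fragment (the
decay shape is our invention; only its direction — worse at artificial
termini — mirrors real predictors). All randomness streams from one
seed, so every regression value in the test suite is pinned.

What the generator does *not* emulate: real β-sheet geometry, sequence-
dependent folding, correlated (domain-level) prediction errors, register
shifts between fragments, or missing residues. Passing the benchmark
therefore shows the pipeline's algebra and geometry are right — exact
inversion of rigid scrambling, noise propagation at the closed-form rate
($\mathrm{RMSD} = \sigma\sqrt{6}$ between two independently noised
copies), unbiased lumen recovery — not that any particular predictor's
fragment errors are benign.

## Numerical conventions and test design

- Exact-recovery checks run on in-memory models: PDB text rounds
  coordinates to 3 decimals, so a file round-trip caps agreement at
  ~5×10⁻⁴ Å and machine-precision claims are about the algorithm, not the
  serialization. Round-trips through PDB/mmCIF are themselves tested at
  format precision, and a second write is byte-identical.
- Superposition is validated two ways: against an independent quaternion
  characteristic-matrix oracle (shares no code with the SVD path) over
  1000 random instances at 10⁻⁸ Å, and against `bio3d`'s fitted RMSD at
  that function's 3-decimal print precision.
- Benchmark suite sizes (900-residue tubes, 10–30 seeds per Monte-Carlo
  band, 1000 oracle instances) were chosen so the whole default test run
  completes in a few minutes while keeping every stochastic band several
  standard errors wide.
- Confidence values are clamped to [0, 100] on read with a warning;
  altloc keeps the highest-occupancy conformer; insertion codes are
  rejected; multi-model files use the first model with a warning. PDB
  chain ids longer than one character are an error (use mmCIF), never a
  silent truncation.
- The LPD-3 preset (`paper_lpd3 = TRUE`) fixes planner parameters,
  terminal regions and the G200E scan but bundles no sequence or model;
  supplied inputs are checked against the expected residue numbering by
  the `from_aa` guard of `mutation_blockage()`.

## Known limitations

Hard crossover splicing (no loop remodeling or minimization); fixed-center
radius profile (underestimates radius where the true pore axis wanders off
the centroid line); single-sphere side chains; no membrane embedding,
electrostatics or dynamics; TM/amphipathic calls are scale-based
annotations, not topology predictions.
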