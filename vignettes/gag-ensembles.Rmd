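---
title: "Building conformational ensembles of glycosaminoglycan polymers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Building conformational ensembles of glycosaminoglycan polymers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gagchain)
```

## The problem and the model

Glycosaminoglycans (GAGs) are linear polysaccharides of repeating
disaccharide units — here the nonsulfated forms of hyaluronan
`[-4GlcAβ1-3GlcNAcβ1-]`, dermatan `[-4IdoAα1-3GalNAcβ1-]`, keratan
`[-3Galβ1-4GlcNAcβ1-]`, and heparan `[-4IdoAα1-4GlcNAcα1-]`. Their
biological chains reach ~200 monosaccharides, far beyond what atomistic
explicit-solvent simulation can sample routinely. `gagchain` builds
heavy-atom, atomic-resolution conformational ensembles of arbitrary-length
GAG chains from a *conformer database*: pools of monosaccharide-ring
conformations and glycosidic-linkage conformations, each recorded as
internal coordinates.

The construction algorithm rests on one statistical hypothesis: in a long
GAG chain, individual ring puckers and individual linkage conformations
behave *randomly and independently*. Under that hypothesis a valid chain
conformation can be assembled by drawing each ring and each linkage
independently and uniformly from its pool, realizing the draws in
Cartesian space, and then (because independent draws occasionally produce
sterically impossible arrangements) screening the result:

1. sample one ring conformer per residue and one linkage conformer per
   junction, independently and uniformly;
2. realize the chain atom-by-atom from internal coordinates
   (natural-extension placement);
3. relax it by energy minimization with every constructed torsion (and
   angle) held by a harmonic restraint, so the *conformation* is
   maintained while clashes are relieved through small adjustments and,
   when the geometry is truly impossible, through bond stretching;
4. exclude any member whose post-minimization **bond potential energy**
   exceeds a cutoff: the post-minimization bond energy of the
   fully-extended reference conformation plus a 100 kcal/mol buffer.

The screening signal works because the restrained torsions prevent a
nonphysical geometry — two bonds lying on top of one another, or a bond
threaded through the center of another residue's ring — from simply
rotating itself apart; the minimizer can only separate the clashing atoms
by stretching bonds, which raises the bond energy by hundreds of
kcal/mol, far above the ~100 kcal/mol headroom of the cutoff. Defect-free
chains end near zero bond energy.

## Geometry: internal coordinates, templates, stereochemistry

Chains are realized with heavy atoms only: every quantity the pipeline
needs — the glycosidic dihedrals φ = O5–C1–O–Cn and ψ = C1–O–Cn–C(n−1),
ring internals, Cremer–Pople puckers, bond energies, end-to-end distance
and radius of gyration — is defined on heavy atoms. All angles are in
degrees and torsions in (−180°, 180°] under the IUPAC sign convention.

Each residue type (GlcA, IdoA, β/α-GlcNAc, β-GalNAc, Gal) has an
idealized template: a six-membered ring built by the inverse Cremer–Pople
transform (mean ring bond 1.49 Å, total pucker amplitude Q = 0.57 Å) with
exocyclic heavy atoms placed in tetrahedral slots. Stereochemistry is
encoded as a conformation-independent *chirality sign* — the sign of
det[u(prev), u(next), u(substituent)] at each ring carbon — derived once
from the equatorial/axial assignment in the 4C1 reference chair
(all-equatorial for β-gluco; O4 axial for galacto; anomeric O axial for
α; carboxylate axial for the C5 epimer IdoA, whose reference chair is
1C4). The signs were checked against an independently generated 3-D
structure of β-D-glucopyranose.

A ring is rebuilt from a conformer record by a fixed spanning-tree plan
(O5, C1, C2 seeded; C3–C5 by torsions; exocyclic atoms as leaves), so the
ring-closure bond is a derived consistency check, not an input. The six
named linkage parameters (two bonds, two angles, φ, ψ) under-determine
the junction in Cartesian space; each linkage conformer therefore also
records two auxiliary coordinates measured at extraction time: the
torsion C5–O5–C1–O that places the glycosidic oxygen about the donor C1,
and the valence angle O–Cn–C(n−1) that opens the acceptor ring off the
linkage oxygen. The third orientational degree of freedom — the torsion
O–Cn–C(n−1)–C(n−2) — is the acceptor ring's own substituent direction at
Cn and comes from the ring conformer. When ring and linkage conformers
are drawn independently their overlapping acceptor-oxygen parameters can
disagree slightly; by convention the linkage conformer's bond and angle
govern, and re-extraction from a built chain returns the governing
values.

Chains run from the nonreducing end (residue 1) to the reducing end; the
glycosidic oxygen carries the acceptor's O3/O4 name, and only the
reducing-end residue keeps a free anomeric O1.

**End-to-end distance** is measured between the two chain-terminal
oxygens: the reducing-end anomeric O1 and the nonreducing-end free
hydroxyl oxygen at the linkage position (O4, or O3 for keratan). These
are the atoms through which the chain would extend, so the distance spans
the whole molecule; with idealized template geometry this convention
reproduces the four published homogeneous-dihedral 20-mer end-to-end
distances (99.0 / 89.7 / 85.8 / 87.5 Å) within ±2.2%, whereas terminal
backbone carbons leave keratan 5% short. The convention is isolated in
`end_to_end()`.

## Ring puckering

`cremer_pople()` computes (Q, θ, φ) with atoms ordered O5, C1, …, C5;
with this ordering the standard D-pyranose chair sits at θ ≈ 0° (4C1) and
the inverted chair at θ ≈ 180° (1C4) — verified against an independent
reference structure, not assumed. `classify_pucker()` assigns chairs for
θ ≤ 45° / θ ≥ 135° and otherwise the nearest canonical equator vertex:
boats at even multiples of 30° in φ, skew-boats at odd multiples, ties
toward the lower vertex. The vertex↔label wheel (3,OB at φ = 0° through
OS2 at 330°) is calibrated executably in the test suite by constructing
idealized boat and skew displacement patterns from the label definitions.
The published analyses only ever name chairs, boats and skew-boats, so
envelope/half-chair zones are absorbed by the nearest canonical form; the
chair boundary at 45° is a documented choice (any value between the
chair cluster and the θ ≈ 90° equator band gives the same labels for
real data).

## The synthetic database

Real databases come from `extract_conformers()` on a multi-model PDB
ensemble (e.g. converted MD snapshots). For development, testing and
method studies without trajectories, `generate_db()` synthesizes a
database with the statistical structure reported for microsecond MD of
GAG 20-mers:

* **Linkage (φ, ψ)**: a mixture of wrapped-Gaussian basins. Default
  centers and relative free energies are the published per-linkage
  minima (e.g. hyaluronan GlcAβ1-3GlcNAc: basin I at (−71.25°, −123.75°)
  with ΔG = 0; basin II at (−53.75°, 91.25°) with ΔG = 3.06 kcal/mol).
  Basin weights are Boltzmann factors exp(−ΔG/RT) at T = 310 K. The
  angular spread is not printed anywhere; the published contour maps
  reach ~3 kcal/mol at 30–40° from each minimum, and a quadratic well
  crossing 3 kcal/mol at ~35° at 310 K corresponds to a Gaussian spread
  of ≈ 11°, the default (`sigma` column, tunable per basin).
* **Ring puckers**: a mixture over canonical labels. Heparan IdoA uses
  the reported ~54% 1C4 / ~25% 2SO / ~4% 4C1 with the remainder spread
  over the named boat/skew forms; dermatan IdoA proportions are not
  printed and default to 0.55/0.30/0.09 with 0.06 over the equator
  forms (a documented assumption); N-acetyl sugars and Gal default to
  ≥ 99.5% 4C1 with the named rare forms sharing the remainder (Gal and
  α-GlcNAc: 100% 4C1, as only chairs were observed in the 20-mers).
  Rings are realized through the inverse Cremer–Pople transform at the
  label's vertex with Gaussian jitter (σ_Q = 0.02 Å, σ_θ = 6°,
  σ_φ = 8°) and leaf-atom geometric jitter (bonds 0.02 Å, angles 2°,
  exocyclic torsions 3°), so every generated ring is exactly closed.

What the generator emulates: the per-linkage free-energy topography
(positions and depths of basins), the pucker composition, and small
thermal geometric noise, under exact independence of all draws. What it
does not emulate: MD time correlation (snapshots are i.i.d. by
construction, which *is* the algorithm's working hypothesis),
non-Gaussian basin shapes, correlated bond/angle fluctuations, and any
residual inter-residue coupling real chains may have. Tests passing on
synthetic databases therefore validate the construction machinery —
sampling, realization, restraint fidelity, screening — not the physics
of any particular force field.

## Energy model and minimization

The restrained potential is deliberately minimal: harmonic bonds
k_b (b − b0)² with k_b = 300 kcal/mol/Å² over all topology bonds
(equilibria from the templates; this term is the screened quantity);
harmonic restraints holding every placement-plan angle
(k_θ = 60 kcal/mol/rad²) and torsion (k_φ = 500 kcal/mol/rad²) at its
constructed value; and a soft-core repulsion
ε((r_min/r)⁶ − 1)² for r < r_min between atoms more than three bonds
apart (ε = 1 kcal/mol, r_min = 2.8 Å) — steep enough that atoms cannot
pass through one another during a line search, which is what traps a
threaded bond. Minimization is L-BFGS-B with analytic gradients
(compiled, with a Verlet-listed neighbor search); defaults stop at a
projected gradient of 0.02 kcal/mol/Å or a relative energy change of
~2×10⁻⁶, which locates the bond energy to ≪ 1 kcal/mol — ample against
a 100 kcal/mol buffer. A result is `converged` when the optimizer
terminated normally *and* every torsion stayed within 5° of its
constructed value.

The exclusion cutoff is recomputed per database and length:
`build_extended_reference()` picks one homogeneous (φ, ψ) per linkage
type from the low-free-energy bins (≤ 1 kcal/mol) of the database's own
map, maximizing the end-to-end distance over the candidate grid, with
rings at each pool's dominant pucker; the cutoff is that conformation's
post-minimization bond energy plus 100 kcal/mol. Ensemble generation
replaces excluded members until the requested size is reached, with one
counter-derived RNG substream per build attempt so the retained set is
reproducible and independent of iteration details.

## Analysis layer

`free_energy_map()` bins (φ, ψ) into 2.5° × 2.5° cells with edges at
multiples of 2.5° (so published minima like −71.25° are bin centers) and
Boltzmann-inverts the counts, ΔG = −RT ln(n) − k with k fixing the
global minimum at exactly 0 kcal/mol. `histogram_mode()` anchors bins at
zero and reports the center of the maximal-count bin, ties toward the
lower center (0.5 Å bins for 20-mers, 0.25 Å for 10-mers, 5 Å for
200-mers). `percent_difference()` uses the mean-denominator form
|a−b|/((a+b)/2)·100 — the only form that reproduces all four published
ensemble comparisons (2.53, 2.42, 3.39, 4.98%). The radius of gyration
is mass-weighted by default (`weighted = FALSE` for the unweighted
form).

One statistical caveat shapes the validation tests: the *position* of
the minimum bin of a binned free-energy map is intrinsically jittery.
With an ~11° basin and 2.5° bins, even maps built from hundreds of
thousands of samples localize their minimum only to ±1–2 bins — the
published tables themselves show equivalent ensembles' minima differing
by up to two bins. The package's consistency checks therefore assert
that an ensemble map's minimum falls within two bins of the generating
center, and that the ensemble map evaluated at the *input pool's* own
minimum bin stays within the counting resolution of zero
(≤ 0.25 kcal/mol) — the ensemble-vs-input-data comparison that validates
the construction machinery — rather than demanding exact argmax
coincidence.

## Worked example

```{r example, eval = FALSE}
db <- generate_db("hyaluronan", n_per_pool = 2000, seed = 42)
sp <- polymer_spec("hyaluronan", 20)
cut <- compute_cutoff(sp, db)
ens <- generate_ensemble(sp, db, N = 2000, seed = 7, cutoff = cut)
histogram_mode(ens$members$e2e, 0.5)$most_probable  # ~74 A
```

## Problem sizes and limitations

The shipped tests run at desk scale: databases of 400–2000 conformers
per pool, screened ensembles of 1500-2000 members for 10-/20-mers and 1000
members for 200-mers, and construction-only ensembles of a few thousand
members for length-trend checks — sizes chosen so the full suite
exercises every pipeline stage, including a complete 200-mer generation,
in minutes. Published MD-derived databases are ~200 000 samples per
pool; nothing in the code limits pool or ensemble sizes beyond memory.

Known limitations: nonsulfated homopolymeric repeats only (no sulfation
patterns, branching, or protein attachment); heavy atoms only, so
hydrogen-bond analyses and H-relative NMR conventions are out of reach;
the energy model is a screening device, not a force field — retained
ensembles carry no Boltzmann weights beyond those of the input pools;
and the independence hypothesis is an input assumption, inherited from
the evidence in the source simulations, not something a synthetic
database can test.
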