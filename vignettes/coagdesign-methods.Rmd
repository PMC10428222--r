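---
title: "Methods: interaction metrics, MM-GB/SA scoring and coagonist design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: interaction metrics, MM-GB/SA scoring and coagonist design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coagdesign)
```

This vignette is the package's own account of its models and numerical
choices: what is computed, under which assumptions, which knobs matter, and
what the synthetic validation data can and cannot demonstrate.

## The scientific setting

Dual agonists of the glucagon receptor (GCGR) and the GLP-1 receptor
(GLP-1R) are single peptides, built on the 29-residue glucagon scaffold,
that activate both class-B1 GPCRs. Binding is dominated by an amphipathic
helix inserted into the transmembrane pocket with its C-terminal half
engaging the extracellular domain (ECD) and loops (ECL1–3). The design
question is positional: which residues of the scaffold carry the binding
free energy for each receptor, and which substitutions shift the balance
without destroying either interaction. The package answers this with
trajectory-derived interaction statistics, an end-point per-residue
energy decomposition, and a rule-based sequence constructor.

## Trajectory metrics

**Native contacts.** A native contact is a residue pair, nonconsecutive in
sequence (|i−j| > 1; inter-chain pairs always eligible), with any pair of
heavy atoms within 5 Å in the reference structure. Q(x) is the fraction of
these pairs still satisfied per frame, as a hard count. A soft switching
function and a larger sequence separation (|i−j| > 3) are common in the
folding literature; the hard 5 Å count with |i−j| > 1 is used here (both
the cutoff and the separation are arguments) because the quantity serves as
a binding-stability monitor, not a folding coordinate.

**RMSD/RMSF.** Both superpose with the closed-form Kabsch rotation
(SVD with determinant correction). RMSF uses a two-pass mean: frames are
fitted to the first frame, the mean structure is formed, frames are
refitted to that mean, and per-atom fluctuations are averaged within
residues. Superposition removes six rigid-body degrees of freedom, so a
planted isotropic per-coordinate noise σ is recovered as RMSF ≈ σ√3 only
up to a small deficit (about 2% on an eight-residue helix); `fit = FALSE`
applies the direct formula for pre-aligned trajectories.

**Hydrogen bonds and salt bridges.** The literature reports populations,
not geometries, so the geometric criterion is a package choice: donor–
acceptor heavy-atom distance ≤ 3.5 Å and D–H···A angle ≥ 120°, both
configurable; occupancies above 0.80 are flagged "strong". Salt bridges
use the minimum over side-chain N–O atom pairs (Asp/Glu carboxylate
oxygens against Lys NZ, Arg NH1/NH2, His NE2), emitted when the mean
minimum distance over frames is below 4 Å, with occupancy the fraction of
frames below 4 Å. The strong/moderate/weak tier boundaries (0.80 / 0.50)
are package-defined: the vocabulary is standard but no numeric boundary is
established usage. Frames are weighted equally; no block averaging.

## MM-GB/SA binding free energy

The estimate is the standard single-trajectory end point: on each (strided)
frame, every component is evaluated as complex − receptor − ligand *on the
same coordinates*, so the molecular-mechanics terms reduce to interface
pair sums. Components:

* **Electrostatics.** Coulomb sum f·q_iq_j/(ε_in·r), f = 1389.35458
  kJ·mol⁻¹·Å·e⁻², no cutoff; the protein dielectric defaults to ε_in = 2.
* **van der Waals.** 4ε[(σ/r)¹² − (σ/r)⁶] with Lorentz–Berthelot
  combination and one LJ type per element.
* **Polar solvation.** Still-type generalized Born,
  −½(1/ε_in − 1/ε_out)Σ f·q_iq_j/f_GB with
  f_GB = √(r² + B_iB_j·e^(−r²/4B_iB_j)), self terms included. Born radii
  come from Hawkins–Cramer–Truhlar pairwise descreening over intrinsic
  radii (element van der Waals radius − 0.09 Å, neighbour scale 0.8). A
  generalized-Born surrogate is used instead of a grid Poisson–Boltzmann
  solver deliberately: it is closed-form, desk-scale, and preserves the
  four-component decomposition; absolute kJ/mol values are therefore *not*
  comparable to PB-based tables, while signs, rankings and difference maps
  are the intended outputs.
* **Nonpolar solvation.** γ·SASA + c with γ = 0.0227 kJ/mol/Å², c = 0 by
  default; SASA by Shrake–Rupley with 960 deterministic golden-spiral
  points per atom and a 1.4 Å probe. Exact coincident-sphere ties are
  broken by atom order so a duplicated sphere contributes its area once.

Per-residue attribution splits each interface pair term half/half between
the partner residues (alternative attributions would change individual
numbers, not sums); solvation differences are attributed per atom and
summed per residue. Conservation — per-residue columns summing to the
totals within 1e-6 relative — is enforced by construction and tested. No
conformational entropy term is included, and the frame stride is a
configuration knob because no canonical averaging protocol exists for the
end-point estimate.

The parameter set behind these kernels is a bundled minimal table: backbone
partial charges summing to zero per residue plus unit formal charges on the
charged side-chain terminal atoms (Asp/Glu −1, Lys/Arg +1, His neutral).
The package scores and compares interfaces; it does not simulate, so full
force-field fidelity is out of scope by design.

## Design engine

`build_design()` applies, in documented order: the mutation set, the
back-mutations, then the C-terminal graft; each step records provenance and
a wild-type mismatch aborts with the position named, which guards against
numbering drift between constructs. The ΔΔG sign convention is mutant −
reference, negative improves. The classifier's neutral band defaults to
±5 kJ/mol — distinct from the −50 kJ/mol per-residue significance filter,
which selects residues whose *contribution* is large, not mutations whose
*effect* is large. The coupled-affinity score is the sum of the two
receptor ΔG values with |ΔG_GCGR − ΔG_GLP-1R| as an imbalance diagnostic;
a sum is the simplest score that is monotone in both affinities, and the
imbalance column keeps "balanced" distinguishable from "lopsided" at equal
sums. Ranking sorts by composite, then imbalance, then id — fully
deterministic.

Two open choices were settled as follows. The shipped MDD_GR rule file
carries S16W (the GLP-1R-oriented base design is the documented parent;
S16M is one edit away in the YAML). The GLP-1 donor is encoded as
GLP-1(7-37), whose positions 30–31 are Arg,Gly — the residues named for
the C-terminal graft; a longer graft boundary is expressible in the rule
file. Template and donor sequences ship as editable FASTA data, not
hard-coded constants.

## Free-energy surfaces

F = −kT·ln(P/P_max) over a 2D histogram (default 50×50 over the observed
range; the pipeline demo uses 24×24), kT = 0.0083144621·T kJ/mol. The
global minimum is 0 by normalisation, empty bins are masked rather than
zero-filled, and no kernel smoothing is applied. A constant series is a
degenerate range and errors unless explicit edges are supplied. RMSF is a
time average, so as an order parameter each frame is assigned the RMSF of
a centred window (width configurable, default 21 frames) — one defensible
construction among several, chosen for locality and simplicity.

## The synthetic-complex generator

The generator emulates the statistical structure of peptide–GPCR
trajectories, not their physics: an ideal α-helix (φ = −57°, ψ = −47°,
NeRF-built backbone, 1.5 Å rise, 3.6 residues/turn) carrying explicit
terminal atoms on charged side chains, inside a ring pocket of labelled
residues. Planted interactions switch per frame by independent Bernoulli
draws at the target occupancy — contact geometry 2.9 Å collinear for
hydrogen bonds, the planted minimum N–O distance for salt bridges, 8 Å
otherwise — and per-residue isotropic Gaussian noise gives a closed-form
RMSF target. Basic nitrogens are placed along the acid side chain's
outward direction so planted contacts never sweep through the partner
chain. Everything is seeded and bit-reproducible.

What passing tests on these fixtures shows: the detectors measure exactly
what was planted (occupancies to binomial noise, distances, tiers, map
entries), the kernels agree with brute-force evaluation, and conservation
and monotonicity hold. What it does not show: behaviour under correlated
dynamics, kinetically ordered contact formation, solvent/membrane effects,
rotamer rearrangement, or a realistic receptor fold — conclusions about
real trajectories inherit only the definitional correctness, not
statistical validity on those features.

## Numerical choices and degenerate inputs

Coincident atoms in a pair sum raise a singularity error rather than
returning Inf. Nonpositive descreened Born radii (pathologically
overlapping geometry) raise a numeric error. Empty contact sets make Q
undefined and error. Annotation lookup is total: unlabelled receptor
residues report "other". FES minima use the 4-neighbourhood with masked
neighbours ignored and non-strict comparison, so plateau minima are
returned, deterministically ordered by energy then bin index.

Problem sizes used by the test suite and acceptance script — 200-frame
fixtures for occupancy recovery at 3 binomial σ, 500 frames for the 0.9
hydrogen-bond target, 2000 frames for RMSF recovery within 10%, ≤10-residue
/ ≤50-frame instances for oracle equivalence — were chosen as the smallest
sizes at which the statistical tolerances are meaningful.

## Known limitations

* Absolute ΔG_bind values are GB/SA-surrogate numbers on a minimal charge
  model; use them for rankings, signs and difference maps, not for
  comparison with PB- or experiment-derived magnitudes.
* The coarse side-chain representation (terminal charged atoms plus one
  pseudo-atom) cannot express packing, π-stacking or hydrophobic burial
  beyond what SASA captures.
* Alternate locations and insertion codes in PDB input are rejected, not
  interpreted; hydrogens beyond the backbone amide are not modelled.
* The pipeline's candidate scoring is a static single-structure interface
  score in the toy pocket — a demonstration of the chain of operations, not
  an affinity prediction.
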