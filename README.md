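# coagdesign

Trajectory interaction analysis and rational design of dual-agonist
("coagonist") peptides for the glucagon receptor (GCGR) and the GLP-1
receptor (GLP-1R), two class-B1 GPCRs whose simultaneous activation is a
leading strategy against type-2 diabetes and obesity. The package is aimed
at computational structural biologists who have (or simulate) peptide–
receptor complex trajectories and want to turn per-residue interaction
signals into candidate peptide sequences.

## What it computes

**Trajectory metrics.** Fraction of native contacts
*Q(x) = |{(i,j) ∈ C₀ : min d(i,j) ≤ 5 Å}| / |C₀|* over residue pairs with
|i−j| > 1; RMSD after Kabsch superposition; per-residue RMSF; mass-weighted
radius of gyration R_g; hydrogen-bond occupancy networks (D···A ≤ 3.5 Å,
D–H···A ≥ 120°, "strong" above 80% population); salt bridges (minimum
side-chain N–O distance, mean < 4 Å, tiered by occupancy at 80%/50%); and
peptide-residue × receptor-domain (ECD/TM1–7/ECL1–3) contact-frequency maps.

**Binding energetics.** A single-trajectory, end-point MM-GB/SA estimate

ΔG_bind = ⟨ΔE_elec + ΔE_vdW + ΔG_polar + ΔG_nonpolar⟩,

with Coulomb and Lennard-Jones interface sums (ε_in = 2), a Still-type
generalized-Born polar solvation term over pairwise-descreened Born radii,
and a γ·SASA nonpolar term (Shrake–Rupley areas). Every component is
decomposed per residue (interface pair terms split half/half), with
conservation guaranteed: per-residue columns sum to the totals. Difference
maps compare variants position by position.

**Design engine.** Point mutations with wild-type guarding ("S16W" fails
loudly if position 16 is not Ser), C-terminal chimera grafts, a
ΔΔG-threshold mutation classifier (improves both / one receptor /
penalizes / neutral), residue-significance filtering (contribution
< −50 kJ/mol), and candidate ranking by the coupled score
ΔG_GCGR + ΔG_GLP-1R with an |ΔG_GCGR − ΔG_GLP-1R| imbalance diagnostic.
Shipped rule files rebuild the 31-residue MD-directed coagonist MDD_GR
(S16W/Q24D/N28D/R17Q on the glucagon template, positions 3 and 15 back to
Glu, GLP-1 Arg30/Gly31 graft) and the 30-residue clinical reference
Cotadutide.

**Free-energy surfaces.** 2D histograms of order-parameter pairs (RMSD vs
R_g, interface energy vs windowed RMSF) converted to F = −kT ln(P/P_max)
with masked empty bins and minima-basin location.

**Synthetic complexes.** Because validation needs ground truth, the package
generates toy peptide–receptor complexes — an ideal α-helix (φ = −57°,
ψ = −47°) in a ring-shaped pocket — and trajectories with *planted*
hydrogen-bond occupancies, salt-bridge distances and per-residue
fluctuation amplitudes, all seeded and exactly recoverable.

## Worked example

```r
library(coagdesign)

mdd <- build_design("mdd_gr")
mdd
#> <peptide_seq> MDD_GR (31 aa)
#>   HSEGTFTSDYSKYLEWQRAQDFVDWLMDTRG
#>   provenance: S16W, Q24D, N28D, R17Q, Q3E, D15E, graft:glp1_7_37[30-31]

cplx <- assign_params(combine_structures(
  build_ideal_helix(mdd),
  build_toy_receptor(residues = c(`146` = "R", `225` = "D", `231` = "R"),
                     radius = 20)))
plan <- interaction_plan(
  saltbridges = tibble::tibble(acid_chain = "P", acid_resno = 21,
                               base_chain = "R", base_resno = 146,
                               distance = 3.0, occupancy = 0.9),
  fluctuation = tibble::tibble(chain = "P", resno = 1:31, sigma = 0.2),
  seed = 42)
traj <- generate_trajectory(cplx, plan, 100)

salt_bridges(traj)
#>   acid_chain acid_resno acid_resname base_chain base_resno base_resname
#> 1          P         21          ASP          R        146          ARG
#>   mean_min_NO_distance occupancy   tier
#> 1             3.576793      0.89 strong

glance(binding_free_energy(traj, config = energetics_config(frame_stride = 25)))
#> # A tibble: 1 × 6
#>    elec   vdw polar nonpolar dg_bind frame_count
#>   <dbl> <dbl> <dbl>    <dbl>   <dbl>       <int>
#> 1 -166. -1.51  165.   -0.677   -4.11           4
```

The planted Asp21–Arg146 bridge is detected at its planted occupancy and
tiered "strong"; the decomposition shows the signature of charged-interface
binding — a large favourable electrostatic term mostly cancelled by the
polar-solvation penalty, a pattern the per-residue table (`tidy()`) localises
to the charged positions. `run_pipeline(demo_pipeline_config("out"))` chains
all of the above into a TSV/FASTA/JSON report bundle with a manifest.

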