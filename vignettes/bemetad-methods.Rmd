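---
title: "Mapping disordered-peptide free-energy landscapes with bemetad"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping disordered-peptide free-energy landscapes with bemetad}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bemetad)
```

## The problem

Intrinsically disordered peptides (IDPs) do not fold into a single
structure: they interconvert among a broad ensemble of conformations,
and the biologically interesting question is how that ensemble is
organised — which partially structured states exist, how much free
energy above the disordered ground state they cost, and which residues
carry transient helix, strand or polyproline-II (PPII) structure. The
package's study object is the 27-residue C-terminal peptide of the
plant UV-B photoreceptor UVR8 (`GKSWVSPAERYAVVPDETGLTDGSSKG`, author
numbering 397–423) whose conserved Val–Pro motif (V410–P411) mediates
binding to the E3-ligase component COP1. `bemetad` implements the full
computational analysis chain for such a system at desk scale:
collective variables, bias-exchange metadynamics, WHAM free-energy
reconstruction, and free-energy-windowed structural analysis.

Explicit-solvent molecular dynamics is deliberately out of scope.
The sampling engine instead drives *pluggable toy samplers* — an
overdamped Langevin integrator on analytic potentials with
quadrature-exact references, and a torsion-space Metropolis Monte
Carlo sampler for peptides — behind the same interface a real MD
backend would use (`sampler_cvs()`, `sampler_advance()`). Everything
downstream of the sampler is the real method.

## Collective variables

Seven CVs describe the peptide:

* **CV1–CV3** (`ss_rmsd_cv`): counts of 6-residue fragments
  resembling an ideal α-helix, parallel or antiparallel β-sheet. Each
  fragment's backbone N, Cα, C, O, Cβ atoms are superposed on a frozen
  ideal template and the RMSD (nm) is passed through the rational
  switch n(RMSD) = (1−(RMSD/0.08)^8)/(1−(RMSD/0.08)^12), which is 1
  at zero deviation, 2/3 at exactly 0.08 nm (the removable
  singularity is evaluated analytically) and decays as RMSD^−4.
  For the helix the fragments are the L−5 contiguous windows. A
  contiguous 6-mer cannot form a two-stranded sheet, so for CV2/CV3 a
  fragment is a *pair* of 3-residue segments (starts i and j, j ≥ i+4)
  superposed on a frozen two-strand template; unordered pairs are
  counted once. The templates are built from canonical dihedrals
  (helix −57.8/−47.0; strand −119/+113, inter-strand spacing 0.48 nm)
  and shipped as plain-text fixtures so results are bit-stable.
* **CV4, CV5** (`contact_cv`): switched contact numbers with
  C_ij = (1−(r/r0)^n)/(1−(r/r0)^m). The hydrophobic set (CV4) is all
  non-adjacent pairs among V401, P403, A404, A408, V409, V410 and
  P411 at r0 = 0.40 nm (an alternative 0.45 nm preset is exposed, as
  both values are defensible contact radii for side-chain heavy
  atoms); the salt-bridge set (CV5) pairs Asp/Glu against Arg/Lys at
  r0 = 0.35 nm. The contact-switch exponents are n = 6, m = 12 (the
  standard m = 2n rational switch); each residue contributes one
  interaction site, the centroid of its side-chain heavy atoms (the
  simplified Cβ/Cγ/Cδ sites for built peptides, a stored centroid for
  full-atom input, Cβ as fallback).
* **CV6, CV7** (`alphabeta_cv`): side-chain packing similarity
  Σ ½(1+cos(χ−χ_ref)) over residues possessing χ1 (CV6) or χ2 (CV7).
  The reference rotamer means ship as a frozen package table.

All seven CVs are checked against naive brute-force re-implementations
(plain loops, quaternion-method RMSD) to 1e-10.

## Bias-exchange metadynamics

Each replica carries a history-dependent bias on a single CV: Gaussian
hills of height 0.2 kJ/mol are deposited at the replica's current CV
value every 4 ps, with per-CV widths (0.2, 0.2, 0.2, 2.0, 0.65, 0.5,
0.2) for CV1–CV7, at 330 K. Every 20 ps a randomly chosen replica pair
attempts a Metropolis swap of their bias potentials with
Δ = [V_a(x_a)+V_b(x_b)−V_a(x_b)−V_b(x_a)]/kT, accepted with
min(1, e^Δ); the hill height is constant (no well-tempered scaling).
Every stochastic element draws from per-replica L'Ecuyer-CMRG
substreams derived from one master seed, so runs are bit-reproducible
and independent of replica scheduling.

Numerical choices that matter:

* The Langevin sampler defaults to friction γ = 10 (kJ/mol·ps per CV
  unit²) at dt = 0.02 ps. Deposition must be slow compared to local
  relaxation but fast compared to barrier crossing; at γ = 1 the
  walker fully decorrelates between 4 ps deposits and the
  constant-height bias systematically underfills barriers, while γ =
  10 reproduces the analytic barrier of the packaged double well to
  within a few percent. Reflecting walls at the declared domain edges
  keep the walker on the bias grid.
* Hills accumulate on a cached 1-D grid (1201 points, linear
  interpolation) for sampler forces; `bias_energy()` itself always
  evaluates the exact Gaussian sum.
* With constant hill height the negated bias oscillates around −F;
  `metad_profile()` averages the bias over the deposition history
  after a 30% burn-in, which damps the oscillation (a longer average
  is uniformly more accurate once the fill transient is over). Basin free-energy
  differences integrate e^{−F/kT} on each side of the barrier top, the
  same functional the analytic references use.
* The schedule supports `deposit_stop_time`: hills frozen after a fill
  phase while sampling continues. The post-freeze tail is genuine
  static-bias umbrella sampling, which is exactly the regime the WHAM
  estimator assumes; the validation runs use a 5/8 fill fraction.
* The Monte Carlo sampler books one sweep (one proposal per residue
  over φ, ψ, χ1, χ2, Gaussian step, default 20–25°) as 1 ps so the
  deposit/exchange schedule applies unchanged. Detailed balance holds
  with respect to exp(−(U+V_bias)/kT) with the bias evaluated through
  the CV layer on the proposed conformation.

## WHAM free-energy reconstruction

CV space is divided into a grid (half-open bins, final bin closed;
default widths proportional to the hill widths). Per replica, frames
before an equilibration cut (default the first 6% of the run,
mirroring a 30 ns transient of a 500 ns replica) are discarded and the
rest histogrammed. The standard multi-histogram self-consistency
iteration then runs with each replica's bias treated as static (its
final hill sum, evaluated at cell centres along the replica's biased
CV), until the maximum free-energy change is below 1e-6 kJ/mol. The
grid is pinned so the minimum over visited cells is exactly zero;
unvisited cells are +Inf and never interpolated. Disconnected replica
histograms raise an error naming the components, since their offsets
would be undetermined. With a single unbiased replica the estimator
reduces exactly to −kT log(counts). For runs biased on many CVs the
grid may cover a subset of them; a replica whose biased CV is not a
grid dimension is treated as unbiased on that grid with a warning — a
documented approximation appropriate for low-dimensional landscape
views of a 7-CV run. `marginalize()` integrates Boltzmann weights over
dropped dimensions and re-pins; frames are stratified into 5 kJ/mol
windows [0,5), [5,10), … up to 25 kJ/mol above the minimum.

## Structural analysis

* `assign_ss()` is a deliberately simplified DSSP: backbone H-bonds
  scored with the classic electrostatic energy
  E = 27.888·(1/r_ON + 1/r_CH − 1/r_OH − 1/r_CN) kcal/mol (distances
  in Å, bond if E < −0.5 kcal/mol, donor–acceptor separation ≥ 3);
  helix requires two consecutive i→i+4 turns (labelling i+1…i+4);
  strand requires DSSP-pattern bridges extending into ladders of ≥ 3
  consecutive rungs. No π/3-10 helices, bends or isolated bridges.
  The ladder minimum of 3 (one step stricter than a minimal 2-rung
  ladder) reflects that two-rung "ladders" arise spontaneously in
  random extended coil; with real strands being ≥ 3 residues the
  stricter rule keeps chance coil geometry out of the E class.
  Missing amide hydrogens are reconstructed on the bisector-opposed
  N direction at 0.101 nm (prolines and the N terminus have none).
* `assign_ppii()` overlays P on coil residues with φ, ψ within ±29° of
  (−75°, 145°) in runs of ≥ 2.
* `sasa()` is Shrake–Rupley over heavy atoms (probe 0.14 nm, fixed
  element radii, golden-spiral point set — deterministic, so results
  are bit-stable; 960 points reproduce the isolated-sphere closed form
  to 0.5%).
* `radius_of_gyration()` is mass-weighted over heavy atoms.
* `window_report()` aggregates per-residue H/E/P fractions per
  free-energy window — either as fractions of the total population
  (the landscape-figure convention, default) or within-window — plus
  per-residue ΔSASA against the global-minimum window and window means
  of Rg and total SASA.

## The synthetic-data generator

`sample_ensemble()` produces ensembles with known ground truth:
structure is specified as *blocks* (consecutive residues drawn jointly
into H, E or P with a given probability; overlapping blocks are
mutually exclusive alternatives), so minimum run lengths are
realisable by construction. Residues get canonical state dihedrals
(H −57.8/−47; E −119/113; P −75/145) plus wrapped Gaussian noise;
coil residues draw from a two-basin library; χ angles scatter around
the reference rotamers.

Design choices worth knowing, all aimed at keeping the ground truth
*identifiable* — i.e. at ensuring the generator does not accidentally
create genuine secondary structure it does not record:

* The coil library is 75% extended (φ ∈ (−170°, −95°), ψ ∈ (80°,
  180°), PPII box excluded by rejection) and 25% isolated left-handed-α
  draws (φ ∈ (45°, 100°), ψ ∈ (−10°, 60°), never two in a row). The φ
  bound stays clear of the right-handed helical basin, and consecutive
  left-handed draws are forbidden because a run of them is a genuine
  left-handed helix — with real i→i+4 H-bonds the classifier would
  correctly find — and a pair of them is exactly the β-turn motif that
  nucleates chance hairpins in flanking extended segments.
* Drawn H blocks get helix caps: the preceding residue's ψ and the
  following residue's φ are set to helical values, with the cap
  residues' other angle pinned to non-helical cap geometry (φ −135°
  N-side, ψ +120° C-side). The block's terminal H-bonds can then form
  while the caps themselves never read as helical.
* E blocks name two strand ranges separated by exactly two turn
  residues; the generator folds them into an antiparallel hairpin
  using a frozen type II' β-turn (60°, −120°), (−80°, 0°) — of the
  four standard turn types, the only one that yields DSSP-detectable
  strands from the canonical strand dihedrals. Hairpin H-bond registry
  is geometrically delicate: recovery is essentially complete at
  dihedral noise ≤ 2–4° and degrades at 8°, which is the physically
  honest behaviour of rigid ideal geometry.
* Ground-truth PPII labels are assigned *post hoc* from the realised
  (noisy) dihedrals with the same box-and-run rule the classifier
  uses on measured angles — the truth is what the frame actually
  encodes, not what was drawn. H and E truth are the drawn blocks.

What passing the recovery tests shows — and what it does not: the
generator emulates per-residue state mixtures with realisable
geometry, dihedral noise, and hairpin pairing, and the analysis layer
recovers the generating fractions within 3σ binomial error at n = 2000
(with an Agresti–Coull variance floor so zero-count residues have a
finite band). It does not emulate tertiary packing, solvent effects,
side-chain rotamer correlations or the conformational kinetics of a
real IDP ensemble; agreement here validates the analysis chain, not
any force field.

## Validation problem sizes

The packaged validation suite uses desk-scale problem sizes chosen to
give each estimator enough statistics for its stated tolerance:
2.5×10^5 Langevin steps (5000 ps) for the 1-D metadynamics check;
8000 ps per replica (bias frozen after 5000 ps) for the two-replica
2-D BEM+WHAM check; 2000 frames for secondary-structure parameter
recovery; 20 random frames for the CV oracle comparison; 960 sphere
points for the SASA closed-form check. The 7-replica peptide pipeline
is exercised at small sweep counts for structural and determinism
properties rather than converged thermodynamics.

## Known limitations

* The MC and Langevin samplers are surrogates: no solvent, no
  physical kinetics, energy models are toys. Conclusions about real
  peptides require plugging in an MD engine behind the sampler
  interface.
* Static-bias WHAM ignores the time dependence of the bias during the
  fill phase; use a frozen-bias tail (as the validation runs do) or a
  generous equilibration cut.
* The simplified DSSP has no 3-10/π helices and no isolated-bridge
  class; turn content maps to coil.
* A dense 7-D grid is mostly empty at desk scale; landscape views are
  low-dimensional projections with the unrepresentable-bias
  approximation noted above.
* PDB I/O covers single-chain standard residues; side chains beyond
  Cβ/Cγ/Cδ are collapsed into centroid interaction sites on input.
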