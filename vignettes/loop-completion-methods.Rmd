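---
title: "Homology-based loop completion: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Homology-based loop completion: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(loopgraft)
```

## The problem

Crystallographic protein models routinely leave internal stretches of the
chain unmodeled: flexible regions whose electron density was too weak or
too ambiguous at build time. When a homologous structure *has* that region
modeled, its conformation is an excellent template — highly similar
sequences adopt highly similar structures — and the local density often
supports a single well-defined conformation after all. `loopgraft`
rebuilds such regions by grafting the equivalent residues from homologous
chains, regularizing them against the density, and accepting the result
only if it survives a battery of geometric and density-based checks.
"Loop" is used in the broad sense throughout: any unmodeled internal
stretch, regardless of secondary structure.

The package also provides the smaller-scale repairs that usually precede
loop building: reconstruction of one to three missing backbone atoms from
peptide-plane geometry, completion of the C-terminal carboxylate oxygen
(OXT), and normalization of unjustified partial occupancies.

## The procedure

For each chain, a density pre-check first computes the real-space
correlation coefficient (RSCC) of the whole chain against a
model-calculated map; chains below 0.80 are skipped entirely, since an
unreliable chain conformation makes anchor-based grafting meaningless.

Gaps are detected from case-coded sequences: a construct position is
*complete* when N, CA, C and O are all present at occupancy above 0.01 in
at least one alternate location. Internal runs of incomplete positions up
to 30 residues long, with at least five consecutive complete residues on
both sides, become candidate gaps. Stretches modeled wholesale at
occupancy ≤ 0.01 count as unmodeled, but their coordinates are later
admitted as an extra candidate. Gaps whose flanking residues carry
main-chain alternates (other than pure CA alternates) are skipped — the
alignment target is ambiguous.

For every homolog chain passing the eligibility rules (≥ 70% whole-chain
identity; complete backbone over the loop and its ten flanking residues;
≥ 50% sequence identity over both the loop window and the eight alignment
residues, single-residue loops exempt), the eight residues flanking the
gap — excluding the two directly adjacent, which are remodeled together
with the loop — are superposed by closed-form quaternion least squares.
Mutated anchor positions contribute backbone atoms only, and
chemically equivalent atom labels of Asp/Glu/Phe/Tyr are swapped when
that lowers the fit (DEFY flips). Alignments with backbone RMSD of 2.0 Å
or worse are abandoned. Otherwise the homolog residues are transplanted:
occupancies set to 1.00, B factors scaled by the ratio of protein-average
B factors of target and homolog, side chains cropped to CB at mutated
positions, and methionine/selenomethionine converted to the target's
prevailing type.

Clashes between the candidate and the retained model — including
crystallographic symmetry images — are adjudicated by an importance
hierarchy: heavy clashes (< 2.1 Å) of the loop main chain with existing
main chain or ordinary ligands discard the candidate; glycerol, ethanol,
ethanediol and PEG-like compounds are instead deleted; existing side
chains yield to the loop backbone unless they form a disulfide bridge
(which vetoes the candidate); loop side chains are cropped from the γ
atom when they clash; waters and atoms at occupancy ≤ 0.01 are deleted on
any clash below 2.6 Å.

Surviving candidates are deduplicated (pairs closer than 0.1 Å backbone
RMSD keep only the better-aligned member) and the best ten are refined in
real space, after junction N atoms are nudged into any remaining gap at
the graft boundaries. Refined candidates then pass the geometry gates
(bond/angle RMSZ ≤ 1.2, chirality ≤ 1.5, plane/torsion ≤ 2.0; intact
peptide bonds; at most one omega distortion beyond 30°; cis peptides only
where the source loop is also cis), the Ramachandran check (a score below
−5 triggers a 2σ Grubbs comparison against the other candidates and the
source loops), and the density-ratio gate: the mean interpolated density
over the loop's main-chain atoms must exceed 0.25 times the mean over a
control set of main-chain atoms ordered in every homolog (or, if that set
has fewer than 30 atoms, all non-loop main-chain atoms). Among survivors
the candidate with the best absolute loop density is installed. A final
RSCC check of the installed loop against the observed map discards it
below 0.60 and restores every deletion made on its behalf.

## The real-space regularizer

The refinement engine minimizes

E = w_geom · Σ Z² (bonds, angles, peptide planarity, chirality, torsion
tethers) + w_rama · Σ (−log f(φ, ψ)) − w_map · Σ occ·ρ(x)

with L-BFGS and analytic gradients. Restraint targets and sigmas come
from a bundled standard-geometry table; planarity is enforced through
the omega torsion and the carbonyl improper, both with σ = 3°; backbone
and side-chain torsions are tethered to the grafted start conformation
(σ = 10°/15°), which is what keeps the homolog's conformational
information alive through refinement. The region is the candidate plus
one existing residue per side; the next residue out enters the
restraints as a fixed boundary. Defaults: w_geom : w_map = 1 : 3 on the
synthetic map's native scale, w_rama = 0.05, gradient tolerance 1e-3.

The iteration cap is 1500. The restraint system is stiff (bond sigmas
near 0.02 Å against map curvatures of order one give condition numbers
around 10⁴), and L-BFGS regularly needs on the order of a thousand
iterations on fixture-scale regions; a lower cap truncates refinements
that would otherwise converge and mislabels their candidates as
non-converged.

One property of density fitting worth knowing: at working B factors
(B ≈ 35 Å² including map blur) neighboring atoms' Gaussians overlap, so
the per-atom density optimum sits slightly off the true atom center; the
equilibrium between that pull and the geometry terms leaves atoms of an
already-correct model displaced by roughly 0.1 Å. The self-consistency
test therefore uses an atomically sharp, finely sampled map (B = 12,
0.3 Å grid), where the displacement drops below 0.03 Å. This is inherent
to a plain density-sum target, not an optimizer artifact.

## Density machinery

Maps cover one unit cell periodically. Interpolation is separable
4-point Lagrange per axis: exact at grid nodes, exact for per-axis
polynomials up to degree three, continuous everywhere (C¹ continuity is
not claimed), with an analytic gradient for refinement. Synthetic maps
are sums of per-atom isotropic Gaussians with width from B + b_blur and
amplitude proportional to electron count × occupancy; they stand in for
experimentally derived maps in all fixtures. RSCC/RSR are computed over
grid points within 2.0 Å of the atom set; the model-calculated map for
RSCC uses the same Gaussian model (b_blur = 15 Å² by default). CCP4/MRC
mode-2 files are read and written for interoperability.

## Ramachandran reference tables

The φ/ψ reference distributions are generated in code from a
wrapped-Gaussian mixture over the canonical basins, per residue class
(general, Gly, Pro, pre-Pro, Ile/Val), binned at 2°, with a small uniform
floor (3·10⁻⁵) so that far-from-basin conformations score strongly
negative but finite. Reference moments (mean and standard deviation of
the per-residue log-density under the distribution itself) are computed
by exact summation over the bins; a fragment's Z is the mean of
per-residue standardized scores. These tables are a synthetic,
fully reproducible stand-in for tables derived from a curated
high-resolution torsion library: they reproduce the qualitative behavior
that matters for filtering (basin-interior backbones score near or above
zero, random backbones score far below −5) but are not calibrated
against any external dataset, and absolute Z values should not be
compared with those of other programs.

## The fixture generator

`fixture_spec()` + `make_fixture()` define the synthetic study systems:
an ideal-geometry ground truth grown from the bundled geometry table
along a secondary-structure plan (side chains at one canonical rotamer
per type), a target with the gap residues deleted (or kept at occupancy
zero), homologs derived from the truth, and a Gaussian-atom map.

Homolog noise is a smooth low-frequency displacement field along the
chain (per-residue, RMS amplitude = the `noise` parameter, default
0.2 Å): real homologs differ by conformational change with near-ideal
local chemistry, not by independent per-atom jitter, and a smooth field
reproduces exactly that. Mutations swap side chains onto the same
backbone; each homolog also receives a random rigid transform and
optional B-factor scaling.

Recovery fixtures use all-helix plans over a tame residue alphabet: a
continuous ideal helix cannot fold back onto itself, so the ground truth
is guaranteed free of internal steric clashes — which arbitrary φ/ψ
plans with fixed rotamers are not. The "loop" being an unmodeled helical
stretch is consistent with the broad definition above. Problem sizes in
the shipped tests: chains of 24–37 residues, gap lengths 1–14, three
homologs, noise 0.11–0.30 Å, up to three mutations, 0.7 Å map grids.

What the fixtures do *not* emulate: experimental map noise models and
series-termination effects, solvent, crystal packing beyond a single
two-fold for clash tests, alternate conformations beyond simple
injected duplicates, sequence-register errors, and genuinely different
loop conformations between homolog and target. Passing the recovery
tests therefore demonstrates the machinery is correct and the filters
are calibrated to their documented thresholds, not that real-data
success rates will match.

## Numerical and policy choices made where the design was open

- Construct mapping uses a constant numbering offset verified
  residue-by-residue against the construct sequence; chains that cannot
  be mapped without internal mismatches are reported as unmapped rather
  than force-aligned.
- Identity percentages are computed over aligned columns only.
- The B-factor ratio uses protein atoms of the whole donor structure and
  of the whole target.
- Dedup ties on alignment RMSD break by homolog input order; the
  greedy best-first sweep makes the surviving set independent of input
  order.
- Disulfides are detected as SG–SG pairs under 2.5 Å in the input model.
- Clash exclusion around a graft covers the replaced span plus the two
  covalently connected edge residues (their junction bonds are not
  contacts).
- The chain-level RSCC pre-check synthesizes the calculated map from the
  chain itself on the observed map's grid.
- Peptide-bond presence is a C–N distance within [1.2, 1.5] Å;
  "sequential" omega distortions means adjacent peptide bonds; the
  Grubbs comparison uses the fixed 2σ rule.
- Junction closing moves the N atom along the C–N line to a distance
  clamped into [1.33, 1.45] Å (no move needed below 1.6 Å).
- Gap processing runs N- to C-terminal against the continuously updated
  model.
- When a chain begins fewer than five residues before a gap the gap is
  not attempted; the full five-residue anchor is always required.

## Known limitations

- No reciprocal-space refinement or map recalculation follows a build;
  the final RSCC check runs against the supplied map with a
  Gaussian-atom calculated map.
- Side chains of grafted residues are not rebuilt; incomplete side
  chains are only reported.
- Partial-loop building and terminus extension are deliberately absent.
- The regularizer is a simplified engine with bundled restraints; it is
  not a reimplementation of any external refinement program's numerics.
- Multi-conformer grafting is out of scope; one conformation per loop.
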