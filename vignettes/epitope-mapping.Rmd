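---
title: "Structure-based epitope mapping of allergen isoforms: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Structure-based epitope mapping of allergen isoforms: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epimap)
```

## Scope

`epimap` implements the structural-immunoinformatics workflow used to study
polymorphism in pan-allergen families such as plant profilins: how sequence
micro-heterogeneity among isoforms redistributes solvent-exposed surface,
reshapes predicted conformational B-cell epitopes, and shifts the variant
spectrum of linear B-cell epitopes and HLA-DR anchor motifs. The package
covers per-residue solvent accessibility, a three-rule conformational
epitope predictor, alignment variability and variant enumeration,
sliding-window antigenicity profiles, rigid-body superposition, a
disulfide feasibility screen, formal-charge summaries and overlap
classification between conformational and linear epitopes. Homology
modelling, Poisson-Boltzmann electrostatics, secondary-structure
prediction and HLA-DR matrix scoring are out of scope; where their outputs
are needed (T-cell anchor positions, model structures) they are consumed
as inputs.

## Solvent accessibility

Per-atom areas use the Shrake-Rupley construction: each atom's van der
Waals sphere is expanded by the probe radius (default 1.4 Å, a water
molecule) and covered with a deterministic golden-spiral point set
(default 960 points); a point is accessible when it lies outside every
neighbouring expanded sphere, and the accessible fraction scales the
expanded-sphere area. The point set is global (not body-fixed), so areas
are exactly reproducible for a given structure and drift only by the
sampling tolerance (about 1% at 4096 points) under rigid-body motion.
Residue areas are atom sums, so residue totals conserve atom totals
exactly.

Relative SASA divides a residue's area by its maximal accessibility in an
extended Gly-X-Gly tripeptide. Two published tables are shipped:
the theoretical maxima of Tien et al. (2013), the default, and the
Miller et al. (1987) standard-state values. Values above 100% are kept
unclamped — chain termini legitimately exceed the tripeptide reference —
and exposure classes are computed from the unclamped value. The exposure
thresholds are those of the underlying method: buried below 20%, surface
at or above 25%, protruding above 75%. Because the original analysis did
not state which reference table its percentages used, absolute agreement
of epitope counts on real structures depends on this choice;
`epitope_parameter_sweep()` reports the sensitivity of the prediction to
the table and to the distance basis.

## Conformational epitope prediction

The predictor composes three rules, in order:

1. **Centers.** Residues with relative SASA strictly above 75% are
   epitope centers. Centers closer than 5 Å (0.5 nm) combine into a
   single epitope; merging is single-linkage, so chains of centers
   coalesce — the published wording ("two or more of these residues
   closer to each other") does not specify chaining, and transitive
   merging is the only order-independent reading.
2. **Expansion.** Every residue with relative SASA strictly above 20%
   lying within 10 Å (1 nm, the typical radius of an antigen-antibody
   contact surface) of *any* center of the group joins the epitope.
   Distance is Cα-Cα by default; a minimum-heavy-atom basis is available
   because the original tool-based measurement is not specified.
3. **Gap filling.** A single residue whose two sequence neighbours (author
   numbering) are already members is added. This runs once, after
   expansion, and never fills two-residue gaps.

All threshold comparisons are strict, matching the published inequalities;
boundary values (exactly 75%, exactly 5.0 Å) therefore do *not* qualify.
Epitopes are numbered by their smallest center residue number. Epitopes
may share members through expansion — only the center sets are guaranteed
disjoint. Every member carries a provenance tag (`center`, `proximity`,
`gap_fill`).

Two open points were resolved as package design choices: rules run in the
listed order (centers are merged before expansion), and multi-chain files
are analysed one chain at a time (chain A by default for crystal
templates), ignoring lattice or dimer partners.

## Alignment variability and variant enumeration

Wu-Kabat variability of a column is `V = N * k / n` over non-gap residues
(`N` residues, `k` distinct, `n` count of the commonest); gaps are not a
21st symbol. Because raw `V` is bounded below by 1 while the published
classification uses classes below 1, the profile normalises by the
per-alignment median (`viv = V / median(V)`) so that all three classes —
low (`viv < 1`), intermediate, high (`viv > 3`) — are reachable; raw `V`
is reported alongside. The exact index behind the published
classification is not defined in its source, so this normalisation is a
documented stand-in and published per-residue class colourings are not
used as validation targets.

Region variants are keyed by the alignment columns spanned by the
reference positions, including insertion columns inside and immediately
after the span, so indel isoforms appear as length-variant strings.
Records whose region contains an unknown residue are excluded and logged.
Suffix 0 is the designated template's variant regardless of rank; the
remaining suffixes follow descending frequency with ties broken by input
order. Frequencies are unweighted sequence counts and sum to 100% within
rounding.

T-cell anchor motifs are *inputs* (9-mer start positions in reference
numbering, as produced by HLA-DR matrix tools); the package classifies
their per-group frequency — high above 70%, low below 30%, absent at 0 —
and flags anchors high in every group as shared, high in exactly one as
specific.

## Antigenicity profiles and region calling

Three literature scales are embedded: Kyte-Doolittle hydropathy, Welling
antigenicity (log-ratio of residue frequencies in known antigenic regions
versus average proteins) and Parker HPLC hydrophilicity. Profiles are
centred windowed means (default window 7, a common choice for B-cell
epitope scanning; the source analysis states none); positions within half
a window of a terminus use the truncated window and are flagged.

The published region-calling rule is not stated quantitatively, so the
package operationalises it: a position is positive when at least two
scales point in the antigenic direction (Welling and Parker above zero;
hydropathy below zero), maximal runs of at least 5 positions become
regions, and — when exposures are supplied — a region must average more
than 25% relative SASA. Region labels (`A1`, `A2`, ...) are positional,
left to right; correspondence with any published region naming is
positional only. Published region boundary tables are therefore treated
as illustrative, not as validation targets.

## Superposition, disulfides, charges

`kabsch_superpose()` is the SVD solution of the least-squares rigid
superposition with the reflection corrected to a proper rotation
(determinant +1); fewer than three pairs or near-collinear geometry raise
errors. For inter-structure RMSD the residue mapping comes from a global
sequence alignment (match +1, mismatch 0, gap −1) with Cα pairs taken at
aligned non-gap columns; by default all mapped pairs are used, and an
iterative 2-sigma outlier-trimming option mimics the refinement cycles of
interactive viewers, since published RMSD values from such tools typically
reflect trimmed cores.

The disulfide screen lists every unordered cysteine pair with its Cα-Cα
distance; the feasibility window of 3.0-7.5 Å derives from canonical
cystine stereochemistry (the source highlights "most likely" pairs
without a stated cutoff). The charge summary counts Asp/Glu as −1 and
Lys/Arg as +1, with histidine optional and off by default and termini
ignored — the only model consistent with simple percentage bookkeeping of
charged residues.

## Synthetic data with provable ground truth

The generators exist so that every stage is testable without downloading
coordinates. `make_globule()` builds a single-chain, one-atom-per-residue
(Cα) shell: residues are packed on a sphere at 3.8 Å nearest-neighbour
spacing so they occlude each other below the protruding threshold, while
planted residues are displaced 8 Å radially outward and become unoccluded
(relative SASA above 75% under the default configuration, using glycine
whose Gly-X-Gly reference a bare carbon sphere exceeds). Planted residues
take mutually distant shell slots (farthest-point sampling) so the holes
they leave are isolated and no shell residue loses enough neighbours to
protrude spuriously. Cysteine pairs are repositioned to exact target
distances. The construction is verified numerically before the structure
is returned, and the ground truth (protruding set, exact distances) is
emitted alongside.

`make_msa()` plants region variants by largest-remainder quota of the
target frequencies, shuffles assignments with an explicit seed, and forces
the first record onto the template variant in every region so it can act
as the alignment reference without perturbing quotas. Both generators are
byte-deterministic under `spec + seed` and never touch the caller's RNG
stream.

These constructions are idealised on purpose: the algorithms under test
depend only on distances and exposure, so geometry with provable
SASA/distance properties beats ad hoc realism. What they do **not**
emulate — side-chain packing, real fold topology, correlated substitution
patterns, alignment errors — means that green synthetic tests demonstrate
algorithmic correctness, not that predictions on real structures
reproduce any particular published table.

## Validation scale and known limitations

The shipped validation uses globules of 40-100 residues (100 seeds for
oracle equivalence), 10,000-sequence synthetic alignments for exact
variant recovery, and 1,000 random columns for the Wu-Kabat brute-force
check; all property checks run in well under five minutes on one CPU.

Known limitations:

* The three profilin crystal templates (PDB 1g5u, 1cqa, 3nul) are not
  bundled; checks that quantify epitope counts and inter-template RMSD on
  real structures require placing those coordinate files under
  `inst/extdata/templates/` and are expected to fail without them.
* Epitope counts on real structures are sensitive to the Gly-X-Gly table,
  the radii set and the distance basis; `epitope_parameter_sweep()` makes
  this visible rather than hiding it behind one configuration.
* The antigenicity region-calling rule and the viv normalisation are
  documented operationalisations of qualitatively described procedures.
* Residue identity assumes unique author numbering per chain; insertion
  codes are carried but sequence-gap filling treats numbering as the
  sequence order.
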