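---
title: "Ensemble docking post-processing and kinase isoform selectivity"
author: "kindock"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ensemble docking post-processing and kinase isoform selectivity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kindock)
```

## Scope and model

`kindock` covers the analysis layer of a structure-based campaign against two
closely related kinase isoforms. Upstream of the package sit a docking engine
and the public structure/bioactivity databases; the package consumes their
outputs as plain files (PDB coordinates, score tables, activity tables,
position maps) and contributes four pieces of methodology:

1. **Conformational reduction.** Deposited kinase structures over-represent
   popular conformations. The binding site of each monomer — every residue
   with a heavy atom within 5 Å of its co-crystallized ligand — is compared
   across the ensemble by heavy-atom RMSD after a single Kabsch fit of all
   monomers onto a common reference (the structure with the most resolved
   site atoms; ties broken by lexicographic id). Pairwise RMSDs are computed
   in that one frame, *without* per-pair re-fitting, so the matrix measures
   conformational displacement in a shared coordinate system rather than
   per-pair best superposition. Complete-linkage agglomeration of the matrix
   yields compact families; representatives are the cluster medoid plus up
   to two max–min diversity picks.
2. **Screening validation.** Each representative is judged by how well a
   score component separates known actives from inactives: ROC AUC for
   global discrimination, and early-recognition metrics (exponential ROC
   enrichment and enrichment factors) because a prospective screen only ever
   tests the top of the list.
3. **Relative-rank selectivity.** Ranks are normalized within each kinase's
   library (`R = rank/N`, midranks for ties) and the per-ligand difference
   `RR = R_A − R_B` is the selectivity score. RR is a prioritization
   statistic within the screened chemical space, not a binding free-energy
   difference, and the package never converts it to one.
4. **Interaction fingerprints.** Docked poses are reduced to boolean bits
   (canonical site position × interaction type) under explicit geometric
   criteria, enabling motif detection (the double hinge hydrogen bond) and
   exact contingency tests of bit enrichment in actives.

## Tunable parameters

| Parameter | Default | Units | Rationale |
|---|---|---|---|
| site cutoff | 5.0 | Å | standard contact-shell radius around the reference ligand |
| cluster count `k` | max mean silhouette over 2–8 | – | reproducible, unattended; `k` may also be fixed in the config |
| extra representative: population | ≥ 25 % of structures | – | large families deserve a second conformer |
| extra representative: dispersion | mean within-RMSD > across-cluster median | Å | loose families deserve a diversity pick |
| representatives per cluster | ≤ 3 | – | keeps the docking ensemble small |
| re-dock fidelity threshold | 2.0 | Å | conventional pose-reproduction criterion |
| eROCE α | 20 | – | early-recognition emphasis comparable to BEDROC α = 20 |
| cutoff fractions | 0.2, 0.5, 1, 2, 5, 10 | % | the grid on which confusion metrics are reported |
| AUC floor | 0.70 | – | below it a conformer is discarded regardless of enrichment |
| "strong early enrichment" | eROCE and EF1% ≥ ensemble median | – | scale-free across ensembles of different size |
| consensus rank | mean over selected conformers | – | "best-rank" available by config; recorded in hit provenance |
| top fraction | 5 % | – | prospective-screen retention |
| RR cutoff | 0 | – | any kinase-B-leaning ligand is dropped |
| separation margin | 0.05 | – | excludes sub-5-percentile rank separation as noise |
| H-bond | ≤ 3.5 Å, D–H···A ≥ 120° with explicit H | Å, ° | declared defaults; the criteria a commercial GUI applies are not published, so these are stand-ins, not reconstructions |
| hydrophobic | C···C ≤ 4.5 Å | Å | apolar side-chain carbons vs apolar ligand carbons |
| aromatic | ring centroids ≤ 5.5 Å | Å | no face/edge subtype split |
| ionic | opposite charges ≤ 4.0 Å | Å | formal charges are inputs, not perceived |
| Wilcoxon family size `m` | 2 | – | vdW + electrostatics; adjusted α = 0.05/m = 0.025 |

Activity labels follow the assay thresholds: active at pChEMBL > 7 or
standard value ≤ 100 nM, inactive at pChEMBL ≤ 5.5 or ≥ 10 µM, otherwise
unknown. When the two values disagree the curated pChEMBL classification
wins and the conflict is logged.

## Numerical conventions

- Lower score = better, everywhere; every score file states it in a header.
- Ties take midranks in AUC, eROCE false-positive rates and rank
  normalization. Top-set sizes are `⌈f·N⌉`; boundary ties resolve by score
  then input order, so all metrics are deterministic.
- F1 is defined as 0 when precision + recall = 0.
- Medoid, max–min and docking-fidelity replacement ties break by
  lexicographic structure id.
- The Wilcoxon signed-rank test drops zero differences (Wilcoxon's
  convention), uses the exact null for ≤ 25 non-zero pairs (R falls back to
  the normal approximation when ties make the exact null unavailable) and
  the continuity-corrected normal approximation otherwise.
- Kendall's coefficient is the tie-corrected τ-b, since midranks introduce
  ties; Spearman's ρ is Pearson on midranks.
- Classical (Torgerson) MDS keeps eigendirections above a 1e-8 relative
  eigenvalue floor and zero-pads (with a warning) when fewer than the
  requested dimensions remain.
- Degenerate inputs fail loudly: no reference ligand, fewer than 3 or
  collinear superposition pairs, empty common-atom sets (named pair),
  single-class metric inputs, all-zero paired differences, unknown config
  keys. Contacts at residues missing from the position map are recorded
  under an `"unmapped"` sentinel with a warning, never dropped.
- Re-running a configuration reproduces every CSV/JSON output byte for
  byte; the provenance manifest is the one exception because it records
  wall-clock timestamps.

## The synthetic-data module

All tests and the acceptance script run on generated data with known ground
truth; the generators are pure functions of their specs (seed included).

**Conformer ensembles.** A 12-residue pocket template (4 heavy atoms per
residue at radius 6 Å around a 12-atom reference ligand at radius 2 Å) is
displaced per cluster by Normal(0, σ_b) per coordinate and per member by
Normal(0, σ_w). Defaults σ_w = 0.3 Å, σ_b = 3 Å, 5 clusters × 15 members
emulate a deposited-kinase ensemble: a few well-separated conformational
families with sub-angstrom internal scatter. One caveat is worth stating:
with ~140 site coordinates, within-cluster distances concentrate at
σ_w·√2 and cross-cluster distances at √(2σ_w² + 2σ_b²), so planted families
remain separable *whenever σ_b > 0* — including σ_b = σ_w. The honest
no-structure null is therefore σ_b → 0, which is what the calibration test
uses.

**Screen tables.** Inactive totals ~ Normal(0, σ), actives
~ Normal(−δ, σ); a tagged fraction of actives gets an extra −β against
kinase A only; each (kinase, conformer) adds Normal(0, σ/2) jitter; vdW and
electrostatic columns are 0.6·total and 0.2·total plus Normal(0, σ/4) — a
fixed testing convention, since a docking engine's real decomposition is
internal to the engine. Defaults (694 actives, 857 inactives, δ = 1.2σ,
4 conformers, 2 % tagged at β = σ) mirror a curated kinase benchmark. The
population AUC for the base scores is Φ(δ/(σ√2)) ≈ 0.80 — the level a
well-performing rigid-receptor kinase screen reaches — and the observed
per-conformer AUC is slightly lower (Φ(δ/(σ√2·√1.25)) ≈ 0.78) because the
conformer jitter is part of the observed score.

**Toy complexes.** Each planted bit occupies its own spatial pod 20 Å from
the next, with geometry satisfying its criterion with ≥ 0.3 Å slack
(H-bonds at 2.9 Å, hydrophobic at 4.0 Å, centroids at 4.5 Å, ionic at
3.6 Å — the last deliberately outside the 3.5 Å H-bond cutoff, and charged
ligand atoms are typed ionic only, so no cross-talk between bit types).
Decoy atoms are placed ≥ 6 Å from every protein atom. Fingerprint recovery
on these fixtures is therefore exact by construction, which is the point:
it isolates the detector's logic from chemical ambiguity.

What passing these tests does *not* show: the generators are geometric, not
biophysical. Real binding sites have correlated residue motions, partial
occupancy and chemistry that the typing tables only approximate, and real
score components are not linear fractions of the total. The synthetic
results validate the statistical machinery, not docking accuracy on real
kinases.

## Design choices where the field leaves room

- **Superposition method.** A single-frame alignment (Kabsch onto the
  best-resolved structure) was chosen over per-pair fitting so that the
  distance matrix is a true configuration-space embedding; per-pair fitting
  would systematically shrink distances for flexible sites. Whether the
  shared-frame or per-pair convention is "standard" varies across the
  literature; the choice is recorded here and the RMSD routine refuses
  pairs with no common atoms rather than guessing.
- **Consensus site.** The union of per-structure 5 Å sites, with each pair
  compared over the atoms resolved in both. The union (rather than the
  intersection) keeps conformers comparable even when loops are disordered
  in a subset of structures.
- **Cluster count.** No cut criterion accompanies a dendrogram by itself;
  maximum mean silhouette over k ∈ [2, 8] is reproducible and unattended,
  and a fixed k remains available in the configuration.
- **Docking-fidelity index.** The published index this step emulates is not
  reproduced internally; the package consumes externally computed re-dock
  pose deviations and applies a ≤ 2 Å pass rule — a declared stand-in
  consistent with standard practice.
- **eROCE closed form.** The exponential-weight mean over actives,
  `exp(−α·FPR_i)` with midrank FPRs, with α = 20 by default and recorded in
  every report.
- **Multiple testing for bits.** Benjamini–Hochberg q-values are reported
  alongside raw Fisher p-values and the descriptive |difference| ranking,
  so the exploratory reading of the fingerprint table remains available.
- **Hit ordering.** RR ascending, then kinase-A rank: the most
  kinase-A-shifted ligands come first, with the kinase-A rank as a
  deterministic tie-break.

## Problem sizes

The test suite and acceptance script use deliberately small instances: toy
structures of 3–12 residues for geometry oracles, ensembles of 18–75
structures, screens of 80–4000 ligands (2000 per class for the
normal-overlap AUC check), 200-replicate null calibrations, 1000-case
exhaustive comparisons against brute-force oracles, and a 6000-ligand
prospective library. These sizes make every statistical check well-powered
while keeping the whole suite to a few minutes.

## Known limitations

- Interaction typing uses a fixed residue/atom-name table and supplied
  ligand formal charges; there is no perception engine, no water-mediated
  hydrogen bonds (waters are stripped on read) and no π-stacking subtype
  split.
- The fingerprint criteria are declared defaults, not a reconstruction of
  any commercial implementation's unpublished thresholds.
- Pose-consistency RMSD is computed without re-fitting, in the docking
  frame; poses from engines that report coordinates in per-receptor frames
  must be superposed first.
- RR quantifies rank displacement within one screened library; it is not
  transferable across libraries and not a ΔIC₅₀ surrogate.
- mmCIF input, structure preparation (protonation, side-chain
  optimization) and ADME prediction are out of scope; descriptors for the
  drug-likeness rules are inputs.
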