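---
title: "Methods and design choices in dualscreen"
author: "dualscreen authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design choices in dualscreen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The screening problem

`dualscreen` targets the discovery of *dual* inhibitors: single molecules
active on two unrelated enzymes. The motivating application is Alzheimer's
disease, where blocking the peripheral anionic site (PAS) of
acetylcholinesterase (AChE) is thought to slow amyloid-β aggregation while
inhibiting β-secretase (BACE-1) reduces amyloid-β production. The pipeline
couples a fast ligand-based stage — classification models that score
millions of molecules cheaply — with a structure-based stage that audits
docked poses of the shortlist against the interaction pattern of
crystallographic ligands, and a final weighted combination of both scores.

## The filter-ensemble classifier

A model is an ordered set of *filters*. A filter is a conjunction of five
closed ranges over five distinct molecular descriptors; a molecule passes
iff all five ranges hold. Filters are individually weak but interpretable
(e.g. "21 ≤ non-polar atoms ≤ 47 and 416 ≤ weight"), and the ensemble
recovers a graded score.

**Filter scoring.** Every filter carries the confusion rates of its
held-out evaluation: P and N, the percentages of actives and inactives
classified correctly, and Pf = 100 − N, Nf = 100 − P. Its quality is the
Matthews correlation coefficient
MCC = (P·N − Pf·Nf)/√((N+Nf)(N+Pf)(P+Nf)(P+Pf)), chosen because it stays
meaningful under the heavy class imbalance of actives-vs-decoys training
sets. Degenerate filters (a zero factor in the denominator) are defined to
have MCC 0.

**The molecule index.** Screening a molecule through an n-filter model
yields Index = (1/n)·Σ [δᵢ·min(Pᵢ/Pfᵢ, cap) − δᵢᶠ·min(Nfᵢ/Nᵢ, cap)]: each
passed filter contributes its true/false-positive ratio, each failed filter
subtracts its false/true-negative ratio. Raw rate ratios are unbounded (a
filter with Pf → 0 would dominate the sum), while published index tables
for this class of models lie within [−1, 1]; we therefore cap each
contribution at `cap = 1` by default and replace zero denominators by
`eps = 0.5` percentage points. Both knobs are stored in the model object
and serialized with it, because indexes are only comparable under a fixed
convention.

### The search

The training search is an iterative stochastic elimination:

1. **Candidate pool.** Each descriptor is discretized into candidate
   ranges whose endpoints are active-class quantiles at
   0/2/5/10/…/90/95/98/100%. Only ranges retaining at least half of the
   active class are generated: a five-way conjunction multiplies pass
   rates, so a range that already drops most actives cannot be part of any
   useful filter and only slows convergence. The tail quantiles matter for
   the opposite reason — conjunctions are built from *mild* per-descriptor
   cuts, and a plain decile grid cannot express a cut that keeps 95-98% of
   actives. The outermost endpoints are widened to act as one-sided
   ranges.
2. **Generations.** Each generation samples `gen_size` random filters
   (five distinct descriptors, one candidate range each) and scores them on
   the search portion of the data. Every candidate accumulates the average
   MCC of the filters it appeared in; after each generation the bottom
   `elim_frac` of used candidates face elimination with probability
   proportional to their rank (worst first). The loop stops after
   `n_iterations` generations or when the pool is exhausted.
3. **Refinement.** The top filters found stochastically are polished by a
   greedy coordinate sweep: each of the five slots in turn is offered every
   remaining candidate (from any descriptor not already used), keeping the
   substitution that most improves the search-set MCC, until a sweep makes
   no change. This turns "one strong cut plus noise" filters into true
   conjunctions of informative cuts.
4. **Validation.** All surviving filters are re-evaluated on a held-out
   set — a stratified 25% split by default, or an explicit fold in the
   cross-validation harness. Filters below `mcc_min` are dropped. The kept
   filters are *selected and ordered by their search-set MCC*, while the
   stored rates (which drive the index) are the held-out ones. Ordering by
   the held-out estimate itself would make the reported "held-out"
   performance the maximum of many noisy estimates: on label-shuffled data
   that bias is about +0.2 MCC, defeating the very leakage check the
   held-out split exists for. With search-set ordering the shuffled-label
   null is centred at zero (tested over 20 shuffles).

The whole fit is deterministic under its `seed`. The defaults
(`n_iterations = 20`, `gen_size = 300`, `elim_frac = 0.2`) converge in a
few seconds on a 400 × 20 table; they are search-budget knobs, not
statistical parameters.

**Cross-validation and merging.** `ise_cv()` repeats the fit five times,
each 4-fold union validated on the held-out fold, and reports the spread of
best-filter MCC and AUC across folds — similar statistics across folds are
the design's guard against a lucky split. How the five fold-models become
one screening model is a genuinely open choice; `ise_merge()` takes the
union of their filters (optionally truncated to the best by MCC), which
preserves each filter's own held-out rates.

**Cascade screening.** `screen_cascade()` applies the first model as a
gate (index must exceed the stage-1 threshold, default 0) and scores
survivors with all remaining models in parallel; a molecule passes overall
when every model gives it a positive index. Stage-1 failures receive no
downstream indexes — this mirrors screening economics: the gate model is
the cheap filter in front of expensive stages.

## Dataset curation

* **Canonicalization and duplicates.** SMILES are canonicalized through
  OpenBabel on load; records sharing a canonical SMILES collapse to one,
  combining activities by geometric mean (IC50s are log-scaled quantities;
  `min` and `median` are available). Reported potencies below 0.1 nM are
  dropped by default as probable unit errors — the bound is configurable
  because such cutoffs are judgement calls.
* **Diversity pruning.** Pairwise Tanimoto indexes are computed on
  1024-bit OpenBabel FP2 path fingerprints (the dialect is recorded in the
  fingerprint matrix, since TI values are dialect-dependent). Pruning is
  greedy in mol_id order for determinism: a record is dropped when its TI
  to an already-kept record exceeds the cutoff. Fingerprint-identical
  pairs (TI = 1) are always collapsed, so the cutoff-1.0 setting removes
  exactly the fingerprint duplicates.
* **Labelling schemes.** Actives-vs-inactives: IC50 < 10,000 nM is active,
  untagged pool molecules are the inactive class. High-vs-low:
  IC50 < 100 nM vs > 1000 nM (a 3000 nM variant is supported); molecules
  between the cutoffs belong to neither class and are excluded.
* **Decoys.** Pool molecules are eligible as decoys when their H-bond
  donor count, acceptor count, molecular weight and calculated logP all lie
  within mean ± 1.5 sd of the actives — "close to the average" made
  concrete; 1.5 sd keeps ~87% of a matched property marginally while
  excluding genuinely foreign chemistry. Sampling among eligible molecules
  is uniform under the seed, and shortfalls are reported per property.
* **Descriptors.** The descriptor set is an open 2D set: OpenBabel
  properties (weight, logP, TPSA, HBD/HBA, molar refractivity) plus
  heavy-atom element counts and derived counts, with the conventional
  names preserved (`a_hyd` non-polar atoms, `a_nN` nitrogens, `a_nI`
  iodines, `FCharge` total formal charge, `chiral` annotated
  stereocentres). FCharge and chiral are derived from the canonical SMILES
  string. This is deliberately smaller than commercial ~200-descriptor
  sets; the modelling machinery is descriptor-set agnostic and
  `reject_descriptors()` (variance and |r| filters, larger-variance column
  wins, lexicographic tie-break, idempotent) handles redundancy either
  way.

## Docking-pose analysis

Pose generation is external; the package analyzes poses. Hydrogen-bond
detection is heavy-atom based — docked poses and prepared receptors often
lack reliable hydrogens — so a hydrogen bond is any (receptor, ligand)
atom pair of donor/acceptor-capable elements within 3.5 Å, with N and O
accepted in either role and S as acceptor only, and no angle term. Multiple
pairs to one residue count separately. Van der Waals contacts use a 5 Å
heavy-atom cutoff; a residue is contacted if any of its heavy atoms is
within the cutoff of any ligand heavy atom. Waters, ions and bound ligands
are stripped on receptor load, so water-bridged hydrogen bonds are out of
scope by construction.

The *positively docked* rules are target-specific: BACE-1 requires ≥ 4
hydrogen bonds, of which ≥ 2 to the catalytic Asp pair (Asp32/Asp228,
counted over both), and ≥ 8 contacted residues; AChE requires contact with
all nine listed gorge/PAS residues. Whether BACE-1's "eight contacts"
counts listed residues or any protein residue is ambiguous in the source
protocol; the default counts the configured residue list (13 residues for
BACE-1), with `any_residue = TRUE` as the alternative reading. Residue
numbering differs across deposited structures (the catalytic dyad appears
as Asp32/Asp228 or Asp93/Asp289); `numbering_map()` translates canonical
numbers to structure-file numbers and is always explicit configuration,
never inferred.

A molecule's outcome aggregates over structures: docked in a structure if
any of its ≤ 10 poses classifies positively; docked overall if docked in at
least one structure; the reported pose total sums per-structure counts (so
up to 30 over three structures).

**Structure selection.** Candidate receptor structures are compared on a
docking test set: TP/FP enrichment (docked fraction of actives over docked
fraction of inactives) and specificity (1 − docked fraction of inactives).
`rank_structures()` orders by either criterion with deterministic
tie-breaks. Enrichment ratios are reported unrounded and at two significant
figures, the convention used in screening reports.

## Weighted combination and selection

Model indexes (mapped from [−1, 1] to [0, 1]), docked flags and normalized
pose counts form the component vector of each molecule. The exact component
weighting used in the original screening campaign is not public; the
package's fully specified stand-in is a linear score on the weight simplex,
calibrated on reference sets (known dual actives vs randoms) by seeded
random search maximizing the fraction of knowns minus the fraction of
randoms above the selection threshold. The uniform vector is always a
candidate, so calibration can only improve on it, and the returned weights
are serialized with the results for auditability. "Score > 0.5 in all
scores" is read as: the global score *and* each per-target sub-score
(AChE components, BACE-1 components, each renormalized) must strictly
exceed the threshold; calculated logP must be strictly below 4. Rejected
molecules carry the reason of their first failed criterion.

## Synthetic fixtures and what they show

* `make_classification_dataset()` draws class-conditional Gaussians:
  informative descriptors separated by `effect` sd between classes, noise
  descriptors shared. It emulates separable descriptor structure, not real
  descriptor distributions (which are discrete, skewed and correlated);
  passing recovery tests show the search machinery works, not that any
  particular chemistry is learnable.
* `make_pose_fixture()` builds toy receptors (one four-atom backbone
  residue per listed residue, centres 14 Å apart) and ligand poses with
  exactly known interactions: hydrogen-bond atoms rejection-sampled at
  2.8-3.4 Å from the target backbone O while staying > 3.6 Å from every
  other receptor polar atom, contact atoms at 3.8-4.9 Å, decoys beyond
  5.5 Å, minimum atom spacing enforced. No bond-chemistry realism is
  attempted — the profiler is distance/element based, so elements plus
  coordinates are the complete ground truth. Files round-trip through
  bio3d (PDB) and ChemmineR (SDF) to 10⁻³ Å.
* `make_screening_library()` samples a substituent-core-linker grammar
  whose pieces are valid by construction, canonicalizes and deduplicates;
  it produces plausible small-molecule diversity for pipeline tests, not a
  realistic vendor catalogue.

The end-to-end dry run (`dry_run_pipeline()`) chains all of the above:
1000-molecule library, 400 simulated assays whose potency is driven by
three real descriptors plus log-normal noise, high-vs-low and
actives-vs-decoys models (dilution limited to what a 1000-molecule library
supports, ~1-2:1 with 2.5 sd windows; the dilution factor is a
configuration input of the protocol, not a constant), a three-model
cascade, synthetic docking of the 24 best survivors, calibration and
selection. Every stage is deterministic under the master seed.

## Numerical choices and degenerate inputs

* Range bounds use ±10³⁰ as open endpoints so filters serialize as plain
  JSON numbers.
* MCC returns 0 on zero denominators; the index replaces zero denominators
  by 0.5 percentage points before the cap.
* Tanimoto similarity of an empty fingerprint is 0 against everything
  (logged), 1 on the diagonal.
* Ties in descriptor rejection go to the lexicographically first name;
  diversity pruning visits records in mol_id order; structure ranking
  breaks ties by the secondary criterion, then id — all choices are
  deterministic so that reruns are bitwise reproducible.
* Untrainable labellings (an empty class), unreachable `mcc_min` (the best
  MCC found is reported), missing descriptors and absent listed residues
  raise errors that name the offender.

## Limitations

* Hydrogen-bond detection has no geometry beyond distance; strong/weak
  bonds and bifurcation are not distinguished, and π-stacking or cation-π
  interactions are subsumed under the 5 Å contact count.
* The descriptor set is intentionally small and 2D; models trained on it
  are not comparable number-for-number with models built on proprietary
  descriptor sets, and the package makes no attempt to reproduce any
  specific published MCC/AUC table.
* Protonation, tautomer and conformer handling belong to external tools;
  coordinates are consumed as-is.
* The weight-calibration stand-in explores the simplex randomly; with many
  components a local refinement or exhaustive grid may be preferable.
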