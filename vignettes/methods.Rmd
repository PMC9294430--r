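---
title: "Explaining missense variants on predicted protein structures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Explaining missense variants on predicted protein structures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(structvar)
```

## The problem

Most disease-associated human proteins have no experimental structure, but
deep-learning structure predictors (AlphaFold, RoseTTAFold) now produce
usable models with a per-residue confidence estimate (pLDDT, 0--100). Given
such a model, a multiple sequence alignment of the domain family, and the
outputs of standard site and effect predictors (ligand-binding probability,
protein--protein interface score, ddG of mutation, pathogenicity score,
disorder probability), one can ask, mutation by mutation: *is there a
structural or functional rationale for this variant being pathogenic?*

structvar implements that annotation procedure as a tested pipeline:

1. **Quality gating.** A domain is usable when its mean pLDDT is at least
   70 (RoseTTAFold reports 0--1; 0.7 is the equivalent and is rescaled to 70
   at parse time); an individual residue is usable when its own confidence
   passes the same gate. Verdicts are only rendered for gated residues.
   The gate is inclusive (`>= 70`): the sources of the rule print both
   "score of 70" and "lDDT > 70", and we resolve the ambiguity by using one
   inclusive rule everywhere, exposed as `conf_gate`/`conf_inclusive`.
2. **Functional-site proximity.** A mutation is "on or near" a site when its
   residue is a site member or has a site member within 5 Angstrom,
   measured as the minimum heavy-atom distance (hydrogens are discarded at
   parse time). Neighborhoods come from a cell-list search (grid cells of
   edge = radius, 27 adjacent cells scanned), which is exactly equivalent
   to brute force and linear-time in practice. Site classes: ligand-binding
   (predicted probability `>= 0.5`), interface (score `>= 0.34`, the
   operating point commonly used for meta-PPISP-style predictors; the
   cutoff is configurable because that tool's positive threshold is not
   standardized), and conserved positions.
3. **Conservation.** Column conservation is a Valdar-style weighted
   sum-of-pairs score over a BLOSUM62-derived similarity rescaled to unit
   diagonal, with a linear gap penalty: an identical column scores exactly
   1, an all-gap column 0. Conserved sites use a two-tier rule: tier 1,
   score `>= 0.8`; tier 2, score `> 0.65` with a tier-1 position within
   5 Angstrom (strict `<` for the tier-2 neighborhood, inclusive `<=` for
   site proximity; both switches are in the configuration). The tier-1
   threshold is quoted both as `>= 0.8` and `> 0.8` in the rule's sources;
   we use `>= 0.8` so the anchor set and the tier-1 set are one set.
4. **Stability and pathogenicity.** FoldX-convention ddG (positive =
   destabilizing) with the deliberately stringent rule ddG `> 1`
   (kcal/mol assumed; the threshold applies to whatever unit the input
   table carries); DynaMut2-convention ddG (`< 0` = destabilizing) is
   recorded as an agreement check but never enters the verdict, because the
   published accounting uses FoldX as the stability arbiter. Pathogenicity
   uses the MutPred2 decision threshold, score `> 0.611`.
5. **The verdict.** A mutation is *explained* iff it is near a ligand,
   interface or conserved site, or FoldX-destabilizing, or pathogenic.
   Burial (relative solvent accessibility `< 20`%, strict) is reported
   descriptively but is not an explanation channel on its own.
6. **Consensus.** With two models of the same domain, evidence is merged by
   (accession, position, mutant) over the models whose residue passed the
   gate; a mutation explained in the merge but not by the first model is an
   *additional* explanation. Models of one domain share numbering, so the
   paired-model RMSD uses CA atoms matched by residue number under Kabsch
   least-squares superposition (proper rotation enforced); no structural
   alignment search is needed or performed.
7. **Cohort contrast.** Disease vs polymorphism percentages (near site,
   destabilizing, buried, pathogenic) at both the mutation and the unique
   residue-position granularity, two-sided Mann--Whitney tests on
   pathogenicity, RSA and ddG (exact by enumeration when the pooled sample
   is at most 14 and tie-free, normal approximation with continuity and tie
   correction otherwise), and per-amino-acid composition enrichment of the
   mutant residues against a bundled SwissProt background with a seeded
   multinomial bootstrap p-value (no multiple-testing correction by
   default; a Benjamini--Hochberg option exists).

## Solvent accessibility

NACCESS-style accessibility is replaced by the Shrake--Rupley algorithm: a
deterministic Fibonacci sphere of `sasa_points` (default 960) test points
per atom at radius `r_atom + probe` (probe 1.4 Angstrom), with occlusion
tested against all atoms whose expanded spheres overlap. Van der Waals radii
are bundled (C 1.70, N 1.55, O 1.52, S 1.80); unknown elements fall back to
carbon with a warning. Relative accessibility divides the residue sum by the
Tien et al. (2013) theoretical maximum per residue type; the table is
swappable, and because NACCESS's empirical Gly-X-Gly normalization differs
by a few percent, RSA values near the 20% burial boundary can differ
between the two normalizations — a documented caveat, not a configurable
fix. An isolated atom reproduces the analytic sphere area to well under 1%
at the default point count, and totals change by less than 1% when the
quadrature is made 4x denser.

## Every threshold is configuration

All cutoffs live in one `default_config()` object (radius 5.0, conf_gate 70,
ligand_prob 0.5, interface_cut 0.34, foldx_cut 1.0, dynamut_cut 0.0,
patho_cut 0.611, rsa_cut 20, cons_high 0.8, cons_mid 0.65, disorder_cut 0.5,
high_disorder 40, scorecons percent threshold 0.9), together with the
boundary-inclusivity switches. Stage code contains no hard-coded thresholds:
these cutoffs *are* the analysis, and they must be auditable and
overridable. The percent-scorecons threshold (0.9) and the DOPs formula
(100 x distinct column scores rounded to 2 decimals / columns) are our own
concrete choices where the upstream definitions are loose; both are flagged
as approximations of the CATH-style metrics.

## The synthetic cohort: what it emulates, and what it does not

Real inputs (AlphaFold DB models, humsavar variant tables, predictor runs on
553 proteins) cannot be bundled or downloaded in a test environment, so the
generator produces complete input bundles with *stored ground truth*:

* **Structures**: ideal-geometry backbones (CA--CA 3.8 Angstrom; helix,
  antiparallel strand pair, or a compact self-avoiding walk) with N, C, O,
  CB pseudo-atoms. The compact coil's confinement radius is set so roughly
  a fifth of residues are buried (RSA < 20), the burial background typical
  of globular domains. Confidence has a high core (N(85, 5^2)) and low
  termini (N(55, 8^2)), clipped to [0, 100].
* **Second models**: a random rigid motion plus Gaussian noise rescaled to
  hit a target CA RMSD (default 1.7 Angstrom, a typical distance between
  two good independent predictions of one domain), tagged rosettafold-like
  and written on the 0--1 confidence scale so the rescaling path is
  exercised. Confidences are rounded without crossing the 70 gate, so both
  models gate identically and consensus differences are purely geometric.
* **Alignments**: planted conserved columns are invariant (score exactly
  1); other columns mutate at the rate implied by the target mean pairwise
  identity (default 0.45).
* **Predictors**: planted ligand/interface sites score clearly above their
  thresholds, elsewhere clearly below; disease-class ddG is shifted by
  +1.5, pathogenicity is Beta(5, 2.4) vs Beta(2, 3) — parameters chosen
  once so the class percentages fall in the ranges typical of published
  disease-vs-polymorphism contrasts (roughly 60 vs 40% near sites, 40--60
  vs 20--30% buried, 60--70 vs 15% pathogenic).
* **Placement**: disease mutations land within 5 Angstrom of a planted site
  with probability 0.6 (polymorphisms 0.4) and at a buried residue with
  probability 0.6; when no buried residue is available in the eligible
  pool the most buried one is taken, so the burial tendency is preserved
  rather than silently dropped. Sites are seeded at exposed residues
  (RSA >= 30) because ligand pockets and interfaces are surface features;
  this also keeps the burial and proximity effects independent.
* **Ground truth** is computed at generation time by direct rule
  application — plain pairwise distances and threshold comparisons,
  sharing no code with the cell-list/annotation path — and stored as a
  sidecar table. In noiseless mode every generated value keeps a clear
  margin from its decision threshold and non-planted alignment columns are
  forced to high variability, so pipeline verdicts must equal the stored
  labels exactly; with noise, realized conservation can drift across the
  0.65 tier-2 threshold and small disagreements are legitimate.
* **Determinism**: one global seed fans out to per-protein seeds as
  `(seed * 1000003 + i * 7919) mod (2^31 - 1)`, so bundles are stable when
  the protein count changes, and identical seeds give byte-identical
  bundles, verdict tables and manifests.

What passing tests on this cohort shows: the decision rules, gates,
geometry, accessibility, conservation and statistics are implemented
exactly and reproducibly. What it does not show: anything about real
predictor accuracy, real effect sizes, disordered-region behavior beyond a
confidence profile, or side-chain packing — synthetic structures have
idealized pseudo-atoms, synthetic predictors are planted, and the
generator's class contrasts are design choices, not estimates.

## Numerical choices and degenerate inputs

* Distances on the 5 Angstrom boundary: site proximity is a closed ball
  (`<=`), the tier-2 conservation neighborhood is open (`<`), both
  switchable; generated coordinates make exact boundary hits a measure-zero
  event.
* Kabsch superposition uses SVD with the reflection fix
  (`det(R) = +1` always); collinear and rank-deficient inputs are allowed.
* Quality means are plain arithmetic means over segment residues; an empty
  segment is an error, not a silent `NaN`.
* Missing per-mutation predictor entries leave the corresponding flag
  `FALSE` and are counted in a message, never silently imputed.
* Zero-variance correlation input yields `NA` with a warning.
* Mann--Whitney switches from the exact enumeration to the corrected normal
  approximation exactly when ties appear or the pooled size exceeds 14.
* Bootstrap p-values use an add-one correction, so they are never 0.
* Mutation records with identical wild and mutant residues are rejected
  with a warning (not an error); unknown categories are fatal after alias
  mapping (`LP/P`, `LB/B`, `US`).

## Problem sizes used by the validation suite

The shipped tests run the full pipeline on cohorts of 20 proteins of
90--130 residues with 200 + 200 mutations (the generator's default study
conditions) for the ground-truth-recovery and class-contrast checks, and on
smaller 2--6-protein bundles for interface-level checks; the neighbor-search
equivalence check uses 100 structures of 30--200 residues at radii 3, 5 and
8 Angstrom. These sizes were chosen as the smallest at which the planted
contrasts are unambiguous.

## Known limitations

* Single chain, one domain segment per run; no mmCIF, no assemblies.
* Only predicted confidence is consumed; the pipeline never recomputes
  lDDT between models.
* The conservation scorer is a faithful Valdar-style implementation, but
  "scorecons" in the wild has several variants; the scorer sits behind one
  interface precisely so it can be swapped.
* DOPs here is a distinct-score fraction, an approximation to the CATH
  notion of the same name.
* The Mann--Whitney observation unit (per mutation vs per position) is a
  genuine degree of freedom in this kind of analysis; both modes are
  provided (`mode` argument of `compare_cohorts()`), per-mutation being the
  default.
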