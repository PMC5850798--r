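---
title: "Methods: anatomical enrichment and duplicate-gene retention after whole-genome duplication"
author: "ohnologR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: anatomical enrichment and duplicate-gene retention}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ohnologR)
```

## Scope

Vertebrate genomes carry the traces of three ancient whole-genome
duplications: two rounds at the base of vertebrates ("2R") and a third,
teleost-specific round ("3R"). Most duplicates were subsequently lost; the
genes retained in two copies ("ohnologs") are a highly non-random subset.
ohnologR implements the computational machinery needed to ask *which* gene
properties predict retention: anatomical-ontology expression enrichment
with decorrelation, phylogenomic classification of ohnologs, singletons and
small-scale duplicates from event-annotated gene trees, Akashi's test for
translational-accuracy selection, and equal-frequency bin regression of
retention rate on gene covariates. Because the original inputs are large
curated resources (expression databases, genome-wide gene-tree sets), every
analysis here is exercised on synthetic data with planted ground truth; the
generators are first-class, tested package code.

## Anatomical ontology and annotation propagation

The ontology is a DAG of anatomical terms with `is_a` and `part_of` edges
(`parse_obo()`, `ontology_graph()`). Expression annotations are propagated
to all ancestors over both relations (`propagate()`): a gene detected in the
hindbrain is also expressed in the brain. Both relations participate because
anatomical parthood carries expression the same way subclassing does; other
relation types (e.g. `develops_from`) are dropped at parse time with a
warning — propagating them would conflate a precursor's expression with its
derivative's, so they are excluded by default and would need to be encoded
as one of the supported relations to opt in. Only terms with at least five
annotated genes after propagation are tested (`testable_terms()`), counting
distinct genes, not annotation records.

Reference structure lists are resolved set-algebraically
(`build_system_list()`): the *strict* nervous-system list is the descendant
set of the nervous-system root minus the sensory system's descendants; the
*broad* list adds sensory, presumptive-neural and other configured roots via
the `additions` mechanism. Species-specific extension terms are supplied
through configuration rather than hard-coded identifiers.

## Enrichment testing and decorrelation

Each testable term is tested with one-sided hypergeometric (Fisher) tests in
both directions — enrichment as the upper tail, depletion as the lower — and
each direction is FDR-corrected separately (Benjamini–Hochberg via
`stats::p.adjust`), with 10% as the reporting threshold. Expected counts and
folds always come from raw counts:

\[
  \mathrm{expected} = K \cdot \frac{|FG|}{|REF|}, \qquad
  \mathrm{fold} = \frac{\mathrm{observed}}{\mathrm{expected}},
\]

where \(K\) is the term's annotated-gene count in the reference.
Propagation makes parent and child tests strongly dependent; two
decorrelation algorithms are provided:

* **elim** — terms are processed deepest-first; when a term's p-value falls
  below the elimination cutoff (default 0.01), its annotated genes are
  removed from all its ancestors before those are tested. The cutoff is a
  known free parameter of the published elim contract; 0.01 is the
  conventional default and `elim_cutoff = 0` recovers classic exactly
  (no elimination ever fires).
* **weight** — terms hold per-gene weights (initially 1) and are tested on
  contingency tables of weight sums; a child more significant than its
  parent down-weights the shared genes in the parent and all ancestors by
  the p-value ratio, after which the parent is re-tested; a less significant
  child is itself down-weighted by the inverse ratio. Weighted cells are
  rounded to the nearest integer before testing so the statistic remains an
  exact hypergeometric tail; a continuous (non-central hypergeometric)
  alternative would avoid the rounding but forfeit exactness, and at the
  planted effect sizes used here the rounding never changed a ranking.

On an edgeless ontology both algorithms reduce to classic exactly, which the
test suite asserts to machine precision. Ties in p-value are broken by term
id so output order is deterministic.

Overrepresentation of a structure list among enrichment hits
(`overrepresentation_test()`) uses a two-sided Fisher exact p-value and
reports the *sample* odds ratio ad/bc (infinite when bc = 0) rather than the
conditional MLE, matching how such odds ratios are conventionally quoted.

## Gene-tree classification

Trees arrive as Newick/NHX with per-node event type (`D=`), taxon (`S=`) and
duplication confidence (`B=`/`SIS=`, 0–100 mapped to [0, 1]). "High
confidence" is strict: a score of exactly 50 is not confident. The 3R rule
requires a basal speciation node at the pre-duplication level (Neopterygii,
with a gar-like outgroup), a high-confidence duplication at Clupeocephala,
two Clupeocephala speciation children, and exactly one focal-species gene
per subtree with no duplication node on the path to it. Absence of
duplication-and-loss on the focal path is operationalised purely
topologically (one focal leaf, no duplication on the path); detecting losses
elsewhere would require a species-tree reconciliation that the input trees
do not carry. Singletons show a single clean Clupeocephala speciation
instead. The 2R rule allows one or two nested duplication rounds at
Vertebrata (Euteleostomi when no lamprey gene is present), requires at least
two fish species per post-duplication subtree, and *ignores* zero-confidence
duplication nodes on the mammalian path — dense mammalian trees are full of
dubious topology-inconsistency duplications, and treating them as real would
disqualify essentially every tree. Polytomies yield `unclassified` with a
`polytomy` trace, as the rules assume binary event nodes. Small-scale
duplicates are focal paralog pairs under a dated high-confidence duplication
whose pairwise identity lies in [10%, 100%): 100% identity pairs are
probable assembly artifacts, sub-10% pairs probable gene splits.

Every unclassified gene carries a rule trace naming the first failed
condition, which the synthetic generator exploits: each corrupted tree
violates exactly one condition, so classification can be checked label *and*
trace against planted truth.

## Akashi's test

For a pairwise codon alignment (focal species vs a close comparator), sites
are *conserved* when both codons encode the same amino acid (synonymous
differences still count as conserved), *variable* when both encode different
amino acids, and excluded on gaps, `N`s, stops and the terminal codon. Per
amino acid with a defined preferred-codon set, a 2×2 stratum counts focal
codons by (conserved/variable) × (preferred/unpreferred). The association is
summarised by the Mantel–Haenszel stratified odds ratio

\[
  \Psi = \frac{\sum_i a_i d_i / n_i}{\sum_i b_i c_i / n_i}
\]

and the Z score \((\sum_i a_i - \sum_i E_i)/\sqrt{\sum_i V_i}\) with
hypergeometric mean and variance per stratum. Laplace smoothing (pseudocount
1 per cell) is applied, by default *only to strata containing a zero cell*:
smoothing exists to keep \(\Psi\) finite, and smoothing every stratum
unconditionally shrinks the Z statistic enough to make the null test
noticeably conservative at per-gene stratum sizes (measured rejection of
|Z| > 1.96 at nominal 5%: roughly 3% with unconditional smoothing, on-target
with conditional smoothing). `smooth = "all"` restores unconditional
smoothing for sensitivity analysis; increasing the pseudocount pulls \(\Psi\)
monotonically toward 1.

The synthetic codon model plants a per-site 2×2 odds ratio: given the
conservation rate \(r\), marginal preferred-codon frequency \(q\) and target
\(\psi\), the preferred-use probabilities at conserved and variable sites
are solved numerically from
\(r p_c + (1-r) p_v = q\), \(\mathrm{odds}(p_c) = \psi\,\mathrm{odds}(p_v)\).
Defaults — 500 codons per gene, conservation rate 0.7, \(q = 0.5\), eight
two-codon amino acids — give informative strata of a few dozen sites each:
long enough for per-gene \(\Psi\) to be nearly unbiased, while a mouse–rat
level of conservation (~0.93) would leave so few variable sites that any
smoothing dominates. The null calibration runs at 200 codons per gene. The
generator makes no attempt at realistic sequence evolution; it reproduces
only the conserved-site × preferred-codon association structure the test
consumes, so passing tests validate the statistic, not a substitution model.

## Retention analyses

Genes are sorted into `k` equal-frequency bins (sizes differ by at most one;
ties broken by gene id) and the per-bin proportion of the retained class is
regressed on the per-bin median covariate (`bin_regression()`), giving the
slope ("Beta"), a two-sided t-test p-value on k−2 degrees of freedom and
R². dN is log10-transformed before binning, dropping non-positive values
with a logged count (a pairwise dN of exactly zero carries no rate
information). The linear-vs-log-linear contrast (`compare_bin_models()`)
picks the transform with the higher R² on the same k points; AIC is
available as an alternative criterion and agrees at these sample sizes.
A gene counts as a nervous-system gene when it has at least one propagated
annotation to a broad-list structure; the exclusive variant (expressed in
no non-nervous structure) is a flag on the caller's side.

`tissue_ranking()` computes, per sample, the fraction of ohnolog-orthologs
among the *reference* genes called present — the reference being only
orthologs of ohnologs and of singletons, so the proportion is a retention
read-out, invariant to genes outside the reference. Tissues are ranked by
the mean over their samples. `rnaseq_present_calls()` scans candidate TPM
thresholds (0 and every observed value) for the smallest one at which the
fraction of intergenic regions called present is at most 5% of the fraction
of coding genes called present; ties at the threshold are present. Protein
complex annotations resolve to the most dosage-sensitive category:
hetero-multimer > hetero-dimer > uncharacterized > homo-multimer > monomer.

## Synthetic-data design

All generators are pure functions of a `synth_config()` (seed included):
re-running with the same configuration is byte-identical, and the caller's
RNG stream is left untouched. Ontologies use a complete 3-ary tree backbone
plus random extra parents (1–2 parents per term, extra parents drawn from
internal terms only). The backbone guarantees every internal term at least
two children; with single-child chains an ancestor's propagated gene set
can equal its child's exactly, making parent and child statistically
indistinguishable — no enrichment algorithm can then put the planted leaf
strictly first. The planted class (40 of 1000 genes) is annotated to the
enriched leaf at fold × base rate (default 5 × 0.08); all other gene–leaf
pairs at the base rate. Gene trees are drawn from explicit topology
templates per family (3R ohnolog/singleton; 2R with/without lamprey, one or
two duplication rounds, zero-confidence mammalian-path duplications; SSD
with sampled identity), with at most one tagged corruption per tree.
Expression calls use detection probabilities p1 = 0.6 (matching class and
tissue) vs p0 = 0.3; TPM tables are log-normal with coding centred at
10 TPM and intergenic at 0.1 TPM. The covariate generator plants a logistic
retention model in which low dN, high Psi and high maximal nervous
expression each raise retention probability — for nervous-system genes
only, so the nervous vs non-nervous contrast holds by construction.

What the generators do *not* emulate: annotation bias across structures,
correlated expression between related tissues, phylogenetic correlation
among genes, or realistic codon evolution. Passing tests therefore
demonstrate correctness of the algorithms under the stated statistical
structure, not that real-data effect sizes would be reproduced; the
published genome-scale regression coefficients depend on curated inputs
outside this package's scope.

## Problem sizes and numerical choices

The shipped validation suite runs enrichment recovery at 1000 genes × 50
terms over 20 seeds, classification on 500 trees, Akashi calibration at
1000 genes × 200 codons (null) and 200 genes × 500 codons (recovery), and
bin-regression recovery at 5000 genes × 100 seeds — sizes chosen so every
planted effect is detected with comfortable margins while the whole suite
runs in well under a minute per module. Deterministic tie-breaks (term id,
gene id) make every ranking reproducible. Degenerate inputs are handled
explicitly: genes with no informative Akashi stratum are flagged `NA` and
excluded from binning, samples with no expressed reference gene are dropped
with a warning, and an unattainable present-call ratio yields all-absent
calls with a warning rather than an arbitrary threshold.
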