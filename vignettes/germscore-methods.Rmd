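---
title: "germscore: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{germscore: models, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The scientific problem

Mutations can be pathogenic in somatic cells (cancer) and in the germline
(genetic disease), and the two mutational spectra overlap. `germscore`
operationalises one specific form of that overlap: the number of cancer
patients carrying somatic mutations in a gene — its *total somatic mutations*
(TSM) — is treated as an in-vivo readout of how compatible mutations in that
gene are with cellular viability, and combined with the gene's evolutionary
age (a proxy for functional relevance) and 81 genomic/epigenomic covariates
to predict whether germline mutations in the gene produce abnormal
phenotypes. The binary response, *involvement in phenotypic abnormality*
(IPA), is derived from a phenotype ontology: a gene is involved if it is
annotated to the ontology root for abnormal phenotypes or any descendant —
after removing all annotations inside the neoplasm subtree, because for
cancer phenotypes an overlap between somatic and germline mutation sets is
expected a priori and would be circular evidence.

## Annotation propagation and the neoplasm exclusion

Annotations are propagated by the true-path rule: a gene directly annotated
to a term is implicitly annotated to every ancestor. The exclusion is applied
*before* propagation: every (gene, term) pair whose term lies at or below the
designated neoplasm-like root is deleted, and only the surviving pairs are
closed under the ancestor relation. A gene annotated only to a glioma-like
term therefore never reaches "abnormal nervous system morphology", but keeps
that ancestor if it is also annotated to a non-neoplastic descendant of it.
`expand_annotations()` is idempotent and monotone in its input, and the test
suite checks it pair-for-pair against a brute-force delete-then-close oracle
on random DAGs.

Terms without a trained model are mapped to the *closest scored ancestor*.
For multi-parent
DAGs "closest" needs a definition; we chose minimal upward edge distance by breadth-first search over
parent edges, with ties broken by larger associated-gene count and then by
lexicographic term identifier so that the mapping is deterministic. A
semantic-similarity notion of closeness would be an alternative; edge
distance was chosen as the least-assumption reading, not as inferred intent.

## The feature table

* **TSM** counts *patients*, not mutation records: a patient contributes at
  most once per (gene, tumor type), and only the nine recognised variant
  classes count; `protein_changing` mode further drops `Silent`. The
  headline variable sums patient counts over tumor types; the `mean_rate`
  variant divides per-cohort counts by cohort size and averages with equal
  weight, which reweighs small cohorts (a robustness toggle, selectable in
  the pipeline configuration).
* **Age** is a 20-level ordered variable (phylostratum); it enters models
  either as a standardized numeric predictor or as a 20-level categorical.
* **Interval features** (DNase, histone marks, lamin B1, repeats) are merged
  before intersection, so overlapping track entries are never double
  counted; coordinates are 0-based half-open throughout (BED convention).
* **Signal features** (replication timing, nucleosome, transcription,
  recombination) are base-weighted means over the covered part of the
  region within each cell line, then equal-weighted means across cell
  lines. Base-weighting over covered bases
  (rather than interval-weighting) is our choice of average. Cell lines
  with no coverage are dropped;
  a gene covered by no cell line gets a missing value and is later deleted
  listwise (never imputed).
* **Trinucleotide frequencies** use overlapping width-3 windows on the gene
  strand; windows containing non-ACGT characters are skipped and the
  denominator reduced, so the 64 frequencies always form a distribution.
* **PCA**: the `TTT` frequency is dropped (it is exactly collinear with the
  other 63 frequencies), the remaining 80 features are standardized, and
  all 80 principal components are retained — the rotation removes
  collinearity without discarding variance. The dropped column is fixed to
  `TTT` rather than auto-detected, so the retained column set is identical
  across datasets and runs.

## Models and validation

Statistical significance comes from univariable and multivariable logistic
regression with odds ratios per one standard deviation and Wald 95%
confidence intervals. Complete or quasi-complete separation is detected and
reported as an error rather than returning a divergent estimate; rank
deficiency names the aliased columns.

Predictive performance comes from a pluggable classifier bench under nested
cross-validation: 10 stratified outer folds, hyperparameters tuned on 3
inner folds by grid search maximizing AUROC, random oversampling of the
minority class applied strictly inside training partitions (the test suite
asserts that oversampled training indices never intersect test rows).
Stratification is our choice; it preserves
prevalence in small per-phenotype models. The confidence interval on the
mean AUROC is a normal approximation over fold values. Default grids are
deliberately small so that nested CV stays desk-scale while still
exercising the machinery: random forest {trees 100/300, depth none/10,
min leaf 1/5}, logistic ridge {4-point log grid of L2 strength}. The two
mandatory paradigms (logistic, random forest) ship built in;
`register_paradigm()` accepts others.

Per-phenotype models are trained for every term with at least 100 associated
genes (the threshold is exact: 100 retained, 99 discarded). Each term's
AUPRC gain is computed against that term's own prevalence baseline. The
recorded per-gene probabilities are *out-of-fold* predictions, so downstream
rank transforms are leakage-free; the default per-term configuration is a
single random-forest setting (100 trees, minimum node size 10) without inner
tuning, which keeps a multi-term training run desk-scale — pass a multi-row
grid to re-tune per term. For the temporal holdout,
re-tuning on the training portion is supported via the same grid argument.

Temporal holdout emulates annotation growth: genes gaining involvement
between two releases are the test positives; negatives are sampled from
never-positive genes either to parity (balanced) or to a configured positive
fraction (default 22%, the real-data prevalence); all remaining genes train
a fresh model on the old labels.

## Disease scoring

Per-phenotype probabilities are rank-transformed so the highest probability
gets rank 1, normalized by the number of genes to (0, 1]. Two direction
conventions are possible; rank 1 = highest probability is the one under
which true associations concentrate at *low* scores, which is what the
low-score enrichment analysis presumes, and normalizing by N keeps the
scores on a common (0, 1] scale across phenotypes.

A disease's score for a gene is the geometric mean of the gene's normalized
ranks over the disease's phenotypes (after closest-scored-ancestor mapping;
duplicates after mapping are collapsed; phenotypes with no scored ancestor
are dropped with a warning rather than scored at the root). The null
distribution permutes the gene column of the gene–disease association list,
preserving per-disease association counts and the global gene multiset; 100
permutations by default, each independently seeded. Scores are binned into
20 equal-width intervals and each bin's empirical p-value uses the add-one
correction, (1 + #{null counts ≥ observed}) / (1 + #permutations), so p is
never zero with finite permutations; bins with p < 0.01 are flagged, and the
aggregate count of scores below 0.15 is tested the same way. Among the
candidate randomization schemes (permute the gene column, permute diseases,
redraw genes uniformly), gene-column permutation was chosen because it
preserves both marginals of the bipartite graph.

## The synthetic data generator

The generator emulates the structure of every real input with planted truth:

* a random rooted DAG whose non-root terms draw 1–2 parents within their
  branch (acyclic by construction), with a designated neoplasm-like subtree
  holding ~15% of terms by default and sharing no edges with the rest;
* log-normal gene lengths and negative-binomial per-tumor
  patients-with-mutation counts with mean proportional to length — this
  plants the length confounding that makes the multivariable correction
  meaningful; dispersion 0 recovers Poisson; 33 tumor cohorts by default;
* a 20-level age skewed towards old genes; 16 continuous features with
  configurable equicorrelation (fraction-type features mapped through the
  logistic into [0, 1]); CDS strings with per-gene random composition whose
  trinucleotide frequencies are computed by the production counter, so the
  generated feature table satisfies the same invariants as real data (the
  alternative — drawing all 80 features from a multivariate normal — cannot
  satisfy the frequencies-sum-to-one invariant);
* labels from the logistic model `plogis(b0 + log(OR_tsm)·z(TSM) +
  age_effect·(age − mean))` with the intercept solved for a target
  prevalence of 22.75% (the real-data positive fraction); defaults plant
  OR 1.9 per SD for TSM — the magnitude reported for this association in
  real cancer cohorts, used here as simulation truth, not as a claim of
  reproducing any cohort estimate — and 0.1 log-odds per age level;
* positives annotated to 1–5 non-neoplastic leaves; 10% of genes receive
  additional neoplasm-subtree annotations so the exclusion rule is
  exercised; by construction the planted label equals root membership after
  exclusion and expansion, which the tests assert;
* disease catalogs whose causal genes are drawn with probability
  proportional to softmax(sharpness × mean model probability over the
  disease's phenotypes); sharpness 0 is an exact null.

What the generator does *not* emulate: realistic ontology topology,
mutational signatures, genome coordinates on a real build, or inter-term
correlation of model probabilities. The last point matters for interpreting
the disease-score tests: the permutation null only has power when causal
genes are specific to their disease's phenotype ranking, so the enrichment
tests feed the scorer per-term independent probabilities. When all terms
share one global ranking (as happens when per-term models learn the same
global signal from identical features), permuting genes among associations
preserves most of the signal and enrichment is correspondingly weak — on
real data the per-term models differ because the annotation sets differ.

Passing tests on this generator therefore demonstrate correctness of the
machinery and recovery of planted effects under the stated noise model; they
do not certify performance numbers on any real cohort, which depend on
versioned external datasets.

## Problem sizes and numerical choices

The test suite runs at the following sizes, chosen to finish a full run on a
single CPU in well under half an hour while keeping every check at its
stated power: odds-ratio recovery at the full study scale of 18,170 genes ×
500 replicates; null calibration of the nested CV at 1,000 genes (the
calibration of a rank statistic does not depend on n) and of the
multivariable fit at 2,000 genes × 200 replicates; signal-detection at 5,000
genes × 50 replicates with a 100-tree importance forest; temporal-holdout
consistency at 3,000 genes × 50 replicates with the logistic paradigm;
disease-score null and signal at 400 genes, 12 scored terms, 100
randomizations, 200 and 50 pipeline replicates respectively; end-to-end
determinism at 2,000 genes. The acceptance script runs the full pipeline at
2,000 genes with 5-fold per-term CV and reports all headline quantities.

Other numerics: geometric means are computed as `exp(mean(log(x)))`; AUROC
uses midranks (ties get half credit); AUPRC integrates stepwise over
distinct thresholds; equicorrelated normals use the closed-form square root
`sqrt(rho)·z0 + sqrt(1−rho)·Z`; all stochastic steps take explicit seeds,
random forests run single-threaded with a fixed seed, and two runs with the
same configuration are byte-identical on every TSV output.

## Known limitations

* Real-mode feature extraction expects pre-downloaded tracks in plain
  BED/bedGraph/FASTA/TSV dialects; downloading or refreshing external data
  is out of scope, as are liftover and canonical-transcript selection
  beyond a longest-CDS fallback.
* The bench bundles logistic ridge and random forest; further paradigms
  (support vector machines, boosting variants, naive Bayes) plug in through
  `register_paradigm()` but are not bundled with tuned grids.
* Patient identity in a MAF defaults to the full sample barcode; TCGA-style
  truncation to the patient barcode is available as an option.
* Pathway/GO enrichment of score bins is out of scope.
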