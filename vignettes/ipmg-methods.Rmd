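---
title: "Discovering immunotherapy prognostic marker genes: models and methods"
author: "IPMGfinder"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering immunotherapy prognostic marker genes: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Immunotherapy helps only a subset of cancer patients, and single-trial
cohorts are too small to find expression markers of who benefits.
`IPMGfinder` implements a pan-cancer strategy: pool immunotherapy-treated
patients across cancer types under the assumption that the response is
driven by the state of the tumor immune microenvironment rather than the
tissue of origin, correct the bulk expression table for two confounders
(somatic loss of protein function, and immune-cell admixture), screen
every gene for an immunotherapy-specific survival association, and distill
the result into a small panel of immunotherapy prognostic marker genes
(IPMGs) that feed a survival-status classifier, a patient-stratification
scheme and a local SNP association scan.

Because the real pan-cancer inputs are large controlled-access resources,
the package ships a synthetic cohort generator with planted ground truth;
every claim the test suite makes is a statement about recovering planted
structure, not about reproducing any published cohort's numbers.

# Expression preparation

Missing values are imputed by the gene's mean within the same cancer type
(global gene mean as fallback when a type is entirely missing); genes
below an expression floor of 1 in every sample are dropped; the table is
`log2(x + 1)` transformed and quantile normalized.

Two conventions are deliberate choices. The log transform uses a +1
offset: the inputs are non-negative abundance estimates and zero cells
are legitimate, so a plain `log2` would produce `-Inf`. Quantile
normalization resolves ties by the mean of the tied rank range
(the dominant convention; verified in the tests against
`limma::normalizeQuantiles(ties = TRUE)`), so after normalization the
sorted value vectors of any two samples agree exactly up to tie groups.

# Mutation correction

The functional output of a mutated gene is often lower than its mRNA
level suggests. The correction estimates, per gene and sample, a protein
*activity score* in [0, 1] and multiplies the normalized expression by
it. The machinery is built on trinucleotide substitution categories: a
single-nucleotide substitution is keyed by its reference and alternate
base plus the immediate 5' and 3' neighbors, giving 12 x 16 = 192
categories. (A 96-category strand-collapsed view, where each purine
reference key is folded onto its reverse complement, is available via
`collapseCategories()` but is not the default.)

1. **Background frequencies.** Within each cancer type, observed SNVs
   are counted per category and divided by the type's total, yielding
   per-type background frequencies `p` (and `p'` for synonymous use).
2. **Codon backgrounds.** Each codon admits nine single-base changes.
   Every change is classified as synonymous or non-synonymous by the
   standard genetic code (changes to a stop codon count as
   non-synonymous), and its category frequency is looked up in the
   codon's genomic context. Summing gives the per-codon expectations
   `n_i` (non-synonymous) and `s_i` (synonymous), and the per-gene sums
   `N_j` and `S_j`. A trailing stop codon is excluded; an internal stop
   or a length not divisible by three is an error naming the gene.
3. **Selection and significance.** With the per-type observed counts
   `C_j` (non-synonymous) and `C'_j` (synonymous), the regularized ratio
   `dN/dS = (C_j/N_j + 1) / (C'_j/S_j + 1)` is 1 for unmutated genes by
   construction. A gene is called significantly mutated in a type when a
   one-sided binomial test of `C_j` successes in `C_j + C'_j` trials
   against `N_j/(N_j + S_j)` gives p < 0.05 *and* dN/dS > 1; the final
   set is the union over types.
4. **Codon indexes and activity scores.** For each mutated codon of a
   significant gene, `r` is the sample-weighted pan-cancer frequency of
   the observed category (per-type frequency times per-type sample
   count, summed over types) and `T` the pan-cancer non-synonymous event
   count at the codon; the raw index `I = r/T` is min-max scaled to
   [0, 1] across all tabulated codons. A sample's activity score for a
   gene is the product of the scaled indexes of its mutated codons; no
   mutation gives 1, and any frameshift or splice-site event gives 0.

Choices where the procedure admits more than one reading: when several
distinct categories are observed at one codon, `r` is their
event-weighted mean (unbiased pooling); the min-max scaling population is
global across all tabulated codons (a per-gene alternative exists behind
the same table); only frameshift/splice-site events zero the score —
nonsense SNVs count as ordinary non-synonymous changes; scores multiply
the *normalized log-scale* expression, the literal reading of
"multiply the score with the expression value"; and activity scores are
computed only for the significantly mutated genes, the stated aim of the
correction. Rows whose trinucleotide context cannot be resolved still
contribute to `C_j`/`C'_j` but not to category frequencies — counts do
not need contexts, frequencies do.

# Leukocyte fraction correction

Bulk expression of an immune gene scales with how many immune cells are
in the biopsy. A gene is called immune-related when its expression
correlates positively with the leukocyte fraction (Pearson r >= 0.3) and
negatively with tumor purity (r <= -0.3) across all samples; the same
magnitude is used on both sides because a single cutoff is stated for
the procedure. Immune-gene expression is divided by the leukocyte
fraction, floored at 0.01 — near-zero fractions would otherwise inflate
a handful of samples without bound.

# The survival screen

Survival times are administratively censored at 3 years (long-horizon
deaths are dominated by non-cancer causes, and the cap keeps enough
survivors in the analysis). For each gene, the top and bottom
`floor(0.30 n)` samples per cancer type (minimum 1, types with fewer
than 4 filtered samples skipped) are pooled into high/low groups —
stratifying by type prevents cancer-type expression differences from
masquerading as survival signal. Expression ties break by sample id, and
the low group is the tail of the same descending ordering, so groups are
deterministic and never overlap.

The two groups are compared by a one-tailed log-rank test: with `z` the
signed log-rank statistic (positive when the high group dies more than
expected), the high-worse p-value is `P(Z >= z)` and the high-better
p-value its complement. Screening all genes yields two ranked lists
(better/worse), ordered by ascending p with gene-id tie-breaks. The
log-rank core is a small compiled kernel that evaluates thousands of
group assignments in one pass; the tests pin it to
`survival::survdiff` to 1e-6.

# Pathway enrichment and the specificity null

Pre-ranked GSEA uses the ranking statistic `-log10(p)` (descending) and
the weighted Kolmogorov–Smirnov running sum with hit-weight exponent 1;
the enrichment p-value is a gene-permutation Monte-Carlo estimate with
the +1/+1 estimator (`p = (1 + #{null ES >= ES}) / (1 + B)`), sharing
one null per distinct set size. Pathway collections read from GMT drop
sets whose names match "cancer" or "disease" — such sets track general
tumor status, the very confounder the analysis controls.

A pathway associated with survival among immunotherapy patients may
simply track tumor aggressiveness. The specificity test therefore draws
`B` random subsamples of non-immunotherapy patients of the same size as
the immunotherapy arm, reruns the *whole* genome screen once per
resample (never per pathway), and collects each pathway's GSEA p on
every null ranking. A pathway is immunotherapy-specific when its
observed p falls below the 5th percentile of its own null distribution
— the per-pathway null also absorbs the correlation of member genes,
which inflates gene-permutation GSEA p-values for co-expressed sets.

The quantile–quantile construction offers a stricter visual check: the
pathway's sorted gene p-values are compared against the 95th-quantile
significance envelope (the 5th percentile on the p scale, i.e. the 95th
quantile of `-log10 p`) of (a) random same-size gene draws from the
immunotherapy p list and (b) the pathway's own genes across the
non-immunotherapy resamples. A pathway passes when it beats both
envelopes over most positions; a random gene set cannot.

# Feature selection, the panel, and the classifier

Each candidate pathway is scored per patient by single-sample GSEA
(rank-weighted ECDF difference, exponent 0.25, no per-sample range
normalization; invariant to any monotone transform of a patient's
profile). A random survival forest (log-rank splitting, permutation
importance, `ranger` backend) ranks the pathway scores against survival
capped at 1 year; per-feature p-values come from refitting on
response-permuted data (Altmann scheme, 100 refits by default, p < 0.05
selects). Pathways selected under *both* corrections are intersected;
their member genes with a one-tailed screen p < 0.05 under either
correction become candidate IPMGs, ordered by importance.

The classifier predicts 1-year survival status (deceased = event within
365 days, alive = followed at least 365 days, earlier-censored patients
excluded). For each panel size in the sweep (64, 50, 40, 30, 20, 10 by
default), patients split 2/3 : 1/3 stratified by label; the training
split is balanced by SMOTE (synthetic minority points drawn uniformly on
segments to one of the 5 minority nearest neighbors — every synthetic
point lies in the minority convex hull); an elastic-net logistic
regression (mixing 0.5, penalty by internal 5-fold cross-validation
maximizing AUC and repeated over three fold assignments with averaged
predictions, because a single penalty choice on ~100 training points is
unstable; `glmnet` backend) is fitted; and metrics are averaged
over balanced validation subsets (all deceased plus an equal-size random
draw of alive patients, 1000 draws by default). The classifier features
are the *uncorrected* normalized expression of the panel genes: a panel
meant for external cohorts cannot assume mutation calls or leukocyte
fractions are available.

# Patient stratification

All patients are scored by ssGSEA on the IPMG panel and cut into k = 3
groups at the score boundaries that split the immunotherapy-treated
patients equally (remainders to the higher-score groups; ties resolve by
patient id). The immunotherapy arm's k-group log-rank p is contrasted
against 5000 resamples (500 in the scaled test runs) that draw, per
group, the same number of non-immunotherapy patients: a panel that
captures immune state separates survival among treated patients but not
among controls, so the report shows the immunotherapy p, the median
control p, and the fraction of control p's smaller than the
immunotherapy p. For characterization, the best-surviving group (highest
Kaplan–Meier survival at 3 years among treated patients) is compared
with the worst by a one-tailed Mann–Whitney test per gene, and the
resulting ranking feeds pre-ranked GSEA.

# SNP association

SNPs within 100 kb of a panel gene body with minor allele frequency
>= 5% are tested one at a time by a score (Cochran–Armitage-type) test
of 1-year status on additive dosage — with no population structure in
the synthetic cohort, a mixed model would collapse to this, and the
permutation cutoff is the operative error control: each SNP's genotype
is shuffled 1000 times and the 5th percentile of the null p-values is
the cutoff; a SNP is reported when `p < 0.05` and `p < cutoff`. SNPs
passing the association step are then tested for correlation with their
gene's expression (Pearson r > 0.2, p < 0.05, and below a 1000-permutation
cutoff) to flag expression-linked variants.

# The synthetic cohort and what passing means

The generator emulates the shape of a pan-cancer resource at desk
scale: 6 cancer types x 60 samples, 1500 genes partitioned into 60
pathways of 25, a 30% immunotherapy arm — about 108 treated patients,
chosen to match the scale of a pooled pan-cancer immunotherapy cohort
(roughly one hundred patients) while keeping a larger control arm.
Expression is log-normal (gene baseline N(5, 1), cancer-type offsets
N(0, 0.5), unit noise); survival is a proportional-hazards Weibull
(shape 2.2 — the rising hazard typical of late-stage cohorts, and a
sharper 1-year outcome than the exponential special case) with baseline
median 720 days and uniform censoring on [0, 5] years, with
multiplicative effects of the planted genes; mutations fall uniformly
over codons with per-type Dirichlet substitution spectra; one percent
of cells are missing and one percent of genes sit below the expression
floor, so the preprocessing stages do real work. Planted survival genes
carry no cancer-type offsets: they stand for readouts of the immune
state, which the whole design treats as independent of the tissue of
origin.

Planted structure, with effect sizes fixed once from a generator-side
power analysis so that each planted effect is detectable at this sample
size (the spec of the study conditions, not tuning against outcomes):

* one immunotherapy-specific pathway whose first 12 members are
  protective *only in treated patients* at a top-vs-bottom tertile
  hazard ratio of 6;
* one general-prognostic pathway with 5 genes acting in everyone at
  hazard ratio 4;
* 40 immune genes correlated r = 0.6 with the leukocyte fraction
  (purity is `(1 - fraction) x Beta(20, 2)`, so the purity
  anti-correlation is strong);
* 5 hyper-mutated genes receiving ~120 extra non-synonymous events each
  — about 20 per cancer type, enough for the per-type binomial test to
  see them;
* one causal SNP (allele frequency 0.35, per-allele log hazard ratio
  -2.6 in treated patients: the expression-raising allele is
  protective, consistent with the SNP being an eQTL, at r = 0.4, of a
  protective gene). The large SNP effect is deliberate: with ~95
  labeled treated patients and the survival noise injected by the other
  planted effects, smaller effects are undetectable at the stated
  recovery rates.

These effects interact: every planted effect adds patient-level frailty
that dilutes the marginal signal of the others. Under the defaults the
*best* planted gene reaches the top decile of the screen essentially
always, while the *median* planted gene does so only about half the
time — the recovery tests are phrased accordingly.

What the generator does **not** emulate: gene–gene co-expression
networks (each gene's noise is independent), copy-number or methylation
layers, population structure in the genotypes, batch effects, and
non-proportional hazards. Passing tests therefore demonstrate that the
pipeline's inference machinery is correct and calibrated under its own
model assumptions, not that it is robust to these real-data features.

# Numerical conventions and problem sizes

One year is 365 days everywhere. Monte-Carlo p-values always use the
+1/+1 estimator and can never be 0. All tie-breaks (expression groups,
score boundaries, rankings) resolve by identifier so every stage is a
deterministic function of its inputs and seed; the pipeline derives
per-stage child seeds from one master seed. The test and acceptance
runs use scaled resample counts (specificity B = 200, stratification
500, validation 200, GSEA permutations 200) and the desk-scale cohort;
these sizes are the package's chosen test conditions, with the
full-scale defaults (1000/5000/1000) available through `runConfig()`.

# Known limitations

* Gene-permutation GSEA p-values are anti-conservative for strongly
  co-expressed sets; the specificity resampling null corrects this for
  the specificity call, but raw enrichment p-values should be read with
  that caveat.
* The min-max scaling of codon indexes maps the least-frequent mutated
  codon to score 0, which zeroes expression exactly like a frameshift;
  with few tabulated codons the scaling is coarse.
* The RSF importance p-values inherit ranger's permutation-importance
  behavior for correlated features: duplicated features split
  importance.
* The SNP stage implements a single-marker test without kinship
  correction; with real genotypes and population structure a mixed
  model would be required.
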