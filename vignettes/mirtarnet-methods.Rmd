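---
title: "Methods: differential miRNA expression and signed target-network analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: differential miRNA expression and signed target-network analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirtarnet)
```

## The analysis in one paragraph

`mirtarnet` analyses peripheral-blood-mononuclear-cell (PBMC) miRNA count
data from a three-group migraine design — healthy controls, migraine patients
sampled in a headache-free (interictal) phase, and a self-paired subset
sampled during an attack (ictal) — and carries the differential-expression
result through to predicted consequences at the mRNA level. The stages are:
count normalization and empirical-Bayes moderated t-tests per contrast; a
fold-change/p-value filter and average-rank prioritization of the
differentially expressed (DE) miRNAs; a signed bipartite miRNA→gene network
built from a filtered interaction database, whose per-gene node strengths
predict the direction of target expression change; validation of those
predictions against a measured mRNA DE table; and hypergeometric
overrepresentation analysis (ORA) of the predicted target lists with an
annotation-frequency specificity filter.

## Normalization and moderated differential expression

Library scaling uses trimmed-mean-of-M-values (TMM) factors. For each sample
against a reference sample (by default the one whose upper-quartile
depth-normalized count is closest to the cross-sample mean), per-feature log
ratios $M_g = \log_2\!\frac{y_{gj}/N_j}{y_{gr}/N_r}$ and average abundances
$A_g$ are formed over features observed in both libraries; the most extreme
30% of $M$ on each tail and 5% of $A$ on each tail are trimmed and the factor
is $2$ raised to the precision-weighted mean of the remaining $M$-values,
with inverse delta-method variances
$v_g = \frac{N_j-y_{gj}}{N_j y_{gj}} + \frac{N_r-y_{gr}}{N_r y_{gr}}$
as weights. Factors are rescaled to geometric mean 1. The trim fractions
(30%/5%) and the prior count below follow the conventions of the standard
count-normalization literature and are exposed as arguments.

Expression is $\log_2$ counts-per-million with a prior count of 0.5:
$\log_2\!\big(\tfrac{y+0.5}{\hat N+1}\cdot 10^6\big)$ where $\hat N$ is the
TMM-effective library size. Because miRNAs are short, single-"exon" features,
no transcript-length normalization is meaningful; the linear per-million
column reported alongside is therefore counts per million, which is how we
interpret a per-million abundance unit for small-RNA counting.

Each feature receives a precision weight from the mean–variance trend: a
linear model is fitted per feature, $\sqrt{\mathrm{sd}}$ of the residuals is
smoothed against the feature's mean log expression with `lowess`
(span 0.5), and the weight is the inverse fourth power of the trend value —
i.e. the inverse of the implied variance. Weights are constant within a
feature; they standardize the residual variances that enter the
empirical-Bayes step so that low-count, high-variance features do not drag
the shrinkage target.

Inference is a moderated t-test. Per-feature residual variances $s_g^2$ (with
$d$ residual df) are shrunk towards a prior:
$\tilde s_g^2 = \frac{d_0 s_0^2 + d\, s_g^2}{d_0 + d}$, with $(d_0, s_0^2)$
estimated by method of moments on $\log s_g^2$ (the excess of the log
variance spread over $\psi'(d/2)$ determines $d_0$ via the inverse trigamma
function; when the observed spread is no larger than the sampling spread,
$d_0 = \infty$ and all variances pool to $s_0^2$). The moderated t has
$d_0 + d$ degrees of freedom; at $d_0 = 0$ it is exactly the ordinary t.
Benjamini–Hochberg adjusted p-values are reported for every feature.

**Paired contrast.** The ictal samples are self-controls of interictal
patients. Rather than estimating a common within-patient correlation and
feeding it to generalized least squares, the `ictal_vs_interictal` contrast
is fitted on within-patient differences of normalized log expression — a
paired moderated t. This targets the same quantity (the mean within-patient
log fold change), is fully specified, and loses only the ability to borrow
the unpaired samples' information; it is a deliberate design choice of this
package. The two contrasts against healthy controls are ordinary two-group
fits.

**DE filter and prioritization.** A feature is DE when its signed linear
fold change exceeds 1.2 in magnitude and its **raw** p-value is below 0.05,
both strict. The raw-p convention reproduces the published prioritized lists
this package ships as worked examples, which print raw p-values up to 0.049
with no adjusted column; BH values remain available in the table. Signed
fold changes are $2^{\ell}$ for $\ell \ge 0$ and $-2^{-\ell}$ otherwise, so a
halving prints as $-2$. The average rank is the mean of a feature's rank by
$|FC|$ (descending) and by raw p (ascending), with fractional ranks for
ties; ranking is computed over all tested features by default
(`scope = "all_tested"`), because published average ranks exceed the length
of the DE lists, implying ranking over the full tested set; `"de_only"` is
available when only the filtered list should be compared.

## The signed target network

The interaction database has three tiers: experimentally validated records
(kept unfiltered), prediction-score records kept when the score is strictly
above 80.0, and mirSVR records kept when the score is strictly below −1.2
(more negative mirSVR means stronger predicted repression). Surviving
(miRNA, gene) pairs are deduplicated across tiers into **one** edge per pair;
published node strengths are small integers consistent with per-pair
counting, and whether the upstream tooling counted per record or per pair is
not documented, so per-pair is this package's documented choice. Identifier
matching trims whitespace, lower-cases miRNA ids (the `hsa-miR-`/`hsa-let-`
styles are case-insensitive in practice) and preserves gene-symbol case; no
alias resolution is attempted.

Each edge is weighted $+1$ when its miRNA is upregulated and $-1$ when
downregulated, and a gene's node strength is the sum of its incident
weights. Because miRNAs repress their targets, positive strength predicts
target downregulation and negative strength predicts upregulation. Genes
whose up- and down-edges cancel to strength 0 are retained with prediction
"none" — they exist and discarding them would hide information — but are
necessarily inconsistent in validation, which requires a direction. Ranked
target lists break |strength| ties alphabetically for determinism. Network
exports (SIF, GraphML, node-attribute TSV) carry an `emphasized` flag that is
true only for |strength| > 1, mirroring the visualization rule that
de-emphasizes genes at |strength| ≤ 1.

## Validation against measured mRNA fold changes

A predicted target is *validated* (consistent) when its measured mRNA
$\log_2 FC$ is nonzero, its node strength is nonzero, and the two signs are
opposite. Strength 0 or logFC exactly 0 cannot be validated: "consistent"
requires a direction on both sides, a rule this package fixes explicitly
since the source procedure does not discuss the degenerate cases. The join
with the mRNA DE table is an inner join on exact normalized gene symbol.
Flipping every miRNA direction upstream negates every strength and therefore
inverts every consistency flag with nonzero strength and logFC — a
metamorphic property the tests exercise.

## Overrepresentation analysis

For a query of predicted targets (run separately for predicted-down and
predicted-up genes), each term's p-value is the exact hypergeometric upper
tail $P(X \ge k)$ with universe $N$, term size $K$, query size $n$ and
overlap $k$; BH adjustment is applied across the tested terms. Significance
is declared on the raw p at 0.01, matching the web-tool convention the
procedure stands in for, with the FDR reported alongside. The universe is
the set of genes in the interaction database **after** threshold filtering —
predicted targets can only be drawn from the database, so a whole-genome
universe would overstate enrichment; the universe is an explicit argument.
The specificity filter keeps terms whose annotation frequency (the
proportion of gene products annotated to the term) is strictly below 0.15;
higher-frequency terms are too general. Terms lacking a frequency are kept,
flagged non-specific, with a warning — dropping them silently would bias
against sparsely annotated collections. Semantic-similarity clustering of GO
terms is deliberately not reimplemented; only this frequency rule is.

## The synthetic-data generator

The generator exists so that every stage is testable without the original
sequencing data. Its defaults emulate the study design the pipeline was
built for: 12 healthy controls, 16 interictal patients, 8 self-paired ictal
samples; negative-binomial counts with log-linear group effects; 30 planted
miRNAs at $|\log_2 FC| = 1.5$ (the middle of the published DE lists'
effect range); dispersion 0.1 and library sizes uniform on
$[5\times10^5, 2\times10^6]$, typical of small-RNA libraries. The
within-patient dependence is a per-feature Gaussian random effect on the
log2 mean shared by a patient's interictal and ictal samples, with
`pairing_correlation` (default 0.5) the share of the biological variance
(`bio_sd`, default 0.25 on the log2 scale) attributed to the patient level.
Effect-size and dispersion distributions are not published for the cohort,
so these are the package's own documented choices, fixed once.

The interaction-database generator emits every planted edge in one of the
three tiers with a passing score and adds decoy records whose scores fall on
the failing side of each threshold, so threshold filtering must recover
exactly the planted edge set. The mRNA generator gives every
nonzero-strength gene a logFC sign opposite to its strength, flipping an
independent Bernoulli(`flip_fraction`) subset, so the validated fraction
converges to $1 - $ `flip_fraction`. The gene-set generator plants one term
made of the most strongly targeted genes at a low annotation frequency and
spreads the remaining frequencies across both sides of 0.15.

What the generator does **not** emulate: sequencing reads, adapter or
alignment artifacts, GC or length biases, compositional shifts from a few
dominant features, batch effects, and realistic gene-symbol ambiguity.
Passing tests therefore demonstrate the statistical machinery's correctness
and calibration under the assumed generative model, not robustness to every
failure mode of real small-RNA data.

All generator randomness flows from one integer seed: each stage derives its
own 32-bit sub-seed from the master seed and a stage tag, so stages are
individually reproducible and adding a stage does not shift the streams of
the others.

## Numerical choices and degenerate inputs

* Strictness: every published threshold is applied exactly as printed —
  |FC| > 1.2, p < 0.05, score > 80.0, mirSVR < −1.2, frequency < 0.15, all
  strict.
* Decimal commas in transcribed report tables ("2,59") are converted by
  `parse_decimal()`; the bundled DE lists keep the original comma style.
* Ties: fractional (average) ranks in the DE prioritization and in the TMM
  trim window; alphabetical tie-breaks in target rankings.
* Zero counts: the 0.5 prior count keeps log-CPM finite; all-zero samples
  are an error.
* Residual variances of exactly 0 are excluded from the moment estimation
  of the variance prior.
* The lowess trend for precision weights is floored at half the smallest
  positive observed $\sqrt{\mathrm{sd}}$ so weights stay finite.
* `log2fc = 0` maps to signed FC 1 and direction "up" by convention; it
  occurs with probability zero for continuous statistics.

## Problem sizes used by the test suite

The suite favours many small, seeded simulations over few large ones:
null-calibration runs use 50 replicates of 300 features at 8 vs 8 samples;
sensitivity runs plant 30 effects per replicate; the flip-fraction check
uses ~600+ nonzero-strength genes; oracle comparisons use 50×4 count
matrices and exhaustive hypergeometric enumeration up to a universe of 12.
These sizes give the binomial and Monte-Carlo error bounds the assertions
state while keeping the default test run fast.

## Known limitations

* The paired contrast ignores between-patient information that a
  correlation-sharing GLS fit would use; with few pairs its power is lower.
* Exact reproduction of the original cohort's DE statistics is out of
  scope — the raw reads are not consumed; the bundled published tables are
  used as fixed worked examples instead.
* Gene symbols are matched exactly after whitespace/case normalization; no
  alias tables.
* The ORA treats genes as exchangeable; no correction for gene length,
  expression level or inter-gene correlation.
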