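---
title: "Methods: organellar proteomes and the heritability of age-related traits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: organellar proteomes and the heritability of age-related traits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(orgenrich)
```

## The scientific question

Organelles — above all the mitochondrion — are central to mechanistic
theories of aging, so a natural population-genetic question is whether
common-variant heritability of age-related traits concentrates near genes
encoding organellar proteomes. `orgenrich` implements the statistical
machinery for that question as a reusable pipeline: trait prioritization,
gene-set construction from subcellular localization evidence, two
complementary enrichment designs (a catalog screen and a competitive
gene-level regression), expression-specificity and eQTL-landscape models,
mitochondrial-genome association testing, latent-trait correlation, and
constraint summaries. Every stage can be exercised on synthetic data with
planted structure, so the pipeline's operating characteristics (type-I
error, power, estimator bias) are measurable rather than assumed.

## Trait prioritization

Age-related diseases are ranked by the sum of sex-standardized period
prevalence over age bands whose lower bound is at least `age_min`
(default 50 years), restricted to diseases with median onset strictly
above `onset_min` (default 50). The top `top_k` (default 30) are
retained. Because the source prevalence tables label bands by their lower
bound, "bands above 50" is interpreted as `band_lower >= 50`; both
thresholds are arguments since the inclusive/exclusive reading of the
onset rule is a genuine ambiguity. Ties are broken lexicographically by
disease identifier so the ranking is deterministic under row permutation.
Traits enter downstream genetic analyses only when their SNP-heritability
Z-score `h2/se` strictly exceeds 4 — an evidence filter, not a
significance test.

## Gene-set construction

Localization scores are integer evidence levels 0–5 per (gene,
compartment) pair, in the style of integrated localization databases.
Assignment keeps scores strictly above 2, then assigns each gene to every
compartment achieving its maximal score — ties produce multi-organelle
genes by design. Compartments with more than 240 members (strictly) are
retained; the mitochondrion set is replaced by a curated inventory when
one is supplied, reflecting the availability of a higher-confidence
hand-curated mitochondrial proteome. Nuclear sub-compartments are handled
specially: the chromosome set is merged with a curated transcription
factor list; nucleoplasm is made exclusive of the other nuclear subsets
(exclusivity is applied before the size filter); nucleus members in no
subset form an "other nucleus" remainder. TFs are further partitioned
three ways: tissue-specific versus broad at `tau >= 0.76`, age terciles
by phylostratum rank (stable rank, sizes differing by at most one), and
DNA-binding-domain groups (KRAB zinc finger, other zinc finger,
non-zinc-finger).

## The catalog screen and its empirical null

Each trait's associated genes (any association with `p < 5e-8`;
traits kept only with more than 30 such genes) are crossed with
target-set membership over the protein-coding universe in a 2×2 table and
tested by a two-sided Fisher exact test (classical convention: sum of
hypergeometric point probabilities no larger than the observed table's),
with Benjamini–Hochberg correction at FDR 0.1 across traits. The
direction is read from the unconditional sample odds ratio `ad/bc`
(the conditional MLE is available by argument).

The screen's summary statistic is the *enrichment count*: the number of
traits in which the target set is nominally enriched, defined as odds
ratio strictly greater than 1 regardless of significance. Its null
distribution comes from uniform same-size gene samples drawn without
replacement from the universe (default 1000). The one-sided empirical
p-value asks whether the target is enriched in *fewer* traits than random
sets — `Pr(N_null <= N_obs)` — estimated with an add-one pseudo-count so
it can never be exactly zero (the plain proportion is available by
argument). Because the count statistic is discrete, the estimator is
slightly conservative; calibration simulations in the test suite use 100
traits so the support is fine enough for the rejection rate at
nominal 0.05 to land near 0.05.

## Competitive enrichment regression

Gene-level association Z statistics are regressed on a set-membership
indicator plus six technical covariates — gene length, SNP density
(SNPs/kb), inverse minor allele count, and their logarithms — by OLS,
with a one-sided (enrichment-only) t-test on the membership coefficient.
Supplying a control superset restricts the analysis to its genes, making
the test competitive against, for example, all protein-coding genes.
Constraint conditioning replaces the membership indicator by its residual
after projection on `[1, LOEUF, log LOEUF]` before the main fit; the
projection is computed from the QR factorization and tolerates exact
collinearity between LOEUF and its log (which occurs when LOEUF takes few
distinct values). Genes with missing or non-positive LOEUF are dropped
and counted.

The subsampling power framework draws uniform subsamples of a source set
at the sizes of interest (the validation suite uses 1523, 1105, 800 and
350, spanning the realistic range of organelle-proteome set sizes in an
18,000-gene universe), tests each, and reports the significant fraction
with a Wilson 95% interval. The default significance rule applies BH at
the configured FDR across the whole batch of subsample tests; a per-trial
nominal rule is available. At the planted standardized shift of 0.3 used
for validation, analytic power is essentially 1 at *every* size in that
range — the monotonicity check therefore allows ties — and the gradient
across sizes only becomes visible at weaker shifts (the suite uses 0.08
for that property).

## Expression specificity and the eQTL landscape

Tissue specificity uses tau: with `x_hat = x / max(x)` over `n` tissues,
`tau = sum(1 - x_hat) / (n - 1)`, 0 for uniform and 1 for single-tissue
expression; genes whose maximal TPM falls below 1 are excluded. The
tissue-specific/broad threshold is located at the central nadir of the
bimodal tau distribution: a 50-bin histogram smoothed by a 3-bin moving
average, the two largest local modes found (plateaus of equal counts are
collapsed to a single candidate), and the minimum-density bin strictly
between them returned as the threshold. A nadir is only accepted when its
smoothed count is below half the smaller mode (the `min_prominence`
argument); otherwise — unimodal, degenerate, or noisy input — the
documented fallback 0.76 is returned with a warning.

Because expression resources sample correlated subtypes of some tissue
classes (many brain sub-regions, several heart or artery samples), tau
and tissue-count statistics are biased when computed over the full tissue
list; one representative tissue per class is therefore selected via an
explicit class→tissue mapping (no tissue names are hard-coded). The
eQTL-landscape model regresses the number of tissues with a significant
cis-eQTL (`q < 0.05`, strict) on organelle membership, controlling for
the number of expressed tissues (`TPM > 5`, strict), tau, log gene length
and gene length, by OLS with a two-sided test.

## mtDNA association

Variant QC drops, in order: exclusion-listed variants (cluster-plot
review failures are an input list), variants with any heterozygous call,
variants whose call rate falls below 0.95 within any array batch in which
they are assessed (a variant absent from one array is judged on its own
array only), and variants with fewer than 20 alternate carriers. Sample
QC removes samples with call rate below 0.95 over the variants assessed
on their own array. The carrier minimum is applied after sample QC in the
`mt_qc()` wrapper. Binary phenotype–variant pairs additionally require an
expected alternate-genotype case count — carriers × case fraction — of at
least 20.

Continuous traits use OLS with the standard covariate formula (20 nuclear
PCs, sex, age, age², sex·age, sex·age²); binary traits use Firth
logistic regression — the Jeffreys-prior penalty `+ 1/2 log det I(beta)`
keeps estimates finite under the complete separation that array-specific
variants produce. The penalized likelihood is maximized by Newton
iteration with step-halving, converging when the largest modified-score
component drops below 1e-6 (at most 100 iterations; non-convergence is
flagged, never silently accepted), with Wald standard errors from the
penalized information. The array-batch indicator is available for linear
models and deliberately off by default for logistic models, where it
induces separation. mtDNA-wide significance is Bonferroni over tested
pairs, `0.05 / n_pairs`; at the 4337 pairs of the motivating design this
is 1.15e-5. `mt_power_effect()` inverts the Wald power calculation to
size a per-allele effect for a target power at that threshold.

## Trait correlations under a latent-normal model

Pairwise estimators follow the type combination: Pearson
(continuous–continuous), tetrachoric (binary–binary) and biserial
(binary–continuous), all interpreted as estimates of the correlation of
latent bivariate-normal liabilities. The tetrachoric estimator is
two-step: thresholds fixed from the marginal prevalences by inverse
normal, then the latent correlation maximized over (−0.999, 0.999) by
bounded scalar optimization (tolerance 1e-6) of the bivariate-normal cell
likelihood. The rectangle probability is evaluated by one-dimensional
adaptive quadrature of the conditional-CDF integrand — accurate to ~1e-10
and dependency-free. The standard error comes from the observed
information (finite-difference curvature) at the optimum, supporting
normal-approximation p-values; the biserial estimate corrects the
point-biserial by `sqrt(p(1-p))/phi(z_p)`. Binary traits observed in a
single class are skipped with a warning.

Traits are ordered for display by their loading on the first eigenvector
of the element-wise absolute correlation matrix. Two conventions make
this deterministic where the mathematics is not: when the leading
eigenvalue is (numerically) multiple, a uniform start vector is projected
onto the leading eigenspace, which preserves input order for an identity
matrix; loadings are rounded to 9 digits before the final label
tie-break, so exchangeable traits order lexicographically regardless of
floating-point noise. The Bonferroni cutoff across the genetic and
phenotypic arms is `alpha / (C(n_g,2) + C(n_p,2))`; with 24 and 21 traits
this is 0.05/486 ≈ 1.03e-4.

## Constraint summaries

Decile boundaries are type-1 (lower) empirical quantiles of LOEUF over
the full gene table, so they are determinate on tied values; membership
in the lowest decile uses `<=` the first boundary. The set-level
proportion carries a Wilson 95% interval; set-mean LOEUF carries a seeded
percentile bootstrap CI (default 2000 resamples). Comparator sets
(haploinsufficient genes, olfactory receptors) are ordinary GMT inputs.

## The synthetic-data module

Every generator is a pure function of a `sim_config` (and explicit
arguments): identical configuration gives byte-identical output and the
global RNG stream is saved and restored. Defaults are chosen to mirror
the motivating study's regime: an 18,000-gene universe (the order of the
protein-coding genome), planted set size 1523 with standardized Z shift
0.3 (the largest set size and a mid-range effect in the power analysis
design), mtDNA carrier counts log-uniform between 20 and 10% of the
cohort (so QC's 20-carrier floor binds), two array batches with
batch-specific missing-completely-at-random call rates, liability-
threshold binary phenotypes (the data-generating process the tetrachoric
estimator assumes), and log-scale LOEUF shifts per compartment
(multiplicative, hence always positive). Planted localization scores give
each planted gene one high score (3–5) shared across all of its planted
compartments, so the max-score assignment rule recovers plantings exactly
— sensitivity and specificity 1 by construction, which the suite asserts.

What the generators do *not* emulate matters for interpretation: no
linkage disequilibrium or SNP-level structure (gene-level Z statistics
are drawn directly), no relatedness or population stratification beyond
independent synthetic PCs, no correlated traits in the catalog, and
missingness that is completely at random within batch. Passing tests
therefore demonstrate that the statistical machinery is correct and
calibrated under its stated assumptions — not that those assumptions hold
in any particular cohort.

## Validation problem sizes

The test suite and the acceptance script validate at sizes chosen to keep
a full run in tens of seconds while leaving Monte-Carlo error well inside
the asserted tolerances: calibration universes of 1,000–2,000 genes with
500 replicates (type-I bands [0.03, 0.07]); the planted-enrichment
recovery at the full 18,000-gene universe with 100 replicates; the null
mtDNA scan at 1,500 samples × 400 variants (median chi-square vs. the
χ²₁ median 0.455); detection of a planted mtDNA effect sized by
`mt_power_effect(power = 0.95)` — within the "greater than 90% power"
design condition, with headroom for missingness — over 100 replicates at
2,000 samples; and tetrachoric/biserial recovery at n = 50,000.

## Known limitations

The Fisher screen treats trait-associated gene sets as fixed; catalog
curation noise is not modeled. The biserial standard error is a
large-sample approximation. Firth p-values are Wald by default
(a penalized-likelihood-ratio option would be sharper near separation).
The nadir detector assumes the tau histogram is genuinely bimodal;
distributions with three or more modes return the valley between the two
largest. The eQTL-landscape model is linear in counts; a Poisson or
negative-binomial variant may fit better when counts are small.
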