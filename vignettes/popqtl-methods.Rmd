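---
title: "Models and methods behind popqtl"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind popqtl}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

popqtl implements the analysis chain that links genetic variation to gene
expression and splicing in a cohort drawn from many populations: variance
partitioning across population labels, cis-QTL discovery, multi-signal
fine-mapping, conditional effect-size estimation, population
characterisation of causal signals, and regulatory enrichment. This
vignette explains the models, their assumptions, the tunable parameters,
and the design choices made where the design was genuinely open. It states
no empirical result that the test suite or `scripts/acceptance.R` does not
itself compute.

## The synthetic cohort generator

Because individual-level human data cannot ship with a package, popqtl
includes a generator (`sim_config()`, `simulate_cohort()`) that emulates
the statistical structure the analyses assume, with complete ground truth
(`SimTruth`) for recovery testing.

**Population structure.** The default cohort mirrors a globally diverse
LCL panel: 26 populations nested in five continental groups (AFR 7, AMR 4,
EAS 5, EUR 5, SAS 5), 27–30 individuals per population, ~731 samples in
total. Allele frequencies follow a two-level Balding–Nichols model: a
group frequency is Beta-distributed around the ancestral frequency
$p_0$ with differentiation $F_G$ (variance $F_G\,p_0(1-p_0)$), and each
population frequency is drawn analogously around its group frequency with
$F_P$. Defaults $F_G = 0.1$ and $F_P = 0.02$ are in the range estimated
between and within human continental groups.

**Linkage disequilibrium.** Haplotypes are drawn per population by
thresholding latent Gaussian vectors with exchangeable within-block
correlation $\rho$ (default 0.9, blocks of 10 variants) at
frequency-matched quantiles. Two details matter and are deliberate:

* The ancestral frequency is drawn per LD *block* (with a small
  per-variant jitter), and the Balding–Nichols Beta draws use one shared
  uniform quantile per (block, group) and per (block, population) — a
  comonotone copula. Variants in tight LD segregate on shared haplotypes,
  so their frequencies are nearly identical and their drift is shared;
  without this, thresholding decorrelates block-mates whose frequencies
  differ, and no setting of $\rho$ yields realistic dosage correlation.
  The copula leaves every variant's marginal exactly Beta, so the
  variance identity $\mathrm{Var} = F\,p_0(1-p_0)$ still holds
  variant-wise (tested).
* LD strength may differ by continental group (`ld_rho_group`), with
  African-ancestry groups typically lowest. Group-differentiated LD
  between a tag and a co-causal variant is the mechanism that makes a
  purely additive architecture *look* ancestry-heterogeneous, and is the
  study condition for the interaction-rescue analysis below.

Thresholded-Gaussian LD was chosen over coalescent simulation: it is
desk-scale, gives controllable block structure, and the statistics under
test do not require coalescent realism.

**Expression.** For sample $i$ and gene $g$ with causal set $K$,

$$e_{ig} = b_g \prod_{k \in K} \frac{(2-d_{ik}) + d_{ik}\,2^{\delta_k}}{2}
           \cdot 2^{\text{batch} + \text{sex} + \text{group} + \varepsilon},
  \qquad \varepsilon \sim N(0, \sigma^2),$$

the generative inverse of the allelic-fold-change effect-size definition,
so generator and estimator form a consistent pair. Defaults: 0–5 causal
variants per gene with probabilities (0.25, 0.40, 0.20, 0.09, 0.04, 0.02)
— most genes have at most one signal, a sizeable minority several;
$\delta_k \sim N(0, 0.5^2)$ truncated at $\pm\log_2 100$ (median
$|\delta|$ ≈ 0.34, matching the observation that most cis effects are
well under two-fold); residual $\sigma = 0.5$ on the log2 scale; per-gene
batch effects (sd 0.2, 4 batches assigned round-robin within population so
batch never confounds population), a sex effect (sd 0.1), and group-level
expression shifts for 20% of genes (sd 0.25). `group_var_frac` instead
fixes the between-group share of log2 variance exactly (used by the
variance-partition calibration). Causal variants are drawn among variants
with cohort MAF ≥ 0.05; `afc_fixed`, `causal_same_block`,
`causal_separate_blocks` and `causal_bias` (interval-weighted placement)
pin down specific study conditions.

**Splicing.** One cluster per gene with 2–4 introns; per-sample intron
usage is logistic-normal — logits are a cluster baseline plus Gaussian
noise (sd 0.5), shifted additively by causal dosage on one target intron —
and ratios are the softmax, so they sum to one within cluster by
construction.

**What the generator does not emulate.** Read-level sampling noise,
annotation realism (gene density, intron structure), coalescent LD decay,
admixture tracts, sex chromosomes, and trans effects. Passing tests
therefore demonstrate correctness of the statistical machinery under the
stated model, not performance on any particular real data set.

## Normalization

`filter_features()` keeps features with value ≥ 1 in ≥ 20% of samples
(splicing additionally drops zero-variance introns and clusters reduced
below two introns). `inverse_normal_transform()` maps each feature to
$\Phi^{-1}((\text{rank}-0.5)/n)$ with average ranks for ties — the 0.5
offset keeps quantiles bounded and is common in QTL pipelines.
`compute_covariates()` builds genotype PCs from LD-pruned ($r^2 < 0.2$,
50-variant window) standardised dosages, phenotype PCs from the
transformed matrix, batch one-hot (reference dropped) and sex; collinear
columns are dropped with a warning. Defaults of 5 genotype and 15
phenotype PCs are configuration-exposed. `residualize()` takes exact OLS
residuals via the QR decomposition; it is idempotent and its output is
orthogonal to every covariate column.

One covariate decision is worth emphasis: the **variance-partition stage
residualizes batch and sex only**. Genotype and phenotype PCs are
ancestry-correlated by construction, so removing them would subtract the
very signal the population-label partition measures; the association
stages, by contrast, use the full covariate set precisely to protect
against stratification.

## Variance partitioning

Per feature, the proportion of variance explained by the label factor is
the one-way ANOVA $R^2$, computed at the continental-group or population
level (for splicing, per intron, optionally averaged within cluster). The
cohort mean is tested against a permutation null in which labels are
permuted jointly across samples — one shared permutation per replicate for
all features, preserving the inter-feature correlation that the
distribution of the cohort *mean* depends on. With 999 permutations the
smallest reportable p is 1/1000. Under the null the per-feature $R^2$ has
expectation $(k-1)/(n-1)$, so small positive means are expected even
without structure; the permutation test accounts for this.

Differences in within-group variance are tested with a gamma GLM (log
link) of the per-feature per-group sample variance on group, observations
pooled over features (N = features × groups), reporting the
analysis-of-deviance chi-square with $df = n_{\text{groups}} - 1$.
Variances are positive and right-skewed, which the gamma family matches;
a feature-level term is deliberately omitted so N matches the pooled
design. Zero-variance cells are dropped with a message.

## cis-QTL mapping

`nominal_pass()` regresses the residualized phenotype on dosage for every
variant within 1 Mb of the feature anchor (TSS or intron start) with
cohort MAF ≥ 0.01; missing dosages are mean-imputed per variant.
`permutation_pass()` permutes the phenotype (genotypes fixed — covariates
are already removed, so phenotype-only permutation preserves the residual
structure) 1000 times, records the per-permutation best p, fits a Beta
distribution to those minima by maximum likelihood, and reports the
effective gene-level p as the Beta CDF at the observed best p; the raw
empirical p is retained for auditing. Grouped mode takes the minimum over
a gene's introns *inside* each permutation, giving a gene-level sQTL null
over correlated introns. `call_significant()` applies Benjamini–Hochberg
across features, flags eGenes/sGenes at the chosen FDR (default 5%),
interpolates the effective-p threshold at the FDR boundary, converts it
per feature through the inverse Beta CDF into a nominal threshold, and
extracts all significant feature–variant pairs.

## Fine-mapping

`susie_fit()` implements the sum-of-single-effects regression: the
phenotype is a sum of $L$ (default 10) single-effect regressions, each
with exactly one non-zero coefficient. Iterative Bayesian stepwise
selection removes each effect's fitted contribution from the residuals and
refits a single-effect regression: per-variant Bayes factors under a
normal prior whose variance is optimised per effect by one-dimensional
empirical-Bayes maximisation (collapsing to the null when the optimised
marginal likelihood does not beat it), softmaxed into posterior inclusion
weights. The residual variance is updated from the expected residual sum
of squares. The ELBO is tracked exactly — the KL term of each effect is
evaluated against the residual that effect was updated against, which is
what makes the bound provably non-decreasing (asserted in tests to 1e-8)
— and iteration stops when it changes by less than `tol` (1e-3).

Credible sets are the smallest variant sets, by descending inclusion
weight, reaching 95% cumulative mass per effect; sets with purity
(minimum absolute genotype correlation among members) below 0.5 are
discarded and duplicate memberships collapsed — the published defaults of
the reference method. Fine-mapping runs on residualized phenotypes and
internally standardised dosages, keeping the single-effect regression
closed-form. PIPs are $1 - \prod_l (1 - \alpha_{lv})$ over active
effects.

For splicing, `merge_intron_credible_sets()` merges a gene's intron-level
sets that share at least one variant, iterating to the transitive closure;
the result is the connected-component partition and is therefore
invariant to input order (tested over all orderings of a chain). Merging
by nonempty intersection rather than LD similarity is the minimal
reproducible rule. A merged set scores each variant by its maximum
inclusion across sources, and the lead is re-selected afterwards.
`select_lead()` is fully deterministic: maximal inclusion, ties broken by
higher MAF, then lower genomic position, then variant id.

Detection power, not calibration, limits the resolution of weak secondary
signals: a second causal variant with MAF near 0.05 and $|\delta| = 0.5$
carries a marginal z-statistic of only ~3–4 at n = 750 (the per-allele
effect is $\approx\delta/2$), and its 95% set can fail the purity filter
by dragging in diffuse tail mass. This is the same behaviour as the
reference implementation and is reflected in the two-signal detection
rate measured by the acceptance script.

## Conditional allelic fold change

`estimate_afc()` fits, per gene and jointly over all its lead variants,

$$\log_2 e_i \approx c + \sum_k \log_2\!\frac{(2-d_{ik}) + d_{ik} 2^{\delta_k}}{2},$$

by bounded nonlinear least squares (analytic gradient, L-BFGS-B,
$|\delta| \le \log_2 100$ — the convention of reference aFC
implementations, preventing divergence at near-monomorphic leads).
Joint fitting is the point: marginal per-variant fits are biased whenever
leads are correlated, and the package's tests demonstrate that asymmetry
directly. Standard errors come from a nonparametric bootstrap over samples
(default 100 resamples). Estimation is dosage-based (unphased): dosages
suffice for the multiplicative model, and no downstream analysis needs
phase. Input expression must be strictly positive; for count data apply a
pseudocount of 1 upstream (the pipeline does) — the estimator itself does
not add one, so that exact recovery on continuous positive data is
possible.

## Population characterisation of lead QTLs

**FST.** `weir_cockerham_fst()` computes the Weir & Cockerham (1984)
diploid variance components $a$, $b$, $c$ per variant and per
(focal group, other group) pair from allele frequencies, observed
heterozygosities and sample sizes; $\hat\theta = a/(a+b+c)$. Following
the caption convention of focal-group analyses, the per-variant
`mean_theta` is the arithmetic mean of the pairwise focal-versus-other
estimates (a one-vs-pooled alternative would conflate the other groups'
internal structure). Negative estimates are retained — the estimator is
noisy around zero and truncation would bias averages — and
monomorphic-everywhere pairs are undefined rather than zero. For
multi-variant summaries, `fst_overall()` uses the ratio of summed
components $\sum a / \sum(a+b+c)$, the recommended multi-locus combination;
averaging per-variant ratios is biased downward.

**Frequency classes.** `classify_frequency_distribution()` assigns
mutually exclusive classes in the order absent-in-EUR-and-AFR,
absent-in-EUR, globally common (frequency > 0.05 in every group), other.

**DE coupling.** `differential_expression_by_group()` contrasts the focal
group against all other samples per gene (pooled-variance linear
contrast), ranks genes by p into deciles (10th = strongest), and
`fst_de_association()` couples lead-eQTL FST to those deciles plus a
rank-sum test of FST for DE versus non-DE genes with a rank-biserial
effect size and bootstrap interval.

**Interaction testing.** `interaction_scan()` compares, per lead, the
additive model to one with a genotype-by-group interaction (omnibus
F-test over group levels; the group main effect is always present in both
models, as a well-specified interaction test requires). Joint mode adds
additive dosage terms for every other lead of the gene to both models, so
heterogeneity that merely reflects unmodelled additive co-signals
disappears. Leads are tested only with MAF ≥ 0.05 in at least two groups
and groups of at least 10 samples; Bonferroni correction is over tested
leads. All five group levels enter the omnibus test (collapsing small
groups would change its df silently). One caveat the simulations expose:
at large $|\delta|$ the multiplicative aFC model is genuinely non-linear
in dosage, and that dominance curvature interacting with group frequency
differences registers as interaction even for a single causal variant —
the additive-null calibration therefore uses a small effect
($\delta = 0.25$) where the model is locally linear.

**Constraint and replication.** `constraint_associations()` runs the three
standard tests linking gene constraint (e.g. pLI) to eQTL architecture:
rank-sum of score for eGenes versus non-eGenes, quasi-Poisson GLM of
credible-set count on a top-decile-constraint indicator (the quasi-Poisson
point estimate equals the Poisson one; dispersion only widens the SE),
and rank-sum of lead $|\log_2 \text{aFC}|$ for top-decile versus other
genes. `replication_compare()` marks a study-A credible set replicated
when it intersects the union of study-B sets for the same gene, with a
separate status for genes absent from B entirely.

## Enrichment

`annotate_variants()` tests interval containment in internal 1-based
closed coordinates (BED input is converted at the reader; `chr`-prefix
mismatches are reconciled). `enrichment_test()` compares lead hit rates
against a background of non-lead cis variants matched on MAF deciles and
log10 TSS-distance bins at 10:1 (bins without background relax one level
with a warning), using Fisher's exact test with Bonferroni correction over
annotations (times deciles in effect-size-decile mode; decile counts sum
exactly to the pooled run). Matching was chosen over an all-variants
background because MAF and TSS distance are the two confounders these
analyses emphasise; `match = FALSE` gives the unmatched comparison. Note
that a distance-matched background cancels, by construction, any
annotation that is a pure function of TSS distance — the validation
therefore plants placement preference in scattered regulatory patches
rather than a TSS-centred band.

## Pipeline

`run_pipeline()` executes simulate → normalize → variance → map_cis →
finemap → afc → popstats → enrich, writing per-stage outputs and a
manifest with md5 hashes; a stage failure halts downstream stages and is
recorded. The global seed fans out to per-stage seeds through a named
hash so each stage is independently re-runnable. The package is driven
from R — each stage is an exported function and the pipeline is their
composition; configuration comes from `pipeline_config()` or YAML with
unknown keys rejected.

## Problem sizes used in validation

The test suite and `scripts/acceptance.R` run the statistical validation
at the cohort scale the methods target (~730–750 samples) with gene
counts chosen for stable Monte-Carlo estimates: 200 single-causal genes
for credible-set coverage, 50 two-causal replicates for multi-signal
detection, 160 grid fits for aFC accuracy, 10 null and 20 mixed
replicates for the permutation machinery, ~1000 additive replicates for
interaction type-I calibration, 200 genes for variance-partition recovery,
and 25 replicates of 100 planted leads for enrichment detection — the
last sized so the Fisher test has >90% power for 5:1 placement odds at
Bonferroni 0.05. Unit tests use smaller cohorts.

## Known limitations

* Dosage-level only: no phased-haplotype aFC, no genotype likelihoods.
* The interaction omnibus inherits the dominance-curvature caveat above.
* Fine-mapping uses individual-level data; summary-statistic mode and
  functional priors are out of scope.
* The generator's LD is blockwise-exchangeable; long-range decay and
  admixture tracts are not modelled.
* Trans effects, chrX-specific handling, and upstream read processing
  (alignment, quantification, intron clustering) are outside the package;
  the generator produces their outputs directly.
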