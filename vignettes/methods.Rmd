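---
title: "Methods: age effects on the mean and dispersion of brain gene expression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: age effects on the mean and dispersion of brain gene expression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(brainage)
```

# Scope

`brainage` implements a per-region analysis of bulk brain transcriptomes
that asks two distinct questions about aging: does donor age shift the
*mean* expression of a gene, and does it change the *dispersion*
(variance) of expression between age groups? Around those two tests sit
the standard scaffolding of such a study: region-wise normalization,
hidden-factor confounder correction with explicit protection of the age
signal, pathway-level factor association, and a genotype-by-age
interaction scan. A ground-truth simulator generates cohorts with the
structure the pipeline expects, so every stage is testable without any
controlled-access data.

# Preprocessing

Expression arrives as a gene x sample matrix of RPKM-like values for one
region. Three steps, in a fixed order:

1. **Low-expression filter.** The `ceiling(0.10 * G)` genes with the
   smallest mean raw expression are dropped. Filtering happens *before*
   normalization because the criterion is the mean expression level on the
   raw scale; quantile-normalizing first would let the dropped rows distort
   the reference distribution. Ties at the cutoff are broken by gene-id
   lexicographic order, so the filter is deterministic.
2. **Quantile normalization.** Each column is mapped onto the common
   reference distribution formed by the row means of the column-sorted
   matrix. A tie group occupying sorted positions $a..b$ in a column
   receives the mean of the reference values in those positions; this
   keeps the map deterministic and rank-preserving. After normalization
   the sorted columns are identical by construction.
3. **log2 transform**, `log2(x + pseudocount)` with pseudocount 1.0
   (bounded below, conventional; configurable). The pseudocount has the
   units of the expression measure.

The container carries a state tag (`rpkm` / `lognorm` / `residual`) so the
pipeline order is checkable; taking logs of un-normalized data is allowed
but flagged.

# Two-step confounder correction

Bulk expression matrices carry structured technical variation (batch,
ischemia, cell composition) that can mimic or mask age effects. The
correction estimates up to $K = 15$ latent factors and then divides them
into "safe to remove" and "possibly age" classes:

1. **Factor discovery.** Each gene is regressed on the known covariates
   (age, sex, BMI, and ischemic time when recorded); the coefficients are
   reported per gene. Factors are then estimated by alternating least
   squares initialized from the SVD of the matrix with only the *non-age*
   covariates removed. Running discovery on data that still contains
   age-related variation is deliberate: if factors were estimated on
   residuals from a regression that includes age, every factor would be
   exactly orthogonal to age and an age-correlated technical confounder
   could never be identified as such — its age-aligned component would
   instead be silently absorbed into the per-gene age coefficients. With
   age-related structure visible, both genuine age responses and
   age-correlated confounders surface as factors and are handled by the
   filter below.
2. **Age filter.** Each factor score vector is tested against donor age
   with the Pearson correlation test (t transform, $n-2$ df, two-sided);
   factors with $P < 0.05$ are excluded from the covariate set. This is
   the protection step: nothing correlated with age is ever regressed
   out, at the acknowledged cost that a technical artifact genuinely
   correlated with age stays in the data.
3. **Residualization.** Each gene is regressed on an intercept, the kept
   factors and the non-age covariates; the residuals become the corrected
   matrix used by the pathway and dispersion stages. Age is never among
   these regressors, so by the projection property the residuals are
   exactly orthogonal to every removed direction while the age signal is
   untouched.

Numerical choices: convergence is declared when the relative change of
the Frobenius reconstruction error falls below `1e-8` (at most 500
sweeps; with the SVD initialization the alternation starts at the best
rank-$K$ approximation, so this is immediate in practice). Factor scores
are standardized to unit sample variance, each factor's sign is fixed by
making its largest-magnitude loading positive, and $K$ is truncated to
the numerical rank of the residual matrix, so the whole procedure is
deterministic — two runs on the same input are bit-identical. The engine
is a deterministic least-squares factor analysis, exposed behind an
interface so a variational Bayes implementation could be swapped in.

# Per-gene age regression

For each gene the model is

$$Y_i = \mu + \mathrm{Age}_i\,\alpha + \mathrm{Sex}_i\,\beta +
  \mathrm{BMI}_i\,\gamma + \sum_{k=1}^{N} PC_{ki}\,\delta_k + \epsilon_i,$$

fitted by ordinary least squares with the kept factors $PC_k$ as
covariates (getting the degrees of freedom right, rather than testing age
on pre-residualized values). $\alpha$ has units of expression (log2) per
year of age; a gene is age-associated when the two-sided t-test on
$\alpha$ rejects, up-regulated with age if $\alpha > 0$ and down-regulated
if $\alpha < 0$. Sex is coded female = 0, male = 1; any consistent binary
coding gives identical tests. Age enters linearly in years — no spline or
quadratic term, matching the model above.

All genes share one design, so the scan is a single multi-response QR
solve, algebraically identical to gene-by-gene fits.

**Multiplicity.** P-values are adjusted by Benjamini–Hochberg within each
region separately (regions are separate analyses with separate reports),
with calls tallied at FDR 1%, 5% and 10%.

**Subsampling robustness.** To ask whether regional differences in
age-gene counts are a sample-size artifact, the cohort is repeatedly
subsampled without replacement to a target size (the smallest regional
cohort has 54 donors), and the correction plus calling is rerun per draw
(20 seeded replicates by default). Hidden factors are refit inside each
subsample by default — the factor estimates are part of the procedure
being stress-tested — with a flag to reuse the full-data factors instead.

**Cross-region concordance.** A gene's responsiveness to aging in a
region is summarized by its age-test P-value; two regions are compared by
the Spearman rank correlation of their P-value vectors over shared genes,
and the region ordering for display comes from average-linkage
hierarchical clustering of $1 - \mathrm{SCC}$.

# Pathway ("phenotype") factors

On the residual matrix, each gene set is summarized by up to
$\min(5, |{\rm set}| - 1)$ latent factors from the same engine
(intercept-only design — global structure and covariates are already
removed). Each factor is tested against age by the Pearson correlation
test; the set's P-value is the minimum over its factors, and the
Bonferroni adjustment multiplies by (number of sets tested) x (factors
per set). The extra $K$ multiplier is conservative and preserves the
family-wise error rate across both sets and factors; the number of
factors per set and their combination are package decisions, since a
Bayesian factor method leaves both open.

# Genotype-by-age interaction

Genotypes are coded 0/1/2 as the count of non-reference alleles (missing
calls `./.` are dropped pairwise per SNP; multiallelic records are
skipped and counted). SNPs require minor allele frequency above 15%,
with MAF computed from non-missing calls and folded to $[0, 0.5]$. For a
SNP–gene pair the age model is extended with an additive dosage term and
a dosage x age term; the reported P is the two-sided t-test on the
interaction coefficient. The genotype is modeled additively — no 2-df
genotypic model.

The scan draws a seeded random subset of genes (2000 by default, the
scale at which such scans stay tractable) and pairs them with SNPs in a
cis window of ±1 Mb by default; whether the original analysis paired
cis or genome-wide is not recorded, so the window is configurable and an
explicit pair list can be supplied instead. Reported pairs are those
below a nominal $P < 10^{-5}$, flagged as nominal — no multiple-testing
correction is applied at this stage, matching how such interaction scans
are reported.

# Differential variability (dispersion)

Donors are split at a boundary age: young (age ≤ 60) versus old (61–70)
by default, with the alternative 59/60 split available via
`boundary = 59` — both splits appear in the study design and the default
is a documented choice, not a claim that one is privileged. A group must
have at least 2 members to be usable (a singleton's absolute deviation is
identically zero) and the univariate test requires 3 per group.

**Univariate.** Levene's test: the one-way ANOVA F-ratio on the absolute
deviations $z_{kj} = |x_{kj} - \bar x_{k\cdot}|$ from the group *means* —
the classical mean-centered form; a median-centered (Brown–Forsythe)
variant is available but not the default. Direction compares the old and
young group variances. A gene whose within-group deviations are all zero
has an infinite F; it is reported with a degenerate flag and excluded
from the BH pool, since its P of exactly 0 would distort the FDR
adjustment of real genes.

**Multivariate.** For a gene set, each sample's Mahalanobis distance
$MD_i = \sqrt{(x_i - c)^\top \Psi^{-1} (x_i - c)}$ to the pooled centroid
is computed with a robust location/scatter estimate, and the ANOVA
F-ratio compares the distances between age groups. The distances are the
multivariate generalization of the univariate absolute deviations — both
measure how far a sample sits from a center — so comparing their group
means tests dispersion directly, and the direction call (larger mean MD
in the old group = increased dispersion) is the same quantity the F
statistic tests. On a single gene with the classical estimator this
reduces to a pooled-center variant of the univariate test; the two P's
track each other up to the centering convention. P-values come from the
F distribution (no permutation variant), and sets are BH-adjusted across
tested sets.

**Robust estimation.** The location/scatter pair is the minimum
covariance determinant estimate via FAST-MCD: 500 seeded elemental starts
($p+1$ points each), two concentration steps per start (re-estimating
mean and covariance from the $h$ smallest current distances — a step that
provably never increases the determinant), full refinement of the best 10
candidates, smallest determinant wins. The subset size defaults to
$h = \lfloor 0.75\,n \rfloor$; with $h = n$ the estimate is exactly the
classical mean/covariance, and for $h < n$ the scatter is rescaled by the
$\chi^2_p$ median consistency factor so robust distances are comparable
to classical ones under normality. Ill-conditioned candidate subsets are
skipped and retried; if every candidate is singular the error suggests a
larger $h$.

# The simulator and what passing tests mean

`simulate_dataset()` emulates one regional cohort: 80 donors by default
(the regional cohorts span 54–110), integer ages uniform on 20–70, sex
Bernoulli(0.5), BMI Normal(27, 4) truncated at 15, Hardy–Weinberg
genotypes at MAFs uniform on 0.05–0.5. Expression is assembled on the
log2 scale — baseline Normal(5, 1), planted linear age effects of
|0.02| log2 units/year (one log2 unit across the 50-year span, a
moderate, realistic effect), sex and BMI effects, structured hidden
factors with configurable age correlation, planted dosage x age
interactions, and Gaussian noise of SD 0.5 whose scale switches by age
group (ratio 3, the magnitude of the clearest two-gene dispersion
examples) for DV genes — then mapped to an RPKM-like scale through
$2^x - 1$ floored at 0 so the preprocessing round-trips. Every planted
effect is recorded in a truth object. For the false-discovery checks the
planted slope is 0.013 log2 units/year, the value at which the
Benjamini–Hochberg call has roughly 50% power at $n = 80$, so the
false-discovery proportion is estimated where discoveries actually
happen. `simulate_region_panel()` plants block-shared age genes across
regions (related regions share their block's pool; unrelated regions
share none) for the concordance machinery.

What the simulator does *not* emulate — and therefore what passing tests
cannot certify about real data: RNA-seq count noise (negative binomial
reads, library-size artifacts), linkage disequilibrium between SNPs,
correlated gene–gene networks beyond the planted factors, non-linear age
trajectories, and ancestry structure. Tests on this generator establish
that the statistical machinery is correct and calibrated under its
stated model, not that GTEx-scale effect estimates will replicate.

Verification runs use cohorts of 80 donors and 100–2000 genes, 20–100
replicates per property and 5000 replicates for the Levene null — sizes
at which every check completes in seconds to a couple of minutes while
the binomial error bands remain meaningful.

# Orchestration

`run_region()` drives preprocess → correction → age scan → pathway scan →
interaction scan → dispersion scans from one config (list or YAML), with
every threshold above as a keyed default (0.10 low-expression fraction,
K = 15, factor filter P 0.05, FDR tiers 1/5/10%, MAF 0.15, report
P 1e-5, boundary 60, MCD fraction 0.75). Each stage writes a TSV headed
by a provenance comment (package version + config hash); a manifest
records per-stage row counts and parameters, and `resume = TRUE` reuses
stage outputs whose upstream stages were not recomputed. The config hash
covers the analysis parameters, not the output directory.

# Known limitations

* The factor engine is a deterministic least-squares stand-in with the
  same two-step contract as Bayesian factor analysis; it does not
  replicate any particular implementation numerically, and automatic
  selection of $K$ is out of scope.
* An age-correlated technical confounder is flagged and *kept* in the
  data (by design — removing it could remove true age signal); analyses
  of cohorts with such structure inherit that confounding.
* The dispersion F-tests rely on the F distribution; heavy-tailed
  expression could motivate a permutation variant, which is not
  implemented.
* Gene-set dispersion testing requires fewer genes than the smaller age
  group; large sets must be reduced upstream.
* GO enrichment of result lists and semantic clustering of terms are
  outside the package.
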