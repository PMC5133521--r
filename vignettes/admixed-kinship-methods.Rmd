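---
title: "Models and methods: relatedness, structure, and association in admixed families"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: relatedness, structure, and association in admixed families}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(admixkin)
```

## The problem

Family studies in admixed populations confront two entangled sources of
genotypic correlation: recent shared ancestry within pedigrees (kinship) and
ancient shared ancestry between populations (structure). Kinship estimators
that assume a homogeneous population misread ancestry-driven allele sharing
as relatedness; association tests that ignore either source produce inflated
statistics. `admixkin` packages one coherent workflow for studying these
interactions at desk scale: a pedigree simulator with known local ancestry,
marker-selection designs, four kinship estimators plus a PC-adjusted one,
genetic relationship matrices (GRMs) and PCA, a mixed-model association scan
with admixture mapping, and a longitudinal variance model for age-varying
heritability.

Everything the package asserts about estimator behaviour is established on
its own simulations; the test suite recomputes each claim from a seeded run.

## The simulator

### Allele frequencies

Per-variant ancestral frequencies come from a configurable spectrum:
`maf_uniform(lo, hi)` or the sequencing-like mixture `maf_wgs()`, whose
default places 60 % of variants below MAF 0.01 — chosen to mirror sequencing
panels in which a majority of discovered variants are rare in founders.
Population frequencies then follow the Balding–Nichols model: for ancestral
frequency $p$ and differentiation $F_{ST}$, each population draws from
$\mathrm{Beta}$ with mean $p$ and variance $F_{ST}\,p(1-p)$. This one-knob
differentiation model is enough to create both ancestry-informative markers
(for the Homogenizing design to exclude) and structure for PC-based methods
to absorb; it does not model selection, linked drift, or site frequency
spectra beyond the two-component mixture.

### Pedigrees, haplotypes, gene dropping

`simulate_pedigrees()` builds families from one founding couple: every
couple has a fixed number of children, and children in non-terminal
generations marry newly introduced founders. Three generations with
sibship 3 yields 17 members and first- through third-degree pairs;
fourth-degree pairs (for example cousins once removed) first appear with
four generations.

Founders receive admixture proportions $q \sim \mathrm{Dirichlet}(\alpha)$.
With `linkage = TRUE` each founder haplotype is a mosaic of ancestry tracts:
breakpoints follow a Poisson process of `generations_since_admixture`
per Morgan (default 8), tract labels are drawn independently from $q$, and
alleles are Bernoulli draws from the tract population's frequency. Tract
labels are deliberately *not* given an HMM correlation along the
chromosome — independent labels are sufficient for the power and type-I
experiments here and make every length-based expectation checkable in closed
form. Meioses recombine under the Haldane model (Poisson crossovers, no
interference); ancestry labels travel with the alleles, so local ancestry is
known truth, not an inference.

With `linkage = FALSE` every marker segregates independently (each child
locus picks a parental haplotype by a fair coin, founder ancestry labels are
i.i.d. given $q$). This is the mode behind the kinship classification
benchmark, whose design calls for thousands of *independent* SNPs: on a
single linked chromosome the genome-wide realized IBD of a pair varies so
much around its pedigree expectation that classification error would mostly
reflect that biological variance rather than estimator quality.

A single autosome is the default unit; multi-chromosome studies are
concatenations of independent runs combined with
`aggregate_chromosomes()`.

### Phenotypes

`simulate_phenotypes()` generates a longitudinal, blood-pressure-like trait:

$$y_{it} = \mu + \beta_{\mathrm{med}}\,\mathrm{med}_i +
\beta_{\mathrm{smoke}}\,\mathrm{smoke}_i + \beta_{\mathrm{sex}}\,\mathrm{sex}_i
+ \textstyle\sum_v \beta_v g_{iv} + \sum_\ell \gamma_\ell a_{i\ell}
+ u_i + \varepsilon_{it},$$

with $u \sim N(0,\, 2\Phi\,\sigma^2_g)$ a subject-constant polygenic term
($\Phi$ = pedigree kinship), $\varepsilon_{it} \sim
N(0,\,\sigma^2_e(\mathrm{age}_{it}))$ independent noise whose variance is an
arbitrary positive function of age, $g_{iv}$ causal-variant dosages and
$a_{i\ell}$ local-ancestry dosages at designated loci. Medication acts as an
additive fixed effect, matching how the adjustment stage later removes it.
Ages advance deterministically per visit. The generating effect sizes are
configurable because no canonical values exist for them; power experiments
therefore report power for stated effects rather than target numbers.

## Marker-selection designs

The design pipeline reproduces the ordering *prune → filter → prune*:
greedy windowed LD pruning at $r^2 \le 0.2$, a design filter, then pruning
at $r^2 \le 0.1$ (window 50 variants and step 1 by default; the window and
thresholds are parameters, and the tests include an all-pairs oracle for the
greedy rule). The three filters:

* **Agnostic** — every 100th variant of the post-prune ordering, anchored at
  index 0 (the anchor is configurable). Frequency-blind, hence dominated by
  rare variants under a sequencing spectrum.
* **Selective** — sample MAF $\ge$ 0.05, inclusive boundary.
* **Homogenizing** — keep variant $s$ iff
  $(\max_k f_{ks} - \min_k f_{ks})/\bar f_s \le 2$ over the reference
  populations. $\bar f_s$ is the *unweighted mean* of the population-specific
  alternate-allele frequencies: the defining ratio needs an "overall
  frequency", and the unweighted mean avoids tying the design to reference
  panel sample sizes (a pooled frequency is the natural alternative). Note
  the filter uses alternate-allele, not minor-allele, frequencies, and that
  with only two reference populations the ratio never exceeds 2 — it needs
  three or more populations to discriminate.

Monomorphic variants never survive any design.

## Kinship estimators

All estimators use pairwise-complete markers and plug-in sample allele
frequencies (no finite-sample correction; the correction is tool-specific
and is exposed nowhere as a hidden default).

* **Pedigree kinship** is the exact recursion
  $\varphi_{ii} = \tfrac12(1+\varphi_{fm})$,
  $\varphi_{ij} = \tfrac12(\varphi_{fj}+\varphi_{mj})$ over a topological
  order, founders unrelated and non-inbred.
* **KING-robust** uses the between-family heterozygote/opposite-homozygote
  form with denominator $4\min(N^{(i)}_{Aa}, N^{(j)}_{Aa})$; the
  sum-denominator dialect is available via an argument. The min form is
  robust to the two members having different heterozygosities (as happens
  between ancestry groups).
* **MoM IBD** solves the identity-by-state balance equations sequentially
  ($\hat k_0$ from IBS0, $\hat k_1$ from the IBS1 surplus, $\hat k_2$ as
  remainder), clamps to $[0,1]$ and renormalizes;
  $\varphi = k_1/4 + k_2/2$. The clamping induces a small positive bias for
  unrelated pairs, visible in the tests.
* **EM-MLE IBD** maximizes
  $L(k)=\prod_s \sum_d k_d P(g_i,g_j\mid \mathrm{IBD}=d, p_s)$ over the
  2-simplex from the uniform start, stopping when the log-likelihood gain
  drops below $10^{-6}$ (cap 1000 sweeps). Because the log-likelihood is
  concave in $k$, EM converges to the global optimum; a SQUAREM-style
  extrapolation is attempted each cycle and accepted only when it does not
  lose likelihood, preserving the EM ascent guarantee while cutting the slow
  crawl to simplex vertices (unrelated pairs) by an order of magnitude. The
  inner loop is compiled (Rcpp) since the benchmark evaluates thousands of
  pairs over ~20,000 markers.
* **PC-Relate-style estimation** first partitions samples with the greedy
  unrelated-set rule (`pcair_partition()`, threshold 0.025; ties remove the
  candidate whose removal retains the least kinship, then lowest id), builds
  PCs on the unrelated set and projects everyone (`pcair_scores()`), then
  regresses each marker on the PCs over the unrelated set to form
  individual-specific frequencies $\hat\mu_{is}$, truncated to
  $[\varepsilon, 1-\varepsilon]$ with $\varepsilon = 1/(2n)$ so denominators
  stay positive.

Cross-chromosome aggregation is a weighted mean with marker counts as
weights (the natural reading of a "weighted average of chromosome-specific
estimates"; the weights are not otherwise documented anywhere), and negative
aggregated estimates are set to zero — clamping after aggregation by
default, per chromosome behind a flag.

Classification rounds $\hat\varphi$ to the nearest of
$\{0.25, 0.125, 0.0625, 0.03125, 0\}$; exact midpoints go to the more
distant degree, a conservative choice against overstating relatedness.
Truth categories come from exact pedigree kinship; pairs with
$0 < \varphi < 0.015625$ (beyond fourth degree but not unrelated) are
excluded from rate tables so the five categories stay pure.

### The classification benchmark

`kinship_classification_benchmark()` is the package's standard experiment:
20 three-generation pedigrees (~340 subjects), two ancestral populations at
$F_{ST}=0.1$, Dirichlet(3, 1) admixture, 20,000 independent common SNPs
(ancestral MAF uniform on [0.05, 0.5]), Selective design, then
classification rates per true degree. All within-pedigree pairs are
evaluated; unrelated rates use a seeded subsample of 3,000 cross-pedigree
pairs — the subsample estimates the same rate at a fraction of the EM cost.
The PC-adjusted estimator uses 2 PCs, matching the single axis of structure
in a two-population simulation plus slack.

## GRMs, PCA, and ancestry capture

Two normalizations of the empirical GRM are provided, both on minor-allele
dosages with missing genotypes mean-imputed inside the construction only:

$$\psi^{\mathrm{ratio}}_{ij} =
\frac{\sum_s (G_{is}-2\hat p_s)(G_{js}-2\hat p_s)}{\sum_s 2\hat p_s(1-\hat p_s)}
\qquad
\psi^{\mathrm{marker}}_{ij} =
\frac1S \sum_s \frac{(G_{is}-2\hat p_s)(G_{js}-2\hat p_s)}{2\hat p_s(1-\hat p_s)}.$$

The ratio-of-sums form downweights rare variants by construction and needs
no frequency floor; the per-marker (EIGENSTRAT-style) form excludes variants
with $\hat p_s < 1/(2n)$ to avoid division blow-up. PCA is the
eigendecomposition of the raw GRM by default (centering is an option; the
raw matrix is already approximately centered when built from sample
frequencies), with eigenvector signs fixed by making the largest-magnitude
coordinate positive. `ancestry_r2()` regresses each ancestry proportion on
an intercept plus the top 10 or 20 PCs and reports $R^2$.

MAF partitions into "rare" and "common" follow strict inequalities
(< 0.01 or < 0.05 vs > 0.01 or > 0.05); boundary values fall in neither
set, and the tests pin this reading down.

One structural caution the package's experiments make explicit: with exact
simulated proportions that sum to one, any two well-captured ancestry axes
determine the third, so a "rare-variant population" can only be captured
*worse* by common-variant PCs when its proportion axis varies independently
of the others and its divergence genuinely lives in rare variants. The
structure tests construct exactly that geometry.

## Mixed-model association

`fit_null_lmm()` fits $y = X\beta + g + e$, $g\sim N(0,\sigma^2_g K)$,
$e\sim N(0,\sigma^2_e I)$ by REML (ML behind a flag), via one symmetric
eigendecomposition of $K$ and a 1-D optimization over
$h^2=\sigma^2_g/(\sigma^2_g+\sigma^2_e)$. Negative eigenvalues beyond
$-10^{-8}$ (relative) are an error; smaller ones are clipped to zero. When
the criterion is flat at $h^2=0$ (e.g. $K \propto I$) the boundary is
reported with $\sigma^2_g = 0$ and a flag. Per-marker tests are Wald tests
under GLS with the variance components held at the null estimates — the
EMMAX approximation — with two-sided p-values from the large-sample normal;
collinear predictors are flagged and p-values below the smallest positive
normal double are floored and flagged. Genomic control is
$\lambda = \mathrm{median}(\chi^2_1)/0.4549364$.

Thresholds: Bonferroni $\alpha/m$ for SNP-dosage scans, and twice the
genome-wide nominal pointwise value ($2\times 7\times10^{-6} =
1.4\times10^{-5}$) for admixture mapping, implemented literally as $2p_0$
with no recomputation of effective tests.

Admixture mapping scans each ancestral population separately on its
local-ancestry dosage (0/1/2 transmitted copies), with relatedness from the
PC-adjusted estimator and, in the package's calibration experiments, global
ancestry as a fixed covariate — without it, every locus shares the global
ancestry factor and per-genome error rates lose their meaning. The
calibration experiment represents a genome by
$\lceil 0.05 / 1.4\times10^{-5}\rceil = 3{,}572$ effectively independent
ancestry loci, the number at which a calibrated pointwise test yields a
family-wise rate of 0.05. Two honest caveats, both visible in the tests:
with a few hundred subjects the plug-in EMMAX statistic is mildly
conservative that far in the tail (the estimated variance contains the
tested direction, a self-normalization effect that thins extreme values),
and correlated loci make the per-genome hit count overdispersed relative to
binomial; the acceptance check therefore uses a wide binomial interval
around 0.05 rather than a point equality. A 2-df joint ancestry test is
deliberately not implemented.

## Longitudinal variance curves

`adjust_trait()` residualizes the trait on medication, smoking, sex, and
smoking- and sex-specific cubic age splines. `fit_variance_curves()` then
maximizes the Gaussian likelihood of

$$y_{it} = x_{it}\beta + \sigma_g(\mathrm{age}_{it})\,u_i + \varepsilon_{it},
\quad u \sim N(0, 2\Phi), \quad
\varepsilon_{it}\sim N(0, \sigma^2_e(\mathrm{age}_{it})),$$

with $\log\sigma^2_g(\cdot)$ and $\log\sigma^2_e(\cdot)$ cubic B-splines in
age (boundary knots at the 5th/95th age percentiles, 2 internal knots by
default, 0 knots giving the constant-variance submodel). Modeling *both*
variances on the log scale is a deliberate symmetric treatment: it
guarantees positivity for the additive curve as well, at the cost of a
non-literal reading of "additive variance as a function of splines". The
genetic term is a single subject-level factor scaled by $\sigma_g$(age) — a
rank-1 cross-age covariance, $\mathrm{Cov}(y_{it}, y_{jt'}) =
2\Phi_{ij}\sigma_g(a_{it})\sigma_g(a_{jt'})$ — because nothing pins down the
cross-age genetic correlation structure and rank-1 keeps the likelihood
well-defined and testable; visits are conditionally independent given that
factor. Fixed effects are profiled by GLS inside the likelihood; BFGS with
seeded random restarts optimizes the spline coefficients;
$h^2(\mathrm{age}) = \sigma^2_g/(\sigma^2_g+\sigma^2_e)$ pointwise, with
95 % bands from a parametric bootstrap (200 replicates by default — chosen
over the delta method as assumption-light at the price of runtime; the
tests exercise a reduced replicate count and check band shape, and full
coverage calibration is left to users running overnight).
`per_visit_heritability()` is the cross-sectional counterpart through the
null mixed model.

Identifiability at desk scale deserves honesty: the effective information
about $\sigma^2_g$ scales with the number of families, not subjects. The
package's recovery experiments use 15–25 pedigrees with 3–4 visits (450–750
observations); below that, single realizations can legitimately prefer a
flat or even locally increasing heritability curve, which is sampling error,
not an optimizer defect — the tests were sized so the imposed signal
dominates.

## Pipeline and reproducibility

`run_pipeline()` executes simulate → designs → kinship → pca → assoc →
admixmap → longitudinal → report from one configuration (an R list or YAML
file), writes plain-text artifacts plus the effective configuration, and is
byte-reproducible for a fixed master seed. Per-stage seeds derive
deterministically from the master seed by stage-name hashing so a stage can
be rerun alone. `benchmark_report()` assembles the design × estimator ×
degree rate table and the MAF-partition × ancestry $R^2$ table from a run.

## Known limitations

* No genotyping error, missingness process, or variant-QC model; missing
  genotypes are propagated, never imputed, outside GRM construction.
* Ancestry tracts lack cross-tract correlation; no crossover interference;
  no sex-specific maps; sex chromosomes unsupported.
* The Homogenizing design requires per-population frequencies (truth or a
  reference table); with two populations it cannot discriminate.
* Multi-allelic variants are rejected (or dropped on request), never split.
* Map positions outside the framework map are clamped to boundary cM values
  rather than extrapolated — slope extrapolation can produce negative or
  runaway map positions.
* The EM-MLE estimator assumes non-inbred pairs (no inbreeding
  coefficients), and the plain 2-simplex is used without further
  admissibility constraints on $(k_0,k_1,k_2)$.
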