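# admixkin

Kinship estimation, population structure, and mixed-model association in
admixed families — with a simulator that knows the truth.

Estimating how related two people are is harder when their genomes mix
several ancestral populations: allele frequencies differ across populations,
and estimators that plug in a single set of frequencies misread shared
ancestry as shared family. `admixkin` is a desk-scale laboratory for this
problem. It simulates multi-generation admixed pedigrees with known local
ancestry, then runs the full downstream workflow on them, so every method's
accuracy can be measured against truth:

* **Simulator** — Balding–Nichols differentiated allele frequencies
  (per-population Beta with mean *p* and variance *F*<sub>ST</sub>·*p*(1−*p*)),
  Dirichlet founder admixture, Poisson ancestry tracts, Haldane-model gene
  dropping, and longitudinal phenotypes with polygenic covariance 2Φσ²_g and
  age-dependent environmental variance.
* **Marker designs** — greedy LD pruning (r² ≤ 0.2 then ≤ 0.1) composed with
  an *Agnostic* (every 100th variant), *Selective* (MAF ≥ 0.05), or
  *Homogenizing* (max frequency spread / mean ≤ 2 across reference
  populations) filter.
* **Kinship** — exact pedigree recursion; KING-robust
  (φ̂ = ½ + (2N<sub>Aa,Aa</sub> − 4N<sub>AA,aa</sub> − N⁽ⁱ⁾<sub>Aa</sub> −
  N⁽ʲ⁾<sub>Aa</sub>) / 4min(N⁽ⁱ⁾<sub>Aa</sub>, N⁽ʲ⁾<sub>Aa</sub>));
  method-of-moments IBD (k₀,k₁,k₂ from IBS balance); EM maximum-likelihood
  IBD on the probability simplex (compiled inner loop, ascent-preserving
  acceleration); and a PC-adjusted moment estimator with
  individual-specific allele frequencies fit on a greedily chosen unrelated
  set. Pairs are classified by rounding φ̂ to the nearest of
  {0.25, 0.125, 0.0625, 0.03125, 0}.
* **Structure** — ratio-of-sums and per-marker-standardized GRMs, PCA, and
  R² of ancestry proportions on the top 10/20 PCs for rare/common MAF
  partitions.
* **Association** — EMMAX-style scan (REML variance components estimated
  once by 1-D optimization after an eigendecomposition; per-marker GLS Wald
  tests), admixture mapping on local-ancestry dosages at the 2×7×10⁻⁶
  threshold, Bonferroni thresholds, genomic-control λ.
* **Longitudinal** — fixed-effect trait adjustment (medication, smoking,
  sex, and smoking-/sex-specific age splines) and age-varying heritability
  h²(age) = σ²_g(age)/(σ²_g(age)+σ²_e(age)) with both log-variance curves as
  cubic B-splines, fit by profiled Gaussian likelihood with bootstrap bands.

See `vignettes/admixed-kinship-methods.Rmd` for the models, assumptions, and
every numerical choice.

## Worked example

Simulate six admixed three-generation pedigrees, build a common-variant
panel, estimate kinship with the PC-adjusted estimator, and classify every
pair against the pedigree truth:

```r
library(admixkin)

sim <- simulate_family_study(n_pedigrees = 6, generations = 3, sibship = 3,
                             n_variants = 6000, fst = c(0.1, 0.1),
                             alpha = c(3, 1), linkage = FALSE, seed = 42)
stats <- compute_variant_stats(sim$genotypes, sim$ped)
panel <- subset_variants(sim$genotypes, design_selective(stats)$kept)
panel
#> genotype_matrix: 102 samples x 5404 variants
#> chromosomes: 1

Phi  <- pedigree_kinship(sim$ped)
part <- pcair_partition(Phi)
pcs  <- pcair_scores(panel, part$unrelated, n_pcs = 2)
kin  <- pcrelate(panel, pcs$scores, part$unrelated, n_pcs = 2)

truth  <- true_degree(Phi[cbind(kin$i, kin$j)])
called <- classify_relationship(pmax(kin$kinship, 0))
classification_table(truth, called)
#>      degree n_pairs      rate
#> 1       1st     216 0.9120370
#> 2       2nd     216 0.6712963
#> 3       3rd     162 0.2962963
#> 4       4th       0        NA
#> 5 unrelated    4557 0.9486504
```

At this deliberately small scale (102 subjects, ~5,400 SNPs) first-degree
pairs and unrelated pairs are already classified well, second-degree pairs
are noisy, and third-degree pairs are mostly beyond reach — estimator noise
of a few hundredths of kinship spans the gap between adjacent degrees. The
package's standard benchmark (`kinship_classification_benchmark()`, 20
pedigrees and 20,000 independent common SNPs) pushes first/second-degree and
unrelated classification above 99 % for both the EM-MLE and PC-adjusted
estimators.

Heritability of a simulated longitudinal trait at the first visit
(generating model: σ²_g = 12, σ²_e(age) = 20 + 0.3·age, so true first-visit
h² ≈ 0.26 at the mean age):

```r
cfg <- phenotype_config(sigma_g2 = 12, sigma_e2_curve = function(a) 20 + 0.3 * a)
ph  <- simulate_phenotypes(sim$genotypes, sim$ancestry, sim$ped, cfg, seed = 43)
adj <- adjust_trait(ph, n_knots = 1)
per_visit_heritability(adj, Phi, visit = 1)$h2
#> [1] 0.269
```

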