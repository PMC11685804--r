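---
title: "Models and methods behind caneGS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind caneGS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

caneGS implements the statistical machinery of genomic selection for a
multi-stage clonal breeding program: adjusted means and heritability from
multi-environment trials, relationship matrices from pedigree and marker
data, a battery of whole-genome prediction models, multi-trait prediction of
a compound trait, and validation schemes with predictive ability and
coincidence metrics. This vignette records the models, the defaults, and the
design decisions a user should know before trusting the output.

## The trial model and BLUEs

Phenotypic records from stage trials follow

\[
Y_{ijkl} = \mu + E_i + R_{ij} + C_k + EC_{ik} + G_l + GC_{kl} + GE_{il} +
GCE_{ikl} + \varepsilon_{ijkl},
\]

where \(E\) is the environment (location-year), \(R\) the replicate nested
in environment, \(C\) the crop type (plant cane or ratoon), and \(G\) the
genotype. `compute_blues()` treats genotype as fixed and every other term as
random — the standard choice when the adjusted means are to be reused as a
response downstream — while `broad_sense_h2()` refits the same model with
genotype random. Terms without at least two observed levels (a single crop,
an unreplicated stage, one environment) are dropped automatically, so the
same presets serve combined and stratified subsets. Missing factor cells are
simply absent rows; no cell imputation is attempted.

Broad-sense heritability uses the plot-count-adjusted form

\[
H^2 = \frac{\sigma^2_G}{\sigma^2_G + \sigma^2_{GE}/\tilde n_E +
\sigma^2_{GC}/\tilde n_C + \sigma^2_{GEC}/\tilde n_{EC} +
\sigma^2_e/\tilde n_{ECr}},
\]

with \(\tilde n\) the harmonic means of the per-genotype counts of
environments, crops, environment-by-crop cells and records
(`harmonic_means()`). Narrow-sense heritability (`narrow_h2()`) is
\(\sigma^2_A/(\sigma^2_A+\sigma^2_e)\) from a single-kernel REML fit under a
pedigree **A** or marker **G** matrix, on the plot basis by default.

## The REML engine

`reml_fit()` handles \(y = Xb + \sum_i Z_i u_i + e\) with
\(u_i \sim N(0, \sigma^2_i K_i)\) for known (possibly identity) \(K_i\).
Three numerical choices matter:

* **Eigen-reparameterization.** Every kernel term is rewritten as
  \(u = U s\), \(s \sim N(0, \sigma^2 D)\), with \(UDU'\) the
  eigendecomposition of \(K\) restricted to its range (eigenvalues below
  \(10^{-10}\) of the largest are dropped). Centered genomic relationship
  matrices are always singular; inverting them (as the textbook mixed-model
  equations require) is ill-conditioned enough to break the monotonicity of
  EM in double precision. The reparameterized equations have a diagonal
  prior block and are exact, because \(u\) lies in the range of \(K\) almost
  surely.
* **Solvers.** Single-random-term models use an exact profiled REML via a
  one-time spectral decomposition of the mean-projected covariance (the
  classic efficient mixed-model association trick); the variance ratio is
  optimized on a log grid plus local refinement, so no iteration failure is
  possible. Multi-term models use EM-REML with average-information (AI)
  acceleration; AI proposals that would decrease the restricted likelihood
  are halved and ultimately replaced by an EM step, components pinned at the
  boundary are excluded from the AI system, and multi-kernel genetic models
  are warm-started from the exact single-kernel optimum of their first
  kernel. The warm start matters: the \(G/GG\) kernel family is so collinear
  that a cold-started ascent can stall on a likelihood ridge below the
  nested single-kernel optimum.
* **Bounds and convergence.** Components are floored at \(10^{-8}\) times
  the phenotypic variance; convergence is declared at a relative restricted
  log-likelihood change below `tol` (default \(10^{-6}\), at most 200
  iterations). Rank-deficient fixed designs are resolved by dropping aliased
  columns (first level as reference), reported in the fit.

## Relationship matrices

* Additive (`build_grm(kind = "additive")`): dosages centered by twice the
  observed allele frequency, \(G_A = WW'/\sum 2p_jq_j\). Frequencies are
  recomputed after mean imputation; the panel's own frequencies are the
  centering reference.
* Dominance (`"dominance"`): the breeding-model coding
  \((-2p^2,\; 2pq,\; -2q^2)\) for dosages (0, 1, 2), scaled by
  \(\sum (2p_jq_j)^2\). Fractional (imputed) dosages interpolate linearly
  between the three codes.
* Epistasis (`hadamard_kernels()`): \(G_{AA} = G_A \circ G_A\) and
  \(G_{AD} = G_A \circ G_D\), positive semi-definite by the Schur product
  theorem, rescaled to mean diagonal 1 (switchable) so variance components
  are comparable across kernels.
* Pedigree (`amatrix()`): Henderson's tabular method; pedigrees are
  topologically sorted on construction, cycles are an error. An independent
  gene-dropping Monte Carlo (`gene_drop_amatrix()`) is shipped for
  verification.
* Single-step (`hmatrix()`): the hybrid matrix combining `A` over all
  individuals with a genomic `G` over the genotyped subset, with a blending
  weight `tau_blend` (default 0.05; the source literature is silent, and a
  small pedigree share keeps \(G^*\) invertible).

Genotype QC follows the panel conventions: markers with more than 20%
missing calls or minor allele frequency below 10% are dropped
(`filter_markers()`), markers in complete LD collapse to the first
representative in map order (`dedup_complete_ld()`, exact via hashing of
sign-canonicalized standardized columns), and density sweeps use greedy
in-map-order pruning (`ld_prune()`): a marker survives if its squared
dosage correlation with every previously kept marker in a trailing window
(default 50 kept markers) stays below the threshold. Greedy in-order
pruning is deterministic and reproduces the expected monotone marker counts;
the pruning algorithm behind published marker counts is rarely specified, so
this is a declared choice. LD is computed on unphased dosages (composite
LD).

## Prediction models

`gblup_fit()` fits any subset of the kernel family \(\{G, D, GG, GD, H\}\)
plus optional fixed covariates; the genome-wide heterozygosity covariate
(fraction of dosage-1 markers, centered) is the usual adjustment for
heterosis-like mean effects in clonal panels. The reported GEBV is the sum
of all kernel BLUPs — the total genotypic value — rather than the additive
part only; for clonal selection the whole genotypic value is transmitted,
and the choice is switchable by summing individual `blups` components.
Unphenotyped genotypes present in the kernels are predicted through the
covariance automatically.

`rrblup_fit()` solves the equivalent marker-effect ridge model with the
variance ratio from exact REML; its GEBVs are identical to additive GBLUP
(the equivalence is asserted in the tests at \(r \ge 0.999\)).

`bayes_fit()` implements BRR, Bayesian lasso, BayesA, BayesB and BayesC as
compiled single-site Gibbs samplers. Default chains are 12,000 iterations,
2,000 burn-in, thinning 5 (2,000 retained draws). "Default
hyper-parameters" are instantiated the way the established Bayesian
regression packages do it: 5 prior degrees of freedom for every variance,
scales chosen so each term's prior explains \(R^2 = 0.5\) of the phenotypic
variance, and a Beta(5, 5) prior (mean 0.5) on the inclusion probability of
the spike-and-slab priors. The Bayesian lasso's penalty gets a Gamma
hyperprior anchored at the standard starting value. `rkhs_fit()` fits a
Gaussian kernel \(\exp(-h\,\bar d^2)\) on mean-scaled squared Euclidean
marker distance (default bandwidth \(h = 1\); a single kernel, no kernel
averaging) by Gibbs sampling in the kernel eigenbasis. `ml_fit()` wraps
random forest and radial-kernel epsilon-SVR on raw dosages.

`gwas_scan()` is a single-locus mixed linear model: variance components are
estimated once on the markerless null model (exact spectral REML), then
each marker receives a generalized-least-squares Wald test in the whitened
data. This is the standard population-parameters-previously-determined
approximation; compression/enrichment refinements of some GWAS toolkits are
intentionally not reproduced. Markers with \(p < 0.001\) feed
`gs_with_fixed_snps()` as fixed covariates ("G+S"); the scan must be
computed on the training genotypes only, and the fit refuses leaky scans
unless explicitly overridden. With an empty selection the model falls back
to plain GBLUP with a message.

## Multi-trait prediction

`mvgblup_fit()` estimates the Kronecker model
\(\alpha \sim MVN(0, \Sigma \otimes K)\), \(\varepsilon \sim MVN(0, R
\otimes I)\) with unstructured \(\Sigma\) and diagonal \(R\) by REML EM in
the eigenbasis of \(K\) after projecting out trait means; traits are
standardized internally and back-transformed on output (yields and quality
traits differ by orders of magnitude in scale). \(\Sigma\) is repaired to
the PSD cone after every M-step. Missing cells — the hidden target trait of
the validation set — are handled by an outer loop that re-imputes them with
their conditional expectation in the full \(\Sigma \otimes K + R \otimes I\)
system; this slightly shrinks the imputed cells and with them the masked-
cell variance, a bias accepted for its robustness and documented here.
Final predictions are exact BLUPs at the converged estimates. A single
trait is delegated to the single-kernel spectral REML, so the collapse to
ordinary GBLUP is exact. `bmtm_fit()` samples the same model (inverse-
Wishart on \(\Sigma\), per-trait scaled-inverse-\(\chi^2\) residuals, data
augmentation for missing cells); residual updating is joint across traits
via simultaneous diagonalization.

`predict_hidden_trait()` reproduces the multi-trait selection scheme for a
compound trait: the target is masked on the validation genotypes while the
chosen secondary traits stay observed there, and a single-trait baseline is
fitted alongside. Genomic data of all genotypes are always used; only
phenotypes are masked.

## Validation

Fivefold cross-validation (`kfold_split()`, seed-deterministic partition),
cross-stage schemes (train on an early stage's BLUEs, predict a later
stage's genotypes from genomic data alone), predictive ability (Pearson
correlation of GEBVs with BLUEs), and top/bottom 20% coincidence indices
with tail size \(\lceil n \cdot \text{fraction}\rceil\) and stable id-order
tie-breaking. Metrics are averaged across folds (not pooled) by default.
Genotypes shared between training and test stages stay in training only —
the leakage-safe choice — with `keep_overlap = TRUE` available to emulate
analyses where the overlap is part of the design. Any training-fitted
preprocessing (the association scan of G+S) is refitted inside each fold.
`marker_density_sweep()` evaluates the LD thresholds
\(r^2 < 0.1, 0.15, 0.2, 0.3, 0.4, 0.6, 0.8, 0.99\) used in marker-density
studies.

## The synthetic data generator

`sim_config()` defaults describe the reference study conditions: 567
genotypes funnelled through four stages (environment counts 2/8/7/14,
replications 1/2/2/3, plant cane plus two ratoons, heavy/light soils), and
a 20,451-SNP biallelic panel on 10 chromosomes. Design choices:

* **Genotypes** are diploid dosages \(\{0,1,2\}\): complex polyploid dosage
  calling collapses to pseudo-diploid calls in practice, and the VanRaden /
  Vitezica formulas downstream assume diploid coding. Polyploid dosage
  models are out of scope.
* **LD** comes from a Gaussian-copula AR(1) latent haplotype per block
  (within-block correlation `ld_decay^distance`, default 0.9; blocks of 20
  markers), which yields the distance-decaying \(r^2\) a density sweep
  needs without coalescent machinery. Every marker is in Hardy-Weinberg
  proportion, so the VanRaden diagonal averages 1 by construction.
* **Traits.** Four latent traits (TRS, NS, SW, Fiber) are built from
  additive, dominance and pairwise epistatic marker effects with a
  configurable genetic correlation among the additive parts (default:
  near-diagonal with the well-known negative NS-SW trade-off, -0.32). Cane
  yield and sugar yield are the deterministic products
  \(CY = NS \times SW\) and \(SY = CY \times TRS / 1000\) — the /1000
  converts TRS in kg/Mg to Mg — at both the genotypic and the record level,
  exactly as the field derives them from measurements. The product's
  departure from the product-of-additive-parts is booked as epistatic, which
  keeps the additive/dominance/epistasis decomposition exact for all six
  traits.
* **Trials** add environment, replicate, crop and interaction effects plus
  a plot residual on the standardized latent scale (defaults 1.0, 0.1, 0.3,
  0.2 for the design mains; 0.2/0.1/0.1 for GE/GC/GCE; residual 1.0 —
  interaction shares far below the main effects, as multi-environment cane
  trials typically show). Between stages genotypes advance by truncation on
  the previous stage's phenotypic mean of one selection trait (default SY);
  real programs select visually on several traits, which is not modeled.
  Entry fractions default to 1/0.5/0.25/0.1 — the published entry counts of
  staged programs reflect operational decisions, not a rule, so the funnel
  is a free parameter.
* **Missing genotypes** are injected completely at random; the QC filter
  operates on missing rate only, so an informative missingness model would
  add nothing testable.

What passing tests on these data do *not* show: robustness to polyploid
dosage error, to population structure beyond a single panel, to
non-Gaussian residuals, or to the spatial field trends that real stage-2
augmented designs carry. The generator is a correctness instrument, not a
field simulator.

## Problem sizes used in the shipped checks

The automated checks run the models at reduced but non-trivial sizes chosen
as the smallest panels where the examined signal clearly separates from
sampling noise: equivalence and sampler checks at 200 genotypes with
500-1000 markers; heritability recovery at 450 genotypes over 30 replicate
simulations per level; the density sweep at 5,000 markers with 200 causal
loci; multi-trait gains over 20 replicate simulations at 200-220 genotypes.
The full-scale defaults (567 genotypes, 20,451 markers) run through the
same code paths unchanged.

## Known limitations

* EM/AI REML on crossed-factor trial models builds dense mixed-model
  equations; tables with many thousands of genotype-by-environment levels
  will be slow (sparse factorization is the natural extension).
* The Bayesian lasso uses a fixed-anchor Gamma hyperprior on the penalty
  rather than a fully hierarchical treatment.
* `mvgblup_fit()`'s missing-cell EM is an imputation approximation (see
  above); `bmtm_fit()`'s data augmentation is exact in distribution but
  slower to mix.
* Spatial row-column adjustment of unreplicated early stages and
  factor-analytic multi-trait structures are out of scope.
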