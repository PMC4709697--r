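---
title: "Genomic selection with in silico 2b-RAD panels: models and simulation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genomic selection with in silico 2b-RAD panels: models and simulation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(radgs)
```

## Scope

`radgs` evaluates how well reduced-representation (2b-RAD) marker panels
support genomic selection. It provides (i) an in silico genotyping layer --
simulated genomes, SNP injection, BsaXI restriction-tag discovery and marker
panels at three densities; (ii) a forward-in-time breeding simulator with
heritability-controlled phenotypes; (iii) seven genomic prediction models
implemented from first principles; and (iv) cross-validated and
over-generation accuracy evaluation. This vignette documents the models,
the simulation design choices and their rationale, and the package's known
limitations.

## The shared linear model

All estimators operate on

$$ y = \mu + Zw + Xg + e, $$

where $y$ is the phenotype vector, $w$ a vector of family effects with
incidence matrix $Z$ (treated as fixed; dropped automatically when the data
contain one family), $X$ the marker design matrix coded 0/1/2 by copies of
the alternate allele (AA, AB, BB), $g$ the marker effects and
$e \sim N(0, \sigma_e^2 I)$. Marker columns are centred by twice the
training allele frequency $2p_j$ before fitting; predictions for new
individuals use the training-set frequencies, so no information flows from
a validation set into a fit.

The estimators differ in what they assume about $g$:

* **Pedigree BLUP** replaces $Xg$ by a genetic value $u \sim N(0,
  \sigma_a^2 A)$ with $A$ the numerator relationship matrix from the tabular
  method. No markers are used.
* **G-BLUP** uses $u \sim N(0, \sigma_a^2 G)$ with the VanRaden genomic
  relationship matrix $G = X_c X_c' / (2\sum_j p_j(1-p_j))$.
* **RR-BLUP** is ridge regression of $y$ on all markers with one common
  shrinkage $\lambda = \sigma_e^2 / \sigma_g^2$, $\sigma_g^2 = \sigma_a^2 /
  \sum_j 2 p_j (1-p_j)$, solved through the $n \times n$ dual system. With
  this $k$, RR-BLUP and G-BLUP produce algebraically identical GEBVs; the
  identity (to $10^{-8}$) is the central internal oracle of the model
  module. A per-marker $k_j = 2p_j(1-p_j)$ variant is selectable, but the
  summed form is the default because it restores the duality that the
  G-BLUP scaling implies.
* **BayesA** gives every marker its own variance,
  $g_j \mid \sigma_{gj}^2 \sim N(0, \sigma_{gj}^2)$ with
  scaled-inverse-$\chi^2(\nu, S)$ priors; marginally the effects are
  scaled-$t$.
* **BayesB** adds a point mass: $g_j = 0$ with prior probability $\pi_g$
  and BayesA-distributed otherwise. Indicators are Gibbs-sampled from the
  marginal likelihood ratio with the effect integrated out; posterior
  inclusion probabilities are reported. $\pi_g = 0$ recovers BayesA.
* **Bayesian LASSO** places a double-exponential prior on $g_j$ through the
  normal scale-mixture representation
  ($g_j \mid \tau_j^2 \sim N(0, \sigma_e^2 \tau_j^2)$, exponential mixing),
  with $\lambda^2$ fixed or given a Gamma hyperprior updated by its full
  conditional.
* **LASSO** minimises $\frac{1}{2n}\lVert y - Wb - Xg\rVert^2 + \lambda
  \lVert g \rVert_1$ by cyclic coordinate descent with warm starts; the
  penalty is chosen by internal cross-validation on the training split
  only.

Variance components for the BLUP family come from REML, profiled over the
ratio $\sigma_a^2/\sigma_e^2$ using the spectral decomposition of the
relationship matrix projected onto the orthogonal complement of the
fixed-effect space. The projection uses an explicit orthonormal basis of
that complement (not a size-ranked eigenvector subset), which keeps the
restricted likelihood exact when $G$ is rank-deficient -- as it always is
when markers are fewer than records or the population is family-structured.
Standard errors come from the numerical observed information; heritability
SEs by the delta method. Boundary estimates are flagged, not errors.

### MCMC settings

Default chains are 10,000 iterations with 2,000 burn-in and thinning 5;
prior degrees of freedom $\nu = 4.2$ with scale $S$ chosen so that the
prior mean locus variance spreads half the phenotypic variance over the
markers; $\pi_g = 0.95$; residual prior df 4 with scale matched to half the
phenotypic variance. Chains are bit-reproducible given a seed, and a
split-chain potential-scale-reduction diagnostic on $\sigma_e^2$ is
reported with each fit. For the replicated benchmark experiments the
package uses 800-iteration chains (250 burn-in): posterior-mean GEBVs -- the
only quantity those experiments consume -- stabilise within a few hundred
iterations, and we verified that accuracies change by less than 0.01
between 500 and 2,500 iterations on the family-scale design.

## In silico 2b-RAD genotyping

BsaXI is a type IIB enzyme whose tags are modelled as the 29-base pattern
`N10-AC-N5-CTCC-N8`; both strands are searched (the reverse-complement
motif has the `GGAG...GT` core) and tags sharing an interval are
deduplicated. All coordinates are 0-based half-open; a SNP at position $p$
belongs to a tag $[s, s+29)$ iff $s \le p < s + 29$. Reduced tag
representation (RTR) keeps tags whose first base is A and whose last is T,
emulating selective `5'-NNA-3'` adaptor overhangs; under uniform base
composition 1/16 of tags survive. The observed survival fraction in a real
genome depends on its base composition, so the package enforces the literal
flank rule rather than a fixed fraction.

Marker panels: **HD** picks a configurable number of SNPs by even genomic
spacing; **MD** is the SNPs inside BsaXI tags; **LD** the SNPs inside RTR
tags (LD is a subset of MD by construction). On a uniform simulated genome
the raw in-tag SNP density is higher than the target densities of the
full-scale design, so MD/LD are randomly subsampled to the target markers
per Mb.

## Simulation designs

Two desk-scale designs reproduce the evaluation experiments. Scaling
preserves *densities* (markers, QTLs per Mb) and *population structure*
(family sizes, parent counts), which are the quantities the evaluation
depends on, rather than absolute genome size.

**Population-based design** (`sim1_study()`): a 20 Mb genome in 10
chromosomes (1 cM/Mb), SNPs injected at 2%, tags located, MD/LD panels at
50 and 5 markers/Mb and QTLs at ~5/Mb (mirroring 5,000 QTLs on a ~1 Gb
genome, and matching the LD panel 1:1); Fisher-Wright burn-in for 1,000
generations at N = 500 with symmetric mutation at $10^{-5}$; then 100 sires
and 100 dams mated in pairs with 20 offspring each to give G1 (n = 2,000),
repeated from G1 to give G2. QTL effects are N(0, 1).

**Family-based design** (`sim2_study()`): only the tracked loci are
simulated, placed on a 19-chromosome map of 25 cM each -- the map span over
which 2,364 markers occur at the LD-panel density of ~5 markers/cM -- with
the QTL count equal to the marker count (both ~5/Mb at full scale). After
the same burn-in, 10 males and 10 females produce 20 full-sib families of
50 (each parent in two matings); subsets of families give the smaller
sample sizes. The third design reuses this machinery with 5 families and a
trait carrying dominance.

Burn-in tracks a 2.5-fold surplus of candidate loci and draws panels and
QTLs among loci still polymorphic afterwards, because roughly half of the
initial loci fix over 1,000 generations of drift at N = 500; this keeps
panel sizes and QTL counts at their nominal values at phenotyping time.

Phenotypes are genetic values plus normal error with
$\sigma_e^2 = \sigma_A^2 (1-h^2)/h^2$, where $\sigma_A^2$ is the realized
additive variance of the phenotyped individuals -- so the target $h^2$ is
met exactly in each dataset rather than on average. With dominance, the
phenotypic variance shares are additive $h^2$, dominance $d^2$ and residual
$1 - h^2 - d^2$; the interpretation of "additive and dominance shares both
0.3" as shares of *phenotypic* variance is the package default (shares of
genetic variance are obtainable by rescaling the inputs). Dominance
deviations are rescaled at phenotype time, where the realized variances are
known.

## Evaluation

Cross-validation is k-fold (default 5) with `repeats` independent random
partitions; every individual is validated exactly once per partition. QC
(MAF > 5%, call rate >= 70%) and mean imputation run inside each training
split, and validation genotypes are imputed with training-set means.
Accuracy is the Pearson correlation between predicted breeding values and
true breeding values (simulations) or phenotypes (empirical mode; then
divided by $\sqrt{h^2}$, the adjustment implemented by
`adjusted_accuracy()`). The prediction for a validation individual of a
known family includes the estimated family effect plus the genomic value;
for over-generation prediction (train G1, predict G2) the G2 families are
new, so predictions are purely genomic through the train-validation
relationship block. The family term is used where the dataset is
family-structured by design (the family-based and empirical-style
analyses); the population-based design fits no family term, because in a
randomly mated 2,000-individual population the 100 sib groups are not a
meaningful fixed effect and relationship information enters through the
markers themselves. TBV is the additive value only -- dominance deviations
are excluded from the breeding value by definition. The regression slope
of phenotype on EBV is reported as a bias measure.

## The synthetic five-family dataset

The empirical-style analyses run on a synthetic stand-in: 349 individuals
in five families (sizes 72, 70, 70, 69, 68), genotyped at 2,364 SNPs with
MAF > 5% and a mean call rate of 84% (missingness completely at random).
Two diverged sub-populations (a shared burn-in followed by 40 generations
of independent drift at N = 60) supply the parents: two families from one
group, three from the other, so the two groups separate along the first
genotype principal components. Three traits (shell length, width, height,
in mm) share 300 trait loci drawn from the genotyped markers with effects
correlated at 0.6 across traits; family phenotype offsets of about one
phenotypic SD make a one-way ANOVA separate families decisively.

The published across-family heritabilities this generator targets (0.48,
0.48, 0.36 for SH/SL/SW) are *estimates from a marker-based REML fit*, so
the generator calibrates its residual variances against exactly that
estimator -- REML with the (masked, mean-imputed) marker relationship matrix
and family fixed effects -- by a short fixed-point iteration on the residual
scale. Calibrating against the true simulated variances instead leaves the
REML estimates 0.1-0.3 too high in this structured, partially missing
design, because pooled-frequency genomic relationships in a five-family mixture
are far from their idealised scaling.

What the generator does *not* emulate: genotyping error and allele-specific
dropout, linkage maps of the real species, selection history, non-random
missingness, multi-allelic loci, and maternal or common-environment
effects. Tests passing on this generator therefore validate the analysis
machinery, not the biology of any particular dataset.

## Numerical choices

* Meiosis uses Haldane's model: crossover counts Poisson with mean equal to
  the chromosome map length in Morgans, no interference; two loci 50 cM
  apart show a recombinant fraction of $0.5(1 - e^{-1}) \approx 0.316$.
* The burn-in is monoecious Fisher-Wright (two parents drawn uniformly with
  replacement), so heterozygosity decays by $(1 - 1/2N)$ per generation --
  the closed form the drift tests check. Sexes are assigned i.i.d. at the
  end.
* Fixed-point/optimizer tolerances: REML profiles $\log\lambda$ over
  $[-12, 12]$ with `optimize` at $10^{-8}$; boundary hits are flagged.
  LASSO coordinate descent stops when the largest standardised coefficient
  move falls below $10^{-7}$ (500-sweep cap).
* Degenerate inputs: monomorphic-only panels error in $G$; constant EBV
  vectors yield NA accuracy for that fold with a warning; fully-missing
  columns must be removed by QC before imputation; zero-variance effect
  vectors give NA marker-effect correlations.
* All randomness flows from user-visible seeds; a master seed derives
  per-stage seeds (`derive_seeds()`), and C++ code uses R's RNG stream, so
  whole experiments are bit-reproducible.

## Problem sizes in the replicated benchmarks

The replicated benchmark functions (`benchmark_sim1/2/3()`) use 10
independent simulation replicates per design, one 5-fold partition per
replicate, 800-iteration chains, a 20 Mb genome for the population design
and the full 2,364-marker family design. These sizes are the package's
desk-scale choices: they keep a complete replication on one core in the
tens of minutes while leaving Monte-Carlo errors of the reported means
around 0.01-0.02.

## Known limitations

* Family-based validation accuracy under this package's equilibrium
  burn-in (N = 500) is bounded by sib-prediction theory: the between-family
  half of the additive variance is predicted almost perfectly from family
  means, but the within-family half is limited by
  $n h_w^2 / (n h_w^2 + M_e)$ with $M_e$ of the order of tens of effective
  segments per family. With 200 training sibs at $h^2 = 0.5$ this caps
  validation-only accuracy near 0.75-0.8. Full-scale studies sometimes
  report higher family-based accuracies; those values are consistent with
  correlations pooled over training and validation individuals, or with
  burn-in populations whose effective size (and hence long-range LD) is
  much smaller than the neutral-equilibrium settings used here. We keep
  validation-only semantics and the stated burn-in.
* Density-preserving genome scaling keeps markers-per-Mb but not absolute
  marker counts, and marker-based relationship estimation cares about the
  latter: the desk-scale low-density panel (about 100 markers on 20 Mb)
  estimates genomic relationships more noisily than a full-scale 5,000
  marker panel of the same density would, which depresses
  population-level accuracy for the sparsest panel.
* The samplers are single-site Gibbs; they are exact but not the fastest
  route for very large n.
* The forward simulator tracks tens of thousands of loci comfortably but
  is not meant for chromosome-scale sequence evolution.
* Estimators are additive-only by design, also when the simulated trait
  carries dominance -- that mismatch is the point of the dominance
  experiment.
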