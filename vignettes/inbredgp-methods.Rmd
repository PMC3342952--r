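---
title: "Genomic prediction in fully inbred line panels: models, simulator, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genomic prediction in fully inbred line panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(inbredgp)
```

This vignette explains the statistical machinery implemented in `inbredgp`,
the assumptions behind it, what the synthetic-data generator does and does not
emulate, and the numerical and design decisions that were genuinely open.

## The setting

The package targets panels like the *Drosophila* Genetic Reference Panel:
roughly 150–200 lines derived from a natural population by ~20 generations of
full-sib mating, so each line is essentially homozygous at every locus and the
lines act as a fixed library of haplotypes. Phenotypes are measured on ~100
individuals per sex per line; because trait distributions are often skewed,
the analyzed line value is the average of the two per-sex medians,
`y = (median_F + median_M)/2`. Averaging over so many records strips almost
all environmental noise from the line value, which is why line-mean
heritabilities estimated below sit near 1 on such data.

## Line-mean GBLUP

The prediction model is `y = mu*1 + Zg + e` with `g ~ N(0, G sigma_g2)` and
`e ~ N(0, I sigma_e2)`. `G` is VanRaden's method-1 genomic relationship
matrix, `G = ZZ'/(2*sum p_j(1-p_j))` with `Z = W - 2P`. Conventions worth
stating because they are not forced by the algebra:

* **Allele frequencies `p_j` are computed from the analyzed lines
  themselves.** The base-population frequencies are unknown in practice; this
  is a documented convention, and it has one structural consequence — the
  columns of `Z` are centered, so `G %*% 1 = 0`: `G` is always singular with
  the ones-vector in its null space.
* **Genotype codes count copies of the minor-at-load-time allele** (0/1/2);
  inbred analyses require {0,2}. Fully inbred lines have expected `diag(G)`
  of 2 under this outbred-referenced coding; the raw (unadjusted) `G` is used
  for modeling.
* **Variance components are estimated by maximum likelihood**, profiled over
  `h2 = sigma_g2/(sigma_g2 + sigma_e2)`: one eigendecomposition of `G` makes
  each profile evaluation O(n), and a 101-point grid plus golden-section
  refinement (tolerance 1e-8) finds the optimum; boundary values 0 and 1 are
  legitimate answers. REML is available for the individual-record models
  (below), mirroring the split between the tools the line-mean and
  individual-record analyses historically used.

**A numerical trap and its resolution.** Because `G1 = 0` exactly, the full
Gaussian ML likelihood is unbounded as `h2 -> 1`: the fitted mean absorbs the
ones-direction perfectly while the model variance in that direction collapses,
so the log-likelihood spikes to +Inf. Left alone, the "estimate" is
`h2 = 1` whenever there are more SNPs than lines. `fit_gblup_ml()` therefore
evaluates the likelihood on the contrasts orthogonal to the null space of `G`
(where `h2` is identifiable) and estimates `mu` from the excluded direction.
For a nonsingular training submatrix — every cross-validation fold — this is
exactly the plain ML fit.

**Identifiability of `h2`.** With `G` close to `2I` (a panel of essentially
unrelated lines), `sigma_g2` and `sigma_e2` are separated only by the spread
of the eigenvalues of `G`; the ML estimate of `h2` is then extremely noisy and
piles up on the boundaries regardless of sample size. This is a property of
the model, not a defect of the optimizer. The package's parameter-recovery
studies therefore simulate panels from a small base population
(`Ne_sim = 50`), which leaves realized relationship variance comparable to
the relatedness blocks seen in real inbred panels; on near-unrelated panels
users should expect `h2` estimates near 0 or 1 and rely on cross-validation
instead.

Predictions for unphenotyped lines use the covariance projection
`g_hat = sigma_g2 * G[,t] V_t^{-1} (y_t - mu)` with the GLS mean; the full
mixed-model-equation route is also implemented and the two are asserted equal
in the tests. SNP effects come from the RRBLUP equivalence,
`a_hat = (sigma_g2/d) Z' V^{-1} (y - mu)` with `d` the GRM denominator — the
constant is fixed by requiring `Z a_hat = g_hat` to hold exactly, which makes
the back-solve denominator-consistent whatever scaling is chosen for `G`.

## BayesB

The marker-effect model gives each SNP variance a mixture prior: zero with
probability `pi` (default 0.95, leaving ~5% of SNPs with effects), otherwise
scaled inverse-chi-square with `nu = 4.2` degrees of freedom and scale `S`.
`S` is calibrated so the prior-expected total marked variance
`(1-pi) * sum 2p(1-p) * S*nu/(nu-2)` matches the GBLUP `sigma_g2`; the
residual prior is calibrated the same way from `sigma_e2`. The sampler is
Gibbs over the mean, the residual variance, and per-locus (variance, effect)
pairs, with the locus variance updated by Metropolis–Hastings proposals drawn
from the prior (so prior terms cancel in the acceptance ratio) against the
marginal likelihood of the locus-corrected data; 100 MH cycles per locus
update by default. Chain defaults are desk-scaled (10,000 iterations, 2,000
burn-in, thinning 10); all chain parameters, `pi`, and `nu` are configurable
because reference settings in this literature vary. The sampler is compiled
C++ (Rcpp) but uses R's RNG, so `set.seed()`/config seeds reproduce chains
bit for bit.

## Cross-validation designs

A `(q:p)` scheme partitions lines into `q+p` near-equal groups and enumerates
all `choose(q+p, q)` train/validation folds; fold predictive abilities are
averaged per replicate and the reported standard error is the standard
deviation of replicate means over `sqrt(replicates)` (20 replicates by
default, with a fresh random partition each). Information hygiene is strict:
variance components, SNP-subset selection (including the effect-ranked
strategies), and the BayesB fit see training-fold phenotypes only; the tests
assert that corrupting validation phenotypes changes nothing upstream of the
final correlation. Conventions: thinning takes every k-th SNP of the
genome-wide ordered list anchored at the first SNP; an undefined fold
correlation (constant predictor, typically after a boundary fit on a
degenerate SNP subset) is recorded as 0 with a warning so aggregates stay
defined; and when a boundary fit (`sigma_e2 = 0`) meets duplicated genotype
rows, prediction uses a vanishing nugget (1e-8 of the phenotypic variance) to
keep the training covariance invertible.

## Linkage disequilibrium and effective population size

Lines are haplotypes, so `r2 = D^2 / (p_A(1-p_A) p_B(1-p_B))` is computed
from directly counted "haplotype" frequencies; heterozygous inputs are
rejected rather than phased. Independent loci give `E[r2] ~ 1/n` — the
finite-sample floor that Sved's correction subtracts. The LD route to
effective population size inverts `E[r2] = 1/(1 + 4 Ne c_eff) + 1/n` within a
Morgan-distance bin, with `c_eff = 0.5 * c_female` because males do not
recombine (the factor is exposed as `sex_averaging_factor`), and the estimate
refers to about `1/(2 c_eff)` generations ago — the standard distance-to-time
convention, stated as a convention.

The accuracy route fits `r(T) = sqrt(T h2 / (T h2 + Me))` with
`Me = 2 Ne L* / ln(4 Ne L*)` to mean CV accuracies (predictive abilities
divided by `sqrt(h2)` from the full-data GBLUP fit) at several training
sizes, minimizing the squared deviation over `Ne` on a log grid with local
refinement. Two open choices are made explicit and configurable: the
Drosophila variant uses the sex-averaged map length `L* = L_female/2` (a
`mammal` variant uses `L` directly), and the constant inside the logarithm
defaults to 4. Confidence intervals are bias-corrected bootstrap percentile
intervals over resampled `(T, r_bar)` points — the only resampling unit the
design supports, since fold-level accuracies within a replicate share the
partition; `z0 = qnorm(F_boot(Ne_hat))` and the bounds are bootstrap
quantiles at `pnorm(2 z0 ± z_{1-alpha/2})`. With five accuracy points, the
90% interval's empirical coverage in the package's own simulation is about
80% — small-sample undercoverage that is typical for percentile-type
intervals and is reported rather than hidden.

## Individual-record variance components

Three nested REML models run on individual measurements: Model 1 with fixed
sex and random line, sex-by-line, and replicate-within-(sex-by-line) terms;
Model 2 adds a line effect with covariance `G sigma_a2`; Model 3 adds an
additive-by-additive epistatic effect with covariance `G∘G` (the Hadamard
square — PSD by the Schur product theorem). Per-sex runs drop the sex terms
and reduce the replicate term to replicate(line). Dominance terms are absent
by design: there are no heterozygotes in fully inbred lines.

The engine profiles the residual variance out of the REML likelihood and
maximizes over variance ratios with Nelder–Mead (Brent in 1-D) on the log
scale, using the Woodbury identity so each evaluation costs one Cholesky of a
(number of random levels) sized system; non-negativity is enforced by
boundary projection (ratios below 1e-6 are zeroed when that does not lower
the likelihood). Each model is additionally warm-started at the optimum of
its nested reduction, which guarantees the likelihood ordering
`l(Model 3) >= l(Model 2) >= l(Model 1)` that the likelihood-ratio tests
assume. A fit against `lme4` and a closed-form balanced one-way ANOVA serve
as independent oracles in the tests. LRTs for one variance component on the
boundary use the `0.5*chi2_0 + 0.5*chi2_1` mixture (plain `chi2_1` available
as a conservative flag). Because the full-data `G` is singular (see above),
its inverse — needed for the Woodbury step — receives a loud 1e-8 ridge; this
is expected for every in-sample `G`, not an anomaly. Heritability
compositions are stated defaults with every term toggleable:
`H2 = sigma_line2 / (sigma_line2 + sigma_sexline2 + sigma_rep2 + sigma_e2)`
for Model 1, and `h2 = sigma_a2 / (sum of all estimated components)` for
Models 2–3 (the epistatic variance enters the denominator only). Under a
purely additive trait the between-line variance in Model 1 is expected to be
twice the base-population additive variance, since inbreeding doubles the
variance among fully inbred lines; this factor-2 identity is one of the
package's acceptance checks.

## SNP-effect windows versus association anchors

To compare regions of large estimated SNP effects with a list of top
associated positions, the background distribution is the sum of `|a_hat|`
over sliding windows of `w = 100` adjacent SNPs (displacement 10 SNPs by
default — the displacement is a free parameter and the background density is
insensitive to it), never spanning a chromosome-arm boundary. Each of the
`k = 75` most significant anchors contributes the sum over its 50 nearest
SNPs on each side; the window includes the anchor itself (101 effects — the
inclusive reading of "50 on each side", documented as an off-by-one choice)
and is truncated, with a flag, at arm ends. The summary statistic is the
share of anchored sums above the empirical 90% quantile (type-7
interpolation, another stated convention) of the background; exchangeable
effects calibrate this share to ~10%, planted signal drives it up. A
single-marker regression helper generates association p-values on synthetic
data; it stands in for an external association study and only its output
format matters.

## The synthetic-data generator

The generator exists so every analysis above can be exercised end to end with
known truth. It emulates, in order:

1. **A base population** by discrete-generation Wright–Fisher forward
   simulation: random union of gametes, female gametes recombining with
   Poisson crossovers on the female Morgan map (Haldane, no interference),
   male gametes passed intact per arm. Diversity enters as standing variation
   (per-site founder frequencies drawn uniformly, default range 0.05–0.95;
   the studies that need to limit drift-fixation use 0.2–0.8) with optional
   per-gamete mutation; sites fixed by drift are dropped. Chromosome arms
   assort independently — centromere linkage between arm pairs is not
   modeled. A forward simulator was chosen over a coalescent because
   female-only recombination is trivial to encode and desk-scale sizes
   (`Ne_sim <= 500`, tens of thousands of sites) suffice.
2. **Inbred lines** by 20 generations of brother–sister mating from random
   founder pairs, one genotyped individual per line. The full-sib inbreeding
   recursion `F_t = (1 + 2F_{t-1} + F_{t-2})/4` gives `F_20 ~ 0.986`, so
   ~1.4% of initially heterozygous sites remain heterozygous; by default
   these residual calls are forced to the major allele among the final sib
   pair's four haplotypes (ties to the lower code), matching the {0,2}
   analysis assumption, and the raw matrix is preserved when the flag is off.
3. **Sequencing artifacts**: per-SNP coverage from a uniform range spanning
   the preprocessing filter window (so the coverage rule has something to
   remove) and uniform random missingness, giving the fields the filters act
   on (coverage strictly between 2 and 30, minor allele in at least 4 lines,
   called in at least 60 lines; missing cells imputed by the per-SNP mode,
   ties to the lower code — a deliberately naive stand-in for haplotype-model
   imputation).
4. **Phenotypes**: individual value = mean + additive genetic value (allele
   counts times effects) + fixed sex difference + line-by-sex deviation +
   epistatic pair terms (products of centered codes) + line environmental
   deviation + replicate deviation + residual; two replicates of 50
   individuals per sex per line by default, i.e. ~100 records per sex.
   Residuals are normal by default with an optional mean-centered log-normal
   to emulate the skewness that motivates medians. When a target line-mean
   heritability is requested, the line environmental standard deviation is
   calibrated against the realized genetic variance of the panel.

What it does **not** emulate: real Drosophila demography, selection,
structural variants and transposable elements, sequencing-error genotype
miscalls, haplotype-model imputation errors, and centromere linkage. Passing
tests therefore demonstrate the statistical machinery under the stated model,
not robustness to everything real data contain.

## Problem sizes in the packaged studies

The simulation studies shipped in the tests and the acceptance script use
panels of 150–200 lines from base populations of `Ne_sim` 40–100 with
1,200–8,000 seeded sites, 10–20 cross-validation replicates, BayesB chains of
6,000 iterations, 200-run type-I calibrations, and 100-point-set bootstrap
coverage runs. These sizes were chosen so that every Monte-Carlo comparison
has tolerance bands grounded in its own sampling variability while the whole
suite remains a desk-scale computation; all of them are parameters, and users
reproducing the studies at larger sizes only need to change the arguments.

## Known limitations

* ML `h2` on weakly related panels is boundary-heavy (see above); report
  cross-validated predictive ability alongside it.
* The naive mode imputation ignores haplotype structure; with real
  low-coverage data a dedicated imputation tool should run upstream.
* Standard errors of individual-record variance components are not computed
  (no average-information matrix); the LRT is the supported inference.
* The BayesB sampler fits one trait at a time and does not implement BayesA
  or BayesC-pi variants.
* Accuracy-curve Ne estimates inherit the bias of plugging an estimated `h2`
  into the conversion from predictive ability to accuracy; with line-mean
  `h2` near 1 the effect is small.
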