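---
title: "Deleterious load scores: model, conventions, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deleterious load scores: model, conventions, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette documents the statistical model behind `loadscore`, the
conventions the implementation commits to where more than one reasonable
choice existed, and what the synthetic-data generator does and does not
emulate. It is the reference for anyone auditing the package's numerical
behaviour.

## 1. The load score model

The deleterious load score of individual $i$ is

$$L_i = \sum_{v \in V} d_{iv} \, w_v,$$

an additive sum over a variant set $V$ of the derived-allele dosage
$d_{iv} \in [0, 2]$ times a per-site weight $w_v$. The assumptions are:

* **Additivity.** Effects of individual variants sum; no dominance,
  epistasis, or linkage structure enters the score.
* **Polarization.** The derived allele is identified by an ancestral-allele
  annotation: if the ancestral allele equals REF the derived dosage is the
  stored ALT dosage, if it equals ALT the derived dosage is $2 -$ ALT
  dosage, and if it matches neither allele (or is missing) the site is
  *unresolved* and excluded. `derived_dosage()` refuses unresolved input by
  contract rather than guessing.
* **Weights approximate selection.** The default weight is the site's
  phyloP conservation score restricted to $w_v > 0$ (strictly: a score of
  exactly zero is excluded), since positive values indicate uniform
  purifying selection while negative values indicate acceleration. Unit
  weights give the classical mutation burden, `compute_burden()`.

Three variant subsets give three scores — genome-wide, coding-only,
non-coding-only — which are exactly additive because the subsets partition
the filtered variant set.

**Standardization.** Whether load scores should be standardized before
regression is not determined by the raw sums themselves (their scale is
arbitrary, set by the weight units and the panel size). The package's
choice: every `load_score` carries both the raw sum and a z-standardized
copy, the scan uses the z by default (`standardized = TRUE`), so reported
betas are per-SD-of-load, and the raw scale is always retained in output.

### Variant filters

The load-score profile (`load_score_filter()`) keeps biallelic SNVs with
imputation INFO $\ge 0.9$, strictly positive weight score, and a resolvable
ancestral allele. The spectrum-calibration profile (`afs_filter()`) keeps
variants with missingness strictly below 1% regardless of INFO or score
sign, because the spectra span the full score range. All criteria are
individually toggleable in `filter_variants()` and combine by logical
conjunction, so masks are order-independent. Boundary conventions: INFO
$0.9$ is **included** ($\ge$), missingness $0.01$ is **excluded**
(strict $<$), score $0$ is **excluded** (strict $>$).

### Strata

`stratified_loads()` crosses DAF intervals, closed on the left
($[\mathrm{low}, \mathrm{high})$, so DAF $= 0.05$ joins the
$[0.05, \cdot)$ stratum), with score intervals closed on the right
($(\mathrm{low}, \mathrm{high}]$, so phyloP $= 2$ joins the $(\cdot, 2]$
stratum). Overlapping intervals are a configuration error; a partition of
the masked variants makes the stratum loads sum exactly to the total. The
"not close to fixation" bound (DAF $< 0.7$) is a stratum boundary, not a
default filter on the main score, because it only plays a role in
stratified analyses.

### Missing dosages

Imputed dosage data normally has no missingness. Where missing entries do
occur at included variants, `compute_load()` mean-imputes them per variant
(which leaves the expected column contribution unchanged); a strict mode
(`na_action = "error"`) raises instead.

## 2. DAF-spectrum calibration

A deleteriousness score that genuinely tracks purifying selection must
produce derived-allele-frequency spectra that grow steeper as the score
class rises. The calibration stage bins variants into score intervals
(`(low, high]`, defaults: steps of 0.2 over $(0, 0.8]$ for fitCons, 2.5
over $(-10, 10]$ for GERP++, 5 over $(0, 35]$ for CADD, and 2.5 over
$(-5, 10]$ for phyloP), builds one non-normalized spectrum per interval,
fits a log–log slope per spectrum, and regresses the slopes on the integer
rank $1..K$ of the score category. Synonymous, missense and
loss-of-function spectra computed with the same frequency binning serve as
biological controls.

**The slope convention.** Spectra store raw counts over logarithmically
spaced frequency bins spanning $[\min \mathrm{DAF}, 1)$ (20 bins by
default; the lowest edge is pinned to the minimum so no variant is lost to
floating-point rounding). The slope, however, is fit by OLS of
$\log_{10}(\mathrm{count} / \mathrm{bin\ width})$ — a density — on
$\log_{10}$ of the geometric bin midpoint. Normalizing by bin width makes
the fitted slope invariant to the choice of binning and gives the neutral
$1/x$ spectrum slope $-1$ exactly; fitting raw counts on log-spaced bins
would instead give the neutral spectrum slope $0$ and make slopes
binning-dependent. Empty bins are dropped from the fit rather than
pseudocounted, to avoid biasing steep spectra; fewer than two non-empty
bins is an error. A zero-variance response (exactly flat spectrum) reports
$r^2 = 1$, treating the fit as exact.

## 3. The synthetic cohort

The generator produces, from a single integer seed, a bit-reproducible
bundle: annotations, dosages (TSV or VCF 4.2 with a `DS` FORMAT field),
phenotypes with declared types, covariates, and truth tables. Doubles are
written with 17 significant digits so files round-trip exactly.

### What it emulates

* **Frequencies.** Each variant's DAF is drawn by inverse-CDF sampling on a
  2048-point log-spaced grid from the stationary (sojourn) density of the
  Wright–Fisher diffusion for an additive deleterious variant with
  population-scaled selection strength $\gamma \ge 0$:
  $$f(x) \propto \frac{e^{-\gamma x}\left(1 - e^{-\gamma(1-x)}\right)}
  {x(1-x)\left(1 - e^{-\gamma}\right)},$$
  with the neutral limit $f(x) \propto 1/x$ as $\gamma \to 0$, truncated to
  $[x_\min, 1 - x_\min]$, $x_\min = 1/(2n)$ for $n$ diploid individuals.
  This is the minimal standard model in which the mean DAF decreases in
  $\gamma$ and spectra steepen with selection — the qualitative behaviour
  the calibration stage is built to detect. Selection strengths come from
  a point-mass mixture (default: half the variants effectively neutral,
  the rest spread over $\gamma \in \{1, 5, 20, 80\}$), with additive
  $\gamma$ shifts of $+5$ for missense and $+30$ for loss-of-function
  variants so the control-class ordering holds.
* **Scores.** The conservation-like score is
  $2.5\,\log(1+\gamma) + \mathcal N(0, \sigma^2)$ clipped to $[-5, 10]$, a
  phyloP-like range in which neutral variants straddle zero (about half
  negative) and strongly selected variants approach the ceiling. The
  default noise SD of 1 keeps the rank correlation with $\gamma$ high
  while leaving realistic misclassification across score-interval
  boundaries.
* **Genotypes.** Hard genotypes are $\mathrm{Binomial}(2, \mathrm{DAF})$
  per individual (Hardy–Weinberg, no inbreeding); optional additive
  Gaussian noise clipped to $[0,2]$ mimics imputation, and INFO is
  reported as the squared correlation between hard and noisy dosage
  (defined as 1 when they are identical, 0 for monomorphic hard columns
  where no correlation exists). The default noise SD of 0.05 leaves most
  variants above the INFO $\ge 0.9$ filter, as in a well-imputed panel.
  Because real pipelines may hard-call dosages, noise SD 0 produces exact
  hard calls.
* **Allele labels.** REF is ancestral with probability 0.9 by default
  (roughly the genome-wide norm), and the recorded ancestral allele is
  swapped relative to truth with a configurable mislabel rate (default
  0.02) to emulate errors in ancestral inference; the truth table retains
  the true orientation, which is what makes the polarization-robustness
  tests possible.
* **Phenotypes.** Continuous traits are
  $\beta z(L) + \text{covariates} + \mathcal N(0, \sigma^2)$; binary and
  phecode-like traits threshold the same latent liability at the empirical
  quantile achieving the target prevalence; ordinal traits cut the latent
  at fixed cutpoints; nominal traits pick the class with the largest
  Gumbel-perturbed utility (multinomial logit) with the load effect on the
  last class. With $\beta = 0$ a phenotype is independent of load given
  the covariates — the property underlying all null-calibration tests.
  Default load effects are negative, the direction expected for
  fitness-related traits under purifying selection.
* **Truth.** The per-individual true load is the genome-wide weighted sum
  over variants with score $> 0$ and INFO $\ge 0.9$ using *true*
  orientations — the same set the load-score filter profile selects — so
  computed and true loads agree to $10^{-9}$ when labels are clean.

### What it does not emulate

No linkage disequilibrium (variants are independent), no demography or
population structure, no coalescent genealogy, no recurrent mutation, no
transition/transversion structure in allele letters, and the covariates are
independent of the genotypes. Consequently, passing tests demonstrate that
the statistical machinery is correct under the stated model; they cannot
demonstrate robustness to stratification confounding, LD-induced
correlation between scores, or genotyping artefacts in real cohorts.

## 4. The phenome scan

Phenotype retention follows the typed rules: phecodes need **strictly more
than 500 cases**; binary traits need at least 500 cases *and* 500 controls
and at least 5,000 non-missing individuals; other types need at least
5,000 individuals. Model families by type: `lm` for continuous,
`MASS::polr` (proportional-odds cumulative logit) for ordered categorical,
`nnet::multinom` for unordered categorical, and binomial `glm` for
binary/phecode. The multinomial family reports a likelihood-ratio p-value
for the load term and no single coefficient (a per-level Wald test would
not yield the single p-value per phenotype the scan needs). Complete-case
exclusion is applied per phenotype, and the reported `n` is the size of
the analysis set. Non-convergence and separation yield a flagged row with
NA estimates, never an error, so one pathological phenotype cannot abort a
scan.

Continuous responses receive a rank-based inverse-normal transform by
default (Blom offsets), the standard preprocessing in heterogeneous
phenome scans; it is toggleable (`inverse_normal = FALSE`) and both modes
are exercised in the tests. The covariate set is generic — any mix of
numeric and categorical columns, mirroring the usual age, sex, chip,
centre, principal components and socioeconomic variables — because the
appropriate covariate profile is cohort-specific; the generator emits
stand-ins with those roles.

Three sensitivity modes probe reference bias and the weighting choice:
adding the per-individual non-reference allele count as a covariate,
restricting the load to sites where REF equals the recorded ancestral
allele, and swapping the weight column (e.g. a human-reference-free
conservation score). Each returns a separately labelled scan table from
`sensitivity_scan()`.

## 5. The permutation enrichment test

`permute_and_count()` counts phecode-type phenotypes with load p-value
strictly below $\alpha = 0.05$, then shuffles the load values across
sample IDs (covariates and phenotypes untouched, so their joint structure
is preserved — this is exactly what makes the null counts exchangeable
with the observed count) and repeats. The permutation p-value is the plain
fraction of permutations with a count **at least as large** as observed
(ties count toward significance); it can be exactly zero, and the
$(r+1)/(n+1)$ variant is available behind `add_one = TRUE`. Non-converged
fits are dropped from the counts and tallied in `n_dropped` rather than
guessed as null.

Two fitting engines are provided. `engine = "glm"` refits the full
logistic model for the observed and every permuted load. `engine =
"score"` fits the covariate-only null model once per phenotype and
evaluates the Rao score test for each candidate load vector from the
cached fit — the standard device in permutation-based association testing,
orders of magnitude faster, and asymptotically equivalent to the Wald
test. The observed count and the null counts always use the same engine,
so exchangeability (hence calibration) holds for either; the two engines
are cross-checked against each other in the test suite.

## 6. Numerical choices and degenerate inputs

* Inverse-CDF sampling uses trapezoidal integration on a log-spaced grid
  (2048 points by default, minimum 100) with linear interpolation; the
  grid is log-spaced because the density varies fastest near $x_\min$.
* $1 - e^{-\gamma}$ terms use `expm1` and the $e^{-\gamma x}$ factor is
  applied outside, so densities remain finite for $\gamma$ up to the
  hundreds.
* `z_standardize()` maps zero-variance vectors to all zeros rather than
  dividing by zero (an empty variant panel yields all-zero loads).
* The KS normality check standardizes with estimated mean and SD and
  therefore carries the Lilliefors caveat — the p-value is conservative —
  which is recorded in the returned object; zero-variance input and
  $n < 30$ are errors.
* Bonferroni with $n_\text{tests} = 0$ , empty score-bin specifications,
  fewer than three score categories for the rank regression, and
  permutation with zero permutations are parameter errors, not silent
  defaults.
* Scan row order is fixed (score kind, then phenotype name, both sorted)
  so reruns are byte-identical.

## 7. Problem sizes in the test and acceptance tooling

The test suite exercises the statistical properties at sizes chosen to
make Monte-Carlo tolerances (3-SE bands computed from the sizes
themselves) tight while keeping a full run in the minutes range:
$10^5$ draws per spectrum for slope calibration (20 replicates), 1,000
null phenotypes at $n = 2{,}000$ for type-I error, 200 replicate null
cohorts of 200 permutations each (539 phecodes, $n = 500$) for permutation
calibration, 500 small replicates for interval coverage, and 20 enriched
plus 20 null cohorts ($n = 2{,}000$, 539 phecodes, 500 permutations) for
enrichment detection. `scripts/acceptance.R` reruns the same computations
at single-replicate scale from a user-supplied seed.

## 8. Known limitations

Only biallelic SNVs are handled; multi-allelic sites and indels are
excluded by the filters. DAF is computed in-sample (an external reference
frequency can be supplied as a column instead). The score engine applies
to the binomial permutation scan only; ordinal or continuous phenotypes in
a permutation test would need the glm path. The proportional-odds and
multinomial fits inherit the convergence behaviour of `MASS::polr` and
`nnet::multinom`; flagged rows should be inspected rather than silently
trusted. And as noted above, the generator's independence assumptions mean
the package's guarantees are about the statistical machinery, not about
confounding in any particular real cohort.
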