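---
title: "Morphostructural characterization with zoomorph: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Morphostructural characterization with zoomorph}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(zoomorph)
```

## The problem

Local livestock populations — here the Black Creole goat of central Mexico,
a Creole population descended from colonial-era Iberian stock — usually have
no breed standard and no registry. The first step toward conservation is a
*morphostructural characterization*: a quantitative description of body
conformation from standardized linear measurements (zoometry). zoomorph
implements the full analysis chain for such a study: descriptive statistics
and a homogeneity reading, zoometric indices with zootechnical
classification, a correlation-based morphological-harmony model, principal
component analysis of the measurement battery, and hierarchical clustering
of sampling localities. Because the raw field records of the reference
study were never deposited, the package also ships (i) the study's printed
summary tables as plain-text fixtures and (ii) a seeded synthetic-herd
generator that reproduces their statistical structure, so every stage is
testable end to end.

## Data model

A *herd* is a plain tibble: one row per animal with `animal_id`,
`locality`, `sex`, `age_class`, and fourteen measurements in centimetres —
head width (HW), head length (HL), face length (FL), wither height (WH),
chest girth (CG), body length (BL), bicostal width (BW), chest depth (CD),
shoulder width (SW), rump length (RL), rump width (RW), haunch width
(HAW), rump height (RH) and cannon bone perimeter (CBP). Haunch width is
always coded `HAW`; `HW` is reserved for head width (field protocols
sometimes reuse "HW" for both, which this package deliberately refuses to
do). `validate_herd()` enforces presence, positivity and finiteness of all
fourteen columns and is called by every analysis entry point.

## Study-design sample size

`required_sample_size()` implements the precision-based sample size for a
proportion, $n = (z/m)^2\,p(1-p)$, rounded up (a sample must meet or
exceed the required precision, hence ceiling rather than rounding). At
$z = 1.64$ (90% confidence), $m = 0.05$ and $p = 0.3$ this gives the
reference cohort of 226 animals. The quotient form $(z/m)^2$ is the
standard formula; it is the only reading of the design parameters that
reproduces that cohort size.

## Descriptive statistics and homogeneity

`herd_summary()` reports per-variable mean, sample SD ($n-1$ denominator —
the data are a sample, not a census), CV ($100\,s/\bar{x}$), minimum and
maximum. `homogeneity_screen()` applies the conventional zootechnical
reading of the CV: a trait with CV strictly below 10% is *homogeneous*;
above 30% the precision is considered too low and the variable is flagged
as a discard candidate; in between it is intermediate. The thresholds are
half-open exactly as the convention states them ("lower than 10", "exceeds
30"). In the reference population 10 of 14 variables are homogeneous and
none reach the discard bar (the highest CV, bicostal width at 23.32%,
stays intermediate).

## Zoometric indices and their classification

`compute_indices()` evaluates, per animal and without rounding, four
ethnological indices — corporal $COI = 100\,BL/CG$, thoracic
$THI = 100\,BW/CD$, cephalic $CEI = 100\,HW/HL$, pelvic
$PEI = 100\,RW/RL$ — and five productive ones — proportionality
$PRI = 100\,WH/BL$, metacarpal–thoracic $MTI = 100\,CBP/CG$, relative
thorax depth $RDI = 100\,CD/WH$, transversal pelvic $TPI = 100\,RW/WH$ and
longitudinal pelvic $LPI = 100\,RL/WH$. All are scale-invariant ratios.

`index_table()` averages *per-animal ratios* (mean-of-ratios), which is
what a population index table reports; this systematically exceeds the
ratio of population means for these positively-correlated
numerator/denominator pairs (Jensen direction), and the tests assert that
direction on synthetic data.

Classification follows the canonical class intervals, which contain gaps
as published: COI brevilinear $\le 85$, mesolinear $(86, 88)$, longilinear
$\ge 90$; THI elliptical/dairy $\le 85$, circular/meat $\ge 89$. A value
falling inside a gap (e.g. a COI of 85.11) is assigned the nearest class
and flagged (`coi_gap`), which reproduces the zootechnical practice of
calling 85.11 brevilinear while preserving the published thresholds
untouched. MTI uses the closed interval $[10, 11]$ for eumetric (a value
of exactly 10.14 is eumetric; the boundary closure is a documented
choice). PRI has no published threshold; the default 95 reflects the
reading of values near 99 as a "square", dairy-type conformation and is
configurable. The TPI/LPI meat indicators (TPI > 33, LPI < 37) are counted:
two indicators lean meat, none lean dairy, exactly one is a medium
tendency.

## Morphological harmony

The harmony model asks how much of the measurement battery rises and falls
together. `spearman_matrix()` computes, for all 91 unordered pairs of the
14 variables, the Spearman rank correlation with midrank treatment of ties
(measurement data are recorded to fixed precision, so ties are expected)
and a two-sided p-value from the t approximation with $n-2$ degrees of
freedom — the standard choice at $n = 226$. `normality_screen()`
(one-sample Kolmogorov–Smirnov against a normal with the sample moments)
justifies the rank-based branch; its recommendation is advisory and the
pipeline default is Spearman regardless.

`harmony_score()` counts the pairs with *strictly positive* and
*significant* correlation as a percentage of all pairs. A significant
negative correlation never counts (the reference matrix contains exactly
one, BW–RL at $-0.11$); undefined cells stay in the denominator. For
printed matrices that carry significance stars rather than p-values,
a cell is significant iff it carries at least one star. On the packaged
reference matrix this gives 83 of 91 pairs, 91.21%.

`harmony_model()` maps the percentage to a verdict: *high* above 50%,
*low* at or below 25%, *medium* in between. The published rule leaves
"close to 50%" undefined; adopting the whole interval $(25, 50]$ as medium
is the one interpretation that makes the three bands partition the scale,
and is documented as such.

## Principal component analysis

`morpho_pca()` performs PCA on the *correlation* matrix (standardized
variables). This is an inference, not an explicit protocol statement of
the reference study, but it is forced by arithmetic: the leading
eigenvalue of 6.39 corresponds to the reported 45.64% of variance only as
$6.39/14$, which requires each variable to contribute unit variance.
Loadings are eigenvector $\times \sqrt{\lambda}$, i.e. variable–component
correlations; each component is oriented so its loading sum is positive
(eigenvectors are sign-ambiguous; this convention makes a general-size
first component load positively on every measurement). `kaiser_retain()`
keeps components with eigenvalue strictly greater than 1, and
`communalities()` sums squared loadings over the retained set only —
three components for the reference loadings — flagging variables below
0.5 as under-represented.

## Locality clustering

`locality_profiles()` averages each variable within locality.
`locality_distances()` z-scores each variable across localities before
computing Euclidean distances (default). The standardization is again an
inference from magnitudes: the reference distance matrix spans 2.34–7.77,
far too small for raw centimetre profiles dominated by ~70–85 cm trunk
measurements, but exactly the scale of 14 z-scored coordinates. An
unstandardized mode is available.

`ward_cluster()` applies Ward's minimum-variance criterion to the
precomputed distance matrix via the Lance–Williams recurrence on squared
distances, with merge heights reported on the input-distance scale (the
classical "Ward on a Euclidean matrix" contract, `ward.D2` in the hclust
nomenclature; the variant matters and is stated because "Ward's method"
alone is ambiguous). Labels are sorted lexicographically before
clustering so equidistant merges are deterministic. The test suite checks
the implementation against a from-scratch oracle that recomputes the
ESS increase of every candidate merge at every step for up to 8 leaves,
and verifies that merge heights never invert. On the packaged reference
matrix the first merge is Zapote Viejo–Tlacote el Alto at 2.34 and the
three-cluster cut recovers the reference grouping of the eight
localities. `heatmap_matrix()` returns the dendrogram-ordered
locality-by-variable z-score matrix behind the usual heatmap rendering,
and `as_newick()` serializes the tree.

## The synthetic-herd generator

`simulate_herd()` exists so the pipeline can be exercised, and its
statistical behaviour tested, without the undeposited field data. Its
defaults *are* the reference study conditions: 226 animals, the eight
localities at the study's sampling proportions (20, 38, 11, 15, 22, 38,
59, 23), a 216:10 female:male ratio, the reference per-variable means,
SDs and ranges, and the reference Spearman matrix as the correlation
target.

The mechanism is a Gaussian copula. Correlated standard-normal latents are
drawn through an eigen factorization of the target correlation matrix
(first repaired to the nearest positive-semidefinite correlation by
eigenvalue clipping — printed, rounded matrices need not be PSD;
`nearest_valid_correlation()` reports the largest adjustment, about 0.02
here). Each latent is then pushed through a monotone quantile map onto a
truncated-normal marginal on the published \[min, max\] whose *latent*
parameters are solved numerically (multi-start Nelder–Mead on the closed
form truncated-normal moments) so that the *post-truncation* mean and SD
equal the published values. Moment matching matters: naive truncation of
a normal with the published moments would bias means upward for the
strongly right-skewed variables (bicostal width's published minimum sits
only 1.2 SD below its mean), and the generator is required to recover the
published means within sampling error. Because every marginal map is
monotone, ranks — and hence the Spearman structure — are preserved
exactly, and every draw lies inside the published range by construction.

The target correlations are used directly as latent Gaussian correlations
rather than converted from Spearman scale; the systematic difference
($2\sin(\pi\rho/6)$ vs $\rho$) is below 0.02 in magnitude, under the
±0.05 recovery tolerance the tests use.

Two non-Gaussian shapes distort the copula grade $u$ monotonically before
the quantile map: `skewed` uses $u^5$, strong enough that the KS screen
rejects normality for the large majority of variables at $n = 226$ (this
is the shape's purpose: exercising the rank-based branch), and `mixture`
blends two grade maps into a heavier-tailed marginal. Neither preserves
the published means and SDs; only `gaussian` claims to. Per-locality
latent mean offsets are available (`locality_shift_scale`) but default to
0, matching the reference population's homogeneity across localities.

What the generator does *not* emulate: age, parity and nutritional
covariates; sex dimorphism (both sexes share one distribution);
measurement rounding to field precision; and any real locality structure.
Passing tests on synthetic herds therefore demonstrate that the
*pipeline* recovers the structure it was given, not that the reference
population has that structure.

## Numerical choices and problem sizes

* Eigenvalue tolerance for PSD repair: $10^{-10}$; singular correlation
  matrices (collinear variables) are an error naming the offending pair.
* Spearman p-values use the t approximation; at the study's $n = 226$ the
  difference from exact permutation is immaterial for 3-star calls.
* Kaiser retention is strict (`> 1`), so exactly-unit eigenvalues are not
  retained.
* Ties in Ward merges break by lexicographic label order.
* The moments-recovery tests run one herd of $n = 5000$ (CLT bound
  $\pm 2\,\mathrm{SD}/\sqrt{n}$ per variable, ±0.05 on rank correlations);
  the qualitative-recovery test runs 200 replicates at the study's
  $n = 226$ and asks for the "high" harmony verdict in at least 95% and
  2–4 Kaiser components in at least 90%. These sizes keep the full suite
  under a minute while leaving the Monte-Carlo margins comfortable.

## Known limitations

* The classification vocabularies implement the published class intervals
  for goats/cattle zootechnics; thresholds for other species differ and
  are configurable but not curated here.
* The harmony p-values are unadjusted for multiple testing, faithfully to
  the method being reproduced; a corrected variant is a caller decision,
  not a package default.
* The printed reference tables carry their own rounding inconsistencies
  (e.g. a CV reproducible only to ±0.01, component percentages that sum
  to 67.50 vs eigenvalue ratios that sum to 67.49); fixtures store the
  printed values and tests compare at printed precision.

## Reproducing the headline numbers

```{r headline}
required_sample_size(z = 1.64, m = 0.05, p = 0.3)
harmony_score(ref_correlation_matrix())
cut_clusters(ward_cluster(ref_locality_distances()), k = 3)
```

And a full synthetic run:

```{r run}
res <- run_characterization(run_config(seed = 42))
res
```
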