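---
title: "Methods: MSAP epilocus scoring and population-epigenetic statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: MSAP epilocus scoring and population-epigenetic statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epimsap)
```

## Scope and model

`epimsap` analyses methylation-sensitive AFLP (MSAP) data: the same DNA is
digested in parallel with the isoschizomers HpaII and MspI, which share the
recognition site 5'-CCGG-3' but differ in sensitivity to cytosine
methylation. Comparing the dominant (band present/absent) calls of the two
enzyme panels at one locus distinguishes four conditions:

| HpaII | MspI | condition | code |
|---|---|---|---|
| 1 | 1 | nonmethylated | `100` |
| 0 | 1 | internal cytosine methylated | `010` |
| 1 | 0 | external cytosine hemimethylated | `001` |
| 0 | 0 | ambiguous (holomethylation or mutation) | `000` |

This is the *Mixed Scoring 2* encoding: each locus expands into three
binary *epiloci* (nonmethylated / internally methylated / externally
methylated), each treated downstream as an ordinary dominant marker. The
ambiguous `000` condition expands to absence at all three epiloci. We read
"excluded from statistical analysis" as *not scored as a marker type of its
own*, with its zeros counting as absences — the alternative reading
(missing data at all three subcolumns) would leave the dominant-marker
distance machinery undefined wherever a fragment is simply missing, which
is most of any real matrix. State matrices retain the `000` code, so no
information is discarded.

Upstream of scoring, two filters mirror standard MSAP quality control:
a fragment-size window (default 100–600 bp, inclusive at both ends, the
usual convention of scoring software when a range is quoted as "between"),
and a replicate-reproducibility filter. Every sample is assumed to have
been run in duplicate; the default `strict` mode discards any locus with a
single discordant call between replicates (a 100%-reproducibility
requirement), while `tolerance` mode admits a configurable per-locus
discordance fraction and exists mainly for noise studies on synthetic
data.

## Statistics

**Diversity (per group × panel).** A marker is *polymorphic* within a
group when its presence frequency is strictly inside (0, 1). We use this
any-variation criterion rather than a 5% band-frequency rule because one
group of interest has n = 6, where threshold rules degenerate. A
polymorphic marker is *private* to a group when it is present there and
absent from every individual of every other group. Shannon diversity per
marker is $H = -p\ln p - (1-p)\ln(1-p)$ (natural log, $0\ln 0 := 0$);
panels are summarized by the unweighted mean over their markers, groups by
the panel-size-weighted mean $\sum_t n_t \bar H_t / \sum_t n_t$. The
weighted-mean convention was chosen because it exactly reconstructs the
published per-group summary values from the published per-panel ones
(0.189 for the apomictic tetraploids; 0.259 as the minimum among the other
groups), which a simple average does not.

**Differentiation.** AMOVA follows the Excoffier ANOVA-on-distances
algebra on pairwise mismatch counts of the expanded binary view (squared
Euclidean distance on 0/1 data; "haplotypic data with gamma 0.0" in the
original tooling's terms means exactly this uncorrected band-pattern
distance). One-level AMOVA yields $\Phi_{ST} = \sigma^2_a / (\sigma^2_a +
\sigma^2_w)$ with a permutation p-value from random relabeling of
individuals (one-sided, `(1 + #{phi_perm >= phi_obs}) / (1 + n_perm)`).
The two-level hierarchical form uses the standard nested expected mean
squares with unequal-size coefficients; its top component is tested by
permuting whole second-level units among first-level strata, the nested
component by permuting individuals within strata. Negative variance
components are reported as-is and flagged, the standard AMOVA behaviour.
Locus-by-locus AMOVA reports the fraction of significantly differentiated
epiloci over *all* epiloci (monomorphic ones are skipped but stay in the
denominator, since the published quantity is an overall percentage). The
permutation default is 50,000, reducible in configs; tests use a few
hundred. NMDS ordination delegates to `vegan::metaMDS` (iterative stress
majorization, here 20 random restarts under a fixed seed) on Jaccard
distances — the exact tooling this analysis family uses — so coordinates
are defined only up to rotation/reflection and all our tests are
rotation-invariant.

**Spatial statistics.** Geographic distances are great-circle (haversine,
R = 6371 km), with samples inheriting their population centroid. The
stratified Mantel test correlates the upper triangles of the epigenetic
mismatch and geographic distance matrices and permutes sample labels only
within strata (cytotypes in the pipeline); p is one-sided for positive
association by default. Moran's I is computed per locus,
$I = (n/W)\sum_{ij} w_{ij} z_i z_j / \sum_i z_i^2$, and summarized as the
mean over polymorphic loci — the simplest reduction consistent with
one-value-per-group×panel reporting; its closed-form null expectation
$-1/(n-1)$ is reported alongside a permutation p. Local Geary's C uses
Anselin's form $c_i = \sum_j w_{ij}(x_i - x_j)^2 / (2 m_2)$ with
$m_2 = \sum_i z_i^2/(n-1)$, averaged over loci per individual; values
above 1 flag negative local autocorrelation. The weighting scheme is not
stated in the analysis family this package follows, so it is explicit and
recorded in every output: inverse geographic distance restricted to the
k = 10 nearest population rings, row-standardized, with a 1 km offset so
co-located samples stay finite. `env_space_weights()` (inverse
environmental distance, ε = 10⁻⁶) is a documented stand-in that turns
Moran's I into an "autocorrelation in environmental space" statistic; it
is an explicit construction, not a claim about how any published
environment-correlated I was obtained.

**Environmental association.** Each polymorphic epilocus is regressed on
one standardized environmental variable at a time with a two-parameter
logistic model fitted by IRLS (Newton steps with step-halving; the fit is
validated against `stats::glm` in the tests). Wald
($(\hat\beta_1/SE)^2$) and likelihood-ratio G statistics are both
computed, and a locus × variable pair is a candidate only when *both* pass
the corrected threshold — the strict conjunction convention of
Samßada-style association scans. Multiplicity control defaults to
Bonferroni over all loci × variables (the landscape-genomics convention
for this tool family), with Benjamini–Hochberg available. Complete or
quasi-complete separation is detected (diverging slope / singular
information) and such fits are flagged and excluded from candidacy.
Pseudo-R² defaults to Nagelkerke; the published R² values attached to
candidate counts have no stated definition, so no check in this package
targets them. Variables are standardized to z-scores first, making slopes
scale-free.

## The synthetic study

Because the original sample × fragment matrix exists only in a paper
appendix, every stage is exercised on a generator whose defaults *are* the
published study design:

- four combined cytotype × reproduction groups, 2xS/2xM/4xM/4xA, of sizes
  41/6/45/31 (123 samples) in 48 single-group populations of 1–6
  individuals;
- three epilocus panels of 268 (nonmethylated), 378 (externally
  methylated) and 442 (internally methylated) markers;
- per-group polymorphism probabilities equal to the published polymorphic
  percentages, which encode the apomict signature (depleted
  nonmethylated/external variation, elevated internal variation in 4xA);
- candidate epiloci with logistic environmental effects mirroring the
  published breakdown (22 elevation-, 36 temperature-associated, none for
  precipitation); effect sizes are unpublished, so the default slope is 2
  on the standardized variable — comfortably detectable at n = 123 under
  Bonferroni, which is what a planted-recovery test needs;
- alpine covariates: population elevation normal around 1700 m (diploids)
  or 2200 m (tetraploids) with sd 250 m (tetraploids sit higher, as in the
  real system), annual mean temperature = 14 °C − 0.0065 °C/m × elevation
  + N(0, 0.5 °C) (the standard tropospheric lapse rate, so temperature and
  elevation are strongly collinear, as in real alpine data), precipitation
  an independent N(1200, 200) mm draw.

Presence/absence is simulated directly at the epilocus level: dominant
markers carry no allele-dosage information, so a diploid/tetraploid dosage
model would add parameters that nothing downstream could see. Each
epilocus has a focal methylation state; presence maps to that state and
absence to the ambiguous `000` condition (no fragment in either panel),
which makes generation exactly inverse to scoring — the zero-noise
round-trip test `build_epilocus_matrix(states_to_panels(S)) == S` is an
identity, not an approximation. Within-group presence frequencies of
polymorphic loci are Uniform(0.2, 0.8); non-polymorphic loci are fixed
present or absent with equal probability, the fixed state shared across
groups so monomorphic bands are concordant between groups as real
fragments are. Sampling is independent across individuals given
covariates, so there is *no* residual spatial autocorrelation — matching
the near-null Moran's I structure of the emulated study and giving the
spatial null tests a clean stated world.

What the generator does **not** emulate: linkage or shared genetic
background between loci, methylation inheritance across generations,
isolation-by-distance in the residuals, scoring-intensity artifacts
(fragment-size–dependent error), or realistic Shannon magnitudes per
group (the uniform frequency model compresses between-group H'
differences relative to the published table). A green test therefore
establishes correctness of the statistical machinery on data with the
stated marginal structure, not faithfulness of any biological
conclusion.

## Numerical choices and edge cases

- Seeds: every stochastic routine takes a seed and derives per-stage
  sub-seeds below 2³¹, so a pipeline run is byte-reproducible (the
  acceptance suite re-runs the full 123 × 1088 study and compares files
  byte for byte).
- Degenerate inputs: empty size-filter results warn rather than error;
  all-identical samples give zero SSD everywhere and a flagged, undefined
  Φ; constant loci are excluded from Moran/Geary panel means and skipped
  (with a note) in locus-by-locus AMOVA and the association screen;
  constant environmental variables are skipped with a warning; a constant
  distance matrix is an error for Mantel.
- Permutation p-values use the add-one convention `(1 + k)/(1 + n)`, so
  they are never zero and are exactly uniform on a grid under the null.
  With very few loci the mismatch-distance statistics are heavily tied
  across permutations, which makes p conservative; the uniformity tests
  use wide panels where the statistic is effectively continuous.
- The logistic fitter declares separation when the slope diverges
  (|β₁| > 15, or > 10 without convergence) or the information matrix is
  numerically singular; such fits never become candidates.
- `pct_private` is reported relative to polymorphic markers (matching the
  published table's arithmetic, e.g. 2/48 = 4.2%), not total markers.

## Design decisions that were genuinely open

- The published one-factor ANOVA degrees of freedom (F(1, 364)) imply
  ~366 observations from 123 samples; the exact response stacking is not
  stated. The default response here is the per-sample presence count per
  panel (3 × 123 = 369 observations, stacked), which is documented and
  configurable but makes no attempt to reverse-engineer the published df.
- The p-adjustment reference for "adjusted p" is unspecified; Holm is the
  default (uniformly more powerful than Bonferroni at the same FWER),
  with Bonferroni and BH available, and the method is recorded in output.
- Published estimated Moran's I values (~ −0.008) do not equal −1/(n−1)
  for the printed group sizes; both the closed form and the permutation
  estimate are reported here and neither is forced to match.
- Whether the published candidate counts used corrected or raw thresholds
  is unstated; the screen reproduces the *structure* (counts by panel ×
  variable) on synthetic data only.
- A forward-stepwise multivariate association pass is deliberately not
  the default; the univariate marker ~ variable model is what the
  two-parameter description specifies.

## Limitations

Scoring starts from binary fragment panels: electropherogram processing,
peak calling and size binning are out of scope, and locus matching between
the HpaII and MspI panels must be supplied by the input files. The `000`
condition cannot distinguish holomethylation from mutation, and no
disambiguation is attempted. AMOVA variance components can be negative
with weak structure (reported, flagged). None of the published Tables 1/3/4/5
values are reproduced numerically — that would require the original
matrix — only their arithmetic identities and structural properties are
enforced.
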