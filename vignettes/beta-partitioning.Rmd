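---
title: "Partitioning abundance-based beta diversity across sampling grains"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Partitioning abundance-based beta diversity across sampling grains}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(karstbeta)
```

## The question

Site-to-site variation in species composition (beta diversity) can arise from
two very different processes. Individuals of some species at one site may be
*substituted* by an equal number of individuals of other species at another
site — balanced variation in abundance, the abundance analogue of species
turnover. Or one site's assemblage may simply be an abundance-depleted subset
of the other's — an abundance gradient, the analogue of nestedness. Telling
the two apart matters because substitution points to niche processes
(environmental filtering along gradients), while pure abundance loss points
to processes such as disturbance or sampling.

`karstbeta` implements this decomposition for gridded forest-census data and
the two follow-up analyses that make it interpretable: Mantel tests of each
component against topographic distances, and variation partitioning of each
component into habitat and spatial fractions. Because stem-mapped census
data of this kind are rarely public, the package ships a seeded generator
for a virtual karst plot on which the entire workflow runs end to end.

## The decomposition

For a pair of quadrats $m, n$ with per-species abundances $x_{ms}, x_{ns}$,
let

$$A = \sum_s \min(x_{ms}, x_{ns}), \qquad
  B = \sum_s (x_{ms} - \min(x_{ms}, x_{ns})), \qquad
  C = \sum_s (x_{ns} - \min(x_{ms}, x_{ns})).$$

$A$ counts individuals shared by the two quadrats, $B$ and $C$ those unique
to each. The Bray–Curtis (percentage difference) dissimilarity and its two
components are

$$\beta_{BC} = \frac{B + C}{2A + B + C}, \qquad
  \beta_{BC.BAL} = \frac{\min(B, C)}{A + \min(B, C)}, \qquad
  \beta_{BC.GRA} = \frac{|B - C|}{2A + B + C} \cdot \frac{A}{A + \min(B, C)},$$

with $\beta_{BC} = \beta_{BC.BAL} + \beta_{BC.GRA}$ exactly. On
presence/absence data $\beta_{BC}$ reduces to Sørensen dissimilarity and
$\beta_{BC.BAL}$ to Simpson (turnover) dissimilarity; the test suite checks
both collapses.

`beta_decompose()` keeps $A, B, C$ as exact integers and divides only at the
end, so the additivity identity holds to floating-point rounding (asserted
at $10^{-12}$). Internally the whole pair set is computed from two condensed
matrices via $B + C = \sum_s |x_{ms} - x_{ns}|$ (a Manhattan distance) and
$A = (T_m + T_n - (B+C))/2$, which keeps the 1,124,250 pairs of a 10-m
analysis cheap. Pairs involving an empty quadrat are $0/0$ and are returned
as `NA` rather than silently zeroed; real censuses never contain empty
quadrats but synthetic or subsetted data can.

Each defined pair yields a triplet (Similarity $= 1 - \beta_{BC}$, BAL, GRA)
summing to 1; `simplex_summary()` reports the component means, SDs and the
centroid of the pair cloud on that 2-simplex.

## The virtual plot

`synthetic_config()` fixes the study conditions; its defaults describe a
500 × 300 m (15-ha) plot on a fengcong depression — clustered limestone
peaks around a funnel-like low — with elevations spanning 180–370 m,
~220 woody species and ~68,000 stems of dbh ≥ 1 cm, and two censuses five
years apart with plot-wide mortality 14% and recruitment 5.7% of standing
stems (fractions typical of seasonal karst forest censuses, where turnover
concentrates in the seasonally flooded depressions).

The generator works at the 10-m cell level:

* **DEM** (`generate_dem()`): a sum of `n_peaks` Gaussian hills, one
  negative Gaussian (the depression) and a low-frequency smoothed-noise
  field, rescaled so the realised range is exactly `relief`. This is the
  minimal surface with a peak-cluster/depression gradient; it does not
  attempt cliffs, sinkholes or other micro-relief.
* **Community** (`generate_community()`): species $s$ has expected
  log-abundance in cell $c$ equal to
  $b_0 + w \cdot \text{niche}_s(\mathrm{ELE}_c, \mathrm{SLO}_c) +
  (1 - w) \cdot G_s(c)$, where the niche term is a Gaussian response around
  a species-specific elevation and slope optimum, $G_s$ is a species-specific
  Gaussian random field (kernel-smoothed white noise) with correlation
  length `neutral_range`, and $b_0$ normalises each species to a lognormal
  abundance target. Counts are Poisson; stems are placed uniformly inside
  their cell. `niche_weight` $w$ interpolates between pure niche assembly
  ($w = 1$) and pure spatially autocorrelated neutral assembly ($w = 0$);
  `neutral_range = 0` switches the random field off entirely, making counts
  independent Poisson — the calibration case used by the tests.
* **Second census** (`advance_census()`): each stem dies with probability
  `mortality_base` scaled by an elevation weight that (at
  `turnover_concentration = 1`) doubles turnover at the depression floor
  while keeping the plot-wide mean at the base rate; recruits arrive per
  stem with the analogous recruitment intensity and inherit the local
  species composition. Survivors keep their tags and coordinates.

What the generator does *not* emulate: size-structured demography and
growth, dispersal limitation as an explicit kernel, point-pattern clustering
within cells (counts are cell-level Poisson by design, since all downstream
analyses use per-cell counts), liana or disturbance dynamics, and soil
variables. Passing tests therefore show that the statistical machinery
recovers the assembly regime that generated the data, not that any
particular field system behaves this way.

## Quadrats, grains and margins

Stems are binned into half-open cells $[kg, (k+1)g)$; a stem exactly on the
upper plot boundary is invalid input. At grains that do not divide the plot
the far (east/north) margin is discarded: on 500 × 300 m, grain 30 and 60
use 480 × 300, grain 40 uses 480 × 280 (84 cells). The grain-20 abundance
matrix equals the grain-10 matrix summed over 2 × 2 blocks, a property the
tests assert.

## Topographic variables

Eight per-quadrat variables drive the environmental analyses: elevation
(ELE, m), slope (SLO, degrees), convexity (CON, m), the sine and cosine of
aspect, topographic wetness index (TWI), altitude above channels (ACH, m)
and rock-bareness rate (RBR, fraction). Conventions, since field papers
typically defer them to cited methods:

* ELE at grain $g$ is the mean of the constituent 10-m subcell corner-node
  means — a weighted node average that makes coarse ELE nest exactly in
  fine ELE.
* SLO is the mean slope of the four planes through three of the quadrat's
  corner nodes (the forest-plot standard); aspect is the steepest-ascent
  direction of the least-squares plane through the four corners, clockwise
  from north; quadrats with gradient below $10^{-6}$ degrees are flagged
  flat and get SIN = COS = 0.
* CON is focal ELE minus the mean of the up-to-8 neighbouring quadrats;
  edge quadrats use the cell-centre elevation minus their own corner mean.
* TWI and ACH are deliberately simple D8 stand-ins:
  single-direction flow on the quadrat-elevation grid, accumulation $a$ by
  descending-elevation sweep, $\mathrm{TWI} = \ln(a g / \tan(\max(\mathrm{SLO},
  0.1^\circ)))$, channels where $a$ exceeds a threshold (default ~5% of the
  grid), ACH = focal elevation minus that of the nearest channel cell.
  Field-measured TWI/ACH/RBR columns override the internal ones via the
  `overrides` argument; RBR in particular is a field survey with no terrain
  analogue, so the synthetic module supplies one (elevation-linked logistic
  plus smooth noise).

For variation partitioning the six non-aspect variables are centred and
expanded to first, second and third powers (18 columns) plus SIN and COS:
exactly 20 predictors. A constant column keeps its (zero) power columns
with a warning so the 20-column contract survives degenerate inputs.
Environmental distances are Euclidean on per-variable z-scores ($n-1$
denominator); z-scoring is per variable, not joint.

## Mantel tests

`mantel_spearman()` correlates the condensed upper triangles of two distance
matrices by Spearman's method and permutes site labels of the second matrix.
Relabelling permutes the off-diagonal values bijectively, so their ranks are
computed once and re-indexed per permutation — this makes 9,999 permutations
on 375 sites cheap. One-sided ("greater") is the default, matching common
practice; negative observed correlations then carry large p-values, and a
`two.sided` alternative is available. The reported p is
$(1 + \#\{r^* \ge r\})/(n_{perm} + 1)$ and can never fall below
$1/(n_{perm}+1)$. For up to 8 sites `exact = TRUE` enumerates all $n!$
relabellings. The trend of component means across grains is tested with
`grain_trend()`, a two-sided Spearman test that uses the exact permutation
null for $n \le 9$ (seven grains: a perfect monotone trend gives
$p = 2/5040 \approx 0.0004$).

## Spatial eigenvectors and variation partitioning

`build_dbmem()` constructs distance-based Moran's eigenvector maps: the
inter-centroid distance matrix is truncated at $t$ (default: the longest
minimum-spanning-tree edge, the smallest threshold that keeps the sites
connected — on a full grid of square cells this is one lattice step),
distances above $t$ are set to $4t$, and the modified matrix is
double-centred and eigen-decomposed. Axes with eigenvalue above
$10^{-9}\lambda_{max}$ are candidates; Moran's I is computed per axis with
binary $d \le t$ connectivity weights (the classic choice; the literature
does not fix one), and `select_mem()` retains axes with $I$ strictly above
the expectation $-1/(n-1)$. Eigenvector signs are fixed by making the
largest-magnitude loading positive so output is identical across
linear-algebra backends.

Bray–Curtis dissimilarities are not Euclidean-embeddable but their square
roots are, so each component matrix is square-rooted before the
principal-coordinate response is built (`sqrt_transform()`,
`pcoa_response()`; the most negative eigenvalue is recorded and must be
numerically zero after the transform). Fractions follow the habitat/space
convention: with Ezekiel-adjusted $R^2$ of the environmental ($E$), spatial
($S$) and joint models,

$$a = R^2_{adj}(E{+}S) - R^2_{adj}(S), \quad
  c = R^2_{adj}(E{+}S) - R^2_{adj}(E), \quad
  b = R^2_{adj}(E) + R^2_{adj}(S) - R^2_{adj}(E{+}S), \quad
  d = 1 - R^2_{adj}(E{+}S),$$

so $a + b + c + d = 1$ identically; $a$ is pure habitat, $b$ spatially
structured habitat, $c$ pure space, $d$ undetermined. Individual fractions
can be slightly negative, a known property of adjusted-$R^2$ arithmetic.
The Ezekiel adjustment is used for all models (including the distance-based
response) because it is cheap and standard for individual fractions;
permutation-based adjustments would change third-decimal values at most but
dominate run time.

### Forward selection

Predictors enter by forward selection guarded three ways: a global
permutation pre-test (no selection at all unless the model with every
candidate is significant at `alpha`), a partial permutation test of each
entering candidate (candidate and response residualised on the selected
set), and — from the second variable onwards — a stop once the cumulative
adjusted $R^2$ would exceed the global model's. The first variable is
exempt from that ceiling deliberately: the ceiling compares models with
different Ezekiel penalties, and when most candidates are uninformative the
one-variable adjusted $R^2$ legitimately exceeds the heavily penalised
global value, which would otherwise veto even a perfect predictor. The
global pre-test is what controls the selection-wide error rate (the
per-step test alone, being a best-of-k statistic, does not); a simulation
in the test suite checks the realised null selection rate stays near
`alpha`. Selection is implemented by incremental Gram–Schmidt
orthogonalisation, so each step costs one crossproduct per remaining
candidate; 375 sites with ~190 spatial candidates select in seconds. The
pipeline additionally caps each predictor set at $(n-2)/2$ variables so the
joint model stays estimable on very small site sets.

## Numerical choices and degenerate inputs

* $A, B, C$ are exact integers; all three component matrices are `dist`
  objects (condensed storage) and export as site-pair tables.
* PCoA/dbMEM eigenvalue tolerance: $10^{-9} \lambda_{max}$; eigenvectors
  below it are treated as numeric zeros.
* D8 ties are broken in the fixed order E, N, W, S, NE, NW, SW, SE; flow
  accumulation uses a descending-elevation sweep, so pits simply absorb.
* Flat quadrats: SIN = COS = 0 plus a `flat` flag, rather than an arbitrary
  aspect.
* `mortality_base = 1` means certain death everywhere even when turnover is
  elevation-weighted (the weighting otherwise preserves the plot-wide mean).
* Empty predictor sets are legal everywhere and give $a = b = c = 0$,
  $d = 1$.
* Seeds: every stochastic stage takes an explicit seed; `run_pipeline()`
  derives per-stage child seeds from the master seed with a counter scheme
  and records them in the report, so any stage can be reproduced alone.

## Problem sizes used by the checks

The packaged tests run the full decomposition chain at the default study
conditions (1,500 quadrats at 10 m, 375 at 20 m) where the computation is
closed-form, and scaled-down plots (200 × 100 m, 40 species, ~6,000 stems,
50 quadrats at 20 m) for the replicated stochastic checks: 20 seeded
replicates per assembly regime for parameter recovery (niche-dominated
plots must put habitat fractions above pure space, neutral plots the
reverse) and 20 for the Mantel niche-signal check, with 99–199 permutations
per test. `scripts/acceptance.R` runs the full-size plot with 999 Mantel
and 199 selection permutations; the field-standard 9,999 permutations only
sharpen p-values already at the permutation floor.

## Known limitations

* TWI/ACH are single-flow-direction approximations; multi-flow hydrology
  and kriging of irregular field elevations are out of scope.
* The Podani-family decomposition and Jaccard-family indices are not
  implemented; the simplex summary and all tests are specific to the
  Bray–Curtis family.
* Negative PCoA eigenvalues are discarded rather than corrected (none
  survive the square-root transform in practice).
* Mantel and selection p-values are permutation-resolution limited; with
  `n_perm = 999` the smallest reportable p is 0.001.
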