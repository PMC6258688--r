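# karstbeta

Abundance-based beta-diversity partitioning for gridded forest-census data,
with the follow-up analyses that make the partition interpretable: Mantel
tests against topographic gradients and variation partitioning into habitat
and spatial fractions.

## What it does and for whom

Community ecologists working with stem-mapped forest-dynamics plots (and,
with the same machinery, microbiome/metagenomics researchers working with
sample × taxon count tables) often need to know not just *how much* species
composition varies between sampling units, but *how*: by substitution of
individuals of some species for individuals of others (balanced variation,
the abundance analogue of turnover), or by one unit being an
abundance-depleted subset of the other (abundance gradients, the analogue of
nestedness).

For a quadrat pair with `A` shared individuals and `B`, `C` individuals
unique to each side (summed over species):

```
beta_BC     = (B + C) / (2A + B + C)                    Bray-Curtis
beta_BC.BAL = min(B, C) / (A + min(B, C))               balanced variation
beta_BC.GRA = |B - C|/(2A + B + C) * A/(A + min(B, C))  abundance gradient
```

with `beta_BC = beta_BC.BAL + beta_BC.GRA` exactly. The package computes all
pairwise components at a series of sampling grains (10–60 m quadrats, with
the far margin discarded where a grain does not divide the plot), tests each
component against standardised topographic distances (Spearman Mantel tests
with permutation p-values), and partitions each component's variation into
pure habitat (a), spatially structured habitat (b), pure space (c, from
dbMEM spatial eigenvectors) and undetermined (d) fractions via distance-based
redundancy analysis on square-rooted dissimilarities with forward-selected
predictors.

Because stem-mapped census data are rarely public, the package includes a
seeded generator for a virtual karst (fengcong-depression) plot — DEM,
niche/neutral community, and two censuses linked by elevation-dependent
birth–death dynamics — so the full workflow is reproducible offline. See the
methods vignette (`vignettes/beta-partitioning.Rmd`) for the model and every
convention.

## Worked example

```r
library(karstbeta)

cfg <- synthetic_config(seed = 1)          # 500 x 300 m, ~68,000 stems
dem <- generate_dem(cfg)
c1  <- generate_community(dem, cfg)
geo <- plot_geometry(500, 300)

ab  <- aggregate_census(c1, geo, grain = 20)   # 375 quadrats
bc  <- beta_decompose(ab)                      # 70,125 pairs per component
simplex_summary(bc)$means
#>        sim        bal        gra
#> 0.36220266 0.58875179 0.04904555

env <- topo_variables(dem, geo, 20, rbr = generate_rbr(dem, cfg))
mantel_spearman(env_distance(env), bc$bc, n_perm = 999, seed = 2)
#> Mantel test (Spearman), 375 sites, 999 permutations
#>   r = 0.6046, p = 0.001 (greater)
```

Mean dissimilarity at the 20-m grain is 0.64, of which 0.59 is balanced
variation and only 0.05 abundance gradients: pairs of quadrats differ mostly
by swapping individuals of different species, not by thinning, and that
compositional difference tracks the topographic distance (r = 0.60,
significant at the permutation floor).

The numbered scripts under `analysis/` run the whole study on the simulated
plot and write tables under `results/`:

```sh
Rscript analysis/01_simulate.R        # plot, two censuses, turnover summary
Rscript analysis/02_beta_partition.R  # components by grain + trend tests
Rscript analysis/03_topography.R      # per-grain environment tables
Rscript analysis/04_mantel.R          # driver-by-component Mantel battery
Rscript analysis/05_dbmem_varpart.R   # dbMEM + variation partitioning
```

Stage 2, for example, prints the grain-size trend (seed 1):

```
census 1: mean beta_bc 0.751 (10 m) -> 0.521 (60 m); balanced share at 20 m: 92%
  grain trend bc : rho = -1.000, exact p = 0.0004
  grain trend bal: rho = -1.000, exact p = 0.0004
  grain trend gra: rho =  0.821, exact p = 0.0341
```

— total beta diversity and its balanced component decline strictly
monotonically as quadrats grow from 10 m to 60 m (a perfect negative rank
correlation over seven grains has exact two-sided p = 2/5040 ≈ 0.0004), and
stage 5 partitions the 20-m Bray–Curtis variation into a = 0.002 (pure
habitat), b = 0.270 (spatially structured habitat), c = 0.184 (pure space),
d = 0.544 (undetermined): habitat beats pure space, but almost all habitat
signal is itself spatially structured, as expected on a terrain whose
gradients are spatial by construction.

`run_pipeline(pipeline_config(...))` performs the same stages in one call
with per-stage child seeds recorded in its report.

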