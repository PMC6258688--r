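# Synthetic fengcong-depression plot generator.

test_that("dem generation is deterministic and spans the configured relief", {
  cfg <- small_config(seed = 1)
  d1 <- generate_dem(cfg)
  d2 <- generate_dem(cfg)
  expect_identical(d1, d2)
  expect_true(all(is.finite(d1$elev)))
  expect_equal(dim(d1$elev), c(21, 11))
  # rescaled surface: realised range is exactly [base, base + relief]
  expect_equal(min(d1$elev), cfg$base_elevation)
  expect_equal(max(d1$elev), cfg$base_elevation + cfg$relief)
  # regression fixture for the default-config realised surface
  d_def <- generate_dem(synthetic_config(seed = 1))
  expect_equal(range(d_def$elev), c(180, 370))
  expect_equal(dim(d_def$elev), c(51, 31))
})

test_that("dem has peaks and a depression; degenerate configs are flat", {
  d <- generate_dem(small_config(seed = 4, n_peaks = 3))
  z <- d$elev
  interior_max <- max(z[2:(nrow(z) - 1), 2:(ncol(z) - 1)])
  expect_gt(interior_max, mean(z))  # relief concentrated in hills
  # at least one interior local minimum (a depression)
  has_pit <- FALSE
  for (i in 2:(nrow(z) - 1)) for (j in 2:(ncol(z) - 1)) {
    nb <- z[(i - 1):(i + 1), (j - 1):(j + 1)][-5]
    if (all(z[i, j] < nb)) has_pit <- TRUE
  }
  expect_true(has_pit)
  flat <- generate_dem(small_config(seed = 1, n_peaks = 0, relief = 0))
  expect_true(all(flat$elev == flat$elev[1, 1]))
})

test_that("config invariants are enforced", {
  expect_error(synthetic_config(seed = 1, x_extent = 505), "divisible")
  expect_error(synthetic_config(seed = 1, niche_weight = 1.2), "niche_weight")
  expect_error(synthetic_config(1, n_species = 1), "n_species")
  expect_error(synthetic_config(), "seed")
})

test_that("community generation is seed-deterministic and hits stem target", {
  cfg <- small_config(seed = 7)
  dem <- generate_dem(cfg)
  c1 <- generate_community(dem, cfg)
  expect_identical(c1, generate_community(dem, cfg))
  expect_false(anyDuplicated(c1$tag) > 0)
  expect_true(all(c1$gx >= 0 & c1$gx < cfg$x_extent))
  expect_true(all(c1$gy >= 0 & c1$gy < cfg$y_extent))
  expect_true(all(c1$dbh >= 1))
  expect_lt(abs(nrow(c1) - cfg$n_stems_target) / cfg$n_stems_target, 0.1)
})

test_that("w = 0 with zero neutral range gives iid Poisson cell counts", {
  # intensities are then uniform per species, so across-cell variance/mean
  # of any one species' counts is about 1 (1500 cells Monte-Carlo check)
  cfg <- synthetic_config(seed = 21, x_extent = 500, y_extent = 300,
                          n_species = 10, n_stems_target = 30000,
                          niche_weight = 0, neutral_range = 0)
  dem <- generate_dem(cfg)
  c1 <- generate_community(dem, cfg)
  geo <- plot_geometry(500, 300)
  ab <- aggregate_census(c1, geo, 10)
  expect_equal(nrow(ab$counts), 1500)
  top <- order(colSums(ab$counts), decreasing = TRUE)[1:3]
  for (s in top) {
    x <- ab$counts[, s]
    expect_lt(abs(var(x) / mean(x) - 1), 0.15)
  }
})

test_that("w = 1 species with a high-elevation optimum tracks elevation", {
  cfg <- small_config(seed = 5, niche_weight = 1)
  dem <- generate_dem(cfg)
  geo <- plot_geometry(cfg$x_extent, cfg$y_extent)
  env <- topo_variables(dem, geo, 10, compute_twi_ach = FALSE)
  # pick the species whose realised optimum is highest
  pars <- karstbeta:::with_seed(karstbeta:::child_seed(cfg$seed, 2L),
                                karstbeta:::.species_pars(dem, cfg))
  c1 <- generate_community(dem, cfg)
  ab <- aggregate_census(c1, geo, 10,
                         species_levels = sprintf("sp%03d", 1:cfg$n_species))
  common <- which(colSums(ab$counts) >= 50)
  sp_hi <- common[which.max(pars$opt_e[common])]
  expect_gt(cor(ab$counts[, sp_hi], env$ELE, method = "spearman"), 0)
})

test_that("advancing the census respects the degenerate limits", {
  cfg <- small_config(seed = 9, mortality_base = 0, recruitment_base = 0)
  dem <- generate_dem(cfg)
  c1 <- generate_community(dem, cfg)
  c2 <- advance_census(c1, dem, cfg)
  c2$census <- 1L
  expect_equal(c2, c1, ignore_attr = TRUE)
  cfg_x <- small_config(seed = 9, mortality_base = 1, recruitment_base = 0)
  expect_equal(nrow(advance_census(c1, dem, cfg_x)), 0)
})

test_that("realised mortality matches the binomial expectation", {
  cfg <- small_config(seed = 10, mortality_base = 0.15, recruitment_base = 0,
                      turnover_concentration = 0)
  dem <- generate_dem(cfg)
  c1 <- generate_community(dem, cfg)
  c2 <- advance_census(c1, dem, cfg)
  n <- nrow(c1)
  dead <- n - nrow(c2)
  expect_lt(abs(dead - 0.15 * n), 3 * sqrt(n * 0.15 * 0.85))
  # elevation-dependent turnover keeps the same plot-wide expectation
  cfg2 <- small_config(seed = 10, mortality_base = 0.15,
                       recruitment_base = 0, turnover_concentration = 1)
  dead2 <- n - nrow(advance_census(c1, dem, cfg2))
  expect_lt(abs(dead2 - 0.15 * n), 4 * sqrt(n * 0.15 * 0.85))
})

test_that("turnover concentrates in depressions when configured", {
  cfg <- small_config(seed = 12, mortality_base = 0.2,
                      turnover_concentration = 1.5)
  dem <- generate_dem(cfg)
  c1 <- generate_community(dem, cfg)
  c2 <- advance_census(c1, dem, cfg)
  geo <- plot_geometry(cfg$x_extent, cfg$y_extent)
  dyn <- census_dynamics(c1, c2, geo, 20)
  env <- topo_variables(dem, geo, 20, compute_twi_ach = FALSE)
  ab1 <- aggregate_census(c1, geo, 20)
  dead_rate <- dyn$cells$dead[match(env$site, dyn$cells$site)] /
    pmax(rowSums(ab1$counts), 1)
  expect_lt(cor(dead_rate, env$ELE, method = "spearman"), 0)
})

test_that("every census-2 stem is a tagged survivor or a fresh recruit", {
  cfg <- small_config(seed = 13)
  dem <- generate_dem(cfg)
  c1 <- generate_community(dem, cfg)
  c2 <- advance_census(c1, dem, cfg)
  expect_false(anyDuplicated(c2$tag) > 0)
  surv <- c2[c2$tag %in% c1$tag, ]
  expect_true(all(startsWith(setdiff(c2$tag, c1$tag), "R")))
  m <- match(surv$tag, c1$tag)
  expect_equal(surv$gx, c1$gx[m])
  expect_equal(surv$gy, c1$gy[m])
  expect_equal(surv$species, c1$species[m])
})

test_that("single-species communities show no balanced variation", {
  # one species: sites can only differ by abundance gradients
  X <- matrix(c(5L, 2L, 9L, 1L), 4, 1,
              dimnames = list(sprintf("s%d", 1:4), "spA"))
  bc <- beta_decompose(X)
  expect_true(all(as.vector(bc$bal) == 0))
  expect_equal(as.vector(bc$bc), as.vector(bc$gra))
})

test_that("niche-driven plots leave a detectable environmental signal", {
  # pure niche assembly: env-vs-beta Mantel significant in nearly all
  # replicates; pure short-range neutral assembly: r centred near zero
  geo <- plot_geometry(200, 100)
  run_one <- function(seed, w, range) {
    cfg <- synthetic_config(seed = seed, x_extent = 200, y_extent = 100,
                            n_species = 40, n_stems_target = 6000,
                            n_peaks = 2, niche_weight = w,
                            neutral_range = range)
    dem <- generate_dem(cfg)
    bc <- beta_decompose(aggregate_census(generate_community(dem, cfg),
                                          geo, 20))
    env <- topo_variables(dem, geo, 20, rbr = generate_rbr(dem, cfg))
    mantel_spearman(env_distance(env), bc$bc, n_perm = 199, seed = seed)
  }
  niche <- lapply(301:320, run_one, w = 1, range = 0)
  sig <- vapply(niche, function(m) m$statistic > 0 && m$p.value <= 0.05,
                logical(1))
  expect_gte(mean(sig), 0.95)
  neutral <- lapply(301:320, run_one, w = 0, range = 5)
  r_null <- vapply(neutral, `[[`, numeric(1), "statistic")
  expect_lt(abs(mean(r_null)), 0.1)
})

test_that("synthetic rbr is a valid rock-bareness field", {
  cfg <- small_config(seed = 2)
  dem <- generate_dem(cfg)
  rbr <- generate_rbr(dem, cfg)
  expect_equal(dim(rbr), c(20, 10))
  expect_true(all(rbr >= 0 & rbr <= 1))
  # bare rock concentrates on the peaks
  ele <- karstbeta:::.cell_ele(dem, 10, 20, 10)
  expect_gt(cor(as.vector(ele), as.vector(rbr)), 0.5)
})
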