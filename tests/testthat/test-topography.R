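# Topographic variables, polynomial expansion, environmental distances.

# hand-built dem: z = f(x, y) sampled on the node lattice
make_dem <- function(f, x_extent = 100, y_extent = 100, res = 10) {
  x <- seq(0, x_extent, by = res)
  y <- seq(0, y_extent, by = res)
  structure(list(elev = outer(x, y, f), x = x, y = y, resolution = res,
                 x_extent = x_extent, y_extent = y_extent),
            class = "elevation_grid")
}

test_that("a flat dem gives zero slope and convexity, flagged flat", {
  dem <- make_dem(function(x, y) 0 * x + 5)
  geo <- plot_geometry(100, 100)
  env <- topo_variables(dem, geo, 20, compute_twi_ach = FALSE)
  expect_true(all(env$SLO == 0))
  expect_true(all(env$CON == 0))
  expect_true(all(env$flat))
  expect_true(all(env$SIN == 0 & env$COS == 0))
  expect_true(all(env$ELE == 5))
})

test_that("the plane z = x has 45-degree slope and aspect due east", {
  dem <- make_dem(function(x, y) x)
  geo <- plot_geometry(100, 100)
  for (g in c(10, 20, 50)) {
    env <- topo_variables(dem, geo, g, compute_twi_ach = FALSE)
    expect_equal(env$SLO, rep(45, nrow(env)))
    expect_equal(env$SIN, rep(1, nrow(env)))
    expect_equal(env$COS, rep(0, nrow(env)), tolerance = 1e-12)
  }
  # z = y rises due north
  demy <- make_dem(function(x, y) y)
  envy <- topo_variables(demy, geo, 20, compute_twi_ach = FALSE)
  expect_equal(envy$SIN, rep(0, nrow(envy)), tolerance = 1e-12)
  expect_equal(envy$COS, rep(1, nrow(envy)))
})

test_that("convexity: raised interior cell is +1, cardinal neighbours -1/8", {
  ele <- matrix(0, 5, 5)
  ele[3, 3] <- 1
  con <- cell_convexity(ele)
  expect_equal(con[3, 3], 1)
  expect_equal(con[2, 3], -1 / 8)
  expect_equal(con[3, 2], -1 / 8)
  expect_equal(con[4, 3], -1 / 8)
  expect_equal(con[3, 4], -1 / 8)
  expect_equal(con[2, 2], -1 / 8)  # diagonal neighbours likewise
  expect_true(all(is.na(con[1, ])))  # edge cells need centre elevations
  con2 <- cell_convexity(ele, center_ele = ele)
  expect_equal(con2[1, 1], 0)
})

test_that("ELE nests exactly: grain-20 ELE is the mean of its grain-10 ELEs", {
  cfg <- small_config(seed = 8)
  dem <- generate_dem(cfg)
  geo <- plot_geometry(cfg$x_extent, cfg$y_extent)
  e10 <- topo_variables(dem, geo, 10, compute_twi_ach = FALSE)
  e20 <- topo_variables(dem, geo, 20, compute_twi_ach = FALSE)
  for (r in seq_len(nrow(e20))) {
    sub <- e10[e10$ix %/% 2 == e20$ix[r] & e10$iy %/% 2 == e20$iy[r], ]
    expect_equal(e20$ELE[r], mean(sub$ELE))
  }
})

test_that("rotating the dem 90 degrees permutes aspect and preserves slope", {
  cfg <- small_config(seed = 14, x_extent = 100, y_extent = 100)
  dem <- generate_dem(cfg)
  geo <- plot_geometry(100, 100)
  env <- topo_variables(dem, geo, 20, compute_twi_ach = FALSE)
  # rotate nodes 90 deg counter-clockwise: (x, y) -> (y_extent - y, x)
  rot <- dem
  rot$elev <- t(dem$elev)[ncol(dem$elev):1, ]
  envr <- topo_variables(rot, geo, 20, compute_twi_ach = FALSE)
  # cell (ix, iy) maps to rotated cell (ny - 1 - iy, ix)
  ny <- max(env$iy) + 1
  key <- sprintf("x%03d_y%03d", ny - 1 - env$iy, env$ix)
  m <- match(key, envr$site)
  expect_equal(envr$SLO[m], env$SLO, tolerance = 1e-10)
  expect_equal(envr$CON[m], env$CON, tolerance = 1e-10)
  # east in the original becomes north in the rotated frame
  expect_equal(envr$COS[m], env$SIN, tolerance = 1e-10)
  expect_equal(envr$SIN[m], -env$COS, tolerance = 1e-10)
})

test_that("D8 drainage on an inclined plane accumulates along rows", {
  dem <- make_dem(function(x, y) x / 10)  # drains due west
  geo <- plot_geometry(100, 100)
  ta <- twi_ach(dem, geo, 10, channel_threshold = 10)
  acc <- ta$accumulation
  cen <- cell_centroids(geo, 10)
  # accumulation grows from 1 on the east edge to the row length on the west
  expect_true(all(acc[cen$ix == 9] == 1))
  expect_true(all(acc[cen$ix == 0] == 10))
  expect_true(all(ta$ACH[cen$ix == 0] == 0))  # west edge is the channel
  expect_true(all(ta$channel == (acc >= 10)))
})

test_that("a bowl drains to its minimum and channel cells have ACH zero", {
  dem <- make_dem(function(x, y) ((x - 50)^2 + (y - 50)^2) / 1000,
                  x_extent = 100, y_extent = 100)
  geo <- plot_geometry(100, 100)
  ta <- twi_ach(dem, geo, 20, channel_threshold = 25)
  expect_equal(max(ta$accumulation), 25)  # global max at the bowl minimum
  ele <- karstbeta:::.cell_ele(dem, 20, 5, 5)
  expect_equal(which.max(ta$accumulation), which.min(as.vector(ele)))
  expect_equal(sum(ta$channel), 1)
  expect_equal(ta$ACH[ta$channel], 0)
  expect_true(all(ta$ACH[!ta$channel] > 0))
  expect_error(twi_ach(dem, geo, 20, channel_threshold = 26), "channel")
})

test_that("polynomial expansion yields exactly 20 documented columns", {
  cfg <- small_config(seed = 2)
  dem <- generate_dem(cfg)
  geo <- plot_geometry(cfg$x_extent, cfg$y_extent)
  env <- topo_variables(dem, geo, 20, rbr = generate_rbr(dem, cfg))
  ex <- polynomial_expand(env)
  expect_equal(ncol(ex), 20)
  expect_equal(colnames(ex),
               c(t(outer(c("ELE", "SLO", "CON", "TWI", "ACH", "RBR"),
                         c("", ".2", ".3"), paste0)), "SIN", "COS"))
  # first-power columns are centred; powers are powers of the centred value
  expect_equal(unname(colMeans(ex)[["ELE"]]), 0)
  expect_equal(ex[, "ELE.3"], ex[, "ELE"]^3)
  # hand check: v = (-1, 0, 1) is already centred, cube preserved
  env3 <- env[1:3, ]
  for (v in c("ELE", "SLO", "CON", "TWI", "ACH", "RBR")) env3[[v]] <- c(-1, 0, 1)
  ex3 <- polynomial_expand(env3)
  expect_equal(unname(ex3[, "ELE.3"]), c(-1, 0, 1))
})

test_that("a constant variable keeps the 20-column contract with zeros", {
  cfg <- small_config(seed = 2)
  dem <- generate_dem(cfg)
  geo <- plot_geometry(cfg$x_extent, cfg$y_extent)
  env <- topo_variables(dem, geo, 20, rbr = generate_rbr(dem, cfg))
  env$RBR <- 0.5
  expect_warning(ex <- polynomial_expand(env), "constant column RBR")
  expect_equal(ncol(ex), 20)
  expect_true(all(ex[, c("RBR", "RBR.2", "RBR.3")] == 0))
})

test_that("environmental distance is the z-scored Euclidean metric", {
  env <- data.frame(site = c("a", "b"), ELE = c(0, 1))
  d <- env_distance(env, "ELE")
  expect_equal(as.vector(d), sqrt(2), tolerance = 1e-12)  # z = +-0.7071
  env2 <- data.frame(site = c("a", "b"), ELE = c(0, 1), SLO = c(0, 1))
  expect_equal(as.vector(env_distance(env2, c("ELE", "SLO"))), 2)
  env3 <- data.frame(site = c("a", "b"), ELE = c(3, 3), SLO = c(0, 1))
  expect_warning(d3 <- env_distance(env3, c("ELE", "SLO")), "zero-variance")
  expect_equal(as.vector(d3), sqrt(2))
  # identical sites are at distance zero
  env4 <- data.frame(site = c("a", "b", "c"), ELE = c(1, 1, 2), SLO = c(2, 2, 9))
  expect_equal(as.matrix(env_distance(env4, c("ELE", "SLO")))["a", "b"], 0)
})

test_that("environmental distances satisfy the triangle inequality", {
  set.seed(42)
  for (rep in 1:20) {
    env <- matrix(rnorm(8 * 5), 8, 5,
                  dimnames = list(NULL, paste0("v", 1:5)))
    dm <- as.matrix(env_distance(env))
    n <- nrow(dm)
    for (i in 1:n) for (j in 1:n) for (k in 1:n) {
      expect_lte(dm[i, j], dm[i, k] + dm[k, j] + 1e-12)
    }
  }
})

test_that("dem CSV round-trips through read_dem", {
  cfg <- small_config(seed = 3)
  dem <- generate_dem(cfg)
  p <- withr::local_tempfile(fileext = ".csv")
  write_dem(dem, p)
  back <- read_dem(p)
  expect_equal(back$elev, dem$elev, ignore_attr = TRUE)
  expect_equal(back$resolution, 10)
})
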