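# Census I/O, grain sub-extents, quadrat aggregation, dynamics.

test_that("census CSV round-trips and validates", {
  geo <- plot_geometry(500, 300)
  df <- tiny_census(gx = c(0, 10.5, 499.9), gy = c(0, 20.2, 299.9),
                    species = c("spA", "spB", "spA"))
  p <- withr::local_tempfile(fileext = ".csv")
  write_census(df, p)
  got <- read_census(p, geo)
  expect_equal(nrow(got), 3)
  expect_equal(got$species, df$species)
})

test_that("the upper plot boundary is excluded (half-open convention)", {
  geo <- plot_geometry(500, 300)
  df <- tiny_census(gx = c(10, 500), gy = c(10, 10))
  expect_error(validate_census(df, geo), "out-of-bounds.*t002")
  df2 <- tiny_census(gx = c(10, -0.1), gy = c(10, 10))
  expect_error(validate_census(df2, geo), "out-of-bounds")
})

test_that("stems below 1 cm dbh are excluded with a count", {
  geo <- plot_geometry(500, 300)
  df <- tiny_census(gx = c(1, 2, 3), gy = c(1, 2, 3), dbh = c(5, 0.5, 1))
  expect_warning(got <- validate_census(df, geo), "1 stem")
  expect_equal(nrow(got), 2)
  expect_equal(attr(got, "n_excluded_dbh"), 1)
})

test_that("duplicate tags within a census are rejected", {
  geo <- plot_geometry(500, 300)
  df <- tiny_census(gx = c(1, 2), gy = c(1, 2))
  df$tag <- c("t1", "t1")
  expect_error(validate_census(df, geo), "duplicated tag")
})

test_that("missing columns are a format error", {
  geo <- plot_geometry(500, 300)
  expect_error(validate_census(data.frame(tag = "a", gx = 1), geo),
               "lacks column")
})

test_that("sub-extents follow the far-margin discard rule", {
  geo <- plot_geometry(500, 300)
  expect_equal(unname(sub_extent_for_grain(geo, 10)), c(500, 300))
  expect_equal(unname(sub_extent_for_grain(geo, 20)), c(500, 300))
  expect_equal(unname(sub_extent_for_grain(geo, 25)), c(500, 300))
  expect_equal(unname(sub_extent_for_grain(geo, 30)), c(480, 300))
  expect_equal(unname(sub_extent_for_grain(geo, 40)), c(480, 280))
  expect_equal(unname(sub_extent_for_grain(geo, 50)), c(500, 300))
  expect_equal(unname(sub_extent_for_grain(geo, 60)), c(480, 300))
  expect_error(sub_extent_for_grain(geo, 350), "exceeds")
})

test_that("cell counts match the quadrat grid sizes", {
  geo <- plot_geometry(500, 300)
  expect_equal(nrow(cell_centroids(geo, 10)), 1500)  # 50 x 30
  expect_equal(nrow(cell_centroids(geo, 20)), 375)   # 25 x 15
  expect_equal(nrow(cell_centroids(geo, 40)), 84)    # 12 x 7
  expect_equal(nrow(cell_centroids(geo, 60)), 40)    # 8 x 5
  expect_equal(cell_centroids(geo, 20)[1, c("cx", "cy")],
               data.frame(cx = 10, cy = 10))
})

test_that("aggregation assigns half-open cells and discards the margin", {
  geo <- plot_geometry(500, 300)
  df <- tiny_census(gx = c(0, 485, 19.999, 20), gy = c(0, 10, 0, 0),
                    species = c("spA", "spB", "spA", "spA"))
  ab40 <- aggregate_census(df, geo, 40)
  expect_equal(ab40$n_discarded, 1)  # the stem at gx = 485 (sub-extent 480)
  expect_equal(sum(ab40$counts), 3)
  ab20 <- aggregate_census(df, geo, 20)
  expect_equal(ab20$counts["x000_y000", "spA"], 2L)  # 0 and 19.999
  expect_equal(ab20$counts["x001_y000", "spA"], 1L)  # 20 goes to the next cell
  expect_equal(sum(ab20$counts), 4)
})

test_that("one stem per 10-m cell gives the identity abundance matrix", {
  geo <- plot_geometry(500, 300)
  cen <- cell_centroids(geo, 10)
  df <- tiny_census(gx = cen$cx, gy = cen$cy)
  ab <- aggregate_census(df, geo, 10)
  expect_equal(nrow(ab$counts), 1500)
  expect_true(all(ab$counts == 1L))
})

test_that("aggregation conserves stems and nests across grains", {
  cfg <- small_config(seed = 3)
  dem <- generate_dem(cfg)
  c1 <- generate_community(dem, cfg)
  geo <- plot_geometry(cfg$x_extent, cfg$y_extent)
  for (g in c(10, 20, 25, 40, 50)) {
    ab <- aggregate_census(c1, geo, g)
    expect_equal(sum(ab$counts) + ab$n_discarded, nrow(c1))
  }
  # grain-20 equals grain-10 summed over 2x2 blocks of cells
  ab10 <- aggregate_census(c1, geo, 10)
  ab20 <- aggregate_census(c1, geo, 20)
  s10 <- ab10$sites
  for (site in sample(rownames(ab20$counts), 10)) {
    r <- ab20$sites[ab20$sites$site == site, ]
    block <- s10$site[s10$ix %/% 2 == r$ix & s10$iy %/% 2 == r$iy]
    expect_equal(colSums(ab10$counts[block, , drop = FALSE]),
                 ab20$counts[site, ])
  }
})

test_that("dynamics: identical censuses give all-zero turnover", {
  geo <- plot_geometry(500, 300)
  df <- tiny_census(gx = c(1, 2), gy = c(1, 2))
  dyn <- census_dynamics(df, df, geo, 20)
  expect_equal(dyn$dead_total, 0)
  expect_equal(dyn$new_total, 0)
  expect_length(dyn$species_lost, 0)
})

test_that("dynamics: full replacement is counted as one death and one birth", {
  geo <- plot_geometry(500, 300)
  c1 <- tiny_census(gx = 1, gy = 1, species = "spA")
  c2 <- tiny_census(gx = 2, gy = 2, species = "spB")
  c2$tag <- "u001"
  dyn <- census_dynamics(c1, c2, geo, 20)
  expect_equal(dyn$dead_total, 1)
  expect_equal(dyn$new_total, 1)
  expect_equal(dyn$species_lost, "spA")
  expect_equal(dyn$species_gained, "spB")
})

test_that("dynamics agree with a brute-force tag set-difference oracle", {
  cfg <- small_config(seed = 6, mortality_base = 0.1)
  dem <- generate_dem(cfg)
  c1 <- generate_community(dem, cfg)
  c2 <- advance_census(c1, dem, cfg)
  geo <- plot_geometry(cfg$x_extent, cfg$y_extent)
  dyn <- census_dynamics(c1, c2, geo, 25)
  expect_equal(dyn$dead_total, length(setdiff(c1$tag, c2$tag)))
  expect_equal(dyn$new_total, length(setdiff(c2$tag, c1$tag)))
  # per-species and per-cell totals agree (ragged edge cells, no discard)
  expect_equal(sum(dyn$species_dead), sum(dyn$cells$dead))
  expect_equal(sum(dyn$species_new), sum(dyn$cells$new))
  expect_equal(sum(dyn$species_dead), dyn$dead_total)
})

test_that("abundance matrices export in long and wide form", {
  geo <- plot_geometry(500, 300)
  df <- tiny_census(gx = c(0, 30), gy = c(0, 10),
                    species = c("spA", "spB"))
  ab <- aggregate_census(df, geo, 20)
  p <- withr::local_tempfile(fileext = ".csv")
  write_abundance(ab, p, form = "long")
  long <- utils::read.csv(p)
  expect_equal(sum(long$count), 2)
  meta <- jsonlite::read_json(paste0(p, ".json"))
  expect_equal(meta$grain, 20)
})
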