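# Synthetic fengcong-depression forest plot: elevation grid, niche/neutral
# community, and birth-death dynamics linking two censuses.  Stands in for a
# real gridded stem census so every downstream stage is testable offline.

#' Configuration of the synthetic karst plot
#'
#' Defaults emulate a 15-ha (500 x 300 m) karst plot on a
#' fengcong-depression: clustered limestone peaks around a funnel-like
#' depression, ~190 m of relief starting at 180 m a.s.l., roughly 220 woody
#' species and 68,000 stems, and two censuses linked by elevation-dependent
#' mortality and recruitment concentrated in the depressions.
#'
#' @param seed master RNG seed (mandatory; every generator is deterministic
#'   under it).
#' @param x_extent,y_extent plot size in metres.
#' @param dem_resolution elevation node spacing in metres.
#' @param n_peaks number of Gaussian hills.
#' @param relief total elevation range in metres.
#' @param base_elevation elevation of the lowest node in metres a.s.l.
#' @param n_species,n_stems_target community size targets.
#' @param niche_weight w in `[0, 1]`: mixes deterministic niche structure
#'   (w = 1) against a spatially autocorrelated neutral field (w = 0) on the
#'   log-intensity scale.
#' @param neutral_range correlation length (metres) of the neutral Gaussian
#'   random field; 0 disables it (per-cell intensities then depend only on
#'   the niche term, so with w = 0 counts are iid Poisson).
#' @param neutral_sd marginal SD of the neutral field on the log scale.
#' @param mortality_base expected per-stem death probability between the two
#'   censuses (plot-wide mean).
#' @param recruitment_base expected recruits per living stem.
#' @param turnover_concentration strength of the elevation dependence of
#'   turnover: 0 = uniform; 1 doubles turnover at the depression floor
#'   relative to a uniform plot while keeping the plot-wide means at the
#'   base rates.
#' @return object of class `synthetic_config`.
#' @export
synthetic_config <- function(seed,
                             x_extent = 500, y_extent = 300,
                             dem_resolution = 10,
                             n_peaks = 4, relief = 190, base_elevation = 180,
                             n_species = 220, n_stems_target = 68000,
                             niche_weight = 0.5, neutral_range = 50,
                             neutral_sd = 1.5,
                             mortality_base = 0.14,
                             recruitment_base = 0.057,
                             turnover_concentration = 1) {
  if (missing(seed)) stop("seed is mandatory")
  if (x_extent %% dem_resolution != 0 || y_extent %% dem_resolution != 0)
    stop("extents must be divisible by dem_resolution")
  if (niche_weight < 0 || niche_weight > 1)
    stop("niche_weight must lie in [0, 1]")
  if (n_species < 2) stop("n_species must be >= 2 (set 1 only via fields)")
  structure(list(seed = as.integer(seed), x_extent = x_extent,
                 y_extent = y_extent, dem_resolution = dem_resolution,
                 n_peaks = n_peaks, relief = relief,
                 base_elevation = base_elevation, n_species = n_species,
                 n_stems_target = n_stems_target, niche_weight = niche_weight,
                 neutral_range = neutral_range, neutral_sd = neutral_sd,
                 mortality_base = mortality_base,
                 recruitment_base = recruitment_base,
                 turnover_concentration = turnover_concentration),
            class = "synthetic_config")
}

#' Generate the elevation grid
#'
#' The surface is a sum of `n_peaks` positive Gaussian bumps, one negative
#' bump (the central depression) and a low-frequency smoothed-noise field,
#' linearly rescaled so the realised range is exactly
#' `[base_elevation, base_elevation + relief]`.  `relief = 0` gives a flat
#' grid.
#'
#' @param config a [synthetic_config()].
#' @return object of class `elevation_grid`: node matrix `elev`
#'   (x index in rows), node coordinates `x`, `y`, `resolution` and extents.
#' @export
generate_dem <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  res <- config$dem_resolution
  x <- seq(0, config$x_extent, by = res)
  y <- seq(0, config$y_extent, by = res)
  z <- with_seed(child_seed(config$seed, 1L), {
    z <- matrix(0, length(x), length(y))
    xm <- outer(x, rep(1, length(y)))
    ym <- outer(rep(1, length(x)), y)
    span <- min(config$x_extent, config$y_extent)
    if (config$n_peaks > 0) {
      px <- stats::runif(config$n_peaks, 0.1, 0.9) * config$x_extent
      py <- stats::runif(config$n_peaks, 0.1, 0.9) * config$y_extent
      pw <- stats::runif(config$n_peaks, 0.12, 0.25) * span
      ph <- stats::runif(config$n_peaks, 0.5, 1)
      for (k in seq_len(config$n_peaks))
        z <- z + ph[k] * exp(-((xm - px[k])^2 + (ym - py[k])^2) / (2 * pw[k]^2))
      # one funnel-like depression between the peaks
      dx <- stats::runif(1, 0.3, 0.7) * config$x_extent
      dy <- stats::runif(1, 0.3, 0.7) * config$y_extent
      z <- z - 0.8 * exp(-((xm - dx)^2 + (ym - dy)^2) / (2 * (0.3 * span)^2))
    }
    noise <- smooth_field(matrix(stats::rnorm(length(x) * length(y)),
                                 length(x), length(y)), sigma = 5)
    z + 0.15 * noise / max(stats::sd(noise), 1e-12)
  })
  rng <- range(z)
  if (config$relief <= 0 || rng[2] - rng[1] < 1e-12) {
    z[] <- config$base_elevation
  } else {
    z <- config$base_elevation +
      config$relief * (z - rng[1]) / (rng[2] - rng[1])
  }
  structure(list(elev = z, x = x, y = y, resolution = res,
                 x_extent = config$x_extent, y_extent = config$y_extent),
            class = "elevation_grid")
}

# niche + neutral per-cell log-intensities for every species; returns the
# sites x species intensity matrix normalised so each species' expected total
# equals its target abundance.
.species_intensity <- function(dem, config, pars) {
  geometry <- plot_geometry(config$x_extent, config$y_extent,
                            config$dem_resolution)
  res <- config$dem_resolution
  nx <- config$x_extent / res; ny <- config$y_extent / res
  ele <- .cell_ele(dem, res, nx, ny)
  slo <- .cell_slope(.cell_corners(dem, res, nx, ny), res)
  w <- config$niche_weight
  n_cell <- nx * ny
  lam <- matrix(0, n_cell, config$n_species)
  ele_v <- as.vector(ele); slo_v <- as.vector(slo)
  for (s in seq_len(config$n_species)) {
    eta <- numeric(n_cell)
    if (w > 0) {
      niche <- -0.5 * ((ele_v - pars$opt_e[s]) / pars$tol_e[s])^2 -
        0.5 * ((slo_v - pars$opt_s[s]) / pars$tol_s[s])^2
      eta <- eta + w * niche
    }
    if (w < 1 && config$neutral_range > 0) {
      gf <- smooth_field(matrix(stats::rnorm(n_cell), nx, ny),
                         sigma = config$neutral_range / res)
      gf <- (gf - mean(gf)) / max(stats::sd(gf), 1e-12)
      eta <- eta + (1 - w) * config$neutral_sd * as.vector(gf)
    }
    u <- exp(eta - max(eta))
    lam[, s] <- pars$n_target[s] * u / sum(u)
  }
  list(lambda = lam, nx = nx, ny = ny)
}

.species_pars <- function(dem, config) {
  res <- config$dem_resolution
  nx <- config$x_extent / res; ny <- config$y_extent / res
  ele <- .cell_ele(dem, res, nx, ny)
  slo <- .cell_slope(.cell_corners(dem, res, nx, ny), res)
  ns <- config$n_species
  re <- range(ele); rs <- range(slo)
  # lognormal species-abundance distribution
  ab <- exp(stats::rnorm(ns, 0, 1.5))
  list(opt_e = stats::runif(ns, re[1], re[2]),
       tol_e = stats::runif(ns, 0.1, 0.3) * max(re[2] - re[1], 1),
       opt_s = stats::runif(ns, rs[1], rs[2]),
       tol_s = stats::runif(ns, 0.2, 0.5) * max(rs[2] - rs[1], 1),
       n_target = config$n_stems_target * ab / sum(ab))
}

#' Generate the first census
#'
#' Expected abundance of species s in each base-resolution cell is
#' `exp(b0 + w * niche(ELE, SLO) + (1 - w) * GRF(x, y))`, normalised per
#' species to a lognormal species-abundance target; realised counts are
#' Poisson and stems are placed uniformly inside their cell.  The total stem
#' count is Poisson around `n_stems_target` (well within 10%).
#'
#' @param dem an `elevation_grid`.
#' @param config the [synthetic_config()] used for the dem.
#' @return a CensusTable: data.frame with columns `tag`, `species`, `gx`,
#'   `gy`, `dbh`, `census` (= 1), canonically sorted by tag.
#' @export
generate_community <- function(dem, config) {
  stopifnot(inherits(dem, "elevation_grid"),
            inherits(config, "synthetic_config"))
  with_seed(child_seed(config$seed, 2L), {
    pars <- .species_pars(dem, config)
    ints <- .species_intensity(dem, config, pars)
    counts <- matrix(stats::rpois(length(ints$lambda), ints$lambda),
                     nrow(ints$lambda), ncol(ints$lambda))
    total <- sum(counts)
    cell_of <- rep(seq_len(nrow(counts)), times = rowSums(counts))
    # species codes per stem, cell-major
    sp_idx <- unlist(lapply(seq_len(nrow(counts)), function(cl) {
      rep(seq_len(ncol(counts)), times = counts[cl, ])
    }), use.names = FALSE)
    res <- config$dem_resolution
    nx <- ints$nx
    cix <- (cell_of - 1L) %% nx          # cells stored x-fastest
    ciy <- (cell_of - 1L) %/% nx
    gx <- (cix + stats::runif(total)) * res
    gy <- (ciy + stats::runif(total)) * res
    dbh <- 1 + stats::rlnorm(total, meanlog = 0.8, sdlog = 0.9)
    out <- data.frame(tag = sprintf("S%06d", seq_len(total)),
                      species = sprintf("sp%03d", sp_idx),
                      gx = gx, gy = gy, dbh = dbh, census = 1L,
                      stringsAsFactors = FALSE)
    out[order(out$tag), , drop = FALSE]
  })
}

# elevation-dependent turnover weight per base cell, normalised to mean 1
# over the supplied stem cells
.turnover_weight <- function(ele_scaled, concentration) {
  1 + concentration * (1 - ele_scaled)
}

#' Advance the census by one inter-census interval
#'
#' Each stem survives with probability `1 - p(cell)` where `p` is
#' `mortality_base` modulated by scaled elevation (turnover concentrates in
#' the depressions when `turnover_concentration > 0`, the pattern seen in
#' seasonally flooded karst depressions); recruits are drawn per cell with a
#' Poisson intensity proportional to the cell's standing abundance and the
#' same depression weighting, their species sampled from the cell's current
#' composition.  Survivors keep tag and coordinates; recruits get fresh tags.
#' Plot-wide expected death and recruitment fractions equal the base rates.
#'
#' @param census1 the first CensusTable.
#' @param dem the `elevation_grid` the census was generated on.
#' @param config the [synthetic_config()].
#' @return a CensusTable with `census = 2`.
#' @export
advance_census <- function(census1, dem, config) {
  stopifnot(inherits(dem, "elevation_grid"),
            inherits(config, "synthetic_config"))
  with_seed(child_seed(config$seed, 3L), {
    res <- config$dem_resolution
    nx <- config$x_extent / res; ny <- config$y_extent / res
    ele <- .cell_ele(dem, res, nx, ny)
    er <- range(ele)
    esc <- if (er[2] > er[1]) (ele - er[1]) / (er[2] - er[1]) else ele * 0
    cix <- pmin(floor(census1$gx / res), nx - 1L)
    ciy <- pmin(floor(census1$gy / res), ny - 1L)
    cell_of <- cix + nx * ciy + 1L
    wcell <- .turnover_weight(as.vector(esc), config$turnover_concentration)
    wstem <- wcell[cell_of]
    wstem <- wstem / mean(wstem)
    p_death <- if (config$mortality_base >= 1) rep(1, nrow(census1)) else
      pmin(1, config$mortality_base * wstem)
    survives <- stats::runif(nrow(census1)) >= p_death
    surv <- census1[survives, , drop = FALSE]

    n_rec_exp <- config$recruitment_base * wstem
    n_rec <- stats::rpois(nrow(census1), n_rec_exp)
    rec_cells <- rep(cell_of, times = n_rec)
    total_rec <- length(rec_cells)
    if (total_rec > 0) {
      # species of each recruit: sampled from the parent cell's composition
      # (here: the stem whose recruitment event produced it)
      rec_species <- rep(census1$species, times = n_rec)
      rcx <- (rec_cells - 1L) %% nx
      rcy <- (rec_cells - 1L) %/% nx
      rec <- data.frame(tag = sprintf("R%06d", seq_len(total_rec)),
                        species = rec_species,
                        gx = (rcx + stats::runif(total_rec)) * res,
                        gy = (rcy + stats::runif(total_rec)) * res,
                        dbh = 1 + stats::rlnorm(total_rec, -0.5, 0.5),
                        census = 2L, stringsAsFactors = FALSE)
    } else {
      rec <- census1[0, , drop = FALSE]
    }
    surv$census <- rep(2L, nrow(surv))
    out <- rbind(surv, rec)
    out[order(out$tag), , drop = FALSE]
  })
}

#' Synthetic rock-bareness field
#'
#' Rock bareness (fraction of quadrat surface that is exposed rock) is a
#' field survey in real plots; this synthetic stand-in makes it a logistic
#' function of scaled elevation (bare rock concentrates on the peaks) plus a
#' smooth seeded noise field, clipped to `[0, 1]`, on the base-resolution
#' cell grid.
#'
#' @inheritParams generate_community
#' @return matrix (x cells in rows) of values in `[0, 1]`.
#' @export
generate_rbr <- function(dem, config) {
  with_seed(child_seed(config$seed, 4L), {
    res <- config$dem_resolution
    nx <- config$x_extent / res; ny <- config$y_extent / res
    ele <- .cell_ele(dem, res, nx, ny)
    er <- range(ele)
    esc <- if (er[2] > er[1]) (ele - er[1]) / (er[2] - er[1]) else ele * 0
    noise <- smooth_field(matrix(stats::rnorm(nx * ny), nx, ny), sigma = 3)
    noise <- noise / max(stats::sd(noise), 1e-12)
    out <- stats::plogis(3 * (esc - 0.5) + 0.5 * noise)
    out[] <- pmin(1, pmax(0, out))
    out
  })
}

#' Write / read an elevation grid as plain CSV (x, y, elev)
#' @param dem an `elevation_grid`.
#' @param path CSV path.
#' @export
write_dem <- function(dem, path) {
  df <- data.frame(x = rep(dem$x, times = length(dem$y)),
                   y = rep(dem$y, each = length(dem$x)),
                   elev = as.vector(dem$elev))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_dem
#' @param resolution node spacing of the stored grid.
#' @export
read_dem <- function(path, resolution = NULL) {
  df <- utils::read.csv(path)
  if (!all(c("x", "y", "elev") %in% names(df)))
    stop("dem CSV must have columns x, y, elev")
  xs <- sort(unique(df$x)); ys <- sort(unique(df$y))
  res <- if (is.null(resolution)) diff(xs)[1] else resolution
  z <- matrix(NA_real_, length(xs), length(ys))
  z[cbind(match(df$x, xs), match(df$y, ys))] <- df$elev
  if (anyNA(z)) stop("dem CSV does not form a complete lattice")
  structure(list(elev = z, x = xs, y = ys, resolution = res,
                 x_extent = max(xs), y_extent = max(ys)),
            class = "elevation_grid")
}
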