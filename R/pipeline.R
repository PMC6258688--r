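# End-to-end analysis: censuses -> grains -> beta partitioning -> Mantel
# battery -> dbMEM -> variation partitioning -> grain trend, with seed
# management and optional CSV/JSON output.

#' Pipeline configuration
#'
#' @param synthetic a [synthetic_config()], or `NULL` when censuses are
#'   supplied directly.
#' @param census1,census2 CensusTables (ignored when `synthetic` is given;
#'   `census2` optional).
#' @param dem an `elevation_grid` (required with user censuses).
#' @param rbr optional rock-bareness matrix on the base cell grid.
#' @param geometry a [plot_geometry()]; derived from `synthetic` if `NULL`.
#' @param grains grain sizes in metres (default 10, 20, 25, 30, 40, 50, 60).
#' @param n_perm_mantel,n_perm_fs permutation counts for the Mantel battery
#'   and the forward selection (the field default is 9,999; scale down for
#'   quick runs).
#' @param alpha forward-selection entry threshold.
#' @param alternative Mantel alternative, `"greater"` or `"two.sided"`.
#' @param seed master seed; per-stage child seeds are derived from it by the
#'   counter scheme in `child_seed()` and recorded in the report.
#' @param outdir directory for CSV/JSON outputs, or `NULL` to skip writing.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(synthetic = NULL, census1 = NULL, census2 = NULL,
                            dem = NULL, rbr = NULL, geometry = NULL,
                            grains = c(10, 20, 25, 30, 40, 50, 60),
                            n_perm_mantel = 9999, n_perm_fs = 9999,
                            alpha = 0.05,
                            alternative = c("greater", "two.sided"),
                            seed = 1L, outdir = NULL) {
  alternative <- match.arg(alternative)
  if (is.null(synthetic) && is.null(census1))
    stop("either a synthetic config or census1 must be supplied")
  if (!is.null(synthetic) && !inherits(synthetic, "synthetic_config"))
    stop("synthetic must be a synthetic_config")
  if (is.null(geometry)) {
    if (!is.null(synthetic)) {
      geometry <- plot_geometry(synthetic$x_extent, synthetic$y_extent,
                                synthetic$dem_resolution)
    } else if (!is.null(dem)) {
      geometry <- plot_geometry(dem$x_extent, dem$y_extent, dem$resolution)
    } else stop("geometry required with user censuses")
  }
  if (n_perm_mantel < 99 || n_perm_fs < 99) stop("n_perm must be >= 99")
  for (g in grains) {
    if (g > min(geometry$x_extent, geometry$y_extent))
      stop("grain ", g, " is invalid for the plot geometry")
    if (g < geometry$base_resolution)
      stop("grain ", g, " is finer than the base resolution")
  }
  structure(list(synthetic = synthetic, census1 = census1, census2 = census2,
                 dem = dem, rbr = rbr, geometry = geometry, grains = grains,
                 n_perm_mantel = n_perm_mantel, n_perm_fs = n_perm_fs,
                 alpha = alpha, alternative = alternative,
                 seed = as.integer(seed), outdir = outdir),
            class = "pipeline_config")
}

.stage_log <- function(stage, ...) {
  message(sprintf("[%s] %s", stage, paste0(...)))
}

#' Run the full analysis pipeline
#'
#' Stages, per census and grain: quadrat aggregation, Bray-Curtis
#' decomposition and simplex summary; Mantel battery of each topographic
#' driver plus the all-variable environmental distance against each
#' component; dbMEM construction, forward selection of environmental and
#' spatial predictors and variation partitioning per component; and the
#' grain-trend Spearman test per component.  Deterministic under the master
#' seed.  When `config$outdir` is set, every stage output is written as CSV
#' with a JSON sidecar.
#'
#' @param config a [pipeline_config()].
#' @return nested report list with elements `dem`, `censuses`, `dynamics`,
#'   `grains` (per grain: `simplex`, `mantel`, `varpart` per component and
#'   census), `trend`, `seeds`, `params`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  geometry <- config$geometry
  seeds <- list()
  sc <- 0L
  next_seed <- function(label) {
    sc <<- sc + 1L
    s <- child_seed(config$seed, 100L + sc)
    seeds[[label]] <<- s
    s
  }
  outdir <- config$outdir
  if (!is.null(outdir) && !dir.exists(outdir))
    dir.create(outdir, recursive = TRUE)

  # --- stage: data ----------------------------------------------------------
  if (!is.null(config$synthetic)) {
    .stage_log("simulate", "generating synthetic plot, seed ",
               config$synthetic$seed)
    dem <- generate_dem(config$synthetic)
    c1 <- generate_community(dem, config$synthetic)
    c2 <- advance_census(c1, dem, config$synthetic)
    rbr <- generate_rbr(dem, config$synthetic)
  } else {
    dem <- config$dem
    c1 <- validate_census(config$census1, geometry)
    c2 <- if (!is.null(config$census2))
      validate_census(config$census2, geometry) else NULL
    rbr <- config$rbr
  }
  censuses <- Filter(Negate(is.null), list(c1, c2))
  if (!is.null(outdir)) {
    write_dem(dem, file.path(outdir, "dem.csv"))
    for (k in seq_along(censuses))
      write_census(censuses[[k]], file.path(outdir,
                                            sprintf("census%d.csv", k)))
  }

  dynamics <- NULL
  if (length(censuses) == 2) {
    dynamics <- census_dynamics(censuses[[1]], censuses[[2]], geometry,
                                grain = min(config$grains))
    .stage_log("dynamics", dynamics$dead_total, " dead, ",
               dynamics$new_total, " new stems")
  }

  species_all <- sort(unique(unlist(lapply(censuses, `[[`, "species"))))
  grains_out <- list()
  trend_tabs <- list()

  for (g in config$grains) {
    gkey <- paste0("grain", g)
    env <- topo_variables(dem, geometry, g, rbr = rbr)
    env_all_d <- env_distance(env)
    expanded <- polynomial_expand(env)
    mem <- select_mem(build_dbmem(cell_centroids(geometry, g)))
    per_census <- list()
    for (ci in seq_along(censuses)) {
      .stage_log("partition", "grain ", g, ", census ", ci)
      ab <- aggregate_census(censuses[[ci]], geometry, g,
                             species_levels = species_all)
      bc <- beta_decompose(ab)
      sx <- simplex_summary(bc)
      mb <- mantel_battery(bc, env, n_perm = config$n_perm_mantel,
                           alternative = config$alternative,
                           seed = next_seed(sprintf("mantel_g%d_c%d", g, ci)))
      .stage_log("varpart", "grain ", g, ", census ", ci)
      vps <- list()
      for (comp in c("bc", "bal", "gra")) {
        Y <- pcoa_response(sqrt_transform(bc[[comp]]))
        cap <- max(1L, floor((bc$n_sites - 2) / 2))
        fsE <- forward_select(Y, expanded, n_perm = config$n_perm_fs,
                              alpha = config$alpha, max_vars = cap,
                              seed = next_seed(sprintf("fsE_%s_g%d_c%d",
                                                       comp, g, ci)))
        fsS <- forward_select(Y, mem$vectors, n_perm = config$n_perm_fs,
                              alpha = config$alpha, max_vars = cap,
                              seed = next_seed(sprintf("fsS_%s_g%d_c%d",
                                                       comp, g, ci)))
        E <- expanded[, fsE$selected, drop = FALSE]
        S <- mem$vectors[, fsS$selected, drop = FALSE]
        vps[[comp]] <- list(fractions = varpart_fractions(Y, E, S),
                            selected_env = fsE$selected,
                            selected_mem = fsS$selected)
      }
      per_census[[ci]] <- list(simplex = sx, mantel = mb, varpart = vps,
                               n_sites = bc$n_sites,
                               n_discarded = ab$n_discarded)
      trend_tabs[[length(trend_tabs) + 1L]] <- data.frame(
        census = ci, grain = g,
        mean_bc = 1 - sx$means[["sim"]],
        mean_bal = sx$means[["bal"]], mean_gra = sx$means[["gra"]])
      if (!is.null(outdir)) {
        write_beta(bc, file.path(outdir, sprintf("beta_g%d_c%d.csv", g, ci)))
        write_with_sidecar(mb,
          file.path(outdir, sprintf("mantel_g%d_c%d.csv", g, ci)),
          meta = list(grain = g, census = ci,
                      n_perm = config$n_perm_mantel,
                      alternative = config$alternative))
        vp_df <- do.call(rbind, lapply(names(vps), function(comp) {
          f <- vps[[comp]]$fractions
          data.frame(component = comp, a = f$a, b = f$b, c = f$c, d = f$d,
                     ab = f$a + f$b, m_E = f$m_E, m_S = f$m_S)
        }))
        write_with_sidecar(vp_df,
          file.path(outdir, sprintf("varpart_g%d_c%d.csv", g, ci)),
          meta = list(grain = g, census = ci,
                      selected = lapply(vps, function(v)
                        list(env = v$selected_env, mem = v$selected_mem))))
      }
    }
    grains_out[[gkey]] <- list(grain = g, env = env, mem_count =
                                 ncol(mem$vectors), censuses = per_census)
    if (!is.null(outdir))
      write_with_sidecar(env, file.path(outdir, sprintf("env_g%d.csv", g)),
                         meta = list(grain = g))
  }

  trend_tab <- do.call(rbind, trend_tabs)
  trend <- list()
  if (length(config$grains) >= 3) {
    for (ci in seq_along(censuses)) {
      tt <- trend_tab[trend_tab$census == ci, , drop = FALSE]
      trend[[paste0("census", ci)]] <- lapply(
        c(bc = "mean_bc", bal = "mean_bal", gra = "mean_gra"),
        function(col) grain_trend(tt$grain, tt[[col]]))
    }
  }
  report <- list(dem = dem, censuses = censuses, dynamics = dynamics,
                 grains = grains_out, trend = trend, trend_table = trend_tab,
                 seeds = seeds,
                 params = list(grains = config$grains,
                               n_perm_mantel = config$n_perm_mantel,
                               n_perm_fs = config$n_perm_fs,
                               alpha = config$alpha,
                               alternative = config$alternative,
                               seed = config$seed))
  if (!is.null(outdir)) {
    write_with_sidecar(trend_tab, file.path(outdir, "trend_means.csv"),
                       meta = list(seeds = seeds, params = report$params))
  }
  report
}
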