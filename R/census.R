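# Census table validation, quadrat aggregation at a sampling grain, and
# between-census dynamics summaries.

#' Validate a census table
#'
#' Checks the CensusTable invariants: required columns, coordinates inside
#' the half-open plot `[0, x_extent) x [0, y_extent)`, unique tags, and
#' the 1 cm minimum-dbh inclusion rule (undersized stems are dropped with a warning;
#' the count is recorded in the `n_excluded_dbh` attribute).
#'
#' @param census data.frame with columns `tag`, `species`, `gx`, `gy`,
#'   `dbh`, `census`.
#' @param geometry a [plot_geometry()].
#' @return the validated (possibly filtered) census table.
#' @export
validate_census <- function(census, geometry) {
  stopifnot(inherits(geometry, "plot_geometry"))
  need <- c("tag", "species", "gx", "gy", "dbh", "census")
  miss <- setdiff(need, names(census))
  if (length(miss))
    stop("census table lacks column(s): ", paste(miss, collapse = ", "))
  bad <- census$gx < 0 | census$gx >= geometry$x_extent |
    census$gy < 0 | census$gy >= geometry$y_extent
  if (any(bad))
    stop("out-of-bounds coordinates (half-open plot convention) for tag(s): ",
         paste(utils::head(census$tag[bad], 10), collapse = ", "))
  dup <- duplicated(census$tag)
  if (any(dup))
    stop("duplicated tag(s) within census: ",
         paste(utils::head(unique(census$tag[dup]), 10), collapse = ", "))
  small <- census$dbh < 1
  n_small <- sum(small)
  if (n_small > 0) {
    warning(n_small, " stem(s) below the 1 cm dbh inclusion rule excluded")
    census <- census[!small, , drop = FALSE]
  }
  attr(census, "n_excluded_dbh") <- n_small
  census
}

#' Read a census CSV
#'
#' Expects the standard forest-dynamics-plot stem columns
#' `tag,species,gx,gy,dbh,census` and validates them via [validate_census()].
#'
#' @param path CSV file.
#' @inheritParams validate_census
#' @return validated CensusTable.
#' @export
read_census <- function(path, geometry) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_census(df, geometry)
}

#' @rdname read_census
#' @param census a CensusTable.
#' @export
write_census <- function(census, path) {
  utils::write.csv(census, path, row.names = FALSE)
  invisible(path)
}

#' Aggregate stems into a quadrat x species abundance matrix
#'
#' Stems are assigned to half-open cells `[k g, (k+1) g)`; stems falling
#' outside the origin-anchored sub-extent for the grain (see
#' [sub_extent_for_grain()]) are discarded and counted.  Site order is the
#' package standard (ix, then iy), matching [cell_centroids()].
#'
#' @param census a validated CensusTable.
#' @param geometry a [plot_geometry()].
#' @param grain quadrat side length in metres.
#' @param species_levels optional character vector fixing the species
#'   columns (use the union over censuses for between-census comparisons).
#' @return object of class `abundance_matrix`: list with `counts`
#'   (sites x species integer matrix), `sites` (the [cell_centroids()]
#'   frame), `grain`, `sub_x`, `sub_y`, `n_discarded`.
#' @export
aggregate_census <- function(census, geometry, grain, species_levels = NULL) {
  stopifnot(inherits(geometry, "plot_geometry"))
  cen <- cell_centroids(geometry, grain)
  se <- sub_extent_for_grain(geometry, grain)
  if (nrow(census) == 0) warning("empty census: abundance matrix is all zero")
  if (is.null(species_levels)) species_levels <- sort(unique(census$species))
  keep <- census$gx < se[["sub_x"]] & census$gy < se[["sub_y"]]
  n_disc <- sum(!keep)
  kept <- census[keep, , drop = FALSE]
  ix <- floor(kept$gx / grain)
  iy <- floor(kept$gy / grain)
  sid <- factor(site_id(ix, iy), levels = cen$site)
  sp <- factor(kept$species, levels = species_levels)
  if (anyNA(sp)) stop("species found outside species_levels")
  counts <- table(sid, sp)
  counts <- matrix(as.integer(counts), nrow(cen), length(species_levels),
                   dimnames = list(cen$site, species_levels))
  structure(list(counts = counts, sites = cen, grain = grain,
                 sub_x = se[["sub_x"]], sub_y = se[["sub_y"]],
                 n_discarded = n_disc),
            class = "abundance_matrix")
}

#' Between-census dynamics summary
#'
#' Dead stems are tags present in the first census and absent from the
#' second; new stems the converse.  Species lost/gained are defined by
#' presence of at least one stem.  Per-cell counts at the requested grain use
#' ragged edge cells covering the full plot (no margin discard), so the
#' per-species and per-cell totals agree at every grain.
#'
#' @param c1,c2 validated CensusTables sharing a tag namespace.
#' @inheritParams aggregate_census
#' @return list of class `dynamics_summary`: `dead_total`, `new_total`,
#'   `species_dead` / `species_new` (named per-species counts),
#'   `species_lost`, `species_gained`, and `cells` (data.frame of per-cell
#'   dead/new counts).
#' @export
census_dynamics <- function(c1, c2, geometry, grain) {
  if (anyDuplicated(c1$tag) || anyDuplicated(c2$tag))
    stop("duplicated tags within a census")
  dead <- c1[!(c1$tag %in% c2$tag), , drop = FALSE]
  newr <- c2[!(c2$tag %in% c1$tag), , drop = FALSE]
  sp1 <- unique(c1$species); sp2 <- unique(c2$species)
  cell_counts <- function(df) {
    ix <- floor(df$gx / grain); iy <- floor(df$gy / grain)
    tapply(rep(1L, nrow(df)), site_id(ix, iy), sum)
  }
  nxr <- ceiling(geometry$x_extent / grain)
  nyr <- ceiling(geometry$y_extent / grain)
  gridc <- expand.grid(iy = seq_len(nyr) - 1L, ix = seq_len(nxr) - 1L)
  gridc <- gridc[order(gridc$ix, gridc$iy), c("ix", "iy")]
  cells <- data.frame(site = site_id(gridc$ix, gridc$iy),
                      ix = gridc$ix, iy = gridc$iy,
                      dead = 0L, new = 0L, row.names = NULL)
  dc <- cell_counts(dead); nc <- cell_counts(newr)
  cells$dead[match(names(dc), cells$site)] <- as.integer(dc)
  cells$new[match(names(nc), cells$site)] <- as.integer(nc)
  structure(list(
    dead_total = nrow(dead), new_total = nrow(newr),
    species_dead = if (nrow(dead)) table(dead$species) else table(character()),
    species_new = if (nrow(newr)) table(newr$species) else table(character()),
    n_species_dead = length(unique(dead$species)),
    n_species_new = length(unique(newr$species)),
    species_lost = sort(setdiff(sp1, sp2)),
    species_gained = sort(setdiff(sp2, sp1)),
    cells = cells, grain = grain), class = "dynamics_summary")
}

#' Export an abundance matrix
#'
#' Long form (`site,species,count`, zeros omitted) or wide form CSV, with a
#' JSON sidecar carrying the grain and sub-extent metadata.
#'
#' @param abund an `abundance_matrix`.
#' @param path CSV path.
#' @param form `"long"` or `"wide"`.
#' @export
write_abundance <- function(abund, path, form = c("long", "wide")) {
  form <- match.arg(form)
  meta <- list(grain = abund$grain, sub_x = abund$sub_x, sub_y = abund$sub_y,
               n_discarded = abund$n_discarded, form = form)
  if (form == "wide") {
    df <- data.frame(site = rownames(abund$counts), abund$counts,
                     check.names = FALSE)
  } else {
    idx <- which(abund$counts > 0, arr.ind = TRUE)
    df <- data.frame(site = rownames(abund$counts)[idx[, 1]],
                     species = colnames(abund$counts)[idx[, 2]],
                     count = abund$counts[idx])
    df <- df[order(df$site, df$species), , drop = FALSE]
  }
  write_with_sidecar(df, path, meta)
}
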