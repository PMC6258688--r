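# Abundance-based Bray-Curtis decomposition into balanced-variation and
# abundance-gradient components (Baselga's framework).
#
# For a site pair (m, n) with per-species counts x_ms, x_ns:
#   A = sum_s min(x_ms, x_ns)   shared individuals
#   B = sum_s (x_ms - min)      individuals unique to m
#   C = sum_s (x_ns - min)      individuals unique to n
#   beta_bc  = (B + C) / (2A + B + C)          Bray-Curtis dissimilarity
#   beta_bal = min(B, C) / (A + min(B, C))     balanced variation
#   beta_gra = |B - C|/(2A + B + C) * A/(A + min(B, C))   abundance gradient
# and beta_bc = beta_bal + beta_gra holds exactly in rational arithmetic.
# A, B, C are kept as exact integers (doubles are exact for counts < 2^53);
# division happens once, at the end, so the additivity is exact to 1e-12.

#' Shared and unique individuals of a site pair
#'
#' @param x_m,x_n equal-length non-negative integer count vectors over the
#'   same species order.
#' @return named numeric vector `c(A, B, C)`.
#' @export
pair_abc <- function(x_m, x_n) {
  if (length(x_m) != length(x_n)) stop("count vectors differ in length")
  if (any(x_m < 0) || any(x_n < 0)) stop("negative counts")
  A <- sum(pmin(x_m, x_n))
  c(A = A, B = sum(x_m) - A, C = sum(x_n) - A)
}

#' Decompose pairwise Bray-Curtis dissimilarity
#'
#' Computes, for every pair of sites, the total Bray-Curtis dissimilarity and
#' its balanced-variation and abundance-gradient components.  Internally uses
#' the identity `sum_s |x_ms - x_ns| = B + C` (a Manhattan distance) and
#' `A = (T_m + T_n - (B + C)) / 2`, so the whole decomposition runs off two
#' condensed matrices.  Pairs involving a site with zero total abundance are
#' undefined (0/0) and returned as `NA` with a warning; summaries exclude
#' them.
#'
#' @param abund an `abundance_matrix` from [aggregate_census()], or a plain
#'   sites x species count matrix.
#' @return object of class `beta_components`: list of three `dist` objects
#'   `bc`, `bal`, `gra` over the same sites, plus `n_sites`, `n_pairs`,
#'   `n_undefined` and (when available) `grain`.
#' @export
beta_decompose <- function(abund) {
  grain <- NULL
  if (inherits(abund, "abundance_matrix")) {
    grain <- abund$grain
    X <- abund$counts
  } else {
    X <- as.matrix(abund)
  }
  if (nrow(X) < 2) stop("need at least two sites")
  if (any(X < 0)) stop("negative counts")
  Tm <- rowSums(X)
  M <- stats::dist(X, method = "manhattan")  # = B + C per pair
  idx <- pair_indices(nrow(X))
  Tsum <- Tm[idx$i] + Tm[idx$j]              # = 2A + B + C
  A <- (Tsum - M) / 2
  B <- Tm[idx$j] - A                         # dist order: (i, j), i > j; site j first
  C <- Tm[idx$i] - A
  mn <- pmin(B, C)
  undef <- Tm[idx$i] == 0 | Tm[idx$j] == 0
  bc <- bal <- gra <- rep(NA_real_, length(M))
  ok <- !undef
  bc[ok] <- M[ok] / Tsum[ok]
  bal[ok] <- ifelse(A[ok] + mn[ok] == 0, 0, mn[ok] / (A[ok] + mn[ok]))
  gra[ok] <- (abs(B[ok] - C[ok]) / Tsum[ok]) *
    ifelse(A[ok] + mn[ok] == 0, 1, A[ok] / (A[ok] + mn[ok]))
  if (any(undef))
    warning(sum(undef), " site pair(s) undefined (a site has zero total ",
            "abundance); returned as NA")
  as_d <- function(v) {
    d <- M
    d[] <- v
    attr(d, "method") <- NULL
    d
  }
  structure(list(bc = as_d(bc), bal = as_d(bal), gra = as_d(gra),
                 n_sites = nrow(X), n_pairs = length(M),
                 n_undefined = sum(undef), grain = grain),
            class = "beta_components")
}

#' Simplex summary of the decomposition
#'
#' Each defined site pair yields the triplet (Similarity = 1 - beta_bc,
#' balanced, gradient), which sums to 1; this summarises the cloud of pairs
#' on that 2-simplex: per-component means and SDs (n - 1 denominator) and the
#' centroid triplet.
#'
#' @param bc a `beta_components` object.
#' @return list of class `simplex_summary` with `n_pairs`, `means`, `sds`,
#'   `centroid` (each a named length-3 vector over sim/bal/gra).
#' @export
simplex_summary <- function(bc) {
  stopifnot(inherits(bc, "beta_components"))
  ok <- !is.na(bc$bc)
  if (!any(ok)) stop("all site pairs undefined")
  tri <- cbind(sim = 1 - as.vector(bc$bc)[ok],
               bal = as.vector(bc$bal)[ok],
               gra = as.vector(bc$gra)[ok])
  means <- colMeans(tri)
  sds <- apply(tri, 2, stats::sd)
  structure(list(n_pairs = sum(ok), means = means, sds = sds,
                 centroid = means, grain = bc$grain),
            class = "simplex_summary")
}

#' Per-grain component means across a grain series
#'
#' Convenience used by the grain-trend analysis: mean of each component over
#' defined pairs, for each grain.
#'
#' @param census a validated CensusTable.
#' @param geometry a [plot_geometry()].
#' @param grains vector of grain sizes in metres.
#' @return data.frame with columns `grain`, `n_sites`, `n_pairs`,
#'   `mean_bc`, `mean_bal`, `mean_gra`, `sd_bc`, `sd_bal`, `sd_gra`.
#' @export
grain_component_means <- function(census, geometry, grains) {
  rows <- lapply(grains, function(g) {
    bc <- beta_decompose(aggregate_census(census, geometry, g))
    s <- simplex_summary(bc)
    data.frame(grain = g, n_sites = bc$n_sites, n_pairs = s$n_pairs,
               mean_bc = 1 - s$means[["sim"]], mean_bal = s$means[["bal"]],
               mean_gra = s$means[["gra"]], sd_bc = s$sds[["sim"]],
               sd_bal = s$sds[["bal"]], sd_gra = s$sds[["gra"]])
  })
  do.call(rbind, rows)
}

#' Export the condensed component matrices
#'
#' Writes one row per site pair (`site_i`, `site_j`, `bc`, `bal`, `gra`) plus
#' a JSON sidecar with the site-order manifest, so the 1e6-pair matrices at
#' fine grains stream to disk without square duplication.
#'
#' @param bc a `beta_components` object.
#' @param path CSV path.
#' @export
write_beta <- function(bc, path) {
  labs <- attr(bc$bc, "Labels")
  if (is.null(labs)) labs <- as.character(seq_len(bc$n_sites))
  idx <- pair_indices(bc$n_sites)
  df <- data.frame(site_i = labs[idx$i], site_j = labs[idx$j],
                   bc = as.vector(bc$bc), bal = as.vector(bc$bal),
                   gra = as.vector(bc$gra))
  write_with_sidecar(df, path, meta = list(
    sites = labs, grain = bc$grain, n_undefined = bc$n_undefined))
}
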