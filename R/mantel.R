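# Mantel permutation tests (Spearman) between distance matrices, and the
# grain-trend Spearman test with exact small-n p-values.

#' Mantel test with Spearman correlation
#'
#' Correlates the condensed (upper-triangle, diagonal excluded) vectors of
#' two distance matrices by Spearman's method and builds the permutation
#' null by simultaneously permuting rows and columns of the second matrix.
#' Because a site relabelling permutes the off-diagonal entries bijectively,
#' the multiset of values -- and hence their ranks -- is permutation
#' invariant; the ranks are therefore computed once and only re-indexed per
#' permutation, which keeps 9,999 permutations cheap even for hundreds of
#' sites.
#'
#' p-values: `(1 + #{r_perm >= r_obs}) / (n_perm + 1)` for
#' `alternative = "greater"` (the conventional one-sided Mantel test);
#' `"two.sided"` uses `|r|`.  With `exact = TRUE` all `n!` relabellings are
#' enumerated (n <= 8) and `p = #{r_perm >= r_obs} / n!`, the identity
#' included.
#'
#' @param dx,dy `dist` objects over the same sites in the same order.
#' @param n_perm number of random permutations (ignored when `exact`).
#' @param alternative `"greater"` (default) or `"two.sided"`.
#' @param seed RNG seed for the permutation draws.
#' @param exact enumerate all permutations instead of sampling.
#' @return list of class `mantel_result`: `statistic` (Spearman r),
#'   `p.value`, `n_perm`, `alternative`, `n_sites`, `seed`.
#' @export
mantel_spearman <- function(dx, dy, n_perm = 999,
                            alternative = c("greater", "two.sided"),
                            seed = NULL, exact = FALSE) {
  alternative <- match.arg(alternative)
  dx <- stats::as.dist(dx); dy <- stats::as.dist(dy)
  n <- attr(dx, "Size")
  if (n != attr(dy, "Size")) stop("matrices differ in size")
  lx <- attr(dx, "Labels"); ly <- attr(dy, "Labels")
  if (!is.null(lx) && !is.null(ly) && !identical(lx, ly))
    stop("matrices cover different site sets or orders")
  if (n < 3) stop("need at least 3 sites")
  vx <- as.vector(dx); vy <- as.vector(dy)
  if (anyNA(vx) || anyNA(vy)) stop("NA entries in a distance matrix")
  if (stats::sd(vx) == 0 || stats::sd(vy) == 0)
    stop("constant distance matrix: Spearman r undefined")
  rx <- rank(vx)
  ry <- rank(vy)
  L <- length(vx)
  # Pearson on ranks; mean/sd of the rank multiset are permutation-invariant
  mx <- mean(rx); sx <- stats::sd(rx)
  my <- mean(ry); sy <- stats::sd(ry)
  r_of_sum <- function(s) (s - L * mx * my) / ((L - 1) * sx * sy)
  s_obs <- sum(rx * ry)
  r_obs <- r_of_sum(s_obs)
  Rmat <- matrix(0, n, n)
  Rmat[lower.tri(Rmat)] <- ry
  Rmat <- Rmat + t(Rmat)
  lt <- lower.tri(Rmat)
  stat_for <- function(perm) sum(rx * (Rmat[perm, perm])[lt])

  if (exact) {
    if (n > 8) stop("exact enumeration limited to n <= 8")
    perms <- all_permutations(n)
    s_all <- vapply(perms, stat_for, numeric(1))
    r_all <- r_of_sum(s_all)
    p <- if (alternative == "greater") {
      mean(r_all >= r_obs - 1e-12)
    } else {
      mean(abs(r_all) >= abs(r_obs) - 1e-12)
    }
    n_perm <- length(perms)
  } else {
    s_perm <- with_seed(seed, vapply(seq_len(n_perm), function(k) {
      stat_for(sample.int(n))
    }, numeric(1)))
    r_perm <- r_of_sum(s_perm)
    p <- if (alternative == "greater") {
      (1 + sum(r_perm >= r_obs - 1e-12)) / (n_perm + 1)
    } else {
      (1 + sum(abs(r_perm) >= abs(r_obs) - 1e-12)) / (n_perm + 1)
    }
  }
  structure(list(statistic = r_obs, p.value = p, n_perm = n_perm,
                 alternative = alternative, n_sites = n, seed = seed,
                 exact = exact),
            class = "mantel_result")
}

#' @export
print.mantel_result <- function(x, ...) {
  cat("Mantel test (Spearman), ", x$n_sites, " sites, ",
      if (x$exact) "exact enumeration" else paste0(x$n_perm, " permutations"),
      "\n  r = ", format(x$statistic, digits = 4),
      ", p = ", format(x$p.value, digits = 4),
      " (", x$alternative, ")\n", sep = "")
  invisible(x)
}

# all n! permutations of 1..n as a list (n small)
all_permutations <- function(n) {
  if (n == 1) return(list(1L))
  sub <- all_permutations(n - 1L)
  out <- vector("list", n * length(sub))
  k <- 0L
  for (p in sub) for (pos in seq_len(n)) {
    k <- k + 1L
    out[[k]] <- append(p, n, after = pos - 1L)
  }
  out
}

#' Mantel battery over environmental drivers
#'
#' Reproduces the per-driver table structure: one Mantel test per single
#' topographic variable plus one for the all-variable environmental distance
#' (`ALL`), against each dissimilarity component.
#'
#' @param bc a `beta_components` object.
#' @param env an EnvTable from [topo_variables()].
#' @param vars drivers to test singly (default the eight standard ones that
#'   are present in `env`).
#' @param n_perm,alternative,seed passed to [mantel_spearman()].
#' @return data.frame with columns `driver`, `component`, `r`, `p`.
#' @export
mantel_battery <- function(bc, env, vars = NULL, n_perm = 999,
                           alternative = "greater", seed = NULL) {
  stopifnot(inherits(bc, "beta_components"))
  if (is.null(vars))
    vars <- intersect(c("ELE", "SLO", "CON", "TWI", "ACH", "RBR",
                        "SIN", "COS"), names(env))
  comps <- list(bc = bc$bc, bal = bc$bal, gra = bc$gra)
  rows <- list()
  k <- 0L
  for (v in c(vars, "ALL")) {
    dv <- if (v == "ALL") env_distance(env, vars) else env_distance(env, v)
    for (cn in names(comps)) {
      k <- k + 1L
      m <- mantel_spearman(dv, comps[[cn]], n_perm = n_perm,
                           alternative = alternative,
                           seed = if (is.null(seed)) NULL else seed + k)
      rows[[k]] <- data.frame(driver = v, component = cn,
                              r = m$statistic, p = m$p.value)
    }
  }
  do.call(rbind, rows)
}

#' Spearman trend of component means across sampling grains
#'
#' Tests whether a beta-diversity component's mean changes monotonically with
#' the grain size.  Uses the exact permutation null for the Spearman
#' statistic when n <= 9 and there are no ties (the full n! distribution, as
#' implemented in [stats::cor.test()]); with ties, average ranks and the
#' large-sample approximation.  Two-sided.
#'
#' @param grains distinct grain sizes (>= 3).
#' @param means per-grain component means.
#' @return list of class `trend_result`: `rho`, `p.value`, `n`, `exact`.
#' @export
grain_trend <- function(grains, means) {
  if (length(grains) != length(means)) stop("length mismatch")
  if (length(grains) < 3) stop("need at least 3 grains")
  if (anyDuplicated(grains)) stop("tied grain sizes")
  if (stats::sd(means) == 0) stop("constant means: rho undefined")
  exact <- length(grains) <= 9 && !anyDuplicated(means)
  ct <- suppressWarnings(stats::cor.test(grains, means, method = "spearman",
                                         exact = exact,
                                         alternative = "two.sided"))
  structure(list(rho = unname(ct$estimate), p.value = ct$p.value,
                 n = length(grains), exact = exact),
            class = "trend_result")
}
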