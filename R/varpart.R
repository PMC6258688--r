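# Variation partitioning of community dissimilarity via distance-based
# redundancy analysis: response = principal coordinates of the square-rooted
# Bray-Curtis matrix; predictors = forward-selected environmental variables
# (E) and dbMEM spatial eigenfunctions (S); fractions a (pure habitat),
# b (spatially structured habitat), c (pure space), d (undetermined) from
# Ezekiel-adjusted R-squared values.

#' Square-root transform of a dissimilarity matrix
#'
#' Bray-Curtis dissimilarities are not Euclidean-embeddable, but their square
#' roots are, which makes the principal-coordinate response of the db-RDA
#' free of negative eigenvalues.
#'
#' @param D a `dist` with entries in `[0, 1]` (NA-free).
#' @return the element-wise square root, same class and labels.
#' @export
sqrt_transform <- function(D) {
  D <- stats::as.dist(D)
  v <- as.vector(D)
  if (anyNA(v)) stop("NA entries in dissimilarity matrix")
  if (any(v < 0)) stop("negative dissimilarities")
  D[] <- sqrt(v)
  D
}

#' Principal-coordinate response matrix
#'
#' Double-centres `-0.5 * D^2`, eigen-decomposes, keeps axes with eigenvalue
#' above `1e-9 * lambda_max` and scales them to `sqrt(lambda)`, so the
#' inter-site Euclidean distances among the axes reproduce `D` when `D` is
#' Euclidean-embeddable.  The most negative eigenvalue is recorded; after
#' [sqrt_transform()] none should be materially negative.
#'
#' @param D symmetric `dist` with zero diagonal.
#' @return object of class `pcoa_response`: `axes` (site x axis, centred,
#'   scaled to sqrt(eigenvalue)), `values`, `total_inertia`,
#'   `min_eigenvalue`, `n_sites`.
#' @export
pcoa_response <- function(D) {
  D <- stats::as.dist(D)
  if (anyNA(D)) stop("NA entries in dissimilarity matrix")
  Dm <- as.matrix(D)
  n <- nrow(Dm)
  G <- -0.5 * Dm^2
  G <- sweep(G, 1, rowMeans(G))
  G <- sweep(G, 2, colMeans(G))
  eg <- eigen(G, symmetric = TRUE)
  lmax <- max(eg$values)
  if (lmax <= 1e-12)
    stop("degenerate response: all PCoA eigenvalues are zero")
  keep <- which(eg$values > 1e-9 * lmax)
  Y <- eg$vectors[, keep, drop = FALSE] %*% diag(sqrt(eg$values[keep]),
                                                 length(keep))
  rownames(Y) <- attr(D, "Labels")
  structure(list(axes = Y, values = eg$values[keep],
                 total_inertia = sum(eg$values[keep]),
                 min_eigenvalue = min(eg$values), n_sites = n),
            class = "pcoa_response")
}

# R-squared of the multivariate regression of centred Y on X (+ intercept):
# explained sum of squares over total.  Returns the qr rank (number of
# independent predictors) alongside.
.rda_r2 <- function(Y, X) {
  if (is.null(X) || NCOL(X) == 0)
    return(list(r2 = 0, m = 0L))
  X <- as.matrix(X)
  qrx <- qr(cbind(1, X))
  fit <- qr.fitted(qrx, Y)
  fit <- sweep(fit, 2, colMeans(fit))  # Y is centred; guard fp drift
  list(r2 = sum(fit^2) / sum(Y^2), m = qrx$rank - 1L)
}

# Ezekiel's adjusted R-squared
.adj_r2 <- function(r2, n, m) {
  if (m == 0) return(0)
  if (n - m - 1 <= 0) stop("over-parameterised model: n - m - 1 <= 0")
  1 - (1 - r2) * (n - 1) / (n - m - 1)
}

#' Forward selection of predictors for a multivariate response
#'
#' Forward selection in the Blanchet et al. spirit, with three guards against
#' overfitting: (i) a global permutation pre-test -- selection only proceeds
#' when the model with all candidates is itself significant at `alpha`;
#' (ii) at each step the candidate adding the most R-squared enters only if
#' its partial permutation p-value (predictor and response residualised on
#' the already-selected set, response rows permuted) is at or below `alpha`;
#' and (iii) from the second variable on, selection stops once the cumulative
#' adjusted R-squared would exceed that of the global model (the first
#' variable is exempt from this ceiling: it is already guarded by the global
#' pre-test, and with few informative candidates the one-variable adjusted
#' R-squared can legitimately exceed the more heavily penalised global one).
#'
#' @param Y a `pcoa_response` or a centred numeric response matrix.
#' @param X candidate predictor matrix (columns named).
#' @param n_perm permutations per test.
#' @param alpha entry threshold.
#' @param seed RNG seed.
#' @param max_vars hard cap on the number of selected predictors (default
#'   unlimited); the pipeline caps each set at `(n - 2) / 2` so the combined
#'   habitat + space model stays estimable on small site sets.
#' @return list of class `forward_selection`: `selected` (column names, in
#'   entry order), `pvals`, `r2_path`, `adj_r2`, `global_adj_r2`, `n_perm`.
#' @export
forward_select <- function(Y, X, n_perm = 999, alpha = 0.05, seed = NULL,
                           max_vars = Inf) {
  if (inherits(Y, "pcoa_response")) Y <- Y$axes
  Y <- as.matrix(Y)
  Y <- sweep(Y, 2, colMeans(Y))
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- sprintf("X%d", seq_len(ncol(X)))
  n <- nrow(Y)
  if (nrow(X) != n) stop("Y and X disagree on the number of sites")
  glob <- .rda_r2(Y, X)
  if (glob$m >= n - 1) {
    warning("global model is saturated (", glob$m, " independent candidates, ",
            n, " sites): adjusted-R2 stopping rule disabled")
    global_adj <- Inf
  } else {
    global_adj <- .adj_r2(glob$r2, n, glob$m)
  }
  selected <- character(0)
  pvals <- numeric(0)
  r2_path <- numeric(0)
  r2_sel <- 0
  p_global <- NA_real_
  # selection works on centred candidates, orthonormalised incrementally
  # (Gram-Schmidt): the added R-squared of every remaining candidate is a
  # single crossproduct against Y per step, instead of one model fit each
  Xc <- sweep(X, 2, colMeans(X))
  x_ss0 <- colSums(Xc^2)
  ssY <- sum(Y^2)
  active <- which(x_ss0 > 0)
  Q <- matrix(0, n, 0)
  with_seed(seed, {
    # global pre-test: R2 of the all-candidate model vs permuted response
    Qg <- qr.Q(qr(Xc[, active, drop = FALSE]))[, seq_len(glob$m),
                                               drop = FALSE]
    g_obs <- sum(crossprod(Qg, Y)^2)
    g_perm <- vapply(seq_len(n_perm), function(k) {
      sum(crossprod(Qg[sample.int(n), , drop = FALSE], Y)^2)
    }, numeric(1))
    p_global <- (1 + sum(g_perm >= g_obs - 1e-12)) / (n_perm + 1)
    if (p_global > alpha) {
      warning("global model not significant (p = ", signif(p_global, 3),
              "): no variable selected")
      active <- integer(0)
    }
    Xr <- Xc[, active, drop = FALSE]  # residualised on the selected set
    repeat {
      if (length(active) == 0 || length(selected) >= max_vars) break
      ss <- colSums(Xr^2)
      ok <- ss > 1e-10 * x_ss0[active]  # drop collinear leftovers
      if (!any(ok)) break
      added <- rep(-Inf, ncol(Xr))
      proj <- crossprod(Xr[, ok, drop = FALSE], Y)       # cand x axes
      added[ok] <- rowSums(proj^2) / (ss[ok] * ssY)
      bi <- which.max(added)
      if (added[bi] < 1e-12) break  # nothing left to add
      best <- colnames(Xr)[bi]
      q <- Xr[, bi] / sqrt(ss[bi])
      # permutation test of the best candidate, conditioned on the selected
      # set: response and candidate both residualised (q is already), rows
      # of the candidate permuted
      Yr <- Y - Q %*% crossprod(Q, Y)
      ssYr <- ssY - sum(crossprod(Q, Y)^2)
      s_obs <- sum(crossprod(q, Yr)^2) / ssYr
      P <- vapply(seq_len(n_perm), function(k) q[sample.int(n)],
                  numeric(n))
      s_perm <- rowSums(crossprod(P, Yr)^2) / ssYr
      p <- (1 + sum(s_perm >= s_obs - 1e-12)) / (n_perm + 1)
      if (p > alpha) break
      r2_new <- r2_sel + added[bi]
      m_new <- ncol(Q) + 1L
      if (m_new >= n - 1) break  # adding would saturate the model
      adj_new <- .adj_r2(r2_new, n, m_new)
      if (length(selected) >= 1 && adj_new > global_adj + 1e-12)
        break  # adjusted-R2 ceiling (second variable onwards)
      selected <- c(selected, best)
      pvals <- c(pvals, p)
      r2_path <- c(r2_path, r2_new)
      r2_sel <- r2_new
      Q <- cbind(Q, q)
      keep <- setdiff(seq_len(ncol(Xr)), bi)
      Xr <- Xr[, keep, drop = FALSE]
      active <- active[keep]
      if (length(active)) Xr <- Xr - q %*% crossprod(q, Xr)
    }
  })
  if (length(selected) == 0 && p_global <= alpha)
    warning("no candidate significant at alpha = ", alpha)
  structure(list(selected = selected, pvals = pvals, r2_path = r2_path,
                 p_global = p_global,
                 adj_r2 = if (length(selected))
                   .adj_r2(r2_sel, n, length(selected)) else 0,
                 global_adj_r2 = global_adj, n_perm = n_perm, alpha = alpha,
                 seed = seed),
            class = "forward_selection")
}

#' Variation partitioning into habitat and space fractions
#'
#' Given the db-RDA response and the (already forward-selected) environmental
#' and spatial predictor sets, computes raw R-squared for the models `[E]`,
#' `[S]`, `[E + S]`, adjusts each by Ezekiel's formula, and returns
#' `a = adjR2(E+S) - adjR2(S)` (pure habitat),
#' `c = adjR2(E+S) - adjR2(E)` (pure space),
#' `b = adjR2(E) + adjR2(S) - adjR2(E+S)` (spatially structured habitat) and
#' `d = 1 - adjR2(E+S)` (undetermined); `a + b + c + d = 1` by construction.
#'
#' @param Y a `pcoa_response` or centred response matrix.
#' @param E environmental predictor matrix (0 columns / NULL allowed).
#' @param S spatial predictor matrix (0 columns / NULL allowed).
#' @return list of class `varpart_fractions`: `a`, `b`, `c`, `d`, `r2`
#'   (named raw R-squared of E, S, ES), `adj` (their adjusted values), `n`,
#'   `m_E`, `m_S`.
#' @export
varpart_fractions <- function(Y, E = NULL, S = NULL) {
  if (inherits(Y, "pcoa_response")) Y <- Y$axes
  Y <- as.matrix(Y)
  Y <- sweep(Y, 2, colMeans(Y))
  n <- nrow(Y)
  fe <- .rda_r2(Y, E); fs <- .rda_r2(Y, S)
  ES <- if ((is.null(E) || NCOL(E) == 0) && (is.null(S) || NCOL(S) == 0)) {
    NULL
  } else {
    cbind(if (!is.null(E) && NCOL(E)) as.matrix(E),
          if (!is.null(S) && NCOL(S)) as.matrix(S))
  }
  fes <- .rda_r2(Y, ES)
  adjE <- .adj_r2(fe$r2, n, fe$m)
  adjS <- .adj_r2(fs$r2, n, fs$m)
  adjES <- .adj_r2(fes$r2, n, fes$m)
  a <- adjES - adjS
  cc <- adjES - adjE
  b <- adjE + adjS - adjES
  d <- 1 - adjES
  if (min(a, b, cc) < -0.1)
    warning("a fraction below the -0.1 sanity bound; check predictor sets")
  structure(list(a = a, b = b, c = cc, d = d,
                 r2 = c(E = fe$r2, S = fs$r2, ES = fes$r2),
                 adj = c(E = adjE, S = adjS, ES = adjES),
                 n = n, m_E = fe$m, m_S = fs$m),
            class = "varpart_fractions")
}

#' @export
print.varpart_fractions <- function(x, ...) {
  cat("Variation partitioning (adjusted R2, Ezekiel):\n",
      sprintf("  a (pure habitat)        = %8.4f\n", x$a),
      sprintf("  b (spatial habitat)     = %8.4f\n", x$b),
      sprintf("  c (pure space)          = %8.4f\n", x$c),
      sprintf("  d (undetermined)        = %8.4f\n", x$d),
      sprintf("  n = %d, m_E = %d, m_S = %d\n", x$n, x$m_E, x$m_S), sep = "")
  invisible(x)
}
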