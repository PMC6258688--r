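# Distance-based Moran's eigenvector maps (dbMEM / PCNM): spatial
# eigenfunctions from the principal-coordinate decomposition of a truncated
# inter-site distance matrix, with Moran's I per eigenvector.

#' Expected Moran's I under no spatial autocorrelation
#' @param n number of sites.
#' @export
expected_moran <- function(n) -1 / (n - 1)

# Moran's I of vector v (any centring) with binary weight matrix W
.moran_i <- function(v, W) {
  n <- length(v)
  z <- v - mean(v)
  (n / sum(W)) * as.numeric(t(z) %*% W %*% z) / sum(z^2)
}

#' Build the dbMEM basis
#'
#' Truncates the Euclidean inter-site distance matrix at `t` (default: the
#' longest edge of the minimum spanning tree, the smallest threshold that
#' keeps the sites connected), replaces distances above `t` by `4 t`, and
#' takes the principal-coordinate decomposition of the modified matrix.
#' Axes with eigenvalue above `1e-9 * lambda_max` are kept as candidate
#' eigenfunctions (only positive eigenvalues are usable as spatial
#' predictors); each eigenvector's Moran's I is computed with the binary
#' `d <= t` connectivity weights.  Eigenvector signs are fixed by making the
#' largest-magnitude loading positive, so output is reproducible across
#' linear-algebra backends.
#'
#' @param coords two-column matrix/data.frame of site coordinates (metres),
#'   or the `sites` frame of an `abundance_matrix` (columns `cx`, `cy`).
#' @param truncation threshold in metres, or `NULL` for the MST default.
#' @return object of class `mem_basis`: `vectors` (site x axis, unit norm,
#'   centred), `values`, `moran_i`, `expected_i`, `truncation`, `n_sites`,
#'   `retained` (indices; filled by [select_mem()]).
#' @export
build_dbmem <- function(coords, truncation = NULL) {
  if (is.data.frame(coords) && all(c("cx", "cy") %in% names(coords)))
    coords <- as.matrix(coords[, c("cx", "cy")])
  coords <- as.matrix(coords)
  n <- nrow(coords)
  if (n < 2) stop("need at least 2 sites")
  D <- stats::dist(coords)
  if (any(D == 0)) stop("duplicate coordinates")
  if (is.null(truncation)) {
    st <- vegan::spantree(D)
    truncation <- max(st$dist)
  }
  Dm <- as.matrix(D)
  Dstar <- ifelse(Dm > truncation, 4 * truncation, Dm)
  diag(Dstar) <- 0
  # PCoA: double-centred -0.5 * D*^2
  G <- -0.5 * Dstar^2
  G <- sweep(G, 1, rowMeans(G))
  G <- sweep(G, 2, colMeans(G))
  eg <- eigen(G, symmetric = TRUE)
  lmax <- max(eg$values)
  if (lmax <= 0) stop("no positive eigenvalue: degenerate configuration")
  keep <- which(eg$values > 1e-9 * lmax)
  V <- eg$vectors[, keep, drop = FALSE]
  # reproducible sign: largest |loading| positive
  for (k in seq_len(ncol(V))) {
    mi <- which.max(abs(V[, k]))
    if (V[mi, k] < 0) V[, k] <- -V[, k]
  }
  W <- (Dm <= truncation) * 1
  diag(W) <- 0
  # the <= t graph must connect all sites (guaranteed when t is the longest
  # MST edge); assert explicitly
  reach <- logical(n); reach[1] <- TRUE
  frontier <- 1L
  while (length(frontier)) {
    nb <- which(colSums(W[frontier, , drop = FALSE]) > 0 & !reach)
    reach[nb] <- TRUE
    frontier <- nb
  }
  if (!all(reach))
    stop("truncation ", signif(truncation, 6),
         " leaves the connectivity graph disconnected")
  I <- apply(V, 2, .moran_i, W = W)
  rn <- rownames(coords)
  rownames(V) <- rn
  colnames(V) <- sprintf("MEM%d", seq_len(ncol(V)))
  structure(list(vectors = V, values = eg$values[keep], moran_i = I,
                 expected_i = expected_moran(n), truncation = truncation,
                 n_sites = n, coords = coords, retained = NULL),
            class = "mem_basis")
}

#' Retain eigenvectors with positive spatial autocorrelation
#'
#' Keeps the axes whose Moran's I strictly exceeds its expectation
#' `-1/(n-1)`; these are the spatial predictors used downstream.
#'
#' @param basis a `mem_basis`.
#' @return the basis with `vectors`, `values`, `moran_i` subset to the
#'   retained axes and `retained` recording their original indices.
#' @export
select_mem <- function(basis) {
  stopifnot(inherits(basis, "mem_basis"))
  keep <- which(basis$moran_i > basis$expected_i)
  if (length(keep) == 0)
    warning("no eigenvector with Moran's I above expectation")
  basis$retained <- keep
  basis$vectors <- basis$vectors[, keep, drop = FALSE]
  basis$values <- basis$values[keep]
  basis$moran_i <- basis$moran_i[keep]
  basis
}

#' Export a MEM basis (CSV eigenvectors + JSON metadata)
#' @param basis a `mem_basis`.
#' @param path CSV path.
#' @export
write_mem <- function(basis, path) {
  df <- data.frame(site = rownames(basis$vectors) %||%
                     as.character(seq_len(nrow(basis$vectors))),
                   basis$vectors, check.names = FALSE)
  write_with_sidecar(df, path, meta = list(
    truncation = basis$truncation, eigenvalues = basis$values,
    moran_i = basis$moran_i, expected_i = basis$expected_i,
    retained = basis$retained))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
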