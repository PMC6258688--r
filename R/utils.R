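# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed without disturbing the caller's
# random stream.  seed = NULL means "use the current stream".
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  code
}

# Derive a per-stage child seed from a master seed; keeps values in 32-bit
# integer range.  Counter-based so any stage can be re-run in isolation.
child_seed <- function(master, counter) {
  as.integer((as.double(master) * 1009 + 7919 * counter) %% 2147483587L)
}

# Row/column indices (i > j) of the condensed vector produced by stats::dist,
# in dist's storage order (column-major lower triangle).
pair_indices <- function(n) {
  stopifnot(n >= 2)
  j <- rep.int(seq_len(n - 1L), times = (n - 1L):1L)
  i <- unlist(lapply(seq_len(n - 1L), function(k) (k + 1L):n), use.names = FALSE)
  list(i = i, j = j)
}

# Separable Gaussian smoothing of a matrix field; sigma in matrix cells.
# Kernel rows are renormalised, so edges are not damped.
smooth_field <- function(mat, sigma) {
  if (sigma <= 0) return(mat)
  kern <- function(n) {
    d <- abs(outer(seq_len(n), seq_len(n), "-"))
    k <- exp(-0.5 * (d / sigma)^2)
    k / rowSums(k)
  }
  kx <- kern(nrow(mat))
  ky <- kern(ncol(mat))
  kx %*% mat %*% t(ky)
}

# Mean over k x k blocks of a matrix whose dimensions are multiples of k.
block_mean <- function(mat, k) {
  if (k == 1L) return(mat)
  nr <- nrow(mat) %/% k
  nc <- ncol(mat) %/% k
  stopifnot(nr * k == nrow(mat), nc * k == ncol(mat))
  out <- matrix(0, nr, nc)
  for (a in seq_len(k)) {
    for (b in seq_len(k)) {
      out <- out + mat[seq(a, by = k, length.out = nr),
                       seq(b, by = k, length.out = nc), drop = FALSE]
    }
  }
  out / (k * k)
}

# Write a data.frame as CSV together with a JSON metadata sidecar.
write_with_sidecar <- function(df, path, meta = list()) {
  utils::write.csv(df, path, row.names = FALSE)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}
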