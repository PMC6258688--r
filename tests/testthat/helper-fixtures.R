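# Shared fixtures and independent oracles.

# a small but topographically structured synthetic plot
small_config <- function(seed = 1, ...) {
  args <- list(seed = seed, x_extent = 200, y_extent = 100,
               n_species = 40, n_stems_target = 6000, n_peaks = 2)
  extra <- list(...)
  args[names(extra)] <- extra
  do.call(synthetic_config, args)
}

# random quadrat x species count matrix
random_counts <- function(n_sites, n_species, lambda = 3) {
  m <- matrix(rpois(n_sites * n_species, lambda), n_sites, n_species)
  rownames(m) <- sprintf("s%02d", seq_len(n_sites))
  colnames(m) <- sprintf("sp%02d", seq_len(n_species))
  m
}

# brute-force per-species min/surplus decomposition: the independent oracle
# for pair_abc and beta_decompose
brute_beta <- function(X) {
  n <- nrow(X)
  bc <- bal <- gra <- matrix(0, n, n)
  for (m in seq_len(n - 1)) for (o in (m + 1):n) {
    A <- B <- C <- 0
    for (s in seq_len(ncol(X))) {
      A <- A + min(X[m, s], X[o, s])
      B <- B + X[m, s] - min(X[m, s], X[o, s])
      C <- C + X[o, s] - min(X[m, s], X[o, s])
    }
    mn <- min(B, C)
    bc[m, o] <- bc[o, m] <- (B + C) / (2 * A + B + C)
    bal[m, o] <- bal[o, m] <- mn / (A + mn)
    gra[m, o] <- gra[o, m] <- (abs(B - C) / (2 * A + B + C)) * (A / (A + mn))
  }
  list(bc = as.dist(bc), bal = as.dist(bal), gra = as.dist(gra))
}

# brute-force Mantel: direct Spearman correlation on explicitly permuted
# matrices, enumerating all relabellings
brute_mantel_exact <- function(dx, dy, alternative = "greater") {
  mx <- as.matrix(dx); my <- as.matrix(dy)
  n <- nrow(mx)
  vx <- mx[lower.tri(mx)]
  robs <- cor(vx, my[lower.tri(my)], method = "spearman")
  perms <- karstbeta:::all_permutations(n)
  rall <- vapply(perms, function(p) {
    mp <- my[p, p]
    cor(vx, mp[lower.tri(mp)], method = "spearman")
  }, numeric(1))
  if (alternative == "greater") mean(rall >= robs - 1e-12)
  else mean(abs(rall) >= abs(robs) - 1e-12)
}

# census table built by hand
tiny_census <- function(gx, gy, species = NULL, dbh = NULL, census = 1L) {
  n <- length(gx)
  data.frame(tag = sprintf("t%03d", seq_len(n)),
             species = species %||% rep("spA", n),
             gx = gx, gy = gy,
             dbh = dbh %||% rep(5, n), census = census,
             stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
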