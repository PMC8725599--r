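# Shared fixtures and independent oracles, all built in code.

tiny_counts <- function() {
  m <- matrix(c(4L, 5L,
                6L, 3L,
                0L, 4L), nrow = 3, byrow = TRUE,
              dimnames = list(c("A", "B", "C"), c("s1", "s2")))
  m
}

tiny_tree <- function() ape::read.tree(text = "((A:1,B:1):1,C:2);")

# Random community + random coalescent tree for property tests.
random_instance <- function(n_taxa, n_samples, seed) {
  set.seed(seed)
  tree <- ape::rcoal(n_taxa)
  tree$tip.label <- sprintf("t%02d", seq_len(n_taxa))
  counts <- matrix(rpois(n_taxa * n_samples, 3), n_taxa, n_samples,
                   dimnames = list(tree$tip.label,
                                   sprintf("s%02d", seq_len(n_samples))))
  # guarantee no empty sample and no all-zero taxon
  for (j in seq_len(n_samples))
    if (sum(counts[, j]) == 0) counts[sample.int(n_taxa, 1), j] <- 1L
  counts[rowSums(counts) == 0, 1] <- 1L
  storage.mode(counts) <- "integer"
  list(table = community_table(counts), tree = tree)
}

# Exhaustive nearest-taxon betaMNTD oracle: plain double loops over all
# taxon pairs, independent of the package's C++ kernel.
beta_mntd_oracle <- function(table, tree, abundance_weighted = TRUE) {
  m <- unclass(table)
  D <- ape::cophenetic.phylo(tree)[rownames(m), rownames(m)]
  rel <- sweep(m, 2, colSums(m), "/")
  n <- ncol(m)
  out <- matrix(0, n, n, dimnames = list(colnames(m), colnames(m)))
  for (j in seq_len(n)) for (k in seq_len(n)) {
    if (j >= k) next
    pj <- which(m[, j] > 0); pk <- which(m[, k] > 0)
    mntd_dir <- function(from, to, w) {
      tot <- 0; wsum <- 0
      for (i in from) {
        best <- Inf
        for (i2 in to) best <- min(best, D[i, i2])
        wt <- if (abundance_weighted) w[i] else 1
        tot <- tot + wt * best
        wsum <- wsum + wt
      }
      tot / wsum
    }
    out[j, k] <- out[k, j] <-
      0.5 * (mntd_dir(pj, pk, rel[, j]) + mntd_dir(pk, pj, rel[, k]))
  }
  out
}

# One draw of the RC-Bray null assembly procedure applied to every sample
# of a counts matrix (used for self-calibration tests).
rc_null_assembly <- function(m, seed) {
  occ <- rowSums(m > 0)
  pool_p <- rowSums(m) / sum(m)
  rich <- colSums(m > 0)
  totals <- colSums(m)
  set.seed(seed)
  out <- vapply(seq_len(ncol(m)), function(s) {
    drawn <- sample.int(nrow(m), rich[s], prob = occ)
    x <- integer(nrow(m))
    x[drawn] <- 1L
    x[drawn] <- x[drawn] +
      as.integer(rmultinom(1, totals[s] - rich[s], pool_p[drawn]))
    x
  }, integer(nrow(m)))
  dimnames(out) <- dimnames(m)
  out
}

expect_sym <- function(m) expect_lt(max(abs(m - t(m)), na.rm = TRUE), 1e-12)

# community_table() but silently dropping all-zero taxa
community_table_drop_zero <- function(m) suppressWarnings(community_table(m))

# symmetric matrix from an upper-triangle vector (column-major order)
vec_to_sym_test <- function(v, ids) {
  n <- length(ids)
  m <- matrix(0, n, n, dimnames = list(ids, ids))
  m[upper.tri(m)] <- v
  m[lower.tri(m)] <- t(m)[lower.tri(m)]
  m
}
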