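test_that("betaMNTD matches trivial cases on the toy tree", {
  tree <- tiny_tree()
  # identical communities: every taxon matches itself at distance 0
  m <- matrix(c(3L, 3L, 2L, 2L, 1L, 1L), 3, 2, byrow = TRUE,
              dimnames = list(c("A", "B", "C"), c("s1", "s2")))
  bm <- beta_mntd(community_table(m), tree)
  expect_equal(bm["s1", "s2"], 0)

  # single-taxon communities {A} vs {B}: betaMNTD = d(A,B) = 2
  m2 <- matrix(c(5L, 0L,
                 0L, 7L,
                 0L, 0L), 3, 2, byrow = TRUE,
               dimnames = list(c("A", "B", "C"), c("s1", "s2")))
  bm2 <- beta_mntd(community_table_drop_zero(m2), tree)
  expect_equal(bm2["s1", "s2"], 2)
})

test_that("betaMNTD equals the brute-force oracle on random instances", {
  for (seed in 1:20) {
    n_taxa <- sample(4:8, 1)
    n_samp <- sample(3:5, 1)
    inst <- random_instance(n_taxa, n_samp, seed)
    for (weighted in c(TRUE, FALSE)) {
      got <- beta_mntd(inst$table, inst$tree, abundance_weighted = weighted)
      want <- beta_mntd_oracle(inst$table, inst$tree,
                               abundance_weighted = weighted)
      expect_lt(max(abs(got - want)), 1e-12)
    }
  }
})

test_that("betaMNTD ignores taxa absent from the compared samples", {
  tree <- tiny_tree()
  m <- matrix(c(5L, 0L,
                0L, 7L,
                0L, 0L), 3, 2, byrow = TRUE,
              dimnames = list(c("A", "B", "C"), c("s1", "s2")))
  # C is absent everywhere: dropping it changes nothing
  bm_with <- beta_mntd(community_table_drop_zero(m), tree)
  bm_without <- beta_mntd(community_table(m[1:2, ]), tree)
  expect_equal(bm_with["s1", "s2"], bm_without["s1", "s2"])
})

test_that("betaNTI null model behaves as constructed", {
  inst <- random_instance(8, 4, 11)
  res <- bnti(inst$table, inst$tree, n_null = 99, seed = 5)
  expect_s3_class(res, "bnti_result")
  ut <- upper.tri(res$bnti)
  expect_equal(res$bnti[ut],
               ((res$observed - res$null_mean) / res$null_sd)[ut],
               tolerance = 1e-12)

  # reproducible bit-exactly for fixed seed
  res2 <- bnti(inst$table, inst$tree, n_null = 99, seed = 5)
  expect_identical(res$bnti, res2$bnti)

  # near-identical communities: observed betaMNTD ~ 0 (shared taxa match
  # themselves) while tip shuffling separates them -> betaNTI < 0.
  # (Exactly identical presence sets are degenerate under the taxa-label
  # null: every shuffle leaves betaMNTD at 0 -- see the block below.)
  # s1 = {a,b,c} vs s2 = {a,b,d}: shared taxa self-match at 0 and the
  # differing taxa c,d are siblings, so observed betaMNTD is far below the
  # null, where the shuffle can swap in the distant clade {e,f} (present
  # only in the third pool sample) -> betaNTI < 0
  tree <- ape::read.tree(
    text = "(((a:1,b:1):1,(c:1,d:1):1):2,(e:0.5,f:0.5):3.5);")
  m <- matrix(c(3L, 3L, 0L,
                2L, 2L, 0L,
                2L, 0L, 0L,
                0L, 2L, 0L,
                0L, 0L, 3L,
                0L, 0L, 4L), 6, 3, byrow = TRUE,
              dimnames = list(letters[1:6], c("s1", "s2", "s3")))
  ri <- bnti(community_table(m), tree, n_null = 199, seed = 1)
  expect_lt(ri$bnti["s1", "s2"], 0)

  # identical presence sets for the whole pool: every shuffle leaves each
  # taxon matching itself, so the null sd is zero and the pair is flagged
  m_deg <- m
  m_deg[, 2] <- m_deg[, 1] * 2L
  expect_warning(
    deg <- bnti(community_table(m_deg), tree, n_null = 49, seed = 1),
    "degenerate")
  expect_true(is.na(deg$bnti["s1", "s2"]))
  expect_warning(pp_deg <- partition_processes(deg$bnti, deg$bnti),
                 "degenerate pair")
  expect_equal(pp_deg$n_excluded, 1)
  expect_equal(pp_deg$n_pairs, 2)
})

test_that("pair classification implements the two-step thresholds", {
  expect_equal(classify_pair(2.5, 0), "heterogeneous_selection")
  expect_equal(classify_pair(-3.0, 0), "homogeneous_selection")
  expect_equal(classify_pair(1.0, 0.97), "dispersal_limitation")
  expect_equal(classify_pair(0.5, -0.99), "homogenizing_dispersal")
  expect_equal(classify_pair(0.0, 0.30), "drift")
  expect_true(is.na(classify_pair(NA_real_, 0.3)))
})

test_that("process fractions sum to one and are order-invariant", {
  set.seed(21)
  n <- 10
  ids <- paste0("s", 1:n)
  b <- vec_to_sym_test(runif(n * (n - 1) / 2, -4, 4), ids)
  r <- vec_to_sym_test(runif(n * (n - 1) / 2, -1, 1), ids)
  pp <- partition_processes(b, r, "g")
  expect_equal(sum(pp$fractions), 1, tolerance = 1e-15)
  expect_equal(sum(pp$counts), pp$n_pairs)

  p <- sample.int(n)
  pp2 <- partition_processes(b[p, p], r[p, p], "g")
  expect_identical(pp$fractions, pp2$fractions)

  df <- as.data.frame(pp)
  expect_equal(nrow(df), 5)
  expect_equal(sum(df$fraction), 1)
})

test_that("RC-Bray matches construction on degenerate and bounded cases", {
  # identical communities with a diverse pool -> RC ~ -1
  set.seed(3)
  pool <- matrix(rpois(20 * 6, 4) + 1L, 20, 6,
                 dimnames = list(sprintf("t%02d", 1:20), paste0("s", 1:6)))
  pool[, 2] <- pool[, 1]
  res <- rc_bray(community_table(pool), n_null = 499, seed = 9)
  expect_lt(res$rc["s1", "s2"], -0.95)
  v <- res$rc[upper.tri(res$rc)]
  expect_true(all(v >= -1 & v <= 1))

  one_taxon <- matrix(c(5L, 8L), 1, 2,
                      dimnames = list("t1", c("s1", "s2")))
  expect_error(rc_bray(community_table(one_taxon)), "fewer than 2 taxa")

  # fixed seed -> identical result
  res2 <- rc_bray(community_table(pool), n_null = 499, seed = 9)
  expect_identical(res$rc, res2$rc)
})

test_that("phylogenetic-signal correlogram handles boundaries", {
  inst <- random_instance(12, 6, 31)
  env <- data.frame(temperature = seq(5, 30, length.out = 6),
                    salinity = rnorm(6, 34, 0.2))
  # add a taxon present in exactly one sample -> excluded with warning
  m <- unclass(inst$table)
  m[1, ] <- 0L; m[1, 2] <- 4L
  tab <- community_table_drop_zero(m)
  expect_warning(
    ps <- phylo_signal(tab, inst$tree, env, n_classes = 4, n_perm = 49,
                       seed = 1),
    "excluded")
  expect_equal(nrow(ps), 4)
  expect_true(all(ps$p_value > 0 & ps$p_value <= 1, na.rm = TRUE))
  expect_true(all(ps$p_corrected >= ps$p_value, na.rm = TRUE))
})
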