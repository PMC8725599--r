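meta_fixture <- function(n = 12, seed = 2) {
  set.seed(seed)
  data.frame(sample_id = sprintf("s%02d", 1:n),
             latitude = seq(5, 60, length.out = n),
             longitude = -170, layer = "surface",
             temperature = seq(28, 7, length.out = n) + rnorm(n, 0, 0.3),
             nitrate = exp(seq(log(0.3), log(12), length.out = n)) +
               abs(rnorm(n, 0, 0.1)),
             salinity = rnorm(n, 34.5, 0.2),
             noise = rnorm(n))
}

test_that("log(x+1) transform validates and round-trips", {
  meta <- meta_fixture()
  tr <- log1p_env(meta, c("temperature", "nitrate"))
  expect_equal(tr$nitrate, log1p(meta$nitrate))
  expect_equal(expm1(tr$temperature), meta$temperature, tolerance = 1e-12)
  expect_equal(log1p_env(data.frame(sample_id = "a", x = 0), "x")$x, 0)
  expect_equal(log1p_env(data.frame(sample_id = "a", x = exp(1) - 1),
                         "x")$x, 1)
  meta$nitrate[3] <- -0.5
  expect_error(log1p_env(meta, "nitrate"), "negative value.*nitrate")
})

test_that("environmental distance honors normalization and degeneracy", {
  meta <- data.frame(sample_id = c("a", "b"), v = c(0, 10), w = c(1, 1))
  expect_equal(env_distance(meta, "v")["a", "b"], 10)
  expect_equal(env_distance(meta, "v", normalize = TRUE)["a", "b"], 1)
  expect_equal(env_distance(meta, "v")["a", "a"], 0)
  expect_warning(d <- env_distance(meta, c("v", "w"), normalize = TRUE),
                 "constant variable")
  expect_equal(d["a", "b"], 1)

  het <- env_heterogeneity(cbind(meta_fixture(),
                                 zone = rep(c("tropic", "subarctic"),
                                            each = 6)),
                           c("temperature", "nitrate"), group = "zone")
  expect_setequal(unique(het$group), c("tropic", "subarctic"))
  expect_equal(nrow(het), 2 * choose(6, 2))
})

test_that("Mantel statistics match construction and vegan's", {
  meta <- meta_fixture()
  d1 <- env_distance(meta, "temperature")
  d2 <- env_distance(meta, "nitrate")
  res <- mantel(d1, d1, n_perm = 99, seed = 1)
  expect_equal(res$r, 1)
  expect_lt(res$p_value, 0.05)

  # agreement with vegan's statistic (not p, which is permutation-based)
  vg <- vegan::mantel(as.dist(d1), as.dist(d2), permutations = 0)
  expect_equal(mantel(d1, d2, n_perm = 9, seed = 1)$r, unname(vg$statistic),
               tolerance = 1e-10)

  # invariant to a common relabeling
  p <- sample(nrow(d1))
  expect_equal(mantel(d1[p, p], d2[p, p], n_perm = 9, seed = 1)$r,
               mantel(d1, d2, n_perm = 9, seed = 1)$r, tolerance = 1e-12)

  const <- matrix(1, 12, 12); diag(const) <- 0
  dimnames(const) <- dimnames(d1)
  expect_error(mantel(d1, const), "zero variance")
})

test_that("partial Mantel controls and degenerates correctly", {
  meta <- meta_fixture()
  dA <- env_distance(meta, "temperature")
  dB <- env_distance(meta, "nitrate")
  dC <- env_distance(meta, "noise")
  # controlling a matrix for itself is 0/0: rejected as undefined
  expect_error(partial_mantel(dA, dB, dB, n_perm = 9, seed = 1),
               "perfectly correlated")
  # uncorrelated control barely changes r
  plain <- mantel(dA, dB, n_perm = 9, seed = 1)$r
  part <- partial_mantel(dA, dB, dC, n_perm = 9, seed = 1)$r
  expect_lt(abs(plain - part), 0.12)
  expect_true(abs(part) <= 1)
  # agreement with vegan's partial statistic
  vg <- vegan::mantel.partial(as.dist(dA), as.dist(dB), as.dist(dC),
                              permutations = 0)
  expect_equal(part, unname(vg$statistic), tolerance = 1e-10)
})

test_that("betaNTI-environment table recovers the driving factor", {
  sim <- simulate_metacommunity(scenario_config(
    "selection", n_taxa = 60, n_samples = 14, reads_per_sample = 600,
    latitudes = seq(4, 64, length.out = 14), match_range = TRUE, seed = 6))
  b <- suppressWarnings(bnti(sim$table, sim$tree, n_null = 99, seed = 2))
  vars <- c("temperature", "salinity", "ammonia", "iron")
  tabres <- bnti_env_correlation(b, sim$meta, vars, n_perm = 99, seed = 3)
  expect_equal(nrow(tabres), length(vars))
  expect_equal(tabres$variable[which.max(tabres$adj_r)], "temperature")

  sim$meta$constant <- 1
  expect_warning(
    res2 <- bnti_env_correlation(b, sim$meta, c("temperature", "constant"),
                                 n_perm = 49, seed = 3),
    "constant")
  expect_equal(nrow(res2), 1)
})

test_that("PCNM eigenvectors are orthogonal and track a transect", {
  meta <- meta_fixture(n = 30)
  geo <- geographic_distance(meta)
  vec <- pcnm(geo)
  expect_lte(ncol(vec), nrow(geo) - 1)
  g <- crossprod(vec)
  expect_lt(max(abs(g[upper.tri(g)])), 1e-8)
  # the broadest-scale eigenvector is a half-wave along the transect;
  # its linear correlation with the coordinate plateaus near 0.8
  expect_gt(abs(cor(vec[, 1], meta$latitude)), 0.75)
  expect_gt(abs(cor(vec[, 1], meta$latitude, method = "spearman")), 0.75)
  expect_error(pcnm(geo[1:2, 1:2]), ">= 3 samples")
})

test_that("factor selection drops collinear factors and keeps drivers", {
  sim <- simulate_metacommunity(scenario_config(
    "selection", n_taxa = 50, n_samples = 14, reads_per_sample = 500,
    latitudes = seq(4, 64, length.out = 14), match_range = TRUE, seed = 9))
  meta <- sim$meta
  meta$temp_copy <- meta$temperature * 2 + 1    # perfectly collinear
  set.seed(1); meta$noise <- rnorm(nrow(meta))
  kept <- select_factors(sim$table, meta,
                         c("temperature", "temp_copy", "noise", "salinity"),
                         n_perm = 99, seed = 4)
  expect_true(xor("temperature" %in% kept, "temp_copy" %in% kept))
  expect_false("noise" %in% kept)
  scr <- attr(kept, "screening")
  expect_true(all(scr$p_value > 0 & scr$p_value <= 1))
})

test_that("variation partitioning fractions are coherent and match vegan", {
  sim <- simulate_metacommunity(scenario_config(
    "selection", n_taxa = 40, n_samples = 16, reads_per_sample = 500,
    latitudes = seq(4, 64, length.out = 16), match_range = TRUE, seed = 3))
  meta <- sim$meta
  set.seed(2)
  meta$noise1 <- rnorm(16); meta$noise2 <- rnorm(16)

  v <- vpa(sim$table, meta, x1 = c("temperature", "salinity"),
           x2 = c("noise1", "noise2"))
  expect_equal(sum(v$fractions), 1, tolerance = 1e-10)
  expect_gt(v$fractions["pure_x1"], v$fractions["pure_x2"])
  expect_lt(abs(v$fractions["shared"]), 0.1)

  # oracle: vegan::varpart on the same Hellinger matrix
  Y <- sqrt(t(unclass(sim$table)) / colSums(sim$table))
  vp <- vegan::varpart(Y, ~ temperature + salinity, ~ noise1 + noise2,
                       data = meta)
  ind <- vp$part$indfract$Adj.R.square   # rows: X1|X2, X2|X1, shared, resid
  expect_equal(unname(v$fractions["pure_x1"]), ind[1], tolerance = 1e-10)
  expect_equal(unname(v$fractions["pure_x2"]), ind[2], tolerance = 1e-10)
  expect_equal(unname(v$fractions["shared"]), ind[3], tolerance = 1e-10)

  # identical sets: pure fractions collapse onto the shared one
  v2 <- vpa(sim$table, meta, x1 = "temperature", x2 = "temperature")
  expect_lt(abs(v2$fractions["pure_x1"]), 1e-10)
  expect_lt(abs(v2$fractions["pure_x2"]), 1e-10)
})
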