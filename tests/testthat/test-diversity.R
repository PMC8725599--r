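test_that("rarefaction subsamples without replacement to exact depth", {
  m <- matrix(c(10L, 40L,
                0L,  20L,
                5L,  40L), 3, 2, byrow = TRUE,
              dimnames = list(c("A", "B", "C"), c("s1", "s2")))
  tab <- community_table(m)

  r <- rarefy(tab, depth = 5, seed = 1)
  expect_equal(unname(colSums(r)), c(5, 5))
  expect_true(all(unclass(r) <= unclass(tab)))

  # rarefying to the full total is the identity
  expect_identical(unclass(rarefy(tab, depth = 15, seed = 1))[, "s1"],
                   m[, "s1"])
  expect_error(rarefy(tab, depth = 50), "exceeds total of sample s1")

  # single present taxon keeps everything in that taxon
  one <- community_table(matrix(c(10L, 0L, 3L, 9L), 2, 2,
                                dimnames = list(c("A", "B"),
                                                c("s1", "s2"))))
  expect_identical(unclass(rarefy(one, depth = 5, seed = 3))[, "s1"],
                   c(A = 5L, B = 0L))

  # hypergeometric expectation: (500, 500) at depth 100 -> E[A] = 50
  big <- community_table(matrix(c(500L, 500L), 2, 1,
                                dimnames = list(c("A", "B"), "s1")))
  draws <- vapply(1:1000, function(s)
    unclass(rarefy(big, depth = 100, seed = s))["A", 1], 1L)
  expect_lt(abs(mean(draws) - 50), 3)
})

test_that("alpha diversity matches closed forms", {
  m <- matrix(c(5L, 1L, 0L,
                5L, 0L, 7L), nrow = 2, byrow = TRUE,
              dimnames = list(c("A", "B"), c("even", "mixed", "mono")))
  a <- alpha_diversity(community_table(m))
  even <- a[a$sample_id == "even", ]
  expect_equal(even$shannon_h, log(2), tolerance = 1e-12)
  expect_equal(even$gini_simpson, 0.5, tolerance = 1e-12)
  mono <- a[a$sample_id == "mono", ]
  expect_equal(mono$shannon_h, 0)
  expect_equal(mono$gini_simpson, 0)
  # no singletons/doubletons -> chao1 = S_obs
  expect_equal(even$chao1, even$richness)
  # one singleton, no doubleton: S + F1(F1-1)/2 = S
  mixed <- a[a$sample_id == "mixed", ]
  expect_equal(mixed$chao1, mixed$richness)
  # vegan agreement on random data (independent implementation)
  inst <- random_instance(10, 4, 99)
  a2 <- alpha_diversity(inst$table)
  expect_equal(a2$shannon_h,
               unname(vegan::diversity(t(unclass(inst$table)))),
               tolerance = 1e-10)
})

test_that("Bray-Curtis matches the hand-worked example and bounds", {
  m <- matrix(c(6L, 2L,
                2L, 2L,
                0L, 4L), 3, 2, byrow = TRUE,
              dimnames = list(c("A", "B", "C"), c("x", "y")))
  bc <- bray_curtis(community_table(m))
  expect_equal(bc["x", "y"], 0.5)

  dup <- community_table(cbind(m, z = m[, "x"]))
  bc2 <- bray_curtis(dup)
  expect_equal(bc2["x", "z"], 0)

  disj <- community_table(matrix(c(3L, 0L, 0L, 7L), 2, 2,
                                 dimnames = list(c("A", "B"),
                                                 c("s1", "s2"))))
  expect_equal(bray_curtis(disj)["s1", "s2"], 1)

  for (seed in 1:5) {
    inst <- random_instance(8, 5, seed)
    b <- bray_curtis(inst$table)
    expect_sym(b)
    expect_true(all(b >= 0 & b <= 1))
  }
})

test_that("ANOSIM separates perfectly separated groups and is bounded", {
  # two groups, all between-distances > all within-distances
  n <- 8
  g <- rep(c("a", "b"), each = 4)
  d <- matrix(0.9, n, n)
  same <- outer(g, g, "==")
  d[same] <- 0.1
  diag(d) <- 0
  dimnames(d) <- list(paste0("s", 1:n), paste0("s", 1:n))
  res <- anosim(d, g, n_perm = 99, seed = 1)
  expect_equal(res$statistic, 1)
  expect_lt(res$p_value, 0.1)

  expect_error(anosim(d, c(rep("a", 7), "b")), ">= 2 samples")

  for (seed in 1:5) {
    set.seed(seed)
    dr <- as.matrix(dist(matrix(rnorm(n * 2), n)))
    dimnames(dr) <- dimnames(d)
    r <- anosim(dr, sample(g), n_perm = 49, seed = seed)
    expect_true(r$statistic >= -1 && r$statistic <= 1)
  }
})

test_that("geographic distance is haversine on the mean-radius sphere", {
  meta <- data.frame(sample_id = c("o", "e", "n"),
                     latitude = c(0, 0, 0), longitude = c(0, 1, 0),
                     layer = "surface")
  meta$latitude[3] <- 60
  d <- geographic_distance(meta)
  expect_equal(d["o", "o"], 0)
  # one degree of longitude at the equator: R * pi/180
  expect_equal(d["o", "e"], 6371.0088 * pi / 180, tolerance = 1e-6)
  expect_sym(d)
})

test_that("distance decay recovers an exact linear relationship", {
  set.seed(4)
  n <- 10
  coords <- data.frame(sample_id = paste0("s", 1:n),
                       latitude = seq(0, 45, length.out = n),
                       longitude = -170, layer = "surface")
  geo <- geographic_distance(coords)
  slope_true <- -1e-4
  sim <- 0.9 + slope_true * geo
  diag(sim) <- 1
  fit <- suppressWarnings(distance_decay(sim, geo, n_perm = 99, seed = 1))
  expect_equal(fit$slope, slope_true, tolerance = 1e-10)
  expect_equal(fit$r, -1, tolerance = 1e-10)
  expect_equal(fit$n_pairs, n * (n - 1) / 2)
  expect_equal(fit$slope_percent, slope_true * 100, tolerance = 1e-10)
})

test_that("climatic zones follow the Methods boundaries", {
  expect_equal(assign_zone(-10), "tropic")
  expect_equal(assign_zone(30), "subtropic")
  expect_equal(assign_zone(-30), "subtropic")
  expect_equal(assign_zone(55), "subarctic")
  expect_equal(assign_zone(23.5), "tropic")
  expect_equal(assign_zone(40), "subtropic")
  expect_error(assign_zone(-55), "south of the sampled design")
  expect_error(assign_zone(95), "out of range")
})
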