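#' log(x + 1) transform of environmental variables
#'
#' Standard variance-stabilising transform for skewed environmental factors
#' spanning orders of magnitude (nutrients, PAR). Values must be
#' non-negative.
#'
#' @param meta metadata data.frame
#' @param variables column names to transform
#' @return the metadata with the listed columns replaced by `log(x + 1)`
#' @export
log1p_env <- function(meta, variables) {
  for (v in variables) {
    x <- meta[[v]]
    if (is.null(x)) stop("no such variable: ", v)
    if (any(x < 0, na.rm = TRUE))
      stop("negative value in '", v, "' (sample ",
           meta$sample_id[which(x < 0)[1]], "): cannot log(x+1) transform")
    meta[[v]] <- log1p(x)
  }
  meta
}

#' Environmental distance between samples
#'
#' Euclidean distance over the listed variables, optionally after
#' per-variable max-min rescaling to `[0, 1]` so variables with large
#' ranges do not dominate. With a single variable this reduces to the
#' absolute difference.
#'
#' @param meta metadata data.frame with complete values for `variables`
#' @param variables environment column names
#' @param normalize apply `(x - min) / (max - min)` per variable first
#' @return symmetric distance matrix over samples
#' @export
env_distance <- function(meta, variables, normalize = FALSE) {
  X <- as.matrix(meta[, variables, drop = FALSE])
  if (any(!is.finite(X)))
    stop("missing values in ", paste(variables, collapse = ", "),
         ": exclude those samples first")
  if (normalize) {
    rng <- apply(X, 2, function(x) diff(range(x)))
    if (any(rng == 0)) {
      warning("constant variable(s) dropped: ",
              paste(variables[rng == 0], collapse = ", "))
      X <- X[, rng > 0, drop = FALSE]
      rng <- rng[rng > 0]
      if (!ncol(X)) stop("all variables constant")
    }
    X <- sweep(sweep(X, 2, apply(X, 2, min), "-"), 2, rng, "/")
  }
  d <- as.matrix(dist(X))
  dimnames(d) <- list(meta$sample_id, meta$sample_id)
  d
}

#' Within-group environmental heterogeneity
#'
#' The distribution of pairwise environmental distances within each group
#' (e.g. climatic zone): a wider spread marks a more heterogeneous
#' environment.
#'
#' @param meta metadata data.frame
#' @param variables environment column names
#' @param group name of the grouping column (default `"zone"`)
#' @param normalize max-min rescale before the distance (default TRUE)
#' @return data.frame with columns `group`, `sample_a`, `sample_b`,
#'   `distance`
#' @export
env_heterogeneity <- function(meta, variables, group = "zone",
                              normalize = TRUE) {
  res <- lapply(split(meta, meta[[group]]), function(sub) {
    if (nrow(sub) < 2) return(NULL)
    d <- env_distance(sub, variables, normalize = normalize)
    idx <- which(upper.tri(d), arr.ind = TRUE)
    data.frame(group = sub[[group]][1],
               sample_a = rownames(d)[idx[, 1]],
               sample_b = colnames(d)[idx[, 2]],
               distance = d[idx], stringsAsFactors = FALSE)
  })
  do.call(rbind, c(res, list(make.row.names = FALSE)))
}

#' Mantel test
#'
#' Pearson correlation between the upper triangles of two symmetric
#' matrices, with significance from simultaneous row/column permutation of
#' the second matrix. The test is one-sided (greater), the ecological
#' convention for distance-matrix correlations, and the p-value uses the
#' `(1 + count) / (1 + n_perm)` estimator so it is never exactly zero.
#'
#' @param d_a,d_b symmetric matrices over the same samples
#' @param n_perm number of permutations (default 999)
#' @param seed integer seed
#' @return list with `r`, `p_value`, `n_perm`, `adjusted = FALSE`
#' @export
mantel <- function(d_a, d_b, n_perm = 999, seed = 1L) {
  a <- check_square(d_a, "d_a"); b <- check_square(d_b, "d_b")
  if (!identical(dim(a), dim(b))) stop("matrices differ in dimension")
  av <- upper_tri_vec(a); bv <- upper_tri_vec(b)
  if (sd(av) == 0 || sd(bv) == 0)
    stop("zero variance in a distance triangle")
  obs <- cor(av, bv)
  n <- nrow(a)
  perm <- with_seed(seed, vapply(seq_len(n_perm), function(i) {
    p <- sample.int(n)
    cor(av, upper_tri_vec(b[p, p]))
  }, 0))
  list(r = obs, p_value = (1 + sum(perm >= obs)) / (1 + n_perm),
       n_perm = n_perm, adjusted = FALSE)
}

#' Partial Mantel test
#'
#' First-order partial correlation r_AB.C between the triangles of `d_a`
#' and `d_b` controlling for `d_c`, with significance from permutation of
#' `d_a` (one-sided greater).
#'
#' @param d_a,d_b,d_c symmetric matrices over the same samples
#' @param n_perm number of permutations (default 999)
#' @param seed integer seed
#' @return list with `r`, `p_value`, `n_perm`, `adjusted = TRUE`
#' @export
partial_mantel <- function(d_a, d_b, d_c, n_perm = 999, seed = 1L) {
  a <- check_square(d_a, "d_a"); b <- check_square(d_b, "d_b")
  cc <- check_square(d_c, "d_c")
  if (!identical(dim(a), dim(b)) || !identical(dim(a), dim(cc)))
    stop("matrices differ in dimension")
  av <- upper_tri_vec(a); bv <- upper_tri_vec(b); cv <- upper_tri_vec(cc)
  part_r <- function(x) {
    r_ab <- cor(x, bv); r_ac <- cor(x, cv); r_bc <- cor(bv, cv)
    if (abs(r_ac) >= 1 - 1e-12 || abs(r_bc) >= 1 - 1e-12)
      stop("controlling matrix perfectly correlated: partial r undefined")
    (r_ab - r_ac * r_bc) / sqrt((1 - r_ac^2) * (1 - r_bc^2))
  }
  obs <- part_r(av)
  n <- nrow(a)
  perm <- with_seed(seed, vapply(seq_len(n_perm), function(i) {
    p <- sample.int(n)
    part_r(upper_tri_vec(a[p, p]))
  }, 0))
  list(r = obs, p_value = (1 + sum(perm >= obs)) / (1 + n_perm),
       n_perm = n_perm, adjusted = TRUE)
}

#' Mantel correlations between betaNTI and environmental factors
#'
#' For each variable: a Mantel test between the pairwise betaNTI matrix and
#' the between-sample difference in that variable, and a partial Mantel
#' test controlling for the (max-min normalised) Euclidean distance over
#' all other variables. A larger adjusted R marks the variable as a
#' stronger driver of phylogenetic turnover.
#'
#' @param bnti betaNTI matrix or [bnti()] result
#' @param meta metadata data.frame (rows matching the betaNTI samples)
#' @param variables environment column names
#' @param n_perm permutations (default 999)
#' @param seed integer seed
#' @return data.frame with columns `variable`, `mantel_r`, `mantel_p`,
#'   `adj_r`, `adj_p`
#' @export
bnti_env_correlation <- function(bnti, meta, variables, n_perm = 999,
                                 seed = 1L) {
  b <- if (inherits(bnti, "bnti_result")) bnti$bnti else
    check_square(bnti, "bnti")
  diag(b) <- 0
  constant <- vapply(variables, function(v)
    length(unique(meta[[v]])) == 1, TRUE)
  if (any(constant)) {
    warning("constant variable(s) skipped: ",
            paste(variables[constant], collapse = ", "))
    variables <- variables[!constant]
  }
  rows <- list()
  for (i in seq_along(variables)) {
    v <- variables[i]
    d_v <- env_distance(meta, v)
    m1 <- mantel(b, d_v, n_perm = n_perm, seed = derive_seed(seed, 2L * i))
    others <- setdiff(variables, v)
    if (length(others)) {
      d_o <- env_distance(meta, others, normalize = TRUE)
      m2 <- partial_mantel(b, d_v, d_o, n_perm = n_perm,
                           seed = derive_seed(seed, 2L * i + 1L))
    } else m2 <- list(r = NA_real_, p_value = NA_real_)
    rows[[length(rows) + 1]] <-
      data.frame(variable = v, mantel_r = m1$r, mantel_p = m1$p_value,
                 adj_r = m2$r, adj_p = m2$p_value, stringsAsFactors = FALSE)
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' PCNM spatial eigenvectors
#'
#' Principal coordinates of neighbour matrices: the geographic distance
#' matrix is truncated (distances beyond the threshold, by default the
#' largest edge of the minimum spanning tree, are replaced by 4x the
#' threshold), double-centred and eigen-decomposed; the eigenvectors with
#' positive eigenvalues serve as spatial predictor variables from broad to
#' fine scale.
#'
#' @param geo symmetric geographic distance matrix (>= 3 samples)
#' @param threshold truncation distance; default the vegan MST rule
#' @return matrix of spatial eigenvectors (columns `PCNM1`, `PCNM2`, ...)
#'   ordered by decreasing eigenvalue, with eigenvalues in
#'   `attr(, "values")`
#' @export
pcnm <- function(geo, threshold = NULL) {
  g <- check_square(geo, "geographic distance")
  if (nrow(g) < 3) stop("PCNM needs >= 3 samples")
  res <- if (is.null(threshold)) vegan::pcnm(as.dist(g)) else
    vegan::pcnm(as.dist(g), threshold = threshold)
  vec <- res$vectors
  rownames(vec) <- rownames(g)
  attr(vec, "values") <- res$values[seq_len(ncol(vec))]
  vec
}

# Variance inflation factors from the correlation structure of X.
vif_values <- function(X) {
  vapply(seq_len(ncol(X)), function(j) {
    if (ncol(X) == 1) return(1)
    r2 <- summary(lm(X[, j] ~ X[, -j, drop = FALSE]))$r.squared
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, 0)
}

#' Collinearity and significance screening of environmental factors
#'
#' Two-step factor selection before Mantel / variation-partitioning
#' analyses: (1) iteratively drop the factor with the largest variance
#' inflation factor until all VIF are below `vif_threshold`; (2) keep only
#' factors whose vector fit onto the first two principal-coordinate axes of
#' the Bray-Curtis dissimilarity is significant by permutation (the
#' deterministic stand-in for NMDS-based vector fitting).
#'
#' @param table a `community_table`
#' @param meta metadata data.frame
#' @param factors candidate environment column names (>= 2)
#' @param vif_threshold VIF cutoff (default 10)
#' @param alpha significance cutoff for the vector fit (default 0.05)
#' @param n_perm permutations (default 999)
#' @param seed integer seed
#' @return character vector of retained factor names, with the screening
#'   table in `attr(, "screening")`
#' @export
select_factors <- function(table, meta, factors, vif_threshold = 10,
                           alpha = 0.05, n_perm = 999, seed = 1L) {
  if (length(factors) < 2) stop("need >= 2 candidate factors")
  X <- as.matrix(meta[, factors, drop = FALSE])
  if (any(!is.finite(X))) stop("factors contain missing values")
  kept <- factors
  repeat {
    v <- vif_values(X[, kept, drop = FALSE])
    if (all(v < vif_threshold) || length(kept) == 1) break
    kept <- kept[-which.max(v)]
  }
  # PCoA of Bray-Curtis, first two axes
  bc <- bray_curtis(table)
  axes <- stats::cmdscale(as.dist(bc), k = 2)
  n <- nrow(axes)
  fit_r2 <- function(y) summary(lm(y ~ axes))$r.squared
  scr <- lapply(seq_along(kept), function(i) {
    y <- X[, kept[i]]
    obs <- fit_r2(y)
    perm <- with_seed(derive_seed(seed, i), vapply(seq_len(n_perm),
      function(t) fit_r2(y[sample.int(n)]), 0))
    data.frame(factor = kept[i], r2 = obs,
               p_value = (1 + sum(perm >= obs)) / (1 + n_perm),
               stringsAsFactors = FALSE)
  })
  scr <- do.call(rbind, scr)
  retained <- scr$factor[scr$p_value < alpha]
  if (!length(retained))
    stop("no factor passed screening: consider relaxing vif_threshold/alpha")
  structure(retained, screening = scr)
}

#' Variation partitioning between two factor sets
#'
#' Redundancy analysis on Hellinger-transformed counts partitions the
#' community variance into the pure contributions of two explanatory sets
#' (e.g. physical vs nutrient factors), their shared portion, and the
#' residual, using Ezekiel-adjusted R^2:
#' pure_X1 = adjR2(X1 u X2) - adjR2(X2), shared = adjR2(X1) + adjR2(X2) -
#' adjR2(X1 u X2), residual = 1 - adjR2(X1 u X2). The shared fraction can
#' be negative (an adjusted-R^2 artifact) and is reported as-is.
#'
#' @param table a `community_table`
#' @param meta metadata data.frame
#' @param x1,x2 column names of the two explanatory sets
#' @param hellinger transform counts to Hellinger (default) or use raw
#'   proportions
#' @return object of class `vpa_result`: list with `fractions`
#'   (`pure_x1`, `pure_x2`, `shared`, `residual`) and `adj_r2` per
#'   component
#' @export
vpa <- function(table, meta, x1, x2, hellinger = TRUE) {
  m <- counts_matrix(table, "samples_by_taxa")
  n <- nrow(m)
  p_tot <- length(x1) + length(x2)
  if (n - p_tot < 3) stop("need >= 3 samples more than predictors")
  Y <- if (hellinger) sqrt(m / rowSums(m)) else m / rowSums(m)
  adj_r2 <- function(vars) {
    X <- as.matrix(meta[, vars, drop = FALSE])
    if (any(!is.finite(X))) stop("missing values in predictors")
    fit <- vegan::rda(Y ~ X)
    vegan::RsquareAdj(fit)$adj.r.squared
  }
  a1 <- adj_r2(x1)
  a2 <- adj_r2(x2)
  a12 <- adj_r2(c(x1, x2))
  structure(list(fractions = c(pure_x1 = a12 - a2, pure_x2 = a12 - a1,
                               shared = a1 + a2 - a12, residual = 1 - a12),
                 adj_r2 = c(x1 = a1, x2 = a2, combined = a12)),
            class = "vpa_result")
}

#' @export
print.vpa_result <- function(x, ...) {
  cat("vpa_result (adjusted R^2 fractions):\n")
  for (nm in names(x$fractions))
    cat(sprintf("  %-9s %7.4f\n", nm, x$fractions[nm]))
  invisible(x)
}
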