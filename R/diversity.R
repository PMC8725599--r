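#' Rarefy a community table to equal depth
#'
#' Subsamples each sample's counts without replacement to a common depth so
#' that diversity and null-model statistics are comparable across samples.
#'
#' @param table a `community_table`
#' @param depth target reads per sample; default is the minimum sample total
#' @param seed integer seed (subsampling is reproducible for a fixed seed)
#' @return a `community_table` in which every column sums to `depth`
#' @export
rarefy <- function(table, depth = min(colSums(table)), seed = 1L) {
  m <- unclass(table)
  totals <- colSums(m)
  if (depth <= 0) stop("depth must be positive")
  low <- totals < depth
  if (any(low))
    stop("depth ", depth, " exceeds total of sample ",
         colnames(m)[which(low)[1]], " (", totals[which(low)[1]], ")")
  out <- m
  for (j in seq_len(ncol(m))) {
    if (totals[j] == depth) next
    out[, j] <- with_seed(derive_seed(seed, j), {
      picked <- sample.int(totals[j], depth)
      tabulate(findInterval(picked - 1L, cumsum(m[, j]), left.open = FALSE) +
                 1L, nbins = nrow(m))
    })
  }
  keep_zero_ok <- community_table_keep(out)
  keep_zero_ok
}

# Internal constructor that keeps all-zero taxa (rarefaction may zero some
# taxa; dropping them here would silently desynchronise taxon sets between
# groups, so the caller decides).
community_table_keep <- function(m) {
  storage.mode(m) <- "integer"
  structure(m, class = c("community_table", "matrix", "array"))
}

#' Per-sample alpha diversity
#'
#' Richness (observed taxa), Chao1, Shannon's H (natural log) and the
#' Gini-Simpson index (1 - sum p^2).
#'
#' Chao1 uses the bias-corrected form S_obs + F1(F1-1)/(2(F2+1)), with F1
#' and F2 the within-sample singleton and doubleton counts.
#'
#' @param table a `community_table`
#' @return data.frame with columns `sample_id`, `richness`, `chao1`,
#'   `shannon_h`, `gini_simpson`
#' @export
alpha_diversity <- function(table) {
  m <- unclass(table)
  totals <- colSums(m)
  if (any(totals == 0))
    stop("empty sample: ", colnames(m)[which(totals == 0)[1]])
  res <- lapply(seq_len(ncol(m)), function(j) {
    x <- m[, j]
    x <- x[x > 0]
    p <- x / sum(x)
    f1 <- sum(x == 1); f2 <- sum(x == 2)
    data.frame(sample_id = colnames(m)[j],
               richness = length(x),
               chao1 = length(x) + f1 * (f1 - 1) / (2 * (f2 + 1)),
               shannon_h = -sum(p * log(p)),
               gini_simpson = 1 - sum(p^2),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Pairwise Bray-Curtis dissimilarity
#'
#' BC(j,k) = sum_i |x_ij - x_ik| / sum_i (x_ij + x_ik), computed on counts.
#' Community similarity is 1 - BC.
#'
#' @param table a `community_table` (>= 2 samples)
#' @return symmetric matrix of dissimilarities in `[0, 1]`; a pair of two
#'   all-zero samples is undefined and returned as `NA`
#' @export
bray_curtis <- function(table) {
  m <- counts_matrix(table, "samples_by_taxa")
  if (nrow(m) < 2) stop("Bray-Curtis needs >= 2 samples")
  empty <- rowSums(m) == 0
  d <- as.matrix(vegan::vegdist(m, method = "bray", na.rm = FALSE))
  if (any(empty)) {
    d[empty, empty] <- NA_real_
    warning(sum(empty), " all-zero sample(s): pairs flagged NA")
  }
  diag(d) <- 0
  d
}

#' Analysis of similarity (ANOSIM)
#'
#' Rank-based test of whether between-group dissimilarities exceed
#' within-group dissimilarities. R = (mean rank between - mean rank within)
#' / (M/2) with M = n(n-1)/2; the p-value is the permutation estimator
#' (1 + #{perm R >= observed R}) / (1 + n_perm).
#'
#' @param dist symmetric dissimilarity matrix over samples
#' @param groups group label per sample (>= 2 groups of >= 2 samples)
#' @param n_perm number of label permutations
#' @param seed integer seed
#' @return list with `statistic` (R) and `p_value`
#' @export
anosim <- function(dist, groups, n_perm = 999, seed = 1L) {
  d <- check_square(dist, "dissimilarity")
  groups <- as.factor(groups)
  if (length(groups) != nrow(d)) stop("groups length != matrix dimension")
  if (nlevels(droplevels(groups)) < 2) stop("need >= 2 groups")
  if (any(table(groups) < 2)) stop("every group needs >= 2 samples")
  n <- nrow(d)
  rk <- vec_to_sym(rank(upper_tri_vec(d)), seq_len(n))
  m_half <- (n * (n - 1) / 2) / 2
  r_stat <- function(g) {
    same <- outer(g, g, "==")
    within <- rk[upper.tri(rk) & same]
    between <- rk[upper.tri(rk) & !same]
    (mean(between) - mean(within)) / m_half
  }
  obs <- r_stat(groups)
  perm <- with_seed(seed, vapply(seq_len(n_perm), function(i)
    r_stat(sample(groups)), 0))
  list(statistic = obs,
       p_value = (1 + sum(perm >= obs)) / (1 + n_perm))
}

#' Great-circle distance between samples
#'
#' Haversine formula on a sphere of mean Earth radius 6371.0088 km.
#'
#' @param meta metadata data.frame with `sample_id`, `latitude`, `longitude`
#' @return symmetric matrix of distances in km
#' @export
geographic_distance <- function(meta) {
  meta <- validate_metadata(meta)
  lat <- meta$latitude * pi / 180
  lon <- meta$longitude * pi / 180
  n <- length(lat)
  r_earth <- 6371.0088
  dlat <- outer(lat, lat, "-") / 2
  dlon <- outer(lon, lon, "-") / 2
  a <- sin(dlat)^2 + outer(cos(lat), cos(lat)) * sin(dlon)^2
  a <- pmin(pmax(a, 0), 1)
  d <- 2 * r_earth * asin(sqrt(a))
  dimnames(d) <- list(meta$sample_id, meta$sample_id)
  diag(d) <- 0
  d
}

#' Distance-decay regression
#'
#' Ordinary least-squares regression of pairwise community similarity on
#' geographic distance. Because pairs sharing a sample are not independent,
#' significance is assessed by Mantel-style permutation of one matrix
#' (999 permutations); the parametric OLS p-value is reported alongside.
#'
#' @param similarity symmetric similarity matrix (1 - dissimilarity)
#' @param geo symmetric geographic distance matrix (km), same samples
#' @param n_perm permutations for the Mantel-style p-value
#' @param seed integer seed
#' @return list with `slope` (per km), `intercept`, `r`, `p_value`
#'   (permutation), `p_parametric`, `n_pairs`, and `slope_percent`
#'   (similarity expressed in percent)
#' @export
distance_decay <- function(similarity, geo, n_perm = 999, seed = 1L) {
  s <- check_square(similarity, "similarity")
  g <- check_square(geo, "geographic distance")
  if (!identical(dim(s), dim(g))) stop("matrices differ in dimension")
  y <- upper_tri_vec(s)
  x <- upper_tri_vec(g)
  ok <- is.finite(y) & is.finite(x)
  if (sum(ok) < 3) stop("need >= 3 finite pairs")
  fit <- lm(y[ok] ~ x[ok])
  r_obs <- suppressWarnings(cor(x[ok], y[ok]))
  n <- nrow(s)
  perm_r <- with_seed(seed, vapply(seq_len(n_perm), function(i) {
    p <- sample.int(n)
    yp <- upper_tri_vec(s[p, p])
    suppressWarnings(cor(x[ok], yp[ok]))
  }, 0))
  p_perm <- (1 + sum(abs(perm_r) >= abs(r_obs))) / (1 + n_perm)
  list(slope = unname(coef(fit)[2]),
       intercept = unname(coef(fit)[1]),
       r = r_obs,
       p_value = p_perm,
       p_parametric = summary(fit)$coefficients[2, 4],
       n_pairs = sum(ok),
       slope_percent = unname(coef(fit)[2]) * 100)
}

#' Assign a climatic zone from latitude
#'
#' Tropic for |lat| <= 23.5 degrees, subtropic for 23.5 < |lat| <= 40, and
#' subarctic for lat > 40 degrees N. Latitudes south of 40 degrees S fall
#' outside the sampled design and are rejected.
#'
#' @param latitude degrees, in `[-90, 90]`
#' @return one of `"tropic"`, `"subtropic"`, `"subarctic"`
#' @export
assign_zone <- function(latitude) {
  if (!is.finite(latitude) || abs(latitude) > 90)
    stop("latitude out of range: ", latitude)
  if (latitude < -40)
    stop("latitude ", latitude, " is south of the sampled design (-40)")
  if (abs(latitude) <= 23.5) "tropic"
  else if (abs(latitude) <= 40) "subtropic"
  else "subarctic"
}
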