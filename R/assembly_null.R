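#' Beta mean-nearest-taxon distance (betaMNTD)
#'
#' For each pair of samples, the mean patristic distance from every taxon in
#' one sample to its phylogenetically closest taxon in the other, averaged
#' over both directions. With `abundance_weighted = TRUE` (the default) each
#' taxon's nearest-neighbour distance is weighted by its within-sample
#' relative abundance. A taxon present in both samples matches itself at
#' distance zero.
#'
#' @param table a `community_table`; every taxon with a nonzero count must
#'   be a tip of `tree`
#' @param tree rooted `phylo` with branch lengths
#' @param abundance_weighted weight by relative abundance (default) or give
#'   every present taxon equal weight
#' @return symmetric matrix of betaMNTD values over samples
#' @export
beta_mntd <- function(table, tree, abundance_weighted = TRUE) {
  prep <- beta_mntd_prepare(table, tree)
  bm <- betamntd_cpp(prep$D, prep$W, abundance_weighted)
  dimnames(bm) <- list(colnames(table), colnames(table))
  bm
}

# Shared validation and matrix preparation for beta_mntd / bnti.
beta_mntd_prepare <- function(table, tree) {
  m <- unclass(table)
  totals <- colSums(m)
  if (any(totals == 0))
    stop("sample with zero total: ", colnames(m)[which(totals == 0)[1]])
  keep <- rowSums(m) > 0
  m <- m[keep, , drop = FALSE]
  al <- align_taxa(community_table_keep(m), tree)
  D <- patristic_distance(al$tree)
  D <- D[rownames(m), rownames(m)]
  W <- sweep(m, 2, totals, "/")
  list(D = D, W = W)
}

#' Beta nearest-taxon index (betaNTI) null model
#'
#' Standardised effect size of [beta_mntd()] against a null model that
#' shuffles taxon identities across the tips of the pool-pruned tree while
#' holding the community matrix fixed ("taxa labels" randomisation). For
#' each pair, betaNTI = (observed - null mean) / null sd. |betaNTI| > 2
#' indicates dominance of selection: above +2 heterogeneous selection (more
#' phylogenetic turnover than expected), below -2 homogeneous selection.
#'
#' Pairs whose null standard deviation is zero (e.g. a star tree with equal
#' branch lengths) are flagged as degenerate (`NA`) and excluded from the
#' process partition with a warning.
#'
#' @param table a `community_table`: the pool of samples analysed together
#' @param tree rooted `phylo` with branch lengths
#' @param n_null number of randomisations (default 999)
#' @param seed integer seed
#' @param abundance_weighted see [beta_mntd()]
#' @param prune_tree shuffle across the pool's taxa only (default) or across
#'   all tips of the supplied tree
#' @return object of class `bnti_result`: list with `observed`,
#'   `null_mean`, `null_sd`, `bnti` (all symmetric matrices), `n_null`,
#'   `seed`
#' @export
bnti <- function(table, tree, n_null = 999, seed = 1L,
                 abundance_weighted = TRUE, prune_tree = TRUE) {
  if (ncol(table) < 2) stop("need >= 2 samples in the analysis pool")
  prep <- beta_mntd_prepare(table, tree)
  D <- prep$D
  W <- prep$W
  if (!prune_tree) {
    # shuffle across the full tip set: embed the pool's taxa in the full
    # patristic matrix and permute over all tips
    Dfull <- patristic_distance(tree)
    idx <- match(rownames(D), rownames(Dfull))
    ntip <- nrow(Dfull)
    perms <- with_seed(seed, vapply(seq_len(n_null), function(t)
      sample.int(ntip)[idx], integer(length(idx))))
    # remap: permuted positions index Dfull
    null <- betamntd_null_cpp(Dfull, W_embed(W, ntip, idx), abundance_weighted,
                              perms_embed(perms, ntip, idx))
  } else {
    ntaxa <- nrow(D)
    perms <- with_seed(seed, vapply(seq_len(n_null), function(t)
      sample.int(ntaxa), integer(ntaxa)))
    null <- betamntd_null_cpp(D, W, abundance_weighted, perms)
  }
  obs <- betamntd_cpp(D, W, abundance_weighted)
  ids <- colnames(table)
  dimnames(obs) <- dimnames(null$mean) <- dimnames(null$sd) <-
    list(ids, ids)
  sdm <- null$sd
  degen <- upper.tri(sdm) & sdm <= 0
  b <- (obs - null$mean) / ifelse(sdm > 0, sdm, NA_real_)
  diag(b) <- NA_real_
  if (any(degen))
    warning(sum(degen), " pair(s) with zero null sd flagged degenerate")
  structure(list(observed = obs, null_mean = null$mean, null_sd = sdm,
                 bnti = b, n_null = n_null, seed = seed),
            class = "bnti_result")
}

# Helpers for full-tree randomisation: place the pool's community rows into
# the full tip space so tip shuffles can land on out-of-pool tips.
W_embed <- function(W, ntip, idx) {
  We <- matrix(0, ntip, ncol(W))
  We[idx, ] <- W
  We
}
perms_embed <- function(perms, ntip, idx) {
  # betamntd_null_cpp permutes all ntip rows; rows outside the pool have
  # zero abundance so only the pool rows' destinations matter
  out <- matrix(seq_len(ntip), ntip, ncol(perms))
  out[idx, ] <- perms
  out
}

#' @export
print.bnti_result <- function(x, ...) {
  v <- upper_tri_vec(x$bnti)
  cat("bnti_result: ", nrow(x$bnti), " samples, ", sum(is.finite(v)),
      " pairs (", sum(!is.finite(v)), " degenerate), ", x$n_null,
      " randomizations\n", sep = "")
  cat("  betaNTI range: ", paste(signif(range(v, na.rm = TRUE), 4),
                                 collapse = " .. "), "\n", sep = "")
  invisible(x)
}

#' Raup-Crick metric on Bray-Curtis dissimilarity (RC-Bray)
#'
#' Compares each pair's observed Bray-Curtis dissimilarity with a null
#' distribution generated by probabilistic community assembly from the
#' pool: each null community draws the sample's observed richness (taxa
#' selected with probability proportional to pool occupancy), seeds each
#' drawn taxon with one individual, and distributes the remaining observed
#' individuals with probability proportional to pool-wide relative
#' abundance. RC = 2 * (RC_raw - 0.5), with ties counted at half weight, so
#' values lie in `[-1, 1]`; above +0.95 indicates dispersal limitation,
#' below -0.95 homogenizing dispersal, between them drift.
#'
#' Null draws are generated per sample (streams derived from `seed` and the
#' sample index) and shared across the pairs involving that sample, so the
#' result is independent of pair evaluation order.
#'
#' @param table a `community_table`: the pool of samples analysed together
#' @param n_null number of null assemblies per pair (default 9999)
#' @param seed integer seed
#' @return object of class `rc_bray_result`: list with `rc` (symmetric
#'   matrix in `[-1, 1]`), `n_null`, `seed`
#' @export
rc_bray <- function(table, n_null = 9999, seed = 1L) {
  m <- unclass(table)
  if (ncol(m) < 2) stop("need >= 2 samples")
  m <- m[rowSums(m) > 0, , drop = FALSE]
  ntaxa <- nrow(m)
  if (ntaxa < 2) stop("pool has fewer than 2 taxa")
  nsamp <- ncol(m)
  occ <- rowSums(m > 0)
  pool_p <- rowSums(m) / sum(m)
  richness <- colSums(m > 0)
  totals <- colSums(m)
  if (any(richness == 0)) stop("empty sample in pool")

  # per-sample null abundance matrices (ntaxa x n_null)
  nulls <- lapply(seq_len(nsamp), function(s) {
    with_seed(derive_seed(seed, s), {
      out <- matrix(0L, ntaxa, n_null)
      for (t in seq_len(n_null)) {
        drawn <- sample.int(ntaxa, richness[s], prob = occ)
        x <- integer(ntaxa)
        x[drawn] <- 1L
        extra <- totals[s] - richness[s]
        if (extra > 0)
          x[drawn] <- x[drawn] +
            as.integer(rmultinom(1, extra, pool_p[drawn]))
        out[, t] <- x
      }
      out
    })
  })

  obs_bc <- as.matrix(vegan::vegdist(t(m), method = "bray"))
  rc <- matrix(NA_real_, nsamp, nsamp,
               dimnames = list(colnames(m), colnames(m)))
  for (j in seq_len(nsamp - 1)) {
    Xj <- nulls[[j]]
    for (k in (j + 1):nsamp) {
      Xk <- nulls[[k]]
      null_bc <- colSums(abs(Xj - Xk)) / colSums(Xj + Xk)
      obs <- obs_bc[j, k]
      less <- sum(null_bc < obs - 1e-12)
      ties <- sum(abs(null_bc - obs) <= 1e-12)
      rc[j, k] <- rc[k, j] <- 2 * ((less + 0.5 * ties) / n_null - 0.5)
    }
  }
  diag(rc) <- NA_real_
  structure(list(rc = rc, n_null = n_null, seed = seed),
            class = "rc_bray_result")
}

#' @export
print.rc_bray_result <- function(x, ...) {
  v <- upper_tri_vec(x$rc)
  cat("rc_bray_result: ", nrow(x$rc), " samples, ", length(v), " pairs, ",
      x$n_null, " null assemblies\n  RC range: ",
      paste(signif(range(v, na.rm = TRUE), 4), collapse = " .. "),
      "\n", sep = "")
  invisible(x)
}

PROCESS_LEVELS <- c("heterogeneous_selection", "homogeneous_selection",
                    "dispersal_limitation", "homogenizing_dispersal",
                    "drift")

#' Classify one sample pair into an ecological process
#'
#' betaNTI > 2: heterogeneous selection; betaNTI < -2: homogeneous
#' selection; otherwise RC-Bray > 0.95: dispersal limitation; RC-Bray <
#' -0.95: homogenizing dispersal; else drift.
#'
#' @param bnti_value betaNTI for the pair
#' @param rc_value RC-Bray for the pair
#' @return process name (character)
#' @export
classify_pair <- function(bnti_value, rc_value) {
  if (!is.finite(bnti_value)) return(NA_character_)
  if (bnti_value > 2) return("heterogeneous_selection")
  if (bnti_value < -2) return("homogeneous_selection")
  if (!is.finite(rc_value)) return(NA_character_)
  if (rc_value > 0.95) return("dispersal_limitation")
  if (rc_value < -0.95) return("homogenizing_dispersal")
  "drift"
}

#' Partition sample pairs among ecological processes
#'
#' Applies the two-step betaNTI / RC-Bray decision rule to every sample
#' pair and reports the fraction attributed to each process. The five rules
#' are exhaustive and mutually exclusive, so fractions sum to one exactly
#' (as counts over pairs). Degenerate pairs (missing betaNTI or RC value)
#' are excluded with a warning and reported in `n_excluded`.
#'
#' @param bnti betaNTI matrix or a [bnti()] result
#' @param rc RC-Bray matrix or an [rc_bray()] result
#' @param group_id label attached to the output (default `"all"`)
#' @return object of class `process_partition`: list with `group_id`,
#'   `n_pairs`, `n_excluded`, `fractions` (named, sums to 1), `counts`
#' @export
partition_processes <- function(bnti, rc, group_id = "all") {
  b <- if (inherits(bnti, "bnti_result")) bnti$bnti else
    check_square(bnti, "bnti")
  r <- if (inherits(rc, "rc_bray_result")) rc$rc else check_square(rc, "rc")
  if (!identical(dim(b), dim(r)))
    stop("betaNTI and RC matrices differ in dimension")
  bv <- upper_tri_vec(b)
  rv <- upper_tri_vec(r)
  if (!length(bv)) stop("no sample pairs")
  cls <- mapply(classify_pair, bv, rv)
  excluded <- sum(is.na(cls))
  if (excluded > 0)
    warning(excluded, " degenerate pair(s) excluded from partition")
  cls <- cls[!is.na(cls)]
  if (!length(cls)) stop("all pairs degenerate")
  counts <- table(factor(cls, levels = PROCESS_LEVELS))
  structure(list(group_id = group_id,
                 n_pairs = length(cls),
                 n_excluded = excluded,
                 fractions = as.numeric(counts) / length(cls),
                 counts = as.integer(counts)),
            class = "process_partition")
}

#' @export
print.process_partition <- function(x, ...) {
  cat("process_partition [", x$group_id, "]: ", x$n_pairs, " pairs\n",
      sep = "")
  for (i in seq_along(PROCESS_LEVELS))
    cat(sprintf("  %-24s %6.2f%%\n", PROCESS_LEVELS[i],
                100 * x$fractions[i]))
  invisible(x)
}

#' Convert a process partition to a long data.frame
#'
#' @param x a `process_partition`
#' @param ... unused
#' @return data.frame with columns `group`, `process`, `fraction`, `n_pairs`
#' @export
as.data.frame.process_partition <- function(x, ...) {
  data.frame(group = x$group_id, process = PROCESS_LEVELS,
             fraction = x$fractions, n_pairs = x$n_pairs,
             stringsAsFactors = FALSE)
}

#' Phylogenetic signal in niche optima (Mantel correlogram)
#'
#' Tests the premise of phylogenetic-turnover inference: that ecologically
#' similar taxa are phylogenetically related, at least at short phylogenetic
#' distances. Each taxon's niche optimum per environmental variable is its
#' abundance-weighted mean of that variable across samples; niche distance
#' is the Euclidean distance over standardised optima. A Mantel correlogram
#' relates niche distance to patristic distance over `n_classes` equal-width
#' distance classes with permutation tests and progressive Holm correction.
#'
#' @param table a `community_table`
#' @param tree rooted `phylo` with branch lengths
#' @param env data.frame of environmental variables (rows = samples in
#'   table column order) or sample metadata containing those columns
#' @param variables character vector naming the environment columns to use
#' @param n_classes number of equal-width phylogenetic distance classes
#' @param n_perm permutations per class (default 999)
#' @param seed integer seed
#' @return data.frame with one row per class: `class_midpoint`, `n_pairs`,
#'   `mantel_r`, `p_value`, `p_corrected`
#' @export
phylo_signal <- function(table, tree, env, variables = NULL, n_classes = 8,
                         n_perm = 999, seed = 1L) {
  m <- unclass(table)
  if (is.null(variables))
    variables <- names(env)[vapply(env, is.numeric, TRUE) &
                              !names(env) %in% c("latitude", "longitude")]
  E <- as.matrix(env[, variables, drop = FALSE])
  if (nrow(E) != ncol(m)) stop("env rows must match table samples")
  if (any(!is.finite(E))) stop("env variables must be complete")

  keep <- rowSums(m > 0) >= 2
  if (any(!keep))
    warning(sum(!keep), " taxa present in <2 samples excluded from ",
            "phylogenetic-signal test")
  m <- m[keep, , drop = FALSE]
  if (nrow(m) < 4) stop("too few taxa for a correlogram")

  # abundance-weighted niche optimum per taxon per variable
  w <- m / rowSums(m)
  optima <- w %*% E
  optima <- scale(optima)
  optima[, !is.finite(colSums(optima))] <- 0   # constant variable guard

  d_niche <- as.matrix(dist(optima))
  al <- align_taxa(community_table_keep(m), tree)
  d_phylo <- patristic_distance(al$tree)[rownames(m), rownames(m)]

  pv <- upper_tri_vec(d_phylo)
  breaks <- seq(min(pv), max(pv), length.out = n_classes + 1)
  mids <- (breaks[-1] + breaks[-(n_classes + 1)]) / 2
  nv <- upper_tri_vec(d_niche)
  cls <- findInterval(pv, breaks, rightmost.closed = TRUE,
                      all.inside = TRUE)

  n <- nrow(m)
  # normalized Mantel r between niche distance and class membership,
  # negated so positive r = similar niches within the class
  class_r <- function(niche_vec, member) {
    if (sd(member) == 0) return(NA_real_)
    -suppressWarnings(cor(niche_vec, member))
  }
  res <- data.frame(class_midpoint = mids, n_pairs = tabulate(cls, n_classes),
                    mantel_r = NA_real_, p_value = NA_real_,
                    p_corrected = NA_real_)
  perm_nv <- with_seed(derive_seed(seed, 0L),
                       lapply(seq_len(n_perm), function(i) {
                         p <- sample.int(n)
                         upper_tri_vec(d_niche[p, p])
                       }))
  for (c_i in seq_len(n_classes)) {
    member <- as.numeric(cls == c_i)
    if (res$n_pairs[c_i] == 0 || sd(member) == 0) next
    obs <- class_r(nv, member)
    perm <- vapply(perm_nv, function(v) class_r(v, member), 0)
    res$mantel_r[c_i] <- obs
    res$p_value[c_i] <- (1 + sum(abs(perm) >= abs(obs))) / (1 + n_perm)
  }
  # progressive Holm correction in order of increasing distance
  done <- which(is.finite(res$p_value))
  for (i in seq_along(done))
    res$p_corrected[done[i]] <-
      stats::p.adjust(res$p_value[done[seq_len(i)]], "holm")[i]
  attr(res, "n_perm") <- n_perm
  res
}
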