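#' Levins' niche breadth per taxon
#'
#' B_j = 1 / sum_i P_ij^2, where P_ij is the proportion of taxon j's total
#' abundance found in community i (taxon-normalised: P_ij sums to one over
#' communities). B_j ranges from 1 (all abundance in a single community) to
#' N, the number of communities, attained exactly at the uniform spread.
#' High B marks habitat generalists, low B specialists.
#'
#' @param table a `community_table` (the metacommunity / group of samples)
#' @return data.frame with columns `taxon_id`, `b`; zero-total taxa are
#'   excluded with a warning
#' @export
levins_b <- function(table) {
  m <- unclass(table)
  tot <- rowSums(m)
  if (any(tot == 0)) {
    warning(sum(tot == 0), " zero-total taxa excluded from niche breadth")
    m <- m[tot > 0, , drop = FALSE]
    tot <- tot[tot > 0]
  }
  P <- m / tot
  data.frame(taxon_id = rownames(m), b = 1 / rowSums(P^2),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Community-level niche breadth
#'
#' B_com for a sample is the unweighted mean of Levins' B over the taxa
#' present (count > 0) in that sample; with `weighted = TRUE`, the mean is
#' weighted by within-sample relative abundance (sensitivity variant).
#'
#' @param b data.frame from [levins_b()], computed on the same group
#' @param table the `community_table` the breadths were computed on
#' @param weighted abundance-weighted mean instead of the unweighted default
#' @return data.frame with columns `sample_id`, `b_com`, `n_taxa`
#' @export
community_niche_breadth <- function(b, table, weighted = FALSE) {
  m <- unclass(table)
  bj <- setNames(b$b, b$taxon_id)
  res <- lapply(seq_len(ncol(m)), function(j) {
    present <- rownames(m)[m[, j] > 0]
    present <- intersect(present, names(bj))
    if (!length(present)) stop("empty sample: ", colnames(m)[j])
    w <- if (weighted) m[present, j] / sum(m[present, j]) else
      rep(1 / length(present), length(present))
    data.frame(sample_id = colnames(m)[j],
               b_com = sum(w * bj[present]),
               n_taxa = length(present), stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}
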