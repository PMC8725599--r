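#' Construct a community table
#'
#' The central container of the package: an integer abundance matrix with
#' taxa as rows and samples as columns, as produced by amplicon pipelines
#' after OTU clustering. All downstream analyses (diversity, null models,
#' neutral-model fitting, niche breadth) consume this object.
#'
#' All-zero taxa are dropped with a warning during validation: they carry no
#' information and break relative-abundance arithmetic.
#'
#' @param counts numeric matrix of non-negative integers, taxa x samples.
#'   Row names are taxon IDs, column names are sample IDs (both required
#'   unless supplied via `taxon_ids` / `sample_ids`).
#' @param taxon_ids,sample_ids optional character vectors overriding the
#'   dimnames of `counts`.
#' @return an object of class `community_table`: the validated integer
#'   matrix with `taxon_ids` as rownames and `sample_ids` as colnames.
#' @export
community_table <- function(counts, taxon_ids = rownames(counts),
                            sample_ids = colnames(counts)) {
  counts <- as.matrix(counts)
  if (is.null(taxon_ids) || is.null(sample_ids))
    stop("community_table requires taxon and sample IDs")
  if (length(taxon_ids) != nrow(counts) || length(sample_ids) != ncol(counts))
    stop("ID lengths do not match the counts matrix")
  if (anyDuplicated(taxon_ids))
    stop("duplicate taxon ID: ",
         paste(unique(taxon_ids[duplicated(taxon_ids)]), collapse = ", "))
  if (anyDuplicated(sample_ids))
    stop("duplicate sample ID: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  if (any(!is.finite(counts)))
    stop("non-finite count at [",
         paste(which(!is.finite(counts), arr.ind = TRUE)[1, ],
               collapse = ", "), "]")
  if (any(counts < 0)) {
    bad <- which(counts < 0, arr.ind = TRUE)[1, ]
    stop("negative count for taxon '", taxon_ids[bad[1]], "', sample '",
         sample_ids[bad[2]], "'")
  }
  if (any(abs(counts - round(counts)) > 1e-8)) {
    bad <- which(abs(counts - round(counts)) > 1e-8, arr.ind = TRUE)[1, ]
    stop("non-integer count for taxon '", taxon_ids[bad[1]], "', sample '",
         sample_ids[bad[2]], "'")
  }
  storage.mode(counts) <- "integer"
  dimnames(counts) <- list(taxon_ids, sample_ids)
  zero <- rowSums(counts) == 0
  if (any(zero)) {
    warning("dropping ", sum(zero), " all-zero taxa")
    counts <- counts[!zero, , drop = FALSE]
  }
  structure(counts, class = c("community_table", "matrix", "array"))
}

#' @export
print.community_table <- function(x, ...) {
  cat("community_table: ", nrow(x), " taxa x ", ncol(x), " samples; ",
      "sample totals ", min(colSums(x)), "-", max(colSums(x)), "\n", sep = "")
  invisible(x)
}

#' Extract the counts matrix in either orientation
#'
#' @param table a `community_table`
#' @param orientation `"taxa_by_samples"` (storage order) or
#'   `"samples_by_taxa"` (the orientation vegan-style functions expect)
#' @return integer matrix
#' @export
counts_matrix <- function(table,
                          orientation = c("taxa_by_samples",
                                          "samples_by_taxa")) {
  orientation <- match.arg(orientation)
  m <- unclass(table)
  if (orientation == "samples_by_taxa") t(m) else m
}

#' Read an OTU table from TSV
#'
#' Expects a header row (first column the OTU ID, remaining columns sample
#' IDs) and tab-separated integer counts, the common export format of
#' amplicon pipelines.
#'
#' @param path path to a tab-delimited text file
#' @return a [community_table()]
#' @export
read_community_table <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                   comment.char = "", stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("OTU table needs an ID column plus >=1 sample")
  ids <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) stop("non-numeric counts in ", path)
  rownames(m) <- ids
  community_table(m)
}

#' Write an OTU table as TSV
#'
#' Round-trips exactly through [read_community_table()].
#'
#' @param table a `community_table`
#' @param path output path
#' @export
write_community_table <- function(table, path) {
  df <- data.frame(`#OTU_ID` = rownames(table), unclass(table),
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a rooted phylogenetic tree from Newick
#'
#' Wraps [ape::read.tree()] with the validation the downstream null models
#' require: labelled tips and non-negative branch lengths.
#'
#' @param path path to a Newick file
#' @return an [ape::phylo] object
#' @export
read_tree <- function(path) {
  tree <- ape::read.tree(path)
  if (is.null(tree)) stop("could not parse Newick file ", path)
  validate_tree(tree)
  tree
}

validate_tree <- function(tree) {
  if (!inherits(tree, "phylo")) stop("not a phylo object")
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  if (any(tree$edge.length < 0)) stop("negative branch lengths in tree")
  if (is.null(tree$tip.label) || any(!nzchar(tree$tip.label)))
    stop("tree has unlabeled tips")
  if (anyDuplicated(tree$tip.label)) stop("duplicate tip labels in tree")
  invisible(tree)
}

#' Patristic distances between tips
#'
#' @param tree a rooted `phylo` with branch lengths
#' @return symmetric matrix of tip-to-tip path-length distances
#' @export
patristic_distance <- function(tree) {
  validate_tree(tree)
  if (length(tree$tip.label) == 2) {
    # ape::cophenetic.phylo chokes on 2-tip trees
    d <- sum(tree$edge.length[tree$edge[, 2] <= 2])
    m <- matrix(c(0, d, d, 0), 2, 2,
                dimnames = list(tree$tip.label, tree$tip.label))
    return(m)
  }
  ape::cophenetic.phylo(tree)
}

#' Align a community table with a tree
#'
#' Every taxon analysed phylogenetically must match exactly one tip. Tips
#' absent from the table are pruned; taxa absent from the tree are an error.
#'
#' @param table a `community_table`
#' @param tree a `phylo`
#' @return list with the table (unchanged) and the pruned tree
#' @export
align_taxa <- function(table, tree) {
  missing <- setdiff(rownames(table), tree$tip.label)
  if (length(missing))
    stop("taxa missing from tree: ", paste(missing, collapse = ", "))
  extra <- setdiff(tree$tip.label, rownames(table))
  if (length(extra)) tree <- ape::drop.tip(tree, extra)
  list(table = table, tree = tree)
}

#' Remove singleton taxa
#'
#' Drops taxa whose total count across all samples equals one, the standard
#' hygiene step after OTU clustering (singletons are mostly sequencing
#' error). Taxon order is otherwise preserved.
#'
#' @param table a `community_table`
#' @return a `community_table` without singleton (or all-zero) taxa
#' @export
remove_singletons <- function(table) {
  keep <- rowSums(table) > 1
  community_table(unclass(table)[keep, , drop = FALSE])
}

#' Per-taxon occupancy and mean relative abundance
#'
#' Occupancy is the fraction of samples in which a taxon is detected
#' (count > 0); mean relative abundance is averaged over samples.
#'
#' @param table a `community_table`
#' @return data.frame with columns `taxon_id`, `occupancy`,
#'   `mean_rel_abund`
#' @export
occupancy <- function(table) {
  m <- unclass(table)
  if (ncol(m) < 1) stop("occupancy needs at least one sample")
  totals <- colSums(m)
  if (any(totals == 0)) stop("empty sample: ",
                             colnames(m)[which(totals == 0)[1]])
  rel <- sweep(m, 2, totals, "/")
  data.frame(taxon_id = rownames(m),
             occupancy = rowMeans(m > 0),
             mean_rel_abund = rowMeans(rel),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Read sample metadata from CSV
#'
#' Mandatory columns: `sample_id`, `latitude`, `longitude`, `layer`. A
#' `zone` column is derived from latitude via [assign_zone()] when absent.
#' Any further numeric columns are treated as environmental variables;
#' missing values are allowed and propagate as "sample excluded from
#' analyses requiring that variable".
#'
#' @param path path to a CSV file
#' @return data.frame with one row per sample
#' @export
read_sample_metadata <- function(path) {
  df <- read.table(path, header = TRUE, sep = ",", stringsAsFactors = FALSE)
  validate_metadata(df)
}

#' Validate a sample metadata frame
#'
#' Checks the mandatory columns, coordinate ranges and layer levels, and
#' derives the `zone` column from latitude when absent.
#'
#' @param df metadata data.frame
#' @return the validated (possibly zone-augmented) data.frame
#' @export
validate_metadata <- function(df) {
  need <- c("sample_id", "latitude", "longitude", "layer")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("metadata missing mandatory columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample_id in metadata")
  if (any(abs(df$latitude) > 90, na.rm = TRUE) ||
      any(abs(df$longitude) > 180, na.rm = TRUE))
    stop("latitude/longitude out of range")
  if (!all(df$layer %in% c("surface", "DCM")))
    stop("layer must be 'surface' or 'DCM'")
  if (is.null(df$zone)) df$zone <- vapply(df$latitude, assign_zone, "")
  df
}

#' Write sample metadata as CSV
#'
#' Reals are written with 6 significant digits.
#'
#' @param meta metadata data.frame
#' @param path output path
#' @export
write_sample_metadata <- function(meta, path) {
  out <- meta
  num <- vapply(out, is.numeric, TRUE)
  out[num] <- lapply(out[num], signif, digits = 6)
  write.table(out, path, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Extract the upper-triangle (j < k) of a symmetric matrix as a vector,
# in a fixed column-major order shared by all Mantel-style routines.
upper_tri_vec <- function(m) m[upper.tri(m)]

# Rebuild a symmetric matrix from an upper-triangle vector.
vec_to_sym <- function(v, ids, diag = 0) {
  n <- length(ids)
  m <- matrix(diag, n, n, dimnames = list(ids, ids))
  m[upper.tri(m)] <- v
  m[lower.tri(m)] <- t(m)[lower.tri(m)]
  m
}

check_square <- function(d, name = "matrix") {
  d <- as.matrix(d)
  if (nrow(d) != ncol(d)) stop(name, " is not square")
  if (max(abs(d - t(d)), na.rm = TRUE) > 1e-8)
    stop(name, " is not symmetric")
  d
}
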