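#' Read a flat key-value run configuration
#'
#' Minimal YAML-style `key: value` format, one pair per line; `#` starts a
#' comment; comma-separated values become vectors. Recognised keys are the
#' arguments of [run_pipeline()].
#'
#' @param path path to the configuration file
#' @return named list
#' @export
read_run_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  cfg <- list()
  for (ln in lines) {
    kv <- regmatches(ln, regexec("^([A-Za-z0-9_]+) *: *(.*)$", ln))[[1]]
    if (length(kv) != 3) stop("cannot parse config line: ", ln)
    val <- trimws(strsplit(kv[3], ",")[[1]])
    num <- suppressWarnings(as.numeric(val))
    if (!anyNA(num)) val <- num
    cfg[[kv[2]]] <- val
  }
  cfg
}

#' Run the full community-assembly analysis pipeline
#'
#' Orchestrates rarefaction, alpha/beta diversity, ANOSIM, distance decay,
#' the phylogenetic-signal test, the betaNTI and RC-Bray null models with
#' the five-way process partition per sample group, the neutral community
#' model and niche-breadth statistics per group, and (when factor sets are
#' supplied) the betaNTI-environment Mantel table, environmental
#' heterogeneity and variation partitioning. Writes one CSV per stage plus
#' a JSON manifest to `out_dir`. Output is a pure function of (inputs,
#' parameters, seed).
#'
#' Grouping: `"layer"` stratifies the basin-scale analysis by depth layer;
#' `"zone"` groups by climatic zone with layers combined; `"all"` pools
#' every sample; any other value names a metadata column.
#'
#' @param table_path,tree_path,meta_path input file paths (TSV OTU table,
#'   Newick tree, CSV metadata)
#' @param out_dir output directory
#' @param group_by `"layer"`, `"zone"`, `"all"`, or a metadata column
#' @param rarefy_depth `"auto"` (minimum sample total) or an integer
#' @param n_null betaNTI randomisations (default 999)
#' @param n_rc RC-Bray null assemblies (default 9999)
#' @param physical,nutrient optional character vectors of environment
#'   columns for the Mantel table / heterogeneity / VPA stage
#' @param n_classes phylogenetic-signal distance classes (default 8)
#' @param seed integer seed
#' @return invisibly, the manifest list
#' @export
run_pipeline <- function(table_path, tree_path, meta_path, out_dir,
                         group_by = "zone", rarefy_depth = "auto",
                         n_null = 999, n_rc = 9999, physical = NULL,
                         nutrient = NULL, n_classes = 8, seed = 1L) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- "read_inputs"
  manifest <- list(seed = seed, stages = character(), groups = list())
  on.exit({
    if (!identical(stage, "done"))
      writeLines(stage, file.path(out_dir, ".partial"))
  })
  wrap <- function(s, expr) {
    stage <<- s
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", s, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  table <- wrap("read_inputs", read_community_table(table_path))
  tree <- wrap("read_inputs", read_tree(tree_path))
  meta <- wrap("read_inputs", read_sample_metadata(meta_path))
  meta <- meta[match(colnames(table), meta$sample_id), ]
  if (anyNA(meta$sample_id)) stop("metadata missing samples from table")

  table <- wrap("singletons", remove_singletons(table))
  depth <- if (identical(rarefy_depth, "auto")) min(colSums(table)) else
    as.integer(rarefy_depth)
  table <- wrap("rarefy", rarefy(table, depth = depth,
                                 seed = derive_seed(seed, 10L)))
  manifest$rarefy_depth <- depth

  out_csv <- function(df, name) {
    num <- vapply(df, is.numeric, TRUE)
    df[num] <- lapply(df[num], signif, digits = 6)
    write.table(df, file.path(out_dir, name), sep = ",", quote = FALSE,
                row.names = FALSE)
    manifest$stages <<- c(manifest$stages, name)
  }

  wrap("alpha_diversity", out_csv(alpha_diversity(table), "alpha.csv"))

  bc <- wrap("bray_curtis", bray_curtis(table))
  bc_df <- as.data.frame(bc)
  bc_df <- cbind(sample_id = rownames(bc), bc_df)
  out_csv(bc_df, "bray_curtis.csv")

  groups <- switch(group_by,
                   all = rep("all", ncol(table)),
                   as.character(meta[[group_by]]))
  if (is.null(groups)) stop("no metadata column '", group_by, "'")

  wrap("anosim", {
    ok_groups <- names(which(table(groups) >= 2))
    if (length(ok_groups) >= 2) {
      keep <- groups %in% ok_groups
      an <- anosim(bc[keep, keep], groups[keep], n_perm = 999,
                   seed = derive_seed(seed, 11L))
      out_csv(data.frame(grouping = group_by, R = an$statistic,
                         p_value = an$p_value), "anosim.csv")
    }
  })

  wrap("distance_decay", {
    geo <- geographic_distance(meta)
    dd <- distance_decay(1 - bc, geo, seed = derive_seed(seed, 12L))
    out_csv(data.frame(slope = dd$slope, intercept = dd$intercept,
                       r = dd$r, p_value = dd$p_value,
                       n_pairs = dd$n_pairs), "ddr.csv")
  })

  env_vars <- unique(c(physical, nutrient))
  if (!length(env_vars))
    env_vars <- intersect(c("temperature", "salinity", "nitrate",
                            "phosphate", "silicate", "ammonia", "iron",
                            "par", "mld", "eld"), names(meta))

  wrap("phylo_signal", {
    ps <- phylo_signal(table, tree, meta, variables = env_vars,
                       n_classes = n_classes, n_perm = 999,
                       seed = derive_seed(seed, 13L))
    out_csv(ps, "phylo_signal.csv")
  })

  part_rows <- list(); ncm_rows <- list(); niche_rows <- list()
  bnti_long <- list(); rc_long <- list()
  for (g in unique(groups)) {
    idx <- which(groups == g)
    if (length(idx) < 3) next
    sub <- community_table_keep(unclass(table)[, idx, drop = FALSE])
    gseed <- derive_seed(seed, 20L + match(g, unique(groups)))
    b <- wrap(paste0("bnti[", g, "]"),
              bnti(sub, tree, n_null = n_null, seed = gseed))
    r <- wrap(paste0("rc_bray[", g, "]"),
              rc_bray(sub, n_null = n_rc, seed = gseed))
    pp <- wrap(paste0("partition[", g, "]"),
               partition_processes(b, r, group_id = g))
    part_rows[[g]] <- as.data.frame(pp)
    pair_idx <- which(upper.tri(b$bnti), arr.ind = TRUE)
    bnti_long[[g]] <- data.frame(group = g,
                                 sample_a = colnames(sub)[pair_idx[, 1]],
                                 sample_b = colnames(sub)[pair_idx[, 2]],
                                 bnti = b$bnti[pair_idx])
    rc_long[[g]] <- data.frame(group = g,
                               sample_a = colnames(sub)[pair_idx[, 1]],
                               sample_b = colnames(sub)[pair_idx[, 2]],
                               rc_bray = r$rc[pair_idx])
    fit <- wrap(paste0("ncm[", g, "]"), tryCatch(ncm_fit(sub),
                                                 error = function(e) NULL))
    if (!is.null(fit))
      ncm_rows[[g]] <- data.frame(group = g, m = fit$m, N = fit$N,
                                  r_squared = fit$r_squared,
                                  n_taxa = fit$n_taxa)
    nb <- wrap(paste0("niche[", g, "]"), {
      bsub <- levins_b(sub)
      cb <- community_niche_breadth(bsub, sub)
      data.frame(group = g, b_com_mean = mean(cb$b_com),
                 b_mean = mean(bsub$b), n_taxa = nrow(bsub))
    })
    niche_rows[[g]] <- nb
    manifest$groups[[g]] <- list(n_samples = length(idx),
                                 n_pairs = pp$n_pairs,
                                 n_excluded = pp$n_excluded,
                                 seed = gseed)
  }
  out_csv(do.call(rbind, c(part_rows, list(make.row.names = FALSE))),
          "process_partition.csv")
  out_csv(do.call(rbind, c(bnti_long, list(make.row.names = FALSE))),
          "bnti.csv")
  out_csv(do.call(rbind, c(rc_long, list(make.row.names = FALSE))),
          "rcbray.csv")
  if (length(ncm_rows))
    out_csv(do.call(rbind, c(ncm_rows, list(make.row.names = FALSE))),
            "ncm.csv")
  out_csv(do.call(rbind, c(niche_rows, list(make.row.names = FALSE))),
          "niche.csv")

  if (!is.null(physical) || !is.null(nutrient)) {
    wrap("env_stats", {
      ball <- bnti(table, tree, n_null = n_null,
                   seed = derive_seed(seed, 40L))
      mt <- bnti_env_correlation(ball, meta, env_vars, n_perm = 999,
                                 seed = derive_seed(seed, 41L))
      out_csv(mt, "mantel_table.csv")
      out_csv(env_heterogeneity(meta, env_vars), "heterogeneity.csv")
      if (!is.null(physical) && !is.null(nutrient)) {
        vp <- vpa(table, meta, physical, nutrient)
        out_csv(data.frame(component = names(vp$fractions),
                           fraction = vp$fractions), "vpa.csv")
      }
    })
  }

  stage <- "done"
  manifest$parameters <- list(group_by = group_by, n_null = n_null,
                              n_rc = n_rc, n_classes = n_classes)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  unlink(file.path(out_dir, ".partial"))
  invisible(manifest)
}
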