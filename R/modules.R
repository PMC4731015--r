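# Module detection from TOM dissimilarity, eigengenes and membership.

# Conventional size-ordered module colour sequence; the largest module
# is "turquoise", unassigned genes are "grey".
MODULE_COLORS <- c(
  "turquoise", "blue", "brown", "yellow", "green", "red", "black",
  "pink", "magenta", "purple", "greenyellow", "tan", "salmon", "cyan",
  "midnightblue", "lightcyan", "grey60", "lightgreen", "lightyellow",
  "royalblue", "darkred", "darkgreen", "darkturquoise", "darkgrey",
  "orange", "darkorange", "white", "skyblue", "saddlebrown", "steelblue"
)

size_ordered_colors <- function(n) {
  if (n <= length(MODULE_COLORS)) {
    MODULE_COLORS[seq_len(n)]
  } else {
    c(MODULE_COLORS, sprintf("module%d", seq.int(length(MODULE_COLORS) + 1L, n)))
  }
}

#' Construct a module partition
#'
#' A partition assigns every gene to exactly one module label; the
#' reserved label (default `"grey"`) marks unassigned genes.
#'
#' @param assignments named character vector, gene ID -> module label.
#' @param unassigned_label reserved label for unassigned genes.
#' @return object of class `module_partition` with fields `assignments`,
#'   `labels` (module labels ordered by decreasing size) and
#'   `unassigned_label`.
#' @export
module_partition <- function(assignments, unassigned_label = "grey") {
  if (is.null(names(assignments)) || any(!nzchar(names(assignments)))) {
    stop_coexmod("`assignments` must be named by gene ID",
                 "coexmod_bad_partition")
  }
  if (anyDuplicated(names(assignments))) {
    stop_coexmod("duplicate gene IDs in partition",
                 "coexmod_duplicate_id")
  }
  if (anyNA(assignments)) {
    stop_coexmod("every gene needs a module label",
                 "coexmod_bad_partition")
  }
  assignments <- stats::setNames(as.character(assignments),
                                 names(assignments))
  sizes <- table(assignments[assignments != unassigned_label])
  labels <- names(sort(sizes, decreasing = TRUE))
  structure(list(assignments = assignments, labels = labels,
                 unassigned_label = unassigned_label),
            class = "module_partition")
}

#' Module sizes of a partition
#'
#' @param partition a [module_partition].
#' @param include_unassigned count the unassigned label too?
#' @return named integer vector, decreasing by size (unassigned last).
#' @export
module_sizes <- function(partition, include_unassigned = TRUE) {
  a <- partition$assignments
  sizes <- vapply(partition$labels, function(l) sum(a == l), integer(1))
  if (include_unassigned) {
    grey <- sum(a == partition$unassigned_label)
    if (grey > 0L) {
      sizes <- c(sizes,
                 stats::setNames(grey, partition$unassigned_label))
    }
  }
  sizes
}

#' @export
print.module_partition <- function(x, ...) {
  sz <- module_sizes(x)
  cat("module_partition:", length(x$assignments), "genes,",
      length(x$labels), "modules\n")
  print(sz)
  invisible(x)
}

#' Detect modules from a TOM dissimilarity matrix
#'
#' Average-linkage hierarchical clustering of the TOM dissimilarity,
#' cut at a maximum height; branches smaller than `min_module_size` are
#' sent to the unassigned ("grey") label.  Modules are named with the
#' conventional size-ordered colour sequence (largest = turquoise).
#'
#' When `expr` is supplied, two refinements run after the cut: a
#' membership purity filter (genes whose correlation with their own
#' module eigengene falls below `kme_filter` are released to grey —
#' this strips background genes that attach to a branch by chance
#' correlation) and, when `merge_height` is set, merging of modules
#' whose eigengenes are closer than `merge_height` in correlation
#' dissimilarity.
#'
#' @param dissim square symmetric dissimilarity matrix (1 - TOM), gene
#'   IDs in dimnames.
#' @param min_module_size smallest branch kept as a module (default 30).
#' @param cut_height dendrogram cut height in \[0, 1\] (default 0.99):
#'   branches merging above this height are separated.
#' @param expr optional genes-by-samples matrix enabling the
#'   eigengene-based refinements.
#' @param kme_filter minimum own-module kME kept after the cut (default
#'   0.3; 0 disables; ignored without `expr`).
#' @param merge_height optional eigengene-dissimilarity merge threshold
#'   (e.g. 0.2 merges modules whose eigengenes correlate above 0.8).
#' @return a [module_partition] over the genes of `dissim`, in input
#'   order.
#' @export
detect_modules <- function(dissim, min_module_size = 30, cut_height = 0.99,
                           expr = NULL, kme_filter = 0.3,
                           merge_height = NULL) {
  if (!is_square_symmetric(dissim)) {
    stop_coexmod("`dissim` must be a symmetric square matrix",
                 "coexmod_asymmetric")
  }
  n <- nrow(dissim)
  if (min_module_size < 2L) {
    stop_coexmod("`min_module_size` must be at least 2",
                 "coexmod_bad_config")
  }
  if (min_module_size > n) {
    stop_coexmod("`min_module_size` exceeds the gene count",
                 "coexmod_bad_config")
  }
  if (cut_height < 0 || cut_height > 1) {
    stop_coexmod("`cut_height` must lie in [0, 1]", "coexmod_bad_config")
  }
  ids <- rownames(dissim)
  if (is.null(ids)) ids <- sprintf("g%d", seq_len(n))

  tree <- stats::hclust(stats::as.dist(dissim), method = "average")
  cl <- stats::cutree(tree, h = cut_height)
  sizes <- table(cl)
  keep <- names(sizes)[sizes >= min_module_size]
  # order retained branches by decreasing size, then colour them
  keep <- keep[order(-sizes[keep], as.integer(keep))]
  colors <- size_ordered_colors(length(keep))
  assign_vec <- rep("grey", n)
  for (i in seq_along(keep)) {
    assign_vec[cl == as.integer(keep[i])] <- colors[i]
  }
  partition <- module_partition(stats::setNames(assign_vec, ids))

  if (!is.null(expr) && kme_filter > 0 && length(partition$labels) > 0L) {
    av <- partition$assignments
    for (l in partition$labels) {
      members <- names(av)[av == l]
      eig <- module_eigengene(expr, members)
      kme <- as.numeric(stats::cor(t(expr[members, , drop = FALSE]),
                                   eig$eigengene))
      av[members[kme < kme_filter]] <- "grey"
    }
    # modules shrunk below the size floor dissolve entirely
    for (l in partition$labels) {
      if (sum(av == l) < min_module_size) av[av == l] <- "grey"
    }
    sizes <- sort(table(av[av != "grey"]), decreasing = TRUE)
    relab <- av
    colors2 <- size_ordered_colors(length(sizes))
    for (i in seq_along(sizes)) {
      relab[av == names(sizes)[i]] <- colors2[i]
    }
    partition <- module_partition(relab)
  }

  if (!is.null(merge_height)) {
    if (is.null(expr)) {
      stop_coexmod("`expr` is required to merge modules by eigengene",
                   "coexmod_bad_config")
    }
    partition <- merge_close_modules(expr, partition, merge_height)
  }
  partition
}

#' Merge modules with similar eigengenes
#'
#' Clusters module eigengenes by correlation dissimilarity
#' (`1 - cor(ME_a, ME_b)`, average linkage) and merges modules falling
#' below `merge_height`; merged modules are renamed by the size-ordered
#' colour convention.  One merge pass is performed.
#'
#' @param expr genes-by-samples matrix covering the partition's genes.
#' @param partition a [module_partition].
#' @param merge_height eigengene dissimilarity below which modules are
#'   merged (e.g. 0.2).
#' @return a [module_partition].
#' @export
merge_close_modules <- function(expr, partition, merge_height = 0.2) {
  labels <- partition$labels
  if (length(labels) < 2L) return(partition)
  me <- module_eigengenes(expr, partition)
  d <- 1 - stats::cor(me$eigengenes)
  tree <- stats::hclust(stats::as.dist(d), method = "average")
  groups <- stats::cutree(tree, h = merge_height)
  assign_vec <- partition$assignments
  merged <- assign_vec
  for (grp in unique(groups)) {
    members <- colnames(me$eigengenes)[groups == grp]
    if (length(members) > 1L) {
      merged[assign_vec %in% members] <- members[1L]
    }
  }
  # re-colour by size order
  sizes <- sort(table(merged[merged != partition$unassigned_label]),
                decreasing = TRUE)
  colors <- size_ordered_colors(length(sizes))
  out <- merged
  for (i in seq_along(sizes)) {
    out[merged == names(sizes)[i]] <- colors[i]
  }
  module_partition(out, partition$unassigned_label)
}

#' Module eigengene
#'
#' First principal component of the per-gene standardized submatrix:
#' the samples-length summary profile of a module.  Scaled to unit
#' variance and sign-oriented so that the mean correlation of member
#' genes with the eigengene is positive (ties broken toward a positive
#' correlation for the first gene).
#'
#' @param expr genes-by-samples matrix.
#' @param module_genes character vector of at least 2 gene IDs.
#' @return list with `eigengene` (named numeric vector over samples) and
#'   `var_explained` (fraction of standardized variance carried by the
#'   first component, in \[0, 1\]).
#' @export
module_eigengene <- function(expr, module_genes) {
  module_genes <- as.character(module_genes)
  if (length(module_genes) < 2L) {
    stop_coexmod("a module needs at least 2 genes", "coexmod_bad_input")
  }
  if (ncol(expr) < 3L) {
    stop_coexmod("need at least 3 samples", "coexmod_bad_input")
  }
  missing <- setdiff(module_genes, rownames(expr))
  if (length(missing) > 0L) {
    stop_coexmod(paste("genes not in expression matrix:",
                       paste(utils::head(missing, 5L), collapse = ", ")),
                 "coexmod_unknown_gene")
  }
  x <- expr[module_genes, , drop = FALSE]
  sds <- apply(x, 1L, stats::sd)
  if (any(sds == 0)) {
    stop_coexmod("constant gene rows have no defined eigengene loading",
                 "coexmod_constant_gene")
  }
  xs <- t(scale(t(x)))
  sv <- svd(xs, nu = 0L, nv = 1L)
  e <- sv$v[, 1L]
  e <- e / stats::sd(e)
  member_cor <- as.numeric(stats::cor(t(xs), e))
  m <- mean(member_cor)
  if (m < 0 || (abs(m) < 1e-12 && member_cor[1L] < 0)) {
    e <- -e
  }
  names(e) <- colnames(expr)
  list(eigengene = e, var_explained = sv$d[1L]^2 / sum(sv$d^2))
}

#' Eigengenes of every module in a partition
#'
#' @param expr genes-by-samples matrix.
#' @param partition a [module_partition]; the unassigned label is
#'   skipped.
#' @return object of class `eigengene_set`: list with `eigengenes`
#'   (samples x modules matrix, unit-variance columns) and
#'   `var_explained` (named vector).
#' @export
module_eigengenes <- function(expr, partition) {
  labels <- partition$labels
  if (length(labels) == 0L) {
    stop_coexmod("partition has no modules", "coexmod_bad_partition")
  }
  per <- lapply(labels, function(l) {
    genes <- names(partition$assignments)[partition$assignments == l]
    module_eigengene(expr, genes)
  })
  mat <- vapply(per, `[[`, numeric(ncol(expr)), "eigengene")
  dimnames(mat) <- list(colnames(expr), labels)
  structure(list(eigengenes = mat,
                 var_explained = stats::setNames(
                   vapply(per, `[[`, numeric(1), "var_explained"),
                   labels)),
            class = "eigengene_set")
}

#' Module membership (kME) with within-module quantiles
#'
#' kME(g, q) is the Pearson correlation of gene g's profile with module
#' q's eigengene ("eigengene-based connectivity").  Within each module,
#' member genes are ranked by their own-module kME and mapped to integer
#' quantiles 0..100 (`round(100 * (rank - 1) / (size - 1))`; the
#' top-kME gene gets 100).
#'
#' @param expr genes-by-samples matrix.
#' @param eigengenes an `eigengene_set` from [module_eigengenes()],
#'   computed on the same samples (order must match).
#' @param partition a [module_partition]; needed for the quantiles.
#' @return object of class `membership_table`: list with `kme`
#'   (genes x modules matrix) and `table` (data frame: gene, module,
#'   kme, quantile; quantile is `NA` for unassigned genes).
#' @export
module_membership <- function(expr, eigengenes, partition) {
  me <- eigengenes$eigengenes
  if (nrow(me) != ncol(expr) ||
      !identical(rownames(me), colnames(expr))) {
    stop_coexmod("eigengene samples do not match the expression matrix",
                 "coexmod_sample_mismatch")
  }
  kme <- stats::cor(t(expr), me)
  assign_vec <- partition$assignments[rownames(expr)]
  quant <- rep(NA_integer_, nrow(expr))
  own_kme <- rep(NA_real_, nrow(expr))
  for (l in partition$labels) {
    idx <- which(assign_vec == l)
    if (length(idx) == 0L) next
    v <- kme[idx, l]
    own_kme[idx] <- v
    if (length(idx) == 1L) {
      quant[idx] <- 100L
    } else {
      r <- rank(v, ties.method = "first")
      quant[idx] <- as.integer(round(100 * (r - 1) / (length(idx) - 1)))
    }
  }
  tab <- data.frame(gene = rownames(expr), module = unname(assign_vec),
                    kme = own_kme, quantile = quant,
                    stringsAsFactors = FALSE)
  structure(list(kme = kme, table = tab), class = "membership_table")
}

#' Assign a gene to a module by highest membership
#'
#' Returns the module with the largest kME; used to place genes that
#' were left out of the clustering (the "assigned by highest module
#' membership" rule).  Ties break deterministically toward the first
#' label in order; when the best kME falls below `min_kme` the
#' unassigned label is returned.
#'
#' @param kme_row named numeric vector of kME values, one per module.
#' @param min_kme minimum kME required (default 0 disables the floor;
#'   note a kME of exactly `min_kme` is accepted).
#' @param unassigned_label label returned below the floor.
#' @return single module label.
#' @export
assign_by_membership <- function(kme_row, min_kme = 0,
                                 unassigned_label = "grey") {
  if (length(kme_row) == 0L) {
    stop_coexmod("empty kME row", "coexmod_bad_input")
  }
  if (is.null(names(kme_row))) {
    stop_coexmod("`kme_row` must be named by module", "coexmod_bad_input")
  }
  best <- which.max(kme_row)  # first index on ties
  if (min_kme > 0 && kme_row[best] < min_kme) {
    return(unassigned_label)
  }
  names(kme_row)[best]
}
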