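# Cross-dataset module preservation: permutation Z statistics.
#
# For each reference module we ask whether its density (how tightly its
# genes co-express) and its connectivity pattern (which genes are hubs,
# which pairs correlate) carry over into a test dataset.  Observed
# statistics are compared to a null of random same-size gene sets drawn
# from the test dataset's analyzed genes; each statistic yields
# Z = (obs - null mean) / null sd, medians are taken within the density
# and connectivity families, and the Z-summary is their mean.  Z-summary
# above 10 is the conventional strong-evidence preservation threshold;
# below 2 indicates no evidence.

module_preservation_stats <- function(genes, expr_ref, expr_test, beta) {
  cr <- stats::cor(t(expr_ref[genes, , drop = FALSE]))
  ct <- stats::cor(t(expr_test[genes, , drop = FALSE]))
  at <- ((1 + clamp(ct, -1, 1)) / 2)^beta
  diag(at) <- 0
  ar <- ((1 + clamp(cr, -1, 1)) / 2)^beta
  diag(ar) <- 0

  eig <- module_eigengene(expr_test, genes)
  kme <- as.numeric(stats::cor(t(expr_test[genes, , drop = FALSE]),
                               eig$eigengene))

  kim_ref <- rowSums(ar)
  kim_test <- rowSums(at)
  ut <- upper.tri(cr)

  c(mean_adj = mean_offdiag(at),
    mean_abs_kme = mean(abs(kme)),
    var_explained = eig$var_explained,
    cor_kim = suppressWarnings(stats::cor(kim_ref, kim_test)),
    cor_cor = suppressWarnings(stats::cor(cr[ut], ct[ut])))
}

DENSITY_STATS <- c("mean_adj", "mean_abs_kme", "var_explained")
CONNECTIVITY_STATS <- c("cor_kim", "cor_cor")

#' Permutation Z-summary of module preservation
#'
#' Computes, for every module of `partition`, three density statistics
#' (mean intramodular signed adjacency, mean |kME|, eigengene variance
#' explained — all in the test dataset) and two connectivity statistics
#' (correlation of intramodular connectivity between reference and test;
#' correlation of the two gene-gene correlation matrices restricted to
#' the module).  A permutation null is built from `n_perm` random gene
#' sets of identical size drawn from the analyzed genes of the test
#' dataset; each statistic is standardized against its null, medians are
#' taken within the density and connectivity families, and
#' `z_summary = (z_density + z_connectivity) / 2`.
#'
#' @param expr_ref reference genes-by-samples matrix (where the modules
#'   were defined).
#' @param expr_test test genes-by-samples matrix; must contain all
#'   partition genes.
#' @param partition a [module_partition]; the unassigned label is not
#'   evaluated.
#' @param beta soft-threshold power used for the adjacency statistics.
#' @param n_perm number of null gene sets (at least 50 for a reportable
#'   Z; default 200).
#' @param seed integer seed for the null draws.
#' @param null_universe `"all"` (default) draws null sets from every
#'   analyzed gene, `"assigned"` restricts to genes belonging to some
#'   module.
#' @return data frame of class `preservation_result`, one row per
#'   module: observed statistics, their Z scores, `z_density`,
#'   `z_connectivity`, `z_summary`.  Attributes `n_perm` and `seed`
#'   record the run.  Zero null variance yields an infinite Z with a
#'   warning.
#' @export
preservation_zsummary <- function(expr_ref, expr_test, partition,
                                  beta = 12, n_perm = 200, seed = 1,
                                  null_universe = c("all", "assigned")) {
  null_universe <- match.arg(null_universe)
  if (n_perm < 50) {
    stop_coexmod("at least 50 permutations are required for a reportable Z",
                 "coexmod_too_few_perms")
  }
  assign_vec <- partition$assignments
  genes_all <- names(assign_vec)
  missing_ref <- setdiff(genes_all, rownames(expr_ref))
  missing_test <- setdiff(genes_all, rownames(expr_test))
  if (length(missing_ref) > 0L || length(missing_test) > 0L) {
    stop_coexmod("partition genes missing from the expression data",
                 "coexmod_unknown_gene")
  }
  universe <- if (null_universe == "all") genes_all
              else genes_all[assign_vec != partition$unassigned_label]
  labels <- partition$labels
  if (length(labels) == 0L) {
    stop_coexmod("partition has no modules to evaluate",
                 "coexmod_bad_partition")
  }

  stat_names <- c(DENSITY_STATS, CONNECTIVITY_STATS)
  rows <- with_seed(seed, {
    lapply(labels, function(l) {
      genes <- genes_all[assign_vec == l]
      obs <- module_preservation_stats(genes, expr_ref, expr_test, beta)
      null <- matrix(NA_real_, nrow = n_perm, ncol = length(stat_names),
                     dimnames = list(NULL, stat_names))
      for (p in seq_len(n_perm)) {
        rnd <- sample(universe, length(genes))
        null[p, ] <- module_preservation_stats(rnd, expr_ref, expr_test,
                                               beta)
      }
      mu <- colMeans(null, na.rm = TRUE)
      sg <- apply(null, 2L, stats::sd, na.rm = TRUE)
      if (any(sg == 0, na.rm = TRUE)) {
        warning(sprintf("module %s: zero null variance for %s", l,
                        paste(stat_names[which(sg == 0)], collapse = ", ")))
      }
      z <- (obs - mu) / sg
      data.frame(module = l, size = length(genes),
                 as.list(obs),
                 stats::setNames(as.list(z), paste0("z_", stat_names)),
                 z_density = stats::median(z[DENSITY_STATS], na.rm = TRUE),
                 z_connectivity = stats::median(z[CONNECTIVITY_STATS],
                                                na.rm = TRUE),
                 stringsAsFactors = FALSE)
    })
  })
  out <- do.call(rbind, rows)
  out$z_summary <- (out$z_density + out$z_connectivity) / 2
  rownames(out) <- NULL
  attr(out, "n_perm") <- n_perm
  attr(out, "seed") <- seed
  class(out) <- c("preservation_result", "data.frame")
  out
}
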