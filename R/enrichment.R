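# Gene-set statistics: hypergeometric over-representation, the exact
# and Monte-Carlo module-clustering test, Fisher and chi-square overlap
# tests, the fold-change DE filter, and DE-list combination.

#' Construct a gene set
#'
#' @param name set name.
#' @param genes character vector of gene IDs; duplicates are dropped
#'   with a warning.
#' @return object of class `gene_set` with fields `name` and `genes`.
#' @export
gene_set <- function(name, genes) {
  genes <- as.character(genes)
  if (anyDuplicated(genes)) {
    warning(sprintf("gene set '%s': removed %d duplicate ID(s)", name,
                    sum(duplicated(genes))))
    genes <- unique(genes)
  }
  structure(list(name = as.character(name), genes = genes),
            class = "gene_set")
}

#' @export
print.gene_set <- function(x, ...) {
  cat("gene_set '", x$name, "': ", length(x$genes), " genes\n", sep = "")
  invisible(x)
}

enrichment_result <- function(method, observed, background, set_sizes,
                              p_value, statistic = NA_real_,
                              mc_se = NA_real_, n_perm = NA_real_) {
  structure(list(method = method, observed = observed,
                 background = background, set_sizes = set_sizes,
                 p_value = p_value, statistic = statistic,
                 mc_se = mc_se, n_perm = n_perm),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  p_str <- if (identical(x$method, "permutation") && x$p_value == 0) {
    sprintf("< %g", 1 / x$n_perm)
  } else {
    format(x$p_value, digits = 4)
  }
  cat(sprintf("%s test: observed = %s, N = %s, p = %s\n", x$method,
              format(x$observed), format(x$background), p_str))
  if (is.finite(x$mc_se)) {
    cat(sprintf("  Monte-Carlo SE = %.3g (%g permutations)\n", x$mc_se,
                x$n_perm))
  }
  invisible(x)
}

#' Hypergeometric over-representation test
#'
#' Upper-tail probability that a random query of size `|query|` drawn
#' from a background of `background_size` genes hits the module at least
#' `observed` times: `P(X >= observed)` for
#' `X ~ Hypergeometric(N, K = |module|, n = |query|)`.  Overlap is
#' counted on the gene IDs shared by both sets.
#'
#' @param module [gene_set] (or character vector) of module genes.
#' @param query [gene_set] (or character vector) of query genes (e.g. a
#'   disease gene set).
#' @param background_size total number of genes in the universe; must be
#'   at least as large as either set.
#' @return an `enrichment_result` with method `"hypergeometric"`.
#' @export
hypergeom_enrich <- function(module, query, background_size) {
  mg <- if (inherits(module, "gene_set")) module$genes else unique(module)
  qg <- if (inherits(query, "gene_set")) query$genes else unique(query)
  n_bg <- as.numeric(background_size)
  if (length(mg) > n_bg || length(qg) > n_bg) {
    stop_coexmod("background smaller than a gene set",
                 "coexmod_bad_background")
  }
  obs <- length(intersect(mg, qg))
  p <- stats::phyper(obs - 1, length(mg), n_bg - length(mg), length(qg),
                     lower.tail = FALSE)
  enrichment_result("hypergeometric", obs, n_bg,
                    c(module = length(mg), query = length(qg)), p)
}

#' Exact probability that g genes co-cluster in a small module
#'
#' Closed form for the module-clustering question: the probability that
#' `g` genes drawn uniformly without replacement from the `n` genes of a
#' partition all land in one module of size at most `m`:
#'
#'   `p = sum over modules with size s <= m of C(s, g) / C(n, g)`.
#'
#' The unassigned ("grey") label is not a co-expression module and by
#' default never counts as a success, although its genes belong to the
#' pool of `n`.
#'
#' @param partition a [module_partition].
#' @param g number of query genes (>= 1).
#' @param m maximum module size counted as a success.
#' @param include_unassigned treat the unassigned label as an eligible
#'   module (default `FALSE`).
#' @return probability in \[0, 1\].
#' @seealso [permutation_cluster_test()] for the Monte-Carlo version.
#' @export
exact_cluster_prob <- function(partition, g, m,
                               include_unassigned = FALSE) {
  n <- length(partition$assignments)
  g <- as.integer(g)
  m <- as.integer(m)
  if (g < 1L || g > n) {
    stop_coexmod("`g` must lie between 1 and the number of genes",
                 "coexmod_bad_input")
  }
  if (m < 1L) {
    stop_coexmod("`m` must be at least 1", "coexmod_bad_input")
  }
  sizes <- module_sizes(partition, include_unassigned = include_unassigned)
  if (!include_unassigned) {
    sizes <- sizes[names(sizes) != partition$unassigned_label]
  }
  ok <- sizes[sizes <= m & sizes >= g]
  if (length(ok) == 0L) return(0)
  sum(exp(lchoose(as.numeric(ok), g) - lchoose(n, g)))
}

#' Specification for the Monte-Carlo module-clustering test
#'
#' @param g number of query genes.
#' @param m maximum module size counted as a success.
#' @param n_perm number of Monte-Carlo repetitions (default 1e6, the
#'   convention for reported p-values).
#' @param seed integer seed.
#' @return object of class `cluster_test_spec`.
#' @export
cluster_test_spec <- function(g, m, n_perm = 1e6, seed = 1L) {
  g <- as.integer(g)
  m <- as.integer(m)
  if (is.na(g) || g < 1L) {
    stop_coexmod("`g` must be a positive integer", "coexmod_bad_input")
  }
  if (is.na(m) || m < 1L) {
    stop_coexmod("`m` must be a positive integer", "coexmod_bad_input")
  }
  if (n_perm < 1) {
    stop_coexmod("`n_perm` must be at least 1", "coexmod_bad_input")
  }
  structure(list(g = g, m = m, n_perm = as.numeric(n_perm),
                 seed = as.integer(seed)),
            class = "cluster_test_spec")
}

#' Monte-Carlo test for the clustering of a gene set within a partition
#'
#' Repeats `n_perm` times: draw `g` genes uniformly without replacement
#' from the partition's gene list and record a success when all of them
#' carry the same module label and that module has size at most `m`.
#' The estimated p-value is the success fraction; its binomial
#' Monte-Carlo standard error `sqrt(p(1-p)/n_perm)` is reported.  The
#' unassigned label never counts as a success module (its genes remain
#' in the sampling pool), matching [exact_cluster_prob()].
#'
#' @param partition a [module_partition].
#' @param spec a [cluster_test_spec()].
#' @param include_unassigned treat the unassigned label as an eligible
#'   module (default `FALSE`).
#' @return an `enrichment_result` with method `"permutation"`; a p-hat
#'   of 0 prints as `< 1/n_perm`.
#' @export
permutation_cluster_test <- function(partition, spec,
                                     include_unassigned = FALSE) {
  stopifnot(inherits(spec, "cluster_test_spec"))
  assign_vec <- partition$assignments
  n <- length(assign_vec)
  g <- spec$g
  if (g > n) {
    stop_coexmod("`g` exceeds the number of genes", "coexmod_bad_input")
  }
  labels_all <- unique(assign_vec)
  lab_int <- match(assign_vec, labels_all)
  sizes <- tabulate(lab_int, nbins = length(labels_all))
  eligible <- sizes <= spec$m
  if (!include_unassigned) {
    eligible[labels_all == partition$unassigned_label] <- FALSE
  }
  gene_ok <- eligible[lab_int]

  n_perm <- spec$n_perm
  successes <- 0
  with_seed(spec$seed, {
    remaining <- n_perm
    chunk_max <- 1e5
    while (remaining > 0) {
      chunk <- as.integer(min(chunk_max, remaining))
      m_idx <- matrix(sample.int(n, chunk * g, replace = TRUE),
                      nrow = chunk, ncol = g)
      if (g > 1L) {
        # enforce sampling without replacement by redrawing rows with
        # repeated indices (rejection is cheap for g << n)
        repeat {
          dup <- rep(FALSE, chunk)
          for (i in seq_len(g - 1L)) {
            for (j in seq.int(i + 1L, g)) {
              dup <- dup | (m_idx[, i] == m_idx[, j])
            }
          }
          if (!any(dup)) break
          m_idx[dup, ] <- sample.int(n, sum(dup) * g, replace = TRUE)
        }
      }
      lab_mat <- matrix(lab_int[m_idx], nrow = chunk, ncol = g)
      same <- rowSums(lab_mat == lab_mat[, 1L]) == g
      successes <- successes + sum(same & gene_ok[m_idx[, 1L]])
      remaining <- remaining - chunk
    }
  })
  p_hat <- successes / n_perm
  enrichment_result("permutation", successes, n,
                    c(g = g, m = spec$m), p_hat,
                    mc_se = sqrt(p_hat * (1 - p_hat) / n_perm),
                    n_perm = n_perm)
}

#' One-sided Fisher exact test for the overlap of two gene sets
#'
#' Builds the 2x2 table (in both, A only, B only, neither) over a
#' background universe and tests for over-representation of the overlap
#' (one-sided, enrichment tail).  Equivalent to the hypergeometric upper
#' tail on the same margins.
#'
#' @param set_a,set_b [gene_set]s or character vectors.
#' @param background_size size of the gene universe; the table's
#'   "neither" cell must be non-negative.
#' @return an `enrichment_result` with method `"fisher"`.
#' @export
fisher_overlap <- function(set_a, set_b, background_size) {
  ga <- if (inherits(set_a, "gene_set")) set_a$genes else unique(set_a)
  gb <- if (inherits(set_b, "gene_set")) set_b$genes else unique(set_b)
  n_bg <- as.numeric(background_size)
  both <- length(intersect(ga, gb))
  a_only <- length(ga) - both
  b_only <- length(gb) - both
  neither <- n_bg - both - a_only - b_only
  if (neither < 0) {
    stop_coexmod("background smaller than the union of the sets",
                 "coexmod_bad_background")
  }
  tab <- matrix(c(both, a_only, b_only, neither), nrow = 2L)
  p <- stats::fisher.test(tab, alternative = "greater")$p.value
  enrichment_result("fisher", both, n_bg,
                    c(a = length(ga), b = length(gb)), p)
}

#' Pearson chi-square test on a 2x2 overlap table
#'
#' Two-sided Pearson chi-square without continuity correction (df = 1);
#' the convention used to test the overlap between a differential
#' expression list and module membership when sample sizes preclude a
#' per-gene test of means.
#'
#' @param table 2x2 matrix of non-negative counts with positive row and
#'   column sums.
#' @return an `enrichment_result` with method `"chisq"`; the `statistic`
#'   field holds the chi-square value.
#' @export
chisq_overlap <- function(table) {
  tab <- as.matrix(table)
  if (!all(dim(tab) == c(2L, 2L))) {
    stop_coexmod("`table` must be 2x2", "coexmod_bad_input")
  }
  if (any(tab < 0)) {
    stop_coexmod("counts must be non-negative", "coexmod_bad_input")
  }
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop_coexmod("zero marginal in the 2x2 table", "coexmod_bad_input")
  }
  res <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  enrichment_result("chisq", tab[1L, 1L], sum(tab),
                    c(row1 = sum(tab[1L, ]), col1 = sum(tab[, 1L])),
                    unname(res$p.value), statistic = unname(res$statistic))
}

#' Fold-change differential-expression filter
#'
#' For each gene, computes the fold change of the mean case signal
#' relative to the mean control signal on the linear scale, folded to be
#' at least 1 (`max(ratio, 1/ratio)`); a gene passes when its fold
#' change is **at least** the threshold (the boundary value passes).
#'
#' @param case,control linear-scale genes-by-samples matrices over the
#'   same genes (order may differ); all per-gene means must be positive.
#' @param threshold minimum fold change (default 1.5).
#' @return data frame with columns gene, mean_case, mean_control,
#'   fold_change, direction ("up" when the case mean is at least the
#'   control mean, "down" otherwise), passes.
#' @export
de_fold_change_filter <- function(case, control, threshold = 1.5) {
  if (!setequal(rownames(case), rownames(control))) {
    stop_coexmod("case and control gene universes differ",
                 "coexmod_bad_input")
  }
  control <- control[rownames(case), , drop = FALSE]
  mean_case <- rowMeans(case)
  mean_control <- rowMeans(control)
  if (any(mean_case <= 0) || any(mean_control <= 0)) {
    stop_coexmod("non-positive mean signal: fold change undefined",
                 "coexmod_bad_input")
  }
  ratio <- mean_case / mean_control
  fc <- pmax(ratio, 1 / ratio)
  data.frame(gene = rownames(case),
             mean_case = unname(mean_case),
             mean_control = unname(mean_control),
             fold_change = unname(fc),
             direction = ifelse(ratio >= 1, "up", "down"),
             passes = unname(fc >= threshold),
             stringsAsFactors = FALSE)
}

#' Combine differential-expression gene lists
#'
#' Union (to minimize false negatives) or intersection (to minimize
#' false positives) of two or more gene lists, order-stable by first
#' appearance.
#'
#' @param lists list of at least two character vectors.
#' @param mode `"union"` or `"intersection"`.
#' @return character vector.
#' @export
combine_de_lists <- function(lists, mode = c("union", "intersection")) {
  mode <- match.arg(mode)
  if (!is.list(lists) || length(lists) < 2L) {
    stop_coexmod("`lists` must contain at least two gene lists",
                 "coexmod_bad_input")
  }
  lists <- lapply(lists, as.character)
  if (mode == "union") {
    Reduce(union, lists)
  } else {
    Reduce(intersect, lists)
  }
}
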