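# Signed weighted co-expression network construction.
#
# Pipeline: Pearson correlation across samples -> signed soft-threshold
# adjacency a_ij = ((1 + r_ij) / 2)^beta -> topological overlap (TOM).
# The adjacency diagonal is held at 0 so connectivity sums exclude the
# self term; the TOM diagonal is reported as 1 by convention.

#' Pearson correlation matrix across samples
#'
#' Computes gene-gene Pearson correlations of the rows of a
#' genes-by-samples matrix.  Genes with zero variance (constant rows)
#' have no defined correlation; they are dropped with a warning.
#'
#' @param expr numeric matrix, genes in rows, at least 3 samples.
#' @return symmetric correlation matrix with unit diagonal, one
#'   row/column per retained gene.
#' @export
correlation_matrix <- function(expr) {
  if (!is.matrix(expr) || !is.numeric(expr)) {
    stop_coexmod("`expr` must be a numeric matrix", "coexmod_bad_input")
  }
  if (ncol(expr) < 3L) {
    stop_coexmod("need at least 3 samples to correlate",
                 "coexmod_bad_input")
  }
  sds <- apply(expr, 1L, stats::sd)
  if (any(sds == 0)) {
    bad <- rownames(expr)[sds == 0]
    warning(sprintf("removed %d constant gene(s): %s", length(bad),
                    paste(utils::head(bad, 5L), collapse = ", ")))
    expr <- expr[sds > 0, , drop = FALSE]
    if (nrow(expr) < 2L) {
      stop_coexmod("fewer than 2 variable genes remain",
                   "coexmod_bad_input")
    }
  }
  r <- stats::cor(t(expr))
  r <- clamp(r, -1, 1)
  diag(r) <- 1
  r
}

#' Signed soft-threshold adjacency
#'
#' Maps correlations to edge weights `((1 + r) / 2)^beta`, so perfect
#' positive correlation gives weight 1 and perfect anticorrelation gives
#' weight 0 (a *signed* network: opposing genes are disconnected rather
#' than strongly connected).  The diagonal is set to 0 so that row sums
#' are whole-network connectivities.
#'
#' @param corr symmetric correlation matrix with entries in \[-1, 1\].
#' @param beta soft-threshold power (> 0); 12 is the conventional signed
#'   default for large adult-brain datasets.
#' @return adjacency matrix with entries in \[0, 1\] and zero diagonal.
#' @export
signed_adjacency <- function(corr, beta = 12) {
  if (!is.numeric(beta) || length(beta) != 1L || beta <= 0) {
    stop_coexmod("`beta` must be a single positive number",
                 "coexmod_bad_beta")
  }
  if (!is_square_symmetric(corr)) {
    stop_coexmod("`corr` must be a symmetric square matrix",
                 "coexmod_asymmetric")
  }
  if (min(corr) < -1 - 1e-8 || max(corr) > 1 + 1e-8) {
    stop_coexmod("correlations must lie in [-1, 1]", "coexmod_bad_input")
  }
  a <- ((1 + clamp(corr, -1, 1)) / 2)^beta
  a <- clamp(a, 0, 1)
  diag(a) <- 0
  a
}

#' Whole-network connectivity
#'
#' @param adjacency adjacency matrix with zero diagonal.
#' @return named numeric vector of row sums.
#' @export
connectivity <- function(adjacency) {
  rowSums(adjacency)
}

#' Scale-free topology fit index from a connectivity vector
#'
#' Bins the connectivities into `n_bins` equal-width bins, regresses
#' log10(frequency) on log10(mean connectivity per bin), and returns the
#' signed fit `-sign(slope) * R^2`: close to +1 when the degree
#' distribution follows a decaying power law.
#'
#' @param k numeric vector of connectivities (non-negative).
#' @param n_bins number of bins (default 10).
#' @return signed R-squared in \[-1, 1\].
#' @export
scale_free_fit_index <- function(k, n_bins = 10) {
  k <- as.numeric(k)
  if (length(unique(k)) < 2L) {
    stop_coexmod("degenerate connectivities: all values equal",
                 "coexmod_degenerate")
  }
  bins <- cut(k, breaks = n_bins)
  counts <- tabulate(bins, nbins = nlevels(bins))
  mean_k <- vapply(split(k, bins), function(v) {
    if (length(v) == 0L) NA_real_ else mean(v)
  }, numeric(1))
  keep <- counts > 0L & is.finite(mean_k) & mean_k > 0
  if (sum(keep) < 2L) {
    stop_coexmod("need at least 2 non-empty bins with positive mean k",
                 "coexmod_degenerate")
  }
  x <- log10(mean_k[keep])
  y <- log10(counts[keep] / length(k))
  fit <- stats::lm(y ~ x)
  r2 <- summary(fit)$r.squared
  slope <- stats::coef(fit)[["x"]]
  -sign(slope) * r2
}

#' Scale-free topology fit of an adjacency matrix
#'
#' @param adjacency adjacency matrix (zero diagonal).
#' @param n_bins number of connectivity bins.
#' @return signed R-squared of the log-log degree regression.
#' @seealso [scale_free_fit_index()], [pick_beta()]
#' @export
scale_free_fit <- function(adjacency, n_bins = 10) {
  scale_free_fit_index(connectivity(adjacency), n_bins = n_bins)
}

#' Scan soft-threshold powers for scale-free topology
#'
#' Computes the signed scale-free fit for each candidate power and
#' reports the smallest power reaching `target` (if any).
#'
#' @param expr genes-by-samples matrix.
#' @param powers candidate powers.
#' @param target signed R-squared considered adequate (default 0.8).
#' @param n_bins connectivity bins for the fit.
#' @return list with `table` (power, fit, mean connectivity) and `power`
#'   (chosen power, or `NA` with a warning when no power reaches the
#'   target).
#' @export
pick_beta <- function(expr, powers = c(1:10, seq(12, 24, 2)),
                      target = 0.8, n_bins = 10) {
  r <- correlation_matrix(expr)
  rows <- lapply(powers, function(b) {
    a <- signed_adjacency(r, b)
    fit <- tryCatch(scale_free_fit(a, n_bins), error = function(e) NA_real_)
    data.frame(power = b, fit = fit, mean_k = mean(connectivity(a)))
  })
  tab <- do.call(rbind, rows)
  ok <- which(!is.na(tab$fit) & tab$fit >= target)
  if (length(ok) == 0L) {
    warning("no candidate power reaches the target scale-free fit")
    chosen <- NA_real_
  } else {
    chosen <- tab$power[ok[1L]]
  }
  list(table = tab, power = chosen)
}

#' Topological overlap matrix
#'
#' For adjacency `a` with zero diagonal and connectivities
#' `k_i = sum_u a_iu`, the (unsigned) topological overlap is
#'
#'   `w_ij = (l_ij + a_ij) / (min(k_i, k_j) + 1 - a_ij)`,
#'   `l_ij = sum_{u != i,j} a_iu * a_uj`,
#'
#' a similarity that credits shared neighbours: two genes overlap
#' strongly when they connect to the same part of the network even if
#' their direct edge is modest.  The diagonal is reported as 1.
#'
#' @param adjacency symmetric adjacency matrix, entries in \[0, 1\].
#' @return symmetric TOM matrix with unit diagonal.
#' @seealso [tom_dissimilarity()]
#' @export
compute_tom <- function(adjacency) {
  if (!is_square_symmetric(adjacency)) {
    stop_coexmod("adjacency must be a symmetric square matrix",
                 "coexmod_asymmetric")
  }
  if (min(adjacency) < -1e-12 || max(adjacency) > 1 + 1e-12) {
    stop_coexmod("adjacency entries must lie in [0, 1]",
                 "coexmod_bad_input")
  }
  a <- adjacency
  diag(a) <- 0
  l <- a %*% a                       # l_ij = sum_u a_iu a_uj (diag is 0)
  k <- rowSums(a)
  denom <- outer(k, k, pmin) + 1 - a
  tom <- (l + a) / denom
  tom <- clamp(tom, 0, 1)
  diag(tom) <- 1
  dimnames(tom) <- dimnames(adjacency)
  tom
}

#' TOM dissimilarity
#'
#' @param tom topological overlap matrix.
#' @return `1 - tom`, the clustering dissimilarity.
#' @export
tom_dissimilarity <- function(tom) {
  1 - tom
}

#' Export network edges above a TOM cutoff, with hub ranking
#'
#' Returns every unordered gene pair whose topological overlap strictly
#' exceeds `cutoff` (the convention used for module interconnection
#' plots, e.g. TOM > 0.08), plus a per-gene connectivity ranking.  When
#' a partition is supplied the ranking uses intramodular connectivity
#' (sum of TOM to same-module genes); the top-ranked genes are the
#' module hub genes.
#'
#' @param tom topological overlap matrix.
#' @param cutoff edge threshold in \[0, 1\].
#' @param partition optional [module_partition] used for intramodular
#'   connectivity.
#' @return list with `edges` (data frame: gene_a, gene_b, weight, sorted
#'   by decreasing weight) and `hubs` (data frame: gene, module,
#'   connectivity, rank).
#' @export
export_edges <- function(tom, cutoff, partition = NULL) {
  if (!is.numeric(cutoff) || length(cutoff) != 1L || cutoff < 0 ||
      cutoff > 1) {
    stop_coexmod("`cutoff` must be a number in [0, 1]",
                 "coexmod_bad_input")
  }
  if (!is_square_symmetric(tom)) {
    stop_coexmod("`tom` must be a symmetric square matrix",
                 "coexmod_asymmetric")
  }
  ids <- rownames(tom)
  if (is.null(ids)) ids <- sprintf("g%d", seq_len(nrow(tom)))
  ut <- upper.tri(tom)
  hit <- which(ut & tom > cutoff, arr.ind = TRUE)
  edges <- data.frame(gene_a = ids[hit[, 1L]],
                      gene_b = ids[hit[, 2L]],
                      weight = tom[hit],
                      stringsAsFactors = FALSE)
  edges <- edges[order(-edges$weight, edges$gene_a, edges$gene_b), ,
                 drop = FALSE]
  rownames(edges) <- NULL

  t0 <- tom
  diag(t0) <- 0
  if (is.null(partition)) {
    conn <- rowSums(t0)
    modules <- rep(NA_character_, length(ids))
  } else {
    assign_vec <- partition$assignments[ids]
    conn <- vapply(seq_along(ids), function(i) {
      same <- which(assign_vec == assign_vec[i])
      sum(t0[i, same])
    }, numeric(1))
    modules <- unname(assign_vec)
  }
  hubs <- data.frame(gene = ids, module = modules, connectivity = conn,
                     stringsAsFactors = FALSE)
  hubs <- hubs[order(-hubs$connectivity, hubs$gene), , drop = FALSE]
  hubs$rank <- seq_len(nrow(hubs))
  rownames(hubs) <- NULL
  list(edges = edges, hubs = hubs)
}
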