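# Synthetic expression data with planted co-expression modules.
#
# Each module q is driven by a single latent factor f_q (one value per
# sample); member gene g loads on it with loading a_g:
#
#   x_gs = a_g * f_qs + sqrt(1 - a_g^2) * e_gs,   f, e ~ iid N(0, 1)
#
# so every gene is standard normal and the expected correlation between
# two same-module genes is a_i * a_j.  Per-gene loadings are drawn
# uniformly around the module loading a_q (half-width `loading_jitter`),
# which gives modules the hub structure real co-expression modules have
# (some genes more central than others) while keeping the expected
# within-module correlation at a_q^2.  Background genes are pure noise.
# The one-factor form mirrors the module-eigengene summary used
# downstream: the eigengene of a planted module estimates its factor.

#' Configuration for the synthetic expression generator
#'
#' @param module_sizes integer vector, number of genes per planted
#'   module (each at least 2).
#' @param loadings numeric vector, one factor loading per module, each
#'   in \[0, 1\]. The expected within-module gene-gene correlation is the
#'   squared loading.
#' @param n_background number of unstructured (pure-noise) genes.
#' @param n_samples number of samples (columns); at least 3.
#' @param planted_set_spec optional data frame with columns `module`
#'   (module index, or 0 for background) and `count`, describing how
#'   many genes of the planted disease-like set come from where.
#' @param loading_jitter half-width of the per-gene loading spread
#'   around each module loading (default 0.1; loadings are clipped to
#'   \[0, 1\]).  Set to 0 for exchangeable module genes with identical
#'   loadings; a positive jitter gives modules hub structure.
#' @param seed integer root seed; all randomness in the generator and in
#'   derived paired/disease datasets is reproducible from it.
#'
#' @return An object of class `synthetic_config`.
#' @examples
#' cfg <- synthetic_config(c(50, 40), c(0.9, 0.8), n_background = 100,
#'                         n_samples = 60, seed = 1)
#' @export
synthetic_config <- function(module_sizes, loadings, n_background = 0L,
                             n_samples, planted_set_spec = NULL,
                             loading_jitter = 0.1, seed = 1L) {
  module_sizes <- as.integer(module_sizes)
  if (length(module_sizes) < 1L || any(is.na(module_sizes))) {
    stop_coexmod("`module_sizes` must be a non-empty integer vector",
                 "coexmod_bad_config")
  }
  if (any(module_sizes < 2L)) {
    stop_coexmod("every module must have at least 2 genes",
                 "coexmod_bad_config")
  }
  if (length(loadings) != length(module_sizes)) {
    stop_coexmod("`loadings` must match `module_sizes` in length",
                 "coexmod_bad_config")
  }
  if (any(!is.finite(loadings)) || any(loadings < 0) || any(loadings > 1)) {
    stop_coexmod("loadings must lie in [0, 1]", "coexmod_bad_config")
  }
  n_background <- as.integer(n_background)
  if (is.na(n_background) || n_background < 0L) {
    stop_coexmod("`n_background` must be a non-negative integer",
                 "coexmod_bad_config")
  }
  n_samples <- as.integer(n_samples)
  if (is.na(n_samples) || n_samples < 3L) {
    stop_coexmod("`n_samples` must be at least 3", "coexmod_bad_config")
  }
  if (!is.null(planted_set_spec)) {
    planted_set_spec <- as.data.frame(planted_set_spec)
    if (!all(c("module", "count") %in% names(planted_set_spec))) {
      stop_coexmod("`planted_set_spec` needs columns `module` and `count`",
                   "coexmod_bad_config")
    }
    idx <- as.integer(planted_set_spec$module)
    cnt <- as.integer(planted_set_spec$count)
    if (any(idx < 0L) || any(idx > length(module_sizes))) {
      stop_coexmod("planted set module index out of range",
                   "coexmod_bad_config")
    }
    cap <- ifelse(idx == 0L, n_background, module_sizes[pmax(idx, 1L)])
    if (any(cnt < 0L) || any(cnt > cap)) {
      stop_coexmod("planted set counts exceed target module sizes",
                   "coexmod_bad_config")
    }
  }
  if (!is.numeric(loading_jitter) || length(loading_jitter) != 1L ||
      loading_jitter < 0 || loading_jitter > 0.5) {
    stop_coexmod("`loading_jitter` must lie in [0, 0.5]",
                 "coexmod_bad_config")
  }
  structure(list(module_sizes = module_sizes,
                 loadings = as.numeric(loadings),
                 n_background = n_background,
                 n_samples = n_samples,
                 planted_set_spec = planted_set_spec,
                 loading_jitter = as.numeric(loading_jitter),
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

#' @export
print.synthetic_config <- function(x, ...) {
  cat("synthetic_config:", length(x$module_sizes), "modules (",
      paste(x$module_sizes, collapse = ", "), "genes ),",
      x$n_background, "background genes,", x$n_samples, "samples, seed",
      x$seed, "\n")
  invisible(x)
}

module_labels_for <- function(k) paste0("M", seq_len(k))

#' Simulate an expression matrix with planted co-expression modules
#'
#' Generates a genes-by-samples matrix in which each planted module is a
#' one-factor block (see package vignette) and background genes are
#' independent noise, together with the full ground truth: the true
#' partition (background genes carry the unassigned label), the latent
#' factors, and the planted disease-like gene set.
#'
#' @param config a [synthetic_config()].
#' @return A list with elements `expr` (numeric matrix, genes x samples,
#'   gene IDs `G000001...` in rows) and `truth`, a `synthetic_truth`
#'   object with fields `partition` ([module_partition]), `latent_factors`
#'   (modules x samples matrix), `planted_set` (character vector, possibly
#'   empty) and `loadings`.
#' @examples
#' sim <- simulate_expression(
#'   synthetic_config(c(30, 20), c(0.9, 0.8), n_background = 50,
#'                    n_samples = 40, seed = 7))
#' dim(sim$expr)
#' module_sizes(sim$truth$partition)
#' @export
simulate_expression <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  k <- length(config$module_sizes)
  n_mod <- sum(config$module_sizes)
  n <- n_mod + config$n_background
  s <- config$n_samples
  gene_ids <- sprintf("G%06d", seq_len(n))
  sample_ids <- sprintf("S%03d", seq_len(s))
  labels <- module_labels_for(k)

  out <- with_seed(config$seed, {
    factors <- matrix(stats::rnorm(k * s), nrow = k, ncol = s,
                      dimnames = list(labels, sample_ids))
    expr <- matrix(NA_real_, nrow = n, ncol = s,
                   dimnames = list(gene_ids, sample_ids))
    row0 <- 0L
    assign_vec <- character(n)
    gene_loadings <- rep(NA_real_, n)
    for (q in seq_len(k)) {
      sz <- config$module_sizes[q]
      a <- config$loadings[q]
      jit <- config$loading_jitter
      ag <- if (jit > 0) {
        clamp(a + stats::runif(sz, -jit, jit), 0, 1)
      } else {
        rep(a, sz)
      }
      eps <- matrix(stats::rnorm(sz * s), nrow = sz, ncol = s)
      block <- ag * matrix(factors[q, ], nrow = sz, ncol = s,
                           byrow = TRUE) +
        sqrt(1 - ag^2) * eps
      expr[row0 + seq_len(sz), ] <- block
      assign_vec[row0 + seq_len(sz)] <- labels[q]
      gene_loadings[row0 + seq_len(sz)] <- ag
      row0 <- row0 + sz
    }
    if (config$n_background > 0L) {
      expr[row0 + seq_len(config$n_background), ] <-
        matrix(stats::rnorm(config$n_background * s),
               nrow = config$n_background, ncol = s)
      assign_vec[row0 + seq_len(config$n_background)] <- "grey"
    }
    planted <- character(0)
    if (!is.null(config$planted_set_spec)) {
      spec <- config$planted_set_spec
      for (i in seq_len(nrow(spec))) {
        idx <- as.integer(spec$module[i])
        cnt <- as.integer(spec$count[i])
        pool <- if (idx == 0L) gene_ids[assign_vec == "grey"]
                else gene_ids[assign_vec == labels[idx]]
        planted <- c(planted, sample(pool, cnt))
      }
    }
    list(expr = expr, assign = assign_vec, factors = factors,
         planted = planted, gene_loadings = gene_loadings)
  })

  partition <- module_partition(stats::setNames(out$assign, gene_ids))
  truth <- structure(list(partition = partition,
                          latent_factors = out$factors,
                          planted_set = out$planted,
                          loadings = stats::setNames(config$loadings, labels),
                          gene_loadings = stats::setNames(out$gene_loadings,
                                                          gene_ids)),
                     class = "synthetic_truth")
  list(expr = out$expr, truth = truth)
}

#' Simulate a paired dataset with preserved and destroyed modules
#'
#' Emits a second expression matrix over the same genes and a fresh set
#' of samples.  Modules named in `preserved_modules` reuse the latent
#' factors and per-gene loadings recorded in `truth` (with fresh
#' gene-level noise), so both their density and their hub structure
#' carry over; all other modules decohere — their genes are emitted as
#' independent noise, so no trace of the module survives in the test
#' dataset — and background genes are fresh noise.
#'
#' @param truth the `truth` component returned by [simulate_expression()].
#' @param preserved_modules character vector of module labels to preserve
#'   (subset of the truth partition's module labels).
#' @param config the [synthetic_config()] used for the reference dataset;
#'   the paired dataset uses the same sizes, loadings and sample count.
#'   Its seed is advanced deterministically, so the pair is reproducible
#'   from the one root seed.
#' @return numeric matrix, genes x samples.
#' @export
simulate_paired_dataset <- function(truth, preserved_modules, config) {
  stopifnot(inherits(truth, "synthetic_truth"),
            inherits(config, "synthetic_config"))
  k <- length(config$module_sizes)
  labels <- module_labels_for(k)
  preserved_modules <- as.character(preserved_modules)
  unknown <- setdiff(preserved_modules, labels)
  if (length(unknown) > 0L) {
    stop_coexmod(paste("unknown module label(s):",
                       paste(unknown, collapse = ", ")),
                 "coexmod_unknown_module")
  }
  assign_vec <- truth$partition$assignments
  n <- length(assign_vec)
  if (sum(config$module_sizes) + config$n_background != n) {
    stop_coexmod("config does not match the truth partition",
                 "coexmod_bad_config")
  }
  s <- config$n_samples
  gene_ids <- names(assign_vec)
  sample_ids <- sprintf("T%03d", seq_len(s))

  with_seed(derive_seed(config$seed, "paired"), {
    expr <- matrix(NA_real_, nrow = n, ncol = s,
                   dimnames = list(gene_ids, sample_ids))
    for (q in seq_len(k)) {
      rows <- which(assign_vec == labels[q])
      eps <- matrix(stats::rnorm(length(rows) * s), nrow = length(rows))
      if (labels[q] %in% preserved_modules) {
        ag <- truth$gene_loadings[rows]
        expr[rows, ] <- ag * matrix(truth$latent_factors[labels[q], ],
                                    nrow = length(rows), ncol = s,
                                    byrow = TRUE) +
          sqrt(1 - ag^2) * eps
      } else {
        expr[rows, ] <- eps
      }
    }
    bg <- which(assign_vec == truth$partition$unassigned_label)
    if (length(bg) > 0L) {
      expr[bg, ] <- matrix(stats::rnorm(length(bg) * s), nrow = length(bg))
    }
    expr
  })
}

#' Linearize a z-scale expression matrix
#'
#' Networks are built on z-scale (log-like) values; the fold-change
#' differential-expression rule is a ratio of means and therefore needs
#' a positive linear scale.  The convention used throughout the package
#' is `linear = offset * 2^z`.
#'
#' @param expr numeric matrix on the z scale.
#' @param offset positive multiplicative offset (default 20).
#' @return numeric matrix on the linear scale.
#' @export
linearize_expression <- function(expr, offset = 20) {
  if (!is.numeric(offset) || offset <= 0) {
    stop_coexmod("`offset` must be positive", "coexmod_bad_config")
  }
  offset * 2^expr
}

#' Apply case/control fold changes to a linear-scale matrix
#'
#' Multiplies each named gene's values by its fold factor, leaving all
#' other genes untouched.  Input and output are linear-scale matrices
#' (see [linearize_expression()]); a fold factor of 2 makes the gene's
#' mean exactly twice the baseline mean.
#'
#' @param baseline linear-scale expression matrix (all values positive).
#' @param fold_spec named numeric vector of strictly positive fold
#'   factors; names are gene IDs present in `baseline`.
#' @return linear-scale matrix of the same shape as `baseline`.
#' @export
simulate_disease <- function(baseline, fold_spec) {
  if (is.null(names(fold_spec)) || any(!nzchar(names(fold_spec)))) {
    stop_coexmod("`fold_spec` must be a named numeric vector",
                 "coexmod_bad_config")
  }
  if (any(!is.finite(fold_spec)) || any(fold_spec <= 0)) {
    stop_coexmod("fold factors must be strictly positive",
                 "coexmod_bad_fold")
  }
  missing <- setdiff(names(fold_spec), rownames(baseline))
  if (length(missing) > 0L) {
    stop_coexmod(paste("genes not in baseline:",
                       paste(missing, collapse = ", ")),
                 "coexmod_unknown_gene")
  }
  out <- baseline
  out[names(fold_spec), ] <- out[names(fold_spec), , drop = FALSE] * fold_spec
  out
}
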