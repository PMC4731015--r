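# End-to-end pipeline driver: simulate (or load) -> network -> modules
# -> preservation -> enrichment -> differential expression, with
# per-stage timing and output checksums collected in a run manifest.

#' Configuration for [run_pipeline()]
#'
#' With the default `expr_path = NULL` the pipeline simulates its own
#' data from `sim` (full ground truth available, all stages run).  When
#' `expr_path` points to an expression TSV, that matrix is used as the
#' reference dataset instead; stages that need ground truth
#' (preservation pairing, planted-set enrichment, disease simulation)
#' then require `test_path` / `sets_path` and are skipped when those are
#' absent.
#'
#' @param out_dir output directory (created if needed).
#' @param sim a [synthetic_config()]; defaults to three planted modules
#'   of 100/80/60 genes with loadings 0.85/0.80/0.75, 500 background
#'   genes, 120 samples, and a 10-gene disease-like set planted 5/3/2
#'   into modules 1, 2 and the background (echoing a small disease gene
#'   family concentrated in two modules).
#' @param beta soft-threshold power for the signed adjacency.
#' @param tom_edge_cutoff TOM threshold for the exported edge list.
#' @param min_module_size,cut_height,merge_height tree-cut parameters,
#'   see [detect_modules()].
#' @param preserved_modules truth module labels preserved in the paired
#'   dataset (default: the first module; the others are destroyed).
#' @param preservation_n_perm,permtest_n_perm permutation counts for the
#'   Z-summary and the module-clustering test.
#' @param de_fold fold factor applied to the planted genes in the
#'   simulated disease dataset.
#' @param de_threshold fold-change threshold of the DE filter.
#' @param seed root seed; recorded in the manifest.
#' @param expr_path,test_path,sets_path optional input files (expression
#'   TSV, paired expression TSV, GMT).
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir,
                            sim = NULL,
                            beta = 12,
                            tom_edge_cutoff = 0.08,
                            min_module_size = 30,
                            cut_height = 0.99,
                            merge_height = NULL,
                            preserved_modules = NULL,
                            preservation_n_perm = 200,
                            permtest_n_perm = 1e5,
                            de_fold = 1.8,
                            de_threshold = 1.5,
                            seed = 1L,
                            expr_path = NULL,
                            test_path = NULL,
                            sets_path = NULL) {
  if (is.null(sim)) {
    sim <- synthetic_config(
      module_sizes = c(100L, 80L, 60L),
      loadings = c(0.85, 0.80, 0.75),
      n_background = 500L,
      n_samples = 120L,
      planted_set_spec = data.frame(module = c(1L, 2L, 0L),
                                    count = c(5L, 3L, 2L)),
      seed = derive_seed(seed, "sim"))
  }
  structure(list(out_dir = out_dir, sim = sim, beta = beta,
                 tom_edge_cutoff = tom_edge_cutoff,
                 min_module_size = min_module_size,
                 cut_height = cut_height, merge_height = merge_height,
                 preserved_modules = preserved_modules,
                 preservation_n_perm = preservation_n_perm,
                 permtest_n_perm = permtest_n_perm,
                 de_fold = de_fold, de_threshold = de_threshold,
                 seed = as.integer(seed),
                 expr_path = expr_path, test_path = test_path,
                 sets_path = sets_path),
            class = "pipeline_config")
}

validate_pipeline_config <- function(config) {
  for (field in c("expr_path", "test_path", "sets_path")) {
    p <- config[[field]]
    if (!is.null(p) && !file.exists(p)) {
      stop_coexmod(sprintf("%s does not exist: %s", field, p),
                   "coexmod_validation")
    }
  }
  if (config$beta <= 0) {
    stop_coexmod("beta must be positive", "coexmod_validation")
  }
  if (config$tom_edge_cutoff < 0 || config$tom_edge_cutoff > 1) {
    stop_coexmod("tom_edge_cutoff must lie in [0, 1]",
                 "coexmod_validation")
  }
  invisible(TRUE)
}

run_stage <- function(name, manifest_env, code) {
  t0 <- proc.time()[["elapsed"]]
  outputs <- tryCatch(force(code), error = function(e) {
    stop_coexmod(sprintf("stage '%s' failed: %s", name,
                         conditionMessage(e)),
                 "coexmod_stage_error", stage = name)
  })
  elapsed <- proc.time()[["elapsed"]] - t0
  outputs <- as.character(outputs)
  sums <- if (length(outputs) > 0L) {
    unname(tools::md5sum(outputs))
  } else {
    character(0)
  }
  manifest_env$stages <- rbind(
    manifest_env$stages,
    data.frame(stage = name, seconds = round(elapsed, 3),
               outputs = paste(basename(outputs), collapse = ";"),
               md5 = paste(sums, collapse = ";"),
               stringsAsFactors = FALSE))
  invisible(NULL)
}

#' Run the full co-expression analysis pipeline
#'
#' Executes, in order: data simulation (or loading), signed network
#' construction with TOM and edge export, module detection with
#' eigengenes and membership, cross-dataset preservation, gene-set
#' enrichment (hypergeometric, exact and Monte-Carlo clustering tests),
#' and the fold-change DE analysis with chi-square module overlap.  All
#' intermediate results are persisted as TSV under `config$out_dir`.
#'
#' @param config a [pipeline_config()].
#' @return the run manifest: list with the package version, the root
#'   seed, a config checksum, and a per-stage data frame of wall-clock
#'   seconds, output files and their md5 checksums.  Deterministic
#'   stages reproduce identical checksums when rerun with the same
#'   config and seed.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  validate_pipeline_config(config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(...) file.path(config$out_dir, ...)
  env <- new.env()
  env$stages <- data.frame()

  # stage 1: simulate or load ------------------------------------------------
  truth <- NULL
  sets <- NULL
  run_stage("simulate", env, {
    if (is.null(config$expr_path)) {
      sim <- simulate_expression(config$sim)
      env$expr <- sim$expr
      truth <- sim$truth
      write_expression(sim$expr, out("expression.tsv"))
      write_partition(truth$partition, out("truth_partition.tsv"))
      files <- c(out("expression.tsv"), out("truth_partition.tsv"))
      if (length(truth$planted_set) > 0L) {
        write_gmt(gene_set("NBIA_LIKE", truth$planted_set),
                  out("planted_set.gmt"))
        sets <- list(gene_set("NBIA_LIKE", truth$planted_set))
        files <- c(files, out("planted_set.gmt"))
      }
      files
    } else {
      env$expr <- read_expression(config$expr_path)
      if (!is.null(config$sets_path)) {
        sets <- read_gmt(config$sets_path)
      }
      character(0)
    }
  })

  # stage 2: network ----------------------------------------------------------
  run_stage("network", env, {
    r <- correlation_matrix(env$expr)
    adj <- signed_adjacency(r, config$beta)
    env$fit <- scale_free_fit(adj)
    env$tom <- compute_tom(adj)
    ed <- export_edges(env$tom, config$tom_edge_cutoff)
    write_edges(ed$edges, out("edges.tsv"))
    out("edges.tsv")
  })

  # stage 3: modules ----------------------------------------------------------
  run_stage("modules", env, {
    part <- detect_modules(tom_dissimilarity(env$tom),
                           min_module_size = config$min_module_size,
                           cut_height = config$cut_height,
                           expr = env$expr,
                           merge_height = config$merge_height)
    env$partition <- part
    write_partition(part, out("modules.tsv"))
    files <- out("modules.tsv")
    if (length(part$labels) > 0L) {
      me <- module_eigengenes(env$expr, part)
      mm <- module_membership(env$expr, me, part)
      env$membership <- mm
      eg <- data.frame(sample = rownames(me$eigengenes),
                       apply(me$eigengenes, 2L, fmt_num),
                       stringsAsFactors = FALSE, check.names = FALSE)
      write_tsv_raw(eg, out("eigengenes.tsv"))
      tab <- mm$table
      tab$kme <- ifelse(is.na(tab$kme), "NA", fmt_num(tab$kme))
      write_tsv_raw(tab, out("membership.tsv"))
      files <- c(files, out("eigengenes.tsv"), out("membership.tsv"))
    }
    files
  })

  # stage 4: preservation ------------------------------------------------------
  run_stage("preservation", env, {
    test_expr <- if (!is.null(config$test_path)) {
      read_expression(config$test_path)
    } else if (!is.null(truth)) {
      preserved <- config$preserved_modules
      if (is.null(preserved)) {
        preserved <- rownames(truth$latent_factors)[1L]
      }
      px <- simulate_paired_dataset(truth, preserved, config$sim)
      write_expression(px, out("expression_test.tsv"))
      px
    } else {
      NULL
    }
    if (is.null(test_expr) || length(env$partition$labels) == 0L) {
      character(0)
    } else {
      pres <- preservation_zsummary(env$expr, test_expr, env$partition,
                                    beta = config$beta,
                                    n_perm = config$preservation_n_perm,
                                    seed = derive_seed(config$seed, "pres"))
      env$preservation <- pres
      df <- as.data.frame(pres)
      num <- vapply(df, is.numeric, logical(1)) & names(df) != "size"
      df[num] <- lapply(df[num], fmt_num)
      write_tsv_raw(df, out("preservation.tsv"))
      files <- out("preservation.tsv")
      if (is.null(config$test_path)) {
        files <- c(files, out("expression_test.tsv"))
      }
      files
    }
  })

  # stage 5: enrichment ---------------------------------------------------------
  run_stage("enrichment", env, {
    if (is.null(sets) || length(env$partition$labels) == 0L) {
      character(0)
    } else {
    part <- env$partition
    n_bg <- length(part$assignments)
    rows <- list()
    for (s in sets) {
      for (l in part$labels) {
        mod_genes <- names(part$assignments)[part$assignments == l]
        hg <- hypergeom_enrich(mod_genes, s$genes, n_bg)
        rows[[length(rows) + 1L]] <- data.frame(
          set = s$name, module = l, method = "hypergeometric",
          observed = hg$observed, module_size = length(mod_genes),
          set_size = length(s$genes), background = n_bg,
          p_value = hg$p_value, mc_se = NA_real_,
          stringsAsFactors = FALSE)
      }
      # clustering test: g = largest overlap with one module, m = that
      # module's size
      ov <- vapply(part$labels, function(l) {
        length(intersect(s$genes,
                         names(part$assignments)[part$assignments == l]))
      }, integer(1))
      best <- which.max(ov)
      if (ov[best] >= 1L) {
        g <- ov[best]
        m <- module_sizes(part, include_unassigned = FALSE)[
          part$labels[best]]
        p_exact <- exact_cluster_prob(part, g, m)
        spec <- cluster_test_spec(g, m, n_perm = config$permtest_n_perm,
                                  seed = derive_seed(config$seed, "perm"))
        pt <- permutation_cluster_test(part, spec)
        rows[[length(rows) + 1L]] <- data.frame(
          set = s$name, module = part$labels[best], method = "exact",
          observed = g, module_size = unname(m),
          set_size = length(s$genes), background = n_bg,
          p_value = p_exact, mc_se = NA_real_, stringsAsFactors = FALSE)
        rows[[length(rows) + 1L]] <- data.frame(
          set = s$name, module = part$labels[best],
          method = "permutation", observed = g, module_size = unname(m),
          set_size = length(s$genes), background = n_bg,
          p_value = pt$p_value, mc_se = pt$mc_se,
          stringsAsFactors = FALSE)
      }
    }
    df <- do.call(rbind, rows)
    env$enrichment <- df
    df$p_value <- fmt_num(df$p_value)
    df$mc_se <- ifelse(is.na(df$mc_se), "NA", fmt_num(df$mc_se))
    write_tsv_raw(df, out("enrichment.tsv"))
    out("enrichment.tsv")
    }
  })

  # stage 6: differential expression -------------------------------------------
  run_stage("de", env, {
    if (is.null(truth) || length(truth$planted_set) == 0L ||
        length(env$partition$labels) == 0L) {
      character(0)
    } else {
    control <- linearize_expression(env$expr)
    fold_spec <- stats::setNames(rep(config$de_fold,
                                     length(truth$planted_set)),
                                 truth$planted_set)
    case <- simulate_disease(control, fold_spec)
    de <- de_fold_change_filter(case, control, config$de_threshold)
    env$de <- de
    # chi-square overlap of the DE list with the set-enriched module
    part <- env$partition
    top <- if (!is.null(env$enrichment)) {
      hg <- env$enrichment[env$enrichment$method == "hypergeometric", ]
      hg$module[which.min(hg$p_value)]
    } else {
      part$labels[1L]
    }
    in_mod <- part$assignments[de$gene] == top
    tab <- matrix(c(sum(de$passes & in_mod), sum(de$passes & !in_mod),
                    sum(!de$passes & in_mod), sum(!de$passes & !in_mod)),
                  nrow = 2L, byrow = TRUE)
    env$de_overlap <- chisq_overlap(tab)
    df <- de
    for (cc in c("mean_case", "mean_control", "fold_change")) {
      df[[cc]] <- fmt_num(df[[cc]])
    }
    write_tsv_raw(df, out("de_results.tsv"))
    out("de_results.tsv")
    }
  })

  # manifest -------------------------------------------------------------------
  cfg_file <- out("config.txt")
  writeLines(utils::capture.output(utils::str(config)), cfg_file)
  manifest <- list(
    tool = "coexmod",
    version = as.character(utils::packageVersion("coexmod")),
    seed = config$seed,
    config_md5 = unname(tools::md5sum(cfg_file)),
    scale_free_fit = env$fit,
    stages = env$stages)
  write_tsv_raw(env$stages, out("manifest.tsv"))
  manifest$results <- list(partition = env$partition,
                           membership = env$membership,
                           preservation = env$preservation,
                           enrichment = env$enrichment,
                           de = env$de,
                           de_overlap = env$de_overlap)
  class(manifest) <- "run_manifest"
  manifest
}

#' @export
print.run_manifest <- function(x, ...) {
  cat("coexmod run manifest (version", x$version, ", seed", x$seed,
      ")\n")
  print(x$stages[, c("stage", "seconds", "outputs")])
  invisible(x)
}
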