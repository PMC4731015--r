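# Readers and writers for the package's plain-text formats.
#
# Dialect: UTF-8, tab-separated, "." decimal, mandatory header row,
# gene IDs in column 1.  Numbers are written with 17 significant digits
# so that write -> read round-trips doubles exactly and repeated runs
# produce byte-identical files.

fmt_num <- function(x) {
  vapply(x, function(v) sprintf("%.17g", v), character(1))
}

write_tsv_raw <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
}

#' Write an expression matrix as TSV
#'
#' First column `gene_id`, then one column per sample.
#'
#' @param expr numeric genes-by-samples matrix with dimnames.
#' @param path output file.
#' @export
write_expression <- function(expr, path) {
  df <- data.frame(gene_id = rownames(expr),
                   apply(expr, 2L, fmt_num),
                   stringsAsFactors = FALSE, check.names = FALSE)
  write_tsv_raw(df, path)
  invisible(path)
}

#' Read an expression matrix from TSV
#'
#' @param path TSV file written by [write_expression()] (or compatible:
#'   header row of sample IDs, gene IDs in column 1).
#' @return numeric genes-by-samples matrix.
#' @export
read_expression <- function(path) {
  df <- tryCatch(
    utils::read.delim(path, header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE, check.names = FALSE,
                      fill = FALSE),
    error = function(e) {
      stop_coexmod(paste("malformed expression file:",
                         conditionMessage(e)), "coexmod_ragged")
    })
  if (ncol(df) < 2L) {
    stop_coexmod("expression file needs a gene column and >= 1 sample",
                 "coexmod_ragged")
  }
  ids <- as.character(df[[1L]])
  if (anyDuplicated(ids)) {
    stop_coexmod("duplicate gene IDs in expression file",
                 "coexmod_duplicate_id")
  }
  m <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(m)) storage.mode(m) <- "double"
  if (anyNA(m)) {
    stop_coexmod("non-numeric or missing expression values",
                 "coexmod_ragged")
  }
  rownames(m) <- ids
  m
}

#' Write a module partition as two-column TSV
#'
#' @param partition a [module_partition].
#' @param path output file.
#' @export
write_partition <- function(partition, path) {
  df <- data.frame(gene = names(partition$assignments),
                   module = unname(partition$assignments),
                   stringsAsFactors = FALSE)
  write_tsv_raw(df, path)
  invisible(path)
}

#' Read a module partition from two-column TSV
#'
#' @param path TSV with columns gene, module.
#' @param unassigned_label reserved unassigned label.
#' @return a [module_partition].
#' @export
read_partition <- function(path, unassigned_label = "grey") {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2L) {
    stop_coexmod("partition file needs two columns (gene, module)",
                 "coexmod_ragged")
  }
  if (anyDuplicated(df[[1L]])) {
    stop_coexmod("gene listed twice in partition file",
                 "coexmod_duplicate_id")
  }
  module_partition(stats::setNames(as.character(df[[2L]]),
                                   as.character(df[[1L]])),
                   unassigned_label = unassigned_label)
}

#' Write gene sets in GMT format
#'
#' One record per line: set name, description, then tab-separated gene
#' IDs.
#'
#' @param sets a [gene_set] or list of them.
#' @param path output file.
#' @param description description field (recycled).
#' @export
write_gmt <- function(sets, path, description = "coexmod") {
  if (inherits(sets, "gene_set")) sets <- list(sets)
  lines <- vapply(sets, function(s) {
    paste(c(s$name, description, s$genes), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read gene sets from a GMT file
#'
#' @param path GMT file (set name, description, then gene IDs).
#' @return list of [gene_set] objects.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  lapply(lines, function(ln) {
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
    if (length(parts) < 3L) {
      stop_coexmod(sprintf("empty GMT record: '%s'",
                           substr(ln, 1L, 40L)),
                   "coexmod_empty_gmt")
    }
    gene_set(parts[1L], parts[-(1:2)])
  })
}

#' Write an edge list as three-column TSV
#'
#' @param edges data frame with columns gene_a, gene_b, weight (as
#'   produced by [export_edges()]).
#' @param path output file.
#' @export
write_edges <- function(edges, path) {
  df <- edges
  df$weight <- fmt_num(df$weight)
  write_tsv_raw(df, path)
  invisible(path)
}
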