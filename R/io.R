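#' Read a count/expression matrix and sample sheet from TSV
#'
#' The matrix file has gene ids in the first column and sample ids in the
#' header; the sample sheet has columns `sample_id` and `condition`.
#'
#' @param counts_path Path to the gene x sample TSV.
#' @param samples_path Path to the sample-sheet TSV.
#' @param normalised Whether the values are already normalised.
#' @return An [expression_matrix()].
#' @export
read_expression_tsv <- function(counts_path, samples_path,
                                normalised = FALSE) {
  dt <- data.table::fread(counts_path, sep = "\t", header = TRUE,
                          data.table = FALSE)
  if (ncol(dt) < 2) stop("matrix TSV needs an id column plus >= 1 sample")
  ids <- as.character(dt[[1]])
  if (anyDuplicated(ids))
    stop("duplicate gene id in ", counts_path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  vals <- dt[, -1, drop = FALSE]
  bad <- names(vals)[!vapply(vals, is.numeric, logical(1))]
  if (length(bad))
    stop("non-numeric cells in column(s): ", paste(bad, collapse = ", "))
  m <- as.matrix(vals)
  storage.mode(m) <- "double"
  rownames(m) <- ids
  expression_matrix(m, read_sample_sheet(samples_path),
                    normalised = normalised)
}

#' @rdname read_expression_tsv
#' @export
read_sample_sheet <- function(samples_path) {
  ss <- utils::read.delim(samples_path, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "condition") %in% names(ss)))
    stop("sample sheet needs columns 'sample_id' and 'condition'")
  if (anyDuplicated(ss$sample_id))
    stop("duplicate sample id: ",
         paste(unique(ss$sample_id[duplicated(ss$sample_id)]), collapse = ", "))
  stats::setNames(as.character(ss$condition), ss$sample_id)
}

#' Write an expression matrix (and companions) as TSV
#'
#' Numeric values are serialised with 17 significant digits so that a
#' write/read round trip reproduces doubles exactly.
#'
#' @param x An [expression_matrix()].
#' @param path Output file.
#' @export
write_expression_tsv <- function(x, path) {
  stopifnot(inherits(x, "expression_matrix"))
  v <- x$values
  out <- matrix(sprintf("%.17g", v), nrow(v))
  lines <- c(paste(c("gene_id", colnames(v)), collapse = "\t"),
             paste(rownames(v), apply(out, 1, paste, collapse = "\t"),
                   sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_expression_tsv
#' @export
write_sample_sheet <- function(x, path) {
  stopifnot(inherits(x, "expression_matrix"))
  utils::write.table(
    data.frame(sample_id = names(x$condition), condition = x$condition),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @param ids Character vector of gene ids, written one per line.
#' @rdname write_expression_tsv
#' @export
write_gene_list <- function(ids, path) {
  writeLines(as.character(ids), path)
  invisible(path)
}

#' @param path Path to a plain-text gene list (one id per line).
#' @rdname read_expression_tsv
#' @export
read_gene_list <- function(path) {
  ids <- readLines(path)
  ids[nzchar(ids)]
}

# data.frame results (DE tables, null vectors) as TSV, full precision
write_result_tsv <- function(df, path) {
  num <- vapply(df, is.double, logical(1))
  df[num] <- lapply(df[num], function(col) sprintf("%.17g", col))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
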