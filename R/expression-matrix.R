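#' Expression matrix with condition annotations
#'
#' Lightweight container for a gene x sample numeric matrix together with the
#' condition label of every sample. This is the substrate of every stage of
#' the pipeline: raw counts go into [size_factors()] and [normalise_counts()],
#' normalised values into the differential-expression and hypernetwork stages.
#'
#' @param values Numeric gene x sample matrix with unique rownames (gene ids)
#'   and unique colnames (sample ids). All entries must be non-negative and
#'   finite.
#' @param condition Condition label per sample: either a character vector
#'   named by sample id, or an unnamed vector in column order.
#' @param normalised Logical; `TRUE` once values are on a depth-normalised
#'   scale. Stages that require normalised input check this flag.
#'
#' @return An object of class `"expression_matrix"`: a list with elements
#'   `values`, `condition` (named by sample id) and `normalised`.
#' @examples
#' m <- matrix(rpois(12, 20), 4, 3,
#'             dimnames = list(paste0("g", 1:4), paste0("s", 1:3)))
#' x <- expression_matrix(m, c(s1 = "wt", s2 = "wt", s3 = "vector"))
#' x
#' @export
expression_matrix <- function(values, condition, normalised = FALSE) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("'values' must have gene rownames and sample colnames")
  if (anyDuplicated(rownames(values)))
    stop("duplicate gene ids: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]), collapse = ", "))
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample ids: ",
         paste(unique(colnames(values)[duplicated(colnames(values))]), collapse = ", "))
  if (any(!is.finite(values)) || any(values < 0))
    stop("'values' must be non-negative and finite")
  condition <- as.character(condition) |>
    stats::setNames(if (is.null(names(condition))) colnames(values) else names(condition))
  missing <- setdiff(colnames(values), names(condition))
  if (length(missing))
    stop("condition undefined for sample(s): ", paste(missing, collapse = ", "))
  structure(
    list(values = values,
         condition = condition[colnames(values)],
         normalised = isTRUE(normalised)),
    class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix: %d genes x %d samples (%s)\n",
              nrow(x$values), ncol(x$values),
              if (x$normalised) "normalised" else "raw counts"))
  tab <- table(x$condition)
  cat("conditions:", paste(sprintf("%s (n=%d)", names(tab), tab), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.expression_matrix <- function(x) dim(x$values)

# Sample ids belonging to one condition label; errors on unknown labels.
condition_samples <- function(x, condition) {
  stopifnot(inherits(x, "expression_matrix"))
  if (!condition %in% x$condition)
    stop("unknown condition label: ", condition)
  names(x$condition)[x$condition == condition]
}
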