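#' Median-of-ratios size factors
#'
#' Estimates one positive scaling factor per sample by the geometric
#' (median-of-ratios) method: each gene's geometric mean across samples serves
#' as a pseudo-reference, genes containing any zero are excluded from the
#' reference, and a sample's factor is the median over reference genes of the
#' ratio count / geometric mean. Dividing each column by its factor removes
#' between-sample differences in sequencing depth.
#'
#' @param x An [expression_matrix()] of raw counts.
#' @return Named numeric vector of positive size factors, one per sample.
#' @seealso [normalise_counts()]
#' @examples
#' m <- matrix(c(1, 2, 4, 2, 4, 8), 3, 2,
#'             dimnames = list(paste0("g", 1:3), c("a", "b")))
#' x <- expression_matrix(m, c(a = "wt", b = "wt"))
#' size_factors(x)  # 1/sqrt(2), sqrt(2)
#' @export
size_factors <- function(x) {
  stopifnot(inherits(x, "expression_matrix"))
  counts <- x$values
  log_geo <- rowMeans(log(counts))
  ref <- is.finite(log_geo)          # genes with a zero anywhere drop out
  if (!any(ref))
    stop("no reference genes: every gene has a zero count in some sample")
  apply(log(counts[ref, , drop = FALSE]) - log_geo[ref], 2,
        function(r) exp(stats::median(r)))
}

#' Normalise counts by size factors
#'
#' Divides each sample column by its size factor and flags the result as
#' normalised.
#'
#' @param x An [expression_matrix()] of raw counts.
#' @param factors Size factors; computed with [size_factors()] by default.
#' @return A normalised `expression_matrix`.
#' @export
normalise_counts <- function(x, factors = size_factors(x)) {
  stopifnot(inherits(x, "expression_matrix"))
  if (length(factors) != ncol(x$values) || any(factors <= 0))
    stop("'factors' must be one positive value per sample")
  expression_matrix(sweep(x$values, 2, factors, "/"), x$condition,
                    normalised = TRUE)
}

#' Filter genes by minimum expression
#'
#' Keeps genes whose mean normalised expression reaches `threshold` in at
#' least one condition, mirroring the role of an FPKM-style low-expression
#' cut-off. The threshold is applied on whatever normalised scale the matrix
#' carries; gene order is preserved.
#'
#' @param x A normalised [expression_matrix()].
#' @param threshold Non-negative expression cut-off (default 10).
#' @return A filtered `expression_matrix`.
#' @export
filter_expression <- function(x, threshold = 10) {
  stopifnot(inherits(x, "expression_matrix"))
  if (!x$normalised) stop("filter_expression() expects a normalised matrix")
  if (!is.numeric(threshold) || length(threshold) != 1 || threshold < 0)
    stop("'threshold' must be a single non-negative number")
  cond_means <- vapply(unique(x$condition), function(cc)
    rowMeans(x$values[, condition_samples(x, cc), drop = FALSE]),
    numeric(nrow(x$values)))
  keep <- apply(cond_means, 1, max) >= threshold
  expression_matrix(x$values[keep, , drop = FALSE], x$condition,
                    normalised = TRUE)
}
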