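#' Manhattan distance matrix between a gene set and the transcriptome
#'
#' For every gene of `gene_set` (rows) and every gene of the matrix
#' (columns), the Manhattan (L1) distance between their expression profiles
#' over the selected samples:
#' `d(i, j) = sum_s |x_is - x_js|`. The L1 metric is used because it
#' degrades more gracefully than Euclidean distance as dimensionality grows.
#' Distances are computed on `log2(x + 1)` by default so that a handful of
#' highly expressed transcripts does not dominate; `transform = "none"`
#' keeps the scale of the input. Each row gene's own column is masked
#' (`NA`): a self-distance of zero would otherwise always survive
#' binarisation and inflate every hypernetwork uniformly.
#'
#' @param x A normalised [expression_matrix()].
#' @param gene_set Character vector of row genes; must exist in `x`.
#' @param condition Condition label whose replicate columns are used.
#'   Alternatively pass explicit `samples`.
#' @param samples Explicit sample ids (overrides `condition`).
#' @param transform `"log2p1"` (default) or `"none"`.
#' @return Object of class `"distance_matrix"`: list with `values`
#'   (`n_set x n_total`, self-pairs `NA`), `row_genes`, `col_genes`,
#'   `samples`, `transform`.
#' @export
manhattan_distance_matrix <- function(x, gene_set, condition = NULL,
                                      samples = NULL,
                                      transform = c("log2p1", "none")) {
  stopifnot(inherits(x, "expression_matrix"))
  transform <- match.arg(transform)
  if (is.null(samples)) {
    if (is.null(condition)) stop("give either 'condition' or 'samples'")
    samples <- condition_samples(x, condition)
  }
  unknown <- setdiff(samples, colnames(x$values))
  if (length(unknown)) stop("unknown sample(s): ", paste(unknown, collapse = ", "))
  if (length(gene_set) == 0) stop("empty gene set")
  if (anyDuplicated(gene_set)) stop("duplicated ids in gene set")
  ridx <- match(gene_set, rownames(x$values))
  if (anyNA(ridx))
    stop("gene(s) not in matrix: ",
         paste(gene_set[is.na(ridx)], collapse = ", "))
  v <- x$values[, samples, drop = FALSE]
  if (transform == "log2p1") v <- log2(v + 1)
  d <- matrix(0, length(ridx), nrow(v),
              dimnames = list(gene_set, rownames(v)))
  for (s in seq_along(samples))
    d <- d + abs(outer(v[ridx, s], v[, s], "-"))
  d[cbind(seq_along(ridx), ridx)] <- NA_real_
  structure(list(values = d, row_genes = gene_set,
                 col_genes = rownames(v), samples = samples,
                 transform = transform),
            class = "distance_matrix")
}

#' Binarise a distance matrix at a centile threshold
#'
#' Computes the centile threshold `t` by linear interpolation between order
#' statistics (quantile type 7) over all finite entries, then marks an entry
#' 1 when its distance is `<= t` — i.e. only the closest relationships are
#' retained, a fraction of about `centile/100` of all pairs (exactly so up
#' to ties at the threshold, which are retained). Masked self-pairs stay 0.
#'
#' @param dist A `"distance_matrix"` (or a plain numeric matrix; `NA`
#'   entries are treated as masked).
#' @param centile Centile in (0, 100); default 30.
#' @param scope `"global"` (one threshold over the whole matrix, the
#'   default) or `"row"` (a threshold per row gene, for sensitivity
#'   analysis).
#' @return Object of class `"incidence_matrix"`: list with the binary
#'   integer matrix `M`, the `centile`, the attained `threshold` (vector of
#'   per-row thresholds when `scope = "row"`), and gene id vectors.
#' @export
binarise <- function(dist, centile = 30, scope = c("global", "row")) {
  scope <- match.arg(scope)
  d <- if (inherits(dist, "distance_matrix")) dist$values else dist
  if (!is.matrix(d) || !is.numeric(d)) stop("'dist' must be a numeric matrix")
  if (length(d) == 0 || !any(is.finite(d))) stop("empty distance matrix")
  if (!is.numeric(centile) || length(centile) != 1 ||
      centile <= 0 || centile >= 100)
    stop("'centile' must lie strictly between 0 and 100")
  p <- centile / 100
  if (scope == "global") {
    thr <- unname(stats::quantile(d[is.finite(d)], p, type = 7))
    m <- d <= thr
  } else {
    thr <- apply(d, 1, function(r)
      unname(stats::quantile(r[is.finite(r)], p, type = 7)))
    m <- sweep(d, 1, thr, "<=")
  }
  m[is.na(m)] <- FALSE
  storage.mode(m) <- "integer"
  structure(list(M = m, centile = centile, threshold = thr,
                 row_genes = rownames(d), col_genes = colnames(d)),
            class = "incidence_matrix")
}

#' Build the hypernetwork of shared binary relationships
#'
#' Multiplies the binary incidence matrix by its transpose:
#' `H = M %*% t(M)`, so `H[i, j]` counts the transcriptome genes to which
#' both row gene i and row gene j are "close" (share a retained
#' relationship). H is symmetric, `H[i, i]` is the number of relationships
#' of gene i, and `H[i, j] <= min(H[i, i], H[j, j])`. Mean connectivity and
#' per-gene Shannon entropy are attached.
#'
#' @param m An `"incidence_matrix"` from [binarise()], or a plain binary
#'   matrix.
#' @return Object of class `"hypernetwork"`: list with `H`, `gene_ids`,
#'   `n_total` (number of incidence columns), `connectivity` (diagonal
#'   included), `connectivity_offdiag`, and `entropy` (per-gene bits;
#'   `NULL` for a single-gene set).
#' @export
build_hypernetwork <- function(m) {
  mm <- if (inherits(m, "incidence_matrix")) m$M else m
  if (!is.matrix(mm) || !all(mm %in% c(0L, 1L)))
    stop("incidence matrix must be binary (0/1)")
  storage.mode(mm) <- "numeric"
  h <- tcrossprod(mm)
  n <- nrow(h)
  structure(
    list(H = h, gene_ids = rownames(mm), n_total = ncol(mm),
         connectivity = mean(h),
         connectivity_offdiag = if (n > 1) connectivity(h, include_diagonal = FALSE)
                                else NA_real_,
         entropy = if (n >= 2) entropy_per_gene(h) else NULL),
    class = "hypernetwork")
}

#' @export
print.hypernetwork <- function(x, ...) {
  cat(sprintf("hypernetwork: %d genes over %d transcriptome columns\n",
              nrow(x$H), x$n_total))
  cat(sprintf("connectivity (mean of H): %.3f (off-diagonal: %.3f)\n",
              x$connectivity, x$connectivity_offdiag))
  if (!is.null(x$entropy))
    cat(sprintf("median per-gene entropy: %.3f bits\n",
                stats::median(x$entropy)))
  invisible(x)
}

#' Mean connectivity of a hypernetwork
#'
#' The arithmetic mean of all entries of H. The diagonal (each gene's own
#' relationship count) is included by default; `include_diagonal = FALSE`
#' averages the off-diagonal shared counts only.
#'
#' @param h A `"hypernetwork"` or a square numeric matrix.
#' @param include_diagonal Include `H[i, i]` in the mean (default `TRUE`).
#' @return Single numeric value.
#' @export
connectivity <- function(h, include_diagonal = TRUE) {
  hh <- if (inherits(h, "hypernetwork")) h$H else h
  if (!is.matrix(hh) || nrow(hh) != ncol(hh) || length(hh) == 0)
    stop("'h' must be a non-empty square matrix or hypernetwork")
  if (include_diagonal) return(mean(hh))
  n <- nrow(hh)
  if (n == 1) stop("off-diagonal connectivity undefined for a single gene")
  (sum(hh) - sum(diag(hh))) / (n^2 - n)
}

#' Per-gene Shannon entropy of hypernetwork connections
#'
#' For each gene the off-diagonal entries of its row of H are normalised to
#' a probability vector p over the other set genes, and the Shannon entropy
#' `-sum(p * log2(p))` (with `0 * log 0 := 0`) is returned in bits. Low
#' entropy means the gene's shared relationships concentrate on few
#' partners (coordinated organisation); the maximum, `log2(n_set - 1)`,
#' means they are spread uniformly. A gene sharing no relationship with any
#' other (all-zero row) is assigned entropy 0.
#'
#' @param h A `"hypernetwork"` or square numeric matrix with >= 2 rows.
#' @return Named numeric vector of entropies in bits.
#' @export
entropy_per_gene <- function(h) {
  hh <- if (inherits(h, "hypernetwork")) h$H else h
  if (!is.matrix(hh) || nrow(hh) != ncol(hh))
    stop("'h' must be a square matrix or hypernetwork")
  n <- nrow(hh)
  if (n < 2) stop("entropy needs a set of >= 2 genes")
  ent <- vapply(seq_len(n), function(i) {
    p <- hh[i, -i]
    s <- sum(p)
    if (s == 0) return(0)
    p <- p[p > 0] / s
    -sum(p * log2(p))
  }, numeric(1))
  names(ent) <- rownames(hh)
  ent
}
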