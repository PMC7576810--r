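#' Randomised gene-set null distribution
#'
#' Rebuilds the full hypernetwork pipeline (Manhattan distances ->
#' centile binarisation -> `M %*% t(M)`) `n_iter` times, each time on a
#' set of `set_size` genes sampled uniformly without replacement from the
#' eligible universe, and records the connectivity and the median per-gene
#' entropy of every null hypernetwork. Comparing an observed gene set
#' against this distribution asks whether its transcriptome-wide
#' organisation could have arisen from an arbitrary set of the same size.
#'
#' A single master seed deterministically derives one sub-seed per
#' iteration, so the null is reproducible bit-for-bit and independent of
#' scheduling.
#'
#' @param x A normalised [expression_matrix()].
#' @param condition Condition whose replicate columns are used (or pass
#'   `samples`).
#' @param set_size Number of genes per random set.
#' @param n_iter Number of random sets (default 1000).
#' @param centile Binarisation centile (default 30).
#' @param transform Distance scale, as in [manhattan_distance_matrix()].
#' @param seed Master seed.
#' @param genes Eligible gene universe (default: every gene in `x`,
#'   including any observed DE genes — random sets are drawn without
#'   exclusions).
#' @param samples Explicit sample ids overriding `condition`.
#' @return Object of class `"null_distribution"`: list with
#'   `connectivity_null` and `entropy_null` (length `n_iter`), `set_size`,
#'   `n_iter`, `centile`, `seed`.
#' @seealso [empirical_p()]
#' @export
null_distribution <- function(x, condition = NULL, set_size, n_iter = 1000,
                              centile = 30, transform = "log2p1", seed = 1L,
                              genes = NULL, samples = NULL) {
  stopifnot(inherits(x, "expression_matrix"))
  if (is.null(genes)) genes <- rownames(x$values)
  if (set_size > length(genes))
    stop("set_size (", set_size, ") exceeds the ", length(genes),
         " eligible genes")
  if (set_size < 2) stop("set_size must be >= 2")
  if (n_iter < 1) stop("n_iter must be >= 1")
  set.seed(seed)
  sub_seeds <- sample.int(.Machine$integer.max, n_iter)
  conn <- ent <- numeric(n_iter)
  for (i in seq_len(n_iter)) {
    set.seed(sub_seeds[i])
    gs <- sample(genes, set_size)
    hn <- build_hypernetwork(binarise(
      manhattan_distance_matrix(x, gs, condition = condition,
                                samples = samples, transform = transform),
      centile = centile))
    conn[i] <- hn$connectivity
    ent[i] <- stats::median(hn$entropy)
  }
  structure(list(connectivity_null = conn, entropy_null = ent,
                 set_size = as.integer(set_size),
                 n_iter = as.integer(n_iter), centile = centile,
                 seed = as.integer(seed)),
            class = "null_distribution")
}

#' Empirical (add-one) permutation p-value
#'
#' `p = (1 + k) / (1 + n)` where `k` counts null values at least as extreme
#' as the observation (ties count as extreme). The add-one form never
#' returns 0: the smallest attainable p is `1 / (n_iter + 1)`.
#'
#' @param observed Observed statistic.
#' @param null Numeric vector of null statistics.
#' @param tail `"greater"` (extreme = `null >= observed`) or `"less"`.
#' @return p-value in `[1/(n+1), 1]`.
#' @export
empirical_p <- function(observed, null, tail = c("greater", "less")) {
  tail <- match.arg(tail)
  if (length(null) == 0) stop("empty null vector")
  k <- if (tail == "greater") sum(null >= observed) else sum(null <= observed)
  (1 + k) / (1 + length(null))
}

#' Compare two per-gene entropy distributions
#'
#' Two-sided Mann-Whitney U (Wilcoxon rank-sum) test between the per-gene
#' entropy vectors of two hypernetworks — a rank test makes no normality
#' assumption about entropy values, which are bounded above by
#' `log2(n_set - 1)`.
#'
#' @param entropy_a,entropy_b Numeric vectors of per-gene entropies
#'   (length >= 2 each), e.g. the `entropy` element of two
#'   [build_hypernetwork()] results.
#' @return List of class `"entropy_comparison"`: `statistic` (U), `p_value`,
#'   `test`, `median_a`, `median_b`.
#' @export
compare_entropy <- function(entropy_a, entropy_b) {
  if (length(entropy_a) < 2 || length(entropy_b) < 2)
    stop("each entropy vector needs >= 2 values")
  wt <- suppressWarnings(
    stats::wilcox.test(entropy_a, entropy_b, alternative = "two.sided"))
  structure(list(statistic = unname(wt$statistic),
                 p_value = wt$p.value,
                 test = "two-sided Mann-Whitney U",
                 median_a = stats::median(entropy_a),
                 median_b = stats::median(entropy_b)),
            class = "entropy_comparison")
}

#' @export
print.entropy_comparison <- function(x, ...) {
  cat(sprintf("%s: U = %g, p = %.3g\nmedians: %.3f vs %.3f bits\n",
              x$test, x$statistic, x$p_value, x$median_a, x$median_b))
  invisible(x)
}
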