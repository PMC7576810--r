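# Welch p-value for one gene, with an explicit convention when t.test would
# fail on constant data: identical means -> 1, separated means -> 0.
welch_p <- function(a, b) {
  tryCatch(stats::t.test(a, b)$p.value,
           error = function(e)
             if (isTRUE(all.equal(mean(a), mean(b)))) 1 else 0)
}

#' Pairwise differential expression versus a reference condition
#'
#' Per-gene test on `log2(x + pseudocount)` between two conditions, with
#' fold changes computed as `log2((mean_a + c) / (mean_b + c))` on the
#' normalised scale and Benjamini-Hochberg adjustment across all tested
#' genes. A gene is flagged significant when both
#' `|log2fc| > fc_threshold` and `p_adj < alpha`.
#'
#' The default engine is the limma moderated t-statistic with a
#' mean-variance trend (`lmFit` + `eBayes(trend = TRUE)`): with the two or
#' three replicates per condition typical of this design, a per-gene
#' two-sample test has so few degrees of freedom that its p-values cannot
#' survive FDR adjustment even for large true fold changes, whereas
#' empirical-Bayes variance moderation borrows the transcriptome-wide
#' mean-variance relationship and restores power without inflating the
#' type-I error. `method = "welch"` runs a plain per-gene Welch t-test
#' instead.
#'
#' @param x A normalised [expression_matrix()].
#' @param cond_a,cond_b Condition labels to contrast (`cond_b` is typically
#'   the vector control); each needs at least two replicates.
#' @param fc_threshold Absolute log2 fold-change cut-off (default 0.6).
#' @param alpha FDR-adjusted significance level (default 0.05).
#' @param pseudocount Added before log transforms and to fold-change means
#'   (default 1).
#' @param method `"moderated"` (limma, default) or `"welch"`.
#' @return A data.frame of class `"de_result"` with columns `gene_id`,
#'   `log2fc`, `p_raw`, `p_adj`, `significant`; the contrast label is stored
#'   in `attr(, "comparison")`.
#' @export
de_pairwise <- function(x, cond_a, cond_b, fc_threshold = 0.6, alpha = 0.05,
                        pseudocount = 1, method = c("moderated", "welch")) {
  stopifnot(inherits(x, "expression_matrix"))
  method <- match.arg(method)
  if (!x$normalised) stop("de_pairwise() expects a normalised matrix")
  sa <- condition_samples(x, cond_a)
  sb <- condition_samples(x, cond_b)
  if (length(sa) < 2 || length(sb) < 2)
    stop("each condition needs >= 2 replicates (",
         cond_a, ": ", length(sa), ", ", cond_b, ": ", length(sb), ")")
  va <- x$values[, sa, drop = FALSE]
  vb <- x$values[, sb, drop = FALSE]
  log2fc <- log2((rowMeans(va) + pseudocount) / (rowMeans(vb) + pseudocount))
  la <- log2(va + pseudocount)
  lb <- log2(vb + pseudocount)
  p_raw <- if (method == "moderated") {
    design <- cbind(intercept = 1,
                    a_vs_b = c(rep(1, ncol(la)), rep(0, ncol(lb))))
    fit <- limma::eBayes(limma::lmFit(cbind(la, lb), design), trend = TRUE)
    unname(fit$p.value[, "a_vs_b"])
  } else
    vapply(seq_len(nrow(la)),
           function(i) welch_p(la[i, ], lb[i, ]), numeric(1))
  p_adj <- stats::p.adjust(p_raw, method = "BH")
  res <- data.frame(gene_id = rownames(x$values),
                    log2fc = unname(log2fc),
                    p_raw = p_raw, p_adj = p_adj,
                    significant = abs(log2fc) > fc_threshold & p_adj < alpha,
                    row.names = NULL)
  attr(res, "comparison") <- paste0(cond_a, "_vs_", cond_b)
  class(res) <- c("de_result", "data.frame")
  res
}

#' Group ANOVA across all conditions
#'
#' Per-gene one-way fixed-effects ANOVA on `log2(x + pseudocount)` across
#' three or more conditions, flagging genes whose adjusted p-value falls
#' below `alpha` as discriminating between the groups. With `robust = TRUE`
#' a Kruskal-Wallis rank test replaces the ANOVA.
#'
#' @param x A normalised [expression_matrix()].
#' @param conditions Conditions to include (default: all present); at least
#'   three, each with >= 2 replicates.
#' @param alpha Upper bound on the BH-adjusted p-value for the
#'   `discriminating` flag (default 0.01).
#' @param robust Use Kruskal-Wallis instead of ANOVA.
#' @param pseudocount Added before the log transform.
#' @return Data.frame with columns `gene_id`, `p_raw`, `p_adj`,
#'   `discriminating`; the adjusted-p range of discriminating genes is in
#'   `attr(, "p_range")`.
#' @export
anova_groups <- function(x, conditions = NULL, alpha = 0.01, robust = FALSE,
                         pseudocount = 1) {
  stopifnot(inherits(x, "expression_matrix"))
  if (!x$normalised) stop("anova_groups() expects a normalised matrix")
  if (is.null(conditions)) conditions <- unique(x$condition)
  if (length(conditions) < 3)
    stop("group ANOVA needs >= 3 conditions, got ", length(conditions))
  samples <- names(x$condition)[x$condition %in% conditions]
  g <- factor(x$condition[samples])
  if (any(table(g) < 2)) stop("every condition needs >= 2 replicates")
  lv <- log2(x$values[, samples, drop = FALSE] + pseudocount)
  p_one <- function(y) {
    if (stats::var(y) == 0) return(1)
    out <- tryCatch(
      if (robust) stats::kruskal.test(y, g)$p.value
      else stats::oneway.test(y ~ g, var.equal = TRUE)$p.value,
      error = function(e) NA_real_)
    if (is.na(out))   # within-group variance zero but groups separated
      out <- if (all(vapply(split(y, g), stats::var, numeric(1)) == 0)) 0 else 1
    out
  }
  p_raw <- apply(lv, 1, p_one)
  p_adj <- stats::p.adjust(p_raw, method = "BH")
  res <- data.frame(gene_id = rownames(x$values), p_raw = p_raw, p_adj = p_adj,
                    discriminating = p_adj < alpha, row.names = NULL)
  attr(res, "p_range") <- if (any(res$discriminating))
    range(res$p_adj[res$discriminating]) else c(NA_real_, NA_real_)
  res
}

#' Partition two DE results into exclusive, concordant and discordant sets
#'
#' The Venn partition feeding the hypernetwork stage: genes significant in
#' exactly one contrast are `exclusive_a` / `exclusive_b`; genes significant
#' in both with the same fold-change direction are `concordant`; genes
#' significant in both with opposite directions are reported separately as
#' `discordant` rather than silently merged.
#'
#' @param de_a,de_b [de_pairwise()] results over the same gene universe.
#' @return List of class `"gene_set_partition"` with character-vector
#'   elements `exclusive_a`, `exclusive_b`, `concordant`, `discordant` and
#'   the two comparison labels as attributes.
#' @export
partition_gene_sets <- function(de_a, de_b) {
  stopifnot(inherits(de_a, "de_result"), inherits(de_b, "de_result"))
  if (!identical(sort(de_a$gene_id), sort(de_b$gene_id)))
    stop("mismatched gene universes between the two DE results")
  de_b <- de_b[match(de_a$gene_id, de_b$gene_id), ]
  sig_a <- de_a$gene_id[de_a$significant]
  sig_b <- de_b$gene_id[de_b$significant]
  both <- intersect(sig_a, sig_b)
  same_sign <- sign(de_a$log2fc[match(both, de_a$gene_id)]) ==
    sign(de_b$log2fc[match(both, de_b$gene_id)])
  structure(
    list(exclusive_a = setdiff(sig_a, both),
         exclusive_b = setdiff(sig_b, both),
         concordant = both[same_sign],
         discordant = both[!same_sign]),
    comparison_a = attr(de_a, "comparison"),
    comparison_b = attr(de_b, "comparison"),
    class = "gene_set_partition")
}

#' @export
print.gene_set_partition <- function(x, ...) {
  cat(sprintf(
    "gene_set_partition: %d exclusive to %s, %d exclusive to %s, %d concordant, %d discordant\n",
    length(x$exclusive_a), attr(x, "comparison_a"),
    length(x$exclusive_b), attr(x, "comparison_b"),
    length(x$concordant), length(x$discordant)))
  invisible(x)
}
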