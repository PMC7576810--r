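#' Configuration for the end-to-end pipeline
#'
#' Collects every tunable of the analysis in one place. Defaults follow the
#' study design the package emulates: expression filter 10, |log2FC| > 0.6
#' with FDR 0.05 for the pairwise contrasts, adjusted p < 0.01 for the group
#' ANOVA, 30th-centile binarisation, 1000 null iterations.
#'
#' @param counts An in-memory [expression_matrix()] of raw counts, or `NULL`
#'   if `counts_path` is given.
#' @param counts_path,samples_path TSV inputs (ignored when `counts` given).
#' @param out_dir Output directory for stage TSVs and the JSON report;
#'   `NULL` keeps everything in memory.
#' @param control Control condition label (default `"vector"`).
#' @param contrasts List of length-2 character vectors `c(condition,
#'   control)`; default: every non-control condition against `control`.
#' @param expression_threshold,fc_threshold,alpha,anova_alpha,centile,n_iter
#'   Stage thresholds (see the stage functions).
#' @param transform Distance scale for the hypernetwork stage.
#' @param include_diagonal Whether reported connectivity averages the
#'   diagonal of H (both variants appear in the report regardless).
#' @param robust_anova Use Kruskal-Wallis for the group stage.
#' @param de_method Pairwise test engine, see [de_pairwise()].
#' @param truth Optional ground truth from [simulate_counts()]; when given,
#'   per-contrast recall of true DE genes is added to the report.
#' @param seed Master seed for the null stage.
#' @return List of class `"pipeline_config"`.
#' @export
pipeline_config <- function(counts = NULL, counts_path = NULL,
                            samples_path = NULL, out_dir = NULL,
                            control = "vector", contrasts = NULL,
                            expression_threshold = 10, fc_threshold = 0.6,
                            alpha = 0.05, anova_alpha = 0.01, centile = 30,
                            n_iter = 1000, transform = "log2p1",
                            include_diagonal = TRUE, robust_anova = FALSE,
                            de_method = "moderated", truth = NULL, seed = 1L) {
  if (is.null(counts) && (is.null(counts_path) || is.null(samples_path)))
    stop("give either 'counts' or both 'counts_path' and 'samples_path'")
  structure(as.list(environment()), class = "pipeline_config")
}

#' Run the full hypernetwork-organisation pipeline
#'
#' Executes normalise -> filter -> pairwise DE contrasts -> group ANOVA ->
#' Venn partition -> per-condition hypernetwork on the exclusive gene sets
#' -> randomised nulls -> entropy comparison, writes every stage product to
#' `out_dir` (when set) and returns a structured report. With a fixed seed
#' the report is reproducible byte-for-byte apart from the wall-time field.
#'
#' @param config A [pipeline_config()].
#' @return The report: a list of class `"run_report"` with per-stage counts,
#'   per-condition hypernetwork and null summaries, the entropy comparison,
#'   a config echo, package version, and wall time.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  t0 <- proc.time()[["elapsed"]]
  raw <- if (!is.null(config$counts)) config$counts
         else read_expression_tsv(config$counts_path, config$samples_path)

  sf <- size_factors(raw)
  norm <- normalise_counts(raw, sf)
  filt <- filter_expression(norm, config$expression_threshold)

  contrasts <- config$contrasts
  if (is.null(contrasts)) {
    non_ctrl <- setdiff(unique(filt$condition), config$control)
    contrasts <- lapply(non_ctrl, function(cc) c(cc, config$control))
  }
  de <- lapply(contrasts, function(ct)
    de_pairwise(filt, ct[1], ct[2], fc_threshold = config$fc_threshold,
                alpha = config$alpha, method = config$de_method))
  names(de) <- vapply(de, attr, character(1), "comparison")

  anova <- anova_groups(filt, alpha = config$anova_alpha,
                        robust = config$robust_anova)

  part <- if (length(de) == 2) partition_gene_sets(de[[1]], de[[2]]) else NULL

  # hypernetwork + null per contrast condition, on its exclusive gene set
  set.seed(config$seed)
  null_seeds <- sample.int(.Machine$integer.max, length(contrasts))
  hyper <- list()
  for (k in seq_along(contrasts)) {
    cond <- contrasts[[k]][1]
    gs <- if (!is.null(part)) {
      if (k == 1) part$exclusive_a else part$exclusive_b
    } else de[[k]]$gene_id[de[[k]]$significant]
    if (length(gs) < 2) {
      hyper[[cond]] <- list(condition = cond, set_size = length(gs),
                            skipped = "fewer than 2 exclusive genes")
      next
    }
    hn <- build_hypernetwork(binarise(
      manhattan_distance_matrix(filt, gs, condition = cond,
                                transform = config$transform),
      centile = config$centile))
    nd <- null_distribution(filt, condition = cond, set_size = length(gs),
                            n_iter = config$n_iter, centile = config$centile,
                            transform = config$transform,
                            seed = null_seeds[k])
    hyper[[cond]] <- list(
      condition = cond, gene_set = gs, set_size = length(gs),
      n_total = hn$n_total,
      connectivity = hn$connectivity,
      connectivity_offdiag = hn$connectivity_offdiag,
      median_entropy = stats::median(hn$entropy),
      entropy = hn$entropy,
      null = nd,
      p_connectivity = empirical_p(
        if (config$include_diagonal) hn$connectivity else hn$connectivity_offdiag,
        nd$connectivity_null, tail = "greater"),
      p_entropy_low = empirical_p(stats::median(hn$entropy),
                                  nd$entropy_null, tail = "less"))
  }

  built <- Filter(function(h) is.null(h$skipped), hyper)
  entropy_cmp <- if (length(built) >= 2)
    compare_entropy(built[[1]]$entropy, built[[2]]$entropy) else NULL

  recall <- NULL
  if (!is.null(config$truth)) {
    recall <- lapply(seq_along(contrasts), function(k) {
      cond <- contrasts[[k]][1]
      tr <- config$truth$de[[cond]]
      if (is.null(tr)) return(NULL)
      list(condition = cond, n_true = nrow(tr),
           recall = mean(tr$gene_id %in%
                           de[[k]]$gene_id[de[[k]]$significant]))
    })
    recall <- Filter(Negate(is.null), recall)
  }

  report <- structure(list(
    n_genes_input = nrow(raw$values),
    n_genes_filtered = nrow(filt$values),
    size_factors = as.list(round(sf, 10)),
    contrasts = lapply(de, function(d) {
      up <- d$significant & d$log2fc > 0
      list(comparison = attr(d, "comparison"),
           n_significant = sum(d$significant),
           n_up = sum(up), n_down = sum(d$significant) - sum(up))
    }),
    anova = list(n_discriminating = sum(anova$discriminating),
                 adj_p_range = as.numeric(attr(anova, "p_range"))),
    partition = if (!is.null(part)) lapply(unclass(part), length),
    hypernetworks = lapply(hyper, function(h)
      h[setdiff(names(h), c("entropy", "null", "gene_set"))]),
    entropy_comparison = if (!is.null(entropy_cmp)) unclass(entropy_cmp),
    ground_truth_recall = recall,
    config = list(expression_threshold = config$expression_threshold,
                  fc_threshold = config$fc_threshold, alpha = config$alpha,
                  anova_alpha = config$anova_alpha, centile = config$centile,
                  n_iter = config$n_iter, transform = config$transform,
                  include_diagonal = config$include_diagonal,
                  robust_anova = config$robust_anova,
                  de_method = config$de_method,
                  control = config$control, seed = config$seed),
    version = as.character(utils::packageVersion("hynet")),
    wall_time_s = NA_real_), class = "run_report")
  report$wall_time_s <- round(proc.time()[["elapsed"]] - t0, 3)

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    od <- config$out_dir
    for (nm in names(de))
      write_result_tsv(de[[nm]], file.path(od, paste0("de_", nm, ".tsv")))
    write_result_tsv(anova, file.path(od, "anova.tsv"))
    if (!is.null(part))
      for (nm in names(part))
        write_gene_list(part[[nm]], file.path(od, paste0(nm, "_genes.txt")))
    for (h in built) {
      write_result_tsv(
        data.frame(gene_id = names(h$entropy), entropy = unname(h$entropy)),
        file.path(od, paste0("entropy_", h$condition, ".tsv")))
      write_result_tsv(
        data.frame(iteration = seq_len(h$null$n_iter),
                   connectivity = h$null$connectivity_null,
                   median_entropy = h$null$entropy_null),
        file.path(od, paste0("null_", h$condition, ".tsv")))
    }
    jsonlite::write_json(unclass(report), file.path(od, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         null = "null")
  }
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("run_report: %d genes in, %d after filtering\n",
              x$n_genes_input, x$n_genes_filtered))
  for (ct in x$contrasts)
    cat(sprintf("  %s: %d significant (%d up / %d down)\n",
                ct$comparison, ct$n_significant, ct$n_up, ct$n_down))
  if (!is.null(x$partition))
    cat(sprintf("  partition: %d / %d exclusive, %d concordant, %d discordant\n",
                x$partition$exclusive_a, x$partition$exclusive_b,
                x$partition$concordant, x$partition$discordant))
  for (h in x$hypernetworks) {
    if (!is.null(h$skipped)) {
      cat(sprintf("  %s: hypernetwork skipped (%s)\n", h$condition, h$skipped))
    } else {
      cat(sprintf(
        "  %s: n=%d, connectivity %.1f, median entropy %.3f bits, p_conn=%.4g, p_entropy(low)=%.4g\n",
        h$condition, h$set_size, h$connectivity, h$median_entropy,
        h$p_connectivity, h$p_entropy_low))
    }
  }
  if (!is.null(x$entropy_comparison))
    cat(sprintf("  entropy comparison: p = %.3g (medians %.3f vs %.3f)\n",
                x$entropy_comparison$p_value, x$entropy_comparison$median_a,
                x$entropy_comparison$median_b))
  invisible(x)
}
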