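#' Configuration for the count simulator
#'
#' Describes a multi-condition replicated RNA-seq experiment with optional
#' spiked differentially expressed (DE) gene sets. Defaults emulate the study
#' design the package targets: 23766 expressed transcripts, three conditions
#' (an active regulator, a mutant regulator, a vector-only control) in
#' biological triplicate, with 78 DE genes forming a coordinated co-expression
#' module in the first condition and 106 diffusely regulated DE genes in the
#' second.
#'
#' Baseline per-gene abundance is log-normal on the log2 scale; because the
#' emulated transcriptome is one that already passed an expression filter, the
#' default baseline is centred well above zero (mean 6, sd 1.5 on log2).
#' Counts are negative binomial around the per-sample mean. Coordination of
#' a module, active only in the module's own condition, has two canonical
#' ingredients scaled by `coordination` in \[0, 1\]:
#' a shared latent regulator-activity factor (the mean of gene g in sample s
#' is multiplied by `exp(0.3 * coordination * sign(log2fc_g) * z_s)` with
#' `z_s ~ N(0, 1)`, so upregulated targets drift together and against
#' repressed targets), and tighter control of the targets (residual NB
#' dispersion scaled by `1 - 0.9 * coordination`). At `coordination = 0`
#' module genes are indistinguishable from background DE genes.
#'
#' @param n_genes Number of genes (default 23766; scale down freely).
#' @param conditions Condition labels; the first entries receive DE sets, the
#'   `control` label is the unperturbed reference.
#' @param control Which condition is the control (default `"vector"`).
#' @param n_replicates Replicates per condition (default 3).
#' @param baseline_log_mean Length-2 vector `c(mean, sd)` of the per-gene
#'   baseline log2 expression distribution.
#' @param dispersion Negative-binomial dispersion (variance
#'   `mu + dispersion * mu^2`); must be > 0.
#' @param de_sets List of DE-set descriptions, each a list with elements
#'   `condition`, `n` (number of genes), `log2fc_range` (magnitude range,
#'   default `c(0.6, 2.5)`), `prob_up` (probability of upregulation, default
#'   0.7) and `coordination` in \[0, 1\]. Use `list()` for a global-null
#'   (exchangeable) dataset.
#' @param size_factor_range Per-sample library-size factors are drawn
#'   log-uniform in this range so that normalisation is non-trivially
#'   exercised.
#' @param seed Integer seed; identical configurations produce bit-identical
#'   matrices.
#' @return An object of class `"simulation_config"`.
#' @seealso [simulate_counts()]
#' @export
simulation_config <- function(n_genes = 23766,
                              conditions = c("wt", "mut", "vector"),
                              control = "vector",
                              n_replicates = 3,
                              baseline_log_mean = c(mean = 6, sd = 1.5),
                              dispersion = 0.1,
                              de_sets = list(
                                list(condition = "wt", n = 78,
                                     log2fc_range = c(0.6, 2.5),
                                     prob_up = 0.7, coordination = 0.8),
                                list(condition = "mut", n = 106,
                                     log2fc_range = c(0.6, 2.5),
                                     prob_up = 0.7, coordination = 0)),
                              size_factor_range = c(0.7, 1.4),
                              seed = 1L) {
  stopifnot(length(n_genes) == 1, n_genes >= 1,
            length(n_replicates) == 1, n_replicates >= 1,
            length(conditions) >= 1, !anyDuplicated(conditions),
            control %in% conditions,
            length(baseline_log_mean) == 2, baseline_log_mean[2] >= 0,
            length(size_factor_range) == 2, all(size_factor_range > 0))
  if (!is.numeric(dispersion) || length(dispersion) != 1 || dispersion <= 0)
    stop("'dispersion' must be a single positive number")
  de_sets <- lapply(de_sets, function(s) {
    s <- utils::modifyList(
      list(log2fc_range = c(0.6, 2.5), prob_up = 0.7, coordination = 0), s)
    if (is.null(s$condition) || !s$condition %in% conditions)
      stop("DE set condition must be one of: ", paste(conditions, collapse = ", "))
    if (is.null(s$n) || s$n < 1) stop("DE set must have n >= 1 genes")
    if (s$coordination < 0 || s$coordination > 1)
      stop("'coordination' must be in [0, 1]")
    s
  })
  n_de <- sum(vapply(de_sets, `[[`, numeric(1), "n"))
  if (n_de > n_genes)
    stop("DE sets request ", n_de, " genes but only ", n_genes, " exist")
  structure(
    list(n_genes = as.integer(n_genes), conditions = conditions,
         control = control, n_replicates = as.integer(n_replicates),
         baseline_log_mean = unname(baseline_log_mean),
         dispersion = dispersion, de_sets = de_sets,
         size_factor_range = unname(size_factor_range),
         seed = as.integer(seed)),
    class = "simulation_config")
}

#' Simulate a replicated multi-condition count matrix
#'
#' Draws a gene x sample matrix of negative-binomial counts under a
#' [simulation_config()], together with the ground truth needed to score
#' downstream recovery: which genes are DE in which condition, their true
#' log2 fold changes, and which belong to a coordinated module.
#'
#' Random draws happen in a fixed order (baseline means, library-size
#' factors, DE gene assignment, fold changes, latent module factors, counts),
#' so a fixed seed reproduces the matrix bit-for-bit.
#'
#' @param config A [simulation_config()].
#' @param seed Optional override of `config$seed`.
#' @return A list with elements
#'   \describe{
#'     \item{matrix}{raw-count [expression_matrix()], samples named
#'       `<condition>_<replicate>`}
#'     \item{truth}{list with `de` (per condition, a data.frame of
#'       `gene_id`, `log2fc`, `module`), `size_factors`, and the seed used}
#'   }
#' @examples
#' sim <- simulate_counts(simulation_config(n_genes = 200, seed = 7))
#' sim$matrix
#' head(sim$truth$de$wt)
#' @export
simulate_counts <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(seed)
  n_samples <- length(config$conditions) * config$n_replicates
  sample_cond <- rep(config$conditions, each = config$n_replicates)
  sample_ids <- paste(sample_cond, rep(seq_len(config$n_replicates),
                                       times = length(config$conditions)),
                      sep = "_")
  gene_ids <- sprintf("gene_%05d", seq_len(config$n_genes))

  baseline <- stats::rnorm(config$n_genes, config$baseline_log_mean[1],
                           config$baseline_log_mean[2])
  sf <- exp(stats::runif(n_samples, log(config$size_factor_range[1]),
                         log(config$size_factor_range[2])))

  # disjoint DE gene assignment across all sets
  n_de <- sum(vapply(config$de_sets, `[[`, numeric(1), "n"))
  de_pool <- if (n_de) sample.int(config$n_genes, n_de) else integer(0)
  offset <- 0L

  log2_mu <- matrix(baseline, config$n_genes, n_samples,
                    dimnames = list(gene_ids, sample_ids))
  size_mat <- matrix(1 / config$dispersion, config$n_genes, n_samples)
  truth_de <- list()
  for (s in config$de_sets) {
    idx <- de_pool[offset + seq_len(s$n)]
    offset <- offset + s$n
    mag <- stats::runif(s$n, s$log2fc_range[1], s$log2fc_range[2])
    sign <- ifelse(stats::rbinom(s$n, 1, s$prob_up) == 1, 1, -1)
    lfc <- mag * sign
    cols <- which(sample_cond == s$condition)
    log2_mu[idx, cols] <- log2_mu[idx, cols] + lfc
    if (s$coordination > 0) {
      # shared regulator-activity factor across the condition's replicates;
      # each target responds with the sign of its own regulation
      z <- stats::rnorm(config$n_replicates)
      log2_mu[idx, cols] <- log2_mu[idx, cols, drop = FALSE] +
        0.3 * s$coordination * outer(sign, z) / log(2)
      # tighter control: reduced residual overdispersion for module genes
      size_mat[idx, cols] <- 1 / (config$dispersion * (1 - 0.9 * s$coordination))
    }
    df <- data.frame(gene_id = gene_ids[idx], log2fc = lfc,
                     module = s$coordination > 0)
    truth_de[[s$condition]] <- if (is.null(truth_de[[s$condition]]))
      df else rbind(truth_de[[s$condition]], df)
  }

  mu <- sweep(2^log2_mu, 2, sf, "*")
  counts <- matrix(
    stats::rnbinom(length(mu), mu = as.vector(mu), size = as.vector(size_mat)),
    nrow = config$n_genes, dimnames = dimnames(mu))

  list(matrix = expression_matrix(counts,
                                  stats::setNames(sample_cond, sample_ids)),
       truth = list(de = truth_de,
                    size_factors = stats::setNames(sf, sample_ids),
                    seed = as.integer(seed)))
}
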