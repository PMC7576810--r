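# Small in-code fixtures shared across test files.

# gene x sample matrix with deterministic ids
toy_matrix <- function(values, n_genes = nrow(values), n_samples = ncol(values),
                       condition = NULL, normalised = FALSE) {
  dimnames(values) <- list(sprintf("g%02d", seq_len(nrow(values))),
                           sprintf("s%02d", seq_len(ncol(values))))
  if (is.null(condition)) condition <- rep("wt", ncol(values))
  expression_matrix(values, stats::setNames(condition, colnames(values)),
                    normalised = normalised)
}

# random normalised matrix for hypernetwork-stage tests
random_norm_matrix <- function(n_genes, n_samples, seed, conditions = "wt") {
  set.seed(seed)
  v <- matrix(rexp(n_genes * n_samples, rate = 0.02), n_genes, n_samples)
  toy_matrix(v, condition = rep(conditions, length.out = n_samples),
             normalised = TRUE)
}

# independent naive implementations used as oracles ------------------------

naive_manhattan <- function(v, set_idx) {
  d <- matrix(NA_real_, length(set_idx), nrow(v))
  for (i in seq_along(set_idx))
    for (j in seq_len(nrow(v)))
      if (j != set_idx[i])
        d[i, j] <- sum(abs(v[set_idx[i], ] - v[j, ]))
  d
}

naive_hypernetwork <- function(m) {
  n <- nrow(m)
  h <- matrix(0, n, n)
  for (i in seq_len(n))
    for (j in seq_len(n))
      for (k in seq_len(ncol(m)))
        h[i, j] <- h[i, j] + m[i, k] * m[j, k]
  h
}

naive_connectivity <- function(h) {
  tot <- 0
  for (i in seq_len(nrow(h)))
    for (j in seq_len(ncol(h)))
      tot <- tot + h[i, j]
  tot / (nrow(h) * ncol(h))
}

naive_entropy <- function(h) {
  out <- numeric(nrow(h))
  for (i in seq_len(nrow(h))) {
    p <- h[i, -i]
    if (sum(p) > 0) {
      p <- p / sum(p)
      e <- 0
      for (q in p) if (q > 0) e <- e - q * log2(q)
      out[i] <- e
    }
  }
  out
}

# interpolated-quantile oracle (sort + linear interpolation by hand)
naive_quantile <- function(xs, p) {
  xs <- sort(xs)
  h <- (length(xs) - 1) * p + 1
  lo <- floor(h)
  xs[lo] + (h - lo) * (xs[min(lo + 1, length(xs))] - xs[lo])
}
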