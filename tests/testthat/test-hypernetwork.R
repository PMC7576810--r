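test_that("Manhattan distances match hand sums and a brute-force oracle", {
  v <- matrix(c(0, 0, 0,
                1, 2, 3,
                2, 2, 5), 3, 3, byrow = TRUE)
  x <- toy_matrix(v, normalised = TRUE)
  d <- manhattan_distance_matrix(x, c("g01", "g02"),
                                 samples = colnames(x$values),
                                 transform = "none")
  dimnames(v) <- dimnames(x$values)
  expect_true(is.na(d$values["g01", "g01"]))           # self-pair masked
  expect_equal(d$values["g01", "g02"], sum(abs(v[1, ] - v[2, ])))
  expect_equal(d$values["g02", "g03"], 3)              # |1-2|+|2-2|+|3-5|
  # identical profiles are at distance zero
  y <- toy_matrix(rbind(v, v[2, , drop = FALSE]), normalised = TRUE)
  dz <- manhattan_distance_matrix(y, "g02", samples = colnames(y$values),
                                  transform = "none")
  expect_equal(dz$values["g02", "g04"], 0)
  # random matrix vs double loop, exactly
  r <- random_norm_matrix(20, 5, seed = 51)
  set_idx <- c(3, 7, 11, 20)
  dr <- manhattan_distance_matrix(r, rownames(r$values)[set_idx],
                                  samples = colnames(r$values),
                                  transform = "none")
  expect_equal(unname(dr$values), naive_manhattan(r$values, set_idx))
  # log2p1 default equals the oracle on the transformed values
  dl <- manhattan_distance_matrix(r, rownames(r$values)[set_idx],
                                  samples = colnames(r$values))
  expect_equal(unname(dl$values), naive_manhattan(log2(r$values + 1), set_idx))
})

test_that("Manhattan distance is a metric and sample-order invariant", {
  r <- random_norm_matrix(15, 6, seed = 52)
  ids <- rownames(r$values)
  d <- manhattan_distance_matrix(r, ids, samples = colnames(r$values))$values
  set.seed(52)
  for (k in 1:25) {
    ijk <- sample(15, 3)
    expect_equal(d[ijk[1], ijk[2]], d[ijk[2], ijk[1]])  # symmetry
    expect_lte(d[ijk[1], ijk[3]],
               d[ijk[1], ijk[2]] + d[ijk[2], ijk[3]] + 1e-12)  # triangle
  }
  perm <- sample(colnames(r$values))
  dp <- manhattan_distance_matrix(r, ids, samples = perm)$values
  expect_equal(d, dp)
})

test_that("distance-matrix inputs are validated", {
  r <- random_norm_matrix(10, 3, seed = 53)
  expect_error(manhattan_distance_matrix(r, character(0), condition = "wt"),
               "empty gene set")
  expect_error(manhattan_distance_matrix(r, "gX", condition = "wt"),
               "not in matrix")
  expect_error(manhattan_distance_matrix(r, "g01", samples = "sX"),
               "unknown sample")
})

test_that("binarisation follows the interpolated-quantile convention", {
  d <- matrix(as.numeric(1:10), 2, 5)
  b <- binarise(d, 30)
  expect_equal(b$threshold, 3.7)          # sort + interpolate by hand
  expect_equal(sum(b$M), 3)               # {1, 2, 3} retained
  expect_true(all(b$M %in% c(0L, 1L)))
  # ties at the threshold are retained: all-equal matrix -> all ones
  expect_true(all(binarise(matrix(5, 3, 4), 30)$M == 1L))
  # masked (NA) entries stay zero
  dn <- d; dn[1, 1] <- NA
  expect_identical(binarise(dn, 30)$M[1, 1], 0L)
  expect_error(binarise(matrix(NA_real_, 2, 2), 30), "empty")
  expect_error(binarise(d, 0), "centile")
  expect_error(binarise(d, 100), "centile")
})

test_that("ones fraction tracks the centile and the quantile oracle", {
  set.seed(54)
  d <- matrix(runif(1000), 25, 40)
  stopifnot(!anyDuplicated(c(d)))
  b <- binarise(d, 30)
  expect_equal(b$threshold, naive_quantile(c(d), 0.3))
  expect_lt(abs(mean(b$M) - 0.300), 0.001)
  # per-row scope: each row hits the centile on its own
  br <- binarise(d, 30, scope = "row")
  expect_equal(unname(br$threshold),
               apply(d, 1, naive_quantile, p = 0.3))
  expect_true(all(abs(rowMeans(br$M) - 0.3) < 0.013))
})

test_that("hypernetwork construction matches shared-column counting", {
  m <- rbind(c(1, 0, 1),
             c(1, 1, 0))
  rownames(m) <- c("a", "b")
  h <- build_hypernetwork(m)
  expect_equal(unname(h$H), rbind(c(2, 1), c(1, 2)))
  expect_equal(h$connectivity, 1.5)
  expect_equal(unname(build_hypernetwork(diag(3))$H), diag(3))
  z <- matrix(0, 3, 4)
  expect_true(all(build_hypernetwork(z)$H == 0))
  expect_equal(build_hypernetwork(z)$connectivity, 0)
  expect_error(build_hypernetwork(matrix(c(0, 2), 1, 2)), "binary")
})

test_that("hypernetwork, connectivity and entropy match naive oracles exactly", {
  set.seed(55)
  for (rep in 1:50) {
    n <- sample(2:20, 1)
    k <- sample(10:200, 1)
    m <- matrix(rbinom(n * k, 1, runif(1, 0.1, 0.6)), n, k)
    h <- build_hypernetwork(m)
    expect_identical(unname(h$H), naive_hypernetwork(m))
    expect_equal(h$connectivity, naive_connectivity(h$H))
    expect_equal(unname(h$entropy), naive_entropy(h$H))
    # structural invariants
    expect_equal(h$H, t(h$H))
    expect_equal(diag(h$H), rowSums(m) + 0, ignore_attr = TRUE)
    expect_true(all(h$H <= pmin(outer(diag(h$H), rep(1, n)),
                                outer(rep(1, n), diag(h$H)))))
    expect_true(all(h$entropy <= log2(n - 1) + 1e-12))
    expect_gte(min(h$entropy), 0)
  }
})

test_that("entropy reproduces analytic cases", {
  h1 <- rbind(c(9, 2, 2),
              c(2, 9, 2),
              c(2, 2, 9))
  expect_equal(unname(entropy_per_gene(h1)), rep(1, 3))  # p = (1/2, 1/2)
  h2 <- matrix(1, 4, 4); h2[1, ] <- c(7, 4, 0, 0); h2[, 1] <- h2[1, ]
  expect_equal(unname(entropy_per_gene(h2))[1], 0)       # p = (1, 0, 0)
  h3 <- matrix(1, 5, 5)
  expect_equal(unname(entropy_per_gene(h3)), rep(2, 5))  # uniform over 4
  # all-zero row -> entropy 0 by convention
  h4 <- diag(c(4, 4, 4))
  expect_equal(unname(entropy_per_gene(h4)), rep(0, 3))
  expect_error(entropy_per_gene(matrix(1, 1, 1)), ">= 2")
})

test_that("gene-set permutation permutes H and preserves its summaries", {
  r <- random_norm_matrix(60, 3, seed = 56)
  ids <- rownames(r$values)[5:24]
  h <- build_hypernetwork(binarise(
    manhattan_distance_matrix(r, ids, condition = "wt")))
  set.seed(56)
  perm <- sample(ids)
  hp <- build_hypernetwork(binarise(
    manhattan_distance_matrix(r, perm, condition = "wt")))
  expect_equal(hp$H[ids, ids], h$H)
  expect_equal(hp$connectivity, h$connectivity)
  expect_equal(sort(unname(hp$entropy)), sort(unname(h$entropy)))
})

test_that("median hypernetwork entropy is stable under module coordination", {
  # At a fixed 30% incidence density the per-gene entropy of a same-size
  # module is dominated by set size and row density; module coordination
  # must not shift the median materially in either direction.
  diffs <- sapply(1:10, function(s) {
    med <- sapply(c(0, 0.8), function(co) {
      sim <- simulate_counts(simulation_config(
        n_genes = 1000, seed = 100 + s,
        de_sets = list(list(condition = "wt", n = 78, coordination = co))))
      norm <- normalise_counts(sim$matrix)
      hn <- build_hypernetwork(binarise(
        manhattan_distance_matrix(norm, sim$truth$de$wt$gene_id,
                                  condition = "wt")))
      median(hn$entropy)
    })
    med[2] - med[1]
  })
  expect_lt(abs(mean(diffs)), 0.1)
})
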