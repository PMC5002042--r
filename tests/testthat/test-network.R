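# Co-expression network construction: adjacency, TOM, dynamic tree cut,
# eigengenes, module merging, connectivity statistics.

test_that("unsigned adjacency is |r|^power and monotone in |r|", {
  set.seed(10)
  x <- matrix(rnorm(40), 10, 4, dimnames = list(NULL, paste0("g", 1:4)))
  x[, 2] <- x[, 1]          # r = 1
  x[, 3] <- -x[, 1]         # r = -1
  net <- adjacency_matrix(x, power = 7)
  expect_equal(net$A["g1", "g2"], 1)
  expect_equal(net$A["g1", "g3"], 1)
  expect_equal(net$S["g1", "g3"], 1)

  # exact arithmetic at r = 0.5
  expect_equal(0.5^7, 0.0078125)
  r <- seq(0.05, 0.95, by = 0.1)
  expect_true(all(diff(r^7) > 0))

  # zero-variance genes are removed with a warning
  x2 <- cbind(x[, 1:2], const = rep(1, 10))
  colnames(x2) <- c("g1", "g2", "const")
  expect_warning(net2 <- adjacency_matrix(x2), "zero-variance")
  expect_false("const" %in% net2$genes)
})

test_that("TOM matches the closed form and the brute-force oracle", {
  # three nodes, all off-diagonal adjacency 0.5:
  # TOM_12 = (0.25 + 0.5) / (min(1,1) + 1 - 0.5) = 0.5
  A3 <- matrix(0.5, 3, 3); diag(A3) <- 1
  T3 <- tom_similarity(A3)
  expect_equal(T3[1, 2], 0.5)
  expect_equal(diag(T3), rep(1, 3))

  # isolated pair: zero adjacency, no shared neighbours
  A0 <- diag(2)
  expect_equal(tom_similarity(A0)[1, 2], 0)

  # elementwise triple-loop oracle on a random instance
  set.seed(33)
  S <- abs(cor(matrix(rnorm(30 * 25), 30)))
  A <- S^7; diag(A) <- 1
  tom <- tom_similarity(A)
  n <- nrow(A)
  oracle <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) { oracle[i, j] <- 1; next }
    l <- 0
    for (u in seq_len(n)) if (u != i && u != j) l <- l + A[i, u] * A[u, j]
    ki <- sum(A[i, -i]); kj <- sum(A[j, -j])
    oracle[i, j] <- (l + A[i, j]) / (min(ki, kj) + 1 - A[i, j])
  }
  expect_lt(max(abs(tom - oracle)), 1e-10)
  expect_true(all(tom >= 0 & tom <= 1 + 1e-12))

  expect_error(tom_similarity(matrix(c(1, 2, 2, 1), 2)), "\\[0, 1\\]")
})

test_that("dynamic tree cut recovers planted blocks and respects min size", {
  bx <- blocky_expression(n_strains = 30, block_sizes = c(20, 20),
                          n_noise = 20, seed = 7)
  net <- adjacency_matrix(bx$expression, 7)
  labels <- detect_modules(1 - tom_similarity(net$A), min_module_size = 5)
  expect_identical(max(labels), 2L)
  # each planted block lands intact in its own module
  for (b in 1:2) {
    det <- labels[bx$truth == b]
    expect_identical(length(unique(det)), 1L)
    expect_gt(det[1], 0L)
  }
  expect_false(labels[bx$truth == 1][1] == labels[bx$truth == 2][1])
  # noise stays essentially unassigned (an occasional chance correlation
  # may attach a stray gene)
  expect_gte(mean(labels[bx$truth == 0] == 0L), 0.85)

  # a correlated quartet below min size stays unassigned
  bx4 <- blocky_expression(n_strains = 30, block_sizes = 4,
                           n_noise = 30, seed = 8)
  net4 <- adjacency_matrix(bx4$expression, 7)
  lab4 <- detect_modules(1 - tom_similarity(net4$A), min_module_size = 5)
  expect_true(all(lab4 == 0L))

  # determinism
  lab_again <- detect_modules(1 - tom_similarity(net$A), min_module_size = 5)
  expect_identical(labels, lab_again)
})

test_that("module eigengene equals PC1 with oriented sign", {
  set.seed(4)
  base <- rnorm(12)
  # identical members: variance fully explained
  x_same <- matrix(rep(base, 5), 12, dimnames = list(NULL, paste0("g", 1:5)))
  eg <- module_eigengene(x_same)
  expect_equal(eg$variance_explained, 1)
  expect_equal(sum(eg$eigengene^2), 1)
  # sign orientation: positively correlated with mean member expression
  expect_gt(cor(eg$eigengene, rowMeans(scale(x_same))), 0)

  # two orthogonal members split the variance evenly
  x <- cbind(a = c(1, -1, 1, -1, 1, -1, 1, -1),
             b = c(1, 1, -1, -1, 1, 1, -1, -1))
  expect_equal(module_eigengene(x)$variance_explained, 0.5)

  # variance explained is invariant under per-gene affine rescaling
  set.seed(5)
  xr <- matrix(rnorm(20 * 10), 20)
  colnames(xr) <- paste0("g", 1:10)
  xr2 <- sweep(sweep(xr, 2, runif(10, 0.5, 3), "*"), 2, rnorm(10), "+")
  expect_equal(module_eigengene(xr)$variance_explained,
               module_eigengene(xr2)$variance_explained, tolerance = 1e-12)

  expect_error(module_eigengene(cbind(a = rep(1, 5), b = rnorm(5))),
               "zero-variance")
})

test_that("modules with eigengene correlation >= 0.75 are merged", {
  set.seed(6)
  n <- 40
  d <- rnorm(n)
  near <- sapply(1:6, function(i) 0.95 * d + sqrt(1 - 0.95^2) * rnorm(n))
  near2 <- sapply(1:6, function(i) 0.95 * d + sqrt(1 - 0.95^2) * rnorm(n))
  other <- {
    d2 <- rnorm(n)
    sapply(1:6, function(i) 0.95 * d2 + sqrt(1 - 0.95^2) * rnorm(n))
  }
  x <- cbind(near, near2, other)
  colnames(x) <- paste0("g", seq_len(ncol(x)))
  labels <- setNames(rep(1:3, each = 6), colnames(x))
  merged <- merge_similar_modules(labels, x, merge_cor = 0.75)
  # the two highly correlated modules collapse; the third survives
  expect_identical(max(merged), 2L)
  expect_identical(length(unique(merged[1:12])), 1L)
  # post-condition: all remaining eigengene correlations below threshold
  E <- sapply(sort(unique(merged)), function(m)
    module_eigengene(x[, merged == m, drop = FALSE])$eigengene)
  C <- abs(cor(E)); diag(C) <- 0
  expect_lt(max(C), 0.75)
  # merging never increases module count
  expect_lte(max(merged), max(labels))
})

test_that("connectivity statistics: kIM, strict connection rule, hub ties", {
  # perfectly correlated module: kIM = m - 1 for every gene
  m <- 6
  A <- matrix(1, m, m, dimnames = list(paste0("g", 1:m), paste0("g", 1:m)))
  S <- A
  cs <- connectivity_stats(paste0("g", 1:m), A, S)
  expect_true(all(cs$stats$k_im == m - 1))
  # tie on kIM resolves to the lexicographically smallest id
  expect_identical(cs$hub, "g1")

  # strict threshold: |r| = 0.5 exactly does not count
  S2 <- matrix(0.5, 3, 3); diag(S2) <- 1
  dimnames(S2) <- list(paste0("g", 1:3), paste0("g", 1:3))
  cs2 <- connectivity_stats(paste0("g", 1:3), S2^7, S2)
  expect_true(all(cs2$stats$connection_count == 0L))
})

test_that("scale-free fit flags degenerate input and ranks structures", {
  expect_identical(scale_free_fit(rep(3, 50))$flag, "degenerate")
  # discretized power law (freq ~ k^-2 at bin centres): near-perfect fit
  k <- rep(1:10 + 0.001, times = round(1000 * (1:10)^-2))
  sf <- scale_free_fit(k, n_bins = 10)
  expect_gt(sf$r_squared, 0.99)
  expect_lt(sf$slope, 0)
  # equicorrelated data: clearly worse fit than the power law
  set.seed(20)
  d <- rnorm(25)
  eq <- sapply(1:60, function(i) d + rnorm(25, sd = 0.6))
  colnames(eq) <- paste0("g", 1:60)
  sf_eq <- scale_free_fit(adjacency_matrix(eq, 7)$k)
  expect_lt(sf_eq$r_squared, sf$r_squared)
})
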