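# Divergences, affinities, Laplacian spectra, embedding and clustering.

kl_oracle <- function(p, q) { # naive elementwise summation
  s <- 0
  for (i in seq_along(p)) s <- s + p[i] * log(p[i] / q[i])
  s
}

test_that("KL divergence matches hand values and is asymmetric", {
  expect_equal(kl_divergence(c(0.5, 0.5), c(0.9, 0.1)),
               0.5 * log(5 / 9) + 0.5 * log(5))
  expect_equal(kl_divergence(c(0.5, 0.5), c(0.9, 0.1)), 0.51083, tolerance = 1e-4)
  expect_equal(kl_divergence(c(0.9, 0.1), c(0.5, 0.5)),
               0.9 * log(1.8) + 0.1 * log(0.2)) # ~0.36772
  expect_identical(kl_divergence(c(0.2, 0.8), c(0.2, 0.8)), 0)
  expect_error(kl_divergence(c(0.5, 0.6), c(0.5, 0.5)), "sum to 1")
})

test_that("KL divergence agrees with the summation oracle on 1000 random
           pairs at K = 83", {
  set.seed(6)
  for (i in 1:1000) {
    p <- random_pattern(83); q <- random_pattern(83)
    expect_lt(abs(kl_divergence(p, q) - kl_oracle(p, q)), 1e-12)
    expect_gte(kl_divergence(p, q), 0)
  }
  # zero iff identical
  p <- random_pattern(83)
  expect_identical(kl_divergence(p, p), 0)
  q <- p; q[1] <- q[1] * 1.01; q <- q / sum(q)
  expect_gt(kl_divergence(p, q), 0)
})

test_that("the divergence matrix is in col-given-row orientation with
           M(M-1)/2 pairs", {
  set.seed(7)
  pats <- lapply(1:9, function(i) random_pattern(20))
  names(pats) <- paste0("v", 1:9)
  d <- divergence_matrix(pats)
  expect_equal(attr(d, "n_pairs"), 36)
  expect_true(all(diag(unclass(d)) == 0))
  expect_true(all(unclass(d) >= 0))
  # d[r, c] = D(col || row)
  expect_equal(d["v3", "v5"], kl_divergence(pats$v5, pats$v3))
  dup <- divergence_matrix(list(a = pats$v1, b = pats$v1, c = pats$v1))
  expect_true(all(unclass(dup) == 0))
})

test_that("affinity is the symmetric mutual-divergence kernel", {
  set.seed(8)
  p <- random_pattern(15); q <- random_pattern(15)
  expect_identical(affinity(p, p), 1) # formula value for identical patterns
  expect_equal(affinity(p, q),
               exp(-(kl_divergence(p, q) + kl_divergence(q, p)) / (2 * pi)))
  for (i in 1:50) {
    a <- random_pattern(15); b <- random_pattern(15)
    expect_identical(affinity(a, b), affinity(b, a))
    expect_gt(affinity(a, b), 0); expect_lte(affinity(a, b), 1)
  }
  # mutual divergence of exactly 2*pi -> exp(-1); and monotone decrease
  expect_equal(exp(-(2 * pi) / (2 * pi)), exp(-1))
  mut <- function(a, b) kl_divergence(a, b) + kl_divergence(b, a)
  a <- random_pattern(15); b <- random_pattern(15); c <- random_pattern(15)
  ms <- c(mut(a, b), mut(a, c))
  afs <- c(affinity(a, b), affinity(a, c))
  expect_equal(order(ms), order(afs, decreasing = TRUE))
})

test_that("the normalised Laplacian has its closed-form spectra", {
  # 2 views, any affinity: L = [[1,-1],[-1,1]]
  a2 <- matrix(c(1, 0.3, 0.3, 1), 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  l2 <- laplacian(a2)
  expect_equal(unname(l2), matrix(c(1, -1, -1, 1), 2), tolerance = 1e-12)
  expect_equal(eigen(l2)$values, c(2, 0), tolerance = 1e-12)
  # complete graph with constant affinity: 0 once, M/(M-1) with mult M-1
  m <- 6
  ac <- matrix(0.4, m, m); diag(ac) <- 1
  ev <- sort(eigen(laplacian(ac), symmetric = TRUE)$values)
  expect_equal(ev[1], 0, tolerance = 1e-12)
  expect_equal(ev[-1], rep(m / (m - 1), m - 1), tolerance = 1e-12)
  expect_error(laplacian(matrix(1, 1, 1)), "M >= 2")
})

test_that("Laplacian is PSD with spectrum in [0,2] and null vector
           D^{1/2} 1", {
  set.seed(9)
  for (i in 1:20) {
    pats <- lapply(1:7, function(j) random_pattern(12))
    d <- divergence_matrix(pats)
    a <- affinity_matrix(d)
    expect_true(isSymmetric(unclass(a)))
    expect_true(all(unclass(a) > 0 & unclass(a) <= 1))
    l <- laplacian(a)
    ev <- eigen(l, symmetric = TRUE)
    expect_gte(min(ev$values), -1e-10)
    expect_lte(max(ev$values), 2 + 1e-10)
    a0 <- unclass(a); diag(a0) <- 0
    v0 <- sqrt(rowSums(a0))
    expect_lt(max(abs(l %*% v0)), 1e-10)
  }
})

test_that("spectral embedding separates blocks, is permutation-equivariant,
           and reconstructs L at k = M", {
  # two blocks of views with high internal affinity
  a <- matrix(0.05, 6, 6)
  a[1:3, 1:3] <- 0.9; a[4:6, 4:6] <- 0.9; diag(a) <- 1
  rownames(a) <- colnames(a) <- paste0("v", 1:6)
  emb <- spectral_embed(a, k = 2)
  s <- sign(emb$coordinates[, 2])
  expect_true(all(s[1:3] == s[1]) && all(s[4:6] == -s[1]))
  # view reordering permutes coordinates (up to sign, fixed by convention)
  perm <- c(4, 1, 5, 2, 6, 3)
  emb_p <- spectral_embed(a[perm, perm], k = 2)
  expect_equal(abs(emb_p$coordinates[order(perm), ]),
               abs(emb$coordinates), tolerance = 1e-9)
  # full spectrum reconstructs L
  embf <- spectral_embed(a, k = 6)
  l <- laplacian(a)
  rec <- embf$coordinates %*% diag(embf$eigenvalues) %*% t(embf$coordinates)
  expect_lt(max(abs(rec - l)), 1e-8)
})

test_that("view clustering recovers planted blocks and handles degenerate
           cluster counts", {
  a <- matrix(0.02, 8, 8)
  blocks <- rep(1:4, each = 2)
  for (b in 1:4) a[blocks == b, blocks == b] <- 0.95
  diag(a) <- 1
  rownames(a) <- colnames(a) <- paste0("v", 1:8)
  emb <- spectral_embed(a, k = 4)
  cl <- cluster_views(emb, 4, seed = 1)
  expect_equal(adjusted_rand(cl$cluster, blocks), 1)
  expect_equal(sort(unique(cluster_views(emb, 1, seed = 1)$cluster)), 1L)
  expect_equal(cluster_views(emb, 8, seed = 1)$cluster, 1:8)
  # deterministic under the seed
  expect_identical(cluster_views(emb, 4, seed = 5),
                   cluster_views(emb, 4, seed = 5))
})

test_that("embedding distances track mutual divergence on archetype-
           structured ensembles", {
  set.seed(10)
  rhos <- sapply(1:10, function(r) {
    K <- 30
    arch <- lapply(1:3, function(a) {
      v <- rep(1e-3, K); v[((a - 1) * 10 + 1):(a * 10)] <- 1; v / sum(v)
    })
    pats <- lapply(1:9, function(i) {
      b <- arch[[(i - 1) %% 3 + 1]]
      w <- b * exp(rnorm(K, 0, 0.3)); w / sum(w)
    })
    names(pats) <- paste0("v", 1:9)
    d <- divergence_matrix(pats)
    emb <- spectral_embed(affinity_matrix(d), k = 2)
    de <- as.matrix(dist(emb$coordinates))
    mut <- unclass(d) + t(unclass(d))
    iu <- upper.tri(mut)
    cor(de[iu], mut[iu], method = "spearman")
  })
  expect_gt(median(rhos), 0.7)
  expect_true(all(rhos > 0))
})
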