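make_traits <- function(n = 6, p = 5, seed = 1) {
  set.seed(seed)
  x <- as.data.frame(matrix(rnorm(n * p), n, p))
  names(x) <- paste0("fa", seq_len(p))
  rownames(x) <- paste0("cv", seq_len(n))
  x
}

test_that("PCA matches a brute-force eigen-decomposition of the correlation matrix", {
  x <- make_traits()
  res <- trait_pca(x)
  S <- cor(as.matrix(x))
  ref <- eigen(S, symmetric = TRUE)
  expect_equal(res$eigenvalues, ref$values, tolerance = 1e-10)
  for (j in seq_along(res$eigenvalues)) {
    # same axes up to sign
    expect_equal(abs(res$loadings[, j]), abs(ref$vectors[, j]),
                 tolerance = 1e-10, ignore_attr = TRUE)
    # sign convention: dominant loading positive
    expect_gt(res$loadings[which.max(abs(res$loadings[, j])), j], 0)
  }
  expect_equal(sum(res$percent_variance), 100, tolerance = 1e-8)
  expect_equal(colSums(res$contributions), rep(100, 5),
               tolerance = 1e-8, ignore_attr = TRUE)
  expect_true(all(res$cos2 >= 0 & res$cos2 <= 1 + 1e-12))
})

test_that("scores are centred with eigenvalue covariance", {
  res <- trait_pca(make_traits(n = 10, p = 4, seed = 3))
  expect_equal(colMeans(res$scores), rep(0, 4), tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_equal(cov(res$scores), diag(res$eigenvalues), tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("duplicated variables get identical loadings and cos2", {
  x <- make_traits(p = 3, seed = 5)
  x$fa_dup <- x$fa1
  res <- trait_pca(x)
  # the two copies are indistinguishable on every informative component
  # (the null component is exactly their contrast and is excluded)
  keep <- res$eigenvalues > 1e-8
  expect_equal(res$loadings["fa1", keep], res$loadings["fa_dup", keep],
               tolerance = 1e-8, ignore_attr = TRUE)
  expect_equal(res$cos2["fa1", keep], res$cos2["fa_dup", keep],
               tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("six rows and five independent variables span five components", {
  res <- trait_pca(make_traits(n = 6, p = 5, seed = 7))
  expect_length(res$eigenvalues, 5)
  expect_true(all(res$eigenvalues > 1e-10))
  expect_equal(sum(res$percent_variance), 100, tolerance = 1e-8)
})

test_that("supplementary projection never perturbs the decomposition", {
  x <- make_traits(n = 8, p = 4, seed = 11)
  x$Tb <- rowSums(x[, 1:2]) + rnorm(8, 0, 0.1)
  plain <- trait_pca(x, active = paste0("fa", 1:4))
  with_supp <- trait_pca(x, active = paste0("fa", 1:4),
                         supplementary = "Tb")
  expect_identical(plain$eigenvalues, with_supp$eigenvalues)
  expect_identical(plain$scores, with_supp$scores)
  sc <- with_supp$supplementary$coordinates
  expect_equal(unname(sc["Tb", 1]), cor(x$Tb, plain$scores[, 1]),
               tolerance = 1e-12)
  expect_true(all(with_supp$supplementary$cos2 <= 1 + 1e-12, na.rm = TRUE))
})

test_that("degenerate trait tables are rejected with a named column", {
  x <- make_traits()
  x$fa1 <- 1
  expect_error(trait_pca(x), class = "seedhtt_data_error")
  expect_error(trait_pca(x), "fa1")
  expect_error(trait_pca(make_traits(n = 2)), class = "seedhtt_data_error")
})

test_that("clustering on scores recovers planted structure", {
  # every trait differs between clusters, separation >> within-cluster sd
  centres <- rbind(c(0, 0, 0), c(10, 0, 5), c(0, 10, -5))
  hits <- vapply(1:20, function(s) {
    set.seed(s)
    blobs <- make_blobs(centres, n_per = 4, sd = 0.3)
    cl <- hcpc(trait_pca(blobs$x), k = 3)
    # same partition as planted?
    length(unique(paste(cl, blobs$truth))) == 3
  }, TRUE)
  expect_true(all(hits))
})

test_that("clustering labels are deterministic and permutation-equivariant", {
  set.seed(42)
  blobs <- make_blobs(rbind(c(0, 0), c(8, 0)), n_per = 3, sd = 0.1)
  res <- trait_pca(blobs$x)
  cl <- hcpc(res, k = 2)
  # k = n gives singletons
  expect_equal(sort(unique(hcpc(res, k = 6))), 1:6)
  expect_error(hcpc(res, k = 7), class = "seedhtt_data_error")
  # permuting rows permutes labels identically
  perm <- c(3, 1, 2, 6, 5, 4)
  cl_p <- hcpc(trait_pca(blobs$x[perm, ]), k = 2)
  expect_equal(as.vector(cl_p), as.vector(cl)[perm])
})

test_that("trait correlations flag degenerate and low-power cases", {
  x <- make_traits(n = 8, p = 3, seed = 13)
  x$target <- x$fa1
  tab <- trait_correlations(x, paste0("fa", 1:3), "target")
  expect_equal(tab$r[tab$trait == "fa1"], 1, tolerance = 1e-12)
  expect_true(all(tab$low_power))
  # orthogonalized target has zero correlation by construction
  x$ortho <- residuals(lm(target ~ fa2, data = x))
  tab2 <- trait_correlations(x, "fa2", "ortho")
  expect_equal(tab2$r, 0, tolerance = 1e-10)
  x$const <- 5
  tab3 <- trait_correlations(x, "const", "target")
  expect_true(is.na(tab3$r))
})

test_that("a planted correlation is estimated consistently at large n", {
  set.seed(99)
  n <- 200
  z <- rnorm(n)
  x <- data.frame(trait = z, noise = rnorm(n))
  x$target <- 0.8 * z + sqrt(1 - 0.8^2) * rnorm(n)
  tab <- trait_correlations(x, c("trait", "noise"), "target")
  expect_equal(tab$r[tab$trait == "trait"], 0.8, tolerance = 0.05)
  expect_false(any(tab$low_power))
})
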