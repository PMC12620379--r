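make_ranking_data <- function(n = 100, seed = 1) {
  set.seed(seed)
  y <- rep(c("A", "B"), each = n / 2)
  data.frame(perfect = as.numeric(y == "A"),
             noise = rnorm(n),
             constant = rep(2, n))
}

test_that("correlation ranking puts a class-identical attribute first", {
  x <- make_ranking_data(200)
  y <- rep(c("A", "B"), each = 100)
  rk <- correlation_rank(x, y)
  expect_identical(rk$ranking$attribute[1], "perfect")
  expect_equal(rk$scores[["perfect"]], 1.0)
  expect_lt(rk$scores[["noise"]], 0.2)
  expect_equal(rk$scores[["constant"]], 0)
})

test_that("chi-squared ranking matches the closed form for perfect association", {
  x <- make_ranking_data(100)
  y <- rep(c("A", "B"), each = 50)
  rk <- chi2_rank(x, y, n_bins = 2)
  # perfect 2x2 association: statistic equals n
  expect_equal(rk$scores[["perfect"]], 100)
  expect_equal(rk$scores[["constant"]], 0)
  expect_identical(rk$ranking$attribute[1], "perfect")
})

test_that("chi-squared statistic is calibrated under the null", {
  set.seed(2)
  pvals <- replicate(100, {
    x <- data.frame(f = runif(80))
    y <- rep(c("A", "B"), each = 40)
    s <- chi2_rank(x, y, n_bins = 5)$scores[["f"]]
    pchisq(s, df = (5 - 1) * (2 - 1), lower.tail = FALSE)
  })
  expect_gte(mean(pvals > 0.05), 0.80)
})

test_that("significance ranking scores a class-determining attribute maximally", {
  x <- make_ranking_data(120)
  y <- rep(c("A", "B"), each = 60)
  rk <- significance_rank(x, y)
  expect_identical(rk$ranking$attribute[1], "perfect")
  expect_equal(rk$scores[["perfect"]], 1.0)
  expect_equal(rk$scores[["constant"]], 0)
})

test_that("significance and chi-squared usually agree on the top attribute", {
  hits <- vapply(1:30, function(i) {
    set.seed(i + 400)
    n <- 80
    y <- rep(c("A", "B", "C", "D"), each = n / 4)
    shift <- c(A = 0, B = 0.1, C = 0.2, D = 0.3)[y]
    x <- data.frame(eff1 = rnorm(n, shift, 0.1), eff2 = rnorm(n, shift, 0.15),
                    n1 = rnorm(n), n2 = rnorm(n), n3 = rnorm(n))
    chi2_rank(x, y)$ranking$attribute[1] ==
      significance_rank(x, y)$ranking$attribute[1]
  }, logical(1))
  expect_gte(mean(hits), 0.8)
})

test_that("PCA loading priority follows eigenvalue-weighted loadings", {
  # two perfectly correlated attributes: eigenvalues (2, 0), tie broken by index
  x <- data.frame(a = c(1, 2, 3, 4, 5), b = c(2, 4, 6, 8, 10))
  rk <- pca_rank(x, n_components = 2)
  expect_equal(rk$eigenvalues, c(2, 0), tolerance = 1e-12)
  expect_equal(rk$scores[["a"]], rk$scores[["b"]], tolerance = 1e-12)
  expect_identical(rk$ranking$attribute[1], "a")
  # a dominant-variance independent attribute wins the top component (oracle)
  set.seed(3)
  base <- rnorm(200)
  x2 <- data.frame(big = rnorm(200), c1 = base + rnorm(200, 0, 0.2),
                   c2 = base + rnorm(200, 0, 0.2))
  eg <- eigen(cor(x2), symmetric = TRUE)
  oracle <- colnames(x2)[which.max(abs(eg$vectors[, 1]) * eg$values[1] +
                                     abs(eg$vectors[, 2]) * eg$values[2])]
  rk2 <- pca_rank(x2, n_components = 2)
  expect_identical(rk2$ranking$attribute[1], oracle)
})

test_that("PCA ranking is invariant to per-attribute rescaling", {
  set.seed(4)
  x <- as.data.frame(matrix(rnorm(300), ncol = 3))
  r1 <- pca_rank(x, n_components = 2)
  x_scaled <- sweep(x, 2, c(100, 0.01, 7), "*")
  r2 <- pca_rank(x_scaled, n_components = 2)
  expect_identical(r1$ranking$attribute, r2$ranking$attribute)
  expect_equal(r1$ranking$score, r2$ranking$score, tolerance = 1e-9)
})

test_that("correlation-matrix eigenvalues sum to the non-constant attribute count", {
  set.seed(5)
  x <- cbind(as.data.frame(matrix(rnorm(500), ncol = 5)), konst = 1)
  rk <- pca_rank(x)
  expect_equal(sum(rk$eigenvalues), 5, tolerance = 1e-9)
  expect_identical(rk$ranking$attribute[6], "konst")
})

test_that("all four rankers put planted informative attributes first", {
  # mirrors the synthetic-cohort design: several attributes share the group
  # effect (like the paired features of an affected channel), so the effect
  # also dominates a correlation-matrix component and is visible to the
  # unsupervised PCA ranker, not just to the supervised ones
  hits <- vapply(1:25, function(i) {
    set.seed(i + 900)
    n <- 80
    y <- rep(c("a", "b", "c", "d"), each = n / 4)
    shift <- c(a = 0, b = 1, c = 2, d = 3)[y]
    x <- data.frame(eff1 = shift + rnorm(n, 0, 0.3),
                    eff2 = shift + rnorm(n, 0, 0.3),
                    n1 = rnorm(n), n2 = rnorm(n), n3 = rnorm(n))
    top <- c(correlation_rank(x, y)$ranking$attribute[1],
             chi2_rank(x, y)$ranking$attribute[1],
             significance_rank(x, y)$ranking$attribute[1],
             pca_rank(x, n_components = 1)$ranking$attribute[1])
    all(top %in% c("eff1", "eff2"))
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("scores follow attribute permutations", {
  set.seed(6)
  n <- 60
  y <- rep(c("A", "B"), each = 30)
  x <- data.frame(p = as.numeric(y == "A") + rnorm(n, 0, 0.3),
                  q = rnorm(n), r = rnorm(n))
  perm <- c("r", "p", "q")
  for (f in list(function(d) correlation_rank(d, y),
                 function(d) chi2_rank(d, y),
                 function(d) significance_rank(d, y),
                 function(d) pca_rank(d, n_components = 2))) {
    s1 <- f(x)$scores
    s2 <- f(x[, perm])$scores
    expect_equal(s2[perm], s1[perm], tolerance = 1e-12)
  }
})
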