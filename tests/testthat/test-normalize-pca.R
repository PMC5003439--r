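test_that("quantile normalization matches hand-computed references", {
  m <- cbind(a = c(2, 4, 6), b = c(1, 3, 5))
  out <- quantile_normalize(m)
  expect_equal(unname(out[, 1]), c(1.5, 3.5, 5.5))
  expect_equal(unname(out[, 2]), c(1.5, 3.5, 5.5))

  # tie rule: reference (1.5, 2.5, 5.5); the tied 1s share mean(1.5, 2.5)
  mt <- cbind(a = c(1, 1, 5), b = c(2, 4, 6))
  outt <- quantile_normalize(mt)
  expect_equal(unname(outt[, 1]), c(2, 2, 5.5))
  expect_equal(unname(outt[, 2]), c(1.5, 2.5, 5.5))

  # identical columns are a fixed point
  mi <- cbind(c(3, 1, 7), c(3, 1, 7))
  expect_equal(quantile_normalize(mi), mi)

  expect_warning(quantile_normalize(matrix(1:3, 3, 1)), "identity")
  expect_error(quantile_normalize(cbind(c(1, NA), c(1, 2))),
               class = "qc_validation_error")
})

test_that("quantile normalization equalizes distributions and preserves ranks", {
  set.seed(10)
  for (rep in 1:5) {
    m <- matrix(stats::rlnorm(200 * 6), 200, 6)
    out <- quantile_normalize(m)
    sorted <- apply(out, 2, sort)
    for (j in 2:6) expect_equal(sorted[, j], sorted[, 1], tolerance = 1e-12)
    for (j in 1:6) expect_equal(rank(out[, j]), rank(m[, j]))
  }
})

test_that("quantile normalization agrees with the limma implementation", {
  skip_if_not_installed("limma")
  set.seed(11)
  m <- matrix(stats::rlnorm(300 * 5), 300, 5)
  m[sample(300, 20), 2] <- m[sample(300, 20), 2]  # keep some ties possible
  expect_equal(quantile_normalize(m),
               limma::normalizeQuantiles(m, ties = TRUE), tolerance = 1e-10)
})

test_that("median polish recovers additive structure exactly", {
  r <- c(1, 2, 4); cvals <- c(0.5, -1, 3, 0)
  x <- outer(r, cvals, "+")
  expr <- median_polish_summarize(x, rep("ps1", 3))
  expect_equal(unname(expr["ps1", ]), stats::median(r) + cvals, tolerance = 1e-12)

  # constant matrix
  expr2 <- median_polish_summarize(matrix(7, 4, 3), rep("ps", 4))
  expect_equal(unname(expr2[1, ]), rep(7, 3))

  # single-probe probe set passes through
  x3 <- rbind(c(1, 2, 3), c(9, 9, 9), c(9, 9, 9))
  expr3 <- median_polish_summarize(x3, c("solo", "dual", "dual"))
  expect_equal(unname(expr3["solo", ]), c(1, 2, 3))

  expect_error(median_polish_summarize(matrix(c(1, Inf), 1, 2), "p"),
               class = "qc_validation_error")
})

test_that("median polish residual row/column medians drop below tol", {
  set.seed(12)
  for (rep in 1:10) {
    x <- matrix(stats::rnorm(11 * 6, 8, 2), 11, 6)
    fit <- qccircos:::median_polish_fit(x, max_iter = 10L, tol = 0.01)
    expect_lt(max(abs(apply(fit$residuals, 1, stats::median))), 0.01)
    expect_lt(max(abs(apply(fit$residuals, 2, stats::median))), 0.01)
    # decomposition reconstructs the input
    rec <- fit$overall + outer(fit$row, fit$col, "+") + fit$residuals
    expect_equal(rec, x, tolerance = 1e-10)
  }
})

test_that("median polish agrees with stats::medpolish at convergence", {
  set.seed(13)
  x <- matrix(stats::rnorm(20 * 5, 10, 1.5), 20, 5)
  ours <- qccircos:::median_polish_fit(x, max_iter = 50L, tol = 1e-8)
  ref <- stats::medpolish(x, eps = 1e-10, maxiter = 50, trace.iter = FALSE)
  expect_equal(ours$overall + ours$col, ref$overall + ref$col,
               tolerance = 1e-4)
})

test_that("PCA scores match an independent eigendecomposition oracle", {
  x <- rbind(c(2.0, 1.0, 0.0),
             c(0.5, 1.5, 2.5),
             c(1.0, 3.0, 2.0))
  res <- pca_scores(structure(x, dimnames = list(paste0("ps", 1:3),
                                                 paste0("a", 1:3))),
                    n_components = 2L)
  xc <- x - rowMeans(x)
  ev <- eigen(t(xc) %*% xc, symmetric = TRUE)
  expect_equal(abs(res$scores[, 1]) , abs(ev$vectors[, 1] * sqrt(ev$values[1])),
               tolerance = 1e-9, ignore_attr = TRUE)
  expect_equal(res$variance_explained[1:2],
               (ev$values / sum(ev$values))[1:2], tolerance = 1e-9)
  # score columns are mean-centred
  expect_equal(colMeans(res$scores), c(PC1 = 0, PC2 = 0), tolerance = 1e-9)
})

test_that("PCA degenerate and duplicate cases behave as documented", {
  set.seed(14)
  x <- matrix(stats::rnorm(40), 20, 2,
              dimnames = list(paste0("p", 1:20), c("a", "b")))
  res <- pca_scores(x, 1L)
  expect_equal(res$variance_explained[1], 1, tolerance = 1e-12)

  x3 <- cbind(x, b2 = x[, 2])
  expect_warning(res3 <- pca_scores(x3, 5L), "clipped")
  expect_equal(res3$scores["b", ], res3$scores["b2", ], tolerance = 1e-9)

  # variance fractions are non-increasing and sum to 1 over all components
  x4 <- matrix(stats::rnorm(20 * 6), 20, 6,
               dimnames = list(paste0("p", 1:20), paste0("a", 1:6)))
  res4 <- pca_scores(x4, 6L)
  expect_true(all(diff(res4$all_variance_explained) <= 1e-12))
  expect_equal(sum(res4$all_variance_explained), 1, tolerance = 1e-9)
})

test_that("all-component scores reproduce pairwise distances of the centred data", {
  set.seed(15)
  x <- matrix(stats::rnorm(30 * 5, 6, 1), 30, 5,
              dimnames = list(paste0("p", 1:30), paste0("a", 1:5)))
  res <- pca_scores(x, 5L)
  xc <- x - rowMeans(x)
  expect_equal(unname(as.matrix(stats::dist(res$scores))),
               unname(as.matrix(stats::dist(t(xc)))), tolerance = 1e-9)
})

test_that("sign convention: the dominant loading element is positive", {
  set.seed(16)
  x <- matrix(stats::rnorm(50 * 4), 50, 4,
              dimnames = list(paste0("p", 1:50), paste0("a", 1:4)))
  xc <- x - rowMeans(x)
  s <- svd(xc)
  res <- pca_scores(x, 2L)
  for (i in 1:2) {
    j <- which.max(abs(s$u[, i]))
    expected <- s$v[, i] * s$d[i] * sign(s$u[j, i])
    expect_equal(unname(res$scores[, i]), expected, tolerance = 1e-9)
  }
})
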