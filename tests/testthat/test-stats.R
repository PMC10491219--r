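test_that("pseudotime binning splits cells into equal-count ordered bins", {
  pt <- runif(1000)
  X <- matrix(pt * 2, ncol = 1, dimnames = list(NULL, "m"))
  b <- bin_pseudotime(pt, X, B = 200)
  expect_equal(b$counts, rep(5L, 200), ignore_attr = TRUE)
  expect_true(all(diff(b$midpoints) >= 0))
  # remainder spread over the first bins
  b2 <- bin_pseudotime(runif(1003), matrix(rnorm(1003), ncol = 1,
                                           dimnames = list(NULL, "m")), B = 200)
  expect_equal(b2$counts[1:3], rep(6L, 3), ignore_attr = TRUE)
  expect_equal(b2$counts[4:200], rep(5L, 197), ignore_attr = TRUE)
  # constant marker: every bin mean equals the constant
  bc <- bin_pseudotime(pt, matrix(7, 1000, 1, dimnames = list(NULL, "c")), B = 50)
  expect_equal(unname(bc$bin_means[, 1]), rep(7, 50))
  expect_error(bin_pseudotime(pt, X, B = 1), "B")
  expect_error(bin_pseudotime(runif(10), matrix(rnorm(10), ncol = 1,
                                                dimnames = list(NULL, "m")), B = 20),
               "fewer")
})

test_that("bin means conserve the overall mean (weighted identity)", {
  set.seed(13)
  pt <- runif(1537)
  X <- matrix(rnorm(1537 * 3), ncol = 3, dimnames = list(NULL, c("a", "b", "c")))
  b <- bin_pseudotime(pt, X, B = 200)
  overall <- colSums(b$bin_means * b$counts) / sum(b$counts)
  expect_equal(overall, colMeans(X), tolerance = 1e-9)
})

test_that("derivatives of a linear ramp are constant and integrate back", {
  B <- 100
  pt <- seq(0, 1, length.out = 1000)
  X <- matrix(pt, ncol = 1, dimnames = list(NULL, "ramp"))
  b <- bin_pseudotime(pt, X, B = B)
  d <- expression_derivative(b, smoothing_window = 1)
  expect_equal(unname(d$derivative[, 1]), rep(1, B - 1), tolerance = 1e-6)
  # discrete fundamental theorem (unsmoothed): sum of steps = net change
  set.seed(3)
  Y <- matrix(rnorm(1000), ncol = 1, dimnames = list(NULL, "noisy"))
  b2 <- bin_pseudotime(pt, Y, B = B)
  d2 <- expression_derivative(b2, smoothing_window = 1)
  lhs <- sum(d2$derivative[, 1] * diff(b2$midpoints))
  expect_equal(lhs, b2$bin_means[B, 1] - b2$bin_means[1, 1], tolerance = 1e-9,
               ignore_attr = TRUE)
  # constant marker: zero derivative, no inflections
  b3 <- bin_pseudotime(pt, matrix(2, 1000, 1, dimnames = list(NULL, "flat")), B = 50)
  d3 <- expression_derivative(b3, smoothing_window = 1)
  expect_equal(unname(d3$derivative[, 1]), rep(0, 49))
  expect_length(d3$inflections$flat$sign_changes, 0)
  expect_length(d3$inflections$flat$max_rate_bins, 0)
  expect_error(expression_derivative(b3, smoothing_window = 4), "odd")
})

test_that("a logistic marker's steepest bin sits at its inflection time", {
  set.seed(17)
  n <- 20000
  t <- runif(n)
  t0 <- 0.62
  mu <- 1 + 2 / (1 + exp(-(t - t0) / 0.05))
  x <- mu + rnorm(n, 0, 0.25)
  b <- bin_pseudotime(t, matrix(x, ncol = 1, dimnames = list(NULL, "lg")), B = 200)
  d <- expression_derivative(b, smoothing_window = 9)
  peak <- which.max(abs(d$derivative[, 1]))
  t0_bin <- which.min(abs(b$midpoints - t0))
  expect_lte(abs(peak - t0_bin), 3)
})

test_that("Manhattan dissimilarity matches brute force and clusters samples", {
  set.seed(19)
  P <- matrix(rexp(8 * 5), 8, 5)
  P <- P / rowSums(P)
  rownames(P) <- paste0("s", 1:8)
  dm <- sample_dissimilarity(P)
  expect_equal(dm$D, manhattan_brute(P), ignore_attr = TRUE)
  expect_equal(diag(dm$D), rep(0, 8), ignore_attr = TRUE)
  expect_true(isSymmetric(dm$D))
  # triangle inequality
  for (i in 1:8) for (j in 1:8) for (k in 1:8) {
    expect_lte(dm$D[i, j], dm$D[i, k] + dm$D[k, j] + 1e-12)
  }
  # canonical values
  two <- rbind(a = c(1, 0), b = c(0, 1), c = c(0.5, 0.5))
  D2 <- sample_dissimilarity(two)$D
  expect_equal(D2["a", "b"], 2)        # maximal for proportion vectors
  expect_equal(D2["a", "c"], 1)
  expect_equal(D2["a", "a"], 0)
  expect_s3_class(dm$dendrogram, "hclust")
  expect_error(sample_dissimilarity(rbind(c(0.5, 0.2), c(0.5, 0.5))), "sum")
  expect_error(sample_dissimilarity(two[1, , drop = FALSE]), "2 samples")
})

test_that("Wilcoxon p-values are exact for small tie-free groups", {
  v <- cbind(f1 = c(1, 2, 3, 10, 11, 12))
  g <- rep(c("a", "b"), each = 3)
  res <- compare_groups(v, g)
  expect_equal(res$p, 0.1)            # most extreme of choose(6,3)=20 splits
  expect_equal(attr(res, "fdr_method"), "BH")
  # full-enumeration oracle across group sizes <= 6
  set.seed(23)
  for (nx in c(3, 4, 6)) for (ny in c(3, 5, 6)) {
    x <- sample(seq_len(50), nx); y <- sample(seq_len(50) + 100, ny) / 7
    res <- compare_groups(cbind(f = c(x, y)), rep(c("a", "b"), c(nx, ny)))
    expect_equal(res$p, wilcox_enumerate(x, y), tolerance = 1e-12)
  }
  # identical groups: no rank separation
  res0 <- compare_groups(cbind(f = rep(1, 6)), g)
  expect_equal(res0$p, 1)
  expect_error(compare_groups(cbind(f = 1:3), c("a", "a", "b")), "2 samples")
})

test_that("q-values are a monotone FDR adjustment of p", {
  set.seed(29)
  n <- 80  # >= 50 features: local-FDR path
  v <- matrix(rnorm(8 * n), 8, n, dimnames = list(NULL, paste0("f", 1:n)))
  v[1:4, 1:10] <- v[1:4, 1:10] + 4   # true signal in 10 features
  res <- compare_groups(v, rep(c("a", "b"), each = 4))
  expect_equal(attr(res, "fdr_method"), "local-fdr")
  expect_true(all(res$q >= 0 & res$q <= 1))
  ord <- order(res$p)
  expect_true(all(diff(res$q[ord]) >= -1e-12))
  # small family: BH, q >= p
  res2 <- compare_groups(v[, 1:5], rep(c("a", "b"), each = 4))
  expect_equal(attr(res2, "fdr_method"), "BH")
  expect_true(all(res2$q >= res2$p - 1e-12))
})

test_that("percent-positive reports per-sample fractions and flags empty subsets", {
  X <- matrix(c(rep(5, 50), rep(0, 50)), ncol = 1, dimnames = list(NULL, "m"))
  ids <- rep(c("s1", "s2"), each = 50)
  pp <- percent_positive(X, ids, thresholds = c(m = 1))
  expect_equal(unname(pp["s1", "m"]), 100)
  expect_equal(unname(pp["s2", "m"]), 0)
  # threshold at the pooled median: ~50% per construction
  X2 <- matrix(seq(0, 1, length.out = 100), ncol = 1, dimnames = list(NULL, "m"))
  pp2 <- percent_positive(X2, rep("s", 100), thresholds = c(m = median(X2)))
  expect_equal(unname(pp2["s", "m"]), 50, tolerance = 1)
  # empty subset -> NA with warning, never zero
  expect_warning(pp3 <- percent_positive(X, ids, subset = ids == "s1",
                                         thresholds = c(m = 1)), "s2")
  expect_true(is.na(pp3["s2", "m"]))
  expect_equal(unname(pp3["s1", "m"]), 100)
})
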