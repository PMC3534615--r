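# SCN and alternative normalizations, filtering, correlation, binning, blur.

test_that("SCN handles the forced 2x2 and identity cases", {
  s1 <- scn(matrix(1, 2, 2), tol = 1e-9)
  expect_equal(s1$matrix, matrix(1 / sqrt(2), 2, 2))
  expect_equal(s1$n_iterations, 1L)

  s2 <- scn(diag(4), tol = 1e-9)
  expect_equal(s2$matrix, diag(4))
  expect_equal(s2$n_iterations, 0L)    # already a fixed point

  expect_error(scn(rbind(c(1, 0), c(0, 0))), "zero row")
})

test_that("SCN equals the brute-force sweep oracle on random 5x5 matrices", {
  set.seed(42)
  for (rep in 1:5) {
    m <- matrix(runif(25, 0.2, 1), 5, 5)
    m <- (m + t(m)) / 2
    res <- scn(m, tol = 1e-9, max_iter = 500)
    norms <- c(sqrt(rowSums(res$matrix^2)), sqrt(colSums(res$matrix^2)))
    expect_true(all(abs(norms - 1) < 1e-6))
    oracle <- scn_oracle(m, tol = 1e-12)
    expect_equal(res$matrix, oracle, tolerance = 1e-8)
  }
})

test_that("SCN output is a fixed point and is scale invariant", {
  set.seed(7)
  m <- matrix(runif(100, 0.5, 1), 10, 10); m <- (m + t(m)) / 2
  res <- scn(m, tol = 1e-9)
  # one further sweep changes nothing beyond tolerance
  again <- scn(res$matrix, tol = 1e-9)
  expect_equal(again$n_iterations, 0L)
  expect_equal(again$matrix, res$matrix, tolerance = 1e-9)
  # global rescaling of the input does not change the output
  res2 <- scn(37.5 * m, tol = 1e-9)
  expect_equal(res2$matrix, res$matrix, tolerance = 1e-9)
  # zero pattern is preserved
  mz <- m; mz[1, 3] <- mz[3, 1] <- 0
  resz <- scn(mz, tol = 1e-9)
  expect_equal(resz$matrix[1, 3], 0)
  expect_true(all(resz$matrix[mz > 0] > 0))
})

test_that("SCN raises a typed condition when it cannot converge", {
  set.seed(1)
  m <- matrix(runif(64, 0.5, 1), 8, 8); m <- (m + t(m)) / 2
  expect_error(scn(m, tol = 1e-12, max_iter = 1L),
               class = "scn_non_convergence")
})

test_that("norm-product matches its closed form and approximates SCN", {
  np <- norm_product(matrix(1, 2, 2))
  expect_equal(np, matrix(0.5, 2, 2))
  # result rows are not unit vectors (the argument for SCN)
  expect_equal(sqrt(rowSums(np^2)), rep(1 / sqrt(2), 2))

  set.seed(3)
  m <- matrix(runif(400, 0.5, 1), 20, 20); m <- (m + t(m)) / 2
  a <- scn(m, tol = 1e-9)$matrix
  b <- norm_product(m)
  # well-conditioned input: the two maps agree up to a global scale
  off <- upper.tri(m)
  expect_gt(stats::cor(a[off], b[off]), 0.999)
  rel <- (b[off] / sum(b[off])) / (a[off] / sum(a[off]))
  expect_lt(max(abs(rel - 1)), 0.05)
  # quotient maps rescale as 1/alpha under input rescaling
  expect_equal(norm_product(10 * m), b / 10)
})

test_that("marginal-sum normalization and its contrast property", {
  expect_equal(marginal_sum(matrix(1, 2, 2)), matrix(0.25, 2, 2))
  # doubly stochastic input: output is input scaled by a constant
  ds <- matrix(0.25, 4, 4)
  expect_equal(marginal_sum(ds), ds / ds[1, 1] * marginal_sum(ds)[1, 1])
  expect_equal(marginal_sum(5 * ds), marginal_sum(ds) / 5)

  # on structured generator maps the L1 map ranks interactions nearly the
  # same as SCN while weighting fragment coverage differently
  sim <- default_sim()
  set.seed(11)
  cm <- sample_contacts(sim$propensities, sim$frags, 2e5, scope = "intra")
  cmf <- filter_low_norm(cm, 30)
  a <- scn(cmf, max_iter = 300)$matrix$values   # sparse blocks converge slowly
  b <- marginal_sum(cmf)$values
  off <- upper.tri(a)
  expect_gt(stats::cor(a[off], b[off], method = "spearman"), 0.95)
  # L1 normalization is not an L2 fixed point: its rows are not unit vectors
  expect_gt(max(abs(sqrt(rowSums(b^2)) - 1)), 0.1)
})

test_that("low-norm filtering removes exactly the weak fragments", {
  # 3x3 toy with row norms 50, 29, 31
  v <- diag(c(50, 29, 31))
  cm <- cm_from_matrix(v)
  f <- filter_low_norm(cm, 30)
  expect_equal(attr(f, "n_removed"), 1L)
  expect_equal(f$index$fragment_id, c(1L, 3L))
  # zero rows go at any positive threshold
  vz <- matrix(c(1, 0, 0, 0), 2, 2)
  fz <- filter_low_norm(vz, 1e-9)
  expect_equal(dim(fz), c(1L, 1L))
  # threshold 0 is the identity
  f0 <- filter_low_norm(v, 0)
  expect_equal(attr(f0, "n_removed"), 0L)
  expect_error(filter_low_norm(v, 1e6), "all fragments")
})

test_that("correlation map reproduces the textbook Pearson formula", {
  v <- rbind(c(0, 3, 1, 4), c(3, 0, 2, 6), c(1, 2, 0, 2), c(4, 6, 2, 0))
  cc <- correlation_map(cm_from_matrix(v))$values
  pearson <- function(a, b) {
    sum((a - mean(a)) * (b - mean(b))) /
      sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  }
  for (i in 1:4) for (j in 1:4)
    expect_equal(cc[i, j], pearson(v[i, ], v[j, ]), tolerance = 1e-12)
  expect_true(all(cc >= -1 - 1e-12 & cc <= 1 + 1e-12))
  # identical rows correlate at exactly 1
  v2 <- rbind(c(1, 2, 3), c(1, 2, 3), c(9, 1, 4))
  cc2 <- correlation_map(v2)
  expect_equal(cc2[1, 2], 1)
  # zero-variance row: flagged NA
  v3 <- rbind(c(1, 1, 1), c(1, 2, 3), c(9, 1, 4))
  expect_warning(cc3 <- correlation_map(v3), "zero-variance")
  expect_true(is.na(cc3[1, 2]))
})

test_that("binning sums consecutive fragments and conserves mass", {
  cm <- cm_from_matrix(matrix(1, 4, 4))
  b1 <- bin_matrix(cm, 1)
  expect_equal(b1$values, cm$values)
  b2 <- bin_matrix(cm, 2)
  expect_equal(b2$values, matrix(4, 2, 2))
  # random input, partial final bin, two chromosomes
  set.seed(5)
  v <- matrix(rpois(11^2, 4), 11, 11); v <- v + t(v)
  cmr <- cm_from_matrix(v, chrom = rep(c("a", "b"), c(7, 4)))
  for (b in c(1, 2, 3, 5)) {
    bb <- bin_matrix(cmr, b)
    expect_equal(sum(bb$values), sum(v))
    expect_equal(bb$values, t(bb$values))
    # bins never straddle chromosomes
    expect_true(all(tapply(bb$index$chrom, bb$index$bin, function(x)
      length(unique(x))) == 1))
  }
})

test_that("the visualization blur applies the exact 0.05 kernel", {
  v <- matrix(2, 9, 9)
  b1 <- blur(v, reps = 1)
  expect_equal(b1[5, 5], 0.45 * 2)          # interior: kernel sum 0.45
  expect_equal(b1[1, 1], 4 * 0.05 * 2)      # corner under zero padding
  # single impulse spreads to a 3x3 block of 0.05
  imp <- matrix(0, 9, 9); imp[5, 5] <- 1
  bi <- blur(imp, reps = 1)
  expect_equal(bi[4:6, 4:6], matrix(0.05, 3, 3))
  expect_equal(sum(bi), 0.45)
  # ten passes on a constant matrix: 0.45^10 far from the edges
  big <- matrix(1, 41, 41)
  b10 <- blur(big, reps = 10)
  expect_equal(b10[21, 21], 0.45^10, tolerance = 1e-6)
})
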