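test_that("compute_rdm matches the pairwise Pearson oracle", {
  pats <- rbind(c(1, 2, 3), c(1, 2, 4), c(3, 2, 1))
  d <- compute_rdm(pats)
  expect_equal(unclass(d), rdm_oracle(pats), tolerance = 1e-12,
               ignore_attr = TRUE)

  set.seed(3)
  for (n in c(5, 8, 10)) {
    pats <- matrix(rnorm(n * 7), n, 7)
    expect_equal(unclass(compute_rdm(pats)), rdm_oracle(pats),
                 tolerance = 1e-10, ignore_attr = TRUE)
  }
})

test_that("RDM endpoints: identical rows give 0, exact anticorrelation gives 2", {
  pats <- rbind(c(1, 2, 3), c(2, 3, 4), c(5, 4, 3))
  d <- compute_rdm(pats)
  expect_equal(d[1, 2], 0)       # row 2 = row 1 + 1
  expect_equal(d[1, 3], 2)       # row 3 = -(row 1) + shift
  expect_true(all(diag(d) == 0))
  expect_true(all(d >= 0 & d <= 2))
})

test_that("RDMs are invariant to per-row affine changes with positive scale", {
  set.seed(4)
  pats <- matrix(rnorm(24), 4, 6)
  shifted <- pats
  shifted[2, ] <- pats[2, ] * 3.7 + 11
  expect_equal(compute_rdm(pats), compute_rdm(shifted), tolerance = 1e-12)
})

test_that("zero-variance rows are rejected by name", {
  pats <- rbind(a = c(1, 2, 3), b = c(5, 5, 5))
  expect_error(compute_rdm(pats), "b", class = "crosslight_data_error")
})

test_that("lower_triangle has length n(n-1)/2 and reconstructs the RDM", {
  d2 <- compute_rdm(matrix(rnorm(4), 2, 2))
  expect_length(lower_triangle(d2), 1)

  f <- generate_item_features(96, 50, seed = 2)
  d96 <- compute_rdm(f)
  v <- lower_triangle(d96)
  expect_length(v, 96 * 95 / 2)

  # symmetrize-and-refill round trip
  rebuilt <- matrix(0, 96, 96)
  rebuilt[lower.tri(rebuilt)] <- v
  rebuilt <- rebuilt + t(rebuilt)
  expect_equal(rebuilt, unclass(d96), tolerance = 1e-12, ignore_attr = TRUE)

  asym <- matrix(c(0, 1, 2, 0), 2, 2)
  expect_error(lower_triangle(asym), class = "crosslight_data_error")
})

test_that("rsa_score matches the rank-then-Pearson oracle, ties averaged", {
  set.seed(5)
  a <- compute_rdm(matrix(rnorm(20), 4, 5))
  b <- compute_rdm(matrix(rnorm(20), 4, 5))
  expect_equal(rsa_score(a, b),
               spearman_oracle(lower_triangle(a), lower_triangle(b)),
               tolerance = 1e-12)

  # tied entries: compare against the sorting-based average-rank oracle
  ta <- matrix(0, 4, 4); ta[lower.tri(ta)] <- c(1, 1, 2, 3, 2, 1)
  ta <- ta + t(ta)
  tb <- matrix(0, 4, 4); tb[lower.tri(tb)] <- c(2, 1, 1, 3, 3, 2)
  tb <- tb + t(tb)
  expect_equal(rsa_score(as_rdm(ta), as_rdm(tb)),
               spearman_oracle(c(1, 1, 2, 3, 2, 1), c(2, 1, 1, 3, 3, 2)),
               tolerance = 1e-12)
})

test_that("rsa_score endpoints and symmetry", {
  set.seed(6)
  a <- compute_rdm(matrix(rnorm(30), 5, 6))
  expect_equal(rsa_score(a, a), 1)

  # strictly decreasing monotone transform reverses all ranks
  flipped <- as_rdm(2 - unclass(a)); diag(flipped) <- 0
  expect_equal(rsa_score(a, flipped), -1)

  b <- compute_rdm(matrix(rnorm(30), 5, 6))
  expect_equal(rsa_score(a, b), rsa_score(b, a))
  expect_error(rsa_score(a, compute_rdm(matrix(rnorm(12), 4, 3))),
               class = "crosslight_data_error")
})

test_that("rsa_score is invariant under increasing monotone transforms", {
  set.seed(7)
  for (i in 1:5) {
    a <- compute_rdm(matrix(rnorm(42), 6, 7))
    b <- compute_rdm(matrix(rnorm(42), 6, 7))
    warped <- as_rdm(exp(unclass(b)) - 1); diag(warped) <- 0
    expect_equal(rsa_score(a, warped), rsa_score(a, b), tolerance = 1e-12)
  }
})

test_that("constant dissimilarities yield a flagged NA", {
  const <- as_rdm(matrix(1, 3, 3) - diag(3))
  b <- compute_rdm(matrix(rnorm(9), 3, 3))
  expect_warning(v <- rsa_score(const, b), "undefined")
  expect_true(is.na(v))
})

test_that("RDMs round-trip through the tab-separated format", {
  d <- compute_rdm(generate_item_features(8, 20, seed = 3))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_rdm(d, path)
  back <- read_rdm(path)
  expect_equal(unclass(back), unclass(d), tolerance = 1e-12)
})
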