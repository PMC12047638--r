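test_that("sphere offsets equal brute-force lattice enumeration", {
  for (case in list(list(r = 1, v = c(1, 1, 1), n = 7),
                    list(r = 3, v = c(1, 1, 1), n = 123),
                    list(r = 6, v = c(2, 2, 2), n = 123),
                    list(r = 2.5, v = c(2, 2, 2), n = 7),
                    list(r = 4, v = c(2, 2, 4), n = 15))) {
    got <- sphere_offsets(case$r, case$v)
    oracle <- sphere_offsets_oracle(case$r, case$v)
    expect_equal(nrow(got), nrow(oracle))
    if (!is.null(case$n)) expect_equal(nrow(got), case$n)
    expect_equal(unname(got), unname(oracle), ignore_attr = TRUE)
  }
})

test_that("sphere offsets always contain the center and are negation-symmetric", {
  o <- sphere_offsets(0.4, c(1, 1, 1))  # radius below one voxel
  expect_equal(nrow(o), 1)
  expect_equal(as.vector(o), c(0L, 0L, 0L))

  o <- sphere_offsets(5.2, c(2, 2, 2))
  keys <- apply(o, 1, paste, collapse = ",")
  neg <- apply(-o, 1, paste, collapse = ",")
  expect_setequal(keys, neg)
  expect_true("0,0,0" %in% keys)
  expect_error(sphere_offsets(-1, c(1, 1, 1)), class = "crosslight_config_error")
})

test_that("a constant statistic paints the whole mask", {
  mask <- ellipsoid_mask(c(8, 8, 8))
  data <- matrix(rnorm(4 * sum(mask)), 4, sum(mask))
  m <- run_searchlight(data, mask, function(d) 3.5, small_sphere())
  expect_true(all(m$values[mask] == 3.5))
  expect_true(all(is.na(m$values[!mask])))
  expect_true(all(m$validity[mask]))
})

test_that("sphere voxel counts deep inside a solid mask match the lattice oracle", {
  mask <- array(TRUE, dim = c(9, 9, 9))
  data <- matrix(0, 1, sum(mask))
  sph <- sphere_spec(radius_mm = 3, voxel_size_mm = c(1, 1, 1))
  m <- run_searchlight(data, mask, function(d) ncol(d), sph)
  expect_equal(m$values[5, 5, 5], 123)       # full sphere in the interior
  expect_equal(m$values[1, 1, 1], nrow(sphere_offsets_oracle(3, c(1, 1, 1))[
    rowSums(sphere_offsets_oracle(3, c(1, 1, 1)) < 0) == 0, , drop = FALSE]))
  expect_true(all(m$values[mask] >= 1))      # never empty: center always in
})

test_that("the sphere mean of a linear ramp returns the center's own value", {
  dims <- c(9, 9, 9)
  mask <- array(TRUE, dim = dims)
  ramp <- array(0, dim = dims)
  for (i in 1:9) ramp[i, , ] <- ramp[i, , ] + 2 * i
  for (j in 1:9) ramp[, j, ] <- ramp[, j, ] + 5 * j
  for (k in 1:9) ramp[, , k] <- ramp[, , k] - 3 * k
  data <- matrix(ramp[mask], 1, sum(mask))
  sph <- sphere_spec(radius_mm = 3, voxel_size_mm = c(1, 1, 1))
  m <- run_searchlight(data, mask, function(d) mean(d), sph)
  # offsets cancel under negation, so interior sphere means equal the ramp
  expect_equal(m$values[5, 5, 5], ramp[5, 5, 5], tolerance = 1e-10)
  expect_equal(m$values[4, 6, 5], ramp[4, 6, 5], tolerance = 1e-10)
})

test_that("searchlight output is bit-identical across chunkings", {
  set.seed(9)
  mask <- ellipsoid_mask(c(8, 8, 8))
  data <- matrix(rnorm(6 * sum(mask)), 6, sum(mask))
  stat <- function(d) sum(d[1, ]) - sum(d[2, ])
  m1 <- run_searchlight(data, mask, stat, small_sphere(), chunks = 1)
  m4 <- run_searchlight(data, mask, stat, small_sphere(), chunks = 4)
  m9 <- run_searchlight(data, mask, stat, small_sphere(), chunks = 9)
  expect_identical(m1$values, m4$values)
  expect_identical(m1$values, m9$values)
})

test_that("a failing statistic records NA at that center, not a crash", {
  mask <- array(TRUE, dim = c(3, 3, 3))
  data <- matrix(1, 2, 27)
  poison <- function(d) if (ncol(d) == 27) stop("boom") else 1
  expect_warning(m <- run_searchlight(data, mask, poison,
                                      sphere_spec(2.1, c(1, 1, 1))),
                 "failed at")
  expect_true(is.na(m$values[2, 2, 2]))   # only the full 27-voxel sphere fails
  expect_false(m$validity[2, 2, 2])
  expect_equal(m$values[1, 1, 1], 1)
})

test_that("multi-matrix data reaches the callback sliced consistently", {
  mask <- ellipsoid_mask(c(6, 6, 6))
  a <- matrix(rnorm(3 * sum(mask)), 3, sum(mask))
  m <- run_searchlight(list(x = a, y = 2 * a), mask,
                       function(d) mean(d$y - 2 * d$x), small_sphere())
  expect_true(all(abs(m$values[mask]) < 1e-12))
})
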