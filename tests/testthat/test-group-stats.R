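test_that("an isolated voxel's TFCE score approaches v^3/3", {
  for (v in c(0.5, 1, 2.5)) {
    vol <- array(0, dim = c(7, 7, 7))
    vol[4, 4, 4] <- v
    mask <- array(TRUE, dim = c(7, 7, 7))
    t <- tfce_transform(vol, tfce_params(), mask = mask)
    # closed form of the integral of h^2 dh over (0, v] with unit extent
    expect_equal(t[4, 4, 4], v^3 / 3, tolerance = 0.02)
    expect_equal(sum(t != 0), 1)
  }
})

test_that("a uniform block scales the closed form by sqrt(extent)", {
  vol <- array(0, dim = c(8, 8, 8))
  vol[3:5, 3:5, 3:5] <- 2         # 27-voxel block at value 2
  mask <- array(TRUE, dim = c(8, 8, 8))
  t <- tfce_transform(vol, tfce_params(), mask = mask)
  expect_equal(t[4, 4, 4], sqrt(27) * 2^3 / 3, tolerance = 0.02)
})

test_that("the zero map transforms to zero and negatives contribute nothing", {
  mask <- ellipsoid_mask(c(6, 6, 6))
  expect_true(all(tfce_transform(array(0, dim = c(6, 6, 6)),
                                 mask = mask) == 0))
  vol <- array(-1, dim = c(6, 6, 6))
  expect_true(all(tfce_transform(vol, mask = mask) == 0))
})

test_that("the staircase TFCE matches an independent per-threshold labelling oracle", {
  skip_if_not_installed("igraph")
  set.seed(10)
  for (conn in c(6L, 26L)) {
    dims <- c(6, 6, 6)
    mask <- ellipsoid_mask(dims, fill = 1)
    vol <- array(0, dim = dims)
    vol[mask] <- pmax(rnorm(sum(mask), 0.2, 0.6), 0)
    params <- tfce_params(n_steps = 40, connectivity = conn)
    got <- tfce_transform(vol, params, mask = mask)
    want <- tfce_oracle(vol, mask, H = 2, E = 0.5, n_steps = 40,
                        connectivity = conn)
    expect_equal(got, want, tolerance = 1e-10)
  }
})

test_that("TFCE is monotone: raising a voxel never lowers any score", {
  # on a fixed integration grid; the default adaptive dh = max/100 changes
  # the discretization when the map's maximum moves
  set.seed(11)
  dims <- c(6, 6, 6)
  mask <- array(TRUE, dim = dims)
  params <- tfce_params(dh = 0.02)
  for (i in 1:5) {
    vol <- array(pmax(rnorm(prod(dims), 0.3, 0.5), 0), dim = dims)
    t0 <- tfce_transform(vol, params, mask = mask)
    vol2 <- vol
    idx <- sample(prod(dims), 1)
    vol2[idx] <- vol2[idx] + runif(1, 0.2, 1)
    t1 <- tfce_transform(vol2, params, mask = mask)
    expect_true(all(t1 >= t0 - 1e-10))
  }
})

test_that("TFCE parameter validation", {
  expect_error(tfce_params(dh = 0), class = "crosslight_config_error")
  expect_error(tfce_params(connectivity = 10), class = "crosslight_config_error")
  expect_error(tfce_transform(array(0, dim = c(3, 3, 3))),
               class = "crosslight_config_error")  # mask required
})

test_that("identical strongly positive maps attain the minimal p in the region", {
  dims <- c(7, 7, 7)
  mask <- array(TRUE, dim = dims)
  vol <- array(0, dim = dims)
  vol[3:5, 3:5, 3:5] <- 1
  maps <- lapply(1:6, function(i) stat_map(vol, mask))
  stack <- stat_map_stack(maps, subject_pairs(1:3))
  res <- permutation_test(stack, n_permutations = 1000, seed = 1)
  expect_true(res$exhaustive)
  expect_equal(res$n_permutations, 2^6 - 1)
  p_region <- res$p_map[3:5, 3:5, 3:5]
  expect_true(all(p_region == 1 / 2^6))   # minimal attainable p
  expect_true(all(res$p_map[vol == 0] == 1))
})

test_that("maps exactly at the null value give p = 1 everywhere", {
  dims <- c(5, 5, 5)
  mask <- array(TRUE, dim = dims)
  maps <- lapply(1:4, function(i) stat_map(array(0.5, dim = dims), mask))
  stack <- stat_map_stack(maps, subject_pairs(1:2)[c(1, 2, 1, 2), ])
  res <- permutation_test(stack, null_value = 0.5, n_permutations = 200, seed = 2)
  expect_true(all(res$p_map == 1))
})

test_that("the p-map is invariant to the order of maps in the stack", {
  set.seed(12)
  dims <- c(6, 6, 6)
  mask <- ellipsoid_mask(dims)
  vols <- lapply(1:5, function(i) {
    v <- array(NA_real_, dim = dims); v[mask] <- rnorm(sum(mask), 0.1, 0.3); v
  })
  maps <- lapply(vols, function(v) stat_map(v, mask))
  pairs <- subject_pairs(1:3)[1:5, ]
  r1 <- permutation_test(stat_map_stack(maps, pairs), n_permutations = 400, seed = 3)
  r2 <- permutation_test(stat_map_stack(rev(maps), pairs), n_permutations = 400, seed = 3)
  expect_equal(r1$p_map, r2$p_map)
})

test_that("exhaustive enumeration agrees with large Monte-Carlo sampling", {
  set.seed(13)
  dims <- c(5, 5, 5)
  mask <- array(TRUE, dim = dims)
  vols <- lapply(1:12, function(i) {
    v <- array(rnorm(prod(dims), 0.15, 0.25), dim = dims)
    v[2:4, 2:4, 2:4] <- v[2:4, 2:4, 2:4] + 0.4
    v
  })
  maps <- lapply(vols, function(v) stat_map(v, mask))
  pairs <- subject_pairs(1:4)
  exact <- permutation_test(stat_map_stack(maps, pairs),
                            n_permutations = 4095, seed = 1)  # 2^12-1 exhaustive
  mc <- permutation_test(stat_map_stack(maps, pairs),
                         n_permutations = 2000, seed = 5)      # sampled
  expect_true(exact$exhaustive)
  expect_false(mc$exhaustive)
  expect_equal(mean(abs(mc$p_map - exact$p_map)), 0, tolerance = 0.05)
})

test_that("permutation test configuration errors", {
  dims <- c(4, 4, 4)
  mask <- array(TRUE, dim = dims)
  maps <- lapply(1:2, function(i) stat_map(array(rnorm(64), dim = dims), mask))
  stack <- stat_map_stack(maps, subject_pairs(1:2))
  expect_error(permutation_test(stack, n_permutations = 0),
               class = "crosslight_config_error")
  expect_error(permutation_test(stack$maps[1], n_permutations = 10),
               class = "crosslight_config_error")
})
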