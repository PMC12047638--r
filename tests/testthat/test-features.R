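test_that("average_by_item reduces to the elementwise mean in canonical order", {
  # one trial per item: identity up to reordering
  x <- matrix(1:6, 2, 3, byrow = TRUE)
  out <- average_by_item(x, c("2", "1"))
  expect_equal(out["1", ], x[2, ], ignore_attr = TRUE)
  expect_equal(out["2", ], x[1, ], ignore_attr = TRUE)

  # duplicated trials: idempotent mean
  out2 <- average_by_item(rbind(x[1, ], x[1, ]), c(7, 7))
  expect_equal(out2["7", ], x[1, ], ignore_attr = TRUE)

  # elementwise mean oracle
  out3 <- average_by_item(rbind(c(1, 2, 3), c(3, 4, 5)), c(1, 1))
  expect_equal(out3["1", ], c(2, 3, 4), ignore_attr = TRUE)
})

test_that("average_by_item commutes with within-item trial permutation", {
  set.seed(42)
  x <- matrix(rnorm(30), 10, 3)
  labs <- sample(1:3, 10, replace = TRUE)
  perm <- sample(10)
  expect_equal(average_by_item(x, labs), average_by_item(x[perm, ], labs[perm]))
})

test_that("demanding a full item set flags items with zero trials", {
  x <- matrix(rnorm(6), 2, 3)
  expect_error(average_by_item(x, c(1, 2), items = 1:3),
               class = "crosslight_data_error")
  expect_error(average_by_item(x, c(1, 2, 3)), class = "crosslight_data_error")
})

test_that("summarize_by_item shares the averaging contract", {
  x <- matrix(rnorm(12), 4, 3)
  expect_equal(summarize_by_item(x, c(2, 1, 2, 1)),
               average_by_item(x, c(2, 1, 2, 1)))
})

test_that("the tiny backbone is deterministic and shape-stable", {
  set.seed(7)
  imgs <- array(runif(2 * 9 * 9 * 3), dim = c(2, 9, 9, 3))
  f1 <- extract_features(imgs, backbone_spec(hidden_dim = 300))
  f2 <- extract_features(imgs, backbone_spec(hidden_dim = 300))
  expect_identical(f1, f2)
  expect_equal(dim(f1), c(2, 300))

  # identical images give identical feature rows
  imgs[2, , , ] <- imgs[1, , , ]
  f <- extract_features(imgs, backbone_spec(hidden_dim = 20))
  expect_equal(f[1, ], f[2, ])
})

test_that("feature extraction is invariant to batch partitioning", {
  set.seed(8)
  imgs <- array(runif(4 * 8 * 8 * 1), dim = c(4, 8, 8, 1))
  all_at_once <- extract_features(imgs, backbone_spec(hidden_dim = 10))
  in_batches <- rbind(
    extract_features(imgs[1:2, , , , drop = FALSE], backbone_spec(hidden_dim = 10)),
    extract_features(imgs[3:4, , , , drop = FALSE], backbone_spec(hidden_dim = 10)))
  expect_equal(all_at_once, in_batches)
})

test_that("extraction through a custom backbone equals a hand-computed forward pass", {
  # toy backend: 2 fixed pooled descriptors per image
  register_backbone("toy-sum", function(images) {
    t(vapply(as_image_list(images), function(im) c(sum(im), sum(im^2)),
             numeric(2)))
  })
  imgs <- list(array(c(1, 2, 3, 4), dim = c(2, 2, 1)),
               array(c(0, 1, 0, 1), dim = c(2, 2, 1)))
  head <- list(w1 = matrix(c(1, 0, 0, 1, 1, -1), 2, 3), b1 = c(0, 0.5, -30),
               w2 = matrix(0, 3, 2), b2 = c(0, 0))
  got <- extract_features(imgs, backbone_spec(backbone_name = "toy-sum",
                                              hidden_dim = 3), head = head)
  pooled <- rbind(c(10, 30), c(2, 2))
  expected <- selu(sweep(pooled %*% head$w1, 2, head$b1, `+`))
  expect_equal(got, expected, tolerance = 1e-12)
  # spot-check one SELU value by hand: unit 3, image 2 -> 2 - 2 - 30 = -30
  lambda <- 1.0507009873554805; alpha <- 1.6732632423543772
  expect_equal(got[2, 3], lambda * alpha * (exp(-30) - 1), tolerance = 1e-12)
})

test_that("an unregistered backbone is a configuration error", {
  expect_error(extract_features(array(0, c(1, 5, 5, 1)),
                                backbone_spec(backbone_name = "resnet50")),
               class = "crosslight_config_error")
})

test_that("head training lowers the loss and stops after the patience window", {
  set.seed(11)
  n <- 80
  pooled <- matrix(rnorm(n * 6), n, 6)
  classes <- rep(1:2, each = n / 2)
  pooled[classes == 2, 1] <- pooled[classes == 2, 1] + 2
  spec <- backbone_spec(hidden_dim = 8, early_stop_patience = 5)
  fit <- train_head(pooled, classes, spec, max_epochs = 150, seed = 2)
  expect_lt(tail(fit$train_loss, 1), fit$train_loss[1])
  if (fit$epochs_run < 150) {
    # stopped early: the last `patience` epochs brought no improvement
    best <- which.min(fit$val_loss)
    expect_equal(fit$epochs_run - best, spec$early_stop_patience)
  }
  # a patience-1 run can only stop at or before the patience-5 run
  fit1 <- train_head(pooled, classes,
                     backbone_spec(hidden_dim = 8, early_stop_patience = 1),
                     max_epochs = 150, seed = 2)
  expect_lte(fit1$epochs_run, fit$epochs_run)
})

test_that("selu matches its closed form on both branches", {
  lambda <- 1.0507009873554805; alpha <- 1.6732632423543772
  expect_equal(selu(2), lambda * 2)
  expect_equal(selu(-1), lambda * alpha * (exp(-1) - 1))
  expect_equal(selu(0), 0)
})
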