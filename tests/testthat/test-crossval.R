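test_that("ordered subject pairs enumerate n(n-1) combinations", {
  expect_equal(nrow(subject_pairs(1:7)), 42)
  expect_equal(nrow(subject_pairs(1:2)), 2)
  expect_equal(nrow(subject_pairs(1:4)), 12)
  p <- subject_pairs(c("s1", "s2", "s3"))
  expect_true(all(p$train != p$test))
  expect_equal(p$train, rep(c("s1", "s2", "s3"), each = 2))
  expect_error(subject_pairs("only"), class = "crosslight_config_error")
})

test_that("the three scenarios map to the intended condition pairs", {
  expect_equal(scenario("within_conscious")$train_condition, "aware")
  expect_equal(scenario("within_conscious")$test_condition, "aware")
  expect_equal(scenario("within_unconscious")$train_condition, "unaware")
  expect_equal(scenario("within_unconscious")$test_condition, "unaware")
  s <- scenario("conscious_to_unconscious")
  expect_equal(s$train_condition, "aware")
  expect_equal(s$test_condition, "unaware")
  expect_error(scenario("glimpse_to_aware"))
})

test_that("an RSA scenario produces one map per ordered pair", {
  st <- tiny_study(n_subjects = 3, grid = c(10, 10, 10))
  stack <- suppressMessages(
    run_rsa_scenario(st$volumes, st$features, scenario("conscious_to_unconscious"),
                     small_sphere()))
  expect_s3_class(stack, "stat_map_stack")
  expect_length(stack$maps, 6)
  expect_equal(stack$null_value, 0)
  expect_equal(stack$statistic_name, "rsa_spearman")
})

test_that("a pair's map depends only on its own two subjects", {
  st <- tiny_study(n_subjects = 3, grid = c(8, 8, 8))
  scn <- scenario("within_conscious")
  stack1 <- suppressMessages(
    run_rsa_scenario(st$volumes, st$features, scn, small_sphere()))
  # perturb subject 3 heavily; map for pair 1->2 must be bit-identical
  vols2 <- st$volumes
  vols2[["3"]]$data <- vols2[["3"]]$data * 5 + 1
  stack2 <- suppressMessages(
    run_rsa_scenario(vols2, st$features, scn, small_sphere()))
  k <- which(stack1$pairs$train == "1" & stack1$pairs$test == "2")
  expect_identical(stack1$maps[[k]]$values, stack2$maps[[k]]$values)
})

test_that("restricting the subject subset keeps per-pair values unchanged", {
  st <- tiny_study(n_subjects = 4, grid = c(8, 8, 8))
  scn_all <- scenario("within_conscious")
  scn_sub <- scenario("within_conscious", subject_subset = c("1", "2", "3"))
  full <- suppressMessages(
    run_rsa_scenario(st$volumes, st$features, scn_all, small_sphere()))
  sub <- suppressMessages(
    run_rsa_scenario(st$volumes, st$features, scn_sub, small_sphere()))
  expect_length(full$maps, 12)
  expect_length(sub$maps, 6)
  for (k in seq_len(nrow(sub$pairs))) {
    j <- which(full$pairs$train == sub$pairs$train[k] &
                 full$pairs$test == sub$pairs$test[k])
    expect_identical(sub$maps[[k]]$values, full$maps[[j]]$values)
  }
  expect_error(
    run_rsa_scenario(st$volumes, st$features,
                     scenario("within_conscious", subject_subset = "9"),
                     small_sphere()),
    class = "crosslight_config_error")
})

test_that("pairs lacking a condition are skipped with a warning", {
  st <- tiny_study(n_subjects = 2, grid = c(8, 8, 8))
  vols <- st$volumes
  vols[["2"]]$trials$awareness[] <- "glimpse"  # subject 2 has no aware trials
  warns <- character()
  stack <- withCallingHandlers(
    run_rsa_scenario(vols, st$features, scenario("within_conscious"),
                     small_sphere()),
    warning = function(w) {
      warns <<- c(warns, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  # both ordered pairs involve subject 2 in a required condition: all skipped
  expect_length(stack$maps, 0)
  expect_length(warns, 2)
  expect_true(all(grepl("skipped", warns)))
})

test_that("zero-weight data give RSA maps centred on zero", {
  st <- tiny_study(n_subjects = 2, grid = c(10, 10, 10), signal_scale = 0)
  stack <- suppressMessages(
    run_rsa_scenario(st$volumes, st$features, scenario("conscious_to_unconscious"),
                     small_sphere()))
  vals <- unlist(lapply(stack$maps, function(m) m$values[m$validity]))
  expect_lt(abs(mean(vals)), 0.02)
})

test_that("decoding scenarios yield AUC maps above chance only where signal lives", {
  st <- tiny_study(n_subjects = 2, grid = c(10, 10, 10), noise_sd = 0.4)
  stack <- run_decoding_scenario(st$volumes, scenario("conscious_to_unconscious"),
                                 small_sphere())
  expect_length(stack$maps, 2)
  expect_equal(stack$null_value, 0.5)
  m <- stack$maps[[1]]
  sig <- st$truth$signal_mask & m$validity
  null_away <- m$validity & !st$truth$signal_mask
  expect_gt(mean(m$values[sig]), 0.7)
  expect_lt(abs(mean(m$values[null_away]) - 0.5), 0.1)
})

test_that("map stacks validate their pair table and grids", {
  st <- tiny_study(n_subjects = 2, grid = c(8, 8, 8))
  stack <- run_decoding_scenario(st$volumes, scenario("within_conscious"),
                                 small_sphere())
  expect_error(stat_map_stack(stack$maps, stack$pairs[1, , drop = FALSE]),
               class = "crosslight_data_error")
})
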