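test_that("hyperparameter validation clamps the degenerate split size", {
  expect_warning(hp <- hyperparams(min_samples_split = 1), "clamping to 2")
  expect_identical(hp$min_samples_split, 2L)
  expect_error(hyperparams(min_impurity_decrease = -1), "nonnegative")
  expect_error(hyperparams(min_samples_leaf = 0), "positive integer")
})

test_that("constant targets give a single-leaf tree", {
  d <- tibble::tibble(x = 1:10, barthel_index = rep(45, 10))
  fit <- fit_tree(d)
  expect_null(fit$root$feature_index)
  expect_equal(fit$root$value, 45)
  expect_equal(predict(fit, tibble::tibble(x = c(-5, 100))), c(45, 45))
})

test_that("a clean step function is split at the midpoint", {
  d <- tibble::tibble(x = c(1, 2, 3, 10, 11, 12),
                      y = c(0, 0, 0, 100, 100, 100))
  fit <- fit_tree(d, target = "y")
  expect_equal(fit$root$threshold, 6.5)
  expect_equal(fit$root$left$value, 0)
  expect_equal(fit$root$right$value, 100)
  expect_equal(predict(fit, tibble::tibble(x = c(2, 11))), c(0, 100))
  # independent library cross-check on the same data
  skip_if_not_installed("rpart")
  rp <- rpart::rpart(y ~ x, data = d, method = "anova",
                     control = rpart::rpart.control(minsplit = 2, minbucket = 1,
                                                    cp = 0, xval = 0))
  expect_equal(unname(rp$splits[1, "index"]), 6.5)
  expect_equal(unname(predict(rp, tibble::tibble(x = c(2, 11)))), c(0, 100))
})

test_that("fitted trees match the exhaustive oracle on random tables", {
  for (i in 1:30) {
    d <- random_table(n = sample(4:12, 1), p = sample(1:4, 1), seed = 1000 + i)
    fit <- fit_tree(d)
    oracle <- oracle_cart(d, features = fit$feature_names)
    expect_same_tree(fit, oracle)
    expect_equal(predict(fit, d), oracle_cart_predict(oracle, d))
  }
})

test_that("hyperparameter constraints carry through to the oracle", {
  for (i in 1:15) {
    msl <- sample(1:3, 1)
    mss <- sample(2:5, 1)
    mid <- sample(c(0, 5, 50), 1)
    d <- random_table(n = sample(6:12, 1), p = 2, seed = 2000 + i)
    fit <- fit_tree(d, hyperparams(mid, msl, mss))
    oracle <- oracle_cart(d, features = fit$feature_names,
                          min_impurity_decrease = mid, min_samples_leaf = msl,
                          min_samples_split = mss)
    expect_same_tree(fit, oracle)
  }
})

test_that("structural invariants hold on random fits", {
  count_leaf_n <- function(node) {
    if (is.null(node$feature_index)) return(node$n)
    count_leaf_n(node$left) + count_leaf_n(node$right)
  }
  min_leaf_n <- function(node) {
    if (is.null(node$feature_index)) return(node$n)
    min(min_leaf_n(node$left), min_leaf_n(node$right))
  }
  depth_of <- function(node) {
    if (is.null(node$feature_index)) return(0L)
    1L + max(depth_of(node$left), depth_of(node$right))
  }
  train_mse <- function(fit, d) mean((d$barthel_index - predict(fit, d))^2)
  for (i in 1:10) {
    d <- random_table(n = 30, p = 3, seed = 3000 + i)
    fit <- fit_tree(d, hyperparams(min_samples_leaf = 3))
    expect_identical(count_leaf_n(fit$root), nrow(d))
    expect_gte(min_leaf_n(fit$root), 3L)
    # training loss is non-increasing in allowed depth
    losses <- vapply(1:4, function(dep) {
      train_mse(fit_tree(d, hyperparams(max_depth = dep)), d)
    }, numeric(1))
    expect_true(all(diff(losses) <= 1e-9))
    # an impurity-decrease floor above the root variance forces a stump
    stump <- fit_tree(d, hyperparams(min_impurity_decrease =
                                       stats::var(d$barthel_index) + 1))
    expect_null(stump$root$feature_index)
  }
})

test_that("predictions stay within the training target range", {
  d <- random_table(n = 40, p = 3, seed = 77)
  fit <- fit_tree(d)
  newdata <- random_table(n = 1000, p = 3, seed = 78)
  p <- predict(fit, newdata)
  expect_gte(min(p), min(d$barthel_index))
  expect_lte(max(p), max(d$barthel_index))
  expect_error(predict(fit, newdata[, 1:2]), "lacks feature column")
})

test_that("test-tagged rows are refused at fit time", {
  d <- random_table(n = 10, p = 2, seed = 9)
  d$role <- c(rep("modeling", 9), "test")
  expect_error(fit_tree(d), "test")
  expect_error(fit_tree(d[0, ]), "empty")
})

test_that("model JSON round-trips structure and predictions", {
  d <- random_table(n = 25, p = 3, seed = 55)
  fit <- fit_tree(d, hyperparams(min_samples_leaf = 2))
  path <- withr::local_tempfile(fileext = ".json")
  write_model_json(fit, path)
  back <- read_model_json(path)
  expect_equal(predict(back, d), predict(fit, d))
  expect_identical(back$feature_names, fit$feature_names)
})

test_that("the stratified split reproduces the study's 70/30 arithmetic", {
  d <- tibble::tibble(
    aid_group = rep(c("none", "cane_or_walker", "wheelchair"), c(52, 23, 15)),
    barthel_index = stats::runif(90, 0, 100))
  sp <- stratified_split(d, train_fraction = 0.7, seed = 4)
  expect_identical(nrow(sp$train), 63L)
  expect_identical(nrow(sp$validation), 27L)
  train_by_group <- table(sp$train$aid_group)
  expect_identical(as.integer(train_by_group[c("none", "cane_or_walker", "wheelchair")]),
                   c(36L, 16L, 11L))
  # union is the input, intersection is empty
  combined <- dplyr::bind_rows(sp$train, sp$validation)
  expect_equal(dplyr::arrange(combined, barthel_index),
               dplyr::arrange(d, barthel_index))
  # determinism and seed sensitivity
  sp2 <- stratified_split(d, train_fraction = 0.7, seed = 4)
  expect_identical(sp, sp2)
})

test_that("undersized strata go to training with a warning", {
  d <- tibble::tibble(aid_group = c(rep("none", 8), "wheelchair"),
                      barthel_index = 1:9)
  expect_warning(sp <- stratified_split(d, seed = 1), "wheelchair")
  expect_true(all(d$barthel_index[d$aid_group == "wheelchair"] %in%
                    sp$train$barthel_index))
})

test_that("cross-validation selects from the grid deterministically", {
  d <- random_table(n = 28, p = 3, seed = 111)
  one_point <- data.frame(min_impurity_decrease = 0.5, min_samples_leaf = 3,
                          min_samples_split = 4)
  cv <- cross_validate(d, grid = one_point, k = 4, seed = 2)
  expect_equal(cv$best$min_impurity_decrease, 0.5)
  expect_identical(cv$best$min_samples_leaf, 3L)
  expect_identical(cv$best$min_samples_split, 4L)
  expect_error(cross_validate(d, k = 29), "29 folds|only")

  small_grid <- expand.grid(min_impurity_decrease = c(0, 0.2, 1),
                            min_samples_leaf = c(1, 4),
                            min_samples_split = c(2, 6))
  cv1 <- cross_validate(d, grid = small_grid, k = 4, seed = 5)
  cv2 <- cross_validate(d, grid = small_grid, k = 4, seed = 5)
  expect_identical(cv1$scores, cv2$scores)
  expect_identical(unclass(cv1$best), unclass(cv2$best))
})

test_that("the pruning sweep equals refitting at each impurity threshold", {
  # dual route: cross_validate scores every min_impurity_decrease by pruning
  # a single fit; verify against a direct fit at that threshold
  d <- random_table(n = 21, p = 3, seed = 121)
  grid <- expand.grid(min_impurity_decrease = c(0, 1, 3, 10, 40),
                      min_samples_leaf = c(1, 2),
                      min_samples_split = c(2, 5))
  k <- 3
  cv <- cross_validate(d, grid = grid, k = k, seed = 8)
  fold_of <- withr::with_seed(8, {
    idx <- sample.int(nrow(d)); f <- integer(nrow(d))
    f[idx] <- rep_len(seq_len(k), nrow(d)); f
  })
  for (g in seq_len(nrow(grid))) {
    scores <- vapply(seq_len(k), function(f) {
      hp <- hyperparams(grid$min_impurity_decrease[g],
                        grid$min_samples_leaf[g], grid$min_samples_split[g])
      fit <- fit_tree(d[fold_of != f, ], hp)
      held <- d[fold_of == f, ]
      -mean((held$barthel_index - predict(fit, held))^2)
    }, numeric(1))
    expect_equal(cv$scores$mean_score[g], mean(scores), info = paste("grid row", g))
  }
})

test_that("cross-validation recovers a noiseless step function", {
  n <- 60
  d <- withr::with_seed(14, tibble::tibble(
    x = stats::runif(n, 0, 10),
    noise = stats::runif(n, 0, 10)))
  d$barthel_index <- ifelse(d$x < 4, 10, ifelse(d$x < 7, 50, 90))
  grid <- expand.grid(min_impurity_decrease = c(0, 0.5),
                      min_samples_leaf = 1:3,
                      min_samples_split = c(2, 5))
  cv <- cross_validate(d, grid = grid, k = 5, seed = 3)
  fit <- fit_tree(d, cv$best)
  expect_equal(predict(fit, d), d$barthel_index)
  expect_identical(fit$feature_names[fit$root$feature_index], "x")
})

test_that("permutation importance isolates the informative feature", {
  n <- 80
  d <- withr::with_seed(17, tibble::tibble(
    signal = stats::runif(n, 0, 100),
    unused = stats::runif(n, 0, 100)))
  d$barthel_index <- ifelse(d$signal < 50, 20, 80)
  fit <- fit_tree(d, hyperparams(min_samples_leaf = 5))
  imp <- permutation_importance(fit, d, n_repeats = 50, seed = 6)
  expect_equal(imp$baseline_r2, 1)
  means <- setNames(imp$summary$mean_importance, imp$summary$feature)
  expect_lt(abs(means[["unused"]]), 0.01)
  expect_gt(means[["signal"]], 0.5)
  expect_identical(imp$summary$feature[1], "signal")
  # full distribution comes back, deterministically
  expect_identical(nrow(imp$samples), 100L)
  imp2 <- permutation_importance(fit, d, n_repeats = 50, seed = 6)
  expect_identical(imp$samples, imp2$samples)
})
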