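# Small Gaussian blob features keep the SVM tests fast; the texture end of
# the pipeline is exercised in the pipeline and acceptance tests.
make_blobs <- function(n_per_class, centers, sd = 0.15, seed = 1) {
  msiband:::with_seed(seed, {
    x <- do.call(rbind, lapply(seq_len(nrow(centers)), function(k)
      matrix(rnorm(n_per_class * ncol(centers), sd = sd), n_per_class) +
        matrix(centers[k, ], n_per_class, ncol(centers), byrow = TRUE)))
    list(x = x, y = rep(rownames(centers), each = n_per_class))
  })
}

test_that("grid search finds a perfect grid point on separable blobs", {
  blobs <- make_blobs(12, rbind(a = c(0, 0), b = c(3, 3)), seed = 501)
  cfg <- classifier_config(c_grid = 2^(-3:3), g_grid = 2^(-3:3))
  gs <- grid_search(blobs$x, blobs$y, cfg, seed = 1)
  expect_equal(max(gs$accuracy), 100)
  expect_equal(gs$accuracy[as.character(gs$cost), as.character(gs$gamma)], 100)
  expect_true(gs$cost %in% cfg$c_grid && gs$gamma %in% cfg$g_grid)
  expect_error(grid_search(blobs$x, rep("a", 24), cfg), "at least 2 classes")
})

test_that("grid of size 1 is returned without search; ties prefer small c, g", {
  blobs <- make_blobs(8, rbind(a = c(0, 0), b = c(4, 4)), seed = 502)
  one <- classifier_config(c_grid = 2, g_grid = 0.5)
  gs1 <- grid_search(blobs$x, blobs$y, one, seed = 1)
  expect_equal(gs1$cost, 2)
  expect_equal(gs1$gamma, 0.5)
  # fully separable data ties many grid points at 100%: smallest c then g wins
  cfg <- classifier_config(c_grid = c(1, 4), g_grid = c(0.25, 1))
  gs <- grid_search(blobs$x, blobs$y, cfg, seed = 1)
  ties <- which(gs$accuracy == max(gs$accuracy), arr.ind = TRUE)
  if (nrow(ties) > 1) {
    expect_equal(gs$cost, cfg$c_grid[min(ties[, 1])])
  }
})

test_that("holdout evaluation separates blobs and respects report contracts", {
  blobs <- make_blobs(10, rbind(a = c(0, 0), b = c(3, 3), c = c(0, 3),
                                d = c(3, 0)), seed = 503)
  cfg <- classifier_config(c_grid = 2^(-1:3), g_grid = 2^(-3:1),
                           n_shuffles = 5, seed = 7, group_aware = FALSE)
  rep <- holdout_evaluate(blobs$x, blobs$y, cfg)
  expect_gte(rep$mean_accuracy, 99)
  expect_length(rep$per_shuffle_accuracy, 5)
  expect_equal(rep$mean_accuracy, mean(rep$per_shuffle_accuracy))
  expect_true(all(rep$per_shuffle_accuracy >= 0 &
                  rep$per_shuffle_accuracy <= 100))
  expect_gte(rep$mean_accuracy, min(rep$per_shuffle_accuracy))
  expect_lte(rep$mean_accuracy, max(rep$per_shuffle_accuracy))
  expect_equal(rep$n_train + rep$n_test, 40)
  expect_equal(rep$n_train, 28)           # stratified 70% of 40
  expect_identical(rep$class_names, c("a", "b", "c", "d"))

  one <- holdout_evaluate(blobs$x, blobs$y,
    classifier_config(c_grid = 1, g_grid = 1, n_shuffles = 1,
                      group_aware = FALSE))
  expect_length(one$per_shuffle_accuracy, 1)
  expect_equal(one$mean_accuracy, one$per_shuffle_accuracy)
})

test_that("no information leaks from test folds into scaler or grid search", {
  blobs <- make_blobs(10, rbind(a = c(0, 0), b = c(2, 2)), seed = 504)
  cfg <- classifier_config(c_grid = c(1, 8), g_grid = c(0.25, 2),
                           n_shuffles = 3, seed = 21, group_aware = FALSE)
  rep <- holdout_evaluate(blobs$x, blobs$y, cfg)
  for (k in seq_along(rep$per_shuffle)) {
    sh <- rep$per_shuffle[[k]]
    # scaler parameters recompute exactly from the training rows alone
    expect_identical(sh$scaler, msiband:::fit_minmax(blobs$x[sh$train, ]))
    # hyperparameters recompute from the scaled training fold alone
    xs <- msiband:::apply_minmax(blobs$x, sh$scaler)
    gs <- grid_search(xs[sh$train, ], blobs$y[sh$train], cfg,
                      seed = cfg$seed + k)
    expect_identical(c(sh$cost, sh$gamma), c(gs$cost, gs$gamma))
  }
})

test_that("identical base seeds reproduce the report bit for bit", {
  # overlapping classes so per-shuffle accuracy actually varies with the split
  blobs <- make_blobs(8, rbind(a = c(0, 0), b = c(1, 1)), sd = 0.8, seed = 505)
  cfg <- classifier_config(c_grid = 2^(0:2), g_grid = 2^(-2:0),
                           n_shuffles = 4, seed = 33, group_aware = FALSE)
  r1 <- holdout_evaluate(blobs$x, blobs$y, cfg)
  r2 <- holdout_evaluate(blobs$x, blobs$y, cfg)
  expect_identical(r1$per_shuffle_accuracy, r2$per_shuffle_accuracy)
  expect_identical(r1$per_shuffle, r2$per_shuffle)
  r3 <- holdout_evaluate(blobs$x, blobs$y,
    classifier_config(c_grid = 2^(0:2), g_grid = 2^(-2:0), n_shuffles = 4,
                      seed = 34, group_aware = FALSE))
  expect_false(identical(r1$per_shuffle_accuracy, r3$per_shuffle_accuracy))
})

test_that("group-aware splitting keeps slide patches in one fold", {
  set.seed(506)
  n <- 40
  groups <- rep(paste0("slide", 1:10), each = 4)   # 4 patches per slide
  labels <- rep(rep(c("a", "b"), each = 4), 5)
  x <- matrix(rnorm(n * 3), n, 3) + 2 * (labels == "b")
  cfg <- classifier_config(c_grid = 1, g_grid = 1, n_shuffles = 4, seed = 3)
  rep <- holdout_evaluate(x, labels, cfg, groups = groups)
  for (sh in rep$per_shuffle) {
    tr_groups <- unique(groups[sh$train])
    te_groups <- unique(groups[-sh$train])
    expect_length(intersect(tr_groups, te_groups), 0)
  }
  # single-group class cannot be split group-aware
  expect_error(holdout_evaluate(x[1:8, ], labels[1:8], cfg,
                                groups = groups[1:8]),
               "fewer than 2 groups")
  expect_error(holdout_evaluate(x[1:5, ], c("a", "a", "a", "a", "b"), cfg),
               "at least 2 samples")
})

test_that("global-search mode reuses one (c, g) pair across shuffles", {
  blobs <- make_blobs(10, rbind(a = c(0, 0), b = c(2.5, 2.5)), seed = 507)
  cfg <- classifier_config(c_grid = 2^(0:3), g_grid = 2^(-3:0),
                           n_shuffles = 3, seed = 11, group_aware = FALSE,
                           search = "global")
  rep <- holdout_evaluate(blobs$x, blobs$y, cfg)
  cs <- vapply(rep$per_shuffle, `[[`, numeric(1), "cost")
  gs <- vapply(rep$per_shuffle, `[[`, numeric(1), "gamma")
  expect_length(unique(cs), 1)
  expect_length(unique(gs), 1)
})
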