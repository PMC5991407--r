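test_that("the RBF kernel matches its closed form", {
  x <- runif(16); y <- x
  expect_equal(rbf_kernel(x, y, 3), 1.0)
  expect_equal(rbf_kernel(runif(16), runif(16), 0), 1.0)
  u <- rep(0, 16); v <- c(1, rep(0, 15))
  expect_equal(rbf_kernel(u, v, 1), exp(-1), tolerance = 1e-12)
  expect_equal(rbf_kernel(c(1, 2), c(4, 6), 0.5), exp(-0.5 * 25),
               tolerance = 1e-12)
  expect_error(rbf_kernel(c(1, NA), c(1, 2), 1), "finite")
})

test_that("RBF kernel is symmetric, bounded, and Gram matrices are PSD", {
  set.seed(77)
  for (rep in 1:5) {
    pts <- matrix(rnorm(20 * 16), 20, 16)
    g <- runif(1, 0.05, 5)
    K <- matrix(0, 20, 20)
    for (i in 1:20) for (j in 1:20)
      K[i, j] <- rbf_kernel(pts[i, ], pts[j, ], g)
    expect_equal(K, t(K), tolerance = 1e-14)
    expect_true(all(K > 0 & K <= 1))
    expect_gt(min(eigen(K, symmetric = TRUE, only.values = TRUE)$values), -1e-9)
  }
})

test_that("the former cohort splits into 2006-2009 training and 2010 testing", {
  co <- generate_cohort(n_former = 4442, n_later = 0, seed = 10, series = "none")
  parts <- split_cohorts(co$projects)
  expect_equal(nrow(parts$train), 2982)
  expect_equal(nrow(parts$test), 1460)
  expect_equal(nrow(parts$train) + nrow(parts$test), 4442)
  expect_length(intersect(parts$train$project_id, parts$test$project_id), 0)
  only2010 <- data.frame(project_id = "X", completion_year = 2010)
  expect_error(split_cohorts(only2010), "training")
})

test_that("feature scaling is learned on training data only", {
  set.seed(3)
  train <- matrix(runif(50 * 3, 0, 10), 50, 3,
                  dimnames = list(NULL, c("a", "b", "c")))
  test <- matrix(runif(20 * 3, -5, 20), 20, 3,
                 dimnames = list(NULL, c("a", "b", "c")))
  sc <- scale_fit(train)
  expect_equal(unname(sc$offset), unname(apply(train, 2, min)))
  expect_equal(unname(sc$scale), unname(apply(train, 2, max) - apply(train, 2, min)))
  tr_s <- scale_apply(sc, train)
  expect_equal(unname(apply(tr_s, 2, range)), matrix(c(0, 1), 2, 3))
  te_s <- scale_apply(sc, test)
  expect_equal(te_s, sweep(sweep(test, 2, sc$offset), 2, sc$scale, "/"))
  expect_true(any(te_s < 0) || any(te_s > 1))  # test range not used
})

test_that("zero-variance features are dropped with a warning", {
  x <- cbind(a = rep(2, 30), b = runif(30))
  expect_warning(sc <- scale_fit(x), "zero-variance")
  expect_equal(colnames(scale_apply(sc, x)), "b")
})

test_that("grid search separates a separable cohort almost perfectly", {
  d <- separable_clusters(400, gap = 10, seed = 5)
  gs <- grid_search(d$x, d$y, folds = 5, seed = 2, cv_subsample = 400)
  expect_gte(gs$cv_accuracy, 0.99)
})

test_that("grid search on permuted labels stays near the majority rate", {
  set.seed(9)
  n <- 120
  x <- matrix(rnorm(n * 16), n, 16)
  y <- rep(c(1L, -1L), c(70, 50))[sample(n)]
  gs <- grid_search(x, y, folds = 5, seed = 4, cv_subsample = n,
                    coarse_exp = c(-6, 6), max_fine_rounds = 1)
  maj <- 70 / 120
  # binomial 3-sigma band around chance performance, plus selection bias of
  # the best cell over the grid
  expect_lt(gs$cv_accuracy, maj + 4 * sqrt(maj * (1 - maj) / n))
})

test_that("grid search ties break toward the smallest C then g", {
  d <- separable_clusters(120, gap = 20, seed = 11)
  gs <- grid_search(d$x, d$y, folds = 4, seed = 3, cv_subsample = 120,
                    max_fine_rounds = 1)
  top <- gs$grid[gs$grid$cv_accuracy >= gs$cv_accuracy - 1e-12, ]
  expect_equal(gs$chosen_c, min(top$C))
  expect_equal(gs$chosen_g, min(top$g[top$C == gs$chosen_c]))
})

test_that("grid search is deterministic under a fixed seed", {
  d <- separable_clusters(150, gap = 4, seed = 21)
  g1 <- grid_search(d$x, d$y, folds = 5, seed = 7, cv_subsample = 100,
                    max_fine_rounds = 1)
  g2 <- grid_search(d$x, d$y, folds = 5, seed = 7, cv_subsample = 100,
                    max_fine_rounds = 1)
  expect_identical(g1$chosen_c, g2$chosen_c)
  expect_identical(g1$chosen_g, g2$chosen_g)
  expect_identical(g1$grid, g2$grid)
})

test_that("training memorizes separable data and evaluates honestly", {
  d <- separable_clusters(200, gap = 10, seed = 13)
  clf <- train_and_evaluate(d$x, d$y, d$x, d$y, C = 1, g = 0.1)
  expect_equal(clf$test_accuracy, 1.0)
  expect_error(train_and_evaluate(d$x, rep(1, 200), d$x, d$y, 1, 0.1),
               "single class")
})

test_that("prediction on later projects returns labels and a rate", {
  d <- separable_clusters(200, gap = 10, seed = 17)
  colnames(d$x) <- paste0("f", 1:16)
  clf <- train_and_evaluate(d$x, d$y, d$x, d$y, C = 1, g = 0.1)
  later <- as.data.frame(d$x)
  later$project_id <- sprintf("L%03d", 1:200)
  pr <- predict_later(clf, later, feature_cols = paste0("f", 1:16))
  expect_equal(nrow(pr$predictions), 200)
  expect_true(all(pr$predictions$label %in% c(-1L, 1L)))
  expect_equal(pr$rate, mean(pr$predictions$label == 1))
  expect_gt(pr$rate, 0.45); expect_lt(pr$rate, 0.55)

  empty <- predict_later(clf, later[0, ], feature_cols = paste0("f", 1:16))
  expect_equal(nrow(empty$predictions), 0)
  expect_true(is.na(empty$rate))

  later$f3[5] <- NA
  expect_message(pr2 <- predict_later(clf, later, paste0("f", 1:16)),
                 "skipped")
  expect_equal(nrow(pr2$predictions), 199)
})

test_that("published parameter presets cover the four indicators", {
  ps <- svm_parameter_presets()
  expect_equal(ps$indicator, c("pl", "pv", "pp", "mi"))
  expect_true(all(ps$C > 0) && all(ps$g > 0))
})
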