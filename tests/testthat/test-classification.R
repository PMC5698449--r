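blobs <- function(n = 30, gap = 6, seed = 51) {
  withr::with_seed(seed, {
    X <- rbind(
      matrix(rnorm(n * 2), n, 2),
      matrix(rnorm(n * 2, mean = gap), n, 2)
    )
    list(X = X, y = rep(c(1L, 2L), each = n))
  })
}

test_that("well-separated blobs are classified perfectly by the SVM", {
  b <- blobs()
  m <- train_svm(b$X, b$y, c_grid = small_c_grid, g_grid = small_g_grid,
                 seed = 1)
  ev <- evaluate(m, b$X, b$y, b$X, b$y)
  expect_equal(ev$accuracy_cal, 100)
  expect_equal(sum(ev$confusion_cal), 60)
})

test_that("shuffled labels give chance-level prediction accuracy", {
  withr::with_seed(52, {
    X <- matrix(rnorm(200 * 4), 200, 4)
    y <- rep(c(1L, 2L), 100)
    tr <- 1:120
    te <- 121:200
    m <- train_svm(X[tr, ], sample(y[tr]), c_grid = small_c_grid,
                   g_grid = small_g_grid, seed = 2)
    acc <- evaluate(m, X[tr, ], y[tr], X[te, ], sample(y[te]))$accuracy_pred
    expect_gt(acc, 40)
    expect_lt(acc, 60)
  })
})

test_that("the RBF kernel solves XOR where a linear rule cannot", {
  withr::with_seed(53, {
    n <- 50
    centres <- rbind(c(1, 1), c(-1, -1), c(1, -1), c(-1, 1))
    X <- centres[rep(1:4, each = n), ] + matrix(rnorm(4 * n * 2, 0, 0.25),
                                                4 * n, 2)
    y <- rep(c(1L, 1L, 2L, 2L), each = n)
    rbf <- train_svm(X, y, c_grid = small_c_grid, g_grid = small_g_grid,
                     seed = 3)
    expect_gt(evaluate(rbf, X, y, X, y)$accuracy_cal, 90)

    lin <- e1071::svm(X, factor(y), type = "C-classification",
                      kernel = "linear", cost = 1, scale = FALSE)
    lin_acc <- 100 * mean(predict(lin, X) == factor(y))
    expect_lte(lin_acc, 60)
  })
})

test_that("SVM tie-breaking prefers the smaller c then smaller g", {
  # a degenerate grid where every pair scores identically
  b <- blobs(n = 15)
  m <- train_svm(b$X, b$y, c_grid = c(4, 1), g_grid = c(2, 0.5), seed = 4)
  expect_equal(m$params$c, 1)
  expect_equal(m$params$g, 0.5)
})

test_that("an over-provisioned ELM interpolates its calibration set", {
  withr::with_seed(54, {
    for (seed in 1:3) {
      X <- matrix(rnorm(20 * 3), 20, 3)
      y <- rep(c(1L, 2L), 10)
      m <- train_elm(X, y, n_hidden_range = 25, seed = seed)
      expect_equal(evaluate(m, X, y, X, y)$accuracy_cal, 100)
    }
  })
})

test_that("a single hidden node separates ordered 1-D classes", {
  X <- matrix(c(1, 2, 3, 4), 4, 1)
  y <- c(1L, 1L, 2L, 2L)
  m <- train_elm(X, y, n_hidden_range = 1, seed = 7)
  expect_equal(predict(m, X), y)
})

test_that("ELM training is deterministic in its seed", {
  ds <- small_dataset(30, seed = 10)
  m1 <- train_elm(ds, n_hidden_range = 1:20, seed = 5)
  m2 <- train_elm(ds, n_hidden_range = 1:20, seed = 5)
  expect_identical(m1$fit$W, m2$fit$W)
  expect_identical(m1$fit$B, m2$fit$B)
  expect_identical(predict(m1, ds), predict(m2, ds))
  m3 <- train_elm(ds, n_hidden_range = 1:20, seed = 6)
  expect_false(identical(m1$fit$W, m3$fit$W))
})

test_that("accuracy bookkeeping is exact arithmetic", {
  # an over-provisioned ELM memorises its 10 training points; flipping one
  # truth label then yields exactly 9/10 correct
  b <- blobs(n = 5, seed = 55)
  m <- train_elm(b$X, b$y, n_hidden_range = 15, seed = 1)
  ev <- evaluate(m, b$X, b$y, b$X, c(b$y[-10], 3L - b$y[10]))
  expect_equal(ev$accuracy_pred, 90)
  expect_equal(tidy(ev)$accuracy, c(ev$accuracy_cal, 90))
  expect_equal(glance(ev)$n_pred, 10)
  expect_equal(sum(diag(ev$confusion_pred)), 9)
})

test_that("band-restricted models equal models on pre-restricted data", {
  ds <- crop_spectral_range(small_dataset(40, seed = 12), 975, 1646)
  split <- ks_split(ds)
  cal <- calibration_set(split)
  sel <- select_bands(cal, "spa", max_vars = 4)

  m_bands <- train_svm(cal, bands = sel, c_grid = small_c_grid,
                       g_grid = small_g_grid, seed = 9)
  pre <- split
  pre$spectra <- pre$spectra[, sel$band_index, drop = FALSE]
  m_pre <- train_svm(calibration_set(pre), c_grid = small_c_grid,
                     g_grid = small_g_grid, seed = 9)
  ev1 <- evaluate_split(m_bands, split)
  ev2 <- evaluate_split(m_pre, pre)
  expect_equal(ev1$accuracy_cal, ev2$accuracy_cal)
  expect_equal(ev1$accuracy_pred, ev2$accuracy_pred)
})

test_that("raising the class offset never hurts median accuracy", {
  med_acc <- vapply(c(1.005, 1.02, 1.05), function(off) {
    accs <- vapply(1:3, function(s) {
      ds <- generate_spectral_dataset(
        scene_spec(n_seeds_per_class = c(60, 60), class_offset = off,
                   rng_seed = 100 + s),
        60
      )
      ds <- crop_spectral_range(ds, 975, 1646)
      split <- ks_split(ds)
      m <- train_svm(calibration_set(split), c_grid = small_c_grid,
                     g_grid = small_g_grid, seed = s)
      evaluate_split(m, split)$accuracy_pred
    }, numeric(1))
    median(accs)
  }, numeric(1))
  expect_true(all(diff(med_acc) >= -1e-9))
})

test_that("single-class training data are rejected", {
  X <- matrix(rnorm(20), 10, 2)
  expect_error(train_svm(X, rep(1L, 10)), "both classes")
  expect_error(train_elm(X, rep(2L, 10)), "both classes")
})
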