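test_that("Kennard-Stone seeds with the most distant pair and runs max-min", {
  set.seed(51)
  X <- matrix(rnorm(8 * 3), 8, 3)
  sp <- kennard_stone_split(X, 4)
  D <- as.matrix(dist(X))
  far <- which(D == max(D), arr.ind = TRUE)[1, ]
  expect_setequal(sp$calibration_idx[1:2], as.integer(far))

  # 5-point planar toy vs independent loop oracle
  P <- matrix(c(0, 0, 10, 0, 5, 8, 1, 1, 9, 1), ncol = 2, byrow = TRUE)
  sp5 <- kennard_stone_split(P, 3)
  expect_equal(sp5$calibration_idx, ks_oracle(P, 3))

  # larger random instances vs the oracle
  for (seed in 1:4) {
    set.seed(seed)
    Xr <- matrix(rnorm(10 * 4), 10, 4)
    spr <- kennard_stone_split(Xr, 6)
    expect_equal(spr$calibration_idx, ks_oracle(Xr, 6))
  }

  # n_cal = n: validation empty
  all_in <- kennard_stone_split(X, 8)
  expect_equal(length(all_in$validation_idx), 0L)
  expect_setequal(all_in$calibration_idx, 1:8)
  expect_error(kennard_stone_split(X, 1), "at least 2")
})

test_that("Kennard-Stone selection is permutation-equivariant on tie-free data", {
  set.seed(52)
  X <- matrix(rnorm(12 * 3), 12, 3)
  rownames(X) <- sprintf("id%02d", 1:12)
  sp <- kennard_stone_split(X, 7)
  perm <- sample(12)
  sp_p <- kennard_stone_split(X[perm, ], 7)
  expect_setequal(sp_p$calibration_ids, sp$calibration_ids)
})

test_that("evaluation metrics reproduce their defining identities", {
  obs <- c(18, 22, 27, 33, 39, 45)
  perfect <- evaluate_predictions(obs, obs)
  expect_equal(perfect$r2_val, 1)
  expect_equal(perfect$rmse_val, 0)
  expect_equal(perfect$lccc, 1)
  expect_identical(perfect$rpd_class, "high")
  expect_true(is.infinite(perfect$rpd))

  mean_pred <- evaluate_predictions(obs, rep(mean(obs), 6))
  expect_equal(mean_pred$r2_val, 0)
  expect_equal(mean_pred$lccc, 0)
  # RPD identity for the mean predictor: sqrt(n / (n - 1))
  expect_equal(mean_pred$rpd, sqrt(6 / 5))

  # 5-point worked example, frozen from a step-by-step scalar computation
  ev <- evaluate_predictions(c(20, 25, 30, 35, 40), c(22, 24, 31, 33, 41))
  expect_equal(ev$r2_val, 0.956, tolerance = 1e-12)
  expect_equal(ev$rmse_val, sqrt(11 / 5), tolerance = 1e-12)
  expect_equal(ev$rpd, 5.3300179, tolerance = 1e-6)
  expect_equal(ev$lccc, 0.9772122, tolerance = 1e-6)

  expect_error(evaluate_predictions(rep(5, 4), 1:4), "zero variance")
})

test_that("LCCC never exceeds |r|", {
  set.seed(53)
  for (i in 1:200) {
    n <- sample(5:40, 1)
    obs <- rnorm(n, 30, 8)
    pred <- rnorm(n, 30, 8)
    ev <- evaluate_predictions(obs, pred)
    expect_lte(ev$lccc, abs(cor(obs, pred)) + 1e-12)
  }
})

test_that("RPD classes follow the Chang thresholds", {
  expect_identical(rpd_class(1.3), "poor")
  expect_identical(rpd_class(1.7), "moderate")
  expect_identical(rpd_class(2.5), "high")
  expect_identical(rpd_class(1.4), "moderate")
  expect_identical(rpd_class(2.0), "moderate")
  expect_identical(rpd_class(Inf), "high")
  expect_error(rpd_class(-1), "positive")
})

test_that("linear targets are recovered near-perfectly by SVR and PLSR", {
  set.seed(54)
  X <- matrix(rnorm(150 * 5), 150, 5)
  colnames(X) <- paste0("f", 1:5)
  y <- as.vector(X %*% c(3, -1, 2, 0.5, -2)) + 30
  cal <- 1:100; val <- 101:150
  for (method in c("SVR", "PLSR")) {
    mf <- fit_predict_model(model_spec(method, seed = 5),
                            X[cal, ], y[cal], X[val, ])
    ev <- evaluate_predictions(y[val], mf$pred_val)
    expect_gte(ev$r2_val, 0.99)
  }
})

test_that("no method finds signal in pure noise", {
  small_dnn <- list(hidden = c(8L, 8L), dropout = c(0.2, 0.2),
                    epochs = 100L, l1 = 0)
  specs <- list(
    RF = model_spec("RF", grid = list(mtry = 2L, ntree = 200L)),
    SVR = model_spec("SVR", grid = list(cost = 1)),
    DNN = model_spec("DNN", grid = small_dnn),
    PLSR = model_spec("PLSR", grid = list(ncomp_max = 5L)))
  r2 <- sapply(names(specs), function(m) {
    vapply(1:20, function(seed) {
      set.seed(seed)
      X <- matrix(rnorm(70 * 6), 70, 6)
      colnames(X) <- paste0("f", 1:6)
      y <- rnorm(70, 30, 8)                   # independent of X
      spec <- specs[[m]]; spec$seed <- seed
      mf <- fit_predict_model(spec, X[1:50, ], y[1:50], X[51:70, ])
      evaluate_predictions(y[51:70], mf$pred_val)$r2_val
    }, numeric(1))
  })
  for (m in colnames(r2)) expect_lte(median(r2[, m]), 0.2)
})

test_that("model fitting is deterministic given the seed", {
  set.seed(55)
  X <- matrix(rnorm(60 * 8), 60, 8)
  colnames(X) <- paste0("f", 1:8)
  y <- as.vector(X %*% rnorm(8)) + rnorm(60, 0, 0.5) + 30
  for (method in c("RF", "SVR", "DNN", "PLSR")) {
    grid <- if (method == "DNN")
      list(hidden = c(6L, 6L), dropout = c(0.3, 0.3), epochs = 60L,
           l1 = c(0, 1e-4)) else NULL
    spec <- model_spec(method, grid = grid, seed = 99)
    m1 <- fit_predict_model(spec, X[1:45, ], y[1:45], X[46:60, ])
    m2 <- fit_predict_model(spec, X[1:45, ], y[1:45], X[46:60, ])
    expect_identical(m1$pred_val, m2$pred_val)
    expect_identical(m1$best_params, m2$best_params)
  }
})

test_that("PLSR validation accuracy tracks the theoretical noise ceiling", {
  r2 <- vapply(1:10, function(seed) {
    set.seed(seed)
    n <- 300
    X <- matrix(rnorm(n * 10), n, 10)
    colnames(X) <- paste0("f", 1:10)
    signal <- as.vector(X %*% rep(1, 10)) / sqrt(10)   # unit variance
    sigma <- 0.5
    y <- 30 + 5 * signal + rnorm(n, 0, 5 * sigma)
    spec <- model_spec("PLSR", seed = seed)
    mf <- fit_predict_model(spec, X[1:200, ], y[1:200], X[201:300, ])
    evaluate_predictions(y[201:300], mf$pred_val)$r2_val
  }, numeric(1))
  theory <- 1 / (1 + 0.5^2)                  # 1 - sigma^2 / var(y) = 0.8
  expect_lt(abs(median(r2) - theory), 0.1)
})
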