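test_that("parameter accounting matches the layer plan", {
  # dense 2 -> 16 with bias
  expect_equal(2 * 16 + 16, 48)
  # conv 16 -> 32, kernel 3, with bias
  expect_equal(32 * (16 * 3 + 1), 1568)
  # batch normalization over 48 channels: scale + shift only
  m <- build_model("mcsf", 19)
  expect_equal(length(m$net$w$gamma) + length(m$net$w$beta), 96)
  expect_false(any(c("running_mean", "running_var") %in% names(m$net$w)))
  expect_error(build_model("spectral", 3), "n_bands")
  expect_error(build_model("unknown_tag", 19))
})

test_that("spectral encoder parameter count is independent of band count", {
  for (tag in c("spectral", "mcsf")) {
    expect_equal(count_parameters(build_model(tag, 5)),
                 count_parameters(build_model(tag, 19)))
  }
})

test_that("analytic gradients match finite differences for every tag", {
  set.seed(7)
  X <- matrix(runif(6 * 8), 6, 8)
  C <- matrix(runif(12), 6, 2)
  y <- rnorm(6)
  for (tag in c("spectral", "mcsf", "chemical")) {
    net <- zeaxspec:::nn_init(tag, seed = 3)
    Xu <- if (tag == "chemical") NULL else X
    Cu <- if (tag == "spectral") NULL else C
    fw <- zeaxspec:::nn_forward(net, Xu, Cu, training = TRUE)
    net$buffers <- fw$buffers
    g <- zeaxspec:::nn_backward(net, fw$cache, 2 * (fw$yhat - y) / 6)
    for (nm in names(net$w)) {
      idx <- sample(length(net$w[[nm]]), min(3, length(net$w[[nm]])))
      for (i in idx) {
        e <- 1e-5
        lf <- function(delta) {
          n2 <- net
          n2$w[[nm]][i] <- n2$w[[nm]][i] + delta
          f <- zeaxspec:::nn_forward(n2, Xu, Cu, training = TRUE)
          mean((f$yhat - y)^2)
        }
        expect_equal(g[[nm]][i], (lf(e) - lf(-e)) / (2 * e),
                     tolerance = 1e-5)
      }
    }
  }
})

test_that("training is deterministic and flags divergence", {
  d <- default_dataset(seed = 4, n_samples = 60)
  y <- d$chemistry$zeaxanthin_g_per_kg
  cfg <- train_config(epochs = 60, min_epochs = 10, patience = 20, seed = 2)
  f1 <- train_model(build_model("spectral", 19), d$spectra, y, config = cfg)
  f2 <- train_model(build_model("spectral", 19), d$spectra, y, config = cfg)
  expect_identical(f1$net$w, f2$net$w)
  expect_identical(predict(f1, d$spectra), predict(f2, d$spectra))
  cfg_bad <- train_config(epochs = 400, learning_rate = 1e150, seed = 2)
  expect_error(train_model(build_model("spectral", 19), d$spectra, y,
                           config = cfg_bad), "diverged")
})

test_that("the spectral CNN recovers a planted band-linear response", {
  cfg <- synthetic_config(n_samples = 500, noise_sd = 0)
  d <- simulate_peppers(cfg, seed = 5)
  m <- zeaxspec:::spectra_matrix(d$spectra)
  y <- as.numeric(2 * m[, "470"] + m[, "540"] - 1.5 * m[, "645"])
  tr <- 1:400
  te <- 401:500
  fit <- train_model(build_model("spectral", 19), d$spectra[tr, ], y[tr],
                     config = train_config(epochs = 1500, patience = 200,
                                           weight_decay = 0, seed = 1))
  pr <- predict(fit, d$spectra[te, ])
  expect_gt(regression_metrics(y[te], pr)$r2, 0.95)
})

test_that("shuffled responses yield no out-of-sample skill", {
  d <- default_dataset(seed = 6)
  set.seed(1)
  y <- sample(d$chemistry$zeaxanthin_g_per_kg)
  tr <- 1:120
  te <- 121:159
  fit <- train_model(build_model("spectral", 19), d$spectra[tr, ], y[tr],
                     config = train_config(epochs = 500, patience = 100,
                                           seed = 1))
  pr <- predict(fit, d$spectra[te, ])
  expect_lt(regression_metrics(y[te], pr)$r2, 0.1)
})

test_that("LOOCV pools n out-of-fold predictions", {
  # trivial mean predictor: each prediction is the mean of the other two
  mean_learner <- function(x, y, chem) function(xn, cn) mean(y)
  res <- loocv(mean_learner, x = NULL, y = c(1, 2, 6))
  expect_equal(nrow(res), 3)
  expect_equal(res$predicted, c(4, 3.5, 1.5))
  # a memorising learner scores well on duplicated data, poorly on noise
  knn1 <- function(x, y, chem) {
    function(xn, cn) y[which.min(rowSums(sweep(x, 2, as.numeric(xn))^2))]
  }
  set.seed(1)
  X <- matrix(rnorm(40), 10)
  Xdup <- rbind(X, X)
  ydup <- rep(rnorm(10), 2) + rnorm(20, sd = 1e-3)
  good <- loocv(knn1, Xdup, ydup)
  expect_gt(regression_metrics(good$observed, good$predicted)$r2, 0.9)
  set.seed(2)
  bad <- loocv(knn1, matrix(rnorm(200), 20), rnorm(20))
  expect_lt(regression_metrics(bad$observed, bad$predicted)$r2, 0.5)
  expect_error(loocv(mean_learner, NULL, c(1, 2)), "n >= 3")
})

test_that("baseline learners fit, predict and validate", {
  set.seed(10)
  n <- 80
  X <- matrix(rnorm(n * 5), n)
  y <- drop(X %*% c(1, -2, 0.5, 0, 0))
  # pls with full components on noiseless linear data is exact
  pf <- fit_baseline("pls", X, y, ncomp = 5)
  expect_equal(regression_metrics(y, predict(pf, X))$r2, 1,
               tolerance = 1e-8)
  expect_error(fit_baseline("pls", X, y, ncomp = 6), "rank")
  # rf deterministic under a fixed seed
  r1 <- predict(fit_baseline("rf", X, y, seed = 3), X)
  r2 <- predict(fit_baseline("rf", X, y, seed = 3), X)
  expect_identical(r1, r2)
  # bp fits a nonlinear target better than pls (majority over seeds)
  yn <- sin(2 * X[, 1]) + X[, 2]^2
  tr <- 1:60
  te <- 61:80
  wins <- sum(vapply(1:5, function(s) {
    bp <- fit_baseline("bp", X[tr, ], yn[tr], seed = s)
    pl <- fit_baseline("pls", X[tr, ], yn[tr], ncomp = 3)
    r2b <- regression_metrics(yn[te], predict(bp, X[te, ]))$r2
    r2p <- regression_metrics(yn[te], predict(pl, X[te, ]))$r2
    r2b > r2p
  }, logical(1)))
  expect_gte(wins, 3)
})

test_that("fused models consume chemistry and expose pre-head features", {
  d <- default_dataset(seed = 8, n_samples = 80)
  y <- d$chemistry$zeaxanthin_g_per_kg
  chem <- d$chemistry[c("capsanthin_g_per_kg", "total_carotenoids_g_per_kg")]
  cfg <- train_config(epochs = 120, min_epochs = 20, patience = 50, seed = 1)
  fit <- train_model(build_model("mcsf", 19), d$spectra, y, chemistry = chem,
                     config = cfg)
  expect_length(predict(fit, d$spectra, chem), 80)
  feats <- model_features(fit, d$spectra, chem)
  expect_equal(dim(feats), c(80, 40))
  fits <- train_model(build_model("spectral", 19), d$spectra, y,
                      config = cfg)
  expect_equal(dim(model_features(fits, d$spectra)), c(80, 32))
  expect_error(predict(build_model("mcsf", 19), d$spectra, chem),
               "not trained")
  expect_error(train_model(build_model("mcsf", 19), d$spectra, y,
                           chemistry = chem[, 1, drop = FALSE],
                           config = cfg), "exactly 2")
})

test_that("mini-batch training runs and stays deterministic", {
  d <- default_dataset(seed = 9, n_samples = 60)
  y <- d$chemistry$zeaxanthin_g_per_kg
  cfg <- train_config(epochs = 40, min_epochs = 10, patience = 20,
                      batch_size = 16, seed = 5)
  f1 <- train_model(build_model("spectral", 19), d$spectra, y, config = cfg)
  f2 <- train_model(build_model("spectral", 19), d$spectra, y, config = cfg)
  expect_identical(f1$net$w, f2$net$w)
})
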