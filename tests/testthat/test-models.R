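# Detector construction, training contracts, scoring orientation.

test_that("autoencoder architecture: shapes, bottleneck, parameter count", {
  det <- build_autoencoder()
  expect_equal(det$net$layers[[3]]$units, 20)     # bottleneck
  expect_equal(det$net$output_shape$dim, 192)
  # closed-form parameter count over the dense chain 192-80-40-20-40-80-192
  dims <- c(192, 80, 40, 20, 40, 80, 192)
  want <- sum((dims[-length(dims)] + 1) * dims[-1])
  net <- fogkit:::nn_init(det$net, 1)
  expect_equal(fogkit:::nn_count_params(net), want)
  # untrained net still maps 192 -> 192 (shape contract)
  out <- fogkit:::nn_predict(det$net, matrix(runif(5 * 192), 5))
  expect_equal(dim(out), c(5, 192))
  expect_error(build_autoencoder(input_dim = 100), "192")
})

test_that("CNN and CNN-LSTM architectures match their layer plans", {
  cnn <- build_cnn()
  expect_equal(cnn$net$layers[[1]]$dim, 320)      # flatten after two conv/pool
  expect_equal(cnn$net$layers[[1]]$F1, 32)
  expect_equal(cnn$net$layers[[1]]$K1, 8)
  cl <- build_cnn_lstm(3)
  expect_equal(cl$net$layers[[2]]$dim, 832)       # per-step flatten
  expect_equal(cl$net$layers[[4]]$units, 64)      # LSTM cells
  expect_equal(cl$net$layers[[2]]$F1, 128)
  expect_equal(cl$net$layers[[2]]$K2, 4)
  expect_error(build_cnn_lstm(-1), ">= 0")

  # k = 0 degenerate sequence still yields a probability
  fm <- margin_features(10, seed = 3)
  d0 <- train_supervised(build_cnn_lstm(0), fm,
                         train_config(epochs = 2, batch_size = 16, seed = 1))
  p <- fog_score(d0, fm)
  expect_true(all(p >= 0 & p <= 1))
})

test_that("time-distributed conv weights are shared across steps", {
  det <- build_cnn_lstm(2)
  net <- fogkit:::nn_init(det$net, 4)
  X <- matrix(rnorm(3 * 576), 3)
  fw1 <- fogkit:::nn_forward(net, X, FALSE)
  X2 <- X
  X2[, 193:384] <- X2[, 193:384] + rnorm(3 * 192)  # perturb middle step only
  fw2 <- fogkit:::nn_forward(net, X2, FALSE)
  lstm_i <- 4  # unfolded per-step inputs cached by the LSTM layer
  for (s in c(1, 3)) {
    expect_equal(fw1$caches[[lstm_i]]$steps[[s]]$x,
                 fw2$caches[[lstm_i]]$steps[[s]]$x, tolerance = 1e-6)
  }
  expect_gt(max(abs(fw1$caches[[lstm_i]]$steps[[2]]$x -
                      fw2$caches[[lstm_i]]$steps[[2]]$x)), 0.01)
})

test_that("novelty training refuses FOG rows and scores by reconstruction RMSE", {
  fm <- margin_features(20, seed = 5)
  expect_error(train_novelty(build_autoencoder(), fm), "leakage")
  expect_error(fit_shallow("ocsvm", fm), "leakage")

  gait <- fogkit:::features_subset(fm, fm$labels == 0)
  det <- train_novelty(build_autoencoder(), gait,
                       train_config(epochs = 10, batch_size = 16, seed = 2))
  s <- novelty_score(det, fm)
  expect_true(all(is.finite(s)))
  expect_true(all(s >= 0))
  # the score is exactly the per-row RMSE of the normalized reconstruction
  Xn <- fm$values / det$norm_max
  R <- fogkit:::nn_predict(det$net, Xn)
  expect_equal(s, sqrt(rowMeans((Xn - R)^2)), tolerance = 1e-12)
  # scoring does not mutate the detector
  before <- det$norm_max
  invisible(novelty_score(det, gait))
  expect_identical(det$norm_max, before)
})

test_that("denoising autoencoder fits a constant dataset to low error", {
  X <- matrix(rep(runif(192, 0.2, 0.8), each = 40), 40)
  fm <- structure(list(values = X, labels = integer(40),
                       subject_id = rep("A", 40), recording_id = rep("A", 40),
                       start_index = 1:40, representation = "fft",
                       context = 0L), class = "fog_features")
  det <- train_novelty(build_autoencoder(), fm,
                       train_config(epochs = 150, batch_size = 40,
                                    noise_factor = 0, lr = 3e-3, seed = 1,
                                    early_stop_patience = 0))
  expect_lt(mean(novelty_score(det, fm)), 0.05)
})

test_that("supervised deep models separate a wide-margin spectral dataset", {
  fm <- margin_features(60, seed = 7)
  det <- train_supervised(build_cnn(), fm,
                          train_config(epochs = 40, batch_size = 64, seed = 1))
  m <- roc_metrics(fog_score(det, fm), fm$labels)
  expect_gt(m$auc, 0.95)
  expect_true(all(fog_score(det, fm) >= 0 & fog_score(det, fm) <= 1))
  expect_error(train_supervised(build_cnn(),
                                fogkit:::features_subset(fm, fm$labels == 0),
                                train_config(epochs = 1)), "both classes")
})

test_that("shallow baselines fit, score with FOG-positive orientation", {
  fm <- margin_features(40, seed = 11)
  expect_error(fit_shallow("mystery", fm), "unknown")
  expect_error(fit_shallow("random_forest",
                           fogkit:::features_subset(fm, fm$labels == 1)),
               "both classes")

  rf <- fit_shallow("random_forest", fm, seed = 3)
  expect_equal(rf$fit$ntree, 100)
  expect_gt(roc_metrics(fog_score(rf, fm), fm$labels)$auc, 0.95)

  for (kind in c("svm", "adaboost")) {
    det <- fit_shallow(kind, fm, seed = 3)
    m <- roc_metrics(fog_score(det, fm), fm$labels)
    expect_gt(m$auc, 0.9)  # higher = more FOG-like for every detector
  }

  oc <- fit_shallow("ocsvm", fogkit:::features_subset(fm, fm$labels == 0),
                    seed = 3)
  s <- fog_score(oc, fm)
  expect_gt(mean(s[fm$labels == 1]), mean(s[fm$labels == 0]))
})

test_that("default training regimes resolve per model kind", {
  ae <- fogkit:::resolve_cfg(train_config(), "mlp_autoencoder")
  expect_equal(ae$epochs, 250)
  expect_equal(ae$batch_size, 512)
  expect_equal(fogkit:::resolve_cfg(train_config(), "cnn")$batch_size, 512)
  expect_equal(fogkit:::resolve_cfg(train_config(), "cnn_lstm")$batch_size, 1024)
  expect_equal(fogkit:::resolve_cfg(train_config(), "cnn")$epochs, 150)
  cfg <- train_config()
  expect_equal(cfg$lr, 1e-4)
  expect_equal(cfg$clip_value, 1)
  expect_equal(cfg$early_stop_patience, 20L)
  expect_equal(cfg$noise_factor, 0.2)
  # explicit overrides win over the per-kind defaults
  expect_equal(fogkit:::resolve_cfg(train_config(epochs = 7, batch_size = 64),
                                    "cnn")$epochs, 7)
})

test_that("checkpoints round-trip through manifest plus weights", {
  fm <- margin_features(15, seed = 17)
  det <- fit_shallow("random_forest", fm, n_estimators = 20, seed = 1)
  d <- file.path(tempdir(), "ckpt1")
  save_detector(det, d)
  expect_true(file.exists(file.path(d, "manifest.json")))
  back <- load_detector(d)
  expect_equal(fog_score(back, fm), fog_score(det, fm), tolerance = 1e-12)
  expect_error(save_detector(build_cnn(), d), "untrained")
  expect_error(load_detector(tempdir()), "checkpoint")
})

test_that("normalization comes from the training fold only", {
  fm <- margin_features(30, seed = 13)
  tr <- fogkit:::features_subset(fm, 1:40)
  det <- train_supervised(build_cnn(), tr,
                          train_config(epochs = 2, batch_size = 32, seed = 1))
  expect_equal(det$norm_max, max(tr$values))
  # applying to wilder data does not change the stored normalization
  te <- fogkit:::features_subset(fm, 41:60)
  te$values <- te$values * 10
  invisible(fog_score(det, te))
  expect_equal(det$norm_max, max(tr$values))
})
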