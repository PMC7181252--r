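# FOG detectors: novelty detectors (one-class SVM, denoising autoencoder) and
# supervised classifiers (SVM, AdaBoost on stumps, random forest, 1-D CNN,
# time-distributed CNN-LSTM).  Every detector follows the same contract:
#   * normalization state (the training-set maximum used for 0-1 scaling) is
#     computed from training data only and stored in the detector;
#   * fog_score() returns one finite scalar per row, oriented so that higher
#     means more FOG-like, whatever the underlying model.

#' Training configuration for the deep detectors
#'
#' Defaults follow the tuned training regime: Adam (RMSprop for the
#' autoencoder), learning rate 1e-4, element-wise gradient clipping at 1,
#' early stopping after 20 epochs without a training-loss decrease, and a 0.2
#' noise factor for the denoising objective.
#'
#' @param epochs maximum training epochs.
#' @param batch_size mini-batch size.
#' @param lr learning rate.
#' @param clip_value element-wise gradient clip.
#' @param early_stop_patience epochs without improvement before stopping.
#' @param noise_factor sd of the Gaussian corruption used by the denoising
#'   autoencoder (inputs are re-clipped to the unit interval).
#' @param seed integer seed controlling initialization, shuffling, dropout
#'   and denoising noise; recorded in the fitted detector.
#' @return a `fog_train_config` list.
#' @export
train_config <- function(epochs = NULL, batch_size = NULL, lr = 1e-4,
                         clip_value = 1, early_stop_patience = 20L,
                         noise_factor = 0.2, seed = 1L) {
  stopifnot(lr > 0, clip_value >= 0, early_stop_patience >= 0, noise_factor >= 0)
  structure(list(epochs = epochs, batch_size = batch_size, lr = lr,
                 clip_value = clip_value,
                 early_stop_patience = as.integer(early_stop_patience),
                 noise_factor = noise_factor, seed = as.integer(seed)),
            class = "fog_train_config")
}

default_epochs <- c(mlp_autoencoder = 250L, cnn = 150L, cnn_lstm = 150L)
default_batch  <- c(mlp_autoencoder = 512L, cnn = 512L, cnn_lstm = 1024L)

new_detector <- function(kind, ...) {
  structure(c(list(kind = kind, trained = FALSE, norm_max = NA_real_),
              list(...)), class = "fog_detector")
}

#' @export
print.fog_detector <- function(x, ...) {
  cat(sprintf("<fog_detector> %s (%s)%s\n", x$kind,
              if (x$trained) "trained" else "untrained",
              if (!is.null(x$context)) sprintf(", context %d", x$context) else ""))
  invisible(x)
}

## ---- deep architectures -----------------------------------------------------

#' Build the denoising autoencoder (untrained)
#'
#' Seven fully connected layers over the 192-dimensional spectral input:
#' encoder 192-80-40 (tanh), bottleneck 20 (ReLU), decoder 40-80 (tanh) and a
#' 192-unit output.  Binary cross-entropy on 0-1 max-normalized inputs calls
#' for a sigmoid output, which is the default; the tanh variant is available
#' via `output_activation`.
#'
#' @param input_dim input width; must be 192 (64-bin spectrum x 3 axes).
#' @param output_activation `"sigmoid"` (default) or `"tanh"`.
#' @return an untrained `fog_detector` of kind `mlp_autoencoder`.
#' @export
build_autoencoder <- function(input_dim = 192L, output_activation = "sigmoid") {
  if (input_dim != 192L)
    stop("the autoencoder is defined for 192-dimensional spectral input")
  net <- nn_sequential(list(
    layer_dense(80, "tanh"),
    layer_dense(40, "tanh"),
    layer_dense(20, "relu"),
    layer_dense(40, "tanh"),
    layer_dense(80, "tanh"),
    layer_dense(192, output_activation)
  ), input_shape = list(dim = 192L))
  stopifnot(net$output_shape$dim == 192L,
            net$layers[[3]]$units == 20L)  # bottleneck width
  new_detector("mlp_autoencoder", net = net)
}

#' Build the 1-D CNN classifier (untrained)
#'
#' Two valid-padded 1-D convolutions (32 filters, kernel 8, ReLU), each
#' followed by max-pooling of size 2, then dense 128 (dropout 0.5), dense 32
#' (dropout 0.3) and a sigmoid output unit.  Input is one 64-bin spectrum
#' with the three axes as channels.
#'
#' @return an untrained `fog_detector` of kind `cnn`.
#' @export
build_cnn <- function() {
  net <- nn_sequential(list(
    layer_convstack(32, 8, 32, 8),
    layer_dense(128, "relu"),
    layer_dropout(0.5),
    layer_dense(32, "relu"),
    layer_dropout(0.3),
    layer_dense(1, "sigmoid")
  ), input_shape = list(len = 64L, ch = 3L))
  # 64 -> conv 57 -> pool 28 -> conv 21 -> pool 10 -> flatten 320
  stopifnot(net$layers[[1]]$dim == 320L, net$output_shape$dim == 1L)
  new_detector("cnn", net = net, context = 0L)
}

#' Build the time-distributed CNN-LSTM classifier (untrained)
#'
#' The same convolutional stack (128 then 64 filters, kernel 4, ReLU,
#' max-pool 2 each) is applied with shared weights to each of the k+1 stacked
#' spectral windows; the per-step flattened activations feed an LSTM with 64
#' cells, then dense 80 (ReLU), dense 40 (ReLU) and a sigmoid output.
#'
#' @param k context depth: number of previous windows in the input stack.
#' @return an untrained `fog_detector` of kind `cnn_lstm`.
#' @export
build_cnn_lstm <- function(k = 3L) {
  k <- as.integer(k)
  if (k < 0L) stop("context depth k must be >= 0")
  net <- nn_sequential(list(
    layer_fold_steps(),
    layer_convstack(128, 4, 64, 4),
    layer_unfold_steps(),
    layer_lstm(64),
    layer_dense(80, "relu"),
    layer_dense(40, "relu"),
    layer_dense(1, "sigmoid")
  ), input_shape = list(steps = k + 1L, len = 64L, ch = 3L))
  # per step: 64 -> conv 61 -> pool 30 -> conv 27 -> pool 13 -> flatten 832
  stopifnot(net$layers[[2]]$dim == 832L, net$layers[[4]]$units == 64L)
  new_detector("cnn_lstm", net = net, context = k)
}

check_input_dim <- function(det, X) {
  want <- switch(det$kind,
    mlp_autoencoder = 192L,
    cnn = 192L,
    cnn_lstm = (det$context + 1L) * 192L,
    NA_integer_)
  if (!is.na(want) && ncol(X) != want)
    stop(det$kind, " expects ", want, " input columns, got ", ncol(X))
}

## ---- training ---------------------------------------------------------------

resolve_cfg <- function(cfg, kind) {
  if (is.null(cfg$epochs)) cfg$epochs <- unname(default_epochs[kind])
  if (is.null(cfg$batch_size)) cfg$batch_size <- unname(default_batch[kind])
  cfg
}

#' Train a novelty detector on non-FOG windows only
#'
#' The training set must contain no FOG-labeled rows (novelty detection
#' learns normal movement only); passing any is treated as label leakage and
#' refused.  Features are scaled to the unit interval by the training-set maximum; the
#' autoencoder is then fitted with the denoising objective (reconstruct the
#' clean input from input + Gaussian noise of sd `cfg$noise_factor`) under
#' RMSprop with early stopping.
#'
#' @param det an untrained detector from [build_autoencoder()] (or kind
#'   `ocsvm` from [fit_shallow()]'s builder path).
#' @param feats a `fog_features` object whose rows are all non-FOG.
#' @param cfg a [train_config()].
#' @return the trained `fog_detector`.
#' @export
train_novelty <- function(det, feats, cfg = train_config()) {
  if (any(feats$labels != 0))
    stop("leakage: novelty training data contains FOG-labeled rows")
  X <- feats$values
  check_input_dim(det, X)
  cfg <- resolve_cfg(cfg, det$kind)
  det$norm_max <- max(X)
  Xn <- X / det$norm_max
  net <- nn_init(det$net, seed = cfg$seed)
  net <- with_seed(cfg$seed + 1L,
    nn_fit(net, Xn, Xn, epochs = cfg$epochs, batch_size = cfg$batch_size,
           lr = cfg$lr, clip = cfg$clip_value, optimizer = "rmsprop",
           patience = cfg$early_stop_patience, noise_sd = cfg$noise_factor))
  det$net <- net
  det$cfg <- cfg
  det$trained <- TRUE
  det
}

#' Train a supervised deep classifier (CNN or CNN-LSTM)
#'
#' Features are scaled by the training-set maximum; binary cross-entropy is
#' minimized with Adam, element-wise gradient clipping and early stopping.
#' Dropout is active during training only; inference is deterministic.
#'
#' @param det an untrained detector from [build_cnn()] or [build_cnn_lstm()].
#' @param feats a `fog_features` object with both classes present.
#' @param cfg a [train_config()].
#' @return the trained `fog_detector`.
#' @export
train_supervised <- function(det, feats, cfg = train_config()) {
  y <- feats$labels
  if (length(unique(y)) < 2)
    stop("supervised training requires both classes in the training set")
  X <- feats$values
  check_input_dim(det, X)
  cfg <- resolve_cfg(cfg, det$kind)
  det$norm_max <- max(X)
  Xn <- X / det$norm_max
  net <- nn_init(det$net, seed = cfg$seed)
  net <- with_seed(cfg$seed + 1L,
    nn_fit(net, Xn, as.numeric(y), epochs = cfg$epochs,
           batch_size = cfg$batch_size, lr = cfg$lr, clip = cfg$clip_value,
           optimizer = "adam", patience = cfg$early_stop_patience))
  det$net <- net
  det$cfg <- cfg
  det$trained <- TRUE
  det
}

#' Fit a shallow baseline detector
#'
#' Defaults follow the evaluated baselines: SVM with an RBF kernel (gamma
#' 0.3, cost 1), AdaBoost with 100 stump estimators, random forest with 100
#' trees, and a linear-kernel one-class SVM trained on non-FOG rows only.
#' All operate on max-normalized features and return decision-value or
#' probability scores oriented so higher = more FOG-like.
#'
#' @param kind `"svm"`, `"adaboost"`, `"random_forest"` or `"ocsvm"`.
#' @param feats a `fog_features` object (for `"ocsvm"`, all rows non-FOG).
#' @param n_estimators trees/stumps for the ensemble kinds.
#' @param seed integer seed.
#' @return a trained `fog_detector`.
#' @export
fit_shallow <- function(kind, feats, n_estimators = 100L, seed = 1L) {
  if (!kind %in% c("svm", "adaboost", "random_forest", "ocsvm"))
    stop("unknown shallow detector kind: ", kind)
  X <- feats$values
  y <- feats$labels
  det <- new_detector(kind)
  det$norm_max <- max(X)
  Xn <- X / det$norm_max
  if (kind == "ocsvm") {
    if (any(y != 0))
      stop("leakage: novelty training data contains FOG-labeled rows")
    det$fit <- with_seed(seed,
      e1071::svm(Xn, y = NULL, type = "one-classification", kernel = "linear",
                 scale = FALSE))
    det$trained <- TRUE
    return(det)
  }
  if (length(unique(y)) < 2)
    stop("supervised training requires both classes in the training set")
  if (kind == "svm") {
    fit <- with_seed(seed,
      e1071::svm(Xn, factor(y, levels = c(0, 1)), kernel = "radial",
                 gamma = 0.3, cost = 1, scale = FALSE))
    dv <- attr(stats::predict(fit, Xn, decision.values = TRUE), "decision.values")
    det$flip <- mean(dv[y == 1]) < mean(dv[y == 0])
    det$fit <- fit
  } else if (kind == "random_forest") {
    det$fit <- with_seed(seed,
      randomForest::randomForest(Xn, factor(y, levels = c(0, 1)),
                                 ntree = n_estimators))
  } else {  # adaboost on decision stumps
    det$fit <- with_seed(seed, adaboost_fit(Xn, y, n_estimators))
  }
  det$trained <- TRUE
  det
}

#' Score rows of a feature matrix with a trained detector
#'
#' Applies the detector's stored training-set normalization, never mutating
#' the detector.  For the autoencoder the score is the per-row RMSE between
#' input and reconstruction; for the one-class SVM the negated decision
#' value; for supervised models the FOG probability or decision value.
#' Higher always means more FOG-like.
#'
#' @param det a trained `fog_detector`.
#' @param feats a `fog_features` object (or plain matrix).
#' @return numeric score vector, one value per row.
#' @export
fog_score <- function(det, feats) {
  if (!isTRUE(det$trained)) stop("detector is not trained")
  X <- if (inherits(feats, "fog_features")) feats$values else as.matrix(feats)
  check_input_dim(det, X)
  Xn <- X / det$norm_max
  switch(det$kind,
    mlp_autoencoder = {
      R <- nn_predict(det$net, Xn)
      sqrt(rowMeans((Xn - R)^2))
    },
    cnn = ,
    cnn_lstm = as.numeric(nn_predict(det$net, Xn)),
    ocsvm = {
      -as.numeric(attr(stats::predict(det$fit, Xn, decision.values = TRUE),
                       "decision.values"))
    },
    svm = {
      dv <- as.numeric(attr(stats::predict(det$fit, Xn, decision.values = TRUE),
                            "decision.values"))
      if (det$flip) -dv else dv
    },
    random_forest =
      as.numeric(stats::predict(det$fit, Xn, type = "prob")[, "1"]),
    adaboost = adaboost_score(det$fit, Xn),
    stop("unknown detector kind: ", det$kind)
  )
}

#' Reconstruction-error novelty score (autoencoder alias)
#' @inheritParams fog_score
#' @export
novelty_score <- function(det, feats) {
  if (!det$kind %in% c("mlp_autoencoder", "ocsvm"))
    stop("novelty_score is defined for novelty detectors")
  fog_score(det, feats)
}

#' Save / load a trained detector with a JSON manifest
#'
#' The checkpoint directory holds `manifest.json` (kind, context depth,
#' training configuration, seed, normalization constant) next to the fitted
#' parameters in `weights.rds`.
#'
#' @param det a trained `fog_detector`.
#' @param dir checkpoint directory (created if needed).
#' @return `dir` (saving) or the restored `fog_detector` (loading), invisibly
#'   for the former.
#' @export
save_detector <- function(det, dir) {
  if (!isTRUE(det$trained)) stop("refusing to checkpoint an untrained detector")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(kind = det$kind, context = det$context,
                   cfg = if (!is.null(det$cfg)) unclass(det$cfg),
                   norm_max = det$norm_max,
                   package_version = as.character(utils::packageVersion("fogkit")))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, null = "null", digits = NA)
  saveRDS(det, file.path(dir, "weights.rds"))
  invisible(dir)
}

#' @rdname save_detector
#' @export
load_detector <- function(dir) {
  mf <- file.path(dir, "manifest.json")
  wf <- file.path(dir, "weights.rds")
  if (!file.exists(mf) || !file.exists(wf))
    stop("not a detector checkpoint: ", dir)
  det <- readRDS(wf)
  manifest <- jsonlite::read_json(mf)
  if (!identical(manifest$kind, det$kind))
    stop("manifest/weights kind mismatch in ", dir)
  det
}

## ---- AdaBoost on decision stumps -------------------------------------------

# Discrete AdaBoost with depth-1 rpart trees; the score is the weighted vote
# margin, a monotone surrogate for P(FOG).
adaboost_fit <- function(X, y, n_estimators = 100L) {
  n <- nrow(X)
  df <- data.frame(y = factor(y, levels = c(0, 1)), X)
  w <- rep(1 / n, n)
  stumps <- list(); alphas <- numeric(0)
  yy <- ifelse(y == 1, 1, -1)
  for (m in seq_len(n_estimators)) {
    fit <- rpart::rpart(y ~ ., data = df, weights = w,
                        control = rpart::rpart.control(maxdepth = 1, cp = -1,
                                                       minsplit = 2, xval = 0))
    pred <- ifelse(stats::predict(fit, df, type = "class") == "1", 1, -1)
    err <- sum(w * (pred != yy))
    if (err >= 0.5 || length(unique(pred)) < 2) break
    err <- max(err, 1e-10)
    alpha <- 0.5 * log((1 - err) / err)
    w <- w * exp(-alpha * yy * pred)
    w <- w / sum(w)
    stumps[[length(stumps) + 1L]] <- fit
    alphas <- c(alphas, alpha)
    if (err < 1e-8) break
  }
  list(stumps = stumps, alphas = alphas, colnames = colnames(df)[-1])
}

adaboost_score <- function(fit, X) {
  df <- data.frame(X)
  colnames(df) <- fit$colnames
  s <- numeric(nrow(X))
  for (m in seq_along(fit$stumps)) {
    pred <- ifelse(stats::predict(fit$stumps[[m]], df, type = "class") == "1", 1, -1)
    s <- s + fit$alphas[m] * pred
  }
  s
}
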