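# Minimal sequential neural-network engine: dense / 1-D convolution / max-pool /
# LSTM layers with binary cross-entropy loss, Adam and RMSprop optimizers,
# element-wise gradient clipping and early stopping.  Written against base R
# matrix algebra so the deep FOG detectors are self-contained; convolutions are
# lowered to BLAS matrix products via im2col.
#
# Data layouts (all column-major, batch rows first):
#   dense domain   : N x D matrix
#   conv domain    : N x (L*C) matrix, column (c-1)*L + l  ("channel blocks")
#   sequence input : N x (S*L*C) matrix, step-major blocks, oldest step first

#' @keywords internal
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  set.seed(seed)
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  force(code)
}

glorot <- function(fan_in, fan_out, dims) {
  lim <- sqrt(6 / (fan_in + fan_out))
  array(runif(prod(dims), -lim, lim), dims)
}

act_fun <- function(z, act) {
  switch(act,
    linear  = z,
    relu    = pmax(z, 0),
    tanh    = tanh(z),
    sigmoid = 1 / (1 + exp(-z)),
    stop("unknown activation: ", act)
  )
}

# derivative expressed through the activation value a = act(z)
act_grad <- function(a, act) {
  switch(act,
    linear  = 1,
    relu    = (a > 0) * 1,
    tanh    = 1 - a^2,
    sigmoid = a * (1 - a)
  )
}

## ---- layer constructors (specs; parameters are created by nn_init) ----------

layer_dense   <- function(units, activation = "linear")
  list(type = "dense", units = units, activation = activation)
layer_conv1d  <- function(filters, kernel, activation = "relu")
  list(type = "conv1d", filters = filters, kernel = kernel, activation = activation)
layer_maxpool <- function(pool = 2L) list(type = "maxpool", pool = as.integer(pool))
layer_flatten <- function() list(type = "flatten")
layer_dropout <- function(rate) list(type = "dropout", rate = rate)
layer_lstm    <- function(units) list(type = "lstm", units = units)
layer_fold_steps   <- function() list(type = "fold_steps")
layer_unfold_steps <- function() list(type = "unfold_steps")
# fused conv(K1,F1,ReLU)-pool2-conv(K2,F2,ReLU)-pool2-flatten block (C++ path)
layer_convstack <- function(filters1, kernel1, filters2, kernel2)
  list(type = "convstack", F1 = filters1, K1 = kernel1,
       F2 = filters2, K2 = kernel2)

#' Assemble a sequential network and infer every layer's shape
#'
#' @param layers list of layer specs from the `layer_*` constructors.
#' @param input_shape either `list(dim = D)` for flat input,
#'   `list(len = L, ch = C)` for single-window convolutional input, or
#'   `list(steps = S, len = L, ch = C)` for stacked contextual input.
#' @param loss currently `"bce"` (binary cross-entropy; the final layer must
#'   use a sigmoid activation).
#' @return an object of class `fog_net` (uninitialized: no weights yet).
#' @keywords internal
nn_sequential <- function(layers, input_shape, loss = "bce") {
  shp <- input_shape
  steps <- if (!is.null(shp$steps)) as.integer(shp$steps) else NA_integer_
  built <- vector("list", length(layers))
  for (i in seq_along(layers)) {
    ly <- layers[[i]]
    ly <- switch(ly$type,
      fold_steps = {
        stopifnot(!is.na(steps))
        ly$steps <- steps; ly
      },
      conv1d = {
        stopifnot(!is.null(shp$len))
        ly$L <- shp$len; ly$C <- shp$ch
        ly$T <- shp$len - ly$kernel + 1L
        stopifnot(ly$T >= 1L)
        shp <- list(len = ly$T, ch = ly$filters)
        ly
      },
      maxpool = {
        ly$T <- shp$len; ly$F <- shp$ch
        ly$P <- shp$len %/% ly$pool
        shp <- list(len = ly$P, ch = shp$ch)
        ly
      },
      convstack = {
        stopifnot(!is.null(shp$len))
        ly$L <- shp$len; ly$C <- shp$ch
        ly$T1 <- ly$L - ly$K1 + 1L
        ly$L2 <- ly$T1 %/% 2L
        ly$T2 <- ly$L2 - ly$K2 + 1L
        ly$P2 <- ly$T2 %/% 2L
        stopifnot(ly$T1 >= 2L, ly$T2 >= 2L)
        ly$dim <- ly$P2 * ly$F2
        shp <- list(dim = ly$dim)
        ly
      },
      flatten = {
        ly$dim <- shp$len * shp$ch
        shp <- list(dim = ly$dim)
        ly
      },
      unfold_steps = {
        stopifnot(!is.na(steps), !is.null(shp$dim))
        ly$steps <- steps; ly$dim <- shp$dim
        ly
      },
      lstm = {
        ly$steps <- steps; ly$input_dim <- shp$dim
        shp <- list(dim = ly$units)
        ly
      },
      dense = {
        ly$input_dim <- shp$dim
        shp <- list(dim = ly$units)
        ly
      },
      dropout = ly,
      stop("unknown layer type: ", ly$type)
    )
    built[[i]] <- ly
  }
  structure(list(layers = built, input_shape = input_shape,
                 output_shape = shp, loss = loss, initialized = FALSE),
            class = "fog_net")
}

#' @keywords internal
nn_init <- function(net, seed = 0L) {
  with_seed(seed, {
    net$layers <- lapply(net$layers, function(ly) {
      if (ly$type == "dense") {
        ly$W <- glorot(ly$input_dim, ly$units, c(ly$input_dim, ly$units))
        ly$b <- numeric(ly$units)
      } else if (ly$type == "conv1d") {
        kc <- ly$kernel * ly$C
        ly$W <- glorot(kc, ly$filters, c(kc, ly$filters))
        ly$b <- numeric(ly$filters)
      } else if (ly$type == "convstack") {
        kc1 <- ly$K1 * ly$C
        ly$W1 <- glorot(kc1, ly$F1, c(kc1, ly$F1))
        ly$b1 <- numeric(ly$F1)
        kc2 <- ly$K2 * ly$F1
        ly$W2 <- glorot(kc2, ly$F2, c(kc2, ly$F2))
        ly$b2 <- numeric(ly$F2)
      } else if (ly$type == "lstm") {
        H <- ly$units; D <- ly$input_dim
        ly$Wx <- glorot(D, 4 * H, c(D, 4 * H))
        ly$Wh <- glorot(H, 4 * H, c(H, 4 * H))
        ly$b  <- numeric(4 * H)
        ly$b[(H + 1):(2 * H)] <- 1  # forget-gate bias
      }
      ly
    })
  })
  net$initialized <- TRUE
  net
}

## ---- conv helpers -----------------------------------------------------------
#
# The valid 1-D convolution is computed by shift-and-add over the K kernel
# taps:  Y[n, t, f] = sum_k sum_c X[n, t+k-1, c] * W[(c-1)K+k, f].
# Because the conv-domain matrix layout is channel-blocked with the batch
# index fastest, matrix(X, N*L, C) is a relayout-free reshape whose rows are
# (n, l) pairs, and the rows needed for tap k form one contiguous block, so
# each tap costs a single BLAS product and a block add; no im2col buffer.

conv_forward <- function(X, ly) {
  A <- cpp_conv_forward(X, ly$W, ly$b, ly$L, ly$C, ly$kernel,
                        ly$activation == "relu")
  if (ly$activation != "relu") A <- act_fun(A, ly$activation)
  list(out = A, cache = list(X = X, act = A))
}

conv_backward <- function(dout, ly, cache) {
  if (ly$activation != "relu")
    dout <- dout * act_grad(cache$act, ly$activation)
  bk <- cpp_conv_backward(cache$X, ly$W, cache$act, dout, ly$L, ly$C,
                          ly$kernel, ly$activation == "relu")
  list(dX = bk$dX, grads = list(W = bk$dW, b = bk$db))
}

## ---- forward / backward over the whole net ----------------------------------

nn_forward <- function(net, X, training = FALSE) {
  stopifnot(net$initialized)
  caches <- vector("list", length(net$layers))
  cur <- X
  N0 <- nrow(X)
  for (i in seq_along(net$layers)) {
    ly <- net$layers[[i]]
    if (ly$type == "dense") {
      Z <- sweep(cur %*% ly$W, 2, ly$b, "+")
      A <- act_fun(Z, ly$activation)
      caches[[i]] <- list(X = cur, act = A)
      cur <- A
    } else if (ly$type == "conv1d") {
      fw <- conv_forward(cur, ly)
      caches[[i]] <- fw$cache
      cur <- fw$out
    } else if (ly$type == "convstack") {
      fw <- cpp_convstack_forward(cur, ly$W1, ly$b1, ly$W2, ly$b2,
                                  ly$L, ly$C, ly$K1, ly$K2)
      caches[[i]] <- list(ptr = fw$cache)
      cur <- fw$out
    } else if (ly$type == "maxpool") {
      caches[[i]] <- list(X = cur)
      cur <- cpp_maxpool_forward(cur, ly$T, ly$F)
    } else if (ly$type == "flatten") {
      caches[i] <- list(NULL)
    } else if (ly$type == "dropout") {
      if (training && ly$rate > 0) {
        keep <- matrix(runif(length(cur)) >= ly$rate, nrow(cur)) / (1 - ly$rate)
        caches[[i]] <- list(keep = keep)
        cur <- cur * keep
      } else caches[[i]] <- list(keep = NULL)
    } else if (ly$type == "fold_steps") {
      S <- ly$steps; LC <- ncol(cur) %/% S
      n <- nrow(cur)
      cur <- matrix(aperm(array(cur, c(n, LC, S)), c(1, 3, 2)), n * S, LC)
      caches[[i]] <- list(n = n, S = S, LC = LC)
    } else if (ly$type == "unfold_steps") {
      S <- ly$steps; n <- nrow(cur) %/% S; D <- ncol(cur)
      arr <- array(cur, c(n, S, D))
      cur <- lapply(1:S, function(s) arr[, s, , drop = TRUE])
      cur <- lapply(cur, function(m) if (is.null(dim(m))) matrix(m, n) else m)
      caches[[i]] <- list(n = n, S = S, D = D)
    } else if (ly$type == "lstm") {
      S <- length(cur); n <- nrow(cur[[1]]); H <- ly$units
      h <- matrix(0, n, H); cc <- matrix(0, n, H)
      steps <- vector("list", S)
      for (s in 1:S) {
        z <- sweep(cur[[s]] %*% ly$Wx + h %*% ly$Wh, 2, ly$b, "+")
        ig <- 1 / (1 + exp(-z[, 1:H, drop = FALSE]))
        fg <- 1 / (1 + exp(-z[, (H + 1):(2 * H), drop = FALSE]))
        gg <- tanh(z[, (2 * H + 1):(3 * H), drop = FALSE])
        og <- 1 / (1 + exp(-z[, (3 * H + 1):(4 * H), drop = FALSE]))
        c_prev <- cc; h_prev <- h
        cc <- fg * cc + ig * gg
        tc <- tanh(cc)
        h <- og * tc
        steps[[s]] <- list(x = cur[[s]], i = ig, f = fg, g = gg, o = og,
                           c_prev = c_prev, h_prev = h_prev, tc = tc)
      }
      caches[[i]] <- list(steps = steps)
      cur <- h
    }
    net$layers[[i]] <- ly
  }
  list(out = cur, caches = caches, n = N0)
}

nn_backward <- function(net, fw, dout) {
  grads <- vector("list", length(net$layers))
  cur <- dout
  for (i in rev(seq_along(net$layers))) {
    ly <- net$layers[[i]]; ca <- fw$caches[[i]]
    if (ly$type == "dense") {
      dZ <- cur * act_grad(ca$act, ly$activation)
      grads[[i]] <- list(W = crossprod(ca$X, dZ), b = colSums(dZ))
      cur <- dZ %*% t(ly$W)
    } else if (ly$type == "conv1d") {
      bk <- conv_backward(cur, ly, ca)
      grads[[i]] <- bk$grads
      cur <- bk$dX
    } else if (ly$type == "convstack") {
      grads[[i]] <- cpp_convstack_backward(ca$ptr, ly$W1, ly$W2, cur)
      cur <- NULL  # stack sits at the input end; no input gradient needed
    } else if (ly$type == "maxpool") {
      cur <- cpp_maxpool_backward(ca$X, cur, ly$T, ly$F)
    } else if (ly$type == "dropout") {
      if (!is.null(ca$keep)) cur <- cur * ca$keep
    } else if (ly$type == "fold_steps") {
      if (!is.null(cur)) {
        n <- ca$n; S <- ca$S; LC <- ca$LC
        cur <- matrix(aperm(array(cur, c(n, S, LC)), c(1, 3, 2)), n, S * LC)
      }
    } else if (ly$type == "unfold_steps") {
      # cur is a list of S gradient matrices -> back to (n*S) x D
      arr <- array(0, c(ca$n, ca$S, ca$D))
      for (s in 1:ca$S) arr[, s, ] <- cur[[s]]
      cur <- matrix(arr, ca$n * ca$S, ca$D)
    } else if (ly$type == "lstm") {
      steps <- ca$steps; S <- length(steps); H <- ly$units
      n <- nrow(cur)
      dWx <- matrix(0, ly$input_dim, 4 * H); dWh <- matrix(0, H, 4 * H)
      db <- numeric(4 * H)
      dh <- cur; dc <- matrix(0, n, H)
      dxs <- vector("list", S)
      for (s in S:1) {
        st <- steps[[s]]
        do_ <- dh * st$tc
        dct <- dh * st$o * (1 - st$tc^2) + dc
        di <- dct * st$g; df <- dct * st$c_prev; dg <- dct * st$i
        dc <- dct * st$f
        dz <- cbind(di * st$i * (1 - st$i),
                    df * st$f * (1 - st$f),
                    dg * (1 - st$g^2),
                    do_ * st$o * (1 - st$o))
        dWx <- dWx + crossprod(st$x, dz)
        dWh <- dWh + crossprod(st$h_prev, dz)
        db <- db + colSums(dz)
        dxs[[s]] <- dz %*% t(ly$Wx)
        dh <- dz %*% t(ly$Wh)
      }
      grads[[i]] <- list(Wx = dWx, Wh = dWh, b = db)
      cur <- dxs
    }
    # flatten: identity
  }
  grads
}

## ---- loss -------------------------------------------------------------------

bce_loss <- function(p, y) {
  p <- pmin(pmax(p, 1e-7), 1 - 1e-7)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

# gradient w.r.t. the pre-sigmoid activation, folded with the sigmoid
# derivative: d loss / d z = (p - y) / n_elements.  Returned here w.r.t. the
# *output* p so backprop through the final sigmoid reproduces it exactly.
bce_grad_out <- function(p, y) {
  p <- pmin(pmax(p, 1e-7), 1 - 1e-7)
  (-(y / p) + (1 - y) / (1 - p)) / length(p)
}

## ---- optimizers -------------------------------------------------------------

opt_state_new <- function(net, optimizer) {
  lapply(net$layers, function(ly) {
    nm <- intersect(c("W", "b", "Wx", "Wh", "W1", "b1", "W2", "b2"), names(ly))
    st <- lapply(nm, function(p) {
      z <- ly[[p]] * 0
      if (optimizer == "adam") list(m = z, v = z) else list(v = z)
    })
    names(st) <- nm
    st
  })
}

opt_apply <- function(net, grads, state, optimizer, lr, clip, t) {
  for (i in seq_along(net$layers)) {
    g <- grads[[i]]
    if (is.null(g)) next
    for (p in names(g)) {
      gr <- g[[p]]
      if (clip > 0) gr <- pmin(pmax(gr, -clip), clip)
      st <- state[[i]][[p]]
      if (optimizer == "adam") {
        st$m <- 0.9 * st$m + 0.1 * gr
        st$v <- 0.999 * st$v + 0.001 * gr^2
        mhat <- st$m / (1 - 0.9^t)
        vhat <- st$v / (1 - 0.999^t)
        net$layers[[i]][[p]] <- net$layers[[i]][[p]] - lr * mhat / (sqrt(vhat) + 1e-8)
      } else {  # rmsprop
        st$v <- 0.9 * st$v + 0.1 * gr^2
        net$layers[[i]][[p]] <- net$layers[[i]][[p]] - lr * gr / (sqrt(st$v) + 1e-8)
      }
      state[[i]][[p]] <- st
    }
  }
  list(net = net, state = state)
}

## ---- training loop ----------------------------------------------------------

#' Train a sequential network by mini-batch backpropagation
#'
#' @param net an initialized `fog_net`.
#' @param X input matrix (rows = samples, layout per the net's input shape).
#' @param Y target: a vector of 0/1 labels (classifier) or a matrix of the same
#'   shape as the output (autoencoder reconstruction targets).
#' @param epochs,batch_size,lr,clip training hyper-parameters.
#' @param optimizer `"adam"` or `"rmsprop"`.
#' @param patience early-stopping patience: training stops when the epoch loss
#'   has not decreased for this many consecutive epochs (0 disables).
#' @param noise_sd if > 0, i.i.d. Gaussian noise of this sd is added to each
#'   input batch (denoising objective); the noisy input is clipped back to the unit interval
#'   while targets stay clean.
#' @return net with fitted weights and a `history` attribute (per-epoch loss).
#' @keywords internal
nn_fit <- function(net, X, Y, epochs, batch_size, lr = 1e-4, clip = 1,
                   optimizer = "adam", patience = 20L, noise_sd = 0) {
  stopifnot(net$initialized)
  N <- nrow(X)
  y_is_mat <- is.matrix(Y)
  state <- opt_state_new(net, optimizer)
  history <- numeric(0)
  best <- Inf; stale <- 0L; t <- 0L
  for (ep in seq_len(epochs)) {
    ord <- sample.int(N)
    ep_loss <- 0; ep_n <- 0L
    for (b0 in seq(1L, N, by = batch_size)) {
      b1 <- min(N, b0 + batch_size - 1L)
      rows <- ord[b0:b1]
      Xb <- X[rows, , drop = FALSE]
      Yb <- if (y_is_mat) Y[rows, , drop = FALSE] else Y[rows]
      if (noise_sd > 0) {
        Xb <- Xb + matrix(rnorm(length(Xb), 0, noise_sd), nrow(Xb))
        Xb <- pmin(pmax(Xb, 0), 1)
      }
      fw <- nn_forward(net, Xb, training = TRUE)
      p <- fw$out
      loss <- bce_loss(p, if (y_is_mat) Yb else matrix(Yb))
      dout <- bce_grad_out(p, if (y_is_mat) Yb else matrix(Yb))
      grads <- nn_backward(net, fw, dout)
      t <- t + 1L
      up <- opt_apply(net, grads, state, optimizer, lr, clip, t)
      net <- up$net; state <- up$state
      ep_loss <- ep_loss + loss * length(rows); ep_n <- ep_n + length(rows)
    }
    ep_loss <- ep_loss / ep_n
    history <- c(history, ep_loss)
    if (ep_loss < best - 1e-9) { best <- ep_loss; stale <- 0L } else stale <- stale + 1L
    if (patience > 0 && stale >= patience) break
  }
  attr(net, "history") <- history
  net
}

#' @keywords internal
nn_predict <- function(net, X, batch = 4096L) {
  if (!net$initialized) net <- nn_init(net, seed = 0L)
  N <- nrow(X)
  out <- NULL
  for (b0 in seq(1L, N, by = batch)) {
    b1 <- min(N, b0 + batch - 1L)
    o <- nn_forward(net, X[b0:b1, , drop = FALSE], training = FALSE)$out
    out <- if (is.null(out)) o else rbind(out, o)
  }
  out
}

#' @keywords internal
nn_count_params <- function(net) {
  sum(vapply(net$layers, function(ly) {
    nm <- intersect(c("W", "b", "Wx", "Wh", "W1", "b1", "W2", "b2"), names(ly))
    if (!length(nm)) return(0)
    sum(vapply(nm, function(p) length(ly[[p]]), numeric(1)))
  }, numeric(1)))
}
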