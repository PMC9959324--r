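# CNN engine: parameter containers, forward/backward passes, Adam training.
# Convolution and pooling run in C++ (src/convnet.cpp); batch normalization,
# global average pooling, and the dense head are vectorized R. All tensors
# use the (H, W, D, C, N) layout.

BN_EPS <- 1e-5

#' Training configuration
#'
#' Optimizer and schedule settings. The reference profile
#' (`profile = "paper"`) uses Adam with `beta1 = 0.9`, `beta2 = 0.999`,
#' learning rate 0.001, batch size 128 and 100 epochs; the `"desk"` profile
#' keeps the optimizer but scales the schedule down to 15 epochs and batch
#' 32 for CPU-sized experiments.
#'
#' @param epochs Training epochs.
#' @param batch_size Mini-batch size.
#' @param lr Adam learning rate.
#' @param beta1,beta2 Adam moment decay rates.
#' @param seed RNG seed (weight init, shuffling, dropout).
#' @param profile `"desk"` or `"paper"`: fills `epochs`/`batch_size` when
#'   they are not given explicitly.
#' @param verbose Print per-epoch progress.
#' @return A `train_config` list.
#' @export
train_config <- function(epochs = NULL, batch_size = NULL, lr = 0.001,
                         beta1 = 0.9, beta2 = 0.999,
                         seed = 1L, profile = c("desk", "paper"),
                         verbose = FALSE) {
  profile <- match.arg(profile)
  defaults <- if (profile == "paper") c(100L, 128L) else c(15L, 32L)
  epochs <- as.integer(epochs %||% defaults[1])
  batch_size <- as.integer(batch_size %||% defaults[2])
  if (epochs <= 0 || batch_size <= 0 || lr <= 0)
    hsi_abort("epochs, batch size, and learning rate must be positive",
              "parameter_error")
  structure(list(epochs = epochs, batch_size = batch_size, lr = lr,
                 beta1 = beta1, beta2 = beta2,
                 seed = as.integer(seed), profile = profile,
                 verbose = isTRUE(verbose)),
            class = "train_config")
}

#' Build a trainable classifier
#'
#' Instantiates the four-block topology for a given input size in the 3D
#' variant (cube as a single-channel volume; spectral kernel depth capped
#' and spectral pooling stride 1 for 3-band RGB-style inputs) or the 2D
#' variant (bands folded into input channels, convolution and pooling over
#' space only). Convolution and dense weights use He initialization; batch
#' normalization starts at identity.
#'
#' @param input_dims `c(H, W, B)` patch extents.
#' @param variant `"3d"` or `"2d"`.
#' @param spec A [topology_spec()].
#' @param seed Seed for weight initialization.
#' @return An object of class `hsicnn_model`.
#' @export
build_classifier <- function(input_dims, variant = c("3d", "2d"),
                             spec = topology_spec(), seed = 1L) {
  variant <- match.arg(variant)
  geom <- net_geometry(spec, input_dims, variant)
  propagate_shapes(spec, input_dims, variant) # validates extents
  set.seed(seed)
  params <- list(); running <- list()
  for (i in 1:4) {
    blk <- geom$blocks[[i]]
    fan_in <- prod(blk$kernel) * blk$in_ch
    params[[paste0("conv_w", i)]] <-
      array(rnorm(prod(blk$kernel) * blk$in_ch * blk$out_ch,
                  sd = sqrt(2 / fan_in)),
            c(blk$kernel, blk$in_ch, blk$out_ch))
    params[[paste0("conv_b", i)]] <- numeric(blk$out_ch)
    params[[paste0("bn_g", i)]] <- rep(1, blk$out_ch)
    params[[paste0("bn_b", i)]] <- numeric(blk$out_ch)
    running[[paste0("mean", i)]] <- numeric(blk$out_ch)
    running[[paste0("var", i)]] <- rep(1, blk$out_ch)
  }
  nf <- geom$blocks[[4]]$out_ch
  params$W1 <- matrix(rnorm(spec$dense_units * nf, sd = sqrt(2 / nf)),
                      spec$dense_units, nf)
  params$b1 <- numeric(spec$dense_units)
  # zero output layer: the initial logit is exactly the bias, so training
  # starts from a symmetric, noise-free decision surface
  params$W2 <- matrix(0, 1, spec$dense_units)
  params$b2 <- 0
  structure(list(spec = spec, variant = variant,
                 input_dims = as.integer(input_dims), geom = geom,
                 params = params, running = running, trained = FALSE,
                 history = NULL, init_seed = as.integer(seed)),
            class = "hsicnn_model")
}

#' @export
print.hsicnn_model <- function(x, ...) {
  cat(sprintf("<hsicnn_model> %s CNN for %s input, %s\n",
              toupper(x$variant),
              paste(x$input_dims, collapse = "x"),
              if (x$trained) "trained" else "untrained"))
  invisible(x)
}

# ---- forward / backward -----------------------------------------------------

bc_chan <- function(v, A) rep(v, each = A) # per-channel broadcast over (A,C,·)

chan_sum <- function(x, A, C, N) rowSums(colSums(array(x, c(A, C, N)), dims = 1))

net_forward <- function(model, x, training = FALSE) {
  p <- model$params; geom <- model$geom
  cache <- list(x = x)
  a <- x
  for (i in 1:4) {
    blk <- geom$blocks[[i]]
    xd <- dim(a)
    conv <- cpp_conv3d_fwd(a, xd, p[[paste0("conv_w", i)]],
                           dim(p[[paste0("conv_w", i)]]),
                           p[[paste0("conv_b", i)]], TRUE)
    pl <- cpp_maxpool3d_fwd(conv, dim(conv), blk$pool, blk$stride)
    po <- pl$out
    d <- dim(po); A <- prod(d[1:3]); C <- d[4]; N <- d[5]
    if (training) {
      y3 <- array(po, c(A, C, N))
      mu <- rowMeans(colMeans(y3, dims = 1))
      vr <- rowMeans(colMeans(y3^2, dims = 1)) - mu^2
    } else {
      mu <- model$running[[paste0("mean", i)]]
      vr <- model$running[[paste0("var", i)]]
    }
    inv <- 1 / sqrt(vr + BN_EPS)
    xhat <- (po - bc_chan(mu, A)) * bc_chan(inv, A)
    bn <- xhat * bc_chan(p[[paste0("bn_g", i)]], A) +
      bc_chan(p[[paste0("bn_b", i)]], A)
    dim(bn) <- d
    cache[[paste0("blk", i)]] <- list(
      in_dim = xd, conv = conv, pool = pl, xhat = xhat,
      mu = mu, vr = vr, inv = inv, A = A, C = C, N = N)
    a <- bn
  }
  d <- dim(a); A <- prod(d[1:3]); C <- d[4]; N <- d[5]
  feats <- colMeans(array(a, c(A, C, N)), dims = 1) # C x N
  if (is.null(dim(feats))) feats <- matrix(feats, C, N)
  h1 <- p$W1 %*% feats + p$b1
  h1r <- pmax(h1, 0)
  if (training && model$spec$dropout > 0) {
    keep <- 1 - model$spec$dropout
    mask <- matrix(rbinom(length(h1r), 1L, keep), nrow(h1r)) / keep
    h1d <- h1r * mask
  } else {
    mask <- NULL
    h1d <- h1r
  }
  logit <- p$W2 %*% h1d + p$b2
  prob <- 1 / (1 + exp(-logit))
  cache$gap <- list(A = A, C = C, N = N)
  cache$feats <- feats; cache$h1 <- h1r; cache$mask <- mask; cache$h1d <- h1d
  cache$prob <- as.numeric(prob)
  cache
}

# gradient of the mean loss wrt every parameter; glogit is length-N
net_backward <- function(model, cache, glogit) {
  p <- model$params
  grads <- list()
  N <- length(glogit)
  gl <- matrix(glogit, 1, N)
  grads$W2 <- gl %*% t(cache$h1d)
  grads$b2 <- sum(gl)
  gh1d <- t(p$W2) %*% gl
  if (!is.null(cache$mask)) gh1d <- gh1d * cache$mask
  gh1 <- gh1d * (cache$h1 > 0)
  grads$W1 <- gh1 %*% t(cache$feats)
  grads$b1 <- rowSums(gh1)
  gfeats <- t(p$W1) %*% gh1 # C x N
  A <- cache$gap$A; C <- cache$gap$C
  ga <- array(rep(gfeats, each = A) / A, c(A, C, N))
  for (i in 4:1) {
    bl <- cache[[paste0("blk", i)]]
    A <- bl$A; C <- bl$C
    gout <- as.numeric(ga)
    # batch-norm backward (per channel, Nb = A*N elements)
    Nb <- A * N
    gxhat <- gout * bc_chan(p[[paste0("bn_g", i)]], A)
    grads[[paste0("bn_g", i)]] <- chan_sum(gout * bl$xhat, A, C, N)
    grads[[paste0("bn_b", i)]] <- chan_sum(gout, A, C, N)
    s1 <- chan_sum(gxhat, A, C, N)
    s2 <- chan_sum(gxhat * bl$xhat, A, C, N)
    gpool <- bc_chan(bl$inv / Nb, A) *
      (Nb * gxhat - bc_chan(s1, A) - bl$xhat * bc_chan(s2, A))
    gconv <- cpp_maxpool3d_bwd(bl$pool$arg, gpool, bl$pool$odim,
                               dim(bl$conv))
    xin <- if (i == 1) cache$x else {
      # rebuild the block input (bn output of previous block) from cache
      prev <- cache[[paste0("blk", i - 1)]]
      bn_prev <- prev$xhat * bc_chan(p[[paste0("bn_g", i - 1)]], prev$A) +
        bc_chan(p[[paste0("bn_b", i - 1)]], prev$A)
      array(bn_prev, bl$in_dim)
    }
    cb <- cpp_conv3d_bwd(xin, bl$in_dim, p[[paste0("conv_w", i)]],
                         dim(p[[paste0("conv_w", i)]]), bl$conv, gconv, TRUE)
    grads[[paste0("conv_w", i)]] <- cb$gw
    grads[[paste0("conv_b", i)]] <- cb$gb
    ga <- cb$gx
  }
  grads
}

# ---- training ---------------------------------------------------------------

#' Stack patches into a network input tensor
#'
#' 3D variant: `(S, S, B, 1, N)` single-channel volumes; 2D variant:
#' `(S, S, 1, B, N)` with bands as channels.
#'
#' @param patches List of `hsi_patch` objects with identical dimensions.
#' @param variant `"3d"` or `"2d"`.
#' @return A 5-axis numeric array.
#' @export
patches_to_input <- function(patches, variant = c("3d", "2d")) {
  variant <- match.arg(variant)
  d <- dim(patches[[1]]$values)
  N <- length(patches)
  x <- array(0, c(d, N))
  for (i in seq_len(N)) x[, , , i] <- patches[[i]]$values
  # (S, S, B, N) memory order matches both targets: insert the unit axis
  # after the bands (3d: channel axis) or before them (2d: depth axis).
  if (variant == "3d") dim(x) <- c(d[1], d[2], d[3], 1L, N)
  else dim(x) <- c(d[1], d[2], 1L, d[3], N)
  x
}

patch_labels <- function(patches) {
  labs <- vapply(patches, `[[`, "", "label")
  ifelse(labs == "unhealthy", 1, -1)
}

patch_cases <- function(patches) {
  vapply(patches, function(p) as.character(p$case_id), "")
}

#' Train the classifier
#'
#' Minimizes the mean focal loss with Adam over mini-batches. Training and
#' validation patch sets must come from disjoint cases: any shared case
#' identifier raises a hard leakage error. With identical seed and
#' configuration the run is bit-reproducible.
#'
#' @param model An untrained [build_classifier()] model.
#' @param train,val Lists of `hsi_patch` objects (validation may be empty).
#' @param loss [focal_loss_params()] / [loss_spec()].
#' @param cfg [train_config()].
#' @return The trained model, with `$history` holding one row per epoch
#'   (train/val loss, accuracy, MCC).
#' @export
train_classifier <- function(model, train, val = list(),
                             loss = focal_loss_params(),
                             cfg = train_config()) {
  stopifnot(inherits(model, "hsicnn_model"))
  if (length(train) == 0L) hsi_abort("empty training set", "input_error")
  overlap <- intersect(patch_cases(train),
                       if (length(val)) patch_cases(val) else character(0))
  if (length(overlap))
    hsi_abort(paste("cases present in both training and validation:",
                    paste(unique(overlap), collapse = ", ")),
              "leakage_error")
  xtr <- patches_to_input(train, model$variant)
  ytr <- patch_labels(train)
  has_val <- length(val) > 0L
  if (has_val) {
    xva <- patches_to_input(val, model$variant)
    yva <- patch_labels(val)
  }
  N <- length(ytr)
  set.seed(cfg$seed)
  if (!model$trained) {
    # prior initialization of the output bias: start the predicted
    # probability at the empirical positive rate, so early optimizer steps
    # are not spent inflating the majority class and the focal loss can
    # concentrate on the minority from the first batch
    prior <- min(max(mean(ytr == 1), 0.02), 0.98)
    model$params$b2 <- log(prior / (1 - prior))
  }
  adam <- list(m = rapply(model$params, function(p) p * 0, how = "list"),
               v = rapply(model$params, function(p) p * 0, how = "list"),
               t = 0L)
  history <- list()
  for (epoch in seq_len(cfg$epochs)) {
    ord <- sample.int(N)
    ep_loss <- 0; ep_n <- 0L
    tr_prob <- numeric(N)
    # batch-norm inference statistics are re-estimated every epoch as the
    # sample-weighted average of the epoch's batch moments; with the short
    # schedules used here this tracks the weights far better than a slow
    # exponential running average would
    bn_acc <- replicate(4, list(s1 = 0, s2 = 0, n = 0), simplify = FALSE)
    for (b0 in seq(1L, N, by = cfg$batch_size)) {
      idx <- ord[b0:min(b0 + cfg$batch_size - 1L, N)]
      xb <- index_batch(xtr, idx)
      yb <- ytr[idx]
      cache <- net_forward(model, xb, training = TRUE)
      for (i in 1:4) {
        bl <- cache[[paste0("blk", i)]]
        bn_acc[[i]]$s1 <- bn_acc[[i]]$s1 + length(yb) * bl$mu
        bn_acc[[i]]$s2 <- bn_acc[[i]]$s2 + length(yb) * (bl$vr + bl$mu^2)
        bn_acc[[i]]$n <- bn_acc[[i]]$n + length(yb)
      }
      lb <- focal_loss(cache$prob, yb, loss)
      glogit <- focal_loss_grad_logit(cache$prob, yb, loss) / length(yb)
      grads <- net_backward(model, cache, glogit)
      adam$t <- adam$t + 1L
      for (nm in names(model$params)) {
        g <- grads[[nm]]
        adam$m[[nm]] <- cfg$beta1 * adam$m[[nm]] + (1 - cfg$beta1) * g
        adam$v[[nm]] <- cfg$beta2 * adam$v[[nm]] + (1 - cfg$beta2) * g^2
        mh <- adam$m[[nm]] / (1 - cfg$beta1^adam$t)
        vh <- adam$v[[nm]] / (1 - cfg$beta2^adam$t)
        model$params[[nm]] <- model$params[[nm]] - cfg$lr * mh / (sqrt(vh) + 1e-8)
      }
      ep_loss <- ep_loss + sum(lb); ep_n <- ep_n + length(yb)
      tr_prob[idx] <- cache$prob
    }
    for (i in 1:4) {
      mu <- bn_acc[[i]]$s1 / bn_acc[[i]]$n
      model$running[[paste0("mean", i)]] <- mu
      model$running[[paste0("var", i)]] <- bn_acc[[i]]$s2 / bn_acc[[i]]$n - mu^2
    }
    tr_pred <- ifelse(tr_prob > 0.5, 1, -1)
    tr_m <- compute_metrics(confusion_signed(ytr, tr_pred))
    row <- data.frame(epoch = epoch, train_loss = ep_loss / ep_n,
                      train_acc = tr_m$accuracy, train_mcc = tr_m$mcc,
                      val_loss = NA_real_, val_acc = NA_real_,
                      val_mcc = NA_real_)
    if (has_val) {
      vp <- net_predict(model, xva)
      row$val_loss <- mean(focal_loss(vp, yva, loss))
      vm <- compute_metrics(confusion_signed(yva, ifelse(vp > 0.5, 1, -1)))
      row$val_acc <- vm$accuracy; row$val_mcc <- vm$mcc
    }
    history[[epoch]] <- row
    if (cfg$verbose)
      message(sprintf("epoch %3d  loss %.4f  train MCC %.3f  val MCC %s",
                      epoch, row$train_loss, row$train_mcc,
                      ifelse(is.na(row$val_mcc), "-",
                             sprintf("%.3f", row$val_mcc))))
  }
  # precise-BN finalization: re-estimate inference statistics with the
  # *final* weights in one sweep over the training set, so evaluation-mode
  # normalization matches the network actually being deployed rather than
  # an average over mid-epoch weight states
  bn_acc <- replicate(4, list(s1 = 0, s2 = 0, n = 0), simplify = FALSE)
  for (b0 in seq(1L, N, by = cfg$batch_size)) {
    idx <- b0:min(b0 + cfg$batch_size - 1L, N)
    cache <- net_forward(model, index_batch(xtr, idx), training = TRUE)
    for (i in 1:4) {
      bl <- cache[[paste0("blk", i)]]
      bn_acc[[i]]$s1 <- bn_acc[[i]]$s1 + length(idx) * bl$mu
      bn_acc[[i]]$s2 <- bn_acc[[i]]$s2 + length(idx) * (bl$vr + bl$mu^2)
      bn_acc[[i]]$n <- bn_acc[[i]]$n + length(idx)
    }
  }
  for (i in 1:4) {
    mu <- bn_acc[[i]]$s1 / bn_acc[[i]]$n
    model$running[[paste0("mean", i)]] <- mu
    model$running[[paste0("var", i)]] <- bn_acc[[i]]$s2 / bn_acc[[i]]$n - mu^2
  }
  model$trained <- TRUE
  model$history <- do.call(rbind, history)
  model$loss <- loss
  model$train_cfg <- cfg
  model
}

index_batch <- function(x, idx) {
  d <- dim(x)
  out <- x[, , , , idx, drop = FALSE]
  dim(out) <- c(d[1:4], length(idx))
  out
}

# decision rule: unhealthy iff p strictly exceeds the threshold
decide_labels <- function(prob, threshold = 0.5) {
  ifelse(prob > threshold, "unhealthy", "healthy")
}

# evaluation-mode probabilities for a 5-axis input tensor, batched
net_predict <- function(model, x, batch = 64L) {
  N <- dim(x)[5]
  probs <- numeric(N)
  for (b0 in seq(1L, N, by = batch)) {
    idx <- b0:min(b0 + batch - 1L, N)
    cache <- net_forward(model, index_batch(x, idx), training = FALSE)
    probs[idx] <- cache$prob
  }
  probs
}

#' Predict patch labels
#'
#' Runs the trained model in evaluation mode (running batch-norm
#' statistics, no dropout). A patch is called unhealthy iff its predicted
#' probability strictly exceeds the threshold; exactly 0.5 is called
#' healthy.
#'
#' @param model A trained `hsicnn_model`.
#' @param patches List of `hsi_patch` objects matching the model input size.
#' @param threshold Decision threshold (default 0.5, strict).
#' @return A data frame: `case_id`, `truth`, `prob`, `pred`.
#' @export
predict_patches <- function(model, patches, threshold = 0.5) {
  stopifnot(inherits(model, "hsicnn_model"))
  d <- dim(patches[[1]]$values)
  if (!all(d == model$input_dims))
    hsi_abort(sprintf("patch dims %s do not match model input %s",
                      paste(d, collapse = "x"),
                      paste(model$input_dims, collapse = "x")),
              "shape_error")
  x <- patches_to_input(patches, model$variant)
  prob <- net_predict(model, x)
  data.frame(case_id = patch_cases(patches),
             truth = vapply(patches, `[[`, "", "label"),
             prob = prob,
             pred = decide_labels(prob, threshold))
}

#' Save / load a model checkpoint
#'
#' The weights go to an RDS file; a JSON sidecar (`<path>.json`) records
#' the topology, variant, input size, loss and training configuration, and
#' seeds for provenance.
#'
#' @param model A trained `hsicnn_model`.
#' @param path Checkpoint path.
#' @return `path` (`save_model`) or the model (`load_model`).
#' @export
save_model <- function(model, path) {
  saveRDS(model, path)
  sidecar <- list(variant = model$variant,
                  input_dims = model$input_dims,
                  topology = unclass(model$spec),
                  loss = if (!is.null(model$loss)) unclass(model$loss),
                  train_config = if (!is.null(model$train_cfg))
                    unclass(model$train_cfg),
                  init_seed = model$init_seed)
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       null = "null")
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) readRDS(path)

#' Export training history as CSV
#'
#' @param model A trained model.
#' @param path Output CSV path.
#' @return The history data frame, invisibly.
#' @export
write_history <- function(model, path) {
  if (is.null(model$history))
    hsi_abort("model has no training history", "input_error")
  write.csv(model$history, path, row.names = FALSE)
  invisible(model$history)
}
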