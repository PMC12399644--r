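# ---------------------------------------------------------------------------
# Losses, clip-consistent augmentation, SGD training loop, checkpointing.
#
# The total loss is  l = l_S + lambda * l_R  with l_R the mean squared error
# of the reconstructions at every dense-output node (real frames exist at
# every spanned index) and l_S = cross-entropy + soft Dice, supervised only
# at the single annotated node, mirroring the sparse clinical labelling.
# ---------------------------------------------------------------------------

#' Training configuration
#'
#' @param lr SGD learning rate (full-scale reference value 0.05; plain SGD,
#'   no momentum or weight decay, constant schedule).
#' @param epochs number of passes over the training set (scaled default 20).
#' @param batch_size gradients are averaged over this many clips per update
#'   (scaled default 4).
#' @param lambda reconstruction loss weight (default 10).
#' @param seed RNG seed controlling shuffling, augmentation and label-node
#'   placement.
#' @param augment logical: enable clip-consistent augmentation.
#' @param clip_grad maximum global gradient L2 norm (0 disables clipping).
#' @param val_fraction fraction of clips held out for validation-based
#'   checkpoint selection (mean foreground Dice on annotated frames).
#' @return object of class `train_config`.
#' @export
train_config <- function(lr = 0.05, epochs = 20L, batch_size = 4L,
                         lambda = 10, seed = 1L, augment = TRUE,
                         clip_grad = 5, val_fraction = 0.1,
                         optimizer = c("sgd", "adam")) {
  optimizer <- match.arg(optimizer)
  stopifnot(lr > 0, lambda >= 0, epochs >= 1, batch_size >= 1)
  structure(list(lr = lr, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), lambda = lambda,
                 seed = as.integer(seed), augment = isTRUE(augment),
                 clip_grad = clip_grad, val_fraction = val_fraction,
                 optimizer = optimizer),
            class = "train_config")
}

#' Mean-squared-error reconstruction loss (plain arrays)
#' @param x_hat,x arrays of identical shape
#' @return scalar mean over all elements
#' @export
reconstruction_loss <- function(x_hat, x) {
  stopifnot(all(dim(x_hat) == dim(x)))
  mean((x_hat - x)^2)
}

#' Segmentation loss: cross-entropy plus soft Dice (plain arrays)
#'
#' @param probs `h x w x n_classes` softmax probabilities
#' @param labels `h x w` integer label map (0-based)
#' @param delta Dice smoothing term (> 0)
#' @return scalar CE + (1 - mean foreground Dice)
#' @export
segmentation_loss <- function(probs, labels, delta = 1) {
  stopifnot(delta > 0)
  d <- dim(probs)
  stopifnot(all(labels >= 0), all(labels < d[3]))
  idx <- cbind(as.vector(row(labels)), as.vector(col(labels)),
               as.vector(labels) + 1L)
  ce <- -mean(log(pmax(probs[idx], 1e-12)))
  onehot <- array(0, d)
  onehot[idx] <- 1
  cls <- 2:d[3]
  dice <- vapply(cls, function(c) {
    (2 * sum(probs[, , c] * onehot[, , c]) + delta) /
      (sum(probs[, , c]) + sum(onehot[, , c]) + delta)
  }, 0)
  ce + (1 - mean(dice))
}

#' Total loss
#' @param l_s segmentation loss, @param l_r reconstruction loss,
#' @param lambda reconstruction weight (>= 0)
#' @return `l_s + lambda * l_r`
#' @export
total_loss <- function(l_s, l_r, lambda = 10) {
  stopifnot(lambda >= 0)
  l_s + lambda * l_r
}

# --- augmentation -----------------------------------------------------------

#' Clip-consistent augmentation
#'
#' One spatial transform (horizontal flip; random resize + crop/pad back) is
#' sampled per clip and applied identically to every frame and label map
#' (nearest-neighbour for labels); photometric jitter (affine intensity) and
#' a 3x3 Gaussian blur are applied per clip.  Deterministic under `seed`.
#'
#' @param frames `h x w x n` array
#' @param labels `h x w x n` integer array (or NULL)
#' @param seed integer seed (NULL: use current RNG state)
#' @param flip,resize,jitter,blur toggles
#' @return list(frames, labels)
#' @export
augment_clip <- function(frames, labels = NULL, seed = NULL, flip = TRUE,
                         resize = TRUE, jitter = TRUE, blur = TRUE) {
  if (!is.null(seed)) set.seed(seed)
  d <- dim(frames)
  H <- d[1]; W <- d[2]; n <- d[3]
  do_flip <- flip && stats::runif(1) < 0.5
  sc <- if (resize) stats::runif(1, 0.9, 1.1) else 1
  gain <- if (jitter) stats::runif(1, 0.9, 1.1) else 1
  bias <- if (jitter) stats::runif(1, -0.05, 0.05) else 0
  do_blur <- blur && stats::runif(1) < 0.3

  resize_img <- function(m, oh, ow)
    cpp_resize_bilinear(array(m, c(nrow(m), ncol(m), 1)), oh, ow)[, , 1]
  blur3 <- function(m) {
    k <- c(1, 2, 1) / 4
    m2 <- apply(m, 2, function(col) stats::filter(col, k, sides = 2))
    m2[is.na(m2)] <- m[is.na(m2)]
    m3 <- t(apply(m2, 1, function(rw) stats::filter(rw, k, sides = 2)))
    m3[is.na(m3)] <- m2[is.na(m3)]
    m3
  }
  crop_or_pad <- function(m, H, W, fill, nearest = FALSE) {
    h2 <- nrow(m); w2 <- ncol(m)
    if (h2 == H && w2 == W) return(m)
    if (h2 > H) {
      r0 <- (h2 - H) %/% 2; c0 <- (w2 - W) %/% 2
      if (h2 - H > min(H, h2)) stop("crop larger than image")
      m[r0 + seq_len(H), c0 + seq_len(W)]
    } else {
      out <- matrix(fill, H, W)
      r0 <- (H - h2) %/% 2; c0 <- (W - w2) %/% 2
      out[r0 + seq_len(h2), c0 + seq_len(w2)] <- m
      out
    }
  }

  fr2 <- array(0, d)
  lb2 <- if (!is.null(labels)) array(0L, dim(labels)) else NULL
  oh <- max(8L, as.integer(round(H * sc)))
  ow <- max(8L, as.integer(round(W * sc)))
  for (t in seq_len(n)) {
    f <- frames[, , t]
    if (sc != 1) f <- crop_or_pad(resize_img(f, oh, ow), H, W, fill = 0)
    if (do_flip) f <- f[, rev(seq_len(W))]
    f <- f * gain + bias
    if (do_blur) f <- blur3(f)
    fr2[, , t] <- pmin(pmax(f, 0), 1)
  }
  # the same spatial transform applies to every label map (the label stack
  # may hold fewer slices than the frame stack, e.g. one annotated frame)
  if (!is.null(labels)) {
    for (t in seq_len(dim(labels)[3])) {
      l <- labels[, , t]
      if (sc != 1) {
        l <- matrix(as.integer(cpp_resize_nearest(matrix(as.integer(l), H, W),
                                                  oh, ow)), oh, ow)
        l <- crop_or_pad(l, H, W, fill = 0L)
      }
      if (do_flip) l <- l[, rev(seq_len(W))]
      lb2[, , t] <- l
    }
  }
  list(frames = fr2, labels = lb2)
}

# --- datasets ---------------------------------------------------------------

#' Build a phantom training dataset of sparsely annotated clips
#'
#' Each clip comes from an independently generated phantom video (geometry
#' jittered per video) and carries one annotated frame.
#'
#' @param n_clips number of clips
#' @param image_size,n_frames,base_period,pulsation_amplitude,n_classes,
#'   speckle_strength passed to [phantom_config()]
#' @param geometry_jitter per-video geometry perturbation (default 0.08)
#' @param policy sampling policy for the annotated-frame position
#' @param seed master seed
#' @return list of records as returned by [sample_clip()], each with the
#'   generating `video`/`annotation` attached
#' @export
make_phantom_dataset <- function(n_clips, image_size = 64L, n_frames = 24L,
                                 base_period = 20L,
                                 pulsation_amplitude = 0.2, n_classes = 7L,
                                 speckle_strength = 0.18,
                                 geometry_jitter = 0.08,
                                 policy = c("train", "eval"), seed = 1L) {
  policy <- match.arg(policy)
  set.seed(seed)
  seeds <- sample.int(2^30, n_clips + 1L)
  lapply(seq_len(n_clips), function(i) {
    cfg <- phantom_config(image_size = image_size, n_frames = n_frames,
                          base_period = base_period,
                          pulsation_amplitude = pulsation_amplitude,
                          n_classes = n_classes,
                          speckle_strength = speckle_strength,
                          geometry_jitter = geometry_jitter,
                          seed = seeds[i])
    ph <- generate_phantom(cfg)
    # annotate an ED or ES frame, like the clinical datasets
    cand <- c(ph$annotation$ed_frames, ph$annotation$es_frames)
    cand <- cand[cand >= 0 & cand < n_frames]
    set.seed(seeds[i] + 1L)
    k <- if (length(cand)) cand[sample.int(length(cand), 1L)] else n_frames - 1L
    rec <- sample_clip(ph$video, ph$annotation, annotated_frame = k,
                       policy = policy)
    rec$video <- ph$video
    rec$annotation <- ph$annotation
    rec
  })
}

# --- loss graph -------------------------------------------------------------

# Builds the taped total loss for one clip record; returns tape, loss id,
# parameter ids and the separate components.
echode_clip_loss <- function(model, rec, lambda, pos_weight = 10,
                             loss_type = c("bce", "mse")) {
  loss_type <- match.arg(loss_type)
  fwd <- echode_forward_t(model, rec$frames, rec$tau, rec$S)
  tp <- fwd$tape
  lr_ids <- integer(length(rec$S))
  for (i in seq_along(rec$S)) {
    tgt <- rec$recon_targets[, , i]
    tgt3 <- array(rep(tgt, 3), c(dim(tgt), 3))
    lr_ids[i] <- op_mse(tp, fwd$recon[[i]], tgt3)
  }
  l_r <- op_scalar_lincomb(tp, lr_ids, rep(1 / length(lr_ids),
                                           length(lr_ids)))
  if (model$mode == "segmentation") {
    pnode <- fwd$probs[[rec$label_node]]
    ce <- op_ce_from_probs(tp, pnode, rec$label)
    dl <- op_soft_dice(tp, pnode, rec$label)
    l_s <- op_scalar_lincomb(tp, c(ce, dl), c(1, 1))
  } else {
    hm <- heatmap_targets(rec, sigma = max(1, 2 * dim(rec$frames)[1] / 64))
    if (identical(loss_type, "bce")) {
      l_s <- op_bce_logits(tp, fwd$logits[[rec$label_node]], hm,
                           pos_weight = pos_weight)
    } else {
      # mean squared error between the sigmoid heatmaps and the Gaussian
      # targets, upweighted so the two loss branches share a magnitude scale
      p <- op_sigmoid(tp, fwd$logits[[rec$label_node]])
      l_s <- op_affine(tp, op_mse(tp, p, hm), 20)
    }
  }
  loss <- op_scalar_lincomb(tp, c(l_s, l_r), c(1, lambda))
  list(tape = tp, loss = loss, pid = fwd$pid, l_s = tp_v(tp, l_s),
       l_r = tp_v(tp, l_r))
}

# Gaussian keypoint heatmap targets (6 channels: begin/end of IVS,LVID,LVPW)
heatmap_targets <- function(rec, sigma = 2) {
  seg <- rec$annotation$segments[[rec$annotated_frame + 1L]]
  d <- dim(rec$frames)
  H <- d[1]; W <- d[2]
  rr <- matrix(rep(0:(H - 1), W), H, W)
  cc <- t(matrix(rep(0:(W - 1), H), W, H))
  out <- array(0, c(H, W, 6))
  pts <- list(seg$IVS$begin, seg$IVS$end, seg$LVID$begin, seg$LVID$end,
              seg$LVPW$begin, seg$LVPW$end)
  for (i in seq_along(pts)) {
    p <- pts[[i]]
    out[, , i] <- exp(-((rr - p[1])^2 + (cc - p[2])^2) / (2 * sigma^2))
  }
  out
}

# --- SGD loop ---------------------------------------------------------------

.grad_accum <- function(acc, g, pid) {
  for (nm in names(pid)) {
    gi <- g[[pid[[nm]]]]
    if (is.null(gi)) next
    acc[[nm]] <- if (is.null(acc[[nm]])) gi else acc[[nm]] + gi
  }
  acc
}

.sgd_step <- function(params, acc, lr, nbatch, clip_grad) {
  gn2 <- 0
  for (nm in names(acc)) gn2 <- gn2 + sum((acc[[nm]] / nbatch)^2)
  gn <- sqrt(gn2)
  scale <- if (clip_grad > 0 && gn > clip_grad) clip_grad / gn else 1
  for (nm in names(acc))
    params[[nm]] <- params[[nm]] - lr * scale * acc[[nm]] / nbatch
  params
}

# Adam with bias correction; `state` is an environment carrying m/v/t.
# Plain SGD is the reference optimiser; Adam exists because the keypoint
# (measurement) head's extreme positive/negative imbalance defeats SGD at
# desk scale.
.adam_step <- function(params, acc, lr, nbatch, state, clip_grad = 0,
                       b1 = 0.9, b2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  scale <- 1
  if (clip_grad > 0) {
    gn2 <- 0
    for (nm in names(acc)) gn2 <- gn2 + sum((acc[[nm]] / nbatch)^2)
    gn <- sqrt(gn2)
    if (gn > clip_grad) scale <- clip_grad / gn
  }
  for (nm in names(acc)) {
    g <- scale * acc[[nm]] / nbatch
    if (is.null(state$m[[nm]])) {
      state$m[[nm]] <- g * 0
      state$v[[nm]] <- g * 0
    }
    state$m[[nm]] <- b1 * state$m[[nm]] + (1 - b1) * g
    state$v[[nm]] <- b2 * state$v[[nm]] + (1 - b2) * g^2
    mh <- state$m[[nm]] / (1 - b1^state$t)
    vh <- state$v[[nm]] / (1 - b2^state$t)
    params[[nm]] <- params[[nm]] - lr * mh / (sqrt(vh) + eps)
  }
  params
}

#' Train an Echo-ODE model on a clip dataset
#'
#' Plain SGD; both loss components are logged separately per epoch so their
#' relative magnitudes can be inspected.  The checkpoint with the best
#' validation foreground Dice (segmentation) or lowest validation loss
#' (measurement) is returned.
#'
#' @param dataset list of clip records from [make_phantom_dataset()]
#' @param model an [echode_model()]
#' @param config a [train_config()]
#' @param verbose print per-epoch summaries
#' @return list with `model` (best checkpoint), `final_model`, and `log`
#'   (data.frame: epoch, train_seg, train_rec, train_total, val_metric)
#' @export
train_echode <- function(dataset, model, config = train_config(),
                         verbose = TRUE) {
  set.seed(config$seed)
  n <- length(dataset)
  n_val <- max(1L, as.integer(round(config$val_fraction * n)))
  idx <- sample.int(n)
  val_idx <- idx[seq_len(n_val)]
  tr_idx <- idx[-seq_len(n_val)]
  log <- data.frame()
  best <- -Inf
  best_params <- model$params
  opt_state <- new.env(parent = emptyenv())
  opt_state$m <- list(); opt_state$v <- list(); opt_state$t <- 0L
  step_fn <- function(params, acc, nb) {
    if (identical(config$optimizer, "adam"))
      .adam_step(params, acc, config$lr, nb, opt_state, config$clip_grad)
    else .sgd_step(params, acc, config$lr, nb, config$clip_grad)
  }
  for (ep in seq_len(config$epochs)) {
    ord <- sample(tr_idx)
    acc <- list()
    nb <- 0L
    sum_s <- sum_r <- 0
    for (ci in ord) {
      rec <- dataset[[ci]]
      # spatial augmentation would desynchronise the measurement keypoints
      # (segments are stored in original coordinates), so it only applies in
      # segmentation mode
      if (config$augment && model$mode == "segmentation") {
        # augment the full dense frame stack once so that inputs and
        # reconstruction targets stay consistent, then re-derive the inputs
        # (they are the strided subset of the spanned frames)
        lstack <- array(rec$label, c(dim(rec$label), 1L))
        aug <- augment_clip(rec$recon_targets, lstack)
        rec$recon_targets <- aug$frames
        rec$label <- aug$labels[, , 1]
        stride_S <- if (length(rec$tau) > 1)
          (length(rec$S) - 1L) %/% (length(rec$tau) - 1L) else 1L
        rec$frames <- rec$recon_targets[, , seq(1L, dim(aug$frames)[3],
                                                by = stride_S),
                                        drop = FALSE]
      }
      lg <- echode_clip_loss(model, rec, config$lambda)
      if (!is.finite(lg$l_s) || !is.finite(lg$l_r))
        stop(sprintf("training diverged (NaN loss) at epoch %d", ep))
      g <- tp_backward(lg$tape, lg$loss)
      acc <- .grad_accum(acc, g, lg$pid)
      nb <- nb + 1L
      sum_s <- sum_s + lg$l_s
      sum_r <- sum_r + lg$l_r
      if (nb == config$batch_size) {
        model$params <- step_fn(model$params, acc, nb)
        acc <- list(); nb <- 0L
      }
    }
    if (nb > 0)
      model$params <- step_fn(model$params, acc, nb)
    val <- .validate(model, dataset[val_idx], config$lambda)
    log <- rbind(log, data.frame(
      epoch = ep, train_seg = sum_s / length(ord),
      train_rec = sum_r / length(ord),
      train_total = (sum_s + config$lambda * sum_r) / length(ord),
      val_metric = val))
    if (val > best) {
      best <- val
      best_params <- model$params
    }
    if (verbose)
      message(sprintf(
        "epoch %3d  seg %.4f  rec %.4f  total %.4f  val %.4f",
        ep, sum_s / length(ord), sum_r / length(ord),
        (sum_s + config$lambda * sum_r) / length(ord), val))
  }
  best_model <- model
  best_model$params <- best_params
  list(model = best_model, final_model = model, log = log)
}

# validation metric: mean foreground dice on annotated frames (segmentation)
# or negative loss (measurement)
.validate <- function(model, recs, lambda) {
  if (model$mode == "segmentation") {
    mean(vapply(recs, function(rec) {
      out <- echo_ode_forward(model, rec$frames, rec$tau, rec$S)
      lab <- out$labels[, , rec$label_node]
      fg <- sort(unique(as.vector(rec$label)))
      fg <- fg[fg > 0]
      if (!length(fg)) return(1)
      mean(vapply(fg, function(c) dice(lab == c, rec$label == c), 0))
    }, 0))
  } else {
    -mean(vapply(recs, function(rec)
      echode_clip_loss(model, rec, lambda)$l_s, 0))
  }
}

#' Train the per-frame baseline on the annotated frames of a dataset
#'
#' @inheritParams train_echode
#' @param model a [baseline_model()]
#' @return list with `model` and `log`
#' @export
train_baseline <- function(dataset, model, config = train_config(),
                           verbose = TRUE) {
  set.seed(config$seed + 1L)
  log <- data.frame()
  for (ep in seq_len(config$epochs)) {
    ord <- sample(seq_along(dataset))
    acc <- list()
    nb <- 0L
    tot <- 0
    for (ci in ord) {
      rec <- dataset[[ci]]
      img <- rec$recon_targets[, , rec$label_node]
      lab <- rec$label
      if (config$augment) {
        aug <- augment_clip(array(img, c(dim(img), 1L)),
                            array(lab, c(dim(lab), 1L)))
        img <- aug$frames[, , 1]
        lab <- aug$labels[, , 1]
      }
      fw <- baseline_forward_t(model, img)
      tp <- fw$tape
      ce <- op_ce_from_probs(tp, fw$probs, lab)
      dl <- op_soft_dice(tp, fw$probs, lab)
      loss <- op_scalar_lincomb(tp, c(ce, dl), c(1, 1))
      if (!is.finite(tp_v(tp, loss)))
        stop(sprintf("baseline training diverged at epoch %d", ep))
      g <- tp_backward(tp, loss)
      acc <- .grad_accum(acc, g, fw$pid)
      nb <- nb + 1L
      tot <- tot + tp_v(tp, loss)
      if (nb == config$batch_size) {
        model$params <- .sgd_step(model$params, acc, config$lr, nb,
                                  config$clip_grad)
        acc <- list(); nb <- 0L
      }
    }
    if (nb > 0)
      model$params <- .sgd_step(model$params, acc, config$lr, nb,
                                config$clip_grad)
    log <- rbind(log, data.frame(epoch = ep, train = tot / length(ord)))
    if (verbose)
      message(sprintf("baseline epoch %3d  loss %.4f", ep,
                      tot / length(ord)))
  }
  list(model = model, log = log)
}

# --- checkpointing ----------------------------------------------------------

#' Save / load a model checkpoint
#'
#' Checkpoints are versioned RDS files holding the model object and a format
#' tag.
#' @param model a model object, @param path file path
#' @export
save_checkpoint <- function(model, path) {
  saveRDS(list(format = "echode-checkpoint-v1", model = model), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  x <- readRDS(path)
  if (!identical(x$format, "echode-checkpoint-v1"))
    stop("unrecognised checkpoint format")
  x$model
}
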