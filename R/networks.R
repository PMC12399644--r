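# ---------------------------------------------------------------------------
# Network architectures.
#
# Encoder: four pairs of 3x3 convolutions with 2x2 max-pooling between pairs
# (three poolings), so the bottleneck sits at 1/8 resolution.  Full-scale
# channel pairs are (32,32),(64,64),(128,128),(256,256); `width_scale`
# divides all widths for desk-scale runs.
#
# Reconstruction decoder: three nearest-upsample + convolution-pair stages
# that mirror the encoder and end in a 3-channel image; its stage features
# (at 1/4, 1/2 and full resolution) feed the target decoder through skip
# connections.  The target decoder has the same shape and ends in an
# n_classes softmax head (segmentation) or a 6-channel sigmoid head
# (measurement keypoint heatmaps).
# ---------------------------------------------------------------------------

.he_init <- function(k, cin, cout, gain = 1) {
  sd <- gain * sqrt(2 / (k * k * cin))
  matrix(stats::rnorm(k * k * cin * cout, 0, sd), k * k * cin, cout)
}

.conv_par <- function(p, name, cin, cout, k = 3, gain = 1) {
  p[[paste0(name, ".w")]] <- .he_init(k, cin, cout, gain)
  p[[paste0(name, ".b")]] <- numeric(cout)
  p
}

.enc_widths <- function(width_scale) {
  w <- c(32L, 64L, 128L, 256L) %/% as.integer(width_scale)
  if (any(w < 2L)) stop("width_scale too large")
  w
}

#' Construct an Echo-ODE model
#'
#' @param n_classes number of segmentation classes (incl. background).
#' @param width_scale divisor applied to all channel widths (1 = full scale).
#' @param mode `"segmentation"` (softmax head) or `"measurement"`
#'   (6 sigmoid keypoint heatmaps: begin/end of IVS, LVID, LVPW).
#' @param skips logical: skip connections from the reconstruction decoder to
#'   the target decoder (disable to reproduce the no-skip ablation).
#' @param solver an [ode_solve_config()].
#' @param seed RNG seed for weight initialisation.
#' @return object of class `echode_model`.
#' @export
echode_model <- function(n_classes = 7L, width_scale = 1L,
                         mode = c("segmentation", "measurement"),
                         skips = TRUE, solver = ode_solve_config(),
                         seed = 1L) {
  mode <- match.arg(mode)
  set.seed(seed)
  w <- .enc_widths(width_scale)
  C <- w[4]
  n_out <- if (mode == "segmentation") as.integer(n_classes) else 6L
  p <- list()
  # encoder: stage s, conv pair (c1, c2)
  cin <- 3L
  for (s in 1:4) {
    p <- .conv_par(p, sprintf("enc.s%d.c1", s), cin, w[s])
    p <- .conv_par(p, sprintf("enc.s%d.c2", s), w[s], w[s])
    cin <- w[s]
  }
  # encoder-side derivative network f_enc(h): C -> C -> C
  p <- .conv_par(p, "fenc.c1", C, C)
  p <- .conv_par(p, "fenc.c2", C, C)
  p <- .conv_par(p, "fenc.c3", C, C, gain = 0.1)  # mild initial dynamics
  # ConvGRU (hidden C, input C)
  p <- .conv_par(p, "gru.z", 2L * C, C)
  p <- .conv_par(p, "gru.r", 2L * C, C)
  p <- .conv_par(p, "gru.h", 2L * C, C)
  # initial-state convolution h_s0 = conv(D)
  p <- .conv_par(p, "init", C, C)
  # decoder-side derivative f(h, D): concat 2C -> C -> C -> C
  p <- .conv_par(p, "fdec.c1", 2L * C, C)
  p <- .conv_par(p, "fdec.c2", C, C)
  p <- .conv_par(p, "fdec.c3", C, C, gain = 0.1)
  # reconstruction decoder
  p <- .conv_par(p, "rec.s1.c1", w[4], w[3])
  p <- .conv_par(p, "rec.s1.c2", w[3], w[3])
  p <- .conv_par(p, "rec.s2.c1", w[3], w[2])
  p <- .conv_par(p, "rec.s2.c2", w[2], w[2])
  p <- .conv_par(p, "rec.s3.c1", w[2], w[1])
  p <- .conv_par(p, "rec.s3.c2", w[1], w[1])
  p <- .conv_par(p, "rec.out", w[1], 3L)
  # target decoder (skip concat doubles the input width per stage)
  sk <- if (skips) c(w[3], w[2], w[1]) else c(0L, 0L, 0L)
  p <- .conv_par(p, "tgt.s1.c1", w[4] + sk[1], w[3])
  p <- .conv_par(p, "tgt.s1.c2", w[3], w[3])
  p <- .conv_par(p, "tgt.s2.c1", w[3] + sk[2], w[2])
  p <- .conv_par(p, "tgt.s2.c2", w[2], w[2])
  p <- .conv_par(p, "tgt.s3.c1", w[2] + sk[3], w[1])
  p <- .conv_par(p, "tgt.s3.c2", w[1], w[1])
  p <- .conv_par(p, "tgt.out", w[1], n_out)
  # keypoint heads start at a low-confidence prior: with ~25 positive pixels
  # in a 64x64 map, a zero-bias sigmoid head wastes most of its early
  # gradient signal suppressing background
  if (mode == "measurement") p[["tgt.out.b"]][] <- -4
  structure(list(params = p, widths = w, n_classes = as.integer(n_classes),
                 n_out = n_out, mode = mode, skips = skips,
                 solver = solver, width_scale = as.integer(width_scale)),
            class = "echode_model")
}

# push every parameter onto the tape as a leaf; returns named id list
.push_params <- function(tp, params) {
  ids <- lapply(params, function(a) op_leaf(tp, a))
  names(ids) <- names(params)
  ids
}

# --- encoder ----------------------------------------------------------------

# x: tape id of an HxWx3 image; returns bottleneck id + per-stage features
encode_frame <- function(tp, x, pid) {
  stages <- vector("list", 4)
  h <- x
  for (s in 1:4) {
    h <- op_relu(tp, op_conv(tp, h, pid[[sprintf("enc.s%d.c1.w", s)]],
                             pid[[sprintf("enc.s%d.c1.b", s)]]))
    h <- op_relu(tp, op_conv(tp, h, pid[[sprintf("enc.s%d.c2.w", s)]],
                             pid[[sprintf("enc.s%d.c2.b", s)]]))
    stages[[s]] <- h
    if (s < 4) h <- op_maxpool2(tp, h)
  }
  list(bottleneck = h, stages = stages)
}

#' Encode a single image to its bottleneck feature (1/8 resolution)
#'
#' @param model an `echode_model`
#' @param image array `h x w x 3` (grayscale images: replicate the channel)
#' @return list with `bottleneck` (array) and `stages` (list of arrays)
#' @export
encode <- function(model, image) {
  d <- dim(image)
  if (length(d) != 3 || d[3] != 3) stop("image must be h x w x 3")
  if (d[1] %% 8 != 0 || d[2] %% 8 != 0) stop("image dims must be divisible by 8")
  tp <- tape_new()
  pid <- .push_params(tp, model$params)
  r <- encode_frame(tp, op_leaf(tp, image), pid)
  list(bottleneck = tp_v(tp, r$bottleneck),
       stages = lapply(r$stages, function(id) tp_v(tp, id)))
}

# --- decoders ---------------------------------------------------------------

decode_reconstruction_t <- function(tp, h, pid) {
  feats <- vector("list", 3)
  x <- h
  for (s in 1:3) {
    x <- op_upsample2(tp, x)
    x <- op_relu(tp, op_conv(tp, x, pid[[sprintf("rec.s%d.c1.w", s)]],
                             pid[[sprintf("rec.s%d.c1.b", s)]]))
    x <- op_relu(tp, op_conv(tp, x, pid[[sprintf("rec.s%d.c2.w", s)]],
                             pid[[sprintf("rec.s%d.c2.b", s)]]))
    feats[[s]] <- x
  }
  out <- op_conv(tp, x, pid[["rec.out.w"]], pid[["rec.out.b"]])
  list(out = out, feats = feats)
}

# the target decoder uses leaky ReLU: with a low-confidence output prior
# (measurement mode) a plain-ReLU decoder can die into a constant-output
# basin and never recover
decode_target_t <- function(tp, h, skips, pid, use_skips) {
  x <- h
  for (s in 1:3) {
    x <- op_upsample2(tp, x)
    if (use_skips) {
      if (is.null(skips)) stop("skip features required but missing")
      x <- op_concat_c(tp, x, skips[[s]])
    }
    x <- op_lrelu(tp, op_conv(tp, x, pid[[sprintf("tgt.s%d.c1.w", s)]],
                              pid[[sprintf("tgt.s%d.c1.b", s)]]))
    x <- op_lrelu(tp, op_conv(tp, x, pid[[sprintf("tgt.s%d.c2.w", s)]],
                              pid[[sprintf("tgt.s%d.c2.b", s)]]))
  }
  op_conv(tp, x, pid[["tgt.out.w"]], pid[["tgt.out.b"]])  # logits
}

#' Decode a latent state into a reconstructed image
#'
#' @param model an [echode_model()]
#' @param h array at bottleneck resolution (`h/8 x w/8 x C_lat`)
#' @return list with `image` (`h x w x 3`) and `feats` (stage features at
#'   1/4, 1/2 and full resolution, used as skip inputs by [decode_target()])
#' @export
decode_reconstruction <- function(model, h) {
  tp <- tape_new()
  pid <- .push_params(tp, model$params)
  r <- decode_reconstruction_t(tp, op_leaf(tp, h), pid)
  list(image = tp_v(tp, r$out),
       feats = lapply(r$feats, function(id) tp_v(tp, id)))
}

#' Decode a latent state into a task output
#'
#' @inheritParams decode_reconstruction
#' @param skips stage-feature list from [decode_reconstruction()] (required
#'   when the model was built with skip connections)
#' @return for segmentation mode: list with `probs` (softmax) and `labels`
#'   (0-based argmax); for measurement mode: list with `heatmaps`
#'   (6 sigmoid channels)
#' @export
decode_target <- function(model, h, skips = NULL) {
  tp <- tape_new()
  pid <- .push_params(tp, model$params)
  skip_ids <- if (!is.null(skips))
    lapply(skips, function(f) op_leaf(tp, f)) else NULL
  logits <- decode_target_t(tp, op_leaf(tp, h), skip_ids, pid, model$skips)
  if (model$mode == "segmentation") {
    p <- tp_v(tp, op_softmax_c(tp, logits))
    list(probs = p, labels = apply(p, c(1, 2), which.max) - 1L)
  } else {
    list(heatmaps = 1 / (1 + exp(-tp_v(tp, logits))))
  }
}

# --- full forward pass ------------------------------------------------------

# Taped forward pass used by both training and prediction.
# frames: h x w x n array (values in [0,1], single channel) or h x w x 3 x n.
# Returns the tape plus ids of everything a caller might differentiate.
echode_forward_t <- function(model, frames, tau, S) {
  d <- dim(frames)
  n <- d[length(d)]
  stopifnot(length(tau) == n, all(S >= 0), all(S <= 1), !is.unsorted(S))
  tp <- tape_new(8192L)
  pid <- .push_params(tp, model$params)
  to3 <- function(i) {
    f <- if (length(d) == 3) frames[, , i] else frames[, , , i]
    if (is.matrix(f)) array(rep(f, 3), c(d[1], d[2], 3)) else f
  }
  feat_ids <- lapply(seq_len(n), function(i) {
    encode_frame(tp, op_leaf(tp, to3(i)), pid)$bottleneck
  })
  enc <- latent_ode_encode(tp, feat_ids, tau, pid, model$solver)
  f_dec <- make_derivative_fn(pid, "fdec", D = enc$D)
  states <- ode_integrate(tp, f_dec, enc$hs0, 0, S, model$solver)
  recon <- logits <- probs <- vector("list", length(S))
  for (i in seq_along(S)) {
    r <- decode_reconstruction_t(tp, states[[i]], pid)
    recon[[i]] <- r$out
    logits[[i]] <- decode_target_t(tp, states[[i]], r$feats, pid, model$skips)
    if (model$mode == "segmentation")
      probs[[i]] <- op_softmax_c(tp, logits[[i]])
  }
  list(tape = tp, pid = pid, D = enc$D, hs0 = enc$hs0, states = states,
       recon = recon, logits = logits, probs = probs)
}

#' Run the Echo-ODE forward pass
#'
#' Encodes the input frames, runs the backward latent ODE to obtain the
#' per-clip dynamics code `D` and initial state, integrates the
#' dynamics-conditioned decoder ODE to all target times `S` in a single
#' adaptive solve with dense output, and decodes a reconstruction and a task
#' output at every target time.  The number of outputs equals `|S|`
#' regardless of the number of input frames.
#'
#' @param model an [echode_model()]
#' @param frames `h x w x n` array of input frames in `[0, 1]`
#' @param tau input times in `[0, 1]`, one per frame
#' @param S sorted target times in `[0, 1]`
#' @return list with `recon` (`h x w x 3 x |S|`), and for segmentation mode
#'   `probs` (`h x w x n_classes x |S|`, softmax) and `labels`
#'   (`h x w x |S|`, 0-based argmax); for measurement mode `heatmaps`
#'   (`h x w x 6 x |S|`, sigmoid).
#' @export
echo_ode_forward <- function(model, frames, tau, S) {
  r <- echode_forward_t(model, frames, tau, S)
  tp <- r$tape
  d <- dim(tp_v(tp, r$recon[[1]]))
  m <- length(S)
  recon <- array(0, c(d[1], d[2], 3, m))
  for (i in seq_len(m)) recon[, , , i] <- tp_v(tp, r$recon[[i]])
  out <- list(recon = recon, S = S)
  if (model$mode == "segmentation") {
    pr <- array(0, c(d[1], d[2], model$n_classes, m))
    lab <- array(0L, c(d[1], d[2], m))
    for (i in seq_len(m)) {
      p <- tp_v(tp, r$probs[[i]])
      pr[, , , i] <- p
      lab[, , i] <- apply(p, c(1, 2), which.max) - 1L
    }
    out$probs <- pr
    out$labels <- lab
  } else {
    hm <- array(0, c(d[1], d[2], 6, m))
    for (i in seq_len(m))
      hm[, , , i] <- 1 / (1 + exp(-tp_v(tp, r$logits[[i]])))
    out$heatmaps <- hm
  }
  out
}

#' Segment a full video with tiled dense-output windows
#'
#' Tiles the video with eval-policy windows (`n_input` frames, `stride`
#' apart) and stitches the `2 * n_input - 1` dense outputs of each window
#' into per-frame predictions.
#'
#' @inheritParams echo_ode_forward
#' @param video `h x w x n` array of frames
#' @param n_input,stride window geometry (defaults 4 and 2)
#' @return `h x w x n` integer array of 0-based label maps (segmentation
#'   mode) or an `h x w x 6 x n` heatmap array (measurement mode)
#' @export
predict_video <- function(model, video, n_input = 4L, stride = 2L) {
  d <- dim(video)
  n <- d[3]
  span <- stride * (n_input - 1L)
  starts <- seq(0L, max(0L, n - 1L - span), by = span + 1L)
  if (starts[length(starts)] + span < n - 1L)
    starts <- c(starts, n - 1L - span)
  seg <- model$mode == "segmentation"
  out <- if (seg) array(0L, c(d[1], d[2], n)) else array(0, c(d[1], d[2], 6, n))
  done <- logical(n)
  tau <- seq(0, 1, length.out = n_input)
  S <- seq(0, 1, length.out = 2L * n_input - 1L)
  for (st in starts) {
    fidx <- st + stride * (seq_len(n_input) - 1L)
    res <- echo_ode_forward(model, video[, , fidx + 1L, drop = FALSE], tau, S)
    sidx <- st + seq.int(0L, span)
    for (j in seq_along(sidx)) {
      fr <- sidx[j] + 1L
      if (done[fr]) next
      if (seg) out[, , fr] <- res$labels[, , j]
      else out[, , , fr] <- res$heatmaps[, , , j]
      done[fr] <- TRUE
    }
  }
  out
}

# --- per-frame baseline -----------------------------------------------------

#' Construct the per-frame baseline segmenter
#'
#' A small U-shaped network with the same encoder as Echo-ODE and a decoder
#' with skip connections from the encoder stages.  Used only as a
#' temporal-consistency comparator: it sees each frame independently.
#'
#' @inheritParams echode_model
#' @return object of class `baseline_model`
#' @export
baseline_model <- function(n_classes = 7L, width_scale = 1L, seed = 1L) {
  set.seed(seed)
  w <- .enc_widths(width_scale)
  p <- list()
  cin <- 3L
  for (s in 1:4) {
    p <- .conv_par(p, sprintf("enc.s%d.c1", s), cin, w[s])
    p <- .conv_par(p, sprintf("enc.s%d.c2", s), w[s], w[s])
    cin <- w[s]
  }
  p <- .conv_par(p, "up.s1.c1", w[4] + w[3], w[3])
  p <- .conv_par(p, "up.s1.c2", w[3], w[3])
  p <- .conv_par(p, "up.s2.c1", w[3] + w[2], w[2])
  p <- .conv_par(p, "up.s2.c2", w[2], w[2])
  p <- .conv_par(p, "up.s3.c1", w[2] + w[1], w[1])
  p <- .conv_par(p, "up.s3.c2", w[1], w[1])
  p <- .conv_par(p, "out", w[1], as.integer(n_classes))
  structure(list(params = p, widths = w, n_classes = as.integer(n_classes)),
            class = "baseline_model")
}

baseline_forward_t <- function(model, image) {
  tp <- tape_new()
  pid <- .push_params(tp, model$params)
  d <- dim(image)
  img <- if (length(d) == 2 || d[3] == 1)
    array(rep(image, 3), c(d[1], d[2], 3)) else image
  e <- encode_frame(tp, op_leaf(tp, img), pid)
  x <- e$bottleneck
  for (s in 1:3) {
    x <- op_upsample2(tp, x)
    x <- op_concat_c(tp, x, e$stages[[4 - s]])
    x <- op_relu(tp, op_conv(tp, x, pid[[sprintf("up.s%d.c1.w", s)]],
                             pid[[sprintf("up.s%d.c1.b", s)]]))
    x <- op_relu(tp, op_conv(tp, x, pid[[sprintf("up.s%d.c2.w", s)]],
                             pid[[sprintf("up.s%d.c2.b", s)]]))
  }
  logits <- op_conv(tp, x, pid[["out.w"]], pid[["out.b"]])
  probs <- op_softmax_c(tp, logits)
  list(tape = tp, pid = pid, logits = logits, probs = probs)
}

#' Per-frame baseline segmentation
#'
#' @param model a [baseline_model()]
#' @param image `h x w` matrix or `h x w x {1,3}` array
#' @return list with `probs` (`h x w x n_classes`) and `labels` (0-based)
#' @export
baseline_segment <- function(model, image) {
  r <- baseline_forward_t(model, image)
  p <- tp_v(r$tape, r$probs)
  list(probs = p, labels = apply(p, c(1, 2), which.max) - 1L)
}

#' @rdname baseline_segment
#' @param video `h x w x n` array
#' @return for `baseline_segment_video`: `h x w x n` 0-based label array
#' @export
baseline_segment_video <- function(model, video) {
  n <- dim(video)[3]
  out <- array(0L, dim(video))
  for (i in seq_len(n))
    out[, , i] <- baseline_segment(model, video[, , i])$labels
  out
}
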