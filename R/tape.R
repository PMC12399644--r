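#' @useDynLib echode, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# ---------------------------------------------------------------------------
# Tape-based reverse-mode automatic differentiation.
#
# A tape is an append-only record of array-valued nodes.  Every operation
# computes its value eagerly and registers a vector-Jacobian-product closure
# that, given the gradient of the loss with respect to the node's value,
# returns the gradients with respect to each parent.  tp_backward() walks the
# tape once in reverse, accumulating gradients; nodes that are not ancestors
# of the loss (e.g. rejected ODE solver steps) never receive a gradient and
# cost nothing.
#
# Node handles are plain integer ids; values are base-R numeric arrays with
# layout (H, W, C) for spatial tensors.
#
# Every op force()s its id arguments before reading tp$val: callers nest op
# calls (op_relu(tp, op_conv(...))), and R would otherwise fetch the tp$val
# list before the inner promise has appended its node to it.
# ---------------------------------------------------------------------------

tape_new <- function(n_expect = 2048L) {
  tp <- new.env(parent = emptyenv())
  # hashed environments, not lists: element assignment into an env is O(1)
  # and never copies, whereas growing/writing a list whose reference count
  # exceeds one copies the whole pointer array on every push
  tp$val <- new.env(hash = TRUE, parent = emptyenv(), size = n_expect)
  tp$par <- new.env(hash = TRUE, parent = emptyenv(), size = n_expect)
  tp$vjp <- new.env(hash = TRUE, parent = emptyenv(), size = n_expect)
  tp$n <- 0L
  class(tp) <- "echode_tape"
  tp
}

tp_push <- function(tp, value, parents = NULL, vjp = NULL) {
  n <- tp$n + 1L
  ch <- as.character(n)
  assign(ch, value, envir = tp$val)
  if (!is.null(parents)) assign(ch, parents, envir = tp$par)
  if (!is.null(vjp)) assign(ch, vjp, envir = tp$vjp)
  tp$n <- n
  n
}

tp_v <- function(tp, id) tp$val[[as.character(id)]]

# Reverse sweep from node `id` (typically a scalar loss).  Returns the list
# of accumulated gradients indexed by node id (NULL where no gradient flows).
tp_backward <- function(tp, id, seed = NULL) {
  g <- vector("list", tp$n)
  if (is.null(seed)) {
    v <- tp_v(tp, id)
    seed <- if (length(v) == 1L) 1 else array(1, dim(v))
  }
  g[[id]] <- seed
  vjps <- tp$vjp
  pars <- tp$par
  for (i in seq.int(id, 1L)) {
    gi <- g[[i]]
    if (is.null(gi)) next
    ch <- as.character(i)
    f <- vjps[[ch]]
    if (is.null(f)) next
    pg <- f(gi)
    ps <- pars[[ch]]
    for (k in seq_along(ps)) {
      gp <- pg[[k]]
      if (is.null(gp)) next
      p <- ps[[k]]
      g[[p]] <- if (is.null(g[[p]])) gp else g[[p]] + gp
    }
  }
  g
}

# --- leaf / constant --------------------------------------------------------

op_leaf <- function(tp, value) tp_push(tp, value)

# --- elementwise ------------------------------------------------------------

op_relu <- function(tp, a) {
  force(a)
  va <- tp_v(tp, a)
  v <- va * (va > 0)
  tp_push(tp, v, a, function(g) list(g * (va > 0)))
}

# leaky variant: keeps a small negative-side slope so units cannot die
op_lrelu <- function(tp, a, alpha = 0.1) {
  force(a)
  va <- tp_v(tp, a)
  m <- (va > 0) + alpha * (va <= 0)
  tp_push(tp, va * m, a, function(g) list(g * m))
}

op_tanh <- function(tp, a) {
  force(a)
  v <- tanh(tp_v(tp, a))
  tp_push(tp, v, a, function(g) list(g * (1 - v * v)))
}

op_sigmoid <- function(tp, a) {
  force(a)
  v <- 1 / (1 + exp(-tp_v(tp, a)))
  tp_push(tp, v, a, function(g) list(g * v * (1 - v)))
}

op_add <- function(tp, a, b) {
  force(a); force(b)
  tp_push(tp, tp_v(tp, a) + tp_v(tp, b), c(a, b), function(g) list(g, g))
}

op_sub <- function(tp, a, b) {
  force(a); force(b)
  tp_push(tp, tp_v(tp, a) - tp_v(tp, b), c(a, b), function(g) list(g, -g))
}

op_ewmul <- function(tp, a, b) {
  force(a); force(b)
  va <- tp_v(tp, a); vb <- tp_v(tp, b)
  tp_push(tp, va * vb, c(a, b), function(g) list(g * vb, g * va))
}

# alpha * a + beta (scalars are constants, not differentiated through)
op_affine <- function(tp, a, alpha = 1, beta = 0) {
  force(a)
  tp_push(tp, alpha * tp_v(tp, a) + beta, a, function(g) list(alpha * g))
}

# sum_i coeffs[i] * ids[i]; the workhorse of the ODE solver stages
op_lincomb <- function(tp, ids, coeffs) {
  force(ids); force(coeffs)
  v <- coeffs[1] * tp_v(tp, ids[1])
  if (length(ids) > 1L)
    for (k in 2:length(ids)) v <- v + coeffs[k] * tp_v(tp, ids[k])
  tp_push(tp, v, ids, function(g) lapply(coeffs, function(cc) cc * g))
}

# --- structural -------------------------------------------------------------

op_concat_c <- function(tp, a, b) {
  force(a); force(b)
  va <- tp_v(tp, a); vb <- tp_v(tp, b)
  da <- dim(va); db <- dim(vb)
  stopifnot(da[1] == db[1], da[2] == db[2])
  v <- array(c(va, vb), c(da[1], da[2], da[3] + db[3]))
  ca <- da[3]
  tp_push(tp, v, c(a, b), function(g) {
    list(g[, , seq_len(ca), drop = FALSE],
         g[, , ca + seq_len(dim(g)[3] - ca), drop = FALSE])
  })
}

# --- spatial (Rcpp-backed) --------------------------------------------------

op_conv <- function(tp, x, w, b, k = 3L) {
  force(x); force(w); force(b)
  vx <- tp_v(tp, x); vw <- tp_v(tp, w); vb <- tp_v(tp, b)
  v <- cpp_conv2d_fwd(vx, vw, vb, k)
  tp_push(tp, v, c(x, w, b), function(g) {
    r <- cpp_conv2d_bwd(vx, vw, g, k)
    list(r$gx, r$gw, as.numeric(r$gb))
  })
}

op_maxpool2 <- function(tp, a) {
  force(a)
  r <- cpp_maxpool2(tp_v(tp, a))
  idx <- r$idx
  tp_push(tp, r$out, a, function(g) list(cpp_maxpool2_bwd(g, idx)))
}

op_upsample2 <- function(tp, a) {
  force(a)
  tp_push(tp, cpp_upsample2(tp_v(tp, a)), a,
          function(g) list(cpp_upsample2_bwd(g)))
}

# --- losses -----------------------------------------------------------------

op_mse <- function(tp, pred, target) {
  force(pred)
  vp <- tp_v(tp, pred)
  d <- vp - target
  n <- length(d)
  tp_push(tp, sum(d * d) / n, pred, function(g) list(g * 2 * d / n))
}

# channelwise softmax over the 3rd dimension
op_softmax_c <- function(tp, a) {
  force(a)
  va <- tp_v(tp, a)
  m <- apply(va, c(1, 2), max)
  e <- exp(va - as.vector(m))
  s <- apply(e, c(1, 2), sum)
  v <- e / as.vector(s)
  tp_push(tp, v, a, function(g) {
    dot <- apply(g * v, c(1, 2), sum)
    list(v * (g - as.vector(dot)))
  })
}

# mean cross-entropy of softmax probabilities against integer labels
# (labels in 0..C-1, array HxW); probs must come from op_softmax_c
op_ce_from_probs <- function(tp, probs, labels) {
  force(probs)
  vp <- tp_v(tp, probs)
  d <- dim(vp)
  npix <- d[1] * d[2]
  onehot <- array(0, d)
  idx <- cbind(as.vector(row(labels)), as.vector(col(labels)),
               as.vector(labels) + 1L)
  onehot[idx] <- 1
  p_true <- pmax(vp[idx], 1e-12)
  v <- -sum(log(p_true)) / npix
  tp_push(tp, v, probs, function(g) list(g * (-onehot / pmax(vp, 1e-12)) / npix))
}

# soft multi-class Dice loss: 1 - mean over foreground classes present in
# either the target or with predicted mass, of (2*sum(p*y)+delta)/(sum(p)+sum(y)+delta)
op_soft_dice <- function(tp, probs, labels, delta = 1) {
  force(probs)
  vp <- tp_v(tp, probs)
  d <- dim(vp)
  nc <- d[3]
  onehot <- array(0, d)
  idx <- cbind(as.vector(row(labels)), as.vector(col(labels)),
               as.vector(labels) + 1L)
  onehot[idx] <- 1
  cls <- 2:nc  # foreground classes (class 0 = background excluded)
  num <- den <- dice <- numeric(nc)
  for (c in cls) {
    num[c] <- 2 * sum(vp[, , c] * onehot[, , c]) + delta
    den[c] <- sum(vp[, , c]) + sum(onehot[, , c]) + delta
    dice[c] <- num[c] / den[c]
  }
  m <- length(cls)
  v <- 1 - sum(dice[cls]) / m
  tp_push(tp, v, probs, function(g) {
    gp <- array(0, d)
    for (c in cls)
      gp[, , c] <- -g / m * (2 * onehot[, , c] - dice[c]) / den[c]
    list(gp)
  })
}

# weighted mean binary cross-entropy on logits (numerically stable).
# pos_weight > 0 counteracts the extreme background/keypoint imbalance of
# heatmap targets: per-pixel weight w = 1 + pos_weight * target.
op_bce_logits <- function(tp, logits, target, pos_weight = 0) {
  force(logits)
  vx <- tp_v(tp, logits)
  w <- 1 + pos_weight * target
  n <- sum(w)
  p <- 1 / (1 + exp(-vx))
  v <- sum(w * (pmax(vx, 0) - vx * target + log1p(exp(-abs(vx))))) / n
  tp_push(tp, v, logits, function(g) list(g * w * (p - target) / n))
}

# scalar combination: sum_i coeffs[i] * scalar_ids[i]
op_scalar_lincomb <- function(tp, ids, coeffs) {
  force(ids); force(coeffs)
  v <- sum(vapply(seq_along(ids),
                  function(k) coeffs[k] * tp_v(tp, ids[k]), 0))
  tp_push(tp, v, ids, function(g) as.list(g * coeffs))
}
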