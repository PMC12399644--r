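# ---------------------------------------------------------------------------
# Continuous-time machinery: adaptive Dormand-Prince 4(5) integration with
# dense output, the ConvGRU cell, the dynamics-conditioned derivative
# networks, and the backward-in-time latent-ODE encoder.
#
# Everything runs on the autodiff tape, so gradients flow through every
# accepted solver step (discretise-then-optimise); rejected steps stay on the
# tape but never receive gradients.
# ---------------------------------------------------------------------------

#' ODE solver configuration
#'
#' @param method Only `"dopri5"` (adaptive Dormand-Prince 4(5)) is provided.
#' @param rtol,atol Relative/absolute local error tolerances (> 0).
#' @param epsilon Time offset used to seed the backward latent-ODE encoder:
#'   the zero hidden state is placed at `t_n + epsilon` and integrated down
#'   to `t_n` before the first ConvGRU update.  Default 0.01.
#' @param max_steps Hard cap on accepted + rejected solver steps.
#' @return An object of class `ode_solve_config`.
#' @export
ode_solve_config <- function(method = "dopri5", rtol = 1e-4, atol = 1e-4,
                             epsilon = 0.01, max_steps = 10000L) {
  stopifnot(identical(method, "dopri5"), rtol > 0, atol > 0, epsilon > 0)
  structure(list(method = method, rtol = rtol, atol = atol,
                 epsilon = epsilon, max_steps = as.integer(max_steps)),
            class = "ode_solve_config")
}

# Dormand-Prince 4(5) tableau
.dp <- list(
  c = c(0, 1/5, 3/10, 4/5, 8/9, 1, 1),
  a = list(
    c(1/5),
    c(3/40, 9/40),
    c(44/45, -56/15, 32/9),
    c(19372/6561, -25360/2187, 64448/6561, -212/729),
    c(9017/3168, -355/33, 46732/5247, 49/176, -5103/18656),
    c(35/384, 0, 500/1113, 125/192, -2187/6784, 11/84)),
  e = c(71/57600, 0, -71/16695, 71/1920, -17253/339200, 22/525, -1/40),
  d = c(-12715105075/11282082432, 0, 87487479700/32700410799,
        -10690763975/1880347072, 701980252875/199316789632,
        -1453857185/822651844, 69997945/29380423))

# Dense-output interpolant within one accepted step [t, t+h]:
# a linear combination of y0, y1 and the stage derivatives k1, k3..k7.
.dense_coeffs <- function(theta, h) {
  A <- theta
  B <- theta * (1 - theta)
  C <- theta^2 * (1 - theta)
  E <- theta^2 * (1 - theta)^2
  d <- .dp$d
  w01 <- A - B + 2 * C          # weight of (y1 - y0) reassembled below
  c(y0 = 1 - w01,
    y1 = w01,
    k1 = h * (B - C + E * d[1]),
    k3 = h * E * d[3],
    k4 = h * E * d[4],
    k5 = h * E * d[5],
    k6 = h * E * d[6],
    k7 = h * (-C + E * d[7]))
}

#' Integrate a latent ODE and read out states at target times
#'
#' Performs a single adaptive Dormand-Prince 4(5) solve from `t0` and returns
#' the state at every requested target time via the solver's dense-output
#' interpolation (no restarts).  Backward integration (`t0` greater than the
#' targets) is supported with a negative step.  All arithmetic is recorded on
#' the tape so that the result is differentiable.
#'
#' @param tp autodiff tape
#' @param f derivative function: `f(tp, y_id) -> id` (autonomous)
#' @param y0 tape id of the initial state at time `t0`
#' @param t0 initial time
#' @param targets sorted target times (all on one side of `t0`, or equal)
#' @param cfg an [ode_solve_config()]
#' @return integer vector of tape ids, one state per target
#' @keywords internal
ode_integrate <- function(tp, f, y0, t0, targets, cfg = ode_solve_config()) {
  stopifnot(length(targets) >= 1L)
  out <- integer(length(targets))
  span <- targets[length(targets)] - t0
  if (all(abs(targets - t0) < 1e-14)) {
    out[] <- y0
    return(out)
  }
  dirn <- sign(span)
  if (dirn > 0) stopifnot(all(diff(targets) >= 0), targets[1] >= t0 - 1e-14)
  else stopifnot(all(diff(targets) <= 0), targets[1] <= t0 + 1e-14)

  nxt <- 1L
  # targets exactly at t0 are emitted as y0 itself
  while (nxt <= length(targets) && abs(targets[nxt] - t0) < 1e-14) {
    out[nxt] <- y0
    nxt <- nxt + 1L
  }

  t <- t0
  y <- y0
  t_end <- targets[length(targets)]
  h <- dirn * min(abs(span), 0.1)
  k1 <- f(tp, y)
  nstep <- 0L
  rtol <- cfg$rtol; atol <- cfg$atol
  a <- .dp$a; e <- .dp$e

  while (nxt <= length(targets)) {
    nstep <- nstep + 1L
    if (nstep > cfg$max_steps)
      stop(sprintf("ode integration failure: step limit reached at t = %g", t))
    if (abs(h) < 1e-12)
      stop(sprintf("ode integration failure: step underflow at t = %g", t))
    if (dirn * (t + h) > dirn * t_end) h <- t_end - t

    y2 <- op_lincomb(tp, c(y, k1), c(1, h * a[[1]][1]))
    k2 <- f(tp, y2)
    y3 <- op_lincomb(tp, c(y, k1, k2), c(1, h * a[[2]]))
    k3 <- f(tp, y3)
    y4 <- op_lincomb(tp, c(y, k1, k2, k3), c(1, h * a[[3]]))
    k4 <- f(tp, y4)
    y5 <- op_lincomb(tp, c(y, k1, k2, k3, k4), c(1, h * a[[4]]))
    k5 <- f(tp, y5)
    y6 <- op_lincomb(tp, c(y, k1, k2, k3, k4, k5), c(1, h * a[[5]]))
    k6 <- f(tp, y6)
    y1 <- op_lincomb(tp, c(y, k1, k2, k3, k4, k5, k6), c(1, h * a[[6]]))
    k7 <- f(tp, y1)

    ks <- c(k1, k2, k3, k4, k5, k6, k7)
    err <- h * (e[1] * tp_v(tp, k1) + e[3] * tp_v(tp, k3) +
                e[4] * tp_v(tp, k4) + e[5] * tp_v(tp, k5) +
                e[6] * tp_v(tp, k6) + e[7] * tp_v(tp, k7))
    sc <- atol + rtol * pmax(abs(tp_v(tp, y)), abs(tp_v(tp, y1)))
    en <- sqrt(mean((err / sc)^2))

    if (en <= 1) {  # accept
      t_new <- t + h
      while (nxt <= length(targets) &&
             dirn * targets[nxt] <= dirn * t_new + 1e-14) {
        theta <- (targets[nxt] - t) / h
        theta <- min(max(theta, 0), 1)
        co <- .dense_coeffs(theta, h)
        out[nxt] <- op_lincomb(
          tp, c(y, y1, ks[1], ks[3], ks[4], ks[5], ks[6], ks[7]), co)
        nxt <- nxt + 1L
      }
      y <- y1
      k1 <- k7  # FSAL
      t <- t_new
      fac <- if (en == 0) 5 else min(5, max(0.2, 0.9 * en^(-0.2)))
      h <- h * fac
      if (dirn * (t + h) > dirn * t_end && abs(t_end - t) > 0)
        h <- t_end - t
    } else {      # reject
      h <- h * max(0.2, 0.9 * en^(-0.2))
    }
  }
  out
}

# ---------------------------------------------------------------------------
# ConvGRU cell: standard convolutional gating.
#   z = sigmoid(conv([h, x]));  r = sigmoid(conv([h, x]))
#   htilde = tanh(conv([r*h, x]));  h' = (1 - z)*h + z*htilde
# ---------------------------------------------------------------------------
conv_gru_update <- function(tp, h, x, pid, prefix = "gru") {
  dh <- dim(tp_v(tp, h)); dx <- dim(tp_v(tp, x))
  if (dh[1] != dx[1] || dh[2] != dx[2])
    stop("conv_gru_update: spatial shape mismatch")
  hx <- op_concat_c(tp, h, x)
  z <- op_sigmoid(tp, op_conv(tp, hx, pid[[paste0(prefix, ".z.w")]],
                              pid[[paste0(prefix, ".z.b")]]))
  r <- op_sigmoid(tp, op_conv(tp, hx, pid[[paste0(prefix, ".r.w")]],
                              pid[[paste0(prefix, ".r.b")]]))
  rh <- op_ewmul(tp, r, h)
  rhx <- op_concat_c(tp, rh, x)
  cand <- op_tanh(tp, op_conv(tp, rhx, pid[[paste0(prefix, ".h.w")]],
                              pid[[paste0(prefix, ".h.b")]]))
  # h' = h + z * (cand - h)  ==  (1-z)*h + z*cand
  op_add(tp, h, op_ewmul(tp, z, op_sub(tp, cand, h)))
}

# Three-convolution derivative network.  The decoder-side derivative
# concatenates the hidden state with the per-clip dynamics code D before the
# first convolution; the encoder-side derivative sees the state only (D does
# not exist yet while encoding).  tanh between layers, linear final layer.
make_derivative_fn <- function(pid, prefix, D = NULL) {
  force(D)
  function(tp, y) {
    inp <- if (is.null(D)) y else op_concat_c(tp, y, D)
    a1 <- op_tanh(tp, op_conv(tp, inp, pid[[paste0(prefix, ".c1.w")]],
                              pid[[paste0(prefix, ".c1.b")]]))
    a2 <- op_tanh(tp, op_conv(tp, a1, pid[[paste0(prefix, ".c2.w")]],
                              pid[[paste0(prefix, ".c2.b")]]))
    op_conv(tp, a2, pid[[paste0(prefix, ".c3.w")]],
            pid[[paste0(prefix, ".c3.b")]])
  }
}

# ---------------------------------------------------------------------------
# Backward latent-ODE encoder (ODE-RNN).  Starting from a zero hidden state
# placed at t_n + epsilon, integrate the encoder derivative down to t_n and
# apply a ConvGRU update with the last frame's features; then recurse down to
# the first frame.  D is the hidden state after the earliest-frame update;
# the initial decoder state h_s0 is one convolution applied to D.
# ---------------------------------------------------------------------------
latent_ode_encode <- function(tp, feat_ids, tau, pid, cfg) {
  n <- length(feat_ids)
  if (n < 1L) stop("latent_ode_encode: empty input")
  stopifnot(length(tau) == n)
  f_enc <- make_derivative_fn(pid, "fenc")
  d0 <- dim(tp_v(tp, feat_ids[[n]]))
  h <- op_leaf(tp, array(0, d0))
  h <- ode_integrate(tp, f_enc, h, tau[n] + cfg$epsilon, tau[n], cfg)
  h <- h[length(h)]
  h <- conv_gru_update(tp, h, feat_ids[[n]], pid)
  if (n > 1L) {
    for (i in seq.int(n - 1L, 1L)) {
      hm <- ode_integrate(tp, f_enc, h, tau[i + 1L], tau[i], cfg)
      h <- conv_gru_update(tp, hm[length(hm)], feat_ids[[i]], pid)
    }
  }
  D <- h
  hs0 <- op_conv(tp, D, pid[["init.w"]], pid[["init.b"]])
  list(D = D, hs0 = hs0)
}
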