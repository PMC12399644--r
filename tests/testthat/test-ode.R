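# ode_core: solver correctness against closed forms and independent oracles,
# ConvGRU gating, derivative-network structure, encoder recursion.

scalar_grid <- function(x) array(x, c(1, 1, 1))

test_that("zero derivative returns the initial state at every target", {
  tp <- echode:::tape_new()
  y0 <- echode:::op_leaf(tp, array(c(1, -2, 3, 4), c(2, 2, 1)))
  f0 <- function(tp, y) echode:::op_affine(tp, y, 0)
  ids <- echode:::ode_integrate(tp, f0, y0, 0, c(0.3, 0.7, 1))
  for (id in ids)
    expect_equal(echode:::tp_v(tp, id), echode:::tp_v(tp, y0))
})

test_that("linear decay integrates to exp(-t) within rtol (RK4 oracle)", {
  cfg <- ode_solve_config(rtol = 1e-4, atol = 1e-4)
  tp <- echode:::tape_new()
  y0 <- echode:::op_leaf(tp, scalar_grid(1))
  f <- function(tp, y) echode:::op_affine(tp, y, -1)
  ids <- echode:::ode_integrate(tp, f, y0, 0, 1, cfg)
  got <- as.numeric(echode:::tp_v(tp, ids[1]))
  expect_equal(got, exp(-1), tolerance = cfg$rtol)
  oracle <- rk4_scalar(function(y) -y, 1, 0, 1)
  expect_equal(got, oracle, tolerance = cfg$rtol)
})

test_that("dense outputs agree with chained restarted solves within 10*rtol", {
  cfg <- ode_solve_config()
  targets <- c(0.25, 0.5, 0.75, 1)
  tp <- echode:::tape_new()
  y0 <- echode:::op_leaf(tp, scalar_grid(1))
  f <- function(tp, y) echode:::op_affine(tp, y, -1)
  dense <- sapply(echode:::ode_integrate(tp, f, y0, 0, targets, cfg),
                  function(id) as.numeric(echode:::tp_v(tp, id)))
  chain <- numeric(4)
  y <- y0; t <- 0
  for (i in seq_along(targets)) {
    id <- echode:::ode_integrate(tp, f, y, t, targets[i], cfg)
    chain[i] <- as.numeric(echode:::tp_v(tp, id[1]))
    y <- id[1]; t <- targets[i]
  }
  expect_equal(dense, chain, tolerance = 10 * cfg$rtol)
  expect_equal(dense, exp(-targets), tolerance = 10 * cfg$rtol)
})

test_that("semigroup and backward/forward consistency hold for linear decay", {
  cfg <- ode_solve_config()
  tp <- echode:::tape_new()
  y0 <- echode:::op_leaf(tp, scalar_grid(2))
  f <- function(tp, y) echode:::op_affine(tp, y, -1)
  direct <- echode:::ode_integrate(tp, f, y0, 0, 0.9, cfg)
  mid <- echode:::ode_integrate(tp, f, y0, 0, 0.4, cfg)
  two <- echode:::ode_integrate(tp, f, mid[1], 0.4, 0.9, cfg)
  expect_equal(as.numeric(echode:::tp_v(tp, direct[1])),
               as.numeric(echode:::tp_v(tp, two[1])),
               tolerance = 10 * cfg$rtol)
  # backward then forward returns the start
  back <- echode:::ode_integrate(tp, f, y0, 1, 0, cfg)
  forth <- echode:::ode_integrate(tp, f, back[1], 0, 1, cfg)
  expect_equal(as.numeric(echode:::tp_v(tp, forth[1])), 2,
               tolerance = 10 * cfg$rtol)
})

test_that("integration emits the initial state when t0 is a target", {
  tp <- echode:::tape_new()
  y0 <- echode:::op_leaf(tp, scalar_grid(5))
  f <- function(tp, y) echode:::op_affine(tp, y, -1)
  ids <- echode:::ode_integrate(tp, f, y0, 0, c(0, 0.5))
  expect_identical(ids[1], y0)
})

test_that("step-limit violations raise an integration failure", {
  cfg <- ode_solve_config(max_steps = 2L)
  tp <- echode:::tape_new()
  y0 <- echode:::op_leaf(tp, scalar_grid(1))
  stiff <- function(tp, y) echode:::op_affine(tp, y, -5000)
  expect_error(echode:::ode_integrate(tp, stiff, y0, 0, 1, cfg),
               "integration failure")
})

test_that("ConvGRU respects gate limits and convex-combination bounds", {
  set.seed(42)
  m <- echode_model(n_classes = 4, width_scale = 16, seed = 1)
  C <- m$widths[4]
  p <- m$params
  mk <- function(p) {
    tp <- echode:::tape_new()
    pid <- echode:::.push_params(tp, p)
    h <- echode:::op_leaf(tp, array(rnorm(16 * C), c(4, 4, C)))
    x <- echode:::op_leaf(tp, array(rnorm(16 * C), c(4, 4, C)))
    new_h <- echode:::conv_gru_update(tp, h, x, pid)
    list(h = echode:::tp_v(tp, h), x = echode:::tp_v(tp, x),
         out = echode:::tp_v(tp, new_h), tp = tp, pid = pid, hid = h,
         xid = x)
  }
  # z -> 0 (huge negative bias): h' = h
  p0 <- p; p0[["gru.z.b"]] <- rep(-50, C)
  r0 <- mk(p0)
  expect_equal(r0$out, r0$h, tolerance = 1e-12)
  # z -> 1 (huge positive bias): h' = candidate = tanh(conv([r*h, x]))
  p1 <- p; p1[["gru.z.b"]] <- rep(50, C)
  r1 <- mk(p1)
  expect_true(all(r1$out >= -1 - 1e-12 & r1$out <= 1 + 1e-12))
  # generic weights: output elementwise between h and the candidate
  r <- mk(p)
  tp <- echode:::tape_new()
  pid <- echode:::.push_params(tp, p)
  hid <- echode:::op_leaf(tp, r$h)
  xid <- echode:::op_leaf(tp, r$x)
  hx <- echode:::op_concat_c(tp, hid, xid)
  rgate <- echode:::op_sigmoid(tp, echode:::op_conv(tp, hx, pid[["gru.r.w"]],
                                                    pid[["gru.r.b"]]))
  rh <- echode:::op_ewmul(tp, rgate, hid)
  rhx <- echode:::op_concat_c(tp, rh, xid)
  cand <- echode:::tp_v(tp, echode:::op_tanh(
    tp, echode:::op_conv(tp, rhx, pid[["gru.h.w"]], pid[["gru.h.b"]])))
  lo <- pmin(r$h, cand); hi <- pmax(r$h, cand)
  expect_true(all(r$out >= lo - 1e-9 & r$out <= hi + 1e-9))
})

test_that("derivative network equals a layer-by-layer dense oracle", {
  set.seed(7)
  m <- echode_model(n_classes = 4, width_scale = 16, seed = 5)
  C <- m$widths[4]
  tp <- echode:::tape_new()
  pid <- echode:::.push_params(tp, m$params)
  h <- array(rnorm(16 * C), c(4, 4, C))
  D <- array(rnorm(16 * C), c(4, 4, C))
  hid <- echode:::op_leaf(tp, h)
  Did <- echode:::op_leaf(tp, D)
  f <- echode:::make_derivative_fn(pid, "fdec", D = Did)
  got <- echode:::tp_v(tp, f(tp, hid))
  # oracle: direct conv / tanh / conv / tanh / conv on the concatenation
  p <- m$params
  a1 <- tanh(echode:::cpp_conv2d_fwd(array(c(h, D), c(4, 4, 2 * C)),
                                     p[["fdec.c1.w"]], p[["fdec.c1.b"]], 3L))
  a2 <- tanh(echode:::cpp_conv2d_fwd(a1, p[["fdec.c2.w"]],
                                     p[["fdec.c2.b"]], 3L))
  oracle <- echode:::cpp_conv2d_fwd(a2, p[["fdec.c3.w"]],
                                    p[["fdec.c3.b"]], 3L)
  expect_equal(got, oracle, tolerance = 1e-12)
  expect_equal(dim(got), dim(h))
  # pure function: same inputs, same output
  expect_equal(echode:::tp_v(tp, f(tp, hid)), got, tolerance = 1e-15)
  # zero weights give a zero derivative field
  pz <- m$params
  for (nm in grep("^fdec", names(pz), value = TRUE)) pz[[nm]][] <- 0
  tpz <- echode:::tape_new()
  pidz <- echode:::.push_params(tpz, pz)
  fz <- echode:::make_derivative_fn(pidz, "fdec",
                                    D = echode:::op_leaf(tpz, D))
  expect_true(all(echode:::tp_v(tpz, fz(tpz, echode:::op_leaf(tpz, h))) == 0))
})

test_that("latent encoder is deterministic and well-defined for n = 1", {
  set.seed(1)
  m <- echode_model(n_classes = 4, width_scale = 16, seed = 2)
  cfg <- m$solver
  C <- m$widths[4]
  feats <- lapply(1:3, function(i) array(rnorm(4 * C), c(2, 2, C)))
  run <- function() {
    tp <- echode:::tape_new()
    pid <- echode:::.push_params(tp, m$params)
    ids <- lapply(feats, function(f) echode:::op_leaf(tp, f))
    enc <- echode:::latent_ode_encode(tp, ids, c(0, 0.5, 1), pid, cfg)
    list(D = echode:::tp_v(tp, enc$D), h = echode:::tp_v(tp, enc$hs0))
  }
  a <- run(); b <- run()
  expect_identical(a$D, b$D)       # bitwise reproducible
  expect_identical(a$h, b$h)
  # single frame: recursion degenerates but stays well-defined
  tp <- echode:::tape_new()
  pid <- echode:::.push_params(tp, m$params)
  enc1 <- echode:::latent_ode_encode(
    tp, list(echode:::op_leaf(tp, feats[[1]])), 1, pid, cfg)
  expect_true(all(is.finite(echode:::tp_v(tp, enc1$D))))
  expect_error(echode:::latent_ode_encode(tp, list(), numeric(0), pid, cfg),
               "empty")
})

test_that("encoder dynamics are invariant to affine time shifts", {
  # the derivative nets are autonomous, so shifting all input times by a
  # constant (same node spacing) must leave D unchanged
  set.seed(3)
  m <- echode_model(n_classes = 4, width_scale = 16, seed = 4)
  C <- m$widths[4]
  feats <- lapply(1:3, function(i) array(rnorm(4 * C), c(2, 2, C)))
  encode_at <- function(tau) {
    tp <- echode:::tape_new()
    pid <- echode:::.push_params(tp, m$params)
    ids <- lapply(feats, function(f) echode:::op_leaf(tp, f))
    echode:::tp_v(tp, echode:::latent_ode_encode(tp, ids, tau, pid,
                                                 m$solver)$D)
  }
  expect_equal(encode_at(c(0, 0.3, 0.6)), encode_at(c(0.4, 0.7, 1.0)),
               tolerance = 1e-8)
})

test_that("loss gradients reach the derivative-network weights", {
  set.seed(11)
  ph <- tiny_phantom()
  rec <- sample_clip(ph$video, ph$annotation, annotated_frame = 15)
  m <- echode_model(n_classes = 7, width_scale = 8, seed = 6)
  lg <- echode:::echode_clip_loss(m, rec, 10)
  g <- echode:::tp_backward(lg$tape, lg$loss)
  for (nm in c("fdec.c1.w", "fdec.c3.w", "fenc.c1.w", "fenc.c3.w")) {
    gi <- g[[lg$pid[[nm]]]]
    expect_true(all(is.finite(gi)), info = nm)
    expect_gt(sum(abs(gi)), 0)
  }
})
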