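# networks: encoder/decoder shape contracts, weight sharing, output-count
# law, skip ablation, continuity of dense outputs, permutation sensitivity.

test_that("encoder bottleneck sits at 1/8 resolution with stage-4 channels", {
  m <- echode_model(n_classes = 7, width_scale = 1, seed = 1)
  img <- array(stats::runif(64 * 64 * 3), c(64, 64, 3))
  e <- encode(m, img)
  expect_equal(dim(e$bottleneck), c(8, 8, 256))
  m4 <- echode_model(n_classes = 7, width_scale = 4, seed = 1)
  e4 <- encode(m4, array(stats::runif(32 * 32 * 3), c(32, 32, 3)))
  expect_equal(dim(e4$bottleneck), c(4, 4, 64))
  expect_error(encode(m4, array(0, c(30, 30, 3))), "divisible")
})

test_that("encoder weights are shared across frames", {
  m <- echode_model(n_classes = 7, width_scale = 8, seed = 2)
  img <- array(stats::runif(32 * 32 * 3), c(32, 32, 3))
  expect_identical(encode(m, img)$bottleneck, encode(m, img)$bottleneck)
})

test_that("reconstruction decoder restores input resolution with 3 channels", {
  m <- echode_model(n_classes = 7, width_scale = 8, seed = 3)
  tp <- echode:::tape_new()
  pid <- echode:::.push_params(tp, m$params)
  h <- echode:::op_leaf(tp, array(stats::rnorm(8 * 8 * m$widths[4]),
                                  c(8, 8, m$widths[4])))
  r <- echode:::decode_reconstruction_t(tp, h, pid)
  expect_equal(dim(echode:::tp_v(tp, r$out)), c(64, 64, 3))
  # stage features at 1/4, 1/2 and full resolution
  expect_equal(dim(echode:::tp_v(tp, r$feats[[1]]))[1:2], c(16, 16))
  expect_equal(dim(echode:::tp_v(tp, r$feats[[2]]))[1:2], c(32, 32))
  expect_equal(dim(echode:::tp_v(tp, r$feats[[3]]))[1:2], c(64, 64))
  # zero weights: constant bias image
  pz <- m$params
  for (nm in grep("^rec", names(pz), value = TRUE)) pz[[nm]][] <- 0
  tpz <- echode:::tape_new()
  pidz <- echode:::.push_params(tpz, pz)
  rz <- echode:::decode_reconstruction_t(
    tpz, echode:::op_leaf(tpz, array(1, c(8, 8, m$widths[4]))), pidz)
  expect_equal(max(abs(echode:::tp_v(tpz, rz$out))), 0)
})

test_that("target decoder emits per-pixel probability simplexes", {
  m <- echode_model(n_classes = 7, width_scale = 8, seed = 4)
  ph <- tiny_phantom()
  rec <- sample_clip(ph$video, ph$annotation, annotated_frame = 15)
  out <- echo_ode_forward(m, rec$frames, rec$tau, rec$S)
  expect_equal(dim(out$probs), c(32, 32, 7, 7))
  sums <- apply(out$probs[, , , 1], c(1, 2), sum)
  expect_true(all(abs(sums - 1) < 1e-5))
  expect_true(all(out$labels >= 0 & out$labels <= 6))
})

test_that("standalone decoders reproduce the forward pass pieces", {
  m <- echode_model(n_classes = 7, width_scale = 8, seed = 21)
  h <- array(stats::rnorm(4 * 4 * m$widths[4]), c(4, 4, m$widths[4]))
  r <- decode_reconstruction(m, h)
  expect_equal(dim(r$image), c(32, 32, 3))
  t1 <- decode_target(m, h, r$feats)
  expect_equal(dim(t1$probs), c(32, 32, 7))
  expect_error(decode_target(m, h, NULL), "skip")
  mm <- echode_model(n_classes = 7, width_scale = 8, mode = "measurement",
                     seed = 22)
  t2 <- decode_target(mm, h, decode_reconstruction(mm, h)$feats)
  expect_equal(dim(t2$heatmaps), c(32, 32, 6))
  expect_true(all(t2$heatmaps >= 0 & t2$heatmaps <= 1))
})

test_that("skip-disabled (ablation) config produces the same output shapes", {
  m <- echode_model(n_classes = 7, width_scale = 8, skips = FALSE, seed = 5)
  ph <- tiny_phantom()
  rec <- sample_clip(ph$video, ph$annotation, annotated_frame = 15)
  out <- echo_ode_forward(m, rec$frames, rec$tau, rec$S)
  expect_equal(dim(out$probs), c(32, 32, 7, 7))
  expect_equal(dim(out$recon), c(32, 32, 3, 7))
})

test_that("output-count law: |outputs| = |S| for any |tau| >= 1", {
  m <- echode_model(n_classes = 4, width_scale = 8, seed = 6)
  ph <- tiny_phantom(n_classes = 4)
  fr <- ph$video$frames
  for (cfgs in list(list(tau = 0.5, idx = 3, S = c(0, 0.5, 1)),
                    list(tau = c(0, 1), idx = c(1, 5),
                         S = seq(0, 1, by = 0.25)),
                    list(tau = c(0, 1/3, 2/3, 1), idx = c(1, 3, 5, 7),
                         S = (0:6) / 6))) {
    out <- echo_ode_forward(m, fr[, , cfgs$idx, drop = FALSE], cfgs$tau,
                            cfgs$S)
    expect_equal(dim(out$probs)[4], length(cfgs$S))
    expect_equal(dim(out$recon)[4], length(cfgs$S))
  }
  # S strictly between input nodes works under the same contract
  out <- echo_ode_forward(m, fr[, , c(1, 5), drop = FALSE], c(0, 1),
                          c(0.3, 0.6))
  expect_equal(dim(out$probs)[4], 2)
})

test_that("dense outputs vary continuously: midpoints lie near the chord", {
  m <- echode_model(n_classes = 4, width_scale = 8, seed = 7)
  ph <- tiny_phantom(n_classes = 4)
  rec <- sample_clip(ph$video, ph$annotation, annotated_frame = 15)
  S2 <- seq(0, 1, length.out = 9)            # refine x2
  out <- echo_ode_forward(m, rec$frames, rec$tau, S2)
  for (i in seq(2, 8, by = 2)) {
    pl <- out$probs[, , , i - 1]
    pm <- out$probs[, , , i]
    pr <- out$probs[, , , i + 1]
    dev <- mean(abs(pm - (pl + pr) / 2))
    expect_lte(dev, max(0.5 * mean(abs(pr - pl)), 0.02))
  }
})

test_that("shuffling input frames changes the dynamics code D", {
  m <- echode_model(n_classes = 7, width_scale = 8, seed = 8)
  ph <- tiny_phantom()
  rec <- sample_clip(ph$video, ph$annotation, annotated_frame = 15)
  fwd <- echode:::echode_forward_t(m, rec$frames, rec$tau, rec$S)
  shuf <- rec$frames[, , c(3, 1, 4, 2)]
  fwd2 <- echode:::echode_forward_t(m, shuf, rec$tau, rec$S)
  expect_false(isTRUE(all.equal(
    echode:::tp_v(fwd$tape, fwd$D), echode:::tp_v(fwd2$tape, fwd2$D),
    tolerance = 1e-10)))
})

test_that("measurement mode yields 6 sigmoid heatmaps per target time", {
  m <- echode_model(n_classes = 7, width_scale = 8, mode = "measurement",
                    seed = 9)
  ph <- tiny_phantom()
  rec <- sample_clip(ph$video, ph$annotation, annotated_frame = 15)
  out <- echo_ode_forward(m, rec$frames, rec$tau, rec$S)
  expect_equal(dim(out$heatmaps), c(32, 32, 6, 7))
  expect_true(all(out$heatmaps >= 0 & out$heatmaps <= 1))
})

test_that("per-frame baseline maps identical frames to identical outputs", {
  m <- baseline_model(n_classes = 7, width_scale = 8, seed = 10)
  ph <- tiny_phantom()
  img <- ph$video$frames[, , 1]
  a <- baseline_segment(m, img)
  b <- baseline_segment(m, img)
  expect_identical(a$labels, b$labels)
  expect_equal(dim(a$probs), c(32, 32, 7))   # same shape as Echo-ODE output
  labs <- baseline_segment_video(m, ph$video$frames[, , 1:3])
  expect_equal(dim(labs), c(32, 32, 3))
})

test_that("predict_video covers every frame exactly once", {
  m <- echode_model(n_classes = 4, width_scale = 16, seed = 11)
  ph <- tiny_phantom(n_classes = 4, n_frames = 24)
  labs <- predict_video(m, ph$video$frames)
  expect_equal(dim(labs), dim(ph$video$frames))
  expect_true(all(labs >= 0 & labs < 4))
})
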