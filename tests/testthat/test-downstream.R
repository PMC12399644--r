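# downstream: area curves, Savitzky-Golay exactness, phase detection on the
# phantom oracle, matching/MAE rules, heatmap centroids, dimensions.

test_that("lv_area_series counts pixels and scales with spacing", {
  labs <- array(0L, c(8, 8, 3))
  labs[3:5, 3:5, 1] <- 4L
  labs[, , 2] <- 0L
  labs[1:2, 1:2, 3] <- 4L
  a <- lv_area_series(labs, lv_class = 4L)
  expect_equal(as.numeric(a), c(9, 0, 4))
  a2 <- lv_area_series(labs, lv_class = 4L, mm_per_px = 2)
  expect_equal(as.numeric(a2), 4 * as.numeric(a))
})

test_that("Savitzky-Golay reproduces cubics exactly at interior points", {
  t <- 0:49
  y <- 2 + 0.3 * t - 0.02 * t^2 + 0.001 * t^3
  s <- savgol_smooth(y, 13, 3)
  expect_equal(s[7:44], y[7:44], tolerance = 1e-9)
  expect_equal(savgol_smooth(rep(5, 30)), rep(5, 30), tolerance = 1e-12)
})

test_that("Savitzky-Golay reduces interior noise variance (Monte-Carlo)", {
  set.seed(77)
  t <- 0:119
  clean <- 50 + 10 * sin(2 * pi * t / 40)
  noisy <- clean + stats::rnorm(120, 0, 2)
  sm <- savgol_smooth(noisy)
  int <- 7:114
  expect_lt(stats::var((sm - clean)[int]), stats::var((noisy - clean)[int]))
})

test_that("short curves fall back to a smaller width with a warning", {
  y <- stats::rnorm(9)
  expect_warning(s <- savgol_smooth(y, 13, 3), "width")
  expect_length(s, 9)
})

test_that("phase detection recovers the phantom construction exactly", {
  ph <- generate_phantom(phantom_config(image_size = 48, n_frames = 60,
                                        base_period = 20,
                                        speckle_strength = 0))
  ac <- gt_area_curve(ph$annotation)
  ps <- detect_phases(savgol_smooth(ac))
  expect_equal(ps$ed, ph$annotation$ed_frames)
  expect_equal(ps$es, ph$annotation$es_frames)
})

test_that("degenerate curves give empty or trivial phase sets", {
  expect_length(detect_phases(1:50)$ed, 0)     # strictly increasing
  expect_length(detect_phases(1:50)$es, 0)
  tri <- c(0:10, 9:0)                          # single triangle peak at 10
  expect_equal(detect_phases(tri)$ed, 10)
})

test_that("detect_phases on the negated curve swaps ED and ES", {
  ph <- generate_phantom(phantom_config(image_size = 48, n_frames = 60,
                                        base_period = 20,
                                        speckle_strength = 0))
  ac <- savgol_smooth(gt_area_curve(ph$annotation))
  ps <- detect_phases(ac)
  ns <- detect_phases(-as.numeric(ac))
  expect_equal(ns$ed, ps$es)
  expect_equal(ns$es, ps$ed)
})

test_that("phase MAE matching follows the greedy one-to-one window rule", {
  r0 <- phase_mae(c(10, 30), c(10, 30))
  expect_equal(r0$mae, 0)
  expect_equal(r0$n_matched, 2)
  r1 <- phase_mae(c(13, 33), c(10, 30))
  expect_equal(r1$mae, 3)
  r2 <- phase_mae(c(45, 100), 50)
  expect_equal(r2$mae, 5)
  expect_equal(r2$n_matched, 1)
  expect_equal(r2$n_spurious, 1)
  r3 <- phase_mae(integer(0), c(5, 10))
  expect_true(is.na(r3$mae))
  expect_equal(r3$n_missed, 2)
  # outside the 10-frame window nothing matches
  r4 <- phase_mae(100, 50)
  expect_equal(r4$n_matched, 0)
})

test_that("heatmap centroid follows the 0.3-threshold center of gravity", {
  m <- matrix(0, 12, 12)
  m[6, 8] <- 1
  expect_equal(heatmap_to_point(m), c(5, 7))    # 0-based
  # symmetric Gaussian: centroid within 0.1 px of the center (brute-force
  # weighted mean is the definition, so compare against an offset grid)
  g <- outer(0:31, 0:31, function(r, c)
    exp(-((r - 16)^2 + (c - 16)^2) / (2 * 2^2)))
  expect_equal(heatmap_to_point(g), c(16, 16), tolerance = 0.1)
  expect_null(heatmap_to_point(matrix(0.2, 5, 5)))
})

test_that("dimension measurement is Euclidean distance times spacing", {
  expect_equal(measure_dimension(c(0, 0), c(3, 4), 1), 5)
  expect_equal(measure_dimension(c(2, 2), c(2, 2), 1), 0)
  expect_equal(measure_dimension(c(0, 0), c(3, 4), 0.5), 2.5)
  expect_error(measure_dimension(NULL, c(1, 1)), "present")
})

test_that("phantom measurement segments match the analytic wall thickness", {
  ph <- tiny_phantom(image_size = 64, speckle_strength = 0)
  ann <- ph$annotation
  t <- 5
  seg <- ann$segments[[t]]
  g <- echode:::phantom_waveform(ann$phase[t])
  a <- ann$config$pulsation_amplitude
  th_ivs <- 0.050 * 64 * (1 - 0.5 * a * g)
  got <- measure_dimension(seg$IVS$begin, seg$IVS$end, 1)
  expect_equal(got, th_ivs, tolerance = 1e-9)
  lvid <- measure_dimension(seg$LVID$begin, seg$LVID$end, 1)
  expect_equal(lvid, 2 * ann$lv_radii[1] * ann$lv_scale[t], tolerance = 1e-9)
})

test_that("mask jitter keeps phase MAE within 1 frame", {
  # emulate predicted-style masks: erode/dilate the LV by one pixel at random
  set.seed(42)
  ph <- generate_phantom(phantom_config(image_size = 48, n_frames = 60,
                                        base_period = 20,
                                        speckle_strength = 0))
  labs <- ph$annotation$labels
  lv <- ph$annotation$classes[["LV"]]
  n <- dim(labs)[3]
  area <- numeric(n)
  for (t in seq_len(n)) {
    m <- labs[, , t] == lv
    shift <- sample(c(-1L, 0L, 1L), 1)
    if (shift != 0) {  # one-pixel dilate (or erode) along rows
      ms <- m
      if (shift > 0) ms[2:48, ] <- ms[2:48, ] | m[1:47, ]
      else ms <- m & rbind(m[-1, ], FALSE)
      m <- ms
    }
    area[t] <- sum(m)
  }
  ps <- detect_phases(savgol_smooth(area))
  r_ed <- phase_mae(ps$ed, ph$annotation$ed_frames)
  r_es <- phase_mae(ps$es, ph$annotation$es_frames)
  expect_lte(r_ed$mae, 1)
  expect_lte(r_es$mae, 1)
})

test_that("arrhythmia phantom cycle count is recovered for 20% jitter", {
  ph <- generate_phantom(phantom_config(image_size = 48, n_frames = 100,
                                        base_period = 20, arrhythmia = TRUE,
                                        jitter = 0.2, speckle_strength = 0,
                                        seed = 8))
  ac <- savgol_smooth(gt_area_curve(ph$annotation))
  ps <- detect_phases(ac)
  expect_equal(length(ps$ed), length(ph$annotation$ed_frames))
  expect_equal(length(ps$es), length(ph$annotation$es_frames))
})
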