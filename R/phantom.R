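# ---------------------------------------------------------------------------
# Synthetic beating-heart phantom.
#
# A parasternal-long-axis-like scene is built from analytic ellipses and
# elliptical-annulus wall bands that pulsate coherently with a single smooth
# periodic waveform.  Frames are an intensity map multiplied by gamma speckle;
# label maps, ED/ES frame indices, measurement segments and the cycle
# schedule are rendered from the same analytic shapes, so every downstream
# module has exact ground truth.
# ---------------------------------------------------------------------------

#' Phantom configuration
#'
#' @param image_size integer (height = width), divisible by 8.
#' @param n_frames number of frames; must be at least `base_period`.
#' @param base_period frames per cardiac cycle (>= 4).
#' @param pulsation_amplitude `a` in `[0, 0.5)`: the LV semiaxes scale by
#'   `s(t) = 1 + a * g(phase)` where `g` is a mildly asymmetric raised cosine
#'   with one maximum (ED) and one minimum (ES) per cycle.
#' @param n_classes 7 (background, LA, IVS, LVPW, LV, RV, RVAW) or 4
#'   (background, LV, myocardium, LA).
#' @param speckle_strength standard deviation of the multiplicative gamma
#'   speckle (mean 1); 0 disables noise.
#' @param arrhythmia logical; if `TRUE` each cycle's period is drawn as
#'   `base_period * (1 + U(-jitter, jitter))`.
#' @param jitter per-cycle period jitter fraction used in arrhythmia mode.
#' @param geometry_jitter fractional random perturbation of structure centers
#'   and sizes (0 = canonical geometry); used to diversify training sets.
#' @param phase0 initial cardiac phase in `[0, 1)`; the default 0.25 keeps
#'   the first ED/ES events away from the video edges.
#' @param mm_per_px pixel spacing in millimetres.
#' @param seed integer RNG seed; the phantom is bitwise reproducible.
#' @return An object of class `phantom_config`.
#' @export
phantom_config <- function(image_size = 64L, n_frames = 40L,
                           base_period = 20L, pulsation_amplitude = 0.2,
                           n_classes = 7L, speckle_strength = 0.18,
                           arrhythmia = FALSE, jitter = 0.2,
                           geometry_jitter = 0, phase0 = 0.25,
                           mm_per_px = 0.5, seed = 1L) {
  a <- pulsation_amplitude
  if (!(a >= 0 && a < 0.5)) stop("pulsation_amplitude must be in [0, 0.5)")
  if (base_period < 4) stop("base_period must be >= 4 frames")
  if (n_frames < base_period) stop("n_frames must be >= base_period")
  if (!n_classes %in% c(4L, 7L)) stop("n_classes must be 4 or 7")
  if (speckle_strength < 0) stop("speckle_strength must be >= 0")
  structure(list(image_size = as.integer(image_size),
                 n_frames = as.integer(n_frames),
                 base_period = base_period,
                 pulsation_amplitude = a, n_classes = as.integer(n_classes),
                 speckle_strength = speckle_strength,
                 arrhythmia = isTRUE(arrhythmia), jitter = jitter,
                 geometry_jitter = geometry_jitter, phase0 = phase0,
                 mm_per_px = mm_per_px, seed = as.integer(seed)),
            class = "phantom_config")
}

# Cardiac waveform: piecewise raised cosine with systolic fraction fs.
# g(0) = 1 (ED), g(fs) = -1 (ES), period 1, C1-smooth.  fs = 0.45 gives a
# systole mildly faster than diastole while keeping the peak of the
# Savitzky-Golay(13, 3)-smoothed area curve on the constructed ED frame.
.fs_systole <- 0.45

phantom_waveform <- function(phase, fs = .fs_systole) {
  p <- phase %% 1
  ifelse(p < fs, cos(pi * p / fs), cos(pi * (1 - p) / (1 - fs)))
}

# label ids for the 7-class layout
.cls7 <- c(bg = 0L, LA = 1L, IVS = 2L, LVPW = 3L, LV = 4L, RV = 5L, RVAW = 6L)
# 4-class (chamber-view-like) layout: walls merged into one myocardium class
.cls4 <- c(bg = 0L, LV = 1L, MYO = 2L, LA = 3L)

.base_intensity <- c(bg = 0.15, LA = 0.35, IVS = 0.80, LVPW = 0.70,
                     LV = 0.25, RV = 0.30, RVAW = 0.75, MYO = 0.75)

#' Generate a synthetic echo-like video with dense ground truth
#'
#' @param config a [phantom_config()].
#' @return A list with components `video` (class `video_clip`: `frames` array
#'   `h x w x n`, `times` in `[0, 1]`, `mm_per_px`) and `annotation` (class
#'   `phantom_annotation`: `labels` integer array `h x w x n`, `ed_frames`,
#'   `es_frames` (0-based), `segments` per frame, `cycle_schedule`, `phase`
#'   per frame, and the analytic LV semiaxes per frame).
#' @export
generate_phantom <- function(config) {
  stopifnot(inherits(config, "phantom_config"))
  set.seed(config$seed)
  L <- config$image_size
  n <- config$n_frames
  a <- config$pulsation_amplitude

  gj <- config$geometry_jitter
  jit <- function(x) x * (1 + stats::runif(1, -gj, gj))
  # canonical geometry in units of L; (row, col), 0-based pixel centers
  geom <- list(
    lv_c  = c(jit(0.52), jit(0.50)) * (L - 1),
    lv_r  = c(jit(0.14), jit(0.22)) * L,
    th_ivs = jit(0.050) * L, th_pw = jit(0.045) * L,
    rv_c  = c(jit(0.20), jit(0.52)) * (L - 1),
    rv_r  = c(jit(0.085), jit(0.19)) * L,
    th_rvaw = jit(0.035) * L,
    la_c  = c(jit(0.84), jit(0.52)) * (L - 1),
    la_r  = c(jit(0.095), jit(0.16)) * L)

  # cycle schedule (in frames); arrhythmia draws each period independently.
  # starts[k] is the frame position (possibly fractional or negative) where
  # cycle k begins, i.e. where the phase crosses an integer (an ED event).
  periods <- numeric(0)
  starts <- -config$phase0 * config$base_period
  while (starts[length(starts)] < n) {
    p <- if (config$arrhythmia)
      config$base_period * (1 + stats::runif(1, -config$jitter, config$jitter))
    else config$base_period
    p <- max(4, p)
    periods <- c(periods, p)
    starts <- c(starts, starts[length(starts)] + p)
  }
  # phase of every frame: piecewise linear in the schedule
  frame_phase <- vapply(seq_len(n) - 1L, function(t) {
    k <- findInterval(t + 1e-9, starts)
    k <- max(1L, min(k, length(periods)))
    (k - 1) + (t - starts[k]) / periods[k]
  }, 0)

  g <- phantom_waveform(frame_phase)
  s <- 1 + a * g                               # LV scale per frame
  wall <- 1 - 0.5 * a * g                      # walls thicken in systole
  srv <- 1 + 0.5 * a * g                       # RV follows LV, damped
  sla <- 1 - 0.5 * a * g                       # LA in antiphase

  rr <- matrix(rep(0:(L - 1), L), L, L)        # row coordinate
  cc <- t(rr)                                  # col coordinate
  in_ell <- function(ctr, rad) {
    ((rr - ctr[1]) / rad[1])^2 + ((cc - ctr[2]) / rad[2])^2 <= 1
  }

  seven <- config$n_classes == 7L
  cls <- if (seven) .cls7 else .cls4
  labs <- array(0L, c(L, L, n))
  frames <- array(0, c(L, L, n))
  segments <- vector("list", n)

  for (t in seq_len(n)) {
    lvr <- geom$lv_r * s[t]
    ivs_o <- lvr + geom$th_ivs * wall[t]
    pw_o <- lvr + geom$th_pw * wall[t]
    rvr <- geom$rv_r * srv[t]
    lar <- geom$la_r * sla[t]

    m_lv <- in_ell(geom$lv_c, lvr)
    m_ivs <- in_ell(geom$lv_c, ivs_o) & !m_lv & rr < geom$lv_c[1]
    m_pw <- in_ell(geom$lv_c, pw_o) & !m_lv & rr >= geom$lv_c[1]
    m_rv <- in_ell(geom$rv_c, rvr) & !m_ivs & !m_lv
    m_rvaw <- in_ell(geom$rv_c, rvr + geom$th_rvaw * wall[t]) &
      !m_rv & !m_ivs & !m_lv & rr < geom$rv_c[1]
    m_la <- in_ell(geom$la_c, lar) & !m_pw & !m_lv

    lab <- matrix(0L, L, L)
    inten <- matrix(.base_intensity["bg"], L, L)
    paint <- function(mask, name7) {
      id <- if (seven) cls[[name7]]
      else switch(name7, LV = cls[["LV"]], LA = cls[["LA"]],
                  IVS = , LVPW = cls[["MYO"]],
                  RV = , RVAW = 0L)
      iname <- if (seven || name7 %in% c("LV", "LA")) name7 else
        if (name7 %in% c("IVS", "LVPW")) "MYO" else name7
      lab[mask] <<- id
      inten[mask] <<- .base_intensity[[iname]]
    }
    paint(m_la, "LA")
    paint(m_rv, "RV")
    paint(m_rvaw, "RVAW")
    paint(m_ivs, "IVS")
    paint(m_pw, "LVPW")
    paint(m_lv, "LV")
    labs[, , t] <- lab

    img <- inten
    if (config$speckle_strength > 0) {
      ss <- config$speckle_strength
      shape <- 1 / ss^2
      noise <- matrix(stats::rgamma(L * L, shape = shape, scale = 1 / shape),
                      L, L)
      img <- img * noise
    }
    frames[, , t] <- pmin(pmax(img, 0), 1)

    # measurement segments along the vertical line through the LV center
    c0 <- geom$lv_c[2]
    r_top_lv <- geom$lv_c[1] - lvr[1]
    r_bot_lv <- geom$lv_c[1] + lvr[1]
    segments[[t]] <- list(
      IVS = list(begin = c(r_top_lv - geom$th_ivs * wall[t], c0),
                 end = c(r_top_lv, c0)),
      LVID = list(begin = c(r_top_lv, c0), end = c(r_bot_lv, c0)),
      LVPW = list(begin = c(r_bot_lv, c0),
                  end = c(r_bot_lv + geom$th_pw * wall[t], c0)))
  }

  # ED events occur where the phase crosses an integer (cycle starts); ES
  # events at systolic-fraction offsets into each cycle.  The constructed
  # frame index is the nearest integer frame, which by monotonicity of the
  # waveform away from its extrema is also the per-cycle argmax/argmin of
  # the LV area.  Events on the first/last frame are dropped: they are not
  # detectable extrema of the finite curve.
  ed_pos <- starts
  es_pos <- starts[seq_along(periods)] + .fs_systole * periods
  keep <- function(pos) {
    f <- as.integer(round(pos))
    sort(unique(f[f >= 1L & f <= n - 2L]))
  }
  ed <- keep(ed_pos)
  es <- keep(es_pos)

  video <- structure(list(frames = frames,
                          times = seq(0, 1, length.out = n),
                          mm_per_px = config$mm_per_px),
                     class = "video_clip")
  ann <- structure(list(labels = labs, ed_frames = sort(ed),
                        es_frames = sort(es), segments = segments,
                        cycle_schedule = periods, phase = frame_phase,
                        lv_scale = s, lv_center = geom$lv_c,
                        lv_radii = geom$lv_r,
                        classes = cls, n_classes = config$n_classes,
                        config = config),
                   class = "phantom_annotation")
  list(video = video, annotation = ann)
}

#' Ground-truth LV area curve
#'
#' Per-frame LV pixel count scaled by the squared pixel spacing.
#'
#' @param annotation a `phantom_annotation` (or any list with a `labels`
#'   array).
#' @param lv_class integer label id of the LV (default from the annotation).
#' @param mm_per_px pixel spacing; 1 gives areas in px^2.
#' @return numeric vector of per-frame areas (class `area_curve`).
#' @export
gt_area_curve <- function(annotation, lv_class = NULL, mm_per_px = 1) {
  labs <- annotation$labels
  if (is.null(lv_class)) lv_class <- annotation$classes[["LV"]]
  n <- dim(labs)[3]
  v <- vapply(seq_len(n), function(t) sum(labs[, , t] == lv_class), 0)
  if (all(v == 0)) warning("lv_class absent from all label maps; area 0")
  structure(v * mm_per_px^2, class = "area_curve")
}

#' Sample a sparse training/evaluation clip from a phantom video
#'
#' Selects `n_input` frames spaced `stride` apart; the input times `tau` are
#' uniform nodes in `[0, 1]` and the target times `S` are the
#' `2 * n_input - 1` uniform nodes covering every spanned frame.  In the
#' `"eval"` policy the annotated frame is the last input; in the `"train"`
#' policy its position among the inputs is uniform random.
#'
#' @param video a `video_clip`.
#' @param annotation a `phantom_annotation`.
#' @param annotated_frame 0-based index of the frame carrying the
#'   segmentation label (default: last ED frame, mimicking sparse clinical
#'   annotation).
#' @param n_input number of input frames (default 4).
#' @param stride frame stride between inputs (default 2).
#' @param policy `"eval"` or `"train"`.
#' @return list with `frames` (input stack), `tau`, `S`, `frame_idx`
#'   (0-based video frames at `tau`), `span_idx` (0-based frames at `S`),
#'   `recon_targets` (frames at all `S`), `label` (label map at the
#'   annotated frame), `label_node` (index into `S`, 1-based), and
#'   `annotated_frame`.
#' @export
sample_clip <- function(video, annotation, annotated_frame = NULL,
                        n_input = 4L, stride = 2L, policy = c("eval", "train")) {
  policy <- match.arg(policy)
  n <- dim(video$frames)[3]
  if (is.null(annotated_frame)) {
    annotated_frame <- if (length(annotation$ed_frames))
      annotation$ed_frames[length(annotation$ed_frames)] else n - 1L
  }
  k <- as.integer(annotated_frame)
  if (k < 0 || k >= n) stop("annotated frame outside video")
  if (n_input == 1L) {
    tau <- 0; S <- 0
    fidx <- k; sidx <- k; label_node <- 1L
  } else {
    span <- stride * (n_input - 1L)
    pos <- if (policy == "eval") n_input else
      sample.int(n_input, 1L)                 # 1-based position of the label
    start <- k - stride * (pos - 1L)
    # shift the window (in stride steps, preserving the congruence of the
    # annotated frame) if the labeled position pushes it outside the video
    while (start < 0L) start <- start + stride
    while (start + span > n - 1L) start <- start - stride
    if (start < 0L || start + span > n - 1L)
      stop("sampling window does not fit inside the video")
    if (k < start || k > start + span || (k - start) %% stride != 0L)
      stop("annotated frame outside the sampled window")
    fidx <- start + stride * (seq_len(n_input) - 1L)
    sidx <- start + seq.int(0L, span)
    tau <- seq(0, 1, length.out = n_input)
    S <- seq(0, 1, length.out = 2L * n_input - 1L)
    label_node <- which(sidx == k)
  }
  list(frames = video$frames[, , fidx + 1L, drop = FALSE],
       tau = tau, S = S, frame_idx = fidx, span_idx = sidx,
       recon_targets = video$frames[, , sidx + 1L, drop = FALSE],
       label = annotation$labels[, , k + 1L],
       label_node = label_node, annotated_frame = k,
       mm_per_px = video$mm_per_px)
}
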