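# ---------------------------------------------------------------------------
# Region similarity (Dice/IoU) and temporal-consistency metrics.
#
# TC: each mask is turned into its iso-0.5 contour polygon (marching
# squares via grDevices::contourLines, largest component), resampled to
# n_pts points equispaced in arc length; each point gets a shape-context
# descriptor (5 log-spaced radial x 12 angular bins, radii normalised by the
# mean pairwise distance); adjacent-frame contours are matched by
# order-preserving DTW over all cyclic start offsets under the chi^2 bin
# distance, and the mean cost per matched point is the pairwise score tau.
# TC is the mean of tau over adjacent-frame pairs, then over videos.
#
# TCD: mean absolute difference of per-frame ground-truth Dice between
# adjacent frames, then over videos.
# ---------------------------------------------------------------------------

#' Dice and IoU coefficients of two binary masks
#'
#' Both-empty masks score 1 by convention.
#'
#' @param m_a,m_b logical/0-1 matrices of identical shape (or integer label
#'   maps together with `class_id`)
#' @param class_id optional label id; if given, masks are `m == class_id`
#' @return scalar in `[0, 1]`
#' @export
dice <- function(m_a, m_b, class_id = NULL) {
  if (!is.null(class_id)) { m_a <- m_a == class_id; m_b <- m_b == class_id }
  stopifnot(all(dim(m_a) == dim(m_b)))
  a <- sum(m_a); b <- sum(m_b); i <- sum(m_a & m_b)
  if (a + b == 0) return(1)
  2 * i / (a + b)
}

#' @rdname dice
#' @export
iou <- function(m_a, m_b, class_id = NULL) {
  if (!is.null(class_id)) { m_a <- m_a == class_id; m_b <- m_b == class_id }
  stopifnot(all(dim(m_a) == dim(m_b)))
  u <- sum(m_a | m_b)
  if (u == 0) return(1)
  sum(m_a & m_b) / u
}

#' Extract closed contours of a binary mask
#'
#' Marching-squares iso-contours at level 0.5 (the mask is zero-padded so
#' border-touching components close), ordered by decreasing enclosed area and
#' resampled to `n_pts` points equispaced in arc length.
#'
#' @param mask logical/0-1 matrix (or label map with `class_id`)
#' @param class_id optional label id
#' @param n_pts points per resampled polygon (default 100)
#' @return object of class `contour_set`: list of `n_pts x 2` matrices of
#'   (row, col) sub-pixel coordinates (0-based), largest component first;
#'   empty list (with attribute `empty = TRUE`) for an empty mask
#' @export
mask_to_contours <- function(mask, class_id = NULL, n_pts = 100L) {
  if (!is.null(class_id)) mask <- mask == class_id
  m <- matrix(as.numeric(mask), nrow(mask), ncol(mask))
  if (sum(m) == 0) {
    out <- structure(list(), empty = TRUE, class = "contour_set")
    return(out)
  }
  H <- nrow(m); W <- ncol(m)
  pad <- matrix(0, H + 2, W + 2)
  pad[2:(H + 1), 2:(W + 1)] <- m
  # grid coordinates: row index i maps to x = i - 2 so that pixel (r, c)
  # [0-based] sits at (r, c)
  cl <- grDevices::contourLines(x = seq_len(H + 2) - 2, y = seq_len(W + 2) - 2,
                                z = pad, levels = 0.5)
  polys <- lapply(cl, function(ct) cbind(ct$x, ct$y))
  area <- vapply(polys, function(p) {
    x <- p[, 1]; y <- p[, 2]
    abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
  }, 0)
  polys <- polys[order(area, decreasing = TRUE)]
  out <- lapply(polys, resample_closed, n_pts = n_pts)
  structure(out, empty = FALSE, class = "contour_set")
}

# arc-length-uniform resampling of a closed polygon to n points
resample_closed <- function(poly, n_pts) {
  p <- poly
  if (!all(p[1, ] == p[nrow(p), ])) p <- rbind(p, p[1, ])
  seg <- sqrt(rowSums((p[-1, , drop = FALSE] - p[-nrow(p), , drop = FALSE])^2))
  cum <- c(0, cumsum(seg))
  L <- cum[length(cum)]
  if (L == 0) return(matrix(rep(p[1, ], n_pts), n_pts, 2, byrow = TRUE))
  s <- seq(0, L, length.out = n_pts + 1L)[seq_len(n_pts)]
  out <- matrix(0, n_pts, 2)
  j <- 1L
  for (i in seq_len(n_pts)) {
    while (cum[j + 1L] < s[i] && j < length(seg)) j <- j + 1L
    w <- if (seg[j] > 0) (s[i] - cum[j]) / seg[j] else 0
    out[i, ] <- (1 - w) * p[j, ] + w * p[j + 1L, ]
  }
  out
}

#' Shape-context descriptors of a contour
#'
#' For every point, a joint histogram of the relative positions of all other
#' points in `n_r` log-spaced radial bins (radii normalised by the mean
#' pairwise distance; out-of-range radii are clamped into the end bins) and
#' `n_theta` angular bins.  Rows are normalised to sum to one, which makes
#' the descriptor invariant to translation and uniform scaling.
#'
#' @param points `n x 2` matrix of contour points
#' @param n_r,n_theta histogram geometry (defaults 5 x 12)
#' @param r_inner,r_outer radial range in units of the mean pairwise distance
#' @return `n x (n_r * n_theta)` matrix, rows summing to 1
#' @export
shape_context <- function(points, n_r = 5L, n_theta = 12L,
                          r_inner = 0.125, r_outer = 2) {
  n <- nrow(points)
  if (is.null(n) || n < 3) stop("shape_context: need at least 3 points")
  dx <- outer(points[, 1], points[, 1], `-`)
  dy <- outer(points[, 2], points[, 2], `-`)
  r <- sqrt(dx^2 + dy^2)
  mean_d <- mean(r[upper.tri(r)])
  if (!is.finite(mean_d) || mean_d == 0)
    stop("shape_context: degenerate contour (all points coincident)")
  r <- r / mean_d
  edges <- exp(seq(log(r_inner), log(r_outer), length.out = n_r + 1L))
  rbin <- matrix(findInterval(r, edges, all.inside = FALSE), n, n)
  rbin <- pmin(pmax(rbin, 1L), n_r)           # clamp into end bins
  theta <- atan2(dy, dx)                       # (-pi, pi]
  tbin <- pmin(floor((theta + pi) / (2 * pi) * n_theta), n_theta - 1L) + 1L
  H <- matrix(0, n, n_r * n_theta)
  for (i in seq_len(n)) {
    idx <- (rbin[i, -i] - 1L) * n_theta + tbin[i, -i]
    tab <- tabulate(idx, nbins = n_r * n_theta)
    H[i, ] <- tab / (n - 1L)
  }
  H
}

#' Temporal-stability cost between two masks
#'
#' Chi-squared distances between the shape-context descriptors of the two
#' (largest-component) contours, matched by order-preserving dynamic time
#' warping minimised over all cyclic start offsets; returns the mean cost
#' per matched point.  Zero for identical or translated masks.
#'
#' @param m_a,m_b binary masks (or label maps with `class_id`)
#' @param class_id optional label id
#' @param n_pts contour resampling resolution
#' @return nonnegative scalar, or `NA` (with a warning) if either mask is
#'   empty
#' @export
tc_pair <- function(m_a, m_b, class_id = NULL, n_pts = 100L) {
  ca <- mask_to_contours(m_a, class_id, n_pts)
  cb <- mask_to_contours(m_b, class_id, n_pts)
  if (attr(ca, "empty") || attr(cb, "empty")) {
    warning("tc_pair: empty mask; pair skipped")
    return(NA_real_)
  }
  sa <- shape_context(ca[[1]])
  sb <- shape_context(cb[[1]])
  cost <- cpp_chi2_cost(sa, sb)
  cpp_cyclic_dtw(cost)$mean_cost
}

#' Temporal consistency of a mask sequence / a dataset
#'
#' Mean of [tc_pair()] over all adjacent-frame pairs of each video, then the
#' mean over videos.  Pairs touching an empty mask are excluded from the
#' mean and counted in the `n_empty` attribute.
#'
#' @param masks `h x w x n` array of binary masks or label maps
#' @param class_id optional label id
#' @param n_pts contour resampling resolution
#' @return scalar TC with attribute `n_empty`
#' @export
tc_video <- function(masks, class_id = NULL, n_pts = 100L) {
  n <- dim(masks)[3]
  if (n < 2) stop("tc_video: need at least 2 frames")
  vals <- vapply(seq_len(n - 1L), function(t)
    suppressWarnings(tc_pair(masks[, , t], masks[, , t + 1L], class_id,
                             n_pts)), 0)
  n_empty <- sum(is.na(vals))
  v <- if (all(is.na(vals))) NA_real_ else mean(vals, na.rm = TRUE)
  structure(v, n_empty = n_empty)
}

#' @rdname tc_video
#' @param videos list of mask arrays
#' @export
tc_dataset <- function(videos, class_id = NULL, n_pts = 100L) {
  vals <- vapply(videos, function(v)
    as.numeric(tc_video(v, class_id, n_pts)), 0)
  mean(vals, na.rm = TRUE)
}

#' Temporal consistency of Dice (TCD)
#'
#' Mean absolute difference of the per-frame Dice series between adjacent
#' frames (T = transitions per video), then the mean over videos.
#'
#' @param series numeric vector of per-frame Dice values, or a list of such
#'   vectors (one per video)
#' @return nonnegative scalar
#' @export
tcd <- function(series) {
  if (!is.list(series)) series <- list(series)
  vals <- vapply(series, function(s) {
    if (length(s) < 2) stop("tcd: per-video series length must be >= 2")
    mean(abs(diff(s)))
  }, 0)
  mean(vals)
}

#' Per-frame Dice series of a predicted vs ground-truth video segmentation
#'
#' @param pred,gt `h x w x n` label arrays
#' @param class_id label id to score
#' @return numeric vector of per-frame Dice values (class `dice_series`)
#' @export
dice_series <- function(pred, gt, class_id) {
  n <- dim(pred)[3]
  structure(vapply(seq_len(n), function(t)
    dice(pred[, , t], gt[, , t], class_id), 0), class = "dice_series")
}
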