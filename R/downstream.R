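# ---------------------------------------------------------------------------
# Downstream clinical tasks: cardiac-cycle phase detection from the LV area
# curve and ventricular dimension measurement from keypoint heatmaps.
# ---------------------------------------------------------------------------

#' Left-ventricular area per frame
#'
#' @param labels `h x w x n` label array (predicted or ground truth)
#' @param lv_class LV label id
#' @param mm_per_px pixel spacing (1 gives px^2)
#' @return numeric vector (class `area_curve`)
#' @export
lv_area_series <- function(labels, lv_class, mm_per_px = 1) {
  n <- dim(labels)[3]
  structure(vapply(seq_len(n), function(t)
    sum(labels[, , t] == lv_class), 0) * mm_per_px^2, class = "area_curve")
}

#' Savitzky-Golay smoothing
#'
#' Least-squares local polynomial smoothing with the stated width and order.
#' Interior points use the closed-form convolution coefficients; edge points
#' are handled by refitting the polynomial on the truncated window and
#' evaluating it at the edge position.  An order-`order` filter reproduces
#' any polynomial of degree `<= order` exactly at interior points.
#'
#' @param curve numeric vector
#' @param width odd filter width (default 13); if the curve is shorter the
#'   largest odd width `> order` that fits is used, with a warning
#' @param order polynomial order (default 3)
#' @return smoothed numeric vector of the same length
#' @export
savgol_smooth <- function(curve, width = 13L, order = 3L) {
  x <- as.numeric(curve)
  n <- length(x)
  stopifnot(width %% 2 == 1, width > order)
  if (n < width) {
    width <- max(order + 2L - (order %% 2 == 1L), 5L)
    while (width > n) width <- width - 2L
    if (width <= order) return(x)
    warning(sprintf("curve shorter than filter; falling back to width %d",
                    width))
  }
  m <- (width - 1L) %/% 2L
  A <- outer(seq.int(-m, m), 0:order, `^`)
  co <- solve(crossprod(A), t(A))[1, ]  # evaluate fitted poly at offset 0
  out <- x
  for (i in seq_len(n)) {
    lo <- max(1L, i - m); hi <- min(n, i + m)
    if (hi - lo + 1L == width) {
      out[i] <- sum(co * x[lo:hi])
    } else {  # truncated window: refit (order capped by the point count)
      t0 <- seq.int(lo, hi) - i
      ord <- min(order, length(t0) - 1L)
      At <- outer(t0, 0:ord, `^`)
      beta <- solve(crossprod(At), crossprod(At, x[lo:hi]))
      out[i] <- beta[1]
    }
  }
  class(out) <- class(curve)
  out
}

# strict-with-plateau local maxima; plateau ties resolve to the leftmost
# index.  Returns 1-based indices.
.local_maxima <- function(y) {
  n <- length(y)
  if (n < 3) return(integer(0))
  out <- integer(0)
  i <- 2L
  while (i <= n - 1L) {
    if (y[i] > y[i - 1L]) {
      j <- i
      while (j < n && y[j + 1L] == y[j]) j <- j + 1L
      if (j <= n - 1L && y[j + 1L] < y[j]) out <- c(out, i)
      i <- j + 1L
    } else i <- i + 1L
  }
  out
}

# enforce a minimum separation, keeping higher peaks first
.enforce_sep <- function(idx, y, sep) {
  if (length(idx) < 2) return(idx)
  ord <- idx[order(y[idx], decreasing = TRUE)]
  kept <- integer(0)
  for (i in ord)
    if (!length(kept) || all(abs(kept - i) >= sep)) kept <- c(kept, i)
  sort(kept)
}

#' Detect cardiac phases (ED peaks, ES valleys) in an area curve
#'
#' Local maxima of the (smoothed) curve are ED candidates and local minima
#' ES candidates.  A first pass with minimum separation 4 estimates the
#' median cycle length from the peak spacing; the final minimum separation
#' is `max(4, floor(0.5 * median cycle))`.  Plateau ties resolve to the
#' leftmost index.  A monotone curve yields an empty phase set.
#'
#' @param curve numeric vector (apply [savgol_smooth()] first for noisy
#'   predictions)
#' @return list of class `phase_set` with 0-based `ed` and `es` indices
#' @export
detect_phases <- function(curve) {
  y <- as.numeric(curve)
  pk <- .local_maxima(y)
  vl <- .local_maxima(-y)
  est <- c(diff(.enforce_sep(pk, y, 4L)), diff(.enforce_sep(vl, -y, 4L)))
  sep <- if (length(est)) max(4L, floor(0.5 * stats::median(est))) else 4L
  ed <- .enforce_sep(pk, y, sep)
  es <- .enforce_sep(vl, -y, sep)
  structure(list(ed = ed - 1L, es = es - 1L), class = "phase_set")
}

#' Phase-detection error
#'
#' Greedy nearest matching of detected to ground-truth indices within a
#' `window` (each ground-truth index used at most once); MAE over matched
#' pairs.  Unmatched ground truth and spurious detections are counted
#' separately, not folded into the MAE.
#'
#' @param pred,gt integer vectors of frame indices
#' @param window maximum |pred - gt| for a valid match (default 10 frames)
#' @return list: `mae`, `n_matched`, `n_missed` (unmatched gt),
#'   `n_spurious` (unmatched predictions)
#' @export
phase_mae <- function(pred, gt, window = 10) {
  pred <- as.numeric(pred); gt <- as.numeric(gt)
  if (!length(pred) || !length(gt))
    return(list(mae = NA_real_, n_matched = 0L, n_missed = length(gt),
                n_spurious = length(pred)))
  d <- abs(outer(pred, gt, `-`))
  cand <- which(d <= window, arr.ind = TRUE)
  cand <- cand[order(d[cand]), , drop = FALSE]
  used_p <- logical(length(pred)); used_g <- logical(length(gt))
  errs <- numeric(0)
  for (r in seq_len(nrow(cand))) {
    i <- cand[r, 1]; j <- cand[r, 2]
    if (used_p[i] || used_g[j]) next
    used_p[i] <- TRUE; used_g[j] <- TRUE
    errs <- c(errs, d[i, j])
  }
  list(mae = if (length(errs)) mean(errs) else NA_real_,
       n_matched = length(errs), n_missed = sum(!used_g),
       n_spurious = sum(!used_p))
}

#' Heatmap centroid keypoint extraction
#'
#' Score-weighted centroid ("center of gravity") over pixels whose score is
#' at least `threshold`; pixels below the threshold are ignored.  Returns
#' `NULL` when no pixel reaches the threshold (measurement unavailable).
#'
#' @param map `h x w` matrix with values in `[0, 1]`
#' @param threshold minimum score (default 0.3)
#' @return numeric `(row, col)` 0-based sub-pixel point, or `NULL`
#' @export
heatmap_to_point <- function(map, threshold = 0.3) {
  sel <- map >= threshold
  if (!any(sel)) return(NULL)
  w <- map * sel
  tot <- sum(w)
  r <- sum((row(map) - 1) * w) / tot
  c <- sum((col(map) - 1) * w) / tot
  c(r, c)
}

#' Euclidean dimension from two keypoints
#'
#' @param p_begin,p_end `(row, col)` points in pixels
#' @param mm_per_px pixel spacing
#' @return length in mm
#' @export
measure_dimension <- function(p_begin, p_end, mm_per_px = 1) {
  if (is.null(p_begin) || is.null(p_end))
    stop("measure_dimension: both points must be present")
  sqrt(sum((p_begin - p_end)^2)) * mm_per_px
}

#' Measure IVS, LVID and LVPW from a 6-channel heatmap set
#'
#' Channels are ordered (IVS begin, IVS end, LVID begin, LVID end, LVPW
#' begin, LVPW end).
#'
#' @param heatmaps `h x w x 6` array
#' @param mm_per_px pixel spacing
#' @param threshold centroid threshold (default 0.3)
#' @return list per line with `begin`, `end`, `length_mm` (or `NULL` when a
#'   point is unavailable)
#' @export
measure_from_heatmaps <- function(heatmaps, mm_per_px = 1, threshold = 0.3) {
  nm <- c("IVS", "LVID", "LVPW")
  out <- list()
  for (i in seq_along(nm)) {
    pb <- heatmap_to_point(heatmaps[, , 2 * i - 1], threshold)
    pe <- heatmap_to_point(heatmaps[, , 2 * i], threshold)
    out[[nm[i]]] <- if (is.null(pb) || is.null(pe)) NULL else
      list(begin = pb, end = pe,
           length_mm = measure_dimension(pb, pe, mm_per_px))
  }
  out
}
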