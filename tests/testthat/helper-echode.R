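# shared fixtures: everything is generated in code at test time

tiny_phantom <- function(image_size = 32L, n_frames = 24L, seed = 3L, ...) {
  generate_phantom(phantom_config(image_size = image_size,
                                  n_frames = n_frames, seed = seed, ...))
}

fg_dice <- function(pred, gt) {
  fg <- setdiff(sort(unique(as.vector(gt))), 0)
  if (!length(fg)) return(1)
  mean(vapply(fg, function(c) dice(pred == c, gt == c), 0))
}

# independent fixed-step RK4 integrator for scalar linear ODEs (oracle)
rk4_scalar <- function(f, y0, t0, t1, dt = 1e-3) {
  n <- max(1L, ceiling(abs(t1 - t0) / dt))
  h <- (t1 - t0) / n
  y <- y0
  for (i in seq_len(n)) {
    k1 <- f(y); k2 <- f(y + h * k1 / 2); k3 <- f(y + h * k2 / 2)
    k4 <- f(y + h * k3)
    y <- y + h * (k1 + 2 * k2 + 2 * k3 + k4) / 6
  }
  y
}

# brute-force cyclic DTW: enumerate all monotone alignments (steps diag, up,
# left) for every rotation of the second sequence; returns the minimum total
# cost.  Exponential -- only for n <= 8.
brute_dtw_total <- function(cost) {
  n1 <- nrow(cost); n2 <- ncol(cost)
  best_total <- Inf
  rec <- function(i, j, tot, cost_rot) {
    tot <- tot + cost_rot[i, j]
    if (tot >= best_total) return()
    if (i == n1 && j == n2) {
      best_total <<- min(best_total, tot)
      return()
    }
    if (i < n1 && j < n2) rec(i + 1, j + 1, tot, cost_rot)
    if (i < n1) rec(i + 1, j, tot, cost_rot)
    if (j < n2) rec(i, j + 1, tot, cost_rot)
  }
  for (off in 0:(n2 - 1)) {
    cost_rot <- cost[, ((seq_len(n2) - 1 + off) %% n2) + 1, drop = FALSE]
    rec(1, 1, 0, cost_rot)
  }
  best_total
}

# single SGD step loop used by small training probes
sgd_steps <- function(model, rec, steps, lr, lambda = 10, clip = 10,
                      stop_dice = NULL) {
  for (step in seq_len(steps)) {
    lg <- echode:::echode_clip_loss(model, rec, lambda)
    g <- echode:::tp_backward(lg$tape, lg$loss)
    gn2 <- 0
    for (nm in names(lg$pid)) gn2 <- gn2 + sum(g[[lg$pid[[nm]]]]^2)
    gn <- sqrt(gn2)
    sc <- if (clip > 0 && gn > clip) clip / gn else 1
    for (nm in names(lg$pid))
      model$params[[nm]] <- model$params[[nm]] - lr * sc * g[[lg$pid[[nm]]]]
    if (!is.null(stop_dice) && step %% 25 == 0) {
      out <- echo_ode_forward(model, rec$frames, rec$tau, rec$S)
      if (fg_dice(out$labels[, , rec$label_node], rec$label) > stop_dice)
        return(list(model = model, steps = step))
    }
  }
  list(model = model, steps = steps)
}
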