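# Independent oracles and small constructors used across the suite.

# Brute-force event-time simulation of a symmetric alternating-renewal
# (telegraph) process: draws exponential dwell times directly and counts the
# events inside [0, total_ns]. Independent of the package's CTMC sampler.
brute_force_telegraph_count <- function(rate_ns, total_ns) {
  t <- 0
  n <- 0L
  repeat {
    t <- t + stats::rexp(1, rate_ns)
    if (t > total_ns) break
    n <- n + 1L
  }
  n
}

# Naive exact-key grouping oracle: group raw state tuples by string identity.
naive_group <- function(state_matrix) {
  keys <- do.call(paste, c(as.data.frame(state_matrix), sep = "|"))
  tab <- sort(table(keys), decreasing = TRUE)
  tibble::tibble(tuple = names(tab), count = as.integer(tab),
                 W = as.integer(tab) / length(keys))
}

# Gaussian-bump circular histogram with peaks at given angles; valleys sit
# between the peaks.
gaussian_mix_hist <- function(peaks, sd = 15, height = 1000) {
  a <- -180:179
  counts <- numeric(360)
  for (p in peaks) {
    counts <- counts + round(height * exp(-(circular_distance(a, p)^2) /
                                            (2 * sd^2)))
  }
  counts
}

# Piecewise-linear circular profile through (angle, value) anchor points.
anchor_hist <- function(angles, values) {
  o <- order(angles)
  angles <- angles[o]; values <- values[o]
  a <- -180:179
  k <- length(angles)
  counts <- numeric(360)
  for (i in seq_len(k)) {
    a0 <- angles[i]; v0 <- values[i]
    a1 <- if (i < k) angles[i + 1] else angles[1] + 360
    v1 <- if (i < k) values[i + 1] else values[1]
    span <- a1 - a0
    rel <- ((a - a0) %% 360)
    seg <- rel < span
    counts[seg] <- v0 + (v1 - v0) * rel[seg] / span
  }
  round(counts)
}

# Markov chain over cluster labels: from any label, move with probability
# `p_move` to a uniformly chosen other label; the trap label's move
# probability is scaled down by `trap_factor`. Returns the label series.
trap_chain <- function(n_steps, n_labels = 10, p_move = 0.1,
                       trap_label = n_labels, trap_factor = 0.1) {
  labels <- integer(n_steps)
  cur <- 1L
  for (i in seq_len(n_steps)) {
    labels[i] <- cur
    p <- if (cur == trap_label) p_move * trap_factor else p_move
    if (stats::runif(1) < p) {
      cand <- setdiff(seq_len(n_labels), cur)
      cur <- cand[sample.int(n_labels - 1L, 1)]
    }
  }
  labels
}

# minimal assigned-state tibble for hand-constructed cases
make_states_tbl <- function(states_by_traj, dof_id = "d1",
                            frame_interval = 100) {
  out <- purrr::imap_dfr(states_by_traj, function(st, tid) {
    tibble::tibble(trajectory_id = tid, frame = seq_along(st),
                   dof_id = dof_id, state = as.integer(st))
  })
  attr(out, "frame_interval_ps") <- frame_interval
  out
}

# rigid rotation matrix from a seed
random_rotation <- function() {
  q <- qr.Q(qr(matrix(stats::rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}
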