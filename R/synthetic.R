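#' Specify one telegraph-process torsional degree of freedom
#'
#' The synthetic generator models each torsional degree of freedom (DOF) as a
#' continuous-time Markov chain over `n_states` discrete torsional states
#' (state process), observed through circular von Mises-style angular noise
#' about per-state centers (emission process). Sampling the state process on
#' the saved-frame grid reproduces the waiting-time semantics of snapshot-based
#' trajectory analysis: transitions that occur and revert entirely between two
#' saved frames are invisible.
#'
#' A DOF may be declared a *slave* of a master DOF: at each frame it copies the
#' master's current state with probability `coupling`, otherwise it shows its
#' own independent telegraph state. With `coupling = 1` the slave's state
#' sequence equals its master's (modulo state relabeling when state counts
#' differ). This is the simplest mechanism that produces a dominant shared
#' substate (a hub) at coarse temporal resolution.
#'
#' @param dof_id Identifier, unique within an ensemble.
#' @param exit_rates Per-state exit rates in 1/ns (length `n_states`); the mean
#'   dwell time in state `s` is `1/exit_rates[s]` ns.
#' @param state_centers Per-state emission centers in degrees; pairwise
#'   circular distance must be at least 60 degrees.
#' @param n_states 2 for backbone-like DOFs, 3 for side-chain (chi) rotamers.
#' @param emission_kappa von Mises concentration of the angular noise
#'   (dimensionless; `Inf` means noise-free emission at the state center).
#' @param truncate_emission If `TRUE`, emission offsets are confined to
#'   plus/minus (minimum circular gap between centers)/2 - 0.5 degrees, so an
#'   emitted angle always lies inside its true state's arc.
#' @param dof_kind One of `"phi"`, `"psi"`, `"chi1"`, `"chi2"`, `"generic"`.
#' @param residue_index Optional 1-based residue index.
#' @param master `dof_id` of a master DOF, or `NULL` for an independent DOF.
#' @param coupling Per-frame probability of copying the master's state,
#'   in `[0, 1]`. Ignored when `master` is `NULL`.
#' @param transit_mean_frames Mean number of barrier-transit frames emitted
#'   per state flip (geometric distribution; 0, the default, disables the
#'   mechanism). During a transit the emitted angle lies within
#'   `transit_width` degrees of the crossing minimum — one of the inter-state
#'   minima, chosen uniformly, so both spatial routes of a cyclic two-state
#'   DOF occur — moving from the departing state's side to the arriving
#'   state's side. This emulates the finite barrier-crossing time of real
#'   torsional dynamics, which is set by local barrier shape rather than by
#'   the waiting time between flips.
#' @param transit_width Half-width (degrees) of the transit emission window
#'   around the crossing minimum (default 2.4).
#' @return An object of class `telegraph_spec`.
#' @seealso [ensemble_spec()], [simulate_ensemble()]
#' @export
telegraph_spec <- function(dof_id, exit_rates, state_centers, n_states = 2L,
                           emission_kappa = 20, truncate_emission = TRUE,
                           dof_kind = "generic", residue_index = NA_integer_,
                           master = NULL, coupling = 0,
                           transit_mean_frames = 0, transit_width = 2.4) {
  n_states <- as.integer(n_states)
  if (n_states < 2) stop("n_states must be >= 2")
  if (length(exit_rates) == 1) exit_rates <- rep(exit_rates, n_states)
  if (length(exit_rates) != n_states) {
    stop("exit_rates must have length 1 or n_states")
  }
  if (any(!is.finite(exit_rates)) || any(exit_rates <= 0)) {
    stop("exit_rates must be positive and finite (1/ns)")
  }
  if (length(state_centers) != n_states) {
    stop("state_centers must have length n_states")
  }
  state_centers <- normalize_angle(state_centers)
  gaps <- utils::combn(state_centers, 2,
                       function(p) circular_distance(p[1], p[2]))
  if (any(gaps < 60)) {
    stop("state_centers must be pairwise >= 60 degrees apart (circular)")
  }
  if (!is.null(master) && (coupling < 0 || coupling > 1)) {
    stop("coupling must be in [0, 1]")
  }
  dof_kind <- match.arg(dof_kind, c("phi", "psi", "chi1", "chi2", "generic"))
  structure(
    list(dof_id = as.character(dof_id), n_states = n_states,
         exit_rates = as.numeric(exit_rates),
         state_centers = as.numeric(state_centers),
         emission_kappa = emission_kappa,
         truncate_emission = isTRUE(truncate_emission),
         dof_kind = dof_kind, residue_index = residue_index,
         master = if (is.null(master)) NA_character_ else as.character(master),
         coupling = as.numeric(coupling),
         transit_mean_frames = as.numeric(transit_mean_frames),
         transit_width = as.numeric(transit_width)),
    class = "telegraph_spec"
  )
}

#' Specify a synthetic torsional ensemble
#'
#' @param n_trajectories Number of independent trajectories.
#' @param frames_per_trajectory Saved frames per trajectory.
#' @param frame_interval_ps Uniform saving interval in picoseconds.
#' @param dofs List of [telegraph_spec()] objects.
#' @param seed Integer master seed; all randomness flows from it through a
#'   counter-based per-(trajectory, DOF) stream, so results are reproducible in
#'   any iteration order.
#' @return An object of class `ensemble_spec`.
#' @export
ensemble_spec <- function(n_trajectories, frames_per_trajectory,
                          frame_interval_ps, dofs, seed = 1L) {
  if (frame_interval_ps <= 0) stop("frame_interval_ps must be positive")
  if (n_trajectories < 1 || frames_per_trajectory < 1) {
    stop("n_trajectories and frames_per_trajectory must be >= 1")
  }
  if (length(dofs) == 0) stop("at least one DOF spec is required")
  if (inherits(dofs, "telegraph_spec")) dofs <- list(dofs)
  ok <- vapply(dofs, inherits, logical(1), "telegraph_spec")
  if (!all(ok)) stop("dofs must be a list of telegraph_spec objects")
  ids <- vapply(dofs, `[[`, character(1), "dof_id")
  if (anyDuplicated(ids)) stop("duplicate dof_id in spec")
  masters <- vapply(dofs, `[[`, character(1), "master")
  unknown <- masters[!is.na(masters) & !(masters %in% ids)]
  if (length(unknown)) stop("unknown master dof_id: ", unknown[1])
  # slaves of slaves are not supported: the hub mechanism is one level deep
  slave_of_slave <- !is.na(masters) &
    masters %in% ids[!is.na(masters)]
  if (any(slave_of_slave)) stop("a master DOF cannot itself be a slave")
  structure(
    list(n_trajectories = as.integer(n_trajectories),
         frames_per_trajectory = as.integer(frames_per_trajectory),
         frame_interval_ps = as.numeric(frame_interval_ps),
         dofs = stats::setNames(dofs, ids),
         seed = as.integer(seed)),
    class = "ensemble_spec"
  )
}

# von Mises sampler (Best & Fisher 1979 rejection scheme), radians in [-pi, pi]
rvonmises <- function(n, kappa) {
  if (n == 0) return(numeric(0))
  if (!is.finite(kappa)) return(rep(0, n))
  if (kappa <= 0) return(stats::runif(n, -pi, pi))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  got <- 0L
  while (got < n) {
    m <- n - got
    u1 <- stats::runif(m); u2 <- stats::runif(m); u3 <- stats::runif(m)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    ok <- (cc * (2 - cc) - u2 > 0) | (log(cc / u2) + 1 - cc >= 0)
    k <- sum(ok)
    if (k > 0) {
      out[(got + 1L):(got + k)] <- sign(u3[ok] - 0.5) * acos(pmax(pmin(f[ok], 1), -1))
      got <- got + k
    }
  }
  out
}

# Continuous-time Markov chain sampled on the frame grid.
# Returns integer states (0-based) at frame times (0:(n_frames-1)) * dt_ps.
sample_ctmc_states <- function(n_frames, dt_ps, exit_rates_ns, n_states) {
  total_ps <- n_frames * dt_ps
  rates_ps <- exit_rates_ns / 1000
  # stationary start: pi_s proportional to 1/exit_rate (uniform embedded chain)
  p0 <- (1 / rates_ps) / sum(1 / rates_ps)
  s0 <- sample.int(n_states, 1, prob = p0) - 1L
  jump_times <- numeric(0)
  states <- s0
  t <- 0
  cur <- s0
  repeat {
    # draw dwell times in blocks to limit R-level looping
    n_draw <- max(16L, ceiling((total_ps - t) * max(rates_ps) * 1.5))
    n_draw <- min(n_draw, 1e6L)
    block_states <- integer(n_draw)
    block_times <- numeric(n_draw)
    filled <- 0L
    while (filled < n_draw && t <= total_ps) {
      dwell <- stats::rexp(1, rates_ps[cur + 1L])
      t <- t + dwell
      if (t > total_ps) break
      cur <- if (n_states == 2L) {
        1L - cur
      } else {
        others <- setdiff(0:(n_states - 1L), cur)
        others[sample.int(n_states - 1L, 1)]
      }
      filled <- filled + 1L
      block_states[filled] <- cur
      block_times[filled] <- t
    }
    if (filled > 0) {
      jump_times <- c(jump_times, block_times[seq_len(filled)])
      states <- c(states, block_states[seq_len(filled)])
    }
    if (t > total_ps) break
  }
  frame_times <- (seq_len(n_frames) - 1) * dt_ps
  idx <- findInterval(frame_times, jump_times)
  states[idx + 1L]
}

emit_angles <- function(states, spec) {
  centers <- spec$state_centers
  n <- length(states)
  if (!is.finite(spec$emission_kappa)) {
    return(centers[states + 1L])
  }
  off <- rvonmises(n, spec$emission_kappa) * 180 / pi
  if (spec$truncate_emission) {
    gaps <- utils::combn(centers, 2, function(p) circular_distance(p[1], p[2]))
    bound <- min(gaps) / 2 - 0.5
    bad <- which(abs(off) > bound)
    iter <- 0L
    while (length(bad) > 0 && iter < 50L) {
      off[bad] <- rvonmises(length(bad), spec$emission_kappa) * 180 / pi
      bad <- bad[abs(off[bad]) > bound]
      iter <- iter + 1L
    }
    if (length(bad) > 0) off[bad] <- sign(off[bad]) * bound
  }
  normalize_angle(centers[states + 1L] + off)
}

# circular midpoints between adjacent state centers: the generator's true
# inter-state minima (a cyclic k-state DOF has k of them)
true_minima <- function(centers) {
  cs <- sort(normalize_angle(centers))
  k <- length(cs)
  vapply(seq_len(k), function(i) {
    a <- cs[i]
    b <- if (i < k) cs[i + 1] else cs[1] + 360
    normalize_angle((a + b) / 2)
  }, numeric(1))
}

# overwrite the frames right after each state flip with barrier-transit
# emission: angles near a crossing minimum, departing side first
apply_transits <- function(angles, states, dspec) {
  n <- length(states)
  flips <- which(states[-1] != states[-n]) + 1L
  if (length(flips) == 0) return(angles)
  mins <- true_minima(dspec$state_centers)
  for (f in flips) {
    k <- stats::rgeom(1, 1 / (1 + dspec$transit_mean_frames))
    if (k == 0) next
    idx <- f:min(f + k - 1L, n)
    moved_on <- which(states[idx] != states[f])  # next flip cuts the transit
    if (length(moved_on)) idx <- idx[seq_len(moved_on[1] - 1L)]
    if (length(idx) == 0) next
    m <- mins[sample.int(length(mins), 1)]
    old_center <- dspec$state_centers[states[f - 1L] + 1L]
    side_old <- sign(normalize_angle(old_center - m))
    if (side_old == 0) side_old <- 1
    off <- stats::runif(length(idx), 0.1, dspec$transit_width)
    half <- ceiling(length(idx) / 2)
    sides <- c(rep(side_old, half), rep(-side_old, length(idx) - half))
    angles[idx] <- normalize_angle(m + sides * off)
  }
  angles
}

# deterministic per-(trajectory, dof) seed below 2^31
stream_seed <- function(seed, traj_index, dof_index) {
  as.integer((as.double(seed) * 48271 + traj_index * 104729 + dof_index * 7919) %%
               2147483647)
}

#' Simulate a synthetic torsional ensemble
#'
#' Generates one angle trace per (trajectory, DOF) from the telegraph state
#' process plus circular emission noise. The hidden true state sequence is
#' retained in the `state_true` column so downstream detection and counting
#' stages can be validated against ground truth.
#'
#' @param spec An [ensemble_spec()].
#' @return A tibble of class `dihedral_ensemble` with columns `trajectory_id`,
#'   `frame` (1-based), `dof_id`, `angle` (degrees, (-180, 180]) and
#'   `state_true` (0-based). Attributes: `frame_interval_ps` and `dof_info`
#'   (a tibble with one row per DOF: kind, state count, centers, rates).
#' @export
#' @examples
#' sp <- ensemble_spec(2, 500, 4, list(
#'   telegraph_spec("d1", exit_rates = 0.5, state_centers = c(-60, 120))
#' ), seed = 42)
#' ens <- simulate_ensemble(sp)
#' dplyr::count(ens, dof_id, state_true)
simulate_ensemble <- function(spec) {
  stopifnot(inherits(spec, "ensemble_spec"))
  n_fr <- spec$frames_per_trajectory
  dt <- spec$frame_interval_ps
  dof_ids <- names(spec$dofs)
  masters <- vapply(spec$dofs, `[[`, character(1), "master")
  order_idx <- order(!is.na(masters))  # masters (independent DOFs) first
  per_traj <- vector("list", spec$n_trajectories)
  for (ti in seq_len(spec$n_trajectories)) {
    states_mat <- matrix(0L, nrow = n_fr, ncol = length(dof_ids),
                         dimnames = list(NULL, dof_ids))
    angles_mat <- matrix(0, nrow = n_fr, ncol = length(dof_ids),
                         dimnames = list(NULL, dof_ids))
    for (di in order_idx) {
      dspec <- spec$dofs[[di]]
      set.seed(stream_seed(spec$seed, ti, di))
      st <- sample_ctmc_states(n_fr, dt, dspec$exit_rates, dspec$n_states)
      if (!is.na(dspec$master) && dspec$coupling > 0) {
        mst <- states_mat[, dspec$master] %% dspec$n_states
        copy <- stats::runif(n_fr) < dspec$coupling
        st[copy] <- mst[copy]
      }
      states_mat[, di] <- st
      ang <- emit_angles(st, dspec)
      if (dspec$transit_mean_frames > 0) ang <- apply_transits(ang, st, dspec)
      angles_mat[, di] <- ang
    }
    per_traj[[ti]] <- tibble::tibble(
      trajectory_id = sprintf("traj%03d", ti),
      frame = rep(seq_len(n_fr), times = length(dof_ids)),
      dof_id = rep(dof_ids, each = n_fr),
      angle = as.vector(angles_mat),
      state_true = as.integer(states_mat)
    )
  }
  out <- dplyr::bind_rows(per_traj)
  dof_info <- tibble::tibble(
    dof_id = dof_ids,
    dof_kind = vapply(spec$dofs, `[[`, character(1), "dof_kind"),
    n_states = vapply(spec$dofs, `[[`, integer(1), "n_states"),
    residue_index = vapply(spec$dofs, `[[`, integer(1), "residue_index"),
    master = masters,
    coupling = vapply(spec$dofs, `[[`, numeric(1), "coupling"),
    state_centers = lapply(spec$dofs, `[[`, "state_centers"),
    exit_rates = lapply(spec$dofs, `[[`, "exit_rates")
  )
  attr(out, "frame_interval_ps") <- dt
  attr(out, "dof_info") <- dof_info
  class(out) <- c("dihedral_ensemble", class(out))
  out
}

#' Frame interval of an angle ensemble
#'
#' @param x A `dihedral_ensemble` tibble (or any object carrying a
#'   `frame_interval_ps` attribute).
#' @return Frame interval in picoseconds.
#' @export
frame_interval_ps <- function(x) {
  fi <- attr(x, "frame_interval_ps", exact = TRUE)
  if (is.null(fi)) stop("object carries no frame_interval_ps attribute; ",
                        "pass the interval explicitly")
  fi
}

#' Write an ensemble of dihedral traces to a tab-separated angle table
#'
#' One data row per frame and one column per DOF, a single header row with the
#' DOF ids, and `#`-prefixed metadata lines: a global `# frame_interval_ps`
#' line and a `# trajectory_id` line before each trajectory's block. The file
#' round-trips losslessly (to the printed precision) with
#' [read_angle_table()].
#'
#' @param ensemble A `dihedral_ensemble` tibble (columns `trajectory_id`,
#'   `frame`, `dof_id`, `angle`).
#' @param path Output file path.
#' @param digits Decimal digits written for each angle (default 6).
#' @return `path`, invisibly.
#' @export
write_angle_table <- function(ensemble, path, digits = 6) {
  stopifnot(all(c("trajectory_id", "frame", "dof_id", "angle") %in%
                  names(ensemble)))
  dof_ids <- unique(ensemble$dof_id)
  if (length(dof_ids) == 0) stop("ensemble contains no DOFs")
  dt <- frame_interval_ps(ensemble)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# frame_interval_ps\t%s", format(dt)), con)
  writeLines(paste(dof_ids, collapse = "\t"), con)
  fmt <- paste0("%.", digits, "f")
  for (tid in unique(ensemble$trajectory_id)) {
    block <- ensemble[ensemble$trajectory_id == tid, ]
    wide <- tidyr::pivot_wider(block[, c("frame", "dof_id", "angle")],
                               names_from = "dof_id", values_from = "angle")
    wide <- wide[order(wide$frame), dof_ids, drop = FALSE]
    if (anyNA(wide)) stop("ragged trajectory ", tid,
                          ": not every frame has every DOF")
    writeLines(sprintf("# trajectory_id\t%s", tid), con)
    mat <- matrix(sprintf(fmt, as.matrix(wide)), nrow = nrow(wide))
    writeLines(apply(mat, 1, paste, collapse = "\t"), con)
  }
  invisible(path)
}

#' Read a tab-separated angle table
#'
#' @param path File written by [write_angle_table()] (or extracted from MD
#'   trajectories in the same format).
#' @return A `dihedral_ensemble` tibble (without hidden states).
#' @export
read_angle_table <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0) stop("empty angle table: ", path)
  meta <- grepl("^#", lines)
  fi_line <- grep("^# frame_interval_ps\t", lines, value = TRUE)
  if (length(fi_line) != 1) stop("missing frame_interval_ps metadata line")
  dt <- as.numeric(sub("^# frame_interval_ps\t", "", fi_line))
  header_idx <- which(!meta)[1]
  dof_ids <- strsplit(lines[header_idx], "\t", fixed = TRUE)[[1]]
  traj_lines <- grep("^# trajectory_id\t", lines)
  if (length(traj_lines) == 0) stop("no trajectory blocks found")
  blocks <- vector("list", length(traj_lines))
  bounds <- c(traj_lines, length(lines) + 1L)
  for (b in seq_along(traj_lines)) {
    tid <- sub("^# trajectory_id\t", "", lines[traj_lines[b]])
    rows <- lines[(bounds[b] + 1L):(bounds[b + 1L] - 1L)]
    rows <- rows[!grepl("^#", rows) & nzchar(rows)]
    mat <- matrix(as.numeric(unlist(strsplit(rows, "\t", fixed = TRUE))),
                  nrow = length(rows), byrow = TRUE)
    if (ncol(mat) != length(dof_ids)) stop("ragged block for trajectory ", tid)
    blocks[[b]] <- tibble::tibble(
      trajectory_id = tid,
      frame = rep(seq_len(nrow(mat)), times = length(dof_ids)),
      dof_id = rep(dof_ids, each = nrow(mat)),
      angle = as.vector(mat)
    )
  }
  out <- dplyr::bind_rows(blocks)
  attr(out, "frame_interval_ps") <- dt
  class(out) <- c("dihedral_ensemble", class(out))
  out
}
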