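band_levels <- c("T0", "T1", "T2", "T3", "T4", "excluded")

# count frame-to-frame state changes in one trajectory's state vector
count_state_changes <- function(states) {
  if (length(states) < 2) return(0L)
  sum(states[-1] != states[-length(states)])
}

#' Count torsional transitions per DOF
#'
#' A transition is a frame-to-frame change of torsional state, counted
#' regardless of direction or route and summed over trajectories; trajectory
#' boundaries never contribute.
#'
#' @param states A tibble with columns `trajectory_id`, `frame`, `dof_id` and
#'   `state` (see [assign_states()]), or an integer vector of states of a
#'   single trajectory.
#' @return For a tibble: a tibble `dof_id`, `n_trans`. For a vector: an
#'   integer count.
#' @export
#' @examples
#' count_transitions(c(0L, 0L, 1L, 1L, 0L)) # 2
count_transitions <- function(states) {
  if (!is.data.frame(states)) return(count_state_changes(states))
  stopifnot(all(c("trajectory_id", "dof_id", "state") %in% names(states)))
  states |>
    dplyr::group_by(.data$dof_id, .data$trajectory_id) |>
    dplyr::summarise(n = count_state_changes(.data$state[order(.data$frame)]),
                     .groups = "drop") |>
    dplyr::group_by(.data$dof_id) |>
    dplyr::summarise(n_trans = as.integer(sum(.data$n)), .groups = "drop")
}

#' Mean waiting time between torsional transitions
#'
#' @param total_time_us Total simulated time across all trajectories, in
#'   microseconds.
#' @param n_trans Observed transition count.
#' @return `total_time_us / n_trans` in microseconds, or `NA` when
#'   `n_trans = 0` (the DOF is excluded rather than given a numeric waiting
#'   time).
#' @export
#' @examples
#' waiting_time(200, 100) # 2 microseconds
waiting_time <- function(total_time_us, n_trans) {
  stopifnot(total_time_us > 0, n_trans >= 0)
  ifelse(n_trans > 0, total_time_us / n_trans, NA_real_)
}

#' Assign a temporal-resolution band from a transition count
#'
#' Bands are decade bins of the transition count, rescaled with the ensemble
#' length: with `s = total_time_us / 200`, band `Tk` holds
#' `10^k * s < n_trans <= 10^(k+1) * s` (half-open on the left, closed on the
#' right), with `T0` starting at zero exclusive. Algebraically this is
#' identical to fixed waiting-time decades (`T4`: 2-20 ns, `T3`: 20-200 ns,
#' `T2`: 0.2-2 us, `T1`: 2-20 us, `T0`: 20-200 us) for any total time; at
#' 200 us total time the `n_trans` boundaries are 10, 100, 1000, 1e4, 1e5.
#' DOFs with no observed transition, or more transitions than the `T4`
#' ceiling, are `"excluded"` (the latter with a warning).
#'
#' @param n_trans Transition count (vectorized).
#' @param total_time_us Total simulated time in microseconds.
#' @return Character vector of `"T0"`..`"T4"` or `"excluded"`.
#' @export
#' @examples
#' assign_band(50, 200)    # "T1"
#' assign_band(1000, 200)  # "T2" (right boundary inclusive)
assign_band <- function(n_trans, total_time_us) {
  s <- total_time_us / 200
  edges <- 10^(1:5) * s
  band <- rep("excluded", length(n_trans))
  band[n_trans > 0 & n_trans <= edges[1]] <- "T0"
  for (k in 1:4) {
    band[n_trans > edges[k] & n_trans <= edges[k + 1]] <- paste0("T", k)
  }
  if (any(n_trans > edges[5])) {
    warning(sum(n_trans > edges[5]), " DOF(s) exceed the T4 transition-count",
            " ceiling and are excluded")
  }
  band
}

#' Per-DOF transition counts, waiting times and temporal-resolution bands
#'
#' @param states Assigned state tibble (see [assign_states()]).
#' @param frame_interval_ps Frame interval in picoseconds; defaults to the
#'   ensemble attribute.
#' @param dofs Optional subset of DOF ids (e.g. from
#'   [select_clustering_dofs()]).
#' @return A tibble of class `dof_timescales`: `dof_id`, `n_trans`,
#'   `total_time_us`, `t_w_us`, `band`.
#' @export
dof_timescales <- function(states, frame_interval_ps = NULL, dofs = NULL) {
  if (is.null(frame_interval_ps)) frame_interval_ps <- frame_interval_ps(states)
  if (!is.null(dofs)) states <- states[states$dof_id %in% dofs, ]
  counts <- count_transitions(states)
  n_frames_total <- nrow(states) / dplyr::n_distinct(states$dof_id)
  total_us <- n_frames_total * frame_interval_ps * 1e-6
  out <- counts |>
    dplyr::mutate(total_time_us = total_us,
                  t_w_us = waiting_time(total_us, .data$n_trans),
                  band = assign_band(.data$n_trans, total_us))
  class(out) <- c("dof_timescales", class(out))
  out
}

# order bands coarse -> fine; excluded last
band_rank <- function(band) match(band, band_levels)

#' DOFs participating at a temporal resolution
#'
#' Clustering at resolution `Tk` uses the DOFs whose band is `Tk` or coarser;
#' faster DOFs are treated as single-state and excluded.
#'
#' @param timescales A `dof_timescales` tibble.
#' @param resolution `"T0"`..`"T4"`.
#' @return `dof_id`s ordered by (band coarse-to-fine, then `dof_id`) — the
#'   fixed ordering used for the bit encoding.
#' @export
participating_dofs <- function(timescales, resolution) {
  resolution <- match.arg(resolution, band_levels[1:5])
  keep <- timescales$band != "excluded" &
    band_rank(timescales$band) <= band_rank(resolution)
  sel <- timescales[keep, ]
  sel$dof_id[order(band_rank(sel$band), sel$dof_id)]
}
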