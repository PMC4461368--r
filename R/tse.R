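#' Derive transition-state arcs around effective minima
#'
#' For DOFs in the fine bands (`T3`, `T4`) the transition-state region of each
#' effective minimum is the fixed 5-degree arc (2.5 degrees to each side). For
#' the coarse bands (`T0`-`T2`) the arc is grown bin-by-bin in 2.5-degree bins
#' on each side of the minimum: with flank counts `N1, N2, N3, ...` (snapshots
#' per bin, moving away from the minimum), the side stops at the first `i`
#' where `N[i+2] - N[i+1] >= ratio_threshold * (N[i+1] - N[i])` with both
#' differences positive, and bins `1..i+1` are included. The sharp rise in
#' counts marks the end of the sparsely populated barrier region.
#'
#' @param ensemble A `dihedral_ensemble` tibble (angles pooled per DOF supply
#'   the 2.5-degree flank counts).
#' @param fit A `torsion_state_fit`.
#' @param timescales A `dof_timescales` tibble (band per DOF).
#' @param ratio_threshold Quantification of the "much greater" flank-count
#'   jump; default 3.
#' @param min_flank_count Bins with fewer snapshots than this never terminate
#'   growth (default 10).
#' @param max_bins Per-side growth cap in 2.5-degree bins (default 12); when
#'   growth cannot be resolved (fewer than 3 usable flanking bins, or no jump
#'   found) the fixed 5-degree arc is used with a warning.
#' @param dofs Optional subset of DOF ids (default: all DOFs with a band).
#' @return A tibble of class `tse_regions`: `dof_id`, `minimum`, `start`,
#'   `end`, `derivation` (`"fixed_5deg"` or `"curvature"`), `bins_minus`,
#'   `bins_plus`. The arcs are also attached to the models in `fit` via the
#'   returned attribute `fit`.
#' @export
derive_tse_regions <- function(ensemble, fit, timescales, ratio_threshold = 3,
                               min_flank_count = 10, max_bins = 12,
                               dofs = NULL) {
  if (is.null(dofs)) {
    dofs <- timescales$dof_id[timescales$band != "excluded"]
  }
  dofs <- intersect(dofs, names(fit$models))
  out <- purrr::map_dfr(dofs, function(d) {
    m <- fit$models[[d]]
    if (length(m$effective_minima) == 0) return(NULL)
    band <- timescales$band[match(d, timescales$dof_id)]
    ang <- ensemble$angle[ensemble$dof_id == d]
    purrr::map_dfr(m$effective_minima, function(mn) {
      if (band %in% c("T3", "T4")) {
        return(tibble::tibble(dof_id = d, minimum = mn,
                              start = normalize_angle(mn - 2.5),
                              end = normalize_angle(mn + 2.5),
                              derivation = "fixed_5deg",
                              bins_minus = 1L, bins_plus = 1L))
      }
      half_gap <- min(circular_distance(mn,
                                        setdiff(m$effective_minima, mn)))
      usable <- floor(min(max_bins, half_gap / 2 / 2.5))
      grow <- function(side) {
        if (usable < 3) return(NA_integer_)
        counts <- vapply(seq_len(usable), function(i) {
          lo <- mn + side * 2.5 * (i - 1)
          hi <- mn + side * 2.5 * i
          if (side > 0) sum(in_arc(ang, lo, hi)) else sum(in_arc(ang, hi, lo))
        }, numeric(1))
        for (i in seq_len(usable - 2)) {
          d1 <- counts[i + 1] - counts[i]
          d2 <- counts[i + 2] - counts[i + 1]
          if (d1 > 0 && d2 > 0 && d2 >= ratio_threshold * d1 &&
              counts[i + 2] >= min_flank_count) {
            return(i + 1L)
          }
        }
        NA_integer_
      }
      bp <- grow(+1); bm <- grow(-1)
      if (is.na(bp) || is.na(bm)) {
        warning("DOF ", d, ", minimum ", mn, ": flank-count jump not ",
                "resolvable; falling back to the fixed 5-degree arc")
        bp <- 1L; bm <- 1L
        deriv <- "fixed_5deg"
      } else {
        deriv <- "curvature"
      }
      tibble::tibble(dof_id = d, minimum = mn,
                     start = normalize_angle(mn - 2.5 * bm),
                     end = normalize_angle(mn + 2.5 * bp),
                     derivation = deriv, bins_minus = bm, bins_plus = bp)
    })
  })
  if (nrow(out) == 0) {
    out <- tibble::tibble(dof_id = character(0), minimum = numeric(0),
                          start = numeric(0), end = numeric(0),
                          derivation = character(0),
                          bins_minus = integer(0), bins_plus = integer(0))
  }
  class(out) <- c("tse_regions", class(out))
  for (d in unique(out$dof_id)) {
    fit$models[[d]]$tse_arcs <- out[out$dof_id == d,
                                    c("minimum", "start", "end")]
  }
  attr(out, "fit") <- fit
  out
}

# per-side flank growth on an explicit count vector (exposed for testing the
# stated inequality directly)
tse_flank_bins <- function(counts, ratio_threshold = 3, min_flank_count = 0) {
  n <- length(counts)
  if (n < 3) return(NA_integer_)
  for (i in seq_len(n - 2)) {
    d1 <- counts[i + 1] - counts[i]
    d2 <- counts[i + 2] - counts[i + 1]
    if (d1 > 0 && d2 > 0 && d2 >= ratio_threshold * d1 &&
        counts[i + 2] >= min_flank_count) {
      return(i + 1L)
    }
  }
  NA_integer_
}

#' Label transition-state-ensemble events
#'
#' A maximal run of consecutive frames whose angle lies inside a DOF's
#' transition-state arc is an event if and only if the frames immediately
#' before and after the run belong to different conformational substates at
#' the given resolution (a torsional excursion that returns to the same
#' cluster is not a transition state). Runs touching a trajectory boundary
#' are never events. The event's lifetime is the number of in-arc frames
#' times the frame interval.
#'
#' @param ensemble A `dihedral_ensemble` tibble.
#' @param regions A `tse_regions` tibble (see [derive_tse_regions()]).
#' @param hierarchy A `cluster_hierarchy`.
#' @param resolution Band whose cluster keys flank the events.
#' @param frame_interval Frame interval in ps; default from the ensemble.
#' @return A tibble of class `tse_events`: `trajectory_id`, `dof_id`,
#'   `start_frame`, `end_frame`, `n_frames`, `lifetime_ps`, `from_key`,
#'   `to_key`, `resolution`.
#' @export
label_tse_events <- function(ensemble, regions, hierarchy, resolution,
                             frame_interval = NULL) {
  if (is.null(frame_interval)) frame_interval <- frame_interval_ps(ensemble)
  fk <- hierarchy$frame_keys
  keys <- fk[[resolution]]
  if (is.null(keys)) stop("resolution ", resolution, " not in hierarchy")
  key_index <- stats::setNames(seq_len(nrow(fk)),
                               paste(fk$trajectory_id, fk$frame))
  out <- purrr::map_dfr(unique(regions$dof_id), function(d) {
    arcs <- regions[regions$dof_id == d, ]
    dat <- ensemble[ensemble$dof_id == d, ]
    purrr::map_dfr(split(dat, dat$trajectory_id), function(tr) {
      tr <- tr[order(tr$frame), ]
      inside <- rep(FALSE, nrow(tr))
      for (i in seq_len(nrow(arcs))) {
        inside <- inside | in_arc(tr$angle, arcs$start[i], arcs$end[i])
      }
      if (!any(inside)) return(NULL)
      r <- rle(inside)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      runs <- which(r$values)
      tr_keys <- keys[key_index[paste(tr$trajectory_id, tr$frame)]]
      purrr::map_dfr(runs, function(j) {
        i0 <- starts[j]; i1 <- ends[j]
        if (i0 == 1L || i1 == nrow(tr)) return(NULL)  # trajectory edge
        k_before <- tr_keys[i0 - 1L]
        k_after <- tr_keys[i1 + 1L]
        if (identical(k_before, k_after)) return(NULL)
        tibble::tibble(trajectory_id = tr$trajectory_id[1], dof_id = d,
                       start_frame = tr$frame[i0], end_frame = tr$frame[i1],
                       n_frames = i1 - i0 + 1L,
                       lifetime_ps = (i1 - i0 + 1L) * frame_interval,
                       from_key = as.character(k_before),
                       to_key = as.character(k_after),
                       resolution = resolution)
      })
    })
  })
  if (nrow(out) == 0) {
    out <- tibble::tibble(trajectory_id = character(0), dof_id = character(0),
                          start_frame = integer(0), end_frame = integer(0),
                          n_frames = integer(0), lifetime_ps = numeric(0),
                          from_key = character(0), to_key = character(0),
                          resolution = character(0))
  }
  class(out) <- c("tse_events", class(out))
  out
}

#' Lifetime statistics of transition-state-ensemble events
#'
#' @param events A `tse_events` tibble.
#' @param by Grouping: `"resolution"`, `"dof"`, or `"band"` (requires a
#'   `band` column or `timescales`).
#' @param timescales Optional `dof_timescales` tibble for `by = "band"`.
#' @return A tibble: group, `n_events`, `mean_lifetime_ps` (LT_avg),
#'   `median_lifetime_ps`. Groups without events are simply absent.
#' @export
lifetime_stats <- function(events, by = c("resolution", "dof", "band"),
                           timescales = NULL) {
  by <- match.arg(by)
  if (nrow(events) == 0) {
    message("no transition-state events to summarize")
    return(tibble::tibble(group = character(0), n_events = integer(0),
                          mean_lifetime_ps = numeric(0),
                          median_lifetime_ps = numeric(0)))
  }
  events$group <- switch(by,
    resolution = events$resolution,
    dof = events$dof_id,
    band = {
      if (is.null(timescales)) stop("by = 'band' needs timescales")
      timescales$band[match(events$dof_id, timescales$dof_id)]
    })
  events |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(n_events = dplyr::n(),
                     mean_lifetime_ps = mean(.data$lifetime_ps),
                     median_lifetime_ps = stats::median(.data$lifetime_ps),
                     .groups = "drop")
}

#' Plot lifetime distributions of transition-state events
#'
#' @param object A `tse_events` tibble.
#' @param by Facet grouping passed to [lifetime_stats()].
#' @param ... Unused.
#' @return A ggplot: lifetime histograms with the group mean marked.
#' @method autoplot tse_events
#' @export
autoplot.tse_events <- function(object, by = c("resolution", "dof"), ...) {
  by <- match.arg(by)
  object <- dplyr::mutate(object, group = if (by == "dof") .data$dof_id
                          else .data$resolution)
  means <- lifetime_stats(object, by = by)
  ggplot2::ggplot(object, ggplot2::aes(x = .data$lifetime_ps)) +
    ggplot2::geom_histogram(binwidth = NULL, bins = 30, fill = "grey40") +
    ggplot2::geom_vline(data = means,
                        ggplot2::aes(xintercept = .data$mean_lifetime_ps),
                        colour = "seagreen", linetype = "dashed") +
    ggplot2::facet_wrap(~group, scales = "free_y") +
    ggplot2::labs(x = "TSE lifetime (ps)", y = "events")
}
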