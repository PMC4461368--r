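#' Build a 1-degree circular angle histogram
#'
#' Counts over 360 one-degree bins, bin `i` (0-based) covering
#' `[-180 + i, -180 + i + 1)` degrees, with circular adjacency between bin 0
#' and bin 359. Angles are pooled across all trajectories of the ensemble.
#'
#' @param angles Numeric vector of angles in (-180, 180], or a
#'   `dihedral_ensemble` tibble (then one histogram per DOF is returned).
#' @return For a numeric vector: an integer vector of length 360 of class
#'   `angle_histogram`. For an ensemble: a tibble with columns `dof_id`,
#'   `bin` (0-based), `bin_start` and `count`.
#' @export
build_histogram <- function(angles) {
  if (is.data.frame(angles)) {
    stopifnot(all(c("dof_id", "angle") %in% names(angles)))
    if (nrow(angles) == 0) stop("empty input: no frames to histogram")
    out <- angles |>
      dplyr::group_by(.data$dof_id) |>
      dplyr::reframe(bin = 0:359,
                     count = as.integer(tabulate(angle_bin(.data$angle) + 1L,
                                                 nbins = 360))) |>
      dplyr::mutate(bin_start = -180 + .data$bin, .after = "bin")
    return(out)
  }
  if (length(angles) == 0) stop("empty input: no frames to histogram")
  counts <- tabulate(angle_bin(angles) + 1L, nbins = 360)
  structure(as.integer(counts), class = "angle_histogram")
}

# circular moving average over an odd window (in degrees = bins)
smooth_circular <- function(counts, window) {
  if (window <= 1) return(as.numeric(counts))
  if (window %% 2 == 0) stop("smoothing window must be odd")
  h <- (window - 1) / 2
  n <- length(counts)
  ext <- c(counts[(n - h + 1):n], counts, counts[1:h])
  as.numeric(stats::filter(ext, rep(1 / window, window), sides = 2))[(h + 1):(h + n)]
}

# local minima (0-based bin indices) of a circular profile; a plateau run of
# equal values lower than both flanks yields its central bin (ties to the
# lower index)
circular_local_minima <- function(y) {
  n <- length(y)
  if (n < 3 || length(unique(y)) == 1) return(integer(0))
  # compress equal-value runs circularly: rotate so position 1 starts a run
  brk <- which(y != c(y[n], y[-n]))  # run starts
  if (length(brk) == 0) return(integer(0))
  rot <- brk[1] - 1L
  yr <- if (rot > 0) c(y[(rot + 1):n], y[1:rot]) else y
  r <- rle(yr)
  vals <- r$values
  k <- length(vals)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  prev <- vals[c(k, seq_len(k - 1))]
  nxt <- vals[c(seq_len(k - 1) + 1L, 1L)]
  is_min <- vals < prev & vals < nxt
  centers <- integer(0)
  for (i in which(is_min)) {
    # central bin of the run, ties to the lower index
    c_rot <- starts[i] + floor((r$lengths[i] - 1) / 2)
    centers <- c(centers, (c_rot - 1L + rot) %% n)
  }
  sort(centers)
}

#' Find effective local minima of a circular angle histogram
#'
#' Detection proceeds in five steps on the (optionally circularly smoothed)
#' 1-degree histogram: (1) raw local minima; (2) minima separated only by an
#' insignificant maximum are collapsed into one valley (`peak_significance`);
#' (3) shallow dips are removed by a prominence filter (`min_prominence`);
#' (4) iterative proximity merging: while any two minima are circularly
#' closer than `merge_distance`, the pair currently closest is resolved by
#' discarding the minimum with the larger probability density, keeping the
#' deeper (smaller-probability) one; (5) each surviving minimum is re-centered
#' at the circular midpoint of its valley floor — the contiguous region below
#' half the lower flanking peak — so that barrier regions carrying some
#' transition-state density still yield a boundary at the barrier top.
#' Returned minima are pairwise at least `merge_distance` apart.
#'
#' @param hist An `angle_histogram` (length-360 counts) or plain numeric
#'   vector of 360 bin counts.
#' @param smoothing_window Odd circular moving-average window in degrees
#'   applied before minima detection; 1 disables smoothing. Default 5.
#' @param merge_distance Minimum circular separation of surviving minima in
#'   degrees (default 60).
#' @param keep Which member of a too-close pair survives: `"deeper"` (the
#'   smaller-probability minimum, the default) or `"shallower"`.
#' @param min_prominence Depth filter: a minimum is kept only if its smoothed
#'   density is at most this fraction of the lower of the two local maxima
#'   flanking it (default 0.5). Removes the shallow dips that sampling noise
#'   produces on finite histograms while keeping true inter-state valleys,
#'   whose density is far below the peaks; 1 disables the filter.
#' @param peak_significance Two adjacent minima whose separating maximum
#'   holds less than this fraction of the total snapshot count in its
#'   highest smoothed bin (default 1e-4) are treated as one valley — stray
#'   counts inside an essentially empty barrier region do not split it — and
#'   the deeper minimum is kept. 0 disables the rule.
#' @param recenter Re-center minima on their valley floors (step 5)?
#'   Default `TRUE`.
#' @return Numeric vector of minima angles in degrees (left bin edges);
#'   possibly empty for flat or unimodal histograms.
#' @export
find_effective_minima <- function(hist, smoothing_window = 5,
                                  merge_distance = 60,
                                  keep = c("deeper", "shallower"),
                                  min_prominence = 0.5,
                                  peak_significance = 1e-4,
                                  recenter = TRUE) {
  keep <- match.arg(keep)
  counts <- as.numeric(unclass(hist))
  if (length(counts) != 360) stop("histogram must have 360 one-degree bins")
  if (sum(counts) <= 0) stop("histogram total must be positive")
  y <- smooth_circular(counts, smoothing_window)
  bins <- circular_local_minima(y)
  seg_maxima <- function(bins) {
    k <- length(bins)
    vapply(seq_len(k), function(i) {
      lo <- bins[i]
      hi <- bins[if (i == k) 1 else i + 1]
      seg <- if (hi > lo) lo:hi else c(lo:359, 0:hi)
      max(y[seg + 1L])
    }, numeric(1))
  }
  # (2) collapse minima separated only by insignificant maxima (stray counts
  # inside an essentially empty barrier region)
  if (peak_significance > 0) {
    # a separating maximum needs at least a few smoothed counts no matter
    # how small the sample
    thr <- max(peak_significance * sum(counts), 3)
    repeat {
      k <- length(bins)
      if (k < 2) break
      seg_max <- seg_maxima(bins)
      weak <- which(seg_max < thr)
      if (length(weak) == 0) break
      i <- weak[1]
      j <- if (i == k) 1L else i + 1L
      di <- y[bins[i] + 1L]; dj <- y[bins[j] + 1L]
      drop <- if (di > dj) i else if (dj > di) j else max(i, j)
      bins <- bins[-drop]
    }
  }
  # (3) drop shallow dips, least prominent first
  if (min_prominence < 1) {
    repeat {
      k <- length(bins)
      if (k < 2) break
      seg_max <- seg_maxima(bins)
      left_max <- seg_max[c(k, seq_len(k - 1))]
      ratio <- y[bins + 1L] / pmax(pmin(left_max, seg_max), .Machine$double.eps)
      if (max(ratio) <= min_prominence) break
      bins <- bins[-which.max(ratio)]
    }
    if (length(bins) == 1) {
      # a single survivor has no flanking structure left to justify it
      peak <- max(y)
      if (y[bins + 1L] > min_prominence * peak) bins <- integer(0)
    }
  }
  if (length(bins) < 2) return(-180 + as.numeric(bins))
  # (4) 60-degree proximity merging
  dens <- y[bins + 1L]
  ang <- -180 + as.numeric(bins)
  repeat {
    if (length(ang) < 2) break
    dmat <- outer(ang, ang, circular_distance)
    diag(dmat) <- Inf
    if (min(dmat) >= merge_distance) break
    ij <- which(dmat == min(dmat), arr.ind = TRUE)[1, ]
    i <- ij[1]; j <- ij[2]
    # discard per the keep rule; density ties discard the higher-index one
    drop <- if (keep == "deeper") {
      if (dens[i] > dens[j]) i else if (dens[j] > dens[i]) j else max(i, j)
    } else {
      if (dens[i] < dens[j]) i else if (dens[j] < dens[i]) j else max(i, j)
    }
    ang <- ang[-drop]; dens <- dens[-drop]
  }
  ang <- sort(ang)
  # (5) re-center each minimum at the circular midpoint of its valley floor
  if (recenter && length(ang) >= 2) {
    bins <- as.integer((ang + 180) %% 360)
    k <- length(bins)
    seg_max <- seg_maxima(bins)
    left_max <- seg_max[c(k, seq_len(k - 1))]
    new_bins <- vapply(seq_len(k), function(i) {
      floor_thr <- 0.5 * min(left_max[i], seg_max[i])
      lo <- bins[i]
      hi <- bins[i]
      while (y[((lo - 1L) %% 360) + 1L] <= floor_thr &&
             (bins[i] - lo) %% 360 < 179) lo <- (lo - 1L) %% 360
      while (y[((hi + 1L) %% 360) + 1L] <= floor_thr &&
             (hi - bins[i]) %% 360 < 179) hi <- (hi + 1L) %% 360
      span <- (hi - lo) %% 360
      as.integer((lo + floor(span / 2)) %% 360)
    }, integer(1))
    ang <- sort(-180 + as.numeric(unique(new_bins)))
    # recentering can in principle move a pair closer than the threshold
    while (length(ang) >= 2) {
      dmat <- outer(ang, ang, circular_distance)
      diag(dmat) <- Inf
      if (min(dmat) >= merge_distance) break
      ij <- which(dmat == min(dmat), arr.ind = TRUE)[1, ]
      dd <- y[as.integer((ang + 180) %% 360) + 1L]
      i <- ij[1]; j <- ij[2]
      drop <- if (dd[i] > dd[j]) i else if (dd[j] > dd[i]) j else max(i, j)
      ang <- ang[-drop]
    }
  }
  sort(ang)
}

#' Define torsional states from effective minima
#'
#' With two or more minima the circle is split into cyclic half-open arcs
#' `[start, end)` between consecutive minima; each arc is one torsional state
#' with an occupancy fraction taken from the histogram. With fewer than two
#' minima the whole circle is a single state. State indices are assigned by
#' descending occupancy (index 0 = most populated), which makes the
#' downstream bit encoding stable and data driven.
#'
#' @param minima Numeric vector of minima angles (degrees).
#' @param hist Length-360 bin counts (see [build_histogram()]).
#' @param dof_id Optional identifier stored in the model.
#' @return A list of class `torsion_state_model` with elements `dof_id`,
#'   `effective_minima`, `n_states`, `arcs` (tibble: `state`, `start`, `end`,
#'   `occupancy`) and `tse_arcs` (filled by [derive_tse_regions()]).
#' @export
define_states <- function(minima, hist, dof_id = NA_character_) {
  counts <- as.numeric(unclass(hist))
  total <- sum(counts)
  minima <- sort(normalize_angle(minima))
  if (length(minima) < 2) {
    arcs <- tibble::tibble(state = 0L, start = -180, end = 180, occupancy = 1)
    mod <- list(dof_id = dof_id, effective_minima = minima, n_states = 1L,
                arcs = arcs, tse_arcs = NULL)
    class(mod) <- "torsion_state_model"
    return(mod)
  }
  k <- length(minima)
  starts <- minima
  ends <- c(minima[-1], minima[1])
  occ <- vapply(seq_len(k), function(i) {
    bin_edges <- -180 + 0:359
    sum(counts[in_arc(bin_edges, starts[i], ends[i])]) / max(total, 1)
  }, numeric(1))
  ord <- order(-occ, starts)  # rank by descending occupancy, ties by start
  state <- integer(k)
  state[ord] <- seq_len(k) - 1L
  arcs <- tibble::tibble(state = state, start = starts, end = ends,
                         occupancy = occ)
  mod <- list(dof_id = dof_id, effective_minima = minima,
              n_states = k, arcs = arcs, tse_arcs = NULL)
  class(mod) <- "torsion_state_model"
  mod
}

# state index for a vector of angles under one torsion_state_model
assign_states_vec <- function(angles, model) {
  bad <- !is.finite(angles) | angles <= -180 | angles > 180
  if (any(bad)) stop("angle outside (-180, 180]: ", angles[which(bad)[1]])
  arcs <- model$arcs
  if (nrow(arcs) == 1) return(rep(0L, length(angles)))
  bnd <- sort(arcs$start)
  # arcs are [minima_i, minima_{i+1}); angles below the first boundary wrap
  # onto the last arc
  idx <- findInterval(angles, bnd)
  idx[idx == 0L] <- length(bnd)
  # map arc (by start boundary) to its state index
  state_of_start <- arcs$state[order(arcs$start)]
  state_of_start[idx]
}

#' Fit per-DOF torsional-state models for an ensemble
#'
#' Pools each DOF's angles over all trajectories, builds the 1-degree
#' circular histogram, finds effective minima (60-degree proximity merging)
#' and defines the cyclic state arcs.
#'
#' @param ensemble A `dihedral_ensemble` tibble.
#' @inheritParams find_effective_minima
#' @return An object of class `torsion_state_fit`: a named list of
#'   `torsion_state_model`s plus the histograms and fitting parameters.
#'   Methods: [tidy.torsion_state_fit()], [glance.torsion_state_fit()],
#'   [autoplot.torsion_state_fit()].
#' @export
fit_torsion_states <- function(ensemble, smoothing_window = 5,
                               merge_distance = 60,
                               keep = c("deeper", "shallower"),
                               min_prominence = 0.5,
                               peak_significance = 1e-4) {
  keep <- match.arg(keep)
  stopifnot(all(c("dof_id", "angle") %in% names(ensemble)))
  dof_ids <- unique(ensemble$dof_id)
  hists <- lapply(dof_ids, function(d) {
    build_histogram(ensemble$angle[ensemble$dof_id == d])
  })
  names(hists) <- dof_ids
  models <- lapply(dof_ids, function(d) {
    mins <- find_effective_minima(hists[[d]], smoothing_window,
                                  merge_distance, keep, min_prominence,
                                  peak_significance)
    define_states(mins, hists[[d]], dof_id = d)
  })
  names(models) <- dof_ids
  structure(list(models = models, histograms = hists,
                 params = list(smoothing_window = smoothing_window,
                               merge_distance = merge_distance, keep = keep,
                               min_prominence = min_prominence,
                               peak_significance = peak_significance)),
            class = "torsion_state_fit")
}

#' @export
print.torsion_state_fit <- function(x, ...) {
  ns <- vapply(x$models, `[[`, integer(1), "n_states")
  cat("<torsion_state_fit> ", length(ns), " DOFs; state counts: ",
      paste(names(table(ns)), "state:", table(ns), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Assign every frame its torsional state
#'
#' Each frame's angle is mapped to the index of the cyclic arc containing it;
#' arcs are half-open `[start, end)`, so an angle exactly on a minimum belongs
#' to the arc starting there.
#'
#' @param ensemble A `dihedral_ensemble` tibble.
#' @param fit A `torsion_state_fit` (or a single `torsion_state_model` when
#'   `ensemble` holds one DOF).
#' @return The input tibble with an integer `state` column appended.
#' @export
assign_states <- function(ensemble, fit) {
  stopifnot(all(c("dof_id", "angle") %in% names(ensemble)))
  if (inherits(fit, "torsion_state_model")) {
    fit <- structure(list(models = stats::setNames(list(fit),
                                                   unique(ensemble$dof_id)[1])),
                     class = "torsion_state_fit")
  }
  missing <- setdiff(unique(ensemble$dof_id), names(fit$models))
  if (length(missing)) stop("no state model for DOF: ", missing[1])
  st <- integer(nrow(ensemble))
  for (d in unique(ensemble$dof_id)) {
    sel <- ensemble$dof_id == d
    st[sel] <- assign_states_vec(ensemble$angle[sel], fit$models[[d]])
  }
  out <- dplyr::mutate(ensemble, state = st)
  for (a in c("frame_interval_ps", "dof_info")) {
    attr(out, a) <- attr(ensemble, a, exact = TRUE)
  }
  out
}

#' Select DOFs eligible for clustering
#'
#' Backbone mode keeps DOFs with exactly two torsional states (two effective
#' minima); side-chain mode additionally admits three-state DOFs (chi
#' rotamers).
#'
#' @param fit A `torsion_state_fit`.
#' @param mode `"backbone"` (two-state only) or `"sidechain"` (two- and
#'   three-state).
#' @return Character vector of eligible `dof_id`s.
#' @export
select_clustering_dofs <- function(fit, mode = c("backbone", "sidechain")) {
  mode <- match.arg(mode)
  ns <- vapply(fit$models, `[[`, integer(1), "n_states")
  admit <- if (mode == "backbone") ns == 2L else ns %in% c(2L, 3L)
  names(ns)[admit]
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy and summarize torsional-state fits
#'
#' `tidy()` returns one row per (DOF, state arc); `glance()` one row per DOF.
#'
#' @param x A `torsion_state_fit`.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy torsion_state_fit
#' @export
tidy.torsion_state_fit <- function(x, ...) {
  purrr::map_dfr(x$models, function(m) {
    dplyr::mutate(m$arcs, dof_id = m$dof_id, n_states = m$n_states,
                  .before = 1)
  })
}

#' @rdname tidy.torsion_state_fit
#' @method glance torsion_state_fit
#' @export
glance.torsion_state_fit <- function(x, ...) {
  purrr::map_dfr(x$models, function(m) {
    tibble::tibble(dof_id = m$dof_id, n_states = m$n_states,
                   n_minima = length(m$effective_minima),
                   top_occupancy = max(m$arcs$occupancy))
  })
}

#' Plot per-DOF angle histograms with detected minima
#'
#' @param object A `torsion_state_fit`.
#' @param dofs Optional subset of DOF ids to plot.
#' @param ... Unused.
#' @return A ggplot object: 1-degree histograms with state-boundary minima as
#'   dashed vertical lines, one facet per DOF.
#' @method autoplot torsion_state_fit
#' @export
autoplot.torsion_state_fit <- function(object, dofs = NULL, ...) {
  ids <- names(object$models)
  if (!is.null(dofs)) ids <- intersect(ids, dofs)
  hist_df <- purrr::map_dfr(ids, function(d) {
    tibble::tibble(dof_id = d, angle = -180 + 0:359 + 0.5,
                   count = as.numeric(unclass(object$histograms[[d]])))
  })
  min_df <- purrr::map_dfr(ids, function(d) {
    tibble::tibble(dof_id = d, minimum = object$models[[d]]$effective_minima)
  })
  ggplot2::ggplot(hist_df, ggplot2::aes(x = .data$angle, y = .data$count)) +
    ggplot2::geom_col(width = 1, fill = "grey40") +
    ggplot2::geom_vline(data = min_df,
                        ggplot2::aes(xintercept = .data$minimum),
                        linetype = "dashed", colour = "firebrick") +
    ggplot2::facet_wrap(~dof_id, scales = "free_y") +
    ggplot2::labs(x = "dihedral angle (degrees)", y = "snapshots")
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Write torsional-state models to TSV
#'
#' One row per (DOF, state): minima list, arc bounds and occupancy.
#'
#' @param fit A `torsion_state_fit`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_state_models <- function(fit, path) {
  td <- tidy(fit)
  td$minima <- vapply(td$dof_id, function(d) {
    paste(fit$models[[d]]$effective_minima, collapse = ",")
  }, character(1))
  utils::write.table(td, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
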