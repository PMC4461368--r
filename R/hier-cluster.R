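# wide (frames x dofs) integer state matrix in the given DOF order, with
# trajectory_id/frame row metadata; errors on missing states
states_wide <- function(states, dofs) {
  sel <- states[states$dof_id %in% dofs,
                c("trajectory_id", "frame", "dof_id", "state")]
  wide <- tidyr::pivot_wider(sel, names_from = "dof_id",
                             values_from = "state")
  missing_cols <- setdiff(dofs, names(wide))
  if (length(missing_cols)) stop("no states for DOF ", missing_cols[1])
  wide <- wide[order(wide$trajectory_id, wide$frame), ]
  m <- as.matrix(wide[, dofs, drop = FALSE])
  if (anyNA(m)) {
    ij <- which(is.na(m), arr.ind = TRUE)[1, ]
    stop("missing state for DOF ", dofs[ij[2]], " at frame ",
         wide$frame[ij[1]], " of ", wide$trajectory_id[ij[1]])
  }
  list(meta = wide[, c("trajectory_id", "frame")], states = m)
}

# bit layout for a resolution: coarsest band first, then dof_id; 1 bit for
# two-state DOFs, 2 bits for multi-state DOFs (fourth code unused)
key_layout <- function(timescales, resolution, n_states_per_dof) {
  dofs <- participating_dofs(timescales, resolution)
  if (length(dofs) == 0) stop("no participating DOFs at resolution ",
                              resolution)
  ns <- unname(n_states_per_dof[dofs])
  bits <- ifelse(ns > 2L, 2L, 1L)
  total <- sum(bits)
  # shift of each DOF: coarsest DOF occupies the most significant bits
  shift <- rev(cumsum(rev(bits))) - bits
  tibble::tibble(dof_id = dofs,
                 band = timescales$band[match(dofs, timescales$dof_id)],
                 n_states = as.integer(ns), bits = bits, shift = shift,
                 total_bits = total)
}

encode_matrix <- function(m, layout) {
  if (layout$total_bits[1] <= 52) {
    as.vector(m %*% 2^layout$shift)
  } else {
    # byte-string fallback with identical grouping semantics
    apply(m, 1, paste, collapse = "-")
  }
}

#' Bit-encode frames into conformational-substate keys
#'
#' At resolution `Tk` only DOFs whose band is `Tk` or coarser participate;
#' each contributes one bit (two-state) or two bits (three-state mode) to an
#' integer key, coarsest band first then `dof_id`. Keys wider than the native
#' double-precision integer range fall back to string keys with identical
#' grouping semantics.
#'
#' @param states Assigned state tibble (see [assign_states()]).
#' @param timescales A `dof_timescales` tibble.
#' @param resolution `"T0"`..`"T4"`.
#' @param n_states_per_dof Optional named integer vector (from the state fit);
#'   defaults to `max(state) + 1` per DOF.
#' @return A tibble `trajectory_id`, `frame`, `key`, ordered by trajectory
#'   and frame, with the bit layout attached as attribute `layout`.
#' @export
encode_frames <- function(states, timescales, resolution,
                          n_states_per_dof = NULL) {
  if (is.null(n_states_per_dof)) {
    n_states_per_dof <- states |>
      dplyr::group_by(.data$dof_id) |>
      dplyr::summarise(n = max(.data$state) + 1L, .groups = "drop") |>
      (\(d) stats::setNames(as.integer(d$n), d$dof_id))()
  }
  layout <- key_layout(timescales, resolution, n_states_per_dof)
  sw <- states_wide(states, layout$dof_id)
  out <- dplyr::mutate(sw$meta, key = encode_matrix(sw$states, layout))
  attr(out, "layout") <- layout
  out
}

#' Group frames into conformational substates by exact key
#'
#' Radix-style grouping of the encoded keys (sort + run-length encoding on
#' machine integers); equivalent to naive exact-key grouping but linear-time.
#'
#' @param keys Vector of frame keys, or the tibble returned by
#'   [encode_frames()].
#' @return A tibble `key`, `count`, `W` (statistical weight, summing to 1),
#'   in descending weight order.
#' @export
#' @examples
#' cluster_frames(c(3, 3, 1, 3)) # key 3: W = 0.75, key 1: W = 0.25
cluster_frames <- function(keys) {
  if (is.data.frame(keys)) keys <- keys$key
  if (length(keys) == 0) stop("no frames to cluster")
  o <- order(keys, method = "radix")
  r <- rle(keys[o])
  tab <- tibble::tibble(key = r$values, count = r$lengths,
                        W = r$lengths / length(keys))
  dplyr::arrange(tab, dplyr::desc(.data$count), .data$key)
}

# parent key of child keys: drop the bits of DOFs finer than the parent
# resolution (the parent's DOF set is a bit-prefix of the child's)
parent_keys <- function(keys, child_layout, parent_layout) {
  if (!all(parent_layout$dof_id == child_layout$dof_id[
    seq_len(nrow(parent_layout))])) {
    stop("inconsistent DOF ordering between resolutions")
  }
  drop_bits <- child_layout$total_bits[1] - parent_layout$total_bits[1]
  if (is.numeric(keys)) {
    keys %/% 2^drop_bits
  } else {
    n_parent <- nrow(parent_layout)
    vapply(strsplit(keys, "-", fixed = TRUE),
           function(s) paste(s[seq_len(n_parent)], collapse = "-"),
           character(1))
  }
}

#' Hierarchical conformational-substate clustering across temporal resolutions
#'
#' Encodes and groups every frame at each requested resolution and links
#' consecutive resolutions: each fine cluster's parent is its key restricted
#' to the coarser resolution's DOFs, so the fine partition refines the coarse
#' one exactly.
#'
#' @param states Assigned state tibble.
#' @param timescales A `dof_timescales` tibble.
#' @param resolutions Bands to cluster at; default: every band from the
#'   coarsest present to the finest present in `timescales`.
#' @param n_states_per_dof Optional named integer vector of state counts.
#' @return An object of class `cluster_hierarchy`: per-resolution cluster
#'   tables (`key`, `count`, `W`, `parent_key`, `harbors_reference`),
#'   per-frame keys, and the bit layouts. Methods: `tidy()`, `glance()`,
#'   `autoplot()`.
#' @export
cluster_hierarchy <- function(states, timescales, resolutions = NULL,
                              n_states_per_dof = NULL) {
  present <- sort(unique(band_rank(
    timescales$band[timescales$band != "excluded"])))
  if (length(present) == 0) stop("no DOFs in any temporal band")
  if (is.null(resolutions)) {
    resolutions <- band_levels[seq(min(present), max(present))]
  }
  resolutions <- band_levels[sort(match(resolutions, band_levels))]
  frame_keys <- NULL
  layouts <- list()
  tables <- list()
  for (res in resolutions) {
    enc <- encode_frames(states, timescales, res, n_states_per_dof)
    layouts[[res]] <- attr(enc, "layout")
    if (is.null(frame_keys)) {
      frame_keys <- enc[, c("trajectory_id", "frame")]
    }
    frame_keys[[res]] <- enc$key
    tables[[res]] <- cluster_frames(enc$key)
  }
  for (i in seq_along(resolutions)) {
    res <- resolutions[i]
    tab <- tables[[res]]
    if (i == 1) {
      tab$parent_key <- tab$key  # identity mapping at the coarsest level
    } else {
      tab$parent_key <- parent_keys(tab$key, layouts[[res]],
                                    layouts[[resolutions[i - 1]]])
    }
    tab$harbors_reference <- FALSE
    tables[[res]] <- tab
  }
  structure(list(tables = tables, frame_keys = frame_keys,
                 layouts = layouts, resolutions = resolutions,
                 n_frames = nrow(frame_keys)),
            class = "cluster_hierarchy")
}

#' @export
print.cluster_hierarchy <- function(x, ...) {
  cat("<cluster_hierarchy> ", x$n_frames, " frames\n", sep = "")
  for (res in x$resolutions) {
    cat("  ", res, ": ", nrow(x$tables[[res]]), " clusters (",
        nrow(x$layouts[[res]]), " DOFs)\n", sep = "")
  }
  invisible(x)
}

#' @rdname cluster_hierarchy
#' @param x,object A `cluster_hierarchy`.
#' @param ... Unused.
#' @method tidy cluster_hierarchy
#' @export
tidy.cluster_hierarchy <- function(x, ...) {
  purrr::imap_dfr(x$tables, function(tab, res) {
    dplyr::mutate(tab, resolution = res, .before = 1,
                  key = as.character(.data$key),
                  parent_key = as.character(.data$parent_key))
  })
}

#' @rdname cluster_hierarchy
#' @method glance cluster_hierarchy
#' @export
glance.cluster_hierarchy <- function(x, ...) {
  purrr::imap_dfr(x$tables, function(tab, res) {
    tibble::tibble(resolution = res, n_clusters = nrow(tab),
                   n_dofs = nrow(x$layouts[[res]]),
                   top_W = tab$W[1],
                   W_sum_top10 = sum(utils::head(tab$W, 10)))
  })
}

#' @rdname cluster_hierarchy
#' @method autoplot cluster_hierarchy
#' @export
autoplot.cluster_hierarchy <- function(object, ...) {
  df <- purrr::imap_dfr(object$tables, function(tab, res) {
    tibble::tibble(resolution = res, rank = seq_len(nrow(tab)), W = tab$W)
  })
  ggplot2::ggplot(df, ggplot2::aes(x = .data$rank, y = .data$W,
                                   colour = .data$resolution)) +
    ggplot2::geom_step() +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "cluster rank", y = "statistical weight W",
                  colour = "resolution")
}

#' Parent linkage between two consecutive resolutions
#'
#' @param hierarchy A `cluster_hierarchy`.
#' @param resolution A fine resolution present in the hierarchy.
#' @return Tibble `key`, `parent_key`, `count`; each fine cluster maps to
#'   exactly one coarse cluster and coarse counts equal summed child counts.
#' @export
cluster_parents <- function(hierarchy, resolution) {
  tab <- hierarchy$tables[[resolution]]
  if (is.null(tab)) stop("resolution ", resolution, " not in hierarchy")
  tab[, c("key", "parent_key", "count")]
}

#' Assign an external structure to a conformational substate
#'
#' Computes the structure's key exactly as for a trajectory frame and reports
#' the matching cluster, or an "unvisited" verdict when no simulation frame
#' carries that key. A structure whose angle falls inside a transition-state
#' arc of some participating DOF is flagged as a boundary assignment (the
#' state itself is still assigned by the half-open arc rule).
#'
#' @param angles Named numeric vector: one dihedral angle (degrees) per
#'   participating DOF.
#' @param fit A `torsion_state_fit` (with TSE arcs attached if boundary
#'   flagging is wanted, see [derive_tse_regions()]).
#' @param timescales A `dof_timescales` tibble.
#' @param hierarchy A `cluster_hierarchy`.
#' @param resolution Band at which to assign.
#' @return A one-row tibble: `key`, `verdict` (`"member"` or `"unvisited"`),
#'   `W`, `boundary` (logical).
#' @export
assign_external_structure <- function(angles, fit, timescales, hierarchy,
                                      resolution) {
  layout <- hierarchy$layouts[[resolution]]
  if (is.null(layout)) stop("resolution ", resolution, " not in hierarchy")
  missing <- setdiff(layout$dof_id, names(angles))
  if (length(missing)) stop("missing dihedral for DOF ", missing[1])
  st <- vapply(layout$dof_id, function(d) {
    assign_states_vec(normalize_angle(angles[[d]]), fit$models[[d]])
  }, integer(1))
  key <- encode_matrix(matrix(st, nrow = 1), layout)
  tab <- hierarchy$tables[[resolution]]
  hit <- match(key, tab$key)
  boundary <- any(vapply(layout$dof_id, function(d) {
    ta <- fit$models[[d]]$tse_arcs
    if (is.null(ta) || nrow(ta) == 0) return(FALSE)
    any(vapply(seq_len(nrow(ta)), function(i) {
      in_arc(normalize_angle(angles[[d]]), ta$start[i], ta$end[i])
    }, logical(1)))
  }, logical(1)))
  tibble::tibble(key = key,
                 verdict = ifelse(is.na(hit), "unvisited", "member"),
                 W = ifelse(is.na(hit), 0, tab$W[hit]),
                 boundary = boundary)
}

#' Flag clusters harboring reference structures
#'
#' @param hierarchy A `cluster_hierarchy`.
#' @param reference_angles A list of named angle vectors (one per reference
#'   structure), or a data frame with columns `structure_id`, `dof_id`,
#'   `angle`.
#' @param fit,timescales As in [assign_external_structure()].
#' @return The hierarchy with `harbors_reference` set on every resolution's
#'   table.
#' @export
flag_reference_clusters <- function(hierarchy, reference_angles, fit,
                                    timescales) {
  if (is.data.frame(reference_angles)) {
    reference_angles <- split(
      stats::setNames(reference_angles$angle, reference_angles$dof_id),
      reference_angles$structure_id)
  }
  for (res in hierarchy$resolutions) {
    keys <- vapply(reference_angles, function(a) {
      as.character(assign_external_structure(a, fit, timescales, hierarchy,
                                             res)$key)
    }, character(1))
    tab <- hierarchy$tables[[res]]
    tab$harbors_reference <- as.character(tab$key) %in% keys
    hierarchy$tables[[res]] <- tab
  }
  hierarchy
}

#' Write cluster tables to TSV
#'
#' @param hierarchy A `cluster_hierarchy`.
#' @param dir Output directory (one file per resolution); created if absent.
#' @return The file paths, invisibly.
#' @export
write_cluster_tables <- function(hierarchy, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)
  for (res in hierarchy$resolutions) {
    tab <- hierarchy$tables[[res]]
    out <- tab
    out$key <- format_key(out$key)
    out$parent_key <- format_key(out$parent_key)
    p <- file.path(dir, paste0("clusters_", res, ".tsv"))
    layout_line <- paste0("# dof_order\t",
                          paste(hierarchy$layouts[[res]]$dof_id,
                                collapse = ","))
    writeLines(layout_line, p)
    suppressWarnings(utils::write.table(out, p, sep = "\t", quote = FALSE,
                                        row.names = FALSE, append = TRUE))
    paths <- c(paths, p)
  }
  invisible(paths)
}

# hex-printable keys when they fit in 31 bits; wider keys stay decimal/string
format_key <- function(x) {
  if (is.numeric(x) && all(x < 2^31)) sprintf("%x", as.integer(x))
  else as.character(x)
}
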