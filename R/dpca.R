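#' Dihedral principal component analysis
#'
#' Represents circular backbone dihedrals by trigonometric variables and
#' diagonalizes their covariance matrix. Two representations are available:
#'
#' * `"compact"` — `q_{2i-1} = cos(phi_i)`, `q_{2i} = sin(psi_i)`: one cosine
#'   per phi and one sine per psi. Compact, but maps `phi` and `-phi` to the
#'   same variable.
#' * `"full_sincos"` — both `sin` and `cos` of every DOF: the standard
#'   injective dihedral-PCA representation.
#'
#' DOFs are paired as (phi, psi) by `dof_kind` and residue order when that
#' metadata is present; otherwise odd-positioned DOFs take the cosine role
#' and even-positioned DOFs the sine role.
#'
#' @param ensemble A `dihedral_ensemble` tibble.
#' @param representation `"compact"` or `"full_sincos"`.
#' @param trajectories Optional subset of trajectory ids to fit on.
#' @return An object of class `dpca`: `mean`, `covariance`, `eigenvalues`
#'   (descending), `eigenvectors` (columns), `explained` (fractions summing
#'   to 1), `variables`, `representation`, `n_frames`. Methods: `tidy()`,
#'   `glance()`, `autoplot()`, [project_dpca()].
#' @export
fit_dpca <- function(ensemble, representation = c("compact", "full_sincos"),
                     trajectories = NULL) {
  representation <- match.arg(representation)
  if (!is.null(trajectories)) {
    ensemble <- ensemble[ensemble$trajectory_id %in% trajectories, ]
  }
  q <- dihedral_design_matrix(ensemble, representation)
  if (nrow(q) < 2) stop("at least 2 frames are required")
  mu <- colMeans(q)
  sigma <- stats::cov(q) * (nrow(q) - 1) / nrow(q)  # population covariance
  eig <- eigen(sigma, symmetric = TRUE)
  ev <- pmax(eig$values, 0)
  total <- sum(ev)
  explained <- if (total > 0) ev / total else rep(0, length(ev))
  structure(list(mean = mu, covariance = sigma, eigenvalues = ev,
                 eigenvectors = eig$vectors, explained = explained,
                 variables = colnames(q), representation = representation,
                 n_frames = nrow(q)),
            class = "dpca")
}

# frames x variables trigonometric design matrix
dihedral_design_matrix <- function(ensemble, representation) {
  wide <- tidyr::pivot_wider(
    ensemble[, c("trajectory_id", "frame", "dof_id", "angle")],
    names_from = "dof_id", values_from = "angle")
  wide <- wide[order(wide$trajectory_id, wide$frame), ]
  dof_ids <- setdiff(names(wide), c("trajectory_id", "frame"))
  a <- as.matrix(wide[, dof_ids, drop = FALSE]) * pi / 180
  if (representation == "full_sincos") {
    q <- cbind(cos(a), sin(a))
    colnames(q) <- c(paste0("cos_", dof_ids), paste0("sin_", dof_ids))
    return(q)
  }
  info <- attr(ensemble, "dof_info", exact = TRUE)
  kinds <- if (!is.null(info)) {
    info$dof_kind[match(dof_ids, info$dof_id)]
  } else {
    rep("generic", length(dof_ids))
  }
  role <- ifelse(kinds == "phi", "cos",
                 ifelse(kinds == "psi", "sin",
                        ifelse(seq_along(dof_ids) %% 2 == 1, "cos", "sin")))
  q <- vapply(seq_along(dof_ids), function(j) {
    if (role[j] == "cos") cos(a[, j]) else sin(a[, j])
  }, numeric(nrow(a)))
  q <- matrix(q, nrow = nrow(a))
  colnames(q) <- paste0(role, "_", dof_ids)
  q
}

#' @export
print.dpca <- function(x, ...) {
  cat("<dpca> ", x$representation, " representation: ", length(x$eigenvalues),
      " variables, ", x$n_frames, " frames; top-2 variance fraction ",
      round(sum(x$explained[1:min(2, length(x$explained))]), 3), "\n",
      sep = "")
  invisible(x)
}

#' @rdname fit_dpca
#' @param x,object A `dpca` object.
#' @param ... Unused.
#' @method tidy dpca
#' @export
tidy.dpca <- function(x, ...) {
  tibble::tibble(component = seq_along(x$eigenvalues),
                 eigenvalue = x$eigenvalues,
                 explained = x$explained,
                 cumulative = cumsum(x$explained))
}

#' @rdname fit_dpca
#' @method glance dpca
#' @export
glance.dpca <- function(x, ...) {
  tibble::tibble(representation = x$representation,
                 n_variables = length(x$eigenvalues),
                 n_frames = x$n_frames,
                 total_variance = sum(x$eigenvalues),
                 top1 = x$explained[1],
                 top2 = sum(x$explained[1:min(2, length(x$explained))]))
}

#' Project frames onto leading principal components
#'
#' @param model A fitted `dpca`.
#' @param ensemble A `dihedral_ensemble` (defaults must contain the same
#'   DOFs).
#' @param k Number of components (default 2).
#' @return A tibble: `trajectory_id`, `frame`, `PC1..PCk`.
#' @export
project_dpca <- function(model, ensemble, k = 2) {
  q <- dihedral_design_matrix(ensemble, model$representation)
  proj <- sweep(q, 2, model$mean) %*% model$eigenvectors[, seq_len(k),
                                                         drop = FALSE]
  colnames(proj) <- paste0("PC", seq_len(k))
  meta <- dplyr::distinct(ensemble[, c("trajectory_id", "frame")])
  meta <- meta[order(meta$trajectory_id, meta$frame), ]
  dplyr::bind_cols(meta, tibble::as_tibble(proj))
}

#' @rdname fit_dpca
#' @method autoplot dpca
#' @export
autoplot.dpca <- function(object, ...) {
  td <- tidy(object)
  ggplot2::ggplot(td, ggplot2::aes(x = .data$component, y = .data$explained)) +
    ggplot2::geom_col(fill = "grey40") +
    ggplot2::geom_line(ggplot2::aes(y = .data$cumulative),
                       colour = "firebrick") +
    ggplot2::labs(x = "principal component", y = "explained variance fraction")
}

#' Cartesian principal component analysis of backbone coordinates
#'
#' The positional counterpart of [fit_dpca()]: every frame is rigidly
#' superposed onto the ensemble's mean structure (two rounds of Kabsch
#' superposition: first onto an arbitrary reference to compute a mean, then
#' onto that mean), and the covariance of the flattened coordinates is
#' diagonalized.
#'
#' @param frames List of n x 3 coordinate matrices with matched atoms
#'   (e.g. backbone atoms).
#' @return A `dpca` object (representation `"cartesian"`).
#' @export
fit_cartesian_pca <- function(frames) {
  stopifnot(length(frames) >= 2)
  superpose_onto <- function(p, ref) {
    p1 <- sweep(as.matrix(p), 2, colMeans(p))
    r1 <- sweep(as.matrix(ref), 2, colMeans(ref))
    sv <- svd(t(p1) %*% r1)
    d <- sign(det(sv$v %*% t(sv$u)))
    p1 %*% t(sv$v %*% diag(c(1, 1, d)) %*% t(sv$u))
  }
  aligned <- lapply(frames, superpose_onto, ref = frames[[1]])
  mean_str <- Reduce(`+`, aligned) / length(aligned)
  aligned <- lapply(frames, superpose_onto, ref = mean_str)
  q <- do.call(rbind, lapply(aligned, as.vector))
  mu <- colMeans(q)
  sigma <- stats::cov(q) * (nrow(q) - 1) / nrow(q)
  eig <- eigen(sigma, symmetric = TRUE)
  ev <- pmax(eig$values, 0)
  total <- sum(ev)
  structure(list(mean = mu, covariance = sigma, eigenvalues = ev,
                 eigenvectors = eig$vectors,
                 explained = if (total > 0) ev / total else rep(0, length(ev)),
                 variables = paste0("x", seq_along(mu)),
                 representation = "cartesian", n_frames = nrow(q)),
            class = "dpca")
}

#' Explained-variance profile across nested trajectory subsets
#'
#' Fits a dPCA per trajectory subset and reports the fraction of total
#' variance captured by the leading `k` components — the diagnostic that
#' distinguishes single-trajectory landscapes (dominated by one slow
#' collective motion) from pooled multi-trajectory landscapes whose
#' structural diversity flattens the spectrum.
#'
#' @param ensemble A `dihedral_ensemble`.
#' @param subsets Named list of trajectory-id vectors.
#' @param k Leading components to sum (default 2).
#' @param representation Passed to [fit_dpca()].
#' @return A tibble: `subset`, `n_trajectories`, `n_frames`, `top_k_fraction`.
#' @export
explained_variance_profile <- function(ensemble, subsets, k = 2,
                                       representation = "compact") {
  stopifnot(length(subsets) >= 1)
  if (is.null(names(subsets))) {
    names(subsets) <- paste0("subset", seq_along(subsets))
  }
  purrr::imap_dfr(subsets, function(trajs, nm) {
    m <- fit_dpca(ensemble, representation = representation,
                  trajectories = trajs)
    tibble::tibble(subset = nm, n_trajectories = length(trajs),
                   n_frames = m$n_frames,
                   top_k_fraction = sum(m$explained[seq_len(
                     min(k, length(m$explained)))]))
  })
}
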