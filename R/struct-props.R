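# standard atomic masses (amu) and van der Waals radii (Angstrom)
element_masses <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999,
                    S = 32.06, P = 30.974)
vdw_radii <- c(H = 1.2, C = 1.7, N = 1.55, O = 1.52, S = 1.8, P = 1.8)

# residues of the common hydrophobic class
hydrophobic_residues_default <- c("ALA", "VAL", "LEU", "ILE", "PRO", "PHE",
                                  "MET", "TRP")

guess_element <- function(atom_name) {
  e <- sub("^[0-9]*", "", atom_name)
  substr(e, 1, 1)
}

#' Construct an atom table
#'
#' The coordinate container used by all structural-property functions: a
#' tibble with one row per atom.
#'
#' @param atom_name Atom names (e.g. `"CA"`, `"N"`, `"O"`, `"HN"`).
#' @param residue_index 1-based residue numbers.
#' @param x,y,z Coordinates in Angstrom.
#' @param residue_name 3-letter residue names (default `"ALA"`).
#' @param element Chemical elements; guessed from the atom name when missing.
#' @param mass Atomic masses in amu; from the element table when missing.
#' @return A tibble of class `atom_tbl`.
#' @export
atom_tbl <- function(atom_name, residue_index, x, y, z,
                     residue_name = "ALA", element = NULL, mass = NULL) {
  if (is.null(element)) element <- guess_element(atom_name)
  if (is.null(mass)) {
    mass <- unname(element_masses[element])
    if (anyNA(mass)) stop("unknown element(s): ",
                          paste(unique(element[is.na(mass)]), collapse = ", "),
                          "; supply masses explicitly")
  }
  out <- tibble::tibble(atom_name = as.character(atom_name),
                        residue_index = as.integer(residue_index),
                        residue_name = rep_len(as.character(residue_name),
                                               length(atom_name)),
                        element = element, mass = as.numeric(mass),
                        x = as.numeric(x), y = as.numeric(y),
                        z = as.numeric(z))
  if (any(!is.finite(c(out$x, out$y, out$z)))) stop("non-finite coordinates")
  if (any(out$mass <= 0)) stop("masses must be positive")
  class(out) <- c("atom_tbl", class(out))
  out
}

coords_matrix <- function(atoms) {
  cbind(atoms$x, atoms$y, atoms$z)
}

#' Mass-weighted radius of gyration
#'
#' `sqrt(sum(m_i r_i^2) / sum(m_i))` with `r_i` the distance of atom `i` to
#' the molecular center of mass.
#'
#' @param atoms An `atom_tbl`.
#' @return Radius of gyration in Angstrom.
#' @export
#' @examples
#' a <- atom_tbl("CA", 1:2, c(-1, 1), 0, 0, mass = c(1, 1), element = "C")
#' radius_of_gyration(a) # 1
radius_of_gyration <- function(atoms) {
  if (nrow(atoms) == 0) stop("no atoms")
  m <- atoms$mass
  if (sum(m) <= 0) stop("total mass must be positive")
  xyz <- coords_matrix(atoms)
  com <- colSums(xyz * m) / sum(m)
  r2 <- rowSums(sweep(xyz, 2, com)^2)
  sqrt(sum(m * r2) / sum(m))
}

ca_coords <- function(atoms) {
  ca <- atoms[atoms$atom_name == "CA", ]
  if (nrow(ca) == 0) stop("no CA atoms present")
  dup <- duplicated(ca$residue_index)
  ca <- ca[!dup, ]
  ca[order(ca$residue_index), ]
}

# residue-pair contacts of one frame: |i - j| >= min_seq_sep and
# d(CA_i, CA_j) < cutoff
contact_pairs <- function(atoms, cutoff = 6.5, min_seq_sep = 2) {
  ca <- ca_coords(atoms)
  xyz <- coords_matrix(ca)
  d <- as.matrix(stats::dist(xyz))
  idx <- which(upper.tri(d) & d < cutoff, arr.ind = TRUE)
  res_i <- ca$residue_index[idx[, 1]]
  res_j <- ca$residue_index[idx[, 2]]
  keep <- abs(res_i - res_j) >= min_seq_sep
  tibble::tibble(res_i = pmin(res_i[keep], res_j[keep]),
                 res_j = pmax(res_i[keep], res_j[keep]))
}

#' Define the native-contact set from a reference ensemble
#'
#' A residue contact is defined for two non-sequential residues (sequence
#' separation at least `min_seq_sep`) with CA distance smaller than `cutoff`.
#' Contacts shared by at least `prevalence` of the reference models are
#' native.
#'
#' @param reference List of `atom_tbl` models (e.g. crystal structures).
#' @param cutoff CA distance cutoff in Angstrom (default 6.5).
#' @param min_seq_sep Minimum `|i - j|` (default 2, i.e. non-sequential).
#' @param prevalence Fraction of models a pair must appear in (default 2/3).
#' @return A tibble of class `contact_definition`: `res_i`, `res_j`,
#'   `prevalence`, plus the parameters as attributes.
#' @export
define_native_set <- function(reference, cutoff = 6.5, min_seq_sep = 2,
                              prevalence = 2 / 3) {
  stopifnot(length(reference) >= 1, prevalence > 0, prevalence <= 1)
  all_pairs <- purrr::map_dfr(reference, contact_pairs,
                              cutoff = cutoff, min_seq_sep = min_seq_sep)
  counts <- dplyr::count(all_pairs, .data$res_i, .data$res_j, name = "n_models")
  out <- counts |>
    dplyr::mutate(prevalence = .data$n_models / length(reference)) |>
    dplyr::filter(.data$prevalence >= !!prevalence) |>
    dplyr::select("res_i", "res_j", "prevalence")
  attr(out, "cutoff") <- cutoff
  attr(out, "min_seq_sep") <- min_seq_sep
  attr(out, "prevalence_threshold") <- prevalence
  class(out) <- c("contact_definition", class(out))
  out
}

#' Count native contacts of one frame
#'
#' @param atoms An `atom_tbl`.
#' @param native A `contact_definition` (see [define_native_set()]).
#' @return Integer: number of native pairs in contact in this frame.
#' @export
native_contacts <- function(atoms, native) {
  cutoff <- attr(native, "cutoff") %||% 6.5
  sep <- attr(native, "min_seq_sep") %||% 2
  present <- contact_pairs(atoms, cutoff = cutoff, min_seq_sep = sep)
  nrow(dplyr::inner_join(present, native[, c("res_i", "res_j")],
                         by = c("res_i", "res_j")))
}

#' Count hydrogen bonds of one frame
#'
#' A hydrogen bond is a donor-H-acceptor triple with donor-acceptor distance
#' below `dist_cutoff` and D-H-A bend angle above `angle_min`. Donors are N/O
#' atoms with a covalently bound hydrogen (H within `bond_max`); acceptors
#' are N/O atoms other than the donor.
#'
#' @param atoms An `atom_tbl` including hydrogens.
#' @param dist_cutoff Donor-acceptor distance cutoff in Angstrom
#'   (default 3.5; values in 3.0-3.5 give similar cluster orderings).
#' @param angle_min Minimum D-H-A angle in degrees (default 130).
#' @param bond_max Covalent D-H bond length cutoff in Angstrom (default 1.25).
#' @param distance_only If `TRUE`, count donor-acceptor pairs by distance
#'   alone (fallback for hydrogen-free models).
#' @return Integer hydrogen-bond count.
#' @export
hydrogen_bonds <- function(atoms, dist_cutoff = 3.5, angle_min = 130,
                           bond_max = 1.25, distance_only = FALSE) {
  xyz <- coords_matrix(atoms)
  is_da <- atoms$element %in% c("N", "O")
  is_h <- atoms$element == "H"
  if (!any(is_h) && !distance_only) {
    stop("no hydrogens present; use distance_only = TRUE for the ",
         "distance-based fallback")
  }
  da_idx <- which(is_da)
  if (distance_only) {
    d <- as.matrix(stats::dist(xyz[da_idx, , drop = FALSE]))
    return(sum(upper.tri(d) & d < dist_cutoff &
                 outer(atoms$residue_index[da_idx],
                       atoms$residue_index[da_idx], `!=`)[upper.tri(d)]))
  }
  h_idx <- which(is_h)
  n_hb <- 0L
  for (h in h_idx) {
    dh <- sqrt(colSums((t(xyz[da_idx, , drop = FALSE]) - xyz[h, ])^2))
    don <- da_idx[dh < bond_max]
    if (length(don) == 0) next
    don <- don[which.min(dh[dh < bond_max])]
    acc <- setdiff(da_idx, don)
    if (length(acc) == 0) next
    dda <- sqrt(colSums((t(xyz[acc, , drop = FALSE]) - xyz[don, ])^2))
    cand <- acc[dda < dist_cutoff]
    for (a in cand) {
      v1 <- xyz[don, ] - xyz[h, ]
      v2 <- xyz[a, ] - xyz[h, ]
      cosang <- sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
      ang <- acos(pmax(pmin(cosang, 1), -1)) * 180 / pi
      if (ang > angle_min) n_hb <- n_hb + 1L
    }
  }
  n_hb
}

# deterministic golden-spiral unit sphere points
sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(cos(theta) * sin(phi), sin(theta) * sin(phi), cos(phi))
}

#' Solvent-accessible surface area (Shrake-Rupley)
#'
#' Sphere-sampling SASA: each atom's sphere of radius `r_vdw + probe_radius`
#' is sampled with a deterministic golden-spiral point set; points not buried
#' inside any neighboring atom's expanded sphere are accessible.
#'
#' @param atoms An `atom_tbl`.
#' @param probe_radius Probe sphere radius in Angstrom; default 1.4, the
#'   standard water probe. Pass 0.7 to read a "1.4 Angstrom diameter" probe
#'   literally.
#' @param n_points Sphere sample points per atom (default 960).
#' @param radii Named per-element radius table (Angstrom); defaults to the
#'   built-in van der Waals set.
#' @param seed Optional integer; when given, the point set is randomly
#'   rotated (deterministically for a fixed seed).
#' @return Numeric vector: per-atom accessible area in square Angstrom.
#' @export
sasa <- function(atoms, probe_radius = 1.4, n_points = 960, radii = NULL,
                 seed = NULL) {
  if (is.null(radii)) radii <- vdw_radii
  r <- unname(radii[atoms$element])
  if (anyNA(r)) stop("no radius for element(s): ",
                     paste(unique(atoms$element[is.na(r)]), collapse = ", "),
                     "; override the radius table")
  r <- r + probe_radius
  pts <- sphere_points(n_points)
  if (!is.null(seed)) {
    set.seed(seed)
    q <- qr.Q(qr(matrix(stats::rnorm(9), 3)))
    if (det(q) < 0) q[, 1] <- -q[, 1]
    pts <- pts %*% q
  }
  xyz <- coords_matrix(atoms)
  n <- nrow(xyz)
  areas <- numeric(n)
  d2 <- as.matrix(stats::dist(xyz))^2
  for (i in seq_len(n)) {
    nbr <- which(d2[i, ] < (r[i] + r)^2 & seq_len(n) != i)
    p <- sweep(pts * r[i], 2, xyz[i, ], `+`)
    acc <- rep(TRUE, n_points)
    for (j in nbr) {
      if (!any(acc)) break
      dj2 <- (p[acc, 1] - xyz[j, 1])^2 + (p[acc, 2] - xyz[j, 2])^2 +
        (p[acc, 3] - xyz[j, 3])^2
      acc[acc] <- dj2 >= r[j]^2
    }
    areas[i] <- 4 * pi * r[i]^2 * sum(acc) / n_points
  }
  areas
}

#' Hydrophobic solvent-accessible surface area
#'
#' Sum of per-atom SASA over atoms belonging to hydrophobic residues.
#'
#' @inheritParams sasa
#' @param hydrophobic Residue-name set counted as hydrophobic; defaults to
#'   the common class ALA, VAL, LEU, ILE, PRO, PHE, MET, TRP.
#' @return hSASA in square Angstrom.
#' @export
hydrophobic_sasa <- function(atoms, probe_radius = 1.4, n_points = 960,
                             radii = NULL, seed = NULL,
                             hydrophobic = hydrophobic_residues_default) {
  a <- sasa(atoms, probe_radius = probe_radius, n_points = n_points,
            radii = radii, seed = seed)
  sum(a[atoms$residue_name %in% hydrophobic])
}

#' Optimal-superposition RMSD of two coordinate sets (Kabsch)
#'
#' Centers both point sets, finds the optimal rotation by singular value
#' decomposition of the covariance (with reflection correction), and returns
#' the root-mean-square deviation after superposition.
#'
#' @param a,b Numeric n x 3 coordinate matrices with matched rows.
#' @return RMSD in the coordinate units.
#' @export
kabsch_rmsd <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  if (nrow(a) != nrow(b) || ncol(a) != 3 || ncol(b) != 3) {
    stop("coordinate matrices must be n x 3 with matched rows")
  }
  if (nrow(a) < 3) stop("at least 3 atoms are required for superposition")
  a1 <- sweep(a, 2, colMeans(a))
  b1 <- sweep(b, 2, colMeans(b))
  sv <- svd(t(a1) %*% b1)
  d <- sign(det(sv$v %*% t(sv$u)))
  rot <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  sqrt(mean(rowSums((a1 %*% t(rot) - b1)^2)))
}

#' Intra- and inter-cluster pairwise RMSD distributions
#'
#' Samples frame pairs within each cluster (intra) and across clusters
#' (inter), superposes each pair optimally and records the backbone RMSD.
#' Groups with at most `max_pairs` possible pairs are enumerated
#' exhaustively; larger groups are sampled uniformly with the given seed.
#'
#' @param frames List of n x 3 coordinate matrices (common atom set).
#' @param labels Cluster label per frame.
#' @param max_pairs Maximum sampled pairs per group (default 1000).
#' @param seed Seed for pair sampling (default 1).
#' @return A tibble: `pair_type` (`"intra"`/`"inter"`), `i`, `j`, `rmsd`.
#' @export
pairwise_rmsd <- function(frames, labels, max_pairs = 1000, seed = 1) {
  stopifnot(length(frames) == length(labels), length(frames) >= 2)
  set.seed(seed)
  lab <- as.character(labels)
  idx <- seq_along(frames)
  sample_pairs <- function(ii, jj, same) {
    if (same) {
      if (length(ii) < 2) return(NULL)
      all_p <- utils::combn(ii, 2)
      pairs <- if (ncol(all_p) <= max_pairs) all_p else
        all_p[, sample.int(ncol(all_p), max_pairs), drop = FALSE]
    } else {
      total <- length(ii) * length(jj)
      if (total == 0) return(NULL)
      if (total <= max_pairs) {
        pairs <- rbind(rep(ii, each = length(jj)), rep(jj, times = length(ii)))
      } else {
        pairs <- rbind(sample(ii, max_pairs, replace = TRUE),
                       sample(jj, max_pairs, replace = TRUE))
      }
    }
    pairs
  }
  out <- list()
  for (cl in unique(lab)) {
    p <- sample_pairs(idx[lab == cl], NULL, same = TRUE)
    if (!is.null(p)) {
      out[[length(out) + 1L]] <- tibble::tibble(
        pair_type = "intra", i = p[1, ], j = p[2, ],
        rmsd = vapply(seq_len(ncol(p)), function(k) {
          kabsch_rmsd(frames[[p[1, k]]], frames[[p[2, k]]])
        }, numeric(1)))
    }
  }
  cls <- unique(lab)
  if (length(cls) > 1) {
    for (ci in seq_along(cls)[-length(cls)]) {
      for (cj in (ci + 1):length(cls)) {
        p <- sample_pairs(idx[lab == cls[ci]], idx[lab == cls[cj]],
                          same = FALSE)
        if (is.null(p)) next
        out[[length(out) + 1L]] <- tibble::tibble(
          pair_type = "inter", i = p[1, ], j = p[2, ],
          rmsd = vapply(seq_len(ncol(p)), function(k) {
            kabsch_rmsd(frames[[p[1, k]]], frames[[p[2, k]]])
          }, numeric(1)))
      }
    }
  }
  dplyr::bind_rows(out)
}

#' Compute per-frame structural properties
#'
#' @param frames List of `atom_tbl` objects.
#' @param native Optional `contact_definition` for native-contact counts.
#' @param probe_radius,n_points SASA parameters.
#' @param hydrophobic Hydrophobic residue set.
#' @param hbond_distance_only Use the hydrogen-free H-bond fallback?
#' @return A tibble: `frame`, `R_g`, `nHB`, `nNC`, `hSASA`.
#' @export
structure_properties <- function(frames, native = NULL, probe_radius = 1.4,
                                 n_points = 960,
                                 hydrophobic = hydrophobic_residues_default,
                                 hbond_distance_only = FALSE) {
  purrr::imap_dfr(frames, function(fr, i) {
    tibble::tibble(
      frame = as.integer(i),
      R_g = radius_of_gyration(fr),
      nHB = hydrogen_bonds(fr, distance_only = hbond_distance_only),
      nNC = if (is.null(native)) NA_integer_ else native_contacts(fr, native),
      hSASA = hydrophobic_sasa(fr, probe_radius = probe_radius,
                               n_points = n_points,
                               hydrophobic = hydrophobic))
  })
}

#' Write synthetic structures as a multi-model PDB file
#'
#' Emits standard fixed-width ATOM records wrapped in MODEL/ENDMDL blocks.
#' Intended for the package's synthetic fixtures (structures with
#' analytically known geometry); it is not a general PDB exporter.
#'
#' @param models A single `atom_tbl` or list of them.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pdb_models <- function(models, path) {
  if (is.data.frame(models)) models <- list(models)
  con <- file(path, "w")
  on.exit(close(con))
  for (m in seq_along(models)) {
    at <- models[[m]]
    writeLines(sprintf("MODEL     %4d", m), con)
    for (i in seq_len(nrow(at))) {
      writeLines(sprintf(
        "ATOM  %5d %-4s %3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
        i, at$atom_name[i], at$residue_name[i], at$residue_index[i],
        at$x[i], at$y[i], at$z[i], at$element[i]), con)
    }
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Read a (multi-model) PDB file into atom tables
#'
#' A minimal fixed-width ATOM-record reader sufficient for the synthetic
#' fixtures this package writes; for production trajectories use a dedicated
#' structure package and convert to [atom_tbl()].
#'
#' @param path PDB file path.
#' @return A list of `atom_tbl` models.
#' @export
read_pdb_models <- function(path) {
  lines <- readLines(path)
  model_breaks <- grepl("^MODEL", lines)
  model_id <- cumsum(model_breaks)
  if (!any(model_breaks)) model_id <- rep(1L, length(lines))
  keep <- grepl("^ATOM", lines)
  split_ids <- model_id[keep]
  recs <- lines[keep]
  parse_block <- function(rr) {
    atom_tbl(
      atom_name = trimws(substr(rr, 13, 16)),
      residue_name = trimws(substr(rr, 18, 20)),
      residue_index = as.integer(substr(rr, 23, 26)),
      x = as.numeric(substr(rr, 31, 38)),
      y = as.numeric(substr(rr, 39, 46)),
      z = as.numeric(substr(rr, 47, 54)),
      element = trimws(substr(rr, 77, 78)))
  }
  lapply(split(recs, split_ids), parse_block)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
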