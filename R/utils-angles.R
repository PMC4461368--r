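#' Normalize angles to the (-180, 180] degree convention
#'
#' Dihedral angles throughout the package live on the circle, represented in
#' degrees on the half-open interval (-180, 180].
#'
#' @param x Numeric vector of angles in degrees.
#' @return Numeric vector with every value in (-180, 180].
#' @export
#' @examples
#' normalize_angle(c(-180, 180, 270, -190))
normalize_angle <- function(x) {
  x - 360 * ceiling((x - 180) / 360)
}

#' Circular distance between two angles
#'
#' @param a,b Angles in degrees.
#' @return Shortest arc length between `a` and `b`, in [0, 180].
#' @export
circular_distance <- function(a, b) {
  d <- abs(normalize_angle(a - b))
  pmin(d, 360 - d)
}

# 0-based 1-degree bin index for angles in (-180, 180]; bin i covers
# [-180 + i, -180 + i + 1). 180 wraps onto bin 0 (circular adjacency).
angle_bin <- function(x) {
  bad <- !is.finite(x) | x <= -180 | x > 180
  if (any(bad)) {
    stop("angles must be finite and in (-180, 180]; offending value: ",
         x[which(bad)[1]])
  }
  floor(x + 180) %% 360
}

# Membership of angles in a cyclic half-open arc [start, end) (degrees).
# A zero-width arc (start == end) is interpreted as the full circle.
in_arc <- function(x, start, end) {
  width <- (end - start) %% 360
  if (width == 0) return(rep(TRUE, length(x)))
  ((x - start) %% 360) < width
}

# Width of the cyclic arc [start, end) in degrees (0 means full circle -> 360).
arc_width <- function(start, end) {
  w <- (end - start) %% 360
  ifelse(w == 0, 360, w)
}

#' Bookkeeping: total snapshot count of a trajectory ensemble
#'
#' @param n_trajectories Number of independent trajectories.
#' @param trajectory_ns Length of each trajectory in nanoseconds.
#' @param frame_interval_ps Saving interval in picoseconds.
#' @return Total number of saved frames across the ensemble.
#' @export
#' @examples
#' ensemble_frame_count(2000, 100, 4) # 50 million
ensemble_frame_count <- function(n_trajectories, trajectory_ns, frame_interval_ps) {
  stopifnot(n_trajectories > 0, trajectory_ns > 0, frame_interval_ps > 0)
  n_trajectories * (trajectory_ns * 1000 / frame_interval_ps)
}

#' Bookkeeping: number of backbone dihedrals of a single chain
#'
#' A linear chain of `n_residues` residues has one phi per residue except the
#' first and one psi per residue except the last, i.e. `2 * n_residues - 2`
#' backbone dihedral degrees of freedom.
#'
#' @param n_residues Number of residues in the chain.
#' @return Count of phi/psi backbone dihedrals.
#' @export
#' @examples
#' backbone_dihedral_count(129) # 256
backbone_dihedral_count <- function(n_residues) {
  stopifnot(n_residues >= 2)
  2L * as.integer(n_residues) - 2L
}

#' Bookkeeping: transition routes of a cyclic multi-minimum torsion
#'
#' A circular torsional degree of freedom whose two states are separated by
#' `n_minima` effective minima can interconvert along `n_minima` distinct
#' spatial routes, each traversable in two directions.
#'
#' @param n_minima Number of separating effective minima (2 for a two-state
#'   cyclic torsion).
#' @return Number of distinct transition routes (direction counted).
#' @export
#' @examples
#' count_transition_routes(2) # 4: A->minA->B, A->minB->B, B->minA->A, B->minB->A
count_transition_routes <- function(n_minima = 2) {
  stopifnot(n_minima >= 1)
  2L * as.integer(n_minima)
}
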