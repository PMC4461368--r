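#' Canned synthetic study designs
#'
#' Pre-parameterized [ensemble_spec()]s for the three landscape archetypes the
#' package's analyses are validated against. Each design fixes realistic
#' kinetic parameters; only the seed (and an optional size factor) varies.
#'
#' `hub_ensemble_spec()` — a hub-like coarse landscape over a network-like
#' fine landscape: one slow master DOF with a dominant state (98% occupancy,
#' mean waiting time 0.56 us), eight slaves copying it with per-frame
#' fidelity 0.99995 (their rare deviations connect satellite substates
#' directly to the dominant cluster), and six independent fast DOFs (mean
#' waiting 6 ns) that shatter the fine-resolution landscape. 5 trajectories
#' of 2 us at 50 ps spacing.
#'
#' `tse_ensemble_spec()` — four independent two-state DOFs with identical
#' barrier-transit dynamics (`transit_mean_frames = 0.3`, i.e. a mean
#' barrier-crossing time well below the frame interval) but mean waiting
#' times of 4 ns, 40 ns, 400 ns and 4 us — three decades — populating bands
#' T4 through T1. 4 trajectories of 40 us at 200 ps spacing.
#'
#' `dpca_ensemble_spec()` — one slow collective mode (a master plus three
#' fully coupled slaves, waiting time 20 ns) and four independent DOFs
#' frozen on the single-trajectory timescale (waiting time 100 us): a single
#' trajectory's variance is dominated by the collective mode, while pooling
#' trajectories adds four independent directions of comparable variance.
#' 10 trajectories of 0.2 us at 100 ps spacing.
#'
#' @param seed Integer seed.
#' @param size Multiplier on frames per trajectory (default 1; smaller values
#'   give faster, noisier runs for quick checks).
#' @return An [ensemble_spec()].
#' @name study_designs
NULL

#' @rdname study_designs
#' @export
hub_ensemble_spec <- function(seed = 1L, size = 1) {
  dofs <- c(
    list(telegraph_spec("hub00", exit_rates = c(1 / 1100, 1 / 22),
                        state_centers = c(-60, 120))),
    lapply(1:8, function(i) {
      telegraph_spec(sprintf("slave%02d", i), exit_rates = c(2, 0.02),
                     state_centers = c(-60, 120),
                     master = "hub00", coupling = 0.99995)
    }),
    lapply(1:6, function(i) {
      telegraph_spec(sprintf("fast%02d", i), exit_rates = 1 / 6,
                     state_centers = c(-70, 110))
    })
  )
  ensemble_spec(5, round(40000 * size), 50, dofs, seed = seed)
}

#' @rdname study_designs
#' @export
tse_ensemble_spec <- function(seed = 1L, size = 1) {
  waits_ns <- c(4, 40, 400, 4000)
  dofs <- lapply(waits_ns, function(w) {
    telegraph_spec(sprintf("w%04d", w), exit_rates = 1 / w,
                   state_centers = c(-90, 90), emission_kappa = 8,
                   transit_mean_frames = 0.3)
  })
  ensemble_spec(4, round(200000 * size), 200, dofs, seed = seed)
}

#' @rdname study_designs
#' @export
dpca_ensemble_spec <- function(seed = 1L, size = 1) {
  dofs <- c(
    list(telegraph_spec("coll0", exit_rates = 1 / 20,
                        state_centers = c(-150, 30))),
    lapply(1:3, function(i) {
      telegraph_spec(sprintf("coll%d", i), exit_rates = 1 / 20,
                     state_centers = c(-150, 30),
                     master = "coll0", coupling = 1)
    }),
    lapply(1:4, function(i) {
      telegraph_spec(sprintf("froz%d", i), exit_rates = 1e-5,
                     state_centers = c(-150, 30))
    })
  )
  ensemble_spec(10, round(2000 * size), 100, dofs, seed = seed)
}

#' Single-DOF replicate design for waiting-time recovery
#'
#' One symmetric two-state telegraph DOF with true mean waiting time
#' `wait_ns`, simulated for `n_waits` waiting times at a frame interval of
#' `wait_ns / 50` (so frame discretization hides well under 2 of every 100
#' transitions), in a single trajectory. Used to validate that counted
#' transitions recover the true rate and band across decades.
#'
#' @param wait_ns True mean waiting time in nanoseconds.
#' @param seed Integer seed.
#' @param n_waits Expected number of transitions (default 316, the decade
#'   midpoint of a band).
#' @return An [ensemble_spec()].
#' @export
rate_recovery_spec <- function(wait_ns, seed = 1L, n_waits = 316) {
  dof <- telegraph_spec("dof1", exit_rates = 1 / wait_ns,
                        state_centers = c(-90, 90), emission_kappa = 12)
  ensemble_spec(1, n_waits * 50, wait_ns / 50 * 1000, list(dof), seed = seed)
}
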