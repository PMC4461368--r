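test_that("flank-count growth follows the jump inequality", {
  # brute-force evaluation of the stated inequality as an inline oracle
  oracle <- function(counts, ratio) {
    for (i in seq_len(length(counts) - 2)) {
      d1 <- counts[i + 1] - counts[i]
      d2 <- counts[i + 2] - counts[i + 1]
      if (d1 > 0 && d2 > 0 && d2 >= ratio * d1) return(i + 1L)
    }
    NA_integer_
  }
  expect_equal(torsionfel:::tse_flank_bins(c(10, 12, 14, 40), 3),
               oracle(c(10, 12, 14, 40), 3))
  expect_equal(torsionfel:::tse_flank_bins(c(10, 12, 14, 40), 3), 3L)
  expect_true(is.na(torsionfel:::tse_flank_bins(c(10, 12), 3)))
  expect_true(is.na(torsionfel:::tse_flank_bins(c(40, 30, 20, 10), 3)))
  set.seed(8)
  for (rep in 1:50) {
    counts <- cumsum(sample(-3:10, sample(4:12, 1), replace = TRUE)) + 20
    expect_equal(torsionfel:::tse_flank_bins(counts, 3),
                 oracle(counts, 3))
  }
})

test_that("fine-band DOFs get the fixed 5-degree arc", {
  sp <- ensemble_spec(1, 4000, 100, list(
    telegraph_spec("d", exit_rates = 0.25, state_centers = c(-30, 150))
  ), seed = 71)
  ens <- simulate_ensemble(sp)
  fit <- fit_torsion_states(ens)
  states <- assign_states(ens, fit)
  ts <- dof_timescales(states)
  expect_true(ts$band %in% c("T3", "T4"))
  regions <- derive_tse_regions(ens, fit, ts)
  expect_true(all(regions$derivation == "fixed_5deg"))
  for (i in seq_len(nrow(regions))) {
    expect_equal(torsionfel:::arc_width(regions$start[i], regions$end[i]), 5)
    expect_true(torsionfel:::in_arc(regions$minimum[i],
                                    regions$start[i], regions$end[i]))
  }
})

test_that("events require an in-arc run flanked by different clusters", {
  # hand-built single-DOF trajectory: arcs [-120, 60) and [60, 240)
  counts <- gaussian_mix_hist(c(-30, 150))
  model <- define_states(c(-120, 60), counts, dof_id = "d1")
  fit <- structure(list(models = list(d1 = model)),
                   class = "torsion_state_fit")
  angles <- c(-30, 58, 61, 150, 150, 59, 150, -30, -30)
  ens <- tibble::tibble(trajectory_id = "t1", frame = seq_along(angles),
                        dof_id = "d1", angle = angles)
  attr(ens, "frame_interval_ps") <- 4
  states <- assign_states(ens, fit)
  ts <- tibble::tibble(dof_id = "d1", n_trans = 3L, total_time_us = 200,
                       t_w_us = 60, band = "T1")
  hier <- cluster_hierarchy(states, ts)
  regions <- tibble::tibble(dof_id = "d1", minimum = 60,
                            start = 57.5, end = 62.5,
                            derivation = "fixed_5deg",
                            bins_minus = 1L, bins_plus = 1L)
  ev <- label_tse_events(ens, regions, hier, "T1")
  # frames 2-3 (58, 61) cross the minimum: clusters differ across the run
  # frame 6 (59) is an excursion that returns to cluster B: not an event
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$start_frame, 2L)
  expect_equal(ev$end_frame, 3L)
  expect_equal(ev$lifetime_ps, 2 * 4)
  expect_false(identical(ev$from_key, ev$to_key))
  # an instantaneous crossing leaves no event
  angles2 <- c(-30, 150, 150, -30)
  ens2 <- tibble::tibble(trajectory_id = "t1", frame = 1:4,
                         dof_id = "d1", angle = angles2)
  attr(ens2, "frame_interval_ps") <- 4
  states2 <- assign_states(ens2, fit)
  hier2 <- cluster_hierarchy(states2, ts)
  expect_equal(nrow(label_tse_events(ens2, regions, hier2, "T1")), 0L)
})

test_that("lifetime statistics summarize event groups", {
  ev <- tibble::tibble(trajectory_id = "t", dof_id = c("a", "a", "a"),
                       start_frame = 1:3, end_frame = 1:3,
                       n_frames = c(1L, 1L, 2L),
                       lifetime_ps = c(4, 4, 8),
                       from_key = "0", to_key = "1", resolution = "T1")
  st <- lifetime_stats(ev, by = "dof")
  expect_equal(st$mean_lifetime_ps, 16 / 3)
  expect_equal(st$n_events, 3L)
  single <- lifetime_stats(ev[2, ], by = "dof")
  expect_equal(single$mean_lifetime_ps, 4)
  empty <- suppressMessages(lifetime_stats(ev[0, ], by = "dof"))
  expect_equal(nrow(empty), 0L)
})

test_that("synthetic barrier transits produce consistent event sets", {
  sp <- tse_ensemble_spec(seed = 7, size = 0.05)
  ens <- simulate_ensemble(sp)
  fit <- fit_torsion_states(ens)
  states <- assign_states(ens, fit)
  ts <- dof_timescales(states, dofs = select_clustering_dofs(fit))
  hier <- cluster_hierarchy(states, ts)
  res <- hier$resolutions[length(hier$resolutions)]
  regions <- suppressWarnings(derive_tse_regions(ens, fit, ts))
  ev <- label_tse_events(ens, regions, hier, res)
  expect_gt(nrow(ev), 0)
  dt <- frame_interval_ps(ens)
  # lifetimes are positive multiples of the frame interval
  expect_true(all(ev$lifetime_ps > 0))
  expect_true(all(ev$lifetime_ps %% dt == 0))
  # per-DOF event counts never exceed transition counts
  ntr <- stats::setNames(ts$n_trans, ts$dof_id)
  per_dof <- table(ev$dof_id)
  expect_true(all(per_dof <= ntr[names(per_dof)]))
  # nearly every event's flanking pair is a counted network edge; the rare
  # exceptions are runs during which an unrelated DOF also flipped, so the
  # flanking pair was traversed via an intermediate key
  net <- build_network(hier, res)
  edge_ids <- paste(pmin(net$edges$from, net$edges$to),
                    pmax(net$edges$from, net$edges$to))
  ev_from <- as.numeric(ev$from_key)
  ev_to <- as.numeric(ev$to_key)
  ev_ids <- paste(pmin(ev_from, ev_to), pmax(ev_from, ev_to))
  expect_gt(mean(ev_ids %in% edge_ids), 0.9)
})

test_that("noise-free instantaneous flips yield no transition-state frames", {
  sp <- ensemble_spec(1, 3000, 100, list(
    telegraph_spec("d", exit_rates = 0.1, state_centers = c(-90, 90),
                   emission_kappa = Inf)
  ), seed = 91)
  ens <- simulate_ensemble(sp)
  fit <- fit_torsion_states(ens)
  states <- assign_states(ens, fit)
  ts <- dof_timescales(states)
  hier <- cluster_hierarchy(states, ts)
  regions <- suppressWarnings(derive_tse_regions(ens, fit, ts))
  ev <- label_tse_events(ens, regions, hier, hier$resolutions[1])
  expect_lte(nrow(ev), ts$n_trans)
  expect_equal(nrow(ev), 0L)
})
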