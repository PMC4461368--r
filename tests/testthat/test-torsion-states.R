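test_that("histogram binning follows the 1-degree circular convention", {
  h <- build_histogram(rep(0.5, 7))
  expect_s3_class(h, "angle_histogram")
  expect_equal(sum(unclass(h)), 7)
  expect_equal(unclass(h)[181], 7L)  # bin 180 covers [0, 1)
  expect_equal(unclass(build_histogram(-179.5))[1], 1L)   # bin 0
  expect_equal(unclass(build_histogram(180))[1], 1L)      # wraps onto bin 0
  ten <- -180 + c(0, 36, 72, 108, 144, 180, 216, 252, 288, 324) + 0.5
  h10 <- unclass(build_histogram(ten))
  expect_equal(sum(h10 == 1), 10)
  expect_error(build_histogram(numeric(0)), "empty")
  expect_error(build_histogram(-180), "-180")
})

test_that("two clean valleys are both detected", {
  counts <- gaussian_mix_hist(c(-90, 90))
  mins <- find_effective_minima(counts)
  expect_length(mins, 2)
  d_to_valleys <- vapply(mins, function(m) {
    min(circular_distance(m, 0), circular_distance(m, 180))
  }, numeric(1))
  expect_true(all(d_to_valleys < 3))
})

test_that("minima closer than the merge distance collapse to the deeper one", {
  # two valleys 80 degrees apart (depths 10 and 30), high plateau elsewhere
  counts <- anchor_hist(c(-90, -40, 20, 40, 90),
                        c(1000, 10, 400, 30, 1000))
  both <- find_effective_minima(counts, smoothing_window = 1,
                                merge_distance = 60, recenter = FALSE)
  expect_equal(both, c(-40, 40))
  merged <- find_effective_minima(counts, smoothing_window = 1,
                                  merge_distance = 100, recenter = FALSE)
  expect_equal(merged, -40)  # deeper (lower-probability) minimum survives
  shallower <- find_effective_minima(counts, smoothing_window = 1,
                                     merge_distance = 100,
                                     keep = "shallower", recenter = FALSE)
  expect_equal(shallower, 40)
})

test_that("flat histograms yield no minima and plateaus yield central bins", {
  expect_length(find_effective_minima(rep(5, 360)), 0)
  counts <- rep(100L, 360)
  counts[(-10:5) + 181] <- 0L  # zero plateau over [-10, 6)
  got <- find_effective_minima(counts, smoothing_window = 1, recenter = FALSE)
  expect_equal(got, -3)  # central bin, ties to the lower index
})

test_that("minima define cyclic half-open state arcs", {
  counts <- gaussian_mix_hist(c(-30, 150))
  m <- define_states(c(-120, 60), counts, dof_id = "d")
  expect_equal(m$n_states, 2L)
  expect_setequal(m$arcs$start, c(-120, 60))
  arc1 <- m$arcs[m$arcs$start == -120, ]
  expect_equal(arc1$end, 60)
  expect_equal(sum(m$arcs$occupancy), 1)
  # most populated state gets index 0
  expect_equal(m$arcs$state[which.max(m$arcs$occupancy)], 0L)
  m3 <- define_states(c(-150, -30, 90), counts)
  expect_equal(m3$n_states, 3L)
  m0 <- define_states(numeric(0), counts)
  expect_equal(m0$n_states, 1L)
})

test_that("state assignment uses the half-open boundary rule", {
  counts <- gaussian_mix_hist(c(-30, 150))
  m <- define_states(c(-120, 60), counts, dof_id = "d")
  st_inner <- torsionfel:::assign_states_vec(0, m)
  st_boundary <- torsionfel:::assign_states_vec(60, m)
  arc_state <- function(start) m$arcs$state[m$arcs$start == start]
  expect_equal(st_inner, arc_state(-120))
  expect_equal(st_boundary, arc_state(60))   # boundary belongs to its arc start
  m1 <- define_states(numeric(0), counts)
  expect_equal(torsionfel:::assign_states_vec(c(-170, 0, 170), m1),
               rep(0L, 3))
  expect_error(torsionfel:::assign_states_vec(-180, m), "-180")
  expect_error(torsionfel:::assign_states_vec(200, m), "outside")
})

test_that("state arcs partition the circle for random models", {
  set.seed(21)
  grid <- seq(-179.95, 180, by = 0.1)
  for (rep in 1:10) {
    k <- sample(2:4, 1)
    mins <- sort(normalize_angle(stats::runif(1, -180, 180) +
                                   cumsum(stats::runif(k, 60, 120))))
    if (min(outer(mins, mins, circular_distance)[upper.tri(diag(k))]) < 1) next
    m <- define_states(mins, rep(1, 360))
    membership <- vapply(seq_len(nrow(m$arcs)), function(i) {
      sum(torsionfel:::in_arc(grid, m$arcs$start[i], m$arcs$end[i]))
    }, numeric(1))
    expect_equal(sum(membership), length(grid))
    st <- torsionfel:::assign_states_vec(grid, m)
    expect_false(anyNA(st))
  }
})

test_that("noise-free synthetic states are recovered exactly", {
  sp <- ensemble_spec(2, 2000, 100, list(
    telegraph_spec("a", exit_rates = 0.05, state_centers = c(-60, 120),
                   emission_kappa = Inf),
    telegraph_spec("b", exit_rates = 0.01, state_centers = c(-100, 20, 140),
                   n_states = 3, emission_kappa = Inf)
  ), seed = 17)
  ens <- simulate_ensemble(sp)
  fit <- fit_torsion_states(ens)
  states <- assign_states(ens, fit)
  for (d in c("a", "b")) {
    sub <- states[states$dof_id == d, ]
    tab <- table(sub$state, sub$state_true)
    # a bijection between assigned and true labels covers every frame
    expect_equal(sum(apply(tab, 1, max)), nrow(sub))
    expect_equal(sum(apply(tab, 1, max) == rowSums(tab)), nrow(tab))
  }
})

test_that("clustering DOF selection follows the generator's ground truth", {
  sp <- ensemble_spec(2, 3000, 100, list(
    telegraph_spec("two1", exit_rates = 0.05, state_centers = c(-60, 120)),
    telegraph_spec("two2", exit_rates = 0.02, state_centers = c(-90, 90)),
    telegraph_spec("chi1", exit_rates = 0.05, state_centers = c(-100, 20, 140),
                   n_states = 3, dof_kind = "chi1"),
    telegraph_spec("frozen", exit_rates = c(1e-9, 10),
                   state_centers = c(-60, 120))
  ), seed = 19)
  ens <- simulate_ensemble(sp)
  fit <- fit_torsion_states(ens)
  expect_setequal(select_clustering_dofs(fit, "backbone"), c("two1", "two2"))
  expect_setequal(select_clustering_dofs(fit, "sidechain"),
                  c("two1", "two2", "chi1"))
})

test_that("effective minima are pairwise at least 60 degrees apart", {
  set.seed(33)
  for (rep in 1:15) {
    k <- sample(1:4, 1)
    peaks <- sort(stats::runif(k, -180, 180))
    counts <- gaussian_mix_hist(peaks, sd = stats::runif(1, 10, 30)) +
      rpois(360, 2)
    mins <- find_effective_minima(counts)
    if (length(mins) >= 2) {
      d <- outer(mins, mins, circular_distance)
      expect_gte(min(d[upper.tri(d)]), 60)
    }
  }
})

test_that("tidy/glance/write_state_models expose the fitted arcs", {
  sp <- ensemble_spec(1, 1000, 100, list(
    telegraph_spec("a", exit_rates = 0.05, state_centers = c(-60, 120))
  ), seed = 2)
  fit <- fit_torsion_states(simulate_ensemble(sp))
  td <- tidy(fit)
  expect_true(all(c("dof_id", "state", "start", "end", "occupancy") %in%
                    names(td)))
  gl <- glance(fit)
  expect_equal(gl$n_states, 2L)
  f <- tempfile()
  write_state_models(fit, f)
  expect_true(file.exists(f))
  expect_gt(nrow(utils::read.delim(f)), 0)
  unlink(f)
})
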