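# assigned-state tibble for several DOFs with fixed per-frame states
multi_dof_states <- function(mat, bands, frame_interval = 100) {
  dofs <- colnames(mat)
  out <- purrr::map_dfr(dofs, function(d) {
    tibble::tibble(trajectory_id = "t1", frame = seq_len(nrow(mat)),
                   dof_id = d, state = as.integer(mat[, d]))
  })
  attr(out, "frame_interval_ps") <- frame_interval
  ts <- tibble::tibble(dof_id = dofs, n_trans = 1L, total_time_us = 200,
                       t_w_us = 1, band = bands)
  list(states = out, timescales = ts)
}

test_that("frames are encoded with one bit per two-state DOF, coarse first", {
  mat <- cbind(a = 0L, b = 1L, c = 1L)
  x <- multi_dof_states(mat, bands = c("T1", "T1", "T1"))
  enc <- encode_frames(x$states, x$timescales, "T1")
  expect_equal(enc$key, 3)  # bits 011
  layout <- attr(enc, "layout")
  expect_equal(layout$dof_id, c("a", "b", "c"))
  expect_equal(layout$shift, c(2L, 1L, 0L))
  # all DOFs in state 0 -> key 0
  mat0 <- cbind(a = 0L, b = 0L, c = 0L)
  x0 <- multi_dof_states(mat0, bands = c("T1", "T1", "T1"))
  expect_equal(encode_frames(x0$states, x0$timescales, "T1")$key, 0)
})

test_that("DOFs finer than the resolution are excluded from the key", {
  mat <- cbind(a = 1L, b = 1L, c = 1L, d = 1L, e = 1L, f = 1L, g = 1L)
  x <- multi_dof_states(mat, bands = c("T0", "T1", rep("T3", 5)))
  enc <- encode_frames(x$states, x$timescales, "T1")
  expect_equal(attr(enc, "layout")$total_bits[1], 2L)
  expect_equal(enc$key, 3)
})

test_that("radix grouping matches small worked examples", {
  tab <- cluster_frames(c(3, 3, 1, 3))
  expect_equal(tab$key, c(3, 1))
  expect_equal(tab$W, c(0.75, 0.25))
  one <- cluster_frames(rep(7, 10))
  expect_equal(nrow(one), 1L)
  expect_equal(one$W, 1)
})

test_that("radix grouping equals naive grouping on random instances", {
  set.seed(77)
  for (rep in 1:50) {
    d <- sample(2:20, 1)
    n <- 1000
    mat <- matrix(sample(0:1, n * d, replace = TRUE), nrow = n,
                  dimnames = list(NULL, sprintf("d%02d", seq_len(d))))
    x <- multi_dof_states(mat, bands = rep("T2", d))
    enc <- encode_frames(x$states, x$timescales, "T2")
    tab <- cluster_frames(enc$key)
    oracle <- naive_group(mat)
    expect_equal(nrow(tab), nrow(oracle))
    expect_equal(sort(tab$count, decreasing = TRUE), oracle$count)
    expect_equal(sum(tab$W), 1, tolerance = 1e-12)
  }
})

test_that("wide keys fall back to strings with identical grouping", {
  set.seed(5)
  d <- 60  # > 52 bits forces the string-key path
  n <- 500
  mat <- matrix(sample(0:1, n * d, replace = TRUE,
                       prob = c(0.9, 0.1)), nrow = n,
                dimnames = list(NULL, sprintf("d%02d", seq_len(d))))
  x <- multi_dof_states(mat, bands = rep("T2", d))
  enc <- encode_frames(x$states, x$timescales, "T2")
  expect_type(enc$key, "character")
  tab <- cluster_frames(enc$key)
  oracle <- naive_group(mat)
  expect_equal(sort(tab$count, decreasing = TRUE), oracle$count)
})

test_that("the fine partition refines the coarse partition exactly", {
  sp <- ensemble_spec(3, 4000, 100, list(
    telegraph_spec("slow1", exit_rates = 0.005, state_centers = c(-60, 120)),
    telegraph_spec("slow2", exit_rates = 0.005, state_centers = c(-90, 90)),
    telegraph_spec("fast1", exit_rates = 0.5, state_centers = c(-70, 110)),
    telegraph_spec("fast2", exit_rates = 0.5, state_centers = c(-60, 120))
  ), seed = 41)
  ens <- simulate_ensemble(sp)
  fit <- fit_torsion_states(ens)
  states <- assign_states(ens, fit)
  ts <- dof_timescales(states, dofs = select_clustering_dofs(fit))
  hier <- cluster_hierarchy(states, ts)
  expect_gte(length(hier$resolutions), 2)
  ncs <- vapply(hier$tables, nrow, integer(1))
  expect_true(all(diff(ncs) >= 0))  # N_CS non-decreasing with finer bands
  for (i in seq_along(hier$resolutions)) {
    res <- hier$resolutions[i]
    tab <- hier$tables[[res]]
    expect_equal(sum(tab$W), 1, tolerance = 1e-12)
    expect_equal(sum(tab$count), hier$n_frames)
    if (i > 1) {
      coarse <- hier$tables[[hier$resolutions[i - 1]]]
      # every fine cluster's parent exists and coarse counts are the sums
      expect_true(all(tab$parent_key %in% coarse$key))
      sums <- tapply(tab$count, tab$parent_key, sum)
      expect_equal(as.vector(sums[as.character(coarse$key)]),
                   coarse$count)
      # per-frame check: frames of one fine key all carry the parent key
      fk <- hier$frame_keys
      pmap <- stats::setNames(tab$parent_key, as.character(tab$key))
      expect_true(all(pmap[as.character(fk[[res]])] ==
                        fk[[hier$resolutions[i - 1]]]))
    }
  }
})

test_that("adding a three-state DOF never decreases the cluster count", {
  set.seed(9)
  n <- 2000
  base <- matrix(sample(0:1, n * 3, replace = TRUE), nrow = n,
                 dimnames = list(NULL, c("a", "b", "c")))
  chi <- sample(0:2, n, replace = TRUE)
  x1 <- multi_dof_states(base, bands = rep("T2", 3))
  t1 <- cluster_frames(encode_frames(x1$states, x1$timescales, "T2")$key)
  mat2 <- cbind(base, chi = chi)
  x2 <- multi_dof_states(mat2, bands = rep("T2", 4))
  enc2 <- encode_frames(x2$states, x2$timescales, "T2")
  expect_equal(attr(enc2, "layout")$bits[
    attr(enc2, "layout")$dof_id == "chi"], 2L)
  t2 <- cluster_frames(enc2$key)
  expect_gte(nrow(t2), nrow(t1))
})

test_that("external structures are assigned by the same key rule", {
  sp <- ensemble_spec(2, 3000, 100, list(
    telegraph_spec("a", exit_rates = 0.02, state_centers = c(-60, 120)),
    telegraph_spec("b", exit_rates = 0.02, state_centers = c(-90, 90))
  ), seed = 43)
  ens <- simulate_ensemble(sp)
  fit <- fit_torsion_states(ens)
  states <- assign_states(ens, fit)
  ts <- dof_timescales(states, dofs = select_clustering_dofs(fit))
  hier <- cluster_hierarchy(states, ts)
  res <- hier$resolutions[length(hier$resolutions)]
  # a structure at the most-populated state centers lands in a real cluster
  centers <- c(a = -60, b = -90)
  got <- assign_external_structure(centers, fit, ts, hier, res)
  expect_equal(got$verdict, "member")
  expect_gt(got$W, 0)
  expect_error(assign_external_structure(c(a = -60), fit, ts, hier, res),
               "missing dihedral")
  # reference flagging marks the harboring cluster at every resolution
  hier2 <- flag_reference_clusters(hier, list(ref1 = centers), fit, ts)
  for (r in hier2$resolutions) {
    expect_equal(sum(hier2$tables[[r]]$harbors_reference), 1L)
  }
  # a structure from the dominant synthetic state lands in the top cluster
  top <- hier2$tables[[res]]
  expect_true(top$harbors_reference[1] ||
                top$W[match(as.character(got$key), as.character(top$key))] >
                0.1)
})

test_that("cluster tables export with layout metadata", {
  mat <- cbind(a = c(0L, 1L, 0L), b = c(1L, 1L, 0L))
  x <- multi_dof_states(mat, bands = c("T1", "T1"))
  hier <- cluster_hierarchy(x$states, x$timescales)
  dir <- tempfile()
  paths <- write_cluster_tables(hier, dir)
  expect_true(all(file.exists(file.path(dir, paste0("clusters_",
                                                    hier$resolutions,
                                                    ".tsv")))))
  first <- readLines(file.path(dir, paste0("clusters_", hier$resolutions[1],
                                           ".tsv")))[1]
  expect_match(first, "dof_order")
  unlink(dir, recursive = TRUE)
})
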