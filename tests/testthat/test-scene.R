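test_that("scene generation is deterministic and respects degenerate input", {
  acq <- small_acq()
  s1 <- make_neuron_scene(5, acq, seed = 1)
  s2 <- make_neuron_scene(5, acq, seed = 1)
  expect_identical(s1$label_map, s2$label_map)
  s3 <- make_neuron_scene(5, acq, seed = 2)
  expect_false(identical(s1$label_map, s3$label_map))
  expect_error(make_neuron_scene(0, acq), "n_cells")
  empty <- make_neuron_scene(0, acq, allow_empty = TRUE)
  expect_equal(length(empty$cells), 0)
  expect_true(all(empty$label_map == 0))
})

test_that("neuron truth masks are disjoint and counted by brute-force labelling", {
  acq <- acquisition_settings(c(512L, 512L))
  sc <- make_neuron_scene(10, acq, seed = 1)
  nuc <- sc$truth
  all_nuc <- unlist(lapply(nuc, `[[`, "nucleus"))
  expect_equal(length(all_nuc), length(unique(all_nuc)))
  # render the union of nucleus masks and count 8-connected components
  m <- matrix(FALSE, 512, 512)
  m[all_nuc] <- TRUE
  lab <- photofade:::label8(m)
  expect_equal(max(lab), 10)
})

test_that("truth pixels lie where the label map is positive", {
  acq <- small_acq()
  for (sc in list(make_neuron_scene(4, acq, seed = 3),
                  make_microglia_scene(3, acq, seed = 3))) {
    px <- unlist(lapply(sc$truth, `[[`, "profile"))
    expect_true(all(sc$label_map[px] > 0))
    outside <- setdiff(seq_along(sc$label_map), px)
    expect_true(all(sc$label_map[outside] == 0))
  }
})

test_that("microglial profiles are 8-connected, disjoint and in frame", {
  acq <- acquisition_settings(c(512L, 512L))
  sc <- make_microglia_scene(5, acq, seed = 7)
  expect_equal(length(sc$cells), 5)
  all_px <- unlist(lapply(sc$truth, `[[`, "profile"))
  expect_equal(length(all_px), length(unique(all_px)))
  for (tr in sc$truth) {
    m <- matrix(FALSE, 512, 512)
    m[tr$profile] <- TRUE
    lab <- photofade:::label8(m)
    expect_equal(max(lab), 1)
    rows <- ((tr$profile - 1L) %% 512L) + 1L
    cols <- ((tr$profile - 1L) %/% 512L) + 1L
    expect_true(min(rows) > 1 && max(rows) < 512)
    expect_true(min(cols) > 1 && max(cols) < 512)
  }
  expect_error(make_microglia_scene(1, acq), "2..5")
  expect_error(make_microglia_scene(6, acq), "2..5")
})

test_that("zero branching probability yields unbranched primary processes", {
  acq <- small_acq()
  par <- scene_params()
  par$branch_prob <- 0
  sc <- make_microglia_scene(2, acq, seed = 11, params = par)
  for (cl in sc$cells) {
    n_primary <- sum(vapply(cl$branches, function(s) s$depth == 1L, logical(1)))
    # every chain extends to max_depth without splitting
    expect_equal(length(cl$branches), n_primary * par$max_depth)
    for (d in seq_len(par$max_depth))
      expect_equal(sum(vapply(cl$branches, function(s) s$depth == d,
                              logical(1))), n_primary)
  }
})

test_that("branch widths taper and never increase from root to tip", {
  sc <- make_microglia_scene(3, small_acq(), seed = 13)
  for (cl in sc$cells) {
    w_by_depth <- vapply(split(
      vapply(cl$branches, `[[`, numeric(1), "width"),
      vapply(cl$branches, `[[`, numeric(1), "depth")), max, numeric(1))
    expect_true(all(diff(w_by_depth) <= 0))
    expect_equal(unname(max(w_by_depth)), scene_params()$root_width)
    expect_equal(unname(min(w_by_depth)), scene_params()$tip_width)
  }
})
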