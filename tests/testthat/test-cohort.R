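# Pipeline-level behaviour on a scaled-down configuration: the full-size
# calibrated cohort is exercised in test-acceptance.R.

small_config <- function() {
  cfg <- experiment_config(
    master_seed = 7L, n_fields = 3L,
    acquisition = acquisition_settings(c(256L, 256L)),
    schedule = acquisition_schedule(c(0, 60, 120, 900)),
    presets = default_presets())
  for (arm in c("a488", "a546")) {
    cfg$scene_params[[arm]]$n_neurons <- 6L
    # smaller microglia so 2-5 cells fit a quarter-size field
    cfg$scene_params[[arm]]$seg_len_range <- c(4, 8)
    cfg$scene_params[[arm]]$max_depth <- 3L
  }
  cfg$calibrated <- TRUE   # keep the stage-2 defaults
  cfg
}

test_that("census calibration recovers self-generated targets", {
  cfg <- experiment_config()
  # round trip: targets produced by the predictor at a known parameter set
  sp0 <- cfg$scene_params$a488
  sp0$nucleus_dim_w <- 0.4
  sp0$nucleus_amp_meanlog <- log(12)
  sp0$nucleus_amp_sdlog <- 0.9
  preset <- default_presets()$a488
  acq <- cfg$acquisition
  probe <- photofade:::probe_background(acq, 13.5)
  bg_fun <- function(diff) probe
  tt <- c(60, 900)
  tgt <- photofade:::predict_census(sp0, preset, acq, bg_fun, cfg$c, tt,
                                    sp0$signal_share)
  names(tgt) <- tt
  fit <- calibrate_cohort(
    cfg,
    census_targets = list(a488 = tgt, a546 = NULL),
    coverage_targets = list(a488 = NULL, a546 = NULL))
  rep <- fit$calibration$a488_census
  expect_lt(max(abs(rep$predicted - rep$target)), 0.5)
})

test_that("empty calibration targets leave the config unchanged with a warning", {
  cfg <- experiment_config(presets = default_presets())
  expect_warning(out <- calibrate_cohort(
    cfg,
    census_targets = list(a488 = NULL, a546 = NULL),
    coverage_targets = list(a488 = NULL, a546 = NULL)), "unchanged")
  expect_identical(out$scene_params, cfg$scene_params)
  expect_true(out$calibrated)
})

test_that("the experiment pipeline is byte-stable under a fixed seed", {
  cfg <- small_config()
  r1 <- run_experiment(cfg)
  r2 <- run_experiment(cfg)
  expect_identical(r1$loss, r2$loss)
  expect_identical(r1$census, r2$census)
  expect_identical(r1$coverage, r2$coverage)
  expect_identical(r1$fractal_changes, r2$fractal_changes)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  p1 <- write_run_csv(r1, d1); p2 <- write_run_csv(r2, d2)
  for (k in seq_along(p1))
    if (file.exists(p1[k]))
      expect_identical(readLines(p1[k]), readLines(p2[k]))
})

test_that("a run report carries every measurement the study design asks for", {
  cfg <- small_config()
  rep <- run_experiment(cfg)
  expect_setequal(unique(rep$loss$fluorophore), c("a488", "a546"))
  expect_setequal(unique(rep$loss$kind), c("neuron", "microglia"))
  expect_equal(sort(unique(rep$loss$t_s)), c(0, 60, 120, 900))
  # census covers each arm's neuronal fields
  expect_equal(nrow(rep$census), 2 * 3 * 4)
  # seven morphometric parameters per arm when profiles were found
  if (!is.null(rep$fractal_changes))
    expect_true(all(table(rep$fractal_changes$fluorophore) == 7))
  # statistics: gated omnibus with post hoc stars against baseline
  for (arm in c("a488", "a546")) {
    st <- rep$stats[[arm]]
    expect_true(st$intensity$gate %in% c("parametric", "nonparametric"))
    expect_true(all(st$intensity$posthoc$p_adj >=
                      st$intensity$posthoc$p_raw - 1e-12))
    expect_true(all(st$coverage$posthoc$stars %in%
                      c("ns", "*", "**", "***")))
  }
  # descriptive decay fits exist per arm with finite coefficients
  expect_true(all(is.finite(rep$decay_fits$a488$poly2$coeffs)))
})
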