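test_that("background estimation uses truth moments or mode plus MAD", {
  const <- matrix(20L, 32, 32)
  expect_warning(bg <- estimate_background(const), "constant")
  expect_equal(bg$mu_b, 20)
  expect_equal(bg$sigma_b, 0)

  set.seed(3)
  f <- matrix(pmax(0L, as.integer(round(rnorm(128 * 128, 20, 3)))), 128, 128)
  truth_px <- seq_len(128 * 128)
  bg <- estimate_background(f, truth_px)
  expect_equal(bg$mu_b, mean(f))
  expect_equal(bg$sigma_b, sd(f))

  # blind mode estimator on a 90%-background frame
  f2 <- f
  bright <- sample(length(f2), round(0.1 * length(f2)))
  f2[bright] <- 200L
  bg2 <- estimate_background(f2)
  expect_lt(abs(bg2$mu_b - 20), 1)
})

test_that("the nucleus-detectability predicate follows its definition", {
  bg <- list(mu_b = 20, sigma_b = 2)
  f <- matrix(20L, 32, 32)
  nuc <- 1:50
  expect_false(nucleus_detectable(f, nuc, bg))
  f[nuc] <- 40L   # 10 sigma above background
  expect_true(nucleus_detectable(f, nuc, bg))
  # half the nucleus bright, half at background: the covered fraction sits
  # exactly on the f_min boundary
  f[nuc[1:25]] <- 40L; f[nuc[26:50]] <- 20L
  expect_true(nucleus_detectable(f, nuc, bg, c = 3, f_min = 0.5))
  expect_false(nucleus_detectable(f, nuc, bg, c = 3, f_min = 0.6))
})

test_that("census reduction matches an analytic construction", {
  acq <- acquisition_settings(c(128L, 128L), background_level = 10)
  # nine bright nuclei and one that crosses the 3-sigma cutoff between
  # 30 s and 60 s under a 60 s half-life: amplitude 10, cutoff 6
  sc <- manual_nucleus_scene(c(rep(100, 9), 10))
  ser <- generate_time_series(sc, halflife_preset(), acq, seed = 1,
                              noise = FALSE)
  bg <- list(mu_b = 10, sigma_b = 2, source = "constructed")
  cen <- census(ser, bg = bg)
  expect_equal(cen$curve$reduction_pct[ser$times == 0], 0)
  expect_equal(cen$curve$reduction_pct[ser$times == 30], 0)
  expect_equal(cen$curve$reduction_pct[ser$times == 60], 10)
  expect_equal(cen$curve$reduction_pct[ser$times == 120], 10)
  expect_equal(cen$records$faded_at[10], 60)
  # the bright nuclei outlast the dim one (they fade only once the
  # half-life erodes them below the cutoff, after 120 s here)
  expect_true(all(cen$records$faded_at[1:9] > 120))
})

test_that("census is zero under a non-bleaching preset and monotone without noise", {
  acq <- small_acq()
  sc <- make_neuron_scene(8, acq, seed = 12)
  inert <- generate_time_series(sc, no_bleach_preset(), acq, seed = 1,
                                noise = FALSE)
  cen <- census(inert)
  expect_true(all(cen$curve$reduction_pct == 0))

  fading <- generate_time_series(sc, default_presets()$a546, acq, seed = 1,
                                 noise = FALSE)
  cen2 <- census(fading)
  expect_true(all(diff(cen2$curve$reduction_pct) >= 0))
  # once faded, always faded
  det <- cen2$detectable
  for (i in seq_len(nrow(det))) {
    if (!det[i, 1]) next
    gone <- which(!det[i, ])
    if (length(gone)) expect_true(all(!det[i, min(gone):ncol(det)]))
  }
})

test_that("census errors without a detectable baseline population", {
  acq <- acquisition_settings(c(128L, 128L), background_level = 10)
  sc <- manual_nucleus_scene(rep(0.5, 3))   # all below the cutoff
  ser <- generate_time_series(sc, halflife_preset(), acq, seed = 1,
                              noise = FALSE)
  bg <- list(mu_b = 10, sigma_b = 2)
  expect_error(census(ser, bg = bg), "no neuron detectable")
  mg <- make_microglia_scene(2, small_acq(), seed = 1)
  ser_mg <- generate_time_series(mg, halflife_preset(), small_acq(), seed = 1)
  expect_error(census(ser_mg), "neuron scene")
})
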