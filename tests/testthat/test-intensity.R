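test_that("mean intensity matches a brute-force oracle", {
  expect_equal(mean_intensity(matrix(100L, 8, 8)), 100)
  cb <- matrix(c(0L, 255L), 16, 16)
  expect_equal(mean_intensity(cb), 127.5)
  set.seed(42)
  f <- matrix(sample(0:255, 256, replace = TRUE), 16, 16)
  acc <- 0
  for (i in 1:16) for (j in 1:16) acc <- acc + f[i, j]
  expect_equal(mean_intensity(f), acc / 256)
})

test_that("loss curves are plain relative arithmetic on frame means", {
  ser <- manual_series(list(matrix(100L, 4, 4), matrix(35L, 4, 4)), c(0, 30))
  lc <- loss_curve(ser)
  expect_equal(lc$loss_pct, c(0, 65))
  same <- manual_series(list(matrix(7L, 4, 4), matrix(7L, 4, 4),
                             matrix(7L, 4, 4)), c(0, 60, 900))
  expect_equal(loss_curve(same)$loss_pct, c(0, 0, 0))
  zero <- manual_series(list(matrix(0L, 4, 4), matrix(0L, 4, 4)), c(0, 30))
  expect_error(loss_curve(zero), "no signal")
})

test_that("noiseless simulated loss follows the closed-form decay expression", {
  acq <- small_acq()
  par <- scene_params()
  # keep amplitudes far from 8-bit saturation: the closed form assumes an
  # unclipped rendering
  par$soma_dim_w <- 1
  par$soma_amp_meanlog <- log(20)
  par$soma_amp_sdlog <- 0.3
  sc <- make_microglia_scene(3, acq, seed = 6, params = par)
  p <- fluorophore_preset("bi", 0.01, 0.0005, 0.6, 0.35)
  times <- c(0, 30, 60, 120, 300, 600, 900)
  # exact agreement holds on the un-quantised expectation
  frames <- lapply(times, function(t) expected_frame(sc, p, acq, t))
  lc <- loss_curve(manual_series(frames, times))
  m0 <- acq$background_level + sc$diffuse_level + mean(sc$label_map)
  sig_frac <- (sc$diffuse_level + mean(sc$label_map)) / m0
  expected <- 100 * sig_frac * (1 - decay_fraction(p, times))
  expect_equal(lc$loss_pct, expected, tolerance = 1e-9)
  # the rendered 8-bit series departs only by quantisation: rounding the
  # (constant) diffuse level shifts a frame mean by at most 0.5 intensity
  # units, i.e. at most 100 * 2 * 0.5 / mean(0) points of loss
  ser <- generate_time_series(sc, p, acq, seed = 1, noise = FALSE)
  expect_lt(max(abs(loss_curve(ser)$loss_pct - expected)),
            100 / mean(ser$frames[[1]]))
})

test_that("decay fits recover exact polynomial and linear relations", {
  t <- c(0, 30, 60, 120, 300, 600, 900)
  quad <- data.frame(t_s = t, loss_pct = 0.001 * t^2 + 0.05 * t)
  fq <- fit_decay(quad)
  expect_equal(unname(fq$poly2$coeffs), c(0, 0.05, 0.001), tolerance = 1e-9)
  lin <- data.frame(t_s = t, loss_pct = 3 + 0.04 * t)
  fl <- fit_decay(lin)
  expect_lt(abs(fl$poly2$coeffs[["a"]]), 1e-12)
  expect_equal(fl$linear$slope, 0.04, tolerance = 1e-12)
  expect_equal(fl$linear$r_squared, 1)
  expect_error(fit_decay(data.frame(t_s = c(1, 1), loss_pct = c(1, 2))),
               "3 distinct")
})

test_that("noisy quadratic coefficients fall within 3 SE of truth", {
  t <- c(0, 30, 60, 120, 300, 600, 900)
  sigma <- 2
  a <- 0.0001; b <- 0.06
  X <- cbind(1, t, t^2)
  # closed-form OLS covariance oracle
  se <- sqrt(diag(solve(crossprod(X))) * sigma^2)
  set.seed(7)
  ok <- 0
  for (r in 1:20) {
    y <- a * t^2 + b * t + rnorm(length(t), 0, sigma)
    fit <- fit_decay(data.frame(t_s = t, loss_pct = y))
    co <- fit$poly2$coeffs
    ok <- ok + all(abs(co - c(0, b, a)) <= 3 * se)
  }
  expect_gte(ok, 18)
})

test_that("loss depends only on frame contents, not on time labels", {
  f <- list(matrix(80L, 4, 4), matrix(60L, 4, 4))
  a <- loss_curve(manual_series(f, c(0, 30)))
  b <- loss_curve(manual_series(f, c(0, 900)))
  expect_equal(a$loss_pct, b$loss_pct)
})
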