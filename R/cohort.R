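#' Published census and coverage calibration targets
#'
#' Stage-2 calibration targets for scene heterogeneity, from the printed
#' results: detectable-neuron reduction of ~10\% at 60 s for both dyes,
#' 22\% at 900 s for A488 Plus and 20\% at 120 s for A546; microglial
#' area-coverage change of ~55\% at 60 s and ~90\% at 300 s regardless of
#' the dye.
#'
#' @param fluorophore \code{"a488"} or \code{"a546"}.
#' @return named numeric vector (names: seconds, values: percent).
#' @export
printed_census_targets <- function(fluorophore = c("a488", "a546")) {
  fluorophore <- match.arg(fluorophore)
  switch(fluorophore,
    a488 = c(`60` = 10, `900` = 22),
    a546 = c(`60` = 10, `120` = 20))
}

#' @rdname printed_census_targets
#' @export
printed_coverage_targets <- function(fluorophore = c("a488", "a546")) {
  fluorophore <- match.arg(fluorophore)
  c(`60` = 55, `300` = 90)
}

#' Experiment configuration
#'
#' Bundles everything one full study run needs: the two presets (or their
#' calibration targets), schedule, acquisition, cohort sizes (15 fields
#' per group, 2 selected profiles per microglial field), per-arm scene
#' parameters, analysis knobs and the master seed. All defaults match the
#' study design.
#'
#' @param master_seed integer master seed; every stochastic step derives
#'   its own seed from it.
#' @param n_fields fields per group (default 15).
#' @param profiles_per_field selected microglial profiles per field
#'   (default 2, 30 per arm).
#' @param acquisition an \code{\link{acquisition_settings}}.
#' @param schedule an \code{\link{acquisition_schedule}}.
#' @param presets named list of presets, or NULL to calibrate from
#'   \code{\link{printed_loss_targets}}.
#' @param c,f_min nucleus-detectability knobs (see
#'   \code{\link{nucleus_detectable}}).
#' @param k coverage cutoff multiplier (see \code{\link{coverage_curve}}).
#' @param k_profile cutoff multiplier of the per-frame background
#'   threshold used when binarising single-cell profiles.
#' @param box_origins grid origins for box counting.
#' @param calib_tolerance stage-2 tolerance (percentage points).
#' @return object of class \code{experiment_config}.
#' @export
experiment_config <- function(master_seed = 20260921L,
                              n_fields = 15L,
                              profiles_per_field = 2L,
                              acquisition = acquisition_settings(),
                              schedule = acquisition_schedule(),
                              presets = NULL,
                              c = 3, f_min = 0.5, k = 3, k_profile = 2,
                              box_origins = 4L,
                              calib_tolerance = 5) {
  structure(list(
    master_seed = as.integer(master_seed) %% 2147483647L,
    n_fields = as.integer(n_fields),
    profiles_per_field = as.integer(profiles_per_field),
    acquisition = acquisition, schedule = schedule,
    presets = presets,
    scene_params = list(a488 = scene_params(), a546 = scene_params()),
    c = c, f_min = f_min, k = k, k_profile = k_profile,
    box_origins = as.integer(box_origins),
    calib_tolerance = calib_tolerance,
    calibrated = FALSE
  ), class = "experiment_config")
}

# ---- stage-2 analytic predictors -------------------------------------------

# Background statistics the frame estimator would report for a pure
# background field at diffuse level `diff`, from the exact
# Poisson (x) Gaussian pixel-value distribution. The MAD of quantised
# 8-bit noise is a sawtooth in the underlying level (it depends on where
# the mode falls between integer bins), so the probe is evaluated at the
# exact level of interest, never interpolated across levels.
probe_background <- function(acquisition, diff) {
  ps <- acquisition$photon_scale
  rs <- max(acquisition$read_noise_sd, 1e-9)
  lvl <- (acquisition$background_level + diff) * ps
  j <- 0:ceiling(lvl + 8 * sqrt(lvl + 1) + 4)
  pj <- stats::dpois(j, lvl)
  sdv <- sqrt(lvl / ps^2 + rs^2)
  ks <- max(0, floor(lvl / ps - 8 * sdv)):min(255, ceiling(lvl / ps + 8 * sdv))
  # P(value = k) after read noise and rounding
  cdf_hi <- outer(ks + 0.5, j / ps, function(a, b)
    stats::pnorm((a - b) / rs)) %*% pj
  cdf_lo <- outer(ks - 0.5, j / ps, function(a, b)
    stats::pnorm((a - b) / rs)) %*% pj
  pmf <- as.vector(cdf_hi - cdf_lo)
  m <- which.max(pmf)
  mu <- ks[m]
  if (m > 1 && m < length(ks)) {
    denom <- pmf[m - 1] - 2 * pmf[m] + pmf[m + 1]
    if (denom < 0) mu <- mu + 0.5 * (pmf[m - 1] - pmf[m + 1]) / denom
  }
  # distribution median of |value - mu|, matching the sample MAD
  adev <- abs(ks - mu)
  o <- order(adev)
  cum <- cumsum(pmf[o])
  med <- adev[o][min(which(cum >= 0.5 * sum(pmf)))]
  list(mu_b = mu, sigma_b = 1.4826 * med)
}

# P(rounded pixel value >= T) for expected level `lvl` under the camera
# noise model. Gaussian approximation in the far tails; exact
# Poisson (x) Gaussian convolution in the near-threshold band, where the
# shot-noise skew biases the Gaussian approximation.
p_above <- function(lvl, T, acquisition) {
  ps <- acquisition$photon_scale
  rs <- acquisition$read_noise_sd
  thr <- ceiling(T) - 0.5
  sd <- sqrt(lvl / ps + rs^2)
  out <- stats::pnorm((lvl - thr) / pmax(sd, 1e-9))
  band <- which(abs(lvl - thr) < 8 * sd + 1)
  if (length(band)) {
    lv <- lvl[band] * ps
    j <- 0:ceiling(max(lv) + 8 * sqrt(max(lv) + 1) + 4)
    pj <- outer(lv, j, function(l, jj) stats::dpois(jj, l))
    tail <- stats::pnorm((j / ps - thr) / max(rs, 1e-9))
    out[band] <- as.vector(pj %*% tail)
  }
  out
}

# E[min(X, cap)] for X ~ lognormal(mu, sd).
e_capped_lnorm <- function(mu, sd, cap) {
  exp(mu + sd^2 / 2) * stats::pnorm((log(cap) - mu - sd^2) / sd) +
    cap * (1 - stats::pnorm((log(cap) - mu) / sd))
}

# Mixture CDF of the capped nucleus amplitude.
nucleus_cdf <- function(x, sp) {
  if (x >= sp$amp_cap) return(1)
  sp$nucleus_dim_w *
    stats::plnorm(x, sp$nucleus_amp_meanlog, sp$nucleus_amp_sdlog) +
    (1 - sp$nucleus_dim_w) *
    stats::plnorm(x, sp$nucleus_bright_meanlog, sp$nucleus_bright_sdlog)
}

# Expected whole-frame mean amplitude contributed by the neurons, used to
# size the diffuse staining budget per candidate.
neuron_label_mean <- function(sp, acquisition) {
  a <- mean(sp$soma_axis_range)
  b <- a * mean(sp$soma_aspect_range)
  soma_area <- pi * a * b
  nuc_area <- pi * (sp$nucleus_radius_frac * b)^2
  e_mix <- function(scale) {
    sp$nucleus_dim_w *
      e_capped_lnorm(sp$nucleus_amp_meanlog + log(scale),
                     sp$nucleus_amp_sdlog, sp$amp_cap) +
      (1 - sp$nucleus_dim_w) *
      e_capped_lnorm(sp$nucleus_bright_meanlog + log(scale),
                     sp$nucleus_bright_sdlog, sp$amp_cap)
  }
  # soma pixels carry the chord weight (mean 2/3 over the ellipse)
  sp$n_neurons * (nuc_area * e_mix(1) +
                    (soma_area - nuc_area) * (2 / 3) *
                      e_mix(sp$soma_amp_ratio)) /
    prod(acquisition$field_shape)
}

# Predicted detectable-neuron reduction (%) at times tt for nucleus
# amplitudes drawn from the capped bright/dim mixture in `sp`.
predict_census <- function(sp, preset, acquisition, bg_fun, cc, tt,
                           signal_share) {
  s_tot <- acquisition$background_level * signal_share / (1 - signal_share)
  diff <- max(0, s_tot - neuron_label_mean(sp, acquisition))
  bg <- bg_fun(diff)
  cut_at <- function(t) {
    d <- decay_fraction(preset, t)
    (diff * (1 - d) + cc * bg$sigma_b +
       (bg$mu_b - acquisition$background_level - diff)) / d
  }
  p0 <- nucleus_cdf(cut_at(0), sp)
  vapply(tt, function(t) {
    pt <- nucleus_cdf(cut_at(t), sp)
    100 * (max(pt, p0) - p0) / (1 - p0)
  }, numeric(1))
}

# Reference microglial cell pool for the coverage predictor. Each cell,
# generated with unit lognormal soma amplitude, is reduced to a weighted
# histogram of its pixel amplitudes *relative to the soma amplitude*
# (w = amp / M_ref). A cell with soma amplitude M then has pixel
# amplitudes M * w at identical geometry, so a candidate (meanlog, sdlog)
# can be evaluated by integrating over M analytically instead of relying
# on the handful of M values a few scenes would sample.
reference_cell_pool <- function(config, n_scenes = 16L, bins = 32L) {
  par0 <- config$scene_params[[1]]
  par0$soma_dim_w <- 1
  par0$soma_amp_meanlog <- 0; par0$soma_amp_sdlog <- 1
  cells <- list()
  n_px_frame <- prod(config$acquisition$field_shape)
  for (i in seq_len(n_scenes)) {
    n_cells <- with_seed_local(derive_seed(config$master_seed, 900L, i),
                               sample(2:5, 1))
    sc <- make_microglia_scene(n_cells, config$acquisition,
                               seed = derive_seed(config$master_seed, 901L, i),
                               params = par0)
    for (j in seq_along(sc$truth)) {
      w <- sort(sc$label_map[sc$truth[[j]]$profile] /
                  sc$cells[[j]]$soma_intensity)
      grp <- ceiling(seq_along(w) / (length(w) / bins))
      cells[[length(cells) + 1L]] <-
        list(w = as.numeric(tapply(w, grp, mean)),
             cnt = as.numeric(tapply(w, grp, length)),
             n_px = length(w))
    }
  }
  list(cells = cells, n_px_frame = n_px_frame, n_scenes = n_scenes)
}

# Fixed field compositions (common random numbers) over which coverage
# candidates are compared: cell picks from the pool and brightness
# quantiles per cell.
coverage_field_draws <- function(config, pool, n_fields = 400L) {
  with_seed_local(derive_seed(config$master_seed, 905L), {
    lapply(seq_len(n_fields), function(i) {
      n_c <- sample(2:5, 1)
      list(cell = sample(length(pool$cells), n_c, replace = TRUE),
           u = stats::runif(n_c))
    })
  })
}

# Quantile function of the bright/dim soma-amplitude mixture.
q_soma_mix <- function(u, sp) {
  w <- sp$soma_dim_w
  ifelse(u < w,
         stats::qlnorm(pmin(pmax(u / w, 1e-6), 1 - 1e-6),
                       sp$soma_amp_meanlog, sp$soma_amp_sdlog),
         stats::qlnorm(pmin(pmax((u - w) / (1 - w), 1e-6), 1 - 1e-6),
                       sp$soma_bright_meanlog, sp$soma_bright_sdlog))
}

# Expected whole-frame mean amplitude contributed by microglia under `sp`,
# per unit of the capped mixture expectation.
e_soma_mix_capped <- function(sp, cap) {
  sp$soma_dim_w * e_capped_lnorm(sp$soma_amp_meanlog, sp$soma_amp_sdlog, cap) +
    (1 - sp$soma_dim_w) *
    e_capped_lnorm(sp$soma_bright_meanlog, sp$soma_bright_sdlog, cap)
}

# Predicted mean per-field coverage change (%) at times tt for the soma
# amplitude mixture in `sp`: per-cell expected mask areas are tabulated on
# a log-brightness grid and combined over the fixed field draws.
predict_coverage <- function(sp, pool, draws, preset, acquisition,
                             bg_fun, kk, tt, signal_share) {
  amp_cap <- sp$amp_cap
  s_tot <- acquisition$background_level * signal_share / (1 - signal_share)
  cells <- pool$cells
  # diffuse budget: expected label contribution per frame; the pool was
  # generated at unit soma amplitude, so scale its mean pixel weight by the
  # mixture mean (capping applied at the pixel level, approximated at the
  # soma level here — the cap rarely binds below it)
  w_mean <- sum(vapply(cells, function(cl) sum(cl$cnt * cl$w), numeric(1))) /
    (pool$n_scenes * pool$n_px_frame)
  contrib <- w_mean * e_soma_mix_capped(sp, amp_cap)
  diff <- max(0, s_tot - contrib)
  bg <- bg_fun(diff)
  T <- bg$mu_b + kk * bg$sigma_b
  times <- c(0, tt)
  dts <- decay_fraction(preset, times)
  # P(mask) as a function of amplitude, tabulated per time
  sg <- c(0, exp(seq(log(0.02), log(amp_cap), length.out = 240)))
  p_tab <- lapply(dts, function(d)
    p_above(acquisition$background_level + (diff + sg) * d, T, acquisition))
  p_bg <- vapply(dts, function(d)
    p_above(acquisition$background_level + diff * d, T, acquisition),
    numeric(1))
  # expected in-mask pixel count per cell on a log soma-amplitude grid
  mg <- exp(seq(log(0.5), log(amp_cap * 2), length.out = 33))
  area_cm <- lapply(seq_along(times), function(ti) {
    t(vapply(cells, function(cl) {
      s_mat <- pmin(outer(cl$w, mg), amp_cap)
      pv <- matrix(stats::approx(sg, p_tab[[ti]], xout = as.vector(s_mat),
                                 rule = 2)$y, nrow = length(cl$w))
      as.vector(cl$cnt %*% pv)
    }, numeric(length(mg))))
  })
  # combine over the fixed field draws (linear interpolation in log M)
  cell_id <- unlist(lapply(draws, `[[`, "cell"))
  field_id <- rep(seq_along(draws),
                  vapply(draws, function(d) length(d$cell), integer(1)))
  m <- pmin(pmax(q_soma_mix(unlist(lapply(draws, `[[`, "u")), sp),
                 mg[1]), mg[length(mg)])
  lm <- log(m); lmg <- log(mg)
  im <- pmin(findInterval(lm, lmg), length(mg) - 1L)
  fr <- (lm - lmg[im]) / (lmg[im + 1L] - lmg[im])
  n_px_cells <- vapply(cells, `[[`, numeric(1), "n_px")[cell_id]
  n_bg_field <- pool$n_px_frame - as.numeric(rowsum(n_px_cells, field_id))
  a_field <- vapply(seq_along(times), function(ti) {
    a <- area_cm[[ti]][cbind(cell_id, im)] * (1 - fr) +
      area_cm[[ti]][cbind(cell_id, im + 1L)] * fr
    as.numeric(rowsum(a, field_id)) + n_bg_field * p_bg[ti]
  }, numeric(length(draws)))
  ch <- 100 * abs(a_field[, -1, drop = FALSE] - a_field[, 1]) / a_field[, 1]
  colMeans(ch)
}

# Two-pass coarse-to-fine grid minimisation, refined within the original
# bounds (dispersion parameters in particular must not collapse below
# their lower bound into degenerate point masses).
grid_fit <- function(objective, mu_range, sd_range, n = c(24L, 18L)) {
  mu0 <- mu_range; sd0 <- sd_range
  best <- list(value = Inf)
  for (pass in 1:2) {
    mus <- seq(mu_range[1], mu_range[2], length.out = n[1])
    sds <- seq(sd_range[1], sd_range[2], length.out = n[2])
    for (mu in mus) for (sd in sds) {
      v <- objective(mu, sd)
      if (v < best$value) best <- list(value = v, mu = mu, sd = sd)
    }
    dm <- diff(mu_range) / (n[1] - 1); ds <- diff(sd_range) / (n[2] - 1)
    mu_range <- c(max(mu0[1], best$mu - dm), min(mu0[2], best$mu + dm))
    sd_range <- c(max(sd0[1], best$sd - ds), min(sd0[2], best$sd + ds))
  }
  best
}

#' Two-stage cohort calibration
#'
#' Stage 1 fits each preset's bleaching kinetics to that dye's printed
#' whole-frame intensity-loss schedule (\code{\link{calibrate_fluorophore}}).
#' Stage 2 fits, per dye, the scene-heterogeneity knobs by coarse grid
#' search: the lognormal nucleus-amplitude parameters against the printed
#' detectable-neuron reductions, and the lognormal microglial
#' soma-amplitude parameters against the printed area-coverage changes,
#' using analytic predictors of the full measurement chain (threshold from
#' initial-frame background statistics, camera noise, amplitude
#' saturation) evaluated on reference scene geometry. Emits the fitted
#' config; warns when a fitted residual exceeds \code{calib_tolerance}.
#'
#' @param config an \code{\link{experiment_config}}.
#' @param census_targets,coverage_targets named lists (by arm) of target
#'   vectors; NULL for empty. Defaults are the printed values.
#' @return the config with concrete presets, fitted scene parameters and a
#'   \code{calibration} report attached.
#' @export
calibrate_cohort <- function(config = experiment_config(),
                             census_targets = list(
                               a488 = printed_census_targets("a488"),
                               a546 = printed_census_targets("a546")),
                             coverage_targets = list(
                               a488 = printed_coverage_targets("a488"),
                               a546 = printed_coverage_targets("a546"))) {
  if (is.null(config$presets)) config$presets <- default_presets()
  no_targets <- all(vapply(census_targets, length, 1L) == 0) &&
    all(vapply(coverage_targets, length, 1L) == 0)
  if (no_targets) {
    warning("no stage-2 targets supplied: returning config unchanged")
    config$calibrated <- TRUE
    return(config)
  }
  acq <- config$acquisition
  share <- config$scene_params[[1]]$signal_share
  amp_cap <- config$scene_params[[1]]$amp_cap
  s_tot <- acq$background_level * share / (1 - share)
  report <- list()
  if (any(vapply(coverage_targets, length, 1L) > 0)) {
    pool <- reference_cell_pool(config)
    draws <- coverage_field_draws(config, pool)
  }
  # background-statistics estimator response at the exact diffuse level of
  # each candidate (cached; the quantised-noise MAD cannot be interpolated
  # across levels)
  bg_cache <- new.env(parent = emptyenv())
  bg_fun <- function(diff) {
    key <- sprintf("%.3f", diff)
    if (is.null(bg_cache[[key]]))
      bg_cache[[key]] <- probe_background(acq, diff)
    bg_cache[[key]]
  }
  for (arm in names(config$presets)) {
    preset <- config$presets[[arm]]
    # neurons: diffuse level barely depends on the candidate (nuclei are a
    # tiny area fraction); use the budget minus a nominal cell share
    tgt <- census_targets[[arm]]
    if (length(tgt)) {
      tt <- as.numeric(names(tgt))
      cand_sp <- function(w, mu, sd) {
        sp <- config$scene_params[[arm]]
        sp$nucleus_dim_w <- w
        sp$nucleus_amp_meanlog <- mu
        sp$nucleus_amp_sdlog <- sd
        sp
      }
      best <- list(value = Inf)
      for (w in seq(0.1, 0.7, by = 0.05)) {
        obj <- function(mu, sd)
          sum((predict_census(cand_sp(w, mu, sd), preset, acq, bg_fun,
                              config$c, tt, share) - tgt)^2)
        # dispersion floor: a biological staining subpopulation has at
        # least ~30% coefficient of variation; tighter fits are degenerate
        fit <- grid_fit(obj, mu_range = log(c(2, 120)),
                        sd_range = c(0.3, 2.2), n = c(18L, 12L))
        if (fit$value < best$value) { best <- fit; best$w <- w }
      }
      config$scene_params[[arm]]$nucleus_dim_w <- best$w
      config$scene_params[[arm]]$nucleus_amp_meanlog <- best$mu
      config$scene_params[[arm]]$nucleus_amp_sdlog <- best$sd
      ach <- predict_census(config$scene_params[[arm]], preset, acq, bg_fun,
                            config$c, tt, share)
      report[[paste0(arm, "_census")]] <-
        data.frame(t_s = tt, target = as.numeric(tgt), predicted = ach)
      worst <- max(abs(ach - tgt))
      if (worst > config$calib_tolerance)
        warning(sprintf("%s census calibration misses worst target by %.1f pp",
                        arm, worst))
    }
    tgt <- coverage_targets[[arm]]
    if (length(tgt)) {
      tt <- as.numeric(names(tgt))
      cand_sp <- function(w, mu, sd) {
        sp <- config$scene_params[[arm]]
        sp$soma_dim_w <- w
        sp$soma_amp_meanlog <- mu
        sp$soma_amp_sdlog <- sd
        sp
      }
      # scan the dim-cell weight from below: the smallest weight that still
      # fits keeps the most brightly stained (profile-quality) cells
      best <- list(value = Inf)
      for (w in seq(0.45, 0.9, by = 0.05)) {
        obj <- function(mu, sd)
          sum((predict_coverage(cand_sp(w, mu, sd), pool, draws, preset, acq,
                                bg_fun, config$k, tt, share) - tgt)^2)
        # same dispersion floor as the census fit: narrower dim components
        # are degenerate point masses with fragile per-seed behaviour
        fit <- grid_fit(obj, mu_range = log(c(2, 60)), sd_range = c(0.3, 1.6),
                        n = c(14L, 10L))
        if (fit$value < best$value - 0.05) { best <- fit; best$w <- w }
        if (best$value < 0.25) break
      }
      config$scene_params[[arm]]$soma_dim_w <- best$w
      config$scene_params[[arm]]$soma_amp_meanlog <- best$mu
      config$scene_params[[arm]]$soma_amp_sdlog <- best$sd
      ach <- predict_coverage(config$scene_params[[arm]], pool, draws, preset,
                              acq, bg_fun, config$k, tt, share)
      report[[paste0(arm, "_coverage")]] <-
        data.frame(t_s = tt, target = as.numeric(tgt), predicted = ach)
      worst <- max(abs(ach - tgt))
      if (worst > config$calib_tolerance)
        warning(sprintf(
          "%s coverage calibration misses worst target by %.1f pp", arm,
          worst))
    }
    # pin the diffuse staining level per arm and cell type at the value the
    # predictors assumed, so realised cutoffs do not track per-field cell
    # content
    sp_fit <- config$scene_params[[arm]]
    config$scene_params[[arm]]$diffuse_neuron <-
      max(0, s_tot - neuron_label_mean(sp_fit, acq))
    if (exists("pool", inherits = FALSE)) {
      w_mean <- sum(vapply(pool$cells, function(cl) sum(cl$cnt * cl$w),
                           numeric(1))) / (pool$n_scenes * pool$n_px_frame)
      config$scene_params[[arm]]$diffuse_microglia <-
        max(0, s_tot - w_mean * e_soma_mix_capped(sp_fit, amp_cap))
    }
  }
  config$calibration <- report
  config$calibrated <- TRUE
  config
}
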