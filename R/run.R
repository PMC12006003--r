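#' Binarise and pair single-cell profiles at baseline and endpoint
#'
#' Emulates the semi-manual single-cell segmentation: each frame is
#' thresholded against its *own* background statistics (mode + robust SD of
#' the current frame, multiplier \code{k_profile}) — a human segmenting a
#' faded image adapts to its contrast — and each cell's profile is cut out
#' of that mask and cleaned by \code{\link{extract_profile}}. Cells are
#' selected per field as the \code{n_select} with the largest *endpoint*
#' profiles among those binarisable at both time points with at least
#' \code{min_area} pixels — the analyst's "clearly distinguishable, with
#' visible soma and branch structure" call is made on the pair of images
#' being segmented.
#'
#' @param series a \code{time_series} over a microglia scene.
#' @param t_end endpoint of detection (s), one of the schedule times.
#' @param k_profile threshold multiplier for the per-frame cutoff.
#' @param n_select profiles to keep per field.
#' @param min_area smallest profile (px) still counting as a binarisable
#'   cell with visible soma; smaller remnants are treated as faded.
#' @return list of per-cell lists with \code{p0}, \code{p1}
#'   (\code{cell_profile}s) and \code{cell_id}.
#' @export
paired_profiles <- function(series, t_end, k_profile = 2, n_select = 2L,
                            min_area = 400L) {
  stopifnot(t_end %in% series$times)
  k0 <- which(series$times == 0)
  k1 <- which(series$times == t_end)
  prof_at <- function(k) {
    f <- series$frames[[k]]
    bgf <- estimate_background(f)
    mask <- segment(f, threshold_from_background(bgf, k_profile))$pixels
    lapply(seq_along(series$scene$truth), function(j)
      extract_profile(mask, series$scene$truth[[j]]$profile,
                      cell_id = j, t_illum = series$times[k],
                      fluorophore = series$preset$name))
  }
  at0 <- prof_at(k0)
  at1 <- prof_at(k1)
  usable <- function(p) !is_faded(p) && p$area_px >= min_area
  ok <- which(vapply(at0, usable, logical(1)) &
                vapply(at1, usable, logical(1)))
  if (!length(ok)) return(list())
  area1 <- vapply(ok, function(j) at1[[j]]$area_px, numeric(1))
  sel <- ok[order(-area1)][seq_len(min(n_select, length(ok)))]
  lapply(sel, function(j) list(cell_id = j, p0 = at0[[j]], p1 = at1[[j]]))
}

measure_neuron_field <- function(config, arm, i) {
  preset <- config$presets[[arm]]
  scene <- make_neuron_scene(
    config$scene_params[[arm]]$n_neurons, config$acquisition,
    seed = derive_seed(config$master_seed, match(arm, names(config$presets)),
                       1L, i),
    params = config$scene_params[[arm]])
  series <- generate_time_series(
    scene, preset, config$acquisition, config$schedule,
    seed = derive_seed(config$master_seed, match(arm, names(config$presets)),
                       2L, i))
  lc <- loss_curve(series); lc$replicate <- i
  cen <- census(series, c = config$c, f_min = config$f_min)
  cc <- cen$curve; cc$replicate <- i
  list(loss = lc, census = cc)
}

measure_microglia_field <- function(config, arm, i) {
  preset <- config$presets[[arm]]
  arm_i <- match(arm, names(config$presets))
  n_cells <- with_seed_local(derive_seed(config$master_seed, arm_i, 3L, i),
                             sample(2:5, 1))
  scene <- make_microglia_scene(
    n_cells, config$acquisition,
    seed = derive_seed(config$master_seed, arm_i, 4L, i),
    params = config$scene_params[[arm]])
  series <- generate_time_series(
    scene, preset, config$acquisition, config$schedule,
    seed = derive_seed(config$master_seed, arm_i, 5L, i))
  lc <- loss_curve(series); lc$replicate <- i
  cov <- coverage_curve(series, k = config$k); cov$replicate <- i
  pp <- paired_profiles(series, endpoint_of_detection(preset),
                        k_profile = config$k_profile,
                        n_select = config$profiles_per_field)
  frac <- lapply(pp, function(pr) {
    par0 <- fractal_params(pr$p0, origins = config$box_origins)
    par1 <- fractal_params(pr$p1, origins = config$box_origins)
    list(cell_id = pr$cell_id, replicate = i, params0 = par0, params1 = par1,
         signed_change = 100 * (par1 - par0) / par0,
         change = profile_change(par0, par1))
  })
  list(loss = lc, coverage = cov, fractal = frac)
}

fractal_change_tables <- function(frac_list, arm) {
  if (!length(frac_list)) return(NULL)
  ch <- do.call(rbind, lapply(frac_list, function(x) x$signed_change))
  rownames(ch) <- NULL
  per_param <- colMeans(abs(ch))
  data.frame(fluorophore = arm, parameter = names(per_param),
             mean_change_pct = as.numeric(per_param),
             n_profiles = nrow(ch))
}

#' Run the full photobleaching-impact experiment
#'
#' For each fluorophore arm: simulates \code{n_fields} neuronal and
#' \code{n_fields} microglial fields at the illumination schedule, measures
#' whole-frame intensity loss, the detectable-neuron census, thresholded
#' area coverage, and paired single-cell morphometry at the endpoint of
#' detection, then runs the statistical battery (normality-gated omnibus
#' with Dunn's tests against the 0 s baseline; paired change tests against
#' zero). Deterministic given the config's master seed.
#'
#' @param config a calibrated \code{\link{experiment_config}} (calibrated
#'   on the fly when \code{config$calibrated} is FALSE).
#' @param progress print per-stage messages.
#' @return a \code{run_report} list: \code{loss}, \code{census},
#'   \code{coverage}, \code{fractal_changes}, \code{fractal_profiles},
#'   \code{decay_fits}, \code{stats}, \code{config}.
#' @export
run_experiment <- function(config = experiment_config(), progress = FALSE) {
  if (!isTRUE(config$calibrated)) config <- calibrate_cohort(config)
  arms <- names(config$presets)
  loss <- list(); cens <- list(); cov <- list(); frac <- list()
  for (arm in arms) {
    if (progress) message("arm ", arm, ": neuronal fields")
    for (i in seq_len(config$n_fields)) {
      m <- measure_neuron_field(config, arm, i)
      loss[[length(loss) + 1L]] <- m$loss
      cens[[length(cens) + 1L]] <- m$census
    }
    if (progress) message("arm ", arm, ": microglial fields")
    for (i in seq_len(config$n_fields)) {
      m <- measure_microglia_field(config, arm, i)
      loss[[length(loss) + 1L]] <- m$loss
      cov[[length(cov) + 1L]] <- m$coverage
      frac[[arm]] <- c(frac[[arm]], m$fractal)
    }
  }
  loss <- do.call(rbind, loss)
  cens <- do.call(rbind, cens)
  cov <- do.call(rbind, cov)
  fractal_changes <- do.call(rbind, lapply(arms, function(a)
    fractal_change_tables(frac[[a]], a)))
  pooled <- vapply(arms, function(a) {
    if (is.null(fractal_changes)) return(NA_real_)
    tb <- fractal_changes[fractal_changes$fluorophore == a, ]
    if (!nrow(tb)) return(NA_real_)
    mean(tb$mean_change_pct)
  }, numeric(1))

  # descriptive decay fits per arm on the mean loss curve
  decay_fits <- lapply(arms, function(a) {
    lc <- loss[loss$fluorophore == a, ]
    agg <- stats::aggregate(loss_pct ~ t_s, lc, mean)
    fit_decay(data.frame(t_s = agg$t_s, loss_pct = agg$loss_pct))
  })
  names(decay_fits) <- arms

  by_time_groups <- function(df, value_col, a) {
    d <- df[df$fluorophore == a, ]
    split(d[[value_col]], factor(d$t_s, levels = sort(unique(d$t_s))))
  }
  stats_out <- list()
  for (a in arms) {
    stats_out[[a]] <- list(
      intensity = omnibus_with_dunns(by_time_groups(loss, "mean_intensity", a)),
      census = omnibus_with_dunns(by_time_groups(cens, "n_detectable", a)),
      coverage = omnibus_with_dunns(by_time_groups(cov, "area_px", a)))
    if (length(frac[[a]]) >= 5) {
      ch <- do.call(rbind, lapply(frac[[a]], function(x) x$signed_change))
      stats_out[[a]]$fractal <- lapply(
        stats::setNames(colnames(ch), colnames(ch)),
        function(p) paired_change_test(ch[, p]))
    }
  }

  structure(list(loss = loss, census = cens, coverage = cov,
                 fractal_changes = fractal_changes,
                 pooled_change_pct = pooled,
                 fractal_profiles = frac,
                 decay_fits = decay_fits,
                 stats = stats_out,
                 config = config),
            class = "run_report")
}

#' Cohort-mean summaries of a run report
#'
#' Means over replicates of intensity loss, census reduction and coverage
#' change at each schedule time, per fluorophore.
#'
#' @param report a \code{run_report}.
#' @return list of data.frames \code{loss}, \code{census}, \code{coverage}.
#' @export
summarize_run <- function(report) {
  agg <- function(df, col) {
    out <- stats::aggregate(df[[col]],
                            list(fluorophore = df$fluorophore, t_s = df$t_s),
                            mean)
    names(out)[3] <- col
    out[order(out$fluorophore, out$t_s), ]
  }
  list(loss = agg(report$loss, "loss_pct"),
       census = agg(report$census, "reduction_pct"),
       coverage = agg(report$coverage, "change_pct"))
}

#' Write the tidy CSV outputs of a run
#'
#' @param report a \code{run_report}.
#' @param dir output directory.
#' @return invisibly, the written paths.
#' @export
write_run_csv <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(loss = file.path(dir, "intensity_loss.csv"),
             census = file.path(dir, "neuron_census.csv"),
             coverage = file.path(dir, "area_coverage.csv"),
             fractal = file.path(dir, "fractal_changes.csv"))
  utils::write.csv(report$loss, paths["loss"], row.names = FALSE)
  utils::write.csv(report$census, paths["census"], row.names = FALSE)
  utils::write.csv(report$coverage, paths["coverage"], row.names = FALSE)
  if (!is.null(report$fractal_changes))
    utils::write.csv(report$fractal_changes, paths["fractal"],
                     row.names = FALSE)
  invisible(paths)
}
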