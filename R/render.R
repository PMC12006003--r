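#' Expected (noise-free) frame at an illumination time
#'
#' The expected pixel value before noise:
#' \code{background_level + (diffuse + L(x)) * d(t)}, clipped to \[0, 255\].
#'
#' @param scene a \code{scene}.
#' @param preset a \code{\link{fluorophore_preset}}.
#' @param acquisition an \code{\link{acquisition_settings}}.
#' @param t_illum cumulative illumination time (s).
#' @return numeric matrix of expected intensities (not quantised).
#' @export
expected_frame <- function(scene, preset, acquisition, t_illum) {
  stopifnot(t_illum >= 0)
  d <- decay_fraction(preset, t_illum)
  e <- acquisition$background_level + (scene$diffuse_level + scene$label_map) * d
  pmin(pmax(e, 0), 255)
}

#' Render one noisy 8-bit frame
#'
#' Applies Poisson shot noise at \code{photon_scale} photons per intensity
#' unit plus Gaussian read noise to the expected frame, then rounds and
#' clips to 8 bits. With \code{noise = FALSE} the expected frame is just
#' quantised. Deterministic given \code{seed}.
#'
#' @inheritParams expected_frame
#' @param seed integer seed for the noise draw.
#' @param noise logical; disable to obtain the quantised expectation.
#' @return a \code{frame}: integer matrix in \[0, 255\] with attribute
#'   \code{t_illum}.
#' @export
render_frame <- function(scene, preset, acquisition, t_illum, seed = 1L,
                         noise = TRUE) {
  e <- expected_frame(scene, preset, acquisition, t_illum)
  if (noise) {
    ps <- acquisition$photon_scale
    v <- with_seed_local(seed, {
      shot <- stats::rpois(length(e), lambda = as.vector(e) * ps) / ps
      shot + stats::rnorm(length(e), 0, acquisition$read_noise_sd)
    })
    e <- matrix(v, nrow(e), ncol(e))
  }
  f <- matrix(as.integer(pmin(pmax(round(e), 0), 255)), nrow(e), ncol(e))
  attr(f, "t_illum") <- t_illum
  class(f) <- c("frame", class(f))
  f
}

#' Render a full illumination time series
#'
#' One frame per schedule time. Per-frame noise seeds are derived from the
#' master seed so the frames are independent draws but the whole series is
#' reproducible.
#'
#' @inheritParams render_frame
#' @param schedule an \code{\link{acquisition_schedule}}.
#' @return object of class \code{time_series}: list with \code{frames}
#'   (list of frames), \code{times}, \code{scene}, \code{preset}.
#' @export
generate_time_series <- function(scene, preset, acquisition,
                                 schedule = acquisition_schedule(),
                                 seed = 1L, noise = TRUE) {
  frames <- lapply(seq_along(schedule), function(k)
    render_frame(scene, preset, acquisition, schedule[k],
                 seed = derive_seed(seed, 101L, k), noise = noise))
  structure(list(frames = frames, times = as.numeric(schedule),
                 scene = scene, preset = preset, acquisition = acquisition),
            class = "time_series")
}

#' @export
print.time_series <- function(x, ...) {
  cat(sprintf("<time_series '%s'/%s: %d frames at t = %s s>\n",
              x$scene$kind, x$preset$name, length(x$frames),
              paste(x$times, collapse = ", ")))
  invisible(x)
}

#' Write a time series as single-channel 8-bit TIFFs
#'
#' One file per time point, named \code{{prefix}_{fluor}_t{seconds}.tif}.
#'
#' @param series a \code{time_series}.
#' @param dir output directory (created if missing).
#' @param prefix scene label used in filenames.
#' @return invisibly, the written paths.
#' @export
write_series_tiff <- function(series, dir, prefix = "scene") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(length(series$frames))
  for (k in seq_along(series$frames)) {
    p <- file.path(dir, sprintf("%s_%s_t%d.tif", prefix, series$preset$name,
                                as.integer(series$times[k])))
    tiff::writeTIFF(series$frames[[k]] / 255, p, bits.per.sample = 8L)
    paths[k] <- p
  }
  invisible(paths)
}

#' Read a single-channel 8-bit image (TIFF or PNG) as a frame
#'
#' @param path image file; multi-channel images are averaged to one channel.
#' @param t_illum illumination time to attach (s).
#' @return integer \code{frame} in \[0, 255\].
#' @export
read_frame <- function(path, t_illum = NA_real_) {
  img <- if (grepl("\\.png$", path, ignore.case = TRUE))
    png::readPNG(path) else tiff::readTIFF(path)
  if (length(dim(img)) == 3L) img <- apply(img, c(1, 2), mean)
  f <- matrix(as.integer(round(img * 255)), nrow(img), ncol(img))
  attr(f, "t_illum") <- t_illum
  class(f) <- c("frame", class(f))
  f
}
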