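#' Segmentation cutoff from background statistics
#'
#' \code{T = mu_b + k * sigma_b}, clipped to \[0, 255\]. The background
#' statistics always come from the initial (t = 0) frame; the same cutoff
#' is applied to every later frame.
#'
#' @param bg list from \code{\link{estimate_background}}.
#' @param k multiplier (> 0, default 3).
#' @return cutoff in intensity units.
#' @export
threshold_from_background <- function(bg, k = 3) {
  stopifnot(k > 0)
  if (bg$sigma_b == 0) warning("sigma_b = 0: cutoff equals the background mean")
  min(max(bg$mu_b + k * bg$sigma_b, 0), 255)
}

#' Threshold segmentation of a frame
#'
#' Pixel-wise comparison \code{frame >= T}; no morphological
#' post-processing at this stage.
#'
#' @param frame a frame matrix.
#' @param T cutoff in \[0, 255\].
#' @return list with \code{pixels} (logical matrix), \code{cutoff_T},
#'   \code{area_px}, \code{coverage_fraction}.
#' @export
segment <- function(frame, T) {
  stopifnot(T >= 0, T <= 255)
  m <- frame >= T
  list(pixels = m, cutoff_T = T, area_px = sum(m),
       coverage_fraction = sum(m) / length(m))
}

#' Area-coverage change over an illumination series
#'
#' Background statistics are estimated on the t = 0 frame, a single cutoff
#' \code{mu_b + k * sigma_b} is applied to every frame, and the relative
#' area change versus the initial frame is reported as a magnitude
#' (\code{change_pct}); the signed change is retained alongside.
#'
#' @param series a \code{time_series}, first frame at t = 0.
#' @param k cutoff multiplier (default 3).
#' @return data.frame with \code{t_s}, \code{area_px}, \code{change_pct},
#'   \code{signed_change_pct}, plus labels.
#' @export
coverage_curve <- function(series, k = 3) {
  stopifnot(inherits(series, "time_series"), series$times[1] == 0)
  bg <- estimate_background(series$frames[[1]])
  T <- threshold_from_background(bg, k)
  area <- vapply(series$frames, function(f) segment(f, T)$area_px, numeric(1))
  if (area[1] == 0) stop("no segmented area in the initial frame")
  signed <- 100 * (area - area[1]) / area[1]
  data.frame(fluorophore = series$preset$name,
             kind = series$scene$kind,
             t_s = series$times,
             area_px = area,
             change_pct = abs(signed),
             signed_change_pct = signed,
             cutoff_T = T)
}

#' Write a binary mask as an 8-bit PNG (0/255)
#'
#' @param mask logical matrix.
#' @param path output file.
#' @export
write_mask_png <- function(mask, path) {
  png::writePNG(mask * 1, path)
  invisible(path)
}
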