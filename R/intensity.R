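#' Whole-frame mean intensity
#'
#' Arithmetic mean over all pixels of the frame, with no masking — the
#' histogram-tool readout applied to the full micrograph.
#'
#' @param frame an integer frame matrix.
#' @return mean intensity in intensity units.
#' @export
mean_intensity <- function(frame) {
  stopifnot(is.matrix(frame), length(frame) > 0)
  mean(frame)
}

#' Relative intensity-loss curve of a time series
#'
#' Loss at time t is \code{100 * (mean(0) - mean(t)) / mean(0)} of the
#' whole-frame means; 0 by construction at t = 0.
#'
#' @param series a \code{time_series}, first frame at t = 0.
#' @return data.frame with columns \code{t_s}, \code{mean_intensity},
#'   \code{loss_pct}, plus \code{fluorophore} and \code{kind} labels.
#' @export
loss_curve <- function(series) {
  stopifnot(inherits(series, "time_series"), length(series$frames) >= 2,
            series$times[1] == 0)
  m <- vapply(series$frames, mean_intensity, numeric(1))
  if (m[1] == 0) stop("mean intensity at t = 0 is 0: no signal to normalise")
  data.frame(
    fluorophore = series$preset$name,
    kind = series$scene$kind,
    t_s = series$times,
    mean_intensity = m,
    loss_pct = 100 * (m[1] - m) / m[1]
  )
}

#' Descriptive decay fits to a loss curve
#'
#' Ordinary least squares of loss on time: a second-degree polynomial
#' (the descriptive fading fit) and a straight line, both with r-squared.
#' Neither is the generative bleaching model; no extrapolation beyond the
#' sampled schedule is intended.
#'
#' @param curve data.frame from \code{\link{loss_curve}} (columns
#'   \code{t_s}, \code{loss_pct}), at least 3 time points.
#' @return list with \code{poly2} (c, b, a for c + b t + a t^2, and
#'   \code{r_squared}) and \code{linear} (intercept, slope,
#'   \code{r_squared}).
#' @export
fit_decay <- function(curve) {
  t <- curve$t_s; y <- curve$loss_pct
  if (length(unique(t)) < 3) stop("need >= 3 distinct time points")
  fq <- stats::lm(y ~ t + I(t^2))
  fl <- stats::lm(y ~ t)
  r2 <- function(f) summary(f)$r.squared
  list(
    poly2 = list(coeffs = stats::setNames(stats::coef(fq), c("c", "b", "a")),
                 r_squared = r2(fq)),
    linear = list(intercept = unname(stats::coef(fl)[1]),
                  slope = unname(stats::coef(fl)[2]),
                  r_squared = r2(fl))
  )
}
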