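#' Camera and field acquisition settings
#'
#' Parameters of the simulated widefield acquisition. Pixel values are
#' formed as \code{background_level + (diffuse + signal) * d(t)}, Poisson
#' shot noise is applied at \code{photon_scale} photons per intensity
#' unit, Gaussian read noise is added, and the result is clipped and
#' quantised to 8 bits. \code{background_level} is the *non-bleaching*
#' floor (offset, autofluorescence of the mount); diffuse bleachable
#' staining is a scene property (see \code{\link{make_neuron_scene}}).
#'
#' @param field_shape integer (rows, cols), both at least 64.
#' @param photon_scale photons per intensity unit; larger means less shot
#'   noise.
#' @param read_noise_sd Gaussian read noise SD in intensity units.
#' @param background_level non-bleaching background in \[0, 255).
#' @return object of class \code{acquisition_settings}.
#' @export
acquisition_settings <- function(field_shape = c(512L, 512L),
                                 photon_scale = 4,
                                 read_noise_sd = 1.5,
                                 background_level = 8) {
  field_shape <- as.integer(field_shape)
  stopifnot(length(field_shape) == 2L, all(field_shape >= 64L),
            photon_scale > 0, read_noise_sd >= 0,
            background_level >= 0, background_level < 255)
  structure(list(field_shape = field_shape, bit_depth = 8L,
                 photon_scale = photon_scale,
                 read_noise_sd = read_noise_sd,
                 background_level = background_level),
            class = "acquisition_settings")
}

#' Illumination schedule
#'
#' Ordered cumulative illumination times at which single frames are
#' captured. The default matches the study design: an initial frame at
#' 0 s, then frames after 30, 60, 120, 300, 600 and 900 s of illumination.
#'
#' @param times strictly increasing numeric vector starting at 0 (s).
#' @return numeric vector of class \code{acquisition_schedule}.
#' @export
acquisition_schedule <- function(times = c(0, 30, 60, 120, 300, 600, 900)) {
  stopifnot(length(times) >= 1L, times[1] == 0,
            !is.unsorted(times, strictly = TRUE))
  structure(as.numeric(times), class = "acquisition_schedule")
}
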