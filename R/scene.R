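#' Ground-truth synthetic scenes
#'
#' A scene is the noise-free ground truth of one simulated field: cell
#' geometries, a per-pixel signal amplitude map (intensity units above
#' background, before bleaching), a spatially uniform diffuse bleachable
#' staining level, and per-cell truth pixel sets. Scenes are rendered into
#' 8-bit frames by \code{\link{render_frame}}.
#'
#' The diffuse level models non-specific/neuropil staining, which
#' dominates the whole-frame mean in real sections: it is set so that the
#' bleachable share of the expected initial frame mean equals
#' \code{signal_share} (default 0.65, i.e. a non-bleaching residual of
#' 0.35 as implied by the complete A546 bleach plateauing at 65 percent
#' whole-frame loss).
#'
#' @name scene
NULL

new_scene <- function(kind, shape, cells, label_map, diffuse_level, truth,
                      seed, params) {
  structure(list(kind = kind, shape = shape, cells = cells,
                 label_map = label_map, diffuse_level = diffuse_level,
                 truth = truth, seed = seed, params = params),
            class = "scene")
}

#' @export
print.scene <- function(x, ...) {
  cat(sprintf("<scene kind='%s' %dx%d, %d cells, diffuse=%.2f, seed=%d>\n",
              x$kind, x$shape[1], x$shape[2], length(x$cells),
              x$diffuse_level, x$seed))
  invisible(x)
}

diffuse_for_share <- function(label_map, background_level, signal_share) {
  stopifnot(signal_share > 0, signal_share < 1)
  total_bleachable <- background_level * signal_share / (1 - signal_share)
  max(0, total_bleachable - mean(label_map))
}

#' Default scene-heterogeneity parameters
#'
#' Intensity-distribution and geometry defaults for the synthetic fields.
#' Amplitudes are in intensity units above background at t = 0.
#' The lognormal location/scale parameters for nucleus amplitude (neurons)
#' and soma amplitude (microglia) are the knobs refitted per fluorophore by
#' \code{\link{calibrate_cohort}}; everything else is a fixed structural
#' default.
#'
#' @return named list of parameters.
#' @export
scene_params <- function() {
  list(
    # neurons
    n_neurons = 12L,
    soma_axis_range = c(9, 14),        # semi-major axis, px
    soma_aspect_range = c(0.7, 0.95),  # minor/major
    nucleus_radius_frac = 0.5,         # of soma minor semi-axis
    # nucleus amplitude: mixture of a bright well-stained majority and a
    # weakly stained subpopulation; the dim component and its weight are
    # the knobs calibrated per arm
    nucleus_dim_w = 0.35,              # calibrated per arm
    nucleus_amp_meanlog = log(30),     # dim component, calibrated per arm
    nucleus_amp_sdlog = 0.8,           # dim component, calibrated per arm
    nucleus_bright_meanlog = log(140),
    nucleus_bright_sdlog = 0.25,
    soma_amp_ratio = 0.5,              # soma amplitude / nucleus amplitude
    # microglia
    soma_radius_range = c(4.5, 6.5),
    n_primary_range = c(3L, 6L),
    seg_len_range = c(7, 14),
    branch_prob = 0.35,
    max_depth = 4L,
    angle_jitter_sd = 0.35,            # rad
    split_angle_range = c(0.35, 0.7),  # rad
    root_width = 3, tip_width = 1,
    # soma amplitude: mixture of a brightly stained subset (high Iba1
    # expression) and a weakly stained majority; the dim component and its
    # weight are the knobs calibrated per arm
    soma_dim_w = 0.7,                  # calibrated per arm
    soma_amp_meanlog = log(25),        # dim component, calibrated per arm
    soma_amp_sdlog = 1.0,              # dim component, calibrated per arm
    soma_bright_meanlog = log(150),
    soma_bright_sdlog = 0.3,
    branch_base = 0.75,                # primary-branch amp / soma amp
    depth_taper = 0.8,                 # per-generation amplitude factor
    branch_jitter_sdlog = 0.25,
    signal_share = 0.65,
    # fixed diffuse staining levels (intensity units); NULL lets each scene
    # normalise its own bleachable share to signal_share. The calibrated
    # pipeline pins these per arm so the segmentation cutoffs do not
    # anticorrelate with the cells a field happens to contain.
    diffuse_neuron = NULL,
    diffuse_microglia = NULL,
    amp_cap = 230,   # staining saturation: keeps bright structures in range
    max_place_retries = 3000L
  )
}

#' Generate a neuronal field
#'
#' Places \code{n_cells} non-overlapping NeuN-like neurons — an elliptical
#' soma containing a brighter circular nucleus — in the field and builds the
#' amplitude map and truth masks. Deterministic given \code{seed}.
#'
#' @param n_cells number of neurons (>= 1 unless \code{allow_empty}).
#' @param acquisition an \code{\link{acquisition_settings}}.
#' @param seed integer seed.
#' @param params parameter list, see \code{\link{scene_params}}.
#' @param allow_empty if TRUE, \code{n_cells = 0} yields an empty scene
#'   instead of an error.
#' @return a \code{scene}.
#' @export
make_neuron_scene <- function(n_cells, acquisition = acquisition_settings(),
                              seed = 1L, params = scene_params(),
                              allow_empty = FALSE) {
  if (n_cells == 0 && !allow_empty)
    stop("n_cells must be >= 1 (set allow_empty = TRUE for an empty scene)")
  stopifnot(n_cells >= 0)
  shape <- acquisition$field_shape
  with_seed_local(seed, {
    label <- matrix(0, shape[1], shape[2])
    occupied <- matrix(FALSE, shape[1], shape[2])
    cells <- vector("list", n_cells)
    truth <- vector("list", n_cells)
    for (i in seq_len(n_cells)) {
      placed <- FALSE
      for (try in seq_len(params$max_place_retries)) {
        a <- stats::runif(1, params$soma_axis_range[1], params$soma_axis_range[2])
        b <- a * stats::runif(1, params$soma_aspect_range[1],
                              params$soma_aspect_range[2])
        theta <- stats::runif(1, 0, pi)
        m <- ceiling(a) + 2
        ctr <- c(stats::runif(1, 1 + m, shape[1] - m),
                 stats::runif(1, 1 + m, shape[2] - m))
        soma <- ellipse_pixels(shape, ctr, c(a, b), theta)
        soma_px <- soma$idx
        if (length(soma_px) < 9 || any(occupied[soma_px])) next
        rn <- params$nucleus_radius_frac * b
        # the nucleus is rendered flat: NeuN labelling is nuclear and dense
        nuc_px <- disk_pixels(shape, ctr, rn, chord = FALSE)$idx
        nuc_amp <- if (stats::runif(1) < params$nucleus_dim_w)
          stats::rlnorm(1, params$nucleus_amp_meanlog,
                        params$nucleus_amp_sdlog)
        else
          stats::rlnorm(1, params$nucleus_bright_meanlog,
                        params$nucleus_bright_sdlog)
        soma_amp <- params$soma_amp_ratio * nuc_amp
        label[soma_px] <- soma_amp * soma$w
        label[nuc_px] <- nuc_amp
        occupied[soma_px] <- TRUE
        cells[[i]] <- list(kind = "neuron", soma_center = ctr,
                           soma_axes = c(a, b), soma_theta = theta,
                           soma_intensity = soma_amp,
                           nucleus_center = ctr, nucleus_radius = rn,
                           nucleus_intensity = nuc_amp)
        truth[[i]] <- list(profile = soma_px, soma = setdiff(soma_px, nuc_px),
                           nucleus = nuc_px)
        placed <- TRUE
        break
      }
      if (!placed)
        stop("neuron placement failed after ", params$max_place_retries,
             " retries: field too dense for ", n_cells, " cells")
    }
    label <- pmin(label, params$amp_cap)
    diffuse <- if (is.null(params$diffuse_neuron))
      diffuse_for_share(label, acquisition$background_level,
                        params$signal_share)
    else params$diffuse_neuron
    new_scene("neuron", shape, cells, label, diffuse,
              truth, as.integer(seed), params)
  })
}

# Grow one microglial branch tree in field coordinates. Returns a list of
# segments (p0, p1, width, depth, amp) via recursive extension.
grow_tree <- function(ctr, soma_r, soma_amp, params) {
  n_primary <- sample(seq(params$n_primary_range[1],
                          params$n_primary_range[2]), 1)
  base_angles <- stats::runif(1, 0, 2 * pi) +
    seq(0, 2 * pi, length.out = n_primary + 1)[-(n_primary + 1)] +
    stats::rnorm(n_primary, 0, 0.2)
  segs <- list()
  width_at <- function(depth) {
    if (params$max_depth <= 1L) return(params$root_width)
    max(params$tip_width,
        params$root_width - (depth - 1) *
          (params$root_width - params$tip_width) / (params$max_depth - 1))
  }
  extend <- function(p, angle, depth, amp) {
    if (depth > params$max_depth) return(invisible(NULL))
    len <- stats::runif(1, params$seg_len_range[1], params$seg_len_range[2])
    q <- p + len * c(sin(angle), cos(angle))
    segs[[length(segs) + 1L]] <<- list(
      p0 = p, p1 = q, width = width_at(depth), depth = depth,
      amp = amp * exp(stats::rnorm(1, 0, params$branch_jitter_sdlog)))
    if (depth < params$max_depth && stats::runif(1) < params$branch_prob) {
      split <- stats::runif(1, params$split_angle_range[1],
                            params$split_angle_range[2])
      extend(q, angle + split + stats::rnorm(1, 0, params$angle_jitter_sd / 2),
             depth + 1L, amp * params$depth_taper)
      extend(q, angle - split + stats::rnorm(1, 0, params$angle_jitter_sd / 2),
             depth + 1L, amp * params$depth_taper)
    } else if (depth < params$max_depth) {
      extend(q, angle + stats::rnorm(1, 0, params$angle_jitter_sd),
             depth + 1L, amp * params$depth_taper)
    }
    invisible(NULL)
  }
  for (ang in base_angles) {
    start <- ctr + (soma_r - 0.5) * c(sin(ang), cos(ang))
    extend(start, ang, 1L, soma_amp * params$branch_base)
  }
  segs
}

#' Generate a microglial field
#'
#' Places 2-5 Iba1-like microglia — a soma disk plus a recursively
#' branched process tree with tapering width and amplitude — fully inside
#' the frame, with disjoint profiles. Deterministic given \code{seed}.
#'
#' @param n_cells number of microglia, 2 to 5.
#' @inheritParams make_neuron_scene
#' @return a \code{scene}.
#' @export
make_microglia_scene <- function(n_cells, acquisition = acquisition_settings(),
                                 seed = 1L, params = scene_params()) {
  if (n_cells < 2 || n_cells > 5)
    stop("n_cells must be 2..5: each field must contain 2-5 microglia ",
         "fully in frame")
  shape <- acquisition$field_shape
  with_seed_local(seed, {
    label <- matrix(0, shape[1], shape[2])
    occupied <- matrix(FALSE, shape[1], shape[2])
    cells <- vector("list", n_cells)
    truth <- vector("list", n_cells)
    # worst-case radial extent of a tree: soma + max_depth segments; on
    # small fields fall back to a looser margin and let the per-segment
    # in-frame check reject out-of-frame trees
    reach <- ceiling(params$soma_radius_range[2] + 2 +
                       params$max_depth * params$seg_len_range[2])
    reach <- min(reach, max(8L, floor(min(shape) / 4)))
    for (i in seq_len(n_cells)) {
      placed <- FALSE
      for (try in seq_len(params$max_place_retries)) {
        soma_r <- stats::runif(1, params$soma_radius_range[1],
                               params$soma_radius_range[2])
        ctr <- c(stats::runif(1, 1 + reach, shape[1] - reach),
                 stats::runif(1, 1 + reach, shape[2] - reach))
        soma_amp <- if (stats::runif(1) < params$soma_dim_w)
          stats::rlnorm(1, params$soma_amp_meanlog, params$soma_amp_sdlog)
        else
          stats::rlnorm(1, params$soma_bright_meanlog,
                        params$soma_bright_sdlog)
        segs <- grow_tree(ctr, soma_r, soma_amp, params)
        soma <- disk_pixels(shape, ctr, soma_r)
        soma_px <- soma$idx
        px_all <- soma_px
        amp_all <- soma_amp * soma$w
        ok <- TRUE
        for (s in segs) {
          if (any(c(s$p0, s$p1) < 1 + 1) ||
              any(c(s$p0[1], s$p1[1]) > shape[1] - 1) ||
              any(c(s$p0[2], s$p1[2]) > shape[2] - 1)) { ok <- FALSE; break }
          px <- segment_pixels(shape, s$p0, s$p1, s$width)
          px_all <- c(px_all, px$idx)
          amp_all <- c(amp_all, s$amp * px$w)
        }
        if (!ok) next
        # keep the brightest contribution where segments overlap:
        # sort ascending so brighter values overwrite dimmer ones
        o <- order(amp_all)
        px_o <- px_all[o]; amp_o <- amp_all[o]
        cell_px <- unique(px_o)
        if (any(occupied[cell_px])) next
        label[px_o] <- amp_o
        occupied[cell_px] <- TRUE
        cells[[i]] <- list(kind = "microglia", soma_center = ctr,
                           soma_radius = soma_r, soma_intensity = soma_amp,
                           branches = segs)
        truth[[i]] <- list(profile = sort(cell_px), soma = sort(soma_px),
                           nucleus = NULL)
        placed <- TRUE
        break
      }
      if (!placed)
        stop("microglia placement failed after ", params$max_place_retries,
             " retries: field too dense for ", n_cells, " cells")
    }
    label <- pmin(label, params$amp_cap)
    diffuse <- if (is.null(params$diffuse_microglia))
      diffuse_for_share(label, acquisition$background_level,
                        params$signal_share)
    else params$diffuse_microglia
    new_scene("microglia", shape, cells, label, diffuse,
              truth, as.integer(seed), params)
  })
}

#' Serialise scene geometry to JSON
#'
#' Writes cell geometries, the diffuse level, seed and parameters (not the
#' pixel-level maps, which are reproducible from the seed).
#'
#' @param scene a \code{scene}.
#' @param path output file.
#' @export
write_scene_json <- function(scene, path) {
  x <- scene[c("kind", "shape", "diffuse_level", "seed", "params")]
  x$cells <- lapply(scene$cells, function(cl) cl[setdiff(names(cl), "branches")])
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = 8)
  invisible(path)
}
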