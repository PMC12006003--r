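#' Single-cell binary profile extraction
#'
#' Restricts a segmentation mask to one cell's truth support (dilated by a
#' small margin), then applies a deterministic cleanup that stands in for
#' the manual continuity correction of hand-segmented profiles:
#' morphological closing with a 3x3 element followed by keeping the
#' largest 8-connected component.
#'
#' @param mask logical matrix (a segmentation of the full frame).
#' @param truth_cell_pixels integer linear indices of the cell's truth
#'   profile.
#' @param margin dilation margin (px) around the truth support.
#' @param cell_id,t_illum,fluorophore provenance labels.
#' @return a \code{cell_profile}: list with the cropped \code{mask}, its
#'   \code{offset} (row, col of crop origin minus 1), \code{area_px} and
#'   provenance; or a faded marker (see \code{\link{is_faded}}) when the
#'   mask does not intersect the cell.
#' @export
extract_profile <- function(mask, truth_cell_pixels, margin = 2L,
                            cell_id = NA_integer_, t_illum = NA_real_,
                            fluorophore = NA_character_) {
  stopifnot(is.matrix(mask), length(truth_cell_pixels) > 0)
  nr <- nrow(mask)
  tr_r <- ((truth_cell_pixels - 1L) %% nr) + 1L
  tr_c <- ((truth_cell_pixels - 1L) %/% nr) + 1L
  r0 <- max(1L, min(tr_r) - margin); r1 <- min(nr, max(tr_r) + margin)
  c0 <- max(1L, min(tr_c) - margin); c1 <- min(ncol(mask), max(tr_c) + margin)
  crop <- mask[r0:r1, c0:c1, drop = FALSE]
  # dilated truth support within the crop
  supp <- matrix(FALSE, nrow(crop), ncol(crop))
  supp[cbind(tr_r - r0 + 1L, tr_c - c0 + 1L)] <- TRUE
  for (i in seq_len(margin)) supp <- dilate_square(supp)
  cand <- crop & supp
  faded <- structure(list(faded = TRUE, cell_id = cell_id,
                          t_illum = t_illum, fluorophore = fluorophore),
                     class = "cell_profile")
  if (!any(cand)) return(faded)
  cleaned <- close3(cand)
  lab <- label8(cleaned)
  if (max(lab) == 0) return(faded)
  sizes <- tabulate(lab[lab > 0])
  keep <- which.max(sizes)
  prof <- lab == keep
  structure(list(faded = FALSE, mask = prof,
                 offset = c(r0 - 1L, c0 - 1L), area_px = sum(prof),
                 cell_id = cell_id, t_illum = t_illum,
                 fluorophore = fluorophore),
            class = "cell_profile")
}

#' @rdname extract_profile
#' @param profile a \code{cell_profile}.
#' @export
is_faded <- function(profile) isTRUE(profile$faded)

# One-step dilation with a 3x3 square element.
dilate_square <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  p <- matrix(FALSE, nr + 2L, nc + 2L)
  p[2:(nr + 1L), 2:(nc + 1L)] <- mask
  out <- matrix(FALSE, nr, nc)
  for (dr in -1:1) for (dc in -1:1)
    out <- out | p[(2 + dr):(nr + 1 + dr), (2 + dc):(nc + 1 + dc), drop = FALSE]
  out
}

#' Default box-size series for box counting
#'
#' Geometric series of integer box sizes from 2 px to 25 percent of the
#' larger bounding-box side, 8 sizes when the profile permits. The upper
#' cap keeps at least four boxes per dimension at the coarsest scale:
#' larger boxes make the partial-box excess at the bounding-box edge
#' dominate the count and bias the dimension fit.
#'
#' @param mask logical profile mask.
#' @return integer vector of box sizes.
#' @export
default_box_sizes <- function(mask) {
  s_max <- floor(0.25 * max(dim(mask)))
  if (s_max < 2) stop("profile smaller than the smallest box size (2 px)")
  sizes <- unique(round(exp(seq(log(2), log(s_max), length.out = 8))))
  sizes[sizes >= 2]
}

#' Box-counting scan of a binary profile
#'
#' Tiles the profile's bounding box with boxes of each size at \code{G}
#' uniformly spaced grid origins, counting occupied boxes (>= 1 foreground
#' pixel) and recording the mean and population SD of the box masses over
#' occupied boxes.
#'
#' @param profile a \code{cell_profile} or a logical matrix.
#' @param sizes integer box sizes (>= 2 values).
#' @param origins number of grid origins G (>= 1).
#' @return data.frame with columns \code{grid}, \code{eps}, \code{n_boxes},
#'   \code{mass_mean}, \code{mass_sd}.
#' @export
box_count <- function(profile, sizes = NULL, origins = 4L) {
  mask <- if (inherits(profile, "cell_profile")) profile$mask else profile
  stopifnot(is.matrix(mask), any(mask), origins >= 1L)
  # restrict to the tight bounding box
  ij <- which(mask, arr.ind = TRUE)
  r <- ij[, 1] - min(ij[, 1]); c <- ij[, 2] - min(ij[, 2])
  side <- max(max(r), max(c)) + 1L
  if (is.null(sizes)) sizes <- default_box_sizes(mask)
  sizes <- as.integer(sizes)
  if (length(sizes) < 2) stop("need at least 2 box sizes")
  if (min(sizes) > side) stop("profile smaller than the smallest box size")
  out <- vector("list", length(sizes) * origins)
  k <- 0L
  for (eps in sizes) {
    for (g in seq_len(origins)) {
      off <- floor(eps * (g - 1) / origins)
      bid <- ((r + off) %/% eps) * (((max(c) + off) %/% eps) + 2L) +
        ((c + off) %/% eps)
      mass <- tabulate(match(bid, unique(bid)))
      k <- k + 1L
      mu <- mean(mass)
      out[[k]] <- data.frame(grid = g, eps = eps, n_boxes = length(mass),
                             mass_mean = mu,
                             mass_sd = sqrt(mean((mass - mu)^2)))
    }
  }
  do.call(rbind, out)
}

#' Box-counting fractal dimension
#'
#' OLS slope of log occupied-box count against log inverse box size. With
#' \code{cover = "min"} (default) the count at each size is the minimum
#' over grid origins — the most efficient cover, which suppresses the
#' upward partial-box bias at the bounding-box edge; \code{cover = "mean"}
#' instead averages per-grid OLS slopes.
#'
#' @param table data.frame from \code{\link{box_count}}.
#' @param cover \code{"min"} or \code{"mean"} grid aggregation.
#' @return unitless fractal dimension.
#' @export
fractal_dimension <- function(table, cover = c("min", "mean")) {
  cover <- match.arg(cover)
  if (length(unique(table$eps)) < 3)
    stop("need >= 3 box sizes for a dimension fit")
  if (cover == "min") {
    nmin <- tapply(table$n_boxes, table$eps, min)
    eps <- as.numeric(names(nmin))
    unname(stats::coef(stats::lm(log(nmin) ~ log(1 / eps)))[2])
  } else {
    slopes <- vapply(split(table, table$grid), function(tb) {
      unname(stats::coef(stats::lm(log(tb$n_boxes) ~ log(1 / tb$eps)))[2])
    }, numeric(1))
    mean(slopes)
  }
}

#' Box-mass lacunarity
#'
#' \code{lambda(g, eps) = (sd / mean)^2} of the box masses over occupied
#' boxes; the reported lacunarity is the mean of lambda over sizes and
#' grid origins. Sizes with zero mean mass are excluded with a warning.
#'
#' @inheritParams fractal_dimension
#' @return unitless lacunarity (>= 0).
#' @export
lacunarity <- function(table) {
  if (length(unique(table$eps)) < 3)
    stop("need >= 3 box sizes for lacunarity")
  ok <- table$mass_mean > 0
  if (!all(ok)) warning("excluding box sizes with zero mean mass")
  lam <- (table$mass_sd[ok] / table$mass_mean[ok])^2
  mean(lam)
}

# Outer-boundary walk length of a single 8-connected component:
# Moore-neighbour tracing, steps of 1 (edge moves) and sqrt(2) (diagonal).
boundary_perimeter <- function(mask) {
  n_fg <- sum(mask)
  if (n_fg == 1L) return(4)   # degenerate: unit pixel square
  nr <- nrow(mask); nc <- ncol(mask)
  p <- matrix(FALSE, nr + 2L, nc + 2L)
  p[2:(nr + 1L), 2:(nc + 1L)] <- mask
  # clockwise Moore neighbourhood starting at W
  dirs <- rbind(c(0, -1), c(-1, -1), c(-1, 0), c(-1, 1),
                c(0, 1), c(1, 1), c(1, 0), c(1, -1))
  start <- which(p, arr.ind = TRUE)
  start <- start[order(start[, 2], start[, 1]), , drop = FALSE][1, ]
  cur <- start; dir_in <- 1L   # entered "from the west" (backtrack at W)
  per <- 0
  first_move <- NULL
  steps <- 0L; max_steps <- 8L * (n_fg + 4L)
  repeat {
    found <- FALSE
    for (k in 0:7) {
      d <- ((dir_in - 1L + k) %% 8L) + 1L
      nxt <- cur + dirs[d, ]
      if (p[nxt[1], nxt[2]]) {
        per <- per + if (sum(abs(dirs[d, ])) == 2) sqrt(2) else 1
        move <- d
        # new search starts from the backtrack: neighbour before the move
        dir_in <- ((d - 1L - 2L) %% 8L) + 1L
        if (is.null(first_move)) first_move <- move
        cur <- nxt
        found <- TRUE
        break
      }
    }
    if (!found) return(4)  # isolated pixel reached; treat as unit square
    steps <- steps + 1L
    if (steps > max_steps) break
    if (all(cur == start)) {
      # Jacob's criterion: stop on returning to start with the same move
      # about to repeat; one extra probe suffices for closed curves
      probe <- ((dir_in - 1L) %% 8L) + 1L
      nxt <- cur + dirs[probe, ]
      # terminate when the trace has closed
      if (steps >= 2L) break
    }
  }
  per
}

# Convex hull of the profile treated as a union of unit pixel squares:
# hull of all pixel corners. Returns vertices (x = col, y = row), area,
# perimeter, max and min Feret diameters.
pixel_hull <- function(mask) {
  ij <- which(mask, arr.ind = TRUE)
  pts <- rbind(cbind(ij[, 1] - 0.5, ij[, 2] - 0.5),
               cbind(ij[, 1] - 0.5, ij[, 2] + 0.5),
               cbind(ij[, 1] + 0.5, ij[, 2] - 0.5),
               cbind(ij[, 1] + 0.5, ij[, 2] + 0.5))
  h <- grDevices::chull(pts)
  v <- pts[h, , drop = FALSE]           # counter-clockwise or clockwise
  n <- nrow(v)
  x <- v[, 2]; y <- v[, 1]
  area <- abs(sum(x * y[c(2:n, 1)] - x[c(2:n, 1)] * y)) / 2
  per <- sum(sqrt(diff(c(x, x[1]))^2 + diff(c(y, y[1]))^2))
  d2 <- as.matrix(stats::dist(v))
  feret_max <- max(d2)
  # min width over edge directions (valid for convex polygons)
  widths <- vapply(seq_len(n), function(i) {
    j <- if (i == n) 1L else i + 1L
    e <- c(x[j] - x[i], y[j] - y[i])
    L <- sqrt(sum(e^2))
    if (L < 1e-12) return(Inf)
    nrm <- c(-e[2], e[1]) / L
    pr <- x * nrm[1] + y * nrm[2]
    max(pr) - min(pr)
  }, numeric(1))
  list(vertices = v, area = area, perimeter = per,
       feret_max = feret_max, feret_min = max(min(widths), 1))
}

#' Convex-hull shape descriptors of a profile
#'
#' Computes the hull-based descriptors of one binary cell profile, with
#' pixels treated as unit squares:
#' \itemize{
#'   \item \code{area_px}: foreground pixel count;
#'   \item \code{perimeter_px}: outer-boundary walk length (steps of 1 and
#'     sqrt 2 along the 8-connected boundary);
#'   \item \code{span_ratio}: hull longest axis (max Feret diameter) over
#'     the hull's smallest width (min Feret; the "diagonal over short
#'     side" convention, so a 60 x 10 rectangle gives 60.8 / 10 = 6.08);
#'   \item \code{density}: \code{area_px} / hull area;
#'   \item \code{circularity}: \code{4 * pi * hull area / hull perimeter^2}.
#' }
#'
#' @param profile a \code{cell_profile} or logical matrix with >= 3
#'   non-collinear pixels (a 1-px line degenerates to a width floor of 1).
#' @return named list with the five descriptors.
#' @export
hull_metrics <- function(profile) {
  mask <- if (inherits(profile, "cell_profile")) profile$mask else profile
  stopifnot(is.matrix(mask), sum(mask) >= 1)
  h <- pixel_hull(mask)
  list(area_px = sum(mask),
       perimeter_px = boundary_perimeter(mask),
       span_ratio = h$feret_max / h$feret_min,
       density = sum(mask) / h$area,
       circularity = 4 * pi * h$area / h$perimeter^2)
}

#' All seven morphometric parameters of a profile
#'
#' Cell area, perimeter, box-counting fractal dimension, lacunarity, span
#' ratio, hull density and hull circularity.
#'
#' @inheritParams hull_metrics
#' @param sizes,origins passed to \code{\link{box_count}}.
#' @return named numeric vector of the seven parameters.
#' @export
fractal_params <- function(profile, sizes = NULL, origins = 4L) {
  tab <- box_count(profile, sizes = sizes, origins = origins)
  hm <- hull_metrics(profile)
  c(area_px = hm$area_px,
    perimeter_px = hm$perimeter_px,
    fractal_dimension = fractal_dimension(tab),
    lacunarity = lacunarity(tab),
    span_ratio = hm$span_ratio,
    density = hm$density,
    circularity = hm$circularity)
}

#' Per-parameter relative change between paired profiles
#'
#' For a cell profiled at t = 0 (\code{p0}) and at the endpoint of
#' detection (\code{p1}): per-parameter change magnitude
#' \code{100 * |p1 - p0| / p0}, and the pooled change, the mean over the
#' seven parameters. Parameters that are 0 at baseline are excluded with a
#' warning.
#'
#' @param p0,p1 named numeric vectors from \code{\link{fractal_params}}.
#' @return list with \code{change_pct} (named vector) and
#'   \code{pooled_change_pct}.
#' @export
profile_change <- function(p0, p1) {
  stopifnot(identical(names(p0), names(p1)))
  ok <- p0 != 0
  if (!all(ok)) warning("excluding parameters with zero baseline value")
  ch <- 100 * abs(p1[ok] - p0[ok]) / p0[ok]
  list(change_pct = ch, pooled_change_pct = mean(ch))
}
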