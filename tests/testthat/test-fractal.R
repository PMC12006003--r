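test_that("profile extraction restores continuity and keeps the main component", {
  mask <- matrix(FALSE, 64, 64)
  soma <- which(outer(seq_len(64) - 32, seq_len(64) - 32,
                      function(a, b) a^2 + b^2 <= 25))
  branch <- which(outer(seq_len(64) - 32, seq_len(64) - 32,
                        function(a, b) a == 0 & b > 5 & b <= 25))
  truth <- c(soma, branch)
  mask[truth] <- TRUE

  # identity: mask equals the truth profile
  p <- extract_profile(mask, truth)
  expect_false(is_faded(p))
  expect_equal(p$area_px, length(truth))

  # a 1-px gap in the branch is healed by closing into one component
  gap <- which(outer(seq_len(64) - 32, seq_len(64) - 32,
                     function(a, b) a == 0 & b == 15))
  mask_gap <- mask
  mask_gap[gap] <- FALSE
  before <- photofade:::label8(mask_gap)
  expect_equal(max(before), 2)
  p2 <- extract_profile(mask_gap, truth)
  expect_equal(max(photofade:::label8(p2$mask)), 1)
  expect_gte(p2$area_px, length(truth) - 2)

  # fully faded cell yields the faded signal, not an error
  p3 <- extract_profile(matrix(FALSE, 64, 64), truth)
  expect_true(is_faded(p3))
})

test_that("box counts are exact on analytic shapes", {
  sq <- matrix(TRUE, 64, 64)
  tab <- box_count(sq, sizes = c(8, 16, 32), origins = 1L)
  expect_equal(tab$n_boxes[tab$eps == 8], 64)
  expect_equal(tab$n_boxes[tab$eps == 16], 16)

  line <- matrix(FALSE, 64, 64); line[10, ] <- TRUE
  tabl <- box_count(line, sizes = c(8, 16, 32), origins = 1L)
  expect_equal(tabl$n_boxes[tabl$eps == 8], 8)

  # self-similar oracle: an order-8 Sierpinski triangle has 3^k boxes of
  # size side / 2^k
  sp <- sierpinski_mask(8)
  sizes <- 2^(1:6)
  tabs <- box_count(sp, sizes = sizes, origins = 1L)
  for (k in 1:6) {
    expected <- 3^(8 - k)
    got <- tabs$n_boxes[tabs$eps == 2^k]
    expect_lt(abs(got - expected) / expected, 0.05)
  }
  # covering bound: N * eps^2 >= area for every grid and size
  full <- box_count(sp, origins = 4L)
  expect_true(all(full$n_boxes * full$eps^2 >= sum(sp)))
})

test_that("fractal dimensions of reference shapes match analytic values", {
  sq <- matrix(TRUE, 256, 256)
  expect_lt(abs(fractal_dimension(box_count(sq)) - 2), 0.05)
  line <- matrix(FALSE, 256, 256); line[128, ] <- TRUE
  expect_lt(abs(fractal_dimension(box_count(line)) - 1), 0.05)
  sp <- sierpinski_mask(8)
  D <- fractal_dimension(box_count(sp))
  expect_lt(abs(D - log(3) / log(2)), 0.05)
  expect_error(fractal_dimension(box_count(sq, sizes = c(8, 16))), ">= 3")
})

test_that("lacunarity separates homogeneous from gappy masks", {
  sq <- matrix(TRUE, 64, 64)
  tab_sq <- box_count(sq, sizes = c(4, 8, 16), origins = 1L)
  expect_lt(lacunarity(tab_sq), 1e-12)   # exact tiling: equal box masses

  set.seed(5)
  rnd <- matrix(runif(64 * 64) < 0.5, 64, 64)
  tab_rnd <- box_count(rnd, sizes = c(4, 8, 16), origins = 1L)
  expect_gt(lacunarity(tab_rnd), lacunarity(tab_sq))

  # direct moment oracle on one size
  one <- tab_rnd[tab_rnd$eps == 8 & tab_rnd$grid == 1, ]
  masses <- integer(0)
  for (bi in 0:7) for (bj in 0:7) {
    m <- sum(rnd[(bi * 8 + 1):(bi * 8 + 8), (bj * 8 + 1):(bj * 8 + 8)])
    if (m > 0) masses <- c(masses, m)
  }
  expect_equal(one$n_boxes, length(masses))
  expect_equal(one$mass_mean, mean(masses))
  expect_equal(one$mass_sd, sqrt(mean((masses - mean(masses))^2)))
})

test_that("hull metrics reproduce disk and rectangle geometry", {
  dk <- disk_mask(20)
  hm <- hull_metrics(dk)
  expect_lt(abs(hm$circularity - 1), 0.05)
  expect_lt(abs(hm$span_ratio - 1), 0.05)
  expect_gt(hm$density, 0.95)
  expect_lt(abs(hm$perimeter_px - 2 * pi * 20) / (2 * pi * 20), 0.08)

  rect <- matrix(FALSE, 80, 80); rect[11:70, 11:20] <- TRUE
  hr <- hull_metrics(rect)
  # hand oracle: 60 x 10 pixel-square hull, longest axis the diagonal,
  # smallest width the short side
  expect_equal(hr$span_ratio, sqrt(60^2 + 10^2) / 10, tolerance = 1e-6)
  expect_equal(hr$density, 1, tolerance = 1e-6)
  expect_equal(hr$area_px, 600)

  # hull area grows faster than mask area once branches are added
  soma_only <- disk_mask(6, pad = 30)
  withbr <- soma_only
  withbr[37, 43:70] <- TRUE
  withbr[5:30, 37] <- TRUE
  expect_lt(hull_metrics(withbr)$density, hull_metrics(soma_only)$density)
})

test_that("shape descriptors are invariant to translation and 90-degree rotation", {
  sp <- sierpinski_mask(6)
  base <- matrix(FALSE, 100, 100); base[3:66, 3:66] <- sp
  shifted <- matrix(FALSE, 100, 100); shifted[31:94, 20:83] <- sp
  rot <- matrix(FALSE, 100, 100); rot[3:66, 3:66] <- t(sp[64:1, ])
  h0 <- hull_metrics(base); h1 <- hull_metrics(shifted); h2 <- hull_metrics(rot)
  for (k in c("span_ratio", "density", "circularity")) {
    expect_equal(h0[[k]], h1[[k]], tolerance = 1e-12)
    expect_equal(h0[[k]], h2[[k]], tolerance = 1e-12)
  }
})

test_that("dimension is stable under nearest-neighbour upscaling", {
  sp <- sierpinski_mask(6)
  up <- sp[rep(seq_len(64), each = 2), rep(seq_len(64), each = 2)]
  d1 <- fractal_dimension(box_count(sp))
  d2 <- fractal_dimension(box_count(up))
  expect_lt(abs(d1 - d2), 0.05)
})

test_that("profile change is relative-magnitude arithmetic with pooling", {
  p0 <- c(area_px = 100, perimeter_px = 50, fractal_dimension = 1.5,
          lacunarity = 0.3, span_ratio = 1.2, density = 0.4,
          circularity = 0.8)
  expect_equal(profile_change(p0, p0)$pooled_change_pct, 0)
  p1 <- p0; p1["area_px"] <- 82
  ch <- profile_change(p0, p1)
  expect_equal(unname(ch$change_pct["area_px"]), 18)
  expect_equal(ch$pooled_change_pct, 18 / 7)
  p0z <- p0; p0z["lacunarity"] <- 0
  expect_warning(chz <- profile_change(p0z, p1), "zero baseline")
  expect_equal(length(chz$change_pct), 6)
})
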