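# Shared fixtures: small acquisition geometry, analytic masks, and a
# bare-bones time_series constructor for measurement-level tests.

small_acq <- function(...) acquisition_settings(field_shape = c(256L, 256L), ...)

# mono-exponential preset with a 60 s half-life and no residual background
halflife_preset <- function() {
  fluorophore_preset("half60", k_fast = log(2) / 60, k_slow = 0, f_fast = 1,
                     bg_residual = 0)
}

no_bleach_preset <- function() {
  fluorophore_preset("inert", k_fast = 0, k_slow = 0, f_fast = 1,
                     bg_residual = 0)
}

# Sierpinski triangle of side 2^k: pixel (i, j) is foreground iff the
# binary expansions of its 0-based coordinates share no set bit.
sierpinski_mask <- function(k) {
  n <- 2L^k
  idx <- 0:(n - 1L)
  outer(idx, idx, function(i, j) bitwAnd(i, j) == 0L)
}

disk_mask <- function(r, pad = 2L) {
  n <- 2L * (r + pad) + 1L
  ctr <- r + pad + 1
  outer(seq_len(n), seq_len(n),
        function(i, j) (i - ctr)^2 + (j - ctr)^2 <= r^2)
}

# A time series from raw integer matrices (for measurement-level tests
# that do not need the generator).
manual_series <- function(frames, times, fluor = "test", kind = "manual") {
  structure(list(frames = frames, times = times,
                 scene = list(kind = kind),
                 preset = list(name = fluor)),
            class = "time_series")
}

# A hand-built neuron-like scene: flat nucleus disks of given amplitudes
# on an empty field, no diffuse staining.
manual_nucleus_scene <- function(amps, shape = c(128L, 128L), radius = 4) {
  label <- matrix(0, shape[1], shape[2])
  truth <- vector("list", length(amps))
  centres_r <- seq(15, shape[1] - 15, length.out = length(amps))
  for (i in seq_along(amps)) {
    ctr <- c(centres_r[i], shape[2] / 2)
    px <- which(outer(seq_len(shape[1]) - ctr[1], seq_len(shape[2]) - ctr[2],
                      function(a, b) a^2 + b^2 <= radius^2))
    label[px] <- amps[i]
    truth[[i]] <- list(profile = px, soma = integer(0), nucleus = px)
  }
  structure(list(kind = "neuron", shape = shape, cells = as.list(amps),
                 label_map = label, diffuse_level = 0, truth = truth,
                 seed = 0L, params = scene_params()),
            class = "scene")
}
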