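# Shared fixtures: all synthetic, generated in code at test time.

# Small phantom for unit tests (fast to render).
small_params <- function(...) {
  phantom_params(grid_shape = c(48L, 48L, 48L), ...)
}

# A volume containing Gaussian blobs of given sigmas/amplitudes on a flat
# background; returns the volume and blob centres (world mm).
blob_volume <- function(n = 48, blobs, background = 0.1) {
  a <- array(background, c(n, n, n))
  for (b in blobs) {
    w <- ceiling(4 * b$sigma)
    ctr <- b$centre
    ix <- max(1, ctr[1] - w):min(n, ctr[1] + w)
    iy <- max(1, ctr[2] - w):min(n, ctr[2] + w)
    iz <- max(1, ctr[3] - w):min(n, ctr[3] + w)
    d2 <- outer(outer((ix - 1 - ctr[1])^2, (iy - 1 - ctr[2])^2, "+"),
                (iz - 1 - ctr[3])^2, "+")
    a[ix, iy, iz] <- a[ix, iy, iz] + b$amp * exp(-d2 / (2 * b$sigma^2))
  }
  volume3d(a)
}

# Closed-form scale-normalized LoG response (up to a constant) of a 3D
# Gaussian blob of size sigma_b probed at filter scale sigma:
#   response(sigma) ~ sigma^2 / (sigma_b^2 + sigma^2)^(5/2)
blob_log_response <- function(sigma, sigma_b) {
  sigma^2 / (sigma_b^2 + sigma^2)^(5 / 2)
}

# Tiny CropNet specs for CPU-speed training tests.
tiny_spec <- function(blocks = 1L) {
  cropnet_spec(blocks = blocks, roi_mm = 8L, levels = 3L,
               widths = c(2L, 4L, 8L), dropout = 0.1)
}

# Separable toy ROI pools: bright centred sphere (positive) vs noise cube
# (negative), edge 8.
toy_pools <- function(n_per_class = 30, edge = 8, seed = 99) {
  withr_seed <- function(code) { set.seed(seed); code }
  withr_seed({
    mk <- function(n, pos) {
      vapply(seq_len(n), function(i) {
        a <- array(runif(edge^3, 0, 0.3), rep(edge, 3))
        if (pos) {
          c0 <- (edge + 1) / 2
          for (x in seq_len(edge)) for (y in seq_len(edge))
            for (z in seq_len(edge))
              if ((x - c0)^2 + (y - c0)^2 + (z - c0)^2 < 5)
                a[x, y, z] <- min(1, a[x, y, z] + 0.6)
        }
        as.numeric(a)
      }, numeric(edge^3))
    }
    roi_set(cbind(mk(n_per_class, TRUE), mk(n_per_class, FALSE)),
            y = rep(c(1L, 0L), each = n_per_class), edge = edge)
  })
}

# Random annotation table helper.
random_annotations <- function(n, lim = 40, seed = 1) {
  set.seed(seed)
  data.frame(lesion_id = seq_len(n),
             x_mm = runif(n, 5, lim), y_mm = runif(n, 5, lim),
             z_mm = runif(n, 5, lim),
             diameter_mm = runif(n, 2, 14))
}
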