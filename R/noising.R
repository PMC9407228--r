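#' Data-noising configuration
#'
#' Settings of the training-time data noising applied to ROI patches:
#' Simard-style random elastic deformation, gamma correction, axis-aligned
#' 90-degree rotations and per-axis flips.  Defaults keep a centred lesion
#' within the 1.5 mm matching tolerance of the cube centre (label
#' preservation), so a positive patch stays positive.  Noising is applied
#' only inside training losses; pseudo-labeling inference always sees
#' un-noised patches.
#'
#' @param alpha elastic displacement magnitude in voxels (0 disables).
#' @param sigma elastic smoothness: Gaussian sigma (voxels) applied to the
#'   random displacement field (> 0).
#' @param gamma_range interval around 1 for the random gamma exponent.
#' @param flip_prob per-axis flip probability.
#' @param elastic,gamma,rotate,flip per-transform enable flags.
#' @param arbitrary_rotation if `TRUE`, rotations use a random angle about a
#'   random axis (trilinear resampling) instead of interpolation-free
#'   90-degree multiples.  Off by default: orthogonal rotations preserve the
#'   voxel multiset exactly.
#' @return An object of class `noise_config`.
#' @export
noise_config <- function(alpha = 2, sigma = 4, gamma_range = c(0.8, 1.25),
                         flip_prob = 0.5, elastic = TRUE, gamma = TRUE,
                         rotate = TRUE, flip = TRUE,
                         arbitrary_rotation = FALSE) {
  stopifnot(alpha >= 0, sigma > 0, length(gamma_range) == 2L,
            all(gamma_range > 0), gamma_range[1] <= gamma_range[2],
            flip_prob >= 0, flip_prob <= 1)
  structure(list(alpha = alpha, sigma = sigma, gamma_range = gamma_range,
                 flip_prob = flip_prob, elastic = elastic, gamma = gamma,
                 rotate = rotate, flip = flip,
                 arbitrary_rotation = arbitrary_rotation),
            class = "noise_config")
}

#' Random elastic deformation
#'
#' Simard-style deformation: a per-voxel displacement field drawn uniformly
#' from (-1, 1)^3, Gaussian-smoothed with `sigma`, scaled by `alpha`
#' (voxels), then applied by trilinear resampling with mirror boundary.
#'
#' @param roi cubic numeric array.
#' @param alpha displacement magnitude in voxels; `alpha = 0` is the
#'   identity.
#' @param sigma smoothing sigma in voxels (> 0).
#' @param seed integer RNG seed (deterministic output).
#' @return Deformed array of the same shape.
#' @export
elastic_deform <- function(roi, alpha, sigma, seed) {
  if (sigma <= 0) stop("`sigma` must be positive", call. = FALSE)
  if (alpha == 0) return(roi)
  .elastic_deform_cpp(roi, alpha, sigma, as.integer(seed))
}

#' Gamma correction
#'
#' Voxelwise `v^gamma` on intensities in `[0, 1]`; `gamma = 1` is the
#' identity and any positive gamma preserves intensity ordering.
#'
#' @param roi numeric array with values in `[0, 1]`.
#' @param gamma positive exponent.
#' @return Corrected array.
#' @export
gamma_correct <- function(roi, gamma) {
  if (gamma <= 0) stop("`gamma` must be positive", call. = FALSE)
  if (any(roi < 0) || any(roi > 1))
    stop("gamma correction requires intensities in [0, 1]", call. = FALSE)
  roi^gamma
}

# Apply an orthogonal cube transform: axis permutation then per-axis flips.
.apply_ortho <- function(roi, perm, flips) {
  out <- aperm(roi, perm)
  d <- dim(out)
  idx <- lapply(1:3, function(a) if (flips[a]) rev(seq_len(d[a]))
                else seq_len(d[a]))
  out[idx[[1]], idx[[2]], idx[[3]]]
}

#' Random 90-degree rotation and flips
#'
#' Applies a random composition of axis-aligned 90-degree rotations and
#' per-axis flips (an element of the 48-element cube symmetry group).  The
#' voxel multiset is preserved exactly; the sampled transform is attached as
#' attribute `"transform"` so it can be inverted with
#' [invert_rotate_flip()].
#'
#' @param roi cubic numeric array.
#' @param seed integer RNG seed.
#' @param flip_prob per-axis flip probability.
#' @param rotate sample a random axis permutation (otherwise identity).
#' @return Transformed array with a `"transform"` attribute.
#' @export
rotate_flip <- function(roi, seed, flip_prob = 0.5, rotate = TRUE) {
  d <- dim(roi)
  if (length(d) != 3L || length(unique(d)) != 1L)
    stop("`roi` must be a cubic array", call. = FALSE)
  tr <- with_seed(seed, {
    perm <- if (rotate) sample(3L) else 1:3
    flips <- runif(3) < flip_prob
    list(perm = perm, flips = flips)
  })
  out <- .apply_ortho(roi, tr$perm, tr$flips)
  attr(out, "transform") <- tr
  out
}

#' Invert a rotate/flip transform
#'
#' @param roi array produced by [rotate_flip()] (or any array).
#' @param transform the `"transform"` attribute of the forward call.
#' @return The array with the transform undone.
#' @export
invert_rotate_flip <- function(roi, transform = attr(roi, "transform")) {
  if (is.null(transform)) stop("no transform to invert", call. = FALSE)
  d <- dim(roi)
  idx <- lapply(1:3, function(a) if (transform$flips[a]) rev(seq_len(d[a]))
                else seq_len(d[a]))
  out <- roi[idx[[1]], idx[[2]], idx[[3]]]
  aperm(out, order(transform$perm))
}

# Arbitrary-angle rotation about a random axis (trilinear, mirror boundary).
.free_rotate <- function(roi, angle, axis) {
  d <- dim(roi)
  c0 <- (d - 1) / 2
  u <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0), 3, 3,
              byrow = TRUE)
  R <- diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
  base <- cbind(rep(seq_len(d[1]) - 1, times = d[2] * d[3]),
                rep(rep(seq_len(d[2]) - 1, each = d[1]), times = d[3]),
                rep(seq_len(d[3]) - 1, each = d[1] * d[2]))
  pts <- sweep(sweep(base, 2L, c0, "-") %*% t(R), 2L, c0, "+")
  array(.trilinear_sample_cpp(roi, pts), dim = d)
}

#' Apply the full data-noising pipeline
#'
#' Deterministic-under-seed composition: elastic deformation, then gamma
#' correction, then rotation/flip; the output is clipped to `[0, 1]`.  With
#' every transform disabled the input is returned unchanged.
#'
#' @param roi cubic numeric array normalized to `[0, 1]`.
#' @param config a [noise_config()].
#' @param seed integer RNG seed.
#' @return Noised array of the same shape.
#' @export
apply_noise <- function(roi, config = noise_config(), seed) {
  stopifnot(inherits(config, "noise_config"))
  draws <- with_seed(seed, list(
    elastic_seed = next_seed(),
    gamma = runif(1, config$gamma_range[1], config$gamma_range[2]),
    perm = sample(3L),
    flips = runif(3) < config$flip_prob,
    angle = runif(1, 0, 2 * pi),
    axis = rnorm(3)))
  out <- roi
  if (config$elastic && config$alpha > 0)
    out <- .elastic_deform_cpp(out, config$alpha, config$sigma,
                               as.integer(draws$elastic_seed))
  if (config$gamma && draws$gamma != 1) {
    out[out < 0] <- 0
    out[out > 1] <- 1
    out <- out^draws$gamma
  }
  if (config$rotate && config$arbitrary_rotation)
    out <- .free_rotate(out, draws$angle, draws$axis)
  perm <- if (config$rotate && !config$arbitrary_rotation) draws$perm
          else 1:3
  flips <- if (config$flip) draws$flips else rep(FALSE, 3)
  if (any(perm != 1:3) || any(flips))
    out <- .apply_ortho(out, perm, flips)
  out[out < 0] <- 0
  out[out > 1] <- 1
  out
}
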