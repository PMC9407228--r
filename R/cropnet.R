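#' CropNet model specification
#'
#' The CropNet-bX-Ymm family: a contracting 3D CNN with `blocks` (= X)
#' conv(3^3)-ReLU-dropout blocks per resolution level, 2x max-pooling
#' between levels, and a flattened single-unit sigmoid head over the
#' coarsest level.  `roi_mm` (= Y) is the cubic input edge in mm (1 mm
#' voxels).  With the default four levels and width schedule
#' (64, 128, 256, 512) the b2 and b4 variants total ~14.1M and ~32.9M
#' trainable parameters — the teacher and student capacities used by the
#' framework.  Desk-scale work uses narrower schedules such as
#' `c(4, 8, 16, 32)`.
#'
#' @param blocks conv blocks per resolution level (X >= 1).
#' @param roi_mm cubic input edge in mm; must be divisible by
#'   `2^(levels - 1)`.
#' @param levels number of resolution levels.
#' @param widths channel counts per level (length `levels`).
#' @param dropout dropout rate in `[0, 1)`; active only in training mode.
#' @return An object of class `cropnet_spec`.
#' @export
cropnet_spec <- function(blocks = 2L, roi_mm = 16L, levels = 4L,
                         widths = c(64L, 128L, 256L, 512L),
                         dropout = 0.15) {
  blocks <- as.integer(blocks); roi_mm <- as.integer(roi_mm)
  levels <- as.integer(levels); widths <- as.integer(widths)
  if (blocks < 1L) stop("`blocks` must be >= 1", call. = FALSE)
  if (length(widths) != levels)
    stop("`widths` must have one entry per level", call. = FALSE)
  if (any(widths < 1L)) stop("widths must be positive", call. = FALSE)
  if (dropout < 0 || dropout >= 1)
    stop("`dropout` must be in [0, 1)", call. = FALSE)
  if (roi_mm %% 2L^(levels - 1L) != 0L || roi_mm %/% 2L^(levels - 1L) < 1L)
    stop("`roi_mm` must be divisible by 2^(levels - 1)", call. = FALSE)
  structure(list(blocks = blocks, roi_mm = roi_mm, levels = levels,
                 widths = widths, dropout = dropout,
                 name = sprintf("CropNet-b%d-%dmm", blocks, roi_mm)),
            class = "cropnet_spec")
}

#' @export
print.cropnet_spec <- function(x, ...) {
  cat(sprintf("<cropnet_spec> %s: %d levels, widths (%s), dropout %.2f\n",
              x$name, x$levels, paste(x$widths, collapse = ", "), x$dropout))
  invisible(x)
}

# Conv layer channel plan: list of (cin, cout) in network order.
.conv_plan <- function(spec) {
  plan <- list()
  for (l in seq_len(spec$levels))
    for (j in seq_len(spec$blocks)) {
      cin <- if (j == 1L) {
        if (l == 1L) 1L else spec$widths[l - 1L]
      } else spec$widths[l]
      plan[[length(plan) + 1L]] <- c(cin = cin, cout = spec$widths[l])
    }
  plan
}

#' Build a CropNet classifier
#'
#' Instantiates the architecture with fan-in-scaled random initial weights
#' (He-normal for the conv layers, Xavier for the head) drawn from `seed`.
#'
#' @param spec a [cropnet_spec].
#' @param seed integer RNG seed (logged on the model).
#' @return An object of class `cropnet`: `spec`, `params`
#'   (`W`, `b`, `wd`, `bd`) and `seed`.
#' @export
build_model <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "cropnet_spec"))
  plan <- .conv_plan(spec)
  params <- with_seed(seed, {
    W <- lapply(plan, function(p) {
      fan_in <- 27 * p["cin"]
      matrix(rnorm(27 * p["cin"] * p["cout"], sd = sqrt(2 / fan_in)),
             nrow = 27 * p["cin"], ncol = p["cout"])
    })
    b <- lapply(plan, function(p) numeric(p["cout"]))
    side_f <- spec$roi_mm %/% 2L^(spec$levels - 1L)
    nd <- side_f^3 * spec$widths[spec$levels]
    list(W = W, b = b, wd = rnorm(nd, sd = sqrt(1 / nd)), bd = 0)
  })
  structure(list(spec = spec, params = params, seed = as.integer(seed)),
            class = "cropnet")
}

#' @export
print.cropnet <- function(x, ...) {
  cat(sprintf("<cropnet> %s, %s trainable parameters (seed %d)\n",
              x$spec$name, format(count_parameters(x), big.mark = ","),
              x$seed))
  invisible(x)
}

#' Count trainable parameters
#'
#' @param model a [build_model()] classifier.
#' @return Total number of trainable scalars (weights and biases).
#' @export
count_parameters <- function(model) {
  stopifnot(inherits(model, "cropnet"))
  sum(vapply(model$params$W, length, 0)) +
    sum(vapply(model$params$b, length, 0)) +
    length(model$params$wd) + 1
}

# Coerce ROI input (array S^3, array S^3 x N, or V x N matrix) to a V x N
# matrix and validate the edge against the spec.
.roi_batch <- function(rois, side) {
  V <- side^3
  if (is.matrix(rois)) {
    if (nrow(rois) != V)
      stop("ROI size does not match the model's input edge", call. = FALSE)
    return(rois)
  }
  d <- dim(rois)
  if (is.null(d) || !(length(d) %in% c(3L, 4L)) ||
      any(d[1:3] != c(side, side, side)))
    stop("ROI size does not match the model's input edge", call. = FALSE)
  matrix(rois, nrow = V)
}

#' Classify ROI patches
#'
#' Runs the classifier forward on a batch of cubic ROIs, giving one response
#' in `[0, 1]` per ROI (probability the patch contains a lesion).  Inference
#' mode (`training = FALSE`) is deterministic; in training mode dropout is
#' active and driven by `seed`.
#'
#' @param model a `cropnet` classifier.
#' @param rois one ROI array, an `S x S x S x N` array, or an `S^3 x N`
#'   matrix.
#' @param training activate dropout (model noising).
#' @param seed dropout seed for training mode (drawn from the RNG stream if
#'   omitted).
#' @param chunk maximum ROIs per internal pass; large inference batches are
#'   split to bound the activation memory.
#' @return Numeric vector of responses in `[0, 1]`.
#' @export
forward <- function(model, rois, training = FALSE, seed = NULL,
                    chunk = 256L) {
  stopifnot(inherits(model, "cropnet"))
  side <- model$spec$roi_mm
  x <- .roi_batch(rois, side)
  n <- ncol(x)
  if (n == 0L) return(numeric())
  dropout_seed <- if (training && model$spec$dropout > 0) {
    if (is.null(seed)) next_seed() else as.integer(seed)
  } else -1L
  run <- function(xs, ds) {
    as.numeric(.cn_forward_cpp(model$params$W, model$params$b,
                               model$params$wd, model$params$bd,
                               as.numeric(xs), ncol(xs), side,
                               model$spec$levels, model$spec$blocks,
                               model$spec$widths, model$spec$dropout, ds))
  }
  if (n <= chunk) return(run(x, dropout_seed))
  starts <- seq(1L, n, by = chunk)
  unlist(lapply(seq_along(starts), function(i) {
    cols <- starts[i]:min(n, starts[i] + chunk - 1L)
    ds <- if (dropout_seed < 0) -1L else dropout_seed + i - 1L
    run(x[, cols, drop = FALSE], ds)
  }))
}
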