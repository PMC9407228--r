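#' Training configuration
#'
#' Hyperparameters of the paired-batch Adam training used for both teacher
#' and student.  Defaults mirror the full-scale study setup: learning rate
#' 5e-5, Adam decay rates 0.9/0.999, 12,000 batch iterations with no early
#' stopping, teacher batches of 150 positive + 150 negative patches and
#' student batches of 75 labeled-positive + 75 pseudo-positive + 75
#' labeled-negative + 75 pseudo-negative patches.  Desk-scale runs shrink
#' `iterations` and the batch compositions proportionally.
#'
#' @param lambda nonnegative weight of the pseudo-labeled loss term;
#'   `lambda = 1` recovers equal weighting of the two halves.
#' @param lr Adam learning rate.
#' @param beta1,beta2 Adam first/second-moment decay rates.
#' @param iterations number of batch-training iterations (>= 0; 0 returns
#'   the seeded initialization unchanged).
#' @param teacher_batch named counts `c(pos =, neg =)`; must be paired
#'   (equal).
#' @param student_batch named counts
#'   `c(pos =, pseudo_pos =, neg =, pseudo_neg =)`; labeled and pseudo
#'   halves must each be paired.
#' @param seed integer RNG seed driving batch sampling, noising and dropout.
#' @return An object of class `training_config`.
#' @export
training_config <- function(lambda = 1, lr = 5e-5, beta1 = 0.9,
                            beta2 = 0.999, iterations = 12000L,
                            teacher_batch = c(pos = 150L, neg = 150L),
                            student_batch = c(pos = 75L, pseudo_pos = 75L,
                                              neg = 75L, pseudo_neg = 75L),
                            seed = 1L) {
  if (lambda < 0) stop("`lambda` must be >= 0", call. = FALSE)
  if (iterations < 0) stop("`iterations` must be >= 0", call. = FALSE)
  tb <- teacher_batch; sb <- student_batch
  stopifnot(all(c("pos", "neg") %in% names(tb)),
            all(c("pos", "pseudo_pos", "neg", "pseudo_neg") %in% names(sb)),
            all(tb >= 0), all(sb >= 0))
  if (tb[["pos"]] != tb[["neg"]])
    stop("teacher batches must be paired (pos == neg)", call. = FALSE)
  if (sb[["pos"]] != sb[["neg"]] ||
      sb[["pseudo_pos"]] != sb[["pseudo_neg"]])
    stop("student batches must be paired within each half", call. = FALSE)
  structure(list(lambda = lambda, lr = lr, beta1 = beta1, beta2 = beta2,
                 iterations = as.integer(iterations),
                 teacher_batch = tb, student_batch = sb,
                 seed = as.integer(seed), eps = 1e-8),
            class = "training_config")
}

#' Binary cross-entropy loss
#'
#' Mean of `-[y log p + (1 - y) log(1 - p)]` with responses clipped away
#' from 0 and 1 by `eps`.
#'
#' @param responses numeric vector in `[0, 1]`.
#' @param labels binary vector of the same length.
#' @param eps clipping constant.
#' @return Nonnegative scalar.
#' @export
bce_loss <- function(responses, labels, eps = 1e-7) {
  if (length(responses) != length(labels))
    stop("`responses` and `labels` must have equal length", call. = FALSE)
  p <- pmin(pmax(responses, eps), 1 - eps)
  mean(-(labels * log(p) + (1 - labels) * log(1 - p)))
}

#' Combined labeled + pseudo-labeled loss
#'
#' `bce(labeled) + lambda * bce(pseudo)`, each half mean-reduced
#' separately; the value is affine in `lambda`, and `lambda = 0` reduces to
#' the labeled loss alone (the pseudo half may then be empty).
#'
#' @param resp_l,y_l labeled responses and labels.
#' @param resp_u,y_u pseudo-labeled responses and labels.
#' @param lambda nonnegative weight of the pseudo half.
#' @return Scalar loss.
#' @export
combined_loss <- function(resp_l, y_l, resp_u, y_u, lambda) {
  if (lambda < 0) stop("`lambda` must be >= 0", call. = FALSE)
  if (length(resp_l) == 0L)
    stop("labeled half must be non-empty", call. = FALSE)
  if (lambda == 0 && length(resp_u) == 0L)
    return(bce_loss(resp_l, y_l))
  if (length(resp_u) == 0L)
    stop("pseudo half must be non-empty when lambda > 0", call. = FALSE)
  bce_loss(resp_l, y_l) + lambda * bce_loss(resp_u, y_u)
}

#' ROI set container
#'
#' Bundles a batch-ready ROI matrix (one column per patch, voxels in
#' column-major order) with labels and per-ROI provenance.
#'
#' @param x numeric `V x n` matrix of flattened cubic patches.
#' @param y binary labels, length `n` (may be `NULL` for unlabeled sets).
#' @param meta data.frame of per-ROI provenance (source exam, centre,
#'   matched lesion, source kind), `n` rows.
#' @param edge cube edge in voxels.
#' @return An object of class `roi_set`.
#' @export
roi_set <- function(x, y = NULL, meta = NULL, edge = round(nrow(x)^(1 / 3))) {
  edge <- as.integer(round(edge))
  stopifnot(is.matrix(x), nrow(x) == edge^3)
  if (!is.null(y)) stopifnot(length(y) == ncol(x))
  structure(list(x = x, y = y, meta = meta, edge = edge), class = "roi_set")
}

#' @export
print.roi_set <- function(x, ...) {
  cat(sprintf("<roi_set> %d ROIs of edge %d%s\n", ncol(x$x), x$edge,
              if (!is.null(x$y)) sprintf(" (%d positive)", sum(x$y)) else ""))
  invisible(x)
}

#' Sample a paired training batch
#'
#' Draws, with replacement, exactly the requested number of patches from
#' each named pool and shuffles their order.  Pools with a positive
#' requested count must be non-empty.
#'
#' @param pools named list of `V x n_i` ROI matrices.
#' @param composition named integer vector of per-pool counts (names must
#'   exist in `pools`).
#' @param seed integer RNG seed.
#' @return List with `x` (`V x B` matrix), `pool` (factor of source pool
#'   per column) and `index` (source column within its pool).
#' @export
sample_paired_batch <- function(pools, composition, seed) {
  stopifnot(all(names(composition) %in% names(pools)))
  with_seed(seed, {
    src <- character(); idx <- integer()
    for (nm in names(composition)) {
      k <- composition[[nm]]
      if (k == 0L) next
      n <- ncol(pools[[nm]])
      if (is.null(n) || n == 0L)
        stop("pool exhausted: '", nm, "' is empty but ", k,
             " samples were requested", call. = FALSE)
      take <- sample.int(n, k, replace = TRUE)
      src <- c(src, rep(nm, k)); idx <- c(idx, take)
    }
    B <- length(idx)
    if (B == 0L) {
      V <- if (length(pools)) nrow(pools[[1]]) else 0L
      list(x = matrix(numeric(), max(V, 0L), 0L),
           pool = factor(character(), levels = names(pools)),
           index = integer())
    } else {
      ord <- sample.int(B)
      src <- src[ord]; idx <- idx[ord]
      x <- matrix(NA_real_, nrow(pools[[src[1]]]), B)
      for (j in seq_len(B)) x[, j] <- pools[[src[j]]][, idx[j]]
      list(x = x, pool = factor(src, levels = names(pools)), index = idx)
    }
  })
}

# ---- Adam ----------------------------------------------------------------

.adam_init <- function(params) {
  zero_like <- function(p) if (is.list(p)) lapply(p, zero_like) else p * 0
  list(m = zero_like(params), v = zero_like(params))
}

.adam_step <- function(params, grads, state, t, lr, b1, b2, eps) {
  upd <- function(p, g, m, v) {
    if (is.list(p)) {
      out <- mapply(upd, p, g, m, v, SIMPLIFY = FALSE)
      return(list(p = lapply(out, `[[`, "p"), m = lapply(out, `[[`, "m"),
                  v = lapply(out, `[[`, "v")))
    }
    m <- b1 * m + (1 - b1) * g
    v <- b2 * v + (1 - b2) * g^2
    mhat <- m / (1 - b1^t)
    vhat <- v / (1 - b2^t)
    list(p = p - lr * mhat / (sqrt(vhat) + eps), m = m, v = v)
  }
  out <- upd(params, grads, state$m, state$v)
  list(params = out$p, state = list(m = out$m, v = out$v))
}

# ---- shared training core ------------------------------------------------
#
# pools: named list of V x n matrices; composition: counts per pool;
# labels/weights: per-pool class label and per-sample loss weight.
.train_core <- function(pools, spec, config, noise, composition, labels,
                        weights) {
  model <- build_model(spec, seed = config$seed)
  if (config$iterations == 0L) {
    model$log <- data.frame(iteration = integer(), loss = numeric())
    return(model)
  }
  side <- spec$roi_mm
  params <- model$params
  state <- .adam_init(params)
  losses <- numeric(config$iterations)
  noising_on <- !is.null(noise) &&
    (noise$elastic || noise$gamma || noise$rotate || noise$flip)
  with_seed(config$seed + 1L, {
    for (it in seq_len(config$iterations)) {
      batch <- sample_paired_batch(pools, composition, seed = next_seed())
      xb <- batch$x
      if (noising_on) {
        for (j in seq_len(ncol(xb))) {
          roi <- array(xb[, j], dim = c(side, side, side))
          xb[, j] <- apply_noise(roi, noise, seed = next_seed())
        }
      }
      y <- labels[as.character(batch$pool)]
      w <- weights[as.character(batch$pool)]
      g <- .cn_grad_cpp(params$W, params$b, params$wd, params$bd,
                        as.numeric(xb), ncol(xb), side, spec$levels,
                        spec$blocks, spec$widths, spec$dropout,
                        next_seed(), y, w)
      losses[it] <- g$loss
      st <- .adam_step(params, list(W = g$gW, b = g$gb, wd = g$gwd,
                                    bd = g$gbd),
                       state, it, config$lr, config$beta1, config$beta2,
                       config$eps)
      params <- st$params
      state <- st$state
    }
  })
  # restore shapes lost through list surgery
  params$bd <- as.numeric(params$bd)
  model$params <- params
  model$log <- data.frame(iteration = seq_len(config$iterations),
                          loss = losses)
  model
}

#' Train the teacher classifier
#'
#' Minimizes binary cross-entropy over noised paired batches (equal
#' positives and negatives) with Adam, starting from the seeded
#' initialization.
#'
#' @param labeled a [roi_set()] with binary labels covering both classes.
#' @param spec teacher [cropnet_spec()].
#' @param config a [training_config()].
#' @param noise a [noise_config()] (or `NULL` to disable data noising).
#' @return A `cropnet` classifier with a per-iteration `log`.
#' @export
train_teacher <- function(labeled, spec, config, noise = noise_config()) {
  stopifnot(inherits(labeled, "roi_set"), !is.null(labeled$y))
  pools <- list(pos = labeled$x[, labeled$y == 1, drop = FALSE],
                neg = labeled$x[, labeled$y == 0, drop = FALSE])
  comp <- c(pos = config$teacher_batch[["pos"]],
            neg = config$teacher_batch[["neg"]])
  if (config$iterations > 0L && (ncol(pools$pos) == 0L ||
                                 ncol(pools$neg) == 0L))
    stop("pool exhausted: teacher training needs both classes",
         call. = FALSE)
  B <- sum(comp)
  .train_core(pools, spec, config, noise, comp,
              labels = c(pos = 1, neg = 0),
              weights = c(pos = 1 / B, neg = 1 / B))
}

#' Train the student classifier
#'
#' Minimizes the combined loss `bce(labeled) + lambda * bce(pseudo)` over
#' mixed paired batches drawn from the labeled and pseudo-labeled pools;
#' both halves are noised independently.  With `lambda = 0` the pseudo term
#' vanishes and the optimization trajectory equals teacher-style training of
#' the student spec on the labeled pools alone.
#'
#' @param labeled a labeled [roi_set()].
#' @param pseudo a pseudo-label set from [pseudo_label()] (may be empty when
#'   `config$lambda` is 0).
#' @param spec student [cropnet_spec()].
#' @param config a [training_config()]; `lambda` is taken from here.
#' @param noise a [noise_config()].
#' @return A `cropnet` classifier with a per-iteration `log`.
#' @export
train_student <- function(labeled, pseudo, spec, config,
                          noise = noise_config()) {
  stopifnot(inherits(labeled, "roi_set"), !is.null(labeled$y))
  sb <- config$student_batch
  lambda <- config$lambda
  lab_pools <- list(pos = labeled$x[, labeled$y == 1, drop = FALSE],
                    neg = labeled$x[, labeled$y == 0, drop = FALSE])
  if (lambda == 0) {
    comp <- c(pos = sb[["pos"]], neg = sb[["neg"]])
    B <- sum(comp)
    return(.train_core(lab_pools, spec, config, noise, comp,
                       labels = c(pos = 1, neg = 0),
                       weights = c(pos = 1 / B, neg = 1 / B)))
  }
  if (is.null(pseudo) || length(pseudo$labels) == 0L)
    stop("pool exhausted: pseudo set is empty but lambda > 0", call. = FALSE)
  pools <- c(lab_pools,
             list(pseudo_pos = pseudo$x[, pseudo$labels == 1, drop = FALSE],
                  pseudo_neg = pseudo$x[, pseudo$labels == 0, drop = FALSE]))
  comp <- c(pos = sb[["pos"]], pseudo_pos = sb[["pseudo_pos"]],
            neg = sb[["neg"]], pseudo_neg = sb[["pseudo_neg"]])
  n_l <- comp[["pos"]] + comp[["neg"]]
  n_u <- comp[["pseudo_pos"]] + comp[["pseudo_neg"]]
  if (config$iterations > 0L) {
    for (nm in names(comp))
      if (comp[[nm]] > 0L && ncol(pools[[nm]]) == 0L)
        stop("pool exhausted: '", nm, "' is empty", call. = FALSE)
  }
  .train_core(pools, spec, config, noise, comp,
              labels = c(pos = 1, neg = 0, pseudo_pos = 1, pseudo_neg = 0),
              weights = c(pos = 1 / n_l, neg = 1 / n_l,
                          pseudo_pos = lambda / n_u,
                          pseudo_neg = lambda / n_u))
}

# ---- sensitivity calibration and pseudo-labeling -------------------------

#' Sensitivity-vs-threshold staircase
#'
#' Builds the training-set relationship between a response threshold and
#' lesion detection sensitivity from per-lesion maximum classifier
#' responses (pooled over all training lesions; a lesion with no matched
#' candidate contributes `-Inf`, i.e. it is never detected).  For a
#' threshold `t`, `sensitivity(t) = #(max response > t) / L` — a
#' non-increasing staircase.
#'
#' @param max_responses numeric vector of per-lesion maximum responses
#'   (`-Inf` allowed), one entry per training lesion.
#' @return An object of class `sensitivity_curve`.
#' @export
sensitivity_curve <- function(max_responses) {
  if (length(max_responses) == 0L)
    stop("sensitivity curve undefined for zero lesions", call. = FALSE)
  sorted <- sort(max_responses, decreasing = TRUE)
  structure(list(max_responses = sorted, n_lesions = length(sorted)),
            class = "sensitivity_curve")
}

#' Evaluate a sensitivity curve at thresholds
#'
#' @param curve a [sensitivity_curve()].
#' @param thresholds numeric vector.
#' @return Sensitivities in `[0, 1]`, one per threshold (strict `>` rule).
#' @export
sensitivity_at <- function(curve, thresholds) {
  stopifnot(inherits(curve, "sensitivity_curve"))
  vapply(thresholds,
         function(t) sum(curve$max_responses > t) / curve$n_lesions, 0)
}

#' Calibrate the pseudo-labeling threshold
#'
#' Finds the largest response threshold mu whose training sensitivity (under
#' the strict `response > mu` detection rule) still reaches the target
#' `ts`: with `L` lesions and `k = ceiling(ts * L)`, mu is the k-th largest
#' per-lesion maximum response reduced by a relative nudge of 1e-9 so that
#' lesion itself counts as detected.
#'
#' @param curve a [sensitivity_curve()].
#' @param ts target sensitivity in `(0, 1]`.
#' @return An object of class `threshold_calibration`: `ts`, `mu`,
#'   `achieved` (training sensitivity at mu) and `k`.
#' @export
calibrate_mu <- function(curve, ts) {
  stopifnot(inherits(curve, "sensitivity_curve"))
  if (!(ts > 0 && ts <= 1))
    stop("`ts` must be in (0, 1]", call. = FALSE)
  L <- curve$n_lesions
  k <- ceiling(ts * L)
  kth <- curve$max_responses[k]
  if (!is.finite(kth)) {
    peak <- sum(is.finite(curve$max_responses)) / L
    stop(sprintf(paste0("target sensitivity %.3f is not achievable: ",
                        "peak training sensitivity is %.3f"), ts, peak),
         call. = FALSE)
  }
  mu <- kth - 1e-9 * abs(kth)
  achieved <- sensitivity_at(curve, mu)
  structure(list(ts = ts, mu = mu, achieved = achieved, k = k,
                 n_lesions = L),
            class = "threshold_calibration")
}

#' @export
print.threshold_calibration <- function(x, ...) {
  cat(sprintf(paste0("<threshold_calibration> ts = %.3f -> mu = %.6f ",
                     "(achieved %.3f over %d lesions)\n"),
              x$ts, x$mu, x$achieved, x$n_lesions))
  invisible(x)
}

#' Pseudo-label unlabeled ROIs
#'
#' Runs the teacher on un-noised unlabeled patches and assigns binary
#' pseudo-labels by the strict rule `label = 1` iff `response > mu`
#' (a response exactly equal to mu is labeled 0).
#'
#' @param model the current teacher classifier.
#' @param rois a [roi_set()] (or `V x n` matrix) of unlabeled patches.
#' @param mu response threshold in `(0, 1)`.
#' @return An object of class `pseudo_label_set`: `x`, `responses`,
#'   `labels`, `mu`, `meta`.
#' @export
pseudo_label <- function(model, rois, mu) {
  if (!(mu > 0 && mu < 1)) stop("`mu` must be in (0, 1)", call. = FALSE)
  x <- if (inherits(rois, "roi_set")) rois$x else rois
  meta <- if (inherits(rois, "roi_set")) rois$meta else NULL
  responses <- if (ncol(x) > 0) forward(model, x) else numeric()
  structure(list(x = x, responses = responses,
                 labels = as.integer(responses > mu), mu = mu, meta = meta),
            class = "pseudo_label_set")
}

#' @export
print.pseudo_label_set <- function(x, ...) {
  cat(sprintf("<pseudo_label_set> %d ROIs, %d positive at mu = %.4f\n",
              length(x$labels), sum(x$labels), x$mu))
  invisible(x)
}
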