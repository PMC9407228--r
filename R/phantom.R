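#' Synthetic phantom cohort parameters
#'
#' Parameters of the synthetic contrast-enhanced brain phantom used to
#' emulate a labeled/unlabeled metastasis-screening cohort.  Defaults mirror
#' the published cohort statistics the package targets: truncated log-normal
#' lesion diameters with post-truncation mean 5.45 mm and SD 2.67 mm on
#' [2, 14] mm, a Poisson lesion count with mean 4.29 per exam, and bright
#' tubular vessel distractors (the dominant false-positive mode for
#' enhancing-lesion detectors).  Intensities are in arbitrary units around a
#' background level of 100; the pipeline percentile-normalizes per exam.
#'
#' @param grid_shape integer length-3 voxel grid (default 64^3, a desk-scale
#'   field of view; a full brain would use ~192^3 at the same spacing).
#' @param spacing voxel spacing in mm.
#' @param lesion_rate mean lesion count per exam (Poisson; zero-lesion exams
#'   are allowed and exercise the false-positive denominator).
#' @param diameter_mean,diameter_sd post-truncation mean/SD targets (mm) of
#'   the truncated log-normal diameter distribution.
#' @param diameter_range truncation interval (mm); must contain the mean.
#' @param min_separation minimum pairwise lesion-centre distance within one
#'   exam (mm), keeping the 1.5 mm matching unambiguous.
#' @param n_vessels integer range of vessel counts per exam.
#' @param vessel_radius vessel tube radius range (mm).
#' @param vessel_contrast vessel intensity uplift range (arbitrary units).
#' @param lesion_contrast lesion intensity uplift range (arbitrary units).
#' @param noise_sigma Rician noise sigma (arbitrary units).
#' @param background_level mean brain background intensity.
#' @param background_texture amplitude of the smooth background field.
#' @param brain_axes_frac ellipsoid semi-axes as a fraction of grid extent.
#' @return An object of class `phantom_params`.
#' @export
phantom_params <- function(grid_shape = c(64L, 64L, 64L),
                           spacing = c(1, 1, 1),
                           lesion_rate = 4.29,
                           diameter_mean = 5.45,
                           diameter_sd = 2.67,
                           diameter_range = c(2, 14),
                           min_separation = 8,
                           n_vessels = c(3L, 8L),
                           vessel_radius = c(0.5, 1.5),
                           vessel_contrast = c(30, 70),
                           lesion_contrast = c(25, 60),
                           noise_sigma = 4,
                           background_level = 100,
                           background_texture = 8,
                           brain_axes_frac = 0.45) {
  stopifnot(length(grid_shape) == 3L, all(grid_shape >= 8),
            length(spacing) == 3L, all(spacing > 0),
            lesion_rate >= 0, diameter_sd > 0,
            length(diameter_range) == 2L,
            diameter_range[1] < diameter_range[2],
            diameter_mean > diameter_range[1],
            diameter_mean < diameter_range[2],
            min_separation >= 0,
            length(n_vessels) == 2L, n_vessels[1] >= 0,
            n_vessels[1] <= n_vessels[2],
            vessel_radius[1] > 0, vessel_radius[1] <= vessel_radius[2],
            noise_sigma >= 0, background_level > 0,
            brain_axes_frac > 0, brain_axes_frac <= 0.5)
  structure(list(grid_shape = as.integer(grid_shape),
                 spacing = as.numeric(spacing),
                 lesion_rate = lesion_rate,
                 diameter_mean = diameter_mean, diameter_sd = diameter_sd,
                 diameter_range = as.numeric(diameter_range),
                 min_separation = min_separation,
                 n_vessels = as.integer(n_vessels),
                 vessel_radius = as.numeric(vessel_radius),
                 vessel_contrast = as.numeric(vessel_contrast),
                 lesion_contrast = as.numeric(lesion_contrast),
                 noise_sigma = noise_sigma,
                 background_level = background_level,
                 background_texture = background_texture,
                 brain_axes_frac = brain_axes_frac),
            class = "phantom_params")
}

# ---- truncated log-normal diameter model ----------------------------------

# k-th moment of a log-normal truncated to [a, b].
.trunc_lnorm_moment <- function(k, meanlog, sdlog, a, b) {
  za <- (log(a) - meanlog) / sdlog
  zb <- (log(b) - meanlog) / sdlog
  denom <- stats::pnorm(zb) - stats::pnorm(za)
  num <- stats::pnorm(zb - k * sdlog) - stats::pnorm(za - k * sdlog)
  exp(k * meanlog + k^2 * sdlog^2 / 2) * num / denom
}

.diameter_cal_cache <- new.env(parent = emptyenv())

# Solve (meanlog, sdlog) so the truncated distribution hits the target
# post-truncation mean/SD by numerical moment matching.
.calibrate_diameter_model <- function(mean, sd, range) {
  key <- paste(mean, sd, range[1], range[2], sep = "|")
  hit <- .diameter_cal_cache[[key]]
  if (!is.null(hit)) return(hit)
  a <- range[1]; b <- range[2]
  obj <- function(p) {
    m1 <- .trunc_lnorm_moment(1, p[1], exp(p[2]), a, b)
    m2 <- .trunc_lnorm_moment(2, p[1], exp(p[2]), a, b)
    v <- m2 - m1^2
    if (!is.finite(m1) || !is.finite(v) || v <= 0) return(1e6)
    (m1 - mean)^2 + (sqrt(v) - sd)^2
  }
  # untruncated log-normal matching the targets as a start
  s0 <- sqrt(log(1 + (sd / mean)^2))
  m0 <- log(mean) - s0^2 / 2
  fit <- optim(c(m0, log(s0)), obj, method = "Nelder-Mead",
               control = list(maxit = 2000, reltol = 1e-14))
  if (fit$value > 1e-6)
    stop("diameter moment matching failed to converge", call. = FALSE)
  out <- list(meanlog = fit$par[1], sdlog = exp(fit$par[2]), a = a, b = b)
  .diameter_cal_cache[[key]] <- out
  out
}

.sample_diameters <- function(n, params) {
  cal <- .calibrate_diameter_model(params$diameter_mean, params$diameter_sd,
                                   params$diameter_range)
  pa <- plnorm(cal$a, cal$meanlog, cal$sdlog)
  pb <- plnorm(cal$b, cal$meanlog, cal$sdlog)
  qlnorm(runif(n, pa, pb), cal$meanlog, cal$sdlog)
}

# Brain ellipsoid geometry in world mm.
.brain_geometry <- function(params) {
  extent <- params$grid_shape * params$spacing
  centre <- (params$grid_shape - 1) * params$spacing / 2
  axes <- params$brain_axes_frac * extent
  list(centre = centre, axes = axes)
}

# Uniform centres inside the (margin-eroded) brain ellipsoid with a minimum
# pairwise separation; bounded rejection sampling.
.place_centres <- function(n, params, margins_mm, separate = TRUE,
                           max_tries = 500L) {
  geo <- .brain_geometry(params)
  out <- matrix(NA_real_, n, 3)
  if (n == 0L) return(out)
  for (i in seq_len(n)) {
    placed <- FALSE
    shrink <- pmax(geo$axes - margins_mm[i], geo$axes * 0.05)
    for (t in seq_len(max_tries)) {
      p <- geo$centre + runif(3, -1, 1) * shrink
      if (sum(((p - geo$centre) / shrink)^2) > 1) next
      if (separate && i > 1L) {
        d <- sqrt(colSums((t(out[seq_len(i - 1L), , drop = FALSE]) - p)^2))
        if (any(d < params$min_separation)) next
      }
      out[i, ] <- p
      placed <- TRUE
      break
    }
    if (!placed)
      stop("lesion placement failed after bounded retries ",
           "(grid too small for the requested count/separation)",
           call. = FALSE)
  }
  out
}

#' Sample a synthetic lesion population
#'
#' Draws lesion specifications (centre, diameter, contrast) from the phantom
#' model.  Diameters follow the truncated log-normal whose post-truncation
#' moments are numerically matched to the configured targets; centres are
#' uniform inside the brain ellipsoid.  With `separate = TRUE` the minimum
#' pairwise separation is enforced, which is the within-exam convention; for
#' large population draws (marginal statistics over many exams) use
#' `separate = FALSE`, the default, since a single brain cannot pack
#' thousands of separated lesions.
#'
#' @param params a [phantom_params].
#' @param count number of lesions to draw (>= 0).
#' @param seed integer RNG seed; identical seeds give identical populations.
#' @param separate enforce the within-exam minimum pairwise separation.
#' @return A data.frame with columns `lesion_id`, `x_mm`, `y_mm`, `z_mm`,
#'   `diameter_mm`, `contrast`.
#' @export
sample_lesion_population <- function(params, count, seed, separate = FALSE) {
  stopifnot(inherits(params, "phantom_params"))
  if (!is.numeric(count) || length(count) != 1L || is.na(count) || count < 0)
    stop("`count` must be a nonnegative integer", call. = FALSE)
  count <- as.integer(count)
  with_seed(seed, {
    d <- .sample_diameters(count, params)
    ctr <- .place_centres(count, params, margins_mm = d / 2 + 1,
                          separate = separate)
    data.frame(lesion_id = seq_len(count),
               x_mm = ctr[, 1], y_mm = ctr[, 2], z_mm = ctr[, 3],
               diameter_mm = d,
               contrast = runif(count, params$lesion_contrast[1],
                                params$lesion_contrast[2]))
  })
}

# ---- rendering ------------------------------------------------------------

# Squared normalized ellipsoid radius field (rho^2) on the grid.
.rho2_field <- function(params) {
  geo <- .brain_geometry(params)
  n <- params$grid_shape; s <- params$spacing
  ax <- ((seq_len(n[1]) - 1) * s[1] - geo$centre[1])^2 / geo$axes[1]^2
  ay <- ((seq_len(n[2]) - 1) * s[2] - geo$centre[2])^2 / geo$axes[2]^2
  az <- ((seq_len(n[3]) - 1) * s[3] - geo$centre[3])^2 / geo$axes[3]^2
  outer(outer(ax, ay, "+"), az, "+")
}

# Add `f(d2)` contributions in a local window around world point `p`;
# combine = "+" accumulates, "max" takes the voxelwise maximum.
.local_splat <- function(field, params, p, radius_mm, fun, combine = "+") {
  n <- params$grid_shape; s <- params$spacing
  lo <- pmax(1L, as.integer(floor((p - radius_mm) / s)) + 1L)
  hi <- pmin(n, as.integer(ceiling((p + radius_mm) / s)) + 1L)
  if (any(lo > hi)) return(field)
  ix <- lo[1]:hi[1]; iy <- lo[2]:hi[2]; iz <- lo[3]:hi[3]
  dx2 <- ((ix - 1) * s[1] - p[1])^2
  dy2 <- ((iy - 1) * s[2] - p[2])^2
  dz2 <- ((iz - 1) * s[3] - p[3])^2
  d2 <- outer(outer(dx2, dy2, "+"), dz2, "+")
  v <- fun(d2)
  if (combine == "+") field[ix, iy, iz] <- field[ix, iy, iz] + v
  else field[ix, iy, iz] <- pmax(field[ix, iy, iz], v)
  field
}

# Smooth brain background: base level, mild radial falloff, low-frequency
# texture bumps, soft ellipsoid edge.  Consumes RNG draws.
.render_background <- function(params) {
  rho2 <- .rho2_field(params)
  soft <- stats::plogis((1 - sqrt(rho2)) / 0.04)
  base <- params$background_level * (0.9 + 0.1 * pmax(1 - rho2, 0))
  geo <- .brain_geometry(params)
  n_bump <- 4L
  for (i in seq_len(n_bump)) {
    amp <- runif(1, -params$background_texture, params$background_texture)
    ctr <- geo$centre + runif(3, -0.6, 0.6) * geo$axes
    sig <- runif(1, 8, 16)
    base <- .local_splat(base, params, ctr, 3 * sig,
                         function(d2) amp * exp(-d2 / (2 * sig^2)))
  }
  list(volume = base * soft, soft = soft)
}

# Bright tubular vessel field (voxelwise max over tube profiles).
.render_vessels <- function(params) {
  n_v <- if (params$n_vessels[2] > params$n_vessels[1])
    sample(params$n_vessels[1]:params$n_vessels[2], 1L) else params$n_vessels[1]
  field <- array(0, params$grid_shape)
  if (n_v == 0L) return(field)
  geo <- .brain_geometry(params)
  for (v in seq_len(n_v)) {
    radius <- runif(1, params$vessel_radius[1], params$vessel_radius[2])
    amp <- runif(1, params$vessel_contrast[1], params$vessel_contrast[2])
    sig <- radius / sqrt(2 * log(2))  # half-maximum at the tube radius
    len <- runif(1, 25, 55)
    p <- geo$centre + runif(3, -0.7, 0.7) * geo$axes
    dir <- rnorm(3); dir <- dir / sqrt(sum(dir^2))
    step <- 0.5
    for (k in seq_len(ceiling(len / step))) {
      field <- .local_splat(field, params, p, 3 * sig,
                            function(d2) amp * exp(-d2 / (2 * sig^2)),
                            combine = "max")
      dir <- dir + 0.15 * rnorm(3)
      dir <- dir / sqrt(sum(dir^2))
      p <- p + step * dir
      if (sum(((p - geo$centre) / geo$axes)^2) > 0.9) break
    }
  }
  field
}

#' Render a synthetic exam volume
#'
#' Rasterizes one exam: smooth ellipsoidal brain background, bright tubular
#' vessel distractors, soft-edged hyperintense spherical lesions, and
#' Rician-like noise (magnitude of a complex Gaussian).  Two sub-seeds are
#' derived from `seed` and logged on the exam: a structure seed (background,
#' vessels) and a noise seed, so structure can be held fixed across noise
#' realizations.
#'
#' @param lesions data.frame as returned by [sample_lesion_population()]
#'   (may have zero rows).
#' @param params a [phantom_params].
#' @param seed integer RNG seed.
#' @param exam_id,patient_id identifiers attached to the exam.
#' @param labeled logical flag: is this exam part of the labeled arm?
#' @return An object of class `nsbm_exam`: list with `exam_id`,
#'   `patient_id`, `volume` ([volume3d]), `annotations`, `labeled`, `seeds`.
#' @export
render_phantom <- function(lesions, params, seed, exam_id = "exam-001",
                           patient_id = "patient-001", labeled = TRUE) {
  stopifnot(inherits(params, "phantom_params"))
  extent <- (params$grid_shape - 1) * params$spacing
  if (nrow(lesions) > 0) {
    ctr <- as.matrix(lesions[, c("x_mm", "y_mm", "z_mm")])
    if (any(ctr < 0) || any(sweep(ctr, 2L, extent, ">")))
      stop("lesion centre outside the volume extent", call. = FALSE)
  }
  seeds <- with_seed(seed, c(structure = next_seed(), noise = next_seed()))
  vol <- with_seed(seeds["structure"], {
    bg <- .render_background(params)
    ves <- .render_vessels(params)
    v <- bg$volume + ves * bg$soft
    if (nrow(lesions) > 0) {
      les <- array(0, params$grid_shape)
      for (i in seq_len(nrow(lesions))) {
        R <- lesions$diameter_mm[i] / 2
        cc <- lesions$contrast[i]
        p <- c(lesions$x_mm[i], lesions$y_mm[i], lesions$z_mm[i])
        les <- .local_splat(les, params, p, R + 2,
                            function(d2) cc * stats::plogis((R - sqrt(d2)) / 0.35))
      }
      v <- v + les * bg$soft
    }
    v
  })
  if (params$noise_sigma > 0) {
    vol <- with_seed(seeds["noise"], {
      n <- length(vol)
      sqrt((vol + rnorm(n, 0, params$noise_sigma))^2 +
             rnorm(n, 0, params$noise_sigma)^2)
    })
    dim(vol) <- params$grid_shape
  }
  ann <- lesions
  if (nrow(ann) > 0) ann$lesion_id <- seq_len(nrow(ann))
  structure(list(exam_id = exam_id, patient_id = patient_id,
                 volume = volume3d(vol, params$spacing, c(0, 0, 0)),
                 annotations = ann, labeled = labeled, seeds = seeds),
            class = "nsbm_exam")
}

#' @export
print.nsbm_exam <- function(x, ...) {
  cat(sprintf("<nsbm_exam> %s (patient %s, %s): %d lesion(s)%s\n",
              x$exam_id, x$patient_id,
              if (x$labeled) "labeled" else "unlabeled",
              nrow(x$annotations),
              if (is.null(x$volume)) ", volume not rendered" else ""))
  invisible(x)
}

#' Generate a synthetic labeled/unlabeled cohort
#'
#' Builds a two-arm cohort from patient multiplicity tables: a named vector
#' `c("1" = 113, "2" = 33, ...)` meaning 113 patients with one exam, 33 with
#' two, and so on.  Patient identifier sets of the two arms are disjoint.
#' Ground-truth lesions are generated per exam (repeated exams of one
#' patient draw fresh lesions) and retained on unlabeled exams for
#' evaluation, but those exams are flagged unlabeled so training never sees
#' their annotations.
#'
#' @param labeled,unlabeled named nonnegative integer vectors:
#'   exams-per-patient -> patient count.  Either may be empty (`NULL`).
#' @param params a [phantom_params].
#' @param seed integer master seed; every exam derives its own sub-seed.
#' @param render rasterize volumes (`TRUE`) or generate structure only
#'   (`FALSE`; fast, for cohort-level bookkeeping).
#' @return An object of class `nsbm_cohort` with elements `labeled` and
#'   `unlabeled` (lists of `nsbm_exam`), plus `params` and `seed`.
#' @export
generate_cohort <- function(labeled = NULL, unlabeled = NULL, params, seed,
                            render = TRUE) {
  stopifnot(inherits(params, "phantom_params"))
  check_mult <- function(m) {
    if (is.null(m) || length(m) == 0L) return(invisible())
    if (is.null(names(m)) || any(is.na(suppressWarnings(as.integer(names(m))))))
      stop("multiplicity tables must be named by exams-per-patient",
           call. = FALSE)
    if (any(m < 0)) stop("multiplicity counts must be >= 0", call. = FALSE)
  }
  check_mult(labeled); check_mult(unlabeled)
  make_arm <- function(mult, prefix, is_labeled) {
    if (is.null(mult) || length(mult) == 0L) return(list())
    per_patient <- rep(as.integer(names(mult)), times = as.integer(mult))
    exams <- list()
    for (pi in seq_along(per_patient)) {
      pid <- sprintf("%s%04d", prefix, pi)
      for (ei in seq_len(per_patient[pi])) {
        eid <- sprintf("%s-e%d", pid, ei)
        exam_seed <- next_seed()
        n_les <- rpois(1L, params$lesion_rate)
        lesions <- sample_lesion_population(params, n_les, seed = next_seed(),
                                            separate = TRUE)
        ex <- if (render)
          render_phantom(lesions, params, seed = exam_seed, exam_id = eid,
                         patient_id = pid, labeled = is_labeled)
        else
          structure(list(exam_id = eid, patient_id = pid, volume = NULL,
                         annotations = lesions, labeled = is_labeled,
                         seeds = c(structure = exam_seed, noise = NA)),
                    class = "nsbm_exam")
        exams[[eid]] <- ex
      }
    }
    exams
  }
  cohort <- with_seed(seed, {
    lab <- make_arm(labeled, "LP", TRUE)
    unl <- make_arm(unlabeled, "UP", FALSE)
    list(labeled = lab, unlabeled = unl)
  })
  pl <- unique(vapply(cohort$labeled, `[[`, "", "patient_id"))
  pu <- unique(vapply(cohort$unlabeled, `[[`, "", "patient_id"))
  if (length(intersect(pl, pu)) > 0)
    stop("labeled and unlabeled patient id sets overlap", call. = FALSE)
  structure(list(labeled = cohort$labeled, unlabeled = cohort$unlabeled,
                 params = params, seed = seed),
            class = "nsbm_cohort")
}

#' @export
print.nsbm_cohort <- function(x, ...) {
  cat(sprintf("<nsbm_cohort> %d labeled / %d unlabeled exams\n",
              length(x$labeled), length(x$unlabeled)))
  invisible(x)
}

#' Write a cohort to disk
#'
#' Writes each rendered exam as NIfTI (`<exam_id>.nii.gz`), all annotations
#' as one CSV (`annotations.csv` with header
#' `exam_id,patient_id,lesion_id,x_mm,y_mm,z_mm,diameter_mm`), and a
#' tab-separated `manifest.tsv` listing exam ids, patient ids, labeled
#' flags and seeds.  Unlabeled exams' annotations are withheld from the CSV.
#'
#' @param cohort an `nsbm_cohort` (rendered).
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "nsbm_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  all_exams <- c(cohort$labeled, cohort$unlabeled)
  ann_rows <- list()
  man_rows <- list()
  for (ex in all_exams) {
    if (is.null(ex$volume))
      stop("cohort was generated with render = FALSE; nothing to write",
           call. = FALSE)
    write_volume(ex$volume, file.path(dir, paste0(ex$exam_id, ".nii.gz")))
    if (ex$labeled && nrow(ex$annotations) > 0)
      ann_rows[[ex$exam_id]] <- data.frame(
        exam_id = ex$exam_id, patient_id = ex$patient_id,
        lesion_id = ex$annotations$lesion_id,
        x_mm = ex$annotations$x_mm, y_mm = ex$annotations$y_mm,
        z_mm = ex$annotations$z_mm,
        diameter_mm = ex$annotations$diameter_mm)
    man_rows[[ex$exam_id]] <- data.frame(
      exam_id = ex$exam_id, patient_id = ex$patient_id,
      labeled = ex$labeled, structure_seed = ex$seeds[["structure"]],
      noise_seed = ex$seeds[["noise"]])
  }
  ann <- if (length(ann_rows)) do.call(rbind, ann_rows) else
    data.frame(exam_id = character(), patient_id = character(),
               lesion_id = integer(), x_mm = numeric(), y_mm = numeric(),
               z_mm = numeric(), diameter_mm = numeric())
  write.csv(ann, file.path(dir, "annotations.csv"), row.names = FALSE)
  man <- do.call(rbind, man_rows)
  utils::write.table(man, file.path(dir, "manifest.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(dir)
}
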