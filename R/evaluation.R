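# Detection-level evaluation: thresholded detection with NMS, 1.5 mm
# matching, FROC/AFP curves, patient-level cross-validation and the
# hyperparameter sweep driver.

#' Score an exam's candidates with a classifier
#'
#' Detects candidates on the exam, extracts their patches and attaches the
#' classifier response to each, after 1.5 mm non-maximum suppression
#' (keeping the highest-response member of any cluster).
#'
#' @param exam an `nsbm_exam`.
#' @param model a `cropnet` classifier.
#' @param cand_config a [candidate_config()].
#' @param nms_mm response-level NMS radius in mm.
#' @param candidates optional precomputed candidate table for this exam.
#' @return data.frame `exam_id, x_mm, y_mm, z_mm, response`.
#' @export
score_exam <- function(exam, model, cand_config = candidate_config(),
                       nms_mm = 1.5, candidates = NULL) {
  vol <- prepare_exam_volume(exam)
  cands <- if (is.null(candidates)) detect_candidates(vol, cand_config)
           else candidates
  out <- data.frame(exam_id = character(), x_mm = numeric(),
                    y_mm = numeric(), z_mm = numeric(),
                    response = numeric())
  if (nrow(cands) == 0L) return(out)
  edge <- model$spec$roi_mm
  x <- vapply(seq_len(nrow(cands)), function(i)
    as.numeric(extract_roi(vol, c(cands$x_mm[i], cands$y_mm[i],
                                  cands$z_mm[i]), edge)),
    numeric(edge^3))
  resp <- forward(model, matrix(x, nrow = edge^3))
  centres <- as.matrix(cands[, c("x_mm", "y_mm", "z_mm")])
  ord <- order(-resp, centres[, 1], centres[, 2], centres[, 3])
  keep <- ord[.nms(centres[ord, , drop = FALSE], nms_mm, Inf)]
  data.frame(exam_id = exam$exam_id, x_mm = centres[keep, 1],
             y_mm = centres[keep, 2], z_mm = centres[keep, 3],
             response = resp[keep])
}

#' Threshold detections for one exam
#'
#' Keeps scored candidates with `response > threshold` (strict), after
#' non-maximum suppression at `nms_mm` retaining the highest-response
#' member of each cluster.
#'
#' @param exam an `nsbm_exam`.
#' @param model a `cropnet` classifier.
#' @param candidates candidate table for the exam (from
#'   [detect_candidates()]).
#' @param threshold response threshold.
#' @param cand_config a [candidate_config()] (used only if `candidates` is
#'   `NULL`).
#' @param nms_mm NMS radius in mm.
#' @return data.frame of surviving detections.
#' @export
detect_bm <- function(exam, model, candidates = NULL, threshold = 0.5,
                      cand_config = candidate_config(), nms_mm = 1.5) {
  scored <- score_exam(exam, model, cand_config, nms_mm,
                       candidates = candidates)
  scored[scored$response > threshold, , drop = FALSE]
}

#' Match detections to annotated lesions
#'
#' A lesion counts as detected iff at least one detection lies within `tol`
#' mm (inclusive) of its centre; a detection is a false positive iff it is
#' within `tol` of no lesion.  Multiple detections of one lesion count the
#' lesion once and are not false positives.
#'
#' @param dets detection data.frame (`x_mm, y_mm, z_mm`, optionally
#'   `response`).
#' @param annotations lesion data.frame with `lesion_id` and centre columns.
#' @param tol matching tolerance in mm (default 1.5, inclusive).
#' @return List: `detected_lesions` (lesion ids), `false_positives`
#'   (detection rows), `n_tp` and `matched` (per-detection lesion id or
#'   `NA`).
#' @export
match_detections <- function(dets, annotations, tol = 1.5) {
  stopifnot(tol > 0)
  nl <- if (is.null(annotations)) 0L else nrow(annotations)
  nd <- nrow(dets)
  if (nd == 0L)
    return(list(detected_lesions = character(0),
                false_positives = dets, n_tp = 0L,
                matched = integer(0)))
  if (nl == 0L)
    return(list(detected_lesions = character(0), false_positives = dets,
                n_tp = 0L, matched = rep(NA_integer_, nd)))
  dc <- as.matrix(dets[, c("x_mm", "y_mm", "z_mm")])
  ac <- as.matrix(annotations[, c("x_mm", "y_mm", "z_mm")])
  matched <- rep(NA_integer_, nd)
  hit <- logical(nl)
  for (i in seq_len(nd)) {
    d <- sqrt(colSums((t(ac) - dc[i, ])^2))
    within <- d <= tol
    if (any(within)) {
      # a detection detects every lesion within tolerance (set semantics);
      # `matched` reports the nearest one
      matched[i] <- annotations$lesion_id[which.min(d)]
      hit[within] <- TRUE
    }
  }
  list(detected_lesions = annotations$lesion_id[hit],
       false_positives = dets[is.na(matched), , drop = FALSE],
       n_tp = sum(hit), matched = matched)
}

#' FROC curve over a set of exams
#'
#' Sweeps the detection threshold over all observed responses and records,
#' at each operating point, the pooled lesion sensitivity
#' (detected lesions / total lesions, strict `response > t`) and the
#' average false positives per exam (AFP; the denominator counts every
#' exam, including lesion-free ones).  Scored candidates are NMS-reduced
#' once at `tol` before the sweep.
#'
#' @param exam_scores list with one element per exam:
#'   `list(detections = <scored data.frame>, annotations = <lesion df>)`.
#' @param tol matching tolerance in mm.
#' @return An object of class `froc_curve`: data.frame
#'   `threshold, sensitivity, afp` (threshold increasing) with attributes
#'   `n_exams` and `n_lesions`.
#' @export
froc <- function(exam_scores, tol = 1.5) {
  n_exams <- length(exam_scores)
  stopifnot(n_exams >= 1L)
  lesion_max <- numeric(0)
  fp_resp <- numeric(0)
  n_lesions <- 0L
  for (es in exam_scores) {
    dets <- es$detections
    ann <- es$annotations
    nl <- if (is.null(ann)) 0L else nrow(ann)
    n_lesions <- n_lesions + nl
    if (nl > 0) lm <- rep(-Inf, nl)
    matched_any <- rep(FALSE, nrow(dets))
    if (nrow(dets) > 0 && nl > 0) {
      dc <- as.matrix(dets[, c("x_mm", "y_mm", "z_mm")])
      ac <- as.matrix(ann[, c("x_mm", "y_mm", "z_mm")])
      for (i in seq_len(nrow(dets))) {
        d2 <- colSums((t(ac) - dc[i, ])^2)
        within <- d2 <= tol^2
        if (any(within)) {
          matched_any[i] <- TRUE
          lm[within] <- pmax(lm[within], dets$response[i])
        }
      }
    }
    if (nl > 0) lesion_max <- c(lesion_max, lm)
    if (nrow(dets) > 0)
      fp_resp <- c(fp_resp, dets$response[!matched_any])
  }
  if (n_lesions == 0L)
    stop("FROC undefined: no lesions in the evaluation set", call. = FALSE)
  thresholds <- sort(unique(c(lesion_max[is.finite(lesion_max)], fp_resp)))
  if (length(thresholds) == 0L) thresholds <- 0.5
  # operating point just below each observed response, plus one above all
  tgrid <- sort(unique(c(thresholds - 1e-12, max(thresholds) + 1e-12)))
  sens <- vapply(tgrid, function(t) sum(lesion_max > t) / n_lesions, 0)
  afp <- vapply(tgrid, function(t) sum(fp_resp > t) / n_exams, 0)
  out <- data.frame(threshold = tgrid, sensitivity = sens, afp = afp)
  structure(out, class = c("froc_curve", "data.frame"),
            n_exams = n_exams, n_lesions = n_lesions)
}

#' AFP at a requested sensitivity
#'
#' Reads the false-positive cost of reaching sensitivity `s` off a FROC
#' curve: the AFP of the first operating point (in increasing-sensitivity
#' order) whose sensitivity reaches `s`, with optional linear interpolation
#' between the straddling points.
#'
#' @param curve a [froc()] curve.
#' @param s requested sensitivity fraction.
#' @param interpolate linearly interpolate between operating points.
#' @return AFP scalar.
#' @export
afp_at_sensitivity <- function(curve, s, interpolate = TRUE) {
  stopifnot(inherits(curve, "froc_curve"))
  o <- order(curve$sensitivity, curve$afp)
  sens <- curve$sensitivity[o]
  afp <- curve$afp[o]
  # several thresholds can share a sensitivity (false positives dropping
  # with no new lesion found); the operating point at that sensitivity is
  # the cheapest one
  keep <- !duplicated(sens)
  sens <- sens[keep]
  afp <- afp[keep]
  if (s > max(sens) + 1e-12)
    stop(sprintf("sensitivity %.3f not achievable (max %.3f)", s,
                 max(sens)), call. = FALSE)
  i <- which(sens >= s - 1e-12)[1]
  if (!interpolate || i == 1L || abs(sens[i] - s) < 1e-12)
    return(afp[i])
  s0 <- sens[i - 1L]; s1 <- sens[i]
  if (s1 <= s0) return(afp[i])
  w <- (s - s0) / (s1 - s0)
  (1 - w) * afp[i - 1L] + w * afp[i]
}

#' Patient-level cross-validation folds
#'
#' Assigns exams to `folds` bins such that all exams of one patient share a
#' bin and patient counts per bin differ by at most one.
#'
#' @param exams list of `nsbm_exam` objects.
#' @param folds number of folds (>= 2).
#' @param seed integer RNG seed.
#' @return Named integer vector (exam id -> fold) with attribute
#'   `patient_folds`.
#' @export
split_cv_by_patient <- function(exams, folds = 2L, seed = 1L) {
  folds <- as.integer(folds)
  if (folds < 2L) stop("`folds` must be >= 2", call. = FALSE)
  pids <- vapply(exams, `[[`, "", "patient_id")
  eids <- vapply(exams, `[[`, "", "exam_id")
  patients <- unique(pids)
  if (length(patients) < folds)
    stop("fewer patients than folds", call. = FALSE)
  pf <- with_seed(seed, {
    shuffled <- sample(patients)
    setNames(rep(seq_len(folds), length.out = length(shuffled)), shuffled)
  })
  out <- setNames(unname(pf[pids]), eids)
  attr(out, "patient_folds") <- pf
  out
}

# Evaluate teacher/student models on held-out exams -> FROC curve.
evaluate_models_froc <- function(exams, model, cand_config, tol = 1.5,
                                 candidates = NULL) {
  scores <- lapply(seq_along(exams), function(i) {
    ex <- exams[[i]]
    cands <- if (is.null(candidates)) NULL else candidates[[ex$exam_id]]
    list(detections = score_exam(ex, model, cand_config, nms_mm = tol,
                                 candidates = cands),
         annotations = ex$annotations)
  })
  froc(scores, tol = tol)
}

# Interpolate a fold curve onto a shared sensitivity grid (AFP as a
# function of sensitivity; constant extrapolation at the ends).
.curve_on_grid <- function(curve, grid) {
  o <- order(curve$sensitivity)
  s <- curve$sensitivity[o]; a <- curve$afp[o]
  ok <- !duplicated(s)
  s <- s[ok]; a <- a[ok]
  if (length(s) == 1L) return(rep(a, length(grid)))
  approx(s, a, xout = pmin(pmax(grid, min(s)), max(s)), ties = "ordered")$y
}

#' Run a hyperparameter sweep experiment
#'
#' Desk-scale analogue of the framework's validation studies: for every
#' cell of the grid over target sensitivity `ts`, unlabeled-loss weight
#' `lambda`, student `iterations` and `labeled_fraction`, runs patient-level
#' cross-validated noisy-student training and reports teacher/student AFP
#' at the requested sensitivities plus mean FROC curves on a shared
#' sensitivity grid.
#'
#' @param cohort an `nsbm_cohort` with rendered volumes.
#' @param teacher_spec,student_spec [cropnet_spec()]s.
#' @param ts,lambda,iterations,labeled_fraction sweep vectors.
#' @param folds number of patient-level CV folds.
#' @param config a [training_config()].
#' @param cand_config a [candidate_config()].
#' @param noise a [noise_config()].
#' @param afp_at sensitivities at which AFP is tabulated.
#' @param sens_grid shared sensitivity grid for mean curves.
#' @param max_unlabeled_candidates per-exam cap on pseudo-labeled patches.
#' @param seed integer master seed.
#' @return An object of class `nsbm_report`: per-cell fold curves, mean
#'   curves and AFP tables, plus the configuration snapshot.
#' @export
run_experiment <- function(cohort, teacher_spec, student_spec,
                           ts = 0.90, lambda = 1, iterations = 1L,
                           labeled_fraction = 1, folds = 2L,
                           config = training_config(),
                           cand_config = candidate_config(),
                           noise = noise_config(),
                           afp_at = c(0.80, 0.85, 0.90),
                           sens_grid = seq(0.50, 1.00, by = 0.01),
                           max_unlabeled_candidates = 100L,
                           seed = 1L) {
  stopifnot(inherits(cohort, "nsbm_cohort"))
  grid <- expand.grid(ts = ts, lambda = lambda, iterations = iterations,
                      labeled_fraction = labeled_fraction,
                      KEEP.OUT.ATTRS = FALSE)
  fold_of <- split_cv_by_patient(cohort$labeled, folds, seed = seed)
  cells <- vector("list", nrow(grid))
  for (ci in seq_len(nrow(grid))) {
    g <- grid[ci, ]
    fold_results <- list()
    for (f in seq_len(folds)) {
      train_ex <- cohort$labeled[fold_of != f]
      test_ex <- cohort$labeled[fold_of == f]
      if (g$labeled_fraction < 1) {
        tp <- unique(vapply(train_ex, `[[`, "", "patient_id"))
        keep_p <- with_seed(seed + 1000L * ci + f, {
          sample(tp, max(1L, round(g$labeled_fraction * length(tp))))
        })
        train_ex <- Filter(function(e) e$patient_id %in% keep_p, train_ex)
      }
      fit <- ns_loop(train_ex, cohort$unlabeled, teacher_spec, student_spec,
                     ts = g$ts, lambda = g$lambda,
                     iterations = g$iterations, config = config,
                     cand_config = cand_config, noise = noise,
                     max_unlabeled_candidates = max_unlabeled_candidates)
      crv_t <- evaluate_models_froc(test_ex, fit$teacher, cand_config)
      crv_s <- evaluate_models_froc(test_ex, fit$model, cand_config)
      afp_tab <- data.frame(
        sensitivity = afp_at,
        teacher = vapply(afp_at, function(s)
          tryCatch(afp_at_sensitivity(crv_t, s), error = function(e) NA_real_),
          0),
        student = vapply(afp_at, function(s)
          tryCatch(afp_at_sensitivity(crv_s, s), error = function(e) NA_real_),
          0))
      fold_results[[f]] <- list(fold = f, teacher_curve = crv_t,
                                student_curve = crv_s, afp = afp_tab,
                                mu = fit$history[[length(fit$history)]]$mu)
    }
    mean_teacher <- rowMeans(vapply(fold_results, function(fr)
      .curve_on_grid(fr$teacher_curve, sens_grid), numeric(length(sens_grid))))
    mean_student <- rowMeans(vapply(fold_results, function(fr)
      .curve_on_grid(fr$student_curve, sens_grid), numeric(length(sens_grid))))
    cells[[ci]] <- list(config = as.list(g), folds = fold_results,
                        mean_curves = data.frame(
                          sensitivity = sens_grid, teacher = mean_teacher,
                          student = mean_student),
                        afp = Reduce(function(a, b)
                          data.frame(sensitivity = a$sensitivity,
                                     teacher = (a$teacher + b$teacher) / 2,
                                     student = (a$student + b$student) / 2),
                          lapply(fold_results, `[[`, "afp")))
  }
  structure(list(grid = grid, cells = cells, seed = seed,
                 afp_at = afp_at),
            class = "nsbm_report")
}

#' @export
print.nsbm_report <- function(x, ...) {
  cat(sprintf("<nsbm_report> %d configuration cell(s)\n", nrow(x$grid)))
  for (ci in seq_along(x$cells)) {
    g <- x$grid[ci, ]
    cat(sprintf("  ts = %.2f, lambda = %.2f, iter = %d, labeled = %.0f%%\n",
                g$ts, g$lambda, g$iterations, 100 * g$labeled_fraction))
    print(x$cells[[ci]]$afp, row.names = FALSE)
  }
  invisible(x)
}
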