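# Exam-level plumbing that connects candidate detection to classifier
# training: per-exam preprocessing, labeled/unlabeled ROI pool assembly and
# the iterative noisy-student loop.

# Preprocess an exam volume to the 1 mm normalized grid the detector and
# classifier assume.  The upper anchor is the volume maximum (p_high = 100)
# rather than the volume_io default of 99: enhancing structures (lesions
# and vessels) are exactly the signal of interest, and on desk-scale
# phantom grids even a single large lesion exceeds any percentile clip
# budget — upper clipping flattens lesion cores and destroys their blob
# response.  The robust lower anchor (p1 -> 0) is kept.
prepare_exam_volume <- function(exam, p_low = 1, p_high = 100) {
  vol <- exam$volume
  if (is.null(vol)) stop("exam has no rendered volume", call. = FALSE)
  if (any(vol$spacing != 1)) vol <- resample_isotropic(vol, 1)
  normalize_intensity(vol, p_low, p_high)
}

# Globally unique lesion key within a cohort.
.lesion_uid <- function(exam_id, lesion_id) paste0(exam_id, ":", lesion_id)

#' Build labeled training ROI pools from exams
#'
#' Runs candidate detection on each labeled exam, labels candidates against
#' the exam's annotations (1.5 mm rule), and assembles the classifier
#' training set: positives are the matched candidates plus the annotation
#' centres themselves (so lesions the detector under-captures still
#' contribute positive patches); negatives are the unmatched candidates.
#'
#' @param exams list of labeled `nsbm_exam` objects.
#' @param cand_config a [candidate_config()].
#' @param edge ROI edge in mm/voxels.
#' @param tol matching tolerance in mm.
#' @return A list with `rois` (a labeled [roi_set()]; `meta` records exam,
#'   centre, matched lesion uid and source kind), `lesions` (data.frame of
#'   all lesion uids) and `candidates` (per-exam candidate tables).
#' @export
build_labeled_rois <- function(exams, cand_config = candidate_config(),
                               edge = 16L, tol = 1.5) {
  xs <- list(); meta <- list(); lesions <- list(); cand_tabs <- list()
  for (ex in exams) {
    vol <- prepare_exam_volume(ex)
    cands <- detect_candidates(vol, cand_config)
    ann <- ex$annotations
    cands <- label_candidates(cands, ann, tol = tol)
    cand_tabs[[ex$exam_id]] <- cands
    if (!is.null(ann) && nrow(ann) > 0)
      lesions[[ex$exam_id]] <- data.frame(
        lesion_uid = .lesion_uid(ex$exam_id, ann$lesion_id),
        exam_id = ex$exam_id)
    take <- function(center, label, source, lesion_uid) {
      roi <- extract_roi(vol, center, edge)
      xs[[length(xs) + 1L]] <<- as.numeric(roi)
      meta[[length(meta) + 1L]] <<- data.frame(
        exam_id = ex$exam_id, x_mm = center[1], y_mm = center[2],
        z_mm = center[3], label = label, source = source,
        lesion_uid = lesion_uid)
    }
    if (nrow(cands) > 0)
      for (i in seq_len(nrow(cands))) {
        uid <- if (cands$label[i] == 1L)
          .lesion_uid(ex$exam_id, cands$matched_lesion[i]) else NA_character_
        take(c(cands$x_mm[i], cands$y_mm[i], cands$z_mm[i]),
             cands$label[i], "candidate", uid)
      }
    if (!is.null(ann) && nrow(ann) > 0)
      for (i in seq_len(nrow(ann)))
        take(c(ann$x_mm[i], ann$y_mm[i], ann$z_mm[i]), 1L, "annotation",
             .lesion_uid(ex$exam_id, ann$lesion_id[i]))
  }
  meta <- if (length(meta)) do.call(rbind, meta) else
    data.frame(exam_id = character(), x_mm = numeric(), y_mm = numeric(),
               z_mm = numeric(), label = integer(), source = character(),
               lesion_uid = character())
  x <- if (length(xs)) matrix(unlist(xs), ncol = length(xs)) else
    matrix(numeric(), edge^3, 0)
  list(rois = roi_set(x, y = meta$label, meta = meta, edge = edge),
       lesions = if (length(lesions)) do.call(rbind, lesions) else
         data.frame(lesion_uid = character(), exam_id = character()),
       candidates = cand_tabs)
}

#' Build unlabeled ROI pools from exams
#'
#' Detects candidates on each unlabeled exam and extracts the top
#' `max_per_exam` (by rank) as classifier patches for pseudo-labeling.
#' Ground-truth annotations on the exams, if present, are ignored.
#'
#' @param exams list of unlabeled `nsbm_exam` objects.
#' @param cand_config a [candidate_config()].
#' @param edge ROI edge in mm/voxels.
#' @param max_per_exam per-exam cap on extracted candidates.
#' @return An unlabeled [roi_set()].
#' @export
build_unlabeled_rois <- function(exams, cand_config = candidate_config(),
                                 edge = 16L, max_per_exam = Inf) {
  xs <- list(); meta <- list()
  for (ex in exams) {
    vol <- prepare_exam_volume(ex)
    cands <- detect_candidates(vol, cand_config)
    if (nrow(cands) > max_per_exam) cands <- cands[seq_len(max_per_exam), ]
    for (i in seq_len(nrow(cands))) {
      roi <- extract_roi(vol, c(cands$x_mm[i], cands$y_mm[i],
                                cands$z_mm[i]), edge)
      xs[[length(xs) + 1L]] <- as.numeric(roi)
      meta[[length(meta) + 1L]] <- data.frame(
        exam_id = ex$exam_id, x_mm = cands$x_mm[i], y_mm = cands$y_mm[i],
        z_mm = cands$z_mm[i])
    }
  }
  meta <- if (length(meta)) do.call(rbind, meta) else
    data.frame(exam_id = character(), x_mm = numeric(), y_mm = numeric(),
               z_mm = numeric())
  x <- if (length(xs)) matrix(unlist(xs), ncol = length(xs)) else
    matrix(numeric(), edge^3, 0)
  roi_set(x, y = NULL, meta = meta, edge = edge)
}

# Per-lesion maximum model responses over matched candidate patches; lesions
# without a matched candidate get -Inf (never detected by the pipeline).
lesion_max_responses <- function(model, labeled) {
  rois <- labeled$rois
  is_cand_pos <- rois$meta$source == "candidate" & rois$meta$label == 1L
  uids <- labeled$lesions$lesion_uid
  maxima <- setNames(rep(-Inf, length(uids)), uids)
  if (any(is_cand_pos)) {
    resp <- forward(model, rois$x[, is_cand_pos, drop = FALSE])
    agg <- tapply(resp, rois$meta$lesion_uid[is_cand_pos], max)
    maxima[names(agg)] <- agg
  }
  maxima
}

#' Iterative noisy-student training
#'
#' The full semi-supervised loop.  Iteration 1 trains the teacher spec on
#' the labeled pools, calibrates the pseudo-labeling threshold mu so the
#' teacher reaches the target training sensitivity `ts`, pseudo-labels the
#' unlabeled candidate patches and trains the student spec on both pools
#' with unlabeled-loss weight `lambda`.  Each further iteration promotes the
#' previous student to teacher (re-calibrating mu and regenerating
#' pseudo-labels) and trains a fresh student of the student spec.
#'
#' @param labeled_exams,unlabeled_exams lists of `nsbm_exam` objects.
#' @param teacher_spec,student_spec [cropnet_spec()]s; the student capacity
#'   should meet or exceed the teacher's.
#' @param ts target training sensitivity for threshold calibration.
#' @param lambda weight of the pseudo-labeled loss term.
#' @param iterations number of student iterations (>= 1; 1 is the default
#'   setup).
#' @param config a [training_config()] (its `lambda` field is overridden by
#'   the `lambda` argument).
#' @param cand_config a [candidate_config()].
#' @param noise a [noise_config()].
#' @param max_unlabeled_candidates per-exam cap on pseudo-labeled patches.
#' @param tol matching tolerance in mm.
#' @return An object of class `nsbm_ns_fit`: final student `model`, the
#'   initial `teacher`, `history` (per-iteration mu, achieved sensitivity,
#'   pseudo-label counts, training losses), and `pseudo_table` (the final
#'   iteration's per-patch pseudo-label table).
#' @export
ns_loop <- function(labeled_exams, unlabeled_exams, teacher_spec,
                    student_spec, ts = 0.90, lambda = 1, iterations = 1L,
                    config = training_config(),
                    cand_config = candidate_config(),
                    noise = noise_config(),
                    max_unlabeled_candidates = 100L, tol = 1.5) {
  stopifnot(iterations >= 1L)
  config$lambda <- lambda
  labeled <- build_labeled_rois(labeled_exams, cand_config,
                                edge = teacher_spec$roi_mm, tol = tol)
  unlabeled <- build_unlabeled_rois(unlabeled_exams, cand_config,
                                    edge = teacher_spec$roi_mm,
                                    max_per_exam = max_unlabeled_candidates)
  teacher <- train_teacher(labeled$rois, teacher_spec, config, noise)
  current <- teacher
  history <- list()
  for (it in seq_len(iterations)) {
    if (length(unlabeled_exams) == 0L && lambda == 0) {
      student <- train_student(labeled$rois, NULL, student_spec, config,
                               noise)
      history[[it]] <- list(mu = NA_real_, achieved = NA_real_,
                            n_pseudo_pos = 0L, n_pseudo = 0L,
                            final_loss = utils::tail(student$log$loss, 1))
      current <- student
      next
    }
    maxima <- lesion_max_responses(current, labeled)
    cal <- calibrate_mu(sensitivity_curve(maxima), ts)
    ps <- pseudo_label(current, unlabeled, cal$mu)
    student <- train_student(labeled$rois, ps, student_spec, config, noise)
    history[[it]] <- list(mu = cal$mu, achieved = cal$achieved,
                          n_pseudo_pos = sum(ps$labels),
                          n_pseudo = length(ps$labels),
                          final_loss = utils::tail(student$log$loss, 1))
    current <- student
    last_ps <- ps
  }
  pseudo_table <- if (exists("last_ps", inherits = FALSE) &&
                      !is.null(last_ps$meta))
    cbind(last_ps$meta, response = last_ps$responses,
          pseudo_label = last_ps$labels)
  else NULL
  structure(list(model = current, teacher = teacher, history = history,
                 ts = ts, lambda = lambda, iterations = iterations,
                 labeled = labeled, unlabeled_n = ncol(unlabeled$x),
                 pseudo_table = pseudo_table),
            class = "nsbm_ns_fit")
}

#' @export
print.nsbm_ns_fit <- function(x, ...) {
  cat(sprintf(paste0("<nsbm_ns_fit> %d student iteration(s), ts = %.2f, ",
                     "lambda = %.2f\n"), x$iterations, x$ts, x$lambda))
  for (i in seq_along(x$history)) {
    h <- x$history[[i]]
    cat(sprintf("  iter %d: mu = %.4f, %d/%d pseudo-positives\n", i,
                h$mu, h$n_pseudo_pos, h$n_pseudo))
  }
  invisible(x)
}
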