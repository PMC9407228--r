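# Brute-force FROC oracle: re-evaluates matching at every threshold from
# scratch (O(T * detections * lesions)).
oracle_froc <- function(exam_scores, thresholds, tol = 1.5) {
  n_exams <- length(exam_scores)
  n_lesions <- sum(vapply(exam_scores, function(e)
    if (is.null(e$annotations)) 0L else nrow(e$annotations), 0L))
  t(vapply(thresholds, function(t) {
    tp <- 0; fp <- 0
    for (e in exam_scores) {
      d <- e$detections[e$detections$response > t, , drop = FALSE]
      ann <- e$annotations
      if (!is.null(ann) && nrow(ann) > 0) {
        for (i in seq_len(nrow(ann))) {
          dd <- sqrt((d$x_mm - ann$x_mm[i])^2 + (d$y_mm - ann$y_mm[i])^2 +
                       (d$z_mm - ann$z_mm[i])^2)
          if (length(dd) > 0 && any(dd <= tol)) tp <- tp + 1
        }
      }
      if (nrow(d) > 0) {
        for (j in seq_len(nrow(d))) {
          if (is.null(ann) || nrow(ann) == 0) { fp <- fp + 1; next }
          dd <- sqrt((ann$x_mm - d$x_mm[j])^2 + (ann$y_mm - d$y_mm[j])^2 +
                       (ann$z_mm - d$z_mm[j])^2)
          if (all(dd > tol)) fp <- fp + 1
        }
      }
    }
    c(sensitivity = tp / n_lesions, afp = fp / n_exams)
  }, c(sensitivity = 0, afp = 0)))
}

random_scores <- function(n_exams, seed, lesion_free = FALSE) {
  set.seed(seed)
  lapply(seq_len(n_exams), function(i) {
    nl <- if (lesion_free && i == 1) 0L else sample(0:4, 1)
    nd <- sample(0:10, 1)
    ann <- random_annotations(nl, seed = seed * 100 + i)
    dets <- data.frame(x_mm = runif(nd, 0, 45), y_mm = runif(nd, 0, 45),
                       z_mm = runif(nd, 0, 45), response = runif(nd))
    # place a detection near some lesions so matches occur
    if (nl > 0 && nd > 0) {
      k <- sample(nl, 1)
      dets$x_mm[1] <- ann$x_mm[k] + 0.5
      dets$y_mm[1] <- ann$y_mm[k]
      dets$z_mm[1] <- ann$z_mm[k]
    }
    list(detections = dets, annotations = ann)
  })
}

test_that("match_detections applies the inclusive 1.5 mm rule and counts
           multiple detections of one lesion once", {
  ann <- data.frame(lesion_id = 1:2, x_mm = c(10, 30), y_mm = 10, z_mm = 10)
  dets <- data.frame(x_mm = c(10, 10.5, 11.5, 25), y_mm = 10, z_mm = 10,
                     response = c(0.9, 0.8, 0.7, 0.6))
  out <- match_detections(dets, ann)
  expect_identical(out$n_tp, 1L)
  expect_identical(out$detected_lesions, 1L)
  expect_identical(nrow(out$false_positives), 1L)  # only the far one

  # exactly 1.5 mm counts as detected ("up to" is inclusive)
  d15 <- data.frame(x_mm = 11.5, y_mm = 10, z_mm = 10, response = 1)
  expect_identical(match_detections(d15, ann)$n_tp, 1L)
  d16 <- data.frame(x_mm = 11.6, y_mm = 10, z_mm = 10, response = 1)
  expect_identical(match_detections(d16, ann)$n_tp, 0L)

  none <- match_detections(dets[0, ], ann)
  expect_identical(none$n_tp, 0L)
  expect_identical(nrow(none$false_positives), 0L)
})

test_that("match_detections agrees with a brute-force all-pairs oracle", {
  set.seed(51)
  for (rep in 1:30) {
    nl <- sample(0:8, 1); nd <- sample(0:12, 1)
    ann <- random_annotations(nl, seed = rep)
    dets <- data.frame(x_mm = runif(nd, 0, 45), y_mm = runif(nd, 0, 45),
                       z_mm = runif(nd, 0, 45), response = runif(nd))
    out <- match_detections(dets, ann, tol = 4)
    tp_oracle <- 0L
    if (nl > 0) for (i in seq_len(nl)) {
      dd <- sqrt((dets$x_mm - ann$x_mm[i])^2 + (dets$y_mm - ann$y_mm[i])^2 +
                   (dets$z_mm - ann$z_mm[i])^2)
      if (nd > 0 && any(dd <= 4)) tp_oracle <- tp_oracle + 1L
    }
    fp_oracle <- 0L
    if (nd > 0) for (j in seq_len(nd)) {
      dd <- if (nl == 0) Inf else
        sqrt((ann$x_mm - dets$x_mm[j])^2 + (ann$y_mm - dets$y_mm[j])^2 +
               (ann$z_mm - dets$z_mm[j])^2)
      if (all(dd > 4)) fp_oracle <- fp_oracle + 1L
    }
    expect_identical(out$n_tp, tp_oracle)
    expect_identical(nrow(out$false_positives), fp_oracle)
  }
})

test_that("froc reproduces a brute-force threshold sweep and is monotone", {
  for (rep in 1:10) {
    scores <- random_scores(5, seed = 60 + rep)
    n_lesions <- sum(vapply(scores, function(e) nrow(e$annotations), 0L))
    if (n_lesions == 0) next
    crv <- froc(scores)
    expect_s3_class(crv, "froc_curve")
    # monotone: sensitivity and AFP non-increasing in threshold
    expect_true(all(diff(crv$sensitivity) <= 1e-12))
    expect_true(all(diff(crv$afp) <= 1e-12))
    oracle <- oracle_froc(scores, crv$threshold)
    expect_equal(crv$sensitivity, unname(oracle[, "sensitivity"]),
                 tolerance = 1e-12)
    expect_equal(crv$afp, unname(oracle[, "afp"]), tolerance = 1e-12)
  }
})

test_that("lesion-free exams dilute AFP but never sensitivity", {
  scores <- random_scores(4, seed = 77, lesion_free = TRUE)
  crv <- froc(scores)
  # removing the lesion-free exam leaves sensitivities unchanged at every
  # threshold but scales AFP by n/(n-1)
  has_lesion <- vapply(scores, function(e) nrow(e$annotations) > 0, TRUE)
  skip_if(all(has_lesion))
  fp_extra <- nrow(scores[[which(!has_lesion)[1]]]$detections) > 0
  crv2 <- froc(scores[has_lesion])
  s1 <- vapply(crv$threshold, function(t)
    max(crv2$sensitivity[abs(crv2$threshold - t) < 1e-9], -1), 0)
  matched <- s1 >= 0
  expect_equal(crv$sensitivity[matched], s1[matched])
  expect_error(froc(list(list(detections = data.frame(
    x_mm = 1, y_mm = 1, z_mm = 1, response = 0.5),
    annotations = NULL))), "no lesions")
})

test_that("perfect separation yields an operating point with sensitivity 1
           and AFP 0", {
  ann <- random_annotations(3, seed = 5)
  dets <- data.frame(x_mm = c(ann$x_mm, 5), y_mm = c(ann$y_mm, 5),
                     z_mm = c(ann$z_mm, 5),
                     response = c(0.9, 0.85, 0.8, 0.2))
  crv <- froc(list(list(detections = dets, annotations = ann)))
  hit <- crv$sensitivity == 1 & crv$afp == 0
  expect_true(any(hit))
})

test_that("afp_at_sensitivity reads exact points, interpolates between
           them, and rejects unreachable targets", {
  crv <- structure(data.frame(threshold = c(0.7, 0.3),
                              sensitivity = c(0.8, 0.9), afp = c(2, 8)),
                   class = c("froc_curve", "data.frame"),
                   n_exams = 10L, n_lesions = 20L)
  expect_equal(afp_at_sensitivity(crv, 0.8), 2)
  expect_equal(afp_at_sensitivity(crv, 0.9), 8)
  expect_equal(afp_at_sensitivity(crv, 0.85), 5)
  expect_equal(afp_at_sensitivity(crv, 0.85, interpolate = FALSE), 8)
  expect_error(afp_at_sensitivity(crv, 0.95), "not achievable")

  # scan oracle on a random staircase
  set.seed(52)
  scores <- random_scores(6, seed = 53)
  crv2 <- froc(scores)
  for (s in seq(0.05, max(crv2$sensitivity), by = 0.05)) {
    a <- afp_at_sensitivity(crv2, s, interpolate = FALSE)
    ok <- crv2$sensitivity >= s - 1e-12
    expect_equal(a, min(crv2$afp[ok]))
  }
})

test_that("patient-level CV keeps patients intact and balances bins", {
  p <- small_params()
  mult <- c("1" = 113, "2" = 33, "3" = 10, "4" = 2)
  coh <- generate_cohort(labeled = mult, params = p, seed = 3,
                         render = FALSE)
  expect_length(coh$labeled, 217L)
  folds <- split_cv_by_patient(coh$labeled, folds = 2, seed = 1)
  pf <- attr(folds, "patient_folds")
  expect_length(pf, 158L)
  expect_identical(as.integer(table(pf)), c(79L, 79L))
  # all exams of one patient share a fold
  pids <- vapply(coh$labeled, `[[`, "", "patient_id")
  for (pid in unique(pids))
    expect_length(unique(folds[pids == pid]), 1L)
  # partition: union is everything, intersection empty
  expect_identical(sort(names(folds)),
                   sort(unname(vapply(coh$labeled, `[[`, "", "exam_id"))))
  expect_error(split_cv_by_patient(coh$labeled[1], folds = 2), "fewer")
})

test_that("detect_bm thresholds strictly and NMS keeps the strongest of a
           cluster", {
  p <- phantom_params(grid_shape = c(32L, 32L, 32L))
  les <- sample_lesion_population(p, 1, seed = 2, separate = TRUE)
  ex <- render_phantom(les, p, seed = 3)
  spec <- cropnet_spec(blocks = 1, roi_mm = 16, widths = c(2, 4, 4, 4))
  m <- build_model(spec, seed = 1)
  cfg <- candidate_config(max_candidates = 30L)
  scored <- score_exam(ex, m, cfg)
  if (nrow(scored) > 1) {
    d <- as.matrix(dist(scored[, c("x_mm", "y_mm", "z_mm")]))
    expect_true(all(d[upper.tri(d)] >= 1.5))
  }
  hi <- detect_bm(ex, m, threshold = max(scored$response), cand_config = cfg)
  expect_identical(nrow(hi), 0L)
  lo <- detect_bm(ex, m, threshold = -Inf, cand_config = cfg)
  expect_identical(nrow(lo), nrow(scored))
})

test_that("run_experiment produces a per-cell teacher/student AFP table and
           is reproducible in structure", {
  p <- phantom_params(grid_shape = c(48L, 48L, 48L), lesion_rate = 3)
  coh <- generate_cohort(labeled = c("1" = 8), unlabeled = c("1" = 2),
                         params = p, seed = 21)
  tspec <- cropnet_spec(blocks = 1, roi_mm = 16, widths = c(2, 4, 8, 8),
                        dropout = 0.1)
  sspec <- cropnet_spec(blocks = 2, roi_mm = 16, widths = c(2, 4, 8, 8),
                        dropout = 0.1)
  cfg <- training_config(lr = 1e-3, iterations = 8L,
                         teacher_batch = c(pos = 6L, neg = 6L),
                         student_batch = c(pos = 3L, pseudo_pos = 3L,
                                           neg = 3L, pseudo_neg = 3L),
                         seed = 2L)
  # the target sensitivity must sit below the tiny training bins' capture
  # ceiling, so a deliberately modest ts is used here
  rep <- run_experiment(coh, tspec, sspec, ts = 0.50, lambda = 1,
                        iterations = 1L, folds = 2L, config = cfg,
                        cand_config = candidate_config(max_candidates = 120L),
                        max_unlabeled_candidates = 30L, seed = 7)
  expect_s3_class(rep, "nsbm_report")
  expect_identical(nrow(rep$grid), 1L)
  cell <- rep$cells[[1]]
  expect_named(cell$afp, c("sensitivity", "teacher", "student"))
  expect_identical(cell$afp$sensitivity, c(0.80, 0.85, 0.90))
  expect_length(cell$folds, 2L)
  expect_s3_class(cell$folds[[1]]$teacher_curve, "froc_curve")
  expect_identical(names(cell$mean_curves),
                   c("sensitivity", "teacher", "student"))
})
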