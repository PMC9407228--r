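test_that("flat volumes and empty masks yield no candidates", {
  flat <- volume3d(array(0, c(24, 24, 24)))
  expect_warning(out <- detect_candidates(flat), "empty brain mask")
  expect_identical(nrow(out), 0L)
})

test_that("a Gaussian blob is detected at the closed-form best scale", {
  cfg <- candidate_config(mask_threshold = 0.05, min_response = 1e-4)
  for (sigma_b in c(1.5, 2.5, 3.5)) {
    vol <- blob_volume(48, list(list(centre = c(23, 24, 25), sigma = sigma_b,
                                     amp = 0.6)))
    cands <- detect_candidates(vol, cfg)
    expect_gt(nrow(cands), 0)
    top <- cands[1, ]
    d <- sqrt(sum((c(top$x_mm, top$y_mm, top$z_mm) - c(23, 24, 25))^2))
    expect_lt(d, 1.5)
    # independent oracle: argmax over the scale set of the closed-form
    # response of a Gaussian blob
    best <- cfg$scales[which.max(blob_log_response(cfg$scales, sigma_b))]
    expect_equal(top$scale_mm, best)
  }
})

test_that("two well-separated identical blobs rank 1 and 2", {
  vol <- blob_volume(48, list(
    list(centre = c(14, 14, 14), sigma = 2, amp = 0.6),
    list(centre = c(34, 34, 34), sigma = 2, amp = 0.6)))
  cands <- detect_candidates(vol, candidate_config(mask_threshold = 0.05,
                                                   min_response = 1e-4))
  top2 <- cands[1:2, c("x_mm", "y_mm", "z_mm")]
  d1 <- min(sqrt(colSums((t(as.matrix(top2)) - c(14, 14, 14))^2)))
  d2 <- min(sqrt(colSums((t(as.matrix(top2)) - c(34, 34, 34))^2)))
  expect_lt(d1, 1.5)
  expect_lt(d2, 1.5)
  # tie in response is broken lexicographically by centre
  expect_lt(top2$x_mm[1], top2$x_mm[2])
})

test_that("candidate lists are deterministic and capped", {
  p <- small_params()
  ex <- render_phantom(sample_lesion_population(p, 3, seed = 1,
                                                separate = TRUE),
                       p, seed = 2)
  vol <- normalize_intensity(ex$volume, 1, 100)
  cfg <- candidate_config(max_candidates = 40L)
  a <- detect_candidates(vol, cfg)
  b <- detect_candidates(vol, cfg)
  expect_identical(a, b)
  expect_lte(nrow(a), 40L)
  expect_identical(a$rank, seq_len(nrow(a)))
  expect_true(all(diff(a$response) <= 0))
})

test_that("label_candidates applies the inclusive 1.5 mm rule and matches a
           brute-force oracle", {
  ann <- data.frame(lesion_id = 1L, x_mm = 20, y_mm = 20, z_mm = 20)
  near <- data.frame(rank = 1:2,
                     x_mm = c(20 + 1.4, 20 + 1.6), y_mm = 20, z_mm = 20,
                     scale_mm = 2, response = c(0.5, 0.4))
  lab <- label_candidates(near, ann)
  expect_identical(lab$label, c(1L, 0L))
  expect_identical(lab$matched_lesion, c(1L, NA_integer_))

  set.seed(42)
  for (rep in 1:10) {
    nc <- sample(0:20, 1); nl <- sample(1:8, 1)
    cands <- data.frame(rank = seq_len(nc),
                        x_mm = runif(nc, 0, 40), y_mm = runif(nc, 0, 40),
                        z_mm = runif(nc, 0, 40), scale_mm = rep(2, nc),
                        response = runif(nc))
    ann <- random_annotations(nl, seed = rep)
    lab <- label_candidates(cands, ann, tol = 3)
    for (i in seq_len(nc)) {
      d <- sqrt((ann$x_mm - cands$x_mm[i])^2 + (ann$y_mm - cands$y_mm[i])^2 +
                  (ann$z_mm - cands$z_mm[i])^2)
      expect_identical(lab$label[i], as.integer(any(d <= 3)))
    }
  }
})

test_that("extract_roi cuts centred cubes with mirror padding", {
  set.seed(5)
  vol <- volume3d(array(runif(24^3), c(24, 24, 24)))
  roi <- extract_roi(vol, c(12, 12, 12), edge = 16)
  expect_identical(dim(roi), c(16L, 16L, 16L))
  expect_identical(roi[1, 1, 1], vol$data[5, 5, 5])

  # corner extraction: mirror-symmetric across the boundary plane
  corner <- extract_roi(vol, c(0, 12, 12), edge = 16)
  for (k in 1:7)
    expect_identical(corner[9 - k, , ], corner[9 + k, , ])

  cst <- volume3d(array(2, c(20, 20, 20)))
  expect_true(all(extract_roi(cst, c(10, 10, 10), 16) == 2))
  expect_error(extract_roi(vol, c(12, 12, 12), edge = 32), "exceeds")
})

test_that("capture_rate counts covered lesions and is monotone in the
           response threshold", {
  ann <- random_annotations(5, seed = 3)
  cands <- data.frame(rank = 1:5, x_mm = ann$x_mm + 0.5, y_mm = ann$y_mm,
                      z_mm = ann$z_mm, scale_mm = 2, response = runif(5))
  expect_identical(capture_rate(cands, ann), 1)
  expect_identical(capture_rate(cands[0, ], ann), 0)
  expect_error(capture_rate(cands, ann[0, ]), "undefined")

  # brute-force oracle on a mixed case
  set.seed(9)
  cands2 <- data.frame(rank = 1:12, x_mm = runif(12, 0, 40),
                       y_mm = runif(12, 0, 40), z_mm = runif(12, 0, 40),
                       scale_mm = 2, response = runif(12))
  hit <- sapply(seq_len(5), function(i) {
    any(sqrt((cands2$x_mm - ann$x_mm[i])^2 + (cands2$y_mm - ann$y_mm[i])^2 +
               (cands2$z_mm - ann$z_mm[i])^2) <= 5)
  })
  expect_equal(capture_rate(cands2, ann, tol = 5), mean(hit))

  # raising min_response never increases capture
  p <- small_params()
  ex <- render_phantom(sample_lesion_population(p, 4, seed = 6,
                                                separate = TRUE),
                       p, seed = 7)
  vol <- normalize_intensity(ex$volume, 1, 100)
  caps <- vapply(c(0.005, 0.05, 0.15),
                 function(mr) capture_rate(
                   detect_candidates(vol, candidate_config(min_response = mr)),
                   ex$annotations),
                 0)
  expect_true(all(diff(caps) <= 1e-12))
})
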