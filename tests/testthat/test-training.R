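test_that("bce_loss matches analytic values and a hand-summed oracle", {
  expect_equal(bce_loss(0.5, 1), log(2), tolerance = 1e-12)
  expect_lt(bce_loss(c(1, 0), c(1, 0)), 1e-5)
  set.seed(41)
  p <- runif(20); y <- rbinom(20, 1, 0.5)
  hand <- -mean(y * log(pmin(pmax(p, 1e-7), 1 - 1e-7)) +
                  (1 - y) * log(1 - pmin(pmax(p, 1e-7), 1 - 1e-7)))
  expect_equal(bce_loss(p, y), hand, tolerance = 1e-12)
  expect_error(bce_loss(c(0.1, 0.2), 1), "equal length")
})

test_that("combined_loss is affine in lambda and reduces to the labeled
           half at lambda 0", {
  set.seed(42)
  pl <- runif(8); yl <- rbinom(8, 1, 0.5)
  pu <- runif(12); yu <- rbinom(12, 1, 0.5)
  l0 <- combined_loss(pl, yl, pu, yu, 0)
  l1 <- combined_loss(pl, yl, pu, yu, 1)
  expect_equal(l0, bce_loss(pl, yl))
  expect_equal(l1, bce_loss(pl, yl) + bce_loss(pu, yu))
  for (lam in c(0.3, 0.6, 2)) {
    expect_equal(combined_loss(pl, yl, pu, yu, lam),
                 l0 + lam * (l1 - l0), tolerance = 1e-12)
  }
  expect_equal(combined_loss(pl, yl, numeric(), numeric(), 0),
               bce_loss(pl, yl))
  expect_error(combined_loss(pl, yl, numeric(), numeric(), 0.5),
               "non-empty")
  expect_error(combined_loss(pl, yl, pu, yu, -1), ">= 0")
})

test_that("sample_paired_batch delivers exact compositions, with
           replacement, shuffled", {
  pools <- list(pos = matrix(1, 8, 3), neg = matrix(0, 8, 5),
                pseudo_pos = matrix(2, 8, 2), pseudo_neg = matrix(3, 8, 4))
  comp <- c(pos = 6L, pseudo_pos = 6L, neg = 6L, pseudo_neg = 6L)
  b <- sample_paired_batch(pools, comp, seed = 1)
  expect_identical(as.integer(table(b$pool)[names(comp)]), rep(6L, 4))
  expect_identical(ncol(b$x), 24L)
  # with replacement: requesting more than the pool size works
  b2 <- sample_paired_batch(pools["pos"], c(pos = 50L), seed = 2)
  expect_identical(ncol(b2$x), 50L)
  # empty composition and exhausted pool
  b3 <- sample_paired_batch(pools, c(pos = 0L, neg = 0L), seed = 3)
  expect_identical(ncol(b3$x), 0L)
  expect_error(sample_paired_batch(list(pos = matrix(1, 8, 0)),
                                   c(pos = 2L), seed = 1),
               "exhausted")
  # determinism
  expect_identical(sample_paired_batch(pools, comp, seed = 9),
                   sample_paired_batch(pools, comp, seed = 9))
})

test_that("teacher training: 0 iterations returns the initialization;
           learning separates a separable pool; seeds reproduce", {
  pool <- toy_pools(n_per_class = 25)
  spec <- tiny_spec(blocks = 1L)
  cfg0 <- training_config(iterations = 0L,
                          teacher_batch = c(pos = 8L, neg = 8L), seed = 2L)
  m0 <- train_teacher(pool, spec, cfg0)
  expect_identical(m0$params, build_model(spec, seed = 2L)$params)

  cfg <- training_config(lr = 2e-3, iterations = 200L,
                         teacher_batch = c(pos = 10L, neg = 10L), seed = 2L)
  m <- train_teacher(pool, spec, cfg)
  expect_lt(mean(tail(m$log$loss, 20)), m$log$loss[1])
  acc <- mean((forward(m, pool$x) > 0.5) == pool$y)
  expect_gte(acc, 0.95)

  m2 <- train_teacher(pool, spec, cfg)
  expect_identical(m$params, m2$params)

  onecls <- roi_set(pool$x[, pool$y == 1, drop = FALSE],
                    y = rep(1L, sum(pool$y)), edge = 8)
  expect_error(train_teacher(onecls, spec, cfg), "both classes")
})

test_that("sensitivity_curve and calibrate_mu follow the strict-> rule and
           an exhaustive-scan oracle", {
  crv <- sensitivity_curve(c(0.9, 0.8, 0.7, 0.6, 0.5))
  expect_equal(sensitivity_at(crv, 0.65), 3 / 5)
  expect_equal(sensitivity_at(crv, 0.95), 0)
  expect_equal(sensitivity_at(crv, 0.1), 1)

  cal <- calibrate_mu(crv, 0.8)
  expect_lt(cal$mu, 0.6)
  expect_gt(cal$mu, 0.6 - 1e-6)
  expect_equal(cal$achieved, 0.8)

  # ts = 1 with all lesions matched
  cal1 <- calibrate_mu(crv, 1)
  expect_lt(cal1$mu, 0.5)
  expect_equal(cal1$achieved, 1)

  # unmatched lesions bound the peak sensitivity
  crv2 <- sensitivity_curve(c(0.9, 0.8, -Inf, -Inf))
  expect_error(calibrate_mu(crv2, 0.9), "peak")

  # maximality oracle on random configurations
  set.seed(44)
  for (rep in 1:50) {
    L <- sample(3:40, 1)
    maxima <- round(runif(L), 3)
    if (rep %% 3 == 0) maxima[sample(L, 1)] <- -Inf
    ts <- runif(1, 0.1, 1)
    crv3 <- sensitivity_curve(maxima)
    k <- ceiling(ts * L)
    kth <- sort(maxima, decreasing = TRUE)[k]
    if (!is.finite(kth)) {
      expect_error(calibrate_mu(crv3, ts))
    } else {
      cal3 <- calibrate_mu(crv3, ts)
      expect_gte(sensitivity_at(crv3, cal3$mu), ts)
      # maximality: any strictly larger observed response fails ts
      larger <- sort(unique(maxima[is.finite(maxima) & maxima > cal3$mu]))
      if (length(larger) > 0)
        expect_lt(sensitivity_at(crv3, larger[1]), ts)
      # oracle staircase equivalence over a dense scan
      grid <- seq(0, 1, by = 0.01)
      expect_equal(sensitivity_at(crv3, grid),
                   vapply(grid, function(t) mean(maxima > t), 0))
    }
  }
  expect_error(sensitivity_curve(numeric()), "zero lesions")
  expect_error(calibrate_mu(crv, 0), "in \\(0, 1\\]")
})

test_that("pseudo_label applies Eq-style strict thresholding exactly", {
  pool <- toy_pools(n_per_class = 5)
  spec <- tiny_spec()
  m <- build_model(spec, seed = 1)
  ps <- pseudo_label(m, pool, mu = 0.5)
  expect_identical(ps$labels, as.integer(ps$responses > 0.5))

  # boundary: a response exactly equal to mu is labeled 0 (strict >)
  mu_star <- ps$responses[1]
  ps_star <- pseudo_label(m, pool, mu = mu_star)
  expect_identical(ps_star$labels[1], 0L)
  just_below <- mu_star * (1 - 1e-9)
  ps_below <- pseudo_label(m, pool, mu = just_below)
  expect_identical(ps_below$labels[1], 1L)

  # elementwise oracle over random thresholds on the same responses
  set.seed(45)
  for (mu in runif(20, 0.05, 0.95)) {
    psr <- pseudo_label(m, pool, mu = mu)
    expect_identical(psr$labels,
                     vapply(psr$responses,
                            function(r) if (r > mu) 1L else 0L, 1L))
  }
  expect_error(pseudo_label(m, pool, mu = 1.2), "\\(0, 1\\)")
})

test_that("student training with lambda 0 reproduces the teacher-style
           trajectory on the same data", {
  pool <- toy_pools(n_per_class = 15)
  spec <- tiny_spec()
  cfg <- training_config(lambda = 0, lr = 1e-3, iterations = 25L,
                         teacher_batch = c(pos = 6L, neg = 6L),
                         student_batch = c(pos = 6L, pseudo_pos = 0L,
                                           neg = 6L, pseudo_neg = 0L),
                         seed = 8L)
  st <- train_student(pool, NULL, spec, cfg)
  te <- train_teacher(pool, spec, cfg)
  expect_identical(st$params, te$params)
  expect_equal(st$log$loss, te$log$loss)

  cfg2 <- cfg; cfg2$lambda <- 1
  expect_error(train_student(pool, NULL, spec, cfg2), "exhausted")
})

test_that("student training uses pseudo pools and is seed-reproducible", {
  pool <- toy_pools(n_per_class = 15)
  spec <- tiny_spec()
  m <- build_model(spec, seed = 1)
  upool <- toy_pools(n_per_class = 10, seed = 123)
  # threshold at the median response so both pseudo classes are populated
  mu <- median(forward(m, upool$x))
  ps <- pseudo_label(m, upool, mu = mu)
  expect_gt(sum(ps$labels), 0)
  expect_gt(sum(1 - ps$labels), 0)
  cfg <- training_config(lambda = 1, lr = 1e-3, iterations = 15L,
                         student_batch = c(pos = 4L, pseudo_pos = 4L,
                                           neg = 4L, pseudo_neg = 4L),
                         seed = 3L)
  s1 <- train_student(pool, ps, spec, cfg)
  s2 <- train_student(pool, ps, spec, cfg)
  expect_identical(s1$params, s2$params)
  expect_identical(nrow(s1$log), 15L)
})

test_that("training_config validates pairing and lambda", {
  expect_error(training_config(teacher_batch = c(pos = 10L, neg = 8L)),
               "paired")
  expect_error(training_config(student_batch = c(pos = 5L, pseudo_pos = 3L,
                                                 neg = 5L, pseudo_neg = 2L)),
               "paired")
  expect_error(training_config(lambda = -0.1), ">= 0")
})
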