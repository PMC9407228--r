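# Pure-R oracle for the CropNet forward pass: direct zero-padded 3^3
# convolution loops, ReLU, 2x max-pool, flatten, sigmoid head.
oracle_forward <- function(model, x) {
  spec <- model$spec
  conv3 <- function(A, W, b) {
    S <- dim(A)[1]; Cin <- dim(A)[4]; Cout <- ncol(W)
    out <- array(0, c(S, S, S, Cout))
    for (co in seq_len(Cout)) {
      acc <- array(b[co], c(S, S, S))
      for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
        o <- (dx + 1) + 3 * (dy + 1) + 9 * (dz + 1)
        for (ci in seq_len(Cin)) {
          w <- W[o * Cin + ci, co]
          src <- array(0, c(S, S, S))
          xs <- max(1, 1 + dx):min(S, S + dx)
          ys <- max(1, 1 + dy):min(S, S + dy)
          zs <- max(1, 1 + dz):min(S, S + dz)
          src[xs - dx, ys - dy, zs - dz] <- A[xs, ys, zs, ci]
          acc <- acc + w * src
        }
      }
      out[, , , co] <- acc
    }
    out
  }
  pool2 <- function(A) {
    S <- dim(A)[1]; S2 <- S / 2; C <- dim(A)[4]
    out <- array(0, c(S2, S2, S2, C))
    for (c in seq_len(C)) for (z in 1:S2) for (y in 1:S2) for (x in 1:S2)
      out[x, y, z, c] <- max(A[2 * x - 1:0, 2 * y - 1:0, 2 * z - 1:0, c])
    out
  }
  S <- spec$roi_mm
  A <- array(x, c(S, S, S, 1))
  k <- 0
  for (l in seq_len(spec$levels)) {
    for (j in seq_len(spec$blocks)) {
      k <- k + 1
      A <- pmax(conv3(A, model$params$W[[k]], model$params$b[[k]]), 0)
    }
    if (l < spec$levels) A <- pool2(A)
  }
  z <- sum(as.numeric(A) * model$params$wd) + model$params$bd
  1 / (1 + exp(-z))
}

test_that("the compiled forward pass matches a direct-convolution R oracle", {
  set.seed(11)
  spec <- cropnet_spec(blocks = 2, roi_mm = 8, levels = 3,
                       widths = c(2, 3, 4), dropout = 0)
  m <- build_model(spec, seed = 7)
  for (i in 1:3) {
    x <- array(runif(8^3), c(8, 8, 8))
    expect_equal(forward(m, x), oracle_forward(m, x), tolerance = 1e-12)
  }
})

test_that("analytic gradients match finite differences", {
  set.seed(12)
  spec <- cropnet_spec(blocks = 1, roi_mm = 4, levels = 2, widths = c(2, 3),
                       dropout = 0)
  m <- build_model(spec, seed = 3)
  N <- 4
  xb <- matrix(runif(4^3 * N), 4^3, N)
  y <- c(1, 0, 1, 0)
  w <- rep(1 / N, N)
  g <- nsbm:::.cn_grad_cpp(m$params$W, m$params$b, m$params$wd, m$params$bd,
                           as.numeric(xb), N, 4, 2, 1, spec$widths, 0, -1,
                           y, w)
  lossfn <- function(params) {
    p <- nsbm:::.cn_forward_cpp(params$W, params$b, params$wd, params$bd,
                                as.numeric(xb), N, 4, 2, 1, spec$widths,
                                0, -1)
    p <- pmin(pmax(p, 1e-7), 1 - 1e-7)
    sum(w * (-y * log(p) - (1 - y) * log(1 - p)))
  }
  eps <- 1e-6
  for (t in 1:12) {
    k <- sample(2, 1)
    i <- sample(length(m$params$W[[k]]), 1)
    ph <- m$params; ph$W[[k]][i] <- ph$W[[k]][i] + eps
    pl <- m$params; pl$W[[k]][i] <- pl$W[[k]][i] - eps
    expect_equal(g$gW[[k]][i], (lossfn(ph) - lossfn(pl)) / (2 * eps),
                 tolerance = 1e-4)
  }
  i <- sample(length(m$params$wd), 1)
  ph <- m$params; ph$wd[i] <- ph$wd[i] + eps
  pl <- m$params; pl$wd[i] <- pl$wd[i] - eps
  expect_equal(g$gwd[i], (lossfn(ph) - lossfn(pl)) / (2 * eps),
               tolerance = 1e-4)
})

test_that("parameter counts follow the architecture arithmetic", {
  # toy b1-8mm with widths (2,4,8):
  #   conv1 1->2: 27*2+2 = 56;  conv2 2->4: 27*4*2+4 = 220
  #   conv3 4->8: 27*8*4+8 = 872; head: 2^3*8 + 1 = 65
  m <- build_model(tiny_spec(blocks = 1L), seed = 1)
  expect_identical(count_parameters(m), 56 + 220 + 872 + 65)

  # capacity ordering at a shared width schedule: b4 > b2
  w <- c(4L, 8L, 16L, 32L)
  b2 <- build_model(cropnet_spec(blocks = 2, widths = w), seed = 1)
  b4 <- build_model(cropnet_spec(blocks = 4, widths = w), seed = 1)
  expect_gt(count_parameters(b4), count_parameters(b2))
})

test_that("inference is deterministic, bounded and batch-order invariant;
           training-mode dropout is stochastic", {
  spec <- tiny_spec(blocks = 2L)
  m <- build_model(spec, seed = 5)
  set.seed(21)
  xb <- matrix(runif(8^3 * 6, -2, 2), 8^3, 6)
  p1 <- forward(m, xb)
  p2 <- forward(m, xb)
  expect_identical(p1, p2)
  expect_true(all(p1 >= 0 & p1 <= 1))
  expect_equal(forward(m, xb[, c(3, 1)])[2], p1[1], tolerance = 1e-12)

  d1 <- forward(m, xb, training = TRUE, seed = 1)
  d2 <- forward(m, xb, training = TRUE, seed = 2)
  expect_identical(forward(m, xb, training = TRUE, seed = 1), d1)
  expect_false(isTRUE(all.equal(d1, d2)))

  expect_error(forward(m, matrix(0, 10, 2)), "edge")
  expect_error(cropnet_spec(blocks = 2, roi_mm = 12, levels = 4,
                            widths = c(2, 4, 8, 16)),
               "divisible")
})

test_that("model building is seed-reproducible", {
  a <- build_model(tiny_spec(), seed = 9)
  b <- build_model(tiny_spec(), seed = 9)
  expect_identical(a$params, b$params)
  c <- build_model(tiny_spec(), seed = 10)
  expect_false(identical(a$params$W[[1]], c$params$W[[1]]))
})
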