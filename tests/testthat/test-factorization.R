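test_that("similarity L matches the hand-computed worked example", {
  # M' = [[1,1],[1,1]], M = [[2,1],[1,1]]: row error ratios 0.5 and 0 -> L = 75
  W <- matrix(c(1, 1), 2, 1)
  C <- matrix(c(1, 1), 1, 2)
  M <- matrix(c(2, 1, 1, 1), 2, 2, byrow = TRUE)
  expect_equal(similarity_L(M, W, C), 75)
  # exact reconstruction -> L = 100; any error -> strictly below 100
  expect_equal(similarity_L(W %*% C, W, C), 100)
  expect_lt(similarity_L(M, W, C), 100)
})

test_that("similarity L errors when a reconstructed muscle row is zero", {
  W <- matrix(c(1, 0), 2, 1)
  C <- matrix(c(1, 1), 1, 2)
  expect_error(similarity_L(matrix(1, 2, 2), W, C), class = "undefined_ratio")
})

test_that("L decreases as the residual grows", {
  withr::with_seed(11, {
    W <- abs(matrix(rnorm(6 * 2), 6))
    C <- abs(matrix(rnorm(2 * 30), 2))
    Mp <- W %*% C
    noise <- matrix(rnorm(length(Mp)), nrow(Mp))
    Ls <- sapply(c(0, 0.05, 0.2, 0.5), function(s) similarity_L(Mp + s * noise, W, C))
    expect_true(all(diff(Ls) < 0))
  })
})

test_that("synergy normalization preserves the product and is idempotent", {
  W <- matrix(c(3, 4, 0, 0, 0, 0,  1, 1, 1, 1, 1, 1), 6, 2)
  C <- matrix(runif(2 * 8), 2, 8)
  out <- normalize_synergies(W, C)
  expect_equal(out$W[, 1], c(0.6, 0.8, 0, 0, 0, 0))
  expect_equal(out$C[1, ], 5 * C[1, ])
  expect_equal(sqrt(colSums(out$W^2)), c(1, 1))
  expect_equal(out$W %*% out$C, W %*% C, tolerance = 1e-12)
  again <- normalize_synergies(out$W, out$C)
  expect_equal(again$W, out$W)
  expect_error(normalize_synergies(cbind(W[, 1], 0), C),
               class = "degenerate_synergy")
})

test_that("NMF factorizes exactly representable matrices and is deterministic", {
  # rank-1 outer product
  withr::with_seed(5, {
    u <- runif(6); v <- runif(40)
  })
  M1 <- outer(u, v)
  d1 <- nmf(M1, 1, restarts = 5, seed = 7)
  expect_gte(d1$L, 99.9)
  expect_true(all(d1$W >= 0) && all(d1$C >= 0))
  expect_equal(sqrt(colSums(d1$W^2)), 1, ignore_attr = TRUE)

  # exact n = 2 construction from the synthetic module
  gt <- synthetic_ground_truth(m = 6, n = 2, t = 160, pair_angle = 60, seed = 2)
  M2 <- make_trial(gt, 1)
  d2 <- nmf(M2, 2, restarts = 10, seed = 3)
  expect_gte(d2$L, 99)

  # determinism
  d2b <- nmf(M2, 2, restarts = 10, seed = 3)
  expect_identical(d2$W, d2b$W)
  expect_identical(d2$C, d2b$C)
})

test_that("NMF rejects invalid inputs", {
  M <- abs(matrix(rnorm(24), 6))
  Mneg <- M; Mneg[1, 1] <- -1
  expect_error(nmf(Mneg, 2), class = "invalid_input")
  expect_error(nmf(M, 6), class = "invalid_parameter")
  expect_error(nmf(M, 0), class = "invalid_parameter")
})

test_that("multiplicative updates never increase the residual", {
  withr::with_seed(21, {
    V <- abs(matrix(rnorm(6 * 50), 6))
    W <- matrix(runif(12), 6, 2)
    C <- matrix(runif(100), 2, 50)
  })
  eps <- 1e-12
  res <- sqrt(sum((V - W %*% C)^2))
  for (it in 1:50) {
    C <- C * crossprod(W, V) / (crossprod(W, W %*% C) + eps)
    W <- W * (V %*% t(C)) / (W %*% tcrossprod(C) + eps)
    res_new <- sqrt(sum((V - W %*% C)^2))
    expect_lte(res_new, res + 1e-9)
    res <- res_new
  }
})

test_that("scaling the input scales the commands, not the synergies", {
  gt <- synthetic_ground_truth(m = 6, n = 2, t = 80, pair_angle = 60, seed = 9)
  M <- as.matrix(make_trial(gt, 1))
  d1 <- nmf(M, 2, restarts = 5, seed = 4)
  d3 <- nmf(3 * M, 2, restarts = 5, seed = 4)
  perms <- match_synergies(list(d1$W, d3$W))
  expect_equal(d3$W[, perms[[2]]], d1$W, tolerance = 1e-3)
  expect_equal(d3$C[perms[[2]], ], 3 * d1$C, tolerance = 1e-2)
})

test_that("dimension selection finds the smallest adequate dimension", {
  gt <- synthetic_ground_truth(m = 6, n = 2, t = 160, pair_angle = 60,
                               noise_sd = 0.05, seed = 12)
  M <- make_trial(gt, 1)
  sel <- select_dimension(M, threshold = 75, restarts = 5, seed = 12)
  expect_equal(sel$n, 2)
  expect_true(sel$reached_threshold)
  expect_gt(sel$L[2], 75)
  expect_lte(sel$L[1], 75)

  # vanishing threshold: anything fits at n = 1
  expect_equal(select_dimension(M, threshold = 1e-6, restarts = 2,
                                seed = 1, full_curve = FALSE)$n, 1)

  # noise-free rank-1 matrix clears even a 99% threshold at n = 1
  withr::with_seed(5, M1 <- outer(runif(6), runif(40)))
  expect_equal(select_dimension(M1, threshold = 99, restarts = 5, seed = 2,
                                full_curve = FALSE)$n, 1)
  expect_error(select_dimension(M, threshold = 110), class = "invalid_parameter")
})

test_that("best-of-restarts L does not degrade as the dimension grows", {
  gt <- synthetic_ground_truth(m = 6, n = 3, t = 120, pair_angle = 60,
                               noise_sd = 0.1, seed = 31)
  M <- make_trial(gt, 1)
  Ls <- sapply(1:5, function(k) nmf(M, k, restarts = 8, seed = 31)$L)
  expect_true(all(diff(Ls) > -0.5))  # allow small restart jitter, no real drop
})
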