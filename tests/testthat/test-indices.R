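test_that("pearson_r reproduces hand-computed values and matches stats::cor", {
  expect_equal(pearson_r(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(pearson_r(c(1, 2, 3), c(3, 2, 1)), -1)
  # hand arithmetic: covariance sum 1/3, population SDs sqrt(2)/3 each
  expect_equal(pearson_r(c(0, 1, 1), c(0, 0, 1)), 0.5)
  withr::with_seed(8, {
    for (k in 1:10) {
      x <- rnorm(12); y <- rnorm(12)
      expect_equal(pearson_r(x, y), cor(x, y), tolerance = 1e-12)
    }
  })
  expect_error(pearson_r(rep(1, 5), rnorm(5)), class = "zero_variance")
  expect_error(pearson_r(1:3, 1:4), class = "invalid_input")
})

test_that("matching un-swaps permuted synergies and is exhaustive-optimal", {
  withr::with_seed(14, W <- apply(matrix(runif(18), 6, 3), 2,
                                  function(c) c / sqrt(sum(c^2))))
  swapped <- W[, c(3, 1, 2)]
  perms <- match_synergies(list(W, swapped))
  expect_identical(perms[[1]], 1:3)
  expect_equal(swapped[, perms[[2]]], W)
  expect_equal(compute_ssi(list(W, swapped[, perms[[2]]])), 1)

  # identical trials and n = 1 give identity permutations
  expect_identical(match_synergies(list(W, W, W))[[3]], 1:3)
  expect_identical(match_synergies(list(W[, 1, drop = FALSE],
                                        W[, 2, drop = FALSE]))[[2]], 1L)

  # exhaustive oracle: best permutation by direct enumeration
  withr::with_seed(15, W2 <- apply(matrix(runif(18), 6, 3), 2,
                                   function(c) c / sqrt(sum(c^2))))
  perm_pkg <- match_synergies(list(W, W2))[[2]]
  all_perms <- list(c(1,2,3), c(1,3,2), c(2,1,3), c(2,3,1), c(3,1,2), c(3,2,1))
  scores <- sapply(all_perms, function(p)
    sum(sapply(1:3, function(i) cor(W[, i], W2[, p[i]]))))
  expect_equal(sum(sapply(1:3, function(i) cor(W[, i], W2[, perm_pkg[i]]))),
               max(scores))

  expect_error(match_synergies(list(W, W[, 1:2])), class = "invalid_ensemble")
})

test_that("SSI equals the brute-force pairwise enumeration", {
  W1 <- cbind(unit6(1:2), unit6(3:4))
  W2 <- cbind(unit6(c(1, 2, 3), c(2, 1, 1)), unit6(c(3, 4, 5), c(1, 2, 1)))
  W3 <- cbind(unit6(c(1, 2), c(1, 2)), unit6(c(4, 5)))
  W_list <- list(W1, W2, W3)
  expect_equal(compute_ssi(W_list), brute_ssi(W_list), tolerance = 1e-12)
  expect_equal(compute_ssi(list(W1, W1, W1)), 1)
  expect_error(compute_ssi(list(W1)), class = "invalid_ensemble")
})

test_that("SSI_c mirrors SSI on command rows", {
  C1 <- rbind(c(0, 1, 2, 3), c(3, 1, 0, 2))
  C2 <- rbind(c(1, 1, 3, 4), c(2, 0, 0, 3))
  # oracle: mean over the two rows of the pairwise correlation
  manual <- mean(c(cor(C1[1, ], C2[1, ]), cor(C1[2, ], C2[2, ])))
  expect_equal(compute_ssic(list(C1, C2)), manual, tolerance = 1e-12)
  expect_equal(compute_ssic(list(C1, C1, C1)), 1)
  # time-reversing a non-symmetric command lowers the correlation below 1
  expect_lt(suppressWarnings(compute_ssic(list(C1, C1[, 4:1]))), 1)
})

test_that("SCI hits its analytic endpoints and the cosine of the pair angle", {
  w <- unit6(c(1, 3, 5), c(1, 2, 2))
  expect_equal(compute_sci(cbind(w, w, w)), 1)
  expect_equal(compute_sci(cbind(unit6(1:2), unit6(3:4))), 0)
  # two unit columns at 60 degrees: SCI = cos(60) = 0.5
  u <- unit6(1)
  v <- c(cos(pi / 3), sin(pi / 3), 0, 0, 0, 0)
  expect_equal(compute_sci(cbind(u, v)), 0.5)
  expect_error(compute_sci(matrix(u, ncol = 1)), class = "undefined_index")
  expect_error(compute_sci(cbind(2 * u, v)), class = "invalid_input")
})

test_that("SCI is column-order invariant and increases as columns close up", {
  W <- cbind(unit6(1:2), unit6(c(2, 3), c(2, 1)), unit6(c(4, 5)))
  expect_equal(compute_sci(W), compute_sci(W[, 3:1]))
  angles <- c(80, 60, 40, 20)
  scis <- sapply(angles, function(a) {
    v <- c(cos(a * pi / 180), sin(a * pi / 180), 0, 0, 0, 0)
    compute_sci(cbind(unit6(1), v))
  })
  expect_true(all(diff(scis) > 0))
})

test_that("ensembles stay in range and absorb common permutations", {
  gt <- synthetic_ground_truth(m = 6, n = 2, t = 120, pair_angle = 50,
                               sigma_W = 0.1, sigma_C = 0.1, noise_sd = 0.03,
                               seed = 6)
  decs <- lapply(1:4, function(j) nmf(make_trial(gt, j), 2, restarts = 5,
                                      seed = j))
  ens <- synergy_ensemble(decs)
  expect_true(ens$ssi >= 0 && ens$ssi <= 1 + 1e-9)
  expect_true(ens$ssi_c >= 0 && ens$ssi_c <= 1 + 1e-9)
  expect_true(all(ens$sci >= 0 & ens$sci <= 1 + 1e-9))

  # permute every trial's columns identically: indices must not change
  decs_p <- lapply(decs, function(d) {
    d$W <- d$W[, 2:1]; d$C <- d$C[2:1, ]; d
  })
  ens_p <- synergy_ensemble(decs_p)
  expect_equal(ens_p$ssi, ens$ssi, tolerance = 1e-12)
  expect_equal(ens_p$ssi_c, ens$ssi_c, tolerance = 1e-12)
  expect_equal(sort(ens_p$sci), sort(ens$sci), tolerance = 1e-12)
})

test_that("SSI falls as the cross-trial synergy perturbation grows", {
  mean_ssi <- function(sigma_w) {
    mean(sapply(1:6, function(rep) {
      gt <- synthetic_ground_truth(m = 6, n = 2, t = 120, pair_angle = 60,
                                   sigma_W = sigma_w, noise_sd = 0.02,
                                   seed = 100 + rep)
      W_list <- lapply(1:4, function(j) {
        M <- make_trial(gt, j)
        nmf(M, 2, restarts = 4, seed = j)$W
      })
      perms <- match_synergies(W_list)
      compute_ssi(Map(function(W, p) W[, p], W_list, perms))
    }))
  }
  ssis <- sapply(c(0, 0.15, 0.4), mean_ssi)
  expect_true(all(diff(ssis) < 0))
  expect_gt(ssis[1], 0.99)
})
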