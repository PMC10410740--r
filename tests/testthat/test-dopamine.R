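test_that("varicosity placement is uniform in the cube and seeded", {
  q <- place_varicosities(4, 10, seed = 2)
  expect_identical(dim(q), c(4L, 10L, 3L))
  expect_true(all(q >= 0 & q <= 1))
  expect_identical(q, place_varicosities(4, 10, seed = 2))
  big <- place_varicosities(50, 200, seed = 3)
  expect_equal(apply(big, 3, mean), rep(0.5, 3), tolerance = 0.02)
  expect_error(place_varicosities(0, 10, 1), ">= 1")
})

test_that("diffusion kernel: zero-distance value, 1/e decay at lambda, additivity", {
  p <- matrix(c(0.5, 0.5, 0.5), 1, 3)
  q0 <- array(c(0.5, 0.5, 0.5), dim = c(1, 1, 3))         # coincident
  expect_equal(effective_feedback_matrix(p, q0, 0.1)[1, 1], 10)
  qlam <- array(c(0.6, 0.5, 0.5), dim = c(1, 1, 3))       # distance = lambda
  d_lam <- effective_feedback_matrix(p, qlam, 0.1)[1, 1]
  expect_equal(d_lam / 10, exp(-1))                        # 1/e ~ 37%
  # additive over varicosities
  q2 <- array(c(0.5, 0.6, 0.5, 0.5, 0.5, 0.5), dim = c(1, 2, 3))
  expect_equal(effective_feedback_matrix(p, q2, 0.1)[1, 1], 10 + d_lam)
  expect_error(effective_feedback_matrix(p, q0, 0), "positive")
  # strictly positive entries, monotone decay with distance
  set.seed(1)
  P <- matrix(runif(60), 20, 3)
  Q <- place_varicosities(3, 5, seed = 9)
  D <- effective_feedback_matrix(P, Q, 0.1)
  expect_true(all(D > 0))
  dists <- seq(0, 1, by = 0.05)
  vals <- vapply(dists, function(x) {
    effective_feedback_matrix(matrix(c(x, 0, 0), 1),
                              array(0, dim = c(1, 1, 3)), 0.1)[1, 1]
  }, numeric(1))
  expect_true(all(diff(vals) < 0))
})

test_that("dopamine concentration is the linear mixture D r_snc", {
  set.seed(3)
  D <- matrix(runif(20, 0.1, 2), 5, 4)
  expect_equal(dopamine_concentration(D, rep(0, 4)), rep(0, 5))
  expect_equal(dopamine_concentration(D, c(0, 1, 0, 0)), D[, 2])
  r <- rnorm(4)
  manual <- vapply(1:5, function(j) sum(D[j, ] * r), numeric(1))
  expect_equal(dopamine_concentration(D, r), manual)
  expect_error(dopamine_concentration(D, 1:3), "mismatch")
})

test_that("feedback variants: shuffle multiset, homogeneous rows, ideal sign-adjusted transpose", {
  set.seed(4)
  D <- matrix(runif(40, 0.1, 3), 10, 4)
  sh <- make_feedback_variant(D, "shuffled", seed = 7)
  expect_equal(sort(as.vector(sh)), sort(as.vector(D)))
  expect_false(identical(sh, D))
  hom <- make_feedback_variant(D, "homogeneous")
  expect_true(all(hom == mean(D)))
  expect_equal(nrow(unique(hom)), 1)
  no <- make_feedback_variant(D, "none")
  expect_true(all(no == 0))
  W <- matrix(rnorm(40), 4, 10)
  sgn <- rep(c(-1, 1), each = 5)
  id <- make_feedback_variant(D, "ideal", W_str_snr = W, pre_sign = sgn)
  expect_equal(id, sgn * t(W))
  expect_error(make_feedback_variant(D, "sideways"), "unknown")
})

test_that("low-pass filter: DC gain, memoryless limit, impulse response", {
  # constant input converges to the input (normalized filter)
  C <- rep(0, 3)
  for (i in 1:5000) C <- lowpass_dopamine(C, c(1, 2, -3), dt = 1, tau_da = 20)
  expect_equal(C, c(1, 2, -3), tolerance = 1e-9)
  # tau -> 0: memoryless
  expect_equal(lowpass_dopamine(5, 1, dt = 1, tau_da = 1e-9), 1)
  # impulse decays by xi per step
  xi <- exp(-1 / 20)
  C <- lowpass_dopamine(0, 1, 1, 20)
  expect_equal(C, 1 - xi)
  C2 <- lowpass_dopamine(C, 0, 1, 20)
  expect_equal(C2 / C, xi)
  # unnormalized form: DC gain (1 - xi)^-1
  C <- 0
  for (i in 1:5000) C <- lowpass_dopamine(C, 1, 1, 20, normalized = FALSE)
  expect_equal(C, 1 / (1 - xi), tolerance = 1e-9)
  expect_error(lowpass_dopamine(0, 1, 1, 0), "positive")
})

test_that("low-pass then high-pass compensation is an exact identity", {
  set.seed(8)
  x <- matrix(rnorm(400), 4, 100)  # arbitrary bounded sequences
  Cf <- rep(0, 4); A_prev <- rep(0, 4)
  recon <- matrix(NA_real_, 4, 100)
  for (t in 1:100) {
    Cf <- lowpass_dopamine(Cf, x[, t], dt = 1, tau_da = 200)
    hp <- highpass_compensate(Cf, A_prev, dt = 1, tau_da = 200)
    recon[, t] <- hp$a
    A_prev <- hp$A
  }
  expect_equal(recon, x, tolerance = 1e-12)
  # constant input special case
  Cf <- 0; A_prev <- 0
  for (t in 1:50) {
    Cf <- lowpass_dopamine(Cf, 2.5, 1, 30)
    hp <- highpass_compensate(Cf, A_prev, 1, 30)
    A_prev <- hp$A
  }
  expect_equal(hp$a, 2.5, tolerance = 1e-12)
  expect_error(highpass_compensate(1, 0, 1, 0), "positive")
})

test_that("feedback independence: rank-1 gives 0, orthogonal rows 1, lambda limits", {
  D1 <- matrix(rep(c(1, 2, 3, 4), each = 6), 6, 4)  # identical rows
  expect_equal(feedback_independence(D1), 0, tolerance = 1e-12)
  expect_equal(feedback_independence(diag(4)), 1)
  expect_error(feedback_independence(matrix(0, 3, 3)), "zero")
  set.seed(5)
  P <- matrix(runif(90), 30, 3)
  Q <- place_varicosities(4, 10, seed = 2)
  ind <- vapply(c(0.05, 0.1, 10, 1000), function(l) {
    feedback_independence(effective_feedback_matrix(P, Q, l))
  }, numeric(1))
  # homogeneous limit: rows converge to a common vector
  expect_lt(ind[4], 0.01)
  expect_gt(ind[2], ind[4])
  # D -> 0 entrywise as lambda -> 0 (no-feedback limit)
  Dsmall <- effective_feedback_matrix(P, Q, 1e-4)
  expect_lt(max(Dsmall), 1e-8)
})

test_that("more varicosities make D less degenerate at small lambda", {
  set.seed(6)
  P <- matrix(runif(150), 50, 3)
  ind <- vapply(c(1, 10), function(nv) {
    median(vapply(1:9, function(s) {
      Q <- place_varicosities(4, nv, seed = s)
      feedback_independence(effective_feedback_matrix(P, Q, 0.05))
    }, numeric(1)))
  }, numeric(1))
  # a single release site per SNc cell leaves most SPNs unreached; ten sites
  # cover the cube and make the rows of D substantially more independent
  expect_gt(ind[2], ind[1] + 0.05)
})
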