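test_that("eligibility trace: fixed point, decay, and saturation gating", {
  # constant rates: p converges to r_j (1 - r_j) r_i
  p <- matrix(0, 2, 3)
  r_str <- c(0.3, 0.6); r_pre <- c(0.2, 0.5, 0.9)
  for (i in 1:2000) p <- update_eligibility(p, r_str, r_pre, dt = 1, tau_str = 10)
  expect_equal(p, (r_str * (1 - r_str)) %o% r_pre, tolerance = 1e-10)
  # zero presynaptic drive: geometric decay to 0
  p <- matrix(1, 2, 3)
  p1 <- update_eligibility(p, r_str, rep(0, 3), 1, 10)
  expect_equal(p1, p * 0.9)
  # saturated postsynaptic rate: pure decay
  p2 <- update_eligibility(p, c(0, 1), r_pre, 1, 10)
  expect_equal(p2, p * 0.9)
  # masked synapses carry no trace
  m <- matrix(c(1, 0, 1, 0, 1, 0), 2, 3)
  p3 <- update_eligibility(matrix(0, 2, 3), r_str, r_pre, 1, 10, mask = m)
  expect_true(all(p3[m == 0] == 0))
  expect_error(update_eligibility(p, r_str, r_pre, 1, 0), "positive")
})

test_that("striatal three-factor update follows -alpha * p * dopamine and gates", {
  W <- matrix(0.5, 1, 1)
  # alpha = -2.5e-2, p = 0.1, dopamine = 2, dt = 1  ->  dW = +5e-3
  up <- striatal_weight_update(W, matrix(0.1, 1, 1), 2, -2.5e-2, 1)
  expect_equal(up[1, 1], 0.5 + 5e-3)
  # no dopamine or no eligibility: unchanged
  expect_equal(striatal_weight_update(W, matrix(0.3, 1, 1), 0, -2.5e-2, 1), W)
  expect_equal(striatal_weight_update(W, matrix(0, 1, 1), 2, -2.5e-2, 1), W)
  # sign clamp for an excitatory projection
  dn <- striatal_weight_update(matrix(1e-4, 1, 1), matrix(0.5, 1, 1),
                               dopamine_per_spn = -2, alpha_per_spn = -2.5e-2,
                               dt = 1, sign = 1)
  expect_equal(dn[1, 1], 0)
  expect_error(striatal_weight_update(W, matrix(0, 2, 2), 2, -2.5e-2, 1),
               "mismatch")
})

test_that("striatofugal delta rule equals the finite-difference loss gradient", {
  set.seed(10)
  n_str <- 6; d <- 3
  # positive weights well away from zero, so the Dale clamp is inactive and
  # the update is the pure delta rule
  W <- matrix(runif(d * n_str, 0.2, 0.8), d, n_str)
  r_str <- runif(n_str, 0.1, 0.9)
  target <- runif(d, 0.2, 0.8)
  beta <- 1e-3
  loss_of <- function(Wx) output_loss(readout_rates(Wx, r_str), target)
  eps <- snc_error_rates(readout_rates(W, r_str), target)
  up <- striatofugal_update(W, eps, r_str, beta, dt = 1,
                            pre_sign = rep(1, n_str))
  # compare -dW/(beta dt) with brute-force central differences
  for (k in 1:d) for (j in 1:n_str) {
    g <- brute_force_gradient(loss_of, W, k, j)
    expect_equal(-(up[k, j] - W[k, j]) / beta, g, tolerance = 1e-6 * max(1, abs(g)))
  }
  # zero error / silent presynapse leave weights unchanged
  expect_equal(striatofugal_update(W, rep(0, d), r_str, beta, 1, rep(1, n_str)), W)
  expect_equal(striatofugal_update(W, eps, rep(0, n_str), beta, 1, rep(1, n_str)), W)
})

test_that("sign constraints clamp crossings and are idempotent", {
  W <- matrix(c(-0.01, 0.4, 0.3, -0.2), 2, 2)
  sgn <- c(1, -1)  # first presynaptic cell excitatory, second inhibitory
  cl <- apply_sign_constraints(W, sgn)
  expect_equal(cl, matrix(c(0, 0.4, 0, -0.2), 2, 2))
  expect_equal(apply_sign_constraints(cl, sgn), cl)
})

test_that("feedforward limit of the three-factor rule matches the true gradient", {
  set.seed(11)
  n_ctx <- 2; n_str <- 3; d <- 2
  W_cs <- matrix(rnorm(n_str * n_ctx, sd = 0.3), n_str, n_ctx)
  W_ss <- matrix(rnorm(d * n_str, sd = 0.5), d, n_str)
  r_ctx <- runif(n_ctx, 0.2, 0.8)
  target <- c(0.3, 0.7)
  err <- feedforward_gradient_check(W_cs, W_ss, r_ctx, target)
  expect_lt(err, 1e-5)
  # matched output: both the analytic update and the gradient vanish
  r_str <- sigmoid_rate(10 * as.vector(W_cs %*% r_ctx))
  t0 <- readout_rates(W_ss, r_str)
  expect_lt(feedforward_gradient_check(W_cs, W_ss, r_ctx, t0), 1e-4)
})

test_that("with feedback 'none' striatal weights are bitwise constant", {
  cfg <- small_config(feedback_variant = "none")
  res <- run_training(cfg)
  pr <- res$network$projections
  expect_identical(res$W_ctx_str, pr$CtxStr$W)
  expect_identical(res$W_thal_str, pr$ThalStr$W)
  expect_identical(res$W_str_str, pr$StrStr$W)
  expect_false(identical(res$W_str_snr, pr$StrSNr$W))  # readout still learns
})

test_that("Dale's law holds after training and on every readout snapshot", {
  cfg <- small_config(snapshot_every = 10)
  res <- run_training(cfg)
  expect_dale(res)
})

test_that("readout weights align to the class-sign-adjusted feedback matrix", {
  cfg <- sim_config(seed = 5, n_trials = 600, snapshot_every = 100)
  res <- run_training(cfg)
  al <- alignment_trajectory(res$snapshots, res$D, res$spn_class)
  expect_gt(al[length(al)], al[1])
})
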