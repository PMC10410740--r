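test_that("transfer function, membrane step, readout, loss and error code", {
  expect_equal(sigmoid_rate(2, b = 2), 0.5)
  expect_equal(sigmoid_rate(0, b = 2), 1 / (1 + exp(2)))
  expect_equal(sigmoid_rate(1e3, b = 2), 1)
  expect_true(all(diff(sigmoid_rate(seq(-10, 10, 0.5))) > 0))

  expect_equal(step_membrane(1, 0, dt = 1, tau_m = 10), 0.9)
  expect_equal(step_membrane(0, 0, dt = 1, tau_m = 10), 0)
  # fixed point under constant input is tau_m * I
  V <- 0
  for (i in 1:2000) V <- step_membrane(V, 0.3, 1, 10)
  expect_equal(V, 3, tolerance = 1e-10)
  expect_error(step_membrane(1, 0, dt = 10, tau_m = 10), "unstable")

  W <- matrix(0, 2, 3)
  expect_equal(readout_rates(W, c(0.1, 0.2, 0.3)), rep(1 / (1 + exp(2)), 2))
  W[1, 1] <- 0.5
  r1 <- readout_rates(W, c(0.5, 0.5, 0.5))
  W[1, 1] <- 1
  r2 <- readout_rates(W, c(0.5, 0.5, 0.5))
  expect_gt(r2[1], r1[1])
  expect_error(readout_rates(W, 1:4), "mismatch")
  # matches sigmoid of matrix-vector product
  set.seed(2)
  Wr <- matrix(rnorm(6), 2, 3); x <- runif(3)
  expect_equal(readout_rates(Wr, x), sigmoid_rate(as.vector(Wr %*% x)))

  expect_equal(output_loss(c(0.3, 0.3), c(0.3, 0.3)), 0)
  expect_equal(output_loss(c(1, 0, 0, 0), c(0, 0, 0, 0)), 0.5)
  expect_equal(output_loss(c(0.5, 0.5, 0.5, 0.5), c(0.6, 0.4, 0.5, 0.5)), 0.01)

  expect_equal(snc_error_rates(c(0.4, 0.7), c(0.4, 0.7)), c(0, 0))
  expect_equal(snc_error_rates(c(0, 1), c(0.5, 0.2)), c(0, 0))
  expect_equal(snc_error_rates(0.5, 0), 0.125)
  expect_lt(snc_error_rates(0.3, 0.5), 0)  # signed
})

test_that("incoming-weight balancing zeroes the sum and preserves signs", {
  b <- balance_weights(c(2, -1))
  expect_equal(b$weights, c(2, -2))
  expect_equal(sum(b$weights), 0)
  b2 <- balance_weights(c(1, 1, -3))
  expect_equal(b2$weights, c(1.5, 1.5, -3))
  expect_equal(balance_weights(c(1, -1))$weights, c(1, -1))  # fixed point
  one_sign <- balance_weights(c(0.5, 0.25))
  expect_false(one_sign$balanced)
  expect_equal(one_sign$weights, c(0.5, 0.25))
})

test_that("connectivity respects probabilities, signs, and balance", {
  cfg <- tiny_config()
  cfg$conn_prob[] <- 1
  net <- init_connectivity(cfg, seed = 4)
  for (pn in names(net$projections)) {
    pr <- net$projections[[pn]]
    if (pn == "CtxStr") {
      # only excitatory cortical cells project to striatum
      expect_true(all(pr$mask[, net$ctx_sign < 0] == 0))
      expect_true(all(pr$mask[, net$ctx_sign > 0] == 1))
    } else {
      expect_true(all(pr$mask == 1))
    }
    # Dale's law at initialization
    S <- matrix(pr$pre_sign, nrow(pr$W), ncol(pr$W), byrow = TRUE)
    expect_true(all(pr$W * S >= 0))
  }
  # zero probability -> empty projection
  cfg0 <- tiny_config()
  cfg0$conn_prob["ThalStr"] <- 0
  net0 <- init_connectivity(cfg0, seed = 4)
  expect_true(all(net0$projections$ThalStr$W == 0))
  # empirical density ~ Bernoulli(p)
  cfg2 <- sim_config(n_thal = 40, n_ctx = 80, n_dspn = 40, n_ispn = 40,
                     n_trials = 1, seed = 1)
  net2 <- init_connectivity(cfg2, seed = 7)
  dens <- mean(net2$projections$CtxCtx$mask)
  expect_equal(dens, 0.5, tolerance = 3 * sqrt(0.25 / 6400))
  # positions in the unit cube
  expect_true(all(net2$spn_positions >= 0 & net2$spn_positions <= 1))
  # per-neuron incoming sums are zero after balancing
  for (i in seq_len(cfg2$n_str)) {
    s <- sum(net2$projections$ThalStr$W[i, ]) +
      sum(net2$projections$CtxStr$W[i, ]) +
      sum(net2$projections$StrStr$W[i, ])
    expect_equal(s, 0, tolerance = 1e-10)
  }
  for (k in seq_len(cfg2$d)) {
    expect_equal(sum(net2$projections$StrSNr$W[k, ]), 0, tolerance = 1e-10)
  }
})

test_that("synchronous step matches the naive per-neuron loop oracle", {
  cfg <- tiny_config()
  net <- init_connectivity(cfg, seed = 3)
  code <- sample_thalamic_code(cfg$n_thal, 4, seed = 8)
  W <- lapply(net$projections, `[[`, "W")
  V_ctx <- rnorm(cfg$n_ctx, sd = 0.1); V_str <- rnorm(cfg$n_str, sd = 0.1)
  net$V_ctx <- V_ctx; net$V_str <- V_str
  state <- net
  for (s in 0:9) {
    ref <- naive_step(V_ctx, V_str, W, code, s * cfg$dt, cfg$trial_duration,
                      cfg$tau_m, cfg$b, cfg$dt)
    out <- step_network(state, code, s * cfg$dt)
    expect_equal(out$r_snr, ref$r_snr, tolerance = 1e-12)
    expect_equal(out$state$V_ctx, ref$V_ctx, tolerance = 1e-12)
    expect_equal(out$state$V_str, ref$V_str, tolerance = 1e-12)
    state <- out$state
    V_ctx <- ref$V_ctx; V_str <- ref$V_str
  }
})

test_that("pre-training dynamics stay bounded over 1e5 steps", {
  cfg <- sim_config(n_trials = 500, seed = 6, feedback_variant = "none")
  cfg$beta <- 0  # no plasticity anywhere: raw reservoir dynamics
  res <- run_training(cfg)
  expect_true(all(is.finite(res$per_trial_loss)))
  expect_true(all(res$rec_str > 0 & res$rec_str < 1))
  expect_true(all(res$rec_snr > 0 & res$rec_snr < 1))
})

test_that("with all weights zero the network decays to the sigmoid baseline", {
  cfg <- tiny_config()
  cfg$w_max[] <- 0
  net <- init_connectivity(cfg, seed = 2)
  net$V_ctx <- rep(1, cfg$n_ctx)
  code <- sample_thalamic_code(cfg$n_thal, 4, seed = 8)
  state <- net
  for (s in 0:199) state <- step_network(state, code, s)$state
  expect_equal(state$V_ctx, rep(1 * 0.9^200, cfg$n_ctx))
  expect_equal(sigmoid_rate(state$V_str), rep(sigmoid_rate(0), cfg$n_str))
})
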