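# Independent oracles, written as naive scalar loops so that agreement with
# the vectorized/compiled implementation is informative.

# One synchronous dynamics step computed neuron by neuron, synapse by synapse.
naive_step <- function(V_ctx, V_str, W, code, t, T_period, tau_m, b, dt) {
  phi <- function(v) 1 / (1 + exp(-v + b))
  n_thal <- length(code$A)
  r_thal <- numeric(n_thal)
  for (m in seq_len(n_thal)) {
    r_thal[m] <- phi(code$A[m] * cos(2 * pi * t / T_period) +
                       code$B[m] * sin(2 * pi * t / T_period))
  }
  r_ctx <- vapply(V_ctx, phi, numeric(1))
  r_str <- vapply(V_str, phi, numeric(1))
  d <- nrow(W$StrSNr)
  r_snr <- numeric(d)
  for (k in seq_len(d)) {
    s <- 0
    for (j in seq_along(r_str)) s <- s + W$StrSNr[k, j] * r_str[j]
    r_snr[k] <- phi(s)
  }
  V_ctx_new <- V_ctx
  for (i in seq_along(V_ctx)) {
    inp <- 0
    for (m in seq_len(n_thal)) inp <- inp + W$ThalCtx[i, m] * r_thal[m]
    for (j in seq_along(r_ctx)) inp <- inp + W$CtxCtx[i, j] * r_ctx[j]
    V_ctx_new[i] <- V_ctx[i] + dt * (-V_ctx[i] / tau_m + inp)
  }
  V_str_new <- V_str
  for (i in seq_along(V_str)) {
    inp <- 0
    for (m in seq_len(n_thal)) inp <- inp + W$ThalStr[i, m] * r_thal[m]
    for (j in seq_along(r_ctx)) inp <- inp + W$CtxStr[i, j] * r_ctx[j]
    for (j in seq_along(r_str)) inp <- inp + W$StrStr[i, j] * r_str[j]
    V_str_new[i] <- V_str[i] + dt * (-V_str[i] / tau_m + inp)
  }
  list(V_ctx = V_ctx_new, V_str = V_str_new, r_thal = r_thal, r_ctx = r_ctx,
       r_str = r_str, r_snr = r_snr)
}

# Central finite difference of a scalar function of one weight entry.
brute_force_gradient <- function(f, W, i, j, h = 1e-6) {
  Wp <- W; Wp[i, j] <- Wp[i, j] + h
  Wm <- W; Wm[i, j] <- Wm[i, j] - h
  (f(Wp) - f(Wm)) / (2 * h)
}

# Dale's-law audit of the final (and snapshot) weights of a run.
expect_dale <- function(res) {
  cls_sign <- ifelse(res$spn_class == "dSPN", -1, 1)
  expect_true(all(res$W_thal_str >= 0))
  expect_true(all(res$W_ctx_str >= 0))
  expect_true(all(res$W_str_str <= 0))
  for (W in res$snapshots) {
    expect_true(all(sweep(W, 2, cls_sign, `*`) >= 0))
  }
  # masked-out synapses never acquire weight
  pr <- res$network$projections
  expect_true(all(res$W_ctx_str[pr$CtxStr$mask == 0] == 0))
  expect_true(all(res$W_str_snr[pr$StrSNr$mask == 0] == 0))
}
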