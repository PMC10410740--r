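#' Update eligibility traces
#'
#' The synapse-specific factor of the three-factor rule: a low-pass filtered
#' Hebbian product, \eqn{\tau_{Str}\, \dot p_{ji} = -p_{ji} + r_j^{Str}(1 -
#' r_j^{Str})\, r_i^{pre}}, Euler-integrated with the simulation step. The
#' same form applies to corticostriatal, thalamostriatal, and striatostriatal
#' synapses with the appropriate presynaptic rates. Traces are maintained
#' only for existing synapses (`mask`).
#'
#' @param p eligibility matrix, `n_str x n_pre`.
#' @param r_str postsynaptic striatal rates (length `n_str`).
#' @param r_pre presynaptic rates (length `n_pre`).
#' @param dt time step in ms.
#' @param tau_str eligibility time constant in ms (> 0).
#' @param mask 0/1 synapse-existence matrix, or `NULL` for all-existing.
#' @return Updated eligibility matrix.
#' @export
update_eligibility <- function(p, r_str, r_pre, dt, tau_str, mask = NULL) {
  if (tau_str <= 0) stop("tau_str must be positive")
  drive <- (r_str * (1 - r_str)) %o% r_pre
  if (!is.null(mask)) drive <- drive * mask
  p + (dt / tau_str) * (-p + drive)
}

#' Dopamine-gated striatal weight update
#'
#' Three-factor update for a plastic striatal-afferent or striatostriatal
#' projection: \eqn{\Delta w_{ji} = -\alpha_j\, p_{ji}\, a_j\, dt}, where
#' `a_j` is the per-SPN dopamine signal delivered by the feedback field
#' (variant-dependent, possibly filtered/compensated) and \eqn{\alpha_j} is
#' negative for dSPNs and positive for iSPNs (D1 vs. D2 receptor effects).
#' Updates apply only to existing synapses and are followed by sign clamping
#' ([apply_sign_constraints()]).
#'
#' @param W weight matrix, `n_str x n_pre`.
#' @param p eligibility matrix, same shape.
#' @param dopamine_per_spn per-SPN dopamine signal (length `n_str`).
#' @param alpha_per_spn per-SPN learning rate (length `n_str`).
#' @param dt time step in ms.
#' @param mask 0/1 synapse-existence matrix, or `NULL`.
#' @param sign projection sign: `+1` (excitatory afferents) or `-1`
#'   (striatostriatal inhibition), used for clamping.
#' @return Updated, sign-clamped weight matrix.
#' @export
striatal_weight_update <- function(W, p, dopamine_per_spn, alpha_per_spn, dt,
                                   mask = NULL, sign = 1) {
  if (!all(dim(W) == dim(p))) stop("shape mismatch between W and p")
  if (length(dopamine_per_spn) != nrow(W)) stop("dopamine vector length mismatch")
  dW <- -(alpha_per_spn * dopamine_per_spn) * p * dt
  if (!is.null(mask)) dW <- dW * mask
  if (!all(is.finite(dW))) stop("non-finite striatal weight update")
  apply_sign_constraints(W + dW, rep(sign, ncol(W)))
}

#' Delta-rule update of the striatofugal readout weights
#'
#' \eqn{\Delta w_{kj} = -\beta\, \epsilon_k\, r_j^{Str}\, dt}: the exact
#' negative gradient of the instantaneous loss with respect to the readout
#' weights (scaled by \eqn{\beta}), since \eqn{\epsilon_k = (r_k - T_k) r_k
#' (1 - r_k)} already contains the readout sigmoid derivative. Applied to
#' existing synapses and sign-clamped per SPN class.
#'
#' @param W readout weight matrix, `d x n_str`.
#' @param epsilon SNc error vector (length `d`).
#' @param r_str striatal rates (length `n_str`).
#' @param beta learning rate (per ms).
#' @param dt time step in ms.
#' @param pre_sign per-SPN outgoing sign (length `n_str`; -1 dSPN, +1 iSPN).
#' @param mask 0/1 matrix or `NULL`.
#' @return Updated, sign-clamped weight matrix.
#' @export
striatofugal_update <- function(W, epsilon, r_str, beta, dt, pre_sign,
                                mask = NULL) {
  if (length(epsilon) != nrow(W) || length(r_str) != ncol(W)) {
    stop("shape mismatch")
  }
  dW <- -beta * dt * (epsilon %o% r_str)
  if (!is.null(mask)) dW <- dW * mask
  apply_sign_constraints(W + dW, pre_sign)
}

#' Enforce Dale's law by sign clamping
#'
#' Weights whose sign would cross that of their presynaptic cell class are
#' clamped to zero (the synapse stays in the mask and may regrow): excitatory
#' weights are floored at 0 from below, inhibitory weights capped at 0 from
#' above.
#'
#' @param W weight matrix, `n_post x n_pre`.
#' @param pre_sign per-presynaptic-cell sign vector (length `n_pre`).
#' @return Clamped weight matrix.
#' @export
apply_sign_constraints <- function(W, pre_sign) {
  S <- matrix(pre_sign, nrow(W), ncol(W), byrow = TRUE)
  S * pmax(S * W, 0)
}

#' Gradient check of the feedforward plasticity rule
#'
#' Validates that, in the no-recurrence, steady-state limit with ideal
#' feedback, the three-factor update direction equals the true gradient of
#' the instantaneous loss with respect to the corticostriatal weights.
#' A small feedforward chain Ctx -> Str -> SNr is evaluated at its fixed
#' point: \eqn{V_j^* = \tau_m \sum_i w_{ji} r_i}, \eqn{r_j = \phi(V_j^*)},
#' readout \eqn{r_k = \phi(\sum_j w_{kj} r_j)}. With the eligibility trace at
#' its own fixed point \eqn{p_{ji}^* = r_j(1-r_j) r_i} and ideal feedback
#' \eqn{\gamma_j = \sum_k \epsilon_k w_{kj}}, the analytic update
#' \eqn{\gamma_j\, p_{ji}^*\, \tau_m} (the membrane gain \eqn{\tau_m} is the
#' steady-state sensitivity of \eqn{V_j} to its input) is compared against a
#' central finite difference of the loss through the full fixed-point map.
#'
#' @param W_ctx_str feedforward weights, `n_str x n_ctx`.
#' @param W_str_snr readout weights, `d x n_str`.
#' @param r_ctx fixed presynaptic cortical rates (length `n_ctx`).
#' @param target target vector (length `d`).
#' @param tau_m membrane time constant in ms.
#' @param b sigmoid offset.
#' @param h finite-difference step.
#' @return Max relative error between the analytic and numerical gradients
#'   over all feedforward weights.
#' @export
feedforward_gradient_check <- function(W_ctx_str, W_str_snr, r_ctx, target,
                                       tau_m = 10, b = 2, h = 1e-6) {
  loss_of <- function(W) {
    r_str <- sigmoid_rate(tau_m * as.vector(W %*% r_ctx), b = b)
    r_snr <- readout_rates(W_str_snr, r_str, b = b)
    output_loss(r_snr, target)
  }
  r_str <- sigmoid_rate(tau_m * as.vector(W_ctx_str %*% r_ctx), b = b)
  r_snr <- readout_rates(W_str_snr, r_str, b = b)
  eps <- snc_error_rates(r_snr, target)
  gamma <- as.vector(t(W_str_snr) %*% eps)
  p_star <- (r_str * (1 - r_str)) %o% r_ctx
  analytic <- tau_m * gamma * p_star

  max_rel <- 0
  for (j in seq_len(nrow(W_ctx_str))) {
    for (i in seq_len(ncol(W_ctx_str))) {
      Wp <- W_ctx_str; Wp[j, i] <- Wp[j, i] + h
      Wm <- W_ctx_str; Wm[j, i] <- Wm[j, i] - h
      num <- (loss_of(Wp) - loss_of(Wm)) / (2 * h)
      # scale floor keeps the ratio meaningful when both sides vanish
      rel <- abs(num - analytic[j, i]) /
        max(abs(num), abs(analytic[j, i]), 1e-6)
      max_rel <- max(max_rel, rel)
    }
  }
  max_rel
}
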