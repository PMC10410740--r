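#' Shifted logistic transfer function
#'
#' Firing rate as a function of membrane potential:
#' \eqn{\phi(V) = 1 / (1 + e^{-V + b})}. The offset `b` (default 2) shifts the
#' sigmoid to the right so rates are sparse when excitation and inhibition are
#' balanced and potentials fluctuate around zero.
#'
#' @param V membrane potential (vector).
#' @param b sigmoid offset.
#' @return Rates in (0, 1).
#' @export
#' @examples
#' sigmoid_rate(2, b = 2) # 0.5 at the midpoint
sigmoid_rate <- function(V, b = 2) {
  1 / (1 + exp(-V + b))
}

#' One forward-Euler membrane update
#'
#' Leaky integration \eqn{V \leftarrow V + dt(-V/\tau_m + I)}, where `I` is
#' the summed presynaptic weighted rate input at the current step. With zero
#' input the potential decays geometrically by \eqn{1 - dt/\tau_m} per step;
#' under constant input it converges to \eqn{\tau_m I}.
#'
#' @param V membrane potentials (vector).
#' @param input_current summed weighted presynaptic rates (vector).
#' @param dt time step in ms.
#' @param tau_m membrane time constant in ms (must exceed `dt`).
#' @return Updated potentials.
#' @export
step_membrane <- function(V, input_current, dt, tau_m) {
  if (dt >= tau_m) stop("unstable configuration: dt must be smaller than tau_m")
  V + dt * (-V / tau_m + input_current)
}

#' Readout (GPi/SNr) rates
#'
#' The readout population is memoryless: \eqn{r_k = \phi(\sum_j w_{kj}
#' r_j^{Str})}, with no membrane integration.
#'
#' @param W_str_snr readout weight matrix, `d x n_str`.
#' @param r_str striatal rates (length `n_str`).
#' @param b sigmoid offset.
#' @return Readout rates (length `d`).
#' @export
readout_rates <- function(W_str_snr, r_str, b = 2) {
  if (ncol(W_str_snr) != length(r_str)) {
    stop("dimension mismatch between readout weights and striatal rates")
  }
  sigmoid_rate(as.vector(W_str_snr %*% r_str), b = b)
}

#' Instantaneous squared-error loss
#'
#' \eqn{\ell(t) = \frac{1}{2}\sum_k (r_k - T_k)^2} between the readout rates
#' and the target at one time step.
#'
#' @param r_snr readout rates (length `d`).
#' @param target target values (length `d`).
#' @return Nonnegative scalar; zero iff the output matches the target exactly.
#' @export
output_loss <- function(r_snr, target) {
  if (length(r_snr) != length(target)) stop("length mismatch")
  0.5 * sum((r_snr - target)^2)
}

#' SNc error rates
#'
#' The dopamine population encodes the error \eqn{\epsilon_k = (r_k - T_k)
#' r_k (1 - r_k)} — the loss gradient through the readout sigmoid. Negative
#' values are interpreted as deviations below a baseline firing rate.
#'
#' @param r_snr readout rates (length `d`).
#' @param target target values (length `d`).
#' @return Signed error vector (length `d`).
#' @export
snc_error_rates <- function(r_snr, target) {
  if (length(r_snr) != length(target)) stop("length mismatch")
  (r_snr - target) * r_snr * (1 - r_snr)
}

#' Balance one neuron's incoming weights
#'
#' If the signed sum of a neuron's incoming weights is positive, all its
#' inhibitory weights are scaled up uniformly so the sum is exactly zero;
#' if negative, the excitatory weights are scaled up. Signs are preserved.
#' A neuron with inputs of only one sign cannot be balanced and is returned
#' unchanged with a warning-free `balanced = FALSE` flag.
#'
#' @param w signed incoming weight vector (zeros allowed for absent synapses).
#' @return List with `weights` (adjusted vector) and `balanced` (logical).
#' @export
#' @examples
#' balance_weights(c(2, -1))$weights # -1 scaled to -2
balance_weights <- function(w) {
  s <- sum(w)
  if (s == 0) return(list(weights = w, balanced = TRUE))
  exc <- w > 0
  inh <- w < 0
  if (s > 0) {
    if (!any(inh)) return(list(weights = w, balanced = FALSE))
    f <- sum(w[exc]) / -sum(w[inh])
    w[inh] <- w[inh] * f
  } else {
    if (!any(exc)) return(list(weights = w, balanced = FALSE))
    f <- -sum(w[inh]) / sum(w[exc])
    w[exc] <- w[exc] * f
  }
  list(weights = w, balanced = TRUE)
}

# Build one signed sparse projection. `pre_sign` gives the sign (+1/-1) of
# each presynaptic neuron's outgoing synapses; `pre_pool` restricts which
# presynaptic columns may form synapses at all.
make_projection <- function(source, target, n_post, n_pre, p, w_max,
                            pre_sign, plastic, pre_pool = NULL) {
  mask <- matrix(rbinom(n_post * n_pre, 1L, p), n_post, n_pre)
  if (!is.null(pre_pool)) mask[, !pre_pool] <- 0L
  W <- matrix(runif(n_post * n_pre, 0, w_max / n_post), n_post, n_pre)
  W <- W * mask * matrix(pre_sign, n_post, n_pre, byrow = TRUE)
  list(source = source, target = target, W = W, mask = mask,
       pre_sign = pre_sign, plastic = plastic)
}

#' Initialize network connectivity and state
#'
#' Draws the sparse, sign-constrained connectivity: for every ordered cell
#' pair in every projection an independent Bernoulli draw with the
#' projection's connection probability decides whether a synapse exists;
#' existing weights are uniform on `[0, w_max/N_post]`, multiplied by -1 for
#' inhibitory presynaptic cells. The cortical reservoir contains a fixed
#' inhibitory subpopulation (fraction `ctx_inhib_frac`); only excitatory
#' cortical cells project to the striatum. dSPN columns of the readout are
#' inhibitory, iSPN columns excitatory. SPN positions are uniform in the unit
#' cube. After construction, every cortical, striatal, and readout neuron has
#' its incoming weights balanced to a zero sum ([balance_weights()]).
#'
#' @param cfg a [sim_config()] object.
#' @param seed integer seed for the connectivity stage.
#' @return An object of class `"network_state"`: projections (named list of
#'   signed projections), `spn_positions` (`n_str x 3`), `ctx_sign`,
#'   `spn_class` (`"dSPN"`/`"iSPN"` per striatal cell), membrane potentials
#'   `V_ctx`, `V_str` (zeros), and `cfg` echo.
#' @export
init_connectivity <- function(cfg, seed = cfg$seed) {
  validate_sim_config(cfg)
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(seed)

  n_ctx_inh <- max(1L, round(cfg$ctx_inhib_frac * cfg$n_ctx))
  ctx_sign <- c(rep(1, cfg$n_ctx - n_ctx_inh), rep(-1, n_ctx_inh))
  spn_class <- c(rep("dSPN", cfg$n_dspn), rep("iSPN", cfg$n_ispn))
  str_out_sign <- ifelse(spn_class == "dSPN", -1, 1)

  p <- cfg$conn_prob
  wm <- cfg$w_max
  projections <- list(
    ThalCtx = make_projection("Thal", "Ctx", cfg$n_ctx, cfg$n_thal,
                              p["ThalCtx"], wm["ThalCtx"],
                              rep(1, cfg$n_thal), plastic = FALSE),
    CtxCtx = make_projection("Ctx", "Ctx", cfg$n_ctx, cfg$n_ctx,
                             p["CtxCtx"], wm["CtxCtx"],
                             ctx_sign, plastic = FALSE),
    ThalStr = make_projection("Thal", "Str", cfg$n_str, cfg$n_thal,
                              p["ThalStr"], wm["ThalStr"],
                              rep(1, cfg$n_thal), plastic = TRUE),
    CtxStr = make_projection("Ctx", "Str", cfg$n_str, cfg$n_ctx,
                             p["CtxStr"], wm["CtxStr"],
                             rep(1, cfg$n_ctx), plastic = TRUE,
                             pre_pool = ctx_sign > 0),
    StrStr = make_projection("Str", "Str", cfg$n_str, cfg$n_str,
                             p["StrStr"], wm["StrStr"],
                             rep(-1, cfg$n_str), plastic = TRUE),
    StrSNr = make_projection("Str", "SNr", cfg$d, cfg$n_str,
                             p["StrSNr"], wm["StrSNr"],
                             str_out_sign, plastic = TRUE)
  )

  spn_positions <- matrix(runif(cfg$n_str * 3), cfg$n_str, 3,
                          dimnames = list(NULL, c("x", "y", "z")))

  state <- structure(
    list(projections = projections, spn_positions = spn_positions,
         ctx_sign = ctx_sign, spn_class = spn_class,
         V_ctx = rep(0, cfg$n_ctx), V_str = rep(0, cfg$n_str),
         cfg = cfg, seed = seed),
    class = "network_state"
  )
  balance_network(state)
}

# Apply the zero-sum balancing rule to every postsynaptic neuron, pooling
# incoming weights across all projections that target its population.
balance_network <- function(state) {
  targets <- list(
    Ctx = c("ThalCtx", "CtxCtx"),
    Str = c("ThalStr", "CtxStr", "StrStr"),
    SNr = "StrSNr"
  )
  for (popname in names(targets)) {
    projs <- targets[[popname]]
    n_post <- nrow(state$projections[[projs[1]]]$W)
    for (i in seq_len(n_post)) {
      w <- unlist(lapply(projs, function(pn) state$projections[[pn]]$W[i, ]))
      bal <- balance_weights(w)
      offset <- 0L
      for (pn in projs) {
        k <- ncol(state$projections[[pn]]$W)
        state$projections[[pn]]$W[i, ] <- bal$weights[offset + seq_len(k)]
        offset <- offset + k
      }
    }
  }
  state
}

#' @export
print.network_state <- function(x, ...) {
  cat("<network_state>\n")
  for (pn in names(x$projections)) {
    pr <- x$projections[[pn]]
    cat(sprintf("  %s -> %s (%s): %d x %d, density %.2f%s\n",
                pr$source, pr$target, pn, nrow(pr$W), ncol(pr$W),
                mean(pr$mask), if (pr$plastic) ", plastic" else ""))
  }
  invisible(x)
}

#' One synchronous simulation step (reference implementation)
#'
#' Advances the network by one forward-Euler step using the fixed update
#' order: (1) thalamic rates are imposed from the clock code, cortical and
#' striatal rates computed from the current membrane potentials; (2) readout
#' rates and the SNc error vector are computed; (3) the returned rates are
#' those current-step values; (4) membrane potentials are Euler-updated with
#' the current-step rates (synchronous update). This function performs no
#' plasticity; it is the dynamics kernel used by the pure-R reference engine
#' and for oracle testing of the compiled training loop.
#'
#' @param state a `"network_state"`.
#' @param code a `"thalamic_code"`.
#' @param t current time in ms (global, not trial-wrapped).
#' @param target target vector at this step (length `d`), or `NULL` to skip
#'   error computation.
#' @return List with the updated `state` and the current-step `r_thal`,
#'   `r_ctx`, `r_str`, `r_snr`, `epsilon`.
#' @export
step_network <- function(state, code, t, target = NULL) {
  cfg <- state$cfg
  pr <- state$projections
  r_thal <- thalamic_rates(code, t %% cfg$trial_duration, cfg$trial_duration,
                           b = cfg$b)
  r_ctx <- sigmoid_rate(state$V_ctx, b = cfg$b)
  r_str <- sigmoid_rate(state$V_str, b = cfg$b)
  r_snr <- readout_rates(pr$StrSNr$W, r_str, b = cfg$b)
  eps <- if (is.null(target)) NULL else snc_error_rates(r_snr, target)

  I_ctx <- as.vector(pr$ThalCtx$W %*% r_thal + pr$CtxCtx$W %*% r_ctx)
  I_str <- as.vector(pr$ThalStr$W %*% r_thal + pr$CtxStr$W %*% r_ctx +
                       pr$StrStr$W %*% r_str)
  state$V_ctx <- step_membrane(state$V_ctx, I_ctx, cfg$dt, cfg$tau_m)
  state$V_str <- step_membrane(state$V_str, I_str, cfg$dt, cfg$tau_m)
  if (!all(is.finite(state$V_ctx)) || !all(is.finite(state$V_str))) {
    stop("non-finite membrane potential at t = ", t)
  }
  list(state = state, r_thal = r_thal, r_ctx = r_ctx, r_str = r_str,
       r_snr = r_snr, epsilon = eps)
}
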