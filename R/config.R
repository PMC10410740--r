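#' Simulation configuration
#'
#' Builds the full parameter set for one training run: population sizes,
#' dynamics constants, connectivity statistics, plasticity rates, the dopamine
#' diffusion field, the feedback variant, and seeds. Defaults follow the
#' reference model: membrane time constant 10 ms, sigmoid offset 2, 1 ms
#' forward-Euler steps, 200 ms trials, Gaussian-process targets with
#' \eqn{\tau_{task} = 20} ms, dopamine length scale \eqn{\lambda = 0.1} (in
#' units of the striatal cube side) with 10 varicosities per SNc neuron, and
#' learning rates \eqn{\alpha = -2.5\times 10^{-2}} (dSPN),
#' \eqn{+2.5\times 10^{-2}} (iSPN), \eqn{\beta = 10^{-3}} per ms.
#'
#' Population sizes and maximum initial weights are profile-dependent. The
#' `"desk"` profile (default) is a reduced network for interactive work and
#' testing; `"paper"` is the full-scale configuration (5,000 trials). The
#' architecture has six projections: Thal->Ctx, Ctx->Ctx (static cortical
#' reservoir with an inhibitory subpopulation), Thal->Str, Ctx->Str, Str->Str
#' (inhibitory), and the fully connected readout Str->SNr (dSPNs inhibitory,
#' iSPNs excitatory, the indirect pathway being collapsed onto a direct
#' excitatory projection).
#'
#' @param profile `"desk"` or `"paper"`; sets population sizes and trial count.
#' @param d output dimensionality; also the number of SNr readout and SNc
#'   dopamine neurons.
#' @param n_trials number of consecutive target presentations (no state reset
#'   between trials).
#' @param feedback_variant one of `"heterogeneous"` (diffusion-derived feedback
#'   matrix D), `"homogeneous"` (every SPN receives the same scalar signal),
#'   `"shuffled"` (entries of D randomly permuted once), `"ideal"` (feedback is
#'   the current transposed readout weights), `"none"` (striatal plasticity
#'   disabled; only the readout learns).
#' @param lambda_da dopamine diffusion length scale, relative to the cube side.
#' @param n_varicosities varicosities per SNc neuron.
#' @param tau_da dopamine low-pass filter time constant in ms, or `NULL` for
#'   instantaneous dopamine.
#' @param highpass_compensation if `TRUE`, each synapse high-pass filters its
#'   local dopamine concentration (forward-inhibition motif), undoing the
#'   low-pass filter.
#' @param lowpass_unnormalized if `TRUE`, use the raw exponential-convolution
#'   low-pass filter (DC gain \eqn{\tau_{DA}/dt}) instead of the normalized
#'   (unit-DC-gain) form. Only affects runs with a finite `tau_da`.
#' @param lesions named character vector mapping a plastic projection
#'   (`"CtxStr"`, `"ThalStr"`, `"StrStr"`, `"StrSNr"`) to `"static"` (weights
#'   frozen) or `"absent"` (weights removed).
#' @param seed master seed; all stage seeds (targets, thalamic code,
#'   connectivity, varicosities, shuffle) are derived from it.
#' @param n_record_trials number of final trials for which striatal and
#'   readout rates are recorded.
#' @param snapshot_every record the readout weight matrix every this many
#'   trials (0 = only initial and final).
#' @param ... overrides for any other field (population sizes `n_thal`,
#'   `n_ctx`, `n_dspn`, `n_ispn`; `tau_m`, `b`, `dt`, `trial_duration`,
#'   `tau_task`, `tau_str`, `alpha_d`, `alpha_i`, `beta`, `thalamic_radius`,
#'   `target_mean`, `target_sd`, `ctx_inhib_frac`, `conn_prob`, `w_max`).
#'
#' @return An object of class `"sim_config"` (a validated named list).
#' @export
#' @examples
#' cfg <- sim_config(n_trials = 5, seed = 1)
#' cfg$n_str
sim_config <- function(profile = c("desk", "paper"),
                       d = 4L,
                       n_trials = NULL,
                       feedback_variant = c("heterogeneous", "homogeneous",
                                            "shuffled", "ideal", "none"),
                       lambda_da = 0.1,
                       n_varicosities = 10L,
                       tau_da = NULL,
                       highpass_compensation = FALSE,
                       lowpass_unnormalized = FALSE,
                       lesions = NULL,
                       seed = 1L,
                       n_record_trials = 5L,
                       snapshot_every = 0L,
                       ...) {
  profile <- match.arg(profile)
  feedback_variant <- match.arg(feedback_variant)

  sizes <- switch(profile,
    desk  = list(n_thal = 30L, n_ctx = 60L, n_dspn = 40L, n_ispn = 40L,
                 n_trials = 1000L),
    paper = list(n_thal = 40L, n_ctx = 100L, n_dspn = 50L, n_ispn = 50L,
                 n_trials = 5000L)
  )

  cfg <- list(
    profile = profile,
    n_thal = sizes$n_thal,
    n_ctx = sizes$n_ctx,
    n_dspn = sizes$n_dspn,
    n_ispn = sizes$n_ispn,
    d = as.integer(d),
    tau_m = 10,
    b = 2,
    dt = 1,
    trial_duration = 200,
    n_trials = if (is.null(n_trials)) sizes$n_trials else as.integer(n_trials),
    tau_task = 20,
    tau_str = 10,
    alpha_d = -2.5e-2,
    alpha_i = +2.5e-2,
    beta = 1e-3,
    lambda_da = lambda_da,
    n_varicosities = as.integer(n_varicosities),
    tau_da = tau_da,
    highpass_compensation = isTRUE(highpass_compensation),
    lowpass_unnormalized = isTRUE(lowpass_unnormalized),
    feedback_variant = feedback_variant,
    lesions = lesions,
    thalamic_radius = 4,
    target_mean = 0.5,
    target_sd = 0.15,
    gp_jitter = 1e-8,
    ctx_inhib_frac = 0.5,
    # Connection probability per projection; the readout is fully connected,
    # everything else sparse.
    conn_prob = c(ThalCtx = 0.5, CtxCtx = 0.5, ThalStr = 0.5,
                  CtxStr = 0.5, StrStr = 0.5, StrSNr = 1.0),
    # Maximum initial weight per projection; an inserted synapse draws
    # Uniform[0, w_max / N_post] (times -1 for inhibitory projections).
    # Chosen so the untrained balanced network sits in a rich, near-chaotic
    # regime (see the package vignette).
    w_max = c(ThalCtx = 8, CtxCtx = 20, ThalStr = 8,
              CtxStr = 10, StrStr = 10, StrSNr = 2),
    seed = as.integer(seed),
    n_record_trials = as.integer(n_record_trials),
    snapshot_every = as.integer(snapshot_every)
  )

  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown) > 0) {
    stop("unknown sim_config field(s): ", paste(unknown, collapse = ", "))
  }
  for (nm in names(dots)) {
    if (nm %in% c("conn_prob", "w_max")) {
      ov <- dots[[nm]]
      cfg[[nm]][names(ov)] <- ov
    } else {
      cfg[[nm]] <- dots[[nm]]
    }
  }
  cfg$n_thal <- as.integer(cfg$n_thal)
  cfg$n_ctx <- as.integer(cfg$n_ctx)
  cfg$n_dspn <- as.integer(cfg$n_dspn)
  cfg$n_ispn <- as.integer(cfg$n_ispn)
  cfg$n_str <- cfg$n_dspn + cfg$n_ispn
  cfg$n_steps <- as.integer(round(cfg$trial_duration / cfg$dt))

  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

#' Validate a simulation configuration
#'
#' Checks the structural invariants: positive counts, probabilities in
#' \[0, 1\], dt dividing the trial duration, dt below the membrane time
#' constant (forward-Euler stability), a positive dopamine length scale, and
#' well-formed lesion specifications.
#'
#' @param cfg a `"sim_config"` object.
#' @return `cfg`, invisibly, or an error.
#' @export
validate_sim_config <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  counts <- c(cfg$n_thal, cfg$n_ctx, cfg$n_dspn, cfg$n_ispn, cfg$d,
              cfg$n_trials)
  if (any(counts < 1)) stop("all population counts and n_trials must be >= 1")
  if (abs(cfg$n_steps * cfg$dt - cfg$trial_duration) > 1e-9) {
    stop("dt must divide trial_duration exactly")
  }
  if (cfg$dt >= cfg$tau_m) {
    stop("unstable configuration: dt must be smaller than tau_m")
  }
  if (any(cfg$conn_prob < 0 | cfg$conn_prob > 1)) {
    stop("connection probabilities must lie in [0, 1]")
  }
  if (any(cfg$w_max < 0)) stop("w_max must be nonnegative")
  if (cfg$lambda_da <= 0) stop("lambda_da must be positive")
  if (cfg$n_varicosities < 1) stop("n_varicosities must be >= 1")
  if (!is.null(cfg$tau_da) && cfg$tau_da <= 0) {
    stop("tau_da must be positive (or NULL for instantaneous dopamine)")
  }
  if (cfg$highpass_compensation && is.null(cfg$tau_da)) {
    stop("highpass_compensation requires a finite tau_da")
  }
  if (!is.null(cfg$lesions)) {
    plast <- c("CtxStr", "ThalStr", "StrStr", "StrSNr")
    if (!all(names(cfg$lesions) %in% plast)) {
      stop("lesions must name plastic projections: ",
           paste(plast, collapse = ", "))
    }
    if (!all(cfg$lesions %in% c("static", "absent"))) {
      stop("lesion modes are 'static' or 'absent'")
    }
  }
  if (cfg$ctx_inhib_frac <= 0 || cfg$ctx_inhib_frac >= 1) {
    stop("ctx_inhib_frac must be in (0, 1)")
  }
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>", x$profile, "profile\n")
  cat(sprintf("  populations: Thal %d | Ctx %d | Str %d (%d dSPN + %d iSPN) | SNr/SNc %d\n",
              x$n_thal, x$n_ctx, x$n_str, x$n_dspn, x$n_ispn, x$d))
  cat(sprintf("  trials: %d x %g ms (dt %g ms), tau_m %g ms, tau_task %g ms\n",
              x$n_trials, x$trial_duration, x$dt, x$tau_m, x$tau_task))
  cat(sprintf("  dopamine: variant '%s', lambda %g, %d varicosities/SNc, tau_da %s%s\n",
              x$feedback_variant, x$lambda_da, x$n_varicosities,
              if (is.null(x$tau_da)) "instantaneous" else paste0(x$tau_da, " ms"),
              if (x$highpass_compensation) " (high-pass compensated)" else ""))
  if (!is.null(x$lesions)) {
    cat("  lesions:", paste(names(x$lesions), x$lesions, sep = "=",
                            collapse = ", "), "\n")
  }
  cat(sprintf("  seed: %d\n", x$seed))
  invisible(x)
}

# Derive independent stage seeds from the master seed. Deterministic, and all
# values stay below 2^31.
derive_seeds <- function(seed) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  s <- sample.int(.Machine$integer.max - 1L, 5L)
  names(s) <- c("targets", "thalamic", "connectivity", "varicosities", "shuffle")
  s
}
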