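#' Train a network on its target set
#'
#' Runs one complete training experiment: samples the Gaussian-process
#' targets and the thalamic clock code, initializes the balanced
#' sign-constrained connectivity and SPN positions, builds the dopamine
#' feedback field, then simulates `n_trials` consecutive trials (no state
#' reset) with online three-factor plasticity in the striatal projections and
#' the delta rule in the striatofugal readout. Everything is deterministic
#' given `cfg$seed`.
#'
#' The per-trial loss is the time-integral of the instantaneous squared
#' error, \eqn{\sum_t \ell(t)\, dt} over the trial.
#'
#' @param cfg a [sim_config()] object.
#' @param engine `"cpp"` (default, compiled loop) or `"r"` (pure-R reference
#'   implementation built from the exported single-step operations; identical
#'   results, only practical for tiny configurations).
#' @return An object of class `"run_result"`: `per_trial_loss`, final plastic
#'   weights, rate recordings of the first trial (`rec_first_snr`) and the
#'   last `n_record_trials` trials (`rec_str`, `rec_snr`), readout weight
#'   `snapshots` (list of matrices) with `snapshot_trials`, the feedback
#'   matrices `D` (diffusion-derived) and `D_eff` (variant-resolved),
#'   `spn_positions`, `spn_class`, the `targets`, `code`, `network` (initial
#'   state), `cfg` and derived `seeds`.
#' @export
#' @examples
#' cfg <- sim_config(n_trials = 3, seed = 1)
#' res <- run_training(cfg)
#' length(res$per_trial_loss)
run_training <- function(cfg, engine = c("cpp", "r")) {
  engine <- match.arg(engine)
  validate_sim_config(cfg)
  seeds <- derive_seeds(cfg$seed)

  targets <- sample_target_set(cfg$d, cfg$trial_duration, cfg$dt,
                               cfg$tau_task, seeds[["targets"]],
                               mean = cfg$target_mean, sd = cfg$target_sd,
                               jitter = cfg$gp_jitter)
  code <- sample_thalamic_code(cfg$n_thal, cfg$thalamic_radius,
                               seeds[["thalamic"]])
  net <- init_connectivity(cfg, seeds[["connectivity"]])
  vpos <- place_varicosities(cfg$d, cfg$n_varicosities,
                             seeds[["varicosities"]])
  D <- effective_feedback_matrix(net$spn_positions, vpos, cfg$lambda_da)
  D_eff <- make_feedback_variant(D, cfg$feedback_variant,
                                 W_str_snr = net$projections$StrSNr$W,
                                 pre_sign = net$projections$StrSNr$pre_sign,
                                 seed = seeds[["shuffle"]])

  # lesions: absent removes the projection, static freezes it
  plastic <- vapply(net$projections, `[[`, logical(1), "plastic")
  for (pn in names(cfg$lesions)) {
    mode <- cfg$lesions[[pn]]
    if (mode == "absent") {
      net$projections[[pn]]$W[] <- 0
      net$projections[[pn]]$mask[] <- 0L
      plastic[pn] <- FALSE
    } else if (mode == "static") {
      plastic[pn] <- FALSE
    }
  }

  alpha <- ifelse(net$spn_class == "dSPN", cfg$alpha_d, cfg$alpha_i)
  snr_sign <- net$projections$StrSNr$pre_sign
  variant_code <- switch(cfg$feedback_variant,
                         none = 0L, heterogeneous = 1L, homogeneous = 1L,
                         shuffled = 1L, ideal = 2L)

  snap_after <- if (cfg$snapshot_every > 0) {
    unique(sort(c(0L, seq(cfg$snapshot_every, cfg$n_trials,
                          by = cfg$snapshot_every), cfg$n_trials)))
  } else c(0L, cfg$n_trials)

  pr <- net$projections
  args <- list(
    W_thal_ctx = pr$ThalCtx$W, W_ctx_ctx = pr$CtxCtx$W,
    W_thal_str = pr$ThalStr$W, M_thal_str = pr$ThalStr$mask * 1,
    W_ctx_str = pr$CtxStr$W, M_ctx_str = pr$CtxStr$mask * 1,
    W_str_str = pr$StrStr$W, M_str_str = pr$StrStr$mask * 1,
    W_str_snr = pr$StrSNr$W, M_str_snr = pr$StrSNr$mask * 1,
    snr_pre_sign = snr_sign, alpha_per_spn = alpha, beta = cfg$beta,
    D = D_eff, variant = variant_code, targets = targets$values,
    A = code$A, B = code$B,
    tau_m = cfg$tau_m, b = cfg$b, dt = cfg$dt,
    T_period = cfg$trial_duration, tau_str = cfg$tau_str,
    n_trials = cfg$n_trials, n_steps = cfg$n_steps,
    tau_da = if (is.null(cfg$tau_da)) -1 else cfg$tau_da,
    compensate = cfg$highpass_compensation,
    lowpass_normalized = !cfg$lowpass_unnormalized,
    plastic_thal_str = plastic[["ThalStr"]],
    plastic_ctx_str = plastic[["CtxStr"]],
    plastic_str_str = plastic[["StrStr"]],
    plastic_str_snr = plastic[["StrSNr"]],
    n_record_trials = cfg$n_record_trials,
    snap_after = as.integer(snap_after)
  )

  out <- if (engine == "cpp") do.call(.train_loop_cpp, args)
         else do.call(train_loop_r, args)

  snaps <- lapply(seq_along(snap_after), function(i) {
    if (engine == "cpp") out$snapshots[, , i] else out$snapshots[[i]]
  })
  structure(
    list(per_trial_loss = as.vector(out$per_trial_loss),
         W_thal_str = out$W_thal_str, W_ctx_str = out$W_ctx_str,
         W_str_str = out$W_str_str, W_str_snr = out$W_str_snr,
         rec_first_snr = out$rec_first_snr,
         rec_str = out$rec_str, rec_snr = out$rec_snr,
         snapshots = snaps, snapshot_trials = snap_after,
         D = D, D_eff = D_eff, varicosity_positions = vpos,
         spn_positions = net$spn_positions, spn_class = net$spn_class,
         targets = targets, code = code, network = net,
         cfg = cfg, seeds = seeds),
    class = "run_result"
  )
}

# Pure-R reference engine: the same loop as the compiled one, written from
# the exported single-step operations. Slow; used for oracle testing.
train_loop_r <- function(W_thal_ctx, W_ctx_ctx, W_thal_str, M_thal_str,
                         W_ctx_str, M_ctx_str, W_str_str, M_str_str,
                         W_str_snr, M_str_snr, snr_pre_sign, alpha_per_spn,
                         beta, D, variant, targets, A, B, tau_m, b, dt,
                         T_period, tau_str, n_trials, n_steps, tau_da,
                         compensate, lowpass_normalized,
                         plastic_thal_str, plastic_ctx_str, plastic_str_str,
                         plastic_str_snr, n_record_trials, snap_after) {
  n_ctx <- nrow(W_ctx_ctx); n_str <- nrow(W_str_str); d <- nrow(W_str_snr)
  V_ctx <- rep(0, n_ctx); V_str <- rep(0, n_str)
  P_thal <- matrix(0, n_str, ncol(W_thal_str))
  P_ctx <- matrix(0, n_str, ncol(W_ctx_str))
  P_str <- matrix(0, n_str, n_str)
  Cf <- rep(0, n_str); A_prev <- rep(0, n_str)
  code <- structure(list(A = A, B = B), class = "thalamic_code")
  striatal_any <- variant != 0 &&
    (plastic_thal_str || plastic_ctx_str || plastic_str_str)

  trial_loss <- numeric(n_trials)
  rec_first_snr <- matrix(0, d, n_steps)
  n_rec <- min(n_record_trials, n_trials)
  rec_str <- matrix(0, n_str, n_rec * n_steps)
  rec_snr <- matrix(0, d, n_rec * n_steps)
  first_rec <- n_trials - n_rec
  snaps <- vector("list", length(snap_after))
  si <- 1L
  while (si <= length(snap_after) && snap_after[si] == 0L) {
    snaps[[si]] <- W_str_snr; si <- si + 1L
  }

  for (trial in seq_len(n_trials)) {
    acc <- 0
    for (st in seq_len(n_steps)) {
      t <- (st - 1) * dt
      r_thal <- thalamic_rates(code, t, T_period, b = b)
      r_ctx <- sigmoid_rate(V_ctx, b = b)
      r_str <- sigmoid_rate(V_str, b = b)
      r_snr <- readout_rates(W_str_snr, r_str, b = b)
      tgt <- targets[, st]
      acc <- acc + output_loss(r_snr, tgt) * dt
      eps <- snc_error_rates(r_snr, tgt)

      if (striatal_any) {
        c_raw <- if (variant == 2) {
          snr_pre_sign * as.vector(t(W_str_snr) %*% eps)
        } else dopamine_concentration(D, eps)
        if (tau_da > 0) {
          Cf <- lowpass_dopamine(Cf, c_raw, dt, tau_da,
                                 normalized = lowpass_normalized)
          if (compensate) {
            hp <- highpass_compensate(Cf, A_prev, dt, tau_da)
            a <- hp$a; A_prev <- hp$A
          } else a <- Cf
        } else a <- c_raw

        if (plastic_thal_str) {
          P_thal <- update_eligibility(P_thal, r_str, r_thal, dt, tau_str,
                                       mask = M_thal_str)
          W_thal_str <- striatal_weight_update(W_thal_str, P_thal, a,
                                               alpha_per_spn, dt,
                                               mask = M_thal_str, sign = 1)
        }
        if (plastic_ctx_str) {
          P_ctx <- update_eligibility(P_ctx, r_str, r_ctx, dt, tau_str,
                                      mask = M_ctx_str)
          W_ctx_str <- striatal_weight_update(W_ctx_str, P_ctx, a,
                                              alpha_per_spn, dt,
                                              mask = M_ctx_str, sign = 1)
        }
        if (plastic_str_str) {
          P_str <- update_eligibility(P_str, r_str, r_str, dt, tau_str,
                                      mask = M_str_str)
          W_str_str <- striatal_weight_update(W_str_str, P_str, a,
                                              alpha_per_spn, dt,
                                              mask = M_str_str, sign = -1)
        }
      }
      if (plastic_str_snr) {
        W_str_snr <- striatofugal_update(W_str_snr, eps, r_str, beta, dt,
                                         snr_pre_sign, mask = M_str_snr)
      }

      V_ctx <- step_membrane(V_ctx, as.vector(W_thal_ctx %*% r_thal +
                                                W_ctx_ctx %*% r_ctx),
                             dt, tau_m)
      V_str <- step_membrane(V_str, as.vector(W_thal_str %*% r_thal +
                                                W_ctx_str %*% r_ctx +
                                                W_str_str %*% r_str),
                             dt, tau_m)

      if (trial == 1) rec_first_snr[, st] <- r_snr
      if (trial > first_rec) {
        col <- (trial - first_rec - 1) * n_steps + st
        rec_str[, col] <- r_str
        rec_snr[, col] <- r_snr
      }
    }
    if (!all(is.finite(V_ctx)) || !all(is.finite(V_str))) {
      stop("simulation diverged (non-finite state) in trial ", trial)
    }
    trial_loss[trial] <- acc
    while (si <= length(snap_after) && snap_after[si] == trial) {
      snaps[[si]] <- W_str_snr; si <- si + 1L
    }
  }

  list(per_trial_loss = trial_loss, W_thal_str = W_thal_str,
       W_ctx_str = W_ctx_str, W_str_str = W_str_str, W_str_snr = W_str_snr,
       rec_first_snr = rec_first_snr, rec_str = rec_str, rec_snr = rec_snr,
       snapshots = snaps, V_ctx = V_ctx, V_str = V_str)
}

#' Final loss of a run
#'
#' The median per-trial loss over the last `last` trials, damping the jitter
#' of online learning.
#'
#' @param result a `"run_result"` (or a bare per-trial loss vector).
#' @param last number of final trials to aggregate over (default 10).
#' @return Scalar final loss.
#' @export
final_loss <- function(result, last = 10) {
  loss <- if (inherits(result, "run_result")) result$per_trial_loss else result
  n <- length(loss)
  median(loss[seq(max(1, n - last + 1), n)])
}

#' @export
print.run_result <- function(x, ...) {
  cat("<run_result>", x$cfg$feedback_variant, "feedback,",
      length(x$per_trial_loss), "trials\n")
  cat(sprintf("  loss: trial 1 = %.3f, final (median last 10) = %.3f\n",
              x$per_trial_loss[1], final_loss(x)))
  invisible(x)
}

# Run one configuration under several seeds, returning a tidy data frame.
run_condition <- function(cfg, label, seeds, last = 10) {
  rows <- lapply(seq_along(seeds), function(i) {
    cfg$seed <- as.integer(seeds[i])
    res <- run_training(cfg)
    data.frame(condition = label, run = i, seed = seeds[i],
               first_loss = res$per_trial_loss[1],
               final_loss = final_loss(res, last = last),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

summarize_conditions <- function(runs) {
  agg <- lapply(split(runs, runs$condition), function(df) {
    q <- quantile(df$final_loss, c(0.25, 0.5, 0.75), names = FALSE)
    data.frame(condition = df$condition[1], n_runs = nrow(df),
               median = q[2], q1 = q[1], q3 = q[3],
               min = min(df$final_loss), max = max(df$final_loss),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, agg)
  rownames(out) <- NULL
  out[match(unique(runs$condition), out$condition), , drop = FALSE]
}

new_sweep_result <- function(runs) {
  structure(list(runs = runs, summary = summarize_conditions(runs)),
            class = "sweep_result")
}

#' @export
print.sweep_result <- function(x, ...) {
  cat("<sweep_result>\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}

# Seeds for paired runs: condition comparisons reuse the same seed per run
# index, so targets and connectivity are matched across conditions.
paired_seeds <- function(base_seed, n_runs) {
  as.integer(base_seed) + seq_len(n_runs) - 1L
}

#' Compare feedback conditions at matched seeds
#'
#' Trains the network under several feedback variants with paired seeds (run
#' i of every variant shares targets, connectivity, and varicosity placement)
#' and summarizes the final-trial loss per variant by median and quartiles.
#'
#' @param base a [sim_config()]; its `feedback_variant` is overridden.
#' @param variants character vector of feedback variants to compare.
#' @param n_runs runs per variant.
#' @return A `"sweep_result"`: `$runs` (per-run data frame) and `$summary`
#'   (median/quartiles/min/max per condition).
#' @export
compare_conditions <- function(base,
                               variants = c("heterogeneous", "homogeneous",
                                            "none"),
                               n_runs = 10) {
  seeds <- paired_seeds(base$seed, n_runs)
  runs <- do.call(rbind, lapply(variants, function(v) {
    cfg <- base
    cfg$feedback_variant <- v
    run_condition(cfg, v, seeds)
  }))
  new_sweep_result(runs)
}

#' Sweep the dopamine diffusion length scale
#'
#' Final loss as a function of \eqn{\lambda}. Very small \eqn{\lambda}
#' delivers no dopamine to any SPN (no-feedback limit); very large
#' \eqn{\lambda} delivers the same mixture everywhere (homogeneous limit);
#' learning benefits most at intermediate scales where each SPN receives a
#' distinct random projection of the error.
#'
#' @param base a [sim_config()].
#' @param lambdas positive length scales to sweep.
#' @param n_runs runs per value (paired seeds).
#' @return A `"sweep_result"`; conditions are labelled `lambda=<value>`.
#' @export
sweep_lambda <- function(base, lambdas = c(0.001, 0.1, 100), n_runs = 10) {
  if (any(lambdas <= 0)) stop("lambda values must be positive")
  seeds <- paired_seeds(base$seed, n_runs)
  runs <- do.call(rbind, lapply(lambdas, function(l) {
    cfg <- base
    cfg$lambda_da <- l
    run_condition(cfg, sprintf("lambda=%g", l), seeds)
  }))
  out <- new_sweep_result(runs)
  out$lambdas <- lambdas
  out
}

#' Joint sweep of varicosity count and diffusion scale
#'
#' Final loss on the grid of `n_var_values` x `lambdas`. More varicosities
#' per SNc neuron extend the viable range of \eqn{\lambda} to smaller values,
#' because coverage of the cube (and hence the rank of the feedback matrix)
#' is maintained.
#'
#' @param base a [sim_config()].
#' @param n_var_values varicosity counts.
#' @param lambdas diffusion length scales.
#' @param n_runs runs per grid point (paired seeds).
#' @return A `"sweep_result"` with `$grid` (data frame: n_var, lambda,
#'   median final loss, median feedback independence).
#' @export
sweep_varicosities <- function(base, n_var_values = c(1, 10, 50),
                               lambdas = c(0.01, 0.1), n_runs = 5) {
  seeds <- paired_seeds(base$seed, n_runs)
  grid <- expand.grid(n_var = n_var_values, lambda = lambdas)
  runs <- do.call(rbind, lapply(seq_len(nrow(grid)), function(g) {
    cfg <- base
    cfg$n_varicosities <- as.integer(grid$n_var[g])
    cfg$lambda_da <- grid$lambda[g]
    run_condition(cfg, sprintf("n_var=%d,lambda=%g", grid$n_var[g],
                               grid$lambda[g]), seeds)
  }))
  out <- new_sweep_result(runs)
  # feedback independence per grid point (structure only; no training needed)
  grid$independence <- vapply(seq_len(nrow(grid)), function(g) {
    median(vapply(seeds, function(s) {
      ss <- derive_seeds(s)
      pos <- matrix(runif_seeded(base$n_str * 3, ss[["connectivity"]]),
                    ncol = 3)
      vp <- place_varicosities(base$d, as.integer(grid$n_var[g]),
                               ss[["varicosities"]])
      feedback_independence(effective_feedback_matrix(pos, vp,
                                                      grid$lambda[g]))
    }, numeric(1)))
  }, numeric(1))
  grid$median_final_loss <- vapply(seq_len(nrow(grid)), function(g) {
    lbl <- sprintf("n_var=%d,lambda=%g", grid$n_var[g], grid$lambda[g])
    out$summary$median[out$summary$condition == lbl]
  }, numeric(1))
  out$grid <- grid
  out
}

# uniform draws under a local seed (positions proxy for independence checks)
runif_seeded <- function(n, seed) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  runif(n)
}

#' Lesion experiment
#'
#' Trains the network with one or more plastic projections impaired: `static`
#' keeps the initial weights but disables their plasticity; `absent` removes
#' the projection entirely. An unlabelled `"intact"` baseline is included.
#'
#' @param base a [sim_config()].
#' @param lesions named list; each element is a named character vector
#'   mapping projections to modes, e.g.
#'   `list(readout_static = c(StrSNr = "static"))`.
#' @param n_runs runs per condition (paired seeds).
#' @return A `"sweep_result"`.
#' @export
lesion_experiment <- function(base,
                              lesions = list(
                                readout_static = c(StrSNr = "static"),
                                ctx_absent = c(CtxStr = "absent"),
                                thal_absent = c(ThalStr = "absent"),
                                ctx_thal_absent = c(CtxStr = "absent",
                                                    ThalStr = "absent")
                              ),
                              n_runs = 10) {
  seeds <- paired_seeds(base$seed, n_runs)
  base$lesions <- NULL
  runs <- run_condition(base, "intact", seeds)
  for (nm in names(lesions)) {
    cfg <- base
    cfg$lesions <- as.list(lesions[[nm]])
    runs <- rbind(runs, run_condition(cfg, nm, seeds))
  }
  new_sweep_result(runs)
}

#' Slow-dopamine experiment
#'
#' Trains the heterogeneous model with the dopamine concentration low-pass
#' filtered at each `tau_da`, with or without the synaptic high-pass
#' compensation, alongside instantaneous-dopamine and no-striatal-plasticity
#' references. Without compensation the error grows with \eqn{\tau_{DA}} and
#' surpasses the no-striatal-plasticity baseline; with compensation it stays
#' near the instantaneous level.
#'
#' The uncompensated conditions default to the literal exponential
#' convolution (DC gain \eqn{\approx \tau_{DA}/dt}): slow dopamine kinetics
#' both lag and accumulate concentration, which is what degrades learning.
#' The compensated conditions use the unit-gain discretization, the
#' convention under which the feed-forward-inhibition motif reconstructs the
#' instantaneous signal exactly (see [highpass_compensate()]).
#'
#' @param base a [sim_config()].
#' @param tau_da_values filter time constants in ms.
#' @param compensation if `TRUE`, enable the high-pass compensation in the
#'   filtered conditions.
#' @param unnormalized use the literal convolution filter in the filtered
#'   conditions; defaults to `!compensation`.
#' @param n_runs runs per condition (paired seeds).
#' @return A `"sweep_result"`; filtered conditions are labelled
#'   `tau_da=<value>` (plus `+comp` when compensated).
#' @export
slow_dopamine_experiment <- function(base, tau_da_values = c(1, 200),
                                     compensation = FALSE,
                                     unnormalized = !compensation,
                                     n_runs = 10) {
  if (any(tau_da_values <= 0)) stop("tau_da values must be positive")
  seeds <- paired_seeds(base$seed, n_runs)
  inst <- base
  inst$tau_da <- NULL
  inst$highpass_compensation <- FALSE
  runs <- run_condition(inst, "instantaneous", seeds)
  none <- inst
  none$feedback_variant <- "none"
  runs <- rbind(runs, run_condition(none, "no_striatal_plasticity", seeds))
  for (tau in tau_da_values) {
    cfg <- base
    cfg$tau_da <- tau
    cfg$highpass_compensation <- isTRUE(compensation)
    cfg$lowpass_unnormalized <- isTRUE(unnormalized)
    lbl <- sprintf("tau_da=%g%s", tau, if (compensation) "+comp" else "")
    runs <- rbind(runs, run_condition(cfg, lbl, seeds))
  }
  new_sweep_result(runs)
}
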