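#' Periodic distance on a circular time axis
#'
#' Smallest difference between two times on a trial of duration `T_period`,
#' allowing wrap-around: \eqn{\delta(t_1, t_2) = \min(|t_1 - t_2|,
#' |t_1 - t_2 + T|, |t_1 - t_2 - T|)}. Used by the periodic Gaussian-process
#' kernel so that consecutive trials join without discontinuity.
#'
#' @param t1,t2 times in ms (vectors recycle as usual).
#' @param T_period trial duration in ms.
#' @return The wrapped distance, in `[0, T_period/2]`.
#' @export
#' @examples
#' periodic_distance(10, 190, 200) # 20, not 180
periodic_distance <- function(t1, t2, T_period) {
  if (T_period <= 0) stop("T_period must be positive")
  if (any(t1 < 0) || any(t2 < 0) || any(t1 > T_period) || any(t2 > T_period)) {
    stop("times must lie in [0, T_period]")
  }
  diff <- t1 - t2
  pmin(abs(diff), abs(diff + T_period), abs(diff - T_period))
}

#' Periodic squared-exponential covariance matrix
#'
#' Covariance of the target Gaussian process on a grid of times within one
#' trial: \eqn{\sigma^2(t_i, t_j) = 0.15^2 \exp(-\delta(t_i, t_j)^2 /
#' (2\tau_{task}^2))} with the wrap-around distance \eqn{\delta}. The kernel is
#' stationary and periodic, so trials can be concatenated seamlessly.
#'
#' @param times strictly increasing times in `[0, T_period)`.
#' @param tau_task kernel length scale in ms.
#' @param T_period trial duration in ms.
#' @param sd marginal standard deviation of the process (default 0.15).
#' @return A symmetric positive-semidefinite matrix with diagonal `sd^2`.
#' @export
build_periodic_covariance <- function(times, tau_task, T_period, sd = 0.15) {
  if (tau_task <= 0) stop("tau_task must be positive")
  if (is.unsorted(times, strictly = TRUE)) {
    stop("times must be strictly increasing")
  }
  if (any(times < 0) || any(times >= T_period)) {
    stop("times must lie in [0, T_period)")
  }
  delta <- outer(times, times, function(a, b) periodic_distance(a, b, T_period))
  sd^2 * exp(-delta^2 / (2 * tau_task^2))
}

#' Sample a set of Gaussian-process target trajectories
#'
#' Draws `d` independent target dimensions, each a multivariate-normal sample
#' with mean 0.5 and the periodic covariance of
#' [build_periodic_covariance()], on the simulation grid `t = 0, dt, ...,
#' T - dt`. The targets are the desired readout rates; they are not clipped,
#' as the loss is well defined for values outside the sigmoid range.
#'
#' @param d number of target dimensions.
#' @param T_period trial duration in ms.
#' @param dt simulation step in ms (must divide `T_period`).
#' @param tau_task kernel length scale in ms.
#' @param seed integer seed; sampling is reproducible.
#' @param mean process mean (default 0.5).
#' @param sd marginal standard deviation (default 0.15).
#' @param jitter diagonal regularization added before the Cholesky
#'   factorization; the periodic kernel on a fine grid is near-singular.
#' @return An object of class `"target_set"`: list with `values` (a
#'   `d x n_steps` matrix), `times`, `trial_duration`, `dt`, `tau_task`,
#'   `seed`.
#' @export
#' @examples
#' ts <- sample_target_set(d = 4, T_period = 200, dt = 1, tau_task = 20, seed = 7)
#' dim(ts$values)
sample_target_set <- function(d, T_period, dt, tau_task, seed,
                              mean = 0.5, sd = 0.15, jitter = 1e-8) {
  n_steps <- round(T_period / dt)
  if (abs(n_steps * dt - T_period) > 1e-9) stop("dt must divide T_period")
  times <- seq(0, T_period - dt, by = dt)
  K <- build_periodic_covariance(times, tau_task, T_period, sd = sd)
  K <- K + diag(jitter, n_steps)
  # The wrap-around squared-exponential kernel is PSD only up to numerical
  # tolerance (smallest eigenvalues can sit a few 1e-7 below zero on a fine
  # grid). Try the Cholesky factor; if the jitter is insufficient, fall back
  # to an eigendecomposition with tiny negative eigenvalues clipped to zero.
  L <- tryCatch(chol(K), error = function(e) NULL)
  if (is.null(L)) {
    ed <- eigen(K, symmetric = TRUE)
    if (min(ed$values) < -1e-4 * max(ed$values)) {
      stop("covariance not positive semidefinite after jitter regularization")
    }
    L <- t(ed$vectors %*% diag(sqrt(pmax(ed$values, 0))))
  }
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(seed)
  z <- matrix(rnorm(d * n_steps), nrow = d, ncol = n_steps)
  values <- mean + z %*% L   # rows: independent draws with covariance K
  if (!all(is.finite(values))) stop("non-finite target values")
  structure(
    list(values = values, times = times, trial_duration = T_period,
         dt = dt, tau_task = tau_task, seed = seed),
    class = "target_set"
  )
}

#' Sample the thalamic clock code
#'
#' Each thalamic unit carries a phase-shifted sinusoid of the trial period:
#' its coefficients \eqn{(A_m, B_m)} are drawn uniformly on a circle of the
#' given radius, so \eqn{A_m^2 + B_m^2 = \mathrm{radius}^2} for every unit.
#'
#' @param n_thal number of thalamic units.
#' @param radius circle radius (default 4).
#' @param seed integer seed.
#' @return An object of class `"thalamic_code"`: list with vectors `A`, `B`,
#'   plus `radius` and `seed`.
#' @export
sample_thalamic_code <- function(n_thal, radius = 4, seed = 1L) {
  if (n_thal < 1) stop("n_thal must be >= 1")
  if (radius < 0) stop("radius must be nonnegative")
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(seed)
  theta <- runif(n_thal, 0, 2 * pi)
  structure(
    list(A = radius * cos(theta), B = radius * sin(theta),
         radius = radius, seed = seed),
    class = "thalamic_code"
  )
}

#' Thalamic firing rates at a given time
#'
#' The current position within the trial is signaled to the network by
#' clamping the thalamic rates to
#' \eqn{r_m = \phi(A_m \cos(2\pi t/T) + B_m \sin(2\pi t/T))}, with \eqn{\phi}
#' the shifted logistic of [sigmoid_rate()]. The rates are imposed, not
#' integrated, and are identical across trials.
#'
#' @param code a `"thalamic_code"`.
#' @param t time in ms (scalar).
#' @param T_period trial duration in ms.
#' @param b sigmoid offset (default 2).
#' @return Vector of rates in (0, 1).
#' @export
thalamic_rates <- function(code, t, T_period, b = 2) {
  if (t < 0) stop("t must be nonnegative")
  phase <- 2 * pi * t / T_period
  sigmoid_rate(code$A * cos(phase) + code$B * sin(phase), b = b)
}
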