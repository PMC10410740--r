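#' Place dopaminergic varicosities
#'
#' Each SNc neuron's axonal arbor covers the whole striatal volume and
#' releases dopamine from `n_var` varicosities placed independently and
#' uniformly in the unit cube.
#'
#' @param n_snc number of SNc neurons.
#' @param n_var varicosities per SNc neuron.
#' @param seed integer seed.
#' @return Array `n_snc x n_var x 3` of positions in `[0, 1]^3`.
#' @export
place_varicosities <- function(n_snc, n_var, seed = 1L) {
  if (n_snc < 1 || n_var < 1) stop("counts must be >= 1")
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(seed)
  array(runif(n_snc * n_var * 3), dim = c(n_snc, n_var, 3))
}

#' Effective nigrostriatal feedback matrix
#'
#' Dopamine concentration decays exponentially with distance from a
#' varicosity, with length scale `lambda` (relative to the cube side), so the
#' effective weight from SNc neuron `k` onto SPN `j` is
#' \eqn{d_{jk} = \sum_v \frac{1}{\lambda} e^{-\|p_j - q_{kv}\| / \lambda}}.
#' All entries are strictly positive and additive over varicosities. At
#' `lambda = 0.1` the per-varicosity kernel falls to \eqn{1/e \approx 37\%}
#' of its zero-distance value over 10% of the cube side.
#'
#' @param spn_positions `n_str x 3` SPN positions in the unit cube.
#' @param varicosity_positions `n_snc x n_var x 3` array from
#'   [place_varicosities()].
#' @param lambda diffusion length scale (> 0).
#' @return Matrix `n_str x n_snc` of positive effective weights.
#' @export
effective_feedback_matrix <- function(spn_positions, varicosity_positions,
                                      lambda) {
  if (lambda <= 0) stop("lambda must be positive")
  n_str <- nrow(spn_positions)
  n_snc <- dim(varicosity_positions)[1]
  n_var <- dim(varicosity_positions)[2]
  D <- matrix(0, n_str, n_snc)
  for (k in seq_len(n_snc)) {
    for (v in seq_len(n_var)) {
      q <- varicosity_positions[k, v, ]
      dist <- sqrt((spn_positions[, 1] - q[1])^2 +
                     (spn_positions[, 2] - q[2])^2 +
                     (spn_positions[, 3] - q[3])^2)
      D[, k] <- D[, k] + exp(-dist / lambda) / lambda
    }
  }
  D
}

#' Dopamine concentration at each SPN
#'
#' The concentration is linear in the SNc rates:
#' \eqn{C_j = \sum_k r_k^{SNc} d_{jk}}, i.e. `D %*% r_snc`.
#'
#' @param D effective feedback matrix, `n_str x n_snc`.
#' @param r_snc SNc rate (error) vector, length `n_snc`; may be signed.
#' @return Concentration vector, length `n_str`.
#' @export
dopamine_concentration <- function(D, r_snc) {
  if (ncol(D) != length(r_snc)) stop("dimension mismatch")
  as.vector(D %*% r_snc)
}

#' Construct a feedback-variant matrix
#'
#' Produces the effective feedback used by striatal plasticity under each
#' model variant:
#' \describe{
#'   \item{heterogeneous}{the diffusion-derived `D`, unchanged.}
#'   \item{shuffled}{all entries of `D` randomly permuted (elementwise), once
#'     per run — vector-valued feedback without spatial structure.}
#'   \item{homogeneous}{every SPN receives the identical scalar
#'     \eqn{\bar d \sum_k r_k^{SNc}}; implemented as a matrix whose every
#'     entry is the mean of `D`, so the total dopamine gain matches the
#'     heterogeneous condition.}
#'   \item{none}{a zero matrix — striatal plasticity disabled.}
#'   \item{ideal}{the transposed readout weights, with dSPN rows negated so
#'     the pathway-specific plasticity signs cancel and every striatal
#'     afferent descends the true loss gradient; time-dependent, so this
#'     function returns the matrix as of now and the training loop re-reads
#'     the current weights at every step.}
#' }
#'
#' @param D diffusion-derived feedback matrix (`n_str x n_snc`).
#' @param variant one of `"heterogeneous"`, `"homogeneous"`, `"shuffled"`,
#'   `"ideal"`, `"none"`.
#' @param W_str_snr readout weights (`n_snc x n_str`), needed for `"ideal"`.
#' @param pre_sign per-SPN readout sign (-1 dSPN, +1 iSPN), needed for
#'   `"ideal"`.
#' @param seed seed for the `"shuffled"` permutation.
#' @return Matrix of the same shape as `D`.
#' @export
make_feedback_variant <- function(D, variant, W_str_snr = NULL,
                                  pre_sign = NULL, seed = 1L) {
  switch(variant,
    heterogeneous = D,
    shuffled = {
      old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
      on.exit({
        if (is.null(old_seed)) {
          if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
        } else assign(".Random.seed", old_seed, envir = globalenv())
      })
      set.seed(seed)
      matrix(sample(as.vector(D)), nrow(D), ncol(D))
    },
    homogeneous = matrix(mean(D), nrow(D), ncol(D)),
    none = matrix(0, nrow(D), ncol(D)),
    ideal = {
      if (is.null(W_str_snr)) stop("ideal variant needs the readout weights")
      if (is.null(pre_sign)) stop("ideal variant needs the per-SPN signs")
      pre_sign * t(W_str_snr)
    },
    stop("unknown feedback variant: ", variant)
  )
}

#' Low-pass filter the dopamine concentration
#'
#' Discrete exponential low-pass with time constant `tau_da`:
#' \eqn{C' \leftarrow \xi C' + (1 - \xi) C} with \eqn{\xi = e^{-dt/\tau_{DA}}}.
#' This normalized form has unit DC gain (constant input is reproduced
#' exactly in the limit), which is the convention under which the high-pass
#' compensation of [highpass_compensate()] reconstructs the instantaneous
#' concentration. Set `normalized = FALSE` for the raw convolution (DC gain
#' \eqn{(1-\xi)^{-1}}).
#'
#' @param C_filtered current filtered value (vector).
#' @param C_now instantaneous concentration (vector).
#' @param dt time step in ms.
#' @param tau_da filter time constant in ms (> 0).
#' @param normalized unit DC gain if `TRUE` (default).
#' @return Updated filtered concentration.
#' @export
lowpass_dopamine <- function(C_filtered, C_now, dt, tau_da,
                             normalized = TRUE) {
  if (tau_da <= 0) stop("tau_da must be positive")
  xi <- exp(-dt / tau_da)
  if (normalized) xi * C_filtered + (1 - xi) * C_now
  else xi * C_filtered + C_now
}

#' High-pass compensation of slow dopamine
#'
#' A feed-forward inhibition motif in the synaptic biochemical cascade: one
#' node tracks \eqn{A(t) = C'(t) / (1 - \xi)} and another subtracts its value
#' one step ago, \eqn{a(t) = A(t) - \xi A(t - \Delta t)} with
#' \eqn{\xi = e^{-\Delta t/\tau_{DA}}}. Applied to the normalized low-pass
#' output this reconstructs the instantaneous concentration exactly.
#'
#' @param C_filtered current filtered concentration \eqn{C'(t)}.
#' @param A_prev the tracking node's previous value \eqn{A(t - \Delta t)}
#'   (vector, zeros initially).
#' @param dt time step in ms.
#' @param tau_da filter time constant in ms; must be finite (\eqn{\xi < 1}).
#' @return List with `a` (the compensated, plasticity-driving signal) and
#'   `A` (the tracking node's new value, to pass back next step).
#' @export
highpass_compensate <- function(C_filtered, A_prev, dt, tau_da) {
  if (tau_da <= 0) stop("tau_da must be positive")
  xi <- exp(-dt / tau_da)
  if (xi >= 1) stop("xi = 1 (infinite tau_da) is not invertible")
  A <- C_filtered / (1 - xi)
  list(a = A - xi * A_prev, A = A)
}

#' Linear independence of feedback rows
#'
#' Scalar diagnostic in `[0, 1]` for how independently the SPNs sample the
#' error components: the ratio of the smallest to the largest singular value
#' of the row-normalized feedback matrix. Zero for rank-deficient `D`
#' (e.g. identical rows, the homogeneous limit), approaching one when rows
#' are mutually orthogonal.
#'
#' @param D feedback matrix (`n_str x n_snc`).
#' @return Scalar in `[0, 1]`.
#' @export
feedback_independence <- function(D) {
  norms <- sqrt(rowSums(D^2))
  if (all(norms == 0)) stop("all-zero feedback matrix")
  Dn <- D[norms > 0, , drop = FALSE] / norms[norms > 0]
  sv <- svd(Dn, nu = 0, nv = 0)$d
  sv[length(sv)] / sv[1]
}
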