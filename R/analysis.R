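#' Pairwise SPN rate correlation as a function of distance
#'
#' Pearson correlation between the firing-rate traces of every SPN pair,
#' averaged within Euclidean-distance bins (distance relative to the cube
#' side). Pass lists of rate matrices and position matrices to pool pairs
#' across runs; pooling concatenates pairs, not traces. SPNs with constant
#' traces have undefined correlations and are excluded (counted in
#' `n_constant`).
#'
#' @param rates `n_str x n_steps` rate matrix, or a list of such matrices.
#' @param positions `n_str x 3` position matrix, or a matching list.
#' @param breaks distance bin edges (default 0.05-wide bins covering
#'   `[0, sqrt(3)]`).
#' @return An object of class `"correlation_curve"`: data frame with
#'   `bin_lo`, `bin_hi`, `bin_mid`, `mean_correlation`, `n_pairs`, plus
#'   attribute `n_constant`.
#' @export
correlation_vs_distance <- function(rates, positions,
                                    breaks = seq(0, sqrt(3) + 0.05, by = 0.05)) {
  if (!is.list(rates)) {
    rates <- list(rates)
    positions <- list(positions)
  }
  stopifnot(length(rates) == length(positions))
  all_d <- list()
  all_c <- list()
  n_constant <- 0L
  for (i in seq_along(rates)) {
    R <- rates[[i]]
    P <- positions[[i]]
    keep <- apply(R, 1, sd) > 0
    n_constant <- n_constant + sum(!keep)
    R <- R[keep, , drop = FALSE]
    P <- P[keep, , drop = FALSE]
    if (nrow(R) < 2) next
    cc <- cor(t(R))
    dd <- as.matrix(dist(P))
    ut <- upper.tri(cc)
    all_c[[length(all_c) + 1]] <- cc[ut]
    all_d[[length(all_d) + 1]] <- dd[ut]
  }
  corr <- unlist(all_c)
  dist <- unlist(all_d)
  bin <- cut(dist, breaks = breaks, include.lowest = TRUE, right = FALSE)
  mean_corr <- tapply(corr, bin, mean)
  n_pairs <- tapply(corr, bin, length)
  out <- data.frame(
    bin_lo = breaks[-length(breaks)],
    bin_hi = breaks[-1],
    bin_mid = (breaks[-1] + breaks[-length(breaks)]) / 2,
    mean_correlation = as.vector(mean_corr[levels(bin)]),
    n_pairs = as.vector(ifelse(is.na(n_pairs[levels(bin)]), 0,
                               n_pairs[levels(bin)]))
  )
  attr(out, "n_constant") <- n_constant
  class(out) <- c("correlation_curve", "data.frame")
  out
}

#' Preferred target dimension of each SPN
#'
#' Assigns each SPN the target dimension its firing-rate trace is most
#' correlated with (Pearson), after training. The target is tiled to the
#' length of the recorded trace. Ties are broken by the lowest dimension
#' index; constant traces are unassigned (`NA`).
#'
#' @param rates `n_str x n_steps_rec` recorded rate matrix.
#' @param targets a `"target_set"` (or bare `d x n_steps` matrix).
#' @param positions optional `n_str x 3` SPN positions, echoed into the
#'   result for plotting (x, y used; z omitted, an orthographic top view).
#' @param spn_class optional per-SPN class labels, echoed into the result.
#' @return An object of class `"preference_map"`: data frame with
#'   `preferred_dimension` (integer or `NA`) and `max_correlation`, plus
#'   position/class columns when supplied.
#' @export
preferred_dimension <- function(rates, targets, positions = NULL,
                                spn_class = NULL) {
  tv <- if (inherits(targets, "target_set")) targets$values else targets
  n_rec <- ncol(rates)
  reps <- ceiling(n_rec / ncol(tv))
  tiled <- do.call(cbind, rep(list(tv), reps))[, seq_len(n_rec), drop = FALSE]
  d <- nrow(tv)
  pref <- rep(NA_integer_, nrow(rates))
  maxc <- rep(NA_real_, nrow(rates))
  for (j in seq_len(nrow(rates))) {
    if (sd(rates[j, ]) == 0) next
    cj <- vapply(seq_len(d), function(k) cor(rates[j, ], tiled[k, ]),
                 numeric(1))
    pref[j] <- which.max(cj)   # which.max takes the lowest index on ties
    maxc[j] <- cj[pref[j]]
  }
  out <- data.frame(spn = seq_len(nrow(rates)), preferred_dimension = pref,
                    max_correlation = maxc)
  if (!is.null(positions)) {
    out$x <- positions[, 1]; out$y <- positions[, 2]
  }
  if (!is.null(spn_class)) out$spn_class <- spn_class
  class(out) <- c("preference_map", "data.frame")
  out
}

#' Feedback-alignment trajectory
#'
#' Cosine similarity between the vectorized readout weight matrix and the
#' sign-adjusted transposed feedback matrix, per weight snapshot. Columns of
#' \eqn{D^\top} belonging to dSPNs are negated, since feedback alignment
#' drives the (negative) dSPN readout weights toward \eqn{-d_{jk}}. Under
#' heterogeneous feedback the similarity increases over training.
#'
#' @param snapshots list of readout weight matrices (`d x n_str`), e.g.
#'   `run_result$snapshots`.
#' @param D feedback matrix (`n_str x d`).
#' @param spn_class per-SPN class labels (`"dSPN"`/`"iSPN"`).
#' @return Numeric vector of cosine similarities (NA for zero snapshots).
#' @export
alignment_trajectory <- function(snapshots, D, spn_class) {
  Dt <- t(D)
  Dt[, spn_class == "dSPN"] <- -Dt[, spn_class == "dSPN"]
  ref <- as.vector(Dt)
  ref_n <- sqrt(sum(ref^2))
  vapply(snapshots, function(W) {
    w <- as.vector(W)
    wn <- sqrt(sum(w^2))
    if (wn == 0 || ref_n == 0) return(NA_real_)
    sum(w * ref) / (wn * ref_n)
  }, numeric(1))
}
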