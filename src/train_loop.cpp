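// Training loop for the basal-ganglia rate network.
//
// The loop mirrors, step for step, the reference R operations
// (sigmoid_rate, step_membrane, readout_rates, snc_error_rates,
// update_eligibility, striatal_weight_update, striatofugal_update,
// lowpass_dopamine, highpass_compensate); agreement with the pure-R engine
// is asserted in the test suite on small instances.
//
// Fixed update order within a step:
//   (1) thalamic rates imposed; cortical/striatal rates from current V
//   (2) readout rates, error vector, dopamine signal
//   (3) eligibility traces advanced, then weight updates + sign clamping
//   (4) synchronous Euler update of membrane potentials.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline arma::vec sigm(const arma::vec& v, double b) {
  return 1.0 / (1.0 + arma::exp(-v + b));
}

// [[Rcpp::export(name = ".train_loop_cpp")]]
List train_loop_cpp(arma::mat W_thal_ctx, arma::mat W_ctx_ctx,
                    arma::mat W_thal_str, arma::mat M_thal_str,
                    arma::mat W_ctx_str, arma::mat M_ctx_str,
                    arma::mat W_str_str, arma::mat M_str_str,
                    arma::mat W_str_snr, arma::mat M_str_snr,
                    arma::vec snr_pre_sign, arma::vec alpha_per_spn,
                    double beta, arma::mat D, int variant,
                    arma::mat targets, arma::vec A, arma::vec B,
                    double tau_m, double b, double dt, double T_period,
                    double tau_str, int n_trials, int n_steps,
                    double tau_da, bool compensate, bool lowpass_normalized,
                    bool plastic_thal_str, bool plastic_ctx_str,
                    bool plastic_str_str, bool plastic_str_snr,
                    int n_record_trials, IntegerVector snap_after) {
  const int n_ctx = W_ctx_ctx.n_rows;
  const int n_str = W_str_str.n_rows;
  const int d = W_str_snr.n_rows;

  arma::vec V_ctx(n_ctx, arma::fill::zeros);
  arma::vec V_str(n_str, arma::fill::zeros);
  arma::mat P_thal_str(arma::size(W_thal_str), arma::fill::zeros);
  arma::mat P_ctx_str(arma::size(W_ctx_str), arma::fill::zeros);
  arma::mat P_str_str(arma::size(W_str_str), arma::fill::zeros);

  const bool striatal_plastic_any =
      variant != 0 && (plastic_thal_str || plastic_ctx_str || plastic_str_str);
  const double xi = (tau_da > 0) ? std::exp(-dt / tau_da) : 0.0;

  arma::vec Cf(n_str, arma::fill::zeros);
  arma::vec A_prev(n_str, arma::fill::zeros);

  arma::vec trial_loss(n_trials, arma::fill::zeros);
  arma::mat rec_first_snr(d, n_steps, arma::fill::zeros);
  const int rec_steps = std::min(n_record_trials, n_trials) * n_steps;
  arma::mat rec_str(n_str, rec_steps, arma::fill::zeros);
  arma::mat rec_snr(d, rec_steps, arma::fill::zeros);
  const int first_rec_trial = n_trials - std::min(n_record_trials, n_trials);

  const int n_snap = snap_after.size();
  arma::cube snaps(d, n_str, n_snap, arma::fill::zeros);
  int snap_i = 0;
  // snapshot "after 0 trials" = initial weights
  while (snap_i < n_snap && snap_after[snap_i] == 0) {
    snaps.slice(snap_i) = W_str_snr;
    ++snap_i;
  }

  const double two_pi = 2.0 * M_PI;

  for (int trial = 0; trial < n_trials; ++trial) {
    double loss_acc = 0.0;
    for (int st = 0; st < n_steps; ++st) {
      const double t = st * dt;
      const double ph = two_pi * t / T_period;
      const arma::vec r_thal = sigm(A * std::cos(ph) + B * std::sin(ph), b);
      const arma::vec r_ctx = sigm(V_ctx, b);
      const arma::vec r_str = sigm(V_str, b);
      const arma::vec r_snr = sigm(W_str_snr * r_str, b);

      const arma::vec err = r_snr - targets.col(st);
      loss_acc += 0.5 * arma::dot(err, err) * dt;
      const arma::vec eps = err % r_snr % (1.0 - r_snr);

      if (striatal_plastic_any) {
        // dopamine signal per SPN
        arma::vec c_raw;
        if (variant == 2) {
          // Ideal feedback: the current readout weights, adjusted by the
          // SPN class sign so the pathway-specific alpha signs cancel and
          // every afferent follows the true loss gradient.
          c_raw = snr_pre_sign % (W_str_snr.t() * eps);
        } else {
          c_raw = D * eps;
        }
        arma::vec a;
        if (tau_da > 0) {
          Cf = xi * Cf + (lowpass_normalized ? (1.0 - xi) : 1.0) * c_raw;
          if (compensate) {
            const arma::vec A_now = Cf / (1.0 - xi);
            a = A_now - xi * A_prev;
            A_prev = A_now;
          } else {
            a = Cf;
          }
        } else {
          a = c_raw;
        }

        const arma::vec post = r_str % (1.0 - r_str);
        const arma::vec gate = -dt * (alpha_per_spn % a);
        const double kdec = dt / tau_str;
        // Fused per-synapse pass: eligibility Euler step, three-factor
        // weight update, Dale's-law clamp. Masked synapses keep trace and
        // weight at zero throughout.
        auto plast = [&](arma::mat& P, arma::mat& W, const arma::mat& M,
                         const arma::vec& r_pre, const bool inhib) {
          const arma::uword nr = P.n_rows, nc = P.n_cols;
          for (arma::uword c = 0; c < nc; ++c) {
            const double rp = r_pre[c];
            const double* m = M.colptr(c);
            double* p = P.colptr(c);
            double* w = W.colptr(c);
            for (arma::uword r = 0; r < nr; ++r) {
              p[r] += kdec * (post[r] * rp * m[r] - p[r]);
              const double nw = w[r] + gate[r] * p[r];
              w[r] = inhib ? (nw > 0 ? 0.0 : nw) : (nw < 0 ? 0.0 : nw);
            }
          }
        };
        if (plastic_thal_str) plast(P_thal_str, W_thal_str, M_thal_str,
                                    r_thal, false);
        if (plastic_ctx_str) plast(P_ctx_str, W_ctx_str, M_ctx_str,
                                   r_ctx, false);
        if (plastic_str_str) plast(P_str_str, W_str_str, M_str_str,
                                   r_str, true);
      }

      if (plastic_str_snr) {
        W_str_snr += (-beta * dt) * (eps * r_str.t()) % M_str_snr;
        // Dale's law: dSPN columns stay <= 0, iSPN columns >= 0.
        for (int j = 0; j < n_str; ++j) {
          if (snr_pre_sign[j] < 0) {
            for (int k = 0; k < d; ++k)
              if (W_str_snr(k, j) > 0) W_str_snr(k, j) = 0;
          } else {
            for (int k = 0; k < d; ++k)
              if (W_str_snr(k, j) < 0) W_str_snr(k, j) = 0;
          }
        }
      }

      V_ctx += dt * (-V_ctx / tau_m + W_thal_ctx * r_thal + W_ctx_ctx * r_ctx);
      V_str += dt * (-V_str / tau_m + W_thal_str * r_thal +
                     W_ctx_str * r_ctx + W_str_str * r_str);

      if (trial == 0) rec_first_snr.col(st) = r_snr;
      if (trial >= first_rec_trial) {
        const int col = (trial - first_rec_trial) * n_steps + st;
        rec_str.col(col) = r_str;
        rec_snr.col(col) = r_snr;
      }
    }
    if (!V_ctx.is_finite() || !V_str.is_finite()) {
      stop("simulation diverged (non-finite state) in trial %d", trial + 1);
    }
    trial_loss[trial] = loss_acc;
    while (snap_i < n_snap && snap_after[snap_i] == trial + 1) {
      snaps.slice(snap_i) = W_str_snr;
      ++snap_i;
    }
  }

  return List::create(
    _["per_trial_loss"] = trial_loss,
    _["W_thal_str"] = W_thal_str, _["W_ctx_str"] = W_ctx_str,
    _["W_str_str"] = W_str_str, _["W_str_snr"] = W_str_snr,
    _["rec_first_snr"] = rec_first_snr,
    _["rec_str"] = rec_str, _["rec_snr"] = rec_snr,
    _["snapshots"] = snaps,
    _["V_ctx"] = V_ctx, _["V_str"] = V_str);
}
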