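#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Single-spin Metropolis sweep over the r control-kernel layers of a tissue.
// X is the L x r matrix of CK gene values (0/1); fbar the frozen per-cell,
// per-layer spin of the BN-predicted CK update. n_mc distinct cells are drawn
// per layer (partial Fisher-Yates) and proposed sequentially; dE uses the
// partially updated configuration, so detailed balance holds per proposal.
static double sweep_layers(IntegerMatrix& X, const IntegerMatrix& nbr0, int r,
                           double J, double h0, double h, const NumericVector& psi,
                           double temp, int n_mc, const NumericMatrix& fbar,
                           std::vector<int>& idx) {
  const int L = X.nrow();
  double dE_total = 0.0;
  for (int m = 0; m < r; ++m) {
    for (int t = 0; t < n_mc; ++t) {
      int j = t + (int)(unif_rand() * (L - t));
      if (j >= L) j = L - 1;
      std::swap(idx[t], idx[j]);
      const int i = idx[t];
      const double si = 2.0 * X(i, m) - 1.0;
      double nb = 0.0;
      for (int a = 0; a < 4; ++a) nb += 2.0 * X(nbr0(i, a), m) - 1.0;
      const double dE = 2.0 * si * (J * nb + h0 * fbar(i, m) + h * psi[m]);
      if (dE <= 0.0 || unif_rand() < std::exp(-dE / temp)) {
        X(i, m) = 1 - X(i, m);
        dE_total += dE;
      }
    }
  }
  return dE_total;
}

// [[Rcpp::export]]
List cpp_metropolis_sweep(IntegerMatrix X, IntegerMatrix nbr, int r,
                          double J, double h0, double h, NumericVector psi,
                          double temp, int n_mc, NumericMatrix fbar) {
  IntegerMatrix Xs = clone(X);
  const int L = Xs.nrow();
  IntegerMatrix nbr0(L, 4);
  for (int i = 0; i < L; ++i)
    for (int a = 0; a < 4; ++a) nbr0(i, a) = nbr(i, a) - 1;
  std::vector<int> idx(L);
  for (int i = 0; i < L; ++i) idx[i] = i;
  double dE = sweep_layers(Xs, nbr0, r, J, h0, h, psi, temp, n_mc, fbar, idx);
  return List::create(_["spins"] = Xs, _["dE"] = dE);
}

// Hybrid Metropolis + synchronous-BN time evolution on decimal-encoded cell
// states (s in 0..2^n-1, gene 1 = most significant bit).  Precomputed tables:
//   othmap[s]  : non-CK bits (0..2^(n-r)-1) of the synchronous update of s
//   fmap[s, m] : spin (+/-1) the CK gene m+1 would take under the BN update of s
//   ghat[s, w] : projection basis g_w / <g_w, g_w> (used when magnetization or
//                feedback is required; pass a 0-column matrix otherwise)
// Per MC step: freeze fbar, Metropolis sweep of the CK layers, then one
// synchronous perturbed update of the non-CK genes of every cell (the whole
// replacement vector fires per cell with probability 1-(1-q)^n and overwrites
// non-CK genes only; CK genes carry the spin values).
// [[Rcpp::export]]
List cpp_run_tissue(IntegerVector s_init, IntegerMatrix nbr, int n, int r,
                    IntegerVector othmap, NumericMatrix fmap,
                    double J, double h0, double h, NumericVector psi,
                    double T0, double q, int n_mc, int steps,
                    bool selftune, double alpha, double dtau, double tmin,
                    NumericMatrix ghat, bool record_mtype, int record_G_every) {
  const int L = s_init.size();
  const int N = 1 << n;
  const int nfree = n - r;
  const int ckmask = ((1 << r) - 1) << nfree;
  const double rho = 1.0 - std::pow(1.0 - q, (double)n);
  const int W = ghat.ncol();
  const bool need_hist = record_mtype || selftune || record_G_every > 0;

  std::vector<int> s(L);
  for (int i = 0; i < L; ++i) s[i] = s_init[i];
  IntegerMatrix nbr0(L, 4);
  for (int i = 0; i < L; ++i)
    for (int a = 0; a < 4; ++a) nbr0(i, a) = nbr(i, a) - 1;

  double temp = T0;
  std::vector<int> idx(L);
  for (int i = 0; i < L; ++i) idx[i] = i;
  IntegerMatrix Xck(L, r);
  NumericMatrix fbar(L, r);
  std::vector<double> G(need_hist ? N : 0);
  std::vector<double> cw(W > 0 ? W : 1);

  NumericVector Mspin(steps);
  NumericVector Mtype((record_mtype || selftune) ? steps : 0);
  NumericVector Ttrace(selftune ? steps : 0);
  const int n_rec = record_G_every > 0 ? steps / record_G_every : 0;
  NumericMatrix Ghist(record_G_every > 0 ? N : 0, n_rec);
  NumericVector mean_state(n_rec);
  IntegerVector rec_steps(n_rec);
  double n_perturb = 0.0;

  for (int t = 0; t < steps; ++t) {
    // reset the selection pool so every step samples like a fresh sweep call
    for (int i = 0; i < L; ++i) idx[i] = i;
    // freeze fbar and extract CK layers
    for (int i = 0; i < L; ++i) {
      const int si = s[i];
      for (int m = 0; m < r; ++m) {
        Xck(i, m) = (si >> (n - 1 - m)) & 1;
        if (h0 != 0.0) fbar(i, m) = fmap(si, m);
      }
    }
    sweep_layers(Xck, nbr0, r, J, h0, h, psi, temp, n_mc, fbar, idx);
    // write spins back and synchronous perturbed update of non-CK genes
    for (int i = 0; i < L; ++i) {
      int ck = 0;
      for (int m = 0; m < r; ++m) ck = (ck << 1) | Xck(i, m);
      s[i] = (ck << nfree) | (s[i] & ~ckmask);
    }
    for (int i = 0; i < L; ++i) {
      int oth;
      if (rho > 0.0 && unif_rand() < rho) {
        oth = 0;
        for (int l = 0; l < nfree; ++l) oth = (oth << 1) | (unif_rand() < q ? 1 : 0);
        ++n_perturb;
      } else {
        oth = othmap[s[i]];
      }
      s[i] = (s[i] & ckmask) | oth;
    }

    double ms = 0.0;
    for (int i = 0; i < L; ++i) ms += 2.0 * ((s[i] >> (n - 1)) & 1) - 1.0;
    Mspin[t] = ms / L;

    double M = 0.0;
    if (need_hist) {
      std::fill(G.begin(), G.end(), 0.0);
      for (int i = 0; i < L; ++i) G[s[i]] += 1.0;
      for (int u = 0; u < N; ++u) G[u] /= L;
      if (W > 0) {
        double tot = 0.0;
        for (int w = 0; w < W; ++w) {
          double c = 0.0;
          for (int u = 0; u < N; ++u) c += G[u] * ghat(u, w);
          if (c < 0.0) c = 0.0;
          if (c > 1.0) c = 1.0;
          cw[w] = c;
          tot += c;
        }
        if (tot > 0.0) for (int w = 0; w < W; ++w) cw[w] /= tot;
        if (W == 2) M = cw[1] - cw[0];
      }
    }
    if (record_mtype || selftune) Mtype[t] = M;
    if (selftune) {
      temp += dtau * (std::fabs(M) - alpha * temp);
      if (temp < tmin) temp = tmin;
      Ttrace[t] = temp;
    }
    if (record_G_every > 0 && (t + 1) % record_G_every == 0) {
      const int rI = (t + 1) / record_G_every - 1;
      for (int u = 0; u < N; ++u) Ghist(u, rI) = G[u];
      double acc = 0.0;
      for (int i = 0; i < L; ++i) {
        int si = s[i];
        while (si) { acc += si & 1; si >>= 1; }
      }
      mean_state[rI] = acc / ((double)L * n);
      rec_steps[rI] = t + 1;
    }
  }

  IntegerVector s_out(L);
  for (int i = 0; i < L; ++i) s_out[i] = s[i];
  return List::create(_["s"] = s_out, _["M_spin"] = Mspin, _["M_type"] = Mtype,
                      _["T_trace"] = Ttrace, _["T_final"] = temp,
                      _["G_hist"] = Ghist, _["mean_state"] = mean_state,
                      _["steps_recorded"] = rec_steps,
                      _["n_perturbations"] = n_perturb);
}

// Single-cell noisy Boolean chain on decimal states with a precomputed
// deterministic next-state map (0-based).  pin_prefix >= 0 holds the r CK
// bits fixed at that value; the perturbation vector then covers the free
// bits only.  Returns the normalized visit histogram over the recorded steps.
// [[Rcpp::export]]
NumericVector cpp_bn_chain(IntegerVector dmap, int n, int r, int pin_prefix,
                           double q, int steps, int burn_in, int s0) {
  const int N = dmap.size();
  const double rho = 1.0 - std::pow(1.0 - q, (double)n);
  const int nfree = pin_prefix >= 0 ? n - r : n;
  const int base = pin_prefix >= 0 ? (pin_prefix << nfree) : 0;
  std::vector<double> counts(N, 0.0);
  int s = s0;
  for (int t = 0; t < burn_in + steps; ++t) {
    if (rho > 0.0 && unif_rand() < rho) {
      int g = 0;
      for (int l = 0; l < nfree; ++l) g = (g << 1) | (unif_rand() < q ? 1 : 0);
      s = base | g;
    } else {
      s = dmap[s];
    }
    if (t >= burn_in) counts[s] += 1.0;
  }
  NumericVector out(N);
  for (int u = 0; u < N; ++u) out[u] = counts[u] / steps;
  return out;
}

// Dynamic control-kernel chain: eta follows a small discrete-time Markov
// chain over pin states (columns of dmaps; pin_prefix[w] = -1 marks the
// unpinned column), the cell follows the corresponding pinned dynamics.
// [[Rcpp::export]]
List cpp_dynamic_ck_chain(IntegerMatrix dmaps, IntegerVector pin_prefix,
                          int n, int r, double q, NumericMatrix etaP,
                          int steps, int burn_in, int s0, int eta0) {
  const int N = dmaps.nrow();
  const int W = dmaps.ncol();
  const double rho = 1.0 - std::pow(1.0 - q, (double)n);
  std::vector<double> counts(N, 0.0), eta_counts(W, 0.0);
  int s = s0, e = eta0;
  for (int t = 0; t < burn_in + steps; ++t) {
    double u = unif_rand(), acc = 0.0;
    int enew = W - 1;
    for (int a = 0; a < W; ++a) {
      acc += etaP(e, a);
      if (u < acc) { enew = a; break; }
    }
    e = enew;
    const int pp = pin_prefix[e];
    if (rho > 0.0 && unif_rand() < rho) {
      const int nfree = pp >= 0 ? n - r : n;
      const int base = pp >= 0 ? (pp << nfree) : 0;
      int g = 0;
      for (int l = 0; l < nfree; ++l) g = (g << 1) | (unif_rand() < q ? 1 : 0);
      s = base | g;
    } else {
      s = dmaps(s, e);
    }
    if (t >= burn_in) { counts[s] += 1.0; eta_counts[e] += 1.0; }
  }
  NumericVector g_out(N), eta_out(W);
  for (int u = 0; u < N; ++u) g_out[u] = counts[u] / steps;
  for (int w = 0; w < W; ++w) eta_out[w] = eta_counts[w] / steps;
  return List::create(_["g"] = g_out, _["eta_occupancy"] = eta_out);
}
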