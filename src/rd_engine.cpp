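// Core reaction-diffusion engine: exact SSA for the lattice RDME and a
// fixed-step RK4 method-of-lines integrator for the deterministic PDEs.
// Both consume the same generic network description so that the three-species
// model and the five-species Muk model run on one engine.
//
// Conventions:
//   counts        S x nbox integer state (molecules per species per box)
//   stoichR[s,c]  reactant stoichiometry of channel c (one direction of a
//                 reversible reaction); stoichN[s,c] its net change
//   kscaled[c]    k_c * dx^(1-order): propensity of channel c in box i is
//                 kscaled[c] * prod_s n[s][i]^(falling stoichR[s,c])
//                 (falling factorials: exact CME combinatorics)
//   hop[s]        D_s / dx^2; end boxes hop inward only (no-flux boundary)

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// [[Rcpp::export(name = ".ssa_run_cpp")]]
List ssa_run_cpp(IntegerMatrix counts0, NumericVector hop,
                 IntegerMatrix stoichR, IntegerMatrix stoichN,
                 NumericVector kscaled, IntegerVector partner,
                 double t0, double t_end, double sample_dt,
                 double max_events, bool tally_entropy) {
  const int S = counts0.nrow(), B = counts0.ncol(), C = kscaled.size();
  std::vector<double> n(S * B);
  for (int b = 0; b < B; ++b)
    for (int s = 0; s < S; ++s) n[s + b * S] = counts0(s, b);

  // sparse per-channel reactant and net-change lists (raw arrays: the
  // SSA loop must not touch Rcpp accessors)
  std::vector<double> kch(C);
  std::vector<int> nre(C), re_s(C * 4), re_m(C * 4);
  std::vector<int> nch(C), ch_s(C * 4), ch_d(C * 4);
  std::vector<int> part(C);
  for (int c = 0; c < C; ++c) {
    kch[c] = kscaled[c];
    part[c] = partner[c];
    int k = 0;
    for (int s = 0; s < S; ++s)
      if (stoichR(s, c) > 0) { re_s[c * 4 + k] = s; re_m[c * 4 + k] = stoichR(s, c); ++k; }
    nre[c] = k;
    k = 0;
    for (int s = 0; s < S; ++s)
      if (stoichN(s, c) != 0) { ch_s[c * 4 + k] = s; ch_d[c * 4 + k] = stoichN(s, c); ++k; }
    nch[c] = k;
  }
  std::vector<double> hv(S);
  for (int s = 0; s < S; ++s) hv[s] = hop[s];

  std::vector<double> a(C * B), treac(B, 0.0), thop(B, 0.0);
  double ttot = 0.0;
  auto chan_prop = [&](int b, int c) -> double {
    double v = kch[c];
    if (v == 0.0) return 0.0;
    for (int k = 0; k < nre[c]; ++k) {
      double nn = n[re_s[c * 4 + k] + b * S];
      int m = re_m[c * 4 + k];
      v *= nn;
      if (m > 1) v *= (nn - 1.0);
      if (m > 2) v *= (nn - 2.0);
    }
    return v > 0.0 ? v : 0.0;
  };
  auto refresh_box = [&](int b) {
    double tr = 0.0;
    double* ab = &a[b * C];
    for (int c = 0; c < C; ++c) { ab[c] = chan_prop(b, c); tr += ab[c]; }
    double th = 0.0;
    int nn = (B == 1) ? 0 : ((b == 0 || b == B - 1) ? 1 : 2);
    if (nn) {
      const double* nb = &n[b * S];
      for (int s = 0; s < S; ++s) th += hv[s] * nb[s];
      th *= nn;
    }
    ttot += (tr - treac[b]) + (th - thop[b]);
    treac[b] = tr;
    thop[b] = th;
  };
  auto full_refresh = [&]() {
    ttot = 0.0;
    for (int b = 0; b < B; ++b) { treac[b] = 0.0; thop[b] = 0.0; }
    ttot = 0.0;
    for (int b = 0; b < B; ++b) refresh_box(b);
  };
  full_refresh();

  const int nsamp = (int)std::floor((t_end - t0) / sample_dt + 1e-9) + 1;
  IntegerVector snaps(S * B * nsamp);
  NumericVector times(nsamp);
  int isamp = 0;
  auto record_until = [&](double tnow) {
    while (isamp < nsamp && t0 + isamp * sample_dt <= tnow + 1e-12) {
      times[isamp] = t0 + isamp * sample_dt;
      int* sp = &snaps[isamp * S * B];
      for (int i = 0; i < S * B; ++i) sp[i] = (int)n[i];
      ++isamp;
    }
  };

  double t = t0, events = 0.0, entropy = 0.0;
  bool entropy_ok = tally_entropy;
  record_until(t);
  RNGScope scope;
  double since_refresh = 0.0;

  while (t < t_end && isamp < nsamp) {
    if (!(ttot > 0.0)) { t = t_end; break; }
    if (!R_finite(ttot)) stop("propensity overflow at t=%g", t);
    double tnew = t - std::log(unif_rand()) / ttot;
    if (tnew > t_end) { t = t_end; break; }
    record_until(tnew);
    t = tnew;

    // pick box
    double r = unif_rand() * ttot;
    int b = 0;
    for (; b < B - 1; ++b) {
      double tb = treac[b] + thop[b];
      if (r < tb) break;
      r -= tb;
    }
    if (r < treac[b]) {
      // reaction channel
      const double* ab = &a[b * C];
      int c = 0;
      for (; c < C - 1; ++c) {
        if (r < ab[c]) break;
        r -= ab[c];
      }
      double afwd = ab[c];
      for (int k = 0; k < nch[c]; ++k)
        n[ch_s[c * 4 + k] + b * S] += ch_d[c * 4 + k];
      refresh_box(b);
      if (entropy_ok) {
        int p = part[c];
        if (p < 0) entropy_ok = false;
        else {
          double abwd = a[b * C + p];
          if (abwd > 0.0 && afwd > 0.0) entropy += std::log(afwd / abwd);
          else entropy_ok = false;
        }
      }
    } else {
      // hop: walk species, then direction (left neighbour first)
      r -= treac[b];
      int s = 0, dir = 0;
      bool has_l = b > 0, has_r = b < B - 1;
      for (; s < S; ++s) {
        double per = hv[s] * n[s + b * S];
        if (has_l) { if (r < per) { dir = -1; break; } r -= per; }
        if (has_r) { if (r < per) { dir = +1; break; } r -= per; }
      }
      if (s >= S) { s = S - 1; dir = has_r ? +1 : -1; }  // fp guard
      int b2 = b + dir;
      double nfrom = n[s + b * S];
      n[s + b * S] -= 1.0;
      n[s + b2 * S] += 1.0;
      refresh_box(b);
      refresh_box(b2);
      if (entropy_ok) entropy += std::log(nfrom / n[s + b2 * S]);
    }
    events += 1.0;
    since_refresh += 1.0;
    if (since_refresh > 1e6) {  // control fp drift in cached sums
      full_refresh();
      since_refresh = 0.0;
    }
    if (events >= max_events)
      stop("max_events (%g) exceeded at t=%g", max_events, t);
  }
  record_until(t_end);

  snaps.attr("dim") = IntegerVector::create(S, B, nsamp);
  return List::create(_["times"] = times, _["counts"] = snaps,
                      _["n_events"] = events,
                      _["entropy"] = entropy_ok ? entropy : NA_REAL,
                      _["t_final"] = t);
}

// deterministic mass-action + diffusion right-hand side, du/dt for u (S x B)
static void rd_rhs(const std::vector<double>& u, std::vector<double>& du,
                   int S, int B, const std::vector<int>& stR,
                   const std::vector<int>& stN, const std::vector<double>& k,
                   const std::vector<double>& D, double dx) {
  const int C = (int)k.size();
  std::fill(du.begin(), du.end(), 0.0);
  for (int b = 0; b < B; ++b) {
    const double* ub = &u[b * S];
    double* dub = &du[b * S];
    for (int c = 0; c < C; ++c) {
      double f = k[c];
      if (f == 0.0) continue;
      for (int s = 0; s < S; ++s) {
        int m = stR[s + c * S];
        if (m) {
          f *= ub[s];
          if (m > 1) f *= ub[s];
          if (m > 2) f *= ub[s];
        }
      }
      for (int s = 0; s < S; ++s) {
        int nu = stN[s + c * S];
        if (nu) dub[s] += nu * f;
      }
    }
  }
  if (B > 1) {
    double idx2 = 1.0 / (dx * dx);
    for (int b = 0; b < B; ++b) {
      // no-flux ghost cells: the mirror ghost equals the boundary box, so
      // an end box exchanges through its single interior interface only
      int bl = (b == 0) ? b : b - 1;
      int br = (b == B - 1) ? b : b + 1;
      for (int s = 0; s < S; ++s)
        du[s + b * S] +=
            D[s] * idx2 *
            (u[s + bl * S] - 2.0 * u[s + b * S] + u[s + br * S]);
    }
  }
}

static void unpack(const IntegerMatrix& m, std::vector<int>& v) {
  v.assign(m.begin(), m.end());
}

// [[Rcpp::export(name = ".rd_rhs_cpp")]]
NumericMatrix rd_rhs_cpp(NumericMatrix u0, IntegerMatrix stoichR,
                         IntegerMatrix stoichN, NumericVector k,
                         NumericVector D, double dx) {
  const int S = u0.nrow(), B = u0.ncol();
  std::vector<int> stR, stN;
  unpack(stoichR, stR); unpack(stoichN, stN);
  std::vector<double> kv(k.begin(), k.end()), Dv(D.begin(), D.end());
  std::vector<double> u(u0.begin(), u0.end()), du(S * B);
  rd_rhs(u, du, S, B, stR, stN, kv, Dv, dx);
  NumericMatrix out(S, B);
  std::copy(du.begin(), du.end(), out.begin());
  return out;
}

// [[Rcpp::export(name = ".rd_integrate_cpp")]]
List rd_integrate_cpp(NumericMatrix u0, IntegerMatrix stoichR,
                      IntegerMatrix stoichN, NumericVector k, NumericVector D,
                      double dx, double t0, double t_end, double dt,
                      double sample_dt) {
  const int S = u0.nrow(), B = u0.ncol(), n = S * B;
  std::vector<int> stR, stN;
  unpack(stoichR, stR); unpack(stoichN, stN);
  std::vector<double> kv(k.begin(), k.end()), Dv(D.begin(), D.end());
  std::vector<double> u(u0.begin(), u0.end());
  std::vector<double> k1(n), k2(n), k3(n), k4(n), tmp(n);

  const int nsamp = (int)std::floor((t_end - t0) / sample_dt + 1e-9) + 1;
  NumericVector times(nsamp);
  NumericVector snaps(n * nsamp);
  int isamp = 0;
  double t = t0;
  auto record = [&]() {
    times[isamp] = t;
    for (int i = 0; i < n; ++i) snaps[i + isamp * n] = u[i];
    ++isamp;
  };
  record();
  while (isamp < nsamp) {
    double ttarget = t0 + isamp * sample_dt;
    while (t < ttarget - 1e-12) {
      double h = std::min(dt, ttarget - t);
      rd_rhs(u, k1, S, B, stR, stN, kv, Dv, dx);
      for (int i = 0; i < n; ++i) tmp[i] = u[i] + 0.5 * h * k1[i];
      rd_rhs(tmp, k2, S, B, stR, stN, kv, Dv, dx);
      for (int i = 0; i < n; ++i) tmp[i] = u[i] + 0.5 * h * k2[i];
      rd_rhs(tmp, k3, S, B, stR, stN, kv, Dv, dx);
      for (int i = 0; i < n; ++i) tmp[i] = u[i] + h * k3[i];
      rd_rhs(tmp, k4, S, B, stR, stN, kv, Dv, dx);
      bool bad = false;
      for (int i = 0; i < n; ++i) {
        u[i] += h / 6.0 * (k1[i] + 2.0 * k2[i] + 2.0 * k3[i] + k4[i]);
        if (!R_finite(u[i])) bad = true;
        if (u[i] < 0.0 && u[i] > -1e-13) u[i] = 0.0;  // clip roundoff only
      }
      if (bad) stop("integrator diverged (non-finite state) at t=%g", t);
      t += h;
    }
    t = ttarget;
    record();
  }
  snaps.attr("dim") = IntegerVector::create(S, B, nsamp);
  return List::create(_["times"] = times, _["fields"] = snaps);
}
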