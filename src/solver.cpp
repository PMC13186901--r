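// One-dimensional pulse-wave solver for an arterial tree.
//
// Conservative (A, Q) form with an elastic thin-wall tube law
//   P(A) = p_ref + beta/A0 * (sqrt(A) - sqrt(A0)),
// solved per vessel with a two-step MacCormack scheme. Junctions enforce
// mass conservation and total-pressure continuity through Riemann
// invariants (u +/- 4c); terminals couple to R-C-R windkessel elements.
// Cardiac cycles are iterated until the inlet pressure waveform is
// periodic to a relative L2 tolerance.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

namespace {

struct Vessel {
  int n;            // cells
  double dx;
  double A0, beta, cc; // cc = sqrt(beta / (2 rho A0)); c = cc * A^(1/4)
  int off;          // offset into state arrays
  // ghost states
  double Agl, Qgl, Agr, Qgr;
};

struct Solver {
  std::vector<Vessel> ves;
  std::vector<double> A, Q;     // cell states
  double rho, mu, fric_coef, p_ref, p_out;
  double period;

  double wave_c(const Vessel& v, double a) const {
    return v.cc * std::sqrt(std::sqrt(a));
  }
  double pressure(const Vessel& v, double a) const {
    return p_ref + v.beta / v.A0 * (std::sqrt(a) - std::sqrt(v.A0));
  }
  double flux2(const Vessel& v, double a, double q) const {
    return q * q / a + v.beta / (3.0 * rho * v.A0) * a * std::sqrt(a);
  }
  double source2(double a, double q) const {
    // friction: -2 (gamma + 2) pi mu Q / (rho A); fric_coef holds
    // 2 (gamma + 2) pi mu / rho
    return -fric_coef * q / a;
  }
};

// dense Gaussian elimination with partial pivoting, n <= 8
bool gauss_solve(int n, double* M, double* b) {
  for (int col = 0; col < n; ++col) {
    int piv = col;
    for (int r = col + 1; r < n; ++r)
      if (std::fabs(M[r * n + col]) > std::fabs(M[piv * n + col])) piv = r;
    if (std::fabs(M[piv * n + col]) < 1e-300) return false;
    if (piv != col) {
      for (int c = 0; c < n; ++c) std::swap(M[col * n + c], M[piv * n + c]);
      std::swap(b[col], b[piv]);
    }
    for (int r = col + 1; r < n; ++r) {
      double f = M[r * n + col] / M[col * n + col];
      for (int c = col; c < n; ++c) M[r * n + c] -= f * M[col * n + c];
      b[r] -= f * b[col];
    }
  }
  for (int r = n - 1; r >= 0; --r) {
    double s = b[r];
    for (int c = r + 1; c < n; ++c) s -= M[r * n + c] * b[c];
    b[r] = s / M[r * n + r];
  }
  return true;
}

} // namespace

// [[Rcpp::export]]
List solve_network_1d_cpp(
    NumericVector len, NumericVector r0, NumericVector wallh, NumericVector emod,
    IntegerVector ncells,
    IntegerVector junc_parent, List junc_children,
    IntegerVector leaf_vessel, NumericVector tR1, NumericVector tR2,
    NumericVector tC, NumericVector Pc0,
    NumericVector Ainit, NumericVector Qinit,
    int root,
    NumericVector inflow, double period,
    double rho, double nu_poisson, double mu, double gamma_profile,
    double p_ref, double p_out, double cfl,
    int max_cycles, double tol, IntegerVector out_vessels, int n_out) {

  const int nv = len.size();
  Solver S;
  S.rho = rho; S.mu = mu; S.p_ref = p_ref; S.p_out = p_out;
  S.period = period;
  S.fric_coef = 2.0 * (gamma_profile + 2.0) * M_PI * mu / rho;
  S.ves.resize(nv);
  int total = 0;
  for (int v = 0; v < nv; ++v) {
    Vessel& V = S.ves[v];
    V.n = ncells[v];
    V.dx = len[v] / V.n;
    V.A0 = M_PI * r0[v] * r0[v];
    V.beta = std::sqrt(M_PI) * wallh[v] * emod[v] / (1.0 - nu_poisson * nu_poisson);
    V.cc = std::sqrt(V.beta / (2.0 * rho * V.A0));
    V.off = total;
    total += V.n;
  }
  S.A.assign(total, 0.0); S.Q.assign(total, 0.0);
  for (int v = 0; v < nv; ++v) {
    Vessel& V = S.ves[v];
    for (int i = 0; i < V.n; ++i) {
      S.A[V.off + i] = Ainit[v];
      S.Q[V.off + i] = Qinit[v];
    }
    V.Agl = Ainit[v]; V.Qgl = Qinit[v]; V.Agr = Ainit[v]; V.Qgr = Qinit[v];
  }

  const int nj = junc_parent.size();
  std::vector< std::vector<int> > jkids(nj);
  std::vector< std::vector<double> > jsol(nj); // warm-start areas
  for (int j = 0; j < nj; ++j) {
    IntegerVector k = junc_children[j];
    jkids[j].assign(k.begin(), k.end());
    jsol[j].resize(k.size() + 1);
    jsol[j][0] = Ainit[junc_parent[j]];
    for (int c = 0; c < (int)jkids[j].size(); ++c)
      jsol[j][c + 1] = Ainit[jkids[j][c]];
  }
  const int nl = leaf_vessel.size();
  std::vector<double> Pc(Pc0.begin(), Pc0.end()); // windkessel internal pressure

  const int m_in = inflow.size();
  auto inflow_at = [&](double t) {
    double frac = t / period;
    double tau = (frac - std::floor(frac)) * m_in;
    int i = (int)std::floor(tau);
    double w = tau - i;
    int i0 = i % m_in, i1 = (i + 1) % m_in;
    return inflow[i0] * (1 - w) + inflow[i1] * w;
  };

  // output buffers
  const int nov = out_vessels.size();
  NumericMatrix outP(n_out, nov), outQ(n_out, nov), outA(n_out, nov);
  std::vector<char> bin_filled(n_out, 0);
  std::vector<double> inletP_prev(n_out, 0.0), inletP_cur(n_out, 0.0);

  // predictor storage
  std::vector<double> As(total), Qs(total);

  double t = 0.0;
  int cycle = 0;
  std::vector<double> resid_hist;
  bool converged = false;
  int bad_vessel = -1; double bad_time = -1;
  double JM[64], Jb[8], xj[8];

      // boundary conditions: fill ghost states from the given stage
      // arrays; optionally advance the windkessel pressures
      auto solve_bcs = [&](const std::vector<double>& Aa,
                           const std::vector<double>& Qa,
                           double tv, double dt, bool advance_pc) {
        
        // inlet of the root vessel: prescribed flow
        {
          Vessel& V = S.ves[root];
          double a0 = Aa[V.off], q0 = Qa[V.off];
          double u0 = q0 / a0, c0 = S.wave_c(V, a0);
          double W2 = u0 - 4.0 * c0;
          double qin = inflow_at(tv);
          double a = a0;
          for (int it = 0; it < 30; ++it) {
            double c = S.wave_c(V, a);
            double f = qin / a - 4.0 * c - W2;
            double df = -qin / (a * a) - c / a;
            double da = f / df;
            a -= da;
            if (a < 0.05 * V.A0) a = 0.05 * V.A0;
            if (std::fabs(da) < 1e-14 * V.A0) break;
          }
          V.Agl = a; V.Qgl = qin;
        }
        // junctions
        for (int j = 0; j < nj; ++j) {
          Vessel& P = S.ves[junc_parent[j]];
          const std::vector<int>& kids = jkids[j];
          int k = kids.size();
          double ap = Aa[P.off + P.n - 1];
          double up = Qa[P.off + P.n - 1] / ap;
          double W1 = up + 4.0 * S.wave_c(P, ap);
          double W2[8];
          xj[0] = jsol[j][0];
          for (int c = 0; c < k; ++c) {
            Vessel& C = S.ves[kids[c]];
            double a = Aa[C.off];
            double u = Qa[C.off] / a;
            W2[c] = u - 4.0 * S.wave_c(C, a);
            xj[c + 1] = jsol[j][c + 1];
          }
          int dim = k + 1;
          for (int it = 0; it < 15; ++it) {
            double apj = xj[0];
            double cp = S.wave_c(P, apj);
            double upj = W1 - 4.0 * cp;
            double pp = S.pressure(P, apj);
            // residuals
            double mass = apj * upj;
            for (int r = 0; r < dim * dim; ++r) JM[r] = 0.0;
            // row 0: mass
            JM[0] = upj - cp;
            for (int c = 0; c < k; ++c) {
                Vessel& C = S.ves[kids[c]];
                double acj = xj[c + 1];
                double cc = S.wave_c(C, acj);
                double ucj = W2[c] + 4.0 * cc;
                mass -= acj * ucj;
                JM[c + 1] = -(ucj + cc);
                // row c+1: total pressure continuity parent vs child c
                double res = pp + 0.5 * rho * upj * upj -
                                 S.pressure(C, acj) - 0.5 * rho * ucj * ucj;
                JM[(c + 1) * dim + 0] = rho * (cp * cp - upj * cp) / apj;
                JM[(c + 1) * dim + (c + 1)] = -rho * (cc * cc + ucj * cc) / acj;
                Jb[c + 1] = res;
            }
            Jb[0] = mass;
            if (!gauss_solve(dim, JM, Jb)) break;
            double mx = 0.0;
            for (int r = 0; r < dim; ++r) {
                xj[r] -= Jb[r];
                Vessel& VV = (r == 0) ? P : S.ves[kids[r - 1]];
                if (xj[r] < 0.05 * VV.A0) xj[r] = 0.05 * VV.A0;
                mx = std::max(mx, std::fabs(Jb[r]) / VV.A0);
            }
            if (mx < 1e-11) break;
          }
          for (int r = 0; r < dim; ++r) jsol[j][r] = xj[r];
          {
            double apj = xj[0];
            double upj = W1 - 4.0 * S.wave_c(P, apj);
            P.Agr = apj; P.Qgr = apj * upj;
          }
          for (int c = 0; c < k; ++c) {
            Vessel& C = S.ves[kids[c]];
            double acj = xj[c + 1];
            double ucj = W2[c] + 4.0 * S.wave_c(C, acj);
            C.Agl = acj; C.Qgl = acj * ucj;
          }
        }
        // leaf outlets: R-C-R
        for (int l = 0; l < nl; ++l) {
          Vessel& V = S.ves[leaf_vessel[l]];
          double a0 = Aa[V.off + V.n - 1];
          double u0 = Qa[V.off + V.n - 1] / a0;
          double W1 = u0 + 4.0 * S.wave_c(V, a0);
          double a = a0;
          for (int it = 0; it < 30; ++it) {
            double c = S.wave_c(V, a);
            double u = W1 - 4.0 * c;
            double f = a * u - (S.pressure(V, a) - Pc[l]) / tR1[l];
            double df = (u - c) - rho * c * c / (a * tR1[l]);
            double da = f / df;
            a -= da;
            if (a < 0.05 * V.A0) a = 0.05 * V.A0;
            if (std::fabs(da) < 1e-14 * V.A0) break;
          }
          double u = W1 - 4.0 * S.wave_c(V, a);
          double qb = a * u;
          V.Agr = a; V.Qgr = qb;
          if (advance_pc)
            Pc[l] += dt * (qb - (Pc[l] - p_out) / tR2[l]) / tC[l];
        }

      };

  std::vector<double> Pc_start(nl);
  std::vector<double> A_start(total), Q_start(total);
  while (cycle < max_cycles) {
    double cyc_end = (cycle + 1) * period;
    std::fill(bin_filled.begin(), bin_filled.end(), 0);
    std::fill(inletP_cur.begin(), inletP_cur.end(), 0.0);
    Pc_start = Pc;
    A_start = S.A; Q_start = S.Q;

    while (t < cyc_end - 1e-12) {
      // --- time step from CFL ---
      double dt = 1e9;
      for (int v = 0; v < nv; ++v) {
        const Vessel& V = S.ves[v];
        for (int i = 0; i < V.n; ++i) {
          double a = S.A[V.off + i];
          double u = S.Q[V.off + i] / a;
          double c = S.wave_c(V, a);
          double lim = V.dx / (std::fabs(u) + c);
          if (lim < dt) dt = lim;
        }
      }
      dt *= cfl;
      if (t + dt > cyc_end) dt = cyc_end - t;

      // --- two-stage MacCormack update ---
      // stage 1: ghosts from time-n states (right ghosts feed the
      // forward predictor); windkessel pressures advance here
      solve_bcs(S.A, S.Q, t, dt, true);
      for (int v = 0; v < nv; ++v) {
        Vessel& V = S.ves[v];
        double r = dt / V.dx;
        int o = V.off;
        for (int i = 0; i < V.n; ++i) {
          double a = S.A[o + i], q = S.Q[o + i];
          double a1 = (i + 1 < V.n) ? S.A[o + i + 1] : V.Agr;
          double q1 = (i + 1 < V.n) ? S.Q[o + i + 1] : V.Qgr;
          As[o + i] = a - r * (q1 - q);
          Qs[o + i] = q - r * (S.flux2(V, a1, q1) - S.flux2(V, a, q)) +
                      dt * S.source2(a, q);
          if (As[o + i] < 0.05 * V.A0) As[o + i] = 0.05 * V.A0;
        }
      }
      // stage 2: ghosts from predictor states (left ghosts feed the
      // backward corrector)
      solve_bcs(As, Qs, t + dt, dt, false);
      for (int v = 0; v < nv; ++v) {
        Vessel& V = S.ves[v];
        double r = dt / V.dx;
        int o = V.off;
        for (int i = 0; i < V.n; ++i) {
          double am = (i > 0) ? As[o + i - 1] : V.Agl;
          double qm = (i > 0) ? Qs[o + i - 1] : V.Qgl;
          double as = As[o + i], qs = Qs[o + i];
          double anew = 0.5 * (S.A[o + i] + as) - 0.5 * r * (qs - qm);
          double qnew = 0.5 * (S.Q[o + i] + qs) -
                        0.5 * r * (S.flux2(V, as, qs) - S.flux2(V, am, qm)) +
                        0.5 * dt * S.source2(as, qs);
          if (anew < 0.05 * V.A0) anew = 0.05 * V.A0;
          S.A[o + i] = anew; S.Q[o + i] = qnew;
        }
      }

      t += dt;

      // --- record ---
      double tau = t - cycle * period;
      int bin = (int)std::floor(tau / period * n_out);
      if (bin >= n_out) bin = n_out - 1;
      if (bin >= 0) {
        bin_filled[bin] = 1;
        for (int ov = 0; ov < nov; ++ov) {
          Vessel& V = S.ves[out_vessels[ov]];
          int mid = V.off + V.n / 2;
          outA(bin, ov) = S.A[mid];
          outQ(bin, ov) = S.Q[mid];
          outP(bin, ov) = S.pressure(V, S.A[mid]);
        }
        Vessel& R = S.ves[root];
        inletP_cur[bin] = S.pressure(R, S.A[R.off]);
      }
      // NaN guard
      if (!std::isfinite(S.Q[S.ves[root].off])) { bad_vessel = root; bad_time = t; break; }
    }
    if (bad_vessel < 0) {
      for (int v = 0; v < nv && bad_vessel < 0; ++v) {
        const Vessel& V = S.ves[v];
        for (int i = 0; i < V.n; ++i)
          if (!std::isfinite(S.A[V.off + i]) || !std::isfinite(S.Q[V.off + i])) {
            bad_vessel = v; bad_time = t; break;
          }
      }
    }
    if (bad_vessel >= 0) break;
    // wrap-fill leading unvisited bins from the end of the (periodic) cycle
    {
      int f0 = 0;
      while (f0 < n_out && !bin_filled[f0]) ++f0;
      if (f0 > 0 && f0 < n_out && bin_filled[n_out - 1]) {
        for (int b = 0; b < f0; ++b) {
          for (int ov = 0; ov < nov; ++ov) {
            outA(b, ov) = outA(n_out - 1, ov);
            outQ(b, ov) = outQ(n_out - 1, ov);
            outP(b, ov) = outP(n_out - 1, ov);
          }
          inletP_cur[b] = inletP_cur[n_out - 1];
          bin_filled[b] = 1;
        }
      }
    }
    // forward-fill any unvisited bins
    for (int b = 1; b < n_out; ++b) {
      if (!bin_filled[b]) {
        for (int ov = 0; ov < nov; ++ov) {
          outA(b, ov) = outA(b - 1, ov);
          outQ(b, ov) = outQ(b - 1, ov);
          outP(b, ov) = outP(b - 1, ov);
        }
        inletP_cur[b] = inletP_cur[b - 1];
      }
    }
    // periodicity check on inlet pressure
    if (cycle >= 1) {
      double num = 0, den = 0;
      for (int b = 0; b < n_out; ++b) {
        double d = inletP_cur[b] - inletP_prev[b];
        num += d * d;
        den += inletP_cur[b] * inletP_cur[b];
      }
      double resid = std::sqrt(num / den);
      resid_hist.push_back(resid);
      if (resid < tol) { converged = true; ++cycle; break; }
      // Aitken acceleration of the dominant slow relaxation mode of the
      // cycle-to-cycle map, applied to the full state at fixed phase
      if (resid_hist.size() >= 2) {
        double r = resid / resid_hist[resid_hist.size() - 2];
        if (r > 0.2 && r < 0.95) {
          double alpha = r / (1.0 - r);
          for (int l = 0; l < nl; ++l)
            Pc[l] += alpha * (Pc[l] - Pc_start[l]);
          for (int i = 0; i < total; ++i) {
            S.A[i] += alpha * (S.A[i] - A_start[i]);
            S.Q[i] += alpha * (S.Q[i] - Q_start[i]);
          }
          for (int v = 0; v < nv; ++v) {
            const Vessel& V = S.ves[v];
            for (int i = 0; i < V.n; ++i) {
              double& a = S.A[V.off + i];
              if (a < 0.5 * V.A0) a = 0.5 * V.A0;
              if (a > 2.0 * V.A0) a = 2.0 * V.A0;
            }
          }
        }
      }
    }
    inletP_prev = inletP_cur;
    ++cycle;
  }

  NumericVector tgrid(n_out);
  for (int b = 0; b < n_out; ++b) tgrid[b] = (b + 0.5) * period / n_out;
  NumericVector inletP(n_out);
  for (int b = 0; b < n_out; ++b) inletP[b] = inletP_cur[b];

  return List::create(
    _["time"] = tgrid, _["pressure"] = outP, _["flow"] = outQ,
    _["area"] = outA, _["inlet_pressure"] = inletP,
    _["cycles"] = cycle, _["converged"] = converged,
    _["residuals"] = wrap(resid_hist),
    _["failed_vessel"] = bad_vessel, _["failed_time"] = bad_time);
}
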