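// Fixed-step RK4 integration of the nonlinear Schrodinger equation
//   i dPsi/dt = H(Psi) Psi
// on the 4^(L^2)-dimensional occupation basis, with the Hamiltonian
// reassembled from the instantaneous densities at every integrator stage.
//
// Basis index convention (matches the R side): idx = ia + (ib << M), where
// ia holds the human occupation bits (cell 1 = bit 0) and ib the resource
// bits. Mode ordering for the fermionic sign strings is
// (a_1..a_M, b_1..b_M); signs below are derived from that convention and
// cross-checked in the test suite against the sparse-matrix construction.

#include <Rcpp.h>
#include <complex>
#include <vector>
#include <cmath>

using namespace Rcpp;
typedef std::complex<double> cplx;

namespace {

inline int parity(unsigned int v) {
#if defined(__GNUC__) || defined(__clang__)
  return __builtin_parity(v);
#else
  v ^= v >> 16; v ^= v >> 8; v ^= v >> 4; v ^= v >> 2; v ^= v >> 1;
  return v & 1;
#endif
}

struct Model {
  int M;                 // number of cells
  int adim;              // 2^M
  double sigma, tau, mu, p, eps;
  std::vector<int> pa, pb;  // neighbour pairs, 0-based, pa < pb
  // precomputed coupling lists (built once; only coefficients change)
  // exchange X(alpha): ia0 has the cell's a-bit clear, ia1 = ia0 ^ bit,
  // sa = string sign from the a-bits above alpha
  std::vector<std::vector<int> > x_ia0, x_ia1;
  std::vector<std::vector<double> > x_sa;
  // migration M(alpha,beta): ia has bit alpha set, bit beta clear,
  // ja = ia with the two bits swapped, ms = string sign
  std::vector<std::vector<int> > m_ia, m_ja;
  std::vector<std::vector<double> > m_s;
};

void build_lists(Model& m) {
  const int A = m.adim;
  m.x_ia0.resize(m.M); m.x_ia1.resize(m.M); m.x_sa.resize(m.M);
  for (int a = 0; a < m.M; ++a) {
    const int bit = 1 << a;
    for (int ia0 = 0; ia0 < A; ++ia0) {
      if (ia0 & bit) continue;
      m.x_ia0[a].push_back(ia0);
      m.x_ia1[a].push_back(ia0 ^ bit);
      m.x_sa[a].push_back(parity((unsigned)(ia0 >> (a + 1))) ? -1.0 : 1.0);
    }
  }
  const int npair = (int)m.pa.size();
  m.m_ia.resize(npair); m.m_ja.resize(npair); m.m_s.resize(npair);
  for (int k = 0; k < npair; ++k) {
    const int bal = 1 << m.pa[k], bbe = 1 << m.pb[k];
    const int between = (bbe - 1) & ~((bal << 1) - 1);
    for (int ia = 0; ia < A; ++ia) {
      if ((ia & bal) && !(ia & bbe)) {
        m.m_ia[k].push_back(ia);
        m.m_ja[k].push_back(ia ^ bal ^ bbe);
        m.m_s[k].push_back(parity((unsigned)(ia & between)) ? 1.0 : -1.0);
      }
    }
  }
}

// per-cell coefficients from densities (same formulas as the R module)
struct Coeffs {
  std::vector<double> wa, wb, lam;
};

void coeffs_from_densities(const Model& m, const std::vector<double>& na,
                           const std::vector<double>& nb, Coeffs& cf) {
  cf.wa.resize(m.M); cf.wb.resize(m.M); cf.lam.resize(m.M);
  for (int a = 0; a < m.M; ++a) {
    double da = std::max(na[a], m.eps), db = std::max(nb[a], m.eps);
    double K = db / da;
    double wa = m.sigma * std::sqrt(std::exp(-(K - 1.0 / m.tau) * (K - 1.0 / m.tau)) * K);
    double wb = m.sigma * std::sqrt(std::exp(-(K / m.tau) * (K / m.tau)) / K);
    cf.wa[a] = wa; cf.wb[a] = wb; cf.lam[a] = wa + wb + m.mu;
  }
}

// densities (and squared norm) of a state
void densities(const Model& m, const std::vector<cplx>& x,
               std::vector<double>& na, std::vector<double>& nb,
               double* nrm2out) {
  const int A = m.adim;
  std::vector<double> sa(A, 0.0), sb(A, 0.0);
  for (int ib = 0; ib < A; ++ib) {
    const cplx* row = &x[(size_t)ib * A];
    double rs = 0.0;
    for (int ia = 0; ia < A; ++ia) {
      double v = std::norm(row[ia]);
      sa[ia] += v; rs += v;
    }
    sb[ib] = rs;
  }
  double nrm2 = 0.0;
  for (int ia = 0; ia < A; ++ia) nrm2 += sa[ia];
  na.assign(m.M, 0.0); nb.assign(m.M, 0.0);
  for (int a = 0; a < m.M; ++a) {
    int bit = 1 << a;
    double ta = 0.0, tb = 0.0;
    for (int i = 0; i < A; ++i) {
      if (i & bit) { ta += sa[i]; tb += sb[i]; }
    }
    na[a] = ta; nb[a] = tb;
  }
  if (nrm2out) *nrm2out = nrm2;
}

// y = H x for the coefficient set cf (y must be zero-initialized)
void apply_H(const Model& m, const Coeffs& cf, const std::vector<cplx>& x,
             std::vector<cplx>& y) {
  const int A = m.adim;
  // diagonal: sum_alpha wa*ma + wb*mb
  std::vector<double> da(A, 0.0), db(A, 0.0);
  for (int i = 0; i < A; ++i) {
    double va = 0.0, vb = 0.0;
    for (int a = 0; a < m.M; ++a) {
      if (i & (1 << a)) { va += cf.wa[a]; vb += cf.wb[a]; }
    }
    da[i] = va; db[i] = vb;
  }
  // pass 1 (one sweep, row-local): diagonal plus every migration term.
  // Migration M(alpha,beta) = a_al a_be^dag + h.c. acts on the a-index
  // only, with sign -(-1)^{popcount of a-bits strictly between al and be}.
  const int npair = (int)m.pa.size();
  std::vector<double> gam(npair);
  bool any_mig = false;
  for (int k = 0; k < npair; ++k) {
    // gamma = omega_b(K_al) + omega_b(K_be); cf.wb already holds omega_b(K)
    gam[k] = m.p * (cf.wb[m.pa[k]] + cf.wb[m.pb[k]]);
    if (gam[k] != 0.0) any_mig = true;
  }
  for (int ib = 0; ib < A; ++ib) {
    const double* __restrict xr = (const double*)&x[(size_t)ib * A];
    double* __restrict yr = (double*)&y[(size_t)ib * A];
    const double dbv = db[ib];
    for (int ia = 0; ia < A; ++ia) {
      const double dv = da[ia] + dbv;
      yr[2 * ia]     = dv * xr[2 * ia];
      yr[2 * ia + 1] = dv * xr[2 * ia + 1];
    }
    if (!any_mig) continue;
    for (int k = 0; k < npair; ++k) {
      const double g = gam[k];
      if (g == 0.0) continue;
      const int nh = (int)m.m_ia[k].size();
      const int* ial = m.m_ia[k].data();
      const int* jal = m.m_ja[k].data();
      const double* sl = m.m_s[k].data();
      for (int q = 0; q < nh; ++q) {
        const double s = g * sl[q];
        const int ia = 2 * ial[q], ja = 2 * jal[q];
        yr[ja]     += s * xr[ia];
        yr[ja + 1] += s * xr[ia + 1];
        yr[ia]     += s * xr[ja];
        yr[ia + 1] += s * xr[ja + 1];
      }
    }
  }
  // pass 2 (row pairs): intra-cell exchange X(alpha), coupling
  // (ma=1, mb=0) <-> (ma=0, mb=1). Sign on the (ma=0, mb=1) state:
  // parity(ia >> (a+1)) ^ parity(ib & (2^a - 1)). Each unordered row
  // pair (ib0, ib1 = ib0 | bit) is handled once, from its lower row, so
  // the base row stays cached across all cells.
  for (int ib0 = 0; ib0 < A; ++ib0) {
    const double* __restrict x0 = (const double*)&x[(size_t)ib0 * A];
    double* __restrict y0 = (double*)&y[(size_t)ib0 * A];
    for (int a = 0; a < m.M; ++a) {
      const int bit = 1 << a;
      if (ib0 & bit) continue;
      const int ib1 = ib0 | bit;
      const double lam = cf.lam[a];
      const double c = (parity((unsigned)(ib0 & (bit - 1)))) ? -lam : lam;
      const double* __restrict x1 = (const double*)&x[(size_t)ib1 * A];
      double* __restrict y1 = (double*)&y[(size_t)ib1 * A];
      const int nh = (int)m.x_ia0[a].size();
      const int* ia0l = m.x_ia0[a].data();
      const int* ia1l = m.x_ia1[a].data();
      const double* sal = m.x_sa[a].data();
      for (int k = 0; k < nh; ++k) {
        const double s = c * sal[k];
        const int i0 = 2 * ia0l[k], i1 = 2 * ia1l[k];
        y0[i1]     += s * x1[i0];
        y0[i1 + 1] += s * x1[i0 + 1];
        y1[i0]     += s * x0[i1];
        y1[i0 + 1] += s * x0[i1 + 1];
      }
    }
  }
}

// k = -i H(x_stage) x_stage
void deriv(const Model& m, const std::vector<cplx>& x, std::vector<cplx>& hx,
           std::vector<cplx>& k, bool refresh, Coeffs& cf,
           std::vector<double>& na, std::vector<double>& nb) {
  if (refresh) {
    densities(m, x, na, nb, nullptr);
    coeffs_from_densities(m, na, nb, cf);
  }
  apply_H(m, cf, x, hx);
  const cplx mi(0.0, -1.0);
  const size_t n = x.size();
  for (size_t i = 0; i < n; ++i) k[i] = mi * hx[i];
}

} // namespace

// [[Rcpp::export]]
List evolve_fock_cpp(ComplexVector psi0, int M,
                     IntegerVector pair_alpha, IntegerVector pair_beta,
                     double sigma, double tau, double mu, double p,
                     double eps, double dt, int n_steps, int record_every,
                     double norm_tol, bool update_per_stage) {
  Model m;
  m.M = M; m.adim = 1 << M;
  m.sigma = sigma; m.tau = tau; m.mu = mu; m.p = p; m.eps = eps;
  const size_t dim = (size_t)m.adim * m.adim;
  if ((size_t)psi0.size() != dim) stop("psi0 has wrong dimension");
  for (int k = 0; k < pair_alpha.size(); ++k) {
    m.pa.push_back(pair_alpha[k] - 1);   // to 0-based
    m.pb.push_back(pair_beta[k] - 1);
  }
  build_lists(m);

  std::vector<cplx> x(dim), xt(dim), hx(dim), kv(dim), acc(dim);
  for (size_t i = 0; i < dim; ++i)
    x[i] = cplx(psi0[i].r, psi0[i].i);

  const int n_rec = n_steps / record_every + 1;
  NumericMatrix rec_na(n_rec, M), rec_nb(n_rec, M);
  NumericVector rec_t(n_rec), rec_norm(n_rec);

  Coeffs cf;
  std::vector<double> na(M), nb(M);
  double nrm2;
  densities(m, x, na, nb, &nrm2);
  int irec = 0;
  rec_t[0] = 0.0; rec_norm[0] = std::sqrt(nrm2);
  for (int a = 0; a < M; ++a) { rec_na(0, a) = na[a]; rec_nb(0, a) = nb[a]; }
  irec = 1;

  std::string status = "ok";
  int step_done = 0;
  for (int step = 0; step < n_steps; ++step) {
    // stage 1
    deriv(m, x, hx, kv, true, cf, na, nb);
    for (size_t i = 0; i < dim; ++i) {
      acc[i] = x[i] + (dt / 6.0) * kv[i];
      xt[i] = x[i] + (0.5 * dt) * kv[i];
    }
    // stage 2
    deriv(m, xt, hx, kv, update_per_stage, cf, na, nb);
    for (size_t i = 0; i < dim; ++i) {
      acc[i] += (dt / 3.0) * kv[i];
      xt[i] = x[i] + (0.5 * dt) * kv[i];
    }
    // stage 3
    deriv(m, xt, hx, kv, update_per_stage, cf, na, nb);
    for (size_t i = 0; i < dim; ++i) {
      acc[i] += (dt / 3.0) * kv[i];
      xt[i] = x[i] + dt * kv[i];
    }
    // stage 4
    deriv(m, xt, hx, kv, update_per_stage, cf, na, nb);
    for (size_t i = 0; i < dim; ++i)
      x[i] = acc[i] + (dt / 6.0) * kv[i];
    ++step_done;

    if ((step + 1) % record_every == 0) {
      densities(m, x, na, nb, &nrm2);
      double nrm = std::sqrt(nrm2);
      rec_t[irec] = (step + 1) * dt;
      rec_norm[irec] = nrm;
      for (int a = 0; a < M; ++a) { rec_na(irec, a) = na[a]; rec_nb(irec, a) = nb[a]; }
      ++irec;
      if (std::abs(nrm - 1.0) > norm_tol) { status = "norm_drift"; break; }
      Rcpp::checkUserInterrupt();
    }
  }

  ComplexVector psiT(dim);
  for (size_t i = 0; i < dim; ++i) {
    psiT[i].r = x[i].real(); psiT[i].i = x[i].imag();
  }
  return List::create(_["time"] = rec_t, _["n_a"] = rec_na,
                      _["n_b"] = rec_nb, _["norm"] = rec_norm,
                      _["n_recorded"] = irec, _["steps_done"] = step_done,
                      _["psi_final"] = psiT, _["status"] = status);
}

// Exact decoupled per-cell evolution for the no-migration scenario: each
// cell is a 4-state system (c00, c10, c01, c11) evolving under its own
// H_alpha with coefficients from its own densities. Valid when p = 0 and
// the initial state is a per-cell product.
// [[Rcpp::export]]
List evolve_percell_cpp(ComplexMatrix psi0, double sigma, double tau,
                        double mu, double eps, double dt, int n_steps,
                        int record_every, double norm_tol,
                        bool update_per_stage) {
  const int M = psi0.ncol();
  if (psi0.nrow() != 4) stop("psi0 must be a 4 x n_cells matrix");
  std::vector<cplx> x(4 * M), xt(4 * M), kv(4 * M), acc(4 * M);
  for (int c = 0; c < M; ++c)
    for (int r = 0; r < 4; ++r)
      x[4 * c + r] = cplx(psi0(r, c).r, psi0(r, c).i);

  std::vector<double> wa(M), wb(M), lam(M);
  auto refresh = [&](const std::vector<cplx>& s) {
    for (int c = 0; c < M; ++c) {
      const cplx* v = &s[4 * c];
      double na = std::norm(v[1]) + std::norm(v[3]);
      double nb = std::norm(v[2]) + std::norm(v[3]);
      double K = std::max(nb, eps) / std::max(na, eps);
      wa[c] = sigma * std::sqrt(std::exp(-(K - 1.0 / tau) * (K - 1.0 / tau)) * K);
      wb[c] = sigma * std::sqrt(std::exp(-(K / tau) * (K / tau)) / K);
      lam[c] = wa[c] + wb[c] + mu;
    }
  };
  auto deriv4 = [&](const std::vector<cplx>& s, std::vector<cplx>& k,
                    bool upd) {
    if (upd) refresh(s);
    const cplx mi(0.0, -1.0);
    for (int c = 0; c < M; ++c) {
      const cplx* v = &s[4 * c];
      cplx* kc = &k[4 * c];
      kc[0] = cplx(0.0, 0.0);
      kc[1] = mi * (wa[c] * v[1] + lam[c] * v[2]);
      kc[2] = mi * (wb[c] * v[2] + lam[c] * v[1]);
      kc[3] = mi * ((wa[c] + wb[c]) * v[3]);
    }
  };

  const int n_rec = n_steps / record_every + 1;
  NumericMatrix rec_na(n_rec, M), rec_nb(n_rec, M);
  NumericVector rec_t(n_rec), rec_norm(n_rec);
  auto record = [&](int irec, double t) {
    rec_t[irec] = t;
    double lognrm2 = 0.0;
    for (int c = 0; c < M; ++c) {
      const cplx* v = &x[4 * c];
      double n2 = std::norm(v[0]) + std::norm(v[1]) + std::norm(v[2]) +
                  std::norm(v[3]);
      rec_na(irec, c) = std::norm(v[1]) + std::norm(v[3]);
      rec_nb(irec, c) = std::norm(v[2]) + std::norm(v[3]);
      lognrm2 += std::log(n2);
    }
    // product-state norm: product over cells of per-cell norms
    rec_norm[irec] = std::exp(0.5 * lognrm2);
    return rec_norm[irec];
  };
  record(0, 0.0);
  int irec = 1;
  std::string status = "ok";
  const size_t n = x.size();
  for (int step = 0; step < n_steps; ++step) {
    deriv4(x, kv, true);
    for (size_t i = 0; i < n; ++i) {
      acc[i] = x[i] + (dt / 6.0) * kv[i];
      xt[i] = x[i] + (0.5 * dt) * kv[i];
    }
    deriv4(xt, kv, update_per_stage);
    for (size_t i = 0; i < n; ++i) {
      acc[i] += (dt / 3.0) * kv[i];
      xt[i] = x[i] + (0.5 * dt) * kv[i];
    }
    deriv4(xt, kv, update_per_stage);
    for (size_t i = 0; i < n; ++i) {
      acc[i] += (dt / 3.0) * kv[i];
      xt[i] = x[i] + dt * kv[i];
    }
    deriv4(xt, kv, update_per_stage);
    for (size_t i = 0; i < n; ++i) x[i] = acc[i] + (dt / 6.0) * kv[i];

    if ((step + 1) % record_every == 0) {
      double nrm = record(irec, (step + 1) * dt);
      ++irec;
      if (std::abs(nrm - 1.0) > norm_tol) { status = "norm_drift"; break; }
      Rcpp::checkUserInterrupt();
    }
  }

  ComplexMatrix psiT(4, M);
  for (int c = 0; c < M; ++c)
    for (int r = 0; r < 4; ++r) {
      psiT(r, c).r = x[4 * c + r].real();
      psiT(r, c).i = x[4 * c + r].imag();
    }
  return List::create(_["time"] = rec_t, _["n_a"] = rec_na,
                      _["n_b"] = rec_nb, _["norm"] = rec_norm,
                      _["n_recorded"] = irec, _["psi_final"] = psiT,
                      _["status"] = status);
}
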