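// Explicit quasi-static solver: central-difference integration with
// mass-proportional damping (dynamic relaxation), fully integrated 8-noded
// hexahedra with the single-term viscoelastic shear relaxation and a
// mean-dilatation (B-bar) volumetric treatment, Hughes-Liu viscoelastic beam
// elements, penalty beam-in-solid coupling, follower pressure faces, and
// prescribed ("floating") displacement boundaries.
//
// Consistent units: mm, MPa, N, tonne/mm^3, s.
// The algorithm duplicates the R reference implementations element-by-element
// (hex_internal_force, beam_internal_force, update_stress); the R tests pin
// both paths against closed-form oracles.

#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

static const double G2 = 0.5773502691896257; // 1/sqrt(3)

struct Mat { double G0, Ginf, beta, nu, K; };

static inline double relax_phi(double x) {
  if (x < 1e-8) return 1.0 - 0.5 * x;
  return -std::expm1(-x) / x;
}

// 3x3 helpers on row-major double[9]
static inline void mat3_mul(const double* A, const double* B, double* C) {
  for (int i = 0; i < 3; ++i)
    for (int j = 0; j < 3; ++j)
      C[3 * i + j] = A[3 * i] * B[j] + A[3 * i + 1] * B[3 + j] + A[3 * i + 2] * B[6 + j];
}

static inline double mat3_det(const double* J) {
  return J[0] * (J[4] * J[8] - J[5] * J[7])
       - J[1] * (J[3] * J[8] - J[5] * J[6])
       + J[2] * (J[3] * J[7] - J[4] * J[6]);
}

static inline void mat3_inv(const double* J, double det, double* I) {
  double id = 1.0 / det;
  I[0] = (J[4] * J[8] - J[5] * J[7]) * id;
  I[1] = (J[2] * J[7] - J[1] * J[8]) * id;
  I[2] = (J[1] * J[5] - J[2] * J[4]) * id;
  I[3] = (J[5] * J[6] - J[3] * J[8]) * id;
  I[4] = (J[0] * J[8] - J[2] * J[6]) * id;
  I[5] = (J[2] * J[3] - J[0] * J[5]) * id;
  I[6] = (J[3] * J[7] - J[4] * J[6]) * id;
  I[7] = (J[1] * J[6] - J[0] * J[7]) * id;
  I[8] = (J[0] * J[4] - J[1] * J[3]) * id;
}

// voigt order: 11 22 33 12 23 31 (off-diagonal slots hold tensor components)
static inline void voigt_to_full(const double* v, double* S) {
  S[0] = v[0]; S[4] = v[1]; S[8] = v[2];
  S[1] = S[3] = v[3]; S[5] = S[7] = v[4]; S[2] = S[6] = v[5];
}
static inline void full_to_voigt(const double* S, double* v) {
  v[0] = S[0]; v[1] = S[4]; v[2] = S[8];
  v[3] = 0.5 * (S[1] + S[3]); v[4] = 0.5 * (S[5] + S[7]);
  v[5] = 0.5 * (S[2] + S[6]);
}

// sigma += W sigma - sigma W (incremental Jaumann rotation), voigt in place
static inline void jaumann(double* v, const double* W) {
  double S[9], WS[9], SW[9];
  voigt_to_full(v, S);
  mat3_mul(W, S, WS);
  mat3_mul(S, W, SW);
  for (int i = 0; i < 9; ++i) S[i] += WS[i] - SW[i];
  full_to_voigt(S, v);
}

// viscoelastic increment: deps_dev = deviatoric tensor strain increment,
// tr = volumetric strain increment; updates sig and h in place.
static inline void visco_update(double* sig, double* h, const double* deps_dev,
                                double tr, double dt, const Mat& m) {
  double x = m.beta * dt;
  double ex = std::exp(-x);
  double phi = relax_phi(x);
  double c = (m.G0 - m.Ginf) * phi * 2.0;
  for (int i = 0; i < 6; ++i) {
    double hn = ex * h[i] + c * deps_dev[i];
    sig[i] += 2.0 * m.Ginf * deps_dev[i] + (hn - h[i]);
    h[i] = hn;
  }
  double Kt = m.K * tr;
  sig[0] += Kt; sig[1] += Kt; sig[2] += Kt;
}

// q rows = local basis vectors; transpose=false: local = q V q^T
static inline void rot_voigt(const double* v, const double* q, double* out,
                             bool transpose) {
  double S[9], T[9], R[9], qT[9];
  voigt_to_full(v, S);
  for (int i = 0; i < 3; ++i)
    for (int j = 0; j < 3; ++j)
      qT[3 * i + j] = q[3 * j + i];
  if (!transpose) { mat3_mul(q, S, T); mat3_mul(T, qT, R); }
  else            { mat3_mul(qT, S, T); mat3_mul(T, q, R); }
  full_to_voigt(R, out);
}

static inline void cross3(const double* a, const double* b, double* c) {
  c[0] = a[1] * b[2] - a[2] * b[1];
  c[1] = a[2] * b[0] - a[0] * b[2];
  c[2] = a[0] * b[1] - a[1] * b[0];
}

static inline double norm3(const double* a) {
  return std::sqrt(a[0] * a[0] + a[1] * a[1] + a[2] * a[2]);
}

// Hughes-Winget second-order rotation operator
static void rot_update(const double* th, double* R) {
  double S[9] = {0, -th[2], th[1], th[2], 0, -th[0], -th[1], th[0], 0};
  double S2[9];
  mat3_mul(S, S, S2);
  double D = 1.0 + 0.25 * (th[0] * th[0] + th[1] * th[1] + th[2] * th[2]);
  for (int i = 0; i < 9; ++i) R[i] = (S[i] + 0.5 * S2[i]) / D;
  R[0] += 1.0; R[4] += 1.0; R[8] += 1.0;
}

struct HexGP { double dN[8][3]; };

// [[Rcpp::export]]
List cpp_run_explicit(List model, List config) {
  NumericMatrix nodes0 = model["nodes"];
  IntegerMatrix elems = model["elems"];   // 0-based
  IntegerVector emat = model["emat"];     // 0-based
  NumericMatrix mats = model["mats"];     // G0 Ginf beta nu
  double rho = as<double>(model["rho"]);
  LogicalMatrix fixed = model["fixed"];

  const int N = nodes0.nrow();
  const int E = elems.nrow();
  const int M = mats.nrow();
  std::vector<Mat> mat(M);
  for (int m = 0; m < M; ++m) {
    Mat mm;
    mm.G0 = mats(m, 0); mm.Ginf = mats(m, 1); mm.beta = mats(m, 2);
    mm.nu = mats(m, 3);
    mm.K = 2.0 * mm.G0 * (1.0 + mm.nu) / (3.0 * (1.0 - 2.0 * mm.nu));
    mat[m] = mm;
  }

  IntegerMatrix pfaces = model["press_faces"];
  NumericVector press_t = model["press_t"], press_v = model["press_v"];
  const int NF = pfaces.nrow();

  IntegerVector presc_idx = model["presc_idx"];
  NumericVector presc_pos = model["presc_pos"]; // dim (np, 3, nframes)
  NumericVector presc_t = model["presc_t"];
  int presc_ncomp = as<int>(model["presc_ncomp"]);
  const int NP = presc_idx.size();
  const int presc_nf = presc_t.size();
  std::vector<bool> is_presc(N, false);
  for (int p = 0; p < NP; ++p) is_presc[presc_idx[p]] = true;

  bool has_beams = model.containsElementNamed("beams") &&
    !Rf_isNull(model["beams"]);
  int B = 0, S = 0, NSP = 0;
  NumericMatrix bnodes0, bYe0, bYz0, host_w, sec_pts;
  IntegerMatrix bsegs;
  IntegerVector bmat, host_elem;
  NumericVector kpen, sec_wts;
  double barea = 0.0;
  if (has_beams) {
    List bl = model["beams"];
    bnodes0 = as<NumericMatrix>(bl["bnodes"]);
    bsegs = as<IntegerMatrix>(bl["bsegs"]);
    bmat = as<IntegerVector>(bl["bmat"]);
    bYe0 = as<NumericMatrix>(bl["Ye"]);
    bYz0 = as<NumericMatrix>(bl["Yz"]);
    sec_pts = as<NumericMatrix>(bl["sec_pts"]);
    sec_wts = as<NumericVector>(bl["sec_wts"]);
    barea = as<double>(bl["area"]);
    host_elem = as<IntegerVector>(bl["host_elem"]);
    host_w = as<NumericMatrix>(bl["host_w"]);
    kpen = as<NumericVector>(bl["kpen"]);
    B = bnodes0.nrow(); S = bsegs.nrow(); NSP = sec_pts.nrow();
  }

  IntegerVector rec_nodes = model["record_nodes"];
  IntegerVector rec_elems = model["record_elems"];
  IntegerVector rec_segs;
  if (has_beams) {
    List bl = model["beams"];
    if (bl.containsElementNamed("record_segs"))
      rec_segs = as<IntegerVector>(bl["record_segs"]);
  }
  const int NR = rec_nodes.size(), NRE = rec_elems.size();
  const int NRS = rec_segs.size();

  double dt = as<double>(config["dt"]);
  int n_steps = as<int>(config["n_steps"]);
  double alpha = as<double>(config["alpha"]);
  double mass_floor = as<double>(config["mass_floor"]);
  IntegerVector rec_steps = config["rec_steps"]; // 0-based step indices

  HexGP gps[8];
  const double sg[8][3] = {
    {-1,-1,-1},{1,-1,-1},{1,1,-1},{-1,1,-1},{-1,-1,1},{1,-1,1},{1,1,1},{-1,1,1}};
  {
    int g = 0;
    for (int kz = 0; kz < 2; ++kz)
      for (int ke = 0; ke < 2; ++ke)
        for (int kx = 0; kx < 2; ++kx, ++g) {
          double xi = kx ? G2 : -G2, et = ke ? G2 : -G2, ze = kz ? G2 : -G2;
          for (int a = 0; a < 8; ++a) {
            gps[g].dN[a][0] = sg[a][0] * (1 + sg[a][1] * et) * (1 + sg[a][2] * ze) / 8.0;
            gps[g].dN[a][1] = sg[a][1] * (1 + sg[a][0] * xi) * (1 + sg[a][2] * ze) / 8.0;
            gps[g].dN[a][2] = sg[a][2] * (1 + sg[a][0] * xi) * (1 + sg[a][1] * et) / 8.0;
          }
        }
  }

  std::vector<double> x(nodes0.begin(), nodes0.end()); // column-major N x 3
  std::vector<double> xp(x), v(3 * N, 0.0), f(3 * N, 0.0), fext(3 * N, 0.0);
  std::vector<double> sig(E * 8 * 6, 0.0), hmem(E * 8 * 6, 0.0);
  std::vector<double> esigbar(E * 6, 0.0), evol(E, 0.0);

  std::vector<double> bx, bxp, bv, bw, bf, bmo, bYe, bYz, bsig, bh;
  std::vector<double> dUe, dUz, bsigbar;
  if (has_beams) {
    bx.assign(bnodes0.begin(), bnodes0.end());
    bxp = bx;
    bv.assign(3 * B, 0.0); bw.assign(3 * B, 0.0);
    bf.assign(3 * B, 0.0); bmo.assign(3 * B, 0.0);
    bYe.assign(bYe0.begin(), bYe0.end());
    bYz.assign(bYz0.begin(), bYz0.end());
    bsig.assign(S * NSP * 6, 0.0); bh.assign(S * NSP * 6, 0.0);
    dUe.assign(3 * B, 0.0); dUz.assign(3 * B, 0.0);
    bsigbar.assign(S * 6, 0.0);   // volume-weighted mean segment stress
  }

  // lumped masses with stiffness-proportional floors (selective mass scaling)
  std::vector<double> massv(N, 0.0), kest(N, 0.0);
  double total_mass0 = 0.0;
  for (int e = 0; e < E; ++e) {
    double X[8][3];
    for (int a = 0; a < 8; ++a)
      for (int d = 0; d < 3; ++d) X[a][d] = nodes0(elems(e, a), d);
    double vol = 0.0;
    for (int g = 0; g < 8; ++g) {
      double J[9] = {0,0,0,0,0,0,0,0,0};
      for (int a = 0; a < 8; ++a)
        for (int i = 0; i < 3; ++i)
          for (int j = 0; j < 3; ++j)
            J[3 * i + j] += X[a][j] * gps[g].dN[a][i];
      vol += mat3_det(J);
    }
    evol[e] = vol;
    const Mat& mm = mat[emat[e]];
    double h = std::cbrt(vol);
    double kel = (mm.K + 4.0 * mm.G0 / 3.0) * h; // dilatational stiffness est
    for (int a = 0; a < 8; ++a) {
      massv[elems(e, a)] += rho * vol / 8.0;
      kest[elems(e, a)] += kel;
    }
    total_mass0 += rho * vol;
  }
  double mass_added = 0.0;
  for (int i = 0; i < N; ++i) {
    double mreq = mass_floor * kest[i] * dt * dt;
    if (mreq > massv[i]) { mass_added += mreq - massv[i]; massv[i] = mreq; }
  }

  std::vector<double> bmass, binert;
  if (has_beams) {
    bmass.assign(B, 0.0); binert.assign(B, 0.0);
    std::vector<double> bk(B, 0.0), bkr(B, 0.0);
    for (int s = 0; s < S; ++s) {
      int n1 = bsegs(s, 0), n2 = bsegs(s, 1);
      double L = 0.0;
      for (int d = 0; d < 3; ++d) {
        double dd = bnodes0(n2, d) - bnodes0(n1, d);
        L += dd * dd;
      }
      L = std::sqrt(L);
      const Mat& mm = mat[bmat[s]];
      double Eb = 2.0 * mm.G0 * (1.0 + mm.nu);
      double mhalf = rho * barea * L / 2.0;
      bmass[n1] += mhalf; bmass[n2] += mhalf;
      bk[n1] += Eb * barea / L; bk[n2] += Eb * barea / L;
      double kr = Eb * barea * L + mm.G0 * barea * L * L;
      bkr[n1] += kr; bkr[n2] += kr;
      double r2 = barea / M_PI;
      binert[n1] += mhalf * (r2 / 2.0 + L * L / 12.0);
      binert[n2] += mhalf * (r2 / 2.0 + L * L / 12.0);
    }
    for (int b = 0; b < B; ++b) {
      double kk = bk[b] + kpen[b];
      double mreq = mass_floor * kk * dt * dt;
      if (mreq > bmass[b]) { mass_added += mreq - bmass[b]; bmass[b] = mreq; }
      double jreq = mass_floor * bkr[b] * dt * dt;
      if (jreq > binert[b]) binert[b] = jreq;
    }
  }

  const int NFR = rec_steps.size();
  NumericVector disp(NFR * NR * 3);
  disp.attr("dim") = IntegerVector::create(NFR, NR, 3);
  NumericMatrix gauge(NFR, 6);
  NumericMatrix energies(NFR, 3);
  NumericVector out_t(NFR);

  double Wint = 0.0, Wext = 0.0, KE = 0.0;
  bool blown = false;
  int fr = 0;
  const double cdt = 0.5 * alpha * dt;

  auto interp1 = [](const NumericVector& tt, const NumericVector& vv, double t) {
    int n = tt.size();
    if (n == 1 || t <= tt[0]) return vv[0];
    if (t >= tt[n - 1]) return vv[n - 1];
    int k = 1; while (tt[k] < t) ++k;
    double w = (t - tt[k - 1]) / (tt[k] - tt[k - 1]);
    return (1 - w) * vv[k - 1] + w * vv[k];
  };

  for (int step = 0; step < n_steps; ++step) {
    double tnew = (step + 1) * dt;

    // ---- integrate to x^{n+1} using the forces of the previous pass
    KE = 0.0;
    for (int n = 0; n < N; ++n) {
      bool pn = is_presc[n];
      for (int d = 0; d < 3; ++d) {
        int id = n + d * N;
        xp[id] = x[id];
        if (fixed(n, d)) { v[id] = 0.0; continue; }
        if (pn && d < presc_ncomp) continue; // overridden below
        double a = f[id] / massv[n];
        v[id] = ((1.0 - cdt) * v[id] + dt * a) / (1.0 + cdt);
        x[id] += dt * v[id];
        KE += 0.5 * massv[n] * v[id] * v[id];
        Wext += fext[id] * dt * v[id];
      }
    }
    // prescribed positions override (floating displacement boundary)
    if (NP > 0) {
      double tq = tnew > presc_t[presc_nf - 1] ? presc_t[presc_nf - 1] : tnew;
      int k = presc_nf > 1 ? 1 : 0;
      while (k < presc_nf - 1 && presc_t[k] < tq) ++k;
      double wgt = presc_nf > 1 ?
        (tq - presc_t[k - 1]) / (presc_t[k] - presc_t[k - 1]) : 0.0;
      for (int p = 0; p < NP; ++p) {
        int n = presc_idx[p];
        for (int d = 0; d < presc_ncomp; ++d) {
          int id = n + d * N;
          double x0v = presc_nf > 1 ? presc_pos[p + d * NP + (k - 1) * NP * 3]
                                    : presc_pos[p + d * NP];
          double x1v = presc_pos[p + d * NP + k * NP * 3];
          double xt = (1 - wgt) * x0v + wgt * x1v;
          v[id] = (xt - xp[id]) / dt;
          x[id] = xt;
        }
      }
    }
    if (has_beams) {
      for (int b = 0; b < B; ++b)
        for (int d = 0; d < 3; ++d) {
          int id = b + d * B;
          bxp[id] = bx[id];
          double a = bf[id] / bmass[b];
          bv[id] = ((1.0 - cdt) * bv[id] + dt * a) / (1.0 + cdt);
          bx[id] += dt * bv[id];
          KE += 0.5 * bmass[b] * bv[id] * bv[id];
          double aw = bmo[id] / binert[b];
          bw[id] = ((1.0 - cdt) * bw[id] + dt * aw) / (1.0 + cdt);
          KE += 0.5 * binert[b] * bw[id] * bw[id];
        }
    }

    std::fill(f.begin(), f.end(), 0.0);
    std::fill(fext.begin(), fext.end(), 0.0);
    if (has_beams) {
      std::fill(bf.begin(), bf.end(), 0.0);
      std::fill(bmo.begin(), bmo.end(), 0.0);
    }

    // ---- solid internal forces (advances stresses with increment xp -> x)
    for (int e = 0; e < E; ++e) {
      int en[8];
      double X[8][3], dU[8][3];
      for (int a = 0; a < 8; ++a) {
        en[a] = elems(e, a);
        for (int d = 0; d < 3; ++d) {
          X[a][d] = x[en[a] + d * N];
          dU[a][d] = X[a][d] - xp[en[a] + d * N];
        }
      }
      const Mat& mm = mat[emat[e]];
      double dNdy[8][8][3], detJ[8], G9[8][9];
      double trbar = 0.0, volsum = 0.0;
      for (int g = 0; g < 8; ++g) {
        // force integration on the end-of-step configuration
        double J[9] = {0,0,0,0,0,0,0,0,0}, Ji[9];
        for (int a = 0; a < 8; ++a)
          for (int i = 0; i < 3; ++i)
            for (int j = 0; j < 3; ++j)
              J[3 * i + j] += X[a][j] * gps[g].dN[a][i];
        double dj = mat3_det(J);
        if (dj <= 0.0) stop("inverted element %d", e + 1);
        detJ[g] = dj;
        mat3_inv(J, dj, Ji);
        // J as assembled is (dy_j / dp_i): rows = parametric, cols = spatial;
        // dN/dy_j therefore contracts with the j-th ROW of its inverse
        for (int a = 0; a < 8; ++a)
          for (int j = 0; j < 3; ++j)
            dNdy[g][a][j] = gps[g].dN[a][0] * Ji[3 * j] +
                            gps[g].dN[a][1] * Ji[3 * j + 1] +
                            gps[g].dN[a][2] * Ji[3 * j + 2];
        // end-configuration incremental gradient A = d(du)/dy_end ...
        double A[9] = {0,0,0,0,0,0,0,0,0};
        for (int a = 0; a < 8; ++a)
          for (int i = 0; i < 3; ++i)
            for (int j = 0; j < 3; ++j)
              A[3 * i + j] += dU[a][i] * dNdy[g][a][j];
        // ... mapped to the half-step configuration: G = A (I - A/2)^-1,
        // exact, and objective for finite rigid rotation steps
        double M[9], Mi[9];
        for (int i = 0; i < 9; ++i) M[i] = -0.5 * A[i];
        M[0] += 1.0; M[4] += 1.0; M[8] += 1.0;
        mat3_inv(M, mat3_det(M), Mi);
        double* Gm = G9[g];
        mat3_mul(A, Mi, Gm);
        trbar += (Gm[0] + Gm[4] + Gm[8]) * dj;
        volsum += dj;
      }
      trbar /= volsum;  // mean dilatation (B-bar)

      double sbar[6] = {0, 0, 0, 0, 0, 0};
      for (int g = 0; g < 8; ++g) {
        double* Gm = G9[g];
        double W[9];
        double de[6];
        de[0] = Gm[0]; de[1] = Gm[4]; de[2] = Gm[8];
        de[3] = 0.5 * (Gm[1] + Gm[3]);
        de[4] = 0.5 * (Gm[5] + Gm[7]);
        de[5] = 0.5 * (Gm[2] + Gm[6]);
        W[0] = W[4] = W[8] = 0.0;
        W[1] = 0.5 * (Gm[1] - Gm[3]); W[3] = -W[1];
        W[5] = 0.5 * (Gm[5] - Gm[7]); W[7] = -W[5];
        W[2] = 0.5 * (Gm[2] - Gm[6]); W[6] = -W[2];
        double tr = de[0] + de[1] + de[2];
        double dev[6];
        for (int i = 0; i < 3; ++i) dev[i] = de[i] - tr / 3.0;
        for (int i = 3; i < 6; ++i) dev[i] = de[i];
        double* sg_ = &sig[(e * 8 + g) * 6];
        double* hg = &hmem[(e * 8 + g) * 6];
        jaumann(sg_, W);
        jaumann(hg, W);
        visco_update(sg_, hg, dev, trbar, dt, mm);
        // stress power (tensor contraction; off-diagonals doubled)
        Wint += detJ[g] * (sg_[0] * de[0] + sg_[1] * de[1] + sg_[2] * de[2] +
                           2 * (sg_[3] * de[3] + sg_[4] * de[4] + sg_[5] * de[5]));
        double Sf[9];
        voigt_to_full(sg_, Sf);
        for (int a = 0; a < 8; ++a) {
          const double* dn = dNdy[g][a];
          f[en[a]]         -= detJ[g] * (Sf[0] * dn[0] + Sf[1] * dn[1] + Sf[2] * dn[2]);
          f[en[a] + N]     -= detJ[g] * (Sf[3] * dn[0] + Sf[4] * dn[1] + Sf[5] * dn[2]);
          f[en[a] + 2 * N] -= detJ[g] * (Sf[6] * dn[0] + Sf[7] * dn[1] + Sf[8] * dn[2]);
        }
        for (int i = 0; i < 6; ++i) sbar[i] += sg_[i] * detJ[g];
      }
      double vtot = 0.0;
      for (int g = 0; g < 8; ++g) vtot += detJ[g];
      for (int i = 0; i < 6; ++i) esigbar[e * 6 + i] = sbar[i] / vtot;
      evol[e] = vtot;
    }

    // ---- beams
    if (has_beams) {
      // per-node fiber rotation (applied once per node per step)
      for (int b = 0; b < B; ++b) {
        double th[3], R[9];
        for (int d = 0; d < 3; ++d) th[d] = bw[b + d * B] * dt;
        rot_update(th, R);
        double Ye[3], Yz[3];
        for (int i = 0; i < 3; ++i) {
          Ye[i] = R[3*i]*bYe[b] + R[3*i+1]*bYe[b+B] + R[3*i+2]*bYe[b+2*B];
          Yz[i] = R[3*i]*bYz[b] + R[3*i+1]*bYz[b+B] + R[3*i+2]*bYz[b+2*B];
        }
        double ne = norm3(Ye), nz = norm3(Yz);
        for (int i = 0; i < 3; ++i) {
          Ye[i] /= ne; Yz[i] /= nz;
          dUe[b + i * B] = Ye[i] - bYe[b + i * B];
          dUz[b + i * B] = Yz[i] - bYz[b + i * B];
          bYe[b + i * B] = Ye[i];
          bYz[b + i * B] = Yz[i];
        }
      }

      for (int s = 0; s < S; ++s) {
        int n1 = bsegs(s, 0), n2 = bsegs(s, 1);
        const Mat& mm = mat[bmat[s]];
        double Ye1[3], Ye2[3], Yz1[3], Yz2[3];
        double dUe1[3], dUe2[3], dUz1[3], dUz2[3];
        double y1[3], y2[3], du1[3], du2[3];
        for (int i = 0; i < 3; ++i) {
          Ye1[i] = bYe[n1 + i * B]; Yz1[i] = bYz[n1 + i * B];
          Ye2[i] = bYe[n2 + i * B]; Yz2[i] = bYz[n2 + i * B];
          dUe1[i] = dUe[n1 + i * B]; dUz1[i] = dUz[n1 + i * B];
          dUe2[i] = dUe[n2 + i * B]; dUz2[i] = dUz[n2 + i * B];
          y1[i] = bx[n1 + i * B]; y2[i] = bx[n2 + i * B];
          du1[i] = y1[i] - bxp[n1 + i * B];
          du2[i] = y2[i] - bxp[n2 + i * B];
        }
        double e1[3] = {y2[0]-y1[0], y2[1]-y1[1], y2[2]-y1[2]};
        double L = norm3(e1);
        if (L < 1e-14) stop("degenerate beam segment %d", s + 1);
        for (int d = 0; d < 3; ++d) e1[d] /= L;
        double e2p[3] = {Ye1[0]+Ye2[0], Ye1[1]+Ye2[1], Ye1[2]+Ye2[2]};
        double n2p = norm3(e2p);
        for (int d = 0; d < 3; ++d) e2p[d] /= n2p;
        double e3[3]; cross3(e1, e2p, e3);
        double n3 = norm3(e3);
        for (int d = 0; d < 3; ++d) e3[d] /= n3;
        double e2[3]; cross3(e3, e1, e2);
        double q[9] = {e1[0], e1[1], e1[2], e2[0], e2[1], e2[2],
                       e3[0], e3[1], e3[2]};

        double fn[2][3] = {{0,0,0},{0,0,0}};
        double fe_[2][3] = {{0,0,0},{0,0,0}};
        double fz_[2][3] = {{0,0,0},{0,0,0}};
        for (int i = 0; i < 6; ++i) bsigbar[s * 6 + i] = 0.0;
        for (int k = 0; k < NSP; ++k) {
          double ce = sec_pts(k, 0), cz = sec_pts(k, 1);
          double J[9], Ji[9];
          for (int i = 0; i < 3; ++i) {
            J[3*i]   = (y2[i]-y1[i])/2 + ce*(Ye2[i]-Ye1[i])/2 + cz*(Yz2[i]-Yz1[i])/2;
            J[3*i+1] = (Ye1[i]+Ye2[i])/2;
            J[3*i+2] = (Yz1[i]+Yz2[i])/2;
          }
          double dj = mat3_det(J);
          if (std::abs(dj) < 1e-18) stop("singular beam Jacobian, segment %d", s + 1);
          mat3_inv(J, dj, Ji);
          double gN[2][3], gPe[2][3], gPz[2][3];
          const double Nxi[2] = {-0.5, 0.5};
          const double Na[2] = {0.5, 0.5};
          for (int a = 0; a < 2; ++a)
            for (int j = 0; j < 3; ++j) {
              gN[a][j]  = Nxi[a] * Ji[j];
              gPe[a][j] = Nxi[a] * ce * Ji[j] + Na[a] * Ji[3 + j];
              gPz[a][j] = Nxi[a] * cz * Ji[j] + Na[a] * Ji[6 + j];
            }
          // end-config incremental gradient, then the exact half-step map
          // G = A (I - A/2)^-1 (objective for finite rigid steps)
          double A[9], M[9], Mi[9], Gp[9];
          for (int i = 0; i < 3; ++i) {
            double c1 = (du2[i]-du1[i])/2 + ce*(dUe2[i]-dUe1[i])/2 + cz*(dUz2[i]-dUz1[i])/2;
            double c2 = (dUe1[i]+dUe2[i])/2;
            double c3 = (dUz1[i]+dUz2[i])/2;
            for (int j = 0; j < 3; ++j)
              A[3*i+j] = c1 * Ji[j] + c2 * Ji[3+j] + c3 * Ji[6+j];
          }
          for (int i = 0; i < 9; ++i) M[i] = -0.5 * A[i];
          M[0] += 1.0; M[4] += 1.0; M[8] += 1.0;
          mat3_inv(M, mat3_det(M), Mi);
          mat3_mul(A, Mi, Gp);
          double de[6], W[9];
          de[0] = Gp[0]; de[1] = Gp[4]; de[2] = Gp[8];
          de[3] = 0.5 * (Gp[1] + Gp[3]);
          de[4] = 0.5 * (Gp[5] + Gp[7]);
          de[5] = 0.5 * (Gp[2] + Gp[6]);
          W[0] = W[4] = W[8] = 0.0;
          W[1] = 0.5*(Gp[1]-Gp[3]); W[3] = -W[1];
          W[5] = 0.5*(Gp[5]-Gp[7]); W[7] = -W[5];
          W[2] = 0.5*(Gp[2]-Gp[6]); W[6] = -W[2];

          double* sl = &bsig[(s * NSP + k) * 6];
          double* hl = &bh[(s * NSP + k) * 6];
          jaumann(sl, W); jaumann(hl, W);
          double sL[6], hL[6], deL[6];
          rot_voigt(sl, q, sL, false);
          rot_voigt(hl, q, hL, false);
          rot_voigt(de, q, deL, false);
          double xx = mm.beta * dt;
          double Geff = mm.Ginf + (mm.G0 - mm.Ginf) * relax_phi(xx);
          double aa = mm.K + 4.0 * Geff / 3.0, bb = mm.K - 2.0 * Geff / 3.0;
          double sT[6], hT[6];
          for (int i = 0; i < 6; ++i) { sT[i] = sL[i]; hT[i] = hL[i]; }
          {
            double tr = deL[0] + deL[1] + deL[2];
            double dev[6];
            for (int i = 0; i < 3; ++i) dev[i] = deL[i] - tr / 3.0;
            for (int i = 3; i < 6; ++i) dev[i] = deL[i];
            visco_update(sT, hT, dev, tr, dt, mm);
          }
          double den = aa * aa - bb * bb;
          double d22 = (-aa * sT[1] + bb * sT[2]) / den;
          double d33 = (-aa * sT[2] + bb * sT[1]) / den;
          deL[1] += d22; deL[2] += d33;
          {
            double tr = deL[0] + deL[1] + deL[2];
            double dev[6];
            for (int i = 0; i < 3; ++i) dev[i] = deL[i] - tr / 3.0;
            for (int i = 3; i < 6; ++i) dev[i] = deL[i];
            double sN[6], hN[6];
            for (int i = 0; i < 6; ++i) { sN[i] = sL[i]; hN[i] = hL[i]; }
            visco_update(sN, hN, dev, tr, dt, mm);
            sN[1] = 0.0; sN[2] = 0.0;
            Wint += 2.0 * sec_wts[k] * std::abs(dj) *
              (sN[0] * deL[0] + 2 * (sN[3] * deL[3] + sN[4] * deL[4] + sN[5] * deL[5]));
            rot_voigt(sN, q, sl, true);
            rot_voigt(hN, q, hl, true);
          }
          double Sf[9];
          voigt_to_full(sl, Sf);
          double w = 2.0 * sec_wts[k] * dj;
          for (int i = 0; i < 6; ++i) bsigbar[s * 6 + i] += sl[i] * std::abs(w);
          for (int a = 0; a < 2; ++a)
            for (int i = 0; i < 3; ++i) {
              fn[a][i]  += w * (Sf[3*i]*gN[a][0] + Sf[3*i+1]*gN[a][1] + Sf[3*i+2]*gN[a][2]);
              fe_[a][i] += w * (Sf[3*i]*gPe[a][0] + Sf[3*i+1]*gPe[a][1] + Sf[3*i+2]*gPe[a][2]);
              fz_[a][i] += w * (Sf[3*i]*gPz[a][0] + Sf[3*i+1]*gPz[a][1] + Sf[3*i+2]*gPz[a][2]);
            }
        }
        double m1[3], m2[3], t1[3], t2[3];
        cross3(Ye1, fe_[0], m1); cross3(Yz1, fz_[0], t1);
        cross3(Ye2, fe_[1], m2); cross3(Yz2, fz_[1], t2);
        for (int d = 0; d < 3; ++d) {
          bf[n1 + d * B] -= fn[0][d];
          bf[n2 + d * B] -= fn[1][d];
          bmo[n1 + d * B] -= m1[d] + t1[d];
          bmo[n2 + d * B] -= m2[d] + t2[d];
        }
      }

      // ---- penalty coupling (equal and opposite)
      for (int b = 0; b < B; ++b) {
        int e = host_elem[b];
        double xh[3] = {0, 0, 0};
        for (int a = 0; a < 8; ++a) {
          int n = elems(e, a);
          double wgt = host_w(b, a);
          xh[0] += wgt * x[n];
          xh[1] += wgt * x[n + N];
          xh[2] += wgt * x[n + 2 * N];
        }
        for (int d = 0; d < 3; ++d) {
          double fc = kpen[b] * (xh[d] - bx[b + d * B]);
          bf[b + d * B] += fc;
          for (int a = 0; a < 8; ++a)
            f[elems(e, a) + d * N] -= host_w(b, a) * fc;
        }
      }
    }

    // ---- follower pressure
    double pnow = (NF > 0) ? interp1(press_t, press_v, tnew) : 0.0;
    if (NF > 0 && pnow != 0.0) {
      for (int fc = 0; fc < NF; ++fc) {
        int a = pfaces(fc, 0), b = pfaces(fc, 1), c = pfaces(fc, 2), d = pfaces(fc, 3);
        double d1[3], d2[3], an[3];
        for (int i = 0; i < 3; ++i) {
          d1[i] = x[c + i * N] - x[a + i * N];
          d2[i] = x[d + i * N] - x[b + i * N];
        }
        cross3(d1, d2, an); // 2 * area * normal
        for (int i = 0; i < 3; ++i) {
          double ff = -pnow * 0.5 * an[i] / 4.0;
          f[a + i * N] += ff; f[b + i * N] += ff;
          f[c + i * N] += ff; f[d + i * N] += ff;
          fext[a + i * N] += ff; fext[b + i * N] += ff;
          fext[c + i * N] += ff; fext[d + i * N] += ff;
        }
      }
    }

    if ((step & 15) == 0 || step == n_steps - 1) {
      double scale = std::abs(Wint) + 1e-9;
      if (!std::isfinite(KE) || (KE > 10.0 * scale && KE > 1e-8)) {
        blown = true;
        break;
      }
    }

    if (fr < NFR && rec_steps[fr] == step) {
      out_t[fr] = tnew;
      for (int r = 0; r < NR; ++r) {
        int n = rec_nodes[r];
        for (int d = 0; d < 3; ++d)
          disp[fr + r * NFR + d * NFR * NR] = x[n + d * N] - nodes0(n, d);
      }
      if (NRE > 0) {
        double sb[6] = {0,0,0,0,0,0};
        double vt = 0.0;
        for (int ii = 0; ii < NRE; ++ii) {
          int e = rec_elems[ii];
          for (int i = 0; i < 6; ++i) sb[i] += esigbar[e * 6 + i] * evol[e];
          vt += evol[e];
        }
        // embedded fibers superimpose on the matrix volume: the homogenized
        // stress adds the volume-weighted fiber stress to the matrix average
        for (int ii = 0; ii < NRS; ++ii) {
          int s = rec_segs[ii];
          for (int i = 0; i < 6; ++i) sb[i] += bsigbar[s * 6 + i];
        }
        for (int i = 0; i < 6; ++i) gauge(fr, i) = sb[i] / vt;
      }
      energies(fr, 0) = KE;
      energies(fr, 1) = Wint;
      energies(fr, 2) = Wext;
      ++fr;
    }
  }

  NumericMatrix final_nodes(N, 3), final_bnodes(B > 0 ? B : 1, 3);
  for (int n = 0; n < N; ++n)
    for (int d = 0; d < 3; ++d) final_nodes(n, d) = x[n + d * N];
  if (has_beams)
    for (int b = 0; b < B; ++b)
      for (int d = 0; d < 3; ++d) final_bnodes(b, d) = bx[b + d * B];

  return List::create(
    _["times"] = out_t, _["disp"] = disp, _["gauge_stress"] = gauge,
    _["energies"] = energies, _["final_nodes"] = final_nodes,
    _["final_beam_nodes"] = final_bnodes, _["mass_added"] = mass_added,
    _["total_mass"] = total_mass0, _["blown_up"] = blown,
    _["frames_done"] = fr);
}
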