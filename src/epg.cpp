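// Extended phase graph (EPG) simulation of the inversion-prepared,
// gradient-spoiled (FISP) variable-flip-angle echo train, plus the dense
// complex linear algebra used for dictionary compression and matching.
//
// State convention (standard F+/F-/Z bookkeeping): for k = 0..K-1 we track
//   Fp[k] = F(+k)          transverse configuration of dephasing order +k
//   Fm[k] = conj(F(-k))    (the conjugate is stored, so the RF mixing
//                           matrix below acts directly on (Fp, Fm, Z))
//   Z[k]  = longitudinal configuration of order k
// with the redundancy Fm[0] == conj(Fp[0]) maintained throughout.
// The detected signal is F(0) = Fp[0] at the echo time.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

typedef std::complex<double> cplx;

static void epg_single(double t1, double t2, double b1, double m0,
                       const vec &fa_rad, const vec &tr_ms,
                       double ti_ms, double te_ms, double phase_rad,
                       int n_states, double inv_eff,
                       cplx *out) {
  const int nt = fa_rad.n_elem;
  const int K = n_states;
  std::vector<cplx> Fp(K, cplx(0, 0)), Fm(K, cplx(0, 0)), Z(K, cplx(0, 0));

  // Ideal (efficiency-scaled) inversion from equilibrium, then TI recovery.
  const double e1ti = std::exp(-ti_ms / t1);
  Z[0] = cplx(-inv_eff * e1ti + (1.0 - e1ti), 0.0);

  const double e1te = std::exp(-te_ms / t1);
  const double e2te = std::exp(-te_ms / t2);
  const cplx eip = std::polar(1.0, phase_rad);
  const cplx eim = std::conj(eip);

  for (int i = 0; i < nt; ++i) {
    const double a = b1 * fa_rad[i];
    const double ca = std::cos(a), sa = std::sin(a);
    const double c2 = std::cos(a / 2.0), s2 = std::sin(a / 2.0);
    // RF mixing matrix entries (constant RF phase `phase_rad`)
    const cplx t11 = cplx(c2 * c2, 0.0);
    const cplx t12 = eip * eip * (s2 * s2);
    const cplx t13 = cplx(0.0, -1.0) * eip * sa;
    const cplx t21 = eim * eim * (s2 * s2);
    const cplx t22 = t11;
    const cplx t23 = cplx(0.0, 1.0) * eim * sa;
    const cplx t31 = cplx(0.0, -0.5) * eim * sa;
    const cplx t32 = cplx(0.0, 0.5) * eip * sa;
    const cplx t33 = cplx(ca, 0.0);

    for (int k = 0; k < K; ++k) {
      const cplx fp = Fp[k], fm = Fm[k], z = Z[k];
      Fp[k] = t11 * fp + t12 * fm + t13 * z;
      Fm[k] = t21 * fp + t22 * fm + t23 * z;
      Z[k] = t31 * fp + t32 * fm + t33 * z;
    }

    // Relaxation over TE, then echo readout of F(0).
    for (int k = 0; k < K; ++k) {
      Fp[k] *= e2te;
      Fm[k] *= e2te;
      Z[k] *= e1te;
    }
    Z[0] += cplx(1.0 - e1te, 0.0);
    out[i] = m0 * Fp[0];

    // Relaxation over the remainder of the TR.
    const double rem = tr_ms[i] - te_ms;
    const double e1r = std::exp(-rem / t1);
    const double e2r = std::exp(-rem / t2);
    for (int k = 0; k < K; ++k) {
      Fp[k] *= e2r;
      Fm[k] *= e2r;
      Z[k] *= e1r;
    }
    Z[0] += cplx(1.0 - e1r, 0.0);

    // Unit gradient dephasing: F(k) -> F(k+1).
    const cplx fm1 = (K > 1) ? Fm[1] : cplx(0, 0);
    for (int k = K - 1; k >= 1; --k) Fp[k] = Fp[k - 1];
    Fp[0] = std::conj(fm1);
    for (int k = 0; k + 1 < K; ++k) Fm[k] = Fm[k + 1];
    Fm[K - 1] = cplx(0, 0);
  }
}

// Vectorized EPG over a group of tissues sharing one B1 value (so the RF
// mixing coefficients per pulse are shared). States are stored
// structure-of-arrays (separate re/im planes, tissue-major) so the inner
// loops auto-vectorize. Used for dictionary builds, where whole B1 planes
// are simulated at once; per-voxel simulation with spatially varying B1
// uses the scalar path above.
static void epg_group(const double *t1, const double *t2, const double *m0,
                      int n_tissue, double b1,
                      const vec &fa_rad, const vec &tr_ms,
                      double ti_ms, double te_ms, double phase_rad,
                      int n_states, double inv_eff,
                      cx_mat &out, const uvec &rows) {
  const int nt = fa_rad.n_elem;
  const int K = n_states;
  const int n = n_tissue;
  // state planes: index [k * n + j]
  std::vector<double> FpRe(K * n, 0.0), FpIm(K * n, 0.0);
  std::vector<double> FmRe(K * n, 0.0), FmIm(K * n, 0.0);
  std::vector<double> ZRe(K * n, 0.0), ZIm(K * n, 0.0);
  std::vector<double> e1te(n), e2te(n), rec_te(n);
  for (int j = 0; j < n; ++j) {
    const double e1ti = std::exp(-ti_ms / t1[j]);
    ZRe[j] = -inv_eff * e1ti + (1.0 - e1ti);
    e1te[j] = std::exp(-te_ms / t1[j]);
    e2te[j] = std::exp(-te_ms / t2[j]);
    rec_te[j] = 1.0 - e1te[j];
  }
  std::vector<double> e1r(n), e2r(n);
  const cplx eip = std::polar(1.0, phase_rad);

  for (int i = 0; i < nt; ++i) {
    const double a = b1 * fa_rad[i];
    const double ca = std::cos(a), sa = std::sin(a);
    const double c2 = std::cos(a / 2.0), s2 = std::sin(a / 2.0);
    const cplx t11 = cplx(c2 * c2, 0.0);
    const cplx t12 = eip * eip * (s2 * s2);
    const cplx t13 = cplx(0.0, -1.0) * eip * sa;
    const cplx t21 = std::conj(t12);
    const cplx t22 = t11;
    const cplx t23 = std::conj(t13);
    const cplx t31 = cplx(0.0, -0.5) * std::conj(eip) * sa;
    const cplx t32 = std::conj(t31);
    const cplx t33 = cplx(ca, 0.0);

    for (int k = 0; k < K; ++k) {
      double *fpr = &FpRe[k * n], *fpi = &FpIm[k * n];
      double *fmr = &FmRe[k * n], *fmi = &FmIm[k * n];
      double *zr = &ZRe[k * n], *zi = &ZIm[k * n];
      for (int j = 0; j < n; ++j) {
        const double pr = fpr[j], pi = fpi[j];
        const double mr = fmr[j], mi = fmi[j];
        const double qr = zr[j], qi = zi[j];
        fpr[j] = t11.real() * pr - t11.imag() * pi +
                 t12.real() * mr - t12.imag() * mi +
                 t13.real() * qr - t13.imag() * qi;
        fpi[j] = t11.real() * pi + t11.imag() * pr +
                 t12.real() * mi + t12.imag() * mr +
                 t13.real() * qi + t13.imag() * qr;
        fmr[j] = t21.real() * pr - t21.imag() * pi +
                 t22.real() * mr - t22.imag() * mi +
                 t23.real() * qr - t23.imag() * qi;
        fmi[j] = t21.real() * pi + t21.imag() * pr +
                 t22.real() * mi + t22.imag() * mr +
                 t23.real() * qi + t23.imag() * qr;
        zr[j] = t31.real() * pr - t31.imag() * pi +
                t32.real() * mr - t32.imag() * mi +
                t33.real() * qr - t33.imag() * qi;
        zi[j] = t31.real() * pi + t31.imag() * pr +
                t32.real() * mi + t32.imag() * mr +
                t33.real() * qi + t33.imag() * qr;
      }
    }

    // relax over TE, read out F(0)
    for (int k = 0; k < K; ++k) {
      double *fpr = &FpRe[k * n], *fpi = &FpIm[k * n];
      double *fmr = &FmRe[k * n], *fmi = &FmIm[k * n];
      double *zr = &ZRe[k * n], *zi = &ZIm[k * n];
      for (int j = 0; j < n; ++j) {
        fpr[j] *= e2te[j];
        fpi[j] *= e2te[j];
        fmr[j] *= e2te[j];
        fmi[j] *= e2te[j];
        zr[j] *= e1te[j];
        zi[j] *= e1te[j];
      }
    }
    for (int j = 0; j < n; ++j) ZRe[j] += rec_te[j];
    for (int j = 0; j < n; ++j) {
      out(rows[j], i) = cplx(m0[j] * FpRe[j], m0[j] * FpIm[j]);
    }

    // relax over TR - TE
    const double rem = tr_ms[i] - te_ms;
    for (int j = 0; j < n; ++j) {
      e1r[j] = std::exp(-rem / t1[j]);
      e2r[j] = std::exp(-rem / t2[j]);
    }
    for (int k = 0; k < K; ++k) {
      double *fpr = &FpRe[k * n], *fpi = &FpIm[k * n];
      double *fmr = &FmRe[k * n], *fmi = &FmIm[k * n];
      double *zr = &ZRe[k * n], *zi = &ZIm[k * n];
      for (int j = 0; j < n; ++j) {
        fpr[j] *= e2r[j];
        fpi[j] *= e2r[j];
        fmr[j] *= e2r[j];
        fmi[j] *= e2r[j];
        zr[j] *= e1r[j];
        zi[j] *= e1r[j];
      }
    }
    for (int j = 0; j < n; ++j) ZRe[j] += 1.0 - e1r[j];

    // gradient shift F(k) -> F(k+1)
    std::memmove(&FpRe[n], &FpRe[0], sizeof(double) * n * (K - 1));
    std::memmove(&FpIm[n], &FpIm[0], sizeof(double) * n * (K - 1));
    if (K > 1) {
      for (int j = 0; j < n; ++j) {
        FpRe[j] = FmRe[n + j];
        FpIm[j] = -FmIm[n + j];
      }
    } else {
      std::fill(FpRe.begin(), FpRe.end(), 0.0);
      std::fill(FpIm.begin(), FpIm.end(), 0.0);
    }
    std::memmove(&FmRe[0], &FmRe[n], sizeof(double) * n * (K - 1));
    std::memmove(&FmIm[0], &FmIm[n], sizeof(double) * n * (K - 1));
    std::fill(FmRe.begin() + (K - 1) * n, FmRe.end(), 0.0);
    std::fill(FmIm.begin() + (K - 1) * n, FmIm.end(), 0.0);
  }
}

// [[Rcpp::export]]
arma::cx_vec epg_fisp_cpp(double t1, double t2, double b1, double m0,
                          const arma::vec &fa_rad, const arma::vec &tr_ms,
                          double ti_ms, double te_ms, double phase_rad,
                          int n_states, double inv_eff) {
  cx_vec out(fa_rad.n_elem);
  epg_single(t1, t2, b1, m0, fa_rad, tr_ms, ti_ms, te_ms, phase_rad,
             n_states, inv_eff, out.memptr());
  return out;
}

// One row per tissue, one column per time point.
// [[Rcpp::export]]
arma::cx_mat epg_fisp_batch_cpp(const arma::vec &t1, const arma::vec &t2,
                                const arma::vec &b1, const arma::vec &m0,
                                const arma::vec &fa_rad, const arma::vec &tr_ms,
                                double ti_ms, double te_ms, double phase_rad,
                                int n_states, double inv_eff) {
  const uword n = t1.n_elem, nt = fa_rad.n_elem;
  cx_mat out(n, nt);
  // tissues sharing a B1 value take the vectorized group path (dictionary
  // planes); the rest fall back to the scalar recursion (per-voxel B1)
  std::map<double, std::vector<uword> > groups;
  for (uword j = 0; j < n; ++j) groups[b1[j]].push_back(j);
  std::vector<cplx> row(nt);
  for (std::map<double, std::vector<uword> >::const_iterator it =
         groups.begin(); it != groups.end(); ++it) {
    const std::vector<uword> &idx = it->second;
    if (idx.size() >= 8) {
      const uword chunk = 512;
      for (uword s = 0; s < idx.size(); s += chunk) {
        const uword len = std::min(chunk, (uword)idx.size() - s);
        std::vector<double> gt1(len), gt2(len), gm0(len);
        uvec rows(len);
        for (uword j = 0; j < len; ++j) {
          rows[j] = idx[s + j];
          gt1[j] = t1[rows[j]];
          gt2[j] = t2[rows[j]];
          gm0[j] = m0[rows[j]];
        }
        epg_group(gt1.data(), gt2.data(), gm0.data(), (int)len, it->first,
                  fa_rad, tr_ms, ti_ms, te_ms, phase_rad, n_states,
                  inv_eff, out, rows);
      }
    } else {
      for (uword k = 0; k < idx.size(); ++k) {
        const uword j = idx[k];
        epg_single(t1[j], t2[j], b1[j], m0[j], fa_rad, tr_ms, ti_ms, te_ms,
                   phase_rad, n_states, inv_eff, row.data());
        for (uword i = 0; i < nt; ++i) out(j, i) = row[i];
      }
    }
  }
  return out;
}

// L2 norms of the rows of a complex matrix.
// [[Rcpp::export]]
arma::vec row_norms_cpp(const arma::cx_mat &a) {
  vec out(a.n_rows);
  for (uword j = 0; j < a.n_rows; ++j) out[j] = norm(a.row(j), 2);
  return out;
}

// Divide each row by the matching scale (in place on a copy).
// [[Rcpp::export]]
arma::cx_mat row_scale_cpp(const arma::cx_mat &a, const arma::vec &s) {
  cx_mat out = a;
  for (uword j = 0; j < a.n_rows; ++j) out.row(j) /= s[j];
  return out;
}

// |<a_j, s_v>| for every row a_j of `atoms` (N x T) against every column
// s_v of `signals` (T x V), with the inner product <a, s> = sum(conj(a) s).
// Computed as |A conj(S)| so only the (small) signal block is conjugated.
// [[Rcpp::export]]
arma::mat ip_mag_cpp(const arma::cx_mat &atoms, const arma::cx_mat &signals) {
  return abs(atoms * conj(signals));
}

// Plain complex matrix product (BLAS zgemm).
// [[Rcpp::export]]
arma::cx_mat cx_mm_cpp(const arma::cx_mat &a, const arma::cx_mat &b) {
  return a * b;
}

// Conjugate-transpose product A^H B.
// [[Rcpp::export]]
arma::cx_mat cx_ctmm_cpp(const arma::cx_mat &a, const arma::cx_mat &b) {
  return a.t() * b;
}

// Right singular vectors of the atom matrix A (N x T) via the T x T Gram
// matrix A^H A = V S^2 V^H (Hermitian eigendecomposition; cheaper than a
// direct SVD when N >> T and numerically adequate for the leading
// components used in temporal compression).
// Returns the top-`rank` basis (T x rank) and all singular values
// (descending).
// [[Rcpp::export]]
Rcpp::List gram_basis_cpp(const arma::cx_mat &atoms, int rank) {
  cx_mat g = atoms.t() * atoms;  // T x T, Hermitian PSD
  vec eigval;
  cx_mat eigvec;
  eig_sym(eigval, eigvec, g, "std");
  // ascending -> descending
  const uword t = g.n_rows;
  vec sv(t);
  cx_mat basis(t, (uword)rank);
  for (uword i = 0; i < t; ++i) {
    double ev = eigval[t - 1 - i];
    sv[i] = ev > 0 ? std::sqrt(ev) : 0.0;
  }
  for (int r = 0; r < rank; ++r) basis.col(r) = eigvec.col(t - 1 - r);
  return Rcpp::List::create(Rcpp::Named("basis") = basis,
                            Rcpp::Named("singular_values") = sv);
}
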