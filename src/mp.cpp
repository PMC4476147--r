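#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Frequency-domain core for matching pursuit over a complex (quadrature)
// log-Gabor dictionary.
//
// Conventions shared with the R side:
//  * kernels are frequency-domain transfer functions K_k(f), one slice per
//    (scale, orientation) pair, scaled so that the real-valued atom
//    g_phi(u) = Re(e^{i phi} k(u)) has unit l2 norm for every phase phi
//    (requires sum_f |K|^2 = 2 * n_pixels and single-sided support);
//  * the coefficient map of kernel k is C_k = IFFT(R_hat % conj(K_k)),
//    i.e. C_k(x) = <residual, k centered at x> (circular correlation);
//  * subtracting the best real atom amp * Re(e^{i phi} k(. - x0)) from the
//    residual is done in the frequency domain as
//    R_hat -= V + conj(V at -f), with V(f) = (c/2) K(f) e^{-2 pi i f.x0}
//    and c = amp * e^{i phi} the complex coefficient at the arg-max.

static inline void subtract_atom(arma::cx_mat& R, const arma::cx_mat& K,
                                 const std::complex<double>& c,
                                 arma::uword bx, arma::uword by) {
  const arma::uword ny = R.n_rows, nx = R.n_cols;
  arma::cx_vec wy(ny), wx(nx);
  const double two_pi = 2.0 * M_PI;
  for (arma::uword i = 0; i < ny; ++i) {
    double a = -two_pi * (double)(i * by) / (double)ny;
    wy(i) = std::complex<double>(std::cos(a), std::sin(a));
  }
  for (arma::uword j = 0; j < nx; ++j) {
    double a = -two_pi * (double)(j * bx) / (double)nx;
    wx(j) = std::complex<double>(std::cos(a), std::sin(a));
  }
  const std::complex<double> half_c = 0.5 * c;
  for (arma::uword j = 0; j < nx; ++j) {
    arma::uword jn = (nx - j) % nx;
    for (arma::uword i = 0; i < ny; ++i) {
      std::complex<double> V = half_c * K(i, j) * wy(i) * wx(j);
      R(i, j) -= V;
      R((ny - i) % ny, jn) -= std::conj(V);
    }
  }
}

// [[Rcpp::export]]
List cpp_mp(const arma::cx_cube& kernels, const arma::cx_mat& image_hat,
            int n_edges, double residual_target) {
  const arma::uword ny = image_hat.n_rows, nx = image_hat.n_cols;
  const arma::uword nk = kernels.n_slices;
  const double ntot = (double)(ny * nx);
  arma::cx_mat R = image_hat;
  const double e0 = arma::accu(arma::square(arma::abs(R))) / ntot;

  arma::mat sel(n_edges, 5);       // kernel index (0-based), x, y, amp, phase
  arma::vec res_trace(n_edges);    // residual energy fraction after each pick
  int nsel = 0;
  bool reached = false;
  double res = e0;

  if (e0 <= 0.0) {
    reached = true;                // zero-energy image: empty edge list
  } else {
    for (int t = 0; t < n_edges; ++t) {
      double best = -1.0;
      arma::uword bk = 0, bx = 0, by = 0;
      std::complex<double> bc(0.0, 0.0);
      for (arma::uword k = 0; k < nk; ++k) {
        arma::cx_mat C = arma::ifft2(R % arma::conj(kernels.slice(k)));
        // scan in tie-break order: (scale, orientation) via k, then y, then x;
        // strict > keeps the first (lexicographically lowest) maximizer
        for (arma::uword iy = 0; iy < ny; ++iy) {
          for (arma::uword ix = 0; ix < nx; ++ix) {
            double m = std::norm(C(iy, ix));
            if (m > best) {
              best = m; bk = k; bx = ix; by = iy; bc = C(iy, ix);
            }
          }
        }
      }
      double amp = std::abs(bc);
      if (amp <= 0.0) { reached = true; break; }
      subtract_atom(R, kernels.slice(bk), bc, bx, by);
      res -= amp * amp;
      if (res < 0.0) res = 0.0;
      sel(nsel, 0) = (double)bk;
      sel(nsel, 1) = (double)bx;
      sel(nsel, 2) = (double)by;
      sel(nsel, 3) = amp;
      sel(nsel, 4) = std::arg(bc);
      res_trace(nsel) = res / e0;
      ++nsel;
      if (res / e0 <= residual_target) { reached = true; break; }
    }
  }

  const double res_exact = arma::accu(arma::square(arma::abs(R))) / ntot;
  return List::create(
    _["sel"] = sel.head_rows(nsel),
    _["residual_hat"] = R,
    _["initial_energy"] = e0,
    _["residual_energy"] = res_exact,
    _["residual_trace"] = res_trace.head(nsel),
    _["target_reached"] = reached);
}

// Linear analysis: coefficient maps for every kernel.
// [[Rcpp::export]]
arma::cx_cube cpp_correlate(const arma::cx_cube& kernels,
                            const arma::cx_mat& image_hat) {
  const arma::uword nk = kernels.n_slices;
  arma::cx_cube out(image_hat.n_rows, image_hat.n_cols, nk);
  for (arma::uword k = 0; k < nk; ++k)
    out.slice(k) = arma::ifft2(image_hat % arma::conj(kernels.slice(k)));
  return out;
}

// Synthesis: sum of real atoms amp * Re(e^{i phase} k(. - (x, y))).
// [[Rcpp::export]]
arma::mat cpp_synthesize(const arma::cx_cube& kernels,
                         const arma::ivec& kidx, const arma::ivec& x,
                         const arma::ivec& y, const arma::vec& amp,
                         const arma::vec& phase) {
  const arma::uword ny = kernels.n_rows, nx = kernels.n_cols;
  arma::cx_mat A(ny, nx, arma::fill::zeros);
  for (arma::uword e = 0; e < kidx.n_elem; ++e) {
    std::complex<double> c =
        amp(e) * std::complex<double>(std::cos(phase(e)), std::sin(phase(e)));
    // accumulate -(-atom): reuse subtract with negated coefficient
    subtract_atom(A, kernels.slice((arma::uword)kidx(e)), -c,
                  (arma::uword)x(e), (arma::uword)y(e));
  }
  return arma::real(arma::ifft2(A));
}
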