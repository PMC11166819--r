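// Matrix-pencil (GPOF) decomposition of uniformly sampled real signals.
// Hot path for per-voxel spectral mapping: one decomposition per lung voxel.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

struct MPComponent {
  double freq;       // Hz, >= 0 after conjugate merging
  double damping;    // 1/s (negative = decaying)
  double amplitude;  // real-signal amplitude at n = 0
  double phase;      // radians (cosine convention)
};

// Decompose y (length N) sampled at fs into damped sinusoids.
// L: pencil parameter; order: fixed model order, or <= 0 for automatic
// selection by singular values >= sv_tol * largest, capped at max_order.
static std::vector<MPComponent> mp_decompose_core(const vec& y, double fs,
                                                  int L, int order,
                                                  double sv_tol,
                                                  int max_order) {
  const int N = static_cast<int>(y.n_elem);
  const int rows = N - L;
  const int cols = L + 1;
  std::vector<MPComponent> out;

  // Hankel data matrix Y(i, j) = y(i + j)
  mat Y(rows, cols);
  for (int j = 0; j < cols; ++j) Y.col(j) = y.subvec(j, j + rows - 1);

  mat U, V;
  vec s;
  if (!svd_econ(U, s, V, Y)) Rcpp::stop("SVD of the Hankel matrix failed");
  if (s.n_elem == 0 || s(0) <= 0.0) return out;  // all-zero signal

  int M;
  if (order > 0) {
    M = std::min(order, static_cast<int>(s.n_elem));
  } else {
    const double thr = sv_tol * s(0);
    M = 0;
    for (uword i = 0; i < s.n_elem; ++i)
      if (s(i) >= thr) ++M;
    if (M < 1) M = 1;
    if (max_order > 0) M = std::min(M, max_order);
  }
  M = std::min(M, L);

  // Poles from the shifted right-singular-vector pencil
  mat Vm = V.cols(0, M - 1);
  mat V1 = Vm.rows(0, L - 1);
  mat V2 = Vm.rows(1, L);
  mat A;
  if (!pinv(A, V1)) Rcpp::stop("pseudoinverse in the pencil step failed");
  A = A * V2;
  cx_vec z;
  if (!eig_gen(z, A)) Rcpp::stop("pole eigenproblem failed");

  // Drop numerically null poles
  uvec keep = find(abs(z) > 1e-10);
  z = z.elem(keep);
  const int K = static_cast<int>(z.n_elem);
  if (K == 0) return out;

  // Complex amplitudes: least squares against the pole Vandermonde system
  cx_mat B(N, K);
  B.row(0) = cx_rowvec(K, fill::ones);
  for (int n = 1; n < N; ++n) B.row(n) = B.row(n - 1) % z.st();
  cx_vec cy(y, vec(N, fill::zeros));
  cx_vec c;
  // SVD-based solve: tolerant of rank deficiency from coincident noise
  // poles, and silent about it
  if (!solve(c, B, cy, solve_opts::force_approx))
    Rcpp::stop("amplitude least squares failed");

  const double two_pi = 2.0 * datum::pi;
  for (int k = 0; k < K; ++k) {
    const double f = std::arg(z(k)) / two_pi * fs;
    const double d = std::log(std::abs(z(k))) * fs;
    if (std::imag(z(k)) == 0.0) {
      // real pole: DC (z > 0) or Nyquist (z < 0); amplitude is |c|
      MPComponent comp;
      comp.freq = (std::real(z(k)) < 0.0) ? fs / 2.0 : 0.0;
      comp.damping = d;
      comp.amplitude = std::abs(c(k));
      comp.phase = (std::real(c(k)) < 0.0) ? datum::pi : 0.0;
      out.push_back(comp);
    } else if (f > 0.0) {
      // keep one member of each conjugate pair; real amplitude is 2|c|
      MPComponent comp;
      comp.freq = f;
      comp.damping = d;
      comp.amplitude = 2.0 * std::abs(c(k));
      comp.phase = std::arg(c(k));
      out.push_back(comp);
    }
  }
  std::sort(out.begin(), out.end(),
            [](const MPComponent& a, const MPComponent& b) {
              return a.freq < b.freq;
            });
  return out;
}

static Rcpp::NumericMatrix comps_to_matrix(const std::vector<MPComponent>& cs) {
  Rcpp::NumericMatrix m(static_cast<int>(cs.size()), 4);
  for (size_t i = 0; i < cs.size(); ++i) {
    m(i, 0) = cs[i].freq;
    m(i, 1) = cs[i].damping;
    m(i, 2) = cs[i].amplitude;
    m(i, 3) = cs[i].phase;
  }
  Rcpp::colnames(m) =
      Rcpp::CharacterVector::create("frequency", "damping", "amplitude", "phase");
  return m;
}

// [[Rcpp::export]]
Rcpp::NumericMatrix mp_decompose_cpp(Rcpp::NumericVector y, double fs, int L,
                                     int order, double sv_tol,
                                     int max_order) {
  vec yv(y.begin(), y.size(), false);
  return comps_to_matrix(
      mp_decompose_core(yv, fs, L, order, sv_tol, max_order));
}

// Amplitude of the component nearest f0 within +/- tol; 0 when none.
// Components are sorted by frequency, so a strict '<' keeps the lower
// frequency on an exact tie.
static double amplitude_at(const std::vector<MPComponent>& cs, double f0,
                           double tol) {
  double best = std::numeric_limits<double>::infinity();
  double amp = 0.0;
  for (const MPComponent& comp : cs) {
    const double d = std::abs(comp.freq - f0);
    if (d <= tol && d < best) {
      best = d;
      amp = comp.amplitude;
    }
  }
  return amp;
}

// Per-voxel amplitudes at target frequencies. series: N x nvox matrix, one
// voxel time series per column. Returns nvox x length(f0) matrix.
// [[Rcpp::export]]
Rcpp::NumericMatrix mp_band_amplitudes_cpp(Rcpp::NumericMatrix series,
                                           double fs, int L, int order,
                                           double sv_tol, int max_order,
                                           Rcpp::NumericVector f0, double tol) {
  const int N = series.nrow();
  const int nvox = series.ncol();
  const int nf = f0.size();
  Rcpp::NumericMatrix out(nvox, nf);
  mat S(series.begin(), N, nvox, false);
  for (int v = 0; v < nvox; ++v) {
    std::vector<MPComponent> cs =
        mp_decompose_core(S.col(v), fs, L, order, sv_tol, max_order);
    for (int j = 0; j < nf; ++j) out(v, j) = amplitude_at(cs, f0[j], tol);
  }
  return out;
}
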