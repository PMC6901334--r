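// Spiking continuous-attractor core.
//
// Five overlapping populations (N, S, W, E excitatory + one inhibitory) on an
// n x n sheet follow leaky integrate-and-fire dynamics with explicit Euler
// steps. Synaptic input is delivered by convolving per-step spike fields with
// the radial kernels; because the four excitatory populations share one
// kernel shape merely translated by xi along their preferred sheet direction,
// their spike fields are shifted at the source and summed, so a single
// convolution serves all excitatory output. The excitatory and inhibitory
// convolutions are fused into one complex FFT pair per step.
//
// [[Rcpp::depends(RcppArmadillo)]]
#define ARMA_NO_DEBUG
#include <RcppArmadillo.h>
using namespace Rcpp;

// --- counter-based noise stream -------------------------------------------
// Reproducible, restartable: the generator for (seed, absolute step) is keyed
// directly, so a session split across calls sees the identical noise.
static inline uint64_t splitmix64(uint64_t x) {
  x += 0x9E3779B97F4A7C15ULL;
  x = (x ^ (x >> 30)) * 0xBF58476D1CE4E5B9ULL;
  x = (x ^ (x >> 27)) * 0x94D049BB133111EBULL;
  return x ^ (x >> 31);
}

// Marsaglia-Tsang ziggurat tables for the standard normal
static uint32_t zig_kn[128];
static double zig_wn[128], zig_fn[128];
static bool zig_ready = false;
static void zig_init() {
  const double m1 = 2147483648.0;
  double dn = 3.442619855899, tn = dn, vn = 9.91256303526217e-3;
  double q = vn / std::exp(-0.5 * dn * dn);
  zig_kn[0] = (uint32_t)((dn / q) * m1);
  zig_kn[1] = 0;
  zig_wn[0] = q / m1;
  zig_wn[127] = dn / m1;
  zig_fn[0] = 1.0;
  zig_fn[127] = std::exp(-0.5 * dn * dn);
  for (int i = 126; i >= 1; --i) {
    dn = std::sqrt(-2.0 * std::log(vn / dn + std::exp(-0.5 * dn * dn)));
    zig_kn[i + 1] = (uint32_t)((dn / tn) * m1);
    tn = dn;
    zig_fn[i] = std::exp(-0.5 * dn * dn);
    zig_wn[i] = dn / m1;
  }
  zig_ready = true;
}

struct NoiseStream {
  uint64_t s0, s1;
  NoiseStream(uint64_t seed, uint64_t step) {
    if (!zig_ready) zig_init();
    uint64_t k = splitmix64(seed ^ splitmix64(step));
    s0 = splitmix64(k);
    s1 = splitmix64(k ^ 0xDEADBEEFCAFEBABEULL);
    if (s0 == 0 && s1 == 0) s1 = 1;
  }
  inline uint64_t next_u64() {
    uint64_t x = s0, y = s1;
    s0 = y;
    x ^= x << 23;
    s1 = x ^ y ^ (x >> 17) ^ (y >> 26);
    return s1 + y;
  }
  inline double unif() { // (0, 1)
    return ((next_u64() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }
  inline double normal() { // ziggurat
    for (;;) {
      int32_t hz = (int32_t)(uint32_t)next_u64();
      uint32_t iz = (uint32_t)hz & 127u;
      uint32_t ahz = hz < 0 ? (uint32_t)(-(int64_t)hz) : (uint32_t)hz;
      if (ahz < zig_kn[iz]) return hz * zig_wn[iz];
      if (iz == 0) {                       // tail
        double x, y;
        do {
          x = -std::log(unif()) * 0.29047645161474317; // 1/3.442619855899
          y = -std::log(unif());
        } while (y + y < x * x);
        return hz > 0 ? 3.442619855899 + x : -3.442619855899 - x;
      }
      double x = hz * zig_wn[iz];
      if (zig_fn[iz] + unif() * (zig_fn[iz - 1] - zig_fn[iz]) <
          std::exp(-0.5 * x * x))
        return x;
    }
  }
};

// [[Rcpp::export]]
List lif_core_cpp(int n, int m,
                  const arma::mat& Ahat, const arma::mat& Bhat,
                  const arma::mat& drive_maps, const arma::ivec& drive_idx,
                  const arma::vec& a_inh_t, const arma::mat& vel,
                  List prm, bool periodic,
                  const arma::ivec& rec_mask,
                  int snapshot_every, int snapshot_pop,
                  double seed_key, int t0,
                  arma::mat phi, arma::mat Chist, arma::mat Dhist) {
  const int T = drive_idx.n_elem;
  const int n2 = n * n;
  const double dt = prm["dt"];
  const double tau_e = prm["tau_m_exc"], tau_i = prm["tau_m_inh"];
  const int lag_ee = prm["lag_ee"], lag_ei = prm["lag_ei"],
            lag_in = prm["lag_inh"];
  const double alpha = prm["alpha_gain"];
  const double sd_e = prm["sd_exc"], sd_i = prm["sd_inh"];
  const int xi = prm["xi_shift"];
  const double ke = dt / tau_e, ki = dt / tau_i;

  if ((int)phi.n_rows != n2 || phi.n_cols != 5)
    stop("phi must be n^2 x 5");
  if ((int)Chist.n_cols != lag_ee || (int)Dhist.n_cols != lag_in)
    stop("history buffer width mismatch");

  // preferred spatial directions E_P (N,S,W,E) and sheet shifts e_P
  const double Ex[4] = {0, 0, -1, 1}, Ey[4] = {1, -1, 0, 0};
  const int ex[4] = {0, 0, -1, 1}, ey[4] = {1, -1, 0, 0};

  // delay ring buffers for convolved fields
  arma::mat Cring(n2, lag_ee, arma::fill::zeros);
  arma::mat Dring(n2, lag_in, arma::fill::zeros);
  for (int j = 0; j < lag_ee; ++j) {
    int s = t0 - lag_ee + j;                       // absolute step of Chist col j
    Cring.col(((s % lag_ee) + lag_ee) % lag_ee) = Chist.col(j);
  }
  for (int j = 0; j < lag_in; ++j) {
    int s = t0 - lag_in + j;
    Dring.col(((s % lag_in) + lag_in) % lag_in) = Dhist.col(j);
  }

  arma::cx_mat Zin(m, m), Z(m, m), Y(m, m);
  std::vector<int> ev_pop, ev_x, ev_y, ev_t;
  ev_pop.reserve(1 << 20);
  arma::vec tally(n2, arma::fill::zeros);
  arma::imat counts(T, 5, arma::fill::zeros);

  int n_snap = (snapshot_every > 0) ? T / snapshot_every : 0;
  arma::cube snaps(n, n, std::max(n_snap, 1), arma::fill::zeros);
  arma::vec snap_acc(n2, arma::fill::zeros);
  int snap_i = 0;

  const arma::sword* mask = rec_mask.memptr();
  double* tal = tally.memptr();
  double* sac = snap_acc.memptr();

  for (int t = 0; t < T; ++t) {
    const int abs_t = t0 + t;
    const double* Cee = Cring.colptr(((abs_t - lag_ee) % lag_ee + lag_ee) % lag_ee);
    const double* Cei = Cring.colptr(((abs_t - lag_ei) % lag_ee + lag_ee) % lag_ee);
    const double* Din = Dring.colptr(((abs_t - lag_in) % lag_in + lag_in) % lag_in);
    // note: C at lag_ei lives in the same ring as lag_ee since lag_ei < lag_ee

    const double* a_exc = drive_maps.colptr(drive_idx(t) - 1);
    const double a_inh = a_inh_t(t);
    const double vx = vel(t, 0), vy = vel(t, 1);

    Zin.zeros();
    std::complex<double>* zp = Zin.memptr();

    // excitatory populations
    for (int P = 0; P < 4; ++P) {
      NoiseStream ns(static_cast<uint64_t>(seed_key),
                     static_cast<uint64_t>(abs_t) * 8u + P);
      const double g = 1.0 + alpha * (Ex[P] * vx + Ey[P] * vy);
      double* ph = phi.colptr(P);
      int nsp = 0;
      for (int r = 0; r < n2; ++r) {
        double z = sd_e > 0 ? sd_e * ns.normal() : 0.0;
        double v = ph[r] + ke * (-ph[r] + Cee[r] + Din[r] + a_exc[r] * g + z);
        if (v >= 1.0) {
          ++nsp;
          const int x = r % n, y = r / n;
          tal[r] += 1.0;
          if (mask[r]) {
            ev_pop.push_back(P + 1); ev_x.push_back(x + 1);
            ev_y.push_back(y + 1);   ev_t.push_back(abs_t);
          }
          if (snapshot_every > 0 &&
              (snapshot_pop < 0 || snapshot_pop == P))
            sac[r] += 1.0;
          // deposit into combined shifted spike field
          int xx = x + xi * ex[P], yy = y + xi * ey[P];
          if (periodic) {
            xx = (xx % n + n) % n; yy = (yy % n + n) % n;
            zp[yy * m + xx] += std::complex<double>(1.0, 0.0);
          } else if (xx >= 0 && xx < n && yy >= 0 && yy < n) {
            zp[yy * m + xx] += std::complex<double>(1.0, 0.0);
          }
          v = 0.0;
        }
        if (v < -1.0) v = -1.0;
        ph[r] = v;
      }
      counts(t, P) = nsp;
    }

    // inhibitory population
    {
      NoiseStream ns(static_cast<uint64_t>(seed_key),
                     static_cast<uint64_t>(abs_t) * 8u + 4u);
      double* ph = phi.colptr(4);
      int nsp = 0;
      for (int r = 0; r < n2; ++r) {
        double z = sd_i > 0 ? sd_i * ns.normal() : 0.0;
        double v = ph[r] + ki * (-ph[r] + Cei[r] + a_inh + z);
        if (v >= 1.0) {
          ++nsp;
          const int x = r % n, y = r / n;
          if (mask[r]) {
            ev_pop.push_back(5); ev_x.push_back(x + 1);
            ev_y.push_back(y + 1); ev_t.push_back(abs_t);
          }
          zp[y * m + x] += std::complex<double>(0.0, 1.0);
          v = 0.0;
        }
        if (v < -1.0) v = -1.0;
        ph[r] = v;
      }
      counts(t, 4) = nsp;
    }

    if (t % 100 == 99 && !phi.is_finite())
      stop("non-finite membrane potential at step %d", abs_t);

    // fused convolution: Z = fft(Sc + i*Si);
    // Y(k) = A(k) Z(k) + B(k) conj(Z(-k)) with A=(We+Wi)/2, B=(We-Wi)/2
    // => ifft(Y) = (We * Sc) + i (Wi * Si)
    Z = arma::fft2(Zin);
    for (int j = 0; j < m; ++j) {
      const int jr = (m - j) % m;
      for (int i = 0; i < m; ++i) {
        const int ir = (m - i) % m;
        Y(i, j) = Ahat(i, j) * Z(i, j) + Bhat(i, j) * std::conj(Z(ir, jr));
      }
    }
    arma::cx_mat y = arma::ifft2(Y);

    double* Cw = Cring.colptr(((abs_t % lag_ee) + lag_ee) % lag_ee);
    double* Dw = Dring.colptr(((abs_t % lag_in) + lag_in) % lag_in);
    for (int yy = 0; yy < n; ++yy)
      for (int xx = 0; xx < n; ++xx) {
        const std::complex<double> v = y(xx, yy);
        Cw[yy * n + xx] = v.real();
        Dw[yy * n + xx] = v.imag();
      }

    if (snapshot_every > 0 && (t + 1) % snapshot_every == 0) {
      snaps.slice(snap_i++) = arma::reshape(snap_acc, n, n);
      snap_acc.zeros();
    }
  }

  // export chronological history for continuation
  arma::mat Cout(n2, lag_ee), Dout(n2, lag_in);
  for (int j = 0; j < lag_ee; ++j) {
    int s = t0 + T - lag_ee + j;
    Cout.col(j) = Cring.col(((s % lag_ee) + lag_ee) % lag_ee);
  }
  for (int j = 0; j < lag_in; ++j) {
    int s = t0 + T - lag_in + j;
    Dout.col(j) = Dring.col(((s % lag_in) + lag_in) % lag_in);
  }

  IntegerMatrix events(ev_pop.size(), 4);
  for (size_t i = 0; i < ev_pop.size(); ++i) {
    events(i, 0) = ev_pop[i]; events(i, 1) = ev_x[i];
    events(i, 2) = ev_y[i];   events(i, 3) = ev_t[i];
  }
  colnames(events) = CharacterVector::create("pop", "x", "y", "t");

  List out = List::create(
    _["events"] = events,
    _["counts"] = counts,
    _["tally"] = arma::mat(arma::reshape(tally, n, n)),
    _["phi"] = phi,
    _["Chist"] = Cout,
    _["Dhist"] = Dout);
  if (snapshot_every > 0 && n_snap > 0)
    out["snapshots"] = snaps;
  return out;
}

// 4-connected component labelling of a thresholded image (used for attractor
// bump segmentation). Returns integer labels, 0 = background.
// [[Rcpp::export]]
arma::imat label_components_cpp(const arma::mat& img, double threshold) {
  const int nr = img.n_rows, nc = img.n_cols;
  arma::imat lab(nr, nc, arma::fill::zeros);
  int next = 0;
  std::vector<int> stack;
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) {
      if (img(i, j) < threshold || lab(i, j) != 0) continue;
      ++next;
      stack.clear();
      stack.push_back(j * nr + i);
      lab(i, j) = next;
      while (!stack.empty()) {
        int p = stack.back(); stack.pop_back();
        int pi = p % nr, pj = p / nr;
        const int di[4] = {-1, 1, 0, 0}, dj[4] = {0, 0, -1, 1};
        for (int k = 0; k < 4; ++k) {
          int qi = pi + di[k], qj = pj + dj[k];
          if (qi < 0 || qi >= nr || qj < 0 || qj >= nc) continue;
          if (img(qi, qj) >= threshold && lab(qi, qj) == 0) {
            lab(qi, qj) = next;
            stack.push_back(qj * nr + qi);
          }
        }
      }
    }
  return lab;
}
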