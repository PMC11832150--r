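// Interval-censored panel likelihood for continuous-time multi-state Markov
// models with Gompertz (age-log-linear) transition intensities, frozen within
// age bands (piecewise-constant approximation).
//
// Transition probabilities over a band segment of width dt are computed from
// the eigendecomposition of the generator Q (P = V exp(D dt) V^-1), which also
// yields analytic score contributions through the Loewner-matrix form of the
// Frechet derivative of the matrix exponential.  Ill-conditioned eigenvector
// matrices fall back to scaling-and-squaring Pade with block-matrix
// directional derivatives.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

namespace {

struct ModelSpec {
  int n_states;
  ivec tfrom, tto;      // 0-based transition endpoints
  int n_trans;
  int n_cov;
  mat Z;                // n_profiles x n_cov covariate values
  double origin;        // age origin (intensities are baseline at this age)
  double bw;            // band width in years
  int n_bands;
  int absorbing;        // 0-based index, or -1
};

// scaling-and-squaring expm with [6/6] Pade; robust for generator matrices
// (never throws, unlike condition-checked library routines)
mat expm_pade(const mat& A) {
  const int n = A.n_rows;
  double nrm = norm(A, "inf");
  if (!std::isfinite(nrm)) return mat(n, n, fill::value(datum::nan));
  int s = 0;
  if (nrm > 0.5) s = (int)std::ceil(std::log2(nrm / 0.5));
  if (s > 60) s = 60;
  mat As = A / std::pow(2.0, s);
  static const double c[7] = {1.0, 0.5, 3.0 / 26.0, 5.0 / 312.0,
                              5.0 / 3432.0, 1.0 / 11440.0, 1.0 / 308880.0};
  mat A2 = As * As;
  mat U = As * (c[1] * eye(n, n) + c[3] * A2 + c[5] * A2 * A2);
  mat V = c[0] * eye(n, n) + c[2] * A2 + c[4] * A2 * A2 + c[6] * A2 * A2 * A2;
  mat P;
  if (!solve(P, V - U, V + U, solve_opts::fast))
    P = pinv(V - U) * (V + U);
  for (int i = 0; i < s; ++i) P = P * P;
  return P;
}

ModelSpec parse_spec(const Rcpp::List& s) {
  ModelSpec m;
  m.n_states = Rcpp::as<int>(s["n_states"]);
  m.tfrom = Rcpp::as<ivec>(s["tfrom"]) - 1;
  m.tto   = Rcpp::as<ivec>(s["tto"]) - 1;
  m.n_trans = m.tfrom.n_elem;
  m.n_cov = Rcpp::as<int>(s["n_cov"]);
  m.Z = Rcpp::as<mat>(s["Z"]);
  m.origin = Rcpp::as<double>(s["origin"]);
  m.bw = Rcpp::as<double>(s["band_width"]);
  m.n_bands = Rcpp::as<int>(s["n_bands"]);
  m.absorbing = Rcpp::as<int>(s["absorbing"]) - 1;  // -1 when R passes 0
  return m;
}

inline int block_size(const ModelSpec& m) { return 2 + m.n_cov; }

// per-transition intensities and generator at a given age for one profile.
// Linear predictors above 30 (rates beyond 1e13/year) are capped to keep
// optimizer excursions finite; capped transitions are flagged so the score
// can be zeroed there, consistent with the flattened likelihood.
void build_Q(const ModelSpec& m, const vec& theta, const rowvec& z,
             double age, mat& Q, vec& qvals,
             std::vector<unsigned char>& capped) {
  Q.zeros(m.n_states, m.n_states);
  qvals.set_size(m.n_trans);
  capped.assign(m.n_trans, 0);
  const int bs = block_size(m);
  for (int t = 0; t < m.n_trans; ++t) {
    double lp = theta[t * bs] + theta[t * bs + 1] * (age - m.origin);
    for (int c = 0; c < m.n_cov; ++c) lp += theta[t * bs + 2 + c] * z[c];
    if (lp > 30) { lp = 30; capped[t] = 1; }
    double q = std::exp(lp);
    qvals[t] = q;
    Q(m.tfrom[t], m.tto[t]) += q;
    Q(m.tfrom[t], m.tfrom[t]) -= q;
  }
}

inline int band_of(const ModelSpec& m, double age) {
  int b = (int)std::floor((age - m.origin) / m.bw + 1e-12);
  if (b < 0) b = 0;
  if (b >= m.n_bands) b = m.n_bands - 1;
  return b;
}

// band for the left-limit hazard q(t-): an event time sitting exactly on a
// band boundary belongs to the band it was approached through.  Evaluating
// it in the right band would let that band's hazard grow without bound
// (the survival path never traverses it), an unbounded-likelihood spike.
inline int band_of_left(const ModelSpec& m, double age) {
  int b = band_of(m, age);
  if (b > 0 && age - (m.origin + b * m.bw) < 1e-9) --b;
  return b;
}

inline double band_mid(const ModelSpec& m, int b) {
  return m.origin + (b + 0.5) * m.bw;
}

// cached decomposition of Q for one (profile, band)
struct BandCache {
  bool computed = false;
  bool eig_ok = false;
  mat Q;
  vec qvals;
  std::vector<unsigned char> capped;
  cx_mat V, Vinv;
  cx_vec d;
  bool has_full = false;   // P over a full band cached
  mat P_full;
};

struct Engine {
  const ModelSpec& m;
  const vec& theta;
  std::vector<BandCache> cache;   // n_profiles * n_bands
  int n_prof;

  Engine(const ModelSpec& m_, const vec& theta_, int n_prof_)
    : m(m_), theta(theta_), n_prof(n_prof_) {
    cache.resize((size_t)n_prof * m.n_bands);
  }

  BandCache& get(int prof, int band) {
    BandCache& bc = cache[(size_t)prof * m.n_bands + band];
    if (!bc.computed) {
      build_Q(m, theta, m.Z.row(prof), band_mid(m, band), bc.Q, bc.qvals,
              bc.capped);
      cx_vec d;
      cx_mat V;
      bool ok = eig_gen(d, V, bc.Q);
      if (ok) {
        // generator spectra lie in Re <= 0; clip roundoff excursions that
        // would otherwise make exp(d * dt) explode for extreme parameters
        for (uword k = 0; k < d.n_elem; ++k)
          if (d[k].real() > 0) d[k] = cx_double(0.0, d[k].imag());
        cx_mat Vi;
        ok = inv(Vi, V);
        if (ok) {
          double c = cond(V);
          if (std::isfinite(c) && c < 1e8) {
            bc.V = V; bc.Vinv = Vi; bc.d = d; bc.eig_ok = true;
          }
        }
      }
      bc.computed = true;
    }
    return bc;
  }

  // P over [a, a+dt] within one band, written into column-major buffer P
  void segP_into(BandCache& bc, double dt, bool full_band, double* P) {
    const int n = m.n_states;
    if (full_band && bc.has_full) {
      std::copy(bc.P_full.memptr(), bc.P_full.memptr() + n * n, P);
      return;
    }
    if (bc.eig_ok && n > 12) {  // rare large spaces: plain armadillo
      cx_vec e = exp(bc.d * dt);
      mat Pm = real(bc.V * diagmat(e) * bc.Vinv);
      Pm.transform([](double x) { return x < 0 && x > -1e-12 ? 0.0 : x; });
      std::copy(Pm.memptr(), Pm.memptr() + n * n, P);
    } else if (bc.eig_ok) {
      // P = Re( V diag(exp(d dt)) Vinv ), hand-rolled to avoid temporaries
      const cx_double* V = bc.V.memptr();
      const cx_double* Vi = bc.Vinv.memptr();
      cx_double e[12], EV[144];
      for (int k = 0; k < n; ++k) e[k] = std::exp(bc.d[k] * dt);
      for (int j = 0; j < n; ++j)
        for (int k = 0; k < n; ++k) EV[j * n + k] = e[k] * Vi[j * n + k];
      for (int j = 0; j < n; ++j)
        for (int i = 0; i < n; ++i) {
          cx_double acc(0, 0);
          for (int k = 0; k < n; ++k) acc += V[k * n + i] * EV[j * n + k];
          double v = acc.real();
          P[j * n + i] = (v < 0 && v > -1e-12) ? 0.0 : v;
        }
    } else {
      mat Pm = expm_pade(bc.Q * dt);
      Pm.transform([](double x) { return x < 0 && x > -1e-12 ? 0.0 : x; });
      std::copy(Pm.memptr(), Pm.memptr() + n * n, P);
    }
    if (full_band) {
      bc.P_full = mat(P, n, n);
      bc.has_full = true;
    }
  }

  mat segP(BandCache& bc, double dt, bool full_band) {
    mat P(m.n_states, m.n_states);
    segP_into(bc, dt, full_band, P.memptr());
    return P;
  }
};

struct Segment {
  int band;
  double dt;
  bool full;
};

void make_segments(const ModelSpec& m, double a1, double a2,
                   std::vector<Segment>& segs) {
  segs.clear();
  if (a2 <= a1 + 1e-12) return;
  double a = a1;
  while (a < a2 - 1e-12) {
    int b = band_of(m, a);
    double bend = m.origin + (b + 1) * m.bw;
    double nxt = std::min(bend, a2);
    if (nxt <= a + 1e-12) { nxt = a2; }  // beyond last band: freeze at last band
    if (b == m.n_bands - 1) nxt = a2;    // last band extends to any age
    Segment s;
    s.band = b;
    s.dt = nxt - a;
    s.full = std::abs(s.dt - m.bw) < 1e-9 &&
             std::abs(a - (m.origin + b * m.bw)) < 1e-9;
    segs.push_back(s);
    a = nxt;
  }
}

// fallback directional derivative via block matrix exponential
double frechet_block(const mat& Q, double dt, int r, int s, double q,
                     const rowvec& f, const vec& g, int n) {
  mat E(n, n, fill::zeros);
  E(r, s) += q; E(r, r) -= q;
  mat A(2 * n, 2 * n, fill::zeros);
  A.submat(0, 0, n - 1, n - 1) = Q * dt;
  A.submat(n, n, 2 * n - 1, 2 * n - 1) = Q * dt;
  A.submat(0, n, n - 1, 2 * n - 1) = E * dt;
  mat eA = expm_pade(A);
  mat L = eA.submat(0, n, n - 1, 2 * n - 1);
  return as_scalar(f * L * g);
}

}  // namespace

// [[Rcpp::export]]
Rcpp::List cpp_panel_loglik(const arma::vec& theta, const Rcpp::List& spec,
                            const Rcpp::List& ints, bool want_grad) {
  ModelSpec m = parse_spec(spec);
  ivec from = Rcpp::as<ivec>(ints["from"]) - 1;
  ivec type = Rcpp::as<ivec>(ints["type"]);
  ivec to   = Rcpp::as<ivec>(ints["to"]) - 1;
  ivec cmask = Rcpp::as<ivec>(ints["cmask"]);
  vec age1 = Rcpp::as<vec>(ints["age1"]);
  vec age2 = Rcpp::as<vec>(ints["age2"]);
  ivec prof = Rcpp::as<ivec>(ints["prof"]) - 1;
  const int n_int = from.n_elem;
  const int n = m.n_states;
  const int bs = block_size(m);
  const int n_par = m.n_trans * bs;
  const double FLOOR = 1e-300;

  Engine eng(m, theta, m.Z.n_rows);
  double ll = 0.0;
  int n_floored = 0;
  vec grad(n_par, fill::zeros);
  std::vector<Segment> segs;
  std::vector<double> fbuf, gbuf, Sbuf, w(n);

  for (int i = 0; i < n_int; ++i) {
    make_segments(m, age1[i], age2[i], segs);
    const int k = segs.size();
    if ((int)fbuf.size() < (k + 1) * n) {
      fbuf.resize((k + 1) * n);
      gbuf.resize((k + 1) * n);
      Sbuf.resize(k * n * n);
    }

    // terminal vector w (and, for exact deaths, its parameter dependence)
    std::fill(w.begin(), w.end(), 0.0);
    int death_band = -1;
    if (type[i] == 0) {
      w[to[i]] = 1.0;
    } else if (type[i] == 1) {
      death_band = band_of_left(m, age2[i]);
      BandCache& bc = eng.get(prof[i], death_band);
      for (int t = 0; t < m.n_trans; ++t)
        if (m.tto[t] == m.absorbing) w[m.tfrom[t]] += bc.qvals[t];
    } else {
      for (int s = 0; s < n; ++s)
        if (cmask[i] & (1 << s)) w[s] = 1.0;
    }

    // forward pass, storing intermediate row vectors and segment matrices
    double* f0 = fbuf.data();
    std::fill(f0, f0 + n, 0.0);
    f0[from[i]] = 1.0;
    for (int j = 0; j < k; ++j) {
      BandCache& bc = eng.get(prof[i], segs[j].band);
      double* S = Sbuf.data() + j * n * n;
      eng.segP_into(bc, segs[j].dt, segs[j].full, S);
      const double* fj = fbuf.data() + j * n;
      double* fn_ = fbuf.data() + (j + 1) * n;
      for (int c = 0; c < n; ++c) {
        double acc = 0;
        for (int r = 0; r < n; ++r) acc += fj[r] * S[c * n + r];
        fn_[c] = acc;
      }
    }
    const double* fk = fbuf.data() + k * n;
    double p = 0;
    for (int c = 0; c < n; ++c) p += fk[c] * w[c];
    bool floored = false;
    if (!(p > FLOOR)) { p = FLOOR; ++n_floored; floored = true; }
    ll += std::log(p);
    if (!want_grad || floored) continue;

    // backward vectors g_j = S_j ... S_{k-1} w
    double* gk = gbuf.data() + k * n;
    std::copy(w.begin(), w.end(), gk);
    for (int j = k - 1; j >= 0; --j) {
      const double* S = Sbuf.data() + j * n * n;
      const double* gj1 = gbuf.data() + (j + 1) * n;
      double* gj = gbuf.data() + j * n;
      for (int r = 0; r < n; ++r) {
        double acc = 0;
        for (int c = 0; c < n; ++c) acc += S[c * n + r] * gj1[c];
        gj[r] = acc;
      }
    }

    const rowvec z = m.Z.row(prof[i]);
    cx_double u[12], gt[12], Phi[144];
    for (int j = 0; j < k; ++j) {
      BandCache& bc = eng.get(prof[i], segs[j].band);
      const double dt = segs[j].dt;
      const double xage = band_mid(m, segs[j].band) - m.origin;
      const double* fj = fbuf.data() + j * n;
      const double* gj1 = gbuf.data() + (j + 1) * n;
      if (bc.eig_ok && n <= 12) {
        const cx_double* V = bc.V.memptr();
        const cx_double* Vi = bc.Vinv.memptr();
        // u = f' V, gt = Vinv g, Phi = Loewner divided differences at d*dt
        for (int kk = 0; kk < n; ++kk) {
          cx_double au(0, 0), ag(0, 0);
          for (int r = 0; r < n; ++r) {
            au += fj[r] * V[kk * n + r];
            ag += Vi[r * n + kk] * gj1[r];
          }
          u[kk] = au; gt[kk] = ag;
        }
        {
          cx_double dd[12], ed[12];
          for (int a = 0; a < n; ++a) { dd[a] = bc.d[a] * dt; ed[a] = std::exp(dd[a]); }
          for (int a = 0; a < n; ++a)
            for (int b = 0; b < n; ++b) {
              cx_double diff = dd[a] - dd[b];
              if (std::abs(diff) < 1e-7) {
                cx_double h = diff / 2.0;
                Phi[b * n + a] = std::exp((dd[a] + dd[b]) / 2.0) *
                  (1.0 + h * h / 6.0 + h * h * h * h / 120.0);
              } else {
                Phi[b * n + a] = (ed[a] - ed[b]) / diff;
              }
            }
        }
        for (int t = 0; t < m.n_trans; ++t) {
          if (bc.capped[t]) continue;
          const int r = m.tfrom[t], s = m.tto[t];
          // x_a = u_a * Vinv(a, r); y_b = (V(s, b) - V(r, b)) * gt_b
          cx_double acc(0, 0);
          for (int a = 0; a < n; ++a) {
            cx_double xa = u[a] * Vi[r * n + a];
            if (xa == cx_double(0, 0)) continue;
            cx_double inner(0, 0);
            for (int b = 0; b < n; ++b)
              inner += Phi[b * n + a] * (V[b * n + s] - V[b * n + r]) * gt[b];
            acc += xa * inner;
          }
          double c = acc.real() * dt * bc.qvals[t] / p;
          grad[t * bs] += c;
          grad[t * bs + 1] += c * xage;
          for (int cv = 0; cv < m.n_cov; ++cv) grad[t * bs + 2 + cv] += c * z[cv];
        }
      } else {
        rowvec fv(const_cast<double*>(fj), n, false, true);
        vec gv(const_cast<double*>(gj1), n, false, true);
        for (int t = 0; t < m.n_trans; ++t) {
          if (bc.capped[t]) continue;
          double c = frechet_block(bc.Q, dt, m.tfrom[t], m.tto[t], bc.qvals[t],
                                   fv, gv, n) * dt / p;
          grad[t * bs] += c;
          grad[t * bs + 1] += c * xage;
          for (int cv = 0; cv < m.n_cov; ++cv) grad[t * bs + 2 + cv] += c * z[cv];
        }
      }
    }
    // exact-death terminal density term: w depends on theta
    if (type[i] == 1) {
      BandCache& bc = eng.get(prof[i], death_band);
      const double xage = band_mid(m, death_band) - m.origin;
      for (int t = 0; t < m.n_trans; ++t) {
        if (m.tto[t] != m.absorbing || bc.capped[t]) continue;
        double c = fk[m.tfrom[t]] * bc.qvals[t] / p;
        grad[t * bs] += c;
        grad[t * bs + 1] += c * xage;
        for (int cv = 0; cv < m.n_cov; ++cv) grad[t * bs + 2 + cv] += c * z[cv];
      }
    }
  }

  if (want_grad)
    return Rcpp::List::create(Rcpp::Named("loglik") = ll,
                              Rcpp::Named("grad") = grad,
                              Rcpp::Named("n_floored") = n_floored);
  return Rcpp::List::create(Rcpp::Named("loglik") = ll,
                            Rcpp::Named("n_floored") = n_floored);
}

// transition probability matrix P(age1, age2) for one covariate profile
// [[Rcpp::export]]
arma::mat cpp_tpm(const arma::vec& theta, const Rcpp::List& spec,
                  const arma::rowvec& z, double age1, double age2) {
  ModelSpec m = parse_spec(spec);
  m.Z = z;  // single profile
  Engine eng(m, theta, 1);
  std::vector<Segment> segs;
  make_segments(m, age1, age2, segs);
  mat P(m.n_states, m.n_states, fill::eye);
  for (size_t j = 0; j < segs.size(); ++j) {
    BandCache& bc = eng.get(0, segs[j].band);
    P = P * eng.segP(bc, segs[j].dt, segs[j].full);
  }
  return P;
}

// state occupancy probabilities on an age grid, one covariate profile
// [[Rcpp::export]]
arma::mat cpp_occupancy(const arma::vec& theta, const Rcpp::List& spec,
                        const arma::rowvec& z, const arma::rowvec& init,
                        double start_age, double age_max, double step) {
  ModelSpec m = parse_spec(spec);
  m.Z = z;
  Engine eng(m, theta, 1);
  const int n_steps = (int)std::round((age_max - start_age) / step);
  mat occ(n_steps + 1, m.n_states);
  rowvec u = init;
  occ.row(0) = u;
  std::vector<Segment> segs;
  for (int i = 0; i < n_steps; ++i) {
    double a1 = start_age + i * step, a2 = start_age + (i + 1) * step;
    make_segments(m, a1, a2, segs);
    for (size_t j = 0; j < segs.size(); ++j) {
      BandCache& bc = eng.get(0, segs[j].band);
      u = u * eng.segP(bc, segs[j].dt, segs[j].full);
    }
    occ.row(i + 1) = u;
  }
  return occ;
}
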