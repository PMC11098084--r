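// Overdamped Langevin (Brownian dynamics) core for the button-barcode
// pairing simulation. Uses R's RNG (norm_rand/unif_rand) so runs are
// reproducible from set.seed() on the R side; everything is single-threaded
// and iterated in a fixed order.

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <algorithm>
using namespace Rcpp;

namespace {

// Fast counter-free RNG for the inner loop: xoshiro256++ seeded from R's RNG
// stream, so trajectories remain fully reproducible from set.seed() on the R
// side. Normals are generated by Box--Muller with a one-value cache.
inline uint64_t rotl64(const uint64_t x, int k) {
  return (x << k) | (x >> (64 - k));
}

struct FastRng {
  uint64_t s[4];
  bool have_norm = false;
  double cached_norm = 0.0;

  explicit FastRng(uint64_t seed) {
    // splitmix64 expansion of the seed
    for (int i = 0; i < 4; ++i) {
      seed += 0x9e3779b97f4a7c15ULL;
      uint64_t z = seed;
      z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
      z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
      s[i] = z ^ (z >> 31);
    }
  }
  uint64_t next() {
    const uint64_t result = rotl64(s[0] + s[3], 23) + s[0];
    const uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl64(s[3], 45);
    return result;
  }
  double unif() { return (next() >> 11) * 0x1.0p-53; }  // [0, 1)
  double norm() {
    if (have_norm) { have_norm = false; return cached_norm; }
    double u1;
    do { u1 = unif(); } while (u1 <= 0.0);
    const double r = std::sqrt(-2.0 * std::log(u1));
    const double th = 2.0 * M_PI * unif();
    cached_norm = r * std::sin(th);
    have_norm = true;
    return r * std::cos(th);
  }
};

inline uint64_t seed_from_r_rng() {
  const uint64_t a = (uint64_t)(unif_rand() * 4294967296.0);
  const uint64_t b = (uint64_t)(unif_rand() * 4294967296.0);
  return (a << 32) ^ b;
}

struct Params {
  double k_spring, k_bend, k_pair, k_confine, k_tether;
  double friction, kBT, dt;
  double nucleus_radius, rabl_patch_radius, capture_radius;
  double p_unpair, rest_length;
};

inline double get(const List& par, const char* name) {
  return as<double>(par[name]);
}

struct Candidate {
  double d2;
  int a, b; // global button ids, canonical order (chain,node) of a <= b
};

} // namespace

// [[Rcpp::export(name = ".engine_run")]]
List engine_run(NumericMatrix pos0, int n_chains, int n_nodes,
                List buttons, IntegerMatrix bonds0, List par,
                int n_steps, int record_every, int burn_in,
                bool pairing_enabled) {
  Params p;
  p.k_spring = get(par, "k_spring");
  p.k_bend = get(par, "k_bend");
  p.k_pair = get(par, "k_pair");
  p.k_confine = get(par, "k_confine");
  p.k_tether = get(par, "k_tether");
  p.friction = get(par, "friction");
  p.kBT = get(par, "kBT");
  p.dt = get(par, "dt");
  p.nucleus_radius = get(par, "nucleus_radius");
  p.rabl_patch_radius = get(par, "rabl_patch_radius");
  p.capture_radius = get(par, "capture_radius");
  p.p_unpair = get(par, "p_unpair");
  p.rest_length = get(par, "rest_length");

  const int N = n_chains * n_nodes;
  FastRng rng(seed_from_r_rng());
  std::vector<double> X(3 * N), F(3 * N);
  for (int i = 0; i < N; ++i)
    for (int k = 0; k < 3; ++k) X[3 * i + k] = pos0(i, k);

  // Global button table, ordered by (chain, node).
  std::vector<int> btn_chain, btn_node, btn_row;
  for (int c = 0; c < n_chains; ++c) {
    IntegerVector bi = buttons[c];
    for (int j = 0; j < bi.size(); ++j) {
      btn_chain.push_back(c);
      btn_node.push_back(bi[j]);
      btn_row.push_back(c * n_nodes + bi[j]);
    }
  }
  const int NB = (int)btn_chain.size();
  std::vector<int> partner(NB, -1);

  // Seed existing bonds (rows: chain 1-based, node, chain 1-based, node).
  for (int r = 0; r < bonds0.nrow(); ++r) {
    int a = -1, b = -1;
    for (int q = 0; q < NB; ++q) {
      if (btn_chain[q] == bonds0(r, 0) - 1 && btn_node[q] == bonds0(r, 1)) a = q;
      if (btn_chain[q] == bonds0(r, 2) - 1 && btn_node[q] == bonds0(r, 3)) b = q;
    }
    if (a < 0 || b < 0) stop("bond endpoint is not a declared button");
    partner[a] = b;
    partner[b] = a;
  }

  const double R = p.nucleus_radius;
  const bool rabl_on = p.rabl_patch_radius < 2.0 * R;
  const double theta_c =
      2.0 * std::asin(std::min(p.rabl_patch_radius / (2.0 * R), 1.0));
  const double mob = p.dt / p.friction;
  const double sigma = std::sqrt(2.0 * p.kBT * p.dt / p.friction);
  const double cap2 = p.capture_radius * p.capture_radius;

  // Recording buffers.
  std::vector<int> rec_steps;
  std::vector<NumericMatrix> rec_pos;
  std::vector<IntegerMatrix> rec_bonds;
  std::vector<Candidate> cand;
  std::vector<int> freeb;

  auto record = [&](int step) {
    NumericMatrix P(N, 3);
    for (int i = 0; i < N; ++i)
      for (int k = 0; k < 3; ++k) P(i, k) = X[3 * i + k];
    int nb = 0;
    for (int q = 0; q < NB; ++q)
      if (partner[q] > q) ++nb;
    IntegerMatrix B(nb, 4);
    int r = 0;
    for (int q = 0; q < NB; ++q) {
      if (partner[q] > q) {
        B(r, 0) = btn_chain[q] + 1;
        B(r, 1) = btn_node[q];
        B(r, 2) = btn_chain[partner[q]] + 1;
        B(r, 3) = btn_node[partner[q]];
        ++r;
      }
    }
    rec_steps.push_back(step);
    rec_pos.push_back(P);
    rec_bonds.push_back(B);
  };

  record(0);

  for (int step = 1; step <= n_steps; ++step) {
    // --- pairing kinetics (break, then greedy nearest-first formation) ---
    if (pairing_enabled && step > burn_in && NB > 0) {
      for (int q = 0; q < NB; ++q) {
        if (partner[q] > q) {
          if (rng.unif() < p.p_unpair) {
            partner[partner[q]] = -1;
            partner[q] = -1;
          }
        }
      }
      freeb.clear();
      for (int q = 0; q < NB; ++q)
        if (partner[q] < 0) freeb.push_back(q);
      if ((int)freeb.size() >= 2) {
        cand.clear();
        for (size_t u = 0; u + 1 < freeb.size(); ++u) {
          const int a = freeb[u];
          const double *xa = &X[3 * btn_row[a]];
          for (size_t v = u + 1; v < freeb.size(); ++v) {
            const int b = freeb[v];
            const double *xb = &X[3 * btn_row[b]];
            const double dx = xa[0] - xb[0], dy = xa[1] - xb[1],
                         dz = xa[2] - xb[2];
            const double d2 = dx * dx + dy * dy + dz * dz;
            if (d2 < cap2) cand.push_back({d2, a, b});
          }
        }
        std::sort(cand.begin(), cand.end(),
                  [](const Candidate& l, const Candidate& r2) {
                    if (l.d2 != r2.d2) return l.d2 < r2.d2;
                    if (l.a != r2.a) return l.a < r2.a;
                    return l.b < r2.b;
                  });
        for (const Candidate& c : cand) {
          if (partner[c.a] < 0 && partner[c.b] < 0) {
            partner[c.a] = c.b;
            partner[c.b] = c.a;
          }
        }
      }
    }

    // --- forces ---
    std::fill(F.begin(), F.end(), 0.0);
    for (int c = 0; c < n_chains; ++c) {
      const int off = c * n_nodes;
      // backbone springs
      for (int j = 0; j + 1 < n_nodes; ++j) {
        const int i0 = 3 * (off + j), i1 = 3 * (off + j + 1);
        const double ux = X[i1] - X[i0], uy = X[i1 + 1] - X[i0 + 1],
                     uz = X[i1 + 2] - X[i0 + 2];
        const double d = std::sqrt(ux * ux + uy * uy + uz * uz);
        if (d > 0) {
          const double s = p.k_spring * (d - p.rest_length) / d;
          F[i0] += s * ux; F[i0 + 1] += s * uy; F[i0 + 2] += s * uz;
          F[i1] -= s * ux; F[i1 + 1] -= s * uy; F[i1 + 2] -= s * uz;
        }
      }
      // bending: midpoint-deviation penalty
      if (p.k_bend > 0) {
        for (int j = 1; j + 1 < n_nodes; ++j) {
          const int im = 3 * (off + j - 1), ic = 3 * (off + j),
                    ip = 3 * (off + j + 1);
          for (int k = 0; k < 3; ++k) {
            const double v = X[ic + k] - 0.5 * (X[im + k] + X[ip + k]);
            F[ic + k] -= p.k_bend * v;
            F[im + k] += 0.5 * p.k_bend * v;
            F[ip + k] += 0.5 * p.k_bend * v;
          }
        }
      }
      // centromere tether to nearest point of the Rabl cap
      if (rabl_on) {
        const int i0 = 3 * off;
        const double x = X[i0], y = X[i0 + 1], z = X[i0 + 2];
        const double rho = std::sqrt(x * x + y * y);
        const double theta = std::atan2(rho, z);
        const double tp = std::min(theta, theta_c);
        double cx = 1.0, cy = 0.0;
        if (rho > 0) { cx = x / rho; cy = y / rho; }
        const double px = R * std::sin(tp) * cx, py = R * std::sin(tp) * cy,
                     pz = R * std::cos(tp);
        F[i0] += p.k_tether * (px - x);
        F[i0 + 1] += p.k_tether * (py - y);
        F[i0 + 2] += p.k_tether * (pz - z);
      }
    }
    // confinement
    for (int i = 0; i < N; ++i) {
      const double x = X[3 * i], y = X[3 * i + 1], z = X[3 * i + 2];
      const double r = std::sqrt(x * x + y * y + z * z);
      if (r > R) {
        const double s = p.k_confine * (r - R) / r;
        F[3 * i] -= s * x; F[3 * i + 1] -= s * y; F[3 * i + 2] -= s * z;
      }
    }
    // pairing bonds (zero rest length)
    for (int q = 0; q < NB; ++q) {
      const int q2 = partner[q];
      if (q2 > q) {
        const int ia = 3 * btn_row[q], ib = 3 * btn_row[q2];
        for (int k = 0; k < 3; ++k) {
          const double d = X[ia + k] - X[ib + k];
          F[ia + k] -= p.k_pair * d;
          F[ib + k] += p.k_pair * d;
        }
      }
    }

    // --- Euler--Maruyama update ---
    if (p.kBT > 0) {
      for (int i = 0; i < 3 * N; ++i)
        X[i] += mob * F[i] + sigma * rng.norm();
    } else {
      for (int i = 0; i < 3 * N; ++i) X[i] += mob * F[i];
    }

    if (step % 100 == 0 || step == n_steps) {
      for (int i = 0; i < 3 * N; ++i) {
        if (!std::isfinite(X[i])) stop("numerical blow-up: reduce dt");
      }
    }
    if (step % record_every == 0) record(step);
  }

  return List::create(
      _["steps"] = wrap(rec_steps),
      _["positions"] = wrap(rec_pos),
      _["bonds"] = wrap(rec_bonds));
}

// Single kBT=0 relaxation by gradient descent on the elastic energy, used by
// the discrimination-energy calculation: descends until the maximum force
// component falls below `tol` or `max_iter` is reached. Bonds are fixed
// (given, never broken or formed). Returns the relaxed positions.
// [[Rcpp::export(name = ".engine_relax")]]
List engine_relax(NumericMatrix pos0, int n_chains, int n_nodes,
                  IntegerMatrix bond_rows, List par, double step_size,
                  double tol, int max_iter, bool confined) {
  Params p;
  p.k_spring = get(par, "k_spring");
  p.k_bend = get(par, "k_bend");
  p.k_pair = get(par, "k_pair");
  p.k_confine = confined ? get(par, "k_confine") : 0.0;
  p.k_tether = 0.0;
  p.nucleus_radius = get(par, "nucleus_radius");
  p.rest_length = get(par, "rest_length");

  const int N = n_chains * n_nodes;
  std::vector<double> X(3 * N), F(3 * N);
  for (int i = 0; i < N; ++i)
    for (int k = 0; k < 3; ++k) X[3 * i + k] = pos0(i, k);

  double fmax = 0;
  int it = 0;
  for (it = 0; it < max_iter; ++it) {
    std::fill(F.begin(), F.end(), 0.0);
    for (int c = 0; c < n_chains; ++c) {
      const int off = c * n_nodes;
      for (int j = 0; j + 1 < n_nodes; ++j) {
        const int i0 = 3 * (off + j), i1 = 3 * (off + j + 1);
        const double ux = X[i1] - X[i0], uy = X[i1 + 1] - X[i0 + 1],
                     uz = X[i1 + 2] - X[i0 + 2];
        const double d = std::sqrt(ux * ux + uy * uy + uz * uz);
        if (d > 0) {
          const double s = p.k_spring * (d - p.rest_length) / d;
          F[i0] += s * ux; F[i0 + 1] += s * uy; F[i0 + 2] += s * uz;
          F[i1] -= s * ux; F[i1 + 1] -= s * uy; F[i1 + 2] -= s * uz;
        }
      }
      if (p.k_bend > 0) {
        for (int j = 1; j + 1 < n_nodes; ++j) {
          const int im = 3 * (off + j - 1), ic = 3 * (off + j),
                    ip = 3 * (off + j + 1);
          for (int k = 0; k < 3; ++k) {
            const double v = X[ic + k] - 0.5 * (X[im + k] + X[ip + k]);
            F[ic + k] -= p.k_bend * v;
            F[im + k] += 0.5 * p.k_bend * v;
            F[ip + k] += 0.5 * p.k_bend * v;
          }
        }
      }
    }
    if (p.k_confine > 0) {
      const double R = p.nucleus_radius;
      for (int i = 0; i < N; ++i) {
        const double x = X[3 * i], y = X[3 * i + 1], z = X[3 * i + 2];
        const double r = std::sqrt(x * x + y * y + z * z);
        if (r > R) {
          const double s = p.k_confine * (r - R) / r;
          F[3 * i] -= s * x; F[3 * i + 1] -= s * y; F[3 * i + 2] -= s * z;
        }
      }
    }
    for (int r = 0; r < bond_rows.nrow(); ++r) {
      const int ia = 3 * bond_rows(r, 0), ib = 3 * bond_rows(r, 1);
      for (int k = 0; k < 3; ++k) {
        const double d = X[ia + k] - X[ib + k];
        F[ia + k] -= p.k_pair * d;
        F[ib + k] += p.k_pair * d;
      }
    }
    fmax = 0;
    for (int i = 0; i < 3 * N; ++i) fmax = std::max(fmax, std::fabs(F[i]));
    if (fmax < tol) break;
    for (int i = 0; i < 3 * N; ++i) X[i] += step_size * F[i];
  }

  NumericMatrix P(N, 3);
  for (int i = 0; i < N; ++i)
    for (int k = 0; k < 3; ++k) P(i, k) = X[3 * i + k];
  return List::create(_["positions"] = P, _["fmax"] = fmax,
                      _["iterations"] = it);
}
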