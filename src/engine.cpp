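// Metropolis Monte Carlo / REST replica exchange / double-wide FEP core.
//
// The engine advances n_replicas walkers of the same system under
// REST2-scaled Hamiltonians E_m = r*e_ss + sqrt(r)*e_sw + e_ww (r the
// inverse effective-temperature ratio), attempting neighbor swaps on an
// alternating even/odd schedule, and records the ladder-position-0
// (physical) ensemble together with double-wide perturbation energies to
// the neighboring lambda windows.  All randomness comes from per-replica
// xoshiro256++ streams seeded from the user seed, so runs are exactly
// reproducible.

#include <Rcpp.h>
#include <cstdint>
#include <cmath>
#include <vector>

using namespace Rcpp;

// ---- RNG: splitmix64-seeded xoshiro256++ ----
static inline uint64_t splitmix64(uint64_t &x) {
  uint64_t z = (x += 0x9E3779B97F4A7C15ULL);
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}

struct Xoshiro {
  uint64_t s[4];
  void seed(uint64_t seed, uint64_t stream) {
    uint64_t x = seed ^ (0xA3C59AC2ULL * (stream + 1));
    for (int i = 0; i < 4; i++) s[i] = splitmix64(x);
  }
  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }
  uint64_t next() {
    uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3]; s[2] ^= t;
    s[3] = rotl(s[3], 45);
    return result;
  }
  double unif() { return (next() >> 11) * 0x1.0p-53; }
};

// ---- geometry ----
static inline void cross3(const double *a, const double *b, double *o) {
  o[0] = a[1] * b[2] - a[2] * b[1];
  o[1] = a[2] * b[0] - a[0] * b[2];
  o[2] = a[0] * b[1] - a[1] * b[0];
}

// dihedral in degrees on [0, 360)
static double dihedral(const double *p1, const double *p2, const double *p3,
                       const double *p4) {
  double b1[3], b2[3], b3[3], n1[3], n2[3], m1[3], b2n[3];
  for (int k = 0; k < 3; k++) {
    b1[k] = p2[k] - p1[k]; b2[k] = p3[k] - p2[k]; b3[k] = p4[k] - p3[k];
  }
  cross3(b1, b2, n1); cross3(b2, b3, n2);
  double nb2 = std::sqrt(b2[0] * b2[0] + b2[1] * b2[1] + b2[2] * b2[2]);
  for (int k = 0; k < 3; k++) b2n[k] = b2[k] / nb2;
  cross3(n1, b2n, m1);
  double x = n1[0] * n2[0] + n1[1] * n2[1] + n1[2] * n2[2];
  double y = m1[0] * n2[0] + m1[1] * n2[1] + m1[2] * n2[2];
  double ang = std::atan2(y, x) * 180.0 / M_PI;
  ang -= 360.0 * std::floor(ang / 360.0);   // wrap to [0, 360)
  if (ang >= 360.0) ang = 0.0;
  return ang;
}

// rotate point p about unit axis u through c by angle rad (Rodrigues)
static inline void rotate_point(double *p, const double *c, const double *u,
                                double ct, double st) {
  double v[3] = {p[0] - c[0], p[1] - c[1], p[2] - c[2]};
  double uv[3];
  cross3(u, v, uv);
  double udv = u[0] * v[0] + u[1] * v[1] + u[2] * v[2];
  for (int k = 0; k < 3; k++)
    p[k] = c[k] + v[k] * ct + uv[k] * st + u[k] * udv * (1.0 - ct);
}

// ---- energy ----
struct PairP { double qq, e1, s1, g1, e2, s2, g2; };

static inline double pair_energy(const PairP &p, double r2) {
  double r = std::sqrt(r2);
  double e = p.qq / r;
  double r6 = r2 * r2 * r2;
  if (p.e1 != 0.0) {
    double x = p.s1 + r6 / p.g1;
    e += p.e1 * (1.0 / (x * x) - 1.0 / x);
  }
  if (p.e2 != 0.0) {
    double x = p.s2 + r6 / p.g2;
    e += p.e2 * (1.0 / (x * x) - 1.0 / x);
  }
  return e;
}

static inline double torsion_e(double ang_deg, const double *V) {
  double th = ang_deg * M_PI / 180.0;
  return V[0] / 2.0 * (1.0 + std::cos(th)) +
         V[1] / 2.0 * (1.0 - std::cos(2.0 * th)) +
         V[2] / 2.0 * (1.0 + std::cos(3.0 * th));
}

static const double KB = 0.0019872;

struct Engine {
  int n;                       // atoms
  int npair, ntor, nmove, nrep;
  std::vector<int> pi_, pj_, pclass_;
  std::vector<PairP> Pcur, Pprev, Pnext;
  bool has_prev = false, has_next = false;
  std::vector<int> ta, tb, tc, td, tclass_;
  std::vector<std::vector<int>> tmove;
  std::vector<double> Vcur, Vprev, Vnext;  // ntor*3
  std::vector<int> alch_pairs, alch_tors;
  // moves
  std::vector<int> mkind, mtor;
  std::vector<std::vector<int>> matoms;
  std::vector<double> mmax, mcumw;
  std::vector<std::vector<int>> maff_pairs, maff_tors;
  double flip_prob;
  // replicas
  std::vector<std::vector<double>> pos;     // nrep x 3n
  std::vector<double> ess, esw, eww;
  std::vector<double> rlad, sqr;
  std::vector<int> walker;
  std::vector<Xoshiro> rng;
  Xoshiro swap_rng;
  double beta;

  double dist2(const std::vector<double> &x, int i, int j) const {
    double dx = x[3 * i] - x[3 * j], dy = x[3 * i + 1] - x[3 * j + 1],
           dz = x[3 * i + 2] - x[3 * j + 2];
    return dx * dx + dy * dy + dz * dz;
  }

  void full_energy(const std::vector<double> &x, double out[3]) const {
    out[0] = out[1] = out[2] = 0.0;
    for (int p = 0; p < npair; p++) {
      double r2 = dist2(x, pi_[p], pj_[p]);
      if (r2 <= 0.0) stop("overlapping particles: separation must be positive");
      out[pclass_[p]] += pair_energy(Pcur[p], r2);
    }
    for (int t = 0; t < ntor; t++) {
      double ang = dihedral(&x[3 * ta[t]], &x[3 * tb[t]], &x[3 * tc[t]],
                            &x[3 * td[t]]);
      out[tclass_[t]] += torsion_e(ang, &Vcur[3 * t]);
    }
  }

  // energy of the affected terms of move m in configuration x
  void affected_energy(const std::vector<double> &x, int m,
                       double out[3]) const {
    out[0] = out[1] = out[2] = 0.0;
    for (int k : maff_pairs[m]) {
      double r2 = dist2(x, pi_[k], pj_[k]);
      if (r2 <= 0.0) stop("overlapping particles: separation must be positive");
      out[pclass_[k]] += pair_energy(Pcur[k], r2);
    }
    for (int t : maff_tors[m]) {
      double ang = dihedral(&x[3 * ta[t]], &x[3 * tb[t]], &x[3 * tc[t]],
                            &x[3 * td[t]]);
      out[tclass_[t]] += torsion_e(ang, &Vcur[3 * t]);
    }
  }

  // perturbation energy to a neighboring lambda state over the
  // alchemical subset
  double dwide(const std::vector<double> &x,
               const std::vector<PairP> &P2,
               const std::vector<double> &V2) const {
    double de = 0.0;
    for (int k : alch_pairs) {
      double r2 = dist2(x, pi_[k], pj_[k]);
      de += pair_energy(P2[k], r2) - pair_energy(Pcur[k], r2);
    }
    for (int t : alch_tors) {
      double ang = dihedral(&x[3 * ta[t]], &x[3 * tb[t]], &x[3 * tc[t]],
                            &x[3 * td[t]]);
      de += torsion_e(ang, &V2[3 * t]) - torsion_e(ang, &Vcur[3 * t]);
    }
    return de;
  }
};

static std::vector<PairP> as_pairs(const NumericMatrix &P) {
  std::vector<PairP> v(P.nrow());
  for (int i = 0; i < P.nrow(); i++)
    v[i] = {P(i, 0), P(i, 1), P(i, 2), P(i, 3), P(i, 4), P(i, 5), P(i, 6)};
  return v;
}

// [[Rcpp::export]]
List engine_run(NumericMatrix pos0,
                IntegerVector pair_i, IntegerVector pair_j,
                IntegerVector pair_class,
                NumericMatrix P_cur,
                Nullable<NumericMatrix> P_prev, Nullable<NumericMatrix> P_next,
                IntegerMatrix tor_atoms, List tor_moving,
                IntegerVector tor_class,
                NumericMatrix V_cur,
                Nullable<NumericMatrix> V_prev, Nullable<NumericMatrix> V_next,
                IntegerVector alch_pairs, IntegerVector alch_tors,
                IntegerVector move_kind, List move_atoms,
                IntegerVector move_tor, NumericVector move_max,
                NumericVector move_weight, double flip_prob,
                NumericVector ladder_r, int swap_every,
                int n_steps, double temperature, double seed,
                int record_every, double equil_frac,
                bool record_positions, bool record_all) {
  Engine E;
  E.n = pos0.nrow();
  E.npair = pair_i.size();
  E.ntor = tor_atoms.nrow();
  E.nmove = move_kind.size();
  E.nrep = ladder_r.size();
  E.beta = 1.0 / (KB * temperature);
  E.flip_prob = flip_prob;

  E.pi_.assign(pair_i.begin(), pair_i.end());
  E.pj_.assign(pair_j.begin(), pair_j.end());
  E.pclass_.assign(pair_class.begin(), pair_class.end());
  E.Pcur = as_pairs(P_cur);
  if (P_prev.isNotNull()) { E.Pprev = as_pairs(P_prev.get()); E.has_prev = true; }
  if (P_next.isNotNull()) { E.Pnext = as_pairs(P_next.get()); E.has_next = true; }

  E.ta.resize(E.ntor); E.tb.resize(E.ntor); E.tc.resize(E.ntor);
  E.td.resize(E.ntor);
  for (int t = 0; t < E.ntor; t++) {
    E.ta[t] = tor_atoms(t, 0); E.tb[t] = tor_atoms(t, 1);
    E.tc[t] = tor_atoms(t, 2); E.td[t] = tor_atoms(t, 3);
  }
  E.tclass_.assign(tor_class.begin(), tor_class.end());
  E.tmove.resize(E.ntor);
  for (int t = 0; t < E.ntor; t++) {
    IntegerVector mv = tor_moving[t];
    E.tmove[t].assign(mv.begin(), mv.end());
  }
  auto flatV = [&](const NumericMatrix &V) {
    std::vector<double> out(E.ntor * 3);
    for (int t = 0; t < E.ntor; t++)
      for (int k = 0; k < 3; k++) out[3 * t + k] = V(t, k);
    return out;
  };
  E.Vcur = flatV(V_cur);
  if (V_prev.isNotNull()) E.Vprev = flatV(V_prev.get());
  if (V_next.isNotNull()) E.Vnext = flatV(V_next.get());
  E.alch_pairs.assign(alch_pairs.begin(), alch_pairs.end());
  E.alch_tors.assign(alch_tors.begin(), alch_tors.end());

  // moves and their affected term lists
  E.mkind.assign(move_kind.begin(), move_kind.end());
  E.mtor.assign(move_tor.begin(), move_tor.end());
  E.mmax.assign(move_max.begin(), move_max.end());
  E.matoms.resize(E.nmove);
  E.maff_pairs.resize(E.nmove);
  E.maff_tors.resize(E.nmove);
  double wsum = 0.0;
  for (int m = 0; m < E.nmove; m++) wsum += move_weight[m];
  E.mcumw.resize(E.nmove);
  double acc = 0.0;
  for (int m = 0; m < E.nmove; m++) {
    acc += move_weight[m] / wsum;
    E.mcumw[m] = acc;
    IntegerVector mv = move_atoms[m];
    E.matoms[m].assign(mv.begin(), mv.end());
    std::vector<char> in(E.n, 0);
    for (int a : E.matoms[m]) in[a] = 1;
    for (int p = 0; p < E.npair; p++)
      if (in[E.pi_[p]] != in[E.pj_[p]]) E.maff_pairs[m].push_back(p);
    for (int t = 0; t < E.ntor; t++) {
      int cnt = in[E.ta[t]] + in[E.tb[t]] + in[E.tc[t]] + in[E.td[t]];
      if (cnt > 0 && cnt < 4) E.maff_tors[m].push_back(t);
    }
  }

  // replicas
  E.pos.assign(E.nrep, std::vector<double>(3 * E.n));
  for (int r = 0; r < E.nrep; r++)
    for (int i = 0; i < E.n; i++)
      for (int k = 0; k < 3; k++) E.pos[r][3 * i + k] = pos0(i, k);
  E.ess.resize(E.nrep); E.esw.resize(E.nrep); E.eww.resize(E.nrep);
  E.rlad.assign(ladder_r.begin(), ladder_r.end());
  E.sqr.resize(E.nrep);
  for (int r = 0; r < E.nrep; r++) E.sqr[r] = std::sqrt(E.rlad[r]);
  E.walker.resize(E.nrep);
  for (int r = 0; r < E.nrep; r++) E.walker[r] = r;
  E.rng.resize(E.nrep);
  uint64_t sd = (uint64_t)seed;
  for (int r = 0; r < E.nrep; r++) E.rng[r].seed(sd, (uint64_t)r);
  E.swap_rng.seed(sd, (uint64_t)E.nrep + 7);
  for (int r = 0; r < E.nrep; r++) {
    double e[3];
    E.full_energy(E.pos[r], e);
    E.ess[r] = e[0]; E.esw[r] = e[1]; E.eww[r] = e[2];
  }

  // recording plan
  int equil = (int)std::floor(equil_frac * n_steps);
  int n_frames = 0;
  for (int s = 1; s <= n_steps; s++)
    if (s > equil && s % record_every == 0) n_frames++;
  NumericMatrix frames(n_frames, 1 + E.ntor + 4);
  NumericMatrix fpos(record_positions ? n_frames : 0,
                     record_positions ? 3 * E.n : 0);
  std::vector<NumericMatrix> rep_frames;
  if (record_all)
    for (int r = 0; r < E.nrep; r++)
      rep_frames.push_back(NumericMatrix(n_frames, 1 + E.ntor + 4));
  NumericVector de_prev(E.has_prev ? n_frames : 0);
  NumericVector de_next(E.has_next ? n_frames : 0);

  IntegerMatrix acc_attempt(E.nrep, E.nmove), acc_accept(E.nrep, E.nmove);
  int n_epochs = (swap_every > 0 && E.nrep > 1) ? n_steps / swap_every : 0;
  std::vector<double> swap_log;   // epoch, pair, delta, accepted
  IntegerMatrix perm(n_epochs, E.nrep);
  std::vector<int> last_acc(E.nrep, 0);

  int frame = 0, epoch = 0;
  std::vector<double> saved(3 * 16);

  for (int step = 1; step <= n_steps; step++) {
    for (int r = 0; r < E.nrep; r++) {
      Xoshiro &g = E.rng[r];
      // pick move
      double u = g.unif();
      int m = 0;
      while (m < E.nmove - 1 && u > E.mcumw[m]) m++;
      acc_attempt(r, m)++;
      const std::vector<int> &mats = E.matoms[m];
      std::vector<double> &x = E.pos[r];
      // save coordinates of moved atoms
      if (saved.size() < 3 * mats.size()) saved.resize(3 * mats.size());
      for (size_t a = 0; a < mats.size(); a++)
        for (int k = 0; k < 3; k++) saved[3 * a + k] = x[3 * mats[a] + k];
      double e_old[3], e_new[3];
      E.affected_energy(x, m, e_old);
      // propose
      int kind = E.mkind[m];
      if (kind == 0) {             // translate
        double dx[3];
        for (int k = 0; k < 3; k++) dx[k] = (2.0 * g.unif() - 1.0) * E.mmax[m];
        for (int a : mats)
          for (int k = 0; k < 3; k++) x[3 * a + k] += dx[k];
      } else if (kind == 1) {      // rigid rotation about the body centroid
        double ax[3], nrm;
        do {
          for (int k = 0; k < 3; k++) ax[k] = 2.0 * g.unif() - 1.0;
          nrm = ax[0] * ax[0] + ax[1] * ax[1] + ax[2] * ax[2];
        } while (nrm > 1.0 || nrm < 1e-12);
        nrm = std::sqrt(nrm);
        for (int k = 0; k < 3; k++) ax[k] /= nrm;
        double cen[3] = {0, 0, 0};
        for (int a : mats)
          for (int k = 0; k < 3; k++) cen[k] += x[3 * a + k];
        for (int k = 0; k < 3; k++) cen[k] /= (double)mats.size();
        double ang = (2.0 * g.unif() - 1.0) * E.mmax[m] * M_PI / 180.0;
        double ct = std::cos(ang), st = std::sin(ang);
        for (int a : mats) rotate_point(&x[3 * a], cen, ax, ct, st);
      } else {                     // torsion perturbation or flip
        int t = E.mtor[m];
        double delta;
        double uf = g.unif();
        if (uf < E.flip_prob) {
          double uc = g.unif();
          delta = (uc < 1.0 / 3.0) ? 120.0 : (uc < 2.0 / 3.0) ? -120.0 : 180.0;
        } else {
          delta = (2.0 * g.unif() - 1.0) * E.mmax[m];
        }
        double *b = &x[3 * E.tb[t]], *c = &x[3 * E.tc[t]];
        double ax[3] = {c[0] - b[0], c[1] - b[1], c[2] - b[2]};
        double nrm = std::sqrt(ax[0] * ax[0] + ax[1] * ax[1] + ax[2] * ax[2]);
        for (int k = 0; k < 3; k++) ax[k] /= nrm;
        double rad = delta * M_PI / 180.0;
        double ct = std::cos(rad), st = std::sin(rad);
        for (int a : E.tmove[t]) rotate_point(&x[3 * a], b, ax, ct, st);
      }
      E.affected_energy(x, m, e_new);
      double dss = e_new[0] - e_old[0], dsw = e_new[1] - e_old[1],
             dww = e_new[2] - e_old[2];
      double de = E.rlad[r] * dss + E.sqr[r] * dsw + dww;
      bool ok = de <= 0.0 || g.unif() < std::exp(-E.beta * de);
      if (ok) {
        E.ess[r] += dss; E.esw[r] += dsw; E.eww[r] += dww;
        acc_accept(r, m)++;
        last_acc[r] = 1;
      } else {
        for (size_t a = 0; a < mats.size(); a++)
          for (int k = 0; k < 3; k++) x[3 * mats[a] + k] = saved[3 * a + k];
        last_acc[r] = 0;
      }
    }

    // neighbor swaps on alternating even/odd pairs
    if (swap_every > 0 && E.nrep > 1 && step % swap_every == 0) {
      epoch++;
      int start = (epoch % 2 == 1) ? 0 : 1;
      for (int mrep = start; mrep + 1 < E.nrep; mrep += 2) {
        int nrep2 = mrep + 1;
        double delta = E.beta *
          ((E.rlad[mrep] - E.rlad[nrep2]) * (E.ess[nrep2] - E.ess[mrep]) +
           (E.sqr[mrep] - E.sqr[nrep2]) * (E.esw[nrep2] - E.esw[mrep]));
        bool ok = delta <= 0.0 || E.swap_rng.unif() < std::exp(-delta);
        if (ok) {
          std::swap(E.pos[mrep], E.pos[nrep2]);
          std::swap(E.ess[mrep], E.ess[nrep2]);
          std::swap(E.esw[mrep], E.esw[nrep2]);
          std::swap(E.eww[mrep], E.eww[nrep2]);
          std::swap(E.walker[mrep], E.walker[nrep2]);
        }
        swap_log.push_back((double)epoch);
        swap_log.push_back((double)(mrep + 1));  // 1-based pair label
        swap_log.push_back(delta);
        swap_log.push_back(ok ? 1.0 : 0.0);
      }
      for (int r = 0; r < E.nrep; r++) perm(epoch - 1, r) = E.walker[r] + 1;
    }

    if (step > equil && step % record_every == 0) {
      auto fill = [&](NumericMatrix &F, int r) {
        F(frame, 0) = step;
        for (int t = 0; t < E.ntor; t++)
          F(frame, 1 + t) = dihedral(&E.pos[r][3 * E.ta[t]],
                                     &E.pos[r][3 * E.tb[t]],
                                     &E.pos[r][3 * E.tc[t]],
                                     &E.pos[r][3 * E.td[t]]);
        F(frame, 1 + E.ntor) = E.ess[r];
        F(frame, 2 + E.ntor) = E.esw[r];
        F(frame, 3 + E.ntor) = E.eww[r];
        F(frame, 4 + E.ntor) = last_acc[r];
      };
      fill(frames, 0);
      if (record_all)
        for (int r = 0; r < E.nrep; r++) fill(rep_frames[r], r);
      if (record_positions)
        for (int i = 0; i < 3 * E.n; i++) fpos(frame, i) = E.pos[0][i];
      if (E.has_prev) de_prev[frame] = E.dwide(E.pos[0], E.Pprev, E.Vprev);
      if (E.has_next) de_next[frame] = E.dwide(E.pos[0], E.Pnext, E.Vnext);
      frame++;
    }
  }

  NumericMatrix slog(swap_log.size() / 4, 4);
  for (size_t i = 0; i < swap_log.size() / 4; i++)
    for (int k = 0; k < 4; k++) slog(i, k) = swap_log[4 * i + k];
  colnames(slog) = CharacterVector::create("epoch", "pair", "delta",
                                           "accepted");

  NumericMatrix final_pos(E.n, 3);
  for (int i = 0; i < E.n; i++)
    for (int k = 0; k < 3; k++) final_pos(i, k) = E.pos[0][3 * i + k];

  List out = List::create(
    _["frames"] = frames,
    _["positions"] = record_positions ? (SEXP)fpos : R_NilValue,
    _["de_prev"] = E.has_prev ? (SEXP)de_prev : R_NilValue,
    _["de_next"] = E.has_next ? (SEXP)de_next : R_NilValue,
    _["attempts"] = acc_attempt,
    _["accepts"] = acc_accept,
    _["swap_log"] = slog,
    _["permutation"] = perm,
    _["final_positions"] = final_pos,
    _["replica_frames"] = record_all ? (SEXP)wrap(rep_frames) : R_NilValue);
  return out;
}
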