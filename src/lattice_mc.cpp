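// Cubic-lattice model of seeded amyloid fibril elongation.
//
// Each residue occupies one lattice site and carries a side-chain direction
// (one of the six axis directions) and a beta-strand flag.  The Hamiltonian is
//   H = E_hb + E_steric + E_state + E_aa + Phi_solvent(T)
// where only the solvation term depends on temperature, through the
// hydrophobic free energy F_hydr = -alpha * (T - T0)^2 per solvent-exposed
// hydrophobic side chain.  All energies are in reduced (k_B T) units.
//
// The sampler is a single-threaded Metropolis Monte Carlo with optional
// parallel tempering; full-energy re-evaluation is used for every move (the
// systems are tiny, ~70 residues), which keeps the bookkeeping exact.

#include <Rcpp.h>
#include <cstdint>
#include <vector>
#include <map>
#include <array>
#include <cmath>

using namespace Rcpp;

static const int DX[6] = {1, -1, 0, 0, 0, 0};
static const int DY[6] = {0, 0, 1, -1, 0, 0};
static const int DZ[6] = {0, 0, 0, 0, 1, -1};
static inline int dir_axis(int d) { return d / 2; }

// ---------------------------------------------------------------------------
// deterministic RNG (PCG32), independent of R's RNG
struct Pcg32 {
  uint64_t state, inc;
  Pcg32(uint64_t s = 42u, uint64_t seq = 54u) {
    state = 0u;
    inc = (seq << 1u) | 1u;
    next();
    state += s;
    next();
  }
  uint32_t next() {
    uint64_t old = state;
    state = old * 6364136223846793005ULL + inc;
    uint32_t xs = (uint32_t)(((old >> 18u) ^ old) >> 27u);
    uint32_t rot = (uint32_t)(old >> 59u);
    return (xs >> rot) | (xs << ((32u - rot) & 31u));
  }
  double unif() { return (next() + 0.5) * 2.3283064365386963e-10; }
  int below(int n) { return (int)(((uint64_t)next() * (uint64_t)n) >> 32); }
};

// ---------------------------------------------------------------------------
struct Model {
  std::vector<double> pair;  // 20 x 20, row-major
  std::vector<double> solv;  // 20
  double eps_hb, ln_nbeta, steric_pen, alpha, t0;
  bool hydrophobic(int a) const { return solv[a] > 0.0; }
};

struct Sys {
  int box, n, nch, clen;
  std::vector<int> x, y, z;     // per residue
  std::vector<int> dir;         // 0..5
  std::vector<char> beta;       // 0/1
  std::vector<int> chain;       // 0-based chain id per residue
  std::vector<int> resi;        // residue index within chain
  std::vector<int> aa;          // 0..19
  std::vector<char> chain_frozen;  // per chain
  std::vector<int> occ;         // box^3, residue id + 1 or 0

  inline bool inside(int px, int py, int pz) const {
    return px >= 0 && px < box && py >= 0 && py < box && pz >= 0 && pz < box;
  }
  inline int lin(int px, int py, int pz) const {
    return (pz * box + py) * box + px;
  }
  inline bool frozen_res(int r) const { return chain_frozen[chain[r]] != 0; }

  void rebuild_occ() {
    std::fill(occ.begin(), occ.end(), 0);
    for (int r = 0; r < n; ++r) occ[lin(x[r], y[r], z[r])] = r + 1;
  }
};

static Sys make_sys(const IntegerMatrix& pos, const IntegerVector& dir,
                    const LogicalVector& beta, const IntegerVector& chain,
                    const LogicalVector& frozen, const IntegerVector& aa,
                    int box) {
  Sys S;
  S.box = box;
  S.n = pos.nrow();
  S.nch = frozen.size();
  S.x.resize(S.n); S.y.resize(S.n); S.z.resize(S.n);
  S.dir.resize(S.n); S.beta.resize(S.n);
  S.chain.resize(S.n); S.resi.resize(S.n); S.aa.resize(S.n);
  S.chain_frozen.resize(S.nch);
  std::vector<int> cnt(S.nch, 0);
  for (int c = 0; c < S.nch; ++c) S.chain_frozen[c] = frozen[c] ? 1 : 0;
  for (int r = 0; r < S.n; ++r) {
    S.x[r] = pos(r, 0); S.y[r] = pos(r, 1); S.z[r] = pos(r, 2);
    S.dir[r] = dir[r];
    S.beta[r] = beta[r] ? 1 : 0;
    S.chain[r] = chain[r];
    S.resi[r] = cnt[chain[r]]++;
    S.aa[r] = aa[r];
  }
  S.clen = cnt[0];
  S.occ.assign((size_t)box * box * box, 0);
  for (int r = 0; r < S.n; ++r) {
    if (!S.inside(S.x[r], S.y[r], S.z[r]))
      stop("residue outside the simulation box");
    int l = S.lin(S.x[r], S.y[r], S.z[r]);
    if (S.occ[l] != 0) stop("two residues share a lattice site");
    S.occ[l] = r + 1;
  }
  return S;
}

static Model make_model(const NumericMatrix& pairE, const NumericVector& solv,
                        double eps_hb, double ln_nbeta, double steric_pen,
                        double alpha, double t0) {
  Model M;
  M.pair.resize(400);
  for (int i = 0; i < 20; ++i)
    for (int j = 0; j < 20; ++j) M.pair[i * 20 + j] = pairE(i, j);
  M.solv.assign(solv.begin(), solv.end());
  M.eps_hb = eps_hb; M.ln_nbeta = ln_nbeta; M.steric_pen = steric_pen;
  M.alpha = alpha; M.t0 = t0;
  return M;
}

// ---------------------------------------------------------------------------
// energy components; H(T) = e4 + s1 - alpha * (T - t0)^2 * ch
struct Ecomp {
  double ehb = 0, esteric = 0, estate = 0, eaa = 0, s1 = 0;
  int ch = 0;
  double e4() const { return ehb + esteric + estate + eaa; }
  double H(const Model& M, double T) const {
    double dt = T - M.t0;
    return e4() + s1 - M.alpha * dt * dt * (double)ch;
  }
  // enthalpy estimator d(beta H)/d(beta): the quadratic hydrophobic free
  // energy contributes -alpha*(T0^2 - T^2) per exposed hydrophobic contact
  double Eest(const Model& M, double T) const {
    return e4() + s1 - M.alpha * (M.t0 * M.t0 - T * T) * (double)ch;
  }
};

static void extended_flags(const Sys& S, std::vector<char>& ext) {
  // a residue can take part in hydrogen bonding only when its local
  // backbone is extended (interior residues collinear with both
  // neighbours; chain ends are unconstrained)
  ext.assign(S.n, 1);
  for (int r = 0; r < S.n; ++r) {
    if (S.resi[r] == 0 || S.resi[r] == S.clen - 1) continue;
    int b1x = S.x[r] - S.x[r - 1], b1y = S.y[r] - S.y[r - 1],
        b1z = S.z[r] - S.z[r - 1];
    int b2x = S.x[r + 1] - S.x[r], b2y = S.y[r + 1] - S.y[r],
        b2z = S.z[r + 1] - S.z[r];
    if (b1x != b2x || b1y != b2y || b1z != b2z) ext[r] = 0;
  }
}

static Ecomp full_energy(const Sys& S, const Model& M,
                         std::vector<int>& scratch_targets,
                         std::vector<char>& ext) {
  Ecomp e;
  extended_flags(S, ext);
  scratch_targets.clear();
  const int pair_dirs[3] = {0, 2, 4};  // +x, +y, +z: each pair counted once
  for (int r = 0; r < S.n; ++r) {
    int px = S.x[r], py = S.y[r], pz = S.z[r];
    for (int k = 0; k < 3; ++k) {
      int d = pair_dirs[k];
      int qx = px + DX[d], qy = py + DY[d], qz = pz + DZ[d];
      if (!S.inside(qx, qy, qz)) continue;
      int o = S.occ[S.lin(qx, qy, qz)];
      if (!o) continue;
      int r2 = o - 1;
      bool same_chain = (S.chain[r] == S.chain[r2]);
      if (same_chain && std::abs(S.resi[r] - S.resi[r2]) <= 1) continue;
      // side-chain-directed pair interaction: the two side chains must
      // point at each other across the contact
      if (S.dir[r] == d && S.dir[r2] == d + 1)
        e.eaa += M.pair[S.aa[r] * 20 + S.aa[r2]];
    }
    // hydrogen bonds: neighbour on a different chain, both in the beta
    // state, side chains parallel and perpendicular to the separation.
    // Bonds saturate: a residue donates at most two hydrogen bonds (one to
    // the strand on each side of it in a sheet),
    // E_hb = (eps_hb / 2) * sum_i min(2, n_i) with n_i the number of
    // eligible partners; an isolated in-register strand pair thus counts
    // one full bond per residue pair.
    if (S.beta[r] && ext[r]) {
      int nhb = 0;
      for (int d = 0; d < 6 && nhb < 2; ++d) {
        int qx = px + DX[d], qy = py + DY[d], qz = pz + DZ[d];
        if (!S.inside(qx, qy, qz)) continue;
        int o = S.occ[S.lin(qx, qy, qz)];
        if (!o) continue;
        int r2 = o - 1;
        if (S.chain[r2] != S.chain[r] && S.beta[r2] && ext[r2] &&
            S.dir[r] == S.dir[r2] && dir_axis(S.dir[r]) != dir_axis(d))
          ++nhb;
      }
      e.ehb += 0.5 * M.eps_hb * (nhb < 2 ? nhb : 2);
    }
    if (S.beta[r]) e.estate += M.ln_nbeta;
    int d = S.dir[r];
    int tx = px + DX[d], ty = py + DY[d], tz = pz + DZ[d];
    bool tin = S.inside(tx, ty, tz);
    int to = tin ? S.occ[S.lin(tx, ty, tz)] : 0;
    // only residues of another molecule shield a side chain from solvent;
    // a short chain cannot bury its own side chains against its backbone
    bool exposed = !tin || to == 0 || S.chain[to - 1] == S.chain[r];
    if (exposed) {
      e.s1 += M.solv[S.aa[r]];
      if (M.hydrophobic(S.aa[r])) e.ch += 1;
    }
    if (tin) scratch_targets.push_back(S.lin(tx, ty, tz));
  }
  // steric clash: two side chains pointing at the same (empty or not) site
  std::sort(scratch_targets.begin(), scratch_targets.end());
  size_t i = 0;
  while (i < scratch_targets.size()) {
    size_t j = i;
    while (j < scratch_targets.size() &&
           scratch_targets[j] == scratch_targets[i]) ++j;
    size_t k = j - i;
    if (k > 1) e.esteric += M.steric_pen * (double)(k * (k - 1) / 2);
    i = j;
  }
  return e;
}

struct Ops { int cext = 0, native = 0, ch_free = 0; };

static Ops order_params(const Sys& S, const Model& M) {
  Ops o;
  for (int r = 0; r < S.n; ++r) {
    if (S.frozen_res(r)) continue;
    int px = S.x[r], py = S.y[r], pz = S.z[r];
    for (int d = 0; d < 6; ++d) {
      int qx = px + DX[d], qy = py + DY[d], qz = pz + DZ[d];
      if (!S.inside(qx, qy, qz)) continue;
      int oo = S.occ[S.lin(qx, qy, qz)];
      if (!oo) continue;
      int r2 = oo - 1;
      if (S.chain[r2] == S.chain[r]) continue;
      bool count = S.frozen_res(r2) || r2 > r;  // count each pair once
      if (!count) continue;
      o.cext += 1;
      if (S.resi[r] == S.resi[r2]) o.native += 1;  // in-register contact
    }
    int d = S.dir[r];
    int tx = px + DX[d], ty = py + DY[d], tz = pz + DZ[d];
    bool tin = S.inside(tx, ty, tz);
    int to = tin ? S.occ[S.lin(tx, ty, tz)] : 0;
    bool exposed = !tin || to == 0 || S.chain[to - 1] == S.chain[r];
    if (exposed && M.hydrophobic(S.aa[r])) o.ch_free += 1;
  }
  return o;
}

// ---------------------------------------------------------------------------
// rotations about a lattice axis (0=x, 1=y, 2=z) by k quarter turns
static inline void rot_vec(int axis, int k, int& vx, int& vy, int& vz) {
  for (int i = 0; i < k; ++i) {
    int nx = vx, ny = vy, nz = vz;
    if (axis == 0)      { ny = -vz; nz = vy; }
    else if (axis == 1) { nx = vz;  nz = -vx; }
    else                { nx = -vy; ny = vx; }
    vx = nx; vy = ny; vz = nz;
  }
}

static inline int rot_dir(int axis, int k, int d) {
  int vx = DX[d], vy = DY[d], vz = DZ[d];
  rot_vec(axis, k, vx, vy, vz);
  for (int j = 0; j < 6; ++j)
    if (DX[j] == vx && DY[j] == vy && DZ[j] == vz) return j;
  return d;  // unreachable
}

// ---------------------------------------------------------------------------
// move machinery: apply tentatively with undo information
struct Undo {
  std::vector<int> res;            // residue ids, in application order
  std::vector<std::array<int, 4>> old_state;  // x,y,z,dir
  std::vector<char> old_beta;
};

// remove the residues in `rs` from occ, try to place at the new coordinates,
// rolling everything back if any position is outside the box or occupied
static bool try_reposition(Sys& S, const std::vector<int>& rs,
                           const std::vector<std::array<int, 3>>& newpos,
                           const std::vector<int>& newdir, Undo& U) {
  U.res = rs;
  U.old_state.resize(rs.size());
  U.old_beta.clear();
  for (size_t i = 0; i < rs.size(); ++i) {
    int r = rs[i];
    U.old_state[i] = {S.x[r], S.y[r], S.z[r], S.dir[r]};
    S.occ[S.lin(S.x[r], S.y[r], S.z[r])] = 0;
  }
  bool ok = true;
  size_t placed = 0;
  for (size_t i = 0; i < rs.size(); ++i) {
    int r = rs[i];
    int nx = newpos[i][0], ny = newpos[i][1], nz = newpos[i][2];
    if (!S.inside(nx, ny, nz) || S.occ[S.lin(nx, ny, nz)] != 0) {
      ok = false;
      break;
    }
    S.x[r] = nx; S.y[r] = ny; S.z[r] = nz;
    S.dir[r] = newdir[i];
    S.occ[S.lin(nx, ny, nz)] = r + 1;
    ++placed;
  }
  if (!ok) {
    for (size_t i = 0; i < placed; ++i) {
      int r = rs[i];
      S.occ[S.lin(S.x[r], S.y[r], S.z[r])] = 0;
    }
    for (size_t i = 0; i < rs.size(); ++i) {
      int r = rs[i];
      S.x[r] = U.old_state[i][0];
      S.y[r] = U.old_state[i][1];
      S.z[r] = U.old_state[i][2];
      S.dir[r] = U.old_state[i][3];
      S.occ[S.lin(S.x[r], S.y[r], S.z[r])] = r + 1;
    }
  }
  return ok;
}

static void undo_reposition(Sys& S, const Undo& U) {
  for (size_t i = 0; i < U.res.size(); ++i) {
    int r = U.res[i];
    S.occ[S.lin(S.x[r], S.y[r], S.z[r])] = 0;
  }
  for (size_t i = 0; i < U.res.size(); ++i) {
    int r = U.res[i];
    S.x[r] = U.old_state[i][0];
    S.y[r] = U.old_state[i][1];
    S.z[r] = U.old_state[i][2];
    S.dir[r] = U.old_state[i][3];
    S.occ[S.lin(S.x[r], S.y[r], S.z[r])] = r + 1;
  }
}

enum MoveType {
  MV_END = 0, MV_CORNER, MV_CRANK, MV_SIDE, MV_BETA,
  MV_TRANS, MV_JUMP, MV_ROT, MV_SEED_TRANS, MV_SEED_ROT, MV_N
};

struct MoveResult {
  bool valid = false;
  bool beta_move = false;
  int beta_res = -1;
  Undo undo;
};

static int pick_free_chain(const Sys& S, Pcg32& rng,
                           const std::vector<int>& free_chains) {
  return free_chains[rng.below((int)free_chains.size())];
}

static void chain_residues(const Sys& S, int c, std::vector<int>& rs) {
  rs.clear();
  for (int r = 0; r < S.n; ++r)
    if (S.chain[r] == c) rs.push_back(r);
}

static MoveResult propose_move(Sys& S, Pcg32& rng, int type,
                               const std::vector<int>& free_chains) {
  MoveResult mr;
  std::vector<int> rs;
  std::vector<std::array<int, 3>> np;
  std::vector<int> nd;
  switch (type) {
    case MV_END: {
      int c = pick_free_chain(S, rng, free_chains);
      chain_residues(S, c, rs);
      int L = (int)rs.size();
      if (L < 2) return mr;
      bool head = rng.below(2) == 0;
      int r = head ? rs[0] : rs[L - 1];
      int anchor = head ? rs[1] : rs[L - 2];
      int d = rng.below(6);
      rs.assign(1, r);
      np.assign(1, {S.x[anchor] + DX[d], S.y[anchor] + DY[d],
                    S.z[anchor] + DZ[d]});
      nd.assign(1, S.dir[r]);
      break;
    }
    case MV_CORNER: {
      int c = pick_free_chain(S, rng, free_chains);
      chain_residues(S, c, rs);
      int L = (int)rs.size();
      if (L < 3) return mr;
      int i = 1 + rng.below(L - 2);
      int rp = rs[i - 1], r = rs[i], rn = rs[i + 1];
      int vx = S.x[rn] - S.x[rp], vy = S.y[rn] - S.y[rp], vz = S.z[rn] - S.z[rp];
      int nz_comp = (vx != 0) + (vy != 0) + (vz != 0);
      if (nz_comp != 2) return mr;  // straight segment: no corner to flip
      rs.assign(1, r);
      np.assign(1, {S.x[rp] + S.x[rn] - S.x[r], S.y[rp] + S.y[rn] - S.y[r],
                    S.z[rp] + S.z[rn] - S.z[r]});
      nd.assign(1, S.dir[r]);
      break;
    }
    case MV_CRANK: {
      int c = pick_free_chain(S, rng, free_chains);
      chain_residues(S, c, rs);
      int L = (int)rs.size();
      if (L < 4) return mr;
      int i = 1 + rng.below(L - 3);  // rotate residues i, i+1
      int ra = rs[i - 1], rb = rs[i + 2];
      int ax = S.x[rb] - S.x[ra], ay = S.y[rb] - S.y[ra], az = S.z[rb] - S.z[ra];
      if (std::abs(ax) + std::abs(ay) + std::abs(az) != 1) return mr;
      int axis = (ax != 0) ? 0 : (ay != 0) ? 1 : 2;
      int k = 1 + rng.below(3);
      int r1 = rs[i], r2 = rs[i + 1];
      rs.clear(); rs.push_back(r1); rs.push_back(r2);
      np.clear(); nd.clear();
      for (int r : rs) {
        int vx = S.x[r] - S.x[ra], vy = S.y[r] - S.y[ra], vz = S.z[r] - S.z[ra];
        rot_vec(axis, k, vx, vy, vz);
        np.push_back({S.x[ra] + vx, S.y[ra] + vy, S.z[ra] + vz});
        nd.push_back(rot_dir(axis, k, S.dir[r]));
      }
      break;
    }
    case MV_SIDE: {
      int c = pick_free_chain(S, rng, free_chains);
      chain_residues(S, c, rs);
      int r = rs[rng.below((int)rs.size())];
      int d = rng.below(6);
      mr.valid = true;
      mr.undo.res.assign(1, r);
      mr.undo.old_state.assign(1, {S.x[r], S.y[r], S.z[r], S.dir[r]});
      S.dir[r] = d;
      return mr;
    }
    case MV_BETA: {
      int c = pick_free_chain(S, rng, free_chains);
      chain_residues(S, c, rs);
      int r = rs[rng.below((int)rs.size())];
      mr.valid = true;
      mr.beta_move = true;
      mr.beta_res = r;
      S.beta[r] = S.beta[r] ? 0 : 1;
      return mr;
    }
    case MV_TRANS: case MV_JUMP: {
      int c = pick_free_chain(S, rng, free_chains);
      chain_residues(S, c, rs);
      int dx, dy, dz;
      if (type == MV_TRANS) {
        int d = rng.below(6);
        dx = DX[d]; dy = DY[d]; dz = DZ[d];
      } else {
        int hw = S.box / 2;
        dx = rng.below(2 * hw + 1) - hw;
        dy = rng.below(2 * hw + 1) - hw;
        dz = rng.below(2 * hw + 1) - hw;
      }
      np.clear(); nd.clear();
      if (type == MV_JUMP) {
        // jump with random orientation: axis and quarter turns chosen
        // uniformly (includes the identity), a symmetric proposal set
        int axis = rng.below(3), k = rng.below(4);
        int p = rs[0];
        int px = S.x[p], py = S.y[p], pz = S.z[p];
        for (int r : rs) {
          int vx = S.x[r] - px, vy = S.y[r] - py, vz = S.z[r] - pz;
          rot_vec(axis, k, vx, vy, vz);
          np.push_back({px + vx + dx, py + vy + dy, pz + vz + dz});
          nd.push_back(rot_dir(axis, k, S.dir[r]));
        }
      } else {
        for (int r : rs) {
          np.push_back({S.x[r] + dx, S.y[r] + dy, S.z[r] + dz});
          nd.push_back(S.dir[r]);
        }
      }
      break;
    }
    case MV_ROT: {
      int c = pick_free_chain(S, rng, free_chains);
      chain_residues(S, c, rs);
      int axis = rng.below(3), k = 1 + rng.below(3);
      int p = rs[0];
      int px = S.x[p], py = S.y[p], pz = S.z[p];
      np.clear(); nd.clear();
      for (int r : rs) {
        int vx = S.x[r] - px, vy = S.y[r] - py, vz = S.z[r] - pz;
        rot_vec(axis, k, vx, vy, vz);
        np.push_back({px + vx, py + vy, pz + vz});
        nd.push_back(rot_dir(axis, k, S.dir[r]));
      }
      break;
    }
    case MV_SEED_TRANS: case MV_SEED_ROT: {
      rs.clear();
      for (int r = 0; r < S.n; ++r)
        if (S.frozen_res(r)) rs.push_back(r);
      if (rs.empty()) return mr;
      np.clear(); nd.clear();
      if (type == MV_SEED_TRANS) {
        int d = rng.below(6);
        for (int r : rs) {
          np.push_back({S.x[r] + DX[d], S.y[r] + DY[d], S.z[r] + DZ[d]});
          nd.push_back(S.dir[r]);
        }
      } else {
        int axis = rng.below(3), k = 1 + rng.below(3);
        int p = rs[0];
        int px = S.x[p], py = S.y[p], pz = S.z[p];
        for (int r : rs) {
          int vx = S.x[r] - px, vy = S.y[r] - py, vz = S.z[r] - pz;
          rot_vec(axis, k, vx, vy, vz);
          np.push_back({px + vx, py + vy, pz + vz});
          nd.push_back(rot_dir(axis, k, S.dir[r]));
        }
      }
      break;
    }
    default: return mr;
  }
  mr.valid = try_reposition(S, rs, np, nd, mr.undo);
  return mr;
}

static void undo_move(Sys& S, const MoveResult& mr) {
  if (mr.beta_move) {
    S.beta[mr.beta_res] = S.beta[mr.beta_res] ? 0 : 1;
    return;
  }
  if (mr.undo.res.size() == 1 && mr.undo.old_state.size() == 1 &&
      S.x[mr.undo.res[0]] == mr.undo.old_state[0][0] &&
      S.y[mr.undo.res[0]] == mr.undo.old_state[0][1] &&
      S.z[mr.undo.res[0]] == mr.undo.old_state[0][2]) {
    // side-chain move: position unchanged, restore direction only
    S.dir[mr.undo.res[0]] = mr.undo.old_state[0][3];
    return;
  }
  undo_reposition(S, mr.undo);
}

// ---------------------------------------------------------------------------
// [[Rcpp::export]]
List cpp_energy(IntegerMatrix pos, IntegerVector dir, LogicalVector beta,
                IntegerVector chain, LogicalVector frozen, IntegerVector aa,
                int box, NumericMatrix pairE, NumericVector solv,
                double eps_hb, double ln_nbeta, double steric_pen,
                double alpha, double t0, NumericVector temps) {
  Sys S = make_sys(pos, dir, beta, chain, frozen, aa, box);
  Model M = make_model(pairE, solv, eps_hb, ln_nbeta, steric_pen, alpha, t0);
  std::vector<int> scratch;
  std::vector<char> ext;
  Ecomp e = full_energy(S, M, scratch, ext);
  int nt = temps.size();
  NumericVector H(nt), Eest(nt), phi(nt);
  for (int i = 0; i < nt; ++i) {
    H[i] = e.H(M, temps[i]);
    Eest[i] = e.Eest(M, temps[i]);
    phi[i] = H[i] - e.e4();
  }
  return List::create(
      _["e_hb"] = e.ehb, _["e_steric"] = e.esteric, _["e_state"] = e.estate,
      _["e_aa"] = e.eaa, _["solvent_const"] = e.s1, _["c_h_exposed_all"] = e.ch,
      _["phi_solvent"] = phi, _["total"] = H, _["e_est"] = Eest);
}

// [[Rcpp::export]]
List cpp_order_params(IntegerMatrix pos, IntegerVector dir, LogicalVector beta,
                      IntegerVector chain, LogicalVector frozen,
                      IntegerVector aa, int box, NumericVector solv) {
  Sys S = make_sys(pos, dir, beta, chain, frozen, aa, box);
  Model M;
  M.solv.assign(solv.begin(), solv.end());
  Ops o = order_params(S, M);
  return List::create(_["c_ext"] = o.cext, _["native_contacts"] = o.native,
                      _["c_h_exposed"] = o.ch_free);
}

// [[Rcpp::export]]
List cpp_run_mc(IntegerMatrix pos, IntegerVector dir, LogicalVector beta,
                IntegerVector chain, LogicalVector frozen, IntegerVector aa,
                int box, NumericMatrix pairE, NumericVector solv,
                double eps_hb, double ln_nbeta, double steric_pen,
                double alpha, double t0, NumericVector temps,
                int sweeps, int equil, int sample_interval, int pt_interval,
                NumericVector move_weights, double rng_seed,
                IntegerMatrix pos2, IntegerVector dir2, LogicalVector beta2,
                LogicalVector use_second, int restrict_mode,
                int fib_native_min, int mono_cext_max) {
  Sys S0 = make_sys(pos, dir, beta, chain, frozen, aa, box);
  Sys S1 = make_sys(pos2, dir2, beta2, chain, frozen, aa, box);
  Model M = make_model(pairE, solv, eps_hb, ln_nbeta, steric_pen, alpha, t0);
  int nT = temps.size();
  if (nT < 1) stop("need at least one temperature");
  for (int i = 0; i < nT; ++i)
    if (temps[i] <= 0) stop("temperatures must be positive");
  if (move_weights.size() != MV_N) stop("move_weights must have length 10");

  std::vector<int> free_chains;
  for (int c = 0; c < S0.nch; ++c)
    if (!frozen[c]) free_chains.push_back(c);
  if (free_chains.empty()) stop("system has no free chains");

  int n_free_res = 0;
  for (int r = 0; r < S0.n; ++r)
    if (!S0.frozen_res(r)) ++n_free_res;
  int moves_per_sweep = 3 * n_free_res + 4;

  // cumulative move weights
  double wsum = 0;
  for (int i = 0; i < MV_N; ++i) wsum += move_weights[i];
  std::vector<double> cw(MV_N);
  double acc = 0;
  for (int i = 0; i < MV_N; ++i) { acc += move_weights[i] / wsum; cw[i] = acc; }

  Pcg32 rng((uint64_t)rng_seed, 77u);

  if (use_second.size() != nT) stop("use_second must have one entry per temperature");
  std::vector<Sys> reps;
  reps.reserve(nT);
  for (int i = 0; i < nT; ++i) reps.push_back(use_second[i] ? S1 : S0);
  std::vector<Ecomp> cur(nT);
  std::vector<int> scratch;
  std::vector<char> ext;
  for (int i = 0; i < nT; ++i) cur[i] = full_energy(reps[i], M, scratch, ext);

  std::vector<long> attempts(MV_N, 0), accepts(MV_N, 0);
  long swap_att = 0, swap_acc = 0;

  int n_samples = (sweeps > equil)
      ? (sweeps - equil + sample_interval - 1) / sample_interval : 0;
  NumericMatrix samp(n_samples * nT, 12);
  CharacterVector cn = CharacterVector::create(
      "temperature", "sweep", "c_ext", "native_contacts", "c_h_exposed",
      "e_hb", "e_steric", "e_state", "e_aa", "solvent_const", "total",
      "e_est");
  colnames(samp) = cn;
  int row = 0;

  for (int sw = 0; sw < sweeps; ++sw) {
    for (int t = 0; t < nT; ++t) {
      double T = temps[t];
      Sys& S = reps[t];
      for (int m = 0; m < moves_per_sweep; ++m) {
        double u = rng.unif();
        int type = 0;
        while (type < MV_N - 1 && u > cw[type]) ++type;
        attempts[type]++;
        MoveResult mr = propose_move(S, rng, type, free_chains);
        if (!mr.valid) continue;  // rejected (steric/box/ineligible)
        // basin restraint: moves leaving the requested basin are rejected,
        // giving correct sampling of the conditional (restricted) ensemble
        if (restrict_mode != 0 && type != MV_SIDE && type != MV_BETA) {
          // side-chain and beta flips cannot change contact counts
          Ops o = order_params(S, M);
          bool ok = (restrict_mode == 1) ? (o.native >= fib_native_min)
                                         : (o.cext <= mono_cext_max);
          if (!ok) {
            undo_move(S, mr);
            continue;
          }
        }
        Ecomp cand = full_energy(S, M, scratch, ext);
        double dH = cand.H(M, T) - cur[t].H(M, T);
        if (dH <= 0 || rng.unif() < std::exp(-dH / T)) {
          cur[t] = cand;
          accepts[type]++;
        } else {
          undo_move(S, mr);
        }
      }
    }
    // parallel tempering: the Hamiltonian is temperature dependent, so the
    // exchange criterion evaluates each configuration under both temperatures
    if (pt_interval > 0 && nT > 1 && (sw + 1) % pt_interval == 0) {
      int parity = ((sw + 1) / pt_interval) % 2;
      for (int i = parity; i + 1 < nT; i += 2) {
        double Ti = temps[i], Tj = temps[i + 1];
        double delta = cur[i].H(M, Tj) / Tj + cur[i + 1].H(M, Ti) / Ti -
                       cur[i].H(M, Ti) / Ti - cur[i + 1].H(M, Tj) / Tj;
        swap_att++;
        if (delta <= 0 || rng.unif() < std::exp(-delta)) {
          std::swap(reps[i], reps[i + 1]);
          std::swap(cur[i], cur[i + 1]);
          swap_acc++;
        }
      }
    }
    if (sw >= equil && (sw - equil) % sample_interval == 0) {
      for (int t = 0; t < nT; ++t) {
        Ops o = order_params(reps[t], M);
        double T = temps[t];
        samp(row, 0) = T;
        samp(row, 1) = sw;
        samp(row, 2) = o.cext;
        samp(row, 3) = o.native;
        samp(row, 4) = o.ch_free;
        samp(row, 5) = cur[t].ehb;
        samp(row, 6) = cur[t].esteric;
        samp(row, 7) = cur[t].estate;
        samp(row, 8) = cur[t].eaa;
        samp(row, 9) = cur[t].s1;
        samp(row, 10) = cur[t].H(M, T);
        samp(row, 11) = cur[t].Eest(M, T);
        ++row;
      }
    }
  }

  // energy bookkeeping check: tracked components vs fresh recomputation
  double max_drift = 0;
  for (int t = 0; t < nT; ++t) {
    Ecomp fresh = full_energy(reps[t], M, scratch, ext);
    max_drift = std::max(max_drift,
                         std::abs(fresh.H(M, temps[t]) - cur[t].H(M, temps[t])));
  }

  List finals(nT);
  for (int t = 0; t < nT; ++t) {
    Sys& S = reps[t];
    IntegerMatrix fp(S.n, 3);
    IntegerVector fd(S.n);
    LogicalVector fb(S.n);
    for (int r = 0; r < S.n; ++r) {
      fp(r, 0) = S.x[r]; fp(r, 1) = S.y[r]; fp(r, 2) = S.z[r];
      fd[r] = S.dir[r]; fb[r] = S.beta[r] != 0;
    }
    finals[t] = List::create(_["pos"] = fp, _["dir"] = fd, _["beta"] = fb);
  }

  return List::create(
      _["samples"] = samp,
      _["move_attempts"] = IntegerVector(attempts.begin(), attempts.end()),
      _["move_accepts"] = IntegerVector(accepts.begin(), accepts.end()),
      _["swap_attempts"] = (double)swap_att,
      _["swap_accepts"] = (double)swap_acc,
      _["moves_per_sweep"] = moves_per_sweep,
      _["energy_drift"] = max_drift,
      _["final_states"] = finals);
}

// ---------------------------------------------------------------------------
// exhaustive enumeration of all configurations of a single free chain
// (self-avoiding walk x side-chain directions x beta flags) in the presence of
// the frozen chains; configurations are aggregated by their energy components
// and order parameters so that Boltzmann weights at any temperature can be
// formed afterwards.
struct EnumKey {
  long long v[8];
  bool operator<(const EnumKey& o) const {
    for (int i = 0; i < 8; ++i)
      if (v[i] != o.v[i]) return v[i] < o.v[i];
    return false;
  }
};

static void enum_recurse(Sys& S, const Model& M,
                         const std::vector<int>& rs, size_t i,
                         std::map<EnumKey, double>& agg,
                         std::vector<int>& scratch, std::vector<char>& ext) {
  if (i == rs.size()) {
    int L = (int)rs.size();
    long ndirs = 1;
    for (int q = 0; q < L; ++q) ndirs *= 6;
    long nbeta = 1L << L;
    for (long dcode = 0; dcode < ndirs; ++dcode) {
      long dd = dcode;
      for (int q = 0; q < L; ++q) { S.dir[rs[q]] = (int)(dd % 6); dd /= 6; }
      for (long bcode = 0; bcode < nbeta; ++bcode) {
        for (int q = 0; q < L; ++q) S.beta[rs[q]] = (bcode >> q) & 1;
        Ecomp e = full_energy(S, M, scratch, ext);
        Ops o = order_params(S, M);
        EnumKey k;
        k.v[0] = llround(e.ehb * 1e9);
        k.v[1] = llround(e.esteric * 1e9);
        k.v[2] = llround(e.estate * 1e9);
        k.v[3] = llround(e.eaa * 1e9);
        k.v[4] = llround(e.s1 * 1e9);
        k.v[5] = e.ch;
        k.v[6] = o.cext;
        k.v[7] = ((long long)o.native << 20) | (long long)o.ch_free;
        agg[k] += 1.0;
      }
    }
    return;
  }
  int r = rs[i];
  if (i == 0) {
    for (int px = 0; px < S.box; ++px)
      for (int py = 0; py < S.box; ++py)
        for (int pz = 0; pz < S.box; ++pz) {
          int l = S.lin(px, py, pz);
          if (S.occ[l]) continue;
          S.x[r] = px; S.y[r] = py; S.z[r] = pz;
          S.occ[l] = r + 1;
          enum_recurse(S, M, rs, i + 1, agg, scratch, ext);
          S.occ[l] = 0;
        }
  } else {
    int rp = rs[i - 1];
    for (int d = 0; d < 6; ++d) {
      int px = S.x[rp] + DX[d], py = S.y[rp] + DY[d], pz = S.z[rp] + DZ[d];
      if (!S.inside(px, py, pz)) continue;
      int l = S.lin(px, py, pz);
      if (S.occ[l]) continue;
      S.x[r] = px; S.y[r] = py; S.z[r] = pz;
      S.occ[l] = r + 1;
      enum_recurse(S, M, rs, i + 1, agg, scratch, ext);
      S.occ[l] = 0;
    }
  }
}

// [[Rcpp::export]]
DataFrame cpp_enumerate(IntegerMatrix pos, IntegerVector dir,
                        LogicalVector beta, IntegerVector chain,
                        LogicalVector frozen, IntegerVector aa, int box,
                        NumericMatrix pairE, NumericVector solv,
                        double eps_hb, double ln_nbeta, double steric_pen,
                        double alpha, double t0) {
  Sys S = make_sys(pos, dir, beta, chain, frozen, aa, box);
  Model M = make_model(pairE, solv, eps_hb, ln_nbeta, steric_pen, alpha, t0);
  std::vector<int> free_chains;
  for (int c = 0; c < S.nch; ++c)
    if (!S.chain_frozen[c]) free_chains.push_back(c);
  if (free_chains.size() != 1)
    stop("enumeration requires exactly one free chain");
  std::vector<int> rs;
  chain_residues(S, free_chains[0], rs);
  if (rs.size() > 4) stop("enumeration supports free chains of length <= 4");

  // clear the free chain out of the occupancy grid before enumerating
  for (int r : rs) S.occ[S.lin(S.x[r], S.y[r], S.z[r])] = 0;

  std::map<EnumKey, double> agg;
  std::vector<int> scratch;
  std::vector<char> ext;
  enum_recurse(S, M, rs, 0, agg, scratch, ext);

  int nrow = (int)agg.size();
  NumericVector ehb(nrow), est(nrow), estt(nrow), eaa(nrow), s1(nrow),
      cnt(nrow);
  IntegerVector ch(nrow), cext(nrow), native(nrow), chfree(nrow);
  int i = 0;
  for (auto& kv : agg) {
    ehb[i] = kv.first.v[0] / 1e9;
    est[i] = kv.first.v[1] / 1e9;
    estt[i] = kv.first.v[2] / 1e9;
    eaa[i] = kv.first.v[3] / 1e9;
    s1[i] = kv.first.v[4] / 1e9;
    ch[i] = (int)kv.first.v[5];
    cext[i] = (int)kv.first.v[6];
    native[i] = (int)(kv.first.v[7] >> 20);
    chfree[i] = (int)(kv.first.v[7] & ((1 << 20) - 1));
    cnt[i] = kv.second;
    ++i;
  }
  return DataFrame::create(
      _["e_hb"] = ehb, _["e_steric"] = est, _["e_state"] = estt,
      _["e_aa"] = eaa, _["solvent_const"] = s1, _["c_h_exposed_all"] = ch,
      _["c_ext"] = cext, _["native_contacts"] = native,
      _["c_h_exposed"] = chfree, _["multiplicity"] = cnt);
}
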