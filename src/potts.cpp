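// Core lattice engine for the 3D Poissonian cellular Potts model of the ICM.
//
// Conventions shared with the R layer:
//   * labels: flattened 3D integer grid, 0-based linear index i = x + nx*(y + ny*z),
//     label 0 = medium, labels >= 1 are registry entries (cells or the ECM region).
//   * typeOf: integer vector indexed by label (typeOf[0] unused slot for medium),
//     codes 0 = MEDIUM, 1 = EPI, 2 = PRE, 3 = ECM.
//   * Energies in kT units, distances in voxels (1 voxel = 1 um^3), time in minutes.
//   * All randomness goes through R's RNG so set.seed() controls everything.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

static const int T_MEDIUM = 0, T_EPI = 1, T_PRE = 2, T_ECM = 3;

namespace {

struct Grid {
  int nx, ny, nz, n;
  Grid(IntegerVector dims) {
    nx = dims[0]; ny = dims[1]; nz = dims[2]; n = nx * ny * nz;
  }
  inline void coords(int i, int& x, int& y, int& z) const {
    x = i % nx; y = (i / nx) % ny; z = i / (nx * ny);
  }
  inline int idx(int x, int y, int z) const { return x + nx * (y + ny * z); }
  inline bool inside(int x, int y, int z) const {
    return x >= 0 && x < nx && y >= 0 && y < ny && z >= 0 && z < nz;
  }
  // one-voxel frozen shell (closed-box boundary condition)
  inline bool frozen(int x, int y, int z) const {
    return x == 0 || x == nx - 1 || y == 0 || y == ny - 1 || z == 0 || z == nz - 1;
  }
};

// 26 Moore-neighbourhood offsets
struct Moore {
  int dx[26], dy[26], dz[26];
  Moore() {
    int k = 0;
    for (int a = -1; a <= 1; ++a)
      for (int b = -1; b <= 1; ++b)
        for (int c = -1; c <= 1; ++c) {
          if (a == 0 && b == 0 && c == 0) continue;
          dx[k] = a; dy[k] = b; dz[k] = c; ++k;
        }
  }
};
static const Moore MOORE;

inline int typeOfLabel(const IntegerVector& typeOf, int lab) {
  return lab == 0 ? T_MEDIUM : typeOf[lab];
}

inline bool isCellType(int t) { return t == T_EPI || t == T_PRE; }

// interface + volume + ECM-cost energy of a full lattice
double latticeEnergyImpl(const IntegerVector& lab, const Grid& g,
                         const IntegerVector& typeOf, const NumericMatrix& J,
                         double kappa, const NumericVector& vbar, double epsilon) {
  double E = 0.0;
  // volumes
  int maxLab = typeOf.size() - 1;
  std::vector<double> vol(maxLab + 1, 0.0);
  int nEcm = 0;
  for (int i = 0; i < g.n; ++i) {
    int l = lab[i];
    if (l > 0) {
      vol[l] += 1.0;
      if (typeOf[l] == T_ECM) ++nEcm;
    }
  }
  // unordered Moore pairs: visit each pair once via half-neighbourhood
  for (int i = 0; i < g.n; ++i) {
    int x, y, z; g.coords(i, x, y, z);
    int li = lab[i];
    int ti = typeOfLabel(typeOf, li);
    for (int k = 0; k < 26; ++k) {
      int xx = x + MOORE.dx[k], yy = y + MOORE.dy[k], zz = z + MOORE.dz[k];
      if (!g.inside(xx, yy, zz)) continue;
      int j = g.idx(xx, yy, zz);
      if (j <= i) continue;  // count each unordered pair once
      int lj = lab[j];
      if (lj == li) continue;
      E += J(ti, typeOfLabel(typeOf, lj));
    }
  }
  for (int l = 1; l <= maxLab; ++l) {
    if (isCellType(typeOf[l]) && vol[l] > 0) {
      double d = vol[l] - vbar[l];
      E += 0.5 * kappa * d * d;
    }
  }
  E += epsilon * nEcm;
  return E;
}

// incremental energy of flipping voxel i from its label to newLab
double deltaEnergyImpl(const IntegerVector& lab, const Grid& g,
                       const IntegerVector& typeOf, const NumericMatrix& J,
                       double kappa, const NumericVector& vbar,
                       const std::vector<double>& vol, double epsilon,
                       int i, int newLab) {
  int oldLab = lab[i];
  int tOld = typeOfLabel(typeOf, oldLab);
  int tNew = typeOfLabel(typeOf, newLab);
  int x, y, z; g.coords(i, x, y, z);
  double dE = 0.0;
  for (int k = 0; k < 26; ++k) {
    int xx = x + MOORE.dx[k], yy = y + MOORE.dy[k], zz = z + MOORE.dz[k];
    if (!g.inside(xx, yy, zz)) continue;
    int lj = lab[g.idx(xx, yy, zz)];
    int tj = typeOfLabel(typeOf, lj);
    if (lj != oldLab) dE -= J(tOld, tj);
    if (lj != newLab) dE += J(tNew, tj);
  }
  if (oldLab > 0 && isCellType(tOld)) {
    double d0 = vol[oldLab] - vbar[oldLab];
    double d1 = d0 - 1.0;
    dE += 0.5 * kappa * (d1 * d1 - d0 * d0);
  }
  if (newLab > 0 && isCellType(tNew)) {
    double d0 = vol[newLab] - vbar[newLab];
    double d1 = d0 + 1.0;
    dE += 0.5 * kappa * (d1 * d1 - d0 * d0);
  }
  if (tNew == T_ECM) dE += epsilon;
  if (tOld == T_ECM) dE -= epsilon;
  return dE;
}

// Would removing voxel i from its (cell) label keep the cell connected and
// non-empty?  Exact criterion: the cell minus voxel i stays Moore-connected
// iff every same-label Moore neighbour of i lies in one connected component
// of cell \ {i}; flood fill with early termination once all of them are seen.
bool connectedAfterRemoval(const IntegerVector& lab, const Grid& g, int i,
                           double volOfCell) {
  int cell = lab[i];
  if (volOfCell <= 1.0) return false;  // would empty the cell
  int x, y, z; g.coords(i, x, y, z);
  std::vector<int> nbrSame;
  nbrSame.reserve(26);
  for (int k = 0; k < 26; ++k) {
    int xx = x + MOORE.dx[k], yy = y + MOORE.dy[k], zz = z + MOORE.dz[k];
    if (!g.inside(xx, yy, zz)) continue;
    int j = g.idx(xx, yy, zz);
    if (lab[j] == cell) nbrSame.push_back(j);
  }
  if (nbrSame.empty()) return false;  // rest of the cell is elsewhere: split
  if (nbrSame.size() == 1) return true;
  // flood fill from nbrSame[0] inside the cell, excluding i, until all
  // same-label neighbours of i are reached (or the frontier is exhausted)
  std::vector<int> stack;
  std::vector<int> visited;  // for cleanup
  static std::vector<uint8_t> mark;
  if ((int)mark.size() < g.n) mark.assign(g.n, 0);
  int need = (int)nbrSame.size();
  int found = 1;
  mark[nbrSame[0]] = 1; visited.push_back(nbrSame[0]);
  mark[i] = 2;  // barrier
  visited.push_back(i);
  // quick lookup of targets
  for (size_t t = 1; t < nbrSame.size(); ++t) {
    if (!mark[nbrSame[t]]) { mark[nbrSame[t]] = 3; visited.push_back(nbrSame[t]); }
  }
  stack.push_back(nbrSame[0]);
  bool ok = false;
  while (!stack.empty()) {
    int cur = stack.back(); stack.pop_back();
    int cx, cy, cz; g.coords(cur, cx, cy, cz);
    for (int k = 0; k < 26; ++k) {
      int xx = cx + MOORE.dx[k], yy = cy + MOORE.dy[k], zz = cz + MOORE.dz[k];
      if (!g.inside(xx, yy, zz)) continue;
      int j = g.idx(xx, yy, zz);
      if (lab[j] != cell) continue;
      if (mark[j] == 1 || mark[j] == 2) continue;
      if (mark[j] == 3) ++found;
      mark[j] = 1;
      visited.push_back(j);
      stack.push_back(j);
    }
    if (found == need) { ok = true; break; }
  }
  for (int v : visited) mark[v] = 0;
  return ok;
}

// Distinct candidate target labels for voxel i: labels present in the Moore
// neighbourhood differing from the voxel's own, plus the ECM label when the
// voxel belongs to a cell and a *different* PrE cell touches it.
int gatherCandidates(const IntegerVector& lab, const Grid& g,
                     const IntegerVector& typeOf, int i, int ecmLabel,
                     int* cand) {
  int x, y, z; g.coords(i, x, y, z);
  int own = lab[i];
  int nc = 0;
  bool prENeighbour = false;
  for (int k = 0; k < 26; ++k) {
    int xx = x + MOORE.dx[k], yy = y + MOORE.dy[k], zz = z + MOORE.dz[k];
    if (!g.inside(xx, yy, zz)) continue;
    int lj = lab[g.idx(xx, yy, zz)];
    if (lj != own && typeOfLabel(typeOf, lj) == T_PRE) prENeighbour = true;
    if (lj == own) continue;
    bool seen = false;
    for (int c = 0; c < nc; ++c) if (cand[c] == lj) { seen = true; break; }
    if (!seen && nc < 27) cand[nc++] = lj;
  }
  int ownType = typeOfLabel(typeOf, own);
  if (ecmLabel > 0 && isCellType(ownType) && prENeighbour) {
    bool seen = false;
    for (int c = 0; c < nc; ++c) if (cand[c] == ecmLabel) { seen = true; break; }
    if (!seen && nc < 27) cand[nc++] = ecmLabel;
  }
  return nc;
}

}  // namespace

// [[Rcpp::export]]
double cpp_lattice_energy(IntegerVector lab, IntegerVector dims,
                          IntegerVector typeOf, NumericMatrix J, double kappa,
                          NumericVector vbar, double epsilon) {
  Grid g(dims);
  return latticeEnergyImpl(lab, g, typeOf, J, kappa, vbar, epsilon);
}

// [[Rcpp::export]]
double cpp_delta_energy(IntegerVector lab, IntegerVector dims,
                        IntegerVector typeOf, NumericMatrix J, double kappa,
                        NumericVector vbar, NumericVector vols, double epsilon,
                        int i0, int newLab) {
  Grid g(dims);
  std::vector<double> vol(vols.begin(), vols.end());
  return deltaEnergyImpl(lab, g, typeOf, J, kappa, vbar, vol, epsilon, i0, newLab);
}

// [[Rcpp::export]]
IntegerVector cpp_candidates(IntegerVector lab, IntegerVector dims,
                             IntegerVector typeOf, int i0, int ecmLabel) {
  Grid g(dims);
  int cand[27];
  int nc = gatherCandidates(lab, g, typeOf, i0, ecmLabel, cand);
  return IntegerVector(cand, cand + nc);
}

// [[Rcpp::export]]
bool cpp_connected_after_removal(IntegerVector lab, IntegerVector dims, int i0) {
  Grid g(dims);
  int cell = lab[i0];
  double vol = 0;
  for (int i = 0; i < g.n; ++i) if (lab[i] == cell) vol += 1.0;
  return connectedAfterRemoval(lab, g, i0, vol);
}

// connected-component ids (1,2,...) of the voxels carrying `label`,
// 0 elsewhere; Moore connectivity
// [[Rcpp::export]]
IntegerVector cpp_label_components(IntegerVector lab, IntegerVector dims,
                                   int label) {
  Grid g(dims);
  IntegerVector comp(g.n, 0);
  int nextId = 0;
  std::vector<int> stack;
  for (int s = 0; s < g.n; ++s) {
    if (lab[s] != label || comp[s] != 0) continue;
    ++nextId;
    comp[s] = nextId;
    stack.push_back(s);
    while (!stack.empty()) {
      int cur = stack.back(); stack.pop_back();
      int x, y, z; g.coords(cur, x, y, z);
      for (int k = 0; k < 26; ++k) {
        int xx = x + MOORE.dx[k], yy = y + MOORE.dy[k], zz = z + MOORE.dz[k];
        if (!g.inside(xx, yy, zz)) continue;
        int j = g.idx(xx, yy, zz);
        if (lab[j] == label && comp[j] == 0) {
          comp[j] = nextId;
          stack.push_back(j);
        }
      }
    }
  }
  return comp;
}

// per-label voxel counts and centroids (1-based voxel coordinates, to match R
// array indexing); returns matrix rows = labels 1..maxLab, cols = (vol,x,y,z)
// [[Rcpp::export]]
NumericMatrix cpp_cell_stats(IntegerVector lab, IntegerVector dims,
                             int maxLab) {
  Grid g(dims);
  NumericMatrix out(maxLab, 4);
  for (int i = 0; i < g.n; ++i) {
    int l = lab[i];
    if (l < 1 || l > maxLab) continue;
    int x, y, z; g.coords(i, x, y, z);
    out(l - 1, 0) += 1.0;
    out(l - 1, 1) += x + 1.0;
    out(l - 1, 2) += y + 1.0;
    out(l - 1, 3) += z + 1.0;
  }
  for (int l = 0; l < maxLab; ++l) {
    if (out(l, 0) > 0) {
      out(l, 1) /= out(l, 0);
      out(l, 2) /= out(l, 0);
      out(l, 3) /= out(l, 0);
    } else {
      out(l, 1) = NA_REAL; out(l, 2) = NA_REAL; out(l, 3) = NA_REAL;
    }
  }
  return out;
}

// coordinates (1-based) of all voxels carrying a given label
// [[Rcpp::export]]
IntegerMatrix cpp_voxels_of_label(IntegerVector lab, IntegerVector dims,
                                  int label) {
  Grid g(dims);
  int count = 0;
  for (int i = 0; i < g.n; ++i) if (lab[i] == label) ++count;
  IntegerMatrix out(count, 3);
  int r = 0;
  for (int i = 0; i < g.n; ++i) {
    if (lab[i] != label) continue;
    int x, y, z; g.coords(i, x, y, z);
    out(r, 0) = x + 1; out(r, 1) = y + 1; out(r, 2) = z + 1;
    ++r;
  }
  return out;
}

// Advance the tau-leap kinetics by up to nSteps steps of length dt.
// Modifies `lab` and `vbar` in place (caller passes fresh copies).
// Stops early (after completing a step) when a cell's preferred volume
// reaches its division target, so the R layer can perform the division.
// Returns: steps actually done, the dividing label (0 = none) and the final
// per-label volumes.
// [[Rcpp::export]]
List cpp_advance(IntegerVector lab, IntegerVector dims, IntegerVector typeOf,
                 NumericVector vbar, NumericVector divTarget, NumericMatrix J,
                 NumericMatrix phi, NumericVector alpha, double kappa,
                 double epsilon, double kT, double dt, double growthRate,
                 int ecmLabel, int nSteps) {
  Grid g(dims);
  int maxLab = typeOf.size() - 1;
  std::vector<double> vol(maxLab + 1, 0.0);
  for (int i = 0; i < g.n; ++i) if (lab[i] > 0) vol[lab[i]] += 1.0;

  // linear Moore offsets: safe for all non-frozen (interior) voxels, which
  // is the only place label copies can happen (the shell never flips)
  int off[26];
  {
    int k = 0;
    for (int a = -1; a <= 1; ++a)
      for (int b = -1; b <= 1; ++b)
        for (int c = -1; c <= 1; ++c) {
          if (a == 0 && b == 0 && c == 0) continue;
          off[k++] = a + g.nx * (b + g.ny * c);
        }
  }
  // cache type codes and energy rows for speed
  std::vector<int> tcode(maxLab + 1);
  tcode[0] = T_MEDIUM;
  for (int l = 1; l <= maxLab; ++l) tcode[l] = typeOf[l];

  // initial boundary list: non-frozen voxels with a differing Moore neighbour
  std::vector<int> boundary;
  std::vector<uint8_t> inB(g.n, 0);
  for (int i = 0; i < g.n; ++i) {
    int x, y, z; g.coords(i, x, y, z);
    if (g.frozen(x, y, z)) continue;
    int li = lab[i];
    for (int k = 0; k < 26; ++k) {
      if (lab[i + off[k]] != li) { boundary.push_back(i); inB[i] = 1; break; }
    }
  }

  // Fast local RNG (xorshift64*), seeded from R's RNG so that set.seed()
  // still controls the whole simulation.
  uint64_t rngState = 0;
  for (int k = 0; k < 4; ++k)
    rngState = (rngState << 16) ^ (uint64_t)(unif_rand() * 65536.0);
  rngState |= 1;
  auto nextU64 = [&rngState]() {
    uint64_t x = rngState;
    x ^= x >> 12; x ^= x << 25; x ^= x >> 27;
    rngState = x;
    return x * 0x2545F4914F6CDD1DULL;
  };
  auto nextUnif = [&nextU64]() {
    return (nextU64() >> 11) * (1.0 / 9007199254740992.0);
  };

  int cand[27];
  int candCount[27];
  std::vector<int> keep, touched;
  std::vector<uint8_t> frozenMask(g.n, 0);
  for (int i = 0; i < g.n; ++i) {
    int x, y, z; g.coords(i, x, y, z);
    if (g.frozen(x, y, z)) frozenMask[i] = 1;
  }
  int stepsDone = 0;
  int divideLabel = 0;

  for (int step = 0; step < nSteps; ++step) {
    // linear growth of preferred volumes
    if (growthRate != 0.0) {
      for (int l = 1; l <= maxLab; ++l)
        if (isCellType(tcode[l]) && vol[l] > 0) vbar[l] += growthRate * dt;
    }
    // random visiting order (Fisher-Yates)
    int nb = (int)boundary.size();
    for (int a = nb - 1; a > 0; --a) {
      int b = (int)(nextU64() % (uint64_t)(a + 1));
      std::swap(boundary[a], boundary[b]);
    }
    keep.clear();
    touched.clear();
    for (int a = 0; a < nb; ++a) {
      int i = boundary[a];
      int own = lab[i];
      int tOwn = tcode[own];
      // one Moore scan: distinct differing neighbour labels with contact
      // counts (counts give the interface part of dE without a second scan)
      int nc = 0;
      int nOwn = 0;
      bool preNbr = false;
      for (int k = 0; k < 26; ++k) {
        int lj = lab[i + off[k]];
        if (lj == own) { ++nOwn; continue; }
        if (tcode[lj] == T_PRE) preNbr = true;
        int c = 0;
        for (; c < nc; ++c) if (cand[c] == lj) { ++candCount[c]; break; }
        if (c == nc) { cand[nc] = lj; candCount[nc] = 1; ++nc; }
      }
      if (nc == 0) { inB[i] = 0; continue; }  // interior voxel: drop
      keep.push_back(i);
      int nCand = nc;
      if (ecmLabel > 0 && isCellType(tOwn) && preNbr) {
        bool seen = false;
        for (int c = 0; c < nc; ++c)
          if (cand[c] == ecmLabel) { seen = true; break; }
        if (!seen) { cand[nCand] = ecmLabel; candCount[nCand] = 0; ++nCand; }
      }
      int pick = (int)(nextU64() % (uint64_t)nCand);
      int newLab = cand[pick];
      int tNew = tcode[newLab];
      double a_t = alpha[tNew];
      if (a_t <= 0.0) continue;
      // incremental energy from the neighbour-label counts
      double dE = 0.0;
      for (int c = 0; c < nCand; ++c) {
        int tj = tcode[cand[c]];
        dE -= candCount[c] * J(tOwn, tj);              // lost interfaces
        if (cand[c] != newLab)
          dE += candCount[c] * J(tNew, tj);            // gained interfaces
      }
      if (nOwn > 0 && own != newLab)
        dE += nOwn * J(tNew, tOwn);  // former same-label contacts now differ
      if (isCellType(tOwn)) {
        double d0 = vol[own] - vbar[own];
        dE += 0.5 * kappa * ((d0 - 1.0) * (d0 - 1.0) - d0 * d0);
      }
      if (isCellType(tNew)) {
        double d0 = vol[newLab] - vbar[newLab];
        dE += 0.5 * kappa * ((d0 + 1.0) * (d0 + 1.0) - d0 * d0);
      }
      if (tNew == T_ECM) dE += epsilon;
      if (tOwn == T_ECM) dE -= epsilon;
      double ex = phi(tOwn, tNew) - std::max(0.0, dE / kT);
      double p;
      if (ex > 50.0) {
        p = 1.0;  // rate saturates; acceptance certain at any dt
      } else {
        double lambda = a_t * std::exp(ex);
        p = 1.0 - std::exp(-lambda * dt);
      }
      if (unif_rand() >= p) continue;
      // fragmentation guard: never split or empty an EPI/PrE cell
      if (isCellType(tOwn) && !connectedAfterRemoval(lab, g, i, vol[own]))
        continue;
      lab[i] = newLab;
      if (own > 0) vol[own] -= 1.0;
      if (newLab > 0) vol[newLab] += 1.0;
      touched.push_back(i);
    }
    // next boundary list: surviving members + neighbourhoods of flips
    // (non-boundary strays are dropped on their next visit)
    boundary.swap(keep);
    for (int i : touched) {
      for (int k = 0; k < 26; ++k) {
        int j = i + off[k];
        if (inB[j] || frozenMask[j]) continue;
        inB[j] = 1;
        boundary.push_back(j);
      }
      if (!inB[i]) { inB[i] = 1; boundary.push_back(i); }
    }
    ++stepsDone;
    // division trigger: preferred volume reached its sampled target
    for (int l = 1; l <= maxLab; ++l) {
      if (isCellType(typeOf[l]) && vol[l] > 0 && divTarget[l] > 0 &&
          vbar[l] >= divTarget[l]) {
        divideLabel = l;
        break;
      }
    }
    if (divideLabel > 0) break;
  }

  NumericVector volOut(maxLab);
  for (int l = 1; l <= maxLab; ++l) volOut[l - 1] = vol[l];
  // lab and vbar are returned explicitly: callers must not rely on
  // in-place modification surviving any coercion at the R boundary
  return List::create(_["steps_done"] = stepsDone,
                      _["divide_label"] = divideLabel,
                      _["volumes"] = volOut,
                      _["labels"] = lab,
                      _["vbar"] = vbar);
}
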