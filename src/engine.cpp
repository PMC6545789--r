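#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// 26-site neighborhood of the cubic lattice, ordered by shell:
// 6 axis steps, 12 face-diagonal steps, 8 cube-diagonal steps.
static const int NOFF = 26;
static int OFF[NOFF][3];
static int HALF[13]; // indices of lexicographically positive offsets
static bool off_ready = false;

static void init_offsets() {
  if (off_ready) return;
  int k = 0;
  for (int a = 0; a < 3; ++a)
    for (int s = -1; s <= 1; s += 2) {
      OFF[k][0] = OFF[k][1] = OFF[k][2] = 0;
      OFF[k][a] = s;
      ++k;
    }
  for (int a = 0; a < 3; ++a)
    for (int b = a + 1; b < 3; ++b)
      for (int sa = -1; sa <= 1; sa += 2)
        for (int sb = -1; sb <= 1; sb += 2) {
          OFF[k][0] = OFF[k][1] = OFF[k][2] = 0;
          OFF[k][a] = sa;
          OFF[k][b] = sb;
          ++k;
        }
  for (int sx = -1; sx <= 1; sx += 2)
    for (int sy = -1; sy <= 1; sy += 2)
      for (int sz = -1; sz <= 1; sz += 2) {
        OFF[k][0] = sx;
        OFF[k][1] = sy;
        OFF[k][2] = sz;
        ++k;
      }
  int h = 0;
  for (int j = 0; j < NOFF; ++j) {
    int dx = OFF[j][0], dy = OFF[j][1], dz = OFF[j][2];
    if (dz > 0 || (dz == 0 && dy > 0) || (dz == 0 && dy == 0 && dx > 0))
      HALF[h++] = j;
  }
  off_ready = true;
}

// [[Rcpp::export]]
IntegerMatrix cpp_offsets() {
  init_offsets();
  IntegerMatrix m(NOFF, 3);
  for (int j = 0; j < NOFF; ++j)
    for (int c = 0; c < 3; ++c) m(j, c) = OFF[j][c];
  return m;
}

static inline void check_types(const IntegerVector& sites, int n_types) {
  for (R_xlen_t i = 0; i < sites.size(); ++i) {
    int s = sites[i];
    if (s < 0 || s >= n_types)
      stop("site type %d outside the registered range [0, %d]", s, n_types - 1);
  }
}

// Unordered neighbor-pair counts N[a][b] over the 26-neighborhood.
// [[Rcpp::export]]
NumericMatrix cpp_bond_counts(IntegerVector sites, IntegerVector dims, int n_types) {
  init_offsets();
  check_types(sites, n_types);
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  NumericMatrix N(n_types, n_types);
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        const int i = x + nx * (y + ny * z);
        const int a = sites[i];
        for (int h = 0; h < 13; ++h) {
          const int j = HALF[h];
          const int xx = x + OFF[j][0], yy = y + OFF[j][1], zz = z + OFF[j][2];
          if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz) continue;
          const int b = sites[xx + nx * (yy + ny * zz)];
          if (a <= b) N(a, b) += 1; else N(b, a) += 1;
        }
      }
  for (int a = 0; a < n_types; ++a)
    for (int b = a + 1; b < n_types; ++b) N(b, a) = N(a, b);
  return N;
}

// Interfacial energy: sum of gamma over all unordered neighbor pairs.
// [[Rcpp::export]]
double cpp_total_energy(IntegerVector sites, IntegerVector dims, NumericMatrix gamma) {
  init_offsets();
  check_types(sites, gamma.nrow());
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  double E = 0.0;
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        const int i = x + nx * (y + ny * z);
        const int a = sites[i];
        for (int h = 0; h < 13; ++h) {
          const int j = HALF[h];
          const int xx = x + OFF[j][0], yy = y + OFF[j][1], zz = z + OFF[j][2];
          if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz) continue;
          E += gamma(a, sites[xx + nx * (yy + ny * zz)]);
        }
      }
  return E;
}

static inline double local_delta(const IntegerVector& sites, int nx, int ny, int nz,
                                 const NumericMatrix& gamma, int ia, int ib) {
  const int ta = sites[ia], tb = sites[ib];
  double dE = 0.0;
  int x = ia % nx, r = ia / nx, y = r % ny, z = r / ny;
  for (int j = 0; j < NOFF; ++j) {
    const int xx = x + OFF[j][0], yy = y + OFF[j][1], zz = z + OFF[j][2];
    if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz) continue;
    const int n = xx + nx * (yy + ny * zz);
    if (n == ib) continue;
    const int tn = sites[n];
    dE += gamma(tb, tn) - gamma(ta, tn);
  }
  x = ib % nx; r = ib / nx; y = r % ny; z = r / ny;
  for (int j = 0; j < NOFF; ++j) {
    const int xx = x + OFF[j][0], yy = y + OFF[j][1], zz = z + OFF[j][2];
    if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz) continue;
    const int n = xx + nx * (yy + ny * zz);
    if (n == ia) continue;
    const int tn = sites[n];
    dE += gamma(ta, tn) - gamma(tb, tn);
  }
  return dE;
}

// Energy change for swapping the contents of two neighboring sites
// (0-based linear indices), computed from the two local neighborhoods only.
// [[Rcpp::export]]
double cpp_delta_energy(IntegerVector sites, IntegerVector dims, NumericMatrix gamma,
                        int ia, int ib) {
  init_offsets();
  check_types(sites, gamma.nrow());
  return local_delta(sites, dims[0], dims[1], dims[2], gamma, ia, ib);
}

// One call = n_mcs Monte Carlo steps; one MCS = (current mobile count)
// attempted swaps. Uses R's RNG so set.seed() governs reproducibility.
// Draw order per attempt: mobile site, neighbor, then (if needed) the
// Metropolis uniform deviate.
// [[Rcpp::export]]
List cpp_run_mcs(IntegerVector sites, IntegerVector dims, NumericMatrix gamma,
                 double ET, LogicalVector mobile_type, LogicalMatrix swap_ok,
                 int n_mcs) {
  init_offsets();
  check_types(sites, gamma.nrow());
  if (ET <= 0) stop("E_T must be positive");
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  IntegerVector st = clone(sites);

  std::vector<int> mob;
  for (R_xlen_t i = 0; i < st.size(); ++i)
    if (mobile_type[st[i]]) mob.push_back((int)i);
  if (mob.empty()) stop("no mobile sites: nothing to move");

  double attempted = 0.0, accepted = 0.0;
  int cand[NOFF];

  for (int step = 0; step < n_mcs; ++step) {
    const int M = (int)mob.size();
    for (int a = 0; a < M; ++a) {
      int mi = (int)(unif_rand() * M);
      if (mi >= M) mi = M - 1;
      const int s = mob[mi];
      const int x = s % nx, r = s / nx, y = r % ny, z = r / ny;
      int m = 0;
      for (int j = 0; j < NOFF; ++j) {
        const int xx = x + OFF[j][0], yy = y + OFF[j][1], zz = z + OFF[j][2];
        if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz) continue;
        cand[m++] = xx + nx * (yy + ny * zz);
      }
      int ci = (int)(unif_rand() * m);
      if (ci >= m) ci = m - 1;
      const int t = cand[ci];
      attempted += 1.0;
      const int ts = st[s], tt = st[t];
      if (ts == tt) continue;
      if (!swap_ok(ts, tt)) continue;
      const double dE = local_delta(st, nx, ny, nz, gamma, s, t);
      if (dE > 0.0 && unif_rand() >= std::exp(-dE / ET)) continue;
      st[s] = tt;
      st[t] = ts;
      accepted += 1.0;
      if (!mobile_type[tt]) mob[mi] = t; // cell moved into medium/hydrogel
    }
  }
  return List::create(_["sites"] = st, _["attempted"] = attempted,
                      _["accepted"] = accepted);
}

// Connected-component labeling of the indicator volume of a phase.
// connectivity 6 uses the axis shell, 18 adds face diagonals, 26 all offsets.
// [[Rcpp::export]]
IntegerVector cpp_label_components(IntegerVector sites, IntegerVector dims,
                                   LogicalVector in_phase, int connectivity) {
  init_offsets();
  check_types(sites, in_phase.size());
  int nconn;
  if (connectivity == 6) nconn = 6;
  else if (connectivity == 18) nconn = 18;
  else if (connectivity == 26) nconn = 26;
  else stop("connectivity must be 6, 18 or 26");
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = sites.size();
  IntegerVector lab(n, 0);
  std::vector<int> stack;
  int next = 0;
  for (R_xlen_t i = 0; i < n; ++i) {
    if (lab[i] != 0 || !in_phase[sites[i]]) continue;
    ++next;
    lab[i] = next;
    stack.push_back((int)i);
    while (!stack.empty()) {
      const int s = stack.back();
      stack.pop_back();
      const int x = s % nx, r = s / nx, y = r % ny, z = r / ny;
      for (int j = 0; j < nconn; ++j) {
        const int xx = x + OFF[j][0], yy = y + OFF[j][1], zz = z + OFF[j][2];
        if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz) continue;
        const int t = xx + nx * (yy + ny * zz);
        if (lab[t] == 0 && in_phase[sites[t]]) {
          lab[t] = next;
          stack.push_back(t);
        }
      }
    }
  }
  return lab;
}

// For every medium (type 0) site, the number of the six axial ray directions
// along which a non-medium site is met before leaving the box. Non-medium
// sites get -1. Used to separate enclosed (lumen) from exterior medium.
// [[Rcpp::export]]
IntegerVector cpp_blocked_directions(IntegerVector sites, IntegerVector dims) {
  init_offsets();
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = sites.size();
  IntegerVector blocked(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    if (sites[i] != 0) {
      blocked[i] = -1;
      continue;
    }
    const int x = (int)(i % nx), r = (int)(i / nx), y = r % ny, z = r / ny;
    int nb = 0;
    for (int j = 0; j < 6; ++j) {
      int xx = x, yy = y, zz = z;
      for (;;) {
        xx += OFF[j][0];
        yy += OFF[j][1];
        zz += OFF[j][2];
        if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz) break;
        if (sites[xx + nx * (yy + ny * zz)] != 0) {
          ++nb;
          break;
        }
      }
    }
    blocked[i] = nb;
  }
  return blocked;
}
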