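#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

// Intermolecular hybridization minimum free energy (kcal/mol, 37C) by a
// nearest-neighbor dynamic program over antiparallel base pairs between
// two RNA strands.  Watson-Crick and GU wobble pairs stack with
// Turner-style doublet energies; bulges/interior loops take an affine
// penalty; a duplex initiation term and terminal AU/GU penalties apply.
// Intra-strand pairing is not modelled, so an unpairable inter-linker
// never contributes.  The open (unpaired) state has energy 0, hence the
// result is always <= 0.

static const double G_INIT = 4.1;      // duplex initiation
static const double TERM_AU = 0.5;     // terminal AU/GU penalty per end
static const int MAXGAP = 10;          // max unpaired stretch per strand

// bulge initiation by size (Turner 37C, approximate beyond 6)
static const double BULGE_INIT[7] = {0.0, 3.8, 2.8, 3.2, 3.6, 4.0, 4.4};
// interior-loop initiation by total unpaired count
static const double ILOOP_INIT[9] =
  {0.0, 0.0, 1.2, 1.5, 1.7, 1.8, 2.0, 2.2, 2.3};
static const double NINIO = 0.5;       // asymmetry penalty per nt, capped
static const double NINIO_MAX = 3.0;
static const double LOOP_EXT = 0.4;    // per extra nt beyond the tables

// pair type order: CG GC GU UG AU UA (x base with y base)
static inline int baseCode(char c) {
  switch (c) {
    case 'A': return 0; case 'C': return 1;
    case 'G': return 2; case 'U': return 3;
    default: return -1;
  }
}

static inline int pairType(int a, int b) {
  if (a < 0 || b < 0) return -1;
  if (a == 1 && b == 2) return 0;  // CG
  if (a == 2 && b == 1) return 1;  // GC
  if (a == 2 && b == 3) return 2;  // GU
  if (a == 3 && b == 2) return 3;  // UG
  if (a == 0 && b == 3) return 4;  // AU
  if (a == 3 && b == 0) return 5;  // UA
  return -1;
}

// stack[p][q]: pair p = (x_i, y_j), followed inward by q = (x_{i+1}, y_{j-1})
static const double STACK[6][6] = {
  // CG     GC     GU     UG     AU     UA
  {-3.3,  -3.4,  -2.1,  -1.4,  -2.1,  -2.4},  // CG
  {-2.4,  -3.3,  -2.5,  -1.5,  -2.2,  -2.1},  // GC
  {-1.4,  -1.5,  -0.5,   0.3,  -0.6,  -1.0},  // GU
  {-2.1,  -2.5,  -1.3,  -0.5,  -1.4,  -1.3},  // UG
  {-2.1,  -2.2,  -1.4,  -0.6,  -1.1,  -0.9},  // AU
  {-2.4,  -2.1,  -1.3,  -1.0,  -1.3,  -1.3}   // UA
};

static inline double endPenalty(int pt) { return pt >= 2 ? TERM_AU : 0.0; }

// dangling-end energies (kcal/mol): unpaired neighbor stabilizing a
// terminal pair, by pair type (rows, order as above) and dangling base
// (cols A C G U).  Approximate Turner 37C values.
static const double DANGLE5[6][4] = {
  {-0.5, -0.3, -0.2, -0.1},  // CG
  {-0.2, -0.3, -0.0, -0.0},  // GC
  {-0.2, -0.2, -0.2, -0.2},  // GU
  {-0.3, -0.1, -0.2, -0.2},  // UG
  {-0.3, -0.1, -0.2, -0.2},  // AU
  {-0.3, -0.3, -0.4, -0.2}   // UA
};
static const double DANGLE3[6][4] = {
  {-1.1, -0.4, -1.3, -0.6},  // CG
  {-1.7, -0.8, -1.7, -1.2},  // GC
  {-1.2, -0.5, -1.2, -0.7},  // GU
  {-0.8, -0.5, -0.8, -0.6},  // UG
  {-0.7, -0.1, -0.7, -0.1},  // AU
  {-0.8, -0.5, -0.8, -0.6}   // UA
};

// pair type of the same pair read from the other strand (CG<->GC etc.)
static inline int revPair(int pt) { return pt ^ 1; }

// terminal-mismatch stabilization flanking an interior loop: strongest
// for purine-purine (sheared GA-type) and UU mismatches
static inline double mismatch(int a, int b) {
  if (a < 0 || b < 0) return 0.0;
  if ((a == 2 && b == 0) || (a == 0 && b == 2)) return -1.1;  // GA/AG
  if (a == 3 && b == 3) return -0.7;                          // UU
  return -0.4;
}

// cost of the gap between consecutive pairs (u1 unpaired on x, u2 on y),
// including mismatch terms against the flanking pair neighbors
static double loopEnergy(int u1, int u2, int xo, int yo, int xi, int yi) {
  if (u1 == 0 || u2 == 0) {            // bulge on one strand
    int u = u1 + u2;
    double g = u <= 6 ? BULGE_INIT[u] : BULGE_INIT[6] + LOOP_EXT * (u - 6);
    return g;
  }
  int u = u1 + u2;
  double g = u <= 8 ? ILOOP_INIT[u] : ILOOP_INIT[8] + LOOP_EXT * (u - 8);
  double asym = NINIO * (u1 > u2 ? u1 - u2 : u2 - u1);
  if (asym > NINIO_MAX) asym = NINIO_MAX;
  // mismatches adjacent to the outer pair (xo,yo) and inner pair (xi,yi)
  return g + asym + mismatch(xo, yo) + mismatch(xi, yi);
}

// [[Rcpp::export(name = ".duplex_mfe_cpp")]]
double duplex_mfe_cpp(std::string x, std::string y) {
  const int n = (int)x.size(), m = (int)y.size();
  std::vector<int> xc(n), yc(m);
  for (int i = 0; i < n; ++i) xc[i] = baseCode(x[i]);
  for (int j = 0; j < m; ++j) yc[j] = baseCode(y[j]);

  const double INF = 1e9;
  std::vector<std::vector<double> > E(n, std::vector<double>(m, INF));
  double best = 0.0;

  for (int i = 0; i < n; ++i) {
    for (int j = m - 1; j >= 0; --j) {
      int pt = pairType(xc[i], yc[j]);
      if (pt < 0) continue;
      // open a new duplex here, with dangling neighbors if present
      double open = G_INIT + endPenalty(pt);
      if (i > 0 && xc[i - 1] >= 0) open += DANGLE5[pt][xc[i - 1]];
      if (j < m - 1 && yc[j + 1] >= 0)
        open += DANGLE3[revPair(pt)][yc[j + 1]];
      double e = open;
      int klo = i - 1 - MAXGAP; if (klo < 0) klo = 0;
      int lhi = j + 1 + MAXGAP; if (lhi > m - 1) lhi = m - 1;
      for (int k = klo; k <= i - 1; ++k) {
        for (int l = j + 1; l <= lhi; ++l) {
          if (E[k][l] >= INF) continue;
          double ext;
          if (k == i - 1 && l == j + 1) {
            ext = STACK[pairType(xc[k], yc[l])][pt];
          } else {
            int u1 = i - k - 1, u2 = l - j - 1;
            // mismatch neighbors: next to outer pair (k,l) are x[k+1],
            // y[l-1]; next to inner pair (i,j) are x[i-1], y[j+1]
            ext = loopEnergy(u1, u2, xc[k + 1], yc[l - 1],
                             xc[i - 1], yc[j + 1]);
            // single-nt bulges keep the flanking helix stack
            if ((u1 == 1 && u2 == 0) || (u1 == 0 && u2 == 1))
              ext += STACK[pairType(xc[k], yc[l])][pt];
          }
          double cand = E[k][l] + ext;
          if (cand < e) e = cand;
        }
      }
      E[i][j] = e;
      double closed = e + endPenalty(pt);
      if (i < n - 1 && xc[i + 1] >= 0) closed += DANGLE3[pt][xc[i + 1]];
      if (j > 0 && yc[j - 1] >= 0) closed += DANGLE5[revPair(pt)][yc[j - 1]];
      if (closed < best) best = closed;
    }
  }
  return best;
}
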