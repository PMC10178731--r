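#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// 3D binary topology: connected-component labeling and topology-preserving
// thinning by iterative removal of simple border points (endpoint-protected,
// six directional subiterations per cycle).

namespace {

struct Dims {
  int d1, d2, d3;
};

inline int at(const Dims &d, int i, int j, int k) {
  return i + d.d1 * j + d.d1 * d.d2 * k;
}

// ---- 3x3x3 neighborhood machinery -------------------------------------
// Position p in 0..26 encodes offsets (a,b,c) in {0,1,2}^3, p = a + 3b + 9c.
// Center is 13. Offsets are (a-1, b-1, c-1).

inline void decode(int p, int &a, int &b, int &c) {
  a = p % 3;
  b = (p / 3) % 3;
  c = p / 9;
}

bool adj26(int p, int q) {
  int a1, b1, c1, a2, b2, c2;
  decode(p, a1, b1, c1);
  decode(q, a2, b2, c2);
  return std::abs(a1 - a2) <= 1 && std::abs(b1 - b2) <= 1 &&
         std::abs(c1 - c2) <= 1;
}

bool adj6(int p, int q) {
  int a1, b1, c1, a2, b2, c2;
  decode(p, a1, b1, c1);
  decode(q, a2, b2, c2);
  return std::abs(a1 - a2) + std::abs(b1 - b2) + std::abs(c1 - c2) == 1;
}

inline int n_nonzero(int p) {
  int a, b, c;
  decode(p, a, b, c);
  return (a != 1) + (b != 1) + (c != 1);
}

// Fill the 27-voxel neighborhood of (i,j,k); out of bounds = 0.
void neighborhood(const int *V, const Dims &d, int i, int j, int k,
                  int nb[27]) {
  int p = 0;
  for (int dc = -1; dc <= 1; ++dc)
    for (int db = -1; db <= 1; ++db)
      for (int da = -1; da <= 1; ++da, ++p) {
        // p = (da+1) + 3(db+1) + 9(dc+1) given loop order (da fastest)
        int ii = i + da, jj = j + db, kk = k + dc;
        nb[(da + 1) + 3 * (db + 1) + 9 * (dc + 1)] =
            (ii < 0 || ii >= d.d1 || jj < 0 || jj >= d.d2 || kk < 0 ||
             kk >= d.d3)
                ? 0
                : V[at(d, ii, jj, kk)];
        (void)p;
      }
}

int count_fg26(const int nb[27]) {
  int n = 0;
  for (int p = 0; p < 27; ++p)
    if (p != 13 && nb[p]) ++n;
  return n;
}

// Number of 26-connected components of foreground within N26 (center removed).
int components_fg26(const int nb[27]) {
  bool seen[27] = {false};
  int ncomp = 0;
  int stack[27];
  for (int s = 0; s < 27; ++s) {
    if (s == 13 || !nb[s] || seen[s]) continue;
    ++ncomp;
    int top = 0;
    stack[top++] = s;
    seen[s] = true;
    while (top) {
      int p = stack[--top];
      for (int q = 0; q < 27; ++q) {
        if (q == 13 || q == p || seen[q] || !nb[q]) continue;
        if (adj26(p, q)) {
          seen[q] = true;
          stack[top++] = q;
        }
      }
    }
  }
  return ncomp;
}

// Number of 6-connected components of background within the 18-neighborhood
// that touch a face neighbor of the center (Malandain–Bertrand condition).
int components_bg6(const int nb[27]) {
  bool in18[27], seen[27] = {false};
  for (int p = 0; p < 27; ++p)
    in18[p] = (p != 13) && (n_nonzero(p) <= 2);
  int ncomp = 0;
  int stack[27];
  for (int s = 0; s < 27; ++s) {
    if (!in18[s] || nb[s] || seen[s]) continue;
    if (n_nonzero(s) != 1) continue;  // grow only from face neighbors
    ++ncomp;
    int top = 0;
    stack[top++] = s;
    seen[s] = true;
    while (top) {
      int p = stack[--top];
      for (int q = 0; q < 27; ++q) {
        if (!in18[q] || nb[q] || seen[q]) continue;
        if (adj6(p, q)) {
          seen[q] = true;
          stack[top++] = q;
        }
      }
    }
  }
  return ncomp;
}

bool is_simple(const int nb[27]) {
  return components_fg26(nb) == 1 && components_bg6(nb) == 1;
}

}  // namespace

// [[Rcpp::export]]
IntegerVector cpp_label3d(IntegerVector vol, int connectivity) {
  IntegerVector dm = vol.attr("dim");
  Dims d{dm[0], dm[1], dm[2]};
  size_t n = vol.size();
  IntegerVector lab(n);
  lab.attr("dim") = dm;
  const int *V = vol.begin();
  int *L = lab.begin();
  std::vector<int> stack;
  int next = 0;
  for (size_t s = 0; s < n; ++s) {
    if (!V[s] || L[s]) continue;
    ++next;
    L[s] = next;
    stack.push_back((int)s);
    while (!stack.empty()) {
      int p = stack.back();
      stack.pop_back();
      int i = p % d.d1, j = (p / d.d1) % d.d2, k = p / (d.d1 * d.d2);
      for (int dc = -1; dc <= 1; ++dc)
        for (int db = -1; db <= 1; ++db)
          for (int da = -1; da <= 1; ++da) {
            if (!da && !db && !dc) continue;
            if (connectivity == 6 &&
                std::abs(da) + std::abs(db) + std::abs(dc) != 1)
              continue;
            int ii = i + da, jj = j + db, kk = k + dc;
            if (ii < 0 || ii >= d.d1 || jj < 0 || jj >= d.d2 || kk < 0 ||
                kk >= d.d3)
              continue;
            int q = at(d, ii, jj, kk);
            if (V[q] && !L[q]) {
              L[q] = next;
              stack.push_back(q);
            }
          }
    }
  }
  return lab;
}

// [[Rcpp::export]]
IntegerVector cpp_skeletonize3d(IntegerVector vol) {
  IntegerVector dm = vol.attr("dim");
  Dims d{dm[0], dm[1], dm[2]};
  IntegerVector out = clone(vol);
  out.attr("dim") = dm;
  int *V = out.begin();
  size_t n = out.size();
  // six border directions: (da, db, dc)
  const int dir[6][3] = {{-1, 0, 0}, {1, 0, 0},  {0, -1, 0},
                         {0, 1, 0},  {0, 0, -1}, {0, 0, 1}};
  int nb[27];
  bool changed = true;
  std::vector<int> cand;
  while (changed) {
    changed = false;
    for (int s = 0; s < 6; ++s) {
      cand.clear();
      for (int k = 0; k < d.d3; ++k)
        for (int j = 0; j < d.d2; ++j)
          for (int i = 0; i < d.d1; ++i) {
            int p = at(d, i, j, k);
            if (!V[p]) continue;
            int ii = i + dir[s][0], jj = j + dir[s][1], kk = k + dir[s][2];
            int border = (ii < 0 || ii >= d.d1 || jj < 0 || jj >= d.d2 ||
                          kk < 0 || kk >= d.d3)
                             ? 1
                             : !V[at(d, ii, jj, kk)];
            if (!border) continue;
            neighborhood(V, d, i, j, k, nb);
            if (count_fg26(nb) < 2) continue;  // endpoint / isolated: keep
            if (is_simple(nb)) cand.push_back(p);
          }
      // sequential recheck: each deletion must remain a simple-point deletion
      for (size_t t = 0; t < cand.size(); ++t) {
        int p = cand[t];
        int i = p % d.d1, j = (p / d.d1) % d.d2, k = p / (d.d1 * d.d2);
        neighborhood(V, d, i, j, k, nb);
        if (count_fg26(nb) >= 2 && is_simple(nb)) {
          V[p] = 0;
          changed = true;
        }
      }
    }
  }
  (void)n;
  return out;
}
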