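#include <Rcpp.h>
using namespace Rcpp;

// Cell states on the lattice
static const int HEALTHY = 0;
static const int TUMOR = 1;
static const int IMMUNE = 2;

// random integer in [0, k) from R's RNG (RNGScope supplied by attributes)
static inline int rint(int k) {
  int v = (int)(unif_rand() * k);
  return v >= k ? k - 1 : v;
}

static inline void shuffle(std::vector<int>& v) {
  for (int i = (int)v.size() - 1; i > 0; --i) {
    int j = rint(i + 1);
    std::swap(v[i], v[j]);
  }
}

// von Neumann neighbors; rows periodic, columns bounded.
// Columns 0 and n-1 are vessel columns: nutrient sources, never occupied
// by tumor or immune cells. Returns number of neighbors written.
static inline int vn_neighbors(int i, int j, int nr, int nc, int* ni, int* nj) {
  int k = 0;
  ni[k] = (i + 1) % nr;      nj[k] = j; ++k;
  ni[k] = (i + nr - 1) % nr; nj[k] = j; ++k;
  if (j + 1 <= nc - 1) { ni[k] = i; nj[k] = j + 1; ++k; }
  if (j - 1 >= 0)      { ni[k] = i; nj[k] = j - 1; ++k; }
  return k;
}

static inline int moore_neighbors(int i, int j, int nr, int nc,
                                  int* ni, int* nj) {
  int k = 0;
  for (int di = -1; di <= 1; ++di) {
    for (int dj = -1; dj <= 1; ++dj) {
      if (di == 0 && dj == 0) continue;
      int jj = j + dj;
      if (jj < 0 || jj > nc - 1) continue;
      ni[k] = (i + di + nr) % nr;
      nj[k] = jj;
      ++k;
    }
  }
  return k;
}

static inline bool occupiable(int j, int nc) {
  return j >= 1 && j <= nc - 2;  // vessel columns stay cell-free
}

// Asynchronous growth sweeps. One sweep = one action attempt per tumor
// cell, in random order. Division probability 1 - exp(-(N/theta_div)^2)
// (theta_div <= 0 disables division), necrosis exp(-(M/theta_nec)^2)
// (0 at theta_nec = 0), migration 1 - exp(-(M/theta_mig)^2) (0 at
// theta_mig = Inf). Mutates `grid` in place; stops mid-sweep as soon as
// the tumor count reaches `target`.
// [[Rcpp::export]]
List ca_grow_sweeps(IntegerMatrix grid, NumericMatrix N, NumericMatrix M,
                    int nsweeps, double theta_div, double theta_nec,
                    double theta_mig, int target) {
  int nr = grid.nrow(), nc = grid.ncol();
  int ni[8], nj[8], fi[8], fj[8];
  int count = 0;
  for (int k = 0; k < nr * nc; ++k) if (grid[k] == TUMOR) ++count;
  int sweeps_done = 0, divisions = 0;
  bool mig_on = R_finite(theta_mig) && theta_mig > 0;

  for (int sweep = 0; sweep < nsweeps && count < target; ++sweep) {
    std::vector<int> cells;
    cells.reserve(count);
    for (int k = 0; k < nr * nc; ++k) if (grid[k] == TUMOR) cells.push_back(k);
    shuffle(cells);
    for (size_t c = 0; c < cells.size() && count < target; ++c) {
      int k = cells[c];
      if (grid[k] != TUMOR) continue;  // died earlier this sweep
      int i = k % nr, j = k / nr;
      // necrosis: starvation of maintenance nutrient
      if (theta_nec > 0) {
        double p = std::exp(-std::pow(M(i, j) / theta_nec, 2.0));
        if (unif_rand() < p) { grid[k] = HEALTHY; --count; continue; }
      }
      // division into a random free von Neumann neighbor
      if (theta_div > 0) {
        double p = 1.0 - std::exp(-std::pow(N(i, j) / theta_div, 2.0));
        if (unif_rand() < p) {
          int nn = vn_neighbors(i, j, nr, nc, ni, nj), nf = 0;
          for (int q = 0; q < nn; ++q)
            if (grid(ni[q], nj[q]) == HEALTHY && occupiable(nj[q], nc)) {
              fi[nf] = ni[q]; fj[nf] = nj[q]; ++nf;
            }
          if (nf > 0) {
            int q = rint(nf);
            grid(fi[q], fj[q]) = TUMOR;
            ++count; ++divisions;
            continue;
          }
        }
      }
      // migration (disabled at theta_mig = Inf)
      if (mig_on) {
        double p = 1.0 - std::exp(-std::pow(M(i, j) / theta_mig, 2.0));
        if (unif_rand() < p) {
          int nn = vn_neighbors(i, j, nr, nc, ni, nj), nf = 0;
          for (int q = 0; q < nn; ++q)
            if (grid(ni[q], nj[q]) == HEALTHY && occupiable(nj[q], nc)) {
              fi[nf] = ni[q]; fj[nf] = nj[q]; ++nf;
            }
          if (nf > 0) {
            int q = rint(nf);
            grid(fi[q], fj[q]) = TUMOR;
            grid[k] = HEALTHY;
          }
        }
      }
    }
    ++sweeps_done;
  }
  return List::create(_["count"] = count, _["sweeps"] = sweeps_done,
                      _["divisions"] = divisions);
}

// Frozen-tumor lysis phase. One step = one hour = one action attempt per
// immune cell, in random order:
//  - adjacent (von Neumann) to tumor: lyse a random tumor neighbor with
//    probability 1 - exp(-1/theta_lys^2); the lysing cell advances into
//    the lysed site, and with probability 1 - exp(-1/theta_rec^2) a
//    recruit appears on a free Moore neighbor of that site. A cell that
//    has lysed `max_lyses` times is removed.
//  - no tumor in its Moore neighborhood ("far from the tumor"):
//    inactivated with probability 1 - exp(-1/theta_inc^2); survivors may
//    migrate to a random free von Neumann site.
// Mutates `grid`/`lyscount` in place. Returns per-step tumor and immune
// counts (index 0 = initial state).
// [[Rcpp::export]]
List ca_lysis_run(IntegerMatrix grid, IntegerMatrix lyscount,
                  double theta_lys, double theta_rec, double theta_inc,
                  int max_lyses, int max_steps, bool immune_migrate) {
  int nr = grid.nrow(), nc = grid.ncol();
  int ni[8], nj[8], ti[8], tj[8];
  if (theta_lys <= 0 || theta_rec <= 0 || theta_inc <= 0)
    stop("immune action parameters must be positive");
  double p_lys = 1.0 - std::exp(-1.0 / (theta_lys * theta_lys));
  double p_rec = 1.0 - std::exp(-1.0 / (theta_rec * theta_rec));
  double p_inc = 1.0 - std::exp(-1.0 / (theta_inc * theta_inc));

  int tumor = 0, immune = 0;
  for (int k = 0; k < nr * nc; ++k) {
    if (grid[k] == TUMOR) ++tumor;
    else if (grid[k] == IMMUNE) ++immune;
  }
  std::vector<int> tumor_rec, immune_rec;
  tumor_rec.push_back(tumor);
  immune_rec.push_back(immune);

  // once the immune population is extinct nothing can change: stop early
  int step = 0;
  while (tumor > 0 && immune > 0 && step < max_steps) {
    std::vector<int> cells;
    cells.reserve(immune);
    for (int k = 0; k < nr * nc; ++k) if (grid[k] == IMMUNE) cells.push_back(k);
    shuffle(cells);
    for (size_t c = 0; c < cells.size(); ++c) {
      int k = cells[c];
      if (grid[k] != IMMUNE) continue;  // moved or removed earlier
      int i = k % nr, j = k / nr;
      int nn = vn_neighbors(i, j, nr, nc, ni, nj), nt = 0;
      for (int q = 0; q < nn; ++q)
        if (grid(ni[q], nj[q]) == TUMOR) { ti[nt] = ni[q]; tj[nt] = nj[q]; ++nt; }
      if (nt > 0) {
        if (unif_rand() < p_lys) {
          int q = rint(nt);
          int li = ti[q], lj = tj[q];
          // lysed tumor cell is replaced by the advancing effector
          grid(li, lj) = IMMUNE;
          lyscount(li, lj) = lyscount(i, j) + 1;
          grid[k] = HEALTHY;
          lyscount(i, j) = 0;
          --tumor;
          if (lyscount(li, lj) >= max_lyses) {
            grid(li, lj) = HEALTHY;   // exhausted: inactivates
            lyscount(li, lj) = 0;
            --immune;
          }
          if (unif_rand() < p_rec) {
            int mn = moore_neighbors(li, lj, nr, nc, ni, nj), nf = 0;
            for (int q2 = 0; q2 < mn; ++q2)
              if (grid(ni[q2], nj[q2]) == HEALTHY && occupiable(nj[q2], nc)) {
                ti[nf] = ni[q2]; tj[nf] = nj[q2]; ++nf;
              }
            if (nf > 0) {
              int q2 = rint(nf);
              grid(ti[q2], tj[q2]) = IMMUNE;
              lyscount(ti[q2], tj[q2]) = 0;
              ++immune;
            }
          }
        }
      } else {
        // far from the tumor? no tumor cell in the Moore neighborhood
        int mn = moore_neighbors(i, j, nr, nc, ni, nj);
        bool near = false;
        for (int q = 0; q < mn; ++q)
          if (grid(ni[q], nj[q]) == TUMOR) { near = true; break; }
        if (!near && unif_rand() < p_inc) {
          grid[k] = HEALTHY;
          lyscount(i, j) = 0;
          --immune;
          continue;
        }
        if (immune_migrate) {
          int nf = 0;
          for (int q = 0; q < nn; ++q)
            if (grid(ni[q], nj[q]) == HEALTHY && occupiable(nj[q], nc)) {
              ti[nf] = ni[q]; tj[nf] = nj[q]; ++nf;
            }
          if (nf > 0) {
            int q = rint(nf);
            grid(ti[q], tj[q]) = IMMUNE;
            lyscount(ti[q], tj[q]) = lyscount(i, j);
            grid[k] = HEALTHY;
            lyscount(i, j) = 0;
          }
        }
      }
    }
    ++step;
    tumor_rec.push_back(tumor);
    immune_rec.push_back(immune);
  }
  return List::create(_["tumor"] = wrap(tumor_rec),
                      _["immune"] = wrap(immune_rec),
                      _["truncated"] = (tumor > 0));
}
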