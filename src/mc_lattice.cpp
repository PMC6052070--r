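// Kawasaki-exchange Monte Carlo on a molecular lattice.
//
// Grid cells hold 0-based type codes; couplings come from a symmetric
// per-type interaction matrix. Moves exchange the occupants of two sites
// (any two sites, or nearest neighbors), which conserves composition
// exactly. Acceptance is Metropolis at inverse temperature beta, with a
// geometric beta schedule for annealing. The RNG is a self-contained
// mt19937_64 so runs are bit-reproducible for a given seed.

#include <Rcpp.h>
#include <random>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

static inline int wrap(int i, int n) { return (i + n) % n; }

// Sum of couplings of site (r,c), holding type t, with its 4-neighborhood;
// `skip_r/skip_c` excludes one neighbor (the swap partner).
static double site_bonds(const IntegerMatrix &g, const NumericMatrix &M,
                         int r, int c, int t, bool periodic,
                         int skip_r, int skip_c) {
  static const int dr[4] = {-1, 1, 0, 0};
  static const int dc[4] = {0, 0, -1, 1};
  const int nr = g.nrow(), nc = g.ncol();
  double e = 0.0;
  for (int k = 0; k < 4; ++k) {
    int rr = r + dr[k], cc = c + dc[k];
    if (periodic) { rr = wrap(rr, nr); cc = wrap(cc, nc); }
    else if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
    if (rr == skip_r && cc == skip_c) continue;
    e += M(t, g(rr, cc));
  }
  return e;
}

// [[Rcpp::export(name = ".lattice_energy_cpp", rng = false)]]
double lattice_energy_cpp(const IntegerMatrix &grid, const NumericMatrix &M,
                          bool periodic) {
  const int nr = grid.nrow(), nc = grid.ncol();
  double e = 0.0;
  for (int r = 0; r < nr; ++r) {
    for (int c = 0; c < nc; ++c) {
      int t = grid(r, c);
      if (periodic || r + 1 < nr) e += M(t, grid(wrap(r + 1, nr), c));
      if (periodic || c + 1 < nc) e += M(t, grid(r, wrap(c + 1, nc)));
    }
  }
  return e;
}

// [[Rcpp::export(name = ".mc_lattice_cpp", rng = false)]]
List mc_lattice_cpp(IntegerMatrix grid, const NumericMatrix &M,
                    double nsteps, double beta0, double beta1,
                    int seed, int n_snapshots, bool periodic,
                    bool global_moves, int sample_every) {
  const int nr = grid.nrow(), nc = grid.ncol();
  const long long n = (long long)nsteps;
  const int ncell = nr * nc;
  std::mt19937_64 rng((uint64_t)(unsigned int)seed * 0x9E3779B97F4A7C15ULL + 1ULL);
  std::uniform_int_distribution<int> cell(0, ncell - 1);
  std::uniform_int_distribution<int> dir(0, 3);
  std::uniform_real_distribution<double> unif(0.0, 1.0);

  double energy = lattice_energy_cpp(grid, M, periodic);
  long long accepted = 0;
  const bool anneal = (beta1 != beta0) && n > 1;
  const double lr = anneal ? std::log(beta1 / beta0) / (double)(n - 1) : 0.0;

  List snaps;
  NumericVector snap_energy;
  NumericVector snap_step;
  std::vector<long long> snap_at;
  if (n_snapshots > 0) {
    for (int s = 1; s <= n_snapshots; ++s) {
      long long at = (long long)((double)n * s / n_snapshots);
      if (at >= 1 && (snap_at.empty() || at != snap_at.back()))
        snap_at.push_back(at);
    }
  }
  size_t next_snap = 0;

  std::vector<int> samples;
  int ntypes = M.nrow();

  static const int drr[4] = {-1, 1, 0, 0};
  static const int dcc[4] = {0, 0, -1, 1};

  for (long long step = 1; step <= n; ++step) {
    double beta = anneal ? beta0 * std::exp(lr * (double)(step - 1)) : beta0;
    int i1 = cell(rng);
    int r1 = i1 % nr, c1 = i1 / nr;
    int r2, c2;
    if (global_moves) {
      int i2 = cell(rng);
      while (i2 == i1) i2 = cell(rng);
      r2 = i2 % nr; c2 = i2 / nr;
    } else {
      int k = dir(rng);
      r2 = r1 + drr[k]; c2 = c1 + dcc[k];
      if (periodic) { r2 = wrap(r2, nr); c2 = wrap(c2, nc); }
      else if (r2 < 0 || r2 >= nr || c2 < 0 || c2 >= nc) {
        // off-lattice proposal: rejected (keeps proposal symmetric)
        goto bookkeeping;
      }
    }
    {
      int t1 = grid(r1, c1), t2 = grid(r2, c2);
      if (t1 == t2) {
        ++accepted; // identity exchange, trivially accepted
      } else {
        double before = site_bonds(grid, M, r1, c1, t1, periodic, r2, c2) +
                        site_bonds(grid, M, r2, c2, t2, periodic, r1, c1);
        double after  = site_bonds(grid, M, r1, c1, t2, periodic, r2, c2) +
                        site_bonds(grid, M, r2, c2, t1, periodic, r1, c1);
        double dE = after - before;
        bool acc;
        if (dE <= 0.0) acc = true;
        else if (!std::isfinite(beta)) acc = false;
        else acc = (unif(rng) < std::exp(-beta * dE));
        if (acc) {
          grid(r1, c1) = t2;
          grid(r2, c2) = t1;
          energy += dE;
          ++accepted;
        }
      }
    }
  bookkeeping:
    if (sample_every > 0 && step % sample_every == 0) {
      // encode tiny grids as a base-ntypes integer (column-major)
      long long code = 0;
      for (int c = 0; c < nc; ++c)
        for (int r = 0; r < nr; ++r)
          code = code * ntypes + grid(r, c);
      samples.push_back((int)code);
    }
    if (next_snap < snap_at.size() && step == snap_at[next_snap]) {
      snaps.push_back(clone(grid));
      snap_energy.push_back(energy);
      snap_step.push_back((double)step);
      ++next_snap;
    }
  }

  return List::create(
    _["grid"] = grid,
    _["energy"] = energy,
    _["accepted"] = (double)accepted,
    _["snapshots"] = snaps,
    _["snapshotEnergies"] = snap_energy,
    _["snapshotSteps"] = snap_step,
    _["samples"] = IntegerVector(samples.begin(), samples.end()));
}
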