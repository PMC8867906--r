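// 2D Metropolis Monte Carlo for disks with a 100-200 Lennard-Jones
// attraction plus a repulsive Yukawa tail, periodic minimum-image box,
// cell-list neighbour search.  Energies in k_B*T, lengths in sigma0 units
// (any consistent unit works; the potential carries its own scales).
//
// RNG: R's generator (unif_rand), so trajectories are reproducible from
// set.seed() on the R side.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// conv 0: 4*V1*[(s)^200 - (s)^100]   (zero crossing at r = sigma)
// conv 1:   V1*[(s)^200 - 2(s)^100]  (well depth V1 at the minimum)
static inline double pair_pot(double r, double sigma, double V1, double V2,
                              double lam, double rc, int conv) {
  if (r >= rc) return 0.0;
  if (r <= 0.0) return R_PosInf;
  double s100 = std::pow(sigma / r, 100.0);
  double lj = (conv == 0) ? 4.0 * V1 * s100 * (s100 - 1.0)
                          : V1 * s100 * (s100 - 2.0);
  double x = r / lam;
  return lj + V2 * std::exp(-x) / x;
}

// [[Rcpp::export]]
NumericVector pair_potential_cpp(NumericVector r, double sigma, double V1,
                                 double V2, double lam, double rc, int conv) {
  int n = r.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = pair_pot(r[i], sigma, V1, V2, lam, rc, conv);
  return out;
}

struct CellList {
  int ncx, ncy;
  double Lx, Ly, cw_x, cw_y;
  bool use_cells;
  std::vector<int> head;        // first particle in cell, -1 empty
  std::vector<int> nxt;         // linked list
  std::vector<int> cell_of;

  CellList(int n, double Lx_, double Ly_, double rc) : Lx(Lx_), Ly(Ly_) {
    ncx = (int)std::floor(Lx / rc);
    ncy = (int)std::floor(Ly / rc);
    use_cells = (ncx >= 3 && ncy >= 3);
    if (!use_cells) { ncx = ncy = 1; }
    cw_x = Lx / ncx; cw_y = Ly / ncy;
    head.assign(ncx * ncy, -1);
    nxt.assign(n, -1);
    cell_of.assign(n, 0);
  }
  int cell_index(double x, double y) const {
    int cx = (int)(x / cw_x); if (cx >= ncx) cx = ncx - 1; if (cx < 0) cx = 0;
    int cy = (int)(y / cw_y); if (cy >= ncy) cy = ncy - 1; if (cy < 0) cy = 0;
    return cy * ncx + cx;
  }
  void build(const std::vector<double>& x, const std::vector<double>& y) {
    std::fill(head.begin(), head.end(), -1);
    for (size_t i = 0; i < x.size(); ++i) {
      int c = cell_index(x[i], y[i]);
      cell_of[i] = c;
      nxt[i] = head[c];
      head[c] = (int)i;
    }
  }
  void move_particle(int i, double xnew, double ynew) {
    int cnew = cell_index(xnew, ynew);
    int cold = cell_of[i];
    if (cnew == cold) return;
    // unlink from old cell
    int p = head[cold];
    if (p == i) head[cold] = nxt[i];
    else {
      while (nxt[p] != i) p = nxt[p];
      nxt[p] = nxt[i];
    }
    nxt[i] = head[cnew];
    head[cnew] = i;
    cell_of[i] = cnew;
  }
};

static inline double min_image(double d, double L) {
  if (d > 0.5 * L) d -= L;
  else if (d < -0.5 * L) d += L;
  return d;
}

// energy of particle i against all others (cell list or all pairs)
static double particle_energy(int i, double xi, double yi,
                              const std::vector<double>& x,
                              const std::vector<double>& y,
                              const CellList& cl,
                              double sigma, double V1, double V2,
                              double lam, double rc, int conv) {
  double e = 0.0;
  double rc2 = rc * rc;
  int n = (int)x.size();
  if (!cl.use_cells) {
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      double dx = min_image(xi - x[j], cl.Lx);
      double dy = min_image(yi - y[j], cl.Ly);
      double r2 = dx * dx + dy * dy;
      if (r2 < rc2) e += pair_pot(std::sqrt(r2), sigma, V1, V2, lam, rc, conv);
    }
    return e;
  }
  int ci = cl.cell_index(xi, yi);
  int cx = ci % cl.ncx, cy = ci / cl.ncx;
  for (int ddy = -1; ddy <= 1; ++ddy) {
    int ny = (cy + ddy + cl.ncy) % cl.ncy;
    for (int ddx = -1; ddx <= 1; ++ddx) {
      int nx = (cx + ddx + cl.ncx) % cl.ncx;
      for (int j = cl.head[ny * cl.ncx + nx]; j != -1; j = cl.nxt[j]) {
        if (j == i) continue;
        double dx = min_image(xi - x[j], cl.Lx);
        double dy = min_image(yi - y[j], cl.Ly);
        double r2 = dx * dx + dy * dy;
        if (r2 < rc2) e += pair_pot(std::sqrt(r2), sigma, V1, V2, lam, rc, conv);
      }
    }
  }
  return e;
}

// [[Rcpp::export]]
double total_energy_cpp(NumericMatrix pos, double Lx, double Ly, bool periodic,
                        double sigma, double V1, double V2, double lam,
                        double rc, int conv) {
  int n = pos.nrow();
  double e = 0.0, rc2 = rc * rc;
  for (int i = 0; i < n - 1; ++i) {
    for (int j = i + 1; j < n; ++j) {
      double dx = pos(i, 0) - pos(j, 0);
      double dy = pos(i, 1) - pos(j, 1);
      if (periodic) { dx = min_image(dx, Lx); dy = min_image(dy, Ly); }
      double r2 = dx * dx + dy * dy;
      if (r2 < rc2) e += pair_pot(std::sqrt(r2), sigma, V1, V2, lam, rc, conv);
    }
  }
  return e;
}

static inline double pbc_wrap(double v, double L) {
  v -= L * std::floor(v / L);
  if (v >= L) v -= L;          // guard against rounding at the boundary
  if (v < 0) v = 0;
  return v;
}

// Metropolis run: n_sweeps sweeps of N single-particle trial moves.
// Returns final positions, per-sweep energy / acceptance, optional snapshots,
// and the (possibly tuned) displacement amplitude.
// [[Rcpp::export]]
List mc_run_cpp(NumericMatrix pos0, double Lx, double Ly,
                double sigma, double V1, double V2, double lam, double rc,
                int conv, int n_sweeps, double max_disp,
                bool tune, int tune_until, int sample_every) {
  RNGScope scope;
  int n = pos0.nrow();
  std::vector<double> x(n), y(n);
  for (int i = 0; i < n; ++i) { x[i] = pbc_wrap(pos0(i, 0), Lx); y[i] = pbc_wrap(pos0(i, 1), Ly); }

  CellList cl(n, Lx, Ly, rc);
  cl.build(x, y);

  double energy = 0.0;
  {
    NumericMatrix p(n, 2);
    for (int i = 0; i < n; ++i) { p(i, 0) = x[i]; p(i, 1) = y[i]; }
    energy = total_energy_cpp(p, Lx, Ly, true, sigma, V1, V2, lam, rc, conv);
  }

  NumericVector e_series(n_sweeps), acc_series(n_sweeps);
  std::vector<NumericMatrix> snaps;
  std::vector<int> snap_at;

  int acc_window = 0, try_window = 0;
  for (int sweep = 0; sweep < n_sweeps; ++sweep) {
    int accepted = 0;
    for (int k = 0; k < n; ++k) {
      int i = (int)(unif_rand() * n); if (i == n) i = n - 1;
      double xn = pbc_wrap(x[i] + (unif_rand() - 0.5) * 2.0 * max_disp, Lx);
      double yn = pbc_wrap(y[i] + (unif_rand() - 0.5) * 2.0 * max_disp, Ly);
      double e_old = particle_energy(i, x[i], y[i], x, y, cl,
                                     sigma, V1, V2, lam, rc, conv);
      double e_new = particle_energy(i, xn, yn, x, y, cl,
                                     sigma, V1, V2, lam, rc, conv);
      double dE = e_new - e_old;
      bool ok = (dE <= 0.0) || (R_FINITE(dE) && unif_rand() < std::exp(-dE));
      if (ok) {
        x[i] = xn; y[i] = yn;
        cl.move_particle(i, xn, yn);
        energy += dE;
        ++accepted;
      }
    }
    e_series[sweep] = energy;
    acc_series[sweep] = (double)accepted / n;
    acc_window += accepted; try_window += n;

    if (tune && sweep < tune_until && try_window >= 50 * n) {
      double a = (double)acc_window / try_window;
      if (a < 0.30) max_disp *= 0.85;
      else if (a > 0.50) max_disp *= 1.15;
      double cap = 0.45 * std::min(Lx, Ly);
      if (max_disp > cap) max_disp = cap;
      acc_window = 0; try_window = 0;
    }

    if (sample_every > 0 && ((sweep + 1) % sample_every == 0)) {
      NumericMatrix s(n, 2);
      for (int i = 0; i < n; ++i) { s(i, 0) = x[i]; s(i, 1) = y[i]; }
      snaps.push_back(s);
      snap_at.push_back(sweep + 1);
    }
  }

  NumericMatrix fin(n, 2);
  for (int i = 0; i < n; ++i) { fin(i, 0) = x[i]; fin(i, 1) = y[i]; }
  List snaplist(snaps.size());
  for (size_t s = 0; s < snaps.size(); ++s) snaplist[s] = snaps[s];

  return List::create(_["positions"] = fin,
                      _["energy"] = e_series,
                      _["acceptance"] = acc_series,
                      _["snapshots"] = snaplist,
                      _["snapshot_sweeps"] = wrap(snap_at),
                      _["max_disp"] = max_disp);
}
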