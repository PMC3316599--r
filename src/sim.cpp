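// Lattice simulators for territorial central-place foragers.
//
// Animals are nearest-neighbour random walkers with a step bias towards a
// fixed central place (CP). Every site an animal stands on is marked with
// its scent; a site carrying foreign scent younger than the active scent
// time T_AS cannot be entered. Update scheme: random-sequential sweeps, a
// fresh permutation per sweep; a blocked move is a rejected attempt (the
// animal stays put). Time advances by 1/(n_animals * F) per attempt. All
// randomness is drawn from R's RNG so set.seed() gives bit-identical runs.

#include <Rcpp.h>
using namespace Rcpp;

static inline int imod(int i, int n) { return ((i % n) + n) % n; }

// minimal-image displacement from x to c on a ring of n sites
static inline double ring_disp(int x, int c, int n) {
  double d = c - x;
  if (d > n / 2.0) d -= n;
  if (d < -n / 2.0) d += n;
  return d;
}

static void permute(IntegerVector &ord) {
  int n = ord.size();
  for (int i = n - 1; i > 0; --i) {
    int j = (int)std::floor(unif_rand() * (i + 1));
    if (j > i) j = i;
    std::swap(ord[i], ord[j]);
  }
}

// scent record: owner (-1 empty) and time of last mark; expiry is lazy
struct Scent {
  std::vector<int> owner;
  std::vector<double> mark_time;
  double tas;
  Scent(int nsites, double tas_) : owner(nsites, -1), mark_time(nsites, 0.0), tas(tas_) {}
  inline int active_owner(int s, double t) const {
    if (owner[s] < 0) return -1;
    if (tas <= 0.0) return -1;
    return (t - mark_time[s] < tas) ? owner[s] : -1;
  }
  inline bool blocked(int s, double t, int me) const {
    int o = active_owner(s, t);
    return (o >= 0 && o != me);
  }
  inline void mark(int s, double t, int me) { owner[s] = me; mark_time[s] = t; }
};

// [[Rcpp::export]]
NumericVector cpp_move_probs_2d(double dx, double dy, double p) {
  // probabilities for moves (+x, -x, +y, -y) given displacement (dx, dy)
  // from the animal to its CP; drift magnitude is independent of |(dx,dy)|
  NumericVector pr(4, 0.25);
  double nrm = std::sqrt(dx * dx + dy * dy);
  if (nrm > 0) {
    double c = (2.0 * p - 1.0) / 4.0;
    double ux = dx / nrm, uy = dy / nrm;
    pr[0] += c * ux; pr[1] -= c * ux;
    pr[2] += c * uy; pr[3] -= c * uy;
  }
  return pr;
}

// ---------------------------------------------------------------- 1D model

// borders between the active-scent blocks of two animals on a ring.
// Returns (b01, b02, defined). b01: border met going clockwise (increasing
// site index) from animal 0's block; b02: the other interface.
static void borders_1d(const Scent &sc, double t, int nsites,
                       double *b01, double *b02, bool *def) {
  // effective owner per site
  std::vector<int> eff(nsites);
  bool has0 = false, has1 = false;
  for (int s = 0; s < nsites; ++s) {
    eff[s] = sc.active_owner(s, t);
    if (eff[s] == 0) has0 = true;
    if (eff[s] == 1) has1 = true;
  }
  *def = has0 && has1;
  if (!*def) { *b01 = NA_REAL; *b02 = NA_REAL; return; }
  // each animal's active set is a contiguous arc (sites visited within a
  // trailing time window of a continuous walk); find block ends
  auto block = [&](int who, int *lo, int *hi) {
    // find a site not owned by `who`, then scan for the run
    int start = -1;
    for (int s = 0; s < nsites; ++s) if (eff[s] != who) { start = s; break; }
    // start must exist (two non-empty disjoint blocks)
    int first = -1, last = -1;
    for (int k = 1; k <= nsites; ++k) {
      int s = imod(start + k, nsites);
      if (eff[s] == who) { if (first < 0) first = s; last = s; }
      else if (first >= 0) break;
    }
    *lo = first; *hi = last;
  };
  int a_lo, a_hi, b_lo, b_hi;
  block(0, &a_lo, &a_hi);
  block(1, &b_lo, &b_hi);
  // interface clockwise from animal 0's block end to animal 1's block start
  int g1 = imod(b_lo - a_hi, nsites);
  int g2 = imod(a_lo - b_hi, nsites);
  *b01 = a_hi + g1 / 2.0;            // midpoint of interstitial gap
  *b02 = b_hi + g2 / 2.0;
  if (*b01 >= nsites) *b01 -= nsites;
  if (*b02 >= nsites) *b02 -= nsites;
}

// [[Rcpp::export]]
List cpp_run_sim_1d(int nsites, IntegerVector cp, double p, double tas,
                    double jump_rate, int n_sweeps, int record_every,
                    bool record_positions) {
  const int na = cp.size();             // number of animals (2 in the paper)
  std::vector<int> pos(na);
  for (int i = 0; i < na; ++i) pos[i] = cp[i];
  Scent sc(nsites, tas);
  const double dt = 1.0 / (na * jump_rate);
  double t = 0.0;
  IntegerVector ord(na);
  for (int i = 0; i < na; ++i) ord[i] = i;

  int nrec = n_sweeps / record_every;
  NumericVector times(nrec);
  NumericMatrix P(record_positions ? nrec : 0, record_positions ? na : 0);
  NumericMatrix B(nrec, 2);
  LogicalVector Bdef(nrec);
  int rec = 0;

  // mark the starting sites
  for (int i = 0; i < na; ++i) sc.mark(pos[i], t, i);

  for (int sweep = 1; sweep <= n_sweeps; ++sweep) {
    permute(ord);
    for (int k = 0; k < na; ++k) {
      int i = ord[k];
      t += dt;
      // direction: towards CP along the shorter arc w.p. p
      double d = ring_disp(pos[i], cp[i], nsites);
      int towards;
      if (d == 0.0 || std::fabs(d) == nsites / 2.0)
        towards = (unif_rand() < 0.5) ? 1 : -1;
      else
        towards = (d > 0) ? 1 : -1;
      int step = (unif_rand() < p) ? towards : -towards;
      int target = imod(pos[i] + step, nsites);
      if (!sc.blocked(target, t, i)) pos[i] = target;
      sc.mark(pos[i], t, i);
    }
    if (sweep % record_every == 0) {
      times[rec] = t;
      if (record_positions)
        for (int i = 0; i < na; ++i) P(rec, i) = pos[i];
      double b1, b2; bool defd;
      borders_1d(sc, t, nsites, &b1, &b2, &defd);
      B(rec, 0) = b1; B(rec, 1) = b2; Bdef[rec] = defd;
      ++rec;
    }
  }

  IntegerVector owner(nsites);
  NumericVector age(nsites);
  for (int s = 0; s < nsites; ++s) {
    owner[s] = sc.active_owner(s, t);
    age[s] = (owner[s] >= 0) ? t - sc.mark_time[s] : NA_REAL;
  }
  return List::create(_["times"] = times, _["positions"] = P,
                      _["borders"] = B, _["border_defined"] = Bdef,
                      _["final_positions"] = IntegerVector(pos.begin(), pos.end()),
                      _["scent_owner"] = owner, _["scent_age"] = age,
                      _["t_final"] = t);
}

// ---------------------------------------------------------------- 2D model

// [[Rcpp::export]]
List cpp_run_sim_2d(int nx, int ny, IntegerVector cpx, IntegerVector cpy,
                    double p, double tas, double jump_rate, int n_sweeps,
                    int record_every, int n_rays, bool record_positions,
                    double ray_max) {
  const int na = cpx.size();
  std::vector<int> px(na), py(na);
  for (int i = 0; i < na; ++i) { px[i] = cpx[i]; py[i] = cpy[i]; }
  Scent sc(nx * ny, tas);
  const double dt = 1.0 / (na * jump_rate);
  double t = 0.0;
  IntegerVector ord(na);
  for (int i = 0; i < na; ++i) ord[i] = i;
  const double cbias = (2.0 * p - 1.0) / 4.0;

  int nrec = n_sweeps / record_every;
  NumericVector times(nrec);
  NumericMatrix PX(record_positions ? nrec : 0, record_positions ? na : 0),
      PY(record_positions ? nrec : 0, record_positions ? na : 0);
  NumericMatrix R(nrec, na * n_rays);   // radius profile, ray fastest
  int rec = 0;

  for (int i = 0; i < na; ++i) sc.mark(px[i] + nx * py[i], t, i);

  for (int sweep = 1; sweep <= n_sweeps; ++sweep) {
    permute(ord);
    for (int k = 0; k < na; ++k) {
      int i = ord[k];
      t += dt;
      double dx = ring_disp(px[i], cpx[i], nx);
      double dy = ring_disp(py[i], cpy[i], ny);
      double nrm = std::sqrt(dx * dx + dy * dy);
      double pr0 = 0.25, pr1 = 0.25, pr2 = 0.25;  // +x, -x, +y (last = -y)
      if (nrm > 0) {
        double ux = dx / nrm, uy = dy / nrm;
        pr0 += cbias * ux; pr1 -= cbias * ux; pr2 += cbias * uy;
      }
      double u = unif_rand();
      int sx = 0, sy = 0;
      if (u < pr0) sx = 1;
      else if (u < pr0 + pr1) sx = -1;
      else if (u < pr0 + pr1 + pr2) sy = 1;
      else sy = -1;
      int tx = imod(px[i] + sx, nx), ty = imod(py[i] + sy, ny);
      if (!sc.blocked(tx + nx * ty, t, i)) { px[i] = tx; py[i] = ty; }
      sc.mark(px[i] + nx * py[i], t, i);
    }
    if (sweep % record_every == 0) {
      times[rec] = t;
      if (record_positions)
        for (int i = 0; i < na; ++i) { PX(rec, i) = px[i]; PY(rec, i) = py[i]; }
      for (int i = 0; i < na; ++i) {
        for (int k = 0; k < n_rays; ++k) {
          // border radius along the bearing: midpoint of the interstitial
          // gap between the animal's farthest active claim and the nearest
          // foreign claim (the 1D border definition applied radially);
          // without foreign scent on the ray, the farthest own claim
          double th = 2.0 * M_PI * k / n_rays;
          double cs = std::cos(th), sn = std::sin(th);
          double r_own = 0.0, r_foreign = -1.0;
          for (double r = 0.0; r <= ray_max; r += 0.5) {
            int sxs = imod((int)std::lround(cpx[i] + r * cs), nx);
            int sys = imod((int)std::lround(cpy[i] + r * sn), ny);
            int o = sc.active_owner(sxs + nx * sys, t);
            if (o == i) r_own = r;
            else if (o >= 0) { r_foreign = r; break; }
          }
          R(rec, i * n_rays + k) =
              (r_foreign >= 0.0) ? (r_own + r_foreign) / 2.0 : r_own;
        }
      }
      ++rec;
    }
  }

  IntegerVector owner(nx * ny);
  for (int s = 0; s < nx * ny; ++s) owner[s] = sc.active_owner(s, t);
  return List::create(_["times"] = times, _["pos_x"] = PX, _["pos_y"] = PY,
                      _["radii"] = R,
                      _["final_x"] = IntegerVector(px.begin(), px.end()),
                      _["final_y"] = IntegerVector(py.begin(), py.end()),
                      _["scent_owner"] = owner, _["t_final"] = t);
}

// ------------------------------------------------- single-walker oracles

// biased walker on sites smin..smax (reflecting walls), CP at site 0;
// returns positions sampled every `thin` steps after `burn` steps
// [[Rcpp::export]]
IntegerVector cpp_walker_interval(int smin, int smax, double p,
                                  int n_samples, int thin, int burn) {
  int pos = 0;
  IntegerVector out(n_samples);
  long total = (long)burn + (long)n_samples * thin;
  int got = 0; long step_count = 0;
  for (long s = 0; s < total; ++s) {
    int towards = (pos > 0) ? -1 : (pos < 0 ? 1 : ((unif_rand() < 0.5) ? 1 : -1));
    int step = (unif_rand() < p) ? towards : -towards;
    int target = pos + step;
    if (target >= smin && target <= smax) pos = target;
    ++step_count;
    if (step_count > burn && (step_count - burn) % thin == 0) out[got++] = pos;
  }
  return out;
}

// biased 2D walker confined to the disc of radius R_sites around the CP
// [[Rcpp::export]]
NumericMatrix cpp_walker_disc(double R_sites, double p, int n_samples,
                              int thin, int burn) {
  int x = 0, y = 0;
  const double R2 = R_sites * R_sites;
  const double cbias = (2.0 * p - 1.0) / 4.0;
  NumericMatrix out(n_samples, 2);
  long total = (long)burn + (long)n_samples * thin;
  int got = 0;
  for (long s = 0; s < total; ++s) {
    double dx = -x, dy = -y;           // CP at the origin
    double nrm = std::sqrt(dx * dx + dy * dy);
    double pr0 = 0.25, pr1 = 0.25, pr2 = 0.25;
    if (nrm > 0) {
      double ux = dx / nrm, uy = dy / nrm;
      pr0 += cbias * ux; pr1 -= cbias * ux; pr2 += cbias * uy;
    }
    double u = unif_rand();
    int sx = 0, sy = 0;
    if (u < pr0) sx = 1;
    else if (u < pr0 + pr1) sx = -1;
    else if (u < pr0 + pr1 + pr2) sy = 1;
    else sy = -1;
    int tx = x + sx, ty = y + sy;
    if ((double)tx * tx + (double)ty * ty <= R2) { x = tx; y = ty; }
    if (s >= burn && (s - burn + 1) % thin == 0 && got < n_samples) {
      out(got, 0) = x; out(got, 1) = y; ++got;
    }
  }
  return out;
}
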