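#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Component state codes shared with R (see R/AllClasses.R):
// 0 ELEC, 1 POLY, 2 MGF2, 3 MGO, 4 MG, 5 PRODUCT
enum Comp { ELEC = 0, POLY = 1, MGF2 = 2, MGO = 3, MG = 4, PRODUCT = 5 };
static const int NCOMP = 6;

struct Params {
  double perm_poly;     // walker entry prob into intact polymer
  double hyd_poly;      // polymer hydrolysis prob given water contact
  double dis_mgf2, boost_mgf2;
  double dis_mgo,  boost_mgo;
  double dis_mg,   shielding;
  double dis_product;   // chloride attack on Mg(OH)2
  double res_h2o, res_cl, res_h;  // reservoir concentrations (walkers/cell)
  int reservoir_rows;   // replenished boundary rows at each face
  bool moore;
};

static Params read_params(const List& par) {
  Params p;
  p.perm_poly    = as<double>(par["perm_poly"]);
  p.hyd_poly     = as<double>(par["hyd_poly"]);
  p.dis_mgf2     = as<double>(par["dis_mgf2"]);
  p.boost_mgf2   = as<double>(par["boost_mgf2"]);
  p.dis_mgo      = as<double>(par["dis_mgo"]);
  p.boost_mgo    = as<double>(par["boost_mgo"]);
  p.dis_mg       = as<double>(par["dis_mg"]);
  p.shielding    = as<double>(par["shielding"]);
  p.dis_product  = as<double>(par["dis_product"]);
  p.res_h2o      = as<double>(par["res_h2o"]);
  p.res_cl       = as<double>(par["res_cl"]);
  p.res_h        = as<double>(par["res_h"]);
  p.reservoir_rows = as<int>(par["reservoir_rows"]);
  p.moore        = as<bool>(par["moore"]);
  return p;
}

// Neighbor offsets for the configured neighborhood and dimensionality.
// von Neumann: 4 in 2D, 6 in 3D; Moore: 8 in 2D, 26 in 3D.
static void build_offsets(bool moore, int nd,
                          std::vector<int>& dr, std::vector<int>& dc,
                          std::vector<int>& dz) {
  dr.clear(); dc.clear(); dz.clear();
  int zr = (nd > 1) ? 1 : 0;
  for (int z = -zr; z <= zr; ++z)
    for (int r = -1; r <= 1; ++r)
      for (int c = -1; c <= 1; ++c) {
        if (r == 0 && c == 0 && z == 0) continue;
        int manh = std::abs(r) + std::abs(c) + std::abs(z);
        if (!moore && manh != 1) continue;
        dr.push_back(r); dc.push_back(c); dz.push_back(z);
      }
}

struct Grid {
  int nr, nc, nd, n;
  inline int idx(int r, int c, int z) const { return r + nr * (c + nc * z); }
};

// Scratch buffers reused across steps of a run.
struct Scratch {
  std::vector<int> nw;       // transport accumulator
  std::vector<int> S0;       // frozen pre-reaction state
  std::vector<int> nb;       // linear neighbor index buffer (per cell)
  long wsum, csum, hsum;     // walker totals, updated as we go
};

// One synchronous random-walk sweep for a single species. Each walker picks
// a uniform random neighbor; moves into ELEC always, into POLY with the
// permeation probability, never into other solids; blocked walkers stay.
static long transport_species(std::vector<int>& sp, const int* state,
                              const Grid& g, const std::vector<int>& dr,
                              const std::vector<int>& dc,
                              const std::vector<int>& dz, double perm_poly,
                              std::vector<int>& nw) {
  const int ndirs = (int)dr.size();
  long total = 0;
  nw.assign(g.n, 0);
  for (int z = 0; z < g.nd; ++z)
    for (int c = 0; c < g.nc; ++c) {
      const int base = g.nr * (c + g.nc * z);
      for (int r = 0; r < g.nr; ++r) {
        const int i = base + r;
        const int cnt = sp[i];
        if (cnt == 0) continue;
        if (state[i] != ELEC && state[i] != POLY)
          stop("internal corruption: walker found inside an inorganic cell");
        total += cnt;
        for (int k = 0; k < cnt; ++k) {
          int j = (int)(unif_rand() * ndirs);
          if (j == ndirs) j = ndirs - 1;
          const int rr = r + dr[j], cc = c + dc[j], zz = z + dz[j];
          if (rr < 0 || rr >= g.nr || cc < 0 || cc >= g.nc ||
              zz < 0 || zz >= g.nd) { nw[i]++; continue; }
          const int t = g.idx(rr, cc, zz);
          const int st = state[t];
          if (st == ELEC) nw[t]++;
          else if (st == POLY && unif_rand() < perm_poly) nw[t]++;
          else nw[i]++;
        }
      }
    }
  sp.swap(nw);
  return total;
}

static inline int conc_draw(double conc) {
  int base = (int)std::floor(conc);
  double frac = conc - base;
  if (frac > 0 && unif_rand() < frac) base++;
  return base;
}

// Reset the electrolyte cells of the boundary reservoir rows to the bulk
// concentrations, keeping the walker totals in sync. Solid cells in those
// rows (one-face fixtures) are left alone.
static void replenish(std::vector<int>& h2o, std::vector<int>& cl,
                      std::vector<int>& h, const int* state, const Grid& g,
                      const Params& p, Scratch& sc) {
  if (p.reservoir_rows <= 0) return;
  for (int z = 0; z < g.nd; ++z)
    for (int c = 0; c < g.nc; ++c) {
      const int lo = std::min(p.reservoir_rows, g.nr);
      for (int r = 0; r < lo; ++r) {
        const int i = g.idx(r, c, z);
        if (state[i] != ELEC) continue;
        int w = conc_draw(p.res_h2o), cc2 = conc_draw(p.res_cl),
            hh = conc_draw(p.res_h);
        sc.wsum += w - h2o[i]; sc.csum += cc2 - cl[i]; sc.hsum += hh - h[i];
        h2o[i] = w; cl[i] = cc2; h[i] = hh;
      }
      for (int r = std::max(0, g.nr - p.reservoir_rows); r < g.nr; ++r) {
        const int i = g.idx(r, c, z);
        if (state[i] != ELEC) continue;
        int w = conc_draw(p.res_h2o), cc2 = conc_draw(p.res_cl),
            hh = conc_draw(p.res_h);
        sc.wsum += w - h2o[i]; sc.csum += cc2 - cl[i]; sc.hsum += hh - h[i];
        h2o[i] = w; cl[i] = cc2; h[i] = hh;
      }
    }
}

// Reaction phase evaluated on a frozen copy of the post-transport state.
// Events vector: [hydrolysis, mgf2, mgo, mg->product, product dissolution].
// The per-state neighbor scans terminate as soon as the deciding condition
// is met, which keeps the sweep cheap on the (dominant) bulk cells.
static void react(std::vector<int>& state, const std::vector<int>& h2o,
                  const std::vector<int>& cl, const std::vector<int>& h,
                  const Grid& g, const Params& p, const std::vector<int>& dr,
                  const std::vector<int>& dc, const std::vector<int>& dz,
                  std::vector<int>& events,
                  std::vector<std::pair<int,int> >& transitions,
                  Scratch& sc) {
  sc.S0 = state;  // frozen
  const std::vector<int>& S0 = sc.S0;
  const int ndirs = (int)dr.size();
  transitions.clear();
  std::vector<int>& nb = sc.nb;
  nb.resize(ndirs);
  for (int z = 0; z < g.nd; ++z)
    for (int c = 0; c < g.nc; ++c) {
      const int base = g.nr * (c + g.nc * z);
      const bool cedge = (c == 0 || c == g.nc - 1);
      const bool zedge = (g.nd > 1) && (z == 0 || z == g.nd - 1);
      for (int r = 0; r < g.nr; ++r) {
        const int i = base + r;
        const int st = S0[i];
        if (st == ELEC) continue;
        // neighbor index list (edge cells take the checked path)
        int nn = 0;
        if (!cedge && !zedge && r > 0 && r < g.nr - 1) {
          for (int j = 0; j < ndirs; ++j)
            nb[nn++] = i + dr[j] + g.nr * (dc[j] + g.nc * dz[j]);
        } else {
          for (int j = 0; j < ndirs; ++j) {
            const int rr = r + dr[j], cc = c + dc[j], zz = z + dz[j];
            if (rr < 0 || rr >= g.nr || cc < 0 || cc >= g.nc ||
                zz < 0 || zz >= g.nd) continue;
            nb[nn++] = g.idx(rr, cc, zz);
          }
        }
        double prob = 0.0;
        int newst = -1;
        switch (st) {
        case POLY: {
          bool water = h2o[i] > 0;
          for (int k = 0; k < nn && !water; ++k) water = h2o[nb[k]] > 0;
          if (water) { prob = p.hyd_poly; newst = ELEC; }
          break;
        }
        case MGF2: case MGO: {
          bool water_elec = false;
          for (int k = 0; k < nn && !water_elec; ++k)
            water_elec = (S0[nb[k]] == ELEC && h2o[nb[k]] > 0);
          if (water_elec) {
            bool acid = false;
            for (int k = 0; k < nn && !acid; ++k) acid = h[nb[k]] > 0;
            prob = (st == MGF2)
              ? p.dis_mgf2 * (acid ? p.boost_mgf2 : 1.0)
              : p.dis_mgo * (acid ? p.boost_mgo : 1.0);
            newst = ELEC;
          }
          break;
        }
        case MG: {
          bool water_elec = false, prod_nb = false;
          for (int k = 0; k < nn && !water_elec; ++k) {
            const int s = S0[nb[k]];
            if (s == ELEC) { if (h2o[nb[k]] > 0) water_elec = true; }
            else if (s == PRODUCT) prod_nb = true;
          }
          if (water_elec) { prob = p.dis_mg; newst = PRODUCT; }
          else if (prod_nb) {
            prob = p.dis_mg * p.shielding; newst = PRODUCT;
          }
          break;
        }
        case PRODUCT: {
          bool cl_nb = false;
          for (int k = 0; k < nn && !cl_nb; ++k) cl_nb = cl[nb[k]] > 0;
          if (cl_nb) { prob = p.dis_product; newst = ELEC; }
          break;
        }
        }
        if (newst < 0) continue;
        if (prob > 1.0) prob = 1.0;
        if (prob > 0.0 && unif_rand() < prob) {
          state[i] = newst;
          transitions.push_back(std::make_pair(i, st));
          int ev = (st == POLY) ? 0 : (st == MGF2) ? 1 : (st == MGO) ? 2
                   : (st == MG) ? 3 : 4;
          events[ev]++;
        }
      }
    }
}

static void do_step(std::vector<int>& state, std::vector<int>& h2o,
                    std::vector<int>& cl, std::vector<int>& h, const Grid& g,
                    const Params& p, const std::vector<int>& dr,
                    const std::vector<int>& dc, const std::vector<int>& dz,
                    std::vector<int>& events,
                    std::vector<std::pair<int,int> >& transitions,
                    Scratch& sc) {
  sc.wsum = transport_species(h2o, state.data(), g, dr, dc, dz,
                              p.perm_poly, sc.nw);
  sc.csum = transport_species(cl, state.data(), g, dr, dc, dz,
                              p.perm_poly, sc.nw);
  sc.hsum = transport_species(h, state.data(), g, dr, dc, dz,
                              p.perm_poly, sc.nw);
  replenish(h2o, cl, h, state.data(), g, p, sc);
  std::fill(events.begin(), events.end(), 0);
  react(state, h2o, cl, h, g, p, dr, dc, dz, events, transitions, sc);
}

static std::vector<int> as_vec(const IntegerVector& v) {
  return std::vector<int>(v.begin(), v.end());
}
static IntegerVector as_iv(const std::vector<int>& v, IntegerVector dimv) {
  IntegerVector out(v.begin(), v.end());
  out.attr("dim") = dimv;
  return out;
}

// [[Rcpp::export]]
List ca_step_cpp(IntegerVector state, IntegerVector h2o, IntegerVector cl,
                 IntegerVector h, int nr, int nc, int nd, List par) {
  Grid g; g.nr = nr; g.nc = nc; g.nd = nd; g.n = nr * nc * nd;
  if (state.size() != g.n) stop("state length does not match dimensions");
  Params p = read_params(par);
  std::vector<int> dr, dc, dz;
  build_offsets(p.moore, nd, dr, dc, dz);
  std::vector<int> S = as_vec(state), W = as_vec(h2o), C = as_vec(cl),
                   H = as_vec(h);
  std::vector<int> events(5, 0);
  std::vector<std::pair<int,int> > transitions;
  Scratch sc;
  do_step(S, W, C, H, g, p, dr, dc, dz, events, transitions, sc);
  IntegerVector dimv = IntegerVector::create(nr, nc, nd);
  return List::create(
    _["state"] = as_iv(S, dimv), _["h2o"] = as_iv(W, dimv),
    _["cl"] = as_iv(C, dimv), _["h"] = as_iv(H, dimv),
    _["events"] = IntegerVector(events.begin(), events.end()),
    _["walkers"] = NumericVector::create((double)sc.wsum, (double)sc.csum,
                                         (double)sc.hsum));
}

// Full run: iterates the step kernel, maintaining per-region component
// counts incrementally (updated only at transitions) and recording
// per-step event/walker reports and periodic state snapshots.
// [[Rcpp::export]]
List ca_run_cpp(IntegerVector state, IntegerVector h2o, IntegerVector cl,
                IntegerVector h, int nr, int nc, int nd, int steps, List par,
                List region_masks, int snapshot_every) {
  Grid g; g.nr = nr; g.nc = nc; g.nd = nd; g.n = nr * nc * nd;
  if (state.size() != g.n) stop("state length does not match dimensions");
  Params p = read_params(par);
  std::vector<int> dr, dc, dz;
  build_offsets(p.moore, nd, dr, dc, dz);
  std::vector<int> S = as_vec(state), W = as_vec(h2o), C = as_vec(cl),
                   H = as_vec(h);

  const int nreg = region_masks.size();
  if (nreg > 31) stop("too many region masks");
  std::vector<unsigned int> member(g.n, 0u);
  for (int m = 0; m < nreg; ++m) {
    LogicalVector msk = region_masks[m];
    if (msk.size() != g.n) stop("region mask length mismatch");
    for (int i = 0; i < g.n; ++i)
      if (msk[i]) member[i] |= (1u << m);
  }
  // counts[(t * NCOMP + comp) * nreg + m]
  std::vector<double> counts((size_t)(steps + 1) * NCOMP * nreg, 0.0);
  std::vector<long> cur(NCOMP * nreg, 0);
  for (int i = 0; i < g.n; ++i)
    for (int m = 0; m < nreg; ++m)
      if (member[i] & (1u << m)) cur[S[i] * nreg + m]++;
  for (int k = 0; k < NCOMP * nreg; ++k) counts[k] = (double)cur[k];

  NumericMatrix reports(steps, 8);  // 5 event counts + 3 walker totals
  std::vector<int> events(5, 0);
  std::vector<std::pair<int,int> > transitions;
  Scratch sc;
  List snapshots;
  IntegerVector snap_steps;
  IntegerVector dimv = IntegerVector::create(nr, nc, nd);

  for (int t = 1; t <= steps; ++t) {
    do_step(S, W, C, H, g, p, dr, dc, dz, events, transitions, sc);
    for (size_t k = 0; k < transitions.size(); ++k) {
      int i = transitions[k].first, olds = transitions[k].second;
      int news = S[i];
      unsigned int mb = member[i];
      for (int m = 0; m < nreg; ++m)
        if (mb & (1u << m)) {
          cur[olds * nreg + m]--;
          cur[news * nreg + m]++;
        }
    }
    size_t off = (size_t)t * NCOMP * nreg;
    for (int k = 0; k < NCOMP * nreg; ++k) counts[off + k] = (double)cur[k];
    for (int e = 0; e < 5; ++e) reports(t - 1, e) = events[e];
    reports(t - 1, 5) = (double)sc.wsum;
    reports(t - 1, 6) = (double)sc.csum;
    reports(t - 1, 7) = (double)sc.hsum;
    if (snapshot_every > 0 && (t % snapshot_every == 0 || t == steps)) {
      snapshots.push_back(as_iv(S, dimv));
      snap_steps.push_back(t);
    }
  }

  NumericVector counts_out(counts.begin(), counts.end());
  counts_out.attr("dim") = IntegerVector::create(nreg, NCOMP, steps + 1);
  return List::create(
    _["counts"] = counts_out, _["reports"] = reports,
    _["state"] = as_iv(S, dimv), _["h2o"] = as_iv(W, dimv),
    _["cl"] = as_iv(C, dimv), _["h"] = as_iv(H, dimv),
    _["snapshots"] = snapshots, _["snapshot_steps"] = snap_steps);
}
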