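// Spatial chemical-Langevin engine for the multicellular circuit variants.
//
// Cells live on a 2-D lattice, carry intracellular concentration vectors
// advanced by a two-stage (Heun) stochastic Runge-Kutta discretisation of the
// chemical Langevin equation, and communicate through diffusing extracellular
// fields (AI1 secreted by uncommitted cells, AI2 by committed cells, AI3 by
// the throttle). Division, commitment and death are discrete events.
// All randomness is counter-based (rng.h): independent of iteration order.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include "rng.h"

using namespace Rcpp;

static inline double hact(double x, double K, double n) {
  if (x <= 0.0) return 0.0;
  double u = std::pow(x / K, n);
  return u / (1.0 + u);
}
static inline double hinh(double x, double K, double n) {
  if (x <= 0.0) return 1.0;
  return 1.0 / (1.0 + std::pow(x / K, n));
}

struct CircuitPars {
  int system;
  // quorum-sensing readouts (UPC: U senses AI1; CPC: V senses AI2)
  double k_U, K_U, n_U, k_V, K_V, n_V;
  // toggle switch
  double k_T, d_T, K_T, n_T, k_W;
  // oscillator (system 3)
  double a_A, b_A, d_A, K_AA, K_R, a_R, d_R, K_AR, n_osc, K_gate, n_gate;
  // throttle (system 4)
  double s3, K_act, n_act, K_rep, n_rep;
  // fields
  double s1, s2, D1, D2, D3, kdeg1, kdeg2, kdeg3;
  // population events
  double k_div, k_kill, theta_G, n_G;
  // commitment rule
  double c_commit;
  int debounce;
};

static double getd(const List& p, const char* nm) {
  if (!p.containsElementNamed(nm)) stop(std::string("missing parameter: ") + nm);
  return as<double>(p[nm]);
}

static CircuitPars parse_pars(int system, const List& p) {
  CircuitPars c;
  c.system = system;
  c.k_U = getd(p, "k_U"); c.K_U = getd(p, "K_U"); c.n_U = getd(p, "n_U");
  c.k_V = getd(p, "k_V"); c.K_V = getd(p, "K_V"); c.n_V = getd(p, "n_V");
  c.k_T = getd(p, "k_T"); c.d_T = getd(p, "d_T"); c.K_T = getd(p, "K_T");
  c.n_T = getd(p, "n_T"); c.k_W = getd(p, "k_W");
  c.a_A = getd(p, "a_A"); c.b_A = getd(p, "b_A"); c.d_A = getd(p, "d_A");
  c.K_AA = getd(p, "K_AA"); c.K_R = getd(p, "K_R"); c.a_R = getd(p, "a_R");
  c.d_R = getd(p, "d_R"); c.K_AR = getd(p, "K_AR"); c.n_osc = getd(p, "n_osc");
  c.K_gate = getd(p, "K_gate"); c.n_gate = getd(p, "n_gate");
  c.s3 = getd(p, "s3"); c.K_act = getd(p, "K_act"); c.n_act = getd(p, "n_act");
  c.K_rep = getd(p, "K_rep"); c.n_rep = getd(p, "n_rep");
  c.s1 = getd(p, "s1"); c.s2 = getd(p, "s2");
  c.D1 = getd(p, "D1"); c.D2 = getd(p, "D2"); c.D3 = getd(p, "D3");
  c.kdeg1 = getd(p, "kdeg1"); c.kdeg2 = getd(p, "kdeg2"); c.kdeg3 = getd(p, "kdeg3");
  c.k_div = getd(p, "k_div"); c.k_kill = getd(p, "k_kill");
  c.theta_G = getd(p, "theta_G"); c.n_G = getd(p, "n_G");
  c.c_commit = getd(p, "c_commit");
  c.debounce = (int)getd(p, "debounce");
  return c;
}

static int n_species(int system) { return system == 3 ? 6 : 4; }
// species order: 0 U, 1 V, 2 Ton, 3 Toff, [4 A, 5 R]

// production/degradation rates of one cell given its local field levels.
// clamp_w >= 0 substitutes the AND-gate drive U*V (isolation harnesses);
// clamp_r >= 0 substitutes the oscillator repressor level seen by the gate.
static void cell_rates(const CircuitPars& c, const double* x,
                       double ai1, double ai2, double ai3,
                       double clamp_w, double clamp_r,
                       double* prod, double* deg, double* w_out) {
  int NS = n_species(c.system);
  double U = x[0], V = x[1], Ton = x[2], Toff = x[3];
  prod[0] = c.k_U * hact(ai1, c.K_U, c.n_U);  deg[0] = c.k_U * U;
  prod[1] = c.k_V * hinh(ai2, c.K_V, c.n_V);  deg[1] = c.k_V * V;
  double w = (clamp_w >= 0.0) ? clamp_w : U * V;
  if (c.system == 3) {
    double A = x[4], R = x[5];
    prod[4] = c.a_A * hact(A, c.K_AA, c.n_osc) * hinh(R, c.K_R, c.n_osc) + c.b_A;
    deg[4] = c.d_A * A;
    prod[5] = c.a_R * hact(A, c.K_AR, c.n_osc);
    deg[5] = c.d_R * R;
    double Rg = (clamp_r >= 0.0) ? clamp_r : R;
    w *= hinh(Rg, c.K_gate, c.n_gate);
  } else if (c.system == 4) {
    w *= hinh(ai3, c.K_rep, c.n_rep);
  }
  prod[2] = c.k_T * hinh(Toff, c.K_T, c.n_T) + c.k_W * w;
  deg[2] = c.d_T * Ton;
  prod[3] = c.k_T * hinh(Ton, c.K_T, c.n_T);
  deg[3] = c.d_T * Toff;
  (void)NS;
  *w_out = w;
}

// [[Rcpp::export]]
List cpp_cell_rates(int system, List pars, NumericVector x,
                    double ai1, double ai2, double ai3,
                    double clamp_w = -1.0, double clamp_r = -1.0) {
  CircuitPars c = parse_pars(system, pars);
  int NS = n_species(system);
  if ((int)x.size() != NS) stop("state length must be %d for system %d", NS, system);
  std::vector<double> prod(NS), deg(NS);
  double w;
  cell_rates(c, x.begin(), ai1, ai2, ai3, clamp_w, clamp_r, prod.data(), deg.data(), &w);
  return List::create(_["prod"] = NumericVector(prod.begin(), prod.end()),
                      _["deg"] = NumericVector(deg.begin(), deg.end()),
                      _["drive"] = w);
}

// one Heun step of the chemical Langevin equation for one cell
static void langevin_step_cell(const CircuitPars& c, double* x,
                               double ai1, double ai2, double ai3,
                               double clamp_w, double clamp_r,
                               double dt, double inv_sqrt_omega,
                               uint64_t seed, uint64_t step, uint64_t stream) {
  int NS = n_species(c.system);
  double prod0[6], deg0[6], prod1[6], deg1[6], noise[6], xt[6], w;
  cell_rates(c, x, ai1, ai2, ai3, clamp_w, clamp_r, prod0, deg0, &w);
  for (int s = 0; s < NS; ++s) {
    double z1, z2;
    norm2(seed, step, stream, (uint64_t)s, &z1, &z2);
    noise[s] = inv_sqrt_omega *
      (std::sqrt(std::max(prod0[s], 0.0) * dt) * z1 -
       std::sqrt(std::max(deg0[s], 0.0) * dt) * z2);
    xt[s] = x[s] + (prod0[s] - deg0[s]) * dt + noise[s];
    if (xt[s] < 0.0) xt[s] = 0.0;
    if (!std::isfinite(xt[s])) stop("non-finite state in species %d", s);
  }
  cell_rates(c, xt, ai1, ai2, ai3, clamp_w, clamp_r, prod1, deg1, &w);
  for (int s = 0; s < NS; ++s) {
    double f0 = prod0[s] - deg0[s], f1 = prod1[s] - deg1[s];
    x[s] = x[s] + 0.5 * (f0 + f1) * dt + noise[s];
    if (x[s] < 0.0) x[s] = 0.0;
    if (!std::isfinite(x[s])) stop("non-finite state in species %d", s);
  }
}

// [[Rcpp::export]]
NumericMatrix cpp_single_cell(int system, List pars, NumericVector x0,
                              double ai1, double ai2, double ai3,
                              double T, double dt, double omega, int seed,
                              int out_every, double clamp_w = -1.0,
                              double clamp_r = -1.0) {
  CircuitPars c = parse_pars(system, pars);
  int NS = n_species(system);
  if ((int)x0.size() != NS) stop("state length must be %d", NS);
  int n_steps = (int)std::ceil(T / dt);
  int n_out = n_steps / out_every + 1;
  NumericMatrix out(n_out, NS + 1);
  std::vector<double> x(x0.begin(), x0.end());
  double isq = (omega > 0) ? 1.0 / std::sqrt(omega) : 0.0;
  int row = 0;
  out(row, 0) = 0.0;
  for (int s = 0; s < NS; ++s) out(row, s + 1) = x[s];
  ++row;
  for (int step = 1; step <= n_steps; ++step) {
    langevin_step_cell(c, x.data(), ai1, ai2, ai3, clamp_w, clamp_r, dt, isq,
                       (uint64_t)seed, (uint64_t)step, 1ULL);
    if (step % out_every == 0 && row < n_out) {
      out(row, 0) = step * dt;
      for (int s = 0; s < NS; ++s) out(row, s + 1) = x[s];
      ++row;
    }
  }
  return out;
}

// explicit 5-point Laplacian with no-flux boundaries, degradation and source
static void diffuse(std::vector<double>& f, int nr, int nc, double D,
                    double kdeg, double dt, double h,
                    const std::vector<double>& src) {
  static std::vector<double> g;
  g.assign(f.begin(), f.end());
  double a = D * dt / (h * h);
  for (int i = 0; i < nr; ++i) {
    for (int j = 0; j < nc; ++j) {
      int id = i * nc + j;
      double up = g[(i > 0 ? i - 1 : i) * nc + j];
      double dn = g[(i < nr - 1 ? i + 1 : i) * nc + j];
      double lf = g[i * nc + (j > 0 ? j - 1 : j)];
      double rt = g[i * nc + (j < nc - 1 ? j + 1 : j)];
      double lap = up + dn + lf + rt - 4.0 * g[id];
      f[id] = g[id] + a * lap - kdeg * g[id] * dt + src[id] * dt;
      if (f[id] < 0.0) f[id] = 0.0;
    }
  }
}

// [[Rcpp::export]]
NumericMatrix cpp_diffuse_step(NumericMatrix field, double D, double kdeg,
                               double dt, double h, NumericMatrix source) {
  int nr = field.nrow(), nc = field.ncol();
  if (dt > h * h / (4.0 * D) + 1e-12 && D > 0)
    stop("diffusion stability bound violated: dt must be <= h^2/(4 D)");
  std::vector<double> f(nr * nc), s(nr * nc);
  for (int i = 0; i < nr; ++i)
    for (int j = 0; j < nc; ++j) { f[i * nc + j] = field(i, j); s[i * nc + j] = source(i, j); }
  diffuse(f, nr, nc, D, kdeg, dt, h, s);
  NumericMatrix out(nr, nc);
  for (int i = 0; i < nr; ++i)
    for (int j = 0; j < nc; ++j) out(i, j) = f[i * nc + j];
  return out;
}

struct Cell {
  int id, row, col, type;  // type: 0 uncommitted, 1 committed, 2 dead
  double commit_time;
  int debounce;
  double x[6];
};

// [[Rcpp::export]]
List cpp_engine_run(int system, List pars, int nrow_, int ncol_, double h,
                    double dt, double T, int out_every, int snap_every,
                    double omega, int seed, int n0, int trace_max) {
  CircuitPars c = parse_pars(system, pars);
  int NS = n_species(system);
  int nsites = nrow_ * ncol_;
  double maxD = std::max(c.D1, std::max(c.D2, system == 4 ? c.D3 : 0.0));
  if (maxD > 0 && dt > h * h / (4.0 * maxD) + 1e-12)
    stop("diffusion stability bound violated: dt must be <= h^2/(4 max D)");
  if (c.k_div * dt > 0.2 || c.k_kill * dt > 0.2)
    stop("per-step event probability exceeds 0.2; decrease dt");

  std::vector<int> lattice(nsites, -1);
  std::vector<Cell> cells;
  cells.reserve(4 * nsites);
  // initial seeding: n0 uncommitted cells in a centred block
  {
    int side = (int)std::ceil(std::sqrt((double)n0));
    int r0 = nrow_ / 2 - side / 2, c0 = ncol_ / 2 - side / 2, placed = 0;
    for (int i = 0; i < side && placed < n0; ++i)
      for (int j = 0; j < side && placed < n0; ++j) {
        int r = r0 + i, cc = c0 + j;
        if (r < 0 || r >= nrow_ || cc < 0 || cc >= ncol_) continue;
        Cell cl; cl.id = (int)cells.size() + 1; cl.row = r; cl.col = cc;
        cl.type = 0; cl.commit_time = NA_REAL; cl.debounce = 0;
        for (int s = 0; s < 6; ++s) cl.x[s] = 0.0;
        cl.x[3] = 1.0;  // toggle starts in the off state
        lattice[r * ncol_ + cc] = (int)cells.size();
        cells.push_back(cl);
        ++placed;
      }
  }

  std::vector<double> ai1(nsites, 0.0), ai2(nsites, 0.0), ai3(nsites, 0.0);
  std::vector<double> src1(nsites), src2(nsites), src3(nsites);

  int n_steps = (int)std::ceil(T / dt);
  int n_out = n_steps / out_every + 1;
  double isq = (omega > 0) ? 1.0 / std::sqrt(omega) : 0.0;

  NumericVector out_time(n_out);
  IntegerVector out_unc(n_out), out_com(n_out);
  std::vector<double> tr_time; std::vector<int> tr_id, tr_type;
  std::vector<double> tr_x; tr_x.reserve((size_t)n_out * trace_max * NS);
  std::vector<double> ev_time; std::vector<int> ev_kind, ev_id, ev_row, ev_col, ev_parent;
  std::vector<double> snap_time;
  std::vector<IntegerMatrix> snap_type;
  std::vector<NumericMatrix> snap_ai1, snap_ai2, snap_ai3;
  bool extinct = false;

  const int dr[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
  const int dc[8] = {-1, 0, 1, -1, 1, -1, 0, 1};

  auto record_output = [&](int row_i, int step) {
    out_time[row_i] = step * dt;
    int nu = 0, ncm = 0, traced = 0;
    for (auto& cl : cells) {
      if (cl.type == 0) ++nu; else if (cl.type == 1) ++ncm;
      if (cl.type != 2 && traced < trace_max) {
        tr_time.push_back(step * dt); tr_id.push_back(cl.id); tr_type.push_back(cl.type);
        for (int s = 0; s < NS; ++s) tr_x.push_back(cl.x[s]);
        ++traced;
      }
    }
    out_unc[row_i] = nu; out_com[row_i] = ncm;
  };
  auto record_snapshot = [&](int step) {
    IntegerMatrix tm(nrow_, ncol_);
    NumericMatrix f1(nrow_, ncol_), f2(nrow_, ncol_), f3(nrow_, ncol_);
    for (int i = 0; i < nrow_; ++i)
      for (int j = 0; j < ncol_; ++j) {
        int idx = lattice[i * ncol_ + j];
        tm(i, j) = idx < 0 ? NA_INTEGER : cells[idx].type;
        f1(i, j) = ai1[i * ncol_ + j];
        f2(i, j) = ai2[i * ncol_ + j];
        f3(i, j) = ai3[i * ncol_ + j];
      }
    snap_time.push_back(step * dt);
    snap_type.push_back(tm); snap_ai1.push_back(f1); snap_ai2.push_back(f2);
    if (system == 4) snap_ai3.push_back(f3);
  };

  record_output(0, 0);
  record_snapshot(0);
  int out_row = 1;

  for (int step = 1; step <= n_steps; ++step) {
    // (1) fields: secretion sources from current cells, then diffusion
    std::fill(src1.begin(), src1.end(), 0.0);
    std::fill(src2.begin(), src2.end(), 0.0);
    std::fill(src3.begin(), src3.end(), 0.0);
    for (auto& cl : cells) {
      if (cl.type == 2) continue;
      int id = cl.row * ncol_ + cl.col;
      if (cl.type == 0) {
        src1[id] += c.s1;
        if (system == 4) src3[id] += c.s3 * hact(cl.x[2], c.K_act, c.n_act);
      } else {
        src2[id] += c.s2;
      }
    }
    diffuse(ai1, nrow_, ncol_, c.D1, c.kdeg1, dt, h, src1);
    diffuse(ai2, nrow_, ncol_, c.D2, c.kdeg2, dt, h, src2);
    if (system == 4) diffuse(ai3, nrow_, ncol_, c.D3, c.kdeg3, dt, h, src3);

    // (2) intracellular Langevin update
    for (auto& cl : cells) {
      if (cl.type == 2) continue;
      int id = cl.row * ncol_ + cl.col;
      langevin_step_cell(c, cl.x, ai1[id], ai2[id], ai3[id], -1.0, -1.0, dt,
                         isq, (uint64_t)seed, (uint64_t)step, (uint64_t)cl.id);
    }

    // (3) discrete events
    size_t ncur = cells.size();
    for (size_t ci = 0; ci < ncur; ++ci) {
      Cell& cl = cells[ci];
      if (cl.type == 2) continue;
      int id = cl.row * ncol_ + cl.col;
      double u = u01((uint64_t)seed, (uint64_t)step, (uint64_t)cl.id, 1000ULL);
      if (cl.type == 0) {
        double p_div = c.k_div * hinh(ai1[id], c.theta_G, c.n_G) * dt;
        if (u < p_div) {
          int empties[8], ne = 0;
          for (int k = 0; k < 8; ++k) {
            int r = cl.row + dr[k], cc = cl.col + dc[k];
            if (r >= 0 && r < nrow_ && cc >= 0 && cc < ncol_ &&
                lattice[r * ncol_ + cc] < 0) empties[ne++] = k;
          }
          if (ne > 0) {
            double u2 = u01((uint64_t)seed, (uint64_t)step, (uint64_t)cl.id, 1001ULL);
            int k = empties[(int)(u2 * ne) < ne ? (int)(u2 * ne) : ne - 1];
            Cell d; d.id = (int)cells.size() + 1;
            d.row = cl.row + dr[k]; d.col = cl.col + dc[k];
            d.type = 0; d.commit_time = NA_REAL; d.debounce = 0;
            for (int s = 0; s < 6; ++s) d.x[s] = cl.x[s];
            lattice[d.row * ncol_ + d.col] = (int)cells.size();
            ev_time.push_back(step * dt); ev_kind.push_back(1);
            ev_id.push_back(d.id); ev_row.push_back(d.row); ev_col.push_back(d.col);
            ev_parent.push_back(cl.id);
            cells.push_back(d);  // may reallocate: stop using cl after this
          }
        }
      } else if (cl.type == 1) {
        if (u < c.k_kill * dt) {
          cl.type = 2;
          lattice[id] = -1;
          ev_time.push_back(step * dt); ev_kind.push_back(3);
          ev_id.push_back(cl.id); ev_row.push_back(cl.row); ev_col.push_back(cl.col);
          ev_parent.push_back(NA_INTEGER);
        }
      }
    }

    // commitment check with debounce, evaluated at output boundaries
    if (step % out_every == 0) {
      for (auto& cl : cells) {
        if (cl.type != 0) continue;
        if (cl.x[2] >= c.c_commit) {
          if (++cl.debounce >= c.debounce) {
            cl.type = 1;
            cl.commit_time = step * dt;
            ev_time.push_back(step * dt); ev_kind.push_back(2);
            ev_id.push_back(cl.id); ev_row.push_back(cl.row); ev_col.push_back(cl.col);
            ev_parent.push_back(NA_INTEGER);
          }
        } else {
          cl.debounce = 0;
        }
      }
      if (out_row < n_out) record_output(out_row++, step);
    }
    if (snap_every > 0 && step % snap_every == 0) record_snapshot(step);

    bool any_alive = false;
    for (auto& cl : cells) if (cl.type != 2) { any_alive = true; break; }
    if (!any_alive) {
      extinct = true;
      for (; out_row < n_out; ++out_row) out_time[out_row] = NA_REAL;
      break;
    }
  }

  int nt = (int)tr_id.size();
  NumericMatrix traces(nt, NS);
  for (int i = 0; i < nt; ++i)
    for (int s = 0; s < NS; ++s) traces(i, s) = tr_x[(size_t)i * NS + s];

  DataFrame events = DataFrame::create(
    _["time"] = NumericVector(ev_time.begin(), ev_time.end()),
    _["kind"] = IntegerVector(ev_kind.begin(), ev_kind.end()),
    _["cell_id"] = IntegerVector(ev_id.begin(), ev_id.end()),
    _["row"] = IntegerVector(ev_row.begin(), ev_row.end()),
    _["col"] = IntegerVector(ev_col.begin(), ev_col.end()),
    _["parent_id"] = IntegerVector(ev_parent.begin(), ev_parent.end()));

  // final cell table
  int ncells = (int)cells.size();
  IntegerVector cid(ncells), crow(ncells), ccol(ncells), ctype(ncells);
  NumericVector ctime(ncells);
  for (int i = 0; i < ncells; ++i) {
    cid[i] = cells[i].id; crow[i] = cells[i].row; ccol[i] = cells[i].col;
    ctype[i] = cells[i].type; ctime[i] = cells[i].commit_time;
  }

  return List::create(
    _["time"] = out_time, _["uncommitted"] = out_unc, _["committed"] = out_com,
    _["trace_time"] = NumericVector(tr_time.begin(), tr_time.end()),
    _["trace_id"] = IntegerVector(tr_id.begin(), tr_id.end()),
    _["trace_type"] = IntegerVector(tr_type.begin(), tr_type.end()),
    _["traces"] = traces,
    _["events"] = events,
    _["snap_time"] = NumericVector(snap_time.begin(), snap_time.end()),
    _["snap_type"] = snap_type,
    _["snap_ai1"] = snap_ai1, _["snap_ai2"] = snap_ai2, _["snap_ai3"] = snap_ai3,
    _["cells"] = DataFrame::create(_["cell_id"] = cid, _["row"] = crow,
                                   _["col"] = ccol, _["type"] = ctype,
                                   _["commit_time"] = ctime),
    _["extinct"] = extinct);
}
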