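// Core numerics for organ domains and Constrained Constructive Optimization.
// Geometry is in mm throughout; hydraulic resistances are evaluated in SI
// units internally (viscosity cP -> Pa s, lengths/radii mm -> m).

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>
#include <limits>

using namespace Rcpp;

// ---------------------------------------------------------------------------
// Organ domains: postfix programs over sphere / ellipsoid / box primitives
// combined by union / intersection / difference, or a voxel distance field.
// Signed distances are exact for spheres and boxes; ellipsoids use an exact
// bisection solve outside and a smooth approximation inside; CSG combinations
// use the standard min/max estimates (exact sign, lower-bound magnitude).
// ---------------------------------------------------------------------------

struct DomainSpec {
  bool voxel = false;
  std::vector<int> ops;                       // 1 sphere, 2 ellipsoid, 3 box,
                                              // 10 union, 11 intersect, 12 diff
  std::vector<std::vector<double>> params;
  // voxel mode
  std::vector<double> field;                  // unsigned distance, 0 inside
  std::vector<int> mask;                      // 1 inside
  int nx = 0, ny = 0, nz = 0;
  double sx = 1, sy = 1, sz = 1, ox = 0, oy = 0, oz = 0;
};

static double sd_sphere(const std::vector<double>& p, double x, double y, double z) {
  double dx = x - p[0], dy = y - p[1], dz = z - p[2];
  return std::sqrt(dx * dx + dy * dy + dz * dz) - p[3];
}

static double sd_box(const std::vector<double>& p, double x, double y, double z) {
  // p: lower(3), upper(3)
  double cx = 0.5 * (p[0] + p[3]), cy = 0.5 * (p[1] + p[4]), cz = 0.5 * (p[2] + p[5]);
  double hx = 0.5 * (p[3] - p[0]), hy = 0.5 * (p[4] - p[1]), hz = 0.5 * (p[5] - p[2]);
  double qx = std::fabs(x - cx) - hx, qy = std::fabs(y - cy) - hy, qz = std::fabs(z - cz) - hz;
  double ax = std::max(qx, 0.0), ay = std::max(qy, 0.0), az = std::max(qz, 0.0);
  double outside = std::sqrt(ax * ax + ay * ay + az * az);
  double inside = std::min(std::max(qx, std::max(qy, qz)), 0.0);
  return outside + inside;
}

static double sd_ellipsoid(const std::vector<double>& p, double x, double y, double z) {
  double q[3] = {x - p[0], y - p[1], z - p[2]};
  double a[3] = {p[3], p[4], p[5]};
  double k = 0;
  for (int i = 0; i < 3; ++i) k += (q[i] / a[i]) * (q[i] / a[i]);
  if (k <= 1.0) {
    // inside: smooth signed-distance approximation (exact sign, exact zero set)
    double k0 = std::sqrt(k), k1 = 0;
    for (int i = 0; i < 3; ++i) k1 += (q[i] / (a[i] * a[i])) * (q[i] / (a[i] * a[i]));
    k1 = std::sqrt(k1);
    if (k1 < 1e-300) return -(*std::min_element(a, a + 3));
    return k0 * (k0 - 1.0) / k1;
  }
  // outside: exact distance via bisection on the Lagrange parameter t >= 0,
  // F(t) = sum (a_i q_i / (a_i^2 + t))^2 - 1, strictly decreasing
  auto F = [&](double t) {
    double s = 0;
    for (int i = 0; i < 3; ++i) {
      double v = a[i] * q[i] / (a[i] * a[i] + t);
      s += v * v;
    }
    return s - 1.0;
  };
  double lo = 0.0, hi = 1.0;
  while (F(hi) > 0) { hi *= 2.0; if (hi > 1e30) break; }
  for (int it = 0; it < 200; ++it) {
    double mid = 0.5 * (lo + hi);
    if (F(mid) > 0) lo = mid; else hi = mid;
    if (hi - lo < 1e-14 * (1.0 + hi)) break;
  }
  double t = 0.5 * (lo + hi), d2 = 0;
  for (int i = 0; i < 3; ++i) {
    double xi = a[i] * a[i] * q[i] / (a[i] * a[i] + t);
    d2 += (q[i] - xi) * (q[i] - xi);
  }
  return std::sqrt(d2);
}

static double signed_distance_analytic(const DomainSpec& d, double x, double y, double z) {
  std::vector<double> stack;
  stack.reserve(8);
  size_t ip = 0;
  for (size_t k = 0; k < d.ops.size(); ++k) {
    int op = d.ops[k];
    if (op == 1) stack.push_back(sd_sphere(d.params[ip++], x, y, z));
    else if (op == 2) stack.push_back(sd_ellipsoid(d.params[ip++], x, y, z));
    else if (op == 3) stack.push_back(sd_box(d.params[ip++], x, y, z));
    else {
      double b = stack.back(); stack.pop_back();
      double a = stack.back(); stack.pop_back();
      if (op == 10) stack.push_back(std::min(a, b));          // union
      else if (op == 11) stack.push_back(std::max(a, b));     // intersection
      else stack.push_back(std::max(a, -b));                  // difference a \ b
    }
  }
  return stack.back();
}

static double voxel_field_at(const DomainSpec& d, double x, double y, double z) {
  // trilinear interpolation of the distance field at voxel centres; points
  // outside the grid add the distance to the clamped location (continuous)
  double gx = (x - d.ox) / d.sx, gy = (y - d.oy) / d.sy, gz = (z - d.oz) / d.sz;
  double cx = std::min(std::max(gx, 0.0), (double)(d.nx - 1));
  double cy = std::min(std::max(gy, 0.0), (double)(d.ny - 1));
  double cz = std::min(std::max(gz, 0.0), (double)(d.nz - 1));
  double extra2 = (gx - cx) * (gx - cx) * d.sx * d.sx +
                  (gy - cy) * (gy - cy) * d.sy * d.sy +
                  (gz - cz) * (gz - cz) * d.sz * d.sz;
  int i0 = (int)std::floor(cx), j0 = (int)std::floor(cy), k0 = (int)std::floor(cz);
  int i1 = std::min(i0 + 1, d.nx - 1), j1 = std::min(j0 + 1, d.ny - 1),
      k1 = std::min(k0 + 1, d.nz - 1);
  double fx = cx - i0, fy = cy - j0, fz = cz - k0;
  auto at = [&](int i, int j, int k) {
    return d.field[(size_t)i + d.nx * ((size_t)j + (size_t)d.ny * k)];
  };
  double v =
    at(i0,j0,k0)*(1-fx)*(1-fy)*(1-fz) + at(i1,j0,k0)*fx*(1-fy)*(1-fz) +
    at(i0,j1,k0)*(1-fx)*fy*(1-fz)     + at(i1,j1,k0)*fx*fy*(1-fz) +
    at(i0,j0,k1)*(1-fx)*(1-fy)*fz     + at(i1,j0,k1)*fx*(1-fy)*fz +
    at(i0,j1,k1)*(1-fx)*fy*fz         + at(i1,j1,k1)*fx*fy*fz;
  return v + std::sqrt(extra2);
}

static double domain_unsigned(const DomainSpec& d, double x, double y, double z) {
  if (d.voxel) return voxel_field_at(d, x, y, z);
  return std::max(0.0, signed_distance_analytic(d, x, y, z));
}

static bool domain_inside(const DomainSpec& d, double x, double y, double z) {
  if (d.voxel) {
    int i = (int)std::lround((x - d.ox) / d.sx);
    int j = (int)std::lround((y - d.oy) / d.sy);
    int k = (int)std::lround((z - d.oz) / d.sz);
    if (i < 0 || j < 0 || k < 0 || i >= d.nx || j >= d.ny || k >= d.nz) return false;
    return d.mask[(size_t)i + d.nx * ((size_t)j + (size_t)d.ny * k)] != 0;
  }
  return signed_distance_analytic(d, x, y, z) <= 0.0;
}

static DomainSpec parse_domain(const List& spec) {
  DomainSpec d;
  std::string kind = as<std::string>(spec["kind"]);
  if (kind == "voxel") {
    d.voxel = true;
    NumericVector f = spec["field"];
    IntegerVector m = spec["mask"];
    IntegerVector dim = spec["dim"];
    NumericVector sp = spec["spacing"], orig = spec["origin"];
    d.field.assign(f.begin(), f.end());
    d.mask.assign(m.begin(), m.end());
    d.nx = dim[0]; d.ny = dim[1]; d.nz = dim[2];
    d.sx = sp[0]; d.sy = sp[1]; d.sz = sp[2];
    d.ox = orig[0]; d.oy = orig[1]; d.oz = orig[2];
  } else {
    IntegerVector ops = spec["ops"];
    List par = spec["params"];
    d.ops.assign(ops.begin(), ops.end());
    for (R_xlen_t i = 0; i < par.size(); ++i) {
      NumericVector v = par[i];
      d.params.push_back(std::vector<double>(v.begin(), v.end()));
    }
  }
  return d;
}

// [[Rcpp::export]]
NumericVector cpp_domain_distance(List spec, NumericMatrix pts) {
  DomainSpec d = parse_domain(spec);
  NumericVector out(pts.nrow());
  for (int i = 0; i < pts.nrow(); ++i)
    out[i] = domain_unsigned(d, pts(i, 0), pts(i, 1), pts(i, 2));
  return out;
}

// [[Rcpp::export]]
LogicalVector cpp_domain_inside(List spec, NumericMatrix pts) {
  DomainSpec d = parse_domain(spec);
  LogicalVector out(pts.nrow());
  for (int i = 0; i < pts.nrow(); ++i)
    out[i] = domain_inside(d, pts(i, 0), pts(i, 1), pts(i, 2));
  return out;
}

// ---------------------------------------------------------------------------
// Exact Euclidean distance transform (squared), Felzenszwalb-Huttenlocher
// lower-envelope scan applied along each axis with anisotropic spacing.
// ---------------------------------------------------------------------------

static void edt_1d(std::vector<double>& f, double spacing) {
  int n = (int)f.size();
  const double INF = std::numeric_limits<double>::infinity();
  std::vector<int> v(n);
  std::vector<double> zbuf(n + 1), out(n);
  double s2 = spacing * spacing;
  int k = -1;
  for (int q = 0; q < n; ++q) {
    if (f[q] == INF) continue;               // +inf parabolas never contribute
    double s = -INF;
    while (k >= 0) {
      int p = v[k];
      s = ((f[q] + s2 * q * q) - (f[p] + s2 * p * p)) / (2.0 * s2 * (q - p));
      if (s <= zbuf[k]) --k; else break;
    }
    ++k; v[k] = q;
    zbuf[k] = k == 0 ? -INF : s;
    zbuf[k + 1] = INF;
  }
  if (k < 0) return;                         // no sources in this line
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (zbuf[k + 1] < q) ++k;
    int p = v[k];
    out[q] = s2 * (q - p) * (q - p) + f[p];
  }
  f = out;
}

// [[Rcpp::export]]
NumericVector cpp_edt3d(IntegerVector mask, IntegerVector dim, NumericVector spacing) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  size_t total = (size_t)nx * ny * nz;
  std::vector<double> g(total);
  const double INF = std::numeric_limits<double>::infinity();
  for (size_t i = 0; i < total; ++i) g[i] = mask[i] != 0 ? 0.0 : INF;
  auto idx = [&](int i, int j, int k) {
    return (size_t)i + (size_t)nx * ((size_t)j + (size_t)ny * k);
  };
  std::vector<double> line;
  // x-axis
  line.resize(nx);
  for (int k = 0; k < nz; ++k) for (int j = 0; j < ny; ++j) {
    bool any = false;
    for (int i = 0; i < nx; ++i) { line[i] = g[idx(i,j,k)]; if (std::isfinite(line[i])) any = true; }
    if (!any) continue;
    edt_1d(line, spacing[0]);
    for (int i = 0; i < nx; ++i) g[idx(i,j,k)] = line[i];
  }
  // y-axis
  line.resize(ny);
  for (int k = 0; k < nz; ++k) for (int i = 0; i < nx; ++i) {
    bool any = false;
    for (int j = 0; j < ny; ++j) { line[j] = g[idx(i,j,k)]; if (std::isfinite(line[j])) any = true; }
    if (!any) continue;
    edt_1d(line, spacing[1]);
    for (int j = 0; j < ny; ++j) g[idx(i,j,k)] = line[j];
  }
  // z-axis
  line.resize(nz);
  for (int j = 0; j < ny; ++j) for (int i = 0; i < nx; ++i) {
    bool any = false;
    for (int k = 0; k < nz; ++k) { line[k] = g[idx(i,j,k)]; if (std::isfinite(line[k])) any = true; }
    if (!any) continue;
    edt_1d(line, spacing[2]);
    for (int k = 0; k < nz; ++k) g[idx(i,j,k)] = line[k];
  }
  NumericVector out(total);
  for (size_t i = 0; i < total; ++i)
    out[i] = std::isfinite(g[i]) ? std::sqrt(g[i]) : R_PosInf;
  return out;
}

// ---------------------------------------------------------------------------
// CCO tree machinery
// ---------------------------------------------------------------------------

struct CCOConfigC {
  double lambda = 2.0;
  double C = 42.0;
  double gamma = 3.0;
  int visc_model = 0;        // 0 constant, 1 radius-dependent (Fahraeus-Lindqvist)
  double mu_inf = 4.0;       // cP
  double delta = 4.29;       // um
  int root_mode = 0;         // 0 fixed root radius, 1 fixed pressure drop
  double root_radius = 1.0;  // mm
  double dP = 533.0;         // Pa
  double Q = 1.17e-5;        // m^3/s
  double q_leaf = 1.0;       // per-leaf flow (arbitrary units unless root_mode 1)
  double rebal_tol = 1e-10;
  int rebal_maxit = 200;
  int n_cand = 40;
  int n_shortlist = 20;
  double final_tol = 1e-3;   // mm
  double armijo_beta = 0.5;
  double armijo_c1 = 1e-4;
  int gd_maxit = 200;
};

static CCOConfigC parse_config(const List& cfg) {
  CCOConfigC c;
  c.lambda = as<double>(cfg["lambda"]);
  c.C = as<double>(cfg["penalty_C"]);
  c.gamma = as<double>(cfg["gamma"]);
  c.visc_model = as<std::string>(cfg["viscosity"]) == "constant" ? 0 : 1;
  c.mu_inf = as<double>(cfg["mu_inf"]);
  c.delta = as<double>(cfg["delta"]);
  c.root_mode = as<std::string>(cfg["root_condition"]) == "fixed_root_radius" ? 0 : 1;
  c.root_radius = as<double>(cfg["root_radius"]);
  c.dP = as<double>(cfg["pressure_drop"]);
  c.Q = as<double>(cfg["total_flow"]);
  c.q_leaf = c.root_mode == 1 ? c.Q : 1.0;  // resolved after leaf count known
  c.rebal_tol = as<double>(cfg["rebalance_tol"]);
  c.rebal_maxit = as<int>(cfg["rebalance_maxit"]);
  c.n_cand = as<int>(cfg["n_candidates"]);
  c.n_shortlist = as<int>(cfg["n_shortlist"]);
  c.final_tol = as<double>(cfg["final_tolerance"]);
  c.armijo_beta = as<double>(cfg["armijo_beta"]);
  c.armijo_c1 = as<double>(cfg["armijo_c1"]);
  c.gd_maxit = as<int>(cfg["gd_maxit"]);
  return c;
}

// apparent blood viscosity in cP as a function of radius in um
static double viscosity_um(double r_um, const CCOConfigC& c) {
  if (r_um < 4.0) r_um = 4.0;                 // clamp below the formula's range
  auto fl = [&](double r) { double f = 1.0 + c.delta / r; return c.mu_inf * f * f; };
  if (r_um <= 140.0) return fl(r_um);
  if (r_um >= 160.0) return c.mu_inf;
  double t = (r_um - 140.0) / 20.0;
  return (1.0 - t) * fl(140.0) + t * c.mu_inf;
}

struct CCOTree {
  std::vector<double> nx, ny, nz;           // node positions (mm)
  std::vector<int> efrom, eto;              // edges, 0-based node indices
  std::vector<double> radius;               // mm
  int root_node = 0;

  // derived
  std::vector<int> child1, child2, parent;  // edge indices, -1 if none
  std::vector<int> postorder;
  int root_edge = -1;

  int n_edges() const { return (int)efrom.size(); }
  int n_nodes() const { return (int)nx.size(); }

  double elen(int e) const {
    double dx = nx[eto[e]] - nx[efrom[e]];
    double dy = ny[eto[e]] - ny[efrom[e]];
    double dz = nz[eto[e]] - nz[efrom[e]];
    return std::sqrt(dx * dx + dy * dy + dz * dz);
  }

  void build_topology() {
    int ne = n_edges(), nn = n_nodes();
    child1.assign(ne, -1); child2.assign(ne, -1); parent.assign(ne, -1);
    std::vector<int> edge_at_node(nn, -1);   // edge whose terminal is node
    for (int e = 0; e < ne; ++e) edge_at_node[eto[e]] = e;
    root_edge = -1;
    for (int e = 0; e < ne; ++e) {
      if (efrom[e] == root_node) root_edge = e;
      int p = edge_at_node[efrom[e]];
      if (p >= 0) {
        parent[e] = p;
        if (child1[p] < 0) child1[p] = e; else child2[p] = e;
      }
    }
    if (root_edge < 0) stop("tree has no edge leaving the root node");
    // iterative post-order
    postorder.clear(); postorder.reserve(ne);
    std::vector<int> stack, state(ne, 0);
    stack.push_back(root_edge);
    while (!stack.empty()) {
      int e = stack.back();
      if (state[e] == 0) {
        state[e] = 1;
        if (child1[e] >= 0) { stack.push_back(child1[e]); stack.push_back(child2[e]); }
      } else {
        stack.pop_back();
        if (state[e] == 1) { postorder.push_back(e); state[e] = 2; }
      }
    }
  }
};

struct FlowResult {
  std::vector<double> flow, resistance, leafcount;
  bool converged = true;
  int iterations = 0;
};

// Hagen-Poiseuille radius rebalancing with the bifurcation-exponent law.
// One post-order sweep computes reduced subtree resistances and daughter
// radius fractions; a root-to-leaf sweep sets absolute radii.  With constant
// viscosity one sweep is exact; with radius-dependent viscosity the pair of
// sweeps is iterated to a fixed point.
static FlowResult rebalance(CCOTree& tr, const CCOConfigC& cfg) {
  int ne = tr.n_edges();
  FlowResult res;
  res.leafcount.assign(ne, 0.0);
  for (int e : tr.postorder)
    res.leafcount[e] = tr.child1[e] < 0 ? 1.0
                     : res.leafcount[tr.child1[e]] + res.leafcount[tr.child2[e]];
  double total_leaves = res.leafcount[tr.root_edge];
  double q_leaf = cfg.root_mode == 1 ? cfg.Q / total_leaves : 1.0;
  std::vector<double> rho(ne), b1(ne), b2(ne), len_m(ne);
  for (int e = 0; e < ne; ++e) len_m[e] = tr.elen(e) * 1e-3;

  std::vector<double> r_mm = tr.radius;
  double init = cfg.root_mode == 0 ? cfg.root_radius : 1.0;
  for (int e = 0; e < ne; ++e) if (!(r_mm[e] > 0)) r_mm[e] = init;

  int it = 0;
  double change = std::numeric_limits<double>::infinity();
  int maxit = cfg.visc_model == 0 ? 1 : cfg.rebal_maxit;
  while (it < maxit) {
    ++it;
    for (int e : tr.postorder) {
      double mu = cfg.visc_model == 0 ? cfg.mu_inf
                                      : viscosity_um(r_mm[e] * 1e3, cfg);
      double ce = 8.0 * (mu * 1e-3) * len_m[e] / M_PI;
      int c1 = tr.child1[e], c2 = tr.child2[e];
      if (c1 < 0) { rho[e] = ce; continue; }
      double q1 = res.leafcount[c1], q2 = res.leafcount[c2];
      double s1 = std::max(rho[c1], 1e-300), s2 = std::max(rho[c2], 1e-300);
      double x = std::pow((q1 * s1) / (q2 * s2), 0.25);   // beta1 / beta2
      double beta2 = std::pow(1.0 + std::pow(x, cfg.gamma), -1.0 / cfg.gamma);
      double beta1 = x * beta2;
      b1[e] = beta1; b2[e] = beta2;
      double p1 = std::pow(beta1, 4) / s1, p2 = std::pow(beta2, 4) / s2;
      rho[e] = ce + 1.0 / (p1 + p2);
    }
    // absolute scale at the root
    double r_root_mm;
    if (cfg.root_mode == 0) {
      r_root_mm = cfg.root_radius;
    } else {
      double r4 = rho[tr.root_edge] * cfg.Q / cfg.dP;  // r in m
      r_root_mm = std::pow(r4, 0.25) * 1e3;
    }
    // root-to-leaf radius propagation (reverse post-order is a valid pre-order)
    change = 0.0;
    for (int k = (int)tr.postorder.size() - 1; k >= 0; --k) {
      int e = tr.postorder[k];
      double rnew = e == tr.root_edge ? r_root_mm
                  : (e == tr.child1[tr.parent[e]] ? b1[tr.parent[e]] : b2[tr.parent[e]])
                    * r_mm[tr.parent[e]];
      if (r_mm[e] > 0)
        change = std::max(change, std::fabs(rnew - r_mm[e]) / r_mm[e]);
      r_mm[e] = rnew;
    }
    if (cfg.visc_model == 0) break;
    if (change < cfg.rebal_tol) break;
  }
  res.iterations = it;
  res.converged = cfg.visc_model == 0 || change < cfg.rebal_tol;
  tr.radius = r_mm;
  res.flow.assign(ne, 0.0);
  res.resistance.assign(ne, 0.0);
  for (int e = 0; e < ne; ++e) {
    res.flow[e] = res.leafcount[e] * q_leaf;
    double mu = cfg.visc_model == 0 ? cfg.mu_inf : viscosity_um(r_mm[e] * 1e3, cfg);
    double rm = r_mm[e] * 1e-3;
    res.resistance[e] = rm > 0 ? 8.0 * (mu * 1e-3) * len_m[e] / (M_PI * rm * rm * rm * rm)
                               : 0.0;
  }
  return res;
}

static double tree_cost_c(const CCOTree& tr, const DomainSpec* dom,
                          const CCOConfigC& cfg) {
  double vol = 0;
  for (int e = 0; e < tr.n_edges(); ++e)
    vol += tr.elen(e) * std::pow(tr.radius[e], cfg.lambda);
  double pen = 0;
  if (dom && cfg.C > 0) {
    for (int i = 0; i < tr.n_nodes(); ++i) {
      double d = domain_unsigned(*dom, tr.nx[i], tr.ny[i], tr.nz[i]);
      pen += d * d;
    }
  }
  return vol + cfg.C * pen;
}

// insert a temporary bifurcation on edge t towards leaf point P; returns the
// index of the movable bifurcation node
static int insert_bifurcation(CCOTree& tr, int t, const double* P, const double* X) {
  int b = tr.n_nodes();
  tr.nx.push_back(X[0]); tr.ny.push_back(X[1]); tr.nz.push_back(X[2]);
  int L = tr.n_nodes();
  tr.nx.push_back(P[0]); tr.ny.push_back(P[1]); tr.nz.push_back(P[2]);
  int v = tr.eto[t];
  // e1: continuation b -> v inherits t's daughters; e2: new leaf edge b -> L
  tr.efrom.push_back(b); tr.eto.push_back(v); tr.radius.push_back(tr.radius[t]);
  tr.efrom.push_back(b); tr.eto.push_back(L); tr.radius.push_back(0.0);
  tr.eto[t] = b;
  tr.build_topology();
  return b;
}

static double eval_cost_at(CCOTree& tr, int bnode, const double* X,
                           const DomainSpec* dom, const CCOConfigC& cfg) {
  tr.nx[bnode] = X[0]; tr.ny[bnode] = X[1]; tr.nz[bnode] = X[2];
  rebalance(tr, cfg);
  return tree_cost_c(tr, dom, cfg);
}

// gradient-descent with Armijo backtracking on the bifurcation position;
// gradients by central differences (radii fully rebalanced at every cost
// evaluation).  Returns the achieved cost; X is updated in place.
static double optimize_position(CCOTree& tr, int bnode, double* X, double tol,
                                double Lloc, const DomainSpec* dom,
                                const CCOConfigC& cfg, int* iters_out) {
  double f0 = eval_cost_at(tr, bnode, X, dom, cfg);
  double h = std::max(1e-4 * Lloc, 1e-6);
  double step0 = std::max(Lloc * 0.5, tol);
  int it = 0;
  for (; it < cfg.gd_maxit; ++it) {
    double g[3];
    for (int d = 0; d < 3; ++d) {
      double Xp[3] = {X[0], X[1], X[2]}, Xm[3] = {X[0], X[1], X[2]};
      Xp[d] += h; Xm[d] -= h;
      double fp = eval_cost_at(tr, bnode, Xp, dom, cfg);
      double fm = eval_cost_at(tr, bnode, Xm, dom, cfg);
      g[d] = (fp - fm) / (2.0 * h);
    }
    double gn = std::sqrt(g[0] * g[0] + g[1] * g[1] + g[2] * g[2]);
    if (gn < 1e-300) break;
    double dir[3] = {-g[0] / gn, -g[1] / gn, -g[2] / gn};
    double slope = -gn;                       // directional derivative
    double s = step0;
    bool accepted = false;
    for (int ls = 0; ls < 60; ++ls) {
      double Xn[3] = {X[0] + s * dir[0], X[1] + s * dir[1], X[2] + s * dir[2]};
      double fn = eval_cost_at(tr, bnode, Xn, dom, cfg);
      if (fn <= f0 + cfg.armijo_c1 * s * slope) {
        X[0] = Xn[0]; X[1] = Xn[1]; X[2] = Xn[2];
        f0 = fn;
        accepted = true;
        step0 = std::min(2.0 * s, std::max(Lloc, tol));
        break;
      }
      s *= cfg.armijo_beta;
      if (s < 0.125 * tol) break;
    }
    if (!accepted) break;                     // no admissible step: converged
    if (s < tol) break;
  }
  // leave the tree evaluated at the final position
  f0 = eval_cost_at(tr, bnode, X, dom, cfg);
  if (iters_out) *iters_out = it;
  return f0;
}

// try connecting point P to edge t: rough optimization from the edge midpoint
struct CandidateResult {
  int edge;
  double cost;
  double X[3];
};

static CandidateResult try_candidate(const CCOTree& tree, int t, const double* P,
                                     double tol, const double* X0,
                                     const DomainSpec* dom, const CCOConfigC& cfg) {
  CCOTree tmp = tree;
  double X[3] = {X0[0], X0[1], X0[2]};
  // degenerate starts: coincident with an endpoint or the new leaf
  auto close = [&](double ax, double ay, double az) {
    double dx = X[0]-ax, dy = X[1]-ay, dz = X[2]-az;
    return dx*dx + dy*dy + dz*dz < 1e-24;
  };
  if (close(P[0], P[1], P[2]) ||
      close(tree.nx[tree.efrom[t]], tree.ny[tree.efrom[t]], tree.nz[tree.efrom[t]]) ||
      close(tree.nx[tree.eto[t]], tree.ny[tree.eto[t]], tree.nz[tree.eto[t]])) {
    X[0] += 1e-6; X[1] += 1e-6; X[2] += 1e-6;
  }
  int b = insert_bifurcation(tmp, t, P, X);
  double Lloc = std::max(tree.elen(t), 1e-3);
  CandidateResult res;
  res.edge = t;
  res.cost = optimize_position(tmp, b, X, tol, Lloc, dom, cfg, nullptr);
  res.X[0] = X[0]; res.X[1] = X[1]; res.X[2] = X[2];
  return res;
}

static std::vector<int> nearest_edges(const CCOTree& tr, const double* P, int k) {
  std::vector<std::pair<double,int>> d;
  for (int e = 0; e < tr.n_edges(); ++e) {
    if (tr.elen(e) <= 0) continue;            // cannot split a trivial edge
    double mx = 0.5 * (tr.nx[tr.efrom[e]] + tr.nx[tr.eto[e]]);
    double my = 0.5 * (tr.ny[tr.efrom[e]] + tr.ny[tr.eto[e]]);
    double mz = 0.5 * (tr.nz[tr.efrom[e]] + tr.nz[tr.eto[e]]);
    double dx = mx - P[0], dy = my - P[1], dz = mz - P[2];
    d.push_back({dx * dx + dy * dy + dz * dz, e});
  }
  std::stable_sort(d.begin(), d.end(),
                   [](const std::pair<double,int>& a, const std::pair<double,int>& b) {
                     return a.first < b.first || (a.first == b.first && a.second < b.second);
                   });
  std::vector<int> out;
  for (int i = 0; i < (int)d.size() && i < k; ++i) out.push_back(d[i].second);
  return out;
}

// add one leaf: rough-optimize all candidates, shortlist, full optimization,
// commit the best connection
static List add_leaf_c(CCOTree& tr, const double* P, const DomainSpec* dom,
                       const CCOConfigC& cfg) {
  double rough_tol = std::sqrt(cfg.final_tol);
  std::vector<int> cand = nearest_edges(tr, P, cfg.n_cand);
  if (cand.empty()) stop("no candidate edge available for connection");
  std::vector<CandidateResult> rough;
  for (int t : cand) {
    double X0[3] = {0.5 * (tr.nx[tr.efrom[t]] + tr.nx[tr.eto[t]]),
                    0.5 * (tr.ny[tr.efrom[t]] + tr.ny[tr.eto[t]]),
                    0.5 * (tr.nz[tr.efrom[t]] + tr.nz[tr.eto[t]])};
    rough.push_back(try_candidate(tr, t, P, rough_tol, X0, dom, cfg));
  }
  std::stable_sort(rough.begin(), rough.end(),
                   [](const CandidateResult& a, const CandidateResult& b) {
                     return a.cost < b.cost;
                   });
  int ns = std::min((int)rough.size(), cfg.n_shortlist);
  std::vector<CandidateResult> fine;
  for (int i = 0; i < ns; ++i)
    fine.push_back(try_candidate(tr, rough[i].edge, P, cfg.final_tol,
                                 rough[i].X, dom, cfg));
  int best = 0;
  for (int i = 1; i < ns; ++i) if (fine[i].cost < fine[best].cost) best = i;
  insert_bifurcation(tr, fine[best].edge, P, fine[best].X);
  rebalance(tr, cfg);
  NumericVector shortlist_costs(ns);
  for (int i = 0; i < ns; ++i) shortlist_costs[i] = fine[i].cost;
  return List::create(_["edge"] = fine[best].edge + 1,
                      _["cost"] = fine[best].cost,
                      _["shortlist_costs"] = shortlist_costs,
                      _["position"] = NumericVector::create(fine[best].X[0],
                                                            fine[best].X[1],
                                                            fine[best].X[2]));
}

// ---- R interface ----------------------------------------------------------

static CCOTree tree_from_r(NumericMatrix nodes, IntegerVector efrom,
                           IntegerVector eto, NumericVector radius,
                           int root_node) {
  CCOTree tr;
  for (int i = 0; i < nodes.nrow(); ++i) {
    tr.nx.push_back(nodes(i, 0)); tr.ny.push_back(nodes(i, 1)); tr.nz.push_back(nodes(i, 2));
  }
  tr.efrom.assign(efrom.begin(), efrom.end());
  tr.eto.assign(eto.begin(), eto.end());
  for (auto& v : tr.efrom) --v;
  for (auto& v : tr.eto) --v;
  tr.radius.assign(radius.begin(), radius.end());
  tr.root_node = root_node - 1;
  tr.build_topology();
  return tr;
}

static List tree_to_r(const CCOTree& tr) {
  NumericMatrix nodes(tr.n_nodes(), 3);
  for (int i = 0; i < tr.n_nodes(); ++i) {
    nodes(i, 0) = tr.nx[i]; nodes(i, 1) = tr.ny[i]; nodes(i, 2) = tr.nz[i];
  }
  IntegerVector ef(tr.n_edges()), et(tr.n_edges());
  NumericVector rad(tr.n_edges());
  for (int e = 0; e < tr.n_edges(); ++e) {
    ef[e] = tr.efrom[e] + 1; et[e] = tr.eto[e] + 1; rad[e] = tr.radius[e];
  }
  return List::create(_["nodes"] = nodes, _["from"] = ef, _["to"] = et,
                      _["radius"] = rad, _["root_node"] = tr.root_node + 1);
}

// [[Rcpp::export]]
List cpp_rebalance(NumericMatrix nodes, IntegerVector efrom, IntegerVector eto,
                   NumericVector radius, int root_node, List cfg) {
  CCOTree tr = tree_from_r(nodes, efrom, eto, radius, root_node);
  CCOConfigC c = parse_config(cfg);
  FlowResult fr = rebalance(tr, c);
  if (!fr.converged)
    stop("radius rebalancing did not converge within %d sweeps", c.rebal_maxit);
  // leaf pressure drops by root-to-leaf accumulation
  int ne = tr.n_edges();
  std::vector<double> acc(ne, 0.0);
  NumericVector leaf_dp;
  IntegerVector leaf_edge;
  for (int k = (int)tr.postorder.size() - 1; k >= 0; --k) {
    int e = tr.postorder[k];
    double up = tr.parent[e] >= 0 ? acc[tr.parent[e]] : 0.0;
    acc[e] = up + fr.flow[e] * fr.resistance[e];
    if (tr.child1[e] < 0) {
      leaf_dp.push_back(acc[e]);
      leaf_edge.push_back(e + 1);
    }
  }
  return List::create(_["radius"] = NumericVector(tr.radius.begin(), tr.radius.end()),
                      _["flow"] = NumericVector(fr.flow.begin(), fr.flow.end()),
                      _["resistance"] = NumericVector(fr.resistance.begin(), fr.resistance.end()),
                      _["leafcount"] = NumericVector(fr.leafcount.begin(), fr.leafcount.end()),
                      _["leaf_edge"] = leaf_edge,
                      _["leaf_pressure_drop"] = leaf_dp,
                      _["iterations"] = fr.iterations);
}

// [[Rcpp::export]]
double cpp_tree_cost(NumericMatrix nodes, IntegerVector efrom, IntegerVector eto,
                     NumericVector radius, int root_node, List cfg,
                     Nullable<List> domain) {
  CCOTree tr = tree_from_r(nodes, efrom, eto, radius, root_node);
  CCOConfigC c = parse_config(cfg);
  DomainSpec d;
  bool has = domain.isNotNull();
  if (has) d = parse_domain(domain.get());
  return tree_cost_c(tr, has ? &d : nullptr, c);
}

// [[Rcpp::export]]
List cpp_optimize_bifurcation(NumericMatrix nodes, IntegerVector efrom,
                              IntegerVector eto, NumericVector radius,
                              int root_node, int target_edge,
                              NumericVector leaf_point, NumericVector start,
                              double tol, List cfg, Nullable<List> domain) {
  CCOTree tr = tree_from_r(nodes, efrom, eto, radius, root_node);
  CCOConfigC c = parse_config(cfg);
  DomainSpec d;
  bool has = domain.isNotNull();
  if (has) d = parse_domain(domain.get());
  double P[3] = {leaf_point[0], leaf_point[1], leaf_point[2]};
  double X0[3] = {start[0], start[1], start[2]};
  CandidateResult res = try_candidate(tr, target_edge - 1, P, tol, X0,
                                      has ? &d : nullptr, c);
  return List::create(_["position"] = NumericVector::create(res.X[0], res.X[1], res.X[2]),
                      _["cost"] = res.cost);
}

// [[Rcpp::export]]
List cpp_add_leaf(NumericMatrix nodes, IntegerVector efrom, IntegerVector eto,
                  NumericVector radius, int root_node, NumericVector point,
                  List cfg, Nullable<List> domain) {
  CCOTree tr = tree_from_r(nodes, efrom, eto, radius, root_node);
  CCOConfigC c = parse_config(cfg);
  DomainSpec d;
  bool has = domain.isNotNull();
  if (has) d = parse_domain(domain.get());
  double P[3] = {point[0], point[1], point[2]};
  List audit = add_leaf_c(tr, P, has ? &d : nullptr, c);
  return List::create(_["tree"] = tree_to_r(tr), _["audit"] = audit);
}

// [[Rcpp::export]]
List cpp_generate(NumericMatrix nodes, IntegerVector efrom, IntegerVector eto,
                  NumericVector radius, int root_node, NumericMatrix targets,
                  List cfg, Nullable<List> domain) {
  CCOTree tr = tree_from_r(nodes, efrom, eto, radius, root_node);
  CCOConfigC c = parse_config(cfg);
  DomainSpec d;
  bool has = domain.isNotNull();
  if (has) d = parse_domain(domain.get());
  List audit(targets.nrow());
  for (int i = 0; i < targets.nrow(); ++i) {
    double P[3] = {targets(i, 0), targets(i, 1), targets(i, 2)};
    audit[i] = add_leaf_c(tr, P, has ? &d : nullptr, c);
    Rcpp::checkUserInterrupt();
  }
  rebalance(tr, c);
  return List::create(_["tree"] = tree_to_r(tr), _["audit"] = audit);
}

// [[Rcpp::export]]
NumericVector cpp_viscosity(NumericVector r_um, List cfg) {
  CCOConfigC c = parse_config(cfg);
  NumericVector out(r_um.size());
  for (R_xlen_t i = 0; i < r_um.size(); ++i) {
    if (r_um[i] <= 0) stop("viscosity requires r > 0");
    out[i] = viscosity_um(r_um[i], c);
  }
  return out;
}
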