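// Simulation core for the spatially explicit half-sarcomere model.
//
// Layout: n_thick thick filaments anchored at the M-line (x = 0) and n_thin
// thin filaments anchored at the Z-disc (x = L), each a serial chain of
// linear springs. Myosin heads sit at thick-filament nodes; every thin node
// is an actin binding site. A bound crossbridge is a linear + torsional
// spring pair spanning a fixed radial gap between the two filaments; titin is
// a passive exponential spring from the thick filament free end to the Z-disc.
//
// State kinetics: a 6-state crossbridge cycle (1 DRX-free, 2 loosely bound,
// 3 post-powerstroke, 4 rigor-like, 5 free ADP, 6 SRX) per head and a 4-state
// activation chain per thin site, both propagated per 1 ms step through
// P = expm(Q dt) with cumulative-inversion sampling.

#include <RcppArmadillo.h>
#include <unordered_map>
#include <cstdint>

using namespace Rcpp;

// ---------------------------------------------------------------------------
// deterministic RNG (platform-independent): splitmix64 seeding + xorshift64*
// ---------------------------------------------------------------------------

static inline uint64_t splitmix64(uint64_t& s) {
  uint64_t z = (s += 0x9E3779B97F4A7C15ULL);
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}

struct Xorshift {
  uint64_t x;
  explicit Xorshift(uint64_t seed) {
    uint64_t s = seed;
    x = splitmix64(s);
    if (x == 0) x = 0x106689D45497FDB5ULL;
  }
  inline uint64_t next_u64() {
    x ^= x >> 12; x ^= x << 25; x ^= x >> 27;
    return x * 0x2545F4914F6CDD1DULL;
  }
  inline double next_unif() {  // in [0, 1)
    return (next_u64() >> 11) * (1.0 / 9007199254740992.0);
  }
};

// [[Rcpp::export]]
double cpp_record_seed(double master_seed, double index) {
  uint64_t s = (uint64_t)master_seed;
  s ^= 0xD1B54A32D192ED03ULL * (uint64_t)(index + 1);
  uint64_t v = splitmix64(s);
  // keep in double-exact integer range
  return (double)(v >> 12);
}

// ---------------------------------------------------------------------------
// matrix exponential (scaling and squaring with Pade approximation, via
// Armadillo) and stationary distributions
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
arma::mat cpp_expm(const arma::mat& Q, double dt) {
  return arma::expmat(Q * dt);
}

// stationary distribution of a CTMC rate matrix: solve pi Q = 0, sum(pi) = 1
// by least squares on the augmented system.
// [[Rcpp::export]]
arma::vec cpp_stationary(const arma::mat& Q) {
  const arma::uword n = Q.n_rows;
  arma::mat A(n + 1, n);
  A.rows(0, n - 1) = Q.t();
  A.row(n).ones();
  arma::vec b(n + 1, arma::fill::zeros);
  b(n) = 1.0;
  arma::vec pi = arma::pinv(A) * b;
  pi.clamp(0.0, arma::datum::inf);
  double s = arma::accu(pi);
  if (s <= 0) pi.fill(1.0 / n); else pi /= s;
  return pi;
}

// ---------------------------------------------------------------------------
// kinetic + mechanical parameter bundle
// ---------------------------------------------------------------------------

struct Kin {
  // crossbridge springs (KT units, nm, rad)
  double kr, kth, rW, rS, thW, thS, span, kT, dx_star;
  // free-energy offsets (KT)
  double G1, c2, c3, c4, dG_ATP;
  // crossbridge rate constants (ms^-1 unless noted)
  double tau, Ac, Bc, Cc, Dc, Ec, Hc;
  double rx16, rx61_base, rx61_max, ca50, hill_b;
  double ceiling;
  int rx34_variant;   // 0 = D(1+tanh(exp(-F_S))), 1 = D(1+tanh(kappa*F_S))
  double rx34_kappa;
  int rx45_variant;   // 0 = E*max(0, U_S - dG_ATP + exp(-F_S)), 1 = printed (clamped)
  // thin filament
  double rt12c, rt23, rt34, rt41, Kt1c, Kt2, Kt3, coop_factor;
  int coop_on_rt41;
  int coop_lo, coop_hi; // neighbour site states [lo, hi] counted as "calcium bound"
};

static Kin parse_kin(const List& kin) {
  Kin k;
  k.kr = as<double>(kin["k_r"]); k.kth = as<double>(kin["k_theta"]);
  k.rW = as<double>(kin["r_W"]); k.rS = as<double>(kin["r_S"]);
  k.thW = as<double>(kin["theta_W"]); k.thS = as<double>(kin["theta_S"]);
  k.span = as<double>(kin["xb_span"]); k.kT = as<double>(kin["kT_pN_nm"]);
  k.dx_star = as<double>(kin["dx_star"]);
  k.G1 = as<double>(kin["G1"]); k.c2 = as<double>(kin["c2"]);
  k.c3 = as<double>(kin["c3"]); k.c4 = as<double>(kin["c4"]);
  k.dG_ATP = as<double>(kin["dG_ATP"]);
  k.tau = as<double>(kin["tau"]); k.Ac = as<double>(kin["A"]);
  k.Bc = as<double>(kin["B"]); k.Cc = as<double>(kin["C"]);
  k.Dc = as<double>(kin["D"]); k.Ec = as<double>(kin["E"]);
  k.Hc = as<double>(kin["H"]);
  k.rx16 = as<double>(kin["rx16"]); k.rx61_base = as<double>(kin["rx61_base"]);
  k.rx61_max = as<double>(kin["rx61_max"]); k.ca50 = as<double>(kin["ca50"]);
  k.hill_b = as<double>(kin["hill_b"]);
  k.ceiling = as<double>(kin["rate_ceiling"]);
  k.rx34_variant = as<int>(kin["rx34_variant"]);
  k.rx34_kappa = as<double>(kin["rx34_kappa"]);
  k.rx45_variant = as<int>(kin["rx45_variant"]);
  k.rt12c = as<double>(kin["rt12_coeff"]); k.rt23 = as<double>(kin["rt23"]);
  k.rt34 = as<double>(kin["rt34"]); k.rt41 = as<double>(kin["rt41"]);
  k.Kt1c = as<double>(kin["Kt1_coeff"]); k.Kt2 = as<double>(kin["Kt2"]);
  k.Kt3 = as<double>(kin["Kt3"]);
  k.coop_factor = as<double>(kin["coop_factor"]);
  k.coop_on_rt41 = as<int>(kin["coop_on_rt41"]);
  k.coop_lo = as<int>(kin["coop_state_lo"]);
  k.coop_hi = as<int>(kin["coop_state_hi"]);
  return k;
}

// crossbridge geometry at axial offset dx (site minus head), fixed radial span
struct XbGeom {
  double r, th, UW, US, dUW, dUS; // dU* = axial derivative, KT/nm
};

static inline XbGeom xb_geom(double dx, const Kin& k) {
  XbGeom g;
  g.r = std::sqrt(k.span * k.span + dx * dx);
  g.th = std::atan2(k.span, dx);
  const double drW = g.r - k.rW, drS = g.r - k.rS;
  const double dthW = g.th - k.thW, dthS = g.th - k.thS;
  g.UW = 0.5 * k.kr * drW * drW + 0.5 * k.kth * dthW * dthW;
  g.US = 0.5 * k.kr * drS * drS + 0.5 * k.kth * dthS * dthS;
  const double drddx = dx / g.r;
  const double dthddx = -k.span / (g.r * g.r);
  g.dUW = k.kr * drW * drddx + k.kth * dthW * dthddx;
  g.dUS = k.kr * drS * drddx + k.kth * dthS * dthddx;
  return g;
}

static inline double safe_tanh(double x) { return std::tanh(x); }

// the ten crossbridge rates (ms^-1), ungated. factors: phi12, phi23, phi34,
// phi45, phi16 multiply the named forward rates; derived reverses inherit the
// scaled forward through detailed balance.
struct XbRates {
  double r12, r21, r23, r32, r34, r43, r45, r51, r16, r61;
};

static inline XbRates xb_rates(const XbGeom& g, double ca, const Kin& k,
                               double f12, double f23, double f34, double f45,
                               double f16) {
  XbRates r;
  const double cl = k.ceiling;
  auto clip = [cl](double x) { return (x > cl) ? cl : ((x < 0) ? 0.0 : x); };

  const double fwd12 = f12 * k.tau * std::exp(-g.UW);
  r.r12 = clip(fwd12);
  // r21 = r12 * exp(G2 - G1) with G2 = UW + c2: the UW dependence cancels
  r.r21 = clip(f12 * k.tau * std::exp(k.c2 - k.G1));

  const double fwd23 = f23 * k.Ac * (1.0 + safe_tanh(k.Bc + k.Cc * (g.UW - g.US)));
  r.r23 = clip(fwd23);
  r.r32 = clip(fwd23 * std::exp((g.US + k.c3) - (g.UW + k.c2)));

  const double FS = g.dUS; // axial strong-state force, KT/nm
  double fwd34;
  if (k.rx34_variant == 1) {
    fwd34 = k.Dc * (1.0 + safe_tanh(k.rx34_kappa * FS));
  } else {
    const double e = (FS < -30.0) ? std::exp(30.0) : std::exp(-FS);
    fwd34 = k.Dc * (1.0 + safe_tanh(e));
  }
  fwd34 *= f34;
  r.r34 = clip(fwd34);
  r.r43 = clip(fwd34 * std::exp(k.c4 - k.c3)); // G4 - G3 = c4 - c3 (US cancels)

  const double eF = (FS < -7.0) ? std::exp(7.0) : std::exp(-FS);
  double fwd45;
  if (k.rx45_variant == 1) {
    fwd45 = k.Ec * (g.US + k.dG_ATP + eF);   // printed expression, clamped >= 0
  } else {
    fwd45 = k.Ec * (g.US - k.dG_ATP + eF);   // sign-corrected: detachment feasible
  }
  r.r45 = clip(f45 * std::max(0.0, fwd45));

  r.r51 = clip(k.Hc);
  r.r16 = clip(f16 * k.rx16);
  const double cb = std::pow(ca, k.hill_b);
  r.r61 = clip(k.rx61_base + (k.rx61_max - k.rx61_base) * cb /
               (std::pow(k.ca50, k.hill_b) + cb));
  return r;
}

static inline void xb_Q(const XbRates& r, bool gate, arma::mat::fixed<6, 6>& Q) {
  Q.zeros();
  const double r12 = gate ? r.r12 : 0.0;
  Q(0, 1) = r12;   Q(0, 5) = r.r16;
  Q(1, 0) = r.r21; Q(1, 2) = r.r23;
  Q(2, 1) = r.r32; Q(2, 3) = r.r34;
  Q(3, 2) = r.r43; Q(3, 4) = r.r45;
  Q(4, 0) = r.r51;
  Q(5, 0) = r.r61;
  for (int i = 0; i < 6; ++i) Q(i, i) = -arma::accu(Q.row(i)) + Q(i, i);
}

// thin filament rates (ms^-1): rt12, rt21, rt23, rt32, rt34, rt43, rt41.
// cooperativity multiplies the activation-direction forwards (and optionally
// rt41); reverses are derived from the *uncooperative* equilibrium constants
// with the scaled base forward, so the neighbour boost shifts the equilibrium.
static inline void thin_rates(double ca, bool coop, const Kin& k,
                              double f12, double f23, double f34, double f41,
                              double out[7]) {
  const double boost = coop ? k.coop_factor : 1.0;
  const double b12 = f12 * k.rt12c * ca;
  out[0] = b12 * boost;
  out[1] = f12 * k.rt12c / k.Kt1c;   // calcium cancels in rt21
  const double b23 = f23 * k.rt23;
  out[2] = b23 * boost;
  out[3] = b23 / k.Kt2;
  const double b34 = f34 * k.rt34;
  out[4] = b34 * boost;
  out[5] = b34 / k.Kt3;
  out[6] = f41 * k.rt41 * (k.coop_on_rt41 ? boost : 1.0);
}

static inline void thin_Q(const double rt[7], arma::mat::fixed<4, 4>& Q) {
  Q.zeros();
  Q(0, 1) = rt[0]; Q(1, 0) = rt[1];
  Q(1, 2) = rt[2]; Q(2, 1) = rt[3];
  Q(2, 3) = rt[4]; Q(3, 2) = rt[5];
  Q(3, 0) = rt[6]; // rt14 = 0
  for (int i = 0; i < 4; ++i) Q(i, i) = -arma::accu(Q.row(i)) + Q(i, i);
}

// ---------------------------------------------------------------------------
// exported rate/geometry evaluators (thin R wrappers sit on top)
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_xb_geometry(NumericVector dx, List kin) {
  Kin k = parse_kin(kin);
  int n = dx.size();
  NumericVector r(n), th(n), UW(n), US(n), dUW(n), dUS(n);
  for (int i = 0; i < n; ++i) {
    XbGeom g = xb_geom(dx[i], k);
    r[i] = g.r; th[i] = g.th; UW[i] = g.UW; US[i] = g.US;
    dUW[i] = g.dUW; dUS[i] = g.dUS;
  }
  return List::create(_["r"] = r, _["theta"] = th, _["U_W"] = UW,
                      _["U_S"] = US, _["F_W_axial"] = dUW, _["F_S_axial"] = dUS);
}

// [[Rcpp::export]]
NumericMatrix cpp_xb_rates(NumericVector dx, double ca, List kin,
                           NumericVector factors) {
  Kin k = parse_kin(kin);
  int n = dx.size();
  NumericMatrix out(n, 10);
  colnames(out) = CharacterVector::create("rx12", "rx21", "rx23", "rx32",
                                          "rx34", "rx43", "rx45", "rx51",
                                          "rx16", "rx61");
  for (int i = 0; i < n; ++i) {
    XbGeom g = xb_geom(dx[i], k);
    XbRates r = xb_rates(g, ca, k, factors[0], factors[1], factors[2],
                         factors[3], factors[4]);
    out(i, 0) = r.r12; out(i, 1) = r.r21; out(i, 2) = r.r23; out(i, 3) = r.r32;
    out(i, 4) = r.r34; out(i, 5) = r.r43; out(i, 6) = r.r45; out(i, 7) = r.r51;
    out(i, 8) = r.r16; out(i, 9) = r.r61;
  }
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_thin_rates(double ca, bool coop, List kin,
                             NumericVector factors) {
  Kin k = parse_kin(kin);
  double rt[7];
  thin_rates(ca, coop, k, factors[0], factors[1], factors[2], factors[3], rt);
  NumericVector out(7);
  for (int i = 0; i < 7; ++i) out[i] = rt[i];
  out.names() = CharacterVector::create("rt12", "rt21", "rt23", "rt32",
                                        "rt34", "rt43", "rt41");
  return out;
}

// ---------------------------------------------------------------------------
// lattice mechanics
// ---------------------------------------------------------------------------

struct Geom {
  int n_thick, n_thin, nk, na, H, heads_per_node;
  double sk, sa, k_thick, k_thin, L, titin_rest, titin_a, titin_b;
  std::vector<int> head_fil, head_node, head_thin; // per head, 0-based
  std::vector<double> thin_off; // per-thin-filament axial register stagger
};

static Geom parse_geom(const List& geom) {
  Geom g;
  g.n_thick = as<int>(geom["n_thick"]); g.n_thin = as<int>(geom["n_thin"]);
  g.nk = as<int>(geom["nodes_per_thick"]); g.na = as<int>(geom["nodes_per_thin"]);
  g.heads_per_node = as<int>(geom["heads_per_node"]);
  g.sk = as<double>(geom["thick_node_spacing"]);
  g.sa = as<double>(geom["thin_node_spacing"]);
  g.k_thick = as<double>(geom["k_thick_seg"]);
  g.k_thin = as<double>(geom["k_thin_seg"]);
  g.L = as<double>(geom["half_sarcomere_length"]);
  g.titin_rest = as<double>(geom["titin_rest"]);
  g.titin_a = as<double>(geom["titin_a"]);
  g.titin_b = as<double>(geom["titin_b"]);
  NumericVector toff = geom["thin_offset"];
  g.thin_off.assign(toff.begin(), toff.end());
  IntegerVector hf = geom["head_fil"], hn = geom["head_node"], ht = geom["head_thin"];
  g.H = hf.size();
  g.head_fil.assign(hf.begin(), hf.end());
  g.head_node.assign(hn.begin(), hn.end());
  g.head_thin.assign(ht.begin(), ht.end());
  return g;
}

// positions: xk (n_thick x nk), xa (n_thin x na). thick node i rest at
// (i+1)*sk from the M-line; thin node j rest at L - (na - j)*sa (node na-1
// adjacent to the Z-disc). Titin spans thick node nk-1 to the Z-disc.
struct Mech {
  arma::mat xk, xa;
};

static void rest_positions(const Geom& g, Mech& m) {
  m.xk.set_size(g.n_thick, g.nk);
  m.xa.set_size(g.n_thin, g.na);
  for (int f = 0; f < g.n_thick; ++f)
    for (int i = 0; i < g.nk; ++i) m.xk(f, i) = (i + 1) * g.sk;
  for (int f = 0; f < g.n_thin; ++f)
    for (int j = 0; j < g.na; ++j)
      m.xa(f, j) = g.L - g.thin_off[f] - (g.na - j) * g.sa;
}

static inline double titin_force_at(const Geom& g, double x_end) {
  const double dl = (g.L - x_end) - g.titin_rest;
  return g.titin_a * std::exp(g.titin_b * dl);
}

// Tridiagonal chain solve: nodes 0..n-1, spring k between consecutive nodes
// and from node 0 to the anchor; external axial loads f[i]; returns positions.
// anchor at x=anchor0, rest segment length s, chain direction +1 (thick,
// grows toward Z) or -1 (thin, grows toward M from Z).
static void solve_chain(int n, double kseg, double anchor0, double s, int dir,
                        const std::vector<double>& load, std::vector<double>& x) {
  // equilibrium: kseg*(x[i-1] - 2x[i] + x[i+1]) + load[i] = 0 (rest lengths
  // cancel telescopically when written in absolute coordinates with offsets)
  // Solve with Thomas algorithm on u[i] = x[i] - rest[i].
  std::vector<double> a(n, kseg), b(n, -2.0 * kseg), c(n, kseg), d(n), u(n);
  b[n - 1] = -kseg; // free end: only one spring
  for (int i = 0; i < n; ++i) d[i] = -load[i];
  // forward sweep
  c[0] /= b[0]; d[0] /= b[0];
  for (int i = 1; i < n; ++i) {
    double mlt = b[i] - a[i] * c[i - 1];
    c[i] /= mlt;
    d[i] = (d[i] - a[i] * d[i - 1]) / mlt;
  }
  u[n - 1] = d[n - 1];
  for (int i = n - 2; i >= 0; --i) u[i] = d[i] - c[i] * u[i + 1];
  for (int i = 0; i < n; ++i) x[i] = anchor0 + dir * (i + 1) * s + u[i];
}

// state of the discrete system needed by the solver
struct Attach {
  // per bound head: head index, thick (fil,node), thin (fil,node), strong?
  std::vector<int> head, kf, kn, af, an;
  std::vector<bool> strong;
};

// fixed-point mechanics solve; returns iterations used (-1 on failure)
static int solve_mech(const Geom& g, const Kin& k, const Attach& at, Mech& m,
                      double tol, int max_iter, double* resid_out = nullptr) {
  const int nb = (int)at.head.size();
  std::vector<double> lk(g.nk), la(g.na), x(std::max(g.nk, g.na));
  double delta = 0.0;
  int it = 0;
  for (it = 0; it < max_iter; ++it) {
    delta = 0.0;
    // thick filaments
    for (int f = 0; f < g.n_thick; ++f) {
      std::fill(lk.begin(), lk.end(), 0.0);
      for (int bidx = 0; bidx < nb; ++bidx) {
        if (at.kf[bidx] != f) continue;
        double dx = m.xa(at.af[bidx], at.an[bidx]) - m.xk(f, at.kn[bidx]);
        XbGeom gg = xb_geom(dx, k);
        double dU = at.strong[bidx] ? gg.dUS : gg.dUW;
        lk[at.kn[bidx]] += dU * k.kT;      // force on head node, pN
      }
      lk[g.nk - 1] += titin_force_at(g, m.xk(f, g.nk - 1));
      solve_chain(g.nk, g.k_thick, 0.0, g.sk, +1, lk, x);
      for (int i = 0; i < g.nk; ++i) {
        delta = std::max(delta, std::fabs(x[i] - m.xk(f, i)));
        m.xk(f, i) = x[i];
      }
    }
    // thin filaments (anchored at Z; write chain from Z outward then map back)
    for (int f = 0; f < g.n_thin; ++f) {
      std::fill(la.begin(), la.end(), 0.0);
      for (int bidx = 0; bidx < nb; ++bidx) {
        if (at.af[bidx] != f) continue;
        double dx = m.xa(f, at.an[bidx]) - m.xk(at.kf[bidx], at.kn[bidx]);
        XbGeom gg = xb_geom(dx, k);
        double dU = at.strong[bidx] ? gg.dUS : gg.dUW;
        la[at.an[bidx]] -= dU * k.kT;      // force on site node, pN
      }
      // chain index from Z: node q = na-1-j
      std::vector<double> lz(g.na);
      for (int j = 0; j < g.na; ++j) lz[g.na - 1 - j] = la[j];
      solve_chain(g.na, g.k_thin, g.L - g.thin_off[f], g.sa, -1, lz, x);
      for (int j = 0; j < g.na; ++j) {
        double xn = x[g.na - 1 - j];
        delta = std::max(delta, std::fabs(xn - m.xa(f, j)));
        m.xa(f, j) = xn;
      }
    }
    if (delta < tol) break;
  }
  if (resid_out) *resid_out = delta;
  return (delta < tol) ? (it + 1) : -1;
}

// boundary forces: Z-side = thin first-segment tensions + titin; M-side =
// thick first-segment tensions. At equilibrium the two agree.
static void boundary_forces(const Geom& g, const Mech& m, double& fz, double& fm) {
  fz = 0.0; fm = 0.0;
  for (int f = 0; f < g.n_thin; ++f)
    fz += g.k_thin * ((g.L - g.thin_off[f] - m.xa(f, g.na - 1)) - g.sa);
  for (int f = 0; f < g.n_thick; ++f) {
    fz += titin_force_at(g, m.xk(f, g.nk - 1));
    fm += g.k_thick * (m.xk(f, 0) - g.sk);
  }
}

// [[Rcpp::export]]
List cpp_solve_balance(List geom, List kin, IntegerVector b_head,
                       IntegerVector b_kf, IntegerVector b_kn,
                       IntegerVector b_af, IntegerVector b_an,
                       LogicalVector b_strong, double tol, int max_iter) {
  Geom g = parse_geom(geom);
  Kin k = parse_kin(kin);
  Mech m;
  rest_positions(g, m);
  Attach at;
  for (int i = 0; i < b_head.size(); ++i) {
    at.head.push_back(b_head[i]); at.kf.push_back(b_kf[i]);
    at.kn.push_back(b_kn[i]); at.af.push_back(b_af[i]);
    at.an.push_back(b_an[i]); at.strong.push_back(b_strong[i]);
  }
  double resid = 0.0;
  int it = solve_mech(g, k, at, m, tol, max_iter, &resid);
  double fz, fm;
  boundary_forces(g, m, fz, fm);
  return List::create(_["xk"] = m.xk, _["xa"] = m.xa,
                      _["force_z"] = fz, _["force_m"] = fm,
                      _["iterations"] = it, _["residual"] = resid,
                      _["converged"] = (it > 0));
}

// ---------------------------------------------------------------------------
// main twitch simulation
// ---------------------------------------------------------------------------

struct PCache6 {
  std::unordered_map<uint64_t, arma::mat::fixed<6, 6>> map;
};
struct PCache4 {
  std::unordered_map<uint64_t, arma::mat::fixed<4, 4>> map;
};

static inline int sample_row6(const arma::mat::fixed<6, 6>& P, int s, double u) {
  double c = 0.0;
  for (int j = 0; j < 6; ++j) {
    c += P(s, j);
    if (u < c) return j;
  }
  return 5;
}
static inline int sample_row4(const arma::mat::fixed<4, 4>& P, int s, double u) {
  double c = 0.0;
  for (int j = 0; j < 4; ++j) {
    c += P(s, j);
    if (u < c) return j;
  }
  return 3;
}

// [[Rcpp::export]]
List cpp_simulate(List geom, List kin, NumericVector factors,
                  NumericVector ca_per_step, double dt, int n_rep,
                  double seed, bool log_states, bool return_reps,
                  double mech_tol, int mech_max_iter) {
  Geom g = parse_geom(geom);
  Kin k = parse_kin(kin);
  const int T = ca_per_step.size();
  const int H = g.H;
  const int S = g.n_thin * g.na;
  const double f12 = factors[0], f23 = factors[1], f34 = factors[2],
               f45 = factors[3], f16 = factors[4];
  const double t12 = factors[5], t23 = factors[6], t34 = factors[7],
               t41 = factors[8];

  // passive baseline: no attached heads
  Mech m0;
  rest_positions(g, m0);
  Attach none;
  if (solve_mech(g, k, none, m0, mech_tol, mech_max_iter) < 0)
    stop("passive mechanics solve did not converge");
  double fz0, fm0;
  boundary_forces(g, m0, fz0, fm0);

  arma::mat forces(return_reps ? n_rep : 1, T, arma::fill::zeros);
  arma::vec force_mean(T, arma::fill::zeros);
  arma::mat xb_counts, site_counts;
  if (log_states) {
    xb_counts.zeros(T, 6);
    site_counts.zeros(T, 4);
  }

  PCache6 c6; PCache4 c4;
  c6.map.reserve(1 << 14); c4.map.reserve(1 << 10);

  std::vector<int> head_state(H), site_state(S), head_partner(H),
      site_occ(S), paired(H);
  std::vector<bool> coop(S);

  for (int rep = 0; rep < n_rep; ++rep) {
    uint64_t s0 = (uint64_t)seed;
    s0 ^= 0xA0761D6478BD642FULL * (uint64_t)(rep + 1);
    Xorshift rng(s0);

    Mech m = m0;
    std::fill(site_occ.begin(), site_occ.end(), -1);
    std::fill(head_partner.begin(), head_partner.end(), -1);

    const double ca0 = ca_per_step[0];

    // initialize sites from the long-run distribution reached from the
    // blocked state at resting calcium (row of expm(Q T), T -> large)
    {
      double rt[7];
      thin_rates(ca0, false, k, t12, t23, t34, t41, rt);
      arma::mat::fixed<4, 4> Q;
      thin_Q(rt, Q);
      arma::mat Pinf = arma::expmat(arma::mat(Q) * 1.0e6);
      arma::rowvec pi = Pinf.row(0);
      for (int s = 0; s < S; ++s) {
        double u = rng.next_unif(), c = 0.0;
        int st = 3;
        for (int j = 0; j < 4; ++j) { c += pi(j); if (u < c) { st = j; break; } }
        site_state[s] = st;
      }
    }
    // initialize heads from their per-head stationary at resting calcium;
    // heads landing in a bound state attach to their paired site if free,
    // otherwise fall back to the DRX free state.
    for (int h = 0; h < H; ++h) {
      const int tf = g.head_thin[h];
      const double xh = m.xk(g.head_fil[h], g.head_node[h]);
      const double p = xh + k.dx_star;
      int j0 = g.na - 1 - (int)std::lround((g.L - g.thin_off[tf] - p) / g.sa - 1.0);
      int best = -1; double bd = 1e300;
      for (int j = std::max(0, j0 - 2); j <= std::min(g.na - 1, j0 + 2); ++j) {
        double d = std::fabs(m.xa(tf, j) - p);
        if (d < bd - 1e-12) { bd = d; best = j; }
      }
      if (best < 0) best = std::min(std::max(j0, 0), g.na - 1);
      paired[h] = tf * g.na + best;
      const double dx = m.xa(tf, best) - xh;
      XbGeom gg = xb_geom(dx, k);
      XbRates rr = xb_rates(gg, ca0, k, f12, f23, f34, f45, f16);
      bool gate = (site_state[paired[h]] == 3) && (site_occ[paired[h]] < 0);
      arma::mat::fixed<6, 6> Q;
      xb_Q(rr, gate, Q);
      // long-run distribution reached from the free DRX state
      arma::mat Pinf = arma::expmat(arma::mat(Q) * 1.0e6);
      arma::rowvec pi = Pinf.row(0);
      double u = rng.next_unif(), c = 0.0;
      int st = 0;
      for (int j = 0; j < 6; ++j) { c += pi(j); if (u < c) { st = j; break; } }
      if (st >= 1 && st <= 3) { // bound states 2..4 (0-based 1..3)
        if (site_occ[paired[h]] < 0) {
          site_occ[paired[h]] = h;
          head_partner[h] = paired[h];
        } else st = 0;
      }
      head_state[h] = st;
    }

    bool any_bound_prev = false;

    for (int t = 0; t < T; ++t) {
      const double ca = ca_per_step[t];

      // mechanics for the current attachment pattern
      bool any_bound = false;
      Attach at;
      for (int h = 0; h < H; ++h) {
        if (head_partner[h] >= 0) {
          any_bound = true;
          at.head.push_back(h);
          at.kf.push_back(g.head_fil[h]);
          at.kn.push_back(g.head_node[h]);
          at.af.push_back(head_partner[h] / g.na);
          at.an.push_back(head_partner[h] % g.na);
          at.strong.push_back(head_state[h] >= 2); // states 3,4 use strong springs
        }
      }
      if (any_bound) {
        if (solve_mech(g, k, at, m, mech_tol, mech_max_iter) < 0)
          stop("mechanics solve failed to converge at step %d", t + 1);
        any_bound_prev = true;
      } else if (any_bound_prev) {
        m = m0; // relax back to the passive equilibrium
        any_bound_prev = false;
      }

      double fz, fm;
      boundary_forces(g, m, fz, fm);
      if (return_reps) forces(rep, t) = fz;
      force_mean(t) += fz;

      if (log_states) {
        for (int h = 0; h < H; ++h) xb_counts(t, head_state[h]) += 1.0;
        for (int s = 0; s < S; ++s) site_counts(t, site_state[s]) += 1.0;
      }

      // cooperativity flags from start-of-step site states
      for (int f = 0; f < g.n_thin; ++f) {
        for (int j = 0; j < g.na; ++j) {
          const int idx = f * g.na + j;
          bool on = false;
          if (j > 0) {
            int st = site_state[idx - 1] + 1;
            on = on || (st >= k.coop_lo && st <= k.coop_hi);
          }
          if (j < g.na - 1) {
            int st = site_state[idx + 1] + 1;
            on = on || (st >= k.coop_lo && st <= k.coop_hi);
          }
          coop[idx] = on;
        }
      }

      // quantized calcium component of the cache key (via rx61 and rt12)
      const uint64_t qca = (uint64_t)std::lround(std::log(ca) * 128.0) & 0xFFFFFULL;

      // head updates
      for (int h = 0; h < H; ++h) {
        const int tf = g.head_thin[h];
        const double xh = m.xk(g.head_fil[h], g.head_node[h]);
        int site;
        if (head_partner[h] >= 0) {
          site = head_partner[h];
        } else {
          const double p = xh + k.dx_star;
          int j0 = g.na - 1 - (int)std::lround((g.L - g.thin_off[tf] - p) / g.sa - 1.0);
          int best = -1; double bd = 1e300;
          for (int j = std::max(0, j0 - 2); j <= std::min(g.na - 1, j0 + 2); ++j) {
            double d = std::fabs(m.xa(tf, j) - p);
            if (d < bd - 1e-12) { bd = d; best = j; }
          }
          if (best < 0) best = std::min(std::max(j0, 0), g.na - 1);
          site = tf * g.na + best;
          paired[h] = site;
        }
        const double dx = m.xa(site / g.na, site % g.na) - xh;
        const bool gate = (head_partner[h] < 0) && (site_state[site] == 3) &&
                          (site_occ[site] < 0);
        const int64_t qdx = std::lround(dx * 64.0);
        const uint64_t key = ((uint64_t)(qdx + (1 << 22)) << 22) |
                             (qca << 1) | (gate ? 1ULL : 0ULL);
        auto it = c6.map.find(key);
        if (it == c6.map.end()) {
          XbGeom gg = xb_geom(dx, k);
          XbRates rr = xb_rates(gg, ca, k, f12, f23, f34, f45, f16);
          arma::mat::fixed<6, 6> Q;
          xb_Q(rr, gate, Q);
          arma::mat::fixed<6, 6> P;
          P = arma::expmat(arma::mat(Q) * dt);
          it = c6.map.emplace(key, P).first;
        }
        const double u = rng.next_unif();
        const int old = head_state[h];
        int st = sample_row6(it->second, old, u);
        const bool was_bound = (old >= 1 && old <= 3);
        const bool is_bound = (st >= 1 && st <= 3);
        if (!was_bound && is_bound) {
          if (gate) {
            head_partner[h] = site;
            site_occ[site] = h;
          } else {
            st = old; // binding path was closed; stay put
          }
        } else if (was_bound && !is_bound) {
          site_occ[head_partner[h]] = -1;
          head_partner[h] = -1;
        }
        head_state[h] = st;
      }

      // site updates
      for (int s = 0; s < S; ++s) {
        const uint64_t key = (qca << 1) | (coop[s] ? 1ULL : 0ULL);
        auto it = c4.map.find(key);
        if (it == c4.map.end()) {
          double rt[7];
          thin_rates(ca, coop[s], k, t12, t23, t34, t41, rt);
          arma::mat::fixed<4, 4> Q;
          thin_Q(rt, Q);
          arma::mat::fixed<4, 4> P;
          P = arma::expmat(arma::mat(Q) * dt);
          it = c4.map.emplace(key, P).first;
        }
        const double u = rng.next_unif();
        site_state[s] = sample_row4(it->second, site_state[s], u);
      }
    }
  }

  force_mean /= n_rep;
  List out = List::create(
      _["force_mean"] = NumericVector(force_mean.begin(), force_mean.end()),
      _["passive_force"] = fz0,
      _["n_heads"] = H, _["n_sites"] = S);
  if (return_reps) out["forces"] = forces;
  if (log_states) {
    out["xb_counts"] = wrap(xb_counts / n_rep);
    out["site_counts"] = wrap(site_counts / n_rep);
  }
  return out;
}
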