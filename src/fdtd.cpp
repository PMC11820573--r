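// 2-D FDTD Maxwell solver, TM mode (Ez, Hx, Hy) on a Yee grid with
// split-field PML absorbing boundaries.  Material grids are cell-centered
// relative permittivity and conductivity; the solver pads the supplied
// grid with npml edge-replicated cells on every side.
#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

static const double C0   = 2.99792458e8;
static const double EPS0 = 8.8541878128e-12;
static const double MU0  = 1.25663706212e-6;

struct Grids {
  int nz, nx;                       // padded size
  std::vector<double> epsr, sig;    // padded materials, row-major [i*nx+j]
};

static Grids pad_materials(const NumericMatrix& epsr,
                           const NumericMatrix& sigma, int npml) {
  int nzi = epsr.nrow(), nxi = epsr.ncol();
  Grids g;
  g.nz = nzi + 2 * npml;
  g.nx = nxi + 2 * npml;
  g.epsr.assign((size_t)g.nz * g.nx, 1.0);
  g.sig.assign((size_t)g.nz * g.nx, 0.0);
  for (int i = 0; i < g.nz; ++i) {
    int ii = std::min(std::max(i - npml, 0), nzi - 1);
    for (int j = 0; j < g.nx; ++j) {
      int jj = std::min(std::max(j - npml, 0), nxi - 1);
      g.epsr[(size_t)i * g.nx + j] = epsr(ii, jj);
      g.sig [(size_t)i * g.nx + j] = sigma(ii, jj);
    }
  }
  return g;
}

// quartic-graded PML conductivity profile at a (possibly half-integer)
// distance `pos` from the outer boundary measured in cells
static double pml_sigma(double depth_cells, int npml, double dx) {
  if (npml <= 0 || depth_cells <= 0) return 0.0;
  const double m = 4.0, R0 = 1e-7;
  double smax = (m + 1.0) * std::log(1.0 / R0) * EPS0 * C0 /
                (2.0 * npml * dx);
  double u = depth_cells / npml;
  if (u > 1.0) u = 1.0;
  return smax * std::pow(u, m);
}

// depth into the PML (in cells) of coordinate q in [0, n-1] (node units)
static double pml_depth(double q, int n, int npml) {
  double d1 = npml - q;           // distance into low-side PML
  double d2 = q - (n - 1 - npml); // distance into high-side PML
  double d = d1 > d2 ? d1 : d2;
  return d > 0 ? d : 0.0;
}

class FdtdSim {
public:
  int nz, nx, npml;
  double dx, dt;
  std::vector<double> ezx, ezy, hx, hy;
  std::vector<double> caX, cbX, caY, cbY;  // Ez split-component coefficients
  std::vector<double> daHx, dbHx, daHy, dbHy;

  FdtdSim(const NumericMatrix& epsr, const NumericMatrix& sigma,
          double dx_, double dt_, int npml_)
      : npml(npml_), dx(dx_), dt(dt_) {
    Grids g = pad_materials(epsr, sigma, npml);
    nz = g.nz; nx = g.nx;
    ezx.assign((size_t)nz * nx, 0.0);
    ezy.assign((size_t)nz * nx, 0.0);
    hx.assign((size_t)(nz - 1) * nx, 0.0);
    hy.assign((size_t)nz * (nx - 1), 0.0);
    caX.resize((size_t)nz * nx); cbX.resize((size_t)nz * nx);
    caY.resize((size_t)nz * nx); cbY.resize((size_t)nz * nx);
    for (int i = 0; i < nz; ++i) {
      for (int j = 0; j < nx; ++j) {
        size_t id = (size_t)i * nx + j;
        double er = g.epsr[id], sg = g.sig[id];
        double root = std::sqrt(er);
        // PML conductivity scaled for the local medium + physical loss
        double sx = pml_sigma(pml_depth((double)j, nx, npml), npml, dx) *
                    root + sg;
        double sy = pml_sigma(pml_depth((double)i, nz, npml), npml, dx) *
                    root + sg;
        double eps = EPS0 * er;
        double kx = sx * dt / (2.0 * eps), ky = sy * dt / (2.0 * eps);
        caX[id] = (1.0 - kx) / (1.0 + kx);
        cbX[id] = (dt / (eps * dx)) / (1.0 + kx);
        caY[id] = (1.0 - ky) / (1.0 + ky);
        cbY[id] = (dt / (eps * dx)) / (1.0 + ky);
      }
    }
    daHx.resize((size_t)(nz - 1) * nx); dbHx.resize((size_t)(nz - 1) * nx);
    for (int i = 0; i < nz - 1; ++i) {
      for (int j = 0; j < nx; ++j) {
        size_t id = (size_t)i * nx + j;
        double er = g.epsr[(size_t)i * nx + j];
        double ss = pml_sigma(pml_depth(i + 0.5, nz, npml), npml, dx) /
                    std::sqrt(er);
        double sstar = ss * MU0 / EPS0;
        double k = sstar * dt / (2.0 * MU0);
        daHx[id] = (1.0 - k) / (1.0 + k);
        dbHx[id] = (dt / (MU0 * dx)) / (1.0 + k);
      }
    }
    daHy.resize((size_t)nz * (nx - 1)); dbHy.resize((size_t)nz * (nx - 1));
    for (int i = 0; i < nz; ++i) {
      for (int j = 0; j < nx - 1; ++j) {
        size_t id = (size_t)i * (nx - 1) + j;
        double er = g.epsr[(size_t)i * nx + j];
        double ss = pml_sigma(pml_depth(j + 0.5, nx, npml), npml, dx) /
                    std::sqrt(er);
        double sstar = ss * MU0 / EPS0;
        double k = sstar * dt / (2.0 * MU0);
        daHy[id] = (1.0 - k) / (1.0 + k);
        dbHy[id] = (dt / (MU0 * dx)) / (1.0 + k);
      }
    }
  }

  inline double ez(int i, int j) const {
    size_t id = (size_t)i * nx + j;
    return ezx[id] + ezy[id];
  }

  void step_h() {
    for (int i = 0; i < nz - 1; ++i) {
      for (int j = 0; j < nx; ++j) {
        size_t id = (size_t)i * nx + j;
        hx[id] = daHx[id] * hx[id] -
                 dbHx[id] * (ez(i + 1, j) - ez(i, j));
      }
    }
    for (int i = 0; i < nz; ++i) {
      for (int j = 0; j < nx - 1; ++j) {
        size_t id = (size_t)i * (nx - 1) + j;
        hy[id] = daHy[id] * hy[id] +
                 dbHy[id] * (ez(i, j + 1) - ez(i, j));
      }
    }
  }

  void step_e() {
    for (int i = 1; i < nz - 1; ++i) {
      for (int j = 1; j < nx - 1; ++j) {
        size_t id = (size_t)i * nx + j;
        double curlx = hy[(size_t)i * (nx - 1) + j] -
                       hy[(size_t)i * (nx - 1) + j - 1];
        double curly = hx[(size_t)i * nx + j] -
                       hx[(size_t)(i - 1) * nx + j];
        ezx[id] = caX[id] * ezx[id] + cbX[id] * curlx;
        ezy[id] = caY[id] * ezy[id] - cbY[id] * curly;
      }
    }
  }

  void add_source(int i, int j, double val) {
    size_t id = (size_t)i * nx + j;
    ezx[id] += 0.5 * val;
    ezy[id] += 0.5 * val;
  }

  double energy() const {
    // discrete EM field energy (per unit length along the invariant axis),
    // with vacuum eps/mu weights: adequate for growth monitoring
    double eE = 0.0, eH = 0.0;
    for (size_t id = 0; id < ezx.size(); ++id) {
      double v = ezx[id] + ezy[id];
      eE += v * v;
    }
    for (size_t id = 0; id < hx.size(); ++id) eH += hx[id] * hx[id];
    for (size_t id = 0; id < hy.size(); ++id) eH += hy[id] * hy[id];
    return 0.5 * (EPS0 * eE + MU0 * eH) * dx * dx;
  }
};

// [[Rcpp::export]]
NumericVector fdtd_trace_cpp(NumericMatrix epsr, NumericMatrix sigma,
                             double dx, double dt, int nsteps,
                             int src_i, int src_j, int rx_i, int rx_j,
                             NumericVector src_wave, int npml) {
  FdtdSim sim(epsr, sigma, dx, dt, npml);
  int si = src_i + npml, sj = src_j + npml;
  int ri = rx_i + npml, rj = rx_j + npml;
  NumericVector trace(nsteps);
  for (int n = 0; n < nsteps; ++n) {
    sim.step_h();
    sim.step_e();
    if (n < src_wave.size()) sim.add_source(si, sj, src_wave[n]);
    double v = sim.ez(ri, rj);
    if (!std::isfinite(v))
      stop("FDTD instability: non-finite field at step %d", n + 1);
    trace[n] = v;
  }
  return trace;
}

// [[Rcpp::export]]
NumericVector fdtd_energy_cpp(NumericMatrix epsr, NumericMatrix sigma,
                              double dx, double dt, int nsteps,
                              int src_i, int src_j,
                              NumericVector src_wave, int npml,
                              int record_every) {
  FdtdSim sim(epsr, sigma, dx, dt, npml);
  int si = src_i + npml, sj = src_j + npml;
  std::vector<double> out;
  for (int n = 0; n < nsteps; ++n) {
    sim.step_h();
    sim.step_e();
    if (n < src_wave.size()) sim.add_source(si, sj, src_wave[n]);
    if ((n + 1) % record_every == 0) {
      double e = sim.energy();
      if (!std::isfinite(e))
        stop("FDTD instability: non-finite energy at step %d", n + 1);
      out.push_back(e);
    }
  }
  return wrap(out);
}
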