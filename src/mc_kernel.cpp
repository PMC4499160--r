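// Metropolis kernel for the primitive-model electrolyte: single-ion
// displacement moves, minimum-image Coulomb + hard spheres, optional
// cylindrical exclusion regions.  Uses R's RNG so set.seed() governs
// reproducibility.

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <limits>

using namespace Rcpp;

static const double KC = 1389.35;  // kJ A / (mol e^2)

static inline double min_image(double d, double L) {
  return d - L * std::round(d / L);
}

// energy of ion i against all other mobile ions and the fixed charges
static double ion_energy(int i,
                         const std::vector<double>& px,
                         const std::vector<double>& py,
                         const std::vector<double>& pz,
                         const std::vector<double>& q,
                         const std::vector<double>& rad,
                         const NumericMatrix& fpos,
                         const NumericVector& fq,
                         double frad,
                         const double* box, double eps,
                         const NumericMatrix& excl) {
  const double inf = std::numeric_limits<double>::infinity();
  // exclusion cylinders (axes parallel to z, unwrapped coordinates)
  for (int e = 0; e < excl.nrow(); ++e) {
    double dx = px[i] - excl(e, 0), dy = py[i] - excl(e, 1);
    double r = std::sqrt(dx * dx + dy * dy);
    if (r >= excl(e, 2) && r <= excl(e, 3) &&
        pz[i] >= excl(e, 4) && pz[i] <= excl(e, 5))
      return inf;
  }
  double E = 0.0;
  int n = (int)px.size();
  for (int j = 0; j < n; ++j) {
    if (j == i) continue;
    double dx = min_image(px[i] - px[j], box[0]);
    double dy = min_image(py[i] - py[j], box[1]);
    double dz = min_image(pz[i] - pz[j], box[2]);
    double r = std::sqrt(dx * dx + dy * dy + dz * dz);
    if (r < rad[i] + rad[j]) return inf;
    E += KC * q[i] * q[j] / (eps * r);
  }
  for (int m = 0; m < fpos.nrow(); ++m) {
    double dx = min_image(px[i] - fpos(m, 0), box[0]);
    double dy = min_image(py[i] - fpos(m, 1), box[1]);
    double dz = min_image(pz[i] - fpos(m, 2), box[2]);
    double r = std::sqrt(dx * dx + dy * dy + dz * dz);
    if (r < rad[i] + frad) return inf;
    E += KC * q[i] * fq[m] / (eps * r);
  }
  return E;
}

static double total_energy(const std::vector<double>& px,
                           const std::vector<double>& py,
                           const std::vector<double>& pz,
                           const std::vector<double>& q,
                           const std::vector<double>& rad,
                           const NumericMatrix& fpos,
                           const NumericVector& fq,
                           double frad,
                           const double* box, double eps,
                           const NumericMatrix& excl) {
  double E = 0.0;
  int n = (int)px.size();
  for (int i = 0; i < n; ++i) {
    double Ei = ion_energy(i, px, py, pz, q, rad, fpos, fq, frad,
                           box, eps, excl);
    if (!std::isfinite(Ei)) return Ei;
    E += Ei;  // mobile-mobile pairs counted twice, fixed once
  }
  // correct the double counting of mobile-mobile pairs:
  // E_total = 0.5 * sum_i E_mm(i) + sum_i E_mf(i); recompute mf part
  double Emf = 0.0;
  for (int i = 0; i < n; ++i) {
    for (int m = 0; m < fpos.nrow(); ++m) {
      double dx = min_image(px[i] - fpos(m, 0), box[0]);
      double dy = min_image(py[i] - fpos(m, 1), box[1]);
      double dz = min_image(pz[i] - fpos(m, 2), box[2]);
      double r = std::sqrt(dx * dx + dy * dy + dz * dz);
      Emf += KC * q[i] * fq[m] / (eps * r);
    }
  }
  return 0.5 * (E - Emf) + Emf;
}

static inline double wrap(double x, double L) {
  return x - L * std::floor(x / L);
}

// [[Rcpp::export]]
List mc_run_cpp(NumericMatrix pos, NumericVector q, NumericVector rad,
                NumericMatrix fpos, NumericVector fq, double frad,
                NumericVector box_, double eps, double kT,
                int n_sweeps, int burn_sweeps, double move0, bool tune,
                NumericMatrix excl, int sample_every) {
  int n = pos.nrow();
  double box[3] = {box_[0], box_[1], box_[2]};
  std::vector<double> px(n), py(n), pz(n), qq(n), rr(n);
  for (int i = 0; i < n; ++i) {
    px[i] = pos(i, 0); py[i] = pos(i, 1); pz[i] = pos(i, 2);
    qq[i] = q[i]; rr[i] = rad[i];
  }

  double E = total_energy(px, py, pz, qq, rr, fpos, fq, frad, box, eps, excl);
  if (!std::isfinite(E))
    stop("initial configuration has infinite energy (overlap or exclusion)");

  double move = move0;
  double maxmove = std::min(box[0], std::min(box[1], box[2])) / 2.0;
  long acc_prod = 0, att_prod = 0;
  long acc_tune = 0, att_tune = 0;

  int n_samples = 0;
  for (int s = burn_sweeps; s < n_sweeps; ++s)
    if ((s - burn_sweeps) % sample_every == 0) n_samples++;
  NumericVector samples(Dimension(n, 3, std::max(n_samples, 1)));
  NumericVector energies(std::max(n_samples, 1));
  int si = 0;

  for (int sweep = 0; sweep < n_sweeps; ++sweep) {
    for (int m = 0; m < n; ++m) {
      int i = (int)std::floor(R::runif(0.0, 1.0) * n);
      if (i >= n) i = n - 1;
      double ox = px[i], oy = py[i], oz = pz[i];
      double Eold = ion_energy(i, px, py, pz, qq, rr, fpos, fq, frad,
                               box, eps, excl);
      px[i] = wrap(ox + R::runif(-move, move), box[0]);
      py[i] = wrap(oy + R::runif(-move, move), box[1]);
      pz[i] = wrap(oz + R::runif(-move, move), box[2]);
      double Enew = ion_energy(i, px, py, pz, qq, rr, fpos, fq, frad,
                               box, eps, excl);
      double dE = Enew - Eold;
      bool accept;
      if (!std::isfinite(Enew)) accept = false;
      else if (dE <= 0.0) accept = true;
      else accept = (R::runif(0.0, 1.0) < std::exp(-dE / kT));
      if (accept) {
        E += dE;
      } else {
        px[i] = ox; py[i] = oy; pz[i] = oz;
      }
      if (sweep < burn_sweeps) {
        att_tune++; if (accept) acc_tune++;
        if (tune && att_tune >= 20L * n) {
          double rate = (double)acc_tune / (double)att_tune;
          if (rate < 0.30) move *= 0.77;
          else if (rate > 0.50) move *= 1.3;
          if (move > maxmove) move = maxmove;
          if (move < 0.05) move = 0.05;
          acc_tune = 0; att_tune = 0;
        }
      } else {
        att_prod++; if (accept) acc_prod++;
      }
    }
    if ((sweep + 1) % 10 == 0)  // kill accumulated round-off drift
      E = total_energy(px, py, pz, qq, rr, fpos, fq, frad, box, eps, excl);
    if (sweep >= burn_sweeps && (sweep - burn_sweeps) % sample_every == 0) {
      for (int i = 0; i < n; ++i) {
        samples[si * 3 * n + 0 * n + i] = px[i];
        samples[si * 3 * n + 1 * n + i] = py[i];
        samples[si * 3 * n + 2 * n + i] = pz[i];
      }
      energies[si] = E;
      si++;
    }
  }

  NumericMatrix out(n, 3);
  for (int i = 0; i < n; ++i) {
    out(i, 0) = px[i]; out(i, 1) = py[i]; out(i, 2) = pz[i];
  }
  double acc_rate = att_prod > 0 ? (double)acc_prod / (double)att_prod : 0.0;
  return List::create(_["pos_final"] = out,
                      _["samples"] = samples,
                      _["energies"] = energies,
                      _["acceptance"] = acc_rate,
                      _["move_final"] = move);
}
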