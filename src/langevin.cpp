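// Overdamped Langevin stepper for the coarse-grained toy system.
//
// Bead mobility codes: 0 = frozen, 1 = individually mobile (polymer bead),
// 2 = member of the rigid protein body (translated as one unit),
// 3 = member of a rigid polymer body (short stiff oligomer presets).
// Forces: harmonic polymer bonds, Gaussian attraction between "sticky"
// protein beads and polymer beads, Gaussian excluded-volume repulsion,
// uniform electric field on charged beads, per-axis harmonic tethers and an
// optional umbrella spring on the distance between the protein core bead
// and a fixed anchor point. Random numbers come from R's RNG so runs are
// reproducible with set.seed().

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// [[Rcpp::export]]
List langevin_run(NumericMatrix pos0, IntegerVector mobile,
                  IntegerVector poly_idx, double bond_k, double bond_r0,
                  IntegerVector sticky_idx, IntegerVector contact_idx,
                  double att_c, double att_w, double rep_A, double rep_w,
                  NumericVector charges, NumericVector efield,
                  IntegerVector teth_idx, NumericMatrix teth_k,
                  NumericMatrix teth_ref,
                  bool umb_on, double umb_k, double umb_center,
                  NumericVector umb_anchor, int core_idx,
                  double kbt, double D_protein, double D_polymer,
                  double dt, int n_steps, int stride, double max_step) {
  const int n = pos0.nrow();
  std::vector<double> px(n), py(n), pz(n);
  for (int i = 0; i < n; ++i) { px[i] = pos0(i,0); py[i] = pos0(i,1); pz[i] = pos0(i,2); }
  const int npoly = poly_idx.size();
  const int nsticky = sticky_idx.size();
  const int ncontact = contact_idx.size();
  const int nteth = teth_idx.size();
  const double att_cut2 = 16.0 * att_w * att_w;   // 4 sigma
  const double rep_cut2 = 16.0 * rep_w * rep_w;
  const double inv_w2 = 1.0 / (att_w * att_w);
  const double inv_s2 = 1.0 / (rep_w * rep_w);

  const int n_frames = n_steps / stride + 1;
  NumericVector coords(n_frames * n * 3);
  NumericVector times(n_frames);
  NumericVector xi_series(n_frames);

  std::vector<double> fx(n), fy(n), fz(n);
  const double mob_p = D_protein * dt / kbt;
  const double sig_p = std::sqrt(2.0 * D_protein * dt);
  const double mob_b = D_polymer * dt / kbt;
  const double sig_b = std::sqrt(2.0 * D_polymer * dt);

  auto record = [&](int fi, int step) {
    for (int i = 0; i < n; ++i) {
      coords[fi + (long)n_frames * i]                      = px[i];
      coords[fi + (long)n_frames * (i + (long)n)]          = py[i];
      coords[fi + (long)n_frames * (i + 2L * (long)n)]     = pz[i];
    }
    times[fi] = step * dt;
    double dxa = px[core_idx] - umb_anchor[0];
    double dya = py[core_idx] - umb_anchor[1];
    double dza = pz[core_idx] - umb_anchor[2];
    xi_series[fi] = std::sqrt(dxa * dxa + dya * dya + dza * dza);
  };

  record(0, 0);
  int fi = 1;

  for (int step = 1; step <= n_steps; ++step) {
    std::fill(fx.begin(), fx.end(), 0.0);
    std::fill(fy.begin(), fy.end(), 0.0);
    std::fill(fz.begin(), fz.end(), 0.0);

    // polymer bonds
    for (int b = 0; b + 1 < npoly; ++b) {
      int i = poly_idx[b], j = poly_idx[b + 1];
      double dx = px[i]-px[j], dy = py[i]-py[j], dz = pz[i]-pz[j];
      double d = std::sqrt(dx*dx + dy*dy + dz*dz);
      if (d < 1e-12) continue;
      double f = -bond_k * (d - bond_r0) / d;
      fx[i] += f*dx; fy[i] += f*dy; fz[i] += f*dz;
      fx[j] -= f*dx; fy[j] -= f*dy; fz[j] -= f*dz;
    }

    // attraction sticky x polymer
    if (att_c > 0.0) {
      for (int s = 0; s < nsticky; ++s) {
        int i = sticky_idx[s];
        for (int b = 0; b < npoly; ++b) {
          int j = poly_idx[b];
          double dx = px[i]-px[j], dy = py[i]-py[j], dz = pz[i]-pz[j];
          double d2 = dx*dx + dy*dy + dz*dz;
          if (d2 > att_cut2) continue;
          double f = -att_c * std::exp(-0.5 * d2 * inv_w2) * inv_w2;
          fx[i] += f*dx; fy[i] += f*dy; fz[i] += f*dz;
          fx[j] -= f*dx; fy[j] -= f*dy; fz[j] -= f*dz;
        }
      }
    }

    // repulsion contact beads x polymer
    for (int s = 0; s < ncontact; ++s) {
      int i = contact_idx[s];
      for (int b = 0; b < npoly; ++b) {
        int j = poly_idx[b];
        double dx = px[i]-px[j], dy = py[i]-py[j], dz = pz[i]-pz[j];
        double d2 = dx*dx + dy*dy + dz*dz;
        if (d2 > rep_cut2) continue;
        double f = rep_A * std::exp(-0.5 * d2 * inv_s2) * inv_s2;
        fx[i] += f*dx; fy[i] += f*dy; fz[i] += f*dz;
        fx[j] -= f*dx; fy[j] -= f*dy; fz[j] -= f*dz;
      }
    }

    // uniform field on charged beads
    for (int i = 0; i < n; ++i) {
      if (charges[i] != 0.0) {
        fx[i] += charges[i] * efield[0];
        fy[i] += charges[i] * efield[1];
        fz[i] += charges[i] * efield[2];
      }
    }

    // per-axis tethers
    for (int t = 0; t < nteth; ++t) {
      int i = teth_idx[t];
      fx[i] -= teth_k(t,0) * (px[i] - teth_ref(t,0));
      fy[i] -= teth_k(t,1) * (py[i] - teth_ref(t,1));
      fz[i] -= teth_k(t,2) * (pz[i] - teth_ref(t,2));
    }

    // umbrella spring on |core - anchor|
    if (umb_on) {
      double dx = px[core_idx]-umb_anchor[0];
      double dy = py[core_idx]-umb_anchor[1];
      double dz = pz[core_idx]-umb_anchor[2];
      double xi = std::sqrt(dx*dx + dy*dy + dz*dz);
      if (xi > 1e-12) {
        double f = -umb_k * (xi - umb_center) / xi;
        fx[core_idx] += f*dx; fy[core_idx] += f*dy; fz[core_idx] += f*dz;
      }
    }

    // rigid-body translations (2 = protein body, 3 = rigid polymer body)
    for (int body = 2; body <= 3; ++body) {
      double Fpx = 0, Fpy = 0, Fpz = 0; int nbody = 0;
      for (int i = 0; i < n; ++i) {
        if (mobile[i] == body) { Fpx += fx[i]; Fpy += fy[i]; Fpz += fz[i]; ++nbody; }
      }
      if (nbody == 0) continue;
      double mob = (body == 2) ? mob_p : mob_b;
      double sig = (body == 2) ? sig_p : sig_b;
      double ddx = mob * Fpx + sig * norm_rand();
      double ddy = mob * Fpy + sig * norm_rand();
      double ddz = mob * Fpz + sig * norm_rand();
      if (std::fabs(ddx) > max_step || std::fabs(ddy) > max_step ||
          std::fabs(ddz) > max_step)
        stop("numeric instability in rigid-body update at step %d", step);
      for (int i = 0; i < n; ++i) {
        if (mobile[i] == body) { px[i] += ddx; py[i] += ddy; pz[i] += ddz; }
      }
    }

    // individually mobile beads
    for (int i = 0; i < n; ++i) {
      if (mobile[i] == 1) {
        double ddx = mob_b * fx[i] + sig_b * norm_rand();
        double ddy = mob_b * fy[i] + sig_b * norm_rand();
        double ddz = mob_b * fz[i] + sig_b * norm_rand();
        if (std::fabs(ddx) > max_step || std::fabs(ddy) > max_step ||
            std::fabs(ddz) > max_step)
          stop("numeric instability in polymer update at step %d", step);
        px[i] += ddx; py[i] += ddy; pz[i] += ddz;
      }
    }

    if (step % stride == 0) { record(fi, step); ++fi; }
  }

  coords.attr("dim") = IntegerVector::create(n_frames, n, 3);
  return List::create(_["coords"] = coords, _["times"] = times,
                      _["xi"] = xi_series);
}
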