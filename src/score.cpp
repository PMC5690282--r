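#include <Rcpp.h>
using namespace Rcpp;

// Rigid-body pose energy: flat-bottom harmonic restraint term with a linear
// cap beyond the upper bound, plus a soft-sphere clash term over all
// inter-component Calpha pairs. The mobile coordinates are transformed as
// y = rot * x + trans before evaluation.
//
// Returns c(restraint_energy, clash_energy, n_satisfied).
// [[Rcpp::export]]
NumericVector cpp_pose_energy(const NumericMatrix& rec,
                              const NumericMatrix& mob,
                              const NumericMatrix& rot,
                              const NumericVector& trans,
                              const IntegerVector& ri,
                              const IntegerVector& mi,
                              const NumericVector& target,
                              const NumericVector& upper,
                              const NumericVector& weight,
                              double clash_dist,
                              double clash_weight,
                              double outlier_slope,
                              double contact_weight,
                              double contact_range,
                              int flat_bottom) {
  const int nm = mob.nrow(), nr = rec.nrow(), nres = ri.size();
  std::vector<double> mx(nm), my(nm), mz(nm);
  for (int i = 0; i < nm; ++i) {
    const double x = mob(i, 0), y = mob(i, 1), z = mob(i, 2);
    mx[i] = rot(0, 0) * x + rot(0, 1) * y + rot(0, 2) * z + trans[0];
    my[i] = rot(1, 0) * x + rot(1, 1) * y + rot(1, 2) * z + trans[1];
    mz[i] = rot(2, 0) * x + rot(2, 1) * y + rot(2, 2) * z + trans[2];
  }

  double e_res = 0.0;
  int n_sat = 0;
  for (int k = 0; k < nres; ++k) {
    const int a = ri[k], b = mi[k];  // 0-based indices
    const double dx = rec(a, 0) - mx[b];
    const double dy = rec(a, 1) - my[b];
    const double dz = rec(a, 2) - mz[b];
    const double d = std::sqrt(dx * dx + dy * dy + dz * dz);
    if (d <= upper[k]) ++n_sat;
    if (d <= upper[k]) {
      if (d > target[k]) {
        const double v = d - target[k];
        e_res += weight[k] * v * v;
      } else if (!flat_bottom) {
        // harmonic mode: quadratic on both sides of the target distance
        const double v = target[k] - d;
        e_res += weight[k] * v * v;
      }
    } else {
      const double span = upper[k] - target[k];
      e_res += weight[k] * (span * span + outlier_slope * (d - upper[k]));
    }
  }

  // nonbonded term: soft-sphere repulsion below clash_dist plus, when
  // contact_weight > 0, a shallow linear attraction ramp out to
  // contact_range (surface-complementarity proxy, cf. docking vdW terms)
  double e_clash = 0.0, e_att = 0.0;
  const double c2 = clash_dist * clash_dist;
  const double a2 = contact_range * contact_range;
  const double span_att = contact_range - clash_dist;
  for (int i = 0; i < nr; ++i) {
    const double rx = rec(i, 0), ry = rec(i, 1), rz = rec(i, 2);
    for (int j = 0; j < nm; ++j) {
      const double dx = rx - mx[j];
      double d2 = dx * dx;
      if (d2 >= a2) continue;
      const double dy = ry - my[j];
      d2 += dy * dy;
      if (d2 >= a2) continue;
      const double dz = rz - mz[j];
      d2 += dz * dz;
      if (d2 >= a2) continue;
      const double d = std::sqrt(d2);
      if (d < clash_dist) {
        const double v = clash_dist - d;
        e_clash += v * v;
        e_att -= 1.0;  // full attraction at/below contact distance
      } else if (contact_weight > 0.0 && span_att > 0.0) {
        e_att -= 1.0 - (d - clash_dist) / span_att;
      }
    }
  }
  e_clash = e_clash * clash_weight + e_att * contact_weight;

  return NumericVector::create(e_res, e_clash, (double)n_sat);
}

// Cross distances between two coordinate sets (rows), returned as a vector
// in column-major pair order; used by the synthetic-data generator.
// [[Rcpp::export]]
NumericVector cpp_cross_distances(const NumericMatrix& a,
                                  const NumericMatrix& b) {
  const int na = a.nrow(), nb = b.nrow();
  NumericVector out(na * nb);
  for (int j = 0; j < nb; ++j) {
    for (int i = 0; i < na; ++i) {
      const double dx = a(i, 0) - b(j, 0);
      const double dy = a(i, 1) - b(j, 1);
      const double dz = a(i, 2) - b(j, 2);
      out[j * na + i] = std::sqrt(dx * dx + dy * dy + dz * dz);
    }
  }
  return out;
}
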