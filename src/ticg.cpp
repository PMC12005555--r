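// Grid-based TICG Monte Carlo core.
//
// Beads live in a hard-walled cubic box; non-bonded energy is
// sum_{i<j, same grid cell} U(i,j) in kT, bonded energy is the Gaussian
// chain 3/(2 b^2) sum |r_{i+1}-r_i|^2. The grid offset is redrawn every
// sweep. All randomness comes from R's RNG so set.seed() in R controls
// the whole trajectory.

#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <cmath>

using namespace Rcpp;

namespace {

typedef std::unordered_map<uint64_t, std::vector<int> > CellMap;

inline uint64_t cell_key(double x, double y, double z, double inv_g,
                         double ox, double oy, double oz) {
  // indices are >= 0 because coords >= 0 and offsets >= 0
  uint64_t cx = (uint64_t)std::floor((x + ox) * inv_g);
  uint64_t cy = (uint64_t)std::floor((y + oy) * inv_g);
  uint64_t cz = (uint64_t)std::floor((z + oz) * inv_g);
  return (cx << 42) | (cy << 21) | cz;
}

struct Sim {
  int m;
  double b, box, g, inv_g;
  const double* U;           // m x m, column-major
  std::vector<double> x, y, z;
  std::vector<uint64_t> key; // current cell key per bead
  CellMap cells;
  double off[3];
  double Enb;                // tracked non-bonded energy

  double uij(int i, int j) const { return U[i + (size_t)m * j]; }

  // energy change of removing bead i from its cell's occupant list
  double remove_bead(int i) {
    std::vector<int>& v = cells[key[i]];
    double dE = 0.0;
    size_t pos = v.size();
    for (size_t t = 0; t < v.size(); ++t) {
      if (v[t] == i) pos = t; else dE -= uij(i, v[t]);
    }
    v[pos] = v.back();
    v.pop_back();
    if (v.empty()) cells.erase(key[i]);
    return dE;
  }

  double insert_bead(int i, uint64_t k) {
    std::vector<int>& v = cells[k];
    double dE = 0.0;
    for (size_t t = 0; t < v.size(); ++t) dE += uij(i, v[t]);
    v.push_back(i);
    key[i] = k;
    return dE;
  }

  void rebuild_cells() {
    cells.clear();
    Enb = 0.0;
    for (int i = 0; i < m; ++i) {
      uint64_t k = cell_key(x[i], y[i], z[i], inv_g, off[0], off[1], off[2]);
      Enb += insert_bead(i, k);
    }
  }

  double full_nonbonded() const {
    double e = 0.0;
    for (CellMap::const_iterator it = cells.begin(); it != cells.end(); ++it) {
      const std::vector<int>& v = it->second;
      for (size_t a = 0; a + 1 < v.size(); ++a)
        for (size_t c = a + 1; c < v.size(); ++c)
          e += uij(v[a], v[c]);
    }
    return e;
  }

  bool in_box(double px, double py, double pz) const {
    return px >= 0.0 && px <= box && py >= 0.0 && py <= box &&
           pz >= 0.0 && pz <= box;
  }
};

inline bool metropolis(double dE) {
  if (dE <= 0.0) return true;
  return unif_rand() < std::exp(-dE);
}

} // namespace

// [[Rcpp::export]]
List ticg_sample(NumericMatrix U, int m, double b, double box, double g,
                 int n_structures, int n_equil, int n_between,
                 NumericVector move_weights, double step_bead,
                 double crank_max_angle, double step_chain,
                 int check_energy_every) {
  if (U.nrow() != m || U.ncol() != m) stop("U must be m x m");
  RNGScope scope;

  Sim S;
  S.m = m; S.b = b; S.box = box; S.g = g; S.inv_g = 1.0 / g;
  S.U = U.begin();
  S.x.resize(m); S.y.resize(m); S.z.resize(m);
  S.key.resize(m);

  // initial configuration: exact Gaussian-chain draw from the box centre,
  // reflected into the box (equilibration fixes any wall distortion)
  double sd0 = b / std::sqrt(3.0);
  double cx = box / 2, cy = box / 2, cz = box / 2;
  S.x[0] = cx; S.y[0] = cy; S.z[0] = cz;
  for (int i = 1; i < m; ++i) {
    S.x[i] = S.x[i - 1] + sd0 * norm_rand();
    S.y[i] = S.y[i - 1] + sd0 * norm_rand();
    S.z[i] = S.z[i - 1] + sd0 * norm_rand();
  }
  for (int i = 0; i < m; ++i) {   // reflect into [0, box]
    double* p[3] = { &S.x[i], &S.y[i], &S.z[i] };
    for (int a = 0; a < 3; ++a) {
      double period = 2.0 * box;
      double v = *p[a] - period * std::floor(*p[a] / period);
      *p[a] = (v <= box) ? v : 2.0 * box - v;
    }
  }

  double wb = move_weights[0];
  double wc = wb + move_weights[1];
  double kbond = 3.0 / (2.0 * b * b);
  int max_seg = std::min(m - 1, std::max(4, m / 4));

  long attempted = 0, accepted = 0, moves_done = 0;
  double max_echeck = -1.0;

  NumericVector coords(Dimension(n_structures, m, 3));
  NumericMatrix offsets(n_structures, 3);

  long total_sweeps = (long)n_equil + (long)n_between * n_structures;
  int sample_idx = 0;

  for (long sweep = 0; sweep < total_sweeps; ++sweep) {
    S.off[0] = g * unif_rand();
    S.off[1] = g * unif_rand();
    S.off[2] = g * unif_rand();
    S.rebuild_cells();

    for (int mv = 0; mv < m; ++mv) {
      ++attempted;
      double u = unif_rand();
      if (u < wb) {
        // single-bead Gaussian displacement
        int i = (int)(m * unif_rand()); if (i == m) --i;
        double nx = S.x[i] + step_bead * norm_rand();
        double ny = S.y[i] + step_bead * norm_rand();
        double nz = S.z[i] + step_bead * norm_rand();
        if (!S.in_box(nx, ny, nz)) { ++moves_done; continue; }
        double dEb = 0.0;
        if (i > 0) {
          dEb += kbond * ((nx - S.x[i-1])*(nx - S.x[i-1]) +
                          (ny - S.y[i-1])*(ny - S.y[i-1]) +
                          (nz - S.z[i-1])*(nz - S.z[i-1]) -
                          (S.x[i] - S.x[i-1])*(S.x[i] - S.x[i-1]) -
                          (S.y[i] - S.y[i-1])*(S.y[i] - S.y[i-1]) -
                          (S.z[i] - S.z[i-1])*(S.z[i] - S.z[i-1]));
        }
        if (i < m - 1) {
          dEb += kbond * ((nx - S.x[i+1])*(nx - S.x[i+1]) +
                          (ny - S.y[i+1])*(ny - S.y[i+1]) +
                          (nz - S.z[i+1])*(nz - S.z[i+1]) -
                          (S.x[i] - S.x[i+1])*(S.x[i] - S.x[i+1]) -
                          (S.y[i] - S.y[i+1])*(S.y[i] - S.y[i+1]) -
                          (S.z[i] - S.z[i+1])*(S.z[i] - S.z[i+1]));
        }
        uint64_t oldk = S.key[i];
        uint64_t newk = cell_key(nx, ny, nz, S.inv_g,
                                 S.off[0], S.off[1], S.off[2]);
        double dEnb = 0.0;
        if (newk != oldk) {
          dEnb += S.remove_bead(i);
          dEnb += S.insert_bead(i, newk);
        }
        if (metropolis(dEb + dEnb)) {
          S.x[i] = nx; S.y[i] = ny; S.z[i] = nz;
          S.Enb += dEnb;
          ++accepted;
        } else if (newk != oldk) {
          S.remove_bead(i);
          S.insert_bead(i, oldk);
        }
      } else if (u < wc && m >= 3) {
        // crankshaft: rotate interior of segment (i .. j) about axis r_i->r_j
        int seg = 2 + (int)((max_seg - 1) * unif_rand());
        if (seg > m - 1) seg = m - 1;
        int i = (int)((m - seg) * unif_rand()); if (i > m - 1 - seg) i = m - 1 - seg;
        int j = i + seg;
        double ax = S.x[j] - S.x[i], ay = S.y[j] - S.y[i], az = S.z[j] - S.z[i];
        double an = std::sqrt(ax*ax + ay*ay + az*az);
        if (an < 1e-9) { ++moves_done; continue; }
        ax /= an; ay /= an; az /= an;
        double th = crank_max_angle * (2.0 * unif_rand() - 1.0);
        double ct = std::cos(th), st = std::sin(th);
        int nmov = j - i - 1;
        std::vector<double> npx(nmov), npy(nmov), npz(nmov);
        bool ok = true;
        for (int t = 0; t < nmov; ++t) {
          int p = i + 1 + t;
          double vx = S.x[p] - S.x[i], vy = S.y[p] - S.y[i], vz = S.z[p] - S.z[i];
          double ad = ax*vx + ay*vy + az*vz;
          // Rodrigues rotation about unit axis a
          double rx = vx*ct + (ay*vz - az*vy)*st + ax*ad*(1-ct);
          double ry = vy*ct + (az*vx - ax*vz)*st + ay*ad*(1-ct);
          double rz = vz*ct + (ax*vy - ay*vx)*st + az*ad*(1-ct);
          npx[t] = S.x[i] + rx; npy[t] = S.y[i] + ry; npz[t] = S.z[i] + rz;
          if (!S.in_box(npx[t], npy[t], npz[t])) { ok = false; break; }
        }
        if (!ok) { ++moves_done; continue; }
        // bonded energy invariant under rotation about the endpoint axis
        std::vector<uint64_t> oldk(nmov);
        double dEnb = 0.0;
        for (int t = 0; t < nmov; ++t) {
          oldk[t] = S.key[i + 1 + t];
          dEnb += S.remove_bead(i + 1 + t);
        }
        for (int t = 0; t < nmov; ++t) {
          uint64_t k = cell_key(npx[t], npy[t], npz[t], S.inv_g,
                                S.off[0], S.off[1], S.off[2]);
          dEnb += S.insert_bead(i + 1 + t, k);
        }
        if (metropolis(dEnb)) {
          for (int t = 0; t < nmov; ++t) {
            S.x[i + 1 + t] = npx[t]; S.y[i + 1 + t] = npy[t];
            S.z[i + 1 + t] = npz[t];
          }
          S.Enb += dEnb;
          ++accepted;
        } else {
          for (int t = 0; t < nmov; ++t) S.remove_bead(i + 1 + t);
          for (int t = 0; t < nmov; ++t) S.insert_bead(i + 1 + t, oldk[t]);
        }
      } else {
        // whole-chain translation: bonded energy unchanged, but grid cells
        // (hence contacts) change because the grid is fixed in space
        double dx = step_chain * norm_rand();
        double dy = step_chain * norm_rand();
        double dz = step_chain * norm_rand();
        bool ok = true;
        for (int i = 0; i < m && ok; ++i)
          ok = S.in_box(S.x[i] + dx, S.y[i] + dy, S.z[i] + dz);
        if (!ok) { ++moves_done; continue; }
        std::vector<uint64_t> oldk(S.key);
        double dEnb = 0.0;
        for (int i = 0; i < m; ++i) dEnb += S.remove_bead(i);
        for (int i = 0; i < m; ++i) {
          uint64_t k = cell_key(S.x[i] + dx, S.y[i] + dy, S.z[i] + dz,
                                S.inv_g, S.off[0], S.off[1], S.off[2]);
          dEnb += S.insert_bead(i, k);
        }
        if (metropolis(dEnb)) {
          for (int i = 0; i < m; ++i) {
            S.x[i] += dx; S.y[i] += dy; S.z[i] += dz;
          }
          S.Enb += dEnb;
          ++accepted;
        } else {
          for (int i = 0; i < m; ++i) S.remove_bead(i);
          for (int i = 0; i < m; ++i) S.insert_bead(i, oldk[i]);
        }
      }
      ++moves_done;
      if (check_energy_every > 0 && moves_done % check_energy_every == 0) {
        double diff = std::fabs(S.Enb - S.full_nonbonded());
        if (diff > max_echeck) max_echeck = diff;
      }
    }

    if (!R_FINITE(S.Enb)) stop("non-finite non-bonded energy at sweep %ld", sweep);

    if (sweep >= n_equil && (sweep - n_equil + 1) % n_between == 0) {
      if (sample_idx < n_structures) {
        for (int i = 0; i < m; ++i) {
          coords[sample_idx + (size_t)n_structures * i] = S.x[i];
          coords[sample_idx + (size_t)n_structures * (i + (size_t)m)] = S.y[i];
          coords[sample_idx + (size_t)n_structures * (i + 2 * (size_t)m)] = S.z[i];
        }
        offsets(sample_idx, 0) = S.off[0];
        offsets(sample_idx, 1) = S.off[1];
        offsets(sample_idx, 2) = S.off[2];
        ++sample_idx;
      }
    }
  }

  return List::create(
    _["coords"] = coords,
    _["offsets"] = offsets,
    _["acceptance_rate"] = (double)accepted / (double)attempted,
    _["energy_check_max"] = (check_energy_every > 0 && max_echeck >= 0)
                              ? NumericVector::create(max_echeck)
                              : NumericVector::create(NA_REAL));
}

// [[Rcpp::export]]
NumericMatrix ticg_contact_map(NumericVector coords, NumericMatrix offsets,
                               double g) {
  IntegerVector dims = coords.attr("dim");
  int n = dims[0], m = dims[1];
  NumericMatrix H(m, m);
  double inv_g = 1.0 / g;
  std::unordered_map<uint64_t, std::vector<int> > cells;
  for (int s = 0; s < n; ++s) {
    cells.clear();
    double ox = offsets(s, 0), oy = offsets(s, 1), oz = offsets(s, 2);
    for (int i = 0; i < m; ++i) {
      double x = coords[s + (size_t)n * i];
      double y = coords[s + (size_t)n * (i + (size_t)m)];
      double z = coords[s + (size_t)n * (i + 2 * (size_t)m)];
      cells[cell_key(x, y, z, inv_g, ox, oy, oz)].push_back(i);
    }
    for (std::unordered_map<uint64_t, std::vector<int> >::iterator it =
           cells.begin(); it != cells.end(); ++it) {
      std::vector<int>& v = it->second;
      for (size_t a = 0; a + 1 < v.size(); ++a)
        for (size_t c = a + 1; c < v.size(); ++c) {
          H(v[a], v[c]) += 1.0;
          H(v[c], v[a]) += 1.0;
        }
    }
  }
  for (int i = 0; i < m; ++i)
    for (int j = 0; j < m; ++j)
      H(i, j) = (i == j) ? 1.0 : H(i, j) / n;
  return H;
}

// [[Rcpp::export]]
NumericMatrix ticg_mean_distance(NumericVector coords) {
  IntegerVector dims = coords.attr("dim");
  int n = dims[0], m = dims[1];
  NumericMatrix D(m, m);
  for (int s = 0; s < n; ++s) {
    for (int i = 0; i < m; ++i) {
      double xi = coords[s + (size_t)n * i];
      double yi = coords[s + (size_t)n * (i + (size_t)m)];
      double zi = coords[s + (size_t)n * (i + 2 * (size_t)m)];
      for (int j = i + 1; j < m; ++j) {
        double dx = xi - coords[s + (size_t)n * j];
        double dy = yi - coords[s + (size_t)n * (j + (size_t)m)];
        double dz = zi - coords[s + (size_t)n * (j + 2 * (size_t)m)];
        D(i, j) += std::sqrt(dx*dx + dy*dy + dz*dz);
      }
    }
  }
  for (int i = 0; i < m; ++i)
    for (int j = i + 1; j < m; ++j) {
      D(i, j) /= n;
      D(j, i) = D(i, j);
    }
  return D;
}
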