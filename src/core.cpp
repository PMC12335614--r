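#include <Rcpp.h>
using namespace Rcpp;

// Occupancy codes shared with R/AllClasses.R (.OCC constants).
static const int OCC_EMPTY = 0;
static const int OCC_VESSEL = 1;
static const int OCC_CANCER = 2;
static const int OCC_SPASSIVE = 3;
static const int OCC_SREACTIVE = 4;

// Moore neighbourhood offsets (truncated at domain boundary, no wrap).
static const int DR[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
static const int DC[8] = {-1, 0, 1, -1, 1, -1, 0, 1};

static inline int unif_index(int n) {
  // uniform draw in 0..n-1 from R's RNG stream
  int k = (int)(unif_rand() * n);
  return (k >= n) ? n - 1 : k;
}

// Advance the drug field one macro step of length dt, split into nsub explicit
// Euler substeps: 5-point Laplacian with zero-flux (ghost-node reflection)
// boundaries; clearance -mu*d applied at vessel sites only; when delivering,
// d is clamped to 1 at every vessel site after each substep (Dirichlet
// delivery). Mutates d in place.
// [[Rcpp::export]]
void cpp_step_drug(NumericMatrix d, LogicalMatrix vmask, bool delivering,
                   int nsub, double Dd, double mu, double dt, double dx) {
  const int nr = d.nrow(), nc = d.ncol();
  const int n = nr * nc;
  const double dts = dt / nsub;
  const double k = Dd * dts / (dx * dx);
  std::vector<double> buf((size_t)n);
  std::vector<int> vidx;
  {
    const int* vm = LOGICAL(vmask);
    for (int idx = 0; idx < n; ++idx)
      if (vm[idx]) vidx.push_back(idx);
  }
  double* base = REAL(d);
  double* src = base;
  double* dst = buf.data();
  for (int s = 0; s < nsub; ++s) {
    // interior: branch-free 5-point stencil
    for (int j = 1; j < nc - 1; ++j) {
      const int off = j * nr;
      for (int i = 1; i < nr - 1; ++i) {
        const int idx = off + i;
        const double c = src[idx];
        dst[idx] = c + k * (src[idx - 1] + src[idx + 1] + src[idx - nr] +
                            src[idx + nr] - 4.0 * c);
      }
    }
    // boundaries: zero-flux via reflection (missing neighbour := centre)
    for (int j = 0; j < nc; ++j) {
      for (int i = 0; i < nr; i += (j == 0 || j == nc - 1) ? 1 : nr - 1) {
        const int idx = j * nr + i;
        const double c = src[idx];
        const double up = (i > 0) ? src[idx - 1] : c;
        const double dn = (i < nr - 1) ? src[idx + 1] : c;
        const double lf = (j > 0) ? src[idx - nr] : c;
        const double rt = (j < nc - 1) ? src[idx + nr] : c;
        dst[idx] = c + k * (up + dn + lf + rt - 4.0 * c);
        if (nr == 1) break;
      }
    }
    // clearance at vessel sites, then the delivery clamp
    for (size_t v = 0; v < vidx.size(); ++v) {
      const int idx = vidx[v];
      dst[idx] -= dts * mu * src[idx];
      if (delivering) dst[idx] = 1.0;
    }
    std::swap(src, dst);
  }
  if (src != base) std::copy(src, src + n, base);
}

// One explicit Euler macro step of the (non-diffusing) proliferation signal:
//   dp/dt = (beta + gamma * A(x)) * H(1 - p) * s(x) - delta * d * p
// s(x) = 1 at cancer sites, A(x) = number of activated reactive stroma cells
// in the Moore neighbourhood, H(1 - p) = 0 when p >= 1 (hard saturation cap).
// Result clipped to [0, 1]. Mutates p in place.
// [[Rcpp::export]]
void cpp_step_signal(NumericMatrix p, NumericMatrix d, IntegerMatrix occ,
                     LogicalMatrix act, double beta, double gamma,
                     double delta, double dt) {
  const int nr = p.nrow(), nc = p.ncol();
  double* pp = REAL(p);
  const double* pd = REAL(d);
  const int* po = INTEGER(occ);
  const int* pa = LOGICAL(act);
  for (int j = 0; j < nc; ++j) {
    const int off = j * nr;
    for (int i = 0; i < nr; ++i) {
      const int idx = off + i;
      const double pc = pp[idx];
      double prod = 0.0;
      if (po[idx] == OCC_CANCER && pc < 1.0) {
        int a = 0;
        for (int m = 0; m < 8; ++m) {
          const int r = i + DR[m], c = j + DC[m];
          if (r >= 0 && r < nr && c >= 0 && c < nc && pa[c * nr + r]) ++a;
        }
        prod = beta + gamma * a;
      }
      double v = pc + dt * (prod - delta * pd[idx] * pc);
      if (v < 0.0) v = 0.0;
      if (v > 1.0) v = 1.0;
      pp[idx] = v;
    }
  }
}

// Reactive stroma state changes. Activated cells with local drug below hr
// deactivate immediately and deterministically; deactivated reactive stroma
// with d >= hr AND at least one cancer cell in its Moore neighbourhood
// activates with per-step probability pA * dt. Passive stroma never changes.
// Mutates act in place.
// [[Rcpp::export]]
void cpp_update_reactive(IntegerMatrix occ, LogicalMatrix act, NumericMatrix d,
                         double dt, double pA, double hr) {
  const int nr = occ.nrow(), nc = occ.ncol();
  const double pstep = pA * dt;
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      if (occ(i, j) != OCC_SREACTIVE) continue;
      if (act(i, j)) {
        if (d(i, j) < hr) act(i, j) = FALSE;
      } else if (d(i, j) >= hr) {
        bool nearCancer = false;
        for (int m = 0; m < 8 && !nearCancer; ++m) {
          const int r = i + DR[m], c = j + DC[m];
          if (r >= 0 && r < nr && c >= 0 && c < nc &&
              occ(r, c) == OCC_CANCER)
            nearCancer = true;
        }
        if (nearCancer && unif_rand() < pstep) act(i, j) = TRUE;
      }
    }
  }
}

// Cancer phase: cells enumerated at phase entry, visited in a uniform random
// permutation. Viability from the local signal: p < hd -> death (site
// emptied); hd <= p < hp -> quiescent (clock frozen); p >= hp -> clock
// advances by dt and, once the clock reaches the intermitotic time I,
// division is attempted. Cancer has no contact inhibition: division succeeds
// whenever an empty Moore site exists (daughter placed uniformly at random),
// otherwise the clock is held at I and the attempt is retried next step. Both
// daughters get clock 0, fresh independent I ~ U[iMin, iMax], and the local
// signal raised to at least p0 (birth floor) at both sites. Cells born during
// the phase are not revisited. Mutates occ/act/clock/imt/p in place; returns
// c(births, deaths).
// [[Rcpp::export]]
IntegerVector cpp_advance_cancer(IntegerMatrix occ, LogicalMatrix act,
                                 NumericMatrix clock, NumericMatrix imt,
                                 NumericMatrix p, double dt, double hd,
                                 double hp, double p0, double iMin,
                                 double iMax) {
  const int nr = occ.nrow(), nc = occ.ncol();
  std::vector<int> pos;
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i)
      if (occ(i, j) == OCC_CANCER) pos.push_back(i + nr * j);
  const int n = (int)pos.size();
  // Fisher-Yates permutation from R's RNG
  for (int i = n - 1; i > 0; --i) std::swap(pos[i], pos[unif_index(i + 1)]);
  LogicalMatrix born(nr, nc);
  int births = 0, deaths = 0;
  for (int idx = 0; idx < n; ++idx) {
    const int i = pos[idx] % nr, j = pos[idx] / nr;
    if (occ(i, j) != OCC_CANCER || born(i, j)) continue;
    const double ploc = p(i, j);
    if (ploc < hd) {  // death
      occ(i, j) = OCC_EMPTY;
      act(i, j) = FALSE;
      clock(i, j) = 0.0;
      imt(i, j) = 0.0;
      ++deaths;
      continue;
    }
    if (ploc < hp) continue;  // quiescent: clock frozen
    clock(i, j) += dt;
    if (clock(i, j) < imt(i, j)) continue;
    int empties[8], ne = 0;
    for (int m = 0; m < 8; ++m) {
      const int r = i + DR[m], c = j + DC[m];
      if (r >= 0 && r < nr && c >= 0 && c < nc && occ(r, c) == OCC_EMPTY)
        empties[ne++] = r + nr * c;
    }
    if (ne == 0) {  // blocked: hold the clock at I, retry next step
      clock(i, j) = imt(i, j);
      continue;
    }
    const int tgt = empties[unif_index(ne)];
    const int ti = tgt % nr, tj = tgt / nr;
    occ(ti, tj) = OCC_CANCER;
    act(ti, tj) = FALSE;
    born(ti, tj) = TRUE;
    clock(ti, tj) = 0.0;
    imt(ti, tj) = iMin + unif_rand() * (iMax - iMin);
    clock(i, j) = 0.0;
    imt(i, j) = iMin + unif_rand() * (iMax - iMin);
    if (p(i, j) < p0) p(i, j) = p0;  // birth floor at both daughter sites
    if (p(ti, tj) < p0) p(ti, tj) = p0;
    ++births;
  }
  return IntegerVector::create(births, deaths);
}

// Stroma phase: turnover death with per-step probability pT * dt; survivors
// advance clocks by dt unconditionally (stroma ignores the signal). When the
// clock reaches I division is attempted under contact inhibition: aborted
// (clock reset, fresh I) if the number of occupied Moore neighbours (any
// class, vessels included) exceeds nCI, or if no empty Moore site exists.
// Daughters inherit type and activation state. Mutates in place; returns
// c(births, deaths).
// [[Rcpp::export]]
IntegerVector cpp_advance_stroma(IntegerMatrix occ, LogicalMatrix act,
                                 NumericMatrix clock, NumericMatrix imt,
                                 double dt, double pT, int nCI, double iMin,
                                 double iMax) {
  const int nr = occ.nrow(), nc = occ.ncol();
  std::vector<int> pos;
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i)
      if (occ(i, j) == OCC_SPASSIVE || occ(i, j) == OCC_SREACTIVE)
        pos.push_back(i + nr * j);
  const int n = (int)pos.size();
  for (int i = n - 1; i > 0; --i) std::swap(pos[i], pos[unif_index(i + 1)]);
  LogicalMatrix born(nr, nc);
  const double pdeath = pT * dt;
  int births = 0, deaths = 0;
  for (int idx = 0; idx < n; ++idx) {
    const int i = pos[idx] % nr, j = pos[idx] / nr;
    const int type = occ(i, j);
    if ((type != OCC_SPASSIVE && type != OCC_SREACTIVE) || born(i, j))
      continue;
    if (unif_rand() < pdeath) {  // turnover
      occ(i, j) = OCC_EMPTY;
      act(i, j) = FALSE;
      clock(i, j) = 0.0;
      imt(i, j) = 0.0;
      ++deaths;
      continue;
    }
    clock(i, j) += dt;
    if (clock(i, j) < imt(i, j)) continue;
    int nocc = 0, empties[8], ne = 0;
    for (int m = 0; m < 8; ++m) {
      const int r = i + DR[m], c = j + DC[m];
      if (r < 0 || r >= nr || c < 0 || c >= nc) continue;
      if (occ(r, c) == OCC_EMPTY)
        empties[ne++] = r + nr * c;
      else
        ++nocc;
    }
    if (nocc > nCI || ne == 0) {  // aborted: the failed attempt consumes the cycle
      clock(i, j) = 0.0;
      imt(i, j) = iMin + unif_rand() * (iMax - iMin);
      continue;
    }
    const int tgt = empties[unif_index(ne)];
    const int ti = tgt % nr, tj = tgt / nr;
    occ(ti, tj) = type;
    act(ti, tj) = act(i, j);  // daughters inherit type and activation state
    born(ti, tj) = TRUE;
    clock(ti, tj) = 0.0;
    imt(ti, tj) = iMin + unif_rand() * (iMax - iMin);
    clock(i, j) = 0.0;
    imt(i, j) = iMin + unif_rand() * (iMax - iMin);
    ++births;
  }
  return IntegerVector::create(births, deaths);
}

// Vessel-density measure on the lattice:
//   rho(x) = sum_{y in V} exp(-alphaHat * |x - y|) /
//            sum_{y in Omega} exp(-alphaHat * |x - y|)
// Distances in lattice units; coords are 1-based (row, col) vessel positions.
// [[Rcpp::export]]
NumericMatrix cpp_density_map(int nr, int nc, IntegerMatrix coords,
                              double alphaHat) {
  NumericMatrix rho(nr, nc);
  const int nv = coords.nrow();
  // kernel table over absolute offsets
  NumericMatrix E(nr, nc);
  for (int b = 0; b < nc; ++b)
    for (int a = 0; a < nr; ++a)
      E(a, b) = std::exp(-alphaHat * std::sqrt((double)(a * a + b * b)));
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      double num = 0.0;
      for (int v = 0; v < nv; ++v) {
        num += E(std::abs(i - (coords(v, 0) - 1)),
                 std::abs(j - (coords(v, 1) - 1)));
      }
      double den = 0.0;
      for (int jj = 0; jj < nc; ++jj)
        for (int ii = 0; ii < nr; ++ii)
          den += E(std::abs(i - ii), std::abs(j - jj));
      rho(i, j) = (nv == 0) ? 0.0 : num / den;
    }
  }
  return rho;
}
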