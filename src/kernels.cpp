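#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Manual complex arithmetic on (re, im) double pairs: the hot loops avoid
// std::complex, whose IEC-559 multiply is far too slow for these volumes.

// Phase tables along one axis: tab[2*(idx-idx_min)] + i*tab[...+1] =
// exp(2*pi*i * idx * x), built by recurrence from the lowest index.
// Indices are the integer grid indices of the (super)cell box; x is
// fractional in that box, so no sampling-factor bookkeeping is needed.
static void phase_table(int imin, int imax, double x,
                        std::vector<double> &tab) {
  const double tau = 2.0 * M_PI;
  int n = imax - imin + 1;
  tab.resize(2 * n);
  double sr = std::cos(tau * x), si = std::sin(tau * x);
  double cr = std::cos(tau * imin * x), ci = std::sin(tau * imin * x);
  for (int t = 0; t < n; ++t) {
    tab[2 * t] = cr;
    tab[2 * t + 1] = ci;
    double nr = cr * sr - ci * si;
    ci = cr * si + ci * sr;
    cr = nr;
  }
}

struct IndexBounds {
  int hmin, hmax, kmin, kmax, lmin, lmax;
};

static IndexBounds bounds_of(const IntegerVector &ih,
                             const IntegerVector &ik,
                             const IntegerVector &il) {
  IndexBounds b = {0, 0, 0, 0, 0, 0};
  for (int p = 0; p < ih.size(); ++p) {
    if (p == 0 || ih[p] < b.hmin) b.hmin = ih[p];
    if (p == 0 || ih[p] > b.hmax) b.hmax = ih[p];
    if (p == 0 || ik[p] < b.kmin) b.kmin = ik[p];
    if (p == 0 || ik[p] > b.kmax) b.kmax = ik[p];
    if (p == 0 || il[p] < b.lmin) b.lmin = il[p];
    if (p == 0 || il[p] > b.lmax) b.lmax = il[p];
  }
  return b;
}

// One atom's contribution w * exp(2 pi i (h x + k y + l z)) accumulated
// into (acc_re, acc_im) over all grid points.
static void accumulate_atom(const IndexBounds &b, const int *ih,
                            const int *ik, const int *il, int m,
                            double x, double y, double z, double w,
                            std::vector<double> &th, std::vector<double> &tk,
                            std::vector<double> &tl, double *acc_re,
                            double *acc_im) {
  phase_table(b.hmin, b.hmax, x, th);
  phase_table(b.kmin, b.kmax, y, tk);
  phase_table(b.lmin, b.lmax, z, tl);
  for (int p = 0; p < m; ++p) {
    int a = 2 * (ih[p] - b.hmin), c = 2 * (ik[p] - b.kmin),
        d = 2 * (il[p] - b.lmin);
    double hr = th[a], hi = th[a + 1];
    double kr = tk[c], ki = tk[c + 1];
    double lr = tl[d], li = tl[d + 1];
    double hkr = hr * kr - hi * ki;
    double hki = hr * ki + hi * kr;
    double vr = hkr * lr - hki * li;
    double vi = hkr * li + hki * lr;
    acc_re[p] += w * vr;
    acc_im[p] += w * vi;
  }
}

// Plain phase sum S(p) = sum_j w_j exp(2 pi i (ih_p x_j + ik_p y_j +
// il_p z_j)) over one atom group; coords fractional in the periodic box.
// [[Rcpp::export]]
ComplexVector sf_phase_sum_cpp(IntegerVector ih, IntegerVector ik,
                               IntegerVector il, NumericMatrix coords,
                               NumericVector w) {
  int m = ih.size(), n = coords.nrow();
  IndexBounds b = bounds_of(ih, ik, il);
  std::vector<double> re(m, 0.0), im(m, 0.0), th, tk, tl;
  for (int j = 0; j < n; ++j) {
    accumulate_atom(b, &ih[0], &ik[0], &il[0], m, coords(j, 0),
                    coords(j, 1), coords(j, 2), w[j], th, tk, tl,
                    re.data(), im.data());
  }
  ComplexVector out(m);
  for (int p = 0; p < m; ++p) {
    out[p].r = re[p];
    out[p].i = im[p];
  }
  return out;
}

// Streaming Guinier accumulation over an ensemble: per snapshot assemble
// f(p) = sum_groups ffac(p, g) * S_g(p), then accumulate sum f and
// sum |f|^2. coords: one (n_g x 3 x nsnap) array per element group,
// fractional in the periodic box; ffac: per-point form factor per group.
// [[Rcpp::export]]
List guinier_accumulate_cpp(IntegerVector ih, IntegerVector ik,
                            IntegerVector il, List coords, List occs,
                            NumericMatrix ffac) {
  int m = ih.size(), ng = coords.size();
  IndexBounds b = bounds_of(ih, ik, il);
  int nsnap = -1;
  std::vector<NumericVector> carrs;
  std::vector<NumericVector> warrs;
  std::vector<int> natoms(ng);
  for (int g = 0; g < ng; ++g) {
    NumericVector a = coords[g];
    IntegerVector dim = a.attr("dim");
    if (dim.size() != 3 || dim[1] != 3)
      stop("each coords entry must be an n x 3 x nsnap array");
    natoms[g] = dim[0];
    if (nsnap < 0) nsnap = dim[2];
    else if (nsnap != dim[2]) stop("snapshot counts differ between groups");
    carrs.push_back(a);
    warrs.push_back(occs[g]);
  }
  if (nsnap < 1) stop("need at least one snapshot");

  std::vector<double> sum_re(m, 0.0), sum_im(m, 0.0), sum_f2(m, 0.0);
  std::vector<double> f_re(m), f_im(m), s_re(m), s_im(m), th, tk, tl;

  for (int s = 0; s < nsnap; ++s) {
    std::fill(f_re.begin(), f_re.end(), 0.0);
    std::fill(f_im.begin(), f_im.end(), 0.0);
    for (int g = 0; g < ng; ++g) {
      std::fill(s_re.begin(), s_re.end(), 0.0);
      std::fill(s_im.begin(), s_im.end(), 0.0);
      int n = natoms[g];
      NumericVector a = carrs[g];
      NumericVector w = warrs[g];
      R_xlen_t off = (R_xlen_t)s * 3 * n;
      for (int j = 0; j < n; ++j) {
        accumulate_atom(b, &ih[0], &ik[0], &il[0], m, a[off + j],
                        a[off + n + j], a[off + 2 * n + j], w[j], th, tk,
                        tl, s_re.data(), s_im.data());
      }
      for (int p = 0; p < m; ++p) {
        double fv = ffac(p, g);
        f_re[p] += fv * s_re[p];
        f_im[p] += fv * s_im[p];
      }
    }
    for (int p = 0; p < m; ++p) {
      sum_re[p] += f_re[p];
      sum_im[p] += f_im[p];
      sum_f2[p] += f_re[p] * f_re[p] + f_im[p] * f_im[p];
    }
  }
  ComplexVector sf(m);
  NumericVector sf2(m);
  for (int p = 0; p < m; ++p) {
    sf[p].r = sum_re[p];
    sf[p].i = sum_im[p];
    sf2[p] = sum_f2[p];
  }
  return List::create(_["sum_f"] = sf, _["sum_f2"] = sf2,
                      _["n"] = nsnap);
}

// Mode filter: each unmasked pixel is replaced by the representative value
// (lower edge + half width) of the most populated bin of unmasked values in
// its (kernel x kernel) neighborhood; ties go to the lowest bin. Borders
// use the truncated neighborhood; a fully masked neighborhood masks the
// output.
// [[Rcpp::export]]
List mode_filter_cpp(NumericMatrix img, LogicalMatrix mask, int kernel,
                     double bin) {
  int nr = img.nrow(), nc = img.ncol();
  int half = kernel / 2;
  double vmin = R_PosInf, vmax = R_NegInf;
  for (int i = 0; i < nr * nc; ++i) {
    if (!mask[i]) {
      if (img[i] < vmin) vmin = img[i];
      if (img[i] > vmax) vmax = img[i];
    }
  }
  if (!R_FINITE(vmin)) stop("image has no unmasked pixels");
  int bmin = (int)std::floor(vmin / bin);
  int bmax = (int)std::floor(vmax / bin);
  int nbins = bmax - bmin + 1;
  std::vector<int> counts(nbins, 0);
  // precomputed per-pixel bin indices
  std::vector<int> binix(nr * nc, -1);
  for (int i = 0; i < nr * nc; ++i) {
    if (!mask[i]) binix[i] = (int)std::floor(img[i] / bin) - bmin;
  }
  NumericMatrix out(nr, nc);
  LogicalMatrix omask(nr, nc);

  for (int c = 0; c < nc; ++c) {
    int c0 = std::max(0, c - half), c1 = std::min(nc - 1, c + half);
    for (int r = 0; r < nr; ++r) {
      int r0 = std::max(0, r - half), r1 = std::min(nr - 1, r + half);
      if (mask(r, c)) {
        out(r, c) = img(r, c);
        omask(r, c) = true;
        continue;
      }
      int best_bin = -1, best_count = 0, total = 0;
      for (int cc = c0; cc <= c1; ++cc) {
        const int base = cc * nr;
        for (int rr = r0; rr <= r1; ++rr) {
          int bx = binix[base + rr];
          if (bx < 0) continue;
          int cnt = ++counts[bx];
          ++total;
          if (cnt > best_count || (cnt == best_count && bx < best_bin)) {
            best_count = cnt;
            best_bin = bx;
          }
        }
      }
      for (int cc = c0; cc <= c1; ++cc) {
        const int base = cc * nr;
        for (int rr = r0; rr <= r1; ++rr) {
          int bx = binix[base + rr];
          if (bx >= 0) counts[bx] = 0;
        }
      }
      if (total == 0) {
        out(r, c) = img(r, c);
        omask(r, c) = true;
      } else {
        out(r, c) = (best_bin + bmin) * bin + bin / 2.0;
        omask(r, c) = false;
      }
    }
  }
  return List::create(_["values"] = out, _["mask"] = omask);
}
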