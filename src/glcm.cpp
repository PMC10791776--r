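#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Five Haralick statistics of a normalized symmetric GLCM held as a dense
// count matrix. Only the `touched` cells are non-zero, so all sums run over
// that short list (<= 2 * pairs per window) instead of the full N x N grid.
struct Feat {
  double con, cor, dis, ene, hom;
};

static Feat features_from_counts(const std::vector<double>& C,
                                 const std::vector<int>& touched,
                                 int nlev, double total) {
  Feat f = {0.0, 0.0, 0.0, 0.0, 0.0};
  // marginal mean/variance: rows and columns coincide for a symmetric GLCM
  double mu = 0.0;
  for (int idx : touched) {
    double p = C[idx] / total;
    int i = idx / nlev;
    mu += p * i;
  }
  double var = 0.0, corsum = 0.0;
  for (int idx : touched) {
    double p = C[idx] / total;
    int i = idx / nlev, j = idx % nlev;
    int d = i - j;
    f.con += p * d * d;
    f.dis += p * (d < 0 ? -d : d);
    f.ene += p * p;
    f.hom += p / (1.0 + d * d);
    var += p * (i - mu) * (i - mu);
    corsum += p * (i - mu) * (j - mu);
  }
  // degenerate (single-level) window: correlation defined as 0
  f.cor = (var > 1e-12) ? corsum / var : 0.0;
  return f;
}

// Sliding-window GLCM texture rasters.
//   q        quantized image, levels 0..nlev-1, NA_INTEGER = nodata
//   kernel   odd window size (e.g. 5)
//   offs     one (drow, dcol) offset per direction
//   pooled   false: compute features per direction and average them;
//            true: pool counts over directions, compute features once
// Border pixels without a full window and windows containing nodata -> NA.
// [[Rcpp::export]]
List glcm_texture_cpp(IntegerMatrix q, int nlev, int kernel,
                      IntegerMatrix offs, bool pooled) {
  int nr = q.nrow(), nc = q.ncol(), h = kernel / 2, na = offs.nrow();
  NumericMatrix con(nr, nc), cor(nr, nc), dis(nr, nc), ene(nr, nc), hom(nr, nc);
  std::fill(con.begin(), con.end(), NA_REAL);
  std::fill(cor.begin(), cor.end(), NA_REAL);
  std::fill(dis.begin(), dis.end(), NA_REAL);
  std::fill(ene.begin(), ene.end(), NA_REAL);
  std::fill(hom.begin(), hom.end(), NA_REAL);

  std::vector<double> C((size_t)nlev * nlev, 0.0);
  std::vector<int> touched;
  touched.reserve(4 * kernel * kernel);

  for (int r = h; r < nr - h; ++r) {
    for (int c = h; c < nc - h; ++c) {
      bool ok = true;
      for (int wr = r - h; wr <= r + h && ok; ++wr)
        for (int wc = c - h; wc <= c + h; ++wc)
          if (q(wr, wc) == NA_INTEGER) { ok = false; break; }
      if (!ok) continue;

      double scon = 0, scor = 0, sdis = 0, sene = 0, shom = 0;
      int nval = 0;
      double total = 0.0;
      for (int a = 0; a < na; ++a) {
        int dr = offs(a, 0), dc = offs(a, 1);
        for (int wr = r - h; wr <= r + h; ++wr) {
          int pr = wr + dr;
          if (pr < r - h || pr > r + h) continue;
          for (int wc = c - h; wc <= c + h; ++wc) {
            int pc = wc + dc;
            if (pc < c - h || pc > c + h) continue;
            int vi = q(wr, wc), vj = q(pr, pc);
            int i1 = vi * nlev + vj, i2 = vj * nlev + vi;
            if (C[i1] == 0.0) touched.push_back(i1);
            C[i1] += 1.0;
            if (i2 != i1) {
              if (C[i2] == 0.0) touched.push_back(i2);
              C[i2] += 1.0;
            } else {
              C[i2] += 1.0; // diagonal pair counted in both orders
            }
            total += 2.0;
          }
        }
        if (!pooled) {
          if (total > 0) {
            Feat f = features_from_counts(C, touched, nlev, total);
            scon += f.con; scor += f.cor; sdis += f.dis;
            sene += f.ene; shom += f.hom;
            ++nval;
          }
          for (int idx : touched) C[idx] = 0.0;
          touched.clear();
          total = 0.0;
        }
      }
      if (pooled) {
        if (total > 0) {
          Feat f = features_from_counts(C, touched, nlev, total);
          con(r, c) = f.con; cor(r, c) = f.cor; dis(r, c) = f.dis;
          ene(r, c) = f.ene; hom(r, c) = f.hom;
        }
        for (int idx : touched) C[idx] = 0.0;
        touched.clear();
      } else if (nval > 0) {
        con(r, c) = scon / nval; cor(r, c) = scor / nval;
        dis(r, c) = sdis / nval; ene(r, c) = sene / nval;
        hom(r, c) = shom / nval;
      }
    }
  }
  return List::create(_["CON"] = con, _["COR"] = cor, _["DIS"] = dis,
                      _["ENE"] = ene, _["HOM"] = hom);
}
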