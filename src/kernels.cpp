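#include <Rcpp.h>
using namespace Rcpp;

// symmetric (mirror) boundary index into [0, n)
static inline int reflect_idx(int i, int n) {
  while (i < 0 || i >= n) {
    if (i < 0) i = -i - 1;
    if (i >= n) i = 2 * n - i - 1;
  }
  return i;
}

// separable correlation: ky along rows (y), kx along columns (x), both
// centred odd-length kernels; reflect boundary
// [[Rcpp::export]]
NumericMatrix sep_conv2_reflect(const NumericMatrix& img,
                                const NumericVector& ky,
                                const NumericVector& kx) {
  const int nr = img.nrow(), nc = img.ncol();
  const int ry = (ky.size() - 1) / 2, rx = (kx.size() - 1) / 2;
  NumericMatrix tmp(nr, nc), out(nr, nc);
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      double acc = 0.0;
      for (int k = -ry; k <= ry; ++k)
        acc += ky[k + ry] * img(reflect_idx(r + k, nr), c);
      tmp(r, c) = acc;
    }
  }
  for (int r = 0; r < nr; ++r) {
    for (int c = 0; c < nc; ++c) {
      double acc = 0.0;
      for (int k = -rx; k <= rx; ++k)
        acc += kx[k + rx] * tmp(r, reflect_idx(c + k, nc));
      out(r, c) = acc;
    }
  }
  return out;
}

// Hough peak extraction by greedy deflation with bilinear rho voting and
// geometric-support scoring; returns a matrix with columns rho, theta,
// support
// [[Rcpp::export]]
NumericMatrix hough_deflate(NumericVector x, NumericVector y,
                            const NumericVector& thetas, double rho_res,
                            double vote_min, double vote_floor,
                            double support_radius, double consume_factor) {
  std::vector<double> px(x.begin(), x.end()), py(y.begin(), y.end());
  const int nth = thetas.size();
  std::vector<double> cth(nth), sth(nth);
  for (int j = 0; j < nth; ++j) { cth[j] = std::cos(thetas[j]); sth[j] = std::sin(thetas[j]); }
  std::vector<double> out_rho, out_th, out_votes;
  double first_support = -1.0;
  while ((int)px.size() >= (int)vote_floor) {
    const int n = px.size();
    double best_v = -1.0, best_rho = 0.0, best_th = 0.0;
    std::vector<double> rho(n);
    for (int j = 0; j < nth; ++j) {
      double rmin = R_PosInf, rmax = R_NegInf;
      for (int i = 0; i < n; ++i) {
        rho[i] = (px[i] * cth[j] + py[i] * sth[j]) / rho_res;
        if (rho[i] < rmin) rmin = rho[i];
        if (rho[i] > rmax) rmax = rho[i];
      }
      const int lo = (int)std::floor(rmin) - 1, hi = (int)std::floor(rmax) + 1;
      std::vector<double> acc(hi - lo + 2, 0.0);
      for (int i = 0; i < n; ++i) {
        const int b = (int)std::floor(rho[i]);
        const double fr = rho[i] - b;
        acc[b - lo] += 1.0 - fr;
        acc[b - lo + 1] += fr;
      }
      for (size_t b = 0; b < acc.size(); ++b) {
        if (acc[b] > best_v + 1e-9) {
          best_v = acc[b];
          best_rho = (lo + (int)b) * rho_res;
          best_th = thetas[j];
        }
      }
    }
    // geometric support of the winning cell
    const double cb = std::cos(best_th), sb = std::sin(best_th);
    int support = 0;
    for (int i = 0; i < n; ++i)
      if (std::fabs(px[i] * cb + py[i] * sb - best_rho) <= support_radius)
        ++support;
    if (first_support < 0) first_support = support;
    if (support < std::max(vote_floor, vote_min * first_support)) break;
    out_rho.push_back(best_rho);
    out_th.push_back(best_th);
    out_votes.push_back(support);
    // consume a wider band so staircase rails fall with their line
    const double crad = consume_factor * support_radius;
    std::vector<double> nx, ny;
    for (int i = 0; i < n; ++i) {
      if (std::fabs(px[i] * cb + py[i] * sb - best_rho) > crad) {
        nx.push_back(px[i]); ny.push_back(py[i]);
      }
    }
    if ((int)nx.size() == n) break; // nothing consumed: degenerate
    px.swap(nx); py.swap(ny);
  }
  NumericMatrix res(out_rho.size(), 3);
  for (size_t i = 0; i < out_rho.size(); ++i) {
    res(i, 0) = out_rho[i];
    res(i, 1) = out_th[i];
    res(i, 2) = out_votes[i];
  }
  colnames(res) = CharacterVector::create("rho", "theta", "votes");
  return res;
}

// two-pass 8-connected labeling of a logical/numeric mask
// [[Rcpp::export]]
IntegerMatrix label8(const LogicalMatrix& mask) {
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  std::vector<int> parent(1, 0);
  auto find = [&](int a) {
    while (parent[a] != a) { parent[a] = parent[parent[a]]; a = parent[a]; }
    return a;
  };
  auto unite = [&](int a, int b) {
    a = find(a); b = find(b);
    if (a != b) parent[std::max(a, b)] = std::min(a, b);
  };
  int next = 0;
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      if (!mask(r, c)) continue;
      int best = 0;
      // previously-visited 8-neighbours in column-major order
      const int pr[4] = {r - 1, r - 1, r, r + 1};
      const int pc[4] = {c, c - 1, c - 1, c - 1};
      for (int k = 0; k < 4; ++k) {
        if (pr[k] < 0 || pr[k] >= nr || pc[k] < 0) continue;
        const int l = lab(pr[k], pc[k]);
        if (l > 0) {
          if (best == 0) best = l;
          else unite(best, l);
        }
      }
      if (best == 0) {
        best = ++next;
        parent.push_back(best);
      }
      lab(r, c) = best;
    }
  }
  // relabel compactly
  std::vector<int> remap(next + 1, 0);
  int out_n = 0;
  for (int i = 1; i <= next; ++i)
    if (find(i) == i) remap[i] = ++out_n;
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r)
      if (lab(r, c) > 0) lab(r, c) = remap[find(lab(r, c))];
  return lab;
}
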