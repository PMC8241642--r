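#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Tensors use R array layout dim = c(D, H, W, C, N), column-major.
static inline R_xlen_t idx5(int d, int h, int w, int c, int n,
                            int D, int H, int W, int C) {
  return d + (R_xlen_t)D * (h + (R_xlen_t)H * (w + (R_xlen_t)W * (c + (R_xlen_t)C * n)));
}

// 3D convolution, kernel k x k x k, zero padding p, stride s.
// x: dim c(D,H,W,Ci,N); wt: dim c(k,k,k,Ci,Co); b: length Co.
// [[Rcpp::export(name = ".conv3d_fw")]]
NumericVector conv3d_fw(NumericVector x, NumericVector wt, NumericVector b,
                        int stride, int pad) {
  IntegerVector xd = x.attr("dim");
  IntegerVector wd = wt.attr("dim");
  const int D = xd[0], H = xd[1], W = xd[2], Ci = xd[3], N = xd[4];
  const int K = wd[0], Co = wd[4];
  const int Do = (D + 2 * pad - K) / stride + 1;
  const int Ho = (H + 2 * pad - K) / stride + 1;
  const int Wo = (W + 2 * pad - K) / stride + 1;
  NumericVector out((R_xlen_t)Do * Ho * Wo * Co * N);
  out.attr("dim") = IntegerVector::create(Do, Ho, Wo, Co, N);
  const double *px = x.begin(), *pw = wt.begin();
  double *po = out.begin();
  for (int n = 0; n < N; ++n)
    for (int co = 0; co < Co; ++co) {
      const double bias = b[co];
      for (int ow = 0; ow < Wo; ++ow)
        for (int oh = 0; oh < Ho; ++oh)
          for (int od = 0; od < Do; ++od) {
            double acc = bias;
            const int d0 = od * stride - pad;
            const int h0 = oh * stride - pad;
            const int w0 = ow * stride - pad;
            for (int ci = 0; ci < Ci; ++ci)
              for (int kw = 0; kw < K; ++kw) {
                const int iw = w0 + kw;
                if (iw < 0 || iw >= W) continue;
                for (int kh = 0; kh < K; ++kh) {
                  const int ih = h0 + kh;
                  if (ih < 0 || ih >= H) continue;
                  for (int kd = 0; kd < K; ++kd) {
                    const int id = d0 + kd;
                    if (id < 0 || id >= D) continue;
                    acc += px[idx5(id, ih, iw, ci, n, D, H, W, Ci)] *
                           pw[idx5(kd, kh, kw, ci, co, K, K, K, Ci)];
                  }
                }
              }
            po[idx5(od, oh, ow, co, n, Do, Ho, Wo, Co)] = acc;
          }
    }
  return out;
}

// Backward pass: returns gradients w.r.t. input, weights, bias.
// [[Rcpp::export(name = ".conv3d_bw")]]
List conv3d_bw(NumericVector x, NumericVector wt, NumericVector gout,
               int stride, int pad) {
  IntegerVector xd = x.attr("dim");
  IntegerVector wd = wt.attr("dim");
  IntegerVector gd = gout.attr("dim");
  const int D = xd[0], H = xd[1], W = xd[2], Ci = xd[3], N = xd[4];
  const int K = wd[0], Co = wd[4];
  const int Do = gd[0], Ho = gd[1], Wo = gd[2];
  NumericVector gx((R_xlen_t)D * H * W * Ci * N);
  gx.attr("dim") = xd;
  NumericVector gw((R_xlen_t)K * K * K * Ci * Co);
  gw.attr("dim") = wd;
  NumericVector gb(Co);
  const double *px = x.begin(), *pw = wt.begin(), *pg = gout.begin();
  double *pgx = gx.begin(), *pgw = gw.begin();
  for (int n = 0; n < N; ++n)
    for (int co = 0; co < Co; ++co)
      for (int ow = 0; ow < Wo; ++ow)
        for (int oh = 0; oh < Ho; ++oh)
          for (int od = 0; od < Do; ++od) {
            const double g = pg[idx5(od, oh, ow, co, n, Do, Ho, Wo, Co)];
            if (g == 0.0) continue;
            gb[co] += g;
            const int d0 = od * stride - pad;
            const int h0 = oh * stride - pad;
            const int w0 = ow * stride - pad;
            for (int ci = 0; ci < Ci; ++ci)
              for (int kw = 0; kw < K; ++kw) {
                const int iw = w0 + kw;
                if (iw < 0 || iw >= W) continue;
                for (int kh = 0; kh < K; ++kh) {
                  const int ih = h0 + kh;
                  if (ih < 0 || ih >= H) continue;
                  for (int kd = 0; kd < K; ++kd) {
                    const int id = d0 + kd;
                    if (id < 0 || id >= D) continue;
                    const R_xlen_t xi = idx5(id, ih, iw, ci, n, D, H, W, Ci);
                    const R_xlen_t wi = idx5(kd, kh, kw, ci, co, K, K, K, Ci);
                    pgx[xi] += pw[wi] * g;
                    pgw[wi] += px[xi] * g;
                  }
                }
              }
          }
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// Connected-component labelling of a 3D binary mask.
// connectivity: 6 (faces) or 26 (faces+edges+corners).
// Returns integer array of labels, 0 = background, labels 1..n in
// first-encounter (column-major scan) order.
// [[Rcpp::export(name = ".cc3d_label")]]
IntegerVector cc3d_label(LogicalVector mask, int connectivity) {
  IntegerVector md = mask.attr("dim");
  const int D = md[0], H = md[1], W = md[2];
  IntegerVector lab((R_xlen_t)D * H * W);
  lab.attr("dim") = md;
  // neighbour offsets
  std::vector<int> od, oh, ow;
  for (int dw = -1; dw <= 1; ++dw)
    for (int dh = -1; dh <= 1; ++dh)
      for (int dd = -1; dd <= 1; ++dd) {
        if (dd == 0 && dh == 0 && dw == 0) continue;
        int nz = std::abs(dd) + std::abs(dh) + std::abs(dw);
        if (connectivity == 6 && nz > 1) continue;
        od.push_back(dd); oh.push_back(dh); ow.push_back(dw);
      }
  const int nb = (int)od.size();
  int next = 0;
  std::vector<R_xlen_t> stack;
  for (int w = 0; w < W; ++w)
    for (int h = 0; h < H; ++h)
      for (int d = 0; d < D; ++d) {
        R_xlen_t i0 = d + (R_xlen_t)D * (h + (R_xlen_t)H * w);
        if (!mask[i0] || lab[i0] != 0) continue;
        ++next;
        lab[i0] = next;
        stack.clear();
        stack.push_back(i0);
        while (!stack.empty()) {
          R_xlen_t cur = stack.back();
          stack.pop_back();
          int cd = (int)(cur % D);
          int ch = (int)((cur / D) % H);
          int cw = (int)(cur / ((R_xlen_t)D * H));
          for (int k = 0; k < nb; ++k) {
            int nd = cd + od[k], nh = ch + oh[k], nw = cw + ow[k];
            if (nd < 0 || nd >= D || nh < 0 || nh >= H || nw < 0 || nw >= W)
              continue;
            R_xlen_t ni = nd + (R_xlen_t)D * (nh + (R_xlen_t)H * nw);
            if (mask[ni] && lab[ni] == 0) {
              lab[ni] = next;
              stack.push_back(ni);
            }
          }
        }
      }
  return lab;
}
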