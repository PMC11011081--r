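#include <Rcpp.h>
using namespace Rcpp;

// Fused kernels for the hot layers. Tensor layout everywhere:
// column-major (C, H, W, N), element (c,h,w,n) at c + C*(h + H*(w + W*n)).
// Attention heads are contiguous channel blocks of size dh; neighborhood
// offsets are enumerated j = 0..8 as (dy, dx) with dy fastest in -1..1.

static const int OFF[9][2] = {
  {-1,-1},{0,-1},{1,-1},{-1,0},{0,0},{1,0},{-1,1},{0,1},{1,1}};

// logits[j, hd + nh*l] = scale * sum_cc q[.,l] * k[., neighbor_j(l)] + rel[j,hd]
// [[Rcpp::export]]
NumericMatrix attn_logits_cpp(NumericVector q, NumericVector k,
                              int C, int H, int W, int N,
                              int dh, double scale, NumericMatrix rel) {
  int nh = C / dh;
  R_xlen_t L = (R_xlen_t)H * W * N;
  NumericMatrix out(9, nh * L);
  double *pq = q.begin(), *pk = k.begin(), *po = out.begin();
  for (int n = 0; n < N; ++n)
    for (int w = 0; w < W; ++w)
      for (int h = 0; h < H; ++h) {
        R_xlen_t l = h + (R_xlen_t)H * (w + (R_xlen_t)W * n);
        double *qc = pq + (R_xlen_t)C * l;
        double *oc = po + 9 * (R_xlen_t)nh * l;
        for (int j = 0; j < 9; ++j) {
          int h2 = h + OFF[j][0], w2 = w + OFF[j][1];
          if (h2 < 0 || h2 >= H || w2 < 0 || w2 >= W) {
            for (int hd = 0; hd < nh; ++hd) oc[j + 9 * hd] = rel(j, hd);
            continue;
          }
          double *kc = pk + (R_xlen_t)C * (h2 + (R_xlen_t)H * (w2 + (R_xlen_t)W * n));
          for (int hd = 0; hd < nh; ++hd) {
            double s = 0.0;
            int base = hd * dh;
            for (int cc = 0; cc < dh; ++cc) s += qc[base + cc] * kc[base + cc];
            oc[j + 9 * hd] = s * scale + rel(j, hd);
          }
        }
      }
  return out;
}

// out[c, l] = sum_j wt[j, hd + nh*l] * v[c, neighbor_j(l)]
// [[Rcpp::export]]
NumericVector attn_apply_cpp(NumericVector v, NumericMatrix wt,
                             int C, int H, int W, int N, int dh) {
  int nh = C / dh;
  NumericVector out((R_xlen_t)C * H * W * N);
  double *pv = v.begin(), *pw = wt.begin(), *po = out.begin();
  for (int n = 0; n < N; ++n)
    for (int w = 0; w < W; ++w)
      for (int h = 0; h < H; ++h) {
        R_xlen_t l = h + (R_xlen_t)H * (w + (R_xlen_t)W * n);
        double *oc = po + (R_xlen_t)C * l;
        double *wc = pw + 9 * (R_xlen_t)nh * l;
        for (int j = 0; j < 9; ++j) {
          int h2 = h + OFF[j][0], w2 = w + OFF[j][1];
          if (h2 < 0 || h2 >= H || w2 < 0 || w2 >= W) continue;
          double *vc = pv + (R_xlen_t)C * (h2 + (R_xlen_t)H * (w2 + (R_xlen_t)W * n));
          for (int hd = 0; hd < nh; ++hd) {
            double wj = wc[j + 9 * hd];
            if (wj == 0.0) continue;
            int base = hd * dh;
            for (int cc = 0; cc < dh; ++cc) oc[base + cc] += wj * vc[base + cc];
          }
        }
      }
  return out;
}

// dwt[j, hd + nh*l] = sum_cc dout[c, l] * v[c, neighbor_j(l)]
// dv[c, neighbor_j(l)] += dout[c, l] * wt[j, hd + nh*l]
// [[Rcpp::export]]
List attn_dwt_dv_cpp(NumericVector v, NumericMatrix wt, NumericVector dout,
                     int C, int H, int W, int N, int dh) {
  int nh = C / dh;
  R_xlen_t L = (R_xlen_t)H * W * N;
  NumericMatrix dwt(9, nh * L);
  NumericVector dv((R_xlen_t)C * L);
  double *pv = v.begin(), *pw = wt.begin(), *pd = dout.begin();
  double *pdw = dwt.begin(), *pdv = dv.begin();
  for (int n = 0; n < N; ++n)
    for (int w = 0; w < W; ++w)
      for (int h = 0; h < H; ++h) {
        R_xlen_t l = h + (R_xlen_t)H * (w + (R_xlen_t)W * n);
        double *dc = pd + (R_xlen_t)C * l;
        double *wc = pw + 9 * (R_xlen_t)nh * l;
        double *dwc = pdw + 9 * (R_xlen_t)nh * l;
        for (int j = 0; j < 9; ++j) {
          int h2 = h + OFF[j][0], w2 = w + OFF[j][1];
          if (h2 < 0 || h2 >= H || w2 < 0 || w2 >= W) continue;
          R_xlen_t l2 = h2 + (R_xlen_t)H * (w2 + (R_xlen_t)W * n);
          double *vc = pv + (R_xlen_t)C * l2;
          double *dvc = pdv + (R_xlen_t)C * l2;
          for (int hd = 0; hd < nh; ++hd) {
            int base = hd * dh;
            double s = 0.0, wj = wc[j + 9 * hd];
            for (int cc = 0; cc < dh; ++cc) {
              s += dc[base + cc] * vc[base + cc];
              dvc[base + cc] += dc[base + cc] * wj;
            }
            dwc[j + 9 * hd] = s;
          }
        }
      }
  return List::create(_["dwt"] = dwt, _["dv"] = dv);
}

// dq[c, l] += scale * sum_j dlog[j, hd + nh*l] * k[c, neighbor_j(l)]
// dk[c, neighbor_j(l)] += scale * dlog[j, hd + nh*l] * q[c, l]
// [[Rcpp::export]]
List attn_dqk_cpp(NumericVector q, NumericVector k, NumericMatrix dlog,
                  int C, int H, int W, int N, int dh, double scale) {
  int nh = C / dh;
  NumericVector dq((R_xlen_t)C * H * W * N);
  NumericVector dk((R_xlen_t)C * H * W * N);
  double *pq = q.begin(), *pk = k.begin(), *pl = dlog.begin();
  double *pdq = dq.begin(), *pdk = dk.begin();
  for (int n = 0; n < N; ++n)
    for (int w = 0; w < W; ++w)
      for (int h = 0; h < H; ++h) {
        R_xlen_t l = h + (R_xlen_t)H * (w + (R_xlen_t)W * n);
        double *qc = pq + (R_xlen_t)C * l;
        double *dqc = pdq + (R_xlen_t)C * l;
        double *lc = pl + 9 * (R_xlen_t)nh * l;
        for (int j = 0; j < 9; ++j) {
          int h2 = h + OFF[j][0], w2 = w + OFF[j][1];
          if (h2 < 0 || h2 >= H || w2 < 0 || w2 >= W) continue;
          R_xlen_t l2 = h2 + (R_xlen_t)H * (w2 + (R_xlen_t)W * n);
          double *kc = pk + (R_xlen_t)C * l2;
          double *dkc = pdk + (R_xlen_t)C * l2;
          for (int hd = 0; hd < nh; ++hd) {
            double g = lc[j + 9 * hd] * scale;
            if (g == 0.0) continue;
            int base = hd * dh;
            for (int cc = 0; cc < dh; ++cc) {
              dqc[base + cc] += g * kc[base + cc];
              dkc[base + cc] += g * qc[base + cc];
            }
          }
        }
      }
  return List::create(_["dq"] = dq, _["dk"] = dk);
}

// Group normalization forward: per (group, frame) standardization.
// [[Rcpp::export]]
List gn_forward_cpp(NumericVector x, int C, int H, int W, int N,
                    int G, double eps, NumericVector gamma, NumericVector beta) {
  int Cg = C / G;
  R_xlen_t HW = (R_xlen_t)H * W;
  NumericVector y(x.size()), xhat(x.size()), sd((R_xlen_t)G * N);
  double *px = x.begin(), *py = y.begin(), *ph = xhat.begin(), *psd = sd.begin();
  double *pg = gamma.begin(), *pb = beta.begin();
  double m = (double)Cg * HW;
  for (int n = 0; n < N; ++n) {
    for (int g = 0; g < G; ++g) {
      double s = 0.0, s2 = 0.0;
      for (R_xlen_t p = 0; p < HW; ++p) {
        double *xc = px + (R_xlen_t)C * (p + HW * n) + g * Cg;
        for (int cc = 0; cc < Cg; ++cc) { s += xc[cc]; s2 += xc[cc] * xc[cc]; }
      }
      double mu = s / m;
      double var = s2 / m - mu * mu;
      if (var < 0) var = 0;
      double sdv = sqrt(var + eps);
      psd[g + (R_xlen_t)G * n] = sdv;
      for (R_xlen_t p = 0; p < HW; ++p) {
        R_xlen_t off = (R_xlen_t)C * (p + HW * n) + g * Cg;
        for (int cc = 0; cc < Cg; ++cc) {
          double xh = (px[off + cc] - mu) / sdv;
          ph[off + cc] = xh;
          py[off + cc] = xh * pg[g * Cg + cc] + pb[g * Cg + cc];
        }
      }
    }
  }
  return List::create(_["y"] = y, _["xhat"] = xhat, _["sd"] = sd);
}

// Group normalization backward.
// [[Rcpp::export]]
List gn_backward_cpp(NumericVector dout, NumericVector xhat, NumericVector sd,
                     NumericVector gamma, int C, int H, int W, int N, int G) {
  int Cg = C / G;
  R_xlen_t HW = (R_xlen_t)H * W;
  NumericVector dx(dout.size()), dgamma(C), dbeta(C);
  double *pd = dout.begin(), *ph = xhat.begin(), *psd = sd.begin();
  double *pg = gamma.begin(), *pdx = dx.begin();
  double *pdg = dgamma.begin(), *pdb = dbeta.begin();
  double m = (double)Cg * HW;
  for (int n = 0; n < N; ++n) {
    for (int g = 0; g < G; ++g) {
      double m1 = 0.0, m2 = 0.0;
      for (R_xlen_t p = 0; p < HW; ++p) {
        R_xlen_t off = (R_xlen_t)C * (p + HW * n) + g * Cg;
        for (int cc = 0; cc < Cg; ++cc) {
          double dxh = pd[off + cc] * pg[g * Cg + cc];
          m1 += dxh;
          m2 += dxh * ph[off + cc];
          pdg[g * Cg + cc] += pd[off + cc] * ph[off + cc];
          pdb[g * Cg + cc] += pd[off + cc];
        }
      }
      m1 /= m; m2 /= m;
      double sdv = psd[g + (R_xlen_t)G * n];
      for (R_xlen_t p = 0; p < HW; ++p) {
        R_xlen_t off = (R_xlen_t)C * (p + HW * n) + g * Cg;
        for (int cc = 0; cc < Cg; ++cc) {
          double dxh = pd[off + cc] * pg[g * Cg + cc];
          pdx[off + cc] = (dxh - m1 - ph[off + cc] * m2) / sdv;
        }
      }
    }
  }
  return List::create(_["dx"] = dx, _["dgamma"] = dgamma, _["dbeta"] = dbeta);
}

// 3x3 stride-2 max pooling with padding 1; amax stores the linear input
// index (0-based) of each winner.
// [[Rcpp::export]]
List maxpool3_cpp(NumericVector x, int C, int H, int W, int N) {
  int Ho = (H - 1) / 2 + 1, Wo = (W - 1) / 2 + 1;
  NumericVector out((R_xlen_t)C * Ho * Wo * N);
  IntegerVector amax(out.size());
  double *px = x.begin(), *po = out.begin();
  int *pa = amax.begin();
  for (int n = 0; n < N; ++n)
    for (int wo = 0; wo < Wo; ++wo)
      for (int ho = 0; ho < Ho; ++ho) {
        R_xlen_t oi = (R_xlen_t)C * (ho + (R_xlen_t)Ho * (wo + (R_xlen_t)Wo * n));
        for (int c = 0; c < C; ++c) { po[oi + c] = R_NegInf; pa[oi + c] = -1; }
        for (int kj = 0; kj < 3; ++kj) {
          int iw = wo * 2 + kj - 1;
          if (iw < 0 || iw >= W) continue;
          for (int ki = 0; ki < 3; ++ki) {
            int ih = ho * 2 + ki - 1;
            if (ih < 0 || ih >= H) continue;
            R_xlen_t ii = (R_xlen_t)C * (ih + (R_xlen_t)H * (iw + (R_xlen_t)W * n));
            for (int c = 0; c < C; ++c)
              if (px[ii + c] > po[oi + c]) { po[oi + c] = px[ii + c]; pa[oi + c] = (int)(ii + c); }
          }
        }
      }
  return List::create(_["out"] = out, _["amax"] = amax);
}

// [[Rcpp::export]]
NumericVector maxpool3_bwd_cpp(NumericVector dout, IntegerVector amax,
                               R_xlen_t in_len) {
  NumericVector dx(in_len);
  double *pd = dout.begin(), *px = dx.begin();
  int *pa = amax.begin();
  for (R_xlen_t i = 0; i < dout.size(); ++i)
    if (pa[i] >= 0) px[pa[i]] += pd[i];
  return dx;
}
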