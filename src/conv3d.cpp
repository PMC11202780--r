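#include <Rcpp.h>
using namespace Rcpp;

// Volumes are column-major arrays [H, W, D, C]; kernels [kh, kw, kd, Cin, Cout].
// Padding is implicit-zero: any input index falling outside the volume
// contributes nothing. `pad` holds the begin-pad along (H, W, D).

static inline R_xlen_t idx4(int h, int w, int d, int c, int H, int W, int D) {
  return h + (R_xlen_t)H * (w + (R_xlen_t)W * (d + (R_xlen_t)D * c));
}

// [[Rcpp::export(name = ".conv3_fw")]]
NumericVector conv3_fw(NumericVector x, IntegerVector xdim,
                       NumericVector w, IntegerVector wdim,
                       NumericVector b, IntegerVector stride,
                       IntegerVector pad, IntegerVector odim) {
  const int H = xdim[0], W = xdim[1], D = xdim[2], Ci = xdim[3];
  const int kh = wdim[0], kw = wdim[1], kd = wdim[2], Co = wdim[4];
  const int sh = stride[0], sw = stride[1], sd = stride[2];
  const int ph = pad[0], pw = pad[1], pd = pad[2];
  const int Ho = odim[0], Wo = odim[1], Do = odim[2];
  NumericVector y(Rf_allocVector(REALSXP, (R_xlen_t)Ho * Wo * Do * Co));
  const double *px = x.begin(), *pwt = w.begin();
  double *py = y.begin();
  for (int co = 0; co < Co; ++co)
    for (int od = 0; od < Do; ++od)
      for (int ow = 0; ow < Wo; ++ow)
        for (int oh = 0; oh < Ho; ++oh) {
          double acc = b[co];
          for (int ci = 0; ci < Ci; ++ci)
            for (int jd = 0; jd < kd; ++jd) {
              int id = od * sd - pd + jd;
              if (id < 0 || id >= D) continue;
              for (int jw = 0; jw < kw; ++jw) {
                int iw = ow * sw - pw + jw;
                if (iw < 0 || iw >= W) continue;
                for (int jh = 0; jh < kh; ++jh) {
                  int ih = oh * sh - ph + jh;
                  if (ih < 0 || ih >= H) continue;
                  acc += px[idx4(ih, iw, id, ci, H, W, D)] *
                         pwt[jh + (R_xlen_t)kh * (jw + (R_xlen_t)kw *
                             (jd + (R_xlen_t)kd * (ci + (R_xlen_t)Ci * co)))];
                }
              }
            }
          py[idx4(oh, ow, od, co, Ho, Wo, Do)] = acc;
        }
  y.attr("dim") = IntegerVector::create(Ho, Wo, Do, Co);
  return y;
}

// [[Rcpp::export(name = ".conv3_bw")]]
List conv3_bw(NumericVector x, IntegerVector xdim,
              NumericVector w, IntegerVector wdim,
              NumericVector gy, IntegerVector stride,
              IntegerVector pad, IntegerVector odim) {
  const int H = xdim[0], W = xdim[1], D = xdim[2], Ci = xdim[3];
  const int kh = wdim[0], kw = wdim[1], kd = wdim[2], Co = wdim[4];
  const int sh = stride[0], sw = stride[1], sd = stride[2];
  const int ph = pad[0], pw = pad[1], pd = pad[2];
  const int Ho = odim[0], Wo = odim[1], Do = odim[2];
  NumericVector gx(x.size()), gw(w.size()), gb(Co);
  const double *px = x.begin(), *pwt = w.begin(), *pgy = gy.begin();
  double *pgx = gx.begin(), *pgw = gw.begin();
  for (int co = 0; co < Co; ++co)
    for (int od = 0; od < Do; ++od)
      for (int ow = 0; ow < Wo; ++ow)
        for (int oh = 0; oh < Ho; ++oh) {
          double g = pgy[idx4(oh, ow, od, co, Ho, Wo, Do)];
          if (g == 0.0) continue;
          gb[co] += g;
          for (int ci = 0; ci < Ci; ++ci)
            for (int jd = 0; jd < kd; ++jd) {
              int id = od * sd - pd + jd;
              if (id < 0 || id >= D) continue;
              for (int jw = 0; jw < kw; ++jw) {
                int iw = ow * sw - pw + jw;
                if (iw < 0 || iw >= W) continue;
                for (int jh = 0; jh < kh; ++jh) {
                  int ih = oh * sh - ph + jh;
                  if (ih < 0 || ih >= H) continue;
                  R_xlen_t xi = idx4(ih, iw, id, ci, H, W, D);
                  R_xlen_t wi = jh + (R_xlen_t)kh * (jw + (R_xlen_t)kw *
                                (jd + (R_xlen_t)kd * (ci + (R_xlen_t)Ci * co)));
                  pgw[wi] += px[xi] * g;
                  pgx[xi] += pwt[wi] * g;
                }
              }
            }
        }
  gx.attr("dim") = xdim;
  gw.attr("dim") = wdim;
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// [[Rcpp::export(name = ".maxpool3_fw")]]
List maxpool3_fw(NumericVector x, IntegerVector xdim,
                 IntegerVector k, IntegerVector stride,
                 IntegerVector pad, IntegerVector odim) {
  const int H = xdim[0], W = xdim[1], D = xdim[2], C = xdim[3];
  const int kh = k[0], kw = k[1], kd = k[2];
  const int sh = stride[0], sw = stride[1], sd = stride[2];
  const int ph = pad[0], pw = pad[1], pd = pad[2];
  const int Ho = odim[0], Wo = odim[1], Do = odim[2];
  R_xlen_t n = (R_xlen_t)Ho * Wo * Do * C;
  NumericVector y(n);
  IntegerVector amax(n);
  const double *px = x.begin();
  for (int c = 0; c < C; ++c)
    for (int od = 0; od < Do; ++od)
      for (int ow = 0; ow < Wo; ++ow)
        for (int oh = 0; oh < Ho; ++oh) {
          double best = R_NegInf;
          R_xlen_t bi = -1;
          for (int jd = 0; jd < kd; ++jd) {
            int id = od * sd - pd + jd;
            if (id < 0 || id >= D) continue;
            for (int jw = 0; jw < kw; ++jw) {
              int iw = ow * sw - pw + jw;
              if (iw < 0 || iw >= W) continue;
              for (int jh = 0; jh < kh; ++jh) {
                int ih = oh * sh - ph + jh;
                if (ih < 0 || ih >= H) continue;
                R_xlen_t xi = idx4(ih, iw, id, c, H, W, D);
                if (px[xi] > best) { best = px[xi]; bi = xi; }
              }
            }
          }
          R_xlen_t oi = idx4(oh, ow, od, c, Ho, Wo, Do);
          y[oi] = (bi >= 0) ? best : 0.0;
          amax[oi] = (int)bi;  // -1 for all-pad windows (never hit in practice)
        }
  y.attr("dim") = IntegerVector::create(Ho, Wo, Do, C);
  return List::create(_["y"] = y, _["amax"] = amax);
}

// [[Rcpp::export(name = ".maxpool3_bw")]]
NumericVector maxpool3_bw(NumericVector gy, IntegerVector amax, int xlen,
                          IntegerVector xdim) {
  NumericVector gx(xlen);
  for (R_xlen_t i = 0; i < gy.size(); ++i)
    if (amax[i] >= 0) gx[amax[i]] += gy[i];
  gx.attr("dim") = xdim;
  return gx;
}
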