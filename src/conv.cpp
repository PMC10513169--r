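// 3x3 convolution forward/backward for batched column-major feature maps.
//
// A feature map is an (H*W*B) x C matrix: pixels of each image in
// column-major order, images stacked along rows. Each image is embedded in
// a zero-padded (H+2) x (W+2) frame, where every kernel offset (dy, dx)
// becomes a constant row shift s = dx*(H+2) + dy. The convolution is then
// nine strided GEMMs on shifted views of the padded buffer - no gather
// indices anywhere. Padding rings are zero, so shifted reads that cross an
// image border contribute nothing, and rows written into a ring are
// discarded on extraction.

#include <Rcpp.h>
#include <R_ext/BLAS.h>
#include <cstring>

#ifndef FCONE
#define FCONE
#endif

using namespace Rcpp;

static void embed(const double* x, double* xpad, int H, int W, int B,
                  int C, int npix, int npad, int Hp, int NR) {
  for (int c = 0; c < C; ++c) {
    const double* src = x + (R_xlen_t)c * npix * B;
    double* dst = xpad + (R_xlen_t)c * NR;
    for (int b = 0; b < B; ++b)
      for (int col = 0; col < W; ++col)
        std::memcpy(dst + (R_xlen_t)b * npad + (col + 1) * Hp + 1,
                    src + (R_xlen_t)b * npix + col * H,
                    H * sizeof(double));
  }
}

static void extract(const double* xpad, double* x, int H, int W, int B,
                    int C, int npix, int npad, int Hp, int NR) {
  for (int c = 0; c < C; ++c) {
    const double* src = xpad + (R_xlen_t)c * NR;
    double* dst = x + (R_xlen_t)c * npix * B;
    for (int b = 0; b < B; ++b)
      for (int col = 0; col < W; ++col)
        std::memcpy(dst + (R_xlen_t)b * npix + col * H,
                    src + (R_xlen_t)b * npad + (col + 1) * Hp + 1,
                    H * sizeof(double));
  }
}

// [[Rcpp::export(name = ".conv3_fwd")]]
List conv3_fwd(NumericMatrix X, NumericMatrix W, NumericVector bias,
               int H, int Wimg, int B) {
  const int Cin = X.ncol(), Cout = W.ncol();
  const int Hp = H + 2, Wp = Wimg + 2;
  const int npix = H * Wimg, npad = Hp * Wp;
  const int NR = npad * B;
  NumericMatrix Xpad(NR, Cin), Ypad(NR, Cout);
  embed(REAL(X), REAL(Xpad), H, Wimg, B, Cin, npix, npad, Hp, NR);

  const double one = 1.0;
  const int ld = NR, ldw = 9 * Cin;
  int j = 0;
  for (int dx = -1; dx <= 1; ++dx) {
    for (int dy = -1; dy <= 1; ++dy, ++j) {
      const int s = dx * Hp + dy;
      const int lo = s < 0 ? -s : 0;
      const int m = NR - (s < 0 ? -s : s);
      F77_CALL(dgemm)("N", "N", &m, &Cout, &Cin, &one,
                      REAL(Xpad) + lo + s, &ld,
                      REAL(W) + j * Cin, &ldw,
                      &one, REAL(Ypad) + lo, &ld FCONE FCONE);
    }
  }
  NumericMatrix Y(npix * B, Cout);
  extract(REAL(Ypad), REAL(Y), H, Wimg, B, Cout, npix, npad, Hp, NR);
  for (int c = 0; c < Cout; ++c) {
    const double bc = bias[c];
    if (bc != 0.0) {
      double* y = REAL(Y) + (R_xlen_t)c * npix * B;
      for (int i = 0; i < npix * B; ++i) y[i] += bc;
    }
  }
  return List::create(_["Y"] = Y, _["Xpad"] = Xpad);
}

// [[Rcpp::export(name = ".conv3_bwd")]]
List conv3_bwd(NumericMatrix dY, NumericMatrix W, NumericMatrix Xpad,
               int H, int Wimg, int B) {
  const int Cout = dY.ncol(), Cin = W.nrow() / 9;
  const int Hp = H + 2, Wp = Wimg + 2;
  const int npix = H * Wimg, npad = Hp * Wp;
  const int NR = npad * B;
  NumericMatrix dYpad(NR, Cout), dXpad(NR, Cin);
  NumericMatrix dW(9 * Cin, Cout);
  embed(REAL(dY), REAL(dYpad), H, Wimg, B, Cout, npix, npad, Hp, NR);

  const double one = 1.0;
  const int ld = NR, ldw = 9 * Cin;
  int j = 0;
  for (int dx = -1; dx <= 1; ++dx) {
    for (int dy = -1; dy <= 1; ++dy, ++j) {
      const int s = dx * Hp + dy;
      const int lo = s < 0 ? -s : 0;
      const int m = NR - (s < 0 ? -s : s);
      // dW_j = Xpad(shifted)^T . dYpad
      F77_CALL(dgemm)("T", "N", &Cin, &Cout, &m, &one,
                      REAL(Xpad) + lo + s, &ld,
                      REAL(dYpad) + lo, &ld,
                      &one, REAL(dW) + j * Cin, &ldw FCONE FCONE);
      // dXpad(shifted) += dYpad . W_j^T
      F77_CALL(dgemm)("N", "T", &m, &Cin, &Cout, &one,
                      REAL(dYpad) + lo, &ld,
                      REAL(W) + j * Cin, &ldw,
                      &one, REAL(dXpad) + lo + s, &ld FCONE FCONE);
    }
  }
  NumericMatrix dX(npix * B, Cin);
  extract(REAL(dXpad), REAL(dX), H, Wimg, B, Cin, npix, npad, Hp, NR);
  NumericVector db(Cout);
  for (int c = 0; c < Cout; ++c) {
    const double* y = REAL(dY) + (R_xlen_t)c * npix * B;
    double acc = 0.0;
    for (int i = 0; i < npix * B; ++i) acc += y[i];
    db[c] = acc;
  }
  return List::create(_["dX"] = dX, _["dW"] = dW, _["db"] = db);
}
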