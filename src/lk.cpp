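// Pyramidal Lucas-Kanade point tracking.
//
// Frame-to-frame tracking with the weighted-SSD matching criterion
// (weight w = 1): for each point, find the (drow, dcol) minimising
//   sum_patch [ I_t(x) - I_{t+1}(x + d) ]^2
// by Gauss-Newton iterations on a coarse-to-fine image pyramid, as in the
// classical hierarchical formulation. Subpixel sampling is bilinear; the
// spatial-gradient (structure) matrix G is computed once per level from
// the template patch; a track is invalidated when its patch leaves the
// image or when the normalised minimum eigenvalue of G signals too little
// texture to solve the 2x2 system reliably.

#include <Rcpp.h>
#include <vector>
#include <cmath>

using namespace Rcpp;

namespace {

struct Img {
  int h = 0, w = 0;
  std::vector<double> v;  // row-major
  double at(int r, int c) const { return v[(size_t)r * w + c]; }
};

// bilinear sample with clamped borders (callers keep patches in-bounds,
// clamping only guards the +-1 gradient stencil at the very edge)
inline double sample(const Img& im, double r, double c) {
  if (r < 0) r = 0;
  if (c < 0) c = 0;
  if (r > im.h - 1) r = im.h - 1;
  if (c > im.w - 1) c = im.w - 1;
  int r0 = (int)std::floor(r), c0 = (int)std::floor(c);
  int r1 = std::min(r0 + 1, im.h - 1), c1 = std::min(c0 + 1, im.w - 1);
  double fr = r - r0, fc = c - c0;
  return (1 - fr) * ((1 - fc) * im.at(r0, c0) + fc * im.at(r0, c1)) +
         fr * ((1 - fc) * im.at(r1, c0) + fc * im.at(r1, c1));
}

Img fromMatrix(const NumericMatrix& m) {
  Img im;
  im.h = m.nrow();
  im.w = m.ncol();
  im.v.resize((size_t)im.h * im.w);
  for (int r = 0; r < im.h; ++r)
    for (int c = 0; c < im.w; ++c) im.v[(size_t)r * im.w + c] = m(r, c);
  return im;
}

// 5-tap binomial smoothing + decimation by 2 (standard pyramid reduce)
Img reduce(const Img& in) {
  static const double k[5] = {1.0 / 16, 4.0 / 16, 6.0 / 16, 4.0 / 16,
                              1.0 / 16};
  Img tmp;  // smooth along columns
  tmp.h = in.h;
  tmp.w = in.w;
  tmp.v.resize(in.v.size());
  for (int r = 0; r < in.h; ++r)
    for (int c = 0; c < in.w; ++c) {
      double s = 0;
      for (int m = -2; m <= 2; ++m) {
        int cc = std::min(std::max(c + m, 0), in.w - 1);
        s += k[m + 2] * in.at(r, cc);
      }
      tmp.v[(size_t)r * tmp.w + c] = s;
    }
  Img out;
  out.h = (in.h + 1) / 2;
  out.w = (in.w + 1) / 2;
  out.v.resize((size_t)out.h * out.w);
  for (int r = 0; r < out.h; ++r)
    for (int c = 0; c < out.w; ++c) {
      double s = 0;
      for (int m = -2; m <= 2; ++m) {
        int rr = std::min(std::max(2 * r + m, 0), in.h - 1);
        s += k[m + 2] * tmp.at(rr, c);
      }
      out.v[(size_t)r * out.w + c] = s;
    }
  return out;
}

std::vector<Img> pyramid(const NumericMatrix& m, int levels) {
  std::vector<Img> p;
  p.push_back(fromMatrix(m));
  for (int l = 1; l < levels; ++l) {
    if (p.back().h < 8 || p.back().w < 8) break;
    p.push_back(reduce(p.back()));
  }
  return p;
}

}  // namespace

// Track points through a sequence. frames: list of numeric matrices
// (equal size); seeds: n x 2 matrix of 0-based (row, col) positions in
// frame 1. Returns positions (n x T x 2, 0-based) and validity flags.
// [[Rcpp::export(name = ".cpp_lk_track")]]
List cpp_lk_track(List frames, NumericMatrix seeds, int win, int levels,
                  int maxIter, double eps, double minEig) {
  const int T = frames.size();
  const int n = seeds.nrow();
  const int hw = win / 2;
  if (T < 2) stop("need at least 2 frames");
  if (n < 1) stop("parameter error: empty seed list");

  NumericVector pos(Dimension(n, T, 2));
  LogicalMatrix valid(n, T);
  std::vector<double> prow(n), pcol(n);
  std::vector<char> alive(n, 1);

  NumericMatrix f0 = frames[0];
  const int H = f0.nrow(), W = f0.ncol();
  for (int i = 0; i < n; ++i) {
    prow[i] = seeds(i, 0);
    pcol[i] = seeds(i, 1);
    bool in = prow[i] >= hw && prow[i] <= H - 1 - hw && pcol[i] >= hw &&
              pcol[i] <= W - 1 - hw;
    if (prow[i] < 0 || prow[i] > H - 1 || pcol[i] < 0 || pcol[i] > W - 1)
      stop("seed %d lies outside the frame", i + 1);
    alive[i] = in ? 1 : 0;
    valid(i, 0) = alive[i];
    pos[i + (size_t)0 * n] = prow[i];
    pos[i + (size_t)T * n] = pcol[i];
  }

  const int npx = win * win;
  std::vector<double> tv(npx), gr(npx), gc(npx);

  std::vector<Img> prevPyr = pyramid(f0, levels);
  for (int t = 1; t < T; ++t) {
    NumericMatrix ft = frames[t];
    if (ft.nrow() != H || ft.ncol() != W)
      stop("congruence error: frame %d differs in size", t + 1);
    std::vector<Img> nextPyr = pyramid(ft, levels);
    const int L = (int)std::min(prevPyr.size(), nextPyr.size());

    for (int i = 0; i < n; ++i) {
      if (!alive[i]) {  // sticky invalidity; freeze last position
        pos[i + (size_t)t * n] = prow[i];
        pos[i + (size_t)(T + t) * n] = pcol[i];
        valid(i, t) = false;
        continue;
      }
      double grow = 0, gcol = 0;  // guess, at the scale of the level below
      bool ok = true;
      for (int l = L - 1; l >= 0 && ok; --l) {
        const Img& P = prevPyr[l];
        const Img& N = nextPyr[l];
        const double scale = std::ldexp(1.0, -l);  // 2^-l
        const double pr = prow[i] * scale, pc = pcol[i] * scale;
        bool skip = false;
        if (pr < hw || pr > P.h - 1 - hw || pc < hw || pc > P.w - 1 - hw) {
          if (l == 0) ok = false;  // out of bounds at full resolution
          skip = true;             // coarse level too small: skip it
        }
        double g00 = 0, g01 = 0, g11 = 0, det = 0;
        if (!skip) {
          // template patch values and gradients (central differences on
          // bilinearly sampled intensities)
          int k = 0;
          for (int dr = -hw; dr <= hw; ++dr)
            for (int dc = -hw; dc <= hw; ++dc, ++k) {
              double r = pr + dr, c = pc + dc;
              tv[k] = sample(P, r, c);
              gr[k] = 0.5 * (sample(P, r + 1, c) - sample(P, r - 1, c));
              gc[k] = 0.5 * (sample(P, r, c + 1) - sample(P, r, c - 1));
              g00 += gr[k] * gr[k];
              g01 += gr[k] * gc[k];
              g11 += gc[k] * gc[k];
            }
          const double tr = 0.5 * (g00 + g11);
          det = g00 * g11 - g01 * g01;
          const double lmin = tr - std::sqrt(std::max(0.0, tr * tr - det));
          if (l == 0 && lmin / npx < minEig) {
            ok = false;  // texture too flat to solve reliably
            skip = true;
          } else if (det <= 0 || lmin / npx < 1e-12) {
            skip = true;  // coarse level unusable, rely on finer ones
          }
        }
        if (!skip) {
          double vr = 0, vc = 0;  // flow increment at this level
          for (int it = 0; it < maxIter; ++it) {
            double br = 0, bc = 0;
            int k = 0;
            double nr0 = pr + grow + vr, nc0 = pc + gcol + vc;
            if (nr0 < hw || nr0 > N.h - 1 - hw || nc0 < hw ||
                nc0 > N.w - 1 - hw) {
              if (l == 0) ok = false;
              break;
            }
            for (int dr = -hw; dr <= hw; ++dr)
              for (int dc = -hw; dc <= hw; ++dc, ++k) {
                double diff = tv[k] - sample(N, nr0 + dr, nc0 + dc);
                br += diff * gr[k];
                bc += diff * gc[k];
              }
            const double dvr = (g11 * br - g01 * bc) / det;
            const double dvc = (g00 * bc - g01 * br) / det;
            vr += dvr;
            vc += dvc;
            if (std::sqrt(dvr * dvr + dvc * dvc) < eps) break;
          }
          grow += vr;
          gcol += vc;
        }
        if (l > 0) {
          grow *= 2;
          gcol *= 2;
        }
      }
      double nrow_ = prow[i] + grow, ncol_ = pcol[i] + gcol;
      if (ok && nrow_ >= hw && nrow_ <= H - 1 - hw && ncol_ >= hw &&
          ncol_ <= W - 1 - hw) {
        prow[i] = nrow_;
        pcol[i] = ncol_;
        valid(i, t) = true;
      } else {
        alive[i] = 0;
        valid(i, t) = false;
      }
      pos[i + (size_t)t * n] = prow[i];
      pos[i + (size_t)(T + t) * n] = pcol[i];
    }
    prevPyr = std::move(nextPyr);
  }
  return List::create(Named("positions") = pos, Named("valid") = valid);
}
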