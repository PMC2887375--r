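# Orthogonal wavelet decomposition low-pass filters (analysis side).
# Standard published Daubechies / Symlet coefficient values; the high-pass
# filter is derived by the quadrature-mirror relation, and the synthesis
# side is the transpose of the (orthogonal) periodized analysis operator.
.wavelet_filters <- list(
  haar = c(0.70710678118654757, 0.70710678118654757),
  db2 = c(-0.12940952255126037, 0.22414386804201339, 0.83651630373780794,
          0.48296291314453416),
  db4 = c(-0.010597401785069032, 0.032883011666885197, 0.030841381835560764,
          -0.18703481171909309, -0.027983769416859854, 0.63088076792985892,
          0.71484657055291567, 0.23037781330889651),
  sym4 = c(-0.075765714789273325, -0.02963552764599851, 0.49761866763201545,
           0.80373875180591614, 0.29785779560527736, -0.099219543576847216,
           -0.012603967262037833, 0.032223100604042702),
  sym8 = c(-0.0033824159510061256, -0.00054213233179114812,
           0.031695087811492981, 0.0076074873249176054, -0.14329423835080971,
           -0.061273359067658524, 0.48135965125837221, 0.77718575170052351,
           0.3644418948353314, -0.051945838107709037, -0.027219029917056003,
           0.049137179673607506, 0.0038087520138906151, -0.014952258337048231,
           -0.0003029205147213668, 0.0018899503327594609)
)

# high-pass from low-pass: g[m] = (-1)^(m+1) * h[L-1-m]  (m = 0..L-1),
# the phase convention of the common DWT implementations
.qmf_highpass <- function(lo) {
  L <- length(lo)
  -rev(lo) * (-1)^(seq_len(L) - 1L)
}

#' Supported wavelet bases
#' @return character vector of basis names accepted by [waveletConfig()].
#' @export
waveletBases <- function() names(.wavelet_filters)

#' Filter length of a wavelet basis
#' @param basis basis name, see [waveletBases()].
#' @return integer(1); number of filter taps.
#' @export
waveletFilterLength <- function(basis) {
  if (!basis %in% names(.wavelet_filters))
    stop(sprintf("unknown wavelet basis '%s'", basis))
  length(.wavelet_filters[[basis]])
}

# Cache of periodized single-level analysis matrices, keyed by basis:length.
# For signal length N (even) the low-pass analysis matrix is (N/2) x N with
#   L[k, (2k + 2 - m) mod N] += lo[m],   k = 0..N/2-1, m = 0..L-1
# (0-based; wrap-around accumulates when the filter is longer than the
# signal). Stacking [L; H] gives an orthogonal N x N operator, so the
# synthesis side is exactly the transpose.
.dwt_cache <- new.env(parent = emptyenv())

.analysis_matrices <- function(basis, n) {
  key <- paste0(basis, ":", n)
  hit <- .dwt_cache[[key]]
  if (!is.null(hit)) return(hit)
  if (n %% 2L != 0L) stop("periodized DWT needs an even signal length")
  lo <- .wavelet_filters[[basis]]
  hi <- .qmf_highpass(lo)
  L <- length(lo)
  Lm <- matrix(0, n %/% 2L, n)
  Hm <- matrix(0, n %/% 2L, n)
  for (k in seq_len(n %/% 2L) - 1L) {
    for (m in seq_len(L) - 1L) {
      j <- ((2L * k + 2L - m) %% n) + 1L
      Lm[k + 1L, j] <- Lm[k + 1L, j] + lo[m + 1L]
      Hm[k + 1L, j] <- Hm[k + 1L, j] + hi[m + 1L]
    }
  }
  res <- list(lo = Lm, hi = Hm)
  .dwt_cache[[key]] <- res
  res
}
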