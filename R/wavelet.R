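#' @include AllClasses.R wavelet-filters.R
NULL

#' Construct a wavelet configuration
#'
#' Settings of the congruence transform: the orthogonal wavelet family and
#' the decomposition depth. The transform is periodized, so each level
#' halves both frame dimensions exactly; both dimensions must be divisible
#' by \code{2^levels}.
#'
#' @param basis wavelet family; default \code{"sym8"} (Symlet 8), the basis
#'   used throughout the package's reference analyses. See [waveletBases()].
#' @param levels decomposition depth (>= 1); default 4. Functions that build
#'   feature tables clamp this to the deepest feasible level for the frame
#'   at hand.
#' @return a [WaveletConfig-class].
#' @export
waveletConfig <- function(basis = "sym8", levels = 4L)
  new("WaveletConfig", basis = basis, levels = as.integer(levels),
      boundaryMode = "periodic")

setMethod("show", "WaveletConfig", function(object)
  cat(sprintf("WaveletConfig: basis %s, %d level(s), %s boundaries\n",
              object@basis, object@levels, object@boundaryMode)))

#' Deepest feasible decomposition level for a frame shape
#'
#' The periodized transform halves each dimension per level, so the depth is
#' limited by the number of times both dimensions divide evenly by 2.
#' @param frameShape integer(2); (height, width).
#' @return integer(1); 0 if a dimension is odd.
#' @export
maxFeasibleLevels <- function(frameShape) {
  twos <- function(n) {
    l <- 0L
    while (n %% 2L == 0L && n %/% 2L >= 1L) { n <- n %/% 2L; l <- l + 1L }
    l
  }
  min(twos(as.integer(frameShape[1L])), twos(as.integer(frameShape[2L])))
}

.check_levels <- function(frameShape, config) {
  feas <- maxFeasibleLevels(frameShape)
  if (config@levels > feas)
    stop(sprintf(
      "config error: %d levels too deep for a %d x %d frame (max feasible: %d)",
      config@levels, frameShape[1L], frameShape[2L], feas))
}

# single-level periodized separable 2-D DWT; rows filtered along the depth
# axis, cols along the lateral axis. Subband naming: horiz = high-pass rows,
# vert = high-pass cols, diag = high-pass both.
.dwt2_level <- function(x, basis) {
  fr <- .analysis_matrices(basis, nrow(x))
  fc <- .analysis_matrices(basis, ncol(x))
  xl <- x %*% t(fc$lo); xh <- x %*% t(fc$hi)
  list(a = fr$lo %*% xl, h = fr$hi %*% xl,
       v = fr$lo %*% xh, d = fr$hi %*% xh)
}

.idwt2_level <- function(bands, basis) {
  fr <- .analysis_matrices(basis, 2L * nrow(bands$a))
  fc <- .analysis_matrices(basis, 2L * ncol(bands$a))
  t(fr$lo) %*% (bands$a %*% fc$lo + bands$v %*% fc$hi) +
    t(fr$hi) %*% (bands$h %*% fc$lo + bands$d %*% fc$hi)
}

#' Coefficient index map of a frame shape under a configuration
#'
#' The documented fixed flattening order of the full coefficient vector:
#' the approximation band of the deepest level first, then per level from
#' deepest to shallowest the diagonal, vertical and horizontal detail bands,
#' each band row-major. Identical frame shape and configuration give an
#' identical map -- this is what makes the transformed frames congruent.
#'
#' @param frameShape integer(2); (height, width).
#' @param config a [WaveletConfig-class].
#' @return data.frame with columns \code{level}, \code{subband}, \code{row},
#'   \code{col} (1-based within the subband) and \code{index} (position in
#'   the flattened vector); one row per coefficient, totalling
#'   \code{prod(frameShape)}.
#' @export
waveletIndexMap <- function(frameShape, config) {
  .check_levels(frameShape, config)
  h <- as.integer(frameShape[1L]); w <- as.integer(frameShape[2L])
  lv <- config@levels
  band <- function(level, subband, bh, bw)
    data.frame(level = level, subband = subband,
               row = rep(seq_len(bh), each = bw), col = rep(seq_len(bw), bh))
  pieces <- list(band(lv, "approx", h %/% 2L^lv, w %/% 2L^lv))
  for (l in seq(lv, 1L)) {
    bh <- h %/% 2L^l; bw <- w %/% 2L^l
    pieces <- c(pieces, list(band(l, "diag", bh, bw), band(l, "vert", bh, bw),
                             band(l, "horiz", bh, bw)))
  }
  map <- do.call(rbind, pieces)
  map$index <- seq_len(nrow(map))
  rownames(map) <- NULL
  map
}

.flatten_rowmajor <- function(m) as.vector(t(m))
.unflatten_rowmajor <- function(v, nr, nc) matrix(v, nr, nc, byrow = TRUE)

#' Decompose one frame into its full wavelet coefficient vector
#'
#' Runs the periodized 2-D DWT to the configured depth and flattens all
#' subbands in the fixed order documented in [waveletIndexMap()]. The
#' transform is orthogonal: [reconstructFrame()] inverts it to machine
#' precision.
#'
#' @param frame numeric matrix (height x width), finite.
#' @param config a [WaveletConfig-class]; levels must be feasible for the
#'   frame size.
#' @return list with \code{coeffs} (numeric vector, length
#'   \code{prod(dim(frame))}) and \code{indexMap} (see [waveletIndexMap()]).
#' @examples
#' f <- matrix(runif(32 * 32), 32, 32)
#' dec <- decomposeFrame(f, waveletConfig("sym8", 2))
#' max(abs(reconstructFrame(dec$coeffs, waveletConfig("sym8", 2),
#'                          dim(f)) - f))
#' @export
decomposeFrame <- function(frame, config = waveletConfig()) {
  stopifnot(is.matrix(frame))
  if (!all(is.finite(frame))) stop("frame must be finite")
  .check_levels(dim(frame), config)
  a <- frame
  details <- vector("list", config@levels)
  for (l in seq_len(config@levels)) {
    b <- .dwt2_level(a, config@basis)
    details[[l]] <- b[c("d", "v", "h")]
    a <- b$a
  }
  out <- list(.flatten_rowmajor(a))
  for (l in seq(config@levels, 1L))
    out <- c(out, lapply(details[[l]], .flatten_rowmajor))
  list(coeffs = unlist(out, use.names = FALSE),
       indexMap = waveletIndexMap(dim(frame), config))
}

#' Inverse transform of a full coefficient vector
#'
#' @param coeffs numeric vector in the flattening order of
#'   [waveletIndexMap()]; length must equal \code{prod(frameShape)}.
#' @param config the [WaveletConfig-class] used for the decomposition.
#' @param frameShape integer(2); (height, width) of the original frame.
#' @return numeric matrix (height x width).
#' @export
reconstructFrame <- function(coeffs, config, frameShape) {
  h <- as.integer(frameShape[1L]); w <- as.integer(frameShape[2L])
  .check_levels(c(h, w), config)
  if (length(coeffs) != h * w)
    stop(sprintf("coefficient vector has length %d, expected %d",
                 length(coeffs), h * w))
  lv <- config@levels
  pos <- 0L
  take <- function(n) {
    v <- coeffs[pos + seq_len(n)]
    pos <<- pos + n
    v
  }
  bh <- h %/% 2L^lv; bw <- w %/% 2L^lv
  a <- .unflatten_rowmajor(take(bh * bw), bh, bw)
  for (l in seq(lv, 1L)) {
    bh <- h %/% 2L^l; bw <- w %/% 2L^l
    d <- .unflatten_rowmajor(take(bh * bw), bh, bw)
    v <- .unflatten_rowmajor(take(bh * bw), bh, bw)
    hb <- .unflatten_rowmajor(take(bh * bw), bh, bw)
    a <- .idwt2_level(list(a = a, h = hb, v = v, d = d), config@basis)
  }
  a
}

#' Build the congruent feature table of a sequence
#'
#' Decomposes every frame with the same configuration (hence an identical
#' coefficient index map -- the congruence property), measures each
#' coefficient's variance across frames, and retains the \code{nKeep}
#' coefficients with the largest variance. Columns of the resulting table
#' are ordered by descending variance; ties are broken by index-map order,
#' so the selection is deterministic.
#'
#' @param seq an [ImageSequence-class] (>= 2 frames).
#' @param config a [WaveletConfig-class]. If its depth exceeds the deepest
#'   feasible level for the frame size it is clamped (with a message).
#' @param nKeep number of coefficients to retain; default 3000, the table
#'   size used by the package's reference analyses. Must be between 1 and
#'   the total coefficient count.
#' @return a [FeatureTable-class].
#' @examples
#' seq <- imageSequence(array(runif(4 * 32 * 32), c(4, 32, 32)))
#' ft <- buildFeatureTable(seq, waveletConfig("sym8", 2), nKeep = 100)
#' dim(ft@X)
#' @export
buildFeatureTable <- function(seq, config = waveletConfig(), nKeep = 3000L) {
  stopifnot(is(seq, "ImageSequence"))
  d <- frameDim(seq)
  feas <- maxFeasibleLevels(d)
  if (feas < 1L)
    stop(sprintf("config error: %d x %d frames have odd dimensions; crop to even sizes",
                 d[1L], d[2L]))
  if (config@levels > feas) {
    message(sprintf("clamping wavelet depth from %d to %d (max feasible for %d x %d frames)",
                    config@levels, feas, d[1L], d[2L]))
    config <- waveletConfig(config@basis, feas)
  }
  n <- nFrames(seq)
  total <- prod(d)
  nKeep <- as.integer(nKeep)
  if (nKeep < 1L || nKeep > total)
    stop(sprintf("size error: nKeep = %d must be in [1, %d]", nKeep, total))
  C <- matrix(0, n, total)
  map <- NULL
  for (i in seq_len(n)) {
    dec <- decomposeFrame(getFrame(seq, i), config)
    if (is.null(map)) map <- dec$indexMap
    C[i, ] <- dec$coeffs
  }
  mu <- colMeans(C)
  vars <- colSums(sweep(C, 2L, mu)^2) / (n - 1L)
  ord <- order(vars, decreasing = TRUE)  # radix sort: stable, ties by index
  keep <- ord[seq_len(nKeep)]
  new("FeatureTable", X = C[, keep, drop = FALSE],
      indexMap = map[keep, , drop = FALSE], config = config,
      frameShape = as.integer(d), variances = vars[keep],
      nTotal = as.integer(total))
}

setMethod("show", "FeatureTable", function(object) {
  cat(sprintf("FeatureTable: %d frames x %d coefficients (of %d; %s, %d levels)\n",
              nrow(object@X), ncol(object@X), object@nTotal,
              object@config@basis, object@config@levels))
  cat(sprintf("  variance range of retained columns: [%.4g, %.4g]\n",
              min(object@variances), max(object@variances)))
  tab <- table(object@indexMap$subband)
  cat("  retained per subband:",
      paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
})

#' Serialize a feature table to CSV + JSON sidecar
#'
#' Writes the coefficient matrix as CSV (one row per frame) and the index
#' map plus configuration as a JSON sidecar next to it.
#' @param table a [FeatureTable-class].
#' @param path CSV output path; the sidecar gets extension ".json".
#' @return \code{path}, invisibly.
#' @export
writeFeatureTable <- function(table, path) {
  utils::write.csv(as.data.frame(table@X), path, row.names = FALSE)
  side <- sub("\\.csv$", "", path)
  jsonlite::write_json(
    list(config = list(basis = table@config@basis,
                       levels = table@config@levels,
                       boundaryMode = table@config@boundaryMode),
         frameShape = table@frameShape, nTotal = table@nTotal,
         variances = table@variances, indexMap = table@indexMap),
    paste0(side, ".json"), digits = NA, auto_unbox = TRUE)
  invisible(path)
}
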