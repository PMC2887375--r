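#' @include AllClasses.R AllGenerics.R pca.R trajectory.R
#' @useDynLib maci, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

.frames_as_list <- function(seq)
  lapply(seq_len(nFrames(seq)), function(i) getFrame(seq, i))

#' Track points through a sequence by pyramidal Lucas-Kanade
#'
#' Frame-to-frame speckle tracking: for each seeded point the (drow, dcol)
#' minimising the sum of squared intensity differences between the patch
#' around the point and the next frame (weight 1 on every pixel) is found
#' by Gauss-Newton iteration on a coarse-to-fine image pyramid, giving
#' subpixel estimates. A track is invalidated -- permanently -- when its
#' patch leaves the image or when the minimum eigenvalue of the spatial
#' gradient matrix (normalised by patch area) falls below \code{minEig},
#' i.e. when there is too little texture to solve the flow equations.
#'
#' @param seq an [ImageSequence-class] (>= 2 frames).
#' @param seeds numeric matrix (n x 2) of 1-based (row, col) positions in
#'   frame 1, inside the frame.
#' @param window odd patch size in px; default 21.
#' @param pyramidLevels number of pyramid levels; default 3.
#' @param maxIter Gauss-Newton iteration cap per level; default 30.
#' @param eps termination threshold on the update norm in px; default 0.01.
#' @param minEig texture threshold on the normalised minimum eigenvalue of
#'   the gradient matrix; default 1e-4 (intensities are in [0, 1]).
#' @return a [TrackSet-class]; positions are 1-based (row, col).
#' @seealso [trackGrid()], [trackSegmentedRoi()], [displacement()]
#' @export
trackPoints <- function(seq, seeds, window = 21L, pyramidLevels = 3L,
                        maxIter = 30L, eps = 0.01, minEig = 1e-4) {
  stopifnot(is(seq, "ImageSequence"))
  if (is.null(dim(seeds))) seeds <- matrix(seeds, ncol = 2L, byrow = TRUE)
  if (!nrow(seeds)) stop("parameter error: empty seed list")
  if (window %% 2L == 0L) stop("'window' must be odd")
  d <- frameDim(seq)
  if (any(seeds[, 1L] < 1 | seeds[, 1L] > d[1L] |
          seeds[, 2L] < 1 | seeds[, 2L] > d[2L]))
    stop("seeds must lie inside the frame")
  res <- .cpp_lk_track(.frames_as_list(seq), seeds - 1, as.integer(window),
                       as.integer(pyramidLevels), as.integer(maxIter),
                       eps, minEig)
  new("TrackSet", positions = res$positions + 1, valid = res$valid,
      roiSize = c(as.integer(window), as.integer(window)),
      frameRate = frameRate(seq), pixelSpacing = pixelSpacing(seq))
}

setMethod("nFrames", "TrackSet", function(x) dim(x@positions)[2L])
setMethod("frameRate", "TrackSet", function(x) x@frameRate)
setMethod("pixelSpacing", "TrackSet", function(x) x@pixelSpacing)

setMethod("show", "TrackSet", function(object) {
  d <- dim(object@positions)
  cat(sprintf("TrackSet: %d track(s) over %d frames (%d x %d px patches)\n",
              d[1L], d[2L], object@roiSize[1L], object@roiSize[2L]))
  if (!anyNA(object@gridShape))
    cat(sprintf("  seeded as a %d x %d grid\n", object@gridShape[1L],
                object@gridShape[2L]))
  cat(sprintf("  fully valid tracks: %d / %d\n",
              sum(rowSums(!object@valid) == 0L), d[1L]))
})

#' @describeIn trackPoints transversal (row-direction) displacement of each
#'   track relative to frame 1, in px or mm.
#' @param x a [TrackSet-class].
#' @param unit \code{"px"} or \code{"mm"}.
#' @export
setMethod("displacement", "TrackSet", function(x, unit = "px") {
  disp <- x@positions[, , 1L, drop = FALSE]
  disp <- matrix(disp, dim(disp)[1L], dim(disp)[2L])
  disp <- disp - disp[, 1L]
  if (unit == "mm") {
    if (is.na(x@pixelSpacing[1L]))
      stop("mm requested but the track set has no pixel spacing")
    disp <- disp * x@pixelSpacing[1L]
  } else if (unit != "px") stop("unit must be 'px' or 'mm'")
  disp
})

#' Track a segmented ROI and report per-segment displacement
#'
#' Splits a rectangular ROI into \code{nSegments} equal bands along its
#' long axis, tracks the centre of each band, and reports the transversal
#' (row-direction) displacement of every segment relative to frame 1 -- in
#' px always, and in mm when the sequence carries a pixel spacing.
#'
#' @param seq an [ImageSequence-class].
#' @param roi a [RoiRect-class] inside the frame.
#' @param nSegments number of bands (>= 1, <= the ROI's long-axis extent).
#' @param ... passed to [trackPoints()].
#' @return a [DisplacementSeries-class].
#' @export
trackSegmentedRoi <- function(seq, roi, nSegments = 5L, ...) {
  stopifnot(is(seq, "ImageSequence"), is(roi, "RoiRect"))
  d <- frameDim(seq)
  if (roi@row0 + roi@height > d[1L] || roi@col0 + roi@width > d[2L])
    stop("bounds error: ROI outside frame")
  nSegments <- as.integer(nSegments)
  long <- max(roi@height, roi@width)
  if (nSegments < 1L || nSegments > long)
    stop(sprintf("nSegments must be in [1, %d]", long))
  # band centres along the long axis, centred in the short axis
  at <- (seq_len(nSegments) - 0.5) / nSegments
  if (roi@height >= roi@width) {
    rows <- roi@row0 + at * roi@height + 0.5
    cols <- rep(roi@col0 + roi@width / 2 + 0.5, nSegments)
  } else {
    rows <- rep(roi@row0 + roi@height / 2 + 0.5, nSegments)
    cols <- roi@col0 + at * roi@width + 0.5
  }
  tracks <- trackPoints(seq, cbind(rows, cols), ...)
  px <- displacement(tracks, "px")
  mm <- if (!is.na(pixelSpacing(seq)[1L])) displacement(tracks, "mm") else
    matrix(numeric(), 0L, 0L)
  new("DisplacementSeries", dispPx = px, dispMm = mm, tracks = tracks)
}

#' @describeIn trackSegmentedRoi displacement matrix of a series.
#' @param x a [DisplacementSeries-class].
#' @param unit \code{"px"} or \code{"mm"}.
#' @export
setMethod("displacement", "DisplacementSeries", function(x, unit = "px") {
  if (unit == "px") return(x@dispPx)
  if (unit == "mm") {
    if (!length(x@dispMm)) stop("no pixel spacing: mm unavailable")
    return(x@dispMm)
  }
  stop("unit must be 'px' or 'mm'")
})

setMethod("show", "DisplacementSeries", function(object)
  cat(sprintf(
    "DisplacementSeries: %d segment(s) over %d frames; |disp| up to %.2f px%s\n",
    nrow(object@dispPx), ncol(object@dispPx), max(abs(object@dispPx)),
    if (length(object@dispMm))
      sprintf(" (%.2f mm)", max(abs(object@dispMm))) else "")))

#' Track an equidistant grid of ROIs over the whole image plane
#'
#' Seeds \code{rows x cols} points equidistantly (leaving a half-window
#' margin at the borders) and tracks them all; the whole-image analogue of
#' the single-ROI analysis, e.g. a 12 x 12 grid for display or a denser
#' grid for analysis.
#'
#' @param seq an [ImageSequence-class].
#' @param gridShape integer(2); (rows, cols) of the grid.
#' @param window,... as in [trackPoints()].
#' @return a [TrackSet-class] with \code{gridShape} set.
#' @export
trackGrid <- function(seq, gridShape = c(12L, 12L), window = 21L, ...) {
  stopifnot(is(seq, "ImageSequence"))
  gridShape <- as.integer(gridShape)
  d <- frameDim(seq)
  margin <- window %/% 2L + 1L
  if (any(d - 2L * margin < gridShape - 1L))
    stop(sprintf(
      "parameter error: a %d x %d grid is too dense for %d x %d frames with window %d",
      gridShape[1L], gridShape[2L], d[1L], d[2L], window))
  gr <- if (gridShape[1L] == 1L) (d[1L] + 1) / 2 else
    seq(margin + 1L, d[1L] - margin, length.out = gridShape[1L])
  gc <- if (gridShape[2L] == 1L) (d[2L] + 1) / 2 else
    seq(margin + 1L, d[2L] - margin, length.out = gridShape[2L])
  seeds <- cbind(rep(gr, each = length(gc)), rep(gc, length(gr)))
  tracks <- trackPoints(seq, seeds, window = window, ...)
  initialize(tracks, gridShape = gridShape)
}

#' PCA of tracked coordinates
#'
#' Builds the frames x (2 n_valid) two-way table whose columns are the row
#' and column coordinates of every fully valid track and whose rows are
#' the frames, fits a PCA on it, and returns the score trajectory -- the
#' speckle-tracking counterpart of the congruent-image score trajectory,
#' directly comparable with it.
#'
#' @param tracks a [TrackSet-class] with at least one fully valid track.
#' @param k number of components; default 2.
#' @return list with elements \code{model} ([PcaModel-class]),
#'   \code{trajectory} ([ScoreTrajectory-class]) and \code{validTracks}
#'   (indices of the tracks used).
#' @export
pcaOfTracks <- function(tracks, k = 2L) {
  stopifnot(is(tracks, "TrackSet"))
  ok <- rowSums(!tracks@valid) == 0L
  if (!any(ok)) stop("degenerate-input error: no fully valid tracks")
  Tn <- nFrames(tracks)
  rowsM <- t(matrix(tracks@positions[ok, , 1L], sum(ok), Tn))
  colsM <- t(matrix(tracks@positions[ok, , 2L], sum(ok), Tn))
  X <- cbind(rowsM, colsM)
  if (sum(sweep(X, 2L, colMeans(X))^2) < 1e-12)
    stop("degenerate data: tracked coordinates show no variation (static scene?)")
  model <- fitPca(X, k = k)
  list(model = model,
       trajectory = scoreTrajectory(model, frameRate = tracks@frameRate),
       validTracks = which(ok))
}

#' Pennation angle from three tracked points
#'
#' The fascicle insertion angle: per frame, the angle at vertex p2 between
#' the arms (p1 - p2) and (p3 - p2), computed from the normalised dot
#' product, in degrees within [0, 180]. Frames where an arm has zero
#' length (or where a supplied track is invalid) are flagged undefined.
#'
#' @param p1,p2,p3 either numeric matrices (n_frames x 2) of (row, col)
#'   positions, or -- when \code{p1} is a [TrackSet-class] with exactly 3
#'   tracks -- taken from its tracks in order.
#' @return a [PennationSeries-class].
#' @examples
#' pennationAngle(cbind(0, 1), cbind(0, 0), cbind(1, 0))@angle  # 90
#' @export
pennationAngle <- function(p1, p2 = NULL, p3 = NULL) {
  if (is(p1, "TrackSet")) {
    ts <- p1
    if (dim(ts@positions)[1L] != 3L)
      stop("a TrackSet for pennation must contain exactly 3 tracks")
    valid <- colSums(!ts@valid) == 0L
    p1 <- ts@positions[1L, , ]; p2 <- ts@positions[2L, , ]
    p3 <- ts@positions[3L, , ]
  } else valid <- NULL
  p1 <- rbind(p1); p2 <- rbind(p2); p3 <- rbind(p3)
  n <- max(nrow(p1), nrow(p2), nrow(p3))
  expand <- function(p) if (nrow(p) == n) p else
    matrix(p, n, 2L, byrow = TRUE)
  p1 <- expand(p1); p2 <- expand(p2); p3 <- expand(p3)
  a <- p1 - p2; b <- p3 - p2
  na <- sqrt(rowSums(a^2)); nb <- sqrt(rowSums(b^2))
  defined <- na > 0 & nb > 0
  cosang <- rowSums(a * b) / (na * nb)
  ang <- rep(NA_real_, n)
  ang[defined] <- acos(pmin(1, pmax(-1, cosang[defined]))) * 180 / pi
  if (is.null(valid)) valid <- defined else valid <- valid & defined
  pts <- array(0, c(3L, n, 2L))
  pts[1L, , ] <- p1; pts[2L, , ] <- p2; pts[3L, , ] <- p3
  new("PennationSeries", angle = ang, valid = valid, points = pts)
}

setMethod("show", "PennationSeries", function(object)
  cat(sprintf(
    "PennationSeries: %d frames, angle range [%.2f, %.2f] deg (%d undefined)\n",
    length(object@angle), min(object@angle, na.rm = TRUE),
    max(object@angle, na.rm = TRUE), sum(!object@valid))))

#' Export tracks as CSV
#'
#' One row per (track, frame): roi_id, frame, row, col, valid, disp_px and
#' -- when a pixel spacing is known -- disp_mm.
#' @param tracks a [TrackSet-class].
#' @param path CSV output path.
#' @return \code{path}, invisibly.
#' @export
writeTracks <- function(tracks, path) {
  nR <- dim(tracks@positions)[1L]; nT <- nFrames(tracks)
  dp <- displacement(tracks, "px")
  df <- data.frame(
    roi_id = rep(seq_len(nR), nT),
    frame = rep(seq_len(nT), each = nR),
    row = as.vector(tracks@positions[, , 1L]),
    col = as.vector(tracks@positions[, , 2L]),
    valid = as.vector(tracks@valid),
    disp_px = as.vector(dp))
  if (!is.na(tracks@pixelSpacing[1L]))
    df$disp_mm <- df$disp_px * tracks@pixelSpacing[1L]
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
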