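#' @import methods
NULL

#' ImageSequence: an ordered stack of congruently sized grayscale frames
#'
#' Container for a grayscale B-scan ultrasound loop (or any grayscale image
#' sequence). Frames are stored as a 3-D array with dimensions
#' \code{(n_frames, height, width)}, intensities in \eqn{[0, 1]}. All frames
#' share the same height and width -- the congruence precondition for every
#' downstream analysis. Optional acquisition metadata: the frame rate in
#' frames per second, and the pixel spacing in mm per pixel along the
#' (row, col) axes. Rows increase downward with tissue depth, so the
#' transversal (depth) displacement axis is the row axis.
#'
#' @slot frames numeric 3-D array, \code{dim = c(n_frames, height, width)}.
#' @slot frameRate numeric(1); frames per second, \code{NA} if unknown.
#' @slot pixelSpacing numeric(2); mm per pixel along (row, col), \code{NA}
#'   if unknown.
#' @seealso [imageSequence()], [loadSequence()], [cropSequence()]
#' @export
setClass("ImageSequence",
  representation(frames = "array", frameRate = "numeric",
                 pixelSpacing = "numeric"),
  prototype(frameRate = NA_real_, pixelSpacing = c(NA_real_, NA_real_)))

setValidity("ImageSequence", function(object) {
  d <- dim(object@frames)
  if (length(d) != 3L)
    return("'frames' must be a 3-D array (n_frames, height, width)")
  if (d[1L] < 2L)
    return("an image sequence needs at least 2 frames")
  if (anyNA(object@frames) || !all(is.finite(object@frames)))
    return("frame intensities must be finite")
  rng <- range(object@frames)
  if (rng[1L] < 0 || rng[2L] > 1)
    return("frame intensities must lie in [0, 1] (load with normalize=TRUE)")
  if (length(object@frameRate) != 1L)
    return("'frameRate' must be a single number")
  if (!is.na(object@frameRate) && object@frameRate <= 0)
    return("'frameRate' must be positive")
  if (length(object@pixelSpacing) != 2L)
    return("'pixelSpacing' must have length 2 (row, col)")
  if (any(!is.na(object@pixelSpacing) & object@pixelSpacing <= 0))
    return("'pixelSpacing' must be positive")
  TRUE
})

#' RoiRect: a rectangular region of interest
#'
#' Axis-aligned rectangle in frame coordinates. \code{row0}/\code{col0} are
#' the 0-based top-left pixel; \code{height}/\code{width} are extents in
#' pixels. The ROI must lie fully inside the frame it is applied to.
#'
#' @slot row0,col0 integer(1); 0-based top-left corner.
#' @slot height,width integer(1); extents in pixels, > 0.
#' @seealso [roiRect()], [cropSequence()]
#' @export
setClass("RoiRect",
  representation(row0 = "integer", col0 = "integer",
                 height = "integer", width = "integer"))

setValidity("RoiRect", function(object) {
  v <- c(object@row0, object@col0, object@height, object@width)
  if (length(v) != 4L || anyNA(v)) return("ROI fields must be single integers")
  if (object@row0 < 0L || object@col0 < 0L)
    return("ROI corner must be non-negative (0-based)")
  if (object@height <= 0L || object@width <= 0L)
    return("ROI extents must be positive")
  TRUE
})

#' WaveletConfig: settings of the congruence transform
#'
#' @slot basis character(1); orthogonal wavelet family, one of
#'   \code{"haar"}, \code{"db2"}, \code{"db4"}, \code{"sym4"}, \code{"sym8"}.
#' @slot levels integer(1); decomposition depth, >= 1. Each level halves both
#'   frame dimensions, so both must be divisible by \code{2^levels}.
#' @slot boundaryMode character(1); always \code{"periodic"}: the transform
#'   is periodized, which keeps it orthogonal and non-expansive so coefficient
#'   addresses are identical for every frame of a sequence.
#' @seealso [waveletConfig()], [decomposeFrame()], [buildFeatureTable()]
#' @export
setClass("WaveletConfig",
  representation(basis = "character", levels = "integer",
                 boundaryMode = "character"),
  prototype(basis = "sym8", levels = 4L, boundaryMode = "periodic"))

setValidity("WaveletConfig", function(object) {
  if (!object@basis %in% names(.wavelet_filters))
    return(sprintf("unknown wavelet basis '%s' (available: %s)",
                   object@basis, paste(names(.wavelet_filters), collapse = ", ")))
  if (length(object@levels) != 1L || is.na(object@levels) || object@levels < 1L)
    return("'levels' must be a single integer >= 1")
  if (!identical(object@boundaryMode, "periodic"))
    return("only 'periodic' boundary handling is implemented")
  TRUE
})

#' FeatureTable: the congruent two-way table of wavelet coefficients
#'
#' Frames-by-coefficients matrix produced by [buildFeatureTable()]. Each row
#' is one frame; each column is one retained wavelet coefficient, identified
#' by its (level, subband, row, col) address in \code{indexMap}. Because the
#' transform is congruent, a column describes the same image element in every
#' frame. Columns are ordered by decreasing variance across frames.
#'
#' @slot X numeric matrix (n_frames x n_selected).
#' @slot indexMap data.frame with columns \code{level}, \code{subband}
#'   (\code{"approx"}, \code{"horiz"}, \code{"vert"}, \code{"diag"}),
#'   \code{row}, \code{col} (1-based within the subband), \code{index}
#'   (position in the full flattened coefficient vector); one row per column
#'   of \code{X}, in the same order.
#' @slot config the [WaveletConfig-class] used.
#' @slot frameShape integer(2); (height, width) of the source frames.
#' @slot variances numeric; per-column variance over frames, non-increasing.
#' @slot nTotal integer(1); total number of coefficients per frame before
#'   selection.
#' @seealso [buildFeatureTable()], [fitPca()], [reconstructLoadingImage()]
#' @export
setClass("FeatureTable",
  representation(X = "matrix", indexMap = "data.frame",
                 config = "WaveletConfig", frameShape = "integer",
                 variances = "numeric", nTotal = "integer"))

setValidity("FeatureTable", function(object) {
  if (ncol(object@X) != nrow(object@indexMap))
    return("columns of X and rows of indexMap must correspond 1:1")
  if (length(object@variances) != ncol(object@X))
    return("'variances' must have one entry per retained column")
  if (is.unsorted(rev(object@variances)))
    return("'variances' must be non-increasing (descending-variance order)")
  if (anyDuplicated(object@indexMap$index))
    return("coefficient addresses must be unique")
  if (ncol(object@X) > object@nTotal)
    return("cannot retain more coefficients than exist")
  TRUE
})

#' PcaModel: a NIPALS principal component model X = T P' + E
#'
#' Mean-centred (optionally unit-variance scaled) principal component model
#' of a frames x variables table, fitted component-by-component with NIPALS.
#' Loadings are unit-norm and orthogonal; scores are orthogonal; the
#' per-component explained fraction of the centred sum of squares is in
#' \code{r2x}.
#'
#' @slot center numeric(p); column means removed before fitting.
#' @slot scale numeric(p); column scale divisors (all 1 unless scaling was
#'   requested).
#' @slot scores numeric matrix T (n x k).
#' @slot loadings numeric matrix P (p x k).
#' @slot r2x numeric(k); per-component explained variance fraction.
#' @slot k,n,p integer(1); component count and table dimensions.
#' @slot residualSsq numeric(1); total residual sum of squares after k
#'   components.
#' @slot totalSsq numeric(1); total centred (scaled) sum of squares.
#' @seealso [fitPca()], [dmodx()], [r2xReport()], [scoreTrajectory()]
#' @export
setClass("PcaModel",
  representation(center = "numeric", scale = "numeric", scores = "matrix",
                 loadings = "matrix", r2x = "numeric", k = "integer",
                 n = "integer", p = "integer", residualSsq = "numeric",
                 totalSsq = "numeric"))

setValidity("PcaModel", function(object) {
  if (ncol(object@scores) != object@k || ncol(object@loadings) != object@k)
    return("scores/loadings must have k columns")
  if (nrow(object@scores) != object@n || nrow(object@loadings) != object@p)
    return("scores must be n x k and loadings p x k")
  if (length(object@r2x) != object@k)
    return("r2x must have one entry per component")
  if (any(object@r2x < -1e-12 | object@r2x > 1 + 1e-12))
    return("r2x entries must lie in [0, 1]")
  if (sum(object@r2x) > 1 + 1e-8)
    return("cumulative r2x cannot exceed 1")
  TRUE
})

#' DmodxResult: distance-to-model diagnostics
#'
#' Per-observation normalized residual standard deviation (DModX) after PCA
#' projection, the pooled residual standard deviation s0, and the F-based
#' critical limit Dcrit at significance level alpha.
#'
#' @slot dmodx numeric(n); >= 0, zero iff the residual row is all zero.
#' @slot s0 numeric(1); pooled residual standard deviation.
#' @slot dcrit numeric(1); critical DModX limit at level \code{alpha}.
#' @slot alpha numeric(1); significance level used for \code{dcrit}.
#' @seealso [dmodx()]
#' @export
setClass("DmodxResult",
  representation(dmodx = "numeric", s0 = "numeric", dcrit = "numeric",
                 alpha = "numeric"))

#' ScoreTrajectory: time-ordered PCA scores of an image sequence
#'
#' The rows of the score matrix follow acquisition order, so the sequence of
#' score vectors traces the movement through the model space. Phase
#' annotations (turning points, repetition boundaries) are attached as a
#' data.frame of (frame, label) marks.
#'
#' @slot scores numeric matrix (n_frames x k), acquisition order.
#' @slot frameRate numeric(1); frames per second or \code{NA}.
#' @slot annotations data.frame with columns \code{frame} (1-based index)
#'   and \code{label}.
#' @seealso [scoreTrajectory()], [detectTurningPoints()],
#'   [segmentRepetitions()], [adjacentDistances()]
#' @export
setClass("ScoreTrajectory",
  representation(scores = "matrix", frameRate = "numeric",
                 annotations = "data.frame"),
  prototype(frameRate = NA_real_,
            annotations = data.frame(frame = integer(), label = character())))

setValidity("ScoreTrajectory", function(object) {
  if (nrow(object@scores) < 2L) return("a trajectory needs >= 2 frames")
  a <- object@annotations
  if (!all(c("frame", "label") %in% names(a)))
    return("annotations need 'frame' and 'label' columns")
  if (nrow(a) && (any(a$frame < 1L) || any(a$frame > nrow(object@scores))))
    return("annotation frames out of range")
  TRUE
})

#' RepetitionSegments: ordered, non-overlapping repetition intervals
#'
#' Half-open frame intervals \code{[start, end)} (1-based) covering a
#' sequence, one per movement repetition, with strictly increasing starts.
#'
#' @slot start,end integer vectors of equal length.
#' @slot nFrames integer(1); length of the segmented sequence.
#' @seealso [segmentRepetitions()], [repetitionCorrelation()]
#' @export
setClass("RepetitionSegments",
  representation(start = "integer", end = "integer", nFrames = "integer"))

setValidity("RepetitionSegments", function(object) {
  if (length(object@start) != length(object@end))
    return("'start' and 'end' must have equal length")
  if (any(object@end <= object@start))
    return("segments must be non-empty half-open intervals [start, end)")
  if (is.unsorted(object@start, strictly = TRUE))
    return("segment starts must be strictly increasing")
  if (any(object@start < 1L) || any(object@end > object@nFrames + 1L))
    return("segments must lie within the sequence")
  if (length(object@start) > 1L &&
      any(object@start[-1L] < object@end[-length(object@end)]))
    return("segments must not overlap")
  TRUE
})

#' TrackSet: speckle-tracked point positions over time
#'
#' Subpixel (row, col) positions of tracked patch centres for every frame,
#' with validity flags. First-frame positions equal the seeded layout; a
#' track that leaves the image or loses texture is flagged invalid and stays
#' invalid (its position is frozen at the last valid estimate).
#'
#' @slot positions numeric array (n_rois x n_frames x 2), (row, col),
#'   1-based subpixel coordinates.
#' @slot valid logical matrix (n_rois x n_frames).
#' @slot roiSize integer(2); (height, width) of the tracked patches.
#' @slot gridShape integer(2) or NA; (rows, cols) when seeded as a grid.
#' @slot frameRate numeric(1); frames per second or \code{NA}.
#' @slot pixelSpacing numeric(2); mm per pixel (row, col) or \code{NA}.
#' @seealso [trackPoints()], [trackGrid()], [pcaOfTracks()], [displacement()]
#' @export
setClass("TrackSet",
  representation(positions = "array", valid = "matrix", roiSize = "integer",
                 gridShape = "integer", frameRate = "numeric",
                 pixelSpacing = "numeric"),
  prototype(gridShape = c(NA_integer_, NA_integer_), frameRate = NA_real_,
            pixelSpacing = c(NA_real_, NA_real_)))

setValidity("TrackSet", function(object) {
  d <- dim(object@positions)
  if (length(d) != 3L || d[3L] != 2L)
    return("'positions' must be (n_rois, n_frames, 2)")
  if (!identical(dim(object@valid), d[1:2]))
    return("'valid' must match positions (n_rois, n_frames)")
  if (any(!is.finite(object@positions[as.vector(object@valid)])))
    return("positions must be finite where valid")
  # once invalid, always invalid
  if (nrow(object@valid) &&
      any(apply(!object@valid, 1L, function(z) any(diff(cumsum(z) > 0) < 0))))
    return("a track cannot become valid again after invalidation")
  TRUE
})

#' DisplacementSeries: per-segment transversal displacement over time
#'
#' Row-direction (depth-axis) displacement of each tracked ROI segment
#' relative to frame 1, in pixels and -- when the pixel spacing is known --
#' in mm.
#'
#' @slot dispPx numeric matrix (n_segments x n_frames); 0 in column 1.
#' @slot dispMm numeric matrix of the same shape, or 0 x 0 when no pixel
#'   spacing is available.
#' @slot tracks the underlying [TrackSet-class].
#' @seealso [trackSegmentedRoi()], [displacement()]
#' @export
setClass("DisplacementSeries",
  representation(dispPx = "matrix", dispMm = "matrix", tracks = "TrackSet"))

#' PennationSeries: fascicle insertion angle over time
#'
#' Angle (degrees) at vertex p2 between the arms (p1 - p2) and (p3 - p2) of
#' three tracked points, per frame. Frames where either arm has zero length
#' or a track is invalid are flagged.
#'
#' @slot angle numeric(n_frames); degrees in [0, 180], \code{NA} where
#'   undefined.
#' @slot valid logical(n_frames).
#' @slot points numeric array (3 x n_frames x 2).
#' @seealso [pennationAngle()]
#' @export
setClass("PennationSeries",
  representation(angle = "numeric", valid = "logical", points = "array"))

#' SyntheticSpec: recipe for a simulated speckle sequence
#'
#' Fully determines (together with its seed) a synthetic speckle-textured
#' image sequence with a known per-frame displacement field and phase
#' labels. Speckle is emulated by random point scatterers blurred with a
#' Gaussian point-spread function; motion models are rigid translation,
#' depth-graded shear, and a cyclic plantar/dorsal-flexion-like profile.
#'
#' @slot frameShape integer(2); (height, width) in px.
#' @slot nFrames integer(1).
#' @slot scattererDensity numeric(1); scatterers per pixel.
#' @slot psfSigma numeric(1); Gaussian PSF sigma in px.
#' @slot motionModel character(1); \code{"translation"},
#'   \code{"depth_shear"} or \code{"cyclic_flexion"}.
#' @slot motionParams list; model parameters, see [syntheticSpec()].
#' @slot noiseSigma numeric(1); additive Gaussian noise sd (intensity units).
#' @slot seed integer(1); RNG seed, fully determines the output.
#' @slot frameRate numeric(1); metadata only.
#' @seealso [syntheticSpec()], [renderSequence()], [heelRaisePreset()]
#' @export
setClass("SyntheticSpec",
  representation(frameShape = "integer", nFrames = "integer",
                 scattererDensity = "numeric", psfSigma = "numeric",
                 motionModel = "character", motionParams = "list",
                 noiseSigma = "numeric", seed = "integer",
                 frameRate = "numeric"))

setValidity("SyntheticSpec", function(object) {
  if (any(object@frameShape < 8L)) return("frames must be at least 8 x 8")
  if (object@nFrames < 2L) return("need at least 2 frames")
  if (object@scattererDensity <= 0) return("scattererDensity must be > 0")
  if (object@psfSigma <= 0) return("psfSigma must be > 0")
  if (!object@motionModel %in% c("translation", "depth_shear", "cyclic_flexion"))
    return("unknown motion model")
  if (object@noiseSigma < 0) return("noiseSigma must be >= 0")
  TRUE
})

#' GroundTruth: exact motion knowledge for a synthetic sequence
#'
#' Per-frame amplitude profile, depth gain, phase labels, repetition
#' boundaries and turning frames, consistent with the rendered frames by
#' construction. The dense displacement field of any frame is reconstructed
#' on demand by [displacementField()]; the displacement of a material point
#' seeded at rest row r in frame 1 is \code{amplitude[t] * gain[r]} in the
#' row direction (plus any rigid translation component).
#'
#' @slot amplitude numeric(n_frames); scalar motion amplitude per frame (px
#'   at gain 1).
#' @slot gain numeric(height); row-direction gain per rest row (depth shear),
#'   all 1 for rigid translation.
#' @slot velocity numeric(2); rigid per-frame translation (row, col) px.
#' @slot phase character(n_frames); one of rest/concentric/hold/eccentric
#'   (or "static"/"constant" for non-cyclic models).
#' @slot repBoundaries integer; first frame of each repetition.
#' @slot turningFrames integer; true turning frames (one per repetition for
#'   cyclic motion).
#' @slot frameShape integer(2).
#' @seealso [renderSequence()], [displacementField()], [meanDisplacement()]
#' @export
setClass("GroundTruth",
  representation(amplitude = "numeric", gain = "numeric",
                 velocity = "numeric", phase = "character",
                 repBoundaries = "integer", turningFrames = "integer",
                 frameShape = "integer"))
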