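#' @include AllClasses.R
NULL

#' Number of frames in a sequence-like object
#' @param x an [ImageSequence-class], [TrackSet-class] or
#'   [ScoreTrajectory-class].
#' @return integer(1).
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))

#' Frame dimensions (height, width)
#' @param x an [ImageSequence-class] or related object.
#' @return integer(2).
#' @export
setGeneric("frameDim", function(x) standardGeneric("frameDim"))

#' Frame rate in frames per second
#' @param x an object carrying timing metadata.
#' @return numeric(1), possibly \code{NA}.
#' @export
setGeneric("frameRate", function(x) standardGeneric("frameRate"))

#' Pixel spacing in mm per pixel along (row, col)
#' @param x an object carrying spatial calibration metadata.
#' @return numeric(2), possibly \code{NA}.
#' @export
setGeneric("pixelSpacing", function(x) standardGeneric("pixelSpacing"))

#' Extract one frame as a matrix
#' @param x an [ImageSequence-class].
#' @param i frame index (1-based).
#' @return numeric matrix (height x width).
#' @export
setGeneric("getFrame", function(x, i) standardGeneric("getFrame"))

#' Score matrix of a PCA model or trajectory
#' @param x a [PcaModel-class] or [ScoreTrajectory-class].
#' @return numeric matrix (n x k).
#' @export
setGeneric("scores", function(x) standardGeneric("scores"))

#' Loading matrix of a PCA model
#' @param x a [PcaModel-class].
#' @param ... unused.
#' @return numeric matrix (p x k), unit-norm orthogonal columns.
#' @export
setGeneric("loadings")

#' Per-component explained variance fractions
#' @param x a [PcaModel-class].
#' @return numeric(k).
#' @export
setGeneric("explainedVariance", function(x) standardGeneric("explainedVariance"))

#' Transversal (row-direction) displacement relative to frame 1
#' @param x a [TrackSet-class] or [DisplacementSeries-class].
#' @param unit \code{"px"} or \code{"mm"} (mm requires pixel spacing).
#' @return numeric matrix (n_rois x n_frames); row 1 of every track is 0.
#' @export
setGeneric("displacement", function(x, unit = "px") standardGeneric("displacement"))

#' Dense displacement field of a synthetic frame
#' @param x a [GroundTruth-class].
#' @param frame frame index (1-based).
#' @return numeric array (height x width x 2): per-pixel (row, col)
#'   displacement of the material point resting at that pixel in frame 1.
#' @export
setGeneric("displacementField", function(x, frame) standardGeneric("displacementField"))

#' Mean absolute imposed displacement per frame
#'
#' Scalar motion summary of a synthetic sequence: the imposed amplitude
#' times the mean depth gain (plus any rigid translation magnitude), one
#' value per frame. Used as the ground-truth movement profile that score
#' trajectories are compared against.
#' @param x a [GroundTruth-class].
#' @return numeric(n_frames).
#' @export
setGeneric("meanDisplacement", function(x) standardGeneric("meanDisplacement"))
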