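#' @include AllClasses.R AllGenerics.R
NULL

#' Construct an ImageSequence
#'
#' @param frames numeric 3-D array \code{(n_frames, height, width)} with
#'   intensities in \eqn{[0, 1]}, or a list of equally sized matrices.
#' @param frameRate frames per second (optional).
#' @param pixelSpacing mm per pixel, length-1 (isotropic) or length-2
#'   (row, col) (optional).
#' @return an [ImageSequence-class].
#' @examples
#' seq <- imageSequence(array(runif(5 * 16 * 16), c(5, 16, 16)),
#'                      frameRate = 78.6)
#' nFrames(seq)
#' @export
imageSequence <- function(frames, frameRate = NA_real_,
                          pixelSpacing = c(NA_real_, NA_real_)) {
  if (is.list(frames)) {
    dims <- lapply(frames, dim)
    ref <- dims[[1L]]
    for (i in seq_along(dims))
      if (!identical(dims[[i]], ref))
        stop(sprintf(
          "congruence error: frame %d is %s but frame 1 is %s", i,
          paste(dims[[i]], collapse = "x"), paste(ref, collapse = "x")))
    arr <- array(0, c(length(frames), ref[1L], ref[2L]))
    for (i in seq_along(frames)) arr[i, , ] <- frames[[i]]
    frames <- arr
  }
  if (length(pixelSpacing) == 1L) pixelSpacing <- rep(pixelSpacing, 2L)
  new("ImageSequence", frames = frames, frameRate = as.numeric(frameRate),
      pixelSpacing = as.numeric(pixelSpacing))
}

#' @describeIn imageSequence number of frames.
#' @param x,i see generic.
#' @export
setMethod("nFrames", "ImageSequence", function(x) dim(x@frames)[1L])

#' @describeIn imageSequence frame (height, width).
#' @export
setMethod("frameDim", "ImageSequence", function(x) dim(x@frames)[2:3])

#' @describeIn imageSequence frame rate (fps).
#' @export
setMethod("frameRate", "ImageSequence", function(x) x@frameRate)

#' @describeIn imageSequence pixel spacing (mm/px, row then col).
#' @export
setMethod("pixelSpacing", "ImageSequence", function(x) x@pixelSpacing)

#' @describeIn imageSequence extract frame \code{i} as a height x width
#'   matrix.
#' @export
setMethod("getFrame", "ImageSequence", function(x, i) {
  stopifnot(length(i) == 1L, i >= 1L, i <= nFrames(x))
  matrix(x@frames[i, , ], dim(x@frames)[2L], dim(x@frames)[3L])
})

setMethod("show", "ImageSequence", function(object) {
  d <- dim(object@frames)
  cat(sprintf("ImageSequence: %d frames of %d x %d px\n", d[1L], d[2L], d[3L]))
  if (!is.na(object@frameRate))
    cat(sprintf("  frame rate: %.3g fps (%.1f ms/frame)\n",
                object@frameRate, 1000 / object@frameRate))
  if (!anyNA(object@pixelSpacing))
    cat(sprintf("  pixel spacing: %.3g x %.3g mm\n",
                object@pixelSpacing[1L], object@pixelSpacing[2L]))
  cat(sprintf("  intensity range: [%.4g, %.4g]\n",
              min(object@frames), max(object@frames)))
})

#' Construct a rectangular region of interest
#'
#' @param row0,col0 0-based top-left pixel of the ROI.
#' @param height,width ROI extents in pixels (> 0).
#' @return a [RoiRect-class].
#' @examples
#' roiRect(5, 5, 10, 10)
#' @export
roiRect <- function(row0, col0, height, width)
  new("RoiRect", row0 = as.integer(row0), col0 = as.integer(col0),
      height = as.integer(height), width = as.integer(width))

#' Parse an ROI from its "row0,col0,height,width" string form
#'
#' The string form used on the command line and in JSON configs.
#' @param s character(1), four comma-separated integers.
#' @return a [RoiRect-class].
#' @export
parseRoi <- function(s) {
  v <- suppressWarnings(as.integer(strsplit(s, ",")[[1L]]))
  if (length(v) != 4L || anyNA(v))
    stop("ROI string must be 'row0,col0,height,width'")
  roiRect(v[1L], v[2L], v[3L], v[4L])
}

setMethod("show", "RoiRect", function(object)
  cat(sprintf("RoiRect: %d x %d px at (row %d, col %d) [0-based]\n",
              object@height, object@width, object@row0, object@col0)))

.luma <- c(0.299, 0.587, 0.114)  # Rec. 601 luminance weights

.read_frame_file <- function(f) {
  ext <- tolower(tools::file_ext(f))
  img <- switch(ext,
    png = png::readPNG(f),
    tif = , tiff = tiff::readTIFF(f),
    stop(sprintf("unsupported frame format '.%s' (%s)", ext, f)))
  .to_gray(img)
}

.to_gray <- function(img) {
  if (length(dim(img)) == 3L) {
    nch <- dim(img)[3L]
    w <- if (nch >= 3L) c(.luma, rep(0, nch - 3L)) else rep(1 / nch, nch)
    img <- apply(sweep(img, 3L, w, "*"), c(1L, 2L), sum)
  }
  img
}

#' Load a grayscale image sequence
#'
#' Reads either a multi-page TIFF or a directory of single-frame PNG/TIFF
#' images (taken in lexicographic filename order -- no timestamp parsing).
#' Colour input is converted to luminance (Rec. 601 weights); integer pixel
#' data are scaled to \eqn{[0, 1]} by the dtype maximum, not the per-sequence
#' maximum, so brightness changes between frames remain meaningful signal.
#'
#' @param path path to a multi-page TIFF file or a directory of frames.
#' @param normalize logical; kept for symmetry -- the underlying readers
#'   already deliver dtype-max-normalized values in \eqn{[0, 1]}.
#' @param frameRate,pixelSpacing optional acquisition metadata attached to
#'   the result.
#' @return an [ImageSequence-class] with frames in file order.
#' @seealso [writeSequence()], [cropSequence()]
#' @export
loadSequence <- function(path, normalize = TRUE, frameRate = NA_real_,
                         pixelSpacing = c(NA_real_, NA_real_)) {
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.(png|tif|tiff)$",
                             ignore.case = TRUE, full.names = TRUE))
    if (!length(files)) stop(sprintf("empty sequence: no frames in '%s'", path))
    frames <- lapply(files, .read_frame_file)
    names(frames) <- basename(files)
  } else if (file.exists(path)) {
    frames <- tiff::readTIFF(path, all = TRUE)
    if (is.matrix(frames) || (is.array(frames) && length(dim(frames)) <= 3L))
      frames <- list(frames)
    frames <- lapply(frames, .to_gray)
  } else stop(sprintf("no such file or directory: '%s'", path))
  if (length(frames) < 2L)
    stop("empty-sequence error: need at least 2 frames")
  dims <- lapply(frames, dim)
  bad <- which(!vapply(dims, identical, logical(1L), dims[[1L]]))
  if (length(bad)) {
    nm <- if (!is.null(names(frames))) names(frames)[bad[1L]] else bad[1L]
    stop(sprintf("congruence error: frame %s is %s, expected %s",
                 nm, paste(dims[[bad[1L]]], collapse = "x"),
                 paste(dims[[1L]], collapse = "x")))
  }
  imageSequence(frames, frameRate = frameRate, pixelSpacing = pixelSpacing)
}

#' Write a sequence as a multi-page 16-bit TIFF
#'
#' Frames are quantized to 16 bits; a sequence whose intensities already lie
#' on the 16-bit grid round-trips bit-exactly through
#' \code{loadSequence(writeSequence(...))}.
#'
#' @param seq an [ImageSequence-class].
#' @param path output file path (".tif").
#' @return \code{path}, invisibly.
#' @export
writeSequence <- function(seq, path) {
  stopifnot(is(seq, "ImageSequence"))
  pages <- lapply(seq_len(nFrames(seq)), function(i) getFrame(seq, i))
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  invisible(path)
}

#' Quantize intensities to the 16-bit grid
#'
#' Utility for constructing sequences that survive TIFF round trips exactly.
#' @param seq an [ImageSequence-class].
#' @param bits target bit depth; default 16.
#' @return an [ImageSequence-class] with intensities snapped to the
#'   \code{k / (2^bits - 1)} grid.
#' @export
quantizeSequence <- function(seq, bits = 16L) {
  mx <- 2^bits - 1
  initialize(seq, frames = round(seq@frames * mx) / mx)
}

#' Crop a sequence to a rectangular ROI
#'
#' A pure restriction: every output pixel equals the corresponding input
#' pixel; no values are altered.
#'
#' @param seq an [ImageSequence-class].
#' @param roi a [RoiRect-class] lying fully inside the frame bounds.
#' @return an [ImageSequence-class] of shape
#'   \code{(n_frames, roi height, roi width)}.
#' @export
cropSequence <- function(seq, roi) {
  stopifnot(is(seq, "ImageSequence"), is(roi, "RoiRect"))
  d <- frameDim(seq)
  if (roi@row0 + roi@height > d[1L] || roi@col0 + roi@width > d[2L])
    stop(sprintf(
      "bounds error: ROI %dx%d at (%d,%d) exceeds %dx%d frame",
      roi@height, roi@width, roi@row0, roi@col0, d[1L], d[2L]))
  rows <- roi@row0 + seq_len(roi@height)
  cols <- roi@col0 + seq_len(roi@width)
  initialize(seq, frames = seq@frames[, rows, cols, drop = FALSE])
}
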