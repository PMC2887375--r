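#' @include AllClasses.R wavelet.R
NULL

#' LoadingImage: a loading vector reconstructed into image space
#'
#' @slot component integer(1); model component the image belongs to.
#' @slot image numeric matrix of the original frame shape.
#' @seealso [reconstructLoadingImage()]
#' @export
setClass("LoadingImage",
  representation(component = "integer", image = "matrix"))

setMethod("show", "LoadingImage", function(object)
  cat(sprintf("LoadingImage: component %d, %d x %d px, |value| range [%.3g, %.3g]\n",
              object@component, nrow(object@image), ncol(object@image),
              min(abs(object@image)), max(abs(object@image)))))

#' Reconstruct a loading vector as an image
#'
#' Places each loading value at its (level, subband, row, col) coefficient
#' address in an otherwise-zero coefficient structure and applies the
#' inverse 2-D wavelet transform. The resulting spatial image shows which
#' image regions drive the component. Coefficients that were not retained
#' in the feature table carried no model information and are set to zero;
#' the loading image therefore visualises the model, not the full image
#' space.
#'
#' @param model a [PcaModel-class] fitted on \code{table}.
#' @param table the [FeatureTable-class] the model was fitted on; its index
#'   map must match the model's variable order.
#' @param component component index (1-based, <= k).
#' @return a [LoadingImage-class] with the original frame shape.
#' @examples
#' seq <- imageSequence(array(runif(4 * 32 * 32), c(4, 32, 32)))
#' ft <- buildFeatureTable(seq, waveletConfig("sym8", 2), nKeep = 64)
#' m <- fitPca(ft, k = 2)
#' li <- reconstructLoadingImage(m, ft, 1)
#' dim(li@image)
#' @export
reconstructLoadingImage <- function(model, table, component = 1L) {
  stopifnot(is(model, "PcaModel"), is(table, "FeatureTable"))
  if (component < 1L || component > model@k)
    stop(sprintf("component %d out of range (k = %d)", component, model@k))
  if (model@p != ncol(table@X))
    stop(sprintf(
      "congruence error: model has %d variables but table has %d columns",
      model@p, ncol(table@X)))
  full <- numeric(table@nTotal)
  full[table@indexMap$index] <- model@loadings[, component]
  img <- reconstructFrame(full, table@config, table@frameShape)
  new("LoadingImage", component = as.integer(component), image = img)
}

#' Fraction of a loading image's absolute mass inside a region
#'
#' Localization measure: the sum of absolute pixel values inside the ROI
#' (optionally dilated to absorb the spatial spread of the wavelet filters)
#' divided by the total absolute mass.
#'
#' @param li a [LoadingImage-class].
#' @param roi a [RoiRect-class] in frame coordinates.
#' @param dilation dilation radius in pixels applied to the ROI before
#'   measuring; a sensible choice is the wavelet filter support scaled by
#'   the decomposition depth, e.g.
#'   \code{(waveletFilterLength(basis) - 1) * 2^(levels - 1)}.
#' @return numeric(1) in [0, 1].
#' @export
energyFraction <- function(li, roi, dilation = 0L) {
  stopifnot(is(li, "LoadingImage"), is(roi, "RoiRect"))
  a <- abs(li@image)
  tot <- sum(a)
  if (tot == 0) return(0)
  r0 <- max(1L, roi@row0 + 1L - dilation)
  r1 <- min(nrow(a), roi@row0 + roi@height + dilation)
  c0 <- max(1L, roi@col0 + 1L - dilation)
  c1 <- min(ncol(a), roi@col0 + roi@width + dilation)
  sum(a[r0:r1, c0:c1]) / tot
}

#' Write a loading image as float TIFF plus a colormapped PNG
#'
#' The TIFF stores 32-bit float values mapped affinely to \eqn{[0, 1]}
#' (value 0.5 is a zero loading; the symmetric scale factor is the maximum
#' absolute loading pixel). The PNG is a presentation-only rendering on a
#' diverging blue-white-red scale around zero.
#'
#' @param li a [LoadingImage-class].
#' @param basePath output path without extension; ".tif" and ".png" are
#'   appended.
#' @return \code{basePath}, invisibly.
#' @export
writeLoadingImage <- function(li, basePath) {
  m <- li@image / max(1e-12, max(abs(li@image)))  # in [-1, 1]
  tiff::writeTIFF((m + 1) / 2, paste0(basePath, ".tif"),
                  bits.per.sample = 32L)
  pal <- grDevices::colorRampPalette(c("blue", "white", "red"))(255L)
  idx <- pmin(255L, pmax(1L, as.integer(round((m + 1) / 2 * 254)) + 1L))
  rgb <- grDevices::col2rgb(pal[idx]) / 255
  arr <- array(0, c(nrow(m), ncol(m), 3L))
  for (ch in 1:3) arr[, , ch] <- matrix(rgb[ch, ], nrow(m), ncol(m))
  png::writePNG(arr, paste0(basePath, ".png"))
  invisible(basePath)
}
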