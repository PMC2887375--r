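#' @include AllClasses.R AllGenerics.R imageSequence.R
NULL

# run expr with a private RNG state seeded from `seed`
.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Specify a synthetic speckle sequence
#'
#' Builds the full recipe for a simulated grayscale speckle sequence:
#' random point scatterers blurred with a Gaussian point-spread function
#' give speckle-like texture; a motion model displaces the scatterers with
#' subpixel accuracy per frame; Gaussian noise is added. Identical spec +
#' seed give a bit-identical sequence and ground truth.
#'
#' Motion models and their \code{motionParams}:
#' \describe{
#'   \item{translation}{\code{velocity}: numeric(2), (row, col) px/frame;
#'     every material point moves rigidly.}
#'   \item{depth_shear}{\code{amplitude}: numeric(nFrames) scalar profile
#'     in px (or \code{maxDisplacement} + \code{period} for a sinusoidal
#'     profile); \code{layerBoundaries}: rows delimiting tissue layers;
#'     \code{layerGains}: per-layer row-direction gain. Displacement of a
#'     point resting at row r is \code{amplitude[t] * gain(r)} downward --
#'     superficial layers move less than deep ones.}
#'   \item{cyclic_flexion}{\code{nReps}, \code{framesPerRep},
#'     \code{holdFrames}, \code{maxDisplacement}, \code{jitterSd} plus the
#'     layer fields: a concentric / hold / eccentric amplitude profile per
#'     repetition (linear ramps and a plateau), repeated with per-repetition
#'     amplitude jitter, driving the depth-shear field.}
#' }
#'
#' @param frameShape integer(2); default c(128, 128).
#' @param nFrames frame count; default 450.
#' @param motionModel one of \code{"translation"}, \code{"depth_shear"},
#'   \code{"cyclic_flexion"}.
#' @param motionParams list, see Details.
#' @param scattererDensity scatterers per pixel; default 0.08.
#' @param psfSigma Gaussian PSF sigma in px; default 1.2.
#' @param noiseSigma additive noise sd in intensity units; default 0.02.
#' @param seed RNG seed; fully determines the output.
#' @param frameRate metadata frame rate; default 78.6 fps (the acquisition
#'   rate the package's defaults are tuned to).
#' @return a [SyntheticSpec-class].
#' @seealso [renderSequence()], [heelRaisePreset()]
#' @export
syntheticSpec <- function(frameShape = c(128L, 128L), nFrames = 450L,
                          motionModel = "translation",
                          motionParams = list(velocity = c(0, 0)),
                          scattererDensity = 0.08, psfSigma = 1.2,
                          noiseSigma = 0.02, seed = 1L, frameRate = 78.6) {
  new("SyntheticSpec", frameShape = as.integer(frameShape),
      nFrames = as.integer(nFrames), scattererDensity = scattererDensity,
      psfSigma = psfSigma, motionModel = motionModel,
      motionParams = motionParams, noiseSigma = noiseSigma,
      seed = as.integer(seed), frameRate = frameRate)
}

setMethod("show", "SyntheticSpec", function(object)
  cat(sprintf(
    "SyntheticSpec: %d frames of %d x %d px, model '%s', noise sd %.3g, seed %d\n",
    object@nFrames, object@frameShape[1L], object@frameShape[2L],
    object@motionModel, object@noiseSigma, object@seed)))

# piecewise-constant layer gain per rest row
.layer_gain <- function(height, boundaries, gains) {
  if (is.null(boundaries)) boundaries <- round(height * c(1, 2) / 3)
  if (is.null(gains)) gains <- c(0.4, 0.7, 1.0)
  stopifnot(length(gains) == length(boundaries) + 1L)
  g <- numeric(height)
  lims <- c(0, boundaries, height)
  for (l in seq_along(gains))
    g[(lims[l] + 1):lims[l + 1L]] <- gains[l]
  g
}

# concentric / hold / eccentric amplitude profile for one repetition,
# 0 at both ends, 1 on the hold plateau
.rep_profile <- function(framesPerRep, holdFrames) {
  conc <- (framesPerRep - holdFrames) %/% 2L
  ecc <- framesPerRep - holdFrames - conc
  c(seq(0, 1, length.out = conc + 1L)[-1L], rep(1, holdFrames),
    seq(1, 0, length.out = ecc + 1L)[-1L])
}

# resolve the per-frame amplitude profile, phases and truth marks
.motion_profile <- function(spec) {
  mp <- spec@motionParams
  nT <- spec@nFrames
  switch(spec@motionModel,
    translation = list(
      amplitude = rep(0, nT), velocity = as.numeric(mp$velocity),
      phase = rep(if (all(mp$velocity == 0)) "static" else "constant", nT),
      repBoundaries = 1L, turningFrames = integer()),
    depth_shear = {
      amp <- if (!is.null(mp$amplitude)) {
        stopifnot(length(mp$amplitude) == nT)
        as.numeric(mp$amplitude)
      } else mp$maxDisplacement *
        (1 - cos(2 * pi * (seq_len(nT) - 1L) / mp$period)) / 2
      list(amplitude = amp, velocity = c(0, 0),
           phase = rep("constant", nT), repBoundaries = 1L,
           turningFrames = integer())
    },
    cyclic_flexion = {
      nReps <- mp$nReps
      fpr <- mp$framesPerRep
      hold <- if (is.null(mp$holdFrames)) 3L else as.integer(mp$holdFrames)
      stopifnot(nReps * fpr == nT)
      jit <- mp[["jitter"]]  # per-rep amplitude factors, drawn by renderSequence
      if (is.null(jit)) jit <- rep(1, nReps)
      prof <- .rep_profile(fpr, hold)
      conc <- (fpr - hold) %/% 2L
      amp <- as.numeric(mp$maxDisplacement *
                          unlist(lapply(jit, function(j) j * prof)))
      phase <- rep(rep(c("concentric", "hold", "eccentric"),
                       c(conc, hold, fpr - hold - conc)), nReps)
      phase[amp == 0] <- "rest"
      list(amplitude = amp, velocity = c(0, 0), phase = phase,
           repBoundaries = as.integer(seq(1L, by = fpr, length.out = nReps)),
           turningFrames = as.integer(
             (seq_len(nReps) - 1L) * fpr + conc + (hold + 1L) %/% 2L))
    },
    stop("unknown motion model"))
}

# separable Gaussian blur (truncated at 3 sigma); the NA rim left by the
# finite convolution support is confined to the padding margin and cropped
.gauss_blur <- function(m, sigma) {
  half <- max(1L, ceiling(3 * sigma))
  k <- exp(-(-half:half)^2 / (2 * sigma^2))
  k <- k / sum(k)
  b <- stats::filter(m, k, sides = 2)
  t(stats::filter(t(b), k, sides = 2))
}

#' Render a synthetic sequence with its ground truth
#'
#' Scatters random-amplitude point scatterers on a padded canvas, displaces
#' them per frame according to the motion model (bilinear splatting gives
#' subpixel accuracy), blurs with the Gaussian PSF, adds noise, crops the
#' padding and normalises the whole sequence by one global factor (so
#' brightness changes between frames remain meaningful). The returned
#' ground truth is consistent with the rendered frames by construction.
#'
#' @param spec a [SyntheticSpec-class].
#' @return list with \code{sequence} ([ImageSequence-class]) and
#'   \code{truth} ([GroundTruth-class]).
#' @examples
#' out <- renderSequence(syntheticSpec(frameShape = c(64, 64), nFrames = 5,
#'                                     motionParams = list(velocity = c(0.5, 0)),
#'                                     seed = 7))
#' out$sequence
#' @export
renderSequence <- function(spec) {
  stopifnot(is(spec, "SyntheticSpec"))
  # draw per-repetition jitter (part of the seeded randomness) before
  # resolving the profile
  .with_seed(spec@seed, {
    mp <- spec@motionParams
    if (spec@motionModel == "cyclic_flexion" && is.null(mp[["jitter"]])) {
      sd_ <- if (is.null(mp[["jitterSd"]])) 0 else mp[["jitterSd"]]
      mp$jitter <- pmax(0.2, 1 + stats::rnorm(mp$nReps, 0, sd_))
      spec@motionParams <- mp
    }
    prof <- .motion_profile(spec)
    h <- spec@frameShape[1L]; w <- spec@frameShape[2L]
    gain <- if (spec@motionModel == "translation") rep(1, h) else
      .layer_gain(h, mp$layerBoundaries, mp$layerGains)
    maxdisp <- max(abs(prof$amplitude)) * max(abs(gain)) +
      max(abs(prof$velocity)) * (spec@nFrames - 1L)
    margin <- ceiling(maxdisp) + ceiling(3 * spec@psfSigma) + 2L
    H <- h + 2L * margin; W <- w + 2L * margin
    nsc <- round(spec@scattererDensity * H * W)
    sr <- stats::runif(nsc, 1, H)  # rest positions on the padded canvas
    sc <- stats::runif(nsc, 1, W)
    amp0 <- stats::rexp(nsc)
    # gain is defined on visible rest rows; extend it across the padding
    gpad <- c(rep(gain[1L], margin), gain, rep(gain[length(gain)], margin))
    gsc <- gpad[pmin(H, pmax(1L, round(sr)))]
    frames <- array(0, c(spec@nFrames, h, w))
    vis <- margin + seq_len(h)
    visc <- margin + seq_len(w)
    for (t in seq_len(spec@nFrames)) {
      dr <- prof$amplitude[t] * gsc + prof$velocity[1L] * (t - 1L)
      dc <- prof$velocity[2L] * (t - 1L)
      r <- sr + dr; c_ <- sc + dc
      canvas <- matrix(0, H, W)
      r0 <- floor(r); c0 <- floor(c_)
      fr <- r - r0; fc <- c_ - c0
      for (q in 1:4) {
        rr <- r0 + (q > 2); cc <- c0 + (q %% 2L == 0L)
        wq <- (if (q > 2) fr else 1 - fr) * (if (q %% 2L == 0L) fc else 1 - fc)
        okq <- rr >= 1L & rr <= H & cc >= 1L & cc <= W
        if (any(okq)) {
          lin <- (cc[okq] - 1L) * H + rr[okq]
          agg <- rowsum(amp0[okq] * wq[okq], lin)
          canvas[as.integer(rownames(agg))] <-
            canvas[as.integer(rownames(agg))] + agg[, 1L]
        }
      }
      img <- .gauss_blur(canvas, spec@psfSigma)
      frames[t, , ] <- img[vis, visc]
    }
    sf <- max(frames)
    frames <- frames / (1.2 * sf)
    if (spec@noiseSigma > 0) {
      frames <- frames +
        array(stats::rnorm(length(frames), 0, spec@noiseSigma), dim(frames))
      frames <- array(pmin(1, pmax(0, frames)), dim(frames))
    }
    truth <- new("GroundTruth", amplitude = prof$amplitude, gain = gain,
                 velocity = prof$velocity, phase = prof$phase,
                 repBoundaries = prof$repBoundaries,
                 turningFrames = prof$turningFrames,
                 frameShape = spec@frameShape)
    list(sequence = imageSequence(frames, frameRate = spec@frameRate),
         truth = truth)
  })
}

#' Preset: repeated heel raises with depth-graded shear
#'
#' Emulates a functional heel-raise exercise: each repetition is a
#' concentric ramp, a short hold at the raised position and an eccentric
#' return, driving a depth-sheared displacement field in which superficial
#' tissue layers move less than deep ones (gains 0.4 / 0.7 / 1.0 over
#' three layers). Repetitions differ by a small random amplitude factor
#' (sd \code{jitterSd}). Ground truth holds the repetition boundaries and
#' one primary turning frame per repetition (the centre of the hold).
#'
#' @param nReps repetitions; default 3.
#' @param framesPerRep frames per repetition; default 150.
#' @param frameShape frame size; default c(128, 128).
#' @param maxDisplacement deep-layer peak displacement in px; default 6.
#' @param jitterSd sd of the per-repetition amplitude factor; default 0.1.
#' @param noiseSigma additive noise sd; default 0.02.
#' @param seed RNG seed.
#' @return a [SyntheticSpec-class].
#' @export
heelRaisePreset <- function(nReps = 3L, framesPerRep = 150L,
                            frameShape = c(128L, 128L), maxDisplacement = 6,
                            jitterSd = 0.1, noiseSigma = 0.02, seed = 1L) {
  syntheticSpec(
    frameShape = frameShape, nFrames = nReps * framesPerRep,
    motionModel = "cyclic_flexion",
    motionParams = list(nReps = as.integer(nReps),
                        framesPerRep = as.integer(framesPerRep),
                        holdFrames = 3L, maxDisplacement = maxDisplacement,
                        jitterSd = jitterSd),
    noiseSigma = noiseSigma, seed = seed)
}

#' @describeIn renderSequence dense (row, col) displacement field of one
#'   frame, indexed by rest position.
#' @param x a [GroundTruth-class].
#' @param frame frame index.
#' @export
setMethod("displacementField", "GroundTruth", function(x, frame) {
  h <- x@frameShape[1L]; w <- x@frameShape[2L]
  f <- array(0, c(h, w, 2L))
  f[, , 1L] <- x@amplitude[frame] * x@gain + x@velocity[1L] * (frame - 1L)
  f[, , 2L] <- x@velocity[2L] * (frame - 1L)
  f
})

#' @describeIn renderSequence mean absolute imposed displacement per frame.
#' @export
setMethod("meanDisplacement", "GroundTruth", function(x) {
  abs(x@amplitude) * mean(abs(x@gain)) +
    sqrt(sum(x@velocity^2)) * (seq_along(x@amplitude) - 1L)
})

setMethod("show", "GroundTruth", function(object)
  cat(sprintf(
    "GroundTruth: %d frames, %d repetition(s), turning frame(s): %s\n",
    length(object@amplitude), length(object@repBoundaries),
    if (length(object@turningFrames))
      paste(object@turningFrames, collapse = ", ") else "none")))

#' Write a synthetic sequence plus its ground truth to disk
#'
#' Multi-page 16-bit TIFF plus CSV (per-frame amplitude, phase) and JSON
#' (boundaries, turning frames, gains) ground-truth bundle.
#' @param rendered the list returned by [renderSequence()].
#' @param dir output directory.
#' @return \code{dir}, invisibly.
#' @export
writeSynthetic <- function(rendered, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeSequence(quantizeSequence(rendered$sequence),
                file.path(dir, "sequence.tif"))
  tr <- rendered$truth
  utils::write.csv(
    data.frame(frame = seq_along(tr@amplitude), amplitude = tr@amplitude,
               phase = tr@phase),
    file.path(dir, "truth_frames.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(repBoundaries = tr@repBoundaries, turningFrames = tr@turningFrames,
         gain = tr@gain, velocity = tr@velocity,
         frameShape = tr@frameShape),
    file.path(dir, "truth.json"), digits = NA, auto_unbox = TRUE)
  invisible(dir)
}
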