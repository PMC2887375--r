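#' @include AllClasses.R imageSequence.R wavelet.R pca.R trajectory.R
#' @include loadingImage.R tracking.R
NULL

.as_sequence <- function(input, frameRate = NA_real_,
                         pixelSpacing = c(NA_real_, NA_real_)) {
  if (is(input, "ImageSequence")) return(input)
  loadSequence(input, frameRate = frameRate, pixelSpacing = pixelSpacing)
}

#' Run the full congruent-image analysis of a sequence
#'
#' Orchestrates load (or accept) -> optional crop -> congruent wavelet
#' feature table -> NIPALS PCA -> trajectory analytics (turning points,
#' adjacent distances, optional repetition segmentation and similarity) ->
#' DModX -> loading images. With an output directory, writes scores,
#' loadings, DModX, distances and annotations as CSV, a score plot and
#' loading-image renderings, and a JSON run summary (including the
#' configuration, for provenance); outputs are deterministic functions of
#' the input and configuration.
#'
#' @param input an [ImageSequence-class], a multi-page TIFF path, or a
#'   frame directory.
#' @param roi optional [RoiRect-class] (or "row0,col0,height,width"
#'   string) to crop to before analysis.
#' @param config a [WaveletConfig-class]; depth is clamped to the frame
#'   size if needed.
#' @param nKeep retained coefficient count; default 3000.
#' @param k PCA components; default 2.
#' @param alpha DModX significance level; default 0.05.
#' @param smoothWindow,minSeparation turning-point parameters (frames).
#' @param turnMethod turning-point method; the pipeline defaults to
#'   \code{"dwell"} (direction reversal at low trajectory speed in the full
#'   score space), which stays reliable when large displacements bend the
#'   score trajectory; see [detectTurningPoints()].
#' @param segmentSmoothWindow smoothing window (frames) for repetition
#'   segmentation; default 15 (about 190 ms at 78.6 fps). Boundaries are
#'   single deep score valleys, so they tolerate -- and benefit from --
#'   heavier smoothing than turning-point detection.
#' @param nReps expected repetition count; if given, repetitions are
#'   segmented and their pairwise correlations computed.
#' @param outputDir optional directory for the result bundle.
#' @param frameRate,pixelSpacing metadata used when \code{input} is a path.
#' @return list with \code{sequence}, \code{featureTable}, \code{model},
#'   \code{trajectory}, \code{dmodx}, \code{distances},
#'   \code{turningPoints}, \code{segments} (or NULL),
#'   \code{repetitionCorrelation} (or NULL), \code{loadingImages} and
#'   \code{summary}.
#' @export
runMaci <- function(input, roi = NULL, config = waveletConfig(),
                    nKeep = 3000L, k = 2L, alpha = 0.05,
                    smoothWindow = 5L, minSeparation = 10L,
                    turnMethod = c("dwell", "extremum"),
                    segmentSmoothWindow = 15L, nReps = NULL,
                    outputDir = NULL, frameRate = NA_real_,
                    pixelSpacing = c(NA_real_, NA_real_)) {
  turnMethod <- match.arg(turnMethod)
  seq <- .as_sequence(input, frameRate, pixelSpacing)
  if (!is.null(roi)) {
    if (is.character(roi)) roi <- parseRoi(roi)
    seq <- cropSequence(seq, roi)
  }
  ft <- buildFeatureTable(seq, config, min(nKeep, prod(frameDim(seq))))
  model <- fitPca(ft, k = k)
  traj <- scoreTrajectory(model, frameRate = frameRate(seq))
  turns <- detectTurningPoints(traj, smoothWindow = smoothWindow,
                               minSeparation = minSeparation,
                               method = turnMethod)
  traj <- annotateTrajectory(traj, turns, "turn")
  dm <- dmodx(model, ft, alpha = alpha)
  dist <- adjacentDistances(traj)
  segs <- NULL; repcor <- NULL
  if (!is.null(nReps) && nReps >= 2L) {
    segs <- segmentRepetitions(traj, nReps,
                               smoothWindow = segmentSmoothWindow)
    traj <- annotateTrajectory(traj, segs@start[-1L], "rep_start")
    repcor <- repetitionCorrelation(traj, segs)
  }
  lis <- lapply(seq_len(model@k), function(a)
    reconstructLoadingImage(model, ft, a))
  summary <- list(
    nFrames = nFrames(seq), frameShape = frameDim(seq),
    basis = ft@config@basis, levels = ft@config@levels,
    nKeep = ncol(ft@X), k = model@k, r2x = model@r2x,
    r2xCum = sum(model@r2x), turningPoints = turns,
    nAboveDcrit = sum(dm@dmodx > dm@dcrit), dcrit = dm@dcrit,
    repetitionSegments = if (!is.null(segs))
      data.frame(start = segs@start, end = segs@end) else NULL,
    repetitionCorrelation = repcor)
  res <- list(sequence = seq, featureTable = ft, model = model,
              trajectory = traj, dmodx = dm, distances = dist,
              turningPoints = turns, segments = segs,
              repetitionCorrelation = repcor, loadingImages = lis,
              summary = summary)
  if (!is.null(outputDir)) .write_maci_bundle(res, outputDir)
  res
}

.write_maci_bundle <- function(res, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writePcaModel(res$model, dir)
  utils::write.csv(
    data.frame(frame = seq_along(res$dmodx@dmodx), dmodx = res$dmodx@dmodx),
    file.path(dir, "dmodx.csv"), row.names = FALSE)
  utils::write.csv(
    data.frame(frame = seq_along(res$distances),
               distance = res$distances),
    file.path(dir, "adjacent_distances.csv"), row.names = FALSE)
  writeAnnotations(res$trajectory, file.path(dir, "annotations.csv"))
  plotScoreTrajectory(res$trajectory, path = file.path(dir, "score_plot.png"))
  for (a in seq_along(res$loadingImages))
    writeLoadingImage(res$loadingImages[[a]],
                      file.path(dir, sprintf("loading_image_pc%d", a)))
  jsonlite::write_json(res$summary, file.path(dir, "summary.json"),
                       digits = NA, auto_unbox = TRUE)
  invisible(dir)
}

#' Run the reference speckle-tracking analysis of a sequence
#'
#' Segmented-ROI or whole-image grid tracking, with optional PCA of the
#' tracked coordinates and optional pennation-angle measurement from three
#' seed points. With an output directory, writes track and displacement
#' CSVs, displacement plots and a JSON summary.
#'
#' @param input sequence or path, as in [runMaci()].
#' @param mode \code{"roi"} (segmented ROI) or \code{"grid"}.
#' @param roi [RoiRect-class] or string, required for mode "roi".
#' @param nSegments bands for mode "roi"; default 5.
#' @param gridShape grid for mode "grid"; default c(12, 12).
#' @param doPca fit a PCA of the tracks (grid mode); default TRUE.
#' @param pennationSeeds optional 3 x 2 matrix of (row, col) seeds for a
#'   pennation-angle measurement.
#' @param k components for the track PCA.
#' @param outputDir optional output directory.
#' @param frameRate,pixelSpacing metadata used when \code{input} is a path.
#' @param ... tracking parameters passed to [trackPoints()].
#' @return list with \code{tracks} (or \code{displacementSeries}),
#'   \code{trackPca} (or NULL), \code{pennation} (or NULL) and
#'   \code{summary}.
#' @export
runTracking <- function(input, mode = c("grid", "roi"), roi = NULL,
                        nSegments = 5L, gridShape = c(12L, 12L),
                        doPca = TRUE, pennationSeeds = NULL, k = 2L,
                        outputDir = NULL, frameRate = NA_real_,
                        pixelSpacing = c(NA_real_, NA_real_), ...) {
  mode <- match.arg(mode)
  seq <- .as_sequence(input, frameRate, pixelSpacing)
  res <- list()
  if (mode == "roi") {
    if (is.null(roi)) stop("mode 'roi' needs an ROI")
    if (is.character(roi)) roi <- parseRoi(roi)
    ds <- trackSegmentedRoi(seq, roi, nSegments, ...)
    res$displacementSeries <- ds
    res$tracks <- ds@tracks
  } else {
    res$tracks <- trackGrid(seq, gridShape, ...)
  }
  if (doPca && mode == "grid")
    res$trackPca <- pcaOfTracks(res$tracks, k = k)
  if (!is.null(pennationSeeds)) {
    pts <- trackPoints(seq, pennationSeeds, ...)
    res$pennation <- pennationAngle(pts)
  }
  disp <- displacement(res$tracks, "px")
  res$summary <- list(
    mode = mode, nFrames = nFrames(seq), frameShape = frameDim(seq),
    nTracks = nrow(disp),
    nFullyValid = sum(rowSums(!res$tracks@valid) == 0L),
    maxAbsDisplacementPx = max(abs(disp)),
    r2x = if (!is.null(res$trackPca)) res$trackPca$model@r2x else NULL)
  if (!is.null(outputDir)) {
    dir.create(outputDir, showWarnings = FALSE, recursive = TRUE)
    writeTracks(res$tracks, file.path(outputDir, "tracks.csv"))
    if (!is.null(res$trackPca)) {
      writePcaModel(res$trackPca$model, file.path(outputDir, "track_pca"))
      plotScoreTrajectory(res$trackPca$trajectory,
                          path = file.path(outputDir, "track_score_plot.png"))
    }
    if (!is.null(res$pennation))
      utils::write.csv(
        data.frame(frame = seq_along(res$pennation@angle),
                   angle_deg = res$pennation@angle,
                   valid = res$pennation@valid),
        file.path(outputDir, "pennation.csv"), row.names = FALSE)
    .plot_displacement(disp, frameRate(seq),
                       file.path(outputDir, "displacement.png"))
    jsonlite::write_json(res$summary, file.path(outputDir, "summary.json"),
                         digits = NA, auto_unbox = TRUE)
  }
  res
}

.plot_displacement <- function(disp, fps, path) {
  grDevices::png(path, width = 900, height = 500)
  on.exit(grDevices::dev.off())
  x <- if (is.na(fps)) seq_len(ncol(disp)) else (seq_len(ncol(disp)) - 1) / fps
  graphics::matplot(x, t(disp), type = "l", lty = 1,
                    col = grDevices::hcl.colors(nrow(disp), "viridis"),
                    xlab = if (is.na(fps)) "frame" else "time (s)",
                    ylab = "transversal displacement (px)",
                    main = "Per-segment displacement")
  invisible(path)
}

#' Correlation between the two methods' score trajectories
#'
#' Operationalises the cross-method argument: the congruent-image score
#' trajectory and the track-PCA score trajectory of the same sequence
#' should describe the same movement. Reports the absolute Pearson
#' correlation between the chosen components (signs of PCA components are
#' arbitrary).
#'
#' @param trajA,trajB two [ScoreTrajectory-class] objects over the same
#'   frames.
#' @param component component index compared; default 1.
#' @return numeric(1) in [0, 1].
#' @export
crossMethodCorrelation <- function(trajA, trajB, component = 1L) {
  stopifnot(is(trajA, "ScoreTrajectory"), is(trajB, "ScoreTrajectory"))
  if (nrow(trajA@scores) != nrow(trajB@scores))
    stop("trajectories cover different frame counts")
  abs(stats::cor(trajA@scores[, component], trajB@scores[, component]))
}
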