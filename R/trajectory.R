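#' @include AllClasses.R AllGenerics.R
NULL

#' Construct a score trajectory
#'
#' Wraps a time-ordered score matrix (rows = frames in acquisition order)
#' for movement-phase analysis.
#'
#' @param scores numeric matrix (n_frames x k) or a [PcaModel-class] (its
#'   score matrix is taken).
#' @param frameRate frames per second (optional).
#' @return a [ScoreTrajectory-class].
#' @export
scoreTrajectory <- function(scores, frameRate = NA_real_) {
  if (is(scores, "PcaModel")) scores <- scores@scores
  stopifnot(is.matrix(scores))
  new("ScoreTrajectory", scores = scores, frameRate = as.numeric(frameRate))
}

setMethod("nFrames", "ScoreTrajectory", function(x) nrow(x@scores))
setMethod("frameRate", "ScoreTrajectory", function(x) x@frameRate)
setMethod("scores", "ScoreTrajectory", function(x) x@scores)

setMethod("show", "ScoreTrajectory", function(object) {
  cat(sprintf("ScoreTrajectory: %d frames x %d components\n",
              nrow(object@scores), ncol(object@scores)))
  if (nrow(object@annotations))
    cat(sprintf("  annotations: %s\n",
                paste(sprintf("%s@%d", object@annotations$label,
                              object@annotations$frame), collapse = ", ")))
})

# centred moving average with edge-shrunk windows (window odd)
.smooth_ma <- function(x, window) {
  if (window <= 1L) return(x)
  n <- length(x)
  hw <- window %/% 2L
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - hw, 1L)
  hi <- pmin(seq_len(n) + hw, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

.check_component <- function(traj, component) {
  if (component < 1L || component > ncol(traj@scores))
    stop(sprintf("component %d out of range (model has %d)",
                 component, ncol(traj@scores)))
}

#' Euclidean distances between adjacent frames in score space
#'
#' The tissue-dynamics measure: small distances mean similar adjacent
#' frames (hold phases, turning zones where the tissue dwells); large
#' distances mean rapid change (dynamic phases where the tissue is
#' compressed or stretched).
#'
#' @param traj a [ScoreTrajectory-class].
#' @return numeric(n - 1); \code{d[i]} is the distance between frames i and
#'   i + 1 over all k components.
#' @export
adjacentDistances <- function(traj) {
  stopifnot(is(traj, "ScoreTrajectory"))
  d <- diff(traj@scores)
  sqrt(rowSums(d^2))
}

# strict local extrema of a numeric vector; plateaus contribute their
# midpoint. Returns data.frame(frame, value, type)
.local_extrema <- function(s) {
  n <- length(s)
  d <- diff(s)
  nz <- which(d != 0)
  if (length(nz) < 2L)
    return(data.frame(frame = integer(), value = numeric(),
                      type = character()))
  res <- list()
  for (j in seq_len(length(nz) - 1L)) {
    i1 <- nz[j]; i2 <- nz[j + 1L]
    if (sign(d[i1]) != sign(d[i2])) {
      # extremum spans the (possibly flat) run (i1+1) .. i2; take midpoint
      f <- as.integer(floor((i1 + 1L + i2) / 2))
      res[[length(res) + 1L]] <- data.frame(
        frame = f, value = s[f],
        type = if (d[i1] > 0) "max" else "min")
    }
  }
  if (!length(res))
    return(data.frame(frame = integer(), value = numeric(),
                      type = character()))
  do.call(rbind, res)
}

#' Detect turning points of a movement in a score trajectory
#'
#' Two operationalizations of "the frames change direction in the score
#' plot":
#' \describe{
#'   \item{extremum}{smooths the chosen score with a centred moving
#'     average and returns the interior local extrema (strict sign changes
#'     of the first difference; plateau extrema are reported at their
#'     midpoint). Candidates closer than \code{minSeparation} frames are
#'     merged, keeping the one deviating most from the series median.
#'     Appropriate when the chosen score follows the movement
#'     monotonically.}
#'   \item{dwell}{works in the full k-dimensional score space: a turn is a
#'     run of low trajectory speed (smoothed adjacent-frame distance below
#'     the \code{speedQuantile} quantile) across which the travel
#'     direction reverses; the reported frame is the speed-weighted centre
#'     of the run. This exploits the observation that frames in turning
#'     phases are tethered (small adjacent distances) while the trajectory
#'     reverses, and stays reliable when large tissue displacement bends
#'     the trajectory so that no single component is monotone in the
#'     movement.}
#' }
#' Endpoints are never returned by either method.
#'
#' @param traj a [ScoreTrajectory-class] with >= 3 frames.
#' @param component score component for \code{method = "extremum"};
#'   default 1 (the component that separates plantar from dorsal flexion
#'   in the reference analyses).
#' @param smoothWindow centred moving-average window in frames; default 5
#'   (about 64 ms at 78.6 fps). Must be < n.
#' @param minSeparation minimum distance in frames between reported turns
#'   (and the gap that closes low-speed runs for \code{"dwell"}); default
#'   10.
#' @param method \code{"extremum"} (default) or \code{"dwell"}.
#' @param speedQuantile low-speed threshold quantile for \code{"dwell"};
#'   default 0.25.
#' @return integer vector of turning frames (1-based), increasing. The
#'   annotation can be attached to the trajectory with
#'   [annotateTrajectory()].
#' @examples
#' s <- sin(2 * pi * (1:300) / 100)
#' tp <- detectTurningPoints(scoreTrajectory(cbind(s, 0)))
#' tp  # near 25, 75, 125, ...
#' @export
detectTurningPoints <- function(traj, component = 1L, smoothWindow = 5L,
                                minSeparation = 10L,
                                method = c("extremum", "dwell"),
                                speedQuantile = 0.25) {
  stopifnot(is(traj, "ScoreTrajectory"))
  method <- match.arg(method)
  n <- nrow(traj@scores)
  if (n < 3L) stop("need at least 3 frames")
  if (smoothWindow >= n)
    stop(sprintf("parameter error: smoothWindow (%d) must be < n (%d)",
                 smoothWindow, n))
  if (method == "dwell")
    return(.dwell_turns(traj@scores, smoothWindow, minSeparation,
                        speedQuantile))
  .check_component(traj, component)
  s <- .smooth_ma(traj@scores[, component], smoothWindow)
  ex <- .local_extrema(s)
  if (is.null(ex) || !nrow(ex)) return(integer())
  ex <- ex[ex$frame > 1L & ex$frame < n, , drop = FALSE]
  if (!nrow(ex)) return(integer())
  med <- stats::median(s)
  kept <- ex[1L, , drop = FALSE]
  for (j in seq_len(nrow(ex))[-1L]) {
    last <- nrow(kept)
    if (ex$frame[j] - kept$frame[last] < minSeparation) {
      if (abs(ex$value[j] - med) > abs(kept$value[last] - med))
        kept[last, ] <- ex[j, ]
    } else kept <- rbind(kept, ex[j, ])
  }
  as.integer(kept$frame)
}

# dwell-and-reversal turning detection in the full score space
.dwell_turns <- function(S, smoothWindow, minSeparation, speedQuantile,
                         revWindow = 15L) {
  n <- nrow(S)
  Ssm <- apply(S, 2L, .smooth_ma, window = smoothWindow)
  v <- diff(Ssm)
  speed <- .smooth_ma(sqrt(rowSums(v^2)), smoothWindow)
  thr <- stats::quantile(speed, speedQuantile)
  low <- which(speed < thr)
  if (!length(low)) return(integer())
  runs <- split(low, cumsum(c(1, diff(low) > minSeparation)))
  res <- integer()
  for (r in runs) {
    f0 <- min(r); f1 <- max(r)
    if (f0 <= smoothWindow || f1 >= n - smoothWindow) next  # endpoint dwell
    pre <- colMeans(v[max(1L, f0 - revWindow):(f0 - 1L), , drop = FALSE])
    post <- colMeans(v[(f1 + 1L):min(n - 1L, f1 + revWindow), ,
                       drop = FALSE])
    if (sum(pre * post) < 0)
      res <- c(res, as.integer(round(
        stats::weighted.mean(r + 0.5, 1 / (speed[r] + 1e-9)))))
  }
  sort(res)
}

#' Attach phase annotations to a trajectory
#'
#' @param traj a [ScoreTrajectory-class].
#' @param frames integer vector of frame indices.
#' @param labels character vector (recycled) of labels.
#' @return the trajectory with rows appended to its annotations.
#' @export
annotateTrajectory <- function(traj, frames, labels = "turn") {
  ann <- rbind(traj@annotations,
               data.frame(frame = as.integer(frames),
                          label = rep_len(as.character(labels),
                                          length(frames))))
  initialize(traj, annotations = ann[order(ann$frame), , drop = FALSE])
}

# orient a score so that the movement baseline is at the bottom. A
# repetition starts and ends at rest, so the sequence endpoints sit at the
# baseline: flip the sign if their mean lies above the series median.
.orient_up <- function(s) {
  n <- length(s)
  w <- max(3L, n %/% 50L)
  base <- mean(s[c(seq_len(w), n - seq_len(w) + 1L)])
  if (base <= stats::median(s)) s else -s
}

#' Segment a trajectory into movement repetitions
#'
#' Operational definition: the chosen score is smoothed and
#' orientation-normalised (flipped if its dominant excursion from the
#' median points downward, so repetitions appear as peaks); the sequence is
#' then split at the \code{nReps - 1} deepest valleys (local minima) of
#' that signal, i.e. at the inter-repetition returns to baseline. Valleys
#' closer together than half a nominal repetition length
#' (\code{n / (2 nReps)}) are not both used.
#'
#' @param traj a [ScoreTrajectory-class].
#' @param nReps expected number of repetitions (>= 1).
#' @param component score component; default 1.
#' @param smoothWindow smoothing window in frames; default 5.
#' @param method \code{"valley"} (default): boundaries at the deepest
#'   valleys of the orientation-normalised smoothed score;
#'   \code{"dwell"}: boundaries at the baseline-side dwell-and-reversal
#'   points of the full score trajectory (see [detectTurningPoints()]),
#'   which localises better when large displacements bend the trajectory.
#' @return a [RepetitionSegments-class] with \code{nReps} ordered half-open
#'   intervals covering the sequence.
#' @export
segmentRepetitions <- function(traj, nReps, component = 1L,
                               smoothWindow = 5L,
                               method = c("valley", "dwell")) {
  stopifnot(is(traj, "ScoreTrajectory"), nReps >= 1L)
  method <- match.arg(method)
  n <- nrow(traj@scores)
  if (nReps == 1L)
    return(new("RepetitionSegments", start = 1L, end = n + 1L,
               nFrames = as.integer(n)))
  .check_component(traj, component)
  minSep <- n / (2 * nReps)
  s <- .orient_up(.smooth_ma(traj@scores[, component], smoothWindow))
  if (method == "dwell") {
    tp <- .dwell_turns(traj@scores, smoothWindow, 10L, 0.25)
    cand <- tp[tp >= minSep & tp <= n - minSep]
    # baseline-side reversals have a low oriented score
    cand <- cand[order(s[cand])]
    chosen <- integer()
    for (f in cand) {
      if (length(chosen) == nReps - 1L) break
      if (!length(chosen) || all(abs(chosen - f) >= minSep))
        chosen <- c(chosen, f)
    }
    if (length(chosen) == nReps - 1L) {
      b <- sort(chosen)
      return(new("RepetitionSegments", start = c(1L, b), end = c(b, n + 1L),
                 nFrames = as.integer(n)))
    }
    # not enough reversal points: fall through to the valley rule
  }
  ex <- .local_extrema(s)
  # a boundary cannot sit closer to either end than half a repetition
  valleys <- ex[ex$type == "min" & ex$frame >= minSep &
                  ex$frame <= n - minSep, , drop = FALSE]
  # greedily take valleys by depth, enforcing separation
  valleys <- valleys[order(valleys$value), , drop = FALSE]
  chosen <- integer()
  for (f in valleys$frame) {
    if (length(chosen) == nReps - 1L) break
    if (!length(chosen) || all(abs(chosen - f) >= minSep))
      chosen <- c(chosen, f)
  }
  if (length(chosen) < nReps - 1L)
    stop(sprintf(
      "segmentation error: found %d usable valleys but %d repetitions need %d boundaries; supply boundaries manually",
      length(chosen), nReps, nReps - 1L))
  b <- sort(chosen)
  new("RepetitionSegments", start = c(1L, b), end = c(b, n + 1L),
      nFrames = as.integer(n))
}

#' Construct repetition segments from explicit boundaries
#'
#' @param start,end integer vectors of half-open intervals [start, end).
#' @param nFrames sequence length.
#' @return a [RepetitionSegments-class].
#' @export
repetitionSegments <- function(start, end, nFrames)
  new("RepetitionSegments", start = as.integer(start), end = as.integer(end),
      nFrames = as.integer(nFrames))

setMethod("show", "RepetitionSegments", function(object)
  cat(sprintf("RepetitionSegments: %d segment(s) over %d frames: %s\n",
              length(object@start), object@nFrames,
              paste(sprintf("[%d,%d)", object@start, object@end),
                    collapse = " "))))

#' Pairwise similarity of movement repetitions
#'
#' Each repetition's chosen score is linearly resampled to a common length
#' (repetitions may differ in duration), then Pearson correlations are
#' computed for all pairs. By the affine invariance of correlation, the
#' measure compares repetition shape, not amplitude.
#'
#' @param traj a [ScoreTrajectory-class].
#' @param segs a [RepetitionSegments-class] with >= 2 segments of length
#'   >= 3.
#' @param component score component; default 1.
#' @param resampleLen number of resampling points; default 100.
#' @return symmetric correlation matrix with unit diagonal.
#' @export
repetitionCorrelation <- function(traj, segs, component = 1L,
                                  resampleLen = 100L) {
  stopifnot(is(traj, "ScoreTrajectory"), is(segs, "RepetitionSegments"))
  .check_component(traj, component)
  m <- length(segs@start)
  if (m < 2L) stop("need at least 2 segments")
  s <- traj@scores[, component]
  res <- matrix(NA_real_, m, m)
  curves <- vector("list", m)
  for (i in seq_len(m)) {
    idx <- segs@start[i]:(segs@end[i] - 1L)
    if (length(idx) < 3L)
      stop(sprintf("segment %d has fewer than 3 frames", i))
    seg <- s[idx]
    if (stats::sd(seg) == 0)
      stop(sprintf(
        "undefined-correlation error: segment %d is constant", i))
    curves[[i]] <- stats::approx(seq_along(seg), seg,
                                 n = resampleLen)$y
  }
  for (i in seq_len(m)) for (j in seq_len(m))
    res[i, j] <- stats::cor(curves[[i]], curves[[j]])
  diag(res) <- 1
  res
}

#' Export trajectory annotations and segments as CSV
#'
#' @param traj a [ScoreTrajectory-class].
#' @param path CSV output path.
#' @return \code{path}, invisibly. Columns: frame_index, time_s (NA without
#'   a frame rate), label.
#' @export
writeAnnotations <- function(traj, path) {
  a <- traj@annotations
  t_s <- if (is.na(traj@frameRate)) rep(NA_real_, nrow(a)) else
    (a$frame - 1L) / traj@frameRate
  utils::write.csv(
    data.frame(frame_index = a$frame, time_s = t_s, label = a$label),
    path, row.names = FALSE)
  invisible(path)
}

#' Render a score plot (t2 vs t1) with the movement trajectory
#'
#' Presentation helper: draws the frame-ordered trajectory in the plane of
#' two components, with optional phase annotations marked.
#' @param traj a [ScoreTrajectory-class].
#' @param components length-2 integer; default c(1, 2).
#' @param path optional PNG output path; if NULL, draws on the active
#'   device.
#' @return \code{path} (or NULL), invisibly.
#' @export
plotScoreTrajectory <- function(traj, components = c(1L, 2L), path = NULL) {
  s <- traj@scores
  stopifnot(max(components) <= ncol(s))
  if (!is.null(path)) {
    grDevices::png(path, width = 800, height = 800)
    on.exit(grDevices::dev.off())
  }
  x <- s[, components[1L]]; y <- s[, components[2L]]
  graphics::plot(x, y, type = "l", col = "grey60",
                 xlab = sprintf("t%d", components[1L]),
                 ylab = sprintf("t%d", components[2L]),
                 main = "Score trajectory")
  graphics::points(x, y, pch = 16, cex = 0.4,
                   col = grDevices::hcl.colors(length(x), "viridis"))
  a <- traj@annotations
  if (nrow(a)) {
    graphics::points(x[a$frame], y[a$frame], pch = 4, cex = 1.4, lwd = 2,
                     col = "red")
    graphics::text(x[a$frame], y[a$frame], a$label, pos = 3, col = "red")
  }
  invisible(path)
}
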