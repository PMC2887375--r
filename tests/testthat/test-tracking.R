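# shared tracking fixtures
static_seq <- function() fixture("static_seq", function()
  speckle_seq(n = 10, shape = c(96L, 96L), seed = 55))

translating_seq <- function() fixture("translating_seq", function()
  renderSequence(syntheticSpec(
    frameShape = c(96L, 96L), nFrames = 20, motionModel = "translation",
    motionParams = list(velocity = c(1.5, 0)), noiseSigma = 0, seed = 56)))

test_that("a static speckle scene tracks to zero displacement", {
  ts <- trackPoints(static_seq(), cbind(c(30, 50, 70), c(48, 48, 48)))
  expect_true(all(ts@valid))
  expect_lt(max(abs(displacement(ts))), 0.05)
  # first-frame positions equal the seeded layout
  expect_equal(ts@positions[, 1, ], cbind(c(30, 50, 70), c(48, 48, 48)))
})

test_that("rigid translation is recovered within a quarter pixel", {
  out <- translating_seq()
  ts <- trackPoints(out$sequence, cbind(c(20, 35), c(48, 48)))
  truth <- 1.5 * (0:19)
  expect_true(all(ts@valid))
  expect_lt(max(abs(sweep(displacement(ts), 2, truth))), 0.25)
})

test_that("a track driven past the border is flagged invalid and stays so", {
  out <- translating_seq()  # +1.5 rows/frame, 20 frames
  ts <- trackPoints(out$sequence, cbind(c(70, 30), c(48, 48)))
  expect_false(all(ts@valid[1, ]))          # exits the bottom
  expect_true(all(ts@valid[2, ]))
  bad <- which(!ts@valid[1, ])
  expect_identical(bad, min(bad):nFrames(ts))  # sticky invalidity
  # frozen position stays finite
  expect_true(all(is.finite(ts@positions)))
})

test_that("a textureless patch is rejected for lack of gradient information", {
  arr <- array(0.5, c(4, 64, 64))
  set.seed(2)
  arr[, 40:60, 40:60] <- array(runif(4 * 21 * 21), c(4, 21, 21))
  seq <- imageSequence(arr)
  ts <- trackPoints(seq, cbind(c(15, 50), c(15, 50)))
  expect_false(any(ts@valid[1, -1]))  # flat corner
  expect_true(all(ts@valid[2, ]))     # textured patch
})

test_that("tracking the reversed sequence closes the loop (forward-backward)", {
  out <- translating_seq()
  seeds <- cbind(c(20, 40), c(40, 56))
  fwd <- trackPoints(out$sequence, seeds)
  rev_seq <- imageSequence(out$sequence@frames[nFrames(out$sequence):1, , ])
  bwd <- trackPoints(rev_seq, fwd@positions[, nFrames(fwd), ])
  drift <- abs(bwd@positions[, nFrames(bwd), ] - seeds)
  expect_lt(max(drift), 0.5)
})

test_that("empty or out-of-frame seeds are rejected", {
  seq <- static_seq()
  expect_error(trackPoints(seq, matrix(numeric(), 0, 2)), "empty seed")
  expect_error(trackPoints(seq, cbind(500, 48)), "inside the frame")
  expect_error(trackPoints(seq, cbind(30, 48), window = 20), "odd")
})

test_that("segmented ROI tracking reports per-band transversal displacement", {
  out <- renderSequence(syntheticSpec(
    frameShape = c(96L, 64L), nFrames = 15, motionModel = "depth_shear",
    motionParams = list(amplitude = seq(0, 4, length.out = 15),
                        layerBoundaries = c(32L, 64L),
                        layerGains = c(0.3, 0.6, 1.0)),
    noiseSigma = 0, seed = 57))
  roi <- roiRect(20, 24, 60, 12)  # tall ROI crossing the layers
  ds <- trackSegmentedRoi(out$sequence, roi, nSegments = 5)
  d <- displacement(ds)
  expect_identical(dim(d), c(5L, 15L))
  expect_equal(d[, 1], rep(0, 5))
  # depth-graded shear: deeper segments move more, matching the imposed
  # gradient within 10%
  final <- d[, 15]
  expect_true(all(diff(final) >= -0.05))
  centres <- 20 + (seq_len(5) - 0.5) / 5 * 60 + 0.5
  gain <- c(0.3, 0.6, 1.0)[findInterval(centres, c(0, 32, 64)) ]
  expect_lt(max(abs(final - 4 * gain)), 0.1 * 4 + 0.25)
})

test_that("static segmented ROI gives a flat zero series", {
  ds <- trackSegmentedRoi(static_seq(), roiRect(20, 30, 50, 10),
                          nSegments = 3)
  expect_lt(max(abs(displacement(ds))), 0.05)
})

test_that("mm conversion uses the pixel spacing and fails without one", {
  seq0 <- translating_seq()$sequence
  seq_mm <- imageSequence(seq0@frames, pixelSpacing = c(0.5, 0.5))
  ts <- trackPoints(seq_mm, cbind(20, 48))
  expect_equal(displacement(ts, "mm"), displacement(ts, "px") * 0.5)
  ts0 <- trackPoints(seq0, cbind(20, 48))
  expect_error(displacement(ts0, "mm"), "pixel spacing")
})

test_that("grid seeding is equidistant, bounded and validated", {
  seq <- static_seq()
  tg <- trackGrid(seq, c(4, 5))
  expect_identical(dim(tg@positions)[1], 20L)
  expect_identical(tg@gridShape, c(4L, 5L))
  pos0 <- tg@positions[, 1, ]
  expect_true(all(pos0[, 1] >= 11 & pos0[, 1] <= 86))
  expect_equal(length(unique(round(pos0[, 1], 6))), 4L)
  expect_error(trackGrid(seq, c(200, 200)), "parameter error")
})

test_that("grid tracking a rigid translation recovers it for every track", {
  out <- translating_seq()
  tg <- trackGrid(out$sequence, c(4, 4))
  truth <- 1.5 * (0:19)
  ok <- rowSums(!tg@valid) == 0
  expect_gt(sum(ok), 0)
  expect_lt(max(abs(sweep(displacement(tg)[ok, , drop = FALSE], 2, truth))),
            0.25)
})

test_that("PCA of rigidly translating tracks is essentially rank 1", {
  out <- translating_seq()
  tg <- trackGrid(out$sequence, c(4, 4))
  tp <- pcaOfTracks(tg, k = 2)
  expect_gt(tp$model@r2x[1], 0.99)
  expect_identical(nrow(scores(tp$trajectory)), 20L)
})

test_that("PCA of tracks rejects a static scene as degenerate", {
  tg <- trackGrid(static_seq(), c(3, 3))
  expect_error(pcaOfTracks(tg), "degenerate")
})

test_that("pennation angle: right angle, collinear and oracle agreement", {
  expect_equal(pennationAngle(cbind(0, 1), cbind(0, 0), cbind(1, 0))@angle, 90)
  expect_equal(pennationAngle(cbind(0, -1), cbind(0, 0), cbind(0, 1))@angle,
               180)
  expect_equal(pennationAngle(cbind(0, 2), cbind(0, 0), cbind(0, 1))@angle, 0)
  set.seed(64)
  for (i in 1:25) {
    p <- matrix(rnorm(6), 3, 2)
    got <- pennationAngle(p[1, , drop = FALSE], p[2, , drop = FALSE],
                          p[3, , drop = FALSE])@angle
    # independent oracle: difference of atan2 bearings, folded to [0, 180]
    a1 <- atan2(p[1, 1] - p[2, 1], p[1, 2] - p[2, 2])
    a2 <- atan2(p[3, 1] - p[2, 1], p[3, 2] - p[2, 2])
    ref <- abs((a1 - a2) * 180 / pi) %% 360
    if (ref > 180) ref <- 360 - ref
    expect_lt(abs(got - ref), 1e-9)
  }
})

test_that("pennation angle is invariant under rotation and scaling", {
  set.seed(65)
  p <- matrix(rnorm(6), 3, 2)
  base <- pennationAngle(p[1, , drop = FALSE], p[2, , drop = FALSE],
                         p[3, , drop = FALSE])@angle
  th <- 1.1
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  q <- 3.7 * p %*% R
  got <- pennationAngle(q[1, , drop = FALSE], q[2, , drop = FALSE],
                        q[3, , drop = FALSE])@angle
  expect_equal(got, base, tolerance = 1e-9)
})

test_that("zero-length arms are flagged undefined per frame", {
  p1 <- rbind(c(0, 1), c(0, 0))
  p2 <- rbind(c(0, 0), c(0, 0))
  p3 <- rbind(c(1, 0), c(1, 0))
  ps <- pennationAngle(p1, p2, p3)
  expect_equal(ps@angle[1], 90)
  expect_true(is.na(ps@angle[2]))
  expect_identical(ps@valid, c(TRUE, FALSE))
})

test_that("tracks export to CSV with displacement columns", {
  ts <- trackPoints(static_seq(), cbind(c(30, 50), c(48, 48)))
  path <- file.path(withr::local_tempdir(), "tracks.csv")
  writeTracks(ts, path)
  x <- utils::read.csv(path)
  expect_identical(nrow(x), 2L * 10L)
  expect_true(all(c("roi_id", "frame", "row", "col", "valid", "disp_px")
                  %in% names(x)))
})
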