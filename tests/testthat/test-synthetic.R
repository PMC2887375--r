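test_that("identical spec and seed give bit-identical output", {
  spec <- syntheticSpec(frameShape = c(48L, 48L), nFrames = 6,
                        motionModel = "translation",
                        motionParams = list(velocity = c(0.7, 0.2)),
                        noiseSigma = 0.02, seed = 99)
  a <- renderSequence(spec)
  b <- renderSequence(spec)
  expect_identical(a$sequence@frames, b$sequence@frames)
  expect_identical(a$truth@amplitude, b$truth@amplitude)
  # a different seed gives different speckle
  c_ <- renderSequence(syntheticSpec(frameShape = c(48L, 48L), nFrames = 6,
                                     motionModel = "translation",
                                     motionParams = list(velocity = c(0.7, 0.2)),
                                     noiseSigma = 0.02, seed = 100))
  expect_false(identical(a$sequence@frames, c_$sequence@frames))
})

test_that("rendering does not disturb the caller's RNG stream", {
  set.seed(123)
  before <- runif(3)
  set.seed(123)
  invisible(renderSequence(syntheticSpec(frameShape = c(32L, 32L),
                                         nFrames = 3, seed = 5)))
  after <- runif(3)
  expect_identical(before, after)
})

test_that("zero motion and zero noise give identical frames", {
  out <- renderSequence(syntheticSpec(
    frameShape = c(48L, 48L), nFrames = 5, motionModel = "translation",
    motionParams = list(velocity = c(0, 0)), noiseSigma = 0, seed = 7))
  f1 <- getFrame(out$sequence, 1)
  for (i in 2:5) expect_identical(getFrame(out$sequence, i), f1)
  expect_true(all(meanDisplacement(out$truth) == 0))
})

test_that("pure translation shows up at the right phase-correlation offset", {
  out <- renderSequence(syntheticSpec(
    frameShape = c(64L, 64L), nFrames = 4, motionModel = "translation",
    motionParams = list(velocity = c(3, 0)), noiseSigma = 0, seed = 8))
  f1 <- getFrame(out$sequence, 1)
  for (t in 2:4) {
    ft_ <- getFrame(out$sequence, t)
    # FFT cross-correlation oracle: peak at the circular offset (3(t-1), 0)
    X <- fft(f1 - mean(f1)) * Conj(fft(ft_ - mean(ft_)))
    cc <- Re(fft(X, inverse = TRUE))
    peak <- which(cc == max(cc), arr.ind = TRUE)[1, ]
    offset <- (peak - 1)  # 0-based circular lag of f1 relative to ft_
    offset <- ifelse(offset > 32, offset - 64, offset)
    expect_equal(unname(offset), c(-3 * (t - 1), 0))
  }
})

test_that("the dense displacement field matches amplitude times depth gain", {
  out <- renderSequence(syntheticSpec(
    frameShape = c(48L, 32L), nFrames = 6, motionModel = "depth_shear",
    motionParams = list(amplitude = seq(0, 2, length.out = 6),
                        layerBoundaries = 24L, layerGains = c(0.5, 1)),
    noiseSigma = 0, seed = 9))
  fld <- displacementField(out$truth, 6)
  expect_identical(dim(fld), c(48L, 32L, 2L))
  expect_equal(fld[1, 1, 1], 2 * 0.5)
  expect_equal(fld[48, 1, 1], 2 * 1.0)
  expect_true(all(fld[, , 2] == 0))
})

test_that("the heel-raise preset carries consistent ground truth", {
  spec <- heelRaisePreset(nReps = 3, framesPerRep = 40,
                          frameShape = c(64L, 64L), seed = 10)
  out <- renderSequence(spec)
  tr <- out$truth
  expect_identical(tr@repBoundaries, c(1L, 41L, 81L))
  expect_identical(length(tr@turningFrames), 3L)
  # turning frames sit at the hold-plateau centres
  expect_true(all(tr@amplitude[tr@turningFrames] ==
                    vapply(1:3, function(r)
                      max(tr@amplitude[(r - 1) * 40 + 1:40]), 0)))
  # profile returns to rest at each boundary
  expect_true(all(tr@amplitude[c(40, 80, 120)] == 0))
  expect_setequal(unique(tr@phase),
                  c("rest", "concentric", "hold", "eccentric"))
  # superficial layers move less than deep ones
  expect_true(tr@gain[1] < tr@gain[64])
  # single repetition spans the whole sequence
  one <- renderSequence(heelRaisePreset(nReps = 1, framesPerRep = 40,
                                        frameShape = c(64L, 64L), seed = 10))
  expect_identical(one$truth@repBoundaries, 1L)
})

test_that("zero jitter repeats the amplitude profile exactly", {
  out <- renderSequence(heelRaisePreset(nReps = 3, framesPerRep = 30,
                                        frameShape = c(64L, 64L),
                                        jitterSd = 0, seed = 12))
  a <- out$truth@amplitude
  expect_identical(a[1:30], a[31:60])
  expect_identical(a[1:30], a[61:90])
})

test_that("tracking recovers the imposed depth-shear warp (consistency)", {
  out <- renderSequence(syntheticSpec(
    frameShape = c(96L, 64L), nFrames = 10, motionModel = "depth_shear",
    motionParams = list(amplitude = seq(0, 3, length.out = 10)),
    noiseSigma = 0, seed = 13))
  seeds <- cbind(c(20, 80), c(32, 32))   # superficial and deep points
  ts <- trackPoints(out$sequence, seeds)
  d <- displacement(ts)
  truth <- outer(out$truth@gain[c(20, 80)], out$truth@amplitude)
  expect_lt(max(abs(d - truth)), 0.25)
})

test_that("a synthetic bundle writes sequence plus truth files", {
  dir <- withr::local_tempdir()
  out <- renderSequence(syntheticSpec(frameShape = c(32L, 32L), nFrames = 3,
                                      seed = 14))
  writeSynthetic(out, dir)
  expect_true(file.exists(file.path(dir, "sequence.tif")))
  truth <- jsonlite::read_json(file.path(dir, "truth.json"),
                               simplifyVector = TRUE)
  expect_identical(truth$frameShape, c(32L, 32L))
  frames <- utils::read.csv(file.path(dir, "truth_frames.csv"))
  expect_identical(nrow(frames), 3L)
})

test_that("displacements exceeding the frame raise a spec error early", {
  expect_error(syntheticSpec(frameShape = c(8L, 4L)), "8 x 8")
  expect_error(syntheticSpec(nFrames = 1), "at least 2")
})
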