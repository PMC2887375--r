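test_that("adjacent distances are Euclidean norms of score differences", {
  traj <- scoreTrajectory(cbind(c(0, 3, 3), c(0, 4, 4)))
  expect_equal(adjacentDistances(traj), c(5, 0))
  # constant scores give all-zero distances
  expect_equal(adjacentDistances(scoreTrajectory(matrix(1, 5, 2))),
               rep(0, 4))
})

test_that("adjacent distances are invariant to score-space rotation", {
  set.seed(4)
  S <- matrix(rnorm(40 * 3), 40, 3)
  theta <- 0.7
  R1 <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  d0 <- adjacentDistances(scoreTrajectory(S))
  d1 <- adjacentDistances(scoreTrajectory(S %*% R1))
  expect_equal(d0, d1, tolerance = 1e-10)
})

test_that("turning points of a sinusoid sit at the analytic extrema", {
  s <- sin(2 * pi * (1:300) / 100)
  tp <- detectTurningPoints(scoreTrajectory(cbind(s, 0)),
                            smoothWindow = 5, minSeparation = 20)
  # closed-form extrema of sin(2 pi t / 100): t = 25, 75, 125, ...
  truth <- seq(25, 275, by = 50)
  expect_equal(length(tp), length(truth))
  expect_true(all(abs(tp - truth) <= 2))
})

test_that("a monotone score has no turning points", {
  tp <- detectTurningPoints(scoreTrajectory(cbind(seq_len(50), 0)))
  expect_identical(tp, integer())
})

test_that("turning detection validates its parameters", {
  traj <- scoreTrajectory(cbind(rnorm(10), 0))
  expect_error(detectTurningPoints(traj, smoothWindow = 10), "parameter error")
  expect_error(detectTurningPoints(traj, component = 5), "out of range")
})

test_that("dwell method finds turns of a noisy out-and-back trajectory", {
  set.seed(12)
  # two smooth out-and-back cycles along a curved 2-D path, with noise
  amp <- (1 - cos(2 * pi * (1:200) / 100)) / 2  # peaks 50, 150; valley 100
  S <- cbind(3 * amp, 0.5 * amp^2) + matrix(rnorm(400, 0, 0.02), ncol = 2)
  tp <- detectTurningPoints(scoreTrajectory(S), smoothWindow = 5,
                            minSeparation = 15, method = "dwell")
  expect_true(all(vapply(c(50, 100, 150),
                         function(f) any(abs(tp - f) <= 4), logical(1))))
})

test_that("one repetition spans the whole sequence", {
  segs <- segmentRepetitions(scoreTrajectory(cbind(rnorm(30), 0)), 1)
  expect_identical(segs@start, 1L)
  expect_identical(segs@end, 31L)
})

test_that("segmentation recovers concatenated cycle boundaries", {
  # three identical 1 - cos cycles: rest level at the cycle joints
  cyc <- 1 - cos(2 * pi * (0:99) / 100)
  s <- rep(cyc, 3)
  segs <- segmentRepetitions(scoreTrajectory(cbind(s, 0)), 3)
  expect_identical(length(segs@start), 3L)
  expect_true(all(abs(segs@start - c(1, 101, 201)) <= 2))
  # orientation invariance: a flipped score gives the same boundaries
  segs2 <- segmentRepetitions(scoreTrajectory(cbind(-s, 0)), 3)
  expect_equal(segs@start, segs2@start, tolerance = 2)
})

test_that("segmentation fails gracefully without enough valleys", {
  s <- seq(0, 1, length.out = 60)
  expect_error(segmentRepetitions(scoreTrajectory(cbind(s, 0)), 4),
               "segmentation error")
})

test_that("repetition correlations: identical, negated and affine-rescaled segments", {
  cyc <- sin(2 * pi * (0:49) / 50)
  traj <- scoreTrajectory(cbind(c(cyc, cyc, -cyc), 0))
  segs <- repetitionSegments(c(1, 51, 101), c(51, 101, 151), 150)
  R <- repetitionCorrelation(traj, segs)
  expect_equal(diag(R), rep(1, 3))
  expect_equal(R[1, 2], 1, tolerance = 1e-10)
  expect_equal(R[1, 3], -1, tolerance = 1e-10)
  expect_equal(R, t(R))
  # affine invariance: rescaling one segment's score leaves R unchanged
  traj2 <- scoreTrajectory(cbind(c(cyc, 5 * cyc + 2, -cyc), 0))
  expect_equal(repetitionCorrelation(traj2, segs), R, tolerance = 1e-10)
})

test_that("repetition correlation handles unequal segment lengths by resampling", {
  a <- sin(2 * pi * (0:59) / 60)
  b <- sin(2 * pi * (0:89) / 90)  # same shape, different duration
  traj <- scoreTrajectory(cbind(c(a, b), 0))
  segs <- repetitionSegments(c(1, 61), c(61, 151), 150)
  R <- repetitionCorrelation(traj, segs)
  expect_gt(R[1, 2], 0.999)
})

test_that("a constant segment raises an undefined-correlation error", {
  traj <- scoreTrajectory(cbind(c(rep(0, 20), rnorm(20)), 0))
  segs <- repetitionSegments(c(1, 21), c(21, 41), 40)
  expect_error(repetitionCorrelation(traj, segs), "undefined-correlation")
})

test_that("annotations are attached, ordered and exported", {
  traj <- scoreTrajectory(cbind(rnorm(20), rnorm(20)), frameRate = 10)
  traj <- annotateTrajectory(traj, c(15, 3), "turn")
  expect_equal(traj@annotations$frame, c(3L, 15L))
  path <- file.path(withr::local_tempdir(), "ann.csv")
  writeAnnotations(traj, path)
  x <- utils::read.csv(path)
  expect_equal(x$time_s, c(0.2, 1.4))
  expect_error(annotateTrajectory(traj, 99), "out of range")
})
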