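test_that("single-level decomposition matches the frozen external oracle", {
  fx <- pywt_fixture()
  dec <- decomposeFrame(fx$frame, waveletConfig("db2", 1))
  m <- dec$indexMap
  band <- function(sb) matrix(dec$coeffs[m$subband == sb], 4, 4, byrow = TRUE)
  expect_lt(max(abs(band("approx") - fx$cA)), 1e-10)
  expect_lt(max(abs(band("horiz") - fx$cH)), 1e-10)
  expect_lt(max(abs(band("vert") - fx$cV)), 1e-10)
  expect_lt(max(abs(band("diag") - fx$cD)), 1e-10)
})

test_that("decompose + inverse reconstructs frames to machine precision", {
  set.seed(11)
  for (case in list(list(basis = "sym8", levels = 3L, shape = c(64L, 64L)),
                    list(basis = "db4", levels = 2L, shape = c(48L, 32L)),
                    list(basis = "haar", levels = 4L, shape = c(32L, 32L)))) {
    f <- matrix(runif(prod(case$shape)), case$shape[1L], case$shape[2L])
    cfg <- waveletConfig(case$basis, case$levels)
    dec <- decomposeFrame(f, cfg)
    rec <- reconstructFrame(dec$coeffs, cfg, case$shape)
    expect_lt(max(abs(rec - f)), 1e-8)
    # orthogonality: energy is preserved
    expect_lt(abs(sum(dec$coeffs^2) - sum(f^2)), 1e-8 * sum(f^2))
  }
})

test_that("an all-zero frame gives an all-zero coefficient vector", {
  dec <- decomposeFrame(matrix(0, 32, 32), waveletConfig("sym8", 2))
  expect_true(all(dec$coeffs == 0))
})

test_that("frames of equal shape share an identical index map", {
  cfg <- waveletConfig("sym8", 2)
  a <- decomposeFrame(matrix(runif(32 * 32), 32, 32), cfg)
  b <- decomposeFrame(matrix(runif(32 * 32), 32, 32), cfg)
  expect_identical(a$indexMap, b$indexMap)
  expect_false(anyDuplicated(a$indexMap$index) > 0)
  expect_identical(nrow(a$indexMap), 32L * 32L)
})

test_that("infeasible decomposition depth raises a config error", {
  expect_error(decomposeFrame(matrix(0, 8, 8), waveletConfig("sym8", 4)),
               "config error")
  expect_error(decomposeFrame(matrix(0, 9, 8), waveletConfig("sym8", 1)),
               "config error")
  expect_identical(maxFeasibleLevels(c(96L, 96L)), 5L)
  expect_identical(maxFeasibleLevels(c(9L, 8L)), 0L)
})

test_that("variance selection retains exactly the brute-force top-K", {
  set.seed(42)
  seq <- imageSequence(array(runif(20 * 32 * 32), c(20, 32, 32)))
  cfg <- waveletConfig("sym8", 2)
  # brute-force oracle: decompose all frames, full variance vector, sort
  C <- t(vapply(1:20, function(i) decomposeFrame(getFrame(seq, i), cfg)$coeffs,
                numeric(32 * 32)))
  vars <- apply(C, 2, var)
  for (K in c(1L, 10L, 32L * 32L)) {
    ft <- buildFeatureTable(seq, cfg, nKeep = K)
    oracle <- order(vars, decreasing = TRUE)[seq_len(K)]
    expect_setequal(ft@indexMap$index, oracle)
    # descending-variance order with ties by index
    expect_false(is.unsorted(rev(ft@variances)))
    expect_equal(ft@variances, vars[ft@indexMap$index], tolerance = 1e-12)
    expect_equal(unname(ft@X), unname(C[, ft@indexMap$index, drop = FALSE]),
                 tolerance = 1e-12)
  }
})

test_that("identical frames give zero variance and constant columns", {
  f <- matrix(runif(32 * 32), 32, 32)
  seq <- imageSequence(array(rep(f, each = 5), c(5, 32, 32)))
  ft <- buildFeatureTable(seq, waveletConfig("sym8", 2), nKeep = 10)
  expect_true(all(ft@variances < 1e-20))
  expect_true(all(apply(ft@X, 2, function(x) diff(range(x))) < 1e-10))
})

test_that("permuting frame order permutes table rows and nothing else", {
  set.seed(7)
  arr <- array(runif(8 * 32 * 32), c(8, 32, 32))
  perm <- sample(8)
  cfg <- waveletConfig("sym8", 2)
  ft1 <- buildFeatureTable(imageSequence(arr), cfg, nKeep = 50)
  ft2 <- buildFeatureTable(imageSequence(arr[perm, , ]), cfg, nKeep = 50)
  expect_identical(ft1@indexMap, ft2@indexMap)
  expect_equal(ft1@X[perm, ], ft2@X, tolerance = 1e-12)
})

test_that("global intensity offsets concentrate variance in the approximation band", {
  base <- matrix(runif(64 * 64, 0.2, 0.6), 64, 64)
  offs <- seq(0, 0.3, length.out = 6)
  arr <- array(0, c(6, 64, 64))
  for (i in 1:6) arr[i, , ] <- base + offs[i]
  ft <- buildFeatureTable(imageSequence(arr), waveletConfig("sym8", 3),
                          nKeep = 50)
  expect_true(mean(ft@indexMap$subband == "approx") > 0.9)
})

test_that("nKeep outside [1, total] raises a size error", {
  seq <- imageSequence(array(runif(3 * 16 * 16), c(3, 16, 16)))
  expect_error(buildFeatureTable(seq, waveletConfig("haar", 2), 16 * 16 + 1),
               "size error")
  expect_error(buildFeatureTable(seq, waveletConfig("haar", 2), 0), "size error")
})

test_that("feature tables serialize to CSV + JSON sidecar", {
  seq <- imageSequence(array(runif(3 * 16 * 16), c(3, 16, 16)))
  ft <- buildFeatureTable(seq, waveletConfig("haar", 2), 20)
  path <- file.path(withr::local_tempdir(), "table.csv")
  writeFeatureTable(ft, path)
  expect_true(file.exists(path))
  expect_true(file.exists(sub("csv$", "json", path)))
  x <- utils::read.csv(path)
  expect_equal(unname(as.matrix(x)), unname(ft@X), tolerance = 1e-6)
  side <- jsonlite::read_json(sub("csv$", "json", path),
                              simplifyVector = TRUE)
  expect_identical(side$config$basis, "haar")
  expect_equal(side$indexMap$index, ft@indexMap$index)
})
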