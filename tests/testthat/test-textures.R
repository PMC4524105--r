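test_that("first-order features match hand arithmetic and handle degenerate windows", {
  f <- firstOrderFeatures(1:9)
  expect_equal(unname(f["mean"]), 5)
  expect_equal(unname(f["std"]), sqrt(mean((1:9 - 5)^2)), tolerance = 1e-12)
  expect_equal(unname(f["std"]), 2.582, tolerance = 1e-3)
  expect_equal(unname(firstOrderFeatures(rep(7, 9))),
               c(7, 0, 0, 0))
  # Monte-Carlo sanity on N(0,1)
  set.seed(2)
  g <- firstOrderFeatures(rnorm(1e4))
  expect_lt(abs(g["skewness"]), 0.1)
  expect_lt(abs(g["kurtosis"]), 0.2)
})

test_that("GLCM features match the spelled-out small cases", {
  chk <- matrix(c(0, 1, 1, 0), 2, 2)  # checkerboard
  f <- glcmFeatures(chk, directions = 0)
  expect_equal(unname(f["contrast/d0"]), 1)
  expect_equal(unname(f["energy/d0"]), 0.5)
  expect_equal(unname(f["maximum_probability/d0"]), 0.5)
  const <- matrix(5, 4, 4)
  g <- glcmFeatures(const)
  for (ang in c(0, 45, 90, 135)) {
    expect_equal(unname(g[paste0("contrast/d", ang)]), 0)
    expect_equal(unname(g[paste0("energy/d", ang)]), 1)
    expect_equal(unname(g[paste0("correlation/d", ang)]), 0)
    expect_equal(unname(g[paste0("entropy/d", ang)]), 0)
  }
})

test_that("all 18 GLCM statistics equal the literal-formula oracle on random patches", {
  dirs <- list(c(0, 1), c(-1, 1), c(-1, 0), c(-1, -1))
  set.seed(99)
  for (rep in 1:25) {
    L <- sample(4:16, 1)
    patch <- matrix(sample.int(L, 81, replace = TRUE), 9, 9)
    patch[1, 1] <- 1L; patch[2, 1] <- L  # pin the level range
    f <- glcmFeatures(patch, levels = L)
    for (d in 1:4) {
      P <- oracleGlcm(patch, L, dirs[[d]][1], dirs[[d]][2])
      want <- oracleGlcmStats(P)
      ang <- c(0, 45, 90, 135)[d]
      got <- f[paste0(names(want), "/d", ang)]
      expect_equal(unname(got), unname(want), tolerance = 1e-10)
    }
  }
})

test_that("Gabor responses vanish on zero input, prefer matched gratings, and permute under rotation", {
  z <- matrix(0, 32, 32)
  expect_equal(unname(gaborFeatures(z)), rep(0, 12), tolerance = 1e-10)

  # horizontal grating at a tuned frequency: the matched orientation wins
  f0 <- 0.25
  x <- matrix(rep(seq_len(48), each = 48), 48, 48)  # varies along columns
  grating <- sin(2 * pi * f0 * x)
  resp <- gaborFeatures(grating, frequencies = f0)
  expect_gt(resp["f0.25/o0"], resp["f0.25/o90"])

  # rotating the image by 90 degrees permutes orientation channels
  set.seed(5)
  img <- matrix(rnorm(32 * 32), 32, 32)
  rot <- t(img)[32:1, ]  # 90-degree rotation
  a <- gaborFeatures(img)
  b <- gaborFeatures(rot)
  for (f in c(0.1, 0.25, 0.4)) {
    expect_equal(unname(b[paste0("f", f, "/o90")]),
                 unname(a[paste0("f", f, "/o0")]), tolerance = 1e-6)
    expect_equal(unname(b[paste0("f", f, "/o135")]),
                 unname(a[paste0("f", f, "/o45")]), tolerance = 1e-6)
  }
})

test_that("Kirsch features are zero on constants, edge-selective, and offset-invariant", {
  expect_equal(unname(kirschFeatures(matrix(3, 8, 8))), rep(0, 8),
               tolerance = 1e-12)
  # vertical step edge: east/west channels dominate
  step <- cbind(matrix(0, 8, 4), matrix(1, 8, 4))
  f <- kirschFeatures(step)
  expect_equal(sort(names(sort(f, decreasing = TRUE))[1:2]), c("E", "W"))
  # non-negative and invariant to adding a constant
  set.seed(8)
  img <- matrix(rnorm(64), 8, 8)
  expect_true(all(kirschFeatures(img) >= 0))
  expect_equal(kirschFeatures(img + 100), kirschFeatures(img),
               tolerance = 1e-9)
})

test_that("extraction yields exactly 96 provenance-named features per modality", {
  cfg <- tinyConfig(noiseSigma = 5)
  st <- deriveModalities(generateStudy(cfg, 1))
  fm <- extractFeatures(st, "ADC", stride = 3)
  fn <- featureNames(fm)
  expect_length(fn, 96)
  expect_false(anyDuplicated(fn) > 0)
  fam <- sub("^[^/]+/([^/]+)/.*$", "\\1", fn)
  expect_equal(as.integer(table(fam)[c("firstorder", "glcm", "gabor", "kirsch")]),
               c(4L, 72L, 12L, 8L))
  # 18 GLCM features in each of the four directions
  for (ang in c(0, 45, 90, 135))
    expect_length(grep(paste0("/d", ang, "$"), fn), 18)
  # two modalities concatenate to 192 columns in canonical order
  fm2 <- extractFeatures(st, c("ADC", "T2w"), stride = 3)
  expect_length(featureNames(fm2), 192)
  expect_equal(unique(sub("/.*", "", featureNames(fm2))), c("T2w", "ADC"))
})

test_that("window labels come from the centre voxel and samples stay inside the gland", {
  cfg <- phantomConfig(nPatients = 2, gridShape = c(32, 32, 8),
                       tumourFraction = 0.015,
                       lesionCountProbs = c(0, 0.5, 0.5), seed = 21)
  st <- deriveModalities(generateStudy(cfg, 1))
  fm <- extractFeatures(st, "ADC", stride = 1)
  co <- sampleCoords(fm)
  expect_true(all(glandMask(st)[co]))
  expect_identical(unname(sampleLabels(fm) == "cancer"),
                   unname(tumourMask(st)[co]))
  frac <- mean(sampleLabels(fm) == "cancer")
  expect_gt(frac, 0.003); expect_lt(frac, 0.06)
  expect_false(anyNA(featureValues(fm)))
  # deterministic re-extraction
  expect_identical(featureValues(extractFeatures(st, "ADC", stride = 1)),
                   featureValues(fm))
})

test_that("features stay finite on degenerate windows (constant, zero, single bright pixel)", {
  mk <- function(slice) {
    arr <- array(rep(slice, 2), c(nrow(slice), ncol(slice), 2))
    q <- mpmrad:::quantizeMinMax(arr, range(arr), 16L)
    cppRes <- mpmrad:::cppSlidingTexture(slice, q[, , 1],
                                         rep(3:6, each = 4), rep(3:6, 4),
                                         1L, 16L)
    expect_true(all(is.finite(cppRes)))
    expect_true(all(is.finite(gaborFeatures(slice))))
    expect_true(all(is.finite(kirschFeatures(slice))))
  }
  mk(matrix(7, 8, 8))
  mk(matrix(0, 8, 8))
  bright <- matrix(0, 8, 8); bright[4, 4] <- 1
  mk(bright)
})
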