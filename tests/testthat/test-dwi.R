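test_that("ADC log-linear fit is exact on noiseless mono-exponential data", {
  s <- toySeries(s0 = 1000, d = 0.0018)
  mask <- array(TRUE, dim(bVolumes(s)[[1]]))
  fit <- fitADC(s, mask)
  expect_lt(max(abs(imageData(fit$adc) - 0.0018)) / 0.0018, 1e-6)
  expect_lt(max(abs(imageData(fit$s0) - 1000)) / 1000, 1e-6)
  # the closed-form curve at each acquired b-value
  expect_equal(1000 * exp(-c(0, 100, 400, 1000) * 0.0018),
               c(1000, 835.2702, 486.7523, 165.2989), tolerance = 1e-6)
})

test_that("constant signal across b fits D = 0, S0 = the constant", {
  b <- c(0, 100, 400, 1000)
  vols <- lapply(b, function(bb) array(700, c(8, 8, 2)))
  s <- new("DwiSeries", bValues = b, volumes = vols, spacing = c(1, 1, 1))
  fit <- fitADC(s, array(TRUE, c(8, 8, 2)))
  expect_equal(unique(as.numeric(imageData(fit$adc))), 0)
  expect_equal(unique(as.numeric(imageData(fit$s0))), 700, tolerance = 1e-9)
})

test_that("all-zero masked voxels give D = S0 = 0 with a warning; noisy fit is accurate", {
  b <- c(0, 100, 400, 1000)
  vols <- lapply(b, function(bb) array(1000 * exp(-bb * 0.0018), c(8, 8, 1)))
  for (k in seq_along(vols)) vols[[k]][1, 1, 1] <- 0
  s <- new("DwiSeries", bValues = b, volumes = vols, spacing = c(1, 1, 1))
  expect_warning(fit <- fitADC(s, array(TRUE, c(8, 8, 1))), "all-zero")
  expect_equal(imageData(fit$adc)[1, 1, 1], 0)
  expect_equal(imageData(fit$s0)[1, 1, 1], 0)
  expect_equal(attr(imageData(fit$adc), "nDegenerate"), 1L)

  # Monte-Carlo: Rician noise sigma = 5 on S0 = 1000, 500 voxels
  set.seed(42)
  shape <- c(25, 20, 1)
  noisy <- lapply(b, function(bb)
    mpmrad:::ricianNoise(array(1000 * exp(-bb * 0.0018), shape), 5))
  sn <- new("DwiSeries", bValues = b, volumes = noisy, spacing = c(1, 1, 1))
  fitN <- fitADC(sn, array(TRUE, shape))
  expect_lt(abs(stats::median(imageData(fitN$adc)) - 0.0018) / 0.0018, 0.05)
})

test_that("CHB-DWI extrapolates the fitted decay and rejects non-extrapolating targets", {
  shape <- c(8, 8, 2)
  mask <- array(TRUE, shape)
  tum <- toySeries(shape, s0 = 1000, d = 0.0006)
  hea <- toySeries(shape, s0 = 1000, d = 0.0018)
  chbT <- imageData(computeCHBDWI(tum, mask, 2000))[1]
  chbH <- imageData(computeCHBDWI(hea, mask, 2000))[1]
  expect_equal(chbT, 1000 * exp(-1.2), tolerance = 1e-6)  # ~301.2
  expect_equal(chbH, 1000 * exp(-3.6), tolerance = 1e-6)  # ~27.3
  # contrast amplification vs the acquired b = 1000 image
  ratio2000 <- chbT / chbH
  ratio1000 <- exp(-1000 * 0.0006) / exp(-1000 * 0.0018)
  expect_equal(ratio2000, exp(2000 * 0.0012), tolerance = 1e-9)  # ~11.0
  expect_gt(ratio2000, ratio1000)                                # 11.0 > 3.3
  # D = 0: output equals S0 for any target
  flat <- toySeries(shape, s0 = 800, d = 0)
  expect_equal(imageData(computeCHBDWI(flat, mask, 5000))[1], 800,
               tolerance = 1e-6)
  expect_error(computeCHBDWI(tum, mask, 1000), "must exceed")
  # monotone decreasing in D at fixed S0 and target
  ds <- c(0.0004, 0.0008, 0.0012, 0.0016)
  vals <- vapply(ds, function(d)
    imageData(computeCHBDWI(toySeries(shape, 1000, d), mask, 2000))[1],
    numeric(1))
  expect_true(all(diff(vals) < 0))
})

test_that("CDI single-voxel product and uniform-volume invariance hold", {
  s <- toySeries(c(8, 8, 2), s0 = 1000, d = 0.0018)
  mask <- array(TRUE, c(8, 8, 2))
  cdi0 <- computeCDI(s, mask, 0, rescale = FALSE)
  expected <- prod(1000 * exp(-c(0, 100, 400, 1000) * 0.0018))
  expect_equal(imageData(cdi0)[3, 3, 1], expected, tolerance = 1e-9)
  expect_equal(expected / 1e10, 6.7206, tolerance = 1e-4)
  # uniform volume: constant output, invariant to the subvolume radius
  for (r in list(0, 1, c(2, 2, 1))) {
    v <- imageData(computeCDI(s, mask, r, rescale = FALSE))
    expect_equal(max(v) - min(v), 0, tolerance = 1e-6 * expected)
  }
})

test_that("sliding CDI equals the literal triple-loop oracle everywhere", {
  set.seed(31)
  shape <- c(5, 5, 1)
  b <- c(0, 100, 400, 1000)
  vols <- lapply(b, function(bb) array(runif(prod(shape), 100, 1000), shape))
  s <- new("DwiSeries", bValues = b, volumes = vols, spacing = c(1, 1, 1))
  mask <- array(TRUE, shape)
  for (r in list(c(0, 0, 0), c(1, 1, 0), c(2, 1, 0))) {
    got <- imageData(computeCDI(s, mask, r, rescale = FALSE))
    want <- oracleCdi(vols, r)
    expect_equal(got, want, tolerance = 1e-9)
  }
})

test_that("CDI highlights tumour more strongly than ADC on a noisy phantom", {
  cfg <- phantomConfig(nPatients = 2, gridShape = c(32, 32, 8),
                       noiseSigma = 10, lesionCountProbs = c(0, 1, 0),
                       seed = 19)
  st <- deriveModalities(generateStudy(cfg, 1))
  gland <- glandMask(st); tumour <- tumourMask(st)
  healthy <- gland & !tumour
  cdi <- imageData(computeCDI(dwiSeries(st), gland, rescale = FALSE))
  adc <- imageData(derivedVolumes(st)$ADC)
  b4 <- bVolumes(dwiSeries(st))[[4]]
  expect_gt(mean(cdi[tumour]), mean(cdi[healthy]))  # bright nodule
  expect_lt(mean(adc[tumour]), mean(adc[healthy]))  # dark on ADC
  # mean-ratio contrast: the multiplicative signal mixing amplifies the
  # tumour/healthy separation beyond any single acquired b-value image
  # and beyond the ADC ratio
  ratio <- function(v) mean(v[tumour]) / mean(v[healthy])
  expect_gt(ratio(cdi), ratio(b4))
  expect_gt(ratio(cdi), 1 / ratio(adc))  # ADC is dark in tumour
})

test_that("derived modalities are pure functions of the study (deterministic, non-negative)", {
  cfg <- tinyConfig(noiseSigma = 8)
  st <- generateStudy(cfg, 2)
  d1 <- deriveModalities(st)
  d2 <- deriveModalities(st)
  expect_identical(derivedVolumes(d1), derivedVolumes(d2))
  gland <- glandMask(st)
  for (nm in c("ADC", "CHB-DWI", "CDI")) {
    v <- imageData(derivedVolumes(d1)[[nm]])[gland]
    expect_true(all(is.finite(v)))
    expect_true(all(v >= 0))
  }
})
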