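test_that("mutual information matches identity, independence and brute-force cases", {
  x <- rep(0:1, each = 500)
  expect_equal(mutualInformation(x, x), 1, tolerance = 1e-9)  # H = 1 bit
  expect_gte(mutualInformation(x, x), mutualInformation(x, rev(x)))
  # independent permuted copy: plug-in MI stays near zero
  set.seed(4)
  a <- rnorm(1e4); b <- sample(a)
  expect_lt(mutualInformation(a, b), 0.02)
  # constant column
  expect_equal(mutualInformation(rep(1, 100), rnorm(100)), 0)
  # 8-sample brute-force joint-histogram oracle
  xs <- c(1, 1, 2, 2, 3, 3, 1, 2)
  ys <- c(1, 2, 1, 2, 2, 2, 1, 1)
  expect_equal(mutualInformation(xs, ys), oracleMi(xs, ys), tolerance = 1e-12)
  # MI(X;X) = H(X) >= MI(X;Y), MI >= 0
  set.seed(9)
  for (r in 1:20) {
    u <- rnorm(300); v <- rnorm(300) + 0.5 * u
    expect_gte(mutualInformation(u, u), mutualInformation(u, v) - 1e-12)
    expect_gte(mutualInformation(u, v), 0)
  }
})

test_that("mRMR demotes duplicated features and tops the ranking with max marginal MI", {
  set.seed(6)
  n <- 1000
  lab <- factor(rep(c("healthy", "cancer"), each = n / 2),
                levels = c("healthy", "cancer"))
  f1 <- as.numeric(lab == "cancer") + rnorm(n, sd = 0.05)
  x <- cbind(f1 = f1, f2 = f1, f3 = rnorm(n))
  fm <- new("TextureFeatureMatrix", values = x, labels = lab,
            patientIds = rep(c("A", "B"), n / 2),
            coords = matrix(1L, n, 3, dimnames = list(NULL, c("x", "y", "z"))))
  r <- mrmrRank(fm)
  expect_equal(r[1], "f1")          # tie with f2 broken lexicographically
  expect_equal(r[2], "f3")          # redundancy penalty demotes the copy
  expect_equal(r[3], "f2")
  expect_setequal(r, colnames(x))   # a permutation, no inventions
  # single feature
  expect_equal(mrmrRank(subsetFeatures(fm, "f3")), "f3")
  # first ranked = argmax of independently computed marginal MI
  set.seed(7)
  for (rep in 1:10) {
    y <- matrix(rnorm(200 * 5), 200, 5,
                dimnames = list(NULL, paste0("v", 1:5)))
    lab2 <- factor(ifelse(y[, 3] + 0.8 * rnorm(200) > 0, "cancer", "healthy"),
                   levels = c("healthy", "cancer"))
    mi <- apply(y, 2, mutualInformation, y = lab2)
    fm2 <- new("TextureFeatureMatrix", values = y, labels = lab2,
               patientIds = rep(c("A", "B"), 100),
               coords = matrix(1L, 200, 3,
                               dimnames = list(NULL, c("x", "y", "z"))))
    expect_equal(mrmrRank(fm2, maxM = 1), names(which.max(mi)))
  }
  expect_error(mrmrRank(matrix(rnorm(40), 10), labels = rep("a", 10)),
               "binary")
})

test_that("duplicated columns never displace the underlying signals from the top", {
  set.seed(12)
  n <- 600
  lab <- factor(ifelse(runif(n) < 0.3, "cancer", "healthy"),
                levels = c("healthy", "cancer"))
  base <- cbind(s1 = as.numeric(lab == "cancer") * 2 + rnorm(n, sd = 0.4),
                s2 = as.numeric(lab == "cancer") + rnorm(n, sd = 0.6),
                n1 = rnorm(n), n2 = rnorm(n))
  dup <- cbind(base, s1copy = base[, "s1"], s2copy = base[, "s2"])
  mk <- function(x) new("TextureFeatureMatrix", values = x, labels = lab,
                        patientIds = rep(c("A", "B"), n / 2),
                        coords = matrix(1L, n, 3,
                                        dimnames = list(NULL, c("x", "y", "z"))))
  top2 <- function(r) sub("copy$", "", r[1:2])
  expect_setequal(top2(mrmrRank(mk(base))), c("s1", "s2"))
  expect_setequal(top2(mrmrRank(mk(dup))), c("s1", "s2"))
})

test_that("criterion-driven size selection recovers a planted informative subset", {
  fm <- syntheticTable(n = 600, nInformative = 10, nNoise = 90,
                       nPatients = 12, effect = 3, sd = 0.8, seed = 13)
  sel <- selectBestM(fm, "auc", mGrid = seq(10, 100, by = 10), seed = 1)
  expect_s4_class(sel, "SelectionResult")
  expect_lte(bestM(sel), 30)
  # score within 0.05 of using exactly the 10 informative features
  informative <- grep("^ADC/sig", featureNames(fm), value = TRUE)
  oracleScore <- mpmrad:::cvScore(fm, informative, seed = 1)["auc"]
  expect_gte(max(scoreCurve(sel)$auc), oracleScore - 0.05)
  # structural contracts
  expect_identical(bestSubset(sel),
                   rankedFeatures(sel)[seq_len(bestM(sel))])
  expect_equal(nrow(scoreCurve(sel)), 10)
  # bestM attains the curve maximum up to the parsimony tolerance, and
  # no smaller m on the grid does
  curve <- scoreCurve(sel)
  atBest <- curve$score[match(bestM(sel), curve$m)]
  expect_gte(atBest, max(curve$score) - 0.01)
  smaller <- curve$score[curve$m < bestM(sel)]
  if (length(smaller)) expect_true(all(smaller < max(curve$score) - 0.01))
  # single-candidate grid returns everything
  sel1 <- selectBestM(fm, "auc", mGrid = 100, seed = 1)
  expect_identical(bestSubset(sel1), rankedFeatures(sel1))
})

test_that("selection runs are deterministic and criterion switching changes the outcome shape", {
  fm <- syntheticTable(n = 500, nInformative = 4, nNoise = 16,
                       nPatients = 10, effect = 1.2, sd = 1, seed = 14)
  g <- c(5, 10, 20)
  sSens <- selectBestM(fm, "sensitivity", mGrid = g, seed = 2)
  sSens2 <- selectBestM(fm, "sensitivity", mGrid = g, seed = 2)
  expect_identical(scoreCurve(sSens), scoreCurve(sSens2))
  sSpec <- selectBestM(fm, "specificity", mGrid = g, seed = 2)
  # both valid; operating points differ by construction of the policy
  curveS <- scoreCurve(sSens); curveP <- scoreCurve(sSpec)
  expect_gte(mean(curveS$sensitivity), mean(curveP$sensitivity) - 0.02)
  expect_gte(mean(curveP$specificity), mean(curveS$specificity) - 0.02)
  # evaluator failure carries the offending m
  bad <- function(fm, subset, seed) stop("boom")
  expect_error(selectBestM(fm, "auc", mGrid = 5, evaluator = bad),
               "failed at m = 5")
})
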