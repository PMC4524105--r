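# Independent brute-force oracles and tiny fixture builders. These are
# deliberately literal (explicit loops, plug-in formulas) so they share
# no code with the package implementations they check.

# noiseless mono-exponential DWI series on a small grid
toySeries <- function(shape = c(8, 8, 4), s0 = 1000, d = 0.0018,
                      b = c(0, 100, 400, 1000)) {
  vols <- lapply(b, function(bb) array(s0 * exp(-bb * d), shape))
  new("DwiSeries", bValues = b, volumes = vols, spacing = c(1.56, 1.56, 3))
}

# GLCM oracle: literal loops over pixel pairs, then plug-in statistics
# straight from the definitions (levels assumed 1..L integers)
oracleGlcm <- function(patch, L, dr, dc) {
  counts <- matrix(0, L, L)
  nr <- nrow(patch); nc <- ncol(patch)
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    rr <- r + dr; cc <- c + dc
    if (rr >= 1 && rr <= nr && cc >= 1 && cc <= nc) {
      a <- patch[r, c]; b <- patch[rr, cc]
      counts[a, b] <- counts[a, b] + 1
      counts[b, a] <- counts[b, a] + 1
    }
  }
  counts / sum(counts)
}

oracleGlcmStats <- function(P) {
  L <- nrow(P)
  i <- row(P); j <- col(P)
  px <- rowSums(P)
  mu <- sum(seq_len(L) * px)
  sig2 <- sum((seq_len(L) - mu)^2 * px)
  lg <- function(x) ifelse(x > 0, log2(x), 0)
  psum <- sapply(2:(2 * L), function(k) sum(P[(i + j) == k]))
  pdiff <- sapply(0:(L - 1), function(k) sum(P[abs(i - j) == k]))
  sumavg <- sum((2:(2 * L)) * psum)
  diffavg <- sum((0:(L - 1)) * pdiff)
  hx <- -sum(px * lg(px))
  hxy <- -sum(P * lg(P))
  pxipxj <- outer(px, px)
  hxy1 <- -sum(ifelse(P > 0 & pxipxj > 0, P * lg(pxipxj), 0))
  c(energy = sum(P^2),
    contrast = sum((i - j)^2 * P),
    correlation = if (sig2 > 1e-12) (sum(i * j * P) - mu^2) / sig2 else 0,
    variance = sum((i - mu)^2 * P),
    inverse_difference_moment = sum(P / (1 + (i - j)^2)),
    sum_average = sumavg,
    sum_variance = sum(((2:(2 * L)) - sumavg)^2 * psum),
    sum_entropy = -sum(psum * lg(psum)),
    entropy = hxy,
    difference_variance = sum(((0:(L - 1)) - diffavg)^2 * pdiff),
    difference_entropy = -sum(pdiff * lg(pdiff)),
    imc1 = if (hx > 1e-12) (hxy - hxy1) / hx else 0,
    homogeneity = sum(P / (1 + abs(i - j))),
    autocorrelation = sum(i * j * P),
    dissimilarity = sum(abs(i - j) * P),
    cluster_shade = sum((i + j - 2 * mu)^3 * P),
    cluster_prominence = sum((i + j - 2 * mu)^4 * P),
    maximum_probability = max(P))
}

# AUC oracle: O(n^2) pairwise Mann-Whitney count with ties as 1/2
oracleAuc <- function(scores, labels) {
  pos <- scores[labels == "cancer"]
  neg <- scores[labels != "cancer"]
  tot <- 0
  for (p in pos) for (n in neg)
    tot <- tot + if (p > n) 1 else if (p == n) 0.5 else 0
  tot / (length(pos) * length(neg))
}

# CDI oracle: literal triple loop over the clipped subvolume
oracleCdi <- function(volumes, radius) {
  d <- dim(volumes[[1]])
  prodVol <- Reduce(`*`, volumes)
  out <- array(0, d)
  for (x in seq_len(d[1])) for (y in seq_len(d[2])) for (z in seq_len(d[3])) {
    xs <- max(1, x - radius[1]):min(d[1], x + radius[1])
    ys <- max(1, y - radius[2]):min(d[2], y + radius[2])
    zs <- max(1, z - radius[3]):min(d[3], z + radius[3])
    out[x, y, z] <- mean(prodVol[xs, ys, zs])
  }
  out
}

# plug-in MI oracle in bits from raw joint counts of discrete vectors
oracleMi <- function(x, y) {
  tab <- table(x, y)
  n <- sum(tab)
  pj <- tab / n
  px <- rowSums(pj); py <- colSums(pj)
  mi <- 0
  for (a in seq_along(px)) for (b in seq_along(py))
    if (pj[a, b] > 0) mi <- mi + pj[a, b] * log2(pj[a, b] / (px[a] * py[b]))
  unname(as.numeric(mi))
}

# small synthetic feature table with patient structure; `informative`
# columns carry class signal, the rest are noise
syntheticTable <- function(n = 600, nInformative = 3, nNoise = 7,
                           nPatients = 10, posRate = 0.2, effect = 2,
                           sd = 0.6, seed = 1) {
  set.seed(seed)
  lab <- factor(ifelse(runif(n) < posRate, "cancer", "healthy"),
                levels = c("healthy", "cancer"))
  sig <- sapply(seq_len(nInformative), function(k)
    as.numeric(lab == "cancer") * effect / k + rnorm(n, sd = sd))
  noise <- matrix(rnorm(n * nNoise), n, nNoise)
  x <- cbind(sig, noise)
  colnames(x) <- c(paste0("ADC/sig/f", seq_len(nInformative)),
                   paste0("T2w/noise/g", seq_len(nNoise)))
  new("TextureFeatureMatrix", values = x, labels = lab,
      patientIds = rep(sprintf("P%02d", seq_len(nPatients)),
                       length.out = n),
      coords = matrix(1L, n, 3, dimnames = list(NULL, c("x", "y", "z"))))
}

tinyConfig <- function(...) {
  phantomConfig(nPatients = 3, gridShape = c(32, 32, 8), seed = 11, ...)
}
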