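# internal numeric helpers shared across modules

# deterministic per-patient seed, kept well below 2^31
patientSeed <- function(seed, patientIndex) {
  as.integer((as.numeric(seed) * 100003 + patientIndex * 7919) %% 2147483629)
}

# trilinear resize of a 3-D array to a new shape, half-voxel-centre
# convention: voxel i (1-based) is centred at (i - 0.5) * spacing
trilinearResize <- function(arr, outShape) {
  d <- dim(arr)
  outShape <- as.integer(outShape)
  # source continuous index for each output voxel centre
  idx <- lapply(1:3, function(a) {
    s <- (seq_len(outShape[a]) - 0.5) * d[a] / outShape[a] + 0.5
    pmin(pmax(s, 1), d[a])
  })
  i0 <- lapply(1:3, function(a) pmin(floor(idx[[a]]), dim(arr)[a] - 1L))
  i0 <- lapply(1:3, function(a) pmax(i0[[a]], 1L))
  fr <- lapply(1:3, function(a) idx[[a]] - i0[[a]])
  g <- function(ox, oy, oz) {
    arr[cbind(
      rep(i0[[1]] + ox, times = outShape[2] * outShape[3]),
      rep(rep(i0[[2]] + oy, each = outShape[1]), times = outShape[3]),
      rep(i0[[3]] + oz, each = outShape[1] * outShape[2])
    )]
  }
  wx <- rep(fr[[1]], times = outShape[2] * outShape[3])
  wy <- rep(rep(fr[[2]], each = outShape[1]), times = outShape[3])
  wz <- rep(fr[[3]], each = outShape[1] * outShape[2])
  out <-
    g(0L, 0L, 0L) * (1 - wx) * (1 - wy) * (1 - wz) +
    g(1L, 0L, 0L) * wx * (1 - wy) * (1 - wz) +
    g(0L, 1L, 0L) * (1 - wx) * wy * (1 - wz) +
    g(1L, 1L, 0L) * wx * wy * (1 - wz) +
    g(0L, 0L, 1L) * (1 - wx) * (1 - wy) * wz +
    g(1L, 0L, 1L) * wx * (1 - wy) * wz +
    g(0L, 1L, 1L) * (1 - wx) * wy * wz +
    g(1L, 1L, 1L) * wx * wy * wz
  array(out, dim = outShape)
}

# smooth multiplicative bias field: coarse uniform grid upsampled
smoothField <- function(shape, lo = 0.9, hi = 1.1, coarse = c(5, 5, 3)) {
  coarse <- pmin(coarse, shape)
  base <- array(runif(prod(coarse), lo, hi), dim = coarse)
  trilinearResize(base, shape)
}

# mean over a clipped box window for every voxel of a 3-D array,
# via integral image (summed-area table)
boxMean3D <- function(arr, radius) {
  d <- dim(arr)
  radius <- rep_len(radius, 3L)
  cumsumAxis <- function(x, a) {
    perm <- c(a, setdiff(1:3, a))
    y <- aperm(x, perm)
    y <- array(apply(y, c(2, 3), cumsum), dim = dim(x)[perm])
    aperm(y, order(perm))
  }
  sat <- arr
  for (a in 1:3) if (d[a] > 1L) sat <- cumsumAxis(sat, a)
  # sat[i,j,k] = sum over [1..i,1..j,1..k]
  padSat <- array(0, d + 1L)
  padSat[-1, -1, -1] <- sat
  lo <- lapply(1:3, function(a) pmax(seq_len(d[a]) - radius[a], 1L))
  hi <- lapply(1:3, function(a) pmin(seq_len(d[a]) + radius[a], d[a]))
  S <- function(x, y, z) {
    padSat[cbind(
      rep(x, times = d[2] * d[3]),
      rep(rep(y, each = d[1]), times = d[3]),
      rep(z, each = d[1] * d[2])
    )]
  }
  h1 <- hi[[1]] + 1L; h2 <- hi[[2]] + 1L; h3 <- hi[[3]] + 1L
  l1 <- lo[[1]]; l2 <- lo[[2]]; l3 <- lo[[3]]
  tot <- S(h1, h2, h3) - S(l1, h2, h3) - S(h1, l2, h3) - S(h1, h2, l3) +
    S(l1, l2, h3) + S(l1, h2, l3) + S(h1, l2, l3) - S(l1, l2, l3)
  cnt <- outer(outer(hi[[1]] - lo[[1]] + 1, hi[[2]] - lo[[2]] + 1),
               hi[[3]] - lo[[3]] + 1)
  array(tot / cnt, dim = d)
}

# 2-D clipped-window box mean via integral image
boxMean2D <- function(mat, half) {
  d <- dim(mat)
  sat <- apply(apply(mat, 2, cumsum), 1, cumsum) |> t()
  pad <- matrix(0, d[1] + 1L, d[2] + 1L)
  pad[-1, -1] <- sat
  lo1 <- pmax(seq_len(d[1]) - half, 1L); hi1 <- pmin(seq_len(d[1]) + half, d[1])
  lo2 <- pmax(seq_len(d[2]) - half, 1L); hi2 <- pmin(seq_len(d[2]) + half, d[2])
  tot <- pad[hi1 + 1L, hi2 + 1L, drop = FALSE] -
    pad[lo1, hi2 + 1L, drop = FALSE] -
    pad[hi1 + 1L, lo2, drop = FALSE] +
    pad[lo1, lo2, drop = FALSE]
  cnt <- outer(hi1 - lo1 + 1, hi2 - lo2 + 1)
  tot / cnt
}

# 2-D clipped-window max
boxMax2D <- function(mat, half) {
  d <- dim(mat)
  out <- mat
  # max over rows within +/- half, then over columns (separable)
  tmp <- mat
  for (s in seq_len(half)) {
    up <- rbind(mat[-seq_len(s), , drop = FALSE],
                mat[rep(d[1], s), , drop = FALSE])
    dn <- rbind(mat[rep(1L, s), , drop = FALSE],
                mat[seq_len(d[1] - s), , drop = FALSE])
    # clipped: near edges the shifted copies replicate edge rows, which
    # duplicates values already inside the clipped window
    tmp <- pmax(tmp, up, dn)
  }
  out <- tmp
  for (s in seq_len(half)) {
    le <- cbind(out[, -seq_len(s), drop = FALSE],
                out[, rep(d[2], s), drop = FALSE])
    ri <- cbind(out[, rep(1L, s), drop = FALSE],
                out[, seq_len(d[2] - s), drop = FALSE])
    tmp <- pmax(tmp, le, ri)
  }
  tmp
}

# "same"-size 2-D convolution (correlation with pre-flipped kernel is the
# caller's concern) via zero-padded FFT; kernel must have odd dimensions
conv2same <- function(mat, kernel) {
  dm <- dim(mat); dk <- dim(kernel)
  P <- dm + dk - 1L
  A <- matrix(0, P[1], P[2]); A[seq_len(dm[1]), seq_len(dm[2])] <- mat
  K <- matrix(0, P[1], P[2]); K[seq_len(dk[1]), seq_len(dk[2])] <- kernel
  full <- fft(fft(A) * fft(K), inverse = TRUE) / prod(P)
  off <- (dk - 1L) / 2L
  full[off[1] + seq_len(dm[1]), off[2] + seq_len(dm[2])]
}

conv2sameComplex <- function(mat, kernel) {
  dm <- dim(mat); dk <- dim(kernel)
  P <- dm + dk - 1L
  A <- matrix(0 + 0i, P[1], P[2]); A[seq_len(dm[1]), seq_len(dm[2])] <- mat
  K <- matrix(0 + 0i, P[1], P[2]); K[seq_len(dk[1]), seq_len(dk[2])] <- kernel
  full <- fft(fft(A) * fft(K), inverse = TRUE) / prod(P)
  off <- (dk - 1L) / 2L
  full[off[1] + seq_len(dm[1]), off[2] + seq_len(dm[2])]
}

# replicate-pad a matrix by one pixel on each side
padReplicate1 <- function(mat) {
  m <- rbind(mat[1, , drop = FALSE], mat, mat[nrow(mat), , drop = FALSE])
  cbind(m[, 1, drop = FALSE], m, m[, ncol(m), drop = FALSE])
}

# 3x3 correlation with replicate border handling
conv3x3Replicate <- function(mat, kernel) {
  p <- padReplicate1(mat)
  nr <- nrow(mat); nc <- ncol(mat)
  out <- matrix(0, nr, nc)
  for (dr in -1:1) for (dc in -1:1) {
    w <- kernel[dr + 2L, dc + 2L]
    if (w != 0)
      out <- out + w * p[dr + 1L + seq_len(nr), dc + 1L + seq_len(nc)]
  }
  out
}

stopIfNot <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)
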