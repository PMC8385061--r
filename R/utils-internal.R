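# Internal numeric helpers: summed-area tables and box means.

# Summed-area table with a zero first row/column, so that the sum of
# mat[r0:r1, c0:c1] is P[r1+1,c1+1] - P[r0,c1+1] - P[r1+1,c0] + P[r0,c0].
.sat <- function(mat) {
  H <- nrow(mat); W <- ncol(mat)
  P <- matrix(0, H + 1L, W + 1L)
  cs <- mat
  if (H > 1L) cs <- matrix(vapply(seq_len(W), function(j) cumsum(mat[, j]),
                                  numeric(H)), H, W)
  rs <- cs
  if (W > 1L) rs <- t(matrix(vapply(seq_len(H), function(i) cumsum(cs[i, ]),
                                    numeric(W)), W, H))
  P[-1L, -1L] <- rs
  P
}

# Mean over a (2*half+1)^2 window at every pixel, window clipped at the
# image border and renormalized by the actual pixel count (no edge bias).
.boxMeanClamped <- function(mat, half) {
  if (half == 0L) return(mat)
  H <- nrow(mat); W <- ncol(mat)
  P <- .sat(mat)
  r <- seq_len(H); co <- seq_len(W)
  rlo <- pmax(r - half, 1L); rhi <- pmin(r + half, H)
  clo <- pmax(co - half, 1L); chi <- pmin(co + half, W)
  S <- P[rhi + 1L, chi + 1L, drop = FALSE] - P[rlo, chi + 1L, drop = FALSE] -
       P[rhi + 1L, clo, drop = FALSE] + P[rlo, clo, drop = FALSE]
  S / outer(rhi - rlo + 1L, chi - clo + 1L)
}

# Mean over full (2*half+1)^2 windows; NA where the window would leave
# the image (used for the 5x5 tracking score, which requires full patches).
.boxMeanValid <- function(mat, half) {
  H <- nrow(mat); W <- ncol(mat)
  out <- matrix(NA_real_, H, W)
  if (H < 2L * half + 1L || W < 2L * half + 1L) return(out)
  P <- .sat(mat)
  rv <- (half + 1L):(H - half); cv <- (half + 1L):(W - half)
  S <- P[rv + half + 1L, cv + half + 1L, drop = FALSE] -
       P[rv - half, cv + half + 1L, drop = FALSE] -
       P[rv + half + 1L, cv - half, drop = FALSE] +
       P[rv - half, cv - half, drop = FALSE]
  out[rv, cv] <- S / (2L * half + 1L)^2
  out
}

# Rolling mean and sample sd of x over the inclusive index window
# [i - w, i + w], clipped at the series edges. Single-element windows
# get sd 0.
.rollingMeanSd <- function(x, w) {
  n <- length(x)
  i <- seq_len(n)
  lo <- pmax(i - w, 1L); hi <- pmin(i + w, n)
  cnt <- hi - lo + 1L
  c1 <- c(0, cumsum(x)); c2 <- c(0, cumsum(x * x))
  m <- (c1[hi + 1L] - c1[lo]) / cnt
  v <- (c2[hi + 1L] - c2[lo] - cnt * m * m) / pmax(cnt - 1L, 1L)
  v[cnt == 1L] <- 0
  list(mean = m, sd = sqrt(pmax(v, 0)))
}

.isCount <- function(x) length(x) == 1L && is.finite(x) && x >= 0 &&
  abs(x - round(x)) < .Machine$double.eps^0.5

.checkSeedBelow31 <- function(seed) {
  if (!is.finite(seed) || abs(seed) >= 2^31)
    stop("rng seed must be a 32-bit integer")
  as.integer(seed)
}
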