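# Shared fixture builders. Image fixtures are generated in code at test
# time; heavier scenes use a 5 frames/s protocol (300 frames) to keep
# the suite fast while preserving the 10/20/30 s protocol structure.

fastProtocol <- function() StimulusProtocol(frameRate = 5)

# Minimal stack: constant-value frames over a constant background.
constantStack <- function(value = 100, bgValue = 30, H = 12, W = 12,
                          T = 40, nBg = 5,
                          protocol = StimulusProtocol(1, 1, 2, 10)) {
  ImageStack(array(value, c(H, W, T)), array(bgValue, c(H, W, nBg)),
             protocol)
}

# Noise-free stack with a single Gaussian blob following a given path
# (T x 2 matrix of integer centers), on a zero background.
blobPathStack <- function(path, H = 64, W = 64, peak = 200, sigma = 2,
                          nBg = 5, protocol = StimulusProtocol(1, 1, 2, 10)) {
  T <- nrow(path)
  a <- array(0, c(H, W, T))
  half <- ceiling(4 * sigma)
  off <- seq(-half, half)
  prof <- peak * exp(-outer(off^2, off^2, "+") / (2 * sigma^2))
  for (t in seq_len(T)) {
    rr <- path[t, 1] + off; cc <- path[t, 2] + off
    sr <- rr >= 1 & rr <= H; sc <- cc >= 1 & cc <= W
    a[rr[sr], cc[sc], t] <- a[rr[sr], cc[sc], t] + prof[sr, sc]
  }
  ImageStack(a, array(0, c(H, W, nBg)), protocol)
}

wholeFrameSeed <- function(stack, seedPos, refFrame = 1L,
                           animalId = "a01") {
  d <- dim(frames(stack))
  data.frame(animal_id = animalId, seed_row = seedPos[1],
             seed_col = seedPos[2], row0 = 1L, row1 = d[1],
             col0 = 1L, col1 = d[2], ref_frame = refFrame)
}

# A viable NeuronTrack carrying an arbitrary dff trace (for callActivation
# tests that need the S4 path).
dffTrack <- function(x, id = "a01") {
  n <- length(x)
  new("NeuronTrack", animalId = id,
      positions = matrix(1L, n, 2L), F = x + 100, F0 = 100,
      dff = x, viable = TRUE, reason = "",
      roiBounds = c(1L, 5L, 1L, 5L), refFrame = 1L)
}
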