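test_that("background subtraction matches hand arithmetic and round-trips", {
  s <- constantStack(value = 100, bgValue = 30)
  out <- subtractBackground(s)
  expect_true(all(frames(out) == 70))
  s2 <- constantStack(value = 30, bgValue = 30)
  expect_true(all(frames(subtractBackground(s2)) == 0))
  # round-trip on a random stack (float mode, no clipping)
  set.seed(4)
  a <- array(rnorm(12 * 12 * 6, 50, 10), c(12, 12, 6))
  b <- array(rnorm(12 * 12 * 4, 20, 5), c(12, 12, 4))
  st <- ImageStack(a, b, StimulusProtocol(1, 1, 2, 2))
  out <- subtractBackground(st, clip = FALSE)
  bgMean <- rowMeans(b, dims = 2)
  rec <- frames(out) + as.vector(bgMean)
  expect_equal(rec, a)
  # clipped mode only differs where the result would be negative
  outc <- subtractBackground(st, clip = TRUE)
  expect_true(all(frames(outc) >= 0))
  nonneg <- frames(out) >= 0
  expect_equal(frames(outc)[nonneg], frames(out)[nonneg])
})

test_that("stacks with mismatched background shapes are rejected", {
  expect_error(
    ImageStack(array(1, c(10, 10, 4)), array(0, c(8, 8, 2)),
               StimulusProtocol(1, 1, 2, 2)),
    "shape")
})

test_that("frame smoothing: identity, constancy, and point-spread arithmetic", {
  s <- constantStack(value = 55)
  expect_identical(frames(smoothFrames(s, 1)), frames(s))
  expect_equal(frames(smoothFrames(s, 3)), frames(s))
  expect_error(smoothFrames(s, 4), "odd")
  # single bright pixel spreads to 1/9 over its 3x3 neighborhood
  a <- array(0, c(9, 9, 1))
  a[5, 5, 1] <- 9
  st <- ImageStack(a, array(0, c(9, 9, 1)), StimulusProtocol(1, 1, 2, 1))
  sm <- frames(smoothFrames(st, 3))[, , 1]
  expect_equal(sm[4:6, 4:6], matrix(1, 3, 3))
  expect_equal(sum(sm), 9)   # mass preserved away from borders
})

test_that("tracking follows a drifting blob exactly and stays put on a static one", {
  path <- cbind(10 + 2 * (0:14), rep(20, 15))   # 2 px/frame downward
  st <- blobPathStack(path, H = 48, W = 48)
  tr <- trackNeuron(st, wholeFrameSeed(st, path[1, ], refFrame = 1L))
  expect_equal(unname(positions(tr)), unname(path))
  # bidirectional: seeding mid-way recovers both halves
  tr2 <- trackNeuron(st, wholeFrameSeed(st, path[8, ], refFrame = 8L))
  expect_equal(unname(positions(tr2)), unname(path))

  stat <- blobPathStack(matrix(rep(c(24, 24), each = 10), ncol = 2),
                        H = 48, W = 48)
  trs <- trackNeuron(stat, wholeFrameSeed(stat, c(24, 24)))
  expect_true(all(positions(trs)[, 1] == 24 & positions(trs)[, 2] == 24))
})

test_that("a 40 px jump cannot be followed under the 30 px constraint", {
  path <- matrix(rep(c(20, 20), each = 12), ncol = 2)
  path[7:12, 2] <- 60                       # jump of 40 px at frame 7
  # sigma 1.5 keeps the jumped blob's support clear of the 30 px search
  # window, so the jump is genuinely unreachable in one step
  st <- blobPathStack(path, H = 80, W = 80, sigma = 1.5)
  tr <- trackNeuron(st, wholeFrameSeed(st, c(20, 20)))
  after <- positions(tr)[7:12, ]
  expect_true(all(pmax(abs(after[, 1] - 20), abs(after[, 2] - 20)) <= 30))
  expect_false(any(after[, 2] == 60 & after[, 1] == 20))
})

test_that("tracking rejects invalid seeds and undersized ROIs", {
  st <- blobPathStack(matrix(rep(c(10, 10), each = 5), ncol = 2),
                      H = 32, W = 32)
  bad <- wholeFrameSeed(st, c(50, 50))
  expect_error(trackNeuron(st, bad), "outside")
  small <- data.frame(animal_id = "x", seed_row = 10, seed_col = 10,
                      row0 = 9, row1 = 12, col0 = 9, col1 = 12,
                      ref_frame = 1)
  expect_error(trackNeuron(st, small), "5 x 5")
  off <- wholeFrameSeed(st, c(10, 10), refFrame = 99L)
  expect_error(trackNeuron(st, off), "reference frame")
})

test_that("dF/F0 matches its defining formula and flags zero baselines", {
  tr <- dffTrack(rep(0, 40))
  tr@F <- rep(80, 40); tr@dff <- numeric(0)
  out <- computeDff(tr)
  expect_equal(baselineF0(out), 80)
  expect_true(all(dff(out) == 0))
  tr@F <- c(rep(100, 10), rep(150, 30))
  out <- computeDff(tr)
  expect_equal(dff(out)[20], 0.5)
  tr@F <- rep(0, 40)
  out <- computeDff(tr)
  expect_false(isViable(out))
  expect_match(out@reason, "zero baseline")
})

test_that("dF/F0 and the activation call are invariant under positive rescaling of the stack", {
  spec <- SyntheticSceneSpec(arenaSize = c(96, 96), nAnimals = 2, pAct = 1,
                             noiseSd = 0, backgroundLevel = 0,
                             protocol = fastProtocol(), rngSeed = 21)
  g <- generateStack(spec)
  seeds <- seedsFromGroundTruth(g$truth)
  proc <- smoothFrames(subtractBackground(g$stack), 3)
  scaled <- proc; scaled@frames <- scaled@frames * 3.7
  t1 <- computeDff(trackNeuron(proc, seeds[1, ]))
  t2 <- computeDff(trackNeuron(scaled, seeds[1, ]))
  expect_equal(dff(t1), dff(t2))
  expect_equal(positions(t1), positions(t2))
})

test_that("consecutive tracked positions never exceed the step constraint", {
  spec <- SyntheticSceneSpec(arenaSize = c(120, 120), nAnimals = 3,
                             noiseSd = 3, motionFraction = 1,
                             motionJump = 40, protocol = fastProtocol(),
                             rngSeed = 31)
  g <- generateStack(spec)
  seeds <- seedsFromGroundTruth(g$truth)
  proc <- smoothFrames(subtractBackground(g$stack), 3)
  for (i in seq_len(nrow(seeds))) {
    p <- positions(trackNeuron(proc, seeds[i, ]))
    step <- pmax(abs(diff(p[, 1])), abs(diff(p[, 2])))
    expect_true(all(step <= 30))
  }
})

test_that("motion check: static scenes pass, jumps fail, decisions are deterministic", {
  stat <- blobPathStack(matrix(rep(c(24, 24), each = 60), ncol = 2),
                        H = 48, W = 48)
  tr <- trackNeuron(stat, wholeFrameSeed(stat, c(24, 24)))
  out <- motionCheck(stat, tr)
  expect_true(isViable(out))
  expect_true(all(idSeries(out) == 0))

  path <- matrix(rep(c(20, 20), each = 60), ncol = 2)
  path[30:60, 2] <- 60
  stj <- blobPathStack(path, H = 80, W = 80)
  trj <- trackNeuron(stj, wholeFrameSeed(stj, c(20, 20)))
  outj <- motionCheck(stj, trj)
  expect_false(isViable(outj))
  expect_match(outj@reason, "motion")
  # the violation sits at the jump transition
  st <- idSeries(outj)
  expect_equal(which.max(st), 29L)
  expect_identical(isViable(motionCheck(stj, trj)),
                   isViable(motionCheck(stj, trj)))
  expect_error(motionCheck(stj, trj, window = 0), "count")
})

test_that("motion-check rejection on i.i.d. noise matches an independently coded oracle", {
  # independent re-implementation: plain loops over the same criterion
  oracleViable <- function(ids, w = 20) {
    for (i in seq_along(ids)) {
      win <- ids[max(1, i - w):min(length(ids), i + w)]
      m <- mean(win)
      s <- if (length(win) > 1) sd(win) else 0
      ok <- ids[i] < m + s || (s == 0 && ids[i] == m)
      if (!ok) return(FALSE)
    }
    TRUE
  }
  set.seed(77)
  nRep <- 200
  mine <- logical(nRep); theirs <- logical(nRep)
  prot <- StimulusProtocol(1, 1, 2, 20)   # 80 frames
  for (r in seq_len(nRep)) {
    a <- array(rnorm(12 * 12 * 80), c(12, 12, 80))
    st <- ImageStack(a, array(0, c(12, 12, 2)), prot)
    tr <- dffTrack(rep(0, 80))
    tr@roiBounds <- c(1L, 12L, 1L, 12L)
    out <- motionCheck(st, tr)
    mine[r] <- isViable(out)
    theirs[r] <- oracleViable(idSeries(out))
  }
  pHat <- mean(!theirs)
  se <- sqrt(max(pHat * (1 - pHat), 1 / nRep) / nRep)
  expect_lt(abs(mean(!mine) - pHat), 3 * se + 1e-12)
  expect_identical(mine, theirs)
})
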