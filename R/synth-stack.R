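#' Generate a synthetic multi-animal calcium-imaging stack
#'
#' Renders a wide-field acquisition of immobilized worm heads as bright
#' isotropic Gaussian blobs on a flat background, together with 20
#' stimulus-free background frames and a ground-truth sidecar recording
#' every stochastic draw. Responding animals superimpose a GCaMP-like
#' transient (fast rise, slow exponential decay) on their blob starting
#' at odor removal; animals flagged for motion receive a positional jump
#' (or smooth drift) of configurable magnitude at a recorded frame.
#' The intensity of an animal factorizes into a spatial blob profile and
#' a temporal modulation, so the true peak dF/F0 of a responder equals
#' \code{neuronAmplitude} exactly in the noise-free case.
#'
#' The generator is fully determined by \code{spec}: calling it twice
#' with the same spec gives bit-identical stacks and sidecars.
#'
#' @param spec a \linkS4class{SyntheticSceneSpec}.
#' @param nBackground number of background frames (default 20).
#' @return A list with elements
#'   \describe{
#'     \item{stack}{an \linkS4class{ImageStack};}
#'     \item{truth}{the ground-truth sidecar: \code{animals} (one row per
#'       animal: base position, responder flag, transient onset, motion
#'       flag, jump frame and displacement, amplitude), \code{positions}
#'       (long table animal x frame of true positions) and the spec.}
#'   }
#' @examples
#' sc <- SyntheticSceneSpec(arenaSize = c(96, 96), nAnimals = 2,
#'                          noiseSd = 0, rngSeed = 7)
#' g <- generateStack(sc)
#' g$truth$animals
#' @export
generateStack <- function(spec, nBackground = 20L) {
  stopifnot(is(spec, "SyntheticSceneSpec"))
  validObject(spec)
  prot <- spec@protocol
  H <- spec@arenaSize[1L]; W <- spec@arenaSize[2L]
  n <- spec@nAnimals
  T <- nFrames(prot)
  fr <- prot@frameRate

  # placement on a jittered grid; reject arenas that cannot host n blobs
  margin <- max(ceiling(4 * spec@blobSigma), 8L) + 2L
  k <- ceiling(sqrt(n))
  cellH <- floor((H - 2L * margin) / k)
  cellW <- floor((W - 2L * margin) / k)
  minCell <- max(ceiling(8 * spec@blobSigma), 16L)
  if (cellH < minCell || cellW < minCell)
    stop("arena too small for ", n, " animals: need at least ",
         2L * margin + k * minCell, " px per side; increase arenaSize ",
         "or reduce nAnimals")

  set.seed(spec@rngSeed)
  cells <- sample.int(k * k, n)                      # distinct grid cells
  cr <- (cells - 1L) %/% k; cc <- (cells - 1L) %% k
  jitH <- max(cellH - minCell, 0L); jitW <- max(cellW - minCell, 0L)
  row0 <- margin + cr * cellH + minCell %/% 2L +
    if (jitH > 0) sample.int(jitH + 1L, n, replace = TRUE) - 1L else 0L
  col0 <- margin + cc * cellW + minCell %/% 2L +
    if (jitW > 0) sample.int(jitW + 1L, n, replace = TRUE) - 1L else 0L

  responder <- runif(n) < spec@pAct
  moving <- runif(n) < spec@motionFraction
  jumpFrame <- rep(NA_integer_, n)
  jumpFrame[moving] <- sample(seq(2L, T - 1L), sum(moving), replace = TRUE)

  # temporal kernel: difference of exponentials from odor removal,
  # normalized to peak 1 on the discrete frame grid
  tOff <- prot@tBufferPre + prot@tOdor
  tt <- (seq_len(T) - 1L) / fr
  kern <- numeric(T)
  post <- tt >= tOff
  u <- tt[post] - tOff
  kern[post] <- exp(-u / spec@decayTau) - exp(-u / spec@riseTau)
  pk <- max(kern)
  if (pk > 0) kern <- kern / pk
  dip <- numeric(T)
  if (spec@odorDip > 0)
    dip[tt >= prot@tBufferPre & tt < tOff] <- -spec@odorDip

  # per-animal true positions per frame
  posR <- matrix(rep(row0, each = T), T, n)
  posC <- matrix(rep(col0, each = T), T, n)
  jdr <- integer(n); jdc <- integer(n)
  jump <- round(spec@motionJump)
  for (a in which(moving)) {
    dirs <- matrix(c(jump, 0L, -jump, 0L, 0L, jump, 0L, -jump),
                   ncol = 2L, byrow = TRUE)[sample.int(4L), , drop = FALSE]
    ok <- which(row0[a] + dirs[, 1L] >= margin &
                row0[a] + dirs[, 1L] <= H - margin &
                col0[a] + dirs[, 2L] >= margin &
                col0[a] + dirs[, 2L] <= W - margin)
    if (!length(ok))
      stop("arena too small for a ", jump, " px motion jump; ",
           "increase arenaSize or reduce motionJump")
    d <- dirs[ok[1L], ]
    jdr[a] <- d[1L]; jdc[a] <- d[2L]
    if (spec@motionMode == "jump") {
      idx <- jumpFrame[a]:T
      posR[idx, a] <- row0[a] + d[1L]
      posC[idx, a] <- col0[a] + d[2L]
    } else {                                   # linear drift, same endpoint
      frac <- (seq_len(T) - 1L) / (T - 1L)
      posR[, a] <- row0[a] + round(frac * d[1L])
      posC[, a] <- col0[a] + round(frac * d[2L])
      jumpFrame[a] <- NA_integer_              # no single jump frame
    }
  }

  # render: blob profile on a local patch, temporal modulation per frame
  half <- ceiling(4 * spec@blobSigma)
  off <- seq(-half, half)
  prof <- exp(-outer(off^2, off^2, "+") / (2 * spec@blobSigma^2))
  fr3 <- array(spec@backgroundLevel, c(H, W, T))
  for (a in seq_len(n)) {
    mod <- if (responder[a]) 1 + spec@neuronAmplitude * kern + dip else
      rep(1, T)
    ampA <- spec@blobPeak * mod
    # frames grouped into constant-position segments, rendered in one
    # outer product per segment
    segId <- cumsum(c(1L, (diff(posR[, a]) != 0L) | (diff(posC[, a]) != 0L)))
    for (s in unique(segId)) {
      tIdx <- which(segId == s)
      rr <- posR[tIdx[1L], a] + off; cc2 <- posC[tIdx[1L], a] + off
      sel_r <- rr >= 1L & rr <= H; sel_c <- cc2 >= 1L & cc2 <= W
      fr3[rr[sel_r], cc2[sel_c], tIdx] <-
        fr3[rr[sel_r], cc2[sel_c], tIdx] +
        outer(prof[sel_r, sel_c, drop = FALSE], ampA[tIdx])
    }
  }
  if (spec@noiseSd > 0)
    fr3 <- fr3 + array(rnorm(length(fr3), 0, spec@noiseSd), dim(fr3))

  bg <- array(spec@backgroundLevel, c(H, W, nBackground))
  if (spec@noiseSd > 0)
    bg <- bg + array(rnorm(length(bg), 0, spec@noiseSd), dim(bg))

  animals <- data.frame(
    animal_id = sprintf("a%02d", seq_len(n)),
    base_row = row0, base_col = col0,
    responder = responder,
    onset_s = ifelse(responder, tOff, NA_real_),
    p_act = spec@pAct,
    moving = moving,
    jump_frame = jumpFrame,
    jump_drow = ifelse(moving, jdr, NA_integer_),
    jump_dcol = ifelse(moving, jdc, NA_integer_),
    amplitude = ifelse(responder, spec@neuronAmplitude, 0),
    stringsAsFactors = FALSE
  )
  positions <- data.frame(
    animal_id = rep(animals$animal_id, each = T),
    frame = rep(seq_len(T), n),
    row = as.vector(posR), col = as.vector(posC)
  )

  list(stack = ImageStack(fr3, bg, prot),
       truth = list(animals = animals, positions = positions, spec = spec))
}

#' Derive ROI seeds from a ground-truth sidecar
#'
#' Builds the seed table the tracker needs (one ROI rectangle and seed
#' position per animal) from the true positions at the reference frame,
#' emulating the manual head/neuron selection step of the experimental
#' workflow. The ROI is a square of half-width \code{roiHalf} around the
#' seed, clipped to the arena.
#'
#' @param truth the \code{truth} element returned by
#'   \code{\link{generateStack}}.
#' @param refFrame reference frame index; defaults to 2 s after odor
#'   removal (see \code{\link{referenceFrame}}).
#' @param roiHalf ROI half-width in pixels (default 15).
#' @return A data.frame with columns \code{animal_id}, \code{seed_row},
#'   \code{seed_col}, \code{row0}, \code{row1}, \code{col0}, \code{col1},
#'   \code{ref_frame}.
#' @export
seedsFromGroundTruth <- function(truth, refFrame = NULL, roiHalf = 15L) {
  spec <- truth$spec
  prot <- spec@protocol
  if (is.null(refFrame)) refFrame <- referenceFrame(prot)
  refFrame <- as.integer(refFrame)
  H <- spec@arenaSize[1L]; W <- spec@arenaSize[2L]
  p <- truth$positions[truth$positions$frame == refFrame, , drop = FALSE]
  p <- p[match(truth$animals$animal_id, p$animal_id), , drop = FALSE]
  data.frame(
    animal_id = truth$animals$animal_id,
    seed_row = p$row, seed_col = p$col,
    row0 = pmax(p$row - roiHalf, 1L), row1 = pmin(p$row + roiHalf, H),
    col0 = pmax(p$col - roiHalf, 1L), col1 = pmin(p$col + roiHalf, W),
    ref_frame = refFrame,
    stringsAsFactors = FALSE
  )
}
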