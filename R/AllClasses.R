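#' Stimulus protocol for a buffer/odor/buffer acquisition
#'
#' Describes the timing of a single calcium-imaging acquisition: a
#' pre-stimulus buffer interval, an odor interval, and a post-stimulus
#' buffer interval, all in seconds, plus the acquisition frame rate.
#' The three intervals tile the acquisition with no gaps. The default
#' protocol is 10 s buffer, 20 s odor, 30 s buffer at 10 frames/s.
#'
#' @slot tBufferPre numeric(1), pre-stimulus buffer duration in seconds.
#' @slot tOdor numeric(1), odor (stimulus) duration in seconds.
#' @slot tBufferPost numeric(1), post-stimulus buffer duration in seconds.
#' @slot frameRate numeric(1), frames per second.
#'
#' @param tBufferPre,tOdor,tBufferPost,frameRate see slot descriptions.
#' @return A \code{StimulusProtocol} object.
#' @examples
#' p <- StimulusProtocol()
#' nFrames(p)        # 600 at the defaults
#' odorOffFrame(p)   # first frame after odor removal
#' @export StimulusProtocol
#' @exportClass StimulusProtocol
#' @aliases StimulusProtocol-class
setClass("StimulusProtocol",
  representation(
    tBufferPre  = "numeric",
    tOdor       = "numeric",
    tBufferPost = "numeric",
    frameRate   = "numeric"
  ),
  prototype(tBufferPre = 10, tOdor = 20, tBufferPost = 30, frameRate = 10)
)

setValidity("StimulusProtocol", function(object) {
  msg <- character()
  for (s in c("tBufferPre", "tOdor", "tBufferPost", "frameRate")) {
    v <- slot(object, s)
    if (length(v) != 1L || !is.finite(v) || v <= 0)
      msg <- c(msg, sprintf("'%s' must be a single strictly positive number", s))
  }
  if (length(msg)) msg else TRUE
})

StimulusProtocol <- function(tBufferPre = 10, tOdor = 20, tBufferPost = 30,
                             frameRate = 10) {
  new("StimulusProtocol", tBufferPre = tBufferPre, tOdor = tOdor,
      tBufferPost = tBufferPost, frameRate = frameRate)
}

#' @describeIn StimulusProtocol total acquisition duration in seconds.
#' @param object,x a \code{StimulusProtocol}.
#' @export
totalDuration <- function(object) {
  stopifnot(is(object, "StimulusProtocol"))
  object@tBufferPre + object@tOdor + object@tBufferPost
}

#' @rdname StimulusProtocol
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))

#' @rdname StimulusProtocol
setMethod("nFrames", "StimulusProtocol", function(x)
  as.integer(round(totalDuration(x) * x@frameRate)))

#' @rdname StimulusProtocol
#' @export
setGeneric("frameRate", function(x) standardGeneric("frameRate"))

#' @rdname StimulusProtocol
setMethod("frameRate", "StimulusProtocol", function(x) x@frameRate)

#' @describeIn StimulusProtocol 1-based index of the first odor frame.
#' @export
odorOnFrame <- function(object) {
  stopifnot(is(object, "StimulusProtocol"))
  as.integer(round(object@tBufferPre * object@frameRate)) + 1L
}

#' @describeIn StimulusProtocol 1-based index of the first frame after
#'   odor removal.
#' @export
odorOffFrame <- function(object) {
  stopifnot(is(object, "StimulusProtocol"))
  as.integer(round((object@tBufferPre + object@tOdor) * object@frameRate)) + 1L
}

#' @describeIn StimulusProtocol default reference frame for ROI seeding,
#'   2 seconds after odor removal (where activated neurons are brightest).
#' @export
referenceFrame <- function(object) {
  stopifnot(is(object, "StimulusProtocol"))
  as.integer(round((object@tBufferPre + object@tOdor + 2) * object@frameRate)) + 1L
}

setMethod("show", "StimulusProtocol", function(object) {
  cat("StimulusProtocol: ",
      object@tBufferPre, "s buffer / ",
      object@tOdor, "s odor / ",
      object@tBufferPost, "s buffer @ ",
      object@frameRate, " frames/s (", nFrames(object), " frames)\n", sep = "")
})


#' Multi-frame fluorescence image stack
#'
#' Container for a time-ordered grayscale acquisition plus stimulus-free
#' background frames and the stimulus protocol. Frames are stored as a
#' numeric H x W x T array (rows x columns x time); background frames as
#' an H x W x B array. Intensities are arbitrary fluorescence units.
#'
#' @slot frames numeric array, H x W x T.
#' @slot background numeric array, H x W x B (B >= 1; 20 by default from
#'   the synthetic generator).
#' @slot protocol the \linkS4class{StimulusProtocol} of the acquisition.
#' @slot backgroundMean numeric matrix; the cached pixel-wise background
#'   mean after \code{\link{subtractBackground}} (empty before).
#'
#' @param frames,background,protocol see slot descriptions.
#' @return An \code{ImageStack}.
#' @seealso \code{\link{generateStack}}, \code{\link{subtractBackground}},
#'   \code{\link{smoothFrames}}, \code{\link{trackNeuron}}
#' @export ImageStack
#' @exportClass ImageStack
#' @aliases ImageStack-class
setClass("ImageStack",
  representation(
    frames         = "array",
    background     = "array",
    protocol       = "StimulusProtocol",
    backgroundMean = "matrix"
  )
)

setValidity("ImageStack", function(object) {
  d <- dim(object@frames)
  b <- dim(object@background)
  if (length(d) != 3L) return("'frames' must be an H x W x T array")
  if (length(b) != 3L) return("'background' must be an H x W x B array")
  if (b[3L] < 1L) return("at least one background frame is required")
  if (!all(d[1:2] == b[1:2]))
    return("background frames must have the same H x W shape as the frames")
  TRUE
})

ImageStack <- function(frames, background, protocol = StimulusProtocol()) {
  if (length(dim(frames)) != 3L)
    stop("'frames' must be a 3-d array (H x W x T)")
  if (is.matrix(background))
    background <- array(background, c(dim(background), 1L))
  new("ImageStack", frames = frames, background = background,
      protocol = protocol, backgroundMean = matrix(numeric(0), 0, 0))
}

#' @rdname ImageStack
#' @param x an \code{ImageStack}.
#' @export
setGeneric("frames", function(x) standardGeneric("frames"))

#' @rdname ImageStack
setMethod("frames", "ImageStack", function(x) x@frames)

#' @rdname ImageStack
#' @export
setGeneric("backgroundFrames", function(x) standardGeneric("backgroundFrames"))

#' @rdname ImageStack
setMethod("backgroundFrames", "ImageStack", function(x) x@background)

#' @rdname ImageStack
#' @export
setGeneric("protocol", function(x) standardGeneric("protocol"))

#' @rdname ImageStack
setMethod("protocol", "ImageStack", function(x) x@protocol)

#' @rdname ImageStack
setMethod("frameRate", "ImageStack", function(x) x@protocol@frameRate)

#' @rdname ImageStack
setMethod("nFrames", "ImageStack", function(x) dim(x@frames)[3L])

setMethod("show", "ImageStack", function(object) {
  d <- dim(object@frames)
  cat("ImageStack: ", d[1L], " x ", d[2L], " px, ", d[3L], " frames, ",
      dim(object@background)[3L], " background frames\n", sep = "")
  show(object@protocol)
  if (length(object@backgroundMean))
    cat("  background-subtracted (mean background cached)\n")
})


#' Per-neuron track and fluorescence trace
#'
#' Result of tracking one neuron through an image stack: per-frame
#' positions, the raw trace F (mean intensity of the tracked object), the
#' baseline F0, the normalized trace dF/F0, the frame-difference series
#' used by the motion check, and the viability flag with its reason.
#'
#' @slot animalId character(1).
#' @slot positions integer matrix T x 2 of (row, col) per frame.
#' @slot F numeric(T), raw mean intensity per frame.
#' @slot F0 numeric(1), baseline fluorescence (NA before \code{computeDff}).
#' @slot dff numeric(T), normalized trace (F - F0)/F0 (empty before).
#' @slot idSeries numeric(T-1), ROI frame-difference statistic ID_{i,i+1}
#'   (empty before \code{motionCheck}).
#' @slot viable logical(1).
#' @slot reason character(1), why a track is non-viable ("" if viable).
#' @slot roiBounds integer(4), (row0, row1, col0, col1) of the ROI.
#' @slot refFrame integer(1), the reference frame tracking started from.
#'
#' @seealso \code{\link{trackNeuron}}, \code{\link{computeDff}},
#'   \code{\link{motionCheck}}, \code{\link{callActivation}}
#' @exportClass NeuronTrack
#' @aliases NeuronTrack-class
setClass("NeuronTrack",
  representation(
    animalId  = "character",
    positions = "matrix",
    F         = "numeric",
    F0        = "numeric",
    dff       = "numeric",
    idSeries  = "numeric",
    viable    = "logical",
    reason    = "character",
    roiBounds = "integer",
    refFrame  = "integer"
  ),
  prototype(F0 = NA_real_, dff = numeric(0), idSeries = numeric(0),
            viable = TRUE, reason = "")
)

setValidity("NeuronTrack", function(object) {
  n <- length(object@F)
  if (nrow(object@positions) != n)
    return("'positions' must have one row per frame of F")
  if (length(object@dff) && length(object@dff) != n)
    return("'dff' must have the same length as F")
  if (length(object@roiBounds) != 4L)
    return("'roiBounds' must be (row0, row1, col0, col1)")
  TRUE
})

#' @rdname NeuronTrack-class
#' @param x a \code{NeuronTrack}.
#' @export
setGeneric("positions", function(x) standardGeneric("positions"))

#' @rdname NeuronTrack-class
setMethod("positions", "NeuronTrack", function(x) x@positions)

#' @rdname NeuronTrack-class
#' @export
setGeneric("rawTrace", function(x) standardGeneric("rawTrace"))

#' @rdname NeuronTrack-class
setMethod("rawTrace", "NeuronTrack", function(x) x@F)

#' @rdname NeuronTrack-class
#' @export
setGeneric("dff", function(x) standardGeneric("dff"))

#' @rdname NeuronTrack-class
setMethod("dff", "NeuronTrack", function(x) x@dff)

#' @rdname NeuronTrack-class
#' @export
setGeneric("baselineF0", function(x) standardGeneric("baselineF0"))

#' @rdname NeuronTrack-class
setMethod("baselineF0", "NeuronTrack", function(x) x@F0)

#' @rdname NeuronTrack-class
#' @export
setGeneric("isViable", function(x) standardGeneric("isViable"))

#' @rdname NeuronTrack-class
setMethod("isViable", "NeuronTrack", function(x) x@viable)

#' @rdname NeuronTrack-class
#' @export
setGeneric("idSeries", function(x) standardGeneric("idSeries"))

#' @rdname NeuronTrack-class
setMethod("idSeries", "NeuronTrack", function(x) x@idSeries)

#' @rdname NeuronTrack-class
#' @export
setGeneric("roiBounds", function(x) standardGeneric("roiBounds"))

#' @rdname NeuronTrack-class
setMethod("roiBounds", "NeuronTrack", function(x) x@roiBounds)

setMethod("show", "NeuronTrack", function(object) {
  cat("NeuronTrack '", object@animalId, "': ", length(object@F),
      " frames, ", sep = "")
  if (is.na(object@F0)) cat("F0 not computed, ")
  else cat("F0 = ", signif(object@F0, 5), ", ", sep = "")
  if (object@viable) cat("viable\n")
  else cat("NON-VIABLE (", object@reason, ")\n", sep = "")
})


#' Synthetic imaging scene specification
#'
#' Parameters of one synthetic wide-field acquisition: arena geometry,
#' number of immobilized animals, stimulus protocol, GCaMP-like transient
#' amplitude and kinetics, pixel noise, and the motion model. Defaults
#' emulate the study conditions of a multi-animal pulse-arena recording:
#' 16 worm heads per field of view, a 10/20/30 s buffer/odor/buffer
#' protocol at 10 frames/s, and off-stimulus transients in responders.
#'
#' @slot arenaSize integer(2), (H, W) in pixels.
#' @slot nAnimals integer(1), number of animals (>= 1).
#' @slot protocol a \linkS4class{StimulusProtocol}.
#' @slot pAct numeric(1), probability that an animal is a responder.
#' @slot neuronAmplitude numeric(1), peak dF/F0 of a responder transient.
#' @slot noiseSd numeric(1), additive Gaussian pixel-noise sd.
#' @slot backgroundLevel numeric(1), mean pixel offset (also present in
#'   the background frames).
#' @slot blobPeak numeric(1), peak intensity of a neuron blob above
#'   background at baseline.
#' @slot blobSigma numeric(1), sd (px) of the isotropic Gaussian blob.
#' @slot motionFraction numeric(1) in [0, 1], fraction of animals given a
#'   positional perturbation.
#' @slot motionJump numeric(1), magnitude (px) of the perturbation.
#' @slot motionMode character(1), "jump" (single instantaneous jump at a
#'   recorded frame) or "drift" (smooth linear drift of the same total
#'   magnitude).
#' @slot odorDip numeric(1), optional on-stimulus hyperpolarization dip
#'   (dF/F0 units, >= 0; default 0 so the generator matches the
#'   activation caller's assumptions exactly).
#' @slot riseTau,decayTau numeric(1), transient rise/decay time constants
#'   in seconds (difference of exponentials; defaults 0.5 and 5 s).
#' @slot rngSeed integer(1), seed making the scene fully reproducible.
#'
#' @param arenaSize,nAnimals,protocol,pAct,neuronAmplitude,noiseSd
#'   see slot descriptions.
#' @param backgroundLevel,blobPeak,blobSigma,motionFraction,motionJump
#'   see slot descriptions.
#' @param motionMode,odorDip,riseTau,decayTau,rngSeed see slot descriptions.
#' @return A \code{SyntheticSceneSpec}.
#' @seealso \code{\link{generateStack}}
#' @export SyntheticSceneSpec
#' @exportClass SyntheticSceneSpec
#' @aliases SyntheticSceneSpec-class
setClass("SyntheticSceneSpec",
  representation(
    arenaSize       = "integer",
    nAnimals        = "integer",
    protocol        = "StimulusProtocol",
    pAct            = "numeric",
    neuronAmplitude = "numeric",
    noiseSd         = "numeric",
    backgroundLevel = "numeric",
    blobPeak        = "numeric",
    blobSigma       = "numeric",
    motionFraction  = "numeric",
    motionJump      = "numeric",
    motionMode      = "character",
    odorDip         = "numeric",
    riseTau         = "numeric",
    decayTau        = "numeric",
    rngSeed         = "integer"
  )
)

setValidity("SyntheticSceneSpec", function(object) {
  msg <- character()
  if (length(object@arenaSize) != 2L || any(object@arenaSize < 16L))
    msg <- c(msg, "'arenaSize' must be two pixel dimensions >= 16")
  if (object@nAnimals < 1L)
    msg <- c(msg, "'nAnimals' must be >= 1")
  if (object@pAct < 0 || object@pAct > 1)
    msg <- c(msg, "'pAct' must be in [0, 1]")
  if (object@motionFraction < 0 || object@motionFraction > 1)
    msg <- c(msg, "'motionFraction' must be in [0, 1]")
  if (object@noiseSd < 0) msg <- c(msg, "'noiseSd' must be >= 0")
  if (object@blobSigma <= 0) msg <- c(msg, "'blobSigma' must be > 0")
  if (object@blobPeak <= 0) msg <- c(msg, "'blobPeak' must be > 0")
  if (object@odorDip < 0) msg <- c(msg, "'odorDip' must be >= 0")
  if (!object@motionMode %in% c("jump", "drift"))
    msg <- c(msg, "'motionMode' must be \"jump\" or \"drift\"")
  if (length(msg)) msg else TRUE
})

SyntheticSceneSpec <- function(arenaSize = c(256L, 256L), nAnimals = 16,
                               protocol = StimulusProtocol(), pAct = 0.8,
                               neuronAmplitude = 1.5, noiseSd = 2,
                               backgroundLevel = 100, blobPeak = 400,
                               blobSigma = 3, motionFraction = 0,
                               motionJump = 40, motionMode = "jump",
                               odorDip = 0, riseTau = 0.5, decayTau = 5,
                               rngSeed = 1) {
  new("SyntheticSceneSpec",
      arenaSize = as.integer(arenaSize), nAnimals = as.integer(nAnimals),
      protocol = protocol, pAct = pAct, neuronAmplitude = neuronAmplitude,
      noiseSd = noiseSd, backgroundLevel = backgroundLevel,
      blobPeak = blobPeak, blobSigma = blobSigma,
      motionFraction = motionFraction, motionJump = motionJump,
      motionMode = motionMode, odorDip = odorDip,
      riseTau = riseTau, decayTau = decayTau, rngSeed = as.integer(rngSeed))
}

setMethod("show", "SyntheticSceneSpec", function(object) {
  cat("SyntheticSceneSpec: ", object@arenaSize[1L], " x ",
      object@arenaSize[2L], " px, ", object@nAnimals, " animals, p_act = ",
      object@pAct, ", amplitude = ", object@neuronAmplitude,
      ", noise sd = ", object@noiseSd, ", motion fraction = ",
      object@motionFraction, " (", object@motionMode, "), seed = ",
      object@rngSeed, "\n", sep = "")
})
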