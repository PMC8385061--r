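#' Call an odor-removal activation event on a viable trace
#'
#' Decides whether the neuron "activated" upon odor removal: the call is
#' positive when the mean normalized signal in a 10 s post-stimulus
#' window (I_off) exceeds the mean in a 10 s on-stimulus window (I_on)
#' by more than three times the on-stimulus standard deviation
#' (sigma_on). The on-window is the last \code{windowS} seconds of the
#' odor interval and the off-window the first \code{windowS} seconds
#' after odor removal, bracketing the removal event; both can be shifted
#' with the offset arguments (in seconds; positive shifts move the
#' windows later). The rule is invariant under adding a constant to the
#' trace and under multiplication by a positive constant.
#'
#' Non-viable tracks are excluded upstream and are refused here.
#'
#' @param track a viable \linkS4class{NeuronTrack} with \code{dff}
#'   computed, or a bare numeric dF/F0 trace.
#' @param protocol the \linkS4class{StimulusProtocol} of the acquisition.
#' @param windowS window length in seconds (default 10).
#' @param onOffsetS,offOffsetS shifts of the on-window end and off-window
#'   start relative to odor removal, in seconds (defaults 0).
#' @param animalId label used when \code{track} is a numeric vector.
#' @return A one-row data.frame with columns \code{animal_id},
#'   \code{I_on}, \code{I_off}, \code{sigma_on}, \code{responded}.
#' @examples
#' p <- StimulusProtocol()
#' tr <- c(rep(0, 300), rep(1, 300))   # clean step at odor removal
#' callActivation(tr, p)
#' @export
callActivation <- function(track, protocol, windowS = 10,
                           onOffsetS = 0, offOffsetS = 0,
                           animalId = "trace") {
  stopifnot(is(protocol, "StimulusProtocol"))
  if (is(track, "NeuronTrack")) {
    if (!track@viable)
      stop("track '", track@animalId, "' is not viable (",
           track@reason, "); non-viable tracks are never called")
    if (!length(track@dff))
      stop("dff not computed; run computeDff() first")
    x <- track@dff
    animalId <- track@animalId
  } else {
    x <- as.numeric(track)
  }
  fr <- protocol@frameRate
  n <- length(x)
  w <- as.integer(round(windowS * fr))
  if (w < 2L) stop("window too short for the frame rate")
  offFrame <- as.integer(round(
    (protocol@tBufferPre + protocol@tOdor + onOffsetS) * fr))
  onIdx <- (offFrame - w + 1L):offFrame
  offStart <- as.integer(round(
    (protocol@tBufferPre + protocol@tOdor + offOffsetS) * fr)) + 1L
  offIdx <- offStart:(offStart + w - 1L)
  if (onIdx[1L] < 1L || offIdx[w] > n)
    stop("activation windows exceed the trace bounds (trace has ", n,
         " frames, windows span ", onIdx[1L], "..", offIdx[w], ")")
  if (anyNA(x[c(onIdx, offIdx)]))
    stop("activation windows contain missing frames; call refused")

  iOn <- mean(x[onIdx]); iOff <- mean(x[offIdx]); sOn <- sd(x[onIdx])
  data.frame(animal_id = as.character(animalId),
             I_on = iOn, I_off = iOff, sigma_on = sOn,
             responded = (iOff - iOn) > 3 * sOn,
             stringsAsFactors = FALSE)
}

#' Activation rate of a set of calls
#'
#' Fraction of calls flagged as responded, in [0, 1].
#'
#' @param calls a data.frame of activation calls (rows from
#'   \code{\link{callActivation}}) or a logical vector of responses.
#' @return The activation rate.
#' @export
activationRate <- function(calls) {
  r <- if (is.data.frame(calls)) calls$responded else as.logical(calls)
  if (is.null(r) || length(r) == 0L)
    stop("no activation calls supplied")
  mean(r)
}

#' Dose-response contrast between positive and control activation rates
#'
#' The contrast at each concentration is the difference (default) or the
#' ratio of the positive-sample and control-sample activation rates. The
#' two rate vectors must be on the same concentration grid; names, when
#' present, are matched and must agree.
#'
#' @param ratesPositive,ratesControl activation rates per concentration.
#' @param mode \code{"difference"} (default) or \code{"ratio"}.
#' @return Named vector of contrasts per concentration.
#' @examples
#' doseContrast(c(`1e-2` = 0.83, `1e-3` = 0.5),
#'              c(`1e-2` = 0.20, `1e-3` = 0.4))
#' @export
doseContrast <- function(ratesPositive, ratesControl,
                         mode = c("difference", "ratio")) {
  mode <- match.arg(mode)
  if (length(ratesPositive) != length(ratesControl))
    stop("concentration grids differ in length")
  np <- names(ratesPositive); nc <- names(ratesControl)
  if (!is.null(np) && !is.null(nc)) {
    if (!setequal(np, nc))
      stop("concentration grids do not match")
    ratesControl <- ratesControl[np]
  }
  if (mode == "difference") ratesPositive - ratesControl
  else ratesPositive / ratesControl
}
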