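# Disk interfaces: multi-page 16-bit grayscale TIFF for image stacks,
# tidy CSV for seeds, traces, calls, cohort tables and plate counts.

#' Write / read an image stack as multi-page 16-bit TIFF
#'
#' The acquisition frames and the background frames are written as two
#' separate multi-page grayscale TIFF files. Pixel intensities are
#' stored as 16-bit unsigned integers; values are rounded and clipped
#' to [0, 65535] on write, so intensities must be on a 16-bit scale
#' (the synthetic generator's units satisfy this).
#'
#' @param stack an \linkS4class{ImageStack}.
#' @param path TIFF path for the frames.
#' @param backgroundPath TIFF path for the background frames (default:
#'   \code{path} with a \code{_bg} suffix).
#' @return \code{writeImageStack}: the two paths, invisibly.
#' @export
writeImageStack <- function(stack, path,
                            backgroundPath = sub("(\\.tiff?)$", "_bg\\1",
                                                 path)) {
  stopifnot(is(stack, "ImageStack"))
  toPages <- function(a) {
    T <- dim(a)[3L]
    lapply(seq_len(T), function(t) {
      m <- a[, , t]
      m[m < 0] <- 0; m[m > 65535] <- 65535
      round(m) / 65535
    })
  }
  tiff::writeTIFF(toPages(stack@frames), path, bits.per.sample = 16L)
  tiff::writeTIFF(toPages(stack@background), backgroundPath,
                  bits.per.sample = 16L)
  invisible(c(path, backgroundPath))
}

#' @rdname writeImageStack
#' @param protocol the \linkS4class{StimulusProtocol} of the acquisition
#'   (not stored in the TIFF).
#' @return \code{readImageStack}: the \linkS4class{ImageStack}.
#' @export
readImageStack <- function(path, backgroundPath = sub("(\\.tiff?)$",
                                                      "_bg\\1", path),
                           protocol = StimulusProtocol()) {
  fromPages <- function(p) {
    pages <- tiff::readTIFF(p, all = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    array(unlist(pages) * 65535, c(dim(pages[[1L]]), length(pages)))
  }
  ImageStack(fromPages(path), fromPages(backgroundPath), protocol)
}

#' Write / read ROI seed tables
#'
#' Seeds as CSV with columns \code{animal_id}, \code{seed_row},
#' \code{seed_col}, \code{row0}, \code{row1}, \code{col0}, \code{col1},
#' \code{ref_frame}.
#'
#' @param seeds a seed data.frame (\code{\link{seedsFromGroundTruth}}).
#' @param path CSV path.
#' @export
writeRoiSeeds <- function(seeds, path) {
  write.csv(seeds, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeRoiSeeds
#' @export
readRoiSeeds <- function(path) {
  read.csv(path, stringsAsFactors = FALSE)
}

#' Tidy per-frame trace table of a list of tracks
#'
#' One row per animal and frame: \code{animal_id}, \code{frame},
#' \code{time_s}, \code{row}, \code{col}, \code{F}, \code{dff},
#' \code{viable}, \code{reason}.
#'
#' @param tracks list of \linkS4class{NeuronTrack} objects.
#' @param protocol the acquisition \linkS4class{StimulusProtocol}.
#' @return A data.frame.
#' @export
tracksToTable <- function(tracks, protocol) {
  do.call(rbind, lapply(tracks, function(tr) {
    n <- length(tr@F)
    data.frame(
      animal_id = tr@animalId,
      frame = seq_len(n),
      time_s = (seq_len(n) - 1L) / protocol@frameRate,
      row = tr@positions[, 1L], col = tr@positions[, 2L],
      F = tr@F,
      dff = if (length(tr@dff)) tr@dff else NA_real_,
      viable = tr@viable, reason = tr@reason,
      stringsAsFactors = FALSE
    )
  }))
}
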