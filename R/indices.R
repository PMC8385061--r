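#' Neuronal Activation Index (NAI)
#'
#' NAI = 2 (N_act / N_tot - 0.5), where N_act is the number of animals
#' responding with neuronal activation upon odor removal and N_tot the
#' number of viable animals tested. Subtracting 1/2 forces symmetry
#' around zero and the prefactor 2 bounds the index to [-1, 1], making
#' it directly comparable with the chemotaxis index: NAI > 0 means a
#' majority of the tested animals activated.
#'
#' @param nAct count of responding animals (vectorized).
#' @param nTot count of viable animals tested (>= 1).
#' @return The index value(s), in [-1, 1].
#' @examples
#' computeNAI(10, 12)     # 0.667
#' computeNAI(0:12, 12)
#' @export
computeNAI <- function(nAct, nTot) {
  if (any(nTot < 1)) stop("no viable nematodes (N_tot must be >= 1)")
  if (any(nAct < 0) || any(nAct > nTot))
    stop("N_act must satisfy 0 <= N_act <= N_tot")
  2 * (nAct / nTot - 0.5)
}

#' Chemotaxis Index (CI)
#'
#' CI = (worms in the odorant areas - worms in the control areas) /
#' total worms scored on the plate; range [-1, 1]. Worms in neutral
#' regions count in the denominator only.
#'
#' @param nOdorant,nControl,nTotal plate counts (vectorized), or pass a
#'   plate-count data.frame with columns \code{n_odorant},
#'   \code{n_control}, \code{n_total} as the first argument.
#' @return The index value(s).
#' @examples
#' computeCI(60, 30, 100)   # 0.3
#' @export
computeCI <- function(nOdorant, nControl = NULL, nTotal = NULL) {
  if (is.data.frame(nOdorant)) {
    d <- nOdorant
    nOdorant <- d$n_odorant; nControl <- d$n_control; nTotal <- d$n_total
  }
  if (any(nTotal < 1)) stop("no worms on the plate (n_total must be >= 1)")
  if (any(nOdorant < 0) || any(nControl < 0) ||
      any(nOdorant + nControl > nTotal))
    stop("invalid plate counts: need n_odorant + n_control <= n_total, all >= 0")
  (nOdorant - nControl) / nTotal
}

#' Binomial standard deviation of a bounded index
#'
#' Both indices are affine images of a binomial proportion: an index
#' v = 2p - 1 with p estimated from n two-outcome trials has
#' sd = 2 sqrt(p (1 - p) / n), with p = (v + 1)/2. For the NAI, n is the
#' number of viable animals. For the CI, the two-outcome trial is
#' odorant-vs-control among worms that chose a scored area, so n should
#' be the scored count (worms in neutral zones reduce the effective n)
#' and v the index rescaled to the scored worms.
#'
#' @param indexValue index value(s) in [-1, 1].
#' @param n number of trials (>= 1).
#' @param kind \code{"nai"} or \code{"ci"} (same closed form; kept for
#'   self-documenting call sites).
#' @return The binomial sd of the index estimate.
#' @examples
#' binomialSD(0, 100)        # 0.1
#' @export
binomialSD <- function(indexValue, n, kind = c("nai", "ci")) {
  kind <- match.arg(kind)
  if (any(n < 1)) stop("'n' must be >= 1")
  if (any(abs(indexValue) > 1 + 1e-12))
    stop("index values must lie in [-1, 1]")
  p <- (indexValue + 1) / 2
  2 * sqrt(p * (1 - p) / n)
}

#' Aggregate sessions and plates into a per-subject record
#'
#' Per-session NAIs are averaged without weighting by session size
#' (sessions are different experiment days), giving the subject's NAI
#' mean and across-session sd; a pooled mode (NAI of the summed counts,
#' worm-weighted) is also available and its binomial sd from the pooled
#' counts is reported alongside either way. Plate CIs are averaged
#' across replicate plates. Violations of the session policy (fewer
#' than \code{minSessions} sessions, or any session with fewer than
#' \code{minWorms} worms) are reported as warnings, not errors.
#'
#' @param sessions data.frame with one row per session: columns
#'   \code{N_act}, \code{N_tot}, optionally \code{subject_id} and
#'   \code{group}.
#' @param plates optional data.frame of plate counts for the same
#'   subject (columns \code{n_odorant}, \code{n_control},
#'   \code{n_total}).
#' @param minSessions,minWorms session policy (defaults 2 and 25; the
#'   default policy guarantees >= 50 worms per subject).
#' @param mode \code{"unweighted"} (default) or \code{"pooled"} for the
#'   reported \code{nai_mean}.
#' @return A one-row data.frame: \code{subject_id}, \code{group},
#'   \code{nai_mean}, \code{nai_sd} (across sessions),
#'   \code{nai_pooled}, \code{nai_sd_binomial} (from pooled counts),
#'   \code{ci_mean}, \code{ci_sd}, \code{n_sessions},
#'   \code{n_worms_total}.
#' @export
aggregateSubject <- function(sessions, plates = NULL, minSessions = 2L,
                             minWorms = 25L,
                             mode = c("unweighted", "pooled")) {
  mode <- match.arg(mode)
  if (!is.data.frame(sessions) || nrow(sessions) == 0L)
    stop("'sessions' must be a non-empty data.frame")
  sid <- if (!is.null(sessions$subject_id)) as.character(sessions$subject_id[1L])
         else NA_character_
  grp <- if (!is.null(sessions$group)) as.character(sessions$group[1L])
         else NA_character_

  if (nrow(sessions) < minSessions)
    warning("subject ", sid, ": only ", nrow(sessions),
            " session(s); policy requires >= ", minSessions)
  if (any(sessions$N_tot < minWorms))
    warning("subject ", sid, ": session(s) with fewer than ", minWorms,
            " worms")

  nais <- computeNAI(sessions$N_act, sessions$N_tot)
  pooledAct <- sum(sessions$N_act); pooledTot <- sum(sessions$N_tot)
  naiPooled <- computeNAI(pooledAct, pooledTot)
  naiMean <- if (mode == "unweighted") mean(nais) else naiPooled
  naiSd <- if (length(nais) > 1L) sd(nais) else 0

  ciMean <- NA_real_; ciSd <- NA_real_
  if (!is.null(plates) && nrow(plates) > 0L) {
    cis <- computeCI(plates)
    ciMean <- mean(cis)
    ciSd <- if (length(cis) > 1L) sd(cis) else 0
  }

  data.frame(subject_id = sid, group = grp,
             nai_mean = naiMean, nai_sd = naiSd,
             nai_pooled = naiPooled,
             nai_sd_binomial = binomialSD(naiPooled, pooledTot, "nai"),
             ci_mean = ciMean, ci_sd = ciSd,
             n_sessions = nrow(sessions),
             n_worms_total = pooledTot,
             stringsAsFactors = FALSE)
}

#' Default sector scores for the single-worm chemotaxis assay
#'
#' A plain symmetric convention for the sectors of a single-animal
#' tracking plate: three concentric sectors on the odorant side scored
#' +1/+2/+3 with increasing proximity to the source, their mirror
#' images on the control side scored -1/-2/-3, and a neutral center
#' sector scored 0. Any user-supplied named mapping can be used instead.
#'
#' @return Named numeric vector of sector scores.
#' @export
defaultSectorScores <- function() {
  c(O1 = 1, O2 = 2, O3 = 3, C1 = -1, C2 = -2, C3 = -3, N = 0)
}

#' Single-worm chemotaxis score
#'
#' Sum of the scores of the distinct sectors through which the animal
#' traveled (re-entering a sector does not count again). Unknown sector
#' labels are an error.
#'
#' @param visitedSectors ordered character vector of visited sectors
#'   (may be empty).
#' @param sectorScores named numeric mapping sector -> score (default
#'   \code{\link{defaultSectorScores}}).
#' @return The chemotaxis score.
#' @examples
#' singleWormScore(c("N", "O1", "O2", "O1"))   # 0 + 1 + 2 = 3
#' @export
singleWormScore <- function(visitedSectors,
                            sectorScores = defaultSectorScores()) {
  if (length(visitedSectors) == 0L) return(0)
  visitedSectors <- as.character(visitedSectors)
  unknown <- setdiff(visitedSectors, names(sectorScores))
  if (length(unknown))
    stop("unknown sector(s): ", paste(unknown, collapse = ", "))
  sum(sectorScores[unique(visitedSectors)])
}

#' Percentage shares of a count table
#'
#' Convenience for cohort-description arithmetic: converts category
#' counts to percentages of the total.
#'
#' @param counts named integer vector (or single count).
#' @param total denominator (defaults to \code{sum(counts)}).
#' @return Percentages on the 0-100 scale.
#' @examples
#' categoryPercent(c(ductal = 32, lobular = 4))   # 88.9 / 11.1
#' @export
categoryPercent <- function(counts, total = sum(counts)) {
  if (total <= 0) stop("'total' must be positive")
  100 * counts / total
}
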