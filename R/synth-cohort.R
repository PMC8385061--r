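#' Generate a synthetic subject cohort with session-level response counts
#'
#' Emulates a two-group screening cohort at the count level: each subject
#' belongs to the "cancer" or "control" group and is tested in several
#' imaging sessions; in each session the number of responding animals is
#' a binomial draw with the group's activation probability. The defaults
#' mirror the study conditions: 36 subjects per group, each tested in at
#' least 2 sessions with at least 25 worms per session (hence >= 50 worms
#' per subject).
#'
#' @param nPerGroup subjects per group (default 36).
#' @param pActCancer,pActControl per-group activation probabilities
#'   (defaults 0.8 and 0.2).
#' @param wormsPerSession viable worms exposed per session (default 25).
#' @param sessions sessions per subject (default 2).
#' @param rngSeed integer seed.
#' @return A list with
#'   \describe{
#'     \item{cohort}{data.frame (subject_id, group, session, N_act,
#'       N_tot), one row per subject-session;}
#'     \item{truth}{data.frame (subject_id, group, p_act) of the true
#'       activation probabilities.}
#'   }
#' @examples
#' gc <- generateCohort(nPerGroup = 4, rngSeed = 3)
#' head(gc$cohort)
#' @export
generateCohort <- function(nPerGroup = 36, pActCancer = 0.8,
                           pActControl = 0.2, wormsPerSession = 25,
                           sessions = 2, rngSeed = 1) {
  if (pActCancer < 0 || pActCancer > 1 || pActControl < 0 || pActControl > 1)
    stop("activation probabilities must be in [0, 1]")
  if (!.isCount(sessions) || sessions < 1)
    stop("'sessions' must be a count >= 1")
  if (!.isCount(nPerGroup) || nPerGroup < 1)
    stop("'nPerGroup' must be a count >= 1")
  if (!.isCount(wormsPerSession) || wormsPerSession < 1)
    stop("'wormsPerSession' must be a count >= 1")
  set.seed(.checkSeedBelow31(rngSeed))

  ids <- c(sprintf("bc%02d", seq_len(nPerGroup)),
           sprintf("hd%02d", seq_len(nPerGroup)))
  grp <- rep(c("cancer", "control"), each = nPerGroup)
  p <- rep(c(pActCancer, pActControl), each = nPerGroup)

  ns <- as.integer(sessions)
  cohort <- data.frame(
    subject_id = rep(ids, each = ns),
    group = rep(grp, each = ns),
    session = rep(seq_len(ns), length(ids)),
    N_tot = as.integer(wormsPerSession),
    stringsAsFactors = FALSE
  )
  cohort$N_act <- rbinom(nrow(cohort), cohort$N_tot, rep(p, each = ns))
  cohort <- cohort[, c("subject_id", "group", "session", "N_act", "N_tot")]

  list(cohort = cohort,
       truth = data.frame(subject_id = ids, group = grp, p_act = p,
                          stringsAsFactors = FALSE))
}

#' Generate worm counts for one quadrant chemotaxis plate
#'
#' Allocates \code{nWorms} worms to odorant, control and neutral plate
#' regions by a multinomial draw whose expected chemotaxis index equals
#' \code{attraction}: with neutral fraction f, a worm lands in a scored
#' area with probability 1 - f and chooses the odorant side with
#' probability q such that (1 - f)(2q - 1) = attraction.
#'
#' @param nWorms number of worms placed on the plate (>= 1).
#' @param attraction target expected CI, in [-1, 1]; its magnitude may
#'   not exceed 1 - \code{neutralFraction}.
#' @param neutralFraction expected fraction of worms ending in unscored
#'   regions (default 0).
#' @param rngSeed optional integer seed; if NULL the current RNG stream
#'   is used (so callers can draw many plates reproducibly).
#' @return A one-row data.frame (plate count record) with columns
#'   \code{n_odorant}, \code{n_control}, \code{n_neutral}, \code{n_total},
#'   \code{true_attraction}.
#' @examples
#' generatePlateCounts(100, attraction = 0.3, rngSeed = 11)
#' @export
generatePlateCounts <- function(nWorms, attraction, neutralFraction = 0,
                                rngSeed = NULL) {
  if (!.isCount(nWorms) || nWorms < 1)
    stop("'nWorms' must be a count >= 1")
  if (attraction < -1 || attraction > 1)
    stop("'attraction' must be in [-1, 1]")
  if (neutralFraction < 0 || neutralFraction >= 1)
    stop("'neutralFraction' must be in [0, 1)")
  if (abs(attraction) > 1 - neutralFraction + 1e-12)
    stop("|attraction| cannot exceed 1 - neutralFraction")
  if (!is.null(rngSeed)) set.seed(.checkSeedBelow31(rngSeed))

  q <- (attraction / (1 - neutralFraction) + 1) / 2
  p <- c(odorant = (1 - neutralFraction) * q,
         control = (1 - neutralFraction) * (1 - q),
         neutral = neutralFraction)
  cnt <- as.integer(rmultinom(1L, nWorms, p))
  data.frame(n_odorant = cnt[1L], n_control = cnt[2L], n_neutral = cnt[3L],
             n_total = as.integer(nWorms), true_attraction = attraction)
}
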