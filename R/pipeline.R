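# End-to-end orchestration: one YAML config drives both the synthetic
# dataset simulation and the analysis, so a full reproducible run is
# runSimulate(cfg) followed by runPipeline(cfg).

#' Default pipeline configuration
#'
#' Returns the configuration list driving \code{\link{runSimulate}} and
#' \code{\link{runPipeline}}. The defaults describe a desk-scale demo
#' cohort: 36 subjects per group at the count level (2 sessions x 25
#' worms each), of which the first subject of each group is imaged
#' (its sessions are produced as synthetic image stacks and analyzed
#' through the full imaging chain instead of being drawn at the count
#' level), plus triplicate chemotaxis plates per subject.
#'
#' @param outputDir output directory for \code{runSimulate} /
#'   \code{runPipeline}.
#' @param rngSeed master seed; all per-stack and per-table seeds are
#'   derived from it.
#' @return A nested configuration list.
#' @export
defaultPipelineConfig <- function(outputDir = "nemascreen_run",
                                  rngSeed = 1L) {
  list(
    rng_seed = as.integer(rngSeed),
    output_dir = outputDir,
    protocol = list(t_buffer_pre = 10, t_odor = 20, t_buffer_post = 30,
                    frame_rate = 10),
    simulate = list(
      imaging = list(
        subjects_per_group = 1L,
        arena = c(160L, 160L),
        n_animals = 8L,
        neuron_amplitude = 1.5,
        noise_sd = 2,
        background_level = 100,
        blob_peak = 400,
        blob_sigma = 3,
        motion_fraction = 0.1,
        motion_jump = 40,
        p_act_cancer = 0.8,
        p_act_control = 0.2
      ),
      cohort = list(
        n_per_group = 36L,
        worms_per_session = 25L,
        sessions = 2L,
        p_act_cancer = 0.8,
        p_act_control = 0.2
      ),
      plates = list(
        n_worms = 60L,
        plates_per_subject = 3L,
        attraction_cancer = 0.4,
        attraction_control = -0.3,
        neutral_fraction = 0
      )
    ),
    analysis = list(
      kernel_size = 3L,
      motion_window = 20L,
      motion_sd_factor = 5,
      max_step = 30L,
      window_s = 10,
      roi_half = 15L,
      session_policy = list(min_sessions = 2L, min_worms = 25L),
      plots = FALSE
    )
  )
}

#' Read a pipeline configuration from YAML
#'
#' Loads a YAML file and fills any missing entries with the defaults of
#' \code{\link{defaultPipelineConfig}}.
#'
#' @param path YAML file path.
#' @return The configuration list.
#' @export
readPipelineConfig <- function(path) {
  user <- yaml::read_yaml(path)
  .mergeConfig(defaultPipelineConfig(), user)
}

.mergeConfig <- function(base, user) {
  for (k in names(user)) {
    base[[k]] <- if (is.list(base[[k]]) && is.list(user[[k]]))
      .mergeConfig(base[[k]], user[[k]]) else user[[k]]
  }
  base
}

.configProtocol <- function(cfg) {
  p <- cfg$protocol
  StimulusProtocol(p$t_buffer_pre, p$t_odor, p$t_buffer_post, p$frame_rate)
}

.drawSeeds <- function(n) sample.int(.Machine$integer.max - 1L, n)

#' Simulate a synthetic dataset on disk
#'
#' Writes, under the configured output directory: image stacks (frames
#' and background TIFFs), ROI seed CSVs and ground-truth sidecars for
#' every imaged subject-session; the count-level cohort table for the
#' remaining subjects; plate counts for all subjects; and a manifest
#' tying stacks to subjects. The run is idempotent given the seed;
#' existing outputs are refused unless \code{force = TRUE}.
#'
#' @param config configuration list (see
#'   \code{\link{defaultPipelineConfig}}).
#' @param force overwrite an existing dataset (default FALSE).
#' @return The dataset directory, invisibly.
#' @export
runSimulate <- function(config = defaultPipelineConfig(), force = FALSE) {
  dir <- config$output_dir
  manifestPath <- file.path(dir, "manifest.csv")
  if (file.exists(manifestPath) && !force)
    stop("dataset already exists in '", dir, "'; use force = TRUE to ",
         "overwrite")
  dir.create(file.path(dir, "stacks"), recursive = TRUE,
             showWarnings = FALSE)
  prot <- .configProtocol(config)
  sim <- config$simulate
  set.seed(.checkSeedBelow31(config$rng_seed))

  # count-level cohort for all subjects
  cg <- sim$cohort
  cohortSeed <- .drawSeeds(1L)
  gc <- generateCohort(cg$n_per_group, cg$p_act_cancer, cg$p_act_control,
                       cg$worms_per_session, cg$sessions, cohortSeed)
  cohort <- gc$cohort

  # imaged subjects: first k of each group; their sessions come from
  # image stacks instead of the count table
  im <- sim$imaging
  k <- im$subjects_per_group
  imaged <- character(0)
  manifest <- NULL
  if (k > 0L) {
    subj <- gc$truth
    imaged <- unlist(lapply(split(subj$subject_id, subj$group),
                            utils::head, k))
    rows <- cohort$subject_id %in% imaged
    imSessions <- cohort[rows, c("subject_id", "group", "session")]
    cohort <- cohort[!rows, , drop = FALSE]
    stackSeeds <- .drawSeeds(nrow(imSessions))
    manifest <- imSessions
    manifest$stack_id <- sprintf("%s_s%d", imSessions$subject_id,
                                 imSessions$session)
    for (i in seq_len(nrow(imSessions))) {
      pAct <- if (imSessions$group[i] == "cancer") im$p_act_cancer
              else im$p_act_control
      spec <- SyntheticSceneSpec(
        arenaSize = im$arena, nAnimals = im$n_animals, protocol = prot,
        pAct = pAct, neuronAmplitude = im$neuron_amplitude,
        noiseSd = im$noise_sd, backgroundLevel = im$background_level,
        blobPeak = im$blob_peak, blobSigma = im$blob_sigma,
        motionFraction = im$motion_fraction, motionJump = im$motion_jump,
        rngSeed = stackSeeds[i])
      g <- generateStack(spec)
      id <- manifest$stack_id[i]
      base <- file.path(dir, "stacks", id)
      writeImageStack(g$stack, paste0(base, ".tif"))
      writeRoiSeeds(seedsFromGroundTruth(g$truth,
                                         roiHalf = config$analysis$roi_half),
                    paste0(base, "_seeds.csv"))
      write.csv(g$truth$animals, paste0(base, "_truth_animals.csv"),
                row.names = FALSE)
      write.csv(g$truth$positions, paste0(base, "_truth_positions.csv"),
                row.names = FALSE)
    }
  }

  # chemotaxis plates for every subject
  pl <- sim$plates
  plateSeed <- .drawSeeds(1L)
  set.seed(plateSeed)
  plates <- do.call(rbind, lapply(seq_len(nrow(gc$truth)), function(i) {
    att <- if (gc$truth$group[i] == "cancer") pl$attraction_cancer
           else pl$attraction_control
    do.call(rbind, lapply(seq_len(pl$plates_per_subject), function(j) {
      cbind(data.frame(subject_id = gc$truth$subject_id[i],
                       group = gc$truth$group[i], plate_id = j,
                       stringsAsFactors = FALSE),
            generatePlateCounts(pl$n_worms, att, pl$neutral_fraction))
    }))
  }))

  write.csv(cohort, file.path(dir, "cohort.csv"), row.names = FALSE)
  write.csv(gc$truth, file.path(dir, "cohort_truth.csv"), row.names = FALSE)
  write.csv(plates, file.path(dir, "plates.csv"), row.names = FALSE)
  if (is.null(manifest))
    manifest <- data.frame(subject_id = character(0), group = character(0),
                           session = integer(0), stack_id = character(0))
  write.csv(manifest, manifestPath, row.names = FALSE)
  yaml::write_yaml(config, file.path(dir, "config_used.yaml"))
  invisible(dir)
}

#' Run the full analysis pipeline on a dataset
#'
#' Executes the post-processing chain on a dataset directory produced
#' by \code{\link{runSimulate}} (or laid out the same way): for every
#' stack in the manifest, background subtraction, smoothing, tracking
#' from the seed file, dF/F0 and the motion check; activation calls on
#' viable traces; image-derived session counts merged with the
#' count-level cohort table; per-subject aggregation (session policy
#' violations are logged as warnings); and the cohort discrimination
#' report. Every excluded trace is logged with its reason (motion,
#' zero baseline); the log goes to stderr and to
#' \code{pipeline_log.txt} in the dataset directory. Tidy per-frame
#' traces (\code{traces.csv}), activation calls (\code{calls.csv}),
#' the subject table, per-subject predictions and a machine-readable
#' \code{summary.json} are written alongside.
#'
#' @param config configuration list (the one used for
#'   \code{\link{runSimulate}}).
#' @param datasetDir dataset directory (default
#'   \code{config$output_dir}).
#' @return Invisibly, a list with \code{subjects} (the per-subject
#'   table), \code{report} (see \code{\link{discriminate}}),
#'   \code{sessionCounts} and \code{exclusions}.
#' @export
runPipeline <- function(config = defaultPipelineConfig(),
                        datasetDir = config$output_dir) {
  an <- config$analysis
  prot <- .configProtocol(config)
  logLines <- character(0)
  logf <- function(...) {
    line <- paste0(...)
    message(line)
    logLines <<- c(logLines, line)
  }

  manifest <- read.csv(file.path(datasetDir, "manifest.csv"),
                       stringsAsFactors = FALSE)
  cohort <- read.csv(file.path(datasetDir, "cohort.csv"),
                     stringsAsFactors = FALSE)
  plates <- read.csv(file.path(datasetDir, "plates.csv"),
                     stringsAsFactors = FALSE)

  exclusions <- NULL
  imgCounts <- NULL
  allCalls <- NULL
  allTraces <- NULL
  if (nrow(manifest)) {
    for (i in seq_len(nrow(manifest))) {
      id <- manifest$stack_id[i]
      base <- file.path(datasetDir, "stacks", id)
      stack <- tryCatch(
        readImageStack(paste0(base, ".tif"), protocol = prot),
        error = function(e) stop("stage extract failed for stack '", id,
                                 "': ", conditionMessage(e)))
      seeds <- readRoiSeeds(paste0(base, "_seeds.csv"))
      proc <- smoothFrames(subtractBackground(stack), an$kernel_size)
      nAct <- 0L; nTot <- 0L
      stackTracks <- list()
      for (s in seq_len(nrow(seeds))) {
        tr <- trackNeuron(proc, seeds[s, ], maxStep = an$max_step)
        tr <- computeDff(tr)
        tr <- motionCheck(proc, tr, window = an$motion_window,
                          sdFactor = an$motion_sd_factor)
        stackTracks[[s]] <- tr
        if (!tr@viable) {
          logf("stack ", id, " animal ", tr@animalId, ": excluded (",
               tr@reason, ")")
          exclusions <- rbind(exclusions, data.frame(
            stack_id = id, animal_id = tr@animalId, reason = tr@reason,
            stringsAsFactors = FALSE))
          next
        }
        call <- tryCatch(
          callActivation(tr, prot, windowS = an$window_s),
          error = function(e) {
            logf("stack ", id, " animal ", tr@animalId, ": excluded (",
                 conditionMessage(e), ")")
            exclusions <<- rbind(exclusions, data.frame(
              stack_id = id, animal_id = tr@animalId,
              reason = "window bounds", stringsAsFactors = FALSE))
            NULL
          })
        if (is.null(call)) next
        logf("stack ", id, " animal ", tr@animalId, ": viable, responded = ",
             call$responded)
        nTot <- nTot + 1L
        nAct <- nAct + as.integer(call$responded)
        allCalls <- rbind(allCalls, cbind(stack_id = id, call))
      }
      logf("stack ", id, ": ", nTot, "/", nrow(seeds), " traces viable, ",
           nAct, " activated")
      allTraces <- rbind(allTraces,
                         cbind(stack_id = id,
                               tracksToTable(stackTracks, prot)))
      imgCounts <- rbind(imgCounts, data.frame(
        subject_id = manifest$subject_id[i], group = manifest$group[i],
        session = manifest$session[i], N_act = nAct, N_tot = nTot,
        stringsAsFactors = FALSE))
    }
  }

  sessionCounts <- rbind(cohort, imgCounts)
  empty <- sessionCounts$N_tot == 0L
  if (any(empty)) {
    for (i in which(empty))
      logf("subject ", sessionCounts$subject_id[i], " session ",
           sessionCounts$session[i], ": no viable nematodes, dropped")
    sessionCounts <- sessionCounts[!empty, , drop = FALSE]
  }
  pol <- an$session_policy
  subjects <- do.call(rbind, lapply(split(sessionCounts,
                                          sessionCounts$subject_id),
    function(ss) {
      pp <- plates[plates$subject_id == ss$subject_id[1L], , drop = FALSE]
      rec <- withCallingHandlers(
        aggregateSubject(ss, pp, pol$min_sessions, pol$min_worms),
        warning = function(w) {
          logf("policy: ", conditionMessage(w))
          invokeRestart("muffleWarning")
        })
      rec
    }))
  rownames(subjects) <- NULL

  report <- discriminate(subjects)
  logf("cohort: ", nrow(subjects), " subjects; accuracy = ",
       round(report$accuracy, 4), ", AUC(NAI) = ",
       round(report$auc_nai, 4))

  write.csv(subjects, file.path(datasetDir, "subjects.csv"),
            row.names = FALSE)
  write.csv(report$predictions, file.path(datasetDir, "predictions.csv"),
            row.names = FALSE)
  if (!is.null(allCalls))
    write.csv(allCalls, file.path(datasetDir, "calls.csv"),
              row.names = FALSE)
  if (!is.null(allTraces))
    write.csv(allTraces, file.path(datasetDir, "traces.csv"),
              row.names = FALSE)
  summary <- report[c("sensitivity", "specificity", "accuracy", "auc_nai",
                      "auc_ci", "auc_pc1", "pc1_variance_fraction",
                      "pc1_loading_fraction_nai")]
  jsonlite::write_json(summary, file.path(datasetDir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  writeLines(logLines, file.path(datasetDir, "pipeline_log.txt"))

  if (isTRUE(an$plots)) {
    png(file.path(datasetDir, "roc.png"), 600, 600)
    plotRocCurves(report)
    dev.off()
    png(file.path(datasetDir, "distributions.png"), 900, 600)
    plotIndexDistributions(subjects)
    dev.off()
  }

  invisible(list(subjects = subjects, report = report,
                 sessionCounts = sessionCounts, exclusions = exclusions))
}
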