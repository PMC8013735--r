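#' Derive a stage seed from the master seed
#'
#' Every stochastic stage of the pipeline gets its own seed, a deterministic
#' hash of the master seed and the stage name, so stages are reproducible
#' independently of each other.
#'
#' @param master integer master seed.
#' @param stage stage name.
#' @return a positive integer below 2^31.
#' @export
deriveSeed <- function(master, stage) {
  h <- sum(utf8ToInt(stage) * seq_len(nchar(stage)))
  as.integer((as.numeric(master) * 7919 + h * 104729) %% 2147483629) + 1L
}

#' Write a cohort to disk
#'
#' Writes one delimited text file per subject (timepoints x nodes, header row
#' of node labels) plus a JSON manifest (ids, groups, TR, covariates, symptom
#' scores, relative paths). Generator ground truth, when present, goes to a
#' separate JSON sidecar (`truth.json`).
#'
#' @param cohort a [TimeCourseSet-class].
#' @param dir output directory (created if absent).
#' @param sep field separator for the matrices (default tab).
#' @return the manifest path, invisibly.
#' @export
writeCohort <- function(cohort, dir, sep = "\t") {
  stopifnot(is(cohort, "TimeCourseSet"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  info <- as.data.frame(subjectInfo(cohort))
  paths <- file.path("signals", paste0(info$id, ".tsv"))
  dir.create(file.path(dir, "signals"), showWarnings = FALSE)
  for (i in seq_len(nrow(info)))
    utils::write.table(signals(cohort)[[info$id[i]]],
                       file.path(dir, paths[i]), sep = sep,
                       row.names = FALSE, quote = FALSE)
  subjects <- lapply(seq_len(nrow(info)), function(i) {
    s <- info[i, ]
    list(id = s$id, group = as.character(s$group), path = paths[i],
         age = s$age, gender = as.character(s$gender),
         site = as.character(s$site),
         symptoms = list(panss_positive = s$panss_positive,
                         panss_negative = s$panss_negative,
                         panss_total = s$panss_total))
  })
  manifest <- list(tr_seconds = trSeconds(cohort),
                   node_names = nodeNames(cohort),
                   subjects = subjects)
  mpath <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null", pretty = TRUE)
  if (length(cohort@truth)) {
    tr <- cohort@truth
    jsonlite::write_json(
      list(n_states = tr$nStates,
           state_sequences = tr$stateSequences,
           transition_matrices = lapply(tr$transitionMatrices, unclass),
           link_phat = as.list(tr$linkPhat),
           symptom_link = tr$symptomLink,
           node_groups = tr$nodeGroups),
      file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA,
      na = "null", pretty = TRUE)
  }
  invisible(mpath)
}

#' Read a cohort from a manifest
#'
#' Loads the JSON manifest written by [writeCohort()] (or produced by any
#' preprocessing that emits per-subject delimited time-course matrices),
#' validating that every referenced file exists, is rectangular, and shares
#' the manifest's node order. A truth sidecar next to the manifest is
#' attached when present. Missing symptom values are allowed and tallied in
#' the validation attribute.
#'
#' @param manifestPath path to `manifest.json`.
#' @param sep field separator of the matrices (default tab).
#' @return a [TimeCourseSet-class]; `attr(, "validation")` holds subject
#'   counts per group and the missing-score tally.
#' @export
readCohort <- function(manifestPath, sep = "\t") {
  m <- jsonlite::read_json(manifestPath)
  dir <- dirname(manifestPath)
  nodeNames <- unlist(m$node_names)
  sigs <- list(); rows <- list()
  for (s in m$subjects) {
    f <- file.path(dir, s$path)
    if (!file.exists(f))
      stop("subject ", s$id, ": time-course file not found: ", f)
    x <- tryCatch(
      as.matrix(utils::read.table(f, header = TRUE, sep = sep,
                                  check.names = FALSE)),
      error = function(e) stop("subject ", s$id, ": unreadable file ", f,
                               " (", conditionMessage(e), ")"))
    if (!identical(colnames(x), nodeNames))
      stop("subject ", s$id, ": node order (", paste(colnames(x), collapse = ","),
           ") does not match the manifest (", paste(nodeNames, collapse = ","), ")")
    storage.mode(x) <- "double"
    sigs[[s$id]] <- x
    num_or_na <- function(v) if (is.null(v)) NA_real_ else as.numeric(v)
    rows[[s$id]] <- data.frame(
      id = s$id, group = s$group, age = num_or_na(s$age),
      gender = if (is.null(s$gender)) NA_character_ else s$gender,
      site = if (is.null(s$site)) NA_character_ else s$site,
      panss_positive = num_or_na(s$symptoms$panss_positive),
      panss_negative = num_or_na(s$symptoms$panss_negative),
      panss_total = num_or_na(s$symptoms$panss_total))
  }
  info <- do.call(rbind, rows)
  subjects <- S4Vectors::DataFrame(
    id = info$id, group = factor(info$group, levels = c("HC", "SZ")),
    age = info$age, gender = factor(info$gender), site = factor(info$site),
    panss_positive = info$panss_positive,
    panss_negative = info$panss_negative, panss_total = info$panss_total)
  truth <- list()
  tpath <- file.path(dir, "truth.json")
  if (file.exists(tpath)) {
    tj <- jsonlite::read_json(tpath, simplifyVector = TRUE)
    truth <- list(
      stateSequences = lapply(tj$state_sequences, as.integer),
      transitionMatrices = tj$transition_matrices,
      linkPhat = unlist(tj$link_phat),
      symptomLink = tj$symptom_link,
      nodeGroups = tj$node_groups,
      nStates = tj$n_states)
  }
  out <- new("TimeCourseSet", signals = sigs, subjects = subjects,
             nodeNames = nodeNames, trSeconds = m$tr_seconds, truth = truth)
  attr(out, "validation") <- list(
    groups = table(subjects$group),
    missingScores = sum(is.na(subjects$panss_total[subjects$group == "SZ"])))
  out
}

#' Run the full dFC state pipeline
#'
#' Orchestrates simulate/ingest -> windowed connectivity -> state clustering
#' -> transition features -> per-state classification -> symptom association,
#' writing every intermediate and a provenance record to `outDir`. Every
#' stochastic stage is seeded from `masterSeed` via [deriveSeed()], so a
#' rerun with the same configuration is identical.
#'
#' @param cohort a [TimeCourseSet-class], a [CohortConfig-class] (simulated
#'   on the fly with its own seed replaced by the derived stage seed), or a
#'   manifest path.
#' @param outDir output directory, or NULL to skip writing.
#' @param k number of states or `"auto"` (elbow selection over `kRange`).
#' @param kRange elbow search range.
#' @param nReplicates,maxIter clustering control.
#' @param taper a [TaperSpec-class]; defaults to `buildTaper()` at the
#'   cohort's TR.
#' @param alpha elastic-net mixing.
#' @param outerFolds,innerFolds nested-CV folds.
#' @param scales,covariates association settings (see
#'   [associateTransitions()]).
#' @param classify run the per-state classification stage (the slowest one).
#' @param masterSeed master seed for all stages.
#' @param verbose print stage progress.
#' @return list: `cohort`, `taper`, `dfc`, `model`, `transitions`,
#'   `stateSummary`, `classification` (per state), `association`,
#'   `provenance`.
#' @export
runPipeline <- function(cohort, outDir = NULL, k = "auto", kRange = 2:8,
                        nReplicates = 10L, maxIter = 200L, taper = NULL,
                        alpha = 0.5, outerFolds = 10L, innerFolds = 9L,
                        scales = c("panss_positive", "panss_negative",
                                   "panss_total"),
                        covariates = c("age", "gender"),
                        classify = TRUE, masterSeed = 1L, verbose = FALSE) {
  say <- function(...) if (verbose) message("[", format(Sys.time(), "%H:%M:%S"),
                                            "] ", ...)
  if (is.character(cohort)) {
    say("reading cohort from ", cohort)
    cohort <- readCohort(cohort)
  } else if (is(cohort, "CohortConfig")) {
    cohort@seed <- deriveSeed(masterSeed, "simulate")
    say("simulating cohort (seed ", cohort@seed, ")")
    cohort <- generateCohort(cohort)
  }
  stopifnot(is(cohort, "TimeCourseSet"))
  if (is.null(taper)) taper <- buildTaper(trSeconds = trSeconds(cohort))
  say("computing windowed connectivity")
  dfc <- computeDFC(cohort, taper)
  say("clustering states (k = ", if (identical(k, "auto")) "auto" else k, ")")
  model <- clusterStates(dfc, k = k, kRange = kRange,
                         nReplicates = nReplicates, maxIter = maxIter,
                         seed = deriveSeed(masterSeed, "cluster"))
  transitions <- transitionFeatures(model)
  groups <- cohort@truth$nodeGroups
  summaryTab <- if (!is.null(groups))
    stateSummary(model, groups, nodeNames(cohort)) else NULL
  classification <- NULL
  if (classify) {
    classification <- lapply(seq_len(nStates(model)), function(s) {
      say("classifying state ", s)
      ds <- tryCatch(buildStateDataset(dfc, model, cohort, s),
                     error = function(e) NULL)
      if (is.null(ds)) return(NULL)
      tryCatch(
        nestedCVClassify(ds, outerFolds = outerFolds, innerFolds = innerFolds,
                         alpha = alpha,
                         seed = deriveSeed(masterSeed, paste0("classify", s))),
        error = function(e) {
          warning("state ", s, ": classification skipped (",
                  conditionMessage(e), ")")
          NULL
        })
    })
  }
  say("associating transition features with symptoms")
  association <- tryCatch(
    associateTransitions(transitions, cohort, scales = scales,
                         covariates = covariates),
    error = function(e) {
      warning("association skipped: ", conditionMessage(e))
      NULL
    })
  provenance <- list(
    package = "dfcstates",
    version = as.character(utils::packageVersion("dfcstates")),
    masterSeed = masterSeed,
    stageSeeds = list(simulate = deriveSeed(masterSeed, "simulate"),
                      cluster = deriveSeed(masterSeed, "cluster")),
    taper = list(windowTRs = taper@windowTRs, sigmaSeconds = taper@sigmaSeconds,
                 trSeconds = taper@trSeconds),
    k = nStates(model), kRange = kRange, nReplicates = nReplicates,
    alpha = alpha, outerFolds = outerFolds, innerFolds = innerFolds,
    scales = scales, covariates = covariates)
  result <- list(cohort = cohort, taper = taper, dfc = dfc, model = model,
                 transitions = transitions, stateSummary = summaryTab,
                 classification = classification, association = association,
                 provenance = provenance)
  if (!is.null(outDir)) .writePipelineOutputs(result, outDir)
  result
}

.writePipelineOutputs <- function(result, outDir) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(x, f, ...) utils::write.table(
    x, file.path(outDir, f), sep = "\t", quote = FALSE, ...)
  wt(result$model@centroids, "centroids.tsv", row.names = FALSE)
  if (nrow(result$model@inertiaCurve))
    wt(result$model@inertiaCurve, "inertia_curve.tsv", row.names = FALSE)
  assign_tab <- do.call(rbind, result$model@assignments)
  wt(cbind(id = rownames(assign_tab), as.data.frame(assign_tab)),
     "state_sequences.tsv", row.names = FALSE)
  fm <- featureMatrix(result$transitions)
  wt(cbind(id = rownames(fm), as.data.frame(fm)), "transition_features.tsv",
     row.names = FALSE)
  if (!is.null(result$stateSummary))
    wt(cbind(state = rownames(result$stateSummary), result$stateSummary),
       "state_summary.tsv", row.names = FALSE)
  if (!is.null(result$association))
    wt(result$association, "association.tsv", row.names = FALSE)
  if (!is.null(result$classification)) {
    cls <- lapply(result$classification, function(r) {
      if (is.null(r)) return(NULL)
      list(state = r$stateId, auc = r$auc,
           importance = as.list(r$importance),
           topGroup = r$topGroup$topGroup,
           groupDiff = r$groupDiff)
    })
    jsonlite::write_json(cls, file.path(outDir, "classification.json"),
                         auto_unbox = TRUE, digits = NA, na = "null",
                         pretty = TRUE)
  }
  jsonlite::write_json(result$provenance, file.path(outDir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(outDir)
}
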