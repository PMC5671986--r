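# End-to-end pipeline: simulate (or load) -> GFP -> peaks -> peak maps ->
# {K-means, FCM} per condition -> polarity merge -> label alignment ->
# MLP training per method x condition -> probabilistic labeling of the
# full timecourses -> ECDF, subject summaries and the GFP-certainty
# regression. Stage outputs are content-addressed by a hash of the stage
# configuration and its upstream hashes, so rerunning with a changed
# downstream configuration reuses the cached upstream results.

#' Pipeline configuration
#'
#' Bundles the per-module configurations; all randomness flows from the
#' single root `seed`.
#'
#' @param nSubjects number of synthetic subjects (default 8).
#' @param synth base [synthConfig()] shared by the cohort (its seed is
#'   derived from the root seed).
#' @param gainRange per-subject gain range.
#' @param conditionProfiles condition overrides, as in [generateCohort()].
#' @param clustering a [clusterConfig()] (default k = 5).
#' @param mergeThreshold polarity-merge threshold.
#' @param mlp an [mlpConfig()].
#' @param referenceModel model whose template labels anchor the
#'   relabeling, `"<method>.<condition>"` (default `"fcm.imagined"`).
#' @param ecdfProbe probability at which the per-model ECDFs are
#'   evaluated (default 0.9).
#' @param gfpCutoff optional outlier cutoff for the GFP regression.
#' @param seed root seed.
#' @return list of class `pipelineConfig`.
#' @export
pipelineConfig <- function(nSubjects = 8L,
                           synth = synthConfig(duration = 20),
                           gainRange = c(0.8, 1.6),
                           conditionProfiles = list(
                             real = list(meanDwell = 110, noiseSD = 0.5),
                             imagined = list(meanDwell = 70, noiseSD = 0.7)),
                           clustering = clusterConfig(k = 5L, m = 1.8),
                           mergeThreshold = 0.95,
                           mlp = mlpConfig(),
                           referenceModel = "fcm.imagined",
                           ecdfProbe = 0.9,
                           gfpCutoff = NULL,
                           seed = 1L) {
  stopifnot(nSubjects >= 1L, inherits(synth, "synthConfig"),
            inherits(clustering, "clusterConfig"), inherits(mlp, "mlpConfig"))
  structure(list(nSubjects = as.integer(nSubjects), synth = synth,
                 gainRange = gainRange,
                 conditionProfiles = conditionProfiles,
                 clustering = clustering, mergeThreshold = mergeThreshold,
                 mlp = mlp, referenceModel = referenceModel,
                 ecdfProbe = ecdfProbe, gfpCutoff = gfpCutoff,
                 seed = as.integer(seed)),
            class = "pipelineConfig")
}

.writeMatrixCSV <- function(m, path) {
  df <- as.data.frame(format(m, digits = 15, trim = TRUE, scientific = TRUE))
  names(df) <- paste0("c", seq_len(ncol(m)))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
}

#' Run the full pipeline
#'
#' Executes every stage in order, writing text artifacts (template maps,
#' merge logs, objectives, subject summaries, ECDFs, regression fits,
#' recovery scores) and a manifest into `outDir`. Each stage is cached
#' under a content hash of its configuration and upstream hashes;
#' rerunning in the same directory recomputes only stages whose inputs
#' changed, and rerunning with the same config and seed reproduces
#' identical numeric artifacts.
#'
#' @param cfg a [pipelineConfig()].
#' @param outDir run directory (created if missing).
#' @param verbose print per-stage progress.
#' @return (invisibly) list with the cohort, cluster results, template
#'   sets, MLP models, state sequences, subject summaries, per-model
#'   analyses, recovery scores and the manifest.
#' @export
runPipeline <- function(cfg = pipelineConfig(), outDir = tempfile("msrun"),
                        verbose = TRUE) {
  stopifnot(inherits(cfg, "pipelineConfig"))
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  cacheDir <- file.path(outDir, "cache")
  dir.create(cacheDir, showWarnings = FALSE)
  logFile <- file.path(outDir, "run.log")
  manifest <- list(package = "microstates",
                   version = as.character(utils::packageVersion("microstates")),
                   seed = cfg$seed, configHash = configHash(unclass(cfg)),
                   stages = list())

  logLine <- function(...) {
    msg <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"),
                   paste0(...))
    cat(msg, "\n", file = logFile, append = TRUE)
    if (verbose) message(msg)
  }

  runStage <- function(name, conf, depHashes, fun) {
    h <- configHash(list(name, conf, depHashes))
    cacheFile <- file.path(cacheDir, paste0(name, "-", h, ".rds"))
    t0 <- proc.time()[["elapsed"]]
    if (file.exists(cacheFile)) {
      value <- readRDS(cacheFile)
      cached <- TRUE
    } else {
      value <- tryCatch(fun(), error = function(e) {
        rec <- list(stage = name, error = conditionMessage(e))
        jsonlite::write_json(rec, file.path(outDir, "error.json"),
                             auto_unbox = TRUE)
        stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
             call. = FALSE)
      })
      saveRDS(value, cacheFile)
      cached <- FALSE
    }
    logLine(sprintf("stage %-10s %s (%.1fs)%s", name, h,
                    proc.time()[["elapsed"]] - t0,
                    if (cached) " [cached]" else ""))
    manifest$stages[[name]] <<- list(hash = h, cached = cached)
    list(value = value, hash = h)
  }

  seeds <- childSeeds(cfg$seed, 3L)
  methods <- c("kmeans", "fcm")
  conditions <- names(cfg$conditionProfiles)
  modelNames <- as.vector(outer(methods, conditions, paste, sep = "."))

  ## 1. simulate ------------------------------------------------------
  synthCfg <- cfg$synth
  synthCfg$seed <- seeds[[1L]]
  simConf <- list(nSubjects = cfg$nSubjects, synth = unclass(synthCfg),
                  gainRange = cfg$gainRange,
                  profiles = cfg$conditionProfiles)
  sim <- runStage("simulate", simConf, NULL, function() {
    generateCohort(cfg$nSubjects, synthCfg, cfg$gainRange,
                   cfg$conditionProfiles)
  })
  cohort <- sim$value

  ## 2. GFP, peaks, peak maps (pooled per condition) -------------------
  pm <- runStage("peakmaps", list(), sim$hash, function() {
    out <- list()
    for (cond in conditions) {
      entries <- cohort[grepl(paste0("\\.", cond, "$"), names(cohort))]
      mapsList <- lapply(entries, function(e) {
        rec <- rereferenceAverage(e$recording)
        g <- computeGFP(rec)
        peaks <- detectGFPPeaks(g)
        extractPeakMaps(rec, peaks)
      })
      maps <- do.call(rbind, mapsList)
      subjects <- rep(vapply(entries, function(e) subjectID(e$recording),
                             character(1L)),
                      vapply(mapsList, nrow, integer(1L)))
      out[[cond]] <- list(maps = maps, subjects = subjects)
    }
    out
  })
  peakMaps <- pm$value

  ## 3. clustering per method x condition ------------------------------
  clusterSeeds <- childSeeds(seeds[[2L]], length(modelNames))
  cl <- runStage("cluster", list(clustering = unclass(cfg$clustering),
                                 seeds = clusterSeeds),
                 pm$hash, function() {
    out <- list()
    i <- 0L
    for (cond in conditions) {
      for (method in methods) {
        i <- i + 1L
        ccfg <- cfg$clustering
        ccfg$seed <- clusterSeeds[[match(paste(method, cond, sep = "."),
                                         modelNames)]]
        ccfg$condition <- cond
        out[[paste(method, cond, sep = ".")]] <-
          if (method == "kmeans") clusterKMeans(peakMaps[[cond]]$maps, ccfg)
          else clusterFCM(peakMaps[[cond]]$maps, ccfg)
      }
    }
    out
  })
  clusters <- cl$value

  ## 4. polarity merge --------------------------------------------------
  mg <- runStage("merge", list(threshold = cfg$mergeThreshold), cl$hash,
                 function() {
    lapply(clusters, mergePolarityDuplicates,
           threshold = cfg$mergeThreshold)
  })
  merged <- mg$value

  ## 5. label alignment to the reference model --------------------------
  al <- runStage("align", list(reference = cfg$referenceModel), mg$hash,
                 function() {
    ref <- cfg$referenceModel
    if (!ref %in% names(merged)) ref <- names(merged)[1L]
    refT <- merged[[ref]]$templates
    out <- list()
    for (nm in names(merged)) {
      if (nm == ref || nStates(merged[[nm]]$templates) != nStates(refT)) {
        out[[nm]] <- merged[[nm]]
        out[[nm]]$alignedTo <- if (nm == ref) ref else NA_character_
      } else {
        alg <- alignTemplates(refT, merged[[nm]]$templates)
        ap <- applyAlignment(merged[[nm]]$templates, alg,
                             merged[[nm]]$result)
        out[[nm]] <- list(templates = ap$templates, result = ap$result,
                          alignedTo = ref)
      }
    }
    out
  })
  aligned <- al$value

  ## 6. MLP training per model ------------------------------------------
  mlpSeeds <- childSeeds(seeds[[3L]], length(modelNames))
  ml <- runStage("mlp", list(mlp = unclass(cfg$mlp), seeds = mlpSeeds),
                 al$hash, function() {
    out <- list()
    for (nm in names(aligned)) {
      cond <- sub("^[^.]+\\.", "", nm)
      mcfg <- cfg$mlp
      mcfg$seed <- mlpSeeds[[match(nm, modelNames)]]
      out[[nm]] <- trainMLP(peakMaps[[cond]]$maps,
                            hardLabels(aligned[[nm]]$result), mcfg)
    }
    out
  })
  models <- ml$value

  ## 7. probabilistic labeling of the full timecourses ------------------
  pr <- runStage("predict", list(), ml$hash, function() {
    out <- list()
    for (nm in names(models)) {
      cond <- sub("^[^.]+\\.", "", nm)
      entries <- cohort[grepl(paste0("\\.", cond, "$"), names(cohort))]
      out[[nm]] <- lapply(entries, function(e) {
        suppressWarnings(
          predictStateProbabilities(models[[nm]],
                                    rereferenceAverage(e$recording)))
      })
    }
    out
  })
  sequences <- pr$value

  ## 8. analysis ---------------------------------------------------------
  an <- runStage("analyze", list(probe = cfg$ecdfProbe,
                                 gfpCutoff = cfg$gfpCutoff), pr$hash,
                 function() {
    out <- list()
    for (nm in names(sequences)) {
      cond <- sub("^[^.]+\\.", "", nm)
      entries <- cohort[grepl(paste0("\\.", cond, "$"), names(cohort))]
      summaries <- do.call(rbind, Map(function(e, s) {
        summarizeSubject(e$recording, s)
      }, entries, sequences[[nm]]))
      ecdf <- mleEcdf(sequences[[nm]])
      glm <- if (nrow(summaries) >= 3L &&
                 stats::sd(summaries$meanGFP) > 1e-12) {
        gfpCertaintyGLM(summaries, gfpCutoff = cfg$gfpCutoff)
      } else NULL
      out[[nm]] <- list(summaries = summaries, ecdf = ecdf,
                        fractionBelowProbe = ecdfAt(ecdf, cfg$ecdfProbe),
                        glm = glm)
    }
    out
  })
  analysis <- an$value

  ## 9. recovery against ground truth ------------------------------------
  rc <- runStage("recovery", list(), c(al$hash, sim$hash), function() {
    truth <- cohort[[1L]]$truth
    lapply(aligned, function(a) scoreRecovery(a$templates, truth))
  })
  recovery <- rc$value

  ## artifacts ------------------------------------------------------------
  for (nm in names(aligned)) {
    .writeMatrixCSV(templateMaps(aligned[[nm]]$templates),
                    file.path(outDir, paste0("templates_", nm, ".csv")))
    utils::write.csv(mergeLog(aligned[[nm]]$templates),
                     file.path(outDir, paste0("mergelog_", nm, ".csv")),
                     row.names = FALSE)
    jsonlite::write_json(
      list(objective = objectiveValue(clusters[[nm]]),
           replicateObjectives = clusters[[nm]]@replicateObjectives,
           iterations = length(objectiveTrace(clusters[[nm]])),
           templatesAfterMerge = nStates(aligned[[nm]]$templates)),
      file.path(outDir, paste0("cluster_", nm, ".json")),
      auto_unbox = TRUE, digits = NA)
    utils::write.csv(analysis[[nm]]$summaries,
                     file.path(outDir, paste0("summaries_", nm, ".csv")),
                     row.names = FALSE)
    utils::write.csv(analysis[[nm]]$ecdf,
                     file.path(outDir, paste0("ecdf_", nm, ".csv")),
                     row.names = FALSE)
    fit <- analysis[[nm]]$glm
    jsonlite::write_json(
      list(fractionBelowProbe = analysis[[nm]]$fractionBelowProbe,
           glm = if (!is.null(fit)) unclass(fit) else NULL,
           recovery = recovery[[nm]]$matches),
      file.path(outDir, paste0("analysis_", nm, ".json")),
      auto_unbox = TRUE, digits = NA)
  }
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  logLine("pipeline complete: ", length(manifest$stages), " stages")

  invisible(list(cohort = cohort, peakMaps = peakMaps, clusters = clusters,
                 merged = merged, aligned = aligned, models = models,
                 sequences = sequences, analysis = analysis,
                 recovery = recovery, manifest = manifest, outDir = outDir))
}
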