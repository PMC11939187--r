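# Default pipeline configuration; validateConfig() fills unset keys from
# here and rejects keys not listed here.
.defaultPipelineConfig <- function() list(
  seed = NULL,
  output_dir = "maldiDx_out",
  synth = NULL,                 # list of cohortConfig() arguments
  input = NULL,                 # list(dir = <cohort directory>)
  preprocess = list(sgWindow = 21, sgPolyorder = 10, medianWindow = 10,
                    tophatElement = 11),
  peaks = list(minHeightFrac = 0.03, minWidthPoints = 5, tolPpm = 2500,
               matrixLo = 1500, matrixHi = 2000, excludeMatrix = FALSE,
               impute = "zero"),
  screening = list(pThresh = 0.001, fcThresh = 1, topK = 20),
  bench = list(models = c("knn", "svm", "gaussian_nb", "decision_tree",
                          "random_forest", "xgboost", "adaboost", "lgbm"),
               k = 5, testFrac = 0.2),
  interpret = list(enabled = TRUE, model = "random_forest",
                   backgroundSize = 200, shapInstances = 8,
                   shapNsamples = 256, limeInstances = 8,
                   limePerturbations = 1000, topK = 20, topM = 10),
  clinical = list(enabled = TRUE, nThresholds = 100, nFeatures = 3,
                  dcaModel = "random_forest", treatAllVariant = "as_printed"),
  cluster = list(enabled = TRUE, threshold = 0.5, branchingFactor = 50,
                 k = 2, embedding = "pca", useDifferentialFeatures = TRUE),
  plots = FALSE)

.checkBlock <- function(user, defaults, path) {
  if (is.null(user)) return(defaults)
  if (!is.list(user)) stop("'", path, "' must be a mapping/list")
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown))
    stop("unknown configuration key(s): ",
         paste0(path, ".", unknown, collapse = ", "))
  utils::modifyList(defaults, user)
}

#' Validate and default a pipeline configuration
#'
#' Accepts a YAML file path, YAML text, or a nested list; fills every
#' unset key from the package defaults, rejects unknown keys naming the
#' offending key, and type-checks the critical parameters. Exactly one of
#' the \code{synth} block (synthetic cohort arguments, see
#' \code{\link{cohortConfig}}) and the \code{input} block
#' (\code{input$dir}: a cohort directory as written by
#' \code{\link{writeCohort}}) must be present, and \code{seed} must be
#' set.
#'
#' @param raw configuration: file path, YAML string, or list.
#' @return A fully defaulted configuration list (class
#'   \code{maldiDxConfig}).
#' @export
validateConfig <- function(raw) {
  cfg <- if (is.character(raw) && length(raw) == 1) {
    if (file.exists(raw)) yaml::read_yaml(raw) else yaml::yaml.load(raw)
  } else if (is.list(raw)) raw else stop("unparseable configuration")
  defaults <- .defaultPipelineConfig()
  unknown <- setdiff(names(cfg), names(defaults))
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  out <- defaults
  for (nm in c("seed", "output_dir", "plots"))
    if (!is.null(cfg[[nm]])) out[[nm]] <- cfg[[nm]]
  out$synth <- cfg$synth
  out$input <- cfg$input
  for (nm in c("preprocess", "peaks", "screening", "bench", "interpret",
               "clinical", "cluster"))
    out[[nm]] <- .checkBlock(cfg[[nm]], defaults[[nm]], nm)
  if (is.null(out$seed)) stop("'seed' must be set")
  if (!is.numeric(out$seed)) stop("'seed' must be an integer")
  if (is.null(out$synth) == is.null(out$input))
    stop("exactly one of 'synth' and 'input' must be present")
  if (!is.null(out$synth)) {
    bad <- setdiff(names(out$synth), names(formals(cohortConfig)))
    if (length(bad))
      stop("unknown configuration key(s): ",
           paste0("synth.", bad, collapse = ", "))
  }
  if (out$peaks$tolPpm <= 0) stop("'peaks.tolPpm' must be > 0")
  if (out$peaks$minHeightFrac < 0 || out$peaks$minHeightFrac > 1)
    stop("'peaks.minHeightFrac' must lie in [0, 1]")
  if (!out$peaks$impute %in% c("zero", "interpolate"))
    stop("'peaks.impute' must be 'zero' or 'interpolate'")
  badModels <- setdiff(out$bench$models, .modelNames)
  if (length(badModels))
    stop("'bench.models' contains unknown model(s): ",
         paste(badModels, collapse = ", "))
  if (out$screening$pThresh <= 0 || out$screening$pThresh > 1)
    stop("'screening.pThresh' must lie in (0, 1]")
  structure(out, class = c("maldiDxConfig", "list"))
}

.writeFeatureCsv <- function(fm, path) {
  v <- featureValues(fm)
  colnames(v) <- sprintf("%.2f", featureMz(fm))
  df <- data.frame(sample_id = colData(fm)$sample_id,
                   label = sampleGroups(fm), v, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
}

#' Run the full diagnostic pipeline
#'
#' Executes the stages end to end — cohort synthesis (or loading),
#' spectrum preprocessing, peak detection and alignment, differential
#' screening, classifier benchmarking, attribution-based feature
#' selection, clinical validation and clustering concordance — writing
#' CSV/JSON artifacts and a run manifest into the configured output
#' directory. The global seed fans out to fixed per-stage seeds, so
#' re-running an identical configuration reproduces identical CSV/JSON
#' outputs. On a stage failure the partial outputs are retained alongside
#' a \code{FAILED} marker naming the stage, and the error is rethrown.
#'
#' @param config a configuration accepted by \code{\link{validateConfig}}.
#' @return The manifest list, invisibly.
#' @export
runPipeline <- function(config) {
  cfg <- validateConfig(config)
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(...) file.path(cfg$output_dir, ...)
  stageSeed <- function(i) as.integer(cfg$seed) + i

  cfgFile <- tempfile(fileext = ".yaml")
  yaml::write_yaml(unclass(cfg), cfgFile)
  manifest <- list(package = "maldiDx",
                   version = as.character(utils::packageVersion("maldiDx")),
                   seed = cfg$seed,
                   config_hash = unname(tools::md5sum(cfgFile)),
                   stages = list())
  unlink(cfgFile)
  done <- function(name, outputs = character(0)) {
    manifest$stages[[length(manifest$stages) + 1]] <<-
      list(name = name, status = "completed", outputs = outputs)
  }
  current <- "synth"
  tryCatch({
    # 1. cohort -------------------------------------------------------------
    cohort <- if (!is.null(cfg$synth)) {
      sc <- cfg$synth
      if (is.null(sc$seed)) sc$seed <- stageSeed(1)
      generateCohort(do.call(cohortConfig, sc))
    } else readCohort(cfg$input$dir)
    done("synth")

    # 2-3. preprocess + peaks -----------------------------------------------
    current <- "preprocess"
    pp <- cfg$preprocess
    pk <- cfg$peaks
    peakSets <- lapply(cohort$spectra, function(s)
      flagMatrixRegion(
        detectPeaks(preprocessSpectrum(s, pp$sgWindow, pp$sgPolyorder,
                                       pp$medianWindow, pp$tophatElement),
                    pk$minHeightFrac, pk$minWidthPoints),
        pk$matrixLo, pk$matrixHi, exclude = pk$excludeMatrix))
    done("preprocess")
    current <- "peaks"
    fm <- collapseReplicates(imputeMissing(
      greedyAlign(peakSets, tolPpm = pk$tolPpm), mode = pk$impute))
    .writeFeatureCsv(fm, out("feature_matrix.csv"))
    done("peaks", "feature_matrix.csv")

    # 4. screening ------------------------------------------------------------
    current <- "screening"
    sc <- cfg$screening
    vf <- volcanoFilter(differentialTest(fm), sc$pThresh, sc$fcThresh)
    utils::write.csv(vf$table, out("differential.csv"), row.names = FALSE)
    topFc <- topFeatures(vf$table, "abs_log2fc",
                         min(sc$topK, nrow(vf$table)))
    utils::write.csv(topFc, out("top_features.csv"), row.names = FALSE)
    if (isTRUE(cfg$plots)) {
      grDevices::png(out("volcano.png"), 800, 600)
      plotVolcano(vf$table, sc$pThresh, sc$fcThresh)
      grDevices::dev.off()
    }
    done("screening", c("differential.csv", "top_features.csv"))

    # 5. bench ----------------------------------------------------------------
    current <- "bench"
    evals <- benchmarkModels(fm, cfg$bench$models, k = cfg$bench$k,
                             seed = stageSeed(2))
    benchJson <- lapply(evals, function(e) list(
      model = e@modelName, macro_mean_auc = e@macroAuc,
      mean_auc = as.list(e@meanAuc), sd_auc = as.list(e@sdAuc),
      confusion = as.list(e@confusion), metrics = as.list(e@metrics)))
    jsonlite::write_json(benchJson, out("bench.json"), auto_unbox = TRUE,
                         digits = NA)
    done("bench", "bench.json")

    # 6. interpret ------------------------------------------------------------
    current <- "interpret"
    interpretOutputs <- character(0)
    if (isTRUE(cfg$interpret$enabled)) {
      ic <- cfg$interpret
      X <- featureValues(fm)
      colnames(X) <- sprintf("mz_%.2f", featureMz(fm))
      set.seed(stageSeed(3))
      fit <- trainClassifier(fm, ic$model, seed = stageSeed(3))
      gini <- modelImportances(fit, colnames(X))
      bg <- X[sample.int(nrow(X), min(ic$backgroundSize, nrow(X))), ,
              drop = FALSE]
      expl <- sample.int(nrow(X), min(ic$shapInstances, nrow(X)))
      shap <- shapAttributions(fit, bg, X[expl, , drop = FALSE],
                               nsamples = ic$shapNsamples,
                               seed = stageSeed(3))
      limeIdx <- sample.int(nrow(X), min(ic$limeInstances, nrow(X)))
      lime <- limeRankings(fit, X, explainIdx = limeIdx,
                           nPerturb = ic$limePerturbations,
                           seed = stageSeed(3))
      cons <- consensusTopK(list(gini, shap$ranking, lime), k = ic$topK)
      inter <- importanceIntersection(fm, topM = ic$topM,
                                      seed = stageSeed(3))
      utils::write.csv(gini, out("importance_gini.csv"), row.names = FALSE)
      utils::write.csv(shap$ranking, out("importance_shap.csv"),
                       row.names = FALSE)
      utils::write.csv(lime, out("importance_lime.csv"), row.names = FALSE)
      jsonlite::write_json(list(selected = cons$selected,
                                votes = as.list(cons$votes),
                                intersection = inter),
                           out("consensus.json"), auto_unbox = TRUE,
                           digits = NA)
      interpretOutputs <- c("importance_gini.csv", "importance_shap.csv",
                            "importance_lime.csv", "consensus.json")
    }
    done("interpret", interpretOutputs)

    # 7. clinical -------------------------------------------------------------
    current <- "clinical"
    clinicalOutputs <- character(0)
    if (isTRUE(cfg$clinical$enabled)) {
      cc <- cfg$clinical
      v <- featureValues(fm)
      ranked <- topFeatures(vf$table, "p", min(cc$nFeatures, nrow(vf$table)))
      rows <- lapply(seq_len(nrow(ranked)), function(i) {
        j <- which.min(abs(featureMz(fm) - ranked$mz[i]))
        roc <- singleFeatureROC(v[, j], sampleGroups(fm))
        yo <- youdenOptimize(roc$oriented, sampleGroups(fm),
                             nThresholds = cc$nThresholds)
        dca <- singleFeatureDCA(v[, j], sampleGroups(fm),
                                direction = roc$direction,
                                treatAllVariant = cc$treatAllVariant)
        data.frame(mz = ranked$mz[i], auc = roc$auc,
                   direction = roc$direction,
                   optimal_threshold = yo$optimalThreshold,
                   optimal_j = yo$optimalJ,
                   dca_benefit_area = dca$benefitArea)
      })
      utils::write.csv(do.call(rbind, rows), out("clinical_features.csv"),
                       row.names = FALSE)
      dcaM <- dcaCrossval(fm, cc$dcaModel, k = cfg$bench$k,
                          treatAllVariant = cc$treatAllVariant,
                          seed = stageSeed(4))
      utils::write.csv(data.frame(threshold = dcaM$thresholds,
                                  nb_model = dcaM$nbModel,
                                  ci_low = dcaM$ciLow, ci_high = dcaM$ciHigh,
                                  nb_all = dcaM$nbAll, nb_none = dcaM$nbNone),
                       out("dca_model.csv"), row.names = FALSE)
      if (isTRUE(cfg$plots)) {
        grDevices::png(out("dca_model.png"), 800, 600)
        plotDCA(dcaM)
        grDevices::dev.off()
      }
      clinicalOutputs <- c("clinical_features.csv", "dca_model.csv")
    }
    done("clinical", clinicalOutputs)

    # 8. cluster --------------------------------------------------------------
    current <- "cluster"
    clusterOutputs <- character(0)
    if (isTRUE(cfg$cluster$enabled)) {
      cl <- cfg$cluster
      keep <- seq_len(nrow(fm))
      if (isTRUE(cl$useDifferentialFeatures)) {
        difIdx <- which(vf$table$call != "ns")
        if (length(difIdx) >= 2) keep <- difIdx
      }
      sub <- fm[keep, ]
      bk <- bisectingKmeans(sub, k = cl$k, seed = stageSeed(5),
                            standardize = TRUE)
      bi <- birchCluster(sub, threshold = cl$threshold,
                         branchingFactor = cl$branchingFactor, k = cl$k,
                         standardize = TRUE)
      conc <- rbind(
        bisecting_kmeans = clusteringConcordance(bk, sampleGroups(fm)),
        birch = clusteringConcordance(bi, sampleGroups(fm)))
      utils::write.csv(data.frame(sample_id = colData(fm)$sample_id,
                                  group = sampleGroups(fm),
                                  bisecting_kmeans = bk, birch = bi),
                       out("cluster_assignments.csv"), row.names = FALSE)
      utils::write.csv(data.frame(method = rownames(conc), conc),
                       out("cluster_concordance.csv"), row.names = FALSE)
      emb <- embedSamples(sub, method = cl$embedding, seed = stageSeed(6))
      utils::write.csv(data.frame(sample_id = colData(fm)$sample_id, emb),
                       out("embedding.csv"), row.names = FALSE)
      clusterOutputs <- c("cluster_assignments.csv",
                          "cluster_concordance.csv", "embedding.csv")
    }
    done("cluster", clusterOutputs)
  }, error = function(e) {
    writeLines(paste("stage", current, "failed:", conditionMessage(e)),
               out("FAILED"))
    jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                         digits = NA)
    stop(e)
  })
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(manifest)
}
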