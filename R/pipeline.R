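# End-to-end orchestration: simulate (or load) -> classify -> DE ->
# select -> validate, with a manifest that makes reruns reproducible,
# plus recomputation of the packaged reference panel tables.

#' Build a pipeline run configuration
#'
#' Exactly one of `simulation` (specs for the synthetic-data module) or
#' `inputs` (paths to a GTF and expression/group TSVs) must be given.
#'
#' @param simulation list with elements `genome` ([genomeSpec()]),
#'   `study` ([studySpec()]), and optionally `validation` (list with
#'   `nPerGroup`, `effectSize`, `sdLog`).
#' @param inputs list of paths: `gtf`, `mrnaExpr`, `mrnaGroups`,
#'   `lncExpr`, `lncGroups`, and optionally `testExpr`, `testGroups`
#'   (RPKM validation study).
#' @param qThreshold q-value threshold applied to both panels.
#' @param svm list of SVM settings (`cost`, `gamma`, `k`).
#' @param seed integer seed recorded in the manifest and used for every
#'   stochastic stage.
#' @param outdir output directory.
#' @return A validated `RunConfig` list.
#' @export
runConfig <- function(simulation = NULL, inputs = NULL, qThreshold = 0.05,
                      svm = list(cost = 1, gamma = NULL, k = 5L),
                      seed = 1L, outdir = tempfile("lncolink_run_")) {
  if (is.null(simulation) == is.null(inputs))
    stop("exactly one of 'simulation' or 'inputs' must be provided")
  cfg <- list(simulation = simulation, inputs = inputs,
              qThreshold = as.numeric(qThreshold), svm = svm,
              seed = as.integer(seed), outdir = outdir)
  structure(cfg, class = "RunConfig")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file with the [runConfig()] fields; the
#'   `simulation` block holds plain lists of [genomeSpec()] /
#'   [studySpec()] arguments.
#' @param seed optional seed overriding the file's value.
#' @return A `RunConfig`.
#' @export
readRunConfig <- function(path, seed = NULL) {
  y <- yaml::read_yaml(path)
  if (!is.null(seed)) y$seed <- seed
  sim <- y$simulation
  if (!is.null(sim)) {
    sim$genome <- do.call(genomeSpec, c(sim$genome %||% list(),
                                        list(seed = y$seed %||% 1L)))
    sim$study <- do.call(studySpec, c(sim$study %||% list(),
                                      list(seed = (y$seed %||% 1L) + 1L)))
  }
  runConfig(simulation = sim, inputs = y$inputs,
            qThreshold = y$qThreshold %||% 0.05,
            svm = y$svm %||% list(cost = 1, gamma = NULL, k = 5L),
            seed = y$seed %||% 1L,
            outdir = y$outdir %||% tempfile("lncolink_run_"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full biomarker-discovery pipeline
#'
#' Stages, in order: obtain transcript models and expression studies
#' (simulated with ground truth, or loaded from the configured files);
#' map lncRNA-mRNA positional relationships; run Box-Cox/Welch/q-value
#' differential expression separately on the mRNA and lncRNA panels;
#' select paired-significant biomarkers; average the selected panel to
#' gene level, min-max normalize, and validate with a stratified
#' five-fold RBF-SVM plus a cross-platform blind test on the RPKM-style
#' study. All stage outputs are written under `config$outdir` with a
#' manifest (seed, thresholds, package version, file checksums); a
#' rerun with the same config is bit-identical.
#'
#' @param config a [runConfig()].
#' @return Invisibly, a list with all stage results (`calls`, `mrnaDE`,
#'   `lncDE`, `biomarkers`, `tally`, `genes`, `cv`, `crossPlatform`,
#'   `truth` when simulated, `manifest`).
#' @export
runPipeline <- function(config) {
  stopifnot(inherits(config, "RunConfig"))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  step <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  truth <- NULL
  if (!is.null(config$simulation)) {
    sim <- config$simulation
    pairs <- step("simulate", simulateTranscriptPairs(sim$genome))
    studies <- step("simulate", simulateExpressionStudy(pairs, sim$study))
    truth <- studies$truth
    lncs <- lapply(pairs, `[[`, "lnc")
    mrnas <- lapply(pairs, `[[`, "mrna")
    mrnaStudy <- studies$mrna; lncStudy <- studies$lnc
    geneMap <- stats::setNames(vapply(mrnas, geneId, ""),
                               vapply(mrnas, transcriptId, ""))
    step("simulate", writeTranscripts(c(lncs, mrnas),
                                      file.path(config$outdir, "transcripts.gtf")))
  } else {
    inp <- config$inputs
    models <- step("load", readTranscripts(inp$gtf))
    bt <- vapply(models, txBiotype, "")
    lncs <- models[bt == "lncRNA"]; mrnas <- models[bt == "mRNA"]
    mrnaStudy <- step("load", readExpressionStudy(inp$mrnaExpr,
                                                  inp$mrnaGroups, "microarray"))
    lncStudy <- step("load", readExpressionStudy(inp$lncExpr,
                                                 inp$lncGroups, "microarray"))
    geneMap <- stats::setNames(vapply(mrnas, geneId, ""),
                               vapply(mrnas, transcriptId, ""))
  }

  calls <- step("classify", mapRelationships(lncs, mrnas))
  writeRelationshipCalls(calls, file.path(config$outdir, "relationships.tsv"))

  mrnaDE <- step("de", runDE(mrnaStudy))
  lncDE <- step("de", runDE(lncStudy))
  writeDETable(mrnaDE, file.path(config$outdir, "de_mrna.tsv"))
  writeDETable(lncDE, file.path(config$outdir, "de_lnc.tsv"))

  biomarkers <- step("select", selectBiomarkers(mrnaDE, lncDE, calls,
                                                qThreshold = config$qThreshold,
                                                geneMap = geneMap))
  tally <- tallyRelationships(biomarkers)
  genes <- collapseToGenes(biomarkers)
  utils::write.table(biomarkers, file.path(config$outdir, "biomarkers.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(relationship = names(tally),
                                count = as.integer(tally)),
                     file.path(config$outdir, "relationship_tally.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  cv <- NULL; xp <- NULL
  if (length(genes) >= 2L) {
    svmCfg <- config$svm
    geneTrain <- step("validate",
                      averageByGene(
                        expressionStudy(exprValues(mrnaStudy)[biomarkers$mrna_id[!duplicated(biomarkers$mrna_id)], , drop = FALSE],
                                        sampleGroups(mrnaStudy), "microarray"),
                        geneMap))
    cv <- step("validate",
               crossvalidateSvm(minmaxNormalize(geneTrain),
                                k = svmCfg$k %||% 5L, seed = config$seed,
                                cost = svmCfg$cost %||% 1,
                                gamma = svmCfg$gamma))
    testStudy <- NULL
    if (!is.null(config$simulation)) {
      val <- config$simulation$validation %||% list()
      dirs <- .panelDirections(biomarkers, truth, geneMap)
      testStudy <- simulateValidationRnaseq(
        genes, nPerGroup = val$nPerGroup %||% 21L,
        effectSize = val$effectSize %||% config$simulation$study$effectSize,
        directions = dirs, seed = config$seed + 2L,
        sdLog = val$sdLog %||% 0.6)
    } else if (!is.null(config$inputs$testExpr)) {
      testStudy <- step("load", readExpressionStudy(config$inputs$testExpr,
                                                    config$inputs$testGroups,
                                                    "rnaseq"))
    }
    if (!is.null(testStudy))
      xp <- step("validate",
                 crossPlatformEval(geneTrain, testStudy, genes,
                                   seed = config$seed,
                                   k = svmCfg$k %||% 5L,
                                   cost = svmCfg$cost %||% 1,
                                   gamma = svmCfg$gamma))
  }

  report <- list(cv = if (!is.null(cv)) cv[c("confusion", "report")],
                 crossPlatform = if (!is.null(xp)) xp[c("confusion", "report",
                                                        "hyperparameters")])
  jsonlite::write_json(report, file.path(config$outdir, "validation.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  files <- list.files(config$outdir, full.names = TRUE)
  files <- files[basename(files) != "manifest.json"]
  manifest <- list(
    package = "lncoLink",
    version = as.character(utils::packageVersion("lncoLink")),
    seed = config$seed, qThreshold = config$qThreshold,
    svm = list(cost = config$svm$cost %||% 1,
               gamma = config$svm$gamma %||% "1/n_features",
               k = config$svm$k %||% 5L),
    mode = if (is.null(config$simulation)) "real" else "simulation",
    checksums = as.list(tools::md5sum(sort(files))))
  names(manifest$checksums) <- basename(names(manifest$checksums))
  jsonlite::write_json(manifest, file.path(config$outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(calls = calls, mrnaDE = mrnaDE, lncDE = lncDE,
                 biomarkers = biomarkers, tally = tally, genes = genes,
                 cv = cv, crossPlatform = xp, truth = truth,
                 manifest = manifest))
}

# planted direction per selected panel gene, taken from the truth table
.panelDirections <- function(biomarkers, truth, geneMap) {
  if (is.null(truth)) return(NULL)
  planted <- truth[truth$planted %in% TRUE, , drop = FALSE]
  dirs <- stats::setNames(planted$mrna_direction,
                          unname(geneMap[planted$mrna_id]))
  dirs[!is.na(names(dirs))]
}

#' Recompute the packaged reference tables
#'
#' Recomputes, from the packaged fixtures alone, (a) the relationship
#' tally and unique-gene count of the published 41-probe biomarker
#' panel and (b) every printed metric cell of the published SVM
#' confusion matrices, and compares each against the printed values
#' stored with the fixtures.
#'
#' @return data.frame with columns `check`, `expected`, `computed`,
#'   `pass`; attribute `"all_pass"`.
#' @export
reproduceReferenceTables <- function() {
  .checkFixtureChecksums()
  panel <- loadBiomarkerPanel()
  tally <- tallyRelationships(panel)
  expTally <- c(natural_antisense = 16L, bidirectional = 9L,
                exon_sense_overlapping = 7L, intronic_antisense = 6L,
                intron_sense_overlapping = 2L, sense_overlap = 1L)
  rows <- lapply(names(expTally), function(ct)
    data.frame(check = paste0("tally_", ct), expected = expTally[[ct]],
               computed = as.numeric(tally[[ct]]),
               stringsAsFactors = FALSE))
  rows <- c(rows, list(
    data.frame(check = "panel_records", expected = 41,
               computed = nrow(panel), stringsAsFactors = FALSE),
    data.frame(check = "panel_genes", expected = 38,
               computed = length(collapseToGenes(panel)),
               stringsAsFactors = FALSE)))
  cms <- loadConfusionFixtures()
  for (i in seq_len(nrow(cms))) {
    met <- confusionMetrics(cms[i, c("tp", "fp", "fn", "tn")])
    for (m in c("sensitivity", "specificity", "precision", "accuracy")) {
      printed <- cms[i, paste0(m, "_pct")]
      rows <- c(rows, list(data.frame(
        check = paste0(cms$dataset[i], "_", m, "_pct"),
        expected = printed, computed = round(met[[m]] * 100, 1),
        stringsAsFactors = FALSE)))
    }
  }
  out <- do.call(rbind, rows)
  out$pass <- abs(out$expected - out$computed) < 0.051
  attr(out, "all_pass") <- all(out$pass)
  out
}

#' Load the packaged SVM confusion-matrix fixtures
#'
#' Published confusion matrices (positive class = HCC) for the
#' five-fold-validated training set, the held-out 8+8 test set, and the
#' cross-platform RNA-seq blind test set, together with the printed
#' metric values.
#'
#' @return data.frame with columns `dataset`, `tp`, `fp`, `fn`, `tn`
#'   and the printed `*_pct` metrics and `auc`.
#' @export
loadConfusionFixtures <- function() {
  path <- system.file("extdata", "svm_confusion_matrices.tsv",
                      package = "lncoLink", mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE)
}

.FIXTURE_MD5 <- c(
  "hcc_biomarker_panel.tsv" = "2705ff1cd3a067a2a1f334119c3ebade",
  "svm_confusion_matrices.tsv" = "d43d6335d3afea174b612b2cf238c867")

.checkFixtureChecksums <- function() {
  for (f in c("hcc_biomarker_panel.tsv", "svm_confusion_matrices.tsv")) {
    path <- system.file("extdata", f, package = "lncoLink", mustWork = TRUE)
    md5 <- unname(tools::md5sum(path))
    expected <- .FIXTURE_MD5[[f]]
    if (!is.na(expected) && !identical(md5, expected))
      stop("fixture checksum mismatch for ", f,
           " (expected ", expected, ", got ", md5, ")")
  }
  invisible(TRUE)
}
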