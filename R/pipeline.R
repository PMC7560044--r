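#' @include AllClasses.R align.R comsia.R pls.R validation.R contour.R endpoints.R fixtures.R
NULL

#' Default pipeline configuration
#'
#' @param outDir output directory for stage artifacts.
#' @param seed integer seed for conformer embedding.
#' @return a validated configuration list; fields: \code{smilesFile},
#'   \code{activityFile} (NULL = shipped fixtures), \code{templateId},
#'   \code{parentId}, \code{spacing}, \code{margin}, \code{alpha},
#'   \code{filterSD}, \code{maxComponents}, \code{favPct}, \code{disfavPct},
#'   \code{seed}, \code{outDir}.
#' @export
defaultConfig <- function(outDir = tempfile("quinsar-run-"), seed = 1L) {
  validateConfig(list(
    smilesFile = NULL, activityFile = NULL,
    templateId = "Trovafloxacin", parentId = "Trovafloxacin",
    spacing = 2, margin = 4, alpha = 0.3, filterSD = 0.05,
    maxComponents = 10, favPct = 80, disfavPct = 20,
    seed = as.integer(seed), outDir = outDir
  ))
}

#' Validate a pipeline configuration
#'
#' Checks types and ranges before any stage runs; every output embeds the
#' full configuration for provenance.
#'
#' @param config configuration list (see \code{\link{defaultConfig}}).
#' @return the config, invisibly normalized; errors on the first violation.
#' @export
validateConfig <- function(config) {
  num <- function(x) is.numeric(x) && length(x) == 1 && is.finite(x)
  if (!num(config$spacing) || config$spacing <= 0) {
    stop("config: spacing must be a positive number", call. = FALSE)
  }
  if (!num(config$margin) || config$margin < 0) {
    stop("config: margin must be non-negative", call. = FALSE)
  }
  if (!num(config$alpha) || config$alpha <= 0) {
    stop("config: alpha must be positive", call. = FALSE)
  }
  if (!num(config$filterSD) || config$filterSD < 0) {
    stop("config: filterSD must be non-negative", call. = FALSE)
  }
  if (!num(config$maxComponents) || config$maxComponents < 1) {
    stop("config: maxComponents must be >= 1", call. = FALSE)
  }
  if (!num(config$favPct) || !num(config$disfavPct) ||
      config$favPct <= config$disfavPct) {
    stop("config: favored percentile must exceed the disfavored percentile",
         call. = FALSE)
  }
  if (!num(config$seed)) stop("config: seed must be a number", call. = FALSE)
  if (!is.character(config$templateId) || !nzchar(config$templateId)) {
    stop("config: templateId required", call. = FALSE)
  }
  invisible(config)
}

#' Run the full modelling workflow
#'
#' Stages, in order: prepare (3-D conformers, charges, weights), align on
#' the shared core, compute fields, select components and fit the PLS model,
#' validate externally on the designated test compounds, derive contour
#' maps, enumerate registry derivatives, screen derivatives for lower
#' predicted binding, and run the post-analysis arithmetic on the shipped
#' endpoint tables. A stage error is recorded and dependent stages are
#' skipped; independent stages still run.
#'
#' @param config configuration list from \code{\link{defaultConfig}} (or a
#'   modified copy), validated before execution.
#' @return (invisibly) a report list with per-stage outputs, errors, and the
#'   configuration; artifacts (model JSON, validation CSV, screening CSV,
#'   contour table) are written under \code{config$outDir}.
#' @export
runPipeline <- function(config = defaultConfig()) {
  validateConfig(config)
  dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)
  report <- list(config = config, errors = list())
  fail <- function(stage, e) {
    report$errors[[stage]] <<- conditionMessage(e)
    NULL
  }

  activity <- tryCatch({
    if (is.null(config$activityFile)) loadFixture("table1")
    else utils::read.csv(config$activityFile, stringsAsFactors = FALSE)
  }, error = function(e) fail("activity", e))
  structures <- tryCatch({
    if (is.null(config$smilesFile)) loadFixture("quinolones")
    else readSmilesFile(config$smilesFile)
  }, error = function(e) fail("structures", e))

  mols <- if (!is.null(structures)) tryCatch(
    prepareMolecules(stats::setNames(structures$smiles, structures$id),
                     seed = config$seed),
    error = function(e) fail("prepare", e))
  aset <- if (!is.null(mols)) tryCatch(
    alignSet(mols, quinoloneCoreSpec(templateId = config$templateId)),
    error = function(e) fail("align", e))

  fitres <- NULL
  if (!is.null(aset) && !is.null(activity)) {
    fitres <- tryCatch({
      train <- activity[activity$set == "train", ]
      test <- activity[activity$set == "test", ]
      trainSet <- new("AlignedSet", template = aset@template,
                      members = aset@members[train$compound],
                      coreRmsd = aset@coreRmsd[train$compound],
                      coreIdx = aset@coreIdx[train$compound],
                      spec = aset@spec)
      grid <- buildGrid(aset, config$spacing, config$margin)
      probe <- probeSpec(alpha = config$alpha)
      dmAll <- computeDescriptorMatrix(aset, grid = grid, probe = probe,
                                       filterSD = config$filterSD)
      # restrict to the training rows but keep the full-set column layout
      dmTrain <- dmAll
      for (k in names(dmTrain@blocks)) {
        dmTrain@blocks[[k]] <-
          dmTrain@blocks[[k]][train$compound, , drop = FALSE]
      }
      res <- comsiaModel(dmTrain, train$experimental,
                         maxComponents = config$maxComponents)
      XAll <- plsMatrix(dmAll)
      pred <- predictPLS(res$model, XAll[test$compound, , drop = FALSE])
      val <- externalValidation(test$experimental, pred, train$experimental,
                                ids = test$compound)
      serializeModel(res$model, file.path(config$outDir, "model.json"))
      exportValidation(val, csv = file.path(config$outDir, "validation.csv"),
                       json = file.path(config$outDir, "validation.json"))
      c(res, list(validation = val, dmAll = dmAll, train = train,
                  test = test))
    }, error = function(e) fail("fit", e))
  }

  contours <- if (!is.null(fitres)) tryCatch({
    map <- stdevCoeffMap(fitres$model, fitres$descriptors,
                         config$favPct, config$disfavPct)
    exportContours(map, file.path(config$outDir, "contours.tsv"))
    map
  }, error = function(e) fail("contours", e))

  derivatives <- tryCatch(enumerateDerivatives(),
                          error = function(e) fail("derivatives", e))

  screening <- tryCatch({
    t2 <- loadFixture("table2")
    parent <- activity$experimental[activity$compound == config$parentId]
    scr <- screenLowerBinding(
      data.frame(name = t2$name, logfb = t2$logfb_pred), parent
    )
    out <- data.frame(
      name = t2$name,
      logfb = t2$logfb_pred,
      fb = logFbToFb(t2$logfb_pred),
      relativeChangePct = relativeChange(logFbToFb(t2$logfb_pred),
                                         logFbToFb(parent)),
      lowerBinding = t2$name %in% scr,
      stringsAsFactors = FALSE
    )
    utils::write.csv(out, file.path(config$outDir, "screening.csv"),
                     row.names = FALSE)
    list(table = out, selected = scr)
  }, error = function(e) fail("screen", e))

  report$molecules <- mols
  report$alignedSet <- aset
  report$fit <- fitres
  report$contours <- contours
  report$derivatives <- derivatives
  report$screening <- screening
  report$ok <- length(report$errors) == 0L
  invisible(report)
}
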