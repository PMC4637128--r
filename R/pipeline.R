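#' Run the full classification chain on one image pair
#'
#' Registration, focus and artefact QC, segmentation, per-cell measurement
#' and QC, dark-cell pre-classification, and discriminant classification
#' with image-level aggregation. Out-of-focus images, failed registrations
#' and artefact-dominated images are rejected with a named reason. When
#' every QC-passed cell is dark the image short-circuits to negative and the
#' discriminant model is never evaluated.
#'
#' @param pair a [ChannelPair-class].
#' @param model a [TrainedClassifier-class] (may be `NULL` for an all-dark
#'   slide; reaching a non-dark cell without a model is an error).
#' @param cfg a [RunConfig-class].
#' @return list with `call` ([ImageCall-class]), `qc` ([ImageQC-class]),
#'   `seg` ([SegmentationResult-class]), `cells` (the [measureCells()]
#'   result) and `cellCalls` (list of [CellCall-class]).
#' @export
processPair <- function(pair, model = NULL, cfg = runConfig()) {
  q <- imageQC(pair, cfg)
  reject <- function(reason) {
    list(call = new("ImageCall", biochipId = pair@biochipId,
                    sampleId = pair@sampleId,
                    dilutionFactor = pair@dilutionFactor,
                    verdict = "rejected_qc", rejectReason = reason,
                    nCellsTotal = 0L, nCellsClassified = 0L,
                    fractionPositive = NA_real_, titerEstimate = "negative",
                    confidence = 0, classifierEvals = 0L),
         qc = q$qc, seg = NULL, cells = NULL, cellCalls = list())
  }
  if (q$qc@registrationFailed) return(reject("registration_failed"))
  if (!q$qc@inFocus) return(reject("out_of_focus"))
  if (q$qc@artefactAreaFraction > cfg@artefactAreaFractionMax)
    return(reject("artefact_area"))
  seg <- segmentCells(q$pair@red, q$qc@artefactMask, cfg)
  cells <- measureCells(seg, q$pair@green, q$pair@red, cfg, q$qc@artefactMask)
  evaluable <- vapply(cells$records, function(r)
    isTRUE(r@qcPass) && isTRUE(r@orientationReliable), logical(1))
  if (!any(evaluable)) {
    out <- reject("no_evaluable_cells")
    out$call@nCellsTotal <- seg@nComponents
    out$seg <- seg; out$cells <- cells
    return(out)
  }
  dark <- vapply(cells$records, function(r) isTRUE(r@isDark), logical(1))
  bgMean <- cells$background[["mean"]]
  if (all(dark[evaluable])) {
    # all cells dark: image is negative, no discriminant evaluation
    cellCalls <- lapply(which(evaluable), function(i)
      new("CellCall", cellId = cells$records[[i]]@cellId, label = "negative",
          kinetoplastBrightness = extractKinetoplastBrightness(
            cells$profiles[[i]], bgMean, cfg),
          posterior = NA_real_))
    call <- classifyImage(cellCalls, cfg, biochipId = pair@biochipId,
                          sampleId = pair@sampleId,
                          dilutionFactor = pair@dilutionFactor,
                          classifierEvals = 0L)
    call@nCellsTotal <- seg@nComponents
    return(list(call = call, qc = q$qc, seg = seg, cells = cells,
                cellCalls = cellCalls))
  }
  if (is.null(model))
    stop("non-dark cells present but no classifier model supplied")
  before <- classifierInvocations()
  cellCalls <- lapply(seq_along(cells$records), function(i)
    classifyCell(cells$profiles[[i]], cells$records[[i]], model, bgMean, cfg))
  evals <- classifierInvocations() - before
  call <- classifyImage(cellCalls, cfg, biochipId = pair@biochipId,
                        sampleId = pair@sampleId,
                        dilutionFactor = pair@dilutionFactor,
                        classifierEvals = as.integer(evals))
  list(call = call, qc = q$qc, seg = seg, cells = cells,
       cellCalls = cellCalls)
}

#' Process a whole slide and merge per-sample dilutions
#'
#' @param pairs list of [ChannelPair-class] objects (e.g. loaded via
#'   [discoverSlide()] and [loadChannelPair()]).
#' @param model a [TrainedClassifier-class] or `NULL`.
#' @param cfg a [RunConfig-class].
#' @return list with `imageCalls` (list of [ImageCall-class]), `samples`
#'   (list of [SampleResult-class], one per sample id) and `imageTable` /
#'   `sampleTable` (data.frame renderings).
#' @export
processSlide <- function(pairs, model = NULL, cfg = runConfig()) {
  results <- lapply(pairs, processPair, model = model, cfg = cfg)
  calls <- lapply(results, `[[`, "call")
  sampleIds <- vapply(calls, function(x) x@sampleId, character(1))
  samples <- lapply(unique(sampleIds), function(s)
    mergeDilutions(calls[sampleIds == s], cfg))
  list(imageCalls = calls, samples = samples,
       imageTable = imageCallTable(calls),
       sampleTable = sampleResultTable(samples))
}

#' Tabulate image calls / sample results
#'
#' @param calls list of [ImageCall-class].
#' @return data.frame, one row per image (or per sample).
#' @export
imageCallTable <- function(calls) {
  do.call(rbind, lapply(calls, function(x) data.frame(
    sample_id = x@sampleId, biochip_id = x@biochipId,
    dilution_factor = x@dilutionFactor, verdict = x@verdict,
    reject_reason = if (length(x@rejectReason)) x@rejectReason else "",
    n_cells_total = x@nCellsTotal, n_cells_classified = x@nCellsClassified,
    fraction_positive = x@fractionPositive, titer_estimate = x@titerEstimate,
    confidence = x@confidence, classifier_evals = x@classifierEvals,
    stringsAsFactors = FALSE)))
}

#' @rdname imageCallTable
#' @param samples list of [SampleResult-class].
#' @export
sampleResultTable <- function(samples) {
  do.call(rbind, lapply(samples, function(x) data.frame(
    sample_id = x@sampleId, verdict = x@verdict, final_titer = x@finalTiter,
    n_images = length(x@imageCalls), confidence = x@confidence,
    stringsAsFactors = FALSE)))
}

#' Build a labelled training table from simulated images
#'
#' Simulates frames (balanced kinetoplast status, nucleus and basal body
#' fluorescing independently so all six call archetypes occur), runs
#' segmentation and cell measurement, matches every QC-passed cell to the
#' nearest ground-truth centroid, and collects profile features with the
#' true kinetoplast label until `nPerClass` cells of each class are
#' available. This emulates the expert-labelled reference cell database the
#' discriminant is normally trained on.
#'
#' @param nPerClass cells wanted per class.
#' @param simCfg a [SimConfig-class] template; `positiveFraction` is forced
#'   to 0.5 and seeds are drawn per frame from `seed`.
#' @param cfg a [RunConfig-class].
#' @param seed base RNG seed.
#' @param maxImages simulation budget.
#' @param matchRadius maximum centroid distance (px) for truth matching.
#' @return data.frame with `label` plus the [measureCells()] feature
#'   columns.
#' @export
buildTrainingTable <- function(nPerClass = 1000L, simCfg = simConfig(),
                               cfg = runConfig(), seed = 1L,
                               maxImages = 1000L, matchRadius = 10) {
  simCfg@positiveFraction <- 0.5
  got0 <- 0L; got1 <- 0L
  out <- list()
  for (i in seq_len(maxImages)) {
    if (got0 >= nPerClass && got1 >= nPerClass) break
    simCfg@rngSeed <- as.integer((seed + i * 7919) %% .Machine$integer.max)
    sim <- simulateImage(simCfg)
    if (nrow(sim$truth$cells) == 0L) next
    seg <- segmentCells(sim$red, NULL, cfg)
    cells <- measureCells(seg, sim$green, sim$red, cfg)
    if (is.null(cells$table)) next
    tab <- cells$table[cells$table$qc_pass & cells$table$orientation_reliable, ,
                       drop = FALSE]
    if (nrow(tab) == 0L) next
    d2 <- outer(tab$centroid_row, sim$truth$cells$row, "-")^2 +
      outer(tab$centroid_col, sim$truth$cells$col, "-")^2
    nearest <- apply(d2, 1L, which.min)
    okMatch <- sqrt(d2[cbind(seq_len(nrow(tab)), nearest)]) <= matchRadius
    tab <- tab[okMatch, , drop = FALSE]
    if (nrow(tab) == 0L) next
    tab$label <- sim$truth$cells$is_positive[nearest[okMatch]]
    take1 <- tab[tab$label & got1 < nPerClass, , drop = FALSE]
    take0 <- tab[!tab$label & got0 < nPerClass, , drop = FALSE]
    if (nrow(take1) > nPerClass - got1)
      take1 <- take1[seq_len(nPerClass - got1), , drop = FALSE]
    if (nrow(take0) > nPerClass - got0)
      take0 <- take0[seq_len(nPerClass - got0), , drop = FALSE]
    got1 <- got1 + nrow(take1); got0 <- got0 + nrow(take0)
    out[[length(out) + 1L]] <- rbind(take1, take0)
  }
  if (got0 < nPerClass || got1 < nPerClass)
    warning("training table incomplete: ", got0, " negative / ", got1,
            " positive cells collected")
  tab <- do.call(rbind, out)
  rownames(tab) <- NULL
  tab
}
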