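# Accessor generics and show methods. Slot access from user code should go
# through these, not through @.

#' @name clift-accessors
#' @title Accessors for clift result objects
#' @description Read-only accessors for the S4 containers produced by the
#'   pipeline. Each returns the obvious scalar, vector or matrix.
#' @param x a clift S4 object.
#' @return The requested component.
NULL

#' @rdname clift-accessors
#' @export
setGeneric("greenChannel", function(x) standardGeneric("greenChannel"))
#' @rdname clift-accessors
#' @export
setGeneric("redChannel", function(x) standardGeneric("redChannel"))
#' @rdname clift-accessors
#' @export
setGeneric("labelImage", function(x) standardGeneric("labelImage"))
#' @rdname clift-accessors
#' @export
setGeneric("nComponents", function(x) standardGeneric("nComponents"))
#' @rdname clift-accessors
#' @export
setGeneric("verdict", function(x) standardGeneric("verdict"))
#' @rdname clift-accessors
#' @export
setGeneric("titerEstimate", function(x) standardGeneric("titerEstimate"))
#' @rdname clift-accessors
#' @export
setGeneric("fractionPositive", function(x) standardGeneric("fractionPositive"))
#' @rdname clift-accessors
#' @export
setGeneric("confidence", function(x) standardGeneric("confidence"))
#' @rdname clift-accessors
#' @export
setGeneric("focusScore", function(x) standardGeneric("focusScore"))
#' @rdname clift-accessors
#' @export
setGeneric("isInFocus", function(x) standardGeneric("isInFocus"))
#' @rdname clift-accessors
#' @export
setGeneric("artefactMask", function(x) standardGeneric("artefactMask"))
#' @rdname clift-accessors
#' @export
setGeneric("artefactAreaFraction", function(x) standardGeneric("artefactAreaFraction"))
#' @rdname clift-accessors
#' @export
setGeneric("registrationShift", function(x) standardGeneric("registrationShift"))
#' @rdname clift-accessors
#' @export
setGeneric("profileValues", function(x) standardGeneric("profileValues"))
#' @rdname clift-accessors
#' @export
setGeneric("profileSpread", function(x) standardGeneric("profileSpread"))
#' @rdname clift-accessors
#' @export
setGeneric("qcPass", function(x) standardGeneric("qcPass"))
#' @rdname clift-accessors
#' @export
setGeneric("qcReasons", function(x) standardGeneric("qcReasons"))
#' @rdname clift-accessors
#' @export
setGeneric("isDark", function(x) standardGeneric("isDark"))
#' @rdname clift-accessors
#' @export
setGeneric("cellLabel", function(x) standardGeneric("cellLabel"))
#' @rdname clift-accessors
#' @export
setGeneric("kinetoplastBrightness", function(x) standardGeneric("kinetoplastBrightness"))
#' @rdname clift-accessors
#' @export
setGeneric("sensitivity", function(x) standardGeneric("sensitivity"))
#' @rdname clift-accessors
#' @export
setGeneric("specificity", function(x) standardGeneric("specificity"))
#' @rdname clift-accessors
#' @export
setGeneric("accuracy", function(x) standardGeneric("accuracy"))
#' @rdname clift-accessors
#' @export
setGeneric("finalTiter", function(x) standardGeneric("finalTiter"))
#' @rdname clift-accessors
#' @export
setGeneric("imageCalls", function(x) standardGeneric("imageCalls"))

setMethod("greenChannel", "ChannelPair", function(x) x@green)
setMethod("redChannel", "ChannelPair", function(x) x@red)
setMethod("labelImage", "SegmentationResult", function(x) x@labelImage)
setMethod("nComponents", "SegmentationResult", function(x) x@nComponents)
setMethod("verdict", "ImageCall", function(x) x@verdict)
setMethod("verdict", "SampleResult", function(x) x@verdict)
setMethod("titerEstimate", "ImageCall", function(x) x@titerEstimate)
setMethod("fractionPositive", "ImageCall", function(x) x@fractionPositive)
setMethod("confidence", "ImageCall", function(x) x@confidence)
setMethod("confidence", "SampleResult", function(x) x@confidence)
setMethod("focusScore", "ImageQC", function(x) x@focusScore)
setMethod("isInFocus", "ImageQC", function(x) x@inFocus)
setMethod("artefactMask", "ImageQC", function(x) x@artefactMask)
setMethod("artefactAreaFraction", "ImageQC", function(x) x@artefactAreaFraction)
setMethod("registrationShift", "ImageQC", function(x) x@registrationShift)
setMethod("profileValues", "AxisProfile", function(x) x@values)
setMethod("profileSpread", "AxisProfile", function(x) x@spread)
setMethod("qcPass", "CellRecord", function(x) x@qcPass)
setMethod("qcReasons", "CellRecord", function(x) x@qcReasons)
setMethod("isDark", "CellRecord", function(x) x@isDark)
setMethod("cellLabel", "CellCall", function(x) x@label)
setMethod("kinetoplastBrightness", "CellCall", function(x) x@kinetoplastBrightness)
setMethod("sensitivity", "ConfusionSummary", function(x) x@sensitivity)
setMethod("specificity", "ConfusionSummary", function(x) x@specificity)
setMethod("accuracy", "ConfusionSummary", function(x) x@accuracy)
setMethod("finalTiter", "SampleResult", function(x) x@finalTiter)
setMethod("imageCalls", "SampleResult", function(x) x@imageCalls)

setMethod("show", "ChannelPair", function(object) {
  d <- dim(object@red)
  cat(sprintf("ChannelPair %s / biochip %s: %d x %d, %d-bit, dilution 1:%g\n",
              object@sampleId, object@biochipId, d[1], d[2],
              object@bitDepth, object@dilutionFactor))
})

setMethod("show", "SegmentationResult", function(object) {
  cat(sprintf("SegmentationResult: %d component(s) in a %d x %d frame\n",
              object@nComponents, nrow(object@labelImage),
              ncol(object@labelImage)))
})

setMethod("show", "ImageQC", function(object) {
  cat(sprintf(
    "ImageQC: focus %.4g (%s), artefact fraction %.3f, shift (%d, %d)%s\n",
    object@focusScore, if (object@inFocus) "in focus" else "OUT OF FOCUS",
    object@artefactAreaFraction, object@registrationShift[1],
    object@registrationShift[2],
    if (object@registrationFailed) ", REGISTRATION FAILED" else ""))
})

setMethod("show", "CellRecord", function(object) {
  cat(sprintf(
    "CellRecord %d: area %d px, aspect %.2f, solidity %.3f, QC %s%s\n",
    object@cellId, object@areaPx, object@aspectRatio, object@solidity,
    if (object@qcPass) "pass" else
      paste0("fail (", paste(object@qcReasons, collapse = ", "), ")"),
    if (isTRUE(object@isDark)) ", dark" else ""))
})

setMethod("show", "AxisProfile", function(object) {
  cat(sprintf("AxisProfile: %d bins over %.1f px%s\n",
              length(object@values), object@lengthPx,
              if (object@orientationCanonical) " (canonical)" else ""))
})

setMethod("show", "TrainedClassifier", function(object) {
  cat(sprintf(
    "TrainedClassifier (v%s): %d features, n = %d neg / %d pos, training accuracy %.3f\n",
    object@version, length(object@weights),
    object@nPerClass[["negative"]], object@nPerClass[["positive"]],
    object@trainingAccuracy))
})

setMethod("show", "CellCall", function(object) {
  cat(sprintf("CellCall %d: %s, kinetoplast brightness %.4f\n",
              object@cellId, object@label, object@kinetoplastBrightness))
})

setMethod("show", "ImageCall", function(object) {
  cat(sprintf(
    "ImageCall %s/%s (1:%g): %s, %d/%d cells classified, fraction positive %.2f, titer %s, confidence %.2f\n",
    object@sampleId, object@biochipId, object@dilutionFactor, object@verdict,
    object@nCellsClassified, object@nCellsTotal, object@fractionPositive,
    object@titerEstimate, object@confidence))
})

setMethod("show", "SampleResult", function(object) {
  cat(sprintf("SampleResult %s: %s, final titer %s, confidence %.2f (%d image(s))\n",
              object@sampleId, object@verdict, object@finalTiter,
              object@confidence, length(object@imageCalls)))
})

setMethod("show", "ConfusionSummary", function(object) {
  fmt <- function(x) if (is.na(x)) "n/a" else sprintf("%.1f%%", pctHalfUp(x))
  cat(sprintf(
    "ConfusionSummary: TP %d, FP %d, FN %d, TN %d | sensitivity %s, specificity %s, accuracy %s\n",
    object@tp, object@fp, object@fn, object@tn, fmt(object@sensitivity),
    fmt(object@specificity), fmt(object@accuracy)))
})

setMethod("show", "SimConfig", function(object) {
  cat(sprintf(
    "SimConfig: %d x %d px, %d cell(s), positive fraction %.2f, noise sd %.3f, blur %.1f, seed %d\n",
    object@imageWidth, object@imageHeight, object@nCells,
    object@positiveFraction, object@noiseSd, object@blurSigma, object@rngSeed))
})

setMethod("show", "RunConfig", function(object) {
  cat(sprintf(
    "RunConfig: cutoff %.2f, %d profile bins, titer steps %s, dark-cell k %.1f\n",
    object@positiveCellCutoff, object@profileBins,
    paste(object@titerSteps, collapse = " "), object@darkCellK))
})
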