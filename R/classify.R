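#' Train the linear discriminant cell classifier
#'
#' Fits a two-class linear discriminant with pooled within-class covariance
#' (ridge-stabilized) on a labelled cell-profile table: feature vector =
#' per-bin profile means `m1..mB` followed by per-bin spreads `s1..sB`
#' (dimension `2 * profile_bins`), label = fluorescence status of the
#' kinetoplast. A linear discriminant is used for determinism and
#' small-sample stability. Requires at least 50 cells per class. A singular
#' pooled covariance is re-regularized with a 1000-fold ridge and a warning.
#'
#' @param trainingTable data.frame with a logical/0-1 column `label`
#'   (kinetoplast fluorescent) and feature columns `m1..mB`, `s1..sB`, e.g.
#'   from [buildTrainingTable()].
#' @param cfg a [RunConfig-class] (`profile_bins` fixes the expected
#'   feature dimension).
#' @param ridge ridge term added to the covariance diagonal.
#' @return A [TrainedClassifier-class]; its `trainingAccuracy` slot reports
#'   resubstitution accuracy.
#' @export
trainClassifier <- function(trainingTable, cfg = runConfig(), ridge = 1e-6) {
  nb <- cfg@profileBins
  featNames <- c(paste0("m", seq_len(nb)), paste0("s", seq_len(nb)))
  missing <- setdiff(featNames, colnames(trainingTable))
  if (length(missing))
    stop("training table lacks feature column(s): ",
         paste(utils::head(missing, 4), collapse = ", "))
  y <- as.logical(trainingTable$label)
  if (anyNA(y)) stop("training table needs a binary 'label' column")
  X <- as.matrix(trainingTable[, featNames])
  keep <- stats::complete.cases(X) & !is.na(y)
  X <- X[keep, , drop = FALSE]; y <- y[keep]
  n0 <- sum(!y); n1 <- sum(y)
  if (n0 == 0L || n1 == 0L)
    stop("training table must contain both classes")
  if (min(n0, n1) < 50L)
    stop("need >= 50 cells per class; got ", n0, " negative / ", n1,
         " positive")
  m0 <- colMeans(X[!y, , drop = FALSE])
  m1 <- colMeans(X[y, , drop = FALSE])
  S0 <- stats::cov(X[!y, , drop = FALSE])
  S1 <- stats::cov(X[y, , drop = FALSE])
  S <- ((n0 - 1) * S0 + (n1 - 1) * S1) / (n0 + n1 - 2)
  d <- ncol(X)
  fit <- function(rdg) {
    Sr <- S + diag(rdg, d)
    ch <- tryCatch(chol(Sr), error = function(e) NULL)
    if (is.null(ch)) return(NULL)
    backsolve(ch, backsolve(ch, m1 - m0, transpose = TRUE))
  }
  w <- fit(ridge)
  if (is.null(w)) {
    warning("singular pooled covariance; increasing ridge regularization")
    ridge <- ridge * 1000
    w <- fit(ridge)
    if (is.null(w)) stop("pooled covariance not invertible")
  }
  bias <- sum(w * (m0 + m1)) / 2 + log(n0 / n1)
  scores <- as.numeric(X %*% w) - bias
  acc <- mean((scores >= 0) == y)
  new("TrainedClassifier",
      classMeans = rbind(negative = m0, positive = m1), pooledCov = S,
      weights = as.numeric(w), bias = bias, featureNames = featNames,
      ridge = ridge, trainingAccuracy = acc,
      nPerClass = c(negative = n0, positive = n1),
      seed = cfg@rngSeed, version = "1")
}

#' Serialize / restore a trained classifier
#'
#' The model file is versioned JSON holding the discriminant direction and
#' bias at full precision together with the class means, pooled covariance
#' and training metadata, so a reloaded model reproduces in-memory
#' predictions.
#'
#' @param model a [TrainedClassifier-class].
#' @param path JSON file path.
#' @return [saveClassifier()] returns `path` invisibly; [readClassifier()]
#'   the restored model.
#' @export
saveClassifier <- function(model, path) {
  jsonlite::write_json(list(
    version = model@version, feature_names = model@featureNames,
    weights = model@weights, bias = model@bias,
    class_means = list(negative = model@classMeans["negative", ],
                       positive = model@classMeans["positive", ]),
    pooled_cov = model@pooledCov, ridge = model@ridge,
    training_accuracy = model@trainingAccuracy,
    n_per_class = as.list(model@nPerClass), seed = model@seed),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname saveClassifier
#' @export
readClassifier <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  new("TrainedClassifier",
      classMeans = rbind(negative = j$class_means$negative,
                         positive = j$class_means$positive),
      pooledCov = as.matrix(j$pooled_cov), weights = j$weights,
      bias = j$bias, featureNames = j$feature_names, ridge = j$ridge,
      trainingAccuracy = j$training_accuracy,
      nPerClass = c(negative = as.integer(j$n_per_class$negative),
                    positive = as.integer(j$n_per_class$positive)),
      seed = as.integer(j$seed), version = as.character(j$version))
}

#' Extract the kinetoplast brightness of a cell
#'
#' Mean un-normalized green intensity over the kinetoplast band of the
#' canonical axis (bins whose centers fall in fractional positions
#' `kinetoplast_band`, default 0.15--0.35), background-subtracted and
#' clipped at 0. This pre-normalization brightness feeds titer estimation.
#'
#' @param profile an [AxisProfile-class].
#' @param backgroundMean background green level to subtract.
#' @param cfg a [RunConfig-class].
#' @return Non-negative brightness value.
#' @export
extractKinetoplastBrightness <- function(profile, backgroundMean = 0,
                                         cfg = runConfig()) {
  nb <- length(profile@rawValues)
  centers <- (seq_len(nb) - 0.5) / nb
  band <- centers >= cfg@kinetoplastBand[1] & centers <= cfg@kinetoplastBand[2]
  if (!any(band)) band <- which.min(abs(centers - mean(cfg@kinetoplastBand)))
  max(0, mean(profile@rawValues[band]) - backgroundMean)
}

#' Classify one cell by its axis profile
#'
#' Cells failing shape QC or lacking a reliable orientation are `excluded`.
#' Dark cells are negative by the whole-cell brightness threshold and never
#' reach the discriminant (their posterior is `NA`). All remaining cells are
#' scored by the linear discriminant; the posterior is the logistic of the
#' discriminant score and the label is `positive` when the posterior is at
#' least 0.5.
#'
#' @param profile an [AxisProfile-class] (may be `NULL` for excluded cells).
#' @param record a [CellRecord-class] with QC and dark flags set.
#' @param model a [TrainedClassifier-class].
#' @param backgroundMean background green level for brightness extraction.
#' @param cfg a [RunConfig-class].
#' @return A [CellCall-class].
#' @export
classifyCell <- function(profile, record, model, backgroundMean = 0,
                         cfg = runConfig()) {
  if (!isTRUE(record@qcPass) || !isTRUE(record@orientationReliable) ||
      is.null(profile))
    return(new("CellCall", cellId = record@cellId, label = "excluded",
               kinetoplastBrightness = NA_real_, posterior = NA_real_))
  bright <- extractKinetoplastBrightness(profile, backgroundMean, cfg)
  if (isTRUE(record@isDark))
    return(new("CellCall", cellId = record@cellId, label = "negative",
               kinetoplastBrightness = bright, posterior = NA_real_))
  x <- c(profile@values, profile@spread)
  if (length(x) != length(model@weights))
    stop("feature dimension mismatch: profile gives ", length(x),
         ", model expects ", length(model@weights))
  .bumpClassifierCounter()
  score <- sum(x * model@weights) - model@bias
  post <- plogis(score)
  new("CellCall", cellId = record@cellId,
      label = if (score >= 0) "positive" else "negative",
      kinetoplastBrightness = bright, posterior = post)
}

#' Aggregate cell calls into an image verdict
#'
#' `fraction_positive` is computed over classified (non-excluded) cells; the
#' image is positive when the fraction is at least the configured cutoff
#' (ties at the boundary resolved positive). With no evaluable cell the
#' image is `rejected_qc` with reason `"no_evaluable_cells"`. The confidence
#' is a logistic transform of the distance of the fraction from the cutoff
#' scaled by the binomial standard deviation at the number of classified
#' cells, mapped to [0,1] (0.5 at the cutoff, approaching 1 far from it).
#'
#' @param cellCalls list of [CellCall-class].
#' @param cfg a [RunConfig-class].
#' @param biochipId,sampleId,dilutionFactor metadata carried into the call.
#' @param classifierEvals number of discriminant evaluations spent (for the
#'   short-circuit log).
#' @return An [ImageCall-class] (including the titer estimate from
#'   [estimateTiter()]).
#' @export
classifyImage <- function(cellCalls, cfg = runConfig(), biochipId = "biochip",
                          sampleId = "sample", dilutionFactor = 10,
                          classifierEvals = NA_integer_) {
  labels <- vapply(cellCalls, function(x) x@label, character(1))
  nTotal <- length(cellCalls)
  classified <- labels != "excluded"
  nClass <- sum(classified)
  if (nClass == 0L)
    return(new("ImageCall", biochipId = biochipId, sampleId = sampleId,
               dilutionFactor = dilutionFactor, verdict = "rejected_qc",
               rejectReason = "no_evaluable_cells",
               nCellsTotal = as.integer(nTotal), nCellsClassified = 0L,
               fractionPositive = NA_real_, titerEstimate = "negative",
               confidence = 0, classifierEvals = as.integer(classifierEvals)))
  frac <- sum(labels == "positive") / nClass
  pos <- frac >= cfg@positiveCellCutoff
  cut <- cfg@positiveCellCutoff
  binomSd <- sqrt(max(cut * (1 - cut), 0.25 / nClass) / nClass)
  conf <- plogis(abs(frac - cut) / binomSd)
  titer <- estimateTiter(cellCalls, cfg,
                         verdict = if (pos) "positive" else "negative")
  new("ImageCall", biochipId = biochipId, sampleId = sampleId,
      dilutionFactor = dilutionFactor,
      verdict = if (pos) "positive" else "negative",
      rejectReason = character(0), nCellsTotal = as.integer(nTotal),
      nCellsClassified = as.integer(nClass), fractionPositive = frac,
      titerEstimate = titer, confidence = conf,
      classifierEvals = as.integer(classifierEvals))
}

#' Estimate the titer of a positive image
#'
#' Aggregates the kinetoplast brightness of the positive cells (median by
#' default) and maps it through the configured monotone breakpoints onto the
#' titer steps: a brightness at or above breakpoint i proposes step i+1
#' (>= convention at the boundary), so brighter kinetoplasts always propose
#' higher titers. Negative images yield `"negative"`.
#'
#' @param cellCalls list of [CellCall-class].
#' @param cfg a [RunConfig-class]; `brightness_to_titer_breakpoints` must
#'   have exactly one entry fewer than `titer_steps`.
#' @param verdict image verdict; only positive images receive a titer.
#' @return A titer label.
#' @export
estimateTiter <- function(cellCalls, cfg = runConfig(), verdict = "positive") {
  if (length(cfg@brightnessToTiterBreakpoints) !=
      length(cfg@titerSteps) - 1L)
    stop("config error: brightness_to_titer_breakpoints must have one ",
         "entry fewer than titer_steps")
  if (!identical(verdict, "positive")) return("negative")
  b <- vapply(cellCalls, function(x)
    if (x@label == "positive") x@kinetoplastBrightness else NA_real_,
    numeric(1))
  b <- b[!is.na(b)]
  if (length(b) == 0L) return("negative")
  agg <- if (cfg@brightnessAggregate == "mean") mean(b) else median(b)
  level <- 1L + sum(agg >= cfg@brightnessToTiterBreakpoints)
  cfg@titerSteps[level]
}

#' Merge the dilution results of one sample
#'
#' The sample is positive iff any constituent dilution is positive. The
#' final titer is the maximum of the per-image titer proposals and the titer
#' implied by the highest positive dilution (a positive reaction at 1:100
#' implies a titer of at least 1:100). The confidence is the minimum over
#' the contributing images (positive images when the sample is positive,
#' otherwise all evaluable ones).
#'
#' @param calls list of [ImageCall-class] sharing one `sampleId`.
#' @param cfg a [RunConfig-class].
#' @return A [SampleResult-class].
#' @export
mergeDilutions <- function(calls, cfg = runConfig()) {
  if (length(calls) == 0L) stop("no image calls to merge")
  ids <- unique(vapply(calls, function(x) x@sampleId, character(1)))
  if (length(ids) != 1L)
    stop("conflicting sample ids: ", paste(ids, collapse = ", "))
  verdicts <- vapply(calls, function(x) x@verdict, character(1))
  anyPos <- any(verdicts == "positive")
  steps <- cfg@titerSteps
  if (anyPos) {
    posCalls <- calls[verdicts == "positive"]
    estLevels <- vapply(posCalls, function(x)
      match(x@titerEstimate, steps, nomatch = 0L), integer(1))
    implied <- max(vapply(posCalls, function(x)
      titerLevelForDilution(x@dilutionFactor, steps), integer(1)))
    level <- max(c(estLevels, implied, 1L))
    conf <- min(vapply(posCalls, function(x) x@confidence, numeric(1)))
    final <- steps[min(level, length(steps))]
    v <- "positive"
  } else {
    evaluable <- calls[verdicts != "rejected_qc"]
    conf <- if (length(evaluable))
      min(vapply(evaluable, function(x) x@confidence, numeric(1))) else 0
    final <- "negative"
    v <- if (length(evaluable)) "negative" else "rejected_qc"
  }
  new("SampleResult", sampleId = ids, verdict = v, finalTiter = final,
      imageCalls = calls, confidence = conf)
}
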