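# Run configuration: construction, defaults, (de)serialization.
# On disk the schema uses snake_case keys; YAML and JSON carry the same
# schema and load/save/load is idempotent.

.configDefaults <- function() list(
  positive_cell_cutoff = 0.5,
  titer_steps = c("1:10", "1:32", "1:100", "1:320", "1:1000"),
  brightness_to_titer_breakpoints = c(0.319, 0.707, 0.926, 0.985),
  cell_qc_limits = list(area = c(70, 675), aspect_ratio = c(2, 12),
                        solidity = c(0.85, 1)),
  dark_cell_k = 3.0,
  focus_threshold = 0.06,
  artefact_area_fraction_max = 0.1,
  profile_bins = 32L,
  kinetoplast_band = c(0.15, 0.35),
  min_cell_area = 30L,
  min_orientation_aspect = 1.3,
  brightness_aggregate = "median",
  classifier_path = character(0),
  rng_seed = 1L)

#' Construct a run configuration
#'
#' Central container for every tunable decision parameter of the
#' classification pipeline. Arguments use the on-disk snake_case schema;
#' omitted keys take the documented defaults. Notable defaults: a cell
#' fraction cutoff of 0.5 (an image is positive when at least half of its
#' classified cells are positive; ties resolved by the >= convention), 32
#' axis-profile bins (at least four bins per organelle), a 3-sigma dark-cell
#' rule, the kinetoplast band at fractional axis positions 0.15--0.35, and
#' five titer steps from 1:10 (the screening dilution; titers >= 1:10 count
#' as positive) to 1:1000. The brightness-to-titer breakpoints were
#' calibrated once against the simulator's intensity model and ship as
#' defaults.
#'
#' @param ... named overrides of the defaults (snake_case keys).
#' @return A validated [RunConfig-class].
#' @examples
#' cfg <- runConfig(positive_cell_cutoff = 0.4)
#' @export
runConfig <- function(...) {
  over <- list(...)
  defs <- .configDefaults()
  unknown <- setdiff(names(over), names(defs))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  vals <- modifyList(defs, over)
  obj <- new("RunConfig",
             positiveCellCutoff = as.numeric(vals$positive_cell_cutoff),
             titerSteps = as.character(vals$titer_steps),
             brightnessToTiterBreakpoints =
               as.numeric(vals$brightness_to_titer_breakpoints),
             cellQcLimits = lapply(vals$cell_qc_limits, as.numeric),
             darkCellK = as.numeric(vals$dark_cell_k),
             focusThreshold = as.numeric(vals$focus_threshold),
             artefactAreaFractionMax =
               as.numeric(vals$artefact_area_fraction_max),
             profileBins = as.integer(vals$profile_bins),
             kinetoplastBand = as.numeric(vals$kinetoplast_band),
             minCellArea = as.integer(vals$min_cell_area),
             minOrientationAspect = as.numeric(vals$min_orientation_aspect),
             brightnessAggregate = as.character(vals$brightness_aggregate),
             classifierPath = as.character(vals$classifier_path),
             rngSeed = as.integer(vals$rng_seed))
  validObject(obj)
  obj
}

#' Load / save a run configuration
#'
#' The file format is chosen by extension: `.yaml`/`.yml` or `.json`; both
#' carry the same snake_case schema. Absent optional keys are filled with
#' defaults; every invariant is validated on load, and a violated invariant
#' raises an error naming the offending key.
#'
#' @param path configuration file.
#' @return [loadRunConfig()] returns a [RunConfig-class];
#'   [saveRunConfig()] returns `path` invisibly.
#' @export
loadRunConfig <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  vals <- if (ext %in% c("yaml", "yml")) yaml::read_yaml(path)
          else if (ext == "json") jsonlite::read_json(path, simplifyVector = TRUE)
          else stop("unsupported config format: ", ext)
  if (!is.list(vals)) vals <- list()
  if (!is.null(vals$cell_qc_limits))
    vals$cell_qc_limits <- lapply(vals$cell_qc_limits, unlist)
  do.call(runConfig, vals)
}

#' @rdname loadRunConfig
#' @param cfg a [RunConfig-class].
#' @export
saveRunConfig <- function(cfg, path) {
  vals <- list(
    positive_cell_cutoff = cfg@positiveCellCutoff,
    titer_steps = cfg@titerSteps,
    brightness_to_titer_breakpoints = cfg@brightnessToTiterBreakpoints,
    cell_qc_limits = cfg@cellQcLimits,
    dark_cell_k = cfg@darkCellK,
    focus_threshold = cfg@focusThreshold,
    artefact_area_fraction_max = cfg@artefactAreaFractionMax,
    profile_bins = cfg@profileBins,
    kinetoplast_band = cfg@kinetoplastBand,
    min_cell_area = cfg@minCellArea,
    min_orientation_aspect = cfg@minOrientationAspect,
    brightness_aggregate = cfg@brightnessAggregate,
    classifier_path = cfg@classifierPath,
    rng_seed = cfg@rngSeed)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml")) yaml::write_yaml(vals, path)
  else if (ext == "json")
    jsonlite::write_json(vals, path, auto_unbox = FALSE, digits = NA,
                         pretty = TRUE)
  else stop("unsupported config format: ", ext)
  invisible(path)
}
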