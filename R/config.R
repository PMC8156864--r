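#' Pipeline configuration
#'
#' Bundles all segmentation, detection, tracking and evaluation parameters
#' with their defaults. Every field is validated; unknown fields are
#' rejected by [load_config()].
#'
#' @param segmentation list: `n_background` (frames used for the temporal
#'   median), `diff_threshold` (intensity), `area_min`, `area_max` (px^2
#'   blob-size bounds).
#' @param detection a [detect_params()] list.
#' @param tracker a [tracker_params()] list.
#' @param evaluation list: `dist_max` correctness radius (px; about half a
#'   fish length).
#' @param seed integer seed for anything stochastic downstream.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(segmentation = list(n_background = 50,
                                                diff_threshold = 25,
                                                area_min = 100,
                                                area_max = 5000),
                            detection = detect_params(),
                            tracker = tracker_params(),
                            evaluation = list(dist_max = 35),
                            seed = 1L) {
  seg_def <- list(n_background = 50, diff_threshold = 25,
                  area_min = 100, area_max = 5000)
  segmentation <- merge_validated(seg_def, segmentation, "segmentation")
  if (segmentation$diff_threshold <= 0)
    stop("segmentation$diff_threshold must be > 0")
  if (!(segmentation$area_min > 0 && segmentation$area_min < segmentation$area_max))
    stop("need 0 < segmentation$area_min < segmentation$area_max")
  detection <- merge_validated(detect_params(), detection, "detection")
  if (detection$sigma_head <= 0) stop("detection$sigma_head must be > 0")
  if (detection$sigma_ridge <= 0) stop("detection$sigma_ridge must be > 0")
  tracker <- merge_validated(tracker_params(), tracker, "tracker")
  if (tracker$max_age < 1) stop("tracker$max_age must be >= 1")
  if (tracker$min_hits < 1) stop("tracker$min_hits must be >= 1")
  if (tracker$iou_min < 0 || tracker$iou_min > 1)
    stop("tracker$iou_min must be in [0, 1]")
  evaluation <- merge_validated(list(dist_max = 35), evaluation, "evaluation")
  structure(list(segmentation = segmentation, detection = detection,
                 tracker = tracker, evaluation = evaluation,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

# overlay user values on defaults; error on unknown keys, recursing one level
merge_validated <- function(defaults, values, what) {
  if (is.null(values)) return(defaults)
  unknown <- setdiff(names(values), names(defaults))
  if (length(unknown))
    stop("unknown ", what, " field(s): ", paste(unknown, collapse = ", "))
  for (nm in names(values)) {
    if (is.list(defaults[[nm]]) && is.list(values[[nm]]))
      defaults[[nm]] <- merge_validated(defaults[[nm]], values[[nm]],
                                        paste0(what, "$", nm))
    else defaults[[nm]] <- values[[nm]]
  }
  defaults
}

#' Load a pipeline configuration from YAML or JSON
#'
#' Precedence: command-line style `overrides` beat the file, the file beats
#' the package defaults. Unknown keys raise an error naming the field.
#'
#' @param path optional path to a `.yaml`/`.yml` or `.json` file holding a
#'   (possibly partial) configuration.
#' @param overrides optional named list of partial settings applied last.
#' @return a [pipeline_config()].
#' @export
load_config <- function(path = NULL, overrides = NULL) {
  vals <- list()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    vals <- if (grepl("\\.json$", path, ignore.case = TRUE))
      jsonlite::read_json(path, simplifyVector = TRUE)
    else yaml::read_yaml(path)
    if (is.null(vals)) vals <- list()
  }
  top_def <- list(segmentation = NULL, detection = NULL, tracker = NULL,
                  evaluation = NULL, seed = NULL)
  unknown <- setdiff(names(vals), names(top_def))
  if (length(unknown))
    stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  if (!is.null(overrides)) {
    unknown <- setdiff(names(overrides), names(top_def))
    if (length(unknown))
      stop("unknown config field(s): ", paste(unknown, collapse = ", "))
    for (nm in names(overrides)) {
      vals[[nm]] <- if (is.list(vals[[nm]]) && is.list(overrides[[nm]]))
        utils::modifyList(vals[[nm]], overrides[[nm]]) else overrides[[nm]]
    }
  }
  do.call(pipeline_config, c(
    vals[intersect(names(vals), c("segmentation", "detection", "tracker",
                                  "evaluation"))],
    if (!is.null(vals$seed)) list(seed = vals$seed)))
}

#' Serialise a configuration
#'
#' @param config a [pipeline_config()].
#' @param path output file; format by extension (`.yaml` or `.json`).
#' @return `path`, invisibly.
#' @export
dump_config <- function(config, path) {
  x <- unclass(config)
  if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::write_json(x, path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  else yaml::write_yaml(x, path)
  invisible(path)
}
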