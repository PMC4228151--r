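# Caller configuration: every tunable threshold lives here, with the three
# presets used throughout (paired-end WGS, paired-end WES, single-end WES).

.config_fields <- c(
  "min_support", "neighborhood_distance", "max_cluster_join_distance",
  "max_cluster_overlap", "max_target_deletion_gap", "min_clip_length",
  "min_clip_avg_quality", "max_other_end_clip", "clip_position_tolerance",
  "reference_mei_filter_window", "prediction_merge_window", "min_polyA_length",
  "mobilome_max_mismatch_frac", "insert_size_sd_multiplier",
  "require_double_cluster", "mode", "min_anchor_mapq"
)

.preset_base <- list(
  min_support                = 5L,
  neighborhood_distance      = 200L,
  max_cluster_join_distance  = 600L,
  max_cluster_overlap        = 50L,
  max_target_deletion_gap    = 20L,
  min_clip_length            = 35L,
  min_clip_avg_quality       = 20,
  max_other_end_clip         = 7L,
  clip_position_tolerance    = 3L,
  reference_mei_filter_window = 90L,
  prediction_merge_window    = 50L,
  min_polyA_length           = 8L,
  mobilome_max_mismatch_frac = 0.10,
  insert_size_sd_multiplier  = 4,
  require_double_cluster     = TRUE,
  mode                       = "paired",
  min_anchor_mapq            = 20L
)

.presets <- list(
  "wgs-pe" = .preset_base,
  "wes-pe" = utils::modifyList(.preset_base, list(require_double_cluster = FALSE)),
  "wes-se" = utils::modifyList(.preset_base, list(
    mode = "single", min_clip_length = 20L, require_double_cluster = TRUE
  ))
)

#' Construct a caller configuration
#'
#' Returns a validated configuration starting from one of the presets,
#' optionally overriding individual fields. Presets:
#' \describe{
#'   \item{wgs-pe}{paired-end whole-genome calling: 5 supporting reads,
#'     200 bp neighborhood distance, 600 bp maximum join distance for
#'     discordant 5'/3' clusters, 35 bp minimum clip length, double-cluster
#'     support required.}
#'   \item{wes-pe}{paired-end exome calling: as wgs-pe but single-sided
#'     (one-cluster) predictions are allowed, so insertions near capture
#'     region borders are not discarded.}
#'   \item{wes-se}{single-end exome calling: only clipped reads are used,
#'     minimum clip length 20 bp, clip positions on one side may scatter by
#'     at most 3 bp.}
#' }
#'
#' @param preset one of \code{"wgs-pe"}, \code{"wes-pe"}, \code{"wes-se"}
#' @param ... named field overrides (see Details for field names)
#' @return a named list of class \code{caller_config}
#' @details Fields: \code{min_support}, \code{neighborhood_distance},
#'   \code{max_cluster_join_distance}, \code{max_cluster_overlap},
#'   \code{max_target_deletion_gap}, \code{min_clip_length},
#'   \code{min_clip_avg_quality}, \code{max_other_end_clip},
#'   \code{clip_position_tolerance}, \code{reference_mei_filter_window},
#'   \code{prediction_merge_window}, \code{min_polyA_length},
#'   \code{mobilome_max_mismatch_frac}, \code{insert_size_sd_multiplier},
#'   \code{require_double_cluster}, \code{mode} (\code{"paired"} or
#'   \code{"single"}), \code{min_anchor_mapq}.
#' @export
caller_config <- function(preset = "wgs-pe", ...) {
  if (!preset %in% names(.presets)) {
    stop("unknown preset '", preset, "'; available: ",
         paste(names(.presets), collapse = ", "))
  }
  cfg <- .presets[[preset]]
  overrides <- list(...)
  if (length(overrides)) {
    bad <- setdiff(names(overrides), .config_fields)
    if (length(bad)) stop("unknown config field(s): ", paste(bad, collapse = ", "))
    cfg <- utils::modifyList(cfg, overrides)
  }
  cfg$preset <- preset
  validate_config(cfg)
}

#' Validate a caller configuration
#'
#' Checks field types and ranges; returns the config (with class set)
#' or stops with an error naming the offending field.
#'
#' @param cfg a list of configuration fields
#' @return the validated config, classed \code{caller_config}
#' @export
validate_config <- function(cfg) {
  int_fields <- c("min_support", "neighborhood_distance",
                  "max_cluster_join_distance", "max_cluster_overlap",
                  "max_target_deletion_gap", "min_clip_length",
                  "max_other_end_clip", "clip_position_tolerance",
                  "reference_mei_filter_window", "prediction_merge_window",
                  "min_polyA_length", "min_anchor_mapq")
  for (f in int_fields) {
    v <- cfg[[f]]
    if (is.null(v) || length(v) != 1L || is.na(v) || v < 0 || v != as.integer(v)) {
      stop("config field '", f, "' must be a single non-negative integer")
    }
    cfg[[f]] <- as.integer(v)
  }
  if (cfg$min_support < 1L) stop("config field 'min_support' must be >= 1")
  if (!is.numeric(cfg$min_clip_avg_quality) || cfg$min_clip_avg_quality < 0) {
    stop("config field 'min_clip_avg_quality' must be a non-negative number")
  }
  mf <- cfg$mobilome_max_mismatch_frac
  if (!is.numeric(mf) || length(mf) != 1L || mf <= 0 || mf >= 1) {
    stop("config field 'mobilome_max_mismatch_frac' must be in (0, 1)")
  }
  if (!is.numeric(cfg$insert_size_sd_multiplier) || cfg$insert_size_sd_multiplier < 0) {
    stop("config field 'insert_size_sd_multiplier' must be non-negative")
  }
  if (!is.logical(cfg$require_double_cluster) || is.na(cfg$require_double_cluster)) {
    stop("config field 'require_double_cluster' must be TRUE or FALSE")
  }
  if (!cfg$mode %in% c("paired", "single")) {
    stop("config field 'mode' must be 'paired' or 'single'")
  }
  structure(cfg, class = "caller_config")
}

#' Load a configuration from a key=value file
#'
#' The file is flat UTF-8 text, one \code{key = value} pair per line;
#' \code{#} starts a comment. File values override the chosen preset.
#' An empty (or absent) file yields the pure preset.
#'
#' @param path path to a config file, or \code{NULL} for preset only
#' @param preset preset name, see \code{\link{caller_config}}
#' @return validated \code{caller_config}
#' @export
load_config <- function(path = NULL, preset = "wgs-pe") {
  overrides <- list()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    lines <- readLines(path, warn = FALSE)
    lines <- sub("#.*$", "", lines)
    lines <- trimws(lines)
    lines <- lines[nzchar(lines)]
    for (ln in lines) {
      kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
      if (length(kv) != 2L) stop("malformed config line: '", ln, "'")
      key <- trimws(kv[1]); val <- trimws(kv[2])
      if (!key %in% .config_fields) stop("unknown config key: '", key, "'")
      overrides[[key]] <- parse_config_value(key, val)
    }
  }
  do.call(caller_config, c(list(preset = preset), overrides))
}

parse_config_value <- function(key, val) {
  if (key == "mode") return(val)
  if (key == "require_double_cluster") return(as.logical(toupper(val)))
  as.numeric(val)
}

#' Write a configuration to a key=value file
#'
#' Inverse of \code{\link{load_config}}: \code{load_config(dump_config(cfg, f))}
#' reproduces \code{cfg}.
#'
#' @param cfg a \code{caller_config}
#' @param path output file path
#' @return \code{path}, invisibly
#' @export
dump_config <- function(cfg, path) {
  lines <- vapply(.config_fields, function(f) {
    v <- cfg[[f]]
    paste0(f, " = ", if (is.logical(v)) ifelse(v, "TRUE", "FALSE") else format(v, scientific = FALSE))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @export
print.caller_config <- function(x, ...) {
  cat("caller_config (preset:", x$preset %||% "custom", ")\n")
  for (f in .config_fields) cat(sprintf("  %-28s %s\n", f, format(x[[f]])))
  invisible(x)
}
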