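#' Recording container
#'
#' A fixed-rate multi-channel inertial recording: a tibble of samples
#' (`t, ax, ay, az` and optionally `gx, gy, gz`) plus sensor metadata.
#'
#' @param recording_id Identifier string.
#' @param data Sample tibble; `t` in seconds from recording start.
#' @param sample_rate Samples per second (> 0).
#' @param site Body site, one of left_arm, right_arm, left_leg, right_leg,
#'   trunk, head.
#' @param t0 Optional wall-clock start (POSIXct or string), metadata only.
#' @return A `recording` object.
#' @export
new_recording <- function(recording_id, data, sample_rate = 100,
                          site = "left_arm", t0 = NULL) {
  stopifnot(sample_rate > 0, is.data.frame(data),
            all(c("t", "ax", "ay", "az") %in% names(data)),
            site %in% sensor_sites())
  has_gyro <- all(c("gx", "gy", "gz") %in% names(data))
  if (any(c("gx", "gy", "gz") %in% names(data)) && !has_gyro) {
    stop("gyro channels must be all present or all absent", call. = FALSE)
  }
  structure(list(recording_id = recording_id,
                 data = tibble::as_tibble(data),
                 sample_rate = sample_rate, site = site, t0 = t0),
            class = "recording")
}

#' @export
print.recording <- function(x, ...) {
  cat("<recording> ", x$recording_id, ": ", nrow(x$data), " samples @ ",
      x$sample_rate, " Hz, site ", x$site,
      if (all(c("gx", "gy", "gz") %in% names(x$data))) ", accel+gyro"
      else ", accel only", "\n", sep = "")
  invisible(x)
}

sidecar_path <- function(path) sub("\\.csv$", ".json", path)

#' Read / write a recording CSV with its metadata sidecar
#'
#' The on-disk format is a CSV with header `t,ax,ay,az[,gx,gy,gz]` (time in
#' seconds, strictly increasing and consistent with the declared sample rate
#' to within 1e-6 s) plus a JSON sidecar of the same basename holding
#' `recording_id`, `sample_rate` and `site`.
#'
#' @param path CSV path; the sidecar lives at the same path with a `.json`
#'   extension.
#' @return `read_recording()`: a `recording`. `write_recording()`: `path`,
#'   invisibly.
#' @export
read_recording <- function(path) {
  meta_path <- sidecar_path(path)
  if (!file.exists(meta_path)) {
    stop("missing metadata sidecar: ", meta_path, call. = FALSE)
  }
  meta <- jsonlite::fromJSON(meta_path)
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  required <- c("t", "ax", "ay", "az")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("missing columns: ", paste(missing, collapse = ", "), call. = FALSE)
  }
  bad <- which(!stats::complete.cases(df[required]))
  if (length(bad)) {
    stop("malformed rows (non-numeric or missing values) at lines: ",
         paste(utils::head(bad + 1L, 5), collapse = ", "), call. = FALSE)
  }
  if (nrow(df) > 1) {
    dt <- diff(df$t)
    if (any(dt <= 0)) {
      stop("non-monotone time at line ", which(dt <= 0)[1] + 2L,
           call. = FALSE)
    }
    if (any(abs(dt - 1 / meta$sample_rate) > 1e-6)) {
      stop("rate mismatch: declared ", meta$sample_rate,
           " Hz but observed median step ", stats::median(dt), " s",
           call. = FALSE)
    }
  }
  new_recording(meta$recording_id, df, meta$sample_rate, meta$site,
                t0 = meta$t0)
}

#' @rdname read_recording
#' @param recording A `recording` object.
#' @export
write_recording <- function(recording, path) {
  readr::write_csv(recording$data, path, progress = FALSE)
  jsonlite::write_json(
    list(recording_id = recording$recording_id,
         sample_rate = recording$sample_rate,
         site = recording$site, t0 = recording$t0),
    sidecar_path(path), auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read / write a labels table
#'
#' Labelled segments: `recording_id, start_s, end_s, grade, activity, site`
#' with half-open intervals `[start_s, end_s)` in seconds from recording
#' start. Grades are real-valued in \[0, 4\] (rater-averaged fractions such
#' as 2.5 are valid). Overlapping segments for the same recording and site
#' are rejected.
#'
#' @param path CSV path.
#' @return A validated labels tibble.
#' @export
read_labels <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  validate_labels(df)
}

#' @rdname read_labels
#' @param labels Labels data frame.
#' @export
write_labels <- function(labels, path) {
  validate_labels(labels)
  readr::write_csv(labels, path, progress = FALSE)
  invisible(path)
}

validate_labels <- function(df) {
  required <- c("recording_id", "start_s", "end_s", "grade", "activity",
                "site")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("missing columns: ", paste(missing, collapse = ", "), call. = FALSE)
  }
  bad_grade <- which(df$grade < 0 | df$grade > 4)
  if (length(bad_grade)) {
    stop("grade outside [0,4] at line ",
         paste(bad_grade + 1L, collapse = ", "), call. = FALSE)
  }
  bad_iv <- which(df$end_s <= df$start_s | df$start_s < 0)
  if (length(bad_iv)) {
    stop("end <= start at line ", paste(bad_iv + 1L, collapse = ", "),
         call. = FALSE)
  }
  for (key in unique(paste(df$recording_id, df$site))) {
    rows <- which(paste(df$recording_id, df$site) == key)
    if (length(rows) < 2) next
    o <- rows[order(df$start_s[rows])]
    overlap <- which(df$start_s[o][-1] < df$end_s[o][-length(o)])
    if (length(overlap)) {
      stop("overlapping segments at lines ", o[overlap][1] + 1L, " and ",
           o[overlap + 1][1] + 1L, " (same recording and site)",
           call. = FALSE)
    }
  }
  tibble::as_tibble(df)
}

model_schema_version <- "1.1"

#' Save / load a classifier model as JSON
#'
#' Persists the genome (functions by name), feature mode, fitted thresholds
#' and provenance, stamped with a schema version. Files from older 1.x
#' schemas load with the newer fields defaulted; anything else is rejected.
#'
#' @param model A [classifier_model()].
#' @param path JSON path.
#' @return `save_model()`: `path` invisibly. `load_model()`: the model.
#' @export
save_model <- function(model, path) {
  obj <- list(
    schema_version = model_schema_version,
    feature_mode = model$feature_mode,
    genome = jsonlite::fromJSON(genome_to_json(model$genome),
                                simplifyVector = FALSE),
    thresholds = if (!is.null(model$thresholds)) {
      as.list(model$thresholds)
    },
    provenance = model$provenance)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
                  error = function(e) {
                    stop("incompatible model file: ", conditionMessage(e),
                         call. = FALSE)
                  })
  ver <- obj$schema_version
  if (is.null(ver) || !startsWith(as.character(ver), "1.")) {
    stop("incompatible model file: schema version ",
         if (is.null(ver)) "missing" else ver, call. = FALSE)
  }
  if (is.null(obj$genome) || is.null(obj$feature_mode)) {
    stop("incompatible model file: missing genome or feature mode",
         call. = FALSE)
  }
  thresholds <- if (!is.null(obj$thresholds)) {
    tibble::as_tibble(lapply(obj$thresholds, unlist))
  }
  classifier_model(genome_from_json(obj$genome),
                   feature_mode = obj$feature_mode,
                   thresholds = thresholds,
                   provenance = if (is.null(obj$provenance)) list()
                                else obj$provenance)
}

#' Write a run manifest
#'
#' Records everything needed to reproduce a command's artefacts bit-exactly:
#' configuration snapshot, seeds, input file digests and artefact paths.
#'
#' @param path JSON path.
#' @param config Named list / config object snapshot.
#' @param seeds Integer vector of seeds used.
#' @param inputs Character vector of input file paths (digested if present).
#' @param artefacts Character vector of output paths.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(path, config = list(), seeds = integer(),
                           inputs = character(), artefacts = character()) {
  digests <- vapply(inputs, function(f) {
    if (file.exists(f)) {
      as.character(tools::md5sum(f))
    } else {
      NA_character_
    }
  }, character(1))
  jsonlite::write_json(
    list(tool = "caldera",
         version = as.character(utils::packageVersion("caldera")),
         config = config, seeds = seeds,
         inputs = as.list(stats::setNames(digests, inputs)),
         artefacts = artefacts),
    path, auto_unbox = TRUE, digits = NA, null = "null", force = TRUE)
  invisible(path)
}

#' Write a synthetic study to disk
#'
#' Emits each recording as CSV + JSON sidecar, the labels table, and a
#' manifest with splits, seed and ground-truth burst intervals.
#'
#' @param study A `synthetic_study`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character()
  for (rid in names(study$recordings)) {
    p <- file.path(dir, paste0(rid, ".csv"))
    write_recording(study$recordings[[rid]], p)
    paths <- c(paths, p)
  }
  write_labels(study$labels, file.path(dir, "labels.csv"))
  jsonlite::write_json(
    list(seed = study$config$seed,
         splits = split(study$segments$recording_id, study$segments$split),
         truth = study$truth),
    file.path(dir, "manifest.json"),
    auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(dir)
}

#' Read a synthetic study back from disk
#'
#' @param dir Directory written by [write_study()].
#' @return A list with `recordings`, `labels`, `manifest`.
#' @export
read_study <- function(dir) {
  manifest <- jsonlite::fromJSON(file.path(dir, "manifest.json"))
  labels <- read_labels(file.path(dir, "labels.csv"))
  rids <- labels$recording_id
  recordings <- stats::setNames(
    lapply(rids, function(rid) read_recording(file.path(dir,
                                                        paste0(rid, ".csv")))),
    rids)
  list(recordings = recordings, labels = labels, manifest = manifest)
}
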