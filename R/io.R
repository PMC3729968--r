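# Plain-text interchange formats (CSV/TSV/JSON) for geometry, atlas, RSN,
# covariate and adjacency data, plus RDS serialization for epoched recordings
# and beamformer models (bit-exact round trips).

#' Write / read a sensor layout as CSV
#'
#' Columns: channel_id, x, y, z, ox, oy, oz (meters; orientation unit vector).
#'
#' @param sensors a `sensor_array`.
#' @param path file path.
#' @return `read_sensor_layout` returns a `sensor_array`.
#' @export
write_sensor_layout <- function(sensors, path) {
  df <- data.frame(channel_id = sensors$channel_id,
                   x = sensors$position[, 1], y = sensors$position[, 2],
                   z = sensors$position[, 3],
                   ox = sensors$orientation[, 1], oy = sensors$orientation[, 2],
                   oz = sensors$orientation[, 3])
  utils::write.csv(format(df, digits = 15, trim = TRUE), path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_sensor_layout
#' @export
read_sensor_layout <- function(path) {
  df <- tryCatch(utils::read.csv(path, stringsAsFactors = FALSE),
                 error = function(e) stop("malformed sensor layout '", path, "': ",
                                          conditionMessage(e)))
  need <- c("channel_id", "x", "y", "z", "ox", "oy", "oz")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0) {
    stop("sensor layout '", path, "' lacks column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  if (anyDuplicated(df$channel_id)) {
    stop("sensor layout '", path, "' has duplicated channel_id values")
  }
  structure(list(channel_id = as.character(df$channel_id),
                 position = as.matrix(df[, c("x", "y", "z")]),
                 orientation = as.matrix(df[, c("ox", "oy", "oz")])),
            class = "sensor_array")
}

#' Write / read an ROI atlas as JSON
#'
#' Format: `{roi_label: [[x, y, z], ...], ...}` (meters).
#'
#' @param atlas an `roi_atlas`.
#' @param path file path.
#' @return `read_atlas_json` returns an `roi_atlas` (the first voxel of each
#'   ROI is taken as the centroid voxel).
#' @export
write_atlas_json <- function(atlas, path) {
  obj <- lapply(seq_along(atlas$labels), function(k) {
    unname(split(atlas$voxels[atlas$roi_index == k, , drop = FALSE],
                 seq_len(sum(atlas$roi_index == k))))
  })
  names(obj) <- atlas$labels
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = FALSE)
  invisible(path)
}

#' @rdname write_atlas_json
#' @export
read_atlas_json <- function(path) {
  obj <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                  error = function(e) stop("malformed atlas JSON '", path, "': ",
                                           conditionMessage(e)))
  labels <- names(obj)
  if (is.null(labels)) stop("atlas JSON '", path, "' is not a named object")
  vox_list <- lapply(obj, function(v) {
    m <- if (is.list(v)) do.call(rbind, v) else matrix(v, ncol = 3)
    if (ncol(m) != 3) stop("atlas JSON '", path, "' has non 3-vector voxels")
    m
  })
  voxels <- do.call(rbind, vox_list)
  roi_index <- rep(seq_along(labels), vapply(vox_list, nrow, integer(1)))
  centroid_index <- match(seq_along(labels), roi_index)
  structure(list(labels = labels, voxels = unname(voxels),
                 roi_index = roi_index, centroid_index = centroid_index),
            class = "roi_atlas")
}

#' Write / read RSN definitions as JSON
#'
#' Format: `{rsn_name: [roi_label, ...], ...}`. Reading validates every
#' member label against `roi_labels` when supplied.
#'
#' @param rsns named list of character vectors.
#' @param path file path.
#' @param roi_labels optional valid ROI labels for validation.
#' @return `read_rsn_json` returns the named list.
#' @export
write_rsn_json <- function(rsns, path) {
  jsonlite::write_json(rsns, path, auto_unbox = FALSE)
  invisible(path)
}

#' @rdname write_rsn_json
#' @export
read_rsn_json <- function(path, roi_labels = NULL) {
  rsns <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                   error = function(e) stop("malformed RSN JSON '", path, "': ",
                                            conditionMessage(e)))
  if (!is.list(rsns) || is.null(names(rsns))) {
    stop("RSN JSON '", path, "' is not a named object")
  }
  rsns <- lapply(rsns, as.character)
  if (!is.null(roi_labels)) validate_rsns(rsns, roi_labels)
  rsns
}

#' Write / read a subject covariate table as TSV
#'
#' @param subjects data.frame of subject records.
#' @param path file path.
#' @return `read_covariates_tsv` returns the data.frame.
#' @export
write_covariates_tsv <- function(subjects, path) {
  utils::write.table(subjects, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_covariates_tsv
#' @export
read_covariates_tsv <- function(path) {
  df <- tryCatch(utils::read.delim(path, stringsAsFactors = FALSE),
                 error = function(e) stop("malformed covariate TSV '", path, "': ",
                                          conditionMessage(e)))
  if (!all(c("subject_id", "group") %in% names(df))) {
    stop("covariate TSV '", path, "' lacks subject_id/group columns")
  }
  df
}

#' Write / read an adjacency matrix as CSV
#'
#' Square CSV with ROI labels as header and row names, 15 significant digits.
#'
#' @param A an `adjacency_matrix` or plain labeled matrix.
#' @param path file path.
#' @return `read_adjacency_csv` returns the numeric matrix with dimnames.
#' @export
write_adjacency_csv <- function(A, path) {
  v <- adj_values(A)
  df <- as.data.frame(format(v, digits = 15, trim = TRUE, scientific = TRUE))
  utils::write.csv(cbind(roi = rownames(v), df), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' @rdname write_adjacency_csv
#' @export
read_adjacency_csv <- function(path) {
  df <- tryCatch(utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE),
                 error = function(e) stop("malformed adjacency CSV '", path, "': ",
                                          conditionMessage(e)))
  if (names(df)[1] != "roi") stop("adjacency CSV '", path, "' lacks an roi column")
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- df$roi
  if (nrow(m) != ncol(m)) stop("adjacency CSV '", path, "' is not square")
  m
}

#' Long-form adjacency edge list
#'
#' One row per unordered ROI pair: roi_a, roi_b, band, subject, pli.
#'
#' @param A an `adjacency_matrix`.
#' @return data.frame edge list.
#' @export
adjacency_edges <- function(A) {
  v <- adj_values(A)
  ut <- which(upper.tri(v), arr.ind = TRUE)
  band <- if (inherits(A, "adjacency_matrix")) A$band$name else NA_character_
  subject <- if (inherits(A, "adjacency_matrix")) A$subject_id else NA_character_
  data.frame(roi_a = rownames(v)[ut[, 1]], roi_b = colnames(v)[ut[, 2]],
             band = band, subject = subject, pli = v[ut],
             stringsAsFactors = FALSE)
}

#' Save / load an epoched recording (RDS, bit-exact round trip)
#'
#' @param recording an `epoched_recording` (or any pipeline object).
#' @param path file path (`.rds`).
#' @return `load_recording` returns the object.
#' @export
save_recording <- function(recording, path) {
  saveRDS(recording, path)
  invisible(path)
}

#' @rdname save_recording
#' @export
load_recording <- function(path) {
  readRDS(path)
}
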