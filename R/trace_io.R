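#' Construct a trace matrix
#'
#' A `trace_matrix` is a frames x neurons numeric matrix of fluorescence
#' values (arbitrary units) with a frame rate and stable neuron identifiers.
#' Frames are 0-based in all reported frame indices; times are in seconds.
#'
#' @param values numeric matrix, frames in rows, neurons in columns.
#' @param fps frame rate, frames per second (> 0).
#' @param neuron_ids character vector of unique neuron identifiers; defaults
#'   to existing column names or `n001, n002, ...`.
#' @return A matrix of class `trace_matrix` with attributes `fps` and
#'   `neuron_ids`.
#' @export
trace_matrix <- function(values, fps, neuron_ids = NULL) {
  values <- as.matrix(values)
  if (!is.numeric(values)) stop("trace values must be numeric")
  if (anyNA(values) || any(!is.finite(values))) {
    stop("trace values must be finite and non-missing")
  }
  if (!is.numeric(fps) || length(fps) != 1 || fps <= 0) stop("fps must be > 0")
  if (is.null(neuron_ids)) {
    neuron_ids <- colnames(values)
    if (is.null(neuron_ids)) neuron_ids <- sprintf("n%03d", seq_len(ncol(values)))
  }
  neuron_ids <- as.character(neuron_ids)
  if (length(neuron_ids) != ncol(values)) {
    stop("neuron_ids length must match number of columns")
  }
  if (anyDuplicated(neuron_ids)) stop("neuron_ids must be unique")
  dimnames(values) <- list(NULL, neuron_ids)
  structure(values, fps = fps, neuron_ids = neuron_ids, class = "trace_matrix")
}

#' @export
print.trace_matrix <- function(x, ...) {
  cat(sprintf("Trace matrix: %d frames x %d neurons at %g fps (%.1f s)\n",
              nrow(x), ncol(x), attr(x, "fps"), nrow(x) / attr(x, "fps")))
  invisible(x)
}

#' @export
`[.trace_matrix` <- function(x, i, j, ...) {
  out <- unclass(x)[i, j, ...]
  attr(out, "fps") <- NULL
  out
}

# Detect comma vs tab delimiter from the first line of a file.
detect_sep <- function(path) {
  line1 <- readLines(path, n = 1L)
  if (length(line1) == 0) stop("empty file: ", path)
  if (grepl("\t", line1)) "\t" else ","
}

#' Read a trace matrix from delimited text
#'
#' Expects a rectangular comma- or tab-delimited table (auto-detected from
#' the first line), first row neuron ids, subsequent rows one frame each.
#' Loading is strict: any missing, non-numeric or ragged cell raises an
#' error naming its row and column; nothing is imputed.
#'
#' @param path file path.
#' @param fps frame rate to attach, frames per second.
#' @return A [trace_matrix()].
#' @export
read_traces <- function(path, fps) {
  if (!file.exists(path)) stop("trace file not found: ", path)
  sep <- detect_sep(path)
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = "character", check.names = FALSE,
                           comment.char = "", quote = "\"")
  if (ncol(tab) < 1 || nrow(tab) < 1) stop("trace table is empty: ", path)
  vals <- matrix(NA_real_, nrow = nrow(tab), ncol = ncol(tab))
  for (j in seq_len(ncol(tab))) {
    x <- suppressWarnings(as.numeric(tab[[j]]))
    bad <- which(is.na(x))
    if (length(bad) > 0) {
      stop(sprintf(
        "non-numeric or missing value at row %d, column %d ('%s') of %s",
        bad[1], j, colnames(tab)[j], path
      ))
    }
    vals[, j] <- x
  }
  trace_matrix(vals, fps = fps, neuron_ids = colnames(tab))
}

#' Write a trace matrix as delimited text
#'
#' @param traces a [trace_matrix()].
#' @param path output file path.
#' @param sep field separator, `","` (default) or `"\t"`.
#' @return `path`, invisibly.
#' @export
write_traces <- function(traces, path, sep = ",") {
  df <- as.data.frame(unclass(traces))
  colnames(df) <- attr(traces, "neuron_ids")
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a neuron centroid map
#'
#' Three-column delimited text: `neuron_id`, `x_px`, `y_px`. Coordinates must
#' be finite.
#'
#' @param path file path.
#' @return data.frame with columns `neuron_id` (character), `x_px`, `y_px`.
#' @export
read_neuron_map <- function(path) {
  if (!file.exists(path)) stop("neuron map file not found: ", path)
  sep <- detect_sep(path)
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("neuron_id", "x_px", "y_px")
  if (!all(need %in% colnames(tab))) {
    stop("neuron map must have columns neuron_id, x_px, y_px")
  }
  tab$neuron_id <- as.character(tab$neuron_id)
  if (anyDuplicated(tab$neuron_id)) stop("duplicate neuron ids in map")
  if (anyNA(tab$x_px) || anyNA(tab$y_px) ||
      any(!is.finite(tab$x_px)) || any(!is.finite(tab$y_px))) {
    stop("neuron map coordinates must be finite")
  }
  tab[, need]
}

#' Write a neuron centroid map
#' @param map data.frame with `neuron_id`, `x_px`, `y_px`.
#' @param path output file path.
#' @param sep field separator.
#' @return `path`, invisibly.
#' @export
write_neuron_map <- function(map, path, sep = ",") {
  utils::write.table(map[, c("neuron_id", "x_px", "y_px")], path, sep = sep,
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read or write a session manifest
#'
#' The manifest is a YAML list of records, each with `mouse_id`, `state`,
#' `trace_path`, `map_path`. States are validated against a vocabulary;
#' `custom` admits any label.
#'
#' @param path manifest file path.
#' @param states allowed state labels.
#' @param check_paths verify that referenced files exist.
#' @return data.frame of records.
#' @export
read_manifest <- function(path,
                          states = c("baseline_d1", "baseline_d2", "baseline_d3",
                                     "baseline_d4", "baseline_d5", "stress",
                                     "3h", "10days", "custom"),
                          check_paths = TRUE) {
  if (!file.exists(path)) stop("manifest not found: ", path)
  raw <- yaml::read_yaml(path)
  if (length(raw) == 0) stop("manifest is empty")
  recs <- do.call(rbind, lapply(raw, function(r) {
    need <- c("mouse_id", "state", "trace_path", "map_path")
    if (!all(need %in% names(r))) {
      stop("manifest record missing fields: ",
           paste(setdiff(need, names(r)), collapse = ", "))
    }
    as.data.frame(r[need], stringsAsFactors = FALSE)
  }))
  if (!"custom" %in% states) {
    bad <- setdiff(recs$state, states)
    if (length(bad) > 0) {
      stop("unknown state label(s): ", paste(bad, collapse = ", "))
    }
  }
  if (check_paths) {
    base <- dirname(path)
    for (p in c(recs$trace_path, recs$map_path)) {
      full <- if (file.exists(p)) p else file.path(base, p)
      if (!file.exists(full)) stop("manifest references missing file: ", p)
    }
  }
  recs
}

#' @rdname read_manifest
#' @param records data.frame with `mouse_id`, `state`, `trace_path`, `map_path`.
#' @export
write_manifest <- function(records, path) {
  recs <- lapply(seq_len(nrow(records)), function(i) as.list(records[i, ]))
  yaml::write_yaml(recs, path)
  invisible(path)
}

#' Trim a recording to its middle segment
#'
#' Discards `head_s` seconds from the start and `tail_s` from the end. With
#' the defaults (60 s each) a 7-minute recording yields its middle 5 minutes,
#' the standard preprocessing for these sessions.
#'
#' @param traces a [trace_matrix()].
#' @param head_s seconds to drop from the start.
#' @param tail_s seconds to drop from the end.
#' @return The trimmed [trace_matrix()]; neuron order and ids preserved.
#' @export
trim_recording <- function(traces, head_s = 60, tail_s = 60) {
  stopifnot(inherits(traces, "trace_matrix"))
  fps <- attr(traces, "fps")
  n <- nrow(traces)
  drop_head <- as.integer(round(head_s * fps))
  drop_tail <- as.integer(round(tail_s * fps))
  if (drop_head + drop_tail >= n) {
    stop(sprintf(
      "trim would leave an empty segment: %d + %d frames dropped of %d",
      drop_head, drop_tail, n
    ))
  }
  keep <- (drop_head + 1L):(n - drop_tail)
  trace_matrix(unclass(traces)[keep, , drop = FALSE], fps = fps,
               neuron_ids = attr(traces, "neuron_ids"))
}

#' Read or write a binary raster as delimited text
#'
#' Same layout as a trace file (header of neuron ids, one frame per row) with
#' cells restricted to 0/1. `write_raster` optionally writes a JSON
#' provenance sidecar (`<path>.json`) recording the binarization method and
#' parameters.
#'
#' @param path raster file path.
#' @param fps frame rate to attach.
#' @return `read_raster`: a `binary_raster`; `write_raster`: `path`, invisibly.
#' @export
read_raster <- function(path, fps) {
  tm <- read_traces(path, fps)
  vals <- unclass(tm)
  if (!all(vals %in% c(0, 1))) stop("raster cells must be 0 or 1")
  binary_raster(vals, fps = fps, neuron_ids = attr(tm, "neuron_ids"),
                method = "loaded", params = list(source = path))
}

#' @rdname read_raster
#' @param raster a `binary_raster`.
#' @param sidecar write a JSON provenance file alongside the raster.
#' @export
write_raster <- function(raster, path, sidecar = TRUE) {
  stopifnot(inherits(raster, "binary_raster"))
  df <- as.data.frame(unclass(raster))
  colnames(df) <- attr(raster, "neuron_ids")
  utils::write.table(df, path, sep = ",", row.names = FALSE, quote = FALSE)
  if (sidecar) {
    jsonlite::write_json(
      list(method = attr(raster, "method"), params = attr(raster, "params"),
           fps = attr(raster, "fps")),
      paste0(path, ".json"), auto_unbox = TRUE
    )
  }
  invisible(path)
}
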