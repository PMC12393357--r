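EXPORT_META_COLS <- c("Name", "ROI", "X", "Y", "Groups", "Filter",
                      "Detection.Method")

# Format a column for CSV output: integers as plain integers, doubles with
# full round-trip precision (%.17g re-parses bit-exactly).
format_export_col <- function(x) {
  if (is.integer(x)) sprintf("%d", x)
  else if (is.numeric(x)) sprintf("%.17g", x)
  else csv_quote(x)
}

write_export_table <- function(tab, path) {
  cols <- lapply(tab, format_export_col)
  header <- paste(csv_quote(names(tab)), collapse = ",")
  body <- do.call(paste, c(cols, sep = ","))
  con <- file(path, "wb")  # binary: byte-stable LF newlines on any platform
  on.exit(close(con))
  writeLines(c(header, body), con, sep = "\n")
  invisible(path)
}

roi_groups_string <- function(manager) {
  nms <- manager_names(manager)
  vapply(nms, function(nm) {
    gs <- names(manager$groups)[vapply(manager$groups, function(members)
      nm %in% members, TRUE)]
    paste(gs, collapse = ";")
  }, "", USE.NAMES = FALSE)
}

#' Export signal and peak tables to CSV
#'
#' Writes the two-file spreadsheet output: `<prefix>_signal.csv` holds the
#' DF/F trace of every ROI and `<prefix>_peaks.csv` the ternary
#' (-1/0/1) peak flags. Both share the metadata columns `Name` (source
#' recording), `ROI`, `X`, `Y` (ROI centroid), `Groups` (`";"`-joined, empty
#' when ungrouped), `Filter` and `Detection.Method` (processing provenance),
#' followed by one column per frame (`F1` ... `Fn`, 1-based like slice
#' numbers in imaging software). Row order follows the manager's ROI order.
#' Signal values are serialized with full float round-trip precision; peak
#' flags as bare integers.
#'
#' @param manager a [cell_manager()]; every ROI must be present in `traces`.
#' @param traces a [trace_matrix()].
#' @param peaks a `calmov_peakset` from [detect_peaks_traces()], aligned with
#'   `traces`, or `NULL` to export flags of 0 with detection method "none".
#' @param out_prefix path prefix for the two files.
#' @return named character vector with elements `signal` and `peaks`.
#' @export
export_data <- function(manager, traces, peaks, out_prefix) {
  stopifnot(inherits(manager, "calmov_cellmanager"),
            inherits(traces, "calmov_traces"))
  nms <- manager_names(manager)
  if (length(nms) == 0) stop("cell manager holds no ROIs")
  idx <- match(nms, traces$roi_names)
  if (anyNA(idx))
    stop("ROI(s) missing from traces: ", paste(nms[is.na(idx)], collapse = ", "))
  nf <- ncol(traces$values)
  if (is.null(peaks)) {
    flags <- matrix(0L, length(traces$roi_names), nf)
    det <- "none"
  } else {
    stopifnot(inherits(peaks, "calmov_peakset"))
    if (!identical(peaks$roi_names, traces$roi_names) ||
        ncol(peaks$flags) != nf)
      stop("peaks are not aligned with traces")
    flags <- peaks$flags
    det <- peaks$detection_method
  }
  meta <- data.frame(
    Name = rep(traces$source_name, length(nms)),
    ROI = nms,
    X = as.numeric(traces$centroids[idx, 1]),
    Y = as.numeric(traces$centroids[idx, 2]),
    Groups = roi_groups_string(manager),
    Filter = rep(traces$filter, length(nms)),
    Detection.Method = rep(det, length(nms)),
    stringsAsFactors = FALSE, check.names = FALSE
  )
  frame_names <- paste0("F", seq_len(nf))
  sig <- cbind(meta, stats::setNames(as.data.frame(traces$values[idx, ,
    drop = FALSE]), frame_names))
  pk_mat <- matrix(as.integer(flags[idx, , drop = FALSE]), nrow = length(idx))
  pk <- cbind(meta, stats::setNames(as.data.frame(pk_mat), frame_names))
  paths <- c(signal = paste0(out_prefix, "_signal.csv"),
             peaks = paste0(out_prefix, "_peaks.csv"))
  write_export_table(sig, paths["signal"])
  write_export_table(pk, paths["peaks"])
  paths
}

#' Read an exported CSV back
#'
#' Validates the schema (all metadata columns present, at least one frame
#' column) and returns the table with numeric frame columns. Extra unknown
#' columns are preserved untouched. Re-writing the result reproduces the
#' original bytes (canonical serialization).
#'
#' @param path a `_signal.csv` or `_peaks.csv` file.
#' @return a data frame with attribute `"frame_cols"` naming the frame
#'   columns.
#' @export
read_export <- function(path) {
  tab <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  # text metadata columns stay character even when empty (all-"" Groups
  # columns would otherwise parse as logical NA)
  for (cc in intersect(setdiff(EXPORT_META_COLS, c("X", "Y")), names(tab))) {
    tab[[cc]] <- as.character(tab[[cc]])
    tab[[cc]][is.na(tab[[cc]])] <- ""
  }
  missing <- setdiff(EXPORT_META_COLS, names(tab))
  if (length(missing) > 0)
    stop("export file lacks required column(s): ",
         paste(missing, collapse = ", "))
  frame_cols <- grep("^F[0-9]+$", names(tab), value = TRUE)
  if (length(frame_cols) == 0) stop("export file has no frame columns")
  attr(tab, "frame_cols") <- frame_cols
  tab
}

#' Rebuild a trace matrix from an exported signal table
#'
#' @param tab a data frame from [read_export()].
#' @return a [trace_matrix()].
#' @export
export_to_traces <- function(tab) {
  frame_cols <- attr(tab, "frame_cols") %||%
    grep("^F[0-9]+$", names(tab), value = TRUE)
  vals <- as.matrix(tab[, frame_cols, drop = FALSE])
  dimnames(vals) <- NULL
  trace_matrix(vals,
               tab$ROI, cbind(tab$X, tab$Y),
               source_name = tab$Name[1],
               filter = tab$Filter[1],
               detection_method = tab$Detection.Method[1])
}
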