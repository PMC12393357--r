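#' Cell manager: ordered ROI collection with named groups
#'
#' Holds an ordered list of uniquely named ROIs plus named groups (ordered
#' lists of member ROI names). A ROI may belong to several groups; exports
#' join group names with `";"`. Group membership is decided by ROI centroid
#' (cheap, and a good match for compact nuclear ROIs).
#'
#' @param rois list of [roi()] objects with unique names.
#' @param groups named list of character vectors of member ROI names.
#' @return an object of class `calmov_cellmanager`.
#' @export
cell_manager <- function(rois = list(), groups = list()) {
  nms <- vapply(rois, function(r) r$name, "")
  if (anyDuplicated(nms)) stop("duplicate ROI names: ",
                               paste(unique(nms[duplicated(nms)]), collapse = ", "))
  groups <- lapply(groups, as.character)
  for (g in names(groups)) {
    missing <- setdiff(groups[[g]], nms)
    if (length(missing) > 0)
      stop("group '", g, "' references unknown ROI(s): ",
           paste(missing, collapse = ", "))
  }
  structure(list(rois = rois, groups = groups), class = "calmov_cellmanager")
}

#' @export
print.calmov_cellmanager <- function(x, ...) {
  cat(sprintf("<calmov_cellmanager: %d ROI(s), %d group(s)>\n",
              length(x$rois), length(x$groups)))
  invisible(x)
}

manager_names <- function(manager) vapply(manager$rois, function(r) r$name, "")

manager_centroids <- function(manager) {
  if (length(manager$rois) == 0) return(matrix(numeric(0), 0, 2))
  do.call(rbind, lapply(manager$rois, roi_centroid))
}

#' Group ROIs enclosed by a polygon
#'
#' Every ROI whose centroid lies strictly inside the polygon (even-odd rule)
#' is appended to the group, preserving manager order. Idempotent: re-running
#' adds no duplicates.
#'
#' @param manager a [cell_manager()].
#' @param polygon numeric matrix (>= 3 rows) of (x, y) vertices; must have
#'   non-zero area.
#' @param group_name group to create or extend.
#' @return the updated [cell_manager()].
#' @export
group_by_polygon <- function(manager, polygon, group_name) {
  polygon <- rbind(polygon)
  if (nrow(polygon) < 3) stop("grouping polygon needs >= 3 vertices")
  if (abs(polygon_area(polygon[, 1], polygon[, 2])) == 0)
    stop("degenerate grouping polygon (zero area)")
  cents <- manager_centroids(manager)
  if (nrow(cents) == 0) return(manager)
  inside <- point_in_polygon(cents[, 1], cents[, 2],
                             polygon[, 1], polygon[, 2])
  members <- manager_names(manager)[inside]
  existing <- manager$groups[[group_name]] %||% character(0)
  manager$groups[[group_name]] <- c(existing, setdiff(members, existing))
  manager
}

#' Group ROIs by point selection
#'
#' For each point, the ROI with the nearest centroid within `max_distance`
#' is added to the group (ties go to the lowest manager index). Points
#' matching no ROI are reported with a message and counted in the
#' `"unmatched"` attribute of the result; they are not an error.
#'
#' @param manager a [cell_manager()] with at least one ROI.
#' @param points numeric matrix of (x, y) selection points.
#' @param group_name group to create or extend.
#' @param max_distance maximum centroid distance in pixels (> 0).
#' @return the updated [cell_manager()] (attribute `"unmatched"`: number of
#'   points that matched nothing).
#' @export
group_by_points <- function(manager, points, group_name, max_distance) {
  stopifnot(max_distance > 0)
  if (length(manager$rois) == 0) stop("cell manager is empty")
  points <- rbind(points)
  cents <- manager_centroids(manager)
  nms <- manager_names(manager)
  existing <- manager$groups[[group_name]] %||% character(0)
  unmatched <- 0L
  for (p in seq_len(nrow(points))) {
    d <- sqrt((cents[, 1] - points[p, 1])^2 + (cents[, 2] - points[p, 2])^2)
    i <- which.min(d)  # lowest index on ties
    if (d[i] <= max_distance) {
      if (!nms[i] %in% existing) existing <- c(existing, nms[i])
    } else {
      unmatched <- unmatched + 1L
    }
  }
  if (unmatched > 0)
    message(unmatched, " point(s) matched no ROI within ", max_distance, " px")
  manager$groups[[group_name]] <- existing
  attr(manager, "unmatched") <- unmatched
  manager
}

#' Rename all ROIs by pattern
#'
#' The pattern's `{i}` placeholder is replaced by the 1-based ROI index.
#' Group memberships follow the rename. A pattern producing duplicate names
#' is an error.
#'
#' @param manager a [cell_manager()].
#' @param pattern string containing `{i}`, e.g. `"cell_{i}"`.
#' @return the renamed [cell_manager()].
#' @export
rename_rois <- function(manager, pattern = "cell_{i}") {
  n <- length(manager$rois)
  new <- vapply(seq_len(n), function(i) gsub("{i}", i, pattern, fixed = TRUE), "")
  if (anyDuplicated(new))
    stop("rename pattern produces duplicate names; include {i}")
  old <- manager_names(manager)
  for (i in seq_len(n)) manager$rois[[i]]$name <- new[i]
  manager$groups <- lapply(manager$groups, function(members)
    new[match(members, old)])
  manager
}

#' Replace the manager's ROI list (sync)
#'
#' Replaces the ROI list wholesale, deduplicating incoming duplicate names by
#' suffixing `-1`, `-2`, ... (with a warning), and pruning every group of
#' member names no longer present.
#'
#' @param manager a [cell_manager()].
#' @param rois the incoming list of [roi()]s (may be empty).
#' @return the synced [cell_manager()].
#' @export
sync_rois <- function(manager, rois) {
  nms <- vapply(rois, function(r) r$name, "")
  if (anyDuplicated(nms)) {
    warning("duplicate incoming ROI names deduplicated by suffixing")
    for (i in seq_along(rois)) {
      k <- sum(nms[seq_len(i)] == nms[i]) - 1
      if (k > 0) rois[[i]]$name <- paste0(nms[i], "-", k)
    }
    nms <- vapply(rois, function(r) r$name, "")
  }
  groups <- lapply(manager$groups, function(members) members[members %in% nms])
  cell_manager(rois, groups)
}

#' Persist / load a cell manager
#'
#' The manager is stored as a JSON sidecar holding the group structure and a
#' reference to an ImageJ ROI `.zip`/`.roi` file (written alongside), so
#' annotation survives sessions and the ROIs stay ImageJ-compatible.
#'
#' @param manager a [cell_manager()].
#' @param path JSON output path.
#' @param roi_file path for the ROI file; default replaces the JSON extension
#'   with `_rois.zip`.
#' @return `write_cell_manager`: the JSON path, invisibly.
#'   `read_cell_manager`: the restored [cell_manager()].
#' @export
write_cell_manager <- function(manager, path, roi_file = NULL) {
  roi_file <- roi_file %||%
    paste0(tools::file_path_sans_ext(path), "_rois",
           if (length(manager$rois) == 1) ".roi" else ".zip")
  if (length(manager$rois) > 0) write_imagej_rois(manager$rois, roi_file)
  obj <- list(roi_file = basename(roi_file),
              roi_names = manager_names(manager),
              groups = manager$groups)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname write_cell_manager
#' @export
read_cell_manager <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  roi_path <- file.path(dirname(path), obj$roi_file)
  rois <- if (length(obj$roi_names) > 0) read_imagej_rois(roi_path) else list()
  groups <- lapply(obj$groups, as.character)
  if (is.null(names(groups))) groups <- stats::setNames(list(), character(0))
  cell_manager(rois, groups)
}
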