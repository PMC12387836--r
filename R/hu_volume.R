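#' CT attenuation volume
#'
#' Container for a 3D grid of CT attenuation in Hounsfield units (HU) with
#' voxel spacing and physical origin. Attenuation is the densitometric
#' substrate for tissue classification: air is near -1000 HU, water 0 HU.
#'
#' @param values 3D numeric array of HU values; all finite, non-empty.
#' @param spacing voxel edge lengths in mm per axis (length 3, strictly
#'   positive). Clinical thin-slice HRCT is typically ~0.7 x 0.7 x 1-1.5 mm.
#' @param origin physical offset of the first voxel in mm (length 3).
#' @return an object of class `hu_volume`.
#' @seealso [lung_label_map()], [classify_volume()]
#' @export
hu_volume <- function(values, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (!is.array(values) || length(dim(values)) != 3L || length(values) == 0L)
    stop("'values' must be a non-empty 3D array")
  if (!all(is.finite(values)))
    stop("HU values must all be finite")
  spacing <- as.double(spacing)
  if (length(spacing) != 3L || !all(is.finite(spacing)) || any(spacing <= 0))
    stop("'spacing' must be 3 strictly positive voxel edge lengths (mm)")
  origin <- as.double(origin)
  if (length(origin) != 3L || !all(is.finite(origin)))
    stop("'origin' must be 3 finite offsets (mm)")
  structure(list(values = values, spacing = spacing, origin = origin),
            class = "hu_volume")
}

#' @export
print.hu_volume <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<hu_volume> %d x %d x %d voxels, spacing %s mm\n",
              d[1], d[2], d[3], paste(format(x$spacing), collapse = " x ")))
  cat(sprintf("  HU range [%.1f, %.1f], voxel volume %.4f mm^3\n",
              min(x$values), max(x$values), prod(x$spacing)))
  invisible(x)
}

# voxel volume in mL (mm^3 / 1000)
voxel_ml <- function(vol) prod(vol$spacing) / 1000

#' Anatomical lung segment label map
#'
#' Per-voxel integer region codes co-registered with an [hu_volume()]:
#' 0 is background (outside the lungs), each positive code is one
#' bronchopulmonary segment (or a bulk region) described in the label table.
#' The table is authoritative for laterality and lobe membership; no
#' geometric left/right inference is performed.
#'
#' @param labels 3D array of non-negative integer codes.
#' @param table data.frame with columns `code`, `laterality` ("left"/"right"),
#'   `lobe`, `segment`. Every nonzero code present in `labels` must appear.
#' @return an object of class `lung_label_map`.
#' @export
lung_label_map <- function(labels, table) {
  if (!is.array(labels) || length(dim(labels)) != 3L)
    stop("'labels' must be a 3D array")
  storage.mode(labels) <- "integer"
  if (anyNA(labels) || any(labels < 0L))
    stop("label codes must be non-negative integers")
  table <- as.data.frame(table, stringsAsFactors = FALSE)
  req <- c("code", "laterality", "lobe", "segment")
  if (!all(req %in% names(table)))
    stop("label table needs columns: ", paste(req, collapse = ", "))
  table$code <- as.integer(table$code)
  if (anyDuplicated(table$code)) stop("duplicate codes in label table")
  if (!all(table$laterality %in% c("left", "right")))
    stop("laterality must be 'left' or 'right'")
  present <- setdiff(sort(unique(as.vector(labels))), 0L)
  missing <- setdiff(present, table$code)
  if (length(missing))
    stop("codes present in grid but absent from table: ",
         paste(missing, collapse = ", "))
  structure(list(labels = labels, table = table), class = "lung_label_map")
}

#' @export
print.lung_label_map <- function(x, ...) {
  d <- dim(x$labels)
  cat(sprintf("<lung_label_map> %d x %d x %d voxels, %d regions (%d right, %d left)\n",
              d[1], d[2], d[3], nrow(x$table),
              sum(x$table$laterality == "right"), sum(x$table$laterality == "left")))
  invisible(x)
}

check_same_grid <- function(vol, labels) {
  if (!identical(dim(vol$values), dim(labels$labels)))
    stop("HU volume and label map must share the same grid shape")
  invisible(TRUE)
}

#' Default right-lung segment nomenclature
#'
#' Ten right-lung segments (S1-S3 right upper lobe, S4-S5 middle lobe,
#' S6-S10 lower lobe) plus a single bulk region for the left lung, which is
#' modelled only as a whole-lung denominator.
#'
#' @return data.frame with columns `code`, `laterality`, `lobe`, `segment`.
#' @export
default_segment_table <- function() {
  data.frame(
    code = 1:11,
    laterality = c(rep("right", 10), "left"),
    lobe = c(rep("RUL", 3), rep("RML", 2), rep("RLL", 5), "left_lung"),
    segment = c(paste0("S", 1:10), "left_bulk"),
    stringsAsFactors = FALSE
  )
}

#' Read/write volumes and label maps on disk
#'
#' HU volumes and label maps are stored as NIfTI-1 (`.nii`/`.nii.gz`); the
#' label table travels as a sidecar JSON mapping
#' `code -> {laterality, lobe, segment}` (default: same path with extension
#' replaced by `.labels.json`).
#'
#' @param path NIfTI file path.
#' @param vol an [hu_volume()].
#' @return `read_hu_volume()` an `hu_volume`; `read_lung_label_map()` a
#'   `lung_label_map`; writers return their path invisibly.
#' @export
read_hu_volume <- function(path) {
  x <- read_nifti(path)
  hu_volume(x$data, spacing = x$spacing, origin = x$origin)
}

#' @rdname read_hu_volume
#' @export
write_hu_volume <- function(vol, path) {
  write_nifti(path, vol$values, spacing = vol$spacing, origin = vol$origin,
              datatype = "float32")
}

label_sidecar_path <- function(path) sub("\\.nii(\\.gz)?$", ".labels.json", path)

#' @rdname read_hu_volume
#' @param map a [lung_label_map()].
#' @param table_path sidecar JSON path for the label table.
#' @export
write_lung_label_map <- function(map, path, table_path = label_sidecar_path(path)) {
  write_nifti(path, map$labels, datatype = "int32")
  tab <- map$table
  sidecar <- stats::setNames(
    lapply(seq_len(nrow(tab)), function(i)
      list(laterality = tab$laterality[i], lobe = tab$lobe[i],
           segment = tab$segment[i])),
    as.character(tab$code))
  jsonlite::write_json(sidecar, table_path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname read_hu_volume
#' @export
read_lung_label_map <- function(path, table_path = label_sidecar_path(path)) {
  x <- read_nifti(path)
  sidecar <- jsonlite::read_json(table_path)
  table <- data.frame(
    code = as.integer(names(sidecar)),
    laterality = vapply(sidecar, function(e) e$laterality, ""),
    lobe = vapply(sidecar, function(e) e$lobe, ""),
    segment = vapply(sidecar, function(e) e$segment, ""),
    stringsAsFactors = FALSE, row.names = NULL
  )
  lab <- x$data
  storage.mode(lab) <- "integer"
  lung_label_map(lab, table)
}
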