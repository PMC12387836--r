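#' Classify lung voxels by Hounsfield-unit thresholds
#'
#' Maps every lung voxel into one of three tissue classes used for functional
#' volumetry: well-aerated (functional) parenchyma at HU in
#' `[theta_emph, theta_well_max]`, emphysematous (destroyed, hyperinflated)
#' tissue below `theta_emph`, and poorly aerated/non-aerated tissue above
#' `theta_well_max`. Voxels where the label map is 0 are background.
#'
#' The defaults encode the conventional densitometric window for functional
#' parenchyma, -900 to -501 HU; values below -900 HU are read as emphysema
#' and values above as dense, poorly ventilated tissue. The upper boundary is
#' closed at -501 so that non-integer HU in (-501, -500] fall in the
#' non-aerated class.
#'
#' @param vol an [hu_volume()].
#' @param labels a [lung_label_map()] on the same grid.
#' @param theta_emph lower HU bound of well-aerated tissue; strictly below
#'   is emphysematous. Default -900 HU.
#' @param theta_well_max upper HU bound (inclusive) of well-aerated tissue;
#'   strictly above is non-aerated. Default -501 HU.
#' @return a `tissue_class_map`: list with `classes` (3D integer array coded
#'   0 background, 1 well_aerated, 2 emphysematous, 3 non_aerated) and
#'   `thresholds`.
#' @export
classify_volume <- function(vol, labels, theta_emph = -900, theta_well_max = -501) {
  stopifnot(inherits(vol, "hu_volume"), inherits(labels, "lung_label_map"))
  check_same_grid(vol, labels)
  if (theta_emph >= theta_well_max)
    stop("'theta_emph' must be below 'theta_well_max'")
  hu <- vol$values
  if (!all(is.finite(hu))) stop("HU values must all be finite")
  cls <- array(0L, dim = dim(hu))
  lung <- labels$labels > 0L
  cls[lung] <- 1L
  cls[lung & hu < theta_emph] <- 2L
  cls[lung & hu > theta_well_max] <- 3L
  structure(
    list(classes = cls,
         thresholds = c(theta_emph = theta_emph, theta_well_max = theta_well_max)),
    class = "tissue_class_map")
}

TISSUE_CLASSES <- c(well_aerated = 1L, emphysematous = 2L, non_aerated = 3L)

#' @export
print.tissue_class_map <- function(x, ...) {
  n <- tabulate(x$classes + 1L, nbins = 4L)
  lung <- sum(n[2:4])
  cat(sprintf("<tissue_class_map> %d lung voxels (thresholds %g / %g HU)\n",
              lung, x$thresholds[1], x$thresholds[2]))
  if (lung > 0)
    cat(sprintf("  well_aerated %.1f%%  emphysematous %.1f%%  non_aerated %.1f%%\n",
                100 * n[2] / lung, 100 * n[3] / lung, 100 * n[4] / lung))
  invisible(x)
}

#' Per-region tissue-class volumetrics
#'
#' Tallies voxel counts of each tissue class per anatomical segment and
#' converts them to volumes in mL using the voxel volume from the HU volume's
#' spacing. Aggregates (lobe, lung, whole lung) are sums of their constituent
#' segments' voxel counts — never a re-classification — so the class volumes
#' always add up exactly to the total at every level.
#'
#' @param classmap a `tissue_class_map` from [classify_volume()].
#' @param labels the [lung_label_map()] used for classification.
#' @param vol the paired [hu_volume()] (supplies voxel spacing).
#' @return data.frame of class `region_volumetrics`, one row per segment,
#'   per lobe, per lung, plus `whole_lung`; columns `region_id`, `level`,
#'   `laterality`, `lobe`, `segment`, voxel counts (`voxels_*`) and volumes
#'   in mL (`volume_*_ml`). Segments listed in the table but absent from the
#'   grid yield zero-volume rows with a warning.
#' @export
region_volumetrics <- function(classmap, labels, vol) {
  stopifnot(inherits(classmap, "tissue_class_map"),
            inherits(labels, "lung_label_map"), inherits(vol, "hu_volume"))
  check_same_grid(vol, labels)
  if (!identical(dim(classmap$classes), dim(labels$labels)))
    stop("class map and label map must share the same grid shape")
  tab <- labels$table
  vml <- voxel_ml(vol)

  lab <- as.vector(labels$labels)
  cls <- as.vector(classmap$classes)
  inside <- lab > 0L
  lab <- lab[inside]; cls <- cls[inside]
  max_code <- max(tab$code)
  # per-segment class counts via a single tabulate over (code, class) cells
  idx <- (lab - 1L) * 3L + cls
  flat <- tabulate(idx, nbins = max_code * 3L)
  counts <- matrix(flat, nrow = max_code, ncol = 3L, byrow = TRUE)
  colnames(counts) <- names(TISSUE_CLASSES)

  seg_counts <- counts[tab$code, , drop = FALSE]
  absent <- rowSums(seg_counts) == 0
  if (any(absent))
    warning("segments in table but absent from grid (zero volume): ",
            paste(tab$segment[absent], collapse = ", "))

  row_from_counts <- function(region_id, level, laterality, lobe, segment, cnt) {
    cnt <- as.numeric(cnt)
    total <- sum(cnt)
    data.frame(region_id = region_id, level = level, laterality = laterality,
               lobe = lobe, segment = segment,
               voxels_total = total,
               voxels_well_aerated = cnt[[1]],
               voxels_emphysematous = cnt[[2]],
               voxels_non_aerated = cnt[[3]],
               volume_total_ml = total * vml,
               volume_well_aerated_ml = cnt[[1]] * vml,
               volume_emphysematous_ml = cnt[[2]] * vml,
               volume_non_aerated_ml = cnt[[3]] * vml,
               stringsAsFactors = FALSE)
  }

  rows <- lapply(seq_len(nrow(tab)), function(i)
    row_from_counts(as.character(tab$code[i]), "segment", tab$laterality[i],
                    tab$lobe[i], tab$segment[i], seg_counts[i, ]))

  for (lt in unique(tab$laterality)) for (lb in unique(tab$lobe[tab$laterality == lt])) {
    sel <- tab$laterality == lt & tab$lobe == lb
    cnt <- (colSums(seg_counts[sel, , drop = FALSE]))
    rows[[length(rows) + 1L]] <- row_from_counts(paste0("lobe:", lb), "lobe", lt, lb, NA, cnt)
  }
  for (lt in unique(tab$laterality)) {
    sel <- tab$laterality == lt
    cnt <- (colSums(seg_counts[sel, , drop = FALSE]))
    rows[[length(rows) + 1L]] <- row_from_counts(paste0("lung:", lt), "lung", lt, NA, NA, cnt)
  }
  cnt <- (colSums(seg_counts))
  rows[[length(rows) + 1L]] <- row_from_counts("whole_lung", "whole_lung", NA, NA, NA, cnt)

  out <- do.call(rbind, rows)
  attr(out, "voxel_ml") <- vml
  class(out) <- c("region_volumetrics", "data.frame")
  out
}

#' Write region volumetrics as CSV
#'
#' One row per region with identifiers and volumes in mL; voxel-count columns
#' are dropped from the file.
#'
#' @param volumetrics a [region_volumetrics()] data.frame.
#' @param path output CSV path.
#' @export
write_volumetrics_csv <- function(volumetrics, path) {
  keep <- c("region_id", "level", "laterality", "lobe", "segment",
            "volume_total_ml", "volume_well_aerated_ml",
            "volume_emphysematous_ml", "volume_non_aerated_ml")
  utils::write.csv(as.data.frame(volumetrics)[, keep], path, row.names = FALSE)
  invisible(path)
}

#' Resection plan over anatomical segments
#'
#' The set of segment label codes to be removed in a simulated anatomical
#' resection. All removed segments must lie in one lung (resections here are
#' unilateral), and the plan cannot be empty.
#'
#' @param removed_segments integer label codes, or segment names matched
#'   against the table's `segment` column.
#' @param table label table (data.frame with `code`, `laterality`, `segment`).
#' @return object of class `resection_plan`: list with `codes`, `laterality`.
#' @export
resection_plan <- function(removed_segments, table) {
  table <- as.data.frame(table)
  if (length(removed_segments) == 0L) stop("resection plan must be non-empty")
  if (is.character(removed_segments)) {
    codes <- table$code[match(removed_segments, table$segment)]
    if (anyNA(codes))
      stop("unknown segment name(s): ",
           paste(removed_segments[is.na(codes)], collapse = ", "))
  } else {
    codes <- as.integer(removed_segments)
    if (!all(codes %in% table$code))
      stop("unknown segment code(s): ",
           paste(setdiff(codes, table$code), collapse = ", "))
  }
  codes <- unique(codes)
  lat <- unique(table$laterality[match(codes, table$code)])
  if (length(lat) != 1L)
    stop("all removed segments must share one laterality")
  structure(list(codes = codes, laterality = lat), class = "resection_plan")
}

#' Simulated anatomical resection volumetrics
#'
#' Computes the removed/remaining tissue fractions for a planned resection
#' from per-segment volumetrics. "Functional" tissue is the well-aerated
#' class exactly; poorly aerated tissue counts as non-functional.
#'
#' Reported metrics:
#' \describe{
#'   \item{removed_total_fraction}{removed volume / whole-lung volume.}
#'   \item{removed_functional_fraction}{removed well-aerated volume /
#'     whole-lung well-aerated volume — the "% of removed functioning lung
#'     parenchyma" input to the Brunelli regressions (as a 0-1 fraction).}
#'   \item{healthy_over_total}{whole-lung well-aerated / whole-lung total.}
#'   \item{ipsi_remaining_healthy_over_total}{in the operated lung after
#'     removal, well-aerated / total.}
#'   \item{removed_healthy_over_removed_total}{within the removed segments,
#'     well-aerated / total.}
#' }
#'
#' @param volumetrics a [region_volumetrics()] data.frame (segment rows are
#'   used; aggregates are recomputed from them so conservation is exact).
#' @param plan a [resection_plan()].
#' @return object of class `resection_simulation`: the five fractions plus
#'   removed/remaining volumes (mL) per tissue class.
#' @export
simulate_resection <- function(volumetrics, plan) {
  stopifnot(inherits(plan, "resection_plan"))
  df <- as.data.frame(volumetrics)
  seg <- df[df$level == "segment", , drop = FALSE]
  if (nrow(seg) == 0L) stop("volumetrics contain no segment rows")
  if (!all(as.character(plan$codes) %in% seg$region_id))
    stop("plan segments missing from volumetrics: ",
         paste(setdiff(as.character(plan$codes), seg$region_id), collapse = ", "))
  rem <- seg$region_id %in% as.character(plan$codes)
  ipsi <- seg$laterality == plan$laterality

  vol_cols <- c("volume_total_ml", "volume_well_aerated_ml",
                "volume_emphysematous_ml", "volume_non_aerated_ml")
  tot <- colSums(seg[, vol_cols, drop = FALSE])
  removed <- colSums(seg[rem, vol_cols, drop = FALSE])
  remaining <- tot - removed
  ipsi_remaining <- colSums(seg[ipsi & !rem, vol_cols, drop = FALSE])

  frac <- function(num, den, what) {
    if (den <= 0)
      stop("undefined fraction: zero denominator for ", what,
         call. = FALSE)
    num / den
  }
  structure(list(
    removed_total_fraction =
      frac(removed[["volume_total_ml"]], tot[["volume_total_ml"]], "whole-lung volume"),
    removed_functional_fraction =
      frac(removed[["volume_well_aerated_ml"]], tot[["volume_well_aerated_ml"]],
           "whole-lung well-aerated volume"),
    healthy_over_total =
      frac(tot[["volume_well_aerated_ml"]], tot[["volume_total_ml"]], "whole-lung volume"),
    ipsi_remaining_healthy_over_total =
      frac(ipsi_remaining[["volume_well_aerated_ml"]],
           ipsi_remaining[["volume_total_ml"]], "ipsilateral remaining volume"),
    removed_healthy_over_removed_total =
      frac(removed[["volume_well_aerated_ml"]], removed[["volume_total_ml"]],
           "removed volume"),
    removed_ml = removed, remaining_ml = remaining, whole_lung_ml = tot,
    plan = plan
  ), class = "resection_simulation")
}

#' @export
print.resection_simulation <- function(x, ...) {
  cat("<resection_simulation>\n")
  cat(sprintf("  removed segments: %s (%s lung)\n",
              paste(x$plan$codes, collapse = ", "), x$plan$laterality))
  cat(sprintf("  removed: %.1f%% of total lung, %.1f%% of functional parenchyma\n",
              100 * x$removed_total_fraction, 100 * x$removed_functional_fraction))
  cat(sprintf("  healthy/total: %.0f%% whole lung | %.0f%% ipsilateral remaining | %.0f%% removed region\n",
              100 * x$healthy_over_total,
              100 * x$ipsi_remaining_healthy_over_total,
              100 * x$removed_healthy_over_removed_total))
  invisible(x)
}
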