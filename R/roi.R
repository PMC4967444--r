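#' Region-of-interest mask
#'
#' A binary synovium mask on the dynamic image grid. Masks are supplied in
#' dynamic-image space (the registration between the high-resolution
#' segmentation and the dynamic series is taken as identity here).
#'
#' @param x either a logical/0-1 3D array, or an integer matrix of voxel
#'   indices with 3 columns (1-based `i, j, k`).
#' @param voxel_size voxel edge lengths in mm, length-3, strictly positive.
#' @param dim grid dimensions (required when `x` is an index matrix).
#' @return Object of class `"roi_mask"`: list with `dim`, `voxel_size` and
#'   sorted linear `indices`.
#' @export
roi_mask <- function(x, voxel_size, dim = NULL) {
  voxel_size <- as.numeric(voxel_size)
  if (length(voxel_size) != 3L || any(!is.finite(voxel_size)) || any(voxel_size <= 0))
    stop("voxel_size must be three positive lengths (mm)")
  if (is.array(x) && length(base::dim(x)) == 3L) {
    dm <- base::dim(x)
    lin <- which(x != 0)
  } else if (is.matrix(x) && ncol(x) == 3L) {
    if (is.null(dim)) stop("dim is required when supplying voxel indices")
    dm <- as.integer(dim)
    if (nrow(x) > 0L) {
      if (any(x < 1L) || any(t(x) > dm)) stop("mask indices fall outside the grid")
      lin <- as.integer((x[, 3L] - 1L) * dm[1L] * dm[2L] + (x[, 2L] - 1L) * dm[1L] + x[, 1L])
    } else lin <- integer(0)
  } else stop("x must be a 3D array or an n x 3 index matrix")
  structure(list(dim = as.integer(dm), voxel_size = voxel_size,
                 indices = sort(unique(as.integer(lin)))),
            class = "roi_mask")
}

#' Voxel index triples of a mask
#'
#' @param mask a [roi_mask()].
#' @return Integer matrix with columns `i, j, k` (1-based), one row per
#'   in-mask voxel, in increasing linear-index order.
#' @export
mask_voxel_indices <- function(mask) {
  stopifnot(inherits(mask, "roi_mask"))
  lin <- mask$indices - 1L
  d <- mask$dim
  k <- lin %/% (d[1L] * d[2L])
  r <- lin %% (d[1L] * d[2L])
  cbind(i = r %% d[1L] + 1L, j = r %/% d[1L] + 1L, k = k + 1L)
}

#' Mask as a logical array
#' @param mask a [roi_mask()].
#' @return Logical 3D array of the mask's grid dimensions.
#' @export
mask_array <- function(mask) {
  stopifnot(inherits(mask, "roi_mask"))
  a <- array(FALSE, mask$dim)
  a[mask$indices] <- TRUE
  a
}

#' Synovial tissue volume of a mask
#'
#' In-mask voxel count times voxel volume.
#'
#' @param mask a [roi_mask()].
#' @return Volume in cubic millimetres.
#' @examples
#' m <- roi_mask(cbind(1:100, 1, 1), voxel_size = c(1.5, 1.5, 3), dim = c(100, 2, 2))
#' synovial_volume(m)  # 675 mm^3
#' @export
synovial_volume <- function(mask) {
  stopifnot(inherits(mask, "roi_mask"))
  length(mask$indices) * prod(mask$voxel_size)
}

#' Median of a voxelwise parameter over the evaluable ROI voxels
#'
#' The summary statistic reported per subject-visit is the median across
#' in-mask voxels; non-evaluable voxels (e.g., non-positive baseline signal)
#' are excluded first. With an even count the mean of the two central order
#' statistics is used (the `stats::median` convention).
#'
#' @param values numeric vector, one value per in-mask voxel.
#' @param evaluable optional logical vector marking which voxels enter the
#'   median; defaults to `is.finite(values)`.
#' @return The median, or `NA_real_` (with a message) when no voxel is
#'   evaluable — the record is then treated as missing downstream, matching
#'   the exclusion of knees without enhancing synovitis.
#' @export
median_over_roi <- function(values, evaluable = NULL) {
  values <- as.numeric(values)
  if (length(values) < 1L) stop("need at least one voxel value")
  if (is.null(evaluable)) evaluable <- is.finite(values)
  stopifnot(length(evaluable) == length(values))
  keep <- evaluable & is.finite(values)
  if (!any(keep)) {
    message("no evaluable voxels in ROI; record flagged missing")
    return(NA_real_)
  }
  stats::median(values[keep])
}

#' Assemble the long-format cohort table
#'
#' Joins per-subject-per-visit imaging summaries with the clinical table
#' into one record per subject-visit. Subjects lacking either visit (or with
#' a missing imaging summary) are dropped with a logged reason, mirroring a
#' complete-case longitudinal analysis; duplicated subject-visit rows are a
#' hard error.
#'
#' @param imaging `data.frame` with columns `subject_id`, `visit`
#'   (`"baseline"`/`"followup"`), `volume_mm3`, `rer`, `re_late`, `re_max`,
#'   `ktrans`, `ve`. Column order is irrelevant (schema-keyed).
#' @param clinical `data.frame` with columns `subject_id`, `visit`,
#'   `koos_pain` (0-100), `protocol`.
#' @return A `data.frame` of class `"cohort_table"` with columns
#'   `subject_id, visit, protocol, volume_mm3, rer, re_late, re_max, ktrans,
#'   ve, koos_pain`, two rows per retained subject, ordered by subject then
#'   visit. Dropped subjects and reasons are attached as attribute
#'   `"exclusions"`.
#' @export
build_cohort_table <- function(imaging, clinical) {
  img_cols <- c("subject_id", "visit", "volume_mm3", "rer", "re_late",
                "re_max", "ktrans", "ve")
  clin_cols <- c("subject_id", "visit", "koos_pain", "protocol")
  if (!all(img_cols %in% names(imaging)))
    stop("imaging table missing columns: ",
         paste(setdiff(img_cols, names(imaging)), collapse = ", "))
  if (!all(clin_cols %in% names(clinical)))
    stop("clinical table missing columns: ",
         paste(setdiff(clin_cols, names(clinical)), collapse = ", "))
  imaging <- imaging[img_cols]
  clinical <- clinical[clin_cols]
  for (d in list(imaging, clinical)) {
    key <- paste(d$subject_id, d$visit)
    if (anyDuplicated(key)) stop("duplicate subject-visit rows")
    if (!all(d$visit %in% c("baseline", "followup")))
      stop("visit must be 'baseline' or 'followup'")
  }
  if (any(!is.na(clinical$koos_pain) &
          (clinical$koos_pain < 0 | clinical$koos_pain > 100)))
    stop("koos_pain must lie in [0, 100]")

  tab <- merge(imaging, clinical, by = c("subject_id", "visit"), all = FALSE)
  num_cols <- c("volume_mm3", "rer", "re_late", "re_max", "ktrans", "ve", "koos_pain")
  complete <- stats::complete.cases(tab[num_cols])
  exclusions <- data.frame(subject_id = character(0), reason = character(0))
  bad_subj <- unique(tab$subject_id[!complete])
  if (length(bad_subj)) {
    exclusions <- rbind(exclusions, data.frame(
      subject_id = bad_subj, reason = "missing parameter value"))
    tab <- tab[!tab$subject_id %in% bad_subj, , drop = FALSE]
  }
  counts <- table(tab$subject_id)
  incomplete <- names(counts)[counts < 2L]
  if (length(incomplete)) {
    exclusions <- rbind(exclusions, data.frame(
      subject_id = incomplete, reason = "missing visit"))
    tab <- tab[!tab$subject_id %in% incomplete, , drop = FALSE]
  }
  only_img <- setdiff(unique(imaging$subject_id), unique(tab$subject_id))
  only_img <- setdiff(only_img, exclusions$subject_id)
  if (length(only_img))
    exclusions <- rbind(exclusions, data.frame(
      subject_id = only_img, reason = "no matching clinical record"))
  if (nrow(exclusions))
    message(nrow(exclusions), " subject(s) excluded: ",
            paste(unique(exclusions$reason), collapse = "; "))
  tab <- tab[order(tab$subject_id, tab$visit),
             c("subject_id", "visit", "protocol", "volume_mm3", "rer",
               "re_late", "re_max", "ktrans", "ve", "koos_pain")]
  rownames(tab) <- NULL
  attr(tab, "exclusions") <- exclusions
  class(tab) <- c("cohort_table", "data.frame")
  tab
}
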