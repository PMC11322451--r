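#' Parcellation schemes and resection-mask bookkeeping
#'
#' A parcellation scheme couples a label table (integer ids with hemisphere
#' side and group tags) with an optional 3D voxel label volume (0 =
#' background). Resection masks are binary voxel grids on the same grid.
#' The central guarantee of this module is the subject-wise
#' timepoint-invariant parcellation: the two postoperative cavity masks are
#' merged (voxel-wise union) and label portions under the merged mask are
#' excluded identically at every timepoint, so a subject's retained label
#' set never varies across scans.
#'
#' @name parcellation_masking
NULL

new_parcellation <- function(labels, volume = NULL) {
  stopifnot(is.data.frame(labels),
            all(c("id", "name", "side", "groups") %in% names(labels)))
  if (anyDuplicated(labels$id)) stop("duplicate label ids", call. = FALSE)
  if (!is.null(volume)) {
    ids <- setdiff(unique(as.vector(volume)), 0L)
    unknown <- setdiff(ids, labels$id)
    if (length(unknown))
      stop("volume contains label ids absent from the table: ",
           paste(unknown, collapse = ", "), call. = FALSE)
  }
  structure(list(labels = labels, volume = volume), class = "parcellation")
}

#' @export
print.parcellation <- function(x, ...) {
  cat(sprintf("parcellation: %d labels (%d left, %d right, %d midline)\n",
              nrow(x$labels), sum(x$labels$side == "left"),
              sum(x$labels$side == "right"), sum(x$labels$side == "midline")))
  if (!is.null(x$volume))
    cat(sprintf("  label volume %s\n", paste(dim(x$volume), collapse = "x")))
  invisible(x)
}

label_has_group <- function(labels, tag) {
  vapply(strsplit(labels$groups, ","), function(g) tag %in% g, logical(1))
}

#' Merge two postoperative resection masks
#'
#' Voxel-wise union of the two cavity masks, accounting for progressive
#' remodeling of the cavity's shape and size between the postoperative
#' scans. In synthetic space the voxel mapping is the identity; a
#' precomputed voxel mapping for registered real data can be applied by the
#' caller beforehand.
#'
#' @param mask_t1,mask_t2 Binary 3D arrays of identical shape.
#' @return Binary integer array, the union.
#' @export
merge_masks <- function(mask_t1, mask_t2) {
  if (!identical(dim(mask_t1), dim(mask_t2)))
    stop_dim("resection masks have different grid shapes")
  if (!all(mask_t1 %in% c(0, 1)) || !all(mask_t2 %in% c(0, 1)))
    stop("masks must be binary (0/1)", call. = FALSE)
  out <- array(as.integer(mask_t1 | mask_t2), dim = dim(mask_t1))
  out
}

#' Exclude masked label portions from a label volume
#'
#' Sets voxels under the merged resection mask to background and drops
#' labels whose surviving voxel count falls below \code{min_retained_voxels}
#' (default 1: a label survives as long as any voxel does, preserving
#' partially resected peri-cavity labels). The excluded fraction is reported
#' per label so stricter retention policies can be layered on top.
#'
#' @param volume 3D integer label array (0 = background).
#' @param merged Binary mask of the same shape.
#' @param min_retained_voxels Minimum surviving voxels for retention.
#' @return An object of class \code{"filtered_parcellation"}: list with
#'   \code{volume} (masked, non-retained labels blanked),
#'   \code{retained_labels} (ordered integer ids) and
#'   \code{removed_fraction} (named numeric, one entry per original label).
#' @export
exclude_masked_labels <- function(volume, merged, min_retained_voxels = 1L) {
  if (!identical(dim(volume), dim(merged)))
    stop_dim("label volume and mask have different grid shapes")
  orig <- table(factor(volume[volume != 0]))
  masked <- volume
  masked[merged == 1] <- 0L
  left <- table(factor(masked[masked != 0], levels = names(orig)))
  removed_fraction <- 1 - as.numeric(left) / as.numeric(orig)
  names(removed_fraction) <- names(orig)
  retained <- as.integer(names(orig))[as.numeric(left) >= min_retained_voxels]
  masked[!(masked %in% c(0L, retained))] <- 0L
  structure(list(volume = masked,
                 retained_labels = sort(retained),
                 removed_fraction = removed_fraction),
            class = "filtered_parcellation")
}

#' @export
print.filtered_parcellation <- function(x, ...) {
  cat(sprintf("filtered parcellation: %d labels retained; %d partially cut\n",
              length(x$retained_labels),
              sum(x$removed_fraction > 0 & x$removed_fraction < 1)))
  invisible(x)
}

#' Apply the merged-mask filter at every timepoint
#'
#' Filters one label volume per timepoint with the same merged mask and
#' verifies the timepoint-invariance contract: all timepoints must retain an
#' identical label set. A divergence signals a registration or mapping bug
#' and raises an error rather than silently propagating inconsistent
#' parcellations.
#'
#' @param volumes Named list of 3D label arrays, one per timepoint.
#' @param merged Merged binary resection mask.
#' @param min_retained_voxels Passed to [exclude_masked_labels()].
#' @return Named list of \code{filtered_parcellation} objects.
#' @export
apply_filter_to_timepoints <- function(volumes, merged,
                                       min_retained_voxels = 1L) {
  stopifnot(is.list(volumes), length(volumes) >= 1)
  out <- lapply(volumes, exclude_masked_labels, merged = merged,
                min_retained_voxels = min_retained_voxels)
  sets <- lapply(out, `[[`, "retained_labels")
  for (k in seq_along(sets)[-1]) {
    if (!identical(sets[[1]], sets[[k]]))
      stop("timepoint-invariance violation: retained label sets differ ",
           "between timepoints (", names(volumes)[1] %||% 1, " vs ",
           names(volumes)[k] %||% k, ")", call. = FALSE)
  }
  out
}
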