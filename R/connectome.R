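#' Connection-weight (CW) assembly from streamline records
#'
#' Turns streamline-level outputs of microstructure-informed tractography
#' filtering into per-subject connection-weight matrices. Each streamline
#' carries a signal contribution; its CW is the contribution multiplied by
#' the streamline length and divided by the mean length of its bundle (all
#' streamlines sharing the same unordered label pair). Per-connection CW is
#' the sum over the bundle. A direct consequence (used as an exact oracle in
#' the tests): a bundle of n streamlines with equal contributions c has
#' CW = n * c regardless of the length distribution.
#'
#' @name connectome_build
NULL

#' Per-streamline connection weight
#'
#' @param contribution Signal contribution of the streamline (>= 0).
#' @param length Streamline length in mm (> 0).
#' @param bundle_mean_length Mean length of the streamline's bundle (> 0).
#' @return contribution * length / bundle_mean_length (vectorized).
#' @export
streamline_weight <- function(contribution, length, bundle_mean_length) {
  if (any(length <= 0) || any(bundle_mean_length <= 0))
    stop("streamline length and bundle mean length must be > 0",
         call. = FALSE)
  if (any(contribution < 0))
    stop("signal contribution must be >= 0", call. = FALSE)
  contribution * length / bundle_mean_length
}

#' Build a connectivity matrix from streamline records
#'
#' Groups streamlines into bundles by unordered label pair, computes each
#' bundle's mean length, and sums the per-streamline weights into the
#' symmetric CW matrix. Streamlines touching a non-retained (resected)
#' label contribute nothing. The matrix spans the full label set of
#' \code{labels} (stable indexing across pipeline stages); rows of dropped
#' labels are structurally zero.
#'
#' @param streamlines data.frame with columns label_a, label_b, length,
#'   contribution (extra columns ignored). Zero-contribution streamlines
#'   are removed before bundle mean lengths are computed (configurable via
#'   \code{drop_zero_before_mean}; the upstream convention is not fixed by
#'   any published account, see vignette).
#' @param labels Label table (data.frame with id, name) defining matrix
#'   order.
#' @param retained_labels Integer ids to keep; defaults to all.
#' @param drop_zero_before_mean Remove zero-contribution streamlines before
#'   computing bundle mean lengths (default TRUE).
#' @return Symmetric non-negative matrix with label names as dimnames.
#' @export
build_matrix <- function(streamlines, labels,
                         retained_labels = labels$id,
                         drop_zero_before_mean = TRUE) {
  P <- nrow(labels)
  m <- matrix(0, P, P, dimnames = list(labels$name, labels$name))
  if (!nrow(streamlines)) return(m)
  unknown <- setdiff(unique(c(streamlines$label_a, streamlines$label_b)),
                     labels$id)
  if (length(unknown))
    stop("streamlines reference unknown label ids: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  keep <- streamlines$label_a %in% retained_labels &
    streamlines$label_b %in% retained_labels
  s <- streamlines[keep, , drop = FALSE]
  if (drop_zero_before_mean) s <- s[s$contribution > 0, , drop = FALSE]
  if (!nrow(s)) return(m)
  ia <- match(s$label_a, labels$id)
  ib <- match(s$label_b, labels$id)
  lo <- pmin(ia, ib); hi <- pmax(ia, ib)
  bundle <- paste(lo, hi)
  mean_len <- stats::ave(s$length, bundle, FUN = mean)
  cw <- streamline_weight(s$contribution, s$length, mean_len)
  agg <- rowsum(cw, bundle)
  ij <- do.call(rbind, lapply(strsplit(rownames(agg), " "), as.integer))
  m[ij] <- agg[, 1]
  m[ij[, c(2, 1), drop = FALSE]] <- agg[, 1]
  diag(m) <- 0
  m
}

#' Side-flip a connectivity matrix
#'
#' Exchanges every left label's row/column with its homotopic right partner
#' (matched by name, \code{L###} to \code{R###}); midline labels stay
#' fixed. Used to mirror left-focus subjects so the surgical hemisphere
#' occupies a common index block across the cohort. The operation is an
#' involution and preserves the multiset of entries and symmetry.
#'
#' @param mat Symmetric matrix with label-name dimnames.
#' @param parcellation Parcellation supplying sides and homotopic pairs.
#' @return Flipped matrix, same dimnames.
#' @export
side_flip <- function(mat, parcellation) {
  labs <- parcellation$labels
  stopifnot(identical(rownames(mat), labs$name))
  perm <- canonical_side_perm(labs)
  out <- mat[perm, perm, drop = FALSE]
  dimnames(out) <- dimnames(mat)
  out
}

#' Group prevalence threshold on the baseline matrices
#'
#' An edge is retained iff the fraction of subjects with zero CW at t0 is
#' strictly below \code{max_zero_fraction}; at the default 0.10, an edge
#' that is zero in 10% or more of subjects (1 of 10) is removed. The
#' resulting support mask is applied identically to all timepoints.
#'
#' @param t0_matrices List of baseline matrices with identical dimnames.
#' @param max_zero_fraction Removal boundary (default 0.10).
#' @return Symmetric logical matrix (FALSE diagonal) of retained edges.
#' @export
group_threshold <- function(t0_matrices, max_zero_fraction = 0.10) {
  stopifnot(length(t0_matrices) >= 1)
  dn <- dimnames(t0_matrices[[1]])
  for (m in t0_matrices)
    if (!identical(dimnames(m), dn))
      stop("matrices have inconsistent label maps", call. = FALSE)
  zero_frac <- Reduce(`+`, lapply(t0_matrices, function(m) m == 0)) /
    length(t0_matrices)
  mask <- zero_frac < max_zero_fraction
  diag(mask) <- FALSE
  mask
}

#' Apply an edge support mask to a matrix
#'
#' @param mat Connectivity matrix.
#' @param support Logical support mask from [group_threshold()].
#' @return Matrix with non-supported entries zeroed.
#' @export
apply_support <- function(mat, support) {
  stopifnot(identical(dim(mat), dim(support)))
  mat * support
}
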