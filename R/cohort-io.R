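#' Read a clinical metadata table
#'
#' Reads the tab-separated clinical table describing one surgical epilepsy
#' cohort (one row per patient). The schema mirrors the demographic tables
#' customary in surgical-series reports: identifiers, sex, ages, resection
#' description, side of surgery, MRI finding, scan/surgery delays in months,
#' follow-up, Engel seizure-outcome class, postoperative deficit and delay to
#' recovery. The token \code{"NA"} marks not-applicable recovery delays
#' (patients without deficits).
#'
#' Row-level invariants (non-negative ages and durations, onset not after
#' surgery, duration consistent with age at surgery minus age of onset up to
#' one year of rounding) are checked and violations raised as errors.
#'
#' @param path Path to a tab-separated file with the documented header.
#' @return A data.frame with one row per patient.
#' @export
read_clinical_table <- function(path) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                          na.strings = "NA", check.names = FALSE)
  required <- clinical_columns()
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("clinical table missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  if (nrow(df)) validate_clinical(df)
  df
}

clinical_columns <- function() {
  c("patient_id", "sex", "age_at_surgery", "age_of_onset",
    "duration_of_epilepsy", "resection", "side", "mri_finding",
    "delay_baseline_to_surgery_months", "delay_surgery_to_scan1_months",
    "delay_surgery_to_scan2_months", "follow_up_months", "engel_class",
    "postoperative_deficit", "delay_to_recovery_months")
}

validate_clinical <- function(df) {
  bad <- character(0)
  num <- c("age_at_surgery", "age_of_onset", "duration_of_epilepsy",
           "follow_up_months")
  for (cn in num) {
    neg <- which(!is.na(df[[cn]]) & df[[cn]] < 0)
    if (length(neg)) bad <- c(bad, sprintf("row %d: negative %s", neg, cn))
  }
  onset_bad <- which(df$age_of_onset > df$age_at_surgery)
  if (length(onset_bad))
    bad <- c(bad, sprintf("row %d: age_of_onset exceeds age_at_surgery",
                          onset_bad))
  # duration = age_at_surgery - age_of_onset, +/- 1 year for table rounding
  dur_bad <- which(abs(df$duration_of_epilepsy -
                         (df$age_at_surgery - df$age_of_onset)) > 1)
  if (length(dur_bad))
    bad <- c(bad, sprintf("row %d: duration inconsistent with ages", dur_bad))
  sex_bad <- which(!df$sex %in% c("M", "F"))
  if (length(sex_bad)) bad <- c(bad, sprintf("row %d: sex not M/F", sex_bad))
  side_bad <- which(!df$side %in% c("L", "R"))
  if (length(side_bad)) bad <- c(bad, sprintf("row %d: side not L/R", side_bad))
  if (length(bad))
    stop("clinical table validation failed:\n  ",
         paste(bad, collapse = "\n  "), call. = FALSE)
  invisible(df)
}

#' Write a clinical metadata table
#' @param records data.frame as returned by [read_clinical_table()].
#' @param path Output path (tab-separated).
#' @export
write_clinical_table <- function(records, path) {
  utils::write.table(records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' Summarize a clinical cohort
#'
#' Computes the descriptive statistics conventionally reported for a surgical
#' cohort: sample size, sex counts, mean/sd (sample sd, n-1 denominator),
#' minimum and maximum of age at surgery, mean/sd of follow-up duration,
#' counts by side of surgery, Engel class (grouped I vs II by leading Roman
#' numeral) and presence of a postoperative deficit. Reported means and sds
#' are rounded to one decimal, half away from zero; raw values are kept
#' alongside.
#'
#' @param records Clinical data.frame.
#' @return A list of class \code{"cohort_summary"}.
#' @export
summarize_cohort <- function(records) {
  n <- nrow(records)
  one <- function(x) {
    x <- x[!is.na(x)]
    s <- if (length(x) >= 2) stats::sd(x) else NA_real_
    list(mean = mean(x), sd = s,
         mean_1dp = round_half_up(mean(x), 1),
         sd_1dp = if (is.na(s)) NA_real_ else round_half_up(s, 1),
         min = min(x), max = max(x))
  }
  engel_major <- sub("^(I+V?|V).*", "\\1", records$engel_class)
  deficit <- !(is.na(records$postoperative_deficit) |
                 tolower(records$postoperative_deficit) %in% c("none", ""))
  out <- list(
    n = n,
    sex = table(factor(records$sex, levels = c("F", "M"))),
    age = one(records$age_at_surgery),
    follow_up = one(records$follow_up_months),
    side = table(factor(records$side, levels = c("L", "R"))),
    engel = table(factor(engel_major, levels = c("I", "II", "III", "IV"))),
    deficit_n = sum(deficit)
  )
  class(out) <- "cohort_summary"
  out
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf("Cohort of %d patients (%d F / %d M)\n", x$n,
              x$sex[["F"]], x$sex[["M"]]))
  cat(sprintf("  age at surgery: %.1f +/- %.1f years (%g-%g)\n",
              x$age$mean_1dp, x$age$sd_1dp, x$age$min, x$age$max))
  cat(sprintf("  follow-up: %.1f +/- %.1f months\n",
              x$follow_up$mean_1dp, x$follow_up$sd_1dp))
  cat(sprintf("  side of surgery: %d L / %d R\n",
              x$side[["L"]], x$side[["R"]]))
  cat(sprintf("  Engel I: %d, Engel II: %d; postoperative deficit: %d\n",
              x$engel[["I"]], x$engel[["II"]], x$deficit_n))
  invisible(x)
}

#' Write / read a connectivity matrix as TSV
#'
#' Matrices are stored as tab-separated text with label names as both the
#' header row and the first column, at full double precision, so that a
#' write/read round trip is lossless. Reading validates symmetry and
#' non-negativity.
#'
#' @param mat Numeric symmetric matrix with dimnames.
#' @param path File path.
#' @rdname matrix_io
#' @export
write_matrix <- function(mat, path) {
  stopifnot(is.matrix(mat), !is.null(rownames(mat)))
  df <- data.frame(label = rownames(mat),
                   apply(mat, 2, function(col)
                     formatC(col, digits = 17, format = "g")),
                   check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df) <- c("label", colnames(mat))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @param tol Symmetry tolerance for validation on read.
#' @rdname matrix_io
#' @export
read_matrix <- function(path, tol = 1e-8) {
  df <- utils::read.delim(path, sep = "\t", check.names = FALSE,
                          stringsAsFactors = FALSE)
  labs <- df[[1]]
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- labs
  if (!identical(rownames(m), colnames(m)))
    stop("matrix file row/column labels disagree", call. = FALSE)
  if (max(abs(m - t(m))) > tol)
    stop("matrix file is not symmetric", call. = FALSE)
  if (any(m < 0)) stop("matrix file has negative entries", call. = FALSE)
  m
}

#' Write / read a parcellation label table as TSV
#'
#' Columns: \code{id} (integer), \code{name}, \code{side}
#' (left/right/midline), \code{groups} (comma-separated tags, possibly
#' empty).
#'
#' @param labels data.frame with columns id, name, side, groups.
#' @param path File path.
#' @rdname label_table_io
#' @export
write_label_table <- function(labels, path) {
  utils::write.table(labels[, c("id", "name", "side", "groups")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname label_table_io
#' @export
read_label_table <- function(path) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                          colClasses = c(id = "integer", name = "character",
                                         side = "character",
                                         groups = "character"))
  if (anyDuplicated(df$id)) stop("duplicate label ids", call. = FALSE)
  df$groups[is.na(df$groups)] <- ""
  df
}

# ---- minimal NIfTI-1 volume I/O -------------------------------------------
# Single-file uncompressed .nii, identity affine, 1 mm isotropic voxels.
# Only what the synthetic voxel bookkeeping needs; no NIfTI R package is
# assumed. Integer arrays are stored as int32 (datatype 8), doubles as
# float64 (datatype 64).

#' Write a 3D volume as an uncompressed NIfTI-1 file
#'
#' @param vol 3D numeric or integer array.
#' @param path Output path ending in \code{.nii}.
#' @export
write_nifti_volume <- function(vol, path) {
  stopifnot(length(dim(vol)) == 3L)
  is_int <- is.integer(vol) ||
    (is.numeric(vol) && all(vol == round(vol)) && max(abs(vol)) < 2^31)
  datatype <- if (is_int) 8L else 64L
  bitpix <- if (is_int) 32L else 64L
  con <- file(path, "wb")
  on.exit(close(con))
  wint <- function(x, size) writeBin(as.integer(x), con, size = size,
                                     endian = "little")
  wflt <- function(x) writeBin(as.numeric(x), con, size = 4,
                               endian = "little")
  wchr <- function(s, len) {
    r <- raw(len)
    b <- charToRaw(s)
    r[seq_along(b)] <- b
    writeBin(r, con)
  }
  wint(348L, 4)                                    # sizeof_hdr
  wchr("", 10); wchr("", 18)                       # data_type, db_name
  wint(0L, 4); wint(0L, 2)                         # extents, session_error
  writeBin(as.raw(c(114L, 0L)), con)               # regular 'r', dim_info
  wint(c(3L, dim(vol), 1L, 1L, 1L, 1L), 2)         # dim[8]
  wflt(c(0, 0, 0)); wint(0L, 2)                    # intent_p1-3, intent_code
  wint(datatype, 2); wint(bitpix, 2); wint(0L, 2)  # datatype, bitpix, slice_start
  wflt(c(0, 1, 1, 1, 1, 1, 1, 1))                  # pixdim[8]
  wflt(352); wflt(1); wflt(0)                      # vox_offset, scl_slope/inter
  wint(0L, 2); writeBin(as.raw(c(0L, 0L)), con)    # slice_end, slice_code, xyzt
  wflt(c(0, 0, 0, 0))                              # cal_max/min, slice_dur, toffset
  wint(c(0L, 0L), 4)                               # glmax, glmin
  wchr("connremod synthetic volume", 80)           # descrip
  wchr("", 24)                                     # aux_file
  wint(0L, 2); wint(1L, 2)                         # qform_code, sform_code
  wflt(c(0, 0, 0)); wflt(c(0, 0, 0))               # quatern, qoffset
  wflt(c(1, 0, 0, 0)); wflt(c(0, 1, 0, 0)); wflt(c(0, 0, 1, 0))  # srow
  wchr("", 16)
  wchr("n+1", 4)                                   # magic
  writeBin(raw(4), con)                            # no extensions
  if (is_int) writeBin(as.integer(vol), con, size = 4, endian = "little")
  else writeBin(as.numeric(vol), con, size = 8, endian = "little")
  invisible(path)
}

#' Read an uncompressed NIfTI-1 volume
#'
#' Supports datatypes uint8, int16, int32, float32 and float64 and both
#' endiannesses; applies the scl slope/intercept when set.
#'
#' @param path Path to a \code{.nii} file.
#' @return 3D array (integer when the on-disk type is integral and no
#'   scaling applies, double otherwise).
#' @export
read_nifti_volume <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  endian <- "little"
  szh <- readBin(con, "integer", 1, size = 4, endian = endian)
  if (szh != 348L) {
    endian <- "big"
    seek(con, 0)
    szh <- readBin(con, "integer", 1, size = 4, endian = endian)
    if (szh != 348L) stop("not a NIfTI-1 file: ", path, call. = FALSE)
  }
  seek(con, 40)
  dims <- readBin(con, "integer", 8, size = 2, endian = endian)
  nd <- dims[1]
  shape <- dims[2:(1 + max(nd, 3))]
  shape[shape == 0] <- 1L
  shape <- shape[1:3]
  seek(con, 70)
  datatype <- readBin(con, "integer", 1, size = 2, endian = endian)
  seek(con, 108)
  vox_offset <- readBin(con, "numeric", 1, size = 4, endian = endian)
  scl_slope <- readBin(con, "numeric", 1, size = 4, endian = endian)
  scl_inter <- readBin(con, "numeric", 1, size = 4, endian = endian)
  n <- prod(shape)
  seek(con, vox_offset)
  vals <- switch(as.character(datatype),
    "2"  = readBin(con, "integer", n, size = 1, signed = FALSE,
                   endian = endian),
    "4"  = readBin(con, "integer", n, size = 2, endian = endian),
    "8"  = readBin(con, "integer", n, size = 4, endian = endian),
    "16" = readBin(con, "numeric", n, size = 4, endian = endian),
    "64" = readBin(con, "numeric", n, size = 8, endian = endian),
    stop("unsupported NIfTI datatype: ", datatype, call. = FALSE))
  if (!is.na(scl_slope) && scl_slope != 0 &&
      !(scl_slope == 1 && scl_inter == 0))
    vals <- vals * scl_slope + scl_inter
  array(vals, dim = shape)
}

#' Write / read a structured run configuration
#'
#' A single JSON file capturing every tunable of a run: generator settings,
#' seeds, permutation counts, thresholds and null-model parameters.
#' Round-trips preserve all keys.
#'
#' @param config Named list.
#' @param path File path.
#' @rdname config_io
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(config, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' @rdname config_io
#' @export
read_config <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
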