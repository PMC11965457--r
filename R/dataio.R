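#' Analysis-ready ROI dataset
#'
#' Container joining a subjects-by-ROIs measurement matrix for one
#' modality to per-subject covariates. Subject order follows the
#' participants table throughout the pipeline.
#'
#' @param values numeric matrix, subjects in rows (rownames =
#'   \code{subject_id}), ROIs in columns.
#' @param covariates data frame with at least \code{subject_id},
#'   \code{age}, \code{sex}, \code{site}, \code{group}; \code{icv_mm3}
#'   and \code{pclr_total} optional.
#' @param modality one of \code{"thickness"} (mm), \code{"area"} (mm^2),
#'   \code{"volume"} (mm^3).
#' @return object of class \code{roi_dataset}.
#' @export
roi_dataset <- function(values, covariates, modality) {
  modality <- match.arg(modality, c("thickness", "area", "volume"))
  if (!is.matrix(values) || !is.numeric(values))
    stop_field("values", "must be a numeric matrix")
  if (is.null(rownames(values)))
    stop_field("values", "must carry subject_id rownames")
  if (anyDuplicated(rownames(values)))
    stop_field("values", "duplicate subject_id")
  if (anyDuplicated(colnames(values)))
    stop_field("values", "duplicate ROI names")
  need <- c("subject_id", "age", "sex", "site", "group")
  miss <- setdiff(need, names(covariates))
  if (length(miss))
    stop_field("covariates", paste("missing columns:", paste(miss, collapse = ", ")))
  if (!identical(rownames(values), covariates$subject_id))
    stop_field("covariates", "subject_id must match value rownames in order")
  if (anyNA(covariates$age) || anyNA(covariates$site))
    stop_field("covariates", "every subject needs age and site")
  structure(list(modality = modality, values = values,
                 roi_names = colnames(values), covariates = covariates),
            class = "roi_dataset")
}

#' @export
print.roi_dataset <- function(x, ...) {
  cat(sprintf("ROI dataset [%s]: %d subjects x %d ROIs, %d site(s), groups: %s\n",
              x$modality, nrow(x$values), ncol(x$values),
              length(unique(x$covariates$site)),
              paste(names(table(x$covariates$group)), collapse = ", ")))
  invisible(x)
}

# Fixed TSV dialect: tab separator, '.' decimal, UTF-8, header mandatory,
# NA rendered as empty cell.
write_tsv <- function(df, path) {
  ok <- tryCatch({
    utils::write.table(df, path, sep = "\t", quote = FALSE, na = "",
                       row.names = FALSE, fileEncoding = "UTF-8")
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok))
    stop(sprintf("failed to write '%s': %s", path, conditionMessage(ok)),
         call. = FALSE)
  path
}

read_tsv_raw <- function(path) {
  if (!file.exists(path))
    stop(sprintf("file not found: '%s'", path), call. = FALSE)
  utils::read.delim(path, sep = "\t", header = TRUE, colClasses = "character",
                    check.names = FALSE, na.strings = NULL,
                    fileEncoding = "UTF-8")
}

# Strict numeric parsing: a cell that fails to parse raises (with its row
# number), never silently becomes 0 or NA; empty cells become NA.
parse_numeric_col <- function(x, col, path) {
  x[!nzchar(x)] <- NA_character_
  out <- suppressWarnings(as.numeric(x))
  bad <- which(!is.na(x) & is.na(out))
  if (length(bad))
    stop(sprintf("non-numeric value '%s' in column '%s', row %d of '%s'",
                 x[bad[1]], col, bad[1], path), call. = FALSE)
  out
}

#' Read a participants table
#'
#' Reads a BIDS-participants-style TSV with mandatory columns
#' \code{subject_id}, \code{age}, \code{sex}, \code{site}, \code{group}
#' and optional \code{icv_mm3}, \code{pclr_total} (empty when absent).
#'
#' @param path TSV file path.
#' @param group_vocabulary allowed group labels; any label outside it is
#'   an error. \code{NULL} disables the check.
#' @return typed data frame, one row per subject.
#' @export
read_participants <- function(path,
                              group_vocabulary = c("SSD-V", "SSD-NV",
                                                   "nonSSD-V", "HC",
                                                   "REF", "CALIB")) {
  raw <- read_tsv_raw(path)
  need <- c("subject_id", "age", "sex", "site", "group")
  miss <- setdiff(need, names(raw))
  if (length(miss))
    stop(sprintf("participants file '%s' lacks mandatory column(s): %s",
                 path, paste(miss, collapse = ", ")), call. = FALSE)
  out <- data.frame(subject_id = raw$subject_id,
                    age = parse_numeric_col(raw$age, "age", path),
                    sex = raw$sex, site = raw$site, group = raw$group,
                    stringsAsFactors = FALSE)
  out$icv_mm3 <- if ("icv_mm3" %in% names(raw))
    parse_numeric_col(raw$icv_mm3, "icv_mm3", path) else NA_real_
  out$pclr_total <- if ("pclr_total" %in% names(raw))
    parse_numeric_col(raw$pclr_total, "pclr_total", path) else NA_real_
  if (anyDuplicated(out$subject_id))
    stop(sprintf("duplicate subject_id in '%s'", path), call. = FALSE)
  if (anyNA(out$age))
    stop(sprintf("missing age in '%s'", path), call. = FALSE)
  if (any(!nzchar(out$site)))
    stop(sprintf("missing site in '%s'", path), call. = FALSE)
  if (!is.null(group_vocabulary)) {
    unknown <- setdiff(unique(out$group), group_vocabulary)
    if (length(unknown))
      stop(sprintf("group label(s) outside vocabulary in '%s': %s",
                   path, paste(unknown, collapse = ", ")), call. = FALSE)
  }
  out
}

#' Read a wide ROI measurement table
#'
#' Reads a wide TSV (first column \code{subject_id}, remaining columns ROI
#' names) and joins it to an already-loaded participants table. ROI
#' columns are validated against the dictionary for the given modality;
#' unknown columns are dropped with a warning by default. Subjects present
#' in the ROI table but absent from the participants table are an error;
#' participants without ROI data are reported and dropped from the
#' dataset.
#'
#' @param path TSV file path.
#' @param modality \code{"thickness"}, \code{"area"} or \code{"volume"}.
#' @param participants data frame from [read_participants()].
#' @param dictionary ROI dictionary; \code{NULL} skips column validation.
#' @param unknown_roi \code{"drop"} (warn and drop) or \code{"error"}.
#' @return a [roi_dataset()].
#' @export
read_roi_table <- function(path, modality, participants,
                           dictionary = default_roi_dictionary(),
                           unknown_roi = c("drop", "error")) {
  modality <- match.arg(modality, c("thickness", "area", "volume"))
  unknown_roi <- match.arg(unknown_roi)
  raw <- read_tsv_raw(path)
  if (names(raw)[1] != "subject_id")
    stop(sprintf("'%s': first column must be subject_id", path), call. = FALSE)
  roi_cols <- names(raw)[-1]
  if (!is.null(dictionary)) {
    validate_roi_dictionary(dictionary)
    known <- dictionary$roi[dictionary$modality == modality]
    unknown <- setdiff(roi_cols, known)
    if (length(unknown)) {
      if (unknown_roi == "error")
        stop(sprintf("'%s': unknown ROI column(s): %s", path,
                     paste(unknown, collapse = ", ")), call. = FALSE)
      warning(sprintf("'%s': dropping %d unknown ROI column(s): %s", path,
                      length(unknown), paste(unknown, collapse = ", ")),
              call. = FALSE)
      roi_cols <- setdiff(roi_cols, unknown)
    }
  }
  if (!length(roi_cols))
    stop(sprintf("'%s': no ROI columns left after validation", path),
         call. = FALSE)
  vals <- vapply(roi_cols, function(cn) parse_numeric_col(raw[[cn]], cn, path),
                 numeric(nrow(raw)))
  vals <- matrix(vals, nrow = nrow(raw),
                 dimnames = list(raw$subject_id, roi_cols))
  orphan <- setdiff(raw$subject_id, participants$subject_id)
  if (length(orphan))
    stop(sprintf("'%s': subject(s) absent from participants: %s", path,
                 paste(utils::head(orphan, 5), collapse = ", ")),
         call. = FALSE)
  missing_roi <- setdiff(participants$subject_id, raw$subject_id)
  if (length(missing_roi))
    message(sprintf("read_roi_table: %d participant(s) without ROI data dropped (%s)",
                    length(missing_roi),
                    paste(utils::head(missing_roi, 5), collapse = ", ")))
  keep <- participants[participants$subject_id %in% raw$subject_id, ,
                       drop = FALSE]
  vals <- vals[keep$subject_id, , drop = FALSE]
  roi_dataset(vals, keep, modality)
}

#' Write / read a deviation Z-score matrix
#'
#' TSV with first column \code{subject_id} and one column per ROI; column
#' order is preserved. Values are written in full double precision.
#'
#' @param dev a \code{deviation_matrix} (see [compute_zscores()]).
#' @param path output TSV path.
#' @return \code{path}, invisibly.
#' @export
write_deviations <- function(dev, path) {
  stopifnot(inherits(dev, "deviation_matrix"))
  tab <- data.frame(subject_id = rownames(dev$z), dev$z, check.names = FALSE,
                    stringsAsFactors = FALSE)
  old <- options(digits = 17); on.exit(options(old))
  write_tsv(tab, path)
  invisible(path)
}

#' @rdname write_deviations
#' @param modality modality tag to attach on reading.
#' @export
read_deviations <- function(path, modality = "thickness") {
  raw <- read_tsv_raw(path)
  roi_cols <- names(raw)[-1]
  vals <- vapply(roi_cols, function(cn) parse_numeric_col(raw[[cn]], cn, path),
                 numeric(nrow(raw)))
  z <- matrix(vals, nrow = nrow(raw), dimnames = list(raw$subject_id, roi_cols))
  deviation_matrix(z, modality = modality, model_id = basename(path))
}

#' Write a result table
#'
#' Writes any result data frame (group GLM, burden, association, extreme
#' summaries) as TSV with stable column order; an empty table yields a
#' header-only file.
#'
#' @param results data frame.
#' @param path output TSV path.
#' @return \code{path}, invisibly.
#' @export
write_results <- function(results, path) {
  old <- options(digits = 17); on.exit(options(old))
  write_tsv(as.data.frame(results), path)
  invisible(path)
}

#' Convert FreeSurfer-style long stats text to a wide ROI row
#'
#' Convenience converter for aparc/aseg-style per-subject stats text: a
#' whitespace-delimited table with a region-name column and a value
#' column. Returns a one-row wide data frame suitable for binding into a
#' ROI table. Lines starting with '#' are ignored.
#'
#' @param path stats file path.
#' @param subject_id subject identifier for the output row.
#' @param name_col,value_col column indices of region name and value.
#' @return one-row data frame: \code{subject_id} then one column per region.
#' @export
read_stats_long <- function(path, subject_id, name_col = 1L, value_col = 2L) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[!startsWith(trimws(lines), "#") & nzchar(trimws(lines))]
  parts <- strsplit(trimws(lines), "[ \t]+")
  rois <- vapply(parts, `[`, character(1), name_col)
  vals <- parse_numeric_col(vapply(parts, `[`, character(1), value_col),
                            sprintf("col%d", value_col), path)
  out <- as.data.frame(as.list(stats::setNames(vals, rois)),
                       check.names = FALSE)
  cbind(data.frame(subject_id = subject_id, stringsAsFactors = FALSE), out)
}
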