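# ---- beta / M-value matrices -------------------------------------------

#' Construct and validate a beta-value matrix
#'
#' A beta matrix is a plain numeric matrix of methylation fractions
#' (probes in rows, samples in columns) with unique dimnames; values must
#' lie in [0, 1], missing values are allowed (they arise from failed
#' detections and are resolved by the probe filter).
#'
#' @param values numeric matrix with rownames (probe ids) and colnames
#'   (sample ids).
#' @return the validated matrix, classed `beta_matrix`.
#' @export
beta_matrix <- function(values) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  validate_ids(rownames(values), "probe")
  validate_ids(colnames(values), "sample")
  bad <- which(!is.na(values) & (values < 0 | values > 1), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf(
      "beta value out of [0,1] at probe '%s', sample '%s' (value %g)",
      rownames(values)[bad[1, 1]], colnames(values)[bad[1, 2]],
      values[bad[1, , drop = FALSE]]), call. = FALSE)
  }
  structure(values, class = c("beta_matrix", "matrix", "array"))
}

validate_ids <- function(ids, what) {
  if (is.null(ids) || any(is.na(ids)) || any(ids == ""))
    stop(what, " ids missing or empty", call. = FALSE)
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0)
    stop("duplicate ", what, " id(s): ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  invisible(ids)
}

#' Read / write a beta-value matrix as TSV
#'
#' The on-disk format is tab-separated with a header row of sample ids and
#' the probe id in the first column (`probe_id`). Empty cells are missing
#' values. `read_detp_matrix()` reads a detection-p matrix of the same
#' layout (values in [0, 1], no class tag).
#'
#' @param path file path.
#' @param beta a `beta_matrix`.
#' @return `read_beta_matrix()` returns a `beta_matrix`;
#'   `write_beta_matrix()` returns `path` invisibly.
#' @export
read_beta_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, colClasses = NA)
  if (ncol(df) < 2) stop("matrix file needs a probe column and >= 1 sample")
  probes <- as.character(df[[1]])
  samples <- colnames(df)[-1]   # before [.data.frame mangles duplicates
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) stop("non-numeric values in matrix file ", path)
  rownames(m) <- probes
  colnames(m) <- samples
  beta_matrix(m)
}

#' @rdname read_beta_matrix
#' @export
write_beta_matrix <- function(beta, path) {
  df <- data.frame(probe_id = rownames(beta), beta, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname read_beta_matrix
#' @export
read_detp_matrix <- function(path) {
  m <- unclass(read_beta_matrix(path))
  class(m) <- NULL
  m
}

#' Logit-transformed methylation matrix
#'
#' Tags a numeric matrix of M-values (same dimnames discipline as
#' [beta_matrix()]); values are unbounded reals, finite wherever the source
#' beta was strictly inside (0, 1) after clipping.
#'
#' @param values numeric matrix with probe rownames and sample colnames.
#' @return the matrix, classed `m_matrix`.
#' @export
m_matrix <- function(values) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  validate_ids(rownames(values), "probe")
  validate_ids(colnames(values), "sample")
  structure(values, class = c("m_matrix", "matrix", "array"))
}

# ---- sample sheet -------------------------------------------------------

CELL_FRACTION_COLS <- c("cd8t", "cd4t", "nk", "bcell", "mono", "gran")

COHORT_LABEL_RE <- "^(case|control|test|other_disorder:[A-Za-z0-9_.-]+)$"

#' Construct and validate a sample sheet
#'
#' One row per sample: id, cohort label (`case`, `control`, `test`, or
#' `other_disorder:<name>`), sex (`M`/`F`), age in years, batch, and six
#' blood-cell fraction columns (`cd8t`, `cd4t`, `nk`, `bcell`, `mono`,
#' `gran`) that must sum to 1 (renormalised when within 1e-3 of 1).
#'
#' @param df data.frame with the required columns.
#' @return validated data.frame classed `sample_sheet`.
#' @export
sample_sheet <- function(df) {
  need <- c("sample_id", "cohort_label", "sex", "age", "batch",
            CELL_FRACTION_COLS)
  miss <- setdiff(need, names(df))
  if (length(miss) > 0)
    stop("sample sheet missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  df$sample_id <- as.character(df$sample_id)
  validate_ids(df$sample_id, "sample")
  bad <- !grepl(COHORT_LABEL_RE, df$cohort_label)
  if (any(bad))
    stop("unknown cohort label(s): ",
         paste(unique(df$cohort_label[bad]), collapse = ", "), call. = FALSE)
  if (!all(df$sex %in% c("M", "F")))
    stop("sex must be 'M' or 'F'", call. = FALSE)
  if (any(is.na(df$age)) || any(df$age < 0))
    stop("age must be a non-negative number", call. = FALSE)
  df$batch <- as.character(df$batch)
  fr <- as.matrix(df[, CELL_FRACTION_COLS])
  if (any(is.na(fr)) || any(fr < 0))
    stop("cell fractions must be non-negative", call. = FALSE)
  s <- rowSums(fr)
  off <- abs(s - 1) > 1e-3
  if (any(off))
    stop(sprintf("cell fractions of sample '%s' sum to %.4f (must be 1)",
                 df$sample_id[which(off)[1]], s[which(off)[1]]), call. = FALSE)
  df[, CELL_FRACTION_COLS] <- fr / s
  rownames(df) <- NULL
  class(df) <- c("sample_sheet", "data.frame")
  df
}

#' Read / write a sample sheet as TSV
#'
#' @param path file path.
#' @param sheet a `sample_sheet`.
#' @return `read_sample_sheet()` returns a `sample_sheet`;
#'   `write_sample_sheet()` returns `path` invisibly.
#' @export
read_sample_sheet <- function(path) {
  sample_sheet(utils::read.delim(path, check.names = TRUE))
}

#' @rdname read_sample_sheet
#' @export
write_sample_sheet <- function(sheet, path) {
  utils::write.table(sheet, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

# ---- probe manifest -----------------------------------------------------

ALLOWED_CHROMS <- c(paste0("chr", 1:22), "chrX", "chrY")

#' Construct and validate a probe manifest
#'
#' Per probe: id, chromosome (chr1..chr22, chrX, chrY), 1-based position,
#' and flags for SNP-affected and cross-reactive probes.
#'
#' @param df data.frame with columns `probe_id`, `chrom`, `pos`,
#'   `snp_affected`, `cross_reactive`.
#' @return validated data.frame classed `probe_manifest`.
#' @export
probe_manifest <- function(df) {
  need <- c("probe_id", "chrom", "pos", "snp_affected", "cross_reactive")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0)
    stop("manifest missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  df$probe_id <- as.character(df$probe_id)
  validate_ids(df$probe_id, "probe")
  if (!all(df$chrom %in% ALLOWED_CHROMS))
    stop("chromosome outside chr1..chr22/chrX/chrY: ",
         paste(unique(setdiff(df$chrom, ALLOWED_CHROMS)), collapse = ", "),
         call. = FALSE)
  if (any(is.na(df$pos)) || any(df$pos < 1))
    stop("probe positions must be >= 1", call. = FALSE)
  df$snp_affected <- as.logical(df$snp_affected)
  df$cross_reactive <- as.logical(df$cross_reactive)
  rownames(df) <- NULL
  class(df) <- c("probe_manifest", "data.frame")
  df
}

#' Read / write a probe manifest as TSV
#' @param path file path.
#' @param manifest a `probe_manifest`.
#' @return `read_manifest()` returns a `probe_manifest`.
#' @export
read_manifest <- function(path) {
  probe_manifest(utils::read.delim(path))
}

#' @rdname read_manifest
#' @export
write_manifest <- function(manifest, path) {
  utils::write.table(manifest, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

# ---- JSON reports -------------------------------------------------------

#' Write / read a structured result report as JSON
#'
#' Any stage's result (a named list or data.frame) is serialised with a
#' schema version tag and full numeric precision, so a reload compares
#' equal to the original.
#'
#' @param report a named list or data.frame.
#' @param path output file path.
#' @return `write_report()` returns `path` invisibly; `read_report()`
#'   returns the payload (the `schema_version` field stripped).
#' @export
write_report <- function(report, path) {
  bad <- rapply(list(report), function(x)
    is.function(x) || is.environment(x) || typeof(x) == "externalptr",
    how = "unlist")
  if (any(bad))
    stop("report not serialisable to JSON: contains function/environment",
         call. = FALSE)
  payload <- list(schema_version = 1L, payload = report)
  ok <- tryCatch({
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                         na = "null", null = "null")
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok))
    stop("report not serialisable to JSON: ", conditionMessage(ok),
         call. = FALSE)
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  doc$payload
}
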