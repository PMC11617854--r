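# Variant cohort table: HGVS-style variant classification, cohort
# summaries, and phenotype frequency comparison between signature-positive
# and -negative cases.

VARIANT_LABELS <- c("NEDAUS", "NEDAUS_VUS_positive", "NEDAUS_VUS",
                    "NEDAUS_negative")

# Cohort-table labels -> pipeline sample-sheet vocabulary: the discovery
# cases are `case`, everything else is scored as `test`.
LABEL_TO_SHEET <- c(NEDAUS = "case", NEDAUS_VUS_positive = "test",
                    NEDAUS_VUS = "test", NEDAUS_negative = "test")

#' Classify a variant description string
#'
#' Tolerant classifier for the cDNA+protein HGVS (or array-CNV) strings of
#' a clinical cohort table. Precedence: (1) an `arr[...](start_end)x1`
#' descriptor is a `deletion`; (2) a protein change containing `fs` is a
#' `frameshift` (so `fs*NN` descriptions are frameshifts, not nonsense);
#' (3) a substitution to a stop (`*`, either ASCII or U+2217) without `fs`
#' is `nonsense`; (4) `p.?` with an intronic cDNA offset within 3 bp of a
#' splice boundary (e.g. `c.540-2A>G`) is `splice_site`; (5) a single
#' amino-acid substitution is `missense`. Minor typographic noise
#' (duplicated change tokens, a missing or capitalised `c.` prefix) is
#' accepted.
#'
#' @param variant_string non-empty description string (vectorised).
#' @return character vector with values in `nonsense`, `missense`,
#'   `frameshift`, `splice_site`, `deletion`.
#' @export
parse_variant <- function(variant_string) {
  vapply(variant_string, function(s) {
    if (is.na(s) || !nzchar(trimws(s)))
      stop("empty variant string", call. = FALSE)
    x <- gsub("∗", "*", trimws(s))
    if (grepl("^arr\\[.*\\(\\d+_\\d+\\)x1", x)) return("deletion")
    prot <- if (grepl("p\\.", x)) sub(".*p\\.\\(?([^)]*)\\)?.*", "\\1", x)
      else ""
    if (grepl("fs", prot)) return("frameshift")
    if (grepl("\\*", prot)) return("nonsense")
    if (grepl("^\\?", prot)) {
      off <- regmatches(x, regexpr("\\d+[+-]\\d+", x))
      if (length(off) == 1 &&
          abs(as.integer(sub(".*([+-]\\d+)$", "\\1", off))) <= 3)
        return("splice_site")
      stop("unclassifiable variant string: ", s, call. = FALSE)
    }
    if (grepl("^[A-Za-z]{3}\\d+[A-Za-z]{3}$", prot)) return("missense")
    stop("unclassifiable variant string: ", s, call. = FALSE)
  }, character(1), USE.NAMES = FALSE)
}

#' Read a cohort variant table
#'
#' TSV with columns `case`, `label`, `gender`, `variant`, `variant_type`,
#' `classification`, `inheritance`. Every variant string is re-classified
#' with [parse_variant()] and checked against the table's `variant_type`
#' column (stated types use a space, e.g. `splice site`).
#'
#' @param path TSV path; default is the bundled cohort table.
#' @return data.frame classed `variant_table`.
#' @export
read_variant_table <- function(path = system.file(
  "extdata", "cul3_variant_table.tsv", package = "episig")) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          na.strings = character(0))
  need <- c("case", "label", "gender", "variant", "variant_type",
            "classification", "inheritance")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0)
    stop("variant table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (!all(df$label %in% VARIANT_LABELS))
    stop("unknown label(s): ",
         paste(setdiff(df$label, VARIANT_LABELS), collapse = ", "),
         call. = FALSE)
  validate_ids(as.character(df$case), "case")
  parsed <- parse_variant(df$variant)
  stated <- gsub(" ", "_", df$variant_type)
  if (!all(parsed == stated))
    stop("variant_type mismatch for case(s): ",
         paste(df$case[parsed != stated], collapse = ", "), call. = FALSE)
  df$variant_type <- parsed
  class(df) <- c("variant_table", "data.frame")
  df
}

#' Summarise a variant cohort
#'
#' Tallies variant types, sex, inheritance and labels, and derives the two
#' study splits: discovery (label `NEDAUS`) vs validation/assessment
#' (everything else), and episignature status (`NEDAUS` +
#' `NEDAUS_VUS_positive` positive; `NEDAUS_VUS` + `NEDAUS_negative`
#' negative).
#'
#' @param records a `variant_table` (possibly empty).
#' @return list of named count vectors and split sizes.
#' @export
summarize_cohort <- function(records) {
  tab <- function(x, levels) {
    t <- table(factor(x, levels = levels))
    stats::setNames(as.integer(t), names(t))
  }
  list(
    n = nrow(records),
    variant_type = tab(records$variant_type,
                       c("nonsense", "missense", "frameshift",
                         "splice_site", "deletion")),
    gender = tab(records$gender, c("M", "F")),
    inheritance = tab(records$inheritance,
                      c("de novo", "paternal", "maternal", "NA")),
    label = tab(records$label, VARIANT_LABELS),
    discovery_n = sum(records$label == "NEDAUS"),
    validation_n = sum(records$label != "NEDAUS"),
    signature_positive_n = sum(records$label %in%
                                 c("NEDAUS", "NEDAUS_VUS_positive")),
    signature_negative_n = sum(records$label %in%
                                 c("NEDAUS_VUS", "NEDAUS_negative"))
  )
}

#' Sample-sheet skeleton from a variant table
#'
#' Maps cohort-table labels to the pipeline vocabulary (`NEDAUS` ->
#' `case`, all others -> `test`) and fills the covariates the printed
#' table does not carry (age, batch, cell fractions) with neutral
#' placeholder values, so the table can drive sheet-level operations.
#'
#' @param records a `variant_table`.
#' @return a `sample_sheet` with one row per case.
#' @export
sheet_from_variants <- function(records) {
  df <- data.frame(
    sample_id = paste0("p", records$case),
    cohort_label = unname(LABEL_TO_SHEET[records$label]),
    sex = records$gender,
    age = 10,
    batch = "b1",
    stringsAsFactors = FALSE)
  df[CELL_FRACTION_COLS] <- rep(1 / 6, 6)
  sample_sheet(df)
}

#' Compare phenotype frequencies between signature groups
#'
#' Input: one row per case with a `signature_status` column
#' (`positive`/`negative`) and binary feature columns coded 1 (present),
#' 0 (absent), NA (unknown). Frequencies are percentages of known values;
#' a feature unknown for an entire group is reported as missing. Features
#' are ranked by absolute frequency difference.
#'
#' @param table data.frame as described.
#' @return data.frame `feature`, `freq_positive`, `freq_negative`,
#'   `n_known_positive`, `n_known_negative`, `difference`.
#' @export
phenotype_compare <- function(table) {
  stopifnot("signature_status" %in% names(table),
            all(table$signature_status %in% c("positive", "negative")))
  feats <- setdiff(names(table), c("sample_id", "case", "signature_status"))
  if (sum(table$signature_status == "positive") < 1 ||
      sum(table$signature_status == "negative") < 1)
    stop("need >= 1 case per signature group", call. = FALSE)
  one <- function(f, grp) {
    x <- table[[f]][table$signature_status == grp]
    known <- sum(!is.na(x))
    c(freq = if (known > 0) 100 * sum(x, na.rm = TRUE) / known else
      NA_real_, n = known)
  }
  res <- do.call(rbind, lapply(feats, function(f) {
    p <- one(f, "positive"); n <- one(f, "negative")
    data.frame(feature = f, freq_positive = p["freq"],
               freq_negative = n["freq"], n_known_positive = p["n"],
               n_known_negative = n["n"],
               difference = p["freq"] - n["freq"],
               stringsAsFactors = FALSE)
  }))
  rownames(res) <- NULL
  res[order(-abs(res$difference)), , drop = FALSE]
}
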