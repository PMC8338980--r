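# Cohort table I/O, validation, quartile coding and summaries -----------

phq_cols <- function() paste0("PHQ_", 1:9)
gad_cols <- function() paste0("GAD_", 1:7)
total_cols <- function() c("STAI_T", "RAS_T", "RSES_T")
binary_cols <- function() c("lifetime_SA", "gender_female",
                            "institution_hospital")

#' Default cohort schema
#'
#' A named character vector mapping canonical column names to the column
#' names found in a file; identity by default.  Pass a modified copy to
#' [read_cohort()] when a file uses different headers.
#'
#' @return named character vector.
#' @export
cohort_schema <- function() {
  cols <- c("subject_id", phq_cols(), gad_cols(), total_cols(),
            binary_cols(), "MaDE_label", "acute_SI", "KSSI_total")
  stats::setNames(cols, cols)
}

validate_cohort <- function(df, file = "<table>") {
  need <- setdiff(names(cohort_schema()), c("MaDE_label", "KSSI_total"))
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop_ginscreen("missing columns: ", paste(miss, collapse = ", "),
                   class = "ginscreen_schema_error")
  check_range <- function(cols, ok_fun, what) {
    for (cl in cols) {
      v <- df[[cl]]
      bad <- which(is.na(v) | !ok_fun(v))
      if (length(bad))
        stop_ginscreen(file, ": ", what, " violation in column ", cl,
                       ", row(s) ", paste(head(bad, 5), collapse = ", "),
                       class = "ginscreen_schema_error")
    }
  }
  check_range(c(phq_cols(), gad_cols()),
              function(v) v %in% 1:4, "ordinal level (1-4)")
  check_range(total_cols(), function(v) is.finite(v), "numeric total")
  check_range(c(binary_cols(), "acute_SI"),
              function(v) v %in% 0:1, "binary (0/1)")
  if ("MaDE_label" %in% names(df)) {
    v <- df$MaDE_label
    bad <- which(!is.na(v) & !v %in% 0:1)
    if (length(bad))
      stop_ginscreen(file, ": binary (0/1) violation in column MaDE_label, ",
                     "row(s) ", paste(head(bad, 5), collapse = ", "),
                     class = "ginscreen_schema_error")
  }
  if ("KSSI_total" %in% names(df)) {
    v <- df$KSSI_total
    bad <- which(!is.na(v) & v < 0)
    if (length(bad))
      stop_ginscreen(file, ": KSSI_total must be >= 0, row(s) ",
                     paste(head(bad, 5), collapse = ", "),
                     class = "ginscreen_schema_error")
  }
  invisible(df)
}

#' Read and validate a cohort table
#'
#' Reads a CSV or TSV cohort file (delimiter sniffed from the header line
#' unless `delim` is given), renames columns through `schema`, optionally
#' recodes raw 0-3 item responses to the 1-4 level scale, and validates
#' every schema invariant.  Missing values are allowed only in
#' `MaDE_label` and `KSSI_total`; any other missing or out-of-range cell
#' raises a schema error naming the row and column.
#'
#' @param path file path.
#' @param schema a [cohort_schema()] mapping.
#' @param recode_items if `TRUE`, PHQ/GAD items are read as 0-3 and
#'   shifted to 1-4.
#' @param delim `","`, `"\t"`, or `NULL` to sniff.
#' @return validated cohort data frame.
#' @export
read_cohort <- function(path, schema = cohort_schema(), recode_items = FALSE,
                        delim = NULL) {
  if (!file.exists(path))
    stop_ginscreen("file not found: ", path, class = "ginscreen_schema_error")
  if (is.null(delim)) {
    header <- readLines(path, n = 1L)
    delim <- if (grepl("\t", header)) "\t" else ","
  }
  df <- read.csv(path, sep = delim, stringsAsFactors = FALSE,
                 check.names = FALSE)
  required <- schema[!names(schema) %in% c("MaDE_label", "KSSI_total")]
  absent <- setdiff(unname(required), names(df))
  if (length(absent))
    stop_ginscreen(path, ": columns not found: ",
                   paste(absent, collapse = ", "),
                   class = "ginscreen_schema_error")
  extra <- setdiff(names(df), c(unname(schema), "lifetime_SI"))
  if (length(extra))
    stop_ginscreen(path, ": unknown columns: ", paste(extra, collapse = ", "),
                   class = "ginscreen_schema_error")
  present <- schema[schema %in% names(df)]
  keep <- c(present, if ("lifetime_SI" %in% names(df)) c(lifetime_SI = "lifetime_SI"))
  df <- df[, keep, drop = FALSE]
  names(df) <- names(keep)
  if (recode_items) {
    for (cl in c(phq_cols(), gad_cols())) df[[cl]] <- df[[cl]] + 1L
  }
  validate_cohort(df, file = path)
}

#' Write a cohort table as CSV
#'
#' @param df validated cohort data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(df, path) {
  validate_cohort(df)
  write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Fit a quartile coder for scale totals
#'
#' Learns the 25/50/75 empirical percentiles (linear interpolation between
#' order statistics) of each named column on a reference split, to map raw
#' totals to levels 1-4.  Reversed columns (protective scales whose high
#' raw scores should code as level 1) map the top raw quartile to level 1.
#' Ties at a cut point map to the lower level.  Fit the coder on the
#' training split only and apply it unchanged elsewhere, so no
#' distributional information leaks out of the training data.
#'
#' @param table cohort data frame (reference split).
#' @param columns character vector of total-score columns.
#' @param reverse logical vector (recycled) of reversal flags.
#' @return an object of class `quartile_coder`.
#' @export
fit_quartile_coder <- function(table, columns = total_cols(),
                               reverse = c(FALSE, TRUE, TRUE)) {
  stopifnot(nrow(table) >= 4)
  reverse <- rep_len(reverse, length(columns))
  cuts <- lapply(columns, function(cl) {
    v <- table[[cl]]
    if (is.null(v)) stop_ginscreen("column not found: ", cl,
                                   class = "ginscreen_schema_error")
    if (length(unique(v)) == 1L)
      stop_ginscreen("column ", cl, " is constant; quartile coder degenerate",
                     class = "ginscreen_degenerate_coder")
    unname(quantile(v, c(.25, .5, .75), type = 7))
  })
  names(cuts) <- columns
  structure(list(cuts = cuts, reverse = stats::setNames(reverse, columns)),
            class = "quartile_coder")
}

#' Apply a quartile coder
#'
#' Adds a `<column>_q` level column (1-4) for each coded total.  Values
#' beyond the reference range clamp to the extreme levels.
#'
#' @param coder a `quartile_coder`.
#' @param table cohort data frame.
#' @return `table` with the added `_q` columns.
#' @export
apply_quartile_coder <- function(coder, table) {
  stopifnot(inherits(coder, "quartile_coder"))
  for (cl in names(coder$cuts)) {
    cp <- coder$cuts[[cl]]
    lv <- 1L + (table[[cl]] > cp[1]) + (table[[cl]] > cp[2]) +
      (table[[cl]] > cp[3])
    if (coder$reverse[[cl]]) lv <- 5L - lv
    table[[paste0(cl, "_q")]] <- as.integer(lv)
  }
  table
}

#' Summarize outcome prevalences in a cohort
#'
#' Counts and percentages for acute suicidal ideation, lifetime suicide
#' attempt, MaDE-labeled positives, and (when a `lifetime_SI` column is
#' present) lifetime suicidal ideation.  Counts are exact integers;
#' displayed percentages are 100*count/n reported to two decimals.
#'
#' @param table cohort data frame.
#' @return object of class `cohort_summary`: a data frame with columns
#'   `outcome`, `count`, `n`, `pct`.
#' @export
summarize_cohort <- function(table) {
  stopifnot(nrow(table) > 0)
  n <- nrow(table)
  rows <- list(
    c("acute_SI", sum(table$acute_SI == 1)),
    c("lifetime_SA", sum(table$lifetime_SA == 1)),
    c("MaDE_labeled_positive", sum(table$MaDE_label == 1, na.rm = TRUE))
  )
  if ("lifetime_SI" %in% names(table))
    rows <- c(list(c("lifetime_SI", sum(table$lifetime_SI == 1))), rows)
  out <- data.frame(
    outcome = vapply(rows, `[`, "", 1),
    count = as.integer(vapply(rows, `[`, "", 2)),
    n = n, stringsAsFactors = FALSE
  )
  out$pct <- format_pct(out$count, n)
  class(out) <- c("cohort_summary", "data.frame")
  out
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat("Cohort summary (n = ", x$n[1], ")\n", sep = "")
  for (i in seq_len(nrow(x)))
    cat(sprintf("  %-22s %6d (%.2f%%)\n", x$outcome[i], x$count[i], x$pct[i]))
  invisible(x)
}
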