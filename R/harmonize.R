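#' Declare the complex-survey design bindings of an analysis table
#'
#' Binds the column names holding the sample weight, design stratum and primary
#' sampling unit (PSU), plus the number of 2-year cycles combined into the
#' weights. All weighted estimation in the package reads these bindings.
#'
#' @param weight,strata,psu column names.
#' @param cycles number of survey cycles combined (>= 1).
#' @return an object of class `survey_design`.
#' @export
survey_design <- function(weight = "weight", strata = "stratum", psu = "psu",
                          cycles = 1L) {
  stopifnot(is.character(weight), is.character(strata), is.character(psu))
  cycles <- as.integer(cycles)
  if (is.na(cycles) || cycles < 1L) stop("cycles must be a positive integer")
  structure(list(weight = weight, strata = strata, psu = psu, cycles = cycles),
            class = "survey_design")
}

#' @export
print.survey_design <- function(x, ...) {
  cat("Survey design: weight = '", x$weight, "', strata = '", x$strata,
      "', psu = '", x$psu, "', cycles combined = ", x$cycles, "\n", sep = "")
  invisible(x)
}

#' Bundle harmonized respondent data with its design and provenance
#'
#' @param data data frame, one row per respondent. Must contain the design
#'   columns with strictly positive weights.
#' @param design a [survey_design].
#' @param provenance list of prior provenance entries (internal use).
#' @return an object of class `analysis_table`.
#' @export
analysis_table <- function(data, design = survey_design(), provenance = list()) {
  stopifnot(is.data.frame(data))
  for (col in c(design$weight, design$strata, design$psu))
    if (!col %in% names(data))
      stop("design column '", col, "' not present in data")
  w <- data[[design$weight]]
  if (any(is.na(w)) || any(w <= 0))
    stop("all sample weights must be strictly positive")
  tab <- structure(list(data = data, design = design, provenance = provenance),
                   class = "analysis_table")
  if (!length(provenance))
    tab <- log_step(tab, "create", nrow(data))
  tab
}

log_step <- function(tab, op, rows, note = NULL) {
  prev <- tab$provenance
  if (length(prev)) {
    last <- prev[[length(prev)]]$rows
    if (rows > last)
      stop("provenance violation: '", op, "' increased row count (", last,
           " -> ", rows, ")")
  }
  entry <- list(op = op, rows = rows)
  if (!is.null(note)) entry$note <- note
  tab$provenance <- c(prev, list(entry))
  tab
}

#' @export
print.analysis_table <- function(x, ...) {
  cat("Analysis table: ", nrow(x$data), " respondents, ",
      length(unique(x$data[[x$design$strata]])), " strata\n", sep = "")
  print(x$design)
  cat("Provenance:\n")
  for (e in x$provenance)
    cat("  ", e$op, ": ", e$rows, " rows",
        if (!is.null(e$note)) paste0(" (", e$note, ")"), "\n", sep = "")
  invisible(x)
}

#' @export
dim.analysis_table <- function(x) dim(x$data)

#' @export
as.data.frame.analysis_table <- function(x, ...) x$data

#' Provenance log of an analysis table
#'
#' @param tab an [analysis_table].
#' @return list of steps, each with the operation name and resulting row count.
#' @export
provenance <- function(tab) tab$provenance

#' Read a respondent-level survey table
#'
#' Reads a delimited text (RFC-4180 CSV, UTF-8) or SAS transport v5 (XPT) file
#' and applies the supplied codebooks: declared missing codes become `NA`,
#' value codes are decoded to labels, and any code outside a codebook's domain
#' is an error naming the variable, row and code. Column names are lower-cased
#' (XPT files conventionally store upper-case names).
#'
#' @param path file path.
#' @param format `"csv"` or `"xpt"`; default guessed from the extension.
#' @param codebooks named list of [codebook] objects keyed by variable name;
#'   only variables present in the file are decoded.
#' @return a data frame of typed rows.
#' @export
read_survey_table <- function(path, format = c("guess", "csv", "xpt"),
                              codebooks = list()) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "guess")
    format <- if (grepl("\\.xpt$", path, ignore.case = TRUE)) "xpt" else "csv"
  df <- switch(format,
    csv = utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8"),
    xpt = foreign::read.xport(path))
  if (format == "xpt") {
    # transport names are truncated to 8 characters; the variable labels
    # carry the full names, so restore them when they are usable
    info <- foreign::lookup.xport(path)[[1L]]
    lab <- info$label
    if (!is.null(lab) && all(nzchar(lab)) && !anyDuplicated(lab))
      names(df) <- lab[match(toupper(names(df)), info$name)]
  }
  names(df) <- tolower(names(df))
  for (v in names(codebooks)) {
    if (!v %in% names(df)) next
    df[[v]] <- decode_values(df[[v]], codebooks[[v]])
  }
  df
}

#' Combine survey cycles into one table with adjusted weights
#'
#' Concatenates per-cycle tables sharing a schema and divides every weight by
#' the number of combined 2-year cycles, the standard analytic rule that makes
#' the combined weighted total estimate the (average) population size rather
#' than its multiple.
#'
#' @param tables list of data frames, one per cycle, sharing column names.
#' @param design a [survey_design] describing the weight column; its `cycles`
#'   field is updated to the number of tables.
#' @param id column holding the respondent identifier (checked for cross-cycle
#'   duplicates).
#' @return list with `data` (the combined data frame) and `design` (updated).
#' @export
combine_cycles <- function(tables, design = survey_design(), id = "id") {
  stopifnot(is.list(tables), length(tables) >= 1L)
  nm <- names(tables[[1L]])
  for (t in tables[-1L])
    if (!identical(sort(names(t)), sort(nm)))
      stop("all cycle tables must share the same schema")
  if ("cycle" %in% nm) {
    labs <- vapply(tables, function(t) as.character(t$cycle[1L]), "")
    if (anyDuplicated(labs)) stop("cycle labels must be distinct")
  }
  combined <- do.call(rbind, lapply(tables, function(t) t[, nm, drop = FALSE]))
  if (id %in% nm && anyDuplicated(combined[[id]]))
    stop("duplicate respondent id(s) across cycles: ",
         paste(utils::head(unique(combined[[id]][duplicated(combined[[id]])]), 5L),
               collapse = ", "))
  k <- length(tables)
  combined[[design$weight]] <- combined[[design$weight]] / k
  design$cycles <- as.integer(k)
  list(data = combined, design = design)
}

#' Derive a mutually exclusive insurance class from per-plan coverage flags
#'
#' Survey insurance coverage arrives as one indicator per plan type. The
#' derived class is assigned by a priority order (default: private, then
#' Medicare, then Medicaid, then other non-private) so that multiply-insured
#' respondents get a single class. `"uninsured"` requires every flag to be
#' explicitly `FALSE`: a respondent is only known to lack coverage when all
#' plan variables say "not covered". If no flag is `TRUE` and any is missing,
#' the class is missing (`NA`).
#'
#' @param flags data frame (or named list of equal-length logical vectors)
#'   with columns `private`, `medicare`, `medicaid`, `other`; `NA` allowed.
#' @param priority character vector ordering the classes checked for a `TRUE`
#'   flag first.
#' @return factor with levels `private`, `Medicare`, `Medicaid`,
#'   `other non-private`, `uninsured`; `NA` where coverage is indeterminate.
#' @examples
#' derive_insurance(data.frame(private = c(TRUE, FALSE, FALSE),
#'                             medicare = c(TRUE, FALSE, NA),
#'                             medicaid = c(FALSE, FALSE, FALSE),
#'                             other    = c(FALSE, FALSE, FALSE)))
#' @export
derive_insurance <- function(flags,
                             priority = c("private", "medicare", "medicaid", "other")) {
  flags <- as.data.frame(flags)
  need <- c("private", "medicare", "medicaid", "other")
  if (!all(need %in% names(flags)))
    stop("flags must contain columns: ", paste(need, collapse = ", "))
  stopifnot(all(sort(priority) == sort(need)))
  label_of <- c(private = "private", medicare = "Medicare",
                medicaid = "Medicaid", other = "other non-private")
  n <- nrow(flags)
  out <- rep(NA_character_, n)
  for (p in rev(priority)) {
    hit <- !is.na(flags[[p]]) & flags[[p]]
    out[hit] <- label_of[[p]]
  }
  undecided <- is.na(out)
  all_false <- undecided &
    Reduce(`&`, lapply(need, function(p) !is.na(flags[[p]]) & !flags[[p]]))
  out[all_false] <- "uninsured"
  factor(out, levels = c("private", "Medicare", "Medicaid",
                         "other non-private", "uninsured"))
}

#' Categorize the poverty income ratio (PIR)
#'
#' Family income divided by the poverty threshold, cut into the four analysis
#' categories: poor (< 1), near poor (1-1.9), middle income (2-3.9) and higher
#' income (>= 4). Printed ranges are half-open `[lower, next lower)` so the
#' categories partition the non-negative line.
#'
#' @param pir numeric vector, `>= 0`; `NA` passes through.
#' @return ordered factor with the four income levels.
#' @export
categorize_pir <- function(pir) {
  if (is.factor(pir)) return(pir)  # idempotent on already-categorized input
  if (any(!is.na(pir) & pir < 0)) stop("pir must be non-negative")
  cut(pir, breaks = c(0, 1, 2, 4, Inf), right = FALSE, ordered_result = TRUE,
      labels = c("poor", "near poor", "middle income", "higher income"))
}

#' Harmonize fine-grained education codes onto the five analysis levels
#'
#' Decodes stored education codes through the codebook and then maps each
#' fine label through the codebook's group map onto the coarser analysis
#' levels (less than 9th grade; 9-11th grade, which includes 12th grade with
#' no diploma; high school graduate; some college or AA degree; college
#' graduate or above). With an identity (absent) group map the decoded labels
#' are returned unchanged.
#'
#' @param x vector of stored codes, or of labels already in the codebook's
#'   label set (making the operation idempotent).
#' @param cb a [codebook] for the education variable.
#' @return character vector of harmonized labels.
#' @export
harmonize_education <- function(x, cb) {
  stopifnot(inherits(cb, "codebook"))
  chr <- as.character(x)
  already <- !is.na(chr) & chr %in% unname(cb$codes)
  lab <- rep(NA_character_, length(x))
  lab[already] <- chr[already]
  if (any(!already)) lab[!already] <- decode_values(x[!already], cb)
  if (is.null(cb$groups)) return(lab)
  grouped <- !is.na(lab) & lab %in% names(cb$groups)
  # labels already at the group level pass through (idempotence)
  at_group <- !is.na(lab) & !grouped & lab %in% unname(cb$groups)
  missing_map <- !is.na(lab) & !grouped & !at_group
  if (any(missing_map))
    stop("education label(s) without a group mapping: ",
         paste(unique(lab[missing_map]), collapse = ", "))
  lab[grouped] <- unname(cb$groups[lab[grouped]])
  lab
}

#' Restrict an analysis table to a study cohort
#'
#' Applies the inclusion rules of the three study cohorts: `hav_hbv` keeps
#' adults (age over 20) who are not pregnant; `hpv` keeps non-pregnant adults
#' aged 20 to 59; `t2dm` keeps non-pregnant adults over 20 with diagnosed
#' type 2 diabetes (column `diabetes`). Survey age is recorded in completed
#' years, so "over age 20" is implemented as `age >= 20` by default;
#' `strict_age = TRUE` switches to `age > 20`. A missing pregnancy flag is
#' treated as not pregnant (the question is only asked where applicable).
#'
#' @param tab an [analysis_table] with columns `age`, `pregnancy` and (for
#'   `t2dm`) `diabetes`.
#' @param cohort one of `"hav_hbv"`, `"hpv"`, `"t2dm"`.
#' @param strict_age logical; see above.
#' @return the filtered [analysis_table] with a provenance entry appended.
#' @export
filter_cohort <- function(tab, cohort = c("hav_hbv", "hpv", "t2dm"),
                          strict_age = FALSE) {
  stopifnot(inherits(tab, "analysis_table"))
  cohort <- match.arg(cohort)
  d <- tab$data
  age_ok <- if (strict_age) d$age > 20 else d$age >= 20
  not_preg <- is.na(d$pregnancy) | !d$pregnancy
  keep <- switch(cohort,
    hav_hbv = age_ok & not_preg,
    hpv     = age_ok & d$age <= 59 & not_preg,
    t2dm    = age_ok & not_preg & !is.na(d$diabetes) & d$diabetes)
  keep[is.na(keep)] <- FALSE
  tab$data <- d[keep, , drop = FALSE]
  log_step(tab, paste0("filter_cohort[", cohort, "]"), sum(keep))
}

#' Drop rows with missing values in required analysis columns
#'
#' Complete-case restriction on the listed columns, recording the number of
#' rows dropped in the provenance log.
#'
#' @param tab an [analysis_table].
#' @param required character vector of column names that must be non-missing.
#' @return the filtered [analysis_table].
#' @export
drop_missing <- function(tab, required) {
  stopifnot(inherits(tab, "analysis_table"))
  miss <- setdiff(required, names(tab$data))
  if (length(miss)) stop("column(s) not present: ", paste(miss, collapse = ", "))
  keep <- stats::complete.cases(tab$data[, required, drop = FALSE])
  dropped <- sum(!keep)
  tab$data <- tab$data[keep, , drop = FALSE]
  log_step(tab, "drop_missing", sum(keep), note = paste0(dropped, " dropped"))
}

#' Write a harmonized analysis table and its provenance log
#'
#' @param tab an [analysis_table].
#' @param data_path CSV destination for the data.
#' @param provenance_path optional JSON destination for the provenance log.
#' @return `data_path`, invisibly.
#' @export
write_analysis_table <- function(tab, data_path, provenance_path = NULL) {
  stopifnot(inherits(tab, "analysis_table"))
  utils::write.csv(tab$data, data_path, row.names = FALSE)
  if (!is.null(provenance_path))
    jsonlite::write_json(tab$provenance, provenance_path, auto_unbox = TRUE)
  invisible(data_path)
}
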