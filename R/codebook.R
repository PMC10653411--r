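#' Construct a variable codebook
#'
#' A codebook declares, for one survey variable, the mapping from stored codes
#' to analysis labels, which codes denote a missing response (refused, don't
#' know, not asked), and an optional grouping of fine labels onto the coarser
#' labels used in analysis (e.g. collapsing detailed education levels onto the
#' five analysis levels).
#'
#' @param variable variable name the codebook applies to.
#' @param codes named character vector or list: names are codes (as stored,
#'   coerced to character), values are labels. Each code maps to exactly one
#'   label.
#' @param missing character vector of codes to be read back as `NA`. Must be
#'   disjoint from the value codes.
#' @param groups optional named character vector mapping labels onto coarser
#'   group labels; must be a function of label (no duplicated names).
#' @return an object of class `codebook`.
#' @examples
#' cb <- codebook("pregnancy", c(`1` = "yes", `2` = "no"), missing = "9")
#' decode_values(c(1, 2, 9), cb)
#' @export
codebook <- function(variable, codes, missing = character(), groups = NULL) {
  stopifnot(is.character(variable), length(variable) == 1L)
  codes <- unlist(codes)
  code_keys <- as.character(names(codes))
  if (anyDuplicated(code_keys))
    stop("codebook for '", variable, "': duplicated code(s): ",
         paste(unique(code_keys[duplicated(code_keys)]), collapse = ", "))
  missing <- as.character(missing)
  clash <- intersect(code_keys, missing)
  if (length(clash))
    stop("codebook for '", variable, "': code(s) declared both value and missing: ",
         paste(clash, collapse = ", "))
  if (!is.null(groups)) {
    groups <- unlist(groups)
    if (anyDuplicated(names(groups)))
      stop("codebook for '", variable, "': group map assigns a label to two groups")
  }
  structure(list(variable = variable,
                 codes = stats::setNames(as.character(codes), code_keys),
                 missing = missing,
                 groups = groups),
            class = "codebook")
}

#' @export
print.codebook <- function(x, ...) {
  cat("Codebook for '", x$variable, "': ", length(x$codes), " codes, ",
      length(x$missing), " missing code(s)",
      if (!is.null(x$groups)) paste0(", ", length(x$groups), " group mappings"),
      "\n", sep = "")
  invisible(x)
}

#' Decode a vector of stored codes through a codebook
#'
#' Missing codes become `NA`; any code outside the codebook's domain is a
#' validation error naming the variable, the offending rows and the code.
#'
#' @param x vector of stored codes (numeric or character).
#' @param cb a [codebook].
#' @return character vector of labels with `NA` for declared-missing codes.
#' @export
decode_values <- function(x, cb) {
  stopifnot(inherits(cb, "codebook"))
  key <- trimws(as.character(x))
  key[is.na(x)] <- NA_character_
  out <- rep(NA_character_, length(x))
  is_missing_code <- !is.na(key) & key %in% cb$missing
  known <- !is.na(key) & key %in% names(cb$codes)
  bad <- !is.na(key) & !known & !is_missing_code
  if (any(bad)) {
    rows <- which(bad)
    stop("variable '", cb$variable, "': unknown code(s) ",
         paste(unique(key[bad]), collapse = ", "),
         " at row(s) ", paste(utils::head(rows, 5L), collapse = ", "),
         if (length(rows) > 5L) " ..." else "")
  }
  out[known] <- unname(cb$codes[key[known]])
  out
}

#' Read codebooks from a YAML file
#'
#' The YAML holds one entry per variable with keys `variable`, `codes`,
#' `missing` (optional) and `groups` (optional), mirroring [codebook()].
#'
#' @param path path to a YAML file.
#' @return named list of `codebook` objects, keyed by variable name.
#' @export
read_codebooks <- function(path) {
  raw <- yaml::read_yaml(path)
  cbs <- lapply(raw, function(e) {
    codebook(e$variable,
             codes = unlist(e$codes),
             missing = if (is.null(e$missing)) character() else as.character(unlist(e$missing)),
             groups = if (is.null(e$groups)) NULL else unlist(e$groups))
  })
  stats::setNames(cbs, vapply(cbs, `[[`, "", "variable"))
}

#' Write codebooks to a YAML file
#'
#' @param codebooks named list of [codebook] objects.
#' @param path destination YAML path.
#' @return `path`, invisibly.
#' @export
write_codebooks <- function(codebooks, path) {
  out <- lapply(codebooks, function(cb) {
    e <- list(variable = cb$variable, codes = as.list(cb$codes))
    if (length(cb$missing)) e$missing <- as.list(cb$missing)
    if (!is.null(cb$groups)) e$groups <- as.list(cb$groups)
    e
  })
  yaml::write_yaml(out, path)
  invisible(path)
}
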