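#' Default Charlson component weights for the 15 survey comorbidities
#'
#' The survey asks about 15 common conditions; the Charlson Comorbidity Index
#' (CCI) assigns integer weights to a subset of them. This default table is a
#' reconstruction of the original Charlson scheme restricted to those 15
#' conditions — the survey does not carry every condition the full index
#' requires, and conditions outside the Charlson set (hypertension, arthritis,
#' gout, coronary heart disease without infarction) carry weight 0. The four
#' pulmonary conditions (emphysema, chronic bronchitis, COPD, asthma) all map
#' to the single chronic-pulmonary-disease component and are counted once.
#' Diabetes itself is scored separately by [cci_score()]: weight 1, or 2 with
#' retinopathy as diabetes with end-organ complication.
#'
#' @return named list with `weights` (condition -> integer weight) and
#'   `component` (condition -> Charlson component, governing once-only
#'   counting).
#' @export
charlson_weights <- function() {
  conditions <- c(hypertension = 0, asthma = 1, arthritis = 0, gout = 0,
                  chf = 1, coronary_heart_disease = 0, heart_attack = 1,
                  stroke = 1, emphysema = 1, chronic_bronchitis = 1,
                  cancer = 2, liver_disease = 1, copd = 1, kidney_disease = 2,
                  retinopathy = 0)
  component <- c(hypertension = "none", asthma = "pulmonary", arthritis = "none",
                 gout = "none", chf = "chf", coronary_heart_disease = "none",
                 heart_attack = "mi", stroke = "cerebrovascular",
                 emphysema = "pulmonary", chronic_bronchitis = "pulmonary",
                 cancer = "cancer", liver_disease = "liver", copd = "pulmonary",
                 kidney_disease = "renal", retinopathy = "retinopathy")
  list(weights = conditions, component = component)
}

#' Names of the 15 comorbidity flags
#' @return character vector of condition names in canonical order.
#' @export
comorbidity_names <- function() names(charlson_weights()$weights)

#' Charlson Comorbidity Index score and severity level
#'
#' Sums the Charlson component weights over the conditions flagged `TRUE`,
#' counting each component once (the four pulmonary conditions share one
#' component). Diabetes contributes 1, or 2 when diabetic retinopathy marks
#' end-organ complication. The score is banded into four severity levels:
#' none (0), mild (1-2), moderate (3-4), severe (>= 5).
#'
#' @param flags named logical vector (or single-row data frame / list) of the
#'   15 comorbidity indicators; see [comorbidity_names()]. Must be complete —
#'   missing flags are resolved upstream.
#' @param weights weight table as returned by [charlson_weights()].
#' @param has_diabetes logical, diagnosed diabetes.
#' @param has_retinopathy logical; defaults to the `retinopathy` flag.
#' @return list with integer `score` and factor `level`.
#' @examples
#' f <- setNames(rep(FALSE, 15), comorbidity_names())
#' f[c("chf", "emphysema")] <- TRUE
#' cci_score(f)  # score 2, mild
#' @export
cci_score <- function(flags, weights = charlson_weights(),
                      has_diabetes = FALSE,
                      has_retinopathy = isTRUE(flags[["retinopathy"]])) {
  flags <- unlist(flags)
  missing_names <- setdiff(names(weights$weights), names(flags))
  if (length(missing_names))
    stop("comorbidity flag(s) missing: ", paste(missing_names, collapse = ", "))
  if (anyNA(flags[names(weights$weights)]))
    stop("comorbidity flags must be complete (no NA)")
  on <- names(weights$weights)[as.logical(flags[names(weights$weights)])]
  # one count per Charlson component, excluding non-components and retinopathy
  comp <- weights$component[on]
  on <- on[!comp %in% c("none", "retinopathy")]
  comp <- weights$component[on]
  first <- !duplicated(comp)
  score <- sum(weights$weights[on][first])
  if (isTRUE(has_diabetes)) score <- score + if (isTRUE(has_retinopathy)) 2L else 1L
  list(score = as.integer(score), level = cci_level(score))
}

#' Severity level for a CCI score
#' @param score non-negative integer vector of CCI scores.
#' @return ordered factor: none (0), mild (1-2), moderate (3-4), severe (>= 5).
#' @export
cci_level <- function(score) {
  if (any(!is.na(score) & score < 0)) stop("CCI score must be non-negative")
  cut(score, breaks = c(-0.5, 0.5, 2.5, 4.5, Inf), ordered_result = TRUE,
      labels = c("none", "mild", "moderate", "severe"))
}

#' Vectorized CCI over an analysis data frame
#'
#' @param data data frame containing the 15 comorbidity columns (logical) and
#'   a `diabetes` column.
#' @param weights weight table as returned by [charlson_weights()].
#' @return data frame with columns `cci` and `cci_level`, one row per input row.
#' @export
cci_score_all <- function(data, weights = charlson_weights()) {
  comp <- weights$component
  w <- weights$weights
  scored <- names(w)[!comp %in% c("none", "retinopathy")]
  # per component, the max weight among flagged member conditions (counted once)
  score <- rep(0L, nrow(data))
  for (cp in unique(comp[scored])) {
    members <- scored[comp[scored] == cp]
    hit <- Reduce(`|`, lapply(members, function(m) {
      v <- data[[m]]
      !is.na(v) & v
    }))
    score <- score + ifelse(hit, w[[members[1L]]], 0L)
  }
  diab <- !is.na(data$diabetes) & data$diabetes
  ret <- if ("retinopathy" %in% names(data)) !is.na(data$retinopathy) & data$retinopathy else FALSE
  score <- score + ifelse(diab, ifelse(ret, 2L, 1L), 0L)
  data.frame(cci = as.integer(score), cci_level = cci_level(score))
}

#' HbA1c glycemic-control stratum
#'
#' Glycated hemoglobin (%) banded into the four strata used to condition
#' prescribing analyses: < 6%, 6-7%, 7-9%, >= 9%; half-open bands.
#'
#' @param hba1c numeric vector of HbA1c percentages, `> 0`.
#' @return ordered factor with levels `lt6`, `6to7`, `7to9`, `ge9`.
#' @export
hba1c_stratum <- function(hba1c) {
  if (any(!is.na(hba1c) & hba1c <= 0)) stop("HbA1c must be positive")
  cut(hba1c, breaks = c(0, 6, 7, 9, Inf), right = FALSE, ordered_result = TRUE,
      labels = c("lt6", "6to7", "7to9", "ge9"))
}

#' Age bands for the diabetes analyses
#'
#' Adults with type 2 diabetes are banded as 20-45, 46-64, >= 65 (completed
#' years; half-open bands `[20,46)`, `[46,65)`, `[65,Inf)`).
#'
#' @param age numeric vector of ages in completed years, `>= 20`.
#' @return ordered factor with levels `20-45`, `46-64`, `ge65`.
#' @export
t2dm_age_band <- function(age) {
  if (any(!is.na(age) & age < 20))
    stop("age below 20 violates the diabetes cohort definition")
  cut(age, breaks = c(20, 46, 65, Inf), right = FALSE, ordered_result = TRUE,
      labels = c("20-45", "46-64", "ge65"))
}

normalize_drug <- function(x) gsub("\\s+", " ", trimws(tolower(x)))

#' Construct a therapeutic drug map
#'
#' Maps drug names to the ten antidiabetic therapeutic categories
#' (meglitinides, SGLT2is, SUs, biguanides, DPP-4is, insulin, TZDs, GLP-1RAs,
#' AGIs, combinations) and each combination product to its ingredient list.
#' Names are matched case-insensitively after whitespace normalization.
#'
#' @param categories named character vector: drug -> category (one of the nine
#'   non-combination categories, or `"combinations"`).
#' @param combinations named list: combination drug -> character vector of
#'   ingredient drug names, each of which must map into a non-combination
#'   category.
#' @return an object of class `drug_map`.
#' @export
drug_map <- function(categories, combinations = list()) {
  cats <- c("meglitinides", "SGLT2is", "SUs", "biguanides", "DPP-4is",
            "insulin", "TZDs", "GLP-1RAs", "AGIs", "combinations")
  categories <- stats::setNames(as.character(categories),
                                normalize_drug(names(categories)))
  bad <- setdiff(unique(categories), cats)
  if (length(bad)) stop("unknown therapeutic category: ", paste(bad, collapse = ", "))
  combinations <- stats::setNames(lapply(combinations, normalize_drug),
                                  normalize_drug(names(combinations)))
  for (cmb in names(combinations)) {
    if (!identical(unname(categories[cmb]), "combinations"))
      stop("'", cmb, "' has ingredients but is not categorized as a combination")
    for (ing in combinations[[cmb]]) {
      cat_i <- categories[ing]
      if (is.na(cat_i) || cat_i == "combinations")
        stop("ingredient '", ing, "' of '", cmb,
             "' does not map to a non-combination category")
    }
  }
  declared_combos <- names(categories)[categories == "combinations"]
  orphan <- setdiff(declared_combos, names(combinations))
  if (length(orphan))
    stop("combination(s) without ingredient list: ", paste(orphan, collapse = ", "))
  structure(list(categories = categories, combinations = combinations,
                 category_levels = cats),
            class = "drug_map")
}

#' @export
print.drug_map <- function(x, ...) {
  cat("Drug map: ", length(x$categories), " drugs, ",
      length(x$combinations), " combinations\n", sep = "")
  invisible(x)
}

#' Read a drug map from YAML
#'
#' YAML keys: `categories` (drug: category) and `combinations`
#' (drug: [ingredients]).
#'
#' @param path YAML file path.
#' @return a [drug_map].
#' @export
read_drug_map <- function(path) {
  raw <- yaml::read_yaml(path)
  drug_map(unlist(raw$categories),
           lapply(raw$combinations, unlist))
}

#' Bundled default antidiabetic formulary
#'
#' A representative editable formulary spanning the ten therapeutic
#' categories, shipped as YAML in `inst/extdata/drug_map.yaml`.
#'
#' @return a [drug_map].
#' @export
default_drug_map <- function() {
  read_drug_map(system.file("extdata", "drug_map.yaml", package = "svyequity",
                            mustWork = TRUE))
}

lookup_drugs <- function(prescriptions, map) {
  rx <- normalize_drug(prescriptions)
  unknown <- setdiff(rx, names(map$categories))
  if (length(unknown))
    stop("unmapped drug(s): ", paste(unknown, collapse = ", "))
  rx
}

#' Therapeutic-category indicators for a prescription list
#'
#' With `decompose = FALSE`, combinations are kept as their own class and the
#' result spans the ten categories. With `decompose = TRUE`, each combination
#' is expanded to its ingredients' categories and the result spans the nine
#' non-combination categories — the ingredient-level view used when the
#' unspecific "combinations" class would hide which classes a patient actually
#' receives. An empty prescription list sets the `None` indicator.
#'
#' @param prescriptions character vector of drug names (possibly empty).
#' @param map a [drug_map].
#' @param decompose logical; see above.
#' @return named logical vector over the categories plus `None`.
#' @export
categorize_drugs <- function(prescriptions, map = default_drug_map(),
                             decompose = FALSE) {
  cats <- map$category_levels
  if (decompose) cats <- setdiff(cats, "combinations")
  out <- stats::setNames(rep(FALSE, length(cats) + 1L), c(cats, "None"))
  if (!length(prescriptions)) {
    out["None"] <- TRUE
    return(out)
  }
  rx <- lookup_drugs(prescriptions, map)
  for (d in rx) {
    cat_d <- map$categories[[d]]
    if (decompose && cat_d == "combinations") {
      for (ing in map$combinations[[d]]) out[map$categories[[ing]]] <- TRUE
    } else {
      out[cat_d] <- TRUE
    }
  }
  out
}

#' Ingredient-level usage indicators
#'
#' Decomposes combination products and reports one indicator per distinct
#' ingredient (e.g. insulin detemir distinct from insulin glargine), the
#' finest view of utilization disparities.
#'
#' @param prescriptions character vector of drug names.
#' @param map a [drug_map].
#' @return named logical vector over the ingredients observed (normalized
#'   names), `TRUE` for each ingredient the respondent uses; zero-length for
#'   an empty prescription list.
#' @export
ingredient_usage <- function(prescriptions, map = default_drug_map()) {
  if (!length(prescriptions)) return(stats::setNames(logical(), character()))
  rx <- lookup_drugs(prescriptions, map)
  ings <- unlist(lapply(rx, function(d) {
    if (map$categories[[d]] == "combinations") map$combinations[[d]] else d
  }))
  ings <- unique(ings)
  stats::setNames(rep(TRUE, length(ings)), ings)
}
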