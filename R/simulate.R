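#' Default codebooks for the synthetic survey fixtures
#'
#' Covers the coded demographic variables the generator emits: race/ethnicity,
#' gender, fine-grained education (with the group map folding "12th grade no
#' diploma" into the 9-11th grade analysis level) and pregnancy (with 9 as the
#' declared missing/not-asked code).
#'
#' @return named list of [codebook] objects.
#' @export
default_codebooks <- function() {
  list(
    race_ethnicity = codebook("race_ethnicity",
      c(`1` = "NH White", `2` = "NH Black", `3` = "NH Asian",
        `4` = "Hispanic", `5` = "other/unknown")),
    gender = codebook("gender", c(`1` = "male", `2` = "female")),
    education = codebook("education",
      c(`1` = "less than 9th grade", `2` = "9-11th grade",
        `3` = "12th grade no diploma", `4` = "high school graduate",
        `5` = "some college or AA degree", `6` = "college graduate or above"),
      missing = c("7", "9"),
      groups = c("less than 9th grade" = "less than 9th grade",
                 "9-11th grade" = "9-11th grade",
                 "12th grade no diploma" = "9-11th grade",
                 "high school graduate" = "high school graduate",
                 "some college or AA degree" = "some college or AA degree",
                 "college graduate or above" = "college graduate or above")),
    pregnancy = codebook("pregnancy", c(`1` = "TRUE", `2` = "FALSE"),
                         missing = "9")
  )
}

education_levels <- function() {
  c("less than 9th grade", "9-11th grade", "high school graduate",
    "some college or AA degree", "college graduate or above")
}

race_levels <- function() {
  c("NH White", "NH Black", "NH Asian", "Hispanic", "other/unknown")
}

insurance_levels <- function() {
  c("private", "Medicare", "Medicaid", "other non-private", "uninsured")
}

default_outcome_coefs <- function(outcome) {
  # small true odds ratios in the 0.8-1.3 range typical of national
  # utilization contrasts; names follow model.matrix() conventions
  base <- switch(outcome,
    hav_vaccine = list(intercept = stats::qlogis(0.30),
      race = c("NH Black" = 1.09, "NH Asian" = 1.17, "Hispanic" = 1.13,
               "other/unknown" = 1.00),
      female = 1.05,
      pir = c("near poor" = 1.01, "middle income" = 0.99, "higher income" = 1.04),
      edu = c("9-11th grade" = 1.08, "high school graduate" = 1.06,
              "some college or AA degree" = 1.01, "college graduate or above" = 0.99),
      ins = c("Medicare" = 1.01, "Medicaid" = 1.09, "other non-private" = 1.01,
              "uninsured" = 0.85),
      age10 = 0.96),
    hbv_vaccine = list(intercept = stats::qlogis(0.25),
      race = c("NH Black" = 1.05, "NH Asian" = 1.10, "Hispanic" = 1.03,
               "other/unknown" = 1.00),
      female = 1.08,
      pir = c("near poor" = 1.00, "middle income" = 0.99, "higher income" = 1.03),
      edu = c("9-11th grade" = 1.14, "high school graduate" = 1.04,
              "some college or AA degree" = 0.98, "college graduate or above" = 0.98),
      ins = c("Medicare" = 0.99, "Medicaid" = 1.03, "other non-private" = 1.03,
              "uninsured" = 0.90),
      age10 = 0.90),
    biguanides = list(intercept = stats::qlogis(0.55),
      race = c("NH Black" = 0.90, "NH Asian" = 1.02, "Hispanic" = 1.00,
               "other/unknown" = 1.00),
      female = 1.00,
      pir = c("near poor" = 1.02, "middle income" = 0.96, "higher income" = 0.98),
      edu = c("9-11th grade" = 1.07, "high school graduate" = 1.06,
              "some college or AA degree" = 1.03, "college graduate or above" = 0.91),
      ins = c("Medicare" = 0.91, "Medicaid" = 0.94, "other non-private" = 0.99,
              "uninsured" = 0.92),
      age10 = 1.05),
    stop("no default coefficients for outcome '", outcome, "'"))
  cf <- c("(Intercept)" = base$intercept,
          stats::setNames(log(base$race), paste0("race_ethnicity", names(base$race))),
          "genderfemale" = log(base$female),
          stats::setNames(log(base$pir), paste0("pir_category", names(base$pir))),
          stats::setNames(log(base$edu), paste0("education5", names(base$edu))),
          stats::setNames(log(base$ins), paste0("insurance", names(base$ins))),
          "age10" = log(base$age10))
  cf
}

#' Define a synthetic-survey scenario
#'
#' A scenario fixes everything the generator needs: the stratified two-stage
#' design (strata, population PSUs, PSU sizes, per-cycle sample sizes, the
#' minority oversampling rate that makes weights unequal), the covariate
#' marginals, the clinical model (diabetes prevalence, HbA1c mixture,
#' comorbidity prevalences), the true outcome models (logistic coefficients
#' on the analysis covariates), and optional injected share disparities
#' (an observed/target odds multiplier for one subgroup on one outcome).
#' The seed fully determines all generated output.
#'
#' The default scenario is desk-scale: 15 strata x 2 sampled PSUs x 150
#' respondents per cycle over 3 two-year cycles, about 13,500 sampled rows
#' from a census of 48,000. The first sampling stage draws PSUs with
#' replacement, the textbook approximation under which the package's
#' between-PSU variance estimator is exactly unbiased.
#'
#' @param ... overrides of the default fields (unknown names are an error).
#' @return an object of class `scenario`.
#' @export
scenario <- function(...) {
  sc <- list(
    seed = 1L,
    n_strata = 15L,
    psus_per_stratum = 8L,
    psu_size = 400L,
    sample_psus = 2L,
    sample_per_psu = 150L,
    cycles = c("2013-2014", "2015-2016", "2017-2018"),
    oversample_factor = 3,
    race_marginal = c("NH White" = 0.615, "NH Black" = 0.12, "NH Asian" = 0.06,
                      "Hispanic" = 0.175, "other/unknown" = 0.03),
    gender_marginal = c(male = 0.49, female = 0.51),
    education_marginal = c("less than 9th grade" = 0.05, "9-11th grade" = 0.07,
                           "12th grade no diploma" = 0.03,
                           "high school graduate" = 0.25,
                           "some college or AA degree" = 0.31,
                           "college graduate or above" = 0.29),
    insurance_prob = c(private = 0.55, medicare = 0.18, medicaid = 0.12,
                       other = 0.08),
    insurance_missing_rate = 0.01,
    pir_meanlog = 0.7, pir_sdlog = 0.6,
    age_range = c(20L, 80L), under20_share = 0.08,
    pregnancy_rate = 0.05,
    diabetes_intercept = -4.3, diabetes_age_slope = 0.045,
    hba1c_nondiab = c(mean = 5.4, sd = 0.35),
    hba1c_diab = c(mean = 7.3, sd = 1.4),
    comorbidity_prev = c(hypertension = 0.35, asthma = 0.12, arthritis = 0.22,
                         gout = 0.04, chf = 0.03, coronary_heart_disease = 0.04,
                         heart_attack = 0.04, stroke = 0.03, emphysema = 0.02,
                         chronic_bronchitis = 0.05, cancer = 0.09,
                         liver_disease = 0.03, copd = 0.04,
                         kidney_disease = 0.03, retinopathy = 0.18),
    outcome_models = list(
      hav_vaccine = list(coef = default_outcome_coefs("hav_vaccine")),
      hbv_vaccine = list(coef = default_outcome_coefs("hbv_vaccine")),
      biguanides = list(coef = default_outcome_coefs("biguanides"),
                        subset = "diabetes")),
    share_disparity = NULL)
  dots <- list(...)
  unknown <- setdiff(names(dots), names(sc))
  if (length(unknown)) stop("unknown scenario field(s): ", paste(unknown, collapse = ", "))
  sc <- utils::modifyList(sc, dots)
  for (p in c("race_marginal", "gender_marginal", "education_marginal"))
    if (abs(sum(sc[[p]]) - 1) > 1e-8) stop(p, " must sum to 1")
  structure(sc, class = "scenario")
}

#' @export
print.scenario <- function(x, ...) {
  cat("Synthetic survey scenario: seed ", x$seed, ", ",
      x$n_strata, " strata x ", x$psus_per_stratum, " PSUs x ", x$psu_size,
      " persons (census ", x$n_strata * x$psus_per_stratum * x$psu_size, ")\n",
      "  sample: ", x$sample_psus, " PSUs/stratum x ", x$sample_per_psu,
      " respondents x ", length(x$cycles), " cycles\n",
      "  outcomes: ", paste(names(x$outcome_models), collapse = ", "), "\n",
      sep = "")
  if (!is.null(x$share_disparity))
    for (d in x$share_disparity)
      cat("  injected disparity: ", d$outcome, " ", d$variable, "=", d$level,
          " odds multiplier ", d$multiplier, "\n", sep = "")
  invisible(x)
}

# analysis covariates used by the true outcome models; rows whose insurance
# class is indeterminate (missing flags) generate their outcome at the
# reference (private) level
census_model_frame <- function(census) {
  mfr <- data.frame(
    race_ethnicity = factor(census$race_ethnicity, levels = race_levels()),
    gender = factor(census$gender, levels = c("male", "female")),
    pir_category = factor(as.character(categorize_pir(census$pir)),
                          levels = levels(categorize_pir(numeric()))),
    education5 = factor(harmonize_education(census$education,
                                            default_codebooks()$education),
                        levels = education_levels()),
    insurance = derive_insurance(stats::setNames(
      census[, c("ins_priv", "ins_mcare", "ins_mcaid", "ins_other")],
      c("private", "medicare", "medicaid", "other"))),
    age10 = (census$age - 50) / 10)
  mfr$insurance[is.na(mfr$insurance)] <- "private"
  mfr
}

#' Generate a finite synthetic population with known ground truth
#'
#' Draws a census of `n_strata * psus_per_stratum * psu_size` persons:
#' covariates from the scenario's marginals, HbA1c from a non-diabetic /
#' diabetic mixture, comorbidities from their prevalences, and each outcome
#' from `Bernoulli(plogis(x' beta))` under the scenario's true coefficients.
#' An injected share disparity multiplies the outcome odds of every member of
#' the named subgroup. Ground truth (true coefficients, realized subgroup
#' shares and utilization rates) is recorded exactly from the realized census.
#'
#' @param sc a [scenario].
#' @return list with `census` (data frame, one row per person, including the
#'   design identifiers `stratum`, `psu` and frame membership) and `truth`.
#' @export
generate_population <- function(sc) {
  stopifnot(inherits(sc, "scenario"))
  set.seed(sc$seed)
  n <- sc$n_strata * sc$psus_per_stratum * sc$psu_size
  stratum <- rep(seq_len(sc$n_strata), each = sc$psus_per_stratum * sc$psu_size)
  psu <- rep(rep(seq_len(sc$psus_per_stratum), each = sc$psu_size),
             times = sc$n_strata)

  race <- sample(names(sc$race_marginal), n, TRUE, prob = sc$race_marginal)
  gender <- sample(names(sc$gender_marginal), n, TRUE, prob = sc$gender_marginal)
  education <- sample(names(sc$education_marginal), n, TRUE,
                      prob = sc$education_marginal)
  pir <- stats::rlnorm(n, sc$pir_meanlog, sc$pir_sdlog)
  young <- stats::runif(n) < sc$under20_share
  age <- ifelse(young,
                sample(12:19, n, TRUE),
                round(stats::runif(n, sc$age_range[1L], sc$age_range[2L])))
  preg <- rep(NA, n)  # not asked of males: declared-missing downstream
  fem <- gender == "female" & age >= 20 & age <= 45
  preg[gender == "female"] <- FALSE
  preg[fem] <- stats::runif(sum(fem)) < sc$pregnancy_rate

  ins <- sapply(names(sc$insurance_prob), function(p)
    stats::runif(n) < sc$insurance_prob[[p]])
  colnames(ins) <- c("ins_priv", "ins_mcare", "ins_mcaid", "ins_other")
  ins <- as.data.frame(ins)
  for (j in seq_along(ins)) {
    miss <- stats::runif(n) < sc$insurance_missing_rate
    ins[[j]][miss] <- NA
  }

  diab <- stats::runif(n) < stats::plogis(sc$diabetes_intercept +
                                          sc$diabetes_age_slope * age)
  hba1c <- ifelse(diab,
                  stats::rnorm(n, sc$hba1c_diab[["mean"]], sc$hba1c_diab[["sd"]]),
                  stats::rnorm(n, sc$hba1c_nondiab[["mean"]], sc$hba1c_nondiab[["sd"]]))
  hba1c <- pmax(hba1c, 3.5)

  com <- sapply(names(sc$comorbidity_prev), function(cd) {
    p <- sc$comorbidity_prev[[cd]]
    hit <- stats::runif(n) < p
    if (cd == "retinopathy") hit <- hit & diab
    hit
  })
  com <- as.data.frame(com)

  census <- data.frame(census_row = seq_len(n), stratum = stratum, psu = psu,
                       age = age, gender = gender, race_ethnicity = race,
                       education = education, pir = pir, pregnancy = preg,
                       diabetes = diab, hba1c = hba1c,
                       stringsAsFactors = FALSE)
  census <- cbind(census, ins, com)

  mfr <- census_model_frame(census)
  truth_rates <- list()
  for (oc in names(sc$outcome_models)) {
    om <- sc$outcome_models[[oc]]
    X <- stats::model.matrix(~ race_ethnicity + gender + pir_category +
                               education5 + insurance + age10, mfr)
    cf <- om$coef
    bad <- setdiff(names(cf), colnames(X))
    if (length(bad))
      stop("outcome '", oc, "': coefficient(s) not in design: ",
           paste(bad, collapse = ", "))
    eta <- drop(X[, names(cf), drop = FALSE] %*% cf)
    pr <- stats::plogis(eta)
    if (!is.null(om$subset)) pr[!census[[om$subset]]] <- 0
    if (!is.null(sc$share_disparity)) {
      for (dsp in sc$share_disparity) {
        if (dsp$outcome != oc) next
        member <- census[[dsp$variable]] == dsp$level
        member[is.na(member)] <- FALSE
        if (any(member & (pr == 1)))
          stop("infeasible disparity multiplier: implied probability outside (0,1)")
        odds <- pr[member] / (1 - pr[member])
        pr[member] <- dsp$multiplier * odds / (1 + dsp$multiplier * odds)
      }
    }
    census[[oc]] <- stats::runif(n) < pr
    # realized utilization rates by race/ethnicity among the modelled subset
    base <- if (!is.null(om$subset)) census[[om$subset]] else rep(TRUE, n)
    truth_rates[[oc]] <- tapply(census[[oc]][base], census$race_ethnicity[base], mean)
  }

  truth <- list(
    coefficients = lapply(sc$outcome_models, `[[`, "coef"),
    race_shares = prop.table(table(census$race_ethnicity)),
    utilization = truth_rates)
  list(census = census, truth = truth)
}

#' Draw a stratified two-stage survey sample from a census
#'
#' First stage: `sample_psus` PSUs per stratum drawn *with replacement* (each
#' draw is an independent selection, so the with-replacement between-PSU
#' variance estimator is unbiased, including the second-stage contribution).
#' Second stage: within each PSU draw, respondents are sampled equal-
#' probability within two frames — a minority frame (non-Hispanic Black,
#' non-Hispanic Asian, Hispanic) oversampled by `oversample_factor`, and the
#' remainder — giving unequal, exactly known inclusion probabilities. The
#' weight is the inverse inclusion probability
#' `(psus_per_stratum / sample_psus) * N_frame / n_frame`, so
#' Horvitz-Thompson weighted totals estimate census totals.
#'
#' @param census census data frame from [generate_population()].
#' @param sc the [scenario] that produced it.
#' @param cycle cycle label stamped on the sampled rows.
#' @param seed optional seed for this draw (otherwise the current RNG state
#'   is used).
#' @return an [analysis_table]; the `psu` column identifies the PSU *draw*
#'   (two draws of the same census PSU are distinct variance units).
#' @export
draw_survey <- function(census, sc, cycle = sc$cycles[1L], seed = NULL) {
  stopifnot(inherits(sc, "scenario"))
  if (!is.null(seed)) set.seed(seed)
  minority <- census$race_ethnicity %in% c("NH Black", "NH Asian", "Hispanic")
  rows <- list()
  for (h in seq_len(sc$n_strata)) {
    draws <- sample.int(sc$psus_per_stratum, sc$sample_psus, replace = TRUE)
    for (d in seq_along(draws)) {
      in_psu <- which(census$stratum == h & census$psu == draws[d])
      if (length(in_psu) < sc$sample_per_psu)
        stop("requested sample exceeds PSU size in stratum ", h)
      m <- sc$sample_per_psu
      fr_min <- in_psu[minority[in_psu]]
      fr_rest <- in_psu[!minority[in_psu]]
      rate <- m / (sc$oversample_factor * length(fr_min) + length(fr_rest))
      n_min <- min(length(fr_min), max(0L, round(sc$oversample_factor * rate * length(fr_min))))
      n_rest <- m - n_min
      if (n_rest > length(fr_rest)) {
        n_rest <- length(fr_rest); n_min <- m - n_rest
      }
      pick_min <- if (n_min > 0) sample(fr_min, n_min) else integer()
      pick_rest <- if (n_rest > 0) sample(fr_rest, n_rest) else integer()
      picked <- c(pick_min, pick_rest)
      w2 <- c(rep(length(fr_min) / max(n_min, 1L), n_min),
              rep(length(fr_rest) / max(n_rest, 1L), n_rest))
      w1 <- sc$psus_per_stratum / sc$sample_psus
      block <- census[picked, , drop = FALSE]
      block$weight <- w1 * w2
      block$stratum <- h
      block$psu <- paste0(h, ".", d)
      rows[[length(rows) + 1L]] <- block
    }
  }
  out <- do.call(rbind, rows)
  out$cycle <- cycle
  occ <- stats::ave(seq_len(nrow(out)), out$census_row, FUN = seq_along)
  out$id <- sprintf("%s-%06d-%d", cycle, out$census_row, occ)
  out$census_row <- NULL
  rownames(out) <- NULL
  front <- c("id", "cycle", "stratum", "psu", "weight")
  out <- out[, c(front, setdiff(names(out), front)), drop = FALSE]
  analysis_table(out, survey_design("weight", "stratum", "psu", cycles = 1L))
}

#' Simulate a full multi-cycle survey
#'
#' Generates the census once and draws one independent sample per scenario
#' cycle, then combines them with [combine_cycles()] (weights divided by the
#' number of cycles). Ground truth is attached as the `truth` element.
#'
#' @param sc a [scenario].
#' @return list with `tab` (combined [analysis_table]), `census` and `truth`.
#' @export
simulate_survey <- function(sc = scenario()) {
  pop <- generate_population(sc)
  tables <- lapply(seq_along(sc$cycles), function(i)
    draw_survey(pop$census, sc, cycle = sc$cycles[i])$data)
  cc <- combine_cycles(tables, survey_design("weight", "stratum", "psu"))
  tab <- analysis_table(cc$data, cc$design)
  list(tab = tab, census = pop$census, truth = pop$truth)
}

#' Add the derived analysis covariates to a sampled table
#'
#' Computes the derived variables every analysis uses: the mutually exclusive
#' insurance class, PIR category, harmonized 5-level education, HbA1c
#' stratum, CCI score and level, and (for respondents aged 20+) the diabetes
#' age band.
#'
#' @param tab an [analysis_table] holding the generator's raw columns.
#' @return the [analysis_table] with derived columns appended.
#' @export
add_derived_columns <- function(tab) {
  stopifnot(inherits(tab, "analysis_table"))
  d <- tab$data
  d$insurance <- derive_insurance(
    stats::setNames(d[, c("ins_priv", "ins_mcare", "ins_mcaid", "ins_other")],
                    c("private", "medicare", "medicaid", "other")))
  d$pir_category <- categorize_pir(d$pir)
  d$education5 <- factor(harmonize_education(d$education, default_codebooks()$education),
                         levels = education_levels())
  d$race_ethnicity <- factor(d$race_ethnicity, levels = race_levels())
  d$gender <- factor(d$gender, levels = c("male", "female"))
  d$hba1c_stratum <- hba1c_stratum(d$hba1c)
  cci <- cci_score_all(d)
  d$cci <- cci$cci
  d$cci_level <- cci$cci_level
  d$age_band <- factor(NA, levels = levels(t2dm_age_band(20)))
  adult <- !is.na(d$age) & d$age >= 20
  d$age_band[adult] <- t2dm_age_band(d$age[adult])
  d$age10 <- (d$age - 50) / 10
  tab$data <- d
  log_step(tab, "add_derived_columns", nrow(d))
}

encode_with_codebooks <- function(df, codebooks) {
  for (v in names(codebooks)) {
    if (!v %in% names(df)) next
    cb <- codebooks[[v]]
    lab <- as.character(df[[v]])
    rev_map <- stats::setNames(names(cb$codes), unname(cb$codes))
    code <- rev_map[lab]
    if (any(is.na(code) & !is.na(lab)))
      stop("cannot encode label(s) for '", v, "': ",
           paste(unique(lab[is.na(code) & !is.na(lab)]), collapse = ", "))
    if (length(cb$missing)) code[is.na(lab)] <- cb$missing[1L]
    df[[v]] <- as.numeric(code)
  }
  df
}

#' Write a synthetic survey fixture to disk
#'
#' Emits the data in CSV and/or SAS transport (XPT) form with coded
#' categorical variables (labels encoded back through the codebooks, `NA`
#' written as the declared missing code where one exists), plus the codebook
#' YAML and, when supplied, a ground-truth JSON. Files are loadable by
#' [read_survey_table()].
#'
#' @param data data frame or [analysis_table].
#' @param dir destination directory (created if needed).
#' @param format subset of `c("csv", "xpt")`.
#' @param codebooks codebooks used for encoding; written alongside.
#' @param truth optional ground-truth list to serialize as JSON.
#' @param name file stem.
#' @return named character vector of the files written, invisibly.
#' @export
write_fixture <- function(data, dir, format = c("csv", "xpt"),
                          codebooks = default_codebooks(), truth = NULL,
                          name = "survey") {
  if (inherits(data, "analysis_table")) data <- data$data
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  coded <- encode_with_codebooks(data, codebooks)
  # logicals as 0/1 so both formats agree exactly
  for (j in names(coded)) if (is.logical(coded[[j]])) coded[[j]] <- as.numeric(coded[[j]])
  files <- character()
  if ("csv" %in% format) {
    f <- file.path(dir, paste0(name, ".csv"))
    utils::write.csv(coded, f, row.names = FALSE, na = "")
    files["csv"] <- f
  }
  if ("xpt" %in% format) {
    f <- file.path(dir, paste0(name, ".xpt"))
    write_xpt(coded, f, dsname = "SURVEY")
    files["xpt"] <- f
  }
  files["codebooks"] <- file.path(dir, paste0(name, "_codebooks.yaml"))
  write_codebooks(codebooks, files[["codebooks"]])
  if (!is.null(truth)) {
    files["truth"] <- file.path(dir, paste0(name, "_truth.json"))
    tr <- truth
    tr$coefficients <- lapply(tr$coefficients, as.list)  # keep names in JSON
    jsonlite::write_json(tr, files[["truth"]], auto_unbox = TRUE, digits = NA,
                         force = TRUE)
  }
  invisible(files)
}
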