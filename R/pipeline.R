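#' Run the full disparity-analysis pipeline from a configuration
#'
#' Orchestrates harmonize -> code -> estimate -> equity (+ regression) ->
#' report. The configuration (YAML file or list) either names input data
#' files with codebooks or requests the bundled synthetic scenario, then
#' declares the cohort, outcomes, sensitive covariate, optional conditioning
#' column, thresholds and an optional regression formula. All artifacts are
#' written under `out_dir` together with a JSON log carrying row counts, the
#' seed, package version, config hash and the active value of every
#' configurable decision (insurance priority, interval conventions, test
#' mode, lonely-PSU rule), so a run can be re-executed from its log.
#'
#' Config keys: `scenario` (list of [scenario()] overrides) *or* `input`
#' (`path`, `format`, `codebooks`); `cohort` (`hav_hbv`/`hpv`/`t2dm` or
#' `none`); `outcomes` (character); `sensitive` (column); `conditioning`
#' (column or null); `thresholds` (`tau_rule_lower`, `tau_rule_upper`,
#' `alpha`); `test` (`exact`/`normal`); `regression` (formula string or
#' null); `required` (complete-case columns).
#'
#' @param config path to a YAML config, or an equivalent named list.
#' @param out_dir run directory to create.
#' @return invisibly, a list with the `equity_table`, the regression fit (or
#'   `NULL`), the harmonized [analysis_table] and the log.
#' @export
run_pipeline <- function(config, out_dir) {
  config_hash <- NA_character_
  if (is.character(config)) {
    config_hash <- unname(tools::md5sum(config))
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- config$seed %||% 1L
  stage <- "configure"
  log <- list(package = "svyequity",
              version = as.character(utils::packageVersion("svyequity")),
              seed = seed, config_hash = config_hash,
              decisions = list(
                insurance_priority = "private > Medicare > Medicaid > other non-private",
                intervals = "half-open [lower, upper)",
                adult_age = "age >= 20 completed years",
                lonely_psu = "center at grand mean",
                test = config$test %||% "exact",
                p_adjust = config$p_adjust %||% "none"))
  tryCatch({
    stage <- "data"
    if (!is.null(config$scenario) || is.null(config$input)) {
      sc <- do.call(scenario, c(list(seed = seed), config$scenario))
      sim <- simulate_survey(sc)
      tab <- sim$tab
      log$scenario <- "synthetic"
    } else {
      cbs <- if (!is.null(config$input$codebooks))
        read_codebooks(config$input$codebooks) else default_codebooks()
      paths <- config$input$path
      raw <- lapply(paths, read_survey_table,
                    format = config$input$format %||% "guess", codebooks = cbs)
      if (length(raw) > 1L) {
        cc <- combine_cycles(raw, survey_design())
        tab <- analysis_table(cc$data, cc$design)
      } else {
        tab <- analysis_table(raw[[1L]], survey_design())
      }
      log$scenario <- "external input"
    }
    log$rows_input <- nrow(tab$data)

    stage <- "harmonize"
    tab <- add_derived_columns(tab)
    if (!is.null(config$cohort) && config$cohort != "none")
      tab <- filter_cohort(tab, config$cohort)
    required <- config$required %||%
      c("age", "gender", "race_ethnicity", "education5", "insurance",
        "pir_category")
    tab <- drop_missing(tab, required)
    log$rows_analyzed <- nrow(tab$data)

    stage <- "equity"
    th <- do.call(equity_thresholds, config$thresholds %||% list())
    et <- equity_eval(tab,
                      sensitive = config$sensitive %||% "race_ethnicity",
                      outcomes = config$outcomes,
                      conditioning = config$conditioning,
                      thresholds = th,
                      test = config$test %||% "exact",
                      p_adjust = config$p_adjust %||% "none")
    log$thresholds <- th[c("tau_l", "tau_u", "alpha")]
    write_equity_table(et, file.path(out_dir, "equity_table.csv"),
                       file.path(out_dir, "equity_table.json"))
    render_heatmap(et, file.path(out_dir, "equity_heatmap.png"))

    stage <- "regression"
    fit <- NULL
    if (!is.null(config$regression)) {
      fit <- svylogit(stats::as.formula(config$regression), tab)
      or <- odds_ratios(fit)
      write_or_table(or, file.path(out_dir, "odds_ratios.csv"))
      out_cut <- config$outlier_cutoff %||% 3
      fl <- flag_outliers(fit, cutoff = out_cut)
      log$regression <- list(formula = config$regression, n = fit$n,
                             df = fit$df, iterations = fit$iter,
                             outliers_flagged = nrow(fl))
      utils::write.csv(fl, file.path(out_dir, "outliers.csv"), row.names = FALSE)
    }

    stage <- "report"
    write_analysis_table(tab, file.path(out_dir, "analysis_table.csv"),
                         file.path(out_dir, "provenance.json"))
    log$provenance <- tab$provenance
    jsonlite::write_json(log, file.path(out_dir, "run_log.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
    invisible(list(equity = et, fit = fit, tab = tab, log = log))
  }, error = function(e) {
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
}
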