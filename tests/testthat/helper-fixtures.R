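# shared fixtures: all generated in code, no files on disk

# a desk-scale scenario small enough for per-test simulation
small_scenario <- function(...) {
  defaults <- list(n_strata = 4L, psus_per_stratum = 4L, psu_size = 150L,
                   sample_psus = 2L, sample_per_psu = 40L, cycles = c("A", "B"))
  do.call(scenario, utils::modifyList(defaults, list(...)))
}

# hand-built analysis table with a transparent design: 2 strata x 2 PSUs
toy_table <- function() {
  d <- data.frame(
    id = sprintf("r%02d", 1:12),
    stratum = rep(1:2, each = 6),
    psu = rep(c("a", "b", "a", "b"), times = c(3, 3, 3, 3)),
    weight = c(1, 2, 1, 3, 1, 2, 2, 2, 1, 1, 3, 1),
    member = c(TRUE, FALSE, TRUE, TRUE, FALSE, FALSE,
               TRUE, FALSE, FALSE, TRUE, FALSE, TRUE),
    outcome = c(TRUE, TRUE, FALSE, TRUE, FALSE, TRUE,
                TRUE, TRUE, FALSE, FALSE, TRUE, FALSE))
  analysis_table(d, survey_design("weight", "stratum", "psu"))
}

all_false_flags <- function() {
  setNames(rep(FALSE, length(comorbidity_names())), comorbidity_names())
}

# share_estimate constructor shortcut for estimator-level simulations
mk_share <- function(estimate, se, n_eff) {
  svyequity:::share_estimate(estimate, se, n_eff,
                             wtotal = n_eff, n = ceiling(n_eff))
}

# weighted draw of a subgroup-membership share: returns a share_estimate
draw_share <- function(p, w) {
  x <- stats::rbinom(length(w), 1L, p)
  est <- sum(w * x) / sum(w)
  ne <- kish_effective_n(w)
  se <- sqrt(est * (1 - est) / ne)
  mk_share(est, se, ne)
}
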