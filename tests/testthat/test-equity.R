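test_that("rule-based thresholds match their closed form", {
  expect_equal(threshold_from_rule(0), 0)
  expect_lt(abs(threshold_from_rule(0.2) - 0.22314), 1e-5)
  expect_lt(abs(threshold_from_rule(0.4) - 0.51083), 1e-5)
  expect_error(threshold_from_rule(1), "infinite")
  expect_error(threshold_from_rule(-0.1), "\\[0, 1\\)")
  th <- equity_thresholds()
  expect_lt(th$tau_l, th$tau_u)
  expect_error(equity_thresholds(0.4, 0.2), "smaller")
})

test_that("log disparity matches direct arithmetic and flags absence", {
  expect_equal(log_disparity(0.2, 0.2), 0)
  expect_equal(log_disparity(0.1, 0.2), log((0.1 / 0.9) / (0.2 / 0.8)))
  expect_equal(log_disparity(0.1, 0.2), -0.8109, tolerance = 1e-4)
  expect_identical(log_disparity(0, 0.2), -Inf)
  expect_error(log_disparity(0.5, 0), "target")
  expect_error(log_disparity(0.5, 1), "target")
  expect_error(log_disparity(1, 0.5), "observed")
})

test_that("log disparity is antisymmetric and monotone in the observed share", {
  set.seed(77)
  a <- runif(2000, 0.01, 0.99)
  b <- runif(2000, 0.01, 0.99)
  expect_equal(log_disparity(a, b), -log_disparity(b, a), tolerance = 1e-12)
  # strictly increasing in the observed share at fixed target
  o <- sort(runif(500, 0.001, 0.999))
  expect_true(all(diff(log_disparity(o, 0.37)) > 0))
})

test_that("disparity test agrees with an enumeration oracle on fixed counts", {
  obs <- mk_share(10 / 100, sqrt(0.1 * 0.9 / 100), 100)
  tgt <- mk_share(0.25, 0.001, 1e5)
  p_pkg <- test_disparity(obs, tgt, method = "exact")
  # independent oracle: enumerate the binomial(100, 0.25) pmf and sum the
  # probabilities of outcomes no more likely than the observed one
  pmf <- dbinom(0:100, 100, 0.25)
  p_oracle <- sum(pmf[pmf <= pmf[10 + 1] * (1 + 1e-7)])
  expect_equal(p_pkg, p_oracle, tolerance = 1e-10)
})

test_that("disparity test never rejects the exact null and flags degeneracy", {
  obs <- mk_share(0.3, sqrt(0.3 * 0.7 / 5000), 5000)
  tgt <- mk_share(0.3, 0.001, 1e5)
  expect_gt(test_disparity(obs, tgt), 0.95)
  expect_gt(test_disparity(obs, tgt, method = "normal"), 0.95)
  expect_error(test_disparity(obs, mk_share(1, 0, 10)), "degenerate")
  und <- svyequity:::share_estimate(NA, NA, NA, 0, 0, undefined = TRUE)
  expect_error(test_disparity(und, tgt), "undefined")
})

test_that("classification reproduces the six-level legend with half-open bands", {
  th <- equity_thresholds()  # tau_l = 0.22314, tau_u = 0.51083, alpha = 0.05
  # significance gate: non-significant cells are Adequate whatever the score
  expect_identical(as.character(classify_equity(-0.9, 0.2, th)), "Adequate")
  expect_identical(as.character(classify_equity(-0.6, 0.01, th)), "Highly Inadequate")
  expect_identical(as.character(classify_equity(0.3, 0.01, th)), "Abundant")
  # boundary sweep at +/- tau_l, +/- tau_u (significant cells)
  eps <- 1e-9
  sweep <- c(-th$tau_u - eps, -th$tau_u, -th$tau_l - eps, -th$tau_l,
             th$tau_l - eps, th$tau_l, th$tau_u - eps, th$tau_u)
  expect_identical(as.character(classify_equity(sweep, rep(0.01, 8), th)),
                   c("Highly Inadequate", "Inadequate", "Inadequate", "Adequate",
                     "Adequate", "Abundant", "Abundant", "Highly Abundant"))
  # p exactly alpha is significant (the gate requires p > alpha)
  expect_identical(as.character(classify_equity(0.3, 0.05, th)), "Abundant")
  # Absent sentinel wins regardless of p
  expect_identical(as.character(classify_equity(-Inf, 0.5, th)), "Absent")
})

test_that("classification is exhaustive and exclusive over random inputs", {
  set.seed(123)
  th <- equity_thresholds()
  score <- c(runif(500, -2, 2), -Inf)
  p <- runif(501)
  got <- classify_equity(score, p, th)
  expect_false(anyNA(got))
  expect_true(all(as.character(got) %in% equity_levels()))
  # degenerate limit: thresholds -> 0 leaves significant cells only in the
  # extreme classes
  th0 <- equity_thresholds(1e-12, 2e-12)
  sig <- p <= th0$alpha & is.finite(score) & abs(score) > 1e-6
  got0 <- as.character(classify_equity(score, p, th0))
  expect_true(all(got0[sig] %in% c("Highly Inadequate", "Highly Abundant")))
})

test_that("equity evaluation on a null scenario yields all-Adequate cells", {
  # outcomes independent of every covariate: intercept-only truth
  sc <- scenario(seed = 14, outcome_models = list(
    hav_vaccine = list(coef = c("(Intercept)" = qlogis(0.30))),
    hbv_vaccine = list(coef = c("(Intercept)" = qlogis(0.25)))))
  sim <- simulate_survey(sc)
  tab <- add_derived_columns(sim$tab)
  et <- equity_eval(tab, "race_ethnicity", c("hav_vaccine", "hbv_vaccine"))
  expect_s3_class(et, "equity_table")
  expect_identical(nrow(et), 10L)
  expect_true(all(as.character(et$level) == "Adequate"))
})

test_that("conditioned evaluation strata are evaluated independently", {
  sc <- small_scenario(seed = 15)
  sim <- simulate_survey(sc)
  tab <- add_derived_columns(sim$tab)
  tab <- drop_missing(tab, c("race_ethnicity", "insurance", "hba1c_stratum"))
  tab$data$nonprivate <- factor(
    ifelse(tab$data$insurance == "private", "private", "non-private"))
  et <- equity_eval(tab, "race_ethnicity", "biguanides",
                    target = tab$data$diabetes & tab$data$hba1c >= 6,
                    conditioning = "nonprivate")
  expect_identical(nrow(et), 10L)  # 5 subgroups x 1 outcome x 2 strata
  expect_setequal(unique(et$conditioning), c("non-private", "private"))
  # per-stratum target shares each sum to one over the subgroup partition
  for (s in unique(et$conditioning))
    expect_equal(sum(et$target[et$conditioning == s], na.rm = TRUE), 1,
                 tolerance = 1e-12)
})

test_that("structurally missing cells are distinct from Absent", {
  d <- data.frame(id = as.character(1:40), stratum = rep(1:2, 20),
                  psu = rep(1:4, 10), weight = 1,
                  grp = factor(rep(c("a", "b"), each = 20), levels = c("a", "b", "c")),
                  y = rep(c(TRUE, FALSE), 20))
  # subgroup "b" has members but none receive the service -> Absent
  d$y[d$grp == "b"] <- FALSE
  tab <- analysis_table(d, survey_design())
  et <- equity_eval(tab, "grp", "y")
  lev <- setNames(as.character(et$level), et$subgroup)
  expect_identical(unname(lev["b"]), "Absent")
  # subgroup "a" is all of the recipients: infinite odds, Highly Abundant
  expect_identical(unname(lev["a"]), "Highly Abundant")
  # level "c" never occurs: structurally missing, not Absent
  expect_false("c" %in% et$subgroup)
})

test_that("equity tables serialize to CSV and JSON", {
  sc <- small_scenario(seed = 16)
  sim <- simulate_survey(sc)
  tab <- add_derived_columns(sim$tab)
  et <- equity_eval(tab, "gender", "hav_vaccine")
  fc <- tempfile(fileext = ".csv"); fj <- tempfile(fileext = ".json")
  write_equity_table(et, fc, fj)
  back <- read.csv(fc)
  expect_identical(nrow(back), nrow(et))
  expect_true(all(c("subgroup", "observed", "target", "score", "p", "level")
                  %in% names(back)))
  js <- jsonlite::read_json(fj)
  expect_equal(js$thresholds$tau_l, attr(et, "thresholds")$tau_l)
  expect_identical(length(js$cells), nrow(et))
})
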