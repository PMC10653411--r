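test_that("codebook construction enforces its invariants", {
  expect_error(codebook("v", c(`1` = "a", `1` = "b")), "duplicated")
  expect_error(codebook("v", c(`1` = "a"), missing = "1"), "both value and missing")
  expect_error(codebook("v", c(`1` = "a", `2` = "b"),
                        groups = c(a = "g1", a = "g2")),
               "two groups")
  cb <- codebook("v", c(`1` = "a", `2` = "b"), missing = "9")
  expect_s3_class(cb, "codebook")
})

test_that("decoding maps declared-missing codes to NA and rejects unknown codes", {
  cb <- codebook("pregnancy", c(`1` = "yes", `2` = "no"), missing = "9")
  expect_identical(decode_values(c(1, 9, 2, NA), cb),
                   c("yes", NA, "no", NA))
  err <- tryCatch(decode_values(c(1, 4, 2), cb), error = conditionMessage)
  expect_match(err, "pregnancy")
  expect_match(err, "4")
  expect_match(err, "row\\(s\\) 2")
})

test_that("codebooks round-trip through YAML", {
  cbs <- default_codebooks()
  f <- tempfile(fileext = ".yaml")
  write_codebooks(cbs, f)
  back <- read_codebooks(f)
  expect_identical(names(back), names(cbs))
  expect_identical(back$education$codes, cbs$education$codes)
  expect_identical(back$education$groups, cbs$education$groups)
  expect_identical(back$pregnancy$missing, cbs$pregnancy$missing)
})

test_that("CSV and XPT encodings of the same rows read back identically", {
  set.seed(42)
  sc <- small_scenario(seed = 42)
  pop <- generate_population(sc)
  tab <- draw_survey(pop$census, sc, cycle = "A", seed = 7)
  rows <- utils::head(tab$data, 10)
  dir <- tempfile()
  files <- write_fixture(rows, dir, format = c("csv", "xpt"))
  cbs <- read_codebooks(files[["codebooks"]])
  from_csv <- read_survey_table(files[["csv"]], codebooks = cbs)
  from_xpt <- read_survey_table(files[["xpt"]], codebooks = cbs)
  expect_identical(names(from_csv), names(from_xpt))
  for (cn in names(from_csv)) {
    csv_col <- from_csv[[cn]]
    xpt_col <- from_xpt[[cn]]
    # foreign reads absent character cells as ""; CSV reader as NA
    if (is.character(xpt_col)) xpt_col[xpt_col == ""] <- NA
    if (is.numeric(xpt_col)) {
      # XPT is bit-exact; CSV goes through 15-digit decimal text
      expect_equal(csv_col, xpt_col, tolerance = 1e-12, info = cn)
    } else {
      expect_identical(as.character(csv_col), as.character(xpt_col), info = cn)
    }
  }
  # declared missing code comes back absent
  expect_true(anyNA(from_csv$pregnancy))
})

test_that("reading validates codes against the codebook domain", {
  f <- tempfile(fileext = ".csv")
  write.csv(data.frame(id = 1:3, weight = 1, stratum = 1, psu = 1,
                       education = c(1, 4, 8)),
            f, row.names = FALSE)
  expect_error(read_survey_table(f, codebooks = default_codebooks()),
               "education.*unknown code")
  expect_error(read_survey_table(tempfile(), codebooks = list()), "not found")
})

test_that("cycle combination divides weights by the cycle count", {
  t1 <- data.frame(id = "a1", cycle = "c1", weight = 30000)
  t2 <- data.frame(id = "a2", cycle = "c2", weight = 30000)
  t3 <- data.frame(id = "a3", cycle = "c3", weight = 30000)
  out <- combine_cycles(list(t1, t2, t3), survey_design())
  expect_equal(out$data$weight, rep(10000, 3))
  expect_identical(out$design$cycles, 3L)

  one <- combine_cycles(list(t1), survey_design())
  expect_equal(one$data$weight, 30000)

  expect_error(combine_cycles(list(t1, t1), survey_design()), "distinct")
  t_dup <- data.frame(id = "a1", cycle = "c2", weight = 1)
  expect_error(combine_cycles(list(t1, t_dup), survey_design()), "duplicate")
})

test_that("combined weighted total equals the mean of per-cycle totals", {
  set.seed(11)
  tabs <- lapply(c("c1", "c2", "c3"), function(cy)
    data.frame(id = paste0(cy, 1:50), cycle = cy, weight = rlnorm(50, 8, 1)))
  out <- combine_cycles(tabs, survey_design())
  per_cycle <- vapply(tabs, function(t) sum(t$weight), 0)
  expect_equal(sum(out$data$weight), mean(per_cycle), tolerance = 1e-9)
})

test_that("insurance derivation follows the priority order and uninsured rule", {
  grid <- data.frame(
    private  = c(FALSE, TRUE,  FALSE, FALSE, FALSE, TRUE,  FALSE, NA),
    medicare = c(FALSE, FALSE, TRUE,  FALSE, FALSE, TRUE,  NA,    NA),
    medicaid = c(FALSE, TRUE,  TRUE,  TRUE,  FALSE, TRUE,  FALSE, FALSE),
    other    = c(FALSE, FALSE, FALSE, FALSE, TRUE,  TRUE,  FALSE, FALSE))
  got <- derive_insurance(grid)
  expect_identical(as.character(got),
                   c("uninsured",          # all explicitly not covered
                     "private",            # private beats Medicaid
                     "Medicare",           # Medicare beats Medicaid
                     "Medicaid",
                     "other non-private",
                     "private",            # full coverage -> highest priority
                     NA,                   # no TRUE flag, one unknown
                     NA))
  # priority order is configurable
  alt <- derive_insurance(grid[2, ],
                          priority = c("medicaid", "medicare", "private", "other"))
  expect_identical(as.character(alt), "Medicaid")
})

test_that("PIR categorization uses half-open intervals and is idempotent", {
  expect_identical(as.character(categorize_pir(c(0.5, 1.95, 4.0))),
                   c("poor", "near poor", "higher income"))
  # boundary sweep: lower edges belong to the upper category
  edges <- c(0, 1, 2, 4)
  expect_identical(as.character(categorize_pir(edges)),
                   c("poor", "near poor", "middle income", "higher income"))
  expect_identical(as.character(categorize_pir(edges[-1] - 1e-9)),
                   c("poor", "near poor", "middle income"))
  expect_error(categorize_pir(-0.1), "non-negative")
  once <- categorize_pir(c(0.3, 2.2, NA))
  expect_identical(categorize_pir(once), once)
})

test_that("education harmonization folds fine codes onto the five analysis levels", {
  cb <- default_codebooks()$education
  expect_identical(harmonize_education(1, cb), "less than 9th grade")
  expect_identical(harmonize_education(3, cb), "9-11th grade")  # 12th, no diploma
  expect_identical(harmonize_education(c(2, 6), cb),
                   c("9-11th grade", "college graduate or above"))
  # idempotent on already-harmonized labels
  once <- harmonize_education(c(1, 3, 5), cb)
  expect_identical(harmonize_education(once, cb), once)
  # identity when the codebook has no group map
  cb0 <- codebook("education", c(`1` = "low", `2` = "high"))
  expect_identical(harmonize_education(c(2, 1), cb0), c("high", "low"))
  # a label with no group mapping is an error
  cb_bad <- codebook("education", c(`1` = "phantom level"),
                     groups = c("something else" = "x"))
  expect_error(harmonize_education(1, cb_bad), "phantom level")
})

test_that("cohort filters implement the inclusion rules", {
  d <- data.frame(id = as.character(1:6), stratum = 1, psu = rep(1:2, 3),
                  weight = 1,
                  age = c(19, 25, 60, 30, 45, 70),
                  pregnancy = c(NA, FALSE, NA, TRUE, FALSE, NA),
                  diabetes = c(TRUE, FALSE, TRUE, TRUE, TRUE, NA))
  tab <- analysis_table(d, survey_design())
  expect_identical(filter_cohort(tab, "hav_hbv")$data$id, c("2", "3", "5", "6"))
  expect_identical(filter_cohort(tab, "hpv")$data$id, c("2", "5"))  # 60+ out
  expect_identical(filter_cohort(tab, "t2dm")$data$id, c("3", "5"))
  # age 19 excluded everywhere; strict mode also drops exactly-20
  d20 <- d; d20$age[1] <- 20
  t20 <- analysis_table(d20, survey_design())
  expect_true("1" %in% filter_cohort(t20, "hpv")$data$id)
  expect_false("1" %in% filter_cohort(t20, "hpv", strict_age = TRUE)$data$id)
  # empty input stays empty, with provenance recorded
  empty <- analysis_table(d[0, ], survey_design())
  out <- filter_cohort(empty, "hav_hbv")
  expect_identical(nrow(out$data), 0L)
  expect_identical(out$provenance[[2]]$op, "filter_cohort[hav_hbv]")
})

test_that("drop_missing keeps complete cases and logs the dropped count", {
  d <- data.frame(id = as.character(1:10), stratum = 1, psu = 1, weight = 1,
                  pir = c(NA, 2, 3, NA, 1, 2, 3, 4, 5, 6))
  tab <- analysis_table(d, survey_design())
  out <- drop_missing(tab, "pir")
  expect_identical(nrow(out$data), 8L)
  expect_match(out$provenance[[2]]$note, "2 dropped")
  # identity when nothing is missing
  out2 <- drop_missing(out, "pir")
  expect_identical(out2$data, out$data)
  # dropping on a never-observed column empties the table
  d$ghost <- NA_real_
  expect_identical(nrow(drop_missing(analysis_table(d, survey_design()),
                                     "ghost")$data), 0L)
  expect_error(drop_missing(tab, "nope"), "not present")
})

test_that("filters never increase row counts nor alter retained rows", {
  sc <- small_scenario(seed = 3)
  sim <- simulate_survey(sc)
  tab <- add_derived_columns(sim$tab)
  filtered <- filter_cohort(tab, "hpv")
  expect_lte(nrow(filtered$data), nrow(tab$data))
  kept <- tab$data[tab$data$id %in% filtered$data$id, ]
  rownames(kept) <- NULL
  reord <- filtered$data[, names(tab$data)]
  rownames(reord) <- NULL
  expect_identical(reord, kept)
  counts <- vapply(provenance(filtered), `[[`, 0, "rows")
  expect_true(all(diff(counts) <= 0))
})
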