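# compact generator for regression tests: independent rows with fake design ids
logit_data <- function(n, beta = c(`(Intercept)` = -0.5, x = 0.4, zyes = -0.3),
                       n_strata = 10, wt_sd = 0.4) {
  d <- data.frame(x = rnorm(n),
                  z = factor(sample(c("no", "yes"), n, TRUE)),
                  stratum = sample(n_strata, n, TRUE),
                  weight = rlnorm(n, 0, wt_sd))
  d$psu <- paste0(d$stratum, ".", sample(2, n, TRUE))
  X <- model.matrix(~ x + z, d)
  d$y <- rbinom(n, 1, plogis(drop(X[, names(beta)] %*% beta)))
  d
}

test_that("intercept-only fit recovers the logit of the weighted prevalence", {
  set.seed(1)
  d <- logit_data(400)
  fit <- svylogit(y ~ 1, d)
  expect_equal(unname(coef(fit)),
               qlogis(weighted_proportion(d$y, d$weight)),
               tolerance = 1e-8)
})

test_that("a single binary covariate reproduces the weighted 2x2 odds ratio", {
  set.seed(2)
  d <- logit_data(600)
  fit <- svylogit(y ~ z, d)
  w11 <- sum(d$weight[d$z == "yes" & d$y == 1])
  w10 <- sum(d$weight[d$z == "yes" & d$y == 0])
  w01 <- sum(d$weight[d$z == "no" & d$y == 1])
  w00 <- sum(d$weight[d$z == "no" & d$y == 0])
  expect_equal(unname(exp(coef(fit)["zyes"])), (w11 / w10) / (w01 / w00),
               tolerance = 1e-7)
})

test_that("coefficients match a brute-force weighted-likelihood maximizer at n = 12", {
  set.seed(8)
  d <- data.frame(x = rnorm(12), z = factor(sample(c("no", "yes"), 12, TRUE)),
                  stratum = 1, weight = rlnorm(12, 0, 0.5))
  d$psu <- 1:12
  X0 <- model.matrix(~ x + z, d)
  d$y <- rbinom(12, 1, plogis(drop(X0 %*% c(-0.2, 0.4, -0.3))))
  fit <- svylogit(y ~ x + z, d)
  X <- model.matrix(~ x + z, d)
  negll <- function(b) {
    mu <- plogis(drop(X %*% b))
    -sum(d$weight * (d$y * log(mu) + (1 - d$y) * log(1 - mu)))
  }
  grad <- function(b) -drop(crossprod(X, d$weight * (d$y - plogis(drop(X %*% b)))))
  opt <- optim(c(0, 0, 0), negll, grad, method = "BFGS",
               control = list(reltol = 1e-15, maxit = 2000))
  expect_lt(max(abs(unname(coef(fit)) - opt$par)), 1e-6)
})

test_that("coefficients and linearized SEs are invariant to weight rescaling", {
  set.seed(4)
  d <- logit_data(500)
  f1 <- svylogit(y ~ x + z, d)
  d2 <- d; d2$weight <- d2$weight * 7.3e4
  f2 <- svylogit(y ~ x + z, d2)
  expect_equal(coef(f1), coef(f2), tolerance = 1e-9)
  expect_equal(vcov(f1), vcov(f2), tolerance = 1e-9)
})

test_that("with equal weights and singleton PSUs the SEs match the robust sandwich", {
  skip_if_not_installed("sandwich")
  set.seed(5)
  n <- 300
  d <- logit_data(n, wt_sd = 0)
  d$weight <- 1
  d$stratum <- 1
  d$psu <- seq_len(n)
  fit <- svylogit(y ~ x + z, d)
  g <- glm(y ~ x + z, binomial, d)
  V <- sandwich::vcovHC(g, type = "HC0") * n / (n - 1)
  expect_equal(sqrt(diag(vcov(fit))), sqrt(diag(V)), tolerance = 1e-6)
  expect_equal(coef(fit), coef(g), tolerance = 1e-6)
})

test_that("separation is detected and named", {
  d <- data.frame(y = c(rep(0, 10), rep(1, 10)),
                  x = c(rep(0, 10), rep(1, 10)),
                  weight = 1, stratum = rep(1:2, 10), psu = rep(1:4, 5))
  expect_error(svylogit(y ~ x, d, max_iter = 60), "separation")
})

test_that("odds ratios expose the conventional table with CI/significance duality", {
  set.seed(6)
  d <- logit_data(2000)
  fit <- svylogit(y ~ x + z, d)
  or <- odds_ratios(fit)
  expect_true(all(or$lower <= or$or & or$or <= or$upper))
  expect_true(all(or$or > 0))
  excl1 <- or$lower > 1 | or$upper < 1
  expect_identical(or$significant, excl1)
  expect_match(or$display[1], "^\\d+\\.\\d\\d \\(\\d+\\.\\d\\d, \\d+\\.\\d\\d\\)")
  # a null coefficient's CI straddles 1
  set.seed(7)
  d0 <- logit_data(3000, beta = c(`(Intercept)` = -0.3, x = 0, zyes = 0))
  or0 <- odds_ratios(svylogit(y ~ x, d0))
  expect_true(or0$lower[1] < 1 && or0$upper[1] > 1)
})

test_that("outlier flagging finds a planted contrarian respondent", {
  set.seed(8)
  d <- logit_data(400, beta = c(`(Intercept)` = 0, x = 2, zyes = 0))
  # contrarian: covariate implies near-certain outcome, response refuses,
  # and an extreme weight makes the row consequential
  d$x[1] <- 3.5
  d$y[1] <- 0
  d$weight[1] <- max(d$weight) * 5
  fit <- svylogit(y ~ x, d)
  fl <- flag_outliers(fit, cutoff = 3)
  expect_true(1 %in% fl$row)
  expect_identical(nrow(flag_outliers(fit, cutoff = Inf)), 0L)
})

test_that("a well-fitted null model flags no outliers", {
  set.seed(10)
  d <- logit_data(300, beta = c(`(Intercept)` = 0, x = 0, zyes = 0))
  fit <- svylogit(y ~ 1, d)
  # balanced outcome, no covariates: Pearson residuals are all near +/-1
  expect_identical(nrow(flag_outliers(fit, cutoff = 3)), 0L)
})

test_that("fit methods are coherent: predict, residuals, confint, simulate", {
  set.seed(9)
  d <- logit_data(300)
  fit <- svylogit(y ~ x + z, d)
  expect_equal(predict(fit, type = "response"), fit$fitted.values)
  nd <- data.frame(x = 0, z = factor("no", levels = c("no", "yes")))
  expect_equal(unname(predict(fit, nd, type = "link")),
               unname(coef(fit)["(Intercept)"]))
  expect_equal(residuals(fit, "response"), d$y - fit$fitted.values)
  ci <- confint(fit)
  expect_true(all(ci[, 1] < coef(fit) & coef(fit) < ci[, 2]))
  sims <- simulate(fit, nsim = 3, seed = 1)
  expect_identical(dim(sims), c(300L, 3L))
  expect_true(all(unlist(sims) %in% 0:1))
  s <- summary(fit)
  expect_identical(rownames(s$coefficients), names(coef(fit)))
})

test_that("design-based fit on the synthetic survey recovers true odds ratios", {
  sc <- scenario(seed = 17)
  sim <- simulate_survey(sc)
  tab <- add_derived_columns(sim$tab)
  tab <- drop_missing(tab, c("race_ethnicity", "gender", "pir_category",
                             "education5", "insurance"))
  fit <- svylogit(hav_vaccine ~ race_ethnicity + gender + pir_category +
                    education5 + insurance + age10, tab)
  truth <- sim$truth$coefficients$hav_vaccine
  est <- coef(fit)[names(truth)]
  se <- sqrt(diag(vcov(fit)))[names(truth)]
  # every estimate within 4 design-based SEs of its generating value
  expect_true(all(abs(est - truth) < 4 * se))
})
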