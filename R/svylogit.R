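#' Survey-weighted logistic regression
#'
#' Fits a logistic regression maximizing the sample-weighted Bernoulli
#' log-likelihood by iteratively reweighted least squares, with a
#' design-based (Taylor-linearized sandwich) covariance: per-row score
#' contributions are aggregated to PSU totals and their between-PSU
#' variability within strata, with the `n_h/(n_h - 1)` factor, forms the meat
#' of the sandwich. Inference uses a t reference distribution with
#' `#PSUs - #strata` design degrees of freedom. Coefficients are invariant to
#' a uniform rescaling of the weights, and so is the linearized covariance.
#'
#' Categorical covariates use treatment coding against their declared
#' reference level (set via `relevel()`/factor level order in `data`); the
#' convention of the accompanying analyses is non-Hispanic White for
#' race/ethnicity, male for gender, private for insurance, and the lowest
#' level for ordered covariates.
#'
#' @param formula model formula with a binary (logical or 0/1) response.
#' @param data data frame, or an [analysis_table] (in which case `design`
#'   defaults to its design and `data` to its rows).
#' @param design a [survey_design] naming the weight/strata/PSU columns.
#' @param max_iter maximum IRLS iterations.
#' @param tol relative deviance-change convergence tolerance.
#' @return an object of class `svylogit` with components `coefficients`,
#'   `vcov` (linearized), `df` (design degrees of freedom), `fitted.values`,
#'   `linear.predictors`, `deviance`, `iter`, `converged`, plus the model
#'   frame pieces needed by the methods.
#' @seealso [odds_ratios()], [flag_outliers()], [summary.svylogit()]
#' @export
svylogit <- function(formula, data, design = NULL, max_iter = 25L, tol = 1e-8) {
  if (inherits(data, "analysis_table")) {
    if (is.null(design)) design <- data$design
    data <- data$data
  }
  if (is.null(design)) design <- survey_design()
  stopifnot(inherits(design, "survey_design"))
  mf <- stats::model.frame(formula, data = data, na.action = stats::na.omit)
  drop_idx <- attr(mf, "na.action")
  used <- if (is.null(drop_idx)) seq_len(nrow(data)) else setdiff(seq_len(nrow(data)), drop_idx)
  y <- stats::model.response(mf)
  if (is.logical(y)) y <- as.numeric(y)
  if (is.factor(y)) y <- as.numeric(y) - 1
  if (!all(y %in% c(0, 1))) stop("response must be binary (logical or 0/1)")
  # ordered covariates enter as per-level indicators against the lowest
  # level, not polynomial scores, so each level gets its own odds ratio
  ord <- names(mf)[vapply(mf, is.ordered, TRUE)]
  contr <- if (length(ord))
    stats::setNames(rep(list("contr.treatment"), length(ord)), ord) else NULL
  X <- stats::model.matrix(attr(mf, "terms"), mf, contrasts.arg = contr)
  w <- data[[design$weight]][used]
  strata <- data[[design$strata]][used]
  psu <- data[[design$psu]][used]
  if (anyNA(w) || any(w <= 0)) stop("weights must be positive and complete")
  n <- length(y); p <- ncol(X)
  if (n <= p) stop("more parameters than observations")

  # IRLS on the weighted Bernoulli log-likelihood
  beta <- rep(0, p)
  if ("(Intercept)" %in% colnames(X))
    beta[match("(Intercept)", colnames(X))] <- stats::qlogis(
      min(max(weighted_proportion(y, w), 1e-6), 1 - 1e-6))
  dev_old <- Inf
  converged <- FALSE
  trace <- numeric(0)
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    wk <- w * mu * (1 - mu)
    wk <- pmax(wk, 1e-12)
    z <- eta + (y - mu) / pmax(mu * (1 - mu), 1e-12)
    fit <- stats::lm.wfit(X, z, wk)
    beta <- fit$coefficients
    if (anyNA(beta))
      stop("design matrix is rank deficient: ",
           paste(colnames(X)[is.na(beta)], collapse = ", "))
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    dev <- -2 * sum(w * (y * log(pmax(mu, 1e-300)) +
                         (1 - y) * log(pmax(1 - mu, 1e-300))))
    trace <- c(trace, dev)
    rel <- abs(dev - dev_old) / (abs(dev) + 0.1)
    if (is.finite(rel) && rel < tol) { converged <- TRUE; break }
    dev_old <- dev
  }
  # separation diagnostic: fitted probabilities pinned at 0/1 with a
  # diverging coefficient
  pinned <- mu < 1e-10 | mu > 1 - 1e-10
  if (any(pinned) && max(abs(beta)) > 15) {
    j <- which.max(abs(beta))
    stop("apparent separation: coefficient for '", colnames(X)[j],
         "' diverges with fitted probabilities at 0/1")
  }
  if (!converged)
    stop("IRLS did not converge in ", max_iter,
         " iterations; deviance trace: ",
         paste(signif(utils::head(trace, 10), 6), collapse = ", "))

  # Taylor-linearized sandwich covariance
  info <- crossprod(X, X * (w * mu * (1 - mu)))     # bread: observed information
  scores <- X * (w * (y - mu))                      # per-row score contributions
  g <- interaction(strata, psu, drop = TRUE)
  st <- rowsum(scores, g)                           # PSU score totals
  hs <- tapply(as.character(strata), g, function(s) s[1L])
  hs <- hs[rownames(st)]
  meat <- matrix(0, p, p)
  n_psu <- nrow(st); n_strata <- length(unique(hs))
  for (h in unique(hs)) {
    sh <- st[hs == h, , drop = FALSE]
    nh <- nrow(sh)
    if (nh == 1L) {
      dev_h <- sh - matrix(colMeans(st), 1L, p, byrow = TRUE)
      meat <- meat + crossprod(dev_h)
    } else {
      centered <- sweep(sh, 2L, colMeans(sh))
      meat <- meat + nh / (nh - 1) * crossprod(centered)
    }
  }
  bread <- solve(info)
  V <- bread %*% meat %*% bread
  V <- (V + t(V)) / 2
  df <- n_psu - n_strata
  if (df < 1L) stop("design degrees of freedom (#PSUs - #strata) must be >= 1")

  structure(list(coefficients = stats::setNames(drop(beta), colnames(X)),
                 vcov = structure(V, dimnames = list(colnames(X), colnames(X))),
                 df = df, fitted.values = mu, linear.predictors = eta,
                 deviance = dev, iter = it, converged = converged,
                 y = y, X = X, weights = w, strata = strata, psu = psu,
                 used_rows = used, formula = formula, design = design,
                 terms = attr(mf, "terms"), xlevels = stats::.getXlevels(attr(mf, "terms"), mf),
                 n = n),
            class = "svylogit")
}

#' @export
print.svylogit <- function(x, ...) {
  cat("Survey-weighted logistic regression\n")
  cat("  ", deparse(x$formula), "\n", sep = "")
  cat("  n =", x$n, "; design df =", x$df,
      "; IRLS iterations =", x$iter, "\n")
  cat("Coefficients (log-odds):\n")
  print(round(x$coefficients, 4))
  invisible(x)
}

#' @export
coef.svylogit <- function(object, ...) object$coefficients

#' @export
vcov.svylogit <- function(object, ...) object$vcov

#' @export
confint.svylogit <- function(object, parm, level = 0.95, ...) {
  cf <- object$coefficients
  if (missing(parm)) parm <- names(cf)
  se <- sqrt(diag(object$vcov))[parm]
  tq <- stats::qt(1 - (1 - level) / 2, df = object$df)
  out <- cbind(cf[parm] - tq * se, cf[parm] + tq * se)
  colnames(out) <- paste(format(100 * c((1 - level) / 2, 1 - (1 - level) / 2)), "%")
  out
}

#' @export
summary.svylogit <- function(object, ...) {
  se <- sqrt(diag(object$vcov))
  tval <- object$coefficients / se
  pval <- 2 * stats::pt(-abs(tval), df = object$df)
  tab <- cbind(Estimate = object$coefficients, `Std. Error` = se,
               `t value` = tval, `Pr(>|t|)` = pval)
  structure(list(call_formula = object$formula, coefficients = tab,
                 df = object$df, n = object$n, deviance = object$deviance,
                 iter = object$iter),
            class = "summary.svylogit")
}

#' @export
print.summary.svylogit <- function(x, ...) {
  cat("Survey-weighted logistic regression\n  ",
      deparse(x$call_formula), "\n", sep = "")
  cat("  n =", x$n, "; design df =", x$df, "\n\n")
  stats::printCoefmat(x$coefficients, P.values = TRUE, has.Pvalue = TRUE)
  invisible(x)
}

#' @export
predict.svylogit <- function(object, newdata = NULL,
                             type = c("link", "response"), ...) {
  type <- match.arg(type)
  if (is.null(newdata)) {
    eta <- object$linear.predictors
  } else {
    tt <- stats::delete.response(object$terms)
    mf <- stats::model.frame(tt, newdata, xlev = object$xlevels)
    X <- stats::model.matrix(tt, mf)
    eta <- drop(X %*% object$coefficients)
  }
  if (type == "response") stats::plogis(eta) else eta
}

#' @export
residuals.svylogit <- function(object,
                               type = c("pearson", "response", "working"), ...) {
  type <- match.arg(type)
  mu <- object$fitted.values
  r <- object$y - mu
  switch(type,
         response = r,
         pearson = r / sqrt(mu * (1 - mu)),
         working = r / (mu * (1 - mu)))
}

#' @export
simulate.svylogit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  mu <- object$fitted.values
  out <- as.data.frame(replicate(nsim, stats::rbinom(length(mu), 1L, mu)))
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}

#' Adjusted odds ratios with design-based confidence intervals
#'
#' Exponentiates the non-intercept coefficients of a [svylogit()] fit:
#' `OR = exp(beta)` with 95% bounds `exp(beta +/- t_{df, 0.975} * SE)` and a
#' significance flag at Wald p <= 0.05. Each row compares one covariate level
#' with its reference level, holding the other covariates fixed.
#'
#' @param fit a converged [svylogit()] fit.
#' @param level confidence level (default 0.95).
#' @return data frame with columns `term`, `or`, `lower`, `upper`, `p`,
#'   `significant` and a formatted `display` column in the conventional
#'   "OR (low, high)" layout.
#' @export
odds_ratios <- function(fit, level = 0.95) {
  stopifnot(inherits(fit, "svylogit"), isTRUE(fit$converged))
  cf <- fit$coefficients
  keep <- setdiff(names(cf), "(Intercept)")
  se <- sqrt(diag(fit$vcov))[keep]
  tq <- stats::qt(1 - (1 - level) / 2, df = fit$df)
  est <- cf[keep]
  pval <- 2 * stats::pt(-abs(est / se), df = fit$df)
  out <- data.frame(term = keep,
                    or = exp(est),
                    lower = exp(est - tq * se),
                    upper = exp(est + tq * se),
                    p = pval,
                    significant = pval <= 0.05,
                    row.names = NULL, stringsAsFactors = FALSE)
  out$display <- sprintf("%.2f (%.2f, %.2f)%s", out$or, out$lower, out$upper,
                         ifelse(out$significant, "*", ""))
  out
}

#' Flag extreme outliers of a survey-weighted logistic fit
#'
#' Computes standardized Pearson residuals — `(y - mu)/sqrt(mu(1-mu))`
#' divided by `sqrt(1 - h)` with leverages `h` from the weighted IRLS hat
#' matrix — and flags rows exceeding the cutoff in absolute value. Flagged
#' respondents (e.g. an extreme weight combined with a contrarian outcome)
#' are reported for inspection, never dropped.
#'
#' @param fit a converged [svylogit()] fit.
#' @param cutoff absolute residual threshold (default 3; `Inf` flags nothing).
#' @return data frame with `row` (index into the rows used in the fit),
#'   `residual` and `weight`, ordered by decreasing |residual|.
#' @export
flag_outliers <- function(fit, cutoff = 3) {
  stopifnot(inherits(fit, "svylogit"))
  mu <- fit$fitted.values
  wk <- fit$weights * mu * (1 - mu)
  XW <- fit$X * sqrt(wk)
  qrX <- qr(XW)
  h <- rowSums(qr.Q(qrX)[, seq_len(qrX$rank), drop = FALSE]^2)
  h <- pmin(h, 1 - 1e-8)
  r <- (fit$y - mu) / sqrt(mu * (1 - mu))
  rs <- r / sqrt(1 - h)
  hit <- which(abs(rs) > cutoff)
  out <- data.frame(row = fit$used_rows[hit], residual = rs[hit],
                    weight = fit$weights[hit])
  out[order(-abs(out$residual)), , drop = FALSE]
}

#' Export an odds-ratio table as CSV in the conventional layout
#'
#' @param or a data frame from [odds_ratios()].
#' @param path CSV destination.
#' @return `path`, invisibly.
#' @export
write_or_table <- function(or, path) {
  utils::write.csv(or, path, row.names = FALSE)
  invisible(path)
}
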