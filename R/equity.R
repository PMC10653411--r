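#' Equity classification levels, in severity order
#' @return character vector of the six levels.
#' @export
equity_levels <- function() {
  c("Absent", "Highly Inadequate", "Inadequate", "Adequate",
    "Abundant", "Highly Abundant")
}

#' Log-disparity threshold from a rate rule
#'
#' A rate rule of `tau_rule` (e.g. 0.2 for the 80% rule of disparate-impact
#' practice: a subgroup's rate below 80% of proportionate is adverse) maps to
#' a symmetric threshold on the log-disparity scale: `-log(1 - tau_rule)`.
#'
#' @param tau_rule numeric in `[0, 1)`.
#' @return non-negative threshold on the log scale.
#' @examples
#' threshold_from_rule(0.2)  # -log(0.8) = 0.22314
#' threshold_from_rule(0.4)  # -log(0.6) = 0.51083
#' @export
threshold_from_rule <- function(tau_rule) {
  if (any(is.na(tau_rule)) || any(tau_rule < 0) || any(tau_rule >= 1))
    stop("tau_rule must lie in [0, 1): 1 gives an infinite threshold")
  -log(1 - tau_rule)
}

#' Equity thresholds
#'
#' Bundles the lower and upper rate rules (defaults: 0.2, the 80% rule, and
#' 0.4) with the significance level gating the classification. The derived
#' log-scale thresholds are `tau_l = -log(1 - lower)` and
#' `tau_u = -log(1 - upper)`.
#'
#' @param tau_rule_lower,tau_rule_upper rate rules in `[0, 1)`, lower < upper.
#' @param alpha significance level in (0, 1).
#' @return object of class `equity_thresholds` with fields `tau_l`, `tau_u`,
#'   `alpha`.
#' @export
equity_thresholds <- function(tau_rule_lower = 0.2, tau_rule_upper = 0.4,
                              alpha = 0.05) {
  if (!(tau_rule_lower < tau_rule_upper))
    stop("tau_rule_lower must be smaller than tau_rule_upper")
  if (!(alpha > 0 && alpha < 1)) stop("alpha must lie in (0, 1)")
  structure(list(tau_rule_lower = tau_rule_lower,
                 tau_rule_upper = tau_rule_upper,
                 tau_l = threshold_from_rule(tau_rule_lower),
                 tau_u = threshold_from_rule(tau_rule_upper),
                 alpha = alpha),
            class = "equity_thresholds")
}

#' @export
print.equity_thresholds <- function(x, ...) {
  cat(sprintf("Equity thresholds: tau_l = %.5f (rule %.2f), tau_u = %.5f (rule %.2f), alpha = %g\n",
              x$tau_l, x$tau_rule_lower, x$tau_u, x$tau_rule_upper, x$alpha))
  invisible(x)
}

#' Log Disparity score
#'
#' The natural log of the ratio between the subgroup's odds of appearing
#' among service recipients and its odds in the target population:
#' `log[(p_obs/(1-p_obs)) / (p_tgt/(1-p_tgt))]`. Zero means the subgroup is
#' represented among recipients exactly in proportion to its share of the
#' target population; negative values mean under-representation. An observed
#' share of exactly 0 with a positive target share returns `-Inf`, the
#' sentinel routed to the "Absent" level (no continuity correction is
#' applied).
#'
#' @param observed observed subgroup share among recipients, in `[0, 1)`.
#' @param target target subgroup share, in `(0, 1)` (odds undefined at 0/1).
#' @return numeric score (possibly `-Inf`). Vectorized.
#' @export
log_disparity <- function(observed, target) {
  if (any(!is.na(target) & (target <= 0 | target >= 1)))
    stop("target share must lie strictly inside (0, 1): odds undefined at 0 or 1")
  if (any(!is.na(observed) & (observed < 0 | observed >= 1)))
    stop("observed share must lie in [0, 1)")
  log(observed / (1 - observed)) - log(target / (1 - target))
}

#' Significance test for a subgroup share disparity
#'
#' Two-sided test of the null that the subgroup's share among recipients
#' equals its target share. The default mode is an exact binomial test on
#' design-adjusted counts: successes = observed share times the Kish
#' effective number of recipients (rounded), trials = effective n (rounded),
#' null probability = the estimated target share. The alternative
#' `"normal"` mode compares the two shares with a z statistic using their
#' Taylor-linearized standard errors.
#'
#' @param observed,target [share_estimate]s from [subgroup_shares()].
#' @param method `"exact"` (default) or `"normal"`.
#' @return two-sided p-value.
#' @export
test_disparity <- function(observed, target, method = c("exact", "normal")) {
  method <- match.arg(method)
  stopifnot(inherits(observed, "share_estimate"), inherits(target, "share_estimate"))
  if (observed$undefined) stop("observed share undefined: no recipients")
  p0 <- target$estimate
  if (is.na(p0) || p0 <= 0 || p0 >= 1)
    stop("degenerate target share: cannot test against 0 or 1")
  if (method == "exact") {
    n <- max(1L, round(observed$n_eff))
    k <- round(observed$estimate * n)
    stats::binom.test(k, n, p = p0, alternative = "two.sided")$p.value
  } else {
    se <- sqrt(observed$se^2 + target$se^2)
    if (se == 0) return(1)
    z <- (observed$estimate - p0) / se
    2 * stats::pnorm(-abs(z))
  }
}

#' Classify a log-disparity score into one of six equity levels
#'
#' The classification legend: a score of `-Inf` (subgroup present in the
#' target population but absent among recipients) is **Absent**. A
#' non-significant disparity (p > alpha) is **Adequate** regardless of score.
#' Otherwise the score is graded on half-open intervals:
#' `< -tau_u` Highly Inadequate; `[-tau_u, -tau_l)` Inadequate;
#' `[-tau_l, tau_l)` Adequate; `[tau_l, tau_u)` Abundant; `>= tau_u`
#' Highly Abundant.
#'
#' @param score numeric log-disparity score(s); `-Inf` is the Absent sentinel.
#' @param p p-value(s) from [test_disparity()].
#' @param thresholds an [equity_thresholds].
#' @return factor over [equity_levels()]. Vectorized; `NA` score with `NA` p
#'   gives `NA` (structurally missing cell).
#' @export
classify_equity <- function(score, p, thresholds = equity_thresholds()) {
  stopifnot(inherits(thresholds, "equity_thresholds"))
  n <- max(length(score), length(p))
  score <- rep_len(score, n)
  p <- rep_len(p, n)
  out <- rep(NA_character_, n)
  absent <- !is.na(score) & is.infinite(score) & score < 0
  out[absent] <- "Absent"
  todo <- !absent & !is.na(score) & !is.na(p)
  ns <- todo & p > thresholds$alpha
  out[ns] <- "Adequate"
  sig <- todo & !ns
  s <- score[sig]
  lev <- ifelse(s < -thresholds$tau_u, "Highly Inadequate",
         ifelse(s < -thresholds$tau_l, "Inadequate",
         ifelse(s < thresholds$tau_l, "Adequate",
         ifelse(s < thresholds$tau_u, "Abundant", "Highly Abundant"))))
  out[sig] <- lev
  factor(out, levels = equity_levels())
}

#' Evaluate equity of service utilization across subgroups
#'
#' The package's core analysis. For every level of a sensitive covariate,
#' every outcome, and (optionally) every conditioning stratum, it estimates
#' the subgroup's observed share among service recipients and its target
#' share in the in-need population ([subgroup_shares()]), tests the disparity
#' ([test_disparity()]), scores it ([log_disparity()]) and classifies it
#' ([classify_equity()]).
#'
#' Conditioning restricts both shares to clinically comparable
#' subpopulations (e.g. respondents with similar HbA1c, or an insurance
#' class) so that guideline-driven prescribing differences are not read as
#' inequity. Cells whose subgroup does not occur in the target stratum at all
#' are structurally missing (`NA` level), distinct from "Absent" (present in
#' the target but zero recipients).
#'
#' @param tab an [analysis_table].
#' @param sensitive name of the factor/character column whose levels define
#'   the subgroups.
#' @param outcomes character vector of logical outcome columns (receipt of a
#'   service).
#' @param target optional logical vector (length `nrow`) restricting the
#'   target population (default: all respondents).
#' @param conditioning optional name of a factor column; the evaluation is
#'   repeated within each of its levels.
#' @param thresholds an [equity_thresholds].
#' @param test `"exact"` or `"normal"`, see [test_disparity()].
#' @param p_adjust multiplicity correction across cells, a method name for
#'   [stats::p.adjust()]; default `"none"` (no correction is applied unless
#'   requested).
#' @return an object of class `equity_table`: a data frame of cells with
#'   columns `subgroup`, `conditioning`, `outcome`, `observed`, `target`,
#'   `observed_se`, `target_se`, `n_eff`, `score`, `p`, `level`, plus the
#'   thresholds and call metadata as attributes.
#' @export
equity_eval <- function(tab, sensitive, outcomes,
                        target = NULL, conditioning = NULL,
                        thresholds = equity_thresholds(),
                        test = c("exact", "normal"),
                        p_adjust = "none") {
  stopifnot(inherits(tab, "analysis_table"))
  test <- match.arg(test)
  d <- tab$data
  if (!sensitive %in% names(d)) stop("sensitive covariate '", sensitive, "' not found")
  g <- d[[sensitive]]
  glev <- if (is.factor(g)) levels(droplevels(g)) else sort(unique(stats::na.omit(g)))
  if (is.null(target)) target <- rep(TRUE, nrow(d))
  target <- !is.na(target) & target
  cond_lev <- NA_character_
  if (!is.null(conditioning)) {
    cv <- d[[conditioning]]
    if (is.null(cv)) stop("conditioning column '", conditioning, "' not found")
    cond_lev <- if (is.factor(cv)) levels(droplevels(cv)) else sort(unique(stats::na.omit(cv)))
  }
  rows <- list()
  for (cl in cond_lev) {
    in_cond <- if (is.na(cl)) rep(TRUE, nrow(d)) else !is.na(d[[conditioning]]) & d[[conditioning]] == cl
    tgt_stratum <- target & in_cond
    if (!any(tgt_stratum))
      stop("empty target population in conditioning stratum '", cl, "'")
    for (oc in outcomes) {
      y <- d[[oc]]
      if (is.null(y)) stop("outcome column '", oc, "' not found")
      for (sg in glev) {
        member <- !is.na(g) & g == sg
        if (!any(member & tgt_stratum)) {
          rows[[length(rows) + 1L]] <- data.frame(
            subgroup = sg, conditioning = cl, outcome = oc,
            observed = NA_real_, target = NA_real_,
            observed_se = NA_real_, target_se = NA_real_,
            n_eff = NA_real_, score = NA_real_, p = NA_real_,
            stringsAsFactors = FALSE)
          next
        }
        sh <- subgroup_shares(tab, subgroup = member, recipient = y,
                              target = tgt_stratum)
        if (sh$observed$undefined || sh$target$estimate %in% c(0, 1)) {
          score <- NA_real_; pv <- NA_real_
          obs <- NA_real_; ose <- NA_real_; ne <- NA_real_
        } else {
          obs <- sh$observed$estimate; ose <- sh$observed$se
          ne <- sh$observed$n_eff
          # a subgroup making up all recipients has infinite observed odds
          score <- if (obs >= 1) Inf else log_disparity(obs, sh$target$estimate)
          pv <- test_disparity(sh$observed, sh$target, method = test)
        }
        rows[[length(rows) + 1L]] <- data.frame(
          subgroup = sg, conditioning = cl, outcome = oc,
          observed = obs, target = sh$target$estimate,
          observed_se = ose, target_se = sh$target$se,
          n_eff = ne, score = score, p = pv, stringsAsFactors = FALSE)
      }
    }
  }
  cells <- do.call(rbind, rows)
  if (p_adjust != "none") cells$p <- stats::p.adjust(cells$p, method = p_adjust)
  cells$level <- classify_equity(cells$score, cells$p, thresholds)
  structure(cells,
            class = c("equity_table", "data.frame"),
            thresholds = thresholds, sensitive = sensitive,
            conditioning = conditioning, test = test)
}

#' @export
print.equity_table <- function(x, digits = 3, ...) {
  th <- attr(x, "thresholds")
  cat("Equity evaluation over '", attr(x, "sensitive"), "'",
      if (!is.null(attr(x, "conditioning")))
        paste0(" conditioned on '", attr(x, "conditioning"), "'"),
      " (", nrow(x), " cells)\n", sep = "")
  print(th)
  df <- as.data.frame(x)
  df$observed <- round(df$observed, digits)
  df$target <- round(df$target, digits)
  df$score <- round(df$score, digits)
  df$p <- signif(df$p, 2)
  print(df[, c("subgroup", "conditioning", "outcome", "observed", "target",
               "score", "p", "level")], row.names = FALSE)
  invisible(x)
}

#' @export
summary.equity_table <- function(object, ...) {
  tab <- table(level = object$level, useNA = "ifany")
  cat("Equity level counts across", nrow(object), "cells:\n")
  print(tab)
  inadequate <- object[!is.na(object$level) &
                         object$level %in% c("Absent", "Highly Inadequate", "Inadequate"), ]
  if (nrow(inadequate)) {
    cat("\nCells below adequate:\n")
    print(inadequate[, c("subgroup", "conditioning", "outcome", "score", "p", "level")],
          row.names = FALSE)
  }
  invisible(tab)
}

#' Serialize an equity table
#'
#' @param x an `equity_table`.
#' @param csv_path,json_path destinations (either may be `NULL`).
#' @return invisibly, the paths written.
#' @export
write_equity_table <- function(x, csv_path = NULL, json_path = NULL) {
  stopifnot(inherits(x, "equity_table"))
  df <- as.data.frame(x)
  df$level <- as.character(df$level)
  if (!is.null(csv_path)) utils::write.csv(df, csv_path, row.names = FALSE)
  if (!is.null(json_path)) {
    th <- attr(x, "thresholds")
    jsonlite::write_json(list(thresholds = th[c("tau_l", "tau_u", "alpha")],
                              cells = df),
                         json_path, auto_unbox = TRUE, digits = NA, na = "null")
  }
  invisible(c(csv_path, json_path))
}
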