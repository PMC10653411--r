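#' Survey-weighted proportion
#'
#' The Horvitz-Thompson style ratio `sum(w * x) / sum(w)`. Invariant to a
#' uniform rescaling of the weights.
#'
#' @param x logical or 0/1 numeric indicator per row.
#' @param w positive sample weights.
#' @return a proportion in `[0, 1]`.
#' @export
weighted_proportion <- function(x, w) {
  stopifnot(length(x) == length(w))
  if (anyNA(x) || anyNA(w)) stop("indicator and weights must be complete")
  if (any(w < 0)) stop("weights must be non-negative")
  sw <- sum(w)
  if (sw <= 0) stop("weights sum to zero")
  sum(w * as.numeric(x)) / sw
}

#' Kish effective sample size
#'
#' `(sum w)^2 / sum(w^2)`: the equal-weight sample size with the same variance
#' as the weighted sample. Equals the raw n under equal weights and approaches
#' 1 as a single weight dominates.
#'
#' @param w positive sample weights.
#' @return effective sample size, `0 < n_eff <= length(w)`.
#' @export
kish_effective_n <- function(w) {
  if (!length(w)) stop("weights must be nonempty")
  if (anyNA(w) || any(w <= 0)) stop("weights must be positive and complete")
  sum(w)^2 / sum(w^2)
}

#' Taylor-linearized variance of a weighted ratio estimator
#'
#' Variance of `R = sum(w*num) / sum(w*den)` under a stratified design whose
#' first-stage PSUs are treated as sampled with replacement. Per-row influence
#' values `w * (num - R*den) / sum(w*den)` are aggregated to PSU totals; the
#' between-PSU variance within each stratum (with the `n_h / (n_h - 1)`
#' factor) is summed over strata. A stratum holding a single PSU ("lonely
#' PSU") contributes, under the default rule, its squared deviation from the
#' grand mean of all PSU totals; `lonely = "error"` makes it an error.
#'
#' @param num,den numeric per-row contributions (e.g. indicators).
#' @param w positive sample weights.
#' @param strata,psu design identifiers per row.
#' @param lonely `"center"` (default) or `"error"`.
#' @return estimated variance of the ratio.
#' @export
linearized_ratio_var <- function(num, den, w, strata, psu,
                                 lonely = c("center", "error")) {
  lonely <- match.arg(lonely)
  n <- length(w)
  stopifnot(length(num) == n, length(den) == n,
            length(strata) == n, length(psu) == n)
  X <- sum(w * den)
  if (X <= 0) stop("weighted denominator total must be positive")
  R <- sum(w * num) / X
  z <- w * (num - R * den) / X
  g <- interaction(strata, psu, drop = TRUE)
  zt <- rowsum(z, g)                       # PSU totals of influence values
  hs <- tapply(as.character(strata), g, function(s) s[1L])
  hs <- hs[rownames(zt)]
  v <- 0
  grand <- mean(zt)
  for (h in unique(hs)) {
    zh <- zt[hs == h, 1L]
    nh <- length(zh)
    if (nh == 1L) {
      if (lonely == "error") stop("stratum '", h, "' has a single PSU")
      v <- v + (zh - grand)^2
    } else {
      v <- v + nh / (nh - 1) * sum((zh - mean(zh))^2)
    }
  }
  unname(v)
}

share_estimate <- function(estimate, se, n_eff, wtotal, n, absent = FALSE,
                           undefined = FALSE) {
  structure(list(estimate = estimate, se = se, n_eff = n_eff,
                 wtotal = wtotal, n = n, absent = absent,
                 undefined = undefined),
            class = "share_estimate")
}

#' @export
print.share_estimate <- function(x, ...) {
  if (x$undefined) {
    cat("Share estimate: undefined (no rows in denominator)\n")
  } else {
    cat(sprintf("Share estimate: %.4f (SE %.4f), effective n %.1f of %d\n",
                x$estimate, x$se, x$n_eff, x$n))
    if (x$absent) cat("  subgroup absent among recipients (observed share 0)\n")
  }
  invisible(x)
}

#' Observed and target shares of a subgroup
#'
#' The building block of the equity evaluation. Within the target population
#' (the respondents in need of the service), the *target share* is the
#' weighted proportion belonging to the subgroup; the *observed share* is the
#' weighted proportion belonging to the subgroup among those who actually
#' received the service. Both come with Taylor-linearized standard errors and
#' the Kish effective sample size of their denominators.
#'
#' @param tab an [analysis_table].
#' @param subgroup logical vector (length `nrow`) marking subgroup membership.
#' @param target logical vector marking the target (in-need) population;
#'   default everyone.
#' @param recipient logical vector marking receipt of the service.
#' @return list with `observed` and `target` [share_estimate]s. When the
#'   target population contains no recipients at all, the observed share is
#'   flagged `undefined`; when recipients exist but none belong to the
#'   subgroup, the observed estimate is 0 with `absent = TRUE` (the "Absent"
#'   equity level downstream).
#' @export
subgroup_shares <- function(tab, subgroup, recipient,
                            target = rep(TRUE, nrow(tab$data))) {
  stopifnot(inherits(tab, "analysis_table"))
  d <- tab$data
  w <- d[[tab$design$weight]]
  strata <- d[[tab$design$strata]]
  psu <- d[[tab$design$psu]]
  subgroup <- !is.na(subgroup) & subgroup
  target <- !is.na(target) & target
  recipient <- !is.na(recipient) & recipient
  if (!any(target)) stop("target population is empty")

  one_share <- function(denom) {
    wt <- sum(w[denom])
    est <- weighted_proportion(subgroup[denom], w[denom])
    v <- linearized_ratio_var(num = as.numeric(denom & subgroup),
                              den = as.numeric(denom),
                              w = w, strata = strata, psu = psu)
    share_estimate(est, sqrt(v), kish_effective_n(w[denom]), wt, sum(denom))
  }

  tgt <- one_share(target)
  rec <- target & recipient
  if (!any(rec)) {
    obs <- share_estimate(NA_real_, NA_real_, NA_real_, 0, 0, undefined = TRUE)
  } else {
    obs <- one_share(rec)
    if (obs$estimate == 0 && tgt$estimate > 0) obs$absent <- TRUE
  }
  list(observed = obs, target = tgt)
}
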