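# Survival analysis: five-year labels, Kaplan-Meier curves, log-rank
# tests and univariate Cox proportional-hazards fits (Breslow ties, Wald
# intervals), built on the survival package.

#' Derive five-year overall-survival labels
#'
#' A patient is labelled `alive` when overall survival exceeds 60 months
#' (whatever happens later), `dead` when death is observed at or before 60
#' months. Patients censored at or before 60 months cannot be labelled:
#' their `usable` flag is FALSE and they are excluded from classification,
#' but kept for Kaplan-Meier/Cox analyses which handle censoring directly.
#'
#' @param survival data.frame with sample_id, time_months, event.
#' @param horizon_months classification horizon (default 60).
#' @return data.frame: sample_id, label (factor alive/dead), usable.
#' @export
five_year_label <- function(survival, horizon_months = 60) {
  validate_survival(survival)
  alive <- survival$time_months > horizon_months
  dead <- survival$event == 1L & survival$time_months <= horizon_months
  usable <- alive | dead
  label <- factor(ifelse(alive, "alive", ifelse(dead, "dead", NA)),
                  levels = c("alive", "dead"))
  data.frame(sample_id = survival$sample_id, label = label,
             usable = usable, stringsAsFactors = FALSE)
}

#' Kaplan-Meier survival curve
#'
#' Product-limit estimate truncated at `truncate_months`; at tied times
#' events are processed before censorings (the standard convention).
#'
#' @param times follow-up times in months.
#' @param events event flags (1 = death, 0 = censored).
#' @param truncate_months curve truncation (default 60; `Inf` disables).
#' @return object of class `km_curve`: data.frame with columns `time`,
#'   `n_risk`, `n_event`, `n_censor`, `surv`.
#' @export
km_estimate <- function(times, events, truncate_months = 60) {
  if (length(times) < 1L) stopf("need at least one observation")
  fit <- survival::survfit(survival::Surv(times, events) ~ 1)
  out <- data.frame(time = fit$time, n_risk = fit$n.risk,
                    n_event = fit$n.event, n_censor = fit$n.censor,
                    surv = fit$surv)
  out <- out[out$time <= truncate_months, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("km_curve", "data.frame")
  out
}

#' Two-group log-rank test
#'
#' Standard observed-minus-expected chi-square statistic with
#' hypergeometric variance, 1 degree of freedom.
#'
#' @param times follow-up times in months.
#' @param events event flags (1 = death, 0 = censored).
#' @param group two-level grouping (logical, factor, or two unique values).
#' @return list with `chisq`, `df`, `p_value`, `n_per_group`.
#' @export
logrank <- function(times, events, group) {
  group <- factor(group)
  if (nlevels(group) != 2L || any(table(group) == 0L)) {
    stopf("log-rank test needs exactly two non-empty groups")
  }
  fit <- survival::survdiff(survival::Surv(times, events) ~ group)
  chisq <- unname(fit$chisq)
  list(chisq = chisq, df = 1L,
       p_value = stats::pchisq(chisq, df = 1, lower.tail = FALSE),
       n_per_group = as.vector(table(group)))
}

#' Univariate Cox proportional-hazards fit for a binary risk group
#'
#' Maximizes the partial likelihood for a single 0/1 covariate with the
#' Breslow approximation for ties; reports the hazard ratio with a Wald
#' 95% confidence interval and p-value. When one group has no events the
#' partial likelihood is monotone; the fit is returned with an
#' `infinite` flag and unbounded interval.
#'
#' @param group_indicator high-risk indicator (coercible to 0/1).
#' @param times follow-up times in months.
#' @param events event flags (1 = death, 0 = censored).
#' @return list with `log_hr`, `hr`, `ci_lower`, `ci_upper`, `p_value`,
#'   `n_per_group`, `infinite`.
#' @export
cox_univariate <- function(group_indicator, times, events) {
  g <- as.numeric(as.logical(group_indicator))
  if (anyNA(g) || length(unique(g)) != 2L) {
    stopf("group_indicator must contain both groups")
  }
  ev_per_group <- tapply(events, g, sum)
  if (any(ev_per_group == 0)) {
    infinite <- TRUE
  } else {
    infinite <- FALSE
  }
  fit <- suppressWarnings(
    survival::coxph(survival::Surv(times, events) ~ g, ties = "breslow")
  )
  beta <- unname(stats::coef(fit))
  se <- sqrt(unname(stats::vcov(fit)[1, 1]))
  z <- beta / se
  list(
    log_hr = beta,
    hr = exp(beta),
    ci_lower = if (infinite) 0 else exp(beta - stats::qnorm(0.975) * se),
    ci_upper = if (infinite) Inf else exp(beta + stats::qnorm(0.975) * se),
    p_value = 2 * stats::pnorm(-abs(z)),
    n_per_group = as.vector(table(g)),
    infinite = infinite
  )
}

#' Survival analysis of predicted risk groups
#'
#' Thresholds predicted death probabilities at `cutoff` (high risk =
#' predicted dead), then compares the two risk groups on the full survival
#' data (censored and uncensored) with Kaplan-Meier curves, a log-rank
#' test and a univariate Cox fit.
#'
#' @param scores per-sample predicted death probabilities, named by
#'   sample ID or aligned to `survival`.
#' @param cutoff classification cutoff (default 0.5).
#' @param survival survival data.frame (sample_id, time_months, event).
#' @param truncate_months KM truncation (default 60).
#' @return list with `km_high`, `km_low`, `logrank`, `cox`, `groups`;
#'   `degenerate = TRUE` (with a warning) when a risk group is empty.
#' @export
risk_group_survival <- function(scores, cutoff = 0.5, survival,
                                truncate_months = 60) {
  validate_survival(survival)
  if (!is.null(names(scores))) {
    if (!setequal(names(scores), survival$sample_id)) {
      stopf("score names do not match the survival table")
    }
    scores <- scores[survival$sample_id]
  } else if (length(scores) != nrow(survival)) {
    stopf("scores and survival table have different lengths")
  }
  high <- classify_at(scores, cutoff) == 1L
  if (all(high) || !any(high)) {
    warnf("all samples fall in one risk group; survival comparison is degenerate")
    return(list(degenerate = TRUE, groups = high,
                km_high = NULL, km_low = NULL, logrank = NULL, cox = NULL))
  }
  list(
    degenerate = FALSE,
    groups = high,
    km_high = km_estimate(survival$time_months[high], survival$event[high],
                          truncate_months),
    km_low = km_estimate(survival$time_months[!high], survival$event[!high],
                         truncate_months),
    logrank = logrank(survival$time_months, survival$event, high),
    cox = cox_univariate(high, survival$time_months, survival$event)
  )
}
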