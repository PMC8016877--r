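#' Trapezoid-rule area under a glucose-time curve
#'
#' AUC of an insulin-tolerance-test series by the trapezoid rule:
#' the sum over consecutive time pairs of
#' `(t[i+1] - t[i]) * (v[i] + v[i+1]) / 2`, in mg/dL.min.
#'
#' @param times Sampling times in minutes, strictly increasing.
#' @param values Blood glucose values (mg/dL), same length.
#' @return The AUC (mg/dL.min).
#' @export
trapezoid_auc <- function(times, values) {
  if (length(times) < 2 || length(times) != length(values))
    stop("need >= 2 (time, value) pairs of equal length", call. = FALSE)
  if (is.unsorted(times, strictly = TRUE))
    stop("times must be strictly increasing", call. = FALSE)
  sum(diff(times) * (utils::head(values, -1) + utils::tail(values, -1)) / 2)
}

#' One-way ANOVA across groups
#'
#' Classical fixed-effects one-way ANOVA (delegates to [stats::aov()]),
#' with optional Holm-adjusted pairwise Welch t-tests as the post-hoc
#' analysis.
#'
#' @param values Numeric observations.
#' @param group Group label per observation (>= 2 groups, each with
#'   >= 2 observations).
#' @param posthoc Also compute Holm-adjusted pairwise Welch tests.
#' @return List `F`, `p`, `df`, and when `posthoc` a `pairwise`
#'   data.frame (`group_1`, `group_2`, `p_adj`).
#' @export
oneway_anova <- function(values, group, posthoc = FALSE) {
  group <- factor(group)
  if (nlevels(group) < 2 || any(table(group) < 2))
    stop("need >= 2 groups with >= 2 observations each", call. = FALSE)
  fit <- stats::aov(values ~ group)
  s <- summary(fit)[[1]]
  out <- list(F = s[["F value"]][1], p = s[["Pr(>F)"]][1],
              df = s[["Df"]])
  if (posthoc) {
    pw <- stats::pairwise.t.test(values, group, pool.sd = FALSE,
                                 p.adjust.method = "holm")
    m <- pw$p.value
    idx <- which(!is.na(m), arr.ind = TRUE)
    out$pairwise <- data.frame(group_1 = rownames(m)[idx[, 1]],
                               group_2 = colnames(m)[idx[, 2]],
                               p_adj = m[idx], stringsAsFactors = FALSE)
  }
  out
}

#' Two-way fixed-effects ANOVA (group, time)
#'
#' Standard decomposition with interaction on a balanced complete
#' design, the analysis applied to insulin-tolerance-test series
#' (factors: experimental group and sampling time).
#'
#' @param values Numeric observations.
#' @param group,time Factor levels per observation.
#' @return data.frame with rows `group`, `time`, `group:time` and
#'   columns `df`, `F`, `p`.
#' @export
twoway_anova <- function(values, group, time) {
  group <- factor(group); time <- factor(time)
  tab <- table(group, time)
  if (length(unique(as.vector(tab))) != 1 || any(tab < 2))
    stop("design must be balanced and complete with >= 2 replicates ",
         "per cell", call. = FALSE)
  fit <- stats::aov(values ~ group * time)
  s <- summary(fit)[[1]]
  eff <- trimws(rownames(s))
  keep <- eff != "Residuals"
  # convention for degenerate inputs: an effect with zero sum of
  # squares has F = 0, p = 1 (avoids 0/0 when residuals also vanish)
  Fv <- s[["F value"]][keep]
  pv <- s[["Pr(>F)"]][keep]
  ss_scale <- max(sum(s[["Sum Sq"]]), .Machine$double.xmin)
  zero <- s[["Sum Sq"]][keep] / ss_scale <= 1e-12 |
    sum(abs(values - mean(values))) == 0
  Fv[zero] <- 0; pv[zero] <- 1
  data.frame(effect = eff[keep], df = s[["Df"]][keep],
             F = Fv, p = pv,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Two-group log-rank test on tumor-onset records
#'
#' Standard (O-E)^2/V log-rank statistic with one degree of freedom
#' (delegates to [survival::survdiff()]).
#'
#' @param records data.frame with `time_weeks` (or `time`), `event`
#'   (1 = tumor, 0 = censored) and `group`.
#' @param group_a,group_b Group labels to compare.
#' @return List `chi2`, `p`, `observed`, `expected` (per group).
#' @export
logrank <- function(records, group_a, group_b) {
  time <- records$time_weeks %||% records$time
  keep <- records$group %in% c(group_a, group_b)
  if (!any(records$group == group_a) || !any(records$group == group_b))
    stop("unknown group label", call. = FALSE)
  time <- time[keep]; event <- records$event[keep]
  grp <- factor(records$group[keep], levels = c(group_a, group_b))
  if (sum(event) == 0) stop("no events", call. = FALSE)
  sd <- survival::survdiff(survival::Surv(time, event) ~ grp)
  list(chi2 = sd$chisq,
       p = stats::pchisq(sd$chisq, df = 1, lower.tail = FALSE),
       observed = stats::setNames(sd$obs, levels(grp)),
       expected = stats::setNames(sd$exp, levels(grp)))
}

#' Kaplan-Meier curves of tumor incidence
#'
#' Right-censored Kaplan-Meier estimate per group (via
#' [survival::survfit()]); `incidence = 1 - S(t)` matches
#' incidence-style plots (fraction of animals with tumors).
#'
#' @param records data.frame as in [logrank()].
#' @return data.frame `group`, `time`, `survival`, `incidence`,
#'   `n_risk`, `n_event`.
#' @export
km_curve <- function(records) {
  time <- records$time_weeks %||% records$time
  fit <- survival::survfit(
    survival::Surv(time, records$event) ~ group,
    data = data.frame(time = time, event = records$event,
                      group = records$group))
  grp <- if (is.null(fit$strata)) unique(records$group) else
    sub("^group=", "", rep(names(fit$strata), fit$strata))
  data.frame(group = grp, time = fit$time, survival = fit$surv,
             incidence = 1 - fit$surv, n_risk = fit$n.risk,
             n_event = fit$n.event, stringsAsFactors = FALSE)
}
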