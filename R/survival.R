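# Biomarker-stratified survival analysis: mean+1SD dichotomization,
# Kaplan-Meier estimation and the two-group log-rank test. Estimation is
# delegated to the survival package; this module fixes the stratification
# rule and the result contracts.

#' Dichotomize a cohort at mean plus one standard deviation
#'
#' Labels a sample `"high"` when its biomarker expression strictly exceeds
#' the cohort mean plus one sample standard deviation (n-1 denominator), and
#' `"low"` otherwise. Adding a constant to every value leaves the grouping
#' unchanged. With zero variance every sample is `"low"` and a warning is
#' emitted.
#'
#' @param cohort A [survival_cohort] (>= 2 samples), or a numeric biomarker
#'   vector.
#' @return Character vector of `"high"`/`"low"` labels with attributes
#'   `threshold`, `mean`, `sd` and `group_sizes`.
#' @examples
#' dichotomize_mean_plus_sd(c(0, 0, 0, 10))  # threshold 7.5: one high
#' @export
dichotomize_mean_plus_sd <- function(cohort) {
  x <- if (inherits(cohort, "survival_cohort")) cohort$biomarker
       else as.numeric(cohort)
  if (length(x) < 2L) stop("need >= 2 samples to estimate mean and SD")
  m <- mean(x)
  s <- stats::sd(x)
  if (s == 0) warning("zero biomarker variance: every sample labelled 'low'")
  thr <- m + s
  labels <- ifelse(x > thr, "high", "low")
  structure(labels, threshold = thr, mean = m, sd = s,
            group_sizes = c(high = sum(labels == "high"),
                            low = sum(labels == "low")))
}

#' Kaplan-Meier product-limit survival estimate
#'
#' `S(t) = prod over event times t_i <= t of (1 - d_i / n_i)` with `d_i`
#' events and `n_i` at risk at `t_i`; censored subjects leave the risk set
#' just after their time. With no censoring this equals the empirical
#' survival function.
#'
#' @param time Non-negative follow-up times.
#' @param event 1 = event, 0 = censored.
#' @return A `km_curve` data frame with one row per distinct event time:
#'   `time`, `n_risk`, `n_event`, `survival` (non-increasing, starting from
#'   `S(0) = 1`).
#' @export
km_estimate <- function(time, event) {
  if (length(time) == 0L) stop("empty cohort")
  stopifnot(length(time) == length(event), all(time >= 0),
            all(event %in% c(0, 1)))
  fit <- survival::survfit(survival::Surv(time, event) ~ 1,
                           conf.type = "none")
  keep <- fit$n.event > 0
  structure(data.frame(time = fit$time[keep],
                       n_risk = fit$n.risk[keep],
                       n_event = fit$n.event[keep],
                       survival = fit$surv[keep]),
            class = c("km_curve", "data.frame"), n = length(time))
}

#' Evaluate a Kaplan-Meier curve at arbitrary times
#'
#' Right-continuous step-function evaluation of a [km_estimate()] result.
#'
#' @param curve A `km_curve`.
#' @param t Numeric times.
#' @return `S(t)` for each time.
#' @export
km_survival_at <- function(curve, t) {
  vapply(t, function(tt) {
    i <- which(curve$time <= tt)
    if (length(i) == 0L) 1 else curve$survival[max(i)]
  }, numeric(1L))
}

#' Two-group log-rank test
#'
#' Standard log-rank statistic: at each distinct event time, the expected
#' event count in group 1 is `d * n1 / n` with hypergeometric variance
#' `d (n1/n) (1 - n1/n) (n - d) / (n - 1)`; the chi-square statistic is
#' `(O1 - E1)^2 / sum(V)` on 1 degree of freedom. Tied event times are
#' pooled at a single risk-set update. Estimation is delegated to
#' [survival::survdiff()].
#'
#' @param time,event As in [km_estimate()].
#' @param group Two-level grouping (e.g. the output of
#'   [dichotomize_mean_plus_sd()]); each group needs >= 1 subject and the
#'   cohort >= 1 event overall.
#' @return A `logrank_result`: list with `chi_square`, `df` (1), `p`, and
#'   per-group `observed` and `expected` event counts.
#' @export
logrank_test <- function(time, event, group) {
  stopifnot(length(time) == length(event), length(time) == length(group))
  group <- as.character(group)
  lev <- sort(unique(group))
  if (length(lev) != 2L) stop("log-rank test needs exactly 2 groups, got ",
                              length(lev))
  if (any(table(factor(group, lev)) < 1L)) stop("each group needs >= 1 subject")
  if (sum(event) < 1) stop("no events in the cohort: log-rank test undefined")
  sd <- survival::survdiff(survival::Surv(time, event) ~ g,
                           data = data.frame(time = time, event = event,
                                             g = factor(group, lev)))
  chi <- unname(sd$chisq)
  structure(list(chi_square = chi, df = 1L,
                 p = stats::pchisq(chi, df = 1, lower.tail = FALSE),
                 observed = stats::setNames(unname(sd$obs), lev),
                 expected = stats::setNames(unname(sd$exp), lev)),
            class = "logrank_result")
}

#' @export
print.logrank_result <- function(x, ...) {
  cat(sprintf("<logrank_result> chi-square = %.4f (df = %d), p = %.4g\n",
              x$chi_square, x$df, x$p))
  for (g in names(x$observed)) {
    cat(sprintf("  %s: observed %g, expected %.3f\n",
                g, x$observed[g], x$expected[g]))
  }
  invisible(x)
}

#' Mean+1SD stratified survival analysis
#'
#' The full prognostic workflow: dichotomize the cohort at mean + 1 SD of
#' the biomarker, estimate a Kaplan-Meier curve per group, and compare the
#' groups by log-rank test.
#'
#' @param cohort A [survival_cohort].
#' @return List with `threshold`, `group_sizes`, `groups` (per-sample
#'   labels), `curves` (named list of `km_curve`s) and `logrank`
#'   (`logrank_result`).
#' @export
survival_analysis <- function(cohort) {
  stopifnot(inherits(cohort, "survival_cohort"))
  groups <- dichotomize_mean_plus_sd(cohort)
  sizes <- attr(groups, "group_sizes")
  if (any(sizes == 0L)) {
    stop("dichotomization produced an empty group (",
         paste(names(sizes), sizes, sep = " = ", collapse = ", "),
         "); log-rank comparison impossible")
  }
  curves <- lapply(stats::setNames(c("high", "low"), c("high", "low")),
                   function(g) {
                     km_estimate(cohort$time[groups == g],
                                 cohort$event[groups == g])
                   })
  list(threshold = attr(groups, "threshold"),
       group_sizes = sizes,
       groups = stats::setNames(as.character(groups), cohort$id),
       curves = curves,
       logrank = logrank_test(cohort$time, cohort$event, groups))
}
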