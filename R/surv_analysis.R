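#' Censor survival records at a horizon
#'
#' Only the first `t_max_days` of follow-up are analyzed: any record with a
#' longer time, event or not, becomes a censoring at exactly `t_max_days`.
#' Records at or before the horizon are unchanged (the boundary is
#' inclusive: an event at exactly `t_max_days` stays an event).
#'
#' @param records `data.frame` with `time_days` and logical `event`
#'   (as from [read_clinical()]).
#' @param t_max_days horizon, default 1460 days (4 years).
#' @return The capped records.
#' @export
censor_at_horizon <- function(records, t_max_days = 1460) {
  late <- records$time_days > t_max_days
  records$event[late] <- FALSE
  records$time_days[late] <- t_max_days
  records
}

#' Kaplan-Meier survival curve
#'
#' Product-limit estimate via [survival::survfit()], repackaged as a
#' right-continuous step function starting at S(0) = 1. Tied event times are
#' handled as simultaneous events at one time point.
#'
#' @param records `data.frame` with `time_days` and logical `event`.
#' @return Object of class `survival_curve` with fields `event_times`
#'   (times where S drops or a censoring occurs), `survival_probs` (value of
#'   S from that time onward) and `censor_times`.
#' @export
km_curve <- function(records) {
  if (!nrow(records)) stop("no survival records")
  fit <- survival::survfit(
    survival::Surv(records$time_days, records$event) ~ 1)
  survival_curve(event_times = fit$time, survival_probs = fit$surv,
                 censor_times = fit$time[fit$n.censor > 0])
}

#' Construct a step survival curve
#'
#' @param event_times strictly ascending times at which the curve value
#'   changes (or a censoring occurs).
#' @param survival_probs value of S(t) on `[event_times[i],
#'   event_times[i+1])`; non-increasing, within `[0, 1]`. S is 1 before the
#'   first time.
#' @param censor_times times of censoring marks.
#' @return Object of class `survival_curve`.
#' @export
survival_curve <- function(event_times, survival_probs,
                           censor_times = numeric()) {
  stopifnot(length(event_times) == length(survival_probs),
            !is.unsorted(event_times, strictly = TRUE),
            all(survival_probs >= -1e-12 & survival_probs <= 1 + 1e-12),
            !is.unsorted(rev(survival_probs)))
  structure(list(event_times = as.numeric(event_times),
                 survival_probs = pmin(pmax(survival_probs, 0), 1),
                 censor_times = as.numeric(censor_times)),
            class = "survival_curve")
}

#' Evaluate a step survival curve
#'
#' Right-continuous evaluation: S(t) equals the probability attached to the
#' latest event time at or before `t`, and 1 before any event.
#'
#' @param curve a [survival_curve()].
#' @param t times (vectorized).
#' @return S(t).
#' @export
eval_survival <- function(curve, t) {
  c(1, curve$survival_probs)[findInterval(t, curve$event_times) + 1L]
}

#' Median split of a score vector
#'
#' High group: score strictly above the cohort median; low group: at or
#' below it (ties go low, deterministically).
#'
#' @param scores named numeric vector (names = sample ids).
#' @return list with `high` and `low` name vectors and the `median`.
#' @export
median_split <- function(scores) {
  if (length(scores) < 2) stop("need at least 2 samples to split")
  if (length(unique(scores)) == 1) stop("all scores identical; no split")
  med <- stats::median(scores)
  list(high = names(scores)[scores > med],
       low = names(scores)[scores <= med],
       median = med)
}

#' Median-split log-rank survival test
#'
#' Splits the cohort at the score median, caps follow-up at the horizon,
#' and compares the two groups' survival with the log-rank test (chi-square
#' approximation, via [survival::survdiff()]). Also reports the signed
#' normalized survival-difference integral between the groups' KM curves.
#' Because the split depends only on score ranks, the result is invariant
#' to monotone transformations of the score.
#'
#' @param scores named numeric vector (names = sample ids).
#' @param records clinical `data.frame` with `sample_id`, `time_days`,
#'   `event`.
#' @param t_max_days horizon (default 1460).
#' @param cohort,caller,score_name annotations carried into the result.
#' @return One-row `data.frame`: `cohort`, `caller`, `score_name`,
#'   `logrank_p`, `survival_difference`, `n_high`, `n_low`.
#' @export
logrank_median_split <- function(scores, records, t_max_days = 1460,
                                 cohort = NA_character_,
                                 caller = NA_character_,
                                 score_name = "math") {
  shared <- intersect(names(scores), records$sample_id)
  if (length(shared) < 2) stop("scores and records share too few samples")
  scores <- scores[shared]
  rec <- records[match(shared, records$sample_id), , drop = FALSE]
  rec <- censor_at_horizon(rec, t_max_days)
  sp <- median_split(scores)
  if (!length(sp$high) || !length(sp$low))
    stop("median split left a group empty")
  grp <- ifelse(shared %in% sp$high, "high", "low")
  sd_fit <- survival::survdiff(
    survival::Surv(rec$time_days, rec$event) ~ grp)
  p <- stats::pchisq(sd_fit$chisq, df = 1, lower.tail = FALSE)
  sdiff <- survival_difference(
    km_curve(rec[grp == "high", , drop = FALSE]),
    km_curve(rec[grp == "low", , drop = FALSE]),
    t_max_days)
  data.frame(cohort = cohort, caller = caller, score_name = score_name,
             logrank_p = p, survival_difference = sdiff,
             n_high = length(sp$high), n_low = length(sp$low),
             stringsAsFactors = FALSE)
}

#' Signed normalized survival difference
#'
#' `(1 / T_max) * integral_0^T_max [S_high(t) - S_low(t)] dt`, computed
#' exactly by decomposing `[0, T_max]` at the union of both curves' step
#' times (no quadrature). Lies in `[-1, 1]`; negative when the high-score
#' group has worse survival, positive when it has better survival, and
#' antisymmetric under swapping the groups.
#'
#' @param s_high,s_low [survival_curve()] objects.
#' @param t_max_days integration horizon (positive).
#' @return Value in `[-1, 1]`.
#' @export
survival_difference <- function(s_high, s_low, t_max_days = 1460) {
  if (t_max_days <= 0) stop("t_max_days must be positive")
  cuts <- sort(unique(c(0, s_high$event_times, s_low$event_times,
                        t_max_days)))
  cuts <- cuts[cuts >= 0 & cuts <= t_max_days]
  if (cuts[length(cuts)] < t_max_days) cuts <- c(cuts, t_max_days)
  left <- cuts[-length(cuts)]
  widths <- diff(cuts)
  diffs <- eval_survival(s_high, left) - eval_survival(s_low, left)
  sum(diffs * widths) / t_max_days
}

#' Benjamini-Hochberg significance flags
#'
#' Standard BH step-up at level `alpha`, applied jointly across the
#' supplied grid of tests (all cohorts and callers of one score type at a
#' time).
#'
#' @param pvals numeric p-values in `[0, 1]`.
#' @param alpha FDR level (default 0.05).
#' @return Logical vector of significance flags (empty input gives empty
#'   output).
#' @export
bh_correct <- function(pvals, alpha = 0.05) {
  if (!length(pvals)) return(logical())
  stopifnot(all(pvals >= 0 & pvals <= 1))
  stats::p.adjust(pvals, method = "BH") <= alpha
}
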