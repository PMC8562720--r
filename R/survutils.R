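#' Kaplan-Meier survival estimate per group
#'
#' Product-limit estimator of the survival function within each group,
#' computed with [survival::survfit()]. The estimate starts at S(0) = 1,
#' is nonincreasing, and drops only at event times.
#'
#' @param survival data.frame with `sample_id`, `time`, `event`.
#' @param groups group label per sample: either a named vector (names =
#'   sample IDs) or a vector aligned with the rows of `survival`.
#' @return data.frame with columns `group`, `time`, `n_risk`, `n_event`,
#'   `n_censor`, `estimate` (one row per distinct follow-up time per
#'   group).
#' @export
km_estimate <- function(survival, groups) {
  g <- resolve_groups(survival, groups)
  if (any(table(g) == 0L)) {
    stop("km_estimate: empty group", call. = FALSE)
  }
  fit <- survival::survfit(
    survival::Surv(survival$time, survival$event) ~ g)
  strata <- if (is.null(fit$strata)) {
    rep(as.character(unique(g)), length(fit$time))
  } else {
    rep(sub("^g=", "", names(fit$strata)), fit$strata)
  }
  data.frame(
    group = strata,
    time = fit$time,
    n_risk = fit$n.risk,
    n_event = fit$n.event,
    n_censor = fit$n.censor,
    estimate = fit$surv,
    stringsAsFactors = FALSE
  )
}

resolve_groups <- function(survival, groups) {
  if (!is.null(names(groups))) {
    idx <- match(survival$sample_id, names(groups))
    if (anyNA(idx)) {
      stop("group labels missing for sample(s): ",
           paste(utils::head(survival$sample_id[is.na(idx)], 5),
                 collapse = ", "), call. = FALSE)
    }
    groups <- groups[idx]
  }
  if (length(groups) != nrow(survival)) {
    stop("group labels must cover every survival record", call. = FALSE)
  }
  as.character(groups)
}

#' Two-group log-rank test
#'
#' Standard log-rank comparison of two survival distributions via
#' [survival::survdiff()]; p-value from the chi-square distribution with
#' one degree of freedom.
#'
#' @inheritParams km_estimate
#' @return list with `statistic` (chi-square) and `p_value`.
#' @export
logrank_test <- function(survival, groups) {
  g <- resolve_groups(survival, groups)
  if (length(unique(g)) != 2L) {
    stop("logrank_test: exactly two nonempty groups required",
         call. = FALSE)
  }
  if (sum(survival$event) < 1L) {
    stop("logrank_test: no events; statistic undefined", call. = FALSE)
  }
  sd <- survival::survdiff(
    survival::Surv(survival$time, survival$event) ~ g)
  list(statistic = unname(sd$chisq),
       p_value = stats::pchisq(sd$chisq, df = 1L, lower.tail = FALSE))
}

#' AUC for survival status at a fixed horizon
#'
#' Nonparametric discrimination of a risk score for death by time `t`:
#' cases are patients who died at or before the horizon, controls are
#' patients followed beyond it; patients censored before the horizon are
#' excluded. The AUC is the Mann-Whitney concordance probability of the
#' score between cases and controls, ties counted one half.
#'
#' @param scores named numeric vector of risk scores.
#' @param survival data.frame with `sample_id`, `time`, `event`.
#' @param horizon the time horizon `t` (> 0).
#' @return list with `auc`, `n_cases`, `n_controls`, `n_excluded`.
#' @export
survival_auc_at <- function(scores, survival, horizon) {
  if (!is.numeric(horizon) || length(horizon) != 1L || horizon <= 0) {
    stop("survival_auc_at: horizon must be a single positive time",
         call. = FALSE)
  }
  surv <- align_survival(survival,
                         if (is.null(names(scores))) survival$sample_id
                         else names(scores))
  s <- unname(scores)
  case <- surv$event == 1 & surv$time <= horizon
  control <- surv$time > horizon
  excluded <- !(case | control)
  n1 <- sum(case); n0 <- sum(control)
  if (n1 == 0L || n0 == 0L) {
    stop("survival_auc_at: a class is empty after exclusions at horizon ",
         horizon, call. = FALSE)
  }
  r <- rank(c(s[case], s[control]))
  auc <- (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  list(auc = auc, n_cases = n1, n_controls = n0, n_excluded = sum(excluded))
}
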