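#' Kaplan-Meier estimate of overall survival
#'
#' Product-limit estimator with Greenwood standard errors, computed by
#' the survival package.
#'
#' @param records Data.frame with `time_months` (> 0) and `event`
#'   (0/1 death indicator).
#' @return Data.frame with `time`, `n_risk`, `n_event`, `surv`,
#'   `std_err` (Greenwood SE of the survival probability), `lower`,
#'   `upper`; survival starts at 1 and is non-increasing.
#' @export
km_estimate <- function(records) {
  check_survival(records)
  fit <- survival::survfit(
    survival::Surv(time_months, event) ~ 1, data = records,
    conf.type = "log")
  data.frame(time = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
             surv = fit$surv, std_err = fit$std.err * fit$surv,
             lower = fit$lower, upper = fit$upper)
}

check_survival <- function(records) {
  stopifnot(all(c("time_months", "event") %in% names(records)),
            nrow(records) >= 1L)
  if (any(records$time_months <= 0)) stop("non-positive survival time")
  if (!all(records$event %in% c(0, 1))) stop("event must be 0/1")
  invisible(TRUE)
}

#' Log-rank test between two survival groups
#'
#' @param records Data.frame with `time_months` and `event`.
#' @param group Vector of two group labels, parallel to `records`.
#' @return List with `statistic` (chi-square, 1 df) and `p`.
#' @export
logrank_test <- function(records, group) {
  check_survival(records)
  if (length(unique(group)) != 2L) stop("log-rank needs exactly 2 groups")
  if (sum(records$event) < 1L) stop("log-rank needs at least one event")
  d <- cbind(records, .grp = group)
  sd <- survival::survdiff(survival::Surv(time_months, event) ~ .grp,
                           data = d)
  list(statistic = unname(sd$chisq),
       p = stats::pchisq(sd$chisq, df = 1, lower.tail = FALSE))
}

#' Cox proportional-hazards fit
#'
#' Partial-likelihood maximization with Efron handling of tied event
#' times (the default of modern survival software; Breslow is exposed
#' for compatibility with older packages). Returns per-covariate hazard
#' ratios with Wald confidence intervals and p-values.
#'
#' @param records Data.frame with `time_months`, `event` and the
#'   covariate columns.
#' @param covariates Character vector of covariate column names.
#' @param ties `"efron"` or `"breslow"`.
#' @return Data.frame with `term`, `coef` (log HR), `hr`, `se`,
#'   `lower`, `upper` (95% CI on the HR), `p`.
#' @export
cox_fit <- function(records, covariates, ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  check_survival(records)
  if (sum(records$event) < 1L) stop("Cox fit needs at least one event")
  for (cv in covariates) {
    v <- records[[cv]]
    if (is.null(v)) stop("unknown covariate: ", cv)
    if (length(unique(v[!is.na(v)])) < 2L) {
      stop("constant covariate: ", cv)
    }
  }
  fml <- stats::as.formula(paste(
    "survival::Surv(time_months, event) ~",
    paste(covariates, collapse = " + ")))
  fit <- tryCatch(
    survival::coxph(fml, data = records, ties = ties,
                    control = survival::coxph.control(iter.max = 100)),
    warning = function(w) {
      if (grepl("infinite|did not converge|beta may be infinite",
                conditionMessage(w))) {
        warning("possible complete separation; estimates flagged",
                call. = FALSE)
        suppressWarnings(survival::coxph(fml, data = records, ties = ties,
                                         control = survival::coxph.control(
                                           iter.max = 100)))
      } else {
        warning(w); suppressWarnings(
          survival::coxph(fml, data = records, ties = ties,
                          control = survival::coxph.control(iter.max = 100)))
      }
    })
  s <- summary(fit)
  co <- s$coefficients
  data.frame(term = rownames(co), coef = co[, "coef"],
             hr = exp(co[, "coef"]), se = co[, "se(coef)"],
             lower = exp(co[, "coef"] - 1.96 * co[, "se(coef)"]),
             upper = exp(co[, "coef"] + 1.96 * co[, "se(coef)"]),
             p = co[, "Pr(>|z|)"], row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Univariate and multivariate survival report
#'
#' For each molecular feature, fits a univariate Cox model and a
#' multivariate model adjusted for stage (ordinal I-IV), histological
#' variant and gender, reporting HR, 95% CI and p per model — the
#' layout of an overall-survival association table.
#'
#' @param samples Sample sheet with `time_months`, `event`, `stage`,
#'   `histology`, `gender` and the logical feature columns.
#' @param features Feature column names to test.
#' @return Data.frame with one row per feature and model.
#' @export
survival_report <- function(samples,
                            features = c("thyt1_positive",
                                         "chr1q_dup", "tert_dup",
                                         "tert_mut")) {
  samples$stage_ord <- as.numeric(samples$stage)
  samples$histology <- factor(samples$histology)
  samples$gender <- factor(samples$gender)
  rows <- lapply(features, function(f) {
    samples$.feat <- as.numeric(samples[[f]])
    uni <- tryCatch(cox_fit(samples, ".feat"), error = function(e) NULL)
    multi <- tryCatch(
      cox_fit(samples, c(".feat", "stage_ord", "histology", "gender")),
      error = function(e) NULL)
    pick <- function(fit, model) {
      if (is.null(fit)) {
        return(data.frame(feature = f, model = model, hr = NA_real_,
                          lower = NA_real_, upper = NA_real_, p = NA_real_,
                          stringsAsFactors = FALSE))
      }
      r <- fit[fit$term == ".feat", ]
      data.frame(feature = f, model = model, hr = r$hr, lower = r$lower,
                 upper = r$upper, p = r$p, stringsAsFactors = FALSE)
    }
    rbind(pick(uni, "univariate"), pick(multi, "multivariate"))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
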