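#' Confusion-matrix metrics for binary recurrence predictions
#'
#' The positive class is recurrence. Significance of the accuracy is the
#' one-sided exact binomial probability of at least as many correct calls
#' under chance (p = 1/2).
#'
#' @param predictions 0/1 vector of predicted recurrence.
#' @param truth 0/1 vector of observed recurrence.
#' @return list of class `mirvote_confusion`: `TP`, `FN`, `TN`, `FP`,
#'   `accuracy`, `sensitivity`, `specificity`, `binomial_p`.
#' @export
confusion_metrics <- function(predictions, truth) {
  if (!length(predictions)) stop("empty predictions")
  if (length(predictions) != length(truth))
    stop("predictions and truth must align")
  predictions <- as.integer(predictions); truth <- as.integer(truth)
  if (!all(predictions %in% 0:1) || !all(truth %in% 0:1))
    stop("predictions and truth must be binary")
  TP <- sum(predictions == 1 & truth == 1)
  FN <- sum(predictions == 0 & truth == 1)
  TN <- sum(predictions == 0 & truth == 0)
  FP <- sum(predictions == 1 & truth == 0)
  n <- TP + FN + TN + FP
  correct <- TP + TN
  structure(list(
    TP = TP, FN = FN, TN = TN, FP = FP,
    accuracy = correct / n,
    sensitivity = if (TP + FN > 0) TP / (TP + FN) else NA_real_,
    specificity = if (TN + FP > 0) TN / (TN + FP) else NA_real_,
    binomial_p = pbinom(correct - 1, n, 0.5, lower.tail = FALSE)),
    class = "mirvote_confusion")
}

#' @export
print.mirvote_confusion <- function(x, ...) {
  cat(sprintf(
    "accuracy %.3f (sens %.3f, spec %.3f), n = %d, binomial p = %.3g\n",
    x$accuracy, x$sensitivity, x$specificity, x$TP + x$FN + x$TN + x$FP,
    x$binomial_p))
  invisible(x)
}

#' One-tailed Fisher's exact test for risk-group enrichment
#'
#' Tests whether non-recurrent patients are over-represented in a risk
#' group. The 2x2 table is laid out as
#' `[[a = no-recurrence in group, b = recurrence in group], [c, d =
#' remainder]]`; the p-value is the hypergeometric upper-tail probability
#' of drawing at least `a` non-recurrent patients into a group of size
#' `a + b`, margins fixed.
#'
#' @param a,b,c,d nonnegative integer cell counts.
#' @return the one-tailed p-value.
#' @export
fisher_exact_one_tailed <- function(a, b, c, d) {
  cnt <- c(a, b, c, d)
  if (any(cnt < 0) || any(cnt != round(cnt)))
    stop("cell counts must be nonnegative integers")
  # white balls: all non-recurrent (a + c); draws: group size (a + b)
  phyper(a - 1, a + c, b + d, a + b, lower.tail = FALSE)
}

#' Kaplan-Meier curves per risk group
#'
#' Product-limit estimates per group, with steps at event times only.
#' Computed through the survival package; the test suite cross-checks the
#' values against a hand-rolled product-limit oracle.
#'
#' @param time_months positive follow-up/event times.
#' @param event 0/1 event flags.
#' @param group group labels (e.g. risk groups); empty groups are dropped
#'   with a warning.
#' @return named list, one data.frame per group: `time`, `n_risk`,
#'   `n_event`, `surv`.
#' @export
km_curve <- function(time_months, event, group) {
  if (any(time_months <= 0)) stop("times must be positive")
  if (!all(event %in% 0:1)) stop("event flags must be 0/1")
  levels_all <- if (is.factor(group)) levels(group) else unique(as.character(group))
  group <- as.character(group)
  present <- unique(group)
  empty <- setdiff(levels_all, present)
  if (length(empty))
    warning("omitting empty group(s): ", paste(empty, collapse = ", "))
  out <- lapply(present, function(g) {
    i <- group == g
    fit <- survival::survfit(survival::Surv(time_months[i], event[i]) ~ 1)
    s <- summary(fit, censored = FALSE)  # steps at event times only
    data.frame(time = s$time, n_risk = s$n.risk, n_event = s$n.event,
               surv = s$surv, row.names = NULL)
  })
  setNames(out, present)
}

#' Cox proportional-hazards ratio between two groups
#'
#' Fits a proportional-hazards model with a single binary covariate and
#' reports the hazard ratio with its Wald 95% confidence interval and
#' p-value. When every event falls in one group the partial likelihood is
#' monotone and no finite HR exists — the situation an ultralow-risk group
#' with zero recurrences produces — so the result is flagged and the CI
#' reported as unbounded instead of raising an error.
#'
#' @param time_months positive times.
#' @param event 0/1 event flags (at least one event).
#' @param group binary indicator (1 = the higher-risk group).
#' @return list of class `mirvote_hr`: `HR`, `CI_low`, `CI_high`, `p`,
#'   `monotone` (TRUE when the likelihood is monotone).
#' @export
cox_hazard_ratio <- function(time_months, event, group) {
  group <- as.integer(group)
  if (length(unique(group)) < 2) stop("both groups must be non-empty")
  if (sum(event) == 0) stop("no events; hazard ratio undefined")
  ev_by_group <- tapply(event, group, sum)
  if (any(ev_by_group == 0)) {
    # all events in one arm: monotone likelihood, no finite estimate
    return(structure(list(HR = if (ev_by_group["1"] > 0) Inf else 0,
                          CI_low = NA_real_, CI_high = NA_real_,
                          p = NA_real_, monotone = TRUE),
                     class = "mirvote_hr"))
  }
  fit <- survival::coxph(survival::Surv(time_months, event) ~ group)
  beta <- unname(coef(fit)[1])
  se <- sqrt(fit$var[1, 1])
  structure(list(HR = exp(beta),
                 CI_low = exp(beta - qnorm(0.975) * se),
                 CI_high = exp(beta + qnorm(0.975) * se),
                 p = 2 * pnorm(-abs(beta / se)),
                 monotone = FALSE),
            class = "mirvote_hr")
}

#' @export
print.mirvote_hr <- function(x, ...) {
  if (x$monotone) {
    cat("HR not estimable: all events in one group (monotone likelihood)\n")
  } else {
    cat(sprintf("HR %.2f (95%% CI %.2f-%.2f), p = %.3g\n",
                x$HR, x$CI_low, x$CI_high, x$p))
  }
  invisible(x)
}

#' Multivariable logistic independence check
#'
#' Regresses risk-group membership on the classical clinical markers to
#' verify that the expression-based votes are not a proxy for them.
#' Covariate coding: ER positive vs negative (`na` excluded), age
#' dichotomized at > 50 years, tumor size at >= 20 mm, grade at >= 2, plus
#' the outcome itself. A covariate that perfectly predicts membership
#' (e.g. outcome for an ultralow group with zero recurrences) makes the
#' fit separable; its row is reported `n/a` and the model refit without
#' it.
#'
#' @param membership 0/1 risk-group membership per patient.
#' @param clinical clinical data.frame (see [validate_clinical()]),
#'   aligned with `membership`.
#' @param age_cut,size_cut,grade_cut dichotomization cutpoints (defaults
#'   50 years, 20 mm, grade 2).
#' @return data.frame of class `mirvote_independence`: one row per
#'   covariate with `OR`, `CI_low`, `CI_high`, `p`; separable covariates
#'   carry `NA` and `excluded = TRUE`.
#' @export
logistic_independence <- function(membership, clinical, age_cut = 50,
                                  size_cut = 20, grade_cut = 2) {
  if (length(membership) != nrow(clinical))
    stop("membership and clinical must align")
  if (sum(!is.na(membership)) < 20)
    stop("need at least 20 samples for the independence model")
  df <- data.frame(
    member = as.integer(membership),
    er = ifelse(clinical$er_status == "na", NA,
                as.integer(clinical$er_status == "pos")),
    age = as.integer(clinical$age_years > age_cut),
    size = as.integer(clinical$tumor_size_mm >= size_cut),
    grade = as.integer(suppressWarnings(as.numeric(clinical$grade)) >=
                         grade_cut),
    outcome = as.integer(clinical$event))
  df <- df[complete.cases(df), ]
  covars <- c(er = "ER status", age = "Age", size = "Tumor size",
              grade = "Tumor grade", outcome = "Outcome")
  # quasi-complete separation screen: an empty cell of covariate x
  # membership means the logistic estimate diverges
  separable <- vapply(names(covars), function(v) {
    any(table(factor(df[[v]], 0:1), factor(df$member, 0:1)) == 0)
  }, logical(1))
  keep <- names(covars)[!separable]
  est <- matrix(NA_real_, length(covars), 4,
                dimnames = list(names(covars), c("OR", "CI_low", "CI_high", "p")))
  if (length(keep)) {
    fml <- as.formula(paste("member ~", paste(keep, collapse = " + ")))
    fit <- glm(fml, family = binomial(), data = df)
    sm <- summary(fit)$coefficients
    for (v in keep) {
      b <- sm[v, "Estimate"]; se <- sm[v, "Std. Error"]
      est[v, ] <- c(exp(b), exp(b - qnorm(0.975) * se),
                    exp(b + qnorm(0.975) * se), sm[v, "Pr(>|z|)"])
    }
  }
  out <- data.frame(covariate = unname(covars), est,
                    excluded = separable, row.names = NULL)
  class(out) <- c("mirvote_independence", "data.frame")
  out
}

#' Write the evaluation report bundle for a CV run
#'
#' Produces `metrics.tsv` (per-method confusion metrics), `fisher.tsv`
#' (2x2 counts and one-tailed Fisher p per risk group), one
#' `km_<group>.tsv` per risk group, `independence.tsv`, and a plain-text
#' `summary.txt`. Regenerating the report from the same fit is
#' byte-identical.
#'
#' @param fit a `mirvote` fit.
#' @param risk_groups a `mirvote_risk` from [assign_risk_groups()].
#' @param clinical clinical data.frame for the same samples.
#' @param dir output directory (created if needed).
#' @return character vector of the files written, invisibly.
#' @export
build_report <- function(fit, risk_groups, clinical, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cl <- clinical[match(fit$votes$sample_id, clinical$sample_id), ]
  truth <- cl$event
  files <- character(0)

  sm <- summary(fit)
  f <- file.path(dir, "metrics.tsv")
  write.table(sm$per_method, f, sep = "\t", quote = FALSE, row.names = FALSE)
  files <- c(files, f)

  rg <- risk_groups$risk_group[match(fit$votes$sample_id,
                                     risk_groups$sample_id)]
  fisher <- do.call(rbind, lapply(c("ultralow", "low"), function(g) {
    ing <- if (g == "ultralow") rg == "ultralow" else rg %in% c("ultralow", "low")
    a <- sum(ing & truth == 0); b <- sum(ing & truth == 1)
    c_ <- sum(!ing & truth == 0); d <- sum(!ing & truth == 1)
    data.frame(group = g, no_rec_in_group = a, rec_in_group = b,
               no_rec_rest = c_, rec_rest = d,
               p_one_tailed = fisher_exact_one_tailed(a, b, c_, d))
  }))
  f <- file.path(dir, "fisher.tsv")
  write.table(fisher, f, sep = "\t", quote = FALSE, row.names = FALSE)
  files <- c(files, f)

  km <- km_curve(cl$time_months, truth, as.character(rg))
  for (g in names(km)) {
    f <- file.path(dir, paste0("km_", g, ".tsv"))
    write.table(km[[g]], f, sep = "\t", quote = FALSE, row.names = FALSE)
    files <- c(files, f)
  }

  indep <- logistic_independence(as.integer(rg == "ultralow"), cl)
  f <- file.path(dir, "independence.tsv")
  write.table(indep, f, sep = "\t", quote = FALSE, row.names = FALSE)
  files <- c(files, f)

  f <- file.path(dir, "summary.txt")
  con <- file(f, "w")
  sink(con); on.exit({ sink(); close(con) })
  cat("mirvote evaluation report\n=========================\n\n")
  print(fit); cat("\n"); print(sm); cat("\nFisher enrichment (one-tailed):\n")
  print(fisher, row.names = FALSE)
  sink(); close(con); on.exit()
  files <- c(files, f)
  invisible(files)
}
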