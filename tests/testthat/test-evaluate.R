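test_that("confusion metrics reproduce the printed RF triple and edge cases", {
  truth <- c(rep(1, 80), rep(0, 80))
  pred <- c(rep(1, 67), rep(0, 13), rep(0, 70), rep(1, 10))
  cm <- confusion_metrics(pred, truth)
  expect_equal(c(cm$TP, cm$FN, cm$TN, cm$FP), c(67, 13, 70, 10))
  expect_equal(cm$accuracy, 0.85625)   # rounds to the 86% triple
  expect_equal(cm$sensitivity, 0.8375)
  expect_equal(cm$specificity, 0.875)

  cm3 <- confusion_metrics(c(1, 0, 1), c(1, 0, 1))
  expect_equal(cm3$accuracy, 1)
  expect_equal(cm3$binomial_p, 0.125)  # (1/2)^3 exactly

  deg <- confusion_metrics(rep(1, 10), c(rep(1, 4), rep(0, 6)))
  expect_equal(deg$sensitivity, 1)
  expect_equal(deg$specificity, 0)

  expect_error(confusion_metrics(integer(0), integer(0)), "empty")
  # binomial identity p(k = n) = 2^-n
  for (n in c(5, 12)) {
    expect_equal(confusion_metrics(rep(1, n), rep(1, n))$binomial_p, 2^-n,
                 tolerance = 1e-12)
  }
})

test_that("one-tailed Fisher equals exhaustive enumeration and fisher.test", {
  set.seed(13)
  for (i in 1:40) {
    tab <- as.vector(rmultinom(1, sample(8:24, 1), rep(0.25, 4)))
    p <- fisher_exact_one_tailed(tab[1], tab[2], tab[3], tab[4])
    expect_equal(p, fisher_brute(tab[1], tab[2], tab[3], tab[4]),
                 tolerance = 1e-12)
    ft <- fisher.test(matrix(tab, 2, byrow = TRUE), alternative = "greater")
    expect_equal(p, ft$p.value, tolerance = 1e-10)
  }
  # a = 0 with b = group size: the whole upper tail
  expect_equal(fisher_exact_one_tailed(0, 5, 6, 1),
               fisher_brute(0, 5, 6, 1), tolerance = 1e-12)
  expect_error(fisher_exact_one_tailed(-1, 2, 3, 4), "nonnegative")
})

test_that("KM curves are the product-limit estimator", {
  # no events: S(t) = 1, no steps
  km <- km_curve(c(5, 10, 15), c(0, 0, 0), rep("g", 3))
  expect_equal(nrow(km$g), 0)

  # all events at (1, 2, 3): S = 2/3, 1/3, 0
  km <- km_curve(c(1, 2, 3), c(1, 1, 1), rep("g", 3))
  expect_equal(km$g$surv, c(2 / 3, 1 / 3, 0), tolerance = 1e-12)
  expect_equal(km$g$time, c(1, 2, 3))

  # censoring between events, against the hand product-limit
  km <- km_curve(c(1, 1.5, 2), c(1, 0, 1), rep("g", 3))
  oracle <- km_brute(c(1, 1.5, 2), c(1, 0, 1))
  expect_equal(km$g$surv, oracle$surv, tolerance = 1e-12)
  expect_equal(km$g$surv, c(2 / 3, 0), tolerance = 1e-12)

  # no censoring: KM equals the empirical survival function
  set.seed(5)
  t <- sample(1:50, 30, replace = TRUE)
  km <- km_curve(t, rep(1, 30), rep("g", 30))
  expect_equal(km$g$surv, vapply(km$g$time, function(u) mean(t > u),
                                 numeric(1)), tolerance = 1e-12)

  expect_warning(km_curve(c(1, 2), c(1, 1), factor(c("a", "a"), c("a", "b"))),
                 "empty group")
  expect_error(km_curve(c(-1, 2), c(1, 1), c("a", "a")), "positive")
})

test_that("Cox hazard ratios: null, monotone-likelihood flag", {
  set.seed(8)
  n <- 100
  t <- rexp(2 * n, 0.02)
  grp <- rep(0:1, each = n)
  hr <- cox_hazard_ratio(t, rep(1, 2 * n), grp)
  expect_false(hr$monotone)
  expect_lt(abs(log(hr$HR)), 0.5)
  expect_true(hr$CI_low < 1 && hr$CI_high > 1)
  expect_true(hr$CI_low < hr$HR && hr$HR < hr$CI_high)

  # all events in one group: flagged, no finite estimate (the ultralow case)
  hr2 <- cox_hazard_ratio(c(10, 20, 30, 200, 220, 240),
                          c(1, 1, 1, 0, 0, 0), c(1, 1, 1, 0, 0, 0))
  expect_true(hr2$monotone)
  expect_true(is.infinite(hr2$HR))
  expect_true(is.na(hr2$CI_low))

  expect_error(cox_hazard_ratio(c(1, 2), c(0, 0), c(0, 1)), "no events")
  expect_error(cox_hazard_ratio(c(1, 2), c(1, 1), c(1, 1)), "non-empty")
})

test_that("logistic independence: null covariates, OR recovery, separation", {
  clin_for <- function(n, member_dep = NULL, seed = 1) {
    set.seed(seed)
    data.frame(sample_id = sprintf("S%d", 1:n),
               event = rbinom(n, 1, 0.3) * 0 + rep(c(1L, 0L), length.out = n),
               time_months = runif(n, 10, 119),
               age_years = runif(n, 35, 85),
               tumor_size_mm = runif(n, 5, 45),
               er_status = sample(c("pos", "neg"), n, TRUE),
               pr_status = "pos", grade = sample(c("1", "2", "3"), n, TRUE),
               tumor_type = "idc", year_of_surgery = 1990L,
               pair_id = NA_character_, stringsAsFactors = FALSE)
  }

  # membership unrelated to anything: OR ~ 1, p > 0.05 for ER
  cl <- clin_for(400, seed = 2)
  set.seed(3)
  member <- rbinom(400, 1, 0.4)
  tab <- logistic_independence(member, cl)
  er <- tab[tab$covariate == "ER status", ]
  expect_false(er$excluded)
  expect_gt(er$p, 0.05)
  expect_lt(abs(log(er$OR)), 0.5)

  # planted ER association OR = 3: estimate within [2, 4.5] in >= 18/20 seeds
  hits <- vapply(1:20, function(s) {
    cl <- clin_for(500, seed = s)
    set.seed(s + 100)
    er_pos <- as.integer(cl$er_status == "pos")
    pr <- plogis(qlogis(0.3) + log(3) * er_pos)
    member <- rbinom(500, 1, pr)
    tab <- logistic_independence(member, cl)
    or <- tab$OR[tab$covariate == "ER status"]
    or >= 2 && or <= 4.5
  }, logical(1))
  expect_gte(sum(hits), 18)

  # outcome perfectly predicting membership is reported n/a, not an error
  cl <- clin_for(100, seed = 5)
  member <- as.integer(cl$event == 0L)
  member[cl$event == 0L][1:30] <- 0L  # members are a strict subset of controls
  tab <- logistic_independence(member, cl)
  out_row <- tab[tab$covariate == "Outcome", ]
  expect_true(out_row$excluded)
  expect_true(is.na(out_row$OR))
  expect_false(all(tab$excluded))
})

test_that("the report bundle is complete, consistent and deterministic", {
  sim <- tiny_sim(n_pairs = 12, n_features = 40, n_informative = 10,
                  delta = 2, seed = 14)
  fit <- mirvote(sim$cohort, methods = c("NB", "LR", "KNN"), seed = 2)
  rg <- assign_risk_groups(fit, "fixed")
  d1 <- withr::local_tempdir()
  files <- build_report(fit, rg, sim$cohort$clinical, d1)
  expect_true(all(file.exists(files)))
  expect_true(all(c("metrics.tsv", "fisher.tsv", "independence.tsv",
                    "summary.txt") %in% basename(files)))

  fisher <- read.delim(file.path(d1, "fisher.tsv"))
  expect_true(all(rowSums(fisher[, 2:5]) == nrow(fit$votes)))
  metrics <- read.delim(file.path(d1, "metrics.tsv"))
  expect_equal(metrics$method, c("NB", "LR", "KNN"))

  d2 <- withr::local_tempdir()
  build_report(fit, rg, sim$cohort$clinical, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)),
                     label = paste("report file", f))
  }
})
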