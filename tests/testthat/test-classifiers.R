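# Well-separated two-class Gaussian clouds for sanity oracles.
clouds <- function(n_per = 20, p = 6, delta = 3, seed = 1) {
  set.seed(seed)
  X <- matrix(rnorm(2 * n_per * p), 2 * n_per, p,
              dimnames = list(NULL, paste0("f", seq_len(p))))
  y <- rep(c(0L, 1L), each = n_per)
  X[y == 1, ] <- X[y == 1, ] + delta
  surv <- data.frame(
    time_months = ifelse(y == 1, runif(2 * n_per, 20, 100),
                         runif(2 * n_per, 150, 300)),
    event = y)
  list(X = X, y = y, surv = surv)
}

test_that("probabilistic methods separate well-separated clouds in training", {
  cl <- clouds()
  for (m in c("RSVM", "RF", "NB", "LSVM", "LR")) {
    fit <- fit_classifier(m, cl$X, cl$y, survival = cl$surv, seed = 1)
    sc <- recurrence_score(fit, cl$X)
    expect_equal(sc$kind, "probability")
    expect_true(all(sc$value[cl$y == 1] >= 0.5),
                label = paste(m, "case scores >= 0.5"))
    expect_true(all(sc$value >= 0 & sc$value <= 1))
  }
})

test_that("COX-RS recovers a monotone hazard and votes every case up", {
  set.seed(4)
  n <- 10
  x <- c(rnorm(n, 2, 0.2), rnorm(n, 0, 0.2))
  X <- cbind(feat = x, noise = rnorm(2 * n))
  y <- rep(c(1L, 0L), each = n)
  surv <- data.frame(time_months = c(runif(n, 10, 40), runif(n, 200, 300)),
                     event = y)
  fit <- fit_classifier("COX-RS", X, y, survival = surv)
  expect_gt(fit$fit$beta[1], 0)
  sc <- recurrence_score(fit, X)
  expect_equal(sc$kind, "risk_sum")
  v <- cast_vote(sc, fit)
  expect_true(all(v[y == 1] == 1L))
})

test_that("training preconditions and feature contracts are enforced", {
  cl <- clouds(n_per = 5)
  expect_error(fit_classifier("LR", cl$X, rep(0L, nrow(cl$X))), "LR")
  expect_error(fit_classifier("COX-RS", cl$X, cl$y), "survival")

  # zero-variance feature dropped with a warning, fit still works
  X2 <- cbind(cl$X, flat = 1)
  expect_warning(fit <- fit_classifier("NB", X2, cl$y), "flat")
  expect_false("flat" %in% fit$feature_ids)

  # scoring demands every model feature, by name
  fit <- fit_classifier("LR", cl$X, cl$y)
  expect_error(recurrence_score(fit, cl$X[, -2, drop = FALSE]), "f2")
})

test_that("KNN assigns a training case to its own class", {
  cl <- clouds()
  fit <- fit_classifier("KNN", cl$X, cl$y)
  sc <- recurrence_score(fit, cl$X[cl$y == 1, , drop = FALSE])
  expect_equal(sc$kind, "class")
  expect_true(all(sc$value == 1))
})

test_that("vote thresholds follow the documented tie rules", {
  cl <- clouds(n_per = 5)
  lr <- fit_classifier("LR", cl$X, cl$y)
  mk <- function(value, kind) structure(list(value = value, kind = kind),
                                        class = "mirvote_score")
  expect_equal(cast_vote(mk(0.7, "probability"), lr), 1L)
  expect_equal(cast_vote(mk(0.3, "probability"), lr), 0L)
  expect_equal(cast_vote(mk(0.5, "probability"), lr), 1L)  # tie votes up

  cox <- fit_classifier("COX-RS", cl$X, cl$y, survival = cl$surv)
  # a risk-sum exactly at the training median does not vote recurrence
  expect_equal(cast_vote(mk(cox$fit$threshold, "risk_sum"), cox), 0L)
  # zero coefficients give a zero risk-sum for any sample
  cox$fit$beta[] <- 0
  sc <- recurrence_score(cox, cl$X)
  expect_true(all(sc$value == 0))
})

test_that("fits and votes are deterministic given the seed", {
  cl <- clouds(delta = 1)
  test <- clouds(n_per = 10, delta = 1, seed = 2)
  for (m in mirvote_methods()) {
    f1 <- fit_classifier(m, cl$X, cl$y, survival = cl$surv, seed = 11)
    f2 <- fit_classifier(m, cl$X, cl$y, survival = cl$surv, seed = 11)
    expect_identical(f1, f2)
    s1 <- recurrence_score(f1, test$X)
    s2 <- recurrence_score(f2, test$X)
    expect_identical(s1, s2)
    expect_identical(cast_vote(s1, f1), cast_vote(s2, f2))
  }
  # the forest actually uses the seed
  r1 <- fit_classifier("RF", cl$X, cl$y, seed = 1)
  r2 <- fit_classifier("RF", cl$X, cl$y, seed = 2)
  expect_false(identical(r1$fit$trees, r2$fit$trees))
})

test_that("label swap inverts held-out votes for LSVM, LR, NB, KNN", {
  cl <- clouds(n_per = 15, delta = 1, seed = 9)
  test <- clouds(n_per = 10, delta = 1, seed = 10)
  for (m in c("LSVM", "LR", "NB", "KNN")) {
    f1 <- fit_classifier(m, cl$X, cl$y, seed = 1)
    f2 <- fit_classifier(m, cl$X, 1L - cl$y, seed = 1)
    v1 <- cast_vote(recurrence_score(f1, test$X), f1)
    v2 <- cast_vote(recurrence_score(f2, test$X), f2)
    expect_identical(v1, 1L - v2, label = paste(m, "label swap"))
  }
})

test_that("method hyperparameters are configurable, incl. via YAML", {
  ctrl <- method_control(knn = list(k = 3), rf = list(ntree = 50))
  expect_equal(ctrl$knn$k, 3)
  expect_equal(ctrl$rf$ntree, 50)
  expect_equal(ctrl$lr$lambda, 1)  # untouched defaults survive
  expect_error(method_control(boost = list(n = 1)), "unknown method")

  f <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("methods:", "  knn:", "    k: 7", "  lr:",
               "    lambda: 0.5"), f)
  cfg <- read_method_config(f)
  expect_equal(cfg$knn$k, 7)
  expect_equal(cfg$lr$lambda, 0.5)

  cl <- clouds()
  fit <- fit_classifier("KNN", cl$X, cl$y, control = cfg)
  expect_equal(fit$fit$k, 7)
})
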