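test_that("LOPO bookkeeping: one fold per pair, every sample voted once", {
  sim <- tiny_sim(n_pairs = 4, n_features = 20, n_informative = 5,
                  delta = 1, seed = 3)
  fit <- mirvote(sim$cohort, methods = "NB", seed = 1)
  expect_length(fit$fold_features, 4)
  expect_equal(nrow(fit$votes), 8)
  expect_setequal(fit$votes$sample_id, sim$cohort$clinical$sample_id)
  expect_true(all(fit$votes$votes == fit$votes$NB))

  unpaired <- assemble_cohort(sim$cohort$expression, sim$cohort$clinical)
  expect_error(mirvote(unpaired), "match_pairs")
})

test_that("the held-out pair cannot influence its own feature set", {
  sim <- tiny_sim(n_pairs = 5, n_features = 40, n_informative = 10,
                  delta = 1.5, seed = 6)
  fit <- mirvote(sim$cohort, methods = "NB", seed = 1)
  # corrupt the held-out pair of fold 2 beyond recognition
  co2 <- sim$cohort
  held <- c(co2$pairs$case[2], co2$pairs$control[2])
  co2$expression[, held] <- matrix(rnorm(length(held) * nrow(co2$expression),
                                         sd = 50),
                                   nrow(co2$expression), length(held))
  fit2 <- mirvote(co2, methods = "NB", seed = 1)
  expect_identical(fit$fold_features[[2]], fit2$fold_features[[2]])
})

test_that("vote aggregation sums per-method votes and checks completeness", {
  m <- matrix(c(1, 1, 0, 0, 0, 0, 0), 1,
              dimnames = list("S1", mirvote_methods()))
  expect_equal(aggregate_votes(m)$votes, 2L)
  expect_equal(aggregate_votes(m * 0)$votes, 0L)
  expect_equal(aggregate_votes(m * 0 + 1)$votes, 7L)
  m[1, "KNN"] <- NA
  expect_error(aggregate_votes(m), "'S1'.*'KNN'")
  m[1, "KNN"] <- 3
  expect_error(aggregate_votes(m), "0 or 1")
})

test_that("risk-group cutoffs: fixed 0 / 0-1, auto tracks the vote minimum", {
  vt <- data.frame(sample_id = sprintf("S%d", 1:8), votes = 0:7)
  rg <- assign_risk_groups(vt, "fixed")
  expect_equal(as.character(rg$risk_group),
               c("ultralow", "low", rep("high", 6)))
  cut <- attr(rg, "cutoff_used")
  expect_equal(cut$ultralow_votes, 0L)
  expect_equal(cut$low_votes, c(0L, 1L))
  expect_true(all(cut$ultralow_votes %in% cut$low_votes))

  # external regime: nobody below 2 votes
  vt2 <- data.frame(sample_id = sprintf("S%d", 1:6), votes = c(2:6, 2))
  rg2 <- assign_risk_groups(vt2, "auto")
  cut2 <- attr(rg2, "cutoff_used")
  expect_equal(cut2$ultralow_votes, 2L)
  expect_equal(cut2$low_votes, c(2L, 3L))
  expect_equal(as.character(rg2$risk_group),
               c("ultralow", "low", "high", "high", "high", "ultralow"))

  # degenerate: one shared vote value -> everyone ultralow, none high
  vt3 <- data.frame(sample_id = c("a", "b"), votes = c(4L, 4L))
  rg3 <- assign_risk_groups(vt3, "auto")
  expect_true(all(rg3$risk_group == "ultralow"))
})

test_that("controls' votes track the planted indolence score", {
  sim <- tiny_sim(n_pairs = 80, n_features = 300, n_informative = 50,
                  delta = 1.5, seed = 4)
  fit <- mirvote(sim$cohort, seed = 4)
  ctrl <- sim$cohort$pairs$control
  v <- fit$votes$votes[match(ctrl, fit$votes$sample_id)]
  indolence <- -sim$truth$latent_score[ctrl]
  ct <- cor.test(v, indolence, method = "spearman",
                 alternative = "less", exact = FALSE)
  expect_lt(unname(ct$estimate), 0)
  expect_lt(ct$p.value, 0.01)
})

test_that("feature harmonization intersects panels in reference order", {
  mk <- function(feats, seed) {
    sim <- tiny_sim(n_pairs = 2, n_features = length(feats),
                    n_informative = 0, seed = seed)
    rownames(sim$cohort$expression) <- feats
    sim$cohort
  }
  ref <- mk(c("A", "B", "C"), 1)
  ext <- mk(c("B", "C", "D"), 2)
  expect_equal(harmonize_features(ref, ext), c("B", "C"))
  ext2 <- mk(c("C", "B", "D"), 2)
  expect_equal(harmonize_features(ref, ext2), c("B", "C"))
  expect_error(harmonize_features(ref, mk(c("X", "Y", "Z"), 3)),
               "no features")
})

test_that("per-method preselection ranks by p and scans the k grid", {
  sim <- tiny_sim(n_pairs = 10, n_features = 60, n_informative = 20,
                  delta = 3, seed = 12)
  co <- sim$cohort
  shared <- rownames(co$expression)

  # single-candidate grid returns exactly the k smallest-p features
  fs <- preselect_method_features(co, "NB", shared, k_grid = 5, seed = 1)
  de <- paired_differential_expression(co)
  expect_setequal(fs$features, de$feature_id[order(de$p_value)][1:5])
  expect_equal(attr(fs, "k"), 5)

  # equal accuracies: the smaller k wins (data are fully separable)
  fs2 <- preselect_method_features(co, "NB", shared, k_grid = c(5, 10),
                                   seed = 1)
  acc <- attr(fs2, "cv_accuracy")
  expect_equal(attr(fs2, "k"), as.integer(names(acc)[which.max(acc)]))
  if (acc[1] == acc[2]) expect_equal(attr(fs2, "k"), 5)

  # strong signal: the chosen set is dominated by planted features
  expect_gte(mean(fs2$features %in% sim$truth$informative_features), 0.8)

  expect_warning(
    preselect_method_features(co, "NB", shared[1:8], k_grid = c(5, 10),
                              seed = 1),
    "clipped")
})

test_that("external validation transfers feature sets and is reproducible", {
  ref <- tiny_sim(n_pairs = 10, n_features = 50, n_informative = 15,
                  delta = 2.5, seed = 21)
  ext <- tiny_sim(n_pairs = 10, n_features = 50, n_informative = 15,
                  delta = 2.5, seed = 22)  # same planted panel by design
  shared <- harmonize_features(ref$cohort, ext$cohort)
  fs <- preselect_method_features(ref$cohort, "NB", shared,
                                  k_grid = c(5, 10), seed = 1)
  feats <- list(NB = fs$features, LR = fs$features)

  r1 <- external_validation(ext$cohort, feats, seed = 5)
  r2 <- external_validation(ext$cohort, feats, seed = 5)
  expect_identical(r1$votes, r2$votes)
  expect_equal(attr(r1$risk_groups, "mode"), "auto")

  # ultralow group enriched for non-recurrent samples
  truth <- setNames(ext$cohort$clinical$event, ext$cohort$clinical$sample_id)
  tv <- truth[r1$votes$sample_id]
  ing <- r1$risk_groups$risk_group == "ultralow"
  p <- fisher_exact_one_tailed(sum(ing & tv == 0), sum(ing & tv == 1),
                               sum(!ing & tv == 0), sum(!ing & tv == 1))
  expect_lt(p, 0.05)

  expect_error(external_validation(ext$cohort, feats, methods = "KNN"),
               "KNN")
})

test_that("unpaired external cohorts get stratified folds, one vote each", {
  sim <- tiny_sim(n_pairs = 26, n_features = 40, n_informative = 10,
                  delta = 1, seed = 31)
  co <- sim$cohort
  # unbalanced unpaired cohort: 8 cases, 26 controls
  keep <- c(co$pairs$case[1:8], co$pairs$control)
  cl <- co$clinical[co$clinical$sample_id %in% keep, ]
  unb <- assemble_cohort(co$expression[, keep], cl)
  res <- external_validation(unb, rownames(co$expression)[1:10],
                             methods = "NB", seed = 2)
  expect_length(res$folds, 26)  # max(n_case, n_ctrl)
  expect_setequal(unlist(res$folds), keep)
  expect_equal(anyDuplicated(unlist(res$folds)), 0L)
  expect_equal(nrow(res$votes), length(keep))
  expect_true(all(lengths(res$folds) %in% 1:2))
})
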