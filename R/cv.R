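# Shared fold engine: fit the given methods on the training samples and
# vote on the held-out samples. `features` is the fold's feature set.
.fit_fold <- function(expr, clinical, features, train_ids, test_ids,
                      methods, seed, control) {
  Xtr <- t(expr[features, train_ids, drop = FALSE])
  Xte <- t(expr[features, test_ids, drop = FALSE])
  idx <- match(train_ids, clinical$sample_id)
  y <- clinical$event[idx]
  surv <- clinical[idx, c("time_months", "event")]
  votes <- matrix(NA_integer_, length(test_ids), length(methods),
                  dimnames = list(test_ids, methods))
  scores <- matrix(NA_real_, length(test_ids), length(methods),
                   dimnames = list(test_ids, methods))
  for (m in methods) {
    model <- fit_classifier(m, Xtr, y, survival = surv, seed = seed,
                            control = control)
    sc <- recurrence_score(model, Xte)
    votes[, m] <- cast_vote(sc, model)
    scores[, m] <- sc$value
  }
  list(votes = votes, scores = scores)
}

#' Leave-one-pair-out cross-validated ensemble voting
#'
#' The package's fitting function. For every matched pair, the pair is
#' held out, differential expression is recomputed on the remaining pairs,
#' features with FDR below the threshold are selected (falling back to the
#' top-`fallback_k` by p-value when none pass), all requested classifiers
#' are trained on the remaining samples, and the two held-out patients are
#' scored and voted on. Feature selection and standardization see training
#' data only, so the held-out pair can never influence its own feature set
#' — the design that keeps the accuracy estimate honest.
#'
#' @param cohort a paired `mirvote_cohort` with at least 4 pairs.
#' @param methods methods to run (default: all seven, see
#'   [mirvote_methods()]).
#' @param fdr_threshold per-fold FDR cutoff for feature selection
#'   (default 0.05).
#' @param fallback_k rank fallback when no feature passes FDR (default 10).
#' @param seed integer seed; fold `i` uses `seed + i`.
#' @param control hyperparameters from [method_control()].
#' @return object of class `mirvote`: list with `votes` (data.frame:
#'   `sample_id`, one 0/1 column per method, `votes`), `scores`
#'   (samples x methods matrix of native scores), `fold_features` (per-pair
#'   `mirvote_feature_set`), `clinical`, `config`, `call`.
#' @seealso [assign_risk_groups()], [summary.mirvote()], [plot.mirvote()]
#' @export
mirvote <- function(cohort, methods = mirvote_methods(),
                    fdr_threshold = 0.05, fallback_k = 10, seed = 1L,
                    control = method_control()) {
  if (!inherits(cohort, "mirvote_cohort"))
    stop("cohort must be a mirvote_cohort (see assemble_cohort())")
  if (is.null(cohort$pairs))
    stop("leave-one-pair-out CV needs a paired cohort; run match_pairs() ",
         "and assemble_cohort() with the pairing")
  methods <- match.arg(methods, mirvote_methods(), several.ok = TRUE)
  n_pairs <- nrow(cohort$pairs)
  if (n_pairs < 4) stop("need at least 4 pairs for LOPO-CV")
  seed <- as.integer(seed)

  all_votes <- NULL; all_scores <- NULL
  fold_features <- vector("list", n_pairs)
  for (i in seq_len(n_pairs)) {
    de <- paired_differential_expression(cohort, setdiff(seq_len(n_pairs), i))
    fs <- select_features(de, fdr_threshold, fallback_k)
    fold_features[[i]] <- fs
    test_ids <- c(cohort$pairs$case[i], cohort$pairs$control[i])
    train_ids <- setdiff(cohort$clinical$sample_id, test_ids)
    res <- tryCatch(
      .fit_fold(cohort$expression, cohort$clinical, fs$features,
                train_ids, test_ids, methods, seed + i, control),
      error = function(e) stop("fold ", i, ": ", conditionMessage(e),
                               call. = FALSE))
    all_votes <- rbind(all_votes, res$votes)
    all_scores <- rbind(all_scores, res$scores)
  }
  ord <- match(cohort$clinical$sample_id, rownames(all_votes))
  all_votes <- all_votes[ord, , drop = FALSE]
  all_scores <- all_scores[ord, , drop = FALSE]
  votes <- aggregate_votes(all_votes)
  structure(list(votes = votes, scores = all_scores,
                 fold_features = fold_features,
                 clinical = cohort$clinical,
                 config = list(methods = methods,
                               fdr_threshold = fdr_threshold,
                               fallback_k = fallback_k, seed = seed),
                 call = match.call()),
            class = "mirvote")
}

#' @rdname mirvote
#' @export
leave_one_pair_out_cv <- mirvote

#' Aggregate per-method binary votes into a vote table
#'
#' @param per_method samples x methods matrix or data.frame of 0/1 votes
#'   with sample ids as rownames (or a `sample_id` column).
#' @return data.frame: `sample_id`, one column per method, `votes` (the
#'   row sum, 0..number of methods).
#' @export
aggregate_votes <- function(per_method) {
  if (is.data.frame(per_method) && "sample_id" %in% names(per_method)) {
    ids <- as.character(per_method$sample_id)
    per_method <- as.matrix(per_method[, setdiff(names(per_method),
                                                 c("sample_id", "votes")),
                                       drop = FALSE])
    rownames(per_method) <- ids
  }
  per_method <- as.matrix(per_method)
  if (is.null(rownames(per_method)))
    stop("per-method votes need sample identifiers")
  if (anyNA(per_method)) {
    bad <- which(is.na(per_method), arr.ind = TRUE)[1, ]
    stop(sprintf("sample '%s' is missing a vote from method '%s'",
                 rownames(per_method)[bad[1]], colnames(per_method)[bad[2]]))
  }
  if (!all(per_method %in% c(0, 1)))
    stop("per-method votes must be 0 or 1")
  out <- data.frame(sample_id = rownames(per_method), per_method,
                    votes = as.integer(rowSums(per_method)),
                    row.names = NULL, check.names = FALSE,
                    stringsAsFactors = FALSE)
  out
}

#' Assign ultralow / low / high recurrence-risk groups from votes
#'
#' Fixed mode applies the study's cutoffs: 0 votes is ultralow risk, 0-1
#' votes low risk, 2-7 votes high risk. Auto mode adapts the cutoff to the
#' dataset, as done when transferring the classifier to external cohorts
#' where no patient receives 0 or 1 votes: with minimum observed vote
#' `v`, ultralow is `{v}` and low is `{v, v+1}`. The reported labels
#' partition the cohort; "low" means low-but-not-ultralow.
#'
#' @param votes a vote table from [aggregate_votes()], or a `mirvote` fit.
#' @param mode `"fixed"` or `"auto"`.
#' @return data.frame of class `mirvote_risk`: `sample_id`, `votes`,
#'   `risk_group` (factor ultralow/low/high), with attributes
#'   `cutoff_used` (list `ultralow_votes`, `low_votes`) and `mode`.
#' @export
assign_risk_groups <- function(votes, mode = c("fixed", "auto")) {
  mode <- match.arg(mode)
  if (inherits(votes, "mirvote")) votes <- votes$votes
  if (!nrow(votes)) stop("empty vote table")
  v <- votes$votes
  if (mode == "fixed") {
    ultralow <- 0L; low <- c(0L, 1L)
  } else {
    vmin <- min(v)
    ultralow <- vmin; low <- c(vmin, vmin + 1L)
  }
  lab <- ifelse(v %in% ultralow, "ultralow",
                ifelse(v %in% low, "low", "high"))
  out <- data.frame(sample_id = votes$sample_id, votes = v,
                    risk_group = factor(lab, c("ultralow", "low", "high")),
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "cutoff_used") <- list(ultralow_votes = ultralow,
                                   low_votes = low)
  attr(out, "mode") <- mode
  class(out) <- c("mirvote_risk", "data.frame")
  out
}

#' @export
print.mirvote <- function(x, ...) {
  cat(sprintf("mirvote ensemble: %d methods, %d samples, %d LOPO folds\n",
              length(x$config$methods), nrow(x$votes),
              length(x$fold_features)))
  cat(sprintf("  FDR threshold %.3g (fallback top-%d), seed %d\n",
              x$config$fdr_threshold, x$config$fallback_k, x$config$seed))
  tab <- table(factor(x$votes$votes, 0:length(x$config$methods)))
  cat("  vote distribution:\n")
  print(tab)
  invisible(x)
}

#' Summarize an ensemble CV run
#'
#' Per-method held-out confusion metrics against the recurrence labels,
#' the majority-vote metrics, and the fixed-cutoff risk-group composition.
#'
#' @param object a `mirvote` fit.
#' @param ... unused.
#' @return list of class `summary.mirvote` with elements `per_method`
#'   (data.frame of accuracy/sensitivity/specificity and exact binomial p
#'   per method), `majority` (a `mirvote_confusion`), `risk_groups`
#'   (group x outcome table, fixed cutoffs).
#' @export
summary.mirvote <- function(object, ...) {
  truth <- object$clinical$event[match(object$votes$sample_id,
                                       object$clinical$sample_id)]
  per <- lapply(object$config$methods, function(m) {
    cm <- confusion_metrics(object$votes[[m]], truth)
    data.frame(method = m, accuracy = cm$accuracy,
               sensitivity = cm$sensitivity, specificity = cm$specificity,
               binomial_p = cm$binomial_p, stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, per)
  majority <- confusion_metrics(
    as.integer(object$votes$votes * 2 > length(object$config$methods)),
    truth)
  rg <- assign_risk_groups(object, "fixed")
  tab <- table(group = rg$risk_group,
               outcome = ifelse(truth == 1, "recurrence", "no recurrence"))
  structure(list(per_method = per, majority = majority, risk_groups = tab),
            class = "summary.mirvote")
}

#' @export
print.summary.mirvote <- function(x, ...) {
  cat("Held-out performance by method:\n")
  df <- x$per_method
  df[2:4] <- lapply(df[2:4], function(v) sprintf("%.3f", v))
  df$binomial_p <- sprintf("%.3g", x$per_method$binomial_p)
  print(df, row.names = FALSE)
  cat(sprintf("\nMajority vote: accuracy %.3f (sens %.3f, spec %.3f)\n",
              x$majority$accuracy, x$majority$sensitivity,
              x$majority$specificity))
  cat("\nRisk groups (fixed cutoffs: ultralow = 0 votes, low = 0-1):\n")
  print(x$risk_groups)
  invisible(x)
}

#' Vote dot plot for an ensemble CV run
#'
#' Votes per patient, split by diagnosed outcome, in the style of the
#' study's summary figure: the horizontal line at 1.5 votes separates
#' predicted high-risk from low-risk patients, the dashed line at 0.5
#' isolates the ultralow-risk group.
#'
#' @param x a `mirvote` fit.
#' @param ... passed to [plot()].
#' @export
plot.mirvote <- function(x, ...) {
  truth <- x$clinical$event[match(x$votes$sample_id,
                                  x$clinical$sample_id)]
  set.seed(1)
  jx <- ifelse(truth == 1, 1, 2) + runif(length(truth), -0.25, 0.25)
  plot(jx, x$votes$votes, xlim = c(0.5, 2.5),
       ylim = c(-0.3, length(x$config$methods) + 0.3),
       xaxt = "n", xlab = "", ylab = "votes (predicted recurrence)",
       pch = 19, col = ifelse(truth == 1, "firebrick", "steelblue"), ...)
  axis(1, at = c(1, 2), labels = c("recurrence", "recurrence-free"))
  abline(h = 1.5, col = "grey30")
  abline(h = 0.5, col = "grey30", lty = 2)
  invisible(x)
}
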