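#' Harmonize feature panels between two cohorts
#'
#' miRNA platforms differ; only the intersection of the mature-miRNA
#' panels can carry a classifier across cohorts. The intersection is
#' returned in reference order. Expression is never pooled across cohorts
#' — each cohort is standardized within itself downstream.
#'
#' @param reference reference `mirvote_cohort`.
#' @param external external `mirvote_cohort`.
#' @return character vector of shared feature ids, reference order.
#' @export
harmonize_features <- function(reference, external) {
  shared <- intersect(rownames(reference$expression),
                      rownames(external$expression))
  if (!length(shared))
    stop("the two cohorts share no features; panels are disjoint")
  shared
}

# Cross-validation with a FIXED feature set for one method: used for
# k-grid preselection and for external validation, where features come
# from the reference cohort and are never re-selected inside folds.
.cv_fixed_features <- function(cohort, features, method, seed, control) {
  folds <- .make_folds(cohort, seed)
  votes <- integer(0); ids <- character(0)
  for (i in seq_along(folds)) {
    test_ids <- folds[[i]]
    train_ids <- setdiff(cohort$clinical$sample_id, test_ids)
    res <- .fit_fold(cohort$expression, cohort$clinical, features,
                     train_ids, test_ids, method, seed + i, control)
    votes <- c(votes, res$votes[, method])
    ids <- c(ids, test_ids)
  }
  setNames(votes, ids)
}

# Folds: leave-one-pair-out when pairing exists; otherwise stratified
# leave-two-out (one case + one control per fold, random order under the
# seed; with unequal arm sizes the longer arm's surplus samples are held
# out singly, so every sample is voted on exactly once).
.make_folds <- function(cohort, seed) {
  if (!is.null(cohort$pairs)) {
    return(lapply(seq_len(nrow(cohort$pairs)), function(i)
      c(cohort$pairs$case[i], cohort$pairs$control[i])))
  }
  cl <- cohort$clinical
  set.seed(seed)
  cases <- sample(cl$sample_id[cl$event == 1L])
  ctrls <- sample(cl$sample_id[cl$event == 0L])
  if (!length(cases) || !length(ctrls))
    stop("cohort needs both cases and controls to form folds")
  n <- max(length(cases), length(ctrls))
  lapply(seq_len(n), function(i)
    c(if (i <= length(cases)) cases[i],
      if (i <= length(ctrls)) ctrls[i]))
}

#' Preselect a method's feature set on the reference cohort
#'
#' Ranks the shared features by ascending paired-DE p-value in the
#' reference cohort, then evaluates the method's leave-one-pair-out CV
#' accuracy on the reference for each candidate size `k` in the grid (with
#' the candidate set fixed across folds). Returns the top-`k` set with the
#' highest accuracy; ties go to the smaller `k`.
#'
#' @param reference paired reference `mirvote_cohort`.
#' @param method one of [mirvote_methods()].
#' @param shared_features feature ids available in both cohorts (see
#'   [harmonize_features()]).
#' @param k_grid candidate set sizes (default `c(5, 10, 20, 50)`); values
#'   exceeding the shared panel are clipped with a warning.
#' @param seed integer seed.
#' @param control hyperparameters from [method_control()].
#' @return `mirvote_feature_set` with `selection_mode = "preselect"` and
#'   attributes `k` and `cv_accuracy`.
#' @export
preselect_method_features <- function(reference, method, shared_features,
                                      k_grid = c(5, 10, 20, 50), seed = 1L,
                                      control = method_control()) {
  method <- match.arg(method, mirvote_methods())
  if (!length(shared_features)) stop("shared feature list is empty")
  if (any(k_grid > length(shared_features))) {
    warning("k_grid values exceeding the shared panel were clipped to ",
            length(shared_features))
    k_grid <- pmin(k_grid, length(shared_features))
  }
  k_grid <- sort(unique(k_grid))
  de <- paired_differential_expression(reference)
  de <- de[match(shared_features, de$feature_id), ]
  if (anyNA(de$feature_id))
    stop("some shared features are absent from the reference cohort")
  ranked <- de$feature_id[order(de$p_value)]
  truth <- setNames(reference$clinical$event, reference$clinical$sample_id)
  acc <- vapply(k_grid, function(k) {
    v <- .cv_fixed_features(reference, ranked[seq_len(k)], method,
                            as.integer(seed), control)
    mean(v == truth[names(v)])
  }, numeric(1))
  best <- k_grid[which.max(acc)]  # which.max is first-wins: smallest k ties
  out <- structure(list(features = ranked[seq_len(best)],
                        selection_mode = "preselect"),
                   class = "mirvote_feature_set")
  attr(out, "k") <- best
  attr(out, "cv_accuracy") <- setNames(acc, k_grid)
  out
}

#' Validate the classifier in an external cohort
#'
#' Runs cross-validation entirely within the external cohort —
#' leave-one-pair-out when a pairing exists, stratified leave-two-out (one
#' case plus one control per fold) otherwise — fitting each method on its
#' reference-preselected feature set. Features are never re-selected
#' inside folds, since the reference cohort fixed them. Votes are
#' aggregated and risk groups assigned with the dataset-adaptive cutoff,
#' the regime needed when no external patient reaches 0 or 1 votes.
#'
#' @param external external `mirvote_cohort` (paired or unpaired).
#' @param per_method_features named list: method -> feature ids (e.g. from
#'   [preselect_method_features()]); a single character vector or
#'   `mirvote_feature_set` is recycled for all methods.
#' @param methods methods to run (default: the names of
#'   `per_method_features`, else all seven).
#' @param seed integer seed.
#' @param mode risk-group cutoff mode (default `"auto"`).
#' @param control hyperparameters from [method_control()].
#' @return list of class `mirvote_external`: `votes` (vote table),
#'   `risk_groups` (a `mirvote_risk`), `folds`.
#' @export
external_validation <- function(external, per_method_features,
                                methods = NULL, seed = 1L,
                                mode = c("auto", "fixed"),
                                control = method_control()) {
  mode <- match.arg(mode)
  if (inherits(per_method_features, "mirvote_feature_set"))
    per_method_features <- per_method_features$features
  if (is.character(per_method_features)) {
    methods <- if (is.null(methods)) mirvote_methods() else methods
    per_method_features <- setNames(
      rep(list(per_method_features), length(methods)), methods)
  }
  if (is.null(methods)) methods <- names(per_method_features)
  methods <- match.arg(methods, mirvote_methods(), several.ok = TRUE)
  missing_m <- setdiff(methods, names(per_method_features))
  if (length(missing_m))
    stop("no preselected features for method(s): ",
         paste(missing_m, collapse = ", "))
  for (m in methods) {
    fs <- per_method_features[[m]]
    if (inherits(fs, "mirvote_feature_set")) fs <- fs$features
    absent <- setdiff(fs, rownames(external$expression))
    if (length(absent))
      stop(m, ": feature(s) absent from the external cohort: ",
           paste(absent, collapse = ", "))
    per_method_features[[m]] <- fs
  }
  folds <- .make_folds(external, as.integer(seed))
  ids <- external$clinical$sample_id
  votes <- matrix(NA_integer_, length(ids), length(methods),
                  dimnames = list(ids, methods))
  for (i in seq_along(folds)) {
    test_ids <- folds[[i]]
    train_ids <- setdiff(ids, test_ids)
    for (m in methods) {
      res <- .fit_fold(external$expression, external$clinical,
                       per_method_features[[m]], train_ids, test_ids,
                       m, as.integer(seed) + i, control)
      votes[test_ids, m] <- res$votes[, m]
    }
  }
  vt <- aggregate_votes(votes)
  structure(list(votes = vt, risk_groups = assign_risk_groups(vt, mode),
                 folds = folds),
            class = "mirvote_external")
}

#' @export
print.mirvote_external <- function(x, ...) {
  cat(sprintf("mirvote external validation: %d samples, %d folds\n",
              nrow(x$votes), length(x$folds)))
  cu <- attr(x$risk_groups, "cutoff_used")
  cat(sprintf("  cutoffs (%s): ultralow votes {%s}, low votes {%s}\n",
              attr(x$risk_groups, "mode"),
              paste(cu$ultralow_votes, collapse = ","),
              paste(cu$low_votes, collapse = ",")))
  print(table(x$risk_groups$risk_group))
  invisible(x)
}
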