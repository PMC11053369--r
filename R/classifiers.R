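#' The seven ensemble methods, in vote-table column order
#'
#' Radial-kernel SVM, random forest, Gaussian naive Bayes, linear-kernel
#' SVM, Cox risk-sum, k-nearest neighbors, and ridge logistic regression.
#'
#' @return character vector of the seven method names.
#' @export
mirvote_methods <- function() {
  c("RSVM", "RF", "NB", "LSVM", "COX-RS", "KNN", "LR")
}

#' Hyperparameter defaults for the seven methods
#'
#' All knobs are fixed, seedable defaults; none are tuned inside the
#' cross-validation. RSVM: RBF kernel, cost 1, width by the median
#' heuristic, Platt-scaled probabilities. LSVM: linear kernel, cost 1,
#' Platt-scaled. RF: 500 trees, `mtry = floor(sqrt(p))`, probability =
#' fraction of trees voting recurrence. NB: Gaussian class-conditionals.
#' KNN: k = 5 (odd, so no vote ties), Euclidean metric on standardized
#' features. LR: ridge penalty of fixed strength 1 (features can outnumber
#' samples). COX-RS: one univariate proportional-hazards fit per feature.
#'
#' @param ... named overrides, e.g. `method_control(knn = list(k = 7))`.
#' @return nested list of per-method settings.
#' @export
method_control <- function(...) {
  ctrl <- list(
    rsvm = list(cost = 1, gamma = NULL),
    lsvm = list(cost = 1),
    rf = list(ntree = 500, mtry = NULL, min_node = 1, max_depth = 25),
    nb = list(var_floor = 1e-9),
    knn = list(k = 5),
    lr = list(lambda = 1),
    coxrs = list()
  )
  over <- list(...)
  for (nm in names(over)) {
    if (!nm %in% names(ctrl)) stop("unknown method control block: ", nm)
    ctrl[[nm]][names(over[[nm]])] <- over[[nm]]
  }
  ctrl
}

#' Read method hyperparameters from a YAML config file
#'
#' The file's `methods:` section holds per-method blocks whose entries
#' override the [method_control()] defaults.
#'
#' @param path path to a YAML file.
#' @return nested list as from [method_control()].
#' @export
read_method_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  blocks <- if (!is.null(cfg$methods)) cfg$methods else cfg
  do.call(method_control, blocks)
}

.method_key <- c(RSVM = "rsvm", RF = "rf", NB = "nb", LSVM = "lsvm",
                 `COX-RS` = "coxrs", KNN = "knn", LR = "lr")

#' Fit one ensemble member
#'
#' Features are z-standardized internally using training means/SDs (stored
#' in the model and re-applied at scoring time); zero-variance features are
#' dropped with a warning. COX-RS fits one univariate proportional-hazards
#' model per feature on the standardized expression and stores the
#' coefficients together with the training-median risk-sum, which later
#' serves as the vote threshold.
#'
#' @param method one of [mirvote_methods()].
#' @param x training matrix, samples x features (restricted to the fold's
#'   selected feature set).
#' @param y binary event labels (1 = recurrence), one per training sample.
#' @param survival data.frame with `time_months` and `event`, required for
#'   COX-RS.
#' @param seed integer seed (consumed by the random forest; the other six
#'   methods are deterministic).
#' @param control hyperparameters from [method_control()].
#' @return object of class `mirvote_model`.
#' @export
fit_classifier <- function(method, x, y, survival = NULL, seed = 1L,
                           control = method_control()) {
  method <- match.arg(method, mirvote_methods())
  x <- as.matrix(x)
  y <- as.integer(y)
  if (length(y) != nrow(x)) stop("length(y) must equal nrow(x)")
  if (length(unique(y)) < 2 || min(table(y)) < 2)
    stop(method, ": training requires at least 2 samples in each class")
  center <- colMeans(x)
  scale_ <- apply(x, 2, sd)
  drop <- scale_ == 0 | !is.finite(scale_)
  if (any(drop)) {
    warning(method, ": dropping zero-variance feature(s): ",
            paste(colnames(x)[drop], collapse = ", "))
    x <- x[, !drop, drop = FALSE]
    center <- center[!drop]; scale_ <- scale_[!drop]
    if (ncol(x) == 0) stop(method, ": no non-degenerate features left")
  }
  z <- sweep(sweep(x, 2, center), 2, scale_, "/")
  cc <- control[[.method_key[[method]]]]

  fit <- switch(
    method,
    RSVM = .svm_fit(z, y, kernel = "rbf", cost = cc$cost, gamma = cc$gamma),
    LSVM = .svm_fit(z, y, kernel = "linear", cost = cc$cost),
    RF = {
      mtry <- if (is.null(cc$mtry)) max(1L, floor(sqrt(ncol(z)))) else cc$mtry
      list(trees = .rf_grow(z, y, as.integer(cc$ntree), as.integer(mtry),
                            as.integer(cc$min_node), as.integer(cc$max_depth),
                            as.integer(seed)))
    },
    NB = .nb_fit(z, y, cc$var_floor),
    `COX-RS` = {
      if (is.null(survival))
        stop("COX-RS requires survival data (time_months, event)")
      .coxrs_fit(z, survival$time_months, survival$event)
    },
    KNN = list(train = z, y = y, k = cc$k),
    LR = list(beta = .ridge_logistic(z, y, cc$lambda))
  )
  structure(list(method = method, feature_ids = colnames(x),
                 center = center, scale = scale_, fit = fit,
                 seed = as.integer(seed)),
            class = "mirvote_model")
}

# Gaussian naive Bayes on standardized features.
.nb_fit <- function(z, y, var_floor) {
  stats_for <- function(g) {
    zz <- z[y == g, , drop = FALSE]
    list(mean = colMeans(zz), var = pmax(apply(zz, 2, var), var_floor))
  }
  list(g0 = stats_for(0L), g1 = stats_for(1L),
       logprior = log(c(mean(y == 0), mean(y == 1))))
}

.nb_prob <- function(fit, z) {
  ll <- function(g) {
    rowSums(sweep(-(sweep(z, 2, g$mean))^2, 2, 2 * g$var, "/") -
              matrix(log(2 * pi * g$var) / 2, nrow(z), ncol(z), byrow = TRUE))
  }
  l0 <- ll(fit$g0) + fit$logprior[1]
  l1 <- ll(fit$g1) + fit$logprior[2]
  1 / (1 + exp(l0 - l1))
}

# Ridge-penalized logistic regression by IRLS; penalty lambda on all
# coefficients except the intercept.
.ridge_logistic <- function(z, y, lambda, maxit = 50, tol = 1e-9) {
  X <- cbind(1, z)
  p <- ncol(X)
  R <- diag(c(0, rep(lambda, p - 1)), p)
  beta <- rep(0, p)
  for (it in seq_len(maxit)) {
    eta <- as.numeric(X %*% beta)
    mu <- 1 / (1 + exp(-eta))
    w <- pmax(mu * (1 - mu), 1e-10)
    zresp <- eta + (y - mu) / w
    H <- crossprod(X, X * w) + R
    beta_new <- solve(H, crossprod(X, w * zresp))
    if (max(abs(beta_new - beta)) < tol) { beta <- beta_new; break }
    beta <- beta_new
  }
  as.numeric(beta)
}

# Univariate Cox coefficient per standardized feature; risk-sum threshold
# at the training median.
.coxrs_fit <- function(z, time, event) {
  betas <- vapply(seq_len(ncol(z)), function(j) {
    fit <- tryCatch(
      survival::coxph(survival::Surv(time, event) ~ z[, j],
                      control = survival::coxph.control(iter.max = 25)),
      error = function(e) NULL, warning = function(w) {
        suppressWarnings(survival::coxph(
          survival::Surv(time, event) ~ z[, j],
          control = survival::coxph.control(iter.max = 25)))
      })
    if (is.null(fit)) return(0)
    b <- unname(coef(fit)[1])
    if (!is.finite(b)) 0 else b
  }, numeric(1))
  rs <- as.numeric(z %*% betas)
  list(beta = betas, threshold = median(rs))
}

#' Score a sample with a fitted ensemble member
#'
#' Standardizes the sample with the stored training constants and returns
#' the method's native score: a probability of recurrence in `[0, 1]` for
#' RSVM, RF, NB, LSVM and LR; an unbounded Cox risk-sum for COX-RS; a hard
#' 0/1 class for KNN.
#'
#' @param model a `mirvote_model` from [fit_classifier()].
#' @param sample_expression named numeric vector (or samples x features
#'   matrix) covering all of `model$feature_ids`.
#' @return list of class `mirvote_score`: `value` (numeric vector, one per
#'   sample) and `kind` (`"probability"`, `"risk_sum"`, or `"class"`).
#' @export
recurrence_score <- function(model, sample_expression) {
  stopifnot(inherits(model, "mirvote_model"))
  x <- if (is.matrix(sample_expression)) sample_expression else
    matrix(sample_expression, nrow = 1,
           dimnames = list(NULL, names(sample_expression)))
  missing_f <- setdiff(model$feature_ids, colnames(x))
  if (length(missing_f))
    stop("sample is missing model feature(s): ",
         paste(missing_f, collapse = ", "))
  x <- x[, model$feature_ids, drop = FALSE]
  z <- sweep(sweep(x, 2, model$center), 2, model$scale, "/")
  value <- switch(
    model$method,
    RSVM = , LSVM = .platt_prob(model$fit$platt, .svm_decision(model$fit, z)),
    RF = as.numeric(.rf_predict_prob(model$fit$trees, z)),
    NB = .nb_prob(model$fit, z),
    LR = {
      eta <- as.numeric(cbind(1, z) %*% model$fit$beta)
      1 / (1 + exp(-eta))
    },
    `COX-RS` = as.numeric(z %*% model$fit$beta),
    KNN = {
      nn <- FNN::get.knnx(model$fit$train, z, k = model$fit$k)$nn.index
      apply(nn, 1, function(i) as.numeric(sum(model$fit$y[i]) * 2 >
                                            model$fit$k))
    })
  kind <- switch(model$method, `COX-RS` = "risk_sum", KNN = "class",
                 "probability")
  if (kind == "probability") value <- pmin(pmax(value, 0), 1)
  structure(list(value = value, kind = kind), class = "mirvote_score")
}

#' Turn a recurrence score into a binary vote
#'
#' Probabilities vote 1 (recurrence) at `>= 0.5` — the tie at exactly 0.5
#' votes toward recurrence, the conservative direction for a
#' treatment-sparing classifier. Risk-sums vote 1 strictly above the
#' training-median threshold. Class scores vote their class.
#'
#' @param score a `mirvote_score`.
#' @param model the `mirvote_model` that produced it (holds the COX-RS
#'   threshold).
#' @return integer vector of 0/1 votes.
#' @export
cast_vote <- function(score, model) {
  stopifnot(inherits(score, "mirvote_score"))
  switch(score$kind,
         probability = as.integer(score$value >= 0.5),
         risk_sum = as.integer(score$value > model$fit$threshold),
         class = as.integer(score$value))
}

#' @export
print.mirvote_model <- function(x, ...) {
  cat(sprintf("mirvote %s model on %d standardized feature(s)\n",
              x$method, length(x$feature_ids)))
  invisible(x)
}
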