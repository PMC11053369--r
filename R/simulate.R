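#' Simulation parameters for a synthetic matched cohort
#'
#' Defaults reproduce the shape of the study cohort this package emulates:
#' 80 matched case-control pairs profiled over 1212 mature miRNAs, with
#' case event times concentrated within 10 years (mean 58.5 months) and
#' long censoring for recurrence-free controls (mean follow-up 250.35
#' months).
#'
#' @param n_pairs number of matched case-control pairs (default 80).
#' @param n_features number of miRNA features (default 1212).
#' @param n_informative number of planted differentially expressed features
#'   (default 50).
#' @param delta planted case-minus-control mean shift of informative
#'   features, in units of the pooled within-group SD of the feature.
#' @param indolent_fraction share of controls whose latent risk score is
#'   shifted a further `delta_extra` downward — "indolent" tumors whose
#'   expression is most unlike recurring tumors (default 0.5).
#' @param delta_extra additional downward latent shift for indolent
#'   controls, in latent-score units (default 1).
#' @param rho equicorrelation of the feature noise, in `[0, 1)`
#'   (default 0.2).
#' @param case_time_mean mean time-to-metastasis of cases in months, after
#'   truncation at the 120-month case horizon (default 58.5).
#' @param case_time_sdlog lognormal shape (sdlog) of case event times.
#' @param control_followup_mean,control_followup_sd mean/SD of the normal
#'   censoring-time distribution for controls, truncated below at
#'   `control_followup_min` (defaults 250.35 / 30 / 60 months).
#' @param control_followup_min minimum control follow-up in months.
#' @param latent_sd SD of the per-sample latent noise around the group
#'   latent means.
#' @param seed integer seed; identical seeds give bit-identical cohorts.
#' @return a list of class `mirvote_sim_params`.
#' @export
sim_params <- function(n_pairs = 80, n_features = 1212, n_informative = 50,
                       delta = 1, indolent_fraction = 0.5, delta_extra = 1,
                       rho = 0.2, case_time_mean = 58.5,
                       case_time_sdlog = 0.6,
                       control_followup_mean = 250.35,
                       control_followup_sd = 30,
                       control_followup_min = 60,
                       latent_sd = 0.5, seed = 1L) {
  p <- list(n_pairs = as.integer(n_pairs), n_features = as.integer(n_features),
            n_informative = as.integer(n_informative), delta = delta,
            indolent_fraction = indolent_fraction, delta_extra = delta_extra,
            rho = rho, case_time_mean = case_time_mean,
            case_time_sdlog = case_time_sdlog,
            control_followup_mean = control_followup_mean,
            control_followup_sd = control_followup_sd,
            control_followup_min = control_followup_min,
            latent_sd = latent_sd, seed = as.integer(seed))
  if (p$n_informative < 0 || p$n_informative > p$n_features)
    stop("n_informative must lie in [0, n_features]")
  if (p$delta < 0) stop("delta must be nonnegative")
  if (p$rho < 0 || p$rho >= 1) stop("rho must lie in [0, 1)")
  if (p$n_pairs < 2) stop("need at least 2 pairs")
  if (p$indolent_fraction < 0 || p$indolent_fraction > 1)
    stop("indolent_fraction must lie in [0, 1]")
  class(p) <- "mirvote_sim_params"
  p
}

# meanlog of a lognormal(mu, sdlog) whose mean conditional on X <= cap
# equals target. Solved once per simulate_cohort call.
.lognormal_meanlog_for_truncated_mean <- function(target, sdlog, cap) {
  trunc_mean <- function(mu) {
    exp(mu + sdlog^2 / 2) *
      pnorm((log(cap) - mu - sdlog^2) / sdlog) /
      pnorm((log(cap) - mu) / sdlog)
  }
  uniroot(function(mu) trunc_mean(mu) - target,
          lower = log(target) - 3, upper = log(cap))$root
}

#' Simulate a paired case-control miRNA cohort with planted signal
#'
#' Each sample carries a latent recurrence-risk score: cases at `+delta/2`,
#' controls at `-delta/2`, with a configurable fraction of "indolent"
#' controls shifted a further `delta_extra` down, plus per-sample noise.
#' Informative features load on this score with a loading calibrated so
#' that the expected case-minus-control difference equals `delta` in units
#' of the pooled within-group SD; the remaining features are pure noise.
#' Feature noise is equicorrelated with parameter `rho`. Case event times
#' are lognormal, resampled above the 120-month case horizon, with the
#' truncated mean calibrated to `case_time_mean`; control follow-up is
#' truncated normal. Covariates (age, tumor size, ER/PR status, grade,
#' tumor type, year of surgery) are drawn per pair and shared, with small
#' within-pair jitter on the continuous ones, mirroring the matched design.
#'
#' @param params a [sim_params()] object.
#' @return list with elements `cohort` (a `mirvote_cohort`) and `truth`
#'   (list: `informative_features`, `latent_score` named per sample,
#'   `pair_covariates`).
#' @export
simulate_cohort <- function(params = sim_params()) {
  stopifnot(inherits(params, "mirvote_sim_params"))
  p <- params
  set.seed(p$seed)
  n <- 2L * p$n_pairs

  feature_ids <- sprintf("mir-sim-%04d", seq_len(p$n_features))
  informative <- if (p$n_informative > 0) feature_ids[seq_len(p$n_informative)] else character(0)
  case_ids <- sprintf("S%03dC", seq_len(p$n_pairs))
  ctrl_ids <- sprintf("S%03dN", seq_len(p$n_pairs))
  sample_ids <- c(rbind(case_ids, ctrl_ids))
  is_case <- rep(c(1L, 0L), p$n_pairs)

  # latent risk score per sample
  group_mean <- ifelse(is_case == 1L, p$delta / 2, -p$delta / 2)
  indolent <- is_case == 0L & runif(n) < p$indolent_fraction
  group_mean[indolent] <- group_mean[indolent] - p$delta_extra
  score <- group_mean + rnorm(n, sd = p$latent_sd)

  # loading c on informative features so that the expected standardized
  # case-control difference equals delta:
  #   c * (delta + f*de) = delta * sqrt(c^2 * B2 + 1),
  # B2 = latent_sd^2 + f(1-f) de^2 / 2 (pooled within-group latent var).
  f <- p$indolent_fraction; de <- p$delta_extra
  A <- p$delta + f * de
  B2 <- p$latent_sd^2 + f * (1 - f) * de^2 / 2
  load <- if (p$delta == 0) 0 else {
    denom <- A^2 - p$delta^2 * B2
    if (denom <= 0)
      stop("planted effect is not attainable: delta too large relative to ",
           "the latent spread (delta_extra / latent_sd)")
    p$delta / sqrt(denom)
  }

  # equicorrelated noise: sqrt(rho) * shared + sqrt(1-rho) * idiosyncratic
  shared <- rnorm(n)
  eps <- sqrt(p$rho) * matrix(shared, p$n_features, n, byrow = TRUE) +
    sqrt(1 - p$rho) * matrix(rnorm(p$n_features * n), p$n_features, n)
  expr <- eps
  if (p$n_informative > 0) {
    expr[seq_len(p$n_informative), ] <- expr[seq_len(p$n_informative), ] +
      matrix(load * score, p$n_informative, n, byrow = TRUE)
  }
  # shift to a log-intensity-like scale; location is irrelevant downstream
  expr <- expr + 8
  dimnames(expr) <- list(feature_ids, sample_ids)

  # survival structure
  mu <- .lognormal_meanlog_for_truncated_mean(
    p$case_time_mean, p$case_time_sdlog, .case_horizon_months)
  draw_case_time <- function(k) {
    t <- rlnorm(k, mu, p$case_time_sdlog)
    while (any(t > .case_horizon_months)) {
      i <- t > .case_horizon_months
      t[i] <- rlnorm(sum(i), mu, p$case_time_sdlog)
    }
    t
  }
  time <- numeric(n)
  time[is_case == 1L] <- draw_case_time(p$n_pairs)
  time[is_case == 0L] <- truncnorm::rtruncnorm(
    p$n_pairs, a = p$control_followup_min, b = Inf,
    mean = p$control_followup_mean, sd = p$control_followup_sd)

  # pair-level covariates, shared within pair with small jitter
  pair_age <- pmin(pmax(rnorm(p$n_pairs, 61, 10), 33), 88)
  pair_size <- pmin(pmax(rnorm(p$n_pairs, 22, 8), 4), 50)
  pair_er <- sample(c("pos", "neg", "na"), p$n_pairs, TRUE,
                    prob = c(0.64, 0.29, 0.07))
  pair_pr <- sample(c("pos", "neg", "na"), p$n_pairs, TRUE,
                    prob = c(0.55, 0.35, 0.10))
  pair_grade <- sample(c("1", "2", "3", "na"), p$n_pairs, TRUE,
                       prob = c(0.17, 0.33, 0.29, 0.21))
  pair_type <- sample(c("idc", "ilc", "mucinous", "papillary", "metaplasia"),
                      p$n_pairs, TRUE, prob = c(0.80, 0.11, 0.03, 0.03, 0.03))
  pair_year <- sample(1980:2003, p$n_pairs, TRUE)
  jitter_in <- function(x, amt, lo, hi)
    pmin(pmax(x + runif(p$n_pairs, -amt, amt), lo), hi)

  pair_id <- sprintf("P%03d", seq_len(p$n_pairs))
  clin_pair <- function(ids, ev, tm, age, size) {
    data.frame(sample_id = ids, event = ev, time_months = tm,
               age_years = round(age, 1), tumor_size_mm = round(size, 1),
               er_status = pair_er, pr_status = pair_pr, grade = pair_grade,
               tumor_type = pair_type, year_of_surgery = pair_year,
               pair_id = pair_id, stringsAsFactors = FALSE)
  }
  clin <- rbind(
    clin_pair(case_ids, 1L, round(time[is_case == 1L], 1), pair_age, pair_size),
    clin_pair(ctrl_ids, 0L, round(time[is_case == 0L], 1),
              jitter_in(pair_age, 3, 33, 88), jitter_in(pair_size, 3, 4, 50)))
  clin <- clin[match(sample_ids, clin$sample_id), ]

  cohort <- assemble_cohort(expr, clin,
                            data.frame(case = case_ids, control = ctrl_ids,
                                       stringsAsFactors = FALSE))
  truth <- list(
    informative_features = informative,
    latent_score = setNames(score, sample_ids),
    indolent = setNames(indolent, sample_ids),
    pair_covariates = data.frame(
      pair_id = pair_id, age_years = pair_age, tumor_size_mm = pair_size,
      er_status = pair_er, pr_status = pair_pr, grade = pair_grade,
      tumor_type = pair_type, year_of_surgery = pair_year,
      stringsAsFactors = FALSE))
  list(cohort = cohort, truth = truth)
}

#' Matching specification for greedy case-control pairing
#'
#' @param exact_on categorical covariates that must be equal within a pair
#'   (default: tumor type, ER status, grade).
#' @param caliper_on named numeric vector of maximum absolute differences
#'   for continuous covariates (default: age +/- 10 years, tumor size
#'   +/- 10 mm, year of surgery +/- 5).
#' @return list of class `mirvote_match_spec`.
#' @export
match_spec <- function(exact_on = c("tumor_type", "er_status", "grade"),
                       caliper_on = c(age_years = 10, tumor_size_mm = 10,
                                      year_of_surgery = 5)) {
  if (any(caliper_on <= 0)) stop("calipers must be positive")
  structure(list(exact_on = exact_on, caliper_on = caliper_on),
            class = "mirvote_match_spec")
}

#' Greedily match cases to controls on clinical covariates
#'
#' Cases are processed in input order; each is matched to the not-yet-used
#' control that satisfies all exact constraints and calipers and minimizes
#' the sum of caliper-normalized absolute differences, ties broken by
#' control input order. Pairing cases to clinically look-alike controls is
#' what decouples the expression-based classifier from the classical
#' markers.
#'
#' @param clinical clinical data.frame (see [validate_clinical()]).
#' @param spec a [match_spec()].
#' @return list with `pairs` (data.frame `case`, `control`; zero rows if
#'   nothing matched) and `unmatched` (character vector of sample ids).
#' @export
match_pairs <- function(clinical, spec = match_spec()) {
  cl <- validate_clinical(clinical)
  cases <- cl[cl$event == 1L, ]
  ctrls <- cl[cl$event == 0L, ]
  if (nrow(cases) == 0 || nrow(ctrls) == 0)
    stop("need at least one case and one control to match")
  used <- logical(nrow(ctrls))
  res_case <- character(0); res_ctrl <- character(0)
  for (i in seq_len(nrow(cases))) {
    ok <- !used
    for (v in spec$exact_on)
      ok <- ok & ctrls[[v]] == cases[[v]][i]
    dist <- rep(0, nrow(ctrls))
    for (v in names(spec$caliper_on)) {
      d <- abs(ctrls[[v]] - cases[[v]][i])
      ok <- ok & d <= spec$caliper_on[[v]]
      dist <- dist + d / spec$caliper_on[[v]]
    }
    if (any(ok)) {
      j <- which(ok)[which.min(dist[ok])]  # which.min is first-wins: tie rule
      used[j] <- TRUE
      res_case <- c(res_case, cases$sample_id[i])
      res_ctrl <- c(res_ctrl, ctrls$sample_id[j])
    }
  }
  unmatched <- c(setdiff(cases$sample_id, res_case),
                 ctrls$sample_id[!used])
  list(pairs = data.frame(case = res_case, control = res_ctrl,
                          stringsAsFactors = FALSE),
       unmatched = unmatched)
}
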