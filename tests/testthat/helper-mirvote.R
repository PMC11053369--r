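# Small cohorts built in code; no fixture files.

tiny_sim <- function(n_pairs = 6, n_features = 30, n_informative = 10,
                     delta = 0, seed = 1, ...) {
  simulate_cohort(sim_params(n_pairs = n_pairs, n_features = n_features,
                             n_informative = min(n_informative, n_features),
                             delta = delta, seed = seed, ...))
}

# Hand-built 2-pair cohort (4 samples, 3 features) for plumbing tests.
toy_cohort <- function() {
  expr <- matrix(c(1, 2, 3, 4,
                   5, 6, 7, 8,
                   2, 1, 4, 3), 3, 4, byrow = TRUE,
                 dimnames = list(c("hsa-miR-212-3p", "hsa-miR-640",
                                   "hsa-miR-942-5p"),
                                 c("S1", "S2", "S3", "S4")))
  clin <- data.frame(
    sample_id = c("S1", "S2", "S3", "S4"),
    event = c(1L, 0L, 1L, 0L),
    time_months = c(36.5, 250, 48, 260),
    age_years = c(55, 56, 61, 60),
    tumor_size_mm = c(22, 21, 30, 31),
    er_status = c("pos", "pos", "neg", "neg"),
    pr_status = c("pos", "pos", "neg", "neg"),
    grade = c("2", "2", "3", "3"),
    tumor_type = c("idc", "idc", "ilc", "ilc"),
    year_of_surgery = c(1992L, 1992L, 1995L, 1995L),
    pair_id = c("P1", "P1", "P2", "P2"),
    stringsAsFactors = FALSE)
  pairs <- data.frame(case = c("S1", "S3"), control = c("S2", "S4"),
                      stringsAsFactors = FALSE)
  assemble_cohort(expr, clin, pairs)
}

# Brute-force BH step-up by the definition q_(i) = min_{j>=i} p_(j)*m/j.
bh_brute <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- numeric(m)
  for (i in seq_len(m)) {
    q[i] <- min(1, min(ps[i:m] * m / (i:m)))
  }
  q[order(o)]
}

# Exhaustive one-tailed Fisher: enumerate every table with the same
# margins and sum the probabilities of tables at least as enriched.
fisher_brute <- function(a, b, c, d) {
  rs <- a + b; cs <- a + c; n <- a + b + c + d
  amin <- max(0, rs + cs - n); amax <- min(rs, cs)
  probs <- vapply(amin:amax, function(x) {
    choose(cs, x) * choose(n - cs, rs - x) / choose(n, rs)
  }, numeric(1))
  sum(probs[(amin:amax) >= a])
}

# Hand product-limit estimator (steps at event times only).
km_brute <- function(time, event) {
  ut <- sort(unique(time[event == 1]))
  s <- 1
  out <- data.frame(time = numeric(0), surv = numeric(0))
  for (t in ut) {
    n_risk <- sum(time >= t)
    d <- sum(time == t & event == 1)
    s <- s * (1 - d / n_risk)
    out <- rbind(out, data.frame(time = t, surv = s))
  }
  out
}
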