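# Soft-margin SVM via the dual quadratic program (quadprog), linear or RBF
# kernel, with Platt scaling for probability outputs. Internal: the
# environment provides no SVM package, so the classifier is built on the
# standard dual formulation.

.kernel_matrix <- function(X1, X2, kernel, gamma) {
  if (kernel == "linear") return(X1 %*% t(X2))
  # RBF: exp(-gamma * ||x - y||^2)
  d2 <- outer(rowSums(X1^2), rowSums(X2^2), "+") - 2 * X1 %*% t(X2)
  exp(-gamma * pmax(d2, 0))
}

# median heuristic for the RBF width: gamma = 1 / (2 * median(||xi-xj||)^2)
.median_heuristic_gamma <- function(X) {
  d <- as.numeric(stats::dist(X))
  d <- d[d > 0]
  if (!length(d)) return(1)
  1 / (2 * stats::median(d)^2)
}

.svm_fit <- function(X, y01, kernel = c("rbf", "linear"), cost = 1,
                     gamma = NULL) {
  kernel <- match.arg(kernel)
  y <- ifelse(y01 == 1, 1, -1)
  n <- nrow(X)
  if (kernel == "rbf" && is.null(gamma)) gamma <- .median_heuristic_gamma(X)
  K <- .kernel_matrix(X, X, kernel, gamma)
  # dual: max sum(a) - 1/2 a' (yy' * K) a, 0 <= a <= C, sum(a y) = 0
  D <- (y %o% y) * K
  diag(D) <- diag(D) + 1e-8  # ridge for positive definiteness
  A <- cbind(y, diag(n), -diag(n))
  b0 <- c(0, rep(0, n), rep(-cost, n))
  sol <- quadprog::solve.QP(Dmat = D, dvec = rep(1, n), Amat = A,
                            bvec = b0, meq = 1)
  alpha <- pmin(pmax(sol$solution, 0), cost)
  sv <- alpha > 1e-6
  f0 <- as.numeric(K %*% (alpha * y))
  margin <- sv & alpha < cost - 1e-6
  b <- if (any(margin)) mean(y[margin] - f0[margin]) else {
    # no free SVs: midpoint between the class-extreme decision values
    -(max(f0[y == -1]) + min(f0[y == 1])) / 2
  }
  decision <- f0 + b
  platt <- .platt_fit(decision, y01)
  list(kernel = kernel, gamma = gamma, cost = cost,
       alpha_y = (alpha * y)[sv], sv_x = X[sv, , drop = FALSE], b = b,
       platt = platt, train_decision = decision)
}

.svm_decision <- function(fit, X) {
  K <- .kernel_matrix(X, fit$sv_x, fit$kernel, fit$gamma)
  as.numeric(K %*% fit$alpha_y) + fit$b
}

# Platt (1999) sigmoid calibration: P(y=1|f) = 1/(1+exp(A f + B)),
# fit by minimizing cross-entropy against the smoothed targets
# t+ = (N+ + 1)/(N+ + 2), t- = 1/(N- + 2).
.platt_fit <- function(decision, y01) {
  np <- sum(y01 == 1); nn <- sum(y01 == 0)
  t <- ifelse(y01 == 1, (np + 1) / (np + 2), 1 / (nn + 2))
  nll <- function(par) {
    z <- par[1] * decision + par[2]
    # stable log(1+exp(z)) and cross-entropy in terms of z
    lse <- ifelse(z > 0, z + log1p(exp(-z)), log1p(exp(z)))
    sum(t * lse + (1 - t) * (lse - z))
  }
  start <- c(-1, log((nn + 1) / (np + 1)))
  fit <- optim(start, nll, method = "BFGS",
               control = list(maxit = 200, reltol = 1e-10))
  fit$par
}

.platt_prob <- function(par, decision) {
  1 / (1 + exp(par[1] * decision + par[2]))
}
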