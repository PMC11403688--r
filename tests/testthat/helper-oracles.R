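# Independent numerical oracles used to cross-check the package's solvers.
# These deliberately use different algorithms from the implementation:
# proximal-gradient (FISTA) methods and direct summation formulas.

# soft-threshold operator
st_soft <- function(z, t) sign(z) * pmax(abs(z) - t, 0)

# FISTA solver for the graphical-lasso problem:
# minimize -logdet(Theta) + tr(S Theta) + rho * ||Theta||_1 over SPD Theta.
# Backtracking keeps iterates positive definite. Small p only.
oracle_glasso <- function(S, rho, penalize_diag = TRUE, max_iter = 20000,
                          tol = 1e-12) {
  p <- nrow(S)
  fval <- function(Th) {
    ch <- tryCatch(chol(Th), error = function(e) NULL)
    if (is.null(ch)) return(Inf)
    pen <- sum(abs(Th))
    if (!penalize_diag) pen <- pen - sum(abs(diag(Th)))
    -2 * sum(log(diag(ch))) + sum(S * Th) + rho * pen
  }
  gsmooth <- function(Th) S - solve(Th)  # gradient of -logdet + tr(S .)
  proxop <- function(Th, step) {
    out <- st_soft(Th, step * rho)
    if (!penalize_diag) diag(out) <- diag(Th)
    (out + t(out)) / 2
  }
  Th <- diag(1 / (diag(S) + rho), p)
  Y <- Th
  tk <- 1
  L <- 1
  f_old <- fval(Th)
  for (it in seq_len(max_iter)) {
    G <- gsmooth(Y)
    repeat {
      cand <- proxop(Y - G / L, 1 / L)
      fc <- fval(cand)
      if (is.finite(fc)) {
        # sufficient-decrease check on the smooth part
        diffm <- cand - Y
        q <- fval(Y) - rho * (sum(abs(Y)) - if (!penalize_diag) sum(abs(diag(Y))) else 0) +
          sum(G * diffm) + L / 2 * sum(diffm^2) +
          rho * (sum(abs(cand)) - if (!penalize_diag) sum(abs(diag(cand))) else 0)
        if (fc <= q + 1e-12) break
      }
      L <- L * 2
      if (L > 1e12) break
    }
    t_new <- (1 + sqrt(1 + 4 * tk^2)) / 2
    Y <- cand + ((tk - 1) / t_new) * (cand - Th)
    # restart acceleration if the objective went up
    if (fc > f_old) Y <- cand
    delta <- abs(f_old - fc)
    Th <- cand
    tk <- t_new
    f_old <- fc
    if (delta < tol && it > 10) break
  }
  list(theta = Th, objective = -fval(Th))  # on the maximization scale
}

# Breslow partial log-likelihood and its gradient, by direct summation
oracle_cox_loglik <- function(beta, x, time, status) {
  eta <- as.numeric(x %*% beta)
  ll <- 0
  for (i in seq_along(time)) {
    if (status[i] == 1) {
      risk <- which(time >= time[i])
      ll <- ll + eta[i] - log(sum(exp(eta[risk])))
    }
  }
  ll
}

oracle_cox_grad <- function(beta, x, time, status) {
  eta <- as.numeric(x %*% beta)
  g <- numeric(ncol(x))
  for (i in seq_along(time)) {
    if (status[i] == 1) {
      risk <- which(time >= time[i])
      w <- exp(eta[risk])
      g <- g + x[i, ] - colSums(x[risk, , drop = FALSE] * w) / sum(w)
    }
  }
  g
}

# FISTA solver for the lasso Cox problem on glmnet's scale:
# minimize -(1/n) loglik(beta) + lambda * ||beta||_1
oracle_cox_lasso <- function(x, time, status, lambda, max_iter = 50000,
                             tol = 1e-13) {
  n <- nrow(x)
  f <- function(b) -oracle_cox_loglik(b, x, time, status) / n +
    lambda * sum(abs(b))
  gr <- function(b) -oracle_cox_grad(b, x, time, status) / n
  b <- numeric(ncol(x))
  y <- b
  tk <- 1
  L <- 1
  f_old <- f(b)
  for (it in seq_len(max_iter)) {
    g <- gr(y)
    repeat {
      cand <- st_soft(y - g / L, lambda / L)
      d <- cand - y
      lhs <- -oracle_cox_loglik(cand, x, time, status) / n
      rhs <- -oracle_cox_loglik(y, x, time, status) / n + sum(g * d) +
        L / 2 * sum(d^2)
      if (lhs <= rhs + 1e-14) break
      L <- L * 2
      if (L > 1e14) break
    }
    t_new <- (1 + sqrt(1 + 4 * tk^2)) / 2
    y <- cand + ((tk - 1) / t_new) * (cand - b)
    fc <- f(cand)
    if (fc > f_old) y <- cand
    delta <- abs(f_old - fc)
    b <- cand
    tk <- t_new
    f_old <- fc
    if (delta < tol && it > 10) break
  }
  list(beta = b, objective = f(b))
}

# two-group log-rank chi-square by direct O/E/V summation over event times
oracle_logrank <- function(time, status, group) {
  group <- as.factor(group)
  lv <- levels(group)
  ev_times <- sort(unique(time[status == 1]))
  o1 <- e1 <- v <- 0
  for (t in ev_times) {
    at_risk <- time >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & group == lv[1])
    d <- sum(status == 1 & time == t)
    d1 <- sum(status == 1 & time == t & group == lv[1])
    o1 <- o1 + d1
    e1 <- e1 + d * n1 / n
    if (n > 1) v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  (o1 - e1)^2 / v
}

# Kolmogorov distance of a sample from Uniform(0, 1)
ks_uniform <- function(p) {
  p <- sort(p)
  n <- length(p)
  max(pmax(abs(p - seq_len(n) / n), abs(p - (seq_len(n) - 1) / n)))
}
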