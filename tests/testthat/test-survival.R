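test_that("the events-per-variable cap is the ceiling of events/10", {
  expect_identical(compute_pmax(233), 24L)
  expect_identical(compute_pmax(226), 23L)
  expect_identical(compute_pmax(10), 1L)
  expect_identical(compute_pmax(11), 2L)
  expect_error(compute_pmax(0), "count")
})

test_that("partial log-likelihood matches closed forms and brute force", {
  # beta = 0: -sum over events of log risk-set size
  x <- matrix(0, 3, 2)
  expect_equal(cox_penalized_loglik(c(0, 0), x, c(1, 2, 3), c(1, 1, 1)),
               -(log(3) + log(2) + log(1)), tolerance = 1e-12)
  expect_equal(-(log(3) + log(2)), -1.7918, tolerance = 1e-4)

  # a single sample with an event has itself as risk set, so the terms cancel
  expect_equal(cox_penalized_loglik(0.7, matrix(1.2, 1, 1), 2, 1), 0,
               tolerance = 1e-12)

  # random instance vs direct-summation oracle (no ties)
  set.seed(9)
  n <- 25
  xr <- matrix(rnorm(n * 3), n)
  tt <- rexp(n)
  st <- rbinom(n, 1, 0.6)
  st[1] <- 1
  b <- rnorm(3) / 2
  expect_equal(cox_penalized_loglik(b, xr, tt, st, lambda = 0),
               oracle_cox_loglik(b, xr, tt, st), tolerance = 1e-12)
  expect_equal(cox_penalized_loglik(b, xr, tt, st, lambda = 0.3),
               oracle_cox_loglik(b, xr, tt, st) - 0.3 * sum(abs(b)),
               tolerance = 1e-12)
  expect_error(cox_penalized_loglik(b, xr, tt, rep(0, n)), "event")
})

test_that("the path starts at lambda_max and activates just below it", {
  set.seed(12)
  n <- 60
  x <- matrix(rnorm(n * 5), n, dimnames = list(NULL, paste0("g", 1:5)))
  tt <- rexp(n, exp(x %*% c(0.6, -0.6, 0, 0, 0)))
  st <- rbinom(n, 1, 0.8)
  path <- cox_lasso_path(x, tt, st, standardize = FALSE, thresh = 1e-12)
  lmax <- glionet:::cox_lambda_max(x, tt, st, standardize = FALSE)
  expect_equal(path$lambda[1], lmax, tolerance = 1e-8)
  expect_equal(path$df[1], 0)

  # at lambda_max * (1 + eps) the solution stays zero; just below, at
  # least one coefficient enters
  pe <- cox_lasso_path(x, tt, st, standardize = FALSE,
                       lambda = c(lmax * 1.01, lmax * 0.95),
                       thresh = 1e-12)
  expect_equal(pe$df[1], 0)
  expect_gte(pe$df[2], 1)
})

test_that("the unpenalized end of the path matches coxph", {
  set.seed(13)
  n <- 50
  x <- matrix(rnorm(n * 2), n, dimnames = list(NULL, c("g1", "g2")))
  tt <- rexp(n, exp(x %*% c(0.5, -0.8)))
  st <- rbinom(n, 1, 0.8)
  path <- cox_lasso_path(x, tt, st, standardize = FALSE,
                         lambda = c(0.2, 0.05, 0), thresh = 1e-14)
  cph <- survival::coxph(survival::Surv(tt, st) ~ x, ties = "breslow")
  expect_equal(unname(path$beta[, 3]), unname(coef(cph)), tolerance = 1e-4)
})

test_that("penalized solutions attain the convex optimum", {
  set.seed(14)
  n <- 40
  x <- matrix(rnorm(n * 5), n, dimnames = list(NULL, paste0("g", 1:5)))
  tt <- rexp(n, exp(x %*% c(0.8, -0.8, 0.4, 0, 0)))
  st <- rbinom(n, 1, 0.75)
  st[1] <- 1
  lmax <- glionet:::cox_lambda_max(x, tt, st, standardize = FALSE)
  lam <- lmax / 2
  path <- cox_lasso_path(x, tt, st, standardize = FALSE,
                         lambda = c(lmax, lam), thresh = 1e-14)
  mine <- -oracle_cox_loglik(path$beta[, 2], x, tt, st) / n +
    lam * sum(abs(path$beta[, 2]))
  orc <- oracle_cox_lasso(x, tt, st, lam)
  expect_lt(mine - orc$objective, 1e-6)
  expect_equal(path$beta[, 2], setNames(orc$beta, paste0("g", 1:5)),
               tolerance = 1e-4)
})

test_that("model selection returns the densest model within the cap", {
  fake <- structure(list(beta = cbind(c(0, 0, 0), c(1, 0, 0), c(1, 2, 0),
                                      c(1, 2, 3)),
                         lambda = c(0.8, 0.4, 0.2, 0.1),
                         df = c(0, 1, 2, 3),
                         gene_ids = c("a", "b", "c")),
                    class = "glionet_coxpath")
  expect_equal(select_model(fake, pmax = 2)$lambda, 0.2)
  expect_setequal(select_model(fake, pmax = 2)$active_set, c("a", "b"))
  expect_equal(select_model(fake, pmax = 5)$lambda, 0.1)  # densest model
  expect_warning(m0 <- select_model(fake, pmax = 0), "null")
  expect_equal(unname(m0$beta), c(0, 0, 0))
  # the cap is honored on a real path
  set.seed(15)
  x <- matrix(rnorm(80 * 10), 80, dimnames = list(NULL, paste0("g", 1:10)))
  tt <- rexp(80, exp(x[, 1] - x[, 2]))
  st <- rbinom(80, 1, 0.8)
  path <- cox_lasso_path(x, tt, st)
  for (pm in c(1, 3, 5))
    expect_lte(length(select_model(path, pm)$active_set), pm)
})

test_that("the prognostic index is the linear predictor", {
  model <- structure(list(beta = c(g1 = 0.5, g2 = -1)),
                     class = "glionet_coxmodel")
  x <- matrix(c(1, 2), 1, 2, dimnames = list("s1", c("g1", "g2")))
  expect_equal(prognostic_index(x, model), -1.5)
  expect_equal(prognostic_index(2 * x, model), -3)  # linearity
  model0 <- structure(list(beta = c(g1 = 0, g2 = 0)),
                      class = "glionet_coxmodel")
  expect_equal(prognostic_index(x, model0), 0)
  expect_error(prognostic_index(x[, 1, drop = FALSE], model), "missing")
})

test_that("the KDE threshold falls between modes and defaults to median", {
  set.seed(16)
  pi_bi <- c(rnorm(250, -2, 0.5), rnorm(250, 2, 0.5))
  thr <- kde_threshold(pi_bi)
  expect_equal(attr(thr, "method"), "kde-minimum")
  expect_gt(thr, -1)
  expect_lt(thr, 1)

  set.seed(17)
  pi_uni <- rnorm(400)
  thr2 <- kde_threshold(pi_uni)
  expect_equal(attr(thr2, "method"), "median")
  expect_equal(as.numeric(thr2), median(pi_uni))

  # imbalanced mixture: the valley, not the median
  set.seed(18)
  pi_imb <- c(rnorm(200, -3, 0.3), rnorm(600, 1, 0.3))
  thr3 <- kde_threshold(pi_imb)
  expect_equal(attr(thr3, "method"), "kde-minimum")
  expect_gt(thr3, -2.5)
  expect_lt(thr3, 0.5)
  expect_gt(abs(thr3 - median(pi_imb)), 0.5)

  expect_error(kde_threshold(rep(1, 20)), "constant")
  expect_error(kde_threshold(rnorm(5)), "10")
})

test_that("stratification puts the threshold boundary in the low-risk group", {
  s <- stratify(c(-1, 0, 1), threshold = 0)
  expect_equal(as.character(s$group), c("LR", "LR", "HR"))
  expect_true(all(stratify(c(1, 2), Inf)$group == "LR"))
  expect_true(all(stratify(c(1, 2), 0)$group == "HR"))
})

test_that("Kaplan-Meier estimates match the hand-computed product limit", {
  km <- km_estimate(c(1, 2, 3), c(1, 1, 0), rep("all", 3))
  expect_equal(km$surv, c(2 / 3, 1 / 3, 1 / 3), tolerance = 1e-12)

  km0 <- km_estimate(c(1, 2, 3), c(0, 0, 0), rep("all", 3))
  expect_true(all(km0$surv == 1))

  km1 <- km_estimate(1:4, rep(1, 4), rep("all", 4))
  expect_equal(km1$surv[4], 0)
  # right-continuous non-increasing step function within [0, 1]
  expect_true(all(diff(km1$surv) <= 0))
  expect_true(all(km1$surv >= 0 & km1$surv <= 1))
})

test_that("log-rank agrees with the direct O/E/V computation", {
  tt <- c(1, 2, 3, 4)
  st <- rep(1, 4)
  gr <- c("a", "a", "b", "b")
  res <- logrank_test(tt, st, gr)
  expect_equal(res$statistic, oracle_logrank(tt, st, gr), tolerance = 1e-10)
  expect_equal(res$df, 1L)

  set.seed(19)
  tt2 <- rexp(40)
  st2 <- rbinom(40, 1, 0.7)
  gr2 <- rep(c("a", "b"), 20)
  res2 <- logrank_test(tt2, st2, gr2)
  expect_equal(res2$statistic, oracle_logrank(tt2, st2, gr2),
               tolerance = 1e-8)

  # identical groups: statistic 0, p = 1
  tt3 <- rep(c(1, 2, 3), 2)
  st3 <- rep(c(1, 1, 0), 2)
  gr3 <- rep(c("a", "b"), each = 3)
  res3 <- logrank_test(tt3, st3, gr3)
  expect_equal(res3$statistic, 0, tolerance = 1e-12)
  expect_equal(res3$p.value, 1, tolerance = 1e-12)
  expect_error(logrank_test(tt3, st3, rep("a", 6)), "two")
})

test_that("strong prognostic effects separate the risk groups", {
  sig <- vapply(1:10, function(s) {
    cfg <- sim_config(n_per_type = 200, p = 60, block_sizes = rep(5L, 6),
                      partial_corr = 0.2, n_prognostic = 5,
                      effect_size = 0.5, distort_frac = 0, seed = s)
    coh <- simulate_cohort(cfg)
    x <- npn_transform(coh$expression)
    pm <- compute_pmax(sum(coh$clinical$os_event))
    path <- cox_lasso_path(x, coh$clinical$os_time, coh$clinical$os_event)
    model <- select_model(path, pm)
    pi_v <- prognostic_index(x, model)
    strat <- stratify(pi_v, kde_threshold(pi_v))
    logrank_test(coh$clinical$os_time, coh$clinical$os_event,
                 strat$group)$p.value
  }, numeric(1))
  expect_true(all(sig < 0.05))
})
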