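#' Events-per-variable cap on the number of Cox predictors
#'
#' The 10-EPV rule of thumb: the maximum number of candidate predictors is
#' the ceiling of the number of observed events divided by 10.
#'
#' @param n_events number of samples with the outcome event (>= 1).
#' @return integer cap `ceiling(n_events / 10)`.
#' @export
compute_pmax <- function(n_events) {
  if (length(n_events) != 1 || is.na(n_events) || n_events < 1)
    stop("n_events must be a single count >= 1")
  as.integer(ceiling(n_events / 10))
}

#' Penalized Cox partial log-likelihood
#'
#' Breslow-form partial log-likelihood
#' `sum_i delta_i x_i' beta - sum_t d_t log(sum_{j: Y_j >= t} exp(x_j' beta))`
#' (the outer sum over distinct event times t with multiplicity d_t),
#' minus the lasso penalty `lambda * sum_k |beta_k|`.
#'
#' @param beta coefficient vector (one per column of `x`).
#' @param x n x p feature matrix.
#' @param time nonnegative survival/censoring times.
#' @param status event indicators (1 = event, 0 = censored); at least one
#'   event.
#' @param lambda nonnegative penalty (0 gives the plain partial
#'   log-likelihood).
#' @return scalar penalized partial log-likelihood.
#' @export
cox_penalized_loglik <- function(beta, x, time, status, lambda = 0) {
  x <- as.matrix(x)
  if (length(beta) != ncol(x)) stop("beta length must match ncol(x)")
  if (length(time) != nrow(x) || length(status) != nrow(x))
    stop("time/status length must match nrow(x)")
  if (!any(status == 1)) stop("at least one event is required")
  eta <- as.numeric(x %*% beta)
  ll <- sum(eta[status == 1])
  ev_times <- sort(unique(time[status == 1]))
  for (t in ev_times) {
    d_t <- sum(status == 1 & time == t)
    risk <- time >= t
    m <- max(eta[risk])
    ll <- ll - d_t * (m + log(sum(exp(eta[risk] - m))))
  }
  ll - lambda * sum(abs(beta))
}

# largest penalty with an all-zero solution, from the null-model score:
# lambda_max = max_k |(1/n) d loglik / d beta_k| at beta = 0 (glmnet's
# internal scale; features standardized first when standardize = TRUE)
cox_lambda_max <- function(x, time, status, standardize = TRUE) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (standardize) {
    mu <- colMeans(x)
    sdv <- sqrt(colMeans(scale(x, center = mu, scale = FALSE)^2))
    x <- scale(x, center = mu, scale = sdv)
  }
  score <- numeric(ncol(x))
  ev_times <- sort(unique(time[status == 1]))
  score <- colSums(x[status == 1, , drop = FALSE])
  for (t in ev_times) {
    d_t <- sum(status == 1 & time == t)
    risk <- time >= t
    score <- score - d_t * colMeans(x[risk, , drop = FALSE])
  }
  max(abs(score)) / n
}

#' Lasso-penalized Cox regression path
#'
#' Fits the l1-penalized Cox proportional-hazards model over a descending
#' lambda grid (log-spaced from the smallest all-zero-solution lambda down
#' to `lambda_min_ratio` times it), with warm starts along the path.
#' Features are standardized to unit variance before fitting and the
#' coefficients returned on the original scale. Ties are handled by the
#' Breslow convention. The fit is delegated to \pkg{glmnet}
#' (`family = "cox"`) behind this interface.
#'
#' @param x n x p feature matrix (column names are the gene ids).
#' @param time,status survival times and event indicators.
#' @param nlambda number of grid points (default 100).
#' @param lambda_min_ratio smallest lambda as a fraction of lambda_max
#'   (default 0.01).
#' @param lambda optional explicit descending lambda sequence.
#' @param standardize standardize features before fitting (default TRUE).
#' @param thresh coordinate-descent convergence threshold passed through.
#' @return object of class `glionet_coxpath`: list with `beta` (p x
#'   nlambda matrix), `lambda`, `df` (active-set sizes), `gene_ids`,
#'   `n_events`, and the underlying `glmnet` fit.
#' @export
cox_lasso_path <- function(x, time, status, nlambda = 100,
                           lambda_min_ratio = 0.01, lambda = NULL,
                           standardize = TRUE, thresh = 1e-10) {
  x <- as.matrix(x)
  if (!any(status == 1)) stop("at least one event is required for fitting")
  if (any(time < 0)) stop("times must be nonnegative")
  y <- survival::Surv(time, status)
  fit <- glmnet::glmnet(x, y, family = "cox", alpha = 1, nlambda = nlambda,
                        lambda.min.ratio = lambda_min_ratio,
                        lambda = lambda, standardize = standardize,
                        thresh = thresh)
  beta <- as.matrix(fit$beta)
  structure(list(beta = beta, lambda = fit$lambda,
                 df = unname(colSums(beta != 0)), gene_ids = rownames(beta),
                 n = nrow(x), n_events = sum(status == 1), glmnet = fit),
            class = "glionet_coxpath")
}

#' Select the densest path model within the EPV cap
#'
#' Returns the model at the smallest lambda whose active-set size does not
#' exceed `pmax` (the all-zero model always qualifies, so a model always
#' exists; `pmax = 0` returns the null model with a warning).
#'
#' @param path a [cox_lasso_path()] object.
#' @param pmax maximum number of active coefficients (see
#'   [compute_pmax()]).
#' @return object of class `glionet_coxmodel`: list with `beta` (full
#'   named vector), `active_set`, `lambda`, `pmax`, `index`.
#' @export
select_model <- function(path, pmax) {
  stopifnot(inherits(path, "glionet_coxpath"))
  if (pmax < 1) {
    warning("pmax < 1: returning the null (all-zero) model")
    beta <- setNames(numeric(length(path$gene_ids)), path$gene_ids)
    return(structure(list(beta = beta, active_set = character(),
                          lambda = path$lambda[1], pmax = as.integer(pmax),
                          index = NA_integer_),
                     class = "glionet_coxmodel"))
  }
  ok <- which(path$df <= pmax)
  idx <- ok[which.min(path$lambda[ok])]
  beta <- setNames(path$beta[, idx], path$gene_ids)
  structure(list(beta = beta,
                 active_set = path$gene_ids[path$beta[, idx] != 0],
                 lambda = path$lambda[idx], pmax = as.integer(pmax),
                 index = idx),
            class = "glionet_coxmodel")
}

#' @export
print.glionet_coxmodel <- function(x, ...) {
  cat(sprintf("glionet Cox model: %d active genes (pmax %d), lambda = %.4g\n",
              length(x$active_set), x$pmax, x$lambda))
  invisible(x)
}

#' Prognostic index
#'
#' The linear predictor `PI_i = x_i' beta` of the fitted Cox model, over
#' the model's full gene set (zero coefficients contribute nothing).
#'
#' @param x samples x genes matrix containing all model genes by name.
#' @param model a [select_model()] result.
#' @return named numeric vector of prognostic indices.
#' @export
prognostic_index <- function(x, model) {
  genes <- names(model$beta)
  if (!all(genes %in% colnames(x)))
    stop("x is missing model genes: ",
         paste(head(setdiff(genes, colnames(x)), 5), collapse = ", "))
  as.numeric(x[, genes, drop = FALSE] %*% model$beta)
}

#' Risk-stratification threshold from the PI density
#'
#' Gaussian-kernel density estimate of the prognostic-index distribution
#' with the rule-of-thumb bandwidth `0.9 min(sd, IQR/1.34) n^{-1/5}` on a
#' 512-point grid spanning the data plus 3 bandwidths. When the density
#' shows two genuine modes, the threshold is the grid argmin of the
#' density between the two highest local maxima (the valley between the
#' two Gaussian peaks of a bimodal PI distribution); otherwise it falls
#' back to the median split.
#'
#' "Two genuine modes" is made robust to the minor spurious maxima that
#' kernel estimates produce on unimodal samples: local maxima below
#' `peak_frac` of the highest peak are ignored, and the split is only
#' accepted when the valley dips below `valley_frac` of the lower of the
#' two peaks. A clean Gaussian sample thus takes the median fallback,
#' while even heavily imbalanced two-component mixtures are split at the
#' valley.
#'
#' @param pi_values numeric vector of prognostic indices, n >= 10.
#' @param peak_frac minimum height of the secondary peak, as a fraction of
#'   the highest peak (default 0.25).
#' @param valley_frac maximum valley height, as a fraction of the lower of
#'   the two peaks (default 0.9).
#' @return the threshold, with attribute `method` set to `"kde-minimum"`
#'   or `"median"`.
#' @export
kde_threshold <- function(pi_values, peak_frac = 0.25, valley_frac = 0.9) {
  pi_values <- as.numeric(pi_values)
  n <- length(pi_values)
  if (n < 10) stop("kde_threshold needs at least 10 values")
  if (max(pi_values) == min(pi_values))
    stop("kde_threshold: constant prognostic index")
  d <- density(pi_values, bw = "nrd0", n = 512, cut = 3)
  y <- d$y
  k <- length(y)
  is_max <- which(y[2:(k - 1)] > y[1:(k - 2)] & y[2:(k - 1)] > y[3:k]) + 1L
  is_max <- is_max[y[is_max] >= peak_frac * max(y[is_max])]
  median_fallback <- function() {
    thr <- median(pi_values)
    attr(thr, "method") <- "median"
    thr
  }
  if (length(is_max) < 2) return(median_fallback())
  top2 <- sort(is_max[order(y[is_max], decreasing = TRUE)][1:2])
  between <- seq(top2[1], top2[2])
  valley <- which.min(y[between])
  if (y[between[valley]] > valley_frac * min(y[top2]))
    return(median_fallback())
  thr <- d$x[between[valley]]
  attr(thr, "method") <- "kde-minimum"
  thr
}

#' Stratify samples into high- and low-risk groups
#'
#' Low risk iff `PI <= threshold`; high risk otherwise (the boundary is
#' low risk).
#'
#' @param pi_values prognostic indices.
#' @param threshold the PI threshold (see [kde_threshold()]).
#' @return object of class `glionet_strat`: list with `pi`, `threshold`
#'   and `group` (factor with levels LR, HR).
#' @export
stratify <- function(pi_values, threshold) {
  group <- factor(ifelse(pi_values <= threshold, "LR", "HR"),
                  levels = c("LR", "HR"))
  structure(list(pi = pi_values, threshold = as.numeric(threshold),
                 group = group, method = attr(threshold, "method")),
            class = "glionet_strat")
}

#' @export
print.glionet_strat <- function(x, ...) {
  tb <- table(x$group)
  cat(sprintf("glionet risk stratification: LR %d, HR %d (threshold %.4g%s)\n",
              tb[["LR"]], tb[["HR"]], x$threshold,
              if (!is.null(x$method)) paste0(", ", x$method) else ""))
  invisible(x)
}

#' Kaplan-Meier survival curves per group
#'
#' Product-limit estimator `S(t) = prod_{t_k <= t} (1 - d_k / n_k)` for
#' each group, via \pkg{survival}.
#'
#' @param time,status survival times and event indicators.
#' @param group per-sample group labels (each group nonempty).
#' @return data frame with columns `group`, `time`, `n_risk`, `n_event`,
#'   `n_censor`, `surv`; the underlying `survfit` object is attached as
#'   attribute `"survfit"`.
#' @export
km_estimate <- function(time, status, group) {
  group <- as.factor(group)
  if (any(table(group) == 0)) stop("every group must be nonempty")
  df <- data.frame(time = time, status = status, group = group)
  sf <- survival::survfit(survival::Surv(time, status) ~ group, data = df)
  if (is.null(sf$strata)) {
    grp <- rep(levels(group)[1], length(sf$time))
  } else {
    grp <- rep(sub("^group=", "", names(sf$strata)), sf$strata)
  }
  out <- data.frame(group = grp, time = sf$time, n_risk = sf$n.risk,
                    n_event = sf$n.event, n_censor = sf$n.censor,
                    surv = sf$surv, stringsAsFactors = FALSE)
  attr(out, "survfit") <- sf
  out
}

#' Two-group log-rank test
#'
#' Standard log-rank chi-square with 1 degree of freedom comparing the
#' survival distributions of exactly two groups, via \pkg{survival}.
#'
#' @param time,status survival times and event indicators.
#' @param group per-sample labels with exactly two nonempty groups.
#' @return list with `statistic`, `df` (1), `p.value`, `alpha` (0.05).
#' @export
logrank_test <- function(time, status, group) {
  group <- droplevels(as.factor(group))
  if (nlevels(group) != 2)
    stop("logrank_test needs exactly two nonempty groups")
  df <- data.frame(time = time, status = status, group = group)
  sd <- survival::survdiff(survival::Surv(time, status) ~ group, data = df)
  stat <- unname(sd$chisq)
  list(statistic = stat, df = 1L,
       p.value = pchisq(stat, df = 1, lower.tail = FALSE), alpha = 0.05)
}
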