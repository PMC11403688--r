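test_that("empirical covariance matches direct summation", {
  set.seed(7)
  x <- matrix(rnorm(15), 5, 3, dimnames = list(NULL, c("a", "b", "c")))
  s <- empirical_covariance(x)
  brute <- matrix(0, 3, 3)
  for (i in 1:3) for (j in 1:3)
    brute[i, j] <- mean((x[, i] - mean(x[, i])) * (x[, j] - mean(x[, j])))
  expect_equal(unname(s), brute, tolerance = 1e-12)

  # duplicated column: off-diagonal equals the diagonal
  x2 <- cbind(a = x[, 1], b = x[, 1])
  s2 <- empirical_covariance(x2)
  expect_equal(s2[1, 2], s2[1, 1], tolerance = 1e-12)

  # unit-variance input has diagonal (n-1)/n under the 1/n normalization
  xn <- npn_transform(matrix(rnorm(50 * 2), 50, 2,
                             dimnames = list(NULL, c("a", "b"))))
  expect_equal(unname(diag(empirical_covariance(xn))), rep(49 / 50, 2),
               tolerance = 1e-10)
  expect_error(empirical_covariance(x[1, , drop = FALSE]), "2 samples")
})

test_that("glasso reproduces the diagonal-S closed form", {
  fit <- glasso_fit(diag(3), rho = 0.9)
  expect_equal(unname(diag(fit$theta)), rep(1 / 1.9, 3), tolerance = 1e-8)
  expect_equal(max(abs(fit$theta - diag(diag(fit$theta)))), 0)
})

test_that("the 2x2 no-edge condition |s12| <= rho holds exactly", {
  s <- matrix(c(1, 0.5, 0.5, 1), 2)
  fit <- glasso_fit(s, rho = 0.9)
  expect_identical(fit$theta[1, 2], 0)
  # just below the boundary an edge appears
  fit2 <- glasso_fit(s, rho = 0.49, tol = 1e-9)
  expect_gt(abs(fit2$theta[1, 2]), 0)
})

test_that("glasso solutions satisfy the KKT conditions and are SPD", {
  for (s in 1:10) {
    set.seed(s)
    p <- sample(3:6, 1)
    a <- matrix(rnorm(p * p), p)
    S <- crossprod(a) / p + 0.1 * diag(p)
    fit <- glasso_fit(S, rho = 0.3, tol = 1e-9)
    expect_lt(glasso_kkt_residual(fit$theta, S, 0.3), 1e-6)
    ev <- eigen(fit$theta, symmetric = TRUE, only.values = TRUE)$values
    expect_gt(min(ev), 0)
    expect_equal(fit$theta, t(fit$theta))
  }
})

test_that("off-diagonal-only penalization leaves the diagonal unshrunk", {
  set.seed(3)
  a <- matrix(rnorm(16), 4)
  S <- crossprod(a) / 4 + 0.2 * diag(4)
  fit <- glasso_fit(S, rho = 0.25, penalize_diag = FALSE, tol = 1e-9)
  expect_lt(glasso_kkt_residual(fit$theta, S, 0.25, penalize_diag = FALSE),
            1e-6)
  # diagonal of the inverse matches S exactly when unpenalized
  expect_equal(unname(diag(fit$w)), unname(diag(S)), tolerance = 1e-6)
})

test_that("edge count is non-increasing in rho", {
  cfg <- sim_config(n_per_type = 60, p = 30, block_sizes = rep(5L, 4),
                    partial_corr = 0.2, distort_frac = 0, seed = 17)
  coh <- simulate_cohort(cfg)
  S <- empirical_covariance(npn_transform(coh$expression))
  counts <- vapply(seq(0.05, 0.6, by = 0.05), function(r) {
    th <- glasso_fit(S, r)$theta
    sum(abs(th[upper.tri(th)]) > 1e-8)
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
  expect_gt(counts[1], counts[length(counts)])
})

test_that("connected-gene selection follows the off-diagonal support", {
  th <- diag(0.5, 4)
  dimnames(th) <- list(paste0("g", 1:4), paste0("g", 1:4))
  fit <- structure(list(theta = th, gene_ids = rownames(th)),
                   class = "glionet_glasso")
  expect_length(select_connected(fit), 0)

  th[1, 2] <- th[2, 1] <- -0.2
  fit$theta <- th
  expect_setequal(select_connected(fit), c("g1", "g2"))

  th[2, 3] <- th[3, 2] <- 0.1
  fit$theta <- th
  expect_setequal(select_connected(fit), c("g1", "g2", "g3"))
})

test_that("hub measures sum absolute weights and count partners", {
  th <- diag(1, 4)
  dimnames(th) <- list(paste0("g", 1:4), paste0("g", 1:4))
  th[1, 2] <- th[2, 1] <- 0.5
  th[1, 3] <- th[3, 1] <- -0.2
  fit <- structure(list(theta = th, gene_ids = rownames(th)),
                   class = "glionet_glasso")
  tbl <- hub_scores(fit)
  expect_equal(tbl$weight[tbl$gene_id == "g1"], 0.7)
  expect_equal(tbl$count[tbl$gene_id == "g1"], 2L)
  expect_false("g4" %in% tbl$gene_id)  # isolated genes are not ranked

  # weight measure is sign-invariant
  fit2 <- fit
  fit2$theta <- -th + 2 * diag(diag(th))
  expect_equal(hub_scores(fit2)$weight, tbl$weight)
})

test_that("percentile rescaling spaces ranks uniformly on [0, 100]", {
  expect_equal(percentile_rescale(c(1, 2, 3, 4, 5)), c(0, 25, 50, 75, 100))
  expect_equal(percentile_rescale(rep(2, 4)), rep(50, 4))  # average ranks
  expect_equal(percentile_rescale(c(7, 3)), c(100, 0))
  expect_equal(percentile_rescale(5), 100)
})

test_that("hubs are the union of the two measure-specific subsets", {
  tbl <- data.frame(gene_id = c("g1", "g2", "g3"),
                    weight_pct = c(0, 70, 100), count_pct = c(100, 0, 50))
  expect_setequal(identify_hubs(tbl, t = 60), c("g1", "g2", "g3"))
  expect_length(identify_hubs(tbl, t = 100), 0)
  expect_error(identify_hubs(tbl, t = 101), "0, 100")
})

test_that("set comparison reports exclusives, shared and percentages", {
  cmp <- compare_sets(c("a", "b", "c"), c("b", "c", "d"))
  expect_equal(cmp$n_a_only, 1)
  expect_equal(cmp$n_shared, 2)
  expect_equal(cmp$n_b_only, 1)
  expect_equal(cmp$pct_a_only, 100 / 3, tolerance = 1e-12)
  expect_equal(cmp$pct_b_only, 100 / 3, tolerance = 1e-12)

  same <- compare_sets(c("a", "b"), c("a", "b"))
  expect_equal(c(same$n_a_only, same$n_shared, same$n_b_only), c(0, 2, 0))
  expect_equal(compare_sets("x", "y")$n_shared, 0)
})

test_that("rank cross-check bands combined percentiles in thirds", {
  other <- data.frame(gene_id = c("gA", "gB", "gC"),
                      weight_pct = c(4, 100, 40), count_pct = c(4, 100, 60))
  other$combined_pct <- (other$weight_pct + other$count_pct) / 2
  cc <- rank_crosscheck(c("gA", "gB", "gC", "gZ"), other)
  expect_equal(cc$combined_pct, c(4, 100, 50, NA))
  expect_equal(cc$band, c("low", "top", "middle", "not selected"))
})

test_that("per-type selection keeps hubs inside the selected sets", {
  cfg <- sim_config(n_per_type = 80, p = 40, block_sizes = rep(4L, 8),
                    partial_corr = 0.25, distort_frac = 0.2, seed = 23)
  coh <- simulate_cohort(cfg)
  x <- npn_transform(coh$expression)
  sel <- network_selection(x, coh$clinical$type_2021, rho = 0.3)
  for (tp in sel$types) {
    pt <- sel$per_type[[tp]]
    expect_true(all(pt$hubs %in% pt$selected))
    expect_true(all(pt$exclusive %in% pt$selected))
  }
})

test_that("network export writes consistent edge and node files", {
  dir <- withr::local_tempdir()
  set.seed(2)
  a <- matrix(rnorm(25), 5)
  S <- crossprod(a) / 5 + 0.2 * diag(5)
  dimnames(S) <- list(paste0("g", 1:5), paste0("g", 1:5))
  fit <- glasso_fit(S, rho = 0.1)
  paths <- export_network(fit, dir, prefix = "t",
                          highlights = list(hub = "g1"))
  edges <- read.delim(paths[["edges"]])
  th <- fit$theta
  expect_equal(nrow(edges), sum(abs(th[upper.tri(th)]) > 1e-8))
  nodes <- read.delim(paths[["nodes"]])
  expect_equal(nodes$category[nodes$gene_id == "g1"], "hub")
  g <- igraph::read_graph(paths[["graphml"]], format = "graphml")
  expect_equal(igraph::gorder(g), 5)
  expect_equal(igraph::gsize(g), nrow(edges))

  # a diagonal estimate exports an empty edge list
  fitd <- glasso_fit(diag(3), rho = 0.5)
  pd <- export_network(fitd, dir, prefix = "d")
  expect_equal(nrow(read.delim(pd[["edges"]])), 0)
})
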