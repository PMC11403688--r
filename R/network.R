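#' Empirical covariance matrix
#'
#' Population-normalized covariance `S = (1/n) Xc' Xc` with column-centered
#' `Xc` (the form entering the graphical-lasso likelihood; degenerate-safe
#' for n close to p).
#'
#' @param x samples x genes matrix with at least 2 rows.
#' @return p x p symmetric covariance matrix with gene dimnames.
#' @export
empirical_covariance <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (n < 2) stop("empirical_covariance needs at least 2 samples")
  xc <- scale(x, center = TRUE, scale = FALSE)
  s <- crossprod(xc) / n
  s <- (s + t(s)) / 2
  dimnames(s) <- list(colnames(x), colnames(x))
  s
}

#' Graphical lasso precision-matrix estimate
#'
#' Maximizes `log det(Theta) - tr(S Theta) - rho * ||Theta||_1` by block
#' coordinate descent over columns with an inner soft-thresholding lasso
#' solve (compiled). The l1 norm is taken over all entries, so the diagonal
#' is penalized by default; connectivity-based selection depends only on
#' the off-diagonals, and `penalize_diag = FALSE` gives the
#' off-diagonal-only variant for cross-checks.
#'
#' @param s symmetric covariance matrix (see [empirical_covariance()]).
#' @param rho nonnegative regularization parameter; default 0.9, the value
#'   used for the full-transcriptome glioma analysis (data on the
#'   unit-variance nonparanormal scale).
#' @param penalize_diag include the diagonal in the l1 penalty.
#' @param tol convergence tolerance on the maximum absolute change of the
#'   working covariance per sweep; default `1e-5 * mean(|diag(S)|)`.
#' @param max_sweeps iteration cap (error if exceeded).
#' @return object of class `glionet_glasso`: list with `theta` (the
#'   precision estimate), `w` (its inverse as tracked by the solver),
#'   `rho`, `converged`, `n_iter` and `gene_ids`.
#' @export
glasso_fit <- function(s, rho = 0.9, penalize_diag = TRUE, tol = NULL,
                       max_sweeps = 500L) {
  s <- as.matrix(s)
  if (nrow(s) != ncol(s) || max(abs(s - t(s))) > 1e-8)
    stop("s must be a symmetric square matrix")
  if (rho < 0) stop("rho must be nonnegative")
  if (is.null(tol)) tol <- 1e-5 * mean(abs(diag(s)))
  res <- glasso_bcd(s, rho, penalize_diag, tol, as.integer(max_sweeps),
                    inner_tol = tol / 10, inner_max = 10000L)
  genes <- colnames(s)
  if (is.null(genes)) genes <- gene_names(nrow(s))
  dimnames(res$theta) <- list(genes, genes)
  dimnames(res$w) <- list(genes, genes)
  fit <- structure(list(theta = res$theta, w = res$w, rho = rho,
                        penalize_diag = penalize_diag,
                        converged = res$converged, n_iter = res$n_iter,
                        gene_ids = genes), class = "glionet_glasso")
  if (!res$converged) {
    cond <- structure(
      class = c("glionet_glasso_noconv", "error", "condition"),
      list(message = sprintf(
        "graphical lasso did not converge within %d sweeps (residual %.3g > tol %.3g)",
        max_sweeps, res$max_delta, tol),
        call = sys.call(-1), fit = fit, residual = res$max_delta))
    stop(cond)
  }
  fit
}

#' @export
print.glionet_glasso <- function(x, ...) {
  ne <- sum(abs(x$theta[upper.tri(x$theta)]) > 1e-8)
  cat(sprintf("glionet glasso fit: %d genes, rho = %g, %d edges, %d sweeps\n",
              length(x$gene_ids), x$rho, ne, x$n_iter))
  invisible(x)
}

#' Graphical-lasso objective value
#'
#' Evaluates `log det(Theta) - tr(S Theta) - rho ||Theta||_1` (the quantity
#' being maximized); with `penalize_diag = FALSE` the l1 norm runs over the
#' off-diagonal entries only.
#'
#' @param theta precision matrix (positive definite).
#' @param s covariance matrix.
#' @param rho penalty.
#' @param penalize_diag include the diagonal in the penalty.
#' @return scalar objective value.
#' @export
glasso_objective <- function(theta, s, rho, penalize_diag = TRUE) {
  ch <- chol(theta)
  logdet <- 2 * sum(log(diag(ch)))
  pen <- sum(abs(theta))
  if (!penalize_diag) pen <- pen - sum(abs(diag(theta)))
  logdet - sum(s * theta) - rho * pen
}

#' Karush-Kuhn-Tucker residual of a graphical-lasso solution
#'
#' Max-norm violation of the stationarity condition
#' `Theta^{-1} - S = rho * sign(Theta)` on the support and
#' `|Theta^{-1} - S| <= rho` off it.
#'
#' @inheritParams glasso_objective
#' @param zero_tol entries with `|theta| <= zero_tol` count as zero.
#' @return scalar residual (0 at an exact optimum).
#' @export
glasso_kkt_residual <- function(theta, s, rho, penalize_diag = TRUE,
                                zero_tol = 1e-8) {
  g <- solve(theta) - s
  res <- ifelse(abs(theta) > zero_tol,
                abs(g - rho * sign(theta)),
                pmax(0, abs(g) - rho))
  if (!penalize_diag) diag(res) <- abs(diag(g))
  max(res)
}

#' Network-based gene selection: connected nodes
#'
#' Genes with at least one nonzero off-diagonal precision entry; at a high
#' penalty most genes are unconnected, which is what turns the network
#' estimate into a variable-selection device.
#'
#' @param fit a [glasso_fit()] result.
#' @param zero_tol absolute threshold below which an entry counts as zero.
#' @return character vector of selected gene ids.
#' @export
select_connected <- function(fit, zero_tol = 1e-8) {
  th <- fit$theta
  diag(th) <- 0
  fit$gene_ids[rowSums(abs(th) > zero_tol) > 0]
}

#' Hub score table: weight and count measures with percentiles
#'
#' For every selected (connected) gene, the weight measure is the weighted
#' degree `sum_{j != i} |theta_ij|` and the count measure is the number of
#' nonzero off-diagonal partners. Both are rescaled to percentiles over the
#' selected genes with [percentile_rescale()], and the combined percentile
#' is their mean.
#'
#' @inheritParams select_connected
#' @return data frame with columns `gene_id`, `weight`, `count`,
#'   `weight_pct`, `count_pct`, `combined_pct` (selected genes only).
#' @export
hub_scores <- function(fit, zero_tol = 1e-8) {
  th <- fit$theta
  diag(th) <- 0
  nz <- abs(th) > zero_tol
  sel <- rowSums(nz) > 0
  weight <- rowSums(abs(th) * nz)[sel]
  count <- rowSums(nz)[sel]
  tbl <- data.frame(gene_id = fit$gene_ids[sel], weight = unname(weight),
                    count = unname(as.integer(count)),
                    stringsAsFactors = FALSE)
  tbl$weight_pct <- percentile_rescale(tbl$weight)
  tbl$count_pct <- percentile_rescale(tbl$count)
  tbl$combined_pct <- (tbl$weight_pct + tbl$count_pct) / 2
  tbl
}

#' Rescale measures uniformly to \[0, 100\]
#'
#' Ascending average ranks `r_i` are mapped to
#' `p_i = 100 (r_i - 1) / (K - 1)`; a single value maps to 100, and ties
#' share their average rank (so an all-tied vector maps to 50).
#'
#' @param m numeric vector of K >= 1 measures.
#' @return percentiles in \[0, 100\].
#' @export
percentile_rescale <- function(m) {
  k <- length(m)
  if (k == 0) return(numeric())
  if (k == 1) return(100)
  r <- rank(m, ties.method = "average")
  100 * (r - 1) / (k - 1)
}

#' Identify hub genes at a percentile threshold
#'
#' A gene is a hub if its weight percentile or its count percentile exceeds
#' `t` (the union of the two measure-specific hub subsets).
#'
#' @param scores a [hub_scores()] table.
#' @param t percentile threshold in \[0, 100\]; default 60, the value at
#'   which the GBM ranking splits into two clearly separated groups.
#' @return character vector of hub gene ids.
#' @export
identify_hubs <- function(scores, t = 60) {
  if (t < 0 || t > 100) stop("t must be in [0, 100]")
  scores$gene_id[scores$weight_pct > t | scores$count_pct > t]
}

#' Compare two gene sets (Venn-style)
#'
#' @param a,b character vectors of gene ids.
#' @return list with `n_a_only`, `n_shared`, `n_b_only`, the relative
#'   exclusive percentages `pct_a_only = 100 |A \\ B| / |A|` and
#'   `pct_b_only` (NA for empty sets), and the sets themselves.
#' @export
compare_sets <- function(a, b) {
  a <- unique(a); b <- unique(b)
  a_only <- setdiff(a, b); shared <- intersect(a, b); b_only <- setdiff(b, a)
  list(n_a_only = length(a_only), n_shared = length(shared),
       n_b_only = length(b_only),
       pct_a_only = if (length(a)) 100 * length(a_only) / length(a) else NA_real_,
       pct_b_only = if (length(b)) 100 * length(b_only) / length(b) else NA_real_,
       a_only = a_only, shared = shared, b_only = b_only)
}

#' Cross-check gene rankings against another scheme's score table
#'
#' For genes identified (e.g. as exclusive hubs) under one classification
#' scheme, reports their combined percentile in the other scheme's hub
#' score table, banded in thirds: top (>= 66.7), middle (33.3 to 66.7) and
#' low (< 33.3). Genes absent from the other table (not selected there)
#' are flagged as such.
#'
#' @param genes character vector of gene ids to look up.
#' @param other_table a [hub_scores()] table from the other scheme.
#' @return data frame with `gene_id`, `combined_pct`, `band` (one of
#'   "top", "middle", "low", "not selected").
#' @export
rank_crosscheck <- function(genes, other_table) {
  idx <- match(genes, other_table$gene_id)
  pct <- other_table$combined_pct[idx]
  band <- ifelse(is.na(pct), "not selected",
                 ifelse(pct >= 200 / 3, "top",
                        ifelse(pct >= 100 / 3, "middle", "low")))
  data.frame(gene_id = genes, combined_pct = pct, band = band,
             stringsAsFactors = FALSE)
}

#' Per-type graphical-lasso selection under one classification scheme
#'
#' Fits the graphical lasso separately on the samples of each glioma type,
#' selects the connected genes, scores hubs, and derives the per-type
#' exclusive sets (genes selected for exactly one type within the scheme).
#'
#' @param x preprocessed samples x genes matrix.
#' @param types per-sample type labels (character or factor).
#' @param rho graphical-lasso penalty (see [glasso_fit()]).
#' @param hub_t hub percentile threshold (see [identify_hubs()]).
#' @param zero_tol numeric-zero tolerance for edges.
#' @param ... further arguments passed to [glasso_fit()].
#' @return object of class `glionet_selection`: per-type list with `fit`,
#'   `selected`, `scores`, `hubs`, `exclusive`; plus `rho`, `hub_t`.
#' @export
network_selection <- function(x, types, rho = 0.9, hub_t = 60,
                              zero_tol = 1e-8, ...) {
  types <- as.character(types)
  lv <- intersect(glioma_types(), unique(types))
  if (!length(lv)) lv <- sort(unique(types))
  per_type <- lapply(lv, function(tp) {
    xt <- x[types == tp, , drop = FALSE]
    if (nrow(xt) < 2) stop("fewer than 2 samples for type ", tp)
    fit <- glasso_fit(empirical_covariance(xt), rho = rho, ...)
    scores <- hub_scores(fit, zero_tol)
    list(fit = fit, selected = select_connected(fit, zero_tol),
         scores = scores, hubs = identify_hubs(scores, hub_t))
  })
  names(per_type) <- lv
  for (tp in lv) {
    others <- unlist(lapply(setdiff(lv, tp),
                            function(o) per_type[[o]]$selected))
    per_type[[tp]]$exclusive <- setdiff(per_type[[tp]]$selected, others)
  }
  structure(list(per_type = per_type, types = lv, rho = rho, hub_t = hub_t),
            class = "glionet_selection")
}

#' @export
print.glionet_selection <- function(x, ...) {
  cat(sprintf("glionet network selection (rho = %g, hub t = %g)\n",
              x$rho, x$hub_t))
  for (tp in x$types) {
    pt <- x$per_type[[tp]]
    cat(sprintf("  %-18s selected %4d  exclusive %4d  hubs %4d\n", tp,
                length(pt$selected), length(pt$exclusive), length(pt$hubs)))
  }
  invisible(x)
}

#' Export an estimated gene network
#'
#' Writes the nonzero upper-triangle precision entries as an edge list TSV
#' (`gene_a`, `gene_b`, `theta`), a node table TSV with category
#' annotations, and a GraphML file for standard graph tools.
#'
#' @param fit a [glasso_fit()] result.
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix.
#' @param highlights optional named list of gene sets (e.g.
#'   `list(exclusive = ..., survival = ...)`); the node table's `category`
#'   column records the first set containing each gene, else "other".
#' @param zero_tol numeric-zero tolerance for edges.
#' @return invisibly, the written file paths.
#' @export
export_network <- function(fit, dir, prefix = "network", highlights = NULL,
                           zero_tol = 1e-8) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  th <- fit$theta
  ut <- which(upper.tri(th) & abs(th) > zero_tol, arr.ind = TRUE)
  edges <- data.frame(gene_a = fit$gene_ids[ut[, 1]],
                      gene_b = fit$gene_ids[ut[, 2]],
                      theta = th[ut], stringsAsFactors = FALSE)
  category <- rep("other", length(fit$gene_ids))
  for (nm in rev(names(highlights)))
    category[fit$gene_ids %in% highlights[[nm]]] <- nm
  nodes <- data.frame(gene_id = fit$gene_ids, category = category,
                      stringsAsFactors = FALSE)
  edge_path <- file.path(dir, paste0(prefix, "_edges.tsv"))
  node_path <- file.path(dir, paste0(prefix, "_nodes.tsv"))
  gml_path <- file.path(dir, paste0(prefix, ".graphml"))
  write.table(edges, edge_path, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(nodes, node_path, sep = "\t", quote = FALSE, row.names = FALSE)
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = nodes)
  igraph::E(g)$weight <- abs(edges$theta)
  igraph::write_graph(g, gml_path, format = "graphml")
  invisible(c(edges = edge_path, nodes = node_path, graphml = gml_path))
}
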