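#' Simulation configuration for a synthetic glioma cohort
#'
#' Bundles and validates the parameters of the synthetic-cohort generator.
#' The generator emulates the statistical structure the downstream analysis
#' assumes: per-type multivariate-Gaussian expression with block-sparse
#' precision matrices, a subset of monotonically distorted (non-Gaussian)
#' gene columns, two partially discordant classification label schemes, and
#' right-censored survival times from a Cox model with a sparse true
#' coefficient vector.
#'
#' Connected gene blocks occupy consecutive genes starting at gene 1; the
#' three glioma types share block positions but differ in which blocks are
#' active (round-robin: block 1 active for all types, block 2 only for
#' astrocytoma, block 3 only for oligodendroglioma, block 4 only for GBM,
#' block 5 again for all, and so on). This makes per-type exclusive and
#' shared selection sets nontrivial by construction.
#'
#' @param n_per_type samples per glioma type; scalar or length-3 vector
#'   (astrocytoma, oligodendroglioma, GBM).
#' @param p number of genes.
#' @param block_sizes integer vector of connected-block sizes; must sum to
#'   at most `p`. Genes outside blocks are conditionally independent.
#' @param partial_corr magnitude of the within-block partial correlation,
#'   in (0, 1); the sign of the precision entries is chosen so the matrix
#'   is positive definite (see [generate_precision_matrix()]).
#' @param n_prognostic number of genes with nonzero true Cox coefficient.
#' @param effect_size magnitude of the nonzero true Cox coefficients.
#' @param baseline_rate exponential baseline hazard rate (> 0).
#' @param censor_rate target censoring fraction in \[0, 1).
#' @param distort_frac fraction of gene columns passed through `exp()` to
#'   create non-Gaussian marginals, in \[0, 1\].
#' @param discordance_frac fraction of samples whose scheme-A (2016-like)
#'   type label follows histology instead of molecular flags, in \[0, 1\].
#' @param seed integer seed; sub-seeds for the generator stages are derived
#'   from it, so a fixed seed reproduces the cohort bit for bit.
#' @return an object of class `glionet_sim_config` (a validated list).
#' @seealso [simulate_cohort()]
#' @export
sim_config <- function(n_per_type = 150, p = 120, block_sizes = rep(5L, 12),
                       partial_corr = 0.2, n_prognostic = 5,
                       effect_size = 0.5, baseline_rate = 0.1,
                       censor_rate = 0.3, distort_frac = 0.3,
                       discordance_frac = 0.15, seed = 1L) {
  if (length(n_per_type) == 1) n_per_type <- rep(n_per_type, 3)
  if (length(n_per_type) != 3 || any(n_per_type < 1))
    stop("n_per_type must be a positive count per glioma type (3 types)")
  n_per_type <- as.integer(n_per_type)
  p <- as.integer(p)
  if (p < 1) stop("p must be a positive gene count")
  block_sizes <- as.integer(block_sizes)
  if (any(block_sizes < 2)) stop("block_sizes must all be >= 2")
  if (sum(block_sizes) > p) stop("block_sizes must sum to at most p")
  if (partial_corr <= 0 || partial_corr >= 1)
    stop("partial_corr must be in (0, 1)")
  if (n_prognostic < 0 || n_prognostic > p)
    stop("n_prognostic must be between 0 and p")
  if (effect_size < 0) stop("effect_size must be nonnegative")
  if (baseline_rate <= 0) stop("baseline_rate must be positive")
  if (censor_rate < 0 || censor_rate >= 1)
    stop("censor_rate must be in [0, 1)")
  if (distort_frac < 0 || distort_frac > 1)
    stop("distort_frac must be in [0, 1]")
  if (discordance_frac < 0 || discordance_frac > 1)
    stop("discordance_frac must be in [0, 1]")
  cfg <- list(n_per_type = n_per_type, p = p, block_sizes = block_sizes,
              partial_corr = partial_corr,
              n_prognostic = as.integer(n_prognostic),
              effect_size = effect_size, baseline_rate = baseline_rate,
              censor_rate = censor_rate, distort_frac = distort_frac,
              discordance_frac = discordance_frac, seed = as.integer(seed))
  # fail early if the block construction cannot be positive definite
  generate_precision_matrix(p, block_sizes, partial_corr)
  structure(cfg, class = "glionet_sim_config")
}

#' @export
print.glionet_sim_config <- function(x, ...) {
  cat("glionet simulation config\n")
  cat(sprintf("  samples per type: %s  (total %d)\n",
              paste(x$n_per_type, collapse = "/"), sum(x$n_per_type)))
  cat(sprintf("  genes: %d  blocks: %s  partial corr: %g\n", x$p,
              paste(x$block_sizes, collapse = ","), x$partial_corr))
  cat(sprintf("  prognostic genes: %d (effect %g), baseline rate %g, censoring %g\n",
              x$n_prognostic, x$effect_size, x$baseline_rate, x$censor_rate))
  cat(sprintf("  distorted gene fraction: %g, label discordance: %g, seed %d\n",
              x$distort_frac, x$discordance_frac, x$seed))
  invisible(x)
}

# round-robin block activity: "shared" blocks are active for every type,
# the others cycle through the three types
block_categories <- function(n_blocks) {
  cats <- c("shared", glioma_types())
  cats[((seq_len(n_blocks) - 1L) %% 4L) + 1L]
}

gene_names <- function(p) {
  sprintf(paste0("g%0", max(3L, nchar(p)), "d"), seq_len(p))
}

sample_names <- function(n) {
  sprintf(paste0("s%0", max(4L, nchar(n)), "d"), seq_len(n))
}

# gene index -> block index (NA outside blocks)
block_membership <- function(p, block_sizes) {
  member <- rep(NA_integer_, p)
  at <- 1L
  for (b in seq_along(block_sizes)) {
    member[at:(at + block_sizes[b] - 1L)] <- b
    at <- at + block_sizes[b]
  }
  member
}

#' Construct a block-sparse true precision matrix
#'
#' Builds a symmetric positive-definite precision matrix with unit diagonal
#' whose off-diagonal support is exactly the within-block pairs: blocks are
#' fully connected with constant partial correlation of magnitude
#' `partial_corr`; genes outside blocks (and genes in inactive blocks) are
#' isolated. The sign of the precision entries is negative (i.e. positive
#' partial correlations, a co-activated module) whenever that choice is
#' positive definite, and positive otherwise; larger blocks force the
#' positive sign because an equicorrelated precision block with negative
#' entries is only positive definite for magnitudes below `1/(b-1)`.
#'
#' @param p gene count.
#' @param block_sizes integer block sizes (consecutive genes from gene 1);
#'   may be empty for a diagonal matrix.
#' @param partial_corr within-block partial correlation magnitude in (0, 1).
#' @param seed unused; the construction is deterministic. Accepted so the
#'   generator stages share a uniform signature.
#' @param active logical vector, one per block; inactive blocks contribute
#'   no edges (used to differentiate the three glioma types). Default all
#'   active.
#' @return a `p` x `p` precision matrix with gene dimnames.
#' @export
generate_precision_matrix <- function(p, block_sizes = integer(),
                                      partial_corr = 0.2, seed = NULL,
                                      active = NULL) {
  p <- as.integer(p)
  block_sizes <- as.integer(block_sizes)
  if (sum(block_sizes) > p) stop("blocks must fit within p genes")
  if (partial_corr <= 0 || partial_corr >= 1)
    stop("partial_corr magnitude must be in (0, 1)")
  if (is.null(active)) active <- rep(TRUE, length(block_sizes))
  if (length(active) != length(block_sizes))
    stop("active must have one flag per block")

  theta <- diag(1, p)
  member <- block_membership(p, block_sizes)
  for (b in seq_along(block_sizes)) {
    if (!active[b]) next
    idx <- which(member == b)
    bsz <- length(idx)
    # prefer negative precision entries (positive partial correlation);
    # PD requires 1 - (bsz - 1) * partial_corr > 0 for that sign
    sgn <- if (1 - (bsz - 1) * partial_corr > 1e-8) -1 else 1
    off <- sgn * partial_corr
    theta[idx, idx] <- off
    diag(theta)[idx] <- 1
    # restore diagonal
    theta[cbind(idx, idx)] <- 1
  }
  ev <- eigen(theta, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 1e-8)
    stop("constructed precision matrix is not positive definite; ",
         "use a smaller |partial_corr| for these block sizes")
  dimnames(theta) <- list(gene_names(p), gene_names(p))
  theta
}

#' Draw expression data from per-type Gaussian graphical models
#'
#' Samples each type's expression from the zero-mean multivariate normal
#' with covariance equal to the inverse of that type's true precision
#' matrix, then passes a seeded fraction of gene columns through `exp()`
#' (the same columns for all samples) to create non-Gaussian marginals.
#' The monotone distortion preserves ranks, so the nonparanormal transform
#' can undo it.
#'
#' @param precisions named list of per-type precision matrices (all p x p).
#' @param n_per_type samples per type (scalar or one count per type).
#' @param distort_frac fraction of gene columns distorted.
#' @param seed integer seed (or NULL to use the current RNG state).
#' @return list with `x` (observed n x p matrix), `latent` (the Gaussian
#'   matrix before distortion), `type` (per-sample type labels) and
#'   `distorted_cols` (distorted gene names).
#' @export
generate_expression <- function(precisions, n_per_type, distort_frac = 0,
                                seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  types <- names(precisions)
  if (is.null(types)) stop("precisions must be a named per-type list")
  if (length(n_per_type) == 1)
    n_per_type <- rep(n_per_type, length(precisions))
  if (any(n_per_type < 1)) stop("n_per_type entries must all be positive")
  p <- nrow(precisions[[1]])
  genes <- colnames(precisions[[1]])
  if (is.null(genes)) genes <- gene_names(p)

  xs <- vector("list", length(types))
  for (k in seq_along(types)) {
    sigma <- solve(precisions[[k]])
    r <- chol(sigma)
    z <- matrix(rnorm(n_per_type[k] * p), nrow = n_per_type[k])
    xs[[k]] <- z %*% r
  }
  latent <- do.call(rbind, xs)
  colnames(latent) <- genes
  rownames(latent) <- sample_names(nrow(latent))
  type <- rep(types, n_per_type)

  n_distort <- round(distort_frac * p)
  cols <- if (n_distort > 0) sort(sample.int(p, n_distort)) else integer()
  x <- latent
  if (length(cols)) x[, cols] <- exp(x[, cols])
  list(x = x, latent = latent, type = type,
       distorted_cols = genes[cols])
}

#' Derive classification-scheme labels from molecular flags
#'
#' The scheme-B (2021-like) type is deterministic from the molecular flags:
#' IDH-mutant with 1p/19q codeletion is oligodendroglioma, IDH-mutant
#' without codeletion is astrocytoma, and IDH-wildtype is GBM. The scheme-A
#' (2016-like) type equals scheme B except for a seeded `discordance_frac`
#' of samples, whose scheme-A label follows the histology flag instead
#' (emulating histology-driven 2016 diagnoses corrected by the 2021
#' molecular criteria).
#'
#' @param flags data frame with columns `idh_status` (`"mutant"` /
#'   `"wildtype"`), `codel_status` (`"codel"` / `"non-codel"`) and
#'   `histology` (`"astro"` / `"oligo"` / `"gbm-like"`).
#' @param discordance_frac fraction of samples relabelled under scheme A.
#' @param seed integer seed (or NULL).
#' @return data frame with columns `type_2016`, `type_2021`, `discordant`.
#' @export
generate_labels <- function(flags, discordance_frac = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  req <- c("idh_status", "codel_status", "histology")
  if (!all(req %in% names(flags)))
    stop("flags must have columns ", paste(req, collapse = ", "))
  if (any(is.na(flags[req])))
    stop("molecular flags must be complete for every sample")
  bad <- !(flags$idh_status %in% c("mutant", "wildtype")) |
    !(flags$codel_status %in% c("codel", "non-codel")) |
    !(flags$histology %in% histology_levels())
  if (any(bad))
    stop("unknown flag value in rows: ",
         paste(head(which(bad), 5), collapse = ", "))

  type_b <- ifelse(flags$idh_status == "wildtype", "gbm",
                   ifelse(flags$codel_status == "codel",
                          "oligodendroglioma", "astrocytoma"))
  n <- nrow(flags)
  n_disc <- round(discordance_frac * n)
  disc <- rep(FALSE, n)
  if (n_disc > 0) disc[sample.int(n, n_disc)] <- TRUE
  type_a <- type_b
  type_a[disc] <- histology_to_type(flags$histology[disc])
  data.frame(type_2016 = type_a, type_2021 = type_b, discordant = disc,
             stringsAsFactors = FALSE)
}

# mean censoring probability when censoring is Uniform(0, c) and event
# times are exponential with per-sample rates r
censor_fraction_at <- function(cc, rates) {
  mean((1 - exp(-rates * cc)) / (rates * cc))
}

#' Generate right-censored survival times from a Cox model
#'
#' Event times are exponential with per-sample rate
#' `baseline_rate * exp(x_i' beta)`; independent censoring times are
#' Uniform(0, c) with `c` solved numerically so the expected censoring
#' fraction equals `censor_rate` (the censoring probability is monotone
#' decreasing in `c`).
#'
#' @param x n x p expression matrix (the scale on which the true Cox model
#'   acts; for cohorts with distorted marginals this is the latent Gaussian
#'   matrix).
#' @param beta_true true coefficient vector of length p.
#' @param baseline_rate exponential baseline hazard (> 0).
#' @param censor_rate target censoring fraction in \[0, 1); 0 means no
#'   censoring.
#' @param seed integer seed (or NULL).
#' @return data frame with columns `os_time` and `os_event` (1 = death).
#' @export
generate_survival <- function(x, beta_true, baseline_rate = 0.1,
                              censor_rate = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (baseline_rate <= 0) stop("baseline_rate must be positive")
  if (length(beta_true) != ncol(x))
    stop("beta_true must have one coefficient per gene")
  n <- nrow(x)
  rates <- as.numeric(baseline_rate * exp(x %*% beta_true))
  t_event <- rexp(n, rate = rates)
  if (censor_rate <= 0) {
    return(data.frame(os_time = t_event, os_event = 1L,
                      row.names = rownames(x)))
  }
  f <- function(cc) censor_fraction_at(cc, rates) - censor_rate
  upper <- 1
  while (f(upper) > 0 && upper < 1e12) upper <- upper * 2
  cc <- uniroot(f, interval = c(1e-10, upper), tol = 1e-10)$root
  t_cens <- runif(n, 0, cc)
  data.frame(os_time = pmin(t_event, t_cens),
             os_event = as.integer(t_event <= t_cens),
             row.names = rownames(x))
}

# assign prognostic genes across block categories (shared first, then the
# per-type exclusive blocks, cycling) so the case datasets of the survival
# step each contain part of the true signal
place_prognostic_genes <- function(cfg, member, cats) {
  if (cfg$n_prognostic == 0) return(integer())
  order_cats <- c("shared", glioma_types())
  pools <- lapply(order_cats, function(cc) which(!is.na(member) &
                                                   cats[member] == cc))
  leftover <- c(which(is.na(member)))
  chosen <- integer()
  ci <- 0L
  while (length(chosen) < cfg$n_prognostic) {
    ci <- ci + 1L
    cat_i <- ((ci - 1L) %% length(pools)) + 1L
    avail <- setdiff(pools[[cat_i]], chosen)
    if (!length(avail)) avail <- setdiff(unlist(pools), chosen)
    if (!length(avail)) avail <- setdiff(leftover, chosen)
    if (!length(avail)) break
    chosen <- c(chosen, avail[1])
  }
  sort(chosen)
}

#' Simulate a full synthetic glioma cohort
#'
#' Runs the generator stages in sequence (deterministic per-type precision
#' matrices, Gaussian expression with monotone distortion, molecular flags
#' and two classification label schemes, Cox-model survival), deriving one
#' sub-seed per stage from `config$seed` so a fixed seed reproduces the
#' cohort exactly.
#'
#' Survival times are generated from the latent Gaussian expression (the
#' scale the analysis recovers after gaussianization), and the true
#' prognostic genes are spread over shared and type-exclusive blocks.
#'
#' @param config a [sim_config()] object.
#' @return object of class `glionet_cohort`: list with `expression`
#'   (observed samples x genes), `clinical` (sample_id, type_2016,
#'   type_2021, os_time, os_event, idh_status, codel_status, histology),
#'   `truth` (per-type precision matrices, per-type true hub/connected gene
#'   sets, `beta_true`, distorted columns, block table, flags) and
#'   `config`.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "glionet_sim_config"))
  cfg <- config
  types <- glioma_types()
  n_blocks <- length(cfg$block_sizes)
  cats <- block_categories(n_blocks)
  member <- block_membership(cfg$p, cfg$block_sizes)

  precisions <- lapply(types, function(tp) {
    generate_precision_matrix(cfg$p, cfg$block_sizes, cfg$partial_corr,
                              active = cats == "shared" | cats == tp)
  })
  names(precisions) <- types

  expr <- generate_expression(precisions, cfg$n_per_type, cfg$distort_frac,
                              seed = cfg$seed + 1L)

  # molecular flags consistent with the (scheme-B) type each sample was
  # drawn from; histology deviates for the discordant subset
  n <- nrow(expr$x)
  type_true <- expr$type
  idh <- ifelse(type_true == "gbm", "wildtype", "mutant")
  codel <- ifelse(type_true == "oligodendroglioma", "codel", "non-codel")
  hist_concordant <- c("astrocytoma" = "astro",
                       "oligodendroglioma" = "oligo",
                       "gbm" = "gbm-like")[type_true]
  set.seed(cfg$seed + 2L)
  n_disc <- round(cfg$discordance_frac * n)
  disc_idx <- if (n_disc > 0) sample.int(n, n_disc) else integer()
  histology <- unname(hist_concordant)
  for (i in disc_idx) {
    histology[i] <- sample(setdiff(histology_levels(), hist_concordant[i]), 1)
  }
  flags <- data.frame(idh_status = idh, codel_status = codel,
                      histology = histology, stringsAsFactors = FALSE)
  labels <- flags
  labels$type_2021 <- type_true
  labels$type_2016 <- type_true
  labels$type_2016[disc_idx] <- histology_to_type(histology[disc_idx])
  labels$discordant <- seq_len(n) %in% disc_idx

  prog_idx <- place_prognostic_genes(cfg, member, cats)
  beta_true <- numeric(cfg$p)
  if (length(prog_idx))
    beta_true[prog_idx] <- cfg$effect_size *
      rep_len(c(1, -1), length(prog_idx))
  names(beta_true) <- colnames(expr$x)

  surv <- generate_survival(expr$latent, beta_true, cfg$baseline_rate,
                            cfg$censor_rate, seed = cfg$seed + 3L)

  genes <- colnames(expr$x)
  block_table <- data.frame(gene_id = genes, block = member,
                            category = ifelse(is.na(member), "isolated",
                                              cats[member]),
                            stringsAsFactors = FALSE)
  true_connected <- lapply(types, function(tp) {
    act <- which(cats == "shared" | cats == tp)
    genes[!is.na(member) & member %in% act]
  })
  names(true_connected) <- types

  clinical <- data.frame(sample_id = rownames(expr$x),
                         type_2016 = labels$type_2016,
                         type_2021 = labels$type_2021,
                         os_time = surv$os_time, os_event = surv$os_event,
                         idh_status = flags$idh_status,
                         codel_status = flags$codel_status,
                         histology = flags$histology,
                         stringsAsFactors = FALSE)

  truth <- list(precisions = precisions, true_hubs = true_connected,
                true_connected = true_connected, beta_true = beta_true,
                prognostic_genes = genes[prog_idx],
                distorted_cols = expr$distorted_cols,
                block_table = block_table, flags = flags)

  structure(list(expression = expr$x, latent = expr$latent,
                 clinical = clinical, truth = truth, config = cfg),
            class = "glionet_cohort")
}

#' @export
print.glionet_cohort <- function(x, ...) {
  cat(sprintf("glionet synthetic cohort: %d samples x %d genes\n",
              nrow(x$expression), ncol(x$expression)))
  tb <- table(x$clinical$type_2021)
  cat("  2021-scheme types:",
      paste(sprintf("%s=%d", names(tb), tb), collapse = ", "), "\n")
  cat(sprintf("  events: %d / %d, discordant labels: %d, distorted genes: %d\n",
              sum(x$clinical$os_event), nrow(x$clinical),
              sum(x$clinical$type_2016 != x$clinical$type_2021),
              length(x$truth$distorted_cols)))
  invisible(x)
}
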