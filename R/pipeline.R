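#' Pipeline run configuration
#'
#' Parameters of the full two-step workflow: data source (a simulation
#' config, or paths to expression/clinical TSV files), preprocessing,
#' graphical-lasso selection, hub scoring, and the penalized Cox survival
#' step for the three case datasets under each classification scheme.
#'
#' @param sim a [sim_config()] describing the synthetic cohort (ignored
#'   when `expression_file`/`clinical_file` are given).
#' @param expression_file,clinical_file optional input TSVs (see
#'   [read_expression_tsv()] / [read_clinical_tsv()]).
#' @param rho graphical-lasso penalty for the per-type fits. The default
#'   0.35 is matched to the correlation scale of the synthetic cohort;
#'   full-transcriptome glioma data, with much stronger co-expression
#'   modules, uses 0.9 (the [glasso_fit()] default).
#' @param hub_t hub percentile threshold (default 60).
#' @param jb_alpha Jarque-Bera significance level (default 0.05).
#' @param npn_first gaussianize before the normality filter (default);
#'   `FALSE` swaps the order.
#' @param schemes classification schemes to run ("2016", "2021").
#' @param cases case datasets for the survival step: 1 = all selected
#'   genes, 2 = per-type exclusive genes, 3 = hub genes.
#' @param nlambda,lambda_min_ratio Cox path grid (see
#'   [cox_lasso_path()]).
#' @param outdir optional output directory for artifacts.
#' @return object of class `glionet_run_config`.
#' @export
run_config <- function(sim = sim_config(), expression_file = NULL,
                       clinical_file = NULL, rho = 0.35, hub_t = 60,
                       jb_alpha = 0.05, npn_first = TRUE,
                       schemes = c("2016", "2021"), cases = 1:3,
                       nlambda = 100, lambda_min_ratio = 0.01,
                       outdir = NULL) {
  if (rho < 0) stop("rho must be nonnegative")
  if (hub_t < 0 || hub_t > 100) stop("hub_t must be in [0, 100]")
  if (jb_alpha < 0 || jb_alpha >= 1) stop("jb_alpha must be in [0, 1)")
  schemes <- match.arg(schemes, c("2016", "2021"), several.ok = TRUE)
  if (!all(cases %in% 1:3)) stop("cases must be a subset of 1:3")
  structure(list(sim = sim, expression_file = expression_file,
                 clinical_file = clinical_file, rho = rho, hub_t = hub_t,
                 jb_alpha = jb_alpha, npn_first = npn_first,
                 schemes = schemes, cases = as.integer(cases),
                 nlambda = nlambda, lambda_min_ratio = lambda_min_ratio,
                 outdir = outdir),
            class = "glionet_run_config")
}

#' Build a case dataset for the survival step
#'
#' All case datasets span every glioma sample (Pan-Glioma); they differ in
#' their gene sets: case 1 is the union of the per-type selected sets,
#' case 2 the union of the per-type exclusive sets, case 3 the union
#' (pooled over types) of the per-type hub sets. Case 2 and case 3 genes
#' are always contained in case 1.
#'
#' @param selection a [network_selection()] result for the case's scheme.
#' @param case 1, 2 or 3.
#' @param x preprocessed samples x genes matrix over all samples.
#' @return samples x genes submatrix with the case's (deduplicated,
#'   sorted) gene set as columns.
#' @export
build_case_dataset <- function(selection, case, x) {
  stopifnot(inherits(selection, "glionet_selection"))
  if (!case %in% 1:3) stop("case must be 1, 2 or 3")
  field <- c("selected", "exclusive", "hubs")[case]
  genes <- sort(unique(unlist(lapply(selection$per_type, `[[`, field))))
  if (!length(genes))
    stop(sprintf("empty gene set for case %d (%s)", case, field))
  x[, genes, drop = FALSE]
}

#' Cross-tabulate risk groups against glioma types
#'
#' Counts and percentages of the high- and low-risk groups: each group's
#' share of all samples, and each type's share within each group.
#'
#' @param group per-sample risk labels (factor LR/HR or any labels).
#' @param types per-sample glioma type labels.
#' @return object of class `glionet_strat_table`: list with `groups`
#'   (group, n, pct_of_all) and `cross` (type, group, n, pct_of_group).
#'   Percentages are exact; see [format_pct()] for printing.
#' @export
tabulate_stratification <- function(group, types) {
  if (length(group) != length(types))
    stop("group and types must cover the same samples")
  group <- as.factor(group)
  types <- as.character(types)
  n_all <- length(group)
  gt <- table(group)
  groups <- data.frame(group = names(gt), n = as.integer(gt),
                       pct_of_all = 100 * as.integer(gt) / n_all,
                       stringsAsFactors = FALSE)
  tl <- intersect(glioma_types(), unique(types))
  if (!length(tl)) tl <- sort(unique(types))
  cross <- do.call(rbind, lapply(names(gt), function(g) {
    nk <- vapply(tl, function(tp) sum(group == g & types == tp), integer(1))
    data.frame(type = tl, group = g, n = nk,
               pct_of_group = if (gt[[g]] > 0) 100 * nk / gt[[g]] else 0,
               stringsAsFactors = FALSE, row.names = NULL)
  }))
  structure(list(groups = groups, cross = cross, n = n_all),
            class = "glionet_strat_table")
}

#' Format a percentage the way the tables print it
#'
#' @param x numeric percentage.
#' @param style `"text"` for one decimal (e.g. "82.7%") or `"table"` for
#'   integers (e.g. "83%").
#' @return character vector.
#' @export
format_pct <- function(x, style = c("text", "table")) {
  style <- match.arg(style)
  if (style == "text") sprintf("%.1f%%", x) else sprintf("%.0f%%", round(x))
}

#' @export
print.glionet_strat_table <- function(x, ...) {
  cat("glionet risk-group composition\n")
  for (i in seq_len(nrow(x$groups)))
    cat(sprintf("  %s: %d samples (%s of all)\n", x$groups$group[i],
                x$groups$n[i], format_pct(x$groups$pct_of_all[i])))
  for (g in x$groups$group) {
    cc <- x$cross[x$cross$group == g, ]
    cat(sprintf("  %s by type: %s\n", g,
                paste(sprintf("%s %d (%s)", cc$type, cc$n,
                              format_pct(cc$pct_of_group)), collapse = ", ")))
  }
  invisible(x)
}

#' Stability of risk-group membership across case datasets
#'
#' For each risk label, the fraction of samples assigned that label in
#' every case among the samples ever assigned it; plus the overall
#' fraction of samples with an identical label across all cases.
#'
#' @param groups list of per-case label vectors over the same samples (in
#'   the same order).
#' @return list with `per_label` (named fractions) and `overall`.
#' @export
stability_overlap <- function(groups) {
  if (length(groups) < 2) stop("need at least two stratifications")
  n <- unique(vapply(groups, length, integer(1)))
  if (length(n) != 1) stop("stratifications cover different sample sets")
  m <- vapply(groups, as.character, character(n))
  labels <- sort(unique(as.vector(m)))
  per_label <- vapply(labels, function(l) {
    always <- rowSums(m == l) == ncol(m)
    ever <- rowSums(m == l) > 0
    if (!any(ever)) return(0)
    sum(always) / sum(ever)
  }, numeric(1))
  overall <- mean(apply(m, 1, function(r) length(unique(r)) == 1))
  list(per_label = per_label, overall = overall)
}

with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("[stage %s] %s", stage, conditionMessage(e)), call. = FALSE)
  })
}

#' Run the full two-step workflow
#'
#' Executes preprocessing (nonparanormal gaussianization and Jarque-Bera
#' filtering), per-(scheme, type) graphical-lasso selection with hub
#' scoring, cross-scheme comparisons, and for each scheme the three case
#' datasets' penalized Cox fits with EPV cap, KDE-minimum risk
#' stratification, Kaplan-Meier curves, log-rank tests and risk-group
#' cross-tabulations. Deterministic given the simulation seed. When
#' `config$outdir` is set, artifacts (TSV tables, network exports, a JSON
#' run summary) are written as each stage completes.
#'
#' @param config a [run_config()].
#' @return a results bundle (list) with elements `cohort`, `preprocessing`,
#'   `selection` (per scheme), `comparisons`, `survival` (per scheme and
#'   case: model, stratification, KM curves, log-rank, tables),
#'   `stability` and `summary` (the JSON-ready run summary).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "glionet_run_config"))
  out <- list(config = config)

  if (!is.null(config$expression_file)) {
    expr <- with_stage("input", read_expression_tsv(config$expression_file))
    clinical <- with_stage("input", read_clinical_tsv(config$clinical_file))
    cohort <- NULL
  } else {
    cohort <- with_stage("simulate", simulate_cohort(config$sim))
    expr <- cohort$expression
    clinical <- cohort$clinical
  }
  out$cohort <- cohort
  out$clinical <- clinical

  pre <- with_stage("preprocess", {
    if (config$npn_first) {
      xn <- npn_transform(expr)
      fr <- filter_normal(xn, config$jb_alpha)
    } else {
      fr <- filter_normal(expr, config$jb_alpha)
      fr$x <- npn_transform(fr$x)
    }
    fr
  })
  out$preprocessing <- pre
  x <- pre$x

  out$selection <- list()
  for (sc in config$schemes) {
    labels <- clinical[[paste0("type_", sc)]]
    out$selection[[sc]] <- with_stage(
      paste0("network-", sc),
      network_selection(x, labels, rho = config$rho, hub_t = config$hub_t))
  }

  if (length(config$schemes) == 2) {
    out$comparisons <- with_stage("compare-schemes", {
      s16 <- out$selection[["2016"]]
      s21 <- out$selection[["2021"]]
      types <- intersect(s16$types, s21$types)
      per_type <- lapply(types, function(tp) {
        sel_cmp <- compare_sets(s16$per_type[[tp]]$selected,
                                s21$per_type[[tp]]$selected)
        hub_cmp <- compare_sets(s16$per_type[[tp]]$hubs,
                                s21$per_type[[tp]]$hubs)
        # exclusive hubs of each scheme, ranked in the other scheme's table
        cross_2021_in_2016 <- rank_crosscheck(hub_cmp$b_only,
                                              s16$per_type[[tp]]$scores)
        cross_2016_in_2021 <- rank_crosscheck(hub_cmp$a_only,
                                              s21$per_type[[tp]]$scores)
        list(selected = sel_cmp, hubs = hub_cmp,
             cross_2021_in_2016 = cross_2021_in_2016,
             cross_2016_in_2021 = cross_2016_in_2021)
      })
      names(per_type) <- types
      per_type
    })
  }

  out$survival <- list()
  for (sc in config$schemes) {
    sel <- out$selection[[sc]]
    types <- clinical[[paste0("type_", sc)]]
    res_sc <- list()
    for (cs in config$cases) {
      key <- paste0("case", cs)
      res_sc[[key]] <- with_stage(sprintf("survival-%s-case%d", sc, cs), {
        xc <- build_case_dataset(sel, cs, x)
        n_events <- sum(clinical$os_event == 1)
        pmax <- compute_pmax(n_events)
        path <- cox_lasso_path(xc, clinical$os_time, clinical$os_event,
                               nlambda = config$nlambda,
                               lambda_min_ratio = config$lambda_min_ratio)
        model <- select_model(path, pmax)
        pi_v <- prognostic_index(xc, model)
        thr <- kde_threshold(pi_v)
        strat <- stratify(pi_v, thr)
        km <- km_estimate(clinical$os_time, clinical$os_event, strat$group)
        lr <- logrank_test(clinical$os_time, clinical$os_event, strat$group)
        tab <- tabulate_stratification(strat$group, types)
        list(genes = colnames(xc), pmax = pmax, model = model,
             strat = strat, km = km, logrank = lr, table = tab)
      })
    }
    if (length(res_sc) >= 2) {
      res_sc$stability <- with_stage(
        sprintf("stability-%s", sc),
        stability_overlap(lapply(res_sc[paste0("case", config$cases)],
                                 function(r) r$strat$group)))
    }
    out$survival[[sc]] <- res_sc
  }

  out$summary <- pipeline_summary(out)
  if (!is.null(config$outdir))
    with_stage("write", write_pipeline_artifacts(out, config$outdir))
  out
}

# condense a pipeline bundle into a JSON-ready summary
pipeline_summary <- function(out) {
  cfg <- out$config
  sim <- cfg$sim
  summ <- list(
    parameters = list(rho = cfg$rho, hub_t = cfg$hub_t,
                      jb_alpha = cfg$jb_alpha, npn_first = cfg$npn_first,
                      nlambda = cfg$nlambda,
                      lambda_min_ratio = cfg$lambda_min_ratio,
                      seed = if (!is.null(sim)) sim$seed else NA),
    preprocessing = list(
      n_genes_in = nrow(out$preprocessing$report),
      n_genes_kept = sum(out$preprocessing$report$kept)),
    selection = lapply(out$selection, function(sel) {
      lapply(sel$per_type, function(pt)
        list(n_selected = length(pt$selected),
             n_exclusive = length(pt$exclusive),
             n_hubs = length(pt$hubs), selected = pt$selected,
             exclusive = pt$exclusive, hubs = pt$hubs))
    }),
    survival = lapply(out$survival, function(res_sc) {
      cases <- res_sc[grepl("^case", names(res_sc))]
      cs <- lapply(cases, function(r)
        list(n_genes = length(r$genes), pmax = r$pmax,
             lambda = r$model$lambda, active_set = r$model$active_set,
             n_active = length(r$model$active_set),
             pi_threshold = r$strat$threshold,
             threshold_method = r$strat$method,
             n_lr = sum(r$strat$group == "LR"),
             n_hr = sum(r$strat$group == "HR"),
             logrank_chisq = r$logrank$statistic,
             logrank_p = r$logrank$p.value))
      if (!is.null(res_sc$stability))
        cs$stability <- list(per_label = as.list(res_sc$stability$per_label),
                             overall = res_sc$stability$overall)
      cs
    }))
  summ
}

# write TSV/JSON/GraphML artifacts for a completed pipeline bundle
write_pipeline_artifacts <- function(out, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  if (!is.null(out$cohort)) write_cohort(out$cohort, file.path(outdir, "data"))
  write.table(out$preprocessing$report,
              file.path(outdir, "normality_report.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  for (sc in names(out$selection)) {
    sel <- out$selection[[sc]]
    write_selection_json(sel, file.path(outdir,
                                        sprintf("selection_%s.json", sc)))
    for (tp in sel$types) {
      export_network(sel$per_type[[tp]]$fit, file.path(outdir, "networks"),
                     prefix = sprintf("%s_%s", sc, tp),
                     highlights = list(
                       hub = sel$per_type[[tp]]$hubs,
                       exclusive = sel$per_type[[tp]]$exclusive))
    }
  }
  for (sc in names(out$survival)) {
    res_sc <- out$survival[[sc]]
    for (key in grep("^case", names(res_sc), value = TRUE)) {
      r <- res_sc[[key]]
      base <- sprintf("%s_%s", sc, key)
      strat_df <- data.frame(sample_id = out$clinical$sample_id,
                             pi = r$strat$pi,
                             group = as.character(r$strat$group))
      write.table(strat_df, file.path(outdir, paste0(base, "_strat.tsv")),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      write.table(r$km, file.path(outdir, paste0(base, "_km.tsv")),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      write.table(r$table$cross,
                  file.path(outdir, paste0(base, "_risk_by_type.tsv")),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }
  jsonlite::write_json(out$summary, file.path(outdir, "run_summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(outdir)
}
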