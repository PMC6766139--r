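# End-to-end orchestration of the multiphase design: pooled screening ->
# training-phase confirmation -> frozen risk model -> validation -> combined
# ROC -> aggressive-carcinoma (MTC) arm.

#' Run the full simulated biomarker-discovery pipeline
#'
#' Executes every stage of the multiphase case-control design on data drawn
#' from `config`: (1) pooled screening of the full assay universe against
#' the CT/fold-change criteria; (2) an individual-sample cohort whose
#' quantified target assays play the role of the carried-forward candidate
#' set; (3) training-phase low-expression (Cq) filtering and per-miRNA
#' tests, retaining markers with p below `alpha` in the designated
#' comparison(s); (4) a reference-interval risk-score model fitted on the
#' training samples only and then frozen; (5) validation-phase
#' confirmation tests; (6) per-miRNA and panel ROC analyses on the combined
#' training+validation set; and (7) the MTC arm on matched subsets using
#' the up-regulated markers. Identical `config` and `seed` reproduce the
#' report exactly.
#'
#' @param config a [sim_config()]; default [default_paper_config()].
#' @param seed integer master seed for all randomness in the run.
#' @param ct_cutoff,fc_cutoff,whitelist screening criteria, see
#'   [screen_candidates()].
#' @param cq_cutoff,max_fraction low-expression exclusion rule, see
#'   [low_expression_filter()].
#' @param retention_comparisons list of `c(case, control)` pairs; a marker
#'   is retained when its training p-value is below `alpha` in at least one
#'   (`retention_rule = "any"`) or all (`"all"`) of them.
#' @param retention_rule `"any"` or `"all"`.
#' @param alpha significance level for retention/confirmation (default
#'   0.05).
#' @param ci_method AUC confidence-interval method, see [auc_ci()].
#' @param mtc_markers markers for the MTC-arm panel; `NULL` selects those
#'   significant (p < `alpha`) against both matched comparator subsets.
#' @param out_dir if non-`NULL`, the report and intermediate tables are
#'   written there via [write_pipeline_report()].
#' @return Object of class `pipeline_report`.
#' @export
run_pipeline <- function(config = default_paper_config(), seed = NULL,
                         ct_cutoff = 28, fc_cutoff = 5, whitelist = NULL,
                         cq_cutoff = 35, max_fraction = 0.5,
                         retention_comparisons = list(c("PTC", "CONTROL")),
                         retention_rule = c("any", "all"), alpha = 0.05,
                         ci_method = c("delong", "hanley"),
                         mtc_markers = NULL, out_dir = NULL) {
  retention_rule <- match.arg(retention_rule)
  ci_method <- match.arg(ci_method)
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(seed)) set.seed(seed)

  stage <- "screening"
  report <- tryCatch({
    pools <- simulate_pools(config)
    candidates <- screen_candidates(
      pools$PTC, list(pools$BENIGN, pools$CONTROL),
      ct_cutoff = ct_cutoff, fc_cutoff = fc_cutoff, whitelist = whitelist)

    stage <- "simulation"
    cohort <- simulate_cohort(config)

    stage <- "normalization"
    expr <- normalize_expression(cohort$ct)

    stage <- "training"
    train_ids <- expr$samples$sample_id[expr$samples$phase == "TRAINING"]
    valid_ids <- expr$samples$sample_id[expr$samples$phase == "VALIDATION" &
                                          expr$samples$group != "MTC"]
    cq <- low_expression_filter(cohort$ct, cq_cutoff = cq_cutoff,
                                max_fraction = max_fraction,
                                sample_ids = train_ids)
    train_stats <- lapply(retention_comparisons, function(cmp)
      test_groups(expr, cmp[1], cmp[2], sample_ids = train_ids))
    names(train_stats) <- vapply(retention_comparisons, paste, "",
                                 collapse = "_vs_")
    sig <- sapply(train_stats, function(df)
      !is.na(df$p.value) & df$p.value < alpha)
    pass_p <- if (retention_rule == "any") rowSums(sig) > 0
              else rowSums(sig) == length(train_stats)
    assay_ids <- train_stats[[1]]$assay_id
    retained <- assay_ids[pass_p & assay_ids %in% cq$retained]
    directions <- ifelse(
      train_stats[[1]]$mean_a > train_stats[[1]]$mean_b, "UP", "DOWN")
    names(directions) <- assay_ids

    stage <- "risk model"
    train_sub <- subset_expr(expr, train_ids)
    model <- if (length(retained))
      risk_model(train_sub, labels = c("PTC", "CONTROL"),
                 markers = retained, directions = directions[retained])
    else NULL

    stage <- "validation"
    valid_stats <- lapply(retention_comparisons, function(cmp)
      test_groups(expr, cmp[1], cmp[2], sample_ids = valid_ids))
    names(valid_stats) <- names(train_stats)
    valid_stats <- lapply(valid_stats, function(df)
      df[df$assay_id %in% retained, , drop = FALSE])

    stage <- "ROC"
    main_ids <- expr$samples$sample_id[expr$samples$group != "MTC"]
    comparisons <- list(c("PTC", "CONTROL"), c("PTC", "BENIGN"),
                        c("BENIGN", "CONTROL"))
    roc_single <- list(); roc_panel <- list()
    for (cmp in comparisons) {
      lab <- paste(cmp, collapse = " vs ")
      for (mk in retained) {
        r <- marker_roc(expr, mk, cmp, sample_ids = main_ids,
                        ci_method = ci_method)
        roc_single[[paste(lab, mk)]] <- r
      }
      if (!is.null(model)) {
        keep <- expr$samples$sample_id %in% main_ids &
          expr$samples$group %in% cmp
        rsf <- predict(model, subset_expr(expr, expr$samples$sample_id[keep]))
        y <- as.integer(expr$samples$group[keep] == cmp[1])
        roc_panel[[lab]] <- roc(rsf, y, method = ci_method,
                                comparison = paste("panel:", lab))
      }
    }

    stage <- "MTC arm"
    mtc <- mtc_arm(expr, config, model = model, markers = mtc_markers,
                   alpha = alpha, ci_method = ci_method)

    structure(
      list(candidates = candidates, cq_filter = cq,
           training_stats = train_stats, retained = retained,
           directions = directions[retained], model = model,
           validation_stats = valid_stats,
           roc_single = roc_single, roc_panel = roc_panel, mtc = mtc,
           truth = cohort$truth, expr = expr, ct = cohort$ct,
           manifest = list(seed = seed,
                           package_version = as.character(
                             utils::packageVersion("sermir")),
                           alpha = alpha, ct_cutoff = ct_cutoff,
                           fc_cutoff = fc_cutoff, cq_cutoff = cq_cutoff,
                           max_fraction = max_fraction,
                           retention_rule = retention_rule,
                           ci_method = ci_method)),
      class = "pipeline_report")
  }, error = function(e) {
    stop("pipeline failed at stage [", stage, "]: ", conditionMessage(e),
         call. = FALSE)
  })
  if (!is.null(out_dir)) write_pipeline_report(report, out_dir)
  report
}

# expression-matrix row subset by sample id (keeps metadata aligned)
subset_expr <- function(expr, sample_ids) {
  keep <- expr$samples$sample_id %in% sample_ids
  expr$expr <- expr$expr[keep, , drop = FALSE]
  expr$delta_ct <- expr$delta_ct[keep, , drop = FALSE]
  expr$reference_ct <- expr$reference_ct[keep]
  expr$degraded_reference <- expr$degraded_reference[keep]
  expr$samples <- expr$samples[keep, , drop = FALSE]
  expr
}

# single-marker ROC between two groups on the expression scale, with
# orientation so AUC >= 0.5; samples with missing expression are dropped
marker_roc <- function(expr, marker, cmp, sample_ids = NULL,
                       ci_method = "delong") {
  keep <- expr$samples$group %in% cmp
  if (!is.null(sample_ids))
    keep <- keep & expr$samples$sample_id %in% sample_ids
  v <- expr$expr[keep, marker]
  y <- as.integer(expr$samples$group[keep] == cmp[1])
  ok <- is.finite(v)
  roc(v[ok], y[ok], method = ci_method, orient = TRUE,
      comparison = paste0(marker, ": ", paste(cmp, collapse = " vs ")))
}

#' MTC-arm analysis on matched subsets
#'
#' Draws age/sex-matched benign and control subsets of the configured size,
#' restricts attention to the up-regulated markers of the main model (or an
#' explicit marker set), and runs per-marker tests and ROC plus a
#' comparison-specific risk-score panel for MTC vs control and MTC vs
#' benign.
#'
#' @param expr an `expr_matrix` containing MTC samples.
#' @param config the [sim_config()] (for the subset size).
#' @param model the frozen main-phase [risk_model()] (its UP markers seed
#'   the arm); may be `NULL` if `markers` is given.
#' @param markers explicit panel markers; `NULL` selects UP markers of
#'   `model` that reach p < `alpha` against both comparator subsets.
#' @param alpha significance level.
#' @param ci_method AUC confidence-interval method.
#' @return List with `subsets`, `stats`, `roc_single`, `roc_panel`,
#'   `panel_markers`.
#' @export
mtc_arm <- function(expr, config, model = NULL, markers = NULL,
                    alpha = 0.05, ci_method = "delong") {
  mtc_ids <- expr$samples$sample_id[expr$samples$group == "MTC"]
  if (!length(mtc_ids))
    return(list(subsets = NULL, stats = NULL, roc_single = list(),
                roc_panel = list(), panel_markers = character()))
  n_sub <- config$mtc_subset_size
  subs <- lapply(c(BENIGN = "BENIGN", CONTROL = "CONTROL"), function(g) {
    ids <- expr$samples$sample_id[expr$samples$group == g]
    sort(sample(ids, min(n_sub, length(ids))))
  })
  arm_ids <- c(mtc_ids, subs$BENIGN, subs$CONTROL)

  up <- if (!is.null(markers)) markers
        else if (!is.null(model)) model$markers[model$direction == "UP"]
        else character()
  cmps <- list(c("MTC", "CONTROL"), c("MTC", "BENIGN"))
  stats_tab <- lapply(cmps, function(cmp) {
    df <- test_groups(expr, cmp[1], cmp[2], sample_ids = arm_ids)
    df[df$assay_id %in% up, , drop = FALSE]
  })
  names(stats_tab) <- vapply(cmps, paste, "", collapse = "_vs_")

  panel_markers <- if (!is.null(markers)) markers else {
    sig_both <- Reduce(intersect, lapply(stats_tab, function(df)
      df$assay_id[!is.na(df$p.value) & df$p.value < alpha]))
    sig_both
  }

  roc_single <- list(); roc_panel <- list()
  for (cmp in cmps) {
    lab <- paste(cmp, collapse = " vs ")
    for (mk in up)
      roc_single[[paste(lab, mk)]] <-
        marker_roc(expr, mk, cmp, sample_ids = arm_ids,
                   ci_method = ci_method)
    if (length(panel_markers)) {
      keep <- expr$samples$sample_id %in% arm_ids &
        expr$samples$group %in% cmp
      sub <- subset_expr(expr, expr$samples$sample_id[keep])
      m <- risk_model(sub, labels = cmp, markers = panel_markers)
      rsf <- predict(m, sub)
      y <- as.integer(sub$samples$group == cmp[1])
      roc_panel[[lab]] <- roc(rsf, y, method = ci_method,
                              comparison = paste("panel:", lab))
    }
  }
  list(subsets = subs, stats = stats_tab, roc_single = roc_single,
       roc_panel = roc_panel, panel_markers = panel_markers)
}

#' Panel-vs-single AUC comparison
#'
#' Tabulates, per comparison, the risk-score panel AUC against the best and
#' median single-marker AUCs, flagging whether the panel is at least as
#' good as each.
#'
#' @param report a `pipeline_report` from [run_pipeline()].
#' @return Data frame: `comparison`, `panel_auc`, `best_single`,
#'   `median_single`, `panel_ge_best`, `panel_ge_median`.
#' @export
compare_panels <- function(report) {
  stopifnot(inherits(report, "pipeline_report"))
  out <- lapply(names(report$roc_panel), function(lab) {
    singles <- report$roc_single[grepl(lab, names(report$roc_single),
                                       fixed = TRUE)]
    sa <- vapply(singles, function(r) r$auc, 0)
    pa <- report$roc_panel[[lab]]$auc
    data.frame(comparison = lab, panel_auc = pa,
               best_single = if (length(sa)) max(sa) else NA_real_,
               median_single = if (length(sa)) stats::median(sa) else NA_real_,
               panel_ge_best = if (length(sa)) pa >= max(sa) else NA,
               panel_ge_median = if (length(sa)) pa >= stats::median(sa)
                                 else NA)
  })
  do.call(rbind, out)
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("<pipeline_report>\n")
  cat(" screening:  ", sum(x$candidates$candidate), "of",
      nrow(x$candidates), "assays pass the pooled criteria\n")
  cat(" Cq filter:  ", length(x$cq_filter$excluded), "assay(s) excluded (",
      paste(x$cq_filter$excluded, collapse = ", "), ")\n")
  cat(" retained:   ", length(x$retained), "marker(s):",
      paste(sprintf("%s(%s)", x$retained, x$directions), collapse = " "),
      "\n")
  if (length(x$roc_panel)) {
    cat(" panel ROC:\n")
    for (lab in names(x$roc_panel))
      cat(sprintf("   %-20s AUC %.3f (%.3f-%.3f)\n", lab,
                  x$roc_panel[[lab]]$auc, x$roc_panel[[lab]]$ci[1],
                  x$roc_panel[[lab]]$ci[2]))
  }
  if (length(x$mtc$roc_panel)) {
    cat(" MTC arm panel (", paste(x$mtc$panel_markers, collapse = " + "),
        "):\n", sep = "")
    for (lab in names(x$mtc$roc_panel))
      cat(sprintf("   %-20s AUC %.3f (%.3f-%.3f)\n", lab,
                  x$mtc$roc_panel[[lab]]$auc, x$mtc$roc_panel[[lab]]$ci[1],
                  x$mtc$roc_panel[[lab]]$ci[2]))
  }
  invisible(x)
}

roc_summary_row <- function(r, marker = "panel") {
  data.frame(comparison = r$comparison, marker = marker, auc = r$auc,
             ci_lower = unname(r$ci[1]), ci_upper = unname(r$ci[2]),
             ci_method = r$ci_method, n_case = r$n_case,
             n_control = r$n_control, flipped = r$flipped)
}

#' Write a pipeline report to disk
#'
#' Emits CSV tables (candidates, filter log, training/validation stats, ROC
#' summary), the frozen risk model as JSON, the simulated CT table, and a
#' JSON run manifest. Output is a pure function of the report, so identical
#' runs produce byte-identical files.
#'
#' @param report a `pipeline_report`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_pipeline_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(as.data.frame(report$candidates),
                   file.path(dir, "candidates.csv"), row.names = FALSE)
  utils::write.csv(report$cq_filter$log, file.path(dir, "cq_filter.csv"),
                   row.names = FALSE)
  for (lab in names(report$training_stats))
    utils::write.csv(report$training_stats[[lab]],
                     file.path(dir, paste0("training_", lab, ".csv")),
                     row.names = FALSE)
  for (lab in names(report$validation_stats))
    utils::write.csv(report$validation_stats[[lab]],
                     file.path(dir, paste0("validation_", lab, ".csv")),
                     row.names = FALSE)
  rs <- do.call(rbind, c(
    lapply(names(report$roc_single), function(k)
      roc_summary_row(report$roc_single[[k]],
                      sub(".* ", "", k))),
    lapply(report$roc_panel, roc_summary_row),
    lapply(report$mtc$roc_single, function(r)
      roc_summary_row(r, sub(":.*", "", r$comparison))),
    lapply(report$mtc$roc_panel, roc_summary_row)))
  if (!is.null(rs))
    utils::write.csv(rs, file.path(dir, "roc_summary.csv"),
                     row.names = FALSE)
  if (!is.null(report$model))
    write_risk_model(report$model, file.path(dir, "risk_model.json"))
  write_ct_table(report$ct, file.path(dir, "ct_table.csv"))
  jsonlite::write_json(report$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(dir)
}

#' Serialize / restore a frozen risk model
#'
#' @param model a [risk_model()].
#' @param path JSON file path.
#' @return `read_risk_model()` returns the restored `risk_model` (without
#'   the training binarization matrix).
#' @export
write_risk_model <- function(model, path) {
  stopifnot(inherits(model, "risk_model"))
  jsonlite::write_json(
    list(markers = model$markers,
         direction = as.list(model$direction),
         threshold = as.list(model$threshold),
         weight = as.list(model$weight),
         flag = as.list(model$flag),
         down_rule = model$down_rule,
         n_case = model$n_case, n_control = model$n_control),
    path, auto_unbox = TRUE, digits = I(17), pretty = TRUE)
  invisible(path)
}

#' @rdname write_risk_model
#' @export
read_risk_model <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(
    list(markers = j$markers,
         direction = unlist(j$direction), threshold = unlist(j$threshold),
         weight = unlist(j$weight), flag = unlist(j$flag),
         down_rule = j$down_rule, n_case = j$n_case,
         n_control = j$n_control, s_train = NULL,
         control_exceedance = NULL, call = NULL),
    class = "risk_model")
}
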