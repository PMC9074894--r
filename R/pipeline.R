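#' Configuration for an end-to-end pipeline run
#'
#' Collects inputs and run-level constants for [run_pipeline()]. Every input
#' may be given either as an in-memory object or as a path to the
#' corresponding TSV/GMT/JSON file (handy from the command line).
#'
#' @param methylation Beta-stage [meth_matrix], or path to a methylation TSV
#'   (CpGs x samples).
#' @param cohort Cohort data frame, or path to a cohort TSV. Must carry
#'   `sample_id`, `sex`, `ethnicity`, the age-at-testing columns named in
#'   `outcome_spec`, cell-proportion columns (`cell_*` by default), and all
#'   exposure and outcome columns.
#' @param manifest Manifest data frame or TSV path (`cpg_id`, `chr`, `pos`,
#'   `gene`).
#' @param gene_sets [pathway_set()], or path to a GMT file (then
#'   `pathway_meta` must point to the metadata sidecar TSV). Not needed in
#'   EWAS mode.
#' @param pathway_meta Metadata sidecar TSV path when `gene_sets` is a GMT
#'   path.
#' @param profiles Named list of keyword vectors per outcome id; default
#'   [default_keyword_profiles()] over the outcome ids.
#' @param outcome_spec Data frame `id`, `family`, `age_col`.
#' @param exposures Character vector of exposure column names.
#' @param alpha FDR threshold (default 0.05).
#' @param split_fraction Discovery fraction (default 0.70).
#' @param split_seed,boot_seed Seeds for the cohort split and the mediation
#'   bootstrap.
#' @param n_boot,ci_level Bootstrap resamples and CI level for Step 5.
#' @param mode `"mitm"` (pathway preselection, the five-step cascade) or
#'   `"ewas"` (Step 1 skipped; every CpG is in every outcome's universe).
#' @param cell_cols Cell-proportion column names (default: all `cell_*`
#'   columns in the cohort).
#' @param truth Optional `ground_truth` object or JSON path; when given, the
#'   run reports a comparison of selected triples against the planted ones.
#' @param out_dir Optional output directory; when set, report TSVs and a
#'   structured JSON log are written there.
#' @return A list of class `run_config`.
#' @export
run_config <- function(methylation, cohort, manifest,
                       gene_sets = NULL, pathway_meta = NULL,
                       profiles = NULL, outcome_spec = default_outcome_spec(),
                       exposures, alpha = 0.05, split_fraction = 0.70,
                       split_seed = 1L, boot_seed = 1L,
                       n_boot = 500L, ci_level = 0.95,
                       mode = c("mitm", "ewas"), cell_cols = NULL,
                       truth = NULL, out_dir = NULL) {
  mode <- match.arg(mode)
  if (mode == "mitm" && is.null(gene_sets))
    stop("`gene_sets` is required in mitm mode")
  structure(list(methylation = methylation, cohort = cohort,
                 manifest = manifest, gene_sets = gene_sets,
                 pathway_meta = pathway_meta, profiles = profiles,
                 outcome_spec = outcome_spec, exposures = exposures,
                 alpha = alpha, split_fraction = split_fraction,
                 split_seed = as.integer(split_seed),
                 boot_seed = as.integer(boot_seed),
                 n_boot = as.integer(n_boot), ci_level = ci_level,
                 mode = mode, cell_cols = cell_cols, truth = truth,
                 out_dir = out_dir), class = "run_config")
}

load_run_inputs <- function(config) {
  meth <- config$methylation
  if (is.character(meth)) meth <- read_methylation_tsv(meth, stage = "beta")
  cohort <- config$cohort
  if (is.character(cohort)) cohort <- read_cohort_tsv(cohort)
  manifest <- config$manifest
  if (is.character(manifest)) manifest <- read_manifest_tsv(manifest)
  pathways <- config$gene_sets
  if (is.character(pathways)) {
    if (is.null(config$pathway_meta))
      stop("`pathway_meta` sidecar path required when gene sets come from a GMT file")
    pathways <- read_pathway_set(pathways, config$pathway_meta)
  }
  truth <- config$truth
  if (is.character(truth)) truth <- read_ground_truth_json(truth)
  list(meth = meth, cohort = cohort, manifest = manifest,
       pathways = pathways, truth = truth)
}

check_cohort_schema <- function(cohort, outcome_spec, exposures, cell_cols) {
  need <- c("sample_id", "sex", "ethnicity", unique(outcome_spec$age_col),
            outcome_spec$id, exposures, cell_cols)
  miss <- setdiff(need, names(cohort))
  if (length(miss))
    stop("cohort table is missing column(s): ", paste(miss, collapse = ", "))
  invisible(TRUE)
}

#' Run the full five-step pipeline
#'
#' Executes, in order: outlier trimming of exposures and outcomes (4-SD
#' single-pass rule, per column, applied by setting trimmed values missing);
#' methylation QC, logit2 transform and cell-composition residualization;
#' the discovery/validation split; keyword-driven universe selection (Step
#' 1, skipped in EWAS mode where every CpG is eligible for every outcome);
#' the Step 2-4 sequential screens on the discovery set; bootstrap mediation
#' (Step 5) for every surviving triple; and a refit of the selected models
#' on the validation set with sign-agreement reporting. Methylation values
#' are never outlier-trimmed.
#'
#' @param config A [run_config()].
#' @return A list of class `mitm_run`: `universe_counts`, `cascade` (the
#'   [run_sequential_screen()] output), `mediation` (list of
#'   `mediation_result`), `mediation_table` (Table-5-shaped data frame, one
#'   row per triple, proportion in percent), `summary_table` (per-step
#'   estimates and raw p for each selected triple), `validation`,
#'   `qc_report`, `trim_report`, `split`, `truth_comparison` (when a ground
#'   truth was supplied) and `log` (per-step counts, seeds, versions). When
#'   `config$out_dir` is set all tables are also written as TSV plus a JSON
#'   log.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  inp <- load_run_inputs(config)
  cohort <- inp$cohort
  spec <- config$outcome_spec
  cell_cols <- config$cell_cols
  if (is.null(cell_cols)) cell_cols <- grep("^cell_", names(cohort), value = TRUE)
  if (!length(cell_cols)) stop("no cell-proportion columns found in cohort")
  check_cohort_schema(cohort, spec, config$exposures, cell_cols)

  # outlier trimming: exposures and outcomes only
  trim_report <- list()
  for (col in c(config$exposures, spec$id)) {
    v <- stats::setNames(cohort[[col]], cohort$sample_id)
    tr <- trim_outliers(v)
    if (tr$n_removed > 0)
      cohort[[col]][cohort$sample_id %in% tr$removed_ids] <- NA
    trim_report[[col]] <- data.frame(variable = col, n_removed = tr$n_removed,
                                     removed_ids = paste(tr$removed_ids, collapse = ";"),
                                     stringsAsFactors = FALSE)
  }
  trim_report <- do.call(rbind, c(trim_report, make.row.names = FALSE))

  # methylation preprocessing: QC -> M-values -> cell residuals
  qc <- qc_filter(inp$meth, inp$manifest)
  mvals <- beta_to_m(qc$matrix)
  cells <- as.matrix(cohort[, cell_cols, drop = FALSE])
  rownames(cells) <- cohort$sample_id
  keep <- intersect(sample_ids(mvals), cohort$sample_id)
  if (length(keep) < 2) stop("fewer than 2 samples shared by cohort and methylation")
  mvals <- meth_matrix(mvals$values[keep, , drop = FALSE], "M")
  resid <- residualize_cells(mvals, cells)
  cohort <- cohort[match(keep, cohort$sample_id), , drop = FALSE]

  split <- split_cohort(keep, config$split_fraction, config$split_seed)

  # Step 1 (or the EWAS everything-universe)
  if (config$mode == "mitm") {
    profiles <- config$profiles
    if (is.null(profiles)) profiles <- default_keyword_profiles(spec$id)
    universes <- select_universes(inp$pathways, profiles, inp$manifest)
    universe_counts <- attr(universes, "counts")
  } else {
    profiles <- NULL
    universes <- stats::setNames(
      rep(list(cpg_ids(resid)), nrow(spec)), spec$id)
    universe_counts <- data.frame(outcome = spec$id, n_pathways = NA,
                                  n_genes = NA, n_genes_annotated = NA,
                                  n_cpgs = length(cpg_ids(resid)),
                                  stringsAsFactors = FALSE)
  }

  disc <- cohort[cohort$sample_id %in% split$discovery, , drop = FALSE]
  resid_disc <- meth_matrix(resid$values[split$discovery, , drop = FALSE],
                            "M_residual")
  cascade <- run_sequential_screen(disc, resid_disc, universes, spec,
                                   config$exposures, config$alpha)
  universe_counts$n_significant_cpgs <- vapply(universe_counts$outcome,
    function(oid) {
      s2 <- cascade$step2
      sum(s2$selected[s2$response == oid])
    }, integer(1))

  # Step 5 on surviving triples
  mediation <- list()
  if (!is.null(cascade$triples)) {
    for (r in seq_len(nrow(cascade$triples))) {
      tr <- cascade$triples[r, ]
      meds <- strsplit(tr$mediators, ";", fixed = TRUE)[[1]]
      i <- match(tr$outcome, spec$id)
      covs <- data.frame(sex = disc$sex, ethnicity = disc$ethnicity,
                         age = disc[[spec$age_col[i]]],
                         stringsAsFactors = FALSE)
      res <- tryCatch(
        bootstrap_mediation(disc[[tr$outcome]], disc[[tr$exposure]],
                            covs = covs, family = spec$family[i],
                            m_values = mvals$values[split$discovery, meds,
                                                    drop = FALSE],
                            cells = cells[split$discovery, , drop = FALSE],
                            n_boot = config$n_boot,
                            ci_level = config$ci_level,
                            seed = config$boot_seed + r - 1L,
                            exposure_id = tr$exposure,
                            outcome_id = tr$outcome),
        error = function(e) structure(list(exposure = tr$exposure,
                                           outcome = tr$outcome,
                                           error = conditionMessage(e)),
                                      class = "mediation_failure"))
      mediation[[r]] <- res
    }
  }
  mediation_table <- mediation_report_table(mediation, config$ci_level)

  # validation refit of selected triples (no selection decisions)
  val <- cohort[cohort$sample_id %in% split$validation, , drop = FALSE]
  resid_val <- meth_matrix(resid$values[split$validation, , drop = FALSE],
                           "M_residual")
  validation <- validate_triples(cascade, val, resid_val, spec)

  truth_comparison <- NULL
  if (!is.null(inp$truth))
    truth_comparison <- compare_to_truth(cascade, inp$truth)

  log <- list(
    package_version = as.character(utils::packageVersion("meetmiddle")),
    mode = config$mode, alpha = config$alpha,
    seeds = list(split = config$split_seed, bootstrap = config$boot_seed),
    n_samples = nrow(cohort), n_discovery = length(split$discovery),
    n_validation = length(split$validation),
    n_cpgs_post_qc = length(cpg_ids(resid)),
    n_outcomes = nrow(spec), n_exposures = length(config$exposures),
    n_step2_tests = nrow(cascade$step2),
    n_step2_hits = sum(cascade$step2$selected),
    n_step3_tests = if (is.null(cascade$step3)) 0L else nrow(cascade$step3),
    n_step3_hits = if (is.null(cascade$step3)) 0L else sum(cascade$step3$selected),
    n_step4_tests = if (is.null(cascade$step4)) 0L else nrow(cascade$step4),
    n_triples = if (is.null(cascade$triples)) 0L else nrow(cascade$triples),
    trim_total_removed = sum(trim_report$n_removed)
  )

  run <- structure(list(universe_counts = universe_counts, cascade = cascade,
                        mediation = mediation,
                        mediation_table = mediation_table,
                        summary_table = triple_summary_table(cascade),
                        validation = validation, qc_report = qc$report,
                        trim_report = trim_report, split = split,
                        profiles = profiles,
                        truth_comparison = truth_comparison, log = log),
                   class = "mitm_run")
  if (!is.null(config$out_dir)) write_run_reports(run, config$out_dir)
  run
}

#' @export
print.mitm_run <- function(x, ...) {
  cat(sprintf("<mitm_run> mode=%s: %d discovery / %d validation samples\n",
              x$log$mode, x$log$n_discovery, x$log$n_validation))
  cat(sprintf("  Step 2: %d tests, %d CpG hits | Step 3: %d tests, %d pairs | triples: %d\n",
              x$log$n_step2_tests, x$log$n_step2_hits, x$log$n_step3_tests,
              x$log$n_step3_hits, x$log$n_triples))
  invisible(x)
}

mediation_report_table <- function(mediation, ci_level) {
  cols <- c("exposure", "mediator_cpgs", "outcome", "n",
            "total_effect", "direct_effect", "indirect_effect",
            "mediation_pct", "ci_lower_pct", "ci_upper_pct", "note")
  if (!length(mediation)) {
    out <- as.data.frame(stats::setNames(rep(list(character(0)), length(cols)), cols))
    return(out)
  }
  do.call(rbind, lapply(mediation, function(m) {
    if (inherits(m, "mediation_failure"))
      return(data.frame(exposure = m$exposure, mediator_cpgs = "",
                        outcome = m$outcome, n = NA, total_effect = NA,
                        direct_effect = NA, indirect_effect = NA,
                        mediation_pct = NA, ci_lower_pct = NA,
                        ci_upper_pct = NA, note = m$error,
                        stringsAsFactors = FALSE))
    pci <- m$ci[m$ci$quantity == "proportion", ]
    data.frame(exposure = m$exposure,
               mediator_cpgs = paste(m$mediator_cpgs, collapse = ";"),
               outcome = m$outcome, n = m$n, total_effect = m$total,
               direct_effect = m$direct, indirect_effect = m$indirect,
               mediation_pct = 100 * m$proportion,
               ci_lower_pct = 100 * pci$lower, ci_upper_pct = 100 * pci$upper,
               note = if (m$unstable) "unstable_bootstrap" else "",
               stringsAsFactors = FALSE)
  }))
}

triple_summary_table <- function(cascade) {
  if (is.null(cascade$triples)) return(NULL)
  rows <- list()
  for (r in seq_len(nrow(cascade$triples))) {
    tr <- cascade$triples[r, ]
    meds <- strsplit(tr$mediators, ";", fixed = TRUE)[[1]]
    for (k in meds) {
      s2 <- cascade$step2[cascade$step2$response == tr$outcome &
                            cascade$step2$predictor == k, ]
      s3 <- cascade$step3[cascade$step3$outcome == tr$outcome &
                            cascade$step3$response == k &
                            cascade$step3$predictor == tr$exposure, ]
      rows[[length(rows) + 1L]] <- data.frame(
        step = c("step2_outcome_on_cpg", "step3_cpg_on_exposure",
                 "step4_outcome_on_exposure"),
        dependent = c(tr$outcome, k, tr$outcome),
        independent = c(k, tr$exposure, tr$exposure),
        estimate = c(s2$estimate, s3$estimate, tr$step4_estimate),
        p_raw = c(s2$p_raw, s3$p_raw, tr$step4_p_raw),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, c(rows, make.row.names = FALSE))
}

#' Refit selected triples on the validation set
#'
#' For every mediation candidate from the discovery cascade, refits the
#' outcome-on-CpG (Step 2 form) and CpG-on-exposure (Step 3 form) models on
#' the validation samples and reports estimates, raw p-values and agreement
#' of the coefficient sign with the discovery estimate. No selection or FDR
#' decisions are made here. Triples with fewer than 20 validation complete
#' cases, or referencing a column absent from the validation cohort, are
#' flagged rather than fitted.
#'
#' @param cascade A `screen_cascade` from [run_sequential_screen()].
#' @param cohort Validation cohort data frame.
#' @param meth Validation `M_residual`-stage [meth_matrix].
#' @param outcome_spec Data frame `id`, `family`, `age_col`.
#' @return Data frame with one row per triple x mediator x relation, or an
#'   empty data frame when no triples were selected.
#' @export
validate_triples <- function(cascade, cohort, meth, outcome_spec) {
  empty <- data.frame(outcome = character(0), exposure = character(0),
                      cpg = character(0), relation = character(0),
                      estimate = numeric(0), p_raw = numeric(0),
                      estimate_discovery = numeric(0),
                      sign_agreement = logical(0), n = integer(0),
                      note = character(0), stringsAsFactors = FALSE)
  if (is.null(cascade$triples) || !nrow(cascade$triples)) return(empty)
  common <- intersect(cohort$sample_id, sample_ids(meth))
  cohort <- cohort[match(common, cohort$sample_id), , drop = FALSE]
  V <- meth$values[common, , drop = FALSE]
  rows <- list()
  for (r in seq_len(nrow(cascade$triples))) {
    tr <- cascade$triples[r, ]
    meds <- strsplit(tr$mediators, ";", fixed = TRUE)[[1]]
    i <- match(tr$outcome, outcome_spec$id)
    missing_col <- !all(c(tr$outcome, tr$exposure) %in% names(cohort))
    for (k in meds) {
      s2d <- cascade$step2[cascade$step2$response == tr$outcome &
                             cascade$step2$predictor == k, ]
      s3d <- cascade$step3[cascade$step3$outcome == tr$outcome &
                             cascade$step3$response == k &
                             cascade$step3$predictor == tr$exposure, ]
      if (missing_col || !k %in% colnames(V)) {
        for (rel in c("outcome_on_cpg", "cpg_on_exposure"))
          rows[[length(rows) + 1L]] <- data.frame(
            outcome = tr$outcome, exposure = tr$exposure, cpg = k,
            relation = rel, estimate = NA_real_, p_raw = NA_real_,
            estimate_discovery = if (rel == "outcome_on_cpg") s2d$estimate else s3d$estimate,
            sign_agreement = NA, n = 0L, note = "missing_data",
            stringsAsFactors = FALSE)
        next
      }
      covs_o <- data.frame(sex = cohort$sex, ethnicity = cohort$ethnicity,
                           age = cohort[[outcome_spec$age_col[i]]],
                           stringsAsFactors = FALSE)
      f2 <- fit_outcome_on_cpg(cohort[[tr$outcome]], V[, k], covs_o,
                               outcome_spec$family[i],
                               response = tr$outcome, predictor = k)
      has_y <- !is.na(cohort[[tr$outcome]])
      covs_m <- data.frame(sex = cohort$sex[has_y],
                           ethnicity = cohort$ethnicity[has_y],
                           stringsAsFactors = FALSE)
      f3 <- fit_cpg_on_exposure(V[has_y, k], cohort[[tr$exposure]][has_y],
                                covs_m, response = k, predictor = tr$exposure)
      rows[[length(rows) + 1L]] <- data.frame(
        outcome = tr$outcome, exposure = tr$exposure, cpg = k,
        relation = "outcome_on_cpg", estimate = f2$estimate, p_raw = f2$p_raw,
        estimate_discovery = s2d$estimate,
        sign_agreement = if (f2$converged) sign(f2$estimate) == sign(s2d$estimate) else NA,
        n = f2$n,
        note = if (f2$converged) "" else "not_fitted",
        stringsAsFactors = FALSE)
      rows[[length(rows) + 1L]] <- data.frame(
        outcome = tr$outcome, exposure = tr$exposure, cpg = k,
        relation = "cpg_on_exposure", estimate = f3$estimate, p_raw = f3$p_raw,
        estimate_discovery = s3d$estimate,
        sign_agreement = if (f3$converged) sign(f3$estimate) == sign(s3d$estimate) else NA,
        n = f3$n,
        note = if (f3$converged) "" else "not_fitted",
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, c(rows, make.row.names = FALSE))
}

compare_to_truth <- function(cascade, truth) {
  planted <- truth$planted_paths
  sel <- cascade$triples
  sel_keys <- character(0)
  if (!is.null(sel) && nrow(sel))
    sel_keys <- unlist(lapply(seq_len(nrow(sel)), function(r)
      paste(sel$exposure[r], strsplit(sel$mediators[r], ";", fixed = TRUE)[[1]],
            sel$outcome[r], sep = "|")))
  planted_keys <- if (nrow(planted))
    paste(planted$exposure, planted$cpg, planted$outcome, sep = "|") else character(0)
  data.frame(
    n_planted = nrow(planted),
    n_selected = length(sel_keys),
    n_true_positive = length(intersect(sel_keys, planted_keys)),
    n_false_positive = length(setdiff(sel_keys, planted_keys)),
    exact_recovery = setequal(sel_keys, planted_keys) && length(planted_keys) > 0,
    stringsAsFactors = FALSE
  )
}

write_tsv_report <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Write all report tables of a run as TSV plus a JSON log
#'
#' @param run A `mitm_run` from [run_pipeline()].
#' @param out_dir Output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_run_reports <- function(run, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  fp <- function(f) file.path(out_dir, f)
  if (!is.null(run$profiles)) {
    prof <- data.frame(outcome = names(run$profiles),
                       keywords = vapply(run$profiles, paste, "", collapse = ", "),
                       stringsAsFactors = FALSE)
    write_tsv_report(prof, fp("table1_keywords.tsv"))
  }
  write_tsv_report(run$universe_counts, fp("table2_universe_counts.tsv"))
  write_tsv_report(run$cascade$step2, fp("step2_results.tsv"))
  if (!is.null(run$cascade$step3))
    write_tsv_report(run$cascade$step3, fp("step3_results.tsv"))
  if (!is.null(run$cascade$step4))
    write_tsv_report(run$cascade$step4, fp("step4_results.tsv"))
  write_tsv_report(run$mediation_table, fp("table5_mediation.tsv"))
  if (!is.null(run$summary_table))
    write_tsv_report(run$summary_table, fp("table6_summary.tsv"))
  write_tsv_report(run$validation, fp("validation.tsv"))
  write_tsv_report(run$qc_report, fp("qc_report.tsv"))
  write_tsv_report(run$trim_report, fp("outlier_trim.tsv"))
  if (!is.null(run$truth_comparison))
    write_tsv_report(run$truth_comparison, fp("truth_comparison.tsv"))
  jsonlite::write_json(run$log, fp("log.json"), auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

#' Write a generated cohort to disk in the pipeline's input formats
#'
#' Convenience for the `simulate` CLI subcommand: writes the methylation TSV,
#' cohort TSV, manifest TSV, GMT gene sets with metadata sidecar, and the
#' ground-truth JSON.
#'
#' @param sim Output of [generate_cohort()].
#' @param fixture Output of [generate_pathway_fixture()] (optional).
#' @param out_dir Output directory.
#' @return Named list of written paths, invisibly.
#' @export
write_cohort_fixture <- function(sim, fixture = NULL, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  fp <- function(f) file.path(out_dir, f)
  paths <- list(
    methylation = write_methylation_tsv(sim$methylation, fp("methylation.tsv")),
    cohort = write_cohort_tsv(sim$cohort, fp("cohort.tsv")),
    manifest = write_manifest_tsv(sim$manifest, fp("manifest.tsv")),
    truth = write_ground_truth_json(sim$truth, fp("ground_truth.json"))
  )
  if (!is.null(fixture)) {
    paths$gene_sets <- write_gmt(fixture$pathways, fp("gene_sets.gmt"))
    paths$pathway_meta <- write_pathway_meta_tsv(fixture$pathways,
                                                 fp("pathway_meta.tsv"))
  }
  invisible(paths)
}
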