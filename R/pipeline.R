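# Orchestration of the full discovery -> replication -> functional
# follow-up workflow, with seeding, artifact writing and a summary report.

#' Load a pipeline configuration from YAML
#'
#' Reads a YAML file and merges it over the pipeline defaults (stage-1
#' fraction 91/370, q-threshold 0.05, alpha 0.05, forest settings of
#' [rf_config()]). Exactly one of a simulation block (`simulation:`) or real
#' input paths (`inputs:`) must be present.
#'
#' @param path YAML file path.
#' @return a named list of pipeline settings.
#' @export
load_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  defaults <- list(stage1_fraction = 91 / 370, q_threshold = 0.05,
                   alpha = 0.05, seed = 1L, rf = list())
  cfg <- utils::modifyList(defaults, raw)
  has_sim <- !is.null(cfg$simulation)
  has_inputs <- !is.null(cfg$inputs)
  if (has_sim == has_inputs) {
    stop("exactly one of 'simulation' or 'inputs' must be configured", call. = FALSE)
  }
  cfg
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
}

write_manifest <- function(dir, seed, params) {
  lines <- c(sprintf("package: ewasrf %s", as.character(utils::packageVersion("ewasrf"))),
             sprintf("seed: %d", seed),
             vapply(names(params), function(k) {
               sprintf("%s: %s", k, paste(format(params[[k]], digits = 10), collapse = ","))
             }, character(1)))
  writeLines(lines, file.path(dir, "manifest.txt"))
}

#' Run the discovery stage on one cohort
#'
#' Executes the full discovery workflow: stratified split into stage-1 and
#' stage-2 samples, beta-to-M transformation, recursive random-forest CpG
#' selection on stage 1, adjusted-boxplot trimming of the selected CpGs'
#' M-values in stage 2, crude and cell/sex-adjusted logistic models, Storey
#' q-values on the crude p-values, and the discovery rule q < `q_threshold`
#' (crude model). All randomness flows from `seed`.
#'
#' @param cohort a `synthetic_cohort` (or a list with the same components:
#'   `beta`, `phenotypes`, `reference_panel`).
#' @param stage1_fraction proportion of samples used for feature selection.
#' @param rf an [rf_config()]; its `rng_seed` is derived from `seed`.
#' @param q_threshold FDR threshold for discovery.
#' @param seed integer master seed.
#' @param out_dir optional directory for artifacts (trace, selected CpGs,
#'   association table, q-values, discovery list, trim report, estimated
#'   proportions, manifest).
#' @return a `discovery_result` list.
#' @export
run_discovery <- function(cohort, stage1_fraction = 91 / 370,
                          rf = rf_config(), q_threshold = 0.05,
                          seed = 1L, out_dir = NULL) {
  set.seed(seed)
  seeds <- sample.int(.Machine$integer.max - 1L, 3L)
  halves <- split_cohort(cohort, stage1_fraction, seed = seeds[1])
  stage1 <- halves$stage1
  stage2 <- halves$stage2

  m1 <- beta_to_m(stage1$beta)
  rf$rng_seed <- seeds[2]
  selection <- recursive_select(m1, stage1$phenotypes$asthma, rf)

  m2 <- beta_to_m(stage2$beta)[, selection$selected, drop = FALSE]
  trimmed <- trim_outliers(m2)
  props2 <- estimate_proportions(stage2$beta, cohort$reference_panel)
  assoc <- stage2_associations(trimmed$m, stage2$phenotypes, props2)

  crude <- assoc[assoc$model_kind == "logistic_crude", ]
  qset <- storey_qvalues(crude$p_value, ids = crude$cpg_id)
  discovered <- qset$ids[qset$q_values < q_threshold]

  result <- structure(list(
    stage1_ids = stage1$phenotypes$sample_id,
    stage2_ids = stage2$phenotypes$sample_id,
    selection = selection,
    trim_report = trimmed$report,
    proportions = props2,
    associations = assoc,
    qvalues = qset,
    discovered = discovered,
    q_threshold = q_threshold,
    seed = seed
  ), class = "discovery_result")

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_tsv(selection$trace, file.path(out_dir, "selection_trace.tsv"))
    writeLines(selection$selected, file.path(out_dir, "selected_cpgs.txt"))
    write_tsv(trimmed$report, file.path(out_dir, "trim_report.tsv"))
    write_cell_proportions(props2, file.path(out_dir, "cell_proportions.tsv"))
    write_tsv(assoc, file.path(out_dir, "associations.tsv"))
    write_tsv(data.frame(cpg_id = qset$ids, p_value = qset$p_values,
                         q_value = qset$q_values),
              file.path(out_dir, "qvalues.tsv"))
    writeLines(discovered, file.path(out_dir, "discovered_cpgs.txt"))
    write_manifest(out_dir, seed,
                   list(stage1_fraction = stage1_fraction,
                        q_threshold = q_threshold, ntree = rf$ntree,
                        mtry_fraction = rf$mtry_fraction,
                        min_features = rf$min_features,
                        pi0 = qset$pi0))
  }
  result
}

#' @export
print.discovery_result <- function(x, ...) {
  cat(sprintf("discovery_result: %d stage-1 / %d stage-2 samples, %d selected CpGs, %d discovered (q < %g)\n",
              length(x$stage1_ids), length(x$stage2_ids),
              length(x$selection$selected), length(x$discovered), x$q_threshold))
  invisible(x)
}

fit_cohort_models <- function(cohort, cpgs) {
  m <- beta_to_m(cohort$beta)[, cpgs, drop = FALSE]
  trimmed <- trim_outliers(m)
  props <- estimate_proportions(cohort$beta, cohort$reference_panel)
  stage2_associations(trimmed$m, cohort$phenotypes, props)
}

#' Run the full discovery / replication / functional-validation workflow
#'
#' Discovery on `cohort_discovery` (split-sample recursive selection plus
#' stage-2 FDR-gated logistic models); crude and adjusted models at the
#' discovered CpGs on the full (pooled) discovery cohort and on
#' `cohort_replication`, compared for direction consistency and replication
#' significance; and, when a cord-blood cohort `cohort_f2` is supplied, the
#' functional follow-up: percentile-shift expression normalization,
#' DNAm-expression Spearman correlation at a target CpG, and infant-wheeze
#' logistic models for both the CpG's M-values and the target probe's
#' expression.
#'
#' @param cohort_discovery,cohort_replication,cohort_f2 `synthetic_cohort`
#'   objects (replication and F2 optional).
#' @param target_cpg CpG carried into the follow-up (default: the first
#'   discovered CpG, falling back to the first planted truth CpG).
#' @param target_probe expression probe (default: the cohort's coupled
#'   probe).
#' @param alpha replication significance level.
#' @inheritParams run_discovery
#' @return an `ewas_full_report` list with elements `discovery`,
#'   `pooled_models`, `replication` (or `NULL`), `followup` (or a skipped
#'   marker), and `summary`.
#' @export
run_full <- function(cohort_discovery, cohort_replication = NULL,
                     cohort_f2 = NULL, stage1_fraction = 91 / 370,
                     rf = rf_config(), q_threshold = 0.05, alpha = 0.05,
                     seed = 1L, target_cpg = NULL, target_probe = NULL,
                     out_dir = NULL) {
  discovery <- run_discovery(cohort_discovery, stage1_fraction, rf,
                             q_threshold, seed,
                             out_dir = if (is.null(out_dir)) NULL
                                       else file.path(out_dir, "discovery"))
  pooled <- NULL
  replication <- NULL
  if (length(discovery$discovered) > 0L) {
    pooled <- fit_cohort_models(cohort_discovery, discovery$discovered)
    if (!is.null(cohort_replication)) {
      repl_models <- fit_cohort_models(cohort_replication, discovery$discovered)
      replication <- assess_replication(pooled, repl_models, alpha)
    }
  }

  followup <- list(skipped = TRUE, reason = "no cord-blood (F2) cohort supplied")
  if (!is.null(cohort_f2)) {
    if (is.null(target_cpg)) {
      target_cpg <- if (length(discovery$discovered) > 0L &&
                        discovery$discovered[1] %in% colnames(cohort_f2$beta)) {
        discovery$discovered[1]
      } else {
        cohort_f2$truth$cpg_id[1]
      }
    }
    if (is.null(target_probe)) {
      target_probe <- if (!is.null(cohort_f2$target_probe)) cohort_f2$target_probe
                      else colnames(cohort_f2$expression)[1]
    }
    expr_norm <- percentile_shift_normalize(cohort_f2$expression)
    m_f2 <- beta_to_m(cohort_f2$beta)
    m_target <- unclass(m_f2)[, target_cpg]
    e_target <- unclass(expr_norm)[, target_probe]
    corr <- dnam_expression_correlation(m_target, e_target)
    cord_props <- estimate_proportions(cohort_f2$beta, cohort_f2$reference_panel)
    wheeze_dnam <- fit_wheeze_models(m_target, cohort_f2$phenotypes, cord_props,
                                     predictor_id = target_cpg)
    wheeze_expr <- fit_wheeze_models(e_target, cohort_f2$phenotypes, cord_props,
                                     predictor_id = target_probe)
    followup <- list(skipped = FALSE, target_cpg = target_cpg,
                     target_probe = target_probe, dnam_expression = corr,
                     wheeze_dnam = wheeze_dnam, wheeze_expr = wheeze_expr)
  }

  smry <- list(
    n_selected = length(discovery$selection$selected),
    n_discovered = length(discovery$discovered),
    n_direction_consistent = if (is.null(replication)) NA_integer_ else {
      crude <- replication[replication$model_kind == "logistic_crude", ]
      sum(crude$direction_consistent, na.rm = TRUE)
    },
    n_replicated = if (is.null(replication)) NA_integer_ else {
      adj <- replication[replication$model_kind == "logistic_adjusted", ]
      sum(adj$replication_significant & adj$direction_consistent, na.rm = TRUE)
    },
    followup_skipped = followup$skipped
  )

  report <- structure(list(discovery = discovery, pooled_models = pooled,
                           replication = replication, followup = followup,
                           summary = smry),
                      class = "ewas_full_report")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!is.null(pooled)) write_tsv(pooled, file.path(out_dir, "pooled_models.tsv"))
    if (!is.null(replication)) {
      write_tsv(replication, file.path(out_dir, "replication.tsv"))
    }
    if (!followup$skipped) {
      write_tsv(rbind(followup$wheeze_dnam, followup$wheeze_expr),
                file.path(out_dir, "wheeze_models.tsv"))
    }
    writeLines(report_markdown(report), file.path(out_dir, "report.md"))
  }
  report
}

report_markdown <- function(report) {
  s <- report$summary
  lines <- c(
    "# EWAS pipeline report", "",
    "## Discovery",
    sprintf("- selected CpGs after recursive RF: %d", s$n_selected),
    sprintf("- discovered CpGs (crude model, q < %g): %d",
            report$discovery$q_threshold, s$n_discovered),
    ""
  )
  if (!is.null(report$replication)) {
    lines <- c(lines, "## Replication",
               sprintf("- direction-consistent (crude): %d of %d",
                       s$n_direction_consistent, s$n_discovered),
               sprintf("- significant and direction-consistent (adjusted): %d",
                       s$n_replicated),
               "")
  }
  if (!report$followup$skipped) {
    fu <- report$followup
    lines <- c(lines, "## Functional follow-up (cord blood)",
               sprintf("- DNAm (%s) vs expression (%s): rho = %.3f, p = %.3g",
                       fu$target_cpg, fu$target_probe,
                       fu$dnam_expression$rho, fu$dnam_expression$p_value),
               "")
  } else {
    lines <- c(lines, "## Functional follow-up", "- skipped", "")
  }
  lines
}

#' @export
print.ewas_full_report <- function(x, ...) {
  cat(report_markdown(x), sep = "\n")
  invisible(x)
}
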