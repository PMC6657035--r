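# Seeded synthetic methylation cohorts with known cell mixtures, planted
# case-associated CpGs and an expression probe coupled to the first planted
# CpG. Every downstream stage of the pipeline has a recoverable ground truth
# in the returned object.

default_dirichlet_base <- function(panel_name, concentration = 50) {
  means <- switch(panel_name,
    # control-group blood composition means (adult whole blood)
    adult7 = c(CD8T = 0.098, CD4T = 0.110, NK = 0.070, Bcell = 0.039,
               Mono = 0.074, Eos = 0.021, Gran = 0.588),
    # cord blood composition including nucleated red blood cells
    cord7 = c(CD8T = 0.060, CD4T = 0.140, NK = 0.030, Bcell = 0.060,
              Mono = 0.080, Gran = 0.530, nRBC = 0.100),
    stop("unknown panel: ", panel_name, call. = FALSE)
  )
  means / sum(means) * concentration
}

#' Configuration of a synthetic cohort
#'
#' Defaults reproduce the structure of an adolescent asthma case-control
#' methylation study: 370 samples, 13.9% case prevalence, 66.2% female,
#' seven-cell-type blood mixtures whose eosinophil fraction averages 0.045
#' in cases versus 0.021 in controls, and ten planted case-hypomethylated
#' CpGs. `planted_effect` is the per-case shift of the mixture-mean
#' methylation on the M scale (log2 odds of methylation); the default of
#' -1.0 (about 1.5 within-group SDs at the default noise level) is
#' calibrated so that the planted CpGs are reliably recoverable by the
#' split-sample discovery pipeline, which places their crude per-unit-M
#' odds ratios at the strong end of reported associations. `beta_precision`
#' is the Beta-distribution concentration of the residual (biological plus
#' technical) variation around the mixture mean. For cord-blood cohorts
#' (`panel_name = "cord7"`) the case-shifted component is the nRBC fraction.
#'
#' @param n_samples,n_cpgs cohort dimensions.
#' @param prevalence case proportion.
#' @param prop_female female proportion.
#' @param panel_name `"adult7"` or `"cord7"`.
#' @param dirichlet_base per-cell-type Dirichlet concentration weights
#'   (control group); defaults to control blood-composition means scaled to
#'   a total concentration of 50.
#' @param eos_mean_case,eos_mean_control target group means of the shifted
#'   cell fraction (eosinophils; nRBC for cord blood).
#' @param n_discriminating_cpgs_per_type number of cell-type-marker CpGs per
#'   cell type.
#' @param n_planted_cpgs number of case-associated CpGs.
#' @param planted_effect case shift at planted CpGs, M-value units (negative
#'   means cases are hypomethylated).
#' @param beta_precision Beta concentration of measurement noise; `Inf`
#'   disables noise.
#' @param n_expression_probes number of log2 expression probes; probe 1 is
#'   coupled to the first planted CpG.
#' @param expr_dnam_rho target Spearman correlation between probe 1 and the
#'   first planted CpG's M-values.
#' @param expr_wheeze_logor log odds of infant wheeze per unit log2
#'   expression of probe 1.
#' @param wheeze_prevalence baseline infant wheeze proportion.
#' @param rng_seed integer seed for everything sample-level (case status,
#'   compositions, noise, phenotypes, expression); identical seeds give
#'   byte-identical cohorts.
#' @param structure_seed integer seed for the cohort-invariant biology (CpG
#'   role assignment and cell-type profiles). Two configs sharing
#'   `structure_seed` and dimensions describe independent cohorts measured
#'   on the same loci - the replication-study setting.
#' @return a `simulation_config` list.
#' @export
simulation_config <- function(n_samples = 370,
                              n_cpgs = 5000,
                              prevalence = 0.139,
                              prop_female = 0.662,
                              panel_name = "adult7",
                              dirichlet_base = NULL,
                              eos_mean_case = 0.045,
                              eos_mean_control = 0.021,
                              n_discriminating_cpgs_per_type = 40,
                              n_planted_cpgs = 10,
                              planted_effect = -1.0,
                              beta_precision = 45,
                              n_expression_probes = 50,
                              expr_dnam_rho = -0.22,
                              expr_wheeze_logor = log(3.14),
                              wheeze_prevalence = 0.25,
                              rng_seed = 1L,
                              structure_seed = 20201L) {
  if (!panel_name %in% names(CELL_PANELS)) stop("unknown panel: ", panel_name, call. = FALSE)
  if (is.null(dirichlet_base)) dirichlet_base <- default_dirichlet_base(panel_name)
  cfg <- list(n_samples = as.integer(n_samples), n_cpgs = as.integer(n_cpgs),
              prevalence = prevalence, prop_female = prop_female,
              panel_name = panel_name, dirichlet_base = dirichlet_base,
              eos_mean_case = eos_mean_case, eos_mean_control = eos_mean_control,
              n_discriminating_cpgs_per_type = as.integer(n_discriminating_cpgs_per_type),
              n_planted_cpgs = as.integer(n_planted_cpgs),
              planted_effect = planted_effect, beta_precision = beta_precision,
              n_expression_probes = as.integer(n_expression_probes),
              expr_dnam_rho = expr_dnam_rho,
              expr_wheeze_logor = expr_wheeze_logor,
              wheeze_prevalence = wheeze_prevalence,
              rng_seed = as.integer(rng_seed),
              structure_seed = as.integer(structure_seed))
  for (nm in c("prevalence", "prop_female")) {
    if (cfg[[nm]] <= 0 || cfg[[nm]] >= 1) stop(nm, " must lie in (0,1)", call. = FALSE)
  }
  for (nm in c("eos_mean_case", "eos_mean_control")) {
    if (cfg[[nm]] <= 0 || cfg[[nm]] >= 1) {
      stop("infeasible composition target: ", nm, " outside the simplex", call. = FALSE)
    }
  }
  counts <- c("n_samples", "n_cpgs", "n_discriminating_cpgs_per_type",
              "n_planted_cpgs", "n_expression_probes")
  if (any(vapply(cfg[counts], function(v) v < 1L, logical(1)))) {
    stop("all counts must be positive", call. = FALSE)
  }
  k <- length(CELL_PANELS[[panel_name]])
  if (length(cfg$dirichlet_base) != k || any(cfg$dirichlet_base <= 0)) {
    stop("dirichlet_base must hold one positive weight per cell type", call. = FALSE)
  }
  needed <- k * cfg$n_discriminating_cpgs_per_type + cfg$n_planted_cpgs
  if (needed > cfg$n_cpgs) {
    stop("n_cpgs too small for the requested marker and planted CpGs", call. = FALSE)
  }
  class(cfg) <- "simulation_config"
  cfg
}

rdirichlet_mat <- function(n, alpha) {
  k <- length(alpha)
  g <- matrix(stats::rgamma(n * k, shape = rep(alpha, each = n)), nrow = n)
  w <- g / rowSums(g)
  colnames(w) <- names(alpha)
  w
}

# Rescale one column of a composition matrix so its mean hits `target`
# exactly, renormalizing the other components proportionally.
rescale_component <- function(w, col, target) {
  e <- w[, col]
  sc <- target / mean(e)
  e2 <- e * sc
  if (any(e2 >= 1)) {
    stop("infeasible composition target: rescaled fraction leaves the simplex",
         call. = FALSE)
  }
  other <- w[, setdiff(colnames(w), col), drop = FALSE]
  other <- other * (1 - e2) / (1 - e)
  out <- cbind(other, e2)
  colnames(out) <- c(setdiff(colnames(w), col), col)
  out[, colnames(w), drop = FALSE]
}

#' Generate a synthetic methylation cohort
#'
#' Draws per-sample cell compositions from a Dirichlet whose case group has
#' its eosinophil (adult) or nRBC (cord) component rescaled so the realized
#' case/control group means equal the configured targets exactly; builds
#' per-cell-type mean-beta profiles in which marker CpGs are near 0 in one
#' type and near 1 in the others (half in each direction per type); mixes
#' them into bulk means; shifts planted CpGs by `planted_effect` on the M
#' scale in cases; and adds Beta-distributed noise with the configured
#' concentration. Expression probe 1 is generated to have the target
#' Spearman correlation with the first planted CpG's observed M-values, and
#' infant wheeze outcomes are driven by that probe.
#'
#' @param config a [simulation_config()].
#' @return a `synthetic_cohort` list: `beta`, `phenotypes`,
#'   `true_proportions`, `reference_panel`, `profile_library`, `expression`,
#'   `truth` (planted CpG ids and signed effects), `config`.
#' @export
generate_cohort <- function(config = simulation_config()) {
  stopifnot(inherits(config, "simulation_config"))
  n <- config$n_samples
  p <- config$n_cpgs
  cells <- CELL_PANELS[[config$panel_name]]
  k <- length(cells)
  shift_cell <- if (config$panel_name == "cord7") "nRBC" else "Eos"

  sample_ids <- sprintf("s%05d", seq_len(n))
  cpg_ids <- sprintf("cg%07d", seq_len(p))

  # --- cohort-invariant biology: CpG roles and type profiles --------------
  set.seed(config$structure_seed)
  n_disc <- config$n_discriminating_cpgs_per_type
  special <- sample.int(p, k * n_disc + config$n_planted_cpgs)
  disc_idx <- matrix(special[seq_len(k * n_disc)], nrow = k)  # row t = type t's markers
  planted_idx <- special[k * n_disc + seq_len(config$n_planted_cpgs)]

  base_beta <- stats::runif(p, 0.15, 0.85)
  base_beta[planted_idx] <- stats::runif(config$n_planted_cpgs, 0.70, 0.90)
  profile <- matrix(rep(base_beta, each = k), nrow = k,
                    dimnames = list(cells, cpg_ids))
  for (t in seq_len(k)) {
    own <- disc_idx[t, ]
    n_low <- floor(n_disc / 2)                       # near-0 in own type
    low_set <- own[seq_len(n_low)]
    high_set <- setdiff(own, low_set)                # near-1 in own type
    profile[, low_set] <- 0.93 + stats::runif(k * length(low_set), 0, 0.04)
    profile[t, low_set] <- 0.03 + stats::runif(length(low_set), 0, 0.04)
    profile[, high_set] <- 0.03 + stats::runif(k * length(high_set), 0, 0.04)
    profile[t, high_set] <- 0.93 + stats::runif(length(high_set), 0, 0.04)
  }

  # --- sample-level draws -------------------------------------------------
  set.seed(config$rng_seed)

  # --- case status and sex ------------------------------------------------
  n_case <- max(1L, round(config$prevalence * n))
  if (n - n_case < 1L) stop("prevalence leaves no controls", call. = FALSE)
  asthma <- integer(n)
  asthma[sample.int(n, n_case)] <- 1L
  sex <- stats::rbinom(n, 1L, config$prop_female)

  # --- cell compositions --------------------------------------------------
  alpha0 <- sum(config$dirichlet_base)
  base_ctl <- config$dirichlet_base
  names(base_ctl) <- cells
  base_ctl[shift_cell] <- alpha0 * config$eos_mean_control
  base_ctl[setdiff(cells, shift_cell)] <-
    base_ctl[setdiff(cells, shift_cell)] *
    (alpha0 - base_ctl[shift_cell]) / sum(base_ctl[setdiff(cells, shift_cell)])
  base_case <- base_ctl
  base_case[shift_cell] <- alpha0 * config$eos_mean_case
  base_case[setdiff(cells, shift_cell)] <-
    base_ctl[setdiff(cells, shift_cell)] *
    (alpha0 - base_case[shift_cell]) / sum(base_ctl[setdiff(cells, shift_cell)])

  w <- matrix(NA_real_, n, k, dimnames = list(sample_ids, cells))
  idx_case <- which(asthma == 1L)
  idx_ctl <- which(asthma == 0L)
  w[idx_case, ] <- rdirichlet_mat(length(idx_case), base_case)
  w[idx_ctl, ] <- rdirichlet_mat(length(idx_ctl), base_ctl)
  w[idx_case, ] <- rescale_component(w[idx_case, , drop = FALSE], shift_cell,
                                     config$eos_mean_case)
  w[idx_ctl, ] <- rescale_component(w[idx_ctl, , drop = FALSE], shift_cell,
                                    config$eos_mean_control)

  # --- bulk mixture means, planted case shift, noise ----------------------
  mu <- w %*% profile
  if (config$planted_effect != 0) {
    mcase <- log2(mu[idx_case, planted_idx, drop = FALSE] /
                  (1 - mu[idx_case, planted_idx, drop = FALSE]))
    mu[idx_case, planted_idx] <- stats::plogis((mcase + config$planted_effect) * log(2))
  }
  mu <- pmin(pmax(mu, BETA_EPS), 1 - BETA_EPS)
  if (is.finite(config$beta_precision)) {
    s <- config$beta_precision
    obs <- matrix(stats::rbeta(n * p, c(mu) * s, (1 - c(mu)) * s), n, p)
  } else {
    obs <- mu
  }
  beta <- beta_matrix(obs, sample_ids, cpg_ids)

  # --- phenotypes ---------------------------------------------------------
  atopy <- stats::rbinom(n, 1L, stats::plogis(stats::qlogis(0.295) +
            (stats::qlogis(0.66) - stats::qlogis(0.295)) * asthma))
  feno <- exp(log(14) + log(21 / 14) * asthma + stats::rnorm(n, 0, 0.7))
  fev1_fvc <- pmin(pmax(0.88 - 0.05 * asthma + stats::rnorm(n, 0, 0.065), 0.2), 1)
  fef2575 <- pmax(3.94 - 0.20 * asthma + stats::rnorm(n, 0, 0.72), 0.3)
  season <- factor(sample(c("winter", "spring", "summer", "autumn"), n, replace = TRUE),
                   levels = c("winter", "spring", "summer", "autumn"))

  # --- expression ---------------------------------------------------------
  np <- config$n_expression_probes
  probe_ids <- sprintf("pr%05d", seq_len(np))
  m_target <- log2(obs[, planted_idx[1]] / (1 - obs[, planted_idx[1]]))
  z <- as.numeric(scale(m_target))
  rho_pearson <- 2 * sin(pi * config$expr_dnam_rho / 6)  # Gaussian-copula match
  signal <- rho_pearson * z + sqrt(1 - rho_pearson^2) * stats::rnorm(n)
  probe_level <- stats::rnorm(np, 8, 1)
  array_shift <- stats::rnorm(n, 0, 0.5)
  expr <- matrix(stats::rnorm(n * np), n, np) +
    matrix(rep(probe_level, each = n), n, np) + array_shift
  expr[, 1] <- probe_level[1] + array_shift + signal
  expression <- expression_matrix(expr, sample_ids, probe_ids)

  # --- infant wheeze driven by probe 1 ------------------------------------
  lp <- stats::qlogis(config$wheeze_prevalence) +
    config$expr_wheeze_logor * (signal - mean(signal))
  wheeze_no_cold <- stats::rbinom(n, 1L, stats::plogis(lp))
  lp2 <- stats::qlogis(min(0.95, 1.6 * config$wheeze_prevalence)) +
    0.8 * config$expr_wheeze_logor * (signal - mean(signal))
  any_wheeze <- pmax(wheeze_no_cold, stats::rbinom(n, 1L, stats::plogis(lp2)))

  phenotypes <- phenotype_table(data.frame(
    sample_id = sample_ids, asthma = asthma, sex = sex, atopy = atopy,
    feno = feno, fev1_fvc = fev1_fvc, fef2575 = fef2575,
    wheeze_no_cold = wheeze_no_cold, any_wheeze = any_wheeze,
    season_of_birth = season, cohort_label = "synthetic",
    stringsAsFactors = FALSE
  ))

  true_proportions <- cell_proportions(
    data.frame(sample_id = sample_ids, w, check.names = FALSE,
               stringsAsFactors = FALSE),
    config$panel_name, sum_constrained = TRUE
  )

  panel <- reference_panel(profile[, sort(c(disc_idx)), drop = FALSE],
                           config$panel_name)

  structure(list(
    beta = beta,
    phenotypes = phenotypes,
    true_proportions = true_proportions,
    reference_panel = panel,
    profile_library = profile,
    expression = expression,
    truth = data.frame(cpg_id = cpg_ids[planted_idx],
                       effect = config$planted_effect,
                       stringsAsFactors = FALSE),
    target_probe = probe_ids[1],
    config = config
  ), class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("synthetic_cohort: %d samples x %d CpGs (%s panel), %d planted CpGs\n",
              nrow(x$beta), ncol(x$beta), x$config$panel_name, nrow(x$truth)))
  invisible(x)
}

#' Subset a cohort to a set of samples
#' @param cohort a `synthetic_cohort`.
#' @param sample_ids ids to keep (order preserved).
#' @return the subsetted cohort.
#' @export
subset_cohort <- function(cohort, sample_ids) {
  stopifnot(all(sample_ids %in% rownames(cohort$beta)))
  out <- cohort
  out$beta <- cohort$beta[sample_ids, , drop = FALSE]
  out$phenotypes <- phenotype_table(
    cohort$phenotypes[match(sample_ids, cohort$phenotypes$sample_id), , drop = FALSE])
  tp <- cohort$true_proportions[
    match(sample_ids, cohort$true_proportions$sample_id), , drop = FALSE]
  out$true_proportions <- cell_proportions(tp, attr(cohort$true_proportions, "panel_name"),
                                           sum_constrained = TRUE)
  out$expression <- cohort$expression[sample_ids, , drop = FALSE]
  out
}

#' Split a cohort into two disjoint stages, stratified by case status
#'
#' Within each case stratum, `round(stage1_fraction * n_stratum)` samples go
#' to stage 1 and the rest to stage 2, so both halves match the cohort
#' prevalence to within one sample. The partition is exhaustive, disjoint
#' and seeded.
#'
#' @param cohort a `synthetic_cohort`.
#' @param stage1_fraction proportion of samples for stage 1, in (0,1).
#' @param seed integer seed.
#' @return list with elements `stage1` and `stage2` (cohorts).
#' @export
split_cohort <- function(cohort, stage1_fraction, seed = 1L) {
  if (stage1_fraction <= 0 || stage1_fraction >= 1) {
    stop("stage1_fraction must lie in (0,1)", call. = FALSE)
  }
  pheno <- cohort$phenotypes
  strata <- split(pheno$sample_id, pheno$asthma)
  if (any(vapply(strata, length, integer(1)) < 2L)) {
    stop("each case stratum needs >= 2 samples to be split", call. = FALSE)
  }
  set.seed(seed)
  s1 <- unlist(lapply(strata, function(ids) {
    n1 <- round(stage1_fraction * length(ids))
    n1 <- min(max(n1, 1L), length(ids) - 1L)   # both halves non-empty per stratum
    sample(ids, n1)
  }), use.names = FALSE)
  s1 <- pheno$sample_id[pheno$sample_id %in% s1]
  s2 <- setdiff(pheno$sample_id, s1)
  list(stage1 = subset_cohort(cohort, s1), stage2 = subset_cohort(cohort, s2))
}

#' Write a cohort's components to tab-delimited files
#'
#' Writes `beta.tsv`, `pheno.tsv`, `true_props.tsv`, `panel.tsv`,
#' `expression.tsv` and `truth.tsv` into `dir`.
#'
#' @param cohort a `synthetic_cohort`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_matrix(cohort$beta, file.path(dir, "beta.tsv"))
  write_phenotypes(cohort$phenotypes, file.path(dir, "pheno.tsv"))
  write_cell_proportions(cohort$true_proportions, file.path(dir, "true_props.tsv"))
  write_reference_panel(cohort$reference_panel, file.path(dir, "panel.tsv"))
  write_matrix(cohort$expression, file.path(dir, "expression.tsv"))
  utils::write.table(cohort$truth, file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}
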