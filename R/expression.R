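# Cord-blood expression normalization and the DNAm-expression-wheeze
# follow-up models.

#' Percentile-shift normalization of log2 expression
#'
#' Per sample, subtracts that sample's anchor percentile (75th by default,
#' the GeneSpring "percentile shift" convention; type-7 interpolation), so
#' the per-sample anchor percentile of the output is exactly 0. The
#' operation is idempotent and invariant to per-sample constant shifts.
#'
#' @param expr an [expression_matrix()] of log2-scale values.
#' @param percentile anchor percentile, in (0, 100).
#' @return a normalized [expression_matrix()].
#' @export
percentile_shift_normalize <- function(expr, percentile = 75) {
  vals <- unclass(expr)
  n_obs <- rowSums(!is.na(vals))
  if (any(n_obs < 2L)) {
    stop("every sample needs >= 2 non-missing probes to normalize", call. = FALSE)
  }
  anchors <- apply(vals, 1, stats::quantile, probs = percentile / 100,
                   type = 7, na.rm = TRUE)
  out <- sweep(vals, 1, anchors)
  res <- expression_matrix(out, rownames(expr), colnames(expr))
  attr(res, "anchor_percentile") <- percentile
  res
}

#' Spearman correlation between methylation and expression
#'
#' @param m numeric vector of M-values at one CpG.
#' @param expr numeric vector of log2 expression at one probe, aligned with
#'   `m`.
#' @return list with `rho`, `p_value`, `n`, and `flag` (`"constant_input"`
#'   when either vector has no variance).
#' @export
dnam_expression_correlation <- function(m, expr) {
  ok <- stats::complete.cases(m, expr)
  n <- sum(ok)
  if (n < 10L) stop("need >= 10 paired complete observations", call. = FALSE)
  if (stats::sd(m[ok]) == 0 || stats::sd(expr[ok]) == 0) {
    return(list(rho = NA_real_, p_value = NA_real_, n = n, flag = "constant_input"))
  }
  ct <- suppressWarnings(stats::cor.test(m[ok], expr[ok], method = "spearman",
                                         exact = FALSE))
  list(rho = unname(ct$estimate), p_value = ct$p.value, n = n, flag = "")
}

season_dummies <- function(season) {
  season <- factor(season, levels = c("winter", "spring", "summer", "autumn"))
  present <- levels(season)[levels(season) %in% unique(as.character(season))]
  empty <- setdiff(levels(season), present)
  if (length(empty)) {
    warning("season_of_birth has empty levels dropped: ",
            paste(empty, collapse = ", "))
    season <- factor(as.character(season), levels = present)
  }
  if (nlevels(season) < 2L) return(NULL)
  mm <- stats::model.matrix(~season)[, -1, drop = FALSE]
  colnames(mm) <- sub("^season", "season_", colnames(mm))
  # model.matrix drops rows with NA; rebuild on full length
  out <- matrix(NA_real_, length(season), ncol(mm), dimnames = list(NULL, colnames(mm)))
  out[!is.na(season), ] <- mm
  out
}

#' Infant wheeze models for a methylation or expression predictor
#'
#' Per outcome (wheeze without cold, any wheeze), fits three nested logistic
#' models: crude; adjusted for infant sex and season of birth (dummy-coded,
#' winter reference); and further adjusted for cord-blood cell fractions
#' (nRBC retained, granulocytes dropped as the compositional reference).
#'
#' @param predictor numeric vector (M-values at a CpG or log2 expression at
#'   a probe), aligned with `pheno`.
#' @param pheno a [phenotype_table()] with `wheeze_no_cold` / `any_wheeze`
#'   and `season_of_birth`.
#' @param cord_props optional cord-blood [cell_proportions()]; required for
#'   the fully adjusted model.
#' @param outcomes outcomes to model.
#' @param predictor_id label for the output.
#' @return data.frame: `probe_id`, `outcome`, `model` (crude / adjusted1 /
#'   adjusted2), `or_value`, `ci_low`, `ci_high`, `p_value`, `n_used`,
#'   `converged`.
#' @export
fit_wheeze_models <- function(predictor, pheno, cord_props = NULL,
                              outcomes = c("wheeze_no_cold", "any_wheeze"),
                              predictor_id = "predictor") {
  outcomes <- intersect(outcomes, names(pheno))
  if (length(outcomes) == 0L) stop("no wheeze outcomes in the phenotype table", call. = FALSE)
  sd_cov <- season_dummies(pheno$season_of_birth)
  adj1 <- cbind(sex = pheno$sex, sd_cov)
  cellcov <- NULL
  if (!is.null(cord_props)) {
    cellcov <- cell_covariate_matrix(cord_props)
    cellcov <- cellcov[match(pheno$sample_id, rownames(cellcov)), , drop = FALSE]
  }
  res <- list()
  for (outc in outcomes) {
    y <- pheno[[outc]]
    res[[paste0(outc, "_crude")]] <-
      cbind(probe_id = predictor_id, outcome = outc, model = "crude",
            fit_logistic(y, predictor))
    res[[paste0(outc, "_adj1")]] <-
      cbind(probe_id = predictor_id, outcome = outc, model = "adjusted1",
            fit_logistic(y, predictor, adj1))
    if (!is.null(cellcov)) {
      res[[paste0(outc, "_adj2")]] <-
        cbind(probe_id = predictor_id, outcome = outc, model = "adjusted2",
              fit_logistic(y, predictor, cbind(adj1, cellcov)))
    }
  }
  out <- do.call(rbind, res)
  out <- out[, c("probe_id", "outcome", "model", "coefficient", "or_value",
                 "ci_low", "ci_high", "p_value", "n_used", "converged")]
  rownames(out) <- NULL
  out
}
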