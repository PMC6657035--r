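# Stage-2 CpG-wise logistic association (crude and cell/sex adjusted),
# traditional linear EWAS, Storey q-values, replication comparison and
# phenotype correlation analyses.

#' Covariate matrix from cell proportions
#'
#' Cell fractions are compositional (they sum to 1), so one component must
#' be dropped before they enter a model with an intercept; by convention the
#' granulocyte fraction is dropped, keeping nRBC for cord panels.
#'
#' @param props a [cell_proportions()] table.
#' @param drop cell type to drop (default `"Gran"`).
#' @return numeric matrix, samples x retained cell types, with rownames set
#'   to sample ids.
#' @export
cell_covariate_matrix <- function(props, drop = "Gran") {
  cells <- setdiff(names(props), c("sample_id", drop))
  m <- as.matrix(props[cells])
  rownames(m) <- props$sample_id
  m
}

#' Logistic association between a binary outcome and one predictor
#'
#' Maximum-likelihood logistic fit on complete cases, with Wald 95%
#' confidence intervals on the odds-ratio scale. Quasi-complete separation
#' or non-convergence is flagged (`converged = FALSE`) and the fit is
#' retained rather than dropped.
#'
#' @param y binary outcome coded {0,1}.
#' @param x numeric predictor (e.g. M-values at one CpG).
#' @param covariates optional numeric matrix or data.frame of additional
#'   covariates, aligned with `y`.
#' @return one-row data.frame: `coefficient` (log odds per unit `x`),
#'   `or_value`, `ci_low`, `ci_high`, `p_value`, `n_used`, `converged`.
#' @export
fit_logistic <- function(y, x, covariates = NULL) {
  df <- data.frame(.y = y, .x = x)
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    names(covariates) <- make.names(names(covariates))
    df <- cbind(df, covariates)
  }
  cc <- stats::complete.cases(df)
  df <- df[cc, , drop = FALSE]
  if (length(unique(df$.y)) < 2L) stop("outcome has a single class", call. = FALSE)
  separation <- FALSE
  fit <- withCallingHandlers(
    stats::glm(.y ~ ., data = df, family = stats::binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1|did not converge",
                conditionMessage(w))) {
        separation <<- TRUE
        invokeRestart("muffleWarning")
      }
    }
  )
  # quasi-complete separation: fitted probabilities pinned at 0/1 (glm's own
  # warning only fires at machine-epsilon resolution)
  if (any(fit$fitted.values < 1e-7) || any(fit$fitted.values > 1 - 1e-7)) {
    separation <- TRUE
  }
  sm <- summary(fit)$coefficients
  co <- sm[".x", "Estimate"]
  se <- sm[".x", "Std. Error"]
  data.frame(coefficient = co,
             or_value = exp(co),
             ci_low = exp(co - 1.96 * se),
             ci_high = exp(co + 1.96 * se),
             p_value = sm[".x", "Pr(>|z|)"],
             n_used = nrow(df),
             converged = fit$converged && !separation)
}

#' CpG-wise logistic association models for a stage-2 sample
#'
#' Fits, per CpG, a crude logistic model of case status on M-values and
#' (when cell proportions are supplied) a model adjusted for sex and cell
#' fractions with the granulocyte component dropped.
#'
#' @param m an [m_matrix()] (typically trimmed with [trim_outliers()]).
#' @param pheno a [phenotype_table()] aligned with `m` by `sample_id`.
#' @param props optional [cell_proportions()] for the adjusted model.
#' @param cpgs CpG ids to test (default: all columns of `m`).
#' @param models subset of `c("crude", "adjusted")`.
#' @return data.frame of association results, one row per CpG x model, with
#'   `model_kind` in `logistic_crude` / `logistic_adjusted`.
#' @export
stage2_associations <- function(m, pheno, props = NULL,
                                cpgs = colnames(m),
                                models = c("crude", "adjusted")) {
  models <- match.arg(models, several.ok = TRUE)
  stopifnot(all(cpgs %in% colnames(m)))
  y <- pheno$asthma[match(rownames(m), pheno$sample_id)]
  adj_cov <- NULL
  if ("adjusted" %in% models) {
    if (is.null(props)) stop("adjusted models need cell proportions", call. = FALSE)
    cellcov <- cell_covariate_matrix(props)
    cellcov <- cellcov[match(rownames(m), rownames(cellcov)), , drop = FALSE]
    adj_cov <- cbind(sex = pheno$sex[match(rownames(m), pheno$sample_id)], cellcov)
  }
  res <- lapply(cpgs, function(cg) {
    x <- unclass(m)[, cg]
    out <- list()
    if ("crude" %in% models) {
      r <- fit_logistic(y, x)
      out$crude <- cbind(cpg_id = cg, model_kind = "logistic_crude", r)
    }
    if ("adjusted" %in% models) {
      r <- fit_logistic(y, x, adj_cov)
      out$adjusted <- cbind(cpg_id = cg, model_kind = "logistic_adjusted", r)
    }
    do.call(rbind, out)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Traditional linear EWAS
#'
#' Regresses the beta value of each CpG (dependent variable) on case status
#' and optional covariates by ordinary least squares; the reported
#' coefficient is the adjusted mean beta difference (case minus control).
#'
#' @param beta a [beta_matrix()].
#' @param y binary case status aligned with the rows of `beta`.
#' @param covariates optional numeric matrix/data.frame. Supplying all 7
#'   compositional cell fractions together with the intercept is a rank
#'   deficiency and raises an error naming the collinear columns.
#' @return data.frame with one row per CpG: `cpg_id`, `model_kind`,
#'   `coefficient`, `ci_low`, `ci_high`, `p_value`, `n_used`.
#' @export
ewas_linear <- function(beta, y, covariates = NULL) {
  design <- cbind(`(Intercept)` = 1, asthma = y)
  if (!is.null(covariates)) {
    cm <- as.matrix(as.data.frame(covariates))
    design <- cbind(design, cm)
  }
  qrd <- qr(design[stats::complete.cases(design), , drop = FALSE])
  if (qrd$rank < ncol(design)) {
    bad <- colnames(design)[qrd$pivot[(qrd$rank + 1):ncol(design)]]
    stop("rank-deficient design; collinear columns: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  model_kind <- if (is.null(covariates)) "linear_crude" else "linear_adjusted"
  vals <- unclass(beta)
  res <- lapply(colnames(vals), function(cg) {
    df <- data.frame(.b = vals[, cg], design[, -1, drop = FALSE])
    cc <- stats::complete.cases(df)
    fit <- stats::lm(.b ~ ., data = df[cc, , drop = FALSE])
    sm <- summary(fit)$coefficients
    co <- sm["asthma", "Estimate"]; se <- sm["asthma", "Std. Error"]
    data.frame(cpg_id = cg, model_kind = model_kind, coefficient = co,
               ci_low = co - 1.96 * se, ci_high = co + 1.96 * se,
               p_value = sm["asthma", "Pr(>|t|)"], n_used = sum(cc))
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Storey q-values
#'
#' Estimates the null proportion pi0 by the lambda-grid smoother method
#' (lambda = 0.05, 0.10, ..., 0.95; cubic smoothing spline through
#' `#(p > lambda) / (m (1 - lambda))`, evaluated at the largest lambda,
#' clamped to (0, 1]) and converts p-values to q-values by the step-up rule
#' `q_(i) = min_(j >= i) pi0 m p_(j) / j`. With fewer than 100 features the
#' smoother is unreliable, so pi0 is fixed at 1, which makes the q-values
#' identical to Benjamini-Hochberg adjusted p-values.
#'
#' @param p_values numeric vector of p-values in (0, 1].
#' @param ids optional feature ids.
#' @return a `qvalue_set` list: `ids`, `p_values`, `q_values`, `pi0`,
#'   `pi0_method` (`"smoother"` or `"bh_fallback"`).
#' @export
storey_qvalues <- function(p_values, ids = NULL) {
  m <- length(p_values)
  if (m == 0L) stop("empty p-value vector", call. = FALSE)
  if (any(is.na(p_values)) || any(p_values <= 0 | p_values > 1)) {
    stop("p-values must lie in (0, 1]", call. = FALSE)
  }
  if (is.null(ids)) ids <- as.character(seq_len(m))
  if (m < 100L) {
    pi0 <- 1
    method <- "bh_fallback"
  } else {
    lambda <- seq(0.05, 0.95, by = 0.05)
    pi0_l <- vapply(lambda, function(l) mean(p_values > l) / (1 - l), numeric(1))
    fit <- stats::smooth.spline(lambda, pi0_l, df = 3)
    pi0 <- stats::predict(fit, x = max(lambda))$y
    pi0 <- min(pi0, 1)
    if (pi0 <= 0) {
      warning("pi0 estimate <= 0; clamped to 1/m")
      pi0 <- 1 / m
    }
    method <- "smoother"
  }
  o <- order(p_values)
  q_sorted <- pi0 * m * p_values[o] / seq_len(m)
  q_sorted <- pmin(rev(cummin(rev(q_sorted))), 1)
  q <- numeric(m)
  q[o] <- q_sorted
  structure(list(ids = ids, p_values = p_values, q_values = q,
                 pi0 = pi0, pi0_method = method),
            class = "qvalue_set")
}

#' @export
print.qvalue_set <- function(x, ...) {
  cat(sprintf("qvalue_set: %d features, pi0 = %.3f (%s), %d with q < 0.05\n",
              length(x$p_values), x$pi0, x$pi0_method, sum(x$q_values < 0.05)))
  invisible(x)
}

#' Compare discovery and replication association results
#'
#' Per CpG and model kind, flags whether the direction of association
#' (sign of the log odds ratio) agrees between cohorts and whether the
#' replication p-value is below `alpha` (strict inequality). Direction
#' consistency is only assessed where both models converged.
#'
#' @param discovery,replication association data.frames from
#'   [stage2_associations()] (must share CpG ids).
#' @param alpha replication significance level.
#' @return data.frame with per-CpG flags plus a `summary` attribute holding
#'   counts of direction-consistent and replicated loci per model kind.
#' @export
assess_replication <- function(discovery, replication, alpha = 0.05) {
  merged <- merge(discovery, replication, by = c("cpg_id", "model_kind"),
                  suffixes = c("_discovery", "_replication"))
  if (nrow(merged) == 0L) stop("no overlapping CpGs between cohorts", call. = FALSE)
  both_conv <- merged$converged_discovery & merged$converged_replication
  merged$direction_consistent <- ifelse(
    both_conv,
    sign(log(merged$or_value_discovery)) == sign(log(merged$or_value_replication)),
    NA)
  merged$replication_significant <- merged$p_value_replication < alpha
  out <- merged[c("cpg_id", "model_kind", "or_value_discovery", "or_value_replication",
                  "p_value_replication", "direction_consistent",
                  "replication_significant")]
  smry <- stats::aggregate(
    cbind(n_consistent = direction_consistent,
          n_replicated = replication_significant) ~ model_kind,
    data = out, FUN = function(v) sum(v, na.rm = TRUE), na.action = stats::na.pass)
  attr(out, "summary") <- smry
  attr(out, "alpha") <- alpha
  out
}

spearman_row <- function(x, y, label) {
  ok <- stats::complete.cases(x, y)
  n <- sum(ok)
  if (n < 10L) {
    return(data.frame(variable = label, test = "spearman", estimate = NA_real_,
                      p_value = NA_real_, n = n, flag = "too_few_pairs"))
  }
  if (stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) {
    return(data.frame(variable = label, test = "spearman", estimate = NA_real_,
                      p_value = NA_real_, n = n, flag = "zero_variance"))
  }
  ct <- suppressWarnings(stats::cor.test(x[ok], y[ok], method = "spearman",
                                         exact = FALSE))
  data.frame(variable = label, test = "spearman", estimate = unname(ct$estimate),
             p_value = ct$p.value, n = n, flag = "")
}

#' Correlations of methylation at one CpG with phenotypes and cell fractions
#'
#' Spearman correlations of M-values with log(FeNO), FEV1/FVC, FEF25-75 and
#' each estimated cell fraction, plus a Welch t-test of M-values by atopy.
#' FeNO is log-transformed before correlation. Contrasts with fewer than 10
#' paired observations, or zero-variance inputs, are flagged and their
#' statistics omitted.
#'
#' @param m numeric vector of M-values at one CpG, aligned with `pheno`.
#' @param pheno a [phenotype_table()].
#' @param props optional [cell_proportions()] aligned by `sample_id`.
#' @return data.frame: `variable`, `test`, `estimate` (rho, or mean
#'   difference for the t-test), `p_value`, `n`, `flag`.
#' @export
phenotype_correlations <- function(m, pheno, props = NULL) {
  rows <- list()
  if ("feno" %in% names(pheno)) {
    rows$feno <- spearman_row(m, log(pheno$feno), "log_feno")
  }
  if ("fev1_fvc" %in% names(pheno)) {
    rows$fev1_fvc <- spearman_row(m, pheno$fev1_fvc, "fev1_fvc")
  }
  if ("fef2575" %in% names(pheno)) {
    rows$fef2575 <- spearman_row(m, pheno$fef2575, "fef2575")
  }
  if ("atopy" %in% names(pheno)) {
    ok <- stats::complete.cases(m, pheno$atopy)
    n <- sum(ok)
    groups <- split(m[ok], pheno$atopy[ok])
    if (n < 10L || length(groups) < 2L || any(vapply(groups, length, 1L) < 2L)) {
      rows$atopy <- data.frame(variable = "atopy", test = "welch_t",
                               estimate = NA_real_, p_value = NA_real_,
                               n = n, flag = "too_few_pairs")
    } else if (all(vapply(groups, stats::sd, numeric(1)) == 0)) {
      rows$atopy <- data.frame(variable = "atopy", test = "welch_t",
                               estimate = NA_real_, p_value = NA_real_,
                               n = n, flag = "zero_variance")
    } else {
      tt <- stats::t.test(groups[["1"]], groups[["0"]])
      rows$atopy <- data.frame(variable = "atopy", test = "welch_t",
                               estimate = unname(diff(rev(tt$estimate))),
                               p_value = tt$p.value, n = n, flag = "")
    }
  }
  if (!is.null(props)) {
    pm <- props[match(pheno$sample_id, props$sample_id), , drop = FALSE]
    for (cell in setdiff(names(props), "sample_id")) {
      rows[[cell]] <- spearman_row(m, pm[[cell]], cell)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
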