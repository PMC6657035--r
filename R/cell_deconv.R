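# Reference-based cell-type deconvolution: constrained projection of bulk
# methylation onto cell-type mean-beta profiles (the classic
# estimateCellCounts-style approach), for adult and cord blood panels.

#' Select cell-type discriminating CpGs from a profile library
#'
#' For each cell type, ranks CpGs by a one-vs-rest F-type statistic
#' `(beta_type - mean(beta_rest))^2 / var(beta_rest)` computed across the
#' type mean profiles, and keeps the top `k_per_type`, split evenly between
#' CpGs hypermethylated and hypomethylated in that type when both directions
#' are available. The union over types forms the panel.
#'
#' @param profile_library numeric matrix, cell types x CpGs, of mean beta
#'   values (e.g. `cohort$profile_library`).
#' @param k_per_type CpGs to keep per cell type.
#' @param panel_name label for the resulting panel.
#' @return a [reference_panel()] restricted to the selected CpGs.
#' @export
select_discriminating_cpgs <- function(profile_library, k_per_type,
                                       panel_name = "custom") {
  prof <- as.matrix(profile_library)
  k <- nrow(prof)
  if (k < 2L) stop("need >= 2 cell types", call. = FALSE)
  if (k_per_type > ncol(prof)) {
    stop("k_per_type exceeds the number of available CpGs", call. = FALSE)
  }
  types <- rownames(prof)
  picked <- character(0)
  for (t in seq_len(k)) {
    rest <- prof[-t, , drop = FALSE]
    mu_r <- colMeans(rest)
    v_r <- apply(rest, 2, stats::var)
    delta <- prof[t, ] - mu_r
    fstat <- delta^2 / (v_r + 1e-12)
    informative <- which(abs(delta) > 1e-8)
    if (length(informative) < k_per_type) {
      stop("no discriminating CpGs for cell type ", types[t], call. = FALSE)
    }
    hyper <- informative[delta[informative] > 0]
    hypo <- informative[delta[informative] < 0]
    n_hyper <- min(length(hyper), ceiling(k_per_type / 2))
    n_hypo <- min(length(hypo), k_per_type - n_hyper)
    n_hyper <- k_per_type - n_hypo   # fill from the other direction if short
    take <- c(hyper[order(-fstat[hyper])][seq_len(min(n_hyper, length(hyper)))],
              hypo[order(-fstat[hypo])][seq_len(n_hypo)])
    if (length(take) < k_per_type) {
      stop("no discriminating CpGs for cell type ", types[t], call. = FALSE)
    }
    picked <- union(picked, colnames(prof)[take])
  }
  reference_panel(prof[, picked, drop = FALSE], panel_name)
}

# Least squares on the unit simplex: min ||A w - b||^2, w >= 0, sum(w) = 1.
# Lawson-Hanson NNLS on a system augmented with a heavily weighted
# sum-to-one row, followed by exact renormalization; for consistent
# (noiseless) systems the solution is exact.
solve_simplex_ls <- function(A, b, tol = 1e-9) {
  lam <- 1e4 * max(1, sqrt(mean(A^2)) * sqrt(nrow(A)))
  Aa <- rbind(A, rep(lam, ncol(A)))
  ba <- c(b, lam)
  w <- pracma::lsqnonneg(Aa, ba)$x
  s <- sum(w)
  if (!is.finite(s) || s <= tol) {
    stop("simplex least squares failed: degenerate solution", call. = FALSE)
  }
  w <- w / s
  names(w) <- colnames(A)
  w
}

#' Estimate cell-type proportions from bulk methylation
#'
#' Per sample, solves the constrained projection
#' `min_w || beta_sample - t(profile) w ||^2` subject to `w >= 0` and
#' `sum(w) = 1` over the panel CpGs. Panel CpGs absent from the assay are
#' dropped with a warning; estimation is refused when fewer than 80% of the
#' panel CpGs are usable (overall or within a sample).
#'
#' @param beta a [beta_matrix()].
#' @param panel a [reference_panel()].
#' @return a [cell_proportions()] table (rows sum to 1 within 1e-6).
#' @export
estimate_proportions <- function(beta, panel) {
  shared <- intersect(panel$cpg_ids, colnames(beta))
  coverage <- length(shared) / length(panel$cpg_ids)
  if (coverage < 0.8) {
    stop(sprintf("only %.0f%% of panel CpGs present in the assay (>= 80%% required)",
                 100 * coverage), call. = FALSE)
  }
  if (coverage < 1) {
    warning(sprintf("%d panel CpGs absent from the assay; solving over %d",
                    length(panel$cpg_ids) - length(shared), length(shared)))
  }
  prof <- panel$profile[, shared, drop = FALSE]
  if (qr(prof)$rank < nrow(prof)) {
    stop("singular reference profile matrix", call. = FALSE)
  }
  A_full <- t(prof)                      # CpG x cell type
  vals <- unclass(beta)[, shared, drop = FALSE]
  n <- nrow(vals)
  out <- matrix(NA_real_, n, nrow(prof),
                dimnames = list(rownames(vals), panel$cell_types))
  for (i in seq_len(n)) {
    b <- vals[i, ]
    obs <- !is.na(b)
    if (sum(obs) / length(panel$cpg_ids) < 0.8) {
      stop(sprintf("sample '%s' covers < 80%% of the panel CpGs", rownames(vals)[i]),
           call. = FALSE)
    }
    out[i, ] <- solve_simplex_ls(A_full[obs, , drop = FALSE], b[obs])
  }
  cell_proportions(data.frame(sample_id = rownames(vals), out,
                              check.names = FALSE, stringsAsFactors = FALSE),
                   panel$panel_name, sum_constrained = TRUE)
}
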