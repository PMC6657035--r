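# Beta <-> M transformation and medcouple-based adjusted-boxplot trimming.

#' Convert beta values to M-values
#'
#' M = log2(beta / (1 - beta)). Beta values are clipped into
#' `[1e-6, 1 - 1e-6]` at construction, so M-values are finite wherever the
#' source beta was non-missing; missing values propagate.
#'
#' @param beta a [beta_matrix()].
#' @return an [m_matrix()] on the same axes.
#' @export
beta_to_m <- function(beta) {
  m_matrix(log2(unclass(beta) / (1 - unclass(beta))),
           rownames(beta), colnames(beta))
}

#' Convert M-values back to beta values
#'
#' Inverse of [beta_to_m()]: beta = 2^M / (1 + 2^M). The round trip
#' beta -> M -> beta reproduces clipped beta values to within 1e-9.
#'
#' @param m an [m_matrix()].
#' @return a [beta_matrix()].
#' @export
m_to_beta <- function(m) {
  beta_matrix(stats::plogis(unclass(m) * log(2)), rownames(m), colnames(m))
}

#' Medcouple robust skewness statistic
#'
#' The medcouple of a sample is the median of the kernel
#' `h(xi, xj) = ((xj - m) - (m - xi)) / (xj - xi)` over all pairs with
#' `xi <= m <= xj` (m the sample median), with the standard sign kernel for
#' pairs tied at the median: for the i-th and j-th of k median-tied values,
#' `h = -1, 0, +1` as `i + j - 1` is below, at, or above `k`. The result
#' lies in `[-1, 1]`; 0 for symmetric samples.
#'
#' This is the naive O(n^2) evaluation, which is exact and fast for the
#' per-CpG sample sizes (a few hundred) this pipeline works at.
#'
#' @param x numeric vector; missing values are dropped; at least 3
#'   non-missing values are required.
#' @return the medcouple, with attribute `degenerate = TRUE` when all values
#'   are identical (statistic 0 by convention).
#' @export
medcouple <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 3L) stop("medcouple requires >= 3 non-missing values", call. = FALSE)
  if (length(unique(x)) == 1L) {
    return(structure(0, degenerate = TRUE))
  }
  med <- stats::median(x)
  lo <- sort(x[x <= med])          # candidates for xi, ascending
  hi <- sort(x[x >= med])          # candidates for xj, ascending
  h <- outer(lo, hi, function(xi, xj) {
    ifelse(xj > xi, ((xj - med) - (med - xi)) / (xj - xi), NA_real_)
  })
  # sign kernel for pairs of median-tied values (xi == xj == med)
  k <- sum(x == med)
  if (k > 0L) {
    ilo <- which(lo == med)        # positions 1..k within the tied block
    ihi <- which(hi == med)
    for (a in seq_along(ilo)) {
      for (b in seq_along(ihi)) {
        h[ilo[a], ihi[b]] <- sign(a + b - 1L - k)
      }
    }
  }
  structure(stats::median(h, na.rm = FALSE), degenerate = FALSE)
}

#' Skewness-adjusted boxplot fences
#'
#' Hubert-Vandervieren adjusted fences: with quartiles Q1, Q3 (linear, type-7
#' interpolation), IQR = Q3 - Q1 and MC the [medcouple()],
#' \itemize{
#'   \item MC >= 0: `[Q1 - 1.5 exp(-4 MC) IQR, Q3 + 1.5 exp(3 MC) IQR]`
#'   \item MC <  0: `[Q1 - 1.5 exp(-3 MC) IQR, Q3 + 1.5 exp(4 MC) IQR]`
#' }
#' reducing to the classical Tukey fences for symmetric samples (MC = 0).
#'
#' @param x numeric vector with at least 4 non-missing values.
#' @return named numeric vector `c(lower, upper)` with attributes
#'   `medcouple` and `degenerate` (`TRUE` when IQR = 0, in which case the
#'   fences collapse to `[Q1, Q3]`).
#' @export
adjusted_fences <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 4L) stop("adjusted fences require >= 4 non-missing values", call. = FALSE)
  q <- stats::quantile(x, c(0.25, 0.75), type = 7, names = FALSE)
  iqr <- q[2] - q[1]
  mc <- medcouple(x)
  if (iqr == 0) {
    return(structure(c(lower = q[1], upper = q[2]),
                     medcouple = as.numeric(mc), degenerate = TRUE))
  }
  if (mc >= 0) {
    fences <- c(lower = q[1] - 1.5 * exp(-4 * mc) * iqr,
                upper = q[2] + 1.5 * exp(3 * mc) * iqr)
  } else {
    fences <- c(lower = q[1] - 1.5 * exp(-3 * mc) * iqr,
                upper = q[2] + 1.5 * exp(4 * mc) * iqr)
  }
  structure(fences, medcouple = as.numeric(mc),
            degenerate = isTRUE(attr(mc, "degenerate")))
}

#' Trim strong outliers from an M-value matrix
#'
#' Per CpG (column), values outside the [adjusted_fences()] are set to
#' missing. Columns with fewer than 4 non-missing values, or with no spread,
#' are left untouched and flagged. The input matrix is not modified.
#'
#' @param m an [m_matrix()].
#' @return a list with `m` (trimmed copy) and `report`, a data.frame with one
#'   row per CpG: `cpg_id`, `n_trimmed_low`, `n_trimmed_high`, `lower_fence`,
#'   `upper_fence`, `medcouple`, `skipped`, `degenerate`.
#' @export
trim_outliers <- function(m) {
  vals <- unclass(m)
  p <- ncol(vals)
  report <- data.frame(
    cpg_id = colnames(vals),
    n_trimmed_low = integer(p), n_trimmed_high = integer(p),
    lower_fence = NA_real_, upper_fence = NA_real_,
    medcouple = NA_real_,
    skipped = logical(p), degenerate = logical(p),
    stringsAsFactors = FALSE
  )
  for (j in seq_len(p)) {
    col <- vals[, j]
    obs <- !is.na(col)
    if (sum(obs) < 4L) {
      report$skipped[j] <- TRUE
      next
    }
    if (length(unique(col[obs])) == 1L) {
      report$skipped[j] <- TRUE
      report$degenerate[j] <- TRUE
      next
    }
    f <- adjusted_fences(col[obs])
    low <- obs & col < f["lower"]
    high <- obs & col > f["upper"]
    vals[low | high, j] <- NA_real_
    report$n_trimmed_low[j] <- sum(low)
    report$n_trimmed_high[j] <- sum(high)
    report$lower_fence[j] <- f[["lower"]]
    report$upper_fence[j] <- f[["upper"]]
    report$medcouple[j] <- attr(f, "medcouple")
    report$degenerate[j] <- isTRUE(attr(f, "degenerate"))
  }
  list(m = m_matrix(vals, rownames(m), colnames(m)), report = report)
}
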