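# Core containers for methylation, phenotype, cell-proportion and expression
# data, plus tab-delimited readers/writers.

#' Beta-value clipping boundary
#'
#' Methylation proportions are clipped into `[.Machine eps, 1 - eps]` with
#' `eps = 1e-6` before any logit-scale transformation, which bounds M-values
#' at roughly +/- 19.9 while preserving ordering.
#' @keywords internal
BETA_EPS <- 1e-6

#' Blood cell panels
#'
#' Ordered cell-type names for the adult whole-blood panel (`adult7`) and the
#' cord-blood panel including nucleated red blood cells (`cord7`).
#' @export
CELL_PANELS <- list(
  adult7 = c("CD8T", "CD4T", "NK", "Bcell", "Mono", "Eos", "Gran"),
  cord7  = c("CD8T", "CD4T", "NK", "Bcell", "Mono", "Gran", "nRBC")
)

new_assay_matrix <- function(values, class, sample_ids = NULL, feature_ids = NULL) {
  if (!is.matrix(values)) values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (!is.null(sample_ids)) rownames(values) <- sample_ids
  if (!is.null(feature_ids)) colnames(values) <- feature_ids
  if (is.null(rownames(values)) && nrow(values) > 0L) {
    rownames(values) <- paste0("s", seq_len(nrow(values)))
  }
  if (is.null(colnames(values)) && ncol(values) > 0L) {
    colnames(values) <- paste0("f", seq_len(ncol(values)))
  }
  check_unique_ids(rownames(values), "sample id")
  check_unique_ids(colnames(values), "feature id")
  structure(values, class = c(class, "assay_matrix", "matrix", "array"))
}

check_unique_ids <- function(ids, what) {
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0L) {
    stop(sprintf("duplicate %ss: %s", what, paste(utils::head(dup, 5L), collapse = ", ")),
         call. = FALSE)
  }
  invisible(ids)
}

#' @export
`[.assay_matrix` <- function(x, i, j, ..., drop = FALSE) {
  out <- NextMethod(drop = drop)
  if (is.matrix(out)) class(out) <- class(x)
  out
}

#' Construct a matrix of methylation beta values
#'
#' Samples are rows and CpGs columns. Non-missing values outside
#' `(0, 1)` are clipped into `[1e-6, 1 - 1e-6]`; the number of clipped cells
#' is recorded in the `"n_clipped"` attribute. Values already inside the
#' clipping band are never altered.
#'
#' @param values numeric matrix of methylation proportions, samples x CpGs.
#' @param sample_ids,cpg_ids optional identifier vectors overriding dimnames.
#' @return A `beta_matrix` (numeric matrix subclass).
#' @export
beta_matrix <- function(values, sample_ids = NULL, cpg_ids = NULL) {
  m <- new_assay_matrix(values, "beta_matrix", sample_ids, cpg_ids)
  lo <- !is.na(m) & m < BETA_EPS
  hi <- !is.na(m) & m > 1 - BETA_EPS
  m[lo] <- BETA_EPS
  m[hi] <- 1 - BETA_EPS
  attr(m, "n_clipped") <- sum(lo) + sum(hi)
  m
}

#' Construct a matrix of M-values (log2 methylation odds)
#'
#' @param values numeric matrix, samples x CpGs, on the `log2(beta/(1-beta))`
#'   scale. Non-missing values must be finite.
#' @inheritParams beta_matrix
#' @return An `m_matrix`.
#' @export
m_matrix <- function(values, sample_ids = NULL, cpg_ids = NULL) {
  m <- new_assay_matrix(values, "m_matrix", sample_ids, cpg_ids)
  if (any(!is.na(m) & !is.finite(m))) {
    stop("M-values must be finite where non-missing", call. = FALSE)
  }
  m
}

#' Construct a matrix of log2-scale expression values
#'
#' @param values numeric matrix, samples x probes.
#' @param sample_ids,probe_ids optional identifier vectors.
#' @return An `expression_matrix`.
#' @export
expression_matrix <- function(values, sample_ids = NULL, probe_ids = NULL) {
  new_assay_matrix(values, "expression_matrix", sample_ids, probe_ids)
}

#' Read a sample-by-feature matrix from a tab-delimited file
#'
#' The expected layout is a header row of feature ids, a first column named
#' `sample_id`, and `.`-decimal numeric cells. Non-numeric cells become
#' missing; beta values outside `(0,1)` are clipped (count retained in the
#' `"n_clipped"` attribute). Duplicate sample or feature ids and ragged rows
#' are errors.
#'
#' @param path file path.
#' @param kind one of `"beta"`, `"mvalue"`, `"expression"`.
#' @return the corresponding typed matrix.
#' @export
read_matrix <- function(path, kind = c("beta", "mvalue", "expression")) {
  kind <- match.arg(kind)
  nf <- utils::count.fields(path, sep = "\t", quote = "", comment.char = "")
  if (length(unique(nf)) > 1L) {
    stop(sprintf("ragged rows in %s: field counts %s", path,
                 paste(unique(nf), collapse = ", ")), call. = FALSE)
  }
  header <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1]]
  feature_ids <- header[-1L]
  check_unique_ids(feature_ids, "feature id")
  df <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                          colClasses = "character", quote = "")
  sample_ids <- df[[1L]]
  check_unique_ids(sample_ids, "sample id")
  if (ncol(df) >= 2L) {
    vals <- vapply(df[-1L], function(col) suppressWarnings(as.numeric(col)),
                   numeric(nrow(df)))
    vals <- matrix(as.numeric(vals), nrow = nrow(df), ncol = ncol(df) - 1L)
  } else {
    vals <- matrix(numeric(0), nrow = nrow(df), ncol = 0L)
  }
  switch(kind,
    beta = beta_matrix(vals, sample_ids, feature_ids),
    mvalue = m_matrix(vals, sample_ids, feature_ids),
    expression = expression_matrix(vals, sample_ids, feature_ids)
  )
}

#' Write a typed matrix to a tab-delimited file
#'
#' Inverse of [read_matrix()]: first column `sample_id`, header of feature
#' ids, missing values written as `NA`. Round-trips values to better than
#' 1e-12.
#'
#' @param m matrix created by [beta_matrix()], [m_matrix()] or
#'   [expression_matrix()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(m, path) {
  ids <- if (is.null(rownames(m))) character(nrow(m)) else rownames(m)
  df <- data.frame(sample_id = ids, check.names = FALSE,
                   stringsAsFactors = FALSE)
  vals <- unclass(m)
  attr(vals, "n_clipped") <- NULL
  df <- cbind(df, as.data.frame(vals, check.names = FALSE, optional = TRUE))
  colnames(df) <- c("sample_id", colnames(m))
  ok <- tryCatch({
    utils::write.table(format(df, digits = 17, trim = TRUE, scientific = FALSE),
                       path, sep = "\t", quote = FALSE, row.names = FALSE,
                       na = "NA")
    TRUE
  }, error = function(e) {
    stop(sprintf("cannot write matrix to '%s': %s", path, conditionMessage(e)),
         call. = FALSE)
  })
  invisible(path)
}

#' Construct a phenotype table
#'
#' One row per sample. `asthma` and `sex` (female indicator) are required
#' binary columns; atopy, FeNO (ppb), spirometry ratios, infant wheeze
#' outcomes and season of birth are optional.
#'
#' @param df data.frame with at least `sample_id`, `asthma`, `sex`.
#' @return a validated `phenotype_table` data.frame.
#' @export
phenotype_table <- function(df) {
  req <- c("sample_id", "asthma", "sex")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols)) {
    stop("phenotype table missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  check_unique_ids(df$sample_id, "sample id")
  for (col in intersect(c("asthma", "sex", "atopy", "wheeze_no_cold", "any_wheeze"),
                        names(df))) {
    bad <- !is.na(df[[col]]) & !df[[col]] %in% c(0, 1)
    if (any(bad)) stop(sprintf("column '%s' must be coded {0,1}", col), call. = FALSE)
  }
  if ("season_of_birth" %in% names(df) && !is.factor(df$season_of_birth)) {
    df$season_of_birth <- factor(df$season_of_birth,
                                 levels = c("winter", "spring", "summer", "autumn"))
  }
  class(df) <- c("phenotype_table", "data.frame")
  df
}

#' Read / write phenotype tables
#'
#' Tab-delimited, `NA` for missing, columns as in [phenotype_table()].
#' @param path file path.
#' @export
read_phenotypes <- function(path) {
  phenotype_table(utils::read.delim(path, sep = "\t", check.names = FALSE,
                                    stringsAsFactors = FALSE))
}

#' @rdname read_phenotypes
#' @param pheno a `phenotype_table`.
#' @export
write_phenotypes <- function(pheno, path) {
  utils::write.table(pheno, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' Construct a table of per-sample cell-type proportions
#'
#' @param df data.frame with `sample_id` plus one non-negative column per
#'   cell type of the panel.
#' @param panel_name `"adult7"` or `"cord7"` (or any name matching `df`'s
#'   cell columns).
#' @param sum_constrained logical; when `TRUE` (deconvolution output) each
#'   row must sum to 1 within 1e-6.
#' @return a `cell_proportions` data.frame with a `panel_name` attribute.
#' @export
cell_proportions <- function(df, panel_name, sum_constrained = FALSE) {
  cells <- if (panel_name %in% names(CELL_PANELS)) CELL_PANELS[[panel_name]]
           else setdiff(names(df), "sample_id")
  missing_cols <- setdiff(cells, names(df))
  if (length(missing_cols)) {
    stop("missing cell-type columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  check_unique_ids(df$sample_id, "sample id")
  fr <- as.matrix(df[cells])
  if (any(fr < 0, na.rm = TRUE)) stop("cell fractions must be non-negative", call. = FALSE)
  if (sum_constrained) {
    s <- rowSums(fr)
    if (any(abs(s - 1) > 1e-6, na.rm = TRUE)) {
      stop("constrained cell fractions must sum to 1 within 1e-6", call. = FALSE)
    }
  }
  out <- df[c("sample_id", cells)]
  attr(out, "panel_name") <- panel_name
  attr(out, "sum_constrained") <- sum_constrained
  class(out) <- c("cell_proportions", "data.frame")
  out
}

#' Construct a cell-type reference panel
#'
#' @param profile numeric matrix, cell types x CpGs, of mean beta values in
#'   `(0,1)`.
#' @param panel_name panel label, e.g. `"adult7"`.
#' @return a `reference_panel` object.
#' @export
reference_panel <- function(profile, panel_name = "custom") {
  if (!is.matrix(profile)) profile <- as.matrix(profile)
  if (nrow(profile) < 2L) stop("a reference panel needs >= 2 cell types", call. = FALSE)
  if (any(profile <= 0 | profile >= 1)) {
    stop("reference profile values must lie strictly in (0,1)", call. = FALSE)
  }
  check_unique_ids(rownames(profile), "cell type")
  check_unique_ids(colnames(profile), "CpG id")
  structure(list(panel_name = panel_name,
                 cell_types = rownames(profile),
                 cpg_ids = colnames(profile),
                 profile = profile),
            class = "reference_panel")
}

#' @export
print.reference_panel <- function(x, ...) {
  cat(sprintf("reference_panel '%s': %d cell types, %d CpGs\n",
              x$panel_name, length(x$cell_types), length(x$cpg_ids)))
  invisible(x)
}

#' Read / write cell proportions
#' @param path file path.
#' @param panel_name panel label passed to [cell_proportions()].
#' @export
read_cell_proportions <- function(path, panel_name) {
  cell_proportions(utils::read.delim(path, sep = "\t", check.names = FALSE,
                                     stringsAsFactors = FALSE),
                   panel_name)
}

#' @rdname read_cell_proportions
#' @param props a `cell_proportions` table.
#' @export
write_cell_proportions <- function(props, path) {
  utils::write.table(props, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' Read / write a reference panel (rows = cell types, columns = CpGs)
#' @param path file path.
#' @param panel_name panel label.
#' @export
read_reference_panel <- function(path, panel_name = "custom") {
  df <- utils::read.delim(path, sep = "\t", check.names = FALSE,
                          stringsAsFactors = FALSE)
  prof <- as.matrix(df[-1L])
  rownames(prof) <- df[[1L]]
  reference_panel(prof, panel_name)
}

#' @rdname read_reference_panel
#' @param panel a `reference_panel`.
#' @export
write_reference_panel <- function(panel, path) {
  df <- data.frame(cell_type = panel$cell_types, panel$profile,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Table-1 style cohort summary
#'
#' Summarises a phenotype table (optionally with estimated cell proportions)
#' by case status: counts, percent female overall and within groups, and
#' group means of continuous covariates and cell fractions.
#'
#' @param pheno a [phenotype_table()].
#' @param props optional [cell_proportions()] aligned by `sample_id`.
#' @return a list with elements `n`, `n_case`, `n_control`,
#'   `pct_female_overall`, `pct_female_case`, `pct_female_control`, and a
#'   `by_group` data.frame of means.
#' @export
cohort_summary <- function(pheno, props = NULL) {
  case <- pheno$asthma == 1
  out <- list(
    n = nrow(pheno),
    n_case = sum(case),
    n_control = sum(!case),
    pct_female_overall = 100 * mean(pheno$sex == 1),
    pct_female_case = 100 * mean(pheno$sex[case] == 1),
    pct_female_control = 100 * mean(pheno$sex[!case] == 1)
  )
  num_cols <- intersect(c("feno", "fev1_fvc", "fef2575"), names(pheno))
  rows <- lapply(num_cols, function(cn) {
    data.frame(variable = cn,
               mean_case = mean(pheno[[cn]][case], na.rm = TRUE),
               mean_control = mean(pheno[[cn]][!case], na.rm = TRUE))
  })
  if (!is.null(props)) {
    cells <- setdiff(names(props), "sample_id")
    pm <- props[match(pheno$sample_id, props$sample_id), , drop = FALSE]
    rows <- c(rows, lapply(cells, function(cn) {
      data.frame(variable = cn,
                 mean_case = mean(pm[[cn]][case], na.rm = TRUE),
                 mean_control = mean(pm[[cn]][!case], na.rm = TRUE))
    }))
  }
  out$by_group <- do.call(rbind, rows)
  out
}
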