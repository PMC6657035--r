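# Stage-1 recursive random-forest feature selection: balanced sampling,
# per-class OOB misclassification tracking, VIM-ranked halving, and a
# levelling-off stopping rule on the case-class OOB error.

#' Random-forest configuration for recursive selection
#'
#' Defaults follow the discovery-stage settings: 7500 trees, 10% of the
#' current predictors tried per node, balanced per-tree sampling (a
#' stratified bootstrap at minority-class size), and permutation
#' (mean-decrease-accuracy) variable importance.
#'
#' @param ntree trees per forest.
#' @param mtry_fraction fraction of current predictors tried per split.
#' @param balanced use a balanced stratified bootstrap per tree.
#' @param vim_kind `"permutation_accuracy"` (default) or `"gini"`.
#' @param min_features stop the halving once the next set would be smaller.
#' @param level_off_tolerance slack (absolute error units) above the minimum
#'   case-class OOB error within which a later iteration still counts as
#'   "levelled off".
#' @param rng_seed integer seed for the forest-growing RNG.
#' @return an `rf_config` list.
#' @export
rf_config <- function(ntree = 7500, mtry_fraction = 0.10, balanced = TRUE,
                      vim_kind = c("permutation_accuracy", "gini"),
                      min_features = 10, level_off_tolerance = 0,
                      rng_seed = NULL) {
  vim_kind <- match.arg(vim_kind)
  if (mtry_fraction <= 0 || mtry_fraction > 1) {
    stop("mtry_fraction must lie in (0, 1]", call. = FALSE)
  }
  if (ntree < 1 || min_features < 1) stop("ntree and min_features must be >= 1", call. = FALSE)
  structure(list(ntree = as.integer(ntree), mtry_fraction = mtry_fraction,
                 balanced = isTRUE(balanced), vim_kind = vim_kind,
                 min_features = as.integer(min_features),
                 level_off_tolerance = level_off_tolerance,
                 rng_seed = if (is.null(rng_seed)) NULL else as.integer(rng_seed)),
            class = "rf_config")
}

#' Grow one balanced random forest and extract OOB errors and VIMs
#'
#' Missing predictor values are mean-imputed per feature before fitting
#' (association models elsewhere stay complete-case); the number of imputed
#' cells is reported. With `balanced = TRUE` each tree draws
#' `n_minority` samples per class with replacement.
#'
#' @param X numeric matrix (samples x features), e.g. an [m_matrix()].
#' @param y binary outcome ({0,1} or two-level factor); 1 is the case class.
#' @param config an [rf_config()].
#' @return list with `oob_overall`, `oob_class` (named `control`/`case`),
#'   `vim` (named importance vector), `n_imputed`, and the `forest`.
#' @export
grow_forest <- function(X, y, config = rf_config()) {
  X <- unclass(X)
  if (ncol(X) == 0L) stop("no features to grow a forest on", call. = FALSE)
  yf <- if (is.factor(y)) factor(y, labels = c("control", "case")[seq_len(nlevels(y))])
        else factor(ifelse(y == 1, "case", "control"), levels = c("control", "case"))
  if (nlevels(droplevels(yf)) < 2L) stop("outcome has a single class", call. = FALSE)
  n_imputed <- 0L
  if (anyNA(X)) {
    for (j in which(colSums(is.na(X)) > 0L)) {
      nas <- is.na(X[, j])
      X[nas, j] <- mean(X[, j], na.rm = TRUE)
      n_imputed <- n_imputed + sum(nas)
    }
  }
  mtry <- max(1L, floor(config$mtry_fraction * ncol(X)))
  if (!is.null(config$rng_seed)) set.seed(config$rng_seed)
  args <- list(x = X, y = yf, ntree = config$ntree, mtry = mtry,
               importance = config$vim_kind == "permutation_accuracy")
  if (config$balanced) {
    nmin <- min(table(yf))
    args$replace <- TRUE
    args$strata <- yf
    args$sampsize <- stats::setNames(rep(nmin, 2L), levels(yf))
  }
  rf <- do.call(randomForest::randomForest, args)
  oob_class <- rf$confusion[, "class.error"]
  vim_type <- if (config$vim_kind == "permutation_accuracy") 1L else 2L
  vim <- randomForest::importance(rf, type = vim_type, scale = FALSE)[, 1L]
  names(vim) <- colnames(X)
  list(oob_overall = mean(rf$predicted != yf, na.rm = TRUE),
       oob_class = c(control = unname(oob_class["control"]),
                     case = unname(oob_class["case"])),
       vim = vim,
       n_imputed = n_imputed,
       forest = rf)
}

#' Feature count at a given halving iteration
#'
#' Iteration 1 is the full feature set; each subsequent iteration keeps the
#' better-ranked half, `floor(n_start / 2^(iteration - 1))` features.
#'
#' @param n_start starting feature count.
#' @param iteration iteration index (>= 1).
#' @return the feature count at that iteration.
#' @export
feature_count_schedule <- function(n_start, iteration) {
  if (n_start < 1 || iteration < 1) stop("n_start and iteration must be >= 1", call. = FALSE)
  count <- floor(n_start / 2^(iteration - 1))
  if (count < 1) stop("schedule exhausted: no features left at iteration ", iteration,
                      call. = FALSE)
  count
}

#' Recursive random-forest feature selection
#'
#' Repeatedly grows a balanced forest on the current feature set, ranks
#' features by VIM (ties broken by the original feature order), drops the
#' lower-ranked half, and stops once the next set would fall below
#' `min_features`. The selected iteration is the largest (fewest-features)
#' iteration whose case-class OOB misclassification is within
#' `level_off_tolerance` of the minimum across iterations - the point where
#' the case-specific error has levelled off and further halving would lose
#' information.
#'
#' @inheritParams grow_forest
#' @return a `recursive_selection` list: `trace` (data.frame with
#'   `iteration`, `n_features`, `oob_overall`, `oob_control`, `oob_case`),
#'   `retained` and `vim` (per-iteration lists), `selected_iteration`,
#'   `selected` (feature ids).
#' @export
recursive_select <- function(X, y, config = rf_config()) {
  features <- colnames(X)
  if (is.null(features)) stop("X must have feature (column) names", call. = FALSE)
  n_start <- length(features)
  if (n_start < config$min_features) {
    stop("fewer features than min_features", call. = FALSE)
  }
  max_iter <- floor(log2(n_start)) + 1L
  if (is.null(config$rng_seed)) {
    iter_seeds <- sample.int(.Machine$integer.max - 1L, max_iter)
  } else {
    set.seed(config$rng_seed)
    iter_seeds <- sample.int(.Machine$integer.max - 1L, max_iter)
  }
  current <- features
  trace <- list(); retained <- list(); vims <- list()
  k <- 0L
  repeat {
    k <- k + 1L
    cfg_k <- config
    cfg_k$rng_seed <- iter_seeds[k]
    gf <- grow_forest(X[, current, drop = FALSE], y, cfg_k)
    trace[[k]] <- data.frame(iteration = k, n_features = length(current),
                             oob_overall = gf$oob_overall,
                             oob_control = gf$oob_class[["control"]],
                             oob_case = gf$oob_class[["case"]])
    retained[[k]] <- current
    vims[[k]] <- gf$vim
    next_n <- floor(length(current) / 2)
    if (next_n < config$min_features) break
    ord <- order(-gf$vim, seq_along(current))   # stable: ties keep input order
    current <- current[ord[seq_len(next_n)]]
    current <- features[features %in% current]  # restore original feature order
  }
  trace <- do.call(rbind, trace)
  best <- min(trace$oob_case)
  selected_iteration <- max(which(trace$oob_case <= best + config$level_off_tolerance))
  structure(list(trace = trace, retained = retained, vim = vims,
                 selected_iteration = selected_iteration,
                 selected = retained[[selected_iteration]]),
            class = "recursive_selection")
}

#' @export
print.recursive_selection <- function(x, ...) {
  cat(sprintf("recursive_selection: %d iterations, selected iteration %d (%d features)\n",
              nrow(x$trace), x$selected_iteration, length(x$selected)))
  print(x$trace, row.names = FALSE)
  invisible(x)
}
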