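test_that("logistic OR on a 2x2 table equals the cross-product ratio", {
  # exposed: 20 cases / 10 controls; unexposed: 10 cases / 20 controls
  y <- rep(c(1, 0, 1, 0), c(20, 10, 10, 20))
  x <- rep(c(1, 1, 0, 0), c(20, 10, 10, 20))
  fit <- fit_logistic(y, x)
  expect_equal(fit$or_value, 4.0, tolerance = 1e-6)
  expect_true(fit$converged)
  expect_equal(fit$n_used, 60)
})

test_that("null logistic CIs cover OR = 1 at close to the nominal rate", {
  set.seed(41)
  covered <- replicate(200, {
    n <- 150
    y <- rbinom(n, 1, 0.3)
    x <- rnorm(n)
    fit <- fit_logistic(y, x)
    fit$ci_low <= 1 && 1 <= fit$ci_high
  })
  expect_lt(abs(mean(covered) - 0.95), 0.045)
})

test_that("complete separation is flagged rather than silently reported", {
  y <- rep(c(0, 1), each = 20)
  fit <- fit_logistic(y, y)
  expect_false(fit$converged)
})

test_that("complete cases are used and single-class outcomes are errors", {
  y <- c(rep(c(0, 1), 15), NA)
  x <- c(rnorm(30), 0)
  x[1] <- NA
  fit <- fit_logistic(y, x)
  expect_equal(fit$n_used, 29)
  expect_error(fit_logistic(rep(1, 20), rnorm(20)), "single class")
})

test_that("stage-2 models drop granulocytes from the adjusted design", {
  coh <- tiny_cohort(seed = 42, n_samples = 120)
  m <- beta_to_m(coh$beta)[, coh$truth$cpg_id[1:2]]
  props <- coh$true_proportions
  res <- stage2_associations(m, coh$phenotypes, props)
  expect_setequal(unique(res$model_kind), c("logistic_crude", "logistic_adjusted"))
  expect_equal(nrow(res), 4)
  conv <- res[res$converged, ]
  expect_true(all(conv$ci_low <= conv$or_value & conv$or_value <= conv$ci_high))
  expect_true(all(res$p_value > 0 & res$p_value <= 1))
})

test_that("linear EWAS recovers a planted mean-beta difference", {
  set.seed(43)
  n <- 200
  y <- rbinom(n, 1, 0.5)
  b <- beta_matrix(matrix(0.5 + 0.02 * y + rnorm(n, 0, 0.005), n, 1,
                          dimnames = list(sprintf("s%03d", 1:n), "cg1")))
  res <- ewas_linear(b, y)
  expect_lt(abs(res$coefficient - 0.02), 0.005)
  expect_lt(res$p_value, 1e-10)
})

test_that("linear EWAS type-I error is nominal under permutation", {
  set.seed(44)
  n <- 120
  y <- rbinom(n, 1, 0.3)
  b <- beta_matrix(matrix(runif(n * 2000, 0.3, 0.7), n, 2000))
  res <- ewas_linear(b, sample(y))
  expect_lt(abs(mean(res$p_value < 0.05) - 0.05), 0.02)
})

test_that("a full compositional covariate set triggers a collinearity error", {
  coh <- tiny_cohort(seed = 45, n_samples = 60, n_cpgs = 150)
  allcells <- as.matrix(coh$true_proportions[-1])   # 7 fractions summing to 1
  expect_error(ewas_linear(coh$beta[, 1:2], coh$phenotypes$asthma, allcells),
               "collinear")
  ok <- ewas_linear(coh$beta[, 1:2], coh$phenotypes$asthma,
                    cell_covariate_matrix(coh$true_proportions))
  expect_equal(nrow(ok), 2)
  expect_identical(unique(ok$model_kind), "linear_adjusted")
})

test_that("q-values with pi0 = 1 equal Benjamini-Hochberg exactly", {
  qs <- storey_qvalues(c(0.01, 0.02, 0.03, 0.04))
  expect_identical(qs$pi0_method, "bh_fallback")
  expect_equal(qs$q_values, rep(0.04, 4))
  set.seed(46)
  for (i in 1:50) {
    p <- runif(sample(2:99, 1))
    qs <- storey_qvalues(p)
    expect_equal(qs$q_values, p.adjust(p, "BH"), tolerance = 1e-12)
  }
})

test_that("a single p-value is its own q-value under the BH fallback", {
  qs <- storey_qvalues(0.05)
  expect_equal(qs$q_values, 0.05)
  expect_equal(qs$pi0, 1)
})

test_that("pi0 is recovered near 1 on uniform nulls", {
  set.seed(47)
  qs <- storey_qvalues(runif(10000))
  expect_identical(qs$pi0_method, "smoother")
  expect_equal(qs$pi0, 1, tolerance = 0.05)
})

test_that("q-values respect their p-value bounds and monotonicity", {
  set.seed(48)
  p <- c(rbeta(300, 0.3, 4), runif(700))
  qs <- storey_qvalues(p)
  expect_true(all(qs$q_values <= 1))
  expect_true(all(qs$q_values >= qs$pi0 * p / length(p) - 1e-15))
  o <- order(p)
  expect_true(all(diff(qs$q_values[o]) >= -1e-15))
  expect_error(storey_qvalues(numeric(0)), "empty")
  expect_error(storey_qvalues(c(0.5, 0)), "\\(0, 1\\]")
})

test_that("replication assessment flags direction and strict significance", {
  disc <- data.frame(cpg_id = c("cg1", "cg2", "cg3"),
                     model_kind = "logistic_adjusted",
                     or_value = c(0.17, 0.5, 0.8),
                     p_value = c(0.001, 0.01, 0.2),
                     converged = TRUE)
  repl <- data.frame(cpg_id = c("cg1", "cg2", "cg3"),
                     model_kind = "logistic_adjusted",
                     or_value = c(0.57, 2.0, 0.9),
                     p_value = c(0.01, 0.03, 0.05),
                     converged = TRUE)
  out <- assess_replication(disc, repl, alpha = 0.05)
  out <- out[order(out$cpg_id), ]
  expect_equal(out$direction_consistent, c(TRUE, FALSE, TRUE))
  # p exactly alpha is not significant (strict inequality)
  expect_equal(out$replication_significant, c(TRUE, TRUE, FALSE))
  expect_error(assess_replication(disc, transform(repl, cpg_id = c("x", "y", "z"))),
               "no overlapping")
})

test_that("phenotype correlations hit the Spearman bounds on monotone data", {
  n <- 30
  pheno <- phenotype_table(data.frame(
    sample_id = sprintf("s%02d", 1:n), asthma = rep(c(0, 1), 15),
    sex = rep(c(0, 1), 15), feno = exp(seq(1, 3, length.out = n)),
    fev1_fvc = seq(0.95, 0.7, length.out = n)))
  m <- seq_len(n) + 0.5
  out <- phenotype_correlations(m, pheno)
  expect_equal(out$estimate[out$variable == "log_feno"], 1)
  expect_equal(out$estimate[out$variable == "fev1_fvc"], -1)
})

test_that("the atopy contrast detects a planted group shift", {
  set.seed(49)
  n <- 100
  pheno <- phenotype_table(data.frame(
    sample_id = sprintf("s%03d", 1:n), asthma = rbinom(n, 1, 0.2),
    sex = rbinom(n, 1, 0.5), atopy = rep(c(0, 1), each = 50)))
  m <- rnorm(n) + pheno$atopy   # N(0,1) vs N(1,1)
  out <- phenotype_correlations(m, pheno)
  at <- out[out$variable == "atopy", ]
  expect_lt(at$p_value, 0.001)
  expect_lt(abs(at$estimate - 1), 0.7)
  # too-few pairs are flagged, not computed
  short <- phenotype_table(data.frame(sample_id = c("a", "b", "c"),
    asthma = c(0, 1, 0), sex = c(1, 0, 1), atopy = c(0, 1, 0)))
  out2 <- phenotype_correlations(c(1, 2, 3), short)
  expect_identical(out2$flag[out2$variable == "atopy"], "too_few_pairs")
})

test_that("cell-fraction correlations surface composition-driven signal", {
  coh <- tiny_cohort(seed = 50, n_samples = 150)
  # an eosinophil-marker CpG hypomethylated in eosinophils tracks -Eos
  eos_markers <- coh$reference_panel$cpg_ids[
    coh$reference_panel$profile["Eos", coh$reference_panel$cpg_ids] < 0.5 &
    colMeans(coh$reference_panel$profile[, coh$reference_panel$cpg_ids]) > 0.5]
  m <- unclass(beta_to_m(coh$beta))[, eos_markers[1]]
  out <- phenotype_correlations(m, coh$phenotypes, coh$true_proportions)
  eos_row <- out[out$variable == "Eos", ]
  expect_lt(eos_row$estimate, -0.3)
  expect_lt(eos_row$p_value, 1e-4)
})
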