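test_that("identical seeds give identical cohorts; different seeds differ", {
  c1 <- tiny_cohort(seed = 5)
  c2 <- tiny_cohort(seed = 5)
  c3 <- tiny_cohort(seed = 6)
  expect_identical(unclass(c1$beta), unclass(c2$beta))
  expect_identical(c1$phenotypes, c2$phenotypes)
  expect_identical(unclass(c1$expression), unclass(c2$expression))
  expect_false(identical(unclass(c1$beta), unclass(c3$beta)))
})

test_that("true compositions lie exactly on the simplex with target group means", {
  coh <- generate_cohort(simulation_config(rng_seed = 1))
  w <- as.matrix(coh$true_proportions[-1])
  expect_true(all(w >= 0))
  expect_lt(max(abs(rowSums(w) - 1)), 1e-12)
  case <- coh$phenotypes$asthma == 1
  expect_lt(abs(mean(w[case, "Eos"]) - 0.045), 0.005)
  expect_lt(abs(mean(w[!case, "Eos"]) - 0.021), 0.005)
})

test_that("marginal prevalence and sex proportion converge at large n", {
  coh <- tiny_cohort(seed = 3, n_samples = 5000, n_cpgs = 150,
                     n_discriminating_cpgs_per_type = 2, n_planted_cpgs = 3)
  expect_lt(abs(mean(coh$phenotypes$asthma) - 0.139), 0.02)
  expect_lt(abs(mean(coh$phenotypes$sex) - 0.662), 0.02)
})

test_that("a null planted effect leaves case and control means equal", {
  coh <- tiny_cohort(seed = 4, planted_effect = 0, beta_precision = Inf,
                     n_samples = 300)
  case <- coh$phenotypes$asthma == 1
  b <- unclass(coh$beta)[, coh$truth$cpg_id, drop = FALSE]
  diffs <- colMeans(b[case, , drop = FALSE]) - colMeans(b[!case, , drop = FALSE])
  expect_lt(max(abs(diffs)), 0.01)
})

test_that("planted effects have the configured sign in nearly all seeds", {
  signs <- vapply(1:20, function(s) {
    coh <- tiny_cohort(seed = s, n_samples = 120)
    case <- coh$phenotypes$asthma == 1
    m <- unclass(beta_to_m(coh$beta))[, coh$truth$cpg_id, drop = FALSE]
    mean(colMeans(m[case, , drop = FALSE]) - colMeans(m[!case, , drop = FALSE]) < 0)
  }, numeric(1))
  expect_gte(mean(signs == 1), 0.95)
})

test_that("cord cohorts carry nRBC fractions with the shifted means", {
  coh <- tiny_cohort(seed = 9, panel_name = "cord7", n_samples = 200)
  expect_true("nRBC" %in% names(coh$true_proportions))
  case <- coh$phenotypes$asthma == 1
  expect_lt(abs(mean(coh$true_proportions$nRBC[case]) - 0.045), 1e-9)
  expect_lt(abs(mean(coh$true_proportions$nRBC[!case]) - 0.021), 1e-9)
})

test_that("infeasible composition targets are rejected", {
  expect_error(simulation_config(eos_mean_case = 1.2), "infeasible")
  expect_error(simulation_config(n_cpgs = 10), "too small")
  expect_error(simulation_config(prevalence = 0), "prevalence")
})

test_that("the expression probe tracks the first planted CpG negatively", {
  coh <- generate_cohort(simulation_config(rng_seed = 2, n_samples = 1000,
    n_cpgs = 300, n_discriminating_cpgs_per_type = 4, n_planted_cpgs = 3))
  m1 <- unclass(beta_to_m(coh$beta))[, coh$truth$cpg_id[1]]
  e1 <- unclass(coh$expression)[, coh$target_probe]
  rho <- cor(m1, e1, method = "spearman")
  expect_lt(abs(rho - (-0.22)), 0.06)
})

test_that("stratified split reproduces the published stage sizes", {
  coh <- generate_cohort(simulation_config(rng_seed = 1, n_cpgs = 200,
    n_discriminating_cpgs_per_type = 3, n_planted_cpgs = 4))
  halves <- split_cohort(coh, 91 / 370, seed = 2)
  expect_equal(nrow(halves$stage1$beta), 91)
  expect_equal(nrow(halves$stage2$beta), 279)
  expect_length(intersect(halves$stage1$phenotypes$sample_id,
                          halves$stage2$phenotypes$sample_id), 0)
  expect_setequal(c(halves$stage1$phenotypes$sample_id,
                    halves$stage2$phenotypes$sample_id),
                  coh$phenotypes$sample_id)
  # prevalence within one sample of the cohort rate in both halves
  for (h in halves) {
    expect_lte(abs(sum(h$phenotypes$asthma) -
                   mean(coh$phenotypes$asthma) * nrow(h$beta)), 1)
  }
})

test_that("an even split stratifies cases exactly and is seed-reproducible", {
  coh <- tiny_cohort(seed = 10, n_samples = 100, prevalence = 0.5)
  expect_equal(sum(coh$phenotypes$asthma), 50)
  halves <- split_cohort(coh, 0.5, seed = 1)
  expect_equal(sum(halves$stage1$phenotypes$asthma), 25)
  expect_equal(sum(halves$stage2$phenotypes$asthma), 25)
  halves2 <- split_cohort(coh, 0.5, seed = 1)
  expect_identical(halves$stage1$phenotypes$sample_id,
                   halves2$stage1$phenotypes$sample_id)
  halves3 <- split_cohort(coh, 0.5, seed = 2)
  expect_false(identical(halves$stage1$phenotypes$sample_id,
                         halves3$stage1$phenotypes$sample_id))
})

test_that("splitting requires at least two samples per stratum", {
  coh <- tiny_cohort(seed = 11, n_samples = 8, prevalence = 0.13)
  # 8 samples at 13% prevalence -> a single case
  expect_error(split_cohort(coh, 0.5), ">= 2 samples")
})

test_that("cohorts round-trip through the on-disk layout", {
  coh <- tiny_cohort(seed = 12, n_samples = 20, n_cpgs = 60,
                     n_discriminating_cpgs_per_type = 3, n_planted_cpgs = 2)
  dir <- withr::local_tempdir()
  write_cohort(coh, dir)
  expect_true(all(file.exists(file.path(dir,
    c("beta.tsv", "pheno.tsv", "true_props.tsv", "panel.tsv",
      "expression.tsv", "truth.tsv")))))
  b <- read_matrix(file.path(dir, "beta.tsv"), "beta")
  expect_lt(max(abs(unclass(b) - unclass(coh$beta))), 1e-12)
  truth <- read.delim(file.path(dir, "truth.tsv"))
  expect_identical(truth$cpg_id, coh$truth$cpg_id)
})
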