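test_that("beta to M transform matches closed-form values and is monotone", {
  b <- beta_matrix(matrix(c(0.5, 0.8, 0.93, 0.25), 1, 4))
  m <- beta_to_m(b)
  expect_equal(unclass(m)[1, 1], 0)
  expect_equal(unclass(m)[1, 2], 2)
  expect_equal(unclass(m)[1, 3], log2(0.93 / 0.07), tolerance = 1e-10)
  expect_equal(unclass(m)[1, 3], 3.7315, tolerance = 1e-4)

  set.seed(7)
  bs <- sort(runif(50, 0.01, 0.99))
  ms <- unclass(beta_to_m(beta_matrix(matrix(bs, 1))))
  expect_true(all(diff(as.numeric(ms)) > 0))
})

test_that("beta -> M -> beta round-trips within 1e-9 and propagates missing", {
  set.seed(8)
  vals <- matrix(runif(60), 6, 10)
  vals[2, 3] <- NA
  b <- beta_matrix(vals)
  back <- m_to_beta(beta_to_m(b))
  expect_lt(max(abs(unclass(back) - unclass(b)), na.rm = TRUE), 1e-9)
  expect_true(is.na(unclass(back)[2, 3]))
})

test_that("medcouple reproduces worked values", {
  expect_equal(as.numeric(medcouple(c(1, 2, 3))), 0)
  expect_equal(as.numeric(medcouple(c(0, 1, 2, 4, 8, 16))), 3 / 7)
})

test_that("medcouple is antisymmetric and bounded", {
  set.seed(11)
  for (i in 1:20) {
    x <- rexp(sample(5:40, 1))^sample(1:2, 1)
    mc <- as.numeric(medcouple(x))
    expect_gte(mc, -1); expect_lte(mc, 1)
    expect_equal(as.numeric(medcouple(-x)), -mc)
  }
})

test_that("medcouple matches the brute-force kernel enumeration exactly", {
  set.seed(12)
  for (i in 1:200) {
    n <- sample(3:50, 1)
    x <- switch(sample(3, 1), rnorm(n), rexp(n), rlnorm(n))
    expect_identical(as.numeric(medcouple(x)), medcouple_bruteforce(x))
  }
})

test_that("degenerate medcouple input returns 0 with a flag", {
  mc <- medcouple(rep(2.5, 10))
  expect_equal(as.numeric(mc), 0)
  expect_true(attr(mc, "degenerate"))
  expect_error(medcouple(c(1, 2)), ">= 3")
})

test_that("adjusted fences reduce to Tukey fences for symmetric samples", {
  x <- c(1, 2, 3, 4, 5, 6, 7)   # MC = 0
  f <- adjusted_fences(x)
  q <- quantile(x, c(0.25, 0.75), type = 7, names = FALSE)
  iqr <- diff(q)
  expect_equal(as.numeric(f), c(q[1] - 1.5 * iqr, q[2] + 1.5 * iqr))
})

test_that("right-skewed fences extend upward per the exponential factors", {
  x <- c(0, 1, 2, 4, 8, 16)     # MC = 3/7, Q1 = 1.25, Q3 = 7
  f <- adjusted_fences(x)
  q <- quantile(x, c(0.25, 0.75), type = 7, names = FALSE)
  iqr <- diff(q)
  mc <- 3 / 7
  expect_equal(unname(f["lower"]), q[1] - 1.5 * exp(-4 * mc) * iqr)
  expect_equal(unname(f["upper"]), q[2] + 1.5 * exp(3 * mc) * iqr)
  # both fences sit above their Tukey counterparts for a right-skewed sample
  expect_gt(f["lower"], q[1] - 1.5 * iqr)
  expect_gt(f["upper"], q[2] + 1.5 * iqr)
})

test_that("fences mirror exactly under negation", {
  set.seed(13)
  for (i in 1:10) {
    x <- rlnorm(30)
    f <- adjusted_fences(x)
    g <- adjusted_fences(-x)
    expect_equal(unname(g["lower"]), -unname(f["upper"]))
    expect_equal(unname(g["upper"]), -unname(f["lower"]))
  }
})

test_that("zero-IQR input collapses fences to the quartiles with a flag", {
  x <- c(rep(1, 10), 0, 2)
  f <- adjusted_fences(x)
  expect_true(attr(f, "degenerate"))
  expect_equal(as.numeric(f), c(1, 1))
})

test_that("trimming removes exactly the planted outlier and reports fences", {
  set.seed(14)
  col1 <- rnorm(99, 0, 0.1)
  m <- m_matrix(cbind(cg_a = c(col1, 10), cg_b = rnorm(100, 0, 0.1)))
  tr <- trim_outliers(m)
  expect_true(is.na(unclass(tr$m)[100, "cg_a"]))
  expect_equal(tr$report$n_trimmed_high[1], 1)   # the gross outlier alone, above
  # every trimmed value lies outside the reported fences; kept values inside
  rep_a <- tr$report[1, ]
  gone <- is.na(unclass(tr$m)[, "cg_a"])
  expect_equal(sum(gone), rep_a$n_trimmed_low + rep_a$n_trimmed_high)
  expect_true(all(unclass(m)[gone, "cg_a"] < rep_a$lower_fence |
                  unclass(m)[gone, "cg_a"] > rep_a$upper_fence))
  expect_true(all(unclass(m)[!gone, "cg_a"] >= rep_a$lower_fence &
                  unclass(m)[!gone, "cg_a"] <= rep_a$upper_fence))
  expect_false(any(is.na(unclass(m))))   # input untouched
  rep_b <- tr$report[tr$report$cpg_id == "cg_b", ]
  expect_lte(rep_b$lower_fence, rep_b$upper_fence)
  expect_gte(rep_b$medcouple, -1); expect_lte(rep_b$medcouple, 1)
})

test_that("columns that are constant or too short are skipped and flagged", {
  m <- m_matrix(cbind(const = rep(1.5, 8),
                      short = c(1, 2, 3, NA, NA, NA, NA, NA),
                      ok = c(1, 2, 3, 4, 5, 6, 7, 8)))
  tr <- trim_outliers(m)
  expect_true(tr$report$skipped[1])
  expect_true(tr$report$degenerate[1])
  expect_true(tr$report$skipped[2])
  expect_false(tr$report$skipped[3])
  expect_identical(unclass(tr$m)[, "const"], unclass(m)[, "const"])
})

test_that("re-trimming is exactly idempotent where the first pass trimmed nothing", {
  # Fences are re-estimated after trimming, so columns whose extremes were
  # removed can shed a few more values on a second pass; but columns the
  # first pass left alone have identical fences and must be untouched.
  set.seed(15)
  m <- m_matrix(matrix(rnorm(200 * 100), 200, 100))
  t1 <- trim_outliers(m)
  t2 <- trim_outliers(t1$m)
  first <- t1$report$n_trimmed_low + t1$report$n_trimmed_high
  second <- t2$report$n_trimmed_low + t2$report$n_trimmed_high
  expect_true(all(second[first == 0] == 0))
  expect_gt(sum(first == 0), 10)           # the claim is not vacuous
  expect_lt(sum(second), sum(first))       # the cascade shrinks
})
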