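test_that("assays detected late in most samples are excluded, with a strict
           majority boundary", {
  n <- 100
  mk <- function(late_count, assay = "miR-a") {
    ct <- matrix(c(rep(25, n),
                   c(rep(36, late_count), rep(30, n - late_count))),
                 n, 2, dimnames = list(sprintf("s%03d", 1:n),
                                       c("let-7d", assay)))
    make_ct_matrix(ct)
  }
  expect_identical(low_expression_filter(mk(60))$excluded, "miR-a")
  expect_identical(low_expression_filter(mk(0))$excluded, character(0))
  # exactly half above the cutoff is retained (strict ">")
  expect_identical(low_expression_filter(mk(50))$excluded, character(0))
  # censored entries count as late
  x <- mk(40)
  x$ct[61:75, "miR-a"] <- NA; x$censored[61:75, "miR-a"] <- TRUE
  expect_identical(low_expression_filter(x)$excluded, "miR-a")
})

test_that("pooled two-sample t matches the closed form and a t-distribution
           oracle", {
  r0 <- students_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(r0$statistic, 0)
  expect_equal(r0$p.value, 1)

  r <- students_t(c(1, 2, 3), c(4, 5, 6))
  # pooled sd = 1, se = sqrt(2/3), t = -3/sqrt(2/3)
  expect_equal(r$statistic, -3 / sqrt(2 / 3), tolerance = 1e-12)
  expect_equal(r$statistic, -3.674, tolerance = 1e-3)
  expect_equal(r$df, 4)
  expect_equal(r$p.value, 2 * pt(-abs(r$statistic), 4), tolerance = 1e-12)

  # antisymmetry
  rswap <- students_t(c(4, 5, 6), c(1, 2, 3))
  expect_equal(rswap$statistic, -r$statistic)
  expect_equal(rswap$p.value, r$p.value)

  # degenerate zero variance with unequal means
  expect_error(students_t(c(1, 1, 1), c(2, 2, 2)), "zero variance")
})

test_that("summary-based t agrees with the raw-data t", {
  r <- t_from_summary(0, 1, 10, 1, 1, 10)
  expect_equal(r$statistic, -2.2361, tolerance = 1e-4)
  expect_equal(r$df, 18)
  expect_equal(t_from_summary(5, 2, 12, 5, 2, 12)$p.value, 1)

  set.seed(9)
  for (i in 1:20) {
    a <- rnorm(sample(5:40, 1)); b <- rnorm(sample(5:40, 1), 0.3)
    raw <- students_t(a, b)
    smry <- t_from_summary(mean(a), sd(a), length(a),
                           mean(b), sd(b), length(b))
    expect_equal(smry$statistic, raw$statistic, tolerance = 1e-9)
    expect_equal(smry$p.value, raw$p.value, tolerance = 1e-9)
  }
})

test_that("2x2 chi-square matches the closed Pearson form, is symmetric,
           and rejects zero margins", {
  expect_equal(chi_square_2x2(matrix(10, 2, 2))$statistic, 0)
  expect_equal(chi_square_2x2(matrix(10, 2, 2))$p.value, 1)

  tab <- matrix(c(20, 10, 10, 20), 2)
  r <- chi_square_2x2(tab)
  expect_equal(r$statistic, 60 * (20 * 20 - 10 * 10)^2 / (30 * 30 * 30 * 30),
               tolerance = 1e-12)
  expect_equal(r$statistic, 6.667, tolerance = 1e-3)
  expect_equal(r$df, 1)
  expect_equal(chi_square_2x2(t(tab))$statistic, r$statistic)
  expect_error(chi_square_2x2(matrix(c(0, 0, 5, 5), 2)), "margin")
})

test_that("chi-square agrees with direct Pearson evaluation across random
           small tables", {
  set.seed(31)
  pearson <- function(a, b, c, d) {
    n <- a + b + c + d
    n * (a * d - b * c)^2 / ((a + b) * (c + d) * (a + c) * (b + d))
  }
  for (i in 1:500) {
    cells <- as.integer(rmultinom(1, sample(4:30, 1), rep(0.25, 4)))
    tab <- matrix(cells, 2)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
    expect_equal(chi_square_2x2(tab)$statistic,
                 pearson(cells[1], cells[3], cells[2], cells[4]),
                 tolerance = 1e-12)
  }
})

test_that("group summaries report mean, SD and SEM over non-missing values", {
  ct <- matrix(c(25, 25, 25, 25,
                 25 - log2(c(1, 2, 3, 3))), 4, 2,
               dimnames = list(paste0("s", 1:4), c("let-7d", "miR-a")))
  x <- make_ct_matrix(ct, groups = c(rep("PTC", 3), "CONTROL"))
  e <- normalize_expression(x)
  s <- summarize_groups(e)
  ptc <- s[s$group == "PTC", ]
  expect_equal(ptc$n, 3)
  expect_equal(ptc$mean, 2)
  expect_equal(ptc$sd, 1)
  expect_equal(ptc$sem, 1 / sqrt(3), tolerance = 1e-10)
  # single-value group: SEM undefined
  ctl <- s[s$group == "CONTROL", ]
  expect_true(is.na(ctl$sem))
  # missing entries drop out of n
  e$expr[1, "miR-a"] <- NA
  s2 <- summarize_groups(e)
  expect_equal(s2$n[s2$group == "PTC"], 2)
  # constant group has SEM zero
  ct2 <- matrix(c(25, 25, 25, 24, 24, 24), 3, 2,
                dimnames = list(paste0("s", 1:3), c("let-7d", "miR-a")))
  s3 <- summarize_groups(normalize_expression(make_ct_matrix(
    ct2, groups = rep("PTC", 3))))
  expect_equal(s3$sem, 0)
})

test_that("the pooled t holds its nominal size under a lognormal null", {
  set.seed(77)
  reps <- 2000
  p <- numeric(reps)
  for (i in 1:reps) {
    a <- rlnorm(50, 0, 0.5); b <- rlnorm(50, 0, 0.5)
    p[i] <- students_t(a, b)$p.value
  }
  expect_lt(abs(mean(p < 0.05) - 0.05), 0.015)
})
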