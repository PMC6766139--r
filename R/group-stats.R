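# Descriptive statistics and the study's two-group tests, applied per miRNA
# (on the 2^-dCT scale by default) and to cohort demographics.

#' Exclude assays detected too late in too many samples
#'
#' An assay is excluded when the fraction of samples in which it is either
#' censored or has Cq above `cq_cutoff` exceeds `max_fraction` strictly —
#' "detected in most samples only beyond the reliable range".
#'
#' @param x a [ct_matrix()].
#' @param cq_cutoff reliability cutoff in cycles (default 35).
#' @param max_fraction exclusion threshold on the late/censored fraction,
#'   in (0, 1); the fraction must exceed it strictly (default 0.5).
#' @param sample_ids optional subset of samples over which to evaluate the
#'   fractions (e.g. the training set only).
#' @return List with `retained` and `excluded` assay-id vectors and `log`, a
#'   data frame of per-assay late fractions.
#' @export
low_expression_filter <- function(x, cq_cutoff = 35, max_fraction = 0.5,
                                  sample_ids = NULL) {
  stopifnot(inherits(x, "ct_matrix"), max_fraction > 0, max_fraction < 1)
  keep <- if (is.null(sample_ids)) rep(TRUE, nrow(x$ct))
          else x$samples$sample_id %in% sample_ids
  tgt <- x$assays$assay_id[x$assays$role == "TARGET"]
  ct <- x$ct[keep, tgt, drop = FALSE]
  cens <- x$censored[keep, tgt, drop = FALSE]
  late <- cens | (!is.na(ct) & ct > cq_cutoff)
  measured <- cens | !is.na(ct)
  n_meas <- colSums(measured)
  frac <- ifelse(n_meas > 0, colSums(late) / n_meas, 0)
  excl <- tgt[frac > max_fraction]
  list(retained = setdiff(tgt, excl), excluded = excl,
       log = data.frame(assay_id = tgt, n = n_meas,
                        n_late_or_censored = colSums(late),
                        fraction = frac, excluded = frac > max_fraction,
                        row.names = NULL))
}

#' Two-sample Student's t test
#'
#' Pooled-variance two-sample t (df = nA + nB − 2), two-sided, as used for
#' per-miRNA group comparisons; Welch's unequal-variance variant is
#' available behind `welch = TRUE` for sensitivity analysis. Degenerate
#' zero-variance input is resolved before dispatch: equal means give t = 0,
#' p = 1; unequal means with zero pooled variance are an error.
#'
#' @param a,b numeric vectors (>= 2 finite values each).
#' @param welch use Welch's t instead of the pooled test.
#' @param comparison optional label carried into the result.
#' @return A `test_result` list: `statistic`, `df`, `p.value`, `method`,
#'   `comparison`.
#' @export
students_t <- function(a, b, welch = FALSE, comparison = NULL) {
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  if (length(a) < 2 || length(b) < 2)
    stop("each group needs at least 2 finite values")
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    if (mean(a) == mean(b))
      return(test_result(0, length(a) + length(b) - 2, 1,
                         "Student's t (pooled)", comparison))
    stop("zero variance in both groups with unequal means: t undefined")
  }
  ht <- stats::t.test(a, b, var.equal = !welch)
  test_result(unname(ht$statistic), unname(ht$parameter), ht$p.value,
              if (welch) "Welch's t" else "Student's t (pooled)", comparison)
}

#' Pooled t test from group summaries
#'
#' Same pooled-variance t as [students_t()], evaluated from (mean, SD, n)
#' summaries — the form needed to reproduce demographic comparisons
#' reported only as mean ± SD.
#'
#' @param mean_a,sd_a,n_a,mean_b,sd_b,n_b group summaries (`sd >= 0`,
#'   `n >= 2`).
#' @inheritParams students_t
#' @return A `test_result` list.
#' @export
t_from_summary <- function(mean_a, sd_a, n_a, mean_b, sd_b, n_b,
                           comparison = NULL) {
  stopifnot(sd_a >= 0, sd_b >= 0, n_a >= 2, n_b >= 2)
  df <- n_a + n_b - 2
  sp2 <- ((n_a - 1) * sd_a^2 + (n_b - 1) * sd_b^2) / df
  if (sp2 == 0) {
    if (mean_a == mean_b)
      return(test_result(0, df, 1, "Student's t (pooled, from summaries)",
                         comparison))
    stop("zero pooled variance with unequal means: t undefined")
  }
  t <- (mean_a - mean_b) / sqrt(sp2 * (1 / n_a + 1 / n_b))
  test_result(t, df, 2 * stats::pt(-abs(t), df),
              "Student's t (pooled, from summaries)", comparison)
}

#' Pearson chi-square test on a 2x2 table
#'
#' Without continuity correction by default (`correct = TRUE` gives the
#' Yates-corrected variant). All margins must be positive.
#'
#' @param tab 2x2 matrix of nonnegative counts.
#' @param correct apply Yates continuity correction.
#' @inheritParams students_t
#' @return A `test_result` list (df = 1).
#' @export
chi_square_2x2 <- function(tab, correct = FALSE, comparison = NULL) {
  tab <- as.matrix(tab)
  stopifnot(identical(dim(tab), c(2L, 2L)), all(tab >= 0))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("chi-square undefined: zero row or column margin")
  ht <- suppressWarnings(stats::chisq.test(tab, correct = correct))
  test_result(unname(ht$statistic), unname(ht$parameter), ht$p.value,
              paste0("Pearson chi-square", if (correct) " (Yates)"),
              comparison)
}

test_result <- function(statistic, df, p, method, comparison = NULL) {
  structure(list(statistic = statistic, df = df, p.value = p,
                 method = method, comparison = comparison),
            class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  cat("<test_result>", x$method,
      if (!is.null(x$comparison)) paste0("[", x$comparison, "]"), "\n")
  cat(sprintf("  statistic = %.4f, df = %.4g, p = %.4g\n",
              x$statistic, x$df, x$p.value))
  invisible(x)
}

#' Per-group descriptive statistics of relative expression
#'
#' Mean, SD and SEM (= SD/sqrt(n)) of `2^-dCT` per target assay and group,
#' computed over non-missing entries only — the mean ± SEM layout used for
#' reporting serum miRNA levels.
#'
#' @param expr an `expr_matrix` from [normalize_expression()].
#' @param groups groups to summarize (default all present).
#' @param sample_ids optional subset of samples.
#' @return Data frame: `assay_id`, `group`, `n`, `mean`, `sd`, `sem`
#'   (SEM is `NA` when n < 2).
#' @export
summarize_groups <- function(expr, groups = NULL, sample_ids = NULL) {
  stopifnot(inherits(expr, "expr_matrix"))
  keep <- if (is.null(sample_ids)) rep(TRUE, nrow(expr$expr))
          else expr$samples$sample_id %in% sample_ids
  g <- expr$samples$group[keep]
  if (is.null(groups)) groups <- intersect(GROUP_LEVELS, unique(g))
  e <- expr$expr[keep, , drop = FALSE]
  out <- do.call(rbind, lapply(groups, function(gr) {
    sub <- e[g == gr, , drop = FALSE]
    n <- colSums(is.finite(sub))
    m <- apply(sub, 2, function(v) mean(v[is.finite(v)]))
    s <- apply(sub, 2, function(v) stats::sd(v[is.finite(v)]))
    data.frame(assay_id = colnames(e), group = gr, n = n, mean = m, sd = s,
               sem = ifelse(n >= 2, s / sqrt(n), NA_real_), row.names = NULL)
  }))
  out
}

#' Per-miRNA two-group tests on an expression matrix
#'
#' Runs [students_t()] for every target assay between two groups, on the
#' relative-expression scale by default or on the dCT (log2) scale.
#'
#' @param expr an `expr_matrix`.
#' @param group_a,group_b group labels to compare (a vs b).
#' @param scale `"expression"` (2^-dCT, the reporting scale) or
#'   `"delta_ct"`.
#' @param sample_ids optional subset of samples.
#' @inheritParams students_t
#' @return Data frame: `assay_id`, `n_a`, `n_b`, `mean_a`, `mean_b`, `t`,
#'   `df`, `p.value` (NA where a group has < 2 finite values).
#' @export
test_groups <- function(expr, group_a, group_b,
                        scale = c("expression", "delta_ct"),
                        welch = FALSE, sample_ids = NULL) {
  stopifnot(inherits(expr, "expr_matrix"))
  scale <- match.arg(scale)
  mat <- if (scale == "expression") expr$expr else expr$delta_ct
  keep <- if (is.null(sample_ids)) rep(TRUE, nrow(mat))
          else expr$samples$sample_id %in% sample_ids
  g <- expr$samples$group[keep]
  mat <- mat[keep, , drop = FALSE]
  out <- data.frame(assay_id = colnames(mat), n_a = NA_integer_,
                    n_b = NA_integer_, mean_a = NA_real_, mean_b = NA_real_,
                    t = NA_real_, df = NA_real_, p.value = NA_real_)
  for (j in seq_len(ncol(mat))) {
    a <- mat[g == group_a, j]; a <- a[is.finite(a)]
    b <- mat[g == group_b, j]; b <- b[is.finite(b)]
    out$n_a[j] <- length(a); out$n_b[j] <- length(b)
    if (length(a)) out$mean_a[j] <- mean(a)
    if (length(b)) out$mean_b[j] <- mean(b)
    if (length(a) >= 2 && length(b) >= 2) {
      tr <- students_t(a, b, welch = welch)
      out$t[j] <- tr$statistic; out$df[j] <- tr$df
      out$p.value[j] <- tr$p.value
    }
  }
  out
}
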