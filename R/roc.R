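# Empirical ROC analysis. AUC is the tie-corrected concordance probability
# (Mann-Whitney): over all case-control pairs, P(case > control) + 0.5
# P(tie). The curve takes "score > threshold => case" at every distinct
# observed score, so its trapezoidal area equals the pairwise AUC exactly.

#' Mann-Whitney AUC
#'
#' Tie-corrected concordance probability computed from midranks:
#' `AUC = (R1 - n1(n1+1)/2) / (n1 n0)` with `R1` the case rank sum.
#'
#' @param scores numeric vector.
#' @param labels case/control indicator (see [fit_weight()] encodings).
#' @return AUC in `[0, 1]`.
#' @export
auc <- function(scores, labels) {
  y <- as_case_indicator(labels)
  stopifnot(length(scores) == length(y), all(is.finite(scores)))
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) stop("both classes must be nonempty")
  r <- rank(scores, ties.method = "average")
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Empirical ROC curve points
#'
#' Thresholds at every distinct observed score plus the two infinite
#' endpoints, decision rule `score > threshold`. The curve runs from (0,0)
#' to (1,1) and is monotone nondecreasing in both coordinates.
#'
#' @inheritParams auc
#' @return Data frame `threshold`, `fpr`, `tpr`, ordered from (0,0) to
#'   (1,1).
#' @export
roc_points <- function(scores, labels) {
  y <- as_case_indicator(labels)
  stopifnot(length(scores) == length(y), all(is.finite(scores)))
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) stop("both classes must be nonempty")
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE), -Inf)
  tpr <- vapply(thr, function(t) sum(scores[y == 1] > t) / n1, 0)
  fpr <- vapply(thr, function(t) sum(scores[y == 0] > t) / n0, 0)
  data.frame(threshold = thr, fpr = fpr, tpr = tpr)
}

trapezoid_area <- function(fpr, tpr) {
  sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
}

# DeLong placement-value variance of the empirical AUC.
# V10_i = mean_j psi(x_i, y_j) over controls; V01_j = mean_i psi(x_i, y_j);
# var = S10/n1 + S01/n0 with S the sample variances of the placements.
delong_variance <- function(scores, y) {
  x <- scores[y == 1]; z <- scores[y == 0]
  n1 <- length(x); n0 <- length(z)
  psi_case <- vapply(x, function(xi) mean((xi > z) + 0.5 * (xi == z)), 0)
  psi_ctl <- vapply(z, function(zj) mean((x > zj) + 0.5 * (x == zj)), 0)
  stats::var(psi_case) / n1 + stats::var(psi_ctl) / n0
}

# Hanley-McNeil variance (the classic binormal-free approximation).
hanley_variance <- function(a, n1, n0) {
  q1 <- a / (2 - a)
  q2 <- 2 * a^2 / (1 + a)
  (a * (1 - a) + (n1 - 1) * (q1 - a^2) + (n0 - 1) * (q2 - a^2)) / (n1 * n0)
}

#' Normal-approximation confidence interval for the AUC
#'
#' DeLong's placement-value variance (default; tie-robust) or the
#' Hanley-McNeil approximation. Bounds are clipped to `[0, 1]`. A zero
#' variance estimate (e.g. AUC exactly 1 under perfect separation) yields
#' the degenerate interval `(AUC, AUC)` with attribute `degenerate = TRUE`.
#'
#' @inheritParams auc
#' @param level confidence level (default 0.95).
#' @param method `"delong"` or `"hanley"`.
#' @return Length-2 vector `c(lower, upper)` with attribute `degenerate`.
#' @export
auc_ci <- function(scores, labels, level = 0.95,
                   method = c("delong", "hanley")) {
  method <- match.arg(method)
  y <- as_case_indicator(labels)
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  stopifnot(n1 >= 2, n0 >= 2)
  a <- auc(scores, y)
  v <- if (method == "delong") delong_variance(scores, y)
       else hanley_variance(a, n1, n0)
  if (v <= 0)
    return(structure(c(lower = a, upper = a), degenerate = TRUE))
  z <- stats::qnorm(1 - (1 - level) / 2)
  ci <- a + c(-1, 1) * z * sqrt(v)
  structure(c(lower = max(0, ci[1]), upper = min(1, ci[2])),
            degenerate = FALSE)
}

#' Orient scores so that cases tend to score higher
#'
#' Negates the scores when the raw AUC is below 0.5 (e.g. a down-regulated
#' marker used directly as its expression level), so single-marker AUCs are
#' reported on the conventional >= 0.5 side. An AUC of exactly 0.5 keeps the
#' original orientation.
#'
#' @inheritParams auc
#' @return The (possibly negated) scores, with attribute `flipped`.
#' @export
orient_scores <- function(scores, labels) {
  flipped <- auc(scores, labels) < 0.5
  structure(if (flipped) -scores else scores, flipped = flipped)
}

#' Full ROC analysis of one score against case/control labels
#'
#' Bundles [auc()], [roc_points()] and [auc_ci()] into a single classed
#' result, optionally auto-orienting the score first.
#'
#' @inheritParams auc_ci
#' @param orient auto-flip scores so AUC >= 0.5 (records the flip).
#' @param comparison optional label (e.g. `"PTC vs CONTROL"`).
#' @return Object of class `roc_result`: `auc`, `ci`, `ci_method`, `curve`,
#'   `n_case`, `n_control`, `flipped`, `degenerate_ci`, `comparison`.
#' @examples
#' set.seed(1)
#' r <- roc(c(rnorm(20, 1), rnorm(20)), rep(c(1, 0), each = 20))
#' r$auc
#' @export
roc <- function(scores, labels, level = 0.95,
                method = c("delong", "hanley"), orient = FALSE,
                comparison = NULL) {
  method <- match.arg(method)
  y <- as_case_indicator(labels)
  flipped <- FALSE
  if (orient) {
    scores <- orient_scores(scores, y)
    flipped <- attr(scores, "flipped")
  }
  a <- auc(scores, y)
  ci <- auc_ci(scores, y, level = level, method = method)
  curve <- roc_points(scores, y)
  stopifnot(abs(trapezoid_area(curve$fpr, curve$tpr) - a) < 1e-12)
  structure(
    list(auc = a, ci = ci, ci_method = method, level = level,
         curve = curve, n_case = sum(y == 1), n_control = sum(y == 0),
         flipped = flipped, degenerate_ci = attr(ci, "degenerate"),
         comparison = comparison),
    class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat("<roc_result>",
      if (!is.null(x$comparison)) paste0(x$comparison, ": ") else "",
      sprintf("AUC = %.3f (%.0f%% CI %.3f-%.3f, %s)%s\n",
              x$auc, 100 * x$level, x$ci[1], x$ci[2], x$ci_method,
              if (x$degenerate_ci) " [degenerate]" else ""), sep = "")
  cat("  n_case =", x$n_case, ", n_control =", x$n_control,
      if (x$flipped) ", score orientation flipped", "\n")
  invisible(x)
}

#' @export
plot.roc_result <- function(x, ...) {
  plot(x$curve$fpr, x$curve$tpr, type = "s",
       xlab = "False positive rate", ylab = "True positive rate",
       main = if (!is.null(x$comparison)) x$comparison else "ROC",
       xlim = c(0, 1), ylim = c(0, 1), ...)
  graphics::abline(0, 1, lty = 3, col = "grey50")
  graphics::legend("bottomright", bty = "n",
                   legend = sprintf("AUC = %.3f (%.3f-%.3f)",
                                    x$auc, x$ci[1], x$ci[2]))
  invisible(x)
}
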