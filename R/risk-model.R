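# Reference-interval risk-score classifier.
#
# For each marker j the control group defines a reference interval; a sample
# scores s_ij = 1 when it exceeds the control 95th percentile (up-regulated
# marker) or falls below the control 5th percentile (down-regulated marker).
# Each marker's weight W_j is the slope of a univariate logistic regression
# of case status on s_ij — for a binary predictor this is the log odds
# ratio — and a sample's risk score is the weighted sum RSF_i = sum_j W_j s_ij.

#' Control reference-interval threshold
#'
#' 95th percentile of the control values for an up-regulated marker, 5th for
#' a down-regulated one, by linear interpolation between closest order
#' statistics (position `1 + (n-1)p`, [stats::quantile()] type 7).
#'
#' @param controls numeric vector of control-group expression values
#'   (non-finite entries dropped). Fewer than 20 values triggers a warning:
#'   the tail percentile is then unstable.
#' @param direction `"UP"` or `"DOWN"`.
#' @return Threshold on the expression scale.
#' @export
reference_threshold <- function(controls, direction = c("UP", "DOWN")) {
  direction <- match.arg(direction)
  controls <- controls[is.finite(controls)]
  if (!length(controls)) stop("no finite control values")
  if (length(controls) < 20)
    warning("only ", length(controls),
            " control values: tail percentile is unstable")
  p <- if (direction == "UP") 0.95 else 0.05
  unname(stats::quantile(controls, p, type = 7, names = FALSE))
}

#' Binarize one expression value against a reference threshold
#'
#' Strict inequalities; ties score 0. Missing expression scores 0 (the
#' sample contributes no risk for that marker) and is counted in the fit's
#' imputation log. The `down_rule` option also exposes the literal
#' above-the-lower-bound reading (`"above_lower"`) for sensitivity analysis;
#' the default scores a down-regulated marker when expression falls below
#' its 5th-percentile bound.
#'
#' @param x expression value(s); `NA` allowed.
#' @param tau threshold from [reference_threshold()].
#' @param direction `"UP"` or `"DOWN"`.
#' @param down_rule `"below_lower"` (default) or `"above_lower"`.
#' @return Integer 0/1 vector, same length as `x`.
#' @export
binarize <- function(x, tau, direction = c("UP", "DOWN"),
                     down_rule = c("below_lower", "above_lower")) {
  direction <- match.arg(direction)
  down_rule <- match.arg(down_rule)
  stopifnot(is.finite(tau))
  s <- if (direction == "UP") x > tau
       else if (down_rule == "below_lower") x < tau
       else x > tau
  s[!is.finite(x)] <- FALSE
  as.integer(s)
}

#' Univariate logistic-regression weight of one binary risk score
#'
#' Fits `label ~ s` by iteratively reweighted least squares
#' ([stats::glm()], binomial) and returns the slope. For a binary predictor
#' without separation this equals the log of the sample odds ratio. When the
#' 2x2 table of `s` by label has a zero cell (separation), the
#' Haldane-Anscombe correction adds 0.5 to all four cells and the corrected
#' log odds ratio is returned with flag `"SEPARATION"`. A constant `s`
#' carries no information: weight 0 with flag `"DEGENERATE"`.
#'
#' @param s integer 0/1 vector.
#' @param label case/control indicator: logical, 0/1, or a factor whose
#'   second level is the case.
#' @return Numeric weight (log-odds units) with attribute `flag` (`"OK"`,
#'   `"SEPARATION"` or `"DEGENERATE"`).
#' @export
fit_weight <- function(s, label) {
  y <- as_case_indicator(label)
  stopifnot(length(s) == length(y), all(s %in% c(0L, 1L)))
  if (length(unique(y)) < 2) stop("both classes must be present in `label`")
  if (length(unique(s)) < 2)
    return(structure(0, flag = "DEGENERATE"))
  # 2x2 cells: a = case & s1, b = case & s0, c = control & s1, d = control & s0
  a <- sum(y == 1 & s == 1); b <- sum(y == 1 & s == 0)
  cc <- sum(y == 0 & s == 1); d <- sum(y == 0 & s == 0)
  if (min(a, b, cc, d) == 0) {
    w <- log(((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (cc + 0.5)))
    return(structure(w, flag = "SEPARATION"))
  }
  fit <- stats::glm(y ~ s, family = stats::binomial(),
                    control = stats::glm.control(epsilon = 1e-12, maxit = 100))
  structure(unname(stats::coef(fit)[2]), flag = "OK")
}

as_case_indicator <- function(label) {
  if (is.factor(label)) as.integer(label == levels(label)[2])
  else if (is.logical(label)) as.integer(label)
  else if (all(label %in% c(0, 1))) as.integer(label)
  else stop("`label` must be logical, 0/1, or a two-level factor")
}

#' Risk score of one sample
#'
#' Exact weighted sum `sum(w * s)` of the binarized marker exceedances.
#'
#' @param s integer 0/1 vector over markers.
#' @param w numeric weight vector, same length.
#' @return The risk score (log-odds units).
#' @export
risk_score <- function(s, w) {
  if (length(s) != length(w)) stop("length mismatch between s and w")
  sum(w * s)
}

#' Fit a reference-interval risk-score model
#'
#' The model-fitting front end: determines each marker's regulation
#' direction from training group means (case mean above control mean = UP),
#' takes the reference-interval threshold from the training controls, and
#' fits each marker's logistic weight on the training samples. The returned
#' model is frozen — applying it to new data via [predict.risk_model()]
#' re-estimates nothing.
#'
#' @param expr training data: an `expr_matrix` from
#'   [normalize_expression()], or a plain numeric matrix (samples x
#'   markers).
#' @param labels case/control indicator per training sample (see
#'   [fit_weight()] for accepted encodings). When `expr` is an
#'   `expr_matrix`, `labels` may instead be a length-2 character vector
#'   `c(case_group, control_group)` naming the groups to use; other samples
#'   are ignored.
#' @param markers columns to model (default all).
#' @param directions optional named `"UP"`/`"DOWN"` vector overriding the
#'   data-driven direction choice.
#' @param down_rule passed to [binarize()].
#' @return An object of class `risk_model`: per-marker `direction`,
#'   `threshold`, `weight`, `flag`, plus fitting metadata. Methods:
#'   `print`, `summary`, `coef`, `predict`.
#' @examples
#' set.seed(1)
#' x <- rbind(matrix(2^rnorm(60, -1), 30), matrix(2^rnorm(60), 30))
#' colnames(x) <- c("miR-a", "miR-b")
#' fit <- risk_model(x, labels = rep(c(0, 1), each = 30))
#' coef(fit)
#' predict(fit, x)[1:5]
#' @export
risk_model <- function(expr, labels, markers = NULL, directions = NULL,
                       down_rule = c("below_lower", "above_lower")) {
  down_rule <- match.arg(down_rule)
  if (inherits(expr, "expr_matrix")) {
    if (is.character(labels) && length(labels) == 2) {
      keep <- expr$samples$group %in% labels
      y <- as.integer(expr$samples$group[keep] == labels[1])
      groups_used <- labels
      mat <- expr$expr[keep, , drop = FALSE]
    } else {
      mat <- expr$expr
      y <- as_case_indicator(labels)
      groups_used <- NULL
    }
  } else {
    mat <- as.matrix(expr)
    y <- as_case_indicator(labels)
    groups_used <- NULL
  }
  if (is.null(markers)) markers <- colnames(mat)
  stopifnot(length(y) == nrow(mat), all(markers %in% colnames(mat)))
  if (length(unique(y)) < 2) stop("need both cases and controls to fit")
  mat <- mat[, markers, drop = FALSE]

  dir <- character(length(markers)); names(dir) <- markers
  tau <- w <- numeric(length(markers)); names(tau) <- names(w) <- markers
  flag <- character(length(markers)); names(flag) <- markers
  n_imputed <- integer(length(markers)); names(n_imputed) <- markers
  s_train <- matrix(0L, nrow(mat), length(markers),
                    dimnames = list(rownames(mat), markers))
  for (j in markers) {
    v <- mat[, j]
    ctl <- v[y == 0]; cas <- v[y == 1]
    dir[j] <- if (!is.null(directions) && !is.na(directions[j])) {
      match.arg(directions[[j]], c("UP", "DOWN"))
    } else {
      if (mean(cas[is.finite(cas)]) > mean(ctl[is.finite(ctl)])) "UP" else "DOWN"
    }
    tau[j] <- reference_threshold(ctl, dir[j])
    s <- binarize(v, tau[j], dir[j], down_rule)
    n_imputed[j] <- sum(!is.finite(v))
    s_train[, j] <- s
    wj <- fit_weight(s, y)
    w[j] <- as.numeric(wj); flag[j] <- attr(wj, "flag")
  }
  structure(
    list(markers = markers, direction = dir, threshold = tau, weight = w,
         flag = flag, down_rule = down_rule, n_imputed_missing = n_imputed,
         groups_used = groups_used,
         n_case = sum(y == 1), n_control = sum(y == 0),
         s_train = s_train,
         control_exceedance = colMeans(s_train[y == 0, , drop = FALSE]),
         call = match.call()),
    class = "risk_model")
}

#' @export
print.risk_model <- function(x, ...) {
  cat("<risk_model> reference-interval risk score,", length(x$markers),
      "marker(s)\n")
  cat("  fitted on", x$n_case, "cases /", x$n_control, "controls",
      if (!is.null(x$groups_used))
        paste0("(", x$groups_used[1], " vs ", x$groups_used[2], ")"), "\n")
  print(data.frame(direction = x$direction,
                   threshold = signif(x$threshold, 4),
                   weight = signif(x$weight, 4), flag = x$flag),
        right = FALSE)
  invisible(x)
}

#' @export
summary.risk_model <- function(object, ...) {
  # control_exceedance (mean s over training controls) is the calibration
  # quantity: ~0.05 per marker by construction of the reference interval
  df <- data.frame(marker = object$markers, direction = object$direction,
                   threshold = object$threshold, weight = object$weight,
                   flag = object$flag,
                   control_exceedance = object$control_exceedance,
                   row.names = NULL)
  structure(list(table = df, down_rule = object$down_rule,
                 n_case = object$n_case, n_control = object$n_control),
            class = "summary.risk_model")
}

#' @export
print.summary.risk_model <- function(x, ...) {
  cat("Reference-interval risk-score model (down rule:", x$down_rule, ")\n")
  print(x$table, row.names = FALSE, digits = 4)
  invisible(x)
}

#' @export
coef.risk_model <- function(object, ...) object$weight

#' Score samples with a frozen risk-score model
#'
#' Binarizes each marker against the model's stored thresholds and returns
#' the weighted-sum risk score per sample. Nothing is re-fitted.
#'
#' @param object a [risk_model()].
#' @param newdata an `expr_matrix` or numeric matrix containing the model's
#'   markers as columns.
#' @param type `"score"` (RSF vector) or `"binary"` (the 0/1 matrix).
#' @param ... unused.
#' @return Numeric risk-score vector (named by sample), or the 0/1 matrix.
#' @export
predict.risk_model <- function(object, newdata,
                               type = c("score", "binary"), ...) {
  type <- match.arg(type)
  mat <- if (inherits(newdata, "expr_matrix")) newdata$expr
         else as.matrix(newdata)
  miss <- setdiff(object$markers, colnames(mat))
  if (length(miss))
    stop("newdata lacks marker column(s): ", paste(miss, collapse = ", "))
  s <- vapply(object$markers, function(j)
    binarize(mat[, j], object$threshold[j], object$direction[j],
             object$down_rule),
    integer(nrow(mat)))
  if (!is.matrix(s))
    s <- matrix(s, nrow = 1,
                dimnames = list(rownames(mat)[1], object$markers))
  rownames(s) <- rownames(mat)
  if (type == "binary") return(s)
  rsf <- as.numeric(s %*% object$weight[object$markers])
  names(rsf) <- rownames(mat)
  rsf
}
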