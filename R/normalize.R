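# Composite-reference delta-CT normalization.
#
# Abundance halves per extra cycle, so CT differences are log2 ratios:
#   dCT  = CT_target - CT_reference         (per sample)
#   level = 2^-dCT                          (relative expression)
#   ddCT = dCT_case - dCT_comparator ; fold change = 2^-ddCT
# The reference CT is the arithmetic mean of the endogenous-control CTs
# (equivalently the geometric mean of their linear abundances), which makes
# every per-sample quantity invariant to a global input-amount shift.

#' Composite reference CT for one sample
#'
#' Arithmetic mean of the available (finite) endogenous-control CTs. With
#' fewer controls than designated (some censored), the mean of the remainder
#' is returned and the result carries attribute `degraded = TRUE` so the
#' sample can be audited downstream.
#'
#' @param ref_cts numeric vector of reference CT values; `NA` entries are
#'   treated as censored and dropped.
#' @return Composite CT (cycles) with attribute `degraded`.
#' @export
composite_reference_ct <- function(ref_cts) {
  finite <- ref_cts[is.finite(ref_cts)]
  if (!length(finite))
    stop("no finite reference CT: sample cannot be normalized")
  structure(mean(finite), degraded = length(finite) < length(ref_cts))
}

#' Delta-CT of a target against the composite reference
#'
#' @param target_ct target assay CT (cycles).
#' @param reference_ct composite reference CT (cycles).
#' @return dCT = target − reference, in cycles.
#' @export
delta_ct <- function(target_ct, reference_ct) {
  stopifnot(is.finite(target_ct), is.finite(reference_ct))
  as.numeric(target_ct) - as.numeric(reference_ct)
}

#' Relative expression from delta-CT
#'
#' @param dct delta-CT in cycles.
#' @return `2^-dct`, the target's abundance relative to the reference.
#' @export
relative_expression <- function(dct) {
  stopifnot(all(is.finite(dct)))
  2^(-dct)
}

#' Fold change between two pooled profiles
#'
#' `2^-ddCT` with `ddCT = dct_case - dct_comparator`; values above 1 mean
#' higher abundance in the case pool.
#'
#' @param dct_case,dct_comparator delta-CT values (cycles) of the same assay
#'   in the two pools.
#' @return Fold change (dimensionless, > 0).
#' @export
fold_change_pools <- function(dct_case, dct_comparator) {
  stopifnot(all(is.finite(dct_case)), all(is.finite(dct_comparator)))
  2^(-(dct_case - dct_comparator))
}

#' Normalize a CT matrix to relative expression
#'
#' Computes, for every sample, the composite reference CT, then per-target
#' dCT and relative expression `2^-dCT`. A target entry is missing (`NA`)
#' when its CT is censored or unmeasured. Samples whose reference assays are
#' all censored cannot be normalized and are dropped with a warning; samples
#' with 1-2 censored references are normalized on the remainder and flagged.
#'
#' @param x a [ct_matrix()].
#' @return An object of class `expr_matrix`: list with `expr` and `delta_ct`
#'   matrices (samples x target assays), `reference_ct` per sample,
#'   `degraded_reference` logical per sample, `dropped_samples`, and the
#'   `samples`/`assays` tables restricted to what survives.
#' @export
normalize_expression <- function(x) {
  stopifnot(inherits(x, "ct_matrix"))
  ref_ids <- x$assays$assay_id[x$assays$role == "REFERENCE"]
  if (!length(ref_ids)) stop("no REFERENCE assays in the matrix")
  tgt_ids <- x$assays$assay_id[x$assays$role == "TARGET"]
  ref_ct <- x$ct[, ref_ids, drop = FALSE]
  n_ref <- rowSums(!is.na(ref_ct))
  dropped <- x$samples$sample_id[n_ref == 0]
  if (length(dropped))
    warning(length(dropped), " sample(s) dropped: all reference assays censored (",
            paste(utils::head(dropped, 5), collapse = ", "),
            if (length(dropped) > 5) ", ..." else "", ")")
  keep <- n_ref > 0
  comp <- rowMeans(ref_ct[keep, , drop = FALSE], na.rm = TRUE)
  dct <- x$ct[keep, tgt_ids, drop = FALSE] - comp
  structure(
    list(expr = 2^(-dct), delta_ct = dct, reference_ct = comp,
         degraded_reference = (n_ref < length(ref_ids))[keep],
         dropped_samples = dropped,
         samples = x$samples[keep, , drop = FALSE],
         assays = x$assays[x$assays$role == "TARGET", , drop = FALSE]),
    class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat("<expr_matrix> ", nrow(x$expr), " samples x ", ncol(x$expr),
      " target assays (2^-dCT scale)\n", sep = "")
  if (length(x$dropped_samples))
    cat("  dropped (no usable reference):", length(x$dropped_samples), "\n")
  if (any(x$degraded_reference))
    cat("  degraded reference in", sum(x$degraded_reference), "sample(s)\n")
  invisible(x)
}

#' Pooled-screening profile from a pooled sample's CT values
#'
#' Builds the per-assay delta-CT profile of one physical pool: each target CT
#' minus the pool's internal control. The control is configurable: the mean
#' CT of the designated reference assays within the pool (default), or the
#' global mean CT over all assays.
#'
#' @param pool_ct named numeric vector of the pool's CT values per assay
#'   (`NA` = censored).
#' @param group group label of the pool.
#' @param reference_assays assay ids used as the internal control when
#'   `internal_control = "reference"`.
#' @param internal_control `"reference"` or `"global_mean"`.
#' @return Object of class `pool_profile`: data frame `assay_id`, `ct`,
#'   `delta_ct`, with the group and control CT as attributes.
#' @export
pool_profile <- function(pool_ct, group,
                         reference_assays = c("let-7d", "let-7g", "let-7i"),
                         internal_control = c("reference", "global_mean")) {
  internal_control <- match.arg(internal_control)
  group <- check_enum(group, GROUP_LEVELS, "group")
  ids <- names(pool_ct)
  if (is.null(ids)) stop("pool_ct must be a named vector")
  ctrl <- if (internal_control == "reference") {
    as.numeric(composite_reference_ct(pool_ct[ids %in% reference_assays]))
  } else {
    mean(pool_ct, na.rm = TRUE)
  }
  tgt <- ids[!(ids %in% reference_assays)]
  out <- data.frame(assay_id = tgt, ct = unname(pool_ct[tgt]),
                    delta_ct = unname(pool_ct[tgt]) - ctrl,
                    stringsAsFactors = FALSE)
  structure(out, class = c("pool_profile", "data.frame"),
            group = group, control_ct = ctrl)
}
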