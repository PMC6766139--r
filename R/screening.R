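# Array-based candidate screening on pooled serum profiles.
#
# An assay is nominated when all three criteria hold:
#   (1) raw CT in the case pool strictly below ct_cutoff (abundant enough to
#       quantify reliably in individual samples);
#   (2) fold change vs at least one comparator pool of magnitude >= fc_cutoff
#       in either direction (max(FC, 1/FC) — down-regulation counts);
#   (3) membership of a user-supplied whitelist (e.g. a literature-curated
#       set); an empty/NULL whitelist disables the criterion.

#' Screen pooled profiles for candidate miRNAs
#'
#' @param case_profile a [pool_profile()] for the case pool.
#' @param comparator_profiles list of [pool_profile()]s to compare against
#'   (fold change vs any one of them may satisfy the criterion).
#' @param ct_cutoff raw case-pool CT must be strictly below this (cycles).
#' @param fc_cutoff minimum fold-change magnitude (inclusive), >= 1.
#' @param whitelist character vector of assay ids allowed by prior evidence;
#'   `NULL` or empty disables criterion (3).
#' @return A `candidate_report` data frame, one row per screened assay:
#'   `assay_id`, `case_ct`, one `fc_vs_<GROUP>` column per comparator,
#'   `ct_pass`, `fc_pass`, `whitelist_pass`, `indeterminate`, `candidate`.
#'   An assay censored in the case pool fails the CT criterion; an assay
#'   with no finite comparator value is `indeterminate` and never a
#'   candidate.
#' @export
screen_candidates <- function(case_profile, comparator_profiles,
                              ct_cutoff = 28, fc_cutoff = 5,
                              whitelist = NULL) {
  stopifnot(inherits(case_profile, "pool_profile"), ct_cutoff > 0,
            fc_cutoff >= 1)
  if (inherits(comparator_profiles, "pool_profile"))
    comparator_profiles <- list(comparator_profiles)
  stopifnot(length(comparator_profiles) >= 1)

  ids <- case_profile$assay_id
  rep <- data.frame(assay_id = ids, case_ct = case_profile$ct,
                    stringsAsFactors = FALSE)
  fc_mag <- matrix(NA_real_, length(ids), length(comparator_profiles))
  for (k in seq_along(comparator_profiles)) {
    comp <- comparator_profiles[[k]]
    stopifnot(inherits(comp, "pool_profile"))
    m <- match(ids, comp$assay_id)
    dct_comp <- comp$delta_ct[m]
    ok <- is.finite(case_profile$delta_ct) & is.finite(dct_comp)
    fc <- rep(NA_real_, length(ids))
    fc[ok] <- fold_change_pools(case_profile$delta_ct[ok], dct_comp[ok])
    rep[[paste0("fc_vs_", attr(comp, "group"))]] <- fc
    fc_mag[, k] <- pmax(fc, 1 / fc)
  }
  rep$ct_pass <- !is.na(rep$case_ct) & rep$case_ct < ct_cutoff
  best_mag <- apply(fc_mag, 1, function(v)
    if (all(is.na(v))) NA_real_ else max(v, na.rm = TRUE))
  rep$fc_pass <- !is.na(best_mag) & best_mag >= fc_cutoff
  rep$whitelist_pass <- if (is.null(whitelist) || !length(whitelist))
    TRUE else rep$assay_id %in% whitelist
  rep$indeterminate <- is.na(best_mag)
  rep$candidate <- rep$ct_pass & rep$fc_pass & rep$whitelist_pass &
    !rep$indeterminate
  class(rep) <- c("candidate_report", "data.frame")
  rep
}

#' @export
print.candidate_report <- function(x, ...) {
  cat("<candidate_report> ", nrow(x), " assays screened, ",
      sum(x$candidate), " candidates", sep = "")
  if (any(x$indeterminate)) cat(", ", sum(x$indeterminate), " indeterminate")
  cat("\n")
  if (sum(x$candidate))
    print(as.data.frame(x)[x$candidate, ], row.names = FALSE, digits = 4)
  invisible(x)
}
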