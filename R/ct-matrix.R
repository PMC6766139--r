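#' @keywords internal
"_PACKAGE"

GROUP_LEVELS <- c("PTC", "BENIGN", "MTC", "CONTROL")
PHASE_LEVELS <- c("SCREEN_POOL", "TRAINING", "VALIDATION")

# Sentinel strings in the ct column that mean "assay did not cross threshold"
CENSORED_SENTINELS <- c("", "na", "nd", "undetermined", "undet", "censored")

#' Construct a CT matrix
#'
#' A `ct_matrix` holds raw qPCR threshold-cycle values for a set of samples
#' (rows) and assays (columns), together with sample metadata and assay roles
#' (target vs endogenous reference). Entries are either a finite CT in
#' `(0, max_cycles]` or censored (assay not detected within the run's cycle
#' limit). Censored entries are stored as `NA` in `$ct` with `$censored` set;
#' an entry that was never measured has `NA` in `$ct` and `FALSE` in
#' `$censored`.
#'
#' @param ct numeric matrix, samples x assays; `NA` for censored or absent
#'   entries. Must carry row and column names.
#' @param samples data frame with columns `sample_id`, `group`, `phase`
#'   (optionally `age`, `sex`), one row per row of `ct`.
#' @param assays data frame with columns `assay_id`, `role`
#'   (`"TARGET"`/`"REFERENCE"`), one row per column of `ct`.
#' @param censored logical matrix, same shape as `ct`: `TRUE` where the assay
#'   was run but not detected. Defaults to all `FALSE`.
#' @param n_rep integer matrix of technical-replicate counts behind each mean
#'   CT. Defaults to 1 where measured.
#' @param max_cycles run cycle limit; finite CTs above it are coerced to
#'   censored with a warning.
#' @return An object of class `ct_matrix`.
#' @seealso [read_ct_table()], [normalize_expression()]
#' @export
ct_matrix <- function(ct, samples, assays, censored = NULL, n_rep = NULL,
                      max_cycles = 40) {
  stopifnot(is.matrix(ct), is.numeric(ct))
  if (is.null(rownames(ct)) || is.null(colnames(ct)))
    stop("`ct` must have sample row names and assay column names")
  samples <- validate_samples(samples)
  assays <- validate_assays(assays)
  if (!identical(rownames(ct), samples$sample_id))
    stop("row names of `ct` must equal samples$sample_id, in order")
  if (!identical(colnames(ct), assays$assay_id))
    stop("column names of `ct` must equal assays$assay_id, in order")
  if (is.null(censored)) {
    censored <- matrix(FALSE, nrow(ct), ncol(ct), dimnames = dimnames(ct))
  }
  stopifnot(identical(dim(censored), dim(ct)))
  if (is.null(n_rep)) {
    n_rep <- matrix(1L, nrow(ct), ncol(ct), dimnames = dimnames(ct))
    n_rep[is.na(ct) & !censored] <- 0L
  }
  if (any(ct <= 0, na.rm = TRUE))
    stop("CT values must be positive")
  over <- !is.na(ct) & ct > max_cycles
  if (any(over)) {
    warning(sum(over), " CT value(s) above max_cycles = ", max_cycles,
            " coerced to censored")
    censored[over] <- TRUE
    ct[over] <- NA_real_
  }
  structure(
    list(ct = ct, censored = censored, n_rep = n_rep,
         samples = samples, assays = assays, max_cycles = max_cycles),
    class = "ct_matrix")
}

validate_samples <- function(samples) {
  samples <- as.data.frame(samples)
  need <- c("sample_id", "group", "phase")
  miss <- setdiff(need, names(samples))
  if (length(miss))
    stop("samples table missing column(s): ", paste(miss, collapse = ", "))
  samples$sample_id <- as.character(samples$sample_id)
  if (anyDuplicated(samples$sample_id))
    stop("duplicate sample_id in samples table: ",
         samples$sample_id[duplicated(samples$sample_id)][1])
  samples$group <- check_enum(samples$group, GROUP_LEVELS, "group")
  samples$phase <- check_enum(samples$phase, PHASE_LEVELS, "phase")
  if (is.null(samples$age)) samples$age <- NA_real_
  if (is.null(samples$sex)) samples$sex <- NA_character_
  rownames(samples) <- NULL
  samples
}

validate_assays <- function(assays) {
  assays <- as.data.frame(assays)
  if (!all(c("assay_id", "role") %in% names(assays)))
    stop("assays table needs columns assay_id and role")
  assays$assay_id <- as.character(assays$assay_id)
  if (anyDuplicated(assays$assay_id))
    stop("duplicate assay_id: ", assays$assay_id[duplicated(assays$assay_id)][1])
  assays$role <- check_enum(assays$role, c("TARGET", "REFERENCE"), "role")
  rownames(assays) <- NULL
  assays
}

check_enum <- function(x, levels, what) {
  x <- toupper(as.character(x))
  bad <- setdiff(unique(x), levels)
  if (length(bad))
    stop("unknown ", what, " label(s): ", paste(bad, collapse = ", "),
         " (allowed: ", paste(levels, collapse = ", "), ")")
  x
}

#' @export
print.ct_matrix <- function(x, ...) {
  cat("<ct_matrix> ", nrow(x$ct), " samples x ", ncol(x$ct), " assays\n", sep = "")
  cat("  references:",
      paste(x$assays$assay_id[x$assays$role == "REFERENCE"], collapse = ", "), "\n")
  cat("  groups:    ",
      paste(sprintf("%s=%d", names(table(x$samples$group)),
                    table(x$samples$group)), collapse = " "), "\n")
  n_cens <- sum(x$censored)
  cat("  measured entries: ", sum(!is.na(x$ct)), " finite, ", n_cens,
      " censored (max_cycles = ", x$max_cycles, ")\n", sep = "")
  invisible(x)
}

#' Read a long-format CT table
#'
#' Reads a CSV with one row per sample/assay/replicate and the header
#' `sample_id,group,phase,assay_id,replicate,ct`. Technical replicates of the
#' same (sample, assay) are collapsed by the arithmetic mean of their CT
#' values. Non-numeric or sentinel ct cells (empty, `"Undetermined"`, `"NA"`,
#' `"ND"`, `"Censored"`) become censored entries; a (sample, assay) entry is
#' censored only if all its replicates are.
#'
#' @param path CSV file path.
#' @param reference_assays character vector of assay ids to mark as
#'   endogenous references (default the let-7d/g/i composite).
#' @param max_cycles cycle limit passed to [ct_matrix()].
#' @param schema named character vector mapping the required logical columns
#'   (`sample_id`, `group`, `phase`, `assay_id`, `replicate`, `ct`) to the
#'   file's column names, for files with non-default headers.
#' @return A [ct_matrix()].
#' @export
read_ct_table <- function(path, reference_assays = c("let-7d", "let-7g", "let-7i"),
                          max_cycles = 40, schema = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  default <- c(sample_id = "sample_id", group = "group", phase = "phase",
               assay_id = "assay_id", replicate = "replicate", ct = "ct")
  if (!is.null(schema)) default[names(schema)] <- schema
  miss <- setdiff(unname(default[c("sample_id", "group", "assay_id", "ct")]),
                  names(raw))
  if (length(miss))
    stop("missing required column(s): ", paste(miss, collapse = ", "))
  df <- data.frame(
    sample_id = raw[[default[["sample_id"]]]],
    group = raw[[default[["group"]]]],
    phase = if (default[["phase"]] %in% names(raw))
      raw[[default[["phase"]]]] else "TRAINING",
    assay_id = raw[[default[["assay_id"]]]],
    replicate = if (default[["replicate"]] %in% names(raw))
      raw[[default[["replicate"]]]] else "1",
    ct_raw = raw[[default[["ct"]]]],
    stringsAsFactors = FALSE)

  key <- paste(df$sample_id, df$assay_id, df$replicate, sep = "\r")
  if (anyDuplicated(key)) {
    i <- which(duplicated(key))[1]
    stop("duplicate (sample, assay, replicate) row at line ", i + 1L, ": ",
         df$sample_id[i], " / ", df$assay_id[i], " / rep ", df$replicate[i])
  }
  bad_group <- !(toupper(df$group) %in% GROUP_LEVELS)
  if (any(bad_group)) {
    i <- which(bad_group)[1]
    stop("unknown group label '", df$group[i], "' at line ", i + 1L,
         " (sample ", df$sample_id[i], ")")
  }

  ct_num <- suppressWarnings(as.numeric(df$ct_raw))
  sentinel <- tolower(trimws(df$ct_raw)) %in% CENSORED_SENTINELS
  if (any(is.na(ct_num) & !sentinel))
    stop("unparseable ct value '",
         df$ct_raw[which(is.na(ct_num) & !sentinel)[1]], "'")
  df$ct <- ct_num

  samples <- unique(df[, c("sample_id", "group", "phase")])
  if (anyDuplicated(samples$sample_id))
    stop("sample ", samples$sample_id[duplicated(samples$sample_id)][1],
         " appears with inconsistent group/phase labels")
  assay_ids <- unique(df$assay_id)
  assays <- data.frame(
    assay_id = assay_ids,
    role = ifelse(assay_ids %in% reference_assays, "REFERENCE", "TARGET"),
    stringsAsFactors = FALSE)

  dn <- list(samples$sample_id, assay_ids)
  ct <- matrix(NA_real_, nrow(samples), length(assay_ids), dimnames = dn)
  cens <- matrix(FALSE, nrow(samples), length(assay_ids), dimnames = dn)
  n_rep <- matrix(0L, nrow(samples), length(assay_ids), dimnames = dn)
  # collapse replicates: mean of finite CTs; censored iff measured and none finite
  grp <- split(seq_len(nrow(df)), paste(df$sample_id, df$assay_id, sep = "\r"))
  for (idx in grp) {
    s <- df$sample_id[idx[1]]; a <- df$assay_id[idx[1]]
    finite <- df$ct[idx][!is.na(df$ct[idx])]
    n_rep[s, a] <- length(idx)
    if (length(finite)) ct[s, a] <- mean(finite) else cens[s, a] <- TRUE
  }
  ct_matrix(ct, samples, assays, censored = cens, n_rep = n_rep,
            max_cycles = max_cycles)
}

#' Write a CT matrix as a long-format CSV
#'
#' Inverse of [read_ct_table()] for collapsed matrices: one row per measured
#' (sample, assay) entry; censored entries are written with ct
#' `"Undetermined"`. Finite CTs are written with full precision so that a
#' write/read round trip reproduces them bit-exactly.
#'
#' @param x a [ct_matrix()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_ct_table <- function(x, path) {
  stopifnot(inherits(x, "ct_matrix"))
  measured <- which(!is.na(x$ct) | x$censored, arr.ind = TRUE)
  measured <- measured[order(measured[, 1], measured[, 2]), , drop = FALSE]
  s <- x$samples[measured[, 1], ]
  ct_chr <- ifelse(is.na(x$ct[measured]), "Undetermined",
                   sprintf("%.17g", x$ct[measured]))
  out <- data.frame(
    sample_id = s$sample_id, group = s$group, phase = s$phase,
    assay_id = x$assays$assay_id[measured[, 2]],
    replicate = 1L, ct = ct_chr, stringsAsFactors = FALSE)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Describe a study design
#'
#' @param group_sizes named integer vector of expected per-group sample
#'   counts (names from `PTC`, `BENIGN`, `MTC`, `CONTROL`).
#' @param comparisons list of length-2 character vectors naming group pairs
#'   to be compared.
#' @param pools optional named list of sample-id vectors, one per screening
#'   pool.
#' @return An object of class `study_design`.
#' @export
study_design <- function(group_sizes = NULL, comparisons = list(), pools = NULL) {
  if (!is.null(group_sizes)) {
    bad <- setdiff(names(group_sizes), GROUP_LEVELS)
    if (length(bad)) stop("unknown group(s) in group_sizes: ",
                          paste(bad, collapse = ", "))
  }
  for (cmp in comparisons) {
    if (length(cmp) != 2 || cmp[1] == cmp[2])
      stop("each comparison must name two distinct groups")
  }
  structure(list(group_sizes = group_sizes, comparisons = comparisons,
                 pools = pools), class = "study_design")
}

#' Validate a CT matrix against a study design
#'
#' Report-only check run before normalization: flags samples missing some or
#' all reference assays, group-size mismatches against the design, and
#' comparisons with an empty group. A sample lacking every reference assay
#' cannot be normalized and is marked fatal; downstream steps refuse to
#' proceed while fatal flags are present (the caller decides whether to drop
#' the samples and continue).
#'
#' @param x a [ct_matrix()].
#' @param design optional [study_design()].
#' @return A list of class `design_validation` with elements
#'   `degraded_reference` (data frame: sample, available reference count),
#'   `fatal_samples` (character), `group_size_mismatch` (data frame),
#'   `empty_comparisons` (list), and `ok` (logical: no fatal findings).
#' @export
validate_design <- function(x, design = NULL) {
  stopifnot(inherits(x, "ct_matrix"))
  ref_ids <- x$assays$assay_id[x$assays$role == "REFERENCE"]
  ref_ct <- x$ct[, ref_ids, drop = FALSE]
  n_ref <- rowSums(!is.na(ref_ct))
  degraded <- data.frame(
    sample_id = x$samples$sample_id[n_ref > 0 & n_ref < length(ref_ids)],
    n_reference = n_ref[n_ref > 0 & n_ref < length(ref_ids)],
    stringsAsFactors = FALSE)
  fatal <- x$samples$sample_id[n_ref == 0]

  mism <- data.frame(group = character(), expected = integer(),
                     observed = integer(), stringsAsFactors = FALSE)
  empty_cmp <- list()
  if (!is.null(design)) {
    obs <- table(factor(x$samples$group, levels = GROUP_LEVELS))
    if (!is.null(design$group_sizes)) {
      for (g in names(design$group_sizes)) {
        if (obs[[g]] != design$group_sizes[[g]])
          mism <- rbind(mism, data.frame(group = g,
                                         expected = design$group_sizes[[g]],
                                         observed = obs[[g]]))
      }
    }
    for (cmp in design$comparisons) {
      if (any(obs[cmp] == 0)) empty_cmp <- c(empty_cmp, list(cmp))
    }
  }
  res <- list(degraded_reference = degraded, fatal_samples = fatal,
              group_size_mismatch = mism, empty_comparisons = empty_cmp,
              ok = length(fatal) == 0 && nrow(mism) == 0 &&
                length(empty_cmp) == 0)
  class(res) <- "design_validation"
  res
}

#' @export
print.design_validation <- function(x, ...) {
  cat("<design_validation>", if (x$ok) "OK" else "FINDINGS", "\n")
  if (nrow(x$degraded_reference)) {
    cat(" degraded references (sample retained):\n")
    for (i in seq_len(nrow(x$degraded_reference)))
      cat("  -", x$degraded_reference$sample_id[i], "has",
          x$degraded_reference$n_reference[i], "of the reference assays\n")
  }
  if (length(x$fatal_samples))
    cat(" FATAL: no reference assay detected for:",
        paste(x$fatal_samples, collapse = ", "), "\n")
  if (nrow(x$group_size_mismatch)) {
    cat(" group size mismatches:\n")
    print(x$group_size_mismatch, row.names = FALSE)
  }
  if (length(x$empty_comparisons))
    cat(" empty comparisons:",
        paste(vapply(x$empty_comparisons, paste, "", collapse = " vs "),
              collapse = "; "), "\n")
  invisible(x)
}
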