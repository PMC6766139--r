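# Fixtures are built in code: tiny CT tables and matrices with known
# structure, plus a compact simulation configuration for fast Monte Carlo.

# long-format CT CSV written to a temp file; rows = character vector of
# "sample,group,phase,assay,replicate,ct" lines
write_ct_csv <- function(rows) {
  path <- tempfile(fileext = ".csv")
  writeLines(c("sample_id,group,phase,assay_id,replicate,ct", rows), path)
  path
}

# minimal ct_matrix: one sample per row of `ct`, references + targets
make_ct_matrix <- function(ct, groups = rep("CONTROL", nrow(ct)),
                           phases = rep("TRAINING", nrow(ct)),
                           reference = grep("^let", colnames(ct), value = TRUE),
                           max_cycles = 40) {
  samples <- data.frame(sample_id = rownames(ct), group = groups,
                        phase = phases)
  assays <- data.frame(
    assay_id = colnames(ct),
    role = ifelse(colnames(ct) %in% reference, "REFERENCE", "TARGET"))
  ct_matrix(ct, samples, assays, max_cycles = max_cycles)
}

# small simulation config: a few planted assays over three groups, used
# where the full shipped configuration would be needlessly slow
small_config <- function(fc_ptc = c(4, 1/4, 1, 1, 1),
                         control_mean = c(0.5, 1, 0.25, 1, 2),
                         cv = 0.3, tech_sd = 0.1, ref_ct_sd = 1,
                         n = c(PTC = 20, BENIGN = 20, MTC = 0, CONTROL = 20),
                         screen_universe = 0, ...) {
  k <- length(control_mean)
  a <- data.frame(assay_id = sprintf("miR-t%02d", seq_len(k)),
                  mean_CONTROL = control_mean, cv_CONTROL = cv,
                  mean_PTC = control_mean * fc_ptc, cv_PTC = cv,
                  mean_BENIGN = control_mean, cv_BENIGN = cv,
                  mean_MTC = control_mean, cv_MTC = cv)
  half <- function(x) { h <- floor(x / 2); c(PTC = unname(h[["PTC"]]),
                                             BENIGN = unname(h[["BENIGN"]]),
                                             CONTROL = unname(h[["CONTROL"]])) }
  tr <- half(n)
  va <- c(PTC = unname(n[["PTC"]]) - tr[["PTC"]],
          BENIGN = unname(n[["BENIGN"]]) - tr[["BENIGN"]],
          CONTROL = unname(n[["CONTROL"]]) - tr[["CONTROL"]])
  sim_config(a, group_sizes = n, training = tr, validation = va,
             tech_sd = tech_sd, ref_ct_sd = ref_ct_sd,
             screen_universe = screen_universe,
             mtc_subset_size = min(5, n[["BENIGN"]], n[["CONTROL"]]), ...)
}

subset_expr_for_test <- function(e, ids) sermir:::subset_expr(e, ids)

# brute-force pairwise concordance AUC (independent oracle)
auc_brute <- function(scores, y) {
  x <- scores[y == 1]; z <- scores[y == 0]
  tot <- 0
  for (xi in x) for (zj in z)
    tot <- tot + if (xi > zj) 1 else if (xi == zj) 0.5 else 0
  tot / (length(x) * length(z))
}
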