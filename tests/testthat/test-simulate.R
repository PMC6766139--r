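test_that("the shipped configuration encodes the study design", {
  cfg <- default_paper_config()
  expect_equal(unname(cfg$group_sizes),
               c(100, 91, 15, 89))
  expect_equal(unname(cfg$training[c("PTC", "BENIGN", "CONTROL")]),
               c(36, 36, 32))
  expect_equal(unname(cfg$validation[c("PTC", "BENIGN", "CONTROL")]),
               c(64, 55, 57))
  a <- cfg$assays
  expect_equal(a$mean_CONTROL[a$assay_id == "miR-222-3p"], 0.290)
  expect_equal(a$mean_PTC[a$assay_id == "miR-222-3p"], 0.415)
  expect_equal(a$mean_MTC[a$assay_id == "miR-222-3p"], 0.731)
  expect_equal(a$mean_MTC[a$assay_id == "miR-17-5p"], 2.719)
  # null variant zeroes every effect
  nul <- default_paper_config(null = TRUE)
  for (g in c("PTC", "BENIGN", "MTC"))
    expect_equal(nul$assays[[paste0("mean_", g)]], nul$assays$mean_CONTROL)
})

test_that("invalid configurations are rejected naming the field", {
  cfg <- default_paper_config()
  bad <- cfg$assays; bad$mean_PTC[1] <- -1
  expect_error(sim_config(bad, cfg$group_sizes, cfg$training,
                          cfg$validation), "mean_PTC")
  expect_error(sim_config(cfg$assays, cfg$group_sizes,
                          training = c(PTC = 10, BENIGN = 36, CONTROL = 32),
                          validation = cfg$validation), "split")
  expect_error(sim_config(cfg$assays, cfg$group_sizes, cfg$training,
                          cfg$validation, tech_sd = -1), "tech_sd")
})

test_that("identical config and seed give bit-identical cohorts and
           byte-identical CSVs", {
  cfg <- small_config()
  a <- simulate_cohort(cfg, seed = 101)
  b <- simulate_cohort(cfg, seed = 101)
  expect_identical(a$ct$ct, b$ct$ct)
  expect_identical(a$ct$censored, b$ct$censored)
  expect_identical(a$truth, b$truth)
  fa <- tempfile(fileext = ".csv"); fb <- tempfile(fileext = ".csv")
  write_ct_table(a$ct, fa); write_ct_table(b$ct, fb)
  expect_identical(readLines(fa), readLines(fb))
  c2 <- simulate_cohort(cfg, seed = 102)
  expect_false(identical(a$ct$ct, c2$ct$ct))
})

test_that("in the noise-free limit the pipeline recovers planted fold
           changes exactly", {
  cfg <- small_config(fc_ptc = c(4, 1/4, 1, 2, 1), cv = 0,
                      tech_sd = 0, ref_ct_sd = 0)
  co <- simulate_cohort(cfg, seed = 1)
  e <- normalize_expression(co$ct)
  g <- e$samples$group
  # planted 4-fold up: every case dCT exactly 2 cycles below control
  d_ptc <- e$delta_ct[g == "PTC", 1]
  d_ctl <- e$delta_ct[g == "CONTROL", 1]
  expect_equal(unique(round(d_ctl - d_ptc[1], 12)), 2)
  for (j in seq_len(ncol(e$expr))) {
    fc_hat <- mean(e$expr[g == "PTC", j]) / mean(e$expr[g == "CONTROL", j])
    fc_true <- cfg$assays$mean_PTC[j] / cfg$assays$mean_CONTROL[j]
    expect_equal(fc_hat, fc_true, tolerance = 1e-12)
  }
})

test_that("generated group means converge to the configured means", {
  cfg <- small_config(n = c(PTC = 5000, BENIGN = 0, MTC = 0, CONTROL = 5000),
                      cv = 0.5)
  co <- simulate_cohort(cfg, seed = 7)
  e <- normalize_expression(co$ct)
  g <- e$samples$group
  for (j in seq_len(ncol(e$expr))) {
    expect_equal(mean(e$expr[g == "PTC", j]), cfg$assays$mean_PTC[j],
                 tolerance = 0.02)
    expect_equal(mean(e$expr[g == "CONTROL", j]), cfg$assays$mean_CONTROL[j],
                 tolerance = 0.02)
  }
})

test_that("shipped-config cohorts reproduce the configured panel means
           within Monte Carlo error", {
  cfg <- default_paper_config()
  co <- simulate_cohort(cfg, seed = 11)
  e <- normalize_expression(co$ct)
  s <- summarize_groups(e)
  for (g in c("PTC", "CONTROL")) {
    row <- s[s$assay_id == "miR-222-3p" & s$group == g, ]
    expect_lt(abs(row$mean - cfg$assays[[paste0("mean_", g)]][
      cfg$assays$assay_id == "miR-222-3p"]), 3 * row$sem)
  }
})

test_that("low-abundance decoys trip the Cq filter and references are
           always present", {
  co <- simulate_cohort(default_paper_config(), seed = 13)
  f <- low_expression_filter(co$ct)
  expect_true(all(c("miR-151-3p", "miR-19b-3p") %in% f$excluded))
  expect_true(all(c("miR-222-3p", "miR-17-5p") %in% f$retained))
  v <- validate_design(co$ct)
  expect_length(v$fatal_samples, 0)
})

test_that("pooling averages linear abundance and respects determinism", {
  # zero noise: pool dCT equals the common member dCT
  cfg0 <- small_config(cv = 0, tech_sd = 0, ref_ct_sd = 0)
  p0 <- simulate_pools(cfg0, seed = 3)
  expect_equal(p0$CONTROL$delta_ct,
               -log2(cfg0$assays$mean_CONTROL), tolerance = 1e-9)
  expect_error(simulate_pools(cfg0, pool_size = 0), "pool size")

  p1 <- simulate_pools(cfg0, seed = 3)
  expect_identical(as.data.frame(p0$PTC), as.data.frame(p1$PTC))
})

test_that("a planted 5-fold miRNA yields pool fold changes near 5 across
           seeds", {
  cfg <- small_config(fc_ptc = c(5, 1, 1, 1, 1), cv = 0.15, tech_sd = 0.02)
  fc <- numeric(200)
  for (s in 1:200) {
    pools <- simulate_pools(cfg, seed = s)
    fc[s] <- fold_change_pools(pools$PTC$delta_ct[1],
                               pools$CONTROL$delta_ct[1])
  }
  expect_true(all(fc > 4 & fc < 6))
  expect_equal(median(fc), 5, tolerance = 0.1)
})
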