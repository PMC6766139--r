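# helper: pool_profile with references at CT 26, so a target with delta-CT
# d sits at raw pool CT 26 + d
profile_from <- function(dct, group) {
  ct <- c(dct + 26, "let-7d" = 26, "let-7g" = 26, "let-7i" = 26)
  pool_profile(ct, group)
}

test_that("the CT criterion is strict and the fold-change criterion is
           inclusive, two-sided, and 'or' across comparators", {
  # case dCT = 2 puts the raw case-pool CT exactly at 28; comparator dCTs
  # two cycles apart give an exactly representable 4-fold change
  case28 <- profile_from(c("miR-a" = 2), "PTC")
  ben <- profile_from(c("miR-a" = 4), "BENIGN")
  ctl <- profile_from(c("miR-a" = 2 + log2(1.2)), "CONTROL")

  r <- screen_candidates(case28, list(ben, ctl), ct_cutoff = 28,
                         fc_cutoff = 4)
  expect_equal(r$case_ct, 28)
  expect_false(r$ct_pass)  # strict "<"
  expect_equal(r$fc_vs_BENIGN, 4)
  expect_equal(r$fc_vs_CONTROL, 1.2, tolerance = 1e-12)
  expect_true(r$fc_pass)   # 4-fold vs benign at cutoff 4: inclusive, "or"
  expect_false(r$candidate)

  case27 <- profile_from(c("miR-a" = 1.5), "PTC")
  r2 <- screen_candidates(case27, list(ben, ctl), ct_cutoff = 28,
                          fc_cutoff = 4)
  expect_true(r2$ct_pass)
  expect_true(r2$fc_pass)
  expect_true(r2$candidate)  # empty whitelist disables criterion (3)

  # 4-fold DOWN also passes at cutoff 4: max(FC, 1/FC) >= cutoff
  dn <- profile_from(c("miR-a" = 2), "PTC")
  r3 <- screen_candidates(dn, list(profile_from(c("miR-a" = 0), "CONTROL")),
                          fc_cutoff = 4)
  expect_equal(r3$fc_vs_CONTROL, 0.25)
  expect_true(r3$fc_pass)

  # 4.9-fold fails the inclusive >= 5 rule
  weak <- profile_from(c("miR-a" = -log2(4.9)), "PTC")
  r4 <- screen_candidates(weak, list(profile_from(c("miR-a" = 0), "CONTROL")))
  expect_false(r4$fc_pass)
})

test_that("a whitelist gates candidacy only when supplied", {
  case <- profile_from(c("miR-a" = -3, "miR-b" = -3), "PTC")
  comp <- profile_from(c("miR-a" = 0, "miR-b" = 0), "CONTROL")
  r <- screen_candidates(case, list(comp), whitelist = "miR-a")
  expect_identical(r$candidate, c(TRUE, FALSE))
  expect_identical(r$whitelist_pass, c(TRUE, FALSE))
  r2 <- screen_candidates(case, list(comp), whitelist = NULL)
  expect_identical(r2$candidate, c(TRUE, TRUE))
})

test_that("assays absent from every comparator are indeterminate, never
           candidates", {
  case <- profile_from(c("miR-a" = -3, "miR-b" = -3), "PTC")
  comp <- profile_from(c("miR-a" = 0), "CONTROL")
  r <- screen_candidates(case, list(comp))
  expect_true(r$indeterminate[r$assay_id == "miR-b"])
  expect_false(r$candidate[r$assay_id == "miR-b"])
  expect_true(r$candidate[r$assay_id == "miR-a"])
})

test_that("candidacy is monotone in the cutoffs", {
  set.seed(21)
  for (i in 1:25) {
    k <- 12
    dct <- stats::setNames(runif(k, -6, 6), sprintf("m%02d", 1:k))
    case <- profile_from(dct, "PTC")
    comp <- profile_from(stats::setNames(runif(k, -2, 2), names(dct)),
                         "CONTROL")
    strict <- screen_candidates(case, list(comp), ct_cutoff = 27,
                                fc_cutoff = 4)
    looser_fc <- screen_candidates(case, list(comp), ct_cutoff = 27,
                                   fc_cutoff = 2)
    looser_ct <- screen_candidates(case, list(comp), ct_cutoff = 31,
                                   fc_cutoff = 4)
    expect_true(all(looser_fc$candidate[strict$candidate]))
    expect_true(all(looser_ct$candidate[strict$candidate]))
  }
})

test_that("planted large-fold-change assays are recovered from simulated
           pools and null assays are not nominated", {
  # 5 planted at 8-fold (|log2 FC| = 3 >= log2(5) + 3 * pool noise sd),
  # abundant enough to sit far below the CT cutoff; 15 null assays
  cfg <- small_config(
    fc_ptc = c(8, 8, 1/8, 1/8, 8, rep(1, 15)),
    control_mean = c(2, 2, 16, 16, 2, rep(2, 15)),
    cv = 0.3, tech_sd = 0.05)
  planted <- cfg$assays$assay_id[1:5]
  nulls <- cfg$assays$assay_id[-(1:5)]
  hit <- logical(200); clean <- logical(200)
  for (s in 1:200) {
    pools <- simulate_pools(cfg, seed = s)
    r <- screen_candidates(pools$PTC, list(pools$CONTROL))
    hit[s] <- all(planted %in% r$assay_id[r$candidate])
    clean[s] <- !any(nulls %in% r$assay_id[r$candidate])
  }
  expect_gte(mean(hit & clean), 0.95)
})
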