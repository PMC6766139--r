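# CT-level simulator for serum-miRNA case-control studies.
#
# Generative model (per sample i, assay j, group g):
#   base_i      ~ N(0, ref_ct_sd)                 global input-amount shift
#   refCT_ik    = ref_ct_mean + base_i + e_tech   (k = the 3 reference assays)
#   dCT_ij      = mu_jg + e_bio,  e_bio ~ N(0, bio_sd_jg)
#   CT_ij       = ref_ct_mean + base_i + dCT_ij + e_tech
# with mu_jg chosen so the arithmetic mean of the observed 2^-dCT equals the
# configured group mean: expression is lognormal, so
#   mu_jg = -log2(mean_jg) + (ln 2 / 2) * sigma_tot^2,
# where sigma_tot^2 = bio_sd^2 + tech_sd^2 * (1 + 1/3) is the variance of
# the observed dCT (target technical noise plus the averaged reference
# noise). bio_sd is back-solved from the configured coefficient of
# variation: sigma_tot^2 = log(1 + cv^2) / ln(2)^2. CTs above the censoring
# cutoff are not detected. base_i cancels in dCT, so normalization is
# input-shift invariant by construction.

SIM_GROUPS <- c("PTC", "BENIGN", "MTC", "CONTROL")

#' Simulation configuration
#'
#' Validates and assembles the full parameter set of the CT-level study
#' generator. See [default_paper_config()] for the shipped defaults.
#'
#' @param assays data frame with `assay_id` and per-group `mean_<GROUP>` and
#'   `cv_<GROUP>` columns (groups `PTC`, `BENIGN`, `MTC`, `CONTROL`): the
#'   arithmetic-mean relative expression (2^-dCT units) and its
#'   coefficient of variation in each group.
#' @param group_sizes named integer vector over the four groups.
#' @param training,validation named integer vectors giving the
#'   training/validation split of the `PTC`, `BENIGN` and `CONTROL` groups
#'   (must sum to `group_sizes`; `MTC` samples all sit in their own arm).
#' @param reference_assays ids of the endogenous-control assays.
#' @param ref_ct_mean,ref_ct_sd mean and between-sample SD (cycles) of the
#'   reference CT level (serum input-amount variation).
#' @param tech_sd per-well technical noise SD (cycles).
#' @param max_cycles run cycle limit; also the default censoring cutoff.
#' @param censor_cutoff CTs above this are not detected (censored).
#' @param pool_size samples per screening pool.
#' @param screen_universe total assay count on the screening array; the
#'   configured assays are padded with deterministic null fillers up to
#'   this size for pooled screening.
#' @param mtc_subset_size size of the matched benign/control subsets in the
#'   aggressive-carcinoma arm.
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(assays, group_sizes, training, validation,
                       reference_assays = c("let-7d", "let-7g", "let-7i"),
                       ref_ct_mean = 26, ref_ct_sd = 1.5, tech_sd = 0.15,
                       max_cycles = 40, censor_cutoff = max_cycles,
                       pool_size = 20, screen_universe = 756,
                       mtc_subset_size = 15) {
  assays <- as.data.frame(assays)
  need <- c("assay_id", paste0("mean_", SIM_GROUPS), paste0("cv_", SIM_GROUPS))
  miss <- setdiff(need, names(assays))
  if (length(miss))
    stop("assays table missing column(s): ", paste(miss, collapse = ", "))
  for (g in SIM_GROUPS) {
    if (any(assays[[paste0("mean_", g)]] <= 0))
      stop("field mean_", g, ": group means must be > 0")
    if (any(assays[[paste0("cv_", g)]] < 0))
      stop("field cv_", g, ": CVs must be >= 0")
  }
  if (anyDuplicated(assays$assay_id)) stop("field assay_id: duplicates")
  gs <- group_sizes[SIM_GROUPS]
  if (any(is.na(gs)) || any(gs < 0))
    stop("field group_sizes: need nonnegative sizes for ",
         paste(SIM_GROUPS, collapse = ", "))
  for (g in c("PTC", "BENIGN", "CONTROL")) {
    if (training[[g]] + validation[[g]] != gs[[g]])
      stop("field training/validation: split for ", g,
           " does not sum to its group size")
  }
  if (ref_ct_sd < 0 || tech_sd < 0)
    stop("field ref_ct_sd/tech_sd: SDs must be >= 0")
  if (pool_size < 1) stop("field pool_size: must be >= 1")
  if (mtc_subset_size > gs[["BENIGN"]] || mtc_subset_size > gs[["CONTROL"]])
    stop("field mtc_subset_size: exceeds a group size")
  structure(list(
    assays = assays, group_sizes = gs, training = training,
    validation = validation, reference_assays = reference_assays,
    ref_ct_mean = ref_ct_mean, ref_ct_sd = ref_ct_sd, tech_sd = tech_sd,
    max_cycles = max_cycles, censor_cutoff = censor_cutoff,
    pool_size = pool_size, screen_universe = screen_universe,
    mtc_subset_size = mtc_subset_size), class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config> ", nrow(x$assays), " target assays, groups ",
      paste(sprintf("%s=%d", names(x$group_sizes), x$group_sizes),
            collapse = " "), "\n", sep = "")
  cat("  reference:", paste(x$reference_assays, collapse = "/"),
      sprintf("CT ~ N(%.3g, %.3g), tech SD %.3g, censor > %.3g cycles\n",
              x$ref_ct_mean, x$ref_ct_sd, x$tech_sd, x$censor_cutoff))
  invisible(x)
}

#' Shipped study configuration
#'
#' The generator's default conditions: four-group design (PTC 100, benign
#' 91, MTC 15, control 89) with training split 36/36/32 and validation
#' 64/55/57; six panel miRNAs at the reported validation-set group means
#' with CVs derived from the reported SEMs (CV = SEM * sqrt(n) / mean); two
#' low-abundance decoy assays that exercise the Cq > 35 exclusion rule; and
#' 23 null filler targets (31 quantified targets in all, the size of a
#' typical screened candidate set). MTC means for the three miRNAs assayed
#' in that arm come from the MTC comparison table; the remaining panel
#' miRNAs keep their benign-group distribution there.
#'
#' @param null if `TRUE`, every group's mean is set to the control mean
#'   (all fold changes 1) — the null study used for type-I calibration.
#' @return A [sim_config()].
#' @export
default_paper_config <- function(null = FALSE) {
  n_val <- c(PTC = 64, BENIGN = 55, CONTROL = 57)
  panel <- data.frame(
    assay_id = c("miR-222-3p", "miR-17-5p", "miR-451a",
                 "miR-146a-5p", "miR-132-3p", "miR-183-3p"),
    mean_PTC = c(0.415, 1.590, 0.964, 1.627, 1.442, 0.527),
    sem_PTC = c(0.030, 0.139, 0.060, 0.082, 0.067, 0.042),
    mean_BENIGN = c(0.390, 1.771, 0.862, 1.816, 1.566, 0.500),
    sem_BENIGN = c(0.026, 0.159, 0.045, 0.094, 0.086, 0.033),
    mean_CONTROL = c(0.290, 1.152, 0.639, 2.065, 2.052, 0.733),
    sem_CONTROL = c(0.020, 0.086, 0.030, 0.113, 0.104, 0.035))
  for (g in c("PTC", "BENIGN", "CONTROL"))
    panel[[paste0("cv_", g)]] <-
      panel[[paste0("sem_", g)]] * sqrt(n_val[[g]]) / panel[[paste0("mean_", g)]]
  # MTC arm: three assayed miRNAs (n = 15 per group in that comparison)
  mtc_mean <- c("miR-222-3p" = 0.731, "miR-17-5p" = 2.719, "miR-451a" = 0.803)
  mtc_sem <- c("miR-222-3p" = 0.035, "miR-17-5p" = 0.184, "miR-451a" = 0.028)
  panel$mean_MTC <- panel$mean_BENIGN
  panel$cv_MTC <- panel$cv_BENIGN
  i <- match(names(mtc_mean), panel$assay_id)
  panel$mean_MTC[i] <- mtc_mean
  panel$cv_MTC[i] <- mtc_sem * sqrt(15) / mtc_mean
  panel$sem_PTC <- panel$sem_BENIGN <- panel$sem_CONTROL <- NULL

  decoys <- data.frame(assay_id = c("miR-151-3p", "miR-19b-3p"),
                       mean_CONTROL = 5e-4, cv_CONTROL = 0.5)
  nulls <- data.frame(
    assay_id = sprintf("miR-null-%02d", 1:23),
    mean_CONTROL = 2^seq(-4, 2, length.out = 23), cv_CONTROL = 0.5)
  extra <- rbind(decoys, nulls)
  for (g in c("PTC", "BENIGN", "MTC")) {
    extra[[paste0("mean_", g)]] <- extra$mean_CONTROL
    extra[[paste0("cv_", g)]] <- extra$cv_CONTROL
  }
  assays <- rbind(panel[names(panel)], extra[names(panel)])
  if (null) {
    for (g in c("PTC", "BENIGN", "MTC")) {
      assays[[paste0("mean_", g)]] <- assays$mean_CONTROL
      assays[[paste0("cv_", g)]] <- assays$cv_CONTROL
    }
  }
  sim_config(assays,
             group_sizes = c(PTC = 100, BENIGN = 91, MTC = 15, CONTROL = 89),
             training = c(PTC = 36, BENIGN = 36, CONTROL = 32),
             validation = c(PTC = 64, BENIGN = 55, CONTROL = 57))
}

#' Reduced configuration for the aggressive-carcinoma (MTC) arm
#'
#' The MTC comparison conditions on their own: 15 MTC, 15 benign, 15
#' control samples and the three up-regulated miRNAs assayed in that arm,
#' at the matched-subset group means and SEM-derived CVs reported for it
#' (n = 15 per group). Useful for studying the MTC-arm ROC behaviour in
#' isolation from the main cohort.
#'
#' @return A [sim_config()] with groups `MTC = 15`, `BENIGN = 15`,
#'   `CONTROL = 15` (no PTC samples).
#' @export
mtc_arm_config <- function() {
  a <- data.frame(
    assay_id = c("miR-222-3p", "miR-17-5p", "miR-451a"),
    mean_MTC = c(0.731, 2.719, 0.803),
    sem_MTC = c(0.035, 0.184, 0.028),
    mean_BENIGN = c(0.376, 1.669, 0.836),
    sem_BENIGN = c(0.066, 0.322, 0.043),
    mean_CONTROL = c(0.253, 1.079, 0.629),
    sem_CONTROL = c(0.028, 0.163, 0.059))
  for (g in c("MTC", "BENIGN", "CONTROL")) {
    a[[paste0("cv_", g)]] <-
      a[[paste0("sem_", g)]] * sqrt(15) / a[[paste0("mean_", g)]]
    a[[paste0("sem_", g)]] <- NULL
  }
  a$mean_PTC <- a$mean_BENIGN
  a$cv_PTC <- a$cv_BENIGN
  sim_config(a,
             group_sizes = c(PTC = 0, BENIGN = 15, MTC = 15, CONTROL = 15),
             training = c(PTC = 0, BENIGN = 0, CONTROL = 0),
             validation = c(PTC = 0, BENIGN = 15, CONTROL = 15),
             screen_universe = 0, mtc_subset_size = 15)
}

# dCT mean and SD (cycles) for assay row `j` of config in group `g`,
# including the lognormal mean correction described at the top of the file.
dct_params <- function(config, g) {
  m <- config$assays[[paste0("mean_", g)]]
  cv <- config$assays[[paste0("cv_", g)]]
  sigma_tot2 <- log(1 + cv^2) / log(2)^2
  tech_part <- config$tech_sd^2 * (1 + 1 / 3)
  bio_sd <- sqrt(pmax(sigma_tot2 - tech_part, 0))
  sigma_act2 <- bio_sd^2 + tech_part
  list(mu = -log2(m) + log(2) / 2 * sigma_act2, bio_sd = bio_sd)
}

#' Simulate an individual-sample CT cohort
#'
#' Draws the full four-group cohort at the configured effect sizes and
#' noise levels, with training/validation phase labels, matched-subset
#' demographics, and detection-limit censoring. The same `seed` reproduces
#' the matrix bit-identically.
#'
#' @param config a [sim_config()].
#' @param seed integer seed; `NULL` uses the current RNG state.
#' @return List with `ct` (a [ct_matrix()]) and `truth`, the generative
#'   ground truth per assay and group (`true_mean`, `true_delta_ct`,
#'   `fc_vs_control`, `direction`).
#' @export
simulate_cohort <- function(config, seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(seed)) set.seed(seed)
  gs <- config$group_sizes
  groups <- rep(names(gs), gs)
  ids <- unlist(lapply(names(gs), function(g)
    sprintf("%s_%03d", g, seq_len(gs[[g]]))), use.names = FALSE)
  phase <- unlist(lapply(names(gs), function(g) {
    n <- gs[[g]]
    if (g == "MTC") return(rep("VALIDATION", n))
    nt <- config$training[[g]]
    c(rep("TRAINING", nt), rep("VALIDATION", n - nt))
  }), use.names = FALSE)
  n <- length(ids)
  samples <- data.frame(
    sample_id = ids, group = groups, phase = phase,
    age = round(pmin(pmax(stats::rnorm(n, 45, 13), 18), 80), 1),
    sex = ifelse(stats::runif(n) < 0.21, "M", "F"),
    stringsAsFactors = FALSE)

  ref_ids <- config$reference_assays
  tgt <- config$assays$assay_id
  base <- stats::rnorm(n, 0, config$ref_ct_sd)
  ref_ct <- outer(config$ref_ct_mean + base, rep(0, length(ref_ids)), "+") +
    matrix(stats::rnorm(n * length(ref_ids), 0, config$tech_sd), n)
  tgt_ct <- matrix(NA_real_, n, length(tgt))
  for (g in names(gs)) {
    rows <- which(groups == g)
    if (!length(rows)) next
    p <- dct_params(config, g)
    for (j in seq_along(tgt)) {
      dct <- p$mu[j] + stats::rnorm(length(rows), 0, p$bio_sd[j])
      tgt_ct[rows, j] <- config$ref_ct_mean + base[rows] + dct +
        stats::rnorm(length(rows), 0, config$tech_sd)
    }
  }
  ct <- cbind(ref_ct, tgt_ct)
  dimnames(ct) <- list(ids, c(ref_ids, tgt))
  cens <- ct > config$censor_cutoff
  ct[cens] <- NA_real_
  assays <- data.frame(assay_id = c(ref_ids, tgt),
                       role = c(rep("REFERENCE", length(ref_ids)),
                                rep("TARGET", length(tgt))),
                       stringsAsFactors = FALSE)
  x <- ct_matrix(ct, samples, assays, censored = cens,
                 max_cycles = config$max_cycles)

  truth <- do.call(rbind, lapply(names(gs), function(g) {
    p <- dct_params(config, g)
    m <- config$assays[[paste0("mean_", g)]]
    fc <- m / config$assays$mean_CONTROL
    data.frame(assay_id = tgt, group = g, true_mean = m,
               true_delta_ct = p$mu, fc_vs_control = fc,
               direction = ifelse(fc > 1, "UP",
                                  ifelse(fc < 1, "DOWN", "NULL")),
               stringsAsFactors = FALSE)
  }))
  list(ct = x, truth = truth)
}

# Assay table of the full screening array: configured targets padded with
# deterministic null fillers up to `screen_universe` assays.
screen_assay_table <- function(config) {
  a <- config$assays
  n_fill <- config$screen_universe - nrow(a) - length(config$reference_assays)
  if (n_fill < 0) return(a)
  fill <- data.frame(
    assay_id = sprintf("miR-screen-%04d", seq_len(n_fill)),
    mean_CONTROL = 2^seq(-6, 2, length.out = max(n_fill, 1))[seq_len(n_fill)],
    cv_CONTROL = 0.5)
  for (g in c("PTC", "BENIGN", "MTC")) {
    fill[[paste0("mean_", g)]] <- fill$mean_CONTROL
    fill[[paste0("cv_", g)]] <- fill$cv_CONTROL
  }
  rbind(a, fill[names(a)])
}

#' Simulate pooled screening profiles
#'
#' Draws `pool_size` fresh serum samples per group (PTC, benign, control)
#' over the full screening universe and pools them the way equal serum
#' volumes mix: the pooled linear abundance of each assay is the mean of
#' the members' `2^-dCT` values, converted back to a pool dCT. Raw pool CTs
#' carry one technical-noise draw per assay.
#'
#' @param config a [sim_config()].
#' @param pool_size samples per pool (default from config).
#' @param seed integer seed.
#' @return Named list of [pool_profile()]s for `PTC`, `BENIGN`, `CONTROL`,
#'   each with attribute `members` (the pooled sample ids).
#' @export
simulate_pools <- function(config, pool_size = config$pool_size,
                           seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (pool_size < 1) stop("pool size must be >= 1")
  if (pool_size > min(config$group_sizes[c("PTC", "BENIGN", "CONTROL")]))
    stop("pool size exceeds a group size")
  if (!is.null(seed)) set.seed(seed)
  assays <- screen_assay_table(config)
  cfg2 <- config; cfg2$assays <- assays
  out <- list()
  for (g in c("PTC", "BENIGN", "CONTROL")) {
    base <- stats::rnorm(pool_size, 0, config$ref_ct_sd)
    p <- dct_params(cfg2, g)
    # members x assays matrix of true per-sample dCT
    dct <- matrix(stats::rnorm(pool_size * nrow(assays), p$mu, p$bio_sd),
                  pool_size, nrow(assays), byrow = TRUE)
    # equal volumes mix molecules: pool relative abundance is the mean of
    # the members' linear 2^-dCT levels, read back as a pool dCT
    pool_dct <- -log2(colMeans(2^(-dct)))
    pool_ref_ct <- -log2(mean(2^(-(config$ref_ct_mean + base))))
    ct <- c(
      stats::setNames(
        pool_ref_ct + pool_dct + stats::rnorm(nrow(assays), 0, config$tech_sd),
        assays$assay_id),
      stats::setNames(
        pool_ref_ct + stats::rnorm(length(config$reference_assays), 0,
                                   config$tech_sd),
        config$reference_assays))
    ct[ct > config$censor_cutoff] <- NA_real_
    prof <- pool_profile(ct, group = g,
                         reference_assays = config$reference_assays)
    attr(prof, "members") <- sprintf("%s_pool_%02d", g, seq_len(pool_size))
    out[[g]] <- prof
  }
  out
}
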