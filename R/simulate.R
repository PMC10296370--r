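#' Configuration for the synthetic lipidomic cohort generator
#'
#' Builds the parameter list that drives [simulate_clinical()],
#' [simulate_cac()] and [simulate_lipidome()]. Defaults emulate the marginal
#' structure of a statin-era cardiology recruitment cohort: age 61 (SD 12)
#' years, 45% female, BMI 26.9 (SD 4.8) kg/m2, hypertension 39%, diabetes
#' 8.7%, hypercholesterolemia 59%, current smoking 6.4%, one third on
#' statins, and 683 plasma lipid species measured in consecutive batches.
#'
#' @param n_study Number of study participants.
#' @param n_species Number of lipid species (default 683).
#' @param n_batches Number of measurement batches; participants are assigned
#'   to batches in contiguous recruitment blocks.
#' @param batch_sd SD (log scale) of the additive per-batch, per-species
#'   offsets.
#' @param n_informative Number of species carrying a true sCAD class effect.
#' @param effect_low_bmi,effect_high_bmi Class effect planted on informative
#'   species, expressed as log-odds of sCAD+ per noise-SD of the species, in
#'   the BMI < 25 and BMI >= 25 strata respectively.
#' @param noise_sd Residual biological/analytical SD of each species (log
#'   scale).
#' @param qc_noise_sd Technical-replicate SD for QC sample rows.
#' @param frs_link_low_bmi,frs_link_high_bmi Strength of the link between the
#'   standardized traditional-risk-factor index (age, sex, SBP, TC, HDL,
#'   smoking, diabetes) and coronary calcium, per BMI stratum. This is what
#'   gives the Framingham score predictive signal in the simulated cohort.
#' @param age_effect_sd,sex_effect_sd SDs of the per-species age (per year)
#'   and sex effects on log-concentration.
#' @param covariate_params Named list of distribution settings for the
#'   clinical covariates and the calcium model; see the default for the
#'   recognised entries.
#' @param qc_counts Named counts of pooled-QC, technical-QC, blank and
#'   NIST1950 reference samples.
#' @param statin_prob Probability a participant is on a statin.
#' @param seed Integer seed; the whole generator is deterministic given the
#'   config.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_study = 994,
                       n_species = 683,
                       n_batches = 3,
                       batch_sd = 0.5,
                       n_informative = 30,
                       effect_low_bmi = 0.5,
                       effect_high_bmi = 0.5,
                       noise_sd = 0.3,
                       qc_noise_sd = 0.05,
                       frs_link_low_bmi = 0.6,
                       frs_link_high_bmi = 0.6,
                       age_effect_sd = 0.002,
                       sex_effect_sd = 0.02,
                       covariate_params = list(),
                       qc_counts = c(pooled_qc = 6, technical_qc = 6,
                                     blank = 3, nist1950 = 3),
                       statin_prob = 0.33,
                       seed = 1L) {
  defaults <- list(
    age_mean = 61, age_sd = 12,
    female_prob = 0.45,
    bmi_mean = 26.9, bmi_sd = 4.8,
    hypertension_prob = 0.39,
    diabetes_prob = 0.087,
    hypercholesterolemia_prob = 0.59,
    smoking_prob = 0.064,
    sbp_mean = 130, sbp_sd = 15,
    tc_mean = 5.2, tc_sd = 1.0,
    hdl_mean = 1.4, hdl_sd = 0.35,
    # zero-inflated log-normal calcium model; most covariate dependence
    # flows through the risk index (scaled by frs_link_*), the base terms
    # keep the age/sex monotonicities even at zero link
    cac_zero_intercept = 0.2,
    cac_zero_age = -0.02,      # per year: zero mass shrinks with age
    cac_zero_female = 0.5,     # females more likely to have zero calcium
    cac_mean_log = 3,
    cac_log_age = 0.02,        # positive part grows with age
    cac_log_male = 0.2,        # and with male sex
    cac_log_sd = 1.5
  )
  cp <- modifyList(defaults, covariate_params)

  for (nm in c("female_prob", "hypertension_prob", "diabetes_prob",
               "hypercholesterolemia_prob", "smoking_prob")) {
    check_prob(cp[[nm]], nm)
  }
  check_prob(statin_prob, "statin_prob")
  for (nm in c("age_sd", "bmi_sd", "sbp_sd", "tc_sd", "hdl_sd", "cac_log_sd")) {
    check_nonneg(cp[[nm]], nm)
  }
  check_nonneg(batch_sd, "batch_sd")
  check_nonneg(noise_sd, "noise_sd")
  check_nonneg(qc_noise_sd, "qc_noise_sd")
  if (n_informative > n_species) abort("n_informative must be <= n_species")
  if (n_batches < 1 || n_study < n_batches) abort("need 1 <= n_batches <= n_study")
  qc_defaults <- c(pooled_qc = 6, technical_qc = 6, blank = 3, nist1950 = 3)
  qc <- qc_defaults
  qc[names(qc_counts)] <- qc_counts
  if (any(qc < 0)) abort("qc_counts must be non-negative")

  structure(list(
    n_study = as.integer(n_study), n_species = as.integer(n_species),
    n_batches = as.integer(n_batches), batch_sd = batch_sd,
    n_informative = as.integer(n_informative),
    effect_low_bmi = effect_low_bmi, effect_high_bmi = effect_high_bmi,
    noise_sd = noise_sd, qc_noise_sd = qc_noise_sd,
    frs_link_low_bmi = frs_link_low_bmi, frs_link_high_bmi = frs_link_high_bmi,
    age_effect_sd = age_effect_sd, sex_effect_sd = sex_effect_sd,
    covariate_params = cp, qc_counts = qc,
    statin_prob = statin_prob, seed = as.integer(seed)
  ), class = "sim_config")
}

#' Simulate the clinical table of a synthetic cohort
#'
#' Study rows carry full covariates, a batch assigned in contiguous
#' recruitment blocks, and a recruitment order; QC rows (pooled QC, technical
#' QC, blanks, NIST1950 reference plasma) carry only their role and batch.
#' The `cac` column is initialised to `NA` and filled by [simulate_cac()].
#'
#' @param config A [sim_config()].
#' @param seed Overrides `config$seed` when given.
#' @return A clinical tibble, one row per sample.
#' @export
simulate_clinical <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(seed)
  cp <- config$covariate_params
  n <- config$n_study

  block <- ceiling(n / config$n_batches)
  batch <- paste0("B", pmin((seq_len(n) - 1) %/% block + 1, config$n_batches))

  study <- tibble(
    sample_id = sprintf("S%05d", seq_len(n)),
    role = "study",
    age = pmin(pmax(rnorm(n, cp$age_mean, cp$age_sd), 30), 95),
    sex = if_else(runif(n) < cp$female_prob, "F", "M"),
    bmi = pmin(pmax(rnorm(n, cp$bmi_mean, cp$bmi_sd), 15), 55),
    hypertension = runif(n) < cp$hypertension_prob,
    diabetes = runif(n) < cp$diabetes_prob,
    hypercholesterolemia = runif(n) < cp$hypercholesterolemia_prob,
    current_smoking = runif(n) < cp$smoking_prob,
    statin = runif(n) < config$statin_prob,
    sbp = pmax(rnorm(n, cp$sbp_mean, cp$sbp_sd), 80),
    tc = pmax(rnorm(n, cp$tc_mean, cp$tc_sd), 2),
    hdl = pmax(rnorm(n, cp$hdl_mean, cp$hdl_sd), 0.4),
    cac = NA_real_,
    batch = batch,
    recruit_order = seq_len(n)
  )

  qc <- imap(config$qc_counts, function(k, role) {
    if (k == 0) return(NULL)
    tibble(
      sample_id = sprintf("%s_%02d", toupper(role), seq_len(k)),
      role = role,
      # spread QC samples across batches round-robin
      batch = paste0("B", ((seq_len(k) - 1) %% config$n_batches) + 1)
    )
  })
  qc <- list_rbind(qc[!map_lgl(qc, is.null)])
  bind_rows(study, qc)
}

#' Simulate coronary artery calcium scores
#'
#' Zero-inflated log-normal model: the point mass at zero shrinks with age
#' and is larger for females; the positive part is log-normal, increasing in
#' age and male sex. Most of the covariate dependence flows through a
#' standardized traditional-risk-factor index (age, sex, SBP, TC, HDL,
#' smoking, diabetes) whose strength is BMI-stratum-specific
#' (`frs_link_low_bmi` / `frs_link_high_bmi`), so how predictable the
#' derived labels are from Framingham covariates is a per-stratum config
#' choice; small base age/sex terms keep the stated monotonicities even at
#' zero link.
#'
#' @param clinical Clinical tibble from [simulate_clinical()].
#' @param config The same [sim_config()].
#' @param seed RNG seed for this stage.
#' @return Numeric CAC vector aligned with the study rows of `clinical`
#'   (QC rows get `NA`).
#' @export
simulate_cac <- function(clinical, config, seed = config$seed + 1L) {
  stopifnot(inherits(config, "sim_config"))
  check_clinical_tbl(clinical)
  if (!any(clinical$role == "study")) abort("no study rows in clinical table")
  set.seed(seed)
  cp <- config$covariate_params
  s <- clinical[clinical$role == "study", ]
  male <- as.numeric(s$sex == "M")

  z <- 0.45 * (s$age - cp$age_mean) / cp$age_sd +
    0.35 * male +
    0.25 * (s$sbp - cp$sbp_mean) / cp$sbp_sd +
    0.20 * (s$tc - cp$tc_mean) / cp$tc_sd -
    0.20 * (s$hdl - cp$hdl_mean) / cp$hdl_sd +
    0.30 * s$current_smoking + 0.30 * s$diabetes
  link <- if_else(s$bmi < 25, config$frs_link_low_bmi, config$frs_link_high_bmi)

  p_zero <- plogis(cp$cac_zero_intercept +
                     cp$cac_zero_age * (s$age - 60) +
                     cp$cac_zero_female * (1 - male) -
                     link * z)
  is_zero <- runif(nrow(s)) < p_zero
  log_cac <- cp$cac_mean_log +
    cp$cac_log_age * (s$age - 60) +
    cp$cac_log_male * male +
    link * z +
    rnorm(nrow(s), 0, cp$cac_log_sd)
  cac_study <- if_else(is_zero, 0, exp(log_cac))

  out <- rep(NA_real_, nrow(clinical))
  out[clinical$role == "study"] <- cac_study
  out
}

#' Simulate the lipid concentration matrix
#'
#' Log-concentration of species s in sample i is
#' baseline_s + batch_loading\[batch_i, s\] + age/sex effects + class effect
#' (informative species only, size switched on the BMI-25 stratum) +
#' Gaussian noise. Pooled-QC rows are the pooled study biological mean plus
#' the batch loading and technical noise; technical QC and NIST1950 rows are
#' reference profiles plus batch and technical noise; blanks sit at a floor
#' of baseline - 5.
#'
#' @param clinical Clinical tibble with `cac` filled in.
#' @param labels sCAD label tibble from [assign_scad_labels()].
#' @param config The [sim_config()].
#' @param seed RNG seed for this stage.
#' @return A list with `lipids` (lipid table) and `truth` (planted
#'   ground-truth: informative species, per-species signed effects, batch
#'   loadings).
#' @export
simulate_lipidome <- function(clinical, labels, config, seed = config$seed + 2L) {
  stopifnot(inherits(config, "sim_config"))
  check_clinical_tbl(clinical, need_covariates = TRUE)
  set.seed(seed)
  p <- config$n_species
  species <- sprintf("lipid_%03d", seq_len(p))
  cp <- config$covariate_params

  baseline <- rnorm(p, log(10), 1)
  loadings <- matrix(rnorm(config$n_batches * p, 0, config$batch_sd),
                     nrow = config$n_batches, ncol = p,
                     dimnames = list(paste0("B", seq_len(config$n_batches)), species))
  age_coef <- rnorm(p, 0, config$age_effect_sd)
  sex_coef <- rnorm(p, 0, config$sex_effect_sd)
  informative <- sort(sample.int(p, config$n_informative))
  sign_s <- numeric(p)
  sign_s[informative] <- sample(c(-1, 1), config$n_informative, replace = TRUE)
  nist_offset <- rnorm(p, 0, 0.3)

  s <- clinical[clinical$role == "study", ]
  lab <- labels$label[match(s$sample_id, labels$sample_id)]
  eff_size <- if_else(s$bmi < 25, config$effect_low_bmi, config$effect_high_bmi)
  # class contrast applied symmetrically within the stratum: sCAD+ at
  # +effect/2 and sCAD- at -effect/2 (in noise-SD units), so the between-
  # class difference equals effect * noise_sd; excluded samples sit at 0
  class_pos <- dplyr::case_when(
    !is.na(lab) & lab == "sCAD_plus" ~ 0.5,
    !is.na(lab) & lab == "sCAD_minus" ~ -0.5,
    TRUE ~ 0
  )

  n_s <- nrow(s)
  bio <- matrix(baseline, n_s, p, byrow = TRUE) +
    outer(s$age - cp$age_mean, age_coef) +
    outer(as.numeric(s$sex == "M"), sex_coef) +
    outer(class_pos * eff_size * config$noise_sd, sign_s)
  batch_idx <- match(s$batch, rownames(loadings))
  X_study <- bio + loadings[batch_idx, , drop = FALSE] +
    matrix(rnorm(n_s * p, 0, config$noise_sd), n_s, p)

  pooled_mean <- colMeans(bio)
  qc <- clinical[clinical$role != "study", ]
  X_qc <- matrix(NA_real_, nrow(qc), p)
  if (nrow(qc)) {
    ref <- t(vapply(seq_len(nrow(qc)), function(i) {
      switch(qc$role[i],
        pooled_qc = pooled_mean,
        technical_qc = baseline,
        nist1950 = baseline + nist_offset,
        blank = baseline - 5
      )
    }, numeric(p)))
    X_qc <- ref + loadings[match(qc$batch, rownames(loadings)), , drop = FALSE] +
      matrix(rnorm(nrow(qc) * p, 0, config$qc_noise_sd), nrow(qc), p)
  }

  X <- rbind(X_study, X_qc)
  colnames(X) <- species
  lipids <- bind_cols(
    clinical[c(which(clinical$role == "study"), which(clinical$role != "study")),
             LIPID_META_COLS],
    as_tibble(X, .name_repair = "minimal")
  )
  # restore original clinical row order
  lipids <- lipids[match(clinical$sample_id, lipids$sample_id), ]

  truth <- list(
    informative_species = species[informative],
    true_effects = tibble(
      species = species[informative],
      sign = sign_s[informative],
      effect_low_bmi = sign_s[informative] * config$effect_low_bmi,
      effect_high_bmi = sign_s[informative] * config$effect_high_bmi
    ),
    batch_loadings = loadings,
    noise_sd = config$noise_sd
  )
  list(lipids = lipids, truth = truth)
}

#' Simulate a complete cohort: clinical table, calcium, labels and lipidome
#'
#' Convenience wrapper running [simulate_clinical()], [simulate_cac()],
#' [assign_scad_labels()] and [simulate_lipidome()] with per-stage seeds
#' derived from `config$seed`, so the whole cohort is reproducible from the
#' config alone.
#'
#' @param config A [sim_config()].
#' @return A list with `clinical`, `lipids`, `labels` and `truth`.
#' @export
simulate_cohort <- function(config) {
  clinical <- simulate_clinical(config)
  clinical$cac <- simulate_cac(clinical, config)
  labels <- assign_scad_labels(clinical)
  lip <- simulate_lipidome(clinical, labels, config)
  list(clinical = clinical, lipids = lip$lipids, labels = labels,
       truth = c(lip$truth, list(labels = labels)))
}

#' Write a simulated cohort to the package's standard files
#'
#' Writes `clinical.csv`, `lipids.csv` (rows = samples; first columns
#' sample_id/role/batch, remaining columns species) and `truth.json`.
#'
#' @param sim Result of [simulate_cohort()].
#' @param dir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_cohort <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(sim$clinical, file.path(dir, "clinical.csv"))
  readr::write_csv(sim$lipids, file.path(dir, "lipids.csv"))
  truth <- sim$truth
  truth$batch_loadings <- NULL # large; regenerable from the config seed
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "columns")
  invisible(dir)
}
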