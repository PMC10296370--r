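# Small cohort builders used across tests; everything is generated in code.

tiny_config <- function(seed = 1, ...) {
  args <- list(...)
  defaults <- list(n_study = 200, n_species = 60, n_batches = 3,
                   batch_sd = 0.5, n_informative = 10, seed = seed)
  args <- modifyList(defaults, args)
  args$n_informative <- min(args$n_informative, args$n_species)
  do.call(sim_config, args)
}

# A clinical table with fully controlled covariates (no randomness).
manual_clinical <- function(n, age = 60, sex = "M", bmi = 27, cac = 0,
                            statin = FALSE, batch = "B1") {
  tibble::tibble(
    sample_id = sprintf("S%05d", seq_len(n)),
    role = "study",
    age = rep_len(age, n), sex = rep_len(sex, n), bmi = rep_len(bmi, n),
    hypertension = FALSE, diabetes = FALSE, hypercholesterolemia = FALSE,
    current_smoking = FALSE, statin = rep_len(statin, n),
    sbp = 130, tc = 5, hdl = 1.3,
    cac = rep_len(cac, n), batch = rep_len(batch, n),
    recruit_order = seq_len(n)
  )
}

# Lipid table wrapper around a plain matrix.
manual_lipids <- function(m, role = "study", batch = "B1") {
  ids <- rownames(m) %||% sprintf("S%05d", seq_len(nrow(m)))
  dplyr::bind_cols(
    tibble::tibble(sample_id = ids, role = rep_len(role, nrow(m)),
                   batch = rep_len(batch, nrow(m))),
    tibble::as_tibble(m, .name_repair = "minimal")
  )
}

`%||%` <- rlang::`%||%`

two_gaussian_problem <- function(n = 100, delta = 0, seed = 70) {
  set.seed(seed)
  y <- rep(0:1, each = n / 2)
  X <- matrix(rnorm(n * 4), n, 4,
              dimnames = list(sprintf("S%04d", seq_len(n)), paste0("f", 1:4)))
  X[, 1:2] <- X[, 1:2] + delta * y
  list(X = X, y = y)
}

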