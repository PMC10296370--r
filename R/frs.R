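# Sex-specific general cardiovascular disease risk function (Cox model,
# 10-year baseline survival), log-transformed continuous covariates, lipids
# in mg/dL. Versioned constants; do not edit without bumping.
FRS_CONSTANTS <- list(
  version = "general-cvd-2008/1",
  mmol_to_mgdl = 38.67,
  M = list(
    b_log_age = 3.06117, b_log_tc = 1.12370, b_log_hdl = -0.93263,
    b_log_sbp_untreated = 1.93303, b_log_sbp_treated = 1.99881,
    b_smoker = 0.65451, b_diabetes = 0.57367,
    mean_sum = 23.9802, s0_10 = 0.88936
  ),
  F = list(
    b_log_age = 2.32888, b_log_tc = 1.20904, b_log_hdl = -0.70833,
    b_log_sbp_untreated = 2.76157, b_log_sbp_treated = 2.82263,
    b_smoker = 0.52873, b_diabetes = 0.69154,
    mean_sum = 26.1931, s0_10 = 0.95012
  )
)

#' Framingham 10-year general cardiovascular risk
#'
#' Sex-specific risk of a first cardiovascular event within 10 years, from
#' the published general-CVD risk equation (log age, log total and HDL
#' cholesterol, log systolic blood pressure with separate coefficients for
#' treated blood pressure, smoking and diabetes; risk =
#' 1 - S0^exp(sum - mean)). Total and HDL cholesterol are supplied in
#' mmol/L and converted internally. Because the cohort schema carries no
#' antihypertensive-treatment column, the hypertension flag is used as the
#' treated-blood-pressure indicator.
#'
#' @param clinical Clinical tibble (study rows) with age, sex, sbp, tc, hdl,
#'   current_smoking, diabetes and hypertension.
#' @return Numeric vector of risks in (0, 1), aligned with `clinical` rows.
#' @export
framingham_risk <- function(clinical) {
  needed <- c("age", "sex", "sbp", "tc", "hdl", "current_smoking",
              "diabetes", "hypertension")
  missing <- setdiff(needed, names(clinical))
  if (length(missing)) {
    abort(paste0("framingham_risk: missing covariate(s): ",
                 paste(missing, collapse = ", ")))
  }
  for (nm in needed) {
    if (any(is.na(clinical[[nm]]))) {
      abort(paste0("framingham_risk: missing values in ", nm))
    }
  }
  age <- clinical$age
  if (any(age < 30 | age > 74)) {
    warn("age outside 30-74 clamped to the equation's supported range")
    age <- pmin(pmax(age, 30), 74)
  }
  tc <- clinical$tc * FRS_CONSTANTS$mmol_to_mgdl
  hdl <- clinical$hdl * FRS_CONSTANTS$mmol_to_mgdl
  treated <- as.numeric(clinical$hypertension)

  risk <- numeric(nrow(clinical))
  for (sx in c("M", "F")) {
    i <- clinical$sex == sx
    if (!any(i)) next
    k <- FRS_CONSTANTS[[sx]]
    b_sbp <- ifelse(treated[i] == 1, k$b_log_sbp_treated, k$b_log_sbp_untreated)
    s <- k$b_log_age * log(age[i]) + k$b_log_tc * log(tc[i]) +
      k$b_log_hdl * log(hdl[i]) + b_sbp * log(clinical$sbp[i]) +
      k$b_smoker * as.numeric(clinical$current_smoking[i]) +
      k$b_diabetes * as.numeric(clinical$diabetes[i])
    risk[i] <- 1 - k$s0_10^exp(s - k$mean_sum)
  }
  risk
}
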