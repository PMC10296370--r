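#' Benjamini-Hochberg adjustment with missing-value passthrough
#'
#' Step-up false-discovery-rate adjustment (via [stats::p.adjust()]) applied
#' to the non-missing p-values; missing entries (for example species flagged
#' for perfect separation) are passed through unchanged and do not count
#' toward the number of tests.
#'
#' @param p Numeric vector of p-values in \[0, 1\], possibly with `NA`s.
#' @return Adjusted p-values, same length and order.
#' @export
bh_adjust <- function(p) {
  if (!is.numeric(p)) abort("p must be numeric")
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) abort("p-values must lie in [0, 1]")
  out <- p
  out[ok] <- p.adjust(p[ok], method = "BH")
  out
}

logistic_term <- function(fit, term) {
  co <- summary(fit)$coefficients
  if (!term %in% rownames(co)) return(NULL)
  est <- co[term, "Estimate"]
  se <- co[term, "Std. Error"]
  list(or = exp(est), lo = exp(est - 1.96 * se), hi = exp(est + 1.96 * se),
       p = co[term, "Pr(>|z|)"], beta = est, se = se)
}

#' Per-species logistic association of sCAD class with lipid concentration
#'
#' For each species, fits a maximum-likelihood logistic regression of
#' sCAD-/sCAD+ on the (log) concentration: a univariate model and, when a
#' clinical table is supplied, a covariate-adjusted model with BMI,
#' hypertension, current smoking, diabetes and hypercholesterolemia
#' (optionally also age and sex). Effects are reported as odds ratios per
#' unit log-concentration with Wald 95% confidence intervals; p-values are
#' Benjamini-Hochberg adjusted within each model variant. Species with
#' (quasi-)separated fits are flagged, their p set missing and excluded
#' from the FDR.
#'
#' @param lipids Lipid table restricted to the samples to analyse.
#' @param labels Label tibble; only sCAD_minus/sCAD_plus rows are used.
#' @param clinical Optional clinical tibble enabling the adjusted model.
#' @param include_age_sex Also adjust for age and sex?
#' @return Tibble: species, model (univariate/adjusted), odds_ratio, ci_low,
#'   ci_high, p, p_adj, separation flag.
#' @export
fit_lipid_associations <- function(lipids, labels, clinical = NULL,
                                   include_age_sex = FALSE) {
  lab <- labels |> filter(.data$label %in% c("sCAD_minus", "sCAD_plus"))
  keep <- lipids$sample_id %in% lab$sample_id
  X <- lipid_values(lipids[keep, ])
  y <- scad_binary(lab$label[match(rownames(X), lab$sample_id)])
  if (length(unique(y)) < 2) abort("both sCAD classes must be present")
  const <- apply(X, 2, function(x) sd(x) == 0)
  if (any(const)) {
    abort(paste0("constant species: ", paste(colnames(X)[const], collapse = ", ")))
  }

  covs <- NULL
  if (!is.null(clinical)) {
    cn <- c("bmi", "hypertension", "current_smoking", "diabetes",
            "hypercholesterolemia")
    if (include_age_sex) cn <- c(cn, "age", "sex")
    clin <- clinical[match(rownames(X), clinical$sample_id), ]
    covs <- as.data.frame(clin[cn])
    covs$hypertension <- as.numeric(covs$hypertension)
    covs$current_smoking <- as.numeric(covs$current_smoking)
    covs$diabetes <- as.numeric(covs$diabetes)
    covs$hypercholesterolemia <- as.numeric(covs$hypercholesterolemia)
    if (include_age_sex) covs$sex <- as.numeric(covs$sex == "M")
  }

  fit_one <- function(x, model) {
    dat <- data.frame(y = y, x = x)
    if (model == "adjusted") dat <- cbind(dat, covs)
    separated <- FALSE
    fit <- withCallingHandlers(
      glm(y ~ ., data = dat, family = binomial()),
      warning = function(w) {
        if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
          separated <<- TRUE
        }
        invokeRestart("muffleWarning")
      }
    )
    tm <- logistic_term(fit, "x")
    # quasi-separation leaves an absurd Wald SE even when glm stays quiet
    separated <- separated || abs(tm$beta) > 15 || tm$se > 50
    tibble(
      model = model,
      odds_ratio = tm$or, ci_low = tm$lo, ci_high = tm$hi,
      p = if (separated) NA_real_ else tm$p,
      separation = separated
    )
  }

  models <- c("univariate", if (!is.null(covs)) "adjusted")
  res <- map(colnames(X), function(sp) {
    bind_rows(map(models, function(m) fit_one(X[, sp], m))) |>
      mutate(species = sp, .before = 1)
  }) |> list_rbind()

  res |>
    group_by(.data$model) |>
    mutate(p_adj = bh_adjust(.data$p)) |>
    ungroup() |>
    select("species", "model", "odds_ratio", "ci_low", "ci_high",
           "p", "p_adj", "separation")
}

#' Forest-plot table of significant species
#'
#' Filters the covariate-adjusted associations at an FDR threshold, orders
#' them by ascending adjusted p-value, and carries both model variants'
#' odds ratios and confidence intervals side by side, with significance
#' stars (0.05 / 0.01 / 0.001) on the adjusted-model adjusted p-values.
#'
#' @param assoc Output of [fit_lipid_associations()] with both variants.
#' @param fdr FDR threshold on the adjusted model.
#' @return Wide tibble, one row per significant species, ordered by
#'   `p_adj_adjusted`.
#' @export
export_forest_data <- function(assoc, fdr = 0.05) {
  if (!"adjusted" %in% assoc$model) {
    abort("forest export needs the covariate-adjusted model; supply clinical data to fit_lipid_associations()")
  }
  wide <- assoc |>
    select("species", "model", "odds_ratio", "ci_low", "ci_high", "p", "p_adj") |>
    tidyr::pivot_wider(names_from = "model",
                       values_from = c("odds_ratio", "ci_low", "ci_high", "p", "p_adj"))
  wide |>
    filter(!is.na(.data$p_adj_adjusted), .data$p_adj_adjusted < fdr) |>
    arrange(.data$p_adj_adjusted) |>
    mutate(stars = dplyr::case_when(
      .data$p_adj_adjusted < 0.001 ~ "***",
      .data$p_adj_adjusted < 0.01 ~ "**",
      .data$p_adj_adjusted < 0.05 ~ "*",
      TRUE ~ ""
    ))
}
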