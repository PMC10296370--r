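#' Load a cohort from clinical and lipid CSV files
#'
#' Reads the two standard package files and aligns the lipid rows to the
#' clinical sample order. Any sample present in one file but not the other is
#' an error (offenders listed). Lipid values are expected on the natural-log
#' scale; set `lipids_raw = TRUE` if the file holds raw concentrations, in
#' which case they are log-transformed on load.
#'
#' @param clinical_path,lipid_path CSV paths.
#' @param lipids_raw Are lipid values raw (not log) concentrations?
#' @return A list with `clinical` and `lipids` tibbles, samples aligned.
#' @export
load_cohort <- function(clinical_path, lipid_path, lipids_raw = FALSE) {
  for (p in c(clinical_path, lipid_path)) {
    if (!file.exists(p)) abort(paste0("file not found: ", p))
  }
  clinical <- readr::read_csv(clinical_path, show_col_types = FALSE,
                              progress = FALSE)
  lipids <- readr::read_csv(lipid_path, show_col_types = FALSE,
                            progress = FALSE)
  check_clinical_tbl(clinical)
  check_lipid_tbl(lipids)

  only_clin <- setdiff(clinical$sample_id, lipids$sample_id)
  only_lip <- setdiff(lipids$sample_id, clinical$sample_id)
  if (length(only_clin) || length(only_lip)) {
    abort(paste0(
      "sample alignment error; missing from lipid file: ",
      paste(only_clin, collapse = ", "), "; missing from clinical file: ",
      paste(only_lip, collapse = ", ")
    ))
  }
  sp <- lipid_species(lipids)
  if (!all(vapply(lipids[sp], is.numeric, logical(1)))) {
    bad <- sp[!vapply(lipids[sp], is.numeric, logical(1))]
    abort(paste0("non-numeric concentration column(s): ",
                 paste(head(bad, 5), collapse = ", ")))
  }
  lipids <- lipids[match(clinical$sample_id, lipids$sample_id), ]
  if (lipids_raw) {
    m <- lipid_values(lipids)
    if (any(m <= 0, na.rm = TRUE)) abort("raw concentrations must be positive to log-transform")
    lipids <- set_lipid_values(lipids, log(m))
  }
  list(clinical = clinical, lipids = lipids)
}

#' Assign subclinical-CAD labels from coronary calcium
#'
#' Statin users are excluded outright. Among the remainder: zero CAC is
#' sCAD-; CAC at or above the 50th percentile of positive CAC for the
#' participant's sex and age decade is sCAD+; positive CAC below that
#' percentile is excluded as intermediate. The percentile reference is the
#' within-cohort empirical distribution of positive CACs among non-statin
#' participants in the stratum; a stratum with fewer than two positive-CAC
#' members falls back to the sex-only stratum, with a warning.
#'
#' @param clinical Clinical tibble with `cac` present on study rows.
#' @return Tibble with `sample_id` and `label`
#'   (sCAD_minus / sCAD_plus / excluded_statin / excluded_intermediate).
#' @export
assign_scad_labels <- function(clinical) {
  check_clinical_tbl(clinical)
  s <- clinical[clinical$role == "study", ]
  if (!nrow(s)) abort("no study rows")
  if (any(is.na(s$cac))) abort("study rows must have cac")
  if (any(s$cac < 0)) abort("cac must be non-negative")

  decade <- paste0(10 * (s$age %/% 10), "s")
  stratum <- paste(s$sex, decade, sep = "_")

  ref <- s[!s$statin & s$cac > 0, ]
  if (nrow(ref)) {
    ref_stratum <- paste(ref$sex, paste0(10 * (ref$age %/% 10), "s"), sep = "_")
    p50 <- tapply(ref$cac, ref_stratum, function(x) unname(quantile(x, 0.5)))
    n_ref <- tapply(ref$cac, ref_stratum, length)
    p50_sex <- tapply(ref$cac, ref$sex, function(x) unname(quantile(x, 0.5)))
    cutoff <- unname(p50[stratum])
    small <- is.na(cutoff) | unname(n_ref[stratum]) < 2
    if (any(small & !s$statin & s$cac > 0)) {
      warn("stratum with < 2 positive-CAC members; falling back to sex-only stratum")
    }
    cutoff[small] <- unname(p50_sex[s$sex])[small]
  } else {
    cutoff <- rep(Inf, nrow(s)) # no positive-CAC reference: nobody is sCAD+
  }

  label <- dplyr::case_when(
    s$statin ~ "excluded_statin",
    s$cac == 0 ~ "sCAD_minus",
    s$cac >= cutoff ~ "sCAD_plus",
    TRUE ~ "excluded_intermediate"
  )
  tibble(sample_id = s$sample_id,
         label = factor(label, levels = SCAD_LEVELS))
}

#' Split the analytical cohort into discovery and validation by recruitment
#'
#' The analytical cohort (sCAD-/sCAD+ samples) is ordered by recruitment and
#' the first ceiling(fraction * n) samples form the discovery cohort, the
#' rest the validation cohort.
#'
#' @param labels Label tibble from [assign_scad_labels()].
#' @param clinical Clinical tibble (for `recruit_order`).
#' @param discovery_fraction Fraction in (0, 1) recruited into discovery.
#' @return Tibble with `sample_id`, `label`, `recruit_order`, `cohort`
#'   (discovery/validation).
#' @export
split_by_recruitment <- function(labels, clinical, discovery_fraction = 394 / 580) {
  if (!is.numeric(discovery_fraction) || discovery_fraction <= 0 ||
      discovery_fraction >= 1) {
    abort("discovery_fraction must be in (0, 1)")
  }
  analytical <- labels |>
    filter(.data$label %in% c("sCAD_minus", "sCAD_plus")) |>
    inner_join(clinical[c("sample_id", "recruit_order")], by = "sample_id") |>
    arrange(.data$recruit_order)
  if (!nrow(analytical)) abort("analytical cohort is empty")
  n_disc <- ceiling(discovery_fraction * nrow(analytical))
  analytical |>
    mutate(cohort = if_else(row_number() <= n_disc, "discovery", "validation"))
}

# "count (pct%)" with percentages to 2 significant digits, as in clinical
# baseline tables: 444/994 -> "444 (45%)", 86/994 -> "86 (8.7%)".
format_count_pct <- function(count, total) {
  pct <- if (total > 0) 100 * count / total else 0
  pct_chr <- dplyr::case_when(
    count == 0 ~ "0",
    pct >= 10 ~ sprintf("%.0f", signif(pct, 2)),
    TRUE ~ sprintf("%.1f", signif(pct, 2))
  )
  sprintf("%d (%s%%)", count, pct_chr)
}

format_mean_sd <- function(x, digits) {
  sprintf("%s (%s)",
          formatC(round(mean(x), digits), format = "f", digits = digits),
          formatC(round(sd(x), digits), format = "f", digits = digits))
}

#' Baseline characteristics table by analysis group
#'
#' Produces the customary cohort summary: categorical rows as
#' "count (pct%)" with percentages to two significant digits, continuous
#' rows as "mean (SD)". Columns are the whole study cohort and the four
#' cohort-by-class cells of the discovery/validation split.
#'
#' @param clinical Clinical tibble.
#' @param labels Label tibble from [assign_scad_labels()].
#' @param split Optional split tibble from [split_by_recruitment()]; when
#'   omitted only the whole-cohort column is produced.
#' @return Tibble with one row per characteristic, one column per group.
#' @export
summarize_cohort <- function(clinical, labels, split = NULL) {
  check_clinical_tbl(clinical, need_covariates = TRUE)
  s <- clinical |>
    filter(.data$role == "study") |>
    left_join(labels, by = "sample_id")

  groups <- list(`Whole cohort` = s)
  if (!is.null(split)) {
    for (co in c("discovery", "validation")) {
      for (cl in c("sCAD_minus", "sCAD_plus")) {
        ids <- split$sample_id[split$cohort == co & split$label == cl]
        nm <- sprintf("%s %s", c(discovery = "Discovery",
                                 validation = "Validation")[[co]],
                      if (cl == "sCAD_plus") "sCAD+" else "sCAD-")
        groups[[nm]] <- s[s$sample_id %in% ids, ]
      }
    }
  }

  cat_rows <- list(
    "Female, n (%)" = function(d) sum(d$sex == "F"),
    "Hypertension, n (%)" = function(d) sum(d$hypertension),
    "Diabetes Mellitus, n (%)" = function(d) sum(d$diabetes),
    "Hypercholesterolaemia, n (%)" = function(d) sum(d$hypercholesterolemia),
    "Current Smoking Status, n (%)" = function(d) sum(d$current_smoking),
    "Statin, n (%)" = function(d) sum(d$statin)
  )
  cont_rows <- list(
    "Age, years, mean (SD)" = list(var = "age", digits = 0),
    "BMI, kg/m2, mean (SD)" = list(var = "bmi", digits = 1),
    "Coronary Artery Calcium Score, mean (SD)" = list(var = "cac", digits = 0)
  )

  out <- tibble(characteristic = c("n", names(cat_rows), names(cont_rows)))
  for (nm in names(groups)) {
    d <- groups[[nm]]
    cells <- c(
      as.character(nrow(d)),
      map_chr(cat_rows, function(f) format_count_pct(f(d), nrow(d))),
      map_chr(cont_rows, function(r) format_mean_sd(d[[r$var]], r$digits))
    )
    out[[nm]] <- cells
  }
  out
}
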