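#' Extract the numeric concentration matrix from a lipid table
#'
#' A lipid table is a tibble whose first columns are `sample_id`, `role` and
#' `batch`, followed by one numeric column per lipid species
#' (log-concentrations). These helpers move between the tabular form used at
#' the package surface and the plain matrix used internally for linear
#' algebra.
#'
#' @param lipids A lipid table.
#' @return `lipid_values()` returns a numeric matrix (rows named by
#'   `sample_id`); `lipid_species()` returns the character vector of species
#'   column names.
#' @export
lipid_values <- function(lipids) {
  check_lipid_tbl(lipids)
  sp <- lipid_species(lipids)
  m <- as.matrix(lipids[, sp, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- lipids$sample_id
  m
}

#' @rdname lipid_values
#' @export
lipid_species <- function(lipids) {
  setdiff(names(lipids), LIPID_META_COLS)
}

# Rebuild a lipid table from a matrix plus the metadata columns of a template.
set_lipid_values <- function(lipids, m) {
  stopifnot(nrow(m) == nrow(lipids), ncol(m) == length(lipid_species(lipids)))
  out <- lipids
  out[, lipid_species(lipids)] <- as_tibble(m, .name_repair = "minimal")
  out
}

check_lipid_tbl <- function(lipids) {
  if (!is.data.frame(lipids) || !all(LIPID_META_COLS %in% names(lipids))) {
    abort("`lipids` must be a data frame with sample_id/role/batch columns followed by species columns.")
  }
  if (anyDuplicated(lipids$sample_id)) {
    abort("duplicate sample_id in lipid table")
  }
  invisible(lipids)
}

check_clinical_tbl <- function(clinical, need_covariates = FALSE) {
  base <- c("sample_id", "role", "batch")
  if (!is.data.frame(clinical) || !all(base %in% names(clinical))) {
    abort("`clinical` must contain sample_id, role and batch columns.")
  }
  if (anyDuplicated(clinical$sample_id)) abort("duplicate sample_id in clinical table")
  if (need_covariates) {
    covs <- c("age", "sex", "bmi", "hypertension", "diabetes",
              "hypercholesterolemia", "current_smoking", "statin",
              "sbp", "tc", "hdl")
    missing <- setdiff(covs, names(clinical))
    if (length(missing)) {
      abort(paste0("clinical table is missing covariates: ",
                   paste(missing, collapse = ", ")))
    }
  }
  invisible(clinical)
}

check_prob <- function(x, name) {
  if (!is.numeric(x) || any(x < 0 | x > 1, na.rm = TRUE)) {
    abort(paste0("`", name, "` must be a probability in [0, 1]."))
  }
  invisible(x)
}

check_nonneg <- function(x, name) {
  if (!is.numeric(x) || any(x < 0, na.rm = TRUE)) {
    abort(paste0("`", name, "` must be non-negative."))
  }
  invisible(x)
}

# Binary response from an sCAD label vector/factor (sCAD_plus = 1).
scad_binary <- function(label) {
  lab <- as.character(label)
  bad <- setdiff(unique(lab), SCAD_LEVELS)
  if (length(bad)) abort(paste0("unknown sCAD label(s): ", paste(bad, collapse = ", ")))
  if (!all(lab %in% c("sCAD_minus", "sCAD_plus"))) {
    abort("labels must be restricted to the analytical cohort (sCAD_minus/sCAD_plus)")
  }
  as.integer(lab == "sCAD_plus")
}

`%||%` <- rlang::`%||%`
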