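# Youden-optimal threshold on a score vector: the candidate score value
# (calls are score >= t) maximising sensitivity + specificity - 1. Ties go
# to the lowest threshold among the maximisers (more sensitive rule),
# deterministically.
youden_threshold <- function(scores, y) {
  t_cand <- sort(unique(scores))
  j <- vapply(t_cand, function(t) {
    call <- scores >= t
    mean(call[y == 1]) + mean(!call[y == 0]) - 1
  }, numeric(1))
  t_cand[which.max(j)]
}

new_risk_model <- function(kind, fit, feature_names, threshold, meta = list()) {
  structure(list(
    kind = kind, feature_names = feature_names,
    intercept = fit$intercept, beta = fit$beta,
    center = fit$center, scale = fit$scale,
    l2_penalty = fit$penalty, threshold = threshold,
    training_meta = meta
  ), class = "risk_model")
}

#' Fit the ridge-penalised lipid risk score (LRS)
#'
#' Ridge logistic regression of sCAD class on the supplied lipid features
#' (standardised internally; the transform is stored in the model). The
#' binary-call threshold is set to the Youden-optimal cut of the training
#' risk scores.
#'
#' @param data Tibble (or matrix) whose columns are the model features,
#'   e.g. a lipid table restricted to the selected species.
#' @param labels Label tibble or sCAD label vector aligned with `data` rows.
#' @param penalty L2 penalty strength (on the standardised scale).
#' @param features Optional character vector selecting/ordering the feature
#'   columns of `data`.
#' @param kind Model kind label.
#' @return A `risk_model` object.
#' @export
fit_ridge_logistic <- function(data, labels, penalty, features = NULL,
                               kind = "LRS") {
  fm <- feature_matrix(data, features)
  y <- labels_to_binary(labels, rownames(fm))
  fit <- ridge_logistic(fm, y, penalty)
  scores <- ridge_predict(fit, fm)
  new_risk_model(kind, fit, colnames(fm), youden_threshold(scores, y),
                 meta = list(n_train = nrow(fm)))
}

#' Fit the Framingham-score comparator model
#'
#' One-covariate unpenalised logistic regression of sCAD class on the
#' Framingham 10-year risk, so its ROC is a monotone transform of the raw
#' score.
#'
#' @param frs Numeric vector of Framingham risks ([framingham_risk()]).
#' @param labels Labels aligned with `frs`.
#' @return A `risk_model` of kind "FRS" with single feature `frs`.
#' @export
fit_frs_model <- function(frs, labels) {
  dat <- matrix(frs, ncol = 1, dimnames = list(names(frs), "frs"))
  y <- labels_to_binary(labels, rownames(dat))
  fit <- ridge_logistic(dat, y, penalty = 0)
  scores <- ridge_predict(fit, dat)
  new_risk_model("FRS", fit, "frs", youden_threshold(scores, y),
                 meta = list(n_train = length(y)))
}

#' Fit the combined FRS + lipid model
#'
#' Ridge logistic regression over the selected lipid species plus the
#' Framingham risk as one additional predictor (all standardised and
#' penalised together).
#'
#' @param data Lipid table (or feature tibble/matrix) for the lipid features.
#' @param frs Framingham risk vector aligned with `data` rows.
#' @param labels Labels aligned with `data` rows.
#' @param penalty L2 penalty strength.
#' @param features Lipid feature names to use.
#' @return A `risk_model` of kind "FRS_plus_LRS".
#' @export
fit_combined <- function(data, frs, labels, penalty, features = NULL) {
  fm <- feature_matrix(data, features)
  fm <- cbind(fm, frs = frs)
  y <- labels_to_binary(labels, rownames(fm))
  fit <- ridge_logistic(fm, y, penalty)
  scores <- ridge_predict(fit, fm)
  new_risk_model("FRS_plus_LRS", fit, colnames(fm),
                 youden_threshold(scores, y), meta = list(n_train = nrow(fm)))
}

#' Predict risk and binary sCAD calls from a fitted risk model
#'
#' @param model A `risk_model`.
#' @param data Tibble/matrix containing every model feature as a column
#'   (for an FRS model, a column named `frs`; for a combined model, the
#'   lipid species plus `frs`).
#' @return Tibble with `sample_id` (when available), `risk` in (0, 1) and
#'   logical `call` (risk at or above the model threshold).
#' @export
predict_risk <- function(model, data) {
  stopifnot(inherits(model, "risk_model"))
  fm <- feature_matrix(data, model$feature_names)
  risk <- ridge_predict(model, fm)
  tibble(
    sample_id = rownames(fm) %||% sprintf("row_%d", seq_along(risk)),
    risk = risk,
    call = risk >= model$threshold
  )
}

# Build the n x p feature matrix from a lipid table, plain tibble or matrix.
feature_matrix <- function(data, features = NULL) {
  if (is.matrix(data)) {
    fm <- data
  } else if (is.data.frame(data)) {
    fm <- as.matrix(data[setdiff(names(data), LIPID_META_COLS)])
    if ("sample_id" %in% names(data)) rownames(fm) <- data$sample_id
  } else {
    abort("data must be a matrix or data frame of features")
  }
  if (!is.null(features)) {
    missing <- setdiff(features, colnames(fm))
    if (length(missing)) {
      abort(paste0("missing feature(s): ", paste(head(missing, 5), collapse = ", ")))
    }
    fm <- fm[, features, drop = FALSE]
  }
  storage.mode(fm) <- "double"
  fm
}

labels_to_binary <- function(labels, sample_ids = NULL) {
  if (is.data.frame(labels)) {
    if (is.null(sample_ids)) abort("need sample ids to align labels")
    lab <- labels$label[match(sample_ids, labels$sample_id)]
    if (anyNA(lab)) abort("labels missing for some samples")
    scad_binary(lab)
  } else if (is.numeric(labels)) {
    stopifnot(all(labels %in% c(0, 1)))
    as.integer(labels)
  } else {
    scad_binary(labels)
  }
}

#' Bootstrap selection of LRS hyperparameters and features
#'
#' For each bootstrap resample of the discovery cohort, ridge models over
#' all species are fitted in-bag at every candidate penalty; species are
#' ranked by informativity, defined as the mean absolute standardised ridge
#' coefficient across bootstraps. Each grid point (penalty, number of top
#' species) is then scored by the mean out-of-bag AUC of an in-bag refit on
#' the top species, and the best pair is returned (ties prefer fewer
#' features, then the smaller penalty).
#'
#' Selection must never see validation samples: pass the cohort `split` and
#' any validation row in `data` raises an error.
#'
#' @param data Discovery lipid table.
#' @param labels Labels aligned with `data`.
#' @param penalty_grid Candidate L2 penalties (default log-spaced 1e-3..1e3).
#' @param n_features_grid Candidate counts of top species.
#' @param n_boot Number of bootstrap resamples.
#' @param seed RNG seed.
#' @param split Optional [split_by_recruitment()] table used to enforce
#'   discovery-only input.
#' @return List of class `lrs_selection`: `ranking` (chosen-penalty species
#'   ranking), `chosen_n`, `chosen_penalty`, `auc_grid` tibble, and
#'   bootstrap metadata.
#' @export
select_lrs_features <- function(data, labels,
                                penalty_grid = 10^seq(-3, 3),
                                n_features_grid = c(50, 100, 200),
                                n_boot = 100, seed = 1L, split = NULL) {
  fm <- feature_matrix(data)
  if (!is.null(split)) {
    bad <- intersect(rownames(fm), split$sample_id[split$cohort == "validation"])
    if (length(bad)) {
      abort(paste0("feature selection must only see discovery samples; validation rows supplied: ",
                   paste(head(bad, 5), collapse = ", ")))
    }
  }
  y <- labels_to_binary(labels, rownames(fm))
  n <- nrow(fm); p <- ncol(fm)
  n_features_grid <- pmin(n_features_grid, p)
  set.seed(seed)

  boots <- map(seq_len(n_boot), function(b) {
    repeat {
      inbag <- sort(sample.int(n, n, replace = TRUE))
      oob <- setdiff(seq_len(n), inbag)
      if (length(oob) && length(unique(y[inbag])) == 2 &&
          length(unique(y[oob])) == 2) {
        return(list(inbag = inbag, oob = oob))
      }
    }
  })
  if (any(!lengths(map(boots, "oob")))) abort("empty out-of-bag set")

  # pass 1: informativity ranking per penalty
  coef_sum <- matrix(0, length(penalty_grid), p,
                     dimnames = list(NULL, colnames(fm)))
  for (b in boots) {
    for (gi in seq_along(penalty_grid)) {
      fit <- ridge_logistic(fm[b$inbag, , drop = FALSE], y[b$inbag],
                            penalty_grid[gi])
      coef_sum[gi, ] <- coef_sum[gi, ] + abs(fit$beta)
    }
  }
  rankings <- map(seq_along(penalty_grid), function(gi) {
    colnames(fm)[order(coef_sum[gi, ], decreasing = TRUE)]
  })

  # pass 2: out-of-bag AUC per (penalty, n_features)
  grid <- tidyr::expand_grid(penalty = penalty_grid,
                             n_features = unique(n_features_grid))
  auc_mat <- matrix(0, nrow(grid), n_boot)
  for (bi in seq_along(boots)) {
    b <- boots[[bi]]
    for (gi in seq_len(nrow(grid))) {
      rk <- rankings[[match(grid$penalty[gi], penalty_grid)]]
      feats <- rk[seq_len(grid$n_features[gi])]
      fit <- ridge_logistic(fm[b$inbag, feats, drop = FALSE], y[b$inbag],
                            grid$penalty[gi])
      sc <- ridge_predict(fit, fm[b$oob, feats, drop = FALSE])
      auc_mat[gi, bi] <- roc_auc(sc, y[b$oob])$auc
    }
  }
  grid$mean_auc <- rowMeans(auc_mat)
  best <- grid |>
    arrange(dplyr::desc(.data$mean_auc), .data$n_features, .data$penalty) |>
    slice(1)

  structure(list(
    ranking = rankings[[match(best$penalty, penalty_grid)]],
    chosen_n = best$n_features,
    chosen_penalty = best$penalty,
    auc_grid = grid,
    n_boot = n_boot, seed = seed
  ), class = "lrs_selection")
}

#' @method tidy risk_model
#' @export
tidy.risk_model <- function(x, ...) {
  # coefficients on the original feature scale
  beta_orig <- x$beta / x$scale
  int_orig <- x$intercept - sum(x$center * beta_orig)
  tibble(
    term = c("(Intercept)", x$feature_names),
    estimate = c(int_orig, beta_orig),
    estimate_standardized = c(x$intercept, x$beta)
  )
}

#' @method glance risk_model
#' @export
glance.risk_model <- function(x, ...) {
  tibble(
    kind = x$kind, n_features = length(x$feature_names),
    l2_penalty = x$l2_penalty, threshold = x$threshold,
    n_train = x$training_meta$n_train %||% NA_integer_
  )
}

#' @method print risk_model
#' @export
print.risk_model <- function(x, ...) {
  cat(sprintf("<risk_model> %s: %d feature(s), penalty %.3g, threshold %.3f\n",
              x$kind, length(x$feature_names), x$l2_penalty, x$threshold))
  invisible(x)
}
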