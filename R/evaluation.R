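#' ROC curve and AUC
#'
#' AUC is the Mann-Whitney concordance of the score: the proportion of
#' (positive, negative) pairs in which the positive scores higher, with
#' half-credit for ties (computed via midranks). The curve enumerates every
#' unique score as a threshold (calls are score >= threshold).
#'
#' @param scores Numeric risk scores.
#' @param labels Binary labels (0/1 vector, logical, or sCAD label vector).
#' @return List of class `roc_result`: `auc`, `n_pos`, `n_neg`, and a
#'   `curve` tibble (threshold, sensitivity, specificity).
#' @export
roc_auc <- function(scores, labels) {
  y <- labels_to_binary_any(labels)
  stopifnot(length(scores) == length(y))
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) abort("both classes must be present")
  r <- rank(scores, ties.method = "average")
  auc <- (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)

  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  sens <- vapply(thr, function(t) mean(scores[y == 1] >= t), numeric(1))
  spec <- vapply(thr, function(t) mean(scores[y == 0] < t), numeric(1))
  structure(list(
    auc = auc, n_pos = n1, n_neg = n0,
    curve = tibble(threshold = thr, sensitivity = sens, specificity = spec)
  ), class = "roc_result")
}

labels_to_binary_any <- function(labels) {
  if (is.logical(labels)) return(as.integer(labels))
  if (is.numeric(labels) && all(labels %in% c(0, 1))) return(as.integer(labels))
  scad_binary(labels)
}

# Midrank placement values: for each positive, the fraction of negatives it
# outscores (ties half); and symmetrically for negatives.
delong_placements <- function(scores, y) {
  pos <- scores[y == 1]; neg <- scores[y == 0]
  n1 <- length(pos); n0 <- length(neg)
  v10 <- vapply(pos, function(x) (sum(x > neg) + 0.5 * sum(x == neg)) / n0,
                numeric(1))
  v01 <- vapply(neg, function(x) (sum(pos > x) + 0.5 * sum(pos == x)) / n1,
                numeric(1))
  list(v10 = v10, v01 = v01, auc = mean(v10))
}

#' DeLong's test for two correlated AUCs
#'
#' Compares the AUCs of two scores measured on the same samples using the
#' placement-value covariance estimator with midrank tie handling;
#' z = (auc_a - auc_b) / SE with a two-sided normal p-value. When the
#' variance of the difference is zero and the AUCs are equal (e.g. identical
#' scores), z = 0 and p = 1 by convention.
#'
#' @param scores_a,scores_b Paired score vectors.
#' @param labels Shared labels.
#' @return List of class `delong_result`: auc1, auc2, z, p, se.
#' @export
delong_test <- function(scores_a, scores_b, labels) {
  y <- labels_to_binary_any(labels)
  stopifnot(length(scores_a) == length(y), length(scores_b) == length(y))
  pa <- delong_placements(scores_a, y)
  pb <- delong_placements(scores_b, y)
  n1 <- sum(y == 1); n0 <- sum(y == 0)

  s10 <- stats::cov(cbind(pa$v10, pb$v10))
  s01 <- stats::cov(cbind(pa$v01, pb$v01))
  var_diff <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / n1 +
    (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / n0
  d <- pa$auc - pb$auc
  if (var_diff <= 0) {
    z <- if (abs(d) < 1e-12) 0 else sign(d) * Inf
  } else {
    z <- d / sqrt(var_diff)
  }
  structure(list(
    auc1 = pa$auc, auc2 = pb$auc, z = z,
    p = 2 * pnorm(-abs(z)), se = sqrt(max(var_diff, 0))
  ), class = "delong_result")
}

#' @method glance delong_result
#' @export
glance.delong_result <- function(x, ...) {
  tibble(auc1 = x$auc1, auc2 = x$auc2, z = x$z, p = x$p, se = x$se)
}

#' Per-stratum AUC of discovery-trained models on the validation cohort
#'
#' Predictions are computed once per model on the full validation data and
#' then partitioned by stratum; each (model, stratum) cell reports its AUC.
#' A cell whose stratum holds a single class is flagged and its AUC set
#' missing.
#'
#' @param models Named list of `risk_model` objects.
#' @param data Validation feature data passed to [predict_risk()] — either
#'   one object for all models or a named list parallel to `models`.
#' @param labels Labels for the validation samples.
#' @param strata Tibble with `sample_id` and `stratum`
#'   ([stratify_cohort()]); samples missing from it form no cell. A
#'   pseudo-stratum `all` covering every sample is always added.
#' @return Tibble: model, stratum, n, n_pos, auc, note.
#' @export
evaluate_subcohorts <- function(models, data, labels, strata = NULL) {
  stopifnot(is.list(models), length(names(models)) == length(models))
  preds <- imap(models, function(m, nm) {
    d <- if (is.list(data) && !is.data.frame(data)) data[[nm]] else data
    predict_risk(m, d)
  })

  first <- preds[[1]]
  y <- labels_to_binary(labels, first$sample_id)
  names(y) <- first$sample_id

  strata_tbl <- bind_rows(
    tibble(sample_id = first$sample_id, stratum = "all"),
    if (!is.null(strata)) strata |> filter(.data$sample_id %in% first$sample_id)
  )

  rows <- list()
  for (nm in names(preds)) {
    pr <- preds[[nm]]
    for (st in unique(strata_tbl$stratum)) {
      ids <- strata_tbl$sample_id[strata_tbl$stratum == st]
      i <- pr$sample_id %in% ids
      yy <- y[pr$sample_id[i]]
      if (length(unique(yy)) < 2) {
        rows[[length(rows) + 1]] <- tibble(
          model = nm, stratum = st, n = sum(i), n_pos = sum(yy == 1),
          auc = NA_real_, note = "single class")
      } else {
        rows[[length(rows) + 1]] <- tibble(
          model = nm, stratum = st, n = sum(i), n_pos = sum(yy == 1),
          auc = roc_auc(pr$risk[i], yy)$auc, note = "")
      }
    }
  }
  list_rbind(rows)
}

#' Cross-tabulate which model correctly calls each true sCAD+ sample
#'
#' Restricted to the truly sCAD+ samples, counts those correctly called by
#' both models, by the lipid score only, by the Framingham model only, and
#' by neither, with percentages (two significant digits) against the sCAD+
#' denominator.
#'
#' @param calls_lrs,calls_frs Logical call vectors on identical samples
#'   (e.g. the `call` column of [predict_risk()]).
#' @param labels Labels for those samples.
#' @return Tibble: category (both / lrs_only / frs_only / neither), n, pct.
#' @export
compare_model_targets <- function(calls_lrs, calls_frs, labels) {
  if (length(calls_lrs) != length(calls_frs)) abort("call vectors differ in length")
  y <- labels_to_binary_any(labels)
  if (length(y) != length(calls_lrs)) abort("labels length mismatch")
  pos <- y == 1
  a <- as.logical(calls_lrs)[pos] # correct call for a true positive = TRUE
  b <- as.logical(calls_frs)[pos]
  n <- sum(pos)
  counts <- c(both = sum(a & b), lrs_only = sum(a & !b),
              frs_only = sum(!a & b), neither = sum(!a & !b))
  pct <- if (n > 0) unname(signif(100 * counts / n, 2)) else rep(NA_real_, 4)
  tibble(category = names(counts), n = as.integer(counts), pct = pct)
}
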