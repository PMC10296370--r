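#' Principal-component diagnostics of unwanted and wanted variation
#'
#' Runs PCA on the column-centered lipid matrix and, for each of the first
#' `n_pcs` components, reports the variance explained and the coefficient of
#' determination (R^2) from regressing the PC score on batch (dummy-coded),
#' age and sex. Age/sex regressions use the rows where the covariate is
#' available (study samples); batch uses all rows.
#'
#' @param lipids Lipid table.
#' @param clinical Clinical tibble aligned with `lipids`.
#' @param n_pcs Number of leading components to report.
#' @return Tibble with columns `pc`, `var_explained`, `r2_batch`, `r2_age`,
#'   `r2_sex`.
#' @export
pca_diagnostics <- function(lipids, clinical, n_pcs = 30) {
  X <- lipid_values(lipids)
  if (nrow(X) < n_pcs + 1) abort("need at least n_pcs + 1 samples")
  clin <- clinical[match(rownames(X), clinical$sample_id), ]
  pc <- prcomp(X, center = TRUE, scale. = FALSE, rank. = n_pcs)
  scores <- pc$x
  ve <- (pc$sdev^2 / sum(pc$sdev^2))[seq_len(n_pcs)]

  r2_of <- function(score, v) {
    keep <- !is.na(v)
    vv <- v[keep]
    if (length(unique(vv)) < 2) {
      warn("constant variable in PC diagnostics; R^2 reported as 0")
      return(0)
    }
    summary(lm(score[keep] ~ factor(vv)))$r.squared
  }
  r2_num <- function(score, v) {
    keep <- !is.na(v)
    vv <- v[keep]
    if (length(unique(vv)) < 2) {
      warn("constant variable in PC diagnostics; R^2 reported as 0")
      return(0)
    }
    summary(lm(score[keep] ~ vv))$r.squared
  }

  tibble(
    pc = seq_len(n_pcs),
    var_explained = ve,
    r2_batch = map_dbl(seq_len(n_pcs), function(j) r2_of(scores[, j], clin$batch)),
    r2_age = map_dbl(seq_len(n_pcs), function(j) r2_num(scores[, j], clin$age)),
    r2_sex = map_dbl(seq_len(n_pcs), function(j) r2_of(scores[, j], clin$sex))
  )
}

#' Build pseudo-replicate groups for RUV-III
#'
#' Study samples are partitioned into `n_clusters` clinically homogeneous
#' groups by agglomerative hierarchical clustering (Ward linkage, Euclidean
#' distance on standardized age, sex, BMI, hypertension, current smoking,
#' diabetes and hypercholesterolemia). Each QC role present (pooled QC,
#' technical QC, blank, NIST1950) is appended as one additional replicate
#' group, so the default design with all four QC roles yields 84 groups.
#'
#' @param clinical Clinical tibble covering every sample that will enter
#'   [ruv3_fit()].
#' @param n_clusters Number of clinical clusters among study samples.
#' @return A list of class `replicate_structure` with the indicator matrix
#'   `M` (samples x groups, rows in `clinical` order) and a `groups` tibble.
#' @export
make_pseudo_replicates <- function(clinical, n_clusters = 80) {
  check_clinical_tbl(clinical)
  s <- clinical[clinical$role == "study", ]
  if (n_clusters > nrow(s)) abort("n_clusters exceeds the number of study samples")
  check_clinical_tbl(s, need_covariates = TRUE)

  Z <- cbind(
    scale(s$age), scale(s$bmi),
    as.numeric(s$sex == "M"),
    as.numeric(s$hypertension), as.numeric(s$current_smoking),
    as.numeric(s$diabetes), as.numeric(s$hypercholesterolemia)
  )
  Z[is.nan(Z)] <- 0 # constant covariate: contributes nothing to distance
  hc <- hclust(dist(Z), method = "ward.D2")
  cl <- cutree(hc, k = n_clusters)

  group <- setNames(paste0("clin_", cl), s$sample_id)
  qc <- clinical[clinical$role != "study", ]
  if (nrow(qc)) group <- c(group, setNames(paste0("qc_", qc$role), qc$sample_id))
  group <- group[clinical$sample_id]

  levels <- unique(group)
  M <- outer(group, levels, `==`) * 1
  dimnames(M) <- list(clinical$sample_id, levels)

  structure(list(
    M = M,
    groups = tibble(sample_id = clinical$sample_id, group = unname(group))
  ), class = "replicate_structure")
}

#' Select negative-control species for RUV-III
#'
#' Controls are species significantly associated with batch (one-way ANOVA
#' across batches, Benjamini-Hochberg FDR below `batch_fdr`) but not with
#' the biology of interest: the age regression and the sex t-test must both
#' have p above `bio_p`. Batch tests use every sample; age/sex tests use
#' study rows.
#'
#' @param lipids Lipid table.
#' @param clinical Aligned clinical tibble.
#' @param batch_fdr FDR threshold for the batch association.
#' @param bio_p Raw-p exclusion threshold for age and sex association.
#' @return Named integer vector of control column indices into the species
#'   columns, with a `tests` tibble attribute.
#' @export
select_control_features <- function(lipids, clinical, batch_fdr = 0.05,
                                    bio_p = 0.05) {
  X <- lipid_values(lipids)
  clin <- clinical[match(rownames(X), clinical$sample_id), ]
  if (length(unique(clin$batch)) < 2) abort("need at least 2 batches")
  batch <- factor(clin$batch)
  study <- clin$role == "study"

  p_batch <- apply(X, 2, function(x) anova(lm(x ~ batch))[["Pr(>F)"]][1])
  age <- clin$age[study]
  sexM <- clin$sex[study] == "M"
  Xs <- X[study, , drop = FALSE]
  p_age <- apply(Xs, 2, function(x) summary(lm(x ~ age))$coefficients[2, 4])
  p_sex <- apply(Xs, 2, function(x) t.test(x[sexM], x[!sexM])$p.value)

  fdr_batch <- bh_adjust(p_batch)
  keep <- fdr_batch < batch_fdr & p_age > bio_p & p_sex > bio_p
  if (!any(keep)) {
    abort("no control species found; relax batch_fdr and/or bio_p")
  }
  controls <- which(keep)
  attr(controls, "tests") <- tibble(
    species = colnames(X), p_batch = p_batch, fdr_batch = fdr_batch,
    p_age = p_age, p_sex = p_sex, control = keep
  )
  controls
}

ruv_w_from_alpha <- function(Yc_controls, alpha, controls) {
  ac <- alpha[, controls, drop = FALSE]
  G <- tcrossprod(ac) # k x k
  if (rcond(G) < 1e-12) {
    abort("alpha restricted to controls is numerically singular; try a smaller k or more controls")
  }
  Yc_controls %*% t(ac) %*% solve(G)
}

#' Fit RUV-III using pseudo-replicates and negative controls
#'
#' With the column-centered matrix Y, the unwanted-variation coefficients
#' are estimated from the replicate-residual space: Y0 = Y minus replicate
#' group means; alpha = U' Y with U the top-k left singular vectors of Y0;
#' the per-sample scores are W = Y_c alpha_c' (alpha_c alpha_c')^-1 using
#' only control species; the adjusted data are Y - W alpha with the column
#' means added back.
#'
#' @param lipids Lipid table (all samples entering the fit, QC included).
#' @param replicates A [make_pseudo_replicates()] result (or an indicator
#'   matrix over the same samples).
#' @param controls Control column indices from [select_control_features()].
#' @param k Number of unwanted-variation factors.
#' @return A list with `model` (class `ruv_model`: `alpha`, `k`, `controls`,
#'   `feature_means`, `species`) and `adjusted` (lipid table).
#' @export
ruv3_fit <- function(lipids, replicates, controls, k = 8) {
  X <- lipid_values(lipids)
  M <- if (inherits(replicates, "replicate_structure")) replicates$M else replicates
  if (!all(rownames(M) == rownames(X))) {
    M <- M[match(rownames(X), rownames(M)), , drop = FALSE]
    if (anyNA(M)) abort("replicate structure does not cover all lipid samples")
  }
  if (any(rowSums(M) != 1) || any(colSums(M) == 0)) {
    abort("replicate membership matrix must have unit row sums and nonempty groups")
  }
  if (!length(controls)) abort("controls must be nonempty")
  max_k <- min(nrow(X) - ncol(M), ncol(X))
  if (k < 1 || k > max_k) {
    abort(paste0("k must be between 1 and the residual rank (", max_k, ")"))
  }

  feature_means <- colMeans(X)
  Y <- sweep(X, 2, feature_means)
  group <- max.col(M)
  Y0 <- Y - apply(Y, 2, function(col) ave(col, group))
  U <- svd(Y0, nu = k, nv = 0)$u
  alpha <- crossprod(U, Y) # k x p
  W <- ruv_w_from_alpha(Y[, controls, drop = FALSE], alpha, controls)
  adj <- Y - W %*% alpha
  adj <- sweep(adj, 2, feature_means, `+`)

  model <- structure(list(
    alpha = alpha, k = k, controls = controls,
    feature_means = feature_means, species = colnames(X)
  ), class = "ruv_model")
  list(model = model, adjusted = set_lipid_values(lipids, adj), W = W)
}

#' Apply a frozen RUV-III model to a new cohort
#'
#' Centers the new matrix, estimates the new samples' unwanted-variation
#' scores W from the stored alpha restricted to the control species, removes
#' W alpha, and adds the feature-wise means back. By default the new
#' cohort's own column means are used for centering and restoration
#' (`means = "new"`); `means = "stored"` uses the discovery means frozen in
#' the model.
#'
#' @param lipids Lipid table of the new cohort (same species, same order).
#' @param model A `ruv_model` from [ruv3_fit()].
#' @param means Which feature-wise means to center with and restore.
#' @return Adjusted lipid table.
#' @export
ruv3_transfer <- function(lipids, model, means = c("new", "stored")) {
  means <- match.arg(means)
  stopifnot(inherits(model, "ruv_model"))
  X <- lipid_values(lipids)
  if (!identical(colnames(X), model$species)) {
    extra <- setdiff(colnames(X), model$species)
    missing <- setdiff(model$species, colnames(X))
    abort(paste0("species mismatch with fitted model; missing: ",
                 paste(head(missing, 5), collapse = ", "), "; extra: ",
                 paste(head(extra, 5), collapse = ", ")))
  }
  mu <- if (means == "new") colMeans(X) else model$feature_means
  Y <- sweep(X, 2, mu)
  W <- ruv_w_from_alpha(Y[, model$controls, drop = FALSE], model$alpha,
                        model$controls)
  adj <- Y - W %*% model$alpha
  adj <- sweep(adj, 2, mu, `+`)
  set_lipid_values(lipids, adj)
}
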