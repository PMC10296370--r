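#' Individual classifiability scores from repeated cross-validation
#'
#' For each of `r` repeats, samples are split into `f` stratified folds
#' (class-balanced); a ridge logistic model on the supplied features is
#' fitted to the training folds and the held-out fold is binary-predicted,
#' so every sample is predicted exactly once per repeat. A sample's
#' individual classifiability score (ICS) is its proportion of correct
#' predictions over the repeats. Samples are processed in canonical
#' `sample_id` order so the result is invariant to input row order; repeat
#' i uses seed `seed + i`.
#'
#' @param data Discovery lipid table (or feature tibble/matrix).
#' @param labels Labels aligned with `data`.
#' @param features Feature names for the model (e.g. the selected top
#'   species).
#' @param penalty Ridge penalty.
#' @param r Number of repeats (default 50, so scores are multiples of 1/50).
#' @param f Number of folds.
#' @param seed Base RNG seed.
#' @param threshold "youden": calls use the training-fold Youden cut;
#'   "half": probability 0.5.
#' @return Tibble of class `ics_result` with `sample_id` and `ics` in
#'   \[0, 1\]; repeats/folds/model spec kept as attributes.
#' @export
compute_ics <- function(data, labels, features = NULL, penalty = 1,
                        r = 50, f = 5, seed = 1L,
                        threshold = c("youden", "half")) {
  threshold <- match.arg(threshold)
  fm <- feature_matrix(data, features)
  y <- labels_to_binary(labels, rownames(fm)) # aligned with input row order
  ord <- order(rownames(fm))
  fm <- fm[ord, , drop = FALSE]
  y <- y[ord]
  n <- nrow(fm)
  if (min(table(y)) < f) abort("each class must have at least f members")

  correct <- integer(n)
  for (rep_i in seq_len(r)) {
    set.seed(seed + rep_i)
    fold <- integer(n)
    ok <- FALSE
    for (attempt in 1:10) {
      for (cls in c(0, 1)) {
        idx <- which(y == cls)
        fold[idx] <- sample(rep_len(seq_len(f), length(idx)))
      }
      train_ok <- vapply(seq_len(f), function(k) {
        length(unique(y[fold != k])) == 2
      }, logical(1))
      if (all(train_ok)) { ok <- TRUE; break }
    }
    if (!ok) abort("could not draw folds with both classes in every training set")
    for (k in seq_len(f)) {
      tr <- fold != k
      fit <- ridge_logistic(fm[tr, , drop = FALSE], y[tr], penalty)
      cut <- if (threshold == "youden") {
        youden_threshold(ridge_predict(fit, fm[tr, , drop = FALSE]), y[tr])
      } else 0.5
      pred <- ridge_predict(fit, fm[!tr, , drop = FALSE]) >= cut
      correct[!tr] <- correct[!tr] + as.integer(pred == (y[!tr] == 1))
    }
  }

  out <- tibble(sample_id = rownames(fm), ics = correct / r)
  attr(out, "n_repeats") <- r
  attr(out, "n_folds") <- f
  attr(out, "model_spec") <- list(penalty = penalty,
                                  n_features = ncol(fm),
                                  threshold = threshold)
  class(out) <- c("ics_result", class(out))
  out
}

#' Scan clinical candidates for the classifiability-modifying variable
#'
#' One linear regression per candidate: ICS ~ candidate + age + sex. The
#' candidate with the smallest coefficient p-value is the winner — the
#' covariate whose level most alters how well the lipidome classifies a
#' participant.
#'
#' @param ics [compute_ics()] result.
#' @param clinical Clinical tibble.
#' @param candidates Candidate column names.
#' @return Tibble of class `modifier_scan`: candidate, estimate, p, winner
#'   flag; winner name kept as an attribute.
#' @export
find_modifying_variable <- function(ics, clinical,
                                    candidates = c("bmi", "hypertension",
                                                   "hypercholesterolemia")) {
  missing <- setdiff(candidates, names(clinical))
  if (length(missing)) {
    abort(paste0("candidate(s) not in clinical table: ",
                 paste(missing, collapse = ", ")))
  }
  d <- ics |>
    inner_join(clinical[c("sample_id", "age", "sex", candidates)],
               by = "sample_id")

  rows <- map(candidates, function(cand) {
    v <- d[[cand]]
    if (is.logical(v)) v <- as.numeric(v)
    if (length(unique(v[!is.na(v)])) < 2) {
      warn(paste0("candidate '", cand, "' is constant; skipped"))
      return(NULL)
    }
    fit <- lm(d$ics ~ v + d$age + factor(d$sex))
    co <- summary(fit)$coefficients
    tibble(candidate = cand, estimate = co["v", "Estimate"],
           p = co["v", "Pr(>|t|)"])
  })
  out <- list_rbind(rows[!map_lgl(rows, is.null)])
  if (!nrow(out)) abort("no usable candidate variables")
  out <- out |> mutate(winner = .data$p == min(.data$p))
  attr(out, "winner") <- out$candidate[out$winner][1]
  class(out) <- c("modifier_scan", class(out))
  out
}

#' Stratify a cohort on a clinical variable
#'
#' Splits samples at a cutoff (default BMI 25 kg/m2, the conventional
#' overweight boundary): values below the cutoff go to the low group,
#' values at or above it to the high group. Samples with a missing value
#' are dropped with a warning.
#'
#' @param clinical Clinical tibble (study rows are used).
#' @param variable Numeric clinical column to split on.
#' @param cutoff Boundary value (assigned to the high group).
#' @return Tibble with `sample_id` and `stratum` ("low"/"high").
#' @export
stratify_cohort <- function(clinical, variable = "bmi", cutoff = 25) {
  if (!variable %in% names(clinical)) {
    abort(paste0("variable '", variable, "' not in clinical table"))
  }
  s <- clinical[clinical$role == "study", ]
  v <- s[[variable]]
  if (is.logical(v)) v <- as.numeric(v)
  if (!is.numeric(v)) abort("stratification variable must be numeric")
  if (anyNA(v)) {
    warn(paste0(sum(is.na(v)), " sample(s) with missing ", variable, " excluded"))
  }
  tibble(sample_id = s$sample_id, value = v) |>
    filter(!is.na(.data$value)) |>
    mutate(stratum = if_else(.data$value < cutoff, "low", "high")) |>
    select("sample_id", "stratum")
}
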