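test_that("framingham_risk matches the frozen reference-profile value", {
  # 60-year-old male, TC 5.0 mmol/L, HDL 1.2 mmol/L, SBP 130 untreated,
  # non-smoker, non-diabetic; value computed once by an independent hand
  # implementation of the published equation and frozen here
  ref <- manual_clinical(1, age = 60, sex = "M")
  ref$tc <- 5.0; ref$hdl <- 1.2; ref$sbp <- 130
  expect_equal(framingham_risk(ref), 0.1462818415, tolerance = 1e-8)
})

test_that("framingham_risk is monotone in age and bounded in (0,1)", {
  ages <- seq(35, 70, by = 5)
  clin <- manual_clinical(length(ages), age = ages)
  r <- framingham_risk(clin)
  expect_true(all(diff(r) > 0))

  set.seed(60)
  n <- 10000
  rand <- manual_clinical(n, age = runif(n, 30, 74),
                          sex = sample(c("F", "M"), n, TRUE))
  rand$sbp <- runif(n, 95, 185); rand$tc <- runif(n, 3, 8)
  rand$hdl <- runif(n, 0.6, 2.5)
  rand$current_smoking <- runif(n) < 0.3
  rand$diabetes <- runif(n) < 0.2
  rand$hypertension <- runif(n) < 0.4
  r <- framingham_risk(rand)
  expect_true(all(r > 0 & r < 1))
})

test_that("framingham_risk validates input and clamps extreme ages", {
  clin <- manual_clinical(2, age = c(25, 90))
  expect_warning(r <- framingham_risk(clin), "clamped")
  clamped <- framingham_risk(manual_clinical(2, age = c(30, 74)))
  expect_equal(r, clamped)
  expect_error(framingham_risk(manual_clinical(1)[, setdiff(names(clin), "hdl")]),
               "hdl")
})

# small separable-ish two-feature problem shared by several tests
toy_problem <- function(n = 300, seed = 61, delta = 1.5) {
  set.seed(seed)
  y <- rep(0:1, each = n / 2)
  X <- cbind(f1 = rnorm(n) + delta * y, f2 = rnorm(n) - delta / 2 * y)
  rownames(X) <- sprintf("S%04d", seq_len(n))
  list(X = X, y = y)
}

test_that("a tiny penalty reproduces the unpenalized maximum likelihood fit", {
  tp <- toy_problem()
  m <- fit_ridge_logistic(tp$X, tp$y, penalty = 1e-6)
  # independent oracle: Newton-Raphson via glm on the standardized features
  Z <- scale(tp$X)
  or <- glm(tp$y ~ Z, family = binomial())
  expect_equal(unname(m$beta), unname(coef(or)[-1]), tolerance = 1e-3)
  expect_equal(m$intercept, unname(coef(or)[1]), tolerance = 1e-3)
})

test_that("ridge coefficients agree with glmnet at matched penalty", {
  skip_if_not_installed("glmnet")
  tp <- toy_problem(n = 200, seed = 62)
  pen <- 5
  m <- fit_ridge_logistic(tp$X, tp$y, penalty = pen)
  # glmnet minimises -loglik/n + lambda/2 * ||b||^2 on standardized x
  g <- glmnet::glmnet(scale(tp$X), tp$y, family = "binomial", alpha = 0,
                      lambda = pen / 200, standardize = FALSE,
                      thresh = 1e-12)
  expect_equal(unname(m$beta), unname(as.numeric(g$beta)), tolerance = 1e-3)
})

test_that("extreme shrinkage collapses to the prevalence model", {
  tp <- toy_problem()
  m <- fit_ridge_logistic(tp$X, tp$y, penalty = 1e9)
  expect_lt(max(abs(m$beta)), 1e-5)
  pr <- predict_risk(m, tp$X)
  expect_equal(unique(round(pr$risk, 6)), round(mean(tp$y), 6))
})

test_that("the coefficient norm is non-increasing along the penalty path", {
  tp <- toy_problem()
  norms <- vapply(10^seq(-2, 3), function(pen) {
    sqrt(sum(fit_ridge_logistic(tp$X, tp$y, penalty = pen)$beta^2))
  }, numeric(1))
  expect_true(all(diff(norms) <= 1e-8))
})

test_that("planted log-odds effects are recovered as the penalty vanishes", {
  set.seed(63)
  n <- 5000
  X <- cbind(a = rnorm(n), b = rnorm(n))
  rownames(X) <- sprintf("S%05d", 1:n)
  beta_true <- c(0.7, -0.4)
  y <- rbinom(n, 1, plogis(-0.3 + X %*% beta_true))
  m <- fit_ridge_logistic(X, as.numeric(y), penalty = 1e-6)
  se <- coef(summary(glm(y ~ X, family = binomial())))[-1, "Std. Error"]
  beta_orig <- tidy(m)$estimate[-1]
  expect_lt(abs(beta_orig[1] - 0.7), 2 * se[1])
  expect_lt(abs(beta_orig[2] + 0.4), 2 * se[2])
})

test_that("training on a separable toy gives near-perfect training AUC", {
  tp <- toy_problem(delta = 4)
  m <- fit_ridge_logistic(tp$X, tp$y, penalty = 0.1)
  pr <- predict_risk(m, tp$X)
  expect_gt(roc_auc(pr$risk, tp$y)$auc, 0.95)
  expect_identical(pr$risk, predict_risk(m, tp$X)$risk)
})

test_that("the FRS model score is a monotone transform of the raw FRS", {
  set.seed(64)
  frs <- runif(80, 0.02, 0.6)
  names(frs) <- sprintf("S%03d", 1:80)
  y <- rbinom(80, 1, frs)
  m <- fit_frs_model(frs, as.numeric(y))
  pr <- predict_risk(m, tibble::tibble(sample_id = names(frs), frs = frs))
  expect_equal(order(pr$risk), order(frs))
  expect_equal(roc_auc(pr$risk, y)$auc, roc_auc(frs, y)$auc)
})

test_that("combined model tracks FRS when lipids are pure noise and never
           loses much when lipids carry signal", {
  set.seed(65)
  n <- 400
  frs <- runif(n, 0.02, 0.6); names(frs) <- sprintf("S%04d", 1:n)
  y <- rbinom(n, 1, frs)
  noise <- matrix(rnorm(n * 20), n, 20,
                  dimnames = list(names(frs), paste0("l", 1:20)))
  mc <- fit_combined(noise, frs, as.numeric(y), penalty = 10)
  mf <- fit_frs_model(frs, as.numeric(y))
  newdat <- dplyr::bind_cols(tibble::tibble(sample_id = names(frs), frs = frs),
                             tibble::as_tibble(noise))
  auc_c <- roc_auc(predict_risk(mc, newdat)$risk, y)$auc
  auc_f <- roc_auc(predict_risk(mf, newdat)$risk, y)$auc
  expect_gt(auc_c, auc_f - 0.05)

  signal <- noise + outer(y, c(rep(1, 5), rep(0, 15)))
  mc2 <- fit_combined(signal, frs, as.numeric(y), penalty = 10)
  newdat2 <- dplyr::bind_cols(tibble::tibble(sample_id = names(frs), frs = frs),
                              tibble::as_tibble(signal))
  expect_gte(roc_auc(predict_risk(mc2, newdat2)$risk, y)$auc, auc_f - 0.01)
})

test_that("bootstrap selection finds a dominant informative species", {
  first <- vapply(1:10, function(i) {
    set.seed(200 + i)
    n <- 150
    y <- rep(0:1, each = n / 2)
    X <- matrix(rnorm(n * 100), n, 100,
                dimnames = list(sprintf("S%04d", 1:n), paste0("l", 1:100)))
    X[, 1] <- X[, 1] + 2 * y
    sel <- select_lrs_features(X, y, penalty_grid = 1,
                               n_features_grid = c(5, 10), n_boot = 8,
                               seed = 300 + i)
    sel$ranking[1] == "l1"
  }, logical(1))
  expect_gte(mean(first), 0.9)
})

test_that("selection is deterministic, honours a one-point grid and refuses
           validation samples", {
  set.seed(66)
  n <- 80
  y <- rep(0:1, each = n / 2)
  X <- matrix(rnorm(n * 30), n, 30,
              dimnames = list(sprintf("S%04d", 1:n), paste0("l", 1:30)))
  s1 <- select_lrs_features(X, y, penalty_grid = c(1, 10),
                            n_features_grid = 10, n_boot = 5, seed = 7)
  s2 <- select_lrs_features(X, y, penalty_grid = c(1, 10),
                            n_features_grid = 10, n_boot = 5, seed = 7)
  expect_identical(s1$ranking, s2$ranking)
  expect_identical(s1$chosen_penalty, s2$chosen_penalty)

  s3 <- select_lrs_features(X, y, penalty_grid = 2, n_features_grid = 8,
                            n_boot = 4, seed = 7)
  expect_equal(s3$chosen_penalty, 2)
  expect_equal(s3$chosen_n, 8)

  split <- tibble::tibble(sample_id = rownames(X),
                          cohort = rep(c("discovery", "validation"), each = n / 2))
  expect_error(
    select_lrs_features(X, y, penalty_grid = 1, n_features_grid = 5,
                        n_boot = 4, seed = 7, split = split),
    "validation"
  )
})

test_that("tidy and glance expose interpretable model summaries", {
  tp <- toy_problem(n = 100, seed = 67)
  m <- fit_ridge_logistic(tp$X, tp$y, penalty = 1)
  td <- tidy(m)
  expect_equal(td$term, c("(Intercept)", "f1", "f2"))
  # original-scale coefficients reproduce the standardized-scale predictions
  eta <- td$estimate[1] + as.matrix(tp$X) %*% td$estimate[-1]
  expect_equal(plogis(drop(eta)), predict_risk(m, tp$X)$risk, tolerance = 1e-10)
  g <- glance(m)
  expect_equal(g$kind, "LRS")
  expect_equal(g$n_features, 2)
})
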