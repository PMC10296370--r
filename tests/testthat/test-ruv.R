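test_that("pca_diagnostics reports R^2 = 1 for a pure batch component", {
  set.seed(1)
  n <- 60; p <- 20
  batch <- rep(c(-1, 1), each = n / 2)
  # dominant direction exactly equal to the batch contrast
  X <- outer(batch, rnorm(p, 0, 3)) + matrix(rnorm(n * p, 0, 0.01), n, p)
  colnames(X) <- paste0("s", seq_len(p))
  lip <- manual_lipids(X, batch = ifelse(batch < 0, "B1", "B2"))
  clin <- manual_clinical(n)
  clin$batch <- lip$batch
  d <- pca_diagnostics(lip, clin, n_pcs = 5)
  expect_equal(nrow(d), 5)
  expect_gt(d$r2_batch[1], 0.999)
})

test_that("null batch R^2 matches its random-regression expectation", {
  set.seed(2)
  n <- 500; p <- 40
  X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("s", 1:p)))
  lip <- manual_lipids(X, batch = rep(c("B1", "B2"), each = n / 2))
  clin <- manual_clinical(n); clin$batch <- lip$batch
  d <- pca_diagnostics(lip, clin, n_pcs = 30)
  # regressing an arbitrary PC on an unrelated 2-level factor:
  # E[R^2] = (B - 1)/(n - 1)
  expect_lt(mean(d$r2_batch), 0.02)
  expect_equal(nrow(d), 30)
})

test_that("constant covariates get R^2 = 0 with a warning", {
  set.seed(3)
  X <- matrix(rnorm(40 * 6), 40, 6, dimnames = list(NULL, paste0("s", 1:6)))
  lip <- manual_lipids(X)
  clin <- manual_clinical(40) # constant sex and batch
  expect_warning(d <- pca_diagnostics(lip, clin, n_pcs = 3), "constant")
  expect_true(all(d$r2_sex == 0))
})

test_that("pseudo-replicates form 80 clinical clusters plus one group per QC role", {
  cfg <- tiny_config(n_study = 300, seed = 7)
  clin <- simulate_clinical(cfg)
  reps <- make_pseudo_replicates(clin, n_clusters = 80)
  expect_equal(ncol(reps$M), 84)
  expect_true(all(rowSums(reps$M) == 1))
  expect_true(all(colSums(reps$M) >= 1))
  expect_equal(nrow(reps$M), nrow(clin))
  # QC roles are their own groups
  qc_groups <- unique(grep("^qc_", reps$groups$group, value = TRUE))
  expect_length(qc_groups, 4)
  expect_error(make_pseudo_replicates(clin, n_clusters = 10000), "exceeds")
})

test_that("duplicate clinical profiles land in the same cluster", {
  clin <- manual_clinical(40, age = rep(c(40, 50, 60, 70), each = 10),
                          bmi = rep(c(20, 24, 28, 32), each = 10))
  reps <- make_pseudo_replicates(clin, n_clusters = 4)
  g <- reps$groups$group
  expect_equal(length(unique(g[1:10])), 1)
  expect_equal(length(unique(g[31:40])), 1)
})

test_that("control selection keeps batch-driven species and drops biology", {
  set.seed(4)
  n <- 200
  clin <- manual_clinical(n, age = runif(n, 40, 80),
                          sex = rep(c("F", "M"), n / 2),
                          batch = rep(c("B1", "B2"), each = n / 2))
  b <- as.numeric(clin$batch == "B2")
  X <- cbind(
    pure_batch = 2 * b + rnorm(n, 0, 0.3),
    age_and_batch = 2 * b + 0.05 * clin$age + rnorm(n, 0, 0.3),
    pure_noise = rnorm(n)
  )
  rownames(X) <- clin$sample_id
  lip <- manual_lipids(X, batch = clin$batch)
  ctrl <- select_control_features(lip, clin)
  expect_true(1 %in% ctrl)
  expect_false(2 %in% ctrl)
  expect_false(3 %in% ctrl)
})

test_that("control selection controls false positives on an all-noise matrix", {
  # under the global null the BH step rejects rarely; averaged over
  # repetitions almost no species pass the batch-FDR gate
  selected <- vapply(1:8, function(i) {
    set.seed(100 + i)
    n <- 120; p <- 600
    clin <- manual_clinical(n, age = runif(n, 40, 80),
                            sex = rep(c("F", "M"), n / 2),
                            batch = rep(c("B1", "B2", "B3"), each = n / 3))
    X <- matrix(rnorm(n * p), n, p, dimnames = list(clin$sample_id, paste0("s", 1:p)))
    lip <- manual_lipids(X, batch = clin$batch)
    out <- tryCatch(select_control_features(lip, clin), error = function(e) integer())
    length(out)
  }, numeric(1))
  expect_lt(mean(selected), 1)
})

# shared synthetic cohort with planted batch structure for the RUV tests
ruv_fixture <- function(seed = 31, batch_sd = 0.5, n_species = 80, ...) {
  cfg <- tiny_config(seed = seed, n_study = 250, n_species = n_species,
                     batch_sd = batch_sd, ...)
  sim <- simulate_cohort(cfg)
  reps <- make_pseudo_replicates(sim$clinical, n_clusters = 40)
  list(cfg = cfg, sim = sim, reps = reps)
}

test_that("ruv3_fit is near the identity when there is no unwanted variation", {
  # default cohort scale: the k removed directions and the score-estimation
  # noise are a few percent of the data norm
  cfg <- sim_config(batch_sd = 0, seed = 31)
  sim <- suppressWarnings(simulate_cohort(cfg))
  reps <- make_pseudo_replicates(sim$clinical, n_clusters = 80)
  ctrl <- seq_len(300) # any species work as controls without batch effects
  fit <- ruv3_fit(sim$lipids, reps, ctrl, k = 8)
  X <- lipid_values(sim$lipids); A <- lipid_values(fit$adjusted)
  expect_lt(norm(A - X, "F") / norm(X, "F"), 0.05)
})

test_that("ruv3_fit recovers the planted batch subspace with true controls", {
  fx <- ruv_fixture(seed = 32)
  sim <- fx$sim
  true_ctrl <- which(!lipid_species(sim$lipids) %in% sim$truth$informative_species)
  fit <- ruv3_fit(sim$lipids, fx$reps, true_ctrl, k = 3)
  # principal angle between row spaces of alpha and the planted loadings
  L <- sim$truth$batch_loadings
  Lc <- sweep(L, 2, colMeans(L)) # batch contrasts span a 2-D space
  q1 <- qr.Q(qr(t(fit$model$alpha)))
  q2 <- qr.Q(qr(t(Lc)))[, 1:2]
  cosines <- svd(crossprod(q1, q2))$d
  angle_deg <- acos(min(pmin(cosines, 1))) * 180 / pi
  expect_lt(angle_deg, 10)
})

test_that("normalization reduces batch R^2 and at most k directions are removed", {
  fx <- ruv_fixture(seed = 33)
  sim <- fx$sim
  ctrl <- select_control_features(sim$lipids, sim$clinical)
  k <- 8
  fit <- ruv3_fit(sim$lipids, fx$reps, ctrl, k = k)
  pre <- pca_diagnostics(sim$lipids, sim$clinical, n_pcs = 20)
  post <- pca_diagnostics(fit$adjusted, sim$clinical, n_pcs = 20)
  expect_lt(max(post$r2_batch), max(pre$r2_batch))

  X <- lipid_values(sim$lipids); A <- lipid_values(fit$adjusted)
  D <- sweep(X, 2, colMeans(X)) - sweep(A, 2, colMeans(A))
  expect_lte(sum(svd(D)$d > 1e-8), k)
})

test_that("batch R^2 reduction is monotone in k on planted batch structure", {
  fx <- ruv_fixture(seed = 34)
  sim <- fx$sim
  ctrl <- select_control_features(sim$lipids, sim$clinical)
  # three batches span a rank-2 unwanted subspace, so the guaranteed
  # improvement runs up to the true k = 2
  r2 <- vapply(0:2, function(k) {
    if (k == 0) return(max(pca_diagnostics(sim$lipids, sim$clinical,
                                           n_pcs = 10)$r2_batch))
    fit <- ruv3_fit(sim$lipids, fx$reps, ctrl, k = k)
    max(pca_diagnostics(fit$adjusted, sim$clinical, n_pcs = 10)$r2_batch)
  }, numeric(1))
  expect_true(all(diff(r2) <= 1e-8))
})

test_that("adjustment shrinks pooled-QC within-group variance", {
  fx <- ruv_fixture(seed = 35)
  sim <- fx$sim
  ctrl <- select_control_features(sim$lipids, sim$clinical)
  fit <- ruv3_fit(sim$lipids, fx$reps, ctrl, k = 8)
  qc_var <- function(lip) {
    m <- lipid_values(lip[lip$role == "pooled_qc", ])
    mean(apply(m, 2, var))
  }
  expect_lt(qc_var(fit$adjusted), qc_var(sim$lipids))
})

test_that("ruv3_transfer is self-consistent and mean-preserving", {
  fx <- ruv_fixture(seed = 36, n_species = 250)
  sim <- fx$sim
  ctrl <- select_control_features(sim$lipids, sim$clinical)
  fit <- ruv3_fit(sim$lipids, fx$reps, ctrl, k = 8)

  # applying the frozen model to the fitting data reproduces the fit output
  back <- ruv3_transfer(sim$lipids, fit$model)
  expect_lt(max(abs(lipid_values(back) - lipid_values(fit$adjusted))), 1e-8)

  # new cohort without batch structure passes through nearly unchanged
  cfg0 <- tiny_config(seed = 37, n_study = 120, n_species = 250, batch_sd = 0)
  new <- simulate_cohort(cfg0)$lipids
  adj <- ruv3_transfer(new, fit$model)
  Xn <- lipid_values(new); An <- lipid_values(adj)
  # k noise directions plus score-estimation noise are removed; their
  # energy is small next to the data scale
  expect_lt(norm(An - Xn, "F") / norm(Xn, "F"), 0.1)
  # feature-wise means restored exactly
  expect_equal(colMeans(An), colMeans(Xn), tolerance = 1e-12)

  # species mismatch errors with the offending names
  bad <- new
  names(bad)[names(bad) == "lipid_001"] <- "other_species"
  expect_error(ruv3_transfer(bad, fit$model), "lipid_001")
})

test_that("replicate matrices and k are validated", {
  fx <- ruv_fixture(seed = 38)
  sim <- fx$sim
  expect_error(ruv3_fit(sim$lipids, fx$reps, integer(), k = 2), "nonempty")
  expect_error(ruv3_fit(sim$lipids, fx$reps, 1:10, k = 10000), "k must be")
})
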