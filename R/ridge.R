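# Ridge-penalised logistic regression by iteratively reweighted least
# squares. Maximises l(beta) - penalty * ||beta_-0||^2 / 2 with the
# intercept unpenalised; features are standardised internally and the
# transform kept so coefficients can be reported on either scale.
# Convergence is declared when the max-norm of the penalised-likelihood
# gradient falls below `tol`. For p > n the weighted normal equations are
# solved in the n-dimensional dual space.
ridge_logistic <- function(X, y, penalty, tol = 1e-6, max_iter = 100,
                           standardize = TRUE) {
  X <- as.matrix(X)
  stopifnot(length(y) == nrow(X), all(y %in% c(0, 1)))
  check_nonneg(penalty, "penalty")
  n <- nrow(X); p <- ncol(X)

  if (standardize) {
    center <- colMeans(X)
    scale_ <- apply(X, 2, sd)
    scale_[scale_ == 0] <- 1
  } else {
    center <- rep(0, p); scale_ <- rep(1, p)
  }
  Z <- sweep(sweep(X, 2, center), 2, scale_, `/`)

  beta <- rep(0, p)
  b0 <- qlogis(mean(pmin(pmax(mean(y), 1e-6), 1 - 1e-6)))
  grad_norm <- Inf
  for (iter in seq_len(max_iter)) {
    eta <- drop(b0 + Z %*% beta)
    mu <- plogis(eta)
    g <- c(sum(y - mu), drop(crossprod(Z, y - mu)) - penalty * beta)
    grad_norm <- max(abs(g))
    if (grad_norm <= tol) break
    w <- pmax(mu * (1 - mu), 1e-10)
    z_work <- eta + (y - mu) / w
    # weighted ridge solve with unpenalised intercept
    sw <- sum(w)
    zb <- drop(crossprod(Z, w)) / sw      # weighted column means of Z
    zw <- sum(w * z_work) / sw
    Zc <- sweep(Z, 2, zb)
    rc <- z_work - zw
    if (p <= n || penalty < 1e-8) {
      A <- crossprod(Zc, Zc * w) + diag(penalty, p)
      beta <- drop(solve(A, crossprod(Zc, w * rc)))
    } else {
      # dual solve: (A'A + lI)^-1 A' = A'(AA' + lI)^-1 with A = W^(1/2) Zc
      Zw <- Zc * sqrt(w)
      K <- tcrossprod(Zw) + diag(penalty, n)
      beta <- drop(crossprod(Zw, solve(K, sqrt(w) * rc)))
    }
    b0 <- zw - sum(zb * beta)
  }
  if (grad_norm > tol) {
    eta <- drop(b0 + Z %*% beta)
    mu <- plogis(eta)
    g <- c(sum(y - mu), drop(crossprod(Z, y - mu)) - penalty * beta)
    grad_norm <- max(abs(g))
  }
  if (grad_norm > tol) {
    abort(sprintf(
      "ridge logistic IRLS did not converge: %d iterations, gradient max-norm %.3g (tol %.3g)",
      max_iter, grad_norm, tol))
  }
  list(intercept = b0, beta = beta, center = center, scale = scale_,
       penalty = penalty, iter = iter, grad_norm = grad_norm,
       feature_names = colnames(X))
}

ridge_predict <- function(fit, X) {
  X <- as.matrix(X)
  Z <- sweep(sweep(X, 2, fit$center), 2, fit$scale, `/`)
  plogis(drop(fit$intercept + Z %*% fit$beta))
}
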