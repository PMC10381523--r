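# Independent oracles used across tests.

# Ordinary least squares with intercept via the normal equations.
ols_oracle <- function(X, y) {
  Z <- cbind(1, X)
  beta <- solve(crossprod(Z), crossprod(Z, y))
  list(intercept = beta[1L], coefficients = drop(beta[-1L]))
}

# Pearson r from the covariance definition, no stats::cor.
pearson_oracle <- function(a, b) {
  da <- a - mean(a); db <- b - mean(b)
  sum(da * db) / sqrt(sum(da^2) * sum(db^2))
}

# Naive leave-one-out RMSE: refit from scratch for every row and A.
loo_rmse_oracle <- function(X, y, A, scale = TRUE) {
  pred <- vapply(seq_along(y), function(i) {
    fit <- pls_fit(X[-i, , drop = FALSE], y[-i], ncomp = A, scale = scale,
                   allow_constant = TRUE)
    predict(fit, X[i, , drop = FALSE])
  }, numeric(1))
  sqrt(mean((pred - y)^2))
}

# Random full-rank regression instance.
random_instance <- function(seed, n = 8, p = 3) {
  withr::with_seed(seed, {
    X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("x", 1:p)))
    y <- rnorm(n)
    list(X = X, y = y)
  })
}

# The printed all-grafts equation, used as a fixed affine evaluator.
published_eq4 <- function() {
  structure(list(intercept = 58.14,
                 coefficients = c(caco3_wt = 3.6, ti_wt = -0.22,
                                  macroporosity = -0.34)),
            class = "pls_equation")
}
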