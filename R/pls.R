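## Univariate-response PLSR (NIPALS), from scratch.
##
## For a single response the NIPALS inner loop collapses to a closed form
## per component: w_a prop. X'y on the current residuals, t_a = X w_a,
## deflate X by t_a p_a'. Coefficients in the scaled space are
## B = W (P'W)^-1 q; the original-scale equation is recovered through the
## centering/scaling constants. Everything here is deterministic.

.pls_tol <- 1e-12

#' Fit a univariate PLSR model (NIPALS)
#'
#' Predictors and response are mean-centered and (by default) scaled to
#' unit variance (n-1 SD). Each latent component maximizes covariance with
#' the response; for a single response the classical NIPALS iteration is
#' closed-form per component.
#'
#' @param X numeric matrix, n x p, with column names.
#' @param y numeric response, length n (here: %BMC).
#' @param ncomp number of latent components A, `A <= min(p, n-1)`.
#' @param scale logical; scale columns to unit variance (default `TRUE`).
#'   Centering is always applied.
#' @param allow_constant keep zero-variance columns with zero weight instead
#'   of failing. Used internally by cross-validation folds, where excluding
#'   a biomaterial can make a composition column constant; such a column has
#'   zero covariance with the response and receives a zero coefficient.
#' @return A `pls_model`: list with `weights` (W, p x A), `x_loadings` (P),
#'   `y_loadings` (q), `scores` (T, n x A), `coef_scaled`, centering/scaling
#'   constants, `labels`, `ncomp`.
#' @examples
#' dm <- design_matrix(builtin_grafts(), c("caco3_wt", "ti_wt", "macroporosity"))
#' fit <- pls_fit(dm$X, dm$y, ncomp = 2)
#' pls_equation(fit)
#' @export
pls_fit <- function(X, y, ncomp, scale = TRUE, allow_constant = FALSE) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  n <- nrow(X); p <- ncol(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(p))
  if (any(!is.finite(X)) || any(!is.finite(y)))
    gpls_error("non-finite values in X or y", "graftPLS_range_error")
  if (length(y) != n)
    gpls_error("length(y) must equal nrow(X)", "graftPLS_schema_error")
  if (n < 3L) gpls_error("need at least 3 observations", "graftPLS_range_error")
  if (ncomp < 1L || ncomp > min(p, n - 1L))
    gpls_error("ncomp must satisfy 1 <= A <= min(p, n-1)",
               "graftPLS_range_error")

  x_means <- colMeans(X)
  x_sd <- apply(X, 2L, sd)
  const <- x_sd < .pls_tol
  if (any(const) && !allow_constant)
    gpls_error(paste0("zero-variance column(s): ",
                      paste(colnames(X)[const], collapse = ", ")),
               "graftPLS_rank_error")
  x_scales <- if (scale) ifelse(const, 1, x_sd) else rep(1, p)
  y_mean <- mean(y)
  y_sd <- sd(y)
  if (y_sd < .pls_tol)
    gpls_error("response has zero variance", "graftPLS_rank_error")
  y_scale <- if (scale) y_sd else 1

  Xr <- base::scale(X, center = x_means, scale = x_scales)
  yr <- (y - y_mean) / y_scale
  W <- P <- matrix(0, p, ncomp, dimnames = list(colnames(X), NULL))
  Tm <- matrix(0, n, ncomp)
  q <- numeric(ncomp)
  for (a in seq_len(ncomp)) {
    w <- crossprod(Xr, yr)
    wn <- sqrt(sum(w^2))
    if (wn < 1e-10)
      gpls_error(paste0("effective rank exhausted at component ", a),
                 "graftPLS_rank_error")
    w <- w / wn
    t <- drop(Xr %*% w)
    tt <- sum(t^2)
    if (tt < 1e-20)
      gpls_error(paste0("effective rank exhausted at component ", a),
                 "graftPLS_rank_error")
    pl <- drop(crossprod(Xr, t)) / tt
    qa <- sum(yr * t) / tt
    Xr <- Xr - tcrossprod(t, pl)
    yr <- yr - qa * t
    W[, a] <- w; P[, a] <- pl; Tm[, a] <- t; q[a] <- qa
  }
  coef_scaled <- drop(W %*% solve(crossprod(P, W), q))
  structure(list(
    ncomp = ncomp, labels = colnames(X),
    x_means = x_means, x_scales = x_scales,
    y_mean = y_mean, y_scale = y_scale, scaled = scale,
    weights = W, x_loadings = P, y_loadings = q, scores = Tm,
    coef_scaled = coef_scaled
  ), class = "pls_model")
}

#' Back-transform a PLSR model to an original-scale affine equation
#'
#' `coefficient_j = coef_scaled_j * y_scale / x_scales_j`;
#' `intercept = y_mean - sum(coefficient_j * x_means_j)`. Predicting the
#' training rows with the equation equals the model's predictions exactly.
#'
#' @param model a `pls_model`.
#' @return A `pls_equation`: list with `intercept` and named `coefficients`,
#'   both in response units (%BMC, per predictor unit).
#' @export
pls_equation <- function(model) {
  stopifnot(inherits(model, "pls_model"))
  coefficients <- model$coef_scaled * model$y_scale / model$x_scales
  intercept <- model$y_mean - sum(coefficients * model$x_means)
  structure(list(intercept = unname(intercept),
                 coefficients = setNames(as.numeric(coefficients),
                                         model$labels)),
            class = "pls_equation")
}

#' @export
format.pls_equation <- function(x, digits = 4, response = "BMC (%)", ...) {
  co <- signif(x$coefficients, digits)
  terms <- sprintf("%s %s * %s", ifelse(co >= 0, "+", "-"),
                   format(abs(co)), names(co))
  paste(response, "=", format(signif(x$intercept, digits)),
        paste(terms, collapse = " "))
}

#' @export
print.pls_equation <- function(x, ...) {
  cat(format(x, ...), "\n")
  invisible(x)
}

.newdata_matrix <- function(newdata, labels) {
  X <- as.matrix(as.data.frame(newdata))
  if (is.null(colnames(X))) {
    if (ncol(X) != length(labels))
      gpls_error("newdata has no column names and wrong width",
                 "graftPLS_schema_error")
    colnames(X) <- labels
  }
  missing <- setdiff(labels, colnames(X))
  if (length(missing) > 0L)
    gpls_error(paste0("newdata lacks predictor(s): ",
                      paste(missing, collapse = ", ")),
               "graftPLS_schema_error")
  X[, labels, drop = FALSE]
}

#' Predict from a PLSR model or its original-scale equation
#'
#' @param object a `pls_model` or `pls_equation`.
#' @param newdata matrix or data frame containing the model's predictor
#'   columns (matched by name).
#' @param ... unused.
#' @return numeric vector of predicted responses (%BMC).
#' @export
predict.pls_equation <- function(object, newdata, ...) {
  X <- .newdata_matrix(newdata, names(object$coefficients))
  drop(X %*% object$coefficients) + object$intercept
}

#' @rdname predict.pls_equation
#' @export
predict.pls_model <- function(object, newdata, ...) {
  predict(pls_equation(object), newdata, ...)
}

#' @export
print.pls_model <- function(x, ...) {
  cat("PLSR model:", x$ncomp, "component(s),",
      length(x$labels), "predictor(s)",
      if (x$scaled) "(centered, unit variance)\n" else "(centered only)\n")
  print(pls_equation(x))
  invisible(x)
}

#' Leave-one-out cross-validation curve for component selection
#'
#' For each number of components `A = 1..a_max`, every observation is held
#' out once, the model refit on the remaining rows, and the held-out row
#' predicted; RMSE pools all n squared errors (`sqrt(mean(e^2))`). The curve
#' is deterministic and invariant to row order. A fold in which the
#' requested number of components exceeds the fold's effective rank (e.g.
#' after a column turns constant) marks that A invalid (`NA` RMSE);
#' constant columns themselves are retained with zero weight.
#'
#' @inheritParams pls_fit
#' @param a_max largest number of components to try,
#'   `a_max <= min(p, n-2)`.
#' @return A `pls_cv`: list with `rmse` (named numeric, `NA` = invalid A),
#'   `selected` (argmin, ties to the smallest A), `predictions`
#'   (n x a_max matrix of held-out predictions), `valid` (logical).
#' @examples
#' dm <- design_matrix(builtin_grafts(), c("caco3_wt", "ti_wt", "macroporosity"))
#' cv <- pls_loo(dm$X, dm$y, a_max = 3)
#' cv$selected
#' @export
pls_loo <- function(X, y, a_max, scale = TRUE) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  n <- nrow(X); p <- ncol(X)
  if (n < 4L) gpls_error("need at least 4 observations for LOO",
                         "graftPLS_range_error")
  if (a_max < 1L || a_max > min(p, n - 2L))
    gpls_error("a_max must satisfy 1 <= a_max <= min(p, n-2)",
               "graftPLS_range_error")
  pred <- matrix(NA_real_, n, a_max,
                 dimnames = list(rownames(X), paste0("A", seq_len(a_max))))
  for (i in seq_len(n)) {
    for (a in seq_len(a_max)) {
      fit <- tryCatch(
        pls_fit(X[-i, , drop = FALSE], y[-i], ncomp = a, scale = scale,
                allow_constant = TRUE),
        graftPLS_rank_error = function(e) NULL)
      if (is.null(fit)) break
      pred[i, a] <- predict(fit, X[i, , drop = FALSE])
    }
  }
  valid <- colSums(is.na(pred)) == 0L
  rmse <- ifelse(valid, sqrt(colMeans((pred - y)^2)), NA_real_)
  names(rmse) <- paste0("A", seq_len(a_max))
  if (!any(valid))
    gpls_error("no valid number of components under LOO",
               "graftPLS_rank_error")
  selected <- which(rmse == min(rmse, na.rm = TRUE))[1L]
  structure(list(rmse = rmse, selected = unname(selected),
                 predictions = pred, valid = valid, n = n),
            class = "pls_cv")
}

#' @export
print.pls_cv <- function(x, ...) {
  cat("LOO cross-validation (n =", x$n, "):\n")
  print(round(x$rmse, 4))
  cat("selected components:", x$selected, "\n")
  invisible(x)
}

#' Variable importance in projection (VIP)
#'
#' Standard VIP over the fitted components: the squared VIPs average to 1,
#' so predictors with VIP > 1 carry more than an average share of the
#' explained response variance.
#'
#' @param model a `pls_model`.
#' @return named numeric vector of length p.
#' @export
vip <- function(model) {
  stopifnot(inherits(model, "pls_model"))
  ssq <- model$y_loadings^2 * colSums(model$scores^2)  # explained y-variance
  p <- length(model$labels)
  w2 <- model$weights^2  # columns already unit-norm
  v <- sqrt(p * drop(w2 %*% ssq) / sum(ssq))
  setNames(v, model$labels)
}

#' Backward predictor elimination under cross-validated RMSE
#'
#' Starting from the full predictor pool, repeatedly refit with the
#' LOO-selected number of components, rank predictors by the elimination
#' criterion (VIP by default, absolute standardized coefficient as the
#' alternative), and drop the weakest; stop when dropping would increase
#' the best LOO RMSE, or when one predictor remains.
#'
#' @inheritParams pls_fit
#' @param criterion `"vip"` or `"abs_coef"`.
#' @return list with `labels` (retained), `model` (final `pls_model`),
#'   `cv` (final `pls_cv`), `trace` (data frame: one row per accepted step
#'   with the predictor set, selected A, and best LOO RMSE).
#' @export
backward_eliminate <- function(X, y, criterion = c("vip", "abs_coef"),
                               scale = TRUE) {
  criterion <- match.arg(criterion)
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  step_fit <- function(Xc) {
    a_max <- min(ncol(Xc), nrow(Xc) - 2L)
    cv <- pls_loo(Xc, y, a_max = a_max, scale = scale)
    model <- pls_fit(Xc, y, ncomp = cv$selected, scale = scale)
    list(cv = cv, model = model, rmse = min(cv$rmse, na.rm = TRUE))
  }
  cur_labels <- colnames(X)
  cur <- step_fit(X)
  trace <- data.frame(step = 0L, predictors = paste(cur_labels, collapse = "+"),
                      n_predictors = length(cur_labels),
                      selected_A = cur$cv$selected, loo_rmse = cur$rmse,
                      dropped = NA_character_, stringsAsFactors = FALSE)
  step <- 0L
  while (length(cur_labels) > 1L) {
    crit <- switch(criterion,
      vip = vip(cur$model),
      abs_coef = abs(setNames(cur$model$coef_scaled, cur$model$labels)))
    drop_lab <- names(crit)[which.min(crit)]
    cand_labels <- setdiff(cur_labels, drop_lab)
    cand <- tryCatch(step_fit(X[, cand_labels, drop = FALSE]),
                     graftPLS_error = function(e) NULL)
    # non-improving within floating-point slack counts as equal, not worse
    if (is.null(cand) || cand$rmse > cur$rmse * (1 + 1e-8) + 1e-10) break
    step <- step + 1L
    cur_labels <- cand_labels
    cur <- cand
    trace <- rbind(trace, data.frame(
      step = step, predictors = paste(cur_labels, collapse = "+"),
      n_predictors = length(cur_labels), selected_A = cur$cv$selected,
      loo_rmse = cur$rmse, dropped = drop_lab, stringsAsFactors = FALSE))
  }
  list(labels = cur_labels, model = cur$model, cv = cur$cv, trace = trace)
}

#' Pearson correlation between predicted and measured responses
#'
#' @param predicted,measured numeric vectors of equal length >= 3 with
#'   non-zero variance.
#' @return Pearson product-moment r in \[-1, 1\].
#' @export
prediction_correlation <- function(predicted, measured) {
  if (length(predicted) != length(measured) || length(predicted) < 3L)
    gpls_error("need equal-length vectors of length >= 3",
               "graftPLS_range_error")
  if (sd(predicted) < .pls_tol || sd(measured) < .pls_tol)
    gpls_error("zero variance in predicted or measured values",
               "graftPLS_range_error")
  cor(predicted, measured)
}

#' Serialize a PLSR model or equation to JSON
#'
#' Writes labels, centering/scaling constants, weights, loadings,
#' coefficients and intercept with full precision, so that equations
#' round-trip losslessly.
#'
#' @param x a `pls_model` or `pls_equation`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
pls_to_json <- function(x, path) {
  obj <- if (inherits(x, "pls_model")) {
    eq <- pls_equation(x)
    list(type = "pls_model", ncomp = x$ncomp, labels = x$labels,
         x_means = x$x_means, x_scales = x$x_scales,
         y_mean = x$y_mean, y_scale = x$y_scale, scaled = x$scaled,
         weights = x$weights, x_loadings = x$x_loadings,
         y_loadings = x$y_loadings, coef_scaled = x$coef_scaled,
         intercept = eq$intercept, coefficients = as.list(eq$coefficients))
  } else if (inherits(x, "pls_equation")) {
    list(type = "pls_equation", intercept = x$intercept,
         coefficients = as.list(x$coefficients), text = format(x))
  } else gpls_error("not a pls_model or pls_equation", "graftPLS_schema_error")
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE,
                       matrix = "rowmajor")
  invisible(path)
}
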