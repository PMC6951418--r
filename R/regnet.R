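# Regularized linear classifier for elincRNA vs canonical lincRNA.
#
# The objective is the penalized residual sum of squares
#   (1/2n) * sum_i (y_i - b0 - x_i' b)^2 + lambda * sum_j [ (1-alpha)/2 b_j^2
#                                                           + alpha |b_j| ]
# minimized by cyclical coordinate descent on columns standardized to zero
# mean and unit (1/n) variance, with an unpenalized intercept. alpha = 1 is
# the lasso, alpha = 0 ridge, in between the elastic net. Coefficients are
# reported on the original feature scale. Class labels are coded y = +1
# (elinc) / -1 (canonical); a fitted score > 0 predicts elinc, < 0 canonical.

#' Soft-thresholding operator
#'
#' `sign(z) * max(|z| - gamma, 0)`, the lasso coordinate update.
#'
#' @param z numeric vector.
#' @param gamma threshold, `>= 0`.
#' @return shrunken values.
#' @export
soft_threshold <- function(z, gamma) {
  if (any(gamma < 0)) stopf("gamma must be non-negative")
  sign(z) * pmax(abs(z) - gamma, 0)
}

#' Penalized residual sum of squares
#'
#' The exact objective the solver minimizes:
#' `RSS/(2n) + lambda * sum((1-alpha)/2 * beta^2 + alpha * abs(beta))`.
#'
#' @param betas coefficient vector.
#' @param beta0 intercept.
#' @param X design matrix (n x p).
#' @param y response vector.
#' @param alpha elastic-net mixing parameter in \[0,1\].
#' @param lambda penalty weight, `>= 0`.
#' @return scalar objective value.
#' @export
prss <- function(betas, beta0, X, y, alpha, lambda) {
  if (alpha < 0 || alpha > 1) stopf("alpha must lie in [0,1]")
  if (lambda < 0) stopf("lambda must be non-negative")
  r <- y - beta0 - drop(X %*% betas)
  sum(r^2) / (2 * length(y)) +
    lambda * sum((1 - alpha) / 2 * betas^2 + alpha * abs(betas))
}

# ---- internals --------------------------------------------------------------

#' @keywords internal
standardize_columns <- function(X) {
  center <- colMeans(X)
  Xc <- sweep(X, 2, center)
  scale <- sqrt(colMeans(Xc^2))
  if (any(scale == 0))
    stopf("constant (zero-variance) feature column(s): %s",
          paste(colnames(X)[scale == 0], collapse = ", "))
  list(Xs = sweep(Xc, 2, scale, "/"), center = center, scale = scale)
}

# One coordinate-descent solve at fixed (alpha, lambda) on standardized
# data, via the compiled Gram-update core. Optionally records the objective
# after every sweep (it must be non-increasing).
#' @keywords internal
cd_solve <- function(Xs, yc, alpha, lambda, beta_init = NULL,
                     tol = 1e-7, max_iter = 100000, trace = FALSE) {
  n <- nrow(Xs); p <- ncol(Xs)
  beta <- if (is.null(beta_init)) numeric(p) else beta_init
  G <- crossprod(Xs) / n
  g <- drop(crossprod(Xs, yc)) / n
  sol <- cd_solve_gram(G, g, mean(yc^2), alpha, lambda, beta,
                       tol, as.integer(max_iter), trace)
  if (!sol$converged) {
    cnd <- structure(
      class = c("regnet_nonconvergence", "error", "condition"),
      list(message = sprintf(
        "coordinate descent did not converge in %d sweeps", max_iter),
        call = sys.call(-1), beta = drop(sol$beta),
        objective = sol$objective))
    stop(cnd)
  }
  list(beta = drop(sol$beta), iters = sol$iters, converged = TRUE,
       objective = if (trace) sol$objective else NULL)
}

#' @keywords internal
lambda_grid <- function(Xs, yc, alpha, n_lambda = 100,
                        lambda_min_ratio = 1e-4) {
  n <- nrow(Xs)
  lmax <- max(abs(crossprod(Xs, yc))) / n / max(alpha, 1e-3)
  exp(seq(log(lmax), log(lmax * lambda_min_ratio), length.out = n_lambda))
}

# Warm-started path fit on already-standardized data; returns p x n_lambda
# matrix of standardized coefficients.
#' @keywords internal
fit_path_std <- function(Xs, yc, alpha, lambdas, tol = 1e-7,
                         max_iter = 100000) {
  n <- nrow(Xs)
  cd_path_gram(crossprod(Xs) / n, drop(crossprod(Xs, yc)) / n, alpha,
               lambdas, tol, as.integer(max_iter))
}

#' @keywords internal
unstandardize <- function(beta_std, std, ybar) {
  b <- beta_std / std$scale
  list(beta = b, beta0 = ybar - sum(b * std$center))
}

#' @keywords internal
as_response <- function(y) {
  if (is.character(y) || is.factor(y)) {
    y <- as.character(y)
    bad <- !y %in% c("elinc", "canonical")
    if (any(bad)) stopf("labels must be 'elinc' or 'canonical'")
    y <- ifelse(y == "elinc", 1, -1)
  }
  if (!all(y %in% c(-1, 1))) stopf("response must be coded +1 / -1")
  as.numeric(y)
}

# ---- fitting ----------------------------------------------------------------

#' Fit the regularized regression classifier at fixed (alpha, lambda)
#'
#' Cyclical coordinate descent on standardized columns with an unpenalized
#' intercept, iterating full sweeps until the largest coefficient update
#' falls below `tol`. Coefficients are returned on the original scale.
#'
#' @param X feature matrix (n x p) with column names.
#' @param y response: +1/-1 vector, or labels "elinc"/"canonical".
#' @param alpha elastic-net mixing parameter in \[0,1\] (1 = lasso).
#' @param lambda penalty weight `>= 0` on the `(1/2n)` RSS scale.
#' @param tol convergence tolerance on standardized coefficient updates.
#' @param max_iter maximum full sweeps; non-convergence is an error of class
#'   `regnet_nonconvergence` carrying the last iterate in `$beta`.
#' @param trace record the objective after every sweep (in `$objective`).
#' @return object of class `regnet`: `alpha`, `lambda`, `beta0`, `beta`
#'   (named, original scale), `standardization` (center/scale), `features`.
#' @export
regnet_fit <- function(X, y, alpha, lambda, tol = 1e-7, max_iter = 100000,
                       trace = FALSE) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  y <- as_response(y)
  if (nrow(X) < 2) stopf("need at least 2 observations")
  if (length(unique(y)) < 2) stopf("both classes must be present")
  if (alpha < 0 || alpha > 1) stopf("alpha must lie in [0,1]")
  if (lambda < 0) stopf("lambda must be non-negative")
  std <- standardize_columns(X)
  ybar <- mean(y); yc <- y - ybar
  sol <- cd_solve(std$Xs, yc, alpha, lambda, tol = tol, max_iter = max_iter,
                  trace = trace)
  un <- unstandardize(sol$beta, std, ybar)
  beta <- un$beta; names(beta) <- colnames(X)
  structure(list(alpha = alpha, lambda = lambda, beta0 = un$beta0,
                 beta = beta,
                 standardization = list(center = std$center,
                                        scale = std$scale),
                 features = colnames(X), iters = sol$iters,
                 objective = sol$objective),
            class = "regnet")
}

#' @export
print.regnet <- function(x, ...) {
  nz <- sum(x$beta != 0)
  cat(sprintf("<regnet> alpha=%.3g lambda=%.4g intercept=%.4f (%d/%d nonzero)\n",
              x$alpha, x$lambda, x$beta0, nz, length(x$beta)))
  invisible(x)
}

#' Stratified fold assignment
#'
#' @param y class vector (+1/-1 or labels).
#' @param k number of folds.
#' @param seed RNG seed.
#' @return integer fold ids in 1..k; each fold contains both classes when
#'   both class counts are `>= k` is not required, but stratification keeps
#'   fold class ratios as even as possible.
#' @export
make_folds <- function(y, k, seed) {
  y <- as_response(y)
  n <- length(y)
  if (n < k) stopf("n < k: cannot make %d folds from %d observations", k, n)
  set.seed(seed)
  fold <- integer(n)
  for (cls in c(-1, 1)) {
    idx <- which(y == cls)
    idx <- idx[sample.int(length(idx))]
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

#' Cross-validated lambda path at fixed alpha
#'
#' Fits a warm-started path over a log-spaced grid from `lambda_max` (the
#' smallest penalty that zeroes every coefficient at the given alpha) down by
#' a factor `lambda_min_ratio`, on each training fold, and scores held-out
#' mean squared error. The chosen lambda minimizes mean CV MSE (ties broken
#' toward the larger, more parsimonious lambda).
#'
#' @inheritParams regnet_fit
#' @param k folds (default 10), stratified by class.
#' @param n_lambda grid size (default 100).
#' @param lambda_min_ratio `lambda_min / lambda_max` (default 1e-4).
#' @param seed RNG seed for fold assignment (mandatory).
#' @return object of class `lambda_path`: `lambdas` (decreasing), `cv_mse`,
#'   `chosen`, `alpha`, `k`, `seed`.
#' @export
lambda_path_cv <- function(X, y, alpha, k = 10, n_lambda = 100,
                           lambda_min_ratio = 1e-4, seed, tol = 1e-7,
                           max_iter = 100000) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  y <- as_response(y)
  if (missing(seed)) stopf("seed is required")
  if (nrow(X) < k) stopf("n < k")
  std <- standardize_columns(X)
  lambdas <- lambda_grid(std$Xs, y - mean(y), alpha, n_lambda,
                         lambda_min_ratio)
  fold <- make_folds(y, k, seed)
  mse <- matrix(NA_real_, n_lambda, k)
  for (f in seq_len(k)) {
    tr <- fold != f
    if (length(unique(y[tr])) < 2 || !any(!tr)) next
    std_f <- standardize_columns(X[tr, , drop = FALSE])
    ybar <- mean(y[tr])
    B <- fit_path_std(std_f$Xs, y[tr] - ybar, alpha, lambdas, tol, max_iter)
    Xv <- X[!tr, , drop = FALSE]
    for (i in seq_len(n_lambda)) {
      un <- unstandardize(B[, i], std_f, ybar)
      pred <- un$beta0 + drop(Xv %*% un$beta)
      mse[i, f] <- mean((y[!tr] - pred)^2)
    }
  }
  cv_mse <- rowMeans(mse, na.rm = TRUE)
  chosen <- lambdas[which.min(cv_mse)]  # first minimum = largest lambda
  structure(list(lambdas = lambdas, cv_mse = cv_mse, chosen = chosen,
                 alpha = alpha, k = k, seed = seed),
            class = "lambda_path")
}

#' @export
print.lambda_path <- function(x, ...) {
  cat(sprintf("<lambda_path> alpha=%.3g, %d lambdas, chosen=%.4g (CV MSE %.4g)\n",
              x$alpha, length(x$lambdas), x$chosen, min(x$cv_mse)))
  invisible(x)
}

#' Select the elastic-net mixing parameter by cross-validation
#'
#' Runs [lambda_path_cv()] for every alpha in the grid with identical fold
#' assignments and returns the alpha whose best CV MSE is minimal; exact ties
#' are broken toward the larger (sparser) alpha.
#'
#' @inheritParams lambda_path_cv
#' @param alphas numeric grid in \[0,1\].
#' @return list(alpha, path) where `path` is the winning `lambda_path`.
#' @export
select_alpha <- function(X, y, alphas = c(0, 0.5, 1), k = 10, seed,
                         n_lambda = 100, lambda_min_ratio = 1e-4,
                         tol = 1e-7, max_iter = 100000) {
  if (length(alphas) == 0) stopf("empty alpha grid")
  if (any(alphas < 0 | alphas > 1)) stopf("alphas must lie in [0,1]")
  paths <- lapply(alphas, function(a)
    lambda_path_cv(X, y, a, k = k, n_lambda = n_lambda,
                   lambda_min_ratio = lambda_min_ratio, seed = seed,
                   tol = tol, max_iter = max_iter))
  best_mse <- vapply(paths, function(p) min(p$cv_mse), numeric(1))
  winners <- which(best_mse == min(best_mse))
  pick <- winners[which.max(alphas[winners])]
  list(alpha = alphas[pick], path = paths[[pick]])
}

# ---- scoring ----------------------------------------------------------------

#' Score feature vectors with a fitted or published model
#'
#' `score = beta0 + sum_j beta_j x_j`, with features aligned by name.
#'
#' @param model a `regnet` object (fitted or [published_model()]).
#' @param x named numeric vector, or matrix/data.frame with feature columns.
#'   Every model feature must be present by name.
#' @return numeric score(s).
#' @export
regnet_score <- function(model, x) {
  stopifnot(inherits(model, "regnet"))
  if (is.vector(x) && !is.list(x)) x <- matrix(x, 1, dimnames = list(NULL, names(x)))
  x <- as.matrix(x)
  missing_feats <- setdiff(model$features, colnames(x))
  if (length(missing_feats))
    stopf("feature(s) missing from input: %s",
          paste(missing_feats, collapse = ", "))
  drop(model$beta0 + x[, model$features, drop = FALSE] %*%
         model$beta[model$features])
}

#' @export
predict.regnet <- function(object, newdata, ...) regnet_score(object, newdata)

#' Sign-rule classification
#'
#' Score > 0 is `elinc`, < 0 `canonical`, exactly 0 `indeterminate`.
#'
#' @inheritParams regnet_score
#' @return character vector of class labels.
#' @export
regnet_classify <- function(model, x) {
  s <- regnet_score(model, x)
  ifelse(s > 0, "elinc", ifelse(s < 0, "canonical", "indeterminate"))
}

#' The published seven-feature epigenetic model
#'
#' The fitted lasso model reported for mouse ESC lincRNAs: intercept 2.0860
#' with positive weights on TSS DNA methylation (5.79), TSS H3K4me1 (3.16),
#' body DNA methylation (0.53) and body H3K122ac (0.46) marking elincRNAs,
#' and negative weights on body H3K36me3 (-5.17), TSS H3K9ac (-4.13) and TSS
#' H3K4me3 (-0.87) marking canonical lincRNAs. Feature values are coverage
#' fractions / beta means in \[0,1\].
#'
#' @return a `regnet` object usable with [regnet_score()] and
#'   [regnet_classify()].
#' @export
published_model <- function() {
  beta <- c(TSS_DNAme = 5.79, TSS_H3K4me1 = 3.16, Body_DNAme = 0.53,
            Body_H3K122ac = 0.46, Body_H3K36me3 = -5.17, TSS_H3K9ac = -4.13,
            TSS_H3K4me3 = -0.87)
  structure(list(alpha = 1, lambda = NA_real_, beta0 = 2.0860, beta = beta,
                 standardization = NULL, features = names(beta)),
            class = "regnet")
}

# ---- serialization ----------------------------------------------------------

#' Write a model as flat JSON
#' @param model `regnet` object.
#' @param path file.
#' @export
write_regnet <- function(model, path) {
  stopifnot(inherits(model, "regnet"))
  jsonlite::write_json(
    list(alpha = model$alpha, lambda = model$lambda, beta0 = model$beta0,
         beta = as.list(model$beta),
         center = as.list(model$standardization$center %||% list()),
         scale = as.list(model$standardization$scale %||% list())),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a model written by [write_regnet()]
#' @param path file.
#' @return `regnet` object.
#' @export
read_regnet <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  beta <- unlist(x$beta)
  std <- if (length(x$center)) list(center = unlist(x$center),
                                    scale = unlist(x$scale)) else NULL
  structure(list(alpha = x$alpha, lambda = x$lambda %||% NA_real_,
                 beta0 = x$beta0, beta = beta, standardization = std,
                 features = names(beta)),
            class = "regnet")
}
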