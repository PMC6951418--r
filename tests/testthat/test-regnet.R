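# Solver oracles: closed-form ridge, orthonormal-design lasso, ordinary
# least squares, and an independent elastic-net implementation (glmnet,
# used only as a cross-check).

ridge_closed_form <- function(X, y, lambda) {
  # on standardized columns: beta = (G + lambda I)^-1 g, then back-transform
  n <- nrow(X)
  center <- colMeans(X); Xc <- sweep(X, 2, center)
  scale <- sqrt(colMeans(Xc^2)); Xs <- sweep(Xc, 2, scale, "/")
  yc <- y - mean(y)
  G <- crossprod(Xs) / n; g <- drop(crossprod(Xs, yc)) / n
  bs <- solve(G + lambda * diag(ncol(X)), g)
  b <- bs / scale
  list(beta = b, beta0 = mean(y) - sum(b * center))
}

test_that("soft thresholding shrinks toward zero with odd symmetry", {
  expect_equal(soft_threshold(3, 1), 2)
  expect_equal(soft_threshold(0.5, 1), 0)
  expect_equal(soft_threshold(-3, 1), -2)
  z <- seq(-4, 4, by = 0.37)
  expect_equal(soft_threshold(-z, 1.3), -soft_threshold(z, 1.3))
  expect_error(soft_threshold(1, -0.1), "non-negative")
})

test_that("prss reduces to its special cases", {
  pr <- random_problem(20, 4, seed = 1)
  b <- rnorm(4); b0 <- 0.3
  rss_half_n <- sum((pr$y - b0 - pr$X %*% b)^2) / (2 * 20)
  expect_equal(prss(b, b0, pr$X, pr$y, alpha = 0.5, lambda = 0), rss_half_n)
  expect_equal(prss(numeric(4), b0, pr$X, pr$y, 0.5, 1),
               sum((pr$y - b0)^2) / 40)
  # alpha = 1 is the pure L1 penalty, alpha = 0 the pure (halved) L2 penalty
  expect_equal(prss(b, b0, pr$X, pr$y, 1, 2), rss_half_n + 2 * sum(abs(b)))
  expect_equal(prss(b, b0, pr$X, pr$y, 0, 2), rss_half_n + sum(b^2))
  expect_error(prss(b, b0, pr$X, pr$y, 2, 1), "alpha")
  expect_error(prss(b, b0, pr$X, pr$y, 0.5, -1), "lambda")
})

test_that("ridge fits match the closed form to 1e-6", {
  for (seed in 1:3) {
    pr <- random_problem(10, 3, seed = seed)
    for (lambda in c(0.01, 0.3, 2)) {
      f <- regnet_fit(pr$X, pr$y, alpha = 0, lambda = lambda, tol = 1e-10)
      o <- ridge_closed_form(pr$X, pr$y, lambda)
      expect_equal(unname(f$beta), unname(o$beta), tolerance = 1e-6)
      expect_equal(f$beta0, o$beta0, tolerance = 1e-6)
    }
  }
})

test_that("lasso on an orthonormal design equals soft-thresholded OLS", {
  n <- 40; p <- 5
  X <- orthonormal_design(n, p)
  set.seed(5)
  latent <- drop(X %*% c(2, -1.5, 0.4, 0, 0)) + rnorm(n) * 0.3
  y <- ifelse(latent > stats::median(latent) - 0.2, 1, -1)  # unbalanced classes
  lambda <- 0.1
  f <- regnet_fit(X, y, alpha = 1, lambda = lambda, tol = 1e-12)
  z <- drop(crossprod(X, y - mean(y))) / n
  expect_equal(unname(f$beta), unname(soft_threshold(z, lambda)),
               tolerance = 1e-8)
  expect_equal(f$beta0, mean(y), tolerance = 1e-8)
})

test_that("lambda = 0 recovers ordinary least squares", {
  pr <- random_problem(30, 4, seed = 8)
  f <- regnet_fit(pr$X, pr$y, alpha = 1, lambda = 0, tol = 1e-12)
  ols <- stats::lm.fit(cbind(1, pr$X), pr$y)$coefficients
  expect_equal(unname(f$beta), unname(ols[-1]), tolerance = 1e-6)
  expect_equal(f$beta0, unname(ols[1]), tolerance = 1e-6)
  # ridge limit: small lambda approaches OLS
  g <- regnet_fit(pr$X, pr$y, alpha = 0, lambda = 1e-8, tol = 1e-12)
  expect_equal(unname(g$beta), unname(ols[-1]), tolerance = 1e-5)
})

test_that("the objective never increases across coordinate-descent sweeps", {
  pr <- random_problem(60, 12, seed = 13, noise = 1)
  for (cfg in list(c(1, 0.05), c(0.5, 0.1), c(0, 0.2))) {
    f <- regnet_fit(pr$X, pr$y, alpha = cfg[1], lambda = cfg[2], trace = TRUE)
    expect_true(all(diff(f$objective) <= 1e-12))
  }
})

test_that("fits agree with an independent elastic-net implementation", {
  skip_if_not_installed("glmnet")
  for (seed in 1:4) {
    n <- 30 + seed * 10; p <- 5 + seed
    pr <- random_problem(n, p, seed = 100 + seed)
    alpha <- c(0, 0.25, 0.7, 1)[seed]
    lambda <- c(0.08, 0.03, 0.12, 0.05)[seed]
    f <- regnet_fit(pr$X, pr$y, alpha, lambda, tol = 1e-11)
    # family object form: penalizes the raw least-squares objective without
    # glmnet's internal response rescaling, matching prss exactly
    g <- glmnet::glmnet(pr$X, pr$y, alpha = alpha, lambda = lambda,
                        thresh = 1e-14, standardize = TRUE,
                        family = gaussian())
    expect_equal(unname(f$beta), as.numeric(g$beta), tolerance = 1e-4)
    expect_equal(f$beta0, as.numeric(g$a0), tolerance = 1e-4)
  }
})

test_that("CV lambda path recovers planted features and shrinks pure noise", {
  set.seed(31)
  n <- 120; p <- 20
  X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("f", 1:p)))
  y <- sign(2 * X[, 1] - 2 * X[, 2] + rnorm(n))
  y[y == 0] <- 1
  path <- lambda_path_cv(X, y, alpha = 1, k = 10, seed = 32)
  expect_true(all(diff(path$lambdas) < 0))
  expect_true(path$chosen %in% path$lambdas)
  fit <- regnet_fit(X, y, 1, path$chosen)
  expect_true(all(c("f1", "f2") %in% names(which(fit$beta != 0))))
  expect_gt(fit$beta["f1"], 0); expect_lt(fit$beta["f2"], 0)

  ynoise <- sample(c(-1, 1), n, replace = TRUE)
  pnoise <- lambda_path_cv(X, ynoise, alpha = 1, k = 10, seed = 33)
  fnoise <- regnet_fit(X, ynoise, 1, pnoise$chosen)
  expect_lt(max(abs(fnoise$beta)), 0.2)

  # determinism under a fixed seed
  path2 <- lambda_path_cv(X, y, alpha = 1, k = 10, seed = 32)
  expect_identical(path$cv_mse, path2$cv_mse)
  expect_identical(path$chosen, path2$chosen)
})

test_that("lasso support is monotone along the lambda path", {
  pr <- random_problem(80, 10, seed = 41, noise = 1)
  std <- elincnet:::standardize_columns(pr$X)
  yc <- pr$y - mean(pr$y)
  lambdas <- elincnet:::lambda_grid(std$Xs, yc, 1, n_lambda = 50)
  B <- elincnet:::fit_path_std(std$Xs, yc, 1, lambdas)
  nz <- colSums(B != 0)
  expect_true(all(diff(nz) >= 0))  # lambda decreasing -> support grows
})

test_that("alpha selection compares CV error and handles edge cases", {
  set.seed(51)
  n <- 80; p <- 15
  X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("f", 1:p)))
  y <- sign(2 * X[, 1] - 2 * X[, 2] + rnorm(n) * 0.5); y[y == 0] <- 1
  sel <- select_alpha(X, y, alphas = c(0, 1), k = 5, seed = 52)
  p0 <- lambda_path_cv(X, y, 0, k = 5, seed = 52)
  p1 <- lambda_path_cv(X, y, 1, k = 5, seed = 52)
  expected <- if (min(p1$cv_mse) <= min(p0$cv_mse)) 1 else 0
  expect_equal(sel$alpha, expected)
  one <- select_alpha(X, y, alphas = 0.3, k = 5, seed = 53)
  expect_equal(one$alpha, 0.3)
  expect_error(select_alpha(X, y, alphas = numeric(0), k = 5, seed = 1),
               "empty")
  Xbad <- X; Xbad[, 3] <- 1
  expect_error(select_alpha(Xbad, y, alphas = 1, k = 5, seed = 1),
               "constant")
})

test_that("scoring and the sign rule reproduce the published worked examples", {
  m <- published_model()
  x0 <- setNames(numeric(7), m$features)
  expect_equal(regnet_score(m, x0), 2.0860)
  x <- x0; x["Body_H3K36me3"] <- 1
  expect_equal(regnet_score(m, x), 2.0860 - 5.17)
  expect_equal(regnet_classify(m, x), "canonical")
  x <- x0; x["TSS_DNAme"] <- 1
  expect_equal(regnet_score(m, x), 2.0860 + 5.79)
  expect_equal(regnet_classify(m, x), "elinc")
  expect_error(regnet_score(m, c(TSS_DNAme = 1)), "missing")
  zero <- structure(list(alpha = 1, lambda = 0, beta0 = 0, beta = c(a = 1),
                         standardization = NULL, features = "a"),
                    class = "regnet")
  expect_equal(regnet_classify(zero, c(a = 0)), "indeterminate")
})

test_that("model JSON serialization round-trips scores exactly", {
  pr <- random_problem(40, 6, seed = 61)
  f <- regnet_fit(pr$X, pr$y, 0.5, 0.05)
  path <- withr::local_tempfile(fileext = ".json")
  write_regnet(f, path)
  back <- read_regnet(path)
  expect_equal(back$beta, f$beta)
  expect_equal(back$beta0, f$beta0)
  expect_equal(regnet_score(back, pr$X), regnet_score(f, pr$X))
})
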