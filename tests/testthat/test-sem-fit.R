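test_that("sample covariance matches the brute-force double loop", {
  # perfectly collinear pair: closed-form covariance
  d <- data.frame(x = c(1, 2, 3), y = c(2, 4, 6))
  S <- sample_covariance(d)$S
  expect_equal(unname(S), matrix(c(1, 2, 2, 4), 2))
  set.seed(3)
  X <- matrix(rnorm(60), 20, 3, dimnames = list(NULL, c("a", "b", "c")))
  expect_equal(sample_covariance(X)$S, oracle_cov(X))
})

test_that("degenerate covariance inputs error informatively", {
  expect_error(sample_covariance(data.frame(x = c(1, 1, 1), y = 1:3)), "x")
  expect_error(sample_covariance(data.frame(x = 1:2)), "3 complete samples")
  # listwise deletion happens before the checks
  d <- data.frame(x = c(1:5, NA), y = c(rnorm(5), 2))
  expect_equal(sample_covariance(d)$n, 5)
})

test_that("implied covariance matches closed forms", {
  # no paths, identity measurement: Sigma = diag of disturbance variances
  m <- sem_model(observed = c("a", "b"))
  sig <- implied_covariance(m, c(2, 3))
  expect_equal(unname(sig), diag(c(2, 3)))
  # single path x -> y: cov(x,y) = b * var(x), var(y) = b^2 var(x) + psi_y
  m2 <- single_path_model()
  th <- c("y~x" = 0.8, "x~~x" = 2, "y~~y" = 0.5)
  sig2 <- implied_covariance(m2, th[m2$params$label])
  expect_equal(sig2["x", "y"], 0.8 * 2)
  expect_equal(sig2["y", "y"], 0.8^2 * 2 + 0.5)
})

test_that("implied covariance matches large-sample simulation", {
  tm <- rubisco_fixture("prior")
  sig <- implied_covariance(tm$model, tm$theta)
  d <- sem_simulate(tm, n = 2e5, seed = 31)
  emp <- stats::cov(as.matrix(d))[rownames(sig), colnames(sig)]
  # entrywise within ~4 standard errors of a covariance at n = 2e5
  se <- sqrt((outer(diag(sig), diag(sig)) + sig^2) / 2e5)
  expect_true(all(abs(emp - sig) < 4 * se))
})

test_that("ML discrepancy has its closed-form values and symmetries", {
  S <- matrix(c(2, 0.5, 0.5, 1), 2)
  expect_equal(ml_discrepancy(S, S), 0)
  expect_equal(ml_discrepancy(matrix(2), matrix(1)), 1 - log(2))
  # permutation invariance
  set.seed(4)
  A <- crossprod(matrix(rnorm(25), 5))
  B <- crossprod(matrix(rnorm(25), 5))
  perm <- sample(5)
  expect_equal(ml_discrepancy(A, B),
               ml_discrepancy(A[perm, perm], B[perm, perm]))
  expect_gt(ml_discrepancy(A, B), 0)
  expect_error(ml_discrepancy(matrix(-1), matrix(1)), "positive definite")
})

test_that("the analytic gradient matches numerical differentiation", {
  tm <- rubisco_fixture("final")
  d <- sem_simulate(tm, 150, seed = 8)
  S <- sample_covariance(d)$S[tm$model$observed, tm$model$observed]
  ldS <- as.numeric(determinant(S)$modulus)
  fn <- pathsem:::ml_objective(tm$model, S, ldS)
  gr <- pathsem:::ml_gradient(tm$model, S)
  th <- tm$theta * 0.9 + 0.05
  expect_equal(gr(th), numDeriv::grad(fn, th), tolerance = 1e-6)
})

test_that("ML estimates equal the OLS closed form on regression sub-models", {
  set.seed(11)
  n <- 300
  X <- matrix(rnorm(n * 3), n, 3) %*% chol(matrix(c(1, .4, .2,
                                                    .4, 1, .3,
                                                    .2, .3, 1), 3))
  colnames(X) <- c("x1", "x2", "x3")
  y <- 0.5 * X[, 1] - 0.3 * X[, 2] + rnorm(n)
  d <- data.frame(X, y = y)
  m <- sem_model(
    paths = data.frame(from = c("x1", "x2", "x3"), to = "y"),
    covariances = data.frame(a = c("x1", "x1", "x2"),
                             b = c("x2", "x3", "x3"))
  )
  fit <- sem_fit(d, m)
  b_ols <- oracle_ols(X, y)
  b_ml <- fit$theta[c("y~x1", "y~x2", "y~x3")]
  expect_lt(max(abs(b_ml - b_ols)), 1e-6)
})

test_that("a saturated model reproduces S with zero discrepancy", {
  set.seed(12)
  d <- as.data.frame(matrix(rnorm(200 * 4), 200, 4))
  colnames(d) <- paste0("v", 1:4)
  m <- saturated_model(colnames(d))
  expect_equal(sem_df(m), 0)
  fit <- sem_fit(d, m)
  expect_lt(fit$chi_square, 1e-4)
  expect_lt(max(abs(fit$S - fit$Sigma_hat)), 1e-4)
})

test_that("over-parameterized models are rejected before optimization", {
  # f =~ x + y alone: 1 loading + 2 errors + 1 variance = 4 > p(p+1)/2 = 3
  expect_error(sem_fit(data.frame(x = rnorm(10), y = rnorm(10)),
                       sem_model(latents = list(f = c("x", "y")))),
               "not identified")
})

test_that("an empty model cannot be fit", {
  m <- sem_model(observed = character())
  expect_error(sem_fit(data.frame(x = rnorm(5)), m), "empty model")
})

test_that("a single-path fit recovers the generating slope", {
  tm <- single_path_truth(b = 0.7)
  d <- sem_simulate(tm, 1e5, seed = 21)
  fit <- sem_fit(d, tm$model)
  expect_lt(abs(fit$theta["y~x"] - 0.7), 0.01)
  expect_true(fit$converged)
})

test_that("fit index arithmetic follows the definitions", {
  S <- diag(2)
  idx <- fit_indices(20, 10, 101, S, S)
  expect_equal(idx$rmsea, sqrt(10 / (10 * 100)))
  expect_equal(idx$srmr, 0)
  # truncation at T <= df
  idx2 <- fit_indices(5, 10, 101, S, S)
  expect_equal(idx2$rmsea, 0)
  expect_equal(idx2$rmsea_ci_low, 0)
  expect_error(fit_indices(5, 0, 101, S, S), "df = 0")
  # CI brackets the point estimate and p-close is a probability
  idx3 <- fit_indices(60, 30, 48, S, S)
  expect_lte(idx3$rmsea_ci_low, idx3$rmsea)
  expect_gte(idx3$rmsea_ci_high, idx3$rmsea)
  expect_gte(idx3$rmsea_pclose, 0)
  expect_lte(idx3$rmsea_pclose, 1)
})

test_that("RMSEA is non-increasing in df at fixed T and N", {
  S <- diag(2)
  r <- vapply(1:19, function(df) fit_indices(20, df, 101, S, S)$rmsea,
              numeric(1))
  expect_true(all(diff(r) <= 1e-12))
})

test_that("standardized coefficients equal correlations for unit-variance data", {
  set.seed(14)
  n <- 4000
  x <- rnorm(n)
  y <- 0.6 * x + rnorm(n, sd = 0.8)
  d <- data.frame(x = scale(x)[, 1], y = scale(y)[, 1])
  fit <- sem_fit(d, single_path_model())
  std <- fit$standardized
  expect_equal(std$std_estimate[std$label == "y~x"], cor(d$x, d$y),
               tolerance = 1e-5)
})

test_that("standardized coefficients are invariant to rescaling a variable", {
  tm <- rubisco_fixture("final")
  d <- sem_simulate(tm, 500, seed = 15)
  f1 <- sem_fit(d, tm$model)
  d2 <- d
  d2$dp39 <- d2$dp39 * 7.3
  d2$RSS174 <- d2$RSS174 * 0.2
  f2 <- sem_fit(d2, tm$model)
  expect_equal(f1$standardized$std_estimate, f2$standardized$std_estimate,
               tolerance = 1e-4)
})

test_that("Wald statistics follow the normal reference", {
  tm <- single_path_truth(b = 1.96)
  d <- sem_simulate(tm, 2000, seed = 16)
  fit <- sem_fit(d, tm$model)
  w <- wald_tests(fit)
  expect_equal(w$p[w$label == "y~x"],
               2 * pnorm(-abs(fit$theta["y~x"] / fit$se[w$label == "y~x"])),
               ignore_attr = TRUE)
  fit0 <- fit
  fit0$se[] <- 0
  expect_error(wald_tests(fit0), "zero standard error")
})

test_that("Heywood cases are flagged, not hidden", {
  # tiny error variance + small n invites negative estimates; force one by
  # fitting a latent with a near-deterministic indicator pair
  set.seed(200)
  found <- FALSE
  for (s in 1:20) {
    f <- rnorm(30)
    d <- data.frame(i1 = f + rnorm(30, sd = 0.01),
                    i2 = f + rnorm(30, sd = 0.01),
                    y = 0.5 * f + rnorm(30))
    m <- sem_model(paths = data.frame(from = "lat", to = "y"),
                   latents = list(lat = c("i1", "i2")))
    fit <- sem_fit(d, m)
    if (any(grepl("Heywood", fit$warnings))) found <- TRUE
    if (found) break
  }
  expect_true(found)
})
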