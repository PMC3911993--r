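test_that("the Gelman-Rubin statistic matches a hand-evaluated example", {
  ch <- sem_chains(list(matrix(1:4, ncol = 1, dimnames = list(NULL, "b")),
                        matrix(2:5, ncol = 1, dimnames = list(NULL, "b"))),
                   burn_in = 0)
  r <- gelman_rubin(ch)
  # W = 5/3, B = 2, Vhat = 1.75 => psrf = sqrt(1.75 / (5/3))
  expect_equal(r$psrf$psrf, sqrt(1.75 / (5 / 3)), tolerance = 1e-10)
})

test_that("identical chains give psrf = sqrt((n-1)/n)", {
  d <- matrix(rnorm(50), ncol = 1, dimnames = list(NULL, "b"))
  expect_error(gelman_rubin(sem_chains(list(d, d), burn_in = 0)), NA)
  r <- gelman_rubin(sem_chains(list(d, d, d), burn_in = 0))
  expect_equal(r$psrf$psrf, sqrt(49 / 50))
  expect_lte(r$psrf$psrf, 1)
})

test_that("iid chains sit near 1 and agree with an external implementation", {
  set.seed(81)
  dr <- lapply(1:4, function(k) {
    matrix(rnorm(5000 * 3), 5000, 3, dimnames = list(NULL, c("a", "b", "c")))
  })
  ch <- sem_chains(dr, burn_in = 0)
  r <- gelman_rubin(ch)
  expect_true(all(r$psrf$psrf > 0.99 & r$psrf$psrf < 1.05))
  expect_gt(r$mpsrf, 0.99)
  expect_lt(r$mpsrf, 1.05)
  co <- coda::gelman.diag(coda::as.mcmc.list(lapply(dr, coda::as.mcmc)),
                          autoburnin = FALSE, transform = FALSE)
  expect_equal(r$mpsrf, unname(co$mpsrf), tolerance = 1e-3)
})

test_that("separated bimodal chains are detected as non-converged", {
  set.seed(82)
  a <- matrix(rnorm(2000, mean = -2), ncol = 1, dimnames = list(NULL, "b"))
  b <- matrix(rnorm(2000, mean = 2), ncol = 1, dimnames = list(NULL, "b"))
  r <- gelman_rubin(sem_chains(list(a, b), burn_in = 0))
  expect_gt(r$psrf$psrf, 1.1)
})

test_that("degenerate chain sets are rejected with a named parameter", {
  cst <- matrix(1, 10, 1, dimnames = list(NULL, "stuck"))
  rnd <- matrix(rnorm(10), 10, 1, dimnames = list(NULL, "stuck"))
  expect_error(gelman_rubin(sem_chains(list(cst, rnd), burn_in = 0)), "stuck")
  one <- sem_chains(list(rnd), burn_in = 0)
  expect_error(gelman_rubin(one), "2 chains")
  short <- sem_chains(list(rnd, rnd + 0.1), burn_in = 8)
  expect_error(gelman_rubin(short), "4 post-burn-in")
})

test_that("the Gibbs sampler is bit-identical under a fixed seed", {
  tm <- rubisco_fixture("final")
  d <- sem_simulate(tm, 48, seed = 90)
  c1 <- sem_bayes(d, tm$model, n_chains = 2, n_iter = 200, seed = 4)
  c2 <- sem_bayes(d, tm$model, n_chains = 2, n_iter = 200, seed = 4)
  expect_identical(c1$draws, c2$draws)
  c3 <- sem_bayes(d, tm$model, n_chains = 2, n_iter = 200, seed = 5)
  expect_false(identical(c1$draws, c3$draws))
})

test_that("the sampler rejects cycles and non-diagonal disturbances", {
  d <- data.frame(x = rnorm(30), y = rnorm(30))
  loop <- sem_model(paths = data.frame(from = c("x", "y"), to = c("y", "x")))
  expect_error(sem_bayes(d, loop, n_iter = 10), "recursive")
  covm <- sem_model(observed = c("x", "y"),
                    covariances = data.frame(a = "x", b = "y"))
  expect_error(sem_bayes(d, covm, n_iter = 10), "covariances")
  m <- single_path_model()
  expect_error(sem_bayes(d, m, n_chains = 1, n_iter = 10), "2 chains")
  expect_error(sem_bayes(d, m, n_iter = 10, burn_in = 10), "burn_in")
  expect_error(sem_bayes(d, m, n_iter = 10, prior_var_shape = 0), "positive")
})

test_that("posterior means track ML estimates on moderate samples", {
  tm <- rubisco_fixture("final")
  d <- sem_simulate(tm, 500, seed = 91)
  fit <- sem_fit(d, tm$model)
  ch <- sem_bayes(d, tm$model, n_chains = 2, n_iter = 2000, seed = 7)
  ps <- posterior_summary(ch)
  idx <- tm$model$params$class == "path"
  gap <- abs(ps$mean[idx] - fit$theta[idx])
  expect_true(all(gap < 3 * fit$se[idx]))
})

test_that("posterior summaries match brute-force pooled computation", {
  set.seed(93)
  dr <- lapply(1:3, function(k) {
    matrix(rnorm(400 * 2), 400, 2, dimnames = list(NULL, c("a", "b")))
  })
  ch <- sem_chains(dr, burn_in = 100)
  ps <- posterior_summary(ch)
  pooled <- do.call(rbind, lapply(dr, function(d) d[101:400, ]))
  expect_equal(ps$mean, colMeans(pooled))
  expect_equal(ps$sd, apply(pooled, 2, sd))
  expect_equal(ps$ci_low, apply(pooled, 2, quantile, 0.025),
               ignore_attr = TRUE)
  # equal-tail interval of a near-symmetric posterior contains the mean
  expect_true(all(ps$ci_low < ps$mean & ps$mean < ps$ci_high))
  expect_error(posterior_summary(ch, burn_in = 400), "burn_in")
})

test_that("constant chains summarize to their constant", {
  dr <- list(matrix(2.5, 50, 1, dimnames = list(NULL, "c")),
             matrix(2.5, 50, 1, dimnames = list(NULL, "c")))
  ps <- posterior_summary(sem_chains(dr, burn_in = 10))
  expect_equal(ps$mean, 2.5, ignore_attr = TRUE)
  expect_equal(ps$sd, 0, ignore_attr = TRUE)
})

test_that("a model with every parameter fixed yields an empty chain set", {
  m <- sem_model(paths = data.frame(from = "x", to = "y"),
                 fixed = c("y~x" = 0.5, "x~~x" = 1, "y~~y" = 1))
  expect_equal(n_free_params(m), 0)
  d <- data.frame(x = rnorm(20), y = rnorm(20))
  ch <- sem_bayes(d, m, n_chains = 2, n_iter = 50, seed = 1,
                  overdispersed_starts = FALSE)
  expect_equal(ncol(ch$draws[[1]]), 0)
  expect_equal(nrow(posterior_summary(ch)), 0)
})

test_that("psrf evolution stabilizes near 1 for a converged run", {
  tm <- rubisco_fixture("final")
  d <- sem_simulate(tm, 48, seed = 95)
  ch <- sem_bayes(d, tm$model, n_chains = 2, n_iter = 600, seed = 2)
  ev <- psrf_evolution(ch, n_bins = 5)
  expect_true(all(c("iteration", "label", "psrf", "mpsrf") %in% names(ev)))
  expect_gt(nrow(ev), 0)
  last <- ev[ev$iteration == max(ev$iteration), ]
  expect_true(all(is.finite(last$psrf)))
})
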