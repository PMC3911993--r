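test_that("collinear groups match a union-find oracle on random data", {
  set.seed(41)
  for (rep in 1:5) {
    n <- 200
    p <- 8
    X <- matrix(rnorm(n * p), n, p)
    # plant a near-duplicate pair and a triple
    X[, 2] <- X[, 1] + rnorm(n, sd = 0.2)
    X[, 5] <- X[, 4] + rnorm(n, sd = 0.25)
    X[, 6] <- X[, 4] + rnorm(n, sd = 0.25)
    colnames(X) <- paste0("v", seq_len(p))
    thr <- 0.8
    got <- detect_collinear_groups(as.data.frame(X), thr)
    want <- oracle_collinear_groups(X, thr)
    expect_identical(got[order(vapply(got, `[`, "", 1))],
                     want[order(vapply(want, `[`, "", 1))])
  }
})

test_that("independent variables give no collinear groups", {
  set.seed(42)
  X <- as.data.frame(matrix(rnorm(500 * 5), 500, 5))
  expect_identical(detect_collinear_groups(X, 0.9), list())
})

test_that("fixture data yield exactly the two planted groups", {
  tm <- rubisco_fixture("final")
  d <- sem_simulate(tm, 1000, seed = 50)
  groups <- detect_collinear_groups(d, 0.9)
  expect_equal(length(groups), 2)
  expect_true(any(vapply(groups, identical, TRUE, c("RSS174", "RSS175"))))
  expect_true(any(vapply(groups, identical, TRUE, c("dp15", "dp17"))))
})

test_that("collapsing a group re-attaches and merges its paths", {
  g <- build_prior_graph(fragment_fixture(1), rubisco_regulation())
  sk <- to_sem_skeleton(g)
  m <- collapse_to_latent(sk, c("dp15", "dp17"), "dplat")
  expect_true("dplat" %in% names(m$latents))
  # dp39 -> dp15 and dp39 -> dp17 merged into a single dp39 -> dplat path
  expect_equal(sum(m$paths$from == "dp39" & m$paths$to == "dplat"), 1)
  expect_false(any(m$paths$to %in% c("dp15", "dp17")))
  # free-slot bookkeeping survives the rebuild: recount from scratch
  recount <- sum(m$lambda_free) + sum(m$beta_free) +
    sum(m$psi_free[upper.tri(m$psi_free, diag = TRUE)]) +
    sum(diag(m$theta_free))
  expect_equal(n_free_params(m), recount)
  expect_error(collapse_to_latent(sk, "dp15", "solo"), "at least 2")
})

test_that("collapsing a group with no incident paths keeps indicators only", {
  m <- sem_model(paths = data.frame(from = "a", to = "b"),
                 observed = c("a", "b", "c", "d"))
  m2 <- collapse_to_latent(m, c("c", "d"), "lat")
  expect_identical(m2$latents$lat, c("c", "d"))
  expect_identical(m2$paths$from, "a")
})

test_that("prune_step removes the largest non-significant path, then stops", {
  set.seed(60)
  n <- 800
  x <- rnorm(n)
  z <- rnorm(n)
  y <- 0.6 * x + 0 * z + rnorm(n)
  d <- data.frame(x = x, z = z, y = y)
  m <- sem_model(paths = data.frame(from = c("x", "z"), to = "y"),
                 covariances = data.frame(a = "x", b = "z"))
  fit <- sem_fit(d, m)
  step <- prune_step(m, fit, 0.05)
  expect_identical(step$removed, "y~z")
  fit2 <- sem_fit(d, step$model)
  expect_null(prune_step(step$model, fit2, 0.05))
})

test_that("search collapses the planted groups and prunes the true-zero paths", {
  tm <- rubisco_fixture("final")
  d <- sem_simulate(tm, 5000, seed = 70)
  sk <- to_sem_skeleton(build_prior_graph(fragment_fixture(1),
                                          rubisco_regulation()))
  res <- suppressMessages(sem_search(d, sk))
  expect_setequal(
    unlist(lapply(res$collinear_groups, paste, collapse = "+")),
    c("RSS174+RSS175", "dp15+dp17"))
  kept <- paste(res$model$paths$to, res$model$paths$from, sep = "~")
  expect_setequal(kept, c("dp_lat~dp39", "dp7~dp39"))
  # the trace replays: collapse steps first, then prunes, then stop
  acts <- res$trace$action
  expect_identical(acts[1:2], c("collapse", "collapse"))
  expect_identical(acts[length(acts)], "stop")
  expect_true(all(acts[3:(length(acts) - 1)] == "prune"))
})

test_that("search is deterministic given the data", {
  tm <- rubisco_fixture("final")
  d <- sem_simulate(tm, 300, seed = 71)
  sk <- to_sem_skeleton(build_prior_graph(fragment_fixture(1),
                                          rubisco_regulation()))
  r1 <- suppressMessages(sem_search(d, sk))
  r2 <- suppressMessages(sem_search(d, sk))
  expect_identical(r1$trace, r2$trace)
  expect_identical(r1$fit$theta, r2$fit$theta)
})

test_that("data generated from the model itself needs no pruning", {
  tm <- rubisco_fixture("final")
  d <- sem_simulate(tm, 5000, seed = 72)
  res <- suppressMessages(sem_search(d, tm$model))
  expect_false(any(res$trace$action == "prune"))
})

test_that("pruning strictly increases df and terminates", {
  tm <- rubisco_fixture("final")
  d <- sem_simulate(tm, 5000, seed = 73)
  sk <- to_sem_skeleton(build_prior_graph(fragment_fixture(1),
                                          rubisco_regulation()))
  res <- suppressMessages(sem_search(d, sk))
  prunes <- res$trace[res$trace$action == "prune", ]
  expect_true(all(diff(prunes$df) == 1))
  expect_true(all(diff(prunes$n_params) == -1))
  expect_lte(nrow(prunes), n_free_params(sk))
})
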