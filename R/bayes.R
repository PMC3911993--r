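#' Multi-chain MCMC draws
#'
#' Container for posterior draws, either produced by [sem_bayes()] or wrapped
#' around externally generated chains for diagnostic use.
#'
#' @param draws List of numeric matrices (one per chain, iterations x
#'   parameters, identical dimensions and column names).
#' @param burn_in Number of leading iterations to discard in summaries.
#' @param model Optional [sem_model()] the draws belong to.
#' @param config Optional list echoing the sampler configuration.
#' @return A `sem_chains` object.
#' @export
sem_chains <- function(draws, burn_in = 0, model = NULL, config = NULL) {
  stopifnot(is.list(draws), length(draws) >= 1)
  dims <- vapply(draws, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    rlang::abort("all chains must have identical dimensions")
  }
  if (burn_in >= dims[1, 1]) rlang::abort("burn_in must be below chain length")
  draws <- lapply(draws, function(d) {
    if (is.null(colnames(d)) && ncol(d) > 0) {
      colnames(d) <- paste0("par", seq_len(ncol(d)))
    }
    d
  })
  structure(list(draws = draws, burn_in = burn_in, model = model,
                 config = config),
            class = "sem_chains")
}

#' @export
print.sem_chains <- function(x, ...) {
  cat("<sem_chains> ", length(x$draws), " chains x ", nrow(x$draws[[1]]),
      " iterations, ", ncol(x$draws[[1]]), " parameters (burn-in ",
      x$burn_in, ")\n", sep = "")
  invisible(x)
}

#' Bayesian re-estimation of a structural equation model by Gibbs sampling
#'
#' Data-augmentation MCMC for recursive SEMs with independent structural
#' disturbances: each sweep (a) samples latent factor scores from their
#' multivariate-normal full conditional, (b) samples structural coefficients
#' and free loadings equation-by-equation from conjugate normal
#' conditionals, and (c) samples disturbance and measurement-error variances
#' from conjugate inverse-gamma conditionals. Priors are normal(0,
#' `prior_coef_sd`^2) on coefficients and inverse-gamma(`prior_var_shape`,
#' `prior_var_rate`) on variances -- weakly informative defaults that keep
#' every conditional closed-form.
#'
#' Chains start from the maximum-likelihood solution perturbed by
#' chain-specific overdispersed offsets (about two standard errors), so the
#' Gelman-Rubin diagnostic has distinct starting points to contrast. A fixed
#' `seed` makes the draws bit-identical.
#'
#' Models with structural cycles (including self-feedback loops) are
#' rejected: prune the feedback path before the Bayesian stage. Free
#' disturbance covariances are likewise an ML-stage feature only.
#'
#' @param data Data frame of samples x variables.
#' @param model A recursive [sem_model()].
#' @param n_chains Number of chains (>= 2; default 4).
#' @param n_iter Iterations per chain (default 20000).
#' @param burn_in Discarded leading iterations (default `n_iter/2`).
#' @param seed Base seed; chain k uses `seed + k - 1`.
#' @param prior_coef_sd Normal prior SD for loadings and paths (default 10).
#' @param prior_var_shape,prior_var_rate Inverse-gamma hyperparameters for
#'   variances (default 0.001, 0.001).
#' @param overdispersed_starts Start chains at ML +/- ~2 SE offsets
#'   (default `TRUE`).
#' @return A [sem_chains()] object with one iterations x parameters matrix
#'   per chain, columns ordered and named as the model's parameter table.
#' @export
sem_bayes <- function(data, model, n_chains = 4, n_iter = 20000,
                      burn_in = n_iter %/% 2, seed = 1,
                      prior_coef_sd = 10, prior_var_shape = 0.001,
                      prior_var_rate = 0.001, overdispersed_starts = TRUE) {
  stopifnot(inherits(model, "sem_model"))
  if (n_chains < 2) rlang::abort("Gelman-Rubin diagnostics need >= 2 chains")
  if (burn_in >= n_iter) rlang::abort("burn_in must be below n_iter")
  if (prior_coef_sd <= 0 || prior_var_shape <= 0 || prior_var_rate <= 0) {
    rlang::abort("prior hyperparameters must be positive")
  }
  if (!model_is_recursive(model)) {
    rlang::abort(paste0(
      "the Gibbs sampler needs a recursive structural matrix; feedback ",
      "loop(s) involving: ", paste(feedback_nodes(model), collapse = ", "),
      ". Prune the feedback path(s) before Bayesian estimation."))
  }
  offd <- model$psi_free
  diag(offd) <- FALSE
  if (any(offd)) {
    rlang::abort(paste0(
      "free disturbance covariances are not supported by the conjugate ",
      "Gibbs sweep; fix or remove them before Bayesian estimation"))
  }
  df <- as.data.frame(data)
  missing <- setdiff(model$observed, colnames(df))
  if (length(missing)) {
    rlang::abort(paste0("data lack model variables: ",
                        paste(missing, collapse = ", ")))
  }
  Y <- as.matrix(df[stats::complete.cases(df[, model$observed, drop = FALSE]),
                    model$observed, drop = FALSE])
  n <- nrow(Y)
  pr <- model$params
  q <- nrow(pr)

  # chain starting vectors
  starts <- gibbs_starts(model, Y, n_chains, seed, overdispersed_starts)

  # structure bookkeeping
  eta_names <- model$eta
  m <- length(eta_names)
  stoch <- names(model$latents)
  determ <- model$pass_through
  tau2 <- prior_coef_sd^2
  a0 <- prior_var_shape
  b0 <- prior_var_rate

  # per-node free predictors and fixed offsets
  node_pred <- lapply(eta_names, function(i) eta_names[model$beta_free[i, ]])
  names(node_pred) <- eta_names
  # indicator info for declared latents
  ind_info <- lapply(stoch, function(l) {
    ind <- model$latents[[l]]
    list(ind = ind, lambda_free = model$lambda_free[ind, l],
         theta_free = diag(model$theta_free)[match(ind, model$observed)])
  })
  names(ind_info) <- stoch

  chains <- vector("list", n_chains)
  for (k in seq_len(n_chains)) {
    set.seed(seed + k - 1L)
    chains[[k]] <- gibbs_chain(
      model, Y, n_iter, starts[[k]], node_pred, ind_info, stoch, determ,
      tau2, a0, b0
    )
  }
  sem_chains(
    chains, burn_in = burn_in, model = model,
    config = list(n_chains = n_chains, n_iter = n_iter, burn_in = burn_in,
                  seed = seed, prior_coef_sd = prior_coef_sd,
                  prior_var_shape = prior_var_shape,
                  prior_var_rate = prior_var_rate,
                  overdispersed_starts = overdispersed_starts)
  )
}

gibbs_starts <- function(model, Y, n_chains, seed, overdispersed) {
  q <- n_free_params(model)
  vcls <- model$params$class %in% c("variance", "error")
  base <- se <- NULL
  if (overdispersed && q > 0) {
    fit <- tryCatch(
      suppressWarnings(sem_fit(as.data.frame(Y), model)),
      error = function(e) NULL
    )
    if (!is.null(fit) && !anyNA(fit$se)) {
      base <- fit$theta
      se <- fit$se
    }
  }
  if (is.null(base)) {
    base <- sem_start(model, stats::cov(Y))
    se <- pmax(abs(base) * 0.25, 0.25)
  }
  lapply(seq_len(n_chains), function(k) {
    set.seed(seed + 1000L + k)
    th <- base + stats::rnorm(q, 0, 2 * pmin(se, 1))
    th[vcls] <- pmax(base[vcls], 0.05) * exp(stats::rnorm(sum(vcls), 0, 0.5))
    names(th) <- model$params$label
    th
  })
}

gibbs_chain <- function(model, Y, n_iter, theta0, node_pred, ind_info,
                        stoch, determ, tau2, a0, b0) {
  pr <- model$params
  q <- nrow(pr)
  n <- nrow(Y)
  eta_names <- model$eta
  m <- length(eta_names)
  mats <- sem_matrices(model, theta0)
  # keep variances positive at the start
  diag(mats$psi) <- pmax(diag(mats$psi), 1e-3)
  if (length(stoch)) {
    all_ind <- unlist(model$latents, use.names = FALSE)
    idx <- match(all_ind, model$observed)
    d <- diag(mats$theta)
    d[idx] <- pmax(d[idx], 1e-3)
    diag(mats$theta) <- d
  }

  eta <- matrix(0, n, m, dimnames = list(NULL, eta_names))
  eta[, determ] <- Y[, determ]
  # initialize stochastic latents at their indicator means
  for (l in stoch) eta[, l] <- rowMeans(Y[, model$latents[[l]], drop = FALSE])

  out <- matrix(NA_real_, n_iter, q)
  colnames(out) <- pr$label
  psi_free_diag <- diag(model$psi_free)
  names(psi_free_diag) <- eta_names
  theta_free_diag <- diag(model$theta_free)
  names(theta_free_diag) <- model$observed

  for (it in seq_len(n_iter)) {
    # (a) latent factor scores
    if (length(stoch)) {
      A <- diag(m) - mats$beta
      C <- solve(A) %*% mats$psi %*% t(solve(A))
      Q <- solve((C + t(C)) / 2)
      P <- Q[stoch, stoch, drop = FALSE]
      contrib <- matrix(0, n, length(stoch))
      for (s in seq_along(stoch)) {
        info <- ind_info[[s]]
        lam <- mats$lambda[info$ind, stoch[s]]
        th <- diag(mats$theta)[match(info$ind, model$observed)]
        P[s, s] <- P[s, s] + sum(lam^2 / th)
        contrib[, s] <- Y[, info$ind, drop = FALSE] %*% (lam / th)
      }
      rhs <- t(contrib)
      if (length(determ)) {
        rhs <- rhs - Q[stoch, determ, drop = FALSE] %*%
          t(eta[, determ, drop = FALSE])
      }
      R <- chol((P + t(P)) / 2)
      mu <- backsolve(R, backsolve(R, rhs, transpose = TRUE))
      z <- matrix(stats::rnorm(length(stoch) * n), length(stoch), n)
      eta[, stoch] <- t(mu + backsolve(R, z))
    }

    # (b) structural coefficients + (c) disturbance variances, per node
    for (i in eta_names) {
      pred <- node_pred[[i]]
      fixed_row <- mats$beta[i, ]
      fixed_row[pred] <- 0
      offset <- if (any(fixed_row != 0)) eta %*% fixed_row else 0
      r <- eta[, i] - offset
      psi_i <- mats$psi[i, i]
      if (length(pred)) {
        X <- eta[, pred, drop = FALSE]
        prec <- crossprod(X) / psi_i + diag(1 / tau2, length(pred))
        Rp <- chol((prec + t(prec)) / 2)
        mean_b <- backsolve(Rp, backsolve(Rp, crossprod(X, r) / psi_i,
                                          transpose = TRUE))
        b <- mean_b + backsolve(Rp, stats::rnorm(length(pred)))
        mats$beta[i, pred] <- b
        r <- r - X %*% b
      }
      if (psi_free_diag[i]) {
        mats$psi[i, i] <- 1 / stats::rgamma(1, a0 + n / 2,
                                            b0 + sum(r^2) / 2)
      }
    }

    # measurement model for declared latents
    for (s in seq_along(stoch)) {
      l <- stoch[s]
      info <- ind_info[[s]]
      h <- eta[, l]
      for (jj in seq_along(info$ind)) {
        j <- info$ind[jj]
        th_j <- mats$theta[j, j]
        if (info$lambda_free[jj]) {
          prec <- sum(h^2) / th_j + 1 / tau2
          mean_l <- sum(h * Y[, j]) / th_j / prec
          mats$lambda[j, l] <- stats::rnorm(1, mean_l, sqrt(1 / prec))
        }
        if (info$theta_free[jj]) {
          res <- Y[, j] - mats$lambda[j, l] * h
          mats$theta[j, j] <- 1 / stats::rgamma(1, a0 + n / 2,
                                                b0 + sum(res^2) / 2)
        }
      }
    }

    # record current parameter vector
    if (q > 0) {
      for (kk in seq_len(q)) {
        out[it, kk] <- switch(pr$matrix[kk],
          lambda = mats$lambda[pr$row[kk], pr$col[kk]],
          beta = mats$beta[pr$row[kk], pr$col[kk]],
          psi = mats$psi[pr$row[kk], pr$col[kk]],
          theta = mats$theta[pr$row[kk], pr$col[kk]]
        )
      }
    }
  }
  out
}

#' Gelman-Rubin convergence diagnostics
#'
#' Per parameter, with m chains of length n (post burn-in): W is the mean
#' within-chain variance, B = n x variance of the chain means,
#' \eqn{\hat V = ((n-1)/n) W + B/n}, and psrf = sqrt(\eqn{\hat V}/W) (the
#' basic Gelman-Rubin form, without the sampling-variability df correction).
#' The multivariate psrf is the Brooks-Gelman statistic
#' \eqn{\sqrt{(n-1)/n + ((m+1)/m)\lambda_1}} with \eqn{\lambda_1} the largest
#' eigenvalue of \eqn{W^{-1} B/n} computed from the pooled within-chain and
#' between-chain-mean covariance matrices.
#'
#' @param chains A [sem_chains()] object.
#' @param burn_in Burn-in override (default: the object's own).
#' @return A `convergence_report`: list with `psrf` (tibble `label`, `psrf`),
#'   `mpsrf`, `n_used`, `n_chains`.
#' @export
gelman_rubin <- function(chains, burn_in = NULL) {
  stopifnot(inherits(chains, "sem_chains"))
  if (is.null(burn_in)) burn_in <- chains$burn_in
  m <- length(chains$draws)
  if (m < 2) rlang::abort("need >= 2 chains")
  len <- nrow(chains$draws[[1]])
  if (burn_in >= len) rlang::abort("burn_in must be below chain length")
  post <- lapply(chains$draws, function(d) {
    d[(burn_in + 1):len, , drop = FALSE]
  })
  n <- nrow(post[[1]])
  if (n < 4) rlang::abort("need >= 4 post-burn-in draws per chain")
  qn <- ncol(post[[1]])
  if (qn == 0) rlang::abort("chains carry no free parameters")
  labels <- colnames(post[[1]])

  within <- sapply(post, function(d) apply(d, 2, stats::var)) # q x m
  within <- matrix(within, nrow = qn)
  degenerate <- apply(within == 0, 1, any)
  if (any(degenerate)) {
    rlang::abort(paste0("zero within-chain variance for ",
                        paste(labels[degenerate], collapse = ", ")))
  }
  W <- rowMeans(within)
  means <- sapply(post, colMeans)
  means <- matrix(means, nrow = qn)
  B <- n * apply(means, 1, stats::var)
  Vhat <- ((n - 1) / n) * W + B / n
  psrf <- sqrt(Vhat / W)

  Wmat <- Reduce(`+`, lapply(post, stats::cov)) / m
  Vb <- stats::cov(t(means)) # = B_matrix / n
  lam1 <- max(Re(eigen(solve(Wmat, Vb), only.values = TRUE)$values))
  mpsrf <- sqrt((n - 1) / n + ((m + 1) / m) * lam1)

  structure(
    list(psrf = tibble::tibble(label = labels, psrf = psrf),
         mpsrf = mpsrf, n_used = n, n_chains = m),
    class = "convergence_report"
  )
}

#' @export
print.convergence_report <- function(x, ...) {
  cat("<convergence_report> ", x$n_chains, " chains, ", x$n_used,
      " post-burn-in draws each\n", sep = "")
  cat("  multivariate psrf: ", format(round(x$mpsrf, 4)), "\n", sep = "")
  cat("  max univariate psrf: ", format(round(max(x$psrf$psrf), 4)),
      " (", x$psrf$label[which.max(x$psrf$psrf)], ")\n", sep = "")
  invisible(x)
}

#' Posterior summaries
#'
#' Pooled post-burn-in summaries per free parameter: mean, SD, median, 95%
#' equal-tail credible interval, and a batch-means Monte-Carlo standard
#' error of the posterior mean. With `standardized = TRUE`, standardized
#' coefficients are computed per (thinned) draw and summarized the same way.
#'
#' @param chains A [sem_chains()] object.
#' @param burn_in Burn-in override.
#' @param standardized Also summarize standardized coefficients (requires the
#'   chains to carry their model).
#' @param max_std_draws Thinning cap for the per-draw standardization
#'   (default 2000 pooled draws).
#' @return A tibble with one row per parameter.
#' @export
posterior_summary <- function(chains, burn_in = NULL, standardized = FALSE,
                              max_std_draws = 2000) {
  stopifnot(inherits(chains, "sem_chains"))
  if (is.null(burn_in)) burn_in <- chains$burn_in
  len <- nrow(chains$draws[[1]])
  if (burn_in >= len) rlang::abort("burn_in must be below chain length")
  post <- lapply(chains$draws, function(d) {
    d[(burn_in + 1):len, , drop = FALSE]
  })
  pooled <- do.call(rbind, post)
  if (ncol(pooled) == 0) {
    return(tibble::tibble(label = character(), mean = numeric(),
                          sd = numeric(), median = numeric(),
                          ci_low = numeric(), ci_high = numeric(),
                          mcse = numeric()))
  }
  mcse <- apply_batch_mcse(post)
  out <- tibble::tibble(
    label = colnames(pooled),
    mean = colMeans(pooled),
    sd = apply(pooled, 2, stats::sd),
    median = apply(pooled, 2, stats::median),
    ci_low = apply(pooled, 2, stats::quantile, 0.025),
    ci_high = apply(pooled, 2, stats::quantile, 0.975),
    mcse = mcse
  )
  if (standardized) {
    if (is.null(chains$model)) {
      rlang::abort("standardized summaries need chains produced by sem_bayes()")
    }
    thin <- max(1L, floor(nrow(pooled) / max_std_draws))
    sub <- pooled[seq(1, nrow(pooled), by = thin), , drop = FALSE]
    stds <- apply(sub, 1, function(th) {
      sem_standardize(chains$model, th)$std_estimate
    })
    stds <- matrix(stds, ncol = nrow(sub))
    out$std_mean <- rowMeans(stds)
    out$std_ci_low <- apply(stds, 1, stats::quantile, 0.025)
    out$std_ci_high <- apply(stds, 1, stats::quantile, 0.975)
  }
  out
}

# batch-means MCSE of the posterior mean, batches within chains
apply_batch_mcse <- function(post) {
  n <- nrow(post[[1]])
  nb <- max(2L, floor(sqrt(n)))
  bl <- n %/% nb
  bm <- lapply(post, function(d) {
    idx <- rep(seq_len(nb), each = bl)
    d <- d[seq_len(nb * bl), , drop = FALSE]
    apply(d, 2, function(x) tapply(x, idx, mean))
  })
  bm <- do.call(rbind, bm) # (nb * chains) x q batch means
  apply(bm, 2, stats::sd) / sqrt(nrow(bm))
}

#' Running potential scale reduction factors
#'
#' Recomputes the Gelman-Rubin diagnostics on growing prefixes of the chains
#' (discarding the first half of each prefix), giving the iteration-wise
#' psrf evolution commonly plotted to visualize convergence.
#'
#' @param chains A [sem_chains()] object.
#' @param n_bins Number of prefix lengths to evaluate (default 20).
#' @return A tibble with `iteration`, `label`, `psrf`, `mpsrf`.
#' @export
psrf_evolution <- function(chains, n_bins = 20) {
  stopifnot(inherits(chains, "sem_chains"))
  len <- nrow(chains$draws[[1]])
  pts <- unique(round(seq(max(20, len / n_bins), len, length.out = n_bins)))
  out <- list()
  for (l in pts) {
    sub <- sem_chains(lapply(chains$draws, function(d) {
      d[seq_len(l), , drop = FALSE]
    }), burn_in = l %/% 2)
    rep <- tryCatch(gelman_rubin(sub), error = function(e) NULL)
    if (is.null(rep)) next
    out[[length(out) + 1L]] <- dplyr::mutate(rep$psrf, iteration = l,
                                             mpsrf = rep$mpsrf)
  }
  dplyr::bind_rows(out)[, c("iteration", "label", "psrf", "mpsrf")]
}
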