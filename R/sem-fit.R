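#' Sample covariance matrix with SEM-style checks
#'
#' Computes the unbiased (divisor N-1) covariance matrix after listwise
#' deletion of incomplete rows. Zero-variance columns are an error because
#' they make the covariance matrix singular and the ML discrepancy undefined.
#'
#' @param data A data frame or matrix of numeric columns (samples in rows).
#' @return A `sample_moments` object: list with `S` (covariance), `n`
#'   (samples used) and `names`.
#' @export
sample_covariance <- function(data) {
  X <- as.matrix(as.data.frame(data))
  if (!is.numeric(X)) rlang::abort("`data` must be numeric")
  keep <- stats::complete.cases(X)
  X <- X[keep, , drop = FALSE]
  n <- nrow(X)
  if (n < 3) rlang::abort("need at least 3 complete samples")
  v <- apply(X, 2, stats::var)
  if (any(v == 0)) {
    rlang::abort(paste0("zero-variance column(s): ",
                        paste(colnames(X)[v == 0], collapse = ", ")))
  }
  S <- stats::cov(X)
  structure(list(S = S, n = n, names = colnames(X)),
            class = "sample_moments")
}

#' Model-implied covariance matrix
#'
#' \eqn{\Sigma(\theta) = \Lambda (I-B)^{-1} \Psi (I-B)^{-T} \Lambda^T +
#' \Theta_\epsilon}, ordered as `model$observed`.
#'
#' @param model A [sem_model()].
#' @param theta Numeric parameter vector (length [n_free_params()]).
#' @return A symmetric p x p matrix.
#' @export
implied_covariance <- function(model, theta) {
  mats <- sem_matrices(model, theta)
  M <- inv_i_minus_b(model, mats$beta)
  C <- M %*% mats$psi %*% t(M)
  Sigma <- mats$lambda %*% C %*% t(mats$lambda) + mats$theta
  (Sigma + t(Sigma)) / 2
}

inv_i_minus_b <- function(model, beta) {
  A <- diag(nrow(beta)) - beta
  if (abs(det(A)) < 1e-12) {
    fb <- feedback_nodes(model)
    rlang::abort(paste0(
      "I - B is singular at these parameter values; feedback loop(s) ",
      "involving: ", paste(fb, collapse = ", ")
    ))
  }
  solve(A)
}

# latent (node-level) covariance matrix at theta
latent_covariance <- function(model, theta) {
  mats <- sem_matrices(model, theta)
  M <- inv_i_minus_b(model, mats$beta)
  M %*% mats$psi %*% t(M)
}

#' Maximum-likelihood discrepancy between two covariance matrices
#'
#' \eqn{F = \log|\Sigma| + tr(S\Sigma^{-1}) - \log|S| - p}. Non-negative,
#' zero exactly when the matrices coincide.
#'
#' @param S,Sigma Symmetric positive-definite matrices of equal order.
#' @return A non-negative scalar.
#' @export
ml_discrepancy <- function(S, Sigma) {
  p <- nrow(S)
  if (!isTRUE(all.equal(dim(S), dim(Sigma)))) {
    rlang::abort("S and Sigma must have the same order")
  }
  Rs <- tryCatch(chol(S), error = function(e) NULL)
  Rg <- tryCatch(chol(Sigma), error = function(e) NULL)
  if (is.null(Rs) || is.null(Rg)) {
    rlang::abort("both matrices must be positive definite")
  }
  ldS <- 2 * sum(log(diag(Rs)))
  ldG <- 2 * sum(log(diag(Rg)))
  Ginv <- chol2inv(Rg)
  ldG + sum(Ginv * S) - ldS - p
}

# penalized objective used inside the optimizer: large finite value when
# Sigma(theta) is not positive definite so line searches can back off
ml_objective <- function(model, S, ldS) {
  p <- nrow(S)
  function(theta) {
    Sigma <- tryCatch(implied_covariance(model, theta),
                      error = function(e) NULL)
    if (is.null(Sigma)) return(1e10)
    Rg <- tryCatch(chol(Sigma), error = function(e) NULL)
    if (is.null(Rg)) return(1e10 + sum(theta^2))
    Ginv <- chol2inv(Rg)
    2 * sum(log(diag(Rg))) + sum(Ginv * S) - ldS - p
  }
}

# analytic gradient of the ML discrepancy:
# dF/dtheta_k = tr[(Sigma^-1 - Sigma^-1 S Sigma^-1) dSigma/dtheta_k]
ml_gradient <- function(model, S) {
  pr <- model$params
  q <- nrow(pr)
  function(theta) {
    mats <- sem_matrices(model, theta)
    M <- tryCatch(inv_i_minus_b(model, mats$beta), error = function(e) NULL)
    if (is.null(M)) return(rep(0, q))
    C <- M %*% mats$psi %*% t(M)
    Sigma <- mats$lambda %*% C %*% t(mats$lambda) + mats$theta
    Rg <- tryCatch(chol((Sigma + t(Sigma)) / 2), error = function(e) NULL)
    if (is.null(Rg)) return(2 * theta) # gradient of the PD penalty
    Ginv <- chol2inv(Rg)
    A <- Ginv - Ginv %*% S %*% Ginv
    P <- mats$lambda %*% M                      # p x m
    ALC <- A %*% mats$lambda %*% C              # p x m  (for loadings)
    PAP <- t(P) %*% A %*% P                     # m x m  (for psi)
    BGR <- t(P) %*% ALC                         # m x m  (for beta)
    dimnames(A) <- list(model$observed, model$observed)
    dimnames(ALC) <- list(model$observed, model$eta)
    dimnames(PAP) <- dimnames(BGR) <- list(model$eta, model$eta)
    g <- numeric(q)
    for (k in seq_len(q)) {
      r <- pr$row[k]
      cc <- pr$col[k]
      g[k] <- switch(pr$matrix[k],
        lambda = 2 * ALC[r, cc],
        beta = 2 * BGR[r, cc],
        psi = if (r == cc) PAP[r, r] else 2 * PAP[r, cc],
        theta = A[r, cc]
      )
    }
    g
  }
}

#' Fit a structural equation model by maximum likelihood
#'
#' Minimizes the ML discrepancy between the sample covariance matrix and the
#' model-implied covariance with a quasi-Newton (BFGS) optimizer using the
#' analytic gradient. Standard errors come from the inverse numerical Hessian
#' of \eqn{(N-1)/2 \cdot F} at the optimum; when that Hessian is singular
#' (an unidentified ridge, e.g. a self-feedback loop) a Moore-Penrose
#' pseudo-inverse is used and a warning is recorded.
#'
#' @param data A data frame of samples x variables, or a `sample_moments`
#'   object from [sample_covariance()].
#' @param model A [sem_model()] whose observed variables are columns of
#'   `data`.
#' @param se Compute standard errors and Wald statistics (default `TRUE`).
#' @param start Optional named starting vector; defaults to 0.5 for loadings
#'   and paths and data-derived values for variances.
#' @param control Passed to [stats::optim()] (`maxit` default 2000, `reltol`
#'   default 1e-12).
#' @return A `sem_fit` object with elements `theta`, `se`, `z`, `p`,
#'   `standardized`, `indices` (see [fit_indices()]), `converged`, `n_iter`,
#'   `warnings`, plus the inputs needed to reproduce the fit. Use
#'   [tidy()][generics::tidy] and [glance()][generics::glance] on it.
#' @examples
#' tm <- rubisco_fixture("final")
#' d <- sem_simulate(tm, n = 200, seed = 1)
#' fit <- sem_fit(d, tm$model)
#' glance(fit)
#' @export
sem_fit <- function(data, model, se = TRUE, start = NULL, control = list()) {
  stopifnot(inherits(model, "sem_model"))
  p <- length(model$observed)
  if (p == 0) rlang::abort("cannot fit an empty model")
  q <- n_free_params(model)
  if (q > p * (p + 1) / 2) {
    rlang::abort(sprintf(
      "model is not identified: %d free parameters exceed p(p+1)/2 = %d",
      q, p * (p + 1) / 2))
  }
  moments <- as_sample_moments(data, model$observed)
  S <- moments$S[model$observed, model$observed]
  N <- moments$n

  ldS <- as.numeric(determinant(S)$modulus)
  fn <- ml_objective(model, S, ldS)
  gr <- ml_gradient(model, S)
  theta0 <- if (is.null(start)) sem_start(model, S) else start
  ctrl <- utils::modifyList(list(maxit = 2000, reltol = 1e-12, polish = TRUE),
                            control)
  polish <- isTRUE(ctrl$polish)
  ctrl$polish <- NULL
  opt <- stats::optim(theta0, fn, gr, method = "BFGS", control = ctrl)
  if (polish) {
    # restart once from the optimum (helps flat ridges)
    opt2 <- stats::optim(opt$par, fn, gr, method = "BFGS", control = ctrl)
    if (opt2$value < opt$value) {
      opt2$counts <- opt$counts + opt2$counts
      opt <- opt2
    }
  }
  theta_hat <- opt$par
  names(theta_hat) <- model$params$label
  converged <- opt$convergence == 0
  warnings <- character()
  if (!converged) {
    warnings <- c(warnings, "optimizer did not converge")
    rlang::warn("sem_fit: optimizer did not converge")
  }
  vcls <- model$params$class %in% c("variance", "error")
  if (any(theta_hat[vcls] < 0)) {
    warnings <- c(warnings, paste0(
      "Heywood case: negative variance estimate for ",
      paste(model$params$label[vcls][theta_hat[vcls] < 0], collapse = ", ")))
  }

  Fmin <- fn(theta_hat)
  Sigma_hat <- implied_covariance(model, theta_hat)
  Tstat <- max((N - 1) * Fmin, 0)
  df <- sem_df(model)
  indices <- if (df >= 1) {
    fit_indices(Tstat, df, N, S, Sigma_hat)
  } else {
    NULL
  }

  se_vec <- z <- pval <- rep(NA_real_, q)
  vcov_mat <- NULL
  if (se && q > 0) {
    H <- tryCatch(
      numDeriv::jacobian(gr, theta_hat, method = "Richardson",
                         method.args = list(r = 2)),
      error = function(e) NULL)
    if (!is.null(H)) {
      H <- ((N - 1) / 2) * (H + t(H)) / 2
      inv <- tryCatch(solve(H), error = function(e) NULL)
      if (is.null(inv) || any(diag(inv) < 0)) {
        inv <- MASS::ginv(H)
        warnings <- c(warnings,
                      "singular information matrix: pseudo-inverse standard errors")
      }
      vcov_mat <- inv
      se_vec <- sqrt(pmax(diag(inv), 0))
      z <- theta_hat / se_vec
      pval <- 2 * stats::pnorm(-abs(z))
    }
  }

  std <- tryCatch(sem_standardize(model, theta_hat), error = function(e) NULL)

  structure(
    list(
      model = model, theta = theta_hat, se = se_vec, z = z, p = pval,
      standardized = std, indices = indices, S = S, Sigma_hat = Sigma_hat,
      n = N, F_min = Fmin, chi_square = Tstat, df = df,
      converged = converged, n_iter = unname(opt$counts["function"]),
      warnings = warnings, vcov = vcov_mat
    ),
    class = "sem_fit"
  )
}

as_sample_moments <- function(data, vars) {
  if (inherits(data, "sample_moments")) {
    missing <- setdiff(vars, data$names)
    if (length(missing)) {
      rlang::abort(paste0("moments lack model variables: ",
                          paste(missing, collapse = ", ")))
    }
    return(data)
  }
  df <- as.data.frame(data)
  missing <- setdiff(vars, colnames(df))
  if (length(missing)) {
    rlang::abort(paste0("data lack model variables: ",
                        paste(missing, collapse = ", ")))
  }
  sample_covariance(df[, vars, drop = FALSE])
}

#' Goodness-of-fit indices for a covariance-structure model
#'
#' Computes the likelihood-ratio chi-square p-value, RMSEA with its 90%
#' noncentral-chi-square confidence interval and close-fit p-value
#' (H0: RMSEA <= 0.05), and SRMR.
#'
#' @param chi_square Test statistic \eqn{T = (N-1) F_{ML}}.
#' @param df Model degrees of freedom (must be >= 1).
#' @param n Sample size.
#' @param S Sample covariance matrix.
#' @param Sigma_hat Fitted model-implied covariance matrix.
#' @return A `fit_indices` object (list with `chi_square`, `df`, `p_chi`,
#'   `rmsea`, `rmsea_ci_low`, `rmsea_ci_high`, `rmsea_pclose`, `srmr`).
#' @export
fit_indices <- function(chi_square, df, n, S, Sigma_hat) {
  if (df < 1) rlang::abort("fit indices are undefined for df = 0")
  if (n < 2) rlang::abort("need n >= 2")
  Tstat <- chi_square
  p_chi <- stats::pchisq(Tstat, df, lower.tail = FALSE)
  denom <- df * (n - 1)
  rmsea <- sqrt(max(Tstat - df, 0) / denom)

  lam_low <- ncp_root(Tstat, df, 0.95)
  lam_high <- ncp_root(Tstat, df, 0.05)
  ci_low <- sqrt(lam_low / denom)
  ci_high <- sqrt(lam_high / denom)
  lam0 <- 0.05^2 * denom
  pclose <- suppressWarnings(
    stats::pchisq(Tstat, df, ncp = lam0, lower.tail = FALSE))

  Dmat <- (S - Sigma_hat) / sqrt(tcrossprod(diag(S)))
  srmr <- sqrt(mean(Dmat[lower.tri(Dmat, diag = TRUE)]^2))

  structure(
    list(chi_square = Tstat, df = df, p_chi = p_chi, rmsea = rmsea,
         rmsea_ci_low = ci_low, rmsea_ci_high = ci_high,
         rmsea_pclose = pclose, srmr = srmr, n = n),
    class = "fit_indices"
  )
}

# Solve pchisq(T, df, ncp = lambda) = target for lambda >= 0; 0 when no
# admissible root exists.
ncp_root <- function(Tstat, df, target) {
  pnc <- function(l) suppressWarnings(stats::pchisq(Tstat, df, ncp = l))
  if (pnc(0) <= target) return(0)
  upper <- max(Tstat, df) + 10
  while (pnc(upper) > target && upper < 1e7) upper <- upper * 2
  stats::uniroot(function(l) pnc(l) - target,
                 lower = 0, upper = upper, tol = 1e-8)$root
}

#' @export
print.fit_indices <- function(x, ...) {
  cat(sprintf(
    "chi-square %.3f (df = %d, p = %.3f)\nRMSEA %.3f [90%% CI %.3f, %.3f], p-close %.3f\nSRMR %.3f\n",
    x$chi_square, x$df, x$p_chi, x$rmsea, x$rmsea_ci_low, x$rmsea_ci_high,
    x$rmsea_pclose, x$srmr))
  invisible(x)
}

#' Standardized coefficients
#'
#' Rescales each structural path by the ratio of model-implied standard
#' deviations of source and target node, and each loading by the implied
#' standard deviations of latent and indicator, so coefficients are on the
#' correlation-like scale reported alongside pathway diagrams.
#'
#' @param model A [sem_model()].
#' @param theta Parameter vector at which to standardize.
#' @return A tibble with `label`, `class`, `estimate`, `std_estimate`.
#' @export
sem_standardize <- function(model, theta) {
  C <- latent_covariance(model, theta)
  Sigma <- implied_covariance(model, theta)
  eta_var <- diag(C)
  obs_var <- diag(Sigma)
  if (any(eta_var <= 0) || any(obs_var <= 0)) {
    rlang::abort("zero or negative implied variance; cannot standardize")
  }
  pr <- model$params
  std <- rep(NA_real_, nrow(pr))
  for (k in seq_len(nrow(pr))) {
    r <- pr$row[k]
    cc <- pr$col[k]
    std[k] <- switch(pr$class[k],
      path = theta[k] * sqrt(eta_var[cc] / eta_var[r]),
      loading = theta[k] * sqrt(eta_var[cc] / obs_var[r]),
      variance = theta[k] / eta_var[r],
      error = theta[k] / obs_var[r],
      covariance = theta[k] / sqrt(eta_var[r] * eta_var[cc])
    )
  }
  tibble::tibble(label = pr$label, class = pr$class,
                 estimate = unname(theta), std_estimate = std)
}

#' Wald tests for free parameters
#'
#' @param fit A `sem_fit` object with standard errors.
#' @param alpha Two-sided significance level (default 0.05).
#' @return A tibble with `label`, `class`, `estimate`, `se`, `z`, `p`,
#'   `significant`.
#' @export
wald_tests <- function(fit, alpha = 0.05) {
  stopifnot(inherits(fit, "sem_fit"))
  if (anyNA(fit$se)) rlang::abort("fit carries no standard errors")
  if (any(fit$se == 0)) {
    rlang::abort(paste0("zero standard error for ",
                        paste(names(fit$theta)[fit$se == 0], collapse = ", ")))
  }
  z <- fit$theta / fit$se
  tibble::tibble(
    label = fit$model$params$label,
    class = fit$model$params$class,
    estimate = unname(fit$theta),
    se = unname(fit$se),
    z = unname(z),
    p = unname(2 * stats::pnorm(-abs(z))),
    significant = unname(2 * stats::pnorm(-abs(z)) < alpha)
  )
}

#' @export
print.sem_fit <- function(x, ...) {
  cat("<sem_fit> ", length(x$model$observed), " observed variables, ",
      n_free_params(x$model), " free parameters\n", sep = "")
  cat("  converged: ", x$converged, " (", x$n_iter, " function evaluations)\n",
      sep = "")
  if (length(x$warnings)) cat("  warnings: ", paste(x$warnings, collapse = "; "),
                              "\n", sep = "")
  if (!is.null(x$indices)) print(x$indices)
  invisible(x)
}
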