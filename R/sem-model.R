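#' Specify a structural equation model
#'
#' Constructs the covariance-structure model shared by the maximum-likelihood
#' and Bayesian estimation stages. The parameterization is the all-y LISREL
#' form: every observed variable loads on a latent variable (observed-only
#' variables get a pass-through latent with loading fixed to 1 and zero
#' measurement error), structural paths connect latents, and the implied
#' covariance is \eqn{\Sigma = \Lambda (I-B)^{-1} \Psi (I-B)^{-T} \Lambda^T +
#' \Theta_\epsilon}.
#'
#' Each declared latent variable is scaled by fixing its first indicator's
#' loading to 1; remaining loadings and all indicator measurement-error
#' variances are free. Structural disturbance variances are free for every
#' node (exogenous variance and endogenous residual variance occupy the same
#' slot in \eqn{\Psi}).
#'
#' @param paths Data frame with columns `from`, `to` and optionally `value`
#'   (a number fixes the path; `NA` leaves it free). Entries refer to node
#'   variables (latents or observed-only variables), with `to ~ from`
#'   orientation. A row with `from == to` declares a self-feedback loop.
#' @param latents Named list; each element is a character vector of observed
#'   indicator variables measuring that latent.
#' @param observed Character vector of observed variable names (column order
#'   of the data). If `NULL`, inferred from `latents` and `paths`.
#' @param covariances Data frame with columns `a`, `b`: free disturbance
#'   covariances between node variables (e.g. correlated exogenous variables).
#' @param fixed Named numeric vector of additional constraints; names are
#'   parameter labels (`"to~from"`, `"lat=~ind"`, `"v~~v"`, `"a~~b"`).
#' @return An object of class `sem_model`.
#' @examples
#' m <- sem_model(
#'   paths   = data.frame(from = c("RSS", "dp39"), to = c("dp39", "dp7")),
#'   latents = list(RSS = c("RSS174", "RSS175"))
#' )
#' m
#' @export
sem_model <- function(paths = NULL, latents = list(), observed = NULL,
                      covariances = NULL, fixed = NULL) {
  paths <- normalize_paths(paths)
  if (length(latents)) {
    if (is.null(names(latents)) || any(!nzchar(names(latents)))) {
      rlang::abort("every latent must be named")
    }
    if (anyDuplicated(names(latents))) rlang::abort("duplicate latent names")
  }
  indicators <- unlist(latents, use.names = FALSE)
  if (anyDuplicated(indicators)) {
    rlang::abort("an observed variable can indicate at most one latent")
  }
  if (is.null(observed)) {
    endpoints <- setdiff(unique(c(paths$from, paths$to)), names(latents))
    observed <- unique(c(indicators, endpoints))
  }
  observed <- as.character(observed)
  if (anyDuplicated(observed)) rlang::abort("duplicate observed variable names")
  if (any(names(latents) %in% observed)) {
    rlang::abort("latent names must not collide with observed variable names")
  }
  if (!all(indicators %in% observed)) {
    rlang::abort("all latent indicators must be observed variables")
  }

  pass_through <- setdiff(observed, indicators)
  eta <- c(pass_through, names(latents))
  bad <- setdiff(unique(c(paths$from, paths$to)), eta)
  if (length(bad)) {
    rlang::abort(paste0(
      "path endpoints must be node variables (latents or non-indicator ",
      "observed variables); unknown: ", paste(bad, collapse = ", ")
    ))
  }
  covariances <- normalize_covariances(covariances, eta)

  p <- length(observed)
  m <- length(eta)
  dn_l <- list(observed, eta)
  dn_b <- list(eta, eta)
  dn_t <- list(observed, observed)

  lambda_value <- matrix(0, p, m, dimnames = dn_l)
  lambda_free <- matrix(FALSE, p, m, dimnames = dn_l)
  theta_value <- matrix(0, p, p, dimnames = dn_t)
  theta_free <- matrix(FALSE, p, p, dimnames = dn_t)
  beta_value <- matrix(0, m, m, dimnames = dn_b)
  beta_free <- matrix(FALSE, m, m, dimnames = dn_b)
  psi_value <- matrix(0, m, m, dimnames = dn_b)
  psi_free <- matrix(FALSE, m, m, dimnames = dn_b)

  # pass-through measurement: loading 1, error 0 (both fixed)
  for (v in pass_through) lambda_value[v, v] <- 1
  # declared latents: first loading anchored at 1, the rest free; free errors
  for (l in names(latents)) {
    ind <- latents[[l]]
    lambda_value[ind[1L], l] <- 1
    if (length(ind) > 1L) lambda_free[cbind(ind[-1L], l)] <- TRUE
    theta_free[cbind(ind, ind)] <- TRUE
  }
  diag(psi_free) <- TRUE
  if (nrow(covariances)) {
    psi_free[cbind(covariances$a, covariances$b)] <- TRUE
    psi_free[cbind(covariances$b, covariances$a)] <- TRUE
  }
  if (nrow(paths)) {
    fixed_path <- !is.na(paths$value)
    beta_free[cbind(paths$to[!fixed_path], paths$from[!fixed_path])] <- TRUE
    beta_value[cbind(paths$to[fixed_path], paths$from[fixed_path])] <-
      paths$value[fixed_path]
  }

  model <- structure(
    list(
      observed = observed, eta = eta, latents = latents,
      pass_through = pass_through, paths = paths, covariances = covariances,
      lambda_value = lambda_value, lambda_free = lambda_free,
      beta_value = beta_value, beta_free = beta_free,
      psi_value = psi_value, psi_free = psi_free,
      theta_value = theta_value, theta_free = theta_free,
      fixed = NULL
    ),
    class = "sem_model"
  )
  if (!is.null(fixed) && length(fixed)) model <- apply_fixes(model, fixed)
  model$params <- build_param_table(model)
  model
}

normalize_paths <- function(paths) {
  if (is.null(paths) || !nrow(as.data.frame(paths))) {
    return(tibble::tibble(from = character(), to = character(),
                          value = numeric()))
  }
  paths <- tibble::as_tibble(paths)
  if (!all(c("from", "to") %in% names(paths))) {
    rlang::abort("`paths` needs columns `from` and `to`")
  }
  if (!"value" %in% names(paths)) paths$value <- NA_real_
  paths <- dplyr::distinct(paths, .data$from, .data$to, .keep_all = TRUE)
  paths[, c("from", "to", "value")]
}

normalize_covariances <- function(covariances, eta) {
  if (is.null(covariances) || !nrow(as.data.frame(covariances))) {
    return(tibble::tibble(a = character(), b = character()))
  }
  covariances <- tibble::as_tibble(covariances)[, c("a", "b")]
  if (any(covariances$a == covariances$b)) {
    rlang::abort("use the variance slot, not `covariances`, for a == b")
  }
  bad <- setdiff(unique(c(covariances$a, covariances$b)), eta)
  if (length(bad)) {
    rlang::abort(paste0("covariance endpoints must be node variables: ",
                        paste(bad, collapse = ", ")))
  }
  # canonical order so duplicates collapse
  swap <- covariances$a > covariances$b
  tmp <- covariances$a[swap]
  covariances$a[swap] <- covariances$b[swap]
  covariances$b[swap] <- tmp
  dplyr::distinct(covariances)
}

apply_fixes <- function(model, fixed) {
  if (is.null(names(fixed)) || any(!nzchar(names(fixed)))) {
    rlang::abort("`fixed` must be a named numeric vector of parameter labels")
  }
  params <- build_param_table(model)
  for (i in seq_along(fixed)) {
    lab <- names(fixed)[i]
    row <- params[params$label == lab, ]
    if (nrow(row) != 1L) {
      rlang::abort(paste0("cannot fix unknown free parameter: ", lab))
    }
    mat <- row$matrix
    r <- row$row
    c <- row$col
    model[[paste0(mat, "_free")]][r, c] <- FALSE
    model[[paste0(mat, "_value")]][r, c] <- fixed[i]
    if (mat == "psi" && r != c) {
      model$psi_free[c, r] <- FALSE
      model$psi_value[c, r] <- fixed[i]
    }
  }
  model$fixed <- fixed
  model
}

build_param_table <- function(model) {
  out <- list()
  # loadings, per declared latent in order
  for (l in names(model$latents)) {
    ind <- model$latents[[l]]
    free <- ind[model$lambda_free[ind, l]]
    if (length(free)) {
      out[[length(out) + 1L]] <- tibble::tibble(
        label = paste0(l, "=~", free), matrix = "lambda",
        row = free, col = l, class = "loading"
      )
    }
  }
  # structural paths in declaration order
  if (nrow(model$paths)) {
    keep <- model$beta_free[cbind(model$paths$to, model$paths$from)]
    pp <- model$paths[keep, ]
    if (nrow(pp)) {
      out[[length(out) + 1L]] <- tibble::tibble(
        label = paste0(pp$to, "~", pp$from), matrix = "beta",
        row = pp$to, col = pp$from, class = "path"
      )
    }
  }
  # disturbance variances, eta order
  v <- model$eta[diag(model$psi_free)]
  if (length(v)) {
    out[[length(out) + 1L]] <- tibble::tibble(
      label = paste0(v, "~~", v), matrix = "psi", row = v, col = v,
      class = "variance"
    )
  }
  # disturbance covariances
  if (nrow(model$covariances)) {
    keep <- model$psi_free[cbind(model$covariances$a, model$covariances$b)]
    cc <- model$covariances[keep, ]
    if (nrow(cc)) {
      out[[length(out) + 1L]] <- tibble::tibble(
        label = paste0(cc$a, "~~", cc$b), matrix = "psi",
        row = cc$a, col = cc$b, class = "covariance"
      )
    }
  }
  # measurement-error variances, observed order
  e <- model$observed[diag(model$theta_free)]
  if (length(e)) {
    out[[length(out) + 1L]] <- tibble::tibble(
      label = paste0(e, "~~", e), matrix = "theta", row = e, col = e,
      class = "error"
    )
  }
  if (!length(out)) {
    return(tibble::tibble(label = character(), matrix = character(),
                          row = character(), col = character(),
                          class = character()))
  }
  dplyr::bind_rows(out)
}

#' Number of free parameters of a model
#' @param model A [sem_model()].
#' @return Integer count of free parameters.
#' @export
n_free_params <- function(model) {
  stopifnot(inherits(model, "sem_model"))
  nrow(model$params)
}

#' Model degrees of freedom
#'
#' `p(p+1)/2 - q` for `p` observed variables and `q` free parameters.
#' @inheritParams n_free_params
#' @return Integer degrees of freedom (may be negative for over-parameterized
#'   models; fitting rejects those).
#' @export
sem_df <- function(model) {
  p <- length(model$observed)
  as.integer(p * (p + 1) / 2 - n_free_params(model))
}

# Fill the pattern matrices with a parameter vector theta (ordered as
# model$params). Returns list(lambda, beta, psi, theta).
sem_matrices <- function(model, theta) {
  q <- n_free_params(model)
  if (length(theta) != q) {
    rlang::abort(sprintf("theta has length %d, model has %d free parameters",
                         length(theta), q))
  }
  lambda <- model$lambda_value
  beta <- model$beta_value
  psi <- model$psi_value
  thet <- model$theta_value
  pr <- model$params
  for (i in seq_len(q)) {
    v <- theta[i]
    switch(pr$matrix[i],
      lambda = lambda[pr$row[i], pr$col[i]] <- v,
      beta = beta[pr$row[i], pr$col[i]] <- v,
      psi = {
        psi[pr$row[i], pr$col[i]] <- v
        psi[pr$col[i], pr$row[i]] <- v
      },
      theta = thet[pr$row[i], pr$col[i]] <- v
    )
  }
  list(lambda = lambda, beta = beta, psi = psi, theta = thet)
}

# Starting values: 0.5 for free loadings and paths; observed variances for
# variance slots (halved between disturbance and measurement error for
# indicators); 0 for covariances.
sem_start <- function(model, S = NULL) {
  pr <- model$params
  q <- nrow(pr)
  theta <- numeric(q)
  names(theta) <- pr$label
  obs_var <- rep(1, length(model$observed))
  names(obs_var) <- model$observed
  if (!is.null(S)) obs_var[] <- diag(S)[model$observed]
  for (i in seq_len(q)) {
    theta[i] <- switch(pr$class[i],
      loading = 0.5,
      path = 0.5,
      covariance = 0,
      error = obs_var[pr$row[i]] / 2,
      variance = {
        v <- pr$row[i]
        if (v %in% model$pass_through) obs_var[v]
        else mean(obs_var[model$latents[[v]]]) / 2
      }
    )
  }
  theta
}

# TRUE when the structural matrix has no self-loops and no cycles.
model_is_recursive <- function(model) {
  pat <- model$beta_free | model$beta_value != 0
  if (any(diag(pat))) return(FALSE)
  if (!any(pat)) return(TRUE)
  g <- igraph::graph_from_adjacency_matrix(t(pat), mode = "directed")
  igraph::is_dag(g)
}

# Names of nodes involved in structural feedback (self-loops or cycles).
feedback_nodes <- function(model) {
  pat <- model$beta_free | model$beta_value != 0
  loops <- model$eta[diag(pat)]
  g <- igraph::graph_from_adjacency_matrix(t(pat), mode = "directed")
  comp <- igraph::components(g, mode = "strong")
  cyc <- names(comp$membership)[comp$membership %in%
                                  which(comp$csize > 1)]
  unique(c(loops, cyc))
}

#' @export
print.sem_model <- function(x, ...) {
  cat("<sem_model>\n")
  cat("  observed: ", length(x$observed), " (",
      paste(utils::head(x$observed, 8), collapse = ", "),
      if (length(x$observed) > 8) ", ..." else "", ")\n", sep = "")
  if (length(x$latents)) {
    for (l in names(x$latents)) {
      cat("  latent ", l, " =~ ", paste(x$latents[[l]], collapse = " + "),
          "\n", sep = "")
    }
  }
  cat("  structural paths: ", nrow(x$paths),
      "; free parameters: ", n_free_params(x),
      "; df: ", sem_df(x), "\n", sep = "")
  invisible(x)
}
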