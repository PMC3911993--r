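#' Search configuration
#'
#' @param alpha Wald significance level for path pruning (default 0.05).
#' @param collinearity_threshold Absolute Pearson correlation above which two
#'   proteins are treated as expressions of one latent variable
#'   (default 0.9).
#' @param rmsea_max Reporting threshold for RMSEA (default 0.1): the fit is
#'   labelled adequate in the trace when RMSEA stays below it.
#' @param srmr_max Reporting threshold for SRMR (default 0.1).
#' @param max_rounds Cap on prune iterations (default 100).
#' @param batch_prune Remove all non-significant paths at once instead of the
#'   default one-at-a-time backward elimination.
#' @return A `search_config` list.
#' @export
search_config <- function(alpha = 0.05, collinearity_threshold = 0.9,
                          rmsea_max = 0.1, srmr_max = 0.1, max_rounds = 100,
                          batch_prune = FALSE) {
  stopifnot(alpha > 0, alpha < 1,
            collinearity_threshold > 0, collinearity_threshold < 1,
            max_rounds >= 1)
  structure(list(alpha = alpha,
                 collinearity_threshold = collinearity_threshold,
                 rmsea_max = rmsea_max, srmr_max = srmr_max,
                 max_rounds = max_rounds, batch_prune = batch_prune),
            class = "search_config")
}

#' Detect multicollinear protein groups
#'
#' Groups are connected components of the graph on variables with an edge
#' wherever the absolute Pearson correlation exceeds the threshold;
#' singletons are omitted. Such near-identical expression profiles carry one
#' signal and are candidates for collapse into a latent variable.
#'
#' @param data Data frame of samples x variables.
#' @param threshold Absolute-correlation cutoff (default 0.9).
#' @return A list of character vectors (possibly empty).
#' @export
detect_collinear_groups <- function(data, threshold = 0.9) {
  X <- as.matrix(as.data.frame(data))
  if (ncol(X) < 2) rlang::abort("need at least 2 variables")
  R <- stats::cor(X, use = "pairwise.complete.obs")
  A <- abs(R) > threshold
  diag(A) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected")
  comp <- igraph::components(g)
  groups <- split(names(comp$membership), comp$membership)
  groups <- unname(groups[lengths(groups) > 1])
  lapply(groups, sort)
}

# Tolerant Wald table for the pruning loop: a parameter with a zero or
# missing standard error sits on an unidentified ridge (e.g. a self-feedback
# loop), so its significance cannot be established and it is the first
# candidate for removal (p treated as 1).
prune_wald_table <- function(fit, alpha) {
  pr <- fit$model$params
  se <- fit$se
  z <- ifelse(is.na(se) | se <= 0, 0, fit$theta / se)
  p <- ifelse(is.na(se) | se <= 0, 1, 2 * stats::pnorm(-abs(z)))
  tibble::tibble(label = pr$label, class = pr$class,
                 estimate = unname(fit$theta), se = unname(se),
                 z = unname(z), p = unname(p),
                 significant = unname(p < alpha))
}

# derive a readable latent name from its indicators ("RSS174","RSS175" -> "RSS_lat")
latent_group_name <- function(group, taken) {
  prefix <- sub("[0-9]+$", "", group[1])
  for (g in group[-1]) {
    while (nchar(prefix) && !startsWith(sub("[0-9]+$", "", g), prefix)) {
      prefix <- substr(prefix, 1, nchar(prefix) - 1)
    }
  }
  name <- if (nchar(prefix)) paste0(prefix, "_lat") else "lat"
  while (name %in% taken) name <- paste0(name, "1")
  name
}

#' Collapse a group of observed variables into a latent variable
#'
#' The group members become indicators of a new latent (first loading fixed
#' to 1, the rest free, free measurement-error variances). Every structural
#' path touching a member is re-attached to the latent; duplicates created by
#' the merge collapse into one free path.
#'
#' @param model A [sem_model()].
#' @param group Character vector (length >= 2) of observed node variables.
#' @param name Name for the new latent.
#' @return A new [sem_model()].
#' @export
collapse_to_latent <- function(model, group, name) {
  stopifnot(inherits(model, "sem_model"))
  if (length(group) < 2) rlang::abort("a latent needs at least 2 indicators")
  bad <- setdiff(group, setdiff(model$observed, unlist(model$latents)))
  if (length(bad)) {
    rlang::abort(paste0("not observed node variables: ",
                        paste(bad, collapse = ", ")))
  }
  paths <- model$paths
  if (nrow(paths)) {
    self_loop <- paths$from == paths$to
    paths$from[paths$from %in% group] <- name
    paths$to[paths$to %in% group] <- name
    # merged members may create spurious self-paths; keep only original loops
    paths <- paths[paths$from != paths$to | self_loop, ]
    paths <- dplyr::distinct(paths, .data$from, .data$to, .keep_all = TRUE)
  }
  covs <- model$covariances
  if (nrow(covs)) {
    covs$a[covs$a %in% group] <- name
    covs$b[covs$b %in% group] <- name
    covs <- covs[covs$a != covs$b, ]
  }
  latents <- c(model$latents, stats::setNames(list(group), name))
  sem_model(paths = paths, latents = latents, observed = model$observed,
            covariances = if (nrow(covs)) covs else NULL,
            fixed = model$fixed)
}

#' One backward-elimination step
#'
#' Removes the single structural path with the largest Wald p-value at or
#' above `alpha`; refitting after each removal is the caller's job. When an
#' endogenous variable loses its last predictor it simply becomes exogenous
#' (its disturbance variance slot is unchanged); a message notes this.
#'
#' @param model A [sem_model()].
#' @param fit The `sem_fit` of `model` on the current data.
#' @param alpha Significance level.
#' @return A list `(model, removed)` with the pruned model and the removed
#'   path label, or `NULL` (stop signal) when every path is significant.
#' @export
prune_step <- function(model, fit, alpha = 0.05) {
  w <- prune_wald_table(fit, alpha)
  w <- w[w$class == "path", ]
  if (!nrow(w)) return(NULL)
  w <- w[order(-w$p), ]
  if (w$p[1] < alpha) return(NULL)
  label <- w$label[1]
  parts <- strsplit(label, "~", fixed = TRUE)[[1]]
  to <- parts[1]
  from <- parts[2]
  paths <- model$paths
  drop <- paths$to == to & paths$from == from
  paths <- paths[!drop, ]
  if (!any(paths$to == to)) {
    rlang::inform(paste0("pruning left ", to,
                         " without predictors; it is now exogenous"))
  }
  new_model <- sem_model(paths = paths, latents = model$latents,
                         observed = model$observed,
                         covariances = if (nrow(model$covariances))
                           model$covariances else NULL,
                         fixed = model$fixed)
  list(model = new_model, removed = label)
}

#' Iterative model refinement: collapse collinear groups, then prune
#'
#' Reproduces the refinement loop of the analysis: multicollinear groups are
#' detected once and collapsed into latent variables, then the model is fit
#' and the least-significant structural path is removed, refitting after each
#' removal, until every remaining path is significant (or `max_rounds` is
#' hit). The loop contains no randomness: the same data and skeleton always
#' yield the same trace.
#'
#' @param data Data frame of samples x variables covering the skeleton's
#'   observed variables.
#' @param skeleton A [sem_model()], typically from [to_sem_skeleton()].
#' @param config A [search_config()].
#' @return A `sem_search` object: list with `fit` (final [sem_fit()]),
#'   `model`, `trace` (tibble of steps with fit indices), and
#'   `collinear_groups`.
#' @export
sem_search <- function(data, skeleton, config = search_config()) {
  stopifnot(inherits(skeleton, "sem_model"), inherits(config, "search_config"))
  df <- as.data.frame(data)
  missing <- setdiff(skeleton$observed, colnames(df))
  if (length(missing)) {
    rlang::abort(paste0("data lack model variables: ",
                        paste(missing, collapse = ", ")))
  }
  df <- df[, skeleton$observed, drop = FALSE]
  # the loop needs Wald p-values, not 1e-12 precision: lighter optimizer
  fit_control <- list(reltol = 1e-10, polish = FALSE)

  trace <- list()
  step_row <- function(action, what, fit) {
    ind <- fit$indices
    tibble::tibble(
      step = length(trace) + 1L, action = action, what = what,
      n_params = n_free_params(fit$model), df = fit$df,
      chi_square = fit$chi_square,
      rmsea = if (is.null(ind)) NA_real_ else ind$rmsea,
      srmr = if (is.null(ind)) NA_real_ else ind$srmr,
      converged = fit$converged
    )
  }

  model <- skeleton
  groups <- detect_collinear_groups(df, config$collinearity_threshold)
  node_obs <- setdiff(model$observed, unlist(model$latents))
  for (g in groups) {
    g <- intersect(g, node_obs)
    if (length(g) < 2) next
    nm <- latent_group_name(g, c(model$observed, names(model$latents)))
    model <- collapse_to_latent(model, g, nm)
    fit <- sem_fit(df, model, control = fit_control)
    trace[[length(trace) + 1L]] <-
      step_row("collapse", paste0(nm, " := ", paste(g, collapse = " + ")), fit)
  }

  fit <- sem_fit(df, model, control = fit_control)
  for (round in seq_len(config$max_rounds)) {
    if (config$batch_prune) {
      w <- prune_wald_table(fit, config$alpha)
      w <- w[w$class == "path" & !w$significant, ]
      if (!nrow(w)) break
      for (lab in w$label) {
        parts <- strsplit(lab, "~", fixed = TRUE)[[1]]
        model$paths <- model$paths[!(model$paths$to == parts[1] &
                                       model$paths$from == parts[2]), ]
      }
      model <- sem_model(paths = model$paths, latents = model$latents,
                         observed = model$observed,
                         covariances = if (nrow(model$covariances))
                           model$covariances else NULL,
                         fixed = model$fixed)
      fit <- sem_fit(df, model, control = fit_control)
      trace[[length(trace) + 1L]] <-
        step_row("prune", paste(w$label, collapse = ", "), fit)
    } else {
      step <- prune_step(model, fit, config$alpha)
      if (is.null(step)) break
      model <- step$model
      fit <- sem_fit(df, model, control = fit_control)
      trace[[length(trace) + 1L]] <- step_row("prune", step$removed, fit)
    }
  }
  trace[[length(trace) + 1L]] <- step_row("stop", "all paths significant", fit)

  structure(
    list(fit = fit, model = model,
         trace = dplyr::bind_rows(trace),
         collinear_groups = groups, config = config),
    class = "sem_search"
  )
}

#' @export
print.sem_search <- function(x, ...) {
  cat("<sem_search> ", nrow(x$trace), " steps; ",
      length(x$collinear_groups), " collinear group(s) collapsed\n", sep = "")
  print(x$fit)
  invisible(x)
}
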