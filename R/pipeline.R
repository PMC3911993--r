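#' Build and export the prior pathway graph from CSV inputs
#'
#' Reads protein metadata (and optional regulation annotations), builds the
#' prior degradation-pathway graph, and writes it as GraphML, DOT and a JSON
#' edge list into `out_dir`.
#'
#' @param metadata_csv Path to the protein metadata CSV (see
#'   [read_protein_metadata()]).
#' @param regulation_csv Optional path to a CSV with columns `source`,
#'   `target` and optionally `evidence`.
#' @param out_dir Output directory (created if needed).
#' @return The `pathway_graph`, invisibly.
#' @export
run_prior_graph <- function(metadata_csv, regulation_csv = NULL,
                            out_dir = ".") {
  records <- read_protein_metadata(metadata_csv)
  regulation <- if (!is.null(regulation_csv)) {
    readr::read_csv(regulation_csv, show_col_types = FALSE)
  }
  graph <- build_prior_graph(records, regulation)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_pathway_graph(
    graph,
    graphml = file.path(out_dir, "prior_graph.graphml"),
    dot = file.path(out_dir, "prior_graph.dot"),
    json = file.path(out_dir, "prior_graph.json")
  )
  rlang::inform(sprintf(
    "prior graph: %d proteins, %d degradation edges, %d regulation edges",
    nrow(graph$nodes), sum(graph$edges$kind == "degradation"),
    sum(graph$edges$kind == "regulation")))
  invisible(graph)
}

#' Run the full pathway-modelling pipeline
#'
#' Executes model search (collinearity collapse + pruning), reports the
#' maximum-likelihood fit, re-estimates the selected model with the Gibbs
#' sampler and writes the convergence report -- one self-contained output
#' directory per run. Every artefact embeds the seed and configuration, and
#' a fixed seed yields identical JSON reports.
#'
#' @param data Data frame of samples x proteins, or a CSV path.
#' @param model The starting model: a [sem_model()], a `pathway_graph`
#'   (converted with [to_sem_skeleton()]), or a path to a model-grammar text
#'   file.
#' @param out_dir Output directory (created if needed).
#' @param seed Integer seed used for the Bayesian stage.
#' @param search A [search_config()].
#' @param n_chains,n_iter,burn_in Passed to [sem_bayes()].
#' @param skip_bayes If `TRUE`, stop after the ML report.
#' @param plots Write SVG diagnostics plots (default `TRUE`; failures to open
#'   a graphics device are downgraded to a warning).
#' @return A list with `search`, `fit`, `chains` (or `NULL`), `convergence`
#'   (or `NULL`), invisibly.
#' @export
run_pipeline <- function(data, model, out_dir, seed = 1,
                         search = search_config(), n_chains = 4,
                         n_iter = 20000, burn_in = n_iter %/% 2,
                         skip_bayes = FALSE, plots = TRUE) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      rlang::abort(paste0("pipeline stage '", name, "' failed: ",
                          conditionMessage(e)), parent = e)
    })
  }
  df <- stage("read-data", {
    if (is.character(data)) {
      as.data.frame(readr::read_csv(data, show_col_types = FALSE))
    } else {
      as.data.frame(data)
    }
  })
  skeleton <- stage("read-model", {
    if (inherits(model, "sem_model")) model
    else if (inherits(model, "pathway_graph")) to_sem_skeleton(model)
    else parse_sem_model(model)
  })
  missing <- setdiff(skeleton$observed, colnames(df))
  if (length(missing)) {
    rlang::abort(paste0("data lack model variables: ",
                        paste(missing, collapse = ", ")))
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- list(seed = seed, n_chains = n_chains, n_iter = n_iter,
              burn_in = burn_in, skip_bayes = skip_bayes,
              search = unclass(search), n_samples = nrow(df))
  jsonlite::write_json(cfg, file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  res <- stage("search", sem_search(df, skeleton, search))
  jsonlite::write_json(res$trace, file.path(out_dir, "search_trace.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  writeLines(sem_syntax(res$model), file.path(out_dir, "model_final.txt"))

  fit <- res$fit
  stage("ml-report", {
    report <- list(
      seed = seed,
      parameters = tidy(fit),
      fit = glance(fit),
      warnings = fit$warnings
    )
    jsonlite::write_json(report, file.path(out_dir, "fit_ml.json"),
                         dataframe = "rows", auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  })

  chains <- convergence <- NULL
  if (!skip_bayes) {
    chains <- stage("bayes", sem_bayes(df, res$model, n_chains = n_chains,
                                       n_iter = n_iter, burn_in = burn_in,
                                       seed = seed))
    convergence <- stage("bayes-output", {
      for (k in seq_along(chains$draws)) {
        d <- tibble::as_tibble(chains$draws[[k]])
        d <- dplyr::mutate(d, iteration = dplyr::row_number(),
                           .before = 1)
        readr::write_csv(d, file.path(out_dir, sprintf("chain_%d.csv", k)))
      }
      convergence <- gelman_rubin(chains)
      jsonlite::write_json(
        list(seed = seed, mpsrf = convergence$mpsrf,
             n_used = convergence$n_used, n_chains = convergence$n_chains,
             psrf = convergence$psrf,
             posterior = posterior_summary(chains)),
        file.path(out_dir, "convergence.json"),
        dataframe = "rows", auto_unbox = TRUE, digits = NA, pretty = TRUE)
      convergence
    })
  }
  if (plots) {
    try_plot <- function(file, plot) {
      tryCatch(
        suppressMessages(ggplot2::ggsave(file.path(out_dir, file), plot,
                                         width = 8, height = 6)),
        error = function(e) rlang::warn(paste0("could not write ", file, ": ",
                                               conditionMessage(e))))
    }
    try_plot("fit_coefficients.svg", autoplot(fit))
    if (!is.null(chains)) {
      try_plot("trace.svg", autoplot(chains))
      try_plot("psrf_evolution.svg", plot_psrf_evolution(chains))
    }
  }
  invisible(list(search = res, fit = fit, chains = chains,
                 convergence = convergence))
}
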