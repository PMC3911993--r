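#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL

#' Tidy a maximum-likelihood SEM fit
#'
#' @param x A `sem_fit` object.
#' @param ... Unused.
#' @return One row per free parameter: `term`, `class`, `estimate`,
#'   `std.error`, `statistic`, `p.value`, `std.estimate`, `conf.low`,
#'   `conf.high` (95% Wald).
#' @export
tidy.sem_fit <- function(x, ...) {
  crit <- stats::qnorm(0.975)
  tibble::tibble(
    term = x$model$params$label,
    class = x$model$params$class,
    estimate = unname(x$theta),
    std.error = unname(x$se),
    statistic = unname(x$z),
    p.value = unname(x$p),
    std.estimate = if (is.null(x$standardized)) NA_real_ else
      x$standardized$std_estimate,
    conf.low = unname(x$theta - crit * x$se),
    conf.high = unname(x$theta + crit * x$se)
  )
}

#' One-row fit summary
#'
#' @param x A `sem_fit` object.
#' @param ... Unused.
#' @return A tibble with the discrepancy, chi-square test, RMSEA (with CI and
#'   close-fit p), SRMR, convergence flag and iteration count.
#' @export
glance.sem_fit <- function(x, ...) {
  ind <- x$indices
  tibble::tibble(
    n = x$n,
    n_params = n_free_params(x$model),
    df = x$df,
    discrepancy = x$F_min,
    chi_square = x$chi_square,
    p_chi = if (is.null(ind)) NA_real_ else ind$p_chi,
    rmsea = if (is.null(ind)) NA_real_ else ind$rmsea,
    rmsea_ci_low = if (is.null(ind)) NA_real_ else ind$rmsea_ci_low,
    rmsea_ci_high = if (is.null(ind)) NA_real_ else ind$rmsea_ci_high,
    rmsea_pclose = if (is.null(ind)) NA_real_ else ind$rmsea_pclose,
    srmr = if (is.null(ind)) NA_real_ else ind$srmr,
    converged = x$converged,
    n_iter = x$n_iter
  )
}

#' Tidy posterior draws
#'
#' @param x A `sem_chains` object.
#' @param ... Passed to [posterior_summary()].
#' @return Posterior summaries, one row per parameter.
#' @export
tidy.sem_chains <- function(x, ...) {
  out <- posterior_summary(x, ...)
  dplyr::rename(out, term = "label")
}

#' Tidy a convergence report
#'
#' @param x A `convergence_report` object.
#' @param ... Unused.
#' @return Tibble with `term` and `psrf`; the multivariate psrf is carried in
#'   the `mpsrf` attribute and by [glance.convergence_report()].
#' @export
tidy.convergence_report <- function(x, ...) {
  out <- dplyr::rename(x$psrf, term = "label")
  attr(out, "mpsrf") <- x$mpsrf
  out
}

#' @rdname tidy.convergence_report
#' @export
glance.convergence_report <- function(x, ...) {
  tibble::tibble(mpsrf = x$mpsrf, max_psrf = max(x$psrf$psrf),
                 n_used = x$n_used, n_chains = x$n_chains)
}

#' Tidy a model-search trace
#'
#' @param x A `sem_search` object.
#' @param ... Unused.
#' @return The step-by-step trace tibble.
#' @export
tidy.sem_search <- function(x, ...) x$trace

#' @rdname tidy.sem_search
#' @export
glance.sem_search <- function(x, ...) glance(x$fit)
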