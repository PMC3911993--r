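#' Parse a plain-text model description
#'
#' The grammar has one statement per line (blank lines and `#` comments are
#' ignored):
#' \describe{
#'   \item{`target <- source1 + source2`}{structural paths into `target`}
#'   \item{`latent := indicator1 + indicator2`}{measurement model}
#'   \item{`cov(a, b)`}{free disturbance covariance between nodes}
#'   \item{`fix(label, value)`}{fix a parameter, e.g. `fix(dp7~dp39, 0.5)`}
#' }
#'
#' @param text A single string (possibly multi-line) or character vector of
#'   lines, or a file path to a model file.
#' @return A [sem_model()].
#' @seealso [sem_syntax()] for the inverse.
#' @export
parse_sem_model <- function(text) {
  if (length(text) == 1 && !grepl("\n", text) && file.exists(text)) {
    text <- readLines(text, warn = FALSE)
  }
  lines <- unlist(strsplit(text, "\n", fixed = TRUE))
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]

  paths <- list()
  latents <- list()
  covs <- list()
  fixes <- numeric()

  for (ln in lines) {
    if (grepl(":=", ln, fixed = TRUE)) {
      parts <- strsplit(ln, ":=", fixed = TRUE)[[1]]
      if (length(parts) != 2) rlang::abort(paste0("cannot parse line: ", ln))
      lat <- trimws(parts[1])
      ind <- trimws(strsplit(parts[2], "+", fixed = TRUE)[[1]])
      latents[[lat]] <- ind
    } else if (grepl("<-", ln, fixed = TRUE)) {
      parts <- strsplit(ln, "<-", fixed = TRUE)[[1]]
      if (length(parts) != 2) rlang::abort(paste0("cannot parse line: ", ln))
      to <- trimws(parts[1])
      from <- trimws(strsplit(parts[2], "+", fixed = TRUE)[[1]])
      paths[[length(paths) + 1L]] <- tibble::tibble(from = from, to = to)
    } else if (grepl("^cov\\(", ln)) {
      args <- parse_call_args(ln, "cov")
      if (length(args) != 2) rlang::abort(paste0("cov() needs 2 arguments: ", ln))
      covs[[length(covs) + 1L]] <- tibble::tibble(a = args[1], b = args[2])
    } else if (grepl("^fix\\(", ln)) {
      args <- parse_call_args(ln, "fix")
      if (length(args) != 2) rlang::abort(paste0("fix() needs 2 arguments: ", ln))
      val <- suppressWarnings(as.numeric(args[2]))
      if (is.na(val)) rlang::abort(paste0("fix() value is not numeric: ", ln))
      fixes[args[1]] <- val
    } else {
      rlang::abort(paste0("cannot parse model line: ", ln))
    }
  }

  sem_model(
    paths = if (length(paths)) dplyr::bind_rows(paths) else NULL,
    latents = latents,
    covariances = if (length(covs)) dplyr::bind_rows(covs) else NULL,
    fixed = if (length(fixes)) fixes else NULL
  )
}

parse_call_args <- function(ln, fn) {
  inner <- sub(paste0("^", fn, "\\((.*)\\)\\s*$"), "\\1", ln)
  trimws(strsplit(inner, ",", fixed = TRUE)[[1]])
}

#' Serialize a model to the plain-text grammar
#'
#' @param model A [sem_model()].
#' @return A single string that [parse_sem_model()] parses back to an
#'   equivalent model.
#' @export
sem_syntax <- function(model) {
  stopifnot(inherits(model, "sem_model"))
  out <- character()
  for (l in names(model$latents)) {
    out <- c(out, paste0(l, " := ", paste(model$latents[[l]], collapse = " + ")))
  }
  if (nrow(model$paths)) {
    for (to in unique(model$paths$to)) {
      from <- model$paths$from[model$paths$to == to]
      out <- c(out, paste0(to, " <- ", paste(from, collapse = " + ")))
    }
    fx <- model$paths[!is.na(model$paths$value), ]
    if (nrow(fx)) {
      out <- c(out, sprintf("fix(%s~%s, %.17g)", fx$to, fx$from, fx$value))
    }
  }
  if (nrow(model$covariances)) {
    out <- c(out, sprintf("cov(%s, %s)", model$covariances$a,
                          model$covariances$b))
  }
  if (!is.null(model$fixed)) {
    out <- c(out, sprintf("fix(%s, %.17g)", names(model$fixed), model$fixed))
  }
  paste(out, collapse = "\n")
}
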