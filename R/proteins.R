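#' Build a table of identified protein spots
#'
#' One row per 2DE/MS spot. Sequence evidence takes one of two forms, both
#' reducing to set containment: a set of matched peptide strings, or a set of
#' half-open residue intervals `[start, end)` in 0-based coordinates on a
#' named reference subunit.
#'
#' @param id Character spot labels (e.g. `"RLS2"`, `"dp39"`), unique.
#' @param tier `"intact"` or `"fragment"` per spot.
#' @param mass_kda Positive protein masses in kilodaltons.
#' @param reference_subunit Name of the parent sequence the spot's evidence
#'   is placed on (`NA` allowed for peptide evidence). Intact spots reference
#'   themselves.
#' @param evidence List column: per spot either a character vector of
#'   peptides or a two-column numeric matrix of `[start, end)` intervals.
#' @return A `protein_records` tibble.
#' @export
protein_records <- function(id, tier, mass_kda, reference_subunit = NA,
                            evidence = list()) {
  out <- tibble::tibble(
    id = as.character(id),
    tier = as.character(tier),
    mass_kda = as.numeric(mass_kda),
    reference_subunit = as.character(reference_subunit),
    evidence = evidence
  )
  validate_protein_records(out)
  class(out) <- c("protein_records", class(out))
  out
}

validate_protein_records <- function(x) {
  if (anyDuplicated(x$id)) rlang::abort("protein ids must be unique")
  if (!all(x$tier %in% c("intact", "fragment"))) {
    rlang::abort('tier must be "intact" or "fragment"')
  }
  if (any(!is.finite(x$mass_kda) | x$mass_kda <= 0)) {
    rlang::abort("mass_kda must be positive")
  }
  intact <- x$tier == "intact"
  ref_ok <- is.na(x$reference_subunit[intact]) |
    x$reference_subunit[intact] == x$id[intact]
  if (!all(ref_ok)) {
    rlang::abort("intact records must reference their own sequence")
  }
  for (i in seq_len(nrow(x))) {
    ev <- x$evidence[[i]]
    if (is.numeric(ev)) {
      ev <- matrix(ev, ncol = 2)
      if (any(ev[, 1] >= ev[, 2])) {
        rlang::abort(paste0("intervals need start < end (record ", x$id[i], ")"))
      }
      if (any(ev < 0)) {
        rlang::abort(paste0("negative residue coordinates (record ", x$id[i], ")"))
      }
    } else if (!is.character(ev)) {
      rlang::abort(paste0("evidence must be peptides or intervals (record ",
                          x$id[i], ")"))
    }
  }
  invisible(x)
}

evidence_kind <- function(ev) {
  if (is.numeric(ev)) "interval" else "peptide"
}

# merge intervals into a disjoint sorted union
merge_intervals <- function(iv) {
  iv <- matrix(iv, ncol = 2)
  if (nrow(iv) == 0) return(iv)
  iv <- iv[order(iv[, 1], iv[, 2]), , drop = FALSE]
  out <- iv[1, , drop = FALSE]
  for (i in seq_len(nrow(iv))[-1]) {
    k <- nrow(out)
    if (iv[i, 1] <= out[k, 2]) {
      out[k, 2] <- max(out[k, 2], iv[i, 2])
    } else {
      out <- rbind(out, iv[i, ])
    }
  }
  out
}

# is every interval of `inner` covered by the union of `outer`?
intervals_covered <- function(inner, outer) {
  inner <- matrix(inner, ncol = 2)
  if (nrow(inner) == 0) return(FALSE) # empty evidence demonstrates nothing
  u <- merge_intervals(outer)
  if (nrow(u) == 0) return(FALSE)
  for (i in seq_len(nrow(inner))) {
    hit <- which(u[, 1] <= inner[i, 1] & inner[i, 2] <= u[, 2])
    if (!length(hit)) return(FALSE)
  }
  TRUE
}

#' Is a fragment's sequence evidence contained in a parent's?
#'
#' Containment is what links a degradation product to the protein it came
#' from. For interval evidence both records must sit on the same named
#' reference subunit and the fragment's intervals must be covered by the
#' union of the parent's intervals; with different references the answer is
#' `FALSE`. For peptide evidence the fragment's peptide set must be a
#' non-empty subset of the parent's (peptide identity itself carries the
#' sequence evidence, so no shared reference is required -- this is how a
#' fragment can be a product of two near-identical subunits). Comparing a
#' peptide-evidence record against an interval-evidence record is an error
#' of class `pathsem_incomparable_evidence`, not `FALSE`.
#'
#' @param fragment,parent Single rows of a [protein_records()] table.
#' @return `TRUE` or `FALSE`.
#' @export
sequence_contained <- function(fragment, parent) {
  ev_f <- fragment$evidence[[1]]
  ev_p <- parent$evidence[[1]]
  kf <- evidence_kind(ev_f)
  kp <- evidence_kind(ev_p)
  if (kf != kp) {
    rlang::abort(
      paste0("cannot compare ", kf, " evidence (", fragment$id,
             ") with ", kp, " evidence (", parent$id, ")"),
      class = "pathsem_incomparable_evidence"
    )
  }
  if (kf == "peptide") {
    return(length(ev_f) > 0 && all(ev_f %in% ev_p))
  }
  rf <- fragment$reference_subunit
  rp <- parent$reference_subunit
  if (is.na(rf) || is.na(rp) || rf != rp) return(FALSE)
  intervals_covered(ev_f, ev_p)
}

#' Read protein metadata from CSV
#'
#' Expected columns: `id`, `tier`, `mass_kda`, `reference_subunit`,
#' `evidence`. The evidence field is semicolon-separated: either `start-end`
#' residue intervals (0-based, half-open) or peptide strings.
#'
#' @param path CSV file path.
#' @return A [protein_records()] tibble.
#' @export
read_protein_metadata <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  need <- c("id", "tier", "mass_kda", "reference_subunit", "evidence")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    rlang::abort(paste0("metadata CSV lacks column(s): ",
                        paste(missing, collapse = ", ")))
  }
  if (!nrow(df)) rlang::abort("metadata CSV has no records")
  ev <- lapply(seq_len(nrow(df)), function(i) {
    parts <- trimws(strsplit(df$evidence[i], ";", fixed = TRUE)[[1]])
    parts <- parts[nzchar(parts)]
    is_iv <- grepl("^[0-9]+-[0-9]+$", parts)
    if (all(is_iv) && length(parts)) {
      se <- do.call(rbind, strsplit(parts, "-", fixed = TRUE))
      matrix(as.numeric(se), ncol = 2)
    } else if (any(is_iv)) {
      rlang::abort(paste0("record ", df$id[i], " (line ", i + 1,
                          "): mixed interval and peptide evidence"))
    } else {
      parts
    }
  })
  protein_records(df$id, df$tier, df$mass_kda, df$reference_subunit, ev)
}
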