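#' Synthetic fragment-evidence fixture
#'
#' Ten protein records whose masses and planted sequence evidence make
#' [build_prior_graph()] reproduce the hypothesized Rubisco degradation
#' pathway exactly: RLS2 -> {dp39, dp12, dp37}, dp39 -> {dp7, dp15, dp17},
#' and {RSS174, RSS175} -> dp44. The RLS2 family carries residue-interval
#' evidence on the Large Subunit sequence; the Small Subunit spots and dp44
#' carry peptide evidence, with dp44's peptides matched by both RSS spots so
#' it links to either ("and/or"). The exact residue coordinates are
#' synthetic -- planted to encode the published containment statements, not
#' taken from any spectral data.
#'
#' @param seed Integer; perturbs the spot masses within edge-preserving
#'   bounds so repeated draws are not byte-identical while the resulting
#'   graph is invariant.
#' @return A [protein_records()] table.
#' @export
fragment_fixture <- function(seed = 1) {
  set.seed(seed)
  # interval evidence on the Large Subunit (0-based, half-open, length 475):
  # children of dp39 straddle [60, 95) and 105+ so none is contained in
  # dp37 ([95, 440)) or dp12 ([0, 105)), and their staircase layout
  # (increasing starts and ends) rules out containment among them
  iv <- list(
    RLS2 = c(0, 475),
    dp39 = c(60, 390),
    dp37 = c(95, 440),
    dp12 = c(0, 105),
    dp7  = c(61, 130),
    dp15 = c(70, 230),
    dp17 = c(80, 340)
  )
  peptides <- list(
    RSS174 = c("MQVWPPIGKK", "YETLSYLPDL", "SQGFVYRENH", "KSPGYYDGRY",
               "WTMWKLPMFG"),
    RSS175 = c("MQVWPPIGKK", "YETLSYLPDL", "SQGFVYRENH", "KSPGYYDGRY",
               "WTMWKLPLFG"),
    dp44   = c("YETLSYLPDL", "SQGFVYRENH")
  )
  base_mass <- c(RLS2 = 52.7, RSS174 = 15.2, RSS175 = 15.1,
                 dp39 = 39.0, dp12 = 12.0, dp37 = 37.0, dp44 = 9.6,
                 dp7 = 7.0, dp15 = 15.0, dp17 = 17.0)
  ids <- names(base_mass)
  mass <- base_mass + stats::runif(length(ids), -0.04, 0.04)
  tier <- ifelse(ids %in% c("RLS2", "RSS174", "RSS175"), "intact", "fragment")
  ref <- ifelse(ids %in% names(iv), "RLS2", NA_character_)
  ref[ids == "RSS174"] <- "RSS174"
  ref[ids == "RSS175"] <- "RSS175"
  evidence <- lapply(ids, function(id) {
    if (id %in% names(iv)) matrix(iv[[id]], ncol = 2) else peptides[[id]]
  })
  protein_records(ids, tier, mass, ref, evidence)
}

#' Literature-derived regulation edges for the Rubisco fixture
#'
#' Large Subunit synthesis is under self-feedback control and is up-regulated
#' by the Small Subunit; these links are imported annotations, not inferred
#' from sequence evidence.
#'
#' @return A tibble with columns `source`, `target`, `evidence` suitable for
#'   the `regulation` argument of [build_prior_graph()].
#' @export
rubisco_regulation <- function() {
  tibble::tibble(
    source = c("RSS174", "RSS175", "RLS2"),
    target = c("RLS2", "RLS2", "RLS2"),
    evidence = c("RSS up-regulation of RLS synthesis",
                 "RSS up-regulation of RLS synthesis",
                 "RLS self-feedback when in excess")
  )
}
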