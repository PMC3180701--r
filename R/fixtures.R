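#' Packaged anthocyanin cut-set table
#'
#' The published 22-row minimal-cut-set membership table over the twelve
#' anthocyanin-pathway reactions, shipped as a plain-text fixture:
#' `table3_matrix()` returns the raw table, `table3_cutsets()` converts it
#' to a `"cutset_list"` (carrying the published unaffected-mode counts and
#' gene labels) ready for [fragility()].
#'
#' @return `table3_matrix()`: data frame with one row per cut set, the 12
#'   binary membership columns, `total_rxns`, `unaffected` and `genes`.
#'   `table3_cutsets()`: a `"cutset_list"`.
#' @export
table3_matrix <- function() {
  utils::read.delim(pkg_extdata("table3_mcs.tsv"), check.names = FALSE,
                    stringsAsFactors = FALSE)
}

#' @rdname table3_matrix
#' @export
table3_cutsets <- function() {
  d <- table3_matrix()
  M <- as.matrix(d[, abp_candidate_reactions()])
  cutsets_from_matrix(M, unaffected = d$unaffected, genes = d$genes)
}

#' Packaged preliminary-constraint table
#'
#' The measured-concentration constraint values used to pin down the
#' reference flux state: fixed product rates in mmol/(kg h) (converted from
#' mg/kg by molar mass), the lignin growth contribution, and literature
#' ranges for other products. Range rows are keyed by compound name because
#' the published table prints no reaction id for them.
#'
#' @param as_flux_constraints Return a [flux_constraints()] table (dropping
#'   the concentration column) instead of the raw data frame.
#' @return Data frame or `flux_constraints` table.
#' @export
table1_constraints <- function(as_flux_constraints = FALSE) {
  d <- utils::read.delim(pkg_extdata("table1_constraints.tsv"),
                         stringsAsFactors = FALSE)
  if (!as_flux_constraints) return(d)
  flux_constraints(d$reaction_id, d$min, d$max, d$provenance)
}

#' Packaged fixed input fluxes
#'
#' The input fluxes of the reference state that are held constant across
#' all knockout simulations, in mmol/(kg h).
#'
#' @return Named numeric vector (reaction id -> rate).
#' @export
table2_influxes <- function() {
  d <- utils::read.delim(pkg_extdata("table2_influx.tsv"),
                         stringsAsFactors = FALSE)
  stats::setNames(d$rate, d$reaction_id)
}

#' Packaged product-class list
#'
#' The seven flavonoid subclasses, four non-flavonoid groups and the
#' `"others"` catch-all, with the external product compounds known to
#' belong to each (`NA` where the publication names the class but not its
#' member ids).
#'
#' @return Data frame with columns `class`, `kind`, `compound`.
#' @export
flavonoid_classes <- function() {
  utils::read.delim(pkg_extdata("product_classes.tsv"),
                    stringsAsFactors = FALSE)
}

pkg_extdata <- function(file) {
  path <- system.file("extdata", file, package = "fluxcut")
  if (!nzchar(path)) stop("packaged fixture not found: ", file)
  path
}
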