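#' Construct a reaction
#'
#' A reaction converts substrates into products with fixed stoichiometry.
#' Negative coefficients denote consumption, positive ones production.
#'
#' @param id Character scalar, unique reaction identifier.
#' @param stoich Named numeric vector of nonzero stoichiometric coefficients;
#'   names are compound ids.
#' @param reversible Logical; can the reaction run in both directions?
#' @param gene Optional free-text enzyme/gene annotation (e.g. `"DFR(cy)"`).
#' @param lb,ub Optional rate bounds in mmol/(kg h).
#' @param default Optional default rate; `NA` means unknown.
#' @return An object of class `"fc_reaction"`.
#' @examples
#' reaction("R1", c(A = -1, B = 1))
#' @export
reaction <- function(id, stoich, reversible = FALSE, gene = NA_character_,
                     lb = NA_real_, ub = NA_real_, default = NA_real_) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  stoich <- unlist(stoich)
  if (length(stoich) == 0L || is.null(names(stoich)) || any(!nzchar(names(stoich))))
    stop("reaction '", id, "': stoichiometry must be a named numeric vector")
  if (anyDuplicated(names(stoich)))
    stop("reaction '", id, "': duplicated compound in stoichiometry")
  if (any(stoich == 0) || any(!is.finite(stoich)))
    stop("reaction '", id, "': all stoichiometric coefficients must be nonzero and finite")
  if (!is.na(lb) && !is.na(ub) && lb > ub)
    stop("reaction '", id, "': lower bound exceeds upper bound")
  structure(
    list(id = id, stoich = stoich, reversible = isTRUE(reversible),
         gene = as.character(gene), lb = as.numeric(lb), ub = as.numeric(ub),
         default = as.numeric(default)),
    class = "fc_reaction")
}

#' @export
print.fc_reaction <- function(x, ...) {
  cat(format_reaction_equation(x), "\n")
  invisible(x)
}

format_reaction_equation <- function(r) {
  side <- function(coefs) {
    if (length(coefs) == 0L) return("")
    paste(ifelse(abs(coefs) == 1, names(coefs),
                 paste(format(abs(coefs), trim = TRUE), names(coefs))),
          collapse = " + ")
  }
  lhs <- side(r$stoich[r$stoich < 0])
  rhs <- side(r$stoich[r$stoich > 0])
  arrow <- if (r$reversible) "=" else "-->"
  sprintf("%s : %s %s %s", r$id, lhs, arrow, rhs)
}

#' Construct a metabolic network
#'
#' A metabolic network is a hypergraph whose nodes are compounds and whose
#' hyperedges are stoichiometric reactions. Internal compounds are subject to
#' steady-state mass balance; external (boundary/buffered) compounds are not.
#'
#' @param reactions List of [reaction()] objects.
#' @param compounds Data frame with columns `id`, `name`, `role`
#'   (`"internal"` or `"external"`). If `NULL`, compounds are inferred from
#'   the reactions and classified by [preliminary_classification()].
#' @param name Optional network name.
#' @return An object of class `"metabolic_network"` with components
#'   `name`, `compounds` (data frame) and `reactions` (named list).
#' @examples
#' net <- metabolic_network(list(
#'   reaction("r1", c(A = -1, B = 1)),
#'   reaction("r2", c(B = -1, C = 1))))
#' net
#' @export
metabolic_network <- function(reactions, compounds = NULL, name = "") {
  if (inherits(reactions, "fc_reaction")) reactions <- list(reactions)
  stopifnot(is.list(reactions))
  for (r in reactions)
    if (!inherits(r, "fc_reaction")) stop("all reactions must be built with reaction()")
  ids <- vapply(reactions, `[[`, character(1), "id")
  if (anyDuplicated(ids)) stop("duplicated reaction ids: ",
                               paste(unique(ids[duplicated(ids)]), collapse = ", "))
  names(reactions) <- ids
  mentioned <- unique(unlist(lapply(reactions, function(r) names(r$stoich))))
  if (is.null(compounds)) {
    compounds <- data.frame(id = mentioned, name = mentioned,
                            role = NA_character_, stringsAsFactors = FALSE)
  } else {
    compounds <- as.data.frame(compounds, stringsAsFactors = FALSE)
    if (!"id" %in% names(compounds)) stop("compounds must have an 'id' column")
    if (!"name" %in% names(compounds)) compounds$name <- compounds$id
    if (!"role" %in% names(compounds)) compounds$role <- NA_character_
    compounds <- compounds[, c("id", "name", "role")]
    if (anyDuplicated(compounds$id))
      stop("duplicated compound ids: ",
           paste(unique(compounds$id[duplicated(compounds$id)]), collapse = ", "))
    missing <- setdiff(mentioned, compounds$id)
    if (length(missing))
      stop("reactions reference undeclared compounds: ",
           paste(missing, collapse = ", "))
  }
  rownames(compounds) <- NULL
  net <- structure(list(name = name, compounds = compounds, reactions = reactions),
                   class = "metabolic_network")
  if (anyNA(net$compounds$role)) {
    cls <- preliminary_classification(net)
    na <- is.na(net$compounds$role)
    net$compounds$role[na] <- cls[net$compounds$id[na]]
  }
  bad <- !net$compounds$role %in% c("internal", "external")
  if (any(bad))
    stop("compound roles must be 'internal' or 'external': ",
         paste(net$compounds$id[bad], collapse = ", "))
  net
}

#' @export
print.metabolic_network <- function(x, ...) {
  cat(sprintf("Metabolic network%s: %d compounds (%d internal), %d reactions\n",
              if (nzchar(x$name)) paste0(" '", x$name, "'") else "",
              nrow(x$compounds), sum(x$compounds$role == "internal"),
              length(x$reactions)))
  invisible(x)
}

#' @rdname metabolic_network
#' @param net A `metabolic_network`.
#' @export
reaction_ids <- function(net) names(net$reactions)

#' @rdname metabolic_network
#' @export
compound_ids <- function(net) net$compounds$id

#' @rdname metabolic_network
#' @export
internal_compounds <- function(net) net$compounds$id[net$compounds$role == "internal"]

#' @rdname metabolic_network
#' @export
external_compounds <- function(net) net$compounds$id[net$compounds$role == "external"]

#' Stoichiometric matrix
#'
#' One row per compound, one column per reaction; entry is the signed
#' stoichiometric coefficient of the compound in the reaction.
#'
#' @param net A `metabolic_network`.
#' @param internal_only If `TRUE` (default) only internal (mass-balanced)
#'   compounds are included, which is the matrix whose null space defines
#'   steady-state flux distributions.
#' @return Numeric matrix with compound ids as row names and reaction ids as
#'   column names.
#' @export
stoich_matrix <- function(net, internal_only = TRUE) {
  rows <- if (internal_only) internal_compounds(net) else compound_ids(net)
  S <- matrix(0, nrow = length(rows), ncol = length(net$reactions),
              dimnames = list(rows, reaction_ids(net)))
  for (r in net$reactions) {
    hit <- intersect(names(r$stoich), rows)
    if (length(hit)) S[hit, r$id] <- r$stoich[hit]
  }
  S
}

#' Compound connectivity
#'
#' The connectivity of a compound is the number of reactions in which it
#' participates (either side; a reversible reaction counts once). Comparing
#' connectivities between a full network (C_f) and a subnetwork (C_s) drives
#' the hub reclassification rule of the subnetwork extraction.
#'
#' @param net A `metabolic_network`.
#' @param compound_id Character vector of compound ids; default all compounds.
#' @return Named integer vector of reaction counts.
#' @examples
#' net <- metabolic_network(list(
#'   reaction("r1", c(A = -1, B = 1)),
#'   reaction("r2", c(B = -1, C = 1))))
#' connectivity(net, "B")  # 2
#' @export
connectivity <- function(net, compound_id = compound_ids(net)) {
  unknown <- setdiff(compound_id, compound_ids(net))
  if (length(unknown))
    stop("unknown compound id(s): ", paste(unknown, collapse = ", "))
  tab <- table(unlist(lapply(net$reactions, function(r) names(r$stoich))))
  out <- integer(length(compound_id))
  names(out) <- compound_id
  hit <- intersect(compound_id, names(tab))
  out[hit] <- as.integer(tab[hit])
  out
}

#' Reactions mentioning a compound
#'
#' @param net A `metabolic_network`.
#' @param compound_id Single compound id.
#' @return Character vector of reaction ids whose stoichiometry mentions the
#'   compound.
#' @export
reactions_of <- function(net, compound_id) {
  stopifnot(length(compound_id) == 1L)
  if (!compound_id %in% compound_ids(net))
    stop("unknown compound id: ", compound_id)
  names(Filter(function(r) compound_id %in% names(r$stoich), net$reactions))
}

#' Restrict a network to a set of reactions
#'
#' Keeps the given reactions and every compound they mention; compound roles
#' are carried over unchanged from the parent network.
#'
#' @param net A `metabolic_network`.
#' @param keep_reactions Character vector of reaction ids to keep.
#' @param name Name for the restricted network.
#' @return A `metabolic_network`.
#' @export
subnetwork <- function(net, keep_reactions, name = net$name) {
  missing <- setdiff(keep_reactions, reaction_ids(net))
  if (length(missing))
    stop("reactions not in network: ", paste(missing, collapse = ", "))
  rxns <- net$reactions[keep_reactions]
  mentioned <- unique(unlist(lapply(rxns, function(r) names(r$stoich))))
  metabolic_network(rxns,
                    compounds = net$compounds[net$compounds$id %in% mentioned, ,
                                              drop = FALSE],
                    name = name)
}

#' Remove reactions from a network
#'
#' Drops the given reactions; compounds left in no reaction are dropped too.
#' Used to simulate structural knockouts.
#'
#' @inheritParams subnetwork
#' @param drop_reactions Character vector of reaction ids to remove.
#' @return A `metabolic_network`.
#' @export
drop_reactions <- function(net, drop_reactions, name = net$name) {
  subnetwork(net, setdiff(reaction_ids(net), drop_reactions), name = name)
}

#' Validate network invariants
#'
#' Checks id uniqueness, declared compounds, nonzero coefficients, bound
#' ordering, and that every internal compound appears in at least one
#' reaction.
#'
#' @param net A `metabolic_network`.
#' @return Invisibly `TRUE`; stops with an informative error otherwise.
#' @export
validate_network <- function(net) {
  stopifnot(inherits(net, "metabolic_network"))
  conn <- connectivity(net)
  orphan <- names(conn)[conn == 0 &
                          net$compounds$role[match(names(conn), net$compounds$id)] == "internal"]
  if (length(orphan))
    stop("internal compounds in no reaction: ", paste(orphan, collapse = ", "))
  for (r in net$reactions) {
    if (any(r$stoich == 0)) stop("zero coefficient in reaction ", r$id)
    if (!is.na(r$lb) && !is.na(r$ub) && r$lb > r$ub)
      stop("bounds out of order in reaction ", r$id)
  }
  invisible(TRUE)
}

#' Export compound and reaction tables
#'
#' @param net A `metabolic_network`.
#' @return `compound_table()`: the compound data frame with connectivities;
#'   `reaction_table()`: one row per reaction with equation text, direction,
#'   gene label and bounds.
#' @export
compound_table <- function(net) {
  out <- net$compounds
  out$connectivity <- as.integer(connectivity(net, out$id))
  out
}

#' @rdname compound_table
#' @export
reaction_table <- function(net) {
  data.frame(
    id = reaction_ids(net),
    equation = vapply(net$reactions, format_reaction_equation, character(1)),
    reversible = vapply(net$reactions, `[[`, logical(1), "reversible"),
    gene = vapply(net$reactions, `[[`, character(1), "gene"),
    lb = vapply(net$reactions, `[[`, numeric(1), "lb"),
    ub = vapply(net$reactions, `[[`, numeric(1), "ub"),
    row.names = NULL, stringsAsFactors = FALSE)
}
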