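#' Objective specification for cut-set analysis
#'
#' The network function to be destroyed is characterized by its objective
#' reactions — here, by default, the two reactions directly forming the
#' anthocyanin glucosides. `candidate_reaction_ids` optionally restricts
#' which reactions may appear in cuts (e.g. the pathway's own reactions);
#' `NULL` means every reaction occurring in a target mode is a candidate.
#'
#' @param objective_reaction_ids Nonempty character vector.
#' @param candidate_reaction_ids Optional character vector.
#' @return An object of class `"objective_spec"`.
#' @export
objective_spec <- function(objective_reaction_ids = c("PELUDP-RXN", "RXN1F-775"),
                           candidate_reaction_ids = NULL) {
  stopifnot(length(objective_reaction_ids) >= 1L)
  structure(list(objective_reaction_ids = unique(objective_reaction_ids),
                 candidate_reaction_ids =
                   if (is.null(candidate_reaction_ids)) NULL
                   else unique(candidate_reaction_ids)),
            class = "objective_spec")
}

#' Select the target elementary modes of an objective
#'
#' The modes whose support intersects the objective reactions: exactly the
#' modes that must all be hit for the objective's flux to vanish.
#'
#' @param ems An `em_set`.
#' @param objective An [objective_spec()] or a character vector of objective
#'   reaction ids.
#' @return An `em_set` holding only the target modes (column subset).
#' @export
select_target_ems <- function(ems, objective) {
  if (is.character(objective)) objective <- objective_spec(objective)
  obj <- objective$objective_reaction_ids
  missing <- setdiff(obj, rownames(ems$coef))
  if (length(missing))
    stop("objective reaction(s) not in network: ", paste(missing, collapse = ", "))
  hit <- colSums(ems$coef[obj, , drop = FALSE] != 0) > 0
  out <- ems
  out$coef <- ems$coef[, hit, drop = FALSE]
  out$class_label <- ems$class_label[hit]
  out
}

new_cutset_list <- function(sets, sizes = lengths(sets),
                            unaffected = rep(NA_integer_, length(sets)),
                            genes = rep(list(character(0)), length(sets))) {
  structure(list(sets = sets, size = as.integer(sizes),
                 unaffected = as.integer(unaffected), genes = genes),
            class = "cutset_list")
}

#' @export
print.cutset_list <- function(x, ...) {
  cat(length(x$sets), "minimal cut set(s)\n")
  for (i in seq_along(x$sets)) {
    cat(sprintf("  MCS%-3d {%s}", i, paste(x$sets[[i]], collapse = ", ")))
    if (!is.na(x$unaffected[i])) cat("  unaffected:", x$unaffected[i])
    if (length(x$genes[[i]])) cat("  [", paste(x$genes[[i]], collapse = ", "), "]")
    cat("\n")
  }
  invisible(x)
}

#' @export
length.cutset_list <- function(x) length(x$sets)

#' Enumerate minimal cut sets
#'
#' A cut set blocks every target mode (intersects every target support); a
#' minimal cut set (MCS) has no proper subset with that property. MCSs are
#' exactly the minimal hitting sets (hypergraph transversals) of the family
#' of target supports restricted to the candidate reactions, computed here
#' by Berge-style incremental dualization: fold the supports in one at a
#' time, extending each partial transversal by each element of the new
#' support and pruning non-minimal sets.
#'
#' @param target_ems An `em_set` of target modes (see [select_target_ems()]),
#'   or a list of character-vector supports.
#' @param candidates Character vector of reactions allowed in cuts; defaults
#'   to the union of the target supports. A target mode whose support avoids
#'   all candidates can never be cut and raises an error naming the mode.
#' @param network Optional `metabolic_network` supplying gene labels for the
#'   cut reactions (defaults to the em_set's network).
#' @return A `"cutset_list"`: `sets` (list of reaction-id vectors, sorted by
#'   size then lexicographically), `size`, `unaffected` (`NA` until
#'   [unaffected_counts()]), `genes`.
#' @examples
#' mcs <- enumerate_mcs(list(c("a", "b")))
#' mcs$sets  # {a} and {b}
#' @export
enumerate_mcs <- function(target_ems, candidates = NULL, network = NULL) {
  if (inherits(target_ems, "em_set")) {
    supports <- em_supports(target_ems)
    names(supports) <- colnames(target_ems$coef)
    if (is.null(network)) network <- target_ems$network
  } else {
    supports <- target_ems
    if (is.null(names(supports)) && length(supports))
      names(supports) <- paste0("EM", seq_along(supports))
  }
  if (length(supports) == 0L)
    return(new_cutset_list(list()))
  if (is.null(candidates)) candidates <- sort(unique(unlist(supports)))
  restricted <- lapply(supports, intersect, candidates)
  empty <- lengths(restricted) == 0L
  if (any(empty))
    stop("uncuttable mode(s): no candidate reaction in the support of ",
         paste(names(supports)[empty], collapse = ", "))

  transversals <- list(character(0))
  for (P in restricted) {
    hit <- vapply(transversals, function(tr) length(intersect(tr, P)) > 0, logical(1))
    extended <- list()
    for (tr in transversals[!hit])
      for (p in P)
        extended[[length(extended) + 1L]] <- sort(c(tr, p))
    cand <- c(transversals[hit], extended)
    cand <- unique(cand)
    transversals <- cand[minimal_sets(cand)]
  }
  o <- order(lengths(transversals),
             vapply(transversals, paste, character(1), collapse = "\r"))
  sets <- transversals[o]
  genes <- rep(list(character(0)), length(sets))
  if (!is.null(network)) {
    glab <- vapply(network$reactions, `[[`, character(1), "gene")
    genes <- lapply(sets, function(s) {
      g <- glab[match(s, reaction_ids(network))]
      unname(g[!is.na(g)])
    })
  }
  new_cutset_list(sets, genes = genes)
}

## TRUE for sets that are not proper supersets of another set in the list
minimal_sets <- function(sets) {
  n <- length(sets)
  if (n <= 1L) return(rep(TRUE, n))
  keep <- rep(TRUE, n)
  sz <- lengths(sets)
  o <- order(sz)
  for (a in seq_len(n - 1L)) for (b in seq(a + 1L, n)) {
    i <- o[a]; j <- o[b]
    if (keep[j] && sz[i] < sz[j] && all(sets[[i]] %in% sets[[j]]))
      keep[j] <- FALSE
  }
  keep
}

#' Count the modes unaffected by each cut set
#'
#' A mode is unaffected by a cut when its support is disjoint from the cut's
#' reactions. The universe of modes counted is a parameter: the default is
#' every non-target mode, but any label-restricted universe (e.g. only
#' flavonoid modes) can be supplied, since published tables differ in which
#' universe they report.
#'
#' @param cutsets A `"cutset_list"`.
#' @param ems The full `em_set`.
#' @param universe `"non-target"` (default: all modes not hit by
#'   `objective`), `"all"`, or a character vector of class labels selecting
#'   modes by their `class_label`.
#' @param objective Objective reactions used to define the target modes when
#'   `universe = "non-target"`.
#' @return The `cutset_list` with `unaffected` filled in.
#' @export
unaffected_counts <- function(cutsets, ems, universe = "non-target",
                              objective = objective_spec()) {
  if (is.character(objective)) objective <- objective_spec(objective)
  supports <- em_supports(ems)
  sel <- if (identical(universe, "all")) {
    rep(TRUE, n_modes(ems))
  } else if (identical(universe, "non-target")) {
    obj <- intersect(objective$objective_reaction_ids, rownames(ems$coef))
    colSums(ems$coef[obj, , drop = FALSE] != 0) == 0
  } else {
    ems$class_label %in% universe
  }
  cutsets$unaffected <- vapply(cutsets$sets, function(cut)
    sum(vapply(supports[sel], function(s) length(intersect(s, cut)) == 0L,
               logical(1))), integer(1))
  cutsets
}

#' Fragility coefficients
#'
#' The fragility coefficient of a reaction is the average of the reciprocal
#' sizes of the minimal cut sets containing it. A reaction that alone
#' constitutes a cut has fc = 1; membership in large cuts dilutes a
#' reaction's fc, so fc ranks reactions by how crucial each is to the
#' objective rather than by how many modes it touches.
#'
#' @param cutsets A nonempty `"cutset_list"`.
#' @return Named numeric vector over the reactions occurring in at least one
#'   cut set (reactions in no cut set are absent). Values are exact up to
#'   double precision; round to 2 decimals for table display.
#' @examples
#' fragility(enumerate_mcs(list(c("a", "b"))))  # a = 1, b = 1
#' @export
fragility <- function(cutsets) {
  stopifnot(inherits(cutsets, "cutset_list"), length(cutsets$sets) >= 1L)
  rxns <- sort(unique(unlist(cutsets$sets)))
  vapply(stats::setNames(rxns, rxns), function(r) {
    inn <- vapply(cutsets$sets, function(s) r %in% s, logical(1))
    mean(1 / cutsets$size[inn])
  }, numeric(1))
}

#' Build a cut-set list from a binary membership matrix
#'
#' Converts a published cut-set table (rows = cut sets, columns = reactions,
#' entries 0/1) into a `"cutset_list"`, e.g. for recomputing fragility
#' coefficients from a printed table.
#'
#' @param M Binary matrix or data frame with reaction ids as column names.
#' @param unaffected Optional integer vector of unaffected-mode counts.
#' @param genes Optional list (or comma-separated character vector) of gene
#'   labels per cut set.
#' @return A `"cutset_list"`.
#' @export
cutsets_from_matrix <- function(M, unaffected = NULL, genes = NULL) {
  M <- as.matrix(M)
  stopifnot(!is.null(colnames(M)), all(M %in% c(0, 1)))
  sets <- apply(M, 1, function(row) colnames(M)[row == 1], simplify = FALSE)
  if (is.null(unaffected)) unaffected <- rep(NA_integer_, length(sets))
  if (is.null(genes)) genes <- rep(list(character(0)), length(sets))
  if (is.character(genes)) genes <- strsplit(genes, ",[ ]*")
  new_cutset_list(unname(sets), unaffected = unaffected, genes = genes)
}

#' Export a cut-set list as a membership table
#'
#' One row per cut set: binary membership over `candidates`, the cut size,
#' the unaffected-mode count and the gene labels — the layout used for
#' published cut-set tables.
#'
#' @param cutsets A `"cutset_list"`.
#' @param candidates Column order; defaults to the union of the sets.
#' @return A data frame.
#' @export
cutset_table <- function(cutsets, candidates = sort(unique(unlist(cutsets$sets)))) {
  M <- t(vapply(cutsets$sets, function(s) as.integer(candidates %in% s),
                integer(length(candidates))))
  colnames(M) <- candidates
  out <- as.data.frame(M)
  out$total_rxns <- cutsets$size
  out$unaffected <- cutsets$unaffected
  out$genes <- vapply(cutsets$genes, paste, character(1), collapse = ", ")
  out
}
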