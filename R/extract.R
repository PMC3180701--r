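#' Preliminary internal/external classification
#'
#' A compound that consistently appears on one side only — a substrate in
#' every reaction mentioning it, or a product in every reaction mentioning
#' it — can only be balanced by the outside world and is classified
#' external. Participation in any reversible reaction disqualifies a
#' compound from this rule (it can appear on either side), making it
#' internal. Compounds mentioned by no reaction are external by convention
#' and listed in the `"unreferenced"` attribute of the result.
#'
#' @param net A `metabolic_network`.
#' @return Named character vector (`"internal"`/`"external"`) over all
#'   compound ids.
#' @examples
#' net <- metabolic_network(list(
#'   reaction("r1", c(A = -1, B = 1)),
#'   reaction("r2", c(B = -1, C = 1))))
#' preliminary_classification(net)  # A, C external; B internal
#' @export
preliminary_classification <- function(net) {
  ids <- compound_ids(net)
  seen_sub <- seen_prod <- seen_rev <- stats::setNames(logical(length(ids)), ids)
  for (r in net$reactions) {
    cs <- names(r$stoich)
    if (r$reversible) {
      seen_rev[cs] <- TRUE
    } else {
      seen_sub[cs[r$stoich[cs] < 0]] <- TRUE
      seen_prod[cs[r$stoich[cs] > 0]] <- TRUE
    }
  }
  mentioned <- seen_sub | seen_prod | seen_rev
  one_sided <- !seen_rev & xor(seen_sub, seen_prod)
  out <- ifelse(!mentioned | one_sided, "external", "internal")
  names(out) <- ids
  attr(out, "unreferenced") <- ids[!mentioned]
  out
}

#' Extraction configuration
#'
#' Settings for [extract_coherent_subnetwork()]. The buffered list names
#' compounds treated as external reservoirs (carrier molecules, nucleoside
#' phosphates, amino acids, nutrients and similarly ubiquitous compounds);
#' the hub rule reclassifies a compound as external when its full-network
#' connectivity C_f dwarfs its subnetwork connectivity C_s, i.e. when
#' `C_f >= hub_ratio * C_s` and `C_f >= hub_min_connectivity`.
#'
#' @param seed_reaction_ids Character vector of reactions seeding the
#'   prototype subnetwork (e.g. the empirically known pathway reactions).
#' @param buffered Character vector of buffered compound ids.
#' @param hub_ratio Multiplicative threshold (> 1) interpreting "C_f much
#'   larger than C_s"; default 3.
#' @param hub_min_connectivity Absolute full-network connectivity a hub must
#'   reach; default 10.
#' @param max_iterations Iteration cap for the traceback fixed point.
#' @param max_fraction Abort when the subnetwork exceeds this fraction of
#'   the full network's reactions (termination of the heuristic is not
#'   guaranteed in general); default 0.8.
#' @return An object of class `"extraction_config"`.
#' @export
extraction_config <- function(seed_reaction_ids, buffered = character(0),
                              hub_ratio = 3, hub_min_connectivity = 10,
                              max_iterations = 100L, max_fraction = 0.8) {
  stopifnot(length(seed_reaction_ids) >= 1L, hub_ratio > 1,
            hub_min_connectivity >= 0, max_iterations >= 1L,
            max_fraction > 0, max_fraction <= 1)
  structure(list(seed_reaction_ids = unique(seed_reaction_ids),
                 buffered = unique(buffered),
                 hub_ratio = hub_ratio,
                 hub_min_connectivity = hub_min_connectivity,
                 max_iterations = as.integer(max_iterations),
                 max_fraction = max_fraction),
            class = "extraction_config")
}

#' Read a buffered-compound list file
#'
#' Plain text, one compound id per line; `#` starts a comment.
#'
#' @param path File path.
#' @return Character vector of compound ids.
#' @export
read_buffered_list <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines[nzchar(lines)]
}

#' Extract a coherent subnetwork around seed reactions
#'
#' Iteratively grows a prototype subnetwork from the seed reactions: any
#' compound of the prototype that is internal in the full network, not on
#' the buffered list, and not reclassified external by the hub rule, must
#' carry exactly the same reactions in the prototype as in the full network;
#' when it does not, all its full-network reactions are traced (backwards to
#' substrates and forwards to products) and added. Classification,
#' comparison and traceback repeat until no reaction is added, at which
#' point every internal node of the subnetwork sees an identical reaction
#' set in both networks — a coherent subnetwork.
#'
#' The reaction set grows monotonically, so the fixed point is reached in at
#' most `max_iterations` sweeps unless the subnetwork swallows more than
#' `max_fraction` of the full network first, which aborts with an error.
#'
#' @param full The full `metabolic_network` (unchanged by the process).
#' @param config An [extraction_config()].
#' @return A `metabolic_network` whose compound roles reflect the subnetwork
#'   classification (buffered and hub compounds become external), with
#'   attributes `"hub_reclassified"` (compound ids held external by the hub
#'   rule) and `"iterations"`.
#' @export
extract_coherent_subnetwork <- function(full, config) {
  stopifnot(inherits(full, "metabolic_network"),
            inherits(config, "extraction_config"))
  missing_seed <- setdiff(config$seed_reaction_ids, reaction_ids(full))
  if (length(missing_seed))
    stop("seed reaction(s) not in full network: ",
         paste(missing_seed, collapse = ", "))
  unknown_buf <- setdiff(config$buffered, compound_ids(full))
  if (length(unknown_buf))
    warning("buffered compound(s) not in full network (ignored): ",
            paste(unknown_buf, collapse = ", "))
  full_role <- stats::setNames(full$compounds$role, full$compounds$id)
  C_f <- connectivity(full)
  keep <- config$seed_reaction_ids
  it <- 0L
  repeat {
    it <- it + 1L
    sub <- subnetwork(full, keep)
    C_s <- connectivity(sub)
    frontier <- character(0)
    hubs <- character(0)
    for (cmp in compound_ids(sub)) {
      if (full_role[[cmp]] == "external" || cmp %in% config$buffered) next
      if (C_f[[cmp]] >= config$hub_ratio * C_s[[cmp]] &&
          C_f[[cmp]] >= config$hub_min_connectivity) {
        hubs <- c(hubs, cmp)
        next
      }
      if (C_f[[cmp]] > C_s[[cmp]]) frontier <- c(frontier, cmp)
    }
    if (length(frontier) == 0L) break
    # breadth-first trace: add every full-network reaction of every frontier
    # node in this sweep; lexicographic reaction order keeps it deterministic
    new_rxn <- sort(unique(unlist(lapply(frontier, reactions_of, net = full))))
    keep <- union(keep, new_rxn)
    if (length(keep) > config$max_fraction * length(full$reactions))
      stop("subnetwork extraction did not stay contained: ",
           length(keep), " of ", length(full$reactions),
           " reactions absorbed (frontier of ", length(frontier), " nodes)")
    if (it >= config$max_iterations)
      stop("no fixed point within ", config$max_iterations,
           " iterations (frontier of ", length(frontier), " nodes)")
  }
  # order reactions as in the full network for stable output
  keep <- intersect(reaction_ids(full), keep)
  sub <- subnetwork(full, keep)
  ext <- full_role[compound_ids(sub)] == "external" |
    compound_ids(sub) %in% config$buffered | compound_ids(sub) %in% hubs
  sub$compounds$role <- ifelse(ext, "external", "internal")
  attr(sub, "hub_reclassified") <- hubs
  attr(sub, "iterations") <- it
  sub
}

#' Check the coherence of a subnetwork
#'
#' A subnetwork is coherent when every one of its internal compounds has an
#' identical set of incident reactions in the subnetwork and in the full
#' network, so that cutting it out removed no stoichiometric constraint that
#' mattered. Boundary compounds (external in the subnetwork) are exempt.
#'
#' @param full The full `metabolic_network`.
#' @param sub A candidate subnetwork whose reactions all occur in `full` and
#'   whose compound roles define which nodes are internal.
#' @return An object of class `"coherence_report"`: list with `coherent`
#'   (flag) and `offending` (data frame with columns `id`, `C_f`, `C_s`,
#'   `reason`), where `coherent` is `TRUE` iff `offending` is empty.
#' @export
check_coherence <- function(full, sub) {
  extra <- setdiff(reaction_ids(sub), reaction_ids(full))
  if (length(extra))
    stop("subnetwork has reactions absent from the full network: ",
         paste(extra, collapse = ", "))
  offending <- data.frame(id = character(0), C_f = integer(0),
                          C_s = integer(0), reason = character(0),
                          stringsAsFactors = FALSE)
  if (length(sub$reactions)) {
    C_f <- connectivity(full)
    C_s <- connectivity(sub)
    for (cmp in internal_compounds(sub)) {
      rf <- reactions_of(full, cmp)
      rs <- reactions_of(sub, cmp)
      if (!setequal(rf, rs)) {
        offending <- rbind(offending, data.frame(
          id = cmp, C_f = C_f[[cmp]], C_s = C_s[[cmp]],
          reason = paste0("misses reactions: ",
                          paste(setdiff(rf, rs), collapse = ", ")),
          stringsAsFactors = FALSE))
      }
    }
  }
  structure(list(coherent = nrow(offending) == 0L, offending = offending),
            class = "coherence_report")
}

#' @export
print.coherence_report <- function(x, ...) {
  if (x$coherent) {
    cat("Coherent subnetwork: every internal node keeps its full reaction set\n")
  } else {
    cat("NOT coherent;", nrow(x$offending), "internal node(s) offend:\n")
    print(x$offending, row.names = FALSE)
  }
  invisible(x)
}
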