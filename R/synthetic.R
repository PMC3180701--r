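#' Generate a linear chain network
#'
#' External source, `k` irreversible conversions, external sink. Exactly one
#' elementary mode (the whole chain), which makes chains the base case for
#' enumeration tests.
#'
#' @param k Number of reactions, >= 1.
#' @param seed Unused except for interface uniformity (the chain is
#'   deterministic); kept so all generators share a signature.
#' @return List with `network` and `answer` (list with `em_count`,
#'   `em_supports`).
#' @export
gen_linear_chain <- function(k, seed = 1L) {
  stopifnot(k >= 1)
  mid <- if (k > 1) paste0("C", seq_len(k - 1)) else character(0)
  cmp <- c("X-SRC", mid, "X-SINK")
  rxns <- lapply(seq_len(k), function(i)
    reaction(sprintf("chain-r%02d", i),
             stats::setNames(c(-1, 1), c(cmp[i], cmp[i + 1]))))
  roles <- c("external", rep("internal", k - 1), "external")
  net <- metabolic_network(rxns, compounds = data.frame(
    id = cmp, name = cmp, role = roles), name = sprintf("chain-%d", k))
  list(network = net,
       answer = list(em_count = 1L,
                     em_supports = list(reaction_ids(net))))
}

#' Generate a layered branching network
#'
#' Layer `i` offers `layers[i]` parallel single-reaction routes between
#' consecutive internal intermediates, between an external source and an
#' external sink. The elementary modes are exactly the route combinations,
#' so their count is `prod(layers)`; the minimal cut sets for the terminal
#' sink reaction as objective are the sink itself and every full layer
#' (blocking all parallel branches of one layer).
#'
#' @param layers Integer vector of branch counts, all >= 1.
#' @param seed Unused; interface uniformity.
#' @return List with `network` and `answer` (`em_count`, `planted_mcs`,
#'   `objective`).
#' @export
gen_branching <- function(layers, seed = 1L) {
  stopifnot(length(layers) >= 1, all(layers >= 1))
  L <- length(layers)
  nodes <- c("X-SRC", paste0("N", seq_len(L)), "X-SINK")
  roles <- c("external", rep("internal", L), "external")
  rxns <- list()
  layer_ids <- vector("list", L + 1L)
  for (i in seq_len(L)) {
    ids <- sprintf("br-L%d-%d", i, seq_len(layers[i]))
    layer_ids[[i]] <- ids
    for (j in seq_len(layers[i]))
      rxns[[length(rxns) + 1L]] <-
        reaction(ids[j], stats::setNames(c(-1, 1), c(nodes[i], nodes[i + 1])))
  }
  sink_id <- "br-sink"
  layer_ids[[L + 1L]] <- sink_id
  rxns[[length(rxns) + 1L]] <-
    reaction(sink_id, stats::setNames(c(-1, 1), c(nodes[L + 1L], "X-SINK")))
  net <- metabolic_network(rxns, compounds = data.frame(
    id = nodes, name = nodes, role = roles),
    name = paste0("branching-", paste(layers, collapse = "x")))
  planted_mcs <- c(list(sink_id), lapply(seq_len(L), function(i) layer_ids[[i]]))
  planted_mcs <- lapply(planted_mcs, sort)
  o <- order(lengths(planted_mcs),
             vapply(planted_mcs, paste, character(1), collapse = "\r"))
  list(network = net,
       answer = list(em_count = prod(layers),
                     planted_mcs = planted_mcs[o],
                     objective = sink_id))
}

#' Generate a full network with an embedded coherent subnetwork
#'
#' Plants a coherent branching subnetwork inside a larger network by adding
#' (i) hub compounds of high degree attached as cofactors to some planted
#' reactions and consumed by many reactions outside the subnetwork —
#' emulating ubiquitous carrier compounds recognizable by their large
#' connectivity — and (ii) a disjoint decoy component. With the hubs on the
#' buffered list and seeds inside the planted subnetwork,
#' [extract_coherent_subnetwork()] recovers the planted reaction set
#' exactly.
#'
#' @param layers Branch counts of the planted subnetwork.
#' @param n_hubs Number of hub compounds.
#' @param hub_degree Reactions per hub outside the subnetwork.
#' @param decoy_size Reactions in the disjoint decoy chain (0 for none).
#' @param seed Random seed (hub attachment points).
#' @return List with `full`, `planted` (networks), `config` (an
#'   [extraction_config()]) and `answer` (`planted_reaction_ids`).
#' @export
gen_full_with_embedded_subnet <- function(layers = c(2, 3), n_hubs = 2L,
                                          hub_degree = 12L, decoy_size = 4L,
                                          seed = 1L) {
  set.seed(seed)
  planted <- gen_branching(layers)$network
  rxns <- planted$reactions
  compounds <- planted$compounds
  hub_ids <- sprintf("HUB%d", seq_len(n_hubs))
  # attach each hub as an extra substrate of one random planted reaction
  attach_at <- sample(names(rxns), n_hubs, replace = TRUE)
  for (h in seq_len(n_hubs)) {
    r <- rxns[[attach_at[h]]]
    r$stoich <- c(r$stoich, stats::setNames(-1, hub_ids[h]))
    rxns[[attach_at[h]]] <- r
  }
  # outside reactions consuming the hubs
  for (h in seq_len(n_hubs)) {
    for (d in seq_len(hub_degree - 1L)) {
      cid <- sprintf("OUT-%d-%d", h, d)
      compounds <- rbind(compounds, data.frame(id = cid, name = cid,
                                               role = "external"))
      rxns[[length(rxns) + 1L]] <-
        reaction(sprintf("out-h%d-%d", h, d),
                 stats::setNames(c(-1, 1), c(hub_ids[h], cid)))
    }
  }
  compounds <- rbind(compounds, data.frame(id = hub_ids, name = hub_ids,
                                           role = "internal"))
  # disjoint decoy chain
  if (decoy_size > 0L) {
    dmid <- if (decoy_size > 1L) paste0("DECOY", seq_len(decoy_size - 1L))
            else character(0)
    dn <- c("DECOY-SRC", dmid, "DECOY-SINK")
    for (i in seq_len(decoy_size))
      rxns[[length(rxns) + 1L]] <-
        reaction(sprintf("decoy-r%d", i),
                 stats::setNames(c(-1, 1), c(dn[i], dn[i + 1L])))
    compounds <- rbind(compounds, data.frame(
      id = dn, name = dn,
      role = c("external", rep("internal", decoy_size - 1L), "external")))
  }
  full <- metabolic_network(rxns, compounds = compounds, name = "full-embedded")
  planted_ids <- reaction_ids(planted)
  config <- extraction_config(
    seed_reaction_ids = planted_ids[1],
    buffered = hub_ids,
    hub_ratio = 3, hub_min_connectivity = 10)
  # the planted network, as embedded: same reactions but with hub cofactors
  planted_embedded <- subnetwork(full, planted_ids, name = "planted")
  planted_embedded$compounds$role[planted_embedded$compounds$id %in% hub_ids] <-
    "external"
  list(full = full, planted = planted_embedded, config = config,
       answer = list(planted_reaction_ids = planted_ids))
}

#' Miniature two-branch anthocyanin pathway fixture
#'
#' A hand-sized pathway with the structural signature of the anthocyanin
#' branch point: shared early reactions (chalcone synthase and isomerase
#' analogues), one pelargonidin-type branch, one cyanidin-type branch fed by
#' two parallel hydroxylation routes, and a flavonol side branch. Both
#' anthocyanin-forming reactions are objectives. The elementary modes and
#' minimal cut sets are hand-enumerated and returned alongside the network,
#' so every downstream stage can be checked against known answers.
#'
#' Hand enumeration (6 modes): the pelargonidin route; the cyanidin route
#' via the dihydrokaempferol hydroxylation; the cyanidin route via the
#' eriodictyol hydroxylation; and three flavonol routes (one to kaempferol,
#' two to quercetin). The three anthocyanin target modes admit 14 minimal
#' cut sets: the two early-reaction singletons, eight pairs and four
#' triples, including the pair of the two objective glucosylations.
#'
#' @return List with `network`, `answer` (`em_count`, `em_supports`,
#'   `target_em_supports`, `planted_mcs`, `objective`) and `class_map`.
#' @export
make_mini_abp_fixture <- function() {
  rxns <- list(
    reaction("mCHS", c(`PRECURSOR` = -1, `CHALCONE` = 1)),
    reaction("mCHI", c(`CHALCONE` = -1, `NARINGENIN` = 1)),
    reaction("mF3H", c(`NARINGENIN` = -1, `DHK` = 1)),
    reaction("mF3pH-nar", c(`NARINGENIN` = -1, `ERIODICTYOL` = 1)),
    reaction("mF3H-eri", c(`ERIODICTYOL` = -1, `DHQ` = 1)),
    reaction("mF3pH-dhk", c(`DHK` = -1, `DHQ` = 1)),
    reaction("mDFR-pg", c(`DHK` = -1, `PG-AGLYCONE` = 1)),
    reaction("mDFR-cy", c(`DHQ` = -1, `CY-AGLYCONE` = 1)),
    reaction("m3UGT-pg", c(`PG-AGLYCONE` = -1, `PG-GLUCOSIDE` = 1)),
    reaction("m3UGT-cy", c(`CY-AGLYCONE` = -1, `CY-GLUCOSIDE` = 1)),
    reaction("mFLS-pg", c(`DHK` = -1, `KAEMPFEROL` = 1)),
    reaction("mFLS-cy", c(`DHQ` = -1, `QUERCETIN` = 1)))
  ext <- c("PRECURSOR", "PG-GLUCOSIDE", "CY-GLUCOSIDE",
           "KAEMPFEROL", "QUERCETIN")
  ids <- unique(unlist(lapply(rxns, function(r) names(r$stoich))))
  net <- metabolic_network(rxns, compounds = data.frame(
    id = ids, name = ids,
    role = ifelse(ids %in% ext, "external", "internal")),
    name = "mini-ABP")
  shared <- c("mCHS", "mCHI")
  sup_pg <- c(shared, "mF3H", "mDFR-pg", "m3UGT-pg")
  sup_cy1 <- c(shared, "mF3H", "mF3pH-dhk", "mDFR-cy", "m3UGT-cy")
  sup_cy2 <- c(shared, "mF3pH-nar", "mF3H-eri", "mDFR-cy", "m3UGT-cy")
  sup_k <- c(shared, "mF3H", "mFLS-pg")
  sup_q1 <- c(shared, "mF3H", "mF3pH-dhk", "mFLS-cy")
  sup_q2 <- c(shared, "mF3pH-nar", "mF3H-eri", "mFLS-cy")
  supports <- lapply(list(sup_pg, sup_cy1, sup_cy2, sup_k, sup_q1, sup_q2), sort)
  # minimal hitting sets of {pg, cy1, cy2}, worked out by hand:
  planted_mcs <- list(
    c("mCHS"), c("mCHI"),
    c("mF3H", "mF3pH-nar"), c("mF3H", "mF3H-eri"),
    c("mF3H", "mDFR-cy"), c("mF3H", "m3UGT-cy"),
    c("mDFR-pg", "mDFR-cy"), c("mDFR-pg", "m3UGT-cy"),
    c("m3UGT-pg", "mDFR-cy"), c("m3UGT-pg", "m3UGT-cy"),
    c("mDFR-pg", "mF3pH-dhk", "mF3pH-nar"),
    c("mDFR-pg", "mF3pH-dhk", "mF3H-eri"),
    c("m3UGT-pg", "mF3pH-dhk", "mF3pH-nar"),
    c("m3UGT-pg", "mF3pH-dhk", "mF3H-eri"))
  planted_mcs <- lapply(planted_mcs, sort)
  o <- order(lengths(planted_mcs),
             vapply(planted_mcs, paste, character(1), collapse = "\r"))
  class_map <- product_class_map(list(
    anthocyanins = c("PG-GLUCOSIDE", "CY-GLUCOSIDE"),
    flavonols1 = "KAEMPFEROL",
    flavonols2 = "QUERCETIN"))
  list(network = net,
       answer = list(em_count = 6L,
                     em_supports = supports,
                     target_em_supports = lapply(
                       list(sup_pg, sup_cy1, sup_cy2), sort),
                     planted_mcs = planted_mcs[o],
                     objective = c("m3UGT-pg", "m3UGT-cy")),
       class_map = class_map)
}

#' Synthetic flavonoid subnetwork stand-in
#'
#' A synthetic reconstruction of the flavonoid pathway neighbourhood, built
#' from the published pathway topology rather than from the database-derived
#' model (which is not redistributable here). It is a stand-in, not the real
#' 180-compound subnetwork: it carries the canonical reaction identifiers of
#' the anthocyanin branch (N-C-S-RXN for chalcone synthase, APIGNAR-RXN for
#' chalcone isomerase, N-3-D-RXN for flavanone 3-hydroxylase, the RXN-525 /
#' RXN-7652+RXN-7775 parallel hydroxylation routes to the cyanidin side,
#' RXN-600/RXN-602 and D-4-R-RXN/LEUCPEL-RXN for the two
#' reductase/synthase branches, and the objective glucosylations PELUDP-RXN
#' and RXN1F-775), plus flavonol, proanthocyanidin, flavone, flavanone
#' (liquiritigenin, whose chalcone-reductase route bypasses both CHS and
#' CHI analogues of the naringenin line), benzenoid and monolignol/lignin
#' branches. Restricted to the twelve anthocyanin-pathway reactions, its
#' anthocyanin modes reproduce the published branch structure, so cut-set
#' and fragility analyses on it mirror the published table.
#'
#' @return List with `network`, `class_map` (a [product_class_map()] over
#'   the product classes), `constraints` (a demo [flux_constraints()] table
#'   styled after measured-concentration constraints) and `objective`
#'   (an [objective_spec()]).
#' @export
synthetic_flavonoid_network <- function() {
  rxns <- list(
    reaction("PAL-RXN", c(PHE = -1, CINNAMATE = 1), gene = "PAL"),
    reaction("C4H-RXN", c(CINNAMATE = -1, COUMARATE = 1), gene = "C4H"),
    reaction("4CL-RXN", c(COUMARATE = -1, `COUMAROYL-COA` = 1), gene = "4CL"),
    reaction("N-C-S-RXN",
             c(`COUMAROYL-COA` = -1, `MALONYL-COA` = -3, `NARINGENIN-CHALCONE` = 1),
             gene = "CHS"),
    reaction("APIGNAR-RXN", c(`NARINGENIN-CHALCONE` = -1, NARINGENIN = 1),
             gene = "CHI"),
    reaction("N-3-D-RXN", c(NARINGENIN = -1, DHK = 1), gene = "F3H"),
    reaction("RXN-7652", c(NARINGENIN = -1, ERIODICTYOL = 1), gene = "F3'H(i)"),
    reaction("RXN-7775", c(ERIODICTYOL = -1, DHQ = 1), gene = "F3H(cy)"),
    reaction("RXN-525", c(DHK = -1, DHQ = 1), gene = "F3'H(ii)"),
    reaction("D-4-R-RXN", c(DHK = -1, LEUCOPELARGONIDIN = 1), gene = "DFR(pg)"),
    reaction("RXN-600", c(DHQ = -1, LEUCOCYANIDIN = 1), gene = "DFR(cy)"),
    reaction("LEUCPEL-RXN", c(LEUCOPELARGONIDIN = -1, PELARGONIDIN = 1),
             gene = "ANS(pg)"),
    reaction("RXN-602", c(LEUCOCYANIDIN = -1, CYANIDIN = 1), gene = "ANS(cy)"),
    reaction("PELUDP-RXN",
             c(PELARGONIDIN = -1, `UDP-GLUCOSE` = -1, `PG-3-GLUCOSIDE` = 1),
             gene = "3-UGT(pg)"),
    reaction("RXN1F-775",
             c(CYANIDIN = -1, `UDP-GLUCOSE` = -1, `CY-3-GLUCOSIDE` = 1),
             gene = "3-UGT(cy)"),
    reaction("FLS-PG-RXN", c(DHK = -1, KAEMPFEROL = 1), gene = "FLS(pg)"),
    reaction("RXN1F-461",
             c(KAEMPFEROL = -1, `UDP-GLUCOSE` = -1, `KAEMPFEROL-3-GLUCOSIDE` = 1),
             gene = "UGT78D2(k)"),
    reaction("FLS-CY-RXN", c(DHQ = -1, QUERCETIN = 1), gene = "FLS(cy)"),
    reaction("RXN1F-462",
             c(QUERCETIN = -1, `UDP-GLUCOSE` = -1, `QUERCETIN-3-GLUCOSIDE` = 1),
             gene = "UGT78D2(q)"),
    reaction("RXN-1481", c(LEUCOPELARGONIDIN = -1, AFZELECHIN = 1), gene = "LAR(pg)"),
    reaction("RXN-1484", c(LEUCOCYANIDIN = -1, `2-3-TRANS-CATECHIN` = 1),
             gene = "LAR(cy)"),
    reaction("FNS-NAR-RXN", c(NARINGENIN = -1, APIGENIN = 1), gene = "FNS"),
    reaction("FNS-ERI-RXN", c(ERIODICTYOL = -1, LUTEOLIN = 1), gene = "FNS"),
    reaction("CHR-RXN",
             c(`COUMAROYL-COA` = -1, `MALONYL-COA` = -3, ISOLIQUIRITIGENIN = 1),
             gene = "CHR"),
    reaction("LIQ-CHI-RXN", c(ISOLIQUIRITIGENIN = -1, `CPD-3041` = 1),
             gene = "CHI2"),
    reaction("BENZYL-ALC-DEHYDROGENASE-RXN",
             c(`BENZYL-ALCOHOL` = -1, BENZALDEHYDE = 1), gene = "BALDH"),
    reaction("BALDH-RXN", c(BENZALDEHYDE = -1, BENZOATE = 1), gene = "AAO"),
    reaction("BAMT-RXN", c(BENZOATE = -1, METHYLBENZOATE = 1), gene = "BAMT"),
    reaction("CCR-RXN", c(COUMARATE = -1, `COUMARYL-ALCOHOL` = 1), gene = "CCR/CAD"),
    reaction("LIGNIN-RXN", c(`COUMARYL-ALCOHOL` = -1, LIGNIN = 1), gene = "lignin"))
  ext <- c("PHE", "MALONYL-COA", "UDP-GLUCOSE", "BENZYL-ALCOHOL",
           "PG-3-GLUCOSIDE", "CY-3-GLUCOSIDE", "KAEMPFEROL-3-GLUCOSIDE",
           "QUERCETIN-3-GLUCOSIDE", "AFZELECHIN", "2-3-TRANS-CATECHIN",
           "APIGENIN", "LUTEOLIN", "CPD-3041", "METHYLBENZOATE", "LIGNIN")
  ids <- unique(unlist(lapply(rxns, function(r) names(r$stoich))))
  net <- metabolic_network(rxns, compounds = data.frame(
    id = ids, name = ids,
    role = ifelse(ids %in% ext, "external", "internal")),
    name = "synthetic flavonoid subnetwork (stand-in)")
  class_map <- product_class_map(
    list(anthocyanins = c("PG-3-GLUCOSIDE", "CY-3-GLUCOSIDE"),
         flavonols1 = "KAEMPFEROL-3-GLUCOSIDE",
         flavonols2 = "QUERCETIN-3-GLUCOSIDE",
         proanthocyanidins = c("AFZELECHIN", "2-3-TRANS-CATECHIN"),
         flavones = c("APIGENIN", "LUTEOLIN"),
         flavanones = "CPD-3041",
         benzenoids = "METHYLBENZOATE",
         lignin = "LIGNIN"))
  constraints <- flux_constraints(
    reaction_id = c("LIGNIN-RXN", "RXN1F-775", "PELUDP-RXN",
                    "RXN1F-461", "RXN1F-462", "RXN-1481", "RXN-1484",
                    "LIQ-CHI-RXN", "BENZYL-ALC-DEHYDROGENASE-RXN",
                    "FNS-NAR-RXN", "FNS-ERI-RXN", "BAMT-RXN"),
    min = c(0.027, 6.43e-2, 2.35e-3,
            1.64e-1, 8.03e-2, 3.58e-2, 3.58e-2,
            4.0e-2, 10,
            0, 0, 0),
    max = c(0.027, 6.43e-2, 2.35e-3,
            1.64e-1, 8.03e-2, 3.58e-2, 3.58e-2,
            4.0e-2, 10,
            14.4, 50.2, 22.7),
    provenance = c("fixed-value", "fixed-value", "fixed-value",
                   "fixed-value", "fixed-value", "fixed-value", "fixed-value",
                   "fixed-value", "fixed-input",
                   "range", "range", "range"))
  list(network = net, class_map = class_map, constraints = constraints,
       objective = objective_spec(c("PELUDP-RXN", "RXN1F-775")))
}

#' The twelve anthocyanin-pathway candidate reactions
#'
#' The reactions over which the published cut-set table is computed, in its
#' column order.
#'
#' @return Character vector of 12 reaction ids.
#' @export
abp_candidate_reactions <- function() {
  c("N-3-D-RXN", "LEUCPEL-RXN", "D-4-R-RXN", "RXN-525", "APIGNAR-RXN",
    "RXN-600", "RXN-602", "RXN-7652", "PELUDP-RXN", "RXN1F-775",
    "RXN-7775", "N-C-S-RXN")
}

#' Generate a random small network for property testing
#'
#' Random stoichiometric networks with a controlled reaction count, mixing
#' irreversible and reversible unimolecular conversions between a pool of
#' compounds, a random subset of which is external. Used to compare the
#' tableau enumeration against brute-force oracles.
#'
#' @param n_reactions Number of reactions.
#' @param n_compounds Compound pool size.
#' @param p_external Probability a compound is external.
#' @param p_reversible Probability a reaction is reversible.
#' @param seed Random seed.
#' @return A `metabolic_network`.
#' @export
gen_random_network <- function(n_reactions = 8L, n_compounds = 6L,
                               p_external = 0.35, p_reversible = 0.3,
                               seed = 1L) {
  set.seed(seed)
  cmp <- sprintf("M%02d", seq_len(n_compounds))
  role <- ifelse(stats::runif(n_compounds) < p_external, "external", "internal")
  rxns <- list()
  for (i in seq_len(n_reactions)) {
    pair <- sample(n_compounds, 2L)
    coefs <- stats::setNames(c(-sample(1:2, 1), sample(1:2, 1)), cmp[pair])
    rxns[[i]] <- reaction(sprintf("rr%02d", i), coefs,
                          reversible = stats::runif(1) < p_reversible)
  }
  metabolic_network(rxns, compounds = data.frame(id = cmp, name = cmp,
                                                 role = role),
                    name = sprintf("random-%d", seed))
}
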