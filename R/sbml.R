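#' Read a constraint-based model from SBML
#'
#' Supports the subset of SBML Level 2/Level 3 used by constraint-based
#' network models: `species` (with `boundaryCondition`), `reaction` with
#' `listOfReactants`/`listOfProducts` (`stoichiometry` defaults to 1) and the
#' `reversible` attribute. A species is classified external when its
#' `boundaryCondition` flag is true, when its compartment id or name starts
#' with `"ext"` (a convention some exporters use instead of the flag), or
#' when its id is listed in `external_ids`; everything else is internal.
#'
#' @param path Path to an SBML file.
#' @param external_ids Optional character vector of compound ids to force
#'   external, for files that encode boundary status out of band.
#' @return A [metabolic_network()].
#' @seealso [write_sbml()] for the inverse; a write/read round trip
#'   reproduces ids, roles, stoichiometry and reversibility exactly.
#' @export
read_sbml <- function(path, external_ids = NULL) {
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stop("cannot read SBML file '", path,
                                           "': ", conditionMessage(e), call. = FALSE))
  xml2::xml_ns_strip(doc)
  model <- xml2::xml_find_first(doc, ".//model")
  if (inherits(model, "xml_missing")) stop("no <model> element in '", path, "'")

  ext_comp <- character(0)
  for (cp in xml2::xml_find_all(model, ".//listOfCompartments/compartment")) {
    cid <- xml2::xml_attr(cp, "id")
    cname <- xml2::xml_attr(cp, "name")
    if (grepl("^ext", cid, ignore.case = TRUE) ||
        (!is.na(cname) && grepl("^ext", cname, ignore.case = TRUE)))
      ext_comp <- c(ext_comp, cid)
  }

  sp_nodes <- xml2::xml_find_all(model, ".//listOfSpecies/species")
  if (length(sp_nodes) == 0L) stop("no species in '", path, "'")
  ids <- xml2::xml_attr(sp_nodes, "id")
  if (anyNA(ids) || any(!nzchar(ids))) stop("species with no id in '", path, "'")
  nms <- xml2::xml_attr(sp_nodes, "name")
  nms[is.na(nms)] <- ids[is.na(nms)]
  boundary <- tolower(xml2::xml_attr(sp_nodes, "boundaryCondition")) %in% "true"
  in_ext_comp <- xml2::xml_attr(sp_nodes, "compartment") %in% ext_comp
  role <- ifelse(boundary | in_ext_comp | ids %in% external_ids,
                 "external", "internal")
  compounds <- data.frame(id = ids, name = nms, role = role,
                          stringsAsFactors = FALSE)

  reactions <- list()
  for (rn in xml2::xml_find_all(model, ".//listOfReactions/reaction")) {
    rid <- xml2::xml_attr(rn, "id")
    if (is.na(rid) || !nzchar(rid)) stop("reaction with no id in '", path, "'")
    rev <- !tolower(xml2::xml_attr(rn, "reversible")) %in% "false"
    gene <- xml2::xml_attr(rn, "name")
    refs <- function(xpath, sign) {
      nodes <- xml2::xml_find_all(rn, xpath)
      if (length(nodes) == 0L) return(numeric(0))
      sp <- xml2::xml_attr(nodes, "species")
      st <- xml2::xml_attr(nodes, "stoichiometry")
      st <- ifelse(is.na(st), 1, as.numeric(st))
      stats::setNames(sign * st, sp)
    }
    sub <- refs("./listOfReactants/speciesReference", -1)
    prod <- refs("./listOfProducts/speciesReference", +1)
    stoich <- c(sub, prod)
    both <- intersect(names(sub), names(prod))
    if (length(both)) {
      net_c <- prod[both] + sub[both]
      stoich <- stoich[!names(stoich) %in% both]
      stoich <- c(stoich, net_c[net_c != 0])
    }
    reactions[[length(reactions) + 1L]] <-
      reaction(rid, stoich, reversible = rev,
               gene = if (is.na(gene) || !nzchar(gene)) NA_character_ else gene)
  }
  mname <- xml2::xml_attr(model, "name")
  if (is.na(mname)) mname <- xml2::xml_attr(model, "id")
  if (is.na(mname)) mname <- ""
  metabolic_network(reactions, compounds = compounds, name = mname)
}

#' Write a network to SBML Level 3 Version 1
#'
#' External compounds are written with `boundaryCondition="true"`; reaction
#' gene labels (when present) are stored in the reaction `name` attribute so
#' that the round trip is lossless for everything except rate bounds.
#'
#' @param net A `metabolic_network`.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_sbml <- function(net, path) {
  esc <- function(x) {
    x <- gsub("&", "&amp;", x, fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    x <- gsub(">", "&gt;", x, fixed = TRUE)
    gsub('"', "&quot;", x, fixed = TRUE)
  }
  num <- function(x) format(x, trim = TRUE, scientific = FALSE, digits = 15)
  lines <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core" level="3" version="1">',
    sprintf('  <model id="model" name="%s">', esc(net$name)),
    '    <listOfCompartments>',
    '      <compartment id="c1" constant="true"/>',
    '    </listOfCompartments>',
    '    <listOfSpecies>')
  for (i in seq_len(nrow(net$compounds))) {
    lines <- c(lines, sprintf(
      '      <species id="%s" name="%s" compartment="c1" boundaryCondition="%s" hasOnlySubstanceUnits="false" constant="false"/>',
      esc(net$compounds$id[i]), esc(net$compounds$name[i]),
      if (net$compounds$role[i] == "external") "true" else "false"))
  }
  lines <- c(lines, '    </listOfSpecies>', '    <listOfReactions>')
  for (r in net$reactions) {
    gene_attr <- if (!is.na(r$gene)) sprintf(' name="%s"', esc(r$gene)) else ""
    lines <- c(lines, sprintf('      <reaction id="%s"%s reversible="%s" fast="false">',
                              esc(r$id), gene_attr,
                              if (r$reversible) "true" else "false"))
    sub <- r$stoich[r$stoich < 0]
    prod <- r$stoich[r$stoich > 0]
    ref <- function(coefs) sprintf(
      '          <speciesReference species="%s" stoichiometry="%s" constant="true"/>',
      esc(names(coefs)), num(abs(unname(coefs))))
    if (length(sub))
      lines <- c(lines, '        <listOfReactants>', ref(sub), '        </listOfReactants>')
    if (length(prod))
      lines <- c(lines, '        <listOfProducts>', ref(prod), '        </listOfProducts>')
    lines <- c(lines, '      </reaction>')
  }
  lines <- c(lines, '    </listOfReactions>', '  </model>', '</sbml>')
  writeLines(lines, path)
  invisible(path)
}
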