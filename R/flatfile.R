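#' Parse the tab-delimited reaction/metabolite dialect
#'
#' Reads a network from two flat files of the kind distributed alongside
#' AraCyc-derived constraint models. Each reactions row is
#'
#' ```
#' <reaction id> <equation> | <default> <Par1> <Par2> <Par3> <x> <y> <map> <box>
#' ```
#'
#' where `<default>` is `#` when unknown and Par1/Par2 are the rate minimum
#' and maximum. Equations use `-->` (also `->`, `=>`) for irreversible and
#' `=` (also `<=>`, `<->`) for reversible reactions, with integer or decimal
#' coefficients, e.g. `CPD-A + 2 CPD-B --> CPD-C`. One side may be empty for
#' exchange reactions. Each metabolites row is `<identifier> <full name>`.
#' Pixel coordinates, map number and box type are read and ignored.
#'
#' Compound roles are assigned by [preliminary_classification()] unless
#' overridden via `external_ids`.
#'
#' @param reactions_text Character vector of lines, or path to a file.
#' @param metabolites_text Character vector of lines, or path to a file;
#'   `NULL` to declare compounds from the equations alone.
#' @param external_ids Optional character vector forcing these compounds to
#'   role `"external"` in addition to the preliminary classification.
#' @param name Network name.
#' @return A [metabolic_network()].
#' @examples
#' rx <- c("r1 A --> B | # 0 100 0 10 10 1 1",
#'         "r2 B --> C | # 0 100 0 20 10 1 1")
#' mets <- c("A compound A", "B compound B", "C compound C")
#' parse_flatfiles(rx, mets)
#' @export
parse_flatfiles <- function(reactions_text, metabolites_text = NULL,
                            external_ids = NULL, name = "") {
  rx_lines <- read_flat_lines(reactions_text)
  reactions <- list()
  for (i in seq_along(rx_lines)) {
    line <- rx_lines[[i]]
    r <- tryCatch(parse_reaction_row(line),
                  error = function(e) stop("reactions line ", i, ": ",
                                           conditionMessage(e), call. = FALSE))
    reactions[[length(reactions) + 1L]] <- r
  }
  compounds <- NULL
  if (!is.null(metabolites_text)) {
    met_lines <- read_flat_lines(metabolites_text)
    ids <- sub("[ \t].*$", "", met_lines)
    nms <- trimws(sub("^[^ \t]+", "", met_lines))
    nms[!nzchar(nms)] <- ids[!nzchar(nms)]
    compounds <- data.frame(id = ids, name = nms, role = NA_character_,
                            stringsAsFactors = FALSE)
    mentioned <- unique(unlist(lapply(reactions, function(r) names(r$stoich))))
    undeclared <- setdiff(mentioned, ids)
    if (length(undeclared))
      stop("reactions reference metabolites not declared in the metabolites file: ",
           paste(undeclared, collapse = ", "))
  }
  net <- metabolic_network(reactions, compounds = compounds, name = name)
  if (!is.null(external_ids)) {
    net$compounds$role[net$compounds$id %in% external_ids] <- "external"
  }
  net
}

read_flat_lines <- function(x) {
  if (length(x) == 1L && !grepl("\n", x) && file.exists(x))
    x <- readLines(x, warn = FALSE)
  else if (length(x) == 1L && grepl("\n", x))
    x <- strsplit(x, "\n", fixed = TRUE)[[1]]
  x <- trimws(x)
  x[nzchar(x) & !startsWith(x, "#")]
}

parse_reaction_row <- function(line) {
  parts <- strsplit(line, "|", fixed = TRUE)[[1]]
  if (length(parts) < 2L)
    stop("missing '|' separator between equation and parameters")
  head <- trimws(parts[1])
  params <- strsplit(trimws(paste(parts[-1], collapse = "|")), "[ \t]+")[[1]]
  id <- sub("[ \t].*$", "", head)
  eqn <- trimws(sub("^[^ \t]+", "", head))
  if (!nzchar(id) || !nzchar(eqn))
    stop("row must be '<reaction id> <equation> | <parameters>'")
  eq <- parse_equation(eqn)
  num_or_na <- function(tok) {
    if (is.na(tok) || tok == "#") return(NA_real_)
    v <- suppressWarnings(as.numeric(tok))
    if (is.na(v)) stop("unparseable numeric parameter '", tok, "'")
    v
  }
  default <- num_or_na(params[1])
  lb <- if (length(params) >= 2L) num_or_na(params[2]) else NA_real_
  ub <- if (length(params) >= 3L) num_or_na(params[3]) else NA_real_
  reaction(id, eq$stoich, reversible = eq$reversible,
           lb = lb, ub = ub, default = default)
}

parse_equation <- function(eqn) {
  arrows <- c("<=>" = TRUE, "<->" = TRUE, "↔" = TRUE,
              "-->" = FALSE, "=>" = FALSE, "->" = FALSE,
              "→" = FALSE, "=" = TRUE)
  toks <- strsplit(trimws(eqn), "[ \t]+")[[1]]
  at <- which(toks %in% names(arrows))
  if (length(at) == 0L)
    stop("no reaction arrow ('-->' or '=') in equation '", eqn, "'")
  if (length(at) > 1L) stop("more than one arrow in equation '", eqn, "'")
  arrow <- toks[at]
  lhs <- parse_side(paste(toks[seq_len(at - 1L)], collapse = " "))
  rhs <- parse_side(paste(toks[-seq_len(at)], collapse = " "))
  if (length(lhs) == 0L && length(rhs) == 0L)
    stop("empty equation")
  both <- intersect(names(lhs), names(rhs))
  stoich <- c(-lhs, rhs)
  if (length(both)) {        # same compound on both sides: net coefficient
    net <- rhs[both] - lhs[both]
    stoich <- stoich[!names(stoich) %in% both]
    stoich <- c(stoich, net[net != 0])
  }
  list(stoich = stoich, reversible = arrows[[arrow]])
}

parse_side <- function(side) {
  side <- trimws(side)
  if (!nzchar(side)) return(numeric(0))
  terms <- strsplit(side, "[ \t]*\\+[ \t]*")[[1]]
  out <- numeric(0)
  for (term in terms) {
    term <- trimws(term)
    if (!nzchar(term)) stop("empty term in equation side '", side, "'")
    toks <- strsplit(term, "[ \t]+")[[1]]
    coef <- suppressWarnings(as.numeric(toks[1]))
    if (!is.na(coef) && length(toks) >= 2L) {
      cmp <- paste(toks[-1], collapse = " ")
    } else {
      coef <- 1
      cmp <- term
    }
    if (grepl("[ \t]", cmp)) stop("unparseable term '", term, "'")
    out[cmp] <- (if (cmp %in% names(out)) out[[cmp]] else 0) + coef
  }
  out
}

#' Write a network back to the flat-file dialect
#'
#' Inverse of [parse_flatfiles()]; a parse/write/parse round trip preserves
#' reaction count, stoichiometry, reversibility and bounds.
#'
#' @param net A `metabolic_network`.
#' @param reactions_path,metabolites_path Output file paths, or `NULL` to
#'   return the lines instead of writing.
#' @return Invisibly, a list with `reactions` and `metabolites` line vectors.
#' @export
write_flatfiles <- function(net, reactions_path = NULL, metabolites_path = NULL) {
  fmt <- function(x) ifelse(is.na(x), "#", format(x, trim = TRUE, scientific = FALSE))
  rx <- vapply(net$reactions, function(r) {
    side <- function(coefs)
      paste(ifelse(abs(coefs) == 1, names(coefs),
                   paste(format(abs(coefs), trim = TRUE, scientific = FALSE),
                         names(coefs))), collapse = " + ")
    eq <- paste(side(r$stoich[r$stoich < 0]),
                if (r$reversible) "=" else "-->",
                side(r$stoich[r$stoich > 0]))
    sprintf("%s %s | %s %s %s 0 0 0 1 1", r$id, trimws(eq),
            fmt(r$default), fmt(r$lb), fmt(r$ub))
  }, character(1))
  mets <- paste(net$compounds$id, net$compounds$name)
  if (!is.null(reactions_path)) writeLines(rx, reactions_path)
  if (!is.null(metabolites_path)) writeLines(mets, metabolites_path)
  invisible(list(reactions = unname(rx), metabolites = mets))
}
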