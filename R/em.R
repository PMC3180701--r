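## Exact integer arithmetic helpers. All tableau arithmetic happens on
## doubles that hold integers (exact up to 2^53); every row is reduced by
## its gcd after each combination, which keeps entries small at the network
## sizes this package targets.

gcd2 <- function(a, b) {
  a <- abs(a); b <- abs(b)
  while (b > 0) { t <- a %% b; a <- b; b <- t }
  a
}

gcdv <- function(x) {
  g <- 0
  for (v in x[x != 0]) {
    g <- gcd2(g, v)
    if (g == 1) break
  }
  g
}

#' Scale stoichiometric columns to exact integers
#'
#' Each reaction column is multiplied by the least common multiple of the
#' denominators of its coefficients, recovered exactly from decimal input
#' with [MASS::fractions()]. Scaling a column by `l` rescales that
#' reaction's flux unit by `1/l`, so the per-column factors are returned in
#' the `"scale"` attribute and flux vectors computed against the scaled
#' matrix must be multiplied element-wise by them to return to the original
#' units.
#'
#' @param S Numeric stoichiometric matrix.
#' @return Integer-valued numeric matrix of the same shape, with attribute
#'   `"scale"` (numeric vector, one factor per column).
#' @keywords internal
integerize_columns <- function(S) {
  scale <- rep(1, ncol(S))
  if (ncol(S) > 0L && nrow(S) > 0L) {
    for (j in seq_len(ncol(S))) {
      col <- S[, j]
      nz <- col != 0
      if (!any(nz)) next
      fr <- attr(MASS::fractions(col[nz], max.denominator = 1e8), "fracs")
      den <- vapply(strsplit(fr, "/", fixed = TRUE), function(p)
        if (length(p) == 2L) as.numeric(p[2]) else 1, numeric(1))
      l <- 1
      for (d in den) l <- l / gcd2(l, d) * d
      S[, j] <- round(col * l)
      scale[j] <- l
    }
  }
  attr(S, "scale") <- scale
  S
}

#' Enumerate all elementary flux modes
#'
#' An elementary mode (EM) is a flux vector that satisfies steady state on
#' every internal compound and the irreversibility constraints, and whose
#' support (set of active reactions) is minimal: no other steady-state flux
#' uses a strict subset of its reactions. Every feasible steady-state flux
#' of the network is a nonnegative combination of EMs, which makes the EM
#' set a complete catalogue of the network's routes.
#'
#' The computation is the classical null-space tableau scheme: reversible
#' reactions are split into forward/backward columns, internal compounds are
#' eliminated one at a time by combining rows of opposite sign with a
#' support-minimality test after each elimination, and the split halves are
#' recombined at the end (the futile two-cycles created by splitting are
#' discarded). All arithmetic is exact integer arithmetic, so each returned
#' mode satisfies its balance equations exactly, not merely to a tolerance.
#'
#' @param net A `metabolic_network`.
#' @param max_rows Safety cap on the tableau size; exceeded only by networks
#'   far beyond the intended subnetwork scale.
#' @return An object of class `"em_set"`: list with `coef` (matrix, one row
#'   per reaction, one column per EM, coprime integer coefficients with the
#'   first nonzero coefficient positive), `class_label` (per-EM label, `NA`
#'   until [classify_ems()] is applied) and `network`.
#' @examples
#' net <- metabolic_network(list(
#'   reaction("upt", c(Aext = -1, A = 1)),
#'   reaction("r2", c(A = -1, B = 1)),
#'   reaction("out", c(B = -1, Bext = 1))),
#'   compounds = data.frame(id = c("Aext", "A", "B", "Bext"),
#'                          role = c("external", "internal", "internal", "external")))
#' enumerate_ems(net)   # exactly one mode through all three reactions
#' @export
enumerate_ems <- function(net, max_rows = 2e5) {
  stopifnot(inherits(net, "metabolic_network"))
  rxn_ids <- reaction_ids(net)
  n <- length(rxn_ids)
  if (n == 0L)
    return(new_em_set(matrix(0, 0, 0), net))
  rev_flags <- vapply(net$reactions, `[[`, logical(1), "reversible")
  S <- integerize_columns(stoich_matrix(net, internal_only = TRUE))

  # split reversible reactions into forward and backward columns
  split_orig <- c(seq_len(n), which(rev_flags))
  split_sign <- c(rep(1, n), rep(-1, sum(rev_flags)))
  k <- length(split_orig)
  Ssplit <- S[, split_orig, drop = FALSE] *
    rep(split_sign, each = nrow(S))

  m <- nrow(S)
  Tm <- cbind(t(Ssplit), diag(k))          # rows: split reactions
  met_cols <- seq_len(m)
  flux_cols <- m + seq_len(k)

  for (step in seq_len(m)) {
    # pick the unprocessed metabolite column generating fewest combinations
    active <- met_cols[colSums(Tm[, met_cols, drop = FALSE] != 0) > 0]
    if (length(active) == 0L) break
    cost <- vapply(active, function(j) {
      s <- sign(Tm[, j])
      sum(s > 0) * sum(s < 0)
    }, numeric(1))
    j <- active[which.min(cost)]
    keep <- Tm[Tm[, j] == 0, , drop = FALSE]
    pos <- which(Tm[, j] > 0)
    neg <- which(Tm[, j] < 0)
    if (length(pos) && length(neg)) {
      combos <- matrix(0, nrow = length(pos) * length(neg), ncol = ncol(Tm))
      idx <- 0L
      for (p in pos) for (q in neg) {
        idx <- idx + 1L
        row <- abs(Tm[q, j]) * Tm[p, ] + abs(Tm[p, j]) * Tm[q, ]
        g <- gcdv(row)
        if (g > 1) row <- row / g
        combos[idx, ] <- row
      }
      # support-minimality: a combination survives only if no other row of
      # the new tableau has a flux support contained in its own
      supp <- rbind(keep[, flux_cols, drop = FALSE] != 0,
                    combos[, flux_cols, drop = FALSE] != 0)
      nk <- nrow(keep)
      drop <- rep(FALSE, nrow(supp))
      if (nrow(supp) > 1L) {
        M <- (supp * 1) %*% t(!supp)   # M[a, b] = |supp_a \ supp_b|
        sizes <- rowSums(supp)
        for (i in (nk + 1L):nrow(supp)) {
          others <- which(M[, i] == 0)
          others <- others[others != i & sizes[others] < sizes[i]]
          if (length(others)) { drop[i] <- TRUE; next }
          dup <- which(M[, i] == 0 & M[i, ] == 0)
          dup <- dup[dup < i]
          if (length(dup)) drop[i] <- TRUE   # duplicate support: keep first
        }
      }
      Tm <- rbind(keep, combos[!drop[(nk + 1L):nrow(supp)], , drop = FALSE])
    } else {
      Tm <- keep
    }
    if (nrow(Tm) > max_rows)
      stop("tableau exceeded ", max_rows,
           " rows; network too large for exact EM enumeration")
    if (nrow(Tm) == 0L) break
  }

  if (nrow(Tm) == 0L) return(new_em_set(matrix(0, n, 0, dimnames = list(rxn_ids, NULL)), net))

  # map split fluxes back to the original reactions
  V <- matrix(0, nrow = n, ncol = nrow(Tm), dimnames = list(rxn_ids, NULL))
  for (c_i in seq_len(k))
    V[split_orig[c_i], ] <- V[split_orig[c_i], ] +
      split_sign[c_i] * Tm[, flux_cols[c_i]]

  keep_col <- colSums(V != 0) > 0       # drop futile split two-cycles
  V <- V[, keep_col, drop = FALSE]
  if (ncol(V)) {
    # exactness guarantee: integer residual must be identically zero
    if (any(S %*% V != 0)) stop("internal error: nonzero steady-state residual")
    # back to the original flux units (columns of S were scaled by `scale`)
    V <- V * attr(S, "scale")
    V <- apply(V, 2, canonical_mode, rev_flags = rev_flags)
    if (is.null(dim(V))) V <- matrix(V, nrow = n, dimnames = list(rxn_ids, NULL))
    V <- V[, !duplicated(t(V)), drop = FALSE]   # reversible modes found twice
    V <- V[, minimal_support_cols(V), drop = FALSE]
    V <- V[, order_mode_cols(V), drop = FALSE]
  }
  new_em_set(V, net)
}

canonical_mode <- function(v, rev_flags) {
  g <- gcdv(v)
  if (g > 1) v <- v / g
  supp <- which(v != 0)
  if (length(supp) && all(rev_flags[supp]) && v[supp[1]] < 0) v <- -v
  v
}

minimal_support_cols <- function(V) {
  if (ncol(V) <= 1L) return(rep(TRUE, ncol(V)))
  supp <- t(V != 0)
  M <- (supp * 1) %*% t(!supp)
  sizes <- rowSums(supp)
  keep <- rep(TRUE, ncol(V))
  for (i in seq_len(ncol(V))) {
    others <- which(M[, i] == 0)
    if (any(others != i & sizes[others] < sizes[i])) keep[i] <- FALSE
  }
  keep
}

order_mode_cols <- function(V) {
  key <- apply(V, 2, function(v) paste(sprintf("%+.0f", v), collapse = ","))
  order(colSums(V != 0), key)
}

new_em_set <- function(coef, net, class_label = NULL) {
  if (is.null(class_label)) class_label <- rep(NA_character_, ncol(coef))
  if (ncol(coef) > 0L) colnames(coef) <- paste0("EM", seq_len(ncol(coef)))
  structure(list(coef = coef, class_label = class_label, network = net),
            class = "em_set")
}

#' @export
print.em_set <- function(x, ...) {
  cat(sprintf("Set of %d elementary modes over %d reactions\n",
              n_modes(x), nrow(x$coef)))
  if (!all(is.na(x$class_label))) {
    cat("Class counts:\n")
    print(table(x$class_label, useNA = "no"))
  }
  invisible(x)
}

#' @rdname enumerate_ems
#' @param ems An `em_set`.
#' @export
n_modes <- function(ems) ncol(ems$coef)

#' EM supports
#'
#' @param ems An `em_set`.
#' @return List of character vectors: the reactions carrying nonzero flux in
#'   each mode.
#' @export
em_supports <- function(ems) {
  lapply(seq_len(n_modes(ems)), function(i)
    rownames(ems$coef)[ems$coef[, i] != 0])
}

#' Net external production of each mode
#'
#' @param ems An `em_set`.
#' @return Matrix (external compounds x modes) of net production rates per
#'   unit mode; positive entries are net products.
#' @export
em_external_production <- function(ems) {
  net <- ems$network
  ext <- external_compounds(net)
  S <- stoich_matrix(net, internal_only = FALSE)[ext, , drop = FALSE]
  S %*% ems$coef
}

#' Reaction participation counts
#'
#' The number of elementary modes each reaction takes part in — the
#' pleiotropy proxy used to rank pathway genes: early pathway reactions
#' typically appear in many modes, terminal ones in few.
#'
#' @param ems An `em_set`.
#' @return Named integer vector over all network reactions (0 for reactions
#'   in no mode).
#' @export
participation <- function(ems) {
  stats::setNames(as.integer(rowSums(ems$coef != 0)), rownames(ems$coef))
}

#' Product class map
#'
#' Assigns external product compounds to named product classes (e.g. the
#' flavonoid subclasses and non-flavonoid groups). A compound may belong to
#' at most one class; modes producing nothing, or only unmapped compounds,
#' fall into the `"others"` class.
#'
#' @param classes Named list: class name -> character vector of external
#'   compound ids.
#' @param priority Character vector ordering classes for the rare mode that
#'   produces compounds of several classes (first match wins); defaults to
#'   the order of `classes`.
#' @return An object of class `"product_class_map"`.
#' @export
product_class_map <- function(classes, priority = names(classes)) {
  stopifnot(is.list(classes), !is.null(names(classes)), all(nzchar(names(classes))))
  all_ids <- unlist(classes, use.names = FALSE)
  if (anyDuplicated(all_ids))
    stop("compound(s) assigned to more than one class: ",
         paste(unique(all_ids[duplicated(all_ids)]), collapse = ", "))
  stopifnot(setequal(priority, names(classes)))
  structure(list(classes = classes, priority = priority),
            class = "product_class_map")
}

#' Classify elementary modes by product class
#'
#' Each mode is labelled with the class of its net-produced external
#' compound(s). Modes with no net external production (futile cycles) and
#' modes producing only compounds outside the map are labelled `"others"`.
#' A mode producing compounds of several classes receives the
#' highest-priority class and is recorded in the `"ambiguous"` attribute.
#'
#' @param ems An `em_set`.
#' @param class_map A [product_class_map()].
#' @return The `em_set` with `class_label` filled in.
#' @export
classify_ems <- function(ems, class_map) {
  stopifnot(inherits(class_map, "product_class_map"))
  prod <- em_external_production(ems)
  comp2class <- character(0)
  for (cl in names(class_map$classes))
    comp2class[class_map$classes[[cl]]] <- cl
  labels <- character(n_modes(ems))
  ambiguous <- integer(0)
  for (i in seq_len(n_modes(ems))) {
    made <- rownames(prod)[prod[, i] > 0]
    cls <- unique(stats::na.omit(comp2class[made]))
    if (length(made) == 0L || length(cls) == 0L) {
      labels[i] <- "others"
    } else if (length(cls) == 1L) {
      labels[i] <- cls
    } else {
      labels[i] <- class_map$priority[min(match(cls, class_map$priority))]
      ambiguous <- c(ambiguous, i)
    }
  }
  if (length(ambiguous))
    warning("mode(s) producing compounds of several classes, labelled by priority: ",
            paste(colnames(ems$coef)[ambiguous], collapse = ", "))
  ems$class_label <- labels
  attr(ems, "ambiguous") <- ambiguous
  ems
}

#' Export / import an EM set as a tab-delimited matrix
#'
#' One row per reaction, one column per mode, integer coefficients;
#' `read_ems()` restores the matrix (network attachment is the caller's
#' job via the `net` argument).
#'
#' @param ems An `em_set`.
#' @param path File path.
#' @param net For `read_ems()`, the network the modes belong to.
#' @return `write_ems()` invisibly returns `path`; `read_ems()` an `em_set`.
#' @export
write_ems <- function(ems, path) {
  utils::write.table(ems$coef, path, sep = "\t", quote = FALSE,
                     row.names = TRUE, col.names = NA)
  invisible(path)
}

#' @rdname write_ems
#' @export
read_ems <- function(path, net) {
  M <- as.matrix(utils::read.table(path, sep = "\t", header = TRUE,
                                   row.names = 1, check.names = FALSE))
  stopifnot(setequal(rownames(M), reaction_ids(net)))
  new_em_set(M[reaction_ids(net), , drop = FALSE], net)
}
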