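# Independent oracles used to cross-check the package's algorithms.
# They share no code with the implementation: the EM oracle tests every
# support subset with a floating-point null-space computation, the cut-set
# oracle searches all candidate subsets, and both are only feasible for the
# tiny instances the property tests generate.

# Canonical integer vector from a floating-point generator
canon_int <- function(v, rev_flags) {
  v <- v / max(abs(v))      # component ratios are small rationals
  v[abs(v) < 1e-9] <- 0
  nz <- v != 0
  fr <- attr(MASS::fractions(v[nz], max.denominator = 1e6), "fracs")
  den <- vapply(strsplit(fr, "/", fixed = TRUE), function(p)
    if (length(p) == 2L) as.numeric(p[2]) else 1, numeric(1))
  l <- 1
  for (d in den) l <- l / fluxcut:::gcd2(l, d) * d
  w <- round(v * l)
  g <- fluxcut:::gcdv(w)
  if (g > 1) w <- w / g
  supp <- which(w != 0)
  if (length(supp) && all(rev_flags[supp]) && w[supp[1]] < 0) w <- -w
  w
}

# Brute-force elementary mode enumeration: a support set S yields an EM iff
# the null space of the stoichiometric submatrix on S is one-dimensional
# with a generator of full support on S that can be oriented to satisfy
# every irreversibility constraint.
brute_force_ems <- function(net) {
  S <- stoich_matrix(net, internal_only = TRUE)
  rxn <- reaction_ids(net)
  n <- length(rxn)
  rev_flags <- vapply(net$reactions, `[[`, logical(1), "reversible")
  if (nrow(S) == 0L) {   # no balance constraints: each reaction is a mode
    M <- diag(n)
    for (j in which(rev_flags)) M[j, j] <- 1  # orientation: first nz positive
    rownames(M) <- rxn
    return(M)
  }
  out <- list()
  for (code in seq_len(2^n - 1)) {
    supp <- which(bitwAnd(code, 2^(seq_len(n) - 1)) > 0)
    sub <- S[, supp, drop = FALSE]
    if (all(sub == 0)) {
      # unconstrained reactions: elementary iff alone
      if (length(supp) != 1L) next
      g <- 1
    } else {
      ns <- tryCatch(MASS::Null(t(sub)), error = function(e) NULL)
      if (is.null(ns) || NCOL(ns) != 1L) next
      g <- as.vector(ns)
    }
    if (any(abs(g) < 1e-9)) next  # not full support on supp
    irr <- !rev_flags[supp]
    if (any(irr)) {
      sgn <- sign(g[irr])
      if (length(unique(sgn)) > 1L) next
      if (sgn[1] < 0) g <- -g
    }
    v <- numeric(n)
    v[supp] <- g
    out[[length(out) + 1L]] <- canon_int(v, rev_flags)
  }
  out <- unique(out)
  do.call(cbind, c(out, list(matrix(0, n, 0))))
}

em_key_set <- function(M) {
  if (NCOL(M) == 0L) return(character(0))
  unname(sort(apply(M, 2, function(v) paste(v, collapse = ","))))
}

# Brute-force minimal hitting sets over <= 20 candidates
brute_force_hitting_sets <- function(supports, candidates) {
  n <- length(candidates)
  hits <- list()
  for (code in seq_len(2^n - 1)) {
    set <- candidates[bitwAnd(code, 2^(seq_len(n) - 1)) > 0]
    if (all(vapply(supports, function(s) length(intersect(s, set)) > 0,
                   logical(1))))
      hits[[length(hits) + 1L]] <- sort(set)
  }
  keep <- rep(TRUE, length(hits))
  sz <- lengths(hits)
  for (i in seq_along(hits)) for (j in seq_along(hits)) {
    if (i != j && keep[i] && sz[j] < sz[i] && all(hits[[j]] %in% hits[[i]]))
      keep[i] <- FALSE
  }
  hits <- hits[keep]
  hits[order(lengths(hits),
             vapply(hits, paste, character(1), collapse = "\r"))]
}

set_list_key <- function(sets)
  sort(vapply(lapply(sets, sort), paste, character(1), collapse = "|"))

# Random network whose brute-force enumeration stays tractable
random_small_network <- function(seed) {
  gen_random_network(n_reactions = 4L + (seed %% 9L),   # 4..12 reactions
                     n_compounds = 3L + (seed %% 5L),
                     p_external = 0.35, p_reversible = 0.3, seed = seed)
}
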