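#' Convert a tissue concentration to a rate
#'
#' Under the proportionality assumption used to seed the reference state,
#' reaction rates are taken proportional to measured product concentrations;
#' dividing a concentration in mg/kg by the molar mass in g/mol yields the
#' rate value in mmol/(kg h) (the unknown proportionality constant cancels
#' in all reported ratios).
#'
#' @param mg_per_kg Concentration(s), mg/kg, nonnegative.
#' @param molar_mass Molar mass(es), g/mol, positive.
#' @return Rate(s) in mmol/(kg h).
#' @examples
#' convert_concentration(28.9, 449.4)  # 0.0643
#' @export
convert_concentration <- function(mg_per_kg, molar_mass) {
  if (any(molar_mass <= 0)) stop("molar_mass must be positive")
  if (any(mg_per_kg < 0)) stop("mg_per_kg must be nonnegative")
  mg_per_kg / molar_mass
}

#' Lignin composition specification
#'
#' Monomer composition of the lignin macromolecule and its share of biomass
#' growth: by default 370 coniferyl : 238 sinapyl : 60 coumaryl alcohol,
#' a lignin biomass fraction of 0.15 and a growth rate of 0.18 per hour.
#'
#' @param coniferyl,sinapyl,coumaryl Positive monomer coefficients.
#' @param biomass_fraction Lignin fraction of total biomass, in (0, 1).
#' @param growth_rate_mu Growth rate, per hour.
#' @return An object of class `"lignin_spec"`.
#' @export
lignin_spec <- function(coniferyl = 370, sinapyl = 238, coumaryl = 60,
                        biomass_fraction = 0.15, growth_rate_mu = 0.18) {
  stopifnot(coniferyl > 0, sinapyl > 0, coumaryl > 0,
            biomass_fraction > 0, biomass_fraction < 1, growth_rate_mu > 0)
  structure(list(coniferyl = coniferyl, sinapyl = sinapyl, coumaryl = coumaryl,
                 biomass_fraction = biomass_fraction,
                 growth_rate_mu = growth_rate_mu),
            class = "lignin_spec")
}

#' Lignin contribution to growth
#'
#' The flux through lignin synthesis that accounts for the lignin share of
#' biomass growth: `biomass_fraction * growth_rate_mu` (0.15 x 0.18 = 0.027
#' per hour with the defaults). Also returns the lignin pseudo-reaction
#' consuming the monomers in the specified ratio.
#'
#' @param spec A [lignin_spec()].
#' @return List with `rate` (per hour) and `reaction` (the pseudo-reaction
#'   `370 CONIFERYL-ALCOHOL + 238 SINAPYL-ALCOHOL + 60 COUMARYL-ALCOHOL -->
#'   LIGNIN` with the spec's coefficients).
#' @export
lignin_growth_flux <- function(spec = lignin_spec()) {
  stopifnot(inherits(spec, "lignin_spec"))
  stoich <- c(-spec$coniferyl, -spec$sinapyl, -spec$coumaryl, 1)
  names(stoich) <- c("CONIFERYL-ALCOHOL", "SINAPYL-ALCOHOL",
                     "COUMARYL-ALCOHOL", "LIGNIN")
  list(rate = spec$biomass_fraction * spec$growth_rate_mu,
       reaction = reaction("LIGNIN-SYNTHESIS-RXN", stoich))
}

#' Flux constraint table
#'
#' @param reaction_id Character vector of reaction ids.
#' @param min,max Rate bounds, mmol/(kg h); equal for fixed values.
#' @param provenance `"fixed-value"` (a measured product rate), `"range"`
#'   (a literature interval) or `"fixed-input"` (an input flux held constant
#'   across knockout states).
#' @return Data frame of class `"flux_constraints"`.
#' @export
flux_constraints <- function(reaction_id, min, max, provenance = "range") {
  d <- data.frame(reaction_id = reaction_id, min = min, max = max,
                  provenance = provenance, stringsAsFactors = FALSE)
  stopifnot(all(d$provenance %in% c("fixed-value", "range", "fixed-input")))
  if (any(d$min > d$max)) stop("constraint with min > max: ",
                               paste(d$reaction_id[d$min > d$max], collapse = ", "))
  bad <- d$provenance == "fixed-value" & d$min != d$max
  if (any(bad)) stop("fixed-value constraints must have min == max: ",
                     paste(d$reaction_id[bad], collapse = ", "))
  class(d) <- c("flux_constraints", "data.frame")
  d
}

#' Read / write a constraint file
#'
#' Plain text, one constraint per line: `<reaction id> <min> <max>
#' [provenance]`, `#` comments. Mirrors the scenario-file style used by
#' constraint-based analysis tools.
#'
#' @param path File path.
#' @param constraints For writing, a [flux_constraints()] table.
#' @return `read_constraints()` returns a `flux_constraints` table.
#' @export
read_constraints <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  toks <- strsplit(lines, "[ \t]+")
  flux_constraints(
    reaction_id = vapply(toks, `[[`, character(1), 1),
    min = vapply(toks, function(t) as.numeric(t[2]), numeric(1)),
    max = vapply(toks, function(t) as.numeric(t[3]), numeric(1)),
    provenance = vapply(toks, function(t)
      if (length(t) >= 4L) t[4] else "range", character(1)))
}

#' @rdname read_constraints
#' @export
write_constraints <- function(constraints, path) {
  writeLines(sprintf("%s %.10g %.10g %s", constraints$reaction_id,
                     constraints$min, constraints$max, constraints$provenance),
             path)
  invisible(path)
}

## --- internal LP assembly ---------------------------------------------

## Split variables: one column per irreversible reaction, two (fwd, bwd)
## per reversible one; v = fwd - bwd, all split variables >= 0.
split_vars <- function(net) {
  rev_flags <- vapply(net$reactions, `[[`, logical(1), "reversible")
  n <- length(rev_flags)
  orig <- c(seq_len(n), which(rev_flags))
  sign <- c(rep(1, n), rep(-1, sum(rev_flags)))
  list(orig = orig, sign = sign, k = length(orig), n = n,
       ids = reaction_ids(net))
}

## row vector picking out v_r from the split variables
v_row <- function(sv, r_index) {
  row <- numeric(sv$k)
  sel <- sv$orig == r_index
  row[sel] <- sv$sign[sel]
  row
}

balance_rows <- function(net, sv) {
  S <- stoich_matrix(net, internal_only = TRUE)
  if (nrow(S) == 0L) return(matrix(0, 0, sv$k))
  S[, sv$orig, drop = FALSE] * rep(sv$sign, each = nrow(S))
}

## effective [lo, hi] bounds per reaction: network bounds overridden by the
## constraint table; irreversible reactions are >= 0 by construction
bound_list <- function(net, constraints) {
  ids <- reaction_ids(net)
  lo <- stats::setNames(vapply(net$reactions, `[[`, numeric(1), "lb"), ids)
  hi <- stats::setNames(vapply(net$reactions, `[[`, numeric(1), "ub"), ids)
  if (!is.null(constraints)) {
    unknown <- setdiff(constraints$reaction_id, ids)
    if (length(unknown))
      stop("constraints reference unknown reaction(s): ",
           paste(unknown, collapse = ", "))
    lo[constraints$reaction_id] <- constraints$min
    hi[constraints$reaction_id] <- constraints$max
  }
  list(lo = lo, hi = hi)
}

#' Solve the constrained reference flux state
#'
#' Finds a deterministic feasible steady state: internal compounds balance
#' exactly, every bound and constraint holds, and among all such states the
#' one with minimal total flux (L1 norm over reaction rates) found by a
#' deterministic simplex path is returned. Minimal total flux plus Bland's
#' pivoting rule pins down a unique, reproducible state, standing in for
#' the arbitrary feasible state a black-box tool would pick; downstream
#' reports only use ratios between states, which do not depend on the
#' absolute scale of this choice.
#'
#' @param net A `metabolic_network`.
#' @param constraints A [flux_constraints()] table (or `NULL`).
#' @param input_reactions Reactions whose rates are recorded as the fixed
#'   inputs for subsequent knockout states; default: every reaction
#'   consuming only external compounds (pure input exchanges).
#' @param tol Feasibility tolerance.
#' @return An object of class `"flux_state"`: `rates` (named vector),
#'   `kind = "reference"`, `residual_norm`, `inputs` (named vector of input
#'   rates), `constraints` (the table, for reuse by
#'   [simulate_cut_state()]).
#' @export
solve_reference_state <- function(net, constraints = NULL,
                                  input_reactions = NULL, tol = 1e-9) {
  sv <- split_vars(net)
  bl <- bound_list(net, constraints)
  B <- balance_rows(net, sv)
  A <- B; dir <- rep("=", nrow(B)); rhs <- rep(0, nrow(B))
  for (i in seq_along(bl$lo)) {
    if (!is.na(bl$lo[i])) {
      A <- rbind(A, v_row(sv, i)); dir <- c(dir, ">="); rhs <- c(rhs, bl$lo[i])
    }
    if (!is.na(bl$hi[i])) {
      A <- rbind(A, v_row(sv, i)); dir <- c(dir, "<="); rhs <- c(rhs, bl$hi[i])
    }
  }
  sol <- lp_solve(rep(1, sv$k), A, dir, rhs)
  if (sol$status != "optimal") {
    binding <- if (is.null(constraints)) "(none)" else
      paste(sprintf("%s in [%g, %g]", constraints$reaction_id,
                    constraints$min, constraints$max), collapse = "; ")
    stop("no feasible reference state (", sol$status,
         "); active constraints: ", binding)
  }
  rates <- collapse_split(sol$x, sv)
  if (is.null(input_reactions)) input_reactions <- input_reaction_ids(net)
  new_flux_state(rates, "reference", net,
                 inputs = rates[input_reactions], constraints = constraints)
}

collapse_split <- function(x, sv) {
  rates <- numeric(sv$n)
  for (c_i in seq_len(sv$k))
    rates[sv$orig[c_i]] <- rates[sv$orig[c_i]] + sv$sign[c_i] * x[c_i]
  stats::setNames(rates, sv$ids)
}

#' Input reactions of a network
#'
#' Reactions that consume external compounds only — the exchanges through
#' which material enters the subnetwork from the rest of metabolism.
#'
#' @param net A `metabolic_network`.
#' @return Character vector of reaction ids.
#' @export
input_reaction_ids <- function(net) {
  ext <- external_compounds(net)
  names(Filter(function(r) {
    subs <- names(r$stoich)[r$stoich < 0]
    length(subs) > 0 && all(subs %in% ext)
  }, net$reactions))
}

new_flux_state <- function(rates, kind, net, inputs = numeric(0),
                           constraints = NULL, relaxed = character(0)) {
  S <- stoich_matrix(net, internal_only = TRUE)
  resid <- if (nrow(S)) max(abs(S %*% rates)) else 0
  structure(list(rates = rates, kind = kind, residual_norm = resid,
                 inputs = inputs, constraints = constraints,
                 relaxed = relaxed),
            class = "flux_state")
}

#' @export
print.flux_state <- function(x, ...) {
  cat(sprintf("Flux state [%s]: %d reactions, |S v| = %.2e, total flux %.4g\n",
              x$kind, length(x$rates), x$residual_norm, sum(abs(x$rates))))
  if (length(x$relaxed))
    cat("  relaxed constraints:", paste(x$relaxed, collapse = ", "), "\n")
  invisible(x)
}

#' Simulate the flux state of a blocked (knockout) cut set
#'
#' Re-solves the network with the cut reactions constrained to exactly
#' zero, the input fluxes fixed at their reference values, and the
#' preliminary constraints re-imposed. When blocking the cut contradicts a
#' preliminary constraint (it usually does — a measured product rate cannot
#' persist once its route is severed), the preliminary constraints are
#' relaxed minimally: slack variables absorb the smallest total violation
#' (stage 1), and among the minimally relaxed states the minimal-total-flux
#' one is returned (stage 2). Cut zeros and fixed inputs are never relaxed.
#'
#' @param net A `metabolic_network`.
#' @param reference The [solve_reference_state()] result on the same network.
#' @param cutset Character vector of reaction ids, or a `"cutset_list"`
#'   element taken with `cut_index`.
#' @param cut_index When `cutset` is a `cutset_list`, which set to block.
#' @param fixed_inputs Optional [flux_constraints()] of provenance
#'   `"fixed-input"`; default: the reference state's recorded input rates.
#' @param tol Feasibility tolerance.
#' @return A `"flux_state"` with `kind = "blocked(...)"`; `relaxed` names
#'   the preliminary constraints that could not be maintained.
#' @export
simulate_cut_state <- function(net, reference, cutset, cut_index = NULL,
                               fixed_inputs = NULL, tol = 1e-9) {
  stopifnot(inherits(reference, "flux_state"))
  if (inherits(cutset, "cutset_list")) {
    stopifnot(!is.null(cut_index))
    cutset <- cutset$sets[[cut_index]]
    kind <- sprintf("blocked(MCS%d)", cut_index)
  } else {
    kind <- sprintf("blocked(%s)", paste(cutset, collapse = "+"))
  }
  missing <- setdiff(cutset, reaction_ids(net))
  if (length(missing)) stop("cut reaction(s) not in network: ",
                            paste(missing, collapse = ", "))
  sv <- split_vars(net)
  ids <- sv$ids
  B <- balance_rows(net, sv)

  if (is.null(fixed_inputs)) {
    fixed_inputs <- flux_constraints(names(reference$inputs),
                                     reference$inputs, reference$inputs,
                                     "fixed-input")
  }
  prelim <- reference$constraints
  if (!is.null(prelim)) prelim <- prelim[prelim$provenance != "fixed-input", ,
                                         drop = FALSE]

  # hard rows: balance, cut zeros, fixed inputs
  A <- B; dir <- rep("=", nrow(B)); rhs <- rep(0, nrow(B))
  for (r in cutset) {
    A <- rbind(A, v_row(sv, match(r, ids))); dir <- c(dir, "="); rhs <- c(rhs, 0)
  }
  for (i in seq_len(nrow(fixed_inputs))) {
    r <- fixed_inputs$reaction_id[i]
    if (r %in% cutset) next
    A <- rbind(A, v_row(sv, match(r, ids)))
    dir <- c(dir, "="); rhs <- c(rhs, fixed_inputs$min[i])
  }
  n_hard <- nrow(A)

  # soft rows: preliminary constraints with slack columns
  n_soft <- if (is.null(prelim)) 0L else nrow(prelim)
  soft_rows <- integer(0)
  n_slackvar <- 0L
  soft_info <- list()
  if (n_soft > 0L) {
    for (i in seq_len(n_soft)) {
      r <- prelim$reaction_id[i]
      ri <- match(r, ids)
      cut_here <- r %in% cutset
      lo <- prelim$min[i]; hi <- prelim$max[i]
      if (!cut_here || lo > 0) {
        # v >= lo - s_lo ; v <= hi + s_hi   (skip rows a cut makes moot)
        if (is.finite(lo) && !(cut_here && lo <= 0)) {
          n_slackvar <- n_slackvar + 1L
          soft_info[[length(soft_info) + 1L]] <-
            list(row = v_row(sv, ri), dir = ">=", rhs = lo, slack = n_slackvar,
                 slack_sign = +1, label = sprintf("%s >= %g", r, lo))
        }
        if (is.finite(hi) && !cut_here) {
          n_slackvar <- n_slackvar + 1L
          soft_info[[length(soft_info) + 1L]] <-
            list(row = v_row(sv, ri), dir = "<=", rhs = hi, slack = n_slackvar,
                 slack_sign = -1, label = sprintf("%s <= %g", r, hi))
        }
      }
    }
  }
  nvar <- sv$k + n_slackvar
  A2 <- cbind(A, matrix(0, nrow(A), n_slackvar))
  for (s in soft_info) {
    row <- c(s$row, numeric(n_slackvar))
    row[sv$k + s$slack] <- s$slack_sign
    A2 <- rbind(A2, row)
    dir <- c(dir, s$dir); rhs <- c(rhs, s$rhs)
  }

  # stage 1: minimal total relaxation
  obj1 <- c(numeric(sv$k), rep(1, n_slackvar))
  s1 <- lp_solve(obj1, A2, dir, rhs)
  if (s1$status != "optimal")
    stop("cut state infeasible even with preliminary constraints relaxed: {",
         paste(cutset, collapse = ", "), "}")
  # stage 2: minimal total flux among minimally relaxed states
  A3 <- rbind(A2, obj1)
  dir3 <- c(dir, "<="); rhs3 <- c(rhs, s1$value + 1e-8)
  obj2 <- c(rep(1, sv$k), numeric(n_slackvar))
  s2 <- lp_solve(obj2, A3, dir3, rhs3)
  if (s2$status != "optimal")
    stop("stage-2 solve failed for cut {", paste(cutset, collapse = ", "), "}")

  rates <- collapse_split(s2$x[seq_len(sv$k)], sv)
  rates[cutset] <- 0   # exact zeros on the cut
  slack_vals <- s2$x[sv$k + seq_len(n_slackvar)]
  relaxed <- vapply(soft_info, `[[`, character(1), "label")[
    vapply(soft_info, function(s) slack_vals[s$slack] > 1e-6, logical(1))]
  new_flux_state(rates, kind, net, inputs = reference$inputs,
                 constraints = reference$constraints, relaxed = relaxed)
}

#' Maximum achievable flux through a reaction
#'
#' Linear program maximizing one reaction's rate subject to steady state,
#' optional zeroed reactions and a uniform flux cap. Used to verify cut
#' sets: a valid cut drives the maximum objective flux to exactly zero.
#'
#' @param net A `metabolic_network`.
#' @param reaction_id Reaction whose flux is maximized.
#' @param zero_reactions Reactions constrained to zero (the cut).
#' @param cap Uniform bound on |v| keeping the LP bounded; default 1000.
#' @return The maximal rate (numeric scalar).
#' @export
max_flux <- function(net, reaction_id, zero_reactions = character(0),
                     cap = 1000) {
  sv <- split_vars(net)
  B <- balance_rows(net, sv)
  A <- B; dir <- rep("=", nrow(B)); rhs <- rep(0, nrow(B))
  for (r in zero_reactions) {
    A <- rbind(A, v_row(sv, match(r, sv$ids)))
    dir <- c(dir, "="); rhs <- c(rhs, 0)
  }
  A <- rbind(A, diag(sv$k))
  dir <- c(dir, rep("<=", sv$k)); rhs <- c(rhs, rep(cap, sv$k))
  obj <- v_row(sv, match(reaction_id, sv$ids))
  sol <- lp_solve(obj, A, dir, rhs, maximize = TRUE)
  if (sol$status != "optimal") stop("max_flux LP not optimal: ", sol$status)
  sol$value
}

#' Flux ratios and product-class averages
#'
#' Normalizes a blocked state against the reference: each reaction's ratio
#' is its blocked rate divided by its reference rate (undefined — `NA` —
#' where the reference rate is zero, and excluded from averages). The class
#' average is the arithmetic mean of the defined ratios of the class's end
#' reactions, i.e. the reactions directly producing the class's external
#' compounds.
#'
#' @param blocked,reference `"flux_state"`s on the same network.
#' @param class_map A [product_class_map()].
#' @param net The `metabolic_network` (defines end reactions).
#' @param tol Rates with |reference| below `tol` count as zero.
#' @return An object of class `"ratio_report"`: `per_reaction_ratio` (named
#'   vector with `NA` for undefined), `per_class_average` (named vector),
#'   `class_end_reactions` (list).
#' @export
ratio_report <- function(blocked, reference, class_map, net, tol = 1e-9) {
  stopifnot(inherits(blocked, "flux_state"), inherits(reference, "flux_state"),
            identical(names(blocked$rates), names(reference$rates)))
  ref <- reference$rates
  ratio <- ifelse(abs(ref) > tol, blocked$rates / ref, NA_real_)
  names(ratio) <- names(ref)
  ends <- class_end_reactions(net, class_map)
  avg <- vapply(ends, function(rs) {
    vals <- ratio[rs]
    vals <- vals[!is.na(vals)]
    if (length(vals)) mean(vals) else NA_real_
  }, numeric(1))
  structure(list(per_reaction_ratio = ratio, per_class_average = avg,
                 class_end_reactions = ends),
            class = "ratio_report")
}

#' @export
print.ratio_report <- function(x, ...) {
  cat("Per-class average flux ratios (blocked / reference):\n")
  print(round(x$per_class_average, 3))
  invisible(x)
}

#' End reactions of each product class
#'
#' @param net A `metabolic_network`.
#' @param class_map A [product_class_map()].
#' @return Named list: class -> reaction ids with positive stoichiometry on
#'   at least one of the class's external compounds.
#' @export
class_end_reactions <- function(net, class_map) {
  lapply(class_map$classes, function(cmp_ids) {
    names(Filter(function(r) {
      made <- names(r$stoich)[r$stoich > 0]
      length(intersect(made, cmp_ids)) > 0
    }, net$reactions))
  })
}
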