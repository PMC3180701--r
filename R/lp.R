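#' Solve a small linear program
#'
#' Dense two-phase primal simplex with Bland's anti-cycling rule, for the
#' small flux-balance programs this package builds (tens of variables).
#' Bland's rule makes the solver fully deterministic: identical inputs give
#' identical optimal bases, which is what lets a "reference flux state" be
#' reproducible.
#'
#' Solves `min (or max) obj' x` subject to `A x (dir) rhs`, `x >= 0`, with
#' `dir` entries `"<="`, `">="` or `"="`.
#'
#' @param obj Numeric objective vector (length n).
#' @param A Constraint matrix (m x n).
#' @param dir Character vector of constraint directions (length m).
#' @param rhs Numeric right-hand side (length m).
#' @param maximize Maximize instead of minimize?
#' @param tol Numerical tolerance for pivoting and feasibility (default 1e-9).
#' @return List with `status` (`"optimal"`, `"infeasible"` or
#'   `"unbounded"`), `x` (solution, length n) and `value`.
#' @export
lp_solve <- function(obj, A, dir, rhs, maximize = FALSE, tol = 1e-9) {
  A <- as.matrix(A)
  m <- nrow(A); n <- ncol(A)
  stopifnot(length(obj) == n, length(dir) == m, length(rhs) == m,
            all(dir %in% c("<=", ">=", "=")))
  if (maximize) obj <- -obj

  # normalize to rhs >= 0
  flip <- rhs < 0
  A[flip, ] <- -A[flip, , drop = FALSE]
  rhs[flip] <- -rhs[flip]
  dir[flip & dir == "<="] <- ">=tmp"
  dir[flip & dir == ">="] <- "<="
  dir[dir == ">=tmp"] <- ">="

  # slack / surplus columns
  n_slack <- sum(dir != "=")
  S <- matrix(0, m, n_slack)
  sj <- 0L
  slack_basic <- rep(NA_integer_, m)   # row -> column index usable as basis
  for (i in seq_len(m)) {
    if (dir[i] == "=") next
    sj <- sj + 1L
    S[i, sj] <- if (dir[i] == "<=") 1 else -1
    if (dir[i] == "<=") slack_basic[i] <- n + sj
  }
  # artificial columns where no slack can serve as the initial basis
  need_art <- is.na(slack_basic)
  n_art <- sum(need_art)
  Ar <- matrix(0, m, n_art)
  aj <- 0L
  for (i in which(need_art)) {
    aj <- aj + 1L
    Ar[i, aj] <- 1
    slack_basic[i] <- n + n_slack + aj
  }
  Tab <- cbind(A, S, Ar)
  ncols <- ncol(Tab)
  basis <- slack_basic
  b <- rhs

  pivot_to <- function(Tab, b, basis, enter, leave_row) {
    piv <- Tab[leave_row, enter]
    Tab[leave_row, ] <- Tab[leave_row, ] / piv
    b[leave_row] <- b[leave_row] / piv
    for (r in seq_len(nrow(Tab))) {
      if (r == leave_row) next
      f <- Tab[r, enter]
      if (f != 0) {
        Tab[r, ] <- Tab[r, ] - f * Tab[leave_row, ]
        b[r] <- b[r] - f * b[leave_row]
      }
    }
    basis[leave_row] <- enter
    list(Tab = Tab, b = b, basis = basis)
  }

  run_simplex <- function(Tab, b, basis, cost, allowed) {
    repeat {
      # reduced costs: c_j - c_B' B^-1 A_j (tableau is already B^-1 A)
      cb <- cost[basis]
      red <- cost - as.vector(cb %*% Tab)
      enter <- 0L
      for (j in allowed) {            # Bland: smallest eligible index
        if (red[j] < -tol) { enter <- j; break }
      }
      if (enter == 0L) return(list(Tab = Tab, b = b, basis = basis, status = "optimal"))
      col <- Tab[, enter]
      cand <- which(col > tol)
      if (length(cand) == 0L) return(list(Tab = Tab, b = b, basis = basis,
                                          status = "unbounded"))
      ratio <- b[cand] / col[cand]
      best <- min(ratio)
      ties <- cand[ratio <= best + tol]
      leave_row <- ties[which.min(basis[ties])]   # Bland on leaving variable
      res <- pivot_to(Tab, b, basis, enter, leave_row)
      Tab <- res$Tab; b <- res$b; basis <- res$basis
    }
  }

  # canonicalize initial tableau w.r.t. the starting basis
  for (i in seq_len(m)) {
    piv <- Tab[i, basis[i]]
    if (abs(piv - 1) > 0) { Tab[i, ] <- Tab[i, ] / piv; b[i] <- b[i] / piv }
  }

  if (n_art > 0L) {
    cost1 <- c(rep(0, n + n_slack), rep(1, n_art))
    res <- run_simplex(Tab, b, basis, cost1, allowed = seq_len(ncols))
    if (res$status != "optimal")
      return(list(status = "infeasible", x = rep(NA_real_, n), value = NA_real_))
    Tab <- res$Tab; b <- res$b; basis <- res$basis
    phase1 <- sum(cost1[basis] * b)
    if (phase1 > 1e3 * tol)
      return(list(status = "infeasible", x = rep(NA_real_, n), value = NA_real_))
    # drive remaining artificials out of the basis where possible
    art_cols <- n + n_slack + seq_len(n_art)
    for (i in which(basis %in% art_cols)) {
      sub <- Tab[i, seq_len(n + n_slack)]
      j <- which(abs(sub) > tol)
      if (length(j)) {
        res <- pivot_to(Tab, b, basis, j[1], i)
        Tab <- res$Tab; b <- res$b; basis <- res$basis
      }
      # else: redundant row; harmless to leave the artificial at zero
    }
  }

  cost2 <- c(obj, rep(0, n_slack), rep(0, max(0L, ncols - n - n_slack)))
  allowed <- seq_len(n + n_slack)     # artificials stay out in phase 2
  res <- run_simplex(Tab, b, basis, cost2, allowed)
  if (res$status == "unbounded")
    return(list(status = "unbounded", x = rep(NA_real_, n), value = NA_real_))
  x <- rep(0, ncols)
  x[res$basis] <- res$b
  value <- sum(obj * x[seq_len(n)])
  list(status = "optimal", x = x[seq_len(n)],
       value = if (maximize) -value else value)
}
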