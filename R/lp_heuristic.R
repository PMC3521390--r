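# LP-relaxation heuristic.
#
# The remaining distance from a node t to the goal G is bounded below by
# the optimum of the operator-count program
#     minimize sum_k w_k  subject to  G - t = sum_k w_k O_k,  w_k >= 0,
# the continuous relaxation of the integer program in which w_k counts how
# often rule k is applied. The relaxation ignores rule ordering and the
# applicability gates, so its optimum never exceeds the true path length:
# an admissible (and consistent) A* heuristic computable in polynomial time.
#
# The solver is a dense two-phase primal simplex written for this problem
# class: small integer equality systems whose rows are heavily linearly
# dependent (the constraint matrix has one row per vocabulary label but
# rank at most the number of rules). Bland's rule guarantees termination
# under the resulting degeneracy; redundant rows are dropped after phase 1.

# One simplex phase on a maintained tableau. `tab` is m x (N+1) (rhs last),
# `basis` length m, `cost` length N; only `allowed` columns may enter.
# Bland's pivoting rule throughout (smallest entering index, smallest
# basis-index leaving among ratio ties): finite termination even under
# degeneracy. Returns list(tab, basis, status).
.simplex_run <- function(tab, basis, cost, allowed, tol = 1e-9,
                         max_iter = 20000L) {
  m <- nrow(tab)
  rhs <- ncol(tab)
  for (iter in seq_len(max_iter)) {
    cb <- cost[basis]
    red <- cost[allowed] -
      as.vector(crossprod(tab[, allowed, drop = FALSE], cb))
    ent <- which(red < -tol)
    if (length(ent) == 0) {
      return(list(tab = tab, basis = basis, status = "optimal"))
    }
    j <- allowed[ent[1]]
    col <- tab[, j]
    pos <- which(col > tol)
    if (length(pos) == 0) {
      return(list(tab = tab, basis = basis, status = "unbounded"))
    }
    ratios <- tab[pos, rhs] / col[pos]
    rmin <- min(ratios)
    cand <- pos[ratios <= rmin + tol]
    r <- cand[which.min(basis[cand])]
    piv <- tab[r, ] / tab[r, j]
    tab <- tab - outer(tab[, j], piv)
    tab[r, ] <- piv
    basis[r] <- j
  }
  list(tab = tab, basis = basis, status = "maxiter")
}

# min 1'w s.t. A w = b, w >= 0, with b >= 0 (caller negates rows).
# Returns list(feasible, objective, weights) or errors on solver failure.
.lp_solve_eq <- function(A, b, tol = 1e-9) {
  m <- nrow(A)
  n <- ncol(A)
  tab <- cbind(A, diag(m), b, deparse.level = 0)
  basis <- n + seq_len(m)

  # phase 1: minimize the artificial total
  p1 <- .simplex_run(tab, basis, cost = c(rep(0, n), rep(1, m)),
                     allowed = seq_len(n), tol = tol)
  if (p1$status == "maxiter") {
    stop("LP solver failed to converge (iteration limit); not an infeasibility")
  }
  art_total <- sum(p1$tab[p1$basis > n, n + m + 1])
  if (art_total > 1e-7 * max(1, sum(b))) {
    return(list(feasible = FALSE, objective = NA_real_, weights = NULL))
  }
  tab <- p1$tab
  basis <- p1$basis

  # pivot remaining zero-level artificials out; a row with no eligible
  # pivot in the original columns is redundant and is dropped
  drop_rows <- integer(0)
  for (r in which(basis > n)) {
    j <- which(abs(tab[r, seq_len(n)]) > tol)
    if (length(j) == 0) {
      drop_rows <- c(drop_rows, r)
    } else {
      j <- j[1]
      piv <- tab[r, ] / tab[r, j]
      tab <- tab - outer(tab[, j], piv)
      tab[r, ] <- piv
      basis[r] <- j
    }
  }
  if (length(drop_rows) > 0) {
    tab <- tab[-drop_rows, , drop = FALSE]
    basis <- basis[-drop_rows]
  }

  # phase 2 on the original columns only
  p2 <- .simplex_run(tab, basis, cost = c(rep(1, n), rep(0, m)),
                     allowed = seq_len(n), tol = tol)
  if (p2$status != "optimal") {
    # the objective is bounded below by 0, so "unbounded" cannot occur
    stop("LP solver failed to converge (iteration limit); not an infeasibility")
  }
  rhs <- ncol(p2$tab)
  w <- numeric(n)
  keep <- p2$basis <= n
  w[p2$basis[keep]] <- p2$tab[keep, rhs]
  w[w < 0 & w > -1e-9] <- 0
  list(feasible = TRUE, objective = max(0, sum(w)), weights = w)
}

#' Solve the continuous relaxation of the operator-count program
#'
#' Minimizes `sum(w)` subject to `operators %*% w == delta`, `w >= 0`.
#' Rows where no operator has support are resolved directly: a nonzero
#' `delta` there proves infeasibility. A solver that stops on its
#' iteration limit raises an error distinct from infeasibility.
#'
#' @param delta Integer (or numeric) target vector `G - t`.
#' @param operators Numeric matrix, one column per operator vector; row
#'   dimension must match `delta`.
#' @return List with `feasible` (logical), `objective` (non-negative
#'   number; `NA` when infeasible) and `weights`.
#' @export
solve_relaxation <- function(delta, operators) {
  operators <- as.matrix(operators)
  if (ncol(operators) == 0) stop("operators matrix has no columns")
  if (nrow(operators) != length(delta)) {
    stop("dimension mismatch between delta and operators")
  }
  delta <- as.numeric(delta)
  m <- ncol(operators)

  live <- rowSums(operators != 0) > 0
  if (any(delta[!live] != 0)) {
    return(list(feasible = FALSE, objective = NA_real_, weights = NULL))
  }
  A <- operators[live, , drop = FALSE]
  b <- delta[live]
  if (nrow(A) == 0 || all(b == 0)) {
    return(list(feasible = TRUE, objective = 0, weights = numeric(m)))
  }
  neg <- b < 0
  A[neg, ] <- -A[neg, , drop = FALSE]
  b[neg] <- -b[neg]
  .lp_solve_eq(A, b)
}

#' LP goal-distance heuristic for one node
#'
#' Evaluates the LP relaxation of the operator-count program for
#' `delta = G - t`. When feasible the objective is by default tightened to
#' `ceiling(objective - tol)` — true distances are integers, so the ceiling
#' remains admissible and consistent while pruning harder; `ceiling = FALSE`
#' returns the raw LP value. An infeasible relaxation proves the goal is
#' unreachable from `t` and returns `Inf` (the node is pruned).
#'
#' @param t,goal `compound_vector`s on the rule set's vocabulary.
#' @param rs A `rule_set`.
#' @param cache Optional environment mapping state keys to values; reuse it
#'   across calls within one search, clear it between searches.
#' @param ceiling Apply integer tightening (default `TRUE`).
#' @param tol Tolerance subtracted before the ceiling (default `1e-6`).
#' @return Non-negative number, possibly `Inf`.
#' @export
lp_h <- function(t, goal, rs, cache = NULL, ceiling = TRUE, tol = 1e-6) {
  stopifnot(inherits(rs, "rule_set"))
  .check_same_vocab(t, goal)
  key <- NULL
  if (!is.null(cache)) {
    key <- paste(as.integer(t), collapse = " ")
    if (exists(key, envir = cache, inherits = FALSE)) {
      return(get(key, envir = cache, inherits = FALSE))
    }
  }
  delta <- as.integer(goal) - as.integer(t)
  if (all(delta == 0L)) {
    h <- 0
  } else {
    sol <- solve_relaxation(delta, rs$O_mat)
    if (!sol$feasible) {
      h <- Inf
    } else {
      h <- if (ceiling) max(0, ceiling(sol$objective - tol)) else sol$objective
    }
  }
  if (!is.null(cache)) assign(key, h, envir = cache)
  h
}

# Internal: closure evaluating the LP heuristic toward a fixed goal,
# with a per-search cache.
.make_lp_heuristic <- function(goal, rs, ceiling = TRUE, tol = 1e-6) {
  cache <- new.env(hash = TRUE, parent = emptyenv())
  goal_i <- as.integer(goal)
  function(t) {
    key <- paste(t, collapse = " ")
    if (exists(key, envir = cache, inherits = FALSE)) {
      return(get(key, envir = cache, inherits = FALSE))
    }
    delta <- goal_i - t
    if (all(delta == 0L)) {
      h <- 0
    } else {
      sol <- solve_relaxation(delta, rs$O_mat)
      h <- if (!sol$feasible) Inf
           else if (ceiling) max(0, ceiling(sol$objective - tol))
           else sol$objective
    }
    assign(key, h, envir = cache)
    h
  }
}
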