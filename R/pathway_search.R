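# Shortest pathway search in compound-vector space.
#
# Nodes are non-negative integer compound vectors; an edge is the
# application of a reaction rule R = (U, O): allowed when the current
# vector dominates the substrate gate (t >= U entrywise) and the result
# stays non-negative (t + O >= 0), in which case the successor is t + O.
# Distance is the number of rule applications. A* with an admissible
# heuristic returns minimum-length rule sequences; the zero heuristic is
# breadth-first search.

#' Can a rule be applied to a compound vector?
#'
#' True iff the substrate-inclusion condition `t >= U` and the
#' non-negativity condition `t + O >= 0` both hold entrywise.
#'
#' @param rule A `reaction_rule`.
#' @param t A `compound_vector` on the same vocabulary.
#' @return Logical scalar.
#' @export
is_applicable <- function(rule, t) {
  stopifnot(inherits(rule, "reaction_rule"))
  if (length(t) != length(rule$U)) stop("vocabulary mismatch")
  ti <- as.integer(t)
  all(ti >= rule$U) && all(ti + rule$O >= 0L)
}

#' Apply a reaction rule to a compound vector
#'
#' Returns `t + O`. Errors (never clamps) if the rule is not applicable.
#'
#' @inheritParams is_applicable
#' @return A `compound_vector`.
#' @export
apply_rule <- function(t, rule) {
  if (!is_applicable(rule, t)) {
    stop("rule ", rule$rule_id, " is not applicable to this compound vector")
  }
  structure(as.integer(t) + rule$O, class = "compound_vector",
            vocab_sig = attr(t, "vocab_sig"), id = NA_character_)
}

# Internal: indices of applicable rules for a bare integer state.
.applicable_idx <- function(ti, rs) {
  ok_u <- colSums(rs$U_mat > ti) == 0L
  ok_n <- colSums(rs$O_mat < -ti) == 0L
  unname(which(ok_u & ok_n))
}

#' Successor states of a compound vector under a rule set
#'
#' One entry per applicable rule, in rule-set order; the length of the
#' list is the node's branching count.
#'
#' @param t A `compound_vector`.
#' @param rs A `rule_set`.
#' @return List of `list(rule_id, state)` pairs.
#' @export
successors <- function(t, rs) {
  stopifnot(inherits(rs, "rule_set"))
  ti <- as.integer(t)
  if (length(ti) != nrow(rs$O_mat)) stop("vocabulary mismatch")
  idx <- .applicable_idx(ti, rs)
  lapply(idx, function(k) {
    list(rule_id = rs$rules[[k]]$rule_id,
         state = .as_compound_vector(ti + rs$O_mat[, k], rs$vocab))
  })
}

#' Normalized Manhattan goal-distance heuristic
#'
#' `sum(abs(t - G)) / max_norm`. Dividing the Manhattan distance by the
#' largest operator 1-norm makes it admissible: one rule application moves
#' the vector by at most `max_norm` in 1-norm.
#'
#' @param t,G `compound_vector`s on the same vocabulary.
#' @param max_norm Positive integer, see [max_operator_norm()].
#' @return Non-negative number.
#' @export
mh_heuristic <- function(t, G, max_norm) {
  if (length(t) != length(G)) stop("vocabulary mismatch")
  if (!is.numeric(max_norm) || length(max_norm) != 1 || max_norm < 1) {
    stop("max_norm must be a positive integer (>= 1)")
  }
  sum(abs(as.integer(t) - as.integer(G))) / max_norm
}

#' Replay a rule sequence from a start vector
#'
#' Applies the rules in order, checking both constraint conditions at each
#' step; errors on the first violation.
#'
#' @param start A `compound_vector`.
#' @param rule_ids Character vector of rule ids (possibly empty).
#' @param rs A `rule_set`.
#' @return The final `compound_vector`.
#' @export
replay_path <- function(start, rule_ids, rs) {
  stopifnot(inherits(rs, "rule_set"))
  ids <- vapply(rs$rules, `[[`, "", "rule_id")
  t <- start
  for (rid in rule_ids) {
    k <- match(rid, ids)
    if (is.na(k)) stop("unknown rule id: ", rid)
    t <- apply_rule(t, rs$rules[[k]])
  }
  t
}

# Internal: resolve a heuristic spec to an evaluator function over bare
# integer states.
.make_heuristic <- function(heuristic, goal, rs, lp_options) {
  if (is.function(heuristic)) return(heuristic)
  kind <- match.arg(heuristic, c("lp", "mh", "bf"))
  goal_i <- as.integer(goal)
  switch(kind,
    bf = function(t) 0,
    mh = {
      mn <- rs$max_norm
      function(t) sum(abs(t - goal_i)) / mn
    },
    lp = do.call(.make_lp_heuristic,
                 c(list(goal = goal, rs = rs), lp_options)))
}

#' A* shortest pathway search between two compound vectors
#'
#' Best-first search over the integer-vector space induced by a rule set,
#' guided by `f(t) = p(t) + h'(t)` where `p` is the path length from the
#' start and `h'` an admissible estimate of the remaining distance. With
#' the `"bf"` (zero) heuristic this is breadth-first search. The goal test
#' is exact vector equality, performed when a node is popped. Ties in `f`
#' are broken by smaller `h'`, then by insertion order, so results are
#' deterministic.
#'
#' Duplicate states are handled by a best-cost map keyed on the state
#' vector; a successor is enqueued only when it improves the known cost.
#' Reopening of closed nodes is supported for user-supplied heuristics and
#' counted in the diagnostics (it never triggers for the built-in
#' consistent heuristics).
#'
#' With `enumerate_all = TRUE` the search continues until every frontier
#' `f` exceeds the optimal distance and returns every distinct optimal
#' rule-id sequence (up to `max_paths`), collected via a predecessor DAG.
#'
#' @param start,goal `compound_vector`s on the rule set's vocabulary.
#' @param rs A `rule_set`.
#' @param heuristic `"lp"`, `"mh"`, `"bf"`, or a function mapping a bare
#'   integer state vector to a non-negative number.
#' @param enumerate_all Collect all optimal rule sequences.
#' @param max_expansions Stop (status `"limit-exceeded"`) after this many
#'   node expansions.
#' @param max_depth Nodes at this path length are not expanded; an
#'   exhausted frontier after such pruning also reports
#'   `"limit-exceeded"` rather than `"unreachable"`.
#' @param max_paths Cap on enumerated optimal sequences.
#' @param lp_options Options passed to the LP heuristic
#'   (`ceiling`, `tol`).
#' @param record_expanded Keep the expanded state vectors (with their `g`
#'   and `h'`) in the diagnostics.
#'
#' @return Object of class `search_result`: list with `status` (`"found"`,
#'   `"unreachable"`, `"limit-exceeded"`), `distance`, `paths` (list of
#'   character vectors of rule ids), and `diagnostics` (`expansions`,
#'   `branchings`, `heuristic_calls`, `frontier_max`, `reopenings`, and
#'   optionally `expanded`).
#' @export
astar <- function(start, goal, rs, heuristic = c("lp", "mh", "bf"),
                  enumerate_all = FALSE, max_expansions = 1e6,
                  max_depth = 20L, max_paths = 100L,
                  lp_options = list(), record_expanded = FALSE) {
  stopifnot(inherits(rs, "rule_set"))
  .check_same_vocab(start, goal)
  ndim <- nrow(rs$O_mat)
  if (length(start) != ndim || length(goal) != ndim) {
    stop("start/goal vectors do not match the rule set's vocabulary")
  }
  start_i <- as.integer(start)
  goal_i <- as.integer(goal)
  if (any(start_i < 0L) || any(goal_i < 0L)) {
    stop("compound vectors must be non-negative")
  }
  hfun <- .make_heuristic(heuristic, goal, rs, lp_options)

  key_of <- function(ti) paste(ti, collapse = " ")
  start_key <- key_of(start_i)
  goal_key <- key_of(goal_i)

  best_g <- new.env(hash = TRUE, parent = emptyenv())
  closed <- new.env(hash = TRUE, parent = emptyenv())
  preds <- new.env(hash = TRUE, parent = emptyenv())
  states <- new.env(hash = TRUE, parent = emptyenv())

  # growable frontier arrays with lazy deletion
  cap <- 256L
  q_key <- character(cap); q_g <- integer(cap)
  q_h <- numeric(cap); q_f <- numeric(cap)
  q_live <- logical(cap)
  q_n <- 0L
  push <- function(key, g, h) {
    if (q_n == cap) {
      cap <<- cap * 2L
      length(q_key) <<- cap; length(q_g) <<- cap
      length(q_h) <<- cap; length(q_f) <<- cap
      q_live <<- c(q_live, logical(cap %/% 2L))
    }
    q_n <<- q_n + 1L
    q_key[q_n] <<- key; q_g[q_n] <<- g
    q_h[q_n] <<- h; q_f[q_n] <<- g + h
    q_live[q_n] <<- TRUE
  }

  diag <- list(expansions = 0L, branchings = 0L, heuristic_calls = 0L,
               frontier_max = 0L, reopenings = 0L)
  expanded <- list()
  depth_pruned <- FALSE
  limit_hit <- FALSE
  d_star <- NA_integer_
  eps <- 1e-9

  diag$heuristic_calls <- diag$heuristic_calls + 1L
  h0 <- hfun(start_i)
  assign(start_key, 0L, envir = best_g)
  assign(start_key, start_i, envir = states)
  if (is.finite(h0)) push(start_key, 0L, h0)

  repeat {
    live <- which(q_live[seq_len(q_n)])
    diag$frontier_max <- max(diag$frontier_max, length(live))
    if (length(live) == 0) break
    fmin <- min(q_f[live])
    sel <- live[q_f[live] <= fmin + eps]
    if (length(sel) > 1) {
      hmin <- min(q_h[sel])
      sel <- sel[q_h[sel] <= hmin + eps]
    }
    i <- sel[1]
    q_live[i] <- FALSE
    key <- q_key[i]; g <- q_g[i]; f <- q_f[i]

    if (g > get(key, envir = best_g, inherits = FALSE)) next  # stale entry
    if (exists(key, envir = closed, inherits = FALSE) &&
        get(key, envir = closed, inherits = FALSE) <= g) next

    if (!is.na(d_star) && f > d_star + eps) break  # optimal tier exhausted

    if (key == goal_key) {
      if (is.na(d_star)) d_star <- g
      if (!enumerate_all) break
      next  # optimal paths never pass through the goal twice
    }
    if (g >= max_depth) {
      depth_pruned <- TRUE
      next
    }

    assign(key, g, envir = closed)
    diag$expansions <- diag$expansions + 1L
    ti <- get(key, envir = states, inherits = FALSE)
    if (record_expanded) {
      expanded[[length(expanded) + 1L]] <- list(state = ti, g = g, h = q_h[i])
    }

    idx <- .applicable_idx(ti, rs)
    diag$branchings <- diag$branchings + length(idx)
    for (k in idx) {
      t2 <- ti + rs$O_mat[, k]
      k2 <- key_of(t2)
      g2 <- g + 1L
      old <- if (exists(k2, envir = best_g, inherits = FALSE)) {
        get(k2, envir = best_g, inherits = FALSE)
      } else .Machine$integer.max
      rid <- rs$rules[[k]]$rule_id
      if (g2 < old) {
        assign(k2, g2, envir = best_g)
        assign(k2, t2, envir = states)
        assign(k2, list(list(pred = key, rule_id = rid, g_pred = g)),
               envir = preds)
        if (exists(k2, envir = closed, inherits = FALSE)) {
          diag$reopenings <- diag$reopenings + 1L
          rm(list = k2, envir = closed)
        }
        diag$heuristic_calls <- diag$heuristic_calls + 1L
        h2 <- hfun(t2)
        if (is.finite(h2)) push(k2, g2, h2)
      } else if (g2 == old) {
        pl <- get(k2, envir = preds, inherits = FALSE)
        dup <- any(vapply(pl, function(p) {
          p$pred == key && p$rule_id == rid
        }, logical(1)))
        if (!dup) {
          pl[[length(pl) + 1L]] <- list(pred = key, rule_id = rid, g_pred = g)
          assign(k2, pl, envir = preds)
        }
      }
    }
    if (diag$expansions >= max_expansions) {
      limit_hit <- TRUE
      break
    }
  }

  if (record_expanded) diag$expanded <- expanded

  if (is.na(d_star)) {
    status <- if (limit_hit || depth_pruned) "limit-exceeded" else "unreachable"
    return(structure(list(status = status, distance = NA_integer_,
                          paths = list(), diagnostics = diag),
                     class = "search_result"))
  }

  # backtrack all optimal sequences over the predecessor DAG
  paths <- if (d_star == 0L) {
    list(character(0))
  } else {
    memo <- new.env(hash = TRUE, parent = emptyenv())
    backtrack <- function(key) {
      if (key == start_key &&
          get(key, envir = best_g, inherits = FALSE) == 0L) {
        return(list(character(0)))
      }
      if (exists(key, envir = memo, inherits = FALSE)) {
        return(get(key, envir = memo, inherits = FALSE))
      }
      out <- list()
      gk <- get(key, envir = best_g, inherits = FALSE)
      for (p in get(key, envir = preds, inherits = FALSE)) {
        if (p$g_pred + 1L != gk) next
        if (p$g_pred != get(p$pred, envir = best_g, inherits = FALSE)) next
        for (s in backtrack(p$pred)) {
          out[[length(out) + 1L]] <- c(s, p$rule_id)
          if (length(out) >= max_paths) break
        }
        if (length(out) >= max_paths) break
      }
      assign(key, out, envir = memo)
      out
    }
    backtrack(goal_key)
  }
  if (!enumerate_all && length(paths) > 1) paths <- paths[1]
  paths <- paths[order(vapply(paths, paste, "", collapse = "\r"),
                       method = "radix")]
  paths <- unique(paths)

  structure(list(status = "found", distance = as.integer(d_star),
                 paths = paths, diagnostics = diag),
            class = "search_result")
}

#' Breadth-first shortest pathway search
#'
#' [astar()] with the zero heuristic: the exhaustive reference search.
#' Identical contract and return type.
#'
#' @inheritParams astar
#' @param ... Passed on to [astar()].
#' @return A `search_result`.
#' @export
bfs <- function(start, goal, rs, ...) {
  astar(start, goal, rs, heuristic = "bf", ...)
}

#' @export
print.search_result <- function(x, ...) {
  cat(sprintf("<search_result: %s", x$status))
  if (x$status == "found") {
    cat(sprintf(", distance %d, %d optimal path(s)", x$distance,
                length(x$paths)))
  }
  cat(sprintf(">\n  expansions %d, branchings %d, heuristic calls %d, max frontier %d\n",
              x$diagnostics$expansions, x$diagnostics$branchings,
              x$diagnostics$heuristic_calls, x$diagnostics$frontier_max))
  invisible(x)
}
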