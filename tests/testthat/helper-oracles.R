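# Independent oracles used to cross-check the implementation. They share
# no code path with the package internals: path counting goes through
# igraph's simple-path enumeration, shortest routes through a plain
# depth-bounded DFS on raw matrices, and the operator-count IP through
# bounded exhaustive enumeration.

# Path-count oracle: enumerate all directed simple paths with igraph and
# halve the depth >= 1 counts (each undirected path is found once from
# either end).
oracle_path_counts <- function(g, l, u) {
  syms <- g$atoms
  counts <- new.env(parent = emptyenv())
  bump <- function(key, by = 1) {
    prev <- if (exists(key, envir = counts, inherits = FALSE)) {
      get(key, envir = counts, inherits = FALSE)
    } else 0
    assign(key, prev + by, envir = counts)
  }
  if (l == 0) for (s in syms) bump(s)
  if (u >= 1 && nrow(g$bonds) > 0) {
    bsym <- c("1" = "-", "2" = "=", "3" = "#", "4" = ":")
    ig <- igraph::graph_from_data_frame(
      data.frame(from = g$bonds$a1, to = g$bonds$a2,
                 sym = bsym[as.character(g$bonds$order)]),
      directed = FALSE,
      vertices = data.frame(name = seq_along(syms)))
    ekey <- new.env(parent = emptyenv())
    for (i in seq_len(nrow(g$bonds))) {
      assign(paste(g$bonds$a1[i], g$bonds$a2[i]),
             bsym[[as.character(g$bonds$order[i])]], envir = ekey)
    }
    bond_sym <- function(a, b) {
      k <- paste(min(a, b), max(a, b))
      get(k, envir = ekey, inherits = FALSE)
    }
    for (v in seq_along(syms)) {
      ps <- igraph::all_simple_paths(ig, from = as.character(v), cutoff = u)
      for (p in ps) {
        vs <- as.integer(names(p))
        d <- length(vs) - 1L
        if (d < max(l, 1L) || d > u) next
        toks <- character(2L * length(vs) - 1L)
        toks[seq(1, length(toks), by = 2)] <- syms[vs]
        for (j in seq_len(d)) {
          toks[2L * j] <- bond_sym(vs[j], vs[j + 1L])
        }
        f <- paste0(toks, collapse = "")
        r <- paste0(rev(toks), collapse = "")
        bump(sort(c(f, r), method = "radix")[1], by = 0.5)
      }
    }
  }
  labs <- ls(counts)
  vals <- vapply(labs, get, numeric(1), envir = counts)
  stopifnot(all(abs(vals - round(vals)) < 1e-9))
  out <- stats::setNames(as.integer(round(vals)), labs)
  d <- vecpath::path_depth(names(out))
  out[order(d, names(out), method = "radix")]
}

# Exhaustive all-shortest-route oracle: depth-bounded DFS over raw U/O
# matrices, collecting every rule-id sequence of minimum length.
oracle_shortest <- function(start, goal, rs, dmax = 6L) {
  U <- rs$U_mat
  O <- rs$O_mat
  ids <- vapply(rs$rules, `[[`, "", "rule_id")
  best <- new.env(parent = emptyenv())
  best$d <- NA_integer_
  best$paths <- list()
  s0 <- as.integer(start)
  gv <- as.integer(goal)
  dfs <- function(t, path) {
    d <- length(path)
    if (all(t == gv)) {
      if (is.na(best$d) || d < best$d) {
        best$d <- d
        best$paths <- list(path)
      } else if (d == best$d) {
        best$paths[[length(best$paths) + 1L]] <- path
      }
      return(invisible())
    }
    if (!is.na(best$d) && d + 1L > best$d) return(invisible())
    if (d >= dmax) return(invisible())
    for (k in seq_len(ncol(O))) {
      if (all(t >= U[, k]) && all(t + O[, k] >= 0L)) {
        dfs(t + O[, k], c(path, ids[k]))
      }
    }
    invisible()
  }
  dfs(s0, character(0))
  paths <- unique(best$paths)
  paths <- paths[order(vapply(paths, paste, "", collapse = "\r"),
                       method = "radix")]
  list(distance = best$d, paths = paths)
}

# Bounded exhaustive solver of the operator-count integer program:
# min sum(w) s.t. operators %*% w == delta, w integer in [0, wmax].
oracle_ip_min <- function(delta, operators, wmax = 5L) {
  m <- ncol(operators)
  grid <- as.matrix(expand.grid(rep(list(0:wmax), m)))
  hits <- grid[rowSums(abs(grid %*% t(operators) -
                             matrix(delta, nrow(grid), length(delta),
                                    byrow = TRUE))) == 0, , drop = FALSE]
  if (nrow(hits) == 0) return(Inf)
  min(rowSums(hits))
}

# Reverse breadth-first sweep from the goal: true distance-to-goal for
# every state within dmax rule applications. pred = t - O_k is a
# predecessor of t iff pred >= 0 and pred >= U_k.
oracle_true_dist_map <- function(goal, rs, dmax = 8L) {
  U <- rs$U_mat
  O <- rs$O_mat
  dist <- new.env(hash = TRUE, parent = emptyenv())
  gv <- as.integer(goal)
  key <- function(t) paste(t, collapse = " ")
  assign(key(gv), 0L, envir = dist)
  frontier <- list(gv)
  for (d in seq_len(dmax)) {
    nxt <- list()
    for (t in frontier) {
      for (k in seq_len(ncol(O))) {
        p <- t - O[, k]
        if (any(p < 0L) || any(p < U[, k])) next
        kk <- key(p)
        if (!exists(kk, envir = dist, inherits = FALSE)) {
          assign(kk, d, envir = dist)
          nxt[[length(nxt) + 1L]] <- p
        }
      }
    }
    if (length(nxt) == 0) break
    frontier <- nxt
  }
  dist
}

# Random valence-legal molecule with n_heavy heavy atoms (tree plus an
# occasional ring closure), hydrogens made explicit.
random_molecule <- function(n_heavy) {
  elements <- c("C", "C", "C", "N", "O", "S", "Cl")
  val <- c(H = 1, C = 4, N = 3, O = 2, S = 2, Cl = 1)
  atoms <- sample(elements, 1)
  bonds <- data.frame(a1 = integer(), a2 = integer(), order = integer())
  bsum <- 0
  while (length(atoms) < n_heavy) {
    el <- sample(elements, 1)
    free <- val[atoms] - bsum
    cand <- which(free >= 1)
    if (length(cand) == 0) break
    at <- if (length(cand) == 1) cand else sample(cand, 1)
    ord <- if (free[at] >= 2 && val[[el]] >= 2 && stats::runif(1) < 0.2) 2L else 1L
    atoms <- c(atoms, el)
    bonds <- rbind(bonds, data.frame(a1 = at, a2 = length(atoms), order = ord))
    bsum <- c(bsum, 0)
    bsum[at] <- bsum[at] + ord
    bsum[length(atoms)] <- ord
  }
  free <- val[atoms] - bsum
  open <- which(free >= 1 & atoms == "C")
  if (length(open) >= 2 && stats::runif(1) < 0.3) {
    pr <- sample(open, 2)
    adjacent <- any((bonds$a1 == min(pr) & bonds$a2 == max(pr)))
    if (!adjacent) {
      bonds <- rbind(bonds, data.frame(a1 = min(pr), a2 = max(pr), order = 1L))
    }
  }
  add_implicit_hydrogens(molgraph(atoms, bonds, id = "random"))
}

# Tiny hand-built rule set over an abstract vocabulary of n dimensions,
# for unit tests that need full control of U and O.
toy_ruleset <- function(U_list, O_list, ids) {
  n <- length(U_list[[1]])
  vocab <- structure(list(l = 0L, u = 0L, labels = paste0("d", seq_len(n)),
                          depth = rep(0L, n),
                          sig = paste0("toy", n)),
                     class = "path_vocab")
  rules <- lapply(seq_along(ids), function(k) {
    structure(list(rule_id = ids[k], U = as.integer(U_list[[k]]),
                   O = as.integer(O_list[[k]]), provenance = ids[k],
                   vocab_sig = vocab$sig),
              class = "reaction_rule")
  })
  O_mat <- vapply(rules, `[[`, integer(n), "O")
  U_mat <- vapply(rules, `[[`, integer(n), "U")
  if (is.null(dim(O_mat))) {
    O_mat <- matrix(O_mat, nrow = n)
    U_mat <- matrix(U_mat, nrow = n)
  }
  colnames(O_mat) <- colnames(U_mat) <- ids
  structure(list(vocab = vocab, rules = rules, U_mat = U_mat, O_mat = O_mat,
                 max_norm = max(colSums(abs(O_mat))),
                 dedup = list()),
            class = "rule_set")
}

# Rewrap a bare integer state as a compound_vector on the same vocabulary
# as `like`.
.as_cv <- function(t, like) {
  structure(as.integer(t), class = "compound_vector",
            vocab_sig = attr(like, "vocab_sig"))
}

toy_vec <- function(x, n = length(x)) {
  structure(as.integer(x), class = "compound_vector",
            vocab_sig = paste0("toy", n))
}
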