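# Seeded synthetic compound corpora and reaction networks with known
# ground truth, so every search component is testable without any
# database download. Generated compounds are valence-legal molecular
# graphs; reactions are graph edits (or one-step group substitutions), so
# the featurizer's assumptions hold for every intermediate.

.chain_graph <- function(L, id = NA_character_) {
  bonds <- if (L > 1) {
    data.frame(a1 = seq_len(L - 1), a2 = seq_len(L - 1) + 1L, order = 1L)
  } else {
    data.frame(a1 = integer(), a2 = integer(), order = integer())
  }
  molgraph(rep("C", L), bonds, id = id)
}

# Monovalent substituent groups used by the ring generator. Each spec lists
# the group's heavy atoms, internal bonds, and which group atom bonds to
# the scaffold; implicit hydrogens complete the valences later.
.ring_groups <- list(
  Cl     = list(atoms = "Cl"),
  F      = list(atoms = "F"),
  Br     = list(atoms = "Br"),
  I      = list(atoms = "I"),
  OH     = list(atoms = "O"),
  NH2    = list(atoms = "N"),
  SH     = list(atoms = "S"),
  CH3    = list(atoms = "C"),
  OCH3   = list(atoms = c("O", "C"), bonds = rbind(c(1, 2, 1))),
  NHCH3  = list(atoms = c("N", "C"), bonds = rbind(c(1, 2, 1))),
  SCH3   = list(atoms = c("S", "C"), bonds = rbind(c(1, 2, 1))),
  CH2Cl  = list(atoms = c("C", "Cl"), bonds = rbind(c(1, 2, 1))),
  CH2F   = list(atoms = c("C", "F"), bonds = rbind(c(1, 2, 1))),
  CH2Br  = list(atoms = c("C", "Br"), bonds = rbind(c(1, 2, 1))),
  CH2I   = list(atoms = c("C", "I"), bonds = rbind(c(1, 2, 1))),
  CH2OH  = list(atoms = c("C", "O"), bonds = rbind(c(1, 2, 1))),
  CH2NH2 = list(atoms = c("C", "N"), bonds = rbind(c(1, 2, 1))),
  CH2SH  = list(atoms = c("C", "S"), bonds = rbind(c(1, 2, 1))),
  CHO    = list(atoms = c("C", "O"), bonds = rbind(c(1, 2, 2))),
  CH2CH3 = list(atoms = c("C", "C"), bonds = rbind(c(1, 2, 1))),
  COOH   = list(atoms = c("C", "O", "O"),
                bonds = rbind(c(1, 2, 2), c(1, 3, 1))),
  CN     = list(atoms = c("C", "N"), bonds = rbind(c(1, 2, 3))),
  CHCl2  = list(atoms = c("C", "Cl", "Cl"),
                bonds = rbind(c(1, 2, 1), c(1, 3, 1))),
  CF3    = list(atoms = c("C", "F", "F", "F"),
                bonds = rbind(c(1, 2, 1), c(1, 3, 1), c(1, 4, 1)))
)

# Attach a group spec to atom `at` of graph `g` via a single bond.
.attach_group <- function(g, at, spec) {
  base_n <- length(g$atoms)
  atoms <- c(g$atoms, spec$atoms)
  extra <- data.frame(a1 = at, a2 = base_n + 1L, order = 1L)
  if (!is.null(spec$bonds)) {
    extra <- rbind(extra,
                   data.frame(a1 = base_n + spec$bonds[, 1],
                              a2 = base_n + spec$bonds[, 2],
                              order = spec$bonds[, 3]))
  }
  molgraph(atoms, rbind(g$bonds, extra), id = g$id)
}

#' The methane worked example
#'
#' Explicit-hydrogen methane plus its expected depth 0-2 path counts
#' (`C` 1, `H` 4, `C-H` 4, `H-C-H` 6) and the oxygen-containing labels
#' whose counts must be zero when present in a vocabulary (given in
#' canonical rendering: `O`, `H-O`, `H-C=O`).
#'
#' @return List with `graph`, `expected` (named integer vector) and
#'   `zero_labels` (character).
#' @export
methane_fixture <- function() {
  g <- molgraph(c("C", "H", "H", "H", "H"),
                data.frame(a1 = 1L, a2 = 2:5, order = 1L),
                id = "methane")
  list(graph = g,
       expected = c("C" = 1L, "H" = 4L, "C-H" = 4L, "H-C-H" = 6L),
       zero_labels = c("O", "H-O", "H-C=O"))
}

# Assemble a fixture_network: featurize everything, build the rule set,
# and record BFS ground truth (full optimal tier) for each query pair.
.assemble_network <- function(structures, reactions, query_pairs, depth,
                              seed, kind, max_depth = 25L) {
  structures <- lapply(structures, add_implicit_hydrogens)
  vocab <- build_vocabulary(structures, depth[1], depth[2])
  vectors <- lapply(structures, featurize, vocab = vocab)
  rs <- build_ruleset(reactions, structures, vocab, add_hydrogens = FALSE)
  if (is.null(query_pairs)) query_pairs <- list()
  queries <- lapply(query_pairs, function(q) {
    res <- bfs(vectors[[q[1]]], vectors[[q[2]]], rs,
               enumerate_all = TRUE, max_depth = max_depth)
    list(start = q[1], goal = q[2], status = res$status,
         distance = res$distance, paths = res$paths)
  })
  structure(list(structures = structures, reactions = reactions,
                 vocab = vocab, vectors = vectors, ruleset = rs,
                 queries = queries, depth = as.integer(depth),
                 seed = seed, kind = kind),
            class = "fixture_network")
}

#' @export
print.fixture_network <- function(x, ...) {
  cat(sprintf("<fixture_network '%s': %d compounds, %d reactions, %d queries, depth %d-%d, seed %s>\n",
              x$kind, length(x$structures), nrow(x$reactions),
              length(x$queries), x$depth[1], x$depth[2],
              ifelse(is.null(x$seed), "-", x$seed)))
  invisible(x)
}

#' Random edit network with known ground truth
#'
#' Starts from a random small alkane scaffold and grows a tree of
#' compounds by random valence-legal graph edits (attach a terminal C, O,
#' N or Cl; remove a terminal heavy atom; toggle a C-C bond between single
#' and double). Each edit becomes one reaction (reversible with
#' probability 1/2). Query pairs are two ancestor/descendant pairs plus
#' one random ordered pair; ground truth (distance and the full optimal
#' tier) is recorded by breadth-first search over the resulting rules.
#'
#' @param n_compounds Number of compounds (>= 2).
#' @param seed Integer seed; the same seed reproduces the network exactly.
#' @param depth Representation-depth range (default 0-2).
#' @return A `fixture_network`.
#' @export
gen_edit_network <- function(n_compounds, seed, depth = c(0L, 2L)) {
  stopifnot(n_compounds >= 2)
  withr::with_seed(seed, {
    free_val <- function(g) {
      bsum <- numeric(length(g$atoms))
      if (nrow(g$bonds) > 0) {
        v <- .bond_valence[as.character(g$bonds$order)]
        for (i in seq_len(nrow(g$bonds))) {
          bsum[g$bonds$a1[i]] <- bsum[g$bonds$a1[i]] + v[i]
          bsum[g$bonds$a2[i]] <- bsum[g$bonds$a2[i]] + v[i]
        }
      }
      vals <- .standard_valence[g$atoms]
      vals - bsum
    }
    rand_edit <- function(g) {
      kind <- sample(c("add", "remove", "bond"), 1,
                     prob = c(0.55, 0.25, 0.20))
      fv <- free_val(g)
      if (kind == "add") {
        cand <- which(fv >= 1 & g$atoms != "H")
        if (length(cand) == 0) return(NULL)
        at <- if (length(cand) == 1) cand else sample(cand, 1)
        el <- sample(c("C", "O", "N", "Cl"), 1, prob = c(0.5, 0.2, 0.2, 0.1))
        return(molgraph(c(g$atoms, el),
                        rbind(g$bonds,
                              data.frame(a1 = at, a2 = length(g$atoms) + 1L,
                                         order = 1L)),
                        id = g$id))
      }
      if (kind == "remove") {
        deg <- tabulate(c(g$bonds$a1, g$bonds$a2), length(g$atoms))
        cand <- which(deg == 1 & g$atoms != "H")
        if (length(cand) == 0 || length(g$atoms) <= 2) return(NULL)
        at <- if (length(cand) == 1) cand else sample(cand, 1)
        keep <- setdiff(seq_along(g$atoms), at)
        remap <- match(seq_along(g$atoms), keep)
        b <- g$bonds[g$bonds$a1 != at & g$bonds$a2 != at, , drop = FALSE]
        b$a1 <- remap[b$a1]; b$a2 <- remap[b$a2]
        return(molgraph(g$atoms[keep], b, id = g$id))
      }
      # bond order toggle on a C-C bond
      cc <- which(g$atoms[g$bonds$a1] == "C" & g$atoms[g$bonds$a2] == "C")
      up <- cc[g$bonds$order[cc] == 1 &
                 fv[g$bonds$a1[cc]] >= 1 & fv[g$bonds$a2[cc]] >= 1]
      down <- cc[g$bonds$order[cc] == 2]
      cand <- c(up, down)
      if (length(cand) == 0) return(NULL)
      bi <- if (length(cand) == 1) cand else sample(cand, 1)
      b <- g$bonds
      b$order[bi] <- if (b$order[bi] == 1L) 2L else 1L
      molgraph(g$atoms, b, id = g$id)
    }

    sig_of <- function(g) {
      ep <- enumerate_paths(add_implicit_hydrogens(g), depth[1], depth[2])
      paste(names(ep), ep, collapse = ";")
    }

    heavy <- list(.chain_graph(sample(2:4, 1)))
    heavy[[1]]$id <- "C01"
    sigs <- sig_of(heavy[[1]])
    parent <- NA_integer_
    rows <- NULL
    while (length(heavy) < n_compounds) {
      placed <- FALSE
      for (try in 1:40) {
        p <- sample(length(heavy), 1)
        g2 <- rand_edit(heavy[[p]])
        if (is.null(g2)) next
        s <- sig_of(g2)
        if (s %in% sigs) next
        i <- length(heavy) + 1L
        g2$id <- sprintf("C%02d", i)
        heavy[[i]] <- g2
        sigs <- c(sigs, s)
        parent[i] <- p
        rows <- rbind(rows, data.frame(
          reaction_id = sprintf("R%02d", i - 1L),
          substrate_id = heavy[[p]]$id, product_id = g2$id,
          reversible = sample(0:1, 1), stringsAsFactors = FALSE))
        placed <- TRUE
        break
      }
      if (!placed) {
        stop("could not generate ", n_compounds,
             " structurally distinct compounds; try another seed")
      }
    }
    names(heavy) <- vapply(heavy, function(g) g$id, "")

    ancestors <- function(i) {
      out <- integer(0)
      while (!is.na(parent[i])) {
        i <- parent[i]
        out <- c(out, i)
      }
      out
    }
    qp <- list()
    desc <- which(!is.na(parent))
    for (k in seq_len(min(2, length(desc)))) {
      d <- if (length(desc) == 1) desc else sample(desc, 1)
      anc <- ancestors(d)
      a <- if (length(anc) == 1) anc else sample(anc, 1)
      qp[[length(qp) + 1L]] <- c(heavy[[a]]$id, heavy[[d]]$id)
    }
    pr <- sample(length(heavy), 2, replace = FALSE)
    qp[[length(qp) + 1L]] <- c(heavy[[pr[1]]]$id, heavy[[pr[2]]]$id)

    # true distances are bounded by the edit-tree depth (< n_compounds),
    # so a modest search cap records exact ground truth quickly
    .assemble_network(heavy, rows, qp, depth, seed, "edit_network",
                      max_depth = max(8L, n_compounds + 2L))
  })
}

#' Closed-circuit pathway network with known ground truth
#'
#' Emulates a closed degradation circuit: `n_nodes` compounds sharing a
#' pentane scaffold, each carrying one distinct monovalent substituent
#' group at the central carbon. Consecutive ring compounds are linked by a
#' forward one-step group-substitution reaction (the circuit closes back
#' to the start); for `n_nodes >= 10` a few reversible cross-link
#' reactions are added as shortcuts. Every distinct substituent makes
#' every edge operator distinct and keeps substrate gates selective, so
#' optimal route tiers stay small. All `n_nodes * (n_nodes - 1)` ordered
#' pairs become query pairs with BFS-recorded ground truth.
#'
#' @param n_nodes Number of ring compounds, between 3 and 24 (one distinct
#'   substituent group per node).
#' @param seed Integer seed (shuffles group assignment and chord placement).
#' @param depth Representation-depth range (default 0-2).
#' @return A `fixture_network`.
#' @export
gen_ring_pathway <- function(n_nodes, seed, depth = c(0L, 2L)) {
  stopifnot(n_nodes >= 3)
  if (n_nodes > length(.ring_groups)) {
    stop("gen_ring_pathway supports at most ", length(.ring_groups),
         " nodes (one distinct substituent group per node)")
  }
  withr::with_seed(seed, {
    groups <- .ring_groups[sample(length(.ring_groups), n_nodes)]
    base <- .chain_graph(5L)
    structures <- lapply(seq_len(n_nodes), function(i) {
      g <- .attach_group(base, 3L, groups[[i]])
      g$id <- sprintf("C%02d", i)
      g
    })
    names(structures) <- vapply(structures, function(g) g$id, "")

    rows <- data.frame(
      reaction_id = sprintf("E%02d", seq_len(n_nodes)),
      substrate_id = sprintf("C%02d", seq_len(n_nodes)),
      product_id = sprintf("C%02d", c(seq_len(n_nodes)[-1], 1L)),
      reversible = 0L, stringsAsFactors = FALSE)
    if (n_nodes >= 10) {
      n_chords <- max(1L, n_nodes %/% 7L)
      jump <- n_nodes %/% 3L
      at <- sample(n_nodes, n_chords)
      rows <- rbind(rows, data.frame(
        reaction_id = sprintf("X%02d", seq_len(n_chords)),
        substrate_id = sprintf("C%02d", at),
        product_id = sprintf("C%02d", (at + jump - 1L) %% n_nodes + 1L),
        reversible = 1L, stringsAsFactors = FALSE))
    }

    ids <- names(structures)
    qp <- list()
    for (a in ids) for (b in ids) {
      if (a != b) qp[[length(qp) + 1L]] <- c(a, b)
    }
    fx <- .assemble_network(structures, rows, qp, depth, seed, "ring_pathway",
                            max_depth = n_nodes + 5L)

    sig <- vapply(fx$vectors, paste, "", collapse = " ")
    if (anyDuplicated(sig)) {
      stop("ring compounds collapsed to identical vectors at this depth")
    }
    fx
  })
}

#' Fixture with exactly two optimal route orderings
#'
#' Propane can be chlorinated at one end and aminated at the other; the
#' two substitutions are independent, giving two distinct two-step routes
#' from propane to 1-chloro-3-aminopropane (via 1-chloropropane or via
#' propylamine). Substrate gates block every other sequence, so the
#' optimal tier has exactly these two rule sequences. Used to exercise
#' all-shortest-path enumeration.
#'
#' @param depth Representation-depth range (default 0-2).
#' @return A `fixture_network` whose single query is start `S` to goal
#'   `G`; the ground-truth tier holds the two routes.
#' @export
gen_two_route_fixture <- function(depth = c(0L, 2L)) {
  S <- .chain_graph(3L, id = "S")
  A <- molgraph(c("C", "C", "C", "Cl"),
                data.frame(a1 = c(1, 2, 1), a2 = c(2, 3, 4), order = 1L),
                id = "A")
  B <- molgraph(c("C", "C", "C", "N"),
                data.frame(a1 = c(1, 2, 3), a2 = c(2, 3, 4), order = 1L),
                id = "B")
  G <- molgraph(c("C", "C", "C", "Cl", "N"),
                data.frame(a1 = c(1, 2, 1, 3), a2 = c(2, 3, 4, 5),
                           order = 1L),
                id = "G")
  structures <- list(S = S, A = A, B = B, G = G)
  rows <- data.frame(
    reaction_id = c("r1", "r2", "r3", "r4"),
    substrate_id = c("S", "A", "S", "B"),
    product_id = c("A", "G", "B", "G"),
    reversible = 0L, stringsAsFactors = FALSE)
  fx <- .assemble_network(structures, rows, list(c("S", "G")), depth,
                          seed = NULL, kind = "two_route")
  # the two substitutions must commute exactly in vector space
  v <- fx$vectors
  stopifnot(identical(as.integer(v$G) - as.integer(v$A),
                      as.integer(v$B) - as.integer(v$S)))
  fx
}

#' Serialize a fixture network to a directory
#'
#' Writes `structures.sdf` (explicit-hydrogen V2000), `reactions.tsv` and
#' `ground_truth.json` (depth, seed, queries with recorded distances and
#' optimal route tiers), loadable through the standard input paths.
#'
#' @param fx A `fixture_network`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_fixture <- function(fx, dir) {
  stopifnot(inherits(fx, "fixture_network"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_structures(fx$structures, file.path(dir, "structures.sdf"))
  utils::write.table(fx$reactions, file.path(dir, "reactions.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  gt <- list(kind = fx$kind, depth = fx$depth, seed = fx$seed,
             queries = lapply(fx$queries, function(q) {
               list(start = q$start, goal = q$goal, status = q$status,
                    distance = q$distance, paths = q$paths)
             }))
  jsonlite::write_json(gt, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, null = "null", na = "null",
                       digits = NA)
  invisible(dir)
}

#' Load a serialized fixture network
#'
#' Inverse of [write_fixture()]: rebuilds the vocabulary, vectors and rule
#' set from the serialized structures and reaction table, and restores the
#' recorded ground truth.
#'
#' @param dir Directory written by [write_fixture()].
#' @return A `fixture_network`.
#' @export
read_fixture <- function(dir) {
  gt <- jsonlite::read_json(file.path(dir, "ground_truth.json"),
                            simplifyVector = FALSE)
  depth <- as.integer(unlist(gt$depth))
  structures <- read_structures(file.path(dir, "structures.sdf"))
  reactions <- read_reaction_table(file.path(dir, "reactions.tsv"))
  fx <- .assemble_network(structures, reactions, NULL, depth,
                          seed = gt$seed, kind = gt$kind)
  # keep the *recorded* ground truth (regenerated one is cross-checked in tests)
  fx$queries <- lapply(gt$queries, function(q) {
    list(start = q$start, goal = q$goal, status = q$status,
         distance = if (is.null(q$distance)) NA_integer_
                    else as.integer(q$distance),
         paths = lapply(q$paths, function(p) unlist(p, use.names = FALSE)))
  })
  fx
}
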