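# Molecular graphs, path enumeration and compound feature vectors.
#
# A compound is a labelled undirected graph (atoms = nodes, bonds = edges).
# Its feature vector counts, for every labelled simple path with between
# l and u bonds that occurs in a reference corpus, how many times that path
# appears in the compound ("representation-depth l-u").

# Bond-order codes follow MDL V2000: 1 single, 2 double, 3 triple, 4 aromatic.
.bond_symbols <- c("1" = "-", "2" = "=", "3" = "#", "4" = ":")
.bond_valence <- c("1" = 1, "2" = 2, "3" = 3, "4" = 1.5)

# Standard valences used when topping up implicit hydrogens.
.standard_valence <- c(
  H = 1, C = 4, N = 3, O = 2, S = 2,
  F = 1, Cl = 1, Br = 1, I = 1
)

.element_symbols <- c(
  "H", "He", "Li", "Be", "B", "C", "N", "O", "F", "Ne", "Na", "Mg", "Al",
  "Si", "P", "S", "Cl", "Ar", "K", "Ca", "Sc", "Ti", "V", "Cr", "Mn", "Fe",
  "Co", "Ni", "Cu", "Zn", "Ga", "Ge", "As", "Se", "Br", "Kr", "Rb", "Sr",
  "Y", "Zr", "Nb", "Mo", "Tc", "Ru", "Rh", "Pd", "Ag", "Cd", "In", "Sn",
  "Sb", "Te", "I", "Xe", "Cs", "Ba", "La", "Ce", "Pr", "Nd", "Pm", "Sm",
  "Eu", "Gd", "Tb", "Dy", "Ho", "Er", "Tm", "Yb", "Lu", "Hf", "Ta", "W",
  "Re", "Os", "Ir", "Pt", "Au", "Hg", "Tl", "Pb", "Bi", "Po", "At", "Rn",
  "Fr", "Ra", "Ac", "Th", "Pa", "U"
)

#' Construct a molecular graph
#'
#' @param atoms Character vector of element symbols; position is the atom
#'   index (1-based).
#' @param bonds Data frame with integer columns `a1`, `a2` (atom indices)
#'   and `order` (1 single, 2 double, 3 triple, 4 aromatic). May have zero
#'   rows.
#' @param id Compound identifier (single string).
#'
#' @return An object of class `molgraph`: a list with elements `atoms`,
#'   `bonds` (normalized so `a1 < a2`) and `id`.
#' @export
molgraph <- function(atoms, bonds = data.frame(a1 = integer(), a2 = integer(),
                                               order = integer()),
                     id = NA_character_) {
  atoms <- as.character(atoms)
  bad <- setdiff(unique(atoms), .element_symbols)
  if (length(bad) > 0) {
    stop("invalid element symbol(s): ", paste(bad, collapse = ", "))
  }
  bonds <- as.data.frame(bonds)
  if (nrow(bonds) > 0) {
    bonds$a1 <- as.integer(bonds$a1)
    bonds$a2 <- as.integer(bonds$a2)
    bonds$order <- as.integer(bonds$order)
    if (any(bonds$a1 == bonds$a2)) stop("self-bond not allowed")
    n <- length(atoms)
    if (any(bonds$a1 < 1L | bonds$a1 > n | bonds$a2 < 1L | bonds$a2 > n)) {
      stop("bond references a non-existent atom index")
    }
    if (!all(bonds$order %in% 1:4)) {
      stop("bond order must be 1, 2, 3 or 4 (aromatic)")
    }
    swap <- bonds$a1 > bonds$a2
    tmp <- bonds$a1[swap]
    bonds$a1[swap] <- bonds$a2[swap]
    bonds$a2[swap] <- tmp
    if (anyDuplicated(bonds[, c("a1", "a2")])) {
      stop("duplicate bond between the same atom pair")
    }
  }
  bonds <- bonds[, c("a1", "a2", "order")]
  rownames(bonds) <- NULL
  structure(list(atoms = unname(atoms), bonds = bonds,
                 id = as.character(id)[1]),
            class = "molgraph")
}

#' @export
print.molgraph <- function(x, ...) {
  cat(sprintf("<molgraph %s: %d atoms, %d bonds>\n",
              ifelse(is.na(x$id), "(unnamed)", x$id),
              length(x$atoms), nrow(x$bonds)))
  invisible(x)
}

# Split raw SDF/MOL text into records (vectors of lines). A lone MOL block
# without a "$$$$" terminator is a single record.
.split_sdf_records <- function(lines) {
  term <- which(trimws(lines) == "$$$$")
  if (length(term) == 0) {
    return(list(list(lines = lines, offset = 0L)))
  }
  out <- list()
  start <- 1L
  for (t in term) {
    rec <- lines[start:(t - 1L)]
    if (any(nzchar(trimws(rec)))) {
      out[[length(out) + 1L]] <- list(lines = rec, offset = start - 1L)
    }
    start <- t + 1L
  }
  if (start <= length(lines) && any(nzchar(trimws(lines[start:length(lines)])))) {
    out[[length(out) + 1L]] <- list(lines = lines[start:length(lines)],
                                    offset = start - 1L)
  }
  out
}

# Validate one V2000 record; returns list(natoms, nbonds). Errors name the
# record and the (1-based) line in the original stream.
.validate_v2000_record <- function(rec, irec) {
  lines <- rec$lines
  off <- rec$offset
  id <- trimws(lines[1])
  where <- function(local_line) {
    sprintf("record %d ('%s'), line %d", irec,
            ifelse(nzchar(id), id, "?"), off + local_line)
  }
  if (length(lines) < 4) {
    stop(where(length(lines)), ": truncated MOL block", call. = FALSE)
  }
  counts <- lines[4]
  natoms <- suppressWarnings(as.integer(substr(counts, 1, 3)))
  nbonds <- suppressWarnings(as.integer(substr(counts, 4, 6)))
  if (is.na(natoms) || is.na(nbonds) || natoms < 0 || nbonds < 0) {
    stop(where(4), ": malformed counts line '", counts, "'", call. = FALSE)
  }
  if (!grepl("V2000", counts, fixed = TRUE)) {
    stop(where(4), ": unsupported MOL version (expected V2000)", call. = FALSE)
  }
  if (length(lines) < 4 + natoms + nbonds) {
    stop(where(length(lines)), ": truncated atom/bond block", call. = FALSE)
  }
  if (nbonds > 0) {
    for (b in seq_len(nbonds)) {
      ln <- lines[4 + natoms + b]
      a1 <- suppressWarnings(as.integer(substr(ln, 1, 3)))
      a2 <- suppressWarnings(as.integer(substr(ln, 4, 6)))
      if (is.na(a1) || is.na(a2)) {
        stop(where(4 + natoms + b), ": malformed bond line '", ln, "'",
             call. = FALSE)
      }
      if (a1 < 1 || a1 > natoms || a2 < 1 || a2 > natoms) {
        stop(where(4 + natoms + b), ": bond references atom ", max(a1, a2),
             " but the record has only ", natoms,
             " atoms (indices are 1-based)", call. = FALSE)
      }
    }
  }
  list(natoms = natoms, nbonds = nbonds)
}

#' Read 2D structures from MOL/SDF V2000 text
#'
#' Parses a single MDL MOL block or a multi-record SDF file (records
#' separated by `$$$$`). Each record is validated (counts line, bond index
#' bounds, version tag) with errors naming the offending record and line,
#' then parsed via [ChemmineR::read.SDFset()]. Bond type 4 is kept as
#' aromatic.
#'
#' @param stream Path to a file, or a character vector of lines (a single
#'   string containing newlines is also accepted).
#' @param id_field Optional SDF data-field name to take the compound id
#'   from; by default the MOL title line is used.
#'
#' @return List of [molgraph] objects, in file order, atom indices as in
#'   the file.
#' @export
read_structures <- function(stream, id_field = NULL) {
  if (length(stream) == 1 && !grepl("\n", stream) && file.exists(stream)) {
    lines <- readLines(stream, warn = FALSE)
  } else if (length(stream) == 1) {
    lines <- strsplit(stream, "\n", fixed = TRUE)[[1]]
  } else {
    lines <- as.character(stream)
  }
  recs <- .split_sdf_records(lines)
  if (length(recs) == 0) return(list())
  for (i in seq_along(recs)) .validate_v2000_record(recs[[i]], i)

  tf <- tempfile(fileext = ".sdf")
  on.exit(unlink(tf), add = TRUE)
  body <- unlist(lapply(recs, function(r) c(r$lines, "$$$$")), use.names = FALSE)
  writeLines(body, tf)
  sdf <- suppressWarnings(ChemmineR::read.SDFset(tf))

  out <- vector("list", length(recs))
  for (i in seq_along(recs)) {
    mol <- sdf[[i]]
    ab <- ChemmineR::atomblock(mol)
    bb <- ChemmineR::bondblock(mol)
    syms <- sub("_[0-9]+$", "", rownames(ab))
    if (nrow(bb) > 0) {
      bonds <- data.frame(a1 = as.integer(bb[, 1]),
                          a2 = as.integer(bb[, 2]),
                          order = as.integer(bb[, 3]))
    } else {
      bonds <- data.frame(a1 = integer(), a2 = integer(), order = integer())
    }
    id <- trimws(recs[[i]]$lines[1])
    if (!is.null(id_field)) {
      db <- ChemmineR::datablock(mol)
      if (id_field %in% names(db)) id <- unname(db[[id_field]])
    }
    if (!nzchar(id)) id <- sprintf("record_%d", i)
    out[[i]] <- molgraph(syms, bonds, id = id)
  }
  names(out) <- vapply(out, function(g) g$id, character(1))
  out
}

#' Write molecular graphs as an SDF (V2000) file
#'
#' Minimal V2000 emitter (coordinates are written as zeros; only 2D
#' topology is represented). Round-trips through [read_structures()].
#'
#' @param graphs A `molgraph` or list of them.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_structures <- function(graphs, path) {
  if (inherits(graphs, "molgraph")) graphs <- list(graphs)
  con <- file(path, open = "w")
  on.exit(close(con), add = TRUE)
  for (g in graphs) {
    lines <- c(
      ifelse(is.na(g$id), "", g$id),
      "  vecpath",
      "",
      sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000",
              length(g$atoms), nrow(g$bonds)),
      sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
              0, 0, 0, g$atoms)
    )
    if (nrow(g$bonds) > 0) {
      lines <- c(lines, sprintf("%3d%3d%3d  0  0  0  0",
                                g$bonds$a1, g$bonds$a2, g$bonds$order))
    }
    lines <- c(lines, "M  END", "$$$$")
    writeLines(lines, con)
  }
  invisible(path)
}

#' Add implicit hydrogens up to standard valence
#'
#' Appends hydrogen atoms so every atom reaches its standard valence
#' (C 4, N 3, O 2, S 2, halogens 1), counting bond orders (aromatic bonds
#' count 1.5; the per-atom total is rounded to the nearest integer).
#' Atoms already carrying explicit hydrogens are topped up, never stripped.
#' Elements without a valence rule are left untouched with a warning.
#'
#' @param g A [molgraph].
#' @return A [molgraph] with explicit hydrogens.
#' @export
add_implicit_hydrogens <- function(g) {
  stopifnot(inherits(g, "molgraph"))
  n <- length(g$atoms)
  if (n == 0) return(g)
  bsum <- numeric(n)
  if (nrow(g$bonds) > 0) {
    v <- .bond_valence[as.character(g$bonds$order)]
    for (i in seq_len(nrow(g$bonds))) {
      bsum[g$bonds$a1[i]] <- bsum[g$bonds$a1[i]] + v[i]
      bsum[g$bonds$a2[i]] <- bsum[g$bonds$a2[i]] + v[i]
    }
  }
  atoms <- g$atoms
  bonds <- g$bonds
  no_rule <- character(0)
  for (i in seq_len(n)) {
    sym <- g$atoms[i]
    if (!sym %in% names(.standard_valence)) {
      no_rule <- c(no_rule, sym)
      next
    }
    deficit <- .standard_valence[[sym]] - floor(bsum[i] + 0.5)
    if (deficit > 0) {
      for (k in seq_len(deficit)) {
        atoms <- c(atoms, "H")
        bonds <- rbind(bonds, data.frame(a1 = i, a2 = length(atoms),
                                         order = 1L))
      }
    }
  }
  if (length(no_rule) > 0) {
    warning("no valence rule for element(s): ",
            paste(unique(no_rule), collapse = ", "),
            "; no hydrogens added there")
  }
  molgraph(atoms, bonds, id = g$id)
}

# Canonical rendering of a path given its token sequence
# (atom, bond, atom, ...): the lexicographically smaller (C locale) of the
# forward and reversed renderings, so a path and its reversal share one label.
.canonical_label <- function(tokens) {
  f <- paste0(tokens, collapse = "")
  r <- paste0(rev(tokens), collapse = "")
  if (f == r) f else sort(c(f, r), method = "radix")[1]
}

#' Depth (number of bonds) of a path label
#'
#' @param label Character vector of path labels.
#' @return Integer vector of depths (count of bond symbols in each label).
#' @export
path_depth <- function(label) {
  nchar(gsub("[^-=#:]", "", label))
}

#' Enumerate labelled simple paths of a molecular graph
#'
#' Counts every simple path (no repeated atom) with between `l` and `u`
#' bonds; each undirected path is counted exactly once (not once per
#' direction). Depth-0 paths are single-atom occurrences. Labels alternate
#' atom symbols and bond symbols (`-` single, `=` double, `#` triple,
#' `:` aromatic), canonicalized as the lexicographic minimum of the forward
#' and reversed renderings.
#'
#' @param g A [molgraph]; hydrogens should already be explicit (see
#'   [add_implicit_hydrogens()]).
#' @param l,u Depth range, `u >= l >= 0`.
#' @return Named integer vector mapping path label to occurrence count,
#'   ordered by (depth, label).
#' @export
enumerate_paths <- function(g, l = 0L, u = 2L) {
  stopifnot(inherits(g, "molgraph"), u >= l, l >= 0)
  n <- length(g$atoms)
  counts0 <- new.env(hash = TRUE, parent = emptyenv())
  counts1 <- new.env(hash = TRUE, parent = emptyenv())
  bump <- function(envir, key) {
    prev <- if (exists(key, envir = envir, inherits = FALSE)) {
      get(key, envir = envir, inherits = FALSE)
    } else 0L
    assign(key, prev + 1L, envir = envir)
  }
  if (n == 0) return(stats::setNames(integer(0), character(0)))
  if (l == 0) for (s in g$atoms) bump(counts0, s)

  if (u >= 1 && nrow(g$bonds) > 0) {
    adj_to <- vector("list", n)
    adj_sym <- vector("list", n)
    for (i in seq_len(nrow(g$bonds))) {
      a <- g$bonds$a1[i]; b <- g$bonds$a2[i]
      s <- .bond_symbols[[as.character(g$bonds$order[i])]]
      adj_to[[a]] <- c(adj_to[[a]], b); adj_sym[[a]] <- c(adj_sym[[a]], s)
      adj_to[[b]] <- c(adj_to[[b]], a); adj_sym[[b]] <- c(adj_sym[[b]], s)
    }
    lmin <- max(l, 1L)
    walk <- function(visited, tokens) {
      last <- visited[length(visited)]
      nbrs <- adj_to[[last]]
      for (j in seq_along(nbrs)) {
        nb <- nbrs[j]
        if (nb %in% visited) next
        toks <- c(tokens, adj_sym[[last]][j], g$atoms[nb])
        d <- length(visited)  # bonds in the extended path
        if (d >= lmin) bump(counts1, .canonical_label(toks))
        if (d < u) walk(c(visited, nb), toks)
      }
    }
    for (a in seq_len(n)) walk(a, g$atoms[a])
  }

  labs0 <- ls(counts0)
  labs1 <- ls(counts1)
  vals0 <- vapply(labs0, get, integer(1), envir = counts0)
  # every undirected path of depth >= 1 is traversed once from each end
  vals1 <- vapply(labs1, get, integer(1), envir = counts1) %/% 2L
  out <- c(stats::setNames(as.integer(vals0), labs0),
           stats::setNames(as.integer(vals1), labs1))
  d <- path_depth(names(out))
  out[order(d, names(out), method = "radix")]
}

#' Build a path vocabulary from a compound corpus
#'
#' The vocabulary is the ordered set of canonical path labels with depth in
#' `[l, u]` appearing at least once in the corpus; it fixes the
#' dimensionality and ordering of all compound vectors. Ordering is by
#' (depth, label) under C-locale byte order, so identical corpora yield
#' identical vocabularies on any platform.
#'
#' @param corpus Non-empty list of [molgraph] objects (hydrogens explicit).
#' @param l,u Depth range.
#' @return Object of class `path_vocab`: list with `l`, `u`, `labels`,
#'   `depth` and an opaque signature used to detect vocabulary mismatches.
#' @export
build_vocabulary <- function(corpus, l = 0L, u = 2L) {
  stopifnot(length(corpus) > 0)
  labs <- unique(unlist(lapply(corpus, function(g) {
    names(enumerate_paths(g, l, u))
  }), use.names = FALSE))
  d <- path_depth(labs)
  o <- order(d, labs, method = "radix")
  labs <- labs[o]
  d <- d[o]
  structure(list(l = as.integer(l), u = as.integer(u),
                 labels = labs, depth = d,
                 sig = paste(c(l, u, labs), collapse = "\r")),
            class = "path_vocab")
}

#' @export
print.path_vocab <- function(x, ...) {
  cat(sprintf("<path_vocab depth %d-%d: %d labels>\n",
              x$l, x$u, length(x$labels)))
  invisible(x)
}

#' Featurize a compound against a vocabulary
#'
#' Returns the compound's path-count vector aligned to the vocabulary
#' ordering. Labels present in the compound but absent from the vocabulary
#' are counted, reported via `message()` and the `"oov"` attribute, and
#' excluded from the vector (they are never silently dropped).
#'
#' @param g A [molgraph] with explicit hydrogens.
#' @param vocab A [build_vocabulary()] result.
#' @return Object of class `compound_vector`: integer vector of length
#'   `length(vocab$labels)` with attributes `vocab_sig` and `id`.
#' @export
featurize <- function(g, vocab) {
  stopifnot(inherits(g, "molgraph"), inherits(vocab, "path_vocab"))
  ep <- enumerate_paths(g, vocab$l, vocab$u)
  idx <- match(names(ep), vocab$labels)
  counts <- integer(length(vocab$labels))
  hit <- !is.na(idx)
  counts[idx[hit]] <- as.integer(ep[hit])
  oov <- ep[!hit]
  if (length(oov) > 0) {
    message(sprintf(
      "featurize: compound '%s' has %d path label(s) outside the vocabulary (%s); excluded",
      ifelse(is.na(g$id), "?", g$id), length(oov),
      paste(utils::head(names(oov), 5), collapse = ", ")))
  }
  structure(counts, class = "compound_vector",
            vocab_sig = vocab$sig, id = g$id,
            oov = if (length(oov) > 0) oov else NULL)
}

#' @export
print.compound_vector <- function(x, ...) {
  nz <- which(x != 0)
  cat(sprintf("<compound_vector %s: %d dims, %d nonzero>\n",
              ifelse(is.null(attr(x, "id")) || is.na(attr(x, "id")), "",
                     attr(x, "id")),
              length(x), length(nz)))
  invisible(x)
}

# Internal: make a bare compound_vector from integer counts.
.as_compound_vector <- function(counts, vocab, id = NA_character_) {
  structure(as.integer(counts), class = "compound_vector",
            vocab_sig = vocab$sig, id = id)
}

.check_same_vocab <- function(...) {
  sigs <- vapply(list(...), function(x) {
    s <- attr(x, "vocab_sig")
    if (is.null(s)) NA_character_ else s
  }, character(1))
  if (length(unique(sigs[!is.na(sigs)])) > 1) {
    stop("vocabulary mismatch: vectors were featurized against different vocabularies")
  }
  invisible(TRUE)
}

#' Write a vocabulary to TSV
#'
#' Columns: `index`, `depth`, `label`.
#' @param vocab A `path_vocab`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_vocabulary <- function(vocab, path) {
  utils::write.table(
    data.frame(index = seq_along(vocab$labels), depth = vocab$depth,
               label = vocab$labels),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write compound vectors as a TSV matrix
#'
#' One row per compound: id followed by the counts in vocabulary order.
#' @param vectors Named list of `compound_vector` objects.
#' @param vocab The shared vocabulary.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_vectors <- function(vectors, vocab, path) {
  m <- do.call(rbind, lapply(vectors, as.integer))
  df <- data.frame(compound_id = names(vectors), m, check.names = FALSE)
  names(df) <- c("compound_id", vocab$labels)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
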