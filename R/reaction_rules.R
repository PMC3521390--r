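# Reaction rules: an enzyme reaction acting on a "main" substrate/product
# pair becomes a rule R = (U, O), where U is the substrate's compound
# vector (the applicability gate) and O is the operator vector, the exact
# entrywise difference product - substrate. Applying the reaction to any
# compound vector is then addition of O.

#' Build one reaction rule from a substrate/product vector pair
#'
#' @param substrate,product `compound_vector`s on the same vocabulary.
#' @param reaction_id Identifier recorded as provenance.
#' @return A `reaction_rule` (list with `rule_id`, `U`, `O`, `provenance`),
#'   or `NULL` when the operator is all-zero (the structure is unchanged by
#'   the reaction; such rules are filtered and tallied upstream).
#' @export
make_rule <- function(substrate, product, reaction_id) {
  if (length(substrate) != length(product)) {
    stop("vocabulary mismatch: substrate and product vectors differ in length")
  }
  .check_same_vocab(substrate, product)
  O <- as.integer(product) - as.integer(substrate)
  if (all(O == 0L)) return(NULL)
  structure(list(rule_id = as.character(reaction_id),
                 U = as.integer(substrate),
                 O = O,
                 provenance = as.character(reaction_id),
                 vocab_sig = attr(substrate, "vocab_sig")),
            class = "reaction_rule")
}

#' @export
print.reaction_rule <- function(x, ...) {
  cat(sprintf("<reaction_rule %s: ||O||1 = %d, provenance: %s>\n",
              x$rule_id, sum(abs(x$O)), paste(x$provenance, collapse = ",")))
  invisible(x)
}

#' Read a reaction table from TSV
#'
#' Expected header: `reaction_id`, `substrate_id`, `product_id`,
#' `reversible` (0/1).
#' @param path TSV file path.
#' @return Data frame with those four columns.
#' @export
read_reaction_table <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, quote = "")
  need <- c("reaction_id", "substrate_id", "product_id", "reversible")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) {
    stop("reaction table is missing column(s): ", paste(miss, collapse = ", "))
  }
  df$reversible <- as.integer(df$reversible)
  df[, need]
}

#' Build a deduplicated rule set from substrate/product pairs
#'
#' Reversible reactions emit two directed rules (ids suffixed `_f` and
#' `_r`); irreversible ones emit the forward rule only. Rules identical in
#' the exact `(U, O)` integer pair are merged with concatenated provenance.
#' The dedup report tallies why raw reactions collapse: zero operators
#' (structure unchanged), identical `(U, O)` vectors (different reactions,
#' same representation), and — reported but *not* merged — groups sharing
#' the operator `O` with different substrates `U`.
#'
#' @param pairs Data frame as from [read_reaction_table()].
#' @param structures Named list of [molgraph] (ids must cover the table),
#'   or a named list of pre-featurized `compound_vector`s.
#' @param vocab The session vocabulary.
#' @param add_hydrogens Make hydrogens explicit before featurizing
#'   (default `TRUE`; ignored when `structures` are already vectors).
#' @return Object of class `rule_set`: list with `vocab`, `rules`,
#'   `U_mat`/`O_mat` (dims x rules matrices), `max_norm`, `dedup`.
#' @export
build_ruleset <- function(pairs, structures, vocab, add_hydrogens = TRUE) {
  stopifnot(inherits(vocab, "path_vocab"))
  ids <- unique(c(pairs$substrate_id, pairs$product_id))
  miss <- setdiff(ids, names(structures))
  if (length(miss) > 0) {
    bad <- pairs$reaction_id[pairs$substrate_id %in% miss |
                               pairs$product_id %in% miss]
    stop("unresolvable compound id(s) ", paste(miss, collapse = ", "),
         " in reaction(s) ", paste(unique(bad), collapse = ", "))
  }
  vec_of <- function(id) {
    x <- structures[[id]]
    if (inherits(x, "compound_vector")) return(x)
    if (add_hydrogens) x <- add_implicit_hydrogens(x)
    featurize(x, vocab)
  }
  vecs <- lapply(stats::setNames(ids, ids), vec_of)

  directed <- list()
  n_zero <- 0L
  for (i in seq_len(nrow(pairs))) {
    rid <- pairs$reaction_id[i]
    s <- pairs$substrate_id[i]
    p <- pairs$product_id[i]
    dirs <- if (pairs$reversible[i] == 1L) {
      list(c(s, p, paste0(rid, "_f")), c(p, s, paste0(rid, "_r")))
    } else {
      list(c(s, p, paste0(rid, "_f")))
    }
    for (d in dirs) {
      r <- make_rule(vecs[[d[1]]], vecs[[d[2]]], d[3])
      if (is.null(r)) n_zero <- n_zero + 1L else {
        directed[[length(directed) + 1L]] <- r
      }
    }
  }

  # merge identical (U, O) pairs, keeping first-seen order
  seen <- new.env(hash = TRUE, parent = emptyenv())
  rules <- list()
  n_merged <- 0L
  for (r in directed) {
    key <- paste(c(r$U, "|", r$O), collapse = " ")
    if (exists(key, envir = seen, inherits = FALSE)) {
      k <- get(key, envir = seen, inherits = FALSE)
      rules[[k]]$provenance <- c(rules[[k]]$provenance, r$provenance)
      n_merged <- n_merged + 1L
    } else {
      assign(key, length(rules) + 1L, envir = seen)
      rules[[length(rules) + 1L]] <- r
    }
  }
  if (length(rules) == 0) {
    stop("rule set is empty: every input reaction collapsed to a zero operator")
  }

  O_mat <- vapply(rules, function(r) r$O, integer(length(vocab$labels)))
  U_mat <- vapply(rules, function(r) r$U, integer(length(vocab$labels)))
  if (is.null(dim(O_mat))) {  # single-label vocabulary
    O_mat <- matrix(O_mat, nrow = length(vocab$labels))
    U_mat <- matrix(U_mat, nrow = length(vocab$labels))
  }
  colnames(O_mat) <- colnames(U_mat) <- vapply(rules, `[[`, "", "rule_id")

  # reason-1 tally: same operator, different substrate (kept distinct)
  okey <- apply(O_mat, 2, paste, collapse = " ")
  shared <- table(okey)
  n_shared_ops <- sum(shared > 1)
  n_rules_sharing <- sum(shared[shared > 1])

  structure(list(
    vocab = vocab,
    rules = rules,
    U_mat = U_mat,
    O_mat = O_mat,
    max_norm = max(colSums(abs(O_mat))),
    dedup = list(
      input_pairs = nrow(pairs),
      directed_reactions = length(directed) + n_zero,
      zero_operator_dropped = n_zero,
      merged_identical_vector = n_merged,
      same_operator_different_substrate_groups = n_shared_ops,
      rules_in_those_groups = as.integer(n_rules_sharing),
      rules = length(rules))
  ), class = "rule_set")
}

#' @export
print.rule_set <- function(x, ...) {
  d <- x$dedup
  cat(sprintf(paste0(
    "<rule_set: %d rules over %d dims (depth %d-%d), ||O_max||1 = %d>\n",
    "  from %d reaction pairs -> %d directed reactions;",
    " dropped %d zero-operator, merged %d identical-vector\n",
    "  %d operator(s) shared across substrates (%d rules, kept distinct)\n"),
    d$rules, length(x$vocab$labels), x$vocab$l, x$vocab$u, x$max_norm,
    d$input_pairs, d$directed_reactions, d$zero_operator_dropped,
    d$merged_identical_vector, d$same_operator_different_substrate_groups,
    d$rules_in_those_groups))
  invisible(x)
}

#' Maximum operator 1-norm of a rule set
#'
#' The largest `sum(abs(O))` over all rules; the normalizer that makes the
#' Manhattan goal-distance heuristic admissible (one rule application can
#' change the compound vector by at most this amount in 1-norm).
#'
#' @param rs A `rule_set`.
#' @return Positive integer.
#' @export
max_operator_norm <- function(rs) {
  stopifnot(inherits(rs, "rule_set"))
  if (length(rs$rules) == 0) stop("empty rule set")
  max(colSums(abs(rs$O_mat)))
}

#' Export a rule set to TSV
#'
#' Columns: `rule_id`, `provenance` (comma-separated source reactions) and
#' the nonzero `index:value` entries of `U` and `O`.
#' @param rs A `rule_set`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ruleset <- function(rs, path) {
  sparse <- function(v) {
    nz <- which(v != 0)
    paste(sprintf("%d:%d", nz, v[nz]), collapse = ";")
  }
  df <- data.frame(
    rule_id = vapply(rs$rules, `[[`, "", "rule_id"),
    provenance = vapply(rs$rules, function(r) {
      paste(r$provenance, collapse = ",")
    }, ""),
    U = vapply(rs$rules, function(r) sparse(r$U), ""),
    O = vapply(rs$rules, function(r) sparse(r$O), ""))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
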