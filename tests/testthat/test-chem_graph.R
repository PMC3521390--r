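# Structure parsing, implicit hydrogens and path-count featurization.

methane_mol <- function(title = "methane") {
  c(title, "  test", "",
    "  5  4  0  0  0  0  0  0  0  0999 V2000",
    sprintf("    0.0000    0.0000    0.0000 %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
            c("C", "H", "H", "H", "H")),
    "  1  2  1  0  0  0  0",
    "  1  3  1  0  0  0  0",
    "  1  4  1  0  0  0  0",
    "  1  5  1  0  0  0  0",
    "M  END")
}

test_that("MOL/SDF parsing preserves records and validates structure", {
  g <- read_structures(methane_mol())[[1]]
  expect_s3_class(g, "molgraph")
  expect_equal(length(g$atoms), 5)
  expect_equal(nrow(g$bonds), 4)
  expect_true(all(g$bonds$order == 1L))
  expect_equal(g$id, "methane")

  sdf <- c(methane_mol("m1"), "$$$$", methane_mol("m2"), "$$$$",
           methane_mol("m3"), "$$$$")
  gs <- read_structures(sdf)
  expect_length(gs, 3)
  expect_equal(names(gs), c("m1", "m2", "m3"))

  bad <- methane_mol()
  bad[10] <- "  1  0  1  0  0  0  0"  # V2000 atom indices are 1-based
  expect_error(read_structures(bad), "record 1.*line 10")
  bad2 <- methane_mol()
  bad2[10] <- "  1  9  1  0  0  0  0"
  expect_error(read_structures(bad2), "only 5 atoms")
  bad3 <- methane_mol()
  bad3[4] <- "  X  4  0  0  0  0  0  0  0  0999 V2000"
  expect_error(read_structures(bad3), "malformed counts line")
  bad4 <- methane_mol()
  bad4[4] <- sub("V2000", "V3000", bad4[4])
  expect_error(read_structures(bad4), "V2000")
})

test_that("structures round-trip through the SDF writer", {
  set.seed(421)
  gs <- lapply(5:9, random_molecule)
  names(gs) <- paste0("m", seq_along(gs))
  for (i in seq_along(gs)) gs[[i]]$id <- names(gs)[i]
  tf <- tempfile(fileext = ".sdf")
  write_structures(gs, tf)
  back <- read_structures(tf)
  expect_equal(names(back), names(gs))
  for (i in seq_along(gs)) {
    expect_equal(back[[i]]$atoms, gs[[i]]$atoms)
    expect_equal(back[[i]]$bonds, gs[[i]]$bonds)
  }
})

test_that("implicit hydrogens complete standard valences and are idempotent", {
  ch4 <- add_implicit_hydrogens(molgraph("C"))
  expect_equal(sort(table(ch4$atoms), decreasing = TRUE),
               sort(table(c("C", "H", "H", "H", "H")), decreasing = TRUE),
               ignore_attr = TRUE)
  expect_equal(nrow(ch4$bonds), 4)

  # formaldehyde heavy atoms: two H on the carbon, none on the oxygen
  fa <- add_implicit_hydrogens(
    molgraph(c("C", "O"), data.frame(a1 = 1, a2 = 2, order = 2)))
  expect_equal(sum(fa$atoms == "H"), 2)
  expect_true(all(fa$bonds$a1[fa$bonds$order == 1] == 1))

  expect_identical(add_implicit_hydrogens(ch4), ch4)

  # benzene: aromatic bonds count 1.5, one H per carbon
  benz <- molgraph(rep("C", 6),
                   data.frame(a1 = 1:6, a2 = c(2:6, 1), order = 4L))
  bh <- add_implicit_hydrogens(benz)
  expect_equal(sum(bh$atoms == "H"), 6)

  expect_warning(add_implicit_hydrogens(molgraph(c("C", "Fe"))), "Fe")
})

test_that("path enumeration reproduces the worked examples", {
  mf <- methane_fixture()
  expect_identical(enumerate_paths(mf$graph, 0, 2), mf$expected)

  expect_identical(enumerate_paths(molgraph("C"), 0, 0), c("C" = 1L))

  ethane <- add_implicit_hydrogens(
    molgraph(c("C", "C"), data.frame(a1 = 1, a2 = 2, order = 1)))
  got <- enumerate_paths(ethane, 0, 2)
  # frozen from the igraph oracle (and by hand: 2 CH3 groups -> C(3,2)*2
  # H-C-H pairs, 6 C-H bonds each extendable across the C-C bond)
  expect_identical(got, oracle_path_counts(ethane, 0, 2))
  expect_equal(got[["C-C"]], 1L)
  expect_equal(got[["C-H"]], 6L)
  expect_equal(got[["H-C-H"]], 6L)
  expect_equal(got[["C-C-H"]], 6L)

  expect_length(enumerate_paths(molgraph(character(0)), 0, 2), 0)
})

test_that("path enumeration matches the igraph oracle on random molecules", {
  set.seed(101)
  for (i in 1:30) {
    g <- random_molecule(sample(3:10, 1))
    for (rng in list(c(0, 1), c(0, 2), c(1, 3))) {
      expect_identical(enumerate_paths(g, rng[1], rng[2]),
                       oracle_path_counts(g, rng[1], rng[2]),
                       info = sprintf("molecule %d depth %d-%d", i,
                                      rng[1], rng[2]))
    }
  }
})

test_that("path counts are invariant under atom reindexing", {
  set.seed(202)
  for (i in 1:10) {
    g <- random_molecule(sample(4:9, 1))
    perm <- sample(length(g$atoms))
    inv <- match(seq_along(perm), perm)
    g2 <- molgraph(g$atoms[perm],
                   data.frame(a1 = match(g$bonds$a1, perm),
                              a2 = match(g$bonds$a2, perm),
                              order = g$bonds$order))
    expect_identical(enumerate_paths(g, 0, 3), enumerate_paths(g2, 0, 3))
  }
})

test_that("vocabulary is a deterministic, ordered union over the corpus", {
  mf <- methane_fixture()$graph
  water <- add_implicit_hydrogens(molgraph("O", id = "water"))
  v1 <- build_vocabulary(list(mf, water), 0, 1)
  expect_setequal(v1$labels, c("C", "H", "O", "C-H", "H-O"))
  expect_equal(v1$depth, path_depth(v1$labels))
  # ordering: depth first, then label in C-locale byte order
  expect_false(is.unsorted(v1$depth))

  v2 <- build_vocabulary(list(mf, water), 0, 1)
  expect_identical(v1, v2)

  v_m <- build_vocabulary(list(mf), 0, 2)
  expect_identical(v_m$labels, c("C", "H", "C-H", "H-C-H"))
})

test_that("featurize aligns counts and zero-fills foreign labels", {
  mf <- methane_fixture()
  v <- build_vocabulary(list(mf$graph), 0, 2)
  cv <- featurize(mf$graph, v)
  expect_identical(as.integer(cv), c(1L, 4L, 4L, 6L))

  # with oxygen compounds in the corpus, methane's O-entries are zero
  fa <- add_implicit_hydrogens(
    molgraph(c("C", "O"), data.frame(a1 = 1, a2 = 2, order = 2), id = "fa"))
  meoh <- add_implicit_hydrogens(
    molgraph(c("C", "O"), data.frame(a1 = 1, a2 = 2, order = 1), id = "meoh"))
  v2 <- build_vocabulary(list(mf$graph, fa, meoh), 0, 2)
  cv2 <- featurize(mf$graph, v2)
  for (lab in mf$zero_labels) {
    expect_true(lab %in% v2$labels, info = lab)
    expect_equal(cv2[[match(lab, v2$labels)]], 0L, ignore_attr = TRUE)
  }
  # depth-0 counts sum to the atom count
  expect_equal(sum(cv2[v2$depth == 0]), length(mf$graph$atoms))

  # out-of-vocabulary labels are reported, never silently dropped
  expect_message(cv3 <- featurize(fa, v), "outside the vocabulary")
  expect_true(sum(attr(cv3, "oov")) > 0)
  expect_equal(as.integer(cv3)[match("C", v$labels)], 1L)
})

test_that("vocabulary and vector TSV exports are readable", {
  mf <- methane_fixture()$graph
  v <- build_vocabulary(list(mf), 0, 2)
  tv <- tempfile(fileext = ".tsv")
  write_vocabulary(v, tv)
  back <- utils::read.table(tv, header = TRUE, sep = "\t")
  expect_equal(back$label, v$labels)
  expect_equal(back$depth, v$depth)

  tm <- tempfile(fileext = ".tsv")
  write_vectors(list(methane = featurize(mf, v)), v, tm)
  mat <- utils::read.table(tm, header = TRUE, sep = "\t", check.names = FALSE)
  expect_equal(unname(unlist(mat[1, -1])), c(1L, 4L, 4L, 6L))
})
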