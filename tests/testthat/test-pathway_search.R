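# Constraint checking, successor generation and shortest-path search.

test_that("applicability enforces substrate inclusion and non-negativity", {
  rs <- toy_ruleset(U_list = list(c(1, 1, 0)), O_list = list(c(-1, 0, 1)),
                    ids = "r")
  r <- rs$rules[[1]]
  expect_true(is_applicable(r, toy_vec(c(2, 1, 0))))
  # substrate inclusion fails
  r2 <- toy_ruleset(list(c(1, 0)), list(c(0, 1)), "r2")$rules[[1]]
  expect_false(is_applicable(r2, toy_vec(c(0, 1))))
  # result would go negative
  r3 <- toy_ruleset(list(c(1, 0)), list(c(-2, 0)), "r3")$rules[[1]]
  expect_false(is_applicable(r3, toy_vec(c(1, 0))))
})

test_that("apply_rule adds the operator and never clamps", {
  rs <- toy_ruleset(list(c(0, 0)), list(c(-1, 1)), "r")
  r <- rs$rules[[1]]
  t <- toy_vec(c(2, 2))
  t2 <- apply_rule(t, r)
  expect_identical(as.integer(t2), c(1L, 3L))
  expect_identical(as.integer(t), c(2L, 2L))  # input unmodified
  # a rule and its exact reverse cancel
  rrev <- toy_ruleset(list(c(0, 0)), list(c(1, -1)), "rr")$rules[[1]]
  rrev$vocab_sig <- r$vocab_sig
  expect_identical(as.integer(apply_rule(t2, rrev)), as.integer(t))

  rneg <- toy_ruleset(list(c(0, 0)), list(c(-3, 0)), "rn")$rules[[1]]
  expect_error(apply_rule(t, rneg), "not applicable")
})

test_that("successors match a brute-force filter of the rule set", {
  fx <- gen_edit_network(6, seed = 21)
  rs <- fx$ruleset
  for (v in fx$vectors) {
    succ <- successors(v, rs)
    brute <- Filter(function(r) is_applicable(r, v), rs$rules)
    expect_equal(vapply(succ, `[[`, "", "rule_id"),
                 vapply(brute, `[[`, "", "rule_id"))
    for (s in succ) {
      expect_true(all(as.integer(s$state) >= 0))
    }
  }
  # empty and full cases
  none <- toy_ruleset(list(c(5, 5)), list(c(1, 0)), "r")
  expect_length(successors(toy_vec(c(0, 0)), none), 0)
  all_ok <- toy_ruleset(list(c(0, 0), c(0, 0)), list(c(1, 0), c(0, 1)),
                        c("a", "b"))
  expect_length(successors(toy_vec(c(0, 0)), all_ok), 2)
})

test_that("the Manhattan heuristic is the normalized 1-norm distance", {
  expect_equal(mh_heuristic(toy_vec(c(1, 2)), toy_vec(c(1, 2)), 3), 0)
  expect_equal(mh_heuristic(toy_vec(c(0, 0)), toy_vec(c(3, 1)), 2), 2.0)
  expect_error(mh_heuristic(toy_vec(c(0, 0)), toy_vec(c(3, 1)), 0),
               "positive")
})

test_that("trivial searches: identical endpoints and unreachable goals", {
  rs <- toy_ruleset(list(c(0, 0)), list(c(1, 0)), "r")
  s <- toy_vec(c(1, 1))
  for (h in c("bf", "mh", "lp")) {
    res <- astar(s, s, rs, heuristic = h)
    expect_equal(res$status, "found")
    expect_equal(res$distance, 0L)
    expect_identical(res$paths, list(character(0)))
  }
  # goal differs on an index no operator touches: the uninformed search
  # can only exhaust its depth budget on the infinite ray ...
  res <- bfs(toy_vec(c(0, 0)), toy_vec(c(0, 1)), rs, max_depth = 5)
  expect_equal(res$status, "limit-exceeded")
  expect_true(is.na(res$distance))
  # ... but with no rule at all the frontier genuinely empties
  gated <- toy_ruleset(list(c(9, 9)), list(c(1, 0)), "r")
  res_g <- bfs(toy_vec(c(0, 0)), toy_vec(c(0, 1)), gated, max_depth = 5)
  expect_equal(res_g$status, "unreachable")
  # the LP heuristic proves the same unreachability by infeasibility
  res_lp <- astar(toy_vec(c(0, 0)), toy_vec(c(0, 1)), rs, heuristic = "lp")
  expect_equal(res_lp$status, "unreachable")
  expect_equal(res_lp$diagnostics$expansions, 0L)
})

test_that("a two-step toy network is solved with the exact rule order", {
  # r2's substrate gate is only satisfied after r1 has fired
  rs <- toy_ruleset(
    U_list = list(c(1, 0, 0), c(1, 1, 0), c(0, 0, 0)),
    O_list = list(c(0, 1, 0), c(-1, -1, 1), c(0, 0, 2)),
    ids = c("r1", "r2", "r3"))
  start <- toy_vec(c(1, 0, 0))
  goal <- toy_vec(c(0, 0, 1))
  oracle <- oracle_shortest(start, goal, rs, dmax = 5)
  expect_equal(oracle$distance, 2L)
  expect_identical(oracle$paths, list(c("r1", "r2")))
  for (h in c("bf", "mh", "lp")) {
    res <- astar(start, goal, rs, heuristic = h, enumerate_all = TRUE)
    expect_equal(res$distance, 2L)
    expect_identical(res$paths, oracle$paths)
  }
})

test_that("limit-exceeded status reports best-so-far diagnostics", {
  rs <- toy_ruleset(list(c(0, 0), c(0, 0)), list(c(1, 0), c(0, 1)),
                    c("a", "b"))
  res <- bfs(toy_vec(c(0, 0)), toy_vec(c(6, 6)), rs, max_expansions = 5)
  expect_equal(res$status, "limit-exceeded")
  expect_equal(res$diagnostics$expansions, 5L)
  res2 <- bfs(toy_vec(c(0, 0)), toy_vec(c(6, 6)), rs, max_depth = 3)
  expect_equal(res2$status, "limit-exceeded")
})

test_that("all optimal orderings are enumerated on the two-route fixture", {
  fx <- gen_two_route_fixture()
  start <- fx$vectors$S
  goal <- fx$vectors$G
  oracle <- oracle_shortest(start, goal, fx$ruleset, dmax = 4)
  expect_equal(oracle$distance, 2L)
  expect_length(oracle$paths, 2)
  for (h in c("bf", "mh", "lp")) {
    res <- astar(start, goal, fx$ruleset, heuristic = h,
                 enumerate_all = TRUE)
    expect_equal(res$distance, 2L)
    expect_identical(res$paths, oracle$paths, info = h)
  }
})

test_that("returned paths replay validly and searches agree across heuristics", {
  for (seed in c(31, 32, 33, 34, 35)) {
    fx <- gen_edit_network(6, seed = seed)
    for (q in fx$queries) {
      s <- fx$vectors[[q$start]]
      g <- fx$vectors[[q$goal]]
      b <- bfs(s, g, fx$ruleset, max_depth = 8, enumerate_all = TRUE)
      m <- astar(s, g, fx$ruleset, heuristic = "mh", max_depth = 8,
                 enumerate_all = TRUE)
      l <- astar(s, g, fx$ruleset, heuristic = "lp", max_depth = 8,
                 enumerate_all = TRUE)
      expect_identical(b$distance, m$distance)
      expect_identical(b$distance, l$distance)
      expect_identical(b$paths, m$paths)
      expect_identical(b$paths, l$paths)
      expect_equal(m$diagnostics$reopenings, 0L)
      expect_equal(l$diagnostics$reopenings, 0L)
      if (b$status == "found") {
        for (p in b$paths) {
          expect_length(p, b$distance)
          final <- replay_path(s, p, fx$ruleset)  # errors on any violation
          expect_identical(as.integer(final), as.integer(g))
        }
      }
    }
  }
})

test_that("informed searches expand no more nodes than uninformed ones", {
  for (seed in 41:45) {
    fx <- gen_edit_network(6, seed = seed)
    for (q in fx$queries) {
      s <- fx$vectors[[q$start]]
      g <- fx$vectors[[q$goal]]
      b <- bfs(s, g, fx$ruleset, max_depth = 8)
      m <- astar(s, g, fx$ruleset, heuristic = "mh", max_depth = 8)
      l <- astar(s, g, fx$ruleset, heuristic = "lp", max_depth = 8)
      expect_lte(l$diagnostics$expansions, m$diagnostics$expansions)
      expect_lte(m$diagnostics$expansions, b$diagnostics$expansions)
    }
  }
})

test_that("a user-supplied heuristic function is accepted", {
  rs <- toy_ruleset(list(c(0, 0), c(0, 0)), list(c(1, 0), c(0, 1)),
                    c("a", "b"))
  goal <- toy_vec(c(2, 1))
  h <- function(t) sum(abs(t - c(2L, 1L))) / 1  # admissible here (unit ops)
  res <- astar(toy_vec(c(0, 0)), goal, rs, heuristic = h)
  expect_equal(res$distance, 3L)
})
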