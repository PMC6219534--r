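test_that("cleaning removes dead ends and free-only producers to a fixpoint", {
  u1 <- make_u1()
  targets <- c("A", "C", "D")
  # r4's product E is neither a target nor consumed downstream
  expect_identical(clean_pathway(c("r1", "r2", "r3", "r4"), u1, targets, "P"),
                   c("r1", "r2", "r3"))
  # idempotent on clean input
  expect_identical(clean_pathway(c("r1", "r2", "r3"), u1, targets, "P"),
                   c("r1", "r2", "r3"))
  # a reaction producing only pool compounds is dropped
  u5 <- reaction_universe(c(u1$reactions, list(reaction("r5", "C", "P"))))
  expect_identical(clean_pathway(c("r1", "r2", "r5"), u5, c("A", "C"), "P"),
                   c("r1", "r2"))
  # cascading removal: r4 feeds only r6, r6 feeds nothing -> both go
  u6 <- reaction_universe(c(u1$reactions, list(reaction("r6", "E", "F"))))
  expect_identical(clean_pathway(c("r1", "r2", "r3", "r4", "r6"), u6, targets, "P"),
                   c("r1", "r2", "r3"))
  expect_identical(clean_pathway(character(), u1, targets, "P"), character(0))
})

test_that("cleaning is idempotent and preserves goal and feasibility", {
  set.seed(7)
  for (s in 1:8) {
    rp <- make_random_problem(sample(5:10, 1), seed = 400 + s)
    res <- run_aco(rp$problem, aco_params(n_ants = 5, alpha = 100,
                                          max_iterations = 15,
                                          stall_iterations = 5, seed = s))
    path <- res$pathway
    if (!length(path)) next
    cleaned <- clean_pathway(path, rp$universe, rp$problem$targets,
                             rp$problem$free_compounds)
    expect_identical(
      clean_pathway(cleaned, rp$universe, rp$problem$targets,
                    rp$problem$free_compounds),
      cleaned)
    expect_lte(length(cleaned), length(path))
    # cleaning never increases the length or unique-reaction components
    expect_lte(count_unique(cleaned, rp$universe),
               max(1L, count_unique(path, rp$universe)))
  }
})

test_that("unique and productive reaction counts follow their definitions", {
  u1 <- make_u1()
  expect_identical(count_unique(c("r1", "r2", "r3"), u1), 3L)
  expect_identical(count_unique(character(), u1), 0L)
  # both directions of a reversible reaction count once
  urev <- reaction_universe(split_reversible("rX", "A", "B", "reversible"))
  expect_identical(count_unique(c("rX", "rX_rev"), urev), 1L)

  expect_identical(count_productive(c("r1", "r2", "r3"), u1, "P"), 3L)
  # second producer of an already-produced compound is unproductive
  udup <- reaction_universe(list(reaction("ra", "A", "B"),
                                 reaction("rb", "C", "B"),
                                 reaction("rc", "A", "C")))
  expect_identical(count_productive(c("ra", "rc", "rb"), udup, character()), 2L)
  # only free products: unproductive
  u5 <- reaction_universe(c(u1$reactions, list(reaction("r5", "C", "P"))))
  expect_identical(count_productive("r5", u5, "P"), 0L)
})

test_that("connectivity distinguishes complete from partial pathways", {
  u1 <- make_u1()
  targets <- c("A", "C", "D")
  expect_identical(connectivity(c("r1", "r2", "r3"), u1, targets, "P", 100), 1)
  expect_identical(connectivity(c("r1", "r2"), u1, targets, "P", 100), 100)
  expect_identical(connectivity("r1", u1, "A", "P", 100), 1)
  expect_error(connectivity(character(), u1, targets, "P", 100), "empty")
  expect_error(connectivity("r1", u1, character(), "P", 100), "target")
})

test_that("connectivity agrees with an independently coded sweep", {
  set.seed(11)
  for (s in 1:10) {
    rp <- make_random_problem(sample(5:10, 1), seed = 500 + s)
    res <- bfs_search(rp$problem, rp$initial_available)
    path <- res$pathway
    if (!length(path)) next
    expect_identical(
      connectivity(path, rp$universe, rp$problem$targets,
                   rp$problem$free_compounds, 100),
      kappa_oracle(path, rp$universe, rp$problem$targets,
                   rp$problem$free_compounds, 100))
  }
})

test_that("the cost breakdown combines the four components", {
  u1 <- make_u1()
  targets <- c("A", "C", "D")
  cb <- pathway_cost(c("r1", "r2", "r3"), u1, targets, "P", 100)
  expect_identical(cb$length, 3L)
  expect_identical(cb$n_unique, 3L)
  expect_identical(cb$n_productive, 3L)
  expect_identical(cb$kappa, 1)
  expect_identical(cb$total, 3)

  cb2 <- pathway_cost(c("r1", "r2"), u1, targets, "P", 100)
  expect_identical(cb2$kappa, 100)
  expect_identical(cb2$total, 200)

  expect_error(pathway_cost(character(), u1, targets, "P", 100), "empty")

  # appending a fully redundant reaction strictly increases total cost
  urev <- reaction_universe(c(u1$reactions,
                              split_reversible("r9", "B", "C", "reversible")[2]))
  base <- pathway_cost(c("r1", "r2", "r3"), urev, targets, "P", 100)$total
  # r9_rev consumes C, produces B (already present): unproductive
  longer <- pathway_cost(c("r1", "r2", "r3", "r9_rev"), urev, targets, "P", 100)$total
  expect_gt(longer, base)
})

test_that("complete solutions always cost less than partial ones under large alpha", {
  u1 <- make_u1()
  targets <- c("A", "C", "D")
  complete <- pathway_cost(c("r1", "r2", "r3"), u1, targets, "P", 100)$total
  partial_costs <- c(
    pathway_cost("r1", u1, targets, "P", 100)$total,
    pathway_cost(c("r1", "r2"), u1, targets, "P", 100)$total,
    pathway_cost(c("r1", "r3"), u1, targets, "P", 100)$total)
  expect_true(all(complete < partial_costs))
})

test_that("the branching factor averages substrate usage over non-free substrates", {
  u1 <- make_u1()
  expect_identical(branching_factor(c("r1", "r2", "r3"), u1, "P"), 1.5)
  expect_identical(branching_factor(c("r1", "r2"), u1, "P"), 1)
  # P filtered out: A, B, C each used once
  expect_identical(branching_factor(c("r1", "r2", "r4"), u1, "P"), 1)
  upool <- reaction_universe(list(reaction("rp", "P", "Q")))
  expect_error(branching_factor("rp", upool, "P"), "freely available")
  # beta is always >= 1 on random solutions
  for (s in 1:5) {
    rp <- make_random_problem(6, seed = 600 + s)
    path <- bfs_search(rp$problem, rp$initial_available)$pathway
    if (!length(path)) next
    expect_gte(branching_factor(path, rp$universe, rp$problem$free_compounds), 1)
  }
})

test_that("reference comparison computes TP/FP/FN and PR/RC/Acc at both levels", {
  u <- reaction_universe(list(
    reaction("r1", "A", "B"), reaction("r2", "B", "C"),
    reaction("r3", "A", "D"), reaction("r4", "D", "E")))
  identical_rep <- compare_to_reference(c("r1", "r2"), c("r1", "r2"), u, "reactions")
  expect_identical(identical_rep$precision, 1)
  expect_identical(identical_rep$recall, 1)
  expect_identical(identical_rep$accuracy, 1)

  half <- compare_to_reference(c("r1", "r2"), c("r1", "r3"), u, "reactions")
  expect_identical(c(half$tp, half$fp, half$fn), c(1L, 1L, 1L))
  expect_identical(half$precision, 0.5)
  expect_identical(half$recall, 0.5)
  expect_identical(half$accuracy, 0.5)

  disjoint <- compare_to_reference("r1", "r4", u, "compounds")
  expect_identical(disjoint$precision, 0)
  expect_identical(disjoint$accuracy, 0)

  # compound level with free-compound exclusion
  u2 <- reaction_universe(list(reaction("r1", c("A", "P"), "B"),
                               reaction("r2", "A", c("B", "P"))))
  with_free <- compare_to_reference("r1", "r2", u2, "compounds",
                                    free_compounds = "P")
  expect_identical(with_free$precision, 1)  # {A,B} vs {A,B}
  incl <- compare_to_reference("r1", "r2", u2, "compounds",
                               free_compounds = "P", include_free = TRUE)
  expect_identical(incl$precision, 1)  # {A,P,B} vs {A,B,P}

  # reactions compared on parent ids: a reverse direction still matches
  urev <- reaction_universe(c(list(reaction("r1", "A", "B")),
                              split_reversible("r2", "B", "C", "reversible")))
  rev_match <- compare_to_reference(c("r1", "r2_rev"), c("r1", "r2"), urev,
                                    "reactions")
  expect_identical(rev_match$precision, 1)

  expect_error(compare_to_reference("r1", character(), u, "reactions"), "non-empty")
})
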