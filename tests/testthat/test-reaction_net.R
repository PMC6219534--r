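test_that("reaction construction enforces its invariants", {
  r <- reaction("R1", c("A", "B"), "C")
  expect_s3_class(r, "reaction")
  expect_identical(r$parent_id, "R1")
  expect_error(reaction("R1", character(), "C"), "non-empty")
  expect_error(reaction("R1", "A", character()), "non-empty")
  expect_error(reaction("R1", "A", "A"), "never produce a new compound")
  # overlapping but unequal sets (catalytic cycle) are allowed
  expect_silent(reaction("R1", c("A", "B"), c("A", "C")))
})

test_that("splitting on the direction flag yields one or two reactions", {
  fwd <- split_reversible("R1", c("A", "B"), "C", "forward")
  expect_length(fwd, 1L)
  expect_identical(fwd[[1]]$substrates, c("A", "B"))

  both <- split_reversible("R1", "A", c("B", "C"), "reversible")
  expect_length(both, 2L)
  expect_identical(both[[1]]$id, "R1")
  expect_identical(both[[2]]$id, "R1_rev")
  expect_identical(both[[2]]$substrates, c("B", "C"))
  expect_identical(both[[2]]$products, "A")
  expect_identical(both[[1]]$parent_id, "R1")
  expect_identical(both[[2]]$parent_id, "R1")

  expect_error(split_reversible("R1", "A", "A", "reversible"))
})

test_that("the tabular reader parses, splits, and reports errors by line", {
  tmp <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "# comment",
    "R1\tA\tB\tforward",
    "R2\tB\t2 C + D\treversible",
    ""
  ), tmp)
  u <- parse_reaction_table(tmp)
  expect_identical(u$ids, c("R1", "R2", "R2_rev"))
  # stoichiometric coefficient discarded
  expect_identical(u$reactions[["R2"]]$products, c("C", "D"))
  expect_identical(u$reactions[["R2_rev"]]$substrates, c("C", "D"))
  expect_setequal(u$compounds, c("A", "B", "C", "D"))

  writeLines("R1\tA\tA\tforward", tmp)
  expect_error(parse_reaction_table(tmp), "line 1")
  writeLines(c("R1\tA\tB\tforward", "R1\tB\tC\tforward"), tmp)
  expect_error(parse_reaction_table(tmp), "duplicate")
  writeLines("R1\tA\tB", tmp)
  expect_error(parse_reaction_table(tmp), "expected 4")
  writeLines("R1\tA\tB\tboth", tmp)
  expect_error(parse_reaction_table(tmp), "direction")
})

test_that("the JSON dialect is equivalent to the TSV one", {
  tmp <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(
    list(id = "R1", substrates = list("A"), products = list("B"),
         direction = "reversible")
  ), tmp, auto_unbox = TRUE)
  u <- parse_reaction_table(tmp, dialect = "json")
  expect_identical(u$ids, c("R1", "R1_rev"))
})

test_that("splitting count and round-trip properties hold on random tables", {
  set.seed(42)
  for (rep in 1:5) {
    n_fwd <- sample(1:6, 1)
    n_rev <- sample(1:6, 1)
    comp <- sprintf("C%02d", 1:8)
    lines <- character(0)
    for (i in seq_len(n_fwd + n_rev)) {
      subs <- sample(comp, sample(1:2, 1))
      prods <- sample(setdiff(comp, subs), sample(1:2, 1))
      dir <- if (i <= n_fwd) "forward" else "reversible"
      lines <- c(lines, paste(sprintf("R%02d", i),
                              paste(subs, collapse = "+"),
                              paste(prods, collapse = "+"), dir, sep = "\t"))
    }
    tmp <- withr::local_tempfile(fileext = ".tsv")
    writeLines(lines, tmp)
    u <- parse_reaction_table(tmp)
    expect_identical(length(u$ids), n_fwd + 2L * n_rev)
    # round-trip: write directed universe, reparse, identical ids and sets
    tmp2 <- withr::local_tempfile(fileext = ".tsv")
    write_reaction_table(u, tmp2)
    u2 <- parse_reaction_table(tmp2)
    expect_identical(u2$ids, u$ids)
    for (id in u$ids) {
      expect_identical(u2$reactions[[id]]$substrates, u$reactions[[id]]$substrates)
      expect_identical(u2$reactions[[id]]$products, u$reactions[[id]]$products)
    }
  }
})

test_that("search problems validate their compound-set relations", {
  u1 <- make_u1()
  expect_silent(search_problem(u1, c("A", "C"), "A", "P"))
  expect_error(search_problem(u1, c("A", "C"), "B", "P"), "subset of the targets")
  expect_error(search_problem(u1, c("A", "P"), "A", "P"), "freely available")
  expect_error(search_problem(u1, c("A", "Z"), "A", "P"), "no reaction")
})

test_that("pathway export writes ordered JSON and a bipartite DOT graph", {
  pr <- u1_problem()
  tmp <- withr::local_tempfile(fileext = ".json")
  write_pathway(c("r1", "r2", "r3"), pr, tmp, "json", alpha = 100)
  out <- jsonlite::fromJSON(tmp, simplifyVector = FALSE)
  expect_length(out$reactions, 3L)
  expect_identical(out$reactions[[1]]$id, "r1")
  expect_identical(unlist(out$reactions[[2]]$new_compounds), "C")
  expect_equal(out$cost$total, 3)

  dot <- withr::local_tempfile(fileext = ".dot")
  write_pathway(c("r1", "r2", "r3"), pr, dot, "dot")
  lines <- readLines(dot)
  # branched pathway: compound B feeds two reactions
  expect_length(grep("\"cpd:B\" -> ", lines, fixed = TRUE), 2L)
  expect_length(grep("shape=box", lines), 3L)

  # pool substrate flagged as free in the export
  dot2 <- withr::local_tempfile(fileext = ".dot")
  write_pathway(c("r1", "r2", "r4"), pr, dot2, "dot")
  expect_length(grep("cpd:P.*dashed", readLines(dot2)), 1L)

  expect_error(write_pathway(character(), pr, tmp), "empty")
})

test_that("the packaged toy fixtures parse", {
  u <- parse_reaction_table(system.file("extdata", "toy_reactions.tsv",
                                        package = "antpath"))
  expect_identical(u$ids, c("r1", "r2", "r3", "r4"))
  free <- read_free_compounds(system.file("extdata", "toy_free.txt",
                                          package = "antpath"))
  expect_identical(free, "P")
})
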