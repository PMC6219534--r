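# Toy universe used throughout: a chain A -> B with a branch at B and a
# pool-dependent tail reaction. Targets {A, C, D}, initial substrate A,
# free compound P.
make_u1 <- function() {
  reaction_universe(list(
    reaction("r1", "A", "B"),
    reaction("r2", "B", "C"),
    reaction("r3", "B", "D"),
    reaction("r4", c("C", "P"), "E")
  ))
}

u1_problem <- function(universe = make_u1()) {
  search_problem(universe, targets = c("A", "C", "D"),
                 initial_candidates = "A", free_compounds = "P")
}
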