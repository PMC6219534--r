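#' @name synthetic_nets
#' @title Synthetic reaction networks with planted pathways
#' @description
#' Generators for reaction universes built around a known feasible pathway,
#' so that search algorithms can be benchmarked against a ground truth
#' without any database download. The planted pathway is the unique shortest
#' route to the targets by construction: distractor reactions only ever
#' produce fresh compounds, never compounds of the planted chain, so they
#' cannot create shortcuts. Pool compounds emulate currency metabolites:
#' freely available and wired into many distractor reactions (high
#' connectivity degree). Distractor reactions anchored on fresh "lock"
#' compounds stay infeasible until those compounds are handed to the search
#' as extra initially-available material ([grow_available_set()]), which is
#' exactly how enlarging the initial compound set inflates the classical
#' searchers' state space.
NULL

# Fresh-compound factory shared by the generators. Fresh compounds are named
# F0001, F0002, ... to avoid collision with chain ("X"), branch ("B") and
# pool ("P") compounds and with KEGG-style "C" ids in mixed tests.
fresh_factory <- function() {
  env <- new.env(parent = emptyenv())
  env$n <- 0L
  function() {
    env$n <- env$n + 1L
    sprintf("F%04d", env$n)
  }
}

# Distractor machinery shared by the linear and branched generators.
# Each pool compound gets ~pool_degree reactions consuming it together with
# a fresh lock compound (currency-metabolite motif: feasible only once the
# lock is available). General distractors anchor either on a backbone
# compound (live dead-end branches from the start) or on a fresh lock
# (unlocked only by extra available compounds); products are always fresh.
make_decoys <- function(anchors, n_distractors, pool, pool_degree, new_fresh,
                        p_live = 0.3) {
  recs <- list()
  for (p in pool) {
    for (d in seq_len(pool_degree)) {
      recs[[length(recs) + 1L]] <- reaction(
        sprintf("DP_%s_%02d", p, d),
        c(p, new_fresh()), new_fresh())
    }
  }
  for (i in seq_len(n_distractors)) {
    anchor <- if (length(anchors) && stats::runif(1) < p_live)
      sample(anchors, 1L)
    else
      new_fresh()
    subs <- anchor
    if (length(pool) && stats::runif(1) < 0.3) subs <- c(subs, sample(pool, 1L))
    recs[[length(recs) + 1L]] <- reaction(sprintf("DX%03d", i), subs, new_fresh())
  }
  recs
}

#' Generate a linear planted network
#'
#' Builds a chain c0 -> c1 -> ... -> cL of `L` reactions (each may
#' additionally consume a pool compound), then surrounds it with pool-linked
#' and general distractor reactions whose products are always fresh
#' compounds -- so the planted chain remains the unique shortest solution
#' from c0 to cL. Targets are `{c0, cL}` and the sole candidate initial
#' substrate is c0; the minimal available set is just `{c0}` (pool compounds
#' are free).
#'
#' @param L Chain length (number of reactions), >= 1.
#' @param n_distractors Number of general distractor reactions.
#' @param n_pool Number of freely available pool compounds.
#' @param pool_degree Approximate number of distractor reactions wired to
#'   each pool compound.
#' @param seed Optional seed; the same call with the same seed yields an
#'   identical network.
#' @return An object of class `planted_network`: list with `universe`,
#'   `planted_pathway` (reaction ids), `problem` (a [search_problem()]) and
#'   `minimal_available` (compound set sufficient to replay the planted
#'   pathway, together with the free compounds).
#' @export
make_linear_network <- function(L, n_distractors = 0, n_pool = 0,
                                pool_degree = 3, seed = NULL) {
  if (!is.numeric(L) || L < 1) stop("L must be >= 1", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  L <- as.integer(L)
  chain <- sprintf("X%04d", 0:L)
  pool <- if (n_pool > 0) sprintf("P%02d", seq_len(n_pool)) else character()
  new_fresh <- fresh_factory()
  chain_recs <- vector("list", L)
  for (i in seq_len(L)) {
    subs <- chain[i]
    if (length(pool) && stats::runif(1) < 0.5) subs <- c(subs, sample(pool, 1L))
    chain_recs[[i]] <- reaction(sprintf("PLT%02d", i), subs, chain[i + 1L])
  }
  decoys <- make_decoys(chain[-(L + 1L)], n_distractors, pool, pool_degree, new_fresh)
  universe <- reaction_universe(c(chain_recs, decoys))
  problem <- search_problem(universe,
                            targets = c(chain[1L], chain[L + 1L]),
                            initial_candidates = chain[1L],
                            free_compounds = pool)
  structure(list(universe = universe,
                 planted_pathway = sprintf("PLT%02d", seq_len(L)),
                 problem = problem,
                 minimal_available = chain[1L]),
            class = "planted_network")
}

#' Generate a branched planted network
#'
#' A common root compound feeds `length(branch_lengths)` independent chains,
#' each ending in a distinct tip compound. Targets are the root plus the
#' tips; the planted pathway is the concatenation of the branch reactions
#' (so its length is `sum(branch_lengths)`), and its branching factor
#' exceeds 1 because the root is consumed by every branch's first reaction.
#'
#' @param branch_lengths Integer vector (>= 2 branches, each >= 1 reaction).
#' @inheritParams make_linear_network
#' @return A `planted_network` (see [make_linear_network()]).
#' @export
make_branched_network <- function(branch_lengths, n_distractors = 0,
                                  n_pool = 0, pool_degree = 3, seed = NULL) {
  if (length(branch_lengths) < 2L)
    stop("at least 2 branches are required", call. = FALSE)
  if (any(branch_lengths < 1))
    stop("every branch must have length >= 1", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  root <- "X0000"
  pool <- if (n_pool > 0) sprintf("P%02d", seq_len(n_pool)) else character()
  new_fresh <- fresh_factory()
  recs <- list()
  planted <- character()
  tips <- character()
  backbone <- root
  for (b in seq_along(branch_lengths)) {
    Lb <- as.integer(branch_lengths[[b]])
    nodes <- c(root, sprintf("B%d_%02d", b, seq_len(Lb)))
    for (i in seq_len(Lb)) {
      subs <- nodes[i]
      if (length(pool) && stats::runif(1) < 0.5) subs <- c(subs, sample(pool, 1L))
      id <- sprintf("PB%d_%02d", b, i)
      recs[[length(recs) + 1L]] <- reaction(id, subs, nodes[i + 1L])
      planted <- c(planted, id)
    }
    tips <- c(tips, nodes[Lb + 1L])
    backbone <- union(backbone, nodes[-(Lb + 1L)])
  }
  decoys <- make_decoys(backbone, n_distractors, pool, pool_degree, new_fresh)
  universe <- reaction_universe(c(recs, decoys))
  problem <- search_problem(universe,
                            targets = c(root, tips),
                            initial_candidates = root,
                            free_compounds = pool)
  structure(list(universe = universe, planted_pathway = planted,
                 problem = problem, minimal_available = root),
            class = "planted_network")
}

#' @export
print.planted_network <- function(x, ...) {
  cat(sprintf("<planted_network> %d reactions (%d planted), %d targets\n",
              length(x$universe$ids), length(x$planted_pathway),
              length(x$problem$targets)))
  invisible(x)
}

#' Enlarge the initial available set of a planted network
#'
#' Draws `n_extra` compounds (without replacement, seeded) from the
#' universe's compounds that are neither already available, freely
#' available, nor targets, and unions them with the minimal available set.
#' For a fixed seed the drawn sets are nested in `n_extra` (a single random
#' permutation is truncated), so growing `n_extra` strictly enlarges the
#' initial conditions -- the protocol used to show how classical search
#' blows up with the size of the initial compound set.
#'
#' @param net A `planted_network`.
#' @param n_extra Number of extra compounds, >= 0.
#' @param seed Optional seed.
#' @return Character vector: `minimal_available` plus the extras.
#' @export
grow_available_set <- function(net, n_extra, seed = NULL) {
  stopifnot(inherits(net, "planted_network"))
  if (!is.numeric(n_extra) || n_extra < 0) stop("n_extra must be >= 0", call. = FALSE)
  n_extra <- as.integer(n_extra)
  if (n_extra == 0L) return(net$minimal_available)
  # exclude compounds already producible from the minimal set: adding one of
  # those would change the problem itself (shortcutting the planted
  # pathway), whereas the protocol being emulated enlarges the initial
  # conditions around a fixed known solution
  producible <- closure_compounds(net$universe,
                                  union(net$minimal_available,
                                        net$problem$free_compounds))
  candidates <- setdiff(net$universe$compounds,
                        c(producible, net$problem$free_compounds,
                          net$problem$targets))
  if (n_extra > length(candidates))
    stop("n_extra (", n_extra, ") exceeds the ", length(candidates),
         " candidate compounds", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  union(net$minimal_available, sample(candidates)[seq_len(n_extra)])
}

#' Generate a random solvable search problem
#'
#' Builds a random reaction universe in which every reaction consumes at
#' least one previously producible non-free compound (seeded by a start
#' compound), then picks targets from the compounds actually reachable from
#' the start plus the free compounds. The resulting problems are guaranteed
#' solvable by exhaustive search and are used to cross-check the ant search
#' against the breadth-first optimum.
#'
#' @param n_reactions Number of reactions to generate.
#' @param n_free Number of freely available compounds.
#' @param seed Optional seed.
#' @return List with `universe`, `problem`, `initial_available` (the start
#'   compound plus the free compounds) and `start`.
#' @export
make_random_problem <- function(n_reactions = 10, n_free = 1, seed = NULL) {
  if (!is.numeric(n_reactions) || n_reactions < 1)
    stop("n_reactions must be >= 1", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  n_reactions <- as.integer(n_reactions)
  repeat {
    n_comp <- n_reactions + 4L
    comp <- sprintf("X%04d", seq_len(n_comp))
    free <- if (n_free > 0) sprintf("P%02d", seq_len(n_free)) else character()
    start <- comp[1L]
    producible <- start
    recs <- vector("list", n_reactions)
    for (i in seq_len(n_reactions)) {
      base <- if (i == 1L) start else sample(producible, 1L)
      subs <- base
      if (stats::runif(1) < 0.3 && length(free)) subs <- c(subs, sample(free, 1L))
      # reactions consuming the start compound keep their substrates within
      # {start} + free: an ant's first reaction seeds its available set with
      # that reaction's substrates, and granting it an unproducible compound
      # there would let it reach states closed to a search that starts from
      # {start} + free alone
      if (base != start && stats::runif(1) < 0.3) {
        extra <- sample(comp[-1L], 1L)
        if (!extra %in% subs) subs <- c(subs, extra)
      }
      prods <- sample(setdiff(comp, subs), sample(1:2, 1L))
      if (stats::runif(1) < 0.2 && length(setdiff(free, subs)))
        prods <- c(prods, sample(setdiff(free, subs), 1L))
      recs[[i]] <- reaction(sprintf("R%03d", i), subs, prods)
      producible <- union(producible, setdiff(prods, free))
    }
    universe <- reaction_universe(recs)
    reachable <- closure_compounds(universe, c(start, free))
    candidates <- setdiff(reachable, c(start, free))
    if (!length(candidates)) next
    targets <- c(start, sample(candidates, min(sample(1:2, 1L), length(candidates))))
    problem <- search_problem(universe, targets,
                              initial_candidates = start,
                              free_compounds = free)
    return(list(universe = universe, problem = problem,
                initial_available = c(start, free), start = start))
  }
}

# Forward closure of producible compounds (fixpoint over feasibility).
closure_compounds <- function(universe, available) {
  avail <- unique(available)
  repeat {
    added <- FALSE
    for (r in universe$reactions) {
      if (all(r$substrates %in% avail) && !all(r$products %in% avail)) {
        avail <- union(avail, r$products)
        added <- TRUE
      }
    }
    if (!added) break
  }
  avail
}
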