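# Independent oracles used to cross-check the searchers and metrics. These
# deliberately avoid the package's compiled-universe machinery: brute-force
# enumeration over character sets, no deduplication, no pruning beyond
# branch-and-bound on the incumbent.

# Minimum number of reactions over ALL feasible reaction sequences (each
# reaction used at most once), or Inf if the targets are unreachable.
brute_min_len <- function(universe, targets, initial_available) {
  rs <- universe$reactions
  n <- length(rs)
  best <- Inf
  rec <- function(avail, used) {
    if (all(targets %in% avail)) {
      best <<- length(used)
      return(invisible())
    }
    if (length(used) + 1 >= best) return(invisible())
    for (i in seq_len(n)) {
      if (i %in% used) next
      if (!all(rs[[i]]$substrates %in% avail)) next
      rec(union(avail, rs[[i]]$products), c(used, i))
    }
  }
  rec(unique(initial_available), integer(0))
  best
}

# Connectivity re-derived as a single ordered sweep over Reduce(), a code
# path disjoint from the package's loop.
kappa_oracle <- function(pathway, universe, targets, free, alpha) {
  rs <- universe$reactions[pathway]
  seed <- union(intersect(rs[[1]]$substrates, targets),
                setdiff(rs[[1]]$products, free))
  X <- Reduce(function(acc, r) {
    if (length(intersect(acc, r$substrates)))
      union(acc, setdiff(r$products, free))
    else acc
  }, rs[-1], init = seed)
  if (all(targets %in% X)) 1 else alpha
}
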