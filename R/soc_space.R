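#' Set-of-compounds search state
#'
#' In the set-of-compounds (SoC) model a state is the set of currently
#' available compounds together with the ordered list of reactions applied so
#' far. Applying a reaction whose substrates are all available adds its
#' products to the set; compounds are never removed, so the model is
#' monotone and every prefix of a pathway is substrate-feasible by
#' construction.
#'
#' @param available Character vector of available compound ids.
#' @param pathway Character vector of reaction ids applied so far.
#' @return An object of class `soc_state`.
#' @export
soc_state <- function(available, pathway = character()) {
  structure(list(available = unique(as.character(available)),
                 pathway = as.character(pathway)),
            class = "soc_state")
}

#' @export
print.soc_state <- function(x, ...) {
  cat(sprintf("<soc_state> %d compounds available, %d reactions applied\n",
              length(x$available), length(x$pathway)))
  invisible(x)
}

#' Enumerate feasible reactions in a state
#'
#' A reaction is feasible when all of its substrates are available. Reactions
#' already applied in the state's pathway are filtered out: a reaction may
#' appear at most once per pathway (re-applying it could add no compound the
#' state does not already have).
#'
#' @param state A [soc_state()].
#' @param universe A [reaction_universe()].
#' @return Character vector of feasible reaction ids, in universe order
#'   (possibly empty).
#' @export
feasible_reactions <- function(state, universe) {
  keep <- vapply(universe$reactions, function(r) {
    all(r$substrates %in% state$available) && !(r$id %in% state$pathway)
  }, logical(1))
  universe$ids[keep]
}

#' Apply a reaction to a state
#'
#' @param state A [soc_state()].
#' @param r A [reaction()] or a reaction id present in `universe`.
#' @param universe A [reaction_universe()]; required when `r` is an id.
#' @return A new `soc_state` with the reaction's products added and the
#'   reaction appended to the pathway. The input state is unmodified.
#' @export
apply_reaction <- function(state, r, universe = NULL) {
  if (is.character(r)) {
    if (is.null(universe)) stop("a universe is needed to resolve a reaction id", call. = FALSE)
    r <- reactions_by_id(universe, r)[[1L]]
  }
  if (!all(r$substrates %in% state$available))
    stop("reaction '", r$id, "' is not feasible: missing substrate(s) ",
         paste(setdiff(r$substrates, state$available), collapse = ", "),
         call. = FALSE)
  if (r$id %in% state$pathway)
    stop("reaction '", r$id, "' already appears in the pathway", call. = FALSE)
  soc_state(c(state$available, r$products), c(state$pathway, r$id))
}

#' Goal test
#'
#' A state is a goal when every target compound is available.
#'
#' @param state A [soc_state()].
#' @param targets Character vector of target compound ids (an empty set is
#'   vacuously reached).
#' @return Logical scalar.
#' @export
is_goal <- function(state, targets) {
  all(targets %in% state$available)
}

# Internal indexed representation of a universe used by the searchers and
# the ant colony: compounds mapped to integer positions, substrate/product
# index vectors per reaction.
compile_universe <- function(universe) {
  comp <- universe$compounds
  idx <- seq_along(comp)
  names(idx) <- comp
  list(
    comp = comp,
    comp_index = idx,
    ids = universe$ids,
    sub = lapply(universe$reactions, function(r) unname(idx[r$substrates])),
    prod = lapply(universe$reactions, function(r) unname(idx[r$products])),
    parent = vapply(universe$reactions, `[[`, character(1), "parent_id"),
    n = length(comp)
  )
}

# Availability bitmap for a compound set (compounds outside the universe,
# e.g. unused pool compounds, are silently dropped).
avail_vector <- function(cp, compounds) {
  v <- rep(FALSE, cp$n)
  hit <- cp$comp_index[intersect(compounds, cp$comp)]
  v[hit] <- TRUE
  v
}

search_result <- function(found, pathway, states_expanded) {
  structure(list(found = found, pathway = pathway,
                 states_expanded = states_expanded),
            class = "search_result")
}

#' @export
print.search_result <- function(x, ...) {
  if (x$found)
    cat(sprintf("<search_result> solution of %d reaction(s), %d states expanded\n",
                length(x$pathway), x$states_expanded))
  else
    cat(sprintf("<search_result> no solution, %d states expanded\n",
                x$states_expanded))
  invisible(x)
}

#' Breadth-first search over the SoC space
#'
#' Exhaustive breadth-first exploration of the set-of-compounds state space.
#' Returns a goal-reaching pathway with the minimum number of reactions, or
#' reports failure if no state containing all targets is reachable. Visited
#' states are deduplicated on the available-compound set alone: under the
#' monotone model two states with equal compound sets can reach exactly the
#' same compound sets, so the pruning preserves shortest solutions.
#'
#' @param problem A [search_problem()].
#' @param initial_available Character vector of initially available
#'   compounds. The caller composes it, typically as the chosen initial
#'   substrate(s) plus the freely available compounds.
#' @return A `search_result` with fields `found`, `pathway` (character ids or
#'   `NULL`), and `states_expanded` (number of states whose successors were
#'   generated).
#' @export
bfs_search <- function(problem, initial_available) {
  cp <- compile_universe(problem$universe)
  target_idx <- unname(cp$comp_index[problem$targets])
  avail0 <- avail_vector(cp, initial_available)
  if (all(avail0[target_idx]))
    return(search_result(TRUE, character(0), 0L))
  M <- length(cp$ids)
  queue <- vector("list", 64L)
  queue[[1L]] <- list(avail = avail0, path = integer(0))
  head <- 1L; tail <- 1L
  visited <- new.env(hash = TRUE, parent = emptyenv())
  assign(paste(which(avail0), collapse = ","), TRUE, envir = visited)
  expanded <- 0L
  while (head <= tail) {
    node <- queue[[head]]
    queue[head] <- list(NULL)
    head <- head + 1L
    expanded <- expanded + 1L
    for (j in seq_len(M)) {
      if (j %in% node$path) next
      if (!all(node$avail[cp$sub[[j]]])) next
      a2 <- node$avail
      a2[cp$prod[[j]]] <- TRUE
      p2 <- c(node$path, j)
      if (all(a2[target_idx]))
        return(search_result(TRUE, cp$ids[p2], expanded))
      key <- paste(which(a2), collapse = ",")
      if (!exists(key, envir = visited, inherits = FALSE)) {
        assign(key, TRUE, envir = visited)
        tail <- tail + 1L
        if (tail > length(queue)) queue <- c(queue, vector("list", length(queue)))
        queue[[tail]] <- list(avail = a2, path = p2)
      }
    }
  }
  search_result(FALSE, NULL, expanded)
}

#' Depth-limited depth-first search over the SoC space
#'
#' Returns the first goal-reaching pathway found by depth-first exploration
#' bounded at `max_depth` reactions. Children are tried in universe order by
#' default; `shuffle = TRUE` draws one random operator ordering for the whole
#' run (seed it with [set.seed()]), mirroring the randomized-runs protocol
#' used for classical-search baselines.
#'
#' @inheritParams bfs_search
#' @param max_depth Positive integer bound on the pathway length.
#' @param shuffle Randomize the operator ordering once per call.
#' @return A `search_result`; `states_expanded` counts visited nodes.
#' @export
dfs_search <- function(problem, initial_available, max_depth, shuffle = FALSE) {
  if (!is.numeric(max_depth) || length(max_depth) != 1L || max_depth < 1)
    stop("max_depth must be a positive integer", call. = FALSE)
  max_depth <- as.integer(max_depth)
  cp <- compile_universe(problem$universe)
  target_idx <- unname(cp$comp_index[problem$targets])
  order <- seq_along(cp$ids)
  if (shuffle) order <- sample(order)
  expanded <- 0L
  found <- NULL
  recurse <- function(avail, path) {
    expanded <<- expanded + 1L
    if (all(avail[target_idx])) {
      found <<- path
      return(TRUE)
    }
    if (length(path) >= max_depth) return(FALSE)
    for (j in order) {
      if (j %in% path) next
      if (!all(avail[cp$sub[[j]]])) next
      a2 <- avail
      a2[cp$prod[[j]]] <- TRUE
      if (recurse(a2, c(path, j))) return(TRUE)
    }
    FALSE
  }
  recurse(avail_vector(cp, initial_available), integer(0))
  if (is.null(found)) search_result(FALSE, NULL, expanded)
  else search_result(TRUE, cp$ids[found], expanded)
}

#' Replay a pathway from an initial compound set
#'
#' Checks feasibility step by step; errors on the first infeasible step.
#' Useful for validating that any returned pathway is substrate-feasible.
#'
#' @param pathway Character vector of reaction ids.
#' @param universe A [reaction_universe()].
#' @param initial_available Character vector of initially available compounds.
#' @return The final [soc_state()].
#' @export
replay_pathway <- function(pathway, universe, initial_available) {
  state <- soc_state(initial_available)
  for (id in pathway) state <- apply_reaction(state, id, universe)
  state
}
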