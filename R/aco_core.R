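#' Ant-colony search parameters
#'
#' @param n_ants Number of ants per iteration (N_k). Ten ants handle
#'   three-compound problems comfortably; five suffice for simple two-compound
#'   chains.
#' @param rho Pheromone evaporation proportion per iteration, in (0, 1).
#' @param alpha Connectivity penalty separating partial from complete
#'   solutions; the recommended value is `10 * n_ants`.
#' @param max_iterations Hard iteration cap.
#' @param stall_iterations Stop after this many iterations without strict
#'   improvement of the best cost.
#' @param max_steps Walk-length bound per ant; defaults to the number of
#'   reactions in the universe (a walk can never exceed it anyway, since a
#'   reaction is used at most once).
#' @param seed Optional random seed applied at the start of [run_aco()] for
#'   full reproducibility.
#' @return An object of class `aco_params`.
#' @export
aco_params <- function(n_ants = 10, rho = 0.1, alpha = 10 * n_ants,
                       max_iterations = 100, stall_iterations = 20,
                       max_steps = NULL, seed = NULL) {
  if (!is.numeric(n_ants) || n_ants < 1) stop("n_ants must be >= 1", call. = FALSE)
  if (!is.numeric(rho) || rho <= 0 || rho >= 1)
    stop("rho must lie strictly between 0 and 1", call. = FALSE)
  if (!is.numeric(alpha) || alpha <= 1)
    stop("alpha must exceed 1 (it penalizes partial solutions)", call. = FALSE)
  if (!is.numeric(max_iterations) || max_iterations < 1)
    stop("max_iterations must be >= 1", call. = FALSE)
  if (!is.numeric(stall_iterations) || stall_iterations < 1)
    stop("stall_iterations must be >= 1", call. = FALSE)
  if (!is.null(max_steps) && (!is.numeric(max_steps) || max_steps < 1))
    stop("max_steps must be >= 1 when given", call. = FALSE)
  structure(list(n_ants = as.integer(n_ants), rho = rho, alpha = alpha,
                 max_iterations = as.integer(max_iterations),
                 stall_iterations = as.integer(stall_iterations),
                 max_steps = if (is.null(max_steps)) NULL else as.integer(max_steps),
                 seed = seed),
            class = "aco_params")
}

#' Initialize an ant colony
#'
#' Builds the list of initial reactions r0 -- every reaction consuming any
#' candidate initial substrate -- and the pheromone matrix Omega. Omega has
#' one row per reaction plus a virtual start row whose support is exactly
#' r0; all supported entries start at 1, so the first iteration selects
#' uniformly. The colony is an environment: [evaporate()] and [deposit()]
#' update the matrix in place.
#'
#' @param problem A [search_problem()] with non-empty `initial_candidates`.
#' @param params An [aco_params()].
#' @param extra_available Character vector of additional compounds available
#'   to every walk from the start. Unlike the free compounds C, these do not
#'   enter the cleaning/connectivity/productivity formulas; they model extra
#'   initially-available material (e.g. from metabolomic knowledge).
#' @return An object of class `ant_colony` (an environment holding `omega`,
#'   `r0`, the compiled universe and the problem).
#' @export
init_colony <- function(problem, params = aco_params(),
                        extra_available = character()) {
  stopifnot(inherits(problem, "search_problem"))
  if (!length(problem$initial_candidates))
    stop("the set of candidate initial substrates is empty", call. = FALSE)
  cp <- compile_universe(problem$universe)
  M <- length(cp$ids)
  r0_idx <- which(vapply(problem$universe$reactions, function(r) {
    length(intersect(r$substrates, problem$initial_candidates)) > 0L
  }, logical(1)))
  if (!length(r0_idx))
    stop("no reaction uses any candidate initial substrate (",
         paste(problem$initial_candidates, collapse = ", "), ")", call. = FALSE)
  omega <- matrix(1, nrow = M + 1L, ncol = M,
                  dimnames = list(c(".start", cp$ids), cp$ids))
  omega[1L, ] <- 0
  omega[1L, r0_idx] <- 1
  colony <- new.env(parent = emptyenv())
  colony$problem <- problem
  colony$params <- params
  colony$cp <- cp
  colony$r0 <- cp$ids[r0_idx]
  colony$r0_idx <- r0_idx
  colony$omega <- omega
  colony$free_idx <- unname(cp$comp_index[
    intersect(union(problem$free_compounds, extra_available), cp$comp)])
  colony$target_idx <- unname(cp$comp_index[problem$targets])
  class(colony) <- c("ant_colony", "environment")
  colony
}

#' @export
print.ant_colony <- function(x, ...) {
  cat(sprintf("<ant_colony> %d reactions, %d initial reaction(s), %d ants\n",
              length(x$cp$ids), length(x$r0), x$params$n_ants))
  invisible(x)
}

#' Pheromone-proportional reaction selection
#'
#' Draws one candidate with probability proportional to its pheromone
#' weight. Selection is pure pheromone-proportional: no heuristic
#' desirability factor and no exponents.
#'
#' @param weights Positive numeric weights, one per candidate.
#' @param candidates Vector of candidates (reaction ids or indices).
#' @return One element of `candidates`.
#' @export
select_reaction <- function(weights, candidates) {
  if (!length(candidates)) stop("no candidate reactions to select from", call. = FALSE)
  if (length(weights) != length(candidates))
    stop("weights and candidates must have equal length", call. = FALSE)
  if (any(weights <= 0)) stop("all selection weights must be positive", call. = FALSE)
  candidates[[sample.int(length(candidates), 1L, prob = weights)]]
}

#' One ant walk
#'
#' The ant picks its first reaction from r0 using the virtual start row of
#' the pheromone matrix; its available set then starts as that reaction's
#' substrates and products together with the freely available compounds.
#' It then repeatedly selects one feasible unused reaction (weighted by the
#' pheromone row of the last reaction taken) and applies it, until all
#' targets are available, no feasible reaction remains, or the step bound is
#' hit. Failed walks are returned as ordinary non-goal pathways.
#'
#' @param colony An initialized [init_colony()] environment.
#' @return Character vector of reaction ids; feasibility-replayable from the
#'   walk's initial compound set.
#' @export
ant_walk <- function(colony) {
  cp <- colony$cp
  params <- colony$params
  M <- length(cp$ids)
  max_steps <- min(params$max_steps %||% M, M)
  start <- colony$r0_idx[[sample.int(length(colony$r0_idx), 1L,
                                     prob = colony$omega[1L, colony$r0_idx])]]
  avail <- rep(FALSE, cp$n)
  avail[cp$sub[[start]]] <- TRUE
  avail[cp$prod[[start]]] <- TRUE
  avail[colony$free_idx] <- TRUE
  walk <- integer(max_steps)
  walk[1L] <- start
  len <- 1L
  in_walk <- rep(FALSE, M)
  in_walk[start] <- TRUE
  while (!all(avail[colony$target_idx]) && len < max_steps) {
    feas <- integer(0)
    for (j in seq_len(M)) {
      if (!in_walk[j] && all(avail[cp$sub[[j]]])) feas <- c(feas, j)
    }
    if (!length(feas)) break
    w <- colony$omega[walk[len] + 1L, feas]
    nxt <- feas[[sample.int(length(feas), 1L, prob = w)]]
    len <- len + 1L
    walk[len] <- nxt
    in_walk[nxt] <- TRUE
    avail[cp$prod[[nxt]]] <- TRUE
  }
  cp$ids[walk[seq_len(len)]]
}

#' Evaporate pheromone
#'
#' Multiplies every pheromone entry by `1 - rho`, emulating the natural loss
#' of trail information. Entries never reach zero, so no transition is ever
#' permanently ruled out.
#'
#' @param colony An [init_colony()] environment (updated in place).
#' @param rho Evaporation proportion; defaults to the colony's parameter.
#' @export
evaporate <- function(colony, rho = NULL) {
  rho <- rho %||% colony$params$rho
  if (!is.numeric(rho) || rho <= 0 || rho >= 1)
    stop("rho must lie strictly between 0 and 1", call. = FALSE)
  colony$omega <- colony$omega * (1 - rho)
  invisible(colony)
}

#' Deposit pheromone along a pathway
#'
#' Adds 1/f to the virtual-start entry of the pathway's first reaction and
#' to every consecutive-pair entry, so cheaper pathways reinforce their
#' transitions more strongly. An empty pathway (a walk that cleaning
#' emptied) deposits nothing.
#'
#' @param colony An [init_colony()] environment (updated in place).
#' @param pathway Character vector of reaction ids (typically cleaned).
#' @param cost Positive total cost f of the pathway.
#' @export
deposit <- function(colony, pathway, cost) {
  if (!length(pathway)) return(invisible(colony))
  if (!is.numeric(cost) || cost <= 0) stop("cost must be positive", call. = FALSE)
  idx <- match(pathway, colony$cp$ids)
  if (anyNA(idx)) stop("pathway contains reactions unknown to the colony", call. = FALSE)
  q <- 1 / cost
  colony$omega[1L, idx[1L]] <- colony$omega[1L, idx[1L]] + q
  if (length(idx) > 1L) {
    pairs <- cbind(idx[-length(idx)] + 1L, idx[-1L])
    colony$omega[pairs] <- colony$omega[pairs] + q
  }
  invisible(colony)
}

#' Run the ant-colony pathway search
#'
#' Each iteration, `n_ants` ants walk independently; every walk is cleaned
#' ([clean_pathway()]) and costed ([pathway_cost()]); pheromone then
#' evaporates and every non-empty cleaned pathway deposits 1/f along its
#' transitions. The best-so-far pathway is updated on strict cost
#' improvement (first-found wins on ties, for determinism). The search stops
#' at `max_iterations` or once the best cost has not improved for
#' `stall_iterations` consecutive iterations.
#'
#' If no ant ever connects all targets the best partial pathway is returned
#' with `complete = FALSE` (its cost carries kappa = alpha) rather than an
#' error.
#'
#' @param problem A [search_problem()].
#' @param params An [aco_params()]; `params$seed`, when non-NULL, makes the
#'   run fully reproducible.
#' @param extra_available Extra initially-available compounds handed to
#'   every walk (see [init_colony()]); kept out of the free-compound set so
#'   the cost formulas are unaffected.
#' @return An object of class `aco_result`: list with `pathway` (character
#'   ids, cleaned), `cost` (a `cost_breakdown` or `NULL` when no ant
#'   produced a scoreable pathway), `complete` (all targets connected),
#'   `iterations`, and `history` (data frame of per-iteration best and mean
#'   cost).
#' @export
run_aco <- function(problem, params = aco_params(), extra_available = character()) {
  stopifnot(inherits(problem, "search_problem"))
  if (!inherits(params, "aco_params")) stop("params must come from aco_params()", call. = FALSE)
  if (!is.null(params$seed)) set.seed(params$seed)
  colony <- init_colony(problem, params, extra_available)
  best <- NULL
  best_total <- Inf
  stall <- 0L
  hist_iter <- integer(0)
  hist_best <- numeric(0)
  hist_mean <- numeric(0)
  iterations <- 0L
  for (it in seq_len(params$max_iterations)) {
    iterations <- it
    deposits <- vector("list", params$n_ants)
    totals <- rep(NA_real_, params$n_ants)
    improved <- FALSE
    for (k in seq_len(params$n_ants)) {
      raw <- ant_walk(colony)
      cleaned <- clean_pathway(raw, problem$universe, problem$targets,
                               problem$free_compounds)
      if (!length(cleaned)) next
      cb <- pathway_cost(cleaned, problem$universe, problem$targets,
                         problem$free_compounds, params$alpha)
      deposits[[k]] <- list(pathway = cleaned, total = cb$total)
      totals[k] <- cb$total
      if (cb$total < best_total) {
        best <- list(pathway = cleaned, cost = cb)
        best_total <- cb$total
        improved <- TRUE
      }
    }
    evaporate(colony)
    for (d in deposits) if (!is.null(d)) deposit(colony, d$pathway, d$total)
    hist_iter <- c(hist_iter, it)
    hist_best <- c(hist_best, if (is.finite(best_total)) best_total else NA_real_)
    hist_mean <- c(hist_mean, if (all(is.na(totals))) NA_real_ else mean(totals, na.rm = TRUE))
    stall <- if (improved) 0L else stall + 1L
    if (stall >= params$stall_iterations) break
  }
  structure(list(
    pathway = if (is.null(best)) character(0) else best$pathway,
    cost = if (is.null(best)) NULL else best$cost,
    complete = !is.null(best) && best$cost$kappa == 1,
    iterations = iterations,
    history = data.frame(iteration = hist_iter, best_cost = hist_best,
                         mean_cost = hist_mean),
    params = params
  ), class = "aco_result")
}

#' @export
print.aco_result <- function(x, ...) {
  if (!length(x$pathway)) {
    cat(sprintf("<aco_result> no scoreable pathway after %d iteration(s)\n",
                x$iterations))
  } else {
    cat(sprintf("<aco_result> %s pathway of %d reaction(s), cost %g, %d iteration(s)\n",
                if (x$complete) "complete" else "partial",
                length(x$pathway), x$cost$total, x$iterations))
    cat("  ", paste(x$pathway, collapse = " -> "), "\n")
  }
  invisible(x)
}
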