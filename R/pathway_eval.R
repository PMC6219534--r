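#' Remove unnecessary reactions from a pathway
#'
#' Cleaning discards, repeatedly until a fixed point, every reaction whose
#' non-free products neither contain a target nor are consumed by any
#' retained reaction occurring later in the pathway. This removes dead-end
#' detours (products used by nothing) and reactions that only produce freely
#' available compounds. The relative order of the retained reactions is
#' preserved, and the result replays feasibly from the same initial compound
#' set: a removed reaction's non-free products are, by the removal rule, not
#' consumed by anything retained.
#'
#' @param pathway Character vector of reaction ids (may be empty).
#' @param universe A [reaction_universe()].
#' @param targets Character vector D of target compounds.
#' @param free_compounds Character vector C of freely available compounds.
#' @return The cleaned pathway (character vector, possibly empty).
#' @export
clean_pathway <- function(pathway, universe, targets,
                          free_compounds = character()) {
  if (!length(pathway)) return(character(0))
  rs <- reactions_by_id(universe, pathway)
  n <- length(pathway)
  keep <- rep(TRUE, n)
  repeat {
    changed <- FALSE
    for (i in rev(seq_len(n))) {
      if (!keep[i]) next
      useful <- setdiff(rs[[i]]$products, free_compounds)
      if (length(intersect(useful, targets))) next
      later <- which(keep)
      later <- later[later > i]
      consumed <- FALSE
      for (j in later) {
        if (length(intersect(useful, rs[[j]]$substrates))) { consumed <- TRUE; break }
      }
      if (!consumed) {
        keep[i] <- FALSE
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  pathway[keep]
}

#' Count direction-agnostic unique reactions
#'
#' Counts distinct underlying reactions (`parent_id`s) in a pathway. The
#' forward and reverse halves of a reversible reaction share a parent, so a
#' pathway using both directions of the same reaction counts it once --
#' which is exactly what the cost function penalizes.
#'
#' @inheritParams clean_pathway
#' @return Non-negative integer count.
#' @export
count_unique <- function(pathway, universe) {
  if (!length(pathway)) return(0L)
  rs <- reactions_by_id(universe, pathway)
  length(unique(vapply(rs, `[[`, character(1), "parent_id")))
}

#' Count reactions producing new non-free compounds
#'
#' A position i is productive when the reaction's products, minus everything
#' produced by earlier positions and minus the freely available compounds,
#' are non-empty. A pathway in which every reaction is productive wastes no
#' step re-synthesizing known material.
#'
#' @inheritParams clean_pathway
#' @return Non-negative integer count.
#' @export
count_productive <- function(pathway, universe, free_compounds = character()) {
  if (!length(pathway)) return(0L)
  rs <- reactions_by_id(universe, pathway)
  produced <- character()
  n_prod <- 0L
  for (r in rs) {
    new <- setdiff(setdiff(r$products, produced), free_compounds)
    if (length(new)) n_prod <- n_prod + 1L
    produced <- union(produced, r$products)
  }
  n_prod
}

#' Connectivity of a pathway to its targets
#'
#' Propagates the set X of compounds synthesized in a chain reachable from
#' the initial substrate: X starts as the first reaction's target substrates
#' together with its non-free products, and each subsequent reaction that
#' consumes anything already in X contributes its non-free products. The
#' pathway is fully connected (kappa = 1) when every target ends up in X;
#' otherwise kappa = `alpha`, the penalty constant separating partial from
#' complete solutions. With alpha >> 1 complete solutions always cost less,
#' so the colony is driven toward pathways that relate all targets.
#'
#' @inheritParams clean_pathway
#' @param alpha Positive penalty for partial connectivity (recommended
#'   10 times the number of ants).
#' @return `1` or `alpha`.
#' @export
connectivity <- function(pathway, universe, targets,
                         free_compounds = character(), alpha = 100) {
  if (!length(pathway)) stop("connectivity of an empty pathway is undefined", call. = FALSE)
  if (!length(targets)) stop("connectivity needs a non-empty target set", call. = FALSE)
  if (!is.numeric(alpha) || alpha <= 0) stop("alpha must be positive", call. = FALSE)
  rs <- reactions_by_id(universe, pathway)
  X <- union(intersect(rs[[1L]]$substrates, targets),
             setdiff(rs[[1L]]$products, free_compounds))
  for (i in seq_along(rs)[-1L]) {
    if (length(intersect(X, rs[[i]]$substrates)))
      X <- union(X, setdiff(rs[[i]]$products, free_compounds))
  }
  if (length(intersect(X, targets)) == length(unique(targets))) 1 else alpha
}

#' Four-component pathway cost
#'
#' The cost combines the pathway length L, the number of direction-agnostic
#' unique reactions u, the number of productive reactions p, and the
#' connectivity kappa:
#'
#'   f = kappa * (3L - u - p)
#'
#' For an ideal pathway (every reaction unique and productive, all targets
#' connected) this reduces to L, pure shortest-path pressure; each fully
#' redundant reaction adds 2 on top of its length contribution; and kappa
#' multiplies the whole term, so with alpha >> 1 any complete solution beats
#' any partial one. The combination is isolated here: any strictly monotone
#' alternative preserves the search's ordering behaviour.
#'
#' @inheritParams connectivity
#' @return An object of class `cost_breakdown`: list with `length`,
#'   `n_unique`, `n_productive`, `kappa`, `total`.
#' @export
pathway_cost <- function(pathway, universe, targets,
                         free_compounds = character(), alpha = 100) {
  if (!length(pathway)) stop("cost of an empty pathway is undefined", call. = FALSE)
  L <- length(pathway)
  u <- count_unique(pathway, universe)
  p <- count_productive(pathway, universe, free_compounds)
  kappa <- connectivity(pathway, universe, targets, free_compounds, alpha)
  structure(list(length = L, n_unique = u, n_productive = p,
                 kappa = kappa, total = kappa * (3 * L - u - p)),
            class = "cost_breakdown")
}

#' @export
print.cost_breakdown <- function(x, ...) {
  cat(sprintf("<cost_breakdown> length=%d unique=%d productive=%d kappa=%g total=%g\n",
              x$length, x$n_unique, x$n_productive, x$kappa, x$total))
  invisible(x)
}

#' Branching factor of a pathway
#'
#' The average number of pathway reactions consuming each non-free
#' substrate. A strictly linear chain has branching factor 1; a value above
#' 1 signals that some compound feeds two or more reactions, i.e. the
#' pathway is branched.
#'
#' @inheritParams clean_pathway
#' @return Numeric >= 1.
#' @export
branching_factor <- function(pathway, universe, free_compounds = character()) {
  if (!length(pathway)) stop("branching factor of an empty pathway is undefined", call. = FALSE)
  rs <- reactions_by_id(universe, pathway)
  all_subs <- unique(unlist(lapply(rs, `[[`, "substrates")))
  sf <- setdiff(all_subs, free_compounds)
  if (!length(sf))
    stop("branching factor undefined: every substrate is freely available", call. = FALSE)
  uses <- vapply(sf, function(s) {
    sum(vapply(rs, function(r) s %in% r$substrates, logical(1)))
  }, numeric(1))
  mean(uses)
}

#' Compare a pathway to a reference pathway
#'
#' Computes true/false positives and false negatives over either the
#' reaction sets (direction-agnostic `parent_id`s) or the compound sets
#' (all substrates and products) of the two pathways, and from them
#' precision PR = TP/(TP+FP), recall RC = TP/(TP+FN) and accuracy
#' Acc = (PR+RC)/2. Freely available compounds are excluded from both sides
#' by default, since reference listings usually omit currency metabolites;
#' set `include_free = TRUE` to keep them.
#'
#' @param pathway Character vector of reaction ids (the synthesized pathway).
#' @param reference Character vector of reaction ids (the reference pathway,
#'   non-empty).
#' @param universe A [reaction_universe()] containing both pathways'
#'   reactions.
#' @param level `"reactions"` or `"compounds"`.
#' @param free_compounds Character vector C, used at the compound level.
#' @param include_free Keep freely available compounds in the compound sets.
#' @return An object of class `comparison_report`: list with `level`, `tp`,
#'   `fp`, `fn`, `precision`, `recall`, `accuracy`.
#' @export
compare_to_reference <- function(pathway, reference, universe,
                                 level = c("reactions", "compounds"),
                                 free_compounds = character(),
                                 include_free = FALSE) {
  level <- match.arg(level)
  if (!length(reference)) stop("reference pathway must be non-empty", call. = FALSE)
  elements <- function(ids) {
    if (!length(ids)) return(character(0))
    rs <- reactions_by_id(universe, ids)
    if (level == "reactions") {
      unique(vapply(rs, `[[`, character(1), "parent_id"))
    } else {
      cpds <- unique(unlist(lapply(rs, function(r) c(r$substrates, r$products))))
      if (include_free) cpds else setdiff(cpds, free_compounds)
    }
  }
  synth <- elements(pathway)
  ref <- elements(reference)
  tp <- length(intersect(synth, ref))
  fp <- length(setdiff(synth, ref))
  fn <- length(setdiff(ref, synth))
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  recall <- if (tp + fn > 0) tp / (tp + fn) else 0
  structure(list(level = level, tp = tp, fp = fp, fn = fn,
                 precision = precision, recall = recall,
                 accuracy = (precision + recall) / 2),
            class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, ...) {
  cat(sprintf("<comparison_report:%s> TP=%d FP=%d FN=%d PR=%.3f RC=%.3f Acc=%.3f\n",
              x$level, x$tp, x$fp, x$fn, x$precision, x$recall, x$accuracy))
  invisible(x)
}
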