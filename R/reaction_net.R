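#' Construct a directed reaction
#'
#' A reaction is a directed transformation between two sets of compounds,
#' written S(r) -> P(r). Stoichiometric coefficients are deliberately ignored:
#' all downstream machinery (feasibility, cleaning, connectivity, branching)
#' is defined on compound *sets*. A reversible biochemical reaction is
#' represented as two independent directed reactions sharing a `parent_id`
#' (see [split_reversible()]).
#'
#' @param id Unique reaction identifier, e.g. `"R01288"` or `"R01288_rev"`.
#' @param substrates Character vector of substrate compound identifiers.
#' @param products Character vector of product compound identifiers.
#' @param parent_id Identifier of the underlying (possibly reversible)
#'   reaction; both directions of a reversible reaction share it. Defaults to
#'   `id`.
#' @return An object of class `reaction`: a list with fields `id`,
#'   `parent_id`, `substrates`, `products`.
#' @details Substrates and products must be non-empty. A reaction whose
#'   substrate set equals its product set is rejected: it can never produce a
#'   new compound, so it can never contribute to a pathway. Overlapping (but
#'   unequal) substrate/product sets are permitted, as in catalytic cycles.
#' @examples
#' reaction("R1", c("C00103"), c("C00092"))
#' @export
reaction <- function(id, substrates, products, parent_id = id) {
  if (!is.character(id) || length(id) != 1L || !nzchar(id))
    stop("reaction id must be a single non-empty string", call. = FALSE)
  substrates <- unique(as.character(substrates))
  products <- unique(as.character(products))
  if (length(substrates) == 0L || any(!nzchar(substrates)))
    stop("reaction '", id, "': substrates must be non-empty", call. = FALSE)
  if (length(products) == 0L || any(!nzchar(products)))
    stop("reaction '", id, "': products must be non-empty", call. = FALSE)
  if (setequal(substrates, products))
    stop("reaction '", id, "': substrates equal products; ",
         "such a reaction can never produce a new compound", call. = FALSE)
  structure(
    list(id = id, parent_id = parent_id,
         substrates = substrates, products = products),
    class = "reaction"
  )
}

#' @export
print.reaction <- function(x, ...) {
  cat(sprintf("<reaction %s> %s -> %s\n", x$id,
              paste(x$substrates, collapse = " + "),
              paste(x$products, collapse = " + ")))
  invisible(x)
}

#' Collect reactions into a universe
#'
#' A reaction universe is the list R of directed reactions available to build
#' pathways, together with the set of all compounds they mention.
#'
#' @param reactions List of [reaction()] objects (order is preserved; the
#'   searchers enumerate operators in this order).
#' @return An object of class `reaction_universe` with fields `reactions`
#'   (named list), `ids` (character vector in input order) and `compounds`
#'   (sorted character vector of every compound appearing in any reaction).
#' @export
reaction_universe <- function(reactions) {
  if (!length(reactions)) stop("a universe needs at least one reaction", call. = FALSE)
  ok <- vapply(reactions, inherits, logical(1), what = "reaction")
  if (!all(ok)) stop("all elements must be reaction objects", call. = FALSE)
  ids <- vapply(reactions, `[[`, character(1), "id")
  dup <- ids[duplicated(ids)]
  if (length(dup))
    stop("duplicate reaction id(s): ", paste(unique(dup), collapse = ", "), call. = FALSE)
  names(reactions) <- ids
  compounds <- sort(unique(unlist(lapply(reactions, function(r) c(r$substrates, r$products)))))
  structure(list(reactions = reactions, ids = unname(ids), compounds = compounds),
            class = "reaction_universe")
}

#' @export
print.reaction_universe <- function(x, ...) {
  cat(sprintf("<reaction_universe> %d reactions over %d compounds\n",
              length(x$ids), length(x$compounds)))
  invisible(x)
}

# Look up reactions by id, with a clear error for unknown ids.
reactions_by_id <- function(universe, ids) {
  missing <- setdiff(ids, universe$ids)
  if (length(missing))
    stop("unknown reaction id(s): ", paste(missing, collapse = ", "), call. = FALSE)
  universe$reactions[ids]
}

#' Split a reaction record on its direction flag
#'
#' Reversible reactions are modelled as a pair of independent reactions with
#' opposite direction. The reverse direction gets the suffix `"_rev"` on its
#' id; both halves share the original id as `parent_id`, so that
#' direction-agnostic bookkeeping (e.g. [count_unique()]) can recognize a
#' pathway using both directions of the same underlying reaction.
#'
#' @param id Reaction identifier from the input record.
#' @param substrates,products Character vectors of compound identifiers.
#' @param direction Either `"forward"` or `"reversible"`.
#' @return A list of one (`forward`) or two (`reversible`) [reaction()]
#'   objects.
#' @export
split_reversible <- function(id, substrates, products, direction) {
  direction <- match.arg(direction, c("forward", "reversible"))
  fwd <- reaction(id, substrates, products)
  if (direction == "forward") return(list(fwd))
  list(fwd, reaction(paste0(id, "_rev"), products, substrates, parent_id = id))
}

# Parse a "+"-separated compound list, discarding optional integer
# stoichiometric coefficients ("2 C00002" -> "C00002").
parse_compound_list <- function(text) {
  parts <- trimws(strsplit(text, "+", fixed = TRUE)[[1L]])
  parts <- sub("^[0-9]+\\s+", "", parts)
  parts[nzchar(parts)]
}

#' Read a reaction table
#'
#' Reads the tabular reaction format: one record per line,
#' `id <TAB> substrates <TAB> products <TAB> direction`, where substrates and
#' products are `+`-separated compound ids (an optional integer coefficient
#' prefix like `2 C00002` is accepted and discarded), direction is `forward`
#' or `reversible`, and `#` starts a comment line. A JSON array of objects
#' with the same four fields is accepted as an alternative dialect.
#'
#' Every reversible record is split into a pair of opposite directed
#' reactions (see [split_reversible()]), so the returned universe contains
#' only directed reactions: `n_forward + 2 * n_reversible` in total.
#'
#' @param file Path to the reaction table (or a connection for `tsv`).
#' @param dialect `"tsv"` (default) or `"json"`.
#' @return A [reaction_universe()].
#' @export
parse_reaction_table <- function(file, dialect = c("tsv", "json")) {
  dialect <- match.arg(dialect)
  records <- if (dialect == "tsv") read_reaction_tsv(file) else read_reaction_json(file)
  reactions <- list()
  for (rec in records) {
    split <- tryCatch(
      split_reversible(rec$id, rec$substrates, rec$products, rec$direction),
      error = function(e) stop("line ", rec$line, ": ", conditionMessage(e), call. = FALSE)
    )
    reactions <- c(reactions, split)
  }
  ids <- vapply(reactions, `[[`, character(1), "id")
  if (anyDuplicated(ids)) {
    dup <- unique(ids[duplicated(ids)])
    stop("duplicate reaction id(s): ", paste(dup, collapse = ", "), call. = FALSE)
  }
  reaction_universe(reactions)
}

read_reaction_tsv <- function(file) {
  if (is.character(file) && !file.exists(file))
    stop("reaction table not found: ", file, call. = FALSE)
  lines <- readLines(file, warn = FALSE)
  records <- list()
  for (i in seq_along(lines)) {
    line <- lines[[i]]
    if (!nzchar(trimws(line)) || startsWith(trimws(line), "#")) next
    fields <- strsplit(line, "\t", fixed = TRUE)[[1L]]
    if (length(fields) != 4L)
      stop("line ", i, ": expected 4 tab-separated fields, got ", length(fields),
           call. = FALSE)
    direction <- trimws(fields[4L])
    if (!direction %in% c("forward", "reversible"))
      stop("line ", i, ": direction must be 'forward' or 'reversible', got '",
           direction, "'", call. = FALSE)
    subs <- parse_compound_list(fields[2L])
    prods <- parse_compound_list(fields[3L])
    if (!length(subs) || !length(prods))
      stop("line ", i, ": empty substrate or product list", call. = FALSE)
    records[[length(records) + 1L]] <- list(
      id = trimws(fields[1L]), substrates = subs, products = prods,
      direction = direction, line = i)
  }
  if (!length(records)) stop("no reaction records found", call. = FALSE)
  records
}

read_reaction_json <- function(file) {
  raw <- jsonlite::fromJSON(file, simplifyVector = FALSE)
  lapply(seq_along(raw), function(i) {
    rec <- raw[[i]]
    for (f in c("id", "substrates", "products", "direction"))
      if (is.null(rec[[f]]))
        stop("record ", i, ": missing field '", f, "'", call. = FALSE)
    list(id = rec$id,
         substrates = unlist(rec$substrates, use.names = FALSE),
         products = unlist(rec$products, use.names = FALSE),
         direction = rec$direction, line = i)
  })
}

#' Write a reaction table
#'
#' Writes a universe back to the tabular format read by
#' [parse_reaction_table()]. Directed reactions are written as `forward`
#' records, so parsing the output reproduces ids, substrate sets and product
#' sets exactly.
#'
#' @param universe A [reaction_universe()].
#' @param file Output path or connection.
#' @export
write_reaction_table <- function(universe, file) {
  lines <- vapply(universe$reactions, function(r) {
    paste(r$id, paste(r$substrates, collapse = "+"),
          paste(r$products, collapse = "+"), "forward", sep = "\t")
  }, character(1))
  writeLines(unname(lines), file)
  invisible(universe)
}

#' Read a free-compounds file
#'
#' One compound id per line; `#` comments and blank lines are skipped. These
#' are the freely available ("pool") compounds C -- ubiquitous metabolites
#' such as water, ATP and NAD that are assumed present without synthesis.
#'
#' @param file Path to the file.
#' @return Character vector of compound ids.
#' @export
read_free_compounds <- function(file) {
  lines <- trimws(readLines(file, warn = FALSE))
  lines[nzchar(lines) & !startsWith(lines, "#")]
}

#' Define a pathway-search problem
#'
#' Bundles the four inputs of the search: the reaction universe R, the target
#' compounds D to relate, the candidate initial substrates I (a subset of the
#' targets from which the pathway may start), and the freely available
#' compounds C.
#'
#' @param universe A [reaction_universe()].
#' @param targets Character vector D of compounds the pathway must relate.
#' @param initial_candidates Character vector I of candidate initial
#'   substrates; must be a subset of `targets`. Pass `targets` itself to let
#'   the search choose the best start ("automatic" initialization).
#' @param free_compounds Character vector C of freely available compounds.
#'   Must be disjoint from `targets`: a freely available compound needs no
#'   synthesis.
#' @return An object of class `search_problem`.
#' @export
search_problem <- function(universe, targets, initial_candidates,
                           free_compounds = character()) {
  stopifnot(inherits(universe, "reaction_universe"))
  targets <- unique(as.character(targets))
  initial_candidates <- unique(as.character(initial_candidates))
  free_compounds <- unique(as.character(free_compounds))
  if (!length(targets)) stop("targets must be non-empty", call. = FALSE)
  if (!all(initial_candidates %in% targets))
    stop("initial candidates must be a subset of the targets", call. = FALSE)
  clash <- intersect(targets, free_compounds)
  if (length(clash))
    stop("compound(s) ", paste(clash, collapse = ", "),
         " are both targets and freely available; a free compound cannot be a ",
         "synthesis target", call. = FALSE)
  absent <- setdiff(targets, universe$compounds)
  if (length(absent))
    stop("target(s) ", paste(absent, collapse = ", "),
         " appear in no reaction of the universe", call. = FALSE)
  structure(list(universe = universe, targets = targets,
                 initial_candidates = initial_candidates,
                 free_compounds = free_compounds),
            class = "search_problem")
}

#' @export
print.search_problem <- function(x, ...) {
  cat(sprintf(paste0("<search_problem> %d targets, %d initial candidates, ",
                     "%d free compounds, %d reactions\n"),
              length(x$targets), length(x$initial_candidates),
              length(x$free_compounds), length(x$universe$ids)))
  invisible(x)
}

#' Write a pathway to JSON or DOT
#'
#' The JSON form lists the reactions in order with, for each step, the
#' compounds newly produced relative to what was available before the step
#' (freely available compounds and the first reaction's substrates count as
#' available from the start), plus the cost breakdown. The DOT form is a
#' bipartite graph -- ellipse nodes for compounds, box nodes for reactions,
#' edges substrate -> reaction -> product -- with freely available compounds
#' drawn dashed and grey.
#'
#' @param pathway Character vector of reaction ids (non-empty).
#' @param problem The [search_problem()] the pathway solves.
#' @param file Output path or connection.
#' @param format `"json"` or `"dot"`.
#' @param alpha Connectivity penalty used in the cost breakdown embedded in
#'   the JSON output.
#' @export
write_pathway <- function(pathway, problem, file, format = c("json", "dot"),
                          alpha = 100) {
  format <- match.arg(format)
  if (!length(pathway)) stop("cannot write an empty pathway", call. = FALSE)
  rs <- reactions_by_id(problem$universe, pathway)
  if (format == "json") {
    avail <- union(problem$free_compounds, rs[[1L]]$substrates)
    steps <- vector("list", length(pathway))
    for (i in seq_along(pathway)) {
      new <- setdiff(rs[[i]]$products, avail)
      avail <- union(avail, rs[[i]]$products)
      steps[[i]] <- list(id = rs[[i]]$id, parent_id = rs[[i]]$parent_id,
                         substrates = rs[[i]]$substrates,
                         products = rs[[i]]$products,
                         new_compounds = new)
    }
    cb <- pathway_cost(pathway, problem$universe, problem$targets,
                       problem$free_compounds, alpha)
    out <- list(
      targets = problem$targets,
      free_compounds = problem$free_compounds,
      reactions = steps,
      cost = unclass(cb)
    )
    jsonlite::write_json(out, file, auto_unbox = TRUE, pretty = TRUE)
  } else {
    compounds <- unique(unlist(lapply(rs, function(r) c(r$substrates, r$products))))
    lines <- c("digraph pathway {", "  rankdir=LR;")
    for (cpd in compounds) {
      style <- if (cpd %in% problem$free_compounds)
        " [shape=ellipse, style=dashed, color=grey, label=\"%s\"]"
      else
        " [shape=ellipse, label=\"%s\"]"
      lines <- c(lines, sprintf(paste0("  \"cpd:%s\"", style), cpd, cpd))
    }
    for (r in rs)
      lines <- c(lines, sprintf("  \"rxn:%s\" [shape=box, label=\"%s\"]", r$id, r$id))
    for (r in rs) {
      lines <- c(lines,
                 sprintf("  \"cpd:%s\" -> \"rxn:%s\"", r$substrates, r$id),
                 sprintf("  \"rxn:%s\" -> \"cpd:%s\"", r$id, r$products))
    }
    lines <- c(lines, "}")
    writeLines(lines, file)
  }
  invisible(pathway)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
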