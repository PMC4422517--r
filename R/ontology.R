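# Ontology: directed acyclic graph of phenotype terms linked by is-a edges,
# with a reflexive-transitive ancestor closure precomputed at load time.

#' Construct an ontology from term ids, names and parent lists
#'
#' Low-level constructor shared by [load_obo()], [extend_ontology()] and the
#' simulator. Validates that every parent reference resolves and that the
#' is-a graph is acyclic, then computes the reflexive-transitive ancestor
#' closure in topological order.
#'
#' @param ids character vector of unique term identifiers.
#' @param names character vector of human-readable labels (recycled to
#'   `ids` if length 1).
#' @param parents named list mapping each id to a character vector of parent
#'   ids (empty vector for roots).
#' @param aliases named character vector mapping alternative ids to
#'   canonical ids (may be empty).
#'
#' @return An object of class `"ontology"`: a list with elements `ids`,
#'   `name`, `parents`, `children`, `ancestors` (reflexive closure),
#'   `roots` and `aliases`.
#' @export
new_ontology <- function(ids, names = ids, parents, aliases = character()) {
  ids <- as.character(ids)
  if (anyDuplicated(ids)) {
    stop("duplicate term ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  if (length(names) == 1L) names <- rep(names, length(ids))
  names(names) <- ids
  parents <- parents[ids]
  names(parents) <- ids
  parents <- lapply(parents, function(p) unique(as.character(p)))

  dangling <- setdiff(unlist(parents, use.names = FALSE), ids)
  if (length(dangling)) {
    stop("is_a target(s) not found in ontology: ",
         paste(sort(dangling), collapse = ", "))
  }

  ord <- topo_sort(ids, parents)   # errors on a cycle

  ancestors <- vector("list", length(ids))
  names(ancestors) <- ids
  for (id in ord) {
    ps <- parents[[id]]
    ancestors[[id]] <- unique(c(id, unlist(ancestors[ps], use.names = FALSE)))
  }

  children <- lapply(ids, function(i) character())
  names(children) <- ids
  for (id in ids) {
    for (p in parents[[id]]) children[[p]] <- c(children[[p]], id)
  }

  structure(
    list(
      ids = ids,
      name = names,
      parents = parents,
      children = children,
      ancestors = ancestors,
      roots = ids[lengths(parents) == 0L],
      aliases = aliases
    ),
    class = "ontology"
  )
}

# Kahn's algorithm; stops with one cycle member named on failure.
topo_sort <- function(ids, parents) {
  indeg <- lengths(parents)
  names(indeg) <- ids
  children <- new.env(parent = emptyenv())
  for (id in ids) {
    for (p in parents[[id]]) {
      assign(p, c(get0(p, envir = children, ifnotfound = character()), id),
             envir = children)
    }
  }
  queue <- ids[indeg == 0L]
  out <- character(0)
  while (length(queue)) {
    v <- queue[[1L]]
    queue <- queue[-1L]
    out <- c(out, v)
    for (ch in get0(v, envir = children, ifnotfound = character())) {
      indeg[[ch]] <- indeg[[ch]] - 1L
      if (indeg[[ch]] == 0L) queue <- c(queue, ch)
    }
  }
  if (length(out) != length(ids)) {
    bad <- setdiff(ids, out)
    stop("cycle detected in is-a graph involving term: ", bad[[1L]])
  }
  out
}

#' @export
print.ontology <- function(x, ...) {
  cat("Ontology with", length(x$ids), "terms,",
      length(x$roots), "root(s),",
      length(x$aliases), "alias(es)\n")
  invisible(x)
}

#' Load an ontology from an OBO flat file
#'
#' Reads `[Term]` stanzas from an OBO 1.2/1.4 file, keeping the `id`,
#' `name`, `is_a`, `alt_id` and `is_obsolete` tags. Only is-a edges are
#' used; other relationship types (`part_of` etc.) are ignored. Obsolete
#' terms are dropped unless `keep_obsolete` is set, and `alt_id` entries
#' are recorded as aliases that resolve silently to the canonical id.
#'
#' @param path path to an OBO file.
#' @param keep_obsolete keep terms flagged `is_obsolete: true`? Default
#'   `FALSE`; obsolete terms never contribute is-a edges.
#' @return An [new_ontology()] object.
#' @export
load_obo <- function(path, keep_obsolete = FALSE) {
  lines <- readLines(path, warn = FALSE)
  starts <- grep("^\\[", lines)
  term_starts <- which(lines == "[Term]")
  if (!length(term_starts)) stop("no [Term] stanzas found in ", path)
  ends <- c(starts[-1L] - 1L, length(lines))
  names(ends) <- as.character(starts)

  ids <- character(0); nms <- character(0)
  parents <- list(); aliases <- character(0); obsolete <- character(0)
  for (s in term_starts) {
    stanza <- lines[(s + 1L):ends[[as.character(s)]]]
    tagval <- function(tag) {
      v <- stanza[startsWith(stanza, paste0(tag, ":"))]
      sub("\\s*(!.*)?$", "", sub(paste0("^", tag, ":\\s*"), "", v))
    }
    id <- tagval("id")
    if (!length(id)) next
    id <- id[[1L]]
    obs <- any(tagval("is_obsolete") == "true")
    if (obs && !keep_obsolete) {
      obsolete <- c(obsolete, id)
      next
    }
    ids <- c(ids, id)
    nm <- tagval("name")
    nms <- c(nms, if (length(nm)) nm[[1L]] else id)
    parents[[id]] <- tagval("is_a")
    for (alt in tagval("alt_id")) aliases[[alt]] <- id
  }

  # is_a references to dropped obsolete terms are themselves dropped
  parents <- lapply(parents, function(p) setdiff(p, obsolete))
  onto <- new_ontology(ids, nms, parents, aliases = aliases)
  onto
}

#' Add new terms to an ontology
#'
#' Used to extend a base ontology with domain terms (for example new
#' platelet-morphology classes under an existing leading class). The
#' ancestor closure is recomputed and the DAG invariant re-checked.
#'
#' @param onto an `"ontology"` object.
#' @param new_terms a data frame with columns `id`, `name` and `parents`
#'   (a list column of character vectors, or a semicolon-joined string).
#' @return The enlarged ontology.
#' @export
extend_ontology <- function(onto, new_terms) {
  stopifnot(inherits(onto, "ontology"))
  nt_id <- as.character(new_terms$id)
  if (any(nt_id %in% onto$ids)) {
    stop("duplicate term id(s): ",
         paste(intersect(nt_id, onto$ids), collapse = ", "))
  }
  ps <- new_terms$parents
  if (!is.list(ps)) ps <- strsplit(as.character(ps), ";", fixed = TRUE)
  ps <- lapply(ps, trimws)
  names(ps) <- nt_id
  missing <- setdiff(unlist(ps), c(onto$ids, nt_id))
  if (length(missing)) {
    stop("parent term(s) not found: ", paste(missing, collapse = ", "))
  }
  new_ontology(
    ids = c(onto$ids, nt_id),
    names = c(onto$name, stats::setNames(as.character(new_terms$name), nt_id)),
    parents = c(onto$parents, ps),
    aliases = onto$aliases
  )
}

#' Resolve term ids, mapping known aliases to canonical ids
#'
#' @param onto an ontology.
#' @param term_ids character vector of ids or aliases.
#' @return canonical ids; unknown ids raise an error naming them.
#' @export
resolve_terms <- function(onto, term_ids) {
  term_ids <- as.character(term_ids)
  is_alias <- term_ids %in% names(onto$aliases)
  if (any(is_alias)) {
    used <- unique(term_ids[is_alias])
    warning("resolving alias id(s) to canonical terms: ",
            paste(used, collapse = ", "), call. = FALSE)
    term_ids[is_alias] <- onto$aliases[term_ids[is_alias]]
  }
  unknown <- setdiff(term_ids, onto$ids)
  if (length(unknown)) {
    stop("unknown term id(s): ", paste(unknown, collapse = ", "))
  }
  term_ids
}

#' Reflexive-transitive ancestors of a set of terms
#'
#' anc(x) includes x itself; for a set the union of the members' closures
#' is returned. Reflexivity guarantees sim(t, t) = IC(t) downstream.
#'
#' @param onto an ontology.
#' @param term_ids character vector of term ids.
#' @return character vector (unordered union of ancestor sets).
#' @export
ancestors <- function(onto, term_ids) {
  term_ids <- resolve_terms(onto, term_ids)
  unique(unlist(onto$ancestors[term_ids], use.names = FALSE))
}

#' Summary subgraph over the ancestors of a term set
#'
#' Builds the induced ancestor subgraph used to draw per-cluster term
#' summaries: nodes are `ancestors(term_ids)` (or, when `display_ids` is
#' given, that subset plus nothing else); an edge x -> y is "direct" when
#' y is a parent of x, and "indirect" when y is a proper non-parent
#' ancestor of x reachable only through omitted nodes.
#'
#' @param onto an ontology.
#' @param term_ids seed term ids.
#' @param display_ids optional subset of nodes to retain; defaults to all
#'   ancestors of `term_ids`.
#' @return list with `nodes` (character) and `edges` (data frame with
#'   columns `from`, `to`, `type` in `{"direct","indirect"}`).
#' @export
summary_subgraph <- function(onto, term_ids, display_ids = NULL) {
  if (!length(term_ids)) {
    return(list(nodes = character(0),
                edges = data.frame(from = character(0), to = character(0),
                                   type = character(0))))
  }
  nodes <- if (is.null(display_ids)) {
    ancestors(onto, term_ids)
  } else {
    resolve_terms(onto, display_ids)
  }
  from <- character(0); to <- character(0); type <- character(0)
  for (x in nodes) {
    disp_anc <- intersect(setdiff(onto$ancestors[[x]], x), nodes)
    # keep only the minimal displayed ancestors: drop any y that is a
    # proper ancestor of another displayed ancestor z (the edge x -> y is
    # then implied transitively through z)
    implied <- unique(unlist(
      lapply(disp_anc, function(z) setdiff(onto$ancestors[[z]], z)),
      use.names = FALSE))
    keep <- setdiff(disp_anc, implied)
    for (y in keep) {
      from <- c(from, x); to <- c(to, y)
      type <- c(type,
                if (y %in% onto$parents[[x]]) "direct" else "indirect")
    }
  }
  list(nodes = nodes,
       edges = data.frame(from = from, to = to, type = type,
                          stringsAsFactors = FALSE))
}

#' Export a summary subgraph as DOT text
#'
#' Direct is-a relations are drawn solid, indirect ones dashed.
#'
#' @param sg result of [summary_subgraph()].
#' @param onto ontology supplying node labels.
#' @param path optional file to write; if `NULL` the DOT text is returned.
#' @return DOT source, invisibly when written to `path`.
#' @export
subgraph_to_dot <- function(sg, onto, path = NULL) {
  esc <- function(x) gsub("\"", "\\\\\"", x)
  lab <- onto$name[sg$nodes]
  lab[is.na(lab)] <- sg$nodes[is.na(lab)]
  out <- c(
    "digraph ontology_summary {",
    "  rankdir=BT;",
    sprintf("  \"%s\" [label=\"%s\"];", esc(sg$nodes), esc(lab)),
    if (nrow(sg$edges)) {
      sprintf("  \"%s\" -> \"%s\" [style=%s];",
              esc(sg$edges$from), esc(sg$edges$to),
              ifelse(sg$edges$type == "direct", "solid", "dashed"))
    },
    "}"
  )
  txt <- paste(out, collapse = "\n")
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(txt)
}

#' Export the ancestor closure as JSON
#'
#' @param onto an ontology.
#' @param path file to write.
#' @export
closure_to_json <- function(onto, path) {
  jsonlite::write_json(onto$ancestors, path, auto_unbox = FALSE)
  invisible(path)
}
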