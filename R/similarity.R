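# Collection-relative information content, most-informative-common-ancestor
# term similarity, symmetric best-match-average case similarity, and the
# scale-free rank distance. These are the statistical core of the pipeline.

#' Fit collection-relative term frequencies and information content
#'
#' For every term t appearing in any case's ancestor-propagated annotation
#' set, the frequency p_t is the proportion of cases whose propagated set
#' contains t (term-or-descendant counting), and IC(t) = -log(p_t) in
#' natural-log units (nats). Propagated counting makes IC monotone
#' non-increasing towards the leaves' ancestors: an ancestor is at least
#' as frequent as any descendant, so IC never decreases from root to leaf,
#' and a term covering the whole collection has IC 0.
#'
#' Terms annotated to no case (directly or through descendants) have no
#' defined frequency and are absent from the model.
#'
#' @param cohort a `"cohort"` whose cases carry explicit term sets.
#' @param onto the ontology.
#' @return object of class `"term_ic"`: list with `collection_size`,
#'   `freq` (named numeric in (0,1]) and `ic` (named numeric, nats).
#' @export
fit_frequencies <- function(cohort, onto) {
  stopifnot(inherits(cohort, "cohort"))
  n <- length(cohort$terms)
  if (n == 0L) stop("cannot fit term frequencies on an empty cohort")
  prop <- lapply(cohort$terms, function(d) ancestors(onto, d))
  counts <- table(unlist(prop, use.names = FALSE))
  freq <- as.numeric(counts) / n
  names(freq) <- names(counts)
  structure(
    list(collection_size = n, freq = freq, ic = -log(freq)),
    class = "term_ic"
  )
}

#' @export
print.term_ic <- function(x, ...) {
  cat("Term frequency model over", x$collection_size, "cases;",
      length(x$ic), "terms with defined IC (max",
      round(max(x$ic), 4), "nats)\n")
  invisible(x)
}

#' Information content of terms
#' @param model a `"term_ic"` model.
#' @param term_ids term ids; every id must have a defined IC.
#' @return named numeric vector of IC values (nats).
#' @export
term_ic <- function(model, term_ids) {
  undef <- setdiff(term_ids, names(model$ic))
  if (length(undef)) {
    stop("term(s) without defined IC (absent from the collection): ",
         paste(undef, collapse = ", "))
  }
  model$ic[term_ids]
}

#' Resnik-style similarity between two terms
#'
#' The similarity of terms s and t is the information content of their
#' most informative common ancestor, where ancestor sets are reflexive:
#' sim(t, t) = IC(t). Terms with no common ancestor (possible in
#' multi-root ontologies) get similarity 0 with a warning.
#'
#' @param s,t term ids with defined IC.
#' @param model a `"term_ic"` model.
#' @param onto the ontology.
#' @return non-negative similarity in nats; symmetric in (s, t).
#' @export
term_similarity <- function(s, t, model, onto) {
  term_ic(model, c(s, t))   # validates both
  common <- intersect(onto$ancestors[[s]], onto$ancestors[[t]])
  if (!length(common)) {
    warning("terms ", s, " and ", t, " share no ancestor; similarity 0",
            call. = FALSE)
    return(0)
  }
  max(model$ic[common])
}

# All-pairs MICA similarity over a term universe. Filling in decreasing-IC
# order means each cell receives the IC of the most informative common
# ancestor first and is never overwritten.
term_similarity_matrix <- function(terms, model, onto) {
  term_ic(model, terms)
  k <- length(terms)
  S <- matrix(NA_real_, k, k, dimnames = list(terms, terms))
  anc_universe <- unique(unlist(onto$ancestors[terms], use.names = FALSE))
  anc_universe <- intersect(anc_universe, names(model$ic))
  # terms x ancestors incidence: A[t, v] <=> v in anc(t)
  A <- matrix(FALSE, k, length(anc_universe),
              dimnames = list(terms, anc_universe))
  for (t in terms) A[t, intersect(onto$ancestors[[t]], anc_universe)] <- TRUE
  ord <- anc_universe[order(model$ic[anc_universe], decreasing = TRUE)]
  for (v in ord) {
    dv <- which(A[, v])
    if (!length(dv)) next
    block <- S[dv, dv, drop = FALSE]
    block[is.na(block)] <- model$ic[[v]]
    S[dv, dv] <- block
    if (!anyNA(S)) break
  }
  S[is.na(S)] <- 0   # disjoint-root pairs
  S
}

#' Symmetric best-match-average similarity between two cases
#'
#' For annotation sets D_a and D_b, each term in D_a is matched to its
#' best-scoring partner in D_b and vice versa; the two directed averages
#' are themselves averaged, giving a symmetric measure:
#' sim(D_a, D_b) = (1 / 2|D_a|) sum over s in D_a of max_t sim(s, t)
#'              + (1 / 2|D_b|) sum over s in D_b of max_t sim(s, t).
#' The self-similarity sim(D, D) equals the mean IC of D.
#'
#' @param d_a,d_b non-empty character vectors of term ids.
#' @param model a `"term_ic"` model.
#' @param onto the ontology.
#' @return non-negative similarity (nats).
#' @export
case_similarity <- function(d_a, d_b, model, onto) {
  if (!length(d_a) || !length(d_b)) {
    stop("case_similarity requires non-empty term sets")
  }
  S <- term_similarity_matrix(unique(c(d_a, d_b)), model, onto)
  sub <- S[d_a, d_b, drop = FALSE]
  mean(apply(sub, 1L, max)) / 2 + mean(apply(sub, 2L, max)) / 2
}

#' Pairwise case-similarity matrix
#'
#' Computes sim(D_a, D_b) over all case pairs. The diagonal holds the
#' self-similarity (mean IC of the case's term set). Negated, the matrix
#' is the dissimilarity input for medoid clustering.
#'
#' @param cohort a `"cohort"` with >= 2 cases, all with non-empty term sets.
#' @param model a `"term_ic"` model fitted on (a superset of) the cohort.
#' @param onto the ontology.
#' @return symmetric numeric matrix with case ids as dimnames.
#' @export
similarity_matrix <- function(cohort, model, onto) {
  stopifnot(inherits(cohort, "cohort"))
  ids <- case_ids(cohort)
  if (length(ids) < 2L) stop("similarity_matrix needs >= 2 cases")
  if (any(lengths(cohort$terms[ids]) == 0L)) {
    stop("cases with empty term sets present; run filter_terms first")
  }
  universe <- unique(unlist(cohort$terms[ids], use.names = FALSE))
  S <- term_similarity_matrix(universe, model, onto)
  n <- length(ids)
  M <- matrix(0, n, n, dimnames = list(ids, ids))
  term_idx <- lapply(cohort$terms[ids], function(d) match(d, universe))
  for (a in seq_len(n)) {
    ia <- term_idx[[a]]
    for (b in a:n) {
      sub <- S[ia, term_idx[[b]], drop = FALSE]
      v <- mean(apply(sub, 1L, max)) / 2 + mean(apply(sub, 2L, max)) / 2
      M[a, b] <- v
      M[b, a] <- v
    }
  }
  M
}

#' Rank distance between two cases
#'
#' A scale-independent dissimilarity of a case pair with respect to the
#' rest of the collection: for each member i of the pair, count the other
#' cases j whose similarity to i is at least sim(D_a, D_b), and halve the
#' total:
#' dist(a, b) = 1/2 * sum over i in {a,b} of
#'              #( j outside {a,b} : sim(D_i, D_j) >= sim(D_a, D_b) ).
#' Ties count (non-strict inequality). The range is [0, n - 2]; a small
#' value means the pair is unusually similar relative to the collection.
#' Rescaling all IC values by a positive constant leaves every rank
#' distance unchanged.
#'
#' @param a,b distinct case ids present in `simmat`.
#' @param simmat similarity matrix from [similarity_matrix()] (n >= 3).
#' @return rank distance (multiple of 0.5).
#' @export
rank_distance <- function(a, b, simmat) {
  if (identical(a, b)) stop("rank_distance requires two distinct cases")
  ids <- rownames(simmat)
  if (!all(c(a, b) %in% ids)) {
    stop("case(s) missing from similarity matrix: ",
         paste(setdiff(c(a, b), ids), collapse = ", "))
  }
  if (length(ids) < 3L) stop("rank_distance needs a collection of >= 3 cases")
  thr <- simmat[a, b]
  others <- setdiff(ids, c(a, b))
  (sum(simmat[a, others] >= thr) + sum(simmat[b, others] >= thr)) / 2
}

#' All-pairs rank-distance matrix
#'
#' Precomputes [rank_distance()] for every case pair; used by the
#' Monte-Carlo group test, which evaluates many subsets against the same
#' collection.
#'
#' @param simmat similarity matrix (n >= 3).
#' @return symmetric numeric matrix, diagonal 0.
#' @export
rank_distance_matrix <- function(simmat) {
  ids <- rownames(simmat)
  n <- length(ids)
  if (n < 3L) stop("rank_distance_matrix needs >= 3 cases")
  D <- matrix(0, n, n, dimnames = list(ids, ids))
  for (a in seq_len(n - 1L)) {
    for (b in (a + 1L):n) {
      thr <- simmat[a, b]
      keep <- -c(a, b)
      d <- (sum(simmat[a, keep] >= thr) + sum(simmat[b, keep] >= thr)) / 2
      D[a, b] <- d
      D[b, a] <- d
    }
  }
  D
}

#' Mean pairwise rank distance of a case group
#'
#' dist(Z) is the mean of [rank_distance()] over all unordered pairs in Z;
#' near 0 when the group's members are mutually among the most similar
#' pairs in the collection.
#'
#' @param z character vector of >= 2 case ids.
#' @param simmat similarity matrix, or a precomputed
#'   [rank_distance_matrix()] when `precomputed = TRUE`.
#' @param precomputed is `simmat` already a rank-distance matrix?
#' @return mean rank distance.
#' @export
group_distance <- function(z, simmat, precomputed = FALSE) {
  z <- unique(as.character(z))
  if (length(z) < 2L) stop("group_distance requires a group of >= 2 cases")
  D <- if (precomputed) simmat else rank_distance_matrix(simmat)
  missing <- setdiff(z, rownames(D))
  if (length(missing)) {
    stop("case(s) missing from matrix: ", paste(missing, collapse = ", "))
  }
  sub <- D[z, z]
  sum(sub[upper.tri(sub)]) / choose(length(z), 2)
}

#' Write / read a similarity matrix as TSV
#'
#' @param simmat symmetric matrix with case-id dimnames.
#' @param path file path.
#' @return the matrix (read) or the path, invisibly (write).
#' @export
write_similarity_matrix <- function(simmat, path) {
  utils::write.table(
    data.frame(case_id = rownames(simmat), simmat, check.names = FALSE),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_similarity_matrix
#' @export
read_similarity_matrix <- function(path) {
  tab <- utils::read.delim(path, sep = "\t", check.names = FALSE,
                           stringsAsFactors = FALSE)
  m <- as.matrix(tab[, -1L, drop = FALSE])
  rownames(m) <- tab$case_id
  storage.mode(m) <- "double"
  m
}

#' Export a term-frequency model as JSON
#'
#' @param model a `"term_ic"` model.
#' @param path output file.
#' @export
model_to_json <- function(model, path) {
  jsonlite::write_json(
    list(collection_size = model$collection_size,
         terms = data.frame(term = names(model$freq),
                            p = unname(model$freq),
                            ic = unname(model$ic))),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
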