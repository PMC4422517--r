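# Partitioning Around Medoids on the negated similarity matrix, plus
# Fisher-exact characterisation of the resulting clusters.

#' Partition cases around medoids (PAM)
#'
#' Classic BUILD + SWAP k-medoids on the dissimilarity -sim(D_a, D_b).
#' BUILD greedily seeds k medoids (first the case minimising total
#' dissimilarity, then the case giving the largest cost reduction); SWAP
#' repeatedly applies the single medoid/non-medoid exchange with the
#' largest cost decrease until no exchange lowers the total cost. Both
#' phases break ties by case order, so the result is deterministic;
#' `seed` only matters when `restarts > 0`, which adds randomly seeded
#' restarts and keeps the lowest-cost solution.
#'
#' By default only index cases are clustered: affected relatives would
#' otherwise pull clusters towards heavily enrolled pedigrees.
#'
#' @param simmat similarity matrix from [similarity_matrix()].
#' @param k number of clusters, 2 <= k <= n.
#' @param cohort optional `"cohort"`; when supplied (and
#'   `index_only = TRUE`) clustering is restricted to its index cases.
#' @param index_only restrict to index cases when `cohort` is given.
#' @param restarts number of extra random initialisations (default 0).
#' @param seed RNG seed for restarts.
#' @return object of class `"pam_partition"`: list with `k`, `medoids`,
#'   `assignment` (named integer vector), `total_cost`, `diss`.
#' @export
pam_partition <- function(simmat, k, cohort = NULL, index_only = TRUE,
                          restarts = 0L, seed = NULL) {
  ids <- rownames(simmat)
  if (!is.null(cohort) && index_only) {
    ids <- intersect(ids, case_ids(cohort, index_only = TRUE))
  }
  n <- length(ids)
  if (k > n) stop("k = ", k, " exceeds the ", n, " cases available")
  if (k < 1L) stop("k must be >= 1")
  diss <- -simmat[ids, ids]

  best <- pam_run(diss, k)
  if (restarts > 0L) {
    cands <- with_seed(seed, {
      lapply(seq_len(restarts), function(r) {
        init <- sort(sample.int(n, k))
        pam_run(diss, k, init = init)
      })
    })
    for (cand in cands) if (cand$total_cost < best$total_cost) best <- cand
  }
  structure(
    list(k = as.integer(k), medoids = ids[best$medoids],
         assignment = stats::setNames(best$assignment, ids),
         total_cost = best$total_cost, diss = diss),
    class = "pam_partition"
  )
}

# One BUILD+SWAP run on a dissimilarity matrix; init overrides BUILD.
pam_run <- function(diss, k, init = NULL) {
  n <- nrow(diss)
  cost_of <- function(med) sum(apply(diss[, med, drop = FALSE], 1L, min))
  if (is.null(init)) {
    med <- integer(0)
    for (step in seq_len(k)) {
      candidates <- setdiff(seq_len(n), med)
      costs <- vapply(candidates, function(c) cost_of(c(med, c)), numeric(1))
      med <- c(med, candidates[[which.min(costs)]])
    }
  } else {
    med <- init
  }
  cost <- cost_of(med)
  repeat {
    best_delta <- 0
    best_swap <- NULL
    nonmed <- setdiff(seq_len(n), med)
    for (mi in seq_along(med)) {
      for (h in nonmed) {
        trial <- med
        trial[[mi]] <- h
        delta <- cost_of(trial) - cost
        if (delta < best_delta - 1e-12) {
          best_delta <- delta
          best_swap <- trial
        }
      }
    }
    if (is.null(best_swap)) break
    med <- best_swap
    cost <- cost + best_delta
  }
  med <- sort(med)
  dm <- diss[, med, drop = FALSE]
  assignment <- apply(dm, 1L, which.min)   # ties -> lowest cluster index
  assignment[med] <- seq_along(med)        # each medoid owns its cluster
  list(medoids = med, assignment = as.integer(assignment),
       total_cost = cost_of(med))
}

#' @export
print.pam_partition <- function(x, ...) {
  cat("PAM partition: k =", x$k, "; sizes",
      paste(table(x$assignment), collapse = "/"),
      sprintf("; total cost %.4f\n", x$total_cost))
  invisible(x)
}

#' Scan cluster counts by mean silhouette width
#'
#' Convenience helper for choosing k: runs [pam_partition()] over a range
#' of k and reports the mean silhouette width of each partition. No claim
#' is made that any particular cohort's published cluster count is
#' recoverable this way.
#'
#' @param simmat similarity matrix.
#' @param k_range integer vector of candidate k.
#' @param ... passed to [pam_partition()].
#' @return data frame with columns `k`, `mean_silhouette`, `total_cost`.
#' @export
silhouette_scan <- function(simmat, k_range = 2:10, ...) {
  res <- lapply(k_range, function(k) {
    part <- pam_partition(simmat, k, ...)
    data.frame(k = k,
               mean_silhouette = mean_silhouette(part),
               total_cost = part$total_cost)
  })
  do.call(rbind, res)
}

mean_silhouette <- function(part) {
  d <- part$diss
  d <- d - min(d)          # silhouette needs non-negative dissimilarities
  cl <- part$assignment
  n <- length(cl)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- which(cl == cl[[i]])
    if (length(own) == 1L) { s[[i]] <- 0; next }
    a <- mean(d[i, setdiff(own, i)])
    b <- min(vapply(setdiff(unique(cl), cl[[i]]),
                    function(c) mean(d[i, cl == c]), numeric(1)))
    s[[i]] <- (b - a) / max(a, b)
  }
  mean(s)
}

#' Characterise a cluster by Fisher-exact term enrichment
#'
#' For every ontology node present in at least one case's
#' ancestor-propagated term set, tests the 2x2 table
#' (inside/outside cluster) x (has/lacks node) with a two-sided Fisher
#' exact test. The cluster label is the node with the smallest P overall,
#' plus up to two further nodes with P below `label_threshold` drawn from
#' distinct lineages: no selected label may be an ancestor or descendant
#' (reflexive closure) of an earlier one, so within a lineage only the
#' most significant node is kept.
#'
#' @param partition a `"pam_partition"`.
#' @param cluster cluster index to characterise.
#' @param cohort the clustered `"cohort"`.
#' @param onto the ontology.
#' @param label_threshold P cutoff for the 2nd/3rd label (default 1e-3).
#' @param max_labels maximum number of labels (default 3).
#' @return object of class `"cluster_summary"`: list with `cluster`,
#'   `labels` (data frame `term`, `name`, `p`) and `all_tested`
#'   (data frame `term`, `in_with`, `in_without`, `out_with`,
#'   `out_without`, `p` sorted by P).
#' @export
characterize_cluster <- function(partition, cluster, cohort, onto,
                                 label_threshold = 1e-3, max_labels = 3L) {
  inside <- names(partition$assignment)[partition$assignment == cluster]
  if (!length(inside)) stop("cluster ", cluster, " is empty")
  outside <- setdiff(names(partition$assignment), inside)
  if (!length(outside)) {
    stop("cluster ", cluster, " covers the whole cohort; nothing to test")
  }
  prop <- lapply(cohort$terms[c(inside, outside)],
                 function(d) ancestors(onto, d))
  nodes <- sort(unique(unlist(prop, use.names = FALSE)))
  n_in <- length(inside); n_out <- length(outside)
  in_with <- vapply(nodes, function(t) {
    sum(vapply(prop[inside], function(p) t %in% p, logical(1)))
  }, integer(1))
  out_with <- vapply(nodes, function(t) {
    sum(vapply(prop[outside], function(p) t %in% p, logical(1)))
  }, integer(1))
  p <- vapply(seq_along(nodes), function(i) {
    stats::fisher.test(matrix(c(in_with[[i]], n_in - in_with[[i]],
                                out_with[[i]], n_out - out_with[[i]]),
                              nrow = 2))$p.value
  }, numeric(1))
  tested <- data.frame(term = nodes, in_with = in_with,
                       in_without = n_in - in_with, out_with = out_with,
                       out_without = n_out - out_with, p = p,
                       stringsAsFactors = FALSE)
  tested <- tested[order(tested$p, tested$term), , drop = FALSE]
  rownames(tested) <- NULL

  labels <- tested[0, c("term", "p")]
  for (i in seq_len(nrow(tested))) {
    if (nrow(labels) >= max_labels) break
    cand <- tested$term[[i]]
    if (nrow(labels) > 0L) {
      if (tested$p[[i]] >= label_threshold) break
      related <- vapply(labels$term, function(l) {
        cand %in% onto$ancestors[[l]] || l %in% onto$ancestors[[cand]]
      }, logical(1))
      if (any(related)) next
    }
    labels <- rbind(labels, data.frame(term = cand, p = tested$p[[i]]))
  }
  labels$name <- unname(onto$name[labels$term])
  structure(
    list(cluster = cluster, labels = labels[, c("term", "name", "p")],
         all_tested = tested),
    class = "cluster_summary"
  )
}

#' @export
print.cluster_summary <- function(x, ...) {
  cat("Cluster", x$cluster, "labels:\n")
  if (nrow(x$labels)) {
    for (i in seq_len(nrow(x$labels))) {
      cat(sprintf("  %s (%s), P = %.3g\n", x$labels$name[[i]],
                  x$labels$term[[i]], x$labels$p[[i]]))
    }
  } else cat("  (none)\n")
  invisible(x)
}

#' Variant-carrier enrichment of a cluster
#'
#' Two-sided Fisher exact test of (inside/outside cluster) x
#' (carrier/non-carrier of a gene's qualifying variants).
#'
#' @param partition a `"pam_partition"`.
#' @param cluster cluster index.
#' @param carriers case ids carrying the variant(s); an empty set returns
#'   P = 1 with a warning.
#' @return list with `table` (2x2 matrix) and `p`.
#' @export
cluster_variant_enrichment <- function(partition, cluster, carriers) {
  all_ids <- names(partition$assignment)
  carriers <- intersect(unique(as.character(carriers)), all_ids)
  inside <- all_ids[partition$assignment == cluster]
  outside <- setdiff(all_ids, inside)
  tab <- matrix(
    c(sum(inside %in% carriers), sum(!inside %in% carriers),
      sum(outside %in% carriers), sum(!outside %in% carriers)),
    nrow = 2,
    dimnames = list(c("carrier", "non_carrier"), c("inside", "outside")))
  if (!length(carriers)) {
    warning("empty carrier set: enrichment P is 1", call. = FALSE)
    return(list(table = tab, p = 1))
  }
  list(table = tab, p = stats::fisher.test(tab)$p.value)
}

#' Write a partition as TSV / summaries as JSON
#'
#' @param partition a `"pam_partition"`.
#' @param path output file.
#' @export
write_partition <- function(partition, path) {
  utils::write.table(
    data.frame(case_id = names(partition$assignment),
               cluster = unname(partition$assignment)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @param summaries list of `"cluster_summary"` objects.
#' @rdname write_partition
#' @export
write_cluster_summaries <- function(summaries, path) {
  out <- lapply(summaries, function(s) {
    list(cluster = s$cluster,
         labels = s$labels)
  })
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
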