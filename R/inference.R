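# Group-level inference: Monte-Carlo significance of phenotypic closeness,
# Fisher's-method meta-analysis, and leading-class association chi-squared.

# Run code with a locally seeded RNG, restoring the caller's stream.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv())) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv())) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(code)
}

#' Monte-Carlo test of a group's phenotypic closeness
#'
#' Tests whether the mean pairwise rank distance of a case group Z is
#' smaller than expected for a random group of the same size drawn from
#' the collection. `n_subsets` subsets of size |Z| are drawn uniformly
#' (without replacement within a subset, independently across subsets)
#' from the eligible cases — by default the index cases, so that null
#' groups are not made artificially similar by enrolled relatives — and
#' the one-tail P value is the fraction of subsets W with
#' dist(W) <= dist(Z). Z itself is not excluded from the draw space, so
#' P is never exactly 0 in expectation terms, but the plain fraction may
#' be 0; `smoothed` switches to the (k + 1) / (n + 1) permutation
#' estimate.
#'
#' @param z character vector of >= 2 case ids (may include relatives).
#' @param simmat similarity matrix over the whole collection.
#' @param eligible case ids the null subsets are drawn from; defaults to
#'   all cases in `simmat` (pass the index cases for cohort analyses).
#' @param n_subsets number of random subsets (default 250000).
#' @param seed integer seed; identical seed and inputs give identical
#'   results.
#' @param smoothed use the add-one permutation estimate? Default `FALSE`.
#' @param rankdist optional precomputed [rank_distance_matrix()] of
#'   `simmat` (it is recomputed otherwise).
#' @return object of class `"group_test"`: list with `group`,
#'   `observed_distance`, `p_value`, `n_subsets`, `seed`.
#' @export
monte_carlo_group_p <- function(z, simmat, eligible = rownames(simmat),
                                n_subsets = 250000L, seed = NULL,
                                smoothed = FALSE, rankdist = NULL) {
  z <- unique(as.character(z))
  if (length(z) < 2L) stop("group must contain >= 2 cases")
  if (n_subsets < 1L) stop("n_subsets must be >= 1")
  eligible <- unique(as.character(eligible))
  if (length(eligible) < length(z)) {
    stop("group size ", length(z), " exceeds the ", length(eligible),
         " eligible cases")
  }
  missing <- setdiff(c(z, eligible), rownames(simmat))
  if (length(missing)) {
    stop("case(s) missing from similarity matrix: ",
         paste(missing, collapse = ", "))
  }
  if (is.null(rankdist)) rankdist <- rank_distance_matrix(simmat)
  observed <- group_distance(z, rankdist, precomputed = TRUE)

  k <- length(z)
  De <- rankdist[eligible, eligible]
  m <- length(eligible)
  pair_i <- combn_pairs(k)
  n_le <- with_seed(seed, {
    hits <- 0L
    tol <- 1e-9
    for (b in seq_len(n_subsets)) {
      w <- sample.int(m, k)
      dw <- mean(De[cbind(w[pair_i$i], w[pair_i$j])])
      if (dw <= observed + tol) hits <- hits + 1L
    }
    hits
  })
  p <- if (smoothed) (n_le + 1) / (n_subsets + 1) else n_le / n_subsets
  structure(
    list(group = z, observed_distance = observed, p_value = p,
         n_subsets = as.integer(n_subsets), n_le = n_le,
         seed = seed, eligible_size = m, smoothed = smoothed),
    class = "group_test"
  )
}

# index pairs (i < j) for a group of size k
combn_pairs <- function(k) {
  i <- rep(seq_len(k - 1L), times = (k - 1L):1L)
  j <- unlist(lapply(seq_len(k - 1L), function(a) (a + 1L):k))
  list(i = i, j = j)
}

#' @export
print.group_test <- function(x, ...) {
  cat(sprintf(
    "Group of %d cases: dist = %.3f, Monte-Carlo P = %.3g (%d subsets)\n",
    length(x$group), x$observed_distance, x$p_value, x$n_subsets))
  invisible(x)
}

#' Combine independent P values by Fisher's method
#'
#' X^2 = -2 * sum(log p_i) is referred to a chi-squared distribution with
#' 2k degrees of freedom; the upper-tail probability is returned. A zero
#' input P (possible for Monte-Carlo fractions below resolution) yields a
#' combined P of 0 with a warning.
#'
#' @param p_values numeric vector of P values in [0, 1], non-empty.
#' @return combined P value.
#' @export
fishers_method <- function(p_values) {
  if (!length(p_values)) stop("fishers_method requires >= 1 P value")
  if (any(p_values < 0 | p_values > 1)) stop("P values must lie in [0, 1]")
  if (any(p_values == 0)) {
    warning("input P value of 0: combined P reported as 0 ",
            "(below numerical resolution)", call. = FALSE)
    return(0)
  }
  x2 <- -2 * sum(log(p_values))
  stats::pchisq(x2, df = 2 * length(p_values), lower.tail = FALSE)
}

#' Chi-squared association between leading-class strata and feature terms
#'
#' For each stratum (for example, cases annotated in a given organ-system
#' leading class), counts how many cases carry each feature term in their
#' ancestor-propagated annotation set, inside the stratum versus in all
#' other cases, and tests the terms x (inside, outside) contingency table
#' by Pearson chi-squared (no continuity correction). Terms with a zero
#' expected count are dropped with a warning. P values are
#' Bonferroni-adjusted by `n_comparisons` (default: number of strata).
#'
#' @param cohort a `"cohort"`.
#' @param onto the ontology.
#' @param feature_terms character vector of term ids whose distribution is
#'   compared.
#' @param strata named list mapping stratum name to case ids.
#' @param n_comparisons Bonferroni multiplier.
#' @return data frame with columns `stratum`, `chisq`, `df`, `p`,
#'   `p_adjusted`.
#' @export
class_association_chisq <- function(cohort, onto, feature_terms, strata,
                                    n_comparisons = length(strata)) {
  if (!length(feature_terms)) stop("feature_terms must be non-empty")
  feature_terms <- resolve_terms(onto, feature_terms)
  prop <- lapply(cohort$terms, function(d) ancestors(onto, d))
  has_term <- vapply(feature_terms,
                     function(t) vapply(prop, function(p) t %in% p,
                                        logical(1)),
                     logical(length(prop)))
  rownames(has_term) <- names(prop)

  res <- lapply(names(strata), function(s) {
    inside <- intersect(strata[[s]], rownames(has_term))
    if (!length(inside)) stop("stratum '", s, "' has no cases")
    outside <- setdiff(rownames(has_term), inside)
    tab <- cbind(
      inside = colSums(has_term[inside, , drop = FALSE]),
      outside = colSums(has_term[outside, , drop = FALSE])
    )
    # drop feature rows whose expected counts vanish (term in no case)
    keep <- rowSums(tab) > 0
    if (!all(keep)) {
      warning("stratum '", s, "': dropping term(s) with zero counts: ",
              paste(rownames(tab)[!keep], collapse = ", "), call. = FALSE)
      tab <- tab[keep, , drop = FALSE]
    }
    ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    data.frame(stratum = s,
               chisq = unname(ct$statistic),
               df = unname(ct$parameter),
               p = unname(ct$p.value),
               p_adjusted = min(1, unname(ct$p.value) * n_comparisons),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Write group-test results as TSV
#'
#' @param results list of `"group_test"` objects, optionally named.
#' @param path output file.
#' @return the table, invisibly.
#' @export
write_group_tests <- function(results, path) {
  tab <- data.frame(
    group_id = if (is.null(names(results))) seq_along(results)
               else names(results),
    size = vapply(results, function(r) length(r$group), integer(1)),
    dist = vapply(results, function(r) r$observed_distance, numeric(1)),
    p = vapply(results, function(r) r$p_value, numeric(1)),
    n_subsets = vapply(results, function(r) r$n_subsets, integer(1)),
    seed = vapply(results, function(r) {
      if (is.null(r$seed)) NA_integer_ else as.integer(r$seed)
    }, integer(1)),
    stringsAsFactors = FALSE
  )
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(tab)
}
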