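# Synthetic data: random ontologies, annotated cohorts with planted
# structure (pedigree/syndrome-like groups), and variant tables with a
# planted causal gene. Everything is a pure function of (config, seed),
# and truth labels are returned alongside but never consumed by analysis
# code.

#' Simulation configuration
#'
#' Defaults state a world resembling a real rare-disease collection:
#' around 200 annotated cases whose per-case term counts follow
#' Poisson(7) truncated to [1, 23] (echoing a reported median of 7.5
#' terms per case, range 1 to 23), background terms sampled with weight
#' proportional to 1 / (number of descendants) so that most annotations
#' are specific (leaf-like) terms, one planted 5-case group sharing a
#' 3-term core with 10\% dropout, and one planted causal gene whose
#' carriers are exactly that group.
#'
#' @param n_terms,n_roots,max_parents ontology shape.
#' @param n_cases cohort size.
#' @param terms_per_case_lambda Poisson mean for per-case term counts.
#' @param terms_per_case_range truncation range for term counts.
#' @param planted_groups list of lists with fields `size`, `core_size`
#'   (or explicit `core` term ids) and `dropout` probability in [0, 1).
#' @param planted_gene list with `symbol`, `group` (index into
#'   `planted_groups`) and `background_rate` (per-case probability of a
#'   passing variant in a background gene).
#' @param n_background_genes number of non-causal genes simulated.
#' @param seed integer seed.
#' @return list of class `"sim_config"`.
#' @export
sim_config <- function(n_terms = 150L, n_roots = 1L, max_parents = 2L,
                       n_cases = 200L,
                       terms_per_case_lambda = 7,
                       terms_per_case_range = c(1L, 23L),
                       planted_groups = list(
                         list(size = 5L, core_size = 3L, dropout = 0.1)),
                       planted_gene = list(symbol = "GENE1", group = 1L,
                                           background_rate = 0.03),
                       n_background_genes = 10L,
                       seed = 1L) {
  stopifnot(n_terms >= n_roots, n_roots >= 1L, max_parents >= 1L,
            n_cases >= 1L)
  for (g in planted_groups) {
    stopifnot(g$size <= n_cases, g$dropout >= 0, g$dropout < 1)
  }
  structure(
    list(n_terms = as.integer(n_terms), n_roots = as.integer(n_roots),
         max_parents = as.integer(max_parents),
         n_cases = as.integer(n_cases),
         terms_per_case_lambda = terms_per_case_lambda,
         terms_per_case_range = as.integer(terms_per_case_range),
         planted_groups = planted_groups, planted_gene = planted_gene,
         n_background_genes = as.integer(n_background_genes),
         seed = as.integer(seed)),
    class = "sim_config"
  )
}

#' Simulate a random ontology DAG
#'
#' Terms are added in order; the first `n_roots` are roots, and every
#' later term receives 1 to `max_parents` parents drawn uniformly from
#' the earlier terms, so insertion order is a topological order and the
#' graph is acyclic by construction.
#'
#' @param config a [sim_config()].
#' @return an `"ontology"`.
#' @export
simulate_ontology <- function(config) {
  with_seed(config$seed, {
    n <- config$n_terms
    ids <- sprintf("SY:%06d", seq_len(n))
    parents <- vector("list", n)
    names(parents) <- ids
    for (i in seq_len(n)) {
      if (i <= config$n_roots) {
        parents[[i]] <- character(0)
      } else {
        np <- sample.int(min(config$max_parents, i - 1L), 1L)
        parents[[i]] <- ids[sample.int(i - 1L, np)]
      }
    }
    new_ontology(ids, paste("synthetic term", seq_len(n)), parents)
  })
}

#' Simulate an annotated cohort with planted groups
#'
#' Background cases draw a term count from a truncated Poisson and sample
#' terms without replacement, weighted towards specific terms
#' (weight 1 / (1 + number of proper descendants)). Members of a planted
#' group receive its core term set, with each core term independently
#' dropped with the group's dropout probability, plus background noise
#' terms up to their drawn count. Group cores are sampled from the
#' specific half of the ontology unless given explicitly.
#'
#' @param onto an `"ontology"` (typically from [simulate_ontology()]).
#' @param config a [sim_config()].
#' @return list with `cohort` (a `"cohort"`, all index cases) and `truth`
#'   (data frame `case_id`, `group`; "background" for unplanted cases),
#'   plus `cores` (list of core term sets per planted group).
#' @export
simulate_cohort <- function(onto, config) {
  with_seed(config$seed + 1L, {
    n <- config$n_cases
    ids <- sprintf("case%03d", seq_len(n))
    n_desc <- term_descendant_counts(onto)
    w <- 1 / (1 + n_desc)
    lo <- config$terms_per_case_range[[1L]]
    hi <- config$terms_per_case_range[[2L]]
    draw_count <- function(m) {
      x <- stats::rpois(m, config$terms_per_case_lambda)
      pmin(pmax(x, lo), hi)
    }
    counts <- draw_count(n)

    groups <- config$planted_groups
    truth <- rep("background", n)
    cores <- list()
    assigned <- integer(0)
    specific <- onto$ids[n_desc <= stats::median(n_desc)]
    used_cores <- character(0)
    for (gi in seq_along(groups)) {
      g <- groups[[gi]]
      members <- setdiff(seq_len(n), assigned)[seq_len(g$size)]
      assigned <- c(assigned, members)
      truth[members] <- paste0("group", gi)
      core <- if (!is.null(g[["core"]])) {
        resolve_terms(onto, g[["core"]])
      } else {
        # cores of different planted groups are kept disjoint so groups
        # are phenotypically distinct
        sample(setdiff(specific, used_cores), g$core_size)
      }
      used_cores <- c(used_cores, core)
      cores[[gi]] <- core
    }

    terms <- vector("list", n)
    for (i in seq_len(n)) {
      gi <- match(truth[[i]], paste0("group", seq_along(groups)))
      kept_core <- character(0)
      if (!is.na(gi)) {
        core <- cores[[gi]]
        kept_core <- core[stats::runif(length(core)) >=
                            groups[[gi]]$dropout]
      }
      n_bg <- max(counts[[i]] - length(kept_core), 1L)
      bg <- sample(onto$ids, n_bg, prob = w)
      terms[[i]] <- unique(c(kept_core, bg))
    }
    list(
      cohort = new_cohort(ids, terms, gender = "unknown",
                          pedigree_id = NA_character_, is_index = TRUE),
      truth = data.frame(case_id = ids, group = truth,
                         stringsAsFactors = FALSE),
      cores = cores
    )
  })
}

# proper-descendant counts per term
term_descendant_counts <- function(onto) {
  counts <- stats::setNames(integer(length(onto$ids)), onto$ids)
  for (t in onto$ids) {
    anc <- setdiff(onto$ancestors[[t]], t)
    counts[anc] <- counts[anc] + 1L
  }
  counts
}

#' Simulate a variant table with a planted causal gene
#'
#' Carriers of the planted gene are exactly the members of the designated
#' planted group, each with one heterozygous, protein-altering, filter-
#' passing variant. Background genes receive variants in random cases at
#' the configured rate; a fraction of background records
#' (`violation_rate`) is generated to violate one filter rule each, so
#' the exclusion filters have work to do.
#'
#' @param sim result of [simulate_cohort()].
#' @param config a [sim_config()].
#' @param violation_rate fraction of background records built to break a
#'   randomly chosen exclusion rule (default 0.3).
#' @return a `"variant_table"`.
#' @export
simulate_variants <- function(sim, config, violation_rate = 0.3) {
  with_seed(config$seed + 2L, {
    gene <- config$planted_gene
    carriers <- sim$truth$case_id[
      sim$truth$group == paste0("group", gene$group)]
    if (!length(carriers)) stop("planted gene's carrier group is empty")
    clean_record <- function(case_id, g, variant_id) {
      data.frame(case_id = case_id, gene = g, variant_id = variant_id,
                 genotype = "het", protein_altering = TRUE,
                 max_ref_af = 0, alt_reads = 10L,
                 inhouse_control_ac = 0L, cross_project_ac = 1L,
                 hgmd = FALSE, phenotype_match = "unknown",
                 pedigree_consistent = NA,
                 stringsAsFactors = FALSE)
    }
    recs <- list()
    for (i in seq_along(carriers)) {
      recs[[length(recs) + 1L]] <-
        clean_record(carriers[[i]], gene$symbol,
                     sprintf("chr1:%d A/G", 1000L + i))
    }
    all_ids <- sim$truth$case_id
    for (b in seq_len(config$n_background_genes)) {
      g <- sprintf("BG%02d", b)
      n_car <- stats::rbinom(1L, length(all_ids), gene$background_rate)
      if (!n_car) next
      for (cid in sample(all_ids, n_car)) {
        r <- clean_record(cid, g,
                          sprintf("chr2:%d C/T",
                                  10000L + b * 100L +
                                    match(cid, all_ids)))
        if (stats::runif(1) < violation_rate) {
          rule <- sample.int(6L, 1L)
          r <- switch(rule,
            { r$max_ref_af <- 0.05; r },
            { r$protein_altering <- FALSE; r },
            { r$pedigree_consistent <- FALSE; r },
            { r$alt_reads <- 1L; r },
            { r$inhouse_control_ac <- 3L; r },
            { r$cross_project_ac <- 50L; r })
        }
        recs[[length(recs) + 1L]] <- r
      }
    }
    variant_table(do.call(rbind, recs))
  })
}

#' Write an ontology in OBO format
#'
#' Round-trips through [load_obo()]; used by the simulator's file
#' interface.
#'
#' @param onto an `"ontology"`.
#' @param path output file.
#' @export
write_obo <- function(onto, path) {
  out <- c("format-version: 1.2", "")
  for (id in onto$ids) {
    ps <- onto$parents[[id]]
    out <- c(out, "[Term]", paste0("id: ", id),
             paste0("name: ", onto$name[[id]]),
             if (length(ps)) paste0("is_a: ", ps), "")
  }
  writeLines(out, path)
  invisible(path)
}
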