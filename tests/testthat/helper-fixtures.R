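# Shared fixtures and independent oracles.
#
# The oracles deliberately avoid the package's own data structures and
# algorithms: ancestor closures are recomputed by a naive recursive walk
# over an edge list, similarities by brute-force double loops, Fisher P
# values by full hypergeometric enumeration, and PAM optimality by an
# exhaustive swap check.

# --- fixture: 6-term ontology (edges child -> parent) ----------------------
# T1 -> T0, T2 -> T0, T3 -> T1, T4 -> T1, T5 -> T2
fixture_parents <- list(
  T0 = character(0), T1 = "T0", T2 = "T0",
  T3 = "T1", T4 = "T1", T5 = "T2"
)

make_fixture_ontology <- function() {
  new_ontology(names(fixture_parents), parents = fixture_parents)
}

fixture_obo_text <- function() {
  c("format-version: 1.2", "",
    "[Term]", "id: T0", "name: root term", "",
    "[Term]", "id: T1", "name: branch one", "is_a: T0 ! root term", "",
    "[Term]", "id: T2", "name: branch two", "is_a: T0", "",
    "[Term]", "id: T3", "name: leaf three", "is_a: T1", "alt_id: T3alt", "",
    "[Term]", "id: T4", "name: leaf four", "is_a: T1", "",
    "[Term]", "id: T5", "name: leaf five", "is_a: T2", "",
    "[Term]", "id: T9", "name: gone", "is_a: T0", "is_obsolete: true", "")
}

# --- fixture: cohort C4 ----------------------------------------------------
c4_terms <- list(c1 = "T3", c2 = c("T3", "T5"), c3 = "T4", c4 = "T5")

make_c4_cohort <- function() {
  new_cohort(names(c4_terms), c4_terms,
             gender = c("female", "male", "female", "male"),
             pedigree_id = c("P1", "P1", NA, NA),
             is_index = TRUE)
}

# --- oracle: ancestors / IC / similarities ---------------------------------
oracle_ancestors <- function(term, parents = fixture_parents) {
  out <- term
  for (p in parents[[term]]) out <- c(out, oracle_ancestors(p, parents))
  unique(out)
}

# propagate-and-count IC over a list of explicit term sets
oracle_ic <- function(term_sets, parents = fixture_parents) {
  prop <- lapply(term_sets, function(d) {
    unique(unlist(lapply(d, oracle_ancestors, parents = parents)))
  })
  universe <- unique(unlist(prop))
  p <- vapply(universe, function(t) {
    mean(vapply(prop, function(s) t %in% s, logical(1)))
  }, numeric(1))
  -log(p)
}

oracle_term_sim <- function(s, t, ic, parents = fixture_parents) {
  common <- intersect(oracle_ancestors(s, parents),
                      oracle_ancestors(t, parents))
  if (!length(common)) return(0)
  max(ic[common])
}

oracle_case_sim <- function(d_a, d_b, ic, parents = fixture_parents) {
  best_a <- vapply(d_a, function(s) {
    max(vapply(d_b, function(t) oracle_term_sim(s, t, ic, parents),
               numeric(1)))
  }, numeric(1))
  best_b <- vapply(d_b, function(s) {
    max(vapply(d_a, function(t) oracle_term_sim(s, t, ic, parents),
               numeric(1)))
  }, numeric(1))
  sum(best_a) / (2 * length(d_a)) + sum(best_b) / (2 * length(d_b))
}

oracle_sim_matrix <- function(term_sets, parents = fixture_parents) {
  ic <- oracle_ic(term_sets, parents)
  ids <- names(term_sets)
  m <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
  for (a in ids) for (b in ids) {
    m[a, b] <- oracle_case_sim(term_sets[[a]], term_sets[[b]], ic, parents)
  }
  m
}

oracle_rank_distance <- function(a, b, simmat) {
  ids <- rownames(simmat)
  thr <- simmat[a, b]
  total <- 0
  for (i in c(a, b)) {
    for (j in setdiff(ids, c(a, b))) {
      if (simmat[i, j] >= thr) total <- total + 1
    }
  }
  total / 2
}

# --- oracle: two-sided Fisher exact by hypergeometric enumeration ----------
oracle_fisher_2x2 <- function(tab) {
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ])
  c1 <- sum(tab[, 1])
  prob <- function(x) {
    choose(c1, x) * choose(r1 + r2 - c1, r1 - x) / choose(r1 + r2, r1)
  }
  xs <- max(0, r1 - (r1 + r2 - c1)):min(r1, c1)
  ps <- vapply(xs, prob, numeric(1))
  p_obs <- prob(tab[1, 1])
  sum(ps[ps <= p_obs * (1 + 1e-7)])
}

# --- oracle: PAM optimality (no improving single swap) ---------------------
pam_no_improving_swap <- function(part) {
  diss <- part$diss
  ids <- rownames(diss)
  med <- match(part$medoids, ids)
  cost_of <- function(m) sum(apply(diss[, m, drop = FALSE], 1, min))
  cost <- cost_of(med)
  for (mi in seq_along(med)) {
    for (h in setdiff(seq_along(ids), med)) {
      trial <- med
      trial[mi] <- h
      if (cost_of(trial) < cost - 1e-9) return(FALSE)
    }
  }
  TRUE
}

# --- adjusted Rand index ---------------------------------------------------
adjusted_rand_index <- function(x, y) {
  tab <- table(x, y)
  a <- sum(choose(tab, 2))
  b <- sum(choose(rowSums(tab), 2))
  c_ <- sum(choose(colSums(tab), 2))
  n <- sum(tab)
  expected <- b * c_ / choose(n, 2)
  (a - expected) / ((b + c_) / 2 - expected)
}

# --- fixture: toy variant table --------------------------------------------
# One clean record plus one violator per exclusion rule, in rule order.
toy_variant_table <- function() {
  base <- data.frame(
    case_id = sprintf("v%d", 1:7),
    gene = "G1",
    variant_id = sprintf("chr1:%d A/T", 1:7),
    genotype = "het",
    protein_altering = TRUE,
    max_ref_af = 0,
    alt_reads = 10L,
    inhouse_control_ac = 0L,
    cross_project_ac = 1L,
    hgmd = FALSE,
    phenotype_match = "unknown",
    pedigree_consistent = NA,
    stringsAsFactors = FALSE
  )
  base$max_ref_af[2] <- 0.05            # rule 1
  base$protein_altering[3] <- FALSE     # rule 2
  base$pedigree_consistent[4] <- FALSE  # rule 3
  base$alt_reads[5] <- 2L               # rule 4
  base$inhouse_control_ac[6] <- 2L      # rule 5
  base$cross_project_ac[7] <- 21L       # rule 6
  variant_table(base)
}

# --- C4 convenience: fitted model + similarity matrix ----------------------
c4_setup <- function() {
  onto <- make_fixture_ontology()
  cohort <- make_c4_cohort()
  model <- fit_frequencies(cohort, onto)
  list(onto = onto, cohort = cohort, model = model,
       simmat = similarity_matrix(cohort, model, onto))
}
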