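test_that("the six exclusion rules fire exactly as designed", {
  flt <- filter_variants(toy_variant_table())
  expect_identical(nrow(flt$retained), 1L)
  expect_identical(flt$retained$case_id, "v1")
  expect_identical(flt$excluded$rule, 1:6)
  expect_identical(flt$excluded$rules, as.character(1:6))

  # retained + excluded partition the input
  expect_identical(nrow(flt$retained) + nrow(flt$excluded), 7L)
  expect_length(intersect(flt$retained$case_id, flt$excluded$case_id), 0L)

  # multiple violations: all rule ids recorded, first one tags
  multi <- toy_variant_table()[2, ]
  multi$alt_reads <- 0L
  fm <- filter_variants(variant_table(multi))
  expect_identical(fm$excluded$rule, 1L)
  expect_identical(fm$excluded$rules, "1;4")
})

test_that("boundary and missing values follow the stated conventions", {
  rec <- toy_variant_table()[1, ]

  rec$max_ref_af <- 0.001               # exactly at threshold: retained
  expect_identical(nrow(filter_variants(rec)$retained), 1L)

  rec$alt_reads <- 3L                   # exactly 3 reads: retained
  expect_identical(nrow(filter_variants(rec)$retained), 1L)

  rec$alt_reads <- NA_integer_          # missing support: excluded (rule 4)
  expect_identical(filter_variants(rec)$excluded$rule, 4L)

  rec$alt_reads <- 10L
  rec$max_ref_af <- NA_real_            # unobserved frequency: retained
  expect_identical(nrow(filter_variants(rec)$retained), 1L)

  # no sequenced relative (NA) passes the segregation rule vacuously
  rec$max_ref_af <- 0
  rec$pedigree_consistent <- NA
  expect_identical(nrow(filter_variants(rec)$retained), 1L)

  # filtering is idempotent
  flt <- filter_variants(toy_variant_table())
  again <- filter_variants(flt$retained)
  expect_identical(nrow(again$retained), nrow(flt$retained))
  expect_identical(nrow(again$excluded), 0L)

  expect_identical(nrow(filter_variants(toy_variant_table()[0, ])$retained),
                   0L)
})

test_that("variant table validation catches malformed input", {
  tab <- as.data.frame(toy_variant_table())
  expect_error(variant_table(tab[, -2]), "gene")
  bad <- tab; bad$max_ref_af[1] <- 1.5
  expect_error(variant_table(bad), "\\[0, 1\\]")
  bad <- tab; bad$genotype[1] <- "diploid"
  expect_error(variant_table(bad), "diploid")
  bad <- tab; bad$phenotype_match[1] <- "maybe"
  expect_error(variant_table(bad), "maybe")
})

test_that("variant TSV round-trip preserves types", {
  path <- withr::local_tempfile(fileext = ".tsv")
  write_variants(toy_variant_table(), path)
  back <- load_variants(path)
  expect_identical(back$protein_altering, toy_variant_table()$protein_altering)
  expect_identical(back$pedigree_consistent,
                   toy_variant_table()$pedigree_consistent)
  expect_identical(nrow(filter_variants(back)$retained), 1L)
})

test_that("group_cases_by_gene applies the inheritance models", {
  cohort <- new_cohort(
    c("i1", "i2", "i3", "r1", "f1", "m1"),
    list(i1 = "T3", i2 = "T3", i3 = "T3", r1 = "T3", f1 = "T3", m1 = "T3"),
    gender = c("male", "female", "male", "female", "female", "male"),
    is_index = c(TRUE, TRUE, TRUE, FALSE, TRUE, TRUE))
  rec <- function(cid, gene, vid, gt) {
    data.frame(case_id = cid, gene = gene, variant_id = vid, genotype = gt,
               protein_altering = TRUE, max_ref_af = 0, alt_reads = 10L,
               inhouse_control_ac = 0L, cross_project_ac = 1L,
               hgmd = FALSE, phenotype_match = "unknown",
               pedigree_consistent = NA, stringsAsFactors = FALSE)
  }
  recs <- variant_table(rbind(
    rec("i1", "G1", "va", "het"), rec("i2", "G1", "vb", "het"),
    rec("i3", "G1", "vc", "hom"),
    rec("r1", "G1", "va", "het"),            # relative: never grouped
    rec("i1", "G2", "vd", "het"),            # single het
    rec("i2", "G2", "ve", "het"), rec("i2", "G2", "vf", "het"),
    rec("i3", "G2", "vg", "hom"),
    rec("m1", "G3", "vh", "hemi"), rec("f1", "G3", "vi", "hom"),
    rec("i1", "G3", "vj", "het")))

  ad <- group_cases_by_gene(recs, cohort, "autosomal_dominant")
  expect_setequal(ad$G1, c("i1", "i2", "i3"))
  expect_false("r1" %in% unlist(ad))

  ar <- group_cases_by_gene(recs, cohort, "autosomal_recessive")
  expect_setequal(ar$G2, c("i2", "i3"))      # compound het + hom
  expect_false("i1" %in% ar$G2)              # single het not grouped
  flags <- attr(ar, "phase_unverified")
  expect_true(any(flags$case_id == "i2" & flags$gene == "G2"))

  xl <- group_cases_by_gene(recs, cohort, "x_linked")
  expect_setequal(xl$G3, c("m1", "f1"))      # hemi male + hom female
  expect_false("i1" %in% xl$G3)

  expect_error(group_cases_by_gene(recs, cohort, "mitochondrial"))
})

test_that("classify_variants applies PV/LPV/VUS rules and demotion", {
  rec <- function(cid, vid, hgmd, match) {
    data.frame(case_id = cid, gene = "ACTN1", variant_id = vid,
               genotype = "het", protein_altering = TRUE, max_ref_af = 0,
               alt_reads = 10L, inhouse_control_ac = 0L,
               cross_project_ac = 1L, hgmd = hgmd,
               phenotype_match = match, pedigree_consistent = NA,
               stringsAsFactors = FALSE)
  }
  known <- c("ACTN1", "MYH9")

  # database variant with matched phenotype -> PV
  pv <- classify_variants(variant_table(rec("a", "v1", TRUE, "matched")),
                          known)
  expect_identical(pv$classification, "PV")

  # novel variant, matched gene phenotype -> LPV
  lpv <- classify_variants(variant_table(rec("a", "v2", FALSE, "matched")),
                           known)
  expect_identical(lpv$classification, "LPV")

  # neither -> VUS
  expect_identical(
    classify_variants(variant_table(rec("a", "v3", TRUE, "unknown")),
                      known)$classification, "VUS")
  expect_identical(
    classify_variants(variant_table(rec("a", "v4", FALSE, "unmatched")),
                      known)$classification, "VUS")

  # demotion: second carrier of the same variant with unmatched phenotype
  both <- variant_table(rbind(rec("a", "v5", TRUE, "matched"),
                              rec("b", "v5", TRUE, "unmatched")))
  dem <- classify_variants(both, known)
  expect_identical(dem$classification, c("VUS", "VUS"))
  expect_match(dem$rationale[[1L]], "demoted PV")

  # classification rules never cross the database boundary
  set.seed(99)
  grid <- expand.grid(hgmd = c(TRUE, FALSE),
                      match = c("matched", "unmatched", "unknown"),
                      stringsAsFactors = FALSE)
  for (i in seq_len(nrow(grid))) {
    cl <- classify_variants(
      variant_table(rec("a", paste0("g", i), grid$hgmd[[i]],
                        grid$match[[i]])), known)$classification
    if (cl == "PV") expect_true(grid$hgmd[[i]])
    if (cl == "LPV") expect_false(grid$hgmd[[i]])
  }

  # unknown gene directs to the discovery scan
  stray <- rec("a", "v9", TRUE, "matched")
  stray$gene <- "NOVELGENE"
  expect_error(classify_variants(variant_table(stray), known),
               "gene_similarity_scan")
})

test_that("gene_similarity_scan ranks genes by group closeness", {
  cfg <- sim_config(n_terms = 80L, n_cases = 100L,
                    planted_groups = list(
                      list(size = 5L, core_size = 3L, dropout = 0.1)),
                    seed = 17L)
  onto <- simulate_ontology(cfg)
  sim <- simulate_cohort(onto, cfg)
  vars <- simulate_variants(sim, cfg)
  model <- fit_frequencies(sim$cohort, onto)
  M <- similarity_matrix(sim$cohort, model, onto)
  flt <- filter_variants(vars)
  groups <- group_cases_by_gene(flt$retained, sim$cohort,
                                "autosomal_dominant")
  scan <- gene_similarity_scan(groups, M, n_subsets = 2000L, seed = 4L)
  expect_identical(scan$gene[[1L]], "GENE1")
  expect_lt(scan$p[[1L]], 0.05)
  # singletons carry NA and sort last
  if (any(scan$size < 2)) expect_true(all(is.na(scan$p[scan$size < 2])))

  # identical carrier sets give identical P under the same seed
  g2 <- list(A = groups$GENE1, B = groups$GENE1)
  s2 <- gene_similarity_scan(g2, M, n_subsets = 500L, seed = 6L)
  expect_equal(s2$p[[1L]], s2$p[[2L]])

  # a gene whose carriers equal a planted pedigree reproduces that
  # group's Monte-Carlo P exactly under the same seed
  direct <- monte_carlo_group_p(groups$GENE1, M, n_subsets = 2000L,
                                seed = 4L)
  expect_equal(scan$p[scan$gene == "GENE1"], direct$p_value)
})
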