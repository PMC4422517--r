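# Rare-variant triage: the six exclusion filters, gene-wise grouping of
# carriers under an inheritance model, phenotype-similarity scoring of
# gene groups, and PV/LPV/VUS classification in known disease genes.

VARIANT_COLUMNS <- c(
  "case_id", "gene", "variant_id", "genotype", "protein_altering",
  "max_ref_af", "alt_reads", "inhouse_control_ac", "cross_project_ac",
  "hgmd", "phenotype_match", "pedigree_consistent"
)

#' Construct a variant table
#'
#' One row per case-variant observation. `max_ref_af` is the maximum
#' allele frequency over all reference cohorts (equivalent to checking
#' each cohort against the threshold); `phenotype_match` is a curated
#' judgement, never computed.
#'
#' @param df data frame with (at least) the columns
#'   `case_id`, `gene`, `variant_id`, `genotype` (`het`/`hom`/`hemi`),
#'   `protein_altering` (logical), `max_ref_af`, `alt_reads`,
#'   `inhouse_control_ac`, `cross_project_ac`, `hgmd` (logical),
#'   `phenotype_match` (`matched`/`unmatched`/`unknown`),
#'   `pedigree_consistent` (logical; `NA` when no affected relative was
#'   sequenced, in which case the segregation filter passes vacuously).
#' @return the validated data frame, class `"variant_table"`.
#' @export
variant_table <- function(df) {
  missing <- setdiff(VARIANT_COLUMNS, names(df))
  if (length(missing)) {
    stop("variant table missing column(s): ", paste(missing, collapse = ", "))
  }
  if (any(df$max_ref_af < 0 | df$max_ref_af > 1, na.rm = TRUE)) {
    stop("max_ref_af must lie in [0, 1]")
  }
  counts <- c("alt_reads", "inhouse_control_ac", "cross_project_ac")
  for (cn in counts) {
    if (any(df[[cn]] < 0, na.rm = TRUE)) stop(cn, " must be >= 0")
  }
  bad_gt <- setdiff(unique(df$genotype), c("het", "hom", "hemi"))
  if (length(bad_gt)) {
    stop("genotype must be het/hom/hemi, got: ",
         paste(bad_gt, collapse = ", "))
  }
  bad_pm <- setdiff(unique(df$phenotype_match),
                    c("matched", "unmatched", "unknown"))
  if (length(bad_pm)) {
    stop("phenotype_match must be matched/unmatched/unknown, got: ",
         paste(bad_pm, collapse = ", "))
  }
  class(df) <- c("variant_table", "data.frame")
  df
}

#' Read a variant table from TSV
#'
#' @param path path to a tab-separated file with the [variant_table()]
#'   columns; logical columns accept `true`/`false`.
#' @return a `"variant_table"`.
#' @export
load_variants <- function(path) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  for (cn in c("protein_altering", "hgmd", "pedigree_consistent")) {
    if (is.character(df[[cn]])) {
      v <- tolower(df[[cn]])
      df[[cn]] <- ifelse(v %in% c("true", "1", "yes"), TRUE,
                         ifelse(v %in% c("false", "0", "no"), FALSE, NA))
    }
  }
  variant_table(df)
}

#' Apply the six variant-exclusion criteria
#'
#' A record is excluded if any of the following holds:
#' \enumerate{
#'   \item allele frequency above `max_ref_af` (strictly) in any
#'     reference cohort;
#'   \item not predicted to alter the protein;
#'   \item not present in the sequenced affected relatives (segregation
#'     failure; passes vacuously when none were sequenced,
#'     `pedigree_consistent = NA`);
#'   \item fewer than `min_alt_reads` reads supporting the alternate
#'     allele (a missing read count is treated as failing);
#'   \item allele count above `max_inhouse_ac` in the in-house sequenced
#'     control panel;
#'   \item overall allele count above `max_overall_ac` across projects.
#' }
#' Boundary values survive: an allele frequency exactly at the threshold
#' or exactly `min_alt_reads` supporting reads is retained. A missing
#' reference allele frequency is treated as 0 (retain) — conservative for
#' discovery.
#'
#' @param records a `"variant_table"`.
#' @param max_ref_af reference-cohort frequency threshold (default 0.001,
#'   i.e. 0.1\%).
#' @param min_alt_reads minimum alternate-read support (default 3).
#' @param max_inhouse_ac maximum in-house control allele count (default 1).
#' @param max_overall_ac maximum cross-project allele count (default 20).
#' @return list with `retained` (a `"variant_table"`), `excluded` (the
#'   dropped rows plus columns `rule` — first triggering rule id — and
#'   `rules` — all triggering ids, semicolon-joined).
#' @export
filter_variants <- function(records, max_ref_af = 0.001,
                            min_alt_reads = 3L, max_inhouse_ac = 1L,
                            max_overall_ac = 20L) {
  records <- variant_table(as.data.frame(records))
  af <- records$max_ref_af
  af[is.na(af)] <- 0
  reads <- records$alt_reads
  reads[is.na(reads)] <- -Inf      # missing support fails rule 4
  seg <- records$pedigree_consistent
  viol <- cbind(
    `1` = af > max_ref_af,
    `2` = !records$protein_altering,
    `3` = !is.na(seg) & !seg,
    `4` = reads < min_alt_reads,
    `5` = records$inhouse_control_ac > max_inhouse_ac,
    `6` = records$cross_project_ac > max_overall_ac
  )
  any_viol <- rowSums(viol) > 0
  excluded <- as.data.frame(records)[any_viol, , drop = FALSE]
  if (nrow(excluded)) {
    vr <- viol[any_viol, , drop = FALSE]
    excluded$rule <- apply(vr, 1L, function(r) as.integer(which(r)[[1L]]))
    excluded$rules <- apply(vr, 1L, function(r) {
      paste(which(r), collapse = ";")
    })
  } else {
    excluded$rule <- integer(0)
    excluded$rules <- character(0)
  }
  retained <- records[!any_viol, , drop = FALSE]
  class(retained) <- c("variant_table", "data.frame")
  list(retained = retained, excluded = excluded)
}

#' Group index cases by gene under an inheritance model
#'
#' Autosomal dominant: any case carrying at least one retained het or hom
#' variant in the gene. Autosomal recessive: cases with a hom variant or
#' with two or more distinct het variants in the gene (compound-het phase
#' unknowable from the table; flagged `phase_unverified`). X-linked:
#' hemizygous males or homozygous females. Only index cases enter groups.
#'
#' @param retained a `"variant_table"` of filtered records.
#' @param cohort the `"cohort"` (supplies gender and index flags).
#' @param model one of `"autosomal_dominant"`, `"autosomal_recessive"`,
#'   `"x_linked"`.
#' @return named list mapping gene symbol to a character vector of index
#'   case ids; attribute `phase_unverified` lists (gene, case) pairs
#'   grouped on unphased compound hets.
#' @export
group_cases_by_gene <- function(retained, cohort,
                                model = c("autosomal_dominant",
                                          "autosomal_recessive",
                                          "x_linked")) {
  model <- match.arg(model)
  meta <- cohort$meta
  idx_ids <- meta$case_id[meta$is_index]
  recs <- as.data.frame(retained)
  recs <- recs[recs$case_id %in% idx_ids, , drop = FALSE]
  phase_flags <- data.frame(gene = character(0), case_id = character(0))
  groups <- lapply(split(recs, recs$gene), function(g) {
    per_case <- split(g, g$case_id)
    qualifies <- vapply(per_case, function(cv) {
      switch(model,
        autosomal_dominant = any(cv$genotype %in% c("het", "hom")),
        autosomal_recessive =
          any(cv$genotype == "hom") ||
          length(unique(cv$variant_id[cv$genotype == "het"])) >= 2L,
        x_linked = {
          gender <- meta$gender[match(cv$case_id[[1L]], meta$case_id)]
          (gender == "male" && any(cv$genotype == "hemi")) ||
            (gender == "female" && any(cv$genotype == "hom"))
        })
    }, logical(1))
    names(per_case)[qualifies]
  })
  if (model == "autosomal_recessive") {
    for (gene in names(groups)) {
      g <- recs[recs$gene == gene & recs$case_id %in% groups[[gene]], ]
      for (cid in unique(g$case_id)) {
        cv <- g[g$case_id == cid, ]
        if (!any(cv$genotype == "hom") &&
            length(unique(cv$variant_id[cv$genotype == "het"])) >= 2L) {
          phase_flags <- rbind(phase_flags,
                               data.frame(gene = gene, case_id = cid))
        }
      }
    }
  }
  groups <- groups[lengths(groups) > 0L]
  attr(groups, "phase_unverified") <- phase_flags
  groups
}

#' Score gene groups by phenotypic closeness of their carriers
#'
#' Runs the Monte-Carlo group test for every gene whose carriers form a
#' group of two or more cases with phenotype data, and ranks genes by P
#' (ascending), breaking ties by group size (descending) then gene name.
#' Singleton groups are reported with `NA` statistics.
#'
#' @param gene_groups result of [group_cases_by_gene()].
#' @param simmat similarity matrix over the collection.
#' @param eligible null-draw space (default: all cases in `simmat`; pass
#'   index cases for cohort analyses).
#' @param n_subsets,seed passed to [monte_carlo_group_p()]; each gene is
#'   tested with the same seed, so identical carrier sets give identical
#'   P values.
#' @return data frame with columns `gene`, `size`, `dist`, `p`.
#' @export
gene_similarity_scan <- function(gene_groups, simmat,
                                 eligible = rownames(simmat),
                                 n_subsets = 250000L, seed = NULL) {
  rankdist <- rank_distance_matrix(simmat)
  rows <- lapply(names(gene_groups), function(gene) {
    grp <- intersect(gene_groups[[gene]], rownames(simmat))
    if (length(grp) < 2L) {
      return(data.frame(gene = gene, size = length(grp),
                        dist = NA_real_, p = NA_real_))
    }
    gt <- monte_carlo_group_p(grp, simmat, eligible = eligible,
                              n_subsets = n_subsets, seed = seed,
                              rankdist = rankdist)
    data.frame(gene = gene, size = length(grp),
               dist = gt$observed_distance, p = gt$p_value)
  })
  tab <- do.call(rbind, rows)
  tab <- tab[order(tab$p, -tab$size, tab$gene, na.last = TRUE), ,
             drop = FALSE]
  rownames(tab) <- NULL
  tab
}

#' Classify variants in known disease genes as PV / LPV / VUS
#'
#' Pathogenic variant (PV): present in the mutation database (`hgmd`)
#' with a matched phenotype. Likely pathogenic variant (LPV): not in the
#' database, in a gene whose previously reported cases match the case's
#' phenotype. All other variants are of unknown significance (VUS).
#' A PV or LPV is then demoted to VUS when any other collection case
#' carrying the same variant has an inconsistent relationship with
#' phenotype and mode of inheritance (operationally:
#' `phenotype_match == "unmatched"`); all carriers of such a variant are
#' demoted together, and the demotion is recorded in the rationale.
#'
#' @param records a `"variant_table"` restricted to the known-gene list.
#' @param known_genes character vector of known disease genes; a record in
#'   any other gene is an error (such genes belong in
#'   [gene_similarity_scan()]).
#' @return data frame: the input plus `classification`
#'   (`PV`/`LPV`/`VUS`) and `rationale` (rule trace).
#' @export
classify_variants <- function(records, known_genes) {
  recs <- as.data.frame(variant_table(as.data.frame(records)))
  outside <- setdiff(unique(recs$gene), known_genes)
  if (length(outside)) {
    stop("gene(s) not in the known-gene list: ",
         paste(outside, collapse = ", "),
         "; use gene_similarity_scan for discovery genes")
  }
  matched <- recs$phenotype_match == "matched"
  cls <- ifelse(recs$hgmd & matched, "PV",
                ifelse(!recs$hgmd & matched, "LPV", "VUS"))
  rationale <- ifelse(
    cls == "PV", "in mutation database with matched phenotype",
    ifelse(cls == "LPV",
           "not in mutation database; gene phenotype matched",
           ifelse(recs$hgmd,
                  "in mutation database but phenotype not matched",
                  "no database support and phenotype not matched")))
  # demotion: any carrier of the same variant with an unmatched phenotype
  for (vid in unique(recs$variant_id)) {
    rows <- which(recs$variant_id == vid)
    if (any(recs$phenotype_match[rows] == "unmatched")) {
      demote <- rows[cls[rows] %in% c("PV", "LPV")]
      if (length(demote)) {
        rationale[demote] <- paste0(
          rationale[demote], "; demoted ", cls[demote],
          " -> VUS: carrier with inconsistent phenotype for ", vid)
        cls[demote] <- "VUS"
      }
    }
  }
  recs$classification <- cls
  recs$rationale <- rationale
  recs
}

#' Write variant analysis outputs
#'
#' @param x a data frame (retained/excluded/classified variants).
#' @param path output TSV file.
#' @export
write_variants <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
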