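# Pipeline orchestration: one entry point dispatching the analysis
# subcommands, with provenance-stamped artefacts. The thin executable in
# inst/cli wraps this function for shell use.

#' Run configuration for the pipeline
#'
#' @param ontology,cohort,labs,variants,known_genes,groups,exclusion input
#'   file paths (only those needed by the chosen command are required).
#' @param out_dir output directory (created if absent).
#' @param n_subsets Monte-Carlo subset count (default 250000).
#' @param seed integer seed recorded in every artefact.
#' @param k cluster count for the `cluster` command.
#' @param model inheritance model for `genescan`.
#' @param max_ref_af,min_alt_reads,max_inhouse_ac,max_overall_ac variant
#'   filter thresholds (defaults as in [filter_variants()]).
#' @return list of class `"run_config"`.
#' @export
run_config <- function(ontology = NULL, cohort = NULL, labs = NULL,
                       variants = NULL, known_genes = NULL, groups = NULL,
                       exclusion = NULL, out_dir = ".",
                       n_subsets = 250000L, seed = 1L, k = 2L,
                       model = "autosomal_dominant",
                       max_ref_af = 0.001, min_alt_reads = 3L,
                       max_inhouse_ac = 1L, max_overall_ac = 20L) {
  structure(as.list(environment()), class = "run_config")
}

provenance <- function(config) {
  cfg <- unclass(config)
  cfg <- cfg[!vapply(cfg, is.null, logical(1))]
  list(tool = "phenoclust",
       version = as.character(utils::packageVersion("phenoclust")),
       seed = config$seed,
       config_hash = sum(utf8ToInt(paste(
         names(cfg), vapply(cfg, paste, character(1), collapse = ","),
         collapse = "|"))),
       config = cfg)
}

write_provenance <- function(config, path) {
  jsonlite::write_json(provenance(config), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
}

#' Run a pipeline command
#'
#' Commands:
#' \describe{
#'   \item{annotate}{load ontology + cohort, apply term filtering; writes
#'     the analysis-ready cohort.}
#'   \item{simmatrix}{fit term frequencies and write the case-similarity
#'     matrix.}
#'   \item{grouptest}{Monte-Carlo closeness test for each group in the
#'     groups file (TSV: `group_id`, `case_ids` semicolon-joined).}
#'   \item{cluster}{PAM partition of the index cases plus per-cluster
#'     Fisher-exact term summaries.}
#'   \item{variants}{apply the six exclusion filters; writes retained and
#'     excluded tables.}
#'   \item{genescan}{filter variants, group carriers by gene under the
#'     inheritance model, and rank genes by group-similarity P.}
#'   \item{simulate}{write a synthetic ontology, cohort, variant table and
#'     truth labels.}
#' }
#' Every invocation writes `provenance.json` (tool version, seed, config)
#' into the output directory. On error, partially written artefacts from
#' the failed invocation are removed.
#'
#' @param command one of the commands above.
#' @param config a [run_config()].
#' @return invisibly, a named list of artefact paths.
#' @export
run_pipeline <- function(command = c("annotate", "simmatrix", "grouptest",
                                     "cluster", "variants", "genescan",
                                     "simulate"),
                         config = run_config()) {
  command <- match.arg(command)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  out <- function(name) {
    p <- file.path(config$out_dir, name)
    written <<- c(written, p)
    p
  }
  need <- function(field) {
    p <- config[[field]]
    if (is.null(p)) stop("command '", command, "' requires config$", field)
    if (!file.exists(p)) stop("input not found: ", p)
    p
  }
  artefacts <- tryCatch({
    res <- switch(command,
      annotate = {
        onto <- load_obo(need("ontology"))
        cohort <- load_cohort(need("cohort"), onto)
        excl <- if (!is.null(config$exclusion)) {
          readLines(need("exclusion"), warn = FALSE)
        } else character(0)
        cohort <- filter_terms(cohort, onto, exclusion = excl)
        write_cohort(cohort, out("cohort_annotated.tsv"))
        list(cohort = file.path(config$out_dir, "cohort_annotated.tsv"))
      },
      simmatrix = {
        onto <- load_obo(need("ontology"))
        cohort <- load_cohort(need("cohort"), onto)
        model <- fit_frequencies(cohort, onto)
        simmat <- similarity_matrix(
          filter_terms(cohort, onto), model, onto)
        write_similarity_matrix(simmat, out("similarity_matrix.tsv"))
        model_to_json(model, out("term_ic.json"))
        list(simmat = file.path(config$out_dir, "similarity_matrix.tsv"))
      },
      grouptest = {
        onto <- load_obo(need("ontology"))
        cohort <- load_cohort(need("cohort"), onto)
        model <- fit_frequencies(cohort, onto)
        cohort_f <- filter_terms(cohort, onto)
        simmat <- similarity_matrix(cohort_f, model, onto)
        gtab <- utils::read.delim(need("groups"), sep = "\t",
                                  stringsAsFactors = FALSE)
        rankdist <- rank_distance_matrix(simmat)
        idx <- case_ids(cohort_f, index_only = TRUE)
        results <- lapply(seq_len(nrow(gtab)), function(i) {
          z <- trimws(strsplit(gtab$case_ids[[i]], ";")[[1L]])
          monte_carlo_group_p(z, simmat, eligible = idx,
                              n_subsets = config$n_subsets,
                              seed = config$seed, rankdist = rankdist)
        })
        names(results) <- gtab$group_id
        write_group_tests(results, out("group_tests.tsv"))
        list(results = file.path(config$out_dir, "group_tests.tsv"))
      },
      cluster = {
        onto <- load_obo(need("ontology"))
        cohort <- load_cohort(need("cohort"), onto)
        model <- fit_frequencies(cohort, onto)
        cohort_f <- filter_terms(cohort, onto)
        simmat <- similarity_matrix(cohort_f, model, onto)
        part <- pam_partition(simmat, config$k, cohort = cohort_f)
        write_partition(part, out("clusters.tsv"))
        summaries <- lapply(seq_len(config$k), function(ci) {
          characterize_cluster(part, ci, cohort_f, onto)
        })
        write_cluster_summaries(summaries, out("cluster_summaries.json"))
        list(partition = file.path(config$out_dir, "clusters.tsv"),
             summaries = file.path(config$out_dir,
                                   "cluster_summaries.json"))
      },
      variants = {
        recs <- load_variants(need("variants"))
        flt <- filter_variants(recs,
                               max_ref_af = config$max_ref_af,
                               min_alt_reads = config$min_alt_reads,
                               max_inhouse_ac = config$max_inhouse_ac,
                               max_overall_ac = config$max_overall_ac)
        write_variants(flt$retained, out("variants_retained.tsv"))
        write_variants(flt$excluded, out("variants_excluded.tsv"))
        list(retained = file.path(config$out_dir,
                                  "variants_retained.tsv"),
             excluded = file.path(config$out_dir,
                                  "variants_excluded.tsv"))
      },
      genescan = {
        onto <- load_obo(need("ontology"))
        cohort <- load_cohort(need("cohort"), onto)
        model <- fit_frequencies(cohort, onto)
        cohort_f <- filter_terms(cohort, onto)
        simmat <- similarity_matrix(cohort_f, model, onto)
        recs <- load_variants(need("variants"))
        flt <- filter_variants(recs,
                               max_ref_af = config$max_ref_af,
                               min_alt_reads = config$min_alt_reads,
                               max_inhouse_ac = config$max_inhouse_ac,
                               max_overall_ac = config$max_overall_ac)
        groups <- group_cases_by_gene(flt$retained, cohort_f,
                                      model = config$model)
        scan <- gene_similarity_scan(
          groups, simmat,
          eligible = case_ids(cohort_f, index_only = TRUE),
          n_subsets = config$n_subsets, seed = config$seed)
        utils::write.table(scan, out("gene_scan.tsv"), sep = "\t",
                           quote = FALSE, row.names = FALSE)
        list(scan = file.path(config$out_dir, "gene_scan.tsv"))
      },
      simulate = {
        cfg <- sim_config(seed = config$seed)
        onto <- simulate_ontology(cfg)
        sim <- simulate_cohort(onto, cfg)
        vars <- simulate_variants(sim, cfg)
        write_obo(onto, out("ontology.obo"))
        write_cohort(sim$cohort, out("cohort.tsv"))
        write_variants(vars, out("variants.tsv"))
        jsonlite::write_json(
          list(truth = sim$truth, cores = sim$cores,
               planted_gene = cfg$planted_gene),
          out("truth.json"), auto_unbox = TRUE, digits = NA)
        list(ontology = file.path(config$out_dir, "ontology.obo"),
             cohort = file.path(config$out_dir, "cohort.tsv"),
             variants = file.path(config$out_dir, "variants.tsv"),
             truth = file.path(config$out_dir, "truth.json"))
      })
    write_provenance(config, out("provenance.json"))
    res
  }, error = function(e) {
    unlink(written)
    stop("command '", command, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
  invisible(artefacts)
}
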