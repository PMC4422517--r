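# Cohort annotation: case phenotypes as explicit ontology term sets plus
# metadata, lab-driven automatic/suggested annotation, and term filtering.

#' Construct a cohort of annotated cases
#'
#' @param case_id character vector of unique case identifiers.
#' @param terms named list mapping case id to a character vector of
#'   explicit ontology term ids (the annotation set D of a case).
#' @param gender factor-like vector in `{"male","female","unknown"}`.
#' @param pedigree_id pedigree identifier per case (`NA` when unrelated).
#' @param is_index logical; `TRUE` for index cases, `FALSE` for affected
#'   relatives.
#' @return An object of class `"cohort"`: list with `terms` (named list)
#'   and `meta` (data frame with the remaining columns).
#' @export
new_cohort <- function(case_id, terms,
                       gender = "unknown",
                       pedigree_id = NA_character_,
                       is_index = TRUE) {
  case_id <- as.character(case_id)
  if (anyDuplicated(case_id)) {
    stop("duplicate case_id: ",
         paste(unique(case_id[duplicated(case_id)]), collapse = ", "))
  }
  terms <- lapply(terms, function(x) unique(as.character(x)))
  names(terms) <- case_id
  gender <- rep_len(as.character(gender), length(case_id))
  bad_gender <- setdiff(gender, c("unknown", "male", "female"))
  if (length(bad_gender)) {
    stop("gender must be one of male/female/unknown, got: ",
         paste(bad_gender, collapse = ", "))
  }
  meta <- data.frame(
    case_id = case_id,
    gender = rep_len(gender, length(case_id)),
    pedigree_id = rep_len(as.character(pedigree_id), length(case_id)),
    is_index = rep_len(as.logical(is_index), length(case_id)),
    stringsAsFactors = FALSE
  )
  structure(list(terms = terms, meta = meta), class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  n <- length(x$terms)
  cat("Cohort of", n, "cases (", sum(x$meta$is_index), "index );",
      "median", stats::median(lengths(x$terms)), "terms/case\n")
  invisible(x)
}

#' Case ids of a cohort
#' @param cohort a `"cohort"` object.
#' @param index_only restrict to index cases?
#' @return character vector.
#' @export
case_ids <- function(cohort, index_only = FALSE) {
  ids <- cohort$meta$case_id
  if (index_only) ids <- ids[cohort$meta$is_index]
  ids
}

#' Load a cohort annotation table
#'
#' Reads a tab-separated table with columns `case_id`, `hpo_ids`
#' (semicolon-joined term ids), `gender`, `pedigree_id`, `is_index`.
#' All term ids are validated against the ontology, aliases resolved and
#' within-case duplicates removed.
#'
#' @param path path to the TSV file.
#' @param onto ontology used for validation.
#' @return a `"cohort"` object.
#' @export
load_cohort <- function(path, onto) {
  tab <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                           colClasses = "character")
  required <- c("case_id", "hpo_ids", "gender", "pedigree_id", "is_index")
  missing <- setdiff(required, names(tab))
  if (length(missing)) {
    stop("cohort table missing column(s): ", paste(missing, collapse = ", "))
  }
  if (!nrow(tab)) {
    warning("cohort file ", path, " contains no cases", call. = FALSE)
    return(new_cohort(character(0), list()))
  }
  if (anyDuplicated(tab$case_id)) {
    stop("duplicate case_id in ", path, ": ",
         paste(unique(tab$case_id[duplicated(tab$case_id)]), collapse = ", "))
  }
  term_sets <- strsplit(tab$hpo_ids, ";", fixed = TRUE)
  term_sets <- lapply(term_sets, function(x) trimws(x[nzchar(trimws(x))]))
  for (i in seq_along(term_sets)) {
    term_sets[[i]] <- tryCatch(
      unique(resolve_terms(onto, term_sets[[i]])),
      error = function(e) {
        stop("case ", tab$case_id[[i]], ": ", conditionMessage(e),
             call. = FALSE)
      })
  }
  ped <- tab$pedigree_id
  ped[!nzchar(ped)] <- NA_character_
  new_cohort(tab$case_id, term_sets,
             gender = ifelse(nzchar(tab$gender), tab$gender, "unknown"),
             pedigree_id = ped,
             is_index = tolower(tab$is_index) %in% c("true", "1", "yes"))
}

#' Reference-interval annotation rules
#'
#' One rule per assay/gender combination. A numeric lab value strictly
#' below `lower` triggers `term_below`, strictly above `upper` triggers
#' `term_above`; values on the boundary or inside the interval trigger
#' nothing. `mode = "automatic"` rules add the term directly;
#' `mode = "suggested"` rules only emit a suggestion for manual review.
#'
#' Defaults ship for platelet count (PLT, 100--400 x10^9/L) and mean
#' platelet volume (MPV, 6--12 fL); all other assays must be configured.
#'
#' @param assay assay name matched against the lab table.
#' @param unit unit string; lab rows must match exactly.
#' @param lower,upper interval bounds (either may be `NA`).
#' @param gender applicability: `"any"`, `"male"` or `"female"`.
#' @param term_below,term_above ontology ids added/suggested outside the
#'   interval (either may be `NA`).
#' @param mode `"automatic"` or `"suggested"`.
#' @return data frame of class `"interval_rules"` (rbind-able).
#' @export
interval_rule <- function(assay, unit, lower = NA_real_, upper = NA_real_,
                          gender = "any",
                          term_below = NA_character_,
                          term_above = NA_character_,
                          mode = c("automatic", "suggested")) {
  mode <- match.arg(mode)
  if (!is.na(lower) && !is.na(upper) && !(lower < upper)) {
    stop("interval_rule: lower must be < upper")
  }
  if (is.na(term_below) && is.na(term_above)) {
    stop("interval_rule: at least one of term_below/term_above required")
  }
  structure(
    data.frame(assay = assay, unit = unit, lower = lower, upper = upper,
               gender = gender, term_below = term_below,
               term_above = term_above, mode = mode,
               stringsAsFactors = FALSE),
    class = c("interval_rules", "data.frame")
  )
}

#' Default reference-interval rules (PLT and MPV)
#'
#' @param plt_term_low,plt_term_high,mpv_term_low,mpv_term_high ontology
#'   ids to attach; defaults are the standard HPO ids for
#'   thrombocytopenia, thrombocytosis and decreased/increased mean
#'   platelet volume.
#' @return an `"interval_rules"` data frame with two automatic rules.
#' @export
default_interval_rules <- function(plt_term_low = "HP:0001873",
                                   plt_term_high = "HP:0001894",
                                   mpv_term_low = "HP:0005537",
                                   mpv_term_high = "HP:0011877") {
  rbind(
    interval_rule("PLT", "x10^9/L", lower = 100, upper = 400,
                  term_below = plt_term_low, term_above = plt_term_high,
                  mode = "automatic"),
    interval_rule("MPV", "fL", lower = 6, upper = 12,
                  term_below = mpv_term_low, term_above = mpv_term_high,
                  mode = "automatic")
  )
}

#' Annotate cases from laboratory results
#'
#' Applies reference-interval rules to a lab-result table. Automatic rules
#' add the out-of-interval term to the case's annotation set; suggested
#' rules (and automatic rules whose gender restriction cannot be checked
#' because the case gender is unknown) emit suggestions for manual
#' confirmation instead. Running the function twice adds nothing new.
#'
#' @param cohort a `"cohort"`.
#' @param labs data frame with columns `case_id`, `assay`, `value`, `unit`.
#' @param rules an `"interval_rules"` data frame,
#'   e.g. [default_interval_rules()].
#' @return list with `cohort` (terms possibly extended) and `suggestions`
#'   (data frame `case_id`, `term`, `reason`).
#' @export
auto_annotate <- function(cohort, labs, rules = default_interval_rules()) {
  stopifnot(inherits(cohort, "cohort"))
  sug_case <- character(0); sug_term <- character(0); sug_reason <- character(0)
  for (i in seq_len(nrow(labs))) {
    cid <- as.character(labs$case_id[[i]])
    if (!cid %in% names(cohort$terms)) {
      stop("lab result for unknown case: ", cid)
    }
    g <- cohort$meta$gender[match(cid, cohort$meta$case_id)]
    rr <- rules[rules$assay == labs$assay[[i]], , drop = FALSE]
    if (!nrow(rr)) {
      stop("no interval rule covers assay '", labs$assay[[i]], "'")
    }
    rr_g <- rr[rr$gender %in% c("any", g), , drop = FALSE]
    gender_blocked <- nrow(rr_g) == 0L && g == "unknown"
    if (gender_blocked) rr_g <- rr   # evaluate, but only ever suggest
    for (j in seq_len(nrow(rr_g))) {
      rule <- rr_g[j, ]
      if (!identical(as.character(labs$unit[[i]]), rule$unit)) {
        stop("unit mismatch for assay ", rule$assay, ": lab '",
             labs$unit[[i]], "' vs rule '", rule$unit, "'")
      }
      val <- as.numeric(labs$value[[i]])
      term <- NA_character_; why <- NULL
      if (!is.na(rule$lower) && val < rule$lower && !is.na(rule$term_below)) {
        term <- rule$term_below
        why <- sprintf("%s %g %s < lower limit %g", rule$assay, val,
                       rule$unit, rule$lower)
      } else if (!is.na(rule$upper) && val > rule$upper &&
                 !is.na(rule$term_above)) {
        term <- rule$term_above
        why <- sprintf("%s %g %s > upper limit %g", rule$assay, val,
                       rule$unit, rule$upper)
      }
      if (is.na(term)) next
      if (rule$mode == "automatic" && !gender_blocked) {
        cohort$terms[[cid]] <- unique(c(cohort$terms[[cid]], term))
      } else {
        reason <- if (gender_blocked) {
          paste0(why, " (gender-restricted rule, case gender unknown)")
        } else why
        sug_case <- c(sug_case, cid)
        sug_term <- c(sug_term, term)
        sug_reason <- c(sug_reason, reason)
      }
    }
  }
  list(cohort = cohort,
       suggestions = data.frame(case_id = sug_case, term = sug_term,
                                reason = sug_reason,
                                stringsAsFactors = FALSE))
}

#' Remove excluded and redundant terms from case annotation sets
#'
#' Excluded term ids (for example gender-specific terms such as
#' menorrhagia, which confound similarity between male and female cases)
#' are removed from every case. With `reduce_redundancy`, any term that is
#' a proper ancestor of another term annotated to the same case is
#' removed, so no case retains an ancestor-descendant pair. Cases left
#' with an empty term set are dropped with a warning; they cannot enter
#' similarity analyses.
#'
#' @param cohort a `"cohort"`.
#' @param onto the ontology.
#' @param exclusion character vector of term ids to strip (may be empty).
#' @param reduce_redundancy drop in-case proper ancestors? Default `TRUE`.
#' @return the filtered `"cohort"`.
#' @export
filter_terms <- function(cohort, onto, exclusion = character(),
                         reduce_redundancy = TRUE) {
  stopifnot(inherits(cohort, "cohort"))
  if (length(exclusion)) exclusion <- resolve_terms(onto, exclusion)
  new_terms <- lapply(cohort$terms, function(d) {
    d <- setdiff(d, exclusion)
    if (reduce_redundancy && length(d) > 1L) {
      proper_anc <- unique(unlist(
        lapply(d, function(t) setdiff(onto$ancestors[[t]], t)),
        use.names = FALSE))
      d <- setdiff(d, proper_anc)
    }
    d
  })
  empty <- names(new_terms)[lengths(new_terms) == 0L]
  if (length(empty)) {
    warning("dropping case(s) with empty term set after filtering: ",
            paste(empty, collapse = ", "), call. = FALSE)
    keep <- setdiff(names(new_terms), empty)
    cohort$meta <- cohort$meta[cohort$meta$case_id %in% keep, , drop = FALSE]
    new_terms <- new_terms[keep]
  }
  cohort$terms <- new_terms
  cohort
}

#' Write a cohort back to the TSV interchange format
#'
#' @param cohort a `"cohort"`.
#' @param path output file.
#' @export
write_cohort <- function(cohort, path) {
  tab <- data.frame(
    case_id = cohort$meta$case_id,
    hpo_ids = vapply(cohort$terms[cohort$meta$case_id],
                     paste, character(1), collapse = ";"),
    gender = cohort$meta$gender,
    pedigree_id = ifelse(is.na(cohort$meta$pedigree_id), "",
                         cohort$meta$pedigree_id),
    is_index = ifelse(cohort$meta$is_index, "true", "false"),
    stringsAsFactors = FALSE
  )
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
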