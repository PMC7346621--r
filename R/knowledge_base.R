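#' @title The complexity-factor knowledge base
#' @description The catalogue of 61 complexity factors, the question bank
#'   (key questions bound to automated findings, distinct questions asked
#'   regardless of findings, and one open-ended question), and the measure
#'   registry (recommendations for action, training-material stubs, and
#'   references to the five alternative-drug algorithms). Content lives in a
#'   packaged, human-editable JSON file so it can be revised without code
#'   changes; `load_knowledge_base()` cross-links and validates it.
#' @name knowledge_base
NULL

kb_categories <- c("dosage_form", "dosage_scheme", "additional_instructions",
                   "patient", "product", "process")
kb_mechanisms <- c("pzn", "dosage_scheme", "schedule_lines", "keywords",
                   "pzn_and_keywords")
kb_measure_types <- c("recommendation_for_action", "training_material", "algorithm")
kb_algorithms <- c("alternative_strength", "alternative_form",
                   "frequency_reduction", "combination_product",
                   "prefilled_device")

#' Path of a packaged data file
#'
#' @param file File name under `inst/extdata`.
#' @return Absolute path.
#' @keywords internal
kb_default_path <- function(file = "knowledge_base.json") {
  system.file("extdata", file, package = "medcomplexity", mustWork = TRUE)
}

#' Load and validate the knowledge base
#'
#' Reads the packaged (or a user-supplied) JSON knowledge base and checks
#' every structural invariant: 61 factors, the expected automation flags and
#' category populations, cross-references from factors to questions and
#' measures, exactly 8 distinct questions plus 1 open question, and exactly 5
#' distinct substitution algorithms in the measure registry.
#'
#' @param path Path to a KB JSON file; defaults to the packaged catalogue.
#' @param validate If `FALSE`, skip invariant checking (test harness use).
#' @return An object of class `knowledge_base` with elements `factors`,
#'   `questions`, `measures` (each a named list keyed by id), `factor_order`,
#'   and `meta`.
#' @export
load_knowledge_base <- function(path = kb_default_path(), validate = TRUE) {
  raw <- tryCatch(jsonlite::read_json(path),
                  error = function(e) stop("cannot parse knowledge base ", path,
                                           ": ", conditionMessage(e), call. = FALSE))
  for (key in c("factors", "questions", "measures")) {
    if (is.null(raw[[key]])) stop("knowledge base lacks top-level key '", key, "'",
                                  call. = FALSE)
  }
  factors <- raw$factors
  names(factors) <- vapply(factors, function(x) x$factor_id %||% stop(
    "factor record without factor_id", call. = FALSE), "")
  questions <- raw$questions
  names(questions) <- vapply(questions, `[[`, "", "question_id")
  measures <- raw$measures
  names(measures) <- vapply(measures, `[[`, "", "measure_id")
  kb <- structure(list(factors = factors,
                       questions = questions,
                       measures = measures,
                       factor_order = names(factors),
                       meta = list(version = raw$kb_version %||% NA_character_,
                                   language = raw$language %||% "en",
                                   path = normalizePath(path),
                                   digest = file_digest(path))),
                  class = "knowledge_base")
  if (validate) {
    violations <- validate_kb(kb)
    if (length(violations)) {
      stop("knowledge base failed validation:\n  - ",
           paste(violations, collapse = "\n  - "), call. = FALSE)
    }
  }
  kb
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# stable content digest used to identify inputs in reports
file_digest <- function(path) unname(tools::md5sum(path))

#' @export
print.knowledge_base <- function(x, ...) {
  s <- kb_stats(x)
  cat("<knowledge_base> version ", x$meta$version, " (", x$meta$language, ")\n",
      "  ", s$n_factors, " factors (", s$n_automated, " automated, ",
      s$n_in_tool, " in tool), ", s$n_distinct_questions,
      " distinct questions, ", s$n_algorithms, " algorithms\n", sep = "")
  invisible(x)
}

#' Validate knowledge-base invariants
#'
#' Violations are returned as data, not raised: each element names the
#' offending record and the broken rule. An empty character vector means the
#' KB is valid.
#'
#' @param kb A `knowledge_base` (possibly loaded with `validate = FALSE`).
#' @return Character vector of violation descriptions.
#' @export
validate_kb <- function(kb) {
  v <- character()
  f <- kb$factors
  q <- kb$questions
  m <- kb$measures

  if (length(f) != 61) {
    v <- c(v, sprintf("expected 61 factors, found %d", length(f)))
  }
  if (anyDuplicated(names(f))) v <- c(v, "duplicate factor_id")
  if (anyDuplicated(names(q))) v <- c(v, "duplicate question_id")
  if (anyDuplicated(names(m))) v <- c(v, "duplicate measure_id")

  for (fac in f) {
    id <- fac$factor_id
    if (!(fac$category %in% kb_categories)) {
      v <- c(v, sprintf("factor %s: unknown category '%s'", id, fac$category))
    }
    auto <- isTRUE(fac$automated)
    mech <- fac$detection_mechanism
    if (auto && (is.null(mech) || !(mech %in% kb_mechanisms))) {
      v <- c(v, sprintf("factor %s: automated but mechanism missing/unknown", id))
    }
    if (!auto && !is.null(mech)) {
      v <- c(v, sprintf("factor %s: non-automated factor carries a mechanism", id))
    }
    qids <- unlist(fac$question_ids)
    mids <- unlist(fac$measure_ids)
    if (isTRUE(fac$in_tool)) {
      if (length(qids) < 1) v <- c(v, sprintf("factor %s: in tool but no question", id))
      if (length(mids) < 1) v <- c(v, sprintf("factor %s: in tool but no measure", id))
    } else {
      if (length(qids) > 0 || length(mids) > 0) {
        v <- c(v, sprintf("factor %s: not considered in tool but has questions/measures", id))
      }
      if (auto) v <- c(v, sprintf("factor %s: automated factor cannot be out of tool", id))
    }
    dangling_q <- setdiff(qids, names(q))
    if (length(dangling_q)) {
      v <- c(v, sprintf("factor %s: dangling question reference %s", id,
                        paste(dangling_q, collapse = ", ")))
    }
    dangling_m <- setdiff(mids, names(m))
    if (length(dangling_m)) {
      v <- c(v, sprintf("factor %s: dangling measure reference %s", id,
                        paste(dangling_m, collapse = ", ")))
    }
  }

  kinds <- vapply(q, `[[`, "", "kind")
  if (sum(kinds == "distinct") != 8) {
    v <- c(v, sprintf("expected 8 distinct questions, found %d",
                      sum(kinds == "distinct")))
  }
  if (sum(kinds == "open") != 1) {
    v <- c(v, sprintf("expected exactly 1 open question, found %d",
                      sum(kinds == "open")))
  }
  key_ids <- names(q)[kinds == "key"]
  referenced <- unlist(lapply(f[vapply(f, function(x) isTRUE(x$automated), TRUE)],
                              function(x) unlist(x$question_ids)))
  orphans <- setdiff(key_ids, referenced)
  if (length(orphans)) {
    v <- c(v, sprintf("key question(s) not referenced by any automated factor: %s",
                      paste(orphans, collapse = ", ")))
  }
  for (qu in q) {
    for (sb in unlist(qu$shared_by)) {
      if (!(sb %in% names(f))) {
        v <- c(v, sprintf("question %s: shared_by references unknown factor %s",
                          qu$question_id, sb))
      }
    }
    if (is.null(qu$parts) || !length(qu$parts)) {
      v <- c(v, sprintf("question %s: no parts", qu$question_id))
      next
    }
    for (p in qu$parts) {
      pred <- p$predicate$name %||% ""
      if (!(pred %in% c("yes_is_problem", "no_is_problem", "numeric_below",
                        "numeric_above", "info"))) {
        v <- c(v, sprintf("question %s: unknown predicate '%s'", qu$question_id, pred))
      }
      if (pred %in% c("numeric_below", "numeric_above") &&
          is.null(p$predicate$threshold)) {
        v <- c(v, sprintf("question %s: numeric predicate without threshold",
                          qu$question_id))
      }
    }
  }

  for (me in m) {
    if (!(me$type %in% kb_measure_types)) {
      v <- c(v, sprintf("measure %s: unknown type '%s'", me$measure_id, me$type))
    }
    if (identical(me$type, "algorithm") && is.null(me$algorithm_ref)) {
      v <- c(v, sprintf("measure %s: algorithm measure without algorithm_ref",
                        me$measure_id))
    }
  }
  alg_refs <- unique(unlist(lapply(m, function(x) x$algorithm_ref)))
  if (length(alg_refs) != 5) {
    v <- c(v, sprintf("expected 5 algorithms, found %d (%s)", length(alg_refs),
                      paste(alg_refs, collapse = ", ")))
  }
  unknown_algs <- setdiff(alg_refs, kb_algorithms)
  if (length(unknown_algs)) {
    v <- c(v, sprintf("unknown algorithm_ref(s): %s",
                      paste(unknown_algs, collapse = ", ")))
  }
  v
}

#' Summarize knowledge-base structure
#'
#' All counts are computed by enumeration over the loaded records, never
#' hard-coded: deleting a factor from a KB copy decrements the counts.
#'
#' @param kb A `knowledge_base`.
#' @return A list of class `kb_stats` with counts: `n_factors`,
#'   `n_automated`, `n_not_automated`, `n_in_tool`, `n_not_considered`,
#'   `n_per_category`, `n_per_mechanism`, `n_distinct_questions`,
#'   `n_key_questions`, `n_open_questions`, `n_algorithms`, `n_measures`.
#' @export
kb_stats <- function(kb) {
  stopifnot(inherits(kb, "knowledge_base"))
  f <- kb$factors
  auto <- vapply(f, function(x) isTRUE(x$automated), TRUE)
  in_tool <- vapply(f, function(x) isTRUE(x$in_tool), TRUE)
  cats <- vapply(f, function(x) as.character(x$category %||% NA_character_), "")
  mech <- vapply(f, function(x) {
    if (isTRUE(x$automated)) as.character(x$detection_mechanism) else NA_character_
  }, "")
  kinds <- vapply(kb$questions, `[[`, "", "kind")
  n_per_category <- vapply(kb_categories, function(k) sum(cats == k, na.rm = TRUE), 0L)
  n_per_mechanism <- vapply(kb_mechanisms, function(k) sum(mech == k, na.rm = TRUE), 0L)
  structure(list(
    n_factors = length(f),
    n_automated = sum(auto),
    n_not_automated = sum(!auto),
    n_in_tool = sum(in_tool),
    n_not_considered = sum(!in_tool),
    n_per_category = as.list(n_per_category),
    n_per_mechanism = as.list(n_per_mechanism),
    n_distinct_questions = sum(kinds == "distinct"),
    n_key_questions = sum(kinds == "key"),
    n_open_questions = sum(kinds == "open"),
    n_algorithms = length(unique(unlist(lapply(kb$measures,
                                               function(x) x$algorithm_ref)))),
    n_measures = length(kb$measures)
  ), class = "kb_stats")
}

#' @export
print.kb_stats <- function(x, ...) {
  cat("Complexity-factor catalogue\n")
  cat(sprintf("  factors:            %d\n", x$n_factors))
  cat(sprintf("  automated:          %d\n", x$n_automated))
  cat(sprintf("  not automated:      %d\n", x$n_not_automated))
  cat(sprintf("  considered in tool: %d\n", x$n_in_tool))
  cat(sprintf("  not considered:     %d\n", x$n_not_considered))
  cat("  per category:\n")
  for (k in names(x$n_per_category)) {
    cat(sprintf("    %-24s %d\n", k, x$n_per_category[[k]]))
  }
  cat(sprintf("  distinct questions: %d\n", x$n_distinct_questions))
  cat(sprintf("  key questions:      %d\n", x$n_key_questions))
  cat(sprintf("  algorithms:         %d\n", x$n_algorithms))
  invisible(x)
}

#' Serialize a knowledge base back to JSON
#'
#' Semantic round-trip partner of [load_knowledge_base()] (field order in the
#' file is not significant).
#'
#' @param kb A `knowledge_base`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_knowledge_base <- function(kb, path) {
  stopifnot(inherits(kb, "knowledge_base"))
  out <- list(kb_version = kb$meta$version,
              language = kb$meta$language,
              factors = unname(kb$factors),
              questions = unname(kb$questions),
              measures = unname(kb$measures))
  jsonlite::write_json(out, path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}
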