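#' @title Assessment reports
#' @description The JSON report produced by the analysis pipeline: a config
#'   echo, digests identifying every input, the embedded schedule rows, the
#'   findings with evidence, the personalized question set, and -- after the
#'   interview -- the confirmed factors and the measure plan. Identical
#'   inputs yield byte-identical reports (no timestamps unless requested).
#' @name report
NULL

report_schema_version <- "1.0"

#' Run the automated analysis and assemble a report
#'
#' @param schedule A `medication_schedule`.
#' @param drugref A `drug_reference`.
#' @param kb A `knowledge_base`.
#' @param lexicon A `keyword_lexicon`, or `NULL` for the packaged default.
#' @param config A `detection_config`.
#' @param timestamp Include a creation timestamp (off by default so reports
#'   are byte-reproducible).
#' @return A list of class `assessment_report`.
#' @export
analyze_schedule <- function(schedule, drugref, kb = load_knowledge_base(),
                             lexicon = NULL, config = detection_config(),
                             timestamp = FALSE) {
  if (is.null(lexicon)) lexicon <- load_lexicon(language = config$lexicon_language)
  findings <- detect(schedule, drugref, kb, lexicon, config)
  question_set <- build_question_set(findings, kb, schedule)
  structure(list(
    schema_version = report_schema_version,
    tool = list(name = "medcomplexity",
                version = as.character(utils::packageVersion("medcomplexity"))),
    created = if (timestamp) format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z") else NULL,
    config = unclass(config),
    inputs = list(kb_digest = kb$meta$digest,
                  lexicon_digest = lexicon$digest,
                  drugref_digest = attr(drugref, "digest"),
                  schedule_digest = schedule_digest(schedule)),
    schedule = schedule_as_list(schedule),
    findings = lapply(findings, unclass),
    warnings = as.character(attr(findings, "warnings") %||% character()),
    question_set = lapply(question_set, unclass),
    answers = NULL,
    confirmed = NULL,
    plan = NULL
  ), class = "assessment_report")
}

#' Attach interview results to a report
#'
#' Resolves the answers against the report's question set, plans measures
#' for the confirmed factors, and returns the completed report.
#'
#' @param report An `assessment_report` from [analyze_schedule()].
#' @param answers Named list (instance id to value) or data frame/list with
#'   `question_instance_id` and `value` entries.
#' @param drugref The `drug_reference` used for the analysis.
#' @param kb The `knowledge_base`.
#' @return The updated `assessment_report`.
#' @export
interview_report <- function(report, answers, drugref, kb = load_knowledge_base()) {
  stopifnot(inherits(report, "assessment_report"))
  answers <- normalize_answers(answers)
  schedule <- schedule_from_list(report$schedule)
  question_set <- lapply(report$question_set, function(q) {
    structure(q, class = "question_instance")
  })
  confirmed <- resolve_answers(question_set, answers, kb)
  plan <- plan_measures(confirmed, schedule, drugref, kb)
  report$answers <- answers
  report$confirmed <- unclass(confirmed)
  report$plan <- unclass(plan)
  report$warnings <- c(report$warnings, confirmed$warnings)
  report
}

normalize_answers <- function(answers) {
  if (is.null(answers)) return(list())
  if (!is.null(names(answers)) && all(nzchar(names(answers)))) return(answers)
  out <- list()
  for (a in answers) {
    id <- a$question_instance_id %||% a$instance_id
    if (is.null(id)) stop("answer entry without question_instance_id", call. = FALSE)
    out[[id]] <- a$value
  }
  out
}

schedule_as_list <- function(schedule) {
  list(patient_ref = schedule$patient_ref,
       issued_on = schedule$issued_on,
       rows = lapply(schedule$rows, function(r) {
         r$scheme <- NULL  # reparsed on load
         unclass(r)
       }))
}

schedule_from_list <- function(x) {
  rows <- lapply(x$rows, function(r) {
    medication_row(pzn = r$pzn, brand_name = r$brand_name,
                   active_ingredient = r$active_ingredient,
                   dosage_form = r$dosage_form, strength = r$strength,
                   scheme_text = r$scheme_text %||% "", unit = r$unit,
                   instructions = r$instructions %||% "",
                   indication = r$indication,
                   prn = isTRUE(r$prn))
  })
  medication_schedule(rows, patient_ref = x$patient_ref %||% NA_character_,
                      issued_on = x$issued_on %||% NA_character_)
}

schedule_digest <- function(schedule) {
  tmp <- tempfile(fileext = ".xml")
  on.exit(unlink(tmp))
  write_schedule_xml(schedule, tmp)
  file_digest(tmp)
}

#' Write a report as JSON
#'
#' Serialization is deterministic: identical reports produce byte-identical
#' files.
#'
#' @param report An `assessment_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "assessment_report"))
  jsonlite::write_json(drop_nulls(unclass(report)), path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA, na = "null")
  invisible(path)
}

drop_nulls <- function(x) {
  if (!is.list(x)) return(x)
  x <- x[!vapply(x, is.null, TRUE)]
  lapply(x, drop_nulls)
}

#' Read a report written by [write_report()]
#'
#' @param path Report JSON path.
#' @return An `assessment_report`.
#' @export
read_report <- function(path) {
  raw <- jsonlite::read_json(path)
  if (!identical(raw$schema_version, report_schema_version)) {
    stop("unsupported report schema version: ",
         raw$schema_version %||% "<missing>", call. = FALSE)
  }
  structure(raw, class = "assessment_report")
}

#' @export
print.assessment_report <- function(x, ...) {
  cat("<assessment_report> schema ", x$schema_version, "\n", sep = "")
  cat("  rows:      ", length(x$schedule$rows), "\n", sep = "")
  cat("  findings:  ", length(x$findings), "\n", sep = "")
  cat("  questions: ", length(x$question_set), "\n", sep = "")
  if (!is.null(x$confirmed)) {
    cat("  confirmed: ", length(x$confirmed$confirmed), "\n", sep = "")
    cat("  plan:      ", length(x$plan$entries), " entries\n", sep = "")
  }
  if (length(x$warnings)) {
    cat("  warnings:  ", paste(x$warnings, collapse = "; "), "\n", sep = "")
  }
  invisible(x)
}
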