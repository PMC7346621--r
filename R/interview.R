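#' @title Patient interview: personalized question set and resolution
#' @description Turns automated findings into the patient-facing question
#'   set: one key-question instance per (question, row) for every finding
#'   (device-specific variants chosen when the product's subtype is known),
#'   the eight distinct questions asked regardless of findings, and the
#'   open-ended question always asked last. Answers are evaluated against
#'   per-question problem predicates; only factors whose predicate fires are
#'   confirmed and passed on to measure planning.
#' @name interview
NULL

question_instance <- function(question, factor_ids, row_indices, schedule = NULL) {
  rows <- as.integer(row_indices)
  iid <- if (length(rows)) {
    paste0(question$question_id, "@", paste(rows, collapse = "_"))
  } else {
    question$question_id
  }
  prefix <- ""
  if (length(rows) && !is.null(schedule)) {
    brands <- vapply(schedule$rows[rows], function(r) {
      ifelse(is.na(r$brand_name), "?", r$brand_name)
    }, "")
    prefix <- sprintf("[%s] ", paste(brands, collapse = ", "))
  }
  texts <- vapply(question$parts, `[[`, "", "text")
  structure(list(instance_id = iid,
                 question_id = question$question_id,
                 kind = question$kind,
                 factor_ids = factor_ids,
                 row_indices = rows,
                 text = paste0(prefix, paste(texts, collapse = " ")),
                 parts = question$parts,
                 answer_types = vapply(question$parts, `[[`, "", "answer_type")),
            class = "question_instance")
}

#' @export
print.question_instance <- function(x, ...) {
  cat(sprintf("<question> %s (%s): %s\n", x$instance_id, x$kind, x$text))
  invisible(x)
}

# questions of a factor applicable to a finding's device subtype
select_factor_questions <- function(kb, factor_id, device_subtype) {
  qids <- unlist(kb$factors[[factor_id]]$question_ids)
  qs <- kb$questions[qids]
  subtypes <- vapply(qs, function(q) q$device_subtype %||% NA_character_, "")
  generic <- qs[is.na(subtypes)]
  if (!is.na(device_subtype)) {
    matching <- qs[!is.na(subtypes) & subtypes == device_subtype]
    if (length(matching)) return(c(matching, generic))
  }
  if (length(generic)) return(generic)
  fallback <- qs[vapply(qs, function(q) isTRUE(q$fallback), TRUE)]
  if (length(fallback)) return(fallback)
  qs
}

#' Build the personalized question set
#'
#' Key questions are instantiated per finding and per triggering row (no
#' deduplication across rows: each drug gets its own question); shared
#' distinct questions appear exactly once even though they cover several
#' factors; the open question is always present and last.
#'
#' @param findings Result of [detect()].
#' @param kb A validated `knowledge_base`.
#' @param schedule Optional `medication_schedule`; when given, row-bound
#'   question texts are prefixed with the drug's brand name.
#' @return Ordered list of `question_instance` objects.
#' @export
build_question_set <- function(findings, kb, schedule = NULL) {
  stopifnot(inherits(kb, "knowledge_base"))
  instances <- list()
  seen <- character()
  add <- function(inst) {
    if (!(inst$instance_id %in% seen)) {
      seen <<- c(seen, inst$instance_id)
      instances[[length(instances) + 1]] <<- inst
    }
  }
  for (fd in findings) {
    qs <- select_factor_questions(kb, fd$factor_id, fd$device_subtype)
    if (!length(qs)) {
      stop("finding for factor ", fd$factor_id,
           " has no key question in the KB", call. = FALSE)
    }
    if (length(fd$row_indices) > 1 &&
        fd$evidence$type != "ingredient_pair") {
      # per-row phrasing for multi-row per-row findings
      for (r in fd$row_indices) {
        for (q in qs) add(question_instance(q, fd$factor_id, r, schedule))
      }
    } else {
      for (q in qs) {
        add(question_instance(q, fd$factor_id, fd$row_indices, schedule))
      }
    }
  }
  kinds <- vapply(kb$questions, `[[`, "", "kind")
  for (q in kb$questions[kinds == "distinct"]) {
    add(question_instance(q, unlist(q$shared_by), integer(0)))
  }
  open_q <- kb$questions[kinds == "open"]
  add(question_instance(open_q[[1]], character(0), integer(0)))
  instances
}

eval_predicate <- function(predicate, value, instance_id) {
  name <- predicate$name
  if (name == "info") return(FALSE)
  if (name %in% c("yes_is_problem", "no_is_problem")) {
    v <- parse_yes_no(value)
    if (is.na(v)) {
      stop("answer to ", instance_id, " must be yes/no, got: ",
           paste(format(value), collapse = ","), call. = FALSE)
    }
    return(if (name == "yes_is_problem") v else !v)
  }
  if (name %in% c("numeric_below", "numeric_above")) {
    v <- suppressWarnings(as.numeric(value))
    if (length(v) != 1 || is.na(v)) {
      stop("answer to ", instance_id, " must be numeric, got: ",
           paste(format(value), collapse = ","), call. = FALSE)
    }
    thr <- predicate$threshold
    return(if (name == "numeric_below") v < thr else v > thr)
  }
  stop("unknown predicate: ", name, call. = FALSE)
}

parse_yes_no <- function(value) {
  if (is.logical(value) && length(value) == 1 && !is.na(value)) return(value)
  if (is.character(value) && length(value) == 1) {
    v <- tolower(trimws(value))
    if (v %in% c("yes", "y", "true", "ja", "1")) return(TRUE)
    if (v %in% c("no", "n", "false", "nein", "0")) return(FALSE)
  }
  if (is.numeric(value) && length(value) == 1 && value %in% c(0, 1)) {
    return(value == 1)
  }
  NA
}

#' Resolve answers into confirmed complexity factors
#'
#' Each answer is evaluated by its question's problem predicate; multi-part
#' questions combine their sub-answers by OR (any problematic sub-answer
#' confirms). Key-question instances confirm the factor of their finding;
#' distinct questions confirm every factor they cover; the open question's
#' text is stored verbatim as a note, never auto-mapped to a factor.
#' Unanswered questions are treated as not confirming, with a warning.
#'
#' @param question_set Result of [build_question_set()].
#' @param answers Named list mapping `instance_id` to a value (yes/no,
#'   number, or text; multi-part questions take a list/vector of sub-values,
#'   one per part).
#' @param kb The `knowledge_base`.
#' @return A list of class `confirmed_factor_set`: `confirmed` (one entry
#'   per factor: `factor_id`, `row_indices`, `source`), `free_text_notes`,
#'   and `warnings`.
#' @export
resolve_answers <- function(question_set, answers, kb) {
  stopifnot(inherits(kb, "knowledge_base"))
  confirmed <- list()
  notes <- character()
  warnings <- character()

  for (inst in question_set) {
    ans <- answers[[inst$instance_id]]
    if (inst$kind == "open") {
      if (!is.null(ans) && nzchar(trimws(paste(ans, collapse = " ")))) {
        notes <- c(notes, paste(ans, collapse = " "))
      }
      next
    }
    if (is.null(ans)) {
      warnings <- c(warnings, paste0("unanswered question: ", inst$instance_id))
      next
    }
    vals <- if (is.list(ans)) ans else as.list(ans)
    if (length(vals) != length(inst$parts)) {
      if (length(inst$parts) == 1 && length(vals) > 1) {
        stop("answer to ", inst$instance_id, " has ", length(vals),
             " values for a single-part question", call. = FALSE)
      }
      if (length(vals) == 1) vals <- rep(vals, length(inst$parts))
      else stop("answer to ", inst$instance_id, " needs ", length(inst$parts),
                " sub-values, got ", length(vals), call. = FALSE)
    }
    fired <- FALSE
    for (k in seq_along(inst$parts)) {
      fired <- fired || eval_predicate(inst$parts[[k]]$predicate, vals[[k]],
                                       inst$instance_id)
    }
    if (fired) {
      source <- if (inst$kind == "key") "automated+answer" else "distinct_question"
      for (fid in inst$factor_ids) {
        confirmed[[length(confirmed) + 1]] <- list(factor_id = fid,
                                                   row_indices = inst$row_indices,
                                                   source = source)
      }
    }
  }

  # aggregate per factor, union of triggering rows, KB catalogue order
  by_factor <- split(confirmed, vapply(confirmed, `[[`, "", "factor_id"))
  merged <- lapply(by_factor, function(entries) {
    list(factor_id = entries[[1]]$factor_id,
         row_indices = sort(unique(unlist(lapply(entries, `[[`, "row_indices")))),
         source = entries[[1]]$source)
  })
  merged <- merged[order(match(names(merged), kb$factor_order))]
  structure(list(confirmed = unname(merged),
                 free_text_notes = notes,
                 warnings = warnings),
            class = "confirmed_factor_set")
}

#' @export
print.confirmed_factor_set <- function(x, ...) {
  cat("<confirmed_factor_set> ", length(x$confirmed), " factor(s) confirmed\n",
      sep = "")
  for (cf in x$confirmed) {
    rows <- if (length(cf$row_indices)) {
      paste0(" [rows ", paste(cf$row_indices, collapse = ","), "]")
    } else ""
    cat("  - ", cf$factor_id, rows, " (", cf$source, ")\n", sep = "")
  }
  if (length(x$free_text_notes)) {
    cat("  notes: ", paste(x$free_text_notes, collapse = " | "), "\n", sep = "")
  }
  invisible(x)
}

#' Non-problem answer template for a question set
#'
#' Convenience for tests and batch use: returns, for every non-open
#' question, the answer that does **not** confirm a problem.
#'
#' @param question_set Result of [build_question_set()].
#' @return Named list of answers keyed by instance id.
#' @export
answer_template <- function(question_set) {
  out <- list()
  for (inst in question_set) {
    if (inst$kind == "open") next
    out[[inst$instance_id]] <- lapply(inst$parts, function(p) {
      switch(p$predicate$name,
             yes_is_problem = "no",
             no_is_problem = "yes",
             numeric_below = p$predicate$threshold + 1,
             numeric_above = p$predicate$threshold,
             info = "no")
    })
  }
  out
}
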