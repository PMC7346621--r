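#' @title Automated complexity-factor detection
#' @description The 38 automated detection rules. Four rule families screen a
#'   medication schedule: product-attribute rules joined via the Pharmacy
#'   Product Number, dosage-scheme rules over the four-slot dose quadruple,
#'   schedule-level rules over the whole plan (line count, ingredient
#'   duplication), and case-insensitive word-boundary keyword rules over the
#'   free-text fields. Every finding carries evidence (matched keyword, slot
#'   pattern, product attribute, line count, or ingredient pair).
#' @name detection_engine
NULL

# canonical evidence type(s) per KB detection mechanism
mechanism_evidence_types <- list(
  pzn = c("pzn_attribute", "ingredient_pair"),
  dosage_scheme = "slot_pattern",
  schedule_lines = "line_count",
  keywords = "matched_keyword",
  pzn_and_keywords = "pzn_and_keyword"
)

# form_class (+ gates) -> dosage-form factor
form_factor_map <- list(
  inhaler = "inhalers",
  transdermal_patch = "transdermal_patches",
  oropharyngeal_solid = "oropharyngeal_solid",
  oropharyngeal_liquid = "oropharyngeal_liquid",
  ophthalmic = "ophthalmic_preparations",
  rectal = "rectal_preparations",
  liquid_oral = "liquid_oral_forms",
  otological = "otological_preparations",
  vaginal = "vaginal_preparations"
)

#' Detection configuration
#'
#' @param polypharmacy_threshold Row count at or above which the
#'   total-number-of-drugs factor fires. The characteristic ("lines in the
#'   medication schedule") comes from the catalogue; the cut-off of 5 is a
#'   package default following the common polypharmacy convention, and is
#'   configurable.
#' @param lexicon_language Language tag selecting the packaged lexicon
#'   (`"en"` or `"de"`).
#' @param missing_pzn `"warn"` (default) records a warning and skips PZN
#'   rules for rows without a resolvable product; `"ignore"` skips silently.
#' @return A list of class `detection_config`; echoed into every report for
#'   reproducibility.
#' @export
detection_config <- function(polypharmacy_threshold = 5L,
                             lexicon_language = "en",
                             missing_pzn = c("warn", "ignore")) {
  stopifnot(is.numeric(polypharmacy_threshold), polypharmacy_threshold >= 1)
  structure(list(polypharmacy_threshold = as.integer(polypharmacy_threshold),
                 lexicon_language = match.arg(lexicon_language, c("en", "de")),
                 missing_pzn = match.arg(missing_pzn)),
            class = "detection_config")
}

#' Load a keyword lexicon
#'
#' The packaged English lexicon carries the six meal keywords as printed for
#' the meal-dependent factor; all other phrase lists are repository-curated
#' defaults and flagged as such via their `provenance` field. A parallel
#' German lexicon ships alongside.
#'
#' @param path Lexicon JSON path, or `NULL` to select the packaged file for
#'   `language`.
#' @param language `"en"` or `"de"`.
#' @return A list of class `keyword_lexicon` keyed by factor id.
#' @export
load_lexicon <- function(path = NULL, language = "en") {
  if (is.null(path)) {
    path <- kb_default_path(paste0("lexicon_", language, ".json"))
  }
  raw <- jsonlite::read_json(path)
  entries <- raw$entries
  names(entries) <- vapply(entries, `[[`, "", "factor_id")
  for (id in names(entries)) {
    entries[[id]]$phrases <- unlist(entries[[id]]$phrases)
    entries[[id]]$fields <- unlist(entries[[id]]$fields)
    if (!length(entries[[id]]$phrases)) {
      stop("lexicon entry ", id, " has no phrases", call. = FALSE)
    }
  }
  structure(list(language = raw$language %||% language, entries = entries,
                 digest = file_digest(path), source = normalizePath(path)),
            class = "keyword_lexicon")
}

finding <- function(factor_id, row_indices, evidence, device_subtype = NA_character_) {
  structure(list(factor_id = factor_id,
                 row_indices = as.integer(row_indices),
                 evidence = evidence,
                 device_subtype = device_subtype),
            class = "finding")
}

#' @export
print.finding <- function(x, ...) {
  rows <- if (length(x$row_indices)) paste(x$row_indices, collapse = ",") else "plan"
  cat(sprintf("<finding> %s [row %s] evidence=%s\n", x$factor_id, rows,
              x$evidence$type))
  invisible(x)
}

#' Match keyword phrases in free text
#'
#' Unicode-aware, case-insensitive matching at word boundaries: a phrase
#' matches only where it is not embedded in a longer letter/digit run
#' (`"food"` does not match inside `"seafood"`). Multi-word phrases match
#' across single spaces.
#'
#' @param text String to scan.
#' @param phrases Character vector of phrases.
#' @return List of hits, each `list(phrase, start, end)`, in text order.
#' @export
match_keywords <- function(text, phrases) {
  if (length(text) != 1 || is.na(text) || !nzchar(text)) return(list())
  hits <- list()
  for (phrase in phrases) {
    esc <- gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", phrase)
    pattern <- paste0("(?i)(?<![\\p{L}\\p{N}])", esc, "(?![\\p{L}\\p{N}])")
    m <- gregexpr(pattern, text, perl = TRUE)[[1]]
    if (m[1] == -1) next
    lens <- attr(m, "match.length")
    for (k in seq_along(m)) {
      hits[[length(hits) + 1]] <- list(phrase = phrase,
                                       start = as.integer(m[k]),
                                       end = as.integer(m[k] + lens[k] - 1L))
    }
  }
  hits[order(vapply(hits, `[[`, 0L, "start"),
             vapply(hits, `[[`, 0L, "end"))]
}

#' Apply PZN-based rules to one row
#'
#' Maps the product's form class (with device subtype) to its dosage-form
#' factor, applies the prescription-only gate for nasal and dermatological
#' preparations, and fires the attribute-driven factors: palatability issues
#' of liquid oral forms, lack of training in dosage-form use, and
#' self-performed complex measurements (product flag plus a keyword hit in
#' the instructions).
#'
#' @param row A `medication_row`.
#' @param row_index Position of the row in the schedule.
#' @param record The row's `drug_record` (from [drug_lookup()]).
#' @param lexicon A `keyword_lexicon` (for the measurements factor).
#' @return List of findings.
#' @export
apply_pzn_rules <- function(row, row_index, record, lexicon) {
  if (is.null(record)) return(list())
  out <- list()
  fc <- record$form_class
  dev <- record$device_subtype

  factor_id <- NULL
  if (fc %in% names(form_factor_map)) {
    factor_id <- form_factor_map[[fc]]
  } else if (fc == "injection") {
    factor_id <- if (identical(dev, "prefilled_injector")) {
      "injection_prefilled"
    } else {
      "injection_non_prefilled"
    }
  } else if (fc == "nasal" && isTRUE(record$prescription_only)) {
    factor_id <- "nasal_preparations_rx"
  } else if (fc == "dermatological" && isTRUE(record$prescription_only)) {
    factor_id <- "dermatological_preparations_rx"
  }
  if (!is.null(factor_id)) {
    out[[length(out) + 1]] <- finding(
      factor_id, row_index,
      evidence = list(type = "pzn_attribute", attribute = "form_class",
                      value = fc),
      device_subtype = if (is.na(dev)) NA_character_ else dev)
  }

  if (isTRUE(record$palatability_issue) && fc == "liquid_oral") {
    out[[length(out) + 1]] <- finding(
      "unfriendly_liquid_oral", row_index,
      evidence = list(type = "pzn_attribute", attribute = "palatability_issue",
                      value = TRUE))
  }
  if (isTRUE(record$requires_technique_training)) {
    out[[length(out) + 1]] <- finding(
      "lack_of_training", row_index,
      evidence = list(type = "pzn_attribute",
                      attribute = "requires_technique_training", value = TRUE))
  }
  if (isTRUE(record$self_measurement_linked)) {
    entry <- lexicon$entries[["complex_measurements"]]
    hits <- if (is.null(entry)) list() else match_keywords(row$instructions, entry$phrases)
    if (length(hits)) {
      out[[length(out) + 1]] <- finding(
        "complex_measurements", row_index,
        evidence = list(type = "pzn_and_keyword",
                        attribute = "self_measurement_linked",
                        field = "instructions",
                        phrase = hits[[1]]$phrase))
    }
  }
  out
}

#' Apply dosage-scheme rules to one row
#'
#' Seven rules over the four-slot dose quadruple: tablet splitting
#' (fractional slot dose on a solid oral form), administration more than two
#' times daily (more than two non-zero slots), administration at lunch time
#' (non-zero noon slot), multiple doses concurrently (any slot dose of two
#' or more), different doses at different times of day (two or more distinct
#' non-zero slot doses), variable dosing (free-text scheme on a non-PRN
#' row), and being the only drug at one specific point in time (a non-zero
#' slot where every other row is zero; needs at least two rows).
#'
#' @param row A `medication_row`.
#' @param row_index Its position.
#' @param schedule The full `medication_schedule` (for the slot-uniqueness
#'   rule).
#' @param record The row's `drug_record`, or `NULL` (the splitting rule then
#'   stays silent since the solid-oral gate cannot be checked).
#' @return List of findings.
#' @export
apply_scheme_rules <- function(row, row_index, schedule, record = NULL) {
  out <- list()
  sc <- row$scheme
  if (!sc$structured) {
    if (nzchar(trimws(sc$text)) && !row$prn) {
      out[[length(out) + 1]] <- finding(
        "variable_dosing", row_index,
        evidence = list(type = "slot_pattern", scheme_text = sc$text))
    }
    return(out)
  }
  slots <- sc$slots
  ev <- function() list(type = "slot_pattern", slots = slots)

  if (!is.null(record) && identical(record$form_class, "solid_oral") &&
      any(slots > 0 & slots %% 1 != 0)) {
    out[[length(out) + 1]] <- finding("tablet_splitting", row_index, ev())
  }
  if (sum(slots > 0) > 2) {
    out[[length(out) + 1]] <- finding("more_than_twice_daily", row_index, ev())
  }
  if (slots[2] > 0) {
    out[[length(out) + 1]] <- finding("lunch_time_administration", row_index, ev())
  }
  if (any(slots >= 2)) {
    out[[length(out) + 1]] <- finding("multiple_doses_concurrently", row_index, ev())
  }
  if (length(unique(slots[slots > 0])) >= 2) {
    out[[length(out) + 1]] <- finding("different_doses_same_drug", row_index, ev())
  }
  n_rows <- length(schedule$rows)
  if (n_rows >= 2) {
    others <- setdiff(seq_len(n_rows), row_index)
    for (s in which(slots > 0)) {
      other_doses <- vapply(schedule$rows[others], function(r) {
        if (r$scheme$structured) r$scheme$slots[s] else 0
      }, 0)
      if (all(other_doses == 0)) {
        out[[length(out) + 1]] <- finding(
          "only_drug_at_time_point", row_index,
          evidence = list(type = "slot_pattern", slots = slots, slot = s))
        break
      }
    }
  }
  out
}

#' Apply schedule-level rules
#'
#' Two rules over the whole plan: the total number of drugs (line count at
#' or above the polypharmacy threshold) and the same active ingredient
#' appearing in different preparations (two rows whose products share an
#' ingredient under different PZNs).
#'
#' @param schedule A `medication_schedule`.
#' @param drugref A `drug_reference`.
#' @param config A `detection_config`.
#' @return List of findings (each schedule-level factor at most once).
#' @export
apply_schedule_rules <- function(schedule, drugref, config = detection_config()) {
  out <- list()
  n <- length(schedule$rows)
  if (n >= config$polypharmacy_threshold) {
    out[[length(out) + 1]] <- finding(
      "total_number_of_drugs", integer(0),
      evidence = list(type = "line_count", line_count = n,
                      threshold = config$polypharmacy_threshold))
  }
  recs <- lapply(schedule$rows, function(r) drug_lookup(drugref, r$pzn))
  pairs <- list()
  involved <- integer(0)
  for (i in seq_len(max(n - 1, 0))) {
    for (j in seq((i + 1), n)) {
      ri <- recs[[i]]; rj <- recs[[j]]
      if (is.null(ri) || is.null(rj) || identical(ri$pzn, rj$pzn)) next
      shared <- intersect(tolower(ri$active_ingredients),
                          tolower(rj$active_ingredients))
      if (length(shared)) {
        pairs[[length(pairs) + 1]] <- list(rows = c(i, j),
                                           ingredient = shared[1])
        involved <- union(involved, c(i, j))
      }
    }
  }
  if (length(pairs)) {
    out[[length(out) + 1]] <- finding(
      "same_ingredient_different_preparations", sort(involved),
      evidence = list(type = "ingredient_pair", pairs = pairs))
  }
  out
}

#' Apply keyword rules to one row
#'
#' Screens the instructions field (and, for frequency-related factors, the
#' raw scheme text) against each keyword factor's phrase list. A hit yields
#' at most one finding per factor per row, carrying the first matched phrase
#' as evidence. The as-needed (PRN) factor additionally fires on the row's
#' PRN flag.
#'
#' @param row A `medication_row`.
#' @param row_index Its position.
#' @param lexicon A `keyword_lexicon`.
#' @return List of findings.
#' @export
apply_keyword_rules <- function(row, row_index, lexicon) {
  out <- list()
  for (id in names(lexicon$entries)) {
    if (id == "complex_measurements") next  # handled by the PZN family
    entry <- lexicon$entries[[id]]
    hit <- NULL
    for (field in entry$fields) {
      text <- switch(field, instructions = row$instructions,
                     scheme_text = row$scheme_text, "")
      hits <- match_keywords(text, entry$phrases)
      if (length(hits)) {
        hit <- list(field = field, phrase = hits[[1]]$phrase,
                    start = hits[[1]]$start, end = hits[[1]]$end)
        break
      }
    }
    if (is.null(hit) && id == "prn_medication" && isTRUE(row$prn)) {
      hit <- list(field = "prn_flag", phrase = "PRN", start = NA_integer_,
                  end = NA_integer_)
    }
    if (!is.null(hit)) {
      out[[length(out) + 1]] <- finding(
        id, row_index,
        evidence = c(list(type = "matched_keyword"), hit))
    }
  }
  out
}

#' Detect complexity factors in a medication schedule
#'
#' Runs all four rule families and returns the union of their findings in a
#' deterministic order (first triggering row, then factor id; schedule-level
#' findings last). Each per-row factor fires at most once per row, each
#' schedule-level factor at most once per schedule. `detect()` is a pure
#' function of its inputs.
#'
#' @param schedule A `medication_schedule` with at least one row.
#' @param drugref A `drug_reference`.
#' @param kb A validated `knowledge_base`.
#' @param lexicon A `keyword_lexicon`; defaults to the packaged lexicon for
#'   `config$lexicon_language`.
#' @param config A `detection_config`.
#' @return List of `finding` objects with a `warnings` attribute (character
#'   vector, e.g. rows whose PZN could not be resolved).
#' @export
detect <- function(schedule, drugref, kb, lexicon = NULL,
                   config = detection_config()) {
  stopifnot(inherits(schedule, "medication_schedule"),
            inherits(drugref, "drug_reference"),
            inherits(kb, "knowledge_base"))
  if (!length(schedule$rows)) stop("schedule has no rows", call. = FALSE)
  if (is.null(lexicon)) lexicon <- load_lexicon(language = config$lexicon_language)

  warnings <- character()
  findings <- list()
  for (i in seq_along(schedule$rows)) {
    row <- schedule$rows[[i]]
    record <- drug_lookup(drugref, row$pzn)
    if (is.null(record) && config$missing_pzn == "warn") {
      warnings <- c(warnings, sprintf(
        "row %d (%s): no PZN match in drug reference; PZN rules skipped",
        i, ifelse(is.na(row$brand_name), "?", row$brand_name)))
    }
    findings <- c(findings,
                  apply_pzn_rules(row, i, record, lexicon),
                  apply_scheme_rules(row, i, schedule, record),
                  apply_keyword_rules(row, i, lexicon))
  }
  findings <- c(findings, apply_schedule_rules(schedule, drugref, config))

  known <- vapply(findings, function(fd) fd$factor_id %in% names(kb$factors), TRUE)
  if (!all(known)) {
    stop("detection produced findings for factors missing from the KB: ",
         paste(unique(vapply(findings[!known], `[[`, "", "factor_id")),
               collapse = ", "), call. = FALSE)
  }
  first_row <- vapply(findings, function(fd) {
    if (length(fd$row_indices)) min(fd$row_indices) else Inf
  }, 0)
  ids <- vapply(findings, `[[`, "", "factor_id")
  findings <- findings[order(first_row, ids)]
  attr(findings, "warnings") <- warnings
  findings
}

#' Summarize findings as a data frame
#'
#' @param findings Result of [detect()].
#' @return A data frame with one line per finding: factor id, triggering
#'   rows, evidence type and a short evidence string.
#' @export
findings_table <- function(findings) {
  if (!length(findings)) {
    return(data.frame(factor_id = character(), rows = character(),
                      evidence_type = character(), evidence = character(),
                      stringsAsFactors = FALSE))
  }
  data.frame(
    factor_id = vapply(findings, `[[`, "", "factor_id"),
    rows = vapply(findings, function(fd) paste(fd$row_indices, collapse = ","), ""),
    evidence_type = vapply(findings, function(fd) fd$evidence$type, ""),
    evidence = vapply(findings, function(fd) {
      ev <- fd$evidence
      switch(ev$type,
             matched_keyword = sprintf("'%s' in %s", ev$phrase, ev$field),
             slot_pattern = if (!is.null(ev$slots)) {
               paste(ev$slots, collapse = "-")
             } else ev$scheme_text,
             pzn_attribute = sprintf("%s=%s", ev$attribute, ev$value),
             pzn_and_keyword = sprintf("%s + '%s'", ev$attribute, ev$phrase),
             line_count = sprintf("%d lines (threshold %d)", ev$line_count,
                                  ev$threshold),
             ingredient_pair = paste(vapply(ev$pairs, function(p) {
               sprintf("%s (rows %s)", p$ingredient,
                       paste(p$rows, collapse = "&"))
             }, ""), collapse = "; "),
             "")
    }, ""),
    stringsAsFactors = FALSE)
}
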