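# shared fixtures: packaged inputs are loaded once per test run
kb_fix <- load_knowledge_base()
drugref_fix <- read_drug_reference()
lexicon_fix <- load_lexicon(language = "en")

automated_factors <- names(kb_fix$factors)[
  vapply(kb_fix$factors, function(f) isTRUE(f$automated), TRUE)]

# row builder backed by the fixture reference
fix_row <- function(pzn, scheme = "1-0-1-0", instructions = "", prn = FALSE,
                    unit = "unit") {
  rec <- drug_lookup(drugref_fix, pzn)
  medication_row(pzn = rec$pzn, brand_name = rec$brand_name,
                 active_ingredient = paste(rec$active_ingredients, collapse = "+"),
                 dosage_form = rec$form_class,
                 strength = paste0(paste(rec$strengths_mg, collapse = "+"), " mg"),
                 scheme_text = scheme, unit = unit,
                 instructions = instructions, prn = prn)
}

fix_schedule <- function(...) medication_schedule(list(...))

# write an ad-hoc drug reference CSV and load it
make_drugref <- function(rows) {
  header <- c("pzn", "brand_name", "active_ingredients", "form_class",
              "device_subtype", "prescription_only", "strengths_mg",
              "divisible", "orodispersible", "extended_release",
              "palatability_issue", "requires_technique_training",
              "self_measurement_linked", "equivalence_group")
  tmp <- tempfile(fileext = ".csv")
  lines <- c(paste(header, collapse = ","),
             vapply(rows, paste, "", collapse = ","))
  writeLines(lines, tmp)
  read_drug_reference(tmp)
}

# --- independent brute-force re-implementation of the dosage-scheme rules ---
# Deliberately written from the rule definitions, not from the engine code:
# given the slot quadruple of the row under test, the slots of the other
# rows, and whether the product is a divisible solid oral tablet, list the
# factor ids that must fire.
oracle_scheme_rules <- function(slots, other_slots_list, solid_oral = TRUE) {
  fired <- character()
  frac <- slots - floor(slots)
  if (solid_oral && any(slots > 0 & frac != 0)) {
    fired <- c(fired, "tablet_splitting")
  }
  if (length(which(slots != 0)) > 2) fired <- c(fired, "more_than_twice_daily")
  if (slots[2] != 0) fired <- c(fired, "lunch_time_administration")
  if (max(slots) >= 2) fired <- c(fired, "multiple_doses_concurrently")
  nz <- slots[slots != 0]
  if (length(unique(nz)) >= 2) fired <- c(fired, "different_doses_same_drug")
  if (length(other_slots_list) >= 1) {  # schedule has >= 2 rows
    for (s in 1:4) {
      if (slots[s] > 0 &&
          all(vapply(other_slots_list, function(o) o[s] == 0, TRUE))) {
        fired <- c(fired, "only_drug_at_time_point")
        break
      }
    }
  }
  sort(fired)
}

# --- test-only helper: apply a suggestion to a schedule copy -----------------
# The tool itself never mutates the schedule; this helper emulates a
# prescriber accepting a suggestion so the reduction property can be checked.
apply_suggestion <- function(schedule, sugg, drugref, mode) {
  rows <- schedule$rows
  mk <- function(rec, scheme, instructions = "") {
    medication_row(pzn = rec$pzn, brand_name = rec$brand_name,
                   active_ingredient = paste(rec$active_ingredients, collapse = "+"),
                   dosage_form = rec$form_class,
                   strength = paste0(paste(rec$strengths_mg, collapse = "+"), " mg"),
                   scheme_text = scheme, unit = "unit",
                   instructions = instructions)
  }
  rec <- drug_lookup(drugref, sugg$pzn)
  if (mode == "combination") {
    pair <- sugg$rows
    scheme <- rows[[pair[1]]]$scheme_text
    rows[[pair[1]]] <- mk(rec, scheme)
    rows <- rows[-pair[2]]
  } else {
    r <- sugg$rows[1]
    old <- rows[[r]]
    old_rec <- drug_lookup(drugref, old$pzn)
    scheme <- switch(mode,
      strength = {  # rescale slots so the new strength gives the same dose
        ratio <- old_rec$strength_mg / rec$strength_mg
        paste(old$scheme$slots * ratio, collapse = "-")
      },
      form = old$scheme_text,
      frequency = "1-0-0-0",      # extended release: once daily
      device = old$scheme_text)
    instructions <- if (mode == "form") "" else old$instructions
    rows[[r]] <- mk(rec, scheme, instructions)
  }
  medication_schedule(rows, patient_ref = schedule$patient_ref,
                      issued_on = schedule$issued_on)
}

# answer that DOES confirm a problem for a given question instance
problem_answer <- function(inst) {
  lapply(inst$parts, function(p) {
    switch(p$predicate$name,
           yes_is_problem = "yes",
           no_is_problem = "no",
           numeric_below = p$predicate$threshold - 1,
           numeric_above = p$predicate$threshold + 1,
           info = "no")
  })
}

find_instance <- function(question_set, instance_id) {
  for (inst in question_set) if (inst$instance_id == instance_id) return(inst)
  stop("no such instance: ", instance_id)
}

count_factor <- function(findings, factor_id) {
  sum(vapply(findings, function(f) f$factor_id == factor_id, TRUE))
}
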