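#' @title Optimisation measures and the five substitution algorithms
#' @description Maps confirmed complexity factors to their optimisation
#'   measures -- recommendations for action (aid / explain / review),
#'   training-material stubs, and algorithmic drug substitution. Five
#'   algorithms suggest alternative products from the drug reference's
#'   curated equivalence groups: strength substitution (whole units instead
#'   of split or stacked tablets), easier dosage forms, extended-release
#'   frequency reduction, fixed-dose combinations, and prefilled injection
#'   devices. Suggestions are advisory; the schedule is never mutated.
#' @name recommender
NULL

measure_type_order <- c(algorithm = 1L, recommendation_for_action = 2L,
                        training_material = 3L)

suggestion <- function(record, rationale, rows = integer(0)) {
  list(pzn = record$pzn, brand_name = record$brand_name,
       strengths_mg = record$strengths_mg, form_class = record$form_class,
       device_subtype = record$device_subtype, rows = as.integer(rows),
       rationale = rationale)
}

#' Suggest alternative strengths (algorithm A1)
#'
#' For split tablets: products in the same equivalence group whose strength
#' equals the administered part-dose (slot dose times current strength), so
#' a whole unit replaces the fragment. For stacked doses (a slot dose of two
#' or more): products whose strength equals the stacked amount, so one unit
#' replaces several.
#'
#' @param row A `medication_row` with a structured scheme.
#' @param record The row's `drug_record`.
#' @param drugref A `drug_reference`.
#' @return List of suggestions (possibly empty).
#' @export
alg_alternative_strength <- function(row, record, drugref) {
  if (is.null(record) || is.na(record$strength_mg) || !row$scheme$structured) {
    return(list())
  }
  slots <- row$scheme$slots
  doses <- unique(slots[slots > 0 & (slots %% 1 != 0 | slots >= 2)])
  out <- list()
  for (d in sort(doses)) {
    target <- d * record$strength_mg
    alts <- find_alternatives(drugref, record$equivalence_group,
                              exclude_pzn = record$pzn, strength_mg = target,
                              form_class = record$form_class)
    for (alt in alts) {
      out[[length(out) + 1]] <- suggestion(alt, sprintf(
        "one %g mg unit replaces a slot dose of %g x %g mg",
        target, d, record$strength_mg))
    }
  }
  out
}

#' Suggest an easier dosage form (algorithm A2)
#'
#' Same equivalence group, equivalent strength, but a form that avoids
#' swallowing or crushing whole tablets: liquid oral products or
#' orodispersible solids.
#'
#' @inheritParams alg_alternative_strength
#' @export
alg_alternative_form <- function(row, record, drugref) {
  if (is.null(record) || identical(record$form_class, "liquid_oral")) {
    return(list())
  }
  group <- record$equivalence_group
  liquids <- find_alternatives(drugref, group, exclude_pzn = record$pzn,
                               form_class = "liquid_oral",
                               strength_mg = record$strength_mg)
  orodisp <- find_alternatives(drugref, group, exclude_pzn = record$pzn,
                               form_class = "solid_oral", orodispersible = TRUE,
                               strength_mg = record$strength_mg)
  c(lapply(liquids, suggestion,
           rationale = "liquid form avoids swallowing/crushing the tablet"),
    lapply(orodisp, suggestion,
           rationale = "orodispersible form avoids swallowing/crushing the tablet"))
}

#' Suggest less frequent dosing (algorithm A3)
#'
#' Extended-release siblings whose single-unit strength equals the row's
#' total daily dose, allowing a once-daily scheme instead of several
#' administrations.
#'
#' @inheritParams alg_alternative_strength
#' @export
alg_frequency_reduction <- function(row, record, drugref) {
  if (is.null(record) || is.na(record$strength_mg) || !row$scheme$structured) {
    return(list())
  }
  slots <- row$scheme$slots
  if (sum(slots > 0) <= 1) return(list())  # already at one administration
  daily <- sum(slots) * record$strength_mg
  alts <- find_alternatives(drugref, record$equivalence_group,
                            exclude_pzn = record$pzn, strength_mg = daily,
                            extended_release = TRUE)
  lapply(alts, suggestion, rationale = sprintf(
    "extended-release %g mg once daily replaces %d administrations",
    daily, sum(slots > 0)))
}

#' Suggest fixed-dose combinations (algorithm A4)
#'
#' Pairs of schedule rows whose single-ingredient products co-occur in a
#' fixed-dose combination record at matching strengths (and identical dosing
#' schemes) are replaced by the combination, reducing the line count by one
#' per pair.
#'
#' @param schedule A `medication_schedule`.
#' @param drugref A `drug_reference`.
#' @return List of suggestions; each carries `rows`, the pair it replaces.
#' @export
alg_combination_product <- function(schedule, drugref) {
  n <- length(schedule$rows)
  if (n < 2) return(list())
  recs <- lapply(schedule$rows, function(r) drug_lookup(drugref, r$pzn))
  is_fdc <- vapply(drugref$active_ingredients, function(x) length(x) >= 2, TRUE)
  fdcs <- lapply(which(is_fdc), function(i) as_drug_record(drugref[i, , drop = FALSE]))
  out <- list()
  for (i in seq_len(n - 1)) {
    for (j in seq((i + 1), n)) {
      ri <- recs[[i]]; rj <- recs[[j]]
      if (is.null(ri) || is.null(rj)) next
      if (length(ri$active_ingredients) != 1 || length(rj$active_ingredients) != 1) next
      si <- schedule$rows[[i]]$scheme; sj <- schedule$rows[[j]]$scheme
      if (!si$structured || !sj$structured || !identical(si$slots, sj$slots)) next
      want_ing <- tolower(c(ri$active_ingredients, rj$active_ingredients))
      want_str <- c(ri$strength_mg, rj$strength_mg)
      for (fdc in fdcs) {
        fing <- tolower(fdc$active_ingredients)
        if (length(fing) != 2 || !setequal(fing, want_ing)) next
        ord <- match(fing, want_ing)
        if (anyNA(ord)) next
        if (!isTRUE(all(abs(fdc$strengths_mg - want_str[ord]) < 1e-9))) next
        out[[length(out) + 1]] <- suggestion(fdc, sprintf(
          "fixed-dose combination replaces rows %d and %d", i, j),
          rows = c(i, j))
      }
    }
  }
  out
}

#' Suggest a prefilled injection device (algorithm A5)
#'
#' Equivalence-group members delivered as prefilled injectors with the same
#' ingredient and strength as the row's non-prefilled device.
#'
#' @inheritParams alg_alternative_strength
#' @export
alg_prefilled_device <- function(row, record, drugref) {
  if (is.null(record) || identical(record$device_subtype, "prefilled_injector")) {
    return(list())
  }
  alts <- find_alternatives(drugref, record$equivalence_group,
                            exclude_pzn = record$pzn,
                            device_subtype = "prefilled_injector",
                            strength_mg = record$strength_mg)
  same_ing <- Filter(function(a) {
    setequal(tolower(a$active_ingredients), tolower(record$active_ingredients))
  }, alts)
  lapply(same_ing, suggestion,
         rationale = "prefilled device with identical ingredient and strength")
}

algorithm_registry <- list(
  alternative_strength = function(schedule, rows, record_for, drugref) {
    do.call(c, lapply(rows, function(r) {
      lapply(alg_alternative_strength(schedule$rows[[r]], record_for(r), drugref),
             function(s) { s$rows <- r; s })
    }))
  },
  alternative_form = function(schedule, rows, record_for, drugref) {
    do.call(c, lapply(rows, function(r) {
      lapply(alg_alternative_form(schedule$rows[[r]], record_for(r), drugref),
             function(s) { s$rows <- r; s })
    }))
  },
  frequency_reduction = function(schedule, rows, record_for, drugref) {
    do.call(c, lapply(rows, function(r) {
      lapply(alg_frequency_reduction(schedule$rows[[r]], record_for(r), drugref),
             function(s) { s$rows <- r; s })
    }))
  },
  combination_product = function(schedule, rows, record_for, drugref) {
    alg_combination_product(schedule, drugref)
  },
  prefilled_device = function(schedule, rows, record_for, drugref) {
    do.call(c, lapply(rows, function(r) {
      lapply(alg_prefilled_device(schedule$rows[[r]], record_for(r), drugref),
             function(s) { s$rows <- r; s })
    }))
  }
)

#' Plan optimisation measures for confirmed factors
#'
#' Instantiates every measure of every confirmed factor. Algorithm measures
#' are executed immediately against the drug reference; when an algorithm
#' returns nothing, the entry degrades to a "no alternative found" note and
#' the factor's other measures still apply. Entries are ordered by factor
#' (catalogue order), then measure type: algorithm, recommendation, training.
#'
#' @param confirmed A `confirmed_factor_set` from [resolve_answers()].
#' @param schedule The analysed `medication_schedule`.
#' @param drugref A `drug_reference`.
#' @param kb The `knowledge_base`.
#' @return A list of class `measure_plan` with `entries`; each entry has
#'   `factor_id`, `row_indices`, `measure_id`, `measure_type`, and `payload`.
#' @export
plan_measures <- function(confirmed, schedule, drugref, kb) {
  stopifnot(inherits(confirmed, "confirmed_factor_set"),
            inherits(kb, "knowledge_base"))
  record_for <- function(r) drug_lookup(drugref, schedule$rows[[r]]$pzn)
  entries <- list()
  order_conf <- confirmed$confirmed[
    order(match(vapply(confirmed$confirmed, `[[`, "", "factor_id"),
                kb$factor_order))]
  for (cf in order_conf) {
    mids <- unlist(kb$factors[[cf$factor_id]]$measure_ids)
    ms <- kb$measures[mids]
    types <- vapply(ms, `[[`, "", "type")
    ms <- ms[order(measure_type_order[types], mids)]
    for (m in ms) {
      payload <- switch(m$type,
        algorithm = {
          fn <- algorithm_registry[[m$algorithm_ref]]
          rows <- if (length(cf$row_indices)) cf$row_indices else seq_along(schedule$rows)
          sugg <- fn(schedule, rows, record_for, drugref)
          if (is.null(sugg)) sugg <- list()
          list(algorithm = m$algorithm_ref, suggestions = sugg,
               note = if (!length(sugg)) "no alternative found" else NULL)
        },
        recommendation_for_action = list(topic = m$topic, instruction = m$title),
        training_material = list(resource_ref = m$resource_ref, title = m$title))
      entries[[length(entries) + 1]] <- list(
        factor_id = cf$factor_id,
        row_indices = cf$row_indices,
        measure_id = m$measure_id,
        measure_type = m$type,
        payload = payload)
    }
  }
  structure(list(entries = entries), class = "measure_plan")
}

#' @export
print.measure_plan <- function(x, ...) {
  cat("<measure_plan> ", length(x$entries), " entr",
      if (length(x$entries) == 1) "y" else "ies", "\n", sep = "")
  for (e in x$entries) {
    extra <- if (e$measure_type == "algorithm") {
      n <- length(e$payload$suggestions)
      if (n) {
        sprintf(" -> %d suggestion(s): %s", n,
                paste(vapply(e$payload$suggestions, `[[`, "", "brand_name"),
                      collapse = ", "))
      } else " -> no alternative found"
    } else ""
    cat(sprintf("  %s: %s [%s]%s\n", e$factor_id, e$measure_id,
                e$measure_type, extra))
  }
  invisible(x)
}
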