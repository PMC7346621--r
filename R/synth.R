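#' @title Synthetic schedule generator with known ground truth
#' @description Builds fictional medication schedules in which requested
#'   complexity factors are planted by construction, together with the exact
#'   list of planted findings. Row templates are designed so that rules do
#'   not fire by accident: background rows are clean solid-oral products
#'   dosed morning+evening, the night slot is reserved for the
#'   "only drug at one time point" recipe, and noise text is drawn from a
#'   phrase pool free of lexicon keywords. Recipes that necessarily co-fire
#'   another rule (e.g. three administrations per day always include the
#'   noon slot) record those side effects in the ground truth, so detection
#'   output and ground truth agree exactly, not statistically.
#' @name synth
NULL

# clean generic solid-oral products reserved for background rows and
# single-product recipes (unique ingredients, no attribute flags)
synth_generic_pool <- c("04773414", paste0("200000", sprintf("%02d", 2:30)))

synth_noise_pool <- c(
  "store at room temperature",
  "protect from light",
  "keep out of reach of children",
  "prescribed by the specialist",
  "continue until further notice",
  "see accompanying card"
)

#' Specification for a synthetic schedule
#'
#' @param seed Integer seed; fully determines the generated schedule.
#' @param inject Character vector of factor ids to plant (must be automated
#'   factors).
#' @param n_rows Minimum number of rows; padded with clean background rows.
#' @param background_noise Probability of an irrelevant free-text phrase per
#'   row (the pool contains no lexicon keywords, so noise never creates
#'   findings).
#' @return A list of class `synth_spec`.
#' @export
synth_spec <- function(seed, inject = character(), n_rows = NULL,
                       background_noise = 0.2) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  structure(list(seed = as.integer(seed), inject = unique(inject),
                 n_rows = n_rows, background_noise = background_noise),
            class = "synth_spec")
}

# one recipe per automated factor: returns rows (list of medication_row) and
# planted (list of list(factor_id, rows)) with rows relative to the recipe
synth_recipes <- function(drugref, rng_pick, take_generic) {
  std_row <- function(pzn, scheme = "1-0-1-0", instructions = "", prn = FALSE) {
    rec <- drug_lookup(drugref, pzn)
    medication_row(pzn = rec$pzn, brand_name = rec$brand_name,
                   active_ingredient = paste(rec$active_ingredients, collapse = "+"),
                   dosage_form = rec$form_class,
                   strength = paste0(paste(rec$strengths_mg, collapse = "+"), " mg"),
                   scheme_text = scheme, unit = "unit",
                   instructions = instructions, prn = prn)
  }
  gen_row <- function(scheme = "1-0-1-0", instructions = "", prn = FALSE) {
    std_row(take_generic(), scheme, instructions, prn)
  }
  form_recipe <- function(pzns, factor_id) {
    function() {
      pzn <- if (length(pzns) == 1) pzns else rng_pick(pzns)
      list(rows = list(std_row(pzn)), planted = list(list(factor_id, 1L)))
    }
  }
  keyword_recipe <- function(factor_id, lexicon, scheme = "1-0-1-0") {
    function() {
      phrase <- rng_pick(lexicon$entries[[factor_id]]$phrases)
      list(rows = list(gen_row(scheme = scheme, instructions = phrase)),
           planted = list(list(factor_id, 1L)))
    }
  }
  lex <- load_lexicon(language = "en")

  list(
    inhalers = form_recipe(paste0("1000000", 1:5), "inhalers"),
    injection_non_prefilled = form_recipe("10000011", "injection_non_prefilled"),
    injection_prefilled = form_recipe("10000013", "injection_prefilled"),
    transdermal_patches = form_recipe("10000021", "transdermal_patches"),
    nasal_preparations_rx = form_recipe("10000022", "nasal_preparations_rx"),
    oropharyngeal_solid = form_recipe("10000024", "oropharyngeal_solid"),
    oropharyngeal_liquid = form_recipe("10000025", "oropharyngeal_liquid"),
    ophthalmic_preparations = form_recipe(c("10000026", "10000027"),
                                          "ophthalmic_preparations"),
    rectal_preparations = form_recipe("10000028", "rectal_preparations"),
    dermatological_preparations_rx = form_recipe("10000029",
                                                 "dermatological_preparations_rx"),
    liquid_oral_forms = form_recipe(c("10000031", "10000032", "10000033"),
                                    "liquid_oral_forms"),
    otological_preparations = form_recipe("10000035", "otological_preparations"),
    vaginal_preparations = form_recipe("10000036", "vaginal_preparations"),

    unfriendly_liquid_oral = function() {
      list(rows = list(std_row("10000034")),
           planted = list(list("liquid_oral_forms", 1L),
                          list("unfriendly_liquid_oral", 1L)))
    },
    lack_of_training = function() {
      list(rows = list(std_row("10000037")),
           planted = list(list("lack_of_training", 1L)))
    },
    complex_measurements = function() {
      phrase <- rng_pick(lex$entries$complex_measurements$phrases)
      list(rows = list(std_row("10000038", instructions = phrase)),
           planted = list(list("complex_measurements", 1L)))
    },
    same_ingredient_different_preparations = function() {
      list(rows = list(std_row("30000013"), std_row("30000014")),
           planted = list(list("same_ingredient_different_preparations",
                               c(1L, 2L))))
    },

    tablet_splitting = function() {
      list(rows = list(std_row("30000002", scheme = "0.5-0-0.5-0")),
           planted = list(list("tablet_splitting", 1L)))
    },
    more_than_twice_daily = function() {
      # three administrations need the noon slot, which co-fires the
      # lunch-time rule; two rows keep the noon slot non-unique
      list(rows = list(gen_row(scheme = "1-1-1-0"), gen_row(scheme = "1-1-1-0")),
           planted = list(list("more_than_twice_daily", 1L),
                          list("lunch_time_administration", 1L),
                          list("more_than_twice_daily", 2L),
                          list("lunch_time_administration", 2L)))
    },
    lunch_time_administration = function() {
      list(rows = list(gen_row(scheme = "0-1-1-0"), gen_row(scheme = "0-1-1-0")),
           planted = list(list("lunch_time_administration", 1L),
                          list("lunch_time_administration", 2L)))
    },
    multiple_doses_concurrently = function() {
      list(rows = list(std_row("30000003", scheme = "2-0-2-0")),
           planted = list(list("multiple_doses_concurrently", 1L)))
    },
    different_doses_same_drug = function() {
      # non-solid, non-form-factor product so the fractional morning dose
      # does not co-fire tablet splitting
      list(rows = list(std_row("10000039", scheme = "0.5-0-1-0")),
           planted = list(list("different_doses_same_drug", 1L)))
    },
    variable_dosing = function() {
      list(rows = list(gen_row(scheme = "according to plan")),
           planted = list(list("variable_dosing", 1L)))
    },
    only_drug_at_time_point = function() {
      # night slot is reserved schedule-wide for this recipe
      list(rows = list(gen_row(scheme = "0-0-0-1")),
           planted = list(list("only_drug_at_time_point", 1L)))
    },
    total_number_of_drugs = function() {
      list(rows = list(), planted = list(), pad_to_threshold = TRUE)
    },
    prn_medication = function() {
      list(rows = list(gen_row(scheme = "", prn = TRUE)),
           planted = list(list("prn_medication", 1L)))
    },

    once_weekly = keyword_recipe("once_weekly", lex, scheme = ""),
    every_two_days_or_less = keyword_recipe("every_two_days_or_less", lex,
                                            scheme = ""),
    fixed_dosing_interval = keyword_recipe("fixed_dosing_interval", lex,
                                           scheme = ""),
    occasional_episodic = keyword_recipe("occasional_episodic", lex),
    meal_dependent = keyword_recipe("meal_dependent", lex),
    crushing_tablets = keyword_recipe("crushing_tablets", lex),
    disintegrating_forms = keyword_recipe("disintegrating_forms", lex),
    fixed_times_of_day = keyword_recipe("fixed_times_of_day", lex),
    advised_liquid_intake = keyword_recipe("advised_liquid_intake", lex),
    opening_capsules = keyword_recipe("opening_capsules", lex),
    increasing_doses = keyword_recipe("increasing_doses", lex),
    decreasing_doses = keyword_recipe("decreasing_doses", lex)
  )
}

#' Generate a synthetic schedule with ground truth
#'
#' @param spec A [synth_spec()].
#' @param drugref A `drug_reference` containing the packaged fixture
#'   products.
#' @param kb A `knowledge_base` (used to reject non-automated injections).
#' @param config A `detection_config` (supplies the polypharmacy threshold).
#' @return List with `schedule` (a `medication_schedule`), `ground_truth`
#'   (list of `list(factor_id, rows)` naming every planted condition), and
#'   `conflicts` (character; conditions that could not be avoided, e.g. the
#'   polypharmacy factor firing because `n_rows` reached the threshold).
#' @export
generate_schedule <- function(spec, drugref = read_drug_reference(),
                              kb = load_knowledge_base(),
                              config = detection_config()) {
  stopifnot(inherits(spec, "synth_spec"))
  automated <- names(kb$factors)[vapply(kb$factors, function(f) isTRUE(f$automated), TRUE)]
  bad <- setdiff(spec$inject, automated)
  if (length(bad)) {
    stop("cannot inject non-automated factor(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }

  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(spec$seed)

  pool <- synth_generic_pool
  take_generic <- function() {
    if (!length(pool)) stop("generic product pool exhausted", call. = FALSE)
    p <- pool[1]
    pool <<- pool[-1]
    p
  }
  rng_pick <- function(x) if (length(x) == 1) x else x[sample.int(length(x), 1)]
  recipes <- synth_recipes(drugref, rng_pick, take_generic)

  rows <- list()
  ground_truth <- list()
  conflicts <- character()
  pad_to_threshold <- FALSE

  inject <- intersect(names(recipes), spec$inject)  # stable catalogue order
  for (fid in inject) {
    res <- recipes[[fid]]()
    offset <- length(rows)
    rows <- c(rows, res$rows)
    for (p in res$planted) {
      ground_truth[[length(ground_truth) + 1]] <-
        list(factor_id = p[[1]], rows = p[[2]] + offset)
    }
    if (isTRUE(res$pad_to_threshold)) pad_to_threshold <- TRUE
  }

  # background rows: at least two, more if n_rows or the polypharmacy
  # recipe demands it
  target <- max(length(rows) + 2,
                spec$n_rows %||% 0,
                if (pad_to_threshold) config$polypharmacy_threshold else 0)
  while (length(rows) < target) {
    rec <- drug_lookup(drugref, take_generic())
    rows[[length(rows) + 1]] <- medication_row(
      pzn = rec$pzn, brand_name = rec$brand_name,
      active_ingredient = rec$active_ingredients[1],
      dosage_form = "tablet", strength = paste0(rec$strength_mg, " mg"),
      scheme_text = "1-0-1-0", unit = "tablet")
  }

  # per-row irrelevant free text (keyword-free pool)
  for (i in seq_along(rows)) {
    if (stats::runif(1) < spec$background_noise) {
      noise <- rng_pick(synth_noise_pool)
      rows[[i]]$instructions <- if (nzchar(rows[[i]]$instructions)) {
        paste0(rows[[i]]$instructions, "; ", noise)
      } else noise
    }
  }

  if (length(rows) >= config$polypharmacy_threshold) {
    if (!("total_number_of_drugs" %in% inject)) {
      conflicts <- c(conflicts, sprintf(
        "schedule has %d rows, at/above the polypharmacy threshold %d; the total-number-of-drugs factor fires although it was not injected",
        length(rows), config$polypharmacy_threshold))
    }
    ground_truth[[length(ground_truth) + 1]] <-
      list(factor_id = "total_number_of_drugs", rows = integer(0))
  }

  schedule <- medication_schedule(rows,
                                  patient_ref = sprintf("synth-%d", spec$seed))
  list(schedule = schedule, ground_truth = ground_truth, conflicts = conflicts)
}

#' Canonical string form of findings or ground truth
#'
#' Both [detect()] output and [generate_schedule()] ground truth reduce to
#' `"factor@rows"` strings, enabling exact set comparison.
#'
#' @param x List of findings or ground-truth entries.
#' @return Sorted character vector.
#' @export
finding_keys <- function(x) {
  sort(vapply(x, function(e) {
    rows <- if (!is.null(e$row_indices)) e$row_indices else e$rows
    paste0(e$factor_id, "@", paste(sort(as.integer(rows)), collapse = ","))
  }, ""))
}

#' Generate a regression suite of synthetic schedules
#'
#' Emulates iterative testing on a corpus of fictional plans: by default 50
#' schedules, each planting one factor in catalogue rotation plus one
#' further randomly chosen automated factor, so the suite collectively
#' covers all 38 automated factors.
#'
#' @param n_schedules Number of schedules (default 50).
#' @param seed Master seed; per-schedule seeds are derived from it.
#' @param drugref,kb,config Passed through to [generate_schedule()].
#' @param background_noise Per-row noise probability.
#' @return List of `generate_schedule()` results.
#' @export
generate_suite <- function(n_schedules = 50, seed = 1,
                           drugref = read_drug_reference(),
                           kb = load_knowledge_base(),
                           config = detection_config(),
                           background_noise = 0.2) {
  if (n_schedules <= 0) return(list())
  automated <- names(kb$factors)[vapply(kb$factors, function(f) isTRUE(f$automated), TRUE)]
  out <- vector("list", n_schedules)
  for (k in seq_len(n_schedules)) {
    seed_k <- (as.integer(seed) %% 100000L) * 20011L + k
    set.seed(seed_k)
    primary <- automated[(k - 1L) %% length(automated) + 1L]
    extra <- sample(setdiff(automated, primary), 1)
    out[[k]] <- generate_schedule(
      synth_spec(seed = seed_k, inject = c(primary, extra),
                 background_noise = background_noise),
      drugref = drugref, kb = kb, config = config)
  }
  out
}
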