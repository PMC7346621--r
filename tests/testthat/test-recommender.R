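test_that("strength substitution suggests whole-unit replacements", {
  # half of a 10 mg divisible tablet -> the 5 mg sibling
  row <- fix_row("30000002", "0.5-0-0.5-0")
  s <- alg_alternative_strength(row, drug_lookup(drugref_fix, "30000002"),
                                drugref_fix)
  expect_length(s, 1)
  expect_identical(s[[1]]$pzn, "30000001")
  # two 300 mg units per slot -> the 600 mg sibling
  row <- fix_row("30000003", "2-0-2-0")
  s <- alg_alternative_strength(row, drug_lookup(drugref_fix, "30000003"),
                                drugref_fix)
  expect_identical(s[[1]]$pzn, "30000004")
  # no matching strength -> nothing
  row <- fix_row("30000008", "0.5-0-0-0")  # 25 mg not in metoprolol family
  expect_length(alg_alternative_strength(row, drug_lookup(drugref_fix, "30000008"),
                                         drugref_fix), 0)
})

test_that("form substitution proposes liquids and orodispersibles, once", {
  row <- fix_row("30000005", "1-0-1-0")
  s <- alg_alternative_form(row, drug_lookup(drugref_fix, "30000005"), drugref_fix)
  expect_setequal(vapply(s, `[[`, "", "pzn"), c("30000006", "30000007"))
  # already liquid -> nothing
  row <- fix_row("30000006", "1-0-1-0")
  expect_length(alg_alternative_form(row, drug_lookup(drugref_fix, "30000006"),
                                     drugref_fix), 0)
  # group without easier forms -> nothing
  row <- fix_row("30000001", "1-0-1-0")
  expect_length(alg_alternative_form(row, drug_lookup(drugref_fix, "30000001"),
                                     drugref_fix), 0)
})

test_that("frequency reduction finds extended-release dose equivalents", {
  row <- fix_row("30000008", "1-1-1-0")  # 3 x 50 mg
  s <- alg_frequency_reduction(row, drug_lookup(drugref_fix, "30000008"),
                               drugref_fix)
  expect_length(s, 1)
  expect_identical(s[[1]]$pzn, "30000009")  # 150 mg extended release
  # once daily already -> nothing
  row <- fix_row("30000008", "1-0-0-0")
  expect_length(alg_frequency_reduction(row, drug_lookup(drugref_fix, "30000008"),
                                        drugref_fix), 0)
  # no ER sibling -> nothing
  row <- fix_row("30000001", "1-1-1-0")
  expect_length(alg_frequency_reduction(row, drug_lookup(drugref_fix, "30000001"),
                                        drugref_fix), 0)
})

test_that("combination substitution pairs rows into fixed-dose combinations", {
  sch <- fix_schedule(fix_row("30000010", "1-0-0-0"),
                      fix_row("30000011", "1-0-0-0"))
  s <- alg_combination_product(sch, drugref_fix)
  expect_length(s, 1)
  expect_identical(s[[1]]$pzn, "30000012")
  expect_equal(s[[1]]$rows, c(1L, 2L))
  # strength mismatch -> nothing (10 mg amlodipine has no FDC partner here)
  sch <- fix_schedule(fix_row("30000002", "1-0-0-0"),
                      fix_row("30000011", "1-0-0-0"))
  expect_length(alg_combination_product(sch, drugref_fix), 0)
  # differing schemes are never merged
  sch <- fix_schedule(fix_row("30000010", "1-0-0-0"),
                      fix_row("30000011", "0-0-1-0"))
  expect_length(alg_combination_product(sch, drugref_fix), 0)
  expect_length(alg_combination_product(
    fix_schedule(fix_row("30000010", "1-0-0-0")), drugref_fix), 0)
})

test_that("prefilled-device substitution needs identical ingredient and strength", {
  row <- fix_row("10000011", "0-0-1-0")
  s <- alg_prefilled_device(row, drug_lookup(drugref_fix, "10000011"), drugref_fix)
  expect_length(s, 1)
  expect_identical(s[[1]]$pzn, "10000012")
  # already prefilled -> nothing
  row <- fix_row("10000012", "0-0-1-0")
  expect_length(alg_prefilled_device(row, drug_lookup(drugref_fix, "10000012"),
                                     drugref_fix), 0)
  # no prefilled sibling -> nothing
  row <- fix_row("30000001", "1-0-0-0")
  expect_length(alg_prefilled_device(row, drug_lookup(drugref_fix, "30000001"),
                                     drugref_fix), 0)
})

test_that("suggestions are always drawn from the product's equivalence group", {
  scenarios <- list(
    list(alg_alternative_strength, "30000002", "0.5-0-0.5-0"),
    list(alg_alternative_form, "30000005", "1-0-1-0"),
    list(alg_frequency_reduction, "30000008", "1-1-1-0"),
    list(alg_prefilled_device, "10000011", "0-0-1-0"))
  for (sc in scenarios) {
    rec <- drug_lookup(drugref_fix, sc[[2]])
    group_pzns <- vapply(find_alternatives(drugref_fix, rec$equivalence_group,
                                           exclude_pzn = rec$pzn), `[[`, "", "pzn")
    s <- sc[[1]](fix_row(sc[[2]], sc[[3]]), rec, drugref_fix)
    expect_true(all(vapply(s, `[[`, "", "pzn") %in% group_pzns))
    expect_false(rec$pzn %in% vapply(s, `[[`, "", "pzn"))
  }
})

test_that("planning instantiates all measures with deterministic ordering", {
  sch <- fix_schedule(fix_row("30000002", "0.5-0-0.5-0"))
  f <- detect(sch, drugref_fix, kb_fix)
  qs <- build_question_set(f, kb_fix, sch)
  ans <- answer_template(qs)
  ans[["q_tablet_splitting@1"]] <- "yes"
  ans[["dq_swallowing"]] <- "yes"
  conf <- resolve_answers(qs, ans, kb_fix)
  plan <- plan_measures(conf, sch, drugref_fix, kb_fix)
  # factor order follows the catalogue; within a factor the algorithm
  # measure precedes recommendation and training entries
  expect_identical(vapply(plan$entries, `[[`, "", "factor_id"),
                   c("tablet_splitting", "tablet_splitting",
                     "swallowing_difficulties", "swallowing_difficulties",
                     "swallowing_difficulties"))
  expect_identical(vapply(plan$entries, `[[`, "", "measure_type"),
                   c("algorithm", "training_material",
                     "algorithm", "recommendation_for_action",
                     "training_material"))
  # the splitting algorithm found the half-strength product
  expect_identical(plan$entries[[1]]$payload$suggestions[[1]]$pzn, "30000001")
  # swallowing on a divisible-only group degrades to a note
  expect_identical(plan$entries[[3]]$payload$note, "no alternative found")
  expect_identical(plan, plan_measures(conf, sch, drugref_fix, kb_fix))
})

test_that("an empty confirmed set yields an empty plan", {
  conf <- resolve_answers(build_question_set(list(), kb_fix), list(), kb_fix)
  plan <- plan_measures(conf, fix_schedule(fix_row("20000002")), drugref_fix,
                        kb_fix)
  expect_length(plan$entries, 0)
})

test_that("accepting a suggestion removes the triggering finding (all 5 algorithms)", {
  confirm_and_plan <- function(sch, instance_id) {
    f <- detect(sch, drugref_fix, kb_fix)
    qs <- build_question_set(f, kb_fix, sch)
    ans <- answer_template(qs)
    ans[[instance_id]] <- problem_answer(find_instance(qs, instance_id))
    conf <- resolve_answers(qs, ans, kb_fix)
    plan_measures(conf, sch, drugref_fix, kb_fix)
  }
  reduction <- function(sch, factor_id, instance_id, mode) {
    before <- count_factor(detect(sch, drugref_fix, kb_fix), factor_id)
    plan <- confirm_and_plan(sch, instance_id)
    algo_entries <- Filter(function(e) {
      e$factor_id == factor_id && e$measure_type == "algorithm" &&
        length(e$payload$suggestions)
    }, plan$entries)
    expect_true(length(algo_entries) >= 1, info = factor_id)
    sugg <- algo_entries[[1]]$payload$suggestions[[1]]
    after_sch <- apply_suggestion(sch, sugg, drugref_fix, mode)
    after <- count_factor(detect(after_sch, drugref_fix, kb_fix), factor_id)
    expect_lt(after, before)
  }

  # A1 via tablet splitting
  reduction(fix_schedule(fix_row("30000002", "0.5-0-0.5-0")),
            "tablet_splitting", "q_tablet_splitting@1", "strength")
  # A1 via stacked doses
  reduction(fix_schedule(fix_row("30000003", "2-0-2-0")),
            "multiple_doses_concurrently", "q_multiple_concurrent@1", "strength")
  # A2 via crushing instructions
  reduction(fix_schedule(fix_row("30000005", "1-0-1-0",
                                 "crush before intake")),
            "crushing_tablets", "q_crushing@1", "form")
  # A3 via thrice-daily dosing (second row keeps noon non-unique)
  reduction(fix_schedule(fix_row("30000008", "1-1-1-0"),
                         fix_row("20000002", "1-1-1-0")),
            "more_than_twice_daily", "q_more_than_twice@1", "frequency")
  # A4 via the polypharmacy factor on a five-line plan
  reduction(medication_schedule(c(list(fix_row("30000010", "1-0-0-0"),
                                       fix_row("30000011", "1-0-0-0")),
                                  lapply(sprintf("200000%02d", 2:4), fix_row))),
            "total_number_of_drugs", "q_total_drugs", "combination")
  # A5 via the non-prefilled injection device
  reduction(fix_schedule(fix_row("10000011", "1-0-1-0")),
            "injection_non_prefilled", "q_injection_site@1", "device")
})
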