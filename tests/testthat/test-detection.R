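test_that("a clean single-row schedule yields no findings", {
  sch <- fix_schedule(fix_row("20000002", "1-0-0-0"))
  expect_length(detect(sch, drugref_fix, kb_fix), 0)
})

test_that("one factor of each mechanism fires on an engineered schedule", {
  sch <- fix_schedule(
    fix_row("10000021", "1-0-1-0"),                       # patch: product rule
    fix_row("30000002", "0.5-0-0.5-0"),                   # half tablets: scheme rule
    fix_row("20000002", "1-0-1-0", "take with breakfast"),# keyword rule
    fix_row("20000003", "1-0-1-0"),
    fix_row("20000004", "1-0-1-0"))                       # 5 lines: schedule rule
  f <- detect(sch, drugref_fix, kb_fix)
  expect_length(f, 4)
  expect_setequal(vapply(f, `[[`, "", "factor_id"),
                  c("transdermal_patches", "tablet_splitting",
                    "meal_dependent", "total_number_of_drugs"))
  # determinism: identical inputs give identical finding lists
  expect_identical(f, detect(sch, drugref_fix, kb_fix))
})

test_that("keyword matching is word-bounded, case-insensitive, span-reporting", {
  expect_length(match_keywords("", "food"), 0)
  hit <- match_keywords("take with food", "food")
  expect_length(hit, 1)
  expect_identical(substr("take with food", hit[[1]]$start, hit[[1]]$end), "food")
  expect_length(match_keywords("seafood platter", "food"), 0)
  expect_length(match_keywords("Breakfast only", "breakfast"), 1)
  expect_length(match_keywords("beat the eggs", "eat"), 0)
  expect_length(match_keywords("repeat daily", "eat"), 0)
  # multi-word phrases match across single spaces
  expect_length(match_keywords("drink a glass of water now", "glass of water"), 1)
})

test_that("the six printed meal keywords each trigger the meal factor", {
  for (kw in c("meal", "food", "eat", "breakfast", "lunch", "dinner")) {
    for (instr in c(sprintf("take with %s", kw), sprintf("%s FIRST", toupper(kw)))) {
      row <- fix_row("20000002", "1-0-0-0", instr)
      f <- apply_keyword_rules(row, 1L, lexicon_fix)
      ids <- vapply(f, `[[`, "", "factor_id")
      expect_true("meal_dependent" %in% ids, info = instr)
    }
  }
  # embedded substrings do not match
  f <- apply_keyword_rules(fix_row("20000002", "1-0-0-0", "seafood platter"),
                           1L, lexicon_fix)
  expect_false("meal_dependent" %in% vapply(f, `[[`, "", "factor_id"))
})

test_that("appending text never removes a keyword finding (monotonicity)", {
  set.seed(99)
  suffixes <- c(" and more", "; store at room temperature", " STAT", " x")
  for (i in 1:20) {
    entry <- lexicon_fix$entries[[sample(names(lexicon_fix$entries), 1)]]
    phrase <- sample(entry$phrases, 1)
    base_row <- fix_row("20000002", "1-0-0-0", phrase)
    base_ids <- vapply(apply_keyword_rules(base_row, 1L, lexicon_fix),
                       `[[`, "", "factor_id")
    longer <- fix_row("20000002", "1-0-0-0",
                      paste0(phrase, sample(suffixes, 1)))
    long_ids <- vapply(apply_keyword_rules(longer, 1L, lexicon_fix),
                       `[[`, "", "factor_id")
    expect_true(all(base_ids %in% long_ids), info = phrase)
  }
})

test_that("spec'd scheme examples fire the expected rule combinations", {
  # companion covers every slot so the slot-uniqueness rule stays silent
  sch2 <- function(scheme) {
    fix_schedule(fix_row("30000002", scheme), fix_row("20000002", "1-1-1-1"))
  }
  ids_of <- function(sch) {
    vapply(apply_scheme_rules(sch$rows[[1]], 1L, sch,
                              drug_lookup(drugref_fix, sch$rows[[1]]$pzn)),
           `[[`, "", "factor_id")
  }
  expect_setequal(ids_of(sch2("0.5-0-0.5-0")), "tablet_splitting")
  expect_setequal(ids_of(sch2("1-1-1-0")),
                  c("more_than_twice_daily", "lunch_time_administration"))
  expect_setequal(ids_of(sch2("1-0-2-0")),
                  c("different_doses_same_drug", "multiple_doses_concurrently"))
  # variable dosing: free-text scheme, non-PRN
  sch <- fix_schedule(fix_row("20000002", "according to plan"))
  expect_setequal(ids_of(sch), "variable_dosing")
  # ...but suppressed for PRN rows
  schp <- fix_schedule(fix_row("20000002", "according to plan", prn = TRUE))
  expect_length(apply_scheme_rules(schp$rows[[1]], 1L, schp, NULL), 0)
})

test_that("scheme rules equal the brute-force oracle on all 625 half-unit schemes", {
  vals <- c(0, 0.5, 1, 1.5, 2)
  grid <- expand.grid(m = vals, n = vals, e = vals, ni = vals)
  companion <- fix_row("20000002", "1-0-1-0")
  rec <- drug_lookup(drugref_fix, "30000002")  # divisible solid oral
  for (k in seq_len(nrow(grid))) {
    slots <- as.numeric(grid[k, ])
    scheme <- paste(slots, collapse = "-")
    row <- fix_row("30000002", scheme)
    sch <- medication_schedule(list(row, companion))
    got <- sort(vapply(apply_scheme_rules(row, 1L, sch, rec), `[[`, "",
                       "factor_id"))
    want <- oracle_scheme_rules(slots, list(c(1, 0, 1, 0)), solid_oral = TRUE)
    expect_identical(got, want, info = scheme)
  }
})

test_that("product rules map form classes and gate on prescription status", {
  one <- function(pzn) {
    row <- fix_row(pzn, "1-0-0-0")
    apply_pzn_rules(row, 1L, drug_lookup(drugref_fix, pzn), lexicon_fix)
  }
  f <- one("10000021")
  expect_identical(f[[1]]$factor_id, "transdermal_patches")
  expect_identical(f[[1]]$evidence$type, "pzn_attribute")
  # device subtype travels with the finding
  f <- one("10000002")
  expect_identical(f[[1]]$factor_id, "inhalers")
  expect_identical(f[[1]]$device_subtype, "elpenhaler")
  # prescription-only gate: OTC nasal product must not fire
  expect_length(one("10000023"), 0)
  expect_identical(one("10000022")[[1]]$factor_id, "nasal_preparations_rx")
  # palatability flag fires only on liquid oral forms
  ids <- vapply(one("10000034"), `[[`, "", "factor_id")
  expect_setequal(ids, c("liquid_oral_forms", "unfriendly_liquid_oral"))
  custom <- make_drugref(list(
    c("111", "SolidBitter", "x", "solid_oral", "", "true", "1", "false",
      "false", "false", "true", "false", "false", "g")))
  row <- medication_row(pzn = "111", brand_name = "SolidBitter",
                        scheme_text = "1-0-0-0")
  expect_length(apply_pzn_rules(row, 1L, drug_lookup(custom, "111"),
                                lexicon_fix), 0)
  # complex measurements need the product flag AND an instructions keyword
  quiet <- fix_row("10000038", "1-0-0-0")
  expect_length(apply_pzn_rules(quiet, 1L, drug_lookup(drugref_fix, "10000038"),
                                lexicon_fix), 0)
  flagged <- fix_row("10000038", "1-0-0-0", "adjust after INR")
  f <- apply_pzn_rules(flagged, 1L, drug_lookup(drugref_fix, "10000038"),
                       lexicon_fix)
  expect_identical(f[[1]]$factor_id, "complex_measurements")
  expect_identical(f[[1]]$evidence$type, "pzn_and_keyword")
})

test_that("schedule-level rules: line count and ingredient duplication", {
  rows5 <- lapply(sprintf("200000%02d", 2:6), fix_row)
  f <- apply_schedule_rules(medication_schedule(rows5), drugref_fix)
  expect_length(f, 1)
  expect_identical(f[[1]]$factor_id, "total_number_of_drugs")
  expect_equal(f[[1]]$evidence$line_count, 5)
  expect_length(f[[1]]$row_indices, 0)

  dup <- medication_schedule(list(fix_row("30000013"), fix_row("30000014")))
  f <- apply_schedule_rules(dup, drugref_fix)
  expect_length(f, 1)
  expect_identical(f[[1]]$factor_id, "same_ingredient_different_preparations")
  expect_equal(f[[1]]$row_indices, c(1L, 2L))
  expect_identical(f[[1]]$evidence$pairs[[1]]$ingredient, "ibuprofen")

  four <- medication_schedule(lapply(sprintf("200000%02d", 2:5), fix_row))
  expect_length(apply_schedule_rules(four, drugref_fix), 0)
})

test_that("PRN factor fires on the row flag or on lexicon phrases", {
  by_flag <- apply_keyword_rules(fix_row("20000002", "", prn = TRUE),
                                 1L, lexicon_fix)
  expect_identical(by_flag[[1]]$factor_id, "prn_medication")
  by_text <- apply_keyword_rules(fix_row("20000002", "", "take if necessary"),
                                 1L, lexicon_fix)
  expect_identical(by_text[[1]]$factor_id, "prn_medication")
  expect_identical(by_text[[1]]$evidence$phrase, "if necessary")
})

test_that("every finding's evidence type matches its factor's mechanism", {
  allowed <- list(pzn = c("pzn_attribute", "ingredient_pair"),
                  dosage_scheme = "slot_pattern",
                  schedule_lines = "line_count",
                  keywords = "matched_keyword",
                  pzn_and_keywords = "pzn_and_keyword")
  suite <- generate_suite(10, seed = 23, drugref = drugref_fix, kb = kb_fix)
  n_checked <- 0
  for (s in suite) {
    for (f in detect(s$schedule, drugref_fix, kb_fix)) {
      mech <- kb_fix$factors[[f$factor_id]]$detection_mechanism
      expect_true(f$evidence$type %in% allowed[[mech]],
                  info = paste(f$factor_id, f$evidence$type))
      n_checked <- n_checked + 1
    }
  }
  expect_gt(n_checked, 10)
})

test_that("rows without a resolvable PZN skip product rules with a warning", {
  sch <- medication_schedule(list(
    medication_row(brand_name = "Mystery", scheme_text = "1-0-1-0")))
  f <- detect(sch, drugref_fix, kb_fix)
  expect_length(f, 0)
  expect_match(attr(f, "warnings"), "no PZN match", all = FALSE)
})
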