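#' @title PZN-keyed drug reference
#' @description Stand-in for the national product database: a flat table
#'   keyed by Pharmacy Product Number supplying the product attributes the
#'   PZN-based detection rules and the substitution algorithms need (dosage
#'   form class, device subtype, strengths, divisibility, flags, and a curated
#'   `equivalence_group` linking substitutable products). A fixture spanning
#'   every form class ships with the package.
#' @name drug_reference
NULL

drug_form_classes <- c("inhaler", "injection", "transdermal_patch", "nasal",
                       "oropharyngeal_solid", "oropharyngeal_liquid",
                       "ophthalmic", "rectal", "dermatological", "liquid_oral",
                       "otological", "vaginal", "solid_oral", "other")

drug_device_subtypes <- c("metered_dose_inhaler", "elpenhaler", "nebuliser",
                          "capsule_inhaler", "other_inhaler", "eye_drops",
                          "eye_ointment", "liquid_measuring_device",
                          "dry_syrup", "oral_drops", "prefilled_injector",
                          "non_prefilled_injector")

#' Read a drug reference table
#'
#' @param path CSV file with the documented columns; defaults to the packaged
#'   fixture (~50 synthetic products covering every form class and device
#'   subtype).
#' @return An object of class `drug_reference`: a data frame keyed by
#'   normalized PZN with list-columns `active_ingredients` and `strengths_mg`.
#' @export
read_drug_reference <- function(path = kb_default_path("drug_reference.csv")) {
  df <- utils::read.csv(path, colClasses = "character", check.names = FALSE,
                        encoding = "UTF-8")
  needed <- c("pzn", "brand_name", "active_ingredients", "form_class",
              "device_subtype", "prescription_only", "strengths_mg",
              "divisible", "orodispersible", "extended_release",
              "palatability_issue", "requires_technique_training",
              "self_measurement_linked", "equivalence_group")
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols)) {
    stop("drug reference lacks column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  df$pzn <- vapply(df$pzn, normalize_pzn, "")
  if (anyDuplicated(df$pzn)) stop("duplicate PZN in drug reference", call. = FALSE)
  bad_form <- setdiff(unique(df$form_class), drug_form_classes)
  if (length(bad_form)) {
    stop("unknown form_class: ", paste(bad_form, collapse = ", "), call. = FALSE)
  }
  bad_dev <- setdiff(setdiff(unique(df$device_subtype), ""), drug_device_subtypes)
  if (length(bad_dev)) {
    stop("unknown device_subtype: ", paste(bad_dev, collapse = ", "), call. = FALSE)
  }
  for (col in c("prescription_only", "divisible", "orodispersible",
                "extended_release", "palatability_issue",
                "requires_technique_training", "self_measurement_linked")) {
    df[[col]] <- tolower(df[[col]]) %in% c("true", "1", "yes")
  }
  df$active_ingredients <- strsplit(df$active_ingredients, "+", fixed = TRUE)
  df$strengths_mg <- lapply(strsplit(df$strengths_mg, "+", fixed = TRUE), as.numeric)
  ok <- vapply(df$strengths_mg, function(s) !length(s) || all(is.finite(s) & s > 0), TRUE)
  if (!all(ok)) stop("non-positive strength in drug reference", call. = FALSE)
  rownames(df) <- df$pzn
  structure(df, class = c("drug_reference", "data.frame"),
            digest = file_digest(path), source = normalizePath(path))
}

#' Look up a product by PZN
#'
#' The query PZN is normalized (zero-padded) before exact matching; an
#' unknown PZN yields `NULL` (a value, not an error).
#'
#' @param ref A `drug_reference`.
#' @param pzn PZN string or number.
#' @return A one-row `drug_record` list, or `NULL` if not found.
#' @export
drug_lookup <- function(ref, pzn) {
  stopifnot(inherits(ref, "drug_reference"))
  p <- tryCatch(normalize_pzn(pzn), error = function(e) NA_character_)
  if (is.na(p) || !(p %in% ref$pzn)) return(NULL)
  as_drug_record(ref[p, , drop = FALSE])
}

as_drug_record <- function(row1) {
  rec <- as.list(row1)
  rec$active_ingredients <- row1$active_ingredients[[1]]
  rec$strengths_mg <- row1$strengths_mg[[1]]
  rec$strength_mg <- if (length(rec$strengths_mg) == 1) rec$strengths_mg else NA_real_
  if (identical(rec$device_subtype, "")) rec$device_subtype <- NA_character_
  structure(rec, class = "drug_record")
}

#' @export
print.drug_record <- function(x, ...) {
  cat("<drug_record> ", x$pzn, " ", x$brand_name, " (",
      paste(x$active_ingredients, collapse = " + "), "), ", x$form_class,
      if (!is.na(x$device_subtype)) paste0("/", x$device_subtype), "\n", sep = "")
  invisible(x)
}

#' Find substitutable alternative products
#'
#' Returns the members of an equivalence group (curated family of mutually
#' substitutable products) that satisfy every supplied constraint, excluding
#' the query product itself, in a deterministic order: strength ascending,
#' ties broken by PZN.
#'
#' @param ref A `drug_reference`.
#' @param equivalence_group Group key; unknown groups yield an empty list
#'   with a warning.
#' @param exclude_pzn PZN of the query product to drop from the results.
#' @param form_class Optional constraint: keep only these form classes.
#' @param device_subtype Optional constraint on device subtype.
#' @param strength_mg Optional constraint: single-ingredient strength must
#'   equal this value (within `1e-9`).
#' @param divisible Optional logical constraint on the score-line flag.
#' @param extended_release Optional logical constraint.
#' @param orodispersible Optional logical constraint.
#' @return List of `drug_record`s (possibly empty).
#' @export
find_alternatives <- function(ref, equivalence_group, exclude_pzn = NULL,
                              form_class = NULL, device_subtype = NULL,
                              strength_mg = NULL, divisible = NULL,
                              extended_release = NULL, orodispersible = NULL) {
  stopifnot(inherits(ref, "drug_reference"))
  idx <- ref$equivalence_group == equivalence_group
  if (!any(idx)) {
    warning("unknown equivalence_group: ", equivalence_group, call. = FALSE)
    return(list())
  }
  sub <- ref[idx, , drop = FALSE]
  if (!is.null(exclude_pzn)) {
    sub <- sub[sub$pzn != normalize_pzn(exclude_pzn), , drop = FALSE]
  }
  if (!is.null(form_class)) sub <- sub[sub$form_class %in% form_class, , drop = FALSE]
  if (!is.null(device_subtype)) {
    sub <- sub[sub$device_subtype %in% device_subtype, , drop = FALSE]
  }
  if (!is.null(strength_mg)) {
    keep <- vapply(sub$strengths_mg, function(s) {
      length(s) == 1 && abs(s - strength_mg) < 1e-9
    }, TRUE)
    sub <- sub[keep, , drop = FALSE]
  }
  for (flag in c("divisible", "extended_release", "orodispersible")) {
    want <- get(flag)
    if (!is.null(want)) sub <- sub[sub[[flag]] == want, , drop = FALSE]
  }
  if (nrow(sub) == 0) return(list())
  first_strength <- vapply(sub$strengths_mg, function(s) {
    if (length(s)) min(s) else Inf
  }, 0)
  sub <- sub[order(first_strength, sub$pzn), , drop = FALSE]
  lapply(seq_len(nrow(sub)), function(i) as_drug_record(sub[i, , drop = FALSE]))
}
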