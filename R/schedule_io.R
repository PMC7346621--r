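#' @title Medication schedule I/O and dosage-scheme parsing
#' @description Readers and writers for the repository's simplified dialect of
#'   the German nationally standardized medication plan (BMP), plus the
#'   dosage-scheme grammar. A schedule is an ordered list of rows, one per
#'   drug line; each row carries the product identifier (PZN), brand name,
#'   active ingredient, dosage form, strength, the four-slot dosage scheme
#'   (morning-noon-evening-night), the dose unit, free-text instructions, the
#'   indication, and an as-needed (PRN) flag.
#' @name schedule_io
NULL

#' Construct a medication row
#'
#' At least one of `pzn` and `brand_name` must be present. PZNs are stored as
#' zero-padded 8-character strings; leading zeros are significant.
#'
#' @param pzn Pharmacy Product Number (7-8 digits) or `NA`.
#' @param brand_name Brand name printed on the plan.
#' @param active_ingredient Active ingredient; combination products list
#'   ingredients separated by `"+"`.
#' @param dosage_form Free-text dosage form from the plan.
#' @param strength Strength string including unit (e.g. `"10 mg"`).
#' @param scheme_text Raw dosage-scheme string (e.g. `"1-0-1-0"`).
#' @param unit Dose unit (e.g. `"tablet"`).
#' @param instructions Free-text instructions for use.
#' @param indication Free-text indication.
#' @param prn Logical; `TRUE` for as-needed (pro re nata) rows.
#' @return An object of class `medication_row`.
#' @export
medication_row <- function(pzn = NA_character_, brand_name = NA_character_,
                           active_ingredient = NA_character_,
                           dosage_form = NA_character_, strength = NA_character_,
                           scheme_text = "", unit = NA_character_,
                           instructions = "", indication = NA_character_,
                           prn = FALSE) {
  pzn <- normalize_pzn(pzn)
  if ((is.na(pzn) || !nzchar(pzn)) && (is.na(brand_name) || !nzchar(brand_name))) {
    stop("medication row needs at least one of pzn or brand_name", call. = FALSE)
  }
  scheme_text <- if (is.na(scheme_text)) "" else as.character(scheme_text)
  row <- list(
    pzn = pzn,
    brand_name = as.character(brand_name),
    active_ingredient = as.character(active_ingredient),
    dosage_form = as.character(dosage_form),
    strength = as.character(strength),
    scheme_text = scheme_text,
    scheme = parse_dosage_scheme(scheme_text),
    unit = as.character(unit),
    instructions = if (is.na(instructions)) "" else as.character(instructions),
    indication = as.character(indication),
    prn = isTRUE(prn)
  )
  structure(row, class = "medication_row")
}

#' Construct a medication schedule
#'
#' @param rows List of [medication_row()] objects, in plan order.
#' @param patient_ref Opaque patient identifier.
#' @param issued_on Issue date (`"YYYY-MM-DD"`) or `NA`.
#' @return An object of class `medication_schedule`.
#' @export
medication_schedule <- function(rows, patient_ref = NA_character_,
                                issued_on = NA_character_) {
  stopifnot(is.list(rows))
  for (i in seq_along(rows)) {
    if (!inherits(rows[[i]], "medication_row")) {
      stop("rows[[", i, "]] is not a medication_row", call. = FALSE)
    }
  }
  structure(list(patient_ref = as.character(patient_ref),
                 issued_on = as.character(issued_on),
                 rows = rows),
            class = "medication_schedule")
}

#' @export
print.medication_schedule <- function(x, ...) {
  cat("<medication_schedule> ", length(x$rows), " row(s)",
      if (!is.na(x$issued_on)) paste0(", issued ", x$issued_on), "\n", sep = "")
  for (i in seq_along(x$rows)) {
    r <- x$rows[[i]]
    cat(sprintf("  %2d. %s [%s] %s %s%s\n", i,
                ifelse(is.na(r$brand_name), "?", r$brand_name),
                ifelse(is.na(r$pzn), "-", r$pzn),
                r$scheme_text,
                ifelse(is.na(r$unit), "", r$unit),
                if (r$prn) " (PRN)" else ""))
  }
  invisible(x)
}

#' Normalize a Pharmacy Product Number
#'
#' PZNs are opaque digit strings of 7-8 digits; they are zero-padded to
#' 8 characters and never treated as integers (leading zeros are
#' significant).
#'
#' @param pzn Character or number.
#' @return 8-character string, or `NA_character_` for missing/empty input.
#' @export
normalize_pzn <- function(pzn) {
  if (length(pzn) != 1 || is.na(pzn)) return(NA_character_)
  p <- trimws(as.character(pzn))
  if (!nzchar(p)) return(NA_character_)
  if (!grepl("^[0-9]{1,8}$", p)) {
    stop("invalid PZN: ", p, call. = FALSE)
  }
  paste0(strrep("0", 8L - nchar(p)), p)
}

#' Parse a dosage-scheme string
#'
#' The national plan prints dosing as up to four dash-separated slot doses
#' (morning-noon-evening-night). Two- or three-token schemes are right-padded
#' with zeros (night, then evening). Decimal commas are normalized to dots and
#' simple fractions (`"1/2"`) to decimals. Any other content -- empty strings,
#' ranges, words -- yields an unstructured scheme carrying the original text;
#' this function never raises.
#'
#' @param text Any string (or `NA`).
#' @return A list of class `dosage_scheme` with elements `structured`
#'   (logical), `slots` (numeric quadruple; only when structured) and `text`
#'   (original input).
#' @examples
#' parse_dosage_scheme("1-0-1-0")$slots
#' parse_dosage_scheme("1/2-0-1/2")$slots   # fractions, padding
#' parse_dosage_scheme("as directed")$structured
#' @export
parse_dosage_scheme <- function(text) {
  orig <- if (length(text) != 1 || is.na(text)) "" else as.character(text)
  unstructured <- structure(list(structured = FALSE, slots = NULL, text = orig),
                            class = "dosage_scheme")
  s <- trimws(orig)
  if (!nzchar(s)) return(unstructured)
  s <- gsub(",", ".", s, fixed = TRUE)
  tokens <- strsplit(s, "-", fixed = TRUE)[[1]]
  if (length(tokens) < 2 || length(tokens) > 4) return(unstructured)
  vals <- vapply(tokens, parse_dose_token, numeric(1), USE.NAMES = FALSE)
  if (anyNA(vals) || any(vals < 0) || any(!is.finite(vals))) return(unstructured)
  slots <- c(vals, rep(0, 4 - length(vals)))
  structure(list(structured = TRUE, slots = slots, text = orig),
            class = "dosage_scheme")
}

# single slot token: decimal ("0.5") or simple fraction ("1/2"); NA otherwise
parse_dose_token <- function(tok) {
  tok <- trimws(tok)
  if (grepl("^[0-9]+/[0-9]+$", tok)) {
    parts <- as.numeric(strsplit(tok, "/", fixed = TRUE)[[1]])
    if (parts[2] == 0) return(NA_real_)
    return(parts[1] / parts[2])
  }
  if (grepl("^[0-9]+(\\.[0-9]+)?$", tok)) return(as.numeric(tok))
  NA_real_
}

schedule_fields <- c("pzn", "name", "ingredient", "form", "strength", "scheme",
                     "unit", "instructions", "indication", "prn")

#' Read a medication schedule from XML
#'
#' Expects the documented dialect: a `<medicationSchedule>` root with optional
#' `patient` and `issued` attributes and one `<row>` element per drug line
#' with attributes `pzn`, `name`, `ingredient`, `form`, `strength`, `scheme`,
#' `unit`, `instructions`, `indication`, `prn`. Unknown attributes are ignored
#' with a warning.
#'
#' @param source Path or connection to an XML file.
#' @return A [medication_schedule()].
#' @export
read_schedule_xml <- function(source) {
  doc <- xml2::read_xml(source)
  root <- xml2::xml_name(doc)
  if (root != "medicationSchedule") {
    stop("expected <medicationSchedule> root, found <", root, ">", call. = FALSE)
  }
  row_nodes <- xml2::xml_find_all(doc, "./row")
  rows <- vector("list", length(row_nodes))
  for (i in seq_along(row_nodes)) {
    at <- as.list(xml2::xml_attrs(row_nodes[[i]]))
    unknown <- setdiff(names(at), schedule_fields)
    if (length(unknown)) {
      warning("row ", i, ": ignoring unknown attribute(s) ",
              paste(unknown, collapse = ", "), call. = FALSE)
    }
    rows[[i]] <- tryCatch(
      row_from_fields(at),
      error = function(e) stop("row ", i, ": ", conditionMessage(e), call. = FALSE)
    )
  }
  medication_schedule(rows,
                      patient_ref = xml2::xml_attr(doc, "patient"),
                      issued_on = xml2::xml_attr(doc, "issued"))
}

row_from_fields <- function(at) {
  g <- function(k, default = NA_character_) {
    v <- at[[k]]
    if (is.null(v) || (length(v) == 1 && is.na(v))) default else as.character(v)
  }
  medication_row(
    pzn = g("pzn"),
    brand_name = g("name"),
    active_ingredient = g("ingredient"),
    dosage_form = g("form"),
    strength = g("strength"),
    scheme_text = g("scheme", ""),
    unit = g("unit"),
    instructions = g("instructions", ""),
    indication = g("indication"),
    prn = tolower(g("prn", "false")) %in% c("true", "1", "yes")
  )
}

#' Write a medication schedule as XML
#'
#' Inverse of [read_schedule_xml()]: all analysed fields round-trip exactly.
#'
#' @param schedule A [medication_schedule()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_schedule_xml <- function(schedule, path) {
  stopifnot(inherits(schedule, "medication_schedule"))
  doc <- xml2::xml_new_root("medicationSchedule")
  if (!is.na(schedule$patient_ref)) xml2::xml_set_attr(doc, "patient", schedule$patient_ref)
  if (!is.na(schedule$issued_on)) xml2::xml_set_attr(doc, "issued", schedule$issued_on)
  for (r in schedule$rows) {
    node <- xml2::xml_add_child(doc, "row")
    vals <- c(pzn = r$pzn, name = r$brand_name, ingredient = r$active_ingredient,
              form = r$dosage_form, strength = r$strength, scheme = r$scheme_text,
              unit = r$unit, instructions = r$instructions,
              indication = r$indication,
              prn = if (r$prn) "true" else "false")
    for (k in names(vals)) {
      if (!is.na(vals[[k]])) xml2::xml_set_attr(node, k, vals[[k]])
    }
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

#' Read a medication schedule from CSV
#'
#' Column names match the XML attribute names (`pzn`, `name`, `ingredient`,
#' `form`, `strength`, `scheme`, `unit`, `instructions`, `indication`,
#' `prn`); the header is mandatory and files are UTF-8, comma-separated.
#' Equivalent content yields a schedule equal to the XML reader's.
#'
#' @param source Path to a CSV file.
#' @return A [medication_schedule()].
#' @export
read_schedule_csv <- function(source) {
  df <- utils::read.csv(source, colClasses = "character", check.names = FALSE,
                        encoding = "UTF-8")
  if (nrow(df) == 0) stop("no rows in ", source, call. = FALSE)
  needed <- c("name", "scheme")
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols)) {
    stop("missing mandatory column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  rows <- vector("list", nrow(df))
  for (i in seq_len(nrow(df))) {
    at <- as.list(df[i, , drop = FALSE])
    at <- lapply(at, function(v) if (identical(v, "")) NA_character_ else v)
    if (identical(at$instructions, NA_character_)) at$instructions <- ""
    if (identical(at$scheme, NA_character_)) at$scheme <- ""
    rows[[i]] <- tryCatch(
      row_from_fields(at),
      error = function(e) stop("row ", i, ": ", conditionMessage(e), call. = FALSE)
    )
  }
  medication_schedule(rows,
                      patient_ref = if ("patient" %in% names(df)) df$patient[1] else NA_character_,
                      issued_on = if ("issued" %in% names(df)) df$issued[1] else NA_character_)
}

#' Write a medication schedule as CSV
#'
#' @param schedule A [medication_schedule()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_schedule_csv <- function(schedule, path) {
  stopifnot(inherits(schedule, "medication_schedule"))
  df <- do.call(rbind, lapply(schedule$rows, function(r) {
    data.frame(pzn = r$pzn, name = r$brand_name, ingredient = r$active_ingredient,
               form = r$dosage_form, strength = r$strength, scheme = r$scheme_text,
               unit = r$unit, instructions = r$instructions,
               indication = r$indication,
               prn = if (r$prn) "true" else "false",
               stringsAsFactors = FALSE)
  }))
  df[is.na(df)] <- ""
  utils::write.csv(df, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
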