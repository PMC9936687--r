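# Dispatch-register data model: construction, CSV reading/writing with
# row-level validation, study inclusion/exclusion, and the A/B/C/D -> binary
# urgency dichotomy.

#' Dispatch priorities and mission statuses
#'
#' `dispatch_priorities()` returns the four Finnish EMS dispatch priorities:
#' A (suspected life threat) and B (urgent) are lights-and-siren responses,
#' C (reach within 30 min) and D (within 2 h) are not.
#' `mission_statuses()` returns the recognised mission outcomes; only
#' `"completed_patient_confronted"` records enter the analysis.
#'
#' @return character vector of admissible values.
#' @export
dispatch_priorities <- function() c("A", "B", "C", "D")

#' @rdname dispatch_priorities
#' @export
mission_statuses <- function() {
  c("completed_patient_confronted", "cancelled", "aborted",
    "patient_not_confronted", "first_responder", "invalid_data")
}

excluded_statuses <- function() setdiff(mission_statuses(), "completed_patient_confronted")

paramedic_assessments <- function() c("urgent", "non_urgent", "not_documented")

# Canonical column set of a dispatch register, with the prototype value used
# when an optional column is absent from a source file.
register_columns <- function() {
  list(
    record_id             = NA_character_,
    category              = NA_character_,
    emd_priority          = NA_character_,
    status                = "completed_patient_confronted",
    transported           = FALSE,
    transport_priority    = NA_character_,
    paramedic_assessment  = "not_documented",
    deceased              = FALSE,
    spo2_percent          = NA_real_,
    blood_glucose_mmol_l  = NA_real_,
    spco_percent          = NA_real_,
    convulsion            = FALSE,
    allergic_reaction     = FALSE,
    overdose_or_poisoning = FALSE,
    bronchodilator        = FALSE,
    anticonvulsant        = FALSE,
    epinephrine           = FALSE,
    airway_management     = FALSE,
    cpr                   = FALSE,
    iv_glucose            = FALSE,
    oxygen                = FALSE,
    antidote              = FALSE
  )
}

intervention_columns <- function() {
  c("bronchodilator", "anticonvulsant", "epinephrine", "airway_management",
    "cpr", "iv_glucose", "oxygen", "antidote")
}

condition_columns <- function() {
  c("deceased", "convulsion", "allergic_reaction", "overdose_or_poisoning")
}

#' Construct a dispatch register in memory
#'
#' Builds a validated `dispatch_register` data frame from per-record vectors.
#' All arguments are recycled to the length of `category`; omitted clinical
#' and intervention fields default to absent/false, matching how empty cells
#' in a register export are interpreted.
#'
#' @param category dispatch category labels (free text; matched
#'   case-insensitively after whitespace normalisation downstream).
#' @param emd_priority dispatcher priority, one of `"A"`, `"B"`, `"C"`, `"D"`.
#' @param status mission status, see [mission_statuses()].
#' @param transported logical; was the patient conveyed.
#' @param transport_priority conveyance priority letter; must be present
#'   exactly when `transported` is `TRUE`.
#' @param paramedic_assessment `"urgent"`, `"non_urgent"` or
#'   `"not_documented"` (documentation on scene was voluntary).
#' @param deceased,convulsion,allergic_reaction,overdose_or_poisoning logical
#'   condition flags.
#' @param spo2_percent,blood_glucose_mmol_l,spco_percent vital signs;
#'   `NA` means not measured, which is distinct from any numeric value.
#' @param bronchodilator,anticonvulsant,epinephrine,airway_management,cpr,iv_glucose,oxygen,antidote
#'   logical intervention flags.
#' @param record_id unique record identifiers; generated when omitted.
#' @return a `dispatch_register` data frame, one row per dispatch.
#' @export
dispatch_register <- function(category, emd_priority,
                              status = "completed_patient_confronted",
                              transported = FALSE, transport_priority = NA_character_,
                              paramedic_assessment = "not_documented",
                              deceased = FALSE,
                              spo2_percent = NA_real_, blood_glucose_mmol_l = NA_real_,
                              spco_percent = NA_real_,
                              convulsion = FALSE, allergic_reaction = FALSE,
                              overdose_or_poisoning = FALSE,
                              bronchodilator = FALSE, anticonvulsant = FALSE,
                              epinephrine = FALSE, airway_management = FALSE,
                              cpr = FALSE, iv_glucose = FALSE, oxygen = FALSE,
                              antidote = FALSE,
                              record_id = NULL) {
  n <- if (length(category) == 0) 0L
  else max(length(record_id %||% character(1)),
           lengths(list(category, emd_priority, status, transported,
                        transport_priority, paramedic_assessment, deceased,
                        spo2_percent, blood_glucose_mmol_l, spco_percent,
                        convulsion, allergic_reaction, overdose_or_poisoning,
                        bronchodilator, anticonvulsant, epinephrine,
                        airway_management, cpr, iv_glucose, oxygen, antidote)))
  if (is.null(record_id)) record_id <- sprintf("R%06d", seq_len(n))
  df <- data.frame(
    record_id = rep_len(as.character(record_id), n),
    category = rep_len(normalize_category(category), n),
    emd_priority = rep_len(as.character(emd_priority), n),
    status = rep_len(as.character(status), n),
    transported = rep_len(as.logical(transported), n),
    transport_priority = rep_len(as.character(transport_priority), n),
    paramedic_assessment = rep_len(as.character(paramedic_assessment), n),
    deceased = rep_len(as.logical(deceased), n),
    spo2_percent = rep_len(as.numeric(spo2_percent), n),
    blood_glucose_mmol_l = rep_len(as.numeric(blood_glucose_mmol_l), n),
    spco_percent = rep_len(as.numeric(spco_percent), n),
    convulsion = rep_len(as.logical(convulsion), n),
    allergic_reaction = rep_len(as.logical(allergic_reaction), n),
    overdose_or_poisoning = rep_len(as.logical(overdose_or_poisoning), n),
    bronchodilator = rep_len(as.logical(bronchodilator), n),
    anticonvulsant = rep_len(as.logical(anticonvulsant), n),
    epinephrine = rep_len(as.logical(epinephrine), n),
    airway_management = rep_len(as.logical(airway_management), n),
    cpr = rep_len(as.logical(cpr), n),
    iv_glucose = rep_len(as.logical(iv_glucose), n),
    oxygen = rep_len(as.logical(oxygen), n),
    antidote = rep_len(as.logical(antidote), n),
    stringsAsFactors = FALSE
  )
  validate_register(new_register(df))
}

new_register <- function(df, parse_report = empty_parse_report()) {
  stopifnot(is.data.frame(df))
  structure(df, class = c("dispatch_register", "data.frame"),
            parse_report = parse_report)
}

empty_parse_report <- function() {
  data.frame(row = integer(0), field = character(0), reason = character(0),
             stringsAsFactors = FALSE)
}

validate_register <- function(x) {
  bad <- setdiff(names(register_columns()), names(x))
  if (length(bad)) stop_input("register is missing columns: ", paste(bad, collapse = ", "))
  if (anyDuplicated(x$record_id)) stop_input("record_id values must be unique")
  ok_pri <- is.na(x$emd_priority) | x$emd_priority %in% dispatch_priorities()
  if (!all(ok_pri)) stop_input("invalid emd_priority value(s): ",
                               paste(unique(x$emd_priority[!ok_pri]), collapse = ", "))
  if (!all(x$status %in% mission_statuses())) stop_input("invalid mission status value(s)")
  if (!all(x$paramedic_assessment %in% paramedic_assessments()))
    stop_input("invalid paramedic_assessment value(s)")
  incl <- x$status == "completed_patient_confronted"
  if (any(incl & (is.na(x$category) | x$category == "")))
    stop_input("included records must carry a dispatch category")
  if (any(incl & is.na(x$emd_priority)))
    stop_input("included records must carry an EMD priority")
  mismatch <- incl & (x$transported != !is.na(x$transport_priority))
  if (any(mismatch))
    stop_input("transport_priority must be present exactly when transported is TRUE (",
               sum(mismatch), " record(s) violate this)")
  x
}

#' Access the parse report of a register read from disk
#'
#' [read_register()] never drops a malformed row: the row is retained with
#' status `"invalid_data"` (so the exclusion count stays auditable) and the
#' offending field is recorded here.
#'
#' @param x a `dispatch_register`.
#' @return data frame with columns `row` (1-based data row in the source
#'   file), `field` and `reason`.
#' @export
parse_report <- function(x) {
  attr(x, "parse_report") %||% empty_parse_report()
}

#' Default column mapping for register CSV files
#'
#' Register exports from different record systems name their columns
#' differently; `read_register()` takes a mapping from the canonical field
#' names used by this package to the column names in the file. The default
#' is the identity mapping over the canonical schema (the schema
#' [write_register()] emits).
#'
#' @return named character vector: `names()` are canonical fields, values are
#'   file column names.
#' @export
default_schema <- function() {
  cols <- names(register_columns())
  stats::setNames(cols, cols)
}

parse_logical_token <- function(x) {
  x <- tolower(trimws(x))
  out <- rep(NA, length(x))
  out[x %in% c("true", "yes", "y", "1")] <- TRUE
  out[x %in% c("false", "no", "n", "0", "")] <- FALSE
  out
}

status_aliases <- function() {
  c(completed_patient_confronted = "completed_patient_confronted",
    completed = "completed_patient_confronted",
    cancelled = "cancelled", canceled = "cancelled",
    aborted = "aborted",
    patient_not_confronted = "patient_not_confronted",
    not_confronted = "patient_not_confronted",
    first_responder = "first_responder",
    invalid_data = "invalid_data")
}

#' Read a dispatch register from CSV
#'
#' Reads a comma-separated, UTF-8 register export with a mandatory header
#' row. Lines starting with `#` (provenance comments written by
#' [write_register()]) are skipped. Rows that fail validation are *kept*,
#' re-flagged with status `"invalid_data"`, and reported via
#' [parse_report()]; they are then removed from analysis by
#' [apply_exclusions()] like any other excluded status, so the total
#' exclusion count remains auditable.
#'
#' Empty cells mean: vital sign not measured, intervention/condition flag
#' false, paramedic assessment not documented, no transport priority.
#'
#' @param path path to the CSV file.
#' @param schema column mapping as returned by [default_schema()]; only
#'   `category`, `emd_priority`, `status` and `transported` are mandatory in
#'   the file, all other canonical fields default when unmapped or absent.
#' @return a `dispatch_register` with a [parse_report()] attached.
#' @export
read_register <- function(path, schema = default_schema()) {
  if (!file.exists(path)) stop_input("register file not found: ", path)
  raw <- tryCatch(
    utils::read.csv(path, colClasses = "character", comment.char = "#",
                    check.names = FALSE, fileEncoding = "UTF-8"),
    error = function(e) {
      if (grepl("no lines available|empty", conditionMessage(e)))
        return(NULL)
      stop_input("failed to parse ", path, ": ", conditionMessage(e))
    })
  if (is.null(raw) || ncol(raw) == 0) {
    warning("register file is empty: ", path)
    return(new_register(dispatch_register(character(0), character(0))))
  }

  mandatory <- c("category", "emd_priority", "status", "transported")
  missing_map <- setdiff(mandatory, names(schema))
  if (length(missing_map))
    stop_input("schema does not map mandatory column(s): ",
               paste(missing_map, collapse = ", "))
  absent <- schema[mandatory][!schema[mandatory] %in% names(raw)]
  if (length(absent))
    stop_input("mandatory column(s) missing from file: ",
               paste(absent, collapse = ", "))

  n <- nrow(raw)
  proto <- register_columns()
  get_col <- function(field) {
    src <- schema[[field]]
    if (!is.null(src) && src %in% names(raw)) trimws(raw[[src]]) else rep("", n)
  }

  issues <- list()
  note <- function(rows, field, reason) {
    if (length(rows))
      issues[[length(issues) + 1L]] <<- data.frame(row = rows, field = field,
                                                  reason = reason,
                                                  stringsAsFactors = FALSE)
  }

  rec_id <- get_col("record_id")
  if (all(rec_id == "")) rec_id <- sprintf("R%06d", seq_len(n))
  dup <- duplicated(rec_id)
  note(which(dup), "record_id", "duplicate identifier")

  category <- normalize_category(get_col("category"))
  note(which(category == ""), "category", "missing dispatch category")

  pri_raw <- toupper(get_col("emd_priority"))
  bad_pri <- !(pri_raw %in% dispatch_priorities())
  note(which(bad_pri), "emd_priority",
       ifelse(pri_raw[bad_pri] == "", "missing dispatch priority",
              paste0("unrecognised priority '", pri_raw[bad_pri], "'")))
  emd_priority <- ifelse(bad_pri, NA_character_, pri_raw)

  st_raw <- tolower(gsub("[ -]", "_", get_col("status")))
  st_raw[st_raw == ""] <- "completed_patient_confronted"
  status <- unname(status_aliases()[st_raw])
  note(which(is.na(status)), "status",
       paste0("unrecognised mission status '", st_raw[is.na(status)], "'"))
  status[is.na(status)] <- "invalid_data"

  transported <- parse_logical_token(get_col("transported"))
  note(which(is.na(transported)), "transported", "unrecognised yes/no token")

  tp_raw <- toupper(get_col("transport_priority"))
  transport_priority <- ifelse(tp_raw == "", NA_character_, tp_raw)
  bad_tp <- !is.na(transport_priority) & !transport_priority %in% dispatch_priorities()
  note(which(bad_tp), "transport_priority",
       paste0("unrecognised priority '", transport_priority[bad_tp], "'"))
  transport_priority[bad_tp] <- NA_character_
  tp_mismatch <- !is.na(transported) &
    (transported != !is.na(transport_priority)) & !bad_tp
  note(which(tp_mismatch), "transport_priority",
       ifelse(transported[tp_mismatch],
              "transported but no transport priority",
              "transport priority recorded without transport"))

  pa_raw <- tolower(gsub("[ -]", "_", get_col("paramedic_assessment")))
  pa_raw[pa_raw == ""] <- "not_documented"
  bad_pa <- !pa_raw %in% paramedic_assessments()
  note(which(bad_pa), "paramedic_assessment",
       paste0("unrecognised assessment '", pa_raw[bad_pa], "'"))
  paramedic_assessment <- ifelse(bad_pa, "not_documented", pa_raw)

  parse_num <- function(field, lo = 0, hi = Inf) {
    x <- get_col(field)
    out <- suppressWarnings(as.numeric(x))
    bad <- x != "" & is.na(out)
    note(which(bad), field, "not a number")
    oob <- !is.na(out) & (out < lo | out > hi)
    note(which(oob), field, sprintf("outside [%s, %s]", lo, hi))
    out[oob] <- NA_real_
    list(value = out, bad = bad | oob)
  }
  spo2 <- parse_num("spo2_percent", 0, 100)
  gluc <- parse_num("blood_glucose_mmol_l", 0)
  spco <- parse_num("spco_percent", 0)

  flags <- c(condition_columns(), intervention_columns())
  flag_vals <- list()
  flag_bad <- rep(FALSE, n)
  for (f in flags) {
    v <- parse_logical_token(get_col(f))
    note(which(is.na(v)), f, "unrecognised yes/no token")
    flag_bad <- flag_bad | is.na(v)
    v[is.na(v)] <- FALSE
    flag_vals[[f]] <- v
  }

  report <- if (length(issues)) do.call(rbind, issues) else empty_parse_report()
  report <- report[order(report$row), , drop = FALSE]
  rownames(report) <- NULL

  invalid <- seq_len(n) %in% report$row
  status[invalid] <- "invalid_data"
  # Coerce invalidated rows back into a well-formed frame (they are already
  # flagged, so normalising here loses no audit information).
  transported[is.na(transported)] <- FALSE
  transport_priority[!transported] <- NA_character_
  transported[transported & is.na(transport_priority)] <- FALSE

  df <- data.frame(
    record_id = rec_id, category = category, emd_priority = emd_priority,
    status = status, transported = transported,
    transport_priority = transport_priority,
    paramedic_assessment = paramedic_assessment,
    deceased = flag_vals$deceased,
    spo2_percent = spo2$value, blood_glucose_mmol_l = gluc$value,
    spco_percent = spco$value,
    convulsion = flag_vals$convulsion,
    allergic_reaction = flag_vals$allergic_reaction,
    overdose_or_poisoning = flag_vals$overdose_or_poisoning,
    bronchodilator = flag_vals$bronchodilator,
    anticonvulsant = flag_vals$anticonvulsant,
    epinephrine = flag_vals$epinephrine,
    airway_management = flag_vals$airway_management,
    cpr = flag_vals$cpr, iv_glucose = flag_vals$iv_glucose,
    oxygen = flag_vals$oxygen, antidote = flag_vals$antidote,
    stringsAsFactors = FALSE
  )
  # Deduplicate ids on invalidated rows so the register invariant holds.
  if (any(dup)) df$record_id[dup] <- paste0(df$record_id[dup], "_dup", which(dup))
  validate_register(new_register(df, parse_report = report))
}

format_csv_number <- function(x) {
  out <- ifelse(is.na(x), "", vapply(x, function(v) {
    if (is.na(v)) return("")
    s <- sprintf("%.17g", v)
    # shortest representation that round-trips to the same double
    for (d in 1:16) {
      c <- sprintf("%.*g", d, v)
      if (as.numeric(c) == v) return(c)
    }
    s
  }, character(1)))
  out
}

#' Write a dispatch register to CSV
#'
#' Emits the canonical schema that [read_register()] reads with
#' [default_schema()]. Logical flags are written as `true`/`false`, missing
#' vitals as empty cells, undocumented paramedic assessment as an empty
#' cell. Numeric vitals are written with enough digits to round-trip
#' bit-identically. Optional provenance lines are prepended as `#` comments.
#'
#' @param register a `dispatch_register`.
#' @param path output file path.
#' @param provenance optional character vector written as comment lines.
#' @return `path`, invisibly.
#' @export
write_register <- function(register, path, provenance = NULL) {
  df <- as.data.frame(register)
  out <- df
  for (f in c(condition_columns(), intervention_columns(), "transported"))
    out[[f]] <- ifelse(df[[f]], "true", "false")
  for (f in c("spo2_percent", "blood_glucose_mmol_l", "spco_percent"))
    out[[f]] <- format_csv_number(df[[f]])
  out$transport_priority <- ifelse(is.na(df$transport_priority), "", df$transport_priority)
  out$paramedic_assessment <- ifelse(df$paramedic_assessment == "not_documented",
                                     "", df$paramedic_assessment)
  out <- out[, names(register_columns())]
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  if (!is.null(provenance)) writeLines(paste0("# ", provenance), con)
  utils::write.csv(out, con, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Apply the study inclusion criteria
#'
#' Splits a register into the analysed set (mission completed with the
#' patient confronted) and the excluded set (cancelled, aborted, patient not
#' confronted, first-responder missions, and rows with invalid data). The
#' split is a partition: every input record lands in exactly one side.
#'
#' @param register a `dispatch_register`.
#' @return list with elements `included` and `excluded` (both
#'   `dispatch_register`s) and `tally`, a named integer count of exclusion
#'   reasons.
#' @export
apply_exclusions <- function(register) {
  keep <- register$status == "completed_patient_confronted"
  included <- new_register(as.data.frame(register)[keep, , drop = FALSE])
  excluded <- new_register(as.data.frame(register)[!keep, , drop = FALSE])
  rownames(included) <- rownames(excluded) <- NULL
  tally <- table(factor(excluded$status, levels = excluded_statuses()))
  list(included = included, excluded = excluded,
       tally = stats::setNames(as.integer(tally), names(tally)))
}

#' Dichotomise a dispatch priority into urgent / non-urgent
#'
#' Priorities A and B (lights-and-siren responses) are urgent; C and D are
#' non-urgent. This is the dichotomy applied to the dispatcher's side of the
#' comparison.
#'
#' @param priority character vector of priorities (`"A"`-`"D"`).
#' @return character vector of `"urgent"` / `"non_urgent"`.
#' @export
dichotomise_emd <- function(priority) {
  map <- c(A = "urgent", B = "urgent", C = "non_urgent", D = "non_urgent")
  bad <- !priority %in% names(map)
  if (any(bad))
    stop_input("invalid dispatch priority: ", paste(unique(priority[bad]), collapse = ", "))
  unname(map[priority])
}

#' @export
print.dispatch_register <- function(x, ...) {
  cat(sprintf("<dispatch_register: %d records, %d categories>\n",
              nrow(x), length(unique(x$category[!is.na(x$category)]))))
  st <- table(x$status)
  cat("  status:", paste(sprintf("%s=%d", names(st), st), collapse = ", "), "\n")
  pr <- parse_report(x)
  if (nrow(pr)) cat(sprintf("  parse report: %d issue(s) on %d row(s)\n",
                            nrow(pr), length(unique(pr$row))))
  invisible(x)
}
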