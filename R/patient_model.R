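# Patient parameter catalogue, medication vocabulary and input validation.

#' Chapters of the demonstration rule base
#'
#' The four therapeutic areas covered by the engine, in canonical order.
#' @export
CHAPTERS <- c("glycemic_management", "dyslipidemia", "blood_pressure", "antiplatelet")

#' Load a parameter catalogue
#'
#' The catalogue declares every clinical parameter the engine may consume:
#' its value kind (numeric, boolean or categorical), unit, plausible range or
#' allowed values, and the chapters that require it. Plausible ranges are
#' configuration, not code constants: a different catalogue file changes what
#' counts as a valid record.
#'
#' @param path path to a YAML catalogue file.
#' @return an object of class `parameter_catalogue`.
#' @export
load_parameter_catalogue <- function(path) {
  if (!file.exists(path)) config_error(paste0("catalogue file not found: ", path))
  doc <- yaml::read_yaml(path)
  if (is.null(doc) || is.null(doc$parameters)) {
    config_error("catalogue file is empty or lacks a 'parameters' section")
  }
  cat_ <- structure(list(version = doc$version %||% "unversioned",
                         parameters = doc$parameters),
                    class = "parameter_catalogue")
  assert_catalogue(cat_)
  cat_
}

# Configuration errors (malformed catalogue) are distinct from clinical-value
# issues, which always travel inside a validation report.
assert_catalogue <- function(catalogue) {
  if (!inherits(catalogue, "parameter_catalogue")) {
    config_error("not a parameter_catalogue object")
  }
  pars <- catalogue$parameters
  nms <- vapply(pars, function(p) p$name %||% "", character(1))
  if (any(nms == "")) config_error("catalogue entry without a name")
  if (anyDuplicated(nms)) {
    config_error(paste0("duplicate catalogue parameter: ", nms[duplicated(nms)][1]))
  }
  for (p in pars) {
    kind <- p$kind %||% ""
    if (!kind %in% c("numeric", "boolean", "categorical")) {
      config_error(paste0("parameter '", p$name, "' has unknown kind '", kind, "'"))
    }
    if (kind == "numeric") {
      rng <- unlist(p$range)
      if (length(rng) != 2 || !is.numeric(rng) || rng[1] >= rng[2]) {
        config_error(paste0("parameter '", p$name, "' needs a numeric range with lower < upper"))
      }
    }
    if (kind == "categorical" && length(p$values) < 1) {
      config_error(paste0("parameter '", p$name, "' needs allowed values"))
    }
  }
  invisible(catalogue)
}

catalogue_entry <- function(catalogue, name) {
  for (p in catalogue$parameters) if (identical(p$name, name)) return(p)
  NULL
}

catalogue_names <- function(catalogue) {
  vapply(catalogue$parameters, function(p) p$name, character(1))
}

# Parameters required by at least one of the requested chapters.
required_parameters <- function(catalogue, chapters) {
  req <- vapply(catalogue$parameters, function(p) {
    any(unlist(p$chapters) %in% chapters)
  }, logical(1))
  catalogue_names(catalogue)[req]
}

#' Construct a patient record
#'
#' @param params named list of clinical parameter values (names must match the
#'   catalogue; booleans are `TRUE`/`FALSE`, categorical values are strings).
#' @param regimen current medication regimen: a character vector of substance
#'   names, or a list of `list(substance =, dose =)` entries. Substances are
#'   canonical lower-case medicinal-substance names; the engine is brand
#'   agnostic and never stores pharmaceutical product names.
#' @return an object of class `patient_record`.
#' @export
patient_record <- function(params = list(), regimen = list()) {
  if (is.character(regimen)) {
    regimen <- lapply(regimen, function(s) list(substance = s, dose = NULL))
  }
  regimen <- lapply(regimen, function(m) {
    list(substance = tolower(trimws(m$substance)), dose = m$dose %||% NULL)
  })
  structure(list(params = params, regimen = regimen), class = "patient_record")
}

new_validation_report <- function(issues) {
  structure(list(valid = nrow(issues) == 0L, issues = issues),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  if (x$valid) {
    cat("validation_report: valid (0 issues)\n")
  } else {
    cat("validation_report:", nrow(x$issues), "issue(s)\n")
    print(x$issues, row.names = FALSE)
  }
  invisible(x)
}

#' Validate a patient record against the parameter catalogue
#'
#' Validation is total: clinically impossible values never throw, they are
#' reported as issues. A parameter is `missing` only when a requested chapter
#' requires it; supplied values outside their catalogue range (or of the wrong
#' kind, e.g. mismatched units pushing a value out of range) are
#' `out_of_range`; names absent from the catalogue are `unrecognized`;
#' repeated substances in the regimen are `duplicate`.
#'
#' @param record a [patient_record()].
#' @param catalogue a [load_parameter_catalogue()] result.
#' @param chapters character vector of requested chapter ids.
#' @param class_table optional named character vector mapping substance ->
#'   medication class (usually `kb$substances`); when supplied, regimen
#'   substances absent from it are reported as `unrecognized`.
#' @return a `validation_report` with fields `valid` and `issues`.
#' @export
validate_patient_record <- function(record, catalogue, chapters = CHAPTERS,
                                    class_table = NULL) {
  assert_catalogue(catalogue)
  bad <- setdiff(chapters, CHAPTERS)
  if (length(bad)) config_error(paste0("unknown chapter(s): ", paste(bad, collapse = ", ")))
  issues <- issue_table()
  params <- record$params

  for (name in required_parameters(catalogue, chapters)) {
    v <- params[[name]]
    if (is.null(v) || (length(v) == 1L && is.na(v))) {
      issues <- add_issue(issues, name, "missing",
                          paste0("required parameter '", name, "' is missing"))
    }
  }

  for (name in names(params)) {
    v <- params[[name]]
    if (is.null(v) || (length(v) == 1L && is.na(v))) next
    entry <- catalogue_entry(catalogue, name)
    if (is.null(entry)) {
      issues <- add_issue(issues, name, "unrecognized",
                          paste0("parameter '", name, "' is not in the catalogue"))
      next
    }
    ok <- switch(entry$kind,
      numeric = is.numeric(v) && length(v) == 1L &&
        v >= unlist(entry$range)[1] && v <= unlist(entry$range)[2],
      boolean = is.logical(v) && length(v) == 1L,
      categorical = is.character(v) && length(v) == 1L && v %in% unlist(entry$values)
    )
    if (!ok) {
      issues <- add_issue(issues, name, "out_of_range",
                          paste0("parameter '", name, "' = ", format(v),
                                 " violates its catalogue ", entry$kind, " constraint"))
    }
  }

  subs <- vapply(record$regimen, function(m) m$substance, character(1))
  if (anyDuplicated(subs)) {
    for (s in unique(subs[duplicated(subs)])) {
      issues <- add_issue(issues, s, "duplicate",
                          paste0("substance '", s, "' appears more than once in the regimen"))
    }
  }
  if (!is.null(class_table)) {
    for (s in unique(subs)) {
      if (!s %in% names(class_table)) {
        issues <- add_issue(issues, s, "unrecognized",
                            paste0("substance '", s, "' is not a recognized medicinal substance"))
      }
    }
  }
  new_validation_report(issues)
}

#' Normalize a raw medication regimen against the substance -> class table
#'
#' Resolves each recognized substance to exactly one medication class, merges
#' duplicates (recording a `duplicate` issue) and reports unrecognized names
#' (including brand names, which are deliberately not in the vocabulary)
#' rather than silently dropping them.
#'
#' @param entries character vector of substance names, or a list of
#'   `list(substance =, dose =)` entries.
#' @param class_table named character vector: substance -> medication class.
#' @return list with `regimen` (list of medications with `substance`, `class`,
#'   `dose`) and `report` (a `validation_report`).
#' @export
normalize_regimen <- function(entries, class_table) {
  if (length(class_table) == 0) config_error("empty substance->class table")
  if (is.character(entries)) {
    entries <- lapply(entries, function(s) list(substance = s, dose = NULL))
  }
  issues <- issue_table()
  out <- list()
  seen <- character(0)
  for (e in entries) {
    s <- tolower(trimws(e$substance))
    if (!s %in% names(class_table)) {
      issues <- add_issue(issues, e$substance, "unrecognized",
                          paste0("'", e$substance, "' is not a recognized medicinal substance ",
                                 "(brand names are not accepted)"))
      next
    }
    if (s %in% seen) {
      issues <- add_issue(issues, s, "duplicate",
                          paste0("substance '", s, "' appears more than once; merged"))
      next
    }
    seen <- c(seen, s)
    out[[length(out) + 1L]] <- list(substance = s,
                                    class = unname(class_table[[s]]),
                                    dose = e$dose %||% NULL)
  }
  list(regimen = out, report = new_validation_report(issues))
}
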