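# Packaged demonstration artifacts: the demo knowledge base, the parameter
# catalogue, per-chapter generation constraints, and the bundled external
# expert-review dataset (response and adjudication counts from a two-phase
# review of a four-chapter T2D rule base, expanded to per-case records).

#' Path to a packaged example file
#' @param file file name under `inst/extdata`; lists the directory when empty.
#' @return a file path.
#' @export
cdsrules_example <- function(file = "") {
  if (!nzchar(file)) {
    return(dir(system.file("extdata", package = "cdsrules")))
  }
  path <- system.file("extdata", file, package = "cdsrules")
  if (!nzchar(path)) stop("no packaged example file '", file, "'", call. = FALSE)
  path
}

#' Load the demonstration knowledge base
#'
#' Illustrative guideline content for the four chapters (glycemic management,
#' dyslipidemia, blood pressure control, anti-platelet therapy) with all seven
#' rule types. Not for clinical use.
#'
#' @return a `knowledge_base`.
#' @export
load_demo_knowledge_base <- function() {
  load_knowledge_base(cdsrules_example("demo_kb.yaml"))
}

#' Load the demonstration parameter catalogue
#' @return a `parameter_catalogue`.
#' @export
load_demo_catalogue <- function() {
  load_parameter_catalogue(cdsrules_example("parameter_catalogue.yaml"))
}

#' Default generation constraints for a chapter of the demo knowledge base
#'
#' Regimen classes are the agents the chapter's rules reason about; comorbidity
#' flags draw at 50% prevalence (scenario coverage, not epidemiology) except
#' pregnancy (5%).
#'
#' @param chapter chapter id.
#' @param kb,catalogue demo knowledge base and catalogue (loaded when `NULL`).
#' @return a `generation_constraints` object.
#' @export
demo_generation_constraints <- function(chapter, kb = NULL, catalogue = NULL) {
  kb <- kb %||% load_demo_knowledge_base()
  catalogue <- catalogue %||% load_demo_catalogue()
  spec <- switch(chapter,
    glycemic_management = list(
      classes = c("biguanide", "SGLT2i", "GLP-1RA", "DPP-4i", "sulfonylurea", "insulin"),
      max = 3),
    dyslipidemia = list(classes = c("statin", "ezetimibe"), max = 2),
    blood_pressure = list(classes = c("ACEi_ARB", "CCB", "thiazide"), max = 3),
    antiplatelet = list(classes = c("antiplatelet"), max = 1),
    config_error(paste0("unknown chapter: ", chapter)))
  generation_constraints(catalogue, chapter, kb,
                         classes = spec$classes,
                         regimen_min = 0, regimen_max = spec$max,
                         prevalence = c(pregnancy = 0.05))
}

#' Bundled external expert-review dataset
#'
#' Expands the packaged response and adjudication count tables of a two-phase
#' external expert review (18 reviewers, 1000 single-chapter cases, 950
#' predicted positive and 50 predicted negative) into per-case records:
#' phase-1 responses, phase-2 adjudication transitions, and the
#' experimenter-side polarity labels. Case ids are synthetic; counts are the
#' dataset's substance.
#'
#' @return list with data frames `responses` (case_id, reviewer_id, phase,
#'   answer, comment), `transitions` (case_id, from, to, note) and
#'   `polarities` (case_id, chapter, polarity).
#' @export
example_validation_study <- function() {
  counts <- utils::read.csv(cdsrules_example("external_review_phase1_counts.csv"),
                            stringsAsFactors = FALSE)
  trans <- utils::read.csv(cdsrules_example("external_review_transitions.csv"),
                           stringsAsFactors = FALSE)
  responses <- list()
  polarities <- list()
  idx <- stats::setNames(rep(0L, length(CHAPTERS)), CHAPTERS)
  for (i in seq_len(nrow(counts))) {
    row <- counts[i, ]
    if (row$count == 0) next
    ids <- sprintf("%s-%04d", toupper(substr(row$chapter, 1, 3)),
                   idx[[row$chapter]] + seq_len(row$count))
    idx[[row$chapter]] <- idx[[row$chapter]] + row$count
    responses[[length(responses) + 1L]] <- data.frame(
      case_id = ids,
      reviewer_id = paste0("R-", toupper(substr(row$chapter, 1, 3))),
      phase = 1L, answer = row$answer,
      comment = if (row$answer %in% c("no", "not_sure")) "see interview notes" else "",
      stringsAsFactors = FALSE)
    polarities[[length(polarities) + 1L]] <- data.frame(
      case_id = ids, chapter = row$chapter, polarity = row$polarity,
      stringsAsFactors = FALSE)
  }
  responses <- do.call(rbind, responses)
  polarities <- do.call(rbind, polarities)

  # transitions draw from the PP cases of the matching phase-1 answer, in id
  # order; a case receives at most one transition
  transitions <- list()
  used <- character(0)
  for (i in seq_len(nrow(trans))) {
    row <- trans[i, ]
    if (row$count == 0) next
    pool <- responses$case_id[
      responses$answer == row$from &
        responses$case_id %in% polarities$case_id[polarities$chapter == row$chapter &
                                                    polarities$polarity == "PP"] &
        !responses$case_id %in% used]
    stopifnot(length(pool) >= row$count)
    take <- pool[seq_len(row$count)]
    used <- c(used, take)
    transitions[[length(transitions) + 1L]] <- data.frame(
      case_id = take, from = row$from, to = row$to,
      note = "phase-2 interview", stringsAsFactors = FALSE)
  }
  transitions <- do.call(rbind, transitions)
  list(responses = responses, transitions = transitions, polarities = polarities)
}
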