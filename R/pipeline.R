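# End-to-end study pipeline: generate -> evaluate -> mutate -> assign, plus
# report rendering. Every written artifact embeds the tool version, knowledge
# base version and root seed; re-running with the same configuration
# reproduces byte-identical cases and assignment.

#' Build a study configuration
#'
#' @param kb_path,catalogue_path paths to the knowledge base and catalogue.
#' @param total total number of test cases.
#' @param shares named chapter shares summing to 1.
#' @param pn_fraction fraction of cases converted to predicted negatives.
#' @param reviewers data frame `reviewer_id`, `chapter`, `quota`; when `NULL`,
#'   one reviewer per chapter with a quota equal to the chapter's case count.
#' @param seed root seed; all stage streams are derived from it.
#' @param out_dir output directory for the study bundle.
#' @param base_counts,buffer optional fixed per-chapter allocation (see
#'   [allocate_study_cases()]).
#' @return a `study_config` list.
#' @export
study_config <- function(kb_path, catalogue_path, total = 100,
                         shares = c(glycemic_management = 0.3, dyslipidemia = 0.3,
                                    blood_pressure = 0.3, antiplatelet = 0.1),
                         pn_fraction = 0.05, reviewers = NULL, seed = 1L,
                         out_dir = tempfile("study_"),
                         base_counts = NULL, buffer = NULL) {
  structure(list(kb_path = kb_path, catalogue_path = catalogue_path,
                 total = total, shares = shares, pn_fraction = pn_fraction,
                 reviewers = reviewers, seed = as.integer(seed),
                 out_dir = out_dir, base_counts = base_counts, buffer = buffer),
            class = "study_config")
}

pipeline_stage_error <- function(stage, e) {
  stop(structure(class = c("cdsrules_stage_error", "error", "condition"),
                 list(message = paste0("pipeline stage '", stage, "' failed: ",
                                       conditionMessage(e)),
                      call = NULL, stage = stage, parent = e)))
}

#' Run the full validation-study pipeline
#'
#' Loads and verifies the knowledge base, allocates cases over chapters,
#' generates constrained random inputs, evaluates them into predicted-positive
#' cases, converts the allocated slots into predicted negatives, assigns cases
#' to reviewers and writes the study bundle: the experimenter-side case file
#' (with polarity), the blinded reviewer-facing case file, the assignment
#' table, an empty response template and the configuration echo.
#'
#' @param config a [study_config()].
#' @return invisibly, a list with `cases`, `allocation`, `assignment`,
#'   `baseline`, `meta` and the output paths.
#' @export
run_study_pipeline <- function(config) {
  stopifnot(inherits(config, "study_config"))
  if (!file.exists(config$kb_path)) {
    pipeline_stage_error("startup", simpleError(paste0("knowledge base path not found: ",
                                                       config$kb_path)))
  }
  if (!file.exists(config$catalogue_path)) {
    pipeline_stage_error("startup", simpleError(paste0("catalogue path not found: ",
                                                       config$catalogue_path)))
  }
  kb <- tryCatch(load_knowledge_base(config$kb_path),
                 error = function(e) pipeline_stage_error("load_kb", e))
  catalogue <- tryCatch(load_parameter_catalogue(config$catalogue_path),
                        error = function(e) pipeline_stage_error("load_catalogue", e))
  kb_issues <- validate_knowledge_base(kb, catalogue)
  if (nrow(kb_issues) > 0) {
    pipeline_stage_error("validate_kb", simpleError(
      paste0(nrow(kb_issues), " knowledge-base issue(s), first: ",
             kb_issues$message[1])))
  }
  alloc <- tryCatch(
    allocate_study_cases(config$total, config$shares, config$pn_fraction,
                         config$seed, config$base_counts, config$buffer),
    error = function(e) pipeline_stage_error("allocate", e))

  cases <- list()
  for (i in seq_len(nrow(alloc$chapters))) {
    ch <- alloc$chapters$chapter[i]
    n <- alloc$chapters$n_cases[i]
    if (n == 0) next
    cons <- demo_generation_constraints(ch, kb, catalogue)
    inputs <- tryCatch(
      generate_case_inputs(cons, n, derive_seed(config$seed, paste0("casegen-", ch))),
      error = function(e) pipeline_stage_error("generate", e))
    ch_cases <- tryCatch(build_test_cases(inputs, kb, catalogue, ch),
                         error = function(e) pipeline_stage_error("evaluate", e))
    pn_at <- alloc$pn_positions[[ch]]
    for (j in seq_along(pn_at)) {
      pos <- pn_at[j]
      strategy <- if (j %% 2 == 1) "swap_with_other" else "alter_recommendation"
      ch_cases[[pos]] <- tryCatch(
        make_predicted_negative(ch_cases[[pos]], ch_cases, strategy, kb, catalogue,
                                derive_seed(config$seed, paste0("pn-", ch, "-", pos))),
        error = function(e) pipeline_stage_error("mutate_pn", e))
    }
    cases <- c(cases, ch_cases)
  }

  reviewers <- config$reviewers
  if (is.null(reviewers)) {
    reviewers <- data.frame(
      reviewer_id = paste0("R-", toupper(substr(alloc$chapters$chapter, 1, 3))),
      chapter = alloc$chapters$chapter,
      quota = alloc$chapters$n_cases, stringsAsFactors = FALSE)
  }
  assignment <- tryCatch(assign_cases_to_reviewers(cases, reviewers, config$seed),
                         error = function(e) pipeline_stage_error("assign", e))
  baseline <- baseline_snapshot(cases, kb)

  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  meta <- list(tool = "cdsrules", tool_version = as.character(utils::packageVersion("cdsrules")),
               kb_version = kb$version, seed = config$seed)
  paths <- list(
    cases_full = file.path(config$out_dir, "cases_full.jsonl"),
    cases_reviewer = file.path(config$out_dir, "cases_reviewer.jsonl"),
    assignment = file.path(config$out_dir, "assignment.csv"),
    response_template = file.path(config$out_dir, "response_template.csv"),
    config = file.path(config$out_dir, "study_config.json"))

  full_lines <- vapply(cases, function(cs) {
    canonical_json(list(meta = meta, case_id = cs$id, chapter = cs$chapter,
                        polarity = cs$polarity,
                        mutation = cs$mutation,
                        input = list(params = cs$input$params,
                                     regimen = lapply(cs$input$regimen, function(m) m$substance)),
                        prediction = jsonlite::fromJSON(serialize_prediction(cs$prediction),
                                                        simplifyVector = FALSE)))
  }, character(1))
  writeLines(full_lines, paths$cases_full)
  export_reviewer_cases(cases, assignment, paths$cases_reviewer)

  meta_line <- paste0("# cdsrules ", meta$tool_version, " kb ", meta$kb_version,
                      " seed ", meta$seed)
  writeLines(c(meta_line, "case_id,chapter,reviewer_id,position",
               sprintf("%s,%s,%s,%d", assignment$case_id, assignment$chapter,
                       assignment$reviewer_id, assignment$position)),
             paths$assignment)
  writeLines(c(meta_line, "case_id,reviewer_id,phase,answer,comment",
               sprintf("%s,%s,1,,", assignment$case_id, assignment$reviewer_id)),
             paths$response_template)
  jsonlite::write_json(c(meta, list(total = config$total,
                                    shares = as.list(config$shares),
                                    pn_fraction = config$pn_fraction)),
                       paths$config, auto_unbox = TRUE)

  invisible(list(cases = cases, allocation = alloc, assignment = assignment,
                 baseline = baseline, meta = meta, paths = paths))
}

fmt_pct <- function(x) ifelse(is.na(x), "n/a", sprintf("%.1f", 100 * x))

#' Render study metrics as a Markdown report
#'
#' Tables mirror the study bookkeeping: predicted-positive counts after final
#' adjudication, predicted-negative outcomes, and the precision row per
#' chapter and overall. Percentages are formatted to one decimal; an undefined
#' precision (no yes/no responses) renders as `n/a`, never as 0 or 100.
#'
#' @param metrics a `study_metrics` object.
#' @return character vector of report lines.
#' @export
render_report <- function(metrics) {
  pc <- metrics$per_chapter
  ov <- metrics$overall
  lines <- c("# Validation study report", "")
  if (is.null(pc) || nrow(pc) == 0) {
    lines <- c(lines, "No chapter data.", "",
               paste0("Overall precision: ", fmt_pct(ov$precision)))
    return(lines)
  }
  tab <- rbind(pc, ov)
  lines <- c(lines,
    "## Final adjudicated responses (predicted-positive cases)", "",
    "| Chapter | PP | Yes (TP) | No (FP) | Not sure | Missing | Precision (%) |",
    "|---|---|---|---|---|---|---|",
    sprintf("| %s | %d | %d | %d | %d | %d | %s |",
            tab$chapter, tab$pp, tab$tp, tab$fp, tab$not_sure, tab$missing,
            fmt_pct(tab$precision)),
    "",
    "## Predicted-negative cases", "",
    "| Chapter | PN | Accepted (reviewer error) | Rejected | Not sure | Error rate (%) |",
    "|---|---|---|---|---|---|",
    sprintf("| %s | %d | %d | %d | %d | %s |",
            tab$chapter, tab$pn, tab$tn, tab$pn_rejected, tab$pn_not_sure,
            fmt_pct(tab$reviewer_error)),
    "")
  lines
}
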