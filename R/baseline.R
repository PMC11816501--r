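# Baseline regression snapshots: freeze the engine's predictions for a case
# suite and diff later builds against them, so recommendations never change
# unless the change was intended and reviewed.

#' Snapshot a test-case suite as a regression baseline
#'
#' @param cases list of `test_case`s (predictions as produced by the engine).
#' @param kb the `knowledge_base` the predictions came from.
#' @return a `baseline_suite`: kb version, per-case input and prediction
#'   digests, and the stored inputs needed to re-evaluate.
#' @export
baseline_snapshot <- function(cases, kb) {
  entries <- data.frame(
    id = vapply(cases, function(c) c$id, character(1)),
    chapter = vapply(cases, function(c) c$chapter, character(1)),
    input_digest = vapply(cases, function(c) fnv1a32(canonical_json(c$input$params)),
                          character(1)),
    prediction_digest = vapply(cases, function(c) prediction_digest(c$prediction),
                               character(1)),
    stringsAsFactors = FALSE)
  inputs <- stats::setNames(lapply(cases, function(c) c$input),
                            entries$id)
  chapters <- stats::setNames(entries$chapter, entries$id)
  structure(list(kb_version = kb$version, entries = entries,
                 inputs = inputs, case_chapters = chapters),
            class = "baseline_suite")
}

#' Compare current engine behaviour against a baseline suite
#'
#' Re-evaluates every stored input with the current knowledge base and lists
#' the cases whose prediction digest changed, with a field-level diff. An
#' empty diff means no behavioural change.
#'
#' @param suite a [baseline_snapshot()] result.
#' @param kb,catalogue current knowledge base and catalogue.
#' @param cases optional list of current `test_case`s; cases absent from the
#'   baseline are reported as new.
#' @return a `baseline_diff`: data frame `changed` (id, chapter, diffs) plus
#'   character vectors `new_cases` and `removed_cases`; `identical` is TRUE
#'   when all three are empty.
#' @export
compare_to_baseline <- function(suite, kb, catalogue, cases = NULL) {
  stopifnot(inherits(suite, "baseline_suite"))
  if (is.null(suite$kb_version) || !nzchar(suite$kb_version)) {
    warning("baseline suite has no knowledge-base version; comparison proceeds")
  }
  changed <- data.frame(id = character(), chapter = character(),
                        diffs = character(), stringsAsFactors = FALSE)
  for (i in seq_len(nrow(suite$entries))) {
    id <- suite$entries$id[i]
    ch <- suite$entries$chapter[i]
    rs <- evaluate_record(evaluation_request(suite$inputs[[id]], ch), kb, catalogue)
    new_json <- serialize_prediction(rs)
    if (!identical(fnv1a32(new_json), suite$entries$prediction_digest[i])) {
      changed <- rbind(changed, data.frame(
        id = id, chapter = ch,
        diffs = paste0("prediction digest ", suite$entries$prediction_digest[i],
                       " -> ", fnv1a32(new_json)),
        stringsAsFactors = FALSE))
    }
  }
  new_cases <- character(0)
  removed_cases <- character(0)
  if (!is.null(cases)) {
    cur_ids <- vapply(cases, function(c) c$id, character(1))
    new_cases <- setdiff(cur_ids, suite$entries$id)
    removed_cases <- setdiff(suite$entries$id, cur_ids)
  }
  structure(list(changed = changed, new_cases = new_cases,
                 removed_cases = removed_cases,
                 identical = nrow(changed) == 0 && length(new_cases) == 0 &&
                   length(removed_cases) == 0),
            class = "baseline_diff")
}

#' Field-level diff between two predictions
#'
#' @param old_rs,new_rs two `recommendation_set`s.
#' @return character vector of JSON paths whose values differ.
#' @export
prediction_diff <- function(old_rs, new_rs) {
  a <- jsonlite::fromJSON(serialize_prediction(old_rs), simplifyVector = FALSE)
  b <- jsonlite::fromJSON(serialize_prediction(new_rs), simplifyVector = FALSE)
  diff_paths(a, b, "")
}

diff_paths <- function(a, b, path) {
  if (is.list(a) && is.list(b)) {
    out <- character(0)
    if (is.null(names(a)) && is.null(names(b))) {
      for (k in seq_len(max(length(a), length(b)))) {
        ka <- if (k <= length(a)) a[[k]] else NULL
        kb_ <- if (k <= length(b)) b[[k]] else NULL
        sub <- paste0(path, "/", k)
        if (is.null(ka) != is.null(kb_)) out <- c(out, sub)
        else if (!is.null(ka)) out <- c(out, diff_paths(ka, kb_, sub))
      }
    } else {
      for (k in union(names(a), names(b))) {
        ka <- a[[k]]
        kb_ <- b[[k]]
        sub <- paste0(path, "/", k)
        if (is.null(ka) != is.null(kb_)) out <- c(out, sub)
        else if (!is.null(ka)) out <- c(out, diff_paths(ka, kb_, sub))
      }
    }
    return(out)
  }
  if (!identical(a, b)) return(path)
  character(0)
}
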