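# Deterministic layered evaluation of a patient record against a knowledge
# base. Pipeline order is fixed: main -> safety -> inter_chapter -> master ->
# recommendation-type / treatment-aim annotation -> renal dose adjustment ->
# feedback. Master rules run after the other modifying layers because they
# may overrule any earlier effect. Within a layer, rules apply in
# (priority, id) order and later rules see earlier rules' effects.

#' Construct an evaluation request
#'
#' @param record a [patient_record()].
#' @param chapters non-empty subset of [CHAPTERS].
#' @param kb_version optional version pin; evaluation aborts with a
#'   configuration error when it does not match the knowledge base.
#' @return an `evaluation_request`.
#' @export
evaluation_request <- function(record, chapters = CHAPTERS, kb_version = NULL) {
  if (length(chapters) == 0) config_error("chapters must be non-empty")
  bad <- setdiff(chapters, CHAPTERS)
  if (length(bad)) config_error(paste0("unknown chapter(s): ", paste(bad, collapse = ", ")))
  structure(list(record = record,
                 chapters = CHAPTERS[CHAPTERS %in% chapters],
                 kb_version = kb_version),
            class = "evaluation_request")
}

new_rec <- function(chapter, action, class = NULL, substance = NULL,
                    replaces = NULL, references = character(0),
                    rule_ids = character(0)) {
  list(chapter = chapter, action = action, class = class, substance = substance,
       replaces = replaces, rec_type = NULL, aim = NULL,
       dose_guidance = NULL, renal_flag = NULL,
       references = references, safety_annotations = character(0),
       rule_ids = rule_ids)
}

rec_class <- function(rec, kb) {
  if (!is.null(rec$class)) return(rec$class)
  if (!is.null(rec$substance)) return(substance_class(kb, rec$substance))
  NULL
}

# Non-null fields of a recommendation, in a fixed order, for canonical JSON.
clean_rec <- function(rec) {
  keep <- c("chapter", "action", "class", "substance", "replaces", "rec_type",
            "aim", "dose_guidance", "renal_flag", "references",
            "safety_annotations", "rule_ids")
  out <- list()
  for (k in keep) {
    v <- rec[[k]]
    if (is.null(v) || (is.character(v) && length(v) == 0)) next
    out[[k]] <- v
  }
  out
}

new_recset <- function(chapters, kb_version) {
  structure(list(
    chapters = stats::setNames(vector("list", length(chapters)), chapters),
    hints = data.frame(chapter = character(), rule_id = character(),
                       hint = character(), stringsAsFactors = FALSE),
    notes = data.frame(chapter = character(), rule_id = character(),
                       note = character(), stringsAsFactors = FALSE),
    audit = list(),
    kb_version = kb_version
  ), class = "recommendation_set")
}

audit_add <- function(rs, layer, rule_id, effect, detail = "") {
  rs$audit[[length(rs$audit) + 1L]] <-
    c(layer, rule_id %||% NA_character_, effect, detail)
  rs
}

#' Audit trail of an evaluation as a data frame
#' @param rs a `recommendation_set`.
#' @return data frame with columns layer, rule_id, effect, detail (append-only,
#'   in pipeline execution order).
#' @export
audit_trail <- function(rs) {
  if (length(rs$audit) == 0) {
    return(data.frame(layer = character(), rule_id = character(),
                      effect = character(), detail = character(),
                      stringsAsFactors = FALSE))
  }
  m <- do.call(rbind, rs$audit)
  data.frame(layer = m[, 1], rule_id = m[, 2], effect = m[, 3], detail = m[, 4],
             stringsAsFactors = FALSE)
}

all_recs <- function(rs) unlist(rs$chapters, recursive = FALSE, use.names = FALSE)

recommended_classes <- function(rs, kb) {
  cls <- unlist(lapply(all_recs(rs), function(r) {
    if (r$action %in% c("no_change", "discontinue")) return(NULL)
    rec_class(r, kb)
  }))
  unique(cls %||% character(0))
}

#' Canonical serialization of the clinical content of a recommendation set
#'
#' Covers the per-chapter recommendations and feedback hints (the content a
#' reviewer judges), not the audit trail. Identical input and knowledge base
#' yield a byte-identical string; this is the basis of prediction digests and
#' baseline regression comparison.
#'
#' @param rs a `recommendation_set`.
#' @return a JSON string.
#' @export
serialize_prediction <- function(rs) {
  canonical_json(list(
    chapters = lapply(rs$chapters, function(recs) lapply(recs, clean_rec)),
    hints = rs$hints,
    notes = rs$notes
  ))
}

#' Compact digest of a recommendation set's clinical content
#' @param rs a `recommendation_set`.
#' @return an 8-hex-character string.
#' @export
prediction_digest <- function(rs) fnv1a32(serialize_prediction(rs))

# --- layers -----------------------------------------------------------------

run_main_layer <- function(rs, ctx, kb) {
  for (ch in names(rs$chapters)) {
    fired <- FALSE
    recs <- list()
    for (r in kb_rules(kb, "main", ch)) {
      if (!eval_condition(r$condition, ctx)) next
      fired <- TRUE
      rs <- audit_add(rs, "main", r$id, "fired", paste0("cluster ", r$cluster))
      for (a in r$actions %||% list()) {
        recs[[length(recs) + 1L]] <- new_rec(
          chapter = ch, action = a$action,
          class = a$class %||% a$with_class %||% NULL,
          substance = a$substance %||% NULL,
          replaces = if (identical(a$action, "replace")) a$class else NULL,
          references = as.character(unlist(r$references)),
          rule_ids = r$id)
        if (identical(a$action, "replace")) {
          # a replace action names the replaced agent in `class` and the
          # replacing agent in `with_class`
          recs[[length(recs)]]$class <- a$with_class
          recs[[length(recs)]]$replaces <- a$class
        }
      }
    }
    if (!fired) {
      recs[[1L]] <- new_rec(ch, "no_change", references = "no applicable main rule",
                            rule_ids = character(0))
      rs <- audit_add(rs, "main", NA_character_, "fired",
                      paste0("default no_change for chapter ", ch))
    }
    rs$chapters[[ch]] <- recs
  }
  rs
}

rec_matches_target <- function(rec, effect, kb) {
  if (!is.null(effect$substance)) {
    return(identical(rec$substance, effect$substance))
  }
  if (!is.null(effect$class)) {
    cl <- rec_class(rec, kb)
    return(!is.null(cl) && identical(cl, effect$class))
  }
  TRUE # untargeted effect applies to every recommendation
}

apply_effects <- function(rs, rule, layer, ctx, kb) {
  for (eff in rule$effects %||% list()) {
    kind <- eff$effect %||% ""
    if (kind == "remove") {
      for (ch in names(rs$chapters)) {
        keep <- list()
        for (rec in rs$chapters[[ch]]) {
          if (rec$action != "no_change" && rec_matches_target(rec, eff, kb)) {
            rs <- audit_add(rs, layer, rule$id,
                            if (layer == "master") "overruled" else "removed",
                            paste0(rec$action, " ", rec$class %||% rec$substance))
            rs$notes <- rbind(rs$notes, data.frame(
              chapter = ch, rule_id = rule$id,
              note = eff$note %||% paste0("recommendation for ",
                                          eff$class %||% eff$substance,
                                          " withdrawn by rule ", rule$id),
              stringsAsFactors = FALSE))
          } else {
            keep[[length(keep) + 1L]] <- rec
          }
        }
        rs$chapters[[ch]] <- keep
      }
    } else if (kind == "replace") {
      for (ch in names(rs$chapters)) {
        for (i in seq_along(rs$chapters[[ch]])) {
          rec <- rs$chapters[[ch]][[i]]
          if (rec$action != "no_change" && rec_matches_target(rec, eff, kb)) {
            old <- rec$class %||% substance_class(kb, rec$substance)
            rec$action <- "replace"
            rec$replaces <- old
            rec$class <- eff$with_class
            rec$substance <- NULL
            rec$safety_annotations <- c(rec$safety_annotations,
                                        eff$note %||% paste0("substituted by rule ", rule$id))
            rec$rule_ids <- c(rec$rule_ids, rule$id)
            rs$chapters[[ch]][[i]] <- rec
            rs <- audit_add(rs, layer, rule$id,
                            if (layer == "master") "overruled" else "modified",
                            paste0(old, " -> ", eff$with_class))
          }
        }
      }
    } else if (kind == "annotate") {
      for (ch in names(rs$chapters)) {
        for (i in seq_along(rs$chapters[[ch]])) {
          rec <- rs$chapters[[ch]][[i]]
          if (rec_matches_target(rec, eff, kb)) {
            rec$safety_annotations <- c(rec$safety_annotations, eff$note %||% "")
            rec$rule_ids <- unique(c(rec$rule_ids, rule$id))
            rs$chapters[[ch]][[i]] <- rec
            rs <- audit_add(rs, layer, rule$id, "annotated",
                            paste0(rec$action, " ", rec$class %||% rec$substance %||% ""))
          }
        }
      }
    } else if (kind == "recommend") {
      ch <- rule$chapter %||% names(rs$chapters)[1]
      if (ch %in% names(rs$chapters)) {
        rs$chapters[[ch]][[length(rs$chapters[[ch]]) + 1L]] <- new_rec(
          chapter = ch, action = eff$action %||% "add_class",
          class = eff$class %||% NULL, substance = eff$substance %||% NULL,
          references = as.character(unlist(rule$references)), rule_ids = rule$id)
        rs <- audit_add(rs, layer, rule$id,
                        if (layer == "master") "overruled" else "modified",
                        paste0("added ", eff$action %||% "add_class", " ",
                               eff$class %||% eff$substance))
      }
    } else if (kind == "note") {
      rs$notes <- rbind(rs$notes, data.frame(
        chapter = rule$chapter %||% "all", rule_id = rule$id,
        note = eff$note %||% "", stringsAsFactors = FALSE))
      rs <- audit_add(rs, layer, rule$id, "annotated", "note added")
    } else {
      config_error(paste0("rule '", rule$id, "': unknown effect '", kind, "'"))
    }
  }
  rs
}

#' Apply one modifying rule layer to a draft recommendation set
#'
#' Safety and inter-chapter rules may remove, replace or annotate draft
#' recommendations (drug-drug interactions, contraindications, cross-chapter
#' constraints); master rules run with the highest precedence and may overrule
#' any earlier effect, including re-issuing a removed recommendation. The
#' application is a pure function of (draft, record, kb); every effect is
#' audited.
#'
#' @param draft a `recommendation_set` produced by earlier layers.
#' @param layer one of `"safety"`, `"inter_chapter"`, `"master"`.
#' @param record the `patient_record` under evaluation (regimen already
#'   normalized, or normalizable against `kb$substances`).
#' @param kb the `knowledge_base`.
#' @return the modified `recommendation_set`.
#' @export
apply_rule_layer <- function(draft, layer, record, kb) {
  stopifnot(layer %in% c("safety", "inter_chapter", "master"))
  ctx <- engine_context(record, kb)
  rules <- kb_rules(kb, layer)
  for (r in rules) {
    # safety rules are chapter-scoped; skip those whose chapter is not in play
    if (layer == "safety" && !is.null(r$chapter) &&
        !r$chapter %in% names(draft$chapters)) next
    if (layer != "safety" && !is.null(r$chapter) &&
        !r$chapter %in% names(draft$chapters)) next
    ctx$recommended_classes <- recommended_classes(draft, kb)
    if (!eval_condition(r$condition, ctx)) next
    if (layer == "safety" && !is.null(r$chapter)) {
      # restrict effects to the rule's own chapter
      sub <- draft
      sub$chapters <- draft$chapters[r$chapter]
      sub <- apply_effects(sub, r, layer, ctx, kb)
      draft$chapters[r$chapter] <- sub$chapters
      draft$notes <- sub$notes
      draft$audit <- sub$audit
    } else {
      draft <- apply_effects(draft, r, layer, ctx, kb)
    }
  }
  draft
}

#' Annotate drug-change recommendations with type and aim
#'
#' Recommendation-type rules decide whether a recommendation is made "by
#' addition" (a new agent on top of the retained regimen) or "by replacement";
#' treatment-aim rules mark whether an agent is suggested for cardiorenal
#' protection or for glycemic control. Annotation never alters the drug
#' content of a recommendation, and annotating twice equals annotating once.
#' An add/replace recommendation matched by zero recommendation-type rules
#' produces a completeness warning in the audit trail, not an error.
#'
#' @inheritParams apply_rule_layer
#' @param draft a `recommendation_set` with finalized drug changes.
#' @return the annotated `recommendation_set`.
#' @export
annotate_recommendations <- function(draft, record, kb) {
  ctx <- engine_context(record, kb)
  type_rules <- kb_rules(kb, "recommendation_type")
  aim_rules <- kb_rules(kb, "treatment_aim")
  for (ch in names(draft$chapters)) {
    for (i in seq_along(draft$chapters[[ch]])) {
      rec <- draft$chapters[[ch]][[i]]
      if (!rec$action %in% c("add_class", "add_substance", "replace")) next
      ctx$rec <- list(action = rec$action, class = rec_class(rec, kb),
                      substance = rec$substance, chapter = ch)
      matched <- FALSE
      for (r in type_rules) {
        if (eval_condition(r$condition, ctx)) {
          rec$rec_type <- r$set$value
          draft <- audit_add(draft, "recommendation_type", r$id, "annotated",
                             paste0(rec$class %||% rec$substance, " -> ", r$set$value))
          matched <- TRUE
          break
        }
      }
      if (!matched) {
        draft <- audit_add(draft, "recommendation_type", NA_character_, "annotated",
                           paste0("warning: no recommendation_type rule matched ",
                                  rec$action, " ", rec$class %||% rec$substance))
      }
      for (r in aim_rules) {
        if (eval_condition(r$condition, ctx)) {
          rec$aim <- r$set$value
          draft <- audit_add(draft, "treatment_aim", r$id, "annotated",
                             paste0(rec$class %||% rec$substance, " -> ", r$set$value))
          break
        }
      }
      draft$chapters[[ch]][[i]] <- rec
    }
  }
  draft
}

#' Attach renal dose guidance from the knowledge base dose table
#'
#' Each recommended agent with a dose-table entry receives the guidance of the
#' eGFR band containing the record's eGFR; an eGFR above all bands maps to the
#' standard dose; a missing eGFR withholds guidance and flags the
#' recommendation as "renal dosing not assessed".
#'
#' @inheritParams apply_rule_layer
#' @param draft a `recommendation_set`.
#' @return the `recommendation_set` with dose guidance filled in.
#' @export
adjust_renal_dosing <- function(draft, record, kb) {
  egfr <- record$params[["egfr"]]
  have_egfr <- !is.null(egfr) && !is.na(egfr)
  for (ch in names(draft$chapters)) {
    for (i in seq_along(draft$chapters[[ch]])) {
      rec <- draft$chapters[[ch]][[i]]
      if (!rec$action %in% c("add_class", "add_substance", "replace",
                             "continue", "titrate")) next
      entry <- dose_table_entry(kb, rec$substance, rec_class(rec, kb))
      if (is.null(entry)) next
      if (!have_egfr) {
        rec$renal_flag <- "renal dosing not assessed (eGFR missing)"
        draft <- audit_add(draft, "dose", entry$agent, "annotated",
                           "eGFR missing; guidance withheld")
      } else {
        band <- match_dose_band(entry, egfr)
        rec$dose_guidance <- band$guidance
        rec$renal_flag <- if (isTRUE(band$adjusted)) "renal dose adjustment" else "standard"
        draft <- audit_add(draft, "dose", entry$agent, "annotated",
                           paste0("eGFR ", egfr, " -> ", band$guidance))
      }
      draft$chapters[[ch]][[i]] <- rec
    }
  }
  draft
}

dose_table_entry <- function(kb, substance, class) {
  for (entry in kb$dose_table) {
    if (!is.null(substance) && identical(entry$agent, substance)) return(entry)
  }
  for (entry in kb$dose_table) {
    if (!is.null(class) && identical(entry$agent, class)) return(entry)
  }
  NULL
}

match_dose_band <- function(entry, egfr) {
  for (b in entry$bands %||% list()) {
    lo <- as.numeric(b$min %||% 0)
    hi <- as.numeric(b$max %||% Inf)
    if (egfr >= lo && egfr < hi) {
      return(list(guidance = b$guidance, adjusted = isTRUE(b$adjusted)))
    }
  }
  list(guidance = "standard dose", adjusted = FALSE)
}

run_feedback_layer <- function(rs, ctx, kb) {
  for (ch in names(rs$chapters)) {
    for (r in kb_rules(kb, "feedback", ch)) {
      if (!eval_condition(r$condition, ctx)) next
      rs$hints <- rbind(rs$hints, data.frame(chapter = ch, rule_id = r$id,
                                             hint = r$hint %||% "",
                                             stringsAsFactors = FALSE))
      rs <- audit_add(rs, "feedback", r$id, "fired", r$hint %||% "")
    }
  }
  rs
}

engine_context <- function(record, kb) {
  regimen <- record$regimen
  # fill classes if the record has not been normalized yet
  regimen <- lapply(regimen, function(m) {
    if (is.null(m$class)) m$class <- substance_class(kb, m$substance) %||% ""
    m
  })
  record_context(record$params, regimen)
}

#' Evaluate a patient record against the knowledge base
#'
#' Runs the full deterministic pipeline and returns referenced, annotated
#' recommendations with a complete audit trail. A chapter in which no main
#' rule fires yields an explicit `no_change` recommendation rather than
#' silence, so single-chapter test cases always carry a label. Feedback rules
#' only ever produce hints; they cannot alter drug recommendations.
#'
#' @param request an [evaluation_request()] (or a `patient_record`, in which
#'   case all chapters are evaluated).
#' @param kb a `knowledge_base`.
#' @param catalogue a `parameter_catalogue` used to validate the record.
#' @param validate set `FALSE` to skip record validation (for callers that
#'   already validated, e.g. bulk test-case construction).
#' @param master_hooks optional named list of functions
#'   `function(draft, record, kb)` registered as procedural master overrides;
#'   applied after declarative master rules, in name order, with audit
#'   entries.
#' @return a `recommendation_set`.
#' @export
evaluate_record <- function(request, kb, catalogue, validate = TRUE,
                            master_hooks = NULL) {
  if (inherits(request, "patient_record")) {
    request <- evaluation_request(request)
  }
  stopifnot(inherits(request, "evaluation_request"))
  if (!is.null(request$kb_version) && !identical(request$kb_version, kb$version)) {
    config_error(paste0("knowledge base version mismatch: request pins '",
                        request$kb_version, "', loaded '", kb$version, "'"))
  }
  record <- request$record
  norm <- normalize_regimen(record$regimen, kb$substances)
  if (validate) {
    report <- validate_patient_record(record, catalogue, request$chapters,
                                      class_table = kb$substances)
    if (!report$valid) {
      cond <- structure(
        class = c("cdsrules_invalid_record", "error", "condition"),
        list(message = paste0("record failed validation with ",
                              nrow(report$issues), " issue(s): ",
                              paste(report$issues$message, collapse = "; ")),
             call = NULL, report = report))
      stop(cond)
    }
  }
  record$regimen <- norm$regimen
  ctx <- record_context(record$params, record$regimen)

  rs <- new_recset(request$chapters, kb$version)
  rs <- run_main_layer(rs, ctx, kb)
  rs <- apply_rule_layer(rs, "safety", record, kb)
  rs <- apply_rule_layer(rs, "inter_chapter", record, kb)
  rs <- apply_rule_layer(rs, "master", record, kb)
  if (!is.null(master_hooks)) {
    for (nm in sort(names(master_hooks))) {
      rs <- master_hooks[[nm]](rs, record, kb)
      rs <- audit_add(rs, "master", nm, "overruled", "procedural master hook")
    }
  }
  rs <- annotate_recommendations(rs, record, kb)
  rs <- adjust_renal_dosing(rs, record, kb)
  rs <- run_feedback_layer(rs, ctx, kb)
  rs
}

#' @export
print.recommendation_set <- function(x, ...) {
  cat("recommendation_set (kb ", x$kb_version, ")\n", sep = "")
  for (ch in names(x$chapters)) {
    cat("  ", ch, ":\n", sep = "")
    for (rec in x$chapters[[ch]]) {
      tgt <- rec$substance %||% rec$class %||% ""
      extra <- c(
        if (!is.null(rec$replaces)) paste0("replaces ", rec$replaces),
        if (!is.null(rec$rec_type)) rec$rec_type,
        if (!is.null(rec$aim)) rec$aim,
        if (!is.null(rec$dose_guidance)) rec$dose_guidance)
      cat("    - ", rec$action, " ", tgt,
          if (length(extra)) paste0(" [", paste(extra, collapse = "; "), "]") else "",
          "\n", sep = "")
    }
  }
  if (nrow(x$hints)) cat("  hints:", nrow(x$hints), "\n")
  if (nrow(x$notes)) cat("  safety notes:", nrow(x$notes), "\n")
  cat("  audit entries:", length(x$audit), "\n")
  invisible(x)
}
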