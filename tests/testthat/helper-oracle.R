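# Naive reference interpreter: a flat, unoptimized re-implementation of the
# rule semantics (straight loops in precedence order, no shared engine code).
# Used as the independent oracle for engine equivalence over a discretized
# scenario space. Output is an order-insensitive content summary.

naive_cmp <- function(v, op, val) {
  if (is.null(v) || (length(v) == 1 && is.na(v))) return(FALSE)
  if (op == "<") return(isTRUE(v < val))
  if (op == "<=") return(isTRUE(v <= val))
  if (op == "==") return(isTRUE(v == val))
  if (op == ">=") return(isTRUE(v >= val))
  if (op == ">") return(isTRUE(v > val))
  if (op == "in") return(isTRUE(v %in% unlist(val)))
  stop("naive: bad op ", op)
}

naive_cond <- function(cond, params, classes, substances, recommended = character(0),
                       rec = NULL) {
  if (isTRUE(cond)) return(TRUE)
  keys <- names(cond)
  if ("all" %in% keys) {
    for (c2 in cond$all) {
      if (!naive_cond(c2, params, classes, substances, recommended, rec)) return(FALSE)
    }
    return(TRUE)
  }
  if ("any" %in% keys) {
    for (c2 in cond$any) {
      if (naive_cond(c2, params, classes, substances, recommended, rec)) return(TRUE)
    }
    return(FALSE)
  }
  if ("not" %in% keys) return(!naive_cond(cond$not, params, classes, substances, recommended, rec))
  if ("always" %in% keys) return(isTRUE(cond$always))
  if ("param" %in% keys) return(naive_cmp(params[[cond$param]], cond$op, cond$value))
  if ("takes_class" %in% keys) return(cond$takes_class %in% classes)
  if ("takes_substance" %in% keys) return(cond$takes_substance %in% substances)
  if ("regimen_size" %in% keys) return(naive_cmp(length(substances), cond$regimen_size$op, cond$regimen_size$value))
  if ("recommended_class" %in% keys) return(cond$recommended_class %in% recommended)
  if ("rec" %in% keys) return(naive_cmp(rec[[cond$rec]], cond$op, cond$value))
  stop("naive: bad condition node")
}

naive_sorted_rules <- function(kb, type) {
  rules <- Filter(function(r) r$type == type, kb$rules)
  pri <- sapply(rules, function(r) as.numeric(if (is.null(r$priority)) 1000 else r$priority))
  ids <- sapply(rules, function(r) r$id)
  if (length(rules) == 0) return(list())
  rules[order(pri, ids)]
}

naive_class_of <- function(kb, rec) {
  if (!is.null(rec$class)) return(rec$class)
  if (!is.null(rec$substance)) return(unname(kb$substances[[rec$substance]]))
  NULL
}

naive_matches <- function(kb, rec, eff) {
  if (!is.null(eff$substance)) return(identical(rec$substance, eff$substance))
  if (!is.null(eff$class)) {
    cl <- naive_class_of(kb, rec)
    return(!is.null(cl) && identical(cl, eff$class))
  }
  TRUE
}

naive_apply_effects <- function(state, rule, kb, chapter) {
  for (eff in rule$effects) {
    kind <- eff$effect
    if (kind == "remove") {
      keep <- list()
      for (rec in state$recs) {
        if (rec$action != "no_change" && naive_matches(kb, rec, eff)) {
          state$notes <- c(state$notes,
                           if (!is.null(eff$note)) eff$note
                           else paste0("recommendation for ", eff$class,
                                       " withdrawn by rule ", rule$id))
        } else keep[[length(keep) + 1]] <- rec
      }
      state$recs <- keep
    } else if (kind == "replace") {
      for (i in seq_along(state$recs)) {
        rec <- state$recs[[i]]
        if (rec$action != "no_change" && naive_matches(kb, rec, eff)) {
          old <- naive_class_of(kb, rec)
          rec$action <- "replace"; rec$replaces <- old
          rec$class <- eff$with_class; rec$substance <- NULL
          rec$ann <- c(rec$ann, if (!is.null(eff$note)) eff$note
                       else paste0("substituted by rule ", rule$id))
          state$recs[[i]] <- rec
        }
      }
    } else if (kind == "annotate") {
      for (i in seq_along(state$recs)) {
        if (naive_matches(kb, state$recs[[i]], eff)) {
          state$recs[[i]]$ann <- c(state$recs[[i]]$ann,
                                   if (is.null(eff$note)) "" else eff$note)
        }
      }
    } else if (kind == "recommend") {
      tgt_ch <- if (is.null(rule$chapter)) chapter else rule$chapter
      if (identical(tgt_ch, chapter)) {
        state$recs[[length(state$recs) + 1]] <-
          list(action = if (is.null(eff$action)) "add_class" else eff$action,
               class = eff$class, substance = eff$substance,
               replaces = NULL, ann = character(0),
               rec_type = NULL, aim = NULL, dose = NULL, renal = NULL)
      }
    } else if (kind == "note") {
      state$notes <- c(state$notes, if (is.null(eff$note)) "" else eff$note)
    } else stop("naive: bad effect ", kind)
  }
  state
}

naive_evaluate <- function(params, regimen_substances, chapter, kb) {
  substances <- tolower(regimen_substances)
  classes <- unique(unname(kb$substances[substances]))
  state <- list(recs = list(), notes = character(0), hints = character(0))

  # main layer: all matching main rules of the chapter fire
  fired <- FALSE
  for (r in naive_sorted_rules(kb, "main")) {
    if (!identical(r$chapter, chapter)) next
    if (!naive_cond(r$condition, params, classes, substances)) next
    fired <- TRUE
    for (a in r$actions) {
      rec <- list(action = a$action, class = a$class, substance = a$substance,
                  replaces = NULL, ann = character(0),
                  rec_type = NULL, aim = NULL, dose = NULL, renal = NULL)
      if (identical(a$action, "replace")) {
        rec$class <- a$with_class; rec$replaces <- a$class
      }
      state$recs[[length(state$recs) + 1]] <- rec
    }
  }
  if (!fired) {
    state$recs[[1]] <- list(action = "no_change", class = NULL, substance = NULL,
                            replaces = NULL, ann = character(0),
                            rec_type = NULL, aim = NULL, dose = NULL, renal = NULL)
  }

  # safety (own chapter), then inter-chapter, then master (highest precedence)
  for (r in naive_sorted_rules(kb, "safety")) {
    if (!identical(r$chapter, chapter)) next
    if (naive_cond(r$condition, params, classes, substances)) {
      state <- naive_apply_effects(state, r, kb, chapter)
    }
  }
  for (layer in c("inter_chapter", "master")) {
    for (r in naive_sorted_rules(kb, layer)) {
      if (!is.null(r$chapter) && !identical(r$chapter, chapter)) next
      recommended <- unique(unlist(lapply(state$recs, function(rec) {
        if (rec$action %in% c("no_change", "discontinue")) NULL
        else naive_class_of(kb, rec)
      })))
      if (naive_cond(r$condition, params, classes, substances, recommended)) {
        state <- naive_apply_effects(state, r, kb, chapter)
      }
    }
  }

  # annotation: first matching recommendation-type and treatment-aim rule
  for (i in seq_along(state$recs)) {
    rec <- state$recs[[i]]
    if (!rec$action %in% c("add_class", "add_substance", "replace")) next
    rctx <- list(action = rec$action, class = naive_class_of(kb, rec),
                 substance = rec$substance, chapter = chapter)
    for (r in naive_sorted_rules(kb, "recommendation_type")) {
      if (naive_cond(r$condition, params, classes, substances, rec = rctx)) {
        rec$rec_type <- r$set$value; break
      }
    }
    for (r in naive_sorted_rules(kb, "treatment_aim")) {
      if (naive_cond(r$condition, params, classes, substances, rec = rctx)) {
        rec$aim <- r$set$value; break
      }
    }
    state$recs[[i]] <- rec
  }

  # renal dose adjustment
  egfr <- params[["egfr"]]
  for (i in seq_along(state$recs)) {
    rec <- state$recs[[i]]
    if (!rec$action %in% c("add_class", "add_substance", "replace", "continue",
                           "titrate")) next
    entry <- NULL
    for (e in kb$dose_table) if (identical(e$agent, rec$substance)) entry <- e
    if (is.null(entry)) {
      for (e in kb$dose_table) if (identical(e$agent, naive_class_of(kb, rec))) entry <- e
    }
    if (is.null(entry)) next
    if (is.null(egfr) || is.na(egfr)) {
      rec$renal <- "renal dosing not assessed (eGFR missing)"
    } else {
      got <- NULL
      for (b in entry$bands) {
        lo <- if (is.null(b$min)) 0 else b$min
        hi <- if (is.null(b$max)) Inf else b$max
        if (egfr >= lo && egfr < hi) { got <- b; break }
      }
      if (is.null(got)) got <- list(guidance = "standard dose", adjusted = FALSE)
      rec$dose <- got$guidance
      rec$renal <- if (isTRUE(got$adjusted)) "renal dose adjustment" else "standard"
    }
    state$recs[[i]] <- rec
  }

  # feedback hints
  for (r in naive_sorted_rules(kb, "feedback")) {
    if (!identical(r$chapter, chapter)) next
    if (naive_cond(r$condition, params, classes, substances)) {
      state$hints <- c(state$hints, r$hint)
    }
  }

  tuples <- if (length(state$recs)) {
    sort(vapply(state$recs, naive_rec_tuple, character(1)))
  } else character(0)
  list(recs = tuples, hints = sort(state$hints), notes = sort(state$notes))
}

naive_rec_tuple <- function(rec) {
  paste(rec$action,
        if (is.null(rec$class)) "-" else rec$class,
        if (is.null(rec$substance)) "-" else rec$substance,
        if (is.null(rec$replaces)) "-" else rec$replaces,
        if (is.null(rec$rec_type)) "-" else rec$rec_type,
        if (is.null(rec$aim)) "-" else rec$aim,
        if (is.null(rec$dose)) "-" else rec$dose,
        if (is.null(rec$renal)) "-" else rec$renal,
        paste(sort(rec$ann), collapse = "&"),
        sep = "|")
}

# The same content summary extracted from an engine recommendation_set.
engine_summary <- function(rs, chapter) {
  recs <- sort(vapply(rs$chapters[[chapter]], function(r) {
    naive_rec_tuple(list(action = r$action, class = r$class,
                         substance = r$substance, replaces = r$replaces,
                         rec_type = r$rec_type, aim = r$aim,
                         dose = r$dose_guidance, renal = r$renal_flag,
                         ann = r$safety_annotations))
  }, character(1)))
  list(recs = recs, hints = sort(rs$hints$hint), notes = sort(rs$notes$note))
}
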