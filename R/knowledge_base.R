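# Loading, static verification and scenario-space checks of the chaptered,
# typed rule set.

RULE_TYPES <- c("main", "safety", "inter_chapter", "feedback", "master",
                "recommendation_type", "treatment_aim")
REC_ACTIONS <- c("add_class", "add_substance", "replace", "continue",
                 "discontinue", "titrate", "no_change")

#' Load a knowledge base from YAML
#'
#' A knowledge base holds the four chapters, the typed rules (seven kinds:
#' main, safety, inter-chapter, feedback, master, recommendation-type,
#' treatment-aim), the substance -> medication-class table and the renal dose
#' table. Loading is pure (no global state) and schema-checks the document:
#' unknown chapters, rule types, actions or missing clusters abort with the
#' offending rule named.
#'
#' @param path path to a YAML knowledge-base file.
#' @return an object of class `knowledge_base`.
#' @export
load_knowledge_base <- function(path) {
  if (!file.exists(path)) config_error(paste0("knowledge base file not found: ", path))
  doc <- tryCatch(yaml::read_yaml(path),
                  error = function(e) config_error(paste0("parse error in ", path, ": ",
                                                          conditionMessage(e))))
  if (is.null(doc) || length(doc) == 0) {
    config_error(paste0("parse error: ", path, " is empty"))
  }
  kb <- structure(list(
    version = as.character(doc$version %||% "unversioned"),
    name = doc$name %||% basename(path),
    banner = doc$banner %||% NULL,
    chapters = doc$chapters %||% list(),
    rules = doc$rules %||% list(),
    substances = unlist(doc$substances %||% list()),
    dose_table = doc$dose_table %||% list()
  ), class = "knowledge_base")
  assert_kb_schema(kb)
  kb
}

assert_kb_schema <- function(kb) {
  chap_ids <- vapply(kb$chapters, function(ch) ch$id %||% "", character(1))
  bad <- setdiff(chap_ids, CHAPTERS)
  if (length(bad)) config_error(paste0("unknown chapter id '", bad[1], "'"))
  for (r in kb$rules) {
    id <- r$id %||% "<missing id>"
    if (is.null(r$type) || !r$type %in% RULE_TYPES) {
      config_error(paste0("rule '", id, "': unknown rule type '", r$type %||% "", "'"))
    }
    if (!is.null(r$chapter) && !r$chapter %in% chap_ids) {
      config_error(paste0("rule '", id, "': unknown chapter '", r$chapter, "'"))
    }
    if (r$type %in% c("main", "safety", "feedback") && is.null(r$chapter)) {
      config_error(paste0("rule '", id, "': type '", r$type, "' requires a chapter"))
    }
    if (r$type == "main" && is.null(r$cluster)) {
      config_error(paste0("main rule '", id, "' lacks a cluster"))
    }
    if (is.null(r$condition)) {
      config_error(paste0("rule '", id, "' lacks a condition"))
    }
    if (r$type == "main") {
      for (a in r$actions %||% list()) {
        if (!(a$action %||% "") %in% REC_ACTIONS) {
          config_error(paste0("rule '", id, "': unknown action '", a$action %||% "", "'"))
        }
      }
    }
  }
  invisible(kb)
}

kb_rules <- function(kb, type = NULL, chapter = NULL) {
  rules <- kb$rules
  if (!is.null(type)) rules <- Filter(function(r) r$type == type, rules)
  if (!is.null(chapter)) rules <- Filter(function(r) identical(r$chapter, chapter), rules)
  # deterministic order: (priority, id); ties broken lexicographically by id
  pri <- vapply(rules, function(r) as.numeric(r$priority %||% 1000), numeric(1))
  ids <- vapply(rules, function(r) r$id, character(1))
  rules[order(pri, ids)]
}

substance_class <- function(kb, substance) {
  if (is.null(substance)) return(NULL)
  cl <- kb$substances[[substance]]
  if (is.null(cl)) NULL else unname(cl)
}

kb_classes <- function(kb) sort(unique(unname(kb$substances)))

# substances of a class, sorted for determinism
class_substances <- function(kb, class) {
  sort(names(kb$substances)[unname(kb$substances) == class])
}

#' Serialize a knowledge base back to YAML
#'
#' Round-trip contract: `load_knowledge_base(serialize_knowledge_base(kb, f))`
#' equals `kb` field by field.
#'
#' @param kb a `knowledge_base`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
serialize_knowledge_base <- function(kb, path) {
  doc <- list(version = kb$version, name = kb$name)
  if (!is.null(kb$banner)) doc$banner <- kb$banner
  doc$chapters <- kb$chapters
  doc$rules <- kb$rules
  doc$substances <- as.list(kb$substances)
  doc$dose_table <- kb$dose_table
  yaml::write_yaml(doc, path)
  invisible(path)
}

#' Statically verify a knowledge base
#'
#' The machine analogue of a second expert reviewing the rule set: reports
#' duplicate rule ids, rules without references, dangling parameter names
#' (when a catalogue is supplied), malformed conditions, chapters without main
#' rules, overlapping renal dose bands, and -- when a catalogue is supplied --
#' main-rule clusters in which two rules are simultaneously satisfiable over
#' the discretized scenario space (ambiguity).
#'
#' @param kb a `knowledge_base`.
#' @param catalogue optional `parameter_catalogue`; enables dangling-name and
#'   ambiguity checks.
#' @param scenario_cap refuse enumeration above this many scenarios.
#' @return a data frame of issues (zero rows when the knowledge base is clean).
#' @export
validate_knowledge_base <- function(kb, catalogue = NULL, scenario_cap = 1e5) {
  issues <- issue_table()
  ids <- vapply(kb$rules, function(r) r$id, character(1))
  for (dup in unique(ids[duplicated(ids)])) {
    issues <- add_issue(issues, dup, "duplicate_id",
                        paste0("rule id '", dup, "' is not unique"))
  }
  chap_ids <- vapply(kb$chapters, function(ch) ch$id, character(1))
  for (ch in chap_ids) {
    if (length(kb_rules(kb, "main", ch)) == 0) {
      issues <- add_issue(issues, ch, "empty_chapter",
                          paste0("chapter '", ch, "' has no main rules"))
    }
  }
  known_params <- if (!is.null(catalogue)) catalogue_names(catalogue) else NULL
  for (r in kb$rules) {
    if (length(r$references %||% list()) == 0) {
      issues <- add_issue(issues, r$id, "missing_reference",
                          paste0("rule '", r$id, "' has no references"))
    }
    for (p in check_condition_syntax(r$condition, r$id)) {
      issues <- add_issue(issues, r$id, "bad_condition", p)
    }
    if (!is.null(known_params)) {
      refs <- collect_condition_refs(r$condition)
      for (nm in setdiff(refs$params, known_params)) {
        issues <- add_issue(issues, r$id, "dangling_parameter",
                            paste0("rule '", r$id, "' references unknown parameter '", nm, "'"))
      }
      for (cl in setdiff(refs$classes, kb_classes(kb))) {
        issues <- add_issue(issues, r$id, "dangling_class",
                            paste0("rule '", r$id, "' references unknown class '", cl, "'"))
      }
      for (s in setdiff(refs$substances, names(kb$substances))) {
        issues <- add_issue(issues, r$id, "dangling_substance",
                            paste0("rule '", r$id, "' references unknown substance '", s, "'"))
      }
    }
  }
  issues <- rbind(issues, check_dose_table(kb))
  if (!is.null(catalogue)) {
    for (ch in chap_ids) {
      amb <- tryCatch(find_ambiguous_clusters(kb, ch, catalogue, scenario_cap),
                      error = function(e) NULL)
      if (!is.null(amb)) issues <- rbind(issues, amb)
    }
  }
  issues
}

check_dose_table <- function(kb) {
  issues <- issue_table()
  for (entry in kb$dose_table) {
    bands <- entry$bands %||% list()
    if (length(bands) < 2) next
    lo <- vapply(bands, function(b) as.numeric(b$min %||% 0), numeric(1))
    hi <- vapply(bands, function(b) as.numeric(b$max %||% Inf), numeric(1))
    ord <- order(lo)
    lo <- lo[ord]; hi <- hi[ord]
    if (any(lo >= hi)) {
      issues <- add_issue(issues, entry$agent, "bad_dose_band",
                          paste0("dose band for '", entry$agent, "' has min >= max"))
    }
    if (any(hi[-length(hi)] > lo[-1])) {
      issues <- add_issue(issues, entry$agent, "overlapping_dose_bands",
                          paste0("overlapping eGFR bands for '", entry$agent, "'"))
    }
  }
  issues
}

# --- scenario enumeration -------------------------------------------------

#' Build the default discretization of a chapter's scenario space
#'
#' Each numeric parameter referenced by the chapter's main rules is
#' represented by its catalogue range endpoints plus the midpoint; booleans by
#' both states; categoricals by all allowed values; each referenced medication
#' class by present/absent.
#'
#' @param kb a `knowledge_base`.
#' @param chapter chapter id.
#' @param catalogue a `parameter_catalogue`.
#' @return list with `params` (named list of value vectors) and `classes`.
#' @export
default_discretization <- function(kb, chapter, catalogue) {
  mains <- kb_rules(kb, "main", chapter)
  params <- character(0); classes <- character(0)
  for (r in mains) {
    refs <- collect_condition_refs(r$condition)
    params <- union(params, refs$params)
    classes <- union(classes, c(refs$classes,
                                unlist(lapply(refs$substances, substance_class, kb = kb))))
  }
  values <- list()
  for (nm in sort(params)) {
    entry <- catalogue_entry(catalogue, nm)
    if (is.null(entry)) config_error(paste0("parameter '", nm, "' not in catalogue"))
    values[[nm]] <- switch(entry$kind,
      numeric = { rng <- unlist(entry$range); c(rng[1], mean(rng), rng[2]) },
      boolean = c(TRUE, FALSE),
      categorical = unlist(entry$values))
  }
  list(params = values, classes = sort(classes))
}

# Enumerate the Cartesian scenario space of a discretization. Returns a data
# frame: one row per scenario, parameter columns plus logical takes_<class>
# columns.
enumerate_scenarios <- function(discretization, cap = 1e5) {
  cls <- discretization$classes
  cols <- discretization$params
  if (length(cls) > 0) {
    cols <- c(cols, stats::setNames(rep(list(c(TRUE, FALSE)), length(cls)),
                                    paste0("takes_", cls)))
  }
  if (length(cols) == 0) return(data.frame(.dummy = 1)[, 0, drop = FALSE])
  size <- prod(vapply(cols, length, numeric(1)))
  if (size > cap) {
    stop("scenario space has ", format(size, big.mark = ",", scientific = FALSE),
         " combinations, above the cap of ",
         format(cap, big.mark = ",", scientific = FALSE), call. = FALSE)
  }
  do.call(expand.grid, c(cols, stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE))
}

scenario_context <- function(kb, scenario_row, discretization) {
  params <- as.list(scenario_row[names(discretization$params)])
  classes <- discretization$classes[unlist(
    scenario_row[paste0("takes_", discretization$classes)])]
  substances <- vapply(classes, function(cl) class_substances(kb, cl)[1], character(1))
  list(params = params, classes = classes,
       substances = unname(substances), regimen_size = length(classes),
       recommended_classes = character(0), rec = NULL)
}

#' Check that a chapter's main rules cover every discretized scenario
#'
#' Enumerates the Cartesian product of the discretized parameter values and
#' regimen-class states and returns the scenarios matched by zero main rules
#' of the chapter. An empty result (together with unambiguous clusters) means
#' exactly one main rule fires for every scenario.
#'
#' @inheritParams default_discretization
#' @param discretization a discretization as returned by
#'   [default_discretization()]; built from the catalogue when `NULL`.
#' @param catalogue required when `discretization` is `NULL`.
#' @param cap refuse to enumerate more than this many scenarios.
#' @return data frame of uncovered scenarios (zero rows = full coverage).
#' @export
check_cluster_exhaustiveness <- function(kb, chapter, discretization = NULL,
                                         catalogue = NULL, cap = 1e5) {
  if (is.null(discretization)) {
    if (is.null(catalogue)) config_error("need a discretization or a catalogue")
    discretization <- default_discretization(kb, chapter, catalogue)
  }
  grid <- enumerate_scenarios(discretization, cap)
  mains <- kb_rules(kb, "main", chapter)
  covered <- logical(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    ctx <- scenario_context(kb, grid[i, , drop = FALSE], discretization)
    covered[i] <- any(vapply(mains, function(r) eval_condition(r$condition, ctx),
                             logical(1)))
  }
  grid[!covered, , drop = FALSE]
}

# Ambiguity: two main rules of one cluster satisfiable on the same scenario.
find_ambiguous_clusters <- function(kb, chapter, catalogue, cap = 1e5) {
  issues <- issue_table()
  discretization <- default_discretization(kb, chapter, catalogue)
  grid <- enumerate_scenarios(discretization, cap)
  mains <- kb_rules(kb, "main", chapter)
  if (length(mains) < 2 || nrow(grid) == 0) return(issues)
  clusters <- vapply(mains, function(r) r$cluster, character(1))
  ids <- vapply(mains, function(r) r$id, character(1))
  hit <- matrix(FALSE, nrow(grid), length(mains))
  for (i in seq_len(nrow(grid))) {
    ctx <- scenario_context(kb, grid[i, , drop = FALSE], discretization)
    hit[i, ] <- vapply(mains, function(r) eval_condition(r$condition, ctx), logical(1))
  }
  reported <- character(0)
  for (cl in unique(clusters)) {
    members <- which(clusters == cl)
    if (length(members) < 2) next
    multi <- rowSums(hit[, members, drop = FALSE]) > 1
    if (any(multi)) {
      i <- which(multi)[1]
      pair <- ids[members][hit[i, members]][1:2]
      key <- paste(cl, collapse = "")
      if (key %in% reported) next
      reported <- c(reported, key)
      issues <- add_issue(issues, cl, "ambiguous_cluster",
                          paste0("cluster '", cl, "' in chapter '", chapter,
                                 "': rules ", pair[1], " and ", pair[2],
                                 " are simultaneously satisfiable"))
    }
  }
  issues
}
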