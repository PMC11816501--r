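# The rule condition language: boolean combinators over parameter
# comparisons, regimen predicates and (for annotation / inter-chapter rules)
# recommendation predicates. Deliberately no arithmetic between parameters,
# which keeps coverage and ambiguity checking decidable by finite enumeration.

CONDITION_OPS <- c("<", "<=", "==", ">=", ">", "in")

apply_op <- function(v, op, value) {
  if (is.null(v) || (length(v) == 1L && is.na(v))) return(FALSE)
  if (is.null(op)) config_error("comparison leaf without an 'op'")
  switch(op,
    "<"  = isTRUE(v <  value),
    "<=" = isTRUE(v <= value),
    "==" = isTRUE(v == value),
    ">=" = isTRUE(v >= value),
    ">"  = isTRUE(v >  value),
    "in" = isTRUE(v %in% unlist(value)),
    config_error(paste0("unsupported comparison operator '", op, "'"))
  )
}

# Evaluation context: list(params, classes, substances, regimen_size,
# recommended_classes = NULL, rec = NULL).
eval_condition <- function(cond, ctx) {
  if (isTRUE(cond)) return(TRUE)
  if (!is.list(cond)) config_error("condition node must be a mapping")
  if (!is.null(cond$all)) {
    return(all(vapply(cond$all, eval_condition, logical(1), ctx)))
  }
  if (!is.null(cond$any)) {
    return(any(vapply(cond$any, eval_condition, logical(1), ctx)))
  }
  if (!is.null(cond$not)) return(!eval_condition(cond$not, ctx))
  if (!is.null(cond$always)) return(isTRUE(cond$always))
  if (!is.null(cond$param)) {
    return(apply_op(ctx$params[[cond$param]], cond$op, cond$value))
  }
  if (!is.null(cond$takes_class)) return(cond$takes_class %in% ctx$classes)
  if (!is.null(cond$takes_substance)) return(cond$takes_substance %in% ctx$substances)
  if (!is.null(cond$regimen_size)) {
    return(apply_op(ctx$regimen_size, cond$regimen_size$op, cond$regimen_size$value))
  }
  if (!is.null(cond$recommended_class)) {
    return(cond$recommended_class %in% ctx$recommended_classes)
  }
  if (!is.null(cond$rec)) {
    return(apply_op(ctx$rec[[cond$rec]], cond$op, cond$value))
  }
  config_error(paste0("unsupported condition node: ",
                      paste(names(cond), collapse = ", ")))
}

# Collect the parameter names, medication classes and substances a condition
# tree refers to (used for dangling-name checks and scenario discretization).
collect_condition_refs <- function(cond) {
  refs <- list(params = character(0), classes = character(0),
               substances = character(0), regimen_size = FALSE)
  walk <- function(node) {
    if (!is.list(node)) return(invisible())
    if (!is.null(node$all)) { lapply(node$all, walk); return(invisible()) }
    if (!is.null(node$any)) { lapply(node$any, walk); return(invisible()) }
    if (!is.null(node$not)) { walk(node$not); return(invisible()) }
    if (!is.null(node$param)) refs$params <<- c(refs$params, node$param)
    if (!is.null(node$takes_class)) refs$classes <<- c(refs$classes, node$takes_class)
    if (!is.null(node$takes_substance)) refs$substances <<- c(refs$substances, node$takes_substance)
    if (!is.null(node$regimen_size)) refs$regimen_size <<- TRUE
    invisible()
  }
  walk(cond)
  refs$params <- unique(refs$params)
  refs$classes <- unique(refs$classes)
  refs$substances <- unique(refs$substances)
  refs
}

# Static well-formedness check of a condition tree (unknown node kinds,
# missing operators). Returns a character vector of problems.
check_condition_syntax <- function(cond, where) {
  probs <- character(0)
  walk <- function(node) {
    if (isTRUE(node)) return(invisible())
    if (!is.list(node)) {
      probs <<- c(probs, paste0(where, ": condition node is not a mapping"))
      return(invisible())
    }
    keys <- names(node)
    if (!is.null(node$all)) { lapply(node$all, walk); return(invisible()) }
    if (!is.null(node$any)) { lapply(node$any, walk); return(invisible()) }
    if (!is.null(node$not)) { walk(node$not); return(invisible()) }
    if (!is.null(node$always)) return(invisible())
    leaf_keys <- c("param", "takes_class", "takes_substance", "regimen_size",
                   "recommended_class", "rec")
    hit <- intersect(leaf_keys, keys)
    if (length(hit) != 1) {
      probs <<- c(probs, paste0(where, ": unrecognized condition node {",
                                paste(keys, collapse = ", "), "}"))
      return(invisible())
    }
    if (hit %in% c("param", "rec") && !(node$op %||% "") %in% CONDITION_OPS) {
      probs <<- c(probs, paste0(where, ": bad operator '", node$op %||% "", "'"))
    }
    invisible()
  }
  walk(cond)
  probs
}

record_context <- function(params, regimen) {
  list(params = params,
       classes = unique(vapply(regimen, function(m) m$class %||% "", character(1))),
       substances = vapply(regimen, function(m) m$substance, character(1)),
       regimen_size = length(regimen),
       recommended_classes = character(0),
       rec = NULL)
}
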