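# The two-phase external-validation protocol: blinded reviewer assignment,
# response capture, phase-2 adjudication and precision / reviewer-error
# metrics.

ANSWER_VOCAB <- c("yes", "no", "not_sure", "missing")

#' Assign test cases to chapter-expert reviewers
#'
#' Each reviewer sees cases from a single chapter only, matching their area of
#' expertise; quotas per chapter must sum exactly to that chapter's case
#' count. Predicted-negative cases are dealt round-robin over a seeded random
#' reviewer order, so same-chapter reviewers differ by at most one PN case,
#' and PN/PP labels never enter the assignment (blinding).
#'
#' @param cases list of `test_case`s.
#' @param reviewers data frame with columns `reviewer_id`, `chapter`, `quota`.
#' @param seed integer seed.
#' @return data frame `case_id`, `chapter`, `reviewer_id`, `position`.
#' @export
assign_cases_to_reviewers <- function(cases, reviewers, seed) {
  chapters <- unique(vapply(cases, function(c) c$chapter, character(1)))
  short <- character(0)
  for (ch in chapters) {
    n_cases <- sum(vapply(cases, function(c) identical(c$chapter, ch), logical(1)))
    quota <- sum(reviewers$quota[reviewers$chapter == ch])
    if (quota != n_cases) {
      short <- c(short, paste0(ch, " (", n_cases, " cases vs quota ", quota, ")"))
    }
  }
  if (length(short)) {
    stop("reviewer quotas do not match case counts in: ",
         paste(short, collapse = ", "), call. = FALSE)
  }
  out <- list()
  withr::with_seed(derive_seed(seed, "assignment"), {
    for (ch in chapters) {
      ch_cases <- Filter(function(c) identical(c$chapter, ch), cases)
      revs <- reviewers[reviewers$chapter == ch, , drop = FALSE]
      rev_order <- sample(nrow(revs))
      is_pn <- vapply(ch_cases, function(c) identical(c$polarity, "PN"), logical(1))
      pn_cases <- sample(which(is_pn))
      pp_cases <- sample(which(!is_pn))
      slots <- rep(revs$reviewer_id[rev_order], revs$quota[rev_order])
      # deal PN round-robin across reviewers, then fill quotas with PP
      remaining <- stats::setNames(revs$quota[rev_order], revs$reviewer_id[rev_order])
      assignment <- character(length(ch_cases))
      ri <- 1L
      for (idx in pn_cases) {
        while (remaining[[ri]] == 0) ri <- ri %% length(remaining) + 1L
        assignment[idx] <- names(remaining)[ri]
        remaining[[ri]] <- remaining[[ri]] - 1L
        ri <- ri %% length(remaining) + 1L
      }
      fill <- rep(names(remaining), times = remaining)
      assignment[pp_cases] <- fill[seq_along(pp_cases)]
      for (i in seq_along(ch_cases)) {
        out[[length(out) + 1L]] <- data.frame(
          case_id = ch_cases[[i]]$id, chapter = ch,
          reviewer_id = assignment[i], stringsAsFactors = FALSE)
      }
    }
  })
  res <- do.call(rbind, out)
  res <- res[order(res$chapter, res$reviewer_id, res$case_id), , drop = FALSE]
  res$position <- stats::ave(seq_len(nrow(res)), res$reviewer_id, FUN = seq_along)
  rownames(res) <- NULL
  res
}

#' Reviewer-facing export of assigned cases
#'
#' Writes one JSON object per line: case id, chapter, reviewer, the clinical
#' input and the presented recommendations. Polarity labels and mutation
#' records are visible to the experimenters only and are structurally excluded
#' from this export.
#'
#' @param cases list of `test_case`s.
#' @param assignment data frame from [assign_cases_to_reviewers()].
#' @param path output JSON Lines file.
#' @return `path`, invisibly.
#' @export
export_reviewer_cases <- function(cases, assignment, path) {
  idx <- stats::setNames(seq_along(cases), vapply(cases, function(c) c$id, character(1)))
  lines <- vapply(seq_len(nrow(assignment)), function(i) {
    cs <- cases[[idx[[assignment$case_id[i]]]]]
    canonical_json(list(
      case_id = cs$id, chapter = cs$chapter,
      reviewer_id = assignment$reviewer_id[i],
      input = list(params = cs$input$params,
                   regimen = lapply(cs$input$regimen, function(m) m$substance)),
      recommendations = lapply(cs$prediction$chapters[[cs$chapter]], clean_rec),
      hints = cs$prediction$hints$hint))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Validate reviewer responses against the answer-flow rules
#'
#' Phase-1 "no" and "not sure" answers require a comment explaining the
#' disagreement; comments are optional for "yes". Answers outside the
#' vocabulary and duplicate (case, phase) responses are flagged.
#'
#' @param responses data frame with columns `case_id`, `reviewer_id`, `phase`,
#'   `answer`, `comment`.
#' @return data frame of issues (zero rows when clean).
#' @export
validate_responses <- function(responses) {
  issues <- issue_table()
  for (i in seq_len(nrow(responses))) {
    r <- responses[i, ]
    if (!r$answer %in% ANSWER_VOCAB) {
      issues <- add_issue(issues, r$case_id, "vocabulary",
                          paste0("answer '", r$answer, "' is not one of ",
                                 paste(ANSWER_VOCAB, collapse = "/")))
    }
    if (r$phase == 1 && r$answer %in% c("no", "not_sure") &&
        (is.na(r$comment) || !nzchar(trimws(r$comment)))) {
      issues <- add_issue(issues, r$case_id, "mandatory_comment",
                          paste0("phase-1 '", r$answer, "' answer for case ",
                                 r$case_id, " requires a comment"))
    }
  }
  key <- paste(responses$case_id, responses$phase)
  for (k in unique(key[duplicated(key)])) {
    issues <- add_issue(issues, k, "duplicate_response",
                        paste0("duplicate response for (case, phase) ", k))
  }
  issues
}

#' Apply phase-2 adjudication transitions to phase-1 responses
#'
#' Only "no" and "not sure" phase-1 answers were revisited in the moderated
#' interview phase; post-interview answers are final. A transition referring
#' to an unknown case, to a case answered "yes" in phase 1, or (when
#' polarities are supplied) to a predicted-negative case is a protocol error.
#' Applying the same transitions twice equals applying them once.
#'
#' @param phase1 data frame with columns `case_id`, `answer` (and optionally
#'   `phase1_answer`, which takes precedence so that adjudication is
#'   idempotent on its own output).
#' @param transitions data frame with columns `case_id`, `from`, `to` and
#'   optionally `note`.
#' @param polarities optional data frame `case_id`, `polarity`; enforces that
#'   PN cases are never adjudicated.
#' @return data frame `case_id`, `phase1_answer`, `answer` (final).
#' @export
apply_adjudication <- function(phase1, transitions, polarities = NULL) {
  base <- if ("phase1_answer" %in% names(phase1)) phase1$phase1_answer else phase1$answer
  final <- stats::setNames(base, phase1$case_id)
  p1 <- stats::setNames(base, phase1$case_id)
  if (nrow(transitions) > 0) {
    for (i in seq_len(nrow(transitions))) {
      tr <- transitions[i, ]
      if (!tr$case_id %in% names(p1)) {
        stop("transition refers to unknown case '", tr$case_id, "'", call. = FALSE)
      }
      if (!is.null(polarities)) {
        pol <- polarities$polarity[match(tr$case_id, polarities$case_id)]
        if (identical(pol, "PN")) {
          stop("case '", tr$case_id, "' is predicted negative; PN cases are not adjudicated",
               call. = FALSE)
        }
      }
      from <- p1[[tr$case_id]]
      if (!from %in% c("no", "not_sure")) {
        stop("case '", tr$case_id, "' was answered '", from,
             "' in phase 1; only no/not_sure responses are adjudicated", call. = FALSE)
      }
      if (!is.null(tr$from) && !is.na(tr$from) && !identical(tr$from, from)) {
        stop("transition for case '", tr$case_id, "' expects phase-1 answer '",
             tr$from, "' but found '", from, "'", call. = FALSE)
      }
      if (!tr$to %in% ANSWER_VOCAB) {
        stop("transition target '", tr$to, "' is not a valid answer", call. = FALSE)
      }
      final[[tr$case_id]] <- tr$to
    }
  }
  data.frame(case_id = phase1$case_id,
             phase1_answer = unname(p1[phase1$case_id]),
             answer = unname(final[phase1$case_id]),
             stringsAsFactors = FALSE)
}

#' Compute study metrics from final responses and case polarities
#'
#' For predicted-positive (PP) cases: TP = final "yes", FP = final "no";
#' precision = TP / (TP + FP), excluding "not sure" and "missing" from the
#' denominator. Predicted-negative (PN) cases are excluded from precision
#' entirely; a "yes" on a PN case is a reviewer error (the study's "TN"
#' label), and reviewer error rate = TN / PN. Accuracy = (TP + TN) / final
#' valid n (missing excluded, "not sure" retained in the denominator).
#'
#' @param final_responses data frame `case_id`, `answer` (post-adjudication).
#' @param polarities data frame `case_id`, `chapter`, `polarity` (`PP`/`PN`).
#' @return a `study_metrics` object: data frames `per_chapter` and `overall`
#'   carrying all intermediate counts for audit.
#' @export
compute_study_metrics <- function(final_responses, polarities) {
  m <- match(final_responses$case_id, polarities$case_id)
  if (anyNA(m)) {
    stop("response(s) for unknown case(s): ",
         paste(utils::head(final_responses$case_id[is.na(m)], 3), collapse = ", "),
         call. = FALSE)
  }
  df <- data.frame(answer = final_responses$answer,
                   chapter = polarities$chapter[m],
                   polarity = polarities$polarity[m],
                   stringsAsFactors = FALSE)
  metric_row <- function(d, label) {
    pp <- d[d$polarity == "PP", , drop = FALSE]
    pn <- d[d$polarity == "PN", , drop = FALSE]
    tp <- sum(pp$answer == "yes")
    fp <- sum(pp$answer == "no")
    ns <- sum(pp$answer == "not_sure")
    miss <- sum(pp$answer == "missing")
    tn <- sum(pn$answer == "yes")           # reviewer error: accepted a PN
    pn_rej <- sum(pn$answer == "no")        # PN correctly rejected
    pn_ns <- sum(pn$answer == "not_sure")
    valid_n <- nrow(d) - miss - sum(pn$answer == "missing")
    data.frame(
      chapter = label, pp = nrow(pp), pn = nrow(pn),
      tp = tp, fp = fp, not_sure = ns, missing = miss,
      tn = tn, pn_rejected = pn_rej, pn_not_sure = pn_ns,
      precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
      reviewer_error = if (nrow(pn) > 0) tn / nrow(pn) else NA_real_,
      accuracy = if (valid_n > 0) (tp + tn) / valid_n else NA_real_,
      stringsAsFactors = FALSE)
  }
  per_chapter <- do.call(rbind, lapply(
    CHAPTERS[CHAPTERS %in% unique(df$chapter)],
    function(ch) metric_row(df[df$chapter == ch, , drop = FALSE], ch)))
  overall <- metric_row(df, "overall")
  structure(list(per_chapter = per_chapter, overall = overall),
            class = "study_metrics")
}

#' @export
print.study_metrics <- function(x, ...) {
  cat("study_metrics\n")
  show <- rbind(x$per_chapter, x$overall)
  show$precision <- ifelse(is.na(show$precision), NA,
                           sprintf("%.1f%%", 100 * show$precision))
  print(show[, c("chapter", "pp", "pn", "tp", "fp", "not_sure", "missing",
                 "tn", "precision")], row.names = FALSE)
  invisible(x)
}
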