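# Constrained random generation of medically plausible single-chapter test
# cases, predicted-negative mutation, study allocation and sample size.

#' Build generation constraints for one chapter
#'
#' Constraints tighten (never widen) the catalogue: numeric parameters draw
#' uniformly from their range, boolean comorbidity flags draw with a per-flag
#' prevalence, and the regimen draws between `regimen_min` and `regimen_max`
#' medication classes from `classes` (one random substance per class).
#'
#' @param catalogue a `parameter_catalogue`.
#' @param chapter chapter id the cases are generated for.
#' @param kb a `knowledge_base` (source of the substance vocabulary).
#' @param classes medication classes the regimen may draw from.
#' @param regimen_min,regimen_max regimen size bounds.
#' @param ranges named list overriding numeric ranges (must lie inside the
#'   catalogue ranges).
#' @param prevalence named numeric vector of P(flag = TRUE) per boolean
#'   parameter; default 0.5 for every flag.
#' @return a `generation_constraints` object.
#' @export
generation_constraints <- function(catalogue, chapter, kb,
                                   classes = kb_classes(kb),
                                   regimen_min = 0, regimen_max = 3,
                                   ranges = list(), prevalence = numeric(0)) {
  assert_catalogue(catalogue)
  if (!chapter %in% CHAPTERS) config_error(paste0("unknown chapter: ", chapter))
  params <- list()
  for (nm in required_parameters(catalogue, chapter)) {
    entry <- catalogue_entry(catalogue, nm)
    spec <- list(kind = entry$kind)
    if (entry$kind == "numeric") {
      rng <- unlist(entry$range)
      if (!is.null(ranges[[nm]])) {
        sub <- unlist(ranges[[nm]])
        if (sub[1] < rng[1] || sub[2] > rng[2] || sub[1] > sub[2]) {
          config_error(paste0("constraint range for '", nm,
                              "' is empty or outside the catalogue range"))
        }
        rng <- sub
      }
      spec$range <- rng
    } else if (entry$kind == "boolean") {
      spec$p_true <- if (nm %in% names(prevalence)) prevalence[[nm]] else 0.5
    } else {
      spec$values <- unlist(entry$values)
    }
    params[[nm]] <- spec
  }
  if (regimen_min > regimen_max || regimen_max > length(classes)) {
    config_error("regimen constraints unsatisfiable: need regimen_min <= regimen_max <= length(classes)")
  }
  subs_by_class <- stats::setNames(lapply(classes, class_substances, kb = kb), classes)
  empty <- names(subs_by_class)[vapply(subs_by_class, length, integer(1)) == 0]
  if (length(empty)) {
    config_error(paste0("no substances for class(es): ", paste(empty, collapse = ", ")))
  }
  structure(list(chapter = chapter, params = params, classes = classes,
                 regimen_min = regimen_min, regimen_max = regimen_max,
                 substances_by_class = subs_by_class),
            class = "generation_constraints")
}

#' Generate constrained random patient records
#'
#' Draws exactly `n` records satisfying the constraints; every record passes
#' [validate_patient_record()] for the constraint's chapter. Identical
#' `(constraints, n, seed)` produce an element-wise identical list.
#'
#' @param constraints a [generation_constraints()] object.
#' @param n number of records.
#' @param seed integer seed for this generation stream.
#' @return list of `patient_record`s.
#' @export
generate_case_inputs <- function(constraints, n, seed) {
  stopifnot(inherits(constraints, "generation_constraints"), n >= 0)
  if (n == 0) return(list())
  withr::with_seed(seed, {
    lapply(seq_len(n), function(i) {
      params <- list()
      for (nm in names(constraints$params)) {
        spec <- constraints$params[[nm]]
        params[[nm]] <- switch(spec$kind,
          numeric = round(stats::runif(1, spec$range[1], spec$range[2]), 1),
          boolean = stats::runif(1) < spec$p_true,
          categorical = sample(spec$values, 1))
      }
      k <- sample(seq(constraints$regimen_min, constraints$regimen_max), 1)
      regimen <- character(0)
      if (k > 0) {
        cls <- sample(constraints$classes, k)
        regimen <- vapply(cls, function(cl) {
          subs <- constraints$substances_by_class[[cl]]
          if (length(subs) == 1) subs else sample(subs, 1)
        }, character(1))
      }
      patient_record(params, unname(regimen))
    })
  })
}

#' Turn record inputs into predicted-positive test cases
#'
#' Each case stores the input and the engine's recommendations for it (the
#' "prediction labels"); polarity starts as `"PP"`.
#'
#' @param inputs list of `patient_record`s.
#' @param kb,catalogue knowledge base and catalogue.
#' @param chapter chapter the cases belong to.
#' @param ids optional case ids; autogenerated when `NULL`.
#' @return list of `test_case` objects.
#' @export
build_test_cases <- function(inputs, kb, catalogue, chapter, ids = NULL) {
  if (length(inputs) == 0) return(list())
  if (is.null(ids)) {
    ids <- sprintf("%s-%04d", toupper(substr(chapter, 1, 3)), seq_along(inputs))
  }
  stopifnot(length(ids) == length(inputs))
  lapply(seq_along(inputs), function(i) {
    rs <- tryCatch(
      evaluate_record(evaluation_request(inputs[[i]], chapter), kb, catalogue),
      error = function(e) stop("case ", ids[i], " (input ", i, "): ",
                               conditionMessage(e), call. = FALSE))
    structure(list(id = ids[i], chapter = chapter, input = inputs[[i]],
                   prediction = rs, polarity = "PP", mutation = NULL),
              class = "test_case")
  })
}

#' Allocate study cases over chapters and choose predicted-negative slots
#'
#' Integer allocation uses largest-remainder rounding over the chapter shares;
#' the predicted-negative (PN) total is `round(pn_fraction * total)`,
#' apportioned over chapters by the same rule and placed at random positions
#' within each chapter (seeded). When the study design fixes per-chapter base
#' counts (e.g. from a sample-size calculation) plus buffer cases, pass
#' `base_counts` and `buffer` explicitly; the default buffer split is
#' proportional to the shares with largest-remainder rounding.
#'
#' @param total total number of cases.
#' @param chapter_shares named numeric vector over [CHAPTERS] summing to 1.
#' @param pn_fraction fraction of cases converted to predicted negatives,
#'   in `[0, 1)`.
#' @param seed integer seed for PN placement.
#' @param base_counts optional per-chapter case counts (same names as
#'   `chapter_shares`); buffer cases bring them up to `total`.
#' @param buffer optional per-chapter buffer counts.
#' @return a `study_allocation` object.
#' @export
allocate_study_cases <- function(total, chapter_shares, pn_fraction, seed,
                                 base_counts = NULL, buffer = NULL) {
  if (abs(sum(chapter_shares) - 1) > 1e-8) {
    stop("chapter shares must sum to 1", call. = FALSE)
  }
  if (pn_fraction < 0 || pn_fraction >= 1) {
    stop("pn_fraction must be in [0, 1)", call. = FALSE)
  }
  chapters <- names(chapter_shares)
  if (is.null(base_counts)) {
    counts <- largest_remainder(chapter_shares, total)
  } else {
    base_counts <- base_counts[chapters]
    extra <- total - sum(base_counts)
    if (extra < 0) stop("base counts exceed total", call. = FALSE)
    if (is.null(buffer)) buffer <- largest_remainder(chapter_shares, extra)
    if (sum(buffer) != extra) stop("buffer counts must bring base counts to total", call. = FALSE)
    counts <- as.integer(base_counts + buffer)
  }
  pn_total <- round(pn_fraction * total)
  pn_counts <- largest_remainder(chapter_shares, pn_total)
  pn_positions <- stats::setNames(vector("list", length(chapters)), chapters)
  withr::with_seed(derive_seed(seed, "pn-positions"), {
    for (i in seq_along(chapters)) {
      pn_positions[[i]] <- if (pn_counts[i] > 0) {
        sort(sample(counts[i], pn_counts[i]))
      } else integer(0)
    }
  })
  structure(list(total = as.integer(total),
                 chapters = data.frame(chapter = chapters,
                                       n_cases = counts, n_pn = pn_counts,
                                       stringsAsFactors = FALSE),
                 pn_positions = pn_positions,
                 pn_fraction = pn_fraction, seed = seed),
            class = "study_allocation")
}

#' Convert a predicted-positive case into a predicted negative
#'
#' Corrupts the case's prediction labels so they no longer match what the
#' engine actually recommends, either by swapping in another case's prediction
#' (`swap_with_other`) or by altering a recommended agent
#' (`alter_recommendation`). The mismatch is verified by re-evaluating the
#' case input; a mutation that accidentally reproduces the true output is
#' retried with a different draw, and a bounded number of failures raises an
#' error (degenerate knowledge base).
#'
#' @param case a `test_case` with polarity `"PP"`.
#' @param pool list of `test_case`s from the same chapter (swap source).
#' @param strategy `"swap_with_other"` or `"alter_recommendation"`.
#' @param kb,catalogue knowledge base and catalogue.
#' @param seed integer seed for this mutation.
#' @param max_retries retry bound for the mismatch check.
#' @return the mutated `test_case` with polarity `"PN"` and a filled
#'   mutation record.
#' @export
make_predicted_negative <- function(case, pool,
                                    strategy = c("swap_with_other", "alter_recommendation"),
                                    kb, catalogue, seed, max_retries = 20) {
  strategy <- match.arg(strategy)
  stopifnot(inherits(case, "test_case"), identical(case$polarity, "PP"))
  truth <- evaluate_record(evaluation_request(case$input, case$chapter), kb, catalogue)
  truth_json <- serialize_prediction(truth)

  if (strategy == "swap_with_other") {
    others <- Filter(function(x) !identical(x$id, case$id) &&
                       identical(x$chapter, case$chapter), pool)
    if (length(others) == 0) {
      stop("pool contains no other case of chapter ", case$chapter, " to swap with",
           call. = FALSE)
    }
    ord <- withr::with_seed(seed, sample(seq_along(others)))
    for (j in ord) {
      cand <- others[[j]]$prediction
      if (!identical(serialize_prediction(cand), truth_json)) {
        case$prediction <- cand
        case$polarity <- "PN"
        case$mutation <- list(strategy = strategy,
                              detail = paste0("prediction swapped with case ",
                                              others[[j]]$id))
        return(case)
      }
    }
    stop("no pool case with a differing prediction found for ", case$id,
         call. = FALSE)
  }

  # alter_recommendation: change the recommended agent of one drug-change
  # recommendation to a different class (or graft a spurious drug change onto
  # a no-change prediction)
  withr::with_seed(seed, {
    classes <- kb_classes(kb)
    for (attempt in seq_len(max_retries)) {
      mutated <- case$prediction
      recs <- mutated$chapters[[case$chapter]]
      drug_idx <- which(vapply(recs, function(r)
        r$action %in% c("add_class", "add_substance", "replace", "continue", "titrate"),
        logical(1)))
      if (length(drug_idx) > 0) {
        i <- if (length(drug_idx) == 1) drug_idx else sample(drug_idx, 1)
        old <- recs[[i]]$class %||% substance_class(kb, recs[[i]]$substance)
        alt <- setdiff(classes, old)
        newcl <- if (length(alt) == 1) alt else sample(alt, 1)
        recs[[i]]$class <- newcl
        recs[[i]]$substance <- NULL
        recs[[i]]$action <- if (recs[[i]]$action == "add_substance") "add_class" else recs[[i]]$action
        detail <- paste0("recommended agent ", old %||% "(none)", " -> ", newcl)
      } else {
        # no drug-change content (a pure no-change prediction, or everything
        # was withdrawn): graft a spurious drug addition onto the prediction
        newcl <- if (length(classes) == 1) classes else sample(classes, 1)
        if (length(recs) == 0) {
          recs[[1]] <- new_rec(case$chapter, "add_class", class = newcl,
                               references = "mutated", rule_ids = character(0))
        } else {
          i <- if (length(recs) == 1) 1L else sample(length(recs), 1)
          recs[[i]]$action <- "add_class"
          recs[[i]]$class <- newcl
          recs[[i]]$substance <- NULL
        }
        detail <- paste0("spurious add_class ", newcl, " grafted onto prediction")
      }
      mutated$chapters[[case$chapter]] <- recs
      if (!identical(serialize_prediction(mutated), truth_json)) {
        case$prediction <- mutated
        case$polarity <- "PN"
        case$mutation <- list(strategy = strategy, detail = detail)
        return(case)
      }
    }
    stop("could not produce a mismatching mutation for ", case$id, " after ",
         max_retries, " attempts", call. = FALSE)
  })
}

#' Goodness-of-fit check of the numeric case sampler
#'
#' Chi-square test that draws of a numeric parameter are uniform over its
#' constraint range. Expected bin probabilities account exactly for the
#' sampler's rounding to one decimal (interior grid values carry equal mass,
#' the two endpoints half mass), so the test is calibrated for the generator
#' as implemented.
#'
#' @param values numeric draws (as produced by [generate_case_inputs()]).
#' @param range length-2 numeric range the draws were taken from.
#' @param bins number of equal-width bins.
#' @return an `htest` from [stats::chisq.test()].
#' @export
sampler_uniformity_test <- function(values, range, bins = 10) {
  lo <- range[1]; hi <- range[2]
  # round() so grid doubles are bit-identical to the generator's rounded draws
  grid <- round(seq(lo, hi, by = 0.1), 1)
  mass <- rep(1, length(grid))
  mass[c(1, length(grid))] <- 0.5
  breaks <- seq(lo, hi, length.out = bins + 1)
  gbin <- cut(grid, breaks, include.lowest = TRUE)
  p <- as.vector(tapply(mass, gbin, sum))
  p <- p / sum(p)
  obs <- as.vector(table(cut(values, breaks, include.lowest = TRUE)))
  stats::chisq.test(obs, p = p)
}

#' Required sample size for a binomial proportion confidence interval
#'
#' Standard normal-approximation formula `ceiling(z^2 p (1 - p) / d^2)` for a
#' two-sided interval of half-width `d` around an anticipated proportion `p`.
#'
#' @param target_precision anticipated proportion `p`, in (0, 1).
#' @param half_width CI half-width `d`, in (0, 1).
#' @param confidence confidence level, in (0, 1).
#' @return integer sample size.
#' @export
required_sample_size <- function(target_precision, half_width, confidence = 0.95) {
  if (!(target_precision > 0 && target_precision < 1)) stop("target_precision must be in (0,1)", call. = FALSE)
  if (!(half_width > 0 && half_width < 1)) stop("half_width must be in (0,1)", call. = FALSE)
  if (!(confidence > 0 && confidence < 1)) stop("confidence must be in (0,1)", call. = FALSE)
  z <- stats::qnorm(1 - (1 - confidence) / 2)
  as.integer(ceiling(z^2 * target_precision * (1 - target_precision) / half_width^2))
}
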