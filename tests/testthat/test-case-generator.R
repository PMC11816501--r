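test_that("generated case inputs always satisfy the chapter constraints", {
  cons <- demo_generation_constraints("glycemic_management", demo_kb, demo_cat)
  inputs <- generate_case_inputs(cons, 200, seed = 42)
  expect_length(inputs, 200)
  ok <- vapply(inputs, function(rec) {
    validate_patient_record(rec, demo_cat, "glycemic_management",
                            class_table = demo_kb$substances)$valid
  }, logical(1))
  expect_true(all(ok))
})

test_that("generation is deterministic in (constraints, n, seed) and n = 0 is empty", {
  cons <- demo_generation_constraints("dyslipidemia", demo_kb, demo_cat)
  a <- generate_case_inputs(cons, 25, seed = 7)
  b <- generate_case_inputs(cons, 25, seed = 7)
  expect_identical(a, b)
  expect_length(generate_case_inputs(cons, 0, seed = 7), 0)
})

test_that("unsatisfiable constraints name the offending parameter", {
  expect_error(
    generation_constraints(demo_cat, "glycemic_management", demo_kb,
                           ranges = list(hba1c = c(25, 30))),
    "hba1c", class = "cdsrules_config_error")
})

test_that("predicted-positive cases are re-evaluation stable", {
  cons <- demo_generation_constraints("blood_pressure", demo_kb, demo_cat)
  inputs <- generate_case_inputs(cons, 10, seed = 5)
  cases <- build_test_cases(inputs, demo_kb, demo_cat, "blood_pressure")
  expect_length(cases, 10)
  for (cs in cases) {
    expect_equal(cs$polarity, "PP")
    rs <- eval_chapter(cs$input, "blood_pressure")
    expect_identical(serialize_prediction(rs), serialize_prediction(cs$prediction))
  }
  expect_length(build_test_cases(list(), demo_kb, demo_cat, "blood_pressure"), 0)
})

test_that("an invalid input aborts case construction naming the case", {
  bad <- make_record(list(sbp = 500))
  expect_error(build_test_cases(list(bad), demo_kb, demo_cat, "blood_pressure"),
               "input 1")
})

test_that("study allocation reproduces the published design arithmetic", {
  shares <- c(glycemic_management = 0.3, dyslipidemia = 0.3,
              blood_pressure = 0.3, antiplatelet = 0.1)
  alloc <- allocate_study_cases(1000, shares, 0.05, seed = 1)
  expect_equal(sum(alloc$chapters$n_pn), 50)
  expect_equal(alloc$chapters$n_pn, c(15, 15, 15, 5))
  expect_equal(sum(alloc$chapters$n_cases), 1000)

  # fixed per-chapter base counts plus explicit buffer reproduce 297/297/297/109
  alloc2 <- allocate_study_cases(1000, shares, 0.05, seed = 1,
                                 base_counts = c(glycemic_management = 271,
                                                 dyslipidemia = 271,
                                                 blood_pressure = 271,
                                                 antiplatelet = 101),
                                 buffer = c(26, 26, 26, 8))
  expect_equal(alloc2$chapters$n_cases, c(297, 297, 297, 109))

  # no predicted negatives when the fraction is zero
  alloc3 <- allocate_study_cases(200, shares, 0, seed = 1)
  expect_equal(sum(alloc3$chapters$n_pn), 0)

  expect_error(allocate_study_cases(100, c(a = 0.5, b = 0.4), 0.05, 1), "sum to 1")
})

test_that("allocation conserves totals over randomized designs", {
  withr::with_seed(11, {
    for (i in 1:20) {
      total <- sample(50:2000, 1)
      w <- stats::runif(4)
      shares <- stats::setNames(w / sum(w), CHAPTERS)
      pf <- stats::runif(1, 0, 0.2)
      alloc <- allocate_study_cases(total, shares, pf, seed = i)
      expect_equal(sum(alloc$chapters$n_cases), total)
      expect_equal(sum(alloc$chapters$n_pn), round(pf * total))
      expect_true(all(alloc$chapters$n_pn <= alloc$chapters$n_cases))
      for (ch in CHAPTERS) {
        expect_length(alloc$pn_positions[[ch]],
                      alloc$chapters$n_pn[alloc$chapters$chapter == ch])
      }
    }
  })
})

test_that("swapping predictions between differing cases yields a verified PN", {
  cons <- demo_generation_constraints("glycemic_management", demo_kb, demo_cat)
  inputs <- generate_case_inputs(cons, 12, seed = 21)
  cases <- build_test_cases(inputs, demo_kb, demo_cat, "glycemic_management")
  pn <- make_predicted_negative(cases[[1]], cases, "swap_with_other",
                                demo_kb, demo_cat, seed = 3)
  expect_equal(pn$polarity, "PN")
  truth <- eval_chapter(pn$input, "glycemic_management")
  expect_false(identical(serialize_prediction(pn$prediction),
                         serialize_prediction(truth)))
  expect_match(pn$mutation$detail, "swapped")
})

test_that("altering a recommended agent guarantees a mismatch", {
  cons <- demo_generation_constraints("dyslipidemia", demo_kb, demo_cat)
  inputs <- generate_case_inputs(cons, 5, seed = 8)
  cases <- build_test_cases(inputs, demo_kb, demo_cat, "dyslipidemia")
  pn <- make_predicted_negative(cases[[2]], cases, "alter_recommendation",
                                demo_kb, demo_cat, seed = 4)
  truth <- eval_chapter(pn$input, "dyslipidemia")
  expect_false(identical(serialize_prediction(pn$prediction),
                         serialize_prediction(truth)))
  expect_equal(pn$polarity, "PN")
})

test_that("a swap pool containing only the case itself is an error", {
  cons <- demo_generation_constraints("antiplatelet", demo_kb, demo_cat)
  inputs <- generate_case_inputs(cons, 1, seed = 9)
  cases <- build_test_cases(inputs, demo_kb, demo_cat, "antiplatelet")
  expect_error(make_predicted_negative(cases[[1]], cases, "swap_with_other",
                                       demo_kb, demo_cat, seed = 1),
               "no other case")
})

test_that("the binomial sample-size formula matches direct arithmetic", {
  # oracle: ceiling(qnorm(.975)^2 * 0.25 / 0.05^2) = ceiling(384.146) = 385
  expect_equal(required_sample_size(0.5, 0.05, 0.95), 385L)
  expect_equal(required_sample_size(0.5, 0.5, 0.95), 4L)
  expect_error(required_sample_size(0.5, 0.05, 0))
  expect_error(required_sample_size(0.5, 0.05, 1))
  expect_error(required_sample_size(0, 0.05, 0.95))
})

test_that("an unchanged knowledge base produces an empty baseline diff", {
  cons <- demo_generation_constraints("glycemic_management", demo_kb, demo_cat)
  inputs <- generate_case_inputs(cons, 15, seed = 31)
  cases <- build_test_cases(inputs, demo_kb, demo_cat, "glycemic_management")
  suite <- baseline_snapshot(cases, demo_kb)
  diff <- compare_to_baseline(suite, demo_kb, demo_cat, cases)
  expect_true(diff$identical)
  expect_equal(nrow(diff$changed), 0)
})

test_that("editing a main-rule threshold flags exactly the crossing cases", {
  cons <- demo_generation_constraints("glycemic_management", demo_kb, demo_cat)
  inputs <- generate_case_inputs(cons, 40, seed = 32)
  cases <- build_test_cases(inputs, demo_kb, demo_cat, "glycemic_management")
  suite <- baseline_snapshot(cases, demo_kb)

  kb2 <- demo_kb
  kb2$version <- "1.1"
  bump <- function(cond) {
    if (!is.list(cond)) return(cond)
    if (!is.null(cond$param) && cond$param == "hba1c" && cond$value == 7.0) {
      cond$value <- 8.5
    }
    for (k in c("all", "any")) {
      if (!is.null(cond[[k]])) cond[[k]] <- lapply(cond[[k]], bump)
    }
    if (!is.null(cond$not)) cond$not <- bump(cond$not)
    cond
  }
  for (i in seq_along(kb2$rules)) {
    kb2$rules[[i]]$condition <- bump(kb2$rules[[i]]$condition)
  }
  diff <- compare_to_baseline(suite, kb2, demo_cat, cases)
  # oracle: re-evaluate each case under both rule sets and compare directly
  expected_changed <- vapply(cases, function(cs) {
    a <- serialize_prediction(eval_chapter(cs$input, "glycemic_management"))
    b <- serialize_prediction(evaluate_record(
      evaluation_request(cs$input, "glycemic_management"), kb2, demo_cat))
    !identical(a, b)
  }, logical(1))
  expect_setequal(diff$changed$id,
                  vapply(cases, function(c) c$id, character(1))[expected_changed])
  expect_gt(nrow(diff$changed), 0)
})

test_that("cases absent from the baseline are reported as new", {
  cons <- demo_generation_constraints("antiplatelet", demo_kb, demo_cat)
  inputs <- generate_case_inputs(cons, 5, seed = 33)
  cases <- build_test_cases(inputs, demo_kb, demo_cat, "antiplatelet")
  suite <- baseline_snapshot(cases[1:4], demo_kb)
  diff <- compare_to_baseline(suite, demo_kb, demo_cat, cases)
  expect_equal(diff$new_cases, cases[[5]]$id)
  expect_false(diff$identical)
})
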