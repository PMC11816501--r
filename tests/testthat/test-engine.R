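test_that("metabolic decompensation yields insulin as primary therapy, without metformin", {
  rec <- make_record(list(metabolic_decompensation = TRUE, hba1c = 12))
  rs <- eval_chapter(rec, "glycemic_management")
  recs <- rec_summary(rs, "glycemic_management")
  expect_true("add_class:insulin" %in% recs)
  classes <- vapply(rs$chapters$glycemic_management,
                    function(r) r$class %||% "", character(1))
  expect_false("biguanide" %in% classes)
})

test_that("a record at all targets yields only no-change and feedback output", {
  rs <- evaluate_record(evaluation_request(make_record(), CHAPTERS), demo_kb, demo_cat)
  for (ch in CHAPTERS) {
    actions <- vapply(rs$chapters[[ch]], function(r) r$action, character(1))
    expect_equal(unique(actions), "no_change", info = ch)
  }
})

test_that("heart failure above A1C target on metformin triggers an SGLT2i by addition for cardiorenal protection", {
  rec <- make_record(list(hf = TRUE, hba1c = 8.4), regimen = "metformin")
  rs <- eval_chapter(rec, "glycemic_management")
  sglt <- Filter(function(r) identical(r$class, "SGLT2i"), rs$chapters$glycemic_management)
  expect_equal(length(sglt), 1)
  expect_equal(sglt[[1]]$action, "add_class")
  expect_equal(sglt[[1]]$rec_type, "by_addition")
  expect_equal(sglt[[1]]$aim, "cardiorenal_protection")
  expect_true(length(sglt[[1]]$references) >= 1)
  trail <- audit_trail(rs)
  expect_true("GLY-M-04" %in% trail$rule_id)
})

test_that("a safety rule removes a contraindicated recommendation and audits it", {
  rec <- make_record(list(hf = TRUE, hba1c = 8.4, egfr = 25))
  rs <- eval_chapter(rec, "glycemic_management")
  classes <- vapply(rs$chapters$glycemic_management, function(r) r$class %||% "", character(1))
  expect_false("SGLT2i" %in% classes)
  expect_true(any(rs$notes$rule_id == "GLY-S-01"))
  trail <- audit_trail(rs)
  expect_true(any(trail$layer == "safety" & trail$rule_id == "GLY-S-01" &
                    trail$effect == "removed"))
})

test_that("a layer with no matching rules returns the draft unchanged", {
  rec <- make_record(list(hf = TRUE, hba1c = 8.4))
  draft <- eval_chapter(rec, "glycemic_management")
  after <- apply_rule_layer(draft, "safety", rec, demo_kb) # eGFR 90: nothing fires
  expect_equal(serialize_prediction(after), serialize_prediction(draft))
})

test_that("master rules overrule safety rules on the same recommendation", {
  # synthetic knowledge base: main recommends SGLT2i, safety removes it,
  # master re-issues it; the master directive must win
  kb <- tiny_kb(list(
    list(id = "T-M1", type = "main", chapter = "glycemic_management", cluster = "c",
         priority = 1, condition = list(always = TRUE),
         actions = list(list(action = "add_class", class = "SGLT2i")),
         references = list("r")),
    list(id = "T-S1", type = "safety", chapter = "glycemic_management",
         priority = 1, condition = list(always = TRUE),
         effects = list(list(effect = "remove", class = "SGLT2i", note = "safety out")),
         references = list("r")),
    list(id = "T-X1", type = "master", priority = 1,
         condition = list(always = TRUE),
         effects = list(list(effect = "recommend", action = "add_class", class = "SGLT2i")),
         references = list("r"))))
  rec <- make_record()
  rs <- evaluate_record(evaluation_request(rec, "glycemic_management"), kb, demo_cat,
                        validate = FALSE)
  classes <- vapply(rs$chapters$glycemic_management, function(r) r$class %||% "", character(1))
  expect_true("SGLT2i" %in% classes)
  trail <- audit_trail(rs)
  expect_true(any(trail$layer == "master" & trail$effect == "overruled"))
})

test_that("replacement recommendations carry both agents and the by_replacement type", {
  rec <- make_record(list(hba1c = 8.2), regimen = c("metformin", "sitagliptin"))
  rs <- eval_chapter(rec, "glycemic_management")
  repl <- Filter(function(r) r$action == "replace", rs$chapters$glycemic_management)
  expect_equal(length(repl), 1)
  expect_equal(repl[[1]]$class, "GLP-1RA")
  expect_equal(repl[[1]]$replaces, "DPP-4i")
  expect_equal(repl[[1]]$rec_type, "by_replacement")
  # the incretin inter-chapter rule also asks to stop the DPP-4i
  actions <- rec_summary(rs, "glycemic_management")
  expect_true("discontinue:DPP-4i" %in% actions)
})

test_that("annotation is idempotent and never alters drug content", {
  rec <- make_record(list(hf = TRUE, hba1c = 8.4), regimen = "metformin")
  rs <- eval_chapter(rec, "glycemic_management")
  again <- annotate_recommendations(rs, rec, demo_kb)
  expect_equal(serialize_prediction(again), serialize_prediction(rs))
})

test_that("renal dose bands map eGFR to the right guidance", {
  # eGFR 38: SGLT2i falls in the reduced band [30, 45)
  rec <- make_record(list(hf = TRUE, hba1c = 8.4, egfr = 38))
  rs <- eval_chapter(rec, "glycemic_management")
  sglt <- Filter(function(r) identical(r$class, "SGLT2i"), rs$chapters$glycemic_management)
  expect_match(sglt[[1]]$dose_guidance, "reduced dose")
  expect_equal(sglt[[1]]$renal_flag, "renal dose adjustment")

  # eGFR 120 is above every band: standard dose
  rec <- make_record(list(hf = TRUE, hba1c = 8.4, egfr = 120))
  rs <- eval_chapter(rec, "glycemic_management")
  sglt <- Filter(function(r) identical(r$class, "SGLT2i"), rs$chapters$glycemic_management)
  expect_equal(sglt[[1]]$dose_guidance, "standard dose")

  # missing eGFR: guidance withheld and flagged
  params <- base_params(); params$egfr <- NULL
  rec <- patient_record(utils::modifyList(params, list(hf = TRUE, hba1c = 8.4)))
  draft <- evaluate_record(evaluation_request(rec, "glycemic_management"),
                           demo_kb, demo_cat, validate = FALSE)
  sglt <- Filter(function(r) identical(r$class, "SGLT2i"), draft$chapters$glycemic_management)
  expect_null(sglt[[1]]$dose_guidance)
  expect_match(sglt[[1]]$renal_flag, "not assessed")
})

test_that("invalid records are rejected with the validation report attached", {
  err <- tryCatch(eval_chapter(make_record(list(hba1c = 45)), "glycemic_management"),
                  error = function(e) e)
  expect_s3_class(err, "cdsrules_invalid_record")
  expect_false(err$report$valid)
})

test_that("a knowledge-base version pin mismatch is a configuration error", {
  rec <- make_record()
  expect_error(
    evaluate_record(evaluation_request(rec, "glycemic_management", kb_version = "9.9"),
                    demo_kb, demo_cat),
    class = "cdsrules_config_error")
})

test_that("two evaluations of the same request serialize byte-identically", {
  rec <- make_record(list(hf = TRUE, ckd = TRUE, hba1c = 9.1, egfr = 52),
                     regimen = c("metformin", "empagliflozin", "gliclazide"))
  a <- evaluate_record(evaluation_request(rec, CHAPTERS), demo_kb, demo_cat)
  b <- evaluate_record(evaluation_request(rec, CHAPTERS), demo_kb, demo_cat)
  expect_identical(serialize_prediction(a), serialize_prediction(b))
  expect_identical(canonical_json <- cdsrules:::canonical_json(audit_trail(a)),
                   cdsrules:::canonical_json(audit_trail(b)))
})

test_that("pregnancy master rule withdraws contraindicated agents across chapters", {
  rec <- make_record(list(pregnancy = TRUE, hba1c = 8.5, hf = TRUE,
                          sbp = 150, age = 45, ascvd = FALSE))
  rs <- evaluate_record(evaluation_request(rec, CHAPTERS), demo_kb, demo_cat)
  for (ch in CHAPTERS) {
    classes <- vapply(rs$chapters[[ch]], function(r) r$class %||% "", character(1))
    expect_false(any(classes %in% c("SGLT2i", "GLP-1RA", "statin", "ACEi_ARB")),
                 info = ch)
  }
  expect_true(any(rs$notes$rule_id == "MR-01"))
})

test_that("procedural master hooks run last and are audited", {
  rec <- make_record(list(hf = TRUE, hba1c = 8.4))
  hook <- function(draft, record, kb) {
    draft$chapters$glycemic_management <- list(
      cdsrules:::new_rec("glycemic_management", "no_change",
                         references = "hook", rule_ids = "hook-1"))
    draft
  }
  rs <- evaluate_record(evaluation_request(rec, "glycemic_management"),
                        demo_kb, demo_cat, master_hooks = list(override = hook))
  expect_equal(rec_summary(rs, "glycemic_management"), "no_change:")
  trail <- audit_trail(rs)
  expect_true(any(trail$rule_id == "override" & trail$effect == "overruled"))
})
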