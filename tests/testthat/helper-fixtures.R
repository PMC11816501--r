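# Shared fixtures: demo knowledge base / catalogue (loaded once per run) and
# record builders with clinically sensible defaults.

demo_kb <- load_demo_knowledge_base()
demo_cat <- load_demo_catalogue()

# A record valid for every chapter: all targets met, no comorbidity flags.
# Age below 40 so the primary-prevention statin rule stays silent.
base_params <- function() {
  list(age = 38, hba1c = 6.5, egfr = 90, ldl_c = 2.0, sbp = 120, dbp = 75,
       potassium = 4.2, ascvd = FALSE, hf = FALSE, ckd = FALSE,
       metabolic_decompensation = FALSE, symptomatic_hyperglycemia = FALSE,
       pregnancy = FALSE, bleeding_risk = FALSE, frailty = FALSE)
}

make_record <- function(overrides = list(), regimen = character(0)) {
  params <- utils::modifyList(base_params(), overrides)
  patient_record(params, regimen)
}

eval_chapter <- function(record, chapter, kb = demo_kb, catalogue = demo_cat, ...) {
  evaluate_record(evaluation_request(record, chapter), kb, catalogue, ...)
}

rec_summary <- function(rs, chapter) {
  vapply(rs$chapters[[chapter]], function(r) {
    paste(r$action, r$class %||% r$substance %||% "", sep = ":")
  }, character(1))
}

# Lightweight stand-in test case for assignment tests (no engine run needed).
stub_case <- function(id, chapter, polarity = "PP") {
  structure(list(id = id, chapter = chapter, input = NULL, prediction = NULL,
                 polarity = polarity, mutation = NULL),
            class = "test_case")
}

# A tiny synthetic knowledge base built in code, used to probe layer
# precedence and validation seeding without touching the demo content.
tiny_kb <- function(rules, substances = c(metformin = "biguanide",
                                          empagliflozin = "SGLT2i",
                                          semaglutide = "GLP-1RA")) {
  structure(list(version = "tiny-1", name = "tiny", banner = NULL,
                 chapters = list(list(id = "glycemic_management",
                                      title = "Glycemic management",
                                      references = list("tiny ref"))),
                 rules = rules, substances = substances, dose_table = list()),
            class = "knowledge_base")
}
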