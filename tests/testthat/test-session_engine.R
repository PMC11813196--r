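test_that("a fresh session on the default KB presents the always-enabled items", {
  kb <- default_kb_cached()
  s <- new_session(kb)
  expect_length(active_findings(s), 0L)
  en <- enabled_items(s)
  # 13 interview + 1 examination always-enabled items; the synthesis item
  # is also enabled for all patients
  expect_identical(sum(en$phase == "interview"), 13L)
  expect_identical(sum(en$phase == "examination"), 1L)
  expect_identical(sum(en$phase == "synthesis"), 1L)
  # interview items precede examination items, which precede synthesis
  expect_identical(en$phase, en$phase[order(match(
    en$phase, c("interview", "examination", "synthesis")))])
})

test_that("a minimal KB session enables exactly its one item and an invalid KB is refused", {
  s <- new_session(minimal_kb())
  expect_identical(enabled_items(s)$item_id, "q1")

  bad <- minimal_kb_list()
  bad$diagnoses[[1]]$rule <- list(atom = list(item = "zz", response = "present"))
  bad$diagnoses[[1]]$evidence_atoms <- list(list(item = "zz", response = "present"))
  expect_error(new_session(kb_from_list(bad)), class = "lbp_integrity_error")
})

test_that("recording and retracting findings enforces enablement and domains", {
  kb <- default_kb_cached()
  s <- new_session(kb)
  s <- record_finding(s, "buttock_pain", "present")
  expect_length(s$findings, 1L)

  # conditional item before its condition holds
  expect_error(record_finding(s, "dermatomal_distribution", "present"),
               class = "lbp_enablement_error")
  expect_error(record_finding(s, "no_such_item", "present"),
               class = "lbp_integrity_error")
  expect_error(record_finding(s, "buttock_pain", "maybe"),
               class = "lbp_domain_error")

  s <- retract_finding(s, "buttock_pain")
  expect_length(s$findings, 0L)
  expect_error(retract_finding(s, "buttock_pain"),
               class = "lbp_not_found_error")
})

test_that("recording then retracting an enabler restores the empty-findings enabled set", {
  kb <- default_kb_cached()
  s0 <- new_session(kb)
  base <- enabled_items(s0)$item_id
  s <- record_finding(s0, "sensory_changes_nerve_root", "present")
  expect_gt(nrow(enabled_items(s)), length(base))
  s <- retract_finding(s, "sensory_changes_nerve_root")
  expect_identical(enabled_items(s)$item_id, base)
})

test_that("findings on newly disabled items are retained but inactive, restored on re-enabling", {
  kb <- chain_kb()
  s <- new_session(kb)
  s <- record_finding(s, "A", "present")
  s <- record_finding(s, "B", "present")
  s <- retract_finding(s, "A")
  expect_true("B" %in% names(s$findings))
  expect_false("B" %in% names(active_findings(s)))
  s <- record_finding(s, "A", "present")
  expect_true("B" %in% names(active_findings(s)))
})

test_that("active findings are the greatest self-consistent subset (fixed point on a 3-chain)", {
  kb <- chain_kb()
  s <- new_session(kb)
  s <- record_finding(s, "A", "present")
  s <- record_finding(s, "B", "present")
  s <- record_finding(s, "C", "present")
  expect_setequal(names(active_findings(s)), c("A", "B", "C"))
  s <- retract_finding(s, "A")
  # B loses its enabler, and with B inactive so does C
  expect_length(active_findings(s), 0L)
  # every active finding is itself enabled given the active set
  af <- active_findings(s)
  for (id in names(af)) {
    expect_true(evaluate_expression(kb$items[[id]]$enabled_when, af))
  }
})

test_that("the patient summary orders phases correctly and ignores insertion order", {
  kb <- default_kb_cached()
  script <- list(
    c("lumbar_provocation", "present"),
    c("buttock_pain", "present"),
    c("pain_low_back", "present"))
  build <- function(ord) {
    s <- new_session(kb)
    for (f in script[ord]) s <- record_finding(s, f[1], f[2])
    patient_summary(s)
  }
  sm <- build(1:3)
  expect_identical(nrow(sm), 3L)
  expect_identical(sm$phase, c("interview", "interview", "examination"))
  for (ord in list(c(2, 1, 3), c(3, 2, 1))) {
    expect_identical(build(ord), sm)
  }
  expect_identical(nrow(patient_summary(new_session(kb))), 0L)
})

test_that("sessions round-trip through JSON and reject mismatched KB versions", {
  kb <- default_kb_cached()
  s <- new_session(kb)
  s <- record_finding(s, "buttock_pain", "present")
  s <- set_dx_selection(s, "dx_sacroiliac", "accepted")
  path <- withr::local_tempfile(fileext = ".json")
  save_session(s, path)
  s2 <- load_session(kb, path)
  expect_identical(s2$findings, s$findings)
  expect_identical(s2$dx_selections, s$dx_selections)
  expect_identical(s2$treatment_selections, s$treatment_selections)

  kb2 <- kb
  kb2$version <- "other-version"
  expect_error(load_session(kb2, path), class = "lbp_version_error")

  trunc <- withr::local_tempfile(fileext = ".json")
  writeLines(substr(paste(readLines(path), collapse = ""), 1, 40), trunc)
  expect_error(load_session(kb, trunc), class = "lbp_format_error")
})

test_that("enabled items are a pure function of the findings map", {
  kb <- default_kb_cached()
  set.seed(7)
  target <- c(sensory_changes_nerve_root = "present",
              buttock_pain = "present",
              pain_widespread = "present")
  reference <- NULL
  for (rep_i in 1:20) {
    # random interleaving of records/retracts that ends at `target`
    s <- new_session(kb)
    ops <- sample(c("noise", "final"), 8, replace = TRUE)
    for (op in ops) {
      if (op == "noise") {
        id <- sample(names(target), 1L)
        if (id %in% names(s$findings)) {
          s <- retract_finding(s, id)
        } else {
          s <- record_finding(s, id, "absent")
        }
      }
    }
    for (id in names(target)) {
      if (id %in% names(s$findings)) s <- retract_finding(s, id)
      s <- record_finding(s, id, target[[id]])
    }
    en <- enabled_items(s)
    if (is.null(reference)) reference <- en
    expect_identical(en, reference)
  }
})
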