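piriformis_findings <- function(which = c("radiating_leg_pain",
                                          "sciatic_notch_tenderness",
                                          "buttock_pain", "slr_positive",
                                          "increased_pain_prolonged_sitting")) {
  stats::setNames(rep("present", length(which)), which)
}

test_that("expression evaluation follows the unanswered-is-false convention", {
  kb <- default_kb_cached()
  rule <- kb$diagnoses[["dx_piriformis"]]$rule
  expect_true(evaluate_expression(rule, c(buttock_pain = "present")))
  expect_false(evaluate_expression(rule, character()))
  # a negated atom over an unanswered item fires
  expect_true(evaluate_expression(expr_not(expr_atom("buttock_pain")), character()))
  expect_false(evaluate_expression(
    expr_not(expr_atom("buttock_pain")), c(buttock_pain = "present")))
  # a recorded non-matching response also leaves the atom false
  expect_false(evaluate_expression(expr_atom("buttock_pain"),
                                   c(buttock_pain = "absent")))
  expect_error(
    evaluate_expression(expr_atom("nope"), character(), kb = kb),
    class = "lbp_integrity_error")
})

test_that("evaluator agrees with the truth-table oracle on random expressions", {
  pool <- data.frame(item = paste0("v", 1:6),
                     response = rep("present", 6),
                     stringsAsFactors = FALSE)
  set.seed(11)
  responses <- c("present", "absent")
  for (trial in 1:40) {
    e <- random_expr(pool, depth = 3L)
    # all 2^6 fully answered assignments
    grid <- expand.grid(rep(list(responses), 6), stringsAsFactors = FALSE)
    for (r in seq_len(nrow(grid))) {
      f <- stats::setNames(as.character(grid[r, ]), pool$item)
      expect_identical(evaluate_expression(e, f), oracle_eval(e, f))
    }
  }
  # and spot checks including unanswered items
  for (trial in 1:40) {
    e <- random_expr(pool, depth = 3L)
    ans <- sample(c("present", "absent", NA), 6, replace = TRUE)
    f <- stats::setNames(ans[!is.na(ans)], pool$item[!is.na(ans)])
    expect_identical(evaluate_expression(e, f), oracle_eval(e, f))
  }
})

test_that("evidence counting enumerates the satisfied piriformis atoms", {
  kb <- default_kb_cached()
  full <- evidence_count(kb, "dx_piriformis", piriformis_findings())
  expect_identical(full$count, 5L)

  one <- evidence_count(kb, "dx_piriformis", c(buttock_pain = "present"))
  expect_identical(one$count, 1L)
  expect_identical(one$supporting$item, "buttock_pain")
  expect_identical(one$supporting$response, "present")

  none <- evidence_count(kb, "dx_piriformis", character())
  expect_identical(none$count, 0L)
  expect_identical(nrow(none$supporting), 0L)
})

test_that("likeliness scale maps counts proportionally, hitting both anchors", {
  kb <- default_kb_cached()
  s <- new_session(kb)
  ev0 <- evaluate_diagnoses(kb, s)
  expect_true(all(!ev0$triggered))
  expect_true(all(ev0$scale_value == 0L))

  s1 <- record_finding(s, "buttock_pain", "present")
  ev1 <- evaluate_diagnoses(kb, s1)
  row <- ev1[ev1$dx_id == "dx_piriformis", ]
  expect_true(row$triggered)
  expect_identical(row$evidence_count, 1L)
  expect_identical(row$scale_value, 1L)   # ceiling(5 * 1/5)

  # all five findings -> full scale
  s5 <- s1
  s5 <- record_finding(s5, "radiating_leg_pain", "present")
  s5 <- record_finding(s5, "sciatic_notch_tenderness", "present")
  s5 <- record_finding(s5, "slr_positive", "present")
  s5 <- record_finding(s5, "increased_pain_prolonged_sitting", "present")
  ev5 <- evaluate_diagnoses(kb, s5)
  row <- ev5[ev5$dx_id == "dx_piriformis", ]
  expect_identical(row$evidence_count, 5L)
  expect_identical(row$scale_value, row$scale_max)
})

test_that("scale values stay within bounds and hit the maximum only on full evidence", {
  kb <- default_kb_cached()
  set.seed(23)
  for (i in 1:40) {
    sc <- generate_random_scenario(kb, seed = i)
    s <- replay_scenario(sc, kb)
    ev <- evaluate_diagnoses(kb, s)
    expect_true(all(ev$scale_value >= 0 & ev$scale_value <= ev$scale_max))
    expect_true(all(ev$scale_value[!ev$triggered] == 0L))
    expect_true(all(ev$scale_value[ev$triggered] >= 1L))
    for (r in seq_len(nrow(ev))) {
      n_atoms <- nrow(kb$diagnoses[[ev$dx_id[r]]]$evidence)
      if (ev$triggered[r]) {
        expect_identical(ev$scale_value[r] == ev$scale_max[r],
                         ev$evidence_count[r] == n_atoms)
      }
    }
  }
})

test_that("suppression requires strict evidence dominance between triggered competitors", {
  kb <- default_kb_cached()
  # piriformis 3 findings, claudication 4 -> suppressed with named reason
  s <- new_session(kb)
  for (f in c("radiating_leg_pain", "buttock_pain", "leg_symptoms_walking")) {
    s <- record_finding(s, f, "present")
  }
  s <- record_finding(s, "sciatic_notch_tenderness", "present")
  s <- record_finding(s, "extension_relief_walking", "present")
  s <- record_finding(s, "treadmill_provocation", "present")
  ev <- evaluate_diagnoses(kb, s)
  pir <- ev[ev$dx_id == "dx_piriformis", ]
  ncl <- ev[ev$dx_id == "dx_neurogenic_claudication", ]
  expect_identical(pir$evidence_count, 3L)
  expect_identical(ncl$evidence_count, 4L)
  expect_true(pir$suppressed)
  expect_match(pir$suppression_reason, "Neurogenic claudication")
  # counts and scale are untouched by suppression
  expect_identical(pir$scale_value, 3L)

  # equal counts -> no suppression
  s2 <- new_session(kb)
  for (f in c("buttock_pain", "leg_symptoms_walking")) {
    s2 <- record_finding(s2, f, "present")
  }
  ev2 <- evaluate_diagnoses(kb, s2)
  expect_false(ev2$suppressed[ev2$dx_id == "dx_piriformis"])

  # competitor untriggered -> no suppression
  s3 <- record_finding(new_session(kb), "buttock_pain", "present")
  ev3 <- evaluate_diagnoses(kb, s3)
  expect_false(ev3$triggered[ev3$dx_id == "dx_neurogenic_claudication"])
  expect_false(ev3$suppressed[ev3$dx_id == "dx_piriformis"])
})

test_that("supporting findings expose exactly the satisfied atoms, always within the active findings", {
  kb <- default_kb_cached()
  s <- new_session(kb)
  s <- record_finding(s, "buttock_pain", "present")
  s <- record_finding(s, "radiating_leg_pain", "present")
  sup <- supporting_findings(kb, s, "dx_piriformis")
  expect_setequal(sup$item, c("buttock_pain", "radiating_leg_pain"))
  af <- active_findings(s)
  expect_true(all(sup$item %in% names(af)))
  expect_error(supporting_findings(kb, s, "dx_unknown"),
               class = "lbp_not_found_error")
})

test_that("diagnosis ranking is a deterministic total order", {
  kb <- default_kb_cached()
  s <- replay_scenario(multifactorial_scenario(), kb)
  ev1 <- evaluate_diagnoses(kb, s)
  ev2 <- evaluate_diagnoses(kb, s)
  expect_identical(ev1, ev2)
  expect_identical(sort(ev1$dx_id), sort(kb$dx_order))
  # unsuppressed block first, scale non-increasing within it
  sup_idx <- which(ev1$suppressed)
  if (length(sup_idx) > 0L) {
    expect_true(min(sup_idx) > max(which(!ev1$suppressed)))
  }
  un <- ev1[!ev1$suppressed, ]
  expect_true(all(diff(un$scale_value) <= 0))
})

test_that("clinician selections support acceptance, rejection, override and reset", {
  kb <- default_kb_cached()
  s <- new_session(kb)
  s <- record_finding(s, "leg_symptoms_walking", "present")
  s <- set_dx_selection(s, "dx_neurogenic_claudication", "accepted")
  expect_identical(unname(s$dx_selections["dx_neurogenic_claudication"]),
                   "accepted")
  expect_false(s$dx_overrides[["dx_neurogenic_claudication"]])

  # accepting an untriggered diagnosis records an override marker
  s <- set_dx_selection(s, "dx_radicular", "accepted")
  expect_true(s$dx_overrides[["dx_radicular"]])

  s <- set_dx_selection(s, "dx_radicular", "undecided")
  expect_false("dx_radicular" %in% names(s$dx_selections))
  expect_false("dx_radicular" %in% names(s$dx_overrides))
  expect_error(set_dx_selection(s, "dx_missing", "accepted"),
               class = "lbp_not_found_error")
})

test_that("evidence counts are monotone in findings for negation-free rules", {
  kb <- default_kb_cached()
  set.seed(31)
  for (trial in 1:15) {
    sc <- generate_random_scenario(kb, seed = 1000 + trial)
    s <- new_session(kb)
    prev <- evaluate_diagnoses(kb, s)
    prev_counts <- stats::setNames(prev$evidence_count, prev$dx_id)
    for (f in sc$findings_script) {
      s <- record_finding(s, f$item, f$response)
      ev <- evaluate_diagnoses(kb, s)
      counts <- stats::setNames(ev$evidence_count, ev$dx_id)
      expect_true(all(counts[names(prev_counts)] >= prev_counts))
      prev_counts <- counts
    }
  }
})

test_that("evidence tables serialise to parseable JSON", {
  kb <- default_kb_cached()
  s <- replay_scenario(multifactorial_scenario(), kb)
  ev <- evaluate_diagnoses(kb, s)
  js <- evidence_to_json(ev)
  parsed <- jsonlite::fromJSON(js, simplifyVector = FALSE)
  expect_length(parsed, nrow(ev))
  expect_identical(parsed[[1]]$dx_id, ev$dx_id[1])
  expect_identical(length(parsed[[1]]$supporting), nrow(ev$supporting[[1]]))
})
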