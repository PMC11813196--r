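#' Built-in clinical scenarios
#'
#' The four fictional usability-test encounters, shipped as replayable
#' fixtures: acute nociceptive pain, chronic nociceptive pain, chronic
#' nociceptive pain combined with symptoms of neurogenic claudication,
#' and radicular pain. Each scenario carries a findings script authored
#' against the default knowledge base (respecting enabling order), the
#' diagnoses expected to top the ranking, and any diagnoses expected to
#' be rejected by the model.
#'
#' @return A list of exactly four `lbp_scenario` objects.
#' @seealso [multifactorial_scenario()] for the complex
#'   claudication-plus-nociplastic demonstration encounter.
#' @export
builtin_scenarios <- function() {
  nms <- c("acute_nociceptive", "chronic_nociceptive",
           "chronic_nociceptive_claudication", "radicular")
  lapply(nms, load_scenario)
}

#' The multifactorial demonstration scenario
#'
#' A complex encounter with evidence for all three pain-mechanism
#' macrodiagnoses, in which neurogenic claudication and nociplastic pain
#' carry the strongest evidence and piriformis syndrome -- although its
#' rule triggers -- is rejected by the model because its symptoms overlap
#' with neurogenic claudication and the evidence for neurogenic
#' claudication is stronger.
#'
#' @return An `lbp_scenario`.
#' @export
multifactorial_scenario <- function() {
  load_scenario("multifactorial")
}

load_scenario <- function(name) {
  path <- system.file("extdata", "scenarios", paste0(name, ".json"),
                      package = "lbpcds", mustWork = TRUE)
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  scenario_from_list(doc)
}

scenario_from_list <- function(doc) {
  structure(list(
    scenario_id = as.character(doc$scenario_id),
    title = if (is.null(doc$title)) as.character(doc$scenario_id)
            else as.character(doc$title),
    narrative = if (is.null(doc$narrative)) "" else as.character(doc$narrative),
    findings_script = lapply(doc$findings, function(f) {
      list(item = as.character(f$item),
           response = if (is.null(f$response)) "present"
                      else as.character(f$response))
    }),
    expected_top_dx = vapply(doc$expected_top_dx, as.character, ""),
    expected_suppressed = vapply(doc$expected_suppressed, as.character, "")
  ), class = "lbp_scenario")
}

#' Replay a scenario on a fresh session
#'
#' Records the scenario's findings script in order on a new session;
#' every step must respect the adaptive enabling logic (an enablement
#' error aborts the replay).
#'
#' @param scenario An `lbp_scenario`.
#' @param kb Knowledge base to replay against (default: the shipped KB).
#' @return The resulting `lbp_session`.
#' @export
replay_scenario <- function(scenario, kb = default_kb()) {
  s <- new_session(kb)
  for (f in scenario$findings_script) {
    s <- record_finding(s, f$item, f$response)
  }
  s
}

#' Generate a seeded random scenario
#'
#' Walks the knowledge base's items in enabling order (repeated passes in
#' declaration order until no newly enabled item remains), answering each
#' enabled item at random: `present` with probability `p_present`,
#' otherwise `absent` with probability `p_absent`, otherwise left
#' unanswered. When `target_dx` is given, its evidence atoms are instead
#' answered with their required response with probability `p_target`,
#' biasing the encounter toward that diagnosis. Deterministic for a given
#' `(kb, seed, target_dx)`; the emitted script replays cleanly because
#' answers are only ever recorded on currently enabled items.
#'
#' @param kb An `lbp_kb`.
#' @param seed Integer seed.
#' @param target_dx Optional diagnosis id to bias toward.
#' @param p_present Probability a non-target item is answered `present`.
#' @param p_absent Probability a non-target item is answered `absent`
#'   (given it was not answered `present`).
#' @param p_target Probability a target evidence atom receives its
#'   required response.
#' @return An `lbp_scenario` with a replayable findings script.
#' @export
generate_random_scenario <- function(kb, seed, target_dx = NULL,
                                     p_present = 0.3, p_absent = 0.5,
                                     p_target = 0.9) {
  if (!is.null(target_dx) && !target_dx %in% kb$dx_order) {
    lbp_not_found_error(sprintf("unknown target diagnosis `%s`", target_dx))
  }
  target_ev <- if (is.null(target_dx)) {
    data.frame(item = character(), response = character())
  } else {
    kb$diagnoses[[target_dx]]$evidence
  }

  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old_seed, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))

  s <- new_session(kb)
  script <- list()
  visited <- character(0L)
  repeat {
    en <- enabled_items(s)$item_id
    todo <- setdiff(en, visited)
    if (length(todo) == 0L) break
    # process in declaration order for determinism
    todo <- kb$item_order[kb$item_order %in% todo]
    for (id in todo) {
      visited <- c(visited, id)
      # item may have been disabled by an earlier answer in this pass
      if (!eval_expr_(kb$items[[id]]$enabled_when, active_findings(s))) next
      ti <- which(target_ev$item == id)
      resp <- NULL
      if (length(ti) > 0L) {
        if (stats::runif(1L) < p_target) resp <- target_ev$response[ti[1L]]
      } else {
        u <- stats::runif(1L)
        if (u < p_present) {
          resp <- "present"
        } else if (stats::runif(1L) < p_absent) {
          resp <- if ("absent" %in% kb$items[[id]]$responses) "absent"
                  else NULL
        }
      }
      if (!is.null(resp)) {
        s <- record_finding(s, id, resp)
        script[[length(script) + 1L]] <- list(item = id, response = resp)
      }
    }
  }
  structure(list(
    scenario_id = sprintf("random_seed_%d%s", as.integer(seed),
                          if (is.null(target_dx)) "" else paste0("_", target_dx)),
    title = "randomly generated encounter",
    narrative = sprintf(
      "Synthetic encounter generated with seed %d%s.", as.integer(seed),
      if (is.null(target_dx)) "" else sprintf(" targeting %s", target_dx)),
    findings_script = script,
    expected_top_dx = character(0L),
    expected_suppressed = character(0L)
  ), class = "lbp_scenario")
}

#' Write / read a scenario as JSON
#'
#' @param scenario An `lbp_scenario`.
#' @param path File path.
#' @return `write_scenario()` the path invisibly; `read_scenario()` the
#'   `lbp_scenario`.
#' @export
write_scenario <- function(scenario, path) {
  doc <- list(
    scenario_id = scenario$scenario_id,
    title = scenario$title,
    narrative = scenario$narrative,
    findings = scenario$findings_script,
    expected_top_dx = as.list(scenario$expected_top_dx),
    expected_suppressed = as.list(scenario$expected_suppressed)
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname write_scenario
#' @export
read_scenario <- function(path) {
  if (!file.exists(path)) {
    lbp_format_error(sprintf("scenario file not found: %s", path))
  }
  scenario_from_list(jsonlite::fromJSON(path, simplifyVector = FALSE))
}

#' @export
print.lbp_scenario <- function(x, ...) {
  cat(sprintf("<lbp_scenario> %s: %d scripted finding(s)\n",
              x$scenario_id, length(x$findings_script)))
  if (length(x$expected_top_dx) > 0L) {
    cat(sprintf("  expected top diagnoses: %s\n",
                paste(x$expected_top_dx, collapse = ", ")))
  }
  if (length(x$expected_suppressed) > 0L) {
    cat(sprintf("  expected rejected: %s\n",
                paste(x$expected_suppressed, collapse = ", ")))
  }
  invisible(x)
}
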