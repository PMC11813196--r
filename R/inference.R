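#' Evidence count for a diagnosis
#'
#' Counts how many of a diagnosis's evidence atoms are satisfied by a
#' findings map, and returns the satisfied atoms themselves (the
#' traceability set shown when hovering over a diagnosis).
#'
#' @param kb An `lbp_kb`.
#' @param dx_id Diagnosis identifier.
#' @param findings Findings map (named character vector or equivalent).
#' @return List with elements `count` (integer) and `supporting`
#'   (data frame of satisfied `(item, response)` atoms).
#' @export
evidence_count <- function(kb, dx_id, findings) {
  dx <- kb$diagnoses[[dx_id]]
  if (is.null(dx)) lbp_not_found_error(sprintf("unknown diagnosis `%s`", dx_id))
  f <- as_findings(findings)
  ev <- dx$evidence
  sat <- vapply(seq_len(nrow(ev)), function(i) {
    !is.na(f[ev$item[i]]) && identical(unname(f[ev$item[i]]), ev$response[i])
  }, logical(1L))
  list(count = sum(sat), supporting = ev[sat, , drop = FALSE])
}

# Likeliness mapping: untriggered -> 0; triggered -> ceiling-proportional
# count on the 1..scale_max display scale, clamped to at least 1.
scale_value_for <- function(triggered, count, n_atoms, scale_max) {
  if (!triggered) return(0L)
  if (n_atoms == 0L) return(scale_max)
  max(1L, as.integer(ceiling(scale_max * count / n_atoms)))
}

#' Evaluate all diagnoses against a session
#'
#' Produces one evidence row per knowledge-base diagnosis: whether its
#' Boolean rule is satisfied by the active findings, how many evidence
#' atoms are satisfied, the graded likeliness value on the diagnosis's
#' 1..`scale_max` display scale (0 when untriggered; `scale_max` anchors
#' "more likely", 1 anchors "less likely"), the supporting findings, and
#' the result of cross-diagnosis suppression. Output rows are sorted by
#' (unsuppressed first, likeliness descending, evidence count descending,
#' declaration order) -- a deterministic total order.
#'
#' @param kb An `lbp_kb`.
#' @param session An `lbp_session` bound to `kb`.
#' @return A data frame of class `lbp_evidence`; column `supporting` is a
#'   list column of data frames.
#' @export
evaluate_diagnoses <- function(kb, session) {
  af <- active_findings(session)
  rows <- lapply(kb$dx_order, function(id) {
    dx <- kb$diagnoses[[id]]
    triggered <- eval_expr_(dx$rule, af)
    ec <- evidence_count(kb, id, af)
    data.frame(
      dx_id = id, name = dx$name, level = dx$level,
      triggered = triggered,
      evidence_count = ec$count,
      scale_value = scale_value_for(triggered, ec$count,
                                    nrow(dx$evidence), dx$scale_max),
      scale_max = dx$scale_max,
      suppressed = FALSE,
      suppression_reason = NA_character_,
      stringsAsFactors = FALSE)
  })
  ev <- do.call(rbind, rows)
  ev$supporting <- lapply(kb$dx_order, function(id) {
    evidence_count(kb, id, af)$supporting
  })
  ev <- apply_suppression(ev, kb)
  ord <- order(ev$suppressed, -ev$scale_value, -ev$evidence_count,
               match(ev$dx_id, kb$dx_order))
  ev <- ev[ord, , drop = FALSE]
  rownames(ev) <- NULL
  class(ev) <- c("lbp_evidence", "data.frame")
  ev
}

#' Apply cross-diagnosis suppression
#'
#' For each suppressor entry declared in the knowledge base (diagnosis D
#' suppressed by competitor C), D is marked suppressed iff both are
#' triggered and C's evidence count strictly exceeds D's. Suppression is
#' a single pass over pre-suppression counts: it never alters counts or
#' scales, only the flag and its reason, and does not chain
#' transitively.
#'
#' @param evidences Evidence table as computed before suppression.
#' @param kb An `lbp_kb`.
#' @return The evidence table with `suppressed` / `suppression_reason`
#'   filled in.
#' @export
apply_suppression <- function(evidences, kb) {
  counts <- stats::setNames(evidences$evidence_count, evidences$dx_id)
  trig <- stats::setNames(evidences$triggered, evidences$dx_id)
  for (i in seq_len(nrow(evidences))) {
    dx <- kb$diagnoses[[evidences$dx_id[i]]]
    for (s in dx$suppressors) {
      if (!s$by %in% names(counts)) {
        lbp_integrity_error(sprintf(
          "suppressor of `%s` names unknown diagnosis `%s`", dx$id, s$by))
      }
      if (isTRUE(trig[[dx$id]]) && isTRUE(trig[[s$by]]) &&
          counts[[s$by]] > counts[[dx$id]]) {
        evidences$suppressed[i] <- TRUE
        evidences$suppression_reason[i] <- sprintf(
          "suppressed by %s: stronger evidence (%d vs %d findings)",
          kb$diagnoses[[s$by]]$name, counts[[s$by]], counts[[dx$id]])
      }
    }
  }
  evidences
}

#' Supporting findings for one diagnosis
#'
#' Traceability accessor: the exact `(item, response)` atoms of a
#' diagnosis satisfied by the session's active findings (what the
#' prototype highlights in the patient summary on hover).
#'
#' @param kb An `lbp_kb`.
#' @param session An `lbp_session`.
#' @param dx_id Diagnosis identifier.
#' @return Data frame of satisfied atoms (`item`, `response`).
#' @export
supporting_findings <- function(kb, session, dx_id) {
  if (!dx_id %in% kb$dx_order) {
    lbp_not_found_error(sprintf("unknown diagnosis `%s`", dx_id))
  }
  evidence_count(kb, dx_id, active_findings(session))$supporting
}

#' Record the clinician's diagnosis selection
#'
#' Clinicians may accept, reject, or reset to undecided any working
#' diagnosis, including accepting one the model did not trigger: such an
#' acceptance is recorded with an override marker rather than refused,
#' reflecting that the model output is advisory.
#'
#' @param session An `lbp_session`.
#' @param dx_id Diagnosis identifier.
#' @param state One of `"accepted"`, `"rejected"`, `"undecided"`.
#' @return The updated session.
#' @export
set_dx_selection <- function(session, dx_id, state) {
  kb <- session$kb
  if (!dx_id %in% kb$dx_order) {
    lbp_not_found_error(sprintf("unknown diagnosis `%s`", dx_id))
  }
  state <- match.arg(state, c("accepted", "rejected", "undecided"))
  if (state == "undecided") {
    session$dx_selections <-
      session$dx_selections[names(session$dx_selections) != dx_id]
    session$dx_overrides <-
      session$dx_overrides[names(session$dx_overrides) != dx_id]
  } else {
    session$dx_selections[[dx_id]] <- state
    if (state == "accepted") {
      ev <- evaluate_diagnoses(kb, session)
      session$dx_overrides[[dx_id]] <-
        !ev$triggered[ev$dx_id == dx_id] || ev$scale_value[ev$dx_id == dx_id] == 0L
    } else {
      session$dx_overrides <-
        session$dx_overrides[names(session$dx_overrides) != dx_id]
    }
  }
  touch(session)
}

accepted_dx <- function(session) {
  names(session$dx_selections)[session$dx_selections == "accepted"]
}

#' Serialise an evidence table to JSON
#'
#' @param evidences An `lbp_evidence` table.
#' @return A JSON string (array of per-diagnosis objects).
#' @export
evidence_to_json <- function(evidences) {
  rows <- lapply(seq_len(nrow(evidences)), function(i) {
    sup <- evidences$supporting[[i]]
    list(
      dx_id = evidences$dx_id[i],
      name = evidences$name[i],
      level = evidences$level[i],
      triggered = evidences$triggered[i],
      evidence_count = evidences$evidence_count[i],
      scale_value = evidences$scale_value[i],
      scale_max = evidences$scale_max[i],
      supporting = lapply(seq_len(nrow(sup)), function(j) {
        list(item = sup$item[j], response = sup$response[j])
      }),
      suppressed = evidences$suppressed[i],
      suppression_reason = if (is.na(evidences$suppression_reason[i])) NULL
                           else evidences$suppression_reason[i]
    )
  })
  as.character(jsonlite::toJSON(rows, auto_unbox = TRUE, null = "null"))
}

#' @export
print.lbp_evidence <- function(x, ...) {
  cat("Working diagnoses (ranked)\n")
  for (i in seq_len(nrow(x))) {
    bar <- if (x$scale_value[i] > 0L) {
      paste0("[", strrep("#", x$scale_value[i]),
             strrep(".", x$scale_max[i] - x$scale_value[i]), "]")
    } else {
      paste0("[", strrep(".", x$scale_max[i]), "]")
    }
    flag <- if (x$suppressed[i]) "  (rejected by model)" else ""
    cat(sprintf("  %s %-32s %d finding(s)%s\n",
                bar, x$name[i], x$evidence_count[i], flag))
  }
  invisible(x)
}
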