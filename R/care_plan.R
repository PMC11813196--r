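#' Treatment recommendations for accepted diagnoses
#'
#' Returns every treatment whose `applies_to` set intersects the accepted
#' diagnoses, plus all treatments that apply to every working diagnosis
#' (`ALL`), de-duplicated. Each treatment carries its contributing
#' diagnoses (the intersection; the full accepted set for `ALL`
#' treatments). Ordering is by number of contributing diagnoses
#' descending -- absent published evidence weights, breadth of
#' contribution is the only principled priority -- with ties broken by
#' knowledge-base declaration order.
#'
#' @param kb An `lbp_kb`.
#' @param accepted Character vector of accepted diagnosis ids (non-empty).
#' @return Data frame with columns `treatment_id`, `name`,
#'   `contributing` (list column of dx id vectors), `priority_note`.
#' @export
recommend_treatments <- function(kb, accepted) {
  if (length(accepted) == 0L) {
    lbp_empty_plan_error("a care plan requires at least one accepted diagnosis")
  }
  bad <- setdiff(accepted, kb$dx_order)
  if (length(bad) > 0L) {
    lbp_not_found_error(sprintf("unknown diagnosis id(s): %s",
                                paste(bad, collapse = ", ")))
  }
  rows <- lapply(kb$tx_order, function(id) {
    tx <- kb$treatments[[id]]
    contrib <- if (identical(tx$applies_to, "ALL")) {
      accepted
    } else {
      intersect(tx$applies_to, accepted)
    }
    if (length(contrib) == 0L) return(NULL)
    list(treatment_id = id, name = tx$name,
         contributing = contrib, priority_note = tx$priority_note)
  })
  rows <- Filter(Negate(is.null), rows)
  if (length(rows) == 0L) {
    return(data.frame(treatment_id = character(), name = character(),
                      priority_note = character(),
                      stringsAsFactors = FALSE))
  }
  out <- data.frame(
    treatment_id = vapply(rows, `[[`, "", "treatment_id"),
    name = vapply(rows, `[[`, "", "name"),
    priority_note = vapply(rows, `[[`, NA_character_, "priority_note"),
    stringsAsFactors = FALSE)
  out$contributing <- lapply(rows, `[[`, "contributing")
  n_contrib <- vapply(out$contributing, length, integer(1L))
  out <- out[order(-n_contrib, match(out$treatment_id, kb$tx_order)), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Patient education materials for accepted diagnoses
#'
#' Union of the education materials linked to the accepted diagnoses,
#' de-duplicated, in knowledge-base declaration order.
#'
#' @param kb An `lbp_kb`.
#' @param accepted Character vector of accepted diagnosis ids.
#' @return Data frame with columns `edu_id`, `title`, `body`.
#' @export
select_education <- function(kb, accepted) {
  bad <- setdiff(accepted, kb$dx_order)
  if (length(bad) > 0L) {
    lbp_not_found_error(sprintf("unknown diagnosis id(s): %s",
                                paste(bad, collapse = ", ")))
  }
  ids <- unique(unlist(lapply(accepted, function(d) {
    kb$diagnoses[[d]]$education
  })))
  ids <- kb$edu_order[kb$edu_order %in% ids]
  data.frame(
    edu_id = ids,
    title = vapply(ids, function(i) kb$education[[i]]$title, "",
                   USE.NAMES = FALSE),
    body = vapply(ids, function(i) kb$education[[i]]$body, "",
                  USE.NAMES = FALSE),
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Build the care plan for a session
#'
#' Combines the clinician's accepted diagnoses with treatment
#' recommendations and education materials. All recommended treatments
#' default to selected (on); [toggle_treatment()] switches individual
#' ones off, and the export reflects only selected treatments.
#'
#' @param kb An `lbp_kb`.
#' @param session An `lbp_session` with at least one accepted diagnosis.
#' @return Object of class `lbp_care_plan`.
#' @export
build_care_plan <- function(kb, session) {
  acc <- accepted_dx(session)
  tx <- recommend_treatments(kb, acc)   # raises empty-plan error if none
  sel <- vapply(tx$treatment_id, function(id) {
    if (id %in% names(session$treatment_selections)) {
      session$treatment_selections[[id]]
    } else TRUE
  }, logical(1L))
  structure(list(
    accepted = acc,
    treatments = tx,
    selected = stats::setNames(sel, tx$treatment_id),
    education = select_education(kb, acc),
    generated = utc_now()
  ), class = "lbp_care_plan")
}

#' Toggle a treatment recommendation on or off
#'
#' @param session An `lbp_session`.
#' @param treatment_id A treatment currently in the session's plan.
#' @param on Logical: selected state.
#' @return The updated session.
#' @export
toggle_treatment <- function(session, treatment_id, on = TRUE) {
  plan_tx <- recommend_treatments(session$kb, accepted_dx(session))
  if (!treatment_id %in% plan_tx$treatment_id) {
    lbp_not_found_error(sprintf(
      "treatment `%s` is not part of the current care plan", treatment_id))
  }
  session$treatment_selections[[treatment_id]] <- isTRUE(on)
  touch(session)
}

#' Export a copy-pasteable clinical note
#'
#' Renders the encounter as deterministic plain text: the patient
#' summary, the accepted working diagnoses with their likeliness grades
#' and supporting findings, the selected treatments with contributing
#' diagnoses, and the education material titles. A pure function of its
#' inputs: identical sessions produce byte-identical notes.
#'
#' @param session An `lbp_session`.
#' @param evidences Evidence table from [evaluate_diagnoses()].
#' @param plan Care plan from [build_care_plan()].
#' @return A single character string (UTF-8 plain text).
#' @export
export_note <- function(session, evidences, plan) {
  if (length(plan$accepted) == 0L) {
    lbp_empty_plan_error("cannot export a note without accepted diagnoses")
  }
  kb <- session$kb
  out <- c("LOW BACK PAIN CDS NOTE", strrep("=", 22), "")

  out <- c(out, "PATIENT SUMMARY")
  sm <- patient_summary(session)
  if (nrow(sm) == 0L) {
    out <- c(out, "  (no findings recorded)")
  } else {
    for (ph in unique(sm$phase)) {
      rows <- sm[sm$phase == ph, , drop = FALSE]
      out <- c(out, sprintf("  %s:", toupper(ph)),
               sprintf("    - %s: %s", rows$text, rows$response))
    }
  }
  out <- c(out, "", "ACCEPTED WORKING DIAGNOSES")
  for (d in plan$accepted) {
    row <- evidences[evidences$dx_id == d, , drop = FALSE]
    marker <- if (isTRUE(session$dx_overrides[[d]])) " [clinician override]" else ""
    out <- c(out, sprintf("  - %s (likeliness %d/%d)%s",
                          row$name, row$scale_value, row$scale_max, marker))
    sup <- row$supporting[[1L]]
    if (nrow(sup) > 0L) {
      txt <- vapply(sup$item, function(i) kb$items[[i]]$text, "",
                    USE.NAMES = FALSE)
      out <- c(out, sprintf("      evidence: %s",
                            paste(sprintf("%s (%s)", txt, sup$response),
                                  collapse = "; ")))
    }
  }
  out <- c(out, "", "TREATMENT RECOMMENDATIONS")
  on_tx <- plan$treatments[plan$selected[plan$treatments$treatment_id], ,
                           drop = FALSE]
  if (nrow(on_tx) == 0L) {
    out <- c(out, "  (all treatments deselected)")
  } else {
    for (i in seq_len(nrow(on_tx))) {
      contrib <- vapply(on_tx$contributing[[i]],
                        function(d) kb$diagnoses[[d]]$name, "",
                        USE.NAMES = FALSE)
      out <- c(out, sprintf("  - %s", on_tx$name[i]),
               sprintf("      for: %s", paste(contrib, collapse = "; ")))
    }
  }
  out <- c(out, "", "PATIENT EDUCATION")
  if (nrow(plan$education) == 0L) {
    out <- c(out, "  (none)")
  } else {
    out <- c(out, sprintf("  - %s", plan$education$title))
  }
  paste0(paste(out, collapse = "\n"), "\n")
}

#' Export education materials as markdown files
#'
#' Writes one markdown file per material in the plan, named
#' `edu_<edu_id>.md`, into `dir`.
#'
#' @param plan An `lbp_care_plan`.
#' @param dir Output directory (created if missing).
#' @return Character vector of written paths, invisibly.
#' @export
export_education <- function(plan, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0L)
  for (i in seq_len(nrow(plan$education))) {
    p <- file.path(dir, sprintf("edu_%s.md", plan$education$edu_id[i]))
    writeLines(c(sprintf("# %s", plan$education$title[i]), "",
                 plan$education$body[i]), p)
    paths <- c(paths, p)
  }
  invisible(paths)
}

#' Serialise a care plan to JSON
#'
#' @param plan An `lbp_care_plan`.
#' @return A JSON string.
#' @export
care_plan_to_json <- function(plan) {
  doc <- list(
    accepted = as.list(plan$accepted),
    treatments = lapply(seq_len(nrow(plan$treatments)), function(i) {
      list(treatment_id = plan$treatments$treatment_id[i],
           name = plan$treatments$name[i],
           selected = unname(plan$selected[plan$treatments$treatment_id[i]]),
           contributing = as.list(plan$treatments$contributing[[i]]))
    }),
    education = lapply(seq_len(nrow(plan$education)), function(i) {
      list(edu_id = plan$education$edu_id[i],
           title = plan$education$title[i])
    }),
    generated = plan$generated
  )
  as.character(jsonlite::toJSON(doc, auto_unbox = TRUE))
}

#' @export
print.lbp_care_plan <- function(x, ...) {
  cat(sprintf("<lbp_care_plan> %d accepted diagnosis(es), %d treatment(s), %d education material(s)\n",
              length(x$accepted), nrow(x$treatments), nrow(x$education)))
  invisible(x)
}
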