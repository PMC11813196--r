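#' Start a patient encounter session
#'
#' A session binds one patient encounter to a knowledge base: the recorded
#' interview/examination findings, the adaptively enabled item set derived
#' from them, and the clinician's diagnosis and treatment selections.
#' Sessions are immutable values; recording functions return an updated
#' copy.
#'
#' @param kb A valid `lbp_kb`; construction is refused (integrity error)
#'   if the knowledge base fails validation.
#' @return An object of class `lbp_session`.
#' @export
new_session <- function(kb) {
  stopifnot(inherits(kb, "lbp_kb"))
  if (!isTRUE(attr(kb, "validated"))) {     # load_kb caches a clean report
    rep <- validate_kb(kb)
    if (any(rep$severity == "error")) {
      lbp_integrity_error("refusing to open a session on an invalid knowledge base",
                          report = rep)
    }
  }
  now <- utc_now()
  structure(list(
    kb = kb,
    kb_version = kb$version,
    findings = stats::setNames(character(), character()),
    dx_selections = stats::setNames(character(), character()),
    dx_overrides = stats::setNames(logical(), character()),
    treatment_selections = stats::setNames(logical(), character()),
    created = now,
    modified = now
  ), class = "lbp_session")
}

utc_now <- function() format(Sys.time(), "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")

touch <- function(session) {
  session$modified <- utc_now()
  session
}

#' Active findings of a session
#'
#' The inference input contract: the greatest subset `S` of the recorded
#' findings such that every item of `S` is enabled when enabling
#' conditions are evaluated against `S` itself. Computed by iterating
#' removal of disabled items to a fixed point, which terminates because
#' the enabling graph is acyclic. Findings on items that have become
#' disabled are retained in the session but excluded here.
#'
#' @param session An `lbp_session`.
#' @return Named character vector mapping item ids to responses.
#' @export
active_findings <- function(session) {
  kb <- session$kb
  af <- session$findings
  repeat {
    keep <- vapply(names(af), function(id) {
      eval_expr_(kb$items[[id]]$enabled_when, af)
    }, logical(1L))
    if (all(keep)) break
    af <- af[keep]
    if (length(af) == 0L) break
  }
  af
}

# Items enabled under a given findings map, in display-contract order:
# interview before examination before synthesis, clusters contiguous in
# first-declaration order, declaration order within cluster.
enabled_under <- function(kb, findings) {
  en <- vapply(kb$item_order, function(id) {
    eval_expr_(kb$items[[id]]$enabled_when, findings)
  }, logical(1L))
  ids <- kb$item_order[en]
  order_items(kb, ids)
}

order_items <- function(kb, ids) {
  if (length(ids) == 0L) return(character())
  phase <- vapply(ids, function(id) kb$items[[id]]$phase, "")
  cluster <- vapply(ids, function(id) kb$items[[id]]$cluster, "")
  phase_rank <- match(phase, c("interview", "examination", "synthesis"))
  # cluster order = first appearance in KB declaration order, per phase
  all_phase <- vapply(kb$item_order, function(id) kb$items[[id]]$phase, "")
  all_cluster <- vapply(kb$item_order, function(id) kb$items[[id]]$cluster, "")
  cluster_key <- paste(all_phase, all_cluster, sep = "\r")
  first_seen <- match(paste(phase, cluster, sep = "\r"), unique(cluster_key))
  decl <- match(ids, kb$item_order)
  ids[order(phase_rank, first_seen, decl)]
}

#' Currently enabled items
#'
#' An item is presented iff its enabling condition is satisfied by the
#' session's [active_findings()]. The result is ordered for display:
#' interview items before examination items (paralleling clinical
#' workflow), then the synthesis item; microdiagnosis clusters are kept
#' contiguous and declaration order is preserved within a cluster. The
#' set is recomputed from scratch on each call, so it is a pure function
#' of the active findings.
#'
#' @param session An `lbp_session`.
#' @return Data frame with columns `item_id`, `text`, `phase`, `cluster`.
#' @export
enabled_items <- function(session) {
  ids <- enabled_under(session$kb, active_findings(session))
  data.frame(
    item_id = ids,
    text = vapply(ids, function(id) session$kb$items[[id]]$text, ""),
    phase = vapply(ids, function(id) session$kb$items[[id]]$phase, ""),
    cluster = vapply(ids, function(id) session$kb$items[[id]]$cluster, ""),
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Record a finding
#'
#' Stores a response for a currently enabled item. Recording a finding
#' may enable further conditional items; retracting one upstream may
#' deactivate findings downstream (they are retained but excluded from
#' [active_findings()] until re-enabled).
#'
#' @param session An `lbp_session`.
#' @param item_id Identifier of an enabled item.
#' @param response A response within the item's response domain.
#' @return The updated session.
#' @export
record_finding <- function(session, item_id, response = "present") {
  kb <- session$kb
  if (!item_id %in% kb$item_order) {
    lbp_integrity_error(sprintf("unknown item `%s`", item_id))
  }
  it <- kb$items[[item_id]]
  if (!response %in% it$responses) {
    lbp_domain_error(sprintf(
      "response `%s` is outside the domain of item `%s` (%s)",
      response, item_id, paste(it$responses, collapse = ", ")))
  }
  af <- active_findings(session)
  if (!eval_expr_(it$enabled_when, af)) {
    lbp_enablement_error(sprintf(
      "item `%s` is not enabled under the current findings", item_id))
  }
  session$findings[[item_id]] <- response
  touch(session)
}

#' Retract a finding
#'
#' @param session An `lbp_session`.
#' @param item_id Item whose finding should be removed.
#' @return The updated session.
#' @export
retract_finding <- function(session, item_id) {
  if (!item_id %in% names(session$findings)) {
    lbp_not_found_error(sprintf("no finding recorded for item `%s`", item_id))
  }
  session$findings <- session$findings[names(session$findings) != item_id]
  touch(session)
}

#' Patient summary
#'
#' The persistent summary panel: one row per active finding with the
#' item's display text, ordered interview then examination then
#' synthesis, clusters contiguous. Deterministic and invariant under the
#' order in which findings were entered.
#'
#' @param session An `lbp_session`.
#' @return Data frame of class `lbp_summary` with columns `item_id`,
#'   `text`, `response`, `phase`, `cluster`.
#' @export
patient_summary <- function(session) {
  af <- active_findings(session)
  ids <- order_items(session$kb, names(af))
  out <- data.frame(
    item_id = ids,
    text = vapply(ids, function(id) session$kb$items[[id]]$text,
                  "", USE.NAMES = FALSE),
    response = unname(af[ids]),
    phase = vapply(ids, function(id) session$kb$items[[id]]$phase,
                   "", USE.NAMES = FALSE),
    cluster = vapply(ids, function(id) session$kb$items[[id]]$cluster,
                     "", USE.NAMES = FALSE),
    row.names = NULL, stringsAsFactors = FALSE)
  class(out) <- c("lbp_summary", "data.frame")
  out
}

#' @export
print.lbp_summary <- function(x, ...) {
  if (nrow(x) == 0L) {
    cat("Patient summary: no findings recorded.\n")
    return(invisible(x))
  }
  cat("Patient summary\n")
  for (ph in unique(x$phase)) {
    cat(sprintf("  %s:\n", ph))
    rows <- x[x$phase == ph, , drop = FALSE]
    for (i in seq_len(nrow(rows))) {
      cat(sprintf("    - %s: %s\n", rows$text[i], rows$response[i]))
    }
  }
  invisible(x)
}

#' Save / load a session
#'
#' Sessions persist as a single JSON document holding the knowledge-base
#' version, findings and all selections; persistence is whole-file
#' replace. Loading requires the same knowledge-base version the session
#' was created against.
#'
#' @param session An `lbp_session`.
#' @param path File path.
#' @return `save_session()` returns the path invisibly; `load_session()`
#'   returns the restored `lbp_session`.
#' @export
save_session <- function(session, path) {
  doc <- list(
    kb_version = session$kb_version,
    findings = as.list(session$findings),
    dx_selections = as.list(session$dx_selections),
    dx_overrides = as.list(session$dx_overrides),
    treatment_selections = as.list(session$treatment_selections),
    created = session$created,
    modified = session$modified
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname save_session
#' @param kb The knowledge base the session was created against.
#' @export
load_session <- function(kb, path) {
  if (!file.exists(path)) {
    lbp_format_error(sprintf("session file not found: %s", path))
  }
  doc <- tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
                  error = function(e) {
                    lbp_format_error(sprintf(
                      "cannot parse session file `%s`: %s",
                      path, conditionMessage(e)))
                  })
  if (!is.list(doc) || is.null(doc$kb_version)) {
    lbp_format_error(sprintf("session file `%s` is missing `kb_version`", path))
  }
  if (!identical(as.character(doc$kb_version), kb$version)) {
    lbp_version_error(sprintf(
      "session was saved against KB version `%s` but the supplied KB is version `%s`",
      doc$kb_version, kb$version))
  }
  s <- new_session(kb)
  s$findings <- stats::setNames(
    vapply(doc$findings, as.character, ""), names(doc$findings))
  s$dx_selections <- stats::setNames(
    vapply(doc$dx_selections, as.character, ""), names(doc$dx_selections))
  s$dx_overrides <- stats::setNames(
    vapply(doc$dx_overrides, isTRUE, logical(1L)), names(doc$dx_overrides))
  s$treatment_selections <- stats::setNames(
    vapply(doc$treatment_selections, isTRUE, logical(1L)),
    names(doc$treatment_selections))
  if (!is.null(doc$created)) s$created <- as.character(doc$created)
  if (!is.null(doc$modified)) s$modified <- as.character(doc$modified)
  s
}

#' @export
print.lbp_session <- function(x, ...) {
  cat(sprintf("<lbp_session> KB version %s; %d finding(s) (%d active), %d diagnosis selection(s)\n",
              x$kb_version, length(x$findings), length(active_findings(x)),
              length(x$dx_selections)))
  invisible(x)
}
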