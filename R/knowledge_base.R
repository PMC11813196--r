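#' Load a clinical knowledge base
#'
#' Reads a knowledge-base file in the package's declarative dialect (JSON
#' canonical, YAML accepted 1:1), cross-links all references and verifies
#' every structural invariant. The knowledge base carries the complete
#' clinical model: interview/examination/synthesis items with their
#' adaptive enabling conditions, macro- and micro-level working diagnoses
#' with Boolean rules and evidence atoms, treatment recommendations, and
#' patient education materials.
#'
#' @param path Path to a `.json`, `.yaml` or `.yml` knowledge-base file.
#' @return An object of class `lbp_kb`.
#' @seealso [default_kb()], [validate_kb()], [kb_census()]
#' @export
load_kb <- function(path) {
  if (!file.exists(path)) {
    lbp_format_error(sprintf("knowledge-base file not found: %s", path))
  }
  ext <- tolower(tools::file_ext(path))
  raw <- tryCatch(
    if (ext %in% c("yaml", "yml")) {
      yaml::read_yaml(path)
    } else {
      jsonlite::fromJSON(path, simplifyVector = FALSE)
    },
    error = function(e) {
      lbp_format_error(sprintf("cannot parse knowledge base `%s`: %s",
                               path, conditionMessage(e)))
    }
  )
  kb <- kb_from_list(raw)
  rep <- validate_kb(kb)
  errs <- rep[rep$severity == "error", , drop = FALSE]
  if (nrow(errs) > 0L) {
    lbp_integrity_error(
      sprintf("knowledge base fails validation with %d error(s):\n%s",
              nrow(errs),
              paste(sprintf("  [%s] %s", errs$code, errs$message),
                    collapse = "\n")),
      report = rep)
  }
  attr(kb, "validated") <- TRUE
  kb
}

#' The shipped default low back pain knowledge base
#'
#' Loads the knowledge base distributed with the package: 44 interview,
#' examination and synthesis items and 12 working diagnoses (3
#' macrodiagnoses, 9 microdiagnoses). Printed clinical constraints (item
#' class counts, the piriformis-syndrome rule, the adaptive nerve-root
#' cluster) are encoded verbatim; rules not published in full carry
#' `source: reconstructed` metadata.
#'
#' @return An `lbp_kb` object.
#' @export
default_kb <- function() {
  load_kb(system.file("extdata", "lbp_kb.json", package = "lbpcds",
                      mustWork = TRUE))
}

#' Construct a knowledge base from an R list
#'
#' Builds an `lbp_kb` from the same nested structure the file dialect
#' uses (top-level keys `version`, `items`, `diagnoses`, `treatments`,
#' `education`, optional `metadata`). Construction is lenient: structural
#' problems are reported by [validate_kb()], not raised here, so that
#' broken knowledge bases can be inspected.
#'
#' @param x Nested list mirroring the KB file dialect.
#' @return An `lbp_kb` object (possibly invalid; see [validate_kb()]).
#' @export
kb_from_list <- function(x) {
  if (!is.list(x)) lbp_format_error("knowledge base must be an object")
  get_chr <- function(obj, field, default = NA_character_) {
    v <- obj[[field]]
    if (is.null(v)) default else as.character(v)
  }

  items <- lapply(x$items, function(it) {
    if (is.null(it$id)) lbp_format_error("item missing `id` field")
    list(
      id        = as.character(it$id),
      text      = get_chr(it, "text", as.character(it$id)),
      phase     = get_chr(it, "phase", "interview"),
      cluster   = get_chr(it, "cluster", "general"),
      info      = get_chr(it, "info"),
      responses = if (is.null(it$responses)) c("present", "absent")
                  else vapply(it$responses, as.character, ""),
      enabled_when = parse_expr(it$enabled_when),
      source    = get_chr(it, "source", "authored")
    )
  })
  item_order <- vapply(items, `[[`, "", "id")
  names(items) <- item_order

  diagnoses <- lapply(x$diagnoses, function(dx) {
    if (is.null(dx$id)) lbp_format_error("diagnosis missing `id` field")
    ev <- dx$evidence_atoms
    ev_df <- if (is.null(ev) || length(ev) == 0L) {
      data.frame(item = character(), response = character(),
                 stringsAsFactors = FALSE)
    } else {
      data.frame(
        item = vapply(ev, function(a) as.character(a$item), ""),
        response = vapply(ev, function(a) {
          if (is.null(a$response)) "present" else as.character(a$response)
        }, ""),
        stringsAsFactors = FALSE)
    }
    sup <- lapply(dx$suppressors, function(s) {
      list(by = as.character(s$by),
           policy = if (is.null(s$policy)) "stronger_evidence"
                    else as.character(s$policy))
    })
    list(
      id = as.character(dx$id),
      name = get_chr(dx, "name", as.character(dx$id)),
      level = get_chr(dx, "level", "micro"),
      parent = get_chr(dx, "parent"),
      rule = parse_expr(dx$rule),
      evidence = ev_df,
      scale_max = if (is.null(dx$scale_max)) 5L else as.integer(dx$scale_max),
      suppressors = sup,
      education = vapply(dx$education, as.character, ""),
      graded = if (is.null(dx$graded)) TRUE else isTRUE(dx$graded),
      source = get_chr(dx, "source", "authored")
    )
  })
  dx_order <- vapply(diagnoses, `[[`, "", "id")
  names(diagnoses) <- dx_order

  treatments <- lapply(x$treatments, function(tx) {
    if (is.null(tx$id)) lbp_format_error("treatment missing `id` field")
    ap <- tx$applies_to
    applies_to <- if (is.null(ap)) character() else
      if (identical(ap, "ALL") || identical(ap, list("ALL"))) "ALL" else
      vapply(ap, as.character, "")
    list(id = as.character(tx$id),
         name = get_chr(tx, "name", as.character(tx$id)),
         applies_to = applies_to,
         priority_note = get_chr(tx, "priority_note"))
  })
  tx_order <- vapply(treatments, `[[`, "", "id")
  names(treatments) <- tx_order

  education <- lapply(x$education, function(ed) {
    if (is.null(ed$id)) lbp_format_error("education material missing `id` field")
    list(id = as.character(ed$id),
         title = get_chr(ed, "title", as.character(ed$id)),
         body = get_chr(ed, "body", ""),
         reading_level_note = get_chr(ed, "reading_level_note"))
  })
  edu_order <- vapply(education, `[[`, "", "id")
  names(education) <- edu_order

  structure(list(
    version = get_chr(x, "version", "0"),
    metadata = x$metadata,
    items = items, item_order = item_order,
    diagnoses = diagnoses, dx_order = dx_order,
    treatments = treatments, tx_order = tx_order,
    education = education, edu_order = edu_order
  ), class = "lbp_kb")
}

#' Serialise a knowledge base back to the file dialect
#'
#' @param kb An `lbp_kb`.
#' @return A nested list; `write_kb()` writes it as canonical JSON.
#' @export
kb_to_list <- function(kb) {
  list(
    version = kb$version,
    metadata = kb$metadata,
    items = lapply(unname(kb$items[kb$item_order]), function(it) {
      out <- list(id = it$id, text = it$text, phase = it$phase,
                  cluster = it$cluster)
      if (!is.na(it$info)) out$info <- it$info
      if (!identical(it$responses, c("present", "absent"))) {
        out$responses <- as.list(it$responses)
      }
      if (!expr_is_true(it$enabled_when)) {
        out$enabled_when <- unparse_expr(it$enabled_when)
      }
      out$source <- it$source
      out
    }),
    diagnoses = lapply(unname(kb$diagnoses[kb$dx_order]), function(dx) {
      out <- list(id = dx$id, name = dx$name, level = dx$level)
      if (!is.na(dx$parent)) out$parent <- dx$parent
      out$rule <- unparse_expr(dx$rule)
      out$evidence_atoms <- lapply(seq_len(nrow(dx$evidence)), function(i) {
        list(item = dx$evidence$item[i], response = dx$evidence$response[i])
      })
      out$scale_max <- dx$scale_max
      if (length(dx$suppressors) > 0L) out$suppressors <- dx$suppressors
      out$education <- as.list(dx$education)
      if (!dx$graded) out$graded <- FALSE
      out$source <- dx$source
      out
    }),
    treatments = lapply(unname(kb$treatments[kb$tx_order]), function(tx) {
      out <- list(id = tx$id, name = tx$name)
      out$applies_to <- if (identical(tx$applies_to, "ALL")) "ALL"
                        else as.list(tx$applies_to)
      if (!is.na(tx$priority_note)) out$priority_note <- tx$priority_note
      out
    }),
    education = lapply(unname(kb$education[kb$edu_order]), function(ed) {
      out <- list(id = ed$id, title = ed$title, body = ed$body)
      if (!is.na(ed$reading_level_note)) {
        out$reading_level_note <- ed$reading_level_note
      }
      out
    })
  )
}

#' @rdname kb_to_list
#' @param path Output path for the JSON file.
#' @export
write_kb <- function(kb, path) {
  jsonlite::write_json(kb_to_list(kb), path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

# Directed enabling-dependency graph: edge item -> item its condition reads.
enabling_graph <- function(kb) {
  edges <- do.call(rbind, lapply(kb$items, function(it) {
    deps <- expr_atoms(it$enabled_when)$item
    if (length(deps) == 0L) return(NULL)
    cbind(from = rep(it$id, length(deps)), to = deps)
  }))
  verts <- kb$item_order
  if (is.null(edges)) {
    igraph::make_empty_graph(directed = TRUE) + igraph::vertices(verts)
  } else {
    keep <- edges[, "to"] %in% verts   # unknown refs reported separately
    igraph::graph_from_data_frame(
      as.data.frame(edges[keep, , drop = FALSE]),
      directed = TRUE, vertices = verts)
  }
}

#' Validate a knowledge base
#'
#' Runs every structural check on a knowledge base and returns a report
#' rather than raising: duplicate or dangling identifiers, enabling-graph
#' cycles, rules whose atoms are missing from their evidence lists,
#' micro diagnoses without a macro parent, orphan treatments or education
#' materials, diagnoses left without any applicable treatment, and rules
#' that can never trigger. Validation is pure: the same knowledge base
#' always yields the same report.
#'
#' @param kb An `lbp_kb`.
#' @return A data frame of class `lbp_validation` with columns
#'   `severity` (`"error"`/`"warning"`), `code`, `message`.
#' @export
validate_kb <- function(kb) {
  findings <- list()
  add <- function(severity, code, message) {
    findings[[length(findings) + 1L]] <<-
      data.frame(severity = severity, code = code, message = message,
                 stringsAsFactors = FALSE)
  }
  err  <- function(code, msg) add("error", code, msg)
  warn <- function(code, msg) add("warning", code, msg)

  item_ids <- kb$item_order
  dup <- unique(item_ids[duplicated(item_ids)])
  for (d in dup) err("DUP_ITEM_ID", sprintf("duplicate item id `%s`", d))

  phases <- c("interview", "examination", "synthesis")
  for (it in kb$items) {
    if (!it$phase %in% phases) {
      err("BAD_PHASE", sprintf("item `%s` has unknown phase `%s`",
                               it$id, it$phase))
    }
    at <- expr_atoms(it$enabled_when)
    for (i in seq_len(nrow(at))) {
      if (!at$item[i] %in% item_ids) {
        err("UNKNOWN_ITEM_REF", sprintf(
          "enabling condition of `%s` references unknown item `%s`",
          it$id, at$item[i]))
      } else if (!at$response[i] %in% kb$items[[at$item[i]]]$responses) {
        err("BAD_RESPONSE_REF", sprintf(
          "enabling condition of `%s` requires response `%s` outside the domain of `%s`",
          it$id, at$response[i], at$item[i]))
      }
    }
    if (contradictory_and(it$enabled_when)) {
      warn("UNREACHABLE_ITEM", sprintf(
        "item `%s` can never be enabled (contradictory condition)", it$id))
    }
  }

  g <- enabling_graph(kb)
  if (!igraph::is_dag(g)) {
    comp <- igraph::components(g, mode = "strong")
    cyc <- names(comp$membership)[comp$membership %in%
                                    which(comp$csize > 1L)]
    ends <- igraph::as_edgelist(g)
    self <- ends[ends[, 1L] == ends[, 2L], 1L]
    cyc <- sort(unique(c(cyc, self)))
    err("ENABLING_CYCLE", sprintf(
      "enabling-dependency graph contains a cycle involving: %s",
      paste(cyc, collapse = ", ")))
  }

  dx_ids <- kb$dx_order
  dup <- unique(dx_ids[duplicated(dx_ids)])
  for (d in dup) err("DUP_DX_ID", sprintf("duplicate diagnosis id `%s`", d))

  for (dx in kb$diagnoses) {
    at <- expr_atoms(dx$rule)
    for (i in seq_len(nrow(at))) {
      if (!at$item[i] %in% item_ids) {
        err("RULE_UNKNOWN_ITEM", sprintf(
          "rule of diagnosis `%s` references unknown item `%s`",
          dx$id, at$item[i]))
      } else if (!at$response[i] %in% kb$items[[at$item[i]]]$responses) {
        err("RULE_BAD_RESPONSE", sprintf(
          "rule of `%s` requires response `%s` outside the domain of `%s`",
          dx$id, at$response[i], at$item[i]))
      }
    }
    ev_key <- paste(dx$evidence$item, dx$evidence$response, sep = "\r")
    rule_key <- paste(at$item, at$response, sep = "\r")
    missing <- at$item[!rule_key %in% ev_key]
    for (m in missing) {
      err("RULE_ATOM_NOT_IN_EVIDENCE", sprintf(
        "rule atom `%s` of diagnosis `%s` is missing from evidence_atoms",
        m, dx$id))
    }
    for (i in seq_len(nrow(dx$evidence))) {
      if (!dx$evidence$item[i] %in% item_ids) {
        err("EVIDENCE_UNKNOWN_ITEM", sprintf(
          "evidence atom of `%s` references unknown item `%s`",
          dx$id, dx$evidence$item[i]))
      }
    }
    if (!dx$level %in% c("macro", "micro")) {
      err("BAD_LEVEL", sprintf("diagnosis `%s` has unknown level `%s`",
                               dx$id, dx$level))
    }
    if (identical(dx$level, "micro")) {
      if (is.na(dx$parent) || !dx$parent %in% dx_ids ||
          !identical(kb$diagnoses[[dx$parent]]$level, "macro")) {
        err("MISSING_PARENT", sprintf(
          "micro diagnosis `%s` lacks a resolvable macro parent", dx$id))
      }
    } else if (identical(dx$level, "macro") && !is.na(dx$parent)) {
      err("MACRO_WITH_PARENT", sprintf(
        "macro diagnosis `%s` must not declare a parent", dx$id))
    }
    if (is.na(dx$scale_max) || dx$scale_max < 1L) {
      err("BAD_SCALE_MAX", sprintf(
        "diagnosis `%s` has scale_max < 1", dx$id))
    }
    for (s in dx$suppressors) {
      if (!s$by %in% dx_ids) {
        err("SUPPRESSOR_UNKNOWN_DX", sprintf(
          "suppressor of `%s` names unknown diagnosis `%s`", dx$id, s$by))
      }
    }
    for (e in dx$education) {
      if (!e %in% kb$edu_order) {
        err("EDU_UNKNOWN", sprintf(
          "diagnosis `%s` references unknown education material `%s`",
          dx$id, e))
      }
    }
    if (contradictory_and(dx$rule) ||
        (nrow(at) == 0L && !expr_is_true(dx$rule))) {
      warn("RULE_NEVER_TRIGGERS", sprintf(
        "rule of diagnosis `%s` can never be satisfied", dx$id))
    }
  }

  tx_ids <- kb$tx_order
  dup <- unique(tx_ids[duplicated(tx_ids)])
  for (d in dup) err("DUP_TX_ID", sprintf("duplicate treatment id `%s`", d))
  has_all_tx <- FALSE
  for (tx in kb$treatments) {
    if (length(tx$applies_to) == 0L) {
      err("TX_EMPTY_APPLIES", sprintf(
        "treatment `%s` applies to no diagnosis (use ALL or a non-empty list)",
        tx$id))
    } else if (identical(tx$applies_to, "ALL")) {
      has_all_tx <- TRUE
    } else {
      for (d in tx$applies_to) {
        if (!d %in% dx_ids) {
          err("TX_UNKNOWN_DX", sprintf(
            "treatment `%s` applies to unknown diagnosis `%s`", tx$id, d))
        }
      }
    }
  }
  if (!has_all_tx) {
    for (dx in kb$diagnoses) {
      covered <- any(vapply(kb$treatments, function(tx) {
        dx$id %in% tx$applies_to
      }, logical(1L)))
      if (!covered) {
        err("DX_NO_TREATMENT", sprintf(
          "diagnosis `%s` has no applicable treatment", dx$id))
      }
    }
  }

  edu_ids <- kb$edu_order
  dup <- unique(edu_ids[duplicated(edu_ids)])
  for (d in dup) err("DUP_EDU_ID", sprintf("duplicate education id `%s`", d))
  referenced <- unique(unlist(lapply(kb$diagnoses, `[[`, "education")))
  for (ed in kb$education) {
    if (!nzchar(ed$body)) {
      err("EMPTY_EDU_BODY", sprintf(
        "education material `%s` has an empty body", ed$id))
    }
    if (!ed$id %in% referenced) {
      err("ORPHAN_EDU", sprintf(
        "education material `%s` is referenced by no diagnosis", ed$id))
    }
  }

  rep <- if (length(findings) == 0L) {
    data.frame(severity = character(), code = character(),
               message = character(), stringsAsFactors = FALSE)
  } else {
    do.call(rbind, findings)
  }
  class(rep) <- c("lbp_validation", "data.frame")
  rep
}

# TRUE when some AND node requires two different responses for one item,
# which is unsatisfiable under a single-response-per-item findings map.
contradictory_and <- function(expr) {
  found <- FALSE
  walk <- function(e) {
    if (found) return(invisible(NULL))
    switch(e$kind,
      and = {
        at <- do.call(rbind, lapply(e$children, function(k) {
          if (identical(k$kind, "atom")) {
            data.frame(item = k$item, response = k$response,
                       stringsAsFactors = FALSE)
          } else NULL
        }))
        if (!is.null(at) &&
            anyDuplicated(at$item) && !anyDuplicated(at)) {
          dup_items <- unique(at$item[duplicated(at$item)])
          for (d in dup_items) {
            if (length(unique(at$response[at$item == d])) > 1L) {
              found <<- TRUE
            }
          }
        }
        for (k in e$children) walk(k)
      },
      or = for (k in e$children) walk(k),
      not = walk(e$child),
      invisible(NULL)
    )
  }
  walk(expr)
  found
}

#' @export
print.lbp_validation <- function(x, ...) {
  if (nrow(x) == 0L) {
    cat("Knowledge base valid: no findings.\n")
  } else {
    cat(sprintf("Validation findings: %d error(s), %d warning(s)\n",
                sum(x$severity == "error"), sum(x$severity == "warning")))
    for (i in seq_len(nrow(x))) {
      cat(sprintf("  %-7s [%s] %s\n", x$severity[i], x$code[i], x$message[i]))
    }
  }
  invisible(x)
}

#' Serialise a validation report to JSON lines
#'
#' @param report An `lbp_validation` report.
#' @return Character vector, one JSON object per finding.
#' @export
validation_to_jsonl <- function(report) {
  vapply(seq_len(nrow(report)), function(i) {
    jsonlite::toJSON(as.list(report[i, , drop = FALSE]), auto_unbox = TRUE)
  }, "")
}

#' Structural census of a knowledge base
#'
#' Counts items by phase and enabling kind (always enabled vs conditional
#' on other items; synthesis items counted as their own class) and
#' diagnoses by level. For the shipped default knowledge base this
#' reproduces the published structure: 44 items in total, of which 13
#' interview items are always enabled, 13 interview items conditional,
#' 1 examination item always enabled, 16 examination items conditional,
#' and 1 synthesis item; 12 diagnoses comprising 3 macrodiagnoses and 9
#' microdiagnoses.
#'
#' @param kb An `lbp_kb`.
#' @return An object of class `lbp_census`: a named integer list.
#' @export
kb_census <- function(kb) {
  phase <- vapply(kb$items, `[[`, "", "phase")
  always <- vapply(kb$items, function(it) expr_is_true(it$enabled_when),
                   logical(1L))
  level <- vapply(kb$diagnoses, `[[`, "", "level")
  out <- list(
    total_items            = length(kb$items),
    interview_always       = sum(phase == "interview" & always),
    interview_conditional  = sum(phase == "interview" & !always),
    examination_always     = sum(phase == "examination" & always),
    examination_conditional = sum(phase == "examination" & !always),
    synthesis              = sum(phase == "synthesis"),
    diagnoses_total        = length(kb$diagnoses),
    macro                  = sum(level == "macro"),
    micro                  = sum(level == "micro")
  )
  out <- lapply(out, as.integer)
  class(out) <- "lbp_census"
  out
}

#' @export
print.lbp_census <- function(x, ...) {
  cat("Knowledge-base census\n")
  cat(sprintf("  items: %d total (interview %d always + %d conditional; examination %d always + %d conditional; synthesis %d)\n",
              x$total_items, x$interview_always, x$interview_conditional,
              x$examination_always, x$examination_conditional, x$synthesis))
  cat(sprintf("  diagnoses: %d total (%d macro, %d micro)\n",
              x$diagnoses_total, x$macro, x$micro))
  invisible(x)
}

#' @export
print.lbp_kb <- function(x, ...) {
  ttl <- if (!is.null(x$metadata$title)) x$metadata$title else "knowledge base"
  cat(sprintf("<lbp_kb> %s (version %s)\n", ttl, x$version))
  print(kb_census(x))
  invisible(x)
}
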