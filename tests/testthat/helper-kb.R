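# Builders for toy and randomised knowledge bases, plus the independent
# truth-table oracle used to cross-check the expression evaluator.

minimal_kb_list <- function() {
  list(
    version = "test-1",
    items = list(
      list(id = "q1", text = "Single always-enabled item", phase = "interview")
    ),
    diagnoses = list(
      list(id = "d1", name = "Toy diagnosis", level = "macro",
           rule = list(atom = list(item = "q1", response = "present")),
           evidence_atoms = list(list(item = "q1", response = "present")),
           education = list("e1"))
    ),
    treatments = list(
      list(id = "t1", name = "Toy treatment", applies_to = "ALL")
    ),
    education = list(
      list(id = "e1", title = "Toy education", body = "Body text.")
    )
  )
}

minimal_kb <- function() kb_from_list(minimal_kb_list())

# Three-item enabling chain A -> enables B -> enables C.
chain_kb <- function() {
  kb_from_list(list(
    version = "chain-1",
    items = list(
      list(id = "A", text = "Item A", phase = "interview"),
      list(id = "B", text = "Item B", phase = "interview",
           enabled_when = list(atom = list(item = "A", response = "present"))),
      list(id = "C", text = "Item C", phase = "examination",
           enabled_when = list(atom = list(item = "B", response = "present")))
    ),
    diagnoses = list(
      list(id = "d1", name = "Chain diagnosis", level = "macro",
           rule = list(or = list(
             list(atom = list(item = "A", response = "present")),
             list(atom = list(item = "B", response = "present")),
             list(atom = list(item = "C", response = "present")))),
           evidence_atoms = list(
             list(item = "A", response = "present"),
             list(item = "B", response = "present"),
             list(item = "C", response = "present")),
           education = list("e1"))
    ),
    treatments = list(list(id = "t1", name = "Toy", applies_to = "ALL")),
    education = list(list(id = "e1", title = "Toy", body = "Body."))
  ))
}

# Random valid KB: enabling conditions only reference earlier-declared
# items, so the enabling graph is acyclic by construction.
random_kb <- function(n_items = 8L) {
  phases <- sample(c("interview", "examination", "synthesis"), n_items,
                   replace = TRUE, prob = c(0.5, 0.4, 0.1))
  items <- lapply(seq_len(n_items), function(i) {
    it <- list(id = sprintf("q%02d", i), text = sprintf("Item %d", i),
               phase = phases[i])
    if (i > 1L && stats::runif(1) < 0.5) {
      dep <- sample(i - 1L, 1L)
      it$enabled_when <- list(atom = list(item = sprintf("q%02d", dep),
                                          response = "present"))
    }
    it
  })
  n_macro <- sample(1:2, 1L)
  dxs <- lapply(seq_len(n_macro), function(j) {
    atom_items <- sample(n_items, sample(1:min(3L, n_items), 1L))
    atoms <- lapply(atom_items, function(i) {
      list(atom = list(item = sprintf("q%02d", i), response = "present"))
    })
    list(id = sprintf("dx%d", j), name = sprintf("Diagnosis %d", j),
         level = "macro",
         rule = list(or = atoms),
         evidence_atoms = lapply(atom_items, function(i) {
           list(item = sprintf("q%02d", i), response = "present")
         }),
         education = list("e1"))
  })
  kb_from_list(list(
    version = "rand-1",
    items = items,
    diagnoses = dxs,
    treatments = list(list(id = "t1", name = "Toy", applies_to = "ALL")),
    education = list(list(id = "e1", title = "Toy", body = "Body."))
  ))
}

# Random Boolean expression over the given (item, response) atom pool.
random_expr <- function(atom_pool, depth = 3L) {
  kinds <- if (depth <= 0L) "atom" else c("atom", "and", "or", "not")
  kind <- sample(kinds, 1L, prob = if (depth <= 0L) 1 else c(0.4, 0.2, 0.3, 0.1))
  switch(kind,
    atom = {
      i <- sample(nrow(atom_pool), 1L)
      expr_atom(atom_pool$item[i], atom_pool$response[i])
    },
    not = expr_not(random_expr(atom_pool, depth - 1L)),
    and = do.call(expr_and, lapply(seq_len(sample(2:3, 1L)), function(.) {
      random_expr(atom_pool, depth - 1L)
    })),
    or = do.call(expr_or, lapply(seq_len(sample(2:3, 1L)), function(.) {
      random_expr(atom_pool, depth - 1L)
    }))
  )
}

# Independent oracle: compute each atom's truth value directly from the
# assignment, then evaluate the connective structure through R's own
# logical operators via string construction and parse().
oracle_eval <- function(expr, findings) {
  to_r <- function(e) {
    switch(e$kind,
      true = "TRUE",
      atom = {
        v <- findings[e$item]
        if (!is.na(v) && identical(unname(v), e$response)) "TRUE" else "FALSE"
      },
      not = sprintf("(!%s)", to_r(e$child)),
      and = sprintf("(%s)", paste(vapply(e$children, to_r, ""),
                                  collapse = " & ")),
      or = sprintf("(%s)", paste(vapply(e$children, to_r, ""),
                                 collapse = " | "))
    )
  }
  eval(parse(text = to_r(expr)))
}

default_kb_cached <- local({
  kb <- NULL
  function() {
    if (is.null(kb)) kb <<- default_kb()
    kb
  }
})
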