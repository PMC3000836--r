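# Independent oracles and small generators used across the suite.

# Hypergeometric upper tail P(X >= k) by direct enumeration of
# C(K,j) C(N-K, n-j) / C(N,n) -- deliberately naive, no phyper.
hyper_tail_enum <- function(N, K, n, k) {
  jmax <- min(n, K)
  if (k > jmax) return(0)
  js <- seq(k, jmax)
  sum(choose(K, js) * choose(N - K, n - js)) / choose(N, n)
}

# Exhaustive one-rule-at-a-time application of the dependency rules, visiting
# elements in a random order, until no rule fires.  Independent of the
# package's sweep-based fixpoint engine.
propagate_oracle <- function(pw, status, order_seed = 1) {
  st <- stats::setNames(status$status, status$element_id)
  glyphs <- bcml:::all_glyphs(pw)
  arcs <- pw$arcs
  bad <- function(id) st[[id]] %in% c("excluded", "affected")
  set.seed(order_seed)
  repeat {
    fired <- FALSE
    ids <- sample(names(st))
    for (id in ids) {
      if (st[[id]] != "included") next
      g <- glyphs[[id]]
      make_affected <- FALSE
      if (!is.null(g)) {
        if (g$cls == "complex" && length(g$components) > 0 &&
            any(vapply(g$components, function(c) bad(c$id), TRUE))) {
          make_affected <- TRUE
        }
        if (g$cls %in% c("process", "association", "dissociation")) {
          for (a in arcs) {
            if (a$target == id &&
                a$cls %in% c("consumption", "catalysis",
                             "necessary-stimulation") && bad(a$source)) {
              make_affected <- TRUE
            }
          }
        }
        if (!g$cls %in% c("process", "association", "dissociation",
                          "and-operator", "or-operator", "not-operator")) {
          producers <- character()
          for (a in arcs) {
            if (a$cls == "production" && a$target == id) {
              producers <- c(producers, a$source)
            }
          }
          if (length(producers) > 0 && all(vapply(producers, bad, TRUE))) {
            make_affected <- TRUE
          }
        }
      } else {
        a <- Filter(function(a) a$id == id, arcs)[[1]]
        if (bad(a$source) || bad(a$target)) make_affected <- TRUE
      }
      if (make_affected) {
        st[[id]] <- "affected"
        fired <- TRUE
      }
    }
    if (!fired) break
  }
  out <- status
  out$status <- unname(st[out$element_id])
  out
}

# Small random pathway (<= max_glyphs glyphs) with plausible wiring:
# entities feed processes, processes produce entities, one optional complex.
random_small_pathway <- function(seed, max_glyphs = 12) {
  set.seed(seed)
  human <- register_term("organism", "NCBITaxon:9606", "Homo sapiens")
  n_ent <- sample(2:6, 1)
  n_proc <- sample(1:3, 1)
  glyphs <- list()
  for (i in seq_len(n_ent)) {
    glyphs[[length(glyphs) + 1]] <-
      glyph(paste0("e", i), "macromolecule",
            xrefs = list(xref("EntrezGene", as.character(1000 + i))))
  }
  if (runif(1) < 0.6 && n_ent >= 2) {
    glyphs[[length(glyphs) + 1]] <- glyph(
      "cx", "complex",
      components = list(
        glyph("cxa", "macromolecule",
              xrefs = list(xref("EntrezGene", "2001"))),
        glyph("cxb", "macromolecule",
              xrefs = list(xref("EntrezGene", "2002")))))
  }
  for (i in seq_len(n_proc)) {
    glyphs[[length(glyphs) + 1]] <- glyph(paste0("p", i), "process")
  }
  ent_ids <- vapply(Filter(function(g) g$cls != "process", glyphs), `[[`, "",
                    "id")
  proc_ids <- vapply(Filter(function(g) g$cls == "process", glyphs), `[[`, "",
                     "id")
  arcs <- list()
  k <- 0
  for (p in proc_ids) {
    ins <- sample(ent_ids, sample(1:2, 1))
    for (src in ins) {
      k <- k + 1
      arcs[[k]] <- arc(paste0("a", k),
                       sample(c("consumption", "catalysis",
                                "necessary-stimulation", "stimulation",
                                "inhibition"), 1),
                       src, p)
    }
    outs <- sample(setdiff(ent_ids, ins), min(sample(1:2, 1),
                                              length(setdiff(ent_ids, ins))))
    for (tgt in outs) {
      k <- k + 1
      arcs[[k]] <- arc(paste0("a", k), "production", p, tgt)
    }
  }
  pathway("rp", "RP", human, glyphs = glyphs, arcs = arcs, check = TRUE)
}

# random total status map over a pathway with some excluded elements
random_status <- function(pw, seed) {
  set.seed(seed)
  ids <- c(names(bcml:::all_glyphs(pw)), vapply(pw$arcs, `[[`, "", "id"))
  tibble::tibble(
    element_id = ids,
    element = c(rep("glyph", length(names(bcml:::all_glyphs(pw)))),
                rep("arc", length(pw$arcs))),
    status = sample(c("included", "excluded"), length(ids), replace = TRUE,
                    prob = c(0.75, 0.25))
  )
}

# reference contexts used when building tiny pathways in tests
test_terms <- function() {
  list(
    human = register_term("organism", "NCBITaxon:9606", "Homo sapiens"),
    mouse = register_term("organism", "NCBITaxon:10090", "Mus musculus"),
    dc = register_term("cell-type", "CL:0000451", "dendritic cell"),
    mf = register_term("cell-type", "CL:0000235", "macrophage")
  )
}
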