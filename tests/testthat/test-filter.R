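# Small two-step pathway used in several propagation tests:
# complex(A, B) --consumption--> P --production--> Q
two_step_pathway <- function(b_finding = NULL) {
  tt <- test_terms()
  cx <- glyph("cx", "complex", components = list(
    glyph("A", "macromolecule", xrefs = list(xref("EntrezGene", "11")),
          findings = list(finding(tt$human, cell_type = tt$dc))),
    glyph("B", "macromolecule", xrefs = list(xref("EntrezGene", "12")),
          findings = if (is.null(b_finding)) list() else list(b_finding))))
  q <- glyph("Q", "macromolecule", xrefs = list(xref("EntrezGene", "13")),
             findings = list(finding(tt$human, cell_type = tt$dc)))
  p <- glyph("P", "process")
  pathway("w", "W", tt$human, glyphs = list(cx, q, p),
          arcs = list(arc("a1", "consumption", "cx", "P"),
                      arc("a2", "production", "P", "Q")))
}

test_that("match_finding implements per-vocabulary subset matching", {
  tt <- test_terms()
  f <- finding(tt$human, cell_type = tt$dc)
  expect_true(match_finding(f, filter_criteria(cell_type = tt$dc)))
  expect_true(match_finding(f, filter_criteria()))
  expect_false(match_finding(finding(tt$mouse),
                             filter_criteria(organism = tt$human)))
  # a constrained vocabulary missing from the finding fails the match
  expect_false(match_finding(finding(tt$human),
                             filter_criteria(cell_type = tt$dc)))
})

test_that("initial_status applies evidence and the unknown policy", {
  tt <- test_terms()
  pw <- pathway("s", "S", tt$human, glyphs = list(
    glyph("dc_g", "macromolecule",
          findings = list(finding(tt$human, cell_type = tt$dc))),
    glyph("mf_g", "macromolecule",
          findings = list(finding(tt$human, cell_type = tt$mf))),
    glyph("bare", "macromolecule")))
  crit_dc <- filter_criteria(cell_type = tt$dc)
  st <- initial_status(pw, crit_dc)
  s <- stats::setNames(st$status, st$element_id)
  expect_identical(unname(s[c("dc_g", "mf_g", "bare")]),
                   c("included", "excluded", "included"))
  strict <- filter_criteria(cell_type = tt$dc, unknown_policy = "strict")
  s2 <- initial_status(pw, strict)
  expect_identical(s2$status[s2$element_id == "bare"], "excluded")
})

test_that("affected status propagates through complexes and processes", {
  tt <- test_terms()
  # B carries only macrophage evidence -> excluded under a DC filter
  pw <- two_step_pathway(finding(tt$human, cell_type = tt$mf))
  res <- apply_filter(pw, filter_criteria(cell_type = tt$dc))
  s <- stats::setNames(res$status$status, res$status$element_id)
  expect_identical(unname(s["B"]), "excluded")
  expect_identical(unname(s["cx"]), "affected")   # complex misses a subunit
  expect_identical(unname(s["P"]), "affected")    # consumes the complex
  expect_identical(unname(s["Q"]), "affected")    # only producer compromised
  expect_identical(unname(s["a1"]), "affected")
  expect_identical(unname(s["a2"]), "affected")

  # all-included input is a fixpoint
  st0 <- initial_status(pw, filter_criteria())
  expect_identical(propagate_affected(pw, st0), st0)
})

test_that("plain stimulation does not propagate, necessary stimulation does", {
  tt <- test_terms()
  mk <- function(cls) {
    pathway("s", "S", tt$human,
            glyphs = list(
              glyph("mod", "macromolecule",
                    findings = list(finding(tt$mouse))),
              glyph("in1", "macromolecule"),
              glyph("out1", "macromolecule"),
              glyph("P", "process")),
            arcs = list(arc("am", cls, "mod", "P"),
                        arc("ai", "consumption", "in1", "P"),
                        arc("ao", "production", "P", "out1")))
  }
  crit <- filter_criteria(organism = tt$human)
  s1 <- apply_filter(mk("stimulation"), crit)$status
  expect_identical(s1$status[s1$element_id == "P"], "included")
  s2 <- apply_filter(mk("necessary-stimulation"), crit)$status
  expect_identical(s2$status[s2$element_id == "P"], "affected")
})

test_that("propagation is idempotent and order-independent (oracle check)", {
  for (s in 1:40) {
    pw <- random_small_pathway(s)
    st <- random_status(pw, s * 7)
    fix <- propagate_affected(pw, st)
    expect_identical(propagate_affected(pw, fix), fix)
    # two different exhaustive visiting orders agree with the engine
    expect_identical(propagate_oracle(pw, st, order_seed = 1)$status,
                     fix$status)
    expect_identical(propagate_oracle(pw, st, order_seed = 2)$status,
                     fix$status)
  }
})

test_that("apply_filter with drop prunes excluded elements monotonically", {
  pw <- table1_fixture("TLR3")
  tt <- test_terms()
  # identity filter keeps everything
  res <- apply_filter(pw, filter_criteria(), drop = TRUE)
  expect_identical(sort(bcml:::all_glyph_ids(res$pathway)),
                   sort(bcml:::all_glyph_ids(pw)))
  expect_true(all(res$status$status == "included"))

  # a context never curated: every entity glyph is excluded
  res2 <- apply_filter(pw, filter_criteria(organism = tt$mouse))
  tl <- tidy(pw)
  ent_ids <- tl$element_id[tl$element == "glyph" &
                             tl$cls %in% c("macromolecule", "complex",
                                           "simple-chemical")]
  s <- stats::setNames(res2$status$status, res2$status$element_id)
  expect_true(all(s[ent_ids] == "excluded"))

  # dropped sub-pathway only loses elements, never gains
  res3 <- apply_filter(pw, filter_criteria(organism = tt$mouse), drop = TRUE)
  expect_true(all(bcml:::all_glyph_ids(res3$pathway) %in%
                    bcml:::all_glyph_ids(pw)))
  v <- validate(res3$pathway)
  expect_false(any(v$severity == "error"))
})
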