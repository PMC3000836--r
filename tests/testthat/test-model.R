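test_that("vocabulary registration interns terms and rejects conflicts", {
  t1 <- register_term("cell-type", "CL:TEST0001", "test cell")
  t2 <- register_term("cell-type", "CL:TEST0001", "test cell")
  expect_identical(t1, t2)
  expect_identical(lookup_term("cell-type", "CL:TEST0001"), t1)
  expect_error(register_term("cell-type", "CL:TEST0001", "other label"),
               "label conflict")
  expect_error(register_term("flavor", "X", "y"), "unknown vocabulary")
  expect_error(register_term("organism", "", "empty"), "non-empty")
})

test_that("bundled vocabulary is loaded and findings check term vocabularies", {
  expect_s3_class(lookup_term("organism", "NCBITaxon:9606"), "bcml_term")
  vt <- vocabulary_table()
  expect_true(all(c("organism", "cell-type") %in% vt$vocabulary))
  tt <- test_terms()
  f <- finding(tt$human, cell_type = tt$dc, references = "PMID:1")
  expect_identical(f$organism$identifier, "NCBITaxon:9606")
  # a cell-type term cannot stand in for an organism
  expect_error(finding(tt$dc), "vocabulary")
})

test_that("gene_identifiers handles genes, chemicals and complex expansion", {
  g <- glyph("socs1", "macromolecule", label = "SOCS1",
             xrefs = list(xref("EntrezGene", "8651")))
  expect_identical(gene_identifiers(g), "8651")
  expect_identical(entity_kind(g), "gene")

  chem <- glyph("pip2", "simple-chemical", label = "PI(4,5)P2")
  expect_identical(gene_identifiers(chem), character())
  expect_identical(entity_kind(chem), "chemical")

  cx <- glyph("cd8086", "complex", components = list(
    glyph("cd80", "macromolecule", xrefs = list(xref("EntrezGene", "941"))),
    glyph("cd86", "macromolecule", xrefs = list(xref("EntrezGene", "942")))))
  expect_identical(gene_identifiers(cx, expand_complexes = TRUE),
                   c("941", "942"))
  expect_identical(gene_identifiers(cx, expand_complexes = FALSE), character())
  # idempotent and order-independent over components
  cx2 <- glyph("cd8086b", "complex", components = list(
    glyph("cd86b", "macromolecule", xrefs = list(xref("EntrezGene", "942"))),
    glyph("cd80b", "macromolecule", xrefs = list(xref("EntrezGene", "941")))))
  expect_identical(gene_identifiers(cx2), gene_identifiers(cx))
})

test_that("constructor invariants reject malformed elements", {
  expect_error(glyph("p", "process", xrefs = list(xref("EntrezGene", "1"))),
               "carry no xrefs")
  expect_error(glyph("m", "macromolecule",
                     components = list(glyph("x", "macromolecule"))),
               "only complex")
  # self-containing nesting (duplicated id along the path) is rejected
  expect_error(glyph("c1", "complex", components = list(
    glyph("c1", "macromolecule"))), "acyclic")
  expect_error(arc("a", "consumption", "x", "x"), "must differ")
  expect_error(pathway_module("m", "sensing", members = character()),
               "at least one member")
  expect_error(pathway_module("m", "sensing", members = "a",
                              entry = "a", exit = "b"), "members")
})

test_that("pathway constructor enforces referential integrity", {
  tt <- test_terms()
  g1 <- glyph("g1", "macromolecule")
  expect_error(
    pathway("p", "P", tt$human, glyphs = list(g1, g1)),
    "duplicate")
  expect_error(
    pathway("p", "P", tt$human, glyphs = list(g1),
            arcs = list(arc("a1", "consumption", "g1", "missing"))),
    "missing glyph")
  expect_error(
    pathway("p", "P", tt$human, glyphs = list(g1),
            modules = list(pathway_module("m1", "sensing", members = "nope"))),
    "missing elements")
})

test_that("module chaining on shipped fixtures shares boundary glyphs", {
  for (nm in tlr_pathway_names()) {
    pw <- table1_fixture(nm)
    mods <- stats::setNames(pw$modules, vapply(pw$modules, `[[`, "", "id"))
    for (p in pw$module_chain) {
      expect_identical(mods[[p[1]]]$exit, mods[[p[2]]]$entry)
    }
  }
})
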