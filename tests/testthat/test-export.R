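test_that("fixture gene lists reproduce the curated new-gene counts", {
  counts <- c("TLR1/TLR2" = 21, "TLR2/TLR6" = 26, "TLR3" = 23, "TLR4" = 37,
              "TLR7" = 7, "TLR8" = 5, "TLR9" = 21)
  for (nm in names(counts)) {
    expect_length(gene_list(table1_fixture(nm), scope = "new_only"),
                  unname(counts[nm]))
  }
  # the TLR5 outcome list double-counts IL18 in print; unique genes = 24
  expect_length(gene_list(table1_fixture("TLR5"), scope = "new_only"), 24)

  # chemical exclusion and family expansion behind the TLR4 count
  tlr4 <- table1_fixture("TLR4")
  gl <- gene_list(tlr4, scope = "new_only")
  expect_false(any(grepl("^PI", gl)))           # accessions only
  expect_true(all(c("26052", "1785", "1759") %in% gl))  # dynamin family
  tl <- tidy(tlr4)
  expect_true("PI(4,5)P2" %in% tl$label[tl$kind == "chemical"])
})

test_that("gene_list respects modules, status and ordering invariance", {
  pw <- table1_fixture("TLR9")
  mods <- vapply(pw$modules, `[[`, "", "id")
  sens <- mods[vapply(pw$modules, `[[`, "", "mtype") == "sensing"]
  expect_true("81622" %in% gene_list(pw, modules = sens))  # UNC93B1 sensing
  expect_error(gene_list(pw, modules = "nope"), "unknown module")

  # excluded elements drop out through a status map
  st <- initial_status(pw, filter_criteria())
  st$status[st$element_id == "tlr9_s_unc93b1"] <- "excluded"
  expect_false("81622" %in% gene_list(pw, status = st))

  sets <- module_gene_sets(pw)
  expect_identical(sort(names(sets)), sort(mods))
  # boundary transcription factor is shared by transduction and outcome
  t_id <- mods[vapply(pw$modules, `[[`, "", "mtype") == "transduction"]
  o_id <- mods[vapply(pw$modules, `[[`, "", "mtype") == "outcome"]
  shared <- intersect(sets[[t_id]], sets[[o_id]])
  expect_gt(length(shared), 0)
  # union over modules is contained in the full list
  expect_true(all(unlist(sets) %in% gene_list(pw)))
})

test_that("grp and gmt writers emit the expected plain-text formats", {
  pw <- table1_fixture("TLR8")
  genes <- gene_list(pw, scope = "new_only")
  f <- withr::local_tempfile(fileext = ".grp")
  write_grp(genes, f)
  expect_identical(readLines(f), genes)

  sets <- module_gene_sets(pw)
  names(sets) <- paste0("TLR8_", names(sets))
  g <- withr::local_tempfile(fileext = ".gmt")
  write_gmt(sets, g)
  lines <- strsplit(readLines(g), "\t")
  expect_length(lines, length(sets))
  expect_identical(vapply(lines, `[[`, "", 1), names(sets))
  expect_identical(lines[[1]][-(1:2)], sets[[1]])
})

spia_toy <- function() {
  tt <- test_terms()
  pathway("sp", "SP", tt$human,
          glyphs = list(
            glyph("A", "macromolecule", xrefs = list(xref("EntrezGene", "1"))),
            glyph("B", "macromolecule", xrefs = list(xref("EntrezGene", "2"))),
            glyph("C", "macromolecule", xrefs = list(xref("EntrezGene", "3"))),
            glyph("P", "process"), glyph("P2", "process")),
          arcs = list(arc("a1", "consumption", "A", "P"),
                      arc("a2", "production", "P", "B"),
                      arc("a3", "inhibition", "C", "P2"),
                      arc("a4", "consumption", "B", "P2"),
                      arc("a5", "production", "P2", "A")))
}

test_that("SPIA relations carry single-step signs and binding symmetry", {
  rel <- to_spia_relations(spia_toy())
  expect_true(nrow(dplyr::filter(rel, source == "1", target == "2",
                                 relation == "activation")) == 1)
  expect_true(nrow(dplyr::filter(rel, source == "3", target == "1",
                                 relation == "inhibition")) == 1)
  expect_false(any(rel$source == rel$target))

  cx <- glyph("cx", "complex", components = list(
    glyph("m1", "macromolecule", xrefs = list(xref("EntrezGene", "10"))),
    glyph("m2", "macromolecule", xrefs = list(xref("EntrezGene", "20")))))
  tt <- test_terms()
  pw <- pathway("b", "B", tt$human, glyphs = list(cx))
  rel2 <- to_spia_relations(pw)
  expect_setequal(paste(rel2$source, rel2$target, rel2$relation),
                  c("10 20 binding", "20 10 binding"))
})

test_that("SPIA relations honour not-operators and status exclusion", {
  tt <- test_terms()
  pw <- pathway("n", "N", tt$human,
                glyphs = list(
                  glyph("A", "macromolecule",
                        xrefs = list(xref("EntrezGene", "1"))),
                  glyph("B", "macromolecule",
                        xrefs = list(xref("EntrezGene", "2"))),
                  glyph("ntg", "not-operator"), glyph("P", "process"),
                  glyph("D", "macromolecule",
                        xrefs = list(xref("EntrezGene", "4")))),
                arcs = list(arc("l1", "logic-arc", "A", "ntg"),
                            arc("s1", "stimulation", "ntg", "P"),
                            arc("c1", "consumption", "D", "P"),
                            arc("p1", "production", "P", "B")))
  rel <- to_spia_relations(pw)
  expect_identical(
    rel$relation[rel$source == "1" & rel$target == "2"], "inhibition")
  expect_identical(
    rel$relation[rel$source == "4" & rel$target == "2"], "activation")

  st <- tibble::tibble(
    element_id = c("A", "B", "ntg", "P", "D", "l1", "s1", "c1", "p1"),
    element = c(rep("glyph", 5), rep("arc", 4)),
    status = c("excluded", rep("included", 8)))
  rel2 <- to_spia_relations(pw, status = st)
  expect_false(any(rel2$source == "1"))
})

test_that("overlay assigns states by threshold with max-magnitude aggregation", {
  tt <- test_terms()
  pw <- pathway("o", "O", tt$human, glyphs = list(
    glyph("up_g", "macromolecule", xrefs = list(xref("EntrezGene", "1"))),
    glyph("cxg", "complex", components = list(
      glyph("w1", "macromolecule", xrefs = list(xref("EntrezGene", "2"))),
      glyph("w2", "macromolecule", xrefs = list(xref("EntrezGene", "3"))))),
    glyph("tie", "complex", components = list(
      glyph("t1", "macromolecule", xrefs = list(xref("EntrezGene", "4"))),
      glyph("t2", "macromolecule", xrefs = list(xref("EntrezGene", "5"))))),
    glyph("nox", "unspecified-entity")))
  m <- matrix(c(2, 0.2, -1.5, 1.2, -1.2), ncol = 1,
              dimnames = list(c("1", "2", "3", "4", "5"), "cond"))
  sm <- overlay(pw, m, "cond", threshold = 1)
  s <- stats::setNames(sm$state, sm$glyph_id)
  v <- stats::setNames(sm$value, sm$glyph_id)
  expect_identical(unname(s["up_g"]), "up")
  expect_identical(unname(s["cxg"]), "down")       # max |member| wins
  expect_identical(unname(v[["cxg"]]), -1.5)
  expect_identical(unname(s["tie"]), "unchanged")  # opposite-sign tie
  expect_identical(unname(s["nox"]), "unmeasured")
  expect_error(overlay(pw, m, "absent"), "absent")
  expect_error(overlay(pw, m, "cond", threshold = 0))
})
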