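# Curated Toll-like receptor fixture pathways.
#
# Eight TLR pathways of human dendritic cells with their newly curated
# member genes (tagged "new"), each placed in its stated module class
# (sensing / transduction / outcome).  Protein families (MHC, PI3K, dynamin)
# are complex-class family glyphs expanded to one component per member gene;
# PI(4,5)P2 is a simple chemical.  The wiring scaffold (receptor, adaptor,
# transcription factor, one process per module, boundary chaining) is
# synthetic: it exists to make the documents structurally valid and
# module-chained, not to reproduce the full curated topology.

.g <- function(symbol, id) list(type = "gene", symbol = symbol, id = id)
.f <- function(symbol, members) list(type = "family", symbol = symbol,
                                     members = members)
.c <- function(symbol) list(type = "chemical", symbol = symbol)

MHC_12 <- c("HLA-E" = "3133", "HLA-DMB" = "3109", "HLA-DOA" = "3111",
            "HLA-DPA1" = "3113", "HLA-DPB1" = "3115", "HLA-DQA1" = "3117",
            "HLA-DQB1" = "3119", "HLA-DRA" = "3122", "HLA-DRB1" = "3123",
            "HLA-DRB3" = "3125", "HLA-DRB4" = "3126", "HLA-DRB5" = "3127")
MHCII_11 <- MHC_12[names(MHC_12) != "HLA-E"]
MHC_5 <- c("HLA-DRB5" = "3127", "HLA-DRB4" = "3126", "HLA-DRB3" = "3125",
           "HLA-DRB1" = "3123", "HLA-DRA" = "3122")
PI3K_15 <- c("PIK3R2" = "5296", "PIK3CG" = "5294", "PIK3CD" = "5293",
             "PIK3CB" = "5291", "PIK3CA" = "5290", "PIK3C3" = "5289",
             "PIK3C2G" = "5288", "PIK3C2B" = "5287", "PIK3C2A" = "5286",
             "PIK3R1" = "5295", "PIK3R5" = "23533", "PIK3R6" = "146850",
             "PIK3R4" = "30849", "PIK3R1OS" = "404543", "PIK3R3" = "8503")
DYNAMIN_3 <- c("DNM3" = "26052", "DNM2" = "1785", "DNM1" = "1759")

TLR_TABLE1 <- list(
  "TLR1/TLR2" = list(
    receptor = c("TLR1" = "7096", "TLR2" = "7097"), location = "pm",
    adaptor = .g("MYD88", "4615"), tf = .g("NFKB1", "4790"),
    sensing = list(),
    transduction = list(.g("SOCS1", "8651"), .g("BTK", "695"),
                        .g("PPARG", "5468")),
    outcome = list(.g("CXCL2", "2920"), .g("IL2", "3558"),
                   .g("MAP3K8", "1326"), .f("MHC", MHC_12),
                   .g("CD86", "942"), .g("CCL19", "6363"), .g("CCL2", "6347"))
  ),
  "TLR2/TLR6" = list(
    receptor = c("TLR2" = "7097", "TLR6" = "10333"), location = "pm",
    adaptor = .g("MYD88", "4615"), tf = .g("NFKB1", "4790"),
    sensing = list(),
    transduction = list(.g("SOCS1", "8651"), .g("BTK", "695"),
                        .g("PPARG", "5468"), .g("PRKCA", "5578")),
    outcome = list(.g("CXCL2", "2920"), .g("IL2", "3558"),
                   .g("MAP3K8", "1326"), .f("MHC", MHC_12),
                   .g("CD86", "942"), .g("CCL19", "6363"), .g("CCL2", "6347"),
                   .g("IL10", "3586"), .g("CD80", "941"), .g("CD40", "958"),
                   .g("CCR7", "1236"))
  ),
  "TLR3" = list(
    receptor = c("TLR3" = "7098"), location = "endo",
    adaptor = .g("TICAM1", "148022"), tf = .g("IRF3", "3661"),
    sensing = list(),
    transduction = list(.g("PRKCA", "5578"), .g("PRKCB1", "5579"),
                        .g("CREBBP", "1387"), .g("SRC", "6714"),
                        .g("AKT1", "207")),
    outcome = list(.g("IL10", "3586"), .g("IL29", "282618"),
                   .g("IL28A", "282616"), .g("IL28B", "282617"),
                   .g("IL1A", "3552"), .g("CCL3", "6348"), .g("CCR7", "1236"),
                   .g("CD274", "29126"), .g("STAT4", "6775"),
                   .g("SOCS1", "8651"), .g("INDO", "3620"),
                   .g("ICAM1", "3383"), .g("CD83", "9308"),
                   .f("MHC", MHC_5))
  ),
  "TLR4" = list(
    receptor = c("TLR4" = "7099"), location = "pm",
    adaptor = .g("MYD88", "4615"), tf = .g("NFKB1", "4790"),
    sensing = list(),
    transduction = list(.c("PI(4,5)P2"), .g("IRAK2", "3656"),
                        .g("IRAK3", "11213"), .g("MAP3K7IP3", "257397"),
                        .f("dynamin", DYNAMIN_3), .g("RIPK3", "11035"),
                        .g("TNKS", "8658"), .g("AZI2", "64343"),
                        .g("TBKBP1", "9755")),
    outcome = list(.g("IL1A", "3552"), .g("IL10", "3586"),
                   .g("IL12A", "3592"), .g("IL12B", "3593"),
                   .g("IL15", "3600"), .g("IL23A", "51561"),
                   .g("LTA", "4049"), .g("CCL19", "6363"),
                   .g("TNFSF10", "8743"), .g("IRF1", "3659"),
                   .g("IRF3", "3661"), .g("IRF5", "3663"),
                   .g("IRF7", "3665"), .g("IRF9", "10379"),
                   .g("CXCL10", "3627"), .f("MHC", MHC_12))
  ),
  "TLR5" = list(
    receptor = c("TLR5" = "7100"), location = "pm",
    adaptor = .g("MYD88", "4615"), tf = .g("NFKB1", "4790"),
    sensing = list(),
    transduction = list(.f("PI3K", PI3K_15), .g("PRKD1", "5587"),
                        .g("AKT1", "207")),
    # the printed outcome list names IL18 twice; the fixture stores the 24
    # unique genes and records the printed count of 25 in an extension note
    outcome = list(.g("CXCL2", "2920"), .g("IL18", "3606"),
                   .g("CCL20", "6364"), .g("IL10", "3586"),
                   .g("IL12A", "3592"), .g("IL12B", "3593"),
                   .g("CCL2", "6347")),
    note = c("printed-new-gene-count" = "25")
  ),
  "TLR7" = list(
    receptor = c("TLR7" = "51284"), location = "endo",
    adaptor = .g("MYD88", "4615"), tf = .g("IRF7", "3665"),
    sensing = list(),
    transduction = list(.g("MEF2C", "4208"), .g("PIK3CA", "5290"),
                        .g("PIK3CB", "5291"), .g("PIK3CG", "5294"),
                        .g("IRF4", "3662")),
    outcome = list(.g("IL12A", "3592"), .g("IL12B", "3593"))
  ),
  "TLR8" = list(
    receptor = c("TLR8" = "51311"), location = "endo",
    adaptor = .g("MYD88", "4615"), tf = .g("NFKB1", "4790"),
    sensing = list(),
    transduction = list(.g("MEF2C", "4208"), .g("IRF1", "3659")),
    outcome = list(.g("IL12A", "3592"), .g("IL12B", "3593"),
                   .g("NOS2", "4843"))
  ),
  "TLR9" = list(
    receptor = c("TLR9" = "54106"), location = "endo",
    adaptor = .g("MYD88", "4615"), tf = .g("NFKB1", "4790"),
    sensing = list(.g("UNC93B1", "81622")),
    transduction = list(.g("PIK3CD", "5293")),
    outcome = list(.f("MHCII", MHCII_11), .g("CD80", "941"),
                   .g("CD83", "9308"), .g("CD86", "942"), .g("CD40", "958"),
                   .g("CCL3", "6348"), .g("CXCL10", "3627"),
                   .g("ICAM1", "3383"), .g("CCR7", "1236"))
  )
)

#' Names of the bundled TLR fixture pathways
#' @return Character vector of the 8 pathway names.
#' @export
tlr_pathway_names <- function() names(TLR_TABLE1)

sanitize_id <- function(x) {
  tolower(gsub("[^A-Za-z0-9]+", "_", x))
}

human_dc_finding <- function() {
  finding(register_term("organism", "NCBITaxon:9606", "Homo sapiens"),
          cell_type = register_term("cell-type", "CL:0000451",
                                    "dendritic cell"))
}

item_glyph <- function(prefix, item, compartment, tag = "new") {
  fnd <- list(human_dc_finding())
  id <- paste0(prefix, "_", sanitize_id(item$symbol))
  switch(item$type,
    gene = glyph(id, "macromolecule", label = item$symbol,
                 compartment = compartment,
                 xrefs = list(entrez_xref(item$id)), findings = fnd,
                 tags = tag),
    chemical = glyph(id, "simple-chemical", label = item$symbol,
                     compartment = compartment, findings = fnd, tags = tag),
    family = glyph(id, "complex", label = item$symbol,
                   compartment = compartment, family = TRUE, findings = fnd,
                   tags = tag,
                   components = lapply(names(item$members), function(sym) {
                     glyph(paste0(id, "_", sanitize_id(sym)),
                           "macromolecule", label = sym,
                           compartment = compartment,
                           xrefs = list(entrez_xref(item$members[[sym]])),
                           findings = list(human_dc_finding()))
                   }))
  )
}

#' Build one curated TLR fixture pathway
#'
#' @param pathway_name One of [tlr_pathway_names()]: `"TLR1/TLR2"`,
#'   `"TLR2/TLR6"`, `"TLR3"`, `"TLR4"`, `"TLR5"`, `"TLR7"`, `"TLR8"`,
#'   `"TLR9"`.
#' @return A valid `bcml_pathway` with one sensing, one transduction and one
#'   outcome module chained through their boundary glyphs (adaptor,
#'   transcription factor), all newly curated entries tagged `"new"`.
#' @examples
#' pw <- table1_fixture("TLR9")
#' length(gene_list(pw, scope = "new_only"))  # 21
#' @export
table1_fixture <- function(pathway_name) {
  if (!pathway_name %in% names(TLR_TABLE1)) {
    stop("unknown pathway name: '", pathway_name, "'; expected one of ",
         paste(names(TLR_TABLE1), collapse = ", "), call. = FALSE)
  }
  def <- TLR_TABLE1[[pathway_name]]
  px <- sanitize_id(pathway_name)
  fnd <- list(human_dc_finding())

  compartments <- list(compartment("pm", "plasma membrane"),
                       compartment("endo", "endosome"),
                       compartment("cyt", "cytoplasm"),
                       compartment("nuc", "nucleus"))

  rec_id <- paste0(px, "_rec")
  rec <- if (length(def$receptor) > 1) {
    glyph(rec_id, "complex", label = pathway_name,
          compartment = def$location, findings = fnd,
          components = lapply(names(def$receptor), function(sym) {
            glyph(paste0(rec_id, "_", sanitize_id(sym)), "macromolecule",
                  label = sym, compartment = def$location,
                  xrefs = list(entrez_xref(def$receptor[[sym]])),
                  findings = list(human_dc_finding()))
          }))
  } else {
    glyph(rec_id, "macromolecule", label = names(def$receptor),
          compartment = def$location,
          xrefs = list(entrez_xref(def$receptor[[1]])), findings = fnd)
  }
  adaptor <- glyph(paste0(px, "_adaptor"), "macromolecule",
                   label = def$adaptor$symbol, compartment = "cyt",
                   xrefs = list(entrez_xref(def$adaptor$id)), findings = fnd)
  tf <- glyph(paste0(px, "_tf"), "macromolecule", label = def$tf$symbol,
              compartment = "nuc", xrefs = list(entrez_xref(def$tf$id)),
              findings = fnd)
  ps <- glyph(paste0(px, "_ps"), "process", label = "sensing")
  pt <- glyph(paste0(px, "_pt"), "process", label = "transduction")
  po <- glyph(paste0(px, "_po"), "process", label = "transcription")

  sens_items <- lapply(def$sensing, item_glyph, prefix = paste0(px, "_s"),
                       compartment = def$location)
  trans_items <- lapply(def$transduction, item_glyph,
                        prefix = paste0(px, "_t"), compartment = "cyt")
  out_items <- lapply(def$outcome, item_glyph, prefix = paste0(px, "_o"),
                      compartment = "nuc")

  glyphs <- c(list(rec, adaptor, tf, ps, pt, po), sens_items, trans_items,
              out_items)

  aid <- function(...) paste0(px, "_a_", paste(..., sep = "_"))
  arcs <- list(
    arc(aid("rec_ps"), "consumption", rec$id, ps$id),
    arc(aid("ps_adaptor"), "production", ps$id, adaptor$id),
    arc(aid("adaptor_pt"), "consumption", adaptor$id, pt$id),
    arc(aid("pt_tf"), "production", pt$id, tf$id),
    arc(aid("tf_po"), "consumption", tf$id, po$id)
  )
  for (g in sens_items) {
    arcs[[length(arcs) + 1]] <- arc(aid(g$id, "cat"), "catalysis", g$id, ps$id)
  }
  for (g in trans_items) {
    arcs[[length(arcs) + 1]] <- arc(aid(g$id, "cat"), "catalysis", g$id, pt$id)
  }
  for (g in out_items) {
    arcs[[length(arcs) + 1]] <- arc(aid("po", g$id), "production", po$id, g$id)
  }

  arc_id_of <- stats::setNames(vapply(arcs, `[[`, "", "id"),
                               vapply(arcs, `[[`, "", "id"))
  sens_members <- c(rec$id, ps$id, adaptor$id,
                    vapply(sens_items, `[[`, "", "id"),
                    aid("rec_ps"), aid("ps_adaptor"),
                    vapply(sens_items, function(g) aid(g$id, "cat"), ""))
  trans_members <- c(adaptor$id, pt$id, tf$id,
                     vapply(trans_items, `[[`, "", "id"),
                     aid("adaptor_pt"), aid("pt_tf"),
                     vapply(trans_items, function(g) aid(g$id, "cat"), ""))
  out_members <- c(tf$id, po$id, vapply(out_items, `[[`, "", "id"),
                   aid("tf_po"),
                   vapply(out_items, function(g) aid("po", g$id), ""))

  short <- sanitize_id(pathway_name)
  modules <- list(
    pathway_module(paste0(px, "_m_s"), "sensing",
                   label = gsub("/", "-", pathway_name),
                   members = sens_members, entry = rec$id, exit = adaptor$id),
    pathway_module(paste0(px, "_m_t"), "transduction",
                   label = def$adaptor$symbol,
                   members = trans_members, entry = adaptor$id, exit = tf$id),
    pathway_module(paste0(px, "_m_o"), "outcome", label = def$tf$symbol,
                   members = out_members, entry = tf$id)
  )
  chain <- list(c(paste0(px, "_m_s"), paste0(px, "_m_t")),
                c(paste0(px, "_m_t"), paste0(px, "_m_o")))

  extensions <- character()
  if (!is.null(def$note)) {
    extensions <- vapply(names(def$note), function(k) {
      sprintf('<note key="%s">%s</note>', k, def$note[[k]])
    }, "")
  }

  pathway(id = px, name = pathway_name,
          organism = register_term("organism", "NCBITaxon:9606",
                                   "Homo sapiens"),
          compartments = compartments, glyphs = glyphs, arcs = arcs,
          modules = modules, module_chain = chain, extensions = extensions)
}

#' Build the full curated TLR pathway ensemble
#'
#' @return Named list of 8 valid `bcml_pathway` objects; TLR7 and TLR8 are
#'   curated separately (distinct pathways despite the shared ligand).
#' @export
table1_fixture_set <- function() {
  stats::setNames(lapply(names(TLR_TABLE1), table1_fixture),
                  names(TLR_TABLE1))
}
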