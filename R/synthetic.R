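# Synthetic pathway/expression generator.
#
# Emulates the study design the analysis layer is meant for: a treated-vs-
# control expression experiment in which a known set of pathway modules is
# activated with a fixed fold change, on top of lognormal baseline
# intensities and multiplicative replicate noise.  Ground truth (which
# modules are active per condition) travels with the data, closing the
# generate -> enrich -> cluster validation loop without any downloads.

#' Specify a synthetic study
#'
#' Defaults encode the reference validation design: two treated conditions,
#' three replicates, 4-fold activation of the active modules, lognormal
#' replicate noise with sigma 0.25 on the log2 scale.
#'
#' @param n_pathways Number of generated pathways.
#' @param modules_per_pathway Named integer vector
#'   `c(sensing=, transduction=, outcome=)`.
#' @param genes_per_module Genes per module (>= 5 keeps modules on the Fisher
#'   branch of the PEF transform; transduction modules need >= 5 to fit
#'   their complex).
#' @param n_conditions Treated conditions.
#' @param replicates Replicates per condition (treated and control).
#' @param active_modules Named list: condition id -> list(modules =
#'   character vector of PEF row names, direction = +1/-1).  Default:
#'   condition *i* activates (direction +1) the transduction and outcome
#'   modules of pathway `((i-1) %% n_pathways) + 1`.
#' @param effect Linear fold change applied to active-module genes (> 1).
#' @param noise_sigma SD (log2 scale) of multiplicative replicate noise
#'   (>= 0).
#' @param n_background_genes Measured genes outside every pathway.
#' @param seed Integer seed; generation is fully deterministic.
#' @return A `bcml_synth_spec` list.
#' @export
synth_spec <- function(n_pathways = 2,
                       modules_per_pathway = c(sensing = 1, transduction = 2,
                                               outcome = 1),
                       genes_per_module = 8,
                       n_conditions = 2,
                       replicates = 3,
                       active_modules = NULL,
                       effect = 4,
                       noise_sigma = 0.25,
                       n_background_genes = 300,
                       seed = 1) {
  stopifnot(n_pathways >= 1, effect > 1, noise_sigma >= 0,
            genes_per_module >= 3, replicates >= 1, n_conditions >= 1,
            all(c("sensing", "transduction", "outcome") %in%
                  names(modules_per_pathway)),
            all(modules_per_pathway >= c(1, 1, 1)))
  structure(list(n_pathways = n_pathways,
                 modules_per_pathway = modules_per_pathway,
                 genes_per_module = genes_per_module,
                 n_conditions = n_conditions, replicates = replicates,
                 active_modules = active_modules, effect = effect,
                 noise_sigma = noise_sigma,
                 n_background_genes = n_background_genes, seed = seed),
            class = "bcml_synth_spec")
}

synth_contexts <- function() {
  human <- register_term("organism", "NCBITaxon:9606", "Homo sapiens")
  mouse <- register_term("organism", "NCBITaxon:10090", "Mus musculus")
  dc <- register_term("cell-type", "CL:0000451", "dendritic cell")
  mf <- register_term("cell-type", "CL:0000235", "macrophage")
  list(human_dc = finding(human, cell_type = dc),
       mouse_dc = finding(mouse, cell_type = dc),
       human_mf = finding(human, cell_type = mf))
}

# deterministic accession supply: synthetic EntrezGene-style ids
accession_pool <- function(n, offset = 0) {
  as.character(100000 + offset + seq_len(n))
}

#' Generate synthetic pathways
#'
#' Each pathway mirrors the sensing/transduction/outcome architecture:
#' receptor, shared adaptor (sensing exit = transduction entry), one
#' transcription factor per transduction module, outcome modules assigned to
#' transcription factors round-robin.  Each transduction module contains one
#' two-member complex; entity glyphs carry findings drawn from a small
#' context set (human DC, mouse DC, human macrophage) so filtering is
#' exercised.  Gene accessions are disjoint across modules and pathways.
#'
#' @param spec A [synth_spec()].
#' @return Named list of valid `bcml_pathway` objects.
#' @export
synth_pathways <- function(spec) {
  stopifnot(inherits(spec, "bcml_synth_spec"))
  set.seed(spec$seed)
  ctx <- synth_contexts()
  pick_findings <- function(backbone = FALSE) {
    if (backbone) return(list(ctx$human_dc))
    u <- runif(1)
    if (u < 0.7) list(ctx$human_dc)
    else if (u < 0.85) list(ctx$human_dc, ctx$mouse_dc)
    else if (u < 0.95) list(ctx$mouse_dc)
    else list(ctx$human_mf)
  }
  n_genes_total <- spec$n_pathways *
    (sum(spec$modules_per_pathway) + 2) * (spec$genes_per_module + 2)
  pool <- sample(accession_pool(n_genes_total * 2))
  next_acc <- local({
    i <- 0
    function() {
      i <<- i + 1
      pool[i]
    }
  })

  out <- list()
  for (p in seq_len(spec$n_pathways)) {
    name <- paste0("SP", p)
    px <- tolower(name)
    nt <- spec$modules_per_pathway[["transduction"]]
    no <- spec$modules_per_pathway[["outcome"]]
    gm <- spec$genes_per_module

    mk_gene <- function(id, label, backbone = FALSE, compartment = "cyt") {
      glyph(id, "macromolecule", label = label, compartment = compartment,
            xrefs = list(entrez_xref(next_acc())),
            findings = pick_findings(backbone))
    }
    compartments <- list(compartment("pm", "plasma membrane"),
                         compartment("cyt", "cytoplasm"),
                         compartment("nuc", "nucleus"))
    rec <- mk_gene(paste0(px, "_rec"), paste0(name, "R"), backbone = TRUE,
                   compartment = "pm")
    adaptor <- mk_gene(paste0(px, "_adaptor"), paste0(name, "A"),
                       backbone = TRUE)
    tfs <- lapply(seq_len(nt), function(j) {
      mk_gene(paste0(px, "_tf", j), paste0(name, "TF", j), backbone = TRUE,
              compartment = "nuc")
    })
    glyphs <- c(list(rec, adaptor), tfs)
    arcs <- list()
    modules <- list()
    chain <- list()
    add_arc <- function(id, cls, s, t) {
      arcs[[length(arcs) + 1]] <<- arc(id, cls, s, t)
      id
    }

    # sensing
    ps <- glyph(paste0(px, "_ps"), "process")
    glyphs <- c(glyphs, list(ps))
    s_extra <- lapply(seq_len(gm - 2), function(k) {
      mk_gene(paste0(px, "_sg", k), paste0(name, "S", k), compartment = "pm")
    })
    glyphs <- c(glyphs, s_extra)
    s_arcs <- c(add_arc(paste0(px, "_a_rec"), "consumption", rec$id, ps$id),
                add_arc(paste0(px, "_a_ad"), "production", ps$id, adaptor$id),
                vapply(s_extra, function(g) {
                  add_arc(paste0(g$id, "_cat"), "catalysis", g$id, ps$id)
                }, ""))
    m_s <- pathway_module(paste0(px, "_m_s"), "sensing", label = "R",
                          members = c(rec$id, adaptor$id, ps$id,
                                      vapply(s_extra, `[[`, "", "id"),
                                      s_arcs),
                          entry = rec$id, exit = adaptor$id)
    modules <- c(modules, list(m_s))

    # transduction modules (shared adaptor entry, own TF exit)
    for (j in seq_len(nt)) {
      pt <- glyph(paste0(px, "_pt", j), "process")
      n_extra <- max(0, gm - 4)
      extras <- lapply(seq_len(n_extra), function(k) {
        mk_gene(paste0(px, "_t", j, "g", k), paste0(name, "T", j, "_", k))
      })
      cplx <- glyph(paste0(px, "_t", j, "cx"), "complex",
                    label = paste0(name, "T", j, "cx"),
                    compartment = "cyt",
                    findings = pick_findings(),
                    components = list(
                      mk_gene(paste0(px, "_t", j, "cxa"),
                              paste0(name, "T", j, "cxA")),
                      mk_gene(paste0(px, "_t", j, "cxb"),
                              paste0(name, "T", j, "cxB"))))
      glyphs <- c(glyphs, list(pt, cplx), extras)
      t_arcs <- c(
        add_arc(paste0(px, "_a_pt", j, "_in"), "consumption", adaptor$id,
                pt$id),
        add_arc(paste0(px, "_a_pt", j, "_out"), "production", pt$id,
                tfs[[j]]$id),
        add_arc(paste0(px, "_a_pt", j, "_cx"), "catalysis", cplx$id, pt$id),
        vapply(extras, function(g) {
          add_arc(paste0(g$id, "_cat"), "catalysis", g$id, pt$id)
        }, ""))
      m_t <- pathway_module(
        paste0(px, "_m_t", j), "transduction", label = paste0("TF", j),
        members = c(adaptor$id, tfs[[j]]$id, pt$id, cplx$id,
                    vapply(extras, `[[`, "", "id"), t_arcs),
        entry = adaptor$id, exit = tfs[[j]]$id)
      modules <- c(modules, list(m_t))
      chain <- c(chain, list(c(m_s$id, m_t$id)))
    }

    # outcome modules, round-robin over transcription factors
    for (j in seq_len(no)) {
      tf_j <- tfs[[((j - 1) %% nt) + 1]]
      po <- glyph(paste0(px, "_po", j), "process")
      targets <- lapply(seq_len(gm - 1), function(k) {
        mk_gene(paste0(px, "_o", j, "g", k), paste0(name, "O", j, "_", k),
                compartment = "nuc")
      })
      pheno <- glyph(paste0(px, "_o", j, "ph"), "phenotype",
                     label = "maturation")
      glyphs <- c(glyphs, list(po, pheno), targets)
      o_arcs <- c(
        add_arc(paste0(px, "_a_po", j, "_in"), "consumption", tf_j$id,
                po$id),
        vapply(targets, function(g) {
          add_arc(paste0(px, "_a_po", j, "_", g$id), "production", po$id,
                  g$id)
        }, ""),
        add_arc(paste0(px, "_a_po", j, "_ph"), "stimulation", tf_j$id,
                pheno$id))
      m_o <- pathway_module(
        paste0(px, "_m_o", j), "outcome", label = paste0("O", j),
        members = c(tf_j$id, po$id, pheno$id,
                    vapply(targets, `[[`, "", "id"), o_arcs),
        entry = tf_j$id)
      modules <- c(modules, list(m_o))
      chain <- c(chain, list(c(paste0(px, "_m_t", ((j - 1) %% nt) + 1),
                               m_o$id)))
    }

    out[[name]] <- pathway(
      id = px, name = name,
      organism = register_term("organism", "NCBITaxon:9606", "Homo sapiens"),
      compartments = compartments, glyphs = glyphs, arcs = arcs,
      modules = modules, module_chain = chain)
  }
  out
}

# PEF row name -> gene set, across a list of pathways
pef_row_gene_sets <- function(pathways) {
  out <- list()
  for (pw in pathways) {
    sets <- module_gene_sets(pw)
    for (mod in pw$modules) {
      out[[module_row_name(pw, mod)]] <- sets[[mod$id]]
    }
  }
  out
}

default_active_modules <- function(pathways, spec) {
  out <- list()
  for (i in seq_len(spec$n_conditions)) {
    pw <- pathways[[((i - 1) %% length(pathways)) + 1]]
    keys <- vapply(pw$modules, function(m) module_row_name(pw, m), "")
    mt <- vapply(pw$modules, `[[`, "", "mtype")
    out[[paste0("cond", i)]] <- list(
      modules = keys[mt %in% c("transduction", "outcome")], direction = 1)
  }
  out
}

#' Generate a synthetic expression experiment
#'
#' Baseline intensities are lognormal (mean 8, sd 1 on the log2 scale) per
#' gene; genes of the active modules are multiplied by
#' `effect^direction` in their condition; every sample adds multiplicative
#' replicate noise lognormal with sd `noise_sigma` (log2 scale).  The
#' measured gene universe is the union of the pathway genes plus
#' `n_background_genes` unrelated genes.  The generating truth is attached
#' as attribute `"truth"` (condition -> active PEF row names + direction).
#'
#' @param pathways Pathways from [synth_pathways()].
#' @param spec The same [synth_spec()].
#' @return A [expression_table()] with a `"truth"` attribute.
#' @export
synth_expression <- function(pathways, spec) {
  force(pathways)  # must be built before this function seeds the RNG
  stopifnot(inherits(spec, "bcml_synth_spec"))
  set.seed(spec$seed + 10000L)
  row_sets <- pef_row_gene_sets(pathways)
  active <- spec$active_modules
  if (is.null(active)) active <- default_active_modules(pathways, spec)
  unknown <- setdiff(unlist(lapply(active, `[[`, "modules")),
                     names(row_sets))
  if (length(unknown) > 0) {
    stop("active modules not present in generated pathways: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  if (!setequal(names(active), paste0("cond", seq_len(spec$n_conditions)))) {
    stop("active_modules must name conditions cond1..cond",
         spec$n_conditions, call. = FALSE)
  }

  pathway_genes <- sort(unique(unlist(lapply(pathways, gene_list))))
  bg <- accession_pool(spec$n_background_genes, offset = 800000)
  genes <- c(pathway_genes, bg)

  conditions <- paste0("cond", seq_len(spec$n_conditions))
  design <- tibble::tibble(
    sample = c(paste0(rep(conditions, each = spec$replicates), "_r",
                      rep(seq_len(spec$replicates), length(conditions))),
               paste0("control_r", seq_len(spec$replicates))),
    condition = c(rep(conditions, each = spec$replicates),
                  rep("control", spec$replicates)),
    replicate = c(rep(seq_len(spec$replicates), length(conditions)),
                  seq_len(spec$replicates)),
    role = c(rep("treated", spec$replicates * length(conditions)),
             rep("control", spec$replicates))
  )

  baseline <- 2^rnorm(length(genes), mean = 8, sd = 1)
  names(baseline) <- genes
  values <- matrix(0, nrow = length(genes), ncol = nrow(design),
                   dimnames = list(genes, design$sample))
  for (i in seq_len(nrow(design))) {
    v <- baseline
    cond <- design$condition[i]
    if (design$role[i] == "treated") {
      act <- active[[cond]]
      act_genes <- unique(unlist(row_sets[act$modules], use.names = FALSE))
      v[act_genes] <- v[act_genes] * spec$effect^act$direction
    }
    if (spec$noise_sigma > 0) {
      v <- v * 2^rnorm(length(v), mean = 0, sd = spec$noise_sigma)
    }
    values[, i] <- v
  }
  expr <- expression_table(values, design)
  attr(expr, "truth") <- active
  expr
}
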