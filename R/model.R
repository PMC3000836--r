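# BCML document model: SBGN Process Description glyphs, arcs, compartments,
# modules and context findings, assembled into a pathway container.
# Constructors enforce local invariants; structural PD rules live in
# validate() so that a parsed-but-broken document can still be inspected.

GLYPH_CLASSES <- c("macromolecule", "simple-chemical", "nucleic-acid-feature",
                   "complex", "unspecified-entity", "source-sink", "phenotype",
                   "process", "association", "dissociation",
                   "and-operator", "or-operator", "not-operator")
PROCESS_CLASSES <- c("process", "association", "dissociation")
LOGIC_CLASSES <- c("and-operator", "or-operator", "not-operator")
ENTITY_CLASSES <- setdiff(GLYPH_CLASSES, c(PROCESS_CLASSES, LOGIC_CLASSES))

ARC_CLASSES <- c("consumption", "production", "catalysis", "stimulation",
                 "inhibition", "necessary-stimulation", "modulation",
                 "logic-arc")
MODULATION_ARCS <- c("catalysis", "stimulation", "inhibition",
                     "necessary-stimulation", "modulation")

MODULE_TYPES <- c("sensing", "transduction", "outcome")

#' Create a database cross-reference
#'
#' @param database Database name, e.g. `"EntrezGene"` or `"UniProt"`.
#' @param accession Accession string within that database.
#' @return A `bcml_xref` object.
#' @export
xref <- function(database, accession) {
  database <- as.character(database)
  accession <- as.character(accession)
  if (!nzchar(database) || !nzchar(accession)) {
    stop("xref database and accession must be non-empty", call. = FALSE)
  }
  structure(list(database = database, accession = accession),
            class = "bcml_xref")
}

# shorthand used throughout the package and fixtures
entrez_xref <- function(accession) xref("EntrezGene", accession)

#' Create an evidence annotation ("finding")
#'
#' A finding ties a pathway element to the biological context in which the
#' evidence for it was obtained: the organism (mandatory), and optionally the
#' organism part (tissue), cell type, biological environment and experiment
#' type, each a controlled-vocabulary term, plus literature references.
#'
#' @param organism `bcml_term` (vocabulary `organism`) or a registered
#'   identifier string.
#' @param organism_part,cell_type,environment,experiment_type Optional terms
#'   of the matching vocabularies (or registered identifier strings).
#' @param references Character vector of literature identifiers
#'   (e.g. `"PMID:17452530"`).
#' @return A `bcml_finding` object.
#' @export
finding <- function(organism, organism_part = NULL, cell_type = NULL,
                    environment = NULL, experiment_type = NULL,
                    references = character()) {
  structure(list(
    organism = as_term(organism, "organism"),
    organism_part = as_term(organism_part, "organism-part"),
    cell_type = as_term(cell_type, "cell-type"),
    environment = as_term(environment, "environment"),
    experiment_type = as_term(experiment_type, "experiment-type"),
    references = as.character(references)
  ), class = "bcml_finding")
}

check_id <- function(id, what) {
  id <- as.character(id)
  if (length(id) != 1 || !nzchar(id)) {
    stop(what, " id must be a non-empty string", call. = FALSE)
  }
  id
}

#' Create a pathway glyph (SBGN PD node)
#'
#' Entity pool nodes (macromolecule, simple chemical, complex, ...), process
#' nodes and logic operators are all glyphs distinguished by `cls`.  Complex
#' glyphs nest their subunits as `components`; a protein family (e.g. MHC
#' class II, the PI3K family) is modelled as a complex-class glyph with
#' `family = TRUE` and one component per member gene, so that identifier
#' lists can expand families to individual genes.
#'
#' @param id Document-unique element id.
#' @param cls SBGN PD class, one of
#'   `r paste0('\x60', GLYPH_CLASSES, '\x60', collapse = ", ")`.
#' @param label Display label; defaults to `id`.
#' @param compartment Optional compartment id.
#' @param components List of `bcml_glyph` subunits (complex class only).
#' @param xrefs List of [xref()] database identifiers.  Process-type glyphs
#'   and logic operators carry none.
#' @param findings List of [finding()] annotations.
#' @param family Logical: is this complex a protein-family container?
#' @param tags Optional character vector of curation tags (e.g. `"new"` for
#'   entries absent from previously published versions of the pathway).
#' @return A `bcml_glyph` object.
#' @export
glyph <- function(id, cls, label = id, compartment = NULL,
                  components = list(), xrefs = list(), findings = list(),
                  family = FALSE, tags = character()) {
  id <- check_id(id, "glyph")
  cls <- match.arg(cls, GLYPH_CLASSES)
  if (length(components) > 0 && cls != "complex") {
    stop("glyph '", id, "': only complex glyphs may have components",
         call. = FALSE)
  }
  if (inherits(xrefs, "bcml_xref")) xrefs <- list(xrefs)
  if (inherits(findings, "bcml_finding")) findings <- list(findings)
  stopifnot(all(vapply(components, inherits, TRUE, "bcml_glyph")),
            all(vapply(xrefs, inherits, TRUE, "bcml_xref")),
            all(vapply(findings, inherits, TRUE, "bcml_finding")))
  if (length(xrefs) > 0 && cls %in% c(PROCESS_CLASSES, LOGIC_CLASSES)) {
    stop("glyph '", id, "': process and logic-operator glyphs carry no xrefs",
         call. = FALSE)
  }
  g <- structure(list(
    id = id, cls = cls, label = as.character(label),
    compartment = if (is.null(compartment)) NULL else as.character(compartment),
    components = components, xrefs = xrefs, findings = findings,
    family = isTRUE(family), tags = as.character(tags)
  ), class = "bcml_glyph")
  nested <- glyph_ids_recursive(g)
  if (anyDuplicated(nested)) {
    stop("glyph '", id, "': duplicated id in component nesting (",
         paste(unique(nested[duplicated(nested)]), collapse = ", "),
         "); nesting must be acyclic", call. = FALSE)
  }
  g
}

glyph_ids_recursive <- function(g) {
  c(g$id, unlist(lapply(g$components, glyph_ids_recursive), use.names = FALSE))
}

#' Create an arc (SBGN PD edge)
#'
#' @param id Document-unique element id.
#' @param cls One of `r paste0('\x60', ARC_CLASSES, '\x60', collapse = ", ")`.
#' @param source,target Glyph ids; must differ.
#' @param findings List of [finding()] annotations (arcs may carry their own
#'   evidence; by default filtering lets arcs inherit their endpoints').
#' @return A `bcml_arc` object.
#' @export
arc <- function(id, cls, source, target, findings = list()) {
  id <- check_id(id, "arc")
  cls <- match.arg(cls, ARC_CLASSES)
  source <- check_id(source, "arc source")
  target <- check_id(target, "arc target")
  if (identical(source, target)) {
    stop("arc '", id, "': source and target must differ", call. = FALSE)
  }
  if (inherits(findings, "bcml_finding")) findings <- list(findings)
  structure(list(id = id, cls = cls, source = source, target = target,
                 findings = findings),
            class = "bcml_arc")
}

#' Create a cellular compartment
#'
#' @param id Document-unique id.
#' @param label Display label, e.g. `"plasma membrane"`, `"endosome"`.
#' @return A `bcml_compartment` object.
#' @export
compartment <- function(id, label = id) {
  structure(list(id = check_id(id, "compartment"), label = as.character(label)),
            class = "bcml_compartment")
}

#' Create a functional module
#'
#' Pathways are decomposed into three module types: a *sensing* module
#' (receptor/ligand recognition), *transduction* modules (signal relay down
#' to a transcription factor) and *outcome* modules (transcription-factor
#' driven targets and phenotypes).  Adjacent modules share their boundary
#' glyph: the exit of the upstream module is the entry of the downstream one.
#'
#' @param id Document-unique id.
#' @param mtype One of `"sensing"`, `"transduction"`, `"outcome"`.
#' @param label Short label used in analysis row names (conventionally the
#'   adaptor or transcription factor the module is built around).
#' @param members Character vector of member glyph and arc ids (non-empty).
#' @param entry,exit Optional boundary glyph ids; if both are set they must
#'   be members.
#' @return A `bcml_module` object.
#' @export
pathway_module <- function(id, mtype, label = id, members,
                           entry = NULL, exit = NULL) {
  id <- check_id(id, "module")
  mtype <- match.arg(mtype, MODULE_TYPES)
  members <- sort(unique(as.character(members)), method = "radix")
  if (length(members) == 0) {
    stop("module '", id, "' must have at least one member", call. = FALSE)
  }
  entry <- if (is.null(entry)) NULL else as.character(entry)
  exit <- if (is.null(exit)) NULL else as.character(exit)
  if (!is.null(entry) && !is.null(exit) &&
      !(entry %in% members && exit %in% members)) {
    stop("module '", id, "': entry and exit must both be members",
         call. = FALSE)
  }
  structure(list(id = id, mtype = mtype, label = as.character(label),
                 members = members, entry = entry, exit = exit),
            class = "bcml_module")
}

#' Assemble a pathway document
#'
#' @param id Pathway id.
#' @param name Pathway name, e.g. `"TLR3"`.
#' @param organism `organism` vocabulary term (or registered identifier).
#' @param compartments List of [compartment()] objects.
#' @param glyphs List of top-level [glyph()] objects (complex components are
#'   nested inside their parent, not repeated here).
#' @param arcs List of [arc()] objects.
#' @param modules List of [pathway_module()] objects.
#' @param module_chain List of length-2 character vectors
#'   `c(upstream_module_id, downstream_module_id)` recording module
#'   adjacencies.
#' @param extensions Character vector of serialized XML fragments preserved
#'   verbatim on round-trip (forward compatibility).
#' @param check Verify referential integrity (unique ids, arc endpoints and
#'   module members resolve).  Parsing uses `check = TRUE`; set `FALSE` only
#'   to build a document whose problems you intend to inspect with
#'   [validate()].
#' @return A `bcml_pathway` object.
#' @export
pathway <- function(id, name, organism, compartments = list(),
                    glyphs = list(), arcs = list(), modules = list(),
                    module_chain = list(), extensions = character(),
                    check = TRUE) {
  id <- check_id(id, "pathway")
  stopifnot(all(vapply(compartments, inherits, TRUE, "bcml_compartment")),
            all(vapply(glyphs, inherits, TRUE, "bcml_glyph")),
            all(vapply(arcs, inherits, TRUE, "bcml_arc")),
            all(vapply(modules, inherits, TRUE, "bcml_module")))
  module_chain <- lapply(module_chain, function(p) {
    p <- as.character(p)
    if (length(p) != 2) stop("module_chain entries are (upstream, downstream) pairs",
                             call. = FALSE)
    p
  })
  # canonical element order (sorted by id) so that structurally equal
  # documents are identical() and serialization is deterministic
  sort_by_id <- function(xs) {
    xs[order(vapply(xs, `[[`, "", "id"), method = "radix")]
  }
  if (length(module_chain) > 0) {
    module_chain <- module_chain[order(vapply(module_chain, paste, "",
                                              collapse = "\r"),
                                       method = "radix")]
  }
  pw <- structure(list(
    id = id, name = as.character(name),
    organism = as_term(organism, "organism"),
    compartments = compartments, glyphs = sort_by_id(glyphs),
    arcs = sort_by_id(arcs), modules = sort_by_id(modules),
    module_chain = module_chain,
    extensions = as.character(extensions)
  ), class = "bcml_pathway")
  if (isTRUE(check)) check_pathway(pw)
  pw
}

# referential-integrity errors (parse-time contract); structural PD rules
# are reported, not thrown, by validate()
check_pathway <- function(pw) {
  gids <- all_glyph_ids(pw)
  aids <- vapply(pw$arcs, `[[`, "", "id")
  mids <- vapply(pw$modules, `[[`, "", "id")
  cids <- vapply(pw$compartments, `[[`, "", "id")
  ids <- c(gids, aids, mids, cids)
  if (anyDuplicated(ids)) {
    stop("duplicate element ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  top <- gids
  for (a in pw$arcs) {
    if (!a$source %in% top || !a$target %in% top) {
      stop("arc '", a$id, "' references missing glyph (",
           a$source, " -> ", a$target, ")", call. = FALSE)
    }
  }
  el <- c(gids, aids)
  for (m in pw$modules) {
    missing <- setdiff(m$members, el)
    if (length(missing) > 0) {
      stop("module '", m$id, "' references missing elements: ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
  }
  for (p in pw$module_chain) {
    if (!all(p %in% mids)) {
      stop("module_chain references unknown module: ",
           paste(setdiff(p, mids), collapse = ", "), call. = FALSE)
    }
  }
  invisible(pw)
}

# ---- accessors ------------------------------------------------------------

# all glyphs, including complex components, as a flat named list
all_glyphs <- function(pw) {
  out <- list()
  walk <- function(g) {
    out[[g$id]] <<- g
    lapply(g$components, walk)
    invisible(NULL)
  }
  lapply(pw$glyphs, walk)
  out
}

all_glyph_ids <- function(pw) {
  unlist(lapply(pw$glyphs, glyph_ids_recursive), use.names = FALSE)
}

arc_ids <- function(pw) vapply(pw$arcs, `[[`, "", "id")

glyph_by_id <- function(pw, id) all_glyphs(pw)[[id]]

is_process_glyph <- function(g) g$cls %in% PROCESS_CLASSES
is_logic_glyph <- function(g) g$cls %in% LOGIC_CLASSES
is_entity_glyph <- function(g) g$cls %in% ENTITY_CLASSES

#' Derived entity kind of a glyph
#'
#' A glyph is a `gene` iff it carries an `"EntrezGene"` cross-reference,
#' a `chemical` if it is a simple chemical, and `other` otherwise.  The kind
#' is computed, never stored, so that gene lists and chemical exclusion stay
#' consistent with the document content.
#'
#' @param g A `bcml_glyph`.
#' @return `"gene"`, `"chemical"` or `"other"`.
#' @export
entity_kind <- function(g) {
  stopifnot(inherits(g, "bcml_glyph"))
  dbs <- vapply(g$xrefs, `[[`, "", "database")
  if (any(dbs == "EntrezGene")) return("gene")
  if (g$cls == "simple-chemical") return("chemical")
  "other"
}

#' Gene identifiers carried by a glyph
#'
#' Returns the EntrezGene accessions attached to a glyph.  With
#' `expand_complexes = TRUE` (the default) complex and family glyphs also
#' contribute their components' accessions, recursively.  Chemicals and
#' glyphs without gene cross-references yield an empty set.
#'
#' @param g A `bcml_glyph`.
#' @param expand_complexes Recurse into complex components.
#' @return Sorted character vector of unique accessions.
#' @export
gene_identifiers <- function(g, expand_complexes = TRUE) {
  stopifnot(inherits(g, "bcml_glyph"))
  own <- character()
  for (x in g$xrefs) if (x$database == "EntrezGene") own <- c(own, x$accession)
  if (isTRUE(expand_complexes)) {
    for (comp in g$components) {
      own <- c(own, gene_identifiers(comp, expand_complexes = TRUE))
    }
  }
  sort(unique(own))
}

#' @export
print.bcml_pathway <- function(x, ...) {
  cat(sprintf("<bcml_pathway> %s (%s), organism %s\n", x$name, x$id,
              format(x$organism)))
  cat(sprintf("  %d glyphs (%d incl. nested), %d arcs, %d compartments, %d modules\n",
              length(x$glyphs), length(all_glyph_ids(x)), length(x$arcs),
              length(x$compartments), length(x$modules)))
  if (length(x$modules) > 0) {
    mt <- table(factor(vapply(x$modules, `[[`, "", "mtype"),
                       levels = MODULE_TYPES))
    cat(sprintf("  modules: %d sensing, %d transduction, %d outcome\n",
                mt[["sensing"]], mt[["transduction"]], mt[["outcome"]]))
  }
  invisible(x)
}

#' Tabulate pathway elements
#'
#' @param x A `bcml_pathway`.
#' @param ... Unused.
#' @return A tibble with one row per glyph (including nested components) and
#'   arc: `element_id`, `element` (glyph/arc), `cls`, `label`, `kind`,
#'   `n_findings`, `modules` (comma-joined ids).
#' @method tidy bcml_pathway
#' @export
tidy.bcml_pathway <- function(x, ...) {
  gl <- all_glyphs(x)
  mod_of <- element_module_map(x)
  grows <- tibble::tibble(
    element_id = names(gl),
    element = "glyph",
    cls = vapply(gl, `[[`, "", "cls"),
    label = vapply(gl, `[[`, "", "label"),
    kind = vapply(gl, entity_kind, ""),
    n_findings = vapply(gl, function(g) length(g$findings), 0L)
  )
  arows <- tibble::tibble(
    element_id = arc_ids(x),
    element = "arc",
    cls = vapply(x$arcs, `[[`, "", "cls"),
    label = "",
    kind = "other",
    n_findings = vapply(x$arcs, function(a) length(a$findings), 0L)
  )
  out <- dplyr::bind_rows(grows, arows)
  out$modules <- vapply(out$element_id, function(id) {
    paste(mod_of[[id]], collapse = ",")
  }, "")
  out
}

element_module_map <- function(pw) {
  out <- list()
  for (m in pw$modules) {
    for (id in m$members) out[[id]] <- c(out[[id]], m$id)
  }
  out
}
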