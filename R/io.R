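# BCML XML dialect
# ----------------
# Single <pathway> root; children in deterministic order: <organism>,
# <compartment>*, <glyph>* (sorted by id; complex components nested),
# <arc>* (sorted by id), <module>* (sorted by id), <chain>*, then any
# preserved extension elements.  Ids are XML IDs.  See the package vignette
# for the full format reference; a schema ships in inst/extdata/bcml.xsd.

KNOWN_ROOT_ELEMENTS <- c("organism", "compartment", "glyph", "arc", "module",
                         "chain")

term_to_xml <- function(node, name, term) {
  if (is.null(term)) return(invisible(NULL))
  xml2::xml_add_child(node, name, vocabulary = term$vocabulary,
                      identifier = term$identifier, label = term$label)
  invisible(NULL)
}

finding_to_xml <- function(node, f) {
  fn <- xml2::xml_add_child(node, "finding")
  term_to_xml(fn, "context", f$organism)
  term_to_xml(fn, "context", f$organism_part)
  term_to_xml(fn, "context", f$cell_type)
  term_to_xml(fn, "context", f$environment)
  term_to_xml(fn, "context", f$experiment_type)
  for (r in f$references) xml2::xml_add_child(fn, "reference", r)
  invisible(NULL)
}

glyph_to_xml <- function(node, g) {
  at <- list(id = g$id, class = g$cls, label = g$label)
  if (!is.null(g$compartment)) at$compartment <- g$compartment
  if (isTRUE(g$family)) at$family <- "true"
  if (length(g$tags) > 0) at$tags <- paste(g$tags, collapse = " ")
  gn <- do.call(xml2::xml_add_child, c(list(node, "glyph"), at))
  for (x in g$xrefs) {
    xml2::xml_add_child(gn, "xref", database = x$database,
                        accession = x$accession)
  }
  for (f in g$findings) finding_to_xml(gn, f)
  for (comp in g$components) glyph_to_xml(gn, comp)
  invisible(NULL)
}

#' Serialize a pathway to BCML XML
#'
#' Serialization is deterministic: element order is fixed (compartments,
#' glyphs sorted by id, arcs sorted by id, modules sorted by id, chain
#' adjacencies), so repeated writes of the same model are byte-identical and
#' documents diff cleanly under version control.
#'
#' @param pw A `bcml_pathway`.
#' @param file Optional path; when given, the document is written there.
#' @return An `xml2::xml_document` (invisibly when `file` is given).
#' @seealso [parse_pathway()]
#' @export
write_pathway <- function(pw, file = NULL) {
  stopifnot(inherits(pw, "bcml_pathway"))
  doc <- xml2::xml_new_root("pathway", id = pw$id, name = pw$name)
  root <- xml2::xml_root(doc)
  term_to_xml(root, "organism", pw$organism)
  for (cp in pw$compartments) {
    xml2::xml_add_child(root, "compartment", id = cp$id, label = cp$label)
  }
  ord <- order(vapply(pw$glyphs, `[[`, "", "id"), method = "radix")
  for (g in pw$glyphs[ord]) glyph_to_xml(root, g)
  ord <- order(vapply(pw$arcs, `[[`, "", "id"), method = "radix")
  for (a in pw$arcs[ord]) {
    an <- xml2::xml_add_child(root, "arc", id = a$id, class = a$cls,
                              source = a$source, target = a$target)
    for (f in a$findings) finding_to_xml(an, f)
  }
  ord <- order(vapply(pw$modules, `[[`, "", "id"), method = "radix")
  for (m in pw$modules[ord]) {
    at <- list(id = m$id, type = m$mtype, label = m$label)
    if (!is.null(m$entry)) at$entry <- m$entry
    if (!is.null(m$exit)) at$exit <- m$exit
    mn <- do.call(xml2::xml_add_child, c(list(root, "module"), at))
    for (mem in m$members) xml2::xml_add_child(mn, "member", ref = mem)
  }
  for (p in pw$module_chain) {
    xml2::xml_add_child(root, "chain", upstream = p[1], downstream = p[2])
  }
  for (ext in pw$extensions) {
    xml2::xml_add_child(root, xml2::read_xml(ext))
  }
  if (!is.null(file)) {
    xml2::write_xml(doc, file)
    return(invisible(doc))
  }
  doc
}

xml_attr_or_null <- function(node, name) {
  v <- xml2::xml_attr(node, name)
  if (is.na(v)) NULL else v
}

term_from_xml <- function(node) {
  register_term(xml2::xml_attr(node, "vocabulary"),
                xml2::xml_attr(node, "identifier"),
                xml2::xml_attr(node, "label"))
}

finding_from_xml <- function(node) {
  slots <- list(organism = NULL, organism_part = NULL, cell_type = NULL,
                environment = NULL, experiment_type = NULL)
  for (ctx in xml2::xml_find_all(node, "./context")) {
    term <- term_from_xml(ctx)
    field <- switch(term$vocabulary,
                    "organism" = "organism",
                    "organism-part" = "organism_part",
                    "cell-type" = "cell_type",
                    "environment" = "environment",
                    "experiment-type" = "experiment_type")
    slots[[field]] <- term
  }
  if (is.null(slots$organism)) {
    stop("finding without organism context", call. = FALSE)
  }
  refs <- xml2::xml_text(xml2::xml_find_all(node, "./reference"))
  finding(slots$organism, slots$organism_part, slots$cell_type,
          slots$environment, slots$experiment_type, refs)
}

glyph_from_xml <- function(node) {
  tags <- xml_attr_or_null(node, "tags")
  glyph(
    id = xml2::xml_attr(node, "id"),
    cls = xml2::xml_attr(node, "class"),
    label = xml2::xml_attr(node, "label"),
    compartment = xml_attr_or_null(node, "compartment"),
    components = lapply(xml2::xml_find_all(node, "./glyph"), glyph_from_xml),
    xrefs = lapply(xml2::xml_find_all(node, "./xref"), function(x) {
      xref(xml2::xml_attr(x, "database"), xml2::xml_attr(x, "accession"))
    }),
    findings = lapply(xml2::xml_find_all(node, "./finding"), finding_from_xml),
    family = identical(xml_attr_or_null(node, "family"), "true"),
    tags = if (is.null(tags)) character() else strsplit(tags, " ")[[1]]
  )
}

#' Parse a BCML XML document
#'
#' Parsing checks well-formedness and referential integrity (unique ids,
#' resolvable references) and errors on violations; structural Process
#' Description rules are *not* checked here — run [validate()] on the result.
#' Unknown root-level elements are preserved verbatim in the pathway's
#' extension slot and written back by [write_pathway()].
#'
#' @param x A file path, XML string, or `xml2::xml_document`.
#' @return A `bcml_pathway`.
#' @export
parse_pathway <- function(x) {
  doc <- if (inherits(x, "xml_document")) x else xml2::read_xml(x)
  root <- xml2::xml_root(doc)
  if (xml2::xml_name(root) != "pathway") {
    stop("not a BCML document: root element is <", xml2::xml_name(root), ">",
         call. = FALSE)
  }
  org_node <- xml2::xml_find_first(root, "./organism")
  if (inherits(org_node, "xml_missing")) {
    stop("BCML document lacks an <organism> element", call. = FALSE)
  }
  compartments <- lapply(xml2::xml_find_all(root, "./compartment"), function(n) {
    compartment(xml2::xml_attr(n, "id"), xml2::xml_attr(n, "label"))
  })
  glyphs <- lapply(xml2::xml_find_all(root, "./glyph"), glyph_from_xml)
  arcs <- lapply(xml2::xml_find_all(root, "./arc"), function(n) {
    arc(xml2::xml_attr(n, "id"), xml2::xml_attr(n, "class"),
        xml2::xml_attr(n, "source"), xml2::xml_attr(n, "target"),
        findings = lapply(xml2::xml_find_all(n, "./finding"),
                          finding_from_xml))
  })
  modules <- lapply(xml2::xml_find_all(root, "./module"), function(n) {
    pathway_module(xml2::xml_attr(n, "id"), xml2::xml_attr(n, "type"),
                   xml2::xml_attr(n, "label"),
                   members = xml2::xml_attr(xml2::xml_find_all(n, "./member"),
                                            "ref"),
                   entry = xml_attr_or_null(n, "entry"),
                   exit = xml_attr_or_null(n, "exit"))
  })
  chain <- lapply(xml2::xml_find_all(root, "./chain"), function(n) {
    c(xml2::xml_attr(n, "upstream"), xml2::xml_attr(n, "downstream"))
  })
  extensions <- vapply(
    xml2::xml_children(root)[!xml2::xml_name(xml2::xml_children(root)) %in%
                               KNOWN_ROOT_ELEMENTS],
    as.character, "")
  pathway(
    id = xml2::xml_attr(root, "id"),
    name = xml2::xml_attr(root, "name"),
    organism = term_from_xml(org_node),
    compartments = compartments, glyphs = glyphs, arcs = arcs,
    modules = modules, module_chain = chain,
    extensions = trimws(extensions),
    check = TRUE
  )
}

#' Path to the bundled BCML XML schema
#'
#' @return Path to the XSD file; validate a document against it with
#'   `xml2::xml_validate(doc, xml2::read_xml(bcml_schema()))`.
#' @export
bcml_schema <- function() {
  system.file("extdata", "bcml.xsd", package = "bcml")
}

# ---- structural validation ------------------------------------------------

violation <- function(rule_id, severity, element_id, message) {
  tibble::tibble(rule_id = rule_id, severity = severity,
                 element_id = element_id, message = message)
}

#' Validate a pathway against the Process Description rule catalogue
#'
#' @param x A `bcml_pathway`.
#' @param ... Unused.
#' @return A tibble of violations (`rule_id`, `severity`, `element_id`,
#'   `message`); zero rows means the document is valid.  Violations are data,
#'   not conditions: validation never throws.
#'
#' @details The rule catalogue:
#' \describe{
#'   \item{PD-ARC-01 (error)}{consumption arcs run entity to process.}
#'   \item{PD-ARC-02 (error)}{production arcs run process to entity.}
#'   \item{PD-ARC-03 (error)}{modulation-family arcs (catalysis, stimulation,
#'     inhibition, necessary-stimulation, modulation) run from an entity or
#'     logic operator to a process or phenotype.}
#'   \item{PD-ARC-04 (error)}{logic arcs run entity to logic operator.}
#'   \item{PD-PROC-01 (error)}{every process has at least one consumption and
#'     one production arc.  Demoted to a warning on pathways produced by
#'     [apply_filter()] with `drop = TRUE`, where pruning legitimately leaves
#'     truncated processes.}
#'   \item{PD-PROC-02 (error)}{phenotype glyphs take part in no production or
#'     consumption arcs.}
#'   \item{PD-REF-01 (error)}{all id references resolve.}
#'   \item{PD-COMP-01 (error)}{compartment references resolve.}
#'   \item{PD-MOD-01 (error)}{module members resolve.}
#'   \item{PD-MOD-02 (warning)}{chained modules share their boundary glyph
#'     (upstream exit equals downstream entry).  A warning because module
#'     chaining is a curation convention layered on top of the PD grammar.}
#' }
#' @export
validate <- function(x, ...) UseMethod("validate")

#' @rdname validate
#' @export
validate.bcml_pathway <- function(x, ...) {
  pw <- x
  out <- list()
  add <- function(v) out[[length(out) + 1]] <<- v
  gl <- all_glyphs(pw)
  gcls <- vapply(gl, `[[`, "", "cls")
  top_ids <- vapply(pw$glyphs, `[[`, "", "id")
  cls_of <- function(id) if (id %in% names(gl)) gcls[[id]] else NA_character_

  demoted <- isTRUE(attr(pw, "filtered"))

  for (a in pw$arcs) {
    scls <- cls_of(a$source)
    tcls <- cls_of(a$target)
    if (is.na(scls) || is.na(tcls)) {
      add(violation("PD-REF-01", "error", a$id,
                    sprintf("arc references unresolved glyph id(s): %s",
                            paste(setdiff(c(a$source, a$target), names(gl)),
                                  collapse = ", "))))
      next
    }
    if (a$cls == "consumption" &&
        !(scls %in% setdiff(ENTITY_CLASSES, "phenotype") &&
          tcls %in% PROCESS_CLASSES)) {
      add(violation("PD-ARC-01", "error", a$id,
                    sprintf("consumption arc must run entity -> process (got %s -> %s)",
                            scls, tcls)))
    }
    if (a$cls == "production" &&
        !(scls %in% PROCESS_CLASSES &&
          tcls %in% setdiff(ENTITY_CLASSES, "phenotype"))) {
      add(violation("PD-ARC-02", "error", a$id,
                    sprintf("production arc must run process -> entity (got %s -> %s)",
                            scls, tcls)))
    }
    if (a$cls %in% MODULATION_ARCS &&
        !((scls %in% ENTITY_CLASSES || scls %in% LOGIC_CLASSES) &&
          (tcls %in% PROCESS_CLASSES || tcls == "phenotype"))) {
      add(violation("PD-ARC-03", "error", a$id,
                    sprintf("%s arc must run entity/logic-operator -> process/phenotype (got %s -> %s)",
                            a$cls, scls, tcls)))
    }
    if (a$cls == "logic-arc" &&
        !(scls %in% ENTITY_CLASSES && tcls %in% LOGIC_CLASSES)) {
      add(violation("PD-ARC-04", "error", a$id,
                    sprintf("logic arc must run entity -> logic operator (got %s -> %s)",
                            scls, tcls)))
    }
  }

  asrc <- vapply(pw$arcs, `[[`, "", "source")
  atgt <- vapply(pw$arcs, `[[`, "", "target")
  acls <- vapply(pw$arcs, `[[`, "", "cls")
  for (id in names(gl)) {
    if (gcls[[id]] %in% PROCESS_CLASSES) {
      has_cons <- any(acls == "consumption" & atgt == id)
      has_prod <- any(acls == "production" & asrc == id)
      if (!has_cons || !has_prod) {
        add(violation("PD-PROC-01", if (demoted) "warning" else "error", id,
                      sprintf("process lacks %s arc(s)",
                              paste(c("consumption", "production")[!c(has_cons, has_prod)],
                                    collapse = " and "))))
      }
    }
    if (gcls[[id]] == "phenotype") {
      touching <- acls %in% c("production", "consumption") &
        (asrc == id | atgt == id)
      if (any(touching)) {
        add(violation("PD-PROC-02", "error", id,
                      "phenotype glyph takes part in production/consumption arcs"))
      }
    }
  }

  comp_ids <- vapply(pw$compartments, `[[`, "", "id")
  for (g in gl) {
    if (!is.null(g$compartment) && !g$compartment %in% comp_ids) {
      add(violation("PD-COMP-01", "error", g$id,
                    sprintf("unknown compartment '%s'", g$compartment)))
    }
  }

  el_ids <- c(names(gl), arc_ids(pw))
  mods <- stats::setNames(pw$modules, vapply(pw$modules, `[[`, "", "id"))
  for (m in pw$modules) {
    missing <- setdiff(m$members, el_ids)
    if (length(missing) > 0) {
      add(violation("PD-MOD-01", "error", m$id,
                    sprintf("module members unresolved: %s",
                            paste(missing, collapse = ", "))))
    }
  }
  for (p in pw$module_chain) {
    up <- mods[[p[1]]]; down <- mods[[p[2]]]
    if (is.null(up) || is.null(down)) {
      add(violation("PD-REF-01", "error", paste(p, collapse = "->"),
                    "module chain references unknown module"))
      next
    }
    if (is.null(up$exit) || is.null(down$entry) ||
        !identical(up$exit, down$entry)) {
      add(violation("PD-MOD-02", "warning", paste(p, collapse = "->"),
                    "chained modules do not share their boundary glyph (upstream exit != downstream entry)"))
    }
  }

  if (length(out) == 0) {
    return(violation(character(), character(), character(), character()))
  }
  dplyr::bind_rows(out)
}

#' Is a pathway structurally valid?
#'
#' @param pw A `bcml_pathway`.
#' @return `TRUE` when [validate()] reports no error-severity violations.
#' @export
is_valid <- function(pw) {
  v <- validate(pw)
  !any(v$severity == "error")
}

# ---- GraphML export -------------------------------------------------------

# Figure-style colour legend: excluded elements grey, dependency-affected
# elements blue; expression overlay colours up-regulated red, down-regulated
# green.
STATUS_COLORS <- c(excluded = "#999999", affected = "#3366CC")
STATE_COLORS <- c(up = "#CC0000", down = "#009900")

element_color <- function(status, state) {
  if (!is.na(status) && status %in% names(STATUS_COLORS)) {
    return(unname(STATUS_COLORS[[status]]))
  }
  if (!is.na(state) && state %in% names(STATE_COLORS)) {
    return(unname(STATE_COLORS[[state]]))
  }
  "#FFFFFF"
}

#' Export a pathway as GraphML
#'
#' One node per top-level glyph (complex components are carried as a node
#' attribute) and one edge per arc.  When a filter [StatusMap][apply_filter()]
#' and/or an expression [StateMap][overlay()] are supplied, nodes carry
#' `filter_status`, `state`, `value` and a display `color`: excluded
#' elements grey, dependency-affected elements blue, up-regulated red,
#' down-regulated green.
#'
#' @param pw A valid `bcml_pathway`.
#' @param status Optional status tibble from [apply_filter()] /
#'   [initial_status()].
#' @param states Optional state tibble from [overlay()].
#' @param file Optional output path.
#' @return An `xml2::xml_document` holding the GraphML.
#' @export
to_graphml <- function(pw, status = NULL, states = NULL, file = NULL) {
  stopifnot(inherits(pw, "bcml_pathway"))
  if (!is_valid(pw)) {
    stop("pathway does not pass validation; fix errors before export",
         call. = FALSE)
  }
  status_of <- status_lookup(status)
  state_of <- state_lookup(states)
  mod_of <- element_module_map(pw)

  doc <- xml2::xml_new_root(
    "graphml",
    xmlns = "http://graphml.graphdrawing.org/xmlns")
  root <- xml2::xml_root(doc)
  keys <- list(
    c("d_label", "node", "label"), c("d_class", "node", "class"),
    c("d_compartment", "node", "compartment"),
    c("d_modules", "node", "modules"),
    c("d_components", "node", "components"),
    c("d_status", "node", "filter_status"), c("d_state", "node", "state"),
    c("d_value", "node", "value"), c("d_color", "node", "color"),
    c("e_class", "edge", "class"), c("e_status", "edge", "filter_status"),
    c("e_color", "edge", "color")
  )
  for (k in keys) {
    xml2::xml_add_child(root, "key", id = k[1], `for` = k[2],
                        attr.name = k[3], attr.type = "string")
  }
  gr <- xml2::xml_add_child(root, "graph", id = pw$id, edgedefault = "directed")
  add_data <- function(node, key, value) {
    if (is.null(value) || is.na(value) || !nzchar(value)) return(invisible(NULL))
    d <- xml2::xml_add_child(node, "data", key = key)
    xml2::xml_text(d) <- as.character(value)
    invisible(NULL)
  }
  for (g in pw$glyphs) {
    n <- xml2::xml_add_child(gr, "node", id = g$id)
    add_data(n, "d_label", g$label)
    add_data(n, "d_class", g$cls)
    add_data(n, "d_compartment", g$compartment)
    add_data(n, "d_modules", paste(mod_of[[g$id]], collapse = ","))
    if (length(g$components) > 0) {
      add_data(n, "d_components",
               paste(vapply(g$components, `[[`, "", "label"), collapse = ","))
    }
    st <- status_of(g$id)
    sta <- state_of(g$id)
    add_data(n, "d_status", st)
    add_data(n, "d_state", sta$state)
    if (!is.na(sta$value)) add_data(n, "d_value", format(sta$value))
    add_data(n, "d_color", element_color(st, sta$state))
  }
  for (a in pw$arcs) {
    e <- xml2::xml_add_child(gr, "edge", id = a$id, source = a$source,
                             target = a$target)
    add_data(e, "e_class", a$cls)
    st <- status_of(a$id)
    add_data(e, "e_status", st)
    add_data(e, "e_color", element_color(st, NA_character_))
  }
  if (!is.null(file)) xml2::write_xml(doc, file)
  doc
}

status_lookup <- function(status) {
  if (is.null(status)) return(function(id) NA_character_)
  v <- stats::setNames(status$status, status$element_id)
  function(id) if (id %in% names(v)) v[[id]] else NA_character_
}

state_lookup <- function(states) {
  if (is.null(states)) {
    return(function(id) list(state = NA_character_, value = NA_real_))
  }
  s <- stats::setNames(states$state, states$glyph_id)
  val <- stats::setNames(states$value, states$glyph_id)
  function(id) {
    if (id %in% names(s)) list(state = s[[id]], value = val[[id]])
    else list(state = NA_character_, value = NA_real_)
  }
}
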