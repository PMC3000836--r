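# Context filtering: match findings against criteria, assign each element an
# initial included/excluded status, then propagate structural "affected"
# states (a complex missing a subunit, a process missing an input, ...) to a
# fixpoint.

#' Build filter criteria
#'
#' A criterion constrains any subset of the five finding vocabularies; an
#' element matches when at least one of its findings carries, for every
#' constrained vocabulary, exactly the required term.  Empty criteria match
#' everything.
#'
#' @param organism,organism_part,cell_type,environment,experiment_type
#'   Optional required terms (a `bcml_term` or a registered identifier
#'   string).
#' @param unknown_policy What to do with elements that carry no findings at
#'   all: `"permissive"` (default) includes them — curation coverage is
#'   incomplete and absence of evidence is not evidence of absence — while
#'   `"strict"` excludes them, exposing the gaps.
#' @return A `bcml_criteria` object.
#' @export
filter_criteria <- function(organism = NULL, organism_part = NULL,
                            cell_type = NULL, environment = NULL,
                            experiment_type = NULL,
                            unknown_policy = c("permissive", "strict")) {
  constraints <- list(
    organism = as_term(organism, "organism"),
    organism_part = as_term(organism_part, "organism-part"),
    cell_type = as_term(cell_type, "cell-type"),
    environment = as_term(environment, "environment"),
    experiment_type = as_term(experiment_type, "experiment-type")
  )
  constraints <- constraints[!vapply(constraints, is.null, TRUE)]
  structure(list(constraints = constraints,
                 unknown_policy = match.arg(unknown_policy)),
            class = "bcml_criteria")
}

#' Does a finding match filter criteria?
#'
#' @param f A [finding()].
#' @param criteria A [filter_criteria()].
#' @return `TRUE` iff, for every constrained vocabulary, the finding carries
#'   the required term (a missing field fails that constraint).  Empty
#'   criteria match every finding.
#' @export
match_finding <- function(f, criteria) {
  stopifnot(inherits(f, "bcml_finding"), inherits(criteria, "bcml_criteria"))
  for (field in names(criteria$constraints)) {
    if (!terms_equal(f[[field]], criteria$constraints[[field]])) return(FALSE)
  }
  TRUE
}

element_matches <- function(findings, criteria) {
  # NA = no findings (policy decides); TRUE/FALSE = evidence decides
  if (length(findings) == 0) return(NA)
  for (f in findings) if (match_finding(f, criteria)) return(TRUE)
  FALSE
}

#' Initial filter status of every pathway element
#'
#' Each glyph (including nested complex components) and arc is marked
#' `included` (some finding matches), `excluded` (findings exist, none
#' match), or — when it has no findings — according to the criteria's
#' `unknown_policy`.  Arcs without findings of their own inherit from their
#' endpoints by default: they are excluded when either endpoint is excluded.
#'
#' @param pw A valid `bcml_pathway`.
#' @param criteria A [filter_criteria()].
#' @param arc_findings `"inherit"` (default): an arc with no findings follows
#'   its endpoints; `"own"`: the unknown policy applies to arcs directly.
#' @return A status tibble: `element_id`, `element` (glyph/arc), `status`.
#' @export
initial_status <- function(pw, criteria,
                           arc_findings = c("inherit", "own")) {
  stopifnot(inherits(pw, "bcml_pathway"))
  arc_findings <- match.arg(arc_findings)
  default <- if (criteria$unknown_policy == "permissive") "included" else "excluded"
  gl <- all_glyphs(pw)
  gstat <- vapply(gl, function(g) {
    m <- element_matches(g$findings, criteria)
    if (is.na(m)) default else if (m) "included" else "excluded"
  }, "")
  astat <- vapply(pw$arcs, function(a) {
    m <- element_matches(a$findings, criteria)
    if (!is.na(m)) return(if (m) "included" else "excluded")
    if (arc_findings == "inherit") {
      if (gstat[[a$source]] == "excluded" || gstat[[a$target]] == "excluded") {
        "excluded"
      } else {
        "included"
      }
    } else {
      default
    }
  }, "")
  tibble::tibble(
    element_id = c(names(gl), arc_ids(pw)),
    element = c(rep("glyph", length(gl)), rep("arc", length(pw$arcs))),
    status = c(unname(gstat), unname(astat))
  )
}

# Dependency rules, shared by the fixpoint engine below and by the
# brute-force oracle in the test suite (which re-implements them naively).
#
# R1 complex  -> affected if any component is excluded or affected
# R2 process  -> affected if any glyph feeding it through an
#                existence-critical arc is excluded or affected
# R3 arc      -> affected if either endpoint is excluded or affected
# R4 entity   -> affected if it has >= 1 incoming production arc and all its
#                producing processes are excluded or affected
#
# The rules are monotone on the order included < affected with excluded held
# fixed, so the fixpoint exists, is unique, and is reached in at most
# |elements| sweeps regardless of visiting order.

CRITICAL_ARCS <- c("consumption", "catalysis", "necessary-stimulation")

#' Propagate dependency effects to a fixpoint
#'
#' Starting from an [initial_status()] map, marks as `affected` the elements
#' that are structurally compromised by excluded or affected dependencies: a
#' complex missing a subunit, a process one of whose existence-critical
#' inputs (consumption, catalysis, necessary stimulation) is gone, any arc
#' with a compromised endpoint, and an entity all of whose producing
#' processes are compromised.  `excluded` is never downgraded.  Plain
#' stimulation/inhibition inputs do not propagate: a missing modulator
#' changes kinetics, not feasibility (configurable via `critical_arcs`).
#'
#' @param pw A valid `bcml_pathway`.
#' @param status A status tibble as from [initial_status()].
#' @param critical_arcs Arc classes whose loss compromises the target
#'   process.
#' @return The fixpoint status tibble (same shape as the input).
#' @export
propagate_affected <- function(pw, status,
                               critical_arcs = CRITICAL_ARCS) {
  stopifnot(inherits(pw, "bcml_pathway"))
  st <- stats::setNames(status$status, status$element_id)
  gl <- all_glyphs(pw)
  needed <- c(names(gl), arc_ids(pw))
  missing <- setdiff(needed, names(st))
  if (length(missing) > 0) {
    stop("status map is not total; missing elements: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }

  bad <- function(ids) {
    length(ids) > 0 && any(st[ids] %in% c("excluded", "affected"))
  }
  mark <- function(id) {
    if (st[[id]] == "included") {
      st[[id]] <<- "affected"
      TRUE
    } else {
      FALSE
    }
  }

  asrc <- vapply(pw$arcs, `[[`, "", "source")
  atgt <- vapply(pw$arcs, `[[`, "", "target")
  acls <- vapply(pw$arcs, `[[`, "", "cls")
  aid <- arc_ids(pw)

  repeat {
    changed <- FALSE
    for (g in gl) {
      if (g$cls == "complex" && length(g$components) > 0 &&
          bad(vapply(g$components, `[[`, "", "id"))) {
        changed <- mark(g$id) || changed
      }
      if (is_process_glyph(g)) {
        feeders <- asrc[acls %in% critical_arcs & atgt == g$id]
        if (bad(feeders)) changed <- mark(g$id) || changed
      }
      if (is_entity_glyph(g)) {
        producers <- asrc[acls == "production" & atgt == g$id]
        if (length(producers) > 0 &&
            all(st[producers] %in% c("excluded", "affected"))) {
          changed <- mark(g$id) || changed
        }
      }
    }
    for (i in seq_along(aid)) {
      if (bad(c(asrc[i], atgt[i]))) changed <- mark(aid[i]) || changed
    }
    if (!changed) break
  }
  out <- status
  out$status <- unname(st[out$element_id])
  out
}

#' Filter a pathway to a biological context
#'
#' Composes [initial_status()] and [propagate_affected()].  With
#' `drop = TRUE` a pruned sub-pathway is returned: excluded glyphs and arcs
#' are removed, arcs are kept only when both endpoints survive, module member
#' lists are pruned (modules left empty are dropped, as are chain entries
#' that lose a module or their boundary glyph).  Affected elements are
#' retained — they carry the dependency signal — and remain marked in the
#' returned status.  The pruned pathway is flagged so that [validate()]
#' demotes truncated-process findings (PD-PROC-01) to warnings.
#'
#' @param pw A valid `bcml_pathway`.
#' @param criteria A [filter_criteria()].
#' @param drop Return a pruned sub-pathway instead of the full one.
#' @inheritParams initial_status
#' @inheritParams propagate_affected
#' @return A list with elements `pathway` and `status` (the full fixpoint
#'   status map of the original pathway).
#' @export
apply_filter <- function(pw, criteria, drop = FALSE,
                         arc_findings = c("inherit", "own"),
                         critical_arcs = CRITICAL_ARCS) {
  status <- propagate_affected(
    pw, initial_status(pw, criteria, arc_findings = arc_findings),
    critical_arcs = critical_arcs)
  if (!isTRUE(drop)) {
    return(list(pathway = pw, status = status))
  }
  st <- stats::setNames(status$status, status$element_id)
  keep_glyph <- function(g) st[[g$id]] != "excluded"
  prune_glyph <- function(g) {
    # excluded nested components stay: they document why the complex is
    # affected, and gene_list() drops them through the status map
    g
  }
  glyphs <- lapply(Filter(keep_glyph, pw$glyphs), prune_glyph)
  gids <- unlist(lapply(glyphs, glyph_ids_recursive), use.names = FALSE)
  top_ids <- vapply(glyphs, `[[`, "", "id")
  arcs <- Filter(function(a) {
    st[[a$id]] != "excluded" && a$source %in% top_ids && a$target %in% top_ids
  }, pw$arcs)
  surviving <- c(gids, vapply(arcs, `[[`, "", "id"),
                 if (length(arcs) == 0) character())
  modules <- list()
  for (m in pw$modules) {
    members <- intersect(m$members, surviving)
    if (length(members) == 0) next
    entry <- if (!is.null(m$entry) && m$entry %in% members) m$entry
    exit <- if (!is.null(m$exit) && m$exit %in% members) m$exit
    modules[[length(modules) + 1]] <-
      pathway_module(m$id, m$mtype, m$label, members, entry, exit)
  }
  mids <- vapply(modules, `[[`, "", "id")
  chain <- Filter(function(p) all(p %in% mids), pw$module_chain)
  sub <- pathway(pw$id, pw$name, pw$organism, pw$compartments, glyphs, arcs,
                 modules, chain, pw$extensions, check = TRUE)
  attr(sub, "filtered") <- TRUE
  list(pathway = sub, status = status)
}
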