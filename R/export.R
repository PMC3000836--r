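# Analysis-ready derivatives of a pathway document: flat gene lists
# (GSEA .grp), per-module gene sets (GMT), SPIA-style signed relation
# tables, and expression-state overlays.

status_vector <- function(status) {
  if (is.null(status)) return(NULL)
  stats::setNames(status$status, status$element_id)
}

excluded_in <- function(st, id) {
  !is.null(st) && id %in% names(st) && st[[id]] == "excluded"
}

# genes of one glyph honouring a status map: excluded glyphs and excluded
# nested components contribute nothing; affected ones are retained
glyph_genes <- function(g, st = NULL) {
  if (excluded_in(st, g$id)) return(character())
  own <- character()
  for (x in g$xrefs) if (x$database == "EntrezGene") own <- c(own, x$accession)
  for (comp in g$components) own <- c(own, glyph_genes(comp, st))
  unique(own)
}

#' Flat gene list of a pathway
#'
#' The union of EntrezGene accessions over the pathway's entity glyphs, with
#' complexes and protein families expanded to their member genes, chemicals
#' omitted, de-duplicated and sorted.  The list can be restricted to a set
#' of modules, filtered through a status map (excluded elements drop out,
#' affected ones are retained), and limited to entries tagged `"new"` in the
#' curation (`scope = "new_only"`).
#'
#' @param pw A valid `bcml_pathway`.
#' @param modules Optional character vector of module ids to restrict to.
#' @param status Optional status tibble from [apply_filter()].
#' @param scope `"all"` (default) or `"new_only"` (glyphs tagged `"new"`).
#' @return Sorted character vector of unique gene accessions.
#' @export
gene_list <- function(pw, modules = NULL, status = NULL,
                      scope = c("all", "new_only")) {
  stopifnot(inherits(pw, "bcml_pathway"))
  scope <- match.arg(scope)
  st <- status_vector(status)
  glyphs <- pw$glyphs
  if (!is.null(modules)) {
    mids <- vapply(pw$modules, `[[`, "", "id")
    unknown <- setdiff(modules, mids)
    if (length(unknown) > 0) {
      stop("unknown module id(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
    members <- unique(unlist(lapply(
      pw$modules[mids %in% modules], `[[`, "members"), use.names = FALSE))
    glyphs <- Filter(function(g) g$id %in% members, glyphs)
  }
  if (scope == "new_only") {
    glyphs <- Filter(function(g) "new" %in% g$tags, glyphs)
  }
  genes <- unlist(lapply(glyphs, glyph_genes, st = st), use.names = FALSE)
  sort(unique(genes))
}

#' Per-module gene sets
#'
#' @param pw A valid `bcml_pathway`.
#' @return Named list (module id -> sorted accession vector).  Boundary
#'   glyphs shared by chained modules appear in both sets.
#' @export
module_gene_sets <- function(pw) {
  stopifnot(inherits(pw, "bcml_pathway"))
  out <- lapply(pw$modules, function(m) gene_list(pw, modules = m$id))
  stats::setNames(out, vapply(pw$modules, `[[`, "", "id"))
}

#' Write a flat gene list (.grp)
#'
#' @param genes Character vector of accessions.
#' @param file Output path; one accession per line (GSEA .grp-compatible).
#' @export
write_grp <- function(genes, file) {
  writeLines(as.character(genes), file)
  invisible(file)
}

#' Write gene sets in GMT format
#'
#' @param sets Named list of accession vectors.
#' @param file Output path.
#' @param descriptions Optional character vector of set descriptions
#'   (recycled; defaults to the set names).
#' @export
write_gmt <- function(sets, file, descriptions = names(sets)) {
  stopifnot(!is.null(names(sets)), all(nzchar(names(sets))))
  descriptions <- rep_len(descriptions, length(sets))
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t")
  }, "")
  writeLines(lines, file)
  invisible(file)
}

# ---- SPIA-style relations -------------------------------------------------

#' Signed gene-gene relation table
#'
#' Flattens the process-centred topology into pairwise signed relations
#' amenable to impact analysis: for each process, every gene feeding it
#' (through consumption, catalysis, stimulation, necessary stimulation or
#' inhibition arcs, with one-level expansion through logic operators) is
#' related to every gene it produces.  The relation is `inhibition` when the
#' path traverses an inhibition arc or a not-operator, `activation`
#' otherwise; co-members of a complex additionally yield symmetric `binding`
#' relations.  The sign computation stops at the first process — downstream
#' propagation is the impact analysis' job, not the format conversion's.
#' When a status map is given, excluded elements contribute no relations.
#'
#' @param pw A valid `bcml_pathway`.
#' @param status Optional status tibble from [apply_filter()].
#' @return A tibble: `source`, `target` (gene accessions), `relation`
#'   (`activation`/`inhibition`/`binding`), `arc_id` (the input arc, or the
#'   complex glyph id for binding rows).
#' @export
to_spia_relations <- function(pw, status = NULL) {
  stopifnot(inherits(pw, "bcml_pathway"))
  st <- status_vector(status)
  gl <- all_glyphs(pw)
  rows <- list()
  emit <- function(src, tgt, rel, aid) {
    for (s in src) for (t in tgt) {
      if (s != t) rows[[length(rows) + 1]] <<- c(s, t, rel, aid)
    }
  }

  # inputs feeding a glyph (process or, recursively, logic operator);
  # returns list of (genes, inhibited, arc_id)
  inputs_of <- function(target_id, inhibited) {
    res <- list()
    for (a in pw$arcs) {
      if (a$target != target_id) next
      if (!a$cls %in% c(CRITICAL_ARCS, "stimulation", "inhibition",
                        "logic-arc")) next
      if (excluded_in(st, a$id)) next
      src <- gl[[a$source]]
      if (is.null(src) || excluded_in(st, src$id)) next
      inh <- xor(inhibited, a$cls == "inhibition")
      if (is_logic_glyph(src)) {
        res <- c(res, inputs_of(src$id, xor(inh, src$cls == "not-operator")))
      } else {
        genes <- glyph_genes(src, st)
        if (length(genes) > 0) {
          res[[length(res) + 1]] <- list(genes = genes, inhibited = inh,
                                         arc_id = a$id)
        }
      }
    }
    res
  }

  for (g in pw$glyphs) {
    if (is_process_glyph(g) && !excluded_in(st, g$id)) {
      outs <- character()
      for (a in pw$arcs) {
        if (a$cls == "production" && a$source == g$id &&
            !excluded_in(st, a$id)) {
          tgt <- gl[[a$target]]
          if (!is.null(tgt) && !excluded_in(st, tgt$id)) {
            outs <- unique(c(outs, glyph_genes(tgt, st)))
          }
        }
      }
      if (length(outs) == 0) next
      for (inp in inputs_of(g$id, FALSE)) {
        emit(inp$genes, outs,
             if (inp$inhibited) "inhibition" else "activation", inp$arc_id)
      }
    }
    if (g$cls == "complex" && length(g$components) > 0 &&
        !excluded_in(st, g$id)) {
      members <- lapply(g$components, glyph_genes, st = st)
      members <- unique(unlist(members, use.names = FALSE))
      emit(members, members, "binding", g$id)
    }
  }

  if (length(rows) == 0) {
    return(tibble::tibble(source = character(), target = character(),
                          relation = character(), arc_id = character()))
  }
  m <- do.call(rbind, rows)
  dplyr::distinct(tibble::tibble(source = m[, 1], target = m[, 2],
                                 relation = m[, 3], arc_id = m[, 4]))
}

# ---- expression overlay ---------------------------------------------------

#' Overlay expression ratios on a pathway
#'
#' Matches a condition's mean log2 treated/control ratios to glyphs by
#' EntrezGene accession.  Single-gene glyphs take their gene's value;
#' complexes and families take the member value of maximum magnitude (the
#' strongest signal; a tie between members of opposite sign yields
#' `unchanged`).  Glyphs with no matched gene are `unmeasured`.  States are
#' `up` when the value is at least `+threshold`, `down` at or below
#' `-threshold`, `unchanged` otherwise.
#'
#' @param pw A valid `bcml_pathway`.
#' @param ratios A ratio table from [compute_ratios()] (or a numeric matrix,
#'   genes in rownames, conditions in colnames).
#' @param condition Condition (column) id.
#' @param threshold Positive log2 fold-change threshold.
#' @return A state tibble: `glyph_id`, `label`, `value`, `state`.
#' @export
overlay <- function(pw, ratios, condition, threshold = 1) {
  stopifnot(inherits(pw, "bcml_pathway"), threshold > 0)
  m <- if (inherits(ratios, "bcml_ratios")) unclass_ratios(ratios) else as.matrix(ratios)
  if (!condition %in% colnames(m)) {
    stop("condition '", condition, "' absent from the ratio table",
         call. = FALSE)
  }
  vals <- m[, condition]
  rows <- lapply(pw$glyphs, function(g) {
    genes <- intersect(gene_identifiers(g), names(vals))
    if (length(genes) == 0) {
      return(tibble::tibble(glyph_id = g$id, label = g$label,
                            value = NA_real_, state = "unmeasured"))
    }
    v <- vals[genes]
    mx <- max(abs(v))
    cand <- v[abs(v) == mx]
    if (length(unique(sign(cand))) > 1) {
      # equal-magnitude members disagree in direction
      return(tibble::tibble(glyph_id = g$id, label = g$label, value = 0,
                            state = "unchanged"))
    }
    value <- unname(cand[1])
    state <- if (value >= threshold) "up" else if (value <= -threshold) "down" else "unchanged"
    tibble::tibble(glyph_id = g$id, label = g$label, value = value,
                   state = state)
  })
  dplyr::bind_rows(rows)
}
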