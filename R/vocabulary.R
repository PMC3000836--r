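# Controlled vocabulary: five fixed vocabularies of (identifier, label) terms.
# Terms are interned in a registry so that equal annotations share identity and
# conflicting labels for one accession are impossible.

VOCABULARIES <- c("organism", "organism-part", "cell-type", "environment",
                  "experiment-type")

.registry <- new.env(parent = emptyenv())

registry_key <- function(vocabulary, identifier) {
  paste(vocabulary, identifier, sep = "\r")
}

seed_registry <- function() {
  if (isTRUE(.registry$seeded)) return(invisible(NULL))
  .registry$seeded <- TRUE
  path <- system.file("extdata", "vocabulary.tsv", package = "bcml")
  if (nzchar(path)) {
    tab <- read.delim(path, header = FALSE, sep = "\t", quote = "",
                      col.names = c("vocabulary", "identifier", "label"),
                      stringsAsFactors = FALSE, fileEncoding = "UTF-8")
    for (i in seq_len(nrow(tab))) {
      register_term(tab$vocabulary[i], tab$identifier[i], tab$label[i])
    }
  }
  invisible(NULL)
}

new_term <- function(vocabulary, identifier, label) {
  structure(list(vocabulary = vocabulary, identifier = identifier,
                 label = label),
            class = "bcml_term")
}

#' Register a controlled-vocabulary term
#'
#' Evidence annotations ("findings") reference biological context through five
#' controlled vocabularies: `organism`, `organism-part`, `cell-type`,
#' `environment` and `experiment-type`.  Terms are interned: registering the
#' same `(vocabulary, identifier)` pair again returns the canonical term, and
#' registering it with a different label is an error.  A small default term
#' set is bundled with the package and loaded on first use; additional terms
#' can be registered at any time (there are no live ontology lookups).
#'
#' @param vocabulary One of `r paste0('\x60', VOCABULARIES, '\x60', collapse = ", ")`.
#' @param identifier Ontology-style accession string (non-empty), e.g.
#'   `"CL:0000451"`.
#' @param label Human-readable label, e.g. `"dendritic cell"`.
#' @return A `bcml_term` object (list with fields `vocabulary`, `identifier`,
#'   `label`).
#' @examples
#' register_term("cell-type", "CL:0000451", "dendritic cell")
#' @export
register_term <- function(vocabulary, identifier, label) {
  vocabulary <- as.character(vocabulary)
  if (length(vocabulary) != 1 || !vocabulary %in% VOCABULARIES) {
    stop("unknown vocabulary: ", vocabulary[1], call. = FALSE)
  }
  identifier <- as.character(identifier)
  if (length(identifier) != 1 || !nzchar(identifier)) {
    stop("term identifier must be a non-empty string", call. = FALSE)
  }
  label <- as.character(label)
  key <- registry_key(vocabulary, identifier)
  existing <- .registry[[key]]
  if (!is.null(existing)) {
    if (!identical(existing$label, label)) {
      stop("label conflict for ", vocabulary, " term ", identifier, ": '",
           existing$label, "' already registered, got '", label, "'",
           call. = FALSE)
    }
    return(existing)
  }
  term <- new_term(vocabulary, identifier, label)
  .registry[[key]] <- term
  term
}

#' Look up a registered term
#'
#' @inheritParams register_term
#' @return The `bcml_term`, or `NULL` if not registered.
#' @export
lookup_term <- function(vocabulary, identifier) {
  seed_registry()
  if (!vocabulary %in% VOCABULARIES) {
    stop("unknown vocabulary: ", vocabulary, call. = FALSE)
  }
  .registry[[registry_key(vocabulary, identifier)]]
}

#' Tabulate the registered vocabulary
#'
#' @return A tibble with columns `vocabulary`, `identifier`, `label`.
#' @export
vocabulary_table <- function() {
  seed_registry()
  keys <- setdiff(ls(.registry), "seeded")
  terms <- lapply(keys, function(k) .registry[[k]])
  out <- tibble::tibble(
    vocabulary = vapply(terms, `[[`, "", "vocabulary"),
    identifier = vapply(terms, `[[`, "", "identifier"),
    label = vapply(terms, `[[`, "", "label")
  )
  dplyr::arrange(out, .data$vocabulary, .data$identifier)
}

#' @export
print.bcml_term <- function(x, ...) {
  cat(sprintf("<%s> %s (%s)\n", x$vocabulary, x$label, x$identifier))
  invisible(x)
}

#' @export
format.bcml_term <- function(x, ...) {
  sprintf("%s [%s]", x$label, x$identifier)
}

# Coerce a term-or-identifier argument to a bcml_term for a given vocabulary.
as_term <- function(x, vocabulary) {
  if (is.null(x)) return(NULL)
  if (inherits(x, "bcml_term")) {
    if (x$vocabulary != vocabulary) {
      stop("term ", x$identifier, " belongs to vocabulary '", x$vocabulary,
           "', expected '", vocabulary, "'", call. = FALSE)
    }
    return(x)
  }
  found <- lookup_term(vocabulary, as.character(x))
  if (is.null(found)) {
    stop("no registered ", vocabulary, " term with identifier '", x,
         "'; use register_term()", call. = FALSE)
  }
  found
}

terms_equal <- function(a, b) {
  !is.null(a) && !is.null(b) &&
    a$vocabulary == b$vocabulary && a$identifier == b$identifier
}
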