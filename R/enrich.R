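# Modular pathway enrichment: treated/control log2 ratios, fold-change DEG
# selection, one-sided Fisher exact test per module, and the signed Pathway
# Enrichment Factor (PEF) transform with a bounded score for small modules.

#' Bundle an expression matrix with its design
#'
#' @param values Numeric matrix of strictly positive absolute-scale
#'   intensities, genes in rows (rownames = accessions), samples in columns.
#' @param design Data frame with one row per sample: `sample` (matching the
#'   column names), `condition`, `replicate` (integer index), `role`
#'   (`"treated"` or `"control"`), and optionally `control` naming the
#'   control condition paired with each treated condition (inferred when the
#'   design has a single control condition).
#' @return A `bcml_expression` object.
#' @export
expression_table <- function(values, design) {
  values <- as.matrix(values)
  design <- tibble::as_tibble(design)
  stopifnot(!is.null(rownames(values)), !is.null(colnames(values)))
  if (any(!is.finite(values)) || any(values <= 0)) {
    stop("expression values must be strictly positive and finite",
         call. = FALSE)
  }
  req <- c("sample", "condition", "replicate", "role")
  if (!all(req %in% names(design))) {
    stop("design needs columns: ", paste(req, collapse = ", "), call. = FALSE)
  }
  if (!setequal(design$sample, colnames(values)) ||
      anyDuplicated(design$sample)) {
    stop("design samples must match the value matrix columns exactly",
         call. = FALSE)
  }
  if (!all(design$role %in% c("treated", "control"))) {
    stop("design role must be 'treated' or 'control'", call. = FALSE)
  }
  ctrl_conditions <- unique(design$condition[design$role == "control"])
  if (!"control" %in% names(design)) {
    if (length(ctrl_conditions) != 1) {
      stop("design lacks a 'control' column and does not have exactly one ",
           "control condition", call. = FALSE)
    }
    design$control <- ifelse(design$role == "treated", ctrl_conditions,
                             NA_character_)
  }
  treated <- unique(design$condition[design$role == "treated"])
  for (cond in treated) {
    ctrl <- unique(design$control[design$condition == cond &
                                    design$role == "treated"])
    if (length(ctrl) != 1 || is.na(ctrl) ||
        !ctrl %in% ctrl_conditions) {
      stop("treated condition '", cond,
           "' has no designated control condition", call. = FALSE)
    }
  }
  structure(list(values = values[, design$sample, drop = FALSE],
                 design = design),
            class = "bcml_expression")
}

#' @export
print.bcml_expression <- function(x, ...) {
  cat(sprintf("<bcml_expression> %d genes x %d samples (%d treated conditions)\n",
              nrow(x$values), ncol(x$values),
              length(unique(x$design$condition[x$design$role == "treated"]))))
  invisible(x)
}

new_ratios <- function(m) structure(m, class = c("bcml_ratios", "matrix"))
unclass_ratios <- function(x) {
  class(x) <- "matrix"
  x
}

#' Mean treated/control log2 ratios per condition
#'
#' For every treated condition, each treated replicate is paired with the
#' control replicate of the same index (replicate *i* treated over replicate
#' *i* control); treated replicates without an index partner are divided by
#' the mean of the control replicates.  Per-replicate ratios are
#' log2-transformed and averaged over replicates, damping inter-donor
#' variability.
#'
#' @param expr A [expression_table()].
#' @return A `bcml_ratios` object: numeric matrix, genes x treated
#'   conditions, of mean log2 ratios.
#' @export
compute_ratios <- function(expr) {
  stopifnot(inherits(expr, "bcml_expression"))
  d <- expr$design
  v <- expr$values
  treated <- unique(d$condition[d$role == "treated"])
  cols <- lapply(treated, function(cond) {
    td <- d[d$condition == cond & d$role == "treated", ]
    ctrl_cond <- td$control[1]
    cd <- d[d$condition == ctrl_cond & d$role == "control", ]
    ctrl_by_rep <- stats::setNames(cd$sample, cd$replicate)
    ctrl_mean <- rowMeans(v[, cd$sample, drop = FALSE])
    lr <- vapply(seq_len(nrow(td)), function(i) {
      tv <- v[, td$sample[i]]
      key <- as.character(td$replicate[i])
      cv <- if (key %in% names(ctrl_by_rep)) v[, ctrl_by_rep[[key]]] else ctrl_mean
      log2(tv / cv)
    }, numeric(nrow(v)))
    rowMeans(matrix(lr, nrow = nrow(v)))
  })
  m <- do.call(cbind, cols)
  dimnames(m) <- list(rownames(v), treated)
  new_ratios(m)
}

#' @export
print.bcml_ratios <- function(x, ...) {
  cat(sprintf("<bcml_ratios> %d genes x %d conditions\n", nrow(x), ncol(x)))
  invisible(x)
}

#' @method tidy bcml_ratios
#' @export
tidy.bcml_ratios <- function(x, ...) {
  m <- unclass_ratios(x)
  tibble::tibble(
    gene = rep(rownames(m), ncol(m)),
    condition = rep(colnames(m), each = nrow(m)),
    log2_ratio = as.vector(m)
  )
}

#' Select differentially expressed genes by fold change
#'
#' @param ratios A `bcml_ratios` object.
#' @param condition Condition id.
#' @param fold_threshold Fold-change cutoff on the linear scale (>= 1);
#'   a gene is selected when `|log2 ratio| >= log2(fold_threshold)`
#'   (boundary inclusive).  Default 2-fold.
#' @return A tibble: `gene`, `log2_ratio`, `sign` (+1/-1).
#' @export
select_degs <- function(ratios, condition, fold_threshold = 2) {
  stopifnot(inherits(ratios, "bcml_ratios"), fold_threshold >= 1)
  m <- unclass_ratios(ratios)
  if (!condition %in% colnames(m)) {
    stop("unknown condition: ", condition, call. = FALSE)
  }
  lr <- m[, condition]
  keep <- abs(lr) >= log2(fold_threshold)
  tibble::tibble(gene = rownames(m)[keep],
                 log2_ratio = unname(lr[keep]),
                 sign = unname(ifelse(lr[keep] >= 0, 1, -1)))
}

#' One-sided Fisher enrichment p-value
#'
#' Hypergeometric upper tail `P(X >= k)` for drawing `k` differentially
#' expressed genes in a module of `n` measured genes, out of `N` background
#' genes of which `K` are differentially expressed.
#'
#' @param module_genes Character vector (subset of `background`).
#' @param degs Character vector of DEG accessions (subset of `background`).
#' @param background Character vector of all measured genes (non-empty).
#' @return p-value in (0, 1]; exactly 1 when no module gene is a DEG.
#' @export
fisher_enrichment <- function(module_genes, degs, background) {
  background <- unique(as.character(background))
  if (length(background) == 0) stop("empty background", call. = FALSE)
  module_genes <- unique(as.character(module_genes))
  degs <- unique(as.character(degs))
  if (length(setdiff(module_genes, background)) > 0) {
    stop("module_genes must be a subset of background", call. = FALSE)
  }
  if (length(setdiff(degs, background)) > 0) {
    stop("degs must be a subset of background", call. = FALSE)
  }
  N <- length(background)
  K <- length(degs)
  n <- length(module_genes)
  k <- length(intersect(module_genes, degs))
  phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Signed Pathway Enrichment Factor
#'
#' Modules with at least `small_module_threshold` measured genes score
#' `sign * min(-log10 p, cap)`; smaller modules, where the exact test is
#' uninformative, score `sign * cap * n_de / n_module` (0 when the module
#' has no measured genes).  The cap keeps Euclidean distances between PEF
#' profiles finite when p-values underflow.
#'
#' @param p Fisher p-value in (0, 1].
#' @param sign +1 or -1: the sign of the summed log2 ratios of the module's
#'   DEGs (+1 when there are none or they cancel exactly).
#' @param n_module Number of module genes measured on the array.
#' @param n_de Number of those that are DEGs.
#' @param small_module_threshold Modules below this size use the fractional
#'   score (default 5).
#' @param cap Magnitude bound (default 16).
#' @return Signed numeric PEF.
#' @export
signed_pef <- function(p, sign, n_module, n_de,
                       small_module_threshold = 5, cap = 16) {
  stopifnot(length(p) == 1, p > 0, p <= 1, sign %in% c(-1, 1),
            n_de <= n_module, cap > 0)
  if (n_module >= small_module_threshold) {
    sign * min(-log10(p), cap)
  } else if (n_module == 0) {
    0
  } else {
    sign * cap * n_de / n_module
  }
}

#' Module-by-condition matrix of Pathway Enrichment Factors
#'
#' Runs the full modular enrichment over a set of pathways: module gene sets
#' (boundary genes shared between chained modules appear in both), DEG
#' selection per condition, one-sided Fisher test against the measured
#' background, and the signed PEF transform.  Rows are named
#' `<pathway>_<s|t|o>_<module label>` (s/t/o = sensing, transduction,
#' outcome).
#'
#' @param pathways A `bcml_pathway` or list of them.
#' @param ratios A `bcml_ratios` object.
#' @param fold_threshold DEG cutoff, see [select_degs()].
#' @param small_module_threshold,cap See [signed_pef()].
#' @param background Background gene set; defaults to the genes measured in
#'   `ratios` (standard enrichment practice).
#' @return A `bcml_pef` object: numeric matrix (modules x conditions) with a
#'   per-cell result table available through [tidy()].
#' @export
pef_matrix <- function(pathways, ratios, fold_threshold = 2,
                       small_module_threshold = 5, cap = 16,
                       background = NULL) {
  if (inherits(pathways, "bcml_pathway")) pathways <- list(pathways)
  stopifnot(all(vapply(pathways, inherits, TRUE, "bcml_pathway")),
            inherits(ratios, "bcml_ratios"))
  m <- unclass_ratios(ratios)
  if (is.null(background)) background <- rownames(m)
  conditions <- colnames(m)

  mods <- list()
  for (pw in pathways) {
    sets <- module_gene_sets(pw)
    for (mod in pw$modules) {
      key <- module_row_name(pw, mod)
      mods[[key]] <- list(pathway = pw$name, module = mod$id,
                          mtype = mod$mtype,
                          genes = intersect(sets[[mod$id]], background))
    }
  }
  degs_by_cond <- lapply(conditions, function(cond) {
    d <- select_degs(ratios, cond, fold_threshold)
    d <- d[d$gene %in% background, ]
    d
  })
  names(degs_by_cond) <- conditions

  rows <- list()
  pef <- matrix(0, nrow = length(mods), ncol = length(conditions),
                dimnames = list(names(mods), conditions))
  for (key in names(mods)) {
    info <- mods[[key]]
    for (cond in conditions) {
      d <- degs_by_cond[[cond]]
      in_mod <- d[d$gene %in% info$genes, ]
      n_module <- length(info$genes)
      n_de <- nrow(in_mod)
      p <- if (n_module == 0) 1 else fisher_enrichment(info$genes, d$gene,
                                                       background)
      sgn <- if (n_de == 0 || sum(in_mod$log2_ratio) == 0) 1 else
        sign(sum(in_mod$log2_ratio))
      val <- signed_pef(p, sgn, n_module, n_de, small_module_threshold, cap)
      pef[key, cond] <- val
      rows[[length(rows) + 1]] <- tibble::tibble(
        row = key, pathway = info$pathway, module = info$module,
        mtype = info$mtype, condition = cond, n_module = n_module,
        n_de = n_de, p = p, sign = sgn, pef = val,
        used_small_metric = n_module < small_module_threshold)
    }
  }
  structure(pef, class = c("bcml_pef", "matrix"),
            results = dplyr::bind_rows(rows),
            params = list(fold_threshold = fold_threshold,
                          small_module_threshold = small_module_threshold,
                          cap = cap, n_background = length(background)))
}

module_row_name <- function(pw, mod) {
  paste0(pw$name, "_", substr(mod$mtype, 1, 1), "_", mod$label)
}

#' @export
print.bcml_pef <- function(x, ...) {
  cat(sprintf("<bcml_pef> %d modules x %d conditions (fold cutoff %g, cap %g)\n",
              nrow(x), ncol(x), attr(x, "params")$fold_threshold,
              attr(x, "params")$cap))
  print(structure(unclass(x), results = NULL, params = NULL), ...)
  invisible(x)
}

#' @method tidy bcml_pef
#' @export
tidy.bcml_pef <- function(x, ...) attr(x, "results")

#' @method glance bcml_pef
#' @export
glance.bcml_pef <- function(x, ...) {
  p <- attr(x, "params")
  tibble::tibble(n_modules = nrow(x), n_conditions = ncol(x),
                 n_background = p$n_background,
                 fold_threshold = p$fold_threshold,
                 small_module_threshold = p$small_module_threshold,
                 cap = p$cap)
}

#' Write a PEF matrix as a tab-delimited table
#'
#' @param x A `bcml_pef`.
#' @param file Output path; rows labelled `<pathway>_<s|t|o>_<label>`.
#' @export
write_pef <- function(x, file) {
  stopifnot(inherits(x, "bcml_pef"))
  m <- structure(unclass(x), results = NULL, params = NULL)
  utils::write.table(m, file, sep = "\t", quote = FALSE,
                     col.names = NA)
  invisible(file)
}

#' Read a PEF matrix written by [write_pef()]
#'
#' @param file Path to the tab-delimited matrix.
#' @return A `bcml_pef` matrix (without per-cell results).
#' @export
read_pef <- function(file) {
  m <- as.matrix(utils::read.table(file, sep = "\t", header = TRUE,
                                   row.names = 1, check.names = FALSE))
  structure(m, class = c("bcml_pef", "matrix"),
            results = NULL, params = list())
}

#' @method autoplot bcml_pef
#' @export
autoplot.bcml_pef <- function(object, ...) {
  df <- tibble::tibble(
    module = factor(rep(rownames(object), ncol(object)),
                    levels = rev(rownames(object))),
    condition = rep(colnames(object), each = nrow(object)),
    pef = as.vector(unclass(object))
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$condition, .data$module,
                                   fill = .data$pef)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "#009900", mid = "black",
                                  high = "#CC0000", midpoint = 0) +
    ggplot2::labs(x = "condition", y = NULL, fill = "PEF") +
    ggplot2::theme_minimal()
}
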