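# Hierarchical clustering of PEF profiles with multiscale bootstrap
# resampling.  Features (the non-clustered axis) are resampled with
# replacement at several sample-size scales; the per-scale bootstrap
# probabilities of each cluster are extrapolated to an approximately
# unbiased (AU) support value through the signed-distance/curvature model
# z(r) = v*sqrt(r) + c/sqrt(r), fitted by weighted least squares.

DEFAULT_SCALES <- seq(0.5, 1.4, by = 0.1)

items_matrix <- function(m, axis = c("rows", "columns")) {
  axis <- match.arg(axis)
  m <- as.matrix(m)
  x <- if (axis == "rows") m else t(m)
  if (is.null(rownames(x))) rownames(x) <- paste0("item", seq_len(nrow(x)))
  x
}

#' Agglomerative clustering of a PEF matrix
#'
#' Euclidean distance over the chosen axis; items are ordered
#' lexicographically by label before clustering so that the result is
#' invariant to input order (deterministic tie-breaking).
#'
#' @param m A matrix (e.g. a `bcml_pef`).
#' @param axis Cluster `"rows"` or `"columns"`.
#' @param linkage `"average"` (default), `"complete"` or `"single"`.
#' @return An [stats::hclust] tree.
#' @export
hcluster <- function(m, axis = c("rows", "columns"),
                     linkage = c("average", "complete", "single")) {
  linkage <- match.arg(linkage)
  x <- items_matrix(m, axis)
  if (nrow(x) < 2) stop("need at least 2 items to cluster", call. = FALSE)
  x <- x[order(rownames(x), method = "radix"), , drop = FALSE]
  hclust(dist(x), method = linkage)
}

# leaf-set key of every internal node of an hclust tree, in merge order
cluster_keys <- function(hc) {
  n <- length(hc$labels)
  sets <- vector("list", n - 1)
  for (i in seq_len(n - 1)) {
    pick <- function(j) if (j < 0) hc$labels[-j] else sets[[j]]
    sets[[i]] <- c(pick(hc$merge[i, 1]), pick(hc$merge[i, 2]))
  }
  lapply(sets, function(s) sort(s, method = "radix"))
}

keys_as_strings <- function(sets) {
  vapply(sets, paste, "", collapse = "\r")
}

#' Multiscale bootstrap probabilities of the original clusters
#'
#' For each scale `r`, `B` replicates resample `ceiling(r * m)` of the `m`
#' features (the non-clustered axis) with replacement, re-cluster the items,
#' and record the fraction of replicate trees containing each cluster of the
#' original tree (exact leaf-set identity).
#'
#' @inheritParams hcluster
#' @param scales Positive resampling scales (default 0.5 to 1.4 by 0.1, the
#'   canonical grid).
#' @param B Bootstrap replicates per scale (default 1000).
#' @param seed Integer seed; the run is fully reproducible.
#' @return A `bcml_bp` object: list with the original `hclust`, the cluster
#'   leaf sets, `scales`, `B`, and the clusters x scales `bp` matrix.
#' @export
multiscale_bootstrap <- function(m, axis = c("rows", "columns"),
                                 linkage = c("average", "complete", "single"),
                                 scales = DEFAULT_SCALES, B = 1000,
                                 seed = 1) {
  linkage <- match.arg(linkage)
  stopifnot(B >= 1, all(scales > 0))
  x <- items_matrix(m, axis)
  x <- x[order(rownames(x), method = "radix"), , drop = FALSE]
  hc <- hclust(dist(x), method = linkage)
  orig_sets <- cluster_keys(hc)
  orig_keys <- keys_as_strings(orig_sets)
  nf <- ncol(x)
  labels <- rownames(x)
  n <- length(labels)

  set.seed(seed)
  bp <- matrix(0, nrow = length(orig_keys), ncol = length(scales))
  for (si in seq_along(scales)) {
    msize <- ceiling(scales[si] * nf)
    counts <- numeric(length(orig_keys))
    for (b in seq_len(B)) {
      idx <- sample.int(nf, msize, replace = TRUE)
      hb <- hclust(dist(x[, idx, drop = FALSE]), method = linkage)
      rep_keys <- keys_as_strings(cluster_keys(hb))
      counts <- counts + (orig_keys %in% rep_keys)
    }
    bp[, si] <- counts / B
  }
  dimnames(bp) <- list(NULL, paste0("r", scales))
  structure(list(hclust = hc, clusters = orig_sets, scales = scales, B = B,
                 bp = bp, linkage = linkage, seed = seed),
            class = "bcml_bp")
}

#' Approximately unbiased p-value from multiscale bootstrap probabilities
#'
#' Fits `qnorm(1 - BP(r)) = v*sqrt(r) + c/sqrt(r)` across scales by weighted
#' least squares (binomial weights) and returns `1 - pnorm(v - c)`.
#' Degenerate inputs fall back: BP identically 1 gives `au = 1`, identically
#' 0 gives `au = 0`, and with fewer than two scales strictly inside (0, 1)
#' the BP at the scale closest to 1 is returned.
#'
#' @param bp Numeric vector of bootstrap probabilities, one per scale.
#' @param scales Matching scales.
#' @param B Replicates behind each BP (for the weights).
#' @return AU support in `[0, 1]`, with attributes `v` and `c` when the
#'   model was fitted.
#' @export
au_pvalue <- function(bp, scales = DEFAULT_SCALES, B = 1000) {
  stopifnot(length(bp) == length(scales))
  if (all(bp >= 1)) return(1)
  if (all(bp <= 0)) return(0)
  use <- bp > 0 & bp < 1
  if (sum(use) < 2 || length(unique(scales[use])) < 2) {
    # too few informative scales to fit: fall back to the usable BP whose
    # scale is closest to 1 (or the scale-1 BP when none is usable)
    pick <- if (any(use)) which(use)[which.min(abs(scales[use] - 1))] else
      which.min(abs(scales - 1))
    return(unname(bp[pick]))
  }
  r <- scales[use]
  z <- qnorm(1 - bp[use])
  w <- B * dnorm(z)^2 / (bp[use] * (1 - bp[use]))
  X <- cbind(sqrt(r), 1 / sqrt(r))
  fit <- stats::lm.wfit(X, z, w)
  v <- fit$coefficients[1]
  cc <- fit$coefficients[2]
  au <- 1 - pnorm(v - cc)
  attr(au, "v") <- unname(v)
  attr(au, "c") <- unname(cc)
  unname_keep_attrs(au)
}

unname_keep_attrs <- function(x) {
  names(x) <- NULL
  x
}

#' Cluster with bootstrap and AU support per node
#'
#' Composes [hcluster()], [multiscale_bootstrap()] and [au_pvalue()]: every
#' internal node of the tree gets a plain bootstrap probability (`bp`, at
#' scale 1) and an approximately unbiased support (`au`).
#'
#' @inheritParams multiscale_bootstrap
#' @return A `bcml_dendrogram`: list with the `hclust` tree and a `support`
#'   tibble (`node`, `members` (list-column), `n_members`, `height`, `bp`,
#'   `au`).
#' @export
cluster_with_support <- function(m, axis = c("rows", "columns"),
                                 linkage = c("average", "complete", "single"),
                                 scales = DEFAULT_SCALES, B = 1000,
                                 seed = 1) {
  boot <- multiscale_bootstrap(m, axis, linkage, scales, B, seed)
  scale1 <- which.min(abs(boot$scales - 1))
  au <- vapply(seq_along(boot$clusters), function(i) {
    as.numeric(au_pvalue(boot$bp[i, ], boot$scales, boot$B))
  }, 0)
  support <- tibble::tibble(
    node = seq_along(boot$clusters),
    members = boot$clusters,
    n_members = lengths(boot$clusters),
    height = boot$hclust$height,
    bp = boot$bp[, scale1],
    au = au
  )
  structure(list(hclust = boot$hclust, support = support,
                 scales = boot$scales, B = boot$B, seed = boot$seed,
                 bp_table = boot$bp),
            class = "bcml_dendrogram")
}

#' @export
print.bcml_dendrogram <- function(x, ...) {
  cat(sprintf("<bcml_dendrogram> %d items, %d internal nodes (B = %d, seed = %d)\n",
              length(x$hclust$labels), nrow(x$support), x$B, x$seed))
  hi <- x$support[x$support$au >= 0.95, ]
  cat(sprintf("  %d node(s) with AU >= 0.95\n", nrow(hi)))
  invisible(x)
}

#' @method tidy bcml_dendrogram
#' @export
tidy.bcml_dendrogram <- function(x, ...) x$support

#' @method glance bcml_dendrogram
#' @export
glance.bcml_dendrogram <- function(x, ...) {
  tibble::tibble(n_items = length(x$hclust$labels),
                 n_nodes = nrow(x$support), B = x$B, seed = x$seed,
                 n_scales = length(x$scales),
                 max_au = max(x$support$au), min_au = min(x$support$au))
}

#' Write a support-annotated tree in Newick format
#'
#' Internal nodes are labelled `au|bp` with both supports rounded to two
#' decimals (the root, whose support is trivially 1, is left unlabelled by
#' most renderers).  Node labels are matched to clades by leaf set, so the
#' annotation is robust to node renumbering.
#'
#' @param x A `bcml_dendrogram`.
#' @param file Optional output path.
#' @return The Newick string (invisibly when `file` is given).
#' @export
write_support_newick <- function(x, file = NULL) {
  stopifnot(inherits(x, "bcml_dendrogram"))
  phy <- ape::as.phylo(x$hclust)
  parts <- ape::prop.part(phy)
  key_of <- vapply(x$support$members, paste, "", collapse = "\r")
  node_labels <- vapply(seq_along(parts), function(i) {
    k <- paste(sort(phy$tip.label[parts[[i]]], method = "radix"),
               collapse = "\r")
    j <- match(k, key_of)
    if (is.na(j)) "" else sprintf("%.2f|%.2f", x$support$au[j],
                                  x$support$bp[j])
  }, "")
  phy$node.label <- node_labels
  nwk <- ape::write.tree(phy)
  if (!is.null(file)) {
    writeLines(nwk, file)
    return(invisible(nwk))
  }
  nwk
}

#' Colour ramp for cluster support
#'
#' Maps support in `[0.5, 1]` onto a pink-to-black ramp (0.5 pink, 1 black);
#' values below 0.5 stay pink.
#'
#' @param support Numeric vector in `[0, 1]`.
#' @return Hex colour strings.
#' @export
support_color <- function(support) {
  f <- pmin(1, pmax(0, (support - 0.5) / 0.5))
  ramp <- grDevices::colorRamp(c("#FFC0CB", "#000000"))
  grDevices::rgb(ramp(f), maxColorValue = 255)
}

#' Export a support-coloured dendrogram as GraphML
#'
#' Leaves and internal nodes become GraphML nodes; each internal node
#' carries its `bp`, `au` and a display colour from [support_color()].
#'
#' @param x A `bcml_dendrogram`.
#' @param file Optional output path.
#' @return An `xml2::xml_document`.
#' @export
dendrogram_graphml <- function(x, file = NULL) {
  stopifnot(inherits(x, "bcml_dendrogram"))
  hc <- x$hclust
  n <- length(hc$labels)
  doc <- xml2::xml_new_root("graphml",
                            xmlns = "http://graphml.graphdrawing.org/xmlns")
  root <- xml2::xml_root(doc)
  for (k in list(c("d_label", "label"), c("d_bp", "bp"), c("d_au", "au"),
                 c("d_color", "color"), c("d_height", "height"))) {
    xml2::xml_add_child(root, "key", id = k[1], `for` = "node",
                        attr.name = k[2], attr.type = "string")
  }
  gr <- xml2::xml_add_child(root, "graph", id = "dendrogram",
                            edgedefault = "directed")
  add_data <- function(node, key, value) {
    d <- xml2::xml_add_child(node, "data", key = key)
    xml2::xml_text(d) <- as.character(value)
  }
  node_id <- function(j) if (j < 0) paste0("leaf_", -j) else paste0("node_", j)
  for (i in seq_len(n)) {
    nd <- xml2::xml_add_child(gr, "node", id = paste0("leaf_", i))
    add_data(nd, "d_label", hc$labels[i])
  }
  for (i in seq_len(n - 1)) {
    nd <- xml2::xml_add_child(gr, "node", id = paste0("node_", i))
    add_data(nd, "d_bp", sprintf("%.4f", x$support$bp[i]))
    add_data(nd, "d_au", sprintf("%.4f", x$support$au[i]))
    add_data(nd, "d_color", support_color(x$support$au[i]))
    add_data(nd, "d_height", format(hc$height[i]))
    for (child in hc$merge[i, ]) {
      xml2::xml_add_child(gr, "edge", source = paste0("node_", i),
                          target = node_id(child))
    }
  }
  if (!is.null(file)) xml2::write_xml(doc, file)
  doc
}

#' @method autoplot bcml_dendrogram
#' @export
autoplot.bcml_dendrogram <- function(object, ...) {
  segs <- dendro_segments(object$hclust)
  lab <- tibble::tibble(x = seq_along(object$hclust$labels),
                        label = object$hclust$labels[object$hclust$order])
  nodes <- node_positions(object)
  ggplot2::ggplot() +
    ggplot2::geom_segment(data = segs,
                          ggplot2::aes(x = .data$x, y = .data$y,
                                       xend = .data$xend, yend = .data$yend)) +
    ggplot2::geom_text(data = nodes,
                       ggplot2::aes(x = .data$x, y = .data$y,
                                    label = sprintf("%.0f", 100 * .data$au),
                                    colour = .data$au),
                       vjust = -0.4, size = 3) +
    ggplot2::scale_colour_gradient(low = "#FFC0CB", high = "#000000",
                                   limits = c(0.5, 1), oob = scales_squish) +
    ggplot2::scale_x_continuous(breaks = lab$x, labels = lab$label) +
    ggplot2::labs(x = NULL, y = "height", colour = "AU") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1))
}

scales_squish <- function(x, range = c(0, 1)) {
  pmin(range[2], pmax(range[1], x))
}

# horizontal + vertical segments of an hclust tree in plotting coordinates
dendro_segments <- function(hc) {
  n <- length(hc$labels)
  leaf_x <- stats::setNames(seq_len(n), hc$order)
  xs <- numeric(n - 1)
  xpos <- function(j) if (j < 0) leaf_x[[as.character(-j)]] else xs[j]
  ypos <- function(j) if (j < 0) 0 else hc$height[j]
  segs <- list()
  for (i in seq_len(n - 1)) {
    xl <- xpos(hc$merge[i, 1]); xr <- xpos(hc$merge[i, 2])
    yl <- ypos(hc$merge[i, 1]); yr <- ypos(hc$merge[i, 2])
    xs[i] <- mean(c(xl, xr))
    h <- hc$height[i]
    segs[[length(segs) + 1]] <- tibble::tibble(
      x = c(xl, xl, xr), y = c(yl, h, yr),
      xend = c(xl, xr, xr), yend = c(h, h, h))
  }
  dplyr::bind_rows(segs)
}

# positions of leaves and internal nodes in plotting coordinates
node_positions <- function(object) {
  hc <- object$hclust
  n <- length(hc$labels)
  leaf_x <- stats::setNames(seq_len(n), hc$order)
  xs <- numeric(n - 1)
  for (i in seq_len(n - 1)) {
    xpos <- function(j) if (j < 0) leaf_x[[as.character(-j)]] else xs[j]
    xs[i] <- mean(c(xpos(hc$merge[i, 1]), xpos(hc$merge[i, 2])))
  }
  tibble::tibble(x = xs, y = hc$height, au = object$support$au)
}
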