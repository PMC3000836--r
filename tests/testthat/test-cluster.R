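block_matrix <- function(seed = 1, n_features = 30, block = 6, sep = 8) {
  set.seed(seed)
  m <- cbind(matrix(rnorm(n_features * block), n_features, block),
             matrix(rnorm(n_features * block, mean = sep), n_features, block))
  colnames(m) <- c(paste0("A", seq_len(block)), paste0("B", seq_len(block)))
  rownames(m) <- paste0("f", seq_len(n_features))
  m
}

test_that("hcluster is deterministic and merges nearest pairs first", {
  m <- matrix(c(0, 1, 10), nrow = 1)
  colnames(m) <- c("x", "y", "z")
  hc <- hcluster(m, axis = "columns")
  first <- sort(hc$labels[-hc$merge[1, ]])
  expect_identical(first, c("x", "y"))

  # identical columns merge at height 0
  m2 <- matrix(c(1, 2, 1, 2, 5, 9), nrow = 2)
  colnames(m2) <- c("a", "b", "c")
  hc2 <- hcluster(m2, axis = "columns")
  expect_identical(hc2$height[1], 0)

  # permuting the input order leaves the tree unchanged
  m3 <- block_matrix(3)
  hc_a <- hcluster(m3, axis = "columns")
  hc_b <- hcluster(m3[, sample(ncol(m3))], axis = "columns")
  expect_identical(hc_a$merge, hc_b$merge)
  expect_equal(hc_a$height, hc_b$height)
  expect_identical(hc_a$labels, hc_b$labels)

  expect_error(hcluster(matrix(1, 1, 1)), "at least 2")
})

test_that("multiscale bootstrap is reproducible and respects B = 1", {
  m <- block_matrix(4)
  b1 <- multiscale_bootstrap(m, axis = "columns", B = 50, seed = 9)
  b2 <- multiscale_bootstrap(m, axis = "columns", B = 50, seed = 9)
  expect_identical(b1$bp, b2$bp)

  b3 <- multiscale_bootstrap(m, axis = "columns", B = 1, seed = 1)
  expect_true(all(b3$bp %in% c(0, 1)))

  # duplicate columns far from everything else: their pair has BP 1 always
  m2 <- cbind(block_matrix(5), dup1 = rep(50, 30), dup2 = rep(50, 30))
  b4 <- multiscale_bootstrap(m2, axis = "columns", B = 100, seed = 2)
  key <- vapply(b4$clusters, paste, "", collapse = ",")
  i <- match("dup1,dup2", key)
  expect_false(is.na(i))
  expect_true(all(b4$bp[i, ] == 1))
})

test_that("au_pvalue fallbacks and model fit behave", {
  expect_identical(au_pvalue(rep(1, 10)), 1)
  expect_identical(au_pvalue(rep(0, 10)), 0)
  # one usable scale falls back to the BP nearest scale 1
  bp <- c(rep(0, 9), 0.7)
  expect_equal(au_pvalue(bp, scales = seq(0.5, 1.4, 0.1)), 0.7)

  # exact model-generated BPs recover the closed form
  scales <- seq(0.5, 1.4, 0.1)
  for (vc in list(c(0.6, 0.3), c(1.2, 0.4), c(-0.4, 0.25))) {
    bp <- 1 - pnorm(vc[1] * sqrt(scales) + vc[2] / sqrt(scales))
    au <- au_pvalue(bp, scales, B = 1e6)
    expect_equal(as.numeric(au), 1 - pnorm(vc[1] - vc[2]), tolerance = 1e-6)
  }
})

test_that("BP at scale 1 is consistent across bootstrap sizes", {
  m <- block_matrix(6)
  scale1 <- 1
  b_small <- multiscale_bootstrap(m, axis = "columns", scales = 1, B = 1000,
                                  seed = 3)
  b_large <- multiscale_bootstrap(m, axis = "columns", scales = 1, B = 10000,
                                  seed = 4)
  expect_lt(max(abs(b_small$bp[, 1] - b_large$bp[, 1])), 0.05)
})

test_that("cluster_with_support yields a complete annotated tree", {
  m <- block_matrix(7)
  d <- cluster_with_support(m, axis = "columns", B = 200, seed = 5)
  n <- ncol(m)
  expect_identical(nrow(d$support), n - 1L)
  expect_true(all(d$support$bp >= 0 & d$support$bp <= 1))
  expect_true(all(d$support$au >= 0 & d$support$au <= 1))
  # every item appears exactly once as a leaf; root holds all of them
  expect_setequal(d$support$members[[n - 1]], colnames(m))

  # same seed, same Newick
  d2 <- cluster_with_support(m, axis = "columns", B = 200, seed = 5)
  expect_identical(write_support_newick(d), write_support_newick(d2))

  # the Newick parses back with the right tips
  phy <- ape::read.tree(text = write_support_newick(d))
  expect_setequal(phy$tip.label, colnames(m))
  expect_identical(phy$Nnode, n - 1L)

  # a structure-free matrix still yields a complete tree
  set.seed(8)
  m0 <- matrix(rnorm(120), 10, 12,
               dimnames = list(NULL, paste0("c", 1:12)))
  d0 <- cluster_with_support(m0, axis = "columns", B = 100, seed = 6)
  expect_identical(nrow(d0$support), 11L)
})

test_that("support colours ramp from pink to black and GraphML is complete", {
  expect_identical(support_color(0.5), "#FFC0CB")
  expect_identical(support_color(1), "#000000")
  expect_identical(support_color(0.2), "#FFC0CB")

  m <- block_matrix(9)
  d <- cluster_with_support(m, axis = "columns", B = 50, seed = 7)
  doc <- xml2::read_xml(as.character(dendrogram_graphml(d)))
  nodes <- xml2::xml_find_all(doc, "//*[local-name()='node']")
  edges <- xml2::xml_find_all(doc, "//*[local-name()='edge']")
  n <- ncol(m)
  expect_length(nodes, n + (n - 1))
  expect_length(edges, 2 * (n - 1))
})
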