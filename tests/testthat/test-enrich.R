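toy_expression <- function(values_by_cond, replicates = 2) {
  # values_by_cond: named list condition -> per-replicate multiplier vectors
  genes <- paste0("g", seq_along(values_by_cond[[1]][[1]]))
  samples <- list()
  design <- list()
  for (cond in names(values_by_cond)) {
    for (r in seq_along(values_by_cond[[cond]])) {
      nm <- paste0(cond, "_r", r)
      samples[[nm]] <- values_by_cond[[cond]][[r]]
      design[[length(design) + 1]] <- tibble::tibble(
        sample = nm, condition = cond, replicate = r,
        role = if (cond == "control") "control" else "treated")
    }
  }
  values <- do.call(cbind, samples)
  rownames(values) <- genes
  expression_table(values, dplyr::bind_rows(design))
}

test_that("compute_ratios pairs replicates and averages log2 ratios", {
  expr <- toy_expression(list(
    condA = list(c(8, 2), c(8, 16)),
    control = list(c(2, 4), c(2, 4))))
  r <- compute_ratios(expr)
  expect_equal(unname(unclass(r)[, "condA"]), c(2, (-1 + 2) / 2))

  # treated identical to control gives zero everywhere
  expr0 <- toy_expression(list(condA = list(c(3, 5), c(7, 11)),
                               control = list(c(3, 5), c(7, 11))))
  expect_true(all(unclass(compute_ratios(expr0)) == 0))

  # mean over three replicate ratios 1, 2, 3 (log2) is 2
  expr3 <- toy_expression(list(
    condA = list(c(2), c(4), c(8)), control = list(c(1), c(1), c(1))))
  expect_equal(unname(unclass(compute_ratios(expr3))[, "condA"]), 2)

  # an unpaired extra replicate falls back to the control mean
  expr4 <- toy_expression(list(
    condA = list(c(4), c(4), c(4)), control = list(c(2), c(2))))
  expect_equal(unname(unclass(compute_ratios(expr4))[, "condA"]), 1)

  expect_error(expression_table(matrix(c(1, -1), 2, 1,
                                       dimnames = list(c("a", "b"), "s1")),
                                tibble::tibble(sample = "s1",
                                               condition = "c",
                                               replicate = 1,
                                               role = "treated")),
               "positive")
})

test_that("select_degs applies the inclusive fold-change boundary", {
  m <- matrix(c(1, -0.5, 0, 2.5), ncol = 1,
              dimnames = list(paste0("g", 1:4), "c1"))
  r <- bcml:::new_ratios(m)
  d <- select_degs(r, "c1", fold_threshold = 2)
  expect_setequal(d$gene, c("g1", "g4"))
  expect_identical(d$sign[d$gene == "g1"], 1)
  # threshold 1 admits every gene with a nonzero ratio... and the zero one
  d1 <- select_degs(r, "c1", fold_threshold = 1)
  expect_setequal(d1$gene, paste0("g", 1:4))
  expect_error(select_degs(r, "zz"), "unknown condition")
  expect_error(select_degs(r, "c1", fold_threshold = 0.5))
})

test_that("fisher_enrichment matches direct tail enumeration", {
  bg <- as.character(1:100)
  degs <- as.character(1:10)
  mod <- as.character(c(1:5, 50:54))
  expect_equal(fisher_enrichment(mod, degs, bg),
               hyper_tail_enum(100, 10, 10, 5), tolerance = 1e-12)
  # degenerate cases
  expect_identical(fisher_enrichment(as.character(20:29), degs, bg)[[1]], 1)
  expect_identical(fisher_enrichment(bg, degs, bg), 1)
  expect_error(fisher_enrichment("x", degs, bg), "subset")
  expect_error(fisher_enrichment(character(), character(), character()),
               "empty background")

  # random instances across the N <= 30 lattice
  set.seed(11)
  for (i in 1:200) {
    N <- sample(1:30, 1)
    K <- sample(0:N, 1)
    n <- sample(0:N, 1)
    bg <- as.character(seq_len(N))
    degs <- sample(bg, K)
    mod <- sample(bg, n)
    expect_equal(fisher_enrichment(mod, degs, bg),
                 hyper_tail_enum(N, K, n, length(intersect(mod, degs))),
                 tolerance = 1e-12)
  }
})

test_that("signed_pef follows the two-branch transform", {
  expect_identical(signed_pef(1, 1, 10, 0), 0)
  expect_equal(signed_pef(0.001, -1, 10, 3), -3)
  expect_equal(signed_pef(1e-30, 1, 10, 9), 16)     # capped
  expect_equal(signed_pef(0.5, 1, 3, 3), 16)        # small-module saturation
  expect_equal(signed_pef(0.5, -1, 4, 1), -4)       # 16 * 1/4
  expect_identical(signed_pef(0.5, 1, 0, 0), 0)
  # antisymmetric in sign; monotone in p on the Fisher branch
  ps <- c(0.5, 0.1, 0.01, 1e-4)
  vals <- vapply(ps, signed_pef, 0, sign = 1, n_module = 8, n_de = 4)
  expect_true(all(diff(vals) > 0))
  expect_equal(vapply(ps, signed_pef, 0, sign = -1, n_module = 8, n_de = 4),
               -vals)
})

test_that("pef_matrix scores constructed activation and null conditions", {
  spec <- synth_spec(seed = 21)
  pws <- synth_pathways(spec)
  expr <- synth_expression(pws, spec)
  pm <- pef_matrix(pws, compute_ratios(expr))
  truth <- attr(expr, "truth")
  for (cond in names(truth)) {
    for (mod in truth[[cond]]$modules) {
      expect_gt(pm[mod, cond], 0)
      expect_identical(unname(pm[mod, cond]), max(pm[mod, ]))
    }
  }
  res <- tidy(pm)
  expect_true(all(res$n_de <= res$n_module))
  expect_true(all(res$p > 0 & res$p <= 1))
  expect_identical(res$used_small_metric, res$n_module < 5)

  # a condition with zero DEGs yields an all-zero column
  null_spec <- synth_spec(n_conditions = 1, noise_sigma = 0, seed = 22,
                          active_modules = list(
                            cond1 = list(modules = character(),
                                         direction = 1)))
  pws0 <- synth_pathways(null_spec)
  expr0 <- synth_expression(pws0, null_spec)
  pm0 <- pef_matrix(pws0, compute_ratios(expr0))
  expect_true(all(pm0[, "cond1"] == 0))
})

test_that("duplicated module content gives identical PEF rows", {
  spec <- synth_spec(n_pathways = 1, seed = 23)
  pw <- synth_pathways(spec)[[1]]
  # a disjoint twin pathway whose modules hold the same genes under new names
  twin <- pw
  twin$id <- "tw"
  twin$name <- "TW"
  pw2 <- pathway(twin$id, twin$name, twin$organism, twin$compartments,
                 lapply(pw$glyphs, function(g) {
                   # fresh ids to keep documents distinct
                   g
                 }), pw$arcs, pw$modules, pw$module_chain)
  expr <- synth_expression(list(pw), spec)
  pm <- pef_matrix(list(pw, pw2), compute_ratios(expr))
  for (mod in pw$modules) {
    r1 <- bcml:::module_row_name(pw, mod)
    r2 <- bcml:::module_row_name(pw2, mod)
    expect_equal(unname(pm[r1, ]), unname(pm[r2, ]))
  }
})
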