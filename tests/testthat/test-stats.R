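make_panel <- function(expr_list, times = NULL) {
  # expr_list: named list condition -> genes x replicates matrix
  conds <- names(expr_list)
  expr <- do.call(cbind, expr_list)
  samples <- tibble::tibble(
    sample = paste0("s", seq_len(ncol(expr))),
    condition = rep(conds, vapply(expr_list, ncol, 1L)),
    time = if (is.null(times)) "t1" else times,
    replicate = unlist(lapply(expr_list, function(m) seq_len(ncol(m))))
  )
  colnames(expr) <- samples$sample
  expression_panel(expr, samples, baseline = conds[1])
}

test_that("mean edge weight summarises within-module differential activity", {
  d <- toy_dcn("a", "b", .5, "b", "c", .5, "c", "d", .9,
               genes = letters[1:5])
  expect_equal(mean_edge_weight(c("a", "b", "c"), d), 0.5)
  expect_equal(mean_edge_weight(c("b", "c", "d"), d), 0.7)
  expect_true(is.na(mean_edge_weight(c("a", "e"), d)))
  # dense mean counts absent pairs as zeros
  expect_equal(mean_edge_weight(c("a", "b", "c"), d, dense = TRUE), 1 / 3)
})

test_that("module activity is the mean z-score over members and cells", {
  set.seed(2)
  X <- matrix(rnorm(4 * 12, mean = 5), 4, 12,
              dimnames = list(paste0("g", 1:4), NULL))
  panel <- make_panel(list(b = X[, 1:6], d = X[, 7:12]),
                      times = rep(rep(c("t1", "t2"), each = 3), 2))
  act <- module_activity(c("g1", "g2"), panel)
  # independent two-step recomputation
  z <- t(scale(t(X)))
  colnames(z) <- panel$samples$sample
  for (row in seq_len(nrow(act))) {
    cell <- panel$samples$sample[panel$samples$condition == act$condition[row] &
                                 panel$samples$time == act$time[row]]
    expect_equal(act$activity[row], mean(z[c("g1", "g2"), cell]), tolerance = 1e-12)
  }
  # single-gene module: activity = that gene's per-cell mean z
  one <- module_activity("g3", panel)
  cell <- panel$samples$sample[panel$samples$condition == "d" & panel$samples$time == "t1"]
  expect_equal(one$activity[one$condition == "d" & one$time == "t1"],
               mean(z["g3", cell]), tolerance = 1e-12)

  # mirror-image z-profiles cancel
  Y <- rbind(up = 1:8, down = 8:1) + 0
  p2 <- make_panel(list(b = Y[, 1:4], d = Y[, 5:8]))
  act2 <- module_activity(c("up", "down"), p2)
  expect_equal(act2$activity, c(0, 0), tolerance = 1e-12)
})

test_that("activity of a union of disjoint equal-size modules averages", {
  sim <- simulate_panel(default_fixture("tiny"), seed = 13)
  m1 <- sim$truth$modules$genes[[1]]
  m2 <- sim$truth$modules$genes[[2]]
  a1 <- module_activity(m1, sim$panel)
  a2 <- module_activity(m2, sim$panel)
  au <- module_activity(c(m1, m2), sim$panel)
  expect_equal(au$activity, (a1$activity + a2$activity) / 2, tolerance = 1e-12)
})

test_that("regulation calls detect directional shifts", {
  set.seed(4)
  n_genes <- 10
  base <- matrix(rnorm(n_genes * 5, mean = 5), n_genes, 5,
                 dimnames = list(paste0("g", 1:n_genes), NULL))
  up <- base + 2 + rnorm(50, sd = 0.1)
  panel <- make_panel(list(b = base, d = up))
  call_up <- regulation_call(paste0("g", 1:n_genes), panel, "d", "t1")
  expect_equal(call_up$call, "up")
  expect_lt(call_up$p, 0.01)

  down <- base - 2 + rnorm(50, sd = 0.1)
  pd <- make_panel(list(b = base, d = down))
  expect_equal(regulation_call(paste0("g", 1:n_genes), pd, "d", "t1")$call, "down")

  same <- make_panel(list(b = base, d = base + rnorm(50, sd = 0.01)))
  expect_equal(regulation_call(paste0("g", 1:n_genes), same, "d", "t1")$call, "none")

  # not enough genes for the gene-level test
  few <- regulation_call("g1", panel, "d", "t1")
  expect_equal(few$call, "none")
  expect_true(is.na(few$p))
  # replicate-pooled alternative still sees the shift
  expect_equal(regulation_call("g1", panel, "d", "t1", unit = "replicate")$call, "up")
})

test_that("phenotype correlation matches Pearson and its invariances", {
  act <- tibble::tibble(
    condition = rep(c("c1", "c2"), each = 4),
    time = rep(paste0("t", 1:4), 2),
    activity = c(1, 2, 3, 4, 2, 1, 4, 3)
  )
  pheno <- act %>% dplyr::mutate(m = activity, .keep = "unused")
  expect_equal(phenotype_correlation(act, pheno, "m"), 1)
  pheno$m <- -pheno$m
  expect_equal(phenotype_correlation(act, pheno, "m"), -1)
  # affine transforms leave it unchanged
  set.seed(1)
  pheno$m <- rnorm(8)
  r0 <- phenotype_correlation(act, pheno, "m")
  expect_equal(r0, cor(act$activity, pheno$m))
  act2 <- act %>% dplyr::mutate(activity = 3 * activity - 7)
  pheno2 <- pheno %>% dplyr::mutate(m = -2 * m + 1)
  expect_equal(abs(phenotype_correlation(act2, pheno2, "m")), abs(r0))
  # restriction to the module's conditions
  expect_equal(phenotype_correlation(act, pheno, "m", conditions = "c1"),
               cor(act$activity[1:4], pheno$m[1:4]))
  # fewer than 3 matched cells -> missing
  expect_true(is.na(phenotype_correlation(act[1:2, ], pheno, "m")))
  # FS-style inversion flips the sign of correlations with an FS measure
  phfs <- pheno %>% dplyr::rename(FS = m)
  expect_equal(phenotype_correlation(act, phfs, "FS", fs_invert = TRUE),
               -phenotype_correlation(act, phfs, "FS"), tolerance = 1e-12)
})

test_that("hypergeometric enrichment matches closed forms", {
  catalog <- tibble::tibble(
    module_id = c("m1", "m2"),
    genes = list(sprintf("u%04d", 1:10), sprintf("u%04d", 500:505))
  )
  universe <- sprintf("u%04d", 1:1000)
  coll <- gene_set_collection(list(hit = sprintf("u%04d", 1:10),
                                   other = sprintf("u%04d", 900:920)), universe)
  enr <- hypergeometric_enrichment(catalog, coll)
  p_hit <- enr$p[enr$module_id == "m1" & enr$set == "hit"]
  # module identical to the set: P = 1 / C(1000, 10)
  expect_equal(log(p_hit), -lchoose(1000, 10), tolerance = 1e-9)
  expect_true(enr$significant[enr$module_id == "m1" & enr$set == "hit"])
  # disjoint module contributes nothing
  expect_false(any(enr$significant[enr$module_id == "m2"]))
  g <- glance(enr)
  expect_equal(g$specificity, 0.5)
  expect_equal(g$sensitivity, 0.5)
  # p non-increasing in the overlap at fixed sizes
  ps <- vapply(0:10, function(k) {
    stats::phyper(k - 1, 10, 990, 10, lower.tail = FALSE)
  }, numeric(1))
  expect_true(all(diff(ps) <= 0))
})

test_that("the one-sided Fisher comparison matches exact enumeration", {
  got <- enrichment_fisher_test(8, 10, 2, 10)
  # enumeration over the hypergeometric tail with fixed margins
  want <- sum(vapply(8:10, function(k) {
    choose(10, k) * choose(10, 10 - k) / choose(20, 10)
  }, numeric(1)))
  expect_equal(got, want, tolerance = 1e-12)
})

test_that("edge-delta tables report thresholded weight changes", {
  a <- toy_dcn("a", "b", .5, "b", "c", .4, genes = letters[1:3], condition = "c1")
  b <- toy_dcn("a", "b", .8, "b", "c", .4, genes = letters[1:3], condition = "c2")
  expect_equal(nrow(edge_delta_table(letters[1:3], a, a, min_delta = 0.01)), 0)
  tab <- edge_delta_table(letters[1:3], a, b, min_delta = 0.2)
  expect_equal(nrow(tab), 1)
  expect_equal(tab$delta, 0.3)
  # deltas equal the component-matrix subtraction
  full <- edge_delta_table(letters[1:3], a, b, min_delta = 0)
  D <- component_adjacency(letters[1:3], b) - component_adjacency(letters[1:3], a)
  for (row in seq_len(nrow(full))) {
    expect_equal(full$delta[row], D[full$gene_a[row], full$gene_b[row]])
  }
})
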