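test_that("the same truth and seed reproduce the dataset exactly", {
  truth <- default_fixture("tiny")
  a <- simulate_panel(truth, seed = 17)
  b <- simulate_panel(truth, seed = 17)
  expect_identical(a$panel$expr, b$panel$expr)
  expect_identical(a$de, b$de)
  expect_identical(a$phenotype, b$phenotype)
  c <- simulate_panel(truth, seed = 18)
  expect_false(identical(a$panel$expr, c$panel$expr))
})

test_that("preset designs have the documented shapes", {
  tiny <- default_fixture("tiny")
  expect_equal(tiny$n_genes, 60)
  expect_equal(nrow(tiny$modules), 3)
  small <- default_fixture("small")
  expect_equal(small$n_genes, 300)
  expect_equal(nrow(small$modules), 3)
  expect_equal(lengths(small$modules$subset), c(3L, 2L, 1L))
  ps <- default_fixture("paper-shaped")
  sim <- simulate_panel(ps, seed = 1)
  non_base <- sum(sim$panel$samples$condition != ps$baseline)
  expect_equal(non_base, 3 * 4 * 4)
  expect_equal(nrow(sim$panel$expr), 2000)
})

test_that("planted modules are more co-expressed than background", {
  truth <- default_fixture("tiny")
  sim <- simulate_panel(truth, seed = 23)
  for (i in seq_len(nrow(truth$modules))) {
    m <- truth$modules[i, ]
    cc <- m$subset[[1]][1]
    X <- condition_matrix(sim$panel, cc)
    R <- abs(cor(t(X[m$genes[[1]], ])))
    in_cor <- mean(R[upper.tri(R)])
    bg_genes <- setdiff(rownames(X), unlist(truth$modules$genes))
    Rb <- abs(cor(t(X[bg_genes, ])))
    # within-module correlation clears background by a wide margin
    expect_gt(in_cor, mean(Rb[upper.tri(Rb)]) + 0.3)
  }
})

test_that("planted effects map monotonically onto smaller p-values", {
  truth <- default_fixture("small")
  sim <- simulate_panel(truth, seed = 29)
  eff <- setNames(numeric(truth$n_genes), truth$genes)
  for (i in seq_len(nrow(truth$modules))) {
    if ("c1" %in% truth$modules$subset[[i]]) {
      eff[truth$modules$genes[[i]]] <- mean(abs(truth$modules$effect[[i]]))
    }
  }
  eff[sim$truth$marker_genes] <- sim$truth$marker_effect
  rho <- cor(eff, -log(sim$de$c1), method = "spearman")
  expect_gt(rho, 0.5)
})

test_that("zeroed truth produces near-empty networks", {
  truth <- null_truth(default_fixture("small"))
  sim <- simulate_panel(truth, seed = 31)
  dcns <- suppressWarnings(build_dcns(sim$panel, sim$de, delta = 0.8))
  expect_lt(max(vapply(dcns, function(d) nrow(d$edges), 1L)), 40)
})

test_that("rewired modules change their within-module edge pattern", {
  truth <- default_fixture("rewired-pair")
  sim <- simulate_panel(truth, seed = 37)
  dcns <- build_dcns(sim$panel, sim$de, delta = 0.8)
  rew <- truth$modules$genes[[which(truth$modules$rewired)[1]]]
  sta <- truth$modules$genes[[which(!truth$modules$rewired)[1]]]
  pattern <- function(genes, d) component_adjacency(genes, d) > 0
  rew_diff <- sum(pattern(rew, dcns[[1]]) != pattern(rew, dcns[[2]]))
  sta_diff <- sum(pattern(sta, dcns[[1]]) != pattern(sta, dcns[[2]]))
  expect_gt(rew_diff, 20)
  expect_lt(sta_diff, 10)
})

test_that("datasets round-trip through the on-disk format", {
  sim <- simulate_panel(default_fixture("tiny"), seed = 41)
  dir <- withr::local_tempdir()
  write_synthetic_dataset(sim, dir)
  panel <- read_expression_panel(file.path(dir, "expression.tsv"))
  expect_equal(panel$expr, sim$panel$expr, tolerance = 1e-12)
  de <- read_de_pvalues(file.path(dir, "de_pvalues.tsv"))
  expect_equal(de$c1, unname(sim$de$c1), tolerance = 1e-12)
  ph <- read_phenotypes(file.path(dir, "phenotypes.tsv"))
  expect_equal(ph$pheno1, sim$phenotype$pheno1, tolerance = 1e-12)
  manifest <- jsonlite::read_json(file.path(dir, "truth.json"))
  expect_equal(manifest$n_genes, 60)
  expect_length(manifest$modules, 3)
})

test_that("impossible truth specifications are rejected", {
  expect_error(synthetic_truth(10, "c1", modules = planted_module(20, "c1")),
               "more genes")
  expect_error(synthetic_truth(10, "c1", n_marker = 11), "marker")
  expect_error(planted_module(5, "c9") %>% synthetic_truth(n_genes = 50, conditions = "c1", modules = .),
               "not in")
})
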