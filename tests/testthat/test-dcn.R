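test_that("edge weights follow the -log p normalisation", {
  # both endpoints at the global minimum p-value -> weight exactly 1
  expect_equal(edge_weight(1e-6, 1e-6, -log(1e-6)), 1)
  # no differential expression at all -> weight 0
  expect_equal(edge_weight(1, 1, 5), 0)
  # hand evaluation: p_i = e^-4, p_j = e^-9, max |log p| = 9
  expect_equal(edge_weight(exp(-4), exp(-9), 9), sqrt(13) / sqrt(18))
  expect_error(edge_weight(0, 0.5, 1), "> 0")
  expect_error(edge_weight(0.5, 0.5, 0), "positive")
})

test_that("direct dependence survives conditioning, mediated chains do not", {
  set.seed(1)
  n <- 100
  x <- rnorm(n)
  direct <- rbind(x = x, y = x + rnorm(n, sd = 0.05), z = rnorm(n))
  sc <- correlation_screen(direct, delta = 0.8)
  xy <- sc[sc$gene_a == "x" & sc$gene_b == "y", ]
  expect_true(xy$q > 0.8)
  expect_true(xy$pass)

  z <- rnorm(n)
  chain <- rbind(x = z + rnorm(n, sd = 0.3), z = z, y = z + rnorm(n, sd = 0.3))
  sc2 <- correlation_screen(chain, delta = 0.8)
  xy2 <- sc2[sc2$gene_a == "x" & sc2$gene_b == "y", ]
  if (nrow(xy2)) {
    expect_lt(xy2$q, 0.2)
    expect_false(xy2$pass)
  }
  # the mediated pair's partial given z is near zero even though the
  # marginal correlation is high
  expect_gt(abs(cor(chain["x", ], chain["y", ])), 0.8)
})

test_that("the screen's q matches brute-force partial-correlation evaluation", {
  set.seed(7)
  expr <- matrix(rnorm(6 * 8), 6, 8, dimnames = list(letters[1:6], NULL))
  expr <- expr + 2 * rep(rnorm(8), each = 6)  # common factor so pairs clear delta
  sc <- correlation_screen(expr, delta = 0.5)
  R <- cor(t(expr))
  for (row in seq_len(nrow(sc))) {
    i <- sc$gene_a[row]; j <- sc$gene_b[row]
    zs <- setdiff(rownames(expr), c(i, j))
    parts <- vapply(zs, function(z) {
      den <- sqrt((1 - R[i, z]^2) * (1 - R[j, z]^2))
      if (den < 1e-12) return(NA_real_)
      abs((R[i, j] - R[i, z] * R[j, z]) / den)
    }, numeric(1))
    expect_equal(sc$q[row], min(parts, na.rm = TRUE), tolerance = 1e-12)
    expect_equal(sc$r[row], abs(R[i, j]), tolerance = 1e-12)
  }
})

test_that("constructed DCNs satisfy the weight and symmetry invariants", {
  sim <- simulate_panel(default_fixture("tiny"), seed = 11)
  expr <- condition_matrix(sim$panel, "c1")
  p <- setNames(sim$de$c1, sim$de$gene)
  dcn <- build_dcn(expr, p, delta = 0.8, condition = "c1")
  expect_true(all(dcn$edges$weight > 0 & dcn$edges$weight <= 1))
  A <- dcn_matrix(dcn, dense = TRUE)
  expect_identical(A, t(A))
  expect_true(all(diag(A) == 0))
  # every edge passed the marginal threshold
  sc <- suppressWarnings(correlation_screen(expr, delta = 0.8))
  marg <- paste(sc$gene_a, sc$gene_b)
  expect_true(all(paste(dcn$edges$from, dcn$edges$to) %in% marg))
})

test_that("edge sets are nested as delta increases", {
  sim <- simulate_panel(default_fixture("tiny"), seed = 11)
  expr <- condition_matrix(sim$panel, "c1")
  p <- setNames(sim$de$c1, sim$de$gene)
  prev <- NULL
  for (d in c(0.8, 0.85, 0.9, 0.95)) {
    dcn <- suppressWarnings(build_dcn(expr, p, delta = d))
    key <- paste(dcn$edges$from, dcn$edges$to)
    if (!is.null(prev)) expect_true(all(key %in% prev))
    prev <- key
  }
})

test_that("planted co-expressed cliques get heavier edges than background", {
  truth <- default_fixture("tiny")
  sim <- simulate_panel(truth, seed = 11)
  dcns <- build_dcns(sim$panel, sim$de, delta = 0.8)
  m1 <- truth$modules$genes[[1]]
  planted <- unlist(truth$modules$genes)
  w_in <- dcns$c1$edges$weight[dcns$c1$edges$from %in% m1 & dcns$c1$edges$to %in% m1]
  w_bg <- dcns$c1$edges$weight[!(dcns$c1$edges$from %in% planted |
                                 dcns$c1$edges$to %in% planted)]
  expect_gt(length(w_in), 10)
  expect_gt(mean(w_in), median(w_bg))
})

test_that("near-boundary thresholds give empty networks with a warning", {
  set.seed(2)
  expr <- matrix(rnorm(10 * 30), 10, 30, dimnames = list(letters[1:10], NULL))
  p <- setNames(runif(10, 0.01, 1), letters[1:10])
  expect_warning(dcn <- build_dcn(expr, p, delta = 0.99), "no edges")
  expect_equal(nrow(dcn$edges), 0)
})

test_that("select_delta maximises genes connected in all networks", {
  # the paper's operating point from a one-point grid
  sim <- simulate_panel(default_fixture("tiny"), seed = 11)
  expect_equal(select_delta(sim$panel, grid = 0.8)$delta, 0.8)

  # fully correlated panel: every grid value connects everything,
  # tie broken toward the largest (sparsest) threshold
  set.seed(5)
  f <- rnorm(9)
  expr <- matrix(rep(f, each = 6), 6, 9, dimnames = list(paste0("g", 1:6), NULL)) +
    matrix(rnorm(54, sd = 0.01), 6, 9)
  samples <- tibble::tibble(sample = paste0("s", 1:9),
                            condition = rep(c("b", "c1", "c2"), each = 3),
                            time = "t1", replicate = rep(1:3, 3))
  colnames(expr) <- samples$sample
  panel <- expression_panel(expr, samples, baseline = "b")
  sel <- select_delta(panel, grid = c(0.5, 0.7, 0.9))
  expect_equal(sel$delta, 0.9)
  expect_true(all(sel$profile$n_connected_all == 6))
})
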