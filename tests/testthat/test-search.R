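test_that("node importance reflects connectivity strength", {
  star <- toy_dcn(
    "hub", "l1", 1, "hub", "l2", 1, "hub", "l3", 1, "hub", "l4", 1
  )
  imp <- node_importance(star)
  hub <- imp$importance[imp$gene == "hub"]
  leaves <- imp$importance[imp$gene != "hub"]
  expect_true(all(hub > leaves))
  expect_equal(max(leaves), min(leaves), tolerance = 1e-12)
  expect_equal(sum(imp$importance), 1)

  two_tri <- toy_dcn(
    "a", "b", .5, "b", "c", .5, "a", "c", .5,
    "x", "y", .5, "y", "z", .5, "x", "z", .5
  )
  imp2 <- node_importance(two_tri)
  expect_equal(max(imp2$importance), min(imp2$importance), tolerance = 1e-12)
})

test_that("importance matches a dense eigensolver on connected graphs", {
  d <- random_dcn(10, p = 0.5, seed = 3)
  # make sure it is one component: chain the genes
  chain <- tibble::tibble(from = d$genes[-10], to = d$genes[-1], weight = 0.2)
  d <- dcn_from_edges(dplyr::bind_rows(d$edges, chain), genes = d$genes)
  A <- dcn_matrix(d, dense = TRUE)
  deg <- rowSums(A)
  Ap <- diag(1 / sqrt(deg)) %*% A %*% diag(1 / sqrt(deg))
  e <- eigen(Ap, symmetric = TRUE)
  v <- abs(e$vectors[, which.max(e$values)])
  v <- v / sum(v)
  imp <- node_importance(d)
  expect_equal(imp$importance, unname(v), tolerance = 1e-8)
  expect_equal(max(e$values), 1, tolerance = 1e-12)
})

test_that("importance extends sqrt-strength continuously across components", {
  d <- toy_dcn(
    "a", "b", .9, "b", "c", .4, "a", "c", .7,
    "x", "y", .3
  )
  imp <- node_importance(d)
  deg <- rowSums(dcn_matrix(d, dense = TRUE))
  expect_equal(imp$importance, unname(sqrt(deg) / sum(sqrt(deg))), tolerance = 1e-12)
  # the limit of joining the components by a vanishing bridge
  eps <- 1e-9
  d2 <- dcn_from_edges(dplyr::bind_rows(d$edges,
          tibble::tibble(from = "c", to = "x", weight = eps)), genes = d$genes)
  A <- dcn_matrix(d2, dense = TRUE)
  deg2 <- rowSums(A)
  Ap <- diag(1 / sqrt(deg2)) %*% A %*% diag(1 / sqrt(deg2))
  e <- eigen(Ap, symmetric = TRUE)
  v <- abs(e$vectors[, which.max(e$values)]); v <- v / sum(v)
  expect_equal(imp$importance, unname(v), tolerance = 1e-4)
  # a strongly weighted clique outranks a weak one of the same shape
  two <- toy_dcn("a", "b", .9, "b", "c", .9, "a", "c", .9,
                 "x", "y", .1, "y", "z", .1, "x", "z", .1)
  i2 <- node_importance(two)
  expect_gt(min(i2$importance[i2$gene %in% c("a", "b", "c")]),
            max(i2$importance[i2$gene %in% c("x", "y", "z")]))
})

test_that("seed combination z-scores, averages and takes the top fraction", {
  # single network: seed order equals importance order
  d <- random_dcn(12, p = 0.4, seed = 9)
  imp <- node_importance(d)
  cr <- combine_rankings(list(imp), fraction = 0.25)
  expect_equal(cr$gene[1], imp$gene[which.max(imp$importance)])
  expect_equal(sum(cr$seed), ceiling(0.25 * sum(imp$importance > 0)))

  # a gene top-ranked in all networks is the first seed
  g <- setNames(c(10, 5, 4, 3, 2, 1), letters[1:6]) / 25
  g2 <- setNames(c(9, 1, 2, 3, 4, 5) / 24, letters[1:6])
  cr2 <- combine_rankings(list(g, g2, g), fraction = 0.5)
  expect_equal(cr2$gene[1], "a")

  # ceil arithmetic: 60 active genes at fraction 0.10 -> 6 seeds
  g3 <- setNames(runif(60) + 0.01, sprintf("g%02d", 1:60))
  g3 <- g3 / sum(g3)
  cr3 <- combine_rankings(list(g3), fraction = 0.10)
  expect_equal(sum(cr3$seed), 6)
})

test_that("module entropy has its closed-form values", {
  # isolated clique: all weight inside -> H = 0
  cl <- toy_dcn("a", "b", .7, "b", "c", .7, "a", "c", .7,
                "x", "y", .2, genes = c("a", "b", "c", "x", "y"))
  expect_equal(module_entropy(c("a", "b", "c"), list(cl)), 0)

  # gene with equal in- and out-module weight: term log 2
  half <- toy_dcn("a", "b", .5, "a", "c", .5, "b", "d", .5,
                  genes = c("a", "b", "c", "d"))
  expect_equal(module_entropy(c("a", "b"), list(half)), log(2))

  # absent from the searched network entirely: log 2 per gene
  other <- toy_dcn("x", "y", .4, genes = c("a", "b", "c", "d", "x", "y"))
  both <- toy_dcn("a", "b", .5, genes = c("a", "b", "c", "d", "x", "y"))
  expect_equal(module_entropy(c("a", "b"), list(both, other)), log(2))
})

test_that("module entropy agrees with brute-force summation on random graphs", {
  for (s in 1:5) {
    d1 <- random_dcn(9, p = 0.45, seed = s, condition = "c1")
    d2 <- random_dcn(9, p = 0.45, seed = s + 100, condition = "c2")
    set.seed(s)
    genes <- sample(d1$genes, 4)
    expect_equal(module_entropy(genes, list(d1, d2)),
                 oracle_entropy(genes, list(d1, d2)), tolerance = 1e-12)
  }
})

test_that("expansion recovers a planted near-clique from an inside seed", {
  dcns <- planted_pair()
  out <- expand_seed("g01", dcns)
  expect_gte(length(intersect(out$genes[[1]], sprintf("g%02d", 1:6))), 5)
  expect_true(all(diff(out$trace[[1]]) < 0))
  expect_equal(out$H, module_entropy(out$genes[[1]], dcns), tolerance = 1e-12)
})

test_that("every greedy move matches exhaustive re-evaluation on small graphs", {
  for (s in c(2, 5, 8)) {
    d1 <- random_dcn(8, p = 0.4, seed = s, condition = "c1")
    d2 <- random_dcn(8, p = 0.4, seed = s + 50, condition = "c2")
    deg <- rowSums(dcn_matrix(d1, dense = TRUE)) + rowSums(dcn_matrix(d2, dense = TRUE))
    seed_gene <- names(which.max(deg))
    got <- expand_seed(seed_gene, list(d1, d2))
    want <- oracle_expand(seed_gene, list(d1, d2))
    expect_equal(sort(got$genes[[1]]), want$genes)
    expect_equal(got$H, want$H, tolerance = 1e-10)
    expect_equal(got$trace[[1]], want$trace, tolerance = 1e-10)
  }
})

test_that("expansion never crosses into a disconnected clique", {
  two <- toy_dcn(
    "a", "b", .9, "b", "c", .9, "a", "c", .9,
    "x", "y", .9, "y", "z", .9, "x", "z", .9
  )
  out <- expand_seed("a", list(two))
  expect_true(all(out$genes[[1]] %in% c("a", "b", "c")))
})

test_that("greedy entropy is bounded below by exhaustive enumeration", {
  d1 <- random_dcn(8, p = 0.5, seed = 13)
  seed_gene <- "g01"
  got <- expand_seed(seed_gene, list(d1))
  # enumerate all connected gene sets containing the seed
  genes <- d1$genes
  A <- dcn_matrix(d1, dense = TRUE)
  best <- Inf
  for (k in 1:(2^8 - 1)) {
    members <- genes[bitwAnd(k, 2^(0:7)) > 0]
    if (!(seed_gene %in% members) || length(members) < 2) next
    sub <- A[members, members, drop = FALSE]
    comp <- mdmnet:::components_cpp(row(sub)[sub > 0], col(sub)[sub > 0], length(members))
    if (length(unique(comp)) > 1) next
    best <- min(best, module_entropy(members, list(d1)))
  }
  expect_gte(got$H + 1e-12, best)
})

test_that("refinement drops small candidates and merges overlapping ones", {
  dcns <- planted_pair()
  cands <- tibble::tibble(
    genes = list(sprintf("g%02d", 1:6), sprintf("g%02d", 1:6),
                 sprintf("g%02d", c(1:3, 7:12)), sprintf("g%02d", 1:4)),
    n_genes = c(6L, 6L, 9L, 4L),
    H = c(0.1, 0.1, 0.5, 0.2)
  )
  ref <- refine_candidates(cands, dcns, min_size = 5, jaccard = 0.5)
  # identical 6-gene candidates collapse; J({1..6},{1,2,3,7..12}) = 3/12 < .5
  expect_equal(nrow(ref), 2)
  expect_true(any(vapply(ref$genes, function(g) setequal(g, sprintf("g%02d", 1:6)), TRUE)))
  # the size-4 candidate is gone
  expect_false(any(ref$n_genes == 4))
})

test_that("relabeling genes permutes the discovery output correspondingly", {
  dcns <- planted_pair()
  out1 <- discover_mdms(dcns, min_size = 4)
  relabel <- setNames(sprintf("h%02d", 20:1), sprintf("g%02d", 1:20))
  dcns2 <- lapply(dcns, function(d) {
    dcn_from_edges(
      tibble::tibble(from = unname(relabel[d$edges$from]),
                     to = unname(relabel[d$edges$to]),
                     weight = d$edges$weight),
      genes = unname(relabel[d$genes]), condition = d$condition, delta = d$delta
    )
  })
  out2 <- discover_mdms(dcns2, min_size = 4)
  sets1 <- lapply(out1$genes, function(g) sort(unname(relabel[g])))
  sets2 <- lapply(out2$genes, sort)
  expect_setequal(vapply(sets1, paste, "", collapse = ","),
                  vapply(sets2, paste, "", collapse = ","))
})

test_that("level assignment keeps each module at its maximal subset", {
  catalog <- tibble::tibble(
    module_id = c("a", "b", "c", "d"),
    conditions = list("c1", c("c1", "c2"), c("c1", "c2"), "c3"),
    level = c(1L, 2L, 2L, 1L),
    genes = list(letters[1:6], letters[1:6], letters[10:15], letters[20:25]),
    n_genes = c(6L, 6L, 6L, 6L),
    H = c(.1, .1, .2, .3),
    significant = c(TRUE, TRUE, TRUE, FALSE)
  )
  class(catalog) <- c("mdm_catalog", class(catalog))
  out <- assign_levels(catalog)
  # the 1-level copy of the shared module is dropped; the non-significant
  # module never enters
  expect_setequal(out$module_id, c("b", "c"))
})

test_that("subset enumeration is guarded and single networks give 1-DMs", {
  d <- planted_pair()[[1]]
  out <- discover_mdms(list(d), min_size = 4)
  expect_true(all(out$level == 1))
  seven <- lapply(1:7, function(i) { x <- d; x$condition <- paste0("c", i); x })
  expect_error(discover_mdms(seven), "more than 6")
})
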