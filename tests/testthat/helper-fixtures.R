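# Shared fixture builders and independent oracles.  Everything here is
# deliberately naive: direct evaluation of the printed formulas, used to
# cross-check the package's optimised implementations.

toy_dcn <- function(..., genes = NULL, condition = "c1") {
  edges <- tibble::tribble(~from, ~to, ~weight, ...)
  dcn_from_edges(edges, genes = genes, condition = condition, delta = 0.8)
}

# random weighted graph over n named genes with edge probability p
random_dcn <- function(n, p = 0.3, condition = "c1", seed = 1) {
  set.seed(seed)
  genes <- sprintf("g%02d", seq_len(n))
  pairs <- t(combn(genes, 2))
  keep <- runif(nrow(pairs)) < p
  edges <- tibble::tibble(
    from = pairs[keep, 1], to = pairs[keep, 2],
    weight = round(runif(sum(keep), 0.1, 1), 3)
  )
  dcn_from_edges(edges, genes = genes, condition = condition, delta = 0.8)
}

# Entropy by direct summation of the vertex-network terms.
oracle_entropy <- function(genes, dcns) {
  genes <- sort(unique(genes))
  terms <- 0
  for (d in dcns) {
    A <- as.matrix(dcn_matrix(d))
    for (g in genes) {
      Ltot <- sum(A[g, ])
      Lin <- sum(A[g, setdiff(genes, g)])
      terms <- terms + if (Lin <= 0 || Ltot <= 0) {
        log(2)
      } else {
        p <- Lin / Ltot
        if (p >= 1) 0 else -p * log(p) - (1 - p) * log(1 - p)
      }
    }
  }
  terms / length(genes)
}

# Greedy expansion re-implemented step by step (best single
# add-adjacent-gene or drop-non-seed-member move under strict decrease,
# ties by radix gene order), for cross-checking the C++ search.
oracle_expand <- function(seed, dcns) {
  genes <- dcns[[1]]$genes
  mats <- lapply(dcns, function(d) as.matrix(dcn_matrix(d)))
  nbrs <- function(g) {
    unique(unlist(lapply(mats, function(A) names(which(A[g, ] > 0)))))
  }
  C <- sort(union(seed, nbrs(seed)))
  if (length(C) < 2) return(NULL)
  H <- oracle_entropy(C, dcns)
  trace <- H
  repeat {
    cand_add <- setdiff(sort(unique(unlist(lapply(C, nbrs)))), C)
    cand_rem <- if (length(C) > 2) setdiff(C, seed) else character()
    moves <- c(cand_add, cand_rem)
    if (!length(moves)) break
    hs <- vapply(moves, function(g) {
      newC <- if (g %in% C) setdiff(C, g) else union(C, g)
      oracle_entropy(newC, dcns)
    }, numeric(1))
    ord <- order(hs, rank(moves))
    best <- ord[1]
    if (hs[best] < H - 1e-12) {
      g <- moves[best]
      C <- if (g %in% C) setdiff(C, g) else sort(union(C, g))
      H <- hs[best]
      trace <- c(trace, H)
    } else break
  }
  list(genes = sort(C), H = unname(H), trace = unname(trace))
}

# A small deterministic multi-network pair of DCNs with a planted
# 6-clique in both networks plus scattered background edges.
planted_pair <- function(seed = 42) {
  set.seed(seed)
  genes <- sprintf("g%02d", 1:20)
  clique <- genes[1:6]
  cl_edges <- t(combn(clique, 2))
  build <- function(extra_seed) {
    set.seed(extra_seed)
    bg_pairs <- t(combn(genes[7:20], 2))
    keep <- runif(nrow(bg_pairs)) < 0.12
    edges <- tibble::tibble(
      from = c(cl_edges[, 1], bg_pairs[keep, 1]),
      to = c(cl_edges[, 2], bg_pairs[keep, 2]),
      weight = c(runif(nrow(cl_edges), 0.8, 1), runif(sum(keep), 0.1, 0.4))
    )
    dcn_from_edges(edges, genes = genes, condition = paste0("c", extra_seed), delta = 0.8)
  }
  list(build(1), build(2))
}

expect_setequal_genes <- function(a, b) expect_setequal(unlist(a), unlist(b))
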