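# Module search: propagation-based seed ranking, greedy entropy
# expansion, candidate refinement, and enumeration of network subsets.

# Internal search context: integer edge triplets and dense adjacency
# matrices over the common gene set, per-gene total strengths, and a
# deterministic tie-break order.  The permutation null rebuilds this
# hundreds of times, so everything here is plain vectors and matrices.
dcn_stack <- function(dcns) {
  dcns <- unname(dcns)
  genes <- dcns[[1]]$genes
  for (d in dcns) {
    if (!identical(d$genes, genes)) abort("all DCNs must share the same gene set, in the same order")
  }
  triplets <- lapply(dcns, function(d) {
    list(i = match(d$edges$from, genes), j = match(d$edges$to, genes),
         w = d$edges$weight)
  })
  stack_from_triplets(genes, triplets, vapply(dcns, `[[`, "", "condition"))
}

stack_from_triplets <- function(genes, triplets, conditions) {
  n <- length(genes)
  mats <- lapply(triplets, function(tr) {
    A <- matrix(0, n, n)
    A[cbind(tr$i, tr$j)] <- tr$w
    A[cbind(tr$j, tr$i)] <- tr$w
    A
  })
  totals <- vapply(mats, .rowSums, numeric(n), n = n, m = n)
  if (is.null(dim(totals))) totals <- matrix(totals, ncol = length(mats))
  list(genes = genes, mats = mats, totals = totals, triplets = triplets,
       ord = gene_rank(genes), conditions = conditions)
}

stack_active <- function(stack) stack$genes[rowSums(stack$totals > 0) > 0]

#' Propagation importance of genes in one network
#'
#' The importance vector is the stationary point of `g = A'g` on the
#' symmetrically degree-normalised weighted adjacency
#' `A' = D^{-1/2} A D^{-1/2}`: the importance of a gene grows with its
#' number of neighbours, the strength of its connections, and the
#' importance of those neighbours.  The stationary solution has a
#' closed form: on a connected graph the principal (eigenvalue-1)
#' eigenvector of `A'` is exactly the square root of a gene's total
#' strength.  On a graph with several components the eigenvalue-1
#' eigenspace is degenerate and the package resolves it by continuity:
#' `g_i = sqrt(d_i)`, normalised to unit sum over the whole gene set,
#' is the unique limit of the principal eigenvector as the components
#' are joined by vanishing bridge weights, and it keeps the stated
#' meaning -- stronger genes rank higher -- across components.
#' (A power iteration from a uniform start would instead converge to a
#' projection whose per-component mass exactly cancels the strength
#' scale, ranking a strongly connected module no higher than a weak
#' one.)  Isolated genes get importance 0.
#'
#' @param dcn A `dcn` object with at least one edge.
#' @return A tibble with columns `gene` and `importance`.
#' @export
node_importance <- function(dcn) {
  if (!nrow(dcn$edges)) abort(paste0("network '", dcn$condition, "' has no edges"))
  i <- match(dcn$edges$from, dcn$genes)
  j <- match(dcn$edges$to, dcn$genes)
  g <- importance_from_triplet(i, j, dcn$edges$weight, length(dcn$genes))
  tibble(gene = dcn$genes, importance = g)
}

# Closed-form stationary importance from an integer edge triplet:
# sqrt of total strength, unit-sum normalised (see node_importance).
importance_from_triplet <- function(i, j, w, n) {
  deg <- numeric(n)
  acc <- rowsum(c(w, w), c(i, j))
  deg[as.integer(rownames(acc))] <- acc
  sq <- sqrt(deg)
  sq / sum(sq)
}

#' Combine per-network importance rankings into a seed list
#'
#' Each network's importances are z-scored over the active gene set,
#' averaged across networks per gene, and the top fraction by average
#' z-score is selected (ties broken by gene id).  A network whose
#' importances have zero spread contributes 0 for every gene, with a
#' warning.
#'
#' @param rankings List of named importance vectors (or tibbles from
#'   [node_importance()]) over the same genes.
#' @param v_active Genes with degree >= 1 in at least one network; the
#'   z-scores and the 10%-rule are computed over this set.
#' @param fraction Fraction of active genes to keep as seeds
#'   (`ceiling(fraction * |V_active|)`).
#' @return A tibble (gene, mean_z, seed) sorted by decreasing mean z.
#' @export
combine_rankings <- function(rankings, v_active = NULL, fraction = 0.10) {
  if (fraction <= 0 || fraction > 1) abort("`fraction` must be in (0, 1]")
  rankings <- lapply(rankings, function(r) {
    if (is.data.frame(r)) setNames(r$importance, r$gene) else r
  })
  genes <- names(rankings[[1]])
  if (is.null(v_active)) v_active <- genes[Reduce(`+`, rankings) > 0]
  v_active <- intersect(genes, v_active)
  if (!length(v_active)) abort("no active genes to rank")
  zs <- vapply(rankings, function(r) {
    x <- r[v_active]
    s <- sd(x)
    if (is.na(s) || s == 0) {
      warn("a network's importances have zero spread; its z contribution is 0")
      return(numeric(length(x)))
    }
    (x - mean(x)) / s
  }, numeric(length(v_active)))
  if (is.null(dim(zs))) zs <- matrix(zs, ncol = length(rankings))
  mean_z <- rowMeans(zs)
  n_seed <- ceiling(fraction * length(v_active))
  ord <- order(-mean_z, gene_rank(v_active))
  tibble(
    gene = v_active[ord],
    mean_z = mean_z[ord],
    seed = seq_along(ord) <= n_seed
  )
}

#' Seed ranking across a set of networks
#'
#' Convenience wrapper: importance per network, z-combination, top-10%
#' seed selection over the genes active in at least one of the networks.
#'
#' @param dcns List of `dcn` objects over the same gene set.
#' @param fraction Seed fraction (default 0.10).
#' @return A tibble (gene, mean_z, seed).
#' @export
rank_seeds <- function(dcns, fraction = 0.10) {
  stack <- dcn_stack(dcns)
  rank_seeds_stack(stack, fraction)
}

rank_seeds_stack <- function(stack, fraction = 0.10) {
  rankings <- lapply(seq_along(stack$triplets), function(k) {
    tr <- stack$triplets[[k]]
    if (!length(tr$i)) abort(paste0("network '", stack$conditions[k], "' has no edges"))
    setNames(importance_from_triplet(tr$i, tr$j, tr$w, length(stack$genes)),
             stack$genes)
  })
  combine_rankings(rankings, v_active = stack_active(stack), fraction = fraction)
}

# Lean twin of rank_seeds_stack + combine_rankings for the permutation
# null: returns the seed gene *indices* without building tibbles.
seed_idx_stack <- function(stack, fraction = 0.10) {
  n <- length(stack$genes)
  active <- which(rowSums(stack$totals > 0) > 0)
  if (!length(active)) return(integer())
  zsum <- numeric(length(active))
  for (k in seq_along(stack$triplets)) {
    tr <- stack$triplets[[k]]
    if (!length(tr$i)) abort(paste0("network '", stack$conditions[k], "' has no edges"))
    g <- importance_from_triplet(tr$i, tr$j, tr$w, n)[active]
    sdg <- sd(g)
    if (is.na(sdg) || sdg == 0) {
      warn("a network's importances have zero spread; its z contribution is 0")
    } else {
      zsum <- zsum + (g - mean(g)) / sdg
    }
  }
  mean_z <- zsum / length(stack$triplets)
  n_seed <- ceiling(fraction * length(active))
  active[order(-mean_z, stack$ord[active])][seq_len(n_seed)]
}

#' Graph entropy of a gene module across networks
#'
#' For every member gene i and network k, `p_ik` is the fraction of i's
#' total edge weight that stays inside the module; the vertex term is
#' the binary entropy `-p log p - (1-p) log(1-p)` (natural log).  A gene
#' with no in-module connectivity in network k -- no edges into the
#' module, or no edges at all -- contributes `log 2` for that network,
#' so connectivity that exists in only some of the searched networks is
#' not mistaken for coherence.  `H(C)` is the sum of all
#' vertex-network terms divided by the module size; sharply bounded
#' modules (all weight inside) approach 0.
#'
#' @param genes Character vector, the module members (>= 2).
#' @param dcns List of `dcn` objects (the networks of the searched
#'   subset).
#' @return The entropy score, a non-negative scalar.
#' @export
module_entropy <- function(genes, dcns) {
  stack <- dcn_stack(dcns)
  module_entropy_stack(genes, stack)
}

module_entropy_stack <- function(genes, stack) {
  idx <- match(genes, stack$genes)
  if (anyNA(idx)) abort("module contains genes outside the network node set")
  if (length(idx) < 2) abort("module must have at least 2 genes")
  module_entropy_cpp(stack$mats, stack$totals, as.integer(idx))
}

#' Grow a candidate module around one seed gene
#'
#' Initialises the candidate with the seed's closed neighbourhood (union
#' over the searched networks) and then applies best-improvement moves
#' -- adding a gene adjacent to the module, or dropping a non-seed
#' member -- as long as the entropy strictly decreases.  Ties are broken
#' by gene id; the seed is never removed.
#'
#' @param seed Seed gene id.
#' @param dcns List of `dcn` objects (networks of the searched subset).
#' @return A tibble row: seed, genes (list), n_genes, H, trace (list of
#'   H after initialisation and after each accepted move); or a
#'   zero-row tibble when the seed is isolated in every network (with a
#'   warning).
#' @export
expand_seed <- function(seed, dcns) {
  stack <- dcn_stack(dcns)
  out <- expand_seed_stack(seed, stack)
  if (is.null(out)) {
    warn(paste0("seed '", seed, "' is isolated in every searched network; skipped"))
    return(tibble(seed = character(), genes = list(), n_genes = integer(),
                  H = double(), trace = list()))
  }
  out
}

expand_seed_stack <- function(seed, stack) {
  i <- match(seed, stack$genes)
  if (is.na(i)) abort(paste0("unknown seed gene '", seed, "'"))
  res <- expand_seed_cpp(stack$mats, stack$totals, i, as.integer(stack$ord))
  if (!length(res$members)) return(NULL)
  genes <- stack$genes[res$members]
  tibble(seed = seed, genes = list(genes), n_genes = length(!!genes),
         H = res$H, trace = list(res$trace))
}

#' Refine candidate modules: size filter and Jaccard merging
#'
#' Drops candidates smaller than `min_size`, then repeatedly merges the
#' candidate pair with the highest Jaccard index while it is at least
#' `jaccard`, recomputing the entropy of each union.  Deterministic
#' given the input order (ties by candidate position).
#'
#' @param cands Tibble of candidates (columns `genes`, `H`, as produced
#'   by [expand_seed()]).
#' @param dcns Networks of the searched subset (for entropy
#'   recomputation).
#' @param min_size Minimum module size (default 5).
#' @param jaccard Merge threshold (default 0.5).
#' @return A tibble (genes, n_genes, H, merged_from).
#' @export
refine_candidates <- function(cands, dcns, min_size = 5, jaccard = 0.5) {
  stack <- dcn_stack(dcns)
  refine_candidates_stack(cands, stack, min_size, jaccard)
}

refine_candidates_stack <- function(cands, stack, min_size = 5, jaccard = 0.5) {
  cands <- as_tibble(cands)
  keep <- which(cands$n_genes >= min_size)
  idx_sets <- lapply(cands$genes[keep], function(g) {
    sort(match(gene_sort(unique(g)), stack$genes))
  })
  ref <- refine_core(idx_sets, cands$H[keep], stack, min_size, jaccard,
                     prov = as.list(keep))
  tibble(
    genes = lapply(ref$sets, function(ii) stack$genes[ii]),
    n_genes = lengths(ref$sets), H = ref$H,
    merged_from = lapply(ref$prov, function(p) sort(unique(p)))
  )
}

# Size filter + iterative highest-Jaccard merging on integer gene sets.
refine_core <- function(sets, H, stack, min_size = 5, jaccard = 0.5, prov = NULL) {
  keep <- lengths(sets) >= min_size
  sets <- sets[keep]; H <- H[keep]
  if (is.null(prov)) prov <- as.list(seq_along(sets)) else prov <- prov[keep]
  if (length(sets) > 1) {
    key <- vapply(sets, paste, "", collapse = ",")
    first <- !duplicated(key)
    for (d in which(!first)) {
      tgt <- match(key[d], key[first])
      prov[first][[tgt]] <- c(prov[first][[tgt]], prov[[d]])
    }
    sets <- sets[first]; H <- H[first]; prov <- prov[first]
  }
  repeat {
    if (length(sets) < 2) break
    best <- c(0, 0); best_j <- -1
    for (a in seq_len(length(sets) - 1)) {
      for (b in (a + 1):length(sets)) {
        u <- length(union(sets[[a]], sets[[b]]))
        jj <- if (u == 0) 0 else length(intersect(sets[[a]], sets[[b]])) / u
        if (jj > best_j + 1e-12) {
          best_j <- jj; best <- c(a, b)
        }
      }
    }
    if (best_j < jaccard) break
    a <- best[1]; b <- best[2]
    u <- sort(union(sets[[a]], sets[[b]]))
    sets[[a]] <- u
    H[a] <- module_entropy_cpp(stack$mats, stack$totals, u)
    prov[[a]] <- c(prov[[a]], prov[[b]])
    sets <- sets[-b]; H <- H[-b]; prov <- prov[-b]
  }
  list(sets = sets, H = H, prov = prov)
}

# Full search on one subset of networks: rank, expand every seed,
# refine.  Plain-vector core shared by discovery and the permutation
# null; returns integer gene sets and their entropies.
search_core <- function(stack, fraction = 0.10, min_size = 5, jaccard = 0.5) {
  seeds <- seed_idx_stack(stack, fraction)
  sets <- vector("list", length(seeds))
  H <- numeric(length(seeds))
  kept <- logical(length(seeds))
  for (a in seq_along(seeds)) {
    res <- expand_seed_cpp(stack$mats, stack$totals, seeds[a], stack$ord)
    if (length(res$members) >= 2) {
      sets[[a]] <- res$members
      H[a] <- res$H
      kept[a] <- TRUE
    }
  }
  refine_core(sets[kept], H[kept], stack, min_size, jaccard)
}

search_subset <- function(stack, fraction = 0.10, min_size = 5, jaccard = 0.5) {
  found <- search_core(stack, fraction, min_size, jaccard)
  tibble(
    genes = lapply(found$sets, function(ii) stack$genes[ii]),
    n_genes = lengths(found$sets), H = found$H,
    merged_from = found$prov
  )
}

subset_label <- function(conditions) paste(conditions, collapse = "+")

enumerate_subsets <- function(conds, which = c("all", "singletons", "pairs", "triples")) {
  which <- match.arg(which)
  M <- length(conds)
  sizes <- switch(which, all = seq_len(M), singletons = 1L, pairs = 2L, triples = 3L)
  sizes <- sizes[sizes <= M]
  out <- list()
  for (s in sizes) {
    cmb <- utils::combn(conds, s, simplify = FALSE)
    out <- c(out, cmb)
  }
  out
}

#' Discover candidate modules on every subset of the networks
#'
#' Runs the seed-rank / expand / refine search independently on every
#' non-empty subset of the M networks (2^M - 1 searches).  The result is
#' a catalog of candidate modules; significance and level assignment are
#' applied afterwards by [mdm_significance()] and [assign_levels()]
#' (or use [find_modules()] for the whole chain).
#'
#' @param dcns Named list of `dcn` objects over a common gene set
#'   (M <= 6; subset enumeration grows as 2^M).
#' @param fraction Seed fraction (default 0.10).
#' @param min_size Minimum module size (default 5).
#' @param jaccard Merge threshold (default 0.5).
#' @param subsets Which subset sizes to search (`"all"`, `"singletons"`,
#'   `"pairs"`, `"triples"`).
#' @return An `mdm_catalog` tibble: module_id, conditions (list), level,
#'   genes (list), n_genes, H.
#' @export
discover_mdms <- function(dcns, fraction = 0.10, min_size = 5, jaccard = 0.5,
                          subsets = "all") {
  if (length(dcns) > 6) abort("more than 6 networks: subset enumeration refused")
  if (!length(dcns)) abort("need at least one network")
  conds <- vapply(dcns, `[[`, "", "condition")
  names(dcns) <- conds
  subs <- enumerate_subsets(conds, subsets)
  rows <- purrr::map(subs, function(ss) {
    stack <- dcn_stack(dcns[ss])
    found <- search_subset(stack, fraction, min_size, jaccard)
    if (!nrow(found)) return(NULL)
    found %>% mutate(
      conditions = list(ss), level = length(ss),
      module_id = paste0(subset_label(ss), ":m", sprintf("%02d", row_number()))
    )
  })
  out <- bind_rows(rows[!vapply(rows, is.null, logical(1))])
  if (!nrow(out)) {
    out <- tibble(module_id = character(), conditions = list(), level = integer(),
                  genes = list(), n_genes = integer(), H = double())
  } else {
    out <- out %>% select("module_id", "conditions", "level", "genes", "n_genes", "H")
  }
  attr(out, "params") <- list(fraction = fraction, min_size = min_size,
                              jaccard = jaccard, subsets = subsets)
  class(out) <- c("mdm_catalog", class(out))
  out
}

#' Assign each significant module to its maximal network subset
#'
#' Two steps.  (1) *Per-network presence:* when `dcns` are supplied,
#' each significant module is tested in every network of its subset --
#' its per-network entropy `H_k(C)/|C|` is compared against `n_rand`
#' random gene sets of the same size drawn from that network's
#' connected genes, and the network is kept only when the module is
#' more coherent than chance there (add-one empirical p <= `alpha`).
#' The module is demoted to the subset of networks where it is
#' present.  This matters because subset-level significance alone
#' cannot fix the level: a module perfectly coherent in two of three
#' networks is still far more coherent than degree-shuffled randomness
#' judged over all three, yet it is a 2-level module, not a 3-level
#' one.  (2) *Maximal-subset dedup:* a module is discarded when a
#' module of a strict superset of its subset matches it at Jaccard >=
#' `jaccard` (and, after demotion, same-subset duplicates keep the
#' lowest-entropy copy), so a shared module is never re-reported as a
#' condition-specific one.
#'
#' @param catalog An `mdm_catalog` with significance columns (from
#'   [mdm_significance()]).
#' @param dcns Named list of all networks (enables the presence test;
#'   omit to apply only the Jaccard dedup).
#' @param jaccard Matching threshold (default 0.5, the merge threshold).
#' @param n_rand Random gene sets per (module, network) presence test.
#' @param alpha Presence threshold on the empirical p-value.
#' @param seed Optional seed for the presence-test draws.
#' @return The filtered catalog (significant, subset-maximal modules)
#'   with `level` and `conditions` reflecting any demotion.
#' @export
assign_levels <- function(catalog, dcns = NULL, jaccard = 0.5,
                          n_rand = 100, alpha = 0.05, seed = NULL) {
  if (!"significant" %in% names(catalog)) {
    abort("run mdm_significance() before assign_levels()")
  }
  sig <- catalog %>% filter(.data$significant)
  if (!nrow(sig)) return(sig)

  if (!is.null(dcns)) {
    conds <- vapply(dcns, `[[`, "", "condition")
    names(dcns) <- conds
    sig <- local_seed(seed, {
      keep_rows <- logical(nrow(sig))
      for (i in seq_len(nrow(sig))) {
        ss <- sig$conditions[[i]]
        present <- vapply(ss, function(cc) {
          network_presence_p(sig$genes[[i]], dcns[[cc]], n_rand) <= alpha
        }, logical(1))
        ss2 <- ss[present]
        keep_rows[i] <- length(ss2) > 0
        sig$conditions[[i]] <- ss2
        sig$level[i] <- length(ss2)
      }
      sig[keep_rows, ]
    })
    # after demotion, same-subset duplicates keep the lowest-H copy
    if (nrow(sig) > 1) {
      labels <- vapply(sig$conditions, subset_label, "")
      ord <- order(sig$H)
      drop <- logical(nrow(sig))
      for (a in seq_along(ord)) {
        i <- ord[a]
        if (drop[i]) next
        for (b in seq_along(ord)) {
          j <- ord[b]
          if (i == j || drop[j] || labels[i] != labels[j] || sig$H[j] < sig$H[i]) next
          if (jaccard_index(sig$genes[[i]], sig$genes[[j]]) >= jaccard) drop[j] <- TRUE
        }
      }
      sig <- sig[!drop, ]
    }
  }

  if (nrow(sig) >= 2) {
    drop <- logical(nrow(sig))
    for (i in seq_len(nrow(sig))) {
      for (j in seq_len(nrow(sig))) {
        if (i == j || drop[i]) next
        si <- sig$conditions[[i]]; sj <- sig$conditions[[j]]
        if (length(sj) > length(si) && all(si %in% sj) &&
            jaccard_index(sig$genes[[i]], sig$genes[[j]]) >= jaccard) {
          drop[i] <- TRUE
        }
      }
    }
    sig <- sig[drop == FALSE, ]
  }
  class(sig) <- c("mdm_catalog", setdiff(class(sig), "mdm_catalog"))
  sig
}

# Add-one empirical p for a module being more coherent in one network
# than size-matched random gene sets drawn from its connected genes.
network_presence_p <- function(genes, dcn, n_rand = 100) {
  stack <- dcn_stack(list(dcn))
  obs <- module_entropy_stack(genes, stack)
  active <- stack_active(stack)
  size <- length(unique(genes))
  if (size > length(active)) return(1)
  null <- vapply(seq_len(n_rand), function(r) {
    module_entropy_stack(sample(active, size), stack)
  }, numeric(1))
  (1 + sum(null <= obs)) / (1 + n_rand)
}

#' @export
glance.mdm_catalog <- function(x, ...) {
  lv <- if (nrow(x)) table(factor(x$level, levels = 1:max(x$level))) else integer()
  tibble(
    n_modules = nrow(x),
    n_significant = if ("significant" %in% names(x)) sum(x$significant) else NA_integer_,
    levels = paste(sprintf("%d-DM: %d", as.integer(names(lv)), as.integer(lv)), collapse = ", "),
    mean_size = if (nrow(x)) mean(x$n_genes) else NA_real_
  )
}
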