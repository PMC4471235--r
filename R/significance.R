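# Empirical significance of candidate modules against degree-preserving
# permutation nulls.

#' Degree-preserving shuffle of a DCN
#'
#' Rewires the topology by repeated double-edge swaps (the standard
#' mixing heuristic: pick two disjoint edges (a,b), (c,d) and replace
#' them with (a,d), (c,b) unless a self-loop or multi-edge would result),
#' attempting `swaps_per_edge` swaps per edge, then randomly permutes
#' the multiset of edge weights over the rewired edge set.  The
#' unweighted degree sequence and the weight multiset are preserved
#' exactly.
#'
#' @param dcn A `dcn` with at least 2 edges.
#' @param swaps_per_edge Attempted swaps per edge (default 10).
#' @param seed Optional seed for this shuffle.
#' @return A rewired `dcn`.
#' @export
shuffle_dcn <- function(dcn, swaps_per_edge = 10, seed = NULL) {
  if (nrow(dcn$edges) < 2) abort("need at least 2 edges to shuffle")
  local_seed(seed, {
    i <- match(dcn$edges$from, dcn$genes)
    j <- match(dcn$edges$to, dcn$genes)
    rw <- rewire_edges_cpp(i, j, length(dcn$genes), swaps_per_edge)
    gi <- dcn$genes[rw$from]
    gj <- dcn$genes[rw$to]
    edges <- tibble(
      from = pmin(gi, gj),
      to = pmax(gi, gj),
      weight = sample(dcn$edges$weight)
    ) %>% arrange(.data$from, .data$to)
    new_dcn(edges, dcn$genes, dcn$condition, dcn$delta, dcn$p_floor_log)
  })
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate control; a thin wrapper over
#' [stats::p.adjust()] that validates its input.
#'
#' @param pvals Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values in the original order.
#' @export
bh_adjust <- function(pvals) {
  if (any(is.na(pvals)) || any(pvals < 0) || any(pvals > 1)) {
    abort("p-values must lie in [0, 1]")
  }
  p.adjust(pvals, method = "BH")
}

# One full null replicate for a subset: shuffle each network
# independently (degree-preserving rewire + weight permutation), re-run
# the whole search with the same parameters, and return the module
# scores found.  Works on the prebuilt stack so the hot loop stays free
# of data-frame overhead.
null_scores_once <- function(stack0, params, swaps_per_edge) {
  n <- length(stack0$genes)
  triplets <- lapply(stack0$triplets, function(tr) {
    rw <- rewire_edges_cpp(tr$i, tr$j, n, swaps_per_edge)
    list(i = rw$from, j = rw$to, w = sample(tr$w))
  })
  stack <- stack_from_triplets(stack0$genes, triplets, stack0$conditions)
  search_core(stack, params$fraction, params$min_size, params$jaccard)$H
}

#' Empirical significance of candidate modules
#'
#' For every network subset represented in the catalog, each network is
#' shuffled `n_rand` times by degree-preserved edge shuffling and the
#' full module search (same parameters) is re-run on the shuffled
#' networks; the scores of all modules found this way are pooled into
#' the subset's null distribution.  A module's empirical p-value is
#' `(1 + #{null <= observed H}) / (1 + #null)` (low entropy = coherent),
#' and p-values are Benjamini-Hochberg adjusted jointly across all
#' modules of all subsets.
#'
#' @param catalog An `mdm_catalog` from [discover_mdms()].
#' @param dcns The real networks the catalog was discovered on.
#' @param n_rand Number of randomisations per subset (default 100).
#' @param alpha Significance threshold on the adjusted p (default 0.05).
#' @param swaps_per_edge Double-edge-swap attempts per edge (default 10).
#' @param seed Optional seed for the permutation stream.
#' @return The catalog with columns `p`, `padj`, `significant` and an
#'   attribute `null_scores` (named list per subset).
#' @export
mdm_significance <- function(catalog, dcns, n_rand = 100, alpha = 0.05,
                             swaps_per_edge = 10, seed = NULL) {
  params <- attr(catalog, "params") %||%
    list(fraction = 0.10, min_size = 5, jaccard = 0.5)
  conds <- vapply(dcns, `[[`, "", "condition")
  names(dcns) <- conds
  labels <- vapply(catalog$conditions, subset_label, "")
  out <- local_seed(seed, {
    nulls <- list()
    for (lab in unique(labels)) {
      ss <- catalog$conditions[[match(lab, labels)]]
      stack0 <- dcn_stack(dcns[ss])
      scores <- purrr::map(seq_len(n_rand), function(r) {
        null_scores_once(stack0, params, swaps_per_edge)
      })
      nulls[[lab]] <- unlist(scores) %||% numeric()
    }
    p <- vapply(seq_len(nrow(catalog)), function(i) {
      ns <- nulls[[labels[i]]]
      if (!length(ns)) {
        warn(paste0("empty null distribution for subset '", labels[i],
                    "': no module was ever found on its randomized networks"))
        return(1)
      }
      (1 + sum(ns <= catalog$H[i])) / (1 + length(ns))
    }, numeric(1))
    list(p = p, nulls = nulls)
  })
  catalog$p <- out$p
  catalog$padj <- if (nrow(catalog)) bh_adjust(out$p) else numeric()
  catalog$significant <- catalog$padj <= alpha
  attr(catalog, "null_scores") <- out$nulls
  catalog
}

#' Full module discovery with significance and level assignment
#'
#' Chains [discover_mdms()], [mdm_significance()] and [assign_levels()].
#'
#' @inheritParams discover_mdms
#' @inheritParams mdm_significance
#' @return The final catalog of significant, subset-maximal modules;
#'   the complete candidate catalog (with p-values) is attached as
#'   attribute `candidates`.
#' @export
find_modules <- function(dcns, fraction = 0.10, min_size = 5, jaccard = 0.5,
                         subsets = "all", n_rand = 100, alpha = 0.05,
                         swaps_per_edge = 10, seed = NULL) {
  catalog <- discover_mdms(dcns, fraction, min_size, jaccard, subsets)
  catalog <- mdm_significance(catalog, dcns, n_rand = n_rand, alpha = alpha,
                              swaps_per_edge = swaps_per_edge, seed = seed)
  final <- assign_levels(catalog, dcns, jaccard = jaccard, n_rand = n_rand,
                         alpha = alpha,
                         seed = if (is.null(seed)) NULL else derive_seed(seed, 11))
  attr(final, "candidates") <- catalog
  final
}
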