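# Connectivity dynamics of shared modules: how much a module's induced
# weighted adjacency rewires between the networks it lives in.

#' Induced weighted adjacency of a module in one network
#'
#' @param genes Module member genes.
#' @param dcn A `dcn` object.
#' @return A symmetric |C| x |C| matrix of edge weights (0 where no
#'   edge), rows and columns in canonical (radix-sorted) gene order so
#'   matrices from different networks align.
#' @export
component_adjacency <- function(genes, dcn) {
  genes <- gene_sort(unique(genes))
  miss <- setdiff(genes, dcn$genes)
  if (length(miss)) abort(paste0("gene(s) not in the network: ", paste(miss, collapse = ", ")))
  as.matrix(dcn_matrix(dcn)[genes, genes, drop = FALSE])
}

matrix_norm <- function(m, norm = c("spectral", "frobenius")) {
  norm <- match.arg(norm)
  if (norm == "spectral") norm_spectral(m) else sqrt(sum(m^2))
}

norm_spectral <- function(m) {
  if (all(m == 0)) return(0)
  max(svd(m, nu = 0, nv = 0)$d)
}

#' Module connectivity dynamics score
#'
#' For each pair of networks, the matrix norm of the difference of the
#' module's induced weighted adjacencies, divided by the module size;
#' the overall score is the mean over pairs.  By default all unordered
#' pairs are averaged (identical to the adjacent-pairs form for two
#' networks); `pairing = "adjacent"` averages consecutive pairs in the
#' order the networks are supplied.  The norm is the induced 2-norm
#' (largest singular value) by default, with the Frobenius norm as an
#' alternative reading of "matrix L2 norm".
#'
#' A score of 0 means the component matrices are identical; larger
#' scores mean more rewiring (edge gains/losses and weight changes both
#' count).
#'
#' @param genes Module member genes.
#' @param dcns List of >= 2 `dcn` objects (the networks the module is
#'   shared by).
#' @param norm `"spectral"` (default) or `"frobenius"`.
#' @param pairing `"allpairs"` (default) or `"adjacent"`.
#' @return The dynamics score, a non-negative scalar.
#' @export
mcds <- function(genes, dcns, norm = c("spectral", "frobenius"),
                 pairing = c("allpairs", "adjacent")) {
  norm <- match.arg(norm)
  pairing <- match.arg(pairing)
  if (length(dcns) < 2) abort("dynamics need at least 2 networks")
  mats <- lapply(dcns, function(d) component_adjacency(genes, d))
  nC <- length(unique(genes))
  pairs <- if (pairing == "allpairs") {
    utils::combn(length(mats), 2, simplify = FALSE)
  } else {
    lapply(seq_len(length(mats) - 1), function(i) c(i, i + 1))
  }
  deltas <- vapply(pairs, function(ij) {
    matrix_norm(mats[[ij[1]]] - mats[[ij[2]]], norm) / nC
  }, numeric(1))
  mean(deltas)
}

#' Dynamics scores for every shared module of a catalog
#'
#' @param catalog An `mdm_catalog`; only modules with level >= 2 are
#'   scored.
#' @param dcns Named list of all `dcn` objects.
#' @inheritParams mcds
#' @return A tibble (module_id, conditions, n_genes, mcds) of class
#'   `mcds_table`.
#' @export
mcds_table <- function(catalog, dcns, norm = "spectral", pairing = "allpairs") {
  conds <- vapply(dcns, `[[`, "", "condition")
  names(dcns) <- conds
  shared <- catalog %>% filter(.data$level >= 2)
  out <- tibble(
    module_id = shared$module_id,
    conditions = shared$conditions,
    genes = shared$genes,
    n_genes = shared$n_genes,
    mcds = vapply(seq_len(nrow(shared)), function(i) {
      mcds(shared$genes[[i]], dcns[shared$conditions[[i]]], norm, pairing)
    }, numeric(1))
  )
  class(out) <- c("mcds_table", class(out))
  attr(out, "norm") <- norm
  attr(out, "pairing") <- pairing
  out
}

#' Permutation significance of dynamics scores
#'
#' The null for each shared module is the dynamics score of `n_rand`
#' random gene sets of the same size, drawn uniformly from the genes
#' connected in at least one of the module's networks.  The one-sided
#' empirical p-value is `(1 + #{null >= observed}) / (1 + n_rand)`
#' (large score = rewired); p-values are BH-adjusted across all shared
#' modules and a module is flagged dynamic at `padj <= alpha`.
#'
#' @param scores An `mcds_table` from [mcds_table()].
#' @param dcns Named list of all `dcn` objects.
#' @param n_rand Random gene sets per module (default 100).
#' @param alpha Threshold on the adjusted p-value (default 0.05; 0.01
#'   gives a stricter dynamic call).
#' @param seed Optional seed.
#' @return The table with columns `p`, `padj`, `dynamic`.
#' @export
mcds_significance <- function(scores, dcns, n_rand = 100, alpha = 0.05, seed = NULL) {
  conds <- vapply(dcns, `[[`, "", "condition")
  names(dcns) <- conds
  norm <- attr(scores, "norm") %||% "spectral"
  pairing <- attr(scores, "pairing") %||% "allpairs"
  p <- local_seed(seed, {
    vapply(seq_len(nrow(scores)), function(i) {
      nets <- dcns[scores$conditions[[i]]]
      active <- unique(unlist(lapply(nets, function(d) names(which(degree_of(d) > 0)))))
      size <- scores$n_genes[i]
      if (size > length(active)) {
        abort(paste0("module '", scores$module_id[i],
                     "' is larger than the active gene set"))
      }
      null <- vapply(seq_len(n_rand), function(r) {
        mcds(sample(active, size), nets, norm, pairing)
      }, numeric(1))
      (1 + sum(null >= scores$mcds[i])) / (1 + n_rand)
    }, numeric(1))
  })
  scores$p <- p
  scores$padj <- if (nrow(scores)) bh_adjust(p) else numeric()
  scores$dynamic <- scores$padj <= alpha
  scores
}
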