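# Differential co-expression networks (DCNs).
#
# One weighted, undirected network per disease condition over a common
# gene set V.  Edges are gene pairs whose expression correlation survives
# a first-order partial-correlation screen at threshold delta; weights
# come from the differential-expression p-values of the two endpoints.

new_dcn <- function(edges, genes, condition, delta, p_floor_log = NA_real_) {
  structure(
    list(edges = edges, genes = genes, condition = condition,
         delta = delta, p_floor_log = p_floor_log),
    class = "dcn"
  )
}

#' Build a DCN from an explicit edge list
#'
#' Mostly useful for tests and for re-importing exported networks; the
#' usual constructor is [build_dcn()].
#'
#' @param edges Data frame with columns `from`, `to`, `weight`
#'   (undirected; unordered duplicates are collapsed).
#' @param genes Character vector, the full node set V (defaults to the
#'   genes appearing in `edges`).
#' @param condition Condition label.
#' @param delta Correlation threshold recorded for provenance.
#' @return A `dcn` object.
#' @export
dcn_from_edges <- function(edges, genes = NULL, condition = "cond", delta = NA_real_) {
  edges <- as_tibble(edges)
  if (!all(c("from", "to", "weight") %in% names(edges))) {
    abort("`edges` needs columns from, to, weight")
  }
  edges <- edges %>% mutate(from = as.character(.data$from), to = as.character(.data$to))
  if (any(edges$from == edges$to)) abort("self-loops are not allowed")
  if (any(edges$weight <= 0) || any(edges$weight > 1)) {
    abort("edge weights must lie in (0, 1]")
  }
  swap <- edges$from > edges$to
  tmp <- edges$from[swap]
  edges$from[swap] <- edges$to[swap]
  edges$to[swap] <- tmp
  edges <- edges %>% dplyr::distinct(.data$from, .data$to, .keep_all = TRUE) %>%
    arrange(.data$from, .data$to)
  genes <- if (is.null(genes)) gene_sort(unique(c(edges$from, edges$to))) else as.character(genes)
  miss <- setdiff(c(edges$from, edges$to), genes)
  if (length(miss)) abort(paste0("edge endpoint(s) not in `genes`: ", paste(miss, collapse = ", ")))
  new_dcn(edges, genes, condition, delta)
}

#' @exportS3Method base::print
print.dcn <- function(x, ...) {
  cat("<dcn> condition '", x$condition, "': ", length(x$genes), " genes, ",
      nrow(x$edges), " edges (delta = ", format(x$delta), ")\n", sep = "")
  invisible(x)
}

#' Sparse symmetric adjacency matrix of a DCN
#' @param dcn A `dcn` object.
#' @param dense Return a base dense matrix instead of a sparse one.
#' @return A symmetric weighted adjacency matrix over all genes of V.
#' @export
dcn_matrix <- function(dcn, dense = FALSE) {
  n <- length(dcn$genes)
  i <- match(dcn$edges$from, dcn$genes)
  j <- match(dcn$edges$to, dcn$genes)
  m <- Matrix::sparseMatrix(
    i = c(i, j), j = c(j, i), x = rep(dcn$edges$weight, 2),
    dims = c(n, n), dimnames = list(dcn$genes, dcn$genes)
  )
  if (dense) as.matrix(m) else m
}

#' @export
tidy.dcn <- function(x, ...) x$edges

#' @export
glance.dcn <- function(x, ...) {
  deg <- degree_of(x)
  qs <- if (nrow(x$edges)) quantile(x$edges$weight, c(.25, .5, .75)) else rep(NA_real_, 3)
  tibble(
    condition = x$condition, n_genes = length(x$genes), n_edges = nrow(x$edges),
    n_connected = sum(deg > 0), delta = x$delta,
    weight_q25 = qs[[1]], weight_median = qs[[2]], weight_q75 = qs[[3]]
  )
}

degree_of <- function(dcn) {
  deg <- setNames(integer(length(dcn$genes)), dcn$genes)
  tab <- table(c(dcn$edges$from, dcn$edges$to))
  deg[names(tab)] <- as.integer(tab)
  deg
}

#' First-order partial Pearson correlation screen
#'
#' For every gene pair whose absolute marginal Pearson correlation
#' reaches `delta`, computes the minimum absolute first-order partial
#' correlation over all conditioning genes z.  The partial correlation
#' is what removes *indirect* edges: a chain x -> z -> y has near-zero
#' partial correlation of (x, y) given z, so the pair is dropped, while
#' genes that co-vary through a shared module factor keep a clearly
#' non-zero partial (about r / (1 + r) given another member) and
#' survive.  A pair therefore passes the screen when its marginal
#' correlation reaches `delta` *and* its minimum partial correlation
#' stays at or above `q_cut`.
#'
#' @param expr Genes x samples matrix for one condition (>= 3 samples).
#' @param delta Marginal-correlation threshold in (0, 1).
#' @param q_cut Indirect-correlation cutoff on the minimum absolute
#'   partial correlation (default 0.2: well above the ~0 partials of
#'   mediated chains, well below the ~0.45 partials within
#'   factor-driven modules).
#' @param conditioning_cap When more conditioning genes are available
#'   than this, only the cap-many genes most correlated with either
#'   endpoint are used (exhaustive first-order screening is cubic).
#' @param log_transform Apply log2(x + 1) before correlating.
#' @return A tibble with columns `gene_a`, `gene_b`, `r` (absolute
#'   marginal correlation), `q` (minimum absolute partial correlation)
#'   and `pass`.
#' @export
correlation_screen <- function(expr, delta, q_cut = 0.2,
                               conditioning_cap = 200, log_transform = FALSE) {
  if (ncol(expr) < 3) abort("need at least 3 samples to correlate")
  if (delta <= 0 || delta >= 1) abort("`delta` must be in (0, 1)")
  if (log_transform) expr <- log2(expr + 1)
  v <- apply(expr, 1, stats::var)
  if (any(v <= 0)) {
    warn(paste0(sum(v <= 0), " zero-variance gene(s) excluded from the correlation screen"))
    expr <- expr[v > 0, , drop = FALSE]
  }
  genes <- rownames(expr)
  n <- length(genes)
  if (n < 2) {
    return(tibble(gene_a = character(), gene_b = character(),
                  r = double(), q = double(), pass = logical()))
  }
  R <- stats::cor(t(expr))
  cand <- which(abs(R) >= delta & upper.tri(R), arr.ind = TRUE)
  if (!nrow(cand)) {
    return(tibble(gene_a = character(), gene_b = character(),
                  r = double(), q = double(), pass = logical()))
  }
  skipped <- 0L
  qv <- vapply(seq_len(nrow(cand)), function(idx) {
    i <- cand[idx, 1]; j <- cand[idx, 2]
    z <- setdiff(seq_len(n), c(i, j))
    if (!length(z)) return(abs(R[i, j]))
    if (length(z) > conditioning_cap) {
      strength <- pmax(abs(R[i, z]), abs(R[j, z]))
      z <- z[order(-strength, z)][seq_len(conditioning_cap)]
    }
    den2 <- (1 - R[i, z]^2) * (1 - R[j, z]^2)
    ok <- sqrt(pmax(den2, 0)) >= 1e-12
    skipped <<- skipped + sum(!ok)
    if (!any(ok)) return(abs(R[i, j]))
    part <- abs((R[i, j] - R[i, z][ok] * R[j, z][ok]) / sqrt(den2[ok]))
    min(part)
  }, numeric(1))
  if (skipped > 0) {
    inform(paste0(skipped, " near-collinear conditioning gene(s) skipped in the partial screen"))
  }
  tibble(
    gene_a = genes[cand[, 1]], gene_b = genes[cand[, 2]],
    r = abs(R[cand]), q = qv, pass = qv >= q_cut
  )
}

#' Differential edge weight from endpoint p-values
#'
#' `sqrt(-log p_i - log p_j) / sqrt(2 * p_floor_log)` with natural
#' logarithms, where `p_floor_log` is the largest `-log p` over all genes
#' of the network's node set.  The weight is 1 exactly when both
#' endpoints attain the global minimum p-value, and 0 when both p-values
#' are 1 (no differential expression).
#'
#' @param p_i,p_j Differential-expression p-values in (0, 1] (vectorised).
#' @param p_floor_log Positive normaliser, `max_l |log p_l|` over the
#'   node set.
#' @return Weights in \[0, 1\].
#' @export
edge_weight <- function(p_i, p_j, p_floor_log) {
  if (any(p_i <= 0) || any(p_j <= 0)) abort("p-values must be > 0 (clamp upstream)")
  if (any(p_i > 1) || any(p_j > 1)) abort("p-values must be <= 1")
  if (length(p_floor_log) != 1 || p_floor_log <= 0) {
    abort("`p_floor_log` must be a single positive number (all p = 1 would give an all-zero network)")
  }
  pmin(sqrt((-log(p_i)) + (-log(p_j))) / sqrt(2 * p_floor_log), 1)
}

#' Build one differential co-expression network
#'
#' Runs the partial-correlation screen on one condition's expression
#' submatrix and weights the surviving pairs by their endpoint
#' differential-expression p-values.  Pairs failing the screen are
#' absent (weight 0); screened pairs whose endpoints both have p = 1
#' get weight 0 and are dropped too.
#'
#' @param expr Genes x samples matrix for the condition.
#' @param de Either a named numeric vector of p-values or a data frame
#'   with columns `gene` and `p` covering every gene of `expr`.
#' @param delta Correlation threshold in (0, 1).
#' @param condition Condition label stored on the network.
#' @inheritParams correlation_screen
#' @return A `dcn` object.
#' @export
build_dcn <- function(expr, de, delta, condition = "cond", q_cut = 0.2,
                      conditioning_cap = 200, log_transform = FALSE) {
  genes <- rownames(expr)
  p <- de_vector(de, genes)
  p_floor_log <- max(-log(p))
  if (p_floor_log <= 0) abort("all p-values are 1; the network would be all-zero")
  screen <- correlation_screen(expr, delta, q_cut = q_cut,
                               conditioning_cap = conditioning_cap,
                               log_transform = log_transform)
  hits <- screen %>% filter(.data$pass)
  edges <- tibble(
    from = pmin(hits$gene_a, hits$gene_b),
    to = pmax(hits$gene_a, hits$gene_b),
    weight = edge_weight(p[hits$gene_a], p[hits$gene_b], p_floor_log)
  ) %>% filter(.data$weight > 0) %>% arrange(.data$from, .data$to)
  if (!nrow(edges)) warn(paste0("DCN for condition '", condition, "' has no edges"))
  new_dcn(edges, genes, condition, delta, p_floor_log)
}

de_vector <- function(de, genes) {
  if (is.data.frame(de)) {
    if (!all(c("gene", "p") %in% names(de))) abort("`de` data frame needs columns gene, p")
    p <- setNames(de$p, de$gene)
  } else {
    p <- de
  }
  miss <- setdiff(genes, names(p))
  if (length(miss)) abort(paste0("p-values missing for ", length(miss), " gene(s), e.g. ", miss[1]))
  p <- p[genes]
  if (any(p <= 0) || any(p > 1)) abort("p-values must lie in (0, 1]")
  p
}

#' Build every condition's DCN from a panel
#'
#' @param panel An `expression_panel`.
#' @param de Tibble with a `gene` column and one p-value column per
#'   non-baseline condition (see [read_de_pvalues()]).
#' @inheritParams build_dcn
#' @return Named list of `dcn` objects, one per non-baseline condition.
#' @export
build_dcns <- function(panel, de, delta, q_cut = 0.2,
                       conditioning_cap = 200, log_transform = FALSE) {
  conds <- panel_conditions(panel)
  miss <- setdiff(conds, names(de))
  if (length(miss)) abort(paste0("p-value columns missing for condition(s): ", paste(miss, collapse = ", ")))
  out <- lapply(conds, function(cc) {
    build_dcn(condition_matrix(panel, cc),
              setNames(de[[cc]], de$gene),
              delta = delta, condition = cc, q_cut = q_cut,
              conditioning_cap = conditioning_cap, log_transform = log_transform)
  })
  setNames(out, conds)
}

#' Choose the correlation threshold from a candidate grid
#'
#' Picks the delta that maximises the number of genes connected
#' (degree >= 1) in *every* condition's network simultaneously, breaking
#' ties towards the larger (sparser) threshold.  The screen is computed
#' once at the smallest grid value; edge sets are nested under
#' increasing delta, so larger thresholds only drop edges.
#'
#' @inheritParams build_dcns
#' @param grid Numeric vector of candidate thresholds in (0, 1).
#' @return A list with the chosen `delta` and a tibble `profile`
#'   (delta, genes connected in all networks).
#' @export
select_delta <- function(panel, grid, q_cut = 0.2,
                         conditioning_cap = 200, log_transform = FALSE) {
  if (!length(grid)) abort("`grid` must be non-empty")
  if (any(grid <= 0) || any(grid >= 1)) abort("grid values must be in (0, 1)")
  grid <- sort(unique(grid))
  conds <- panel_conditions(panel)
  screens <- lapply(conds, function(cc) {
    correlation_screen(condition_matrix(panel, cc), min(grid), q_cut = q_cut,
                       conditioning_cap = conditioning_cap,
                       log_transform = log_transform)
  })
  counts <- vapply(grid, function(d) {
    per_cond <- lapply(screens, function(sc) {
      hit <- sc$r >= d & sc$pass
      unique(c(sc$gene_a[hit], sc$gene_b[hit]))
    })
    length(Reduce(intersect, per_cond))
  }, integer(1))
  best <- max(counts)
  delta <- max(grid[counts == best])
  list(delta = delta, profile = tibble(delta = grid, n_connected_all = counts))
}
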