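# Module-level downstream statistics: differential activity, regulation
# calls, phenotype correlation, gene-set enrichment, and edge-delta
# exports.

#' Mean edge weight of a module in one network
#'
#' The average edge weight of a module is a direct measure of its
#' differential activity in that condition: weights are large when the
#' member genes are strongly differentially expressed.  Only edges that
#' are present are averaged by default, so sparsity is not conflated
#' with low activity; `dense = TRUE` divides by all C(|C|, 2) pairs
#' instead (absent pairs counted as 0).
#'
#' @param genes Module member genes.
#' @param dcn A `dcn` object.
#' @param dense Average over all pairs rather than present edges.
#' @return The mean weight, or `NA` when the module has no within-module
#'   edge in this network.
#' @export
mean_edge_weight <- function(genes, dcn, dense = FALSE) {
  genes <- unique(genes)
  e <- dcn$edges %>% filter(.data$from %in% genes & .data$to %in% genes)
  if (!nrow(e)) return(NA_real_)
  if (dense) sum(e$weight) / choose(length(genes), 2) else mean(e$weight)
}

#' Module activity profile
#'
#' Activity is the average z-score-normalised expression of the member
#' genes: each gene is z-scored across *all* samples of all conditions,
#' replicate values are averaged within each (condition, time) cell,
#' and the cell averages are averaged over member genes.  Zero-variance
#' genes are excluded with a warning.
#'
#' @param genes Module member genes.
#' @param panel An `expression_panel`.
#' @return A tibble (condition, time, activity).
#' @export
module_activity <- function(genes, panel) {
  genes <- unique(genes)
  miss <- setdiff(genes, rownames(panel$expr))
  if (length(miss)) abort(paste0("gene(s) not in the panel: ", paste(miss, collapse = ", ")))
  x <- panel$expr[genes, , drop = FALSE]
  sds <- apply(x, 1, sd)
  if (any(sds == 0)) {
    warn(paste0(sum(sds == 0), " zero-variance gene(s) excluded from module activity"))
    x <- x[sds > 0, , drop = FALSE]
    if (!nrow(x)) abort("no genes left after removing zero-variance genes")
  }
  z <- t(scale(t(x)))
  tibble(
    sample = colnames(z),
    value = colMeans(z)
  ) %>%
    left_join(panel$samples, by = "sample") %>%
    group_by(.data$condition, .data$time) %>%
    summarise(activity = mean(.data$value), .groups = "drop") %>%
    arrange(.data$condition, .data$time)
}

#' Up/down regulation call for a module at one time point
#'
#' Tests whether the module's member genes are shifted between a
#' condition and the baseline at one time point.  The default test unit
#' is the gene: each member's mean expression difference
#' (condition - baseline at that time) is computed and the differences
#' are tested against zero with a two-sided one-sample t-test.  With
#' `unit = "replicate"`, all gene x replicate values are pooled into a
#' two-sample t-test instead.  The call is `up` or `down` by the sign
#' of the mean difference when p < `p_cut`, else `none`.
#'
#' @param genes Module member genes.
#' @param panel An `expression_panel`.
#' @param condition Non-baseline condition label.
#' @param time Time-point label.
#' @param p_cut Call threshold (default 0.01).
#' @param unit `"gene"` (default) or `"replicate"`.
#' @return A tibble (condition, time, call, p, mean_diff).
#' @export
regulation_call <- function(genes, panel, condition, time, p_cut = 0.01,
                            unit = c("gene", "replicate")) {
  unit <- match.arg(unit)
  genes <- unique(genes)
  s <- panel$samples
  cond_s <- s$sample[s$condition == condition & s$time == time]
  base_s <- s$sample[s$condition == panel$baseline & s$time == time]
  if (!length(base_s)) abort(paste0("no baseline samples at time '", time, "'"))
  none <- tibble(condition = condition, time = time, call = "none",
                 p = NA_real_, mean_diff = NA_real_)
  if (unit == "gene") {
    if (length(genes) < 2 || !length(cond_s)) return(none)
    diffs <- rowMeans(panel$expr[genes, cond_s, drop = FALSE]) -
      rowMeans(panel$expr[genes, base_s, drop = FALSE])
    if (sd(diffs) == 0) return(none %>% mutate(mean_diff = mean(diffs)))
    tt <- t.test(diffs)
  } else {
    a <- as.vector(panel$expr[genes, cond_s, drop = FALSE])
    b <- as.vector(panel$expr[genes, base_s, drop = FALSE])
    if (length(a) < 2 || length(b) < 2) return(none)
    tt <- t.test(a, b)
    diffs <- mean(a) - mean(b)
  }
  md <- mean(diffs)
  call <- if (!is.na(tt$p.value) && tt$p.value < p_cut) {
    if (md > 0) "up" else "down"
  } else "none"
  tibble(condition = condition, time = time, call = call,
         p = tt$p.value, mean_diff = md)
}

#' Correlation between module activity and a phenotype measure
#'
#' Pearson correlation between the module's activity and one phenotype
#' measure across matched (condition, time) cells, restricted to the
#' conditions the module was derived from.  With `fs_invert = TRUE`,
#' measures whose name contains "FS" are first replaced by `1 - x` (so
#' that larger always means worse) and every measure is z-scored.
#'
#' @param activity Tibble (condition, time, activity) from
#'   [module_activity()].
#' @param pheno Phenotype tibble (condition, time, measures...).
#' @param measure Name of the measure column.
#' @param conditions Conditions to restrict to (default: all in
#'   `activity`).
#' @param fs_invert Apply the fractional-shortening inversion +
#'   z-scoring transform.
#' @return The correlation, or `NA` when fewer than 3 cells match.
#' @export
phenotype_correlation <- function(activity, pheno, measure, conditions = NULL,
                                  fs_invert = FALSE) {
  if (!measure %in% names(pheno)) abort(paste0("no phenotype measure '", measure, "'"))
  if (fs_invert) {
    for (mm in setdiff(names(pheno), c("condition", "time"))) {
      x <- pheno[[mm]]
      if (grepl("FS", mm, ignore.case = TRUE)) x <- 1 - x
      pheno[[mm]] <- as.numeric(scale(x))
    }
  }
  joined <- activity %>%
    left_join(pheno %>% select("condition", "time", dplyr::all_of(measure)),
              by = c("condition", "time"))
  if (!is.null(conditions)) joined <- joined %>% filter(.data$condition %in% conditions)
  joined <- joined %>% filter(!is.na(.data[[measure]]) & !is.na(.data$activity))
  if (nrow(joined) < 3) return(NA_real_)
  cor(joined$activity, joined[[measure]])
}

#' Hypergeometric enrichment of modules against reference gene sets
#'
#' Upper-tail hypergeometric test of each (module, set) overlap given
#' the background universe, BH-adjusted across all pairs.  Collection
#' level: specificity = fraction of modules with at least one
#' significant set; sensitivity = fraction of sets with at least one
#' significant module.
#'
#' @param catalog An `mdm_catalog` (or any tibble with `module_id` and
#'   list-column `genes`).
#' @param collection A gene-set collection from [gene_set_collection()].
#' @param alpha Threshold on the adjusted p (default 0.05).
#' @return A tibble (module_id, set, overlap, p, padj, significant) of
#'   class `enrichment_result` with attributes `specificity` and
#'   `sensitivity` (also available via [glance()]).
#' @export
hypergeometric_enrichment <- function(catalog, collection, alpha = 0.05) {
  universe <- collection$universe
  if (!length(universe)) abort("empty gene universe")
  N <- length(universe)
  rows <- list()
  for (i in seq_len(nrow(catalog))) {
    mod <- intersect(catalog$genes[[i]], universe)
    for (sn in names(collection$sets)) {
      gs <- collection$sets[[sn]]
      k <- length(intersect(mod, gs))
      p <- phyper(k - 1, length(gs), N - length(gs), length(mod), lower.tail = FALSE)
      rows[[length(rows) + 1]] <- tibble(
        module_id = catalog$module_id[i], set = sn, overlap = k,
        module_size = length(mod), set_size = length(gs), p = p
      )
    }
  }
  out <- bind_rows(rows)
  if (!nrow(out)) {
    out <- tibble(module_id = character(), set = character(), overlap = integer(),
                  module_size = integer(), set_size = integer(), p = double())
  }
  out$padj <- if (nrow(out)) bh_adjust(out$p) else numeric()
  out$significant <- out$padj <= alpha
  spec <- if (nrow(catalog)) {
    mean(vapply(catalog$module_id, function(m) {
      any(out$significant[out$module_id == m])
    }, logical(1)))
  } else NA_real_
  sens <- if (length(collection$sets)) {
    mean(vapply(names(collection$sets), function(sn) {
      any(out$significant[out$set == sn])
    }, logical(1)))
  } else NA_real_
  class(out) <- c("enrichment_result", class(out))
  attr(out, "specificity") <- spec
  attr(out, "sensitivity") <- sens
  out
}

#' @export
glance.enrichment_result <- function(x, ...) {
  tibble(
    n_pairs = nrow(x), n_significant = sum(x$significant),
    specificity = attr(x, "specificity"), sensitivity = attr(x, "sensitivity")
  )
}

#' One-sided Fisher test comparing two enrichment rates
#'
#' Compares the number of significantly enriched modules between two
#' methods (or two module classes) with a one-sided Fisher's exact test
#' on the 2x2 table (significant / not, method A / method B).
#'
#' @param k_a,n_a Significant count and total for group A.
#' @param k_b,n_b Significant count and total for group B.
#' @param alternative Passed to [stats::fisher.test()]; `"greater"`
#'   tests whether group A is more often significant.
#' @return The Fisher p-value.
#' @export
enrichment_fisher_test <- function(k_a, n_a, k_b, n_b, alternative = "greater") {
  tab <- matrix(c(k_a, n_a - k_a, k_b, n_b - k_b), nrow = 2)
  fisher.test(tab, alternative = alternative)$p.value
}

#' Edge-weight changes of a module between two networks
#'
#' The table behind rewiring displays: all within-module gene pairs
#' whose absolute weight difference between the two networks reaches
#' `min_delta`, with the signed change (second minus first), sorted by
#' decreasing magnitude.
#'
#' @param genes Module member genes.
#' @param dcn_a,dcn_b Two `dcn` objects sharing the module.
#' @param min_delta Minimum absolute weight change to report.
#' @return A tibble (gene_a, gene_b, weight_a, weight_b, delta).
#' @export
edge_delta_table <- function(genes, dcn_a, dcn_b, min_delta = 0) {
  A <- component_adjacency(genes, dcn_a)
  B <- component_adjacency(genes, dcn_b)
  idx <- which(upper.tri(A) & abs(B - A) >= min_delta & (A != 0 | B != 0), arr.ind = TRUE)
  out <- tibble(
    gene_a = rownames(A)[idx[, 1]], gene_b = colnames(A)[idx[, 2]],
    weight_a = A[idx], weight_b = B[idx], delta = B[idx] - A[idx]
  ) %>% arrange(desc(abs(.data$delta)), .data$gene_a, .data$gene_b)
  out
}
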