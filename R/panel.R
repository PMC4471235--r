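# Expression panels and the delimited inputs of the pipeline.
#
# A panel holds one genes x samples matrix spanning every condition
# (baseline included), plus per-sample condition / time / replicate
# labels.  All conditions share the same genes in the same order.

#' Construct an expression panel
#'
#' Bundles a genes-by-samples expression matrix with its sample sheet.
#' Expression values are expected on a normalised, roughly log-like scale
#' (FPKM or similar); correlations are computed on the values as stored.
#'
#' @param expr Numeric matrix, genes in rows (rownames = gene ids),
#'   samples in columns (colnames = sample ids).
#' @param samples Data frame with columns `sample`, `condition`, `time`,
#'   `replicate`, one row per column of `expr`.
#' @param baseline Condition label to treat as the healthy/baseline state.
#' @param impute Impute missing cells with the per-gene mean instead of
#'   failing (`FALSE` by default; the loaders reject missing data).
#'
#' @return An object of class `expression_panel`.
#' @export
expression_panel <- function(expr, samples, baseline, impute = FALSE) {
  if (!is.matrix(expr) || !is.numeric(expr)) {
    abort("`expr` must be a numeric matrix (genes x samples)")
  }
  if (is.null(rownames(expr))) abort("`expr` must have gene ids as rownames")
  samples <- as_tibble(samples)
  need <- c("sample", "condition", "time", "replicate")
  if (!all(need %in% names(samples))) {
    abort(paste("`samples` must have columns:", paste(need, collapse = ", ")))
  }
  samples <- samples %>% mutate(
    sample = as.character(.data$sample),
    condition = as.character(.data$condition),
    time = as.character(.data$time)
  )
  if (is.null(colnames(expr))) colnames(expr) <- samples$sample
  if (!identical(colnames(expr), samples$sample)) {
    samples <- samples[match(colnames(expr), samples$sample), ]
    if (anyNA(samples$sample)) abort("`samples` does not cover every column of `expr`")
  }
  dup <- rownames(expr)[duplicated(rownames(expr))]
  if (length(dup)) {
    abort(paste0("duplicated gene id(s): ", paste(unique(dup), collapse = ", ")))
  }
  if (!is_string(baseline) || !baseline %in% samples$condition) {
    abort("baseline condition missing from the sample sheet")
  }
  if (anyNA(expr)) {
    if (!impute) {
      bad <- which(is.na(expr), arr.ind = TRUE)[1, ]
      abort(sprintf("missing value at gene '%s', sample '%s' (set impute = TRUE for per-gene mean imputation)",
                    rownames(expr)[bad[1]], colnames(expr)[bad[2]]))
    }
    for (i in which(rowSums(is.na(expr)) > 0)) {
      expr[i, is.na(expr[i, ])] <- mean(expr[i, ], na.rm = TRUE)
    }
  }
  non_base <- setdiff(unique(samples$condition), baseline)
  n_per <- table(samples$condition)
  small <- non_base[n_per[non_base] < 3]
  if (length(small)) {
    abort(paste0("condition(s) with fewer than 3 samples: ", paste(small, collapse = ", ")))
  }
  structure(
    list(expr = expr, samples = samples, baseline = baseline),
    class = "expression_panel"
  )
}

#' @exportS3Method base::print
print.expression_panel <- function(x, ...) {
  cat("<expression_panel> ", nrow(x$expr), " genes x ", ncol(x$expr), " samples\n", sep = "")
  cat("  baseline: ", x$baseline, "\n", sep = "")
  cat("  conditions: ", paste(unique(x$samples$condition), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Non-baseline condition labels of a panel
#' @param panel An `expression_panel`.
#' @return Character vector of disease condition labels.
#' @export
panel_conditions <- function(panel) {
  setdiff(unique(panel$samples$condition), panel$baseline)
}

#' Expression submatrix for one condition
#' @param panel An `expression_panel`.
#' @param condition Condition label.
#' @return Genes x samples matrix for that condition's samples.
#' @export
condition_matrix <- function(panel, condition) {
  keep <- panel$samples$sample[panel$samples$condition == condition]
  if (!length(keep)) abort(paste0("no samples for condition '", condition, "'"))
  panel$expr[, keep, drop = FALSE]
}

meta_tags <- c("baseline", "condition", "time", "replicate")

#' Write / read an expression panel as tab-separated text
#'
#' The format is plain TSV with leading `#`-prefixed metadata rows
#' (`#baseline`, `#condition`, `#time`, `#replicate`) aligning with the
#' sample columns, then a header row (`gene` + sample ids) and one row
#' per gene.  Chosen for diffability and hand-editable fixtures.
#'
#' @param panel An `expression_panel`.
#' @param path File path.
#' @return `write_expression_panel` returns `path` invisibly;
#'   `read_expression_panel` returns an `expression_panel`.
#' @export
write_expression_panel <- function(panel, path) {
  con <- file(path, "w")
  on.exit(close(con))
  s <- panel$samples
  writeLines(c(
    paste0("#baseline\t", panel$baseline),
    paste(c("#condition", s$condition), collapse = "\t"),
    paste(c("#time", s$time), collapse = "\t"),
    paste(c("#replicate", s$replicate), collapse = "\t"),
    paste(c("gene", s$sample), collapse = "\t")
  ), con)
  body <- cbind(gene = rownames(panel$expr),
                matrix(format(panel$expr, digits = 15, trim = TRUE, scientific = FALSE),
                       nrow = nrow(panel$expr)))
  writeLines(apply(body, 1, paste, collapse = "\t"), con)
  invisible(path)
}

#' @rdname write_expression_panel
#' @param impute Impute missing cells with per-gene means (default: reject).
#' @export
read_expression_panel <- function(path, impute = FALSE) {
  lines <- readLines(path)
  meta_idx <- grep("^#", lines)
  if (!length(meta_idx)) abort("no metadata rows ('#...') found")
  meta <- strsplit(lines[meta_idx], "\t", fixed = TRUE)
  names(meta) <- sub("^#", "", vapply(meta, `[[`, "", 1))
  missing_tags <- setdiff(meta_tags, names(meta))
  if (length(missing_tags)) {
    abort(paste0("missing metadata row(s): ", paste0("#", missing_tags, collapse = ", ")))
  }
  header <- strsplit(lines[max(meta_idx) + 1], "\t", fixed = TRUE)[[1]]
  sample_ids <- header[-1]
  body <- lines[-seq_len(max(meta_idx) + 1)]
  body <- body[nzchar(body)]
  cells <- strsplit(body, "\t", fixed = TRUE)
  genes <- vapply(cells, `[[`, "", 1)
  vals <- lapply(seq_along(cells), function(i) {
    v <- suppressWarnings(as.numeric(cells[[i]][-1]))
    bad <- which(is.na(v) & cells[[i]][-1] != "NA")
    if (length(bad)) {
      abort(sprintf("non-numeric cell at row %d (gene '%s'), column '%s'",
                    i, genes[i], sample_ids[bad[1]]))
    }
    v
  })
  expr <- do.call(rbind, vals)
  rownames(expr) <- genes
  colnames(expr) <- sample_ids
  samples <- tibble(
    sample = sample_ids,
    condition = meta$condition[-1],
    time = meta$time[-1],
    replicate = as.integer(meta$replicate[-1])
  )
  expression_panel(expr, samples, baseline = meta$baseline[2], impute = impute)
}

#' Read / write differential-expression p-value tables
#'
#' TSV with a `gene` column and one column of p-values per non-baseline
#' condition.  P-values must lie in (0, 1]; exact zeros are rejected and
#' values below 1e-300 are clamped (with a warning) so the edge-weight
#' logarithms stay finite.
#'
#' @param path File path.
#' @return A tibble with column `gene` plus one numeric column per condition.
#' @export
read_de_pvalues <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  validate_de_pvalues(tab)
}

validate_de_pvalues <- function(tab) {
  tab <- as_tibble(tab)
  if (!"gene" %in% names(tab)) abort("p-value table needs a 'gene' column")
  conds <- setdiff(names(tab), "gene")
  if (!length(conds)) abort("p-value table has no condition columns")
  for (cc in conds) {
    p <- tab[[cc]]
    if (!is.numeric(p)) abort(paste0("column '", cc, "' is not numeric"))
    if (anyNA(p)) abort(paste0("missing p-value(s) in column '", cc, "'"))
    if (any(p <= 0)) abort(paste0("p-values must be > 0 (zero found in '", cc, "')"))
    if (any(p > 1)) abort(paste0("p-values must be <= 1 ('", cc, "')"))
    if (any(p < 1e-300)) {
      warn(paste0("p-values below 1e-300 clamped in '", cc, "'"))
      tab[[cc]] <- pmax(p, 1e-300)
    }
  }
  if (anyDuplicated(tab$gene)) abort("duplicated gene ids in p-value table")
  tab
}

#' @rdname read_de_pvalues
#' @param de Tibble as returned by [read_de_pvalues()].
#' @export
write_de_pvalues <- function(de, path) {
  readr::write_tsv(de, path, progress = FALSE)
  invisible(path)
}

#' Read / write phenotype tables
#'
#' TSV with `condition` and `time` columns plus one numeric column per
#' phenotype measure (one row per condition/time cell).
#'
#' @param path File path.
#' @return A tibble.
#' @export
read_phenotypes <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (!all(c("condition", "time") %in% names(tab))) {
    abort("phenotype table needs 'condition' and 'time' columns")
  }
  measures <- setdiff(names(tab), c("condition", "time"))
  for (mm in measures) {
    if (!is.numeric(tab[[mm]])) abort(paste0("phenotype measure '", mm, "' is not numeric"))
  }
  tab %>% mutate(condition = as.character(.data$condition), time = as.character(.data$time))
}

#' @rdname read_phenotypes
#' @param pheno Tibble as returned by [read_phenotypes()].
#' @export
write_phenotypes <- function(pheno, path) {
  readr::write_tsv(pheno, path, progress = FALSE)
  invisible(path)
}

#' Read a gene-set collection (GMT)
#'
#' Parses GMT via \pkg{fgsea} and restricts every set to the given gene
#' universe; genes outside the universe are dropped with a warning, and
#' sets left empty are removed.
#'
#' @param path GMT file path.
#' @param universe Character vector of background gene ids.
#' @return A list with elements `sets` (named list of character vectors)
#'   and `universe`.
#' @export
read_gene_sets <- function(path, universe) {
  if (!requireNamespace("fgsea", quietly = TRUE)) {
    abort("reading GMT files requires the 'fgsea' package")
  }
  sets <- fgsea::gmtPathways(path)
  gene_set_collection(sets, universe)
}

#' @rdname read_gene_sets
#' @param sets Named list of character vectors.
#' @export
gene_set_collection <- function(sets, universe) {
  if (!length(universe)) abort("empty gene universe")
  universe <- unique(as.character(universe))
  dropped <- 0L
  sets <- lapply(sets, function(g) {
    keep <- intersect(unique(g), universe)
    dropped <<- dropped + (length(unique(g)) - length(keep))
    keep
  })
  if (dropped > 0) warn(paste0(dropped, " gene(s) outside the universe dropped from gene sets"))
  sets <- sets[lengths(sets) > 0]
  list(sets = sets, universe = universe)
}
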