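# Planted-truth synthetic data: multi-condition expression panels with
# condition-subset-specific co-expressed + differentially expressed
# modules, optional connectivity rewiring, large background
# co-expression blocks that switch on and off by condition (keeping the
# networks dense and connected, the regime the threshold selection
# presumes), and a phenotype coupled to the activity of the rewired
# modules.
#
# The generative model is a single-factor Gaussian per module and
# condition: member genes share a latent factor (loading beta), so the
# within-module correlation is beta^2 / (beta^2 + sigma^2), and get a
# per-time mean shift against baseline (the differential-expression
# effect, in units of the noise sd).  Factors are mean-centered within
# each condition, so the realised differential expression of a module
# equals its specified effect instead of wobbling coherently with the
# factor's sample mean.  Expression values live on a
# log-like scale; p-values come from per-gene Welch t-tests against
# baseline, standing in for an external differential-expression tool.

#' Specify a planted module
#'
#' @param size Number of member genes.
#' @param subset Character vector of condition labels the module is
#'   planted in.
#' @param loading Latent-factor loading (co-expression strength);
#'   pairwise correlation is `loading^2 / (loading^2 + noise_sd^2)`.
#' @param effect Numeric vector of per-time-point mean shifts vs
#'   baseline, in noise-sd units (recycled to the number of time
#'   points).
#' @param rewired Should the module's connectivity differ between the
#'   conditions of `subset`?  Rewired modules split their members into
#'   two latent sub-factors with a partition that changes from
#'   condition to condition, so edges present in one network are absent
#'   in the next.
#' @return A module specification (one-row tibble).
#' @export
planted_module <- function(size, subset, loading = 3, effect = 2.5, rewired = FALSE) {
  tibble(size = as.integer(size), subset = list(as.character(subset)),
         loading = loading, effect = list(effect), rewired = rewired)
}

#' Define the ground truth of a synthetic study
#'
#' @param n_genes Total genes.
#' @param conditions Non-baseline condition labels.
#' @param baseline Baseline condition label.
#' @param n_time,n_rep Time points and replicates per condition.
#' @param modules Module specifications, rows from [planted_module()].
#' @param bg_group_size Size of the background co-expression blocks;
#'   the genes not in any planted module are partitioned into such
#'   blocks.  Real co-expression at |r| >= 0.8 comes in large
#'   correlated blocks, and dense connected background is what keeps
#'   the degree-preserving and random-gene-set nulls non-degenerate.
#' @param bg_on_prob Probability that a background block is
#'   co-expressed in a given condition (independently per condition),
#'   so background connectivity rewires between conditions.
#' @param bg_loading Latent-factor loading of background blocks.
#' @param n_marker,marker_effect Number of strongly differentially
#'   expressed singleton "marker" genes (no co-expression, shifted by
#'   `marker_effect` noise-sd units in every non-baseline condition).
#'   Disease transcriptomes contain many such genes; they pin each
#'   network's `max |log p|` weight normaliser, which is otherwise an
#'   unstable extreme-value statistic.
#' @param noise_sd Independent noise sd (the expression scale unit).
#' @param mu_mean,mu_sd Distribution of per-gene baseline means.
#' @param pheno_noise_sd Noise sds of the phenotype measures (one
#'   measure per entry); measures are sums of the rewired modules'
#'   realised activities plus this noise.
#' @return A `synthetic_truth` object.
#' @export
synthetic_truth <- function(n_genes, conditions, baseline = "base",
                            n_time = 2, n_rep = 3,
                            modules = NULL,
                            bg_group_size = 15, bg_on_prob = 0.7, bg_loading = 2.5,
                            n_marker = 20, marker_effect = 8,
                            noise_sd = 1, mu_mean = 6, mu_sd = 1.5,
                            pheno_noise_sd = c(0.3, 0.6, 1.0)) {
  modules <- if (is.null(modules)) {
    tibble(size = integer(), subset = list(), loading = double(),
           effect = list(), rewired = logical())
  } else {
    as_tibble(modules)
  }
  if (sum(modules$size) > n_genes) abort("planted modules need more genes than available")
  bad <- setdiff(unique(unlist(modules$subset)), conditions)
  if (length(bad)) abort(paste0("module subset condition(s) not in `conditions`: ", paste(bad, collapse = ", ")))
  genes <- sprintf("g%04d", seq_len(n_genes))
  at <- 0L
  modules$name <- if (nrow(modules)) sprintf("M%d", seq_len(nrow(modules))) else character()
  modules$genes <- lapply(seq_len(nrow(modules)), function(i) {
    g <- genes[(at + 1L):(at + modules$size[i])]
    at <<- at + modules$size[i]
    g
  })
  modules$effect <- lapply(modules$effect, function(e) rep_len(e, n_time))
  n_free <- n_genes - sum(modules$size)
  if (n_marker > n_free) abort("not enough genes left for marker genes")
  marker_genes <- genes[sum(modules$size) + seq_len(n_marker)]
  structure(
    list(n_genes = n_genes, genes = genes,
         conditions = as.character(conditions), baseline = baseline,
         n_time = n_time, n_rep = n_rep, modules = modules,
         marker_genes = marker_genes, marker_effect = marker_effect,
         bg_group_size = bg_group_size, bg_on_prob = bg_on_prob,
         bg_loading = bg_loading, noise_sd = noise_sd,
         mu_mean = mu_mean, mu_sd = mu_sd,
         pheno_noise_sd = pheno_noise_sd),
    class = "synthetic_truth"
  )
}

#' Zero out all planted signal
#'
#' Returns a copy of the truth with every module loading and effect and
#' the background-group loading set to 0: pure independent noise, the
#' null condition for calibration runs.
#'
#' @param truth A `synthetic_truth`.
#' @return A `synthetic_truth` with no signal.
#' @export
null_truth <- function(truth) {
  truth$modules$loading <- rep(0, nrow(truth$modules))
  truth$modules$effect <- lapply(truth$modules$effect, function(e) e * 0)
  truth$bg_loading <- 0
  truth$marker_effect <- 0
  truth
}

#' Preset study designs
#'
#' * `tiny`: 60 genes, 3 conditions x 2 time points x 3 replicates,
#'   three 8-gene modules (one per level: planted in all three
#'   conditions, in two, and in one).
#' * `small`: 300 genes, 3 conditions x 4 time points x 4 replicates
#'   (the 4x4 sampling design of a longitudinal disease study), three
#'   10-gene modules (levels 3 / 2 / 1).
#' * `paper-shaped`: 2000 genes, 3 conditions x 4 time points x 4
#'   replicates, three 20-gene modules -- a desk-scale stand-in for a
#'   transcriptome-wide study.
#' * `rewired-pair`: 200 genes, 2 conditions x 4 time points x 32
#'   replicates, four rewired and two static 12-gene shared modules
#'   (rewired time profiles are ramps, static profiles are U-shaped
#'   contrasts orthogonal to them); the
#'   phenotype tracks the rewired modules' activity.  The deep
#'   replication gives correlation estimates precise enough that the
#'   static modules' edge sets are stable at the 0.8 threshold (~99.9%
#'   pair retention), so the planted contrast is connectivity rewiring
#'   and nothing else.
#'
#' @param scale One of `"tiny"`, `"small"`, `"paper-shaped"`,
#'   `"rewired-pair"`.
#' @return A `synthetic_truth`.
#' @export
default_fixture <- function(scale = c("tiny", "small", "paper-shaped", "rewired-pair")) {
  scale <- match.arg(scale)
  c3 <- c("c1", "c2", "c3")
  switch(scale,
    tiny = synthetic_truth(
      60, c3, n_time = 2, n_rep = 3, bg_group_size = 12, n_marker = 6,
      modules = bind_rows(
        planted_module(8, c3, loading = 4, effect = c(3, 4)),
        planted_module(8, c("c1", "c2"), loading = 4, effect = c(-3, -4)),
        planted_module(8, "c1", loading = 4, effect = c(3.5, 3.5))
      )
    ),
    small = synthetic_truth(
      300, c3, n_time = 4, n_rep = 4, bg_group_size = 15,
      modules = bind_rows(
        planted_module(10, c3, effect = c(2.5, 3, 3.5, 4)),
        planted_module(10, c("c1", "c2"), effect = -c(4, 3.5, 3, 2.5)),
        planted_module(10, "c1", effect = c(3.5, 3.5, 3.5, 3.5))
      )
    ),
    `paper-shaped` = synthetic_truth(
      2000, c3, n_time = 4, n_rep = 4, bg_group_size = 50,
      modules = bind_rows(
        planted_module(20, c3, effect = c(1.5, 2, 2.5, 3)),
        planted_module(20, c("c1", "c2"), effect = -c(3, 2.5, 2, 1.5)),
        planted_module(20, "c1", effect = c(2.5, 2.5, 2.5, 2.5))
      )
    ),
    `rewired-pair` = synthetic_truth(
      200, c("c1", "c2"), n_time = 4, n_rep = 32, bg_group_size = 15,
      marker_effect = 4,
      modules = bind_rows(
        planted_module(12, c("c1", "c2"), loading = 4, effect = c(2, 4, 6, 8), rewired = TRUE),
        planted_module(12, c("c1", "c2"), loading = 4, effect = c(3, 4, 6, 7), rewired = TRUE),
        planted_module(12, c("c1", "c2"), loading = 4, effect = c(2, 5, 6, 9), rewired = TRUE),
        planted_module(12, c("c1", "c2"), loading = 4, effect = c(3, 5, 7, 8), rewired = TRUE),
        planted_module(12, c("c1", "c2"), loading = 4, effect = c(6, 3, 3, 6)),
        planted_module(12, c("c1", "c2"), loading = 4, effect = c(3, 6, 6, 3))
      )
    )
  )
}

# Partition labels (0/1) of module members for rewired modules; the
# pattern depends on the condition's position within the module's
# subset, so consecutive conditions use different partitions.
rewire_partition <- function(size, pos) {
  i <- seq_len(size) - 1L
  switch(((pos - 1L) %% 3L) + 1L,
    as.integer(i >= size / 2),      # halves
    i %% 2L,                        # interleaved
    (i + i %/% 2L) %% 2L            # paired blocks
  )
}

welch_p <- function(X, Y) {
  nx <- ncol(X); ny <- ncol(Y)
  mx <- rowMeans(X); my <- rowMeans(Y)
  vx <- rowSums((X - mx)^2) / (nx - 1)
  vy <- rowSums((Y - my)^2) / (ny - 1)
  se2 <- vx / nx + vy / ny
  t <- (mx - my) / sqrt(se2)
  df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  p <- 2 * pt(-abs(t), df)
  p[se2 == 0] <- ifelse(mx[se2 == 0] == my[se2 == 0], 1, 1e-300)
  pmin(pmax(p, 1e-300), 1)
}

#' Simulate a synthetic dataset from a ground truth
#'
#' Generates the expression panel, the per-condition differential-
#' expression p-value table (internal Welch t-test vs baseline; any
#' external table can replace it), and the phenotype table.  The same
#' truth and seed always produce the identical dataset.
#'
#' @param truth A `synthetic_truth`.
#' @param seed Seed for the simulation (optional but recommended).
#' @return A `synthetic_dataset`: list with `panel`
#'   (`expression_panel`), `de` (tibble gene + one column per
#'   condition), `phenotype` (tibble), and `truth`.
#' @export
simulate_panel <- function(truth, seed = NULL) {
  local_seed(seed, {
    genes <- truth$genes
    n <- truth$n_genes
    all_conds <- c(truth$baseline, truth$conditions)
    times <- paste0("t", seq_len(truth$n_time))
    samples <- tidyr::expand_grid(condition = all_conds, time = times,
                                  replicate = seq_len(truth$n_rep)) %>%
      mutate(sample = paste0(.data$condition, "_", .data$time, "_r", .data$replicate)) %>%
      select("sample", "condition", "time", "replicate")
    S <- nrow(samples)

    mu <- rnorm(n, truth$mu_mean, truth$mu_sd)
    expr <- matrix(rnorm(n * S, 0, truth$noise_sd), n, S,
                   dimnames = list(genes, samples$sample)) + mu

    # strong singleton marker genes: shifted in every disease condition
    if (length(truth$marker_genes) && truth$marker_effect != 0) {
      mcols <- samples$condition != truth$baseline
      expr[truth$marker_genes, mcols] <- expr[truth$marker_genes, mcols] +
        truth$marker_effect * truth$noise_sd
    }

    # background co-expression blocks over the remaining genes
    module_genes <- unlist(truth$modules$genes)
    bg <- setdiff(genes, c(module_genes, truth$marker_genes))
    if (length(bg) >= 2 && truth$bg_loading != 0 && truth$bg_group_size >= 2) {
      grp <- split(bg, ceiling(seq_along(bg) / truth$bg_group_size))
      grp <- grp[lengths(grp) >= 2]
      on <- matrix(runif(length(grp) * length(all_conds)) < truth$bg_on_prob,
                   length(grp), length(all_conds),
                   dimnames = list(NULL, all_conds))
      for (h in seq_along(grp)) {
        f <- rnorm(S)
        for (cc in all_conds) {
          if (!on[h, cc]) next
          cols <- samples$condition == cc
          fc <- f[cols] - mean(f[cols])
          expr[grp[[h]], cols] <- expr[grp[[h]], cols] +
            truth$bg_loading * rep(fc, each = length(grp[[h]]))
        }
      }
    }

    # planted modules: shared latent factor + per-time mean shift
    for (i in seq_len(nrow(truth$modules))) {
      m <- truth$modules[i, ]
      members <- m$genes[[1]]
      subset_i <- m$subset[[1]]
      for (pos in seq_along(subset_i)) {
        cc <- subset_i[pos]
        cols <- which(samples$condition == cc)
        if (m$rewired) {
          lab <- rewire_partition(length(members), pos)
          f <- matrix(rnorm(2 * length(cols)), 2)
          f <- f - rowMeans(f)
          expr[members, cols] <- expr[members, cols] +
            m$loading * f[lab + 1L, , drop = FALSE]
        } else {
          f <- rnorm(length(cols))
          f <- f - mean(f)
          expr[members, cols] <- expr[members, cols] +
            m$loading * rep(f, each = length(members))
        }
        shift <- m$effect[[1]][match(samples$time[cols], times)] * truth$noise_sd
        expr[members, cols] <- expr[members, cols] + rep(shift, each = length(members))
      }
    }

    panel <- expression_panel(expr, samples, baseline = truth$baseline)

    base_cols <- samples$sample[samples$condition == truth$baseline]
    de <- tibble(gene = genes)
    for (cc in truth$conditions) {
      cols <- samples$sample[samples$condition == cc]
      de[[cc]] <- welch_p(expr[, cols, drop = FALSE], expr[, base_cols, drop = FALSE])
    }

    # phenotype: sum of the rewired (dynamic) modules' realised
    # activities per (condition, time) cell, plus measure-specific noise
    cells <- samples %>% dplyr::distinct(.data$condition, .data$time)
    dyn <- which(truth$modules$rewired & truth$modules$loading != 0)
    signal <- numeric(nrow(cells))
    for (i in dyn) {
      act <- module_activity(truth$modules$genes[[i]], panel)
      signal <- signal + act$activity[match(
        paste(cells$condition, cells$time),
        paste(act$condition, act$time)
      )]
    }
    pheno <- cells
    for (j in seq_along(truth$pheno_noise_sd)) {
      pheno[[paste0("pheno", j)]] <- signal + rnorm(nrow(cells), 0, truth$pheno_noise_sd[j])
    }

    structure(list(panel = panel, de = de, phenotype = pheno, truth = truth),
              class = "synthetic_dataset")
  })
}

#' Write a synthetic dataset to a directory
#'
#' Emits `expression.tsv`, `de_pvalues.tsv`, `phenotypes.tsv` and a
#' JSON manifest of every planted parameter (`truth.json`).
#'
#' @param sim A `synthetic_dataset` from [simulate_panel()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_synthetic_dataset <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_expression_panel(sim$panel, file.path(dir, "expression.tsv"))
  write_de_pvalues(sim$de, file.path(dir, "de_pvalues.tsv"))
  write_phenotypes(sim$phenotype, file.path(dir, "phenotypes.tsv"))
  truth <- sim$truth
  manifest <- list(
    n_genes = truth$n_genes, conditions = truth$conditions,
    baseline = truth$baseline, n_time = truth$n_time, n_rep = truth$n_rep,
    bg_group_size = truth$bg_group_size, bg_on_prob = truth$bg_on_prob,
    bg_loading = truth$bg_loading, noise_sd = truth$noise_sd,
    n_marker = length(truth$marker_genes), marker_effect = truth$marker_effect,
    marker_genes = truth$marker_genes,
    modules = lapply(seq_len(nrow(truth$modules)), function(i) {
      m <- truth$modules[i, ]
      list(name = m$name, genes = m$genes[[1]], subset = m$subset[[1]],
           loading = m$loading, effect = m$effect[[1]], rewired = m$rewired)
    })
  )
  jsonlite::write_json(manifest, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' @exportS3Method base::print
print.synthetic_truth <- function(x, ...) {
  cat("<synthetic_truth> ", x$n_genes, " genes, baseline '", x$baseline,
      "' + ", length(x$conditions), " condition(s), ",
      x$n_time, " time x ", x$n_rep, " rep\n", sep = "")
  if (nrow(x$modules)) {
    for (i in seq_len(nrow(x$modules))) {
      m <- x$modules[i, ]
      cat("  ", m$name, ": ", m$size, " genes in {",
          paste(m$subset[[1]], collapse = ","), "}",
          if (m$rewired) " [rewired]" else "", "\n", sep = "")
    }
  }
  invisible(x)
}
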