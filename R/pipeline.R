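# End-to-end pipeline: load inputs, build networks, search modules,
# score significance and dynamics, write the report.

#' Assemble and validate a pipeline configuration
#'
#' @param expression Path to the expression panel TSV.
#' @param de_pvalues Path to the differential-expression p-value TSV.
#' @param delta Correlation threshold (required; 0.8 is the usual
#'   operating point).
#' @param out_dir Output directory for the report.
#' @param seed Run seed; every stochastic stage derives its stream from
#'   it, so identical configurations reproduce byte-identical module
#'   tables.
#' @param phenotypes,gene_sets Optional paths (phenotype TSV, GMT).
#' @param delta_grid Optional grid; when given, `delta` is chosen by
#'   [select_delta()] and the configured `delta` is ignored.
#' @param fraction,min_size,jaccard,subsets Search parameters (see
#'   [discover_mdms()]).
#' @param n_rand,alpha,swaps_per_edge Significance parameters (see
#'   [mdm_significance()]).
#' @param mcds_alpha,norm,pairing Dynamics parameters (see
#'   [mcds_significance()], [mcds()]).
#' @param q_cut,conditioning_cap,log_transform Screen parameters (see
#'   [correlation_screen()]).
#' @param p_cut Regulation-call threshold (see [regulation_call()]).
#' @param fs_invert Phenotype transform flag (see
#'   [phenotype_correlation()]).
#' @return A validated config list of class `mdm_config`.
#' @export
pipeline_config <- function(expression, de_pvalues, delta = NULL, out_dir = NULL,
                            seed = 1L, phenotypes = NULL, gene_sets = NULL,
                            delta_grid = NULL, fraction = 0.10, min_size = 5,
                            jaccard = 0.5, subsets = "all", n_rand = 100,
                            alpha = 0.05, swaps_per_edge = 10,
                            mcds_alpha = 0.05, norm = "spectral",
                            pairing = "allpairs", q_cut = 0.2, conditioning_cap = 200,
                            log_transform = FALSE, p_cut = 0.01,
                            fs_invert = FALSE) {
  cfg <- as.list(environment())
  validate_config(cfg)
}

validate_config <- function(cfg) {
  for (field in c("expression", "de_pvalues")) {
    if (is.null(cfg[[field]]) || !is_string(cfg[[field]])) {
      abort(paste0("config field '", field, "' is required"))
    }
  }
  if (is.null(cfg$delta) && is.null(cfg$delta_grid)) {
    abort("config must set 'delta' (or 'delta_grid')")
  }
  if (!is.null(cfg$delta) && (cfg$delta <= 0 || cfg$delta >= 1)) {
    abort("'delta' must be in (0, 1)")
  }
  if (is.null(cfg$seed)) abort("config must set 'seed'")
  structure(cfg, class = "mdm_config")
}

#' Read a pipeline configuration from YAML
#' @param path YAML file; keys as in [pipeline_config()].
#' @return A validated config list.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) abort(paste0("unknown config key(s): ", paste(unknown, collapse = ", ")))
  do.call(pipeline_config, raw)
}

#' Run the full discovery pipeline
#'
#' Network construction, module search over all network subsets,
#' permutation significance, level assignment, dynamics scoring of the
#' shared modules, module statistics, and the report.  All randomness
#' derives from the configured seed.
#'
#' @param config An `mdm_config` from [pipeline_config()] /
#'   [read_pipeline_config()].
#' @return Invisibly, a list with the panel, networks, module catalog,
#'   dynamics table, activity/regulation/correlation tables, and the
#'   output directory (when `out_dir` is set).
#' @export
run_pipeline <- function(config) {
  config <- validate_config(config)
  panel <- stop_stage("load", read_expression_panel(config$expression))
  de <- stop_stage("load", read_de_pvalues(config$de_pvalues))
  miss <- setdiff(rownames(panel$expr), de$gene)
  if (length(miss)) {
    abort(paste0("[load] p-values missing for ", length(miss), " panel gene(s)"))
  }
  pheno <- if (!is.null(config$phenotypes)) stop_stage("load", read_phenotypes(config$phenotypes))
  gsets <- if (!is.null(config$gene_sets)) {
    stop_stage("load", read_gene_sets(config$gene_sets, rownames(panel$expr)))
  }

  delta <- config$delta
  if (!is.null(config$delta_grid)) {
    delta <- stop_stage("select-delta",
      select_delta(panel, config$delta_grid, q_cut = config$q_cut,
                   conditioning_cap = config$conditioning_cap,
                   log_transform = config$log_transform)$delta)
  }

  dcns <- stop_stage("build-dcn",
    build_dcns(panel, de, delta, q_cut = config$q_cut,
               conditioning_cap = config$conditioning_cap,
               log_transform = config$log_transform))

  mods <- stop_stage("find-modules",
    find_modules(dcns, fraction = config$fraction, min_size = config$min_size,
                 jaccard = config$jaccard, subsets = config$subsets,
                 n_rand = config$n_rand, alpha = config$alpha,
                 swaps_per_edge = config$swaps_per_edge,
                 seed = derive_seed(config$seed, 1)))

  dyn <- stop_stage("score-dynamics", {
    tab <- mcds_table(mods, dcns, norm = config$norm, pairing = config$pairing)
    if (nrow(tab)) {
      mcds_significance(tab, dcns, n_rand = config$n_rand,
                        alpha = config$mcds_alpha,
                        seed = derive_seed(config$seed, 2))
    } else tab
  })

  stats <- stop_stage("module-stats", {
    act <- bind_rows(lapply(seq_len(nrow(mods)), function(i) {
      module_activity(mods$genes[[i]], panel) %>%
        mutate(module_id = mods$module_id[i])
    }))
    pc <- NULL
    if (!is.null(pheno) && nrow(mods)) {
      measures <- setdiff(names(pheno), c("condition", "time"))
      pc <- bind_rows(lapply(seq_len(nrow(mods)), function(i) {
        a <- act %>% filter(.data$module_id == mods$module_id[i])
        tibble(module_id = mods$module_id[i], measure = measures,
               correlation = vapply(measures, function(mm) {
                 phenotype_correlation(a, pheno, mm,
                                       conditions = mods$conditions[[i]],
                                       fs_invert = config$fs_invert)
               }, numeric(1)))
      }))
    }
    enr <- if (!is.null(gsets) && nrow(mods)) {
      hypergeometric_enrichment(mods, gsets, alpha = config$alpha)
    }
    list(activity = act, phenotype_correlation = pc, enrichment = enr)
  })

  out_dir <- config$out_dir
  if (!is.null(out_dir)) {
    stop_stage("report",
      write_mdm_report(mods, dyn, out_dir, dcns = dcns, config = config))
    if (!is.null(stats$activity) && nrow(stats$activity)) {
      readr::write_tsv(stats$activity, file.path(out_dir, "module_activity.tsv"), progress = FALSE)
    }
    if (!is.null(stats$phenotype_correlation)) {
      readr::write_tsv(stats$phenotype_correlation,
                       file.path(out_dir, "phenotype_correlation.tsv"), progress = FALSE)
    }
    if (!is.null(stats$enrichment)) {
      readr::write_tsv(stats$enrichment, file.path(out_dir, "enrichment.tsv"), progress = FALSE)
    }
  }

  invisible(list(panel = panel, dcns = dcns, delta = delta, modules = mods,
                 dynamics = dyn, stats = stats, out_dir = out_dir))
}

mods_with_dynamics <- function(mdms, mcds) {
  tab <- mdms %>% mutate(
    conditions = vapply(.data$conditions, subset_label, ""),
    genes = vapply(.data$genes, paste, "", collapse = ",")
  )
  for (col in c("p", "padj", "significant")) {
    if (!col %in% names(tab)) tab[[col]] <- NA
  }
  tab <- tab %>% select("module_id", "level", "conditions", "n_genes", "genes",
                        "H", "p", "padj", "significant")
  if (!is.null(mcds) && nrow(mcds)) {
    dtab <- as_tibble(mcds) %>%
      select("module_id", "mcds", mcds_p = "p", mcds_padj = "padj", "dynamic")
    tab <- tab %>% left_join(dtab, by = "module_id")
  } else {
    tab$mcds <- NA_real_; tab$mcds_p <- NA_real_
    tab$mcds_padj <- NA_real_; tab$dynamic <- NA
  }
  tab
}

#' Write / read the module report
#'
#' `write_mdm_report` emits a delimited module table (`modules.tsv`),
#' one weighted edge-list file per (module, network) pair under
#' `edges/`, and a JSON run manifest with the configuration, seed and
#' library versions.  `read_mdm_report` parses the table back into the
#' same records.
#'
#' @param mdms An `mdm_catalog`.
#' @param mcds An `mcds_table` with significance columns (or `NULL`).
#' @param path Output directory (created if needed).
#' @param dcns Networks, for the per-module edge lists (optional).
#' @param config The run configuration stored in the manifest.
#' @return The directory (write) or a list with `modules` and
#'   `manifest` (read).
#' @export
write_mdm_report <- function(mdms, mcds, path, dcns = NULL, config = NULL) {
  ok <- dir.create(path, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(path)) abort(paste0("cannot create output directory '", path, "'"))
  tab <- mods_with_dynamics(mdms, mcds)
  readr::write_tsv(tab, file.path(path, "modules.tsv"), progress = FALSE)
  if (!is.null(dcns) && nrow(mdms)) {
    edir <- file.path(path, "edges")
    dir.create(edir, showWarnings = FALSE)
    conds <- vapply(dcns, `[[`, "", "condition")
    names(dcns) <- conds
    for (i in seq_len(nrow(mdms))) {
      for (cc in mdms$conditions[[i]]) {
        genes <- mdms$genes[[i]]
        e <- dcns[[cc]]$edges %>%
          filter(.data$from %in% genes & .data$to %in% genes)
        readr::write_tsv(e, file.path(edir, paste0(
          gsub("[^A-Za-z0-9._-]", "_", mdms$module_id[i]), "__", cc, ".tsv")),
          progress = FALSE)
      }
    }
  }
  manifest <- list(
    package = "mdmnet",
    version = as.character(utils::packageVersion("mdmnet")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    created = "run manifest",
    config = if (!is.null(config)) unclass(config),
    n_modules = nrow(mdms)
  )
  jsonlite::write_json(manifest, file.path(path, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE, null = "null")
  invisible(path)
}

#' @rdname write_mdm_report
#' @export
read_mdm_report <- function(path) {
  tab <- readr::read_tsv(file.path(path, "modules.tsv"), show_col_types = FALSE,
                         progress = FALSE,
                         col_types = readr::cols(
                           module_id = readr::col_character(),
                           level = readr::col_integer(),
                           conditions = readr::col_character(),
                           n_genes = readr::col_integer(),
                           genes = readr::col_character(),
                           significant = readr::col_logical(),
                           dynamic = readr::col_logical(),
                           .default = readr::col_double()
                         ))
  tab <- tab %>% mutate(
    conditions = strsplit(.data$conditions, "+", fixed = TRUE),
    genes = strsplit(.data$genes, ",", fixed = TRUE)
  )
  manifest <- jsonlite::read_json(file.path(path, "manifest.json"))
  list(modules = tab, manifest = manifest)
}
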