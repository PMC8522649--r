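# Pipeline orchestration: validated configuration, staged execution
# (simulate -> harmonize -> z-score -> MS -> regional MS -> T map -> PLS ->
# threshold -> enrichment), TSV outputs, and a machine-readable run manifest.

#' Default pipeline configuration
#'
#' Flat named list of every pipeline switch with its default. Thresholds:
#' FDR 0.05 for the regional map, DE screen at p < 0.01 and |log2 FC| > 1,
#' pSI 0.05, bootstrap B = 1000, permutation B_perm = 1000, Z threshold
#' derived from the gene count at run time (4.72 for 20,737 genes).
#'
#' @param ... overrides of individual keys.
#' @return named list.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    mode = "simulate",          # "simulate" or "data"
    out_dir = "mstx_run",
    seed = 1,
    # simulate-mode generator knobs (see simulation_config())
    n_per_group = 50, n_regions = 308, n_left_regions = 151,
    n_features = 7, n_genes = 2000, effect_size = 1.5, n_batches = 2,
    batch_shift = 0.5, batch_scale = 1.2,
    coupling_strength = 0.8, memory_coupling = 0.4,
    # data-mode input paths
    features_path = NULL, meta_path = NULL, expression_path = NULL,
    atlas_path = NULL, de_path = NULL, de_group_path = NULL,
    celltype_path = NULL, gmt_path = NULL,
    # analysis switches
    zscore_axis = "subject", combat_preserve_group = TRUE,
    covariates = c("age", "sex", "education"),
    fisher_alternative = "greater",
    fdr_thresh = 0.05, p_thresh = 0.01, fc_thresh = 1,
    psi_thresh = 0.05, alpha = 0.05, z_crit = NULL,
    B = 1000, B_perm = 1000,
    threads = 1)
  ov <- list(...)
  unknown <- setdiff(names(ov), names(cfg))
  if (length(unknown))
    stop_mstx("pipeline_config: unknown key(s): %s", paste(unknown, collapse = ", "))
  cfg[names(ov)] <- ov
  cfg
}

validate_pipeline_config <- function(cfg, stages) {
  for (k in c("fdr_thresh", "p_thresh", "psi_thresh", "alpha"))
    if (cfg[[k]] <= 0 || cfg[[k]] >= 1)
      stop_mstx("config: %s must lie in (0, 1)", k)
  if (cfg$B < 100) stop_mstx("config: B must be >= 100")
  if (!cfg$mode %in% c("simulate", "data"))
    stop_mstx("config: mode must be 'simulate' or 'data'")
  if (cfg$mode == "data") {
    need <- c("features_path", "meta_path")
    if ("pls" %in% stages) need <- c(need, "expression_path")
    if ("enrich" %in% stages) need <- c(need, "de_path", "de_group_path")
    if ("celltype" %in% stages) need <- c(need, "celltype_path")
    for (k in need) {
      if (is.null(cfg[[k]]))
        stop_mstx("config: %s is required in data mode for the requested stages", k)
      if (!file.exists(cfg[[k]]))
        stop_mstx("config: %s does not exist: %s", k, cfg[[k]])
    }
  }
  invisible(cfg)
}

pipeline_stages <- c("simulate", "harmonize", "ms", "tmap", "pls",
                     "enrich", "celltype")

#' Run the analysis pipeline
#'
#' Executes the requested stages in their fixed order and writes every stage
#' output plus a run manifest (config, seed, config hash, drop/mask counts)
#' under `out_dir`. With the same config and seed the run is bit-reproducible.
#' A stage failure halts the run with the failing stage named; outputs of
#' completed stages are retained.
#'
#' @param config a list from [pipeline_config()] (or a path read with
#'   [read_config()] and passed through it).
#' @param stages subset of `c("simulate","harmonize","ms","tmap","pls",
#'   "enrich","celltype")`, or `"all"`. Later stages pull in what they need.
#' @return invisibly, a list with the in-memory stage results.
#' @export
run_pipeline <- function(config = pipeline_config(), stages = "all") {
  cfg <- config
  if (identical(stages, "all")) stages <- pipeline_stages
  stages <- match.arg(stages, pipeline_stages, several.ok = TRUE)
  # pull dependencies: everything up to the latest requested stage runs
  last <- max(match(stages, pipeline_stages))
  stages <- pipeline_stages[seq_len(last)]
  if (cfg$mode == "data") stages <- setdiff(stages, "simulate")
  validate_pipeline_config(cfg, stages)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  res <- list(config = cfg)
  log <- character()
  note <- function(...) log <<- c(log, sprintf(...))

  run_stage <- function(name, fun) {
    tryCatch(fun(), error = function(e)
      stop_mstx("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
  }

  # -- inputs -------------------------------------------------------------
  if ("simulate" %in% stages) {
    run_stage("simulate", function() {
      sim <- simulation_config(
        n_per_group = cfg$n_per_group, n_regions = cfg$n_regions,
        n_left_regions = cfg$n_left_regions, n_features = cfg$n_features,
        n_genes = cfg$n_genes, effect_size = cfg$effect_size,
        n_batches = cfg$n_batches, batch_shift = cfg$batch_shift,
        batch_scale = cfg$batch_scale,
        coupling_strength = cfg$coupling_strength,
        memory_coupling = cfg$memory_coupling, seed = cfg$seed)
      res$sim_config <<- sim
      res$cohort <<- generate_cohort(sim)
      res$atlas <<- synthetic_atlas(sim)
      write_feature_table(res$cohort,
                          file.path(cfg$out_dir, "features.tsv"),
                          file.path(cfg$out_dir, "metadata.tsv"))
      utils::write.table(res$atlas, file.path(cfg$out_dir, "atlas.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      utils::write.table(
        data.frame(region_id = names(res$cohort$truth$effect_sign),
                   effect_sign = res$cohort$truth$effect_sign),
        file.path(cfg$out_dir, "truth_regions.tsv"),
        sep = "\t", quote = FALSE, row.names = FALSE)
      note("simulate: %d subjects, %d regions", nrow(res$cohort$meta),
           cfg$n_regions)
    })
  } else if (cfg$mode == "data") {
    res$cohort <- run_stage("ingest", function()
      read_feature_table(cfg$features_path, cfg$meta_path))
    res$atlas <- if (!is.null(cfg$atlas_path)) read_region_atlas(cfg$atlas_path)
  }

  # -- morphometry --------------------------------------------------------
  if ("harmonize" %in% stages) {
    run_stage("harmonize", function() {
      covs <- cfg$covariates
      if (isTRUE(cfg$combat_preserve_group)) covs <- c("group", covs)
      nb <- length(unique(res$cohort$meta$batch))
      if (nb > 1) {
        res$cohort <<- harmonize_features(res$cohort, covariates = covs)
        note("harmonize: %d batches adjusted", nb)
      } else note("harmonize: single batch, skipped")
    })
  }
  if ("ms" %in% stages) {
    run_stage("ms", function() {
      res$cohort <<- zscore_features(res$cohort, axis = cfg$zscore_axis)
      res$regional <<- regional_ms_table(res$cohort)
      write_matrix_tsv(res$regional, file.path(cfg$out_dir, "regional_ms.tsv"),
                       id_col = "subject_id")
      note("ms: regional MS for %d subjects x %d regions",
           nrow(res$regional), ncol(res$regional))
    })
  }

  # -- case-control -------------------------------------------------------
  if ("tmap" %in% stages) {
    run_stage("tmap", function() {
      res$tmap <<- ms_tmap(res$regional, res$cohort$meta,
                           covariates = cfg$covariates)
      res$demographics <<- group_compare(res$cohort$meta)
      tab2 <- res$tmap
      if (!is.null(res$atlas))
        tab2 <- merge(res$atlas, tab2, by = "region_id", sort = FALSE)
      tab2 <- tab2[order(sign(tab2$T), tab2$p), , drop = FALSE]
      utils::write.table(tab2, file.path(cfg$out_dir, "tmap.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      utils::write.table(res$demographics,
                         file.path(cfg$out_dir, "demographics.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      sig <- res$tmap$q < cfg$fdr_thresh & !is.na(res$tmap$q)
      res$regions_down <<- res$tmap$region_id[sig & res$tmap$T < 0]
      res$regions_up <<- res$tmap$region_id[sig & res$tmap$T > 0]
      note("tmap: %d decreased, %d increased regions at FDR < %g",
           length(res$regions_down), length(res$regions_up), cfg$fdr_thresh)
      if ("memory_score" %in% names(res$cohort$meta) &&
          any(!is.na(res$cohort$meta$memory_score))) {
        behav <- lapply(
          stats::setNames(c("down", "up"), c("decreased", "increased")),
          function(dirn) {
            regs <- if (dirn == "down") res$regions_down else res$regions_up
            if (length(regs) == 0) return(NULL)
            pc <- partial_correlation(
              mean_ms_subset(res$regional, regs),
              res$cohort$meta$memory_score,
              res$cohort$meta[cfg$covariates])
            data.frame(region_set = dirn, n_regions = length(regs),
                       r = pc$r, p = pc$p, n_effective = pc$n_effective)
          })
        behav <- do.call(rbind, behav)
        res$behavior <<- behav
        if (!is.null(behav))
          utils::write.table(behav, file.path(cfg$out_dir, "behavior.tsv"),
                             sep = "\t", quote = FALSE, row.names = FALSE)
      }
    })
  }

  # -- transcription-imaging ----------------------------------------------
  if ("pls" %in% stages) {
    run_stage("pls", function() {
      if (cfg$mode == "simulate") {
        ex <- generate_expression(res$tmap, res$sim_config)
        res$expr <<- ex$expr
        res$gene_truth <<- ex$truth
        write_matrix_tsv(ex$expr, file.path(cfg$out_dir, "expression.tsv"),
                         id_col = "region_id")
      } else {
        res$expr <<- read_expression_matrix(cfg$expression_path)
      }
      y <- stats::setNames(res$tmap$T, res$tmap$region_id)
      y <- y[rownames(res$expr)]
      fit <- pls1_fit(res$expr, y)
      fit <- pls_bootstrap_z(fit, res$expr, y, B = cfg$B,
                             seed = child_seed(cfg$seed, "bootstrap"))
      sets <- threshold_gene_sets(fit, z_crit = cfg$z_crit, alpha = cfg$alpha)
      res$pls <<- fit; res$gene_sets <<- sets
      gt <- data.frame(gene = names(fit$w), w = fit$w, se_boot = fit$se_boot,
                       z = fit$z,
                       set = ifelse(names(fit$w) %in% sets$pos, "PLS1+",
                             ifelse(names(fit$w) %in% sets$neg, "PLS1-", "ns")))
      utils::write.table(gt, file.path(cfg$out_dir, "pls_genes.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      utils::write.table(
        data.frame(region_id = names(fit$scores), score = fit$scores),
        file.path(cfg$out_dir, "pls_scores.tsv"),
        sep = "\t", quote = FALSE, row.names = FALSE)
      note("pls: varexp_y = %.3f, z_crit = %.2f, %d PLS1+, %d PLS1- genes (%d redrawn resamples)",
           fit$varexp_y, sets$z_crit, length(sets$pos), length(sets$neg),
           fit$n_redrawn)
      spat <- lapply(stats::setNames(c("pos", "neg"), c("PLS1+", "PLS1-")),
                     function(sd) {
                       gs <- sets[[sd]]
                       if (length(gs) == 0) return(NULL)
                       sc <- spatial_correlation(
                         geneset_expression_map(res$expr, gs), y)
                       data.frame(set = if (sd == "pos") "PLS1+" else "PLS1-",
                                  r = sc$r, p = sc$p, n = sc$n)
                     })
      spat <- do.call(rbind, spat)
      if (!is.null(spat)) {
        res$spatial <<- spat
        utils::write.table(spat, file.path(cfg$out_dir, "spatial_correlation.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
      }
    })
  }

  # -- enrichment ---------------------------------------------------------
  if ("enrich" %in% stages) {
    run_stage("enrich", function() {
      if (cfg$mode == "simulate") {
        de_data <- generate_de_dataset(res$sim_config,
                                       coupling = res$gene_truth$coupling)
        res$de_truth <<- de_data$truth
      } else {
        mat <- read_matrix_tsv(cfg$de_path)
        gm <- read_table_checked(cfg$de_group_path, c("sample", "group"))
        de_data <- list(expr = mat, group = gm$group[match(colnames(mat), gm$sample)])
      }
      de <- moderated_de(de_data$expr, de_data$group,
                         p_thresh = cfg$p_thresh, fc_thresh = cfg$fc_thresh)
      res$de <<- de
      utils::write.table(de, file.path(cfg$out_dir, "de_results.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      background <- intersect(de$gene, names(res$pls$w))
      res$background <<- background
      degs <- list(up = intersect(de$gene[de$label == "up"], background),
                   down = intersect(de$gene[de$label == "down"], background))
      pls_sets <- list(`PLS1+` = intersect(res$gene_sets$pos, background),
                       `PLS1-` = intersect(res$gene_sets$neg, background))
      rows <- list()
      for (pn in names(pls_sets)) for (dn in names(degs)) {
        if (!length(pls_sets[[pn]])) next
        r <- fisher_overlap(pls_sets[[pn]], degs[[dn]], background, m = 2,
                            alternative = cfg$fisher_alternative)
        sm <- overlap_summary(r)
        rows[[paste(pn, dn)]] <- data.frame(
          pls_set = pn, deg_set = dn, k = r$k, nA = r$nA, nB = r$nB, N = r$N,
          odds_ratio = r$odds_ratio, p = r$p, p_two_sided = r$p_two_sided,
          pc = r$pc, background_pct = sm$background_pct,
          gene_ratio = sm$gene_ratio)
      }
      res$deg_overlap <<- do.call(rbind, rows)
      utils::write.table(res$deg_overlap,
                         file.path(cfg$out_dir, "deg_overlap.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      note("enrich: %d up / %d down DEGs on background %d",
           length(degs$up), length(degs$down), length(background))
      if (!is.null(cfg$gmt_path)) {
        coll <- read_gmt(cfg$gmt_path)
        coll <- lapply(coll, intersect, background)
        for (pn in names(pls_sets)) {
          if (!length(pls_sets[[pn]])) next
          ora <- ora_collection(pls_sets[[pn]], coll, background,
                                alternative = cfg$fisher_alternative)
          fn <- sprintf("ora_%s.tsv", if (pn == "PLS1+") "pos" else "neg")
          utils::write.table(ora, file.path(cfg$out_dir, fn),
                             sep = "\t", quote = FALSE, row.names = FALSE)
          res$ora[[pn]] <<- ora
        }
      }
    })
  }

  if ("celltype" %in% stages) {
    run_stage("celltype", function() {
      if (cfg$mode == "simulate") {
        ct <- generate_celltype_profiles(res$sim_config,
                                         coupling = res$gene_truth$coupling)
        res$ct_truth <<- ct$truth
        profile <- ct$profile
      } else {
        profile <- read_matrix_tsv(cfg$celltype_path)
      }
      psi <- psi_compute(profile, B_perm = cfg$B_perm,
                         seed = child_seed(cfg$seed, "psi"),
                         psi_thresh = cfg$psi_thresh)
      res$psi <<- psi
      background <- res$background %||% intersect(rownames(profile),
                                                  names(res$pls$w))
      pls_sets <- list(`PLS1+` = intersect(res$gene_sets$pos, background),
                       `PLS1-` = intersect(res$gene_sets$neg, background))
      m_types <- ncol(profile)
      rows <- list()
      for (pn in names(pls_sets)) for (ty in colnames(profile)) {
        if (!length(pls_sets[[pn]])) next
        r <- fisher_overlap(pls_sets[[pn]],
                            intersect(psi$enriched[[ty]], background),
                            background, m = m_types,
                            alternative = cfg$fisher_alternative)
        rows[[paste(pn, ty)]] <- data.frame(
          pls_set = pn, cell_type = ty, k = r$k,
          n_celltype = r$nB, gene_ratio = overlap_summary(r)$gene_ratio,
          p = r$p, p_two_sided = r$p_two_sided, pc = r$pc)
      }
      res$celltype_overlap <<- do.call(rbind, rows)
      utils::write.table(res$celltype_overlap,
                         file.path(cfg$out_dir, "celltype_overlap.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      note("celltype: %s enriched genes per type",
           paste(vapply(psi$enriched, length, integer(1)), collapse = "/"))
    })
  }

  # -- manifest -----------------------------------------------------------
  cfg_json <- jsonlite::toJSON(cfg[!vapply(cfg, is.null, logical(1))],
                               auto_unbox = TRUE, digits = NA)
  manifest <- list(package = "mstx",
                   version = as.character(utils::packageVersion("mstx")),
                   stages = stages, seed = cfg$seed,
                   config = jsonlite::fromJSON(cfg_json),
                   config_hash = fnv1a_hex(as.character(cfg_json)),
                   log = log)
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  res$log <- log
  invisible(res)
}
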