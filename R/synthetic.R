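# Synthetic cohort / expression / DE / cell-type generators with planted truth.
#
# The generative model plants group effects on the *correlation structure* of
# the regional feature vectors (morphometric similarity is a correlation, so
# mean shifts alone would not move it): decreased-MS regions trade shared
# signal for independent noise in cases, increased-MS regions do the reverse,
# with the per-feature variance held fixed so the effect is invisible to
# mass-univariate feature tests.

#' Simulation configuration
#'
#' Bundles every knob of the synthetic-data generators and validates it.
#' Defaults mirror the dimensions of the motivating study design: 308
#' cortical regions whose left half (151) aligns with the expression matrix,
#' 7 features per region, 10 planted decreased-MS and 9 increased-MS regions.
#'
#' @param n_per_group subjects per group (cases = controls).
#' @param n_regions total cortical regions.
#' @param n_left_regions left-hemisphere regions (first `n_left_regions` ids).
#' @param n_features features per region (fixed vocabulary of 7).
#' @param n_genes genes in the expression matrix.
#' @param effect_regions_down,effect_regions_up integer region ids with
#'   planted decreased / increased similarity in cases; must be disjoint.
#'   `NULL` picks evenly spaced defaults (10 down / 9 up, mostly left).
#' @param effect_size standardized magnitude of the planted similarity change
#'   (Cohen's d scale for the regional-MS group contrast).
#' @param n_batches number of acquisition sites/scanners.
#' @param batch_shift sd of per-batch, per-feature additive shifts
#'   (batch 1 is the reference, shift 0).
#' @param batch_scale multiplicative scale applied to non-reference batches
#'   (alternating `batch_scale`, `1/batch_scale`).
#' @param coupling_strength correlation in `[-1, 1]` between planted gene
#'   spatial profiles and the standardized regional T map.
#' @param prop_pos_genes,prop_neg_genes fraction of genes with positive /
#'   negative spatial coupling.
#' @param memory_coupling target magnitude of the partial correlation between
#'   the memory composite and mean MS over the planted regions.
#' @param memory_missing fraction of subjects with missing memory score.
#' @param n_de_samples samples per group in the differential-expression set.
#' @param n_de_up,n_de_down planted up-/down-regulated gene counts; `NULL`
#'   scales them with the gene universe (7.5% / 10%, i.e. 150 / 200 at the
#'   default 2,000 genes).
#' @param de_lfc planted absolute log2 fold change (must exceed 1 to be
#'   screenable at the |log2 FC| > 1 threshold).
#' @param de_overlap_frac fraction of negatively coupled genes recruited into
#'   the planted down-regulated set (drives the enrichment signal).
#' @param cell_types cell-type names for the profile generator.
#' @param n_celltype_genes planted marker genes per cell type; `NULL` scales
#'   with the gene universe (5%, i.e. 100 at the default 2,000 genes).
#' @param celltype_overlap_frac fraction of neuron markers recruited from
#'   negatively coupled genes.
#' @param seed master seed; all generators derive stage seeds from it via
#'   [child_seed()].
#' @return an object of class `"simulation_config"` (a validated list).
#' @export
simulation_config <- function(n_per_group = 50,
                              n_regions = 308,
                              n_left_regions = 151,
                              n_features = 7,
                              n_genes = 2000,
                              effect_regions_down = NULL,
                              effect_regions_up = NULL,
                              effect_size = 1.5,
                              n_batches = 2,
                              batch_shift = 0.5,
                              batch_scale = 1.2,
                              coupling_strength = 0.8,
                              prop_pos_genes = 0.05,
                              prop_neg_genes = 0.05,
                              memory_coupling = 0.4,
                              memory_missing = 0.09,
                              n_de_samples = 16,
                              n_de_up = NULL,
                              n_de_down = NULL,
                              de_lfc = 2,
                              de_overlap_frac = 0.7,
                              cell_types = c("astrocytes", "neurons",
                                             "oligodendrocytes", "microglia"),
                              n_celltype_genes = NULL,
                              celltype_overlap_frac = 0.5,
                              seed = 1L) {
  cfg <- list(
    n_per_group = n_per_group, n_regions = n_regions,
    n_left_regions = n_left_regions, n_features = n_features,
    n_genes = n_genes,
    effect_regions_down = effect_regions_down,
    effect_regions_up = effect_regions_up,
    effect_size = effect_size, n_batches = n_batches,
    batch_shift = batch_shift, batch_scale = batch_scale,
    coupling_strength = coupling_strength,
    prop_pos_genes = prop_pos_genes, prop_neg_genes = prop_neg_genes,
    memory_coupling = memory_coupling, memory_missing = memory_missing,
    n_de_samples = n_de_samples, n_de_up = n_de_up, n_de_down = n_de_down,
    de_lfc = de_lfc, de_overlap_frac = de_overlap_frac,
    cell_types = cell_types, n_celltype_genes = n_celltype_genes,
    celltype_overlap_frac = celltype_overlap_frac,
    seed = as.integer(seed))
  # DE and marker counts scale with the gene universe when unset:
  # 10% down / 7.5% up DEGs and 5% markers per type (200 / 150 / 100 at the
  # default 2,000 genes)
  cfg$n_de_down <- cfg$n_de_down %||% round(0.10 * cfg$n_genes)
  cfg$n_de_up <- cfg$n_de_up %||% round(0.075 * cfg$n_genes)
  cfg$n_celltype_genes <- cfg$n_celltype_genes %||% round(0.05 * cfg$n_genes)
  counts <- c("n_per_group", "n_regions", "n_left_regions", "n_features",
              "n_genes", "n_batches", "n_de_samples")
  for (nm in counts) {
    if (!is.numeric(cfg[[nm]]) || length(cfg[[nm]]) != 1L || cfg[[nm]] < 1)
      stop_mstx("simulation_config: '%s' must be a positive count", nm)
  }
  if (cfg$n_left_regions > cfg$n_regions)
    stop_mstx("simulation_config: n_left_regions exceeds n_regions")
  if (abs(cfg$coupling_strength) > 1)
    stop_mstx("simulation_config: coupling_strength must lie in [-1, 1]")
  if (is.null(cfg$effect_regions_down) && is.null(cfg$effect_regions_up)) {
    eff <- default_effect_regions(cfg$n_regions, cfg$n_left_regions)
    cfg$effect_regions_down <- eff$down
    cfg$effect_regions_up <- eff$up
  }
  cfg$effect_regions_down <- as.integer(cfg$effect_regions_down %||% integer())
  cfg$effect_regions_up <- as.integer(cfg$effect_regions_up %||% integer())
  if (length(intersect(cfg$effect_regions_down, cfg$effect_regions_up)))
    stop_mstx("simulation_config: effect region lists must be disjoint")
  if (cfg$prop_pos_genes + cfg$prop_neg_genes > 1)
    stop_mstx("simulation_config: coupled-gene proportions exceed 1")
  structure(cfg, class = "simulation_config")
}

# Evenly spaced disjoint default effect regions: 10 decreased (7 left, 3
# right) and 9 increased (5 left, 4 right), scaled down for tiny atlases.
default_effect_regions <- function(n_regions, n_left) {
  n_right <- n_regions - n_left
  scl <- min(1, n_regions / 308)
  pick <- function(n, lo, hi, avoid = integer()) {
    if (n <= 0 || hi < lo) return(integer())
    cand <- setdiff(unique(round(seq(lo, hi, length.out = max(n * 2, 2)))), avoid)
    as.integer(head(cand, n))
  }
  nd_l <- max(1, round(7 * scl)); nd_r <- if (n_right > 0) max(1, round(3 * scl)) else 0
  nu_l <- max(1, round(5 * scl)); nu_r <- if (n_right > 0) max(1, round(4 * scl)) else 0
  down <- c(pick(nd_l, 2, n_left - 1),
            pick(nd_r, n_left + 1, n_regions - 1))
  up <- c(pick(nu_l, 2, n_left - 1, avoid = down),
          pick(nu_r, n_left + 1, n_regions - 1, avoid = down))
  list(down = down, up = setdiff(up, down))
}

feature_vocabulary <- function(n = 7) {
  c("FA", "MD", "GMV", "SA", "CT", "IC", "MC")[seq_len(n)]
}

region_ids <- function(cfg) sprintf("R%03d", seq_len(cfg$n_regions))

#' Synthetic region atlas
#'
#' Region ids, names, hemisphere labels and synthetic MNI-like coordinates
#' matching a [simulation_config()]. Coordinates are pass-through metadata.
#'
#' @param config a `simulation_config`.
#' @return data.frame with columns region_id, name, hemisphere, x, y, z.
#' @export
synthetic_atlas <- function(config) {
  ids <- region_ids(config)
  hemi <- ifelse(seq_len(config$n_regions) <= config$n_left_regions, "L", "R")
  with_seed(child_seed(config$seed, "atlas"), {
    data.frame(
      region_id = ids,
      name = paste0(hemi, "_region_", seq_len(config$n_regions)),
      hemisphere = hemi,
      x = round(ifelse(hemi == "L", -1, 1) * stats::runif(config$n_regions, 5, 65), 1),
      y = round(stats::runif(config$n_regions, -100, 65), 1),
      z = round(stats::runif(config$n_regions, -30, 70), 1),
      stringsAsFactors = FALSE)
  })
}

#' Generate a synthetic two-group cohort of regional features
#'
#' Draws a case-control cohort of multimodal regional features with planted
#' group effects on inter-regional correlation structure, per-site batch
#' shifts/scales, demographic covariates and a memory composite coupled to
#' mean similarity over the planted decreased-MS regions.
#'
#' Each subject's region-by-feature matrix is a mixture of two subject-level
#' latent feature patterns (with region loadings shared across subjects) and
#' independent noise. In case subjects, decreased-MS regions swap a fraction
#' of latent signal variance for noise (decorrelating them from the rest of
#' the cortex); increased-MS regions do the opposite. Per-feature variance is
#' preserved, so planted effects act on similarity, not on feature means.
#'
#' @param config a [simulation_config()].
#' @return a list of class `"ms_cohort"`:
#'   \describe{
#'     \item{features}{3-d array, subjects x regions x features.}
#'     \item{meta}{data.frame: subject_id, group (`case`/`control`), age,
#'       sex (`M`/`F`), education, batch, memory_score (NA where missing).}
#'     \item{truth}{planted per-region effect signs (-1/0/+1), batch
#'       location/scale parameters, memory model coefficients.}
#'   }
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  cfg <- config
  bad <- setdiff(c(cfg$effect_regions_down, cfg$effect_regions_up),
                 seq_len(cfg$n_regions))
  if (length(bad))
    stop_mstx("generate_cohort: effect region ids out of range: %s",
              paste(bad, collapse = ", "))
  n <- 2L * cfg$n_per_group
  R <- cfg$n_regions; Fk <- cfg$n_features
  rid <- region_ids(cfg)
  feats <- feature_vocabulary(Fk)

  with_seed(child_seed(cfg$seed, "cohort"), {
    group <- rep(c("case", "control"), each = cfg$n_per_group)
    meta <- data.frame(
      subject_id = sprintf("S%04d", seq_len(n)),
      group = group,
      age = pmin(90, pmax(55, stats::rnorm(n, 75, 8))),
      sex = ifelse(stats::runif(n) < 63 / 106, "M", "F"),
      education = round(pmin(22, pmax(8, stats::rnorm(n, 16, 2.5))), 1),
      batch = paste0("site", 1L + (sample.int(n) %% cfg$n_batches)),
      stringsAsFactors = FALSE)

    # region loadings on the two latent feature patterns; a minority of
    # "balancer" regions load negatively so that within-subject centering
    # leaves the effect regions with clearly positive weighted degree
    bal <- setdiff(seq_len(R), c(cfg$effect_regions_down, cfg$effect_regions_up))
    bal <- bal[seq_len(max(1L, round(0.15 * R)))]
    c1 <- stats::rnorm(R, 1.0, 0.15)
    c1[bal] <- -abs(stats::rnorm(length(bal), 3.5, 0.3))
    c2 <- stats::rnorm(R, 0, 0.5)
    mu_f <- stats::rnorm(Fk, 0, 2)        # arbitrary per-feature offsets
    scale_f <- exp(stats::rnorm(Fk, 0, 0.4)) # arbitrary per-feature scales
    beta_age <- stats::rnorm(Fk, 0, 0.02) # mild age effect, constant in region
    sigma <- 0.6

    # planted signal-share swap; calibrated once so effect_size = 1.5 at
    # n_per_group = 50 meets the >= 80% FDR recovery design point
    w <- min(0.95, 0.5 * cfg$effect_size)

    x <- array(0, dim = c(n, R, Fk), dimnames = list(meta$subject_id, rid, feats))
    down <- cfg$effect_regions_down; up <- cfg$effect_regions_up
    amp2 <- c1^2 + c2^2
    for (s in seq_len(n)) {
      h <- stats::rnorm(Fk); k <- stats::rnorm(Fk)
      sig <- outer(c1, h) + outer(c2, k)          # R x F latent signal
      eps <- matrix(stats::rnorm(R * Fk, 0, sigma), R, Fk)
      gain <- rep(1, R); nvar <- rep(sigma^2, R)
      if (group[s] == "case" && cfg$effect_size > 0) {
        gain[down] <- sqrt(1 - w)
        nvar[down] <- sigma^2 + w * amp2[down]
        gain[up] <- sqrt(1 + w)
        nvar[up] <- pmax(sigma^2 - w * amp2[up], 0.1)
      }
      xs <- sig * gain + eps * sqrt(nvar) / sigma
      x[s, , ] <- sweep(sweep(xs, 2, scale_f, `*`), 2,
                        mu_f + beta_age * (meta$age[s] - 75), `+`)
    }

    # memory composite from the clean (pre-batch) features
    mem_raw <- memory_signal(x, meta, cfg)
    m_std <- as.numeric(scale(mem_raw))
    mem_noise <- stats::rnorm(n)
    mem <- ifelse(group == "case", -0.85, 0.79) +
      0.55 * (cfg$memory_coupling * m_std +
                sqrt(1 - cfg$memory_coupling^2) * mem_noise)
    miss <- stats::runif(n) < cfg$memory_missing
    meta$memory_score <- round(ifelse(miss, NA, mem), 3)

    # per-batch location/scale applied last (what harmonization must undo);
    # batch 1 is the reference
    gamma <- matrix(0, cfg$n_batches, Fk)
    delta <- rep(1, cfg$n_batches)
    if (cfg$n_batches > 1) {
      for (b in 2:cfg$n_batches) {
        gamma[b, ] <- stats::rnorm(Fk, 0, cfg$batch_shift)
        delta[b] <- if (b %% 2 == 0) cfg$batch_scale else 1 / cfg$batch_scale
      }
      bidx <- as.integer(sub("site", "", meta$batch))
      for (s in seq_len(n)) {
        b <- bidx[s]
        xs <- x[s, , ]
        x[s, , ] <- sweep(sweep(xs, 2, mu_f, `-`) * delta[b], 2,
                          mu_f + gamma[b, ], `+`)
      }
    }

    effect_sign <- integer(R)
    effect_sign[down] <- -1L
    effect_sign[up] <- 1L
    truth <- list(effect_sign = stats::setNames(effect_sign, rid),
                  batch_gamma = gamma, batch_delta = delta,
                  memory_coupling = cfg$memory_coupling,
                  loadings = cbind(c1 = c1, c2 = c2))
    structure(list(features = x, meta = meta, truth = truth,
                   config = cfg), class = "ms_cohort")
  })
}

# mean regional MS over the planted decreased regions, from clean features
memory_signal <- function(x, meta, cfg) {
  regs <- cfg$effect_regions_down
  if (!length(regs)) regs <- seq_len(min(10L, cfg$n_regions))
  vapply(seq_len(nrow(meta)), function(s) {
    z <- scale(x[s, , ])
    m <- stats::cor(t(z))
    diag(m) <- NA
    mean(rowMeans(m[regs, , drop = FALSE], na.rm = TRUE))
  }, numeric(1))
}

#' Generate a synthetic regional expression matrix coupled to a T map
#'
#' For coupled genes the spatial profile across left-hemisphere regions is
#' `coupling_strength * standardized(T)` (with the labelled sign) plus
#' independent spatial noise; null genes are pure noise. Each gene is then
#' given an arbitrary affine scale so that column standardization downstream
#' is exercised.
#'
#' @param tmap data.frame with columns `region_id` and `T` covering (at
#'   least) the left-hemisphere regions of `config`.
#' @param config a [simulation_config()].
#' @return list: `expr` (regions x genes matrix, rownames = region ids,
#'   colnames = gene symbols), `truth` (per-gene coupling label in
#'   `{"pos","neg","null"}`).
#' @export
generate_expression <- function(tmap, config) {
  stopifnot(inherits(config, "simulation_config"))
  cfg <- config
  left <- region_ids(cfg)[seq_len(cfg$n_left_regions)]
  if (!all(left %in% tmap$region_id))
    stop_mstx("generate_expression: tmap does not cover the left-hemisphere regions")
  y <- tmap$T[match(left, tmap$region_id)]
  if (anyNA(y)) stop_mstx("generate_expression: tmap has missing T for left regions")
  ys <- as.numeric(scale(y))
  G <- cfg$n_genes
  n_pos <- round(cfg$prop_pos_genes * G)
  n_neg <- round(cfg$prop_neg_genes * G)
  label <- rep("null", G)
  if (n_pos > 0) label[seq_len(n_pos)] <- "pos"
  if (n_neg > 0) label[n_pos + seq_len(n_neg)] <- "neg"
  genes <- sprintf("G%05d", seq_len(G))
  rho <- cfg$coupling_strength
  with_seed(child_seed(cfg$seed, "expression"), {
    noise <- matrix(stats::rnorm(cfg$n_left_regions * G), cfg$n_left_regions, G)
    sgn <- ifelse(label == "pos", 1, ifelse(label == "neg", -1, 0))
    prof <- outer(ys, sgn * rho) + sweep(noise, 2,
            ifelse(sgn != 0, sqrt(1 - rho^2), 1), `*`)
    a <- stats::rnorm(G, 8, 2)
    b <- exp(stats::rnorm(G, 0, 0.5))
    expr <- sweep(sweep(prof, 2, b, `*`), 2, a, `+`)
    dimnames(expr) <- list(left, genes)
    list(expr = expr,
         truth = list(coupling = stats::setNames(label, genes)))
  })
}

#' Generate a two-group sample expression matrix for DE screening
#'
#' Log2-scale expression for `n_de_samples` cases and controls with planted
#' up/down-regulated genes at `de_lfc`. A configurable fraction of the
#' planted down set is recruited from the negatively coupled genes so the
#' downstream overlap test has signal.
#'
#' @param config a [simulation_config()].
#' @param coupling optional named per-gene coupling labels (from
#'   [generate_expression()]); `NULL` plants DEGs among arbitrary genes.
#' @return list: `expr` (genes x samples, log2 scale), `group` (factor),
#'   `truth` (per-gene DE label in `{"up","down","ns"}`).
#' @export
generate_de_dataset <- function(config, coupling = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  cfg <- config
  G <- cfg$n_genes
  if (cfg$n_de_up + cfg$n_de_down > G)
    stop_mstx("generate_de_dataset: fewer genes than planted DE labels")
  genes <- if (!is.null(coupling)) names(coupling) else sprintf("G%05d", seq_len(G))
  label <- rep("ns", G); names(label) <- genes
  with_seed(child_seed(cfg$seed, "de"), {
    neg_pool <- if (!is.null(coupling)) names(coupling)[coupling == "neg"] else character()
    n_from_neg <- min(length(neg_pool), round(cfg$de_overlap_frac * length(neg_pool)),
                      cfg$n_de_down)
    down <- character()
    if (n_from_neg > 0) down <- sample(neg_pool, n_from_neg)
    pool <- setdiff(genes, down)
    if (cfg$n_de_down > length(down))
      down <- c(down, sample(pool, cfg$n_de_down - length(down)))
    up <- sample(setdiff(genes, down), cfg$n_de_up)
    label[down] <- "down"; label[up] <- "up"

    ns <- cfg$n_de_samples
    base <- stats::rnorm(G, 7, 1)
    shift <- ifelse(label == "up", cfg$de_lfc, ifelse(label == "down", -cfg$de_lfc, 0))
    expr <- matrix(stats::rnorm(G * 2 * ns, sd = 0.4), G, 2 * ns) + base
    expr[, seq_len(ns)] <- expr[, seq_len(ns)] + shift
    dimnames(expr) <- list(genes,
                           c(sprintf("case%02d", seq_len(ns)),
                             sprintf("ctrl%02d", seq_len(ns))))
    list(expr = expr,
         group = factor(rep(c("case", "control"), each = ns),
                        levels = c("control", "case")),
         truth = list(de = label))
  })
}

#' Generate cell-type mean-expression profiles
#'
#' Non-negative genes x cell-types profiles with `n_celltype_genes` planted
#' markers per type (expression concentrated in that type). A fraction of the
#' neuron markers is recruited from the negatively coupled genes.
#'
#' @param config a [simulation_config()].
#' @param coupling optional named per-gene coupling labels.
#' @return list: `profile` (genes x cell types, non-negative), `truth`
#'   (per-gene cell-type label, `"none"` for non-markers).
#' @export
generate_celltype_profiles <- function(config, coupling = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  cfg <- config
  G <- cfg$n_genes
  types <- cfg$cell_types
  if (length(types) < 2) stop_mstx("generate_celltype_profiles: need >= 2 cell types")
  if (cfg$n_celltype_genes * length(types) > G)
    stop_mstx("generate_celltype_profiles: fewer genes than planted labels")
  genes <- if (!is.null(coupling)) names(coupling) else sprintf("G%05d", seq_len(G))
  with_seed(child_seed(cfg$seed, "celltype"), {
    prof <- matrix(stats::rlnorm(G * length(types), meanlog = 1, sdlog = 0.6),
                   G, length(types), dimnames = list(genes, types))
    label <- rep("none", G); names(label) <- genes
    taken <- character()
    for (ty in types) {
      pool <- setdiff(genes, taken)
      if (ty == "neurons" && !is.null(coupling)) {
        neg_pool <- setdiff(names(coupling)[coupling == "neg"], taken)
        n_neg <- min(length(neg_pool),
                     round(cfg$celltype_overlap_frac * cfg$n_celltype_genes))
        mk <- character()
        if (n_neg > 0) mk <- sample(neg_pool, n_neg)
        mk <- c(mk, sample(setdiff(pool, mk), cfg$n_celltype_genes - length(mk)))
      } else {
        mk <- sample(pool, cfg$n_celltype_genes)
      }
      prof[mk, ty] <- prof[mk, ty] * 20
      label[mk] <- ty
      taken <- c(taken, mk)
    }
    list(profile = prof, truth = list(celltype = label))
  })
}
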