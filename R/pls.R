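# Transcription-imaging association: first-component partial least squares
# of a regional T map on a regions x genes expression matrix, bootstrap gene
# Z scores, and Bonferroni-derived gene-set thresholds.
#
# With a univariate response, the first PLS weight vector is the normalized
# gene-response covariance vector; that closed form is what is implemented
# (and what the oracle tests check), so the NIPALS/SIMPLS distinction is
# immaterial here.

#' First-component PLS of a regional response on gene expression
#'
#' Gene columns are centered and (by default) scaled to unit variance; the
#' response is centered. The PLS1 gene weight vector is
#' `w = X'y / ||X'y||`, regional scores are `t = Xw`, and the response
#' variance explained is `cor(t, y)^2`. The sign of `w` is fixed so scores
#' correlate positively with the response.
#'
#' Regions are aligned by id (names), never by position.
#'
#' @param X regions x genes numeric matrix with region rownames and gene
#'   colnames.
#' @param y named numeric response (regional T values) covering the regions
#'   of `X`.
#' @param scale_genes scale gene columns to unit variance (default TRUE).
#' @return list of class `"pls_result"`: `w` (named unit-norm gene weights),
#'   `scores` (named regional scores), `varexp_y`, `dropped` (zero-variance
#'   genes), `scale_genes`.
#' @export
pls1_fit <- function(X, y, scale_genes = TRUE) {
  stopifnot(is.matrix(X), is.numeric(X))
  if (is.null(rownames(X)) || is.null(names(y)))
    stop_mstx("pls1_fit: X rownames and y names are required for id alignment")
  miss <- setdiff(rownames(X), names(y))
  if (length(miss))
    stop_mstx("pls1_fit: response missing for region(s): %s",
              paste(utils::head(miss, 5), collapse = ", "))
  y <- y[rownames(X)]
  if (anyNA(y) || anyNA(X)) stop_mstx("pls1_fit: missing values not allowed")
  sds <- col_sds(X)
  dropped <- colnames(X)[sds == 0]
  if (length(dropped)) {
    warn_mstx("pls1_fit: dropping %d zero-variance gene(s)", length(dropped))
    X <- X[, sds > 0, drop = FALSE]
    sds <- sds[sds > 0]
  }
  Xc <- sweep(X, 2, colMeans(X))
  if (scale_genes) Xc <- sweep(Xc, 2, sds, `/`)
  yc <- y - mean(y)
  w <- drop(crossprod(Xc, yc))
  nrm <- sqrt(sum(w^2))
  if (nrm == 0) stop_mstx("pls1_fit: X'y is zero; no association to extract")
  w <- w / nrm
  scores <- drop(Xc %*% w)
  r <- stats::cor(scores, y)
  if (r < 0) { w <- -w; scores <- -scores; r <- -r }
  structure(list(w = stats::setNames(w, colnames(Xc)),
                 scores = stats::setNames(scores, rownames(X)),
                 varexp_y = r^2, dropped = dropped,
                 scale_genes = scale_genes),
            class = "pls_result")
}

#' Bootstrap standard errors and Z scores for PLS1 gene weights
#'
#' Resamples regions (rows) with replacement `B` times, refits [pls1_fit()]
#' on each resample, sign-aligns the resampled weight vector to the point
#' estimate (flip if their inner product is negative), and returns the
#' per-gene standard deviation of aligned weights as `se_boot` and
#' `z = w / se_boot`. Degenerate resamples (constant response or fewer than
#' 3 distinct regions) are redrawn and counted.
#'
#' @param fit a `"pls_result"` from [pls1_fit()] on the same `X`, `y`.
#' @param X,y as in [pls1_fit()].
#' @param B bootstrap resamples (>= 100; default 1000).
#' @param seed integer seed for the resampling.
#' @return the fit, augmented with `se_boot`, `z` (named per gene), `B`,
#'   `n_redrawn`.
#' @export
pls_bootstrap_z <- function(fit, X, y, B = 1000, seed = 1L) {
  stopifnot(inherits(fit, "pls_result"))
  if (B < 100) stop_mstx("pls_bootstrap_z: B must be >= 100")
  genes <- names(fit$w)
  X <- X[, genes, drop = FALSE]
  y <- y[rownames(X)]
  n <- nrow(X)
  Wb <- matrix(0, B, length(genes))
  redrawn <- 0L
  with_seed(as.integer(seed), {
    for (b in seq_len(B)) {
      repeat {
        idx <- sample.int(n, n, replace = TRUE)
        yb <- y[idx]
        if (length(unique(idx)) >= 3L && stats::sd(yb) > 0) break
        redrawn <- redrawn + 1L
      }
      Xb <- X[idx, , drop = FALSE]
      cm <- colMeans(Xb)
      yc <- yb - mean(yb)
      wv <- drop(crossprod(Xb, yc)) - cm * sum(yc)  # centered covariance * (n-1)
      if (fit$scale_genes) {
        sds <- col_sds(Xb)
        ok <- sds > 0
        wv[ok] <- wv[ok] / sds[ok]
        wv[!ok] <- 0
      }
      nrm <- sqrt(sum(wv^2))
      if (nrm > 0) wv <- wv / nrm
      if (sum(wv * fit$w) < 0) wv <- -wv
      Wb[b, ] <- wv
    }
  })
  se <- col_sds(Wb)
  z <- ifelse(se > 0, fit$w / se, NA_real_)
  fit$se_boot <- stats::setNames(se, genes)
  fit$z <- stats::setNames(z, genes)
  fit$B <- B
  fit$n_redrawn <- redrawn
  fit
}

#' Bonferroni-derived Z threshold for gene selection
#'
#' The smallest two-decimal value whose two-sided normal tail probability is
#' at most `alpha / n_genes`; for 20,737 genes at alpha = 0.05 this is 4.72.
#'
#' @param n_genes number of genes tested.
#' @param alpha family-wise error target (default 0.05).
#' @return numeric threshold (two decimals).
#' @export
bonferroni_z_crit <- function(n_genes, alpha = 0.05) {
  stopifnot(n_genes >= 1, alpha > 0, alpha < 1)
  z <- stats::qnorm(1 - alpha / (2 * n_genes))
  zc <- ceiling(z * 100 - 1e-9) / 100
  # guard the ceiling against representation error
  while (2 * stats::pnorm(-zc) > alpha / n_genes) zc <- zc + 0.01
  zc
}

#' Threshold bootstrap Z scores into signed gene sets
#'
#' `PLS1+ = {z > z_crit}`, `PLS1- = {z < -z_crit}` (strict inequalities).
#' When `z_crit` is `NULL` it is derived from the number of genes via
#' [bonferroni_z_crit()].
#'
#' @param fit a `"pls_result"` with `z` (see [pls_bootstrap_z()]).
#' @param z_crit threshold, or `NULL` to derive it.
#' @param alpha family-wise error target used when deriving.
#' @return list: `pos`, `neg` (character gene vectors), `z_crit`,
#'   `n_genes_for_bonferroni`.
#' @export
threshold_gene_sets <- function(fit, z_crit = NULL, alpha = 0.05) {
  stopifnot(inherits(fit, "pls_result"), !is.null(fit$z))
  ng <- length(fit$z)
  if (is.null(z_crit)) z_crit <- bonferroni_z_crit(ng, alpha)
  z <- fit$z[!is.na(fit$z)]
  list(pos = names(z)[z > z_crit],
       neg = names(z)[z < -z_crit],
       z_crit = z_crit,
       n_genes_for_bonferroni = ng)
}

#' Mean regional expression of a gene set
#'
#' Per-region mean of column-standardized expression over the set.
#'
#' @param X regions x genes matrix.
#' @param genes non-empty character vector of gene symbols in `X`.
#' @return named numeric vector over regions.
#' @export
geneset_expression_map <- function(X, genes) {
  if (!length(genes)) stop_mstx("geneset_expression_map: empty gene set")
  miss <- setdiff(genes, colnames(X))
  if (length(miss))
    stop_mstx("geneset_expression_map: unknown gene(s): %s",
              paste(utils::head(miss, 5), collapse = ", "))
  Z <- scale(X[, genes, drop = FALSE])
  stats::setNames(rowMeans(Z), rownames(X))
}

#' Spatial correlation of an expression map with a regional response
#'
#' Pearson correlation (aligned by region id) with a two-sided p.
#'
#' @param map named regional vector (e.g. from [geneset_expression_map()]).
#' @param y named regional response.
#' @return list: r, p, n.
#' @export
spatial_correlation <- function(map, y) {
  if (is.null(names(map)) || is.null(names(y)))
    stop_mstx("spatial_correlation: named vectors required for id alignment")
  common <- intersect(names(map), names(y))
  if (length(common) < 3) stop_mstx("spatial_correlation: < 3 shared regions")
  ct <- stats::cor.test(map[common], y[common])
  list(r = unname(ct$estimate), p = ct$p.value, n = length(common))
}
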