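# Empirical-Bayes location/scale batch harmonization of regional features
# (parametric ComBat model) applied before similarity estimation.

#' Harmonize regional features across sites/scanners
#'
#' Removes per-batch location and scale effects from every (region, feature)
#' series across subjects, with parametric empirical-Bayes shrinkage of the
#' batch parameters: series are standardized against a covariate-preserving
#' grand model, per-batch means (gamma) and variances (delta) are shrunk
#' toward across-series priors estimated within each feature (normal prior
#' on gamma, inverse-gamma moment-matched prior on delta), subtracted /
#' divided out, and the grand location/scale restored. Biological covariates (group by default, plus
#' age, sex, education) stay in the model so harmonization does not remove
#' group signal.
#'
#' With a single batch the input is returned unchanged.
#'
#' @param cohort an `ms_cohort` (see [generate_cohort()] / the readers).
#' @param batch name of the metadata column holding the batch label.
#' @param covariates metadata columns to preserve; categorical columns are
#'   expanded to indicators. Use `character()` to preserve nothing.
#' @return the cohort with harmonized features (same shape and dimnames).
#' @export
harmonize_features <- function(cohort, batch = "batch",
                               covariates = c("group", "age", "sex", "education")) {
  stopifnot(inherits(cohort, "ms_cohort"))
  meta <- cohort$meta
  if (!batch %in% names(meta))
    stop_mstx("harmonize_features: no metadata column '%s'", batch)
  bt <- factor(meta[[batch]])
  if (anyNA(bt)) stop_mstx("harmonize_features: missing batch labels")
  if (nlevels(bt) == 1L) return(cohort)
  nb <- table(bt)
  if (any(nb < 2))
    stop_mstx("harmonize_features: batch(es) with < 2 subjects: %s",
              paste(names(nb)[nb < 2], collapse = ", "))

  x <- cohort$features
  dims <- dim(x)
  n <- dims[1]
  # rows = (region, feature) series, columns = subjects; hyperpriors are
  # estimated within feature blocks (features differ in units and batch
  # susceptibility, so pooling gamma/delta priors across features would
  # shrink a feature-specific batch effect toward the wrong location)
  Y <- t(matrix(x, nrow = n))
  block <- factor(rep(seq_len(dims[3]), each = dims[2]))
  mod <- covariate_design(meta, covariates)
  cohort$features <- array(t(combat_fit(Y, bt, mod, block)), dim = dims,
                           dimnames = dimnames(x))
  cohort
}

covariate_design <- function(meta, covariates) {
  if (!length(covariates)) return(NULL)
  miss <- setdiff(covariates, names(meta))
  if (length(miss))
    stop_mstx("harmonize_features: missing covariate column(s): %s",
              paste(miss, collapse = ", "))
  df <- meta[covariates]
  df[] <- lapply(df, function(v) if (is.character(v)) factor(v) else v)
  mm <- stats::model.matrix(~ ., data = df)
  mm[, -1, drop = FALSE]  # drop intercept; batch indicators carry location
}

# core parametric EB adjustment; Y is series x subjects, block groups the
# series for hyperprior estimation (one level per feature)
combat_fit <- function(Y, batch, mod, block = NULL, eb_iter_tol = 1e-4) {
  nlev <- nlevels(batch)
  n <- ncol(Y)
  batchmod <- stats::model.matrix(~ -1 + batch)
  X <- cbind(batchmod, mod)
  q <- qr(X)
  if (q$rank < ncol(X))
    stop_mstx("harmonize_features: design is rank deficient (collinear covariates: %s)",
              paste(colnames(X)[q$pivot[seq(q$rank + 1, ncol(X))]], collapse = ", "))
  B_hat <- solve(crossprod(X), crossprod(X, t(Y)))   # p x G
  nbs <- as.numeric(table(batch))
  grand_mean <- crossprod(nbs / n, B_hat[seq_len(nlev), , drop = FALSE])
  resid <- Y - t(X %*% B_hat)
  var_pooled <- rowMeans(resid^2)
  if (any(var_pooled <= 0))
    stop_mstx("harmonize_features: %d zero-variance series after model fit",
              sum(var_pooled <= 0))
  stand_mean <- matrix(grand_mean, nrow(Y), n)
  if (!is.null(mod)) {
    stand_mean <- stand_mean +
      t(mod %*% B_hat[-seq_len(nlev), , drop = FALSE])
  }
  Z <- (Y - stand_mean) / sqrt(var_pooled)

  if (is.null(block)) block <- factor(rep(1L, nrow(Y)))
  out <- Z
  for (b in levels(batch)) {
    sel <- which(batch == b)
    Zb <- Z[, sel, drop = FALSE]
    g_hat <- rowMeans(Zb)
    d_hat <- apply(Zb, 1, stats::var)
    if (any(d_hat == 0))
      stop_mstx("harmonize_features: zero-variance series within batch '%s'", b)
    for (blk in levels(block)) {
      rows <- which(block == blk)
      g_bar <- mean(g_hat[rows]); t2 <- stats::var(g_hat[rows])
      a_pr <- a_prior(d_hat[rows]); b_pr <- b_prior(d_hat[rows])
      est <- eb_iterate(Zb[rows, , drop = FALSE], g_hat[rows], d_hat[rows],
                        g_bar, t2, a_pr, b_pr, eb_iter_tol)
      out[rows, sel] <- (Zb[rows, , drop = FALSE] - est$gamma) / sqrt(est$delta)
    }
  }
  out * sqrt(var_pooled) + stand_mean
}

# inverse-gamma moment-matched hyperpriors on the batch variances
a_prior <- function(d) { m <- mean(d); s2 <- stats::var(d); (2 * s2 + m^2) / s2 }
b_prior <- function(d) { m <- mean(d); s2 <- stats::var(d); (m * s2 + m^3) / s2 }

eb_iterate <- function(Zb, g_hat, d_hat, g_bar, t2, a_pr, b_pr, tol) {
  nb <- ncol(Zb)
  g_new <- g_hat; d_new <- d_hat
  repeat {
    g_old <- g_new; d_old <- d_new
    g_new <- (t2 * nb * g_hat + d_new * g_bar) / (t2 * nb + d_new)
    sse <- rowSums((Zb - g_new)^2)
    d_new <- (b_pr + 0.5 * sse) / (nb / 2 + a_pr - 1)
    change <- max(abs(g_new - g_old) / pmax(abs(g_old), 1e-12),
                  abs(d_new - d_old) / pmax(abs(d_old), 1e-12))
    if (change < tol) break
  }
  list(gamma = g_new, delta = d_new)
}
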