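# Regional case-control statistics: covariate-adjusted group contrasts with
# FDR control, region-subset means, partial correlations with behavior, and
# demographic group comparisons.

#' Regional case-control T map
#'
#' Fits, per region, an ordinary least-squares model of regional MS on the
#' group indicator plus nuisance covariates; T is the group coefficient over
#' its standard error with n - p residual degrees of freedom, p two-sided,
#' and q Benjamini-Hochberg adjusted across all regions in one family.
#' Group is coded case = 1, control = 0, so negative T means lower MS in
#' cases.
#'
#' @param regional subjects x regions matrix from [regional_ms_table()].
#' @param meta metadata data.frame with a `group` column (`case`/`control`)
#'   and the covariate columns.
#' @param covariates metadata columns used as nuisance covariates
#'   (categorical expanded to indicators); `character()` reduces T to the
#'   pooled two-sample t statistic.
#' @return data.frame of class `"ms_tmap"`: region_id, T, p, q, direction.
#' @export
ms_tmap <- function(regional, meta,
                    covariates = c("age", "sex", "education")) {
  stopifnot(is.matrix(regional), nrow(regional) == nrow(meta))
  if (!all(meta$group %in% c("case", "control")))
    stop_mstx("ms_tmap: group must be 'case'/'control'")
  if (min(table(meta$group)) < 2)
    stop_mstx("ms_tmap: need >= 2 subjects per group")
  g <- as.numeric(meta$group == "case")
  X <- cbind(`(Intercept)` = 1, group = g)
  if (length(covariates)) {
    cd <- covariate_design(meta, covariates)
    if (anyNA(cd)) stop_mstx("ms_tmap: covariates must be complete")
    X <- cbind(X, cd)
  }
  q <- qr(X)
  if (q$rank < ncol(X))
    stop_mstx("ms_tmap: rank-deficient design (collinear columns: %s)",
              paste(colnames(X)[q$pivot[seq(q$rank + 1, ncol(X))]],
                    collapse = ", "))
  n <- nrow(X); p <- ncol(X)
  XtXinv <- chol2inv(chol(crossprod(X)))
  H <- XtXinv %*% t(X)
  ok_regions <- colSums(is.na(regional)) == 0L
  if (!all(ok_regions))
    warn_mstx("ms_tmap: %d region(s) with missing values get NA statistics",
              sum(!ok_regions))
  Tv <- pv <- rep(NA_real_, ncol(regional))
  Y <- regional[, ok_regions, drop = FALSE]
  coefs <- H %*% Y
  fitted <- X %*% coefs
  rss <- colSums((Y - fitted)^2)
  sigma2 <- rss / (n - p)
  se <- sqrt(sigma2 * XtXinv[2, 2])
  Tv[ok_regions] <- coefs[2, ] / se
  pv[ok_regions] <- 2 * stats::pt(-abs(Tv[ok_regions]), df = n - p)
  qv <- rep(NA_real_, length(pv))
  qv[ok_regions] <- fdr_bh(pv[ok_regions])
  out <- data.frame(
    region_id = colnames(regional) %||% sprintf("R%03d", seq_along(Tv)),
    T = Tv, p = pv, q = qv,
    direction = ifelse(is.na(Tv), NA_integer_, as.integer(sign(Tv))),
    stringsAsFactors = FALSE)
  class(out) <- c("ms_tmap", "data.frame")
  out
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Standard step-up adjusted p-values: order p ascending, take
#' `p[i] * m / i`, enforce monotonicity by a reverse cumulative minimum,
#' clip at 1, and return in the input order.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return adjusted q-values, same length and order.
#' @export
fdr_bh <- function(p) {
  if (anyNA(p) || any(p < 0 | p > 1))
    stop_mstx("fdr_bh: p-values must lie in [0, 1] with no NA")
  m <- length(p)
  if (m == 0L) return(numeric())
  o <- order(p)
  q <- pmin(1, rev(cummin(rev(p[o] * m / seq_len(m)))))
  q[order(o)]
}

#' Mean regional MS over a region subset
#'
#' Per-subject unweighted mean of regional MS over the listed regions (e.g.
#' the significantly decreased or increased sets).
#'
#' @param regional subjects x regions matrix.
#' @param regions region ids (column names) or indices.
#' @return named numeric vector, one value per subject.
#' @export
mean_ms_subset <- function(regional, regions) {
  if (!length(regions)) stop_mstx("mean_ms_subset: empty region list")
  if (is.character(regions)) {
    miss <- setdiff(regions, colnames(regional))
    if (length(miss))
      stop_mstx("mean_ms_subset: unknown region id(s): %s",
                paste(miss, collapse = ", "))
  } else if (any(regions < 1 | regions > ncol(regional))) {
    stop_mstx("mean_ms_subset: region index out of range")
  }
  rowMeans(regional[, regions, drop = FALSE])
}

#' Partial correlation with nuisance covariates
#'
#' Residualizes `x` and `y` on the covariates by OLS (with intercept) and
#' correlates the residuals; p from `t = r * sqrt((n - 2 - k) / (1 - r^2))`
#' with k covariate columns. Only complete cases are used.
#'
#' @param x,y numeric vectors.
#' @param covariates data.frame / matrix of nuisance covariates, or `NULL`
#'   for a plain Pearson correlation.
#' @return list of class `"behavior_cor"`: r, p, n_effective, covariates.
#' @export
partial_correlation <- function(x, y, covariates = NULL) {
  cv <- if (is.null(covariates)) NULL else as.data.frame(covariates)
  keep <- stats::complete.cases(x, y, if (is.null(cv)) rep(TRUE, length(x)) else cv)
  x <- x[keep]; y <- y[keep]
  k <- 0L
  if (!is.null(cv)) {
    cv <- cv[keep, , drop = FALSE]
    cv[] <- lapply(cv, function(v) if (is.character(v)) factor(v) else v)
    mm <- stats::model.matrix(~ ., data = cv)
    k <- ncol(mm) - 1L
    x <- stats::lm.fit(mm, x)$residuals
    y <- stats::lm.fit(mm, y)$residuals
  }
  n <- length(x)
  if (n <= k + 2L) stop_mstx("partial_correlation: n_effective <= k + 2")
  r <- stats::cor(x, y)
  tt <- r * sqrt((n - 2 - k) / (1 - r^2))
  p <- 2 * stats::pt(-abs(tt), df = n - 2 - k)
  structure(list(r = r, p = p, n_effective = n,
                 covariates = colnames(cv) %||% character()),
            class = "behavior_cor")
}

#' Pooled two-sample t statistic from summary statistics
#'
#' @param m1,s1,n1 mean, sd, n of group 1; `m2,s2,n2` of group 2.
#' @return list: t, df, p (two-sided).
#' @export
pooled_t_summary <- function(m1, s1, n1, m2, s2, n2) {
  sp2 <- ((n1 - 1) * s1^2 + (n2 - 1) * s2^2) / (n1 + n2 - 2)
  t <- (m1 - m2) / sqrt(sp2 * (1 / n1 + 1 / n2))
  df <- n1 + n2 - 2
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

#' Demographic group comparison table
#'
#' Pooled-variance two-sample t tests for continuous variables and Pearson
#' chi-squared tests (no continuity correction) for categorical variables,
#' case versus control.
#'
#' @param meta metadata data.frame with a `group` column.
#' @param variables columns to compare; default: all except subject_id,
#'   group, batch.
#' @return data.frame: variable, type, statistic (t or chi-squared), df, p,
#'   and per-group summaries (`mean (sd)` or level counts).
#' @export
group_compare <- function(meta, variables = NULL) {
  if (!all(c("case", "control") %in% meta$group))
    stop_mstx("group_compare: both groups must be present")
  if (is.null(variables))
    variables <- setdiff(names(meta), c("subject_id", "group", "batch"))
  rows <- lapply(variables, function(v) {
    val <- meta[[v]]
    keep <- !is.na(val)
    g <- meta$group[keep]; val <- val[keep]
    if (is.numeric(val)) {
      sm <- function(x) sprintf("%.2f (%.2f)", mean(x), stats::sd(x))
      tt <- pooled_t_summary(mean(val[g == "case"]), stats::sd(val[g == "case"]),
                             sum(g == "case"),
                             mean(val[g == "control"]), stats::sd(val[g == "control"]),
                             sum(g == "control"))
      data.frame(variable = v, type = "continuous",
                 statistic = tt$t, df = tt$df, p = tt$p,
                 case = sm(val[g == "case"]), control = sm(val[g == "control"]),
                 stringsAsFactors = FALSE)
    } else {
      tab <- table(g, val)
      ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
      cnt <- function(grp) paste(tab[grp, ], collapse = "/")
      data.frame(variable = v, type = "categorical",
                 statistic = unname(ct$statistic), df = unname(ct$parameter),
                 p = unname(ct$p.value),
                 case = cnt("case"), control = cnt("control"),
                 stringsAsFactors = FALSE)
    }
  })
  do.call(rbind, rows)
}
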