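# Morphometric similarity estimation: within-subject z-scoring of regional
# features, region x region Pearson similarity, and nodal weighted degree.

#' Z-score regional features within subject
#'
#' Standardizes each feature across regions (mean 0, sd 1 with the n-1
#' denominator). The default axis is within-subject, which makes the
#' similarity matrix a within-individual quantity; `axis = "pooled"` instead
#' standardizes each feature over all subjects and regions jointly
#' (sensitivity switch).
#'
#' @param x an `ms_cohort`, or a 3-d array (subjects x regions x features),
#'   or a single subject's regions x features matrix.
#' @param axis `"subject"` (default) or `"pooled"`.
#' @return object of the same shape with standardized features.
#' @export
zscore_features <- function(x, axis = c("subject", "pooled")) {
  axis <- match.arg(axis)
  if (inherits(x, "ms_cohort")) {
    x$features <- zscore_features(x$features, axis)
    return(x)
  }
  if (is.matrix(x)) return(zscore_one(x, subject = "subject"))
  stopifnot(is.array(x), length(dim(x)) == 3L)
  if (axis == "pooled") {
    for (f in seq_len(dim(x)[3])) {
      v <- x[, , f]
      s <- stats::sd(v)
      if (s == 0)
        stop_mstx("zscore_features: zero-variance feature [%s] pooled",
                  dimnames(x)[[3]][f] %||% f)
      x[, , f] <- (v - mean(v)) / s
    }
    return(x)
  }
  for (s in seq_len(dim(x)[1])) {
    x[s, , ] <- zscore_one(x[s, , , drop = TRUE],
                           subject = dimnames(x)[[1]][s] %||% as.character(s))
  }
  x
}

zscore_one <- function(m, subject) {
  sds <- col_sds(m)
  if (any(sds == 0)) {
    bad <- colnames(m)[sds == 0] %||% which(sds == 0)
    stop_mstx("zscore_features: zero-variance feature(s) [%s] for subject %s",
              paste(bad, collapse = ", "), subject)
  }
  scale(m)[, , drop = FALSE]
}

#' Morphometric similarity matrix for one subject
#'
#' Pearson correlation (across the feature axis) between every pair of
#' regions' z-scored feature vectors. The diagonal carries no information
#' and is set to `NA`. A region whose feature vector has zero variance gets
#' an all-`NA` row/column and a warning (masked, not imputed).
#'
#' @param features one subject's regions x features numeric matrix,
#'   already z-scored (see [zscore_features()]).
#' @return regions x regions symmetric matrix, `NA` diagonal.
#' @export
ms_matrix <- function(features) {
  stopifnot(is.matrix(features), is.numeric(features))
  rv <- apply(features, 1, stats::sd)
  degen <- which(rv == 0)
  m <- suppressWarnings(stats::cor(t(features)))
  if (length(degen)) {
    warn_mstx("ms_matrix: %d region(s) with zero feature variance masked: %s",
              length(degen),
              paste(rownames(features)[degen] %||% degen, collapse = ", "))
    m[degen, ] <- NA_real_
    m[, degen] <- NA_real_
  }
  diag(m) <- NA_real_
  m
}

#' Regional morphometric similarity (weighted degree)
#'
#' The nodal summary of an MS matrix: each region's mean similarity to all
#' other regions (off-diagonal row mean; signed edges retained, no absolute
#' value, no thresholding).
#'
#' @param ms a symmetric MS matrix from [ms_matrix()] (`NA` diagonal).
#' @return named numeric vector, one value per region; `NA` for masked rows
#'   (propagated with a warning).
#' @export
regional_ms <- function(ms) {
  stopifnot(is.matrix(ms), nrow(ms) == ncol(ms))
  v <- suppressWarnings(rowMeans(ms, na.rm = TRUE))
  # a fully masked row is all-NA -> NaN under na.rm; other rows simply
  # exclude masked partners from their means
  masked <- !is.finite(v)
  if (any(masked)) {
    warn_mstx("regional_ms: %d masked region(s) propagate NA", sum(masked))
    v[masked] <- NA_real_
  }
  v
}

#' Subjects x regions table of regional MS
#'
#' Convenience wrapper running [ms_matrix()] and [regional_ms()] for every
#' subject of a z-scored cohort.
#'
#' @param cohort an `ms_cohort` whose features are already harmonized and
#'   z-scored (the shipped order is harmonize, then z-score, then correlate).
#' @return numeric matrix, subjects x regions.
#' @export
regional_ms_table <- function(cohort) {
  stopifnot(inherits(cohort, "ms_cohort"))
  x <- cohort$features
  out <- matrix(NA_real_, dim(x)[1], dim(x)[2],
                dimnames = dimnames(x)[1:2])
  for (s in seq_len(dim(x)[1])) {
    out[s, ] <- regional_ms(ms_matrix(x[s, , , drop = TRUE]))
  }
  out
}
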