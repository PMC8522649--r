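# Differential-expression screening with empirical-Bayes moderated t,
# hypergeometric/Fisher gene-set overlap with Bonferroni correction, and
# generic over-representation for user-supplied collections.

#' Moderated two-group differential expression screen
#'
#' Per gene, a two-group comparison of log2 expression with the standard
#' empirical-Bayes variance moderation: residual variances are shrunk toward
#' a pooled prior, `s2_tilde = (d0 * s0^2 + dg * s2_g) / (d0 + dg)`, with the
#' prior degrees of freedom `d0` and location `s0^2` moment-matched from the
#' distribution of the gene variances (log-variance mean / trigamma
#' matching). The moderated t has `dg + d0` degrees of freedom. Genes are
#' labelled `up` / `down` when `p < p_thresh` and `|log2fc| > fc_thresh`.
#'
#' `prior_df = 0` reduces to the ordinary per-gene pooled t; `prior_df = Inf`
#' uses a single common variance for all genes.
#'
#' @param expr genes x samples matrix of log2-scale expression.
#' @param group factor/character of length `ncol(expr)` with levels
#'   `control` and `case`; log2fc is case minus control.
#' @param p_thresh,fc_thresh screening thresholds (defaults 0.01 and 1; the
#'   p threshold applies to unadjusted p).
#' @param prior_df optional override of the prior degrees of freedom
#'   (`0`, a positive number, or `Inf`); `NULL` estimates it.
#' @param prior_var optional override of the prior variance `s0^2`.
#' @return data.frame of class `"de_result"`: gene, log2fc, t_mod, df, p,
#'   label; attributes `prior_df`, `prior_var`.
#' @export
moderated_de <- function(expr, group, p_thresh = 0.01, fc_thresh = 1,
                         prior_df = NULL, prior_var = NULL) {
  stopifnot(is.matrix(expr), ncol(expr) == length(group))
  group <- as.character(group)
  if (!all(group %in% c("case", "control")))
    stop_mstx("moderated_de: group must be 'case'/'control'")
  i1 <- group == "case"; i2 <- group == "control"
  n1 <- sum(i1); n2 <- sum(i2)
  if (n1 < 2 || n2 < 2) stop_mstx("moderated_de: need >= 2 samples per group")
  m1 <- rowMeans(expr[, i1, drop = FALSE])
  m2 <- rowMeans(expr[, i2, drop = FALSE])
  ss1 <- rowSums((expr[, i1, drop = FALSE] - m1)^2)
  ss2 <- rowSums((expr[, i2, drop = FALSE] - m2)^2)
  dg <- n1 + n2 - 2
  s2 <- (ss1 + ss2) / dg
  if (any(s2 == 0))
    stop_mstx("moderated_de: %d gene(s) with zero variance in both groups",
              sum(s2 == 0))
  if (is.null(prior_df) || is.null(prior_var)) {
    fit <- fit_variance_prior(s2, dg)
    if (is.null(prior_df)) prior_df <- fit$df
    if (is.null(prior_var)) prior_var <- fit$var
  }
  s2t <- if (is.infinite(prior_df)) rep(prior_var, length(s2))
         else (prior_df * prior_var + dg * s2) / (prior_df + dg)
  lfc <- m1 - m2
  tmod <- lfc / sqrt(s2t * (1 / n1 + 1 / n2))
  # total df capped at the pooled residual df of the whole experiment
  df <- min(dg + prior_df, length(s2) * dg)
  p <- 2 * stats::pt(-abs(tmod), df = df)
  label <- rep("ns", length(p))
  label[p < p_thresh & lfc > fc_thresh] <- "up"
  label[p < p_thresh & lfc < -fc_thresh] <- "down"
  out <- data.frame(gene = rownames(expr) %||% seq_along(p),
                    log2fc = lfc, t_mod = tmod, df = df, p = p,
                    label = label, stringsAsFactors = FALSE)
  attr(out, "prior_df") <- prior_df
  attr(out, "prior_var") <- prior_var
  class(out) <- c("de_result", "data.frame")
  out
}

# moment-match a scaled inverse-chi-square prior to the gene variances via
# the log-variance distribution (mean / trigamma matching)
fit_variance_prior <- function(s2, dg) {
  z <- log(s2)
  e <- z - digamma(dg / 2) + log(dg / 2)
  ve <- stats::var(e)
  gap <- ve - trigamma(dg / 2)
  if (is.na(gap) || gap <= 0)
    return(list(df = Inf, var = mean(s2)))
  d0 <- 2 * trigamma_inverse(gap)
  s0 <- exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
  list(df = d0, var = s0)
}

trigamma_inverse <- function(y) {
  if (y > 1e7) return(1 / sqrt(y))
  if (y < 1e-6) return(1 / y)
  x <- 0.5 + 1 / y
  for (i in 1:50) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, deriv = 2)
    x <- x + dif
    if (-dif / x < 1e-8) break
  }
  x
}

#' Gene-set overlap test from counts
#'
#' Hypergeometric / Fisher test of the overlap of two gene sets in a
#' background universe of size `N`. The one-sided enrichment p is the
#' hypergeometric upper tail `P(X >= k)`; the two-sided p is Fisher's exact
#' test. Both are reported; `pc = min(1, m * p)` uses the side selected by
#' `alternative`.
#'
#' @param k overlap count; `nA`, `nB` set sizes; `N` background size.
#' @param m number of comparisons for the Bonferroni correction.
#' @param alternative `"greater"` (enrichment, default) or `"two.sided"`.
#' @return list of class `"overlap_result"`: k, nA, nB, N, odds_ratio,
#'   p (selected side), p_greater, p_two_sided, pc, m, gene_ratio
#'   (`k / nB`), background_fraction (`k / N`).
#' @export
fisher_overlap_counts <- function(k, nA, nB, N, m = 1,
                                  alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  if (k > min(nA, nB) || nA > N || nB > N || k < 0 || k < nA + nB - N)
    stop_mstx("fisher_overlap_counts: inconsistent counts")
  tab <- matrix(c(k, nA - k, nB - k, N - nA - nB + k), 2, 2)
  p_greater <- stats::phyper(k - 1, nA, N - nA, nB, lower.tail = FALSE)
  p_two <- stats::fisher.test(tab)$p.value
  p <- if (alternative == "greater") p_greater else p_two
  denom <- (nA - k) * (nB - k)
  or <- if (denom == 0) Inf else k * (N - nA - nB + k) / denom
  structure(list(k = k, nA = nA, nB = nB, N = N,
                 odds_ratio = or, p = p,
                 p_greater = p_greater, p_two_sided = p_two,
                 pc = min(1, m * p), m = m,
                 gene_ratio = k / nB, background_fraction = k / N,
                 alternative = alternative),
            class = "overlap_result")
}

#' Gene-set overlap test
#'
#' Set-based front end of [fisher_overlap_counts()]: both sets must be
#' subsets of the background universe.
#'
#' @param setA,setB character gene vectors.
#' @param background character gene universe.
#' @param m,alternative see [fisher_overlap_counts()].
#' @return an `"overlap_result"`, plus `genes` (the overlapping symbols).
#' @export
fisher_overlap <- function(setA, setB, background, m = 1,
                           alternative = c("greater", "two.sided")) {
  setA <- unique(setA); setB <- unique(setB); background <- unique(background)
  out_of <- c(setdiff(setA, background), setdiff(setB, background))
  if (length(out_of))
    stop_mstx("fisher_overlap: gene(s) not in background: %s",
              paste(utils::head(out_of, 5), collapse = ", "))
  ov <- intersect(setA, setB)
  res <- fisher_overlap_counts(length(ov), length(setA), length(setB),
                               length(background), m = m,
                               alternative = alternative)
  res$genes <- ov
  res
}

#' Formatted overlap ratios
#'
#' Reporting conventions for overlap tables: the background fraction as a
#' percentage rounded to one decimal, the gene ratio to two significant
#' figures.
#'
#' @param res an `"overlap_result"`.
#' @return list: background_pct, gene_ratio.
#' @export
overlap_summary <- function(res) {
  stopifnot(inherits(res, "overlap_result"))
  list(background_pct = round(res$background_fraction * 100, 1),
       gene_ratio = signif(res$gene_ratio, 2))
}

#' Over-representation analysis over a gene-set collection
#'
#' [fisher_overlap()] of the query against every set of a named collection,
#' Bonferroni-corrected across the collection, sorted by corrected p.
#'
#' @param query character gene vector.
#' @param collection named list of character gene vectors (e.g. from
#'   [read_gmt()]).
#' @param background character gene universe.
#' @param m Bonferroni factor; defaults to the collection size.
#' @param alternative passed to [fisher_overlap()].
#' @return data.frame: set, k, nA, nB, N, odds_ratio, p, p_two_sided, pc,
#'   gene_ratio; one row per set, sorted by pc then p.
#' @export
ora_collection <- function(query, collection, background, m = length(collection),
                           alternative = c("greater", "two.sided")) {
  if (!length(collection)) stop_mstx("ora_collection: empty collection")
  if (is.null(names(collection)))
    stop_mstx("ora_collection: collection must be named")
  alternative <- match.arg(alternative)
  rows <- lapply(names(collection), function(nm) {
    r <- fisher_overlap(collection[[nm]], query, background, m = m,
                        alternative = alternative)
    data.frame(set = nm, k = r$k, nA = r$nA, nB = r$nB, N = r$N,
               odds_ratio = r$odds_ratio, p = r$p,
               p_two_sided = r$p_two_sided, pc = r$pc,
               gene_ratio = r$gene_ratio, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(out$pc, out$p), , drop = FALSE]
}
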