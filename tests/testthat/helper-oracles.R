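# Independent brute-force oracles and small fixture builders shared across
# the suite. Oracles are deliberately naive (loops, enumeration, closed
# forms) and never call the code paths they check.

# textbook Pearson correlation of two vectors, sample sd with n-1
pearson_oracle <- function(a, b) {
  n <- length(a)
  ma <- sum(a) / n; mb <- sum(b) / n
  num <- sum((a - ma) * (b - mb))
  num / sqrt(sum((a - ma)^2) * sum((b - mb)^2))
}

# region x region similarity by double loop
ms_matrix_oracle <- function(feat) {
  R <- nrow(feat)
  m <- matrix(NA_real_, R, R, dimnames = list(rownames(feat), rownames(feat)))
  for (i in seq_len(R)) for (j in seq_len(R)) {
    if (i != j) m[i, j] <- pearson_oracle(feat[i, ], feat[j, ])
  }
  m
}

# direct step-up BH: q_(i) = min over j >= i of p_(j) * m / j
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  for (i in seq_len(m)) {
    q[o[i]] <- min(1, min(p[o[i:m]] * m / (i:m)))
  }
  q
}

# hypergeometric upper tail by full pmf enumeration
hyper_enum_oracle <- function(k, nA, nB, N) {
  kmax <- min(nA, nB)
  pm <- vapply(0:kmax, function(x)
    choose(nA, x) * choose(N - nA, nB - x) / choose(N, nB), numeric(1))
  sum(pm[(k:kmax) + 1])
}

# one-component PLS weights for a univariate response: normalized
# covariance vector, by explicit per-gene loop
pls_w_oracle <- function(X, y, scale_genes = TRUE) {
  y <- y[rownames(X)]
  yc <- y - mean(y)
  w <- numeric(ncol(X))
  for (j in seq_len(ncol(X))) {
    xj <- X[, j] - mean(X[, j])
    if (scale_genes) xj <- xj / stats::sd(X[, j])
    w[j] <- sum(xj * yc)
  }
  w / sqrt(sum(w^2))
}

# first-order partial correlation via the 3x3 correlation-matrix identity
partial_cor_oracle <- function(x, y, z) {
  rxy <- stats::cor(x, y); rxz <- stats::cor(x, z); ryz <- stats::cor(y, z)
  (rxy - rxz * ryz) / sqrt((1 - rxz^2) * (1 - ryz^2))
}

# small cohort configuration for fast tests
tiny_config <- function(...) {
  defaults <- list(n_per_group = 16, n_regions = 40, n_left_regions = 20,
                   n_genes = 120, n_batches = 1, seed = 1)
  args <- utils::modifyList(defaults, list(...))
  do.call(simulation_config, args)
}

# cohort -> regional MS table -> tmap, the standard chain
run_chain <- function(cfg, covariates = c("age", "sex", "education")) {
  coh <- generate_cohort(cfg)
  if (length(unique(coh$meta$batch)) > 1) coh <- harmonize_features(coh)
  coh <- zscore_features(coh)
  reg <- regional_ms_table(coh)
  list(cohort = coh, regional = reg,
       tmap = ms_tmap(reg, coh$meta, covariates = covariates))
}
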