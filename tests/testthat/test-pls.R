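# First-component PLS, bootstrap Z scores, thresholding, expression maps.

make_xy <- function(n = 30, g = 12, seed = 1) {
  set.seed(seed)
  X <- matrix(rnorm(n * g), n, g,
              dimnames = list(paste0("R", 1:n), paste0("G", 1:g)))
  y <- setNames(rnorm(n) + 0.5 * X[, 1], rownames(X))
  list(X = X, y = y)
}

test_that("pls1_fit equals the closed-form covariance-vector oracle", {
  d <- make_xy()
  fit <- pls1_fit(d$X, d$y)
  wo <- pls_w_oracle(d$X, d$y)
  if (sum(wo * fit$w) < 0) wo <- -wo   # oracle is sign-free
  expect_equal(unname(fit$w), wo, tolerance = 1e-12)
  expect_equal(sum(fit$w^2), 1, tolerance = 1e-12)
  expect_gt(cor(fit$scores, d$y), 0)   # sign convention
  expect_equal(fit$varexp_y, cor(fit$scores, d$y)^2, tolerance = 1e-12)
  # unscaled variant agrees with its oracle too
  fit2 <- pls1_fit(d$X, d$y, scale_genes = FALSE)
  wo2 <- pls_w_oracle(d$X, d$y, scale_genes = FALSE)
  if (sum(wo2 * fit2$w) < 0) wo2 <- -wo2
  expect_equal(unname(fit2$w), wo2, tolerance = 1e-12)
})

test_that("single-gene X reduces to the squared correlation", {
  d <- make_xy(g = 1)
  fit <- pls1_fit(d$X, d$y)
  expect_equal(abs(unname(fit$w)), 1)
  expect_equal(fit$varexp_y, cor(d$X[, 1], d$y)^2, tolerance = 1e-12)
})

test_that("alignment is by region id, zero-variance genes are dropped", {
  d <- make_xy()
  # shuffled response order must not matter
  fit1 <- pls1_fit(d$X, d$y)
  fit2 <- pls1_fit(d$X, sample(d$y))
  expect_equal(fit1$w, fit2$w, tolerance = 1e-12)
  expect_error(pls1_fit(d$X, d$y[-1]), "missing for region")
  Xz <- d$X; Xz[, 3] <- 2
  expect_warning(fitz <- pls1_fit(Xz, d$y), "zero-variance")
  expect_identical(fitz$dropped, "G3")
  expect_false("G3" %in% names(fitz$w))
})

test_that("permuted-response variance explained behaves like chance", {
  set.seed(7)
  X <- matrix(rnorm(40 * 10), 40, 10,
              dimnames = list(paste0("R", 1:40), paste0("G", 1:10)))
  y <- setNames(X[, 1] + 0.5 * rnorm(40), rownames(X))  # strong coupling
  obs <- pls1_fit(X, y)$varexp_y
  set.seed(99)
  null <- replicate(100, {
    yp <- setNames(sample(y), names(y))
    pls1_fit(X, yp)$varexp_y
  })
  # observed (coupled) beats the permutation null decisively
  expect_gt(obs, quantile(null, 0.95))
  # null varexp concentrates near k/n
  expect_lt(abs(mean(null) - 10 / 40), 0.12)
})

test_that("bootstrap z is deterministic, finite and rescaling-invariant", {
  d <- make_xy(n = 25, g = 8, seed = 3)
  fit <- pls1_fit(d$X, d$y)
  b1 <- pls_bootstrap_z(fit, d$X, d$y, B = 200, seed = 42)
  b2 <- pls_bootstrap_z(fit, d$X, d$y, B = 200, seed = 42)
  expect_identical(b1$z, b2$z)
  expect_true(all(is.finite(b1$z)))
  # z is invariant to rescaling the response
  fit3 <- pls1_fit(d$X, 3.7 * d$y)
  b3 <- pls_bootstrap_z(fit3, d$X, 3.7 * d$y, B = 200, seed = 42)
  expect_equal(b1$z, b3$z, tolerance = 1e-10)
  expect_error(pls_bootstrap_z(fit, d$X, d$y, B = 50), ">= 100")
})

test_that("flipping the response sign swaps the signed gene sets exactly", {
  d <- make_xy(n = 30, g = 15, seed = 5)
  fit <- pls_bootstrap_z(pls1_fit(d$X, d$y), d$X, d$y, B = 200, seed = 1)
  yneg <- -d$y
  fitn <- pls_bootstrap_z(pls1_fit(d$X, yneg), d$X, yneg, B = 200, seed = 1)
  s <- threshold_gene_sets(fit, z_crit = 1.5)
  sn <- threshold_gene_sets(fitn, z_crit = 1.5)
  expect_setequal(s$pos, sn$neg)
  expect_setequal(s$neg, sn$pos)
})

test_that("the Bonferroni Z threshold reproduces 4.72 for 20,737 genes", {
  expect_equal(bonferroni_z_crit(20737), 4.72)
  # definition: smallest two-decimal value with tail <= alpha/n
  z <- bonferroni_z_crit(20737)
  expect_lte(2 * pnorm(-z), 0.05 / 20737)
  expect_gt(2 * pnorm(-(z - 0.01)), 0.05 / 20737)
  expect_equal(bonferroni_z_crit(1), 1.96)
})

test_that("thresholding uses strict inequalities and handles empty sets", {
  fit <- structure(list(z = c(g1 = 5, g2 = -5, g3 = 4.71),
                        w = c(g1 = .5, g2 = -.5, g3 = .4)),
                   class = "pls_result")
  s <- threshold_gene_sets(fit, z_crit = 4.72)
  expect_identical(s$pos, "g1")
  expect_identical(s$neg, "g2")
  fit0 <- structure(list(z = c(a = 0, b = 0), w = c(a = 0, b = 0)),
                    class = "pls_result")
  s0 <- threshold_gene_sets(fit0, z_crit = 2)
  expect_length(s0$pos, 0)
  expect_length(s0$neg, 0)
})

test_that("null genes essentially never cross the Bonferroni threshold", {
  set.seed(31)
  n <- 40
  X <- matrix(rnorm(n * 30), n, 30,
              dimnames = list(paste0("R", 1:n), paste0("G", 1:30)))
  y <- setNames(rnorm(n), rownames(X))
  fit <- pls_bootstrap_z(pls1_fit(X, y), X, y, B = 300, seed = 8)
  expect_equal(sum(abs(fit$z) > 4.72), 0)
})

test_that("geneset_expression_map and spatial_correlation behave", {
  d <- make_xy(n = 30, g = 10, seed = 9)
  # single gene: map is that gene's standardized profile, r its correlation
  mp <- geneset_expression_map(d$X, "G1")
  expect_equal(unname(mp), as.numeric(scale(d$X[, "G1"])), tolerance = 1e-12)
  sc <- spatial_correlation(mp, d$y)
  expect_equal(sc$r, cor(d$X[, "G1"], d$y), tolerance = 1e-12)
  expect_error(geneset_expression_map(d$X, character()), "empty")
  expect_error(geneset_expression_map(d$X, "nope"), "unknown")
  # null sets give uniform p over replicates
  set.seed(77)
  ps <- replicate(200, {
    X <- matrix(rnorm(20 * 5), 20, 5,
                dimnames = list(paste0("R", 1:20), paste0("G", 1:5)))
    y <- setNames(rnorm(20), rownames(X))
    spatial_correlation(geneset_expression_map(X, colnames(X)), y)$p
  })
  expect_gt(ks.test(ps, "punif")$p.value, 0.01)
})
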