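# Regional group contrasts, FDR, subset means, partial correlation,
# demographics.

test_that("with no covariates the regional T equals the pooled two-sample t", {
  ch <- run_chain(tiny_config(seed = 1), covariates = character())
  tt <- apply(ch$regional, 2, function(v) {
    unname(t.test(v[ch$cohort$meta$group == "case"],
                  v[ch$cohort$meta$group == "control"],
                  var.equal = TRUE)$statistic)
  })
  expect_equal(ch$tmap$T, unname(tt), tolerance = 1e-10)
})

test_that("tmap output satisfies its invariants", {
  ch <- run_chain(tiny_config(seed = 2))
  tm <- ch$tmap
  expect_true(all(tm$q >= tm$p - 1e-15))
  expect_true(all(abs(tm$direction[tm$T != 0]) == 1))
  o <- order(tm$p)
  expect_true(all(diff(tm$q[o]) >= -1e-15))
  # rank-deficient design named
  meta2 <- ch$cohort$meta
  meta2$age2 <- meta2$age
  expect_error(ms_tmap(ch$regional, meta2, covariates = c("age", "age2")),
               "collinear")
})

test_that("fdr_bh matches the step-up oracle and p.adjust", {
  expect_equal(fdr_bh(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(fdr_bh(rep(0.2, 5)), rep(0.2, 5))
  expect_equal(fdr_bh(0.123), 0.123)   # single p unchanged
  set.seed(12)
  p <- runif(100)
  expect_equal(fdr_bh(p), bh_oracle(p))
  expect_equal(fdr_bh(p), p.adjust(p, "BH"))
  expect_error(fdr_bh(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("mean_ms_subset averages the named regions", {
  reg <- matrix(c(0.2, 0.4, 0.6, 0.1, 0.3, 0.5), nrow = 2, byrow = TRUE,
                dimnames = list(c("s1", "s2"), c("R1", "R2", "R3")))
  expect_equal(unname(mean_ms_subset(reg, "R2")), c(0.4, 0.3))
  expect_equal(unname(mean_ms_subset(reg, c("R1", "R2"))), c(0.3, 0.2))
  expect_error(mean_ms_subset(reg, character()), "empty")
  expect_error(mean_ms_subset(reg, "R9"), "unknown")
})

test_that("partial_correlation reduces to Pearson without covariates and is
           exact against the 3x3 correlation-matrix identity", {
  set.seed(3)
  x <- rnorm(60); y <- 0.4 * x + rnorm(60); z <- rnorm(60) + 0.3 * x
  pc0 <- partial_correlation(x, y)
  expect_equal(pc0$r, cor(x, y), tolerance = 1e-12)
  expect_equal(pc0$p, cor.test(x, y)$p.value, tolerance = 1e-12)
  pc1 <- partial_correlation(x, y, data.frame(z = z))
  expect_equal(pc1$r, partial_cor_oracle(x, y, z), tolerance = 1e-10)
  # symmetry and affine invariance of covariates
  expect_equal(partial_correlation(y, x, data.frame(z = z))$r, pc1$r,
               tolerance = 1e-12)
  expect_equal(partial_correlation(x, y, data.frame(z = 3 * z - 5))$r, pc1$r,
               tolerance = 1e-12)
  # y = x gives r = 1 regardless of covariates
  expect_equal(partial_correlation(x, x, data.frame(z = z))$r, 1,
               tolerance = 1e-12)
})

test_that("partial_correlation drops incomplete cases and guards df", {
  x <- c(rnorm(30), NA); y <- rnorm(31); z <- rnorm(31)
  pc <- partial_correlation(x, y, data.frame(z = z))
  expect_equal(pc$n_effective, 30)
  expect_error(partial_correlation(rnorm(3), rnorm(3), data.frame(z = rnorm(3))),
               "n_effective")
})

test_that("group_compare reproduces the printed demographics statistics", {
  # pooled t from the printed MMSE summaries
  tt <- pooled_t_summary(22.92, 3.13, 106, 28.57, 1.73, 106)
  expect_equal(tt$t, -16.26, tolerance = 1e-3)
  expect_equal(pooled_t_summary(1, 1, 10, 1, 1, 10)$t, 0)
  # identical 63/43 sex split: chi-squared 0, p 1
  meta <- data.frame(
    group = rep(c("case", "control"), each = 106),
    sex = c(rep(c("M", "F"), c(63, 43)), rep(c("M", "F"), c(63, 43))),
    age = rnorm(212, 75, 8))
  gc <- group_compare(meta)
  sex_row <- gc[gc$variable == "sex", ]
  expect_equal(sex_row$statistic, 0)
  expect_equal(sex_row$p, 1)
  expect_equal(gc[gc$variable == "age", "type"], "continuous")
  expect_error(group_compare(data.frame(group = "case", age = 1)),
               "both groups")
})

test_that("null simulation keeps regional type-I error near nominal", {
  # zero planted effect; fraction of regional p < 0.05 pooled over 200
  # replicates of a small cohort should sit at ~5%
  fracs <- vapply(1:200, function(i) {
    ch <- run_chain(tiny_config(seed = 1000 + i, n_per_group = 10,
                                n_regions = 24, n_left_regions = 12,
                                effect_size = 0),
                    covariates = character())
    mean(ch$tmap$p < 0.05)
  }, numeric(1))
  expect_lt(abs(mean(fracs) - 0.05), 0.02)
  # and the FDR selection stays controlled: expected false discoveries rare
  expect_lt(mean(vapply(1:20, function(i) {
    ch <- run_chain(tiny_config(seed = 3000 + i, n_per_group = 10,
                                n_regions = 24, n_left_regions = 12,
                                effect_size = 0),
                    covariates = character())
    sum(ch$tmap$q < 0.05)
  }, numeric(1))), 0.5)
})
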