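# Moderated DE, overlap tests, over-representation.

make_de <- function(G = 300, n = 8, lfc = c(), seed = 1) {
  set.seed(seed)
  expr <- matrix(rnorm(G * 2 * n, sd = 0.5), G, 2 * n,
                 dimnames = list(sprintf("g%03d", 1:G), NULL))
  for (g in names(lfc)) expr[g, 1:n] <- expr[g, 1:n] + lfc[[g]]
  list(expr = expr, group = rep(c("case", "control"), each = n))
}

test_that("moderated_de reduces to the per-gene t at prior_df = 0 and to a
           common-variance t at prior_df = Inf", {
  d <- make_de()
  de0 <- moderated_de(d$expr, d$group, prior_df = 0)
  tt <- apply(d$expr, 1, function(v)
    unname(t.test(v[d$group == "case"], v[d$group == "control"],
                  var.equal = TRUE)$statistic))
  expect_equal(de0$t_mod, unname(tt), tolerance = 1e-10)
  v0 <- 0.23
  deI <- moderated_de(d$expr, d$group, prior_df = Inf, prior_var = v0)
  m1 <- rowMeans(d$expr[, d$group == "case"])
  m2 <- rowMeans(d$expr[, d$group == "control"])
  expect_equal(deI$t_mod, unname((m1 - m2) / sqrt(v0 * (1 / 8 + 1 / 8))),
               tolerance = 1e-10)
})

test_that("moderated_de agrees with the limma oracle on a fixture", {
  skip_if_not_installed("limma")
  d <- make_de(seed = 4)
  design <- cbind(1, d$group == "case")
  lf <- limma::eBayes(limma::lmFit(d$expr, design))
  de <- moderated_de(d$expr, d$group)
  expect_equal(attr(de, "prior_df"), lf$df.prior, tolerance = 1e-4)
  expect_equal(attr(de, "prior_var"), lf$s2.prior, tolerance = 1e-4)
  expect_equal(de$t_mod, unname(lf$t[, 2]), tolerance = 1e-6)
  expect_equal(de$p, unname(lf$p.value[, 2]), tolerance = 1e-6)
  expect_equal(de$log2fc, unname(lf$coefficients[, 2]), tolerance = 1e-10)
})

test_that("screening labels follow the thresholds", {
  d <- make_de(lfc = list(g001 = 2, g002 = -2), seed = 2)
  de <- moderated_de(d$expr, d$group)
  expect_identical(de$label[de$gene == "g001"], "up")
  expect_identical(de$label[de$gene == "g002"], "down")
  expect_true(all(de$label == "ns" |
                    (de$p < 0.01 & abs(de$log2fc) > 1)))
  # label invariant: up iff p < thr and lfc > fc_thr
  expect_setequal(de$gene[de$label == "up"],
                  de$gene[de$p < 0.01 & de$log2fc > 1])
  d$expr[5, ] <- 1
  expect_error(moderated_de(d$expr, d$group), "zero variance")
})

test_that("null DE data keeps the p < 0.01 fraction near nominal", {
  fracs <- vapply(1:20, function(i) {
    d <- make_de(G = 2000, seed = 100 + i)
    mean(moderated_de(d$expr, d$group)$p < 0.01)
  }, numeric(1))
  expect_lt(abs(mean(fracs) - 0.01), 0.004)
})

test_that("fisher_overlap matches exhaustive enumeration on small universes", {
  expect_equal(fisher_overlap_counts(3, 5, 4, 20)$p,
               hyper_enum_oracle(3, 5, 4, 20), tolerance = 1e-12)
  # property sweep over N <= 30
  set.seed(21)
  for (rep in 1:40) {
    N <- sample(5:30, 1)
    nA <- sample(N, 1); nB <- sample(N, 1)
    krange <- max(0, nA + nB - N):min(nA, nB)
    k <- krange[sample.int(length(krange), 1)]
    r <- fisher_overlap_counts(k, nA, nB, N)
    expect_equal(r$p, hyper_enum_oracle(k, nA, nB, N), tolerance = 1e-10)
  }
  # k = 0 upper tail is 1
  r0 <- fisher_overlap_counts(0, 5, 4, 50, m = 3)
  expect_equal(r0$p, 1)
  expect_equal(r0$pc, 1)
})

test_that("pc is a capped multiple of p and monotone in m", {
  r1 <- fisher_overlap_counts(8, 20, 20, 100, m = 1)
  r4 <- fisher_overlap_counts(8, 20, 20, 100, m = 4)
  expect_gte(r1$pc, r1$p)
  expect_equal(r4$pc, min(1, 4 * r1$p))
  expect_gte(r4$pc, r1$pc)
})

test_that("set interface validates membership and counts the overlap", {
  bg <- sprintf("g%02d", 1:40)
  A <- bg[1:10]; B <- bg[6:20]
  r <- fisher_overlap(A, B, bg)
  expect_equal(r$k, 5)
  expect_setequal(r$genes, bg[6:10])
  expect_error(fisher_overlap(c(A, "alien"), B, bg), "alien")
})

test_that("overlap_summary applies the printed rounding conventions", {
  r <- fisher_overlap_counts(176, 1932, 1092, 20177, m = 2)
  s <- overlap_summary(r)
  expect_equal(s$background_pct, 0.9)
  expect_equal(overlap_summary(fisher_overlap_counts(195, 3000, 1770, 20177))$gene_ratio,
               0.11)
  expect_equal(overlap_summary(fisher_overlap_counts(33, 3000, 684, 20177))$gene_ratio,
               0.048)
})

test_that("ora_collection ranks a planted term first and handles edge cases", {
  bg <- sprintf("g%03d", 1:200)
  query <- bg[1:30]
  coll <- list(hit = bg[1:25], decoy1 = bg[101:140], decoy2 = bg[51:90])
  res <- ora_collection(query, coll, bg)
  expect_identical(res$set[1], "hit")
  expect_lt(res$pc[1], 0.05)
  # the full universe as a set has p = 1
  resU <- ora_collection(query, list(all = bg), bg)
  expect_equal(resU$p, 1)
  # query identical to a collection set attains the minimal enumerable p
  resI <- ora_collection(bg[1:10], list(same = bg[1:10]), bg[1:30])
  expect_equal(resI$p, hyper_enum_oracle(10, 10, 10, 30), tolerance = 1e-12)
  expect_error(ora_collection(query, list(), bg), "empty")
  expect_error(ora_collection(query, unname(coll), bg), "named")
})
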