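# Generator contracts: validation, determinism, planted structure.

test_that("simulation_config validates its invariants", {
  expect_s3_class(simulation_config(seed = 1), "simulation_config")
  expect_error(simulation_config(n_per_group = 0), "positive count")
  expect_error(simulation_config(coupling_strength = 1.5), "coupling_strength")
  expect_error(simulation_config(effect_regions_down = c(3, 5),
                                 effect_regions_up = c(5, 9)), "disjoint")
  expect_error(simulation_config(n_left_regions = 400), "exceeds")
  # defaults mirror the reference design: 10 decreased, 9 increased regions
  cfg <- simulation_config(seed = 1)
  expect_length(cfg$effect_regions_down, 10)
  expect_length(cfg$effect_regions_up, 9)
})

test_that("generation is bit-reproducible under a fixed seed and the seed
           splitting scheme isolates stages", {
  cfg <- tiny_config(seed = 33)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a, b)
  # different master seeds diverge
  expect_false(identical(a$features,
                         generate_cohort(tiny_config(seed = 34))$features))
  # stage seeds differ per stage label
  expect_false(child_seed(33, "cohort") == child_seed(33, "expression"))
  expect_identical(child_seed(33, "cohort"), child_seed(33, "cohort"))
})

test_that("cohort metadata is complete and group effects act as labelled", {
  cfg <- tiny_config(seed = 5, n_batches = 2)
  coh <- generate_cohort(cfg)
  expect_false(anyNA(coh$features))
  expect_setequal(names(coh$meta),
                  c("subject_id", "group", "age", "sex", "education",
                    "batch", "memory_score"))
  expect_equal(sum(coh$meta$group == "case"), cfg$n_per_group)
  sgn <- coh$truth$effect_sign
  expect_setequal(names(sgn)[sgn == -1],
                  sprintf("R%03d", cfg$effect_regions_down))
  expect_setequal(names(sgn)[sgn == 1],
                  sprintf("R%03d", cfg$effect_regions_up))
})

test_that("effect region ids out of range are rejected", {
  expect_error(generate_cohort(tiny_config(effect_regions_down = c(2, 99))),
               "out of range")
})

test_that("with a single batch the batch parameters are inert", {
  a <- generate_cohort(tiny_config(seed = 2, n_batches = 1,
                                   batch_shift = 0.5, batch_scale = 1.2))
  b <- generate_cohort(tiny_config(seed = 2, n_batches = 1,
                                   batch_shift = 3.0, batch_scale = 2.0))
  expect_identical(a$features, b$features)
})

test_that("zero effect size leaves groups exchangeable at the feature level", {
  coh <- generate_cohort(tiny_config(seed = 9, effect_size = 0))
  # grand feature means should not separate groups beyond noise
  case_mean <- mean(coh$features[coh$meta$group == "case", , ])
  ctrl_mean <- mean(coh$features[coh$meta$group == "control", , ])
  expect_lt(abs(case_mean - ctrl_mean), 0.05)
})

test_that("expression generator plants labelled spatial coupling", {
  cfg <- tiny_config(seed = 13, n_genes = 200)
  ch <- run_chain(cfg)
  ex <- generate_expression(ch$tmap, cfg)
  expect_false(anyNA(ex$expr))
  expect_equal(dim(ex$expr), c(cfg$n_left_regions, cfg$n_genes))
  lab <- ex$truth$coupling
  expect_setequal(unique(lab), c("pos", "neg", "null"))
  y <- ch$tmap$T[match(rownames(ex$expr), ch$tmap$region_id)]
  cors <- cor(ex$expr, y)
  # planted genes correlate with the T map in the labelled direction
  expect_gt(mean(cors[lab == "pos", ]), 0.5)
  expect_lt(mean(cors[lab == "neg", ]), -0.5)
  expect_lt(abs(mean(cors[lab == "null", ])), 0.15)
  # region mismatch is an error
  bad <- ch$tmap[-1, ]
  expect_error(generate_expression(bad, cfg), "cover")
})

test_that("single fully coupled gene attains the maximal |PLS1 weight|", {
  cfg <- tiny_config(seed = 21, n_genes = 50,
                     coupling_strength = 1, prop_pos_genes = 1 / 50,
                     prop_neg_genes = 0)
  ch <- run_chain(cfg)
  ex <- generate_expression(ch$tmap, cfg)
  y <- setNames(ch$tmap$T, ch$tmap$region_id)[rownames(ex$expr)]
  fit <- pls1_fit(ex$expr, y)
  coupled <- names(ex$truth$coupling)[ex$truth$coupling == "pos"]
  expect_identical(names(which.max(abs(fit$w))), coupled)
})

test_that("DE generator plants screenable fold changes and coupling overlap", {
  cfg <- tiny_config(seed = 17, n_genes = 400, n_de_up = 40, n_de_down = 50)
  ch <- run_chain(cfg)
  ex <- generate_expression(ch$tmap, cfg)
  de <- generate_de_dataset(cfg, coupling = ex$truth$coupling)
  expect_equal(dim(de$expr), c(400, 2 * cfg$n_de_samples))
  expect_equal(sum(de$truth$de == "down"), 50)
  # planted down set recruits from the negatively coupled genes
  neg <- names(ex$truth$coupling)[ex$truth$coupling == "neg"]
  expect_gt(length(intersect(names(de$truth$de)[de$truth$de == "down"], neg)),
            0.5 * length(neg) - 2)
  expect_error(generate_de_dataset(tiny_config(n_genes = 100, n_de_up = 80,
                                               n_de_down = 80)),
               "fewer genes")
})

test_that("cell-type generator plants concentrated markers", {
  cfg <- tiny_config(seed = 19, n_genes = 400, n_celltype_genes = 20)
  ct <- generate_celltype_profiles(cfg)
  expect_true(all(ct$profile >= 0))
  lab <- ct$truth$celltype
  for (ty in cfg$cell_types) {
    mk <- names(lab)[lab == ty]
    expect_length(mk, 20)
    others <- setdiff(colnames(ct$profile), ty)
    expect_true(all(ct$profile[mk, ty] >
                      apply(ct$profile[mk, others, drop = FALSE], 1, max)))
  }
  expect_error(generate_celltype_profiles(tiny_config(n_genes = 50,
                                                      n_celltype_genes = 20)),
               "fewer genes")
})
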