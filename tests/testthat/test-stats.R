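# shared null pseudobulk builder: NB counts, sample depth effects, no signal
null_pseudobulk <- function(n_frag = 48, n_genes = 300, seed = 1,
                            mu = 50, size = 2) {
  set.seed(seed)
  depth <- rep(c(1, 1.3, 0.8), length.out = n_frag)
  cnt <- matrix(rnbinom(n_genes * n_frag, mu = mu * rep(depth,
                                                        each = n_genes),
                        size = size), nrow = n_genes)
  pb <- t(cnt)
  dimnames(pb) <- list(sprintf("F%03d", seq_len(n_frag)),
                       sprintf("g%04d", seq_len(n_genes)))
  list(pb = pb, sample = paste0("S", rep(1:3, length.out = n_frag)))
}

test_that("zonated-gene detection finds planted slopes, not null genes", {
  cfg <- lobule_sim_config(n_fragments = 150)
  sim <- simulate_lobule_experiment(cfg, seed = 41)
  exp <- sim$experiment
  panel <- filter_landmarks(simulate_landmark_panel(cfg))
  zon <- bin_layers(compute_zc(fragment_pseudobulk(exp, "LEC", 5, "mean"),
                               panel), merge_extremes = TRUE)
  pb <- fragment_pseudobulk(exp, "LEC", 5, "sum")
  common <- intersect(rownames(pb), zon$fragment)
  de <- zonated_de(pb[common, , drop = FALSE],
                   zon$layer[match(common, zon$fragment)],
                   exp$fragments$sample[match(common,
                                              exp$fragments$fragment)])
  portal <- de[grepl("^pLM", de$gene), ]
  central <- de[grepl("^cLM", de$gene), ]
  expect_true(all(portal$fdr < 0.05 & portal$coef > 0))
  expect_true(all(central$fdr < 0.05 & central$coef < 0))
  expect_error(zonated_de(pb[common, ], rep("L4", length(common)),
                          rep("S1", length(common))), "2 layer levels")
})

test_that("a constant gene among null genes is not called zonated", {
  # comparable library sizes, random layers: identical counts carry no
  # layer signal
  np <- null_pseudobulk(n_frag = 48, n_genes = 200, seed = 7)
  pb <- np$pb
  pb[, "g0001"] <- 40L
  set.seed(8)
  layers <- sample(factor(c("L1-L3", "L4", "L5", "L6", "L7", "L8-L10"),
                          ordered = TRUE), nrow(pb), TRUE)
  de <- zonated_de(pb, layers, np$sample, filter = FALSE)
  flat <- de[de$gene == "g0001", ]
  expect_gt(flat$p, 0.05)
  expect_lt(abs(flat$coef), 0.2)
})

test_that("two-group DE is sign-antisymmetric and finds planted folds", {
  np <- null_pseudobulk(seed = 5)
  groups <- rep(c("g1", "g2"), length.out = nrow(np$pb))
  pb <- np$pb
  # plant a 4-fold increase in g2 for ten genes
  planted <- paste0("g", sprintf("%04d", 1:10))
  pb[groups == "g2", planted] <- pb[groups == "g2", planted] * 4L
  de <- twogroup_de(pb, factor(groups, c("g1", "g2")), np$sample)
  hit <- de[de$gene %in% planted, ]
  expect_true(all(hit$fdr < 0.05 & hit$coef > 0))
  # swapped levels negate the coefficients exactly
  de_sw <- twogroup_de(pb, factor(groups, c("g2", "g1")), np$sample)
  expect_equal(de_sw$coef[match(de$gene, de_sw$gene)], -de$coef,
               tolerance = 1e-8)
  expect_error(twogroup_de(pb, rep("g1", nrow(pb)), np$sample),
               "two non-empty groups")
})

test_that("abundance testing recovers planted composition shifts", {
  cfg <- lobule_sim_config(n_fragments = 120, n_samples = 4,
                           proximal_frac = 0.4)
  sim <- simulate_lobule_experiment(cfg, seed = 23)
  groups <- sim$truth$proximity
  ab <- abundance_test(sim$experiment$cells, groups)
  met <- ab[ab$type == "metastatic", ]
  mac <- ab[ab$type == "macrophage", ]
  kc <- ab[ab$type == "KC", ]
  expect_true(met$fdr < 0.05 && met$coef > 0)  # proximal-enriched
  expect_gt(mac$coef, 0)
  expect_lt(kc$coef, 0)
  # doubling every count of one sample's units leaves cpm and the
  # group effect essentially unchanged (library-size normalization)
  ann2 <- sim$experiment$cells
  dup <- ann2[ann2$sample == "S1", ]
  dup$cell <- paste0(dup$cell, "_dup")
  ab2 <- abundance_test(rbind(ann2, dup), groups)
  expect_equal(ab2$coef[match(ab$type, ab2$type)], ab$coef,
               tolerance = 0.1)
})

test_that("covariate comparison matches exact rank-test behavior", {
  tab <- fragment_table(sprintf("F%d", 1:8))
  tab$size <- c(1, 2, 3, 4, 101, 102, 103, 104)
  tab$n_cells <- rep(5L, 8)
  g <- setNames(rep(c("a", "b"), each = 4), tab$fragment)
  out <- compare_fragment_covariates(tab, g)
  # disjoint supports at n=m=4: minimal attainable two-sided p = 2/70
  expect_equal(out$p[out$covariate == "size"], 2 / choose(8, 4),
               tolerance = 1e-12)
  expect_equal(out$mean_a[out$covariate == "size"], 2.5)
  # identical groups: p in the >= 0.99 region
  tab$size <- rep(c(10, 20, 30, 40), 2)
  out2 <- compare_fragment_covariates(tab, g, covariates = "size")
  expect_gte(out2$p, 0.99)
  expect_error(compare_fragment_covariates(tab, g["F1"]), "two non-empty")
})

test_that("downsampling preserves composition within sampling error", {
  sim <- simulate_lobule_experiment(lobule_sim_config(n_fragments = 40),
                                    seed = 31)
  exp <- sim$experiment
  n <- nrow(exp$cells)
  expect_identical(downsample_cells(exp, n, seed = 1)$cells, exp$cells)
  empty <- downsample_cells(exp, 0, seed = 1)
  expect_equal(nrow(empty$cells), 0)
  expect_error(downsample_cells(exp, n + 1), "exceeds")
  half <- downsample_cells(exp, floor(n / 2), seed = 2)
  expect_equal(validate_experiment(half), character())
  p0 <- prop.table(table(exp$cells$type))
  p1 <- prop.table(table(factor(half$cells$type, names(p0))))
  expect_true(all(abs(p1 - p0) < 4 * sqrt(p0 * (1 - p0) / nrow(half$cells))
                  + 0.01))
})

test_that("low-expression filtering matches a naive predicate oracle", {
  np <- null_pseudobulk(n_frag = 20, n_genes = 100, seed = 9, mu = 8)
  pb <- np$pb
  pb[, 1] <- 0L                      # all-zero gene must go
  pb[, 2] <- 10L                     # constant 10 must stay
  groups <- rep(c("a", "b"), 10)
  kept <- colnames(filter_low_expression(pb, groups))
  expect_false("g0001" %in% kept)
  expect_true("g0002" %in% kept)
  # naive predicate at equal library sizes: >=10 counts in >=70% of the
  # smallest group (edgeR evaluates the rule on cpm at the median library)
  pbe <- matrix(10L, 12, 4,
                dimnames = list(sprintf("F%d", 1:12),
                                sprintf("e%d", 1:4)))
  pbe[, 2] <- c(rep(10L, 6), rep(0L, 6))   # 50% of fragments
  pbe[, 3] <- 0L
  pbe[, 4] <- 9L
  keep2 <- colnames(filter_low_expression(pbe, rep(c("a", "b"), 6)))
  expect_true("e1" %in% keep2)
  expect_false("e2" %in% keep2)
  expect_false("e3" %in% keep2)
})

test_that("reported FDR equals a sort-based Benjamini-Hochberg oracle", {
  np <- null_pseudobulk(n_frag = 24, n_genes = 200, seed = 13)
  de <- twogroup_de(np$pb, rep(c("a", "b"), 12), np$sample,
                    filter = FALSE)
  expect_equal(de$fdr, bh_oracle(de$p), tolerance = 1e-12)
  # and on plain random p vectors
  set.seed(2)
  for (r in 1:5) {
    p <- runif(100)
    expect_equal(p.adjust(p, "BH"), bh_oracle(p), tolerance = 1e-12)
  }
})
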